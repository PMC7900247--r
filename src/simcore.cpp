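// Fixed-step implicit simulation core for the granular-layer microcircuit.
//
// Units: mV, ms, uS, nF, nA, mM.  Voltages are solved with a Crank-Nicolson
// linear step (conductances frozen over the step), Hodgkin-Huxley gates with
// the exponential-Euler update, and Markov schemes (allosteric Na channel,
// receptor kinetics) with backward Euler, which conserves total occupancy
// exactly and preserves positivity.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double FARADAY = 96485.3329; // C/mol

static double pget(const List& p, const char* nm) {
  return as<double>(p[nm]);
}

// ---------- generic rate forms ----------
static double linoid(double v, double A, double V0, double K) {
  double x = (v - V0) / K;
  if (std::fabs(x) < 1e-7) return A * K * (1.0 - x / 2.0);
  return A * (v - V0) / (std::exp(x) - 1.0);
}
static double expo(double v, double A, double V0, double K) {
  return A * std::exp((v - V0) / K);
}
static double sigm(double v, double A, double V0, double K) {
  return A / (1.0 + std::exp((v - V0) / K));
}

// ---------- channel state ----------
struct Chan {
  std::string type;
  int comp;
  double g;      // uS (total for the compartment)
  double e;      // mV
  double q;      // rate multiplier (Q10-resolved)
  std::vector<double> pv;  // kinetic constants, parsed once at build
  std::vector<double> x;   // gates or Markov occupancies
};

// parameter layout per channel type (parsed once from the R-side list)
static std::vector<std::string> chan_par_names(const std::string& type) {
  if (type == "na_allo")
    return { "Aalfa", "Valfa", "Abeta", "Vbeta", "Agamma", "Adelta",
             "Aepsilon", "Ateta", "Vteta", "ACon", "ACoff", "AOon", "AOoff",
             "n1", "n2", "n3", "n4" };
  if (type == "kv" || type == "kir")
    return { "Aa", "V0a", "Ka", "Ab", "V0b", "Kb" };
  if (type == "nap")
    return { "V0m", "Km", "tau_m", "Aon", "Aoff" };
  if (type == "km")
    return { "Aa", "V0a", "Ka", "Ab", "V0b", "Kb", "V0inf", "Kinf" };
  if (type == "ka")
    return { "Aaa", "V0aa", "Kaa", "Aba", "V0ba", "Kba",
             "Aab", "V0ab", "Kab", "Abb", "V0bb", "Kbb" };
  if (type == "kca")
    return { "Aa", "Ba", "Ka", "Ab", "Bb", "Kb" };
  if (type == "cahva")
    return { "Aas", "V0as", "Kas", "Abs", "V0bs", "Kbs",
             "Aau", "V0au", "Kau", "Abu", "V0bu", "Kbu" };
  if (type == "wbna")
    return { "Aam", "V0am", "Kam", "Abm", "V0bm", "Kbm",
             "Aah", "V0ah", "Kah", "Abh", "V0bh", "Kbh" };
  return {};
}

struct NaRates {
  double alfa, beta, gamma, delta, epsilon, teta;
  double Con, Coff, Oon, Ooff, a, b;
  double n1, n2, n3, n4;
};

static NaRates na_rates(const Chan& ch, double v) {
  NaRates r;
  const std::vector<double>& p = ch.pv;
  double q = ch.q;
  r.alfa = q * p[0] * std::exp(v / p[1]);
  r.beta = q * p[2] * std::exp(-v / p[3]);
  r.gamma = q * p[4];
  r.delta = q * p[5];
  r.epsilon = q * p[6];
  r.teta = q * p[7] * std::exp(-v / p[8]);
  r.Con = q * p[9];
  r.Coff = q * p[10];
  r.Oon = q * p[11];
  r.Ooff = q * p[12];
  r.a = std::pow(r.Oon / r.Con, 0.25);
  r.b = std::pow(r.Ooff / r.Coff, 0.25);
  r.n1 = p[13]; r.n2 = p[14]; r.n3 = p[15]; r.n4 = p[16];
  return r;
}

// 13-state allosteric Na scheme: C1-C5 (0-4), O (5), B (6), I1-I6 (7-12).
static arma::mat na_generator(const NaRates& r) {
  arma::mat A(13, 13, arma::fill::zeros);
  auto add = [&](int from, int to, double rate) {
    A(to, from) += rate;
    A(from, from) -= rate;
  };
  const double fa[4] = { r.n1, r.n2, r.n3, r.n4 };
  const double fb[4] = { r.n4, r.n3, r.n2, r.n1 };
  for (int i = 0; i < 4; ++i) {            // C1..C4 <-> C2..C5
    add(i, i + 1, fa[i] * r.alfa);
    add(i + 1, i, fb[i] * r.beta);
  }
  add(4, 5, r.gamma);  add(5, 4, r.delta);     // C5 <-> O
  add(5, 6, r.epsilon); add(6, 5, r.teta);     // O <-> B (open-blocked)
  add(5, 12, r.Oon);   add(12, 5, r.Ooff);     // O <-> I6
  for (int i = 0; i < 5; ++i) {            // C_i <-> I_i
    add(i, 7 + i, r.Con * std::pow(r.a, i));
    add(7 + i, i, r.Coff * std::pow(r.b, i));
  }
  for (int i = 0; i < 4; ++i) {            // I1..I4 <-> I2..I5
    add(7 + i, 8 + i, fa[i] * r.alfa * r.a);
    add(8 + i, 7 + i, fb[i] * r.beta * r.b);
  }
  add(11, 12, r.gamma * r.a); add(12, 11, r.delta * r.b);  // I5 <-> I6
  return A;
}

static arma::vec markov_steady(const arma::mat& A) {
  arma::mat M = A;
  M.row(0).ones();
  arma::vec rhs(A.n_rows, arma::fill::zeros);
  rhs(0) = 1.0;
  return arma::solve(M, rhs);
}

static void markov_backward_euler(std::vector<double>& x, const arma::mat& A,
                                  double dt) {
  arma::vec xv(x.size());
  for (size_t i = 0; i < x.size(); ++i) xv(i) = x[i];
  arma::mat M = arma::eye(x.size(), x.size()) - dt * A;
  arma::vec xn = arma::solve(M, xv);
  for (size_t i = 0; i < x.size(); ++i) x[i] = xn(i);
}

// exponential-Euler gate update from alpha/beta
static void gate_update(double& x, double alpha, double beta, double dt) {
  double tau = 1.0 / (alpha + beta);
  double inf = alpha * tau;
  x = inf + (x - inf) * std::exp(-dt / tau);
}

// HH-type rate evaluation per channel type; returns conductance factor and
// updates gates.  ca is the somatic Ca concentration (mM).
static double chan_open_frac(const Chan& ch) {
  const std::vector<double>& x = ch.x;
  if (ch.type == "leak") return 1.0;
  if (ch.type == "kv")   return std::pow(x[0], 4);
  if (ch.type == "ka")   return x[0] * x[0] * x[0] * x[1];
  if (ch.type == "kir")  return x[0];
  if (ch.type == "nap")  return x[0] * x[1];
  if (ch.type == "km")   return x[0];
  if (ch.type == "kca")  return x[0];
  if (ch.type == "cahva") return x[0] * x[0] * x[1];
  if (ch.type == "wbna") return x[0] * x[0] * x[0] * x[1];
  if (ch.type == "na_allo") return x[5];  // open state O
  stop("unknown channel type");
  return 0.0;
}

static void chan_rates(const Chan& ch, double v, double ca,
                       std::vector<double>& alpha, std::vector<double>& beta) {
  const std::vector<double>& p = ch.pv;
  double q = ch.q;
  if (ch.type == "kv") {
    alpha[0] = q * linoid(v, p[0], p[1], p[2]);
    beta[0]  = q * expo(v, p[3], p[4], p[5]);
  } else if (ch.type == "ka") {
    alpha[0] = q * sigm(v, p[0], p[1], p[2]);
    beta[0]  = q * sigm(v, p[3], p[4], p[5]);
    alpha[1] = q * sigm(v, p[6], p[7], p[8]);
    beta[1]  = q * sigm(v, p[9], p[10], p[11]);
  } else if (ch.type == "kir") {
    alpha[0] = q * expo(v, p[0], p[1], p[2]);
    beta[0]  = q * expo(v, p[3], p[4], p[5]);
  } else if (ch.type == "nap") {
    // fast activation toward its steady state; slow availability gate whose
    // on/off rates are the condition-controlled kinetic scale parameters
    double minf = 1.0 / (1.0 + std::exp((v - p[0]) / p[1]));
    alpha[0] = q * minf / p[2];
    beta[0]  = q * (1.0 - minf) / p[2];
    alpha[1] = q * p[4];   // A_off: recovery of the open pathway
    beta[1]  = q * p[3];   // A_on: occlusion of the open pathway
  } else if (ch.type == "km") {
    double aa = q * expo(v, p[0], p[1], p[2]);
    double bb = q * expo(v, p[3], p[4], p[5]);
    // separately specified steady state, tau from the rates
    double tau = 1.0 / (aa + bb);
    double inf = 1.0 / (1.0 + std::exp((v - p[6]) / p[7]));
    alpha[0] = inf / tau;
    beta[0] = (1.0 - inf) / tau;
  } else if (ch.type == "kca") {
    alpha[0] = q * p[0] / (1.0 + (p[1] / ca) * std::exp(-v * p[2]));
    beta[0]  = q * p[3] / (1.0 + ca / (p[4] * std::exp(-v * p[5])));
  } else if (ch.type == "wbna") {
    alpha[0] = q * linoid(v, p[0], p[1], p[2]);
    beta[0]  = q * expo(v, p[3], p[4], p[5]);
    alpha[1] = q * expo(v, p[6], p[7], p[8]);
    beta[1]  = q * sigm(v, p[9], p[10], p[11]);
  } else if (ch.type == "cahva") {
    alpha[0] = q * expo(v, p[0], p[1], p[2]);
    beta[0]  = q * expo(v, p[3], p[4], p[5]);
    alpha[1] = q * expo(v, p[6], p[7], p[8]);
    beta[1]  = q * expo(v, p[9], p[10], p[11]);
  }
}

static int chan_ngates(const std::string& type) {
  if (type == "leak") return 0;
  if (type == "ka" || type == "cahva" || type == "wbna" || type == "nap") return 2;
  if (type == "na_allo") return 13;
  return 1;
}

// ---------- receptor scheme instance ----------
struct Receptor {
  int ns;
  std::vector<int> open;
  std::vector<int> tr_from, tr_to, tr_lig;  // lig: 0 none, 1 ligand
  std::vector<double> tr_rate;
  double acc_direct, acc_spill;
  double e_rev, w_uS;            // weight in uS (multiplicity folded in)
  bool has_mg;
  double mg_mM, k_conc, k_v;
  std::vector<double> x;
};

static arma::mat receptor_generator(const Receptor& r, double cd, double cs) {
  arma::mat A(r.ns, r.ns, arma::fill::zeros);
  double conc = r.acc_direct * cd + r.acc_spill * cs;
  for (size_t i = 0; i < r.tr_rate.size(); ++i) {
    double rate = r.tr_rate[i] * (r.tr_lig[i] ? conc : 1.0);
    A(r.tr_to[i], r.tr_from[i]) += rate;
    A(r.tr_from[i], r.tr_from[i]) -= rate;
  }
  return A;
}

// ---------- synapse instance ----------
struct Synapse {
  std::string pre;   // "mf", "goc", "grc"
  std::string post;  // "grc", "goc"
  int post_comp;
  double mult;
  // presynaptic TM state
  double p, tau_rec, tau_facil, tau_i, delay;
  double R, E, I, u;
  double t_last;
  bool had_spike;
  // transmitter
  double amp_direct, dur_direct, amp_spill, tau_r, tau_d, spill_scale;
  double y_r, y_d;                       // spillover filter states
  std::vector<double> ev_t, ev_rel;      // direct-pulse events (onset times)
  std::vector<std::pair<double, double>> pending;  // scheduled (time, rel)
  std::vector<Receptor> receptors;
};

static void tm_relax(Synapse& s, double dt) {
  double a = 1.0 / s.tau_i, b = 1.0 / s.tau_rec;
  double E0 = s.E, I0 = s.I;
  s.E = E0 * std::exp(-a * dt);
  if (std::fabs(a - b) < 1e-12) {
    s.I = (I0 + E0 * a * dt) * std::exp(-b * dt);
  } else {
    s.I = I0 * std::exp(-b * dt) + E0 * (a / (a - b)) *
      (std::exp(-b * dt) - std::exp(-a * dt));
  }
  s.R = 1.0 - s.E - s.I;
  s.u *= std::exp(-dt / s.tau_facil);
}

static double tm_spike(Synapse& s, double t) {
  if (s.had_spike) tm_relax(s, t - s.t_last);
  s.u += s.p * (1.0 - s.u);
  double rel = s.u * s.R;
  s.R -= rel;
  s.E += rel;
  s.t_last = t;
  s.had_spike = true;
  return rel;
}

// schedule a presynaptic spike: release happens after the synaptic delay
static void syn_spike(Synapse& s, double t) {
  double rel = tm_spike(s, t);
  s.pending.push_back(std::make_pair(t + s.delay, rel));
}

// advance transmitter filters by one step, activating pending events
static void syn_step(Synapse& s, double t_new, double dt) {
  s.y_r *= std::exp(-dt / s.tau_r);
  s.y_d *= std::exp(-dt / s.tau_d);
  for (size_t i = 0; i < s.pending.size();) {
    if (s.pending[i].first <= t_new + 1e-9) {
      s.y_r += s.pending[i].second;
      s.y_d += s.pending[i].second;
      s.ev_t.push_back(s.pending[i].first);
      s.ev_rel.push_back(s.pending[i].second);
      s.pending.erase(s.pending.begin() + i);
    } else ++i;
  }
}

static double syn_conc_direct(const Synapse& s, double t) {
  double c = 0.0;
  for (size_t i = s.ev_t.size(); i-- > 0;) {
    double age = t - s.ev_t[i];
    if (age > s.dur_direct) break;  // events are time-ordered
    if (age >= 0.0) c += s.ev_rel[i] * s.amp_direct;
  }
  return c;
}
static double syn_conc_spill(const Synapse& s) {
  return s.spill_scale * (s.y_d - s.y_r);
}

// ---------- cell assembly ----------
struct Cell {
  int ncomp;
  std::vector<int> parent;
  std::vector<double> cm;    // nF
  std::vector<double> gax;   // uS to parent
  std::vector<Chan> chans;
  std::vector<double> v;
  // Ca pool (optional, single compartment)
  bool has_ca;
  int ca_comp;
  double ca, ca0, ca_beta, ca_shell_cm3;
  // spike detection
  double v_prev_soma;
  bool armed;
};

static Cell build_cell(const List& spec) {
  Cell c;
  NumericVector cm = spec["cm_nF"];
  IntegerVector par = spec["parent"];
  NumericVector gax = spec["g_ax_uS"];
  c.ncomp = cm.size();
  c.cm = as<std::vector<double>>(cm);
  c.parent = as<std::vector<int>>(par);
  c.gax = as<std::vector<double>>(gax);
  c.v.assign(c.ncomp, -70.0);
  List chl = spec["channels"];
  for (int i = 0; i < chl.size(); ++i) {
    List e = chl[i];
    Chan ch;
    ch.type = as<std::string>(e["type"]);
    ch.comp = as<int>(e["comp"]);
    ch.g = as<double>(e["g_uS"]);
    ch.e = as<double>(e["e_mV"]);
    ch.q = as<double>(e["q"]);
    if (e.containsElementNamed("params")) {
      List prm = as<List>(e["params"]);
      for (const std::string& nm : chan_par_names(ch.type)) {
        ch.pv.push_back(pget(prm, nm.c_str()));
      }
    }
    ch.x.assign(chan_ngates(ch.type), 0.0);
    c.chans.push_back(ch);
  }
  c.has_ca = as<bool>(spec["has_ca"]);
  if (c.has_ca) {
    List cp = spec["ca_pool"];
    c.ca_comp = as<int>(cp["comp"]);
    c.ca0 = as<double>(cp["ca0_mM"]);
    c.ca_beta = as<double>(cp["beta_per_ms"]);
    c.ca_shell_cm3 = as<double>(cp["shell_cm3"]);
  }
  c.ca = c.has_ca ? as<double>(as<List>(spec["ca_pool"])["ca0_mM"]) : 1e-4;
  c.armed = true;
  return c;
}

static void cell_init_states(Cell& c, double v0) {
  for (int i = 0; i < c.ncomp; ++i) c.v[i] = v0;
  for (auto& ch : c.chans) {
    if (ch.type == "leak") continue;
    if (ch.type == "na_allo") {
      arma::vec ss = markov_steady(na_generator(na_rates(ch, v0)));
      for (int i = 0; i < 13; ++i) ch.x[i] = ss(i);
    } else {
      int ng = chan_ngates(ch.type);
      std::vector<double> a(ng), b(ng);
      chan_rates(ch, v0, c.ca, a, b);
      for (int g = 0; g < ng; ++g) ch.x[g] = a[g] / (a[g] + b[g]);
    }
  }
  c.v_prev_soma = v0;
}

// advance channel states given (new) voltages; returns false on non-finite
static bool cell_update_states(Cell& c, double dt) {
  double i_ca_nA = 0.0;
  for (auto& ch : c.chans) {
    double v = c.v[ch.comp];
    if (ch.type == "leak") continue;
    if (ch.type == "na_allo") {
      markov_backward_euler(ch.x, na_generator(na_rates(ch, v)), dt);
    } else {
      int ng = chan_ngates(ch.type);
      std::vector<double> a(ng), b(ng);
      chan_rates(ch, v, c.ca, a, b);
      for (int g = 0; g < ng; ++g) gate_update(ch.x[g], a[g], b[g], dt);
    }
    if (ch.type == "cahva" && c.has_ca) {
      i_ca_nA += ch.g * chan_open_frac(ch) * (v - ch.e);
    }
  }
  if (c.has_ca) {
    // shell model: influx from Ca current, first-order pump/buffer decay
    double influx = -i_ca_nA * 1e-6 / (2.0 * FARADAY * c.ca_shell_cm3); // mM/ms
    double inf = c.ca0 + influx / c.ca_beta;
    c.ca = inf + (c.ca - inf) * std::exp(-dt * c.ca_beta);
    if (c.ca < 1e-8) c.ca = 1e-8;
  }
  for (auto& ch : c.chans)
    for (double xv : ch.x)
      if (!std::isfinite(xv)) return false;
  for (double vv : c.v) if (!std::isfinite(vv)) return false;
  return true;
}

// gating sanity for debug mode: all gates / occupancies within [0,1] slack
static bool cell_gates_ok(const Cell& c) {
  for (const auto& ch : c.chans)
    for (double xv : ch.x)
      if (xv < -1e-6 || xv > 1.0 + 1e-6) return false;
  return true;
}

// total ionic current (nA, outward positive) at clamped voltage
static double cell_ionic_current(const Cell& c) {
  double i = 0.0;
  for (const auto& ch : c.chans) {
    i += ch.g * chan_open_frac(ch) * (c.v[ch.comp] - ch.e);
  }
  return i;
}

// ---------- main driver ----------

// [[Rcpp::export]]
List cpp_sim_circuit(List grc_spec, List goc_spec, List syn_list, List proto) {
  const double dt = as<double>(proto["dt"]);
  const double duration = as<double>(proto["duration"]);
  const std::string mode = as<std::string>(proto["mode"]);
  const std::string clamp_cell =
    proto.containsElementNamed("clamp_cell") ?
      as<std::string>(proto["clamp_cell"]) : "grc";
  const double holding = proto.containsElementNamed("holding") ?
    as<double>(proto["holding"]) : -70.0;
  const double v_init = proto.containsElementNamed("v_init") ?
    as<double>(proto["v_init"]) : (mode == "vc" ? holding : -70.0);
  const double i_bias = proto.containsElementNamed("i_bias_pA") ?
    as<double>(proto["i_bias_pA"]) * 1e-3 : 0.0;  // nA
  double step_amp = 0.0, step_on = 0.0, step_off = 0.0;
  if (proto.containsElementNamed("step")) {
    List st = proto["step"];
    step_amp = as<double>(st["amp_pA"]) * 1e-3;
    step_on = as<double>(st["t_on"]);
    step_off = as<double>(st["t_off"]);
  }
  std::vector<double> mf_times;
  if (proto.containsElementNamed("mf_times")) {
    mf_times = as<std::vector<double>>(proto["mf_times"]);
  }
  const bool debug = proto.containsElementNamed("debug") ?
    as<bool>(proto["debug"]) : false;
  const bool record_goc = proto.containsElementNamed("record_goc") ?
    as<bool>(proto["record_goc"]) : false;

  const bool vc = (mode == "vc");
  const bool have_goc = goc_spec.size() > 0;

  Cell grc = build_cell(grc_spec);
  cell_init_states(grc, vc && clamp_cell == "grc" ? holding : v_init);
  Cell goc;
  if (have_goc) {
    goc = build_cell(goc_spec);
    cell_init_states(goc, vc && clamp_cell == "goc" ? holding :
                     as<double>(goc_spec["v_rest"]));
  }

  // synapses
  std::vector<Synapse> syns;
  for (int i = 0; i < syn_list.size(); ++i) {
    List e = syn_list[i];
    Synapse s;
    s.pre = as<std::string>(e["pre"]);
    s.post = as<std::string>(e["post"]);
    s.post_comp = as<int>(e["post_comp"]);
    s.mult = as<double>(e["mult"]);
    List pp = e["presyn"];
    s.p = pget(pp, "p"); s.tau_rec = pget(pp, "tau_rec");
    s.tau_facil = pget(pp, "tau_facil"); s.tau_i = pget(pp, "tau_i");
    s.delay = pget(pp, "delay");
    s.R = 1.0; s.E = 0.0; s.I = 0.0; s.u = 0.0;
    s.t_last = 0.0; s.had_spike = false;
    List tr = e["trans"];
    s.amp_direct = pget(tr, "amp_direct"); s.dur_direct = pget(tr, "dur_direct");
    s.amp_spill = pget(tr, "amp_spill");
    s.tau_r = pget(tr, "tau_r"); s.tau_d = pget(tr, "tau_d");
    {
      double tp = s.tau_r * s.tau_d / (s.tau_d - s.tau_r) *
        std::log(s.tau_d / s.tau_r);
      double pk = std::exp(-tp / s.tau_d) - std::exp(-tp / s.tau_r);
      s.spill_scale = s.amp_spill / pk;
    }
    s.y_r = 0.0; s.y_d = 0.0;
    List rl = e["receptors"];
    for (int j = 0; j < rl.size(); ++j) {
      List re = rl[j];
      Receptor r;
      r.ns = as<int>(re["ns"]);
      r.open = as<std::vector<int>>(re["open"]);
      r.tr_from = as<std::vector<int>>(re["tr_from"]);
      r.tr_to = as<std::vector<int>>(re["tr_to"]);
      r.tr_lig = as<std::vector<int>>(re["tr_lig"]);
      r.tr_rate = as<std::vector<double>>(re["tr_rate"]);
      r.acc_direct = as<double>(re["acc_direct"]);
      r.acc_spill = as<double>(re["acc_spill"]);
      r.e_rev = as<double>(re["e_rev"]);
      r.w_uS = as<double>(re["w_nS"]) * 1e-3 * s.mult;
      r.has_mg = as<bool>(re["has_mg"]);
      if (r.has_mg) {
        r.mg_mM = as<double>(re["mg_mM"]);
        r.k_conc = as<double>(re["k_conc"]);
        r.k_v = as<double>(re["k_v"]);
      } else { r.mg_mM = 0; r.k_conc = 1; r.k_v = 0; }
      r.x.assign(r.ns, 0.0);
      r.x[0] = 1.0;
      s.receptors.push_back(r);
    }
    syns.push_back(s);
  }

  const bool rec_states = proto.containsElementNamed("record_states") ?
    as<bool>(proto["record_states"]) : false;
  const int nstep = (int)std::lround(duration / dt);
  NumericMatrix states;
  if (rec_states) states = NumericMatrix(nstep + 1, grc.chans.size() + 2);
  NumericVector out(nstep + 1), out_goc(record_goc ? nstep + 1 : 0);
  std::vector<double> spikes_grc, spikes_goc;
  bool gating_ok = true;
  double fail_time = -1.0;

  // mf event cursor
  size_t mf_next = 0;

  // clamp bookkeeping
  const bool grc_clamped = vc && clamp_cell == "grc";
  const bool goc_clamped = vc && clamp_cell == "goc";
  if (grc_clamped) for (int i = 0; i < grc.ncomp; ++i) grc.v[i] = holding;
  if (goc_clamped && have_goc) goc.v[0] = holding;

  auto record = [&](int k) {
    if (grc_clamped) {
      double i_syn = 0.0;
      double t = k * dt;
      for (auto& s : syns) if (s.post == "grc") {
        double cd = syn_conc_direct(s, t), cs = syn_conc_spill(s);
        (void)cd; (void)cs;
        for (auto& r : s.receptors) {
          double open = 0.0;
          for (int oi : r.open) open += r.x[oi];
          double blk = r.has_mg ?
            1.0 / (1.0 + (r.mg_mM / r.k_conc) * std::exp(-r.k_v * holding)) : 1.0;
          i_syn += r.w_uS * open * blk * (holding - r.e_rev);
        }
      }
      out[k] = (cell_ionic_current(grc) + i_syn) * 1000.0;  // pA, outward +
    } else if (goc_clamped) {
      double i_syn = 0.0;
      for (auto& s : syns) if (s.post == "goc") {
        for (auto& r : s.receptors) {
          double open = 0.0;
          for (int oi : r.open) open += r.x[oi];
          double blk = r.has_mg ?
            1.0 / (1.0 + (r.mg_mM / r.k_conc) * std::exp(-r.k_v * holding)) : 1.0;
          i_syn += r.w_uS * open * blk * (holding - r.e_rev);
        }
      }
      out[k] = (cell_ionic_current(goc) + i_syn) * 1000.0;
    } else {
      out[k] = grc.v[0];
    }
    if (record_goc && have_goc) out_goc[k] = goc.v[0];
  };
  auto record_state_row = [&](int k) {
    if (!rec_states) return;
    for (size_t c = 0; c < grc.chans.size(); ++c) {
      states(k, c) = chan_open_frac(grc.chans[c]);
    }
    states(k, grc.chans.size()) = grc.ca;
    for (const auto& ch : grc.chans) {
      if (ch.type == "na_allo") {   // availability: non-inactivated fraction
        double avail = 0.0;
        for (int i = 0; i < 7; ++i) avail += ch.x[i];
        states(k, grc.chans.size() + 1) = avail;
        break;
      }
    }
  };
  record(0);
  record_state_row(0);

  arma::mat Ag(grc.ncomp, grc.ncomp);
  arma::vec bg(grc.ncomp);

  for (int k = 1; k <= nstep; ++k) {
    double t_new = k * dt;
    double t_old = t_new - dt;

    // presynaptic mf spikes occurring in (t_old, t_new]
    while (mf_next < mf_times.size() && mf_times[mf_next] <= t_new + 1e-9) {
      for (auto& s : syns) if (s.pre == "mf") syn_spike(s, mf_times[mf_next]);
      ++mf_next;
    }
    // transmitter filters
    for (auto& s : syns) syn_step(s, t_new, dt);

    // --- membrane solve: GrC (Crank-Nicolson on the voltage equation) ---
    if (!grc_clamped) {
      Ag.zeros(); bg.zeros();
      arma::mat G(grc.ncomp, grc.ncomp, arma::fill::zeros);
      for (int i = 0; i < grc.ncomp; ++i) {
        int p = grc.parent[i];
        if (p >= 0) {
          G(i, i) += grc.gax[i]; G(i, p) -= grc.gax[i];
          G(p, p) += grc.gax[i]; G(p, i) -= grc.gax[i];
        }
      }
      for (auto& ch : grc.chans) {
        double g = ch.g * chan_open_frac(ch);
        G(ch.comp, ch.comp) += g;
        bg(ch.comp) += g * ch.e;
      }
      for (auto& s : syns) if (s.post == "grc") {
        for (auto& r : s.receptors) {
          double open = 0.0;
          for (int oi : r.open) open += r.x[oi];
          double blk = r.has_mg ?
            1.0 / (1.0 + (r.mg_mM / r.k_conc) *
                   std::exp(-r.k_v * grc.v[s.post_comp])) : 1.0;
          double g = r.w_uS * open * blk;
          G(s.post_comp, s.post_comp) += g;
          bg(s.post_comp) += g * r.e_rev;
        }
      }
      double inj = i_bias +
        ((t_new > step_on && t_new <= step_off) ? step_amp : 0.0);
      bg(0) += inj;  // somatic injection
      arma::vec vold(grc.ncomp);
      for (int i = 0; i < grc.ncomp; ++i) vold(i) = grc.v[i];
      arma::mat Cdt = arma::diagmat(arma::vec(grc.cm) / dt);
      arma::vec vn = arma::solve(Cdt + 0.5 * G,
                                 (Cdt - 0.5 * G) * vold + bg);
      for (int i = 0; i < grc.ncomp; ++i) grc.v[i] = vn(i);
    }

    // --- membrane solve: GoC (single compartment, Crank-Nicolson) ---
    if (have_goc && !goc_clamped) {
      double gsum = 0.0, gb = 0.0;
      for (auto& ch : goc.chans) {
        double g = ch.g * chan_open_frac(ch);
        gsum += g; gb += g * ch.e;
      }
      for (auto& s : syns) if (s.post == "goc") {
        for (auto& r : s.receptors) {
          double open = 0.0;
          for (int oi : r.open) open += r.x[oi];
          double blk = r.has_mg ?
            1.0 / (1.0 + (r.mg_mM / r.k_conc) * std::exp(-r.k_v * goc.v[0])) : 1.0;
          double g = r.w_uS * open * blk;
          gsum += g; gb += g * r.e_rev;
        }
      }
      double cdt = goc.cm[0] / dt;
      goc.v[0] = ((cdt - 0.5 * gsum) * goc.v[0] + gb) / (cdt + 0.5 * gsum);
    }

    // --- state updates at the new voltages ---
    if (!cell_update_states(grc, dt) ||
        (have_goc && !cell_update_states(goc, dt))) {
      stop("integration unstable (non-finite state) at t = %f ms", t_new);
    }
    if (debug && (!cell_gates_ok(grc) || (have_goc && !cell_gates_ok(goc)))) {
      gating_ok = false;
      if (fail_time < 0) fail_time = t_new;
    }

    // receptor updates
    for (auto& s : syns) {
      double cd = syn_conc_direct(s, t_new), cs = syn_conc_spill(s);
      for (auto& r : s.receptors) {
        if (r.w_uS == 0.0) continue;
        markov_backward_euler(r.x, receptor_generator(r, cd, cs), dt);
      }
    }

    // --- spike detection and feedback/feedforward events ---
    if (!grc_clamped) {
      double v = grc.v[0];
      if (grc.armed && v >= 0.0 && grc.v_prev_soma < 0.0) {
        spikes_grc.push_back(t_new);
        grc.armed = false;
        for (auto& s : syns) if (s.pre == "grc") syn_spike(s, t_new);
      }
      if (!grc.armed && v < -20.0) grc.armed = true;
      grc.v_prev_soma = v;
    }
    if (have_goc && !goc_clamped) {
      double v = goc.v[0];
      if (goc.armed && v >= 0.0 && goc.v_prev_soma < 0.0) {
        spikes_goc.push_back(t_new);
        goc.armed = false;
        for (auto& s : syns) if (s.pre == "goc") syn_spike(s, t_new);
      }
      if (!goc.armed && v < -20.0) goc.armed = true;
      goc.v_prev_soma = v;
    }

    record(k);
    record_state_row(k);
  }

  List res = List::create(
    _["signal"] = out,
    _["dt"] = dt,
    _["kind"] = grc_clamped || goc_clamped ? "current" : "voltage",
    _["spikes_grc"] = wrap(spikes_grc),
    _["spikes_goc"] = wrap(spikes_goc),
    _["gating_ok"] = gating_ok,
    _["gating_fail_time"] = fail_time);
  if (record_goc) res["v_goc"] = out_goc;
  if (rec_states) res["states"] = states;
  return res;
}

// steady-state open fraction of the allosteric Na scheme vs voltage
// (diagnostic surface for the persistent component)
// [[Rcpp::export]]
NumericVector cpp_na_steady_open(List na_params, NumericVector v, double q) {
  Chan ch;
  ch.type = "na_allo";
  for (const std::string& nm : chan_par_names("na_allo")) {
    ch.pv.push_back(pget(na_params, nm.c_str()));
  }
  ch.q = q;
  NumericVector out(v.size());
  for (int i = 0; i < v.size(); ++i) {
    arma::vec ss = markov_steady(na_generator(na_rates(ch, v[i])));
    out[i] = ss(5);
  }
  return out;
}
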