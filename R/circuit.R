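#' Reduced granular-layer circuit specification
#'
#' One granule cell contacted by `n_mf` mossy fibres (1-4) and `n_goc` Golgi
#' cells (0-7); every mossy fibre also drives every Golgi cell (feedforward
#' inhibition, 1 ms delay per synaptic hop). The granule-to-Golgi feedback
#' loop (parallel-fibre and ascending-axon synapses) is available but
#' disabled by default in the reduced circuit.
#'
#' @param n_mf Number of mossy fibres (1-4).
#' @param n_goc Number of Golgi cells (0-7).
#' @param feedback Enable the GrC->GoC feedback synapses.
#' @return Object of class `circuit_spec`.
#' @export
circuit_spec <- function(n_mf = 3, n_goc = 0, feedback = FALSE) {
  stopifnot(n_mf >= 1, n_mf <= 4, n_goc >= 0, n_goc <= 7)
  structure(list(n_mf = as.integer(n_mf), n_goc = as.integer(n_goc),
                 feedback = isTRUE(feedback)),
            class = "circuit_spec")
}

## receptor scheme -> C++ entry
receptor_to_cpp <- function(rec, mg_mM, mult_off) {
  sch <- rec$scheme
  idx <- function(s) match(s, sch$states) - 1L
  list(ns = length(sch$states),
       open = as.integer(idx(sch$open)),
       tr_from = as.integer(idx(sch$transitions$from)),
       tr_to = as.integer(idx(sch$transitions$to)),
       tr_lig = as.integer(sch$transitions$ligand != "none"),
       tr_rate = as.numeric(sch$transitions$rate),
       acc_direct = if (is.null(sch$access$direct)) 1 else sch$access$direct,
       acc_spill = if (is.null(sch$access$spill)) 1 else sch$access$spill,
       e_rev = sch$e_rev,
       w_nS = if (mult_off) 0 else rec$weight_nS,
       has_mg = !is.null(sch$mg),
       mg_mM = mg_mM,
       k_conc = if (is.null(sch$mg)) 1 else sch$mg$k_conc_mM,
       k_v = if (is.null(sch$mg)) 0 else sch$mg$k_v_per_mV)
}

synapse_to_cpp <- function(syn, pre, post, post_comp, mult, mg_mM,
                           receptor_off) {
  recs <- lapply(syn$receptors, function(r) {
    receptor_to_cpp(r, mg_mM, r$name %in% receptor_off)
  })
  list(pre = pre, post = post, post_comp = as.integer(post_comp),
       mult = as.numeric(mult),
       presyn = list(p = syn$presyn$p, tau_rec = syn$presyn$tau_rec,
                     tau_facil = syn$presyn$tau_facil,
                     tau_i = syn$presyn$tau_i, delay = syn$presyn$delay),
       trans = list(amp_direct = syn$transmitter$direct$amp_mM,
                    dur_direct = syn$transmitter$direct$dur_ms,
                    amp_spill = syn$transmitter$spill$amp_mM,
                    tau_r = syn$transmitter$spill$tau_rise_ms,
                    tau_d = syn$transmitter$spill$tau_decay_ms),
       receptors = unname(recs))
}

## Assemble and run the reduced circuit with the compiled core.  Identical
## deterministic afferents are folded into synapse multiplicities.
run_circuit_raw <- function(condition, circuit, proto, mg_mM = 1.2,
                            receptor_off = character(0), temperature = 30,
                            intensity = 1) {
  cond <- condition_set(condition)
  grc <- build_grc(cond, temperature)
  have_goc <- circuit$n_goc > 0
  goc <- if (have_goc) build_goc(cond, temperature) else NULL
  dend_mf <- 1L    # dendrite compartment receiving excitation
  dend_goc <- 2L   # dendrite compartment receiving inhibition
  syn_mf <- build_synapse("mf_grc", cond, temperature)
  # stimulation-intensity analogue: scales the mossy-fibre drive to the GrC
  for (nm in names(syn_mf$receptors)) {
    syn_mf$receptors[[nm]]$weight_nS <- syn_mf$receptors[[nm]]$weight_nS * intensity
  }
  syns <- list()
  syns$mf_grc <- synapse_to_cpp(syn_mf,
                                "mf", "grc", dend_mf, circuit$n_mf, mg_mM,
                                receptor_off)
  if (have_goc) {
    syns$mf_goc <- synapse_to_cpp(build_synapse("mf_goc", cond, temperature),
                                  "mf", "goc", 0L, circuit$n_mf, mg_mM,
                                  receptor_off)
    syns$goc_grc <- synapse_to_cpp(build_synapse("goc_grc", cond, temperature),
                                   "goc", "grc", dend_goc, circuit$n_goc,
                                   mg_mM, receptor_off)
    if (circuit$feedback) {
      syns$pf_goc <- synapse_to_cpp(build_synapse("pf_goc", cond, temperature),
                                    "grc", "goc", 0L, 1, mg_mM, receptor_off)
      syns$aa_goc <- synapse_to_cpp(build_synapse("aa_goc", cond, temperature),
                                    "grc", "goc", 0L, 1, mg_mM, receptor_off)
    }
  }
  r <- cpp_sim_circuit(grc$spec, if (have_goc) goc$spec else list(),
                       unname(syns), proto)
  r$condition <- cond$name
  r
}

protocol_result <- function(id, condition, traces, stim = list(), params = list(),
                            extras = list()) {
  structure(list(id = id, condition = condition, traces = traces,
                 stim = stim, params = params, extras = extras),
            class = "protocol_result")
}

#' @export
print.protocol_result <- function(x, ...) {
  cat(sprintf("<protocol_result> %s under %s: %d trace(s)\n",
              x$id, x$condition, length(x$traces)))
  invisible(x)
}

#' Somatic current-step protocol (intrinsic excitability)
#'
#' Voltage responses of the granule cell to a family of depolarising current
#' steps with synaptic inputs disabled; the substrate for rheobase, spike
#' threshold, spike counts and f-I curves.
#'
#' @param condition Condition name or [condition_set()].
#' @param steps Step amplitudes (pA), injected on top of the holding bias.
#' @param duration Step duration (ms).
#' @param pre_ms,post_ms Settling time before and tail after the step (ms).
#' @param v_hold Membrane potential the cell is biased to before the step
#'   (mV); the experimental protocol measures intrinsic excitability from a
#'   resting potential of -60 mV.
#' @param dt Time step (ms).
#' @param temperature Simulation temperature (degrees C).
#' @return A `protocol_result` with one voltage trace per amplitude (named by
#'   amplitude); stimulus window in `$stim`.
#' @export
run_current_steps <- function(condition = "control", steps = seq(1, 16, by = 1),
                              duration = 500, pre_ms = 100, post_ms = 100,
                              v_hold = -60, dt = 0.025, temperature = 30) {
  if (length(steps) == 0) stop("empty step range", call. = FALSE)
  cell <- build_grc(condition, temperature)
  bias <- holding_bias_pA(condition, v_hold, temperature, dt)
  total <- pre_ms + duration + post_ms
  traces <- lapply(steps, function(a) {
    integrate_cell(cell, stimulus = list(amp_pA = a, t_on = pre_ms,
                                         t_off = pre_ms + duration),
                   duration = total, dt = dt, mode = "cc",
                   i_bias_pA = bias, v_init = v_hold)
  })
  names(traces) <- as.character(steps)
  protocol_result("current_steps", cell$condition, traces,
                  stim = list(t_on = pre_ms, t_off = pre_ms + duration),
                  params = list(steps = steps, duration = duration, dt = dt,
                                v_hold = v_hold, bias_pA = bias,
                                temperature = temperature))
}

#' Spike count / frequency / threshold table from a current-step protocol
#'
#' @param result A [run_current_steps()] result.
#' @return Data frame with one row per step: amplitude, spike count, average
#'   firing frequency (Hz), first-spike threshold (mV) and first-spike
#'   latency (ms).
#' @export
fi_table <- function(result) {
  stopifnot(inherits(result, "protocol_result"),
            result$id == "current_steps")
  on_ms <- result$stim$t_on
  rows <- lapply(names(result$traces), function(nm) {
    tr <- result$traces[[nm]]
    m <- spike_metrics(tr, stim_onset = on_ms)
    keep <- m$spike_times >= on_ms & m$spike_times <= result$stim$t_off
    nsp <- sum(keep)
    data.frame(amp_pA = as.numeric(nm), n_spikes = nsp,
               avg_freq_hz = if (nsp >= 2) {
                 st <- m$spike_times[keep]
                 1000 * (nsp - 1) / (st[nsp] - st[1])
               } else NA_real_,
               threshold_mV = if (nsp >= 1) m$threshold[which(keep)[1]] else NA_real_,
               first_latency_ms = if (nsp >= 1) m$spike_times[which(keep)[1]] - on_ms else NA_real_)
  })
  do.call(rbind, rows)
}

#' Rheobase from a current-step protocol
#' @param result A [run_current_steps()] result.
#' @return Minimum step amplitude (pA) eliciting at least one spike
#'   (`NA` if none does).
#' @export
rheobase <- function(result) {
  ft <- fi_table(result)
  hit <- ft$amp_pA[ft$n_spikes >= 1]
  if (length(hit)) min(hit) else NA_real_
}

#' EPSC burst protocol (voltage clamp)
#'
#' Clamp-current response of the granule cell to a mossy-fibre burst
#' (4 pulses at 100 Hz by default) at -70 mV, including the residual-current
#' window 50 ms after the last pulse. Implemented at receptor level under an
#' ideal somatic clamp of the compact granule cell.
#'
#' @param condition Condition name or [condition_set()].
#' @param n_pulses,freq Burst geometry (pulse count, Hz).
#' @param holding Holding potential (mV).
#' @param mg_mM Extracellular Mg (mM).
#' @param n_mf Number of active mossy fibres (scales the current).
#' @param receptor_off Receptors silenced pharmacologically.
#' @param t0 Time of the first pulse (ms).
#' @param dt,temperature Integration settings.
#' @return A `protocol_result` with the clamp-current trace and stimulus
#'   times.
#' @export
run_epsc_burst <- function(condition = "control", n_pulses = 4, freq = 100,
                           holding = -70, mg_mM = 1.2, n_mf = 1,
                           receptor_off = character(0), t0 = 60, dt = 0.025,
                           temperature = 30) {
  cond <- condition_set(condition)
  syn <- build_synapse("mf_grc", cond, temperature)
  stim <- t0 + (seq_len(n_pulses) - 1) * 1000 / freq
  duration <- max(stim) + 90
  cur <- synapse_current(syn, stim, v = holding, duration = duration, dt = dt,
                         mg_mM = mg_mM, receptor_off = receptor_off)
  tr <- cur$trace
  tr$values <- tr$values * n_mf
  per <- lapply(cur$per_receptor, function(v) v * n_mf)
  protocol_result("epsc_burst", cond$name, list(clamp = tr),
                  stim = list(times = stim, holding = holding),
                  params = list(n_pulses = n_pulses, freq = freq,
                                mg_mM = mg_mM, n_mf = n_mf,
                                receptor_off = receptor_off, dt = dt),
                  extras = list(per_receptor = per, released = cur$released))
}

#' NMDA-isolation protocol
#'
#' The pharmacologically isolated NMDA current: AMPA blocked, Mg removed,
#' holding -40 mV, mossy-fibre burst. In control the current sums temporally,
#' peaking tens of ms after the last stimulus; under sevoflurane the NMDA
#' weight is zero and the current vanishes.
#'
#' @inheritParams run_epsc_burst
#' @return A `protocol_result`.
#' @export
run_nmda_isolation <- function(condition = "control", n_pulses = 4, freq = 100,
                               holding = -40, n_mf = 1, t0 = 60, dt = 0.025,
                               temperature = 30) {
  run_epsc_burst(condition, n_pulses = n_pulses, freq = freq,
                 holding = holding, mg_mM = 0, n_mf = n_mf,
                 receptor_off = "ampa", t0 = t0, dt = dt,
                 temperature = temperature)
}

#' IPSC protocol at the GoC->GrC synapse (voltage clamp)
#'
#' Single or paired direct stimulation of the Golgi-cell input under voltage
#' clamp; the substrate for IPSC peak, decay tau, charge and paired-pulse
#' ratio. With the chloride reversal at -65 mV the currents are outward
#' (positive) at depolarised holding potentials.
#'
#' @param condition Condition name or [condition_set()].
#' @param n_pulses 1 or 2 stimuli.
#' @param freq Pair frequency (Hz) when `n_pulses == 2`.
#' @param holding Holding potential (mV); -60 mV mirrors the modelled
#'   intracellular recordings, 0 mV the experimental configuration.
#' @param n_goc Number of simultaneously activated Golgi cells.
#' @param gaba_off Gabazine analogue: silence both GABA-A schemes.
#' @param tail_ms Recording window after the last stimulus (ms).
#' @param t0,dt,temperature As in [run_epsc_burst()].
#' @return A `protocol_result`.
#' @export
run_ipsc_protocol <- function(condition = "control", n_pulses = 1, freq = 50,
                              holding = -60, n_goc = 1, gaba_off = FALSE,
                              tail_ms = 200, t0 = 60, dt = 0.025,
                              temperature = 30) {
  stopifnot(n_pulses %in% c(1L, 2L))
  cond <- condition_set(condition)
  syn <- build_synapse("goc_grc", cond, temperature)
  stim <- t0 + (seq_len(n_pulses) - 1) * 1000 / freq
  duration <- max(stim) + tail_ms
  off <- if (gaba_off) c("gabaa_alpha1", "gabaa_alpha6") else character(0)
  cur <- synapse_current(syn, stim, v = holding, duration = duration, dt = dt,
                         mg_mM = 0, receptor_off = off)
  tr <- cur$trace
  tr$values <- tr$values * n_goc
  protocol_result("ipsc", cond$name, list(clamp = tr),
                  stim = list(times = stim, holding = holding),
                  params = list(n_pulses = n_pulses, freq = freq,
                                n_goc = n_goc, gaba_off = gaba_off, dt = dt),
                  extras = list(released = cur$released,
                                per_receptor = cur$per_receptor))
}

#' Single-pulse mf->GoC EPSC (voltage clamp of the Golgi cell)
#'
#' Calibration protocol for the mossy-fibre to Golgi-cell synapse: clamp the
#' Golgi cell, stimulate one mossy fibre once, record the clamp current.
#'
#' @param condition Condition name or [condition_set()].
#' @param holding Holding potential (mV).
#' @param mg_mM Extracellular Mg (mM).
#' @param t0,dt,temperature Protocol settings.
#' @return A `protocol_result` with the GoC clamp-current trace.
#' @export
run_mf_goc_epsc <- function(condition = "control", holding = -70, mg_mM = 1.2,
                            t0 = 60, dt = 0.025, temperature = 30) {
  cond <- condition_set(condition)
  syn <- build_synapse("mf_goc", cond, temperature)
  duration <- t0 + 120
  cur <- synapse_current(syn, t0, v = holding, duration = duration, dt = dt,
                         mg_mM = mg_mM)
  protocol_result("mf_goc_epsc", cond$name, list(clamp = cur$trace),
                  stim = list(times = t0, holding = holding),
                  params = list(mg_mM = mg_mM, dt = dt))
}

## bias current holding the GrC at v_hold: terminal clamp current of a
## voltage-clamp settle run
holding_bias_pA <- function(condition, v_hold, temperature = 30, dt = 0.025,
                            settle_ms = 400) {
  cell <- build_grc(condition, temperature)
  tr <- integrate_cell(cell, duration = settle_ms, dt = dt, mode = "vc",
                       holding = v_hold)
  utils::tail(tr$values, 1)
}

#' Paired-pulse frequency sweep through the reduced circuit
#'
#' Pairs of mossy-fibre action potentials at each input frequency drive the
#' circuit in current clamp; granule-cell spikes are collected for I/O
#' curves, first-spike delay and spike counts per E/I combination.
#'
#' @param condition Condition name or [condition_set()].
#' @param n_mf,n_goc,feedback Circuit composition (see [circuit_spec()]).
#' @param freqs Input frequencies (Hz).
#' @param window_ms Response window from the first stimulus over which output
#'   spikes are counted (fixed 100 ms by default).
#' @param intensity Stimulation-intensity analogue scaling the mossy-fibre
#'   drive to the granule cell (1 = reference intensity).
#' @param t0 First-stimulus time (settling period before it).
#' @param dt,temperature Integration settings.
#' @return A `protocol_result`; `$extras$sweep` holds a data frame with
#'   per-frequency spike count, output frequency and first-spike delay.
#' @export
run_pp_frequency_sweep <- function(condition = "control", n_mf = 3, n_goc = 0,
                                   feedback = FALSE,
                                   freqs = c(10, 20, 50, 100, 200),
                                   window_ms = 100, intensity = 0.8,
                                   t0 = 100, dt = 0.025,
                                   temperature = 30) {
  circuit <- circuit_spec(n_mf, n_goc, feedback)
  bias <- holding_bias_pA(condition, -60, temperature, dt)
  traces <- list()
  rows <- list()
  for (f in freqs) {
    interval <- 1000 / f
    stim <- c(t0, t0 + interval)
    duration <- t0 + interval + window_ms + 20
    r <- run_circuit_raw(condition, circuit,
                         proto = list(mode = "cc", duration = duration,
                                      dt = dt, v_init = -60,
                                      i_bias_pA = bias,
                                      mf_times = stim),
                         intensity = intensity)
    tr <- sg_trace(r$signal, dt = dt, kind = "voltage",
                   meta = list(freq = f, stim = stim))
    sp <- r$spikes_grc
    inwin <- sp[sp >= t0 & sp <= t0 + window_ms]
    rows[[length(rows) + 1L]] <- data.frame(
      freq_hz = f, n_spikes = length(inwin),
      out_hz = 1000 * length(inwin) / window_ms,
      first_delay_ms = if (length(inwin)) inwin[1] - t0 else NA_real_,
      n_goc_spikes = length(r$spikes_goc))
    traces[[as.character(f)]] <- tr
  }
  protocol_result("pp_sweep", condition_set(condition)$name, traces,
                  stim = list(t0 = t0, window_ms = window_ms),
                  params = list(n_mf = n_mf, n_goc = n_goc, freqs = freqs,
                                feedback = feedback, dt = dt),
                  extras = list(sweep = do.call(rbind, rows)))
}

#' EPSP protocol (current clamp near -60 mV)
#'
#' Subthreshold EPSP evoked by a single mossy-fibre volley, with or without
#' feedforward Golgi-cell inhibition, from a membrane potential held near
#' -60 mV by a bias current. A response that triggers a spike is flagged and
#' excluded from EPSP metrics downstream.
#'
#' @param condition Condition name or [condition_set()].
#' @param n_mf Number of active mossy fibres.
#' @param n_goc Number of active Golgi cells (0 disables inhibition).
#' @param v_hold Pre-stimulus membrane potential (mV).
#' @param intensity Stimulation-intensity analogue (sub-threshold stimuli are
#'   obtained with a reduced mossy-fibre drive).
#' @param t0 Stimulus time (ms; preceded by settling at the bias current).
#' @param tail_ms Window after the stimulus (ms).
#' @param dt,temperature Integration settings.
#' @return A `protocol_result` with the somatic voltage trace; `$stim$times`
#'   holds the stimulus time.
#' @export
run_epsp_protocol <- function(condition = "control", n_mf = 1, n_goc = 0,
                              v_hold = -60, intensity = 0.6, t0 = 150,
                              tail_ms = 80, dt = 0.025, temperature = 30) {
  circuit <- circuit_spec(n_mf, n_goc)
  bias <- holding_bias_pA(condition, v_hold, temperature, dt)
  duration <- t0 + tail_ms
  r <- run_circuit_raw(condition, circuit,
                       proto = list(mode = "cc", duration = duration, dt = dt,
                                    v_init = v_hold, i_bias_pA = bias,
                                    mf_times = t0),
                       intensity = intensity)
  tr <- sg_trace(r$signal, dt = dt, kind = "voltage",
                 meta = list(v_hold = v_hold, bias_pA = bias))
  protocol_result("epsp", condition_set(condition)$name, list(vm = tr),
                  stim = list(times = t0, v_hold = v_hold),
                  params = list(n_mf = n_mf, n_goc = n_goc, dt = dt,
                                bias_pA = bias),
                  extras = list(spikes = r$spikes_grc,
                                goc_spikes = r$spikes_goc))
}
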