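## Cell-model assembly: translate the versioned YAML parameter files plus a
## condition bundle into the compartment/channel specification consumed by
## the compiled integrator.

.cell_cache <- new.env(parent = emptyenv())

cyl_area_cm2 <- function(length_um, diam_um) {
  pi * diam_um * length_um * 1e-8
}

## axial resistance of half a cylindrical compartment, in Mohm
half_axial_Mohm <- function(length_um, diam_um, ra_ohm_cm) {
  r_cm <- diam_um / 2 * 1e-4
  (ra_ohm_cm * (length_um / 2 * 1e-4) / (pi * r_cm^2)) * 1e-6
}

grc_comp_layout <- function(geo) {
  # soma(1), dend x4 (2..5), hillock(6), axon(7); indices 0-based for C++
  data.frame(
    name = c("soma", paste0("dend", 1:4), "hillock", "axon"),
    group = c("soma", rep("dend", 4), "hillock", "axon"),
    parent = c(-1L, rep(0L, 4), 0L, 5L),
    length_um = c(geo$soma$length_um, rep(geo$dend$length_um, 4),
                  geo$hillock$length_um, geo$axon$length_um),
    diam_um = c(geo$soma$diam_um, rep(geo$dend$diam_um, 4),
                geo$hillock$diam_um, geo$axon$diam_um),
    stringsAsFactors = FALSE)
}

assemble_cell_spec <- function(x, temperature) {
  lay <- grc_comp_layout(x$compartments)
  area <- cyl_area_cm2(lay$length_um, lay$diam_um)
  cm <- x$capacitance_uF_cm2 * area * 1e3          # nF
  rh <- half_axial_Mohm(lay$length_um, lay$diam_um, x$axial_resistivity_ohm_cm)
  gax <- numeric(nrow(lay))
  for (i in seq_len(nrow(lay))) {
    p <- lay$parent[i]
    if (p >= 0) gax[i] <- 1 / (rh[i] + rh[p + 1L])  # uS (1/Mohm)
  }
  qperm <- q10_factor(x$density_q10$q10, x$density_q10$t_orig_C, temperature)
  channels <- list()
  for (nm in names(x$channels)) {
    ch <- x$channels[[nm]]
    q <- q10_factor(ch$q10, ch$t_orig_C, temperature)
    e <- x$reversal_mV[[ch$e_rev]]
    for (grp in names(ch$density_S_cm2)) {
      comps <- which(lay$group == grp) - 1L
      for (ci in comps) {
        g_uS <- ch$density_S_cm2[[grp]] * qperm * area[ci + 1L] * 1e6
        channels[[length(channels) + 1L]] <- list(
          type = ch$type, comp = as.integer(ci), g_uS = g_uS, e_mV = e, q = q,
          params = if (is.null(ch$params)) list(dummy = 0) else ch$params,
          name = nm)
      }
    }
  }
  has_ca <- !is.null(x$ca_pool)
  ca_pool <- if (has_ca) {
    comp <- which(lay$group == x$ca_pool$compartment)[1] - 1L
    list(comp = as.integer(comp), ca0_mM = x$ca_pool$ca0_mM,
         beta_per_ms = x$ca_pool$beta_per_ms,
         shell_cm3 = area[comp + 1L] * x$ca_pool$depth_um * 1e-4)
  } else list()
  list(cm_nF = cm, parent = as.integer(lay$parent), g_ax_uS = gax,
       channels = channels, has_ca = has_ca, ca_pool = ca_pool,
       v_rest = x$resting_potential_mV, area_cm2 = area,
       comp_names = lay$name)
}

set_leak_reversal <- function(spec, e_leak) {
  spec$channels <- lapply(spec$channels, function(ch) {
    if (ch$name == "leak") ch$e_mV <- e_leak
    ch
  })
  spec
}

## Find the leak reversal that rests the cell at its target potential, by
## secant iteration on short zero-current simulations with the production
## integrator, restoring the resting potential the published adaptation used.
calibrate_leak_reversal <- function(spec, target, settle_ms = 400, dt = 0.025) {
  vend <- function(el) {
    s <- set_leak_reversal(spec, el)
    r <- cpp_sim_circuit(s, list(), list(),
                         list(mode = "cc", duration = settle_ms, dt = dt,
                              v_init = target))
    utils::tail(r$signal, 1)
  }
  e0 <- target; e1 <- target + 15
  f0 <- vend(e0) - target; f1 <- vend(e1) - target
  for (i in 1:8) {
    if (abs(f1) < 0.02) break
    if (f1 == f0) break
    e2 <- e1 - f1 * (e1 - e0) / (f1 - f0)
    e0 <- e1; f0 <- f1
    e1 <- e2; f1 <- vend(e1) - target
  }
  e1
}

build_cell_model <- function(kind, condition, temperature) {
  cond <- condition_set(condition)
  key <- paste(kind, cond$name, temperature, sep = "|")
  if (!is.null(.cell_cache[[key]])) return(.cell_cache[[key]])
  x <- read_params(sg_extdata("cells", paste0(kind, ".yaml")))
  ov <- scoped_overrides(as.list(cond$intrinsic), kind)
  x <- apply_overrides(x, ov, where = paste0("cell ", kind))
  spec <- assemble_cell_spec(x, temperature)
  if (identical(x$leak_reversal, "auto")) {
    el <- calibrate_leak_reversal(spec, x$resting_potential_mV)
    spec <- set_leak_reversal(spec, el)
  }
  m <- structure(list(kind = kind, condition = cond$name,
                      temperature = temperature, spec = spec,
                      resting_target = x$resting_potential_mV,
                      params = x, overrides = attr(x, "override_log")),
                 class = "cell_model")
  .cell_cache[[key]] <- m
  m
}

#' Build the multi-compartment granule-cell model
#'
#' Assembles the GrC (soma, four dendrites, axon hillock, axon) with its full
#' channel complement - allosteric Na scheme (transient/persistent/resurgent
#' components) and Kv in hillock and axon, KA/Kir/KCa/Ca/K-slow in the soma,
#' leak and GABA-A leak conductances - under a condition bundle, with Q10
#' temperature correction, and adjusts the leak reversal so the model rests
#' at -70 mV with zero injected current.
#'
#' @param condition Condition name or [condition_set()] (e.g. `"control"`,
#'   `"sevoflurane"`).
#' @param temperature Simulation temperature in degrees C (20-40; default 30,
#'   the recording-chamber temperature the simulations emulate).
#' @return Object of class `cell_model`.
#' @export
build_grc <- function(condition = "control", temperature = 30) {
  if (temperature < 20 || temperature > 40) {
    stop("temperature must be within [20, 40] C", call. = FALSE)
  }
  build_cell_model("grc", condition, temperature)
}

#' Build the Golgi-cell spiking surrogate
#'
#' A single-compartment conductance-based interneuron (fast Na/K spiking
#' kinetics plus leak) serving as the presynaptic inhibitory spike source:
#' it relays a mossy-fibre volley into spikes with realistic latency, which
#' is all the reduced-circuit protocols require of the Golgi cell. The
#' sevoflurane bundle leaves GoC intrinsic parameters untouched.
#'
#' @inheritParams build_grc
#' @return Object of class `cell_model`.
#' @export
build_goc <- function(condition = "control", temperature = 30) {
  if (temperature < 20 || temperature > 40) {
    stop("temperature must be within [20, 40] C", call. = FALSE)
  }
  build_cell_model("goc", condition, temperature)
}

#' @export
print.cell_model <- function(x, ...) {
  cat("<cell_model>", x$kind, "under", x$condition,
      sprintf("at %g C, %d compartments\n", x$temperature,
              length(x$spec$cm_nF)))
  invisible(x)
}

#' Channel summary table of a cell model
#' @param cell A [build_grc()]/[build_goc()] model.
#' @return Data frame with one row per channel instance: name, type,
#'   compartment, conductance (uS and S/cm2) and reversal (mV).
#' @export
channel_table <- function(cell) {
  stopifnot(inherits(cell, "cell_model"))
  do.call(rbind, lapply(cell$spec$channels, function(ch) {
    data.frame(name = ch$name, type = ch$type,
               compartment = cell$spec$comp_names[ch$comp + 1L],
               g_uS = ch$g_uS,
               density_S_cm2 = ch$g_uS * 1e-6 / cell$spec$area_cm2[ch$comp + 1L],
               e_mV = ch$e_mV)
  }))
}

#' Steady-state open fraction of the allosteric Na scheme
#'
#' Diagnostic for the persistent Na component: equilibrium open probability
#' of the Na scheme as a function of voltage, under a condition bundle.
#'
#' @param condition Condition name or [condition_set()].
#' @param v Voltages (mV).
#' @param temperature Simulation temperature (degrees C).
#' @return Numeric vector of steady-state open fractions.
#' @export
na_steady_open <- function(condition = "control", v = seq(-80, 0, by = 2),
                           temperature = 30) {
  cell <- build_grc(condition, temperature)
  ch <- Filter(function(c) c$type == "na_allo", cell$spec$channels)[[1]]
  cpp_na_steady_open(ch$params, v, ch$q)
}
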