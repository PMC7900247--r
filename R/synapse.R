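SYNAPSE_KINDS <- c("mf_grc", "mf_goc", "pf_goc", "aa_goc", "goc_grc")

#' Build a synapse specification under a condition
#'
#' Assembles presynaptic vesicle-cycling parameters, the transmitter/spillover
#' template and the weighted receptor schemes for one of the five synapse
#' classes of the granular-layer microcircuit: `mf_grc`, `mf_goc` (calibrated
#' to a -66 pA single-pulse EPSC), `pf_goc` (AMPA+NMDA+kainate, release
#' probability 0.1), `aa_goc` (ascending-axon contacts, conductances about
#' twice the parallel-fibre ones) and `goc_grc` (GABA-A alpha1 + alpha6 with
#' glomerular spillover). Condition bundles override keys scoped to the
#' synapse id (e.g. the sevoflurane bundle zeroes the mf_grc NMDA weight and
#' applies the calibrated GABA potentiation at goc_grc).
#'
#' @param kind Synapse class id.
#' @param condition Condition name or [condition_set()].
#' @param temperature Simulation temperature (degrees C).
#' @return Object of class `synapse_spec`.
#' @export
build_synapse <- function(kind, condition = "control", temperature = 30) {
  if (!kind %in% SYNAPSE_KINDS) {
    stop("unknown synapse kind '", kind, "'; registered kinds: ",
         paste(SYNAPSE_KINDS, collapse = ", "), call. = FALSE)
  }
  cond <- condition_set(condition)
  x <- read_params(sg_extdata("synapses", paste0(kind, ".yaml")))
  ov <- scoped_overrides(as.list(cond$synaptic), kind)
  x <- apply_overrides(x, ov, where = paste0("synapse ", kind))
  pre <- presyn_params(x$presyn$p, x$presyn$tau_rec_ms, x$presyn$tau_facil_ms,
                       x$presyn$tau_i_ms, x$presyn$delay_ms)
  receptors <- lapply(names(x$receptors), function(nm) {
    r <- x$receptors[[nm]]
    sch <- receptor_scheme(r$scheme, temperature)
    if (!is.null(r$access)) sch$access <- r$access
    cs <- if (is.null(r$close_scale)) 1 else r$close_scale
    if (cs != 1) {
      leave_open <- sch$transitions$from %in% sch$open
      sch$transitions$rate[leave_open] <- sch$transitions$rate[leave_open] * cs
    }
    ws <- if (is.null(r$weight_scale)) 1 else r$weight_scale
    list(name = nm, scheme = sch, weight_nS = r$weight_nS * ws)
  })
  names(receptors) <- names(x$receptors)
  structure(list(kind = kind, condition = cond$name, presyn = pre,
                 transmitter = x$transmitter, receptors = receptors,
                 target = x$target, temperature = temperature,
                 overrides = attr(x, "override_log")),
            class = "synapse_spec")
}

#' @export
print.synapse_spec <- function(x, ...) {
  cat("<synapse_spec>", x$kind, "under", x$condition, "\n")
  cat(sprintf("  presyn: p=%.3g tau_rec=%g tau_facil=%g tau_i=%g delay=%g ms\n",
              x$presyn$p, x$presyn$tau_rec, x$presyn$tau_facil, x$presyn$tau_i,
              x$presyn$delay))
  for (r in x$receptors) {
    cat(sprintf("  receptor %s: %.3g nS\n", r$scheme$family, r$weight_nS))
  }
  invisible(x)
}

#' Voltage-clamp synaptic current for a presynaptic spike train
#'
#' Full synaptic pipeline at a clamped postsynaptic potential: deterministic
#' release recursion, transmitter + spillover waveforms, receptor-scheme
#' occupancies and summed receptor currents. Used by the voltage-clamp
#' protocols (EPSC bursts, NMDA isolation, IPSC trains); an ideal somatic
#' clamp of the electrotonically compact granule cell is assumed.
#'
#' @param syn A [build_synapse()] spec.
#' @param spike_times Presynaptic spike times (ms); transmitter onset follows
#'   after the synaptic delay.
#' @param v Holding potential (mV).
#' @param duration Trace duration (ms).
#' @param dt Sampling interval (ms).
#' @param mg_mM Extracellular Mg (mM).
#' @param receptor_off Character vector of receptor names to silence
#'   (pharmacological flags, e.g. `c("ampa")` for an NBQX analogue).
#' @return List with `trace` (total current, pA), `per_receptor` (list of
#'   component current vectors) and `released` (per-spike fractions).
#' @export
synapse_current <- function(syn, spike_times, v, duration, dt = 0.025,
                            mg_mM = 1.2, receptor_off = character(0)) {
  stopifnot(inherits(syn, "synapse_spec"))
  rel <- release_sequence(spike_times, syn$presyn)
  tt <- seq(0, duration, by = dt)
  tm <- transmitter_timecourse(
    tt, spike_times + syn$presyn$delay, as.numeric(rel),
    direct = list(amp_mM = syn$transmitter$direct$amp_mM,
                  dur_ms = syn$transmitter$direct$dur_ms),
    spill = list(amp_mM = syn$transmitter$spill$amp_mM,
                 tau_rise_ms = syn$transmitter$spill$tau_rise_ms,
                 tau_decay_ms = syn$transmitter$spill$tau_decay_ms))
  total <- numeric(length(tt))
  per <- list()
  for (r in syn$receptors) {
    if (r$name %in% receptor_off || r$weight_nS == 0) next
    resp <- receptor_response(r$scheme, tm, v, r$weight_nS, mg_mM)
    per[[r$name]] <- resp$trace$values
    total <- total + resp$trace$values
  }
  list(trace = sg_trace(total, dt = dt, kind = "current",
                        meta = list(synapse = syn$kind, condition = syn$condition,
                                    v = v)),
       per_receptor = per, released = as.numeric(rel), transmitter = tm)
}
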