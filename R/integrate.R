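#' Integrate a cell model under current or voltage clamp
#'
#' Fixed-step implicit integration (backward-Euler membrane solve,
#' exponential-Euler gates, conservative backward-Euler Markov schemes) of a
#' single cell with an optional somatic step stimulus. Current clamp returns
#' the somatic membrane potential; voltage clamp returns the total clamp
#' current under an ideal space clamp (positive = outward).
#'
#' @param cell A [build_grc()] / [build_goc()] model.
#' @param stimulus `NULL`, or `list(amp_pA =, t_on =, t_off =)` for a somatic
#'   current step (current clamp only).
#' @param duration Simulation length (ms).
#' @param dt Time step (ms, must be <= 0.05; default 0.025).
#' @param mode `"cc"` (current clamp) or `"vc"` (voltage clamp).
#' @param holding Holding potential (mV); required in voltage clamp.
#' @param i_bias_pA Constant bias current (pA, current clamp).
#' @param v_init Initial potential (mV; defaults to the cell's resting
#'   target in current clamp, the holding potential in voltage clamp).
#' @param debug If `TRUE`, per-step gating-range checks are performed and
#'   reported in the trace metadata.
#' @return An [sg_trace()] (voltage in cc, current in vc) whose metadata
#'   carries detected spike times (`spikes`), the protocol settings and the
#'   gating check result.
#' @export
integrate_cell <- function(cell, stimulus = NULL, duration = 500, dt = 0.025,
                           mode = c("cc", "vc"), holding = NULL,
                           i_bias_pA = 0, v_init = NULL, debug = FALSE) {
  stopifnot(inherits(cell, "cell_model"))
  mode <- match.arg(mode)
  if (dt > 0.05) stop("dt must be <= 0.05 ms", call. = FALSE)
  if (duration <= 0) stop("duration must be positive", call. = FALSE)
  if (mode == "vc" && is.null(holding)) {
    stop("voltage clamp requires a holding potential", call. = FALSE)
  }
  proto <- list(mode = mode, duration = duration, dt = dt,
                clamp_cell = "grc", i_bias_pA = i_bias_pA, debug = debug)
  if (!is.null(holding)) proto$holding <- holding
  proto$v_init <- if (!is.null(v_init)) v_init else {
    if (mode == "vc") holding else cell$resting_target
  }
  if (!is.null(stimulus)) {
    if (mode == "vc") stop("step stimulus is a current-clamp facility", call. = FALSE)
    proto$step <- list(amp_pA = stimulus$amp_pA, t_on = stimulus$t_on,
                       t_off = stimulus$t_off)
  }
  r <- cpp_sim_circuit(cell$spec, list(), list(), proto)
  sg_trace(r$signal, dt = dt,
           kind = if (mode == "vc") "current" else "voltage",
           meta = list(cell = cell$kind, condition = cell$condition,
                       mode = mode, holding = holding, stimulus = stimulus,
                       i_bias_pA = i_bias_pA,
                       spikes = r$spikes_grc, gating_ok = r$gating_ok))
}
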