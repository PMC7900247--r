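#' Presynaptic vesicle-cycling parameters
#'
#' Mean-field Tsodyks-Markram-type description of release with three vesicle
#' pools (recovered, effective, inactive) and a facilitation variable. The
#' canonical bundles are: mf->GrC `p = 0.6, tau_rec = 8, tau_facil = 5,
#' tau_i = 1`; GoC->GrC `p = 0.35, tau_rec = 36, tau_facil = 58.5,
#' tau_i = 0.1`; PF->GoC `p = 0.1` with the mf vesicle-cycling constants.
#'
#' @param p Baseline release probability in \[0, 1\].
#' @param tau_rec Recovery-from-depression time constant (ms).
#' @param tau_facil Facilitation decay time constant (ms).
#' @param tau_i Vesicle inactivation time constant (ms).
#' @param delay Transmission delay (ms); 1 ms for all synapses.
#' @return Object of class `presyn_params`.
#' @export
presyn_params <- function(p, tau_rec, tau_facil, tau_i, delay = 1) {
  stopifnot(is.numeric(p), length(p) == 1, p >= 0, p <= 1,
            tau_rec > 0, tau_facil > 0, tau_i > 0, delay >= 0)
  structure(list(p = p, tau_rec = tau_rec, tau_facil = tau_facil,
                 tau_i = tau_i, delay = delay),
            class = "presyn_params")
}

## Relax the three-pool state over an interval dt (closed form).
## E decays into I with tau_i; I recovers into R with tau_rec; R = 1 - E - I.
relax_pools <- function(state, dt, params) {
  a <- 1 / params$tau_i
  b <- 1 / params$tau_rec
  E0 <- state$E; I0 <- state$I
  E <- E0 * exp(-a * dt)
  I <- if (abs(a - b) < 1e-12) {
    (I0 + E0 * a * dt) * exp(-b * dt)
  } else {
    I0 * exp(-b * dt) + E0 * (a / (a - b)) * (exp(-b * dt) - exp(-a * dt))
  }
  u <- state$u * exp(-dt / params$tau_facil)
  list(R = 1 - E - I, E = E, I = I, u = u)
}

#' Per-spike released fractions from the deterministic recursion
#'
#' At each presynaptic spike the facilitation variable jumps by
#' `u <- u + p * (1 - u)` (so an isolated first spike releases exactly `p`),
#' the released fraction is `u * R`, and the released vesicles move from the
#' recovered to the effective pool. Between spikes the effective pool
#' inactivates with `tau_i`, the inactive pool recovers with `tau_rec`, and
#' `u` decays back to 0 with `tau_facil`.
#'
#' @param spike_times Strictly increasing presynaptic spike times (ms).
#' @param params A [presyn_params()] bundle.
#' @return Numeric vector of released pool fractions, one per spike, each in
#'   \[0, 1\]. The final pool state is attached as attribute `state`.
#' @export
release_sequence <- function(spike_times, params) {
  stopifnot(inherits(params, "presyn_params"))
  if (length(spike_times) == 0) return(numeric(0))
  if (any(diff(spike_times) <= 0)) {
    stop("spike times must be strictly increasing", call. = FALSE)
  }
  state <- list(R = 1, E = 0, I = 0, u = 0)
  rel <- numeric(length(spike_times))
  t_last <- spike_times[1]
  for (k in seq_along(spike_times)) {
    if (k > 1) state <- relax_pools(state, spike_times[k] - t_last, params)
    state$u <- state$u + params$p * (1 - state$u)
    rel[k] <- state$u * state$R
    state$R <- state$R - rel[k]
    state$E <- state$E + rel[k]
    t_last <- spike_times[k]
  }
  attr(rel, "state") <- state
  rel
}
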