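## Ground-truth fixture generation: patch-clamp-like traces with known event
## parameters, so every analysis operator and the presynaptic recursion are
## testable without running the biophysical core.

with_seed <- function(seed, expr) {
  if (is.null(seed)) stop("a seed is mandatory for stochastic generation", call. = FALSE)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  force(expr)
}

#' Biexponential kernel closed forms
#'
#' Kernel `k(t) = s * (exp(-t/tau_decay) - exp(-t/tau_rise))`, scaled so its
#' peak equals `amplitude`. Returns the scale, analytic peak time, charge
#' (integral, `amplitude`-scaled) and the 10-90% rise time (root of the
#' analytic expression).
#'
#' @param tau_rise,tau_decay Kernel time constants, ms (`tau_rise < tau_decay`).
#' @param amplitude Peak amplitude (pA or mV).
#' @return List with `scale`, `t_peak`, `charge`, `rise_10_90`.
#' @export
biexp_kernel_truth <- function(tau_rise, tau_decay, amplitude = 1) {
  stopifnot(tau_rise > 0, tau_decay > tau_rise)
  t_peak <- tau_rise * tau_decay / (tau_decay - tau_rise) * log(tau_decay / tau_rise)
  raw_peak <- exp(-t_peak / tau_decay) - exp(-t_peak / tau_rise)
  scale <- amplitude / raw_peak
  charge <- scale * (tau_decay - tau_rise)
  f <- function(t) (exp(-t / tau_decay) - exp(-t / tau_rise)) / raw_peak
  t10 <- stats::uniroot(function(t) f(t) - 0.1, c(0, t_peak), tol = 1e-12)$root
  t90 <- stats::uniroot(function(t) f(t) - 0.9, c(t10, t_peak), tol = 1e-12)$root
  list(scale = scale, t_peak = t_peak, charge = charge, rise_10_90 = t90 - t10)
}

biexp_eval <- function(t, tau_rise, tau_decay, scale) {
  ifelse(t < 0, 0, scale * (exp(-t / tau_decay) - exp(-t / tau_rise)))
}

#' Specification for a synthetic postsynaptic-current train
#'
#' @param tau_rise,tau_decay Biexponential kernel time constants (ms); the
#'   defaults echo the fast GABAergic kinetics observed at this synapse
#'   (10-90% rise around 1.4 ms, mono-exponential decay around 18 ms).
#' @param amplitude Event peak amplitude (pA).
#' @param event_times Fixed event times (ms), or `NULL` to draw a Poisson
#'   train at `rate_hz`.
#' @param rate_hz Poisson event rate (Hz) when `event_times` is `NULL`.
#' @param noise_sd White Gaussian noise SD (pA).
#' @param duration Trace duration (ms).
#' @param dt Sampling interval (ms).
#' @param seed Mandatory seed for any stochastic draw.
#' @return List of class `synthetic_spec`.
#' @export
synthetic_spec <- function(tau_rise = 1.0, tau_decay = 18, amplitude = -20,
                           event_times = NULL, rate_hz = NULL, noise_sd = 0,
                           duration = 500, dt = 0.025, seed = NULL) {
  stopifnot(tau_rise > 0, tau_decay > tau_rise, dt > 0, duration > 0,
            noise_sd >= 0)
  if (is.null(event_times) && is.null(rate_hz)) {
    stop("provide event_times or rate_hz", call. = FALSE)
  }
  if ((noise_sd > 0 || is.null(event_times)) && is.null(seed)) {
    stop("a seed is mandatory when the spec has any stochastic component",
         call. = FALSE)
  }
  structure(list(tau_rise = tau_rise, tau_decay = tau_decay,
                 amplitude = amplitude, event_times = event_times,
                 rate_hz = rate_hz, noise_sd = noise_sd, duration = duration,
                 dt = dt, seed = seed),
            class = "synthetic_spec")
}

#' Generate a synthetic PSC train with ground truth
#'
#' Sum of biexponential kernels at the event times plus white Gaussian noise.
#' The truth table lists each event's time and analytic peak, peak time,
#' 10-90% rise time and charge; events closer than the kernel peak time are
#' flagged as overlapping.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `trace` (`sg_trace`, current) and `truth` (data frame).
#' @export
gen_psc_train <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  ev <- spec$event_times
  if (is.null(ev)) {
    ev <- with_seed(spec$seed, {
      n <- stats::rpois(1, spec$rate_hz * spec$duration / 1000)
      sort(stats::runif(n, 0, spec$duration))
    })
  }
  k <- biexp_kernel_truth(spec$tau_rise, spec$tau_decay, spec$amplitude)
  t <- seq(0, spec$duration, by = spec$dt)
  y <- numeric(length(t))
  for (te in ev) y <- y + biexp_eval(t - te, spec$tau_rise, spec$tau_decay, k$scale)
  if (spec$noise_sd > 0) {
    noise <- with_seed(spec$seed + 1L, stats::rnorm(length(t), 0, spec$noise_sd))
    y <- y + noise
  }
  overlap <- c(FALSE, diff(ev) < max(k$t_peak, spec$dt))
  truth <- data.frame(
    time = ev,
    amplitude = rep(spec$amplitude, length(ev)),
    peak_time = ev + k$t_peak,
    rise_10_90 = rep(k$rise_10_90, length(ev)),
    charge = rep(k$charge, length(ev)),
    overlapping = if (length(ev)) overlap else logical(0))
  trace <- sg_trace(y, dt = spec$dt, kind = "current",
                    meta = list(generator = "gen_psc_train", seed = spec$seed))
  list(trace = trace, truth = truth)
}

#' Generate a synthetic spike trace with constructed thresholds
#'
#' Each spike template rises from baseline at a sub-criterion slope up to the
#' constructed threshold voltage, then at a supra-criterion slope to the peak,
#' so the dV/dt threshold detector has an exact ground truth.
#'
#' @param spike_times Spike onset times (ms; template upstroke start).
#' @param threshold_mV Constructed threshold voltage (mV).
#' @param peak_mV Spike peak (mV).
#' @param baseline_mV Resting baseline (mV).
#' @param slow_slope,fast_slope Sub-/supra-criterion slopes (mV/ms); the
#'   dV/dt criterion (20 mV/ms) must lie strictly between them.
#' @param duration,dt Trace length and sampling interval (ms).
#' @param noise_sd Gaussian noise SD (mV); requires `seed` if > 0.
#' @param seed Seed for the noise draw.
#' @return List with `trace` (`sg_trace`, voltage) and `truth` (data frame of
#'   spike peak times and constructed thresholds).
#' @export
gen_spike_trace <- function(spike_times, threshold_mV = -50, peak_mV = 30,
                            baseline_mV = -70, slow_slope = 8, fast_slope = 300,
                            duration = NULL, dt = 0.025, noise_sd = 0,
                            seed = NULL) {
  if (slow_slope >= 20 || fast_slope <= 20) {
    stop("template inconsistent with the 20 mV/ms threshold criterion: need ",
         "slow_slope < 20 < fast_slope", call. = FALSE)
  }
  stopifnot(threshold_mV > baseline_mV, peak_mV > threshold_mV)
  t_slow <- (threshold_mV - baseline_mV) / slow_slope
  t_fast <- (peak_mV - threshold_mV) / fast_slope
  t_down <- (peak_mV - baseline_mV) / 100  # repolarisation at 100 mV/ms
  if (is.null(duration)) {
    duration <- if (length(spike_times)) max(spike_times) + 20 else 100
  }
  t <- seq(0, duration, by = dt)
  v <- rep(baseline_mV, length(t))
  for (ts in spike_times) {
    rel <- t - ts
    seg <- ifelse(rel < 0, 0,
           ifelse(rel < t_slow, slow_slope * rel,
           ifelse(rel < t_slow + t_fast,
                  (threshold_mV - baseline_mV) + fast_slope * (rel - t_slow),
           ifelse(rel < t_slow + t_fast + t_down,
                  (peak_mV - baseline_mV) - 100 * (rel - t_slow - t_fast), 0))))
    v <- v + seg
  }
  if (noise_sd > 0) {
    v <- v + with_seed(seed, stats::rnorm(length(t), 0, noise_sd))
  }
  truth <- data.frame(
    peak_time = spike_times + t_slow + t_fast,
    threshold = rep(threshold_mV, length(spike_times)))
  trace <- sg_trace(v, dt = dt, kind = "voltage",
                    meta = list(generator = "gen_spike_trace", seed = seed))
  list(trace = trace, truth = truth)
}

#' Monte-Carlo vesicle-release oracle
#'
#' Stochastic single-vesicle counterpart of [release_sequence()]: each trial
#' follows one release site through the recovered/effective/inactive cycle by
#' exact continuous-time sampling, releasing at each spike with the
#' deterministic facilitation probability. Per-spike release means converge
#' to the deterministic recursion.
#'
#' @param spike_times Strictly increasing spike times (ms).
#' @param params A [presyn_params()] bundle.
#' @param n_trials Number of Monte-Carlo trials (>= 1000).
#' @param seed RNG seed.
#' @return Data frame with per-spike `mean` released fraction, `se`, and the
#'   deterministic `expected` value.
#' @export
stochastic_release_oracle <- function(spike_times, params, n_trials = 10000,
                                      seed = 1) {
  stopifnot(inherits(params, "presyn_params"), n_trials >= 1000)
  if (any(diff(spike_times) <= 0)) {
    stop("spike times must be strictly increasing", call. = FALSE)
  }
  det <- release_sequence(spike_times, params)
  nsp <- length(spike_times)
  out <- with_seed(seed, {
    state <- rep.int(0L, n_trials)  # 0 recovered, 1 effective, 2 inactive
    u <- 0
    released <- matrix(FALSE, n_trials, nsp)
    for (k in seq_len(nsp)) {
      if (k > 1) {
        dt <- spike_times[k] - spike_times[k - 1L]
        u <- u * exp(-dt / params$tau_facil)
        # effective -> inactive -> recovered, exact CTMC sampling; the
        # inactive pool is snapshotted first so no vesicle gets two
        # recovery draws within one interval
        eff <- which(state == 1L)
        ina <- which(state == 2L)
        if (length(eff)) {
          t_ei <- stats::rexp(length(eff), 1 / params$tau_i)
          done <- t_ei <= dt
          t_ir <- stats::rexp(length(eff), 1 / params$tau_rec)
          state[eff[done & (t_ei + t_ir <= dt)]] <- 0L
          state[eff[done & (t_ei + t_ir > dt)]] <- 2L
        }
        if (length(ina)) {
          rec <- stats::rexp(length(ina), 1 / params$tau_rec) <= dt
          state[ina[rec]] <- 0L
        }
      }
      u <- u + params$p * (1 - u)
      avail <- which(state == 0L)
      if (length(avail)) {
        go <- stats::runif(length(avail)) < u
        released[avail[go], k] <- TRUE
        state[avail[go]] <- 1L
      }
    }
    m <- colMeans(released)
    data.frame(spike = seq_len(nsp), mean = m,
               se = sqrt(m * (1 - m) / n_trials), expected = as.numeric(det))
  })
  out
}
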