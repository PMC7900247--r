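## Trace-analysis operators. All operate on sg_trace objects, are clamp-mode
## aware (voltage metrics refuse current traces and vice versa) and are applied
## identically to simulated and synthetic traces.

#' Detect action potentials in a voltage trace
#'
#' One event per suprathreshold upstroke: local maxima above `peak_min` are
#' taken as spike peaks, peaks closer than the 1 ms refractory merging window
#' are merged (the larger survives), and a depolarisation still rising at the
#' end of the trace is excluded and flagged as truncated.
#'
#' @param trace Voltage `sg_trace`.
#' @param peak_min Minimum peak voltage to count as a spike (mV).
#' @param merge_ms Refractory merging window (ms).
#' @return Numeric vector of spike peak times (ms), possibly empty, with
#'   attribute `truncated` (logical) flagging a cut-off terminal spike.
#' @export
detect_spikes <- function(trace, peak_min = -20, merge_ms = 1) {
  stop_unless_kind(trace, "voltage", "detect_spikes")
  v <- trace$values
  n <- length(v)
  truncated <- FALSE
  if (n < 3) return(structure(numeric(0), truncated = FALSE))
  up <- which(v[2:(n - 1)] >= peak_min &
              v[2:(n - 1)] >= v[1:(n - 2)] &
              v[2:(n - 1)] > v[3:n]) + 1L
  # terminal suprathreshold rise with no turning point: truncated spike
  if (v[n] >= peak_min && v[n] >= v[n - 1]) truncated <- TRUE
  if (length(up) == 0) {
    return(structure(numeric(0), truncated = truncated))
  }
  # merge peaks within the refractory window, keeping the larger
  keep <- integer(0)
  for (i in up) {
    if (length(keep) && (i - keep[length(keep)]) * trace$dt < merge_ms) {
      if (v[i] > v[keep[length(keep)]]) keep[length(keep)] <- i
    } else {
      keep <- c(keep, i)
    }
  }
  structure(trace$t0 + (keep - 1L) * trace$dt, truncated = truncated)
}

#' Spike threshold by dV/dt criterion
#'
#' The firing threshold of a spike is the membrane potential at which the
#' depolarisation rate first exceeds `dvdt_crit` (default 20 mV/ms) in the
#' rising phase preceding the spike peak.
#'
#' @param trace Voltage `sg_trace`.
#' @param spike_time Peak time of a detected spike (ms).
#' @param dvdt_crit Criterion slope (mV/ms).
#' @return Threshold voltage (mV), or `NA` with attribute
#'   `undefined_threshold = TRUE` if the criterion is never met.
#' @export
spike_threshold <- function(trace, spike_time, dvdt_crit = 20) {
  stop_unless_kind(trace, "voltage", "spike_threshold")
  v <- trace$values
  ipk <- round((spike_time - trace$t0) / trace$dt) + 1L
  ipk <- max(2L, min(ipk, length(v)))
  dvdt <- c(NA, diff(v)) / trace$dt  # slope into each sample
  # walk back from the peak into the rising phase until the slope criterion
  # is met, then to the start of that supra-criterion run
  i <- ipk
  while (i > 2 && !is.na(dvdt[i]) && dvdt[i] < dvdt_crit &&
         v[i] > v[ipk] - 5) i <- i - 1L
  if (is.na(dvdt[i]) || dvdt[i] < dvdt_crit) {
    return(structure(NA_real_, undefined_threshold = TRUE))
  }
  while (i > 2 && !is.na(dvdt[i - 1L]) && dvdt[i - 1L] >= dvdt_crit) i <- i - 1L
  v[i - 1L]  # voltage where dV/dt first crosses the criterion upward
}

#' Spike-train metrics
#'
#' @param trace Voltage `sg_trace`.
#' @param stim_onset Time (ms) from which the first-spike delay is measured.
#' @param dvdt_crit Threshold criterion passed to [spike_threshold()].
#' @return List with spike times, count, per-spike threshold (mV), AHP depth
#'   (mV, threshold minus post-spike minimum), half-width (ms, at 50% of
#'   peak-threshold), first-spike delay (ms), average frequency (Hz, spikes
#'   per suprathreshold span) and instantaneous frequencies (Hz), summarised
#'   both as the first interspike interval and as the mean inverse interval.
#' @export
spike_metrics <- function(trace, stim_onset = 0, dvdt_crit = 20) {
  stop_unless_kind(trace, "voltage", "spike_metrics")
  st <- detect_spikes(trace)
  n <- length(st)
  out <- list(spike_times = as.numeric(st), count = n,
              truncated = isTRUE(attr(st, "truncated")))
  if (n == 0) {
    out[c("threshold", "ahp", "half_width")] <- list(numeric(0))
    out$first_spike_delay <- NA_real_
    out$avg_freq <- 0
    out$inst_freq <- numeric(0)
    out$inst_freq_first <- NA_real_
    out$inst_freq_mean <- NA_real_
    return(out)
  }
  v <- trace$values
  tt <- trace_time(trace)
  idx <- round((st - trace$t0) / trace$dt) + 1L
  thr <- vapply(st, function(ts) as.numeric(spike_threshold(trace, ts, dvdt_crit)),
                numeric(1))
  ahp <- half_width <- numeric(n)
  for (k in seq_len(n)) {
    i0 <- idx[k]
    i1 <- if (k < n) idx[k + 1L] else length(v)
    ahp[k] <- thr[k] - min(v[i0:i1])
    # half width at 50% of (peak - threshold)
    lev <- thr[k] + 0.5 * (v[i0] - thr[k])
    il <- i0; while (il > 1 && v[il - 1L] >= lev) il <- il - 1L
    ir <- i0; while (ir < i1 && v[ir + 1L] >= lev) ir <- ir + 1L
    half_width[k] <- cross_time(tt, v, ir, lev, rising = FALSE) -
      cross_time(tt, v, il, lev, rising = TRUE)
  }
  isi <- diff(st)
  out$threshold <- thr
  out$ahp <- ahp
  out$half_width <- half_width
  out$first_spike_delay <- st[1] - stim_onset
  out$avg_freq <- if (n >= 2) 1000 * (n - 1) / (st[n] - st[1]) else NA_real_
  out$inst_freq <- if (n >= 2) 1000 / isi else numeric(0)
  out$inst_freq_first <- if (n >= 2) 1000 / isi[1] else NA_real_
  out$inst_freq_mean <- if (n >= 2) mean(1000 / isi) else NA_real_
  out
}

## linear interpolation of the crossing time of level `lev` around index i
cross_time <- function(tt, v, i, lev, rising) {
  j <- if (rising) max(i - 1L, 1L) else min(i + 1L, length(v))
  if (j == i || v[j] == v[i]) return(tt[i])
  tt[i] + (tt[j] - tt[i]) * (lev - v[i]) / (v[j] - v[i])
}

## trapezoidal integral
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2) return(0)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}

## Mono-exponential decay fit y(t) = base + (amp)*exp(-(t - t0)/tau).
fit_monoexp <- function(t, y, base) {
  amp0 <- y[1] - base
  if (abs(amp0) < .Machine$double.eps) {
    return(list(tau = NA_real_, r2 = NA_real_, failed = TRUE, residuals = y - base))
  }
  frac <- (y - base) / amp0
  ok <- frac > 0.02
  tau0 <- if (sum(ok) >= 3) {
    f <- stats::lm(log(frac[ok]) ~ I(t[ok] - t[1]))
    unname(-1 / stats::coef(f)[2])
  } else {
    (t[length(t)] - t[1]) / 3
  }
  if (!is.finite(tau0) || tau0 <= 0) tau0 <- (t[length(t)] - t[1]) / 3
  fit <- try(minpack.lm::nlsLM(
    y ~ base + A * exp(-(t - t[1]) / tau),
    start = list(A = amp0, tau = tau0),
    lower = c(-Inf, 1e-4),
    control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
  if (inherits(fit, "try-error")) {
    return(list(tau = NA_real_, r2 = NA_real_, failed = TRUE, residuals = y - base))
  }
  res <- stats::residuals(fit)
  r2 <- 1 - sum(res^2) / max(sum((y - mean(y))^2), .Machine$double.eps)
  list(tau = unname(stats::coef(fit)[["tau"]]), r2 = r2, failed = FALSE,
       residuals = res)
}

#' Postsynaptic-current metrics
#'
#' Per-event peak amplitude, time-to-peak, 10-90% rise time, mono-exponential
#' decay time constant (least-squares fit from the peak towards the baseline,
#' ending at baseline return or the next stimulus, whichever comes first),
#' transferred charge (trace integral over the event window) and, for paired
#' stimuli, the paired-pulse ratio (second/first peak).
#'
#' @param trace Current `sg_trace`.
#' @param stim_times Stimulus times (ms); the 20 ms preceding the first
#'   stimulus define the baseline.
#' @param sign Event polarity: `"auto"` (dominant deviation), `"positive"` or
#'   `"negative"`.
#' @param baseline_ms Baseline averaging window before the first stimulus.
#' @return List of class `psc_metrics`: vectors `peak`, `time_to_peak`,
#'   `rise_10_90`, `tau_decay`, `charge`, `fit_r2` (one entry per stimulus),
#'   scalars `ppr` and `baseline`, and `fit_failed` flags.
#' @export
psc_metrics <- function(trace, stim_times, sign = c("auto", "positive", "negative"),
                        baseline_ms = 20) {
  stop_unless_kind(trace, "current", "psc_metrics")
  sign <- match.arg(sign)
  stopifnot(length(stim_times) >= 1)
  stim_times <- sort(stim_times)
  tt <- trace_time(trace)
  if (stim_times[1] <= tt[1]) {
    stop("baseline window must precede the first stimulus", call. = FALSE)
  }
  y <- trace$values
  ibase <- which(tt >= stim_times[1] - baseline_ms & tt < stim_times[1])
  if (length(ibase) < 2) ibase <- which(tt < stim_times[1])
  base <- mean(y[ibase])
  if (sign == "auto") {
    post <- y[tt >= stim_times[1]]
    s <- if (abs(max(post) - base) >= abs(min(post) - base)) 1 else -1
  } else {
    s <- if (sign == "positive") 1 else -1
  }
  nst <- length(stim_times)
  peak <- ttp <- rise <- tau <- charge <- r2 <- rep(NA_real_, nst)
  failed <- logical(nst)
  for (k in seq_len(nst)) {
    w0 <- stim_times[k]
    w1 <- if (k < nst) stim_times[k + 1L] else tt[length(tt)]
    iw <- which(tt >= w0 & tt <= w1)
    if (length(iw) < 3) next
    dev <- s * (y[iw] - base)
    ipk <- iw[which.max(dev)]
    peak[k] <- s * max(dev)
    ttp[k] <- tt[ipk] - w0
    # rise 10-90 between window start and peak (interpolated crossings)
    lev10 <- base + 0.1 * (y[ipk] - base)
    lev90 <- base + 0.9 * (y[ipk] - base)
    seg <- iw[1]:ipk
    i10 <- seg[which(s * (y[seg] - base) >= 0.1 * abs(y[ipk] - base))[1]]
    i90 <- seg[which(s * (y[seg] - base) >= 0.9 * abs(y[ipk] - base))[1]]
    if (!is.na(i10) && !is.na(i90)) {
      rise[k] <- cross_time(tt, s * y, i90, s * lev90, rising = TRUE) -
        cross_time(tt, s * y, i10, s * lev10, rising = TRUE)
    }
    # decay fit from peak to baseline return (5% of peak) or next stimulus
    idec <- ipk:iw[length(iw)]
    ret <- which(s * (y[idec] - base) <= 0.05 * abs(y[ipk] - base))[1]
    if (!is.na(ret) && ret >= 5) idec <- idec[1:ret]
    if (length(idec) >= 5) {
      f <- fit_monoexp(tt[idec], y[idec], base)
      tau[k] <- f$tau; r2[k] <- f$r2; failed[k] <- f$failed
    } else {
      failed[k] <- TRUE
    }
    charge[k] <- trapz(tt[iw], y[iw] - base)
  }
  structure(list(peak = peak, time_to_peak = ttp, rise_10_90 = rise,
                 tau_decay = tau, charge = charge, fit_r2 = r2,
                 fit_failed = failed,
                 ppr = if (nst >= 2) peak[2] / peak[1] else NA_real_,
                 baseline = base, sign = s),
            class = "psc_metrics")
}

#' EPSP metrics
#'
#' Peak depolarisation, 10-90% rise time and total depolarisation, the latter
#' computed as the trapezoidal integral of the membrane depolarisation
#' (relative to the pre-stimulus baseline) between the response onset and
#' 50 ms after the synaptic stimulation.
#'
#' @param trace Voltage `sg_trace` (subthreshold; a detected spike in the
#'   analysis window rejects the trace).
#' @param stim_time Stimulation time (ms).
#' @param window_ms Integration window measured from `stim_time` (ms).
#' @param baseline_ms Baseline window preceding the stimulus (ms).
#' @return List with `peak` (mV), `rise_10_90` (ms), `area` (mV ms), `onset`
#'   (ms) and `baseline` (mV); if a spike occurs in the window the metrics are
#'   `NA` and `rejected_spike` is `TRUE`.
#' @export
epsp_metrics <- function(trace, stim_time, window_ms = 50, baseline_ms = 20) {
  stop_unless_kind(trace, "voltage", "epsp_metrics")
  tt <- trace_time(trace)
  y <- trace$values
  ib <- which(tt >= stim_time - baseline_ms & tt < stim_time)
  if (length(ib) < 2) ib <- which(tt < stim_time)
  base <- mean(y[ib])
  bsd <- stats::sd(y[ib])
  iw <- which(tt >= stim_time & tt <= stim_time + window_ms)
  spikes <- detect_spikes(trace)
  spike_in <- any(spikes >= stim_time & spikes <= stim_time + window_ms)
  if (spike_in) {
    return(list(peak = NA_real_, rise_10_90 = NA_real_, area = NA_real_,
                onset = NA_real_, baseline = base, rejected_spike = TRUE))
  }
  crit <- base + max(3 * bsd, 1e-9, na.rm = TRUE)
  ion <- iw[which(y[iw] > crit)[1]]
  if (is.na(ion)) {
    return(list(peak = 0, rise_10_90 = NA_real_, area = 0, onset = NA_real_,
                baseline = base, rejected_spike = FALSE))
  }
  ipk <- iw[which.max(y[iw])]
  peak <- y[ipk] - base
  seg <- ion:ipk
  i10 <- seg[which(y[seg] - base >= 0.1 * peak)[1]]
  i90 <- seg[which(y[seg] - base >= 0.9 * peak)[1]]
  rise <- if (!is.na(i10) && !is.na(i90)) {
    cross_time(tt, y, i90, base + 0.9 * peak, rising = TRUE) -
      cross_time(tt, y, i10, base + 0.1 * peak, rising = TRUE)
  } else NA_real_
  iint <- ion:iw[length(iw)]
  area <- trapz(tt[iint], y[iint] - base)
  list(peak = peak, rise_10_90 = rise, area = area, onset = tt[ion],
       baseline = base, rejected_spike = FALSE)
}

#' Input-output frequency curve with linear fit
#'
#' @param input_hz Input (stimulation) frequencies (Hz).
#' @param output_hz Output (response) frequencies (Hz).
#' @return List of class `io_curve` with the two vectors plus `slope` and
#'   `intercept` from the least-squares linear fit.
#' @export
io_curve <- function(input_hz, output_hz) {
  stopifnot(length(input_hz) == length(output_hz), all(input_hz >= 0),
            all(output_hz >= 0))
  if (stats::var(output_hz) == 0) {
    slope <- 0
    intercept <- output_hz[1]
  } else {
    f <- stats::lm(output_hz ~ input_hz)
    slope <- unname(stats::coef(f)[2])
    intercept <- unname(stats::coef(f)[1])
  }
  structure(list(input_hz = input_hz, output_hz = output_hz,
                 slope = slope, intercept = intercept),
            class = "io_curve")
}

#' Paired comparison of a metric between conditions
#'
#' Reports the percent change `100 * (mean(treated) - mean(control)) /
#' abs(mean(control))`, means with SEM, and a paired two-sided Student t-test.
#'
#' @param control,treated Numeric series of equal length (paired repeats).
#' @param metric Optional metric name carried through to the output.
#' @return List of class `condition_comparison`.
#' @export
compare_conditions <- function(control, treated, metric = "") {
  stopifnot(length(control) == length(treated), length(control) >= 1)
  mc <- mean(control); mt <- mean(treated)
  pct <- 100 * (mt - mc) / abs(mc)
  sem <- function(x) if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else NA_real_
  d <- treated - control
  degenerate <- length(d) < 2 || stats::sd(d) == 0
  if (degenerate) {
    tstat <- if (length(d) >= 2 && all(d == 0)) 0 else NA_real_
    p <- NA_real_
  } else {
    ht <- stats::t.test(treated, control, paired = TRUE)
    tstat <- unname(ht$statistic)
    p <- ht$p.value
  }
  structure(list(metric = metric, control_mean = mc, treated_mean = mt,
                 control_sem = sem(control), treated_sem = sem(treated),
                 percent_change = pct, t = tstat, p = p,
                 degenerate = degenerate, n = length(control)),
            class = "condition_comparison")
}

#' @export
print.condition_comparison <- function(x, ...) {
  cat(sprintf("<condition_comparison> %s: %+.1f%% (control %.4g +/- %.2g, treated %.4g +/- %.2g, n=%d, t=%.3g, p=%.3g)\n",
              x$metric, x$percent_change, x$control_mean, x$control_sem,
              x$treated_mean, x$treated_sem, x$n, x$t, x$p))
  invisible(x)
}
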