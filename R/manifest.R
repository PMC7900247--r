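#' Write a run manifest
#'
#' Records everything needed to reproduce a simulation bit-identically:
#' package version, condition name with the checksums of every parameter
#' file, the protocol function and its arguments, integrator settings and
#' the seed. Exactly one manifest is written per output directory.
#'
#' @param dir Output directory (created if needed).
#' @param protocol Name of the protocol function (e.g.
#'   `"run_current_steps"`).
#' @param args Named list of arguments passed to the protocol function.
#' @param seed Seed recorded for stochastic components (simulations are
#'   deterministic; the seed governs synthetic generators only).
#' @return Path to the manifest file, invisibly.
#' @export
run_manifest <- function(dir, protocol, args, seed = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- c(
    list.files(sg_extdata("cells"), full.names = TRUE),
    list.files(sg_extdata("synapses"), full.names = TRUE),
    list.files(sg_extdata("receptors"), full.names = TRUE),
    list.files(sg_extdata("conditions"), full.names = TRUE))
  sums <- as.list(tools::md5sum(files))
  names(sums) <- basename(files)
  man <- list(schema_version = 1,
              package = "sevogranule",
              version = as.character(utils::packageVersion("sevogranule")),
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
              protocol = protocol,
              args = args,
              seed = seed,
              parameter_checksums = sums)
  path <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(man, path)
  invisible(path)
}

#' Re-run a protocol from its manifest
#'
#' @param dir Directory containing a `manifest.yaml` written by
#'   [run_manifest()].
#' @return The protocol result of re-running the recorded call.
#' @export
rerun_manifest <- function(dir) {
  path <- file.path(dir, "manifest.yaml")
  if (!file.exists(path)) stop("no manifest.yaml in ", dir, call. = FALSE)
  man <- yaml::read_yaml(path)
  if (!identical(man$schema_version, 1L) && !identical(man$schema_version, 1)) {
    stop("manifest schema version ", man$schema_version,
         " is not supported", call. = FALSE)
  }
  fn <- get(man$protocol, envir = asNamespace("sevogranule"))
  do.call(fn, man$args)
}

#' Reproduce the modelled-figure protocols
#'
#' Runs the condition-compared simulation protocols behind the modelling
#' figures and returns the derived metrics next to the published simulation
#' values with the package's acceptance tolerances.
#'
#' Registered ids: `"fig7"` (intrinsic excitability: thresholds and f-I
#' behaviour under current steps), `"fig8a"` (single-stimulus IPSC percent
#' changes), `"fig8b"` (EPSP percent changes with and without inhibition),
#' `"fig8cd"` (paired-pulse E/I sweep orderings).
#'
#' @param figure One of the registered figure ids.
#' @param quick If `TRUE`, coarser step grids are used where applicable.
#' @return Data frame with one row per checked quantity: `metric`, `value`,
#'   `reference`, `tolerance`, `pass`.
#' @export
reproduce <- function(figure = c("fig7", "fig8a", "fig8b", "fig8cd"),
                      quick = FALSE) {
  if (!is.character(figure) || length(figure) != 1 ||
      !figure %in% c("fig7", "fig8a", "fig8b", "fig8cd")) {
    stop("unregistered figure id; valid ids: fig7, fig8a, fig8b, fig8cd",
         call. = FALSE)
  }
  row <- function(metric, value, reference, tolerance) {
    data.frame(metric = metric, value = value, reference = reference,
               tolerance = tolerance,
               pass = is.finite(value) & abs(value - reference) <= tolerance)
  }
  if (figure == "fig7") {
    th <- intrinsic_thresholds(quick = quick)
    out <- rbind(
      row("control_threshold_mV", th["control"], -47, 1.5),
      row("sevoflurane_threshold_mV", th["sevoflurane"], -54.8, 1.5))
  } else if (figure == "fig8a") {
    ch <- ipsc_percent_changes()
    out <- rbind(
      row("ipsc_peak_change_pct", ch["peak"], 46.3, 0.15 * 46.3),
      row("ipsc_charge_change_pct", ch["charge"], 99.6, 0.15 * 99.6))
  } else if (figure == "fig8b") {
    ch <- epsp_percent_changes()
    out <- rbind(
      row("epsp_peak_change_inh_pct", ch["peak_inh"], -32.4, 0.15 * 32.4),
      row("epsp_area_change_inh_pct", ch["area_inh"], -57.1, 0.15 * 57.1),
      row("epsp_peak_change_noinh_pct", ch["peak_noinh"], -8.9, 0.15 * 8.9),
      row("epsp_area_change_noinh_pct", ch["area_noinh"], -10.2, 0.15 * 10.2))
  } else {
    sw <- ei_sweep_summary(quick = quick)
    out <- data.frame(metric = names(sw), value = as.numeric(sw),
                      reference = 1, tolerance = 0,
                      pass = as.numeric(sw) == 1)
  }
  rownames(out) <- NULL
  out
}

## ---- figure-level computations shared by reproduce() and the scripts ----

#' First-spike threshold of control and sevoflurane models near rheobase
#' @param quick Coarser current grid if `TRUE`.
#' @param dt Time step (ms).
#' @return Named vector of thresholds (mV) for the two conditions.
#' @export
intrinsic_thresholds <- function(quick = FALSE, dt = 0.025) {
  vapply(c(control = "control", sevoflurane = "sevoflurane"), function(cond) {
    steps <- if (quick) seq(1, 16, by = 2) else seq(1, 16, by = 1)
    res <- run_current_steps(cond, steps = steps, duration = 500, dt = dt)
    ft <- fi_table(res)
    # threshold read out at the first suprathreshold step (near rheobase)
    ok <- which(ft$n_spikes >= 1)
    if (!length(ok)) return(NA_real_)
    ft$threshold_mV[ok[1]]
  }, numeric(1))
}

#' Single-stimulus IPSC percent changes (sevoflurane vs control)
#' @param holding Holding potential (mV).
#' @return Named vector: `peak`, `charge`, `tau`, and paired-pulse `ppr`
#'   percent changes.
#' @export
ipsc_percent_changes <- function(holding = -60) {
  m <- lapply(c(control = "control", sevoflurane = "sevoflurane"), function(cond) {
    r1 <- run_ipsc_protocol(cond, n_pulses = 1, holding = holding)
    r2 <- run_ipsc_protocol(cond, n_pulses = 2, freq = 50, holding = holding)
    p1 <- psc_metrics(r1$traces$clamp, r1$stim$times)
    p2 <- psc_metrics(r2$traces$clamp, r2$stim$times)
    c(peak = p1$peak[1], charge = p1$charge[1], tau = p1$tau_decay[1],
      ppr = p2$ppr)
  })
  pct <- function(k) 100 * (m$sevoflurane[k] - m$control[k]) / abs(m$control[k])
  c(peak = unname(pct("peak")), charge = unname(pct("charge")),
    tau = unname(pct("tau")), ppr = unname(pct("ppr")))
}

#' EPSP percent changes with and without inhibition
#'
#' The inhibition-active comparison activates three mossy fibres and one
#' Golgi cell; the null-inhibition comparison activates a single mossy fibre
#' (no Golgi cell), mirroring the two modelled EPSP configurations.
#'
#' @param n_mf_inh,n_goc_inh Circuit for the inhibition-active comparison.
#' @param n_mf_noinh Mossy-fibre count for the inhibition-disabled
#'   comparison.
#' @return Named vector: `peak_inh`, `area_inh`, `peak_noinh`, `area_noinh`.
#' @export
epsp_percent_changes <- function(n_mf_inh = 3, n_goc_inh = 1, n_mf_noinh = 1) {
  one <- function(cond, n_mf, n_goc) {
    r <- run_epsp_protocol(cond, n_mf = n_mf, n_goc = n_goc)
    epsp_metrics(r$traces$vm, r$stim$times)
  }
  pct <- function(a, b) 100 * (b - a) / abs(a)
  ci <- one("control", n_mf_inh, n_goc_inh)
  si <- one("sevoflurane", n_mf_inh, n_goc_inh)
  cn <- one("control", n_mf_noinh, 0)
  sn <- one("sevoflurane", n_mf_noinh, 0)
  c(peak_inh = pct(ci$peak, si$peak), area_inh = pct(ci$area, si$area),
    peak_noinh = pct(cn$peak, sn$peak), area_noinh = pct(cn$area, sn$area))
}

#' E/I sweep ordering summary
#'
#' Runs the paired-pulse frequency sweep over E/I combinations under both
#' conditions and evaluates the qualitative orderings: first spike
#' anticipated under sevoflurane with no inhibition, delayed with inhibition
#' (prolongation growing over the lower Golgi-cell counts), I/O slope
#' reduced, spike count reduced wherever at least one GoC is active.
#' A response without any spike is scored as maximally delayed (the full
#' response window).
#'
#' @param n_goc_grid Golgi-cell counts to test.
#' @param freqs Input frequencies (Hz).
#' @param quick Smaller grid if `TRUE`.
#' @return Named logical-as-numeric vector (1 = ordering holds).
#' @export
ei_sweep_summary <- function(n_goc_grid = 0:3, freqs = c(20, 50, 100, 200),
                             quick = FALSE) {
  if (quick) { n_goc_grid <- c(0, 1, 2); freqs <- c(50, 100, 200) }
  sweep1 <- function(cond, n_goc) {
    run_pp_frequency_sweep(cond, n_mf = 3, n_goc = n_goc,
                           freqs = freqs)$extras$sweep
  }
  window <- 100
  ctrl <- lapply(n_goc_grid, function(g) sweep1("control", g))
  sevo <- lapply(n_goc_grid, function(g) sweep1("sevoflurane", g))
  names(ctrl) <- names(sevo) <- as.character(n_goc_grid)
  mean_delay <- function(df) {
    d <- df$first_delay_ms
    d[is.na(d)] <- window
    mean(d)
  }
  slope <- function(df) io_curve(df$freq_hz, df$out_hz)$slope
  with_goc <- as.character(n_goc_grid[n_goc_grid >= 1])
  delay_prol <- vapply(with_goc, function(g) {
    mean_delay(sevo[[g]]) - mean_delay(ctrl[[g]])
  }, numeric(1))
  grows <- if (length(delay_prol) >= 2) {
    # prolongation grows over the GoC counts where inhibition is not yet
    # saturating both conditions (both still producing spikes)
    active <- vapply(with_goc, function(g) {
      sum(ctrl[[g]]$n_spikes) + sum(sevo[[g]]$n_spikes) > 0
    }, logical(1))
    k <- max(2, sum(active))
    all(diff(delay_prol[seq_len(min(k, length(delay_prol)))]) >= 0)
  } else NA
  c(first_spike_anticipated_no_inh =
      as.numeric(mean_delay(sevo[["0"]]) < mean_delay(ctrl[["0"]])),
    first_spike_delayed_with_inh = as.numeric(all(delay_prol > 0)),
    delay_grows_with_goc = as.numeric(grows),
    slope_reduced_with_inh = as.numeric(all(vapply(with_goc, function(g) {
      slope(sevo[[g]]) < slope(ctrl[[g]])
    }, logical(1)))),
    spikes_reduced_with_inh = as.numeric(all(vapply(with_goc, function(g) {
      sum(sevo[[g]]$n_spikes) < sum(ctrl[[g]]$n_spikes)
    }, logical(1)))))
}
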