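#' Voltage-dependent magnesium block of the NMDA receptor
#'
#' Two-parameter sigmoidal (Jahr-Stevens-type) block factor
#' `1 / (1 + mg / k_conc * exp(-k_v * V))`. With `mg = 0` the factor is
#' exactly 1 (Mg-free protocols); it is monotonically non-decreasing in V.
#'
#' @param v Membrane potential (mV), scalar or vector.
#' @param mg Extracellular Mg concentration (mM, >= 0).
#' @param k_conc Half-blocking concentration scale (mM).
#' @param k_v Voltage sensitivity (1/mV).
#' @return Block factor in (0, 1].
#' @export
mg_block <- function(v, mg, k_conc = 3.57, k_v = 0.062) {
  if (any(mg < 0)) stop("mg must be >= 0", call. = FALSE)
  1 / (1 + (mg / k_conc) * exp(-k_v * v))
}

#' Load a multi-state receptor kinetic scheme
#'
#' Schemes are versioned YAML files listing states (with designated open
#' states), ligand-dependent and ligand-independent transition rates, the
#' reversal potential and the receptor-gating Q10 class. The registered
#' families are `ampa`, `nmda`, `gabaa_alpha1`, `gabaa_alpha6` and `kainate`
#' (the kainate scheme is the AMPA scheme with slowed recovery from
#' desensitisation).
#'
#' @param family Scheme name or path to a scheme YAML file.
#' @param temperature Simulation temperature (degrees C); transition rates are
#'   Q10-corrected from the scheme's `t_orig_C`.
#' @return Object of class `receptor_scheme`.
#' @export
receptor_scheme <- function(family, temperature = 30) {
  path <- if (file.exists(family)) family else {
    sg_extdata("receptors", paste0(family, ".yaml"))
  }
  x <- read_params(path)
  states <- unlist(x$states)
  tr <- do.call(rbind, lapply(x$transitions, function(e) {
    data.frame(from = e$from, to = e$to, rate = e$rate,
               ligand = if (is.null(e$ligand)) "none" else e$ligand,
               stringsAsFactors = FALSE)
  }))
  bad <- setdiff(unique(c(tr$from, tr$to, unlist(x$open))), states)
  if (length(bad)) {
    stop("scheme ", x$family, " references unknown states: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  qf <- q10_factor(if (is.null(x$q10)) 2.4 else x$q10,
                   if (is.null(x$t_orig_C)) temperature else x$t_orig_C,
                   temperature)
  tr$rate <- tr$rate * qf
  structure(list(family = x$family, states = states, open = unlist(x$open),
                 transitions = tr, e_rev = x$e_rev_mV,
                 access = x$access,
                 mg = x$mg_block,
                 q10_applied = qf),
            class = "receptor_scheme")
}

## Build the generator matrix A (columns = from-state, conservative by
## construction) at transmitter concentration conc (mM).
scheme_generator <- function(scheme, conc_direct, conc_spill = 0) {
  ns <- length(scheme$states)
  A <- matrix(0, ns, ns, dimnames = list(scheme$states, scheme$states))
  acc <- scheme$access
  wd <- if (is.null(acc$direct)) 1 else acc$direct
  ws <- if (is.null(acc$spill)) 1 else acc$spill
  conc <- wd * conc_direct + ws * conc_spill
  for (i in seq_len(nrow(scheme$transitions))) {
    tr <- scheme$transitions[i, ]
    r <- tr$rate * if (tr$ligand == "none") 1 else conc
    A[tr$to, tr$from] <- A[tr$to, tr$from] + r
    A[tr$from, tr$from] <- A[tr$from, tr$from] - r
  }
  A
}

#' Transmitter concentration time course with glomerular spillover
#'
#' Each release event contributes a direct cleft component (square pulse of
#' 1 ms, amplitude proportional to the released fraction) and a slower
#' glomerular spillover component (biexponential, peak-normalised), emulating
#' diffusion in the cerebellar glomerulus.
#'
#' @param time Sample times (ms).
#' @param release_times Release (transmitter onset) times (ms), i.e. spike
#'   times plus the synaptic delay.
#' @param released Released pool fraction per event (from
#'   [release_sequence()]); scales both components.
#' @param direct List `amp_mM`, `dur_ms` for the cleft pulse.
#' @param spill List `amp_mM`, `tau_rise_ms`, `tau_decay_ms`.
#' @return List of class `transmitter_timecourse` with `time`, `direct`,
#'   `spill` (mM).
#' @export
transmitter_timecourse <- function(time, release_times, released,
                                   direct = list(amp_mM = 1, dur_ms = 1),
                                   spill = list(amp_mM = 0.3, tau_rise_ms = 1.5,
                                                tau_decay_ms = 30)) {
  stopifnot(length(release_times) == length(released))
  dir <- spl <- numeric(length(time))
  if (length(release_times)) {
    k <- biexp_kernel_truth(spill$tau_rise_ms, spill$tau_decay_ms, spill$amp_mM)
    for (i in seq_along(release_times)) {
      t0 <- release_times[i]
      dir <- dir + released[i] * direct$amp_mM *
        as.numeric(time >= t0 & time < t0 + direct$dur_ms)
      spl <- spl + released[i] *
        biexp_eval(time - t0, spill$tau_rise_ms, spill$tau_decay_ms, k$scale)
    }
  }
  structure(list(time = time, direct = dir, spill = spl),
            class = "transmitter_timecourse")
}

#' Postsynaptic current of a receptor scheme
#'
#' Integrates the kinetic scheme occupancies against a transmitter time
#' course (stiff solver, `deSolve::lsoda`) and returns the current
#' `weight * open-occupancy * (V - E_rev) * mg-block`, i.e. a voltage-clamp
#' current for fixed `v`.
#'
#' @param scheme A [receptor_scheme()].
#' @param transmitter A [transmitter_timecourse()].
#' @param v Holding potential (mV, scalar).
#' @param weight_nS Maximal conductance weight (nS).
#' @param mg_mM Extracellular Mg (mM); only used if the scheme declares a
#'   Mg block (NMDA).
#' @param method Integrator: `"euler"` (implicit backward Euler on the
#'   sampling grid; conservative and fast, the default) or `"lsoda"`
#'   (adaptive stiff solver via deSolve; used as an independent cross-check).
#' @return List with `trace` (`sg_trace`, current in pA), `open` (open-state
#'   occupancy over time) and `occupancy` (matrix of all state occupancies).
#' @export
receptor_response <- function(scheme, transmitter, v, weight_nS = 1, mg_mM = 0,
                              method = c("euler", "lsoda")) {
  stopifnot(inherits(scheme, "receptor_scheme"),
            inherits(transmitter, "transmitter_timecourse"),
            length(v) == 1)
  method <- match.arg(method)
  tt <- transmitter$time
  ns <- length(scheme$states)
  x0 <- c(1, rep(0, ns - 1))  # all probability in the first (unbound) state
  if (method == "euler") {
    # generator split into ligand-independent and ligand-proportional parts
    A0 <- scheme_generator(scheme, 0, 0)
    unit <- scheme
    unit$access <- list(direct = 1, spill = 0)
    A1 <- scheme_generator(unit, 1, 0) - A0
    acc <- scheme$access
    wd <- if (is.null(acc$direct)) 1 else acc$direct
    ws <- if (is.null(acc$spill)) 1 else acc$spill
    conc <- wd * transmitter$direct + ws * transmitter$spill
    dt <- tt[2] - tt[1]
    occ <- matrix(0, length(tt), ns, dimnames = list(NULL, scheme$states))
    occ[1, ] <- x0
    x <- x0
    eye <- diag(ns)
    for (k in 2:length(tt)) {
      M <- eye - dt * (A0 + conc[k] * A1)
      x <- solve(M, x)
      occ[k, ] <- x
    }
  } else {
    fd <- stats::approxfun(tt, transmitter$direct, method = "constant",
                           yleft = 0, yright = 0)
    fs <- stats::approxfun(tt, transmitter$spill, rule = 2)
    rhs <- function(t, x, p) {
      A <- scheme_generator(scheme, fd(t), fs(t))
      list(A %*% x)
    }
    sol <- deSolve::lsoda(x0, tt, rhs, parms = NULL, rtol = 1e-8, atol = 1e-10)
    occ <- sol[, -1, drop = FALSE]
    colnames(occ) <- scheme$states
  }
  if (any(abs(rowSums(occ) - 1) > 1e-6)) {
    stop("receptor scheme is not conservative: occupancies drift from 1",
         call. = FALSE)
  }
  open <- rowSums(occ[, scheme$open, drop = FALSE])
  blk <- if (!is.null(scheme$mg)) {
    mg_block(v, mg_mM, scheme$mg$k_conc_mM, scheme$mg$k_v_per_mV)
  } else 1
  i_pa <- weight_nS * open * (v - scheme$e_rev) * blk
  dt <- tt[2] - tt[1]
  list(trace = sg_trace(i_pa, dt = dt, kind = "current", t0 = tt[1],
                        meta = list(receptor = scheme$family, v = v)),
       open = open, occupancy = occ)
}
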