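#' Construct a uniformly sampled trace
#'
#' The unit all analysis operators consume: a voltage (mV) or current (pA)
#' time series at a fixed sampling interval, with protocol metadata.
#'
#' @param values Numeric vector of samples (mV for voltage, pA for current).
#' @param dt Sampling interval in ms (> 0).
#' @param kind `"voltage"` or `"current"`.
#' @param t0 Start time in ms (default 0).
#' @param meta Named list of metadata (protocol id, condition, seed, ...).
#' @return Object of class `sg_trace`.
#' @export
sg_trace <- function(values, dt, kind = c("voltage", "current"), t0 = 0,
                     meta = list()) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(values), is.numeric(dt), length(dt) == 1, dt > 0)
  if (!all(is.finite(values))) {
    stop("trace contains non-finite samples", call. = FALSE)
  }
  structure(list(values = as.numeric(values), dt = as.numeric(dt),
                 kind = kind, t0 = as.numeric(t0), meta = meta),
            class = "sg_trace")
}

#' @export
print.sg_trace <- function(x, ...) {
  cat(sprintf("<sg_trace> %s, %d samples @ %g ms (%.1f ms), range [%.3g, %.3g] %s\n",
              x$kind, length(x$values), x$dt, length(x$values) * x$dt,
              min(x$values), max(x$values),
              if (x$kind == "voltage") "mV" else "pA"))
  invisible(x)
}

#' Time axis of a trace (ms)
#' @param trace An `sg_trace`.
#' @return Numeric vector of sample times.
#' @export
trace_time <- function(trace) {
  trace$t0 + (seq_along(trace$values) - 1L) * trace$dt
}

#' @export
as.data.frame.sg_trace <- function(x, ...) {
  data.frame(time_ms = trace_time(x), value = x$values,
             signal_kind = x$kind, stringsAsFactors = FALSE)
}

stop_unless_kind <- function(trace, kind, what) {
  if (!inherits(trace, "sg_trace")) stop(what, " expects an sg_trace", call. = FALSE)
  if (!identical(trace$kind, kind)) {
    stop(what, " expects a ", kind, " trace, got ", trace$kind, call. = FALSE)
  }
  invisible(TRUE)
}

#' Write a trace to columnar CSV
#'
#' Samples are serialised with 17 significant digits so that a write/read
#' round trip reproduces the double-precision values bit-identically.
#'
#' @param trace An `sg_trace`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "sg_trace"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# sg_trace schema_version=1 dt=%.17g t0=%.17g kind=%s n=%d",
                     trace$dt, trace$t0, trace$kind, length(trace$values)), con)
  writeLines("time_ms,value,signal_kind", con)
  t <- trace_time(trace)
  writeLines(sprintf("%.17g,%.17g,%s", t, trace$values, trace$kind), con)
  invisible(path)
}

#' Read a trace written by [write_trace_csv()]
#' @param path CSV file path.
#' @return An `sg_trace`.
#' @export
read_trace_csv <- function(path) {
  hdr <- readLines(path, n = 1L)
  if (!grepl("^# sg_trace schema_version=1 ", hdr)) {
    stop("not a version-1 sg_trace CSV: ", path, call. = FALSE)
  }
  gv <- function(key) {
    m <- regmatches(hdr, regexpr(paste0(" ", key, "=[^ ]+"), hdr))
    sub(paste0(" ", key, "="), "", m)
  }
  dt <- as.numeric(gv("dt")); t0 <- as.numeric(gv("t0")); kind <- gv("kind")
  n_expect <- as.integer(gv("n"))
  d <- utils::read.csv(path, comment.char = "#")
  if (!identical(names(d), c("time_ms", "value", "signal_kind"))) {
    stop("trace CSV corrupted (unexpected columns): ", path, call. = FALSE)
  }
  if (nrow(d) != n_expect) {
    stop("trace CSV truncated: expected ", n_expect, " rows, found ", nrow(d),
         call. = FALSE)
  }
  sg_trace(d$value, dt = dt, kind = kind, t0 = t0)
}
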