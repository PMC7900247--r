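#' @useDynLib sevogranule, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

sg_extdata <- function(...) {
  p <- system.file("extdata", ..., package = "sevogranule")
  if (identical(p, "")) stop("parameter file not found: ", file.path(...), call. = FALSE)
  p
}

#' Read a versioned parameter file
#'
#' Parameter files are YAML with a `schema_version` field; every load records
#' the file's md5 checksum so run manifests can attest to the exact parameters
#' used.
#'
#' @param path Path to a YAML parameter file.
#' @return Named list with attributes `file` and `md5`.
#' @export
read_params <- function(path) {
  x <- yaml::read_yaml(path)
  if (is.null(x$schema_version)) {
    stop("parameter file lacks schema_version: ", path, call. = FALSE)
  }
  attr(x, "file") <- normalizePath(path)
  attr(x, "md5") <- unname(tools::md5sum(path))
  x
}

#' List registered condition bundles
#' @return Character vector of condition names.
#' @export
list_conditions <- function() {
  sub("\\.yaml$", "", list.files(sg_extdata("conditions"), pattern = "\\.yaml$"))
}

#' Load a named condition bundle
#'
#' A condition is a named, auditable set of deviations from the control
#' parameter files: intrinsic overrides (channel densities, Na-scheme
#' kinetics) and synaptic overrides (receptor weights and kinetic scales,
#' release probability). `"control"` is the identity bundle.
#'
#' @param name Condition name, e.g. `"control"`, `"sevoflurane"`, `"sevo_nap"`,
#'   `"sevo_nap_kv"`.
#' @return Object of class `condition_set`.
#' @export
condition_set <- function(name) {
  if (inherits(name, "condition_set")) return(name)
  stopifnot(is.character(name), length(name) == 1)
  avail <- list_conditions()
  if (!name %in% avail) {
    stop("unknown condition '", name, "'; registered conditions: ",
         paste(avail, collapse = ", "), call. = FALSE)
  }
  x <- read_params(sg_extdata("conditions", paste0(name, ".yaml")))
  x$name <- x$condition
  class(x) <- "condition_set"
  x
}

#' @export
print.condition_set <- function(x, ...) {
  cat("<condition_set>", x$name, "\n")
  ov <- c(x$intrinsic, x$synaptic)
  if (length(ov) == 0) {
    cat("  identity bundle (no overrides)\n")
  } else {
    for (k in names(ov)) cat(sprintf("  %s = %s\n", k, format(ov[[k]])))
  }
  invisible(x)
}

## Apply dotted-path overrides ("a.b.c": value) to a nested list.  Every path
## must already exist in the baseline so condition bundles stay auditable.
apply_overrides <- function(base, overrides, where = "") {
  log <- character(0)
  for (key in names(overrides)) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    node <- base
    for (i in seq_along(parts)) {
      if (!is.list(node) || is.null(node[[parts[i]]])) {
        stop("condition override '", key, "' does not name a baseline key",
             if (nzchar(where)) paste0(" in ", where), call. = FALSE)
      }
      node <- node[[parts[i]]]
    }
    base[[parts]] <- overrides[[key]]
    log <- c(log, sprintf("%s: %s -> %s", key, format(node), format(overrides[[key]])))
  }
  attr(base, "override_log") <- c(attr(base, "override_log"), log)
  base
}

## Overrides scoped to one file: keys look like "grc.densities_S_cm2.na_hillock";
## strip the leading scope token and keep matching entries.
scoped_overrides <- function(overrides, scope) {
  pre <- paste0(scope, ".")
  keep <- startsWith(names(overrides), pre)
  out <- overrides[keep]
  names(out) <- substring(names(out), nchar(pre) + 1L)
  out
}
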