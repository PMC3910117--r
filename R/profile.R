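#' Construct a single time-course profile
#'
#' A profile is one gene's expression series measured at `m` equally
#' spaced time points, with sample `i` at internal time `t_i = i * delta`.
#' Profiles with missing values are excluded upstream (see
#' [read_expression_tsv()]); all fitting operations require finite values.
#'
#' @param gene_id Gene identifier (single string).
#' @param values Numeric vector of expression measurements.
#' @param delta Sampling interval (> 0).
#' @return An object of class `tc_profile`.
#' @export
tc_profile <- function(gene_id, values, delta = 1) {
  stopifnot(is.character(gene_id), length(gene_id) == 1L)
  values <- as.numeric(values)
  if (!all(is.finite(values))) {
    stop("profile '", gene_id, "' contains non-finite values", call. = FALSE)
  }
  if (delta <= 0) stop("delta must be positive", call. = FALSE)
  structure(list(gene_id = gene_id, values = values, delta = delta),
            class = "tc_profile")
}

#' @export
print.tc_profile <- function(x, ...) {
  cat(sprintf("<tc_profile> %s: m = %d, delta = %g\n",
              x$gene_id, length(x$values), x$delta))
  invisible(x)
}

# Accept either a tc_profile or a bare numeric vector everywhere a profile
# is expected; returns list(values, delta).
as_profile_values <- function(x, delta) {
  if (inherits(x, "tc_profile")) {
    list(values = x$values, delta = x$delta)
  } else {
    list(values = as.numeric(x), delta = delta)
  }
}
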