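#' Residual of the constant (white-noise) null model
#'
#' Under the null a profile is a constant plus Gaussian noise,
#' `x(t) = d + eps(t)`. The least-squares intercept is the profile mean
#' and the residual sum of squares is `S0^2 = sum((x - mean(x))^2)`.
#'
#' @inheritParams finite_first_derivative
#' @return List with `s0_sq` and `d_hat` (the mean).
#' @export
null_residual <- function(x, delta = 1) {
  v <- as_profile_values(x, delta)$values
  stopifnot(length(v) >= 2)
  d_hat <- mean(v)
  list(s0_sq = sum((v - d_hat)^2), d_hat = d_hat)
}

#' F statistic comparing the full model to the constant null
#'
#' The six-parameter model nests the one-parameter constant model, so
#' \deqn{F = \frac{(S_0^2 - S_1^2)/5}{S_1^2/(m-6)}}
#' is referred to the F distribution with (5, m - 6) degrees of freedom.
#' Because the two-step fit is not the exact least-squares optimum,
#' `S1^2` can exceed `S0^2` for near-constant profiles; negative values
#' are clamped to 0. A perfect fit (`s1_sq = 0`) returns `Inf`.
#'
#' @param s0_sq Null-model residual sum of squares.
#' @param s1_sq Full-model residual sum of squares.
#' @param m Number of time points (>= 8).
#' @return Nonnegative F value (possibly `Inf`).
#' @export
f_statistic <- function(s0_sq, s1_sq, m) {
  stopifnot(m >= 8, s0_sq >= 0, s1_sq >= 0)
  if (s1_sq == 0) return(Inf)
  max(0, (m - 6) / 5 * (s0_sq / s1_sq - 1))
}

#' Critical value of the screen at a given significance level
#'
#' The upper-`gamma` quantile of the F distribution with (5, m - 6)
#' degrees of freedom.
#'
#' @param gamma Significance level in (0, 1).
#' @param m Number of time points (>= 8).
#' @return The threshold above which the null is rejected.
#' @export
f_threshold <- function(gamma, m) {
  stopifnot(gamma > 0, gamma < 1, m >= 8)
  stats::qf(1 - gamma, 5, m - 6)
}

#' Screen a set of profiles for model-following (non-noise) expression
#'
#' Fits the damped-sinusoid model to every profile, computes the F
#' statistic against the constant-plus-noise null and compares it to the
#' F(5, m - 6) critical value at level `gamma`. Degenerate fits (the
#' Step-1 estimate falls outside the oscillatory regime) are judged not
#' describable by the model and classified as noise with F = 0.
#' Per-profile numerical failures are recorded, not fatal.
#'
#' @param x A [tc_dataset()], numeric matrix (genes in rows), or list of
#'   [tc_profile()] objects; all profiles must share the same length m.
#' @param gamma Significance level (default 0.1).
#' @param delta Sampling interval, used when `x` carries none.
#' @param adjust If `"BH"`, additionally report Benjamini-Hochberg
#'   adjusted p-values in a `p_adjusted` column (informational; the
#'   decision rule remains the F-threshold comparison). Default `"none"`.
#' @return A data.frame with one row per gene: `gene_id`, `f_value`,
#'   `p_value`, `threshold`, `significant`, `degenerate`, `s0_sq`,
#'   `s1_sq`, the six parameter estimates (NA when degenerate), and
#'   `error` (NA unless that profile's fit failed).
#' @export
#' @examples
#' set.seed(1)
#' sim <- generate_mixed_dataset(n_noise = 20, n_signal = 20, seed = 7)
#' res <- classify_profiles(sim$dataset, gamma = 0.1)
#' table(truth = sim$truth, called = res$significant)
classify_profiles <- function(x, gamma = 0.1, delta = 1, adjust = "none") {
  ds <- as_tc_dataset(x, delta)
  mat <- ds$matrix
  m <- ncol(mat)
  n <- nrow(mat)
  check_fit_length(m)
  thr <- f_threshold(gamma, m)
  par_na <- stats::setNames(rep(NA_real_, 6),
                            c("alpha", "omega", "a", "b", "c", "d"))
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    nullr <- null_residual(mat[i, ])
    fit <- tryCatch(suppressWarnings(fit_profile(mat[i, ], delta = ds$delta)),
                    error = function(e) conditionMessage(e))
    if (is.character(fit)) {
      rows[[i]] <- data.frame(gene_id = ds$gene_ids[i], f_value = 0,
                              p_value = 1, threshold = thr,
                              significant = FALSE, degenerate = FALSE,
                              s0_sq = nullr$s0_sq, s1_sq = NA_real_,
                              t(par_na), error = fit)
      next
    }
    if (fit$degenerate) {
      fv <- 0
      pars <- par_na
      s1 <- NA_real_
    } else {
      fv <- f_statistic(nullr$s0_sq, fit$s1_sq, m)
      pars <- unlist(fit$params)
      s1 <- fit$s1_sq
    }
    rows[[i]] <- data.frame(gene_id = ds$gene_ids[i], f_value = fv,
                            p_value = stats::pf(fv, 5, m - 6,
                                                lower.tail = FALSE),
                            threshold = thr,
                            significant = !fit$degenerate && fv > thr,
                            degenerate = fit$degenerate,
                            s0_sq = nullr$s0_sq, s1_sq = s1,
                            t(pars), error = NA_character_)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (identical(adjust, "BH")) {
    out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
  }
  out
}
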