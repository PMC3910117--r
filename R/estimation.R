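#' Central finite-difference derivatives of a profile
#'
#' Second-order central stencils on the interior points `i = 2..m-1`:
#' first derivative `(x[i+1] - x[i-1]) / (2*delta)`, second derivative
#' `(x[i+1] + x[i-1] - 2*x[i]) / delta^2`. Both are exact for quadratics
#' and have O(delta^2) truncation error on smooth signals.
#'
#' @param x A [tc_profile()] or numeric vector (length >= 3).
#' @param delta Sampling interval, used when `x` is a bare vector.
#' @return Numeric vector of length `m - 2`.
#' @export
finite_first_derivative <- function(x, delta = 1) {
  p <- as_profile_values(x, delta)
  m <- length(p$values)
  if (m < 3) stop("profile too short for finite differences (m < 3)",
                  call. = FALSE)
  (p$values[3:m] - p$values[1:(m - 2)]) / (2 * p$delta)
}

#' @rdname finite_first_derivative
#' @export
finite_second_derivative <- function(x, delta = 1) {
  p <- as_profile_values(x, delta)
  m <- length(p$values)
  if (m < 3) stop("profile too short for finite differences (m < 3)",
                  call. = FALSE)
  (p$values[3:m] + p$values[1:(m - 2)] - 2 * p$values[2:(m - 1)]) / p$delta^2
}

# Step-1 design matrix over the interior points t_2..t_{m-1}:
# columns [-xdot, -x, t, 1], response the second derivative. The
# least-squares solution of xddot + A xdot + B x = C t + D.
step1_design <- function(values, delta) {
  m <- length(values)
  t_int <- (2:(m - 1)) * delta
  xd <- (values[3:m] - values[1:(m - 2)]) / (2 * delta)
  xdd <- (values[3:m] + values[1:(m - 2)] - 2 * values[2:(m - 1)]) / delta^2
  list(X = cbind(-xd, -values[2:(m - 1)], t_int, 1), Y = xdd)
}

# Solve the (possibly pooled) normal equations XtX theta = XtY via a
# stabilized solve; errors on rank deficiency. A zero right-hand side
# (e.g. an exactly linear profile, whose second differences vanish) has
# the zero vector as a least-squares solution even when XtX is singular.
solve_normal <- function(XtX, XtY, what = "design matrix") {
  if (all(XtY == 0)) return(numeric(length(XtY)))
  ok <- TRUE
  theta <- tryCatch(solve(XtX, XtY, tol = 1e-12),
                    error = function(e) { ok <<- FALSE; NULL })
  if (!ok) {
    stop("rank-deficient ", what, ": normal equations singular to tolerance",
         call. = FALSE)
  }
  as.numeric(theta)
}

#' Step 1: estimate the ODE coefficients of a profile
#'
#' Regresses the centrally differenced second derivative on
#' `[-xdot, -x, t, 1]` over the `l = m - 2` interior points, giving the
#' least-squares estimates of the ODE coefficients (A, B, C, D). The
#' damping, frequency and trend parameters follow via [ode_to_model()].
#'
#' @inheritParams finite_first_derivative
#' @return An [ode_params()] object.
#' @export
estimate_ode_params <- function(x, delta = 1) {
  p <- as_profile_values(x, delta)
  m <- length(p$values)
  check_fit_length(m)
  d <- step1_design(p$values, p$delta)
  theta <- solve_normal(crossprod(d$X), crossprod(d$X, d$Y),
                        what = "step-1 design matrix")
  ode_params(A = theta[1], B = theta[2], C = theta[3], D = theta[4])
}

check_fit_length <- function(m) {
  if (m < 8) {
    stop("profile too short to fit (m = ", m,
         "; need m >= 8 so the F-test denominator has >= 2 d.f.)",
         call. = FALSE)
  }
  if (m < 12) {
    warning("m = ", m, " < 12: finite-difference error may be large",
            call. = FALSE)
  }
  invisible(m)
}

#' Step 2: estimate the sinusoid coefficients given the other parameters
#'
#' Detrends and de-damps the profile, `z(t_i) = exp(-alpha*t_i) *
#' (x(t_i) - c*t_i - d)`, then linearly regresses z on
#' `cos(omega*t_i)` and `sin(omega*t_i)` over all m points.
#'
#' @inheritParams finite_first_derivative
#' @param alpha,omega,c,d Parameters from Step 1 (`omega > 0`).
#' @return Named numeric vector `c(a = , b = )`.
#' @export
estimate_sinusoid_coeffs <- function(x, alpha, omega, c, d, delta = 1) {
  stopifnot(omega > 0)
  p <- as_profile_values(x, delta)
  t <- seq_along(p$values) * p$delta
  z <- exp(-alpha * t) * (p$values - c * t - d)
  E <- rbind(cos(omega * t), sin(omega * t))
  ab <- solve_normal(tcrossprod(E), E %*% z,
                     what = "sinusoid basis (EE^T)")
  c(a = ab[1], b = ab[2])
}

#' Fit the damped-sinusoid model to one profile
#'
#' The two-step linear least-squares estimator: Step 1 recovers
#' (alpha, omega, c, d) through the ODE-coefficient regression on
#' numerically differenced data; Step 2 recovers (a, b) by linear
#' regression of the detrended, de-damped signal on the cos/sin basis.
#' No iterative nonlinear optimisation is involved, so the fit has no
#' starting-value sensitivity and cannot stall in a local minimum.
#'
#' When Step 1 lands outside the oscillatory regime (`4B - A^2 <= 0` or
#' `B = 0`) the profile is judged not describable by the model: the
#' result carries `degenerate = TRUE`, no parameters, and the null-model
#' residual as `s1_sq` is not computed (it is `NA`).
#'
#' @inheritParams finite_first_derivative
#' @param gene_id Optional identifier stored in the result.
#' @return An object of class `tc_fit`: list with `gene_id`, `params`
#'   ([model_params()] or `NULL`), `degenerate`, `reason`, `s1_sq`
#'   (residual sum of squares of the fitted model over all m points) and
#'   `fitted` (length-m vector, `NULL` when degenerate).
#' @export
#' @examples
#' truth <- model_params(-0.05, 1.2, 1, 0.4, 0.02, 1)
#' x <- evaluate_model(truth, m = 100, delta = 0.1)
#' fit <- fit_profile(x, delta = 0.1)
#' unlist(fit$params)
fit_profile <- function(x, delta = 1, gene_id = NA_character_) {
  p <- as_profile_values(x, delta)
  if (inherits(x, "tc_profile") && is.na(gene_id)) gene_id <- x$gene_id
  ode <- estimate_ode_params(p$values, p$delta)
  conv <- ode_to_model(ode)
  if (conv$degenerate) {
    return(structure(list(gene_id = gene_id, params = NULL,
                          degenerate = TRUE, reason = conv$reason,
                          s1_sq = NA_real_, fitted = NULL),
                     class = "tc_fit"))
  }
  ab <- estimate_sinusoid_coeffs(p$values, alpha = conv$alpha,
                                 omega = conv$omega, c = conv$c, d = conv$d,
                                 delta = p$delta)
  params <- model_params(alpha = conv$alpha, omega = conv$omega,
                         a = ab[["a"]], b = ab[["b"]],
                         c = conv$c, d = conv$d)
  fitted <- evaluate_model(params, m = length(p$values), delta = p$delta)
  structure(list(gene_id = gene_id, params = params,
                 degenerate = FALSE, reason = NA_character_,
                 s1_sq = sum((p$values - fitted)^2), fitted = fitted),
            class = "tc_fit")
}

#' @export
print.tc_fit <- function(x, ...) {
  if (x$degenerate) {
    cat(sprintf("<tc_fit> %s: degenerate (%s)\n", x$gene_id, x$reason))
  } else {
    cat(sprintf("<tc_fit> %s: S1^2 = %.4g\n", x$gene_id, x$s1_sq))
    print(unlist(x$params))
  }
  invisible(x)
}
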