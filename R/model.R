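#' Construct a damped-sinusoid model parameter set
#'
#' The model for a time-course expression profile is
#' \deqn{x(t) = e^{\alpha t}[a\cos(\omega t) + b\sin(\omega t)] + ct + d,}
#' a periodic component with an exponentially changing envelope plus a
#' linear trend. `alpha` is the degradation (or growth) rate of the
#' periodicity, `omega` the angular frequency in radians per unit time,
#' `a` and `b` the cosine/sine coefficients, and `c`, `d` the slope and
#' intercept of the trend.
#'
#' @param alpha Damping exponent per unit time (negative = decaying).
#' @param omega Angular frequency per unit time; must be positive.
#' @param a,b Cosine and sine coefficients (expression units).
#' @param c Linear-trend slope (expression units per unit time).
#' @param d Intercept (expression units).
#' @return An object of class `model_params` (a named list of the six
#'   coefficients).
#' @seealso [evaluate_model()], [fit_profile()]
#' @export
#' @examples
#' p <- model_params(alpha = -0.1, omega = 1, a = 1, b = 0.5, c = 0.05, d = 2)
#' evaluate_model(p, m = 6, delta = 1)
model_params <- function(alpha, omega, a, b, c, d) {
  vals <- c(alpha = alpha, omega = omega, a = a, b = b, c = c, d = d)
  if (!all(is.finite(vals))) {
    stop("all model parameters must be finite", call. = FALSE)
  }
  if (omega <= 0) {
    stop("omega must be positive (the positive root is the convention)",
         call. = FALSE)
  }
  structure(as.list(vals), class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat("Damped-sinusoid model parameters:\n")
  print(unlist(x), ...)
  cat(sprintf("magnitude sqrt(a^2+b^2) = %.4g, phase arctan(a/b) = %.4g rad\n",
              model_magnitude(x), model_phase(x)))
  invisible(x)
}

#' Magnitude and phase of the periodic component
#'
#' For the pure sinusoid reduction (`alpha = c = d = 0`) the model equals
#' `A*sin(omega*t + Phi)` with magnitude `A = sqrt(a^2 + b^2)` and phase
#' `Phi = arctan(a/b)`.
#'
#' @param params A [model_params()] object.
#' @return A single numeric value.
#' @export
model_magnitude <- function(params) sqrt(params$a^2 + params$b^2)

#' @rdname model_magnitude
#' @export
model_phase <- function(params) atan2(params$a, params$b)

#' Construct ODE coefficients
#'
#' The noise-free model is the general solution of the second-order linear
#' ordinary differential equation
#' \deqn{\ddot x(t) + A\dot x(t) + Bx(t) = Ct + D,}
#' whose constant coefficients are linear in the data once the derivatives
#' are known -- the key to the two-step estimator.
#'
#' @param A,B,C,D Finite ODE coefficients.
#' @return An object of class `ode_params`.
#' @seealso [ode_to_model()], [model_to_ode()]
#' @export
ode_params <- function(A, B, C, D) {
  vals <- c(A = A, B = B, C = C, D = D)
  if (!all(is.finite(vals))) {
    stop("all ODE coefficients must be finite", call. = FALSE)
  }
  structure(as.list(vals), class = "ode_params")
}

#' Evaluate the noise-free model on a regular time grid
#'
#' Sample `i` (1-based) sits at time `t_i = i * delta`.
#'
#' @param params A [model_params()] object.
#' @param m Number of time points (>= 1).
#' @param delta Sampling interval (> 0); defaults to 1.
#' @return Numeric vector of length `m`.
#' @export
evaluate_model <- function(params, m, delta = 1) {
  stopifnot(m >= 1, delta > 0)
  t <- seq_len(m) * delta
  exp(params$alpha * t) *
    (params$a * cos(params$omega * t) + params$b * sin(params$omega * t)) +
    params$c * t + params$d
}

#' Convert ODE coefficients to model parameters
#'
#' Inverts the characteristic-root relationship: `alpha = -A/2`,
#' `omega = sqrt(4B - A^2)/2` (positive root), `c = C/B`,
#' `d = D/B - AC/B^2`. The conversion only exists in the oscillatory
#' (complex-root) regime `4B - A^2 > 0` with `B != 0`; outside it the
#' profile is judged not describable by the damped-sinusoid model and a
#' degenerate outcome is returned rather than an error, so that batch
#' screening and clustering can handle such genes explicitly.
#'
#' @param ode An [ode_params()] object.
#' @return A list with elements `degenerate` (logical), `reason`
#'   (`NA_character_` when non-degenerate), and when non-degenerate the
#'   partial parameters `alpha`, `omega`, `c`, `d`.
#' @export
ode_to_model <- function(ode) {
  disc <- 4 * ode$B - ode$A^2
  if (ode$B == 0) {
    return(list(degenerate = TRUE, reason = "B = 0"))
  }
  if (disc <= 0) {
    return(list(degenerate = TRUE, reason = "4B - A^2 <= 0"))
  }
  list(
    degenerate = FALSE,
    reason = NA_character_,
    alpha = -ode$A / 2,
    omega = sqrt(disc) / 2,
    c = ode$C / ode$B,
    d = ode$D / ode$B - ode$A * ode$C / ode$B^2
  )
}

#' Convert model parameters to ODE coefficients
#'
#' Algebraic inverse of [ode_to_model()]: `A = -2*alpha`,
#' `B = alpha^2 + omega^2`, `C = c*B`, `D = d*B - 2*alpha*c`. Useful for
#' round-trip checks and for generating profiles with known ODE
#' coefficients.
#'
#' @param alpha,omega,c,d Model parameters; `omega > 0`.
#' @return An [ode_params()] object.
#' @export
model_to_ode <- function(alpha, omega, c, d) {
  stopifnot(omega > 0)
  B <- alpha^2 + omega^2
  ode_params(A = -2 * alpha, B = B, C = c * B, D = d * B - 2 * alpha * c)
}
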