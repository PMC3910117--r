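#' Default simulation settings
#'
#' The ranges emulate an 18-point, unit-interval time course (the length
#' of the classic alpha-factor yeast cell-cycle matrix): slow amplitude
#' decay (`alpha` in [-0.15, 0]), one-to-several oscillation periods over
#' the course (`omega` in [0.3, 1.5] rad per unit time), periodic
#' magnitude `sqrt(a^2+b^2)` in [1, 2] with uniform phase, a mild linear
#' trend (|c| <= 0.1, |d| <= 1), and Gaussian observation noise with
#' sd 0.5. All entries can be overridden by passing a modified copy.
#'
#' @param m Number of time points.
#' @param delta Sampling interval.
#' @param noise_sd Observation noise standard deviation.
#' @param alpha_range,omega_range,amplitude_range,c_range,d_range
#'   Uniform sampling intervals for the model parameters.
#' @return A named list (class `generator_spec`).
#' @export
generator_spec <- function(m = 18, delta = 1, noise_sd = 0.5,
                           alpha_range = c(-0.15, 0),
                           omega_range = c(0.3, 1.5),
                           amplitude_range = c(1, 2),
                           c_range = c(-0.1, 0.1),
                           d_range = c(-1, 1)) {
  stopifnot(m >= 1, delta > 0, noise_sd >= 0, omega_range[1] > 0)
  structure(list(m = m, delta = delta, noise_sd = noise_sd,
                 alpha_range = alpha_range, omega_range = omega_range,
                 amplitude_range = amplitude_range,
                 c_range = c_range, d_range = d_range),
            class = "generator_spec")
}

runif_range <- function(n, range) stats::runif(n, range[1], range[2])

draw_model_params <- function(spec) {
  amp <- runif_range(1, spec$amplitude_range)
  phi <- stats::runif(1, 0, 2 * pi)
  model_params(alpha = runif_range(1, spec$alpha_range),
               omega = runif_range(1, spec$omega_range),
               a = amp * cos(phi), b = amp * sin(phi),
               c = runif_range(1, spec$c_range),
               d = runif_range(1, spec$d_range))
}

#' Generate pure-noise profiles under the constant null
#'
#' `x(t_i) = d + eps(t_i)` with i.i.d. Gaussian noise.
#'
#' @param n Number of profiles.
#' @param m Time points per profile.
#' @param d Constant level (default 0).
#' @param noise_sd Noise standard deviation.
#' @param delta Sampling interval.
#' @param seed Optional RNG seed.
#' @return List with `dataset` (a [tc_dataset()]) and `truth` (logical,
#'   all `FALSE`: none are model-following).
#' @export
generate_noise_profiles <- function(n, m = 18, d = 0, noise_sd = 0.5,
                                    delta = 1, seed = NULL) {
  stopifnot(n >= 1, m >= 1, noise_sd >= 0)
  if (!is.null(seed)) set.seed(seed)
  mat <- matrix(d + stats::rnorm(n * m, sd = noise_sd), nrow = n)
  list(dataset = tc_dataset(mat,
                            gene_ids = sprintf("noise_%04d", seq_len(n)),
                            delta = delta),
       truth = rep(FALSE, n))
}

#' Generate model-following profiles with random parameters
#'
#' Each profile draws its own parameter set uniformly from the spec's
#' ranges (amplitude and phase drawn jointly so that the periodic
#' magnitude is uniform on `amplitude_range`), evaluates the noise-free
#' model and adds Gaussian observation noise.
#'
#' @param n Number of profiles.
#' @param spec A [generator_spec()].
#' @param seed Optional RNG seed.
#' @return List with `dataset`, `truth` (all `TRUE`) and `params` (list
#'   of the generating [model_params()], for recovery checks).
#' @export
generate_model_profiles <- function(n, spec = generator_spec(),
                                    seed = NULL) {
  stopifnot(n >= 0)
  if (!is.null(seed)) set.seed(seed)
  if (n == 0) {
    return(list(dataset = NULL, truth = logical(0), params = list()))
  }
  params <- replicate(n, draw_model_params(spec), simplify = FALSE)
  mat <- t(vapply(params, evaluate_model, numeric(spec$m),
                  m = spec$m, delta = spec$delta))
  mat <- mat + stats::rnorm(n * spec$m, sd = spec$noise_sd)
  list(dataset = tc_dataset(mat,
                            gene_ids = sprintf("model_%04d", seq_len(n)),
                            delta = spec$delta),
       truth = rep(TRUE, n), params = params)
}

#' Generate the mixed null/model benchmark dataset
#'
#' The significance-screen benchmark: `n_noise` constant-plus-noise
#' profiles and `n_signal` model-following profiles with per-profile
#' random parameters, concatenated. The default sizes (2000 + 2000)
#' match the screen's evaluation protocol.
#'
#' @param n_noise,n_signal Profile counts.
#' @param spec A [generator_spec()]; the null profiles use its `m`,
#'   `delta` and `noise_sd` with level `d = 0`.
#' @param seed Optional RNG seed.
#' @return List with `dataset`, `truth` (TRUE = model-following) and
#'   `params` (generating parameters of the signal profiles).
#' @export
generate_mixed_dataset <- function(n_noise = 2000, n_signal = 2000,
                                   spec = generator_spec(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  noise <- generate_noise_profiles(n_noise, m = spec$m, d = 0,
                                   noise_sd = spec$noise_sd,
                                   delta = spec$delta)
  signal <- generate_model_profiles(n_signal, spec = spec)
  mat <- rbind(noise$dataset$matrix, signal$dataset$matrix)
  list(dataset = tc_dataset(mat, delta = spec$delta),
       truth = c(noise$truth, signal$truth),
       params = signal$params)
}

# Rejection-sample K cluster centres with a minimum pairwise separation
# in (alpha, omega, a, b) space, each coordinate normalised by its
# sampling-range width so the four axes contribute comparably.
draw_separated_centers <- function(K, spec, min_separation = 0.5,
                                   max_tries = 10000) {
  widths <- c(diff(spec$alpha_range), diff(spec$omega_range),
              2 * spec$amplitude_range[2], 2 * spec$amplitude_range[2])
  norm_coords <- function(p) {
    c(p$alpha, p$omega, p$a, p$b) / widths
  }
  centers <- list(draw_model_params(spec))
  tries <- 0
  while (length(centers) < K) {
    cand <- draw_model_params(spec)
    dists <- vapply(centers, function(p) {
      sqrt(sum((norm_coords(p) - norm_coords(cand))^2))
    }, numeric(1))
    if (min(dists) >= min_separation) {
      centers[[length(centers) + 1]] <- cand
    }
    tries <- tries + 1
    if (tries > max_tries) {
      stop("could not place ", K, " cluster centres at separation ",
           min_separation, "; loosen the separation or widen the ranges",
           call. = FALSE)
    }
  }
  centers
}

#' Generate a clustered benchmark dataset
#'
#' Draws K well-separated cluster-centre parameter vectors (rejection
#' sampling with a minimum pairwise distance in normalised
#' (alpha, omega, a, b) space), then generates each member profile from
#' its centre's parameters perturbed by relative Gaussian jitter, plus
#' Gaussian observation noise. The default noise sd for this benchmark
#' is 0.3 (lower than the screen benchmark: cluster structure, not
#' detectability, is the object of study here).
#'
#' @param K Number of clusters.
#' @param sizes Integer vector of length K (cluster sizes).
#' @param spec A [generator_spec()]; its `noise_sd` is overridden by
#'   `noise_sd` below.
#' @param perturbation_sd Relative within-cluster parameter jitter
#'   (default 0.05, i.e. 5%).
#' @param noise_sd Observation noise sd (default 0.3).
#' @param min_separation Minimum normalised centre separation.
#' @param seed Optional RNG seed.
#' @return List with `dataset`, `truth` (integer labels 1..K) and
#'   `centers` (list of K generating [model_params()]).
#' @export
generate_cluster_dataset <- function(K = 6, sizes = rep(60, K),
                                     spec = generator_spec(),
                                     perturbation_sd = 0.05,
                                     noise_sd = 0.3,
                                     min_separation = 0.5,
                                     seed = NULL) {
  stopifnot(K >= 1, length(sizes) == K, all(sizes >= 1))
  if (!is.null(seed)) set.seed(seed)
  centers <- draw_separated_centers(K, spec, min_separation)
  rows <- vector("list", sum(sizes))
  truth <- integer(0)
  idx <- 0
  for (k in seq_len(K)) {
    base <- unlist(centers[[k]])
    for (j in seq_len(sizes[k])) {
      idx <- idx + 1
      repeat { # jittered omega must stay positive
        p <- base * (1 + stats::rnorm(6, sd = perturbation_sd))
        if (p[["omega"]] > 0) break
      }
      member <- model_params(p[["alpha"]], p[["omega"]], p[["a"]],
                             p[["b"]], p[["c"]], p[["d"]])
      rows[[idx]] <- evaluate_model(member, m = spec$m, delta = spec$delta) +
        stats::rnorm(spec$m, sd = noise_sd)
    }
    truth <- c(truth, rep(k, sizes[k]))
  }
  mat <- do.call(rbind, rows)
  list(dataset = tc_dataset(mat,
                            gene_ids = sprintf("g%03d_c%d", seq_len(nrow(mat)),
                                               truth),
                            delta = spec$delta),
       truth = truth, centers = centers)
}
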