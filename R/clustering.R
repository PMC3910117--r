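#' Pooled two-step fit of one cluster of profiles
#'
#' Estimates a single damped-sinusoid parameter set for a cluster by
#' summing the per-profile normal-equation terms: Step 1 solves
#' `(sum X'X)^-1 sum X'Y` over all members' interior points, Step 2
#' solves `(sum EE')^-1 sum EZ'` with the cluster's (alpha, omega, c, d).
#' With a single member this reduces exactly to [fit_profile()].
#'
#' @param x A [tc_dataset()], numeric matrix (members in rows), or single
#'   profile.
#' @param delta Sampling interval, used when `x` carries none.
#' @return A list with `degenerate`, `reason`, and when non-degenerate
#'   `params` (a [model_params()]).
#' @export
estimate_cluster_params <- function(x, delta = 1) {
  ds <- as_tc_dataset(x, delta)
  mat <- ds$matrix
  m <- ncol(mat)
  check_fit_length(m)
  XtX <- matrix(0, 4, 4)
  XtY <- numeric(4)
  for (i in seq_len(nrow(mat))) {
    dsn <- step1_design(mat[i, ], ds$delta)
    XtX <- XtX + crossprod(dsn$X)
    XtY <- XtY + crossprod(dsn$X, dsn$Y)
  }
  theta <- solve_normal(XtX, XtY, what = "pooled step-1 design matrix")
  conv <- ode_to_model(ode_params(theta[1], theta[2], theta[3], theta[4]))
  if (conv$degenerate) {
    return(list(degenerate = TRUE, reason = conv$reason))
  }
  t <- seq_len(m) * ds$delta
  E <- rbind(cos(conv$omega * t), sin(conv$omega * t))
  # z summed over members: E depends only on the shared omega, so the
  # pooled system is (n * EE') ab = E %*% colSums(Z)
  zsum <- colSums(exp(-conv$alpha * rep(t, each = nrow(mat))) *
                    sweep(mat, 2, conv$c * t + conv$d))
  ab <- solve_normal(nrow(mat) * tcrossprod(E), E %*% zsum,
                     what = "pooled sinusoid basis")
  list(degenerate = FALSE, reason = NA_character_,
       params = model_params(alpha = conv$alpha, omega = conv$omega,
                             a = ab[1], b = ab[2],
                             c = conv$c, d = conv$d))
}

# N x K matrix of squared residuals of every profile against every
# cluster curve; degenerate clusters (params NULL) get Inf.
residual_matrix <- function(mat, cluster_params, delta) {
  m <- ncol(mat)
  K <- length(cluster_params)
  R <- matrix(Inf, nrow(mat), K)
  for (k in seq_len(K)) {
    p <- cluster_params[[k]]
    if (is.null(p)) next
    curve <- evaluate_model(p, m = m, delta = delta)
    R[, k] <- rowSums(sweep(mat, 2, curve)^2)
  }
  R
}

#' Pooled squared-residual cost of a partition
#'
#' The clustering objective: the sum over clusters, member profiles and
#' time points of the squared deviation from that cluster's model curve
#' at `t_i = i * delta`.
#'
#' @inheritParams estimate_cluster_params
#' @param labels Integer vector of cluster indices, one per profile.
#' @param cluster_params List of [model_params()] (or `NULL` for a
#'   degenerate cluster); every cluster holding a profile must have
#'   parameters.
#' @return Nonnegative cost.
#' @export
cluster_cost <- function(x, labels, cluster_params, delta = 1) {
  ds <- as_tc_dataset(x, delta)
  K <- length(cluster_params)
  labels <- as.integer(labels)
  stopifnot(length(labels) == nrow(ds$matrix))
  if (any(labels < 1 | labels > K)) {
    stop("unknown cluster label (outside 1..", K, ")", call. = FALSE)
  }
  used <- sort(unique(labels))
  if (any(vapply(cluster_params[used], is.null, logical(1)))) {
    stop("a populated cluster has no parameters", call. = FALSE)
  }
  R <- residual_matrix(ds$matrix, cluster_params, ds$delta)
  sum(R[cbind(seq_along(labels), labels)])
}

#' Assign each profile to its best-fitting cluster model
#'
#' Each profile receives the label of the cluster whose curve minimises
#' its squared residual. Exact ties break to the lowest cluster index;
#' degenerate clusters are skipped.
#'
#' @inheritParams cluster_cost
#' @return Integer label vector.
#' @export
assign_profiles <- function(x, cluster_params, delta = 1) {
  ds <- as_tc_dataset(x, delta)
  if (all(vapply(cluster_params, is.null, logical(1)))) {
    stop("all cluster models are degenerate; cannot assign", call. = FALSE)
  }
  R <- residual_matrix(ds$matrix, cluster_params, ds$delta)
  max.col(-R, ties.method = "first")
}

# Move one profile into each empty cluster so K stays fixed. `scores`
# ranks donor candidates (higher = reseed first): the profile worst
# served by its current cluster. Donor clusters must retain >= 1 member.
reseed_empty <- function(labels, K, scores) {
  for (k in seq_len(K)) {
    if (any(labels == k)) next
    tab <- tabulate(labels, K)
    candidates <- which(tab[labels] > 1)
    if (length(candidates) == 0) break
    i <- candidates[which.max(scores[candidates])]
    labels[i] <- k
    scores[i] <- -Inf
  }
  labels
}

#' Relocation-iteration clustering of time-course profiles
#'
#' Alternates (a) pooled per-cluster parameter estimation
#' ([estimate_cluster_params()]) and (b) reassignment of every profile to
#' its best-fitting cluster model ([assign_profiles()]) until the cost
#' improvement falls below `tol` (relative), memberships stop changing,
#' or `max_iter` is reached. Because the two-step estimator is not the
#' exact least-squares minimiser, a re-estimation step can in principle
#' raise the cost; the iteration therefore keeps the best state seen and
#' stops if a step fails to improve it, which makes the recorded cost
#' trace non-increasing by construction.
#'
#' Empty clusters are reseeded with the profile worst served by its
#' current cluster, keeping K fixed. A cluster whose pooled estimate
#' turns degenerate mid-run retains its previous parameters (with a
#' warning); if degenerate at the first iteration it is reseeded the
#' same way.
#'
#' @inheritParams estimate_cluster_params
#' @param K Number of clusters (>= 1).
#' @param init Integer vector of initial labels in 1..K.
#' @param tol Relative cost-improvement tolerance (default 1e-8).
#' @param max_iter Iteration cap (default 100).
#' @return An object of class `tc_clusters`: `K`, `labels`,
#'   `cluster_params` (list of [model_params()] or `NULL`), `sizes`,
#'   `cost`, `cost_trace`, `n_iter`, `converged`.
#' @export
relocate_iterate <- function(x, K, init, delta = 1, tol = 1e-8,
                             max_iter = 100) {
  ds <- as_tc_dataset(x, delta)
  mat <- ds$matrix
  N <- nrow(mat)
  stopifnot(K >= 1, N >= K, length(init) == N)
  labels <- as.integer(init)
  if (any(labels < 1 | labels > K)) {
    stop("initial labels must lie in 1..K", call. = FALSE)
  }
  # before any model exists, rank reseed donors by profile variability
  s0 <- apply(mat, 1, function(v) sum((v - mean(v))^2))
  labels <- reseed_empty(labels, K, s0)

  params <- vector("list", K)
  trace <- numeric(0)
  best_cost <- Inf
  converged <- FALSE
  s <- 0
  while (s < max_iter) {
    s <- s + 1
    # (a) pooled estimation per cluster
    for (k in seq_len(K)) {
      members <- which(labels == k)
      if (length(members) == 0) next
      est <- tryCatch(
        suppressWarnings(estimate_cluster_params(mat[members, , drop = FALSE],
                                                 ds$delta)),
        error = function(e) list(degenerate = TRUE,
                                 reason = conditionMessage(e)))
      if (!est$degenerate) {
        params[[k]] <- est$params
      } else if (is.null(params[[k]])) {
        # first-iteration degeneracy: refit from the single most
        # variable member so the cluster has a usable model
        i <- members[which.max(s0[members])]
        est1 <- tryCatch(
          suppressWarnings(estimate_cluster_params(mat[i, , drop = FALSE],
                                                   ds$delta)),
          error = function(e) list(degenerate = TRUE))
        if (!est1$degenerate) params[[k]] <- est1$params
      } else {
        warning("cluster ", k, " estimate degenerate at iteration ", s,
                "; retaining previous parameters", call. = FALSE)
      }
    }
    if (all(vapply(params, is.null, logical(1)))) {
      stop("all cluster models are degenerate; cannot continue",
           call. = FALSE)
    }
    # (b) reassignment
    R <- residual_matrix(mat, params, ds$delta)
    new_labels <- max.col(-R, ties.method = "first")
    cost <- sum(R[cbind(seq_len(N), new_labels)])
    if (cost > best_cost) { # failed to improve: keep best state, stop
      converged <- TRUE
      break
    }
    trace <- c(trace, cost)
    improvement <- best_cost - cost
    best_cost <- cost
    best_labels <- reseed_empty(new_labels, K,
                                R[cbind(seq_len(N), new_labels)])
    best_params <- params
    if (identical(as.integer(best_labels), labels) ||
        (is.finite(improvement) && improvement <= tol * max(cost, 1e-300))) {
      labels <- best_labels
      converged <- TRUE
      break
    }
    labels <- best_labels
  }
  structure(list(K = K, labels = labels, cluster_params = best_params,
                 sizes = tabulate(labels, K), cost = best_cost,
                 cost_trace = trace, n_iter = s, converged = converged),
            class = "tc_clusters")
}

#' @export
print.tc_clusters <- function(x, ...) {
  cat(sprintf("<tc_clusters> K = %d, cost = %.6g, %d iteration(s)%s\n",
              x$K, x$cost, x$n_iter,
              if (x$converged) ", converged" else " (not converged)"))
  cat("sizes:", x$sizes, "\n")
  invisible(x)
}

#' Cluster with multiple restarts
#'
#' Runs [relocate_iterate()] from `n_restarts` initial partitions --
#' uniformly random labels, or one Euclidean k-means partition of the raw
#' profile vectors per restart -- and returns the minimum-cost model.
#' Every run's labels are retained so clustering stability can be scored
#' with [aari()].
#'
#' @inheritParams relocate_iterate
#' @param n_restarts Number of independent starts (default 30).
#' @param init_mode `"random"` (uniform labels) or `"kmeans"` (k-means on
#'   the raw m-dimensional vectors, a fresh k-means seed per restart).
#' @param seed Optional master seed; restart r draws its own derived
#'   stream so results are reproducible per (seed, r).
#' @return The best `tc_clusters`, with two extra fields: `restart_labels`
#'   (list of label vectors, one per restart) and `restart_costs`.
#' @export
#' @examples
#' sim <- generate_cluster_dataset(K = 3, sizes = rep(20, 3), seed = 11)
#' cl <- cluster_with_restarts(sim$dataset, K = 3, n_restarts = 5, seed = 1)
#' adjusted_rand_index(cl$labels, sim$truth)
cluster_with_restarts <- function(x, K, n_restarts = 30,
                                  init_mode = c("random", "kmeans"),
                                  delta = 1, seed = NULL, tol = 1e-8,
                                  max_iter = 100) {
  init_mode <- match.arg(init_mode)
  ds <- as_tc_dataset(x, delta)
  N <- nrow(ds$matrix)
  stopifnot(n_restarts >= 1)
  if (!is.null(seed)) set.seed(seed)
  restart_seeds <- sample.int(.Machine$integer.max - 1L, n_restarts)
  runs <- vector("list", n_restarts)
  all_labels <- vector("list", n_restarts)
  costs <- numeric(n_restarts)
  for (r in seq_len(n_restarts)) {
    set.seed(restart_seeds[r])
    init <- switch(init_mode,
      random = sample.int(K, N, replace = TRUE),
      kmeans = stats::kmeans(ds$matrix, centers = K, nstart = 1,
                             iter.max = 50)$cluster)
    runs[[r]] <- suppressWarnings(
      relocate_iterate(ds, K = K, init = init, tol = tol,
                       max_iter = max_iter))
    all_labels[[r]] <- runs[[r]]$labels
    costs[r] <- runs[[r]]$cost
  }
  best <- runs[[which.min(costs)]]
  best$restart_labels <- all_labels
  best$restart_costs <- costs
  best
}

#' Per-cluster parameter table
#'
#' Summarises a clustering as one row per cluster: the six model
#' coefficients and the cluster size.
#'
#' @param clusters A `tc_clusters` object from [relocate_iterate()] or
#'   [cluster_with_restarts()].
#' @return data.frame with columns `cluster`, `size`, `alpha`, `omega`,
#'   `a`, `b`, `c`, `d` (NA for degenerate clusters).
#' @export
cluster_param_table <- function(clusters) {
  stopifnot(inherits(clusters, "tc_clusters"))
  rows <- lapply(seq_len(clusters$K), function(k) {
    p <- clusters$cluster_params[[k]]
    if (is.null(p)) p <- rep(NA_real_, 6)
    data.frame(cluster = k, size = clusters$sizes[k],
               alpha = p[[1]], omega = p[[2]], a = p[[3]], b = p[[4]],
               c = p[[5]], d = p[[6]])
  })
  do.call(rbind, rows)
}
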