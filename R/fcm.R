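#' Initialize a fuzzy partition matrix
#'
#' Draws a random row-stochastic `n x k` membership matrix (uniform draws
#' normalized per row), seeded and reproducible.
#'
#' @param n Number of data points (>= k).
#' @param k Number of clusters (>= 1).
#' @param seed Integer seed.
#' @return An `n x k` matrix whose rows sum to 1.
#' @export
fcm_init_partition <- function(n, k, seed = 1) {
  if (k < 1) stop("k must be at least 1", call. = FALSE)
  if (k > n) stop("cannot form ", k, " clusters from ", n, " points", call. = FALSE)
  withr::with_seed(seed, {
    u <- matrix(stats::runif(n * k), n, k)
    u / rowSums(u)
  })
}

sq_dist <- function(X, C) {
  # N x K matrix of squared Euclidean distances
  D <- matrix(0, nrow(X), nrow(C))
  for (j in seq_len(nrow(C))) {
    D[, j] <- rowSums((X - matrix(C[j, ], nrow(X), ncol(X), byrow = TRUE))^2)
  }
  D
}

#' Fuzzy c-means centroid update
#'
#' Each centroid is the membership^m-weighted mean of all points,
#' `c_k = sum_i u_ik^m x_i / sum_i u_ik^m`. A cluster whose total weight is
#' zero is reinitialized to a random data point (drawn from the current RNG
#' state).
#'
#' @param X `N x d` data matrix.
#' @param U `N x K` row-stochastic membership matrix.
#' @param m Fuzzifier (> 1).
#' @return A `K x d` centroid matrix.
#' @export
fcm_update_centroids <- function(X, U, m = 2) {
  if (m <= 1) stop("fuzzifier m must exceed 1", call. = FALSE)
  X <- as.matrix(X)
  W <- U^m
  tot <- colSums(W)
  C <- matrix(0, ncol(U), ncol(X))
  for (j in seq_len(ncol(U))) {
    if (tot[j] <= 0) {
      C[j, ] <- X[sample.int(nrow(X), 1L), ]
    } else {
      C[j, ] <- colSums(W[, j] * X) / tot[j]
    }
  }
  C
}

#' Fuzzy c-means membership update
#'
#' Standard update `u_ik = 1 / sum_j (d_ik / d_ij)^(2/(m-1))` with Euclidean
#' distances. A point coinciding with a centroid gets membership 1 there
#' (split equally if it coincides with several).
#'
#' @param X `N x d` data matrix.
#' @param C `K x d` centroid matrix.
#' @param m Fuzzifier (> 1).
#' @return An `N x K` row-stochastic membership matrix.
#' @export
fcm_update_membership <- function(X, C, m = 2) {
  if (m <= 1) stop("fuzzifier m must exceed 1", call. = FALSE)
  X <- as.matrix(X); C <- as.matrix(C)
  D2 <- sq_dist(X, C)
  P <- D2^(-1 / (m - 1))
  U <- P / rowSums(P)
  zero <- D2 <= 0
  hit <- rowSums(zero) > 0
  if (any(hit)) {
    U[hit, ] <- zero[hit, , drop = FALSE] / rowSums(zero[hit, , drop = FALSE])
  }
  U
}

#' Fuzzy c-means objective
#'
#' `J = sum_i sum_k u_ik^m ||x_i - c_k||^2`, the weighted within-cluster
#' scatter the algorithm descends.
#'
#' @inheritParams fcm_update_centroids
#' @param C `K x d` centroid matrix.
#' @return A non-negative scalar.
#' @export
fcm_objective <- function(X, U, C, m = 2) {
  sum(U^m * sq_dist(as.matrix(X), as.matrix(C)))
}

#' Fuzzy c-means clustering
#'
#' Alternates centroid and membership updates from a seeded random
#' partition until the change in the objective J between iterations drops
#' below `epsilon`, or `max_iter` is reached (in which case the result is
#' returned with a warning and `converged = FALSE`). The objective trace is
#' non-increasing.
#'
#' @param X `N x d` data matrix (rows are points).
#' @param k Number of clusters (1 <= k <= N).
#' @param m Fuzzifier (> 1, default 2).
#' @param epsilon Stopping threshold on |J_t - J_(t-1)| (> 0).
#' @param max_iter Iteration cap (>= 1).
#' @param seed Integer seed for the initial partition (and any degenerate
#'   centroid reseeding).
#' @return An object of class `fcm_fit`: `memberships` (N x K,
#'   row-stochastic, consistent with the final centroids), `centroids`
#'   (K x d), `objective_trace`, `iterations`, `converged`, plus the call
#'   parameters.
#' @export
#' @examples
#' fit <- fcm(matrix(c(0, 0.1, 10, 10.1)), k = 2, seed = 1)
#' sort(fit$centroids[, 1])
fcm <- function(X, k, m = 2, epsilon = 1e-5, max_iter = 100, seed = 1) {
  X <- as.matrix(X)
  if (epsilon <= 0) stop("epsilon must be positive", call. = FALSE)
  if (max_iter < 1) stop("max_iter must be at least 1", call. = FALSE)
  U <- fcm_init_partition(nrow(X), k, seed)
  withr::with_seed(seed + 1L, {
    trace <- numeric(0)
    converged <- FALSE
    C <- NULL
    for (it in seq_len(max_iter)) {
      C <- fcm_update_centroids(X, U, m)
      J <- fcm_objective(X, U, C, m)
      trace <- c(trace, J)
      if (it > 1 && abs(J - trace[it - 1]) < epsilon) {
        converged <- TRUE
        break
      }
      U <- fcm_update_membership(X, C, m)
    }
  })
  if (!converged) {
    warning("fuzzy c-means did not converge within ", max_iter, " iterations",
            call. = FALSE)
  }
  U <- fcm_update_membership(X, C, m)  # memberships matching final centroids
  structure(
    list(memberships = U, centroids = C, objective_trace = trace,
         iterations = length(trace), converged = converged,
         k = as.integer(k), m = m, epsilon = epsilon, seed = seed),
    class = "fcm_fit"
  )
}

#' De-fuzzify a membership matrix
#'
#' Crisp per-point labels by argmax membership; ties go to the lowest
#' cluster index. Labels are 0-based (0 .. K-1).
#'
#' @param U An `N x K` row-stochastic membership matrix.
#' @return Integer vector of labels in `[0, K-1]`.
#' @export
fcm_defuzzify <- function(U) {
  max.col(U, ties.method = "first") - 1L
}

#' @export
print.fcm_fit <- function(x, ...) {
  cat(sprintf("<fcm_fit> k = %d, m = %g, %d iterations, J = %.6g (%s)\n",
              x$k, x$m, x$iterations, utils::tail(x$objective_trace, 1),
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' Tidy a fuzzy c-means fit
#'
#' @param x An `fcm_fit`.
#' @param ... Unused.
#' @return A tibble with one row per cluster: index, fuzzy size (total
#'   membership mass), crisp size, and centroid coordinates.
#' @method tidy fcm_fit
#' @export
tidy.fcm_fit <- function(x, ...) {
  lab <- fcm_defuzzify(x$memberships)
  ctr <- tibble::as_tibble(x$centroids, .name_repair = ~ paste0("dim", seq_along(.x)))
  dplyr::bind_cols(
    tibble::tibble(
      cluster = seq_len(x$k) - 1L,
      fuzzy_size = colSums(x$memberships),
      crisp_size = vapply(seq_len(x$k) - 1L, function(j) sum(lab == j), integer(1))
    ),
    ctr
  )
}

#' One-line summary of a fuzzy c-means fit
#'
#' @param x An `fcm_fit`.
#' @param ... Unused.
#' @return A one-row tibble: k, m, iterations, final objective, converged.
#' @method glance fcm_fit
#' @export
glance.fcm_fit <- function(x, ...) {
  tibble::tibble(k = x$k, m = x$m, iterations = x$iterations,
                 objective = utils::tail(x$objective_trace, 1),
                 converged = x$converged)
}
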