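test_that("partition initialization is row-stochastic, seeded, and validated", {
  expect_equal(fcm_init_partition(5, 1, seed = 1), matrix(1, 5, 1))
  u <- fcm_init_partition(100, 3, seed = 42)
  expect_equal(rowSums(u), rep(1, 100), tolerance = 1e-12)
  expect_true(all(u >= 0 & u <= 1))
  expect_identical(u, fcm_init_partition(100, 3, seed = 42))
  expect_false(identical(u, fcm_init_partition(100, 3, seed = 43)))
  expect_error(fcm_init_partition(2, 3), "cannot form")
})

test_that("centroid update collapses to plain means for crisp memberships", {
  X <- matrix(c(0, 1, 10, 12), ncol = 1)
  U <- rbind(c(1, 0), c(1, 0), c(0, 1), c(0, 1))
  C <- fcm_update_centroids(X, U, m = 2)
  expect_equal(C, matrix(c(0.5, 11), ncol = 1))
  # total symmetry: both centroids land at the midpoint
  X2 <- matrix(c(0, 1), ncol = 1)
  U2 <- matrix(0.5, 2, 2)
  expect_equal(fcm_update_centroids(X2, U2, m = 2),
               matrix(0.5, 2, 1))
})

test_that("one update cycle matches brute-force formula evaluation", {
  for (case in 1:10) {
    withr::with_seed(100 + case, {
      n <- sample(3:6, 1)
      d <- sample(1:3, 1)
      X <- matrix(rnorm(n * d), n, d)
      m <- runif(1, 1.5, 3)
      U <- fcm_init_partition(n, 2, seed = case)
      C <- fcm_update_centroids(X, U, m)
      expect_equal(C, oracle_fcm_centroids(X, U, m), tolerance = 1e-9)
      U2 <- fcm_update_membership(X, C, m)
      expect_equal(U2, oracle_fcm_membership(X, C, m), tolerance = 1e-9)
      expect_equal(fcm_objective(X, U2, C, m),
                   oracle_fcm_objective(X, U2, C, m), tolerance = 1e-9)
    })
  }
})

test_that("membership update honors symmetry and the zero-distance limit", {
  X <- matrix(c(0, 5), ncol = 1)   # second point equidistant from both centroids
  C <- matrix(c(4, 6), ncol = 1)
  U <- fcm_update_membership(X, C, m = 2)
  expect_equal(U[2, ], c(0.5, 0.5))
  # point sitting exactly on a centroid
  X2 <- matrix(c(4, 0), ncol = 1)
  U2 <- fcm_update_membership(X2, C, m = 2)
  expect_equal(U2[1, ], c(1, 0))
  expect_equal(rowSums(U), rep(1, 2), tolerance = 1e-12)
})

test_that("the objective is zero at a crisp perfect fit and matches hand sums", {
  X <- matrix(c(0, 2), ncol = 1)
  C <- matrix(c(0, 2), ncol = 1)
  U <- diag(2)
  expect_equal(fcm_objective(X, U, C, m = 2), 0)
  expect_equal(fcm_objective(X, U, C, m = 3.7), 0)
  # X = {0, 1}, single centroid at 0.5, memberships all 1, m = 2:
  # J = 0.25 + 0.25
  expect_equal(
    fcm_objective(matrix(c(0, 1), ncol = 1), matrix(1, 2, 1),
                  matrix(0.5), m = 2),
    0.5
  )
})

test_that("fcm recovers well-separated 1-D cluster means", {
  X <- matrix(c(0.0, 0.1, 10.0, 10.1), ncol = 1)
  fit <- fcm(X, k = 2, m = 2, epsilon = 1e-6, seed = 1)
  expect_true(fit$converged)
  expect_equal(sort(fit$centroids[, 1]), c(0.05, 10.05), tolerance = 1e-3)
  # k = 1 gives the global mean almost immediately
  fit1 <- fcm(X, k = 1, seed = 1)
  expect_equal(fit1$centroids[1, 1], mean(X))
  expect_lte(fit1$iterations, 2)
})

test_that("the objective trace is non-increasing and runs are seed-reproducible", {
  for (s in 1:20) {
    withr::with_seed(1000 + s, {
      X <- matrix(rnorm(60), ncol = 2)
    })
    fit <- fcm(X, k = 3, seed = s)
    expect_true(all(diff(fit$objective_trace) <= 1e-9), label = paste("seed", s))
    expect_equal(rowSums(fit$memberships), rep(1, nrow(X)), tolerance = 1e-9)
  }
  X <- matrix(rnorm(40), ncol = 2)
  f1 <- fcm(X, k = 2, seed = 9)
  f2 <- fcm(X, k = 2, seed = 9)
  expect_identical(f1$centroids, f2$centroids)
  expect_identical(f1$objective_trace, f2$objective_trace)
})

test_that("defuzzification takes the argmax with low-index tie-breaks", {
  U <- rbind(c(0.9, 0.1), c(0.5, 0.5), c(0.2, 0.8))
  expect_identical(fcm_defuzzify(U), c(0L, 0L, 1L))
  crisp <- rbind(c(1, 0), c(0, 1))
  expect_identical(fcm_defuzzify(crisp), c(0L, 1L))
})

test_that("cluster relabeling permutes centroids but not the crisp partition", {
  withr::with_seed(77, X <- matrix(c(rnorm(20), rnorm(20, 6)), ncol = 2))
  fit <- fcm(X, k = 3, seed = 2)
  perm <- c(3, 1, 2)
  U_perm <- fit$memberships[, perm]
  lab <- fcm_defuzzify(fit$memberships)
  lab_perm <- fcm_defuzzify(U_perm)
  # same partition as a set: permuted labels induce the same grouping
  expect_equal(length(unique(paste(lab, lab_perm))), length(unique(lab)))
  C_base <- fcm_update_centroids(X, fit$memberships, 2)
  expect_equal(fcm_update_centroids(X, U_perm, 2), C_base[perm, ],
               tolerance = 1e-9)
})

test_that("fcm agrees with an independent implementation on separated data", {
  skip_if_not_installed("e1071")
  withr::with_seed(5, {
    X <- rbind(matrix(rnorm(40, 0, 0.2), ncol = 2),
               matrix(rnorm(40, 5, 0.2), ncol = 2))
  })
  fit <- fcm(X, k = 2, m = 2, epsilon = 1e-8, seed = 1)
  ref <- e1071::cmeans(X, centers = 2, m = 2, iter.max = 200)
  ours <- fit$centroids[order(fit$centroids[, 1]), ]
  theirs <- ref$centers[order(ref$centers[, 1]), ]
  expect_equal(ours, theirs, tolerance = 1e-4, ignore_attr = TRUE)
})

test_that("non-convergence within max_iter is flagged with a warning", {
  withr::with_seed(3, X <- matrix(runif(60), ncol = 2))
  expect_warning(fit <- fcm(X, k = 3, epsilon = 1e-14, max_iter = 3),
                 "did not converge")
  expect_false(fit$converged)
  expect_equal(fit$iterations, 3)
})
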