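# Independent brute-force oracles, deliberately written with plain loops so
# they share no code path with the implementation they check.

# Direct (non-separable) 2-D convolution with symmetric boundary padding.
oracle_conv2 <- function(mat, kernel) {
  r <- (nrow(kernel) - 1) / 2
  n <- nrow(mat); m <- ncol(mat)
  reflect <- function(i, len) {
    if (i < 1) 1 - i else if (i > len) 2 * len - i + 1 else i
  }
  out <- matrix(0, n, m)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      acc <- 0
      for (di in -r:r) {
        for (dj in -r:r) {
          acc <- acc + kernel[di + r + 1, dj + r + 1] *
            mat[reflect(i + di, n), reflect(j + dj, m)]
        }
      }
      out[i, j] <- acc
    }
  }
  out
}

# Per-pixel loop over an RGB array: area / coordinate sums / moments of the
# pixels meeting the lesion condition within 1-based `rows`.
oracle_region_scan <- function(arr, rows, xloc = NULL, yloc = NULL) {
  area <- 0; sumx <- 0; sumy <- 0
  mom <- matrix(0, 3, 3)
  for (i in rows) {
    for (j in seq_len(dim(arr)[2])) {
      r <- arr[i, j, 1]; g <- arr[i, j, 2]; b <- arr[i, j, 3]
      if (g < 90 && r > 5 && b > 5) {
        area <- area + 1
        sumx <- sumx + (i - 1)
        sumy <- sumy + (j - 1)
        if (!is.null(xloc)) {
          for (p in 0:2) {
            for (q in 0:2) {
              mom[p + 1, q + 1] <- mom[p + 1, q + 1] +
                (i - 1 - xloc)^p * (j - 1 - yloc)^q
            }
          }
        }
      }
    }
  }
  list(area = area, sumx = sumx, sumy = sumy,
       moments = c(mom[1, 1], mom[1, 2], mom[1, 3],
                   mom[2, 1], mom[2, 2], mom[2, 3],
                   mom[3, 1], mom[3, 2], mom[3, 3]))
}

# Definitional Pearson r: covariance over the product of standard deviations.
oracle_pearson <- function(u, v) {
  n <- length(u)
  mu <- sum(u) / n; mv <- sum(v) / n
  cov <- sum((u - mu) * (v - mv)) / n
  su <- sqrt(sum((u - mu)^2) / n)
  sv <- sqrt(sum((v - mv)^2) / n)
  cov / (su * sv)
}

# Direct summation of the FCM update formulas.
oracle_fcm_centroids <- function(X, U, m) {
  K <- ncol(U); d <- ncol(X)
  C <- matrix(0, K, d)
  for (k in seq_len(K)) {
    num <- rep(0, d); den <- 0
    for (i in seq_len(nrow(X))) {
      w <- U[i, k]^m
      num <- num + w * X[i, ]
      den <- den + w
    }
    C[k, ] <- num / den
  }
  C
}

oracle_fcm_membership <- function(X, C, m) {
  N <- nrow(X); K <- nrow(C)
  U <- matrix(0, N, K)
  for (i in seq_len(N)) {
    d <- sqrt(rowSums((C - matrix(X[i, ], K, ncol(X), byrow = TRUE))^2))
    if (any(d == 0)) {
      U[i, ] <- (d == 0) / sum(d == 0)
    } else {
      for (k in seq_len(K)) {
        U[i, k] <- 1 / sum((d[k] / d)^(2 / (m - 1)))
      }
    }
  }
  U
}

oracle_fcm_objective <- function(X, U, C, m) {
  J <- 0
  for (i in seq_len(nrow(X))) {
    for (k in seq_len(nrow(C))) {
      J <- J + U[i, k]^m * sum((X[i, ] - C[k, ])^2)
    }
  }
  J
}

# Build a small RGB leaf_image from a function of (row, col) -> c(r, g, b),
# 1-based indices.
make_test_image <- function(h, w, f) {
  a <- array(0, dim = c(h, w, 3))
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      a[i, j, ] <- f(i, j)
    }
  }
  leaf_image(a, "rgb")
}

# Uniform random RGB image with seeded values.
random_rgb_image <- function(h, w, seed) {
  withr::with_seed(seed, {
    leaf_image(array(sample(0:255, h * w * 3, replace = TRUE),
                     dim = c(h, w, 3)), "rgb")
  })
}
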