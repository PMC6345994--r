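# exhaustive k-means oracle: minimum within-cluster sum of squares over all
# assignments of N points to k clusters (k^N enumeration, tiny N only)
exhaustive_kmeans <- function(X, k) {
  n <- nrow(X)
  best <- list(wss = Inf, assign = NULL)
  grid <- rep(list(seq_len(k)), n)
  combos <- do.call(expand.grid, grid)
  for (r in seq_len(nrow(combos))) {
    a <- as.integer(combos[r, ])
    if (length(unique(a)) < k) next
    wss <- 0
    for (j in seq_len(k)) {
      pts <- X[a == j, , drop = FALSE]
      ctr <- colMeans(pts)
      wss <- wss + sum(sweep(pts, 2, ctr)^2)
    }
    if (wss < best$wss - 1e-12) best <- list(wss = wss, assign = a)
  }
  best
}

# two labelings describe the same partition iff their contingency table is a
# (scaled) permutation matrix
same_partition <- function(a, b) {
  tab <- table(a, b)
  all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1)
}

test_that("distinct repeated spectra are recovered exactly with k groups", {
  set.seed(4)
  protos <- matrix(runif(4 * 25, 0.2, 1.6), 4, 25)
  X <- protos[rep(1:4, each = 3), ]
  km <- fit_kmeans(X, k = 4, seed = 2)
  expect_equal(tail(km$inertia, 1), 0)
  # centroids equal the four distinct spectra (in some order)
  d <- as.matrix(dist(rbind(km$centroids, protos)))[1:4, 5:8]
  expect_true(all(apply(d, 1, min) < 1e-9))
  expect_identical(anyDuplicated(apply(d, 1, which.min)), 0L)
})

test_that("k = 1 yields the arithmetic mean and identical points give zero inertia", {
  set.seed(5)
  X <- matrix(rnorm(8 * 25), 8, 25)
  km <- fit_kmeans(X, k = 1, seed = 0)
  expect_equal(km$centroids[1, ], colMeans(X))
  same <- matrix(rep(runif(25), 6), 6, 25, byrow = TRUE)
  expect_equal(tail(fit_kmeans(same, k = 3, seed = 0)$inertia, 1), 0)
  expect_error(fit_kmeans(X[0, , drop = FALSE], k = 1), "empty")
  expect_error(fit_kmeans(X, k = 20), "at least k")
})

test_that("fitted partitions match the exhaustive optimum on tiny separated data", {
  for (case in 1:3) {
    set.seed(40 + case)
    k <- sample(2:3, 1)
    centers <- matrix(runif(k * 3, 0, 10), k, 3) * 3
    X <- centers[rep(seq_len(k), length.out = 8), ] + matrix(rnorm(24, 0, 0.3), 8, 3)
    km <- fit_kmeans(X, k = k, seed = 1)
    ours <- predict(km, X)
    oracle <- exhaustive_kmeans(X, k)
    expect_equal(tail(km$inertia, 1), oracle$wss, tolerance = 1e-9)
    expect_true(same_partition(ours, oracle$assign))
  }
})

test_that("within-cluster sum of squares is non-increasing over updates", {
  set.seed(8)
  X <- matrix(rnorm(300 * 10), 300, 10)
  km <- fit_kmeans(X, k = 5, n_iter = 30, seed = 3)
  expect_true(all(diff(km$inertia) <= 1e-9 * km$inertia[1]))
})

test_that("prediction is nearest-centroid with ties to the lowest index", {
  set.seed(9)
  km <- fit_kmeans(matrix(rnorm(40 * 4), 40, 4), k = 3, seed = 1)
  # a centroid maps to its own index
  expect_identical(predict(km, km$centroids), 1:3)
  # equidistant point between two centroids -> lower index
  C <- matrix(c(0, 0, 2, 0, 0, 2, 4, 4, 6, 6, 8, 8), 6, 2, byrow = TRUE)
  m <- structure(list(centroids = C, k = 6L, n_iter = 0L, seed = 0L,
                      wavelengths = NULL, inertia = numeric(0)),
                 class = "cluster_model")
  expect_identical(predict(m, matrix(c(1, 0), 1, 2)), 1L)
  # brute-force nearest-centroid oracle on random points
  P <- matrix(rnorm(50 * 2, 3, 4), 50, 2)
  brute <- apply(P, 1, function(p) which.min(colSums((t(C) - p)^2)))
  expect_identical(predict(m, P), as.integer(brute))
  expect_error(predict(km, matrix(0, 2, 7)), "bands")
})

test_that("cluster images rank clusters by mean centroid intensity", {
  wl <- seq(450, 690, 10)
  m <- structure(list(centroids = rbind(rep(0.9, 25), rep(0.4, 25)), k = 2L,
                      n_iter = 0L, seed = 0L, wavelengths = wl,
                      inertia = numeric(0)), class = "cluster_model")
  data <- array(0, dim = c(25, 2, 2))
  data[, 1, ] <- 0.9; data[, 2, ] <- 0.4
  stk <- hyper_stack(data, wl, role = "corrected")
  ci <- make_cluster_image(m, stk)
  expect_identical(ci$display[1, ], c(255, 255))
  expect_identical(ci$display[2, ], c(0, 0))
  # permuting cluster order leaves the display unchanged
  m2 <- m; m2$centroids <- m$centroids[2:1, ]
  expect_identical(make_cluster_image(m2, stk)$display, ci$display)
})

test_that("noise-free scenes segment exactly by spectral signature", {
  sc <- generate_scene(clean_config(seed = 6))
  ffc <- flat_field_correct(sc$object, sc$dark, sc$flat)
  X <- px_of(ffc)
  km <- fit_kmeans(X, k = 6, seed = 2)
  ids <- matrix(predict(km, X), 96, 96)
  # reconstruct the signature index per pixel from the bank
  bank <- signature_bank()
  truth_sig <- apply(X, 1, function(p) which.min(colSums((t(bank) - p)^2)))
  # each cluster maps to exactly one signature and vice versa
  tab <- table(ids, truth_sig)
  expect_true(all(rowSums(tab > 0) == 1))
  expect_true(all(colSums(tab > 0) == 1))
  # per-cluster mean spectra match centroids on converged separable data
  cms <- cluster_mean_spectra(km, ffc)
  expect_equal(cms$mean, km$centroids, tolerance = 1e-9)
  expect_true(all(cms$sd < 1e-3))
})

test_that("single-cluster mean spectra equal the global mean", {
  sc <- generate_scene(clean_config(seed = 4))
  ffc <- flat_field_correct(sc$object, sc$dark, sc$flat)
  km <- fit_kmeans(px_of(ffc), k = 1, seed = 0)
  cms <- cluster_mean_spectra(km, ffc)
  expect_equal(cms$mean[1, ], colMeans(px_of(ffc)))
  expect_identical(cms$count, as.integer(96 * 96))
})

test_that("cluster models serialize deterministically and round-trip", {
  set.seed(10)
  X <- matrix(runif(200 * 25), 200, 25)
  p1 <- withr::local_tempfile(fileext = ".json")
  p2 <- withr::local_tempfile(fileext = ".json")
  write_cluster_model(fit_kmeans(X, k = 8, seed = 42, wavelengths = seq(450, 690, 10)), p1)
  write_cluster_model(fit_kmeans(X, k = 8, seed = 42, wavelengths = seq(450, 690, 10)), p2)
  expect_identical(readLines(p1), readLines(p2))
  m <- read_cluster_model(p1)
  expect_equal(m$centroids,
               fit_kmeans(X, k = 8, seed = 42)$centroids, tolerance = 0)
  expect_identical(m$k, 8L)
})
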