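# exhaustive best-split oracle for 1-D features: evaluate every midpoint
# threshold and return the maximum entropy gain
exhaustive_gain_1d <- function(x, y) {
  h <- function(lab) {
    if (!length(lab)) return(0)
    p <- table(lab) / length(lab)
    -sum(p * log2(p))
  }
  hp <- h(y)
  thr <- sort(unique(x))
  thr <- (head(thr, -1) + tail(thr, -1)) / 2
  best <- 0
  for (t in thr) {
    l <- y[x <= t]; r <- y[x > t]
    if (!length(l) || !length(r)) next
    g <- hp - (length(l) * h(l) + length(r) * h(r)) / length(y)
    best <- max(best, g)
  }
  best
}

test_that("entropy reproduces the closed-form values", {
  expect_equal(entropy_bits(rep("a", 10)), 0)
  expect_equal(entropy_bits(c(0, 0, 1, 1)), 1.0)
  expect_equal(entropy_bits(rep(1:4, each = 25)), 2.0)
  expect_error(entropy_bits(integer(0)), "empty")
})

test_that("candidate proposal respects ranges, types and determinism", {
  set.seed(23)
  X <- matrix(runif(30 * 4), 30, 4)
  cand <- propose_candidates(X, n_candidates = 200, seed = 9)
  expect_identical(nrow(cand), 200L)
  for (r in seq_len(50)) {
    expr <- if (cand$type[r] == "single") X[, cand$i[r]]
            else X[, cand$i[r]] - X[, cand$j[r]]
    expect_gte(cand$threshold[r], min(expr))
    expect_lte(cand$threshold[r], max(expr))
  }
  # difference rules use distinct features
  diffs <- cand[cand$type == "difference", ]
  expect_true(all(diffs$i != diffs$j))
  # one feature -> no difference rules
  c1 <- propose_candidates(X[, 1, drop = FALSE], n_candidates = 50, seed = 1)
  expect_true(all(c1$type == "single"))
  # same seed, same list
  expect_identical(propose_candidates(X, 100, seed = 5),
                   propose_candidates(X, 100, seed = 5))
  # degenerate node: all features constant -> empty candidate list
  expect_identical(nrow(propose_candidates(matrix(1, 5, 3), 50, seed = 1)), 0L)
})

test_that("best split maximizes entropy reduction (exhaustive 1-D oracle)", {
  x <- matrix(c(0, 1, 2, 3), 4, 1)
  y <- c(0L, 0L, 1L, 1L)
  cand <- data.frame(type = "single", i = 1L, j = NA_integer_,
                     threshold = c(0.5, 1.5, 2.5))
  bs <- best_split(x, y, cand)
  expect_equal(bs$gain, 1.0)
  expect_equal(bs$rule$threshold, 1.5)
  # all labels identical -> no split
  expect_null(best_split(x, rep(1L, 4), cand))
  # random 1-D sets: giving all midpoints as candidates reaches the
  # exhaustive optimum
  for (case in 1:5) {
    set.seed(30 + case)
    xv <- round(runif(20, 0, 10), 1)
    yv <- sample(0:2, 20, replace = TRUE)
    mids <- sort(unique(xv))
    mids <- (head(mids, -1) + tail(mids, -1)) / 2
    cand <- data.frame(type = "single", i = 1L, j = NA_integer_, threshold = mids)
    bs <- best_split(matrix(xv, 20, 1), yv, cand)
    expect_equal(bs$gain, exhaustive_gain_1d(xv, yv), tolerance = 1e-12)
  }
})

test_that("difference rules separate sign(f1 - f2) where axis-aligned rules cannot", {
  set.seed(33)
  n <- 20
  X <- cbind(runif(n, 0, 1), runif(n, 0, 1))
  X <- X[abs(X[, 1] - X[, 2]) > 0.05, , drop = FALSE]
  y <- as.integer(X[, 1] > X[, 2])
  diff_cand <- data.frame(type = "difference", i = 1L, j = 2L, threshold = 0)
  bs <- best_split(X, y, diff_cand)
  expect_equal(bs$gain, entropy_bits(y), tolerance = 1e-12)
  # exhaustive axis-aligned candidates achieve strictly less
  mids <- function(v) { s <- sort(unique(v)); (head(s, -1) + tail(s, -1)) / 2 }
  ax <- rbind(data.frame(type = "single", i = 1L, j = NA_integer_, threshold = mids(X[, 1])),
              data.frame(type = "single", i = 2L, j = NA_integer_, threshold = mids(X[, 2])))
  bs_ax <- best_split(X, y, ax)
  expect_lt(bs_ax$gain, entropy_bits(y) - 0.05)
})

test_that("single trees honor depth limits, purity and leaf probabilities", {
  set.seed(34)
  X <- matrix(runif(60 * 3), 60, 3)
  y <- as.integer(X[, 1] > 0.5)
  cfg0 <- forest_config(n_trees = 1, max_depth = 50, n_candidates = 200)
  cfg0$max_depth <- 0L
  t0 <- train_tree(X, y, cfg0, classes = 0:1, seed = 1)
  expect_identical(length(t0$type), 1L)
  expect_equal(as.vector(t0$probs[1, ]), as.vector(table(y) / length(y)))
  # pure input -> single leaf with probability 1
  tp <- train_tree(X, rep(1L, 60), forest_config(n_trees = 1), classes = 0:1, seed = 1)
  expect_identical(length(tp$type), 1L)
  expect_equal(as.vector(tp$probs[1, ]), c(0, 1))
  # linearly separable data -> perfect training accuracy
  cfg <- forest_config(n_trees = 1, max_depth = 20, n_candidates = 300)
  tr <- train_tree(X, y, cfg, classes = 0:1, seed = 3)
  forest1 <- structure(list(trees = list(unclass(tr)), config = cfg,
                            classes = 0:1, feature_names = NULL),
                       class = "hs_forest")
  expect_identical(as.integer(predict(forest1, X)), y)
})

test_that("trained forests satisfy the structural invariants", {
  set.seed(35)
  X <- matrix(runif(400 * 5), 400, 5)
  y <- (as.integer(X[, 1] > 0.5) + as.integer(X[, 2] > X[, 3])) %% 3
  cfg <- forest_config(n_trees = 12, max_depth = 8, n_candidates = 100,
                       per_tree_sample = 300, seed = 4)
  rf <- train_forest(X, y, cfg, classes = 0:2)
  for (tr in rf$trees) {
    internal <- tr$type >= 0
    expect_true(all(tr$gain[internal] > 0))
    expect_true(all(tr$depth <= cfg$max_depth))
    leaf_probs <- tr$probs[tr$type == -1L, , drop = FALSE]
    expect_equal(rowSums(leaf_probs), rep(1, nrow(leaf_probs)), tolerance = 1e-9)
    # difference rules reference distinct features
    d <- tr$type == 1L
    expect_true(all(tr$i[d] != tr$j[d]))
  }
})

test_that("probability averaging and argmax prediction behave as defined", {
  leaf_tree <- function(p) list(type = -1L, i = 0L, j = 0L,
                                threshold = NA_real_, gain = NA_real_,
                                left = 0L, right = 0L, depth = 0L,
                                probs = matrix(p, 1))
  rf <- structure(list(trees = list(leaf_tree(c(1, 0)), leaf_tree(c(0, 1))),
                       config = forest_config(n_trees = 2), classes = 0:1,
                       feature_names = NULL), class = "hs_forest")
  p <- predict_proba(rf, matrix(0, 3, 1))
  expect_equal(unname(p), matrix(0.5, 3, 2))
  # tie -> lowest class code
  expect_identical(as.integer(predict(rf, matrix(0, 3, 1))), rep(0L, 3))
  # probabilities sum to one pixel-wise on a real forest
  set.seed(36)
  X <- matrix(runif(200 * 4), 200, 4)
  y <- as.integer(X[, 1] + X[, 2] > 1)
  rf2 <- train_forest(X, y, forest_config(n_trees = 7, max_depth = 6,
                                          n_candidates = 50,
                                          per_tree_sample = 150, seed = 2),
                      classes = 0:1)
  p2 <- predict_proba(rf2, X)
  expect_equal(rowSums(p2), rep(1, 200), tolerance = 1e-9)
  expect_identical(as.integer(predict(rf2, X)),
                   as.integer(rf2$classes[max.col(p2, "first")]))
})

test_that("training is seed-deterministic and rejects missing classes", {
  set.seed(37)
  X <- matrix(runif(300 * 4), 300, 4)
  y <- as.integer(X[, 1] > X[, 2]) + 2L * as.integer(X[, 3] > 0.5)
  cfg <- forest_config(n_trees = 5, max_depth = 10, n_candidates = 80,
                       per_tree_sample = 200, seed = 11)
  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  write_forest(train_forest(X, y, cfg, classes = 0:3), f1)
  write_forest(train_forest(X, y, cfg, classes = 0:3), f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_error(train_forest(X, rep(1L, 300), cfg, classes = 0:3),
               "absent.*0.*2.*3")
  # round trip preserves predictions exactly
  rf <- train_forest(X, y, cfg, classes = 0:3)
  rt <- read_forest(f1)
  expect_equal(predict_proba(rt, X), predict_proba(rf, X))
})

test_that("forests generalize across noise-free scenes", {
  scenes <- lapply(c(51, 52), function(s) generate_scene(clean_config(seed = s)))
  ffc <- lapply(scenes, function(s) flat_field_correct(s$object, s$dark, s$flat))
  km <- fit_kmeans(px_of(ffc[[1]]), k = 6, seed = 1)
  fs <- lapply(ffc, function(x) extract_features(make_cluster_image(km, x)))
  rf <- train_forest(fs[[1]], scenes[[1]]$truth$labels,
                     config = forest_config(n_trees = 15, max_depth = 15,
                                            n_candidates = 200,
                                            per_tree_sample = 6000, seed = 3))
  pred <- predict(rf, fs[[2]])
  expect_gte(mean(pred == scenes[[2]]$truth$labels), 0.95)
})
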