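# central finite-difference oracle for second derivatives on the same grid
fd_hessian <- function(img) {
  h <- nrow(img); w <- ncol(img)
  hxx <- matrix(NA_real_, h, w); hyy <- hxx; hxy <- hxx
  for (y in 2:(h - 1)) for (x in 2:(w - 1)) {
    hxx[y, x] <- img[y, x + 1] - 2 * img[y, x] + img[y, x - 1]
    hyy[y, x] <- img[y + 1, x] - 2 * img[y, x] + img[y - 1, x]
    hxy[y, x] <- (img[y + 1, x + 1] - img[y + 1, x - 1] -
                  img[y - 1, x + 1] + img[y - 1, x - 1]) / 4
  }
  list(hxx = hxx, hyy = hyy, hxy = hxy)
}

interior <- function(m, b) m[(b + 1):(nrow(m) - b), (b + 1):(ncol(m) - b)]

test_that("derivative and dispersion planes vanish on constant images", {
  img <- matrix(5, 20, 20)
  hp <- hessian_planes(img, 7)
  for (p in hp) expect_true(all(abs(p) < 1e-12))
  expect_true(all(abs(laplacian_plane(img, 7)) < 1e-12))
  expect_true(all(local_std_plane(img, 7) < 1e-12))
  expect_true(all(circular_std_plane(img, 7) == 0))
})

test_that("Hessian responses on polynomial images match finite differences", {
  x <- matrix(rep(1:24, each = 24), 24, 24)  # f(x, y) = x
  img <- x^2
  hp <- hessian_planes(img, 7)
  fd <- fd_hessian(img)
  b <- 4
  expect_equal(interior(hp$hxx, b), interior(fd$hxx, b), tolerance = 1e-9)
  expect_true(all(abs(interior(hp$hxx, b) - 2) < 1e-9))
  expect_true(all(abs(interior(hp$hyy, b)) < 1e-9))
  expect_true(all(abs(interior(hp$hxy, b)) < 1e-9))
  # mixed term: f = x * y
  y <- t(x)
  hp2 <- hessian_planes(x * y, 7)
  fd2 <- fd_hessian(x * y)
  expect_equal(interior(hp2$hxy, b), interior(fd2$hxy, b), tolerance = 1e-9)
})

test_that("rotating the image by 90 degrees swaps Hxx and Hyy and keeps eigenvalues", {
  set.seed(14)
  img <- matrix(rnorm(22 * 22), 22, 22)
  rot <- t(img)[, rev(seq_len(22))] # 90-degree rotation
  a <- hessian_planes(img, 7)
  r <- hessian_planes(rot, 7)
  back <- function(m) t(m[, rev(seq_len(22))])  # undo the rotation
  expect_equal(back(r$hxx), a$hyy, tolerance = 1e-10)
  expect_equal(back(r$hyy), a$hxx, tolerance = 1e-10)
  expect_equal(back(r$eig1), a$eig1, tolerance = 1e-10)
  expect_equal(back(r$eig2), a$eig2, tolerance = 1e-10)
})

test_that("the Laplacian is Hxx + Hyy and vanishes on ramps", {
  set.seed(15)
  img <- matrix(rnorm(18 * 18), 18, 18)
  hp <- hessian_planes(img, 7)
  expect_equal(laplacian_plane(img, 7), hp$hxx + hp$hyy)
  ramp <- matrix(rep(1:20, each = 20), 20, 20) * 0.7 +
          matrix(rep(1:20, times = 20), 20, 20) * 1.3
  expect_true(all(abs(interior(laplacian_plane(ramp, 7), 4)) < 1e-9))
})

test_that("local standard deviation matches direct window computation", {
  a <- 6
  cb <- a * (outer(1:16, 1:16, "+") %% 2)  # checkerboard {0, a}
  sd7 <- local_std_plane(cb, 7)
  # direct window oracle: population sd over the 7x7 window (25/24 split of
  # the two values in an odd window, so just below a/2)
  win <- cb[5:11, 5:11]
  expect_equal(sd7[8, 8], sqrt(mean(win^2) - mean(win)^2), tolerance = 1e-12)
  expect_equal(sd7[8, 8], a * sqrt(25 * 24) / 49, tolerance = 1e-12)
  expect_true(all(abs(interior(sd7, 3) - a / 2) < 0.01 * a))
  # homogeneity: scaling the image scales the plane
  set.seed(16)
  img <- matrix(runif(15 * 15), 15, 15)
  expect_equal(local_std_plane(-3 * img, 7), 3 * local_std_plane(img, 7))
})

test_that("circular standard deviation follows the axial dispersion formula", {
  # constant gradient orientation (linear ramp) -> zero dispersion
  ramp <- matrix(rep(1:20, each = 20), 20, 20)
  expect_true(all(abs(interior(circular_std_plane(ramp, 7), 4)) < 1e-10))
  # direct-formula oracle at one interior pixel of a random image
  set.seed(17)
  img <- matrix(rnorm(20 * 20), 20, 20)
  plane <- circular_std_plane(img, 7)
  ks <- hyperclass:::gauss_kernels(7)
  gx <- hyperclass:::conv_sep(img, ks$d1, ks$g)
  gy <- hyperclass:::conv_sep(img, ks$g, ks$d1)
  yc <- 10; xc <- 10
  win <- expand.grid(y = (yc - 3):(yc + 3), x = (xc - 3):(xc + 3))
  gxv <- gx[cbind(win$y, win$x)]; gyv <- gy[cbind(win$y, win$x)]
  m <- sqrt(gxv^2 + gyv^2)
  theta2 <- 2 * atan2(gyv, gxv)
  rbar <- sqrt(sum(m * cos(theta2))^2 + sum(m * sin(theta2))^2) / sum(m)
  expect_equal(plane[yc, xc], sqrt(-2 * log(rbar)), tolerance = 1e-9)
  # orientations spread uniformly -> dispersion approaches the cap
  spots <- matrix(0, 21, 21); spots[11, 11] <- 1
  v <- circular_std_plane(spots, 7)
  expect_true(all(v >= 0 & v <= sqrt(-2 * log(1e-6)) + 1e-9))
})

test_that("the default configuration yields exactly 24 named planes", {
  cfg <- feature_config()
  expect_identical(cfg$total_features, 24L)
  sc <- generate_scene(small_config(seed = 19))
  ffc <- flat_field_correct(sc$object, sc$dark, sc$flat)
  km <- fit_kmeans(px_of(ffc), k = 8, seed = 1)
  fs <- extract_features(make_cluster_image(km, ffc), cfg)
  expect_identical(dim(fs$planes)[3], 24L)
  expect_identical(length(unique(fs$names)), 24L)
  expect_true(all(is.finite(fs$planes)))
  # scale-1 planes equal direct single-scale computation
  disp <- make_cluster_image(km, ffc)$display * 1.0
  hp <- hessian_planes(disp, 7)
  expect_equal(fs$planes[, , fs$names == "hxx_s1"], hp$hxx)
  expect_equal(fs$planes[, , fs$names == "intensity_s1"], disp)
  expect_equal(fs$planes[, , fs$names == "local_std_s1"], local_std_plane(disp, 7))
})

test_that("constant input yields zero derivative planes at every scale", {
  fs <- extract_features(matrix(7, 64, 64))
  for (i in seq_along(fs$names)) {
    if (!grepl("intensity", fs$names[i])) {
      expect_true(all(abs(fs$planes[, , i]) < 1e-10), info = fs$names[i])
    } else {
      expect_true(all(fs$planes[, , i] == 7))
    }
  }
})

test_that("features are translation-equivariant away from borders", {
  set.seed(20)
  base <- matrix(runif(80 * 80, 0, 255), 80, 80)
  big <- rbind(cbind(base, base), cbind(base, base))[1:96, 1:96]
  shift <- 8  # multiple of the coarsest block size
  shifted <- big[c((shift + 1):96, 1:shift), ]
  f1 <- extract_features(big)
  f2 <- extract_features(shifted)
  margin <- 24
  for (i in seq_along(f1$names)) {
    a <- f1$planes[(margin + shift + 1):(96 - margin), margin:(96 - margin), i]
    b <- f2$planes[(margin + 1):(96 - margin - shift), margin:(96 - margin), i]
    expect_equal(a, b, tolerance = 1e-9, info = f1$names[i])
  }
})

test_that("images smaller than the kernel at a scale are rejected", {
  expect_error(extract_features(matrix(1, 20, 20)), "smaller than kernel")
  expect_error(hessian_planes(matrix(1, 4, 4), 7), "smaller")
  expect_error(feature_config(kernel = 4), "odd")
})
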