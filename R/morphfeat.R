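# Multi-scale morphological (texture and edge-based) features computed from
# the display channel of a cluster image: Gaussian-derivative Hessian
# components and eigenvalues, Laplacian, local standard deviation, and the
# circular standard deviation of gradient orientations, at scales 1, 1/2 and
# 1/4 with a fixed kernel size.

#' Feature extraction configuration
#'
#' @param kernel Window / filter size in pixels (odd, >= 3; default 7).
#' @param scales Downscale factors (default `c(1, 1/2, 1/4)`).
#' @return List of class `feature_config`. With the default 8 per-scale
#'   planes (raw intensity, Hxx, Hyy, Hxy, two Hessian eigenvalues, local
#'   standard deviation, circular standard deviation) and three scales the
#'   total feature count is 24.
#' @export
feature_config <- function(kernel = 7L, scales = c(1, 1/2, 1/4)) {
  kernel <- as.integer(kernel)
  if (kernel < 3L || kernel %% 2L == 0L) stop("kernel must be odd and >= 3")
  if (any(scales <= 0 | scales > 1)) stop("scales must lie in (0, 1]")
  per_scale <- c("intensity", "hxx", "hyy", "hxy", "eig1", "eig2",
                 "local_std", "circ_std")
  structure(list(kernel = kernel, scales = scales,
                 per_scale_features = per_scale,
                 total_features = length(per_scale) * length(scales)),
            class = "feature_config")
}

# ---- separable convolution with symmetric (reflect) padding ----

reflect_index <- function(n, r) c(r:1, 1:n, n:(n - r + 1L))

# convolve rows (y direction) and columns (x direction) with 1-d kernels
conv_sep <- function(img, kx, ky) {
  r <- (length(kx) - 1L) %/% 2L
  h <- nrow(img); w <- ncol(img)
  if (h < length(ky) || w < length(kx)) stop("image smaller than kernel")
  pad <- img[reflect_index(h, r), reflect_index(w, r), drop = FALSE]
  # columns (x)
  tmp <- matrix(0, h + 2L * r, w)
  for (u in seq_along(kx)) {
    tmp <- tmp + kx[u] * pad[, u:(u + w - 1L), drop = FALSE]
  }
  out <- matrix(0, h, w)
  for (u in seq_along(ky)) {
    out <- out + ky[u] * tmp[u:(u + h - 1L), , drop = FALSE]
  }
  out
}

# Sampled Gaussian smoothing/derivative kernels, sigma = kernel/4, normalized
# so that responses to 1, x and x^2 are exactly 1, d/dx x = 1 and
# d^2/dx^2 x^2 = 2 on the discrete grid.
gauss_kernels <- function(kernel) {
  r <- (kernel - 1L) %/% 2L
  sigma <- kernel / 4
  u <- -r:r
  g <- dnorm(u, 0, sigma); g <- g / sum(g)
  d1 <- -(u / sigma^2) * dnorm(u, 0, sigma)
  d1 <- d1 / sum(-u * d1)            # response to f(x)=x is 1
  d2 <- ((u^2 - sigma^2) / sigma^4) * dnorm(u, 0, sigma)
  d2 <- d2 - mean(d2)                # zero response to constants
  d2 <- d2 * (2 / sum(u^2 * d2))     # response to f(x)=x^2 is 2
  list(g = g, d1 = d1, d2 = d2, r = r)
}

#' Hessian feature planes
#'
#' Second-derivative responses from Gaussian-derivative filters (standard
#' deviation `kernel/4`), with x along columns and y along rows, plus the two
#' eigenvalues of the per-pixel 2x2 Hessian sorted descending.
#'
#' @param img Numeric matrix (single-channel image).
#' @param kernel Filter size in pixels (odd).
#' @return List of matrices `hxx`, `hyy`, `hxy`, `eig1`, `eig2`.
#' @export
hessian_planes <- function(img, kernel = 7L) {
  ks <- gauss_kernels(kernel)
  hxx <- conv_sep(img, ks$d2, ks$g)
  hyy <- conv_sep(img, ks$g, ks$d2)
  hxy <- conv_sep(img, ks$d1, ks$d1)
  tr2 <- (hxx + hyy) / 2
  disc <- sqrt(((hxx - hyy) / 2)^2 + hxy^2)
  list(hxx = hxx, hyy = hyy, hxy = hxy, eig1 = tr2 + disc, eig2 = tr2 - disc)
}

#' Laplacian feature plane
#'
#' Sum of the two unmixed second derivatives, `Hxx + Hyy`.
#'
#' @inheritParams hessian_planes
#' @return Numeric matrix.
#' @export
laplacian_plane <- function(img, kernel = 7L) {
  h <- hessian_planes(img, kernel)
  h$hxx + h$hyy
}

# window mean via separable box filter (reflect padding)
box_mean <- function(img, kernel) {
  k <- rep(1 / kernel, kernel)
  conv_sep(img, k, k)
}

#' Local standard deviation plane
#'
#' Population standard deviation of the intensities in each kernel x kernel
#' window (reflect-padded borders).
#'
#' @inheritParams hessian_planes
#' @return Numeric matrix.
#' @export
local_std_plane <- function(img, kernel = 7L) {
  m <- box_mean(img, kernel)
  v <- box_mean(img^2, kernel) - m^2
  v[v < 0] <- 0
  sqrt(v)
}

# cap: circular std evaluated at mean resultant length 1e-6
circ_std_cap <- function() sqrt(-2 * log(1e-6))

#' Circular standard deviation plane
#'
#' Circular standard deviation `sqrt(-2 ln Rbar)` of the local gradient
#' orientations over each kernel x kernel window, weighted by gradient
#' magnitude. Orientations are axial (an edge at angle theta is the same as
#' theta + pi), so the doubled-angle convention is used. Windows with zero
#' total gradient magnitude yield 0; `Rbar` is floored at 1e-6, capping the
#' value at about 5.26.
#'
#' @inheritParams hessian_planes
#' @return Numeric matrix with values in `[0, sqrt(-2 log 1e-6)]`.
#' @export
circular_std_plane <- function(img, kernel = 7L) {
  ks <- gauss_kernels(kernel)
  gx <- conv_sep(img, ks$d1, ks$g)
  gy <- conv_sep(img, ks$g, ks$d1)
  m <- sqrt(gx^2 + gy^2)
  # magnitudes at floating-noise level relative to the image scale (e.g. on
  # constant images) count as zero gradient
  m[m <= 1e-12 * max(abs(img))] <- 0
  nz <- m > 0
  # magnitude-weighted doubled-angle components: m*cos(2t), m*sin(2t)
  c2 <- matrix(0, nrow(img), ncol(img)); s2 <- c2
  c2[nz] <- (gx[nz]^2 - gy[nz]^2) / m[nz]
  s2[nz] <- 2 * gx[nz] * gy[nz] / m[nz]
  k1 <- rep(1, kernel)
  C <- conv_sep(c2, k1, k1)
  S <- conv_sep(s2, k1, k1)
  M <- conv_sep(m, k1, k1)
  out <- matrix(0, nrow(img), ncol(img))
  ok <- M > 1e-12 * max(M, 1e-300)
  rbar <- pmin(1, pmax(1e-6, sqrt(C[ok]^2 + S[ok]^2) / M[ok]))
  out[ok] <- sqrt(-2 * log(rbar))
  out
}

# block-mean downscale by integer factor (edge-replicated to a multiple)
downscale_area <- function(img, factor) {
  if (factor == 1) return(img)
  b <- as.integer(round(1 / factor))
  h <- nrow(img); w <- ncol(img)
  H <- ceiling(h / b) * b; W <- ceiling(w / b) * b
  if (H != h || W != w) {
    img <- img[c(seq_len(h), rep(h, H - h)), c(seq_len(w), rep(w, W - w)), drop = FALSE]
  }
  # mean over b x b blocks: pool rows, then columns via transpose
  rows <- matrix(colMeans(matrix(img, nrow = b)), nrow = H %/% b, ncol = W)
  t(matrix(colMeans(matrix(t(rows), nrow = b)), nrow = W %/% b, ncol = H %/% b))
}

# nearest-neighbor upsample back to (h, w)
upsample_nn <- function(img, h, w) {
  ri <- pmin(nrow(img), ceiling(seq_len(h) * nrow(img) / h))
  ci <- pmin(ncol(img), ceiling(seq_len(w) * ncol(img) / w))
  img[ri, ci, drop = FALSE]
}

#' Extract the multi-scale morphological feature stack
#'
#' For each scale the cluster-image display channel is downscaled by block
#' averaging, the per-scale feature planes are computed with the fixed kernel,
#' and each plane is upsampled back to full resolution by nearest neighbor.
#' Plane order is stable: per-scale features in the order of
#' `config$per_scale_features`, scales in the order of `config$scales`. With
#' defaults this yields exactly 24 planes.
#'
#' @param cimg A [make_cluster_image()] result, or a plain numeric matrix
#'   used directly as the single-channel input.
#' @param config A [feature_config()].
#' @return Object of class `feature_stack`: `planes` (H x W x total_features
#'   array), `names` (plane names with scale suffixes), `config`.
#' @export
extract_features <- function(cimg, config = feature_config()) {
  img <- if (inherits(cimg, "cluster_image")) cimg$display else as.matrix(cimg)
  img <- img * 1.0
  h <- nrow(img); w <- ncol(img)
  planes <- array(0, dim = c(h, w, config$total_features))
  nms <- character(config$total_features)
  i <- 0L
  for (s in config$scales) {
    sc <- downscale_area(img, s)
    if (nrow(sc) < config$kernel || ncol(sc) < config$kernel) {
      stop("downscaled image smaller than kernel at scale ", s)
    }
    hs <- hessian_planes(sc, config$kernel)
    per <- list(intensity = sc, hxx = hs$hxx, hyy = hs$hyy, hxy = hs$hxy,
                eig1 = hs$eig1, eig2 = hs$eig2,
                local_std = local_std_plane(sc, config$kernel),
                circ_std = circular_std_plane(sc, config$kernel))
    for (nm in config$per_scale_features) {
      i <- i + 1L
      planes[, , i] <- upsample_nn(per[[nm]], h, w)
      nms[i] <- sprintf("%s_s%g", nm, s)
    }
  }
  structure(list(planes = planes, names = nms, config = config),
            class = "feature_stack")
}

#' @export
print.feature_stack <- function(x, ...) {
  d <- dim(x$planes)
  cat(sprintf("feature_stack: %d planes, %d x %d px\n", d[3L], d[1L], d[2L]))
  invisible(x)
}

# features as an N x F matrix (pixels in column-major order)
feature_matrix <- function(fs) {
  d <- dim(fs$planes)
  m <- matrix(fs$planes, nrow = d[1L] * d[2L], ncol = d[3L])
  colnames(m) <- fs$names
  m
}
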