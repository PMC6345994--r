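# Spectrum-wise k-means information reduction and cluster images.
#
# All pixels of the flat-field corrected images are clustered in spectral
# space (Euclidean distance over the 25 band values); each pixel of the
# cluster image then encodes its cluster's intensity rank, turning the
# hyperspectral cube into a single ordinal channel that carries spectral
# category information.

# nearest-centroid assignment; ties broken toward the lowest cluster index
assign_nearest <- function(X, C) {
  cpp_assign_nearest(X, C)
}

# k-means++ seeding: first centroid uniform, then each new centroid sampled
# with probability proportional to squared distance to the nearest chosen one
kmeanspp_init <- function(X, k) {
  n <- nrow(X)
  rs <- rowSums(X^2)
  centers <- matrix(0, k, ncol(X))
  idx <- sample.int(n, 1L)
  centers[1L, ] <- X[idx, ]
  d2_to <- function(ctr) pmax(0, rs - 2 * drop(X %*% ctr) + sum(ctr^2))
  if (k > 1L) {
    d2 <- d2_to(centers[1L, ])
    for (j in 2:k) {
      tot <- sum(d2)
      idx <- if (tot <= 0) sample.int(n, 1L)
             else sample.int(n, 1L, prob = d2 / tot)
      centers[j, ] <- X[idx, ]
      d2 <- pmin(d2, d2_to(centers[j, ]))
    }
  }
  centers
}

#' Fit a spectral k-means model
#'
#' k-means with k-means++ seeding followed by a fixed number of Lloyd updates
#' (assign every spectrum to its nearest centroid by Euclidean distance, then
#' recompute centroids as cluster means). The update count is fixed at 30 by
#' default with no early exit; once converged, further updates are idempotent.
#' Clusters left empty by an update are re-seeded with the point currently
#' farthest from its centroid, so the cluster count stays exactly `k`.
#'
#' @param pixels N x B matrix of spectra (rows are pixels).
#' @param k Number of clusters (the evaluation default downstream is 32; the
#'   useful range on these images is 16--64).
#' @param n_iter Number of Lloyd updates (default 30).
#' @param seed Integer seed; the fit is deterministic given the seed.
#' @param wavelengths Optional band wavelengths stored with the model.
#' @return An object of class `cluster_model` with elements `centroids`
#'   (k x B), `k`, `n_iter`, `seed`, `wavelengths`, `inertia` (within-cluster
#'   sum of squares after each update).
#' @export
fit_kmeans <- function(pixels, k, n_iter = 30L, seed = 0L, wavelengths = NULL) {
  pixels <- as.matrix(pixels)
  if (nrow(pixels) == 0L) stop("empty input")
  if (!all(is.finite(pixels))) stop("spectra must be finite")
  if (nrow(pixels) < k) stop("need at least k spectra")
  with_seed(seed, {
    C0 <- kmeanspp_init(pixels, k)
    res <- cpp_kmeans_lloyd(pixels, C0, as.integer(n_iter))
    structure(list(centroids = res$centroids, k = as.integer(k),
                   n_iter = as.integer(n_iter), seed = as.integer(seed),
                   wavelengths = wavelengths, inertia = res$inertia),
              class = "cluster_model")
  })
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("cluster_model: k = %d, %d bands, %d updates, seed %d\n",
              x$k, ncol(x$centroids), x$n_iter, x$seed))
  cat(sprintf("  final within-cluster SS: %.6g\n", tail(x$inertia, 1L)))
  invisible(x)
}

#' Assign spectra to their nearest cluster
#'
#' @param object A fitted [fit_kmeans()] model.
#' @param pixels N x B matrix of spectra, or a corrected [hyper_stack()].
#' @param ... Unused.
#' @return Integer vector of cluster indices in `1..k` (ties go to the lowest
#'   index).
#' @export
predict.cluster_model <- function(object, pixels, ...) {
  if (inherits(pixels, "hyper_stack")) pixels <- stack_pixels(pixels)
  pixels <- as.matrix(pixels)
  if (ncol(pixels) != ncol(object$centroids)) {
    stop("spectra have ", ncol(pixels), " bands; model expects ",
         ncol(object$centroids))
  }
  assign_nearest(pixels, object$centroids)
}

# display value per cluster: rank clusters by centroid mean intensity
# (rank 0 = darkest) and scale linearly to 8 bits
cluster_display_values <- function(centroids) {
  k <- nrow(centroids)
  r <- rank(rowMeans(centroids), ties.method = "first") - 1
  if (k == 1L) return(0)
  round(r * 255 / (k - 1))
}

#' Build a cluster image from a corrected stack
#'
#' Each pixel is assigned to its nearest spectral cluster; the display channel
#' encodes the cluster's rank by centroid mean intensity over the bands
#' (rank 0 = darkest cluster), scaled linearly to 8 bits, so the single
#' channel is ordinal in brightness. Downstream feature extraction operates on
#' this display channel.
#'
#' @param model A [fit_kmeans()] model.
#' @param corrected A corrected [hyper_stack()] with exactly the model's bands.
#' @return Object of class `cluster_image`: `ids` (H x W cluster indices,
#'   1-based), `display` (H x W 8-bit values), `k`.
#' @export
make_cluster_image <- function(model, corrected) {
  stopifnot(inherits(model, "cluster_model"), inherits(corrected, "hyper_stack"))
  d <- dim(corrected$data)
  if (d[1L] != ncol(model$centroids)) {
    stop("stack has ", d[1L], " bands; model expects ", ncol(model$centroids))
  }
  ids <- matrix(predict(model, stack_pixels(corrected)), d[2L], d[3L])
  disp <- matrix(cluster_display_values(model$centroids)[ids], d[2L], d[3L])
  structure(list(ids = ids, display = disp, k = model$k),
            class = "cluster_image")
}

#' @export
print.cluster_image <- function(x, ...) {
  cat(sprintf("cluster_image: %d x %d px, k = %d\n",
              nrow(x$ids), ncol(x$ids), x$k))
  invisible(x)
}

#' Per-cluster mean spectra
#'
#' Mean and standard deviation of the corrected spectra over the member
#' pixels of each cluster, plus member counts. Empty clusters are reported
#' with zero count and zero mean/sd.
#'
#' @param model A [fit_kmeans()] model.
#' @param corrected Corrected [hyper_stack()].
#' @param cimg [make_cluster_image()] result for `corrected` (recomputed when
#'   omitted).
#' @return List with `mean` (k x B), `sd` (k x B), `count` (length k).
#' @export
cluster_mean_spectra <- function(model, corrected, cimg = NULL) {
  if (is.null(cimg)) cimg <- make_cluster_image(model, corrected)
  X <- stack_pixels(corrected)
  ids <- as.vector(cimg$ids)
  k <- model$k; B <- ncol(X)
  m <- matrix(0, k, B); s <- matrix(0, k, B); cnt <- integer(k)
  for (j in seq_len(k)) {
    rows <- ids == j
    cnt[j] <- sum(rows)
    if (cnt[j] > 0L) {
      Xi <- X[rows, , drop = FALSE]
      m[j, ] <- colMeans(Xi)
      # population sd over member pixels
      s[j, ] <- sqrt(pmax(0, colMeans(Xi^2) - m[j, ]^2))
    }
  }
  list(mean = m, sd = s, count = cnt)
}

#' Serialize / deserialize a cluster model as JSON
#'
#' @param model A [fit_kmeans()] model.
#' @param path File path.
#' @return `write_cluster_model` invisibly returns `path`;
#'   `read_cluster_model` returns the model.
#' @export
write_cluster_model <- function(model, path) {
  obj <- list(k = model$k, n_iter = model$n_iter, seed = model$seed,
              wavelengths_nm = model$wavelengths,
              centroids = model$centroids)
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = I(17), null = "null"),
             path)
  invisible(path)
}

#' @rdname write_cluster_model
#' @export
read_cluster_model <- function(path) {
  obj <- jsonlite::fromJSON(path)
  structure(list(centroids = as.matrix(obj$centroids), k = as.integer(obj$k),
                 n_iter = as.integer(obj$n_iter), seed = as.integer(obj$seed),
                 wavelengths = obj$wavelengths_nm, inertia = numeric(0)),
            class = "cluster_model")
}
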