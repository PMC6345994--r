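# Acquisition quality metrics: lateral two-point resolution under partially
# coherent illumination (Hopkins criterion) and illumination stability
# statistics (temporal fluctuation, spatial non-uniformity).

#' Optical configuration
#'
#' @param na_objective Objective numerical aperture (default 0.45, the
#'   manufacturer value for the 20x universal semi-apochromat used).
#' @param na_illumination Condenser/illumination numerical aperture (0.063 at
#'   the minimum iris aperture setting).
#' @param wavelength Wavelength in nm.
#' @return List of class `optical_config`.
#' @export
optical_config <- function(na_objective = 0.45, na_illumination = 0.063,
                           wavelength = 550) {
  if (na_objective <= 0 || na_objective >= 1.5) stop("invalid objective NA")
  if (na_illumination <= 0 || na_illumination > na_objective) {
    stop("need 0 < na_illumination <= na_objective")
  }
  structure(list(na_objective = na_objective,
                 na_illumination = na_illumination,
                 wavelength = wavelength),
            class = "optical_config")
}

#' Coherence ratio
#'
#' `sigma = NA_illumination / NA_objective`; sigma -> 0 is the coherent
#' limit, large sigma the incoherent limit.
#'
#' @param config An [optical_config()].
#' @return The coherence ratio.
#' @export
coherence_ratio <- function(config) {
  config$na_illumination / config$na_objective
}

# Hopkins two-point resolution factor A(sigma): constant 0.82 on the
# near-coherent plateau (sigma <= 0.2), decreasing toward the incoherent
# (Rayleigh, 0.61) limit; linear interpolation between table entries.
hopkins_table <- function() {
  list(sigma = c(0, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8, 0.9, 1.0, 1.25, 1.5, 2.0),
       A = c(0.82, 0.82, 0.80, 0.78, 0.76, 0.74, 0.72, 0.70, 0.68, 0.66,
             0.645, 0.63, 0.62))
}

#' Lateral resolution by Hopkins' two-point criterion
#'
#' `R = A(sigma) * lambda / NA_objective`, with the two-point factor
#' `A(sigma)` interpolated from the tabulated partially coherent resolution
#' curve (A = 0.82 on the coherent plateau sigma <= 0.2). With the default
#' optics (NA 0.45, illumination NA 0.063, sigma ~ 0.14) this gives 0.820,
#' 1.002 and 1.184 um at 450, 550 and 650 nm.
#'
#' @param config An [optical_config()].
#' @param wavelength Wavelength in nm (defaults to the config's), must lie
#'   in `[350, 900]`.
#' @return Resolution in micrometers.
#' @export
hopkins_resolution <- function(config = optical_config(),
                               wavelength = config$wavelength) {
  if (wavelength < 350 || wavelength > 900) stop("wavelength outside [350, 900] nm")
  sigma <- coherence_ratio(config)
  tab <- hopkins_table()
  if (sigma < min(tab$sigma) || sigma > max(tab$sigma)) {
    stop("coherence ratio outside tabulated range")
  }
  A <- stats::approx(tab$sigma, tab$A, xout = sigma)$y
  A * (wavelength / 1000) / config$na_objective
}

#' Temporal illumination fluctuation
#'
#' For repeated illumination images, computes each pixel's maximum absolute
#' deviation from its temporal mean as a percent of the global mean
#' intensity, and reports the fraction of pixels within each tolerance.
#'
#' @param images List of >= 2 matrices of identical shape.
#' @param tolerances Tolerances in percent (default `c(3, 4, 5)`).
#' @return List of class `stability_report`: `fluctuation_fractions` (named
#'   by tolerance), `max_deviation_percent` (per-pixel matrix).
#' @export
temporal_fluctuation <- function(images, tolerances = c(3, 4, 5)) {
  if (length(images) < 2L) stop("need at least 2 images")
  dims <- lapply(images, dim)
  if (!all(vapply(dims, identical, logical(1), dims[[1]]))) stop("shape mismatch")
  arr <- simplify2array(images)
  tm <- apply(arr, c(1, 2), mean)
  dev <- apply(abs(sweep(arr, c(1, 2), tm)), c(1, 2), max)
  gm <- mean(arr)
  pct <- dev / gm * 100
  fr <- vapply(tolerances, function(tol) mean(pct <= tol), numeric(1))
  structure(list(fluctuation_fractions = setNames(fr, tolerances),
                 max_deviation_percent = pct),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  fr <- x$fluctuation_fractions
  cat("temporal fluctuation: fraction of pixels within tolerance\n")
  for (i in seq_along(fr)) {
    cat(sprintf("  <= %s%%: %.1f%%\n", names(fr)[i], 100 * fr[i]))
  }
  invisible(x)
}

# 5x5 median filter with reflect padding, to suppress shot noise
median_filter5 <- function(img) {
  r <- 2L
  h <- nrow(img); w <- ncol(img)
  pad <- img[reflect_index(h, r), reflect_index(w, r), drop = FALSE]
  stackv <- matrix(0, h * w, 25L)
  k <- 0L
  for (dx in 0:(2L * r)) for (dy in 0:(2L * r)) {
    k <- k + 1L
    stackv[, k] <- as.vector(pad[(1L + dy):(h + dy), (1L + dx):(w + dx)])
  }
  matrix(apply(stackv, 1L, median), h, w)
}

#' Spatial non-uniformity of an illumination image
#'
#' Peak-to-peak intensity range over the field of view after 5x5 median
#' smoothing, as a percent of the mean intensity:
#' `(max - min) / mean * 100`.
#'
#' @param image Numeric matrix.
#' @return Non-uniformity in percent.
#' @export
spatial_nonuniformity <- function(image) {
  image <- as.matrix(image)
  if (length(image) == 0L) stop("empty image")
  m <- mean(image)
  if (m == 0) stop("zero mean intensity")
  sm <- median_filter5(image)
  (max(sm) - min(sm)) / m * 100
}
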