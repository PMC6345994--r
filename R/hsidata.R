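# Data model and I/O for hyperspectral stacks, dark/flat references and label
# maps, plus flat-field correction and band selection.

#' Validate a wavelength grid
#'
#' A wavelength grid is the ordered vector of band-center wavelengths (in nm)
#' attached to a hyperspectral stack. Grids must be strictly increasing and lie
#' in the visible/near-visible range covered by the instrument.
#'
#' @param wavelengths Numeric vector of band-center wavelengths in nm.
#' @return The validated numeric vector, invisibly usable as a grid.
#' @export
wavelength_grid <- function(wavelengths) {
  wavelengths <- as.numeric(wavelengths)
  if (length(wavelengths) < 1L) stop("wavelength grid must have length >= 1")
  if (any(!is.finite(wavelengths))) stop("wavelengths must be finite")
  if (any(wavelengths < 350 | wavelengths > 900)) {
    stop("wavelengths must lie in [350, 900] nm")
  }
  if (any(diff(wavelengths) <= 0)) stop("wavelengths must be strictly increasing")
  wavelengths
}

#' Construct a hyperspectral stack
#'
#' A stack is a bands x height x width cube of non-negative intensities with an
#' explicit wavelength grid and a role: `"raw_object"` (O), `"dark"` (D),
#' `"flat"` (F) or `"corrected"` (the flat-field corrected image, FFC). Raw,
#' dark and flat stacks hold integer camera counts (12--16 bit range);
#' corrected stacks hold non-negative reals on the transmittance scale.
#'
#' @param data Numeric array with dim `c(bands, height, width)`.
#' @param wavelengths Band-center wavelengths in nm, one per band.
#' @param role One of `"raw_object"`, `"dark"`, `"flat"`, `"corrected"`.
#' @param invalid Optional height x width logical matrix flagging pixels whose
#'   flat-field denominator was non-positive (see [flat_field_correct()]).
#' @return An object of class `hyper_stack`.
#' @export
hyper_stack <- function(data, wavelengths,
                        role = c("raw_object", "dark", "flat", "corrected"),
                        invalid = NULL) {
  role <- match.arg(role)
  wavelengths <- wavelength_grid(wavelengths)
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("data must be a 3-d array (bands x height x width)")
  }
  d <- dim(data)
  if (d[1L] != length(wavelengths)) {
    stop(sprintf("number of bands (%d) does not match wavelength count (%d)",
                 d[1L], length(wavelengths)))
  }
  if (d[2L] < 1L || d[3L] < 1L) stop("image dimensions must be >= 1")
  if (role != "corrected" && any(data < 0)) {
    stop("raw/dark/flat intensities must be non-negative")
  }
  if (!is.null(invalid)) {
    stopifnot(is.logical(invalid), all(dim(invalid) == d[2:3]))
  }
  structure(list(data = data, wavelengths = wavelengths, role = role,
                 invalid = invalid),
            class = "hyper_stack")
}

#' @export
print.hyper_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("hyper_stack: %d bands x %d x %d px, role '%s'\n",
              d[1L], d[2L], d[3L], x$role))
  cat(sprintf("  wavelengths: %g..%g nm\n", min(x$wavelengths), max(x$wavelengths)))
  if (!is.null(x$invalid) && any(x$invalid)) {
    cat(sprintf("  invalid pixels: %d\n", sum(x$invalid)))
  }
  invisible(x)
}

#' @export
dim.hyper_stack <- function(x) dim(x$data)

# Pixels of a stack as an N x bands matrix, N = H*W in column-major pixel order.
stack_pixels <- function(stack) {
  d <- dim(stack$data)
  t(matrix(stack$data, nrow = d[1L]))
}

sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), ".json")

#' Write a hyperspectral stack to a multi-page TIFF with JSON sidecar
#'
#' One TIFF page per band. Raw, dark and flat stacks are stored as 16-bit
#' unsigned integers; corrected stacks as 32-bit samples after division by a
#' power-of-two scale recorded in the sidecar, so corrected values round-trip
#' with a relative quantization error below 1e-9 (32-bit resolution). The
#' sidecar JSON records the role and the wavelength grid.
#'
#' @param stack A [hyper_stack()].
#' @param path Output TIFF path; the sidecar is written next to it with a
#'   `.json` extension.
#' @param metadata_path Optional explicit sidecar path.
#' @return Invisibly, the sidecar path.
#' @export
write_stack <- function(stack, path, metadata_path = sidecar_path(path)) {
  stopifnot(inherits(stack, "hyper_stack"))
  d <- dim(stack$data)
  if (d[1L] < 1L) stop("stack has no bands")
  pages <- lapply(seq_len(d[1L]), function(b) matrix(stack$data[b, , ], d[2L], d[3L]))
  meta <- list(role = stack$role, wavelengths_nm = stack$wavelengths)
  if (stack$role == "corrected") {
    mx <- max(1, max(stack$data))
    scale <- 2^ceiling(log2(mx))
    meta$scale <- scale
    pages <- lapply(pages, function(p) p / scale)
    tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  } else {
    if (max(stack$data) > 65535) stop("raw counts exceed 16-bit range")
    pages <- lapply(pages, function(p) p / 65535)
    tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  }
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = I(17)), metadata_path)
  invisible(metadata_path)
}

#' Read a hyperspectral stack written by [write_stack()]
#'
#' @param path Multi-page TIFF path.
#' @param metadata_path JSON sidecar path (defaults to `path` with `.json`).
#' @return A [hyper_stack()]. Errors if the page count does not match the
#'   sidecar wavelength count or the wavelengths are not strictly increasing.
#' @export
read_stack <- function(path, metadata_path = sidecar_path(path)) {
  meta <- jsonlite::fromJSON(metadata_path)
  wl <- wavelength_grid(meta$wavelengths_nm)
  raw_role <- !identical(meta$role, "corrected")
  pages <- tiff::readTIFF(path, all = TRUE, as.is = raw_role)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) != length(wl)) {
    stop(sprintf("page count (%d) does not match wavelength count (%d)",
                 length(pages), length(wl)))
  }
  h <- nrow(pages[[1L]]); w <- ncol(pages[[1L]])
  data <- array(0, dim = c(length(pages), h, w))
  for (b in seq_along(pages)) {
    p <- pages[[b]]
    if (!raw_role) p <- p * meta$scale
    data[b, , ] <- p
  }
  hyper_stack(data, wl, role = meta$role)
}

#' Write / read a class-coded label map
#'
#' Label maps are height x width matrices of class codes: 0 external region,
#' 1 neuronal cell body, 2 glial cell body, 3 process, 255 ignore (pixels
#' excluded from training and evaluation). Stored as 8-bit grayscale PNG.
#'
#' @param labels Integer matrix of class codes.
#' @param path PNG file path.
#' @return `write_label_map` invisibly returns `path`; `read_label_map`
#'   returns the validated label matrix.
#' @export
write_label_map <- function(labels, path) {
  labels <- validate_labels(labels)
  png::writePNG(labels / 255, path)
  invisible(path)
}

#' @rdname write_label_map
#' @export
read_label_map <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  validate_labels(round(img * 255))
}

validate_labels <- function(labels) {
  labels <- as.matrix(labels)
  storage.mode(labels) <- "integer"
  bad <- setdiff(unique(as.vector(labels)), c(0L, 1L, 2L, 3L, 255L))
  if (length(bad)) stop("invalid label codes: ", paste(bad, collapse = ", "))
  labels
}

#' Flat-field correction
#'
#' Computes the flat-field corrected stack FFC = (O - D) / (F - D) per pixel
#' and per band, from a raw object image O, a dark image D (light path
#' shuttered) and a flat-field reference image F (illumination without a
#' specimen). The correction removes both the sensor dark offset and the
#' spatial non-uniformity of the illumination.
#'
#' Pixels where F - D <= 0 in any band (possible for isolated pixels under
#' sensor noise) cannot be corrected: their value is set to 0 in the affected
#' bands and the pixel is flagged in the result's `invalid` mask, which
#' downstream training/evaluation treats like the ignore label.
#'
#' @param O,D,F [hyper_stack()] objects with roles `"raw_object"`, `"dark"`
#'   and `"flat"`, sharing shape and wavelength grid.
#' @return A `hyper_stack` with role `"corrected"` and an `invalid` mask.
#' @export
flat_field_correct <- function(O, D, F) {
  stopifnot(inherits(O, "hyper_stack"), inherits(D, "hyper_stack"),
            inherits(F, "hyper_stack"))
  if (!identical(dim(O$data), dim(D$data)) || !identical(dim(O$data), dim(F$data))) {
    stop("O, D, F must share the same shape")
  }
  if (!isTRUE(all.equal(O$wavelengths, D$wavelengths)) ||
      !isTRUE(all.equal(O$wavelengths, F$wavelengths))) {
    stop("O, D, F must share the same wavelength grid")
  }
  denom <- F$data - D$data
  bad <- denom <= 0
  ffc <- (O$data - D$data) / denom
  ffc[bad] <- 0
  invalid <- apply(bad, c(2L, 3L), any)
  n_inv <- sum(invalid)
  if (n_inv > 0L) {
    message(sprintf("flat_field_correct: %d pixel(s) with F - D <= 0 flagged invalid", n_inv))
  }
  hyper_stack(ffc, O$wavelengths, role = "corrected", invalid = invalid)
}

#' Select a subset of bands by wavelength
#'
#' Extracts the requested wavelengths (exact integer-nm matches; no
#' interpolation) from a stack, in the requested order. The classification
#' pipeline uses the 25 bands from 450 to 690 nm at a 10-nm pitch out of the
#' 63 acquired bands.
#'
#' @param stack A [hyper_stack()].
#' @param requested Numeric vector of wavelengths in nm; each must be present
#'   in the stack's grid.
#' @return A `hyper_stack` restricted to the requested bands.
#' @export
select_bands <- function(stack, requested) {
  stopifnot(inherits(stack, "hyper_stack"))
  requested <- wavelength_grid(requested)
  idx <- match(requested, stack$wavelengths)
  if (anyNA(idx)) {
    stop("wavelength(s) not present in stack: ",
         paste(requested[is.na(idx)], collapse = ", "), " nm")
  }
  hyper_stack(stack$data[idx, , , drop = FALSE], requested, role = stack$role,
              invalid = stack$invalid)
}
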