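# Seeded generator of synthetic hyperspectral scenes with ground truth,
# emulating transmission images of differentiated neural stem cell cultures:
# elliptical cell bodies with a bright center zone and a darker edge band,
# thin processes attached to the bodies, a smooth illumination field, a dark
# offset and additive sensor noise.

#' Default spectral signature bank
#'
#' Six 25-band spectral signatures on the flat-field-corrected (transmittance)
#' scale, covering the subcellular spectral structure of the four pixel
#' classes: neuronal cell bodies carry a high-intensity center spectrum
#' (`N_high`) and a low-intensity edge spectrum (`N_low`); glial cell bodies
#' likewise (`G_high`, `G_low`), with the glial center spectrum rising toward
#' long wavelengths relative to the process spectrum (`P_process`); the
#' external region (`E_external`) is flat near 1.
#'
#' @param wavelengths Band centers in nm (default 450--690 at 10 nm).
#' @return Numeric matrix, one row per signature, one column per band.
#' @export
signature_bank <- function(wavelengths = seq(450, 690, by = 10)) {
  t <- (wavelengths - min(wavelengths)) / diff(range(wavelengths))
  bank <- rbind(
    N_high     = 1.45 - 0.10 * (t - 0.5),
    N_low      = 0.55 + 0.05 * (t - 0.5),
    G_high     = 0.95 + 0.50 * t,
    G_low      = 0.68 + 0.04 * (t - 0.5),
    P_process  = 0.84 - 0.06 * t,
    E_external = 1.00 + 0.02 * (t - 0.5))
  colnames(bank) <- wavelengths
  bank
}

#' Scene generator configuration
#'
#' Parameters of a synthetic hyperspectral scene. Defaults emulate the study
#' conditions: 25 bands (450--690 nm), a few neurons and glia per field with
#' processes, 10% peak-to-peak smooth illumination non-uniformity (within the
#' 3.5--14.1% range observed on the instrument), a dark offset, and additive
#' Gaussian sensor noise of 2% of the dynamic range.
#'
#' @param height,width Scene size in pixels (>= 64).
#' @param n_neurons,n_glia Number of neuronal / glial cell bodies.
#' @param body_radius Range (px) of body semi-axes.
#' @param edge_band Width (px) of the low-intensity edge zone of a body.
#' @param processes_per_body Range of process count per body.
#' @param process_width Range (px) of process thickness.
#' @param process_length Range (steps) of process random-walk length.
#' @param illum_amplitude Peak-to-peak amplitude of the smooth multiplicative
#'   illumination field, as a fraction of its mean.
#' @param dark_level,flat_level Dark offset and flat-field level in camera
#'   counts; `flat_level > dark_level`.
#' @param noise_sd Additive Gaussian noise s.d. in counts (applied to object,
#'   dark and flat frames; clipped at 0).
#' @param ignore_fraction Fraction of the scene area covered by an injected
#'   ignore-labeled (code 255) rectangle, to exercise masking paths.
#' @param seed Integer seed; scenes are deterministic given the seed.
#' @return A list of class `scene_config`.
#' @export
scene_config <- function(height = 256, width = 256,
                         n_neurons = 4, n_glia = 2,
                         body_radius = c(10, 18), edge_band = 3,
                         processes_per_body = c(1, 3),
                         process_width = c(2, 3), process_length = c(30, 70),
                         illum_amplitude = 0.10,
                         dark_level = 100, flat_level = 3100,
                         noise_sd = 0.02 * (flat_level - dark_level),
                         ignore_fraction = 0, seed = 1) {
  cfg <- list(height = as.integer(height), width = as.integer(width),
              n_neurons = as.integer(n_neurons), n_glia = as.integer(n_glia),
              body_radius = body_radius, edge_band = edge_band,
              processes_per_body = as.integer(processes_per_body),
              process_width = process_width, process_length = process_length,
              illum_amplitude = illum_amplitude,
              dark_level = dark_level, flat_level = flat_level,
              noise_sd = noise_sd, ignore_fraction = ignore_fraction,
              seed = as.integer(seed))
  if (cfg$height < 64 || cfg$width < 64) stop("scene dimensions must be >= 64")
  if (cfg$flat_level <= cfg$dark_level) stop("flat_level must exceed dark_level")
  if (cfg$n_neurons < 0 || cfg$n_glia < 0 || cfg$noise_sd < 0) {
    stop("counts and noise_sd must be >= 0")
  }
  class(cfg) <- "scene_config"
  cfg
}

# Evaluate an expression with a temporary RNG seed, restoring global state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Smooth multiplicative illumination field with given peak-to-peak amplitude;
# random low-order polynomial in normalized coordinates, mid-value 1.
make_illumination <- function(h, w, amplitude) {
  a <- runif(5, -1, 1)
  X <- matrix(rep((seq_len(w) - 0.5) / w - 0.5, each = h), h, w)
  Y <- matrix(rep((seq_len(h) - 0.5) / h - 0.5, times = w), h, w)
  base <- a[1] * X + a[2] * Y + a[3] * X * Y + a[4] * X^2 + a[5] * Y^2
  rng <- diff(range(base))
  if (rng < 1e-12 || amplitude == 0) return(matrix(1, h, w))
  1 + amplitude * (base - (max(base) + min(base)) / 2) / rng
}

#' Generate a synthetic hyperspectral scene
#'
#' Places non-overlapping elliptical cell bodies (neuronal and glial), each
#' with a high-signature center and a low-signature edge band, attaches
#' widened random-walk processes (class 3, one spectral signature regardless
#' of parent type), and renders raw object (O), dark (D) and flat (F) count
#' stacks: `O = round(signature x illumination x (flat - dark) + dark + noise)`,
#' `F = round(dark + illumination x (flat - dark) + noise)`,
#' `D = round(dark + noise)`, all clipped at 0. Flat-field correction of the
#' result recovers the signatures (exactly, up to count rounding, when
#' `noise_sd = 0`).
#'
#' @param config A [scene_config()].
#' @param bank Signature bank matrix (rows `N_high`, `N_low`, `G_high`,
#'   `G_low`, `P_process`, `E_external`).
#' @return A list of class `hs_scene` with elements `object`, `dark`, `flat`
#'   ([hyper_stack()]s), `truth` (list with `labels` matrix and `objects`,
#'   each object a list `id`, `class`, `pixels` of linear indices), and
#'   `illumination` (the field used).
#' @export
generate_scene <- function(config, bank = signature_bank()) {
  stopifnot(inherits(config, "scene_config"))
  wl <- as.numeric(colnames(bank))
  n_bands <- ncol(bank)
  h <- config$height; w <- config$width
  with_seed(config$seed, {
    field <- make_illumination(h, w, config$illum_amplitude)
    labels <- matrix(0L, h, w)
    sig_idx <- matrix(6L, h, w)  # E_external
    objects <- list()
    next_id <- 1L

    classes <- c(rep(1L, config$n_neurons), rep(2L, config$n_glia))
    rmax <- max(config$body_radius)
    for (cls in classes) {
      placed <- FALSE
      for (attempt in seq_len(200L)) {
        rx <- runif(1, config$body_radius[1], config$body_radius[2])
        ry <- runif(1, config$body_radius[1], config$body_radius[2])
        phi <- runif(1, 0, pi)
        cx <- runif(1, rmax + 2, w - rmax - 2)
        cy <- runif(1, rmax + 2, h - rmax - 2)
        xs <- seq_len(w); ys <- seq_len(h)
        DX <- matrix(rep(xs - cx, each = h), h, w)
        DY <- matrix(rep(ys - cy, times = w), h, w)
        U <- (DX * cos(phi) + DY * sin(phi)) / rx
        V <- (-DX * sin(phi) + DY * cos(phi)) / ry
        d2 <- U^2 + V^2
        inside <- d2 <= 1
        if (any(labels[inside] != 0L)) next
        shrink <- max(0, 1 - config$edge_band / min(rx, ry))
        center <- d2 <= shrink^2
        labels[inside] <- cls
        sig_hi <- if (cls == 1L) 1L else 3L
        sig_lo <- if (cls == 1L) 2L else 4L
        sig_idx[inside] <- sig_lo
        sig_idx[center] <- sig_hi
        objects[[next_id]] <- list(id = next_id, class = cls,
                                   pixels = which(inside),
                                   center = c(cx, cy), radii = c(rx, ry),
                                   phi = phi)
        next_id <- next_id + 1L
        placed <- TRUE
        break
      }
      if (!placed) stop("could not place a cell body within the retry limit")
    }

    # processes: widened random walks growing outward from body boundaries
    body_objs <- objects
    for (obj in body_objs) {
      np <- sample(seq(config$processes_per_body[1], config$processes_per_body[2]), 1L)
      for (p in seq_len(np)) {
        theta <- runif(1, 0, 2 * pi)
        rx <- obj$radii[1]; ry <- obj$radii[2]; phi <- obj$phi
        # boundary point of the ellipse at parameter theta
        bx <- obj$center[1] + rx * cos(theta) * cos(phi) - ry * sin(theta) * sin(phi)
        by <- obj$center[2] + rx * cos(theta) * sin(phi) + ry * sin(theta) * cos(phi)
        dir <- atan2(by - obj$center[2], bx - obj$center[1])
        len <- round(runif(1, config$process_length[1], config$process_length[2]))
        wid <- runif(1, config$process_width[1], config$process_width[2])
        r <- wid / 2
        px <- bx; py <- by
        pix <- integer(0)
        for (s in seq_len(len)) {
          px <- px + cos(dir); py <- py + sin(dir)
          dir <- dir + rnorm(1, 0, 0.25)
          if (px < 2 || px > w - 1 || py < 2 || py > h - 1) break
          x0 <- max(1L, floor(px - r)); x1 <- min(w, ceiling(px + r))
          y0 <- max(1L, floor(py - r)); y1 <- min(h, ceiling(py + r))
          for (x in x0:x1) for (y in y0:y1) {
            if ((x - px)^2 + (y - py)^2 <= r^2 && labels[y, x] == 0L) {
              pix <- c(pix, y + (x - 1L) * h)
            }
          }
        }
        pix <- unique(pix)
        if (length(pix) >= 5L) {
          labels[pix] <- 3L
          sig_idx[pix] <- 5L
          objects[[next_id]] <- list(id = next_id, class = 3L, pixels = pix)
          next_id <- next_id + 1L
        }
      }
    }

    if (config$ignore_fraction > 0) {
      area <- config$ignore_fraction * h * w
      side <- max(2L, round(sqrt(area)))
      x0 <- sample.int(max(1L, w - side), 1L)
      y0 <- sample.int(max(1L, h - side), 1L)
      labels[y0:(y0 + side - 1L), x0:(x0 + side - 1L)] <- 255L
      ignored <- which(labels == 255L)
      objects <- lapply(objects, function(o) {
        o$pixels <- setdiff(o$pixels, ignored); o
      })
      objects <- Filter(function(o) length(o$pixels) > 0L, objects)
    }

    # render count stacks
    dyn <- config$flat_level - config$dark_level
    spec <- signature_bank_matrix(bank, sig_idx)  # N x bands
    fv <- as.vector(field)
    n_px <- h * w
    O <- array(0, dim = c(n_bands, h, w))
    D <- array(0, dim = c(n_bands, h, w))
    F <- array(0, dim = c(n_bands, h, w))
    for (b in seq_len(n_bands)) {
      ob <- spec[, b] * fv * dyn + config$dark_level
      fb <- config$dark_level + fv * dyn
      db <- rep(config$dark_level, n_px)
      if (config$noise_sd > 0) {
        ob <- ob + rnorm(n_px, 0, config$noise_sd)
        fb <- fb + rnorm(n_px, 0, config$noise_sd)
        db <- db + rnorm(n_px, 0, config$noise_sd)
      }
      O[b, , ] <- matrix(pmax(0, round(ob)), h, w)
      F[b, , ] <- matrix(pmax(0, round(fb)), h, w)
      D[b, , ] <- matrix(pmax(0, round(db)), h, w)
    }

    structure(list(
      object = hyper_stack(O, wl, role = "raw_object"),
      dark = hyper_stack(D, wl, role = "dark"),
      flat = hyper_stack(F, wl, role = "flat"),
      truth = list(labels = labels,
                   objects = lapply(objects, function(o)
                     list(id = o$id, class = o$class, pixels = o$pixels))),
      illumination = field,
      config = config), class = "hs_scene")
  })
}

# rows of `bank` picked per pixel, as an N x bands matrix
signature_bank_matrix <- function(bank, sig_idx) {
  bank[as.vector(sig_idx), , drop = FALSE]
}

#' Generate a dataset of synthetic scenes
#'
#' Generates `n_images` scenes with seeds `base_seed`, `base_seed + 1`, ...;
#' every scene is guaranteed to contain at least one neuron and one glial
#' cell (the study's images each contained at least one cell of each marker).
#'
#' @param n_images Number of scenes (>= 2, as needed for cross-validation).
#' @param base_config A [scene_config()] whose `n_neurons` and `n_glia` are
#'   both >= 1.
#' @param base_seed Seed of the first scene.
#' @return List of `hs_scene` objects.
#' @export
generate_dataset <- function(n_images, base_config = scene_config(),
                             base_seed = base_config$seed) {
  if (n_images < 2) stop("n_images must be >= 2")
  if (base_config$n_neurons < 1 || base_config$n_glia < 1) {
    stop("every scene must contain at least one neuron and one glial cell")
  }
  lapply(seq_len(n_images), function(i) {
    cfg <- base_config
    cfg$seed <- as.integer(base_seed + i - 1L)
    generate_scene(cfg)
  })
}
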