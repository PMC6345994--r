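# Small scene configurations shared across tests; scenes are generated in
# code (no stored fixtures) and kept small so the suite stays fast.

small_config <- function(seed = 3, noise_sd = 30, illum_amplitude = 0.1, ...) {
  scene_config(height = 96, width = 96, n_neurons = 2, n_glia = 1,
               body_radius = c(7, 11), process_length = c(20, 40),
               noise_sd = noise_sd, illum_amplitude = illum_amplitude,
               seed = seed, ...)
}

clean_config <- function(seed = 3, ...) {
  # no noise, flat illumination: FFC recovers signatures up to count rounding
  small_config(seed = seed, noise_sd = 0, illum_amplitude = 0, ...)
}

# connected components of a logical mask (8-connectivity), as an oracle for
# object counts; simple stack-based flood fill
count_components <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  seen <- matrix(FALSE, h, w)
  n <- 0L
  for (start in which(mask & !seen)) {
    if (seen[start]) next
    n <- n + 1L
    stack <- start
    seen[start] <- TRUE
    while (length(stack)) {
      cur <- stack[length(stack)]
      stack <- stack[-length(stack)]
      y <- (cur - 1L) %% h + 1L
      x <- (cur - 1L) %/% h + 1L
      for (dy in -1:1) for (dx in -1:1) {
        yy <- y + dy; xx <- x + dx
        if (yy >= 1L && yy <= h && xx >= 1L && xx <= w) {
          id <- yy + (xx - 1L) * h
          if (mask[id] && !seen[id]) {
            seen[id] <- TRUE
            stack <- c(stack, id)
          }
        }
      }
    }
  }
  n
}

# pixel matrix of a stack (exported helper mirror for tests)
px_of <- function(stack) {
  d <- dim(stack$data)
  t(matrix(stack$data, nrow = d[1]))
}
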