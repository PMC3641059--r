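# Brute-force oracles, kept deliberately naive and independent of the
# package's vectorized/compiled implementations.

# Per-pixel double-loop local mean with reflective borders.
naive_local_mean <- function(image, radius, window = "disk") {
  r <- floor(radius)
  refl <- function(n) {
    i <- seq(1 - r, n + r)
    while (any(i < 1 | i > n)) {
      i <- ifelse(i < 1, 2 - i, i)
      i <- ifelse(i > n, 2 * n - i, i)
    }
    i
  }
  pad <- image[refl(nrow(image)), refl(ncol(image))]
  out <- matrix(0, nrow(image), ncol(image))
  for (ii in seq_len(nrow(image))) for (jj in seq_len(ncol(image))) {
    s <- 0; cnt <- 0
    for (di in -r:r) for (dj in -r:r) {
      if (window == "disk" && di^2 + dj^2 > radius^2) next
      s <- s + pad[ii + r + di, jj + r + dj]
      cnt <- cnt + 1
    }
    out[ii, jj] <- s / cnt
  }
  out
}

naive_local_threshold <- function(image, radius, offset, window = "disk") {
  image > naive_local_mean(image, radius, window) + offset
}

# Direct grayscale opening with an explicit ball structuring element
# (min-then-max over the ball support, border treated as +/-Inf).
naive_ball_open <- function(image, radius) {
  r <- floor(radius)
  off <- expand.grid(dr = -r:r, dc = -r:r)
  off <- off[off$dr^2 + off$dc^2 <= radius^2, ]
  off$h <- sqrt(radius^2 - off$dr^2 - off$dc^2)
  h <- nrow(image); w <- ncol(image)
  er <- matrix(Inf, h, w)
  for (ii in seq_len(h)) for (jj in seq_len(w)) {
    for (k in seq_len(nrow(off))) {
      i2 <- ii + off$dr[k]; j2 <- jj + off$dc[k]
      v <- if (i2 >= 1 && i2 <= h && j2 >= 1 && j2 <= w)
        image[i2, j2] - off$h[k] else Inf
      if (v < er[ii, jj]) er[ii, jj] <- v
    }
  }
  di <- matrix(-Inf, h, w)
  for (ii in seq_len(h)) for (jj in seq_len(w)) {
    for (k in seq_len(nrow(off))) {
      i2 <- ii - off$dr[k]; j2 <- jj - off$dc[k]
      v <- if (i2 >= 1 && i2 <= h && j2 >= 1 && j2 <= w)
        er[i2, j2] + off$h[k] else -Inf
      if (v > di[ii, jj]) di[ii, jj] <- v
    }
  }
  di
}

# Small, fast field configuration for image-level tests.
test_field_config <- function(...) {
  sim_field_config(field_shape = c(128L, 128L), n_cells = 4, ...)
}

# Welch formulas transcribed from the textbook definition, step by step.
textbook_welch <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  m1 <- sum(x) / n1; m2 <- sum(y) / n2
  v1 <- sum((x - m1)^2) / (n1 - 1)
  v2 <- sum((y - m2)^2) / (n2 - 1)
  t <- (m1 - m2) / sqrt(v1 / n1 + v2 / n2)
  df <- (v1 / n1 + v2 / n2)^2 /
    ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  list(t = t, df = df, p = 1 - pt(t, df))
}
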