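# Independent oracles, kept deliberately separate from the package's
# Jones-calculus implementation.

# Mueller matrix of a linear retarder, fast axis at theta, retardance delta
mueller_retarder <- function(delta, theta) {
  C <- cos(2 * theta); S <- sin(2 * theta)
  cd <- cos(delta); sd_ <- sin(delta)
  matrix(c(1, 0, 0, 0,
           0, C^2 + S^2 * cd, C * S * (1 - cd), -S * sd_,
           0, C * S * (1 - cd), S^2 + C^2 * cd, C * sd_,
           0, S * sd_, -C * sd_, cd),
         4, 4, byrow = TRUE)
}

# intensity behind an ideal linear analyzer at angle alpha
mueller_analyzer_intensity <- function(stokes, alpha) {
  0.5 * (stokes[1] + stokes[2] * cos(2 * alpha) + stokes[3] * sin(2 * alpha))
}

# full Mueller-calculus prediction of the four channel intensities for a
# uniform retarder under circular illumination (S = (I, 0, 0, s3*I)).
# With the Stokes convention S3 = 2*Im(Ex*Conj(Ey)), the package's
# illumination Jones vector (1, i)/sqrt(2) has s3 = -1.
mueller_channels <- function(delta, theta, intensity = 1, s3 = -1) {
  s_in <- c(intensity, 0, 0, s3 * intensity)
  s_out <- mueller_retarder(delta, theta) %*% s_in
  vapply(c(0, 45, 90, 135) * pi / 180,
         function(a) mueller_analyzer_intensity(s_out, a), 0)
}

# brute-force maximum pairwise distance over convex-hull vertices
brute_hull_max <- function(mask) {
  v <- mask_hull_points(mask)
  best <- 0
  for (i in seq_len(nrow(v)))
    best <- max(best, sqrt(rowSums(sweep(v, 2, v[i, ])^2)))
  best
}

# random blob mask: union of a few overlapping discs, reproducible
random_blob <- function(seed, n = 24) {
  set.seed(seed)
  k <- sample(2:4, 1)
  cx <- runif(k, n * 0.3, n * 0.7); cy <- runif(k, n * 0.3, n * 0.7)
  r <- runif(k, 2, n * 0.18)
  X <- matrix(seq_len(n), n, n, byrow = TRUE)
  Y <- matrix(seq_len(n), n, n)
  m <- matrix(FALSE, n, n)
  for (j in seq_len(k)) m <- m | ((X - cx[j])^2 + (Y - cy[j])^2 <= r[j]^2)
  if (!any(m)) m[round(n / 2), round(n / 2)] <- TRUE
  m
}

# axis-aligned filled rectangle mask with margins
rect_mask <- function(h, w, pad = 5) {
  m <- matrix(FALSE, h + 2 * pad, w + 2 * pad)
  m[(pad + 1):(pad + h), (pad + 1):(pad + w)] <- TRUE
  m
}

# rasterized disc of radius r
disc_mask <- function(r, pad = 5) {
  n <- 2 * ceiling(r) + 2 * pad + 1
  cc <- (n + 1) / 2
  X <- matrix(seq_len(n), n, n, byrow = TRUE)
  Y <- matrix(seq_len(n), n, n)
  (X - cc)^2 + (Y - cc)^2 <= r^2
}

# band-limited random complex field for propagation tests
bandlimited_field <- function(n, pitch, wavelength, seed = 1, keep = 0.25) {
  set.seed(seed)
  g <- matrix(complex(real = stats::rnorm(n^2),
                      imaginary = stats::rnorm(n^2)), n, n)
  G <- stats::fft(g)
  f <- fft_freq_axis(n, pitch)
  ok <- outer((wavelength * f)^2, (wavelength * f)^2, "+") < keep
  G[!ok] <- 0
  complex_field(stats::fft(G, inverse = TRUE) / n^2, pitch, wavelength)
}
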