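#' Sampled complex optical field
#'
#' @param values complex (or numeric) matrix of field samples; rows index
#'   y, columns index x.
#' @param pitch sample spacing in metres.
#' @param wavelength wavelength in metres.
#' @return An object of class `complex_field`.
#' @export
complex_field <- function(values, pitch, wavelength) {
  stopifnot(is.matrix(values), pitch > 0, wavelength > 0)
  if (!is.complex(values)) storage.mode(values) <- "complex"
  if (any(!is.finite(Re(values)) | !is.finite(Im(values))))
    stop("complex_field values must be finite")
  structure(list(values = values, pitch = pitch, wavelength = wavelength),
            class = "complex_field")
}

#' Hologram intensity from interfering waves
#'
#' Intensity of the coherent superposition of an object wave and a
#' reference wave, `I = |U_R + U_O|^2`, the sum of the two self terms and
#' the cross terms that encode the object phase.
#'
#' @param u_o object-wave [complex_field()].
#' @param u_r reference-wave [complex_field()] on the same grid.
#' @return Real non-negative intensity matrix.
#' @export
form_hologram <- function(u_o, u_r) {
  stopifnot(inherits(u_o, "complex_field"), inherits(u_r, "complex_field"))
  if (!identical(dim(u_o$values), dim(u_r$values)) ||
      u_o$pitch != u_r$pitch || u_o$wavelength != u_r$wavelength)
    stop("object and reference waves must share grid, pitch and wavelength")
  Mod(u_r$values + u_o$values)^2
}

#' Suppress the undiffracted (DC) term of a hologram
#'
#' In-line holograms carry a large zero-order background. `mean_subtract`
#' removes the spatial mean; `freq_notch` multiplies the spectrum by an
#' inverted Gaussian centred on zero frequency.
#'
#' @param h real intensity matrix.
#' @param method `"mean_subtract"` or `"freq_notch"`.
#' @param notch_radius Gaussian notch radius in frequency bins
#'   (freq_notch only).
#' @return Real matrix of the same shape.
#' @export
suppress_dc <- function(h, method = c("mean_subtract", "freq_notch"),
                        notch_radius = 2) {
  stopifnot(is.matrix(h), is.numeric(h))
  method <- match.arg(method)
  if (method == "mean_subtract") return(h - mean(h))
  ny <- nrow(h); nx <- ncol(h)
  ky <- fft_freq_axis(ny, 1)   # in cycles/sample, bin spacing 1/ny
  kx <- fft_freq_axis(nx, 1)
  r2 <- outer((ky * ny)^2, (kx * nx)^2, "+")  # bins from origin, squared
  notch <- 1 - exp(-r2 / (2 * notch_radius^2))
  Re(stats::fft(stats::fft(h) * notch, inverse = TRUE)) / length(h)
}

#' Discrete frequency axis for an FFT grid
#'
#' Frequencies in cycles per metre for `n` samples at spacing `pitch`,
#' ordered with the zero-frequency sample first (array-origin
#' convention, matching [stats::fft()]).
#'
#' @param n number of samples.
#' @param pitch sample spacing in metres.
#' @return Numeric vector of length `n`.
#' @export
fft_freq_axis <- function(n, pitch) {
  k <- c(seq.int(0L, floor((n - 1) / 2)), seq.int(-floor(n / 2), -1L))
  k / (n * pitch)
}

#' Angular-spectrum propagation of a complex field
#'
#' Propagates a sampled field over axial distance `z` by multiplying its
#' 2-D spectrum with the exact free-space kernel
#' `exp(-i * 2*pi*z/lambda * sqrt(1 - lambda^2 fx^2 - lambda^2 fy^2))`.
#' Evanescent components (`1 - lambda^2 f^2 < 0`) are hard-zeroed, which
#' keeps the kernel bounded for any `z`. Negative `z` back-propagates.
#'
#' @param field a [complex_field()] of at least 16x16 samples.
#' @param z propagation distance in metres (signed).
#' @return The propagated [complex_field()].
#' @export
angular_spectrum_propagate <- function(field, z) {
  stopifnot(inherits(field, "complex_field"))
  if (!is.numeric(z) || !is.finite(z)) stop("z must be a finite number")
  v <- field$values
  if (nrow(v) < 16 || ncol(v) < 16) stop("field grid must be at least 16x16")
  kern <- as_kernel(nrow(v), ncol(v), field$pitch, field$wavelength, z)
  out <- stats::fft(stats::fft(v) * kern, inverse = TRUE) / length(v)
  complex_field(out, field$pitch, field$wavelength)
}

# angular-spectrum kernel matrix (shared by batched propagation)
as_kernel <- function(ny, nx, pitch, wavelength, z) {
  fy <- fft_freq_axis(ny, pitch)
  fx <- fft_freq_axis(nx, pitch)
  arg <- 1 - outer((wavelength * fy)^2, (wavelength * fx)^2, "+")
  prop <- arg > 0
  kern <- matrix(0i, ny, nx)
  s <- holopol_conventions()$propagation_sign
  kern[prop] <- exp(s * 1i * (2 * pi * z / wavelength) * sqrt(arg[prop]))
  kern
}

# propagate several same-grid real/complex matrices with one kernel
propagate_many <- function(mats, pitch, wavelength, z) {
  kern <- as_kernel(nrow(mats[[1]]), ncol(mats[[1]]), pitch, wavelength, z)
  n <- length(mats[[1]])
  lapply(mats, function(m)
    stats::fft(stats::fft(m) * kern, inverse = TRUE) / n)
}

#' Normalized gradient-energy focus metric
#'
#' Sum of squared first differences of the amplitude image, normalized
#' by the squared mean (scale invariant). Edge sharpness concentrates at
#' the true object plane, so the metric peaks there; intensity-variance
#' style metrics are nearly flat for weak in-line objects because the
#' deviation energy is conserved under propagation.
#'
#' @param amplitude real non-negative matrix.
#' @return Scalar metric value.
#' @export
focus_metric <- function(amplitude) {
  m <- mean(amplitude)
  if (m == 0) return(0)
  g1 <- amplitude[-1, , drop = FALSE] - amplitude[-nrow(amplitude), , drop = FALSE]
  g2 <- amplitude[, -1, drop = FALSE] - amplitude[, -ncol(amplitude), drop = FALSE]
  (sum(g1^2) + sum(g2^2)) / (length(amplitude) * m^2)
}

#' Reconstruct a hologram at a given depth
#'
#' The DC-suppressed hologram is treated as a field (unit on-axis
#' reference, so multiplication by the conjugate reference is the
#' identity) and back-propagated over `-z` with the angular-spectrum
#' kernel, yielding the complex wavefront at the object plane together
#' with amplitude, phase and a focus score.
#'
#' @param h real hologram matrix.
#' @param cfg an [optical_config()]; supplies wavelength and, through
#'   [object_pixel_size()], the grid pitch.
#' @param z reconstruction depth in metres.
#' @param dc DC-suppression method, see [suppress_dc()]; `"none"` skips it.
#' @return A list of class `reconstruction_result` with elements `field`
#'   (a [complex_field()]), `amplitude`, `phase`, `z`, `focus`.
#' @export
reconstruct <- function(h, cfg, z, dc = c("mean_subtract", "freq_notch", "none")) {
  stopifnot(is.matrix(h), is.numeric(h), inherits(cfg, "optical_config"))
  dc <- match.arg(dc)
  g <- if (dc == "none") h else suppress_dc(h, dc)
  f0 <- complex_field(g, object_pixel_size(cfg), cfg$wavelength)
  gam <- angular_spectrum_propagate(f0, -z)
  amp <- Mod(gam$values)
  structure(list(field = gam, amplitude = amp, phase = Arg(gam$values),
                 z = z, focus = focus_metric(amp)),
            class = "reconstruction_result")
}

#' Search the reconstruction depth maximizing focus
#'
#' Evaluates the normalized-variance focus metric on a uniform grid of
#' depths and returns the best one (ties broken toward the smallest z).
#' A flat metric (empty hologram) therefore returns the smallest depth.
#'
#' @param h real hologram matrix.
#' @param cfg an [optical_config()].
#' @param z_range numeric `c(zmin, zmax)`, zmin < zmax.
#' @param n_steps number of grid points (>= 2).
#' @param dc DC-suppression method passed to [reconstruct()]; the
#'   default keeps the background, against which the focused silhouette
#'   has the sharpest edges.
#' @return List with `z_best`, `z_grid`, `metric`.
#' @export
focus_search <- function(h, cfg, z_range, n_steps = 21,
                         dc = "none") {
  stopifnot(length(z_range) == 2)
  if (!(z_range[1] < z_range[2])) stop("z_range must be non-degenerate")
  if (!is.numeric(n_steps) || n_steps < 2) stop("n_steps must be >= 2")
  zs <- seq(z_range[1], z_range[2], length.out = n_steps)
  met <- vapply(zs, function(z) reconstruct(h, cfg, z, dc = dc)$focus, 0)
  list(z_best = zs[which.max(met)], z_grid = zs, metric = met)
}
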