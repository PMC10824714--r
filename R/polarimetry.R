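#' Mosaic layout of the polarization sensor
#'
#' Assignment of the four analyzer angles to the positions of each 2x2
#' pixel group. The default follows the common wire-grid sensor layout
#' with 90/45 on the first row and 135/0 on the second; the true
#' within-group arrangement of a given camera is configurable here.
#'
#' @param angles 2x2 integer matrix containing each of 0, 45, 90, 135
#'   exactly once; `angles[i, j]` is the analyzer angle at row offset `i`,
#'   column offset `j` within the group.
#' @return An object of class `mosaic_layout`.
#' @export
mosaic_layout <- function(angles = matrix(c(90, 135, 45, 0), 2, 2)) {
  angles <- as.matrix(angles)
  if (!identical(dim(angles), c(2L, 2L)) ||
      !setequal(as.vector(angles), c(0, 45, 90, 135)))
    stop("layout must be a 2x2 assignment of the angles 0, 45, 90, 135")
  structure(list(angles = angles), class = "mosaic_layout")
}

#' Four-angle polarization stack
#'
#' Co-registered intensity images behind analyzers at 0, 45, 90 and 135
#' degrees, the raw material for linear Stokes polarimetry.
#'
#' @param I0,I45,I90,I135 non-negative numeric matrices of equal shape.
#' @param pitch per-channel sample pitch in metres.
#' @return An object of class `polarization_stack`.
#' @export
polarization_stack <- function(I0, I45, I90, I135, pitch = 6.9e-6) {
  chans <- list(I0 = I0, I45 = I45, I90 = I90, I135 = I135)
  dims <- lapply(chans, dim)
  if (!all(vapply(chans, is.matrix, TRUE)) ||
      !all(vapply(dims, identical, TRUE, dims[[1]])))
    stop("channels must be matrices of identical shape")
  if (any(vapply(chans, function(m) any(m < 0), TRUE)))
    stop("channel intensities must be non-negative")
  stopifnot(pitch > 0)
  structure(c(chans, list(pitch = pitch)), class = "polarization_stack")
}

#' Split a polarization mosaic into four channels
#'
#' De-interleaves a 2x2-mosaicked image into the four analyzer channels
#' by position sampling; each channel has half the mosaic resolution per
#' axis. Optional bilinear co-registration shifts each channel onto the
#' common group-centre grid to compensate the sub-pixel offsets between
#' analyzer positions.
#'
#' @param mosaic numeric matrix with even dimensions.
#' @param layout a [mosaic_layout()].
#' @param pitch channel pitch in metres of the output stack.
#' @param coregister if `TRUE`, bilinearly interpolate the channels to
#'   the group centre.
#' @return A [polarization_stack()].
#' @export
split_mosaic <- function(mosaic, layout = mosaic_layout(), pitch = 6.9e-6,
                         coregister = FALSE) {
  stopifnot(is.matrix(mosaic), inherits(layout, "mosaic_layout"))
  if (nrow(mosaic) %% 2L != 0L || ncol(mosaic) %% 2L != 0L)
    stop("mosaic dimensions must be even")
  ch <- list()
  for (i in 1:2) for (j in 1:2) {
    sub <- mosaic[seq.int(i, nrow(mosaic), by = 2L),
                  seq.int(j, ncol(mosaic), by = 2L), drop = FALSE]
    if (coregister) sub <- shift_bilinear(sub, (1.5 - i) / 2, (1.5 - j) / 2)
    ch[[sprintf("I%d", layout$angles[i, j])]] <- sub
  }
  polarization_stack(ch$I0, ch$I45, ch$I90, ch$I135, pitch = pitch)
}

# bilinear shift by (dy, dx) in channel pixels, replicating edges
shift_bilinear <- function(m, dy, dx) {
  ny <- nrow(m); nx <- ncol(m)
  y <- pmin(pmax(seq_len(ny) + dy, 1), ny)
  x <- pmin(pmax(seq_len(nx) + dx, 1), nx)
  y0 <- pmin(floor(y), ny - 1L); x0 <- pmin(floor(x), nx - 1L)
  wy <- y - y0; wx <- x - x0
  a <- m[y0, x0, drop = FALSE];     b <- m[y0, x0 + 1L, drop = FALSE]
  c_ <- m[y0 + 1L, x0, drop = FALSE]; d <- m[y0 + 1L, x0 + 1L, drop = FALSE]
  WY <- matrix(wy, ny, nx); WX <- matrix(wx, ny, nx, byrow = TRUE)
  (1 - WY) * ((1 - WX) * a + WX * b) + WY * ((1 - WX) * c_ + WX * d)
}

#' Linear Stokes parameter maps
#'
#' Pixelwise `I = I0 + I90`, `Q = I0 - I90`, `U = I45 - I135` from a
#' four-angle stack.
#'
#' @param stack a [polarization_stack()].
#' @return An object of class `stokes_maps` with elements `I`, `Q`, `U`,
#'   `pitch`.
#' @export
stokes_maps <- function(stack) {
  stopifnot(inherits(stack, "polarization_stack"))
  structure(list(I = stack$I0 + stack$I90,
                 Q = stack$I0 - stack$I90,
                 U = stack$I45 - stack$I135,
                 pitch = stack$pitch),
            class = "stokes_maps")
}

#' Degree of linear polarization map
#'
#' `DoLP = sqrt(Q^2 + U^2) / I`, bounded to `[0, 1]` by physics for
#' ideal measurements. Pixels whose intensity falls below
#' `intensity_floor * max(I)` are set to 0 and flagged invalid instead of
#' dividing by a vanishing intensity.
#'
#' @param s a [stokes_maps()].
#' @param intensity_floor fraction of the frame maximum below which a
#'   pixel is considered dark.
#' @return A `feature_map` list with `kind = "DoLP"`, `values`, `valid`.
#' @export
dolp_map <- function(s, intensity_floor = 1e-3) {
  stopifnot(inherits(s, "stokes_maps"))
  floor_abs <- intensity_floor * max(s$I)
  valid <- s$I > floor_abs
  v <- matrix(0, nrow(s$I), ncol(s$I))
  v[valid] <- sqrt(s$Q[valid]^2 + s$U[valid]^2) / s$I[valid]
  structure(list(kind = "DoLP", values = v, valid = valid, pitch = s$pitch),
            class = "feature_map")
}

#' Angle of polarization map
#'
#' `AoP = 0.5 * atan(U / Q)` with the single-argument arctangent, so the
#' range is `[-pi/4, +pi/4]`. Pixels with `Q = 0` map to
#' `sign(U) * pi/4`; fully depolarized pixels (`Q = U = 0`) are 0 and
#' flagged invalid.
#'
#' @param s a [stokes_maps()].
#' @return A `feature_map` list with `kind = "AoP"`.
#' @export
aop_map <- function(s) {
  stopifnot(inherits(s, "stokes_maps"))
  v <- matrix(0, nrow(s$Q), ncol(s$Q))
  q0 <- s$Q == 0
  v[!q0] <- 0.5 * atan(s$U[!q0] / s$Q[!q0])
  v[q0] <- sign(s$U[q0]) * pi / 4
  valid <- !(q0 & s$U == 0)
  structure(list(kind = "AoP", values = v, valid = valid, pitch = s$pitch),
            class = "feature_map")
}

#' Stack standard deviation (SSD) map
#'
#' Per-pixel population standard deviation (divisor N = 4) across the
#' four analyzer channels — a direct birefringence-contrast feature: for
#' a uniform retarder of retardance `delta` under circular illumination
#' it equals `|sin(delta)| / (2*sqrt(2))` times the total intensity.
#'
#' @param stack a [polarization_stack()].
#' @return A `feature_map` list with `kind = "SSD"`.
#' @export
ssd_map <- function(stack) {
  stopifnot(inherits(stack, "polarization_stack"))
  m <- (stack$I0 + stack$I45 + stack$I90 + stack$I135) / 4
  v <- sqrt(((stack$I0 - m)^2 + (stack$I45 - m)^2 +
             (stack$I90 - m)^2 + (stack$I135 - m)^2) / 4)
  structure(list(kind = "SSD", values = v,
                 valid = matrix(TRUE, nrow(v), ncol(v)),
                 pitch = stack$pitch),
            class = "feature_map")
}
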