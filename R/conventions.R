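#' Sign and handedness conventions
#'
#' All optical sign choices live in this one record so that the simulator,
#' the propagation kernel and the polarimetric analysis cannot drift apart:
#'
#' * `jones_illumination` — Jones vector of the circularly polarized
#'   illumination, left-handed `(1, i)/sqrt(2)` at unit intensity.
#' * `propagation_sign` — sign of the angular-spectrum kernel phase,
#'   `exp(propagation_sign * 1i * 2*pi*z/lambda * sqrt(1 - lambda^2 f^2))`;
#'   `-1` for forward propagation over `+z`.
#' * `retarder_slow_phase` — the slow axis acquires `exp(+1i * delta)`,
#'   the fast axis is the phase reference.
#'
#' @return A named list of the convention constants.
#' @export
holopol_conventions <- function() {
  list(
    jones_illumination = c(1 + 0i, 1i) / sqrt(2),
    propagation_sign   = -1,
    retarder_slow_phase = +1
  )
}

#' Jones matrix of a linear retarder
#'
#' Retarder with retardance `delta` (radians) and fast axis at angle
#' `theta` from the x axis. The slow axis acquires phase `exp(+1i*delta)`
#' (see [holopol_conventions()]).
#'
#' @param delta retardance in radians.
#' @param theta fast-axis angle in radians.
#' @return Complex 2x2 matrix.
#' @export
jones_retarder <- function(delta, theta) {
  e <- exp(1i * delta)
  ct <- cos(theta); st <- sin(theta)
  matrix(c(ct^2 + e * st^2,  (1 - e) * st * ct,
           (1 - e) * st * ct, st^2 + e * ct^2),
         2, 2)
}
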