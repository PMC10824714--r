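#' Optical configuration of the imaging system
#'
#' Describes the holographic recording geometry: a HeNe-class laser, a
#' polarization mosaic sensor whose 2x2 pixel groups carry wire-grid
#' analyzers at 0/45/90/135 degrees, and a lensless in-line layout.
#' The per-channel sampling pitch (`channel_pitch`) is twice the physical
#' pixel pitch because each analyzer angle is sampled once per 2x2 group.
#'
#' @param wavelength illumination wavelength in metres.
#' @param physical_pixel_pitch sensor pixel pitch in metres.
#' @param mosaic_shape integer vector `c(width, height)` of the mosaic in
#'   pixels; both must be even.
#' @param propagation_distance sample-to-sensor distance in metres.
#' @param magnification optical magnification (1 = lensless in-line).
#' @return An object of class `optical_config`.
#' @examples
#' cfg <- optical_config()
#' cfg$channel_pitch  # 6.9e-6
#' @export
optical_config <- function(wavelength = 632.8e-9,
                           physical_pixel_pitch = 3.45e-6,
                           mosaic_shape = c(2464L, 2056L),
                           propagation_distance = 5e-3,
                           magnification = 1.0) {
  stopifnot(is.numeric(wavelength), wavelength > 0,
            is.numeric(physical_pixel_pitch), physical_pixel_pitch > 0,
            length(mosaic_shape) == 2, all(mosaic_shape > 0),
            is.numeric(propagation_distance), is.finite(propagation_distance),
            is.numeric(magnification), magnification > 0)
  mosaic_shape <- as.integer(mosaic_shape)
  if (any(mosaic_shape %% 2L != 0L))
    stop("mosaic_shape dimensions must be even (2x2 analyzer groups)")
  structure(list(
    wavelength = wavelength,
    physical_pixel_pitch = physical_pixel_pitch,
    channel_pitch = 2 * physical_pixel_pitch,
    mosaic_shape = mosaic_shape,
    propagation_distance = propagation_distance,
    magnification = magnification
  ), class = "optical_config")
}

#' Object-plane pixel size
#'
#' Size, in metres, of one channel sample referred to the object plane.
#' @param cfg an [optical_config()].
#' @return length in metres.
#' @export
object_pixel_size <- function(cfg) cfg$channel_pitch / cfg$magnification

#' Material optical properties
#'
#' A material is modelled as a uniform linear retarder: its birefringence
#' enters through a per-particle retardance drawn from
#' `Normal(retardance_mean, retardance_sd)` clipped to `[0, pi]`, plus a
#' scalar amplitude transmittance. Glass is the non-birefringent control
#' (retardance identically zero).
#'
#' @param name one of `"PC"`, `"PET"`, `"PVC"`, `"PP"`, `"PS"`, `"PMMA"`,
#'   `"glass"`, `"lens_paper"`, `"algae"`.
#' @param retardance_mean mean retardance in radians.
#' @param retardance_sd between-particle retardance SD in radians (>= 0).
#' @param amplitude_transmittance scalar field transmittance in `[0, 1]`.
#' @return An object of class `material_spec`.
#' @export
material_spec <- function(name, retardance_mean, retardance_sd = 0.05,
                          amplitude_transmittance = 0.95) {
  name <- match.arg(name, c("PC", "PET", "PVC", "PP", "PS", "PMMA",
                            "glass", "lens_paper", "algae"))
  stopifnot(retardance_mean >= 0, retardance_sd >= 0,
            amplitude_transmittance >= 0, amplitude_transmittance <= 1)
  if (name == "glass" && retardance_mean != 0)
    stop("glass is the non-birefringent reference: retardance_mean must be 0")
  structure(list(name = name,
                 retardance_mean = retardance_mean,
                 retardance_sd = retardance_sd,
                 amplitude_transmittance = amplitude_transmittance),
            class = "material_spec")
}

#' Default material table
#'
#' Synthetic retardance defaults for the six plastics and the controls.
#' These are configuration, not measured physics: the values are chosen
#' only so that the classes are orderable by birefringence contrast, and
#' they are documented as synthetic placeholders.
#'
#' @param retardance_sd between-particle retardance SD applied to every
#'   birefringent material (radians).
#' @return Named list of [material_spec()] objects.
#' @export
default_materials <- function(retardance_sd = 0.05) {
  mk <- function(name, mean, t = 0.95, sd = retardance_sd)
    material_spec(name, mean, sd, t)
  list(
    glass      = material_spec("glass", 0, 0, 0.97),
    PMMA       = mk("PMMA", 0.15),
    PS         = mk("PS",   0.35),
    PVC        = mk("PVC",  0.45),
    PC         = mk("PC",   0.60),
    PP         = mk("PP",   0.90),
    PET        = mk("PET",  1.30),
    lens_paper = material_spec("lens_paper", 0.05, 0.02, 0.80),
    algae      = material_spec("algae", 0, 0, 0.60)
  )
}

#' Particle geometry and optics
#'
#' @param shape_kind one of `"fragment"`, `"pellet"`, `"fiber"`, `"film"`,
#'   `"foam"`, `"bead"`.
#' @param characteristic_size largest in-plane extent in metres.
#' @param centroid numeric `c(x, y)` position in metres at the object plane.
#' @param fast_axis_angle retarder fast-axis angle in `[0, pi)` radians.
#' @param material a [material_spec()].
#' @return An object of class `particle_spec`.
#' @export
particle_spec <- function(shape_kind, characteristic_size, centroid,
                          fast_axis_angle = 0, material) {
  shape_kind <- match.arg(shape_kind, c("fragment", "pellet", "fiber",
                                        "film", "foam", "bead"))
  stopifnot(characteristic_size > 0, length(centroid) == 2,
            inherits(material, "material_spec"))
  fast_axis_angle <- fast_axis_angle %% pi
  structure(list(shape_kind = shape_kind,
                 characteristic_size = characteristic_size,
                 centroid = as.numeric(centroid),
                 fast_axis_angle = fast_axis_angle,
                 material = material),
            class = "particle_spec")
}

#' Detector and medium noise model
#'
#' `background_scatter_sd` is a relative multiplicative intensity
#' perturbation emulating scatter from suspended matter, applied to the
#' rendered channel intensities; `shot_noise_scale` scales a
#' Gaussian-approximated Poisson term `sqrt(I)`; `read_noise_sd` is
#' additive Gaussian in the same intensity units. All zeros gives a
#' bit-reproducible noiseless render.
#'
#' @param background_scatter_sd relative intensity SD (>= 0).
#' @param shot_noise_scale dimensionless shot-noise scale (>= 0).
#' @param read_noise_sd additive read-noise SD in intensity units (>= 0).
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(background_scatter_sd = 0,
                       shot_noise_scale = 0,
                       read_noise_sd = 0) {
  stopifnot(background_scatter_sd >= 0, shot_noise_scale >= 0,
            read_noise_sd >= 0)
  structure(list(background_scatter_sd = background_scatter_sd,
                 shot_noise_scale = shot_noise_scale,
                 read_noise_sd = read_noise_sd),
            class = "noise_spec")
}

#' Flow-cell configuration
#'
#' Rectangular quartz channel with laminar flow driven by a peristaltic
#' pump; the pump's usable range is 2-15 ml/min and the optimized working
#' point is 8 ml/min.
#'
#' @param volume_flow_rate pump rate in ml/min.
#' @param channel_inner_thickness channel thickness in mm.
#' @param channel_width channel width in mm.
#' @param frames_per_second video frame rate in Hz.
#' @param validate_pump_range if `TRUE`, a rate outside `[2, 15]` ml/min
#'   (other than exactly 0) triggers a warning.
#' @return An object of class `flow_spec`.
#' @export
flow_spec <- function(volume_flow_rate = 8,
                      channel_inner_thickness = 5,
                      channel_width = 10,
                      frames_per_second = 20,
                      validate_pump_range = FALSE) {
  stopifnot(volume_flow_rate >= 0, frames_per_second > 0)
  if (channel_inner_thickness <= 0 || channel_width <= 0)
    stop("invalid geometry: channel cross-section must be positive")
  if (validate_pump_range && volume_flow_rate != 0 &&
      (volume_flow_rate < 2 || volume_flow_rate > 15))
    warning("flow rate outside the pump range [2, 15] ml/min")
  structure(list(volume_flow_rate = volume_flow_rate,
                 channel_inner_thickness = channel_inner_thickness,
                 channel_width = channel_width,
                 frames_per_second = frames_per_second),
            class = "flow_spec")
}

#' Declarative synthetic scene
#'
#' @param particles list of [particle_spec()] objects.
#' @param field_of_view integer `c(nx, ny)` extent of each polarization
#'   channel in pixels.
#' @param noise a [noise_spec()].
#' @param seed integer seed that fully determines the render.
#' @param illumination_intensity illumination intensity (arbitrary units).
#' @param strict if `TRUE` (default) every particle support must lie
#'   inside the field of view; `FALSE` permits partially visible particles
#'   (used by the video renderer while particles enter and leave).
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(particles = list(), field_of_view = c(256L, 256L),
                       noise = noise_spec(), seed = 0L,
                       illumination_intensity = 1,
                       strict = TRUE) {
  stopifnot(is.list(particles), length(field_of_view) == 2,
            inherits(noise, "noise_spec"), illumination_intensity > 0)
  structure(list(particles = particles,
                 field_of_view = as.integer(field_of_view),
                 noise = noise,
                 seed = as.integer(seed),
                 illumination_intensity = illumination_intensity,
                 strict = isTRUE(strict)),
            class = "scene_spec")
}
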