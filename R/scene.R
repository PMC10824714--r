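#' Mean flow speed in the channel
#'
#' Bulk (cross-section averaged) flow speed from the volumetric pump rate
#' and the rectangular channel cross-section.
#'
#' @param flow a [flow_spec()].
#' @return Speed in mm/s.
#' @examples
#' mean_flow_speed(flow_spec(8))   # 8 ml/min over 5 x 10 mm = 2.667 mm/s
#' @export
mean_flow_speed <- function(flow) {
  stopifnot(inherits(flow, "flow_spec"))
  area_mm2 <- flow$channel_inner_thickness * flow$channel_width
  if (area_mm2 <= 0) stop("invalid geometry: channel cross-section must be positive")
  # ml/min = 1000 mm^3 / 60 s
  flow$volume_flow_rate * 1000 / 60 / area_mm2
}

# per-particle draws (retardance, orientation, shape irregularity) from a
# particle-local RNG stream that never disturbs the caller's RNG state
particle_draws <- function(p, seed) {
  r <- local_rng(seed)
  delta <- min(max(r$norm(1, p$material$retardance_mean,
                          p$material$retardance_sd), 0), pi)
  list(delta = delta,
       phase0 = r$unif(1, 0, 2 * pi),
       radii = r$unif(8, 0.55, 1),
       lobes = r$int(1, 5, 8))
}

# tiny self-contained RNG wrapper: saves and restores the global
# .Random.seed around every draw
local_rng <- function(seed) {
  env <- new.env()
  set_state <- function() {
    env$old <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
  }
  restore <- function() {
    if (is.null(env$old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", env$old, globalenv())
  }
  set_state()
  set.seed(as.integer(seed %% 2147483647))
  env$state <- get(".Random.seed", globalenv())
  restore()
  use <- function(f) function(...) {
    set_state()
    assign(".Random.seed", env$state, globalenv())
    out <- f(...)
    env$state <- get(".Random.seed", globalenv())
    restore()
    out
  }
  list(norm = use(function(n, m, s) stats::rnorm(n, m, s)),
       unif = use(function(n, a, b) stats::runif(n, a, b)),
       int  = use(function(n, a, b) a + floor(stats::runif(n) * (b - a + 1))))
}

#' Rasterize one particle's optical maps
#'
#' Builds, on the channel-pixel grid of the field of view, the particle's
#' support mask and the retardance, fast-axis and amplitude-transmittance
#' maps. The retardance is drawn once per particle from
#' `Normal(mean, sd)` clipped to `[0, pi]` — birefringence is treated as
#' a material property, uniform within a particle. Outside the support
#' the retardance is 0 and the transmittance 1.
#'
#' @param p a [particle_spec()].
#' @param fov integer `c(nx, ny)` field of view in channel pixels.
#' @param pitch object-plane pixel size in metres.
#' @param seed integer seed for the per-particle draws.
#' @param strict if `TRUE`, a support touching the image border (i.e. a
#'   clipped particle) is an error; if `FALSE` it is silently clipped.
#' @return List with matrices `mask` (logical, ny x nx), `delta`,
#'   `theta`, `transmittance`, and scalars `delta_drawn`, `centroid_px`
#'   (x, y in pixel units).
#' @export
make_particle_fields <- function(p, fov, pitch, seed = 0L, strict = TRUE) {
  stopifnot(inherits(p, "particle_spec"), length(fov) == 2, pitch > 0)
  nx <- as.integer(fov[1]); ny <- as.integer(fov[2])
  s_px <- p$characteristic_size / pitch
  if (s_px > min(nx, ny))
    stop("geometry error: particle larger than the field of view")
  cx <- p$centroid[1] / pitch; cy <- p$centroid[2] / pitch
  draws <- particle_draws(p, seed)
  X <- matrix(seq_len(nx), ny, nx, byrow = TRUE) - cx
  Y <- matrix(seq_len(ny), ny, nx) - cy
  mask <- rasterize_shape(p$shape_kind, X, Y, s_px, draws)
  if (strict &&
      (any(mask[1, ]) || any(mask[ny, ]) || any(mask[, 1]) || any(mask[, nx])))
    stop("geometry error: particle support extends beyond the field of view")
  delta <- matrix(0, ny, nx); delta[mask] <- draws$delta
  theta <- matrix(0, ny, nx); theta[mask] <- p$fast_axis_angle
  tr <- matrix(1, ny, nx); tr[mask] <- p$material$amplitude_transmittance
  list(mask = mask, delta = delta, theta = theta, transmittance = tr,
       delta_drawn = draws$delta, centroid_px = c(cx, cy))
}

# analytic shape masks on centred pixel-coordinate grids
rasterize_shape <- function(kind, X, Y, s_px, draws) {
  r2 <- X^2 + Y^2
  half <- s_px / 2
  switch(kind,
    bead = r2 <= half^2,
    pellet = {
      a <- half; b <- half / 1.3; phi <- draws$phase0
      xr <- cos(phi) * X + sin(phi) * Y
      yr <- -sin(phi) * X + cos(phi) * Y
      (xr / a)^2 + (yr / b)^2 <= 1
    },
    fiber = {
      w <- max(2, s_px / 8); phi <- draws$phase0 / 2
      xr <- cos(phi) * X + sin(phi) * Y
      yr <- -sin(phi) * X + cos(phi) * Y
      abs(xr) <= half & abs(yr) <= w / 2
    },
    film = abs(X) <= half & abs(Y) <= half * 0.8,
    foam = {
      ang <- atan2(Y, X)
      rad <- half * (0.55 + 0.45 * cos(draws$lobes * ang + draws$phase0))
      r2 <= pmax(rad, 0.12 * half)^2
    },
    fragment = {
      ang <- atan2(Y, X)
      k <- length(draws$radii)
      num <- matrix(0, nrow(X), ncol(X)); den <- num
      for (j in seq_len(k)) {
        b <- (0.5 + 0.5 * cos(ang - 2 * pi * (j - 1) / k + draws$phase0))^3
        num <- num + draws$radii[j] * b
        den <- den + b
      }
      r2 <= (half * num / den)^2
    },
    stop("unknown shape kind"))
}

#' Render a polarization-resolved in-line hologram
#'
#' Implements the vector Gabor model of the instrument: circularly
#' polarized illumination `(1, i)/sqrt(2)` traverses the sample plane,
#' where each particle acts as a scalar-transmittance linear retarder
#' `J(delta, theta)`; the two Jones components are then propagated
#' independently over the sample-to-sensor distance by the
#' angular-spectrum operator (water and glass treated as isotropic), and
#' each analyzer channel records `|cos(a) Ex + sin(a) Ey|^2`. There is no
#' separate reference beam: the unscattered background serves as the
#' in-line reference, so the twin image is accepted as in any Gabor
#' geometry. Multiplicative background-scatter noise, when requested, is
#' applied last.
#'
#' @param scene a [scene_spec()].
#' @param cfg an [optical_config()].
#' @param noise_seed seed for the background-scatter noise (defaults to a
#'   fixed offset of the scene seed; the video renderer varies it per
#'   frame).
#' @return List with `stack` (a [polarization_stack()] at the detector)
#'   and `truth` (label mask, per-particle table, count).
#' @export
render_polarized_hologram <- function(scene, cfg,
                                      noise_seed = scene$seed + 104729L) {
  stopifnot(inherits(scene, "scene_spec"), inherits(cfg, "optical_config"))
  nx <- scene$field_of_view[1]; ny <- scene$field_of_view[2]
  pitch <- object_pixel_size(cfg)
  z <- cfg$propagation_distance
  # angular-spectrum sampling guard: beyond z_max = N * pitch^2 / lambda
  # the kernel's fringe frequency exceeds Nyquist for the channel pitch
  z_max <- min(nx, ny) * pitch^2 / cfg$wavelength
  if (abs(z) > z_max)
    stop(sprintf(
      "sampling error: |z| = %.3g m exceeds the aliasing limit %.3g m for this grid",
      abs(z), z_max))

  maps <- scene_maps(scene, pitch)
  chans <- vector_gabor_channels(maps$delta, maps$theta, maps$transmittance,
                                 pitch, cfg$wavelength, z,
                                 scene$illumination_intensity)
  if (scene$noise$background_scatter_sd > 0) {
    r <- local_rng(noise_seed)
    for (nm in names(chans)) {
      eps <- matrix(r$norm(length(chans[[nm]]), 0,
                           scene$noise$background_scatter_sd), ny, nx)
      chans[[nm]] <- pmax(chans[[nm]] * (1 + eps), 0)
    }
  }
  stack <- polarization_stack(chans$I0, chans$I45, chans$I90, chans$I135,
                              pitch = cfg$channel_pitch)
  list(stack = stack, truth = maps$truth)
}

#' Analyzer-channel intensities of the vector Gabor model
#'
#' The shared rendering core: applies the per-pixel retarder Jones
#' matrix to the circular illumination, propagates both field
#' components by the angular spectrum over `z`, and projects onto the
#' four analyzer angles.
#'
#' @param delta,theta,transmittance per-pixel retardance (rad),
#'   fast-axis angle (rad) and amplitude transmittance matrices.
#' @param pitch object-plane pixel size in metres.
#' @param wavelength wavelength in metres.
#' @param z propagation distance in metres.
#' @param illumination_intensity illumination intensity.
#' @return Named list of channel intensity matrices `I0`, `I45`, `I90`,
#'   `I135`.
#' @export
vector_gabor_channels <- function(delta, theta, transmittance, pitch,
                                  wavelength, z = 0,
                                  illumination_intensity = 1) {
  conv <- holopol_conventions()
  illum <- conv$jones_illumination * sqrt(illumination_intensity)
  e <- exp(1i * delta)
  ct <- cos(theta); st <- sin(theta)
  jxx <- ct^2 + e * st^2
  jxy <- (1 - e) * st * ct
  jyy <- st^2 + e * ct^2
  Ex <- transmittance * (jxx * illum[1] + jxy * illum[2])
  Ey <- transmittance * (jxy * illum[1] + jyy * illum[2])
  if (z != 0) {
    Ex <- angular_spectrum_propagate(complex_field(Ex, pitch, wavelength), z)$values
    Ey <- angular_spectrum_propagate(complex_field(Ey, pitch, wavelength), z)$values
  }
  chans <- lapply(c(0, 45, 90, 135) * pi / 180, function(a)
    Mod(cos(a) * Ex + sin(a) * Ey)^2)
  names(chans) <- c("I0", "I45", "I90", "I135")
  chans
}

#' Render a uniform retarder frame
#'
#' A frame entirely filled by one retarder (`delta`, `theta`), rendered
#' through the standard vector Gabor path; the workhorse for validating
#' the polarimetric closed forms (`DoLP = |sin delta|`,
#' `SSD = |sin delta|/(2 sqrt 2) * I`).
#'
#' @param delta retardance in radians.
#' @param theta fast-axis angle in radians.
#' @param fov `c(nx, ny)` frame size in pixels.
#' @param cfg an [optical_config()]; set `propagation_distance = 0` for
#'   the exact closed forms.
#' @param illumination_intensity illumination intensity.
#' @return A [polarization_stack()].
#' @export
render_retarder_frame <- function(delta, theta, fov = c(32L, 32L),
                                  cfg = optical_config(propagation_distance = 0),
                                  illumination_intensity = 1) {
  ny <- fov[2]; nx <- fov[1]
  chans <- vector_gabor_channels(matrix(delta, ny, nx), matrix(theta, ny, nx),
                                 matrix(1, ny, nx), object_pixel_size(cfg),
                                 cfg$wavelength, cfg$propagation_distance,
                                 illumination_intensity)
  polarization_stack(chans$I0, chans$I45, chans$I90, chans$I135,
                     pitch = cfg$channel_pitch)
}

# paint all particle maps of a scene; later particles overwrite earlier
scene_maps <- function(scene, pitch) {
  nx <- scene$field_of_view[1]; ny <- scene$field_of_view[2]
  delta <- matrix(0, ny, nx); theta <- matrix(0, ny, nx)
  tr <- matrix(1, ny, nx); labels <- matrix(0L, ny, nx)
  recs <- list()
  for (i in seq_along(scene$particles)) {
    p <- scene$particles[[i]]
    pid <- if (!is.null(attr(p, "particle_id"))) attr(p, "particle_id") else i
    pf <- make_particle_fields(p, scene$field_of_view, pitch,
                               seed = particle_seed(scene$seed, pid),
                               strict = scene$strict)
    m <- pf$mask
    delta[m] <- pf$delta[m]; theta[m] <- pf$theta[m]
    tr[m] <- pf$transmittance[m]
    labels[m] <- pid
    if (any(m)) {
      w <- which(m, arr.ind = TRUE)
      recs[[length(recs) + 1]] <- data.frame(
        id = pid, material = p$material$name, shape = p$shape_kind,
        delta = pf$delta_drawn,
        cx_px = mean(w[, 2]), cy_px = mean(w[, 1]),
        area_px = nrow(w), stringsAsFactors = FALSE)
    }
  }
  truth <- list(labels = labels,
                particles = if (length(recs)) do.call(rbind, recs) else
                  empty_truth_table(),
                count = length(unique(labels[labels > 0])))
  list(delta = delta, theta = theta, transmittance = tr, truth = truth)
}

empty_truth_table <- function() {
  data.frame(id = integer(), material = character(), shape = character(),
             delta = numeric(), cx_px = numeric(), cy_px = numeric(),
             area_px = integer(), stringsAsFactors = FALSE)
}

# stable per-particle seed below 2^31
particle_seed <- function(scene_seed, particle_id) {
  (as.integer(scene_seed) + 7919L * as.integer(particle_id)) %% 2147483647L
}

#' Interleave four channels into a polarization mosaic
#'
#' Inverse of [split_mosaic()]: writes each channel at its 2x2 group
#' position, producing a double-size mosaic, then applies shot noise
#' (Gaussian-approximated Poisson, scaled by `sqrt(I)`) and additive read
#' noise under the given seed. With a zero [noise_spec()] the round trip
#' `mosaic_sample` then `split_mosaic` is the identity.
#'
#' @param stack a [polarization_stack()].
#' @param layout a [mosaic_layout()].
#' @param noise a [noise_spec()].
#' @param seed integer noise seed.
#' @return Numeric mosaic matrix of twice the channel size per axis.
#' @export
mosaic_sample <- function(stack, layout = mosaic_layout(),
                          noise = noise_spec(), seed = 0L) {
  stopifnot(inherits(stack, "polarization_stack"),
            inherits(layout, "mosaic_layout"), inherits(noise, "noise_spec"))
  ny <- nrow(stack$I0); nx <- ncol(stack$I0)
  mos <- matrix(0, 2 * ny, 2 * nx)
  for (i in 1:2) for (j in 1:2) {
    ang <- layout$angles[i, j]
    mos[seq.int(i, 2 * ny, 2), seq.int(j, 2 * nx, 2)] <-
      stack[[sprintf("I%d", ang)]]
  }
  if (noise$shot_noise_scale > 0 || noise$read_noise_sd > 0) {
    r <- local_rng(seed)
    if (noise$shot_noise_scale > 0)
      mos <- mos + noise$shot_noise_scale * sqrt(pmax(mos, 0)) *
        matrix(r$norm(length(mos), 0, 1), nrow(mos))
    if (noise$read_noise_sd > 0)
      mos <- mos + matrix(r$norm(length(mos), 0, noise$read_noise_sd), nrow(mos))
    mos <- pmax(mos, 0)
  }
  mos
}

#' Render a flowing-particle hologram video
#'
#' Translates every particle along the flow axis (image x) by
#' `mean_flow_speed * dt / object_pixel_size` pixels per frame, renders
#' each frame as a polarization mosaic, and records complete ground
#' truth. Particles whose support has fully left the field of view are
#' retired; their identity (and hence the total count) is preserved.
#'
#' @param scene a [scene_spec()] giving the initial particle positions
#'   (particles may start left of the field of view to enter later).
#' @param flow a [flow_spec()].
#' @param n_frames number of frames (>= 1).
#' @param cfg an [optical_config()].
#' @param seed noise seed offset for the per-frame detector noise.
#' @return List with `frames` (list of mosaic matrices), `truth` (list:
#'   `count`, `particles` data.frame, `trajectories` data.frame with
#'   per-frame centroids, `labels` list of per-frame label masks),
#'   `displacement_px` per frame.
#' @export
render_video <- function(scene, flow, n_frames, cfg, seed = 0L) {
  stopifnot(inherits(scene, "scene_spec"), inherits(flow, "flow_spec"),
            n_frames >= 1, inherits(cfg, "optical_config"))
  pitch <- object_pixel_size(cfg)
  speed_mm_s <- mean_flow_speed(flow)
  disp_px <- speed_mm_s * 1e-3 / flow$frames_per_second / pitch
  nx <- scene$field_of_view[1]
  if (disp_px > nx) {
    warning("per-frame displacement exceeds the field of view; clamping")
    disp_px <- nx
  }
  frames <- vector("list", n_frames)
  labels <- vector("list", n_frames)
  traj <- list()
  part_tab <- list()
  for (f in seq_len(n_frames)) {
    shift_m <- disp_px * (f - 1) * pitch
    live <- list()
    for (i in seq_along(scene$particles)) {
      p2 <- scene$particles[[i]]
      p2$centroid <- p2$centroid + c(shift_m, 0)
      cx_px <- p2$centroid[1] / pitch
      half_px <- p2$characteristic_size / pitch / 2
      if (cx_px - half_px > nx + 0.5) next  # retired: fully exited
      attr(p2, "particle_id") <- i
      live[[length(live) + 1]] <- p2
    }
    fs <- scene_spec(live, scene$field_of_view, scene$noise,
                     seed = scene$seed, strict = FALSE,
                     illumination_intensity = scene$illumination_intensity)
    rend <- render_polarized_hologram(fs, cfg,
                                      noise_seed = seed + scene$seed + 53L * f)
    frames[[f]] <- mosaic_sample(rend$stack, noise = scene$noise,
                                 seed = seed + scene$seed + 31L * f)
    labels[[f]] <- rend$truth$labels
    tp <- rend$truth$particles
    if (nrow(tp)) {
      tp <- tp[tp$cx_px >= 1 & tp$cx_px <= nx, , drop = FALSE]
      if (nrow(tp)) {
        traj[[length(traj) + 1]] <- data.frame(frame = f, id = tp$id,
                                               cx_px = tp$cx_px,
                                               cy_px = tp$cy_px)
        for (k in seq_len(nrow(tp))) {
          key <- as.character(tp$id[k])
          # keep the most fully visible version as the particle record
          if (is.null(part_tab[[key]]) ||
              tp$area_px[k] > part_tab[[key]]$area_px)
            part_tab[[key]] <- tp[k, ]
        }
      }
    }
  }
  trajectories <- if (length(traj)) do.call(rbind, traj) else
    data.frame(frame = integer(), id = integer(), cx_px = numeric(),
               cy_px = numeric())
  particles <- if (length(part_tab))
    do.call(rbind, part_tab[order(as.integer(names(part_tab)))]) else
    empty_truth_table()
  list(frames = frames,
       truth = list(count = length(unique(trajectories$id)),
                    particles = particles,
                    trajectories = trajectories,
                    labels = labels),
       displacement_px = disp_px)
}
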