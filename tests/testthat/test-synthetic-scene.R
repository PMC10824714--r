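cfg <- optical_config()                      # z = 5 mm
cfg0 <- optical_config(propagation_distance = 0)
px <- object_pixel_size(cfg)
mats <- default_materials()

test_that("mean flow speed follows Q / A with unit conversion", {
  expect_equal(mean_flow_speed(flow_spec(8)), 8 * 1000 / 60 / 50)
  expect_equal(round(mean_flow_speed(flow_spec(8)), 4), 2.6667)
  expect_equal(mean_flow_speed(flow_spec(0)), 0)
  expect_equal(mean_flow_speed(flow_spec(15)), 5)
  expect_error(flow_spec(8, channel_inner_thickness = 0), "geometry")
})

test_that("particle rasterization honours geometry, material and seed", {
  r_px <- 15
  p <- particle_spec("bead", 2 * r_px * px, c(32, 32) * px, 0, mats$PS)
  pf <- make_particle_fields(p, c(64, 64), px, seed = 3)
  expect_lte(abs(sum(pf$mask) - pi * r_px^2), 4 * r_px)
  expect_true(all(pf$delta[!pf$mask] == 0))
  expect_true(all(pf$transmittance[!pf$mask] == 1))
  # glass: retardance identically zero on the support
  g <- particle_spec("bead", 2 * r_px * px, c(32, 32) * px, 0, mats$glass)
  expect_true(all(make_particle_fields(g, c(64, 64), px, seed = 3)$delta == 0))
  # determinism
  pf2 <- make_particle_fields(p, c(64, 64), px, seed = 3)
  expect_identical(pf$mask, pf2$mask)
  expect_identical(pf$delta, pf2$delta)
  expect_true(make_particle_fields(p, c(64, 64), px, seed = 4)$delta_drawn !=
                pf$delta_drawn)
  big <- particle_spec("bead", 100 * px, c(32, 32) * px, 0, mats$PS)
  expect_error(make_particle_fields(big, c(64, 64), px), "larger")
  edge <- particle_spec("bead", 20 * px, c(2, 32) * px, 0, mats$PS)
  expect_error(make_particle_fields(edge, c(64, 64), px), "beyond")
})

test_that("an empty scene renders as the half-intensity circular background", {
  r <- render_polarized_hologram(scene_spec(field_of_view = c(32, 32)), cfg0)
  for (nm in c("I0", "I45", "I90", "I135"))
    expect_equal(r$stack[[nm]], matrix(0.5, 32, 32))
  expect_equal(r$truth$count, 0)
})

test_that("a uniform retarder frame matches the Mueller oracle channelwise", {
  for (d in c(pi / 6, pi / 2)) for (th in c(0, pi / 8, 1.1)) {
    st <- render_retarder_frame(d, th, fov = c(16L, 16L))
    oracle <- mueller_channels(d, th)
    got <- c(st$I0[3, 3], st$I45[3, 3], st$I90[3, 3], st$I135[3, 3])
    expect_lt(max(abs(got - oracle)), 1e-9)
  }
})

test_that("rendered holograms respect physical bounds and truth bookkeeping", {
  p <- particle_spec("bead", 200e-6, c(64, 64) * px, 0.7, mats$PET)
  sc <- scene_spec(list(p), c(128, 128), seed = 9)
  r <- render_polarized_hologram(sc, cfg)
  expect_equal(r$truth$count, 1)
  expect_equal(nrow(r$truth$particles), 1)
  # fringes present: the I0 channel is no longer uniform
  expect_gt(diff(range(r$stack$I0)), 0.01)
  # energy sanity: channels non-negative; local coherent overshoot is
  # physical after propagation, but the global energy of a transmissive
  # scene cannot exceed the illumination energy, and at the object plane
  # (z = 0) every channel is bounded by the illumination intensity
  for (nm in c("I0", "I45", "I90", "I135"))
    expect_gte(min(r$stack[[nm]]), 0)
  expect_lte(mean(r$stack$I0 + r$stack$I90), 1 + 1e-9)
  expect_lte(mean(r$stack$I45 + r$stack$I135), 1 + 1e-9)
  r0 <- render_polarized_hologram(sc, cfg0)
  for (nm in c("I0", "I45", "I90", "I135"))
    expect_lte(max(r0$stack[[nm]]), 1 + 1e-12)
  # complementarity to numerical precision
  expect_lt(max(abs(r$stack$I0 + r$stack$I90 - r$stack$I45 - r$stack$I135)),
            1e-9)
  # aliasing guard
  cfg_far <- optical_config(propagation_distance = 0.5)
  expect_error(render_polarized_hologram(sc, cfg_far), "sampling")
})

test_that("glass scenes are polarimetrically silent", {
  p <- particle_spec("pellet", 250e-6, c(64, 64) * px, 0.3, mats$glass)
  r <- render_polarized_hologram(scene_spec(list(p), c(128, 128), seed = 1), cfg)
  dl <- dolp_map(stokes_maps(r$stack))
  expect_lt(max(dl$values), 1e-6)
})

test_that("mosaic sampling interleaves losslessly and doubles the size", {
  p <- particle_spec("bead", 200e-6, c(64, 64) * px, 0.7, mats$PC)
  st <- render_polarized_hologram(scene_spec(list(p), c(128, 128), seed = 2),
                                  cfg)$stack
  mos <- mosaic_sample(st)
  expect_equal(dim(mos), c(256L, 256L))
  back <- split_mosaic(mos, pitch = st$pitch)
  for (nm in c("I0", "I45", "I90", "I135"))
    expect_identical(back[[nm]], st[[nm]])
  cst <- polarization_stack(matrix(0.3, 1028, 1232), matrix(0.3, 1028, 1232),
                            matrix(0.3, 1028, 1232), matrix(0.3, 1028, 1232))
  mc <- mosaic_sample(cst)
  expect_equal(dim(mc), c(2056L, 2464L))
  expect_true(all(mc == 0.3))
})

test_that("detector noise is seeded and absent when zeroed", {
  st <- render_retarder_frame(0.5, 0.2, fov = c(16L, 16L))
  ns <- noise_spec(shot_noise_scale = 0.02, read_noise_sd = 0.01)
  m1 <- mosaic_sample(st, noise = ns, seed = 5)
  m2 <- mosaic_sample(st, noise = ns, seed = 5)
  m3 <- mosaic_sample(st, noise = ns, seed = 6)
  expect_identical(m1, m2)
  expect_false(identical(m1, m3))
  expect_true(all(m1 >= 0))
})

test_that("video kinematics follow the flow and retire exiting particles", {
  flow <- flow_spec(8, frames_per_second = 20)
  p <- particle_spec("bead", 150e-6, c(20, 64) * px, 0, mats$PP)
  sc <- scene_spec(list(p), c(128, 128), seed = 4, strict = FALSE)
  vid <- render_video(sc, flow, 6, cfg0)
  tr <- vid$truth$trajectories
  expect_equal(vid$truth$count, 1)
  # per-frame displacement equals speed * dt / pitch within half a pixel,
  # judged on fully visible frames (border clipping shifts the centroid)
  expected <- mean_flow_speed(flow) * 1e-3 / 20 / px
  r_px <- 150e-6 / px / 2
  tr <- tr[order(tr$frame), ]
  vis <- tr$cx_px + r_px + 1 < 128 & tr$cx_px - r_px - 1 > 1
  steps <- diff(tr$cx_px[vis])
  expect_gte(length(steps), 2)
  expect_true(all(abs(steps - expected) <= 0.5))
  # collinear trajectory
  expect_lt(diff(range(tr$cy_px)), 1e-6)
  # zero flow: frames identical
  vid0 <- render_video(sc, flow_spec(0), 3, cfg0)
  expect_identical(vid0$frames[[1]], vid0$frames[[3]])
  # particle placed to exit: retired from later frames
  p2 <- particle_spec("bead", 150e-6, c(58, 32) * px, 0, mats$PP)
  vid2 <- render_video(scene_spec(list(p2), c(64, 64), seed = 4,
                                  strict = FALSE), flow, 8, cfg0)
  tr2 <- vid2$truth$trajectories
  expect_lt(max(tr2$frame), 8)
  expect_equal(vid2$truth$count, 1)
})
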