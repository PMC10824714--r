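cfg_z5 <- optical_config()                       # 5 mm in-line geometry
cfg_z0 <- optical_config(propagation_distance = 0)

test_that("hologram formation reproduces the interference closed forms", {
  grid <- function(v) complex_field(matrix(v, 16, 16), 6.9e-6, 632.8e-9)
  expect_equal(form_hologram(grid(0), grid(2 + 0i)),
               matrix(4, 16, 16))
  expect_equal(form_hologram(grid(1 + 0i), grid(1 + 0i)), matrix(4, 16, 16))
  a <- 0.3; phi <- 1.1
  h <- form_hologram(grid(a * exp(1i * phi)), grid(1 + 0i))
  expect_equal(h, matrix(1 + a^2 + 2 * a * cos(phi), 16, 16))
  # symmetric in the two waves, real and non-negative
  set.seed(4)
  u <- complex_field(matrix(complex(real = rnorm(256), imaginary = rnorm(256)),
                            16, 16), 6.9e-6, 632.8e-9)
  r <- complex_field(matrix(complex(real = rnorm(256), imaginary = rnorm(256)),
                            16, 16), 6.9e-6, 632.8e-9)
  expect_equal(form_hologram(u, r), form_hologram(r, u))
  expect_true(all(form_hologram(u, r) >= 0))
  bad <- complex_field(matrix(1 + 0i, 8, 8), 6.9e-6, 632.8e-9)
  expect_error(form_hologram(u, bad), "grid")
})

test_that("DC suppression removes the mean and spares fringes", {
  expect_equal(suppress_dc(matrix(3.7, 20, 20)), matrix(0, 20, 20))
  set.seed(7)
  h <- matrix(runif(400, 0.2, 1), 20, 20)
  expect_lt(abs(mean(suppress_dc(h))), 1e-12)
  x <- matrix(seq_len(64) - 1, 64, 64, byrow = TRUE)
  fr <- cos(2 * pi * 8 * x / 64)           # integer-period cosine: zero mean
  expect_lt(max(abs(suppress_dc(fr) - fr)), 1e-9)
  expect_error(suppress_dc(h, "bogus"))
  # the frequency notch also kills a constant offset
  notch <- suppress_dc(fr + 5, "freq_notch")
  expect_lt(abs(mean(notch)), 0.05)
})

test_that("angular-spectrum propagation matches plane-wave and inverse symmetries", {
  f <- complex_field(matrix(1 + 0i, 64, 64), 6.9e-6, 632.8e-9)
  expect_lt(max(Mod(angular_spectrum_propagate(f, 0)$values - f$values)), 1e-12)
  z <- 1.3e-3
  p <- angular_spectrum_propagate(f, z)
  expect_lt(max(Mod(p$values - exp(-1i * 2 * pi * z / 632.8e-9))), 1e-9)
  fb <- bandlimited_field(64, 6.9e-6, 632.8e-9, seed = 2)
  rt <- angular_spectrum_propagate(angular_spectrum_propagate(fb, z), -z)
  expect_lt(max(Mod(rt$values - fb$values)), 1e-8)
  # unitary kernel below the evanescent cutoff conserves energy
  e0 <- sum(Mod(fb$values)^2)
  e1 <- sum(Mod(angular_spectrum_propagate(fb, z)$values)^2)
  expect_lt(abs(e1 - e0) / e0, 1e-8)
  expect_error(angular_spectrum_propagate(f, NaN), "finite")
  tiny <- complex_field(matrix(1 + 0i, 8, 8), 6.9e-6, 632.8e-9)
  expect_error(angular_spectrum_propagate(tiny, z), "16x16")
})

test_that("reconstruction is linear and flat for an empty hologram", {
  h0 <- matrix(0.5, 64, 64)
  rec <- reconstruct(h0, cfg_z5, 5e-3)
  expect_lt(diff(range(rec$amplitude)), 1e-6)
  sc <- scene_spec(list(particle_spec("bead", 200e-6, c(96, 96) * 6.9e-6, 0,
                                      default_materials()$PS)),
                   c(192, 192), seed = 5)
  h <- with(render_polarized_hologram(sc, cfg_z5), stack$I0 + stack$I90)
  r1 <- reconstruct(h, cfg_z5, 5e-3)
  r3 <- reconstruct(3 * h, cfg_z5, 5e-3)
  expect_equal(r3$amplitude, 3 * r1$amplitude, tolerance = 1e-10)
  expect_true(all(abs(r1$phase) <= pi + 1e-12))
  expect_equal(r1$amplitude, Mod(r1$field$values))
})

test_that("focus search recovers the render depth and breaks ties low", {
  mats <- default_materials()
  p <- particle_spec("bead", 300e-6, c(128, 128) * 6.9e-6, 0, mats$algae)
  sc <- scene_spec(list(p), c(256, 256), seed = 2)
  h <- with(render_polarized_hologram(sc, cfg_z5), stack$I0 + stack$I90)
  fs <- focus_search(h, cfg_z5, c(2e-3, 8e-3), n_steps = 13)
  step <- diff(fs$z_grid)[1]
  expect_lte(abs(fs$z_best - 5e-3), step + 1e-12)
  # interior peak for an interior true depth
  expect_gt(which.max(fs$metric), 1)
  expect_lt(which.max(fs$metric), length(fs$metric))
  # flat metric (empty hologram) falls back to the smallest depth
  expect_equal(focus_search(matrix(1, 64, 64), cfg_z5, c(1e-3, 3e-3), 5)$z_best,
               1e-3)
  expect_error(focus_search(h, cfg_z5, c(2e-3, 2e-3), 5), "non-degenerate")
  expect_error(focus_search(h, cfg_z5, c(1e-3, 2e-3), 1), "n_steps")
})
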