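stack_const <- function(v0, v45, v90, v135, n = 8)
  polarization_stack(matrix(v0, n, n), matrix(v45, n, n),
                     matrix(v90, n, n), matrix(v135, n, n))

test_that("mosaic splitting de-interleaves by position at half resolution", {
  lay <- mosaic_layout()
  mos <- matrix(0.7, 2056, 2464)
  st <- split_mosaic(mos, lay)
  expect_equal(dim(st$I0), c(1028L, 1232L))
  expect_true(all(st$I0 == 0.7) && all(st$I135 == 0.7))
  # ones only at the 0-degree positions
  ang <- lay$angles
  pos0 <- which(ang == 0, arr.ind = TRUE)
  mos2 <- matrix(0, 8, 8)
  mos2[seq.int(pos0[1], 8, 2), seq.int(pos0[2], 8, 2)] <- 1
  st2 <- split_mosaic(mos2, lay)
  expect_true(all(st2$I0 == 1))
  expect_true(all(st2$I45 == 0) && all(st2$I90 == 0) && all(st2$I135 == 0))
  expect_error(split_mosaic(matrix(0, 7, 8)), "even")
  expect_error(mosaic_layout(matrix(c(0, 45, 90, 90), 2, 2)), "layout")
})

test_that("Stokes maps follow the linear definitions and the Mueller oracle", {
  st <- stokes_maps(stack_const(0.5, 0.5, 0.5, 0.5))
  expect_equal(st$I, matrix(1, 8, 8)); expect_equal(st$Q, matrix(0, 8, 8))
  st2 <- stokes_maps(stack_const(1, 0.5, 0, 0.5))
  expect_equal(st2$I, matrix(1, 8, 8)); expect_equal(st2$Q, matrix(1, 8, 8))
  expect_equal(st2$U, matrix(0, 8, 8))
  # retarder frame against the independent Mueller-calculus oracle
  ch <- mueller_channels(pi / 2, pi / 8)
  rend <- render_retarder_frame(pi / 2, pi / 8)
  got <- c(rend$I0[1, 1], rend$I45[1, 1], rend$I90[1, 1], rend$I135[1, 1])
  expect_lt(max(abs(got - ch)), 1e-9)
  st3 <- stokes_maps(rend)
  expect_lt(max(abs(st3$I - (ch[1] + ch[3]))), 1e-9)
  expect_lt(max(abs(st3$Q - (ch[1] - ch[3]))), 1e-9)
  expect_lt(max(abs(st3$U - (ch[2] - ch[4]))), 1e-9)
})

test_that("DoLP map implements sqrt(Q^2+U^2)/I with an intensity floor", {
  n <- 8
  s <- structure(list(I = matrix(1, n, n), Q = matrix(0, n, n),
                      U = matrix(0, n, n), pitch = 6.9e-6),
                 class = "stokes_maps")
  expect_equal(dolp_map(s)$values, matrix(0, n, n))
  s$Q <- matrix(0.6, n, n); s$U <- matrix(0.8, n, n)
  expect_equal(dolp_map(s)$values, matrix(1, n, n))
  # dark pixels flagged instead of divided
  s$I[1, 1] <- 1e-9; s$Q[1, 1] <- 1e-10; s$U[1, 1] <- 0
  dm <- dolp_map(s)
  expect_false(dm$valid[1, 1])
  expect_equal(dm$values[1, 1], 0)
})

test_that("DoLP of a retarder equals |sin delta| independent of the fast axis", {
  worst <- 0
  for (d in seq(0, pi, length.out = 9))
    for (th in seq(0, pi * 0.9, length.out = 7)) {
      st <- render_retarder_frame(d, th, fov = c(16L, 16L))
      dl <- dolp_map(stokes_maps(st))
      worst <- max(worst, max(abs(dl$values - abs(sin(d)))))
    }
  expect_lt(worst, 1e-6)
})

test_that("AoP uses the single-argument arctangent with a pi/4 bound", {
  mk <- function(q, u) structure(list(I = matrix(1, 2, 2),
                                      Q = matrix(q, 2, 2),
                                      U = matrix(u, 2, 2), pitch = 1),
                                 class = "stokes_maps")
  expect_equal(aop_map(mk(1, 0))$values[1, 1], 0)
  expect_equal(aop_map(mk(0.5, 0.5))$values[1, 1], pi / 8)
  expect_equal(aop_map(mk(0, 0.3))$values[1, 1], pi / 4)
  expect_equal(aop_map(mk(0, -0.3))$values[1, 1], -pi / 4)
  a00 <- aop_map(mk(0, 0))
  expect_equal(a00$values[1, 1], 0)
  expect_false(a00$valid[1, 1])
  set.seed(11)
  n <- 1e5
  s <- structure(list(I = matrix(1, n, 1),
                      Q = matrix(rnorm(n), n, 1),
                      U = matrix(rnorm(n), n, 1), pitch = 1),
                 class = "stokes_maps")
  expect_lte(max(abs(aop_map(s)$values)), pi / 4)
})

test_that("SSD is the population standard deviation across the four channels", {
  expect_equal(ssd_map(stack_const(0.4, 0.4, 0.4, 0.4))$values,
               matrix(0, 8, 8))
  expect_equal(ssd_map(stack_const(0, 1, 0, 1))$values[1, 1], 0.5)
  st <- render_retarder_frame(pi / 2, pi / 8)
  expect_equal(ssd_map(st)$values[1, 1], 1 / (2 * sqrt(2)), tolerance = 1e-6)
  expect_equal(round(ssd_map(st)$values[1, 1], 6), 0.353553)
})

test_that("DoLP and AoP are invariant to global intensity scaling", {
  st <- render_retarder_frame(0.8, 0.3, fov = c(16L, 16L))
  sc <- polarization_stack(7 * st$I0, 7 * st$I45, 7 * st$I90, 7 * st$I135,
                           pitch = st$pitch)
  expect_equal(dolp_map(stokes_maps(st))$values,
               dolp_map(stokes_maps(sc))$values, tolerance = 1e-12)
  expect_equal(aop_map(stokes_maps(st))$values,
               aop_map(stokes_maps(sc))$values, tolerance = 1e-12)
})
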