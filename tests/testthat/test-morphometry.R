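test_that("segmentation finds the discs it should and nothing else", {
  expect_equal(attr(segment_particles(matrix(0, 32, 32)), "n"), 0L)
  img <- matrix(0, 64, 64)
  d1 <- disc_mask(8); d2 <- disc_mask(6)
  img[5 + seq_len(nrow(d1)), 5 + seq_len(ncol(d1))][d1] <- 1
  img[38 + seq_len(nrow(d2)), 38 + seq_len(ncol(d2))][d2] <- 1
  lab <- segment_particles(img, segmentation_params(min_area = 10,
                                                    closing_radius = 0))
  expect_equal(attr(lab, "n"), 2L)
  areas <- sort(tabulate(lab[lab > 0]))
  expect_lt(abs(areas[1] - sum(d2)) / sum(d2), 0.05)
  expect_lt(abs(areas[2] - sum(d1)) / sum(d1), 0.05)
  # a blob below min_area is discarded
  lab2 <- segment_particles(img, segmentation_params(min_area = 500,
                                                     closing_radius = 0))
  expect_equal(attr(lab2, "n"), 0L)
})

test_that("component labelling is 8-connected", {
  m <- matrix(FALSE, 6, 6); m[2, 2] <- TRUE; m[3, 3] <- TRUE; m[5, 5] <- TRUE
  lab <- label_components(m)
  expect_equal(lab[2, 2], lab[3, 3])
  expect_false(lab[5, 5] == lab[2, 2])
  expect_equal(max(lab), 2L)
})

test_that("maximum Feret diameter follows the pixel-corner convention", {
  one <- matrix(FALSE, 5, 5); one[3, 3] <- TRUE
  expect_equal(max_feret(one), sqrt(2))
  expect_equal(max_feret(one, pitch = 2), 2 * sqrt(2))
  expect_equal(max_feret(rect_mask(30, 40)), sqrt(30^2 + 40^2))
  # rotation invariance within 2%
  n <- 101; ang <- 33 * pi / 180
  X <- matrix(seq_len(n), n, n, byrow = TRUE) - (n + 1) / 2
  Y <- matrix(seq_len(n), n, n) - (n + 1) / 2
  xr <- cos(ang) * X + sin(ang) * Y; yr <- -sin(ang) * X + cos(ang) * Y
  rot <- abs(xr) <= 20 & abs(yr) <= 15
  expect_lt(abs(max_feret(rot) - sqrt(40^2 + 30^2)) / 50, 0.02)
  expect_error(max_feret(matrix(FALSE, 4, 4)), "empty")
})

test_that("rotating calipers agree exactly with the brute-force hull oracle", {
  for (s in 1:300) {
    m <- random_blob(s)
    expect_identical(max_feret(m), brute_hull_max(m))
  }
})

test_that("minimum Feret diameter is the smallest caliper width", {
  expect_equal(min_feret(rect_mask(1, 100)), 1)
  d <- disc_mask(20)
  expect_lt(abs(min_feret(d) - 40) / 40, 0.02)
  for (s in 301:500) {
    m <- random_blob(s)
    expect_lte(min_feret(m), max_feret(m) + 1e-12)
  }
})

test_that("circularity matches the closed forms of canonical shapes", {
  expect_gte(circularity(disc_mask(50)), 0.95)
  expect_lte(circularity(disc_mask(50)), 1.03)
  sq <- circularity(rect_mask(50, 50))
  expect_lt(abs(sq - sqrt(pi) / 2), 0.03)
  expect_lte(circularity(rect_mask(2, 200)), 0.35)
  # squared form is the square of the default form
  expect_equal(circularity(rect_mask(10, 10), form = "squared"),
               circularity(rect_mask(10, 10))^2)
  expect_error(circularity(matrix(FALSE, 3, 3)), "empty")
})

test_that("sphere-equivalent volume scales as the cube of linear size", {
  m <- matrix(FALSE, 5, 5); m[2:3, 2:3] <- TRUE   # area 4 px
  ced <- 2 * sqrt(4 / pi)
  expect_equal(se_volume(m, pitch = 2), pi / 6 * ced^3 * 8)
  v1 <- se_volume(disc_mask(10)); v2 <- se_volume(disc_mask(20))
  expect_lt(abs(v2 / v1 - 8), 8 * 0.05)
  expect_error(se_volume(matrix(FALSE, 3, 3)), "empty")
})

test_that("the shape rule cascade is applied in its fixed order", {
  rec <- function(mfd, w, c, s, a = 500, tr = 0.5)
    list(mfd = mfd, width = w, circularity = c, solidity = s,
         area_px = a, transmittance = tr)
  expect_equal(classify_shape(rec(100, 10, 0.3, 0.95)), "fiber")
  expect_equal(classify_shape(rec(20, 19, 0.96, 0.99)), "bead")
  expect_equal(classify_shape(rec(20, 15, 0.88, 0.99)), "pellet")
  # foam precedes film and fragment; fiber precedes foam
  expect_equal(classify_shape(rec(30, 20, 0.5, 0.7)), "foam")
  expect_equal(classify_shape(rec(200, 10, 0.5, 0.7)), "fiber")
  expect_equal(classify_shape(rec(60, 50, 0.6, 0.95, a = 3000, tr = 0.95)),
               "film")
  expect_equal(classify_shape(rec(30, 20, 0.6, 0.95)), "fragment")
})

test_that("simulated beads and fibers classify as their ground-truth shapes", {
  px <- 6.9e-6
  mats <- default_materials()
  hits <- 0
  for (s in 1:100) {
    kind <- if (s %% 2 == 0) "bead" else "fiber"
    p <- particle_spec(kind, (150 + (s %% 7) * 20) * 1e-6, c(48, 48) * px,
                       0.1 * s, mats$PS)
    m <- make_particle_fields(p, c(96, 96), px, seed = s, strict = FALSE)$mask
    rec <- list(mfd = max_feret(m), width = min_feret(m),
                circularity = circularity(m), solidity = 1,
                area_px = sum(m), transmittance = 0.5)
    hits <- hits + (classify_shape(rec) == kind)
  }
  expect_gte(hits / 100, 0.95)
})

test_that("the size-by-material heatmap conserves counts", {
  recs <- data.frame(mfd_um = c(1200, 1400, 2500), material = "PC")
  h <- size_material_heatmap(recs, c(1000, 2000, 3000))
  expect_equal(unname(h["PC", ]), c(2L, 1L))
  expect_equal(sum(size_material_heatmap(data.frame(mfd_um = numeric(),
                                                    material = character()),
                                         c(0, 1))), 0L)
  set.seed(8)
  recs2 <- data.frame(mfd_um = runif(60, 0, 3000),
                      material = sample(c("PC", "PET", "PS"), 60, TRUE))
  edges <- c(0, 500, 1000, 2000, 4000)
  h2 <- size_material_heatmap(recs2, edges)
  expect_equal(sum(h2), 60L)
  perm <- recs2[sample(nrow(recs2)), ]
  expect_identical(size_material_heatmap(perm, edges), h2)
})
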