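test_that("polarimetric features recover the retarder closed forms", {
  st <- render_retarder_frame(pi / 2, 0.6, fov = c(32L, 32L))
  ssd <- ssd_map(st); dolp <- dolp_map(stokes_maps(st))
  mask <- matrix(FALSE, 32, 32); mask[8:24, 8:24] <- TRUE
  fx <- extract_features(mask, ssd, dolp)
  expect_lt(abs(fx["dolp_mean"] - 1), 1e-3)
  st0 <- render_retarder_frame(0, 0, fov = c(32L, 32L))
  fx0 <- extract_features(mask, ssd_map(st0), dolp_map(stokes_maps(st0)))
  expect_lt(abs(fx0["ssd_mean"]), 1e-3)
  expect_lt(abs(fx0["dolp_mean"]), 1e-3)
  expect_error(extract_features(matrix(FALSE, 32, 32), ssd, dolp), "empty")
})

test_that("stratified splitting hits the 8:1:1 sizes within one per class", {
  labels <- rep(letters[1:10], each = 100)
  sp <- split_dataset(labels, c(8, 1, 1), seed = 1)
  expect_equal(length(sp$train), 800)
  expect_equal(length(sp$val), 100)
  expect_equal(length(sp$test), 100)
  expect_equal(sort(c(sp$train, sp$val, sp$test)), seq_along(labels))
  one <- split_dataset(rep("x", 10), c(8, 1, 1), seed = 3)
  expect_equal(lengths(one), c(train = 8L, val = 1L, test = 1L))
  expect_identical(split_dataset(labels, seed = 42),
                   split_dataset(labels, seed = 42))
  expect_false(identical(split_dataset(labels, seed = 42),
                         split_dataset(labels, seed = 43)))
  # stratification: class proportions preserved in every split
  tr_cls <- table(labels[sp$train])
  expect_true(all(tr_cls == 80))
})

test_that("centroid training standardizes and positions class means", {
  x <- matrix(c(1, 2, 3, 4, 10, 20, 30, 40), 4, 2)
  m1 <- train_centroids(x, rep("a", 4))
  expect_lt(max(abs(m1$centroids)), 1e-12)
  x2 <- rbind(matrix(-1, 5, 2) + 0.01 * matrix(rnorm(10), 5),
              matrix(+1, 5, 2) + 0.01 * matrix(rnorm(10), 5))
  m2 <- train_centroids(x2, rep(c("lo", "hi"), each = 5))
  expect_true(all(m2$centroids["lo", ] < 0))
  expect_true(all(m2$centroids["hi", ] > 0))
  expect_lt(max(abs(m2$centroids["lo", ] + m2$centroids["hi", ])), 0.2)
})

test_that("well-separated Gaussian classes are recovered near-perfectly", {
  set.seed(5)
  k <- 4; n <- 80
  mu <- seq_len(k) * 4                      # 4 pooled SD apart, sd = 1
  x <- cbind(rnorm(k * n, rep(mu, each = n), 1),
             rnorm(k * n, rep(rev(mu), each = n), 1))
  y <- rep(letters[1:k], each = n)
  model <- train_centroids(x, y)
  expect_gte(mean(predict(model, x)$class == y), 0.99)
})

test_that("prediction is nearest-centroid with a first-class tie rule", {
  x <- rbind(c(-1, 0), c(1, 0))
  model <- train_centroids(rbind(x, x), rep(c("a", "b"), 2))
  raw_at <- function(p) predict(model, matrix(p, 1))$class
  expect_equal(raw_at(c(-1, 0)), "a")
  expect_equal(raw_at(c(1, 0)), "b")
  expect_equal(raw_at(c(0, 5)), "a")       # equidistant: first class wins
  pr <- predict(model, rbind(c(-1, 0), c(0, 0)))
  expect_gt(pr$margin[1], pr$margin[2])
})

test_that("prediction is invariant to affine rescaling of raw features", {
  set.seed(6)
  x <- matrix(rnorm(60), 30, 2)
  y <- rep(c("p", "q"), 15)
  x[y == "q", 1] <- x[y == "q", 1] + 3
  x2 <- x; x2[, 1] <- 100 * x2[, 1] - 7; x2[, 2] <- 0.01 * x2[, 2] + 2
  m1 <- train_centroids(x, y); m2 <- train_centroids(x2, y)
  expect_equal(predict(m1, x)$class, predict(m2, x2)$class)
})

test_that("evaluation reports accuracy and a conserved confusion matrix", {
  x <- rbind(matrix(0, 10, 2), matrix(5, 10, 2))
  y <- rep(c("a", "b"), each = 10)
  model <- train_centroids(x, y)
  ev <- evaluate_model(model, x, y)
  expect_equal(ev$accuracy, 1)
  expect_equal(unname(diag(ev$confusion)), c(10L, 10L))
  expect_equal(unname(rowSums(ev$confusion)), c(10L, 10L))
  # random labels, k classes: accuracy near 1/k
  set.seed(9)
  k <- 5; n <- 1e4
  xr <- matrix(rnorm(2 * n), n, 2)
  yr <- sample(letters[1:k], n, TRUE)
  mr <- train_centroids(xr, yr)
  acc <- evaluate_model(mr, xr, yr)$accuracy
  se <- sqrt((1 / k) * (1 - 1 / k) / n)
  expect_lt(abs(acc - 1 / k), 3 * se + 0.01)
})

test_that("separation sweeps never degrade expected accuracy", {
  seps <- c(1, 2, 4, 8)
  accs <- vapply(seps, function(s) {
    accs_seed <- vapply(1:20, function(seed) {
      set.seed(seed)
      x <- matrix(c(rnorm(50), rnorm(50) + s), ncol = 1)
      y <- rep(c("a", "b"), each = 50)
      mean(predict(train_centroids(x, y), x)$class == y)
    }, 0)
    mean(accs_seed)
  }, 0)
  expect_true(all(diff(accs) >= -0.005))
})

test_that("model JSON serialization round-trips", {
  set.seed(10)
  x <- matrix(rnorm(40), 20, 2,
              dimnames = list(NULL, c("ssd_mean", "dolp_mean")))
  y <- rep(c("PS", "PET"), 10)
  model <- train_centroids(x, y)
  path <- tempfile(fileext = ".json")
  write_centroid_model(model, path)
  back <- read_centroid_model(path)
  expect_equal(back$classes, model$classes)
  expect_equal(unname(back$centroids), unname(model$centroids))
  expect_equal(predict(back, x)$class, predict(model, x)$class)
})
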