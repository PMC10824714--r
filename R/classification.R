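#' Extract a polarimetric feature vector for one particle
#'
#' Statistics are computed over the pixels of the particle mask that are
#' also valid in the feature maps: mean SSD, 90th-percentile SSD, mean
#' DoLP, and mean relative amplitude transmittance.
#'
#' @param mask logical particle mask.
#' @param ssd SSD `feature_map` (or matrix).
#' @param dolp DoLP `feature_map` (or matrix); its `valid` mask, when
#'   present, restricts the DoLP statistic.
#' @param amplitude optional amplitude matrix for the transmittance
#'   feature (mask mean over background median).
#' @return Named numeric vector `ssd_mean`, `ssd_p90`, `dolp_mean`,
#'   `transmittance`.
#' @export
extract_features <- function(mask, ssd, dolp, amplitude = NULL) {
  if (!any(mask)) stop("empty-overlap error: mask has no pixels")
  sv <- if (inherits(ssd, "feature_map")) ssd$values else ssd
  dv <- if (inherits(dolp, "feature_map")) dolp$values else dolp
  dvalid <- if (inherits(dolp, "feature_map")) dolp$valid & mask else mask
  if (!any(dvalid)) dvalid <- mask
  tr <- if (!is.null(amplitude)) {
    bg <- stats::median(amplitude[!mask])
    if (bg > 0) mean(amplitude[mask]) / bg else NA_real_
  } else NA_real_
  c(ssd_mean = mean(sv[mask]),
    ssd_p90 = unname(stats::quantile(sv[mask], 0.9)),
    dolp_mean = mean(dv[dvalid]),
    transmittance = tr)
}

#' Stratified train/validation/test split
#'
#' Splits record indices into train/validation/test sets stratified by
#' class. Within each class the records are shuffled under the seed and
#' apportioned by largest remainder, so each class's split sizes are
#' within one of the exact ratios (8:1:1 by default).
#'
#' @param labels vector of class labels, one per record.
#' @param ratios positive numeric ratios `c(train, val, test)`.
#' @param seed integer shuffle seed.
#' @return List of integer index vectors `train`, `val`, `test`; an
#'   exhaustive disjoint partition of `seq_along(labels)`.
#' @export
split_dataset <- function(labels, ratios = c(8, 1, 1), seed = 0L) {
  stopifnot(length(ratios) == 3, all(ratios > 0))
  p <- ratios / sum(ratios)
  r <- local_rng(seed)
  out <- list(train = integer(), val = integer(), test = integer())
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    idx <- idx[order(r$unif(length(idx), 0, 1))]
    n <- length(idx)
    raw <- n * p
    base <- floor(raw)
    rem <- n - sum(base)
    if (rem > 0) {
      # remainder to the largest fractional parts; ties favour train, val
      pri <- order(-(raw - base), seq_along(raw))[seq_len(rem)]
      base[pri] <- base[pri] + 1
    }
    cut1 <- base[1]; cut2 <- base[1] + base[2]
    out$train <- c(out$train, idx[seq_len(cut1)])
    out$val <- c(out$val, if (base[2] > 0) idx[(cut1 + 1):cut2] else integer())
    out$test <- c(out$test, if (base[3] > 0) idx[(cut2 + 1):n] else integer())
  }
  lapply(out, sort)
}

#' Train a nearest-centroid material classifier
#'
#' Features are standardized by the training-set mean and the pooled
#' within-class standard deviation (zero-variance features are
#' dropped); each class is represented by its mean standardized vector.
#' Within-class rather than total SD is the operative choice: it
#' expresses class separations in units of measurement noise, so a
#' feature that carries no class signal stays at unit noise instead of
#' being inflated to compete with the informative ones. The model is
#' transparent and deterministic: the discriminative signal of the
#' birefringence features is low-dimensional, so a closed-form model
#' suffices and keeps evaluation reproducible.
#'
#' @param features numeric matrix (records x features) or data frame.
#' @param labels class label per row.
#' @return Object of class `centroid_model`: `centroids`, `center`,
#'   `scale`, `classes`, `features`.
#' @export
train_centroids <- function(features, labels) {
  x <- as.matrix(features)
  stopifnot(nrow(x) == length(labels), nrow(x) >= 1)
  mu <- colMeans(x)
  sd_tot <- apply(x, 2, stats::sd)
  if (nrow(x) == 1) sd_tot[] <- 0
  # pooled within-class SD; total SD when no class has replicates
  cls <- unique(labels)
  ssw <- 0; dof <- 0
  for (cl in cls) {
    xi <- x[labels == cl, , drop = FALSE]
    if (nrow(xi) > 1) {
      ssw <- ssw + apply(xi, 2, function(v) sum((v - mean(v))^2))
      dof <- dof + nrow(xi) - 1
    }
  }
  sd_ <- if (dof > 0) sqrt(ssw / dof) else sd_tot
  # a feature can be constant within classes yet informative between
  # them: fall back to its total SD
  flat <- is.finite(sd_) & sd_ <= 0 & is.finite(sd_tot) & sd_tot > 0
  sd_[flat] <- sd_tot[flat]
  keep <- which(is.finite(sd_) & sd_ > 0)
  if (!length(keep)) {  # degenerate: all features constant
    keep <- seq_len(ncol(x)); sd_[keep] <- 1
  }
  z <- sweep(sweep(x[, keep, drop = FALSE], 2, mu[keep]), 2, sd_[keep], "/")
  classes <- unique(labels)
  cent <- do.call(rbind, lapply(classes, function(cl)
    colMeans(z[labels == cl, , drop = FALSE])))
  rownames(cent) <- classes
  structure(list(centroids = cent, center = mu[keep], scale = sd_[keep],
                 classes = classes, feature_idx = keep,
                 features = colnames(x)[keep] %||% as.character(keep)),
            class = "centroid_model")
}

#' Predict material classes with a centroid model
#'
#' Nearest centroid in standardized Euclidean distance; ties resolve to
#' the first class in model order. The margin is the distance gap
#' between the two nearest centroids.
#'
#' @param object a `centroid_model`.
#' @param features matrix or data frame of raw feature rows.
#' @param ... unused.
#' @return Data frame with `class` and `margin`.
#' @export
predict.centroid_model <- function(object, features, ...) {
  x <- as.matrix(features)
  x <- if (!is.null(colnames(x)) && all(object$features %in% colnames(x)))
    x[, object$features, drop = FALSE]
  else x[, object$feature_idx %||% seq_along(object$features), drop = FALSE]
  z <- sweep(sweep(x, 2, object$center), 2, object$scale, "/")
  d <- vapply(seq_len(nrow(object$centroids)), function(k)
    sqrt(rowSums(sweep(z, 2, object$centroids[k, ])^2)),
    numeric(nrow(z)))
  d <- matrix(d, nrow = nrow(z))
  best <- apply(d, 1, which.min)   # which.min takes the first on ties
  margin <- apply(d, 1, function(r) {
    s <- sort(r); if (length(s) > 1) s[2] - s[1] else Inf })
  data.frame(class = object$classes[best], margin = margin,
             stringsAsFactors = FALSE)
}

#' Evaluate a classifier on a labelled test set
#'
#' @param model a `centroid_model`.
#' @param features test feature rows.
#' @param labels true labels.
#' @return List with `accuracy`, `confusion` (true classes in rows), `n`.
#' @export
evaluate_model <- function(model, features, labels) {
  pred <- predict(model, features)$class
  classes <- union(model$classes, unique(labels))
  conf <- table(factor(labels, levels = classes),
                factor(pred, levels = classes))
  list(accuracy = mean(pred == labels),
       confusion = unclass(conf), n = length(labels))
}

#' Serialize a centroid model to JSON
#' @param model a `centroid_model`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_centroid_model <- function(model, path) {
  obj <- list(centroids = as.data.frame(model$centroids),
              classes = model$classes, center = model$center,
              scale = model$scale, features = model$features)
  write_atomic(path, function(tmp)
    jsonlite::write_json(obj, tmp, digits = NA, auto_unbox = FALSE))
  invisible(path)
}

#' Read a centroid model from JSON
#' @param path JSON file written by [write_centroid_model()].
#' @return A `centroid_model`.
#' @export
read_centroid_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cent <- as.matrix(obj$centroids)
  rownames(cent) <- obj$classes
  structure(list(centroids = cent,
                 center = stats::setNames(obj$center, obj$features),
                 scale = stats::setNames(obj$scale, obj$features),
                 classes = obj$classes, features = obj$features),
            class = "centroid_model")
}
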