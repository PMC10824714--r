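#' Segmentation parameters
#'
#' @param source image to segment on: `"SSD"` (default), `"amplitude"` or
#'   `"raw_intensity"`.
#' @param threshold `"otsu"` for an automatic bimodal threshold or a
#'   fixed numeric value on the normalized `[0, 1]` image.
#' @param min_area smallest component kept, in pixels (>= 1).
#' @param closing_radius radius of the morphological closing brush in
#'   pixels (0 disables closing).
#' @param fill_holes fill interior holes of each component (fringe
#'   interference regularly punches holes into particle blobs).
#' @param min_signal relative detection floor: in the frame pipeline a
#'   detection image whose maximum is below `min_signal` times the
#'   median Stokes intensity is treated as empty (automatic thresholds
#'   otherwise hallucinate structure in contrast-free frames).
#' @param max_fill sanity bound on the thresholded foreground fraction;
#'   particles are sparse in the flow cell, so a "detection" covering
#'   more than this fraction of the frame is discarded as background.
#' @return An object of class `segmentation_params`.
#' @export
segmentation_params <- function(source = c("SSD", "amplitude", "raw_intensity"),
                                threshold = "otsu", min_area = 30,
                                closing_radius = 2, fill_holes = TRUE,
                                min_signal = 0.03, max_fill = 0.6) {
  source <- match.arg(source)
  if (!identical(threshold, "otsu") && !is.numeric(threshold))
    stop("threshold must be \"otsu\" or a numeric value")
  if (min_area < 1) stop("min_area must be >= 1")
  structure(list(source = source, threshold = threshold,
                 min_area = min_area, closing_radius = closing_radius,
                 fill_holes = isTRUE(fill_holes), min_signal = min_signal,
                 max_fill = max_fill),
            class = "segmentation_params")
}

#' Segment particles from a feature or amplitude image
#'
#' Normalizes the image to `[0, 1]`, thresholds (Otsu by default),
#' applies a morphological closing and hole filling, labels
#' 8-connected components and discards those below the minimum area.
#'
#' @param image single-channel numeric matrix.
#' @param params a [segmentation_params()].
#' @return Integer label matrix (0 = background, 1..k = particles) with
#'   attribute `"n"` giving the number of components; a flat image gives
#'   an all-zero labeling.
#' @export
segment_particles <- function(image, params = segmentation_params()) {
  stopifnot(is.matrix(image), is.numeric(image),
            inherits(params, "segmentation_params"))
  rng <- range(image)
  out0 <- matrix(0L, nrow(image), ncol(image))
  if (!is.finite(rng[1]) || diff(rng) < 1e-12) {
    attr(out0, "n") <- 0L
    return(out0)
  }
  norm <- (image - rng[1]) / diff(rng)
  thr <- if (identical(params$threshold, "otsu"))
    EBImage::otsu(norm, range = c(0, 1)) else params$threshold
  bw <- norm > thr
  if (mean(bw) > (params$max_fill %||% 0.6)) {
    attr(out0, "n") <- 0L
    return(out0)
  }
  if (params$closing_radius > 0) {
    brush <- EBImage::makeBrush(2 * params$closing_radius + 1, shape = "disc")
    bw <- EBImage::closing(bw, brush) > 0
  }
  if (params$fill_holes) bw <- EBImage::fillHull(bw) > 0
  lab <- label_components(bw)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= params$min_area)
  relab <- integer(length(sizes)); relab[keep] <- seq_along(keep)
  out <- matrix(0L, nrow(lab), ncol(lab))
  pos <- lab > 0L
  out[pos] <- relab[lab[pos]]
  attr(out, "n") <- length(keep)
  out
}

#' Label 8-connected components
#'
#' EBImage's `bwlabel` uses 4-connectivity; diagonally touching labels
#' are merged here with a union-find pass so the result is 8-connected.
#'
#' @param bw logical matrix.
#' @return Integer label matrix.
#' @export
label_components <- function(bw) {
  stopifnot(is.matrix(bw))
  lab <- EBImage::bwlabel(bw != 0)
  lab <- matrix(as.integer(round(lab)), nrow(bw), ncol(bw))
  n <- max(lab)
  if (n <= 1L) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  # diagonal neighbour pairs with different positive labels
  a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]    # down-right
  a2 <- lab[-nr, -1];  b2 <- lab[-1, -nc]   # down-left
  sel1 <- a1 > 0L & b1 > 0L & a1 != b1
  sel2 <- a2 > 0L & b2 > 0L & a2 != b2
  pairs <- unique(rbind(cbind(a1[sel1], b1[sel1]), cbind(a2[sel2], b2[sel2])))
  if (!nrow(pairs)) return(lab)
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  for (k in seq_len(nrow(pairs))) {
    ra <- find(pairs[k, 1]); rb <- find(pairs[k, 2])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  root <- vapply(seq_len(n), find, 1L)
  relab <- integer(n); relab[sort(unique(root))] <- seq_along(unique(root))
  out <- lab
  pos <- lab > 0L
  out[pos] <- relab[root[lab[pos]]]
  out
}

#' Convex hull of a mask under the pixel-corner convention
#'
#' Every boundary pixel contributes its four corners (at half-integer
#' offsets), so a single pixel has extent 1 and diagonal `sqrt(2)`. The
#' hull of those corner points is the geometric support used by all
#' caliper measures.
#'
#' @param mask logical (or 0/1) matrix.
#' @return Two-column matrix of hull vertices `(x, y)` in pixel units,
#'   in convex order.
#' @export
mask_hull_points <- function(mask) {
  w <- which(mask != 0, arr.ind = TRUE)
  if (!nrow(w)) stop("empty-region error: mask has no foreground pixels")
  # boundary pixels suffice for the hull
  if (nrow(w) > 8) {
    nr <- nrow(mask); nc <- ncol(mask)
    pad <- matrix(FALSE, nr + 2, nc + 2); pad[2:(nr + 1), 2:(nc + 1)] <- mask != 0
    r <- w[, 1] + 1L; c <- w[, 2] + 1L
    bnd <- !(pad[cbind(r - 1L, c)] & pad[cbind(r + 1L, c)] &
             pad[cbind(r, c - 1L)] & pad[cbind(r, c + 1L)])
    w <- w[bnd, , drop = FALSE]
  }
  x <- rep(w[, 2], each = 4) + c(-0.5, 0.5, -0.5, 0.5)
  y <- rep(w[, 1], each = 4) + c(-0.5, -0.5, 0.5, 0.5)
  pts <- unique(cbind(x, y))
  h <- grDevices::chull(pts)
  pts[h, , drop = FALSE]  # chull returns clockwise order
}

#' Maximum Feret diameter
#'
#' Largest distance between two parallel supporting lines of the
#' particle outline ("length"), computed by rotating calipers over the
#' convex hull of the pixel-corner boundary points.
#'
#' @param mask logical matrix.
#' @param pitch physical pixel size in metres (1 = pixel units).
#' @return Length in the units of `pitch`.
#' @export
max_feret <- function(mask, pitch = 1) {
  v <- mask_hull_points(mask)
  pitch * sqrt(calipers_max_sq(v))
}

# rotating-calipers maximum squared vertex distance on a convex polygon
calipers_max_sq <- function(v) {
  n <- nrow(v)
  if (n == 1) return(0)
  if (n == 2) return(sum((v[1, ] - v[2, ])^2))
  area2 <- function(a, b, c_) abs((b[1] - a[1]) * (c_[2] - a[2]) -
                                  (b[2] - a[2]) * (c_[1] - a[1]))
  best <- 0
  j <- 2L
  nxt <- function(i) if (i == n) 1L else i + 1L
  for (i in seq_len(n)) {
    ii <- nxt(i)
    # advance the antipodal pointer while the supported area grows
    while (area2(v[i, ], v[ii, ], v[nxt(j), ]) >
           area2(v[i, ], v[ii, ], v[j, ])) j <- nxt(j)
    best <- max(best,
                sum((v[i, ] - v[j, ])^2),
                sum((v[ii, ] - v[j, ])^2))
  }
  best
}

#' Minimum Feret diameter
#'
#' Smallest width over all caliper directions ("width"): the minimum,
#' over hull edges, of the largest vertex distance from the edge's
#' supporting line.
#'
#' @param mask logical matrix.
#' @param pitch physical pixel size in metres (1 = pixel units).
#' @return Length in the units of `pitch`.
#' @export
min_feret <- function(mask, pitch = 1) {
  v <- mask_hull_points(mask)
  n <- nrow(v)
  if (n <= 2) return(0)
  widths <- vapply(seq_len(n), function(i) {
    j <- if (i == n) 1L else i + 1L
    d <- v[j, ] - v[i, ]
    len <- sqrt(sum(d^2))
    if (len == 0) return(Inf)
    max(abs((v[, 1] - v[i, 1]) * d[2] - (v[, 2] - v[i, 2]) * d[1]) / len)
  }, 0)
  pitch * min(widths)
}

#' Trace the outer crack boundary of a mask
#'
#' Follows the directed edges between foreground and background pixels
#' (the "crack" lattice at half-integer coordinates) and returns the
#' outer closed loop — the pixel-corner outline of the particle. Holes
#' yield inner loops which are discarded.
#'
#' @param mask logical matrix with at least one foreground pixel.
#' @return Two-column matrix of `(x, y)` polygon vertices.
#' @export
trace_boundary <- function(mask) {
  w <- which(mask != 0, arr.ind = TRUE)
  if (!nrow(w)) stop("empty-region error: mask has no foreground pixels")
  nr <- nrow(mask); nc <- ncol(mask)
  m <- matrix(0L, nr + 2, nc + 2); m[2:(nr + 1), 2:(nc + 1)] <- (mask != 0) + 0L
  idx <- which(m == 1L, arr.ind = TRUE)
  r <- idx[, 1]; c <- idx[, 2]
  up    <- m[cbind(r - 1L, c)] == 0L
  down  <- m[cbind(r + 1L, c)] == 0L
  left  <- m[cbind(r, c - 1L)] == 0L
  right <- m[cbind(r, c + 1L)] == 0L
  e <- rbind(
    if (any(up))    cbind(c[up] - 0.5,  r[up] - 0.5,  c[up] + 0.5,  r[up] - 0.5),
    if (any(right)) cbind(c[right] + 0.5, r[right] - 0.5, c[right] + 0.5, r[right] + 0.5),
    if (any(down))  cbind(c[down] + 0.5, r[down] + 0.5, c[down] - 0.5, r[down] + 0.5),
    if (any(left))  cbind(c[left] - 0.5, r[left] + 0.5, c[left] - 0.5, r[left] - 0.5))
  key <- paste(e[, 1], e[, 2])
  lookup <- split(seq_len(nrow(e)), key)
  used <- rep(FALSE, nrow(e))
  best <- NULL; best_area <- -1
  for (i0 in seq_len(nrow(e))) {
    if (used[i0]) next
    verts <- matrix(NA_real_, nrow(e) + 1L, 2); nv <- 0L
    i <- i0
    repeat {
      used[i] <- TRUE; nv <- nv + 1L
      verts[nv, ] <- e[i, 1:2]
      nxt <- lookup[[paste(e[i, 3], e[i, 4])]]
      nxt <- nxt[!used[nxt]]
      if (!length(nxt)) break
      if (length(nxt) > 1L) {
        # saddle vertex: prefer the sharper turn to keep loops separate
        dx <- e[i, 3] - e[i, 1]; dy <- e[i, 4] - e[i, 2]
        cr <- (e[nxt, 3] - e[nxt, 1]) * dy - (e[nxt, 4] - e[nxt, 2]) * dx
        nxt <- nxt[which.max(cr)]
      }
      i <- nxt[1]
    }
    verts <- verts[seq_len(nv), , drop = FALSE]
    a <- abs(sum(verts[, 1] * c(verts[-1, 2], verts[1, 2]) -
                 c(verts[-1, 1], verts[1, 1]) * verts[, 2])) / 2
    if (a > best_area) { best_area <- a; best <- verts }
  }
  # translate from padded back to original pixel coordinates
  best - 1
}

#' Particle perimeter
#'
#' Length of the traced pixel-corner outline after `smooth_iter`
#' midpoint-smoothing passes. The raw crack outline overestimates the
#' length of oblique edges (staircase effect); two midpoint passes make
#' the estimate exact for axis-aligned and 45-degree edges and accurate
#' to a few percent for smooth outlines.
#'
#' @param mask logical matrix.
#' @param pitch physical pixel size in metres (1 = pixel units).
#' @param smooth_iter midpoint-smoothing iterations (default 2).
#' @return Perimeter in the units of `pitch`.
#' @export
particle_perimeter <- function(mask, pitch = 1, smooth_iter = 2) {
  v <- trace_boundary(mask)
  for (i in seq_len(smooth_iter))
    v <- (v + rbind(v[-1, , drop = FALSE], v[1, , drop = FALSE])) / 2
  d <- rbind(v[-1, , drop = FALSE], v[1, , drop = FALSE]) - v
  pitch * sum(sqrt(rowSums(d^2)))
}

#' Circularity
#'
#' Perimeter-equivalence circularity `C = 2*sqrt(pi*A)/P` (the
#' convention of optical morphometry instruments): the ratio of the
#' perimeter of the area-equivalent circle to the measured perimeter,
#' 1 for a perfect circle. The squared form `4*pi*A/P^2` is available
#' via `form = "squared"`.
#'
#' @param mask logical matrix.
#' @param pitch physical pixel size (cancels; accepted for interface
#'   symmetry).
#' @param form `"perimeter_equivalence"` (default) or `"squared"`.
#' @return Dimensionless circularity.
#' @export
circularity <- function(mask, pitch = 1,
                        form = c("perimeter_equivalence", "squared")) {
  form <- match.arg(form)
  a <- sum(mask != 0)
  if (a == 0) stop("empty-region error: mask has no foreground pixels")
  p <- particle_perimeter(mask, 1)
  if (p <= 0) stop("degenerate mask: zero perimeter")
  c_pe <- 2 * sqrt(pi * a) / p
  if (form == "squared") c_pe^2 else c_pe
}

#' Sphere-equivalent volume
#'
#' `(pi/6) * CED^3` with the circular-equivalent diameter
#' `CED = 2*sqrt(A/pi)` of the projected area.
#'
#' @param mask logical matrix.
#' @param pitch physical pixel size in metres.
#' @return Volume in `pitch^3` units.
#' @export
se_volume <- function(mask, pitch = 1) {
  a <- sum(mask != 0)
  if (a == 0) stop("empty-region error: mask has no foreground pixels")
  ced <- 2 * sqrt(a / pi)
  (pi / 6) * ced^3 * pitch^3
}

# solidity: mask area over its convex hull area (shoelace on hull points)
mask_solidity <- function(mask) {
  a <- sum(mask != 0)
  v <- mask_hull_points(mask)
  hull_a <- abs(sum(v[, 1] * c(v[-1, 2], v[1, 2]) -
                    c(v[-1, 1], v[1, 1]) * v[, 2])) / 2
  if (hull_a == 0) return(1)
  min(a / hull_a, 1)
}

#' Default shape-classification thresholds
#' @return Named list of the rule thresholds.
#' @export
shape_rules <- function() {
  list(fiber_aspect = 5,
       bead_circularity = 0.92, bead_aspect = 1.2,
       pellet_circularity = 0.85, pellet_aspect = 1.5,
       foam_solidity = 0.85,
       film_transmittance = 0.9, film_area_px = 2000)
}

#' Classify particle shape
#'
#' Rule cascade over the morphometric descriptors, applied in a fixed
#' order: fiber (aspect `MFD/width >= 5`), bead (circularity >= 0.92 and
#' aspect <= 1.2), pellet (circularity >= 0.85 and aspect <= 1.5), foam
#' (solidity < 0.85), film (mean transmittance >= 0.9 and area above a
#' size threshold), else fragment.
#'
#' @param record one-row data frame (or list) with `mfd`, `width`,
#'   `circularity`, `solidity`, `area_px` and optionally `transmittance`.
#' @param rules threshold list, see [shape_rules()].
#' @return Character shape class.
#' @export
classify_shape <- function(record, rules = shape_rules()) {
  aspect <- record$mfd / max(record$width, .Machine$double.eps)
  tr <- if (!is.null(record$transmittance) && is.finite(record$transmittance))
    record$transmittance else 0
  if (aspect >= rules$fiber_aspect) return("fiber")
  if (record$circularity >= rules$bead_circularity &&
      aspect <= rules$bead_aspect) return("bead")
  if (record$circularity >= rules$pellet_circularity &&
      aspect <= rules$pellet_aspect) return("pellet")
  if (record$solidity < rules$foam_solidity) return("foam")
  if (tr >= rules$film_transmittance &&
      record$area_px >= rules$film_area_px) return("film")
  "fragment"
}

#' Measure all particles of a label image
#'
#' Computes, for every labelled component, the full morphometric record:
#' centroid, area, Feret diameters, circularity, sphere-equivalent
#' volume, solidity, shape class, and (when feature maps are supplied)
#' mean and 90th-percentile SSD, mean DoLP, and mean relative
#' transmittance within the mask.
#'
#' @param labels integer label matrix from [segment_particles()].
#' @param pitch physical pixel size in metres.
#' @param ssd optional SSD `feature_map` or matrix.
#' @param dolp optional DoLP `feature_map` or matrix.
#' @param amplitude optional reconstructed-amplitude matrix used for the
#'   transmittance estimate (mask mean over background median).
#' @param rules shape thresholds, see [shape_rules()].
#' @return Data frame with one row per particle; lengths in micrometres,
#'   areas in square micrometres, volumes in cubic micrometres.
#' @export
measure_particles <- function(labels, pitch, ssd = NULL, dolp = NULL,
                              amplitude = NULL, rules = shape_rules()) {
  fmv <- function(x) if (inherits(x, "feature_map")) x$values else x
  ssd <- fmv(ssd); dolp <- fmv(dolp)
  n <- max(labels)
  um <- pitch * 1e6
  bg_amp <- if (!is.null(amplitude)) stats::median(amplitude[labels == 0]) else NA_real_
  rows <- vector("list", n)
  for (id in seq_len(n)) {
    mask <- labels == id
    w <- which(mask, arr.ind = TRUE)
    area_px <- nrow(w)
    mfd <- max_feret(mask, 1)
    wid <- min_feret(mask, 1)
    circ <- circularity(mask)
    sol <- mask_solidity(mask)
    tr <- if (!is.null(amplitude) && bg_amp > 0)
      mean(amplitude[mask]) / bg_amp else NA_real_
    rec <- list(mfd = mfd, width = wid, circularity = circ, solidity = sol,
                area_px = area_px, transmittance = tr)
    rows[[id]] <- data.frame(
      id = id,
      cx_px = mean(w[, 2]), cy_px = mean(w[, 1]),
      area_um2 = area_px * um^2,
      mfd_um = mfd * um, width_um = wid * um,
      perimeter_um = particle_perimeter(mask, um),
      circularity = circ, solidity = sol,
      se_volume_um3 = se_volume(mask, um),
      shape = classify_shape(rec, rules),
      transmittance = tr,
      ssd_mean = if (!is.null(ssd)) mean(ssd[mask]) else NA_real_,
      ssd_p90 = if (!is.null(ssd))
        unname(stats::quantile(ssd[mask], 0.9)) else NA_real_,
      dolp_mean = if (!is.null(dolp)) mean(dolp[mask]) else NA_real_,
      material = NA_character_,
      stringsAsFactors = FALSE)
  }
  if (!n) return(data.frame())
  do.call(rbind, rows)
}

#' Size-by-material heatmap counts
#'
#' Counts particle records by maximum Feret diameter bin (half-open
#' `[lo, hi)`) and material label.
#'
#' @param records data frame with columns `mfd_um` (or `mfd`) and
#'   `material`.
#' @param size_bin_edges increasing numeric bin edges in the same units
#'   as the MFD column.
#' @param mfd_column which column holds the MFD.
#' @return Integer matrix, materials in rows, size bins in columns.
#' @export
size_material_heatmap <- function(records, size_bin_edges,
                                  mfd_column = "mfd_um") {
  stopifnot(length(size_bin_edges) >= 2, !is.unsorted(size_bin_edges))
  mats <- sort(unique(stats::na.omit(records$material)))
  nb <- length(size_bin_edges) - 1
  bin_names <- sprintf("[%g,%g)", size_bin_edges[-length(size_bin_edges)],
                       size_bin_edges[-1])
  out <- matrix(0L, length(mats), nb, dimnames = list(mats, bin_names))
  if (!nrow(records) || !length(mats)) return(out)
  keep <- !is.na(records$material)
  mfd <- records[[mfd_column]][keep]
  mat <- records$material[keep]
  bin <- findInterval(mfd, size_bin_edges, rightmost.closed = FALSE,
                      left.open = FALSE)
  ok <- bin >= 1 & bin <= nb & mfd < size_bin_edges[length(size_bin_edges)]
  for (k in which(ok)) out[mat[k], bin[k]] <- out[mat[k], bin[k]] + 1L
  out
}
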