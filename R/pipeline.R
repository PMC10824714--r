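#' Process one polarization mosaic frame
#'
#' The per-frame analysis chain: de-interleave the mosaic, compute the
#' polarimetric maps on the raw channels (SSD and DoLP inside a
#' particle's geometric shadow approximate their object-plane closed
#' forms), back-propagate the four channel holograms to the object plane
#' (DC-suppressed), and segment particles on the in-focus mean
#' reconstruction amplitude, where the support is sharpest.
#'
#' @param mosaic mosaic intensity matrix.
#' @param cfg an [optical_config()].
#' @param layout a [mosaic_layout()].
#' @param z reconstruction depth in metres (defaults to the configured
#'   propagation distance).
#' @param seg a [segmentation_params()]; its `source` selects the
#'   detection image (`"amplitude"` = mean reconstruction amplitude,
#'   `"SSD"` = raw-stack SSD, `"raw_intensity"` = Stokes I).
#' @param frame frame index attached to the detections.
#' @param feature_erosion radius (px) by which masks are eroded before
#'   polarimetric feature statistics, suppressing boundary fringe mixing;
#'   the erosion is skipped when fewer than 9 pixels would remain.
#' @return List: `stack` (raw channels), `ssd`, `dolp`, `stokes`,
#'   `amplitude` (mean reconstruction amplitude), `labels`,
#'   `detections`.
#' @export
process_frame <- function(mosaic, cfg, layout = mosaic_layout(),
                          z = cfg$propagation_distance,
                          seg = segmentation_params(source = "amplitude"),
                          frame = 1L, feature_erosion = 2) {
  stack <- split_mosaic(mosaic, layout, pitch = cfg$channel_pitch)
  st <- stokes_maps(stack)
  ssd <- ssd_map(stack)
  dolp <- dolp_map(st)
  chans <- lapply(c("I0", "I45", "I90", "I135"), function(nm) {
    m <- stack[[nm]]; m - mean(m)   # DC suppression before back-propagation
  })
  rec <- propagate_many(chans, object_pixel_size(cfg), cfg$wavelength, -z)
  amp <- Reduce(`+`, lapply(rec, Mod)) / 4
  # twin-image rings oscillate in phase while the in-focus object term is
  # phase-coherent: smoothing the complex field before taking the modulus
  # suppresses the halo, giving a clean candidate-detection image
  K <- gaussian_kernel(3)
  amp_smooth <- Reduce(`+`, lapply(rec, function(g)
    Mod(EBImage::filter2(Re(g), K) + 1i * EBImage::filter2(Im(g), K)))) / 4
  det_img <- switch(seg$source,
                    amplitude = amp,
                    SSD = ssd$values,
                    raw_intensity = st$I)
  coarse_img <- if (seg$source == "amplitude") amp_smooth else det_img
  floor_abs <- (seg$min_signal %||% 0.03) *
    stats::median(st$I) * (if (seg$source == "raw_intensity") 0 else 1)
  labels <- segment_adaptive(det_img, floor_abs, seg, coarse_image = coarse_img)
  det <- detect_frame_from_labels(labels, frame, object_pixel_size(cfg),
                                  ssd = ssd, dolp = dolp,
                                  intensity = st$I,
                                  erosion = feature_erosion)
  list(stack = stack, stokes = st, ssd = ssd, dolp = dolp, amplitude = amp,
       labels = labels, detections = det)
}

#' Adaptive per-candidate segmentation of a detection image
#'
#' Frames can contain particles of very different contrast (weakly and
#' strongly birefringent materials together), where one global automatic
#' threshold drops the faint ones. This detector first finds candidate
#' blobs above an absolute signal floor, then re-thresholds each
#' candidate with an automatic bimodal (Otsu) threshold computed inside
#' its own bounding-box neighbourhood — so every particle is separated
#' from its local background and diffraction halo at its own contrast —
#' before the usual closing, hole-filling and minimum-area filtering.
#'
#' @param image detection image (in-focus amplitude or SSD).
#' @param floor_abs absolute signal floor; below it nothing is detected.
#' @param params a [segmentation_params()] (closing, fill, min_area).
#' @param margin_px bounding-box margin for the local refinement.
#' @param coarse_image image used for candidate finding (defaults to
#'   `image`); the frame pipeline passes a complex-smoothed amplitude
#'   whose twin-image halo is suppressed.
#' @return Integer label matrix with attribute `"n"`.
#' @export
segment_adaptive <- function(image, floor_abs, params = segmentation_params(),
                             margin_px = 10, coarse_image = image) {
  ny <- nrow(image); nx <- ncol(image)
  out0 <- structure(matrix(0L, ny, nx), n = 0L)
  if (max(coarse_image) < floor_abs) return(out0)
  # dilate the coarse mask so a particle's residual diffraction rings
  # join its own candidate blob instead of seeding separate objects
  coarse_bw <- EBImage::dilate(coarse_image > floor_abs,
                               EBImage::makeBrush(9, "disc")) > 0
  coarse <- label_components(coarse_bw)
  ncand <- max(coarse)
  if (!ncand) return(out0)
  sizes <- tabulate(coarse[coarse > 0L])
  bw <- matrix(FALSE, ny, nx)
  for (id in which(sizes >= max(4, params$min_area / 4))) {
    sel <- coarse == id
    w <- which(sel, arr.ind = TRUE)
    r0 <- max(1, min(w[, 1]) - margin_px); r1 <- min(ny, max(w[, 1]) + margin_px)
    c0 <- max(1, min(w[, 2]) - margin_px); c1 <- min(nx, max(w[, 2]) + margin_px)
    roi_img <- image[r0:r1, c0:c1]
    rng <- range(roi_img)
    if (diff(rng) < 1e-12) next
    norm <- (roi_img - rng[1]) / diff(rng)
    thr <- rng[1] + EBImage::otsu(norm, range = c(0, 1)) * diff(rng)
    bw[r0:r1, c0:c1] <- bw[r0:r1, c0:c1] | (roi_img > max(thr, floor_abs))
  }
  if (mean(bw) > (params$max_fill %||% 0.6)) return(out0)
  if (params$closing_radius > 0) {
    brush <- EBImage::makeBrush(2 * params$closing_radius + 1, shape = "disc")
    bw <- EBImage::closing(bw, brush) > 0
  }
  if (params$fill_holes) bw <- EBImage::fillHull(bw) > 0
  lab <- label_components(bw)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= params$min_area)
  relab <- integer(length(sizes)); relab[keep] <- seq_along(keep)
  out <- matrix(0L, ny, nx)
  pos <- lab > 0L
  out[pos] <- relab[lab[pos]]
  attr(out, "n") <- length(keep)
  out
}

# normalized 2-D Gaussian kernel, support 3 sigma
gaussian_kernel <- function(sigma) {
  n <- 2 * ceiling(3 * sigma) + 1
  x <- seq(-(n - 1) / 2, (n - 1) / 2)
  k <- exp(-outer(x^2, x^2, "+") / (2 * sigma^2))
  k / sum(k)
}

# measure + feature-extract from an existing labeling; polarimetric
# statistics use an eroded core mask when enough pixels remain
detect_frame_from_labels <- function(labels, frame, pitch, ssd, dolp,
                                     intensity, erosion = 2) {
  n <- max(labels)
  empty <- data.frame(frame = integer(), det = integer(), cx = numeric(),
                      cy = numeric(), area_px = integer(), mfd_um = numeric(),
                      width_um = numeric(), area_um2 = numeric(),
                      circularity = numeric(), solidity = numeric(),
                      se_volume_um3 = numeric(), shape = character(),
                      ssd_mean = numeric(), ssd_p90 = numeric(),
                      dolp_mean = numeric(), transmittance = numeric())
  if (!n) { attr(empty, "labels") <- labels; return(empty) }
  um <- pitch * 1e6
  bg_int <- stats::median(intensity[labels == 0])
  brush <- if (erosion > 0) EBImage::makeBrush(2 * erosion + 1, "disc") else NULL
  rows <- vector("list", n)
  for (id in seq_len(n)) {
    mask <- labels == id
    core <- mask
    if (!is.null(brush)) {
      er <- EBImage::erode(mask, brush) > 0
      if (sum(er) >= 9) core <- er
    }
    w <- which(mask, arr.ind = TRUE)
    mfd <- max_feret(mask, 1); wid <- min_feret(mask, 1)
    circ <- circularity(mask); sol <- mask_solidity(mask)
    tr <- if (is.finite(bg_int) && bg_int > 0)
      mean(intensity[core]) / bg_int else NA_real_
    fx <- extract_features(core, ssd, dolp)
    rec <- list(mfd = mfd, width = wid, circularity = circ, solidity = sol,
                area_px = nrow(w), transmittance = tr)
    rows[[id]] <- data.frame(
      frame = frame, det = id,
      cx = mean(w[, 2]), cy = mean(w[, 1]),
      area_px = nrow(w), mfd_um = mfd * um, width_um = wid * um,
      area_um2 = nrow(w) * um^2, circularity = circ, solidity = sol,
      se_volume_um3 = se_volume(mask, um),
      shape = classify_shape(rec),
      ssd_mean = unname(fx["ssd_mean"]), ssd_p90 = unname(fx["ssd_p90"]),
      dolp_mean = unname(fx["dolp_mean"]), transmittance = tr,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "labels") <- labels
  out
}

#' Default association gate from the expected flow displacement
#'
#' Twice the expected per-frame displacement plus 10 px.
#'
#' @param flow a [flow_spec()].
#' @param cfg an [optical_config()].
#' @return Gate radius in pixels.
#' @export
auto_gate <- function(flow, cfg) {
  disp <- mean_flow_speed(flow) * 1e-3 / flow$frames_per_second /
    object_pixel_size(cfg)
  2 * disp + 10
}

#' Run the full analysis pipeline on a mosaic video
#'
#' simulate/capture -> features -> reconstruct -> segment -> track ->
#' classify -> report. Emits (under `config$output_dir`, when set) the
#' per-frame SSD and DoLP feature maps, the particle and track tables as
#' CSV, the label masks as PNG, and a JSON summary. Deterministic for a
#' fixed config and input.
#'
#' @param config a `run_config` (see [read_run_config()]) or a list
#'   acceptable to it.
#' @param input list of mosaic matrices, or a path accepted by
#'   [read_mosaic_video()].
#' @param truth optional ground truth from [render_video()] for scoring.
#' @return List: `detections`, `tracks`, `report` (a `count_report`),
#'   `particles` (per-track summary with material), `heatmap`,
#'   `summary` (the JSON-serializable run summary).
#' @export
run_pipeline <- function(config, input, truth = NULL) {
  config <- if (inherits(config, "run_config")) config else read_run_config(config)
  frames <- if (is.character(input)) read_mosaic_video(input) else input
  cfg <- config$optical
  z <- config$reconstruction_z %||% cfg$propagation_distance
  seg <- config$segmentation %||% segmentation_params(source = "amplitude")
  flow <- if (!is.null(config$flow)) do.call(flow_spec, as.list(config$flow))
          else flow_spec()
  trk <- config$tracking
  gate <- trk$gate_px %||% auto_gate(flow, cfg)
  outdir <- config$output_dir
  stage <- function(name, expr) tryCatch(expr, error = function(e)
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))

  det_list <- vector("list", length(frames))
  for (f in seq_along(frames)) {
    pf <- stage("features", process_frame(frames[[f]], cfg, config$layout,
                                          z = z, seg = seg, frame = f))
    det_list[[f]] <- pf$detections
    if (!is.null(outdir)) {
      stage("write", {
        write_feature_tiff(pf$ssd, file.path(outdir, sprintf("ssd_%04d.tiff", f)))
        write_feature_tiff(pf$dolp, file.path(outdir, sprintf("dolp_%04d.tiff", f)))
        write_label_png(pf$labels, file.path(outdir, sprintf("labels_%04d.png", f)))
      })
    }
  }
  detections <- do.call(rbind, det_list)
  tracks <- stage("track", link_tracks(detections, gate_px = gate,
                                       m_confirm = trk$m_confirm %||% 3,
                                       k_miss = trk$k_miss %||% 5))
  report <- stage("count", count_and_score(tracks, truth,
                                           match_radius_px = trk$match_radius_px %||% 15))

  model <- NULL
  if (!is.null(config$classification$model_file))
    model <- stage("classify", read_centroid_model(config$classification$model_file))
  particles <- stage("report", summarize_tracks(tracks, detections, model))
  heat <- size_material_heatmap(particles,
                                size_bin_edges = c(0, 100, 200, 400, 800, 1600, 1e9))
  summary <- list(
    n_frames = length(frames),
    n_detections = nrow(detections),
    count = report$count,
    counting_accuracy = report$counting_accuracy %||% NA,
    gate_px = gate,
    seed = config$seed,
    parameters = list(z = z, source = seg$source,
                      min_area = seg$min_area,
                      m_confirm = trk$m_confirm %||% 3,
                      k_miss = trk$k_miss %||% 5))
  if (!is.null(outdir)) {
    stage("write", {
      write_atomic(file.path(outdir, "particles.csv"), function(tmp)
        utils::write.csv(particles, tmp, row.names = FALSE))
      write_atomic(file.path(outdir, "tracks.csv"), function(tmp)
        utils::write.csv(tracks_table(tracks), tmp, row.names = FALSE))
      write_atomic(file.path(outdir, "summary.json"), function(tmp)
        jsonlite::write_json(summary, tmp, auto_unbox = TRUE, digits = 10,
                             pretty = TRUE))
    })
  }
  list(detections = detections, tracks = tracks, report = report,
       particles = particles, heatmap = heat, summary = summary)
}

# long-format track table (track_id, frame, cx, cy, state)
tracks_table <- function(tracks) {
  if (!length(tracks)) return(data.frame(track_id = integer(),
                                         frame = integer(), cx = numeric(),
                                         cy = numeric(), state = character()))
  do.call(rbind, lapply(tracks, function(t)
    data.frame(track_id = t$id, frame = t$frames, cx = t$cx, cy = t$cy,
               state = t$state, stringsAsFactors = FALSE)))
}

# one row per counted track: median morphometry, mean features, material
summarize_tracks <- function(tracks, detections, model = NULL) {
  counted <- Filter(function(t) isTRUE(t$ever_confirmed), tracks)
  if (!length(counted))
    return(data.frame(track_id = integer(), mfd_um = numeric(),
                      area_um2 = numeric(), material = character()))
  rows <- lapply(counted, function(t) {
    d <- detections[t$det_rows, , drop = FALSE]
    # polarimetric statistics only from fully visible frames: detections
    # clipped at the frame border dilute the features
    full <- d[d$area_px >= 0.8 * max(d$area_px), , drop = FALSE]
    data.frame(track_id = t$id,
               n_detections = nrow(d),
               mfd_um = stats::median(full$mfd_um),
               width_um = stats::median(full$width_um),
               area_um2 = stats::median(full$area_um2),
               circularity = stats::median(full$circularity),
               se_volume_um3 = stats::median(full$se_volume_um3),
               shape = names(which.max(table(full$shape))),
               ssd_mean = stats::median(full$ssd_mean),
               ssd_p90 = stats::median(full$ssd_p90),
               dolp_mean = stats::median(full$dolp_mean),
               transmittance = stats::median(full$transmittance),
               material = NA_character_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(model)) {
    feats <- out[, model$features, drop = FALSE]
    out$material <- predict(model, feats)$class
  }
  out
}
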