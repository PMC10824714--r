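#' Build one easy flowing-video scene for the counting battery
#'
#' Up to five well-separated particles in distinct lateral lanes, drawn
#' from the six plastic materials with a narrow retardance spread
#' (`retardance_sd = 0.02` rad, at least 4 pooled SD between adjacent
#' class means), sizes 170-310 um, shapes bead/pellet/fragment.
#' Particles start at staggered positions along the flow axis, some
#' upstream of the field of view so they enter during the video.
#'
#' @param seed scene seed; fully determines the draw.
#' @param fov channel field of view in pixels (square).
#' @param cfg an [optical_config()].
#' @param noise a [noise_spec()].
#' @param n_frames video length used to bound the start positions.
#' @param flow a [flow_spec()].
#' @return A [scene_spec()].
#' @export
battery_scene <- function(seed, fov = 256L, cfg = optical_config(),
                          noise = noise_spec(), n_frames = 60,
                          flow = flow_spec()) {
  mats <- default_materials(retardance_sd = 0.02)
  plastics <- c("PMMA", "PS", "PVC", "PC", "PP", "PET")
  pitch <- object_pixel_size(cfg)
  disp <- mean_flow_speed(flow) * 1e-3 / flow$frames_per_second / pitch
  r <- local_rng(seed + 577L)
  n <- 3L + r$int(1, 0, 1)               # 3 or 4 particles
  # four lanes with guaranteed lateral clearance: spacing minus jitter
  # always exceeds the largest possible particle diameter plus the
  # closing radius, so distinct-lane particles can never merge
  lanes <- (2 * seq_len(4) - 1) / 8 * fov
  lane_pick <- order(r$unif(4, 0, 1))[seq_len(n)]
  mat_pick <- plastics[((r$int(1, 0, 5) + seq_len(n) - 1L) %% 6L) + 1L]
  shapes <- c("bead", "pellet", "fragment")[r$int(n, 1, 3)]
  sizes <- r$unif(n, 170e-6, 310e-6)
  # start so every particle is fully visible for >= ~13 frames
  x_lo <- -(disp * (n_frames - 18) - 1) * pitch
  x_hi <- 180 * pitch
  xs <- r$unif(n, x_lo / pitch, x_hi / pitch) * pitch
  ys <- (lanes[lane_pick] + r$unif(n, -4, 4)) * pitch
  thetas <- r$unif(n, 0, pi)
  particles <- lapply(seq_len(n), function(i)
    particle_spec(shapes[i], sizes[i], c(xs[i], ys[i]), thetas[i],
                  mats[[mat_pick[i]]]))
  scene_spec(particles, field_of_view = c(fov, fov), noise = noise,
             seed = seed, strict = FALSE)
}

#' Counting-and-classification battery on easy synthetic videos
#'
#' The end-to-end surrogate experiment: renders flowing-particle videos
#' (alternating noiseless and mildly noisy), runs the per-frame feature
#' and reconstruction chain, detects, tracks and counts particles,
#' extracts per-track polarimetric features, trains the nearest-centroid
#' material classifier on an 8:1:1 stratified split of the tracked
#' particles, and reports the pooled fraction of ground-truth particles
#' that are both correctly counted (trajectory overlap >= 50% with a
#' confirmed track) and correctly classified.
#'
#' @param seed base seed; video v uses scene seed `seed + v - 1`.
#' @param n_videos number of videos.
#' @param n_frames frames per video.
#' @param fov channel resolution (square).
#' @param verbose print per-video progress.
#' @return List: `combined_rate_percent`, `counting_rate`,
#'   `classification_rate`, `n_truth`, `particles` (per-truth-particle
#'   table), `model`.
#' @export
counting_classification_battery <- function(seed = 0L, n_videos = 20L,
                                            n_frames = 60L, fov = 256L,
                                            verbose = FALSE) {
  cfg <- optical_config()
  flow <- flow_spec()
  layout <- mosaic_layout()
  seg <- segmentation_params(source = "amplitude")
  gate <- auto_gate(flow, cfg)
  mild <- noise_spec(background_scatter_sd = 0.01, shot_noise_scale = 0.01,
                     read_noise_sd = 0.002)
  rows <- list()
  for (v in seq_len(n_videos)) {
    vseed <- as.integer(seed) + v - 1L
    noise <- if (v %% 2L == 0L) mild else noise_spec()
    scene <- battery_scene(vseed, fov = fov, cfg = cfg, noise = noise,
                           n_frames = n_frames, flow = flow)
    vid <- render_video(scene, flow, n_frames, cfg, seed = vseed)
    det_list <- vector("list", n_frames)
    for (f in seq_len(n_frames)) {
      pf <- process_frame(vid$frames[[f]], cfg, layout, seg = seg, frame = f)
      det_list[[f]] <- pf$detections
    }
    detections <- do.call(rbind, det_list)
    tracks <- link_tracks(detections, gate_px = gate)
    rep <- count_and_score(tracks, vid$truth)
    feats <- summarize_tracks(tracks, detections)
    truth_mat <- stats::setNames(vid$truth$particles$material,
                                 vid$truth$particles$id)
    pp <- rep$per_particle
    if (!is.null(pp) && nrow(pp)) {
      for (k in seq_len(nrow(pp))) {
        tid <- pp$track_id[k]
        fr <- if (!is.na(tid)) feats[feats$track_id == tid, , drop = FALSE]
              else feats[0, , drop = FALSE]
        rows[[length(rows) + 1]] <- data.frame(
          video = v, truth_id = pp$truth_id[k],
          material = unname(truth_mat[as.character(pp$truth_id[k])]),
          counted = pp$correct[k],
          track_id = tid,
          ssd_mean = if (nrow(fr)) fr$ssd_mean else NA_real_,
          ssd_p90 = if (nrow(fr)) fr$ssd_p90 else NA_real_,
          dolp_mean = if (nrow(fr)) fr$dolp_mean else NA_real_,
          transmittance = if (nrow(fr)) fr$transmittance else NA_real_,
          stringsAsFactors = FALSE)
      }
    }
    if (verbose)
      message(sprintf("video %d/%d: truth %d, counted %d", v, n_videos,
                      rep$true_count, rep$count))
  }
  tab <- do.call(rbind, rows)
  has_feat <- !is.na(tab$ssd_mean)
  feat_cols <- c("ssd_mean", "ssd_p90", "dolp_mean", "transmittance")
  idx <- which(has_feat)
  split <- split_dataset(tab$material[idx], ratios = c(8, 1, 1),
                         seed = seed + 9001L)
  train_idx <- idx[split$train]
  model <- train_centroids(tab[train_idx, feat_cols], tab$material[train_idx])
  tab$predicted <- NA_character_
  tab$predicted[idx] <- predict(model, tab[idx, feat_cols])$class
  tab$class_correct <- !is.na(tab$predicted) & tab$predicted == tab$material
  tab$combined <- tab$counted & tab$class_correct
  list(combined_rate_percent = 100 * mean(tab$combined),
       counting_rate = mean(tab$counted),
       classification_rate = mean(tab$class_correct),
       n_truth = nrow(tab),
       particles = tab,
       model = model)
}
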