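#' Detect particles in one frame
#'
#' Segments the frame's detection image and returns one detection per
#' mask: centroid, bounding box and a feature snapshot (area, maximum
#' Feret diameter) plus any polarimetric statistics the caller supplies.
#'
#' @param image single-channel detection image (typically an SSD map).
#' @param params a [segmentation_params()].
#' @param frame integer frame index stored with each detection.
#' @param pitch physical pixel size in metres.
#' @param ssd,dolp,amplitude optional maps forwarded to
#'   [measure_particles()].
#' @return Data frame of detections (possibly empty) and the label
#'   matrix as attribute `"labels"`.
#' @export
detect_frame <- function(image, params = segmentation_params(), frame = 1L,
                         pitch = 6.9e-6, ssd = NULL, dolp = NULL,
                         amplitude = NULL) {
  labels <- segment_particles(image, params)
  recs <- measure_particles(labels, pitch, ssd = ssd, dolp = dolp,
                            amplitude = amplitude)
  if (!nrow(recs)) {
    out <- data.frame(frame = integer(), det = integer(), cx = numeric(),
                      cy = numeric(), x0 = numeric(), x1 = numeric(),
                      y0 = numeric(), y1 = numeric())
    attr(out, "labels") <- labels
    return(out)
  }
  bbox <- t(vapply(seq_len(max(labels)), function(id) {
    w <- which(labels == id, arr.ind = TRUE)
    c(min(w[, 2]), max(w[, 2]), min(w[, 1]), max(w[, 1]))
  }, numeric(4)))
  out <- cbind(data.frame(frame = frame, det = seq_len(nrow(recs)),
                          cx = recs$cx_px, cy = recs$cy_px,
                          x0 = bbox[, 1], x1 = bbox[, 2],
                          y0 = bbox[, 3], y1 = bbox[, 4]),
               recs[, setdiff(names(recs), c("id", "cx_px", "cy_px"))])
  attr(out, "labels") <- labels
  out
}

#' Link per-frame detections into tracks
#'
#' Deterministic constant-velocity greedy linker: each live track
#' predicts its next position as last position plus velocity; detections
#' are greedily assigned to the nearest predicted track within
#' `gate_px` (distance ties resolved toward the lower track id, then the
#' lower detection index). Unmatched detections spawn tentative tracks;
#' a track is confirmed after `m_confirm` consecutive hits and
#' terminated after `k_miss` consecutive misses. Velocity is the
#' difference of the last two matched positions (zero for
#' single-detection tracks).
#'
#' @param detections data frame with columns `frame`, `cx`, `cy` (e.g.
#'   rbind-ed outputs of [detect_frame()]).
#' @param gate_px association gate radius in pixels (> 0).
#' @param m_confirm consecutive hits required for confirmation.
#' @param k_miss consecutive misses before termination.
#' @return List of track records: `id`, `state`, `frames`, `cx`, `cy`,
#'   `velocity`, `n_hits`.
#' @export
link_tracks <- function(detections, gate_px, m_confirm = 3, k_miss = 5) {
  if (!is.numeric(gate_px) || gate_px <= 0)
    stop("gate_px must be a positive number")
  tracks <- list()
  next_id <- 1L
  frames <- sort(unique(detections$frame))
  for (f in frames) {
    rows <- which(detections$frame == f)
    det <- detections[rows, , drop = FALSE]
    live <- which(vapply(tracks, function(t) t$state != "terminated", TRUE))
    live <- live[order(vapply(tracks[live], function(t) t$id, 1L))]
    matched_trk <- integer(0); matched_det <- integer(0)
    if (length(live) && nrow(det)) {
      pred <- t(vapply(tracks[live], function(t)
        c(t$cx[length(t$cx)], t$cy[length(t$cy)]) + t$velocity, numeric(2)))
      d2 <- outer(seq_along(live), seq_len(nrow(det)),
                  Vectorize(function(i, j)
                    (pred[i, 1] - det$cx[j])^2 + (pred[i, 2] - det$cy[j])^2))
      repeat {
        d2v <- d2
        if (!length(d2v) || all(!is.finite(d2v)) || min(d2v) > gate_px^2) break
        # lowest distance; ties -> lower track id (rows ordered by id), then det
        ij <- which(d2 == min(d2), arr.ind = TRUE)
        ij <- ij[order(ij[, 1], ij[, 2]), , drop = FALSE][1, ]
        matched_trk <- c(matched_trk, live[ij[1]])
        matched_det <- c(matched_det, ij[2])
        d2[ij[1], ] <- Inf; d2[, ij[2]] <- Inf
      }
    }
    for (k in seq_along(matched_trk)) {
      ti <- matched_trk[k]; dj <- matched_det[k]
      t <- tracks[[ti]]
      nlast <- length(t$cx)
      t$velocity <- c(det$cx[dj] - t$cx[nlast], det$cy[dj] - t$cy[nlast])
      t$frames <- c(t$frames, f); t$cx <- c(t$cx, det$cx[dj]); t$cy <- c(t$cy, det$cy[dj])
      t$det_rows <- c(t$det_rows, rows[dj])
      t$consecutive_hits <- t$consecutive_hits + 1L
      t$misses <- 0L; t$n_hits <- t$n_hits + 1L
      if (t$state == "tentative" && t$consecutive_hits >= m_confirm)
        t$state <- "confirmed"
      if (t$state == "confirmed") t$ever_confirmed <- TRUE
      tracks[[ti]] <- t
    }
    for (ti in setdiff(live, matched_trk)) {
      t <- tracks[[ti]]
      t$misses <- t$misses + 1L
      t$consecutive_hits <- 0L
      if (t$misses >= k_miss) t$state <- "terminated"
      tracks[[ti]] <- t
    }
    if (nrow(det)) for (dj in setdiff(seq_len(nrow(det)), matched_det)) {
      tracks[[length(tracks) + 1]] <- list(
        id = next_id, state = if (m_confirm <= 1) "confirmed" else "tentative",
        frames = f, cx = det$cx[dj], cy = det$cy[dj],
        velocity = c(0, 0), det_rows = rows[dj],
        consecutive_hits = 1L, misses = 0L, n_hits = 1L,
        ever_confirmed = m_confirm <= 1)
      next_id <- next_id + 1L
    }
  }
  tracks
}

#' Count particles and score against ground truth
#'
#' The estimated count is the number of tracks that reached the
#' confirmed state. With ground truth available, the counting accuracy
#' is `1 - |count - true| / true`, and per-particle correctness is
#' assessed by trajectory overlap: each confirmed track is matched to
#' the truth particle whose trajectory it overlaps most (centroid within
#' `match_radius_px` on shared frames); a truth particle is correctly
#' counted when at least half of its visible frames are covered by its
#' matched track.
#'
#' @param tracks output of [link_tracks()].
#' @param truth optional ground truth list with a `trajectories` data
#'   frame (`frame`, `id`, `cx_px`, `cy_px`) as produced by
#'   [render_video()].
#' @param match_radius_px centroid match radius in pixels.
#' @return List of class `count_report`: `count`, `tracks_summary`, and
#'   (with truth) `true_count`, `counting_accuracy`, `per_particle`
#'   (data frame: truth id, matched track, overlap fraction, correct).
#' @export
count_and_score <- function(tracks, truth = NULL, match_radius_px = 15) {
  # a track counts once it has ever reached the confirmed state, even if
  # it was later terminated when its particle left the field of view
  confirmed <- Filter(function(t) isTRUE(t$ever_confirmed), tracks)
  summ <- if (length(tracks))
    data.frame(id = vapply(tracks, `[[`, 1L, "id"),
               state = vapply(tracks, `[[`, "", "state"),
               n_hits = vapply(tracks, `[[`, 1L, "n_hits"),
               first_frame = vapply(tracks, function(t) t$frames[1], 1L),
               last_frame = vapply(tracks, function(t) t$frames[length(t$frames)], 1L))
  else data.frame()
  out <- list(count = length(confirmed), tracks_summary = summ)
  if (!is.null(truth)) {
    tr <- truth$trajectories
    true_ids <- unique(tr$id)
    out$true_count <- length(true_ids)
    out$counting_accuracy <- if (out$true_count > 0)
      1 - abs(out$count - out$true_count) / out$true_count else NA_real_
    pp <- lapply(true_ids, function(pid) {
      pt <- tr[tr$id == pid, ]
      overlaps <- vapply(confirmed, function(t) {
        common <- intersect(pt$frame, t$frames)
        if (!length(common)) return(0L)
        sum(vapply(common, function(f) {
          i <- match(f, pt$frame); j <- match(f, t$frames)
          (pt$cx_px[i] - t$cx[j])^2 + (pt$cy_px[i] - t$cy[j])^2 <=
            match_radius_px^2
        }, TRUE))
      }, 0L)
      best <- if (length(overlaps)) which.max(overlaps) else integer(0)
      frac <- if (length(best)) overlaps[best] / nrow(pt) else 0
      data.frame(truth_id = pid,
                 track_id = if (length(best) && overlaps[best] > 0)
                   confirmed[[best]]$id else NA_integer_,
                 overlap = frac, correct = frac >= 0.5)
    })
    out$per_particle <- do.call(rbind, pp)
  }
  class(out) <- "count_report"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
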