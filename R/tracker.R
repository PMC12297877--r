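#' Tracker configuration
#'
#' Collects every tunable of the tracking loop in one validated list.
#'
#' @param lambda Motion weight in the blended association cost (`[0, 1]`).
#' @param max_age Frames a confirmed track may go unmatched before
#'   deletion.
#' @param n_init Consecutive hits required to confirm a tentative track.
#' @param gallery_size Embeddings kept per track (oldest evicted first).
#' @param max_coast Consecutive frames for which an unmatched confirmed
#'   track still emits its filter-predicted box.
#' @param gate_threshold Squared-Mahalanobis motion gate; defaults to the
#'   95% chi-squared quantile, 4 df.
#' @param appearance_gate Cosine-distance gate applied when embeddings are
#'   used; `Inf` disables it.
#' @param iou_threshold Minimum overlap for the IoU fallback stage.
#' @param model A [motion_model()].
#' @param ukf [ukf_params()] for the unscented transform.
#' @return A list of class `"tracker_config"`.
#' @export
tracker_config <- function(lambda = 0.5, max_age = 30L, n_init = 3L,
                           gallery_size = 100L, max_coast = 5L,
                           gate_threshold = chi2_gate(),
                           appearance_gate = 0.4,
                           iou_threshold = 0.3,
                           model = motion_model(), ukf = ukf_params()) {
  if (lambda < 0 || lambda > 1) abort("lambda must lie in [0, 1]")
  if (max_age < 1L || n_init < 1L || gallery_size < 1L || max_coast < 0L) {
    abort("max_age, n_init and gallery_size must be >= 1; max_coast >= 0")
  }
  structure(list(lambda = lambda, max_age = as.integer(max_age),
                 n_init = as.integer(n_init),
                 gallery_size = as.integer(gallery_size),
                 max_coast = as.integer(max_coast),
                 gate_threshold = gate_threshold,
                 appearance_gate = appearance_gate,
                 iou_threshold = iou_threshold,
                 model = model, ukf = ukf),
            class = "tracker_config")
}

#' Create an empty tracker
#'
#' @param config A [tracker_config()].
#' @return A list of class `"tracker"` holding the live track records, the
#'   next identity to hand out, and the last processed frame index.
#' @export
new_tracker <- function(config = tracker_config()) {
  structure(list(tracks = list(), next_id = 1L, frame = 0L, config = config),
            class = "tracker")
}

new_track_record <- function(id, z, class, config, embedding = NULL) {
  list(id = id,
       state = ukf_initiate(z, config$model),
       status = "tentative",
       hits = 1L,
       time_since_update = 0L,
       gallery = if (is.null(embedding)) list() else list(embedding),
       class = class)
}

#' Advance the tracker by one frame
#'
#' One full tracking-by-detection cycle: predict every live track with the
#' unscented Kalman filter; associate confirmed tracks to detections with
#' the age-prioritised matching cascade on the blended motion + appearance
#' cost; give tentative tracks and freshly missed confirmed tracks a
#' second chance through IoU matching; update matched tracks (filter
#' update, gallery append, hit count); age and possibly delete unmatched
#' ones; start tentative tracks from unmatched detections; and emit one
#' output box per reportable track — the matched detection box for matched
#' tracks, the filter-predicted box (flagged `source = "predicted"`) for
#' confirmed tracks inside the coasting budget.
#'
#' @param tracker A `"tracker"`.
#' @param frame_index Integer frame number, strictly greater than the last
#'   processed one.
#' @param detections A data frame of boxes for this frame (columns `x`,
#'   `y`, `w`, `h`, optionally `class`, `confidence`).
#' @param embeddings Optional numeric matrix, one embedding per detection
#'   row.
#' @return A list with the advanced `tracker` and `result`, a tibble with
#'   columns `frame`, `track_id`, `x`, `y`, `w`, `h`, `class`, `source`.
#' @export
tracker_step <- function(tracker, frame_index, detections, embeddings = NULL) {
  cfg <- tracker$config
  if (frame_index <= tracker$frame) {
    abort(sprintf("frames must be processed in increasing order (got %d after %d)",
                  frame_index, tracker$frame))
  }
  if (is.null(detections) || nrow(detections) == 0L) {
    detections <- tibble(x = numeric(0), y = numeric(0), w = numeric(0),
                         h = numeric(0), class = character(0),
                         confidence = numeric(0))
  } else {
    detections <- as_tibble(detections)
    check_boxes(detections, "detection")
    if (!"class" %in% names(detections)) detections$class <- "Cell"
  }
  if (!is.null(embeddings) && nrow(detections) > 0L &&
      nrow(embeddings) != nrow(detections)) {
    abort("embeddings must have one row per detection")
  }

  # 1. predict all tracks; aging happens here so the cascade sees
  #    time_since_update = 1 for tracks matched in the previous frame
  tracker$tracks <- lapply(tracker$tracks, function(t) {
    t$state <- ukf_predict(t$state, cfg$model, cfg$ukf)
    t$time_since_update <- t$time_since_update + 1L
    t
  })

  confirmed <- which(vapply(tracker$tracks, function(t) t$status == "confirmed", logical(1)))
  tentative <- which(vapply(tracker$tracks, function(t) t$status == "tentative", logical(1)))

  # 2. matching cascade over confirmed tracks
  app_gate <- if (is.null(embeddings)) Inf else cfg$appearance_gate
  casc <- matching_cascade(tracker$tracks[confirmed], detections, embeddings,
                           max_age = cfg$max_age, lambda = cfg$lambda,
                           model = cfg$model, params = cfg$ukf,
                           gate_threshold = cfg$gate_threshold,
                           appearance_threshold = app_gate)
  matches <- tibble(track = confirmed[casc$matches$track],
                    detection = casc$matches$detection)
  free_dets <- casc$unmatched_detections

  # 3. IoU fallback: tentative tracks + confirmed tracks missed exactly once
  fresh_miss <- confirmed[casc$unmatched_tracks]
  fresh_miss <- fresh_miss[vapply(tracker$tracks[fresh_miss],
                                  function(t) t$time_since_update == 1L, logical(1))]
  iou_pool <- c(tentative, fresh_miss)
  if (length(iou_pool) > 0L && length(free_dets) > 0L) {
    im <- iou_match(tracker$tracks[iou_pool],
                    detections[free_dets, , drop = FALSE],
                    iou_threshold = cfg$iou_threshold)
    if (nrow(im$matches) > 0L) {
      matches <- bind_rows(matches, tibble(
        track = iou_pool[im$matches$track],
        detection = free_dets[im$matches$detection]
      ))
      free_dets <- setdiff(free_dets, matches$detection)
    }
  }

  # 4./5. update matched tracks, age out unmatched ones
  matched_tracks <- matches$track
  for (k in seq_len(nrow(matches))) {
    i <- matches$track[k]; j <- matches$detection[k]
    t <- tracker$tracks[[i]]
    z <- box_to_z(as.numeric(detections[j, c("x", "y", "w", "h")]))
    t$state <- ukf_update(t$state, z, cfg$model, cfg$ukf)
    t$hits <- t$hits + 1L
    t$time_since_update <- 0L
    t$class <- detections$class[j]
    if (!is.null(embeddings)) {
      t$gallery <- c(t$gallery, list(embeddings[j, ]))
      if (length(t$gallery) > cfg$gallery_size) {
        t$gallery <- tail(t$gallery, cfg$gallery_size)
      }
    }
    if (t$status == "tentative" && t$hits >= cfg$n_init) t$status <- "confirmed"
    tracker$tracks[[i]] <- t
  }
  drop <- logical(length(tracker$tracks))
  for (i in seq_along(tracker$tracks)) {
    if (i %in% matched_tracks) next
    t <- tracker$tracks[[i]]
    if (t$status == "tentative" || t$time_since_update > cfg$max_age) drop[i] <- TRUE
  }

  # 6. unmatched detections start new tentative tracks
  det_of_track <- setNames(matches$detection, matches$track)
  for (j in free_dets) {
    z <- box_to_z(as.numeric(detections[j, c("x", "y", "w", "h")]))
    emb <- if (is.null(embeddings)) NULL else embeddings[j, ]
    rec <- new_track_record(tracker$next_id, z, detections$class[j], cfg, emb)
    if (cfg$n_init <= 1L) rec$status <- "confirmed"
    tracker$tracks <- c(tracker$tracks, list(rec))
    drop <- c(drop, FALSE)
    det_of_track[as.character(length(tracker$tracks))] <- j
    tracker$next_id <- tracker$next_id + 1L
  }

  # 7. outputs: confirmed tracks only — detection box when matched, coasted
  #    prediction while within the coasting budget
  out <- list()
  for (i in seq_along(tracker$tracks)) {
    t <- tracker$tracks[[i]]
    if (t$status != "confirmed" || drop[i]) next
    if (t$time_since_update == 0L) {
      j <- det_of_track[[as.character(i)]]
      b <- as.numeric(detections[j, c("x", "y", "w", "h")])
      out[[length(out) + 1L]] <- tibble(
        frame = frame_index, track_id = t$id,
        x = b[1], y = b[2], w = b[3], h = b[4],
        class = t$class, source = "detected")
    } else if (t$time_since_update <= cfg$max_coast) {
      b <- z_to_box(t$state$mean[1:4])
      out[[length(out) + 1L]] <- tibble(
        frame = frame_index, track_id = t$id,
        x = b[1], y = b[2], w = b[3], h = b[4],
        class = t$class, source = "predicted")
    }
  }
  tracker$tracks <- tracker$tracks[!drop]
  tracker$frame <- frame_index

  result <- if (length(out) == 0L) {
    tibble(frame = integer(0), track_id = integer(0), x = numeric(0),
           y = numeric(0), w = numeric(0), h = numeric(0),
           class = character(0), source = character(0))
  } else bind_rows(out)
  list(tracker = tracker, result = result)
}

#' Track a detection stream
#'
#' The main entry point: folds [tracker_step()] over the frames of a
#' detection table and returns the linked tracks. Appearance information
#' can be supplied three ways: not at all (motion-only association),
#' as a per-frame list of embedding matrices, or as raw grayscale frames
#' plus a backbone (embeddings are then computed per detection with
#' [embed_detections()]).
#'
#' @param detections A data frame with columns `frame`, `x`, `y`, `w`,
#'   `h` and optionally `class`, `confidence`.
#' @param embeddings Optional list, indexed by frame number, of embedding
#'   matrices aligned row-wise with that frame's detections.
#' @param frames Optional list, indexed by frame number, of grayscale
#'   frame matrices.
#' @param backbone Backbone used when `frames` are given; defaults to
#'   [toy_backbone()].
#' @param config A [tracker_config()].
#' @param n_frames Number of frames in the sequence; defaults to the
#'   largest frame index present (frames with no detections are still
#'   stepped so tracks can coast through them).
#' @return An object of class `"cell_tracks"`: a list with `results`
#'   (tibble of per-frame outputs), `config`, and `n_frames`. Use
#'   [tidy.cell_tracks()] for the outputs table, [glance.cell_tracks()]
#'   for a one-row summary, and `autoplot()` for trajectories.
#' @examples
#' gt <- simulate_cells(sim_config(frames = 20, n_cells = c(5, 5), seed = 1))
#' dets <- degrade_detections(gt, dropout_p = 0.1, seed = 2)
#' tr <- track_cells(dets)
#' glance(tr)
#' @export
track_cells <- function(detections, embeddings = NULL, frames = NULL,
                        backbone = NULL, config = tracker_config(),
                        n_frames = NULL) {
  detections <- as_tibble(detections)
  if (!"frame" %in% names(detections)) abort("detections need a 'frame' column")
  if (nrow(detections) > 0L) check_boxes(detections, "detection")
  if (is.null(n_frames)) {
    n_frames <- if (nrow(detections) > 0L) max(detections$frame) else 0L
  }
  if (!is.null(frames) && is.null(backbone)) backbone <- toy_backbone()
  tracker <- new_tracker(config)
  results <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    dets_f <- detections[detections$frame == f, , drop = FALSE]
    emb_f <- NULL
    if (!is.null(embeddings)) {
      emb_f <- if (f <= length(embeddings)) embeddings[[f]] else NULL
    } else if (!is.null(frames) && nrow(dets_f) > 0L) {
      emb_f <- embed_detections(frames[[f]], dets_f, backbone)
    }
    step <- tracker_step(tracker, f, dets_f, emb_f)
    tracker <- step$tracker
    results[[f]] <- step$result
  }
  structure(list(results = bind_rows(results), config = config,
                 n_frames = n_frames),
            class = "cell_tracks")
}

#' @export
print.cell_tracks <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<cell_tracks> %d frames, %d tracks, %d boxes (%d coasted)\n",
              g$n_frames, g$n_tracks, g$n_boxes, g$n_coasted))
  invisible(x)
}

#' Tidy and summarise tracking results
#'
#' `tidy()` returns the per-frame output table (one row per emitted box);
#' `glance()` a one-row summary of the run.
#'
#' @param x A `"cell_tracks"` object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.cell_tracks <- function(x, ...) x$results

#' @rdname tidy.cell_tracks
#' @export
glance.cell_tracks <- function(x, ...) {
  r <- x$results
  tibble(n_frames = x$n_frames,
         n_tracks = dplyr::n_distinct(r$track_id),
         n_boxes = nrow(r),
         n_detected = sum(r$source == "detected"),
         n_coasted = sum(r$source == "predicted"))
}
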