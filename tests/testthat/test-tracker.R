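# a clean constant-velocity detection stream: K cells on parallel tracks
linear_stream <- function(K = 4, frames = 20, spacing = 120, v = 3, h = 30) {
  dplyr::bind_rows(lapply(seq_len(frames), function(f) {
    tibble::tibble(frame = f,
                   x = 20 + v * (f - 1), y = spacing * seq_len(K) - h,
                   w = h * 1.2, h = h, class = "Cell", confidence = 1,
                   id = seq_len(K))
  }))
}

test_that("an empty frame on an empty tracker yields an empty result", {
  tk <- new_tracker()
  step <- tracker_step(tk, 1L, NULL)
  expect_equal(nrow(step$result), 0L)
  expect_length(step$tracker$tracks, 0L)
})

test_that("out-of-order frames and misaligned embeddings are rejected", {
  tk <- new_tracker()
  step <- tracker_step(tk, 3L, data.frame(x = 1, y = 1, w = 5, h = 5))
  expect_error(tracker_step(step$tracker, 2L, NULL), "increasing order")
  expect_error(tracker_step(step$tracker, 4L, data.frame(x = 1, y = 1, w = 5, h = 5),
                            embeddings = matrix(0, 2, 4)),
               "one row per detection")
})

test_that("clean well-separated streams give K pure tracks, all detected", {
  stream <- linear_stream(K = 4, frames = 20)
  tr <- track_cells(dplyr::select(stream, -id))
  out <- tidy(tr)
  expect_equal(dplyr::n_distinct(out$track_id), 4L)
  expect_true(all(out$source == "detected"))
  gt <- dplyr::rename(stream, track_id = id)
  expect_equal(count_id_switches(dplyr::rename(stream, id = id), out), 0L)
  # confirmation takes n_init frames: no output before frame 3
  expect_equal(min(out$frame), 3)
  # one output per track per frame from there on
  counts <- dplyr::count(out, frame)
  expect_true(all(counts$n == 4L))
})

test_that("a one-frame detection gap is bridged by a predicted box with the same id", {
  stream <- linear_stream(K = 1, frames = 12)
  dropped <- stream[stream$frame != 7, ]
  tr <- track_cells(dplyr::select(dropped, -id), n_frames = 12)
  out <- tidy(tr)
  expect_equal(dplyr::n_distinct(out$track_id), 1L)
  gap <- out[out$frame == 7, ]
  expect_equal(nrow(gap), 1L)
  expect_equal(gap$source, "predicted")
  # predicted box sits where the constant-velocity motion puts it
  truth <- stream[stream$frame == 7, ]
  expect_lt(abs(gap$x - truth$x), 3)
  expect_lt(abs(gap$y - truth$y), 3)
  # same identity re-attached after the gap
  expect_equal(out$track_id[out$frame == 8], gap$track_id)
  expect_equal(out$source[out$frame == 8], "detected")
})

test_that("coasting stops after max_coast frames and deletion after max_age", {
  stream <- linear_stream(K = 1, frames = 30)
  # detections vanish from frame 11 on
  vanishing <- stream[stream$frame <= 10, ]
  cfg <- tracker_config(max_coast = 5, max_age = 8)
  tr <- track_cells(dplyr::select(vanishing, -id), config = cfg, n_frames = 30)
  out <- tidy(tr)
  coasted <- out[out$source == "predicted", ]
  expect_equal(nrow(coasted), 5L)
  expect_equal(sort(coasted$frame), 11:15)
  expect_equal(max(out$frame), 15)
})

test_that("tentative tracks die on a single early miss; confirmed ids are never reused", {
  # two detections then silence: track never confirms, nothing is emitted
  blip <- linear_stream(K = 1, frames = 2)
  tr <- track_cells(dplyr::select(blip, -id), n_frames = 10)
  expect_equal(nrow(tidy(tr)), 0L)

  # deletion then reappearance gets a fresh, larger id
  stream <- linear_stream(K = 1, frames = 40)
  gap <- stream[stream$frame <= 8 | stream$frame >= 30, ]
  cfg <- tracker_config(max_age = 5, max_coast = 2)
  tr2 <- track_cells(dplyr::select(gap, -id), config = cfg, n_frames = 40)
  out <- tidy(tr2)
  ids <- unique(out$track_id)
  expect_equal(length(ids), 2L)
  first_id <- out$track_id[which.min(out$frame)]
  second_id <- setdiff(ids, first_id)
  expect_gt(second_id, first_id)
  late <- out[out$frame >= 30, ]
  expect_true(all(late$track_id == second_id))
})

test_that("track class follows the most recent matched detection", {
  stream <- linear_stream(K = 1, frames = 8)
  stream$class[stream$frame >= 5] <- "Division"
  tr <- track_cells(dplyr::select(stream, -id))
  out <- tidy(tr)
  expect_equal(out$class[out$frame == 4], "Cell")
  expect_equal(out$class[out$frame == 6], "Division")
  expect_equal(dplyr::n_distinct(out$track_id), 1L)
})

test_that("gallery stays within its budget", {
  stream <- linear_stream(K = 1, frames = 30)
  emb <- lapply(1:30, function(f) matrix(rnorm(8), 1))
  emb <- lapply(emb, function(m) m / sqrt(sum(m^2)))
  cfg <- tracker_config(gallery_size = 10, appearance_gate = Inf)
  tk <- new_tracker(cfg)
  for (f in 1:30) {
    step <- tracker_step(tk, f, stream[stream$frame == f, ], emb[[f]])
    tk <- step$tracker
  }
  expect_length(tk$tracks, 1L)
  expect_lte(length(tk$tracks[[1]]$gallery), 10L)
})

test_that("runs are deterministic and never merge identities", {
  gt <- simulate_cells(sim_config(frames = 40, n_cells = c(10, 10), seed = 21))
  det <- degrade_detections(gt, dropout_p = 0.2, seed = 22)
  emb <- signature_embeddings(det, gt, seed = 23)
  tr1 <- track_cells(det, embeddings = emb, n_frames = 40)
  tr2 <- track_cells(det, embeddings = emb, n_frames = 40)
  expect_identical(tidy(tr1), tidy(tr2))
  # splits possible, merges impossible: at least as many ids as true cells
  expect_gte(dplyr::n_distinct(tidy(tr1)$track_id), dplyr::n_distinct(gt$id))
  # at most one output per track per frame, one detection per track
  out <- tidy(tr1)
  expect_false(any(duplicated(out[, c("frame", "track_id")])))
})

test_that("tracking a dropout-degraded stream beats the raw detections on recall", {
  res <- run_ablation(seed = 42, frames = 60, cells = 12, dropout = 0.3)
  expect_gt(res$tracked$modified_recall, res$raw$modified_recall)
})
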