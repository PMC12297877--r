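test_that("simulation is deterministic and respects the configured count range", {
  cf <- sim_config(frames = 30, seed = 9, division_rate = 0)
  gt1 <- simulate_cells(cf)
  gt2 <- simulate_cells(cf)
  expect_identical(as.data.frame(gt1), as.data.frame(gt2))
  counts <- dplyr::count(as.data.frame(gt1), frame)
  expect_true(all(counts$n >= 10 & counts$n <= 22))
  # no divisions: the population is constant
  expect_equal(length(unique(counts$n)), 1L)
  expect_error(sim_config(division_rate = 2), "division_rate")
})

test_that("boxes stay inside the frame and identities persist across frames", {
  gt <- simulate_cells(sim_config(frames = 50, seed = 13, division_rate = 0))
  cf <- attr(gt, "config")
  expect_true(all(gt$x >= 0 & gt$y >= 0))
  expect_true(all(gt$x + gt$w <= cf$width + 1e-9))
  expect_true(all(gt$y + gt$h <= cf$height + 1e-9))
  # each id appears in a contiguous frame range, once per frame
  for (i in unique(gt$id)) {
    fr <- sort(gt$frame[gt$id == i])
    expect_equal(fr, seq(min(fr), max(fr)))
    expect_false(any(duplicated(fr)))
  }
})

test_that("divisions replace the parent with two fresh daughters at the same frame", {
  gt <- simulate_cells(sim_config(frames = 80, n_cells = c(12, 12),
                                  division_rate = 0.01, seed = 17))
  lin <- attr(gt, "lineage")
  expect_gt(nrow(lin), 0L)
  for (k in seq_len(nrow(lin))) {
    parent_frames <- gt$frame[gt$id == lin$parent[k]]
    d1_frames <- gt$frame[gt$id == lin$daughter1[k]]
    expect_equal(max(parent_frames), lin$frame[k] - 1L)
    expect_equal(min(d1_frames), lin$frame[k])
    expect_equal(min(gt$frame[gt$id == lin$daughter2[k]]), lin$frame[k])
    expect_gt(lin$daughter1[k], lin$parent[k])
  }
  # the division phase is visible: parent carries the Division class at the end
  last_parent <- gt[gt$id == lin$parent[1] & gt$frame == lin$frame[1] - 1L, ]
  expect_equal(last_parent$class, "Division")
  expect_equal(last_parent$w / last_parent$h, 1, tolerance = 1e-9)
})

test_that("degradation drops at the configured rate and never invents boxes", {
  gt <- simulate_cells(sim_config(frames = 60, n_cells = c(20, 20),
                                  division_rate = 0, seed = 19))
  # large-sample drop fraction within 2 points of the nominal rate
  big <- dplyr::bind_rows(replicate(9, as.data.frame(gt), simplify = FALSE))
  attr(big, "config") <- attr(gt, "config")
  det <- degrade_detections(big, dropout_p = 0.3, jitter_sigma = 0, seed = 20)
  frac <- 1 - nrow(det) / nrow(big)
  expect_lt(abs(frac - 0.3), 0.02)
  expect_gte(nrow(big), 10000)
  # no degradation: boxes identical to GT
  clean <- degrade_detections(gt, dropout_p = 0, jitter_sigma = 0, seed = 21)
  expect_equal(nrow(clean), nrow(gt))
  expect_equal(clean$x, gt$x, tolerance = 1e-9)
  expect_true(all(clean$confidence >= 0.5 & clean$confidence <= 1))
  # total dropout: empty stream
  expect_equal(nrow(degrade_detections(gt, dropout_p = 1, seed = 22)), 0L)
  # every surviving detection originates from a GT identity
  det2 <- degrade_detections(gt, dropout_p = 0.3, seed = 23)
  expect_true(all(det2$source_id %in% gt$id))
})

test_that("signature embeddings are unit norm and cluster by cell identity", {
  gt <- simulate_cells(sim_config(frames = 10, n_cells = c(6, 6),
                                  division_rate = 0, seed = 25))
  det <- degrade_detections(gt, dropout_p = 0, jitter_sigma = 0, seed = 26)
  emb <- signature_embeddings(det, gt, seed = 27)
  e1 <- emb[[1]]; e2 <- emb[[2]]
  expect_equal(sqrt(rowSums(e1^2)), rep(1, nrow(e1)), tolerance = 1e-9)
  d1 <- det[det$frame == 1, ]; d2 <- det[det$frame == 2, ]
  same <- cosine_distance(e1[1, ], e2[which(d2$source_id == d1$source_id[1]), ])
  other <- cosine_distance(e1[1, ], e2[which(d2$source_id == d1$source_id[2]), ])
  expect_lt(same, 0.1)
  expect_gt(other, 0.5)
})

test_that("rendering puts bright cells on a dim background, deterministically", {
  cf <- sim_config(frames = 2, width = 240, height = 200, n_cells = c(5, 5),
                   division_rate = 0, seed = 29)
  gt <- simulate_cells(cf)
  fr <- render_frames(gt, seed = 30)
  expect_identical(fr, render_frames(gt, seed = 30))
  img <- fr[[1]]
  expect_equal(dim(img), c(200L, 240L))
  expect_true(all(img >= 0 & img <= 255))
  d <- gt[gt$frame == 1, ][1, ]
  inside <- img[max(1, floor(d$y)):min(200, ceiling(d$y + d$h)),
                max(1, floor(d$x)):min(240, ceiling(d$x + d$w))]
  expect_gt(mean(inside), mean(img) + 5)
  # a frame with no cells is pure background noise at the configured level
  lone <- tibble::tibble(frame = 2L, id = 1L, x = 10, y = 10, w = 20, h = 20,
                         class = "Cell")
  bg <- render_frames(lone, width = 100, height = 100, background = 40,
                      bg_noise = 5, seed = 31)
  expect_equal(mean(bg[[1]]), 40, tolerance = 1)
})

test_that("intensity inversion is an involution with the mirrored mean", {
  set.seed(35)
  img <- matrix(runif(400, 0, 255), 20, 20)
  expect_equal(invert_intensity(invert_intensity(img)), img)
  expect_equal(invert_intensity(matrix(0, 3, 3)), matrix(255, 3, 3))
  expect_equal(mean(invert_intensity(img)), 255 - mean(img))
})
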