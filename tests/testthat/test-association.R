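make_track <- function(z, model = motion_model(), gallery = list()) {
  st <- ukf_predict(ukf_initiate(z, model), model)
  list(state = st, gallery = gallery, time_since_update = 1L)
}

test_that("cost matrix endpoints reduce to pure motion / pure appearance", {
  m <- motion_model()
  dets <- data.frame(x = c(10, 200), y = c(10, 200), w = c(20, 20), h = c(20, 20))
  Z <- as.matrix(boxes_to_measurements(dets))
  emb <- rbind(c(1, 0), c(0, 1))
  tracks <- list(make_track(Z[1, ], m, gallery = list(c(1, 0))),
                 make_track(Z[2, ], m, gallery = list(c(0, 1))))
  cm1 <- build_cost_matrix(tracks, dets, emb, lambda = 1, model = m)
  expect_equal(cm1$costs, cm1$motion_d2)
  cm0 <- build_cost_matrix(tracks, dets, emb, lambda = 0, model = m)
  expect_equal(cm0$costs, cm0$cosine_d)
  # perfect match: zero cost at any lambda
  cm <- build_cost_matrix(tracks, dets, emb, lambda = 0.5, model = m)
  expect_equal(cm$costs[1, 1], 0, tolerance = 1e-9)
  expect_equal(cm$costs[2, 2], 0, tolerance = 1e-9)
  expect_gt(cm$costs[1, 2], 0)
  expect_error(build_cost_matrix(tracks, dets, emb, lambda = 1.5), "lambda")
})

test_that("gallery distance is the minimum over stored embeddings", {
  m <- motion_model()
  dets <- data.frame(x = 10, y = 10, w = 20, h = 20)
  z <- as.matrix(boxes_to_measurements(dets))[1, ]
  emb <- matrix(c(1, 0), 1)
  track <- make_track(z, m, gallery = list(c(0, 1), c(1, 0)))
  cm <- build_cost_matrix(list(track), dets, emb, lambda = 0, model = m)
  expect_equal(cm$costs[1, 1], 0, tolerance = 1e-12)
})

test_that("gating thresholds at the chi-squared quantile and masks far detections", {
  expect_equal(chi2_gate(), qchisq(0.95, 4))
  expect_equal(chi2_gate(), 9.4877, tolerance = 1e-4)
  m <- motion_model()
  near <- data.frame(x = 10, y = 10, w = 20, h = 20)
  Z <- as.matrix(boxes_to_measurements(near))
  tracks <- list(make_track(Z[1, ], m))
  # detection ~100 position sigmas away
  far <- data.frame(x = 1e5, y = 1e5, w = 20, h = 20)
  dets <- rbind(near, far)
  cm <- build_cost_matrix(tracks, dets, lambda = 1, model = m)
  gated <- gate_cost_matrix(cm)
  expect_false(gated$infeasible[1, 1])
  expect_true(gated$infeasible[1, 2])
  expect_false(any(gate_cost_matrix(cm, threshold = Inf)$infeasible))
  res <- solve_assignment(gated)
  expect_equal(res$unmatched_detections, 2L)
})

test_that("tightening the gate never increases the number of matches", {
  set.seed(14)
  m <- motion_model()
  dets <- random_boxes(6, max_xy = 400)
  Z <- as.matrix(boxes_to_measurements(dets))
  tracks <- lapply(1:5, function(i) make_track(Z[i, ] + c(rnorm(2, 0, 3), 0, 0), m))
  cm <- build_cost_matrix(tracks, dets, lambda = 1, model = m)
  thresholds <- c(50, 20, 9.4877, 2, 0.5, 0.05)
  n_matches <- vapply(thresholds, function(th) {
    nrow(solve_assignment(gate_cost_matrix(cm, threshold = th))$matches)
  }, numeric(1))
  expect_true(all(diff(n_matches) <= 0))
})

test_that("assignment solves the 2x2 example and empty inputs", {
  res <- solve_assignment(matrix(c(1, 2, 2, 1), 2, byrow = TRUE))
  expect_equal(res$matches$track, c(1L, 2L))
  expect_equal(res$matches$detection, c(1L, 2L))
  empty <- solve_assignment(matrix(numeric(0), 0, 3))
  expect_equal(empty$unmatched_detections, 1:3)
  expect_equal(nrow(empty$matches), 0L)
})

test_that("solver total cost equals the brute-force minimum on random instances", {
  set.seed(77)
  for (k in 1:200) {
    n <- sample(1:6, 1); m <- sample(1:6, 1)
    costs <- matrix(runif(n * m, 0, 10), n, m)
    res <- solve_assignment(costs)
    expect_one_to_one(res)
    got <- sum(costs[cbind(res$matches$track, res$matches$detection)])
    expect_equal(got, brute_force_assignment(costs)$cost, tolerance = 1e-9)
  }
})

test_that("solver is optimal under feasibility masks too", {
  set.seed(78)
  for (k in 1:50) {
    n <- sample(2:5, 1); m <- sample(2:5, 1)
    costs <- matrix(runif(n * m, 0, 10), n, m)
    mask <- matrix(runif(n * m) < 0.4, n, m)
    res <- solve_assignment(structure(list(costs = costs, infeasible = mask),
                                      class = "cost_matrix"))
    expect_one_to_one(res)
    expect_false(any(mask[cbind(res$matches$track, res$matches$detection)]))
    ref <- brute_force_assignment(costs, mask)
    expect_equal(nrow(res$matches), ref$size)
    got <- sum(costs[cbind(res$matches$track, res$matches$detection)])
    expect_equal(got, ref$cost, tolerance = 1e-9)
  }
})

test_that("equal-cost optima break ties toward low indices", {
  res <- solve_assignment(matrix(1, 3, 3))
  expect_equal(res$matches$detection, 1:3)
  res2 <- solve_assignment(matrix(c(5, 5), 1, 2))
  expect_equal(res2$matches$detection, 1L)
})

test_that("cascade prioritizes recently seen tracks and conserves detections", {
  m <- motion_model()
  dets <- data.frame(x = 10, y = 10, w = 20, h = 20)
  Z <- as.matrix(boxes_to_measurements(dets))
  young <- make_track(Z[1, ], m); young$time_since_update <- 1L
  old <- make_track(Z[1, ], m);   old$time_since_update <- 5L
  res <- matching_cascade(list(old, young), dets, max_age = 30)
  expect_equal(nrow(res$matches), 1L)
  expect_equal(res$matches$track, 2L)  # the age-1 track wins
  expect_equal(res$unmatched_tracks, 1L)
  # empty track set
  res0 <- matching_cascade(list(), dets)
  expect_equal(res0$unmatched_detections, 1L)
})

test_that("single-age cascade equals one direct solve", {
  set.seed(91)
  m <- motion_model()
  dets <- random_boxes(4, max_xy = 300)
  Z <- as.matrix(boxes_to_measurements(dets))
  tracks <- lapply(1:4, function(i) make_track(Z[i, ] + c(rnorm(2, 0, 2), 0, 0), m))
  casc <- matching_cascade(tracks, dets, max_age = 30, lambda = 0.5)
  cm <- gate_cost_matrix(build_cost_matrix(tracks, dets, lambda = 0.5, model = m))
  direct <- solve_assignment(cm)
  expect_equal(dplyr::arrange(casc$matches, track), dplyr::arrange(direct$matches, track))
  expect_one_to_one(casc)
})

test_that("iou fallback matches overlapping predictions and rejects disjoint ones", {
  m <- motion_model()
  dets <- data.frame(x = c(10, 100), y = c(10, 100), w = c(20, 20), h = c(20, 20))
  Z <- as.matrix(boxes_to_measurements(dets))
  tracks <- list(make_track(Z[1, ], m), make_track(Z[2, ], m))
  res <- iou_match(tracks, dets)
  expect_equal(nrow(res$matches), 2L)
  expect_equal(res$matches$detection[order(res$matches$track)], c(1L, 2L))
  # disjoint: nothing matched
  far <- data.frame(x = c(500, 600), y = c(500, 600), w = c(20, 20), h = c(20, 20))
  expect_equal(nrow(iou_match(tracks, far)$matches), 0L)
})

test_that("iou fallback is assignment-optimal on random fixtures", {
  set.seed(55)
  m <- motion_model()
  for (k in 1:20) {
    boxes <- random_boxes(4, max_xy = 120, max_wh = 40)
    Z <- as.matrix(boxes_to_measurements(boxes))
    tracks <- lapply(1:4, function(i) make_track(Z[i, ], m))
    dets <- boxes
    dets$x <- dets$x + runif(4, -5, 5); dets$y <- dets$y + runif(4, -5, 5)
    res <- iou_match(tracks, dets, iou_threshold = 0.1)
    expect_one_to_one(res)
    track_boxes <- boxes
    ious <- iou_matrix(track_boxes, dets)
    ref <- brute_force_assignment(1 - ious, ious < 0.1)
    got <- sum((1 - ious)[cbind(res$matches$track, res$matches$detection)])
    expect_equal(nrow(res$matches), ref$size)
    expect_equal(got, ref$cost, tolerance = 1e-6)
  }
})
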