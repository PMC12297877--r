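#' Chi-squared motion gate threshold
#'
#' Under the motion model, the squared Mahalanobis distance between a
#' track's predicted measurement and its true detection is chi-squared with
#' 4 degrees of freedom, so the 95% quantile (about 9.4877) rejects
#' implausible track-detection pairs at a 5% miss rate.
#'
#' @param p Coverage probability of the gate.
#' @return The squared-distance threshold.
#' @export
chi2_gate <- function(p = 0.95) qchisq(p, df = 4)

# internal constructor for the costs + feasibility pair
new_cost_matrix <- function(costs, infeasible = NULL,
                            motion_d2 = NULL, cosine_d = NULL) {
  if (is.null(infeasible)) {
    infeasible <- matrix(FALSE, nrow(costs), ncol(costs))
  }
  structure(list(costs = costs, infeasible = infeasible,
                 motion_d2 = motion_d2, cosine_d = cosine_d),
            class = "cost_matrix")
}

#' Build the blended motion + appearance cost matrix
#'
#' Cost of assigning detection `j` to track `i` is
#' `C[i, j] = lambda * d2_motion(i, j) + (1 - lambda) * d_cos(i, j)`,
#' where `d2_motion` is the squared Mahalanobis gating distance of the
#' detection's measurement under track `i`'s predicted state, and `d_cos`
#' is the smallest cosine distance between detection `j`'s embedding and
#' any embedding in track `i`'s gallery. With `embeddings = NULL` the cost
#' is the pure motion distance (motion-only operation).
#'
#' @param tracks A list of internal track records (each carrying a
#'   predicted `state` and an embedding `gallery`).
#' @param detections A data frame of detection boxes.
#' @param embeddings A numeric matrix, one embedding per detection row, or
#'   `NULL`.
#' @param lambda Motion weight in `[0, 1]`.
#' @param model A [motion_model()].
#' @param params A [ukf_params()].
#' @return A `cost_matrix` object: `costs` (tracks x detections),
#'   `infeasible` (logical, all `FALSE` here), plus the raw `motion_d2`
#'   and `cosine_d` components.
#' @export
build_cost_matrix <- function(tracks, detections, embeddings = NULL,
                              lambda = 0.5, model = motion_model(),
                              params = ukf_params()) {
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda < 0 || lambda > 1) {
    abort("lambda must lie in [0, 1]")
  }
  n <- length(tracks); m <- nrow(detections)
  d2 <- matrix(0, n, m); dc <- matrix(0, n, m)
  if (n > 0L && m > 0L) {
    Z <- as.matrix(boxes_to_measurements(detections[, c("x", "y", "w", "h")]))
    for (i in seq_len(n)) {
      d2[i, ] <- gating_distance(tracks[[i]]$state, Z, model, params)
      if (!is.null(embeddings) && length(tracks[[i]]$gallery) > 0L) {
        gal <- do.call(rbind, tracks[[i]]$gallery)
        for (j in seq_len(m)) {
          dc[i, j] <- min(cosine_distance_rows(gal, embeddings[j, ]))
        }
      }
    }
  }
  costs <- if (is.null(embeddings)) d2 else lambda * d2 + (1 - lambda) * dc
  new_cost_matrix(costs, motion_d2 = d2, cosine_d = if (is.null(embeddings)) NULL else dc)
}

#' Gate a cost matrix on motion (and optionally appearance) distance
#'
#' Marks entries infeasible when the squared Mahalanobis distance exceeds
#' `threshold` (default: the 95% chi-squared quantile with 4 degrees of
#' freedom) and, if `appearance_threshold` is finite and the matrix carries
#' cosine distances, when the cosine distance exceeds that threshold.
#' Infeasible entries are never selected by the solver.
#'
#' @param cm A `cost_matrix` from [build_cost_matrix()].
#' @param threshold Motion gate on squared Mahalanobis distance.
#' @param appearance_threshold Optional gate on cosine distance (`Inf`
#'   disables it).
#' @return The gated `cost_matrix`.
#' @export
gate_cost_matrix <- function(cm, threshold = chi2_gate(),
                             appearance_threshold = Inf) {
  if (!is.numeric(threshold) || threshold <= 0) abort("gate threshold must be positive")
  inf <- cm$infeasible
  if (!is.null(cm$motion_d2)) inf <- inf | (cm$motion_d2 > threshold)
  if (is.finite(appearance_threshold) && !is.null(cm$cosine_d)) {
    inf <- inf | (cm$cosine_d > appearance_threshold)
  }
  cm$infeasible <- inf
  cm
}

GATE_SENTINEL <- 1e5

#' Solve the one-to-one assignment problem
#'
#' Minimum-cost one-to-one matching of tracks to detections by the
#' Hungarian algorithm. Infeasible entries are given a large finite
#' sentinel during solving and any pair that lands on one is reported
#' unmatched afterwards. Ties between equal-cost optima are broken
#' deterministically in favour of low `(track, detection)` indices by the
#' solver's ascending scan order.
#'
#' @param cm A `cost_matrix` (or a plain numeric matrix, taken as fully
#'   feasible).
#' @return A list of class `"assignment"`: `matches` (tibble with columns
#'   `track`, `detection`), `unmatched_tracks`, `unmatched_detections`
#'   (integer vectors).
#' @export
solve_assignment <- function(cm) {
  if (is.matrix(cm)) cm <- new_cost_matrix(cm)
  costs <- cm$costs
  n <- nrow(costs); m <- ncol(costs)
  if (n == 0L || m == 0L) {
    return(new_assignment(tibble(track = integer(0), detection = integer(0)),
                          seq_len(n), seq_len(m)))
  }
  work <- costs
  work[cm$infeasible] <- GATE_SENTINEL
  # ties between equal-cost optima fall to the solver's ascending row/column
  # scan, which is deterministic and favours low indices
  assign_row <- hungarian_solve(work)
  matched <- which(!is.na(assign_row))
  keep <- matched[!cm$infeasible[cbind(matched, assign_row[matched])]]
  matches <- tibble(track = keep, detection = assign_row[keep])
  new_assignment(matches,
                 setdiff(seq_len(n), matches$track),
                 setdiff(seq_len(m), matches$detection))
}

new_assignment <- function(matches, unmatched_tracks, unmatched_detections) {
  structure(list(matches = matches,
                 unmatched_tracks = as.integer(unmatched_tracks),
                 unmatched_detections = as.integer(unmatched_detections)),
            class = "assignment")
}

#' Age-prioritised matching cascade
#'
#' Runs build-gate-solve repeatedly, once per track age level
#' `1..max_age`, each level matching only the tracks last updated that many
#' frames ago against the detections still unmatched. Recently seen tracks
#' therefore get first claim on detections, which curbs identity switches
#' when tracks have coasted through occlusions for different lengths of
#' time.
#'
#' @inheritParams build_cost_matrix
#' @param max_age Deepest age level to consider.
#' @param gate_threshold Motion gate (squared Mahalanobis).
#' @param appearance_threshold Optional cosine-distance gate.
#' @return An `"assignment"` whose indices refer to the full `tracks` list
#'   and `detections` table.
#' @export
matching_cascade <- function(tracks, detections, embeddings = NULL,
                             max_age = 30L, lambda = 0.5,
                             model = motion_model(), params = ukf_params(),
                             gate_threshold = chi2_gate(),
                             appearance_threshold = Inf) {
  m <- nrow(detections)
  matches <- tibble(track = integer(0), detection = integer(0))
  free_dets <- seq_len(m)
  ages <- vapply(tracks, function(t) t$time_since_update, numeric(1))
  for (age in seq_len(max_age)) {
    if (length(free_dets) == 0L) break
    level <- which(ages == age)
    if (length(level) == 0L) next
    dets <- detections[free_dets, , drop = FALSE]
    emb <- if (is.null(embeddings)) NULL else embeddings[free_dets, , drop = FALSE]
    cm <- build_cost_matrix(tracks[level], dets, emb, lambda, model, params)
    cm <- gate_cost_matrix(cm, gate_threshold, appearance_threshold)
    res <- solve_assignment(cm)
    if (nrow(res$matches) > 0L) {
      matches <- bind_rows(matches, tibble(
        track = level[res$matches$track],
        detection = free_dets[res$matches$detection]
      ))
      free_dets <- setdiff(free_dets, matches$detection)
    }
  }
  new_assignment(matches, setdiff(seq_along(tracks), matches$track), free_dets)
}

#' IoU-based association fallback
#'
#' Matches tracks to detections on cost `1 - IoU` between each track's
#' current predicted box and the detection boxes, with pairs below
#' `iou_threshold` overlap infeasible. Used for tracks too young to have a
#' reliable motion gate (tentative tracks and confirmed tracks missed for
#' a single frame).
#'
#' @param tracks A list of track records with a predicted `state`.
#' @param detections A data frame of detection boxes.
#' @param iou_threshold Minimum overlap for a feasible pair.
#' @return An `"assignment"`.
#' @export
iou_match <- function(tracks, detections, iou_threshold = 0.3) {
  n <- length(tracks); m <- nrow(detections)
  if (n == 0L || m == 0L) {
    return(new_assignment(tibble(track = integer(0), detection = integer(0)),
                          seq_len(n), seq_len(m)))
  }
  track_boxes <- as_tibble(do.call(rbind, lapply(tracks, function(t) {
    setNames(as.list(z_to_box(t$state$mean[1:4])), c("x", "y", "w", "h"))
  })))
  track_boxes <- mutate(track_boxes, dplyr::across(dplyr::everything(), as.numeric))
  ious <- iou_matrix(track_boxes, detections[, c("x", "y", "w", "h")])
  cm <- new_cost_matrix(1 - ious, infeasible = ious < iou_threshold)
  solve_assignment(cm)
}
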