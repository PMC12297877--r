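#' Match one frame of predictions to ground truth
#'
#' Greedy one-to-one matching by descending IoU: the highest-overlap
#' ground-truth/prediction pair is accepted first, both boxes are removed,
#' and the process repeats; pairs with IoU below `iou_threshold` are
#' rejected. Ties are broken towards the lowest (ground-truth, prediction)
#' row indices. Unmatched predictions are ignored — the metrics built on
#' this matching measure completeness against the annotated objects and do
#' not penalise extra predictions.
#'
#' @param gt_boxes,pred_boxes Data frames of boxes (columns `x`, `y`, `w`,
#'   `h`).
#' @param iou_threshold Minimum IoU for a valid match.
#' @return A list: `pairs` (tibble `gt`, `pred`, `iou`), `tp` (matched
#'   ground-truth count) and `fn` (unmatched ground-truth count).
#' @export
match_frame <- function(gt_boxes, pred_boxes, iou_threshold = 0.5) {
  n <- nrow(gt_boxes); m <- nrow(pred_boxes)
  pairs <- tibble(gt = integer(0), pred = integer(0), iou = numeric(0))
  if (n > 0L && m > 0L) {
    ious <- iou_matrix(gt_boxes, pred_boxes)
    repeat {
      best <- max(ious)
      if (best < iou_threshold) break
      hit <- which(ious == best, arr.ind = TRUE)
      # lowest (gt, pred) indices among ties
      hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE][1, ]
      pairs <- bind_rows(pairs, tibble(gt = unname(hit[1]), pred = unname(hit[2]),
                                       iou = best))
      ious[hit[1], ] <- -1
      ious[, hit[2]] <- -1
      if (all(ious < iou_threshold)) break
    }
  }
  list(pairs = pairs, tp = nrow(pairs), fn = n - nrow(pairs))
}

#' Evaluate tracking or detection output against ground truth
#'
#' Runs the greedy IoU matching frame by frame and accumulates true
#' positives, false negatives and matched-pair IoUs, from which Modified
#' Recall and Average IoU are computed. Both inputs are per-frame box
#' tables; `pred` may be raw detections (no identity column) or tracker
#' output.
#'
#' @param gt Ground truth: data frame with `frame`, `x`, `y`, `w`, `h`
#'   and (for identity metrics) `id`.
#' @param pred Predictions: data frame with `frame`, `x`, `y`, `w`, `h`,
#'   optionally `track_id` and `source`.
#' @param iou_threshold Minimum IoU for a ground-truth/prediction match.
#' @param per_class Evaluate each class separately (requires a `class`
#'   column in both inputs) in the `by_class` element.
#' @param include_predicted Count coasted (`source == "predicted"`) boxes
#'   as predictions (default) or drop them first.
#' @return An object of class `"track_eval"` with elements `per_frame`
#'   (tibble: `frame`, `tp`, `fn`, `mean_iou`), `totals` (list: `tp`,
#'   `fn`, `n_pairs`, `sum_iou`), `modified_recall` and `average_iou`
#'   (percentages), and optionally `by_class`. `tidy()` returns the
#'   per-frame table, `glance()` the summary row.
#' @export
evaluate_tracking <- function(gt, pred, iou_threshold = 0.5,
                              per_class = FALSE, include_predicted = TRUE) {
  gt <- as_tibble(gt); pred <- as_tibble(pred)
  if (!include_predicted && "source" %in% names(pred)) {
    pred <- filter(pred, .data$source != "predicted")
  }
  if (nrow(gt) == 0L) abort("undefined metric: no ground-truth boxes")
  frames <- sort(unique(gt$frame))
  per_frame <- vector("list", length(frames))
  ious_all <- numeric(0)
  for (k in seq_along(frames)) {
    f <- frames[k]
    mf <- match_frame(gt[gt$frame == f, , drop = FALSE],
                      pred[pred$frame == f, , drop = FALSE],
                      iou_threshold)
    per_frame[[k]] <- tibble(frame = f, tp = mf$tp, fn = mf$fn,
                             mean_iou = if (mf$tp > 0) mean(mf$pairs$iou) else NA_real_)
    ious_all <- c(ious_all, mf$pairs$iou)
  }
  per_frame <- bind_rows(per_frame)
  totals <- list(tp = sum(per_frame$tp), fn = sum(per_frame$fn),
                 n_pairs = length(ious_all), sum_iou = sum(ious_all))
  out <- structure(list(per_frame = per_frame, totals = totals,
                        modified_recall = modified_recall(totals$tp, totals$fn),
                        average_iou = if (totals$n_pairs > 0)
                          100 * totals$sum_iou / totals$n_pairs else NA_real_,
                        iou_threshold = iou_threshold),
                   class = "track_eval")
  if (per_class) {
    if (!"class" %in% names(gt) || !"class" %in% names(pred)) {
      abort("per-class evaluation needs a 'class' column in both inputs")
    }
    out$by_class <- lapply(setNames(nm = sort(unique(gt$class))), function(cl) {
      evaluate_tracking(gt[gt$class == cl, ], pred[pred$class == cl, ],
                        iou_threshold, per_class = FALSE)
    })
  }
  out
}

#' Modified Recall
#'
#' The fraction of annotated ground-truth objects recovered, summed over
#' all frames: `100 * sum(TP) / sum(TP + FN)`. False positives are not
#' penalised, so the metric is meaningful on incompletely annotated data
#' where an unmatched prediction may simply be an unannotated object.
#'
#' Can be called on a `"track_eval"` object or directly on total TP / FN
#' counts.
#'
#' @param x A `"track_eval"` object, or the total true-positive count.
#' @param fn Total false-negative count (when `x` is a count).
#' @param ... Unused.
#' @return The recall as a percentage.
#' @examples
#' modified_recall(1154, 84)  # 93.21
#' @export
modified_recall <- function(x, ...) UseMethod("modified_recall")

#' @rdname modified_recall
#' @export
modified_recall.track_eval <- function(x, ...) x$modified_recall

#' @rdname modified_recall
#' @export
modified_recall.default <- function(x, fn, ...) {
  tp <- x
  if (tp + fn <= 0) abort("undefined metric: no ground-truth boxes (TP + FN = 0)")
  100 * tp / (tp + fn)
}

#' Average IoU over matched pairs
#'
#' `100 * mean(IoU)` over the matched ground-truth/prediction pairs only,
#' measuring localisation quality of the recovered objects.
#'
#' @param x A `"track_eval"` object.
#' @param ... Unused.
#' @return The mean IoU as a percentage.
#' @export
average_iou <- function(x, ...) UseMethod("average_iou")

#' @rdname average_iou
#' @export
average_iou.track_eval <- function(x, ...) {
  if (x$totals$n_pairs == 0L) abort("undefined metric: no matched pairs")
  x$average_iou
}

#' Count identity switches
#'
#' Matches predictions to ground truth frame by frame (greedy IoU) and
#' counts the frames at which a ground-truth identity's matched predicted
#' identity differs from the predicted identity it was matched to the
#' previous time it was matched at all. Renaming all predicted identities
#' by a fixed bijection leaves the count unchanged.
#'
#' @param gt Data frame `frame`, `id`, `x`, `y`, `w`, `h`.
#' @param pred Data frame `frame`, `track_id`, `x`, `y`, `w`, `h`.
#' @param iou_threshold Minimum IoU for a match.
#' @return Integer count of switches.
#' @export
count_id_switches <- function(gt, pred, iou_threshold = 0.5) {
  gt <- as_tibble(gt); pred <- as_tibble(pred)
  if (!"id" %in% names(gt)) abort("ground truth needs an 'id' column")
  if (!"track_id" %in% names(pred)) abort("predictions need a 'track_id' column")
  last_match <- list()
  switches <- 0L
  for (f in sort(unique(gt$frame))) {
    gt_f <- gt[gt$frame == f, , drop = FALSE]
    pr_f <- pred[pred$frame == f, , drop = FALSE]
    if (nrow(pr_f) == 0L) next
    mf <- match_frame(gt_f, pr_f, iou_threshold)
    for (k in seq_len(nrow(mf$pairs))) {
      gid <- as.character(gt_f$id[mf$pairs$gt[k]])
      pid <- pr_f$track_id[mf$pairs$pred[k]]
      prev <- last_match[[gid]]
      if (!is.null(prev) && prev != pid) switches <- switches + 1L
      last_match[[gid]] <- pid
    }
  }
  switches
}

#' @export
print.track_eval <- function(x, ...) {
  cat(sprintf("<track_eval> Modified Recall %.2f%%, Average IoU %.2f%% (TP %d, FN %d, pairs %d)\n",
              x$modified_recall, x$average_iou,
              x$totals$tp, x$totals$fn, x$totals$n_pairs))
  invisible(x)
}

#' Tidy and summarise an evaluation
#'
#' `tidy()` gives the per-frame TP/FN/IoU table; `glance()` a one-row
#' summary with the two headline metrics.
#'
#' @param x A `"track_eval"` object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.track_eval <- function(x, ...) x$per_frame

#' @rdname tidy.track_eval
#' @export
glance.track_eval <- function(x, ...) {
  tibble(tp = x$totals$tp, fn = x$totals$fn, n_pairs = x$totals$n_pairs,
         modified_recall = x$modified_recall, average_iou = x$average_iou)
}
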