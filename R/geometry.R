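#' Bounding boxes and the tracker's measurement space
#'
#' Detections live in pixel space as top-left boxes `(x, y, w, h)` with a
#' class label (`"Cell"` or `"Division"`) and a detector confidence. The
#' motion filter instead observes the four-vector `(cx, cy, a, h)`: box
#' centre, aspect ratio `w/h`, and height. These helpers convert between the
#' two representations, losslessly and row-wise.
#'
#' Coordinates are 0-based, origin at the top-left of the frame, and boxes
#' are real-valued closed rectangles; no pixel rasterisation happens at any
#' point.
#'
#' @param boxes A data frame with numeric columns `x`, `y`, `w`, `h`
#'   (pixels). Any other columns (e.g. `class`, `confidence`) are carried
#'   through untouched.
#' @param measurements A data frame with numeric columns `cx`, `cy`, `a`,
#'   `h`. Extra columns are carried through.
#' @return A tibble with the converted coordinate columns replacing the
#'   originals, in the same row order.
#' @examples
#' boxes_to_measurements(data.frame(x = 10, y = 20, w = 40, h = 20))
#' @export
boxes_to_measurements <- function(boxes) {
  boxes <- as_tibble(boxes)
  check_boxes(boxes)
  out <- mutate(boxes,
    cx = .data$x + .data$w / 2,
    cy = .data$y + .data$h / 2,
    a  = .data$w / .data$h,
    x = NULL, y = NULL, w = NULL
  )
  select(out, "cx", "cy", "a", "h", dplyr::everything())
}

#' @rdname boxes_to_measurements
#' @export
measurements_to_boxes <- function(measurements) {
  m <- as_tibble(measurements)
  for (col in c("cx", "cy", "a", "h")) {
    if (!col %in% names(m)) abort(sprintf("measurements need a '%s' column", col))
  }
  if (any(!is.finite(m$a)) || any(m$a <= 0) || any(!is.finite(m$h)) || any(m$h <= 0)) {
    abort("invalid measurement: aspect ratio and height must be finite and positive")
  }
  out <- mutate(m,
    w = .data$a * .data$h,
    x = .data$cx - .data$a * .data$h / 2,
    y = .data$cy - .data$h / 2,
    cx = NULL, cy = NULL, a = NULL
  )
  select(out, "x", "y", "w", "h", dplyr::everything())
}

check_boxes <- function(boxes, what = "box") {
  for (col in c("x", "y", "w", "h")) {
    if (!col %in% names(boxes)) abort(sprintf("%s data need a '%s' column", what, col))
  }
  bad <- !is.finite(boxes$w) | boxes$w <= 0 | !is.finite(boxes$h) | boxes$h <= 0
  if (any(bad)) {
    abort(sprintf("invalid %s: width and height must be finite and positive (rows %s)",
                  what, paste(head(which(bad), 5L), collapse = ", ")))
  }
  invisible(boxes)
}

# length-4 numeric versions used by the filter internals
box_to_z <- function(b) c(b[1] + b[3] / 2, b[2] + b[4] / 2, b[3] / b[4], b[4])
z_to_box <- function(z) {
  w <- z[3] * z[4]
  c(z[1] - w / 2, z[2] - z[4] / 2, w, z[4])
}

#' Intersection over union of axis-aligned boxes
#'
#' Areas are real-valued: a box is the closed rectangle
#' `[x, x + w] x [y, y + h]`, so IoU is continuous in the coordinates and
#' identical boxes score exactly 1.
#'
#' `box_iou()` compares two sets of boxes element-wise (recycling a set of
#' one); `iou_matrix()` returns all pairwise values.
#'
#' @param a,b Data frames with columns `x`, `y`, `w`, `h`.
#' @return `box_iou()`: a numeric vector in `[0, 1]`, one value per row
#'   pair. `iou_matrix()`: an `nrow(a) x nrow(b)` matrix.
#' @examples
#' box_iou(data.frame(x = 0, y = 0, w = 2, h = 2),
#'         data.frame(x = 1, y = 1, w = 2, h = 2))  # 1/7
#' @export
box_iou <- function(a, b) {
  check_boxes(a); check_boxes(b)
  n <- max(nrow(a), nrow(b))
  if (nrow(a) != nrow(b) && nrow(a) != 1L && nrow(b) != 1L) {
    abort("box_iou: row counts must match or one input must be a single box")
  }
  ax1 <- rep_len(a$x, n); ay1 <- rep_len(a$y, n)
  ax2 <- rep_len(a$x + a$w, n); ay2 <- rep_len(a$y + a$h, n)
  bx1 <- rep_len(b$x, n); by1 <- rep_len(b$y, n)
  bx2 <- rep_len(b$x + b$w, n); by2 <- rep_len(b$y + b$h, n)
  iw <- pmax(0, pmin(ax2, bx2) - pmax(ax1, bx1))
  ih <- pmax(0, pmin(ay2, by2) - pmax(ay1, by1))
  inter <- iw * ih
  union <- (ax2 - ax1) * (ay2 - ay1) + (bx2 - bx1) * (by2 - by1) - inter
  inter / union
}

#' @rdname box_iou
#' @export
iou_matrix <- function(a, b) {
  check_boxes(a); check_boxes(b)
  out <- matrix(0, nrow(a), nrow(b))
  if (nrow(a) == 0L || nrow(b) == 0L) return(out)
  for (i in seq_len(nrow(a))) {
    out[i, ] <- box_iou(a[i, , drop = FALSE], b)
  }
  out
}
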