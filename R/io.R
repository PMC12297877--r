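MOT_COLS <- c("frame", "id", "x", "y", "w", "h", "confidence", "class_id",
              "visibility")
MOT_CLASS_MAP <- c("1" = "Cell", "2" = "Division")

#' Read and write MOT-challenge track/detection files
#'
#' The nine-column comma-separated dialect
#' `frame, id, x, y, w, h, confidence, class_id, visibility` with 1-based
#' frame numbers, top-left box coordinates, `id = -1` for raw detections,
#' and class identifiers `1 = Cell`, `2 = Division`. Writing sorts records
#' by `(frame, id)` and uses fixed decimal formatting (2 decimals for
#' pixel quantities, 6 for confidence and visibility) so output is
#' byte-stable; round-trips are lossless at that precision.
#'
#' @param path File path.
#' @param records A data frame with the nine MOT columns (missing
#'   `confidence`, `class_id`, `visibility` default to 1).
#' @return `read_mot()` returns a tibble with the nine columns.
#' @export
read_mot <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(as_tibble(setNames(rep(list(numeric(0)), 9L), MOT_COLS)))
  }
  parts <- strsplit(lines, ",", fixed = TRUE)
  bad <- which(lengths(parts) != 9L)
  if (length(bad) > 0L) {
    abort(sprintf("malformed MOT line %d in %s: expected 9 comma-separated fields",
                  bad[1], path))
  }
  vals <- suppressWarnings(lapply(parts, as.numeric))
  bad <- which(vapply(vals, function(v) any(is.na(v)), logical(1)))
  if (length(bad) > 0L) {
    abort(sprintf("malformed MOT line %d in %s: non-numeric field", bad[1], path))
  }
  m <- do.call(rbind, vals)
  colnames(m) <- MOT_COLS
  out <- as_tibble(m)
  out$frame <- as.integer(out$frame)
  out$id <- as.integer(out$id)
  out$class_id <- as.integer(out$class_id)
  out
}

#' @rdname read_mot
#' @export
write_mot <- function(records, path) {
  records <- as_tibble(records)
  for (col in c("confidence", "class_id", "visibility")) {
    if (!col %in% names(records)) records[[col]] <- 1
  }
  records <- arrange(records, .data$frame, .data$id, .data$x, .data$y,
                     .data$w, .data$h)
  lines <- sprintf("%d,%d,%.2f,%.2f,%.2f,%.2f,%.6f,%d,%.6f",
                   as.integer(records$frame), as.integer(records$id),
                   records$x, records$y, records$w, records$h,
                   records$confidence, as.integer(records$class_id),
                   records$visibility)
  writeLines(lines, path)
  invisible(path)
}

#' Convert between MOT records and the package's tables
#'
#' `mot_to_detections()` and `mot_to_gt()` map the numeric `class_id` to
#' the class labels (`1 = Cell`, `2 = Division`); `detections_to_mot()`,
#' `gt_to_mot()` and `tracks_to_mot()` go the other way (raw detections
#' get `id = -1`).
#'
#' @param records,x A MOT record tibble / a package-side table.
#' @return A tibble in the target shape.
#' @export
mot_to_detections <- function(records) {
  tibble(frame = records$frame, x = records$x, y = records$y,
         w = records$w, h = records$h,
         class = unname(MOT_CLASS_MAP[as.character(records$class_id)]),
         confidence = records$confidence)
}

#' @rdname mot_to_detections
#' @export
mot_to_gt <- function(records) {
  tibble(frame = records$frame, id = records$id, x = records$x, y = records$y,
         w = records$w, h = records$h,
         class = unname(MOT_CLASS_MAP[as.character(records$class_id)]))
}

class_to_id <- function(class) ifelse(class == "Division", 2L, 1L)

#' @rdname mot_to_detections
#' @export
detections_to_mot <- function(x) {
  as_tibble(data.frame(
    frame = x$frame, id = -1L, x = x$x, y = x$y, w = x$w, h = x$h,
    confidence = if ("confidence" %in% names(x)) x$confidence else 1,
    class_id = class_to_id(if ("class" %in% names(x)) x$class else "Cell"),
    visibility = 1))
}

#' @rdname mot_to_detections
#' @export
gt_to_mot <- function(x) {
  as_tibble(data.frame(
    frame = x$frame, id = x$id, x = x$x, y = x$y, w = x$w, h = x$h,
    confidence = 1,
    class_id = class_to_id(if ("class" %in% names(x)) x$class else "Cell"),
    visibility = 1))
}

#' @rdname mot_to_detections
#' @export
tracks_to_mot <- function(x) {
  if (inherits(x, "cell_tracks")) x <- x$results
  as_tibble(data.frame(
    frame = x$frame, id = x$track_id, x = x$x, y = x$y, w = x$w, h = x$h,
    confidence = ifelse(x$source == "predicted", 0.5, 1),
    class_id = class_to_id(x$class), visibility = 1))
}

#' Read and write YOLO-style per-frame annotation files
#'
#' One line per box: `class cx cy w h [confidence]`, all coordinates
#' normalised to the frame size (class identifiers `0 = Cell`,
#' `1 = Division`). Reading denormalises to top-left pixel boxes.
#'
#' @param path File path.
#' @param frame_width,frame_height Frame size in pixels.
#' @param boxes A data frame with `x`, `y`, `w`, `h` and optionally
#'   `class`, `confidence`.
#' @param class_map Named character vector mapping class ids to labels.
#' @return `read_yolo_frame()` returns a tibble `x`, `y`, `w`, `h`,
#'   `class`, `confidence`.
#' @export
read_yolo_frame <- function(path, frame_width, frame_height,
                            class_map = c("0" = "Cell", "1" = "Division")) {
  if (frame_width <= 0 || frame_height <= 0) abort("frame dimensions must be positive")
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(tibble(x = numeric(0), y = numeric(0), w = numeric(0), h = numeric(0),
                  class = character(0), confidence = numeric(0)))
  }
  parts <- strsplit(trimws(lines), "\\s+")
  bad <- which(!lengths(parts) %in% c(5L, 6L))
  if (length(bad) > 0L) {
    abort(sprintf("malformed YOLO line %d in %s: expected 5 or 6 fields", bad[1], path))
  }
  rows <- lapply(seq_along(parts), function(i) {
    v <- suppressWarnings(as.numeric(parts[[i]]))
    if (any(is.na(v))) abort(sprintf("malformed YOLO line %d in %s", i, path))
    if (any(v[2:5] < 0) || any(v[2:5] > 1)) {
      abort(sprintf("malformed YOLO line %d in %s: normalized value outside [0, 1]",
                    i, path))
    }
    tibble(x = (v[2] - v[4] / 2) * frame_width,
           y = (v[3] - v[5] / 2) * frame_height,
           w = v[4] * frame_width, h = v[5] * frame_height,
           class = unname(class_map[as.character(as.integer(v[1]))]),
           confidence = if (length(v) == 6L) v[6] else 1)
  })
  bind_rows(rows)
}

#' @rdname read_yolo_frame
#' @export
write_yolo_frame <- function(boxes, path, frame_width, frame_height,
                             class_map = c("0" = "Cell", "1" = "Division")) {
  inv_map <- setNames(names(class_map), class_map)
  class <- if ("class" %in% names(boxes)) boxes$class else rep("Cell", nrow(boxes))
  conf <- if ("confidence" %in% names(boxes)) boxes$confidence else rep(1, nrow(boxes))
  lines <- sprintf("%s %.15f %.15f %.15f %.15f %.6f",
                   inv_map[class],
                   (boxes$x + boxes$w / 2) / frame_width,
                   (boxes$y + boxes$h / 2) / frame_height,
                   boxes$w / frame_width, boxes$h / frame_height, conf)
  writeLines(lines, path)
  invisible(path)
}

#' Read a flat key-value configuration file
#'
#' One `key = value` pair per line; `#` starts a comment. Values are
#' converted to numeric where possible, to logical for `true`/`false`.
#'
#' @param path File path.
#' @return A named list.
#' @export
read_config_file <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (i in seq_along(lines)) {
    kv <- strsplit(lines[i], "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L) abort(sprintf("malformed config line: '%s'", lines[i]))
    key <- trimws(kv[1]); val <- trimws(kv[2])
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num
      else if (tolower(val) %in% c("true", "false")) as.logical(toupper(val))
      else val
  }
  out
}
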