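#' Synthetic time-lapse configuration
#'
#' Parameters of the synthetic cell-motion generator. The defaults emulate
#' the statistical structure of a moderately sparse adherent melanoma
#' culture imaged by long-term grayscale microscopy: 1600 x 1200 frames,
#' 10-22 objects per frame, two object classes (`Cell` and the rarer,
#' larger and rounder `Division`), and cells moving on curved paths.
#' Motion is a heading-noise random walk — a constant speed along a
#' heading that diffuses with Gaussian turn noise — which is deliberately
#' *not* the tracker's constant-velocity model, so tracking is exercised
#' under model mismatch.
#'
#' @param frames Number of frames.
#' @param width,height Frame size in pixels.
#' @param n_cells Integer range `c(min, max)` for the initial cell count
#'   (drawn uniformly).
#' @param division_rate Per-cell per-frame probability that a `Cell`
#'   enters the division phase. The default keeps divisions rare, matching
#'   the strong class imbalance of real mitosis annotations.
#' @param speed Range (px/frame) of per-cell constant speeds.
#' @param turn_sd Heading diffusion (rad/frame).
#' @param h_mean,h_sd Box height distribution (px).
#' @param aspect_mean,aspect_sd Aspect-ratio distribution.
#' @param division_frames Length of the division phase in frames; at its
#'   end the parent is replaced by two daughter cells.
#' @param division_inflate Box inflation factor during the division phase
#'   (divisions appear larger; their aspect ratio is pulled to 1 so they
#'   also appear rounder).
#' @param well_separated If `TRUE`, cells are confined to disjoint tiles
#'   of the frame so trajectories never approach each other — the regime
#'   in which a tracker should make no identity mistakes at all.
#' @param embedding_dim Length of the per-cell appearance signature
#'   vectors used by [signature_embeddings()].
#' @param seed Integer seed; the whole generator is deterministic given
#'   it.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(frames = 100L, width = 1600L, height = 1200L,
                       n_cells = c(10L, 22L), division_rate = 0.002,
                       speed = c(1, 4), turn_sd = 0.3,
                       h_mean = 40, h_sd = 6,
                       aspect_mean = 1.3, aspect_sd = 0.2,
                       division_frames = 5L, division_inflate = 1.4,
                       well_separated = FALSE, embedding_dim = 16L,
                       seed = 1L) {
  if (frames < 1L) abort("frames must be >= 1")
  if (division_rate < 0 || division_rate > 1) abort("division_rate must lie in [0, 1]")
  if (length(n_cells) == 1L) n_cells <- rep(n_cells, 2L)
  if (n_cells[1] > n_cells[2] || n_cells[1] < 1L) abort("invalid n_cells range")
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate ground-truth cell trajectories
#'
#' Generates per-frame ground-truth boxes for a population of cells moving
#' on heading-noise random walks inside the frame (reflecting at the
#' borders). With probability `division_rate` per frame a `Cell` switches
#' to the `Division` class — its box inflates and rounds — for
#' `division_frames` frames, after which it is replaced by two daughter
#' cells with fresh identities.
#'
#' @param config A [sim_config()].
#' @return A tibble of class `"cell_gt"` with columns `frame`, `id`, `x`,
#'   `y`, `w`, `h`, `class`, plus attributes `lineage` (tibble `parent`,
#'   `daughter1`, `daughter2`, `frame`), `signatures` (matrix of unit
#'   appearance signatures, one row per identity) and `config`.
#' @export
simulate_cells <- function(config = sim_config()) {
  cf <- config
  with_preserved_seed(cf$seed, {
    n0 <- if (cf$n_cells[1] == cf$n_cells[2]) cf$n_cells[1] else
      sample(cf$n_cells[1]:cf$n_cells[2], 1L)
    tiles <- if (cf$well_separated) make_tiles(n0, cf$width, cf$height) else NULL
    cells <- lapply(seq_len(n0), function(i) {
      bounds <- if (is.null(tiles)) c(0, cf$width, 0, cf$height) else tiles[i, ]
      margin <- cf$h_mean
      list(id = i,
           cx = runif(1, bounds[1] + margin, bounds[2] - margin),
           cy = runif(1, bounds[3] + margin, bounds[4] - margin),
           heading = runif(1, 0, 2 * pi),
           speed = runif(1, cf$speed[1], cf$speed[2]),
           h = max(rnorm(1, cf$h_mean, cf$h_sd), 12),
           a = max(rnorm(1, cf$aspect_mean, cf$aspect_sd), 0.5),
           class = "Cell", phase_left = NA_integer_, bounds = bounds)
    })
    next_id <- n0 + 1L
    rows <- vector("list", cf$frames)
    lineage <- list()
    for (f in seq_len(cf$frames)) {
      # Cell -> Division transitions
      if (cf$division_rate > 0) {
        for (k in seq_along(cells)) {
          if (cells[[k]]$class == "Cell" && runif(1) < cf$division_rate) {
            cells[[k]]$class <- "Division"
            cells[[k]]$phase_left <- cf$division_frames
          }
        }
      }
      # record frame
      rows[[f]] <- bind_rows(lapply(cells, function(c) {
        dividing <- c$class == "Division"
        h <- if (dividing) c$h * cf$division_inflate else c$h
        a <- if (dividing) 1 else c$a
        w <- a * h
        tibble(frame = f, id = c$id,
               x = min(max(c$cx - w / 2, 0), cf$width - w),
               y = min(max(c$cy - h / 2, 0), cf$height - h),
               w = w, h = h, class = c$class)
      }))
      # complete divisions: replace parent with two daughters
      done <- integer(0)
      spawned <- list()
      for (k in seq_along(cells)) {
        c <- cells[[k]]
        if (c$class != "Division") next
        c$phase_left <- c$phase_left - 1L
        cells[[k]] <- c
        if (c$phase_left <= 0L && f < cf$frames) {
          done <- c(done, k)
          perp <- c$heading + pi / 2
          off <- c$h / 2
          kids <- lapply(1:2, function(s) {
            sgn <- if (s == 1L) 1 else -1
            list(id = next_id + s - 1L,
                 cx = min(max(c$cx + sgn * off * cos(perp), c$bounds[1] + 10),
                          c$bounds[2] - 10),
                 cy = min(max(c$cy + sgn * off * sin(perp), c$bounds[3] + 10),
                          c$bounds[4] - 10),
                 heading = runif(1, 0, 2 * pi),
                 speed = runif(1, cf$speed[1], cf$speed[2]),
                 h = max(c$h * 0.8, 12), a = max(c$a * runif(1, 0.9, 1.1), 0.5),
                 class = "Cell", phase_left = NA_integer_, bounds = c$bounds)
          })
          spawned <- c(spawned, kids)
          lineage[[length(lineage) + 1L]] <-
            tibble(parent = c$id, daughter1 = kids[[1]]$id,
                   daughter2 = kids[[2]]$id, frame = f + 1L)
          next_id <- next_id + 2L
        }
      }
      if (length(done) > 0L) cells <- cells[-done]
      cells <- c(cells, spawned)
      # motion update for the next frame
      cells <- lapply(cells, function(c) {
        c$heading <- c$heading + rnorm(1, 0, cf$turn_sd)
        c$cx <- c$cx + c$speed * cos(c$heading)
        c$cy <- c$cy + c$speed * sin(c$heading)
        margin <- c$h * max(c$a, 1) / 2 + 1
        if (c$cx < c$bounds[1] + margin) { c$cx <- c$bounds[1] + margin; c$heading <- pi - c$heading }
        if (c$cx > c$bounds[2] - margin) { c$cx <- c$bounds[2] - margin; c$heading <- pi - c$heading }
        if (c$cy < c$bounds[3] + margin) { c$cy <- c$bounds[3] + margin; c$heading <- -c$heading }
        if (c$cy > c$bounds[4] - margin) { c$cy <- c$bounds[4] - margin; c$heading <- -c$heading }
        c
      })
    }
    gt <- bind_rows(rows)
    sig <- matrix(rnorm(cf$embedding_dim * (next_id - 1L)), ncol = cf$embedding_dim)
    sig <- sig / sqrt(rowSums(sig^2))
    rownames(sig) <- as.character(seq_len(next_id - 1L))
    structure(gt,
              lineage = if (length(lineage) > 0L) bind_rows(lineage) else
                tibble(parent = integer(0), daughter1 = integer(0),
                       daughter2 = integer(0), frame = integer(0)),
              signatures = sig, config = cf,
              class = c("cell_gt", class(gt)))
  })
}

# disjoint tiles covering the frame, one per cell
make_tiles <- function(n, width, height) {
  ncols <- ceiling(sqrt(n * width / height))
  nrows <- ceiling(n / ncols)
  tw <- width / ncols; th <- height / nrows
  t(vapply(seq_len(n) - 1L, function(k) {
    col <- k %% ncols; row <- k %/% ncols
    c(col * tw, (col + 1) * tw, row * th, (row + 1) * th)
  }, numeric(4)))
}

#' Degrade ground truth into a detector-like stream
#'
#' Emulates an imperfect detector: every ground-truth box is independently
#' dropped with probability `dropout_p`, surviving boxes get Gaussian
#' jitter on centre, width and height, and a confidence drawn uniformly
#' from `[0.5, 1]`. Optionally, spurious clutter boxes are added at a
#' per-frame Poisson rate. The originating ground-truth identity is kept
#' in a `source_id` column (NA for clutter) so that synthetic appearance
#' embeddings can be attached; the tracker itself never reads it.
#'
#' @param gt A `"cell_gt"` tibble from [simulate_cells()].
#' @param dropout_p Per-box miss probability.
#' @param jitter_sigma Box-noise standard deviation in pixels.
#' @param clutter_rate Expected false positives per frame (default 0).
#' @param seed Integer seed (independent of the simulation seed).
#' @return A detections tibble: `frame`, `x`, `y`, `w`, `h`, `class`,
#'   `confidence`, `source_id`.
#' @export
degrade_detections <- function(gt, dropout_p = 0.3, jitter_sigma = 1.0,
                               clutter_rate = 0, seed = 1L) {
  if (dropout_p < 0 || dropout_p > 1) abort("dropout_p must lie in [0, 1]")
  cf <- attr(gt, "config")
  with_preserved_seed(seed, {
    keep <- runif(nrow(gt)) >= dropout_p
    d <- as_tibble(gt)[keep, , drop = FALSE]
    n <- nrow(d)
    cx <- d$x + d$w / 2 + rnorm(n, 0, jitter_sigma)
    cy <- d$y + d$h / 2 + rnorm(n, 0, jitter_sigma)
    w <- pmax(d$w + rnorm(n, 0, jitter_sigma), 4)
    h <- pmax(d$h + rnorm(n, 0, jitter_sigma), 4)
    out <- tibble(frame = d$frame, x = cx - w / 2, y = cy - h / 2, w = w, h = h,
                  class = d$class, confidence = runif(n, 0.5, 1),
                  source_id = d$id)
    if (clutter_rate > 0 && !is.null(cf)) {
      clut <- lapply(sort(unique(gt$frame)), function(f) {
        k <- stats::rpois(1, clutter_rate)
        if (k == 0L) return(NULL)
        h <- pmax(rnorm(k, cf$h_mean, cf$h_sd), 12)
        w <- h * pmax(rnorm(k, cf$aspect_mean, cf$aspect_sd), 0.5)
        tibble(frame = f, x = runif(k, 0, cf$width - w), y = runif(k, 0, cf$height - h),
               w = w, h = h, class = "Cell", confidence = runif(k, 0.5, 1),
               source_id = NA_integer_)
      })
      out <- bind_rows(out, bind_rows(clut))
    }
    arrange(out, .data$frame)
  })
}

#' Synthetic appearance embeddings from cell signatures
#'
#' Attaches to every detection a noisy, re-normalised copy of the unit
#' "appearance signature" of the cell it originated from (clutter
#' detections get independent random signatures). This gives the
#' association stage an appearance channel with the right structure —
#' embeddings of the same cell cluster tightly, embeddings of different
#' cells are nearly orthogonal in high dimension — without rendering any
#' pixels.
#'
#' @param detections A detections tibble from [degrade_detections()]
#'   (needs the `source_id` column).
#' @param gt The `"cell_gt"` the detections came from (supplies the
#'   signature matrix).
#' @param noise_sd Elementwise Gaussian noise added before re-normalising.
#' @param seed Integer seed.
#' @return A list indexed by frame number; element `f` is the embedding
#'   matrix for frame `f`'s detections, rows in detection order.
#' @export
signature_embeddings <- function(detections, gt, noise_sd = 0.05, seed = 1L) {
  sig <- attr(gt, "signatures")
  if (is.null(sig)) abort("gt carries no signature matrix; use simulate_cells()")
  if (!"source_id" %in% names(detections)) {
    abort("detections need the 'source_id' column from degrade_detections()")
  }
  n_frames <- max(gt$frame)
  dim_e <- ncol(sig)
  with_preserved_seed(seed, {
    lapply(seq_len(n_frames), function(f) {
      d <- detections[detections$frame == f, , drop = FALSE]
      if (nrow(d) == 0L) return(NULL)
      emb <- t(vapply(d$source_id, function(id) {
        base <- if (is.na(id)) rnorm(dim_e) else sig[as.character(id), ]
        v <- base + rnorm(dim_e, 0, noise_sd)
        v / sqrt(sum(v^2))
      }, numeric(dim_e)))
      emb
    })
  })
}

#' Render ground truth to grayscale frames
#'
#' Draws each cell as an anisotropic Gaussian intensity blob scaled to its
#' box on a noisy background, `Division`-class cells brighter, and returns
#' 8-bit-range matrices. Intended for exercising the image pipeline on
#' small frames; it makes no attempt at optical realism.
#'
#' @param gt A `"cell_gt"` tibble.
#' @param width,height Frame size in pixels (defaults from the simulation
#'   config).
#' @param background Mean background intensity.
#' @param bg_noise Background noise standard deviation.
#' @param cell_intensity,division_intensity Peak amplitudes added above
#'   background.
#' @param seed Integer seed for the background noise.
#' @return A list of numeric matrices (values in `[0, 255]`), one per
#'   frame.
#' @export
render_frames <- function(gt, width = NULL, height = NULL,
                          background = 40, bg_noise = 5,
                          cell_intensity = 90, division_intensity = 150,
                          seed = 1L) {
  cf <- attr(gt, "config")
  if (is.null(width)) width <- if (!is.null(cf)) cf$width else ceiling(max(gt$x + gt$w))
  if (is.null(height)) height <- if (!is.null(cf)) cf$height else ceiling(max(gt$y + gt$h))
  n_frames <- max(gt$frame)
  with_preserved_seed(seed, {
    lapply(seq_len(n_frames), function(f) {
      img <- matrix(background + rnorm(width * height, 0, bg_noise), height, width)
      d <- gt[gt$frame == f, , drop = FALSE]
      for (k in seq_len(nrow(d))) {
        amp <- if (d$class[k] == "Division") division_intensity else cell_intensity
        img <- add_blob(img, d$x[k] + d$w[k] / 2, d$y[k] + d$h[k] / 2,
                        d$w[k] / 4, d$h[k] / 4, amp)
      }
      pmin(pmax(img, 0), 255)
    })
  })
}

add_blob <- function(img, cx, cy, sx, sy, amp) {
  H <- nrow(img); W <- ncol(img)
  x1 <- max(1L, floor(cx - 3 * sx)); x2 <- min(W, ceiling(cx + 3 * sx))
  y1 <- max(1L, floor(cy - 3 * sy)); y2 <- min(H, ceiling(cy + 3 * sy))
  if (x1 > x2 || y1 > y2) return(img)
  xs <- x1:x2; ys <- y1:y2
  gx <- exp(-((xs - cx)^2) / (2 * sx^2))
  gy <- exp(-((ys - cy)^2) / (2 * sy^2))
  img[ys, xs] <- img[ys, xs] + amp * outer(gy, gx)
  img
}

#' Invert the grayscale levels of a frame
#'
#' The contrast augmentation used on microscopy frames: every 8-bit pixel
#' `p` becomes `255 - p`. Applying it twice is the identity.
#'
#' @param frame A numeric matrix in `[0, 255]`.
#' @return The inverted matrix.
#' @export
invert_intensity <- function(frame) 255 - frame
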