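#' Global average pooling of a convolutional feature map
#'
#' Collapses an `H x W x C` feature map to a length-`C` vector by averaging
#' each channel over all spatial positions.
#'
#' @param f A 3-d numeric array (`H x W x C`) or a matrix (treated as a
#'   single channel).
#' @return A numeric vector of length `C`.
#' @export
pool_feature_map <- function(f) {
  if (is.matrix(f)) f <- array(f, c(dim(f), 1L))
  if (!is.array(f) || length(dim(f)) != 3L || any(dim(f) < 1L)) {
    abort("feature map must be a non-empty H x W x C array")
  }
  if (any(!is.finite(f))) abort("feature map contains non-finite values")
  apply(f, 3L, mean)
}

#' Fuse per-scale pooled vectors into one appearance embedding
#'
#' Concatenates the pooled vectors of the three scales in order and divides
#' by the L2 norm of the concatenation, so every embedding lies on the unit
#' sphere and differences in overall feature magnitude between objects are
#' discarded.
#'
#' @param e1,e2,e3 Numeric vectors (pooled per-scale features).
#' @return A unit-norm numeric vector of length
#'   `length(e1) + length(e2) + length(e3)`.
#' @export
fuse_embeddings <- function(e1, e2, e3 = numeric(0)) {
  v <- c(e1, e2, e3)
  nrm <- sqrt(sum(v^2))
  if (!is.finite(nrm) || nrm == 0) abort("degenerate embedding: zero or non-finite norm")
  v / nrm
}

#' Cosine distance between appearance embeddings
#'
#' `1 - cos(angle)` between the two vectors, normalising by both norms so
#' unnormalised inputs are handled too. Ranges from 0 (parallel) through 1
#' (orthogonal) to 2 (antiparallel).
#'
#' @param a,b Numeric vectors of equal length with nonzero norm.
#' @return A scalar in `[0, 2]`.
#' @export
cosine_distance <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) abort("degenerate embedding: zero norm")
  d <- 1 - sum(a * b) / (na * nb)
  min(max(d, 0), 2)
}

# cosine distances between one embedding matrix (rows) and a single vector
cosine_distance_rows <- function(M, v) {
  apply(M, 1L, cosine_distance, b = v)
}

#' A deterministic, training-free multi-scale backbone
#'
#' Builds a backbone function satisfying the three-scale feature contract
#' used by [embed_detections()]: given an image crop it returns three
#' feature maps at strictly decreasing spatial resolution. Channels are
#' fixed non-linear functionals of the intensity image — sinusoids of
#' random frequency/phase applied to a downsampled copy, mixed with local
#' gradient magnitude — with all coefficients drawn once from `seed` when
#' the backbone is constructed. The same crop therefore always yields
#' bit-identical features, while crops with different intensity patterns
#' separate in cosine distance. It stands in for a learned convolutional
#' backbone wherever reproducibility matters more than discriminative
#' power (tests, simulations); a pretrained network can be plugged in
#' through the same contract.
#'
#' @param channels Integer vector of length 3: channel counts per scale.
#' @param input_size Side length (pixels) crops are resized to before
#'   feature extraction.
#' @param seed Integer seed fixing the random functionals.
#' @return A function `crop -> list of three H_i x W_i x C_i arrays`, with
#'   attributes `input_size` and `channels`.
#' @export
toy_backbone <- function(channels = c(8L, 16L, 32L), input_size = 128L, seed = 1L) {
  stopifnot(length(channels) == 3L, all(channels >= 1L), input_size >= 16L)
  coefs <- with_preserved_seed(seed, {
    lapply(channels, function(C) {
      list(freq  = runif(C, 0.5, 6),
           phase = runif(C, 0, 2 * pi),
           mix   = runif(C, 0, 1))
    })
  })
  sizes <- pmax(c(input_size %/% 4L, input_size %/% 8L, input_size %/% 16L), 2L)
  fn <- function(crop) {
    if (is.null(dim(crop)) || any(dim(crop) == 0L)) abort("empty crop")
    img <- resize_bilinear(crop / 255, input_size, input_size)
    lapply(1:3, function(i) {
      base <- resize_bilinear(img, sizes[i], sizes[i])
      grad <- gradient_magnitude(base)
      co <- coefs[[i]]
      out <- array(0, c(sizes[i], sizes[i], channels[i]))
      for (c in seq_len(channels[i])) {
        out[, , c] <- cos(co$freq[c] * 2 * pi * base + co$phase[c]) * (1 - co$mix[c]) +
          grad * co$mix[c]
      }
      out
    })
  }
  attr(fn, "input_size") <- input_size
  attr(fn, "channels") <- channels
  fn
}

# run code with a temporary RNG state, restoring the caller's stream
with_preserved_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# bilinear resampling of a numeric matrix to out_h x out_w
resize_bilinear <- function(img, out_h, out_w) {
  h <- nrow(img); w <- ncol(img)
  if (h == out_h && w == out_w) return(img)
  ys <- if (out_h == 1L) rep((h + 1) / 2, 1L) else seq(1, h, length.out = out_h)
  xs <- if (out_w == 1L) rep((w + 1) / 2, 1L) else seq(1, w, length.out = out_w)
  y0 <- pmin(floor(ys), h - 1L); x0 <- pmin(floor(xs), w - 1L)
  if (h == 1L) y0 <- rep(1L, out_h)
  if (w == 1L) x0 <- rep(1L, out_w)
  fy <- ys - y0; fx <- xs - x0
  y1 <- pmin(y0 + 1L, h); x1 <- pmin(x0 + 1L, w)
  a <- img[y0, x0, drop = FALSE]; b <- img[y0, x1, drop = FALSE]
  c_ <- img[y1, x0, drop = FALSE]; d <- img[y1, x1, drop = FALSE]
  wy <- matrix(fy, out_h, out_w); wx <- matrix(fx, out_h, out_w, byrow = TRUE)
  a * (1 - wy) * (1 - wx) + b * (1 - wy) * wx + c_ * wy * (1 - wx) + d * wy * wx
}

gradient_magnitude <- function(img) {
  h <- nrow(img); w <- ncol(img)
  gx <- cbind(img[, 2:w, drop = FALSE], img[, w, drop = FALSE]) - img
  gy <- rbind(img[2:h, , drop = FALSE], img[h, , drop = FALSE]) - img
  sqrt(gx^2 + gy^2)
}

# crop a box out of a frame matrix (0..255), clipping to the frame bounds;
# a box fully outside the frame is an error.
crop_box <- function(frame, x, y, w, h) {
  H <- nrow(frame); W <- ncol(frame)
  x1 <- max(floor(x) + 1L, 1L); y1 <- max(floor(y) + 1L, 1L)
  x2 <- min(ceiling(x + w), W); y2 <- min(ceiling(y + h), H)
  if (x1 > x2 || y1 > y2) abort("box lies fully outside the frame: zero-area crop")
  frame[y1:y2, x1:x2, drop = FALSE]
}

#' Embed detections of one frame
#'
#' For each detection box: crop the frame (clipping boxes that stick out of
#' it), resize the crop to the backbone's input size, run the backbone,
#' global-average-pool each of the three feature maps and fuse the pooled
#' vectors into one unit-norm embedding.
#'
#' @param frame A numeric matrix, the grayscale frame with intensities in
#'   `[0, 255]` (rows = y, columns = x).
#' @param boxes A data frame of detection boxes (columns `x`, `y`, `w`,
#'   `h`).
#' @param backbone A backbone function as returned by [toy_backbone()].
#' @return A numeric matrix with one unit-norm embedding per row, rows in
#'   box order.
#' @export
embed_detections <- function(frame, boxes, backbone = toy_backbone()) {
  check_boxes(boxes)
  if (nrow(boxes) == 0L) return(matrix(numeric(0), 0L, 0L))
  emb <- lapply(seq_len(nrow(boxes)), function(i) {
    crop <- crop_box(frame, boxes$x[i], boxes$y[i], boxes$w[i], boxes$h[i])
    maps <- backbone(crop)
    pooled <- lapply(maps, pool_feature_map)
    fuse_embeddings(pooled[[1]], pooled[[2]], pooled[[3]])
  })
  do.call(rbind, emb)
}

#' Read and write grayscale frames
#'
#' Frames are plain numeric matrices with 8-bit intensity semantics
#' (`0..255`). Files are read and written through EBImage, so PNG and TIFF
#' both work; colour images are averaged to grayscale on read.
#'
#' @param path File path.
#' @param frame A numeric matrix in `[0, 255]`.
#' @return `read_frame()` returns a numeric matrix in `[0, 255]`.
#' @export
read_frame <- function(path) {
  img <- EBImage::imageData(EBImage::readImage(path))
  if (length(dim(img)) == 3L) img <- apply(img, c(1, 2), mean)
  t(img) * 255  # EBImage stores x-major; frames here are row = y
}

#' @rdname read_frame
#' @export
write_frame <- function(frame, path) {
  EBImage::writeImage(EBImage::Image(t(pmin(pmax(frame, 0), 255) / 255)), path)
  invisible(path)
}
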