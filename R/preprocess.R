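#' Split a candled image into its colour channels
#'
#' In candling images the red channel carries the strongest egg-versus-
#' background contrast (used to locate the egg) while the blue channel
#' carries the strongest yolk-versus-albumen contrast (used to segment the
#' yolk shadow), so the pipeline works on the separated channels.
#'
#' @param img A `candled_image`.
#' @return Named list of numeric matrices `red`, `green`, `blue`.
#' @export
split_channels <- function(img) {
  if (!inherits(img, "candled_image")) abort("expected a candled_image")
  list(red = img$red, green = img$green, blue = img$blue)
}

#' 3x3 median filter
#'
#' Each output pixel is the median of its 3x3 neighbourhood; the border is
#' handled by edge replication. Implemented as a 19-exchange selection
#' network over the nine shifted copies of the grid, so it is fully
#' vectorized.
#'
#' @param grid Numeric matrix, at least 3x3.
#' @return Filtered matrix of the same shape.
#' @export
median3 <- function(grid) {
  h <- nrow(grid); w <- ncol(grid)
  if (h < 3 || w < 3) abort("median3 needs a grid of at least 3x3")
  ri <- c(1L, seq_len(h), h)          # replicated-edge index vectors
  ci <- c(1L, seq_len(w), w)
  pad <- grid[ri, ci]
  p <- vector("list", 9)
  k <- 0
  for (dc in 0:2) for (dr in 0:2) {
    k <- k + 1
    p[[k]] <- pad[dr + seq_len(h), dc + seq_len(w)]
  }
  sw <- function(a, b) {       # compare-exchange: p[[a]] <= p[[b]] after
    lo <- pmin(p[[a]], p[[b]])
    p[[b]] <<- pmax(p[[a]], p[[b]])
    p[[a]] <<- lo
  }
  # 9-input median selection network (Paeth), 1-based indices
  sw(2, 3); sw(5, 6); sw(8, 9); sw(1, 2); sw(4, 5); sw(7, 8)
  sw(2, 3); sw(5, 6); sw(8, 9); sw(1, 4); sw(6, 9); sw(5, 8)
  sw(4, 7); sw(2, 5); sw(3, 6); sw(5, 8); sw(5, 3); sw(7, 5); sw(5, 3)
  p[[5]]
}

#' Otsu threshold of an intensity grid
#'
#' The integer threshold in `0..254` that maximizes the between-class
#' variance of the 256-bin histogram; pixels *above* the threshold are
#' foreground under [binarize()]. Ties are resolved to the lowest
#' threshold. A constant grid has no between-class variance anywhere; the
#' constant value itself is returned with a warning, so that binarization
#' yields an all-background mask.
#'
#' @param grid Numeric matrix with values in `[0, 255]` (rounded to
#'   integers internally).
#' @return Integer threshold.
#' @export
otsu_level <- function(grid) {
  v <- as.integer(round(grid))
  if (length(v) == 0) abort("empty grid")
  if (any(v < 0L | v > 255L)) abort("values outside [0, 255]")
  counts <- tabulate(v + 1L, nbins = 256L)
  if (sum(counts > 0) == 1) {
    warn("constant grid: Otsu threshold undefined, returning the constant")
    return(which(counts > 0) - 1L)
  }
  n <- length(v)
  lev <- 0:255
  w0 <- cumsum(counts) / n                    # class 0: value <= t
  mu0 <- cumsum(counts * lev) / pmax(cumsum(counts), 1)
  mu <- sum(counts * lev) / n
  mu1 <- (mu - w0 * mu0) / pmax(1 - w0, .Machine$double.eps)
  bcv <- w0 * (1 - w0) * (mu0 - mu1)^2
  bcv <- bcv[1:255]                           # thresholds 0..254
  which.max(bcv) - 1L
}

#' @rdname otsu_level
#' @param threshold Integer threshold; pixels strictly above it become 1.
#' @return `binarize()`: integer 0/1 matrix.
#' @export
binarize <- function(grid, threshold) {
  matrix(as.integer(grid > threshold), nrow(grid), ncol(grid))
}

#' Padded square crop rectangle around the egg
#'
#' Takes the largest 8-connected foreground component of a binary grid,
#' expands its bounding box symmetrically to a square, pads all four sides
#' by `pad` pixels, and clamps the result to the image. If clamping makes
#' the window non-square it is re-squared by shrinking from the opposite,
#' unclamped side.
#'
#' @param binary_grid Binary matrix with at least one foreground pixel.
#' @param pad Padding in pixels on each side (default 30).
#' @return A `crop_rect`: list with 1-based `top`, `left` and `side`.
#' @export
egg_bbox <- function(binary_grid, pad = 30) {
  comp <- largest_component(binary_grid)
  if (is.null(comp)) abort("no foreground pixels")
  idx <- which(comp == 1L, arr.ind = TRUE)
  r0 <- min(idx[, 1]); r1 <- max(idx[, 1])
  c0 <- min(idx[, 2]); c1 <- max(idx[, 2])
  hgt <- r1 - r0 + 1L; wid <- c1 - c0 + 1L
  side <- max(hgt, wid)
  # symmetric expansion of the shorter dimension to `side`
  top <- r0 - floor((side - hgt) / 2)
  left <- c0 - floor((side - wid) / 2)
  top <- top - pad; left <- left - pad
  side <- side + 2L * pad
  clamp_rect(top, left, side, nrow(binary_grid), ncol(binary_grid))
}

clamp_rect <- function(top, left, side, h, w) {
  side <- min(side, h, w)
  # shift the window inside the image (shrinking is only needed when the
  # image itself is smaller than the requested side, handled above)
  top <- min(max(top, 1L), h - side + 1L)
  left <- min(max(left, 1L), w - side + 1L)
  structure(list(top = as.integer(top), left = as.integer(left),
                 side = as.integer(side)), class = "crop_rect")
}

#' @rdname egg_bbox
#' @param grid Matrix to crop.
#' @param rect A `crop_rect`.
#' @return `crop_rect_apply()`: the `side` x `side` submatrix.
#' @export
crop_rect_apply <- function(grid, rect) {
  grid[rect$top + seq_len(rect$side) - 1L,
       rect$left + seq_len(rect$side) - 1L, drop = FALSE]
}

#' Remove the background with a binary mask
#'
#' Elementwise product of a region of interest with its binary egg mask:
#' the background becomes exactly 0, egg-region values are unchanged.
#'
#' @param roi_grid,mask_grid Matrices of identical shape; mask in `{0, 1}`.
#' @return Masked matrix.
#' @export
apply_mask <- function(roi_grid, mask_grid) {
  if (!all(dim(roi_grid) == dim(mask_grid))) abort("shape mismatch")
  roi_grid * (mask_grid != 0)
}

# Catmull-Rom cubic kernel (a = -0.5), the classic bicubic interpolant.
cubic_kernel <- function(x) {
  ax <- abs(x)
  ifelse(ax <= 1, 1.5 * ax^3 - 2.5 * ax^2 + 1,
         ifelse(ax < 2, -0.5 * ax^3 + 2.5 * ax^2 - 4 * ax + 2, 0))
}

# Row-interpolation weight matrix mapping n_in samples to n_out, with the
# kernel widened by the scale factor when downsampling (antialiasing).
# Rows are renormalized to sum to 1, which also supplies edge replication.
resample_weights <- function(n_in, n_out, antialias = TRUE) {
  scale <- n_in / n_out
  kw <- if (antialias && scale > 1) scale else 1
  u <- (seq_len(n_out) - 0.5) * scale - 0.5 + 1   # 1-based source position
  w <- outer(u, seq_len(n_in), function(ui, j) cubic_kernel((ui - j) / kw))
  w / rowSums(w)
}

#' Bicubic resize
#'
#' Separable bicubic (Catmull-Rom) interpolation. When downsampling, the
#' kernel support is widened by the scale factor (antialiasing), matching
#' common image-resize implementations; at the native size the operation
#' is the identity. Output values are clipped to the input's `[0, 255]`
#' range.
#'
#' @param grid Numeric matrix with more than one row and column.
#' @param out_h,out_w Output size.
#' @param antialias Widen the kernel when downsampling (default TRUE).
#' @return `out_h` x `out_w` matrix.
#' @export
resize_bicubic <- function(grid, out_h, out_w = out_h, antialias = TRUE) {
  if (nrow(grid) < 2 || ncol(grid) < 2) abort("degenerate grid")
  wr <- resample_weights(nrow(grid), out_h, antialias)
  wc <- resample_weights(ncol(grid), out_w, antialias)
  out <- wr %*% grid %*% t(wc)
  pmin(pmax(out, 0), 255)
}

#' @rdname resize_bicubic
#' @param side Output side length (default 32, the classifier input size).
#' @export
resize32 <- function(grid, side = 32, antialias = TRUE) {
  resize_bicubic(grid, side, side, antialias = antialias)
}

#' Preprocess a candling image into a 32x32 region of interest
#'
#' The full deterministic preprocessing chain: split the RGB channels;
#' median-filter the red and blue channels (3x3); Otsu-threshold the red
#' channel to find the egg; take the largest 8-connected component,
#' square its bounding box and pad by `pad` pixels; crop the blue channel
#' and the binary mask with that window; zero the background by mask
#' multiplication; bicubic-resize both to `side` x `side`, re-binarizing
#' the mask at 0.5. The result is the grayscale input shared by both
#' classifiers.
#'
#' @param img A `candled_image`.
#' @param pad Crop padding, pixels (default 30).
#' @param side Output side (default 32).
#' @param min_area Minimum pixel area of the largest component for it to
#'   count as an egg.
#' @return A `roi_pair`: list with `roi` (`side` x `side`, 0-255), `mask`
#'   (binary, co-registered: `roi` is 0 wherever `mask` is 0), `crop`
#'   (the `crop_rect` used) and `label` carried over from the image.
#' @export
#' @examples
#' rp <- preprocess_egg(render_egg(egg_scene("SY", seed = 2)))
#' mean(rp$mask)
preprocess_egg <- function(img, pad = 30, side = 32, min_area = 500) {
  ch <- split_channels(img)
  r <- median3(ch$red)
  b <- median3(ch$blue)
  thr <- otsu_level(r)
  egg <- largest_component(binarize(r, thr))
  if (is.null(egg) || sum(egg) < min_area) {
    abort("no egg found", class = "dyegg_no_egg")
  }
  rect <- egg_bbox(egg, pad = pad)
  roi <- crop_rect_apply(b, rect)
  mask <- crop_rect_apply(egg, rect)
  roi <- apply_mask(roi, mask)
  roi_s <- resize32(roi, side)
  mask_s <- matrix(as.integer(resize32(mask * 255, side) >= 127.5),
                   side, side)
  roi_s <- apply_mask(roi_s, mask_s)   # keep co-registration exact
  structure(list(roi = roi_s, mask = mask_s, crop = rect,
                 label = img$label), class = "roi_pair")
}

#' @export
print.roi_pair <- function(x, ...) {
  cat(sprintf("<roi_pair> %dx%d, mask fraction %.2f%s\n",
              nrow(x$roi), ncol(x$roi), mean(x$mask),
              if (!is.null(x$label)) paste0(", label ", x$label) else ""))
  invisible(x)
}
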