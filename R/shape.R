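#' Contours
#'
#' A contour is an ordered, closed sequence of N boundary points stored as
#' an N x 2 matrix with columns `x`, `y` (pixel coordinates; x = column,
#' y = row). Orientation is normalized so the shoelace signed area is
#' positive (counter-clockwise in the stored coordinates); consecutive
#' duplicate points are collapsed.
#'
#' @param xy Two-column numeric matrix of points.
#' @return An `egg_contour`.
#' @export
as_contour <- function(xy) {
  xy <- as.matrix(xy)
  if (ncol(xy) != 2) abort("a contour needs two columns (x, y)")
  dup <- c(FALSE, rowSums(abs(diff(xy))) == 0)
  xy <- xy[!dup, , drop = FALSE]
  if (nrow(xy) >= 2 && all(xy[1, ] == xy[nrow(xy), ])) {
    xy <- xy[-nrow(xy), , drop = FALSE]       # implicit closure
  }
  if (nrow(xy) < 4) abort("a contour needs at least 4 distinct points")
  if (contour_area(xy) < 0) {
    xy <- xy[c(1, rev(seq_len(nrow(xy))[-1])), , drop = FALSE]
  }
  colnames(xy) <- c("x", "y")
  structure(xy, class = c("egg_contour", "matrix", "array"))
}

# Shoelace signed area; positive = counter-clockwise in stored coordinates.
contour_area <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

#' Segment the yolk shadow inside a preprocessed region of interest
#'
#' Three steps: (1) Otsu-threshold the masked ROI so that the bright
#' albumen is white while the darker yolk shadow and the black background
#' are black (the threshold is computed over egg pixels only, since the
#' background is exactly 0 by construction); (2) subtract the albumen
#' image from the egg mask, clipping at 0, which leaves the yolk region
#' plus a thin shell rim white; (3) remove the rim with a 3x3 median
#' filter. The output is the binary yolk image used for boundary tracing.
#'
#' A double-yolked egg with overlapping yolks yields one "8"-shaped
#' component; separated yolks yield two components, a degenerate case
#' that is preserved (downstream boundary tracing uses the largest
#' component only).
#'
#' @param rp A `roi_pair` from [preprocess_egg()].
#' @return Binary integer matrix of the same size as `rp$roi`.
#' @export
segment_yolk <- function(rp) {
  roi <- rp$roi; mask <- rp$mask
  inside <- mask != 0
  if (!any(inside)) abort("empty egg mask")
  if (length(unique(round(roi[inside]))) == 1) {
    # no intensity contrast inside the egg: nothing to segment
    abort("no yolk detected", class = "dyegg_no_yolk")
  }
  thr <- otsu_level(roi[inside])
  albumen <- binarize(roi, thr) * mask
  yolkish <- pmax(mask - albumen, 0)
  yolk <- matrix(as.integer(median3(yolkish) >= 0.5), nrow(roi), ncol(roi))
  if (sum(yolk) == 0) abort("no yolk detected", class = "dyegg_no_yolk")
  yolk
}

# Moore neighbourhood, clockwise starting from west.
moore_dr <- c(0L, -1L, -1L, -1L, 0L, 1L, 1L, 1L)
moore_dc <- c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L)

#' Trace the boundary of the largest component
#'
#' Moore-neighbour boundary tracing of the largest 8-connected foreground
#' component. The start point is the component's topmost, then leftmost,
#' pixel; tracing stops when the start pixel is re-entered from the
#' original direction (Jacob's stopping criterion). The returned contour
#' is orientation-normalized (counter-clockwise shoelace) with the start
#' point first.
#'
#' @param binary_grid Binary matrix with at least one foreground pixel;
#'   the traced component must span at least 4 boundary pixels.
#' @return An `egg_contour` of pixel centres `(x = column, y = row)`.
#' @export
trace_boundary <- function(binary_grid) {
  comp <- largest_component(binary_grid)
  if (is.null(comp)) abort("empty grid")
  h <- nrow(comp); w <- ncol(comp)
  inside <- function(q) q[1] >= 1L && q[1] <= h && q[2] >= 1L &&
    q[2] <= w && comp[q[1], q[2]] == 1L
  idx <- which(t(comp) == 1L)          # row-major scan: topmost then leftmost
  start <- c(((idx[1] - 1L) %/% w) + 1L, ((idx[1] - 1L) %% w) + 1L)
  b0 <- start + c(0L, -1L)             # west neighbour, background by scan
  p <- start; b <- b0
  pts <- matrix(0L, nrow = 4L * sum(comp) + 8L, ncol = 2)
  np <- 0L
  repeat {
    np <- np + 1L
    pts[np, ] <- p
    db <- which(moore_dr == b[1] - p[1] & moore_dc == b[2] - p[2])
    found <- FALSE
    prev <- b
    for (step in 1:8) {
      d <- ((db + step - 1L) %% 8L) + 1L     # clockwise from the backtrack
      q <- p + c(moore_dr[d], moore_dc[d])
      if (inside(q)) { found <- TRUE; break }
      prev <- q
    }
    if (!found) break                        # isolated pixel
    b <- prev                                # background pixel just before q
    p <- q
    if (all(p == start) && all(b == b0)) break   # Jacob's criterion
    if (np >= nrow(pts)) break                   # safety bound
  }
  if (np < 4) {
    abort("component too small to trace (needs >= 4 boundary points)")
  }
  as_contour(cbind(x = pts[seq_len(np), 2], y = pts[seq_len(np), 1]))
}

#' Fourier descriptors of a closed contour
#'
#' Encodes the boundary as the complex sequence `s(k) = x_k + i y_k` and
#' takes its unnormalized discrete Fourier transform
#' `a(u) = sum_k s(k) exp(-2 pi i u k / N)`. The inverse transform of all
#' N coefficients recovers the contour exactly; `a(0) / N` is the
#' centroid.
#'
#' @param contour An `egg_contour` (or two-column matrix).
#' @return A `descriptor_set`: list with complex `coeffs` (length N),
#'   `n_points`, and (after [normalize_fds()]) the real vector `nfd`.
#' @export
fourier_descriptors <- function(contour) {
  xy <- as_contour(contour)
  s <- complex(real = xy[, 1], imaginary = xy[, 2])
  structure(list(coeffs = fft(s), n_points = length(s), nfd = NULL),
            class = "descriptor_set")
}

#' Normalize Fourier descriptors to shape invariants
#'
#' Produces the normalized Fourier descriptors (NFDs)
#' `d(u) = |a(u)| / |a(1)|` for `u = 1 .. m-1`, with `d(0)` set to 0.
#' Dropping the DC term removes translation; dividing by the fundamental
#' magnitude removes scale; taking magnitudes removes rotation and the
#' choice of starting point. Hence `d(0) = 0` and `d(1) = 1` exactly for
#' every non-degenerate contour, and those two constants carry no shape
#' information.
#'
#' @param ds A `descriptor_set` from [fourier_descriptors()].
#' @param m Truncation length: descriptors `d(0) .. d(m-1)` are kept
#'   (default 16).
#' @return The `descriptor_set` with `nfd` filled (length `m`).
#' @export
normalize_fds <- function(ds, m = 16) {
  if (!inherits(ds, "descriptor_set")) abort("expected a descriptor_set")
  if (ds$n_points < m) {
    abort(sprintf("contour has %d points; %d descriptors requested",
                  ds$n_points, m))
  }
  mags <- Mod(ds$coeffs)
  if (mags[2] <= 1e-12 * max(mags)) {
    abort("degenerate contour: no dominant fundamental frequency",
          class = "dyegg_degenerate_contour")
  }
  d <- mags[seq_len(m)] / mags[2]
  d[1] <- 0
  ds$nfd <- d
  ds
}

#' The 14-dimensional yolk shape feature vector
#'
#' Returns `[d(2), d(3), ..., d(15)]`. The constants `d(0) = 0` and
#' `d(1) = 1` are discarded because they are identical for every shape.
#'
#' @param ds A `descriptor_set` with `nfd` of length at least 16.
#' @return Named numeric vector of length 14 (`d2` .. `d15`).
#' @export
feature_vector <- function(ds) {
  if (is.null(ds$nfd)) abort("call normalize_fds() first")
  if (length(ds$nfd) < 16) abort("nfd too short: need d(0)..d(15)")
  setNames(ds$nfd[3:16], paste0("d", 2:15))
}

#' Reconstruct a boundary from its lowest-frequency descriptors
#'
#' Keeps the `n` coefficients of lowest absolute frequency — harmonic
#' orders interleaved as `0, +1, -1, +2, -2, ...`, where order `-u` is
#' stored at index `N - u` — zeroes the rest, and inverse-transforms.
#' With `n = N` the original contour is recovered to numerical precision;
#' a circle is recovered exactly from `n = 2` (DC plus fundamental).
#'
#' @param ds A `descriptor_set`.
#' @param n Number of coefficients to keep, `2 <= n <= N`.
#' @return An `egg_contour` of the reconstructed points.
#' @export
reconstruct_boundary <- function(ds, n) {
  N <- ds$n_points
  if (n < 2 || n > N) abort("n must lie in [2, N]")
  pos <- seq_len(ceiling((N - 1) / 2))
  order_idx <- c(1, rbind(pos + 1, N + 1 - pos))      # 0, +1, -1, +2, -2, ...
  order_idx <- unique(order_idx[order_idx >= 1 & order_idx <= N])[1:N]
  keep <- order_idx[seq_len(n)]
  coeffs <- rep(0 + 0i, N)
  coeffs[keep] <- ds$coeffs[keep]
  s <- fft(coeffs, inverse = TRUE) / N
  as_contour(cbind(x = Re(s), y = Im(s)))
}

#' Boundary reconstruction error
#'
#' The mean, over the original boundary points, of the distance to the
#' nearest reconstructed point:
#' `epsilon = (1/N) sum_k min_j sqrt((x_k - x_j')^2 + (y_k - y_j')^2)`.
#' Zero if and only if every original point coincides with some
#' reconstructed point.
#'
#' @param original,recon Contours (two-column matrices).
#' @return Non-negative scalar, pixels.
#' @export
reconstruction_error <- function(original, recon) {
  a <- as.matrix(original); b <- as.matrix(recon)
  if (nrow(a) == 0 || nrow(b) == 0) abort("empty contour")
  d2 <- outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2
  mean(sqrt(apply(d2, 1, min)))
}

#' Reconstruction-error curve
#'
#' Computes `epsilon_n` for a sequence of harmonic counts, reproducing the
#' characteristic decreasing error curve: the error falls rapidly with the
#' number of retained descriptors and is negligible by about 16.
#'
#' @param contour An `egg_contour`.
#' @param n_values Counts of retained coefficients.
#' @return Tibble with columns `n`, `epsilon`.
#' @export
#' @examples
#' error_curve(analytic_contour("figure_eight", 128))
error_curve <- function(contour, n_values = seq(2, 18, by = 2)) {
  xy <- as_contour(contour)
  ds <- fourier_descriptors(xy)
  n_values <- n_values[n_values <= ds$n_points]
  tibble::tibble(
    n = as.integer(n_values),
    epsilon = purrr::map_dbl(n_values, function(n) {
      reconstruction_error(xy, reconstruct_boundary(ds, n))
    })
  )
}

# Contour serialization --------------------------------------------------

#' Read and write contours and descriptor sets as CSV
#'
#' Contours are stored as columns `k, x, y` (0-based point index);
#' descriptor sets as `u, re, im, nfd` (harmonic order, coefficient parts,
#' normalized descriptor or NA beyond the truncation).
#'
#' @param contour An `egg_contour`; `ds` a `descriptor_set`; `path` a file.
#' @return Readers return the reconstructed object; writers the path,
#'   invisibly.
#' @export
write_contour_csv <- function(contour, path) {
  xy <- as_contour(contour)
  readr::write_csv(tibble::tibble(k = seq_len(nrow(xy)) - 1L,
                                  x = xy[, 1], y = xy[, 2]), path)
  invisible(path)
}

#' @rdname write_contour_csv
#' @export
read_contour_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  as_contour(cbind(df$x, df$y))
}

#' @rdname write_contour_csv
#' @param ds A `descriptor_set`.
#' @export
write_descriptors_csv <- function(ds, path) {
  n <- ds$n_points
  nfd <- rep(NA_real_, n)
  if (!is.null(ds$nfd)) nfd[seq_along(ds$nfd)] <- ds$nfd
  readr::write_csv(tibble::tibble(u = 0:(n - 1), re = Re(ds$coeffs),
                                  im = Im(ds$coeffs), nfd = nfd), path)
  invisible(path)
}
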