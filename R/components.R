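#' Label connected components of a binary grid
#'
#' 8-connected (default) or 4-connected component labelling by
#' breadth-first frontier expansion. Labels are assigned in raster-scan
#' order of each component's first pixel.
#'
#' @param grid Binary matrix (nonzero = foreground).
#' @param connectivity 8 or 4.
#' @return Integer matrix of the same shape: 0 background, 1..k component
#'   labels.
#' @export
label_components <- function(grid, connectivity = 8) {
  stopifnot(connectivity %in% c(4, 8))
  h <- nrow(grid); w <- ncol(grid)
  fg <- grid != 0
  labels <- matrix(0L, h, w)
  if (!any(fg)) return(labels)
  # neighbour linear-index offsets; row masks stop column wrap-around
  dr <- c(-1L, 1L, 0L, 0L)
  dc <- c(0L, 0L, -1L, 1L)
  if (connectivity == 8) {
    dr <- c(dr, -1L, -1L, 1L, 1L)
    dc <- c(dc, -1L, 1L, -1L, 1L)
  }
  todo <- which(fg)               # raster order: column-major, fine for scan
  seen <- matrix(FALSE, h, w)
  k <- 0L
  for (start in todo) {
    if (seen[start]) next
    k <- k + 1L
    frontier <- start
    seen[start] <- TRUE
    labels[start] <- k
    while (length(frontier) > 0) {
      r <- ((frontier - 1L) %% h) + 1L
      c <- ((frontier - 1L) %/% h) + 1L
      nxt <- integer(0)
      for (j in seq_along(dr)) {
        rr <- r + dr[j]; cc <- c + dc[j]
        ok <- rr >= 1L & rr <= h & cc >= 1L & cc <= w
        idx <- (cc[ok] - 1L) * h + rr[ok]
        idx <- idx[fg[idx] & !seen[idx]]
        if (length(idx)) {
          seen[idx] <- TRUE
          labels[idx] <- k
          nxt <- c(nxt, idx)
        }
      }
      frontier <- unique(nxt)
    }
  }
  labels
}

# Binary mask of the largest component (ties broken by lowest label, i.e.
# raster order); returns NULL when there is no foreground.
largest_component <- function(grid, connectivity = 8) {
  labels <- label_components(grid, connectivity)
  if (max(labels) == 0L) return(NULL)
  sizes <- tabulate(labels[labels > 0L])
  matrix(as.integer(labels == which.max(sizes)), nrow(grid), ncol(grid))
}
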