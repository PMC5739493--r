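#' Extract yolk shape features from a dataset of candled images
#'
#' Runs the full image pipeline on every image: preprocessing to the
#' 32x32 region of interest, yolk segmentation, boundary tracing of the
#' largest component, Fourier descriptors, normalization, and the
#' 14-dimensional feature vector `d(2) .. d(15)`. Failures (no egg found,
#' no yolk detected, degenerate contour) are flagged per image, never
#' dropped silently.
#'
#' @param dataset An `egg_dataset` from [make_dataset()], or any tibble
#'   with an `image` list-column of `candled_image`s and a `label` column.
#' @param m Number of normalized descriptors to compute (default 16).
#' @return A tibble with columns `id`, `label`, `separated` (if present),
#'   `ok` (logical), `note` (failure message or NA) and `d2` .. `d15`.
#' @export
#' @examples
#' ds <- make_dataset(2, 2, seed = 3)
#' extract_features(ds)
extract_features <- function(dataset, m = 16) {
  stopifnot(is.data.frame(dataset), "image" %in% names(dataset))
  ids <- if ("id" %in% names(dataset)) dataset$id
         else sprintf("egg%04d", seq_len(nrow(dataset)))
  rows <- purrr::map(dataset$image, function(img) {
    res <- tryCatch({
      fv <- img %>% preprocess_egg() %>% segment_yolk() %>%
        trace_boundary() %>% fourier_descriptors() %>%
        normalize_fds(m = m) %>% feature_vector()
      c(list(ok = TRUE, note = NA_character_), as.list(fv))
    }, error = function(e) {
      c(list(ok = FALSE, note = conditionMessage(e)),
        as.list(setNames(rep(NA_real_, 14), paste0("d", 2:15))))
    })
    tibble::as_tibble(res)
  })
  out <- dplyr::bind_cols(
    tibble::tibble(id = ids, label = dataset$label),
    if ("separated" %in% names(dataset))
      tibble::tibble(separated = dataset$separated),
    dplyr::bind_rows(rows)
  )
  out
}

#' Preprocess a dataset into classifier-ready image arrays
#'
#' Applies [preprocess_egg()] to every image and stacks the normalized
#' ROIs (divided by 255, so values lie in `[0, 1]`) into a
#' `side x side x n` array — the input format of the convolutional
#' network.
#'
#' @inheritParams extract_features
#' @param side ROI side length (default 32).
#' @return List with `x` (array `side x side x n`), `labels` (factor) and
#'   `ok` (logical vector; failed images get an all-zero slice).
#' @export
preprocess_dataset <- function(dataset, side = 32) {
  stopifnot(is.data.frame(dataset), "image" %in% names(dataset))
  n <- nrow(dataset)
  x <- array(0, c(side, side, n))
  ok <- logical(n)
  for (i in seq_len(n)) {
    rp <- tryCatch(preprocess_egg(dataset$image[[i]], side = side),
                   error = function(e) NULL)
    if (!is.null(rp)) {
      x[, , i] <- rp$roi / 255
      ok[i] <- TRUE
    }
  }
  list(x = x, labels = dataset$label, ok = ok)
}
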