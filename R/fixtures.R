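#' Describe a synthetic candled-egg scene
#'
#' An `egg_scene` is a complete parametric description of one candled duck
#' egg as seen in a transmittance image: a bright ellipse (the egg) on a
#' near-black background, containing one roughly circular yolk shadow (SY)
#' or two overlapping yolk shadows forming an "8" (DY). Rendering a scene
#' with [render_egg()] is a pure function of these parameters, so every
#' downstream stage of the pipeline can be tested against exact ground
#' truth.
#'
#' Channel contrast follows what real candling images show: the egg
#' outline is strongest against the background in the red channel, while
#' the yolk shadow is darkest relative to the albumen in the blue channel.
#' Intensity levels are per-channel means in `[0, 255]`.
#'
#' @param label `"SY"` or `"DY"`.
#' @param width,height Image size in pixels.
#' @param egg_center Numeric `(x, y)` centre of the egg ellipse, pixels.
#' @param egg_axes Numeric `(a, b)` semi-axes of the egg ellipse, pixels
#'   (`a` horizontal, `b` vertical).
#' @param yolk_radius Yolk disc radius in pixels.
#' @param yolk_overlap For DY scenes, the overlap fraction of the two yolk
#'   discs in `[0, 1)`: the centre distance is `2 * yolk_radius *
#'   (1 - yolk_overlap)`, so `0` means externally tangent discs and values
#'   near `1` mean near-concentric discs. Negative values encode the
#'   degenerate *separated-yolk* case (two disjoint shadows), the known
#'   failure mode of boundary-based classification.
#' @param yolk_angle For DY scenes, the angle (radians) of the axis joining
#'   the two yolk centres.
#' @param yolk_offset For SY scenes, `(dx, dy)` offset of the yolk centre
#'   from the egg centre, pixels.
#' @param background,albumen,yolk Length-3 numeric vectors of per-channel
#'   `(R, G, B)` mean intensities for the background, the albumen (egg
#'   interior outside the yolk) and the yolk shadow.
#' @param falloff Radial brightness falloff inside the egg: intensity is
#'   multiplied by `1 - falloff * rho^2` where `rho` is the normalized
#'   elliptical radius. Models the dimming towards the shell.
#' @param noise_sigma Standard deviation of additive Gaussian pixel noise,
#'   intensity units.
#' @param seed Integer seed making the rendered noise reproducible.
#'
#' @return An object of class `egg_scene` (a list of the above fields with
#'   `yolk_centers` resolved to an n-by-2 matrix).
#' @seealso [render_egg()], [truth_mask()], [make_dataset()]
#' @export
#' @examples
#' sc <- egg_scene("DY", yolk_overlap = 0.25, seed = 1)
#' img <- render_egg(sc)
#' dim(img$blue)
egg_scene <- function(label = c("SY", "DY"),
                      width = 400, height = 300,
                      egg_center = c(width / 2, height / 2),
                      egg_axes = c(97, 75),
                      yolk_radius = if (match.arg(label) == "SY") 50 else 41,
                      yolk_overlap = 0.25,
                      yolk_angle = 0,
                      yolk_offset = c(0, 0),
                      background = c(10, 10, 12),
                      albumen = c(205, 145, 195),
                      yolk = c(185, 75, 40),
                      falloff = 0.10,
                      noise_sigma = 4,
                      seed = 1L) {
  label <- match.arg(label)
  stopifnot(width >= 32, height >= 32, length(egg_center) == 2,
            length(egg_axes) == 2, all(egg_axes > 0), yolk_radius > 0)
  levels <- c(background, albumen, yolk)
  if (any(levels < 0 | levels > 255)) {
    abort("intensity levels must lie in [0, 255]")
  }
  if (label == "SY") {
    centers <- matrix(egg_center + yolk_offset, ncol = 2)
  } else {
    d <- 2 * yolk_radius * (1 - yolk_overlap)
    u <- c(cos(yolk_angle), sin(yolk_angle)) * d / 2
    centers <- rbind(egg_center + u, egg_center - u)
  }
  scene <- structure(list(
    label = label, width = as.integer(width), height = as.integer(height),
    egg_center = as.numeric(egg_center), egg_axes = as.numeric(egg_axes),
    yolk_centers = centers, yolk_radius = yolk_radius,
    yolk_overlap = if (label == "DY") yolk_overlap else NA_real_,
    background = background, albumen = albumen, yolk = yolk,
    falloff = falloff, noise_sigma = noise_sigma, seed = as.integer(seed)
  ), class = "egg_scene")
  validate_scene(scene)
  scene
}

validate_scene <- function(scene) {
  a <- scene$egg_axes[1]; b <- scene$egg_axes[2]; r <- scene$yolk_radius
  # conservative inside-ellipse test: yolk disc must fit in the ellipse
  # shrunk by the yolk radius along both axes
  if (a <= r || b <= r) abort("yolk disc larger than the egg ellipse")
  rel <- sweep(scene$yolk_centers, 2, scene$egg_center)
  rho <- (rel[, 1] / (a - r))^2 + (rel[, 2] / (b - r))^2
  if (any(rho > 1)) {
    abort("yolk disc protrudes outside the egg ellipse")
  }
  invisible(scene)
}

#' @export
print.egg_scene <- function(x, ...) {
  cat(sprintf("<egg_scene> %s  %dx%d px, egg axes (%.0f, %.0f), yolk r=%.0f\n",
              x$label, x$width, x$height, x$egg_axes[1], x$egg_axes[2],
              x$yolk_radius))
  invisible(x)
}

# Normalized squared elliptical radius of every pixel; matrices are indexed
# [row, col] = [y, x] with a 1-based top-left origin throughout the package.
pixel_grid <- function(width, height) {
  list(x = matrix(rep(seq_len(width), each = height), nrow = height),
       y = matrix(rep(seq_len(height), times = width), nrow = height))
}

#' Render a synthetic candled-egg image
#'
#' Renders an [egg_scene()] into a `candled_image`: three integer-valued
#' channel matrices (`red`, `green`, `blue`) in `[0, 255]`. The egg is an
#' ellipse filled with the albumen levels modulated by a radial falloff;
#' yolk shadows are discs at the yolk levels; i.i.d. Gaussian noise with
#' standard deviation `noise_sigma` is added and the result clipped to
#' `[0, 255]` and rounded. Rendering is deterministic given the scene
#' (including its seed).
#'
#' @param scene An [egg_scene()].
#' @return A `candled_image`: list with `red`, `green`, `blue` matrices
#'   (`height` x `width`), plus `label` and the generating `scene` kept as
#'   an attribute.
#' @export
render_egg <- function(scene) {
  validate_scene(scene)
  g <- pixel_grid(scene$width, scene$height)
  rel_x <- (g$x - scene$egg_center[1]) / scene$egg_axes[1]
  rel_y <- (g$y - scene$egg_center[2]) / scene$egg_axes[2]
  rho2 <- rel_x^2 + rel_y^2
  inside <- rho2 <= 1
  shade <- 1 - scene$falloff * pmin(rho2, 1)
  yolk <- yolk_region(scene, g)
  channels <- local_seed_eval(scene$seed, {
    lapply(1:3, function(ch) {
      m <- matrix(scene$background[ch], scene$height, scene$width)
      m[inside] <- (scene$albumen[ch] * shade)[inside]
      m[yolk] <- (scene$yolk[ch] * shade)[yolk]
      if (scene$noise_sigma > 0) {
        m <- m + rnorm(length(m), sd = scene$noise_sigma)
      }
      matrix(round(pmin(pmax(m, 0), 255)), scene$height, scene$width)
    })
  })
  structure(list(red = channels[[1]], green = channels[[2]],
                 blue = channels[[3]], label = scene$label),
            scene = scene, class = "candled_image")
}

yolk_region <- function(scene, g = pixel_grid(scene$width, scene$height)) {
  r2 <- scene$yolk_radius^2
  reg <- matrix(FALSE, scene$height, scene$width)
  for (i in seq_len(nrow(scene$yolk_centers))) {
    c_i <- scene$yolk_centers[i, ]
    reg <- reg | ((g$x - c_i[1])^2 + (g$y - c_i[2])^2 <= r2)
  }
  reg
}

#' Ground-truth yolk mask of a scene
#'
#' The analytic union of the yolk discs rasterized at full image
#' resolution: 1 inside a yolk disc, 0 elsewhere.
#'
#' @param scene An [egg_scene()].
#' @return Binary integer matrix (`height` x `width`).
#' @export
truth_mask <- function(scene) {
  m <- yolk_region(scene)
  matrix(as.integer(m), scene$height, scene$width)
}

#' @export
print.candled_image <- function(x, ...) {
  cat(sprintf("<candled_image> %dx%d px%s\n", ncol(x$red), nrow(x$red),
              if (!is.null(x$label)) paste0(", label ", x$label) else ""))
  invisible(x)
}

#' Construct a candled image from raw channel matrices
#'
#' @param red,green,blue Numeric matrices of equal dimensions with values
#'   in `[0, 255]`.
#' @param label Optional `"SY"`/`"DY"` ground-truth label.
#' @return A `candled_image`.
#' @export
as_candled_image <- function(red, green, blue, label = NULL) {
  if (!all(dim(red) == dim(green)) || !all(dim(red) == dim(blue))) {
    abort("channel dimensions differ")
  }
  rng <- range(red, green, blue)
  if (rng[1] < 0 || rng[2] > 255) abort("channel values must lie in [0, 255]")
  structure(list(red = red, green = green, blue = blue, label = label),
            class = "candled_image")
}

#' Default parameter ranges for the synthetic dataset generator
#'
#' The ranges from which [make_dataset()] draws per-egg scene parameters.
#' They emulate the variability of real candling sessions: egg position
#' and size jitter, yolk size (DY yolks are drawn slightly smaller than SY
#' yolks, as double yolks are in nature), degree of yolk overlap, and
#' pixel noise. These defaults are frozen: the end-to-end classification
#' benchmarks in the test suite are calibrated against them.
#'
#' @return A named list of `c(min, max)` ranges.
#' @export
egg_param_ranges <- function() {
  list(
    egg_center_jitter = c(-15, 15),
    egg_a = c(92, 102),
    egg_b = c(70, 80),
    yolk_radius_sy = c(45, 54),
    yolk_radius_dy = c(38, 44),
    yolk_overlap = c(0.15, 0.35),
    yolk_overlap_separated = c(-0.25, -0.10),
    yolk_angle = c(-0.30, 0.30),
    sy_offset = c(-6, 6),
    noise_sigma = c(2, 6),
    level_jitter = c(-8, 8)
  )
}

runif1 <- function(range) runif(1, range[1], range[2])

#' Generate a labelled synthetic candled-egg dataset
#'
#' Draws scene parameters uniformly from `param_ranges`, renders each
#' scene, and returns images, labels and ground-truth yolk masks in a
#' tibble. A configurable fraction of the DY scenes is rendered with
#' *separated* yolks (two disjoint shadow discs), the degenerate case in
#' which boundary-based shape features see only one circular component.
#'
#' @param n_sy,n_dy Number of single- and double-yolked scenes.
#' @param param_ranges Ranges as produced by [egg_param_ranges()].
#' @param separated_fraction Fraction of DY scenes with separated yolks
#'   (rounded to a count).
#' @param width,height Rendered image size, pixels.
#' @param seed Integer seed; the whole dataset is reproducible from it.
#' @return A tibble of class `egg_dataset` with columns `id`, `label`
#'   (factor SY/DY), `separated` (logical), `scene`, `image`, `truth`
#'   (list-columns of [egg_scene()], `candled_image`, binary matrix).
#' @export
#' @examples
#' ds <- make_dataset(3, 3, seed = 1)
#' table(ds$label)
make_dataset <- function(n_sy, n_dy, param_ranges = egg_param_ranges(),
                         separated_fraction = 0.05,
                         width = 400, height = 300, seed = 1L) {
  stopifnot(n_sy >= 0, n_dy >= 0)
  bad <- vapply(param_ranges, function(r) length(r) != 2 || r[2] < r[1],
                logical(1))
  if (any(bad)) abort("empty or malformed parameter range(s)")
  n_sep <- round(n_dy * separated_fraction)
  scenes <- local_seed_eval(seed, {
    labels <- c(rep("SY", n_sy), rep("DY", n_dy))
    sep <- c(rep(FALSE, n_sy), rep(FALSE, n_dy - n_sep), rep(TRUE, n_sep))
    purrr::map2(labels, sep, function(lab, is_sep) {
      pr <- param_ranges
      center <- c(width / 2 + runif1(pr$egg_center_jitter),
                  height / 2 + runif1(pr$egg_center_jitter))
      axes <- c(runif1(pr$egg_a), runif1(pr$egg_b))
      jit <- function(v) pmin(pmax(v + runif(3, pr$level_jitter[1],
                                             pr$level_jitter[2]), 0), 255)
      args <- list(
        label = lab, width = width, height = height,
        egg_center = center, egg_axes = axes,
        background = jit(c(10, 10, 12)), albumen = jit(c(205, 145, 175)),
        yolk = jit(c(185, 110, 90)),
        noise_sigma = runif1(pr$noise_sigma),
        seed = sample.int(.Machine$integer.max, 1)
      )
      if (lab == "SY") {
        args$yolk_radius <- runif1(pr$yolk_radius_sy)
        args$yolk_offset <- c(runif1(pr$sy_offset), runif1(pr$sy_offset))
      } else {
        args$yolk_radius <- runif1(pr$yolk_radius_dy)
        args$yolk_overlap <- if (is_sep) runif1(pr$yolk_overlap_separated)
                             else runif1(pr$yolk_overlap)
        args$yolk_angle <- runif1(pr$yolk_angle)
        # separated yolk regions arise from over-high thresholds and are
        # smaller than properly segmented yolks
        if (is_sep) args$yolk_radius <- 0.85 * args$yolk_radius
      }
      list(scene = do.call(egg_scene, args), separated = is_sep)
    })
  })
  out <- tibble::tibble(
    id = sprintf("egg%04d", seq_along(scenes)),
    label = factor(purrr::map_chr(scenes, ~ .x$scene$label),
                   levels = c("SY", "DY")),
    separated = purrr::map_lgl(scenes, "separated"),
    scene = purrr::map(scenes, "scene")
  )
  out$image <- purrr::map(out$scene, render_egg)
  out$truth <- purrr::map(out$scene, truth_mask)
  class(out) <- c("egg_dataset", class(out))
  attr(out, "seed") <- as.integer(seed)
  out
}

#' Analytic test contours
#'
#' Closed, ordered, uniformly parameterized contours with known shape:
#' a circle (the idealized SY yolk boundary) or a lemniscate-like
#' "figure eight" (the idealized DY yolk boundary). Used as exact inputs
#' for Fourier-descriptor tests.
#'
#' The figure eight is the peanut-shaped simple closed curve with polar
#' radius `r(t) = extent * (1 + pinch * cos 2t) / (1 + pinch)` where
#' `pinch = (1 - waist) / (1 + waist)`, rotated by `angle`: two lobes
#' along the major axis joined by a waist whose half-width is `waist`
#' times the lobe extent — the outline of two overlapping yolk discs.
#'
#' @param shape `"circle"` or `"figure_eight"`.
#' @param n_points Number of contour points (at least 8 for the
#'   figure eight; 4 for the circle).
#' @param radius,center Circle radius and centre.
#' @param extent,waist,angle Figure-eight half-length, relative waist
#'   height, and rotation (radians).
#' @return An `egg_contour`: an `n_points` x 2 matrix with columns `x`, `y`.
#' @export
#' @examples
#' analytic_contour("circle", 4, radius = 1)
analytic_contour <- function(shape = c("circle", "figure_eight"),
                             n_points = 64, radius = 1, center = c(0, 0),
                             extent = 2, waist = 0.6, angle = 0) {
  shape <- match.arg(shape)
  if (n_points < 4) abort("n_points must be at least 4")
  t <- 2 * pi * (seq_len(n_points) - 1) / n_points
  if (shape == "circle") {
    xy <- cbind(center[1] + radius * cos(t), center[2] + radius * sin(t))
  } else {
    if (n_points < 8) abort("figure_eight needs n_points >= 8")
    pinch <- (1 - waist) / (1 + waist)
    r <- extent * (1 + pinch * cos(2 * t)) / (1 + pinch)
    x0 <- r * cos(t)
    y0 <- r * sin(t)
    xy <- cbind(center[1] + x0 * cos(angle) - y0 * sin(angle),
                center[2] + x0 * sin(angle) + y0 * cos(angle))
  }
  as_contour(xy)
}

#' Write a dataset to disk as images plus a CSV manifest
#'
#' Images are written as RGB PNG files, truth masks as single-channel PNG,
#' and a `manifest.csv` records filename, label, separated flag, seed and
#' the main scene parameters.
#'
#' @param dataset An `egg_dataset` from [make_dataset()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the manifest tibble.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- dplyr::mutate(
    tibble::as_tibble(dataset[c("id", "label", "separated")]),
    filename = paste0(.data$id, ".png"),
    mask_filename = paste0(.data$id, "_mask.png"),
    seed = purrr::map_int(dataset$scene, "seed"),
    egg_a = purrr::map_dbl(dataset$scene, ~ .x$egg_axes[1]),
    egg_b = purrr::map_dbl(dataset$scene, ~ .x$egg_axes[2]),
    yolk_radius = purrr::map_dbl(dataset$scene, "yolk_radius"),
    yolk_overlap = purrr::map_dbl(dataset$scene, "yolk_overlap"),
    noise_sigma = purrr::map_dbl(dataset$scene, "noise_sigma")
  )
  purrr::pwalk(list(dataset$image, dataset$truth, manifest$filename,
                    manifest$mask_filename), function(img, truth, fn, mfn) {
    write_candled_image(img, file.path(dir, fn))
    png::writePNG(truth + 0.0, file.path(dir, mfn))
  })
  readr::write_csv(manifest, file.path(dir, "manifest.csv"))
  invisible(manifest)
}

#' Read and write candled images
#'
#' PNG (always available) and TIFF (if the tiff package is installed) are
#' supported. Images are stored with channels scaled to `[0, 1]` on disk
#' and `[0, 255]` in memory.
#'
#' @param path File path; format chosen by extension (.png, .tif/.tiff).
#' @param img A `candled_image`.
#' @param label Optional label to attach on read.
#' @return `read_candled_image()` returns a `candled_image`;
#'   `write_candled_image()` returns the path invisibly.
#' @export
read_candled_image <- function(path, label = NULL) {
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE)) {
        abort("reading TIFF requires the 'tiff' package")
      }
      tiff::readTIFF(path)
    },
    abort(sprintf("unsupported image format '.%s' (PNG or TIFF expected)",
                  ext))
  )
  if (length(dim(arr)) == 2) arr <- array(rep(arr, 3), c(dim(arr), 3))
  if (dim(arr)[3] < 3) abort("expected an RGB image")
  as_candled_image(round(arr[, , 1] * 255), round(arr[, , 2] * 255),
                   round(arr[, , 3] * 255), label = label)
}

#' @rdname read_candled_image
#' @export
write_candled_image <- function(img, path) {
  arr <- array(c(img$red, img$green, img$blue) / 255,
               c(dim(img$red), 3))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      abort("writing TIFF requires the 'tiff' package")
    }
    tiff::writeTIFF(arr, path)
  } else {
    png::writePNG(arr, path)
  }
  invisible(path)
}
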