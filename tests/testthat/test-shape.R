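test_that("segment_yolk recovers the yolk region and its topology", {
  # SY: one component overlapping the downsampled truth disc
  sc <- egg_scene("SY", noise_sigma = 0, seed = 31)
  rp <- preprocess_egg(render_egg(sc))
  y <- segment_yolk(rp)
  expect_setequal(unique(as.integer(y)), c(0L, 1L))
  expect_equal(max(label_components(y)), 1)
  truth32 <- matrix(as.integer(
    resize32(crop_rect_apply(truth_mask(sc), rp$crop) * 255) >= 127.5),
    32, 32)
  iou <- sum(y & truth32) / sum(y | truth32)
  expect_gte(iou, 0.6)

  # DY overlapping: one 8-shaped component
  yd <- segment_yolk(fixture_dy_rp())
  expect_equal(max(label_components(yd)), 1)

  # DY separated: the two components are preserved, not hidden
  ys <- segment_yolk(fixture_sep_rp())
  expect_equal(max(label_components(ys)), 2)

  # all-albumen ROI: no yolk
  flat <- structure(list(roi = matrix(c(rep(0, 512), rep(200, 512)), 32),
                         mask = matrix(c(rep(0L, 512), rep(1L, 512)), 32)),
                    class = "roi_pair")
  expect_error(suppressWarnings(segment_yolk(flat)),
               class = "dyegg_no_yolk")
})

test_that("trace_boundary follows the largest component with the documented start", {
  sq <- matrix(0L, 5, 5); sq[2:4, 2:4] <- 1L
  ct <- trace_boundary(sq)
  expect_equal(nrow(ct), 8)                       # 8 border pixels
  expect_equal(unname(ct[1, ]), c(2, 2))          # topmost-then-leftmost
  expect_gt(oracle_shoelace(ct), 0)               # CCW normalization

  two <- matrix(0L, 20, 20)
  two[2:11, 2:6] <- 1L                            # area 50
  two[15:17, 15:17] <- 1L                         # area 9
  ct2 <- trace_boundary(two)
  expect_true(all(ct2[, 1] <= 6 + 1))             # traced the big one

  # perimeter lower bound of the bounding box
  set.seed(8)
  for (i in 1:5) {
    m <- matrix(0L, 30, 30)
    r0 <- sample(3:10, 1); c0 <- sample(3:10, 1)
    m[r0:(r0 + sample(5:15, 1)), c0:(c0 + sample(5:15, 1))] <- 1L
    ct3 <- trace_boundary(m)
    bb_w <- diff(range(ct3[, 1])) + 1; bb_h <- diff(range(ct3[, 2])) + 1
    expect_gte(nrow(ct3), 2 * (bb_w + bb_h) - 4)
  }
  expect_error(trace_boundary(matrix(0L, 4, 4)), "empty")
})

test_that("fourier_descriptors match the brute-force DFT and its identities", {
  circ <- analytic_contour("circle", 32, radius = 5, center = c(3, -2))
  ds <- fourier_descriptors(circ)
  mags <- Mod(ds$coeffs)
  expect_lt(max(mags[-c(1, 2)]) / mags[2], 1e-9)  # only DC + fundamental
  expect_equal(ds$coeffs[1] / 32, complex(real = 3, imaginary = -2),
               tolerance = 1e-9)                  # DC term = centroid

  set.seed(12)
  xy <- cbind(runif(32, -10, 10), runif(32, -10, 10))
  ct <- as_contour(xy)
  got <- fourier_descriptors(ct)$coeffs
  want <- oracle_dft(unclass(ct))
  expect_lt(max(Mod(got - want)) / max(Mod(want)), 1e-9)
})

test_that("NFD normalization yields the documented constants and invariances", {
  circ <- analytic_contour("circle", 64, radius = 7, center = c(10, 20))
  nfd <- normalize_fds(fourier_descriptors(circ))$nfd
  expect_identical(nfd[1], 0)
  expect_identical(nfd[2], 1)
  expect_lt(max(nfd[3:16]), 1e-9)                 # circle: d(2..15) ~ 0

  fig8 <- analytic_contour("figure_eight", 256)
  nfd8 <- normalize_fds(fourier_descriptors(fig8))$nfd
  expect_gt(max(nfd8[3:16]), 0.05)

  fv_c <- feature_vector(normalize_fds(fourier_descriptors(circ)))
  fv_8 <- feature_vector(normalize_fds(fourier_descriptors(fig8)))
  expect_length(fv_c, 14)
  expect_named(fv_c, paste0("d", 2:15))
  expect_gt(sqrt(sum((fv_c - fv_8)^2)), 0.05)

  # similarity transform + start-point shift leaves the features unchanged
  set.seed(99)
  for (i in 1:20) {
    ct <- random_contour(n = sample(32:80, 1))
    theta <- runif(1, 0, 2 * pi); s <- runif(1, 0.2, 4)
    shift <- runif(2, -20, 20); k <- sample(nrow(ct) - 1, 1)
    rot <- s * matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
    xy2 <- sweep(unclass(ct) %*% t(rot), 2, shift, `+`)
    xy2 <- xy2[c((k + 1):nrow(xy2), 1:k), ]
    f1 <- feature_vector(normalize_fds(fourier_descriptors(ct)))
    f2 <- feature_vector(normalize_fds(fourier_descriptors(as_contour(xy2))))
    expect_lt(max(abs(f1 - f2)), 1e-6)
  }

  # degenerate: a contour with no fundamental (pure 2nd harmonic)
  t4 <- 2 * pi * (0:63) / 64
  deg <- cbind(cos(2 * t4), sin(2 * t4))
  expect_error(normalize_fds(fourier_descriptors(deg)),
               class = "dyegg_degenerate_contour")
  expect_error(normalize_fds(fourier_descriptors(random_contour(20)), m = 32),
               "requested")
})

test_that("boundary reconstruction recovers shapes from few harmonics", {
  circ <- analytic_contour("circle", 48, radius = 6)
  ds <- fourier_descriptors(circ)
  # full reconstruction is exact
  full <- reconstruct_boundary(ds, 48)
  expect_lt(reconstruction_error(circ, full), 1e-9)
  # a circle lives on DC + fundamental
  two <- reconstruct_boundary(ds, 2)
  expect_lt(reconstruction_error(circ, two), 1e-9)
  expect_error(reconstruct_boundary(ds, 1), "must lie")
  expect_error(reconstruct_boundary(ds, 49), "must lie")

  # figure eight: error decreases with n and is two-lobed from modest n
  fig8 <- analytic_contour("figure_eight", 256, extent = 12)
  curve <- error_curve(fig8, n_values = seq(4, 18, 2))
  expect_true(all(diff(curve$epsilon) <= 0.1))
  expect_lt(curve$epsilon[curve$n == 16], 0.5)
  rec8 <- reconstruct_boundary(fourier_descriptors(fig8), 8)
  r <- sqrt(rowSums(sweep(unclass(rec8), 2, colMeans(rec8))^2))
  expect_gt(max(r) / min(r), 1.3)                 # waist survives truncation
})

test_that("reconstruction_error equals the exhaustive nearest-point oracle", {
  a <- matrix(c(0, 0), 1)
  b <- matrix(c(3, 4), 1)
  expect_equal(reconstruction_error(a, b), 5)
  ct <- random_contour(40, seed = 4)
  expect_equal(reconstruction_error(ct, ct), 0)

  set.seed(5)
  for (i in 1:4) {
    p <- matrix(runif(40, -10, 10), ncol = 2)
    q <- matrix(runif(30, -10, 10), ncol = 2)
    expect_equal(reconstruction_error(p, q), oracle_recon_error(p, q),
                 tolerance = 1e-12)
  }
})

test_that("yolk boundary error curves behave like the published pattern", {
  for (rp in list(fixture_sy_rp(), fixture_dy_rp())) {
    ct <- trace_boundary(segment_yolk(rp))
    curve <- error_curve(ct, n_values = seq(2, 18, 2))
    expect_true(all(diff(curve$epsilon) <= 0.1))  # non-increasing + jitter
    expect_lt(curve$epsilon[curve$n == 16], 0.5)
    # round trip at full harmonics
    ds <- fourier_descriptors(ct)
    expect_lt(reconstruction_error(ct, reconstruct_boundary(ds, ds$n_points)),
              1e-6)
  }
})

test_that("contours and descriptors round-trip through CSV", {
  dir <- withr::local_tempdir()
  ct <- random_contour(30, seed = 77)
  write_contour_csv(ct, file.path(dir, "c.csv"))
  back <- read_contour_csv(file.path(dir, "c.csv"))
  expect_equal(unclass(back), unclass(ct), tolerance = 1e-12,
               ignore_attr = TRUE)
  ds <- normalize_fds(fourier_descriptors(ct))
  write_descriptors_csv(ds, file.path(dir, "d.csv"))
  df <- readr::read_csv(file.path(dir, "d.csv"), show_col_types = FALSE)
  expect_equal(nrow(df), 30)
  expect_equal(df$nfd[1:16], ds$nfd)
})
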