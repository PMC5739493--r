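test_that("channel splitting is a pure projection", {
  img <- as_candled_image(matrix(255, 4, 4), matrix(0, 4, 4),
                          matrix(0, 4, 4))
  ch <- split_channels(img)
  expect_equal(ch$red, matrix(255, 4, 4))
  expect_equal(ch$green, matrix(0, 4, 4))

  v <- matrix(sample(0:255, 25, replace = TRUE), 5, 5)
  gray <- as_candled_image(v, v, v)
  expect_identical(split_channels(gray)$blue, v)
  expect_error(split_channels(v), "candled_image")
})

test_that("blue channel separates yolk from albumen on a rendered scene", {
  sc <- fixture_sy_scene()
  img <- render_egg(sc)
  yolk <- truth_mask(sc) == 1
  g <- dyegg:::pixel_grid(sc$width, sc$height)
  inside <- ((g$x - sc$egg_center[1]) / sc$egg_axes[1])^2 +
    ((g$y - sc$egg_center[2]) / sc$egg_axes[2])^2 <= 0.95
  expect_lt(mean(img$blue[yolk]), mean(img$blue[inside & !yolk]))
})

test_that("median3 matches the per-pixel sort oracle and its fixed points", {
  expect_equal(median3(matrix(7, 5, 5)), matrix(7, 5, 5))

  salt <- matrix(0, 7, 7); salt[4, 4] <- 255
  expect_equal(median3(salt), matrix(0, 7, 7))

  set.seed(42)
  for (i in 1:5) {
    g <- matrix(sample(0:255, 81, replace = TRUE), 9, 9)
    expect_equal(median3(g), oracle_median3(g))
  }
  g2 <- matrix(runif(60), 5, 12)          # non-square, non-integer
  expect_equal(median3(g2), oracle_median3(g2))
  expect_error(median3(matrix(1, 2, 5)), "3x3")
})

test_that("otsu_level equals the exhaustive between-class-variance search", {
  bimodal <- matrix(c(rep(20, 50), rep(200, 50)), 10, 10)
  t_b <- otsu_level(bimodal)
  expect_gte(t_b, 20); expect_lt(t_b, 200)
  expect_identical(t_b, oracle_otsu(bimodal))

  set.seed(7)
  grids <- list(
    matrix(sample(0:255, 100, replace = TRUE), 10, 10),
    matrix(pmin(pmax(round(c(rnorm(60, 60, 12), rnorm(60, 180, 20))), 0),
                255), 12, 10),
    matrix(sample(c(0, 3, 250, 255), 64, replace = TRUE), 8, 8)
  )
  for (g in grids) expect_identical(otsu_level(g), oracle_otsu(g))

  expect_warning(t_c <- otsu_level(matrix(7, 4, 4)), "constant")
  expect_identical(t_c, 7L)
  expect_equal(sum(binarize(matrix(7, 4, 4), t_c)), 0)  # all background
})

test_that("egg_bbox applies the square-then-pad-30 rule and clamps at edges", {
  g <- matrix(0L, 200, 300); g[100, 100] <- 1L
  r <- egg_bbox(g)
  expect_equal(r$side, 61)                       # 1 + 2*30
  expect_equal(r$top, 100 - 30); expect_equal(r$left, 100 - 30)

  g2 <- matrix(0L, 300, 300); g2[101:110, 101:120] <- 1L   # 10 x 20 blob
  r2 <- egg_bbox(g2)
  expect_equal(r2$side, 80)                      # 20 squared + 2*30

  g3 <- matrix(0L, 100, 100); g3[1:10, 1:10] <- 1L         # corner blob
  r3 <- egg_bbox(g3)
  expect_gte(r3$top, 1); expect_gte(r3$left, 1)
  expect_lte(r3$top + r3$side - 1, 100)
  expect_lte(r3$left + r3$side - 1, 100)
  expect_equal(dim(crop_rect_apply(g3, r3)), c(r3$side, r3$side))

  # largest component wins
  g4 <- matrix(0L, 200, 200)
  g4[50:60, 50:60] <- 1L; g4[150, 150] <- 1L
  r4 <- egg_bbox(g4)
  expect_equal(r4$side, 11 + 60)
  expect_error(egg_bbox(matrix(0L, 5, 5)), "foreground")
})

test_that("label_components distinguishes 4- and 8-connectivity", {
  m <- matrix(0, 5, 5); m[2, 2] <- 1; m[3, 3] <- 1
  expect_equal(max(label_components(m, 8)), 1)
  expect_equal(max(label_components(m, 4)), 2)
  blobs <- matrix(0, 10, 10)
  blobs[2:4, 2:4] <- 1; blobs[7:9, 7:8] <- 1
  lab <- label_components(blobs)
  expect_equal(max(lab), 2)
  expect_equal(sum(lab == 1), 9)   # raster-first blob gets label 1
})

test_that("apply_mask zeroes the background and preserves the egg", {
  g <- matrix(runif(36, 1, 255), 6, 6)
  expect_equal(apply_mask(g, matrix(1, 6, 6)), g)
  expect_equal(apply_mask(g, matrix(0, 6, 6)), matrix(0, 6, 6))
  m <- matrix(rbinom(36, 1, 0.5), 6, 6)
  out <- apply_mask(g, m)
  expect_true(all(out[m == 0] == 0))
  expect_equal(out[m == 1], g[m == 1])
  expect_error(apply_mask(g, matrix(1, 5, 6)), "mismatch")
})

test_that("bicubic resize preserves constants, identity, and brightness", {
  expect_equal(resize32(matrix(100, 64, 64)), matrix(100, 32, 32),
               tolerance = 1e-9)
  x <- matrix(runif(1024, 0, 255), 32, 32)
  expect_equal(resize32(x), x, tolerance = 1e-9)

  checker <- 255 * outer(1:64, 1:64, function(i, j) (i + j) %% 2)
  out <- resize32(checker)
  expect_lt(abs(mean(out) - mean(checker)), 2)

  big <- resize_bicubic(matrix(runif(400, 0, 255), 20, 20), 61, 61)
  expect_true(all(big >= 0 & big <= 255))
  expect_error(resize_bicubic(matrix(1, 1, 1), 32), "degenerate")
})

test_that("preprocess_egg output satisfies its contracts", {
  rp <- fixture_sy_rp()
  expect_equal(dim(rp$roi), c(32, 32))
  expect_equal(sort(unique(as.integer(rp$mask))), c(0L, 1L))
  frac <- mean(rp$mask)
  expect_gt(frac, 0.2); expect_lt(frac, 0.95)
  expect_true(all(rp$roi[rp$mask == 0] == 0))    # co-registration

  img <- render_egg(fixture_sy_scene())
  rp2 <- preprocess_egg(img)
  expect_identical(rp$roi, rp2$roi)              # determinism

  black <- as_candled_image(matrix(0, 100, 100), matrix(0, 100, 100),
                            matrix(0, 100, 100))
  expect_error(suppressWarnings(preprocess_egg(black)),
               class = "dyegg_no_egg")
})

test_that("the resized ROI is robust to translating the egg in the frame", {
  base <- egg_scene("SY", egg_center = c(185, 145), noise_sigma = 0,
                    seed = 5)
  shifted <- egg_scene("SY", egg_center = c(215, 160), noise_sigma = 0,
                       seed = 5)
  r1 <- preprocess_egg(render_egg(base))
  r2 <- preprocess_egg(render_egg(shifted))
  expect_lt(mean(abs(r1$roi - r2$roi)), 5)
})
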