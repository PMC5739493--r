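# Independent brute-force oracles used to validate the implementations.
# These deliberately share no code with the package internals.

# Median filter: per-pixel neighbourhood sort with edge replication.
oracle_median3 <- function(grid) {
  h <- nrow(grid); w <- ncol(grid)
  out <- grid
  for (r in seq_len(h)) for (c in seq_len(w)) {
    vals <- numeric(9); k <- 0
    for (dr in -1:1) for (dc in -1:1) {
      k <- k + 1
      vals[k] <- grid[min(max(r + dr, 1), h), min(max(c + dc, 1), w)]
    }
    out[r, c] <- sort(vals)[5]
  }
  out
}

# Otsu: exhaustive search over all 256 candidate thresholds, computing the
# between-class variance from first principles on the raw pixel values.
oracle_otsu <- function(grid) {
  v <- as.integer(round(grid))
  n <- length(v)
  best_t <- 0L; best_var <- -Inf
  for (t in 0:254) {
    lo <- v[v <= t]; hi <- v[v > t]
    if (length(lo) == 0 || length(hi) == 0) {
      var_b <- 0
    } else {
      w0 <- length(lo) / n; w1 <- 1 - w0
      var_b <- w0 * w1 * (mean(lo) - mean(hi))^2
    }
    if (var_b > best_var + 1e-12) { best_var <- var_b; best_t <- t }
  }
  best_t
}

# DFT: O(N^2) summation straight from the definition.
oracle_dft <- function(xy) {
  n <- nrow(xy)
  s <- complex(real = xy[, 1], imaginary = xy[, 2])
  vapply(0:(n - 1), function(u) {
    sum(s * exp(-2i * pi * u * (0:(n - 1)) / n))
  }, complex(1))
}

# Mean nearest-point distance: exhaustive double loop.
oracle_recon_error <- function(a, b) {
  total <- 0
  for (k in seq_len(nrow(a))) {
    best <- Inf
    for (j in seq_len(nrow(b))) {
      d <- sqrt((a[k, 1] - b[j, 1])^2 + (a[k, 2] - b[j, 2])^2)
      if (d < best) best <- d
    }
    total <- total + best
  }
  total / nrow(a)
}

# Shoelace signed area.
oracle_shoelace <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

# Two-class Bayes rule under a shared Gaussian: assign to the class with
# the larger log posterior, computed directly from means, pooled
# covariance and priors (no classification-function algebra).
oracle_shared_gaussian_bayes <- function(x, mu1, mu2, sigma, p1 = 0.5,
                                         p2 = 0.5) {
  si <- solve(sigma)
  lp <- function(xi, mu, p) {
    -0.5 * drop(t(xi - mu) %*% si %*% (xi - mu)) + log(p)
  }
  apply(x, 1, function(xi) if (lp(xi, mu1, p1) >= lp(xi, mu2, p2)) 1L else 2L)
}

# Random jagged closed contour: a noisy star-convex polygon.
random_contour <- function(n = 48, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  t <- 2 * pi * (0:(n - 1)) / n
  r <- 10 + runif(1, 0, 4) * cos(2 * t + runif(1, 0, pi)) +
    runif(1, 0, 2) * cos(3 * t) + rnorm(n, sd = 0.3)
  as_contour(cbind(20 + r * cos(t), 20 + r * sin(t)))
}

# Shared small rendered fixtures (computed once per test run).
fixture_sy_scene <- function() egg_scene("SY", seed = 11)
fixture_dy_scene <- function(overlap = 0.25) {
  egg_scene("DY", yolk_overlap = overlap, seed = 12)
}
fixture_sep_scene <- function() egg_scene("DY", yolk_overlap = -0.2, seed = 13)

.fixture_cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (!exists(key, .fixture_cache)) {
    assign(key, force(expr), .fixture_cache)
  }
  get(key, .fixture_cache)
}

fixture_sy_rp <- function() {
  cached("sy_rp", preprocess_egg(render_egg(fixture_sy_scene())))
}
fixture_dy_rp <- function() {
  cached("dy_rp", preprocess_egg(render_egg(fixture_dy_scene())))
}
fixture_sep_rp <- function() {
  cached("sep_rp", preprocess_egg(render_egg(fixture_sep_scene())))
}
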