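# Trivially separable image classes: bright left half vs bright right half.
make_toy_images <- function(n = 100, seed = 3) {
  set.seed(seed)
  lab <- rep(c("SY", "DY"), each = n / 2)
  x <- array(0, c(32, 32, n))
  for (i in seq_len(n)) {
    m <- matrix(runif(1024) * 0.2, 32, 32)
    if (lab[i] == "SY") m[, 1:16] <- m[, 1:16] + 0.6
    else m[, 17:32] <- m[, 17:32] + 0.6
    x[, , i] <- m
  }
  list(x = x, labels = lab)
}

test_that("the network has the documented architecture", {
  net <- build_cnn(seed = 1)
  expect_equal(cnn_n_params(net), 1012)
  expect_equal(dim(net$k1), c(5, 5, 4))
  expect_equal(dim(net$k2), c(5, 5, 4, 6))
  expect_equal(dim(net$w3), c(2, 150))

  # same seed, same weights
  expect_identical(build_cnn(seed = 9)$k2, build_cnn(seed = 9)$k2)
  expect_false(identical(build_cnn(seed = 9)$k2, build_cnn(seed = 10)$k2))

  # forward shape chain on one image
  fw <- dyegg:::cnn_forward_pass(net, matrix(runif(1024), 32, 32))
  expect_equal(dim(fw$a1), c(28 * 28 * 1, 4))
  expect_equal(dim(fw$s1), c(14 * 14 * 1, 4))
  expect_equal(dim(fw$a2), c(10 * 10 * 1, 6))
  expect_equal(dim(fw$s2), c(5 * 5 * 1, 6))
  expect_equal(dim(fw$feat), c(150, 1))
  expect_equal(dim(fw$probs), c(2, 1))
})

test_that("the output layer is a proper probability distribution", {
  net <- build_cnn(seed = 2)
  set.seed(4)
  x <- array(runif(32 * 32 * 5), c(32, 32, 5))
  p <- cnn_forward(net, x)
  expect_true(all(p > 0 & p < 1))
  expect_equal(rowSums(p), rep(1, 5), tolerance = 1e-12)

  # zero weights and biases: symmetric logits -> (0.5, 0.5) exactly
  zero <- dyegg:::cnn_set_params(net, rep(0, 1012))
  expect_equal(unname(cnn_forward(zero, x)),
               matrix(0.5, 5, 2), tolerance = 1e-15)
})

test_that("a single conv map on a constant image matches the closed form", {
  net <- build_cnn(seed = 3)
  v <- 0.37
  x <- matrix(v, 32, 32)
  fw <- dyegg:::cnn_forward_pass(net, x)
  for (map in 1:4) {
    want <- 1 / (1 + exp(-(net$b1[map] + sum(net$k1[, , map]) * v)))
    expect_equal(unique(round(fw$a1[, map], 12)), round(want, 12))
  }
})

test_that("analytic gradients match central finite differences for all layers", {
  set.seed(5)
  x <- array(runif(32 * 32 * 8), c(32, 32, 8))
  lab <- rep(c("SY", "DY"), 4)
  for (cfg in list(list(pool = "identity", loss = "cross_entropy"),
                   list(pool = "sigmoid", loss = "cross_entropy"),
                   list(pool = "identity", loss = "mse"))) {
    net <- build_cnn(seed = 6, pool_activation = cfg$pool, loss = cfg$loss)
    analytic <- cnn_gradients(net, x, lab)
    ga <- unlist(lapply(dyegg:::cnn_param_names,
                        function(nm) as.numeric(analytic$grads[[nm]])))
    theta <- dyegg:::cnn_get_params(net)
    eps <- 1e-5
    # every parameter of the small layers; a spread across the big ones
    idx <- unique(c(1:10, 101:104, sample(105:704, 60), 705:710,
                    sample(711:1010, 40), 1011, 1012))
    gn <- vapply(idx, function(i) {
      up <- theta; up[i] <- up[i] + eps
      dn <- theta; dn[i] <- dn[i] - eps
      (dyegg:::cnn_loss(dyegg:::cnn_set_params(net, up), x, lab) -
         dyegg:::cnn_loss(dyegg:::cnn_set_params(net, dn), x, lab)) /
        (2 * eps)
    }, numeric(1))
    rel <- abs(gn - ga[idx]) / pmax(abs(gn) + abs(ga[idx]), 1e-6)
    expect_lt(max(rel), 1e-4)
  }
})

test_that("training learns a separable task and logs a decreasing loss", {
  toy <- make_toy_images(100)
  net <- build_cnn(seed = 1)
  trained <- train_cnn(net, toy$x, toy$labels, epochs = 100, seed = 2)
  acc <- mean(as.character(predict(trained, toy$x)$.pred) == toy$labels)
  expect_gte(acc, 0.95)

  # loss is non-increasing across >= 90% of epoch transitions
  dl <- diff(trained$log$loss)
  expect_gte(mean(dl <= 1e-6), 0.9)

  # zero learning rate leaves the weights untouched
  frozen <- train_cnn(net, toy$x, toy$labels, learning_rate = 0,
                      epochs = 3, seed = 2)
  expect_equal(frozen$k1, net$k1, tolerance = 1e-15)
  expect_equal(frozen$w3, net$w3, tolerance = 1e-15)

  # same seed, same training trajectory
  t2 <- train_cnn(net, toy$x, toy$labels, epochs = 3, seed = 7)
  t3 <- train_cnn(net, toy$x, toy$labels, epochs = 3, seed = 7)
  expect_identical(t2$w3, t3$w3)
})

test_that("repeated stratified splits report per-class accuracy", {
  toy <- make_toy_images(80, seed = 11)
  ev <- evaluate_repeated_splits(toy$x, toy$labels, repeats = 2,
                                 split_ratio = 0.9, epochs = 30, seed = 1)
  expect_equal(nrow(ev$repeats), 2)
  expect_length(ev$confusions, 2)
  expect_true(all(glance(ev)[, c("accuracy_SY", "accuracy_DY")] >= 75))

  # deterministic given the seed
  ev2 <- evaluate_repeated_splits(toy$x, toy$labels, repeats = 2,
                                  split_ratio = 0.9, epochs = 30, seed = 1)
  expect_identical(ev$repeats, ev2$repeats)

  # each validation fold is stratified
  expect_true(all(vapply(ev$confusions, function(cm) {
    rows <- tapply(cm$n, cm$truth, sum)
    length(unique(rows)) == 1
  }, logical(1))))

  expect_error(evaluate_repeated_splits(toy$x, toy$labels,
                                        split_ratio = 0.999),
               "validation fold")
})

test_that("shuffled labels give chance-level accuracy", {
  toy <- make_toy_images(100, seed = 21)
  set.seed(22)
  shuffled <- sample(toy$labels)
  ev <- evaluate_repeated_splits(toy$x, shuffled, repeats = 2,
                                 split_ratio = 0.8, epochs = 20, seed = 2)
  expect_true(abs(mean(ev$mean_accuracy) - 50) <= 15)
})

test_that("a trained network round-trips through JSON", {
  toy <- make_toy_images(40, seed = 31)
  net <- train_cnn(build_cnn(seed = 5), toy$x, toy$labels, epochs = 5,
                   seed = 6)
  path <- withr::local_tempfile(fileext = ".json")
  write_cnn(net, path)
  back <- read_cnn(path)
  expect_equal(back$k2, net$k2, tolerance = 1e-12)
  expect_equal(cnn_forward(back, toy$x[, , 1]),
               cnn_forward(net, toy$x[, , 1]), tolerance = 1e-12)
  expect_equal(nrow(back$log), 5)
})
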