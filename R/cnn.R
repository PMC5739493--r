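#' LeNet-style convolutional network for 32x32 candled-egg ROIs
#'
#' Architecture (fixed): input 32x32x1; conv1 with four 5x5 kernels
#' (valid convolution, sigmoid) -> 4 maps of 28x28; 2x2 average pooling
#' -> 4 x 14x14; conv2 with six output maps, each connected to all four
#' input maps through 5x5 kernels (24 kernels, sigmoid) -> 6 x 10x10;
#' 2x2 average pooling -> 6 x 5x5; flatten to 150; fully connected to 2
#' output units; softmax. Total parameter count:
#' 4*25 + 4 + 6*4*25 + 6 + 150*2 + 2 = 1012.
#'
#' Output unit order is `(DY, SY)`: a DY egg has target `[1, 0]` and an
#' SY egg `[0, 1]`.
#'
#' Weights are initialized uniformly in `[-l, l]` with
#' `l = sqrt(6 / (fan_in + fan_out))`; biases start at zero. The
#' initialization is deterministic given `seed`.
#'
#' @param seed Integer seed for the weight initialization.
#' @param pool_activation `"identity"` (default) or `"sigmoid"`: whether
#'   the average-pooling layers are followed by a sigmoid. Conv-only
#'   sigmoid is the conventional reading of LeNet-style nets; the
#'   pool-sigmoid variant is provided for completeness.
#' @param loss `"cross_entropy"` (default, the canonical pairing with a
#'   softmax output) or `"mse"` (summed squared error on the softmax
#'   outputs, the default of some older toolboxes).
#' @return An object of class `cnn` holding the weight arrays `k1`
#'   (5x5x4), `b1` (4), `k2` (5x5x4x6), `b2` (6), `w3` (2x150), `b3` (2)
#'   plus the configuration.
#' @export
#' @examples
#' net <- build_cnn(seed = 1)
#' cnn_n_params(net)
build_cnn <- function(seed = 1L, pool_activation = c("identity", "sigmoid"),
                      loss = c("cross_entropy", "mse")) {
  pool_activation <- match.arg(pool_activation)
  loss <- match.arg(loss)
  init <- function(dims, fan_in, fan_out) {
    l <- sqrt(6 / (fan_in + fan_out))
    array(runif(prod(dims), -l, l), dims)
  }
  w <- local_seed_eval(seed, list(
    k1 = init(c(5, 5, 4), 25, 25 * 4),
    b1 = numeric(4),
    k2 = init(c(5, 5, 4, 6), 25 * 4, 25 * 6),
    b2 = numeric(6),
    w3 = init(c(2, 150), 150, 2),
    b3 = numeric(2)
  ))
  structure(c(w, list(classes = c("DY", "SY"),
                      pool_activation = pool_activation, loss = loss,
                      seed = as.integer(seed), log = NULL)),
            class = "cnn")
}

#' @rdname build_cnn
#' @param model A `cnn`.
#' @return `cnn_n_params()`: total number of trainable parameters.
#' @export
cnn_n_params <- function(model) {
  length(model$k1) + length(model$b1) + length(model$k2) +
    length(model$b2) + length(model$w3) + length(model$b3)
}

#' @export
print.cnn <- function(x, ...) {
  cat(sprintf(
    "<cnn> 32x32 -> conv5x5(4) -> avgpool -> conv5x5(6) -> avgpool -> fc150x2\n"))
  cat(sprintf("      %d parameters, loss %s, pooling %s\n",
              cnn_n_params(x), x$loss, x$pool_activation))
  if (!is.null(x$log)) {
    cat(sprintf("      trained %d epochs, final loss %.4f\n",
                max(x$log$epoch), x$log$loss[nrow(x$log)]))
  }
  invisible(x)
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# im2col index tables for the two valid 5x5 convolutions. Output-pixel
# rows are column-major over the (out_h x out_w) map; patch columns are
# column-major over the 5x5 kernel (and channel-major for conv2).
conv_index <- function(in_h, k = 5, channels = 1) {
  out <- in_h - k + 1
  pix <- expand.grid(r = seq_len(out), c = seq_len(out))
  ker <- expand.grid(kr = seq_len(k), kc = seq_len(k))
  base <- outer(pix$r, ker$kr, `+`) +
    in_h * outer(pix$c - 1, ker$kc - 1, `+`) - 1   # (out^2) x 25, 1-based
  if (channels == 1) return(base)
  do.call(cbind, lapply(seq_len(channels) - 1, function(ch) base + ch * in_h^2))
}

IDX1 <- conv_index(32)          # 784 x 25, into a 32x32 image
IDX2 <- conv_index(14, channels = 4)  # 100 x 100, into a 14x14x4 stack

# Gather im2col patches for a batch. xmat: (in_len x n) matrix of flattened
# inputs; idx: (rows x cols) index table. Returns (rows * n) x cols with
# row order (out-pixel fastest, then sample).
gather_patches <- function(xmat, idx) {
  n <- ncol(xmat)
  in_len <- nrow(xmat)
  big <- xmat[rep(idx, times = n) +
                rep((seq_len(n) - 1L) * in_len, each = length(idx))]
  a <- array(big, c(nrow(idx), ncol(idx), n))
  matrix(aperm(a, c(1, 3, 2)), nrow(idx) * n, ncol(idx))
}

# 2x2 average pooling of maps stored as (h*h*n) x m matrices.
pool2 <- function(zmat, h, n) {
  m <- ncol(zmat)
  a <- array(zmat, c(h, h, n * m))
  o <- seq(1, h - 1, by = 2)
  p <- (a[o, o, , drop = FALSE] + a[o + 1, o, , drop = FALSE] +
          a[o, o + 1, , drop = FALSE] + a[o + 1, o + 1, , drop = FALSE]) / 4
  matrix(p, (h / 2)^2 * n, m)
}

# Adjoint of pool2: distribute gradients equally over each 2x2 block.
unpool2 <- function(gmat, h_out, n) {
  m <- ncol(gmat)
  h <- 2 * h_out
  g <- array(gmat / 4, c(h_out, h_out, n * m))
  a <- array(0, c(h, h, n * m))
  o <- seq(1, h - 1, by = 2)
  a[o, o, ] <- g; a[o + 1, o, ] <- g; a[o, o + 1, ] <- g; a[o + 1, o + 1, ] <- g
  matrix(a, h^2 * n, m)
}

cnn_forward_pass <- function(model, x) {
  dims <- dim(x)
  if (length(dims) == 2) { x <- array(x, c(dims, 1)); dims <- dim(x) }
  if (dims[1] != 32 || dims[2] != 32) abort("input must be 32x32[xn]")
  n <- dims[3]
  xmat <- matrix(x, 1024, n)
  p1 <- gather_patches(xmat, IDX1)                       # (784n) x 25
  z1 <- sweep(p1 %*% matrix(model$k1, 25, 4), 2, model$b1, `+`)
  a1 <- sigmoid(z1)                                      # (784n) x 4
  s1 <- pool2(a1, 28, n)                                 # (196n) x 4
  h1 <- if (model$pool_activation == "sigmoid") sigmoid(s1) else s1
  # reorder to (pixel-within-map, channel) per sample for conv2's gather
  h1s <- matrix(aperm(array(h1, c(196, n, 4)), c(1, 3, 2)), 784, n)
  p2 <- gather_patches(h1s, IDX2)                        # (100n) x 100
  z2 <- sweep(p2 %*% matrix(model$k2, 100, 6), 2, model$b2, `+`)
  a2 <- sigmoid(z2)                                      # (100n) x 6
  s2 <- pool2(a2, 10, n)                                 # (25n) x 6
  h2 <- if (model$pool_activation == "sigmoid") sigmoid(s2) else s2
  feat <- matrix(aperm(array(h2, c(25, n, 6)), c(1, 3, 2)), 150, n)
  logits <- sweep(model$w3 %*% feat, 1, model$b3, `+`)   # 2 x n
  logits <- sweep(logits, 2, apply(logits, 2, max), `-`)
  ex <- exp(logits)
  probs <- sweep(ex, 2, colSums(ex), `/`)
  list(n = n, p1 = p1, a1 = a1, s1 = s1, h1 = h1, h1s = h1s, p2 = p2,
       a2 = a2, s2 = s2, h2 = h2, feat = feat, probs = probs)
}

#' Forward pass of the network
#'
#' @param model A `cnn`.
#' @param x A single 32x32 matrix or a 32x32xn array with values in
#'   `[0, 1]` (images divided by 255).
#' @return An n x 2 matrix of class probabilities with columns
#'   `DY`, `SY`; rows sum to 1.
#' @export
cnn_forward <- function(model, x) {
  fw <- cnn_forward_pass(model, x)
  out <- t(fw$probs)
  colnames(out) <- model$classes
  out
}

# One-hot targets: DY -> (1, 0), SY -> (0, 1); y is a 2 x n matrix.
cnn_targets <- function(labels) {
  lab <- as.character(labels)
  bad <- setdiff(unique(lab), c("DY", "SY"))
  if (length(bad)) abort("labels must be 'SY' or 'DY'")
  rbind(DY = as.numeric(lab == "DY"), SY = as.numeric(lab == "SY"))
}

cnn_loss_from_probs <- function(probs, y, loss) {
  n <- ncol(probs)
  if (loss == "cross_entropy") {
    -sum(y * log(pmax(probs, 1e-300))) / n
  } else {
    sum((probs - y)^2) / n
  }
}

#' Loss and analytic gradients on a batch
#'
#' Backpropagation through the full network. Used by [train_cnn()]; also
#' exported so the gradients can be verified directly against finite
#' differences.
#'
#' @param model A `cnn`.
#' @param x 32x32xn input array in `[0, 1]`.
#' @param labels Length-n vector of `"SY"`/`"DY"` (or a 2 x n one-hot
#'   matrix in `(DY, SY)` order).
#' @return List with `loss` (mean over the batch) and `grads` (list of
#'   arrays matching `k1, b1, k2, b2, w3, b3`).
#' @export
cnn_gradients <- function(model, x, labels) {
  y <- if (is.matrix(labels)) labels else cnn_targets(labels)
  fw <- cnn_forward_pass(model, x)
  n <- fw$n
  probs <- fw$probs
  loss <- cnn_loss_from_probs(probs, y, model$loss)
  if (model$loss == "cross_entropy") {
    dlogits <- (probs - y) / n                            # 2 x n
  } else {
    dp <- 2 * (probs - y) / n
    dlogits <- probs * sweep(dp, 2, colSums(dp * probs), `-`)
  }
  dw3 <- unname(dlogits %*% t(fw$feat))                   # 2 x 150
  db3 <- unname(rowSums(dlogits))
  dfeat <- t(model$w3) %*% dlogits                        # 150 x n
  dh2 <- matrix(aperm(array(dfeat, c(25, 6, n)), c(1, 3, 2)), 25 * n, 6)
  ds2 <- if (model$pool_activation == "sigmoid") {
    dh2 * fw$h2 * (1 - fw$h2)
  } else dh2
  da2 <- unpool2(ds2, 5, n)                               # (100n) x 6
  dz2 <- da2 * fw$a2 * (1 - fw$a2)
  dk2 <- array(t(fw$p2) %*% dz2, c(5, 5, 4, 6))
  db2 <- colSums(dz2)
  dp2 <- dz2 %*% t(matrix(model$k2, 100, 6))              # (100n) x 100
  # scatter-add back through the conv2 im2col (col2im)
  dh1s <- matrix(0, 784, n)
  off <- rep((seq_len(n) - 1L) * 784L, each = 100L)
  for (j in seq_len(100)) {
    tgt <- rep(IDX2[, j], times = n) + off
    dh1s[tgt] <- dh1s[tgt] + dp2[, j]
  }
  dh1 <- matrix(aperm(array(dh1s, c(196, 4, n)), c(1, 3, 2)), 196 * n, 4)
  ds1 <- if (model$pool_activation == "sigmoid") {
    dh1 * fw$h1 * (1 - fw$h1)
  } else dh1
  da1 <- unpool2(ds1, 14, n)                              # (784n) x 4
  dz1 <- da1 * fw$a1 * (1 - fw$a1)
  dk1 <- array(t(fw$p1) %*% dz1, c(5, 5, 4))
  db1 <- colSums(dz1)
  list(loss = loss, probs = probs,
       grads = list(k1 = dk1, b1 = db1, k2 = dk2, b2 = db2,
                    w3 = dw3, b3 = db3))
}

cnn_param_names <- c("k1", "b1", "k2", "b2", "w3", "b3")

cnn_get_params <- function(model) {
  unlist(lapply(cnn_param_names, function(nm) as.numeric(model[[nm]])))
}

cnn_set_params <- function(model, theta) {
  pos <- 0L
  for (nm in cnn_param_names) {
    len <- length(model[[nm]])
    model[[nm]] <- array(theta[pos + seq_len(len)], dim = dim(model[[nm]]) %||%
                           len)
    pos <- pos + len
  }
  model
}

cnn_loss <- function(model, x, labels) {
  y <- if (is.matrix(labels)) labels else cnn_targets(labels)
  cnn_loss_from_probs(cnn_forward_pass(model, x)$probs, y, model$loss)
}

#' Train the network with minibatch stochastic gradient descent
#'
#' Plain SGD: shuffled minibatches each epoch, a fixed learning rate, no
#' momentum, weight decay or schedule. The per-epoch mean batch loss and
#' running training accuracy are recorded in `model$log`.
#'
#' @param model A `cnn` from [build_cnn()].
#' @param x 32x32xn training array in `[0, 1]`.
#' @param labels Length-n vector of `"SY"`/`"DY"`.
#' @param learning_rate Fixed SGD learning rate (default 0.2).
#' @param batch_size Minibatch size (default 50); a final partial batch
#'   is used as-is.
#' @param epochs Full passes over the training set (default 100).
#' @param seed Integer seed for the shuffling.
#' @return The trained `cnn` with a `log` tibble
#'   (`epoch`, `loss`, `train_acc`).
#' @export
train_cnn <- function(model, x, labels, learning_rate = 0.2,
                      batch_size = 50, epochs = 100, seed = 1L) {
  n <- dim(x)[3]
  if (batch_size > n) batch_size <- n
  y_all <- cnn_targets(labels)
  log <- vector("list", epochs)
  local_seed_eval(seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      starts <- seq(1, n, by = batch_size)
      losses <- numeric(length(starts))
      hits <- 0L
      for (bi in seq_along(starts)) {
        take <- ord[starts[bi]:min(starts[bi] + batch_size - 1, n)]
        bg <- cnn_gradients(model, x[, , take, drop = FALSE],
                            y_all[, take, drop = FALSE])
        if (!is.finite(bg$loss)) {
          abort(sprintf("NaN/Inf loss in epoch %d, batch %d", ep, bi))
        }
        losses[bi] <- bg$loss
        hits <- hits + sum((bg$probs[1, ] > bg$probs[2, ]) ==
                             (y_all[1, take] > y_all[2, take]))
        for (nm in cnn_param_names) {
          model[[nm]] <- model[[nm]] - learning_rate * bg$grads[[nm]]
        }
      }
      log[[ep]] <- tibble::tibble(epoch = ep, loss = mean(losses),
                                  train_acc = hits / n)
    }
  })
  model$log <- dplyr::bind_rows(log)
  model
}

#' Predict classes for new images
#'
#' @param object A trained `cnn`.
#' @param newdata 32x32 matrix or 32x32xn array in `[0, 1]`.
#' @param ... Unused.
#' @return Tibble with `.pred` (factor SY/DY) and probability columns
#'   `.prob_DY`, `.prob_SY`.
#' @export
predict.cnn <- function(object, newdata, ...) {
  probs <- cnn_forward(object, newdata)
  pred <- ifelse(probs[, "DY"] > probs[, "SY"], "DY", "SY")
  tibble::tibble(.pred = factor(pred, levels = c("SY", "DY")),
                 .prob_DY = probs[, "DY"], .prob_SY = probs[, "SY"])
}

#' Repeated stratified split evaluation of the network
#'
#' The protocol used to benchmark the network: the dataset is split into
#' training and validation groups at `split_ratio` with the same number
#' of DY and SY eggs in each group; a freshly initialized network is
#' trained on the large group and evaluated on the small one; the split
#' is repeated `repeats` times and the per-class accuracies averaged.
#'
#' @param x 32x32xn array of preprocessed ROIs in `[0, 1]` (see
#'   [preprocess_dataset()]).
#' @param labels Length-n vector of `"SY"`/`"DY"`.
#' @param repeats Number of random splits (default 10).
#' @param split_ratio Training fraction (default 0.95).
#' @param seed Master seed; repeat r uses `seed + r` for its split,
#'   initialization and shuffling.
#' @param ... Passed to [train_cnn()] (`learning_rate`, `batch_size`,
#'   `epochs`) and [build_cnn()] via `pool_activation`, `loss`.
#' @param pool_activation,loss Forwarded to [build_cnn()].
#' @return An object of class `cnn_eval`: list with `repeats` (tibble of
#'   per-repeat per-class accuracies), `confusions` (list of confusion
#'   tibbles), `mean_accuracy` (named percentages), `models` not kept.
#' @export
evaluate_repeated_splits <- function(x, labels, repeats = 10,
                                     split_ratio = 0.95, seed = 1L,
                                     pool_activation = "identity",
                                     loss = "cross_entropy", ...) {
  labels <- factor(as.character(labels), levels = c("SY", "DY"))
  n <- dim(x)[3]
  stopifnot(length(labels) == n)
  per_class_val <- floor(n * (1 - split_ratio) / 2)
  if (per_class_val < 1) abort("validation fold smaller than 1 per class")
  rows <- vector("list", repeats)
  confusions <- vector("list", repeats)
  for (r in seq_len(repeats)) {
    srep <- as.integer(seed) + r
    val_idx <- local_seed_eval(srep, {
      unlist(lapply(c("SY", "DY"), function(g) {
        sample(which(labels == g), per_class_val)
      }))
    })
    train_idx <- setdiff(seq_len(n), val_idx)
    net <- build_cnn(seed = srep, pool_activation = pool_activation,
                     loss = loss)
    net <- train_cnn(net, x[, , train_idx, drop = FALSE],
                     labels[train_idx], seed = srep, ...)
    pred <- predict(net, x[, , val_idx, drop = FALSE])$.pred
    cm <- confusion_matrix(labels[val_idx], pred)
    acc <- class_accuracy(cm)
    confusions[[r]] <- cm
    rows[[r]] <- tibble::tibble(repeat_id = r, accuracy_SY = acc["SY"],
                                accuracy_DY = acc["DY"])
  }
  per_repeat <- dplyr::bind_rows(rows)
  structure(list(
    repeats = per_repeat, confusions = confusions,
    mean_accuracy = c(SY = mean(per_repeat$accuracy_SY),
                      DY = mean(per_repeat$accuracy_DY)),
    n = n, split_ratio = split_ratio
  ), class = "cnn_eval")
}

#' @export
print.cnn_eval <- function(x, ...) {
  cat(sprintf("CNN evaluation: %d repeats, %.0f:%.0f split, n = %d\n",
              nrow(x$repeats), 100 * x$split_ratio,
              100 * (1 - x$split_ratio), x$n))
  cat(sprintf("Mean per-class accuracy: SY %.1f%%, DY %.1f%%\n",
              x$mean_accuracy["SY"], x$mean_accuracy["DY"]))
  invisible(x)
}

#' @rdname tidy.fld
#' @export
tidy.cnn_eval <- function(x, ...) x$repeats

#' @rdname tidy.fld
#' @export
glance.cnn_eval <- function(x, ...) {
  tibble::tibble(repeats = nrow(x$repeats),
                 accuracy_SY = x$mean_accuracy["SY"],
                 accuracy_DY = x$mean_accuracy["DY"],
                 accuracy_overall = mean(x$mean_accuracy))
}

# serialization -----------------------------------------------------------

#' Save and load a network as JSON
#'
#' Weights are stored flattened with their dimensions, plus the
#' configuration; the training log, if any, is included.
#'
#' @param model A `cnn`.
#' @param path File path.
#' @return `read_cnn()` returns the restored model.
#' @export
write_cnn <- function(model, path) {
  weights <- lapply(setNames(cnn_param_names, cnn_param_names),
                    function(nm) {
                      list(dim = dim(model[[nm]]) %||% length(model[[nm]]),
                           values = as.numeric(model[[nm]]))
                    })
  jsonlite::write_json(list(
    type = "cnn", classes = model$classes,
    pool_activation = model$pool_activation, loss = model$loss,
    seed = model$seed, weights = weights,
    log = model$log
  ), path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_cnn
#' @export
read_cnn <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(j$type, "cnn")) abort("not a cnn model file")
  model <- build_cnn(seed = j$seed, pool_activation = j$pool_activation,
                     loss = j$loss)
  for (nm in cnn_param_names) {
    model[[nm]] <- array(j$weights[[nm]]$values,
                         dim = unlist(j$weights[[nm]]$dim))
  }
  if (!is.null(j$log) && length(j$log)) {
    model$log <- tibble::as_tibble(j$log)
  }
  model
}
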