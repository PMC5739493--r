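#' Fit Fisher's linear discriminant for two classes
#'
#' Computes per-class mean vectors, the pooled within-class covariance
#' `S_p = ((n1 - 1) S_1 + (n2 - 1) S_2) / (n - 2)`, and the Fisher
#' classification functions
#' `f_g(x) = mu_g' S_p^{-1} x - (1/2) mu_g' S_p^{-1} mu_g + log p_g`,
#' one linear score per class; a sample is assigned to the class with the
#' larger score. Priors default to equal. If `S_p` is numerically
#' singular (near-collinear features, e.g. descriptors of nearly circular
#' yolks) a small ridge `1e-6 * trace(S_p) / p` is added to the diagonal
#' with a warning.
#'
#' @param data Data frame with one factor/character label column and
#'   numeric feature columns, or a numeric matrix (then supply `labels`).
#' @param label_col Name of the label column (default `"label"`).
#' @param feature_cols Feature column names; default: all numeric columns
#'   except the label.
#' @param labels Class labels when `data` is a matrix.
#' @param priors Named per-class prior probabilities (default equal).
#' @param tie_break Class assigned on exact score ties (default `"SY"`
#'   when present, otherwise the first class level).
#' @return An object of class `fld`, with elements `means`, `cov`
#'   (pooled), `priors`, `coef` (p x 2 weight matrix), `const` (length-2
#'   constants), `classes`, `features`.
#' @export
#' @examples
#' d <- data.frame(label = rep(c("SY", "DY"), each = 20),
#'                 f1 = c(rnorm(20), rnorm(20, 4)),
#'                 f2 = c(rnorm(20), rnorm(20, -3)))
#' fit <- fit_fld(d)
#' glance(fit)
fit_fld <- function(data, label_col = "label", feature_cols = NULL,
                    labels = NULL, priors = NULL, tie_break = NULL) {
  if (is.matrix(data)) {
    x <- data
    if (is.null(labels)) abort("supply labels with a matrix input")
    y <- labels
    feature_cols <- colnames(x) %||% paste0("f", seq_len(ncol(x)))
    colnames(x) <- feature_cols
  } else {
    stopifnot(is.data.frame(data))
    if (is.null(feature_cols)) {
      feature_cols <- setdiff(names(data)[vapply(data, is.numeric,
                                                 logical(1))], label_col)
    }
    x <- as.matrix(data[, feature_cols, drop = FALSE])
    y <- data[[label_col]]
  }
  y <- droplevels(as.factor(y))
  cls <- levels(y)
  if (length(cls) != 2) abort("exactly two classes are required")
  if ("SY" %in% cls) cls <- c("SY", setdiff(cls, "SY"))
  if (any(!stats::complete.cases(x))) abort("features contain missing values")
  n_g <- table(factor(y, levels = cls))
  if (any(n_g < 1) || sum(n_g) < 3) {
    abort("each class needs at least one sample (and three in total)")
  }
  p <- ncol(x)
  means <- t(vapply(cls, function(g) colMeans(x[y == g, , drop = FALSE]),
                    numeric(p)))
  sp <- Reduce(`+`, lapply(cls, function(g) {
    xg <- x[y == g, , drop = FALSE]
    if (nrow(xg) < 2) return(matrix(0, p, p))   # singleton: no dispersion
    (nrow(xg) - 1) * stats::cov(xg)
  })) / (nrow(x) - 2)
  sp_inv <- tryCatch(solve(sp), error = function(e) NULL)
  rc <- tryCatch(rcond(sp), error = function(e) 0)
  if (is.null(sp_inv) || !is.finite(rc) || rc < 1e-12) {
    warn("pooled covariance is singular; adding a small ridge")
    sp <- sp + diag(1e-6 * sum(diag(sp)) / p, p)
    sp_inv <- solve(sp)
  }
  if (is.null(priors)) {
    priors <- setNames(rep(0.5, 2), cls)
  } else {
    priors <- priors[cls] / sum(priors[cls])
  }
  coef <- sp_inv %*% t(means)                       # p x 2
  const <- vapply(1:2, function(g) {
    -0.5 * drop(means[g, ] %*% sp_inv %*% means[g, ]) + log(priors[g])
  }, numeric(1))
  structure(list(means = means, cov = sp, priors = priors, coef = coef,
                 const = setNames(const, cls), classes = cls,
                 features = feature_cols,
                 tie_break = tie_break %||%
                   (if ("SY" %in% cls) "SY" else cls[1]),
                 n = as.integer(n_g)),
            class = "fld")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.fld <- function(x, ...) {
  cat(sprintf("<fld> classes %s vs %s, %d features, priors %.2f/%.2f\n",
              x$classes[1], x$classes[2], length(x$features),
              x$priors[1], x$priors[2]))
  invisible(x)
}

fld_scores <- function(object, x) {
  x <- as.matrix(x)
  if (ncol(x) != nrow(object$coef)) abort("feature dimension mismatch")
  sweep(x %*% object$coef, 2, object$const, `+`)
}

#' Classify samples with a fitted discriminant
#'
#' Evaluates both Fisher classification functions and assigns each sample
#' to the class with the larger score; exact ties go to the model's
#' `tie_break` class (SY by default).
#'
#' @param object A fitted [fit_fld()] model.
#' @param newdata Data frame containing the model's feature columns, or a
#'   numeric matrix/vector.
#' @param ... Unused.
#' @return A tibble with `.pred` (factor) and one score column per class.
#' @export
predict.fld <- function(object, newdata, ...) {
  if (is.data.frame(newdata)) {
    x <- as.matrix(newdata[, object$features, drop = FALSE])
  } else if (is.null(dim(newdata))) {
    x <- matrix(newdata, nrow = 1)
  } else {
    x <- as.matrix(newdata)
  }
  sc <- fld_scores(object, x)
  pred <- ifelse(sc[, 1] > sc[, 2], object$classes[1],
                 ifelse(sc[, 1] < sc[, 2], object$classes[2],
                        object$tie_break))
  out <- tibble::tibble(.pred = factor(pred, levels = object$classes))
  out[paste0(".score_", object$classes)] <- list(unname(sc[, 1]),
                                                 unname(sc[, 2]))
  out
}

#' @rdname predict.fld
#' @param x A 14-dimensional feature vector (or matrix of rows).
#' @export
fld_classify <- function(object, x) {
  predict(object, x)
}

#' Confusion matrix with per-class accuracies
#'
#' @param truth,pred Factors (or vectors coercible to factors with the
#'   same levels).
#' @return A `confusion` tibble: `truth`, `pred`, `n`, plus attributes
#'   used by [glance.confusion()].
#' @export
confusion_matrix <- function(truth, pred) {
  lv <- union(levels(as.factor(truth)), levels(as.factor(pred)))
  truth <- factor(truth, levels = lv); pred <- factor(pred, levels = lv)
  tab <- as.data.frame(table(truth = truth, pred = pred),
                       responseName = "n")
  out <- tibble::as_tibble(tab)
  class(out) <- c("confusion", class(out))
  out
}

#' @export
print.confusion <- function(x, ...) {
  wide <- tidyr::pivot_wider(x, names_from = "pred", values_from = "n")
  acc <- class_accuracy(x)
  cat("Confusion matrix (rows = truth):\n")
  print(as.data.frame(wide), row.names = FALSE)
  cat("Per-class accuracy (%):",
      paste(sprintf("%s %.1f", names(acc), acc), collapse = ", "), "\n")
  invisible(x)
}

#' Per-class accuracy of a confusion tibble
#'
#' Diagonal count over row sum, as a percentage.
#'
#' @param cm A `confusion` tibble from [confusion_matrix()].
#' @return Named numeric vector of percentages.
#' @export
class_accuracy <- function(cm) {
  lv <- levels(cm$truth)
  vapply(lv, function(g) {
    row <- cm$n[cm$truth == g]
    hit <- cm$n[cm$truth == g & cm$pred == g]
    100 * hit / max(sum(row), 1)
  }, numeric(1))
}

#' Leave-one-out cross-validation of the discriminant
#'
#' For every sample, a discriminant is fitted on all other samples and
#' used to classify the held-out one; the accumulated predictions give
#' the cross-validated confusion matrix and per-class accuracies.
#'
#' @inheritParams fit_fld
#' @return An object of class `fld_cv`: list with `predictions` (tibble
#'   of `id`, `truth`, `pred` plus any `separated` flag carried from
#'   `data`), `confusion`, and `accuracy` (named percentages).
#' @export
fld_loocv <- function(data, label_col = "label", feature_cols = NULL,
                      priors = NULL) {
  stopifnot(is.data.frame(data))
  n <- nrow(data)
  if (n < 4) abort("leave-one-out needs at least 4 samples")
  y <- as.factor(data[[label_col]])
  preds <- character(n)
  for (i in seq_len(n)) {
    train <- data[-i, , drop = FALSE]
    if (length(unique(train[[label_col]])) < 2) {
      abort("a leave-one-out fold lost one of the classes")
    }
    fit <- fit_fld(train, label_col = label_col,
                   feature_cols = feature_cols, priors = priors)
    preds[i] <- as.character(predict(fit, data[i, , drop = FALSE])$.pred[1])
  }
  predictions <- tibble::tibble(
    id = if ("id" %in% names(data)) data$id else seq_len(n),
    truth = y, pred = factor(preds, levels = levels(y))
  )
  if ("separated" %in% names(data)) {
    predictions$separated <- data$separated
  }
  cm <- confusion_matrix(predictions$truth, predictions$pred)
  structure(list(predictions = predictions, confusion = cm,
                 accuracy = class_accuracy(cm)),
            class = "fld_cv")
}

#' @export
print.fld_cv <- function(x, ...) {
  cat("Leave-one-out cross-validation\n")
  print(x$confusion)
  invisible(x)
}

# broom-style methods -----------------------------------------------------

#' Tidy a fitted discriminant
#'
#' One row per feature with the two classification-function weights; the
#' constants appear as term `"(constant)"`.
#'
#' @param x A fitted `fld`.
#' @param ... Unused.
#' @return A tibble with columns `term` and one column per class.
#' @export
tidy.fld <- function(x, ...) {
  out <- tibble::tibble(term = c(x$features, "(constant)"))
  for (g in 1:2) {
    out[[x$classes[g]]] <- c(x$coef[, g], x$const[g])
  }
  out
}

#' @rdname tidy.fld
#' @return `glance.fld()`: one-row tibble with sample sizes and the
#'   log-determinant of the pooled covariance.
#' @export
glance.fld <- function(x, ...) {
  tibble::tibble(n = sum(x$n), n_class1 = x$n[1], n_class2 = x$n[2],
                 p = length(x$features),
                 logdet_cov = determinant(x$cov)$modulus[1])
}

#' @rdname tidy.fld
#' @export
tidy.fld_cv <- function(x, ...) x$confusion

#' @rdname tidy.fld
#' @return `glance.fld_cv()`: one-row tibble with per-class and overall
#'   cross-validated accuracy (%).
#' @export
glance.fld_cv <- function(x, ...) {
  acc <- x$accuracy
  overall <- 100 * sum(x$confusion$n[as.character(x$confusion$truth) ==
                                       as.character(x$confusion$pred)]) /
    sum(x$confusion$n)
  out <- tibble::as_tibble(as.list(setNames(acc, paste0("accuracy_",
                                                        names(acc)))))
  out$accuracy_overall <- overall
  out
}

# serialization -----------------------------------------------------------

#' Save and load a fitted discriminant as JSON
#'
#' @param object A fitted `fld`.
#' @param path File path.
#' @return `read_fld()` returns the restored model.
#' @export
write_fld <- function(object, path) {
  jsonlite::write_json(list(
    type = "fld", classes = object$classes, features = object$features,
    means = object$means, cov = object$cov, priors = object$priors,
    coef = object$coef, const = object$const, tie_break = object$tie_break,
    n = object$n
  ), path, digits = NA, auto_unbox = TRUE, matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_fld
#' @export
read_fld <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(j$type, "fld")) abort("not an fld model file")
  structure(list(
    means = structure(as.matrix(j$means),
                      dimnames = list(j$classes, j$features)),
    cov = as.matrix(j$cov),
    priors = setNames(as.numeric(j$priors), j$classes),
    coef = as.matrix(j$coef),
    const = setNames(as.numeric(j$const), j$classes), classes = j$classes,
    features = j$features, tie_break = j$tie_break, n = as.integer(j$n)
  ), class = "fld")
}
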