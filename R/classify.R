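# Classifier suite and evaluation protocol: ten classical classifiers on the
# kinematic feature vectors, graded by stratified 10-fold cross-validation
# repeated 10 times.

#' Supported classifier names
#' @export
classifier_kinds <- function() {
  c("mindist", "lda", "qda", "knn1", "knn3", "knn5",
    "mahalanobis", "svm_linear", "svm_rbf", "nnet")
}

#' Assemble a labelled feature dataset
#'
#' @param features data.frame / matrix of numeric features (rows = videos).
#' @param labels factor or character vector of class labels.
#' @param feature_names columns to keep, default all numeric columns.
#' @return list of class `feature_dataset` with elements `x` (numeric
#'   matrix) and `y` (factor). Rows with missing feature values are
#'   rejected, as is a dataset with fewer than two classes.
#' @export
feature_dataset <- function(features, labels, feature_names = NULL) {
  features <- as.data.frame(features)
  if (is.null(feature_names))
    feature_names <- names(features)[vapply(features, is.numeric, TRUE)]
  x <- as.matrix(features[, feature_names, drop = FALSE])
  if (anyNA(x)) stop("missing values in the selected features")
  y <- factor(labels)
  stopifnot(nrow(x) == length(y))
  if (nlevels(droplevels(y)) < 2) stop("at least two classes required")
  structure(list(x = x, y = droplevels(y), feature_names = feature_names),
            class = "feature_dataset")
}

zscore_fit <- function(x) {
  mu <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  sdv[sdv == 0] <- 1
  list(mu = mu, sd = sdv)
}
zscore_apply <- function(x, z) sweep(sweep(x, 2, z$mu), 2, z$sd, "/")

#' Train a classifier on kinematic features
#'
#' Supported kinds: `mindist` (nearest class mean), `lda`, `qda`
#' (MASS), `knn1`/`knn3`/`knn5` (deterministic k-nearest neighbours; tied
#' votes fall back to the label of the single nearest neighbour, ties in
#' distance to the lowest class index), `mahalanobis` (per-class Mahalanobis
#' distance), `svm_linear`, `svm_rbf` (e1071, `C = 1`, RBF
#' `gamma = 1 / (n_features * mean feature variance)`), and `nnet` (one
#' hidden layer of 10 units, fixed-seed initialization).
#'
#' @param data a [feature_dataset()].
#' @param kind one of [classifier_kinds()].
#' @param standardize z-score the features using training statistics
#'   (recommended: range features live on a degree scale, F1/F2 on a unit
#'   scale).
#' @param seed seed for the (stochastic) neural-network initialization.
#' @param ... hyperparameter overrides passed to the backing fitter.
#' @return object of class `froglet_classifier` with a [predict] method.
#' @export
train_classifier <- function(data, kind, standardize = TRUE, seed = 1, ...) {
  stopifnot(inherits(data, "feature_dataset"))
  kind <- match.arg(kind, classifier_kinds())
  z <- if (standardize) zscore_fit(data$x) else NULL
  x <- if (standardize) zscore_apply(data$x, z) else data$x
  y <- data$y
  fit <- switch(kind,
    mindist = list(means = class_means(x, y)),
    mahalanobis = {
      covs <- lapply(levels(y), function(l) stats::cov(x[y == l, , drop = FALSE]))
      for (cv in covs) if (!is.finite(determinant(cv)$modulus) ||
                           rcond_safe(cv) < 1e-12)
        stop("singular class covariance; Mahalanobis classifier undefined")
      list(means = class_means(x, y), covs = covs)
    },
    lda = MASS::lda(x, grouping = y, ...),
    qda = MASS::qda(x, grouping = y, ...),
    knn1 = list(x = x, y = y, k = 1L),
    knn3 = list(x = x, y = y, k = 3L),
    knn5 = list(x = x, y = y, k = 5L),
    svm_linear = e1071::svm(x, y, kernel = "linear", cost = 1, scale = FALSE, ...),
    svm_rbf = e1071::svm(x, y, kernel = "radial", cost = 1, scale = FALSE,
                         gamma = 1 / (ncol(x) * max(mean(apply(x, 2, stats::var)), 1e-12)),
                         ...),
    nnet = withr::with_seed(seed,
      nnet::nnet(x, nnet_targets(y), size = 10, decay = 5e-3, maxit = 300,
                 trace = FALSE, ...))
  )
  structure(list(kind = kind, fit = fit, zscore = z, levels = levels(y),
                 feature_names = data$feature_names),
            class = "froglet_classifier")
}

class_means <- function(x, y) {
  m <- rowsum(x, y) / as.vector(table(y))
  m[levels(y), , drop = FALSE]
}

rcond_safe <- function(m) tryCatch(1 / kappa(m, exact = TRUE),
                                   error = function(e) 0)

nnet_targets <- function(y) {
  t <- stats::model.matrix(~ y - 1)
  colnames(t) <- levels(y)
  t
}

# Deterministic KNN: majority vote among the k nearest training points;
# a tied vote falls back to the nearest neighbour's label; equal distances
# are broken by training-row order.
knn_predict <- function(fit, newx) {
  apply(newx, 1, function(p) {
    d <- sqrt(colSums((t(fit$x) - p)^2))
    ord <- order(d, seq_along(d))
    nn <- ord[seq_len(min(fit$k, length(ord)))]
    votes <- table(fit$y[nn])
    top <- names(votes)[votes == max(votes)]
    if (length(top) == 1) top else as.character(fit$y[nn[1]])
  })
}

#' Predict class labels
#'
#' @param object a `froglet_classifier`.
#' @param newdata numeric matrix/data.frame with the training feature
#'   columns.
#' @param ... unused.
#' @return factor of predicted labels. Distance ties (e.g. a point
#'   equidistant from two class means) resolve to the lowest class index.
#' @export
predict.froglet_classifier <- function(object, newdata, ...) {
  newx <- as.matrix(as.data.frame(newdata)[, object$feature_names, drop = FALSE])
  if (ncol(newx) != length(object$feature_names))
    stop("feature dimension mismatch")
  if (!is.null(object$zscore)) newx <- zscore_apply(newx, object$zscore)
  lv <- object$levels
  lab <- switch(object$kind,
    mindist = {
      d <- apply(object$fit$means, 1, function(m) sqrt(rowSums(sweep(newx, 2, m)^2)))
      d <- matrix(d, nrow = nrow(newx))
      lv[apply(d, 1, which.min)]
    },
    mahalanobis = {
      d <- vapply(seq_along(lv), function(i)
        stats::mahalanobis(newx, object$fit$means[i, ], object$fit$covs[[i]]),
        numeric(nrow(newx)))
      d <- matrix(d, nrow = nrow(newx))
      lv[apply(d, 1, which.min)]
    },
    lda = as.character(stats::predict(object$fit, newx)$class),
    qda = as.character(stats::predict(object$fit, newx)$class),
    knn1 = knn_predict(object$fit, newx),
    knn3 = knn_predict(object$fit, newx),
    knn5 = knn_predict(object$fit, newx),
    svm_linear = as.character(stats::predict(object$fit, newx)),
    svm_rbf = as.character(stats::predict(object$fit, newx)),
    nnet = {
      p <- stats::predict(object$fit, newx)
      colnames(p)[apply(p, 1, which.max)]
    })
  factor(lab, levels = lv)
}

stratified_folds <- function(y, n_folds) {
  fold <- integer(length(y))
  for (l in levels(y)) {
    idx <- sample(which(y == l))
    fold[idx] <- rep_len(sample(n_folds), length(idx))
  }
  fold
}

#' Repeated stratified cross-validation
#'
#' Splits the data into `n_folds` stratified folds (each fold holds roughly
#' the same number of animals per class), tests each fold against a model
#' trained on the rest, and repeats the whole partition `n_repeats` times
#' with reshuffled folds. The estimated accuracy is the mean of the fold
#' accuracies; the reported standard deviation is taken over all
#' `n_folds * n_repeats` fold accuracies.
#'
#' @inheritParams train_classifier
#' @param n_folds number of folds (every class must have at least this many
#'   members).
#' @param n_repeats number of repeats.
#' @param seed integer; identical `(data, kind, seed)` gives an identical
#'   result.
#' @return list of class `cv_result`: `classifier`, `feature_names`,
#'   `fold_accuracies` (`n_repeats x n_folds` matrix), `mean_accuracy`,
#'   `std_accuracy`, `n_folds`, `n_repeats`, `seed`.
#' @export
cross_validate <- function(data, kind, n_folds = 10, n_repeats = 10,
                           seed = 1, standardize = TRUE, ...) {
  stopifnot(inherits(data, "feature_dataset"))
  if (any(table(data$y) < n_folds))
    stop("every class needs at least n_folds members")
  acc <- matrix(NA_real_, n_repeats, n_folds)
  withr::with_seed(seed, {
    for (r in seq_len(n_repeats)) {
      fold <- stratified_folds(data$y, n_folds)
      for (f in seq_len(n_folds)) {
        tr <- fold != f
        dtr <- feature_dataset(data$x[tr, , drop = FALSE], data$y[tr],
                               data$feature_names)
        model <- train_classifier(dtr, kind, standardize = standardize,
                                  seed = seed + r, ...)
        pred <- predict(model, data$x[!tr, , drop = FALSE])
        acc[r, f] <- mean(pred == data$y[!tr])
      }
    }
  })
  structure(list(classifier = kind, feature_names = data$feature_names,
                 fold_accuracies = acc, mean_accuracy = mean(acc),
                 std_accuracy = stats::sd(as.vector(acc)),
                 n_folds = n_folds, n_repeats = n_repeats, seed = seed),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s on (%s): accuracy %.1f%% +/- %.1f%% (%dx%d-fold CV)\n",
              x$classifier, paste(x$feature_names, collapse = ", "),
              100 * x$mean_accuracy, 100 * x$std_accuracy,
              x$n_repeats, x$n_folds))
  invisible(x)
}

#' Generate a synthetic feature cohort
#'
#' Draws `n_per_class` animals per damage class from the default motion
#' models (each with its own seeded animal-to-animal variation), simulates
#' ground-truth hindfoot traces for each, and summarizes every animal into
#' the four kinematic features. This is the in-silico analogue of a labelled
#' video cohort and is what the classification harness trains on.
#'
#' @param n_per_class animals per class.
#' @param n_frames,fps trace length per animal.
#' @param seed master seed; all per-animal seeds derive from it.
#' @param radius centroid-to-foot distance used for the range features, px.
#' @return data.frame: `label`, `f1`, `f2`, `f3`, `f4`.
#' @export
generate_feature_cohort <- function(n_per_class = 30, n_frames = 600,
                                    fps = 60, seed = 1, radius = 58) {
  rows <- list()
  for (ci in seq_along(damage_classes())) {
    label <- damage_classes()[ci]
    for (i in seq_len(n_per_class)) {
      aseed <- seed + 1009L * ci + 7L * i
      model <- default_motion_model(label, seed = aseed)
      tr <- generate_traces(model, n_frames, fps, seed = aseed + 1L)
      fe <- extract_features(tr, radius = radius)
      rows[[length(rows) + 1]] <-
        data.frame(label = label, f1 = fe$f1_synchronization,
                   f2 = fe$f2_symmetry, f3 = fe$f3_range_right,
                   f4 = fe$f4_range_left)
    }
  }
  do.call(rbind, rows)
}
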