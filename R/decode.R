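#' SVM specification for decoding
#'
#' The decoder is a polynomial-kernel support-vector machine of the form
#' `y = sum_i alpha_i K(x, x_i) + b`, trained by the SMO-style dual solver of
#' libsvm. Kernel `K(u, v) = (gamma * u.v + coef0)^degree`; `gamma` defaults
#' to 1/d at fit time (d = feature dimension) for conditioning, `coef0 = 1`
#' so that lower-order interaction terms are included.
#'
#' @param degree polynomial degree (>= 1, default 3)
#' @param cost box constraint C (> 0, default 1)
#' @param coef0 kernel offset (default 1)
#' @param gamma kernel scale; `NULL` means 1/ncol(X)
#' @param scale z-scale each feature using training-fold statistics
#' @return an object of class `svm_spec`
#' @export
svm_spec <- function(degree = 3L, cost = 1, coef0 = 1, gamma = NULL,
                     scale = TRUE) {
  if (degree < 1) stop("degree must be >= 1")
  if (cost <= 0) stop("cost must be positive")
  structure(list(degree = as.integer(degree), cost = cost, coef0 = coef0,
                 gamma = gamma, scale = isTRUE(scale)),
            class = "svm_spec")
}

#' Fit a polynomial-kernel SVM classifier
#'
#' Wraps [e1071::svm()] (libsvm) for binary classification. Feature scaling,
#' when enabled, is computed from the supplied (training) data only and
#' reapplied at prediction time; zero-variance features are passed through
#' unscaled. The fit is deterministic given the data and spec.
#'
#' @param X trials x features numeric matrix, no missing values
#' @param y two-class labels (coerced to factor)
#' @param spec an [svm_spec()]
#' @return an object of class `pain_svm` usable with `predict()`
#' @export
fit_svm <- function(X, y, spec = svm_spec()) {
  X <- as.matrix(X)
  y <- droplevels(factor(y))
  if (nlevels(y) != 2) stop("exactly two classes are required")
  if (anyNA(X)) stop("missing values in feature matrix")
  if (spec$scale) {
    ctr <- colMeans(X)
    scl <- apply(X, 2, sd)
    scl[!is.finite(scl) | scl == 0] <- 1
  } else {
    ctr <- rep(0, ncol(X))
    scl <- rep(1, ncol(X))
  }
  Xs <- sweep(sweep(X, 2, ctr, "-"), 2, scl, "/")
  model <- e1071::svm(
    x = Xs, y = y, type = "C-classification", kernel = "polynomial",
    degree = spec$degree, cost = spec$cost, coef0 = spec$coef0,
    gamma = spec$gamma %||% (1 / ncol(X)), scale = FALSE
  )
  structure(list(model = model, center = ctr, scale = scl,
                 levels = levels(y), spec = spec),
            class = "pain_svm")
}

#' @export
predict.pain_svm <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  Xs <- sweep(sweep(X, 2, object$center, "-"), 2, object$scale, "/")
  predict(object$model, Xs)
}

# Stratified fold assignment: within each class, fold ids 1..k are dealt out
# as evenly as possible and shuffled.
stratified_folds <- function(y, k) {
  fid <- integer(length(y))
  for (cl in levels(y)) {
    idx <- which(y == cl)
    if (length(idx) < k) {
      stop("too few trials in class ", cl, " for ", k, "-fold stratification")
    }
    fid[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fid
}

# One pass of k-fold cross-validation: overall fraction of correctly
# classified held-out trials.
cv_accuracy <- function(X, y, spec, fold_id) {
  correct <- 0L
  for (f in unique(fold_id)) {
    test <- fold_id == f
    clf <- fit_svm(X[!test, , drop = FALSE], y[!test], spec)
    pred <- predict(clf, X[test, , drop = FALSE])
    correct <- correct + sum(pred == y[test])
  }
  correct / length(y)
}

new_decoding_trajectory <- function(times, mean_acc, sem_acc = NULL,
                                    acc = NULL, n_mc = NA_integer_,
                                    folds = NA_integer_, chance = NULL,
                                    modality = NULL) {
  stopifnot(length(times) == length(mean_acc),
            all(mean_acc >= 0 & mean_acc <= 1))
  sem_acc <- sem_acc %||% rep(0, length(times))
  stopifnot(all(sem_acc >= 0))
  peak_i <- which.max(mean_acc)  # earliest argmax on ties
  structure(
    list(times = times, mean_acc = mean_acc, sem_acc = sem_acc, acc = acc,
         n_mc = n_mc, folds = folds, chance = chance,
         peak_acc = mean_acc[peak_i], peak_time = times[peak_i],
         modality = modality),
    class = "decoding_trajectory"
  )
}

#' Construct a decoding trajectory from precomputed accuracies
#'
#' Mostly useful for feeding externally computed (or analytically specified)
#' accuracy curves into [onset_from_trajectory()].
#'
#' @param times time grid, seconds
#' @param mean_acc mean accuracy per time, in \[0, 1\]
#' @param sem_acc per-time standard error (default 0)
#' @param chance optional chance level: a [chance_level()] result or a scalar
#' @return a `decoding_trajectory`
#' @export
decoding_trajectory <- function(times, mean_acc, sem_acc = NULL,
                                chance = NULL) {
  new_decoding_trajectory(times, mean_acc, sem_acc, chance = chance)
}

#' Time-resolved cross-validated decoding accuracy
#'
#' For every evaluation bin, classifies the two stimulus labels from that
#' bin's (accumulated) features by stratified k-fold cross-validation,
#' repeated over independent Monte-Carlo runs with fresh fold assignments;
#' reports mean and S.E.M. accuracy per bin. With 5 folds each held-out fold
#' is 20% of trials, i.e. an 80/20 train/test split per fold. Fold partitions
#' are shared across bins within a run, and each run has its own seed
#' substream, so increasing `n_mc` never changes earlier runs.
#'
#' @param features a `feature_series`
#' @param labels two-class labels; defaults to the feature series' stimulus
#'   intensities
#' @param spec an [svm_spec()]
#' @param n_mc number of Monte-Carlo repetitions (default 100)
#' @param folds number of CV folds (default 5)
#' @param bins evaluation bin indices (default: every bin)
#' @param seed master seed for fold randomization
#' @param chance optional [chance_level()] result to attach
#' @param train_frac nominal training fraction; must equal `1 - 1/folds`
#' @return a `decoding_trajectory` with `times`, `mean_acc`, `sem_acc`, the
#'   per-run accuracy matrix `acc`, `peak_acc` and `peak_time`
#' @export
decode_trajectory <- function(features, labels = NULL, spec = svm_spec(),
                              n_mc = 100, folds = 5, bins = NULL, seed = 1,
                              chance = NULL, train_frac = 1 - 1 / folds) {
  y <- droplevels(factor(labels %||% features$intensity))
  if (nlevels(y) != 2) stop("exactly two classes are required")
  if (abs(train_frac - (1 - 1 / folds)) > 1e-8) {
    warning("train_frac is determined by the fold count; using 1 - 1/folds")
  }
  bins <- bins %||% seq_along(features$times)
  Xl <- lapply(bins, function(b) feature_matrix(features, b))
  acc <- matrix(0, nrow = length(bins), ncol = n_mc)
  for (r in seq_len(n_mc)) {
    fid <- with_seed(derive_seed(seed, r), stratified_folds(y, folds))
    for (bi in seq_along(bins)) {
      acc[bi, r] <- cv_accuracy(Xl[[bi]], y, spec, fid)
    }
  }
  mean_acc <- rowMeans(acc)
  sem_acc <- if (n_mc > 1) apply(acc, 1, sd) / sqrt(n_mc) else
    rep(0, nrow(acc))
  new_decoding_trajectory(
    times = features$times[bins], mean_acc = mean_acc, sem_acc = sem_acc,
    acc = acc, n_mc = n_mc, folds = folds, chance = chance,
    modality = features$modality
  )
}

#' @export
print.decoding_trajectory <- function(x, ...) {
  cat(sprintf("<decoding_trajectory> %d bins over (%.2f, %.2f] s%s\n",
              length(x$times), min(x$times) - diff(x$times[1:2] %||% c(0, 0)),
              max(x$times),
              if (!is.null(x$modality)) paste0(", ", x$modality) else ""))
  cat(sprintf("  peak accuracy %.3f at %.2f s", x$peak_acc, x$peak_time))
  ch <- normalize_chance(x$chance)
  if (!is.null(ch)) cat(sprintf(", chance %.3f", ch$mean))
  cat("\n")
  invisible(x)
}

#' Permutation chance level of the decoder
#'
#' Randomly permutes the class labels between the two classes, re-runs the
#' stratified cross-validated decoding at one time bin (the final bin by
#' default), and repeats over many shuffles. The mean shuffled accuracy is
#' the chance level (close to 50% for balanced classes); the across-shuffle
#' SD quantifies its spread. The feature matrix itself is never touched.
#'
#' @inheritParams decode_trajectory
#' @param n_shuffle number of label permutations (default 500)
#' @param bin evaluation bin (default: final bin)
#' @return an object of class `chance_level`: list with `mean`, `sd`,
#'   per-shuffle `accuracies`, `n_shuffle`, `bin`, `time`
#' @export
chance_level <- function(features, labels = NULL, spec = svm_spec(),
                         n_shuffle = 500, folds = 5, bin = NULL, seed = 1) {
  y <- droplevels(factor(labels %||% features$intensity))
  if (nlevels(y) != 2) stop("exactly two classes are required")
  bin <- bin %||% length(features$times)
  X <- feature_matrix(features, bin)
  accs <- vapply(seq_len(n_shuffle), function(s) {
    with_seed(derive_seed(seed, 7919, s), {
      yp <- sample(y)
      fid <- stratified_folds(yp, folds)
      cv_accuracy(X, yp, spec, fid)
    })
  }, numeric(1))
  structure(
    list(mean = mean(accs), sd = sd(accs), accuracies = accs,
         n_shuffle = n_shuffle, bin = bin, time = features$times[bin]),
    class = "chance_level"
  )
}

#' @export
print.chance_level <- function(x, ...) {
  cat(sprintf("<chance_level> %.4f (SD %.4f) from %d shuffles at t = %.2f s\n",
              x$mean, x$sd, x$n_shuffle, x$time))
  invisible(x)
}

# Accept a chance_level object, a bare number, or NULL.
normalize_chance <- function(chance) {
  if (is.null(chance)) return(NULL)
  if (inherits(chance, "chance_level")) {
    list(mean = chance$mean, sd = chance$sd)
  } else if (is.numeric(chance) && length(chance) == 1) {
    list(mean = chance, sd = NA_real_)
  } else if (is.list(chance) && !is.null(chance$mean)) {
    list(mean = chance$mean, sd = chance$sd %||% NA_real_)
  } else {
    stop("cannot interpret chance level")
  }
}
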