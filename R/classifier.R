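# RBF-kernel SVM with one-vs-one multiclass decomposition (libsvm via
# e1071), plus Random Forest and Gaussian Naive Bayes baselines trained on
# the same composition features. Features are frequencies in [0, 1] and are
# not rescaled before fitting.

MODEL_BUNDLE_VERSION <- 1L

#' Model configuration
#'
#' Bundles the feature definition (cluster profile and word length) with
#' the learning algorithm and its hyperparameters.
#'
#' @param profile_name Name of the cluster profile the features come from.
#' @param n Word length of the n-peptide composition (1, 2 or 3).
#' @param C SVM regularization parameter (> 0).
#' @param gamma RBF kernel width (> 0); default `NULL` means `1 / D` with
#'   `D` the feature dimension, resolved at fit time.
#' @param algorithm `"svm"` (RBF, one-vs-one), `"random_forest"` or
#'   `"naive_bayes"`.
#' @param class_weights Optional named vector of per-class weights for the
#'   SVM (default none; the reference protocol uses unweighted classes).
#' @param seed Integer seed consumed by the Random Forest baseline and by
#'   stratified fold assignment.
#' @param ntree Number of trees for the Random Forest baseline.
#' @return A list of class `model_config`.
#' @export
model_config <- function(profile_name = "CP8", n = 3, C = 1, gamma = NULL,
                         algorithm = c("svm", "random_forest", "naive_bayes"),
                         class_weights = NULL, seed = 1L, ntree = 500L) {
  algorithm <- match.arg(algorithm)
  n <- check_word_length(n)
  if (!is.numeric(C) || C <= 0) stop("C must be > 0")
  if (!is.null(gamma) && (!is.numeric(gamma) || gamma <= 0))
    stop("gamma must be > 0")
  structure(list(profile_name = profile_name, n = n, C = C, gamma = gamma,
                 algorithm = algorithm, class_weights = class_weights,
                 kernel = "radial", multiclass = "one-vs-one",
                 seed = as.integer(seed), ntree = as.integer(ntree)),
            class = "model_config")
}

check_training_matrix <- function(fm) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (nrow(fm$x) == 0L) stop("empty feature matrix")
  classes <- sort(unique(fm$labels))
  if (length(classes) < 2L)
    stop("training requires at least 2 classes (got ",
         length(classes), ")")
  classes
}

#' Train a classifier on a feature matrix
#'
#' Fits the model named by `config$algorithm`: an RBF-kernel SVM with
#' one-vs-one multiclass decomposition (the default; `k` classes imply
#' `k(k-1)/2` pairwise machines), a Random Forest, or Gaussian Naive Bayes.
#' SVM fitting is deterministic; the Random Forest consumes `config$seed`;
#' Naive Bayes class-conditional standard deviations are floored at `1e-6`
#' so constant-within-class features stay finite.
#'
#' @param fm A `feature_matrix` from [encode_dataset()].
#' @param config A [model_config()].
#' @return An object of class `raaclass_model` holding the fitted machinery,
#'   the class list, the feature names and a training fingerprint.
#' @export
train_model <- function(fm, config = model_config()) {
  stopifnot(inherits(config, "model_config"))
  classes <- check_training_matrix(fm)
  y <- factor(fm$labels, levels = classes)
  gamma <- if (is.null(config$gamma)) 1 / ncol(fm$x) else config$gamma
  fit <- switch(config$algorithm,
    svm = e1071::svm(fm$x, y, kernel = "radial", cost = config$C,
                     gamma = gamma, scale = FALSE,
                     class.weights = config$class_weights),
    random_forest = {
      set.seed(config$seed)
      randomForest::randomForest(fm$x, y, ntree = config$ntree)
    },
    naive_bayes = {
      nb <- e1071::naiveBayes(as.data.frame(fm$x), y)
      nb$tables <- lapply(nb$tables, function(tab) {
        tab[, 2L] <- pmax(tab[, 2L], 1e-6)
        tab
      })
      nb
    })
  cfg <- config
  cfg$gamma <- gamma
  structure(list(version = MODEL_BUNDLE_VERSION,
                 config = cfg,
                 classes = classes,
                 dimension = ncol(fm$x),
                 feature_names = colnames(fm$x),
                 n_train = nrow(fm$x),
                 n_pairwise = choose(length(classes), 2L),
                 fit = fit),
            class = "raaclass_model")
}

#' @export
print.raaclass_model <- function(x, ...) {
  cat("raaclass model (", x$config$algorithm, "): ", length(x$classes),
      " classes, ", x$dimension, " features, trained on ", x$n_train,
      " sequences\n", sep = "")
  if (x$config$algorithm == "svm")
    cat("  RBF one-vs-one, C = ", format(x$config$C), ", gamma = ",
        format(x$config$gamma), ", ", x$n_pairwise,
        " pairwise machines\n", sep = "")
  invisible(x)
}

#' Predict family labels
#'
#' @param object A `raaclass_model`.
#' @param fm A `feature_matrix` (or bare numeric matrix) with the same
#'   feature dimension as the model.
#' @param ... Unused.
#' @return Character vector of predicted labels, one per row, drawn from
#'   the model's class list.
#' @export
predict.raaclass_model <- function(object, fm, ...) {
  x <- if (inherits(fm, "feature_matrix")) fm$x else as.matrix(fm)
  if (nrow(x) == 0L) return(character(0))
  if (ncol(x) != object$dimension)
    stop("feature dimension mismatch: model expects ", object$dimension,
         ", given ", ncol(x))
  if (object$config$algorithm == "naive_bayes") x <- as.data.frame(x)
  as.character(stats::predict(object$fit, x))
}

#' Train a baseline classifier
#'
#' Convenience wrapper around [train_model()] for the Random Forest and
#' Naive Bayes baselines, consuming the same feature matrix as the SVM.
#'
#' @inheritParams train_model
#' @param algorithm `"random_forest"` or `"naive_bayes"`.
#' @param seed Seed for the Random Forest; Naive Bayes is deterministic.
#' @param ntree Number of trees for the Random Forest.
#' @export
train_baseline <- function(fm, algorithm = c("random_forest", "naive_bayes"),
                           seed = 1L, ntree = 500L) {
  algorithm <- match.arg(algorithm)
  cfg <- model_config(profile_name = fm$profile_name, n = fm$n,
                      algorithm = algorithm, seed = seed, ntree = ntree)
  train_model(fm, cfg)
}

# Stratified fold ids (1..folds) in dataset order, seeded. Each class's
# members are shuffled and dealt round-robin; the global RNG stream is left
# untouched.
stratified_folds <- function(labels, folds, seed) {
  fold <- integer(length(labels))
  withr::with_seed(seed, {
    for (cl in sort(unique(labels))) {
      members <- which(labels == cl)
      members <- members[sample.int(length(members))]
      fold[members] <- rep_len(seq_len(folds), length(members))
    }
  })
  fold
}

#' Grid search for SVM hyperparameters
#'
#' Evaluates every (C, gamma) pair by stratified cross-validated overall
#' accuracy and returns the maximizer. Defaults follow the standard libsvm
#' protocol: `C` over `2^-5 ... 2^15` and `gamma` over `2^-15 ... 2^-5`,
#' both in powers of two (exponent step 1), with fivefold cross-validation.
#' Ties are broken toward smaller `C`, then smaller `gamma`. When the
#' smallest class has fewer members than `folds`, the search falls back to
#' leave-one-out so every fold assignment remains valid; a class with fewer
#' than 2 members is an error.
#'
#' @param fm A `feature_matrix`.
#' @param C_grid Numeric vector of candidate `C` values.
#' @param gamma_grid Numeric vector of candidate `gamma` values.
#' @param folds Number of cross-validation folds (default 5).
#' @param seed Seed for the stratified fold assignment.
#' @return List with `C`, `gamma`, `cv_accuracy`, `folds_used` and the full
#'   `grid` (data.frame of all pairs with their CV accuracy).
#' @export
grid_search <- function(fm, C_grid = 2^(-5:15), gamma_grid = 2^(-15:-5),
                        folds = 5L, seed = 1L) {
  classes <- check_training_matrix(fm)
  if (length(C_grid) == 0L || length(gamma_grid) == 0L)
    stop("empty hyperparameter grid")
  sizes <- table(fm$labels)
  if (min(sizes) < 2L)
    stop("class '", names(sizes)[which.min(sizes)], "' has ", min(sizes),
         " member(s); stratified folding needs at least 2 ",
         "(consider merging or dropping the class)")
  n <- nrow(fm$x)
  if (min(sizes) < folds) {
    message("smallest class has ", min(sizes), " < ", folds,
            " members; falling back to leave-one-out within the search")
    fold <- seq_len(n)
    folds <- n
  } else {
    fold <- stratified_folds(fm$labels, folds, seed)
  }
  grid <- expand.grid(C = sort(C_grid), gamma = sort(gamma_grid))
  acc <- numeric(nrow(grid))
  y <- factor(fm$labels, levels = classes)
  for (g in seq_len(nrow(grid))) {
    correct <- 0L
    for (f in sort(unique(fold))) {
      test <- fold == f
      fit <- e1071::svm(fm$x[!test, , drop = FALSE], y[!test],
                        kernel = "radial", cost = grid$C[g],
                        gamma = grid$gamma[g], scale = FALSE)
      pred <- stats::predict(fit, fm$x[test, , drop = FALSE])
      correct <- correct + sum(as.character(pred) == fm$labels[test])
    }
    acc[g] <- correct / n
  }
  # max accuracy; ties toward smaller C then smaller gamma
  ord <- order(-acc, grid$C, grid$gamma)
  best <- ord[1L]
  list(C = grid$C[best], gamma = grid$gamma[best], cv_accuracy = acc[best],
       folds_used = folds,
       grid = cbind(grid, cv_accuracy = acc))
}

#' Save / load a trained model bundle
#'
#' The bundle records a format version, the configuration, class list and
#' feature-name fingerprint alongside the fitted parameters; loading
#' refuses bundles written by an incompatible version.
#'
#' @param model A `raaclass_model`.
#' @param path File path for the bundle.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "raaclass_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "raaclass_model"))
    stop("'", path, "' is not a raaclass model bundle")
  if (!identical(model$version, MODEL_BUNDLE_VERSION))
    stop("model bundle version ", model$version,
         " is incompatible with this package (expects ",
         MODEL_BUNDLE_VERSION, ")")
  model
}
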