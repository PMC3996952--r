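# Cross-validation and per-class performance metrics.
#
# All metrics are one-vs-rest per class: Sn = TP/(TP+FN), Sp = TN/(TN+FP),
# MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)), and overall
# accuracy OA = sum_i TP(i) / N. A metric whose denominator is zero is
# reported as NA (undefined), never silently as 0; the TSV renderer has a
# compatibility mode that prints 0 for such cells.

subset_feature_matrix <- function(fm, i) {
  structure(list(x = fm$x[i, , drop = FALSE], ids = fm$ids[i],
                 labels = fm$labels[i], profile_name = fm$profile_name,
                 n = fm$n, skipped = character(0)),
            class = "feature_matrix")
}

#' One-vs-rest confusion tallies
#'
#' @param truth Character vector of true labels.
#' @param predicted Character vector of predicted labels, same length.
#' @param classes Class list; defaults to the sorted union of labels seen.
#'   Must contain every label and have at least 2 entries.
#' @return An object of class `class_tally`: data.frame with one row per
#'   class (columns `class`, `TP`, `TN`, `FP`, `FN`) plus attributes `N`
#'   (total examples) and `M` (number of classes). For every class,
#'   `TP + FN` equals the class size and `TP + TN + FP + FN == N`.
#' @export
tally <- function(truth, predicted, classes = NULL) {
  truth <- as.character(truth)
  predicted <- as.character(predicted)
  if (length(truth) != length(predicted))
    stop("truth and predicted differ in length (", length(truth), " vs ",
         length(predicted), ")")
  if (length(truth) == 0L) stop("empty label vectors")
  if (is.null(classes)) classes <- sort(unique(c(truth, predicted)))
  unknown <- setdiff(c(truth, predicted), classes)
  if (length(unknown))
    stop("label(s) not in the class list: ", paste(unknown, collapse = ", "))
  if (length(classes) < 2L)
    stop("evaluation requires at least 2 classes")
  out <- data.frame(class = classes,
                    TP = NA_integer_, TN = NA_integer_,
                    FP = NA_integer_, FN = NA_integer_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(classes)) {
    pos_t <- truth == classes[i]
    pos_p <- predicted == classes[i]
    out$TP[i] <- sum(pos_t & pos_p)
    out$TN[i] <- sum(!pos_t & !pos_p)
    out$FP[i] <- sum(!pos_t & pos_p)
    out$FN[i] <- sum(pos_t & !pos_p)
  }
  structure(out, N = length(truth), M = length(classes),
            class = c("class_tally", "data.frame"))
}

binary_mcc <- function(TP, TN, FP, FN) {
  # products as doubles; denominator 0 -> undefined (NA)
  den <- sqrt((TP + FP) * (TP + FN)) * sqrt((TN + FP) * (TN + FN))
  num <- TP * TN - FP * FN
  ifelse(den == 0, NA_real_, num / den)
}

#' Per-class Sn/Sp/MCC and overall accuracy from a tally
#'
#' @param t A `class_tally` from [tally()].
#' @return An object of class `metrics_report`: list with `per_class`
#'   (data.frame: class, TP, TN, FP, FN, Sn, Sp, MCC), `OA`, `N` and `M`.
#'   Undefined metrics (zero denominator) are `NA`.
#' @export
compute_metrics <- function(t) {
  stopifnot(inherits(t, "class_tally"))
  N <- attr(t, "N")
  per <- as.data.frame(t)
  per$Sn <- ifelse(per$TP + per$FN == 0, NA_real_,
                   per$TP / (per$TP + per$FN))
  per$Sp <- ifelse(per$TN + per$FP == 0, NA_real_,
                   per$TN / (per$TN + per$FP))
  per$MCC <- binary_mcc(as.double(per$TP), as.double(per$TN),
                        as.double(per$FP), as.double(per$FN))
  structure(list(per_class = per, OA = sum(per$TP) / N, N = N,
                 M = attr(t, "M"), scheme = NULL, config = NULL),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("Metrics report",
      if (!is.null(x$scheme)) paste0(" (", x$scheme, ")"), ": N = ", x$N,
      ", OA = ", sprintf("%.2f%%", 100 * x$OA), "\n", sep = "")
  per <- x$per_class
  per$Sn <- sprintf("%.2f%%", 100 * per$Sn)
  per$Sp <- sprintf("%.2f%%", 100 * per$Sp)
  per$MCC <- sprintf("%.2f", per$MCC)
  print(per, row.names = FALSE)
  invisible(x)
}

#' Write a metrics report to TSV
#'
#' One row per class with the tallies and metrics, then an `OA` row.
#' `compat = TRUE` prints undefined (NA) metrics as 0, matching the common
#' table convention; the default keeps them as `NA`.
#'
#' @param report A `metrics_report`.
#' @param path Output path.
#' @param compat Print undefined metrics as 0 (default `FALSE`).
#' @param percent Format Sn/Sp/OA as percentages with two decimals
#'   (default `FALSE`: raw fractions).
#' @export
write_report <- function(report, path, compat = FALSE, percent = FALSE) {
  stopifnot(inherits(report, "metrics_report"))
  per <- report$per_class
  if (compat) {
    per$Sn[is.na(per$Sn)] <- 0
    per$Sp[is.na(per$Sp)] <- 0
    per$MCC[is.na(per$MCC)] <- 0
  }
  if (percent) {
    per$Sn <- sprintf("%.2f%%", 100 * per$Sn)
    per$Sp <- sprintf("%.2f%%", 100 * per$Sp)
    per$MCC <- sprintf("%.2f", per$MCC)
    oa <- sprintf("%.2f%%", 100 * report$OA)
  } else oa <- format(report$OA, digits = 15)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# raaclass metrics",
                    if (!is.null(report$scheme))
                      paste0("\tscheme=", report$scheme),
                    "\tN=", report$N), con)
  utils::write.table(per, con, sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(paste0("OA\t", oa), con)
  invisible(path)
}

#' @rdname write_report
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "metrics_report"))
  jsonlite::write_json(
    list(scheme = report$scheme, N = report$N, M = report$M,
         OA = report$OA, per_class = report$per_class),
    path, auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE)
  invisible(path)
}

prepare_eval <- function(dataset, config, policy, min_class = 2L) {
  stopifnot(inherits(dataset, "labeled_dataset"),
            inherits(config, "model_config"))
  sizes <- table(dataset$records$label)
  if (length(sizes) < 2L) stop("evaluation requires at least 2 classes")
  if (min(sizes) < min_class)
    stop("class '", names(sizes)[which.min(sizes)], "' has ", min(sizes),
         " member(s); every class needs at least ", min_class)
  encode_dataset(dataset, config$profile_name, config$n, policy = policy)
}

finish_eval <- function(fm, predicted, scheme, config) {
  report <- compute_metrics(tally(fm$labels, predicted,
                                  classes = sort(unique(fm$labels))))
  report$scheme <- scheme
  report$config <- config
  list(report = report,
       predictions = data.frame(id = fm$ids, truth = fm$labels,
                                predicted = predicted,
                                stringsAsFactors = FALSE))
}

#' Jackknife (leave-one-out) cross-validation
#'
#' Each sequence is in turn held out and predicted by a model trained on
#' all the others; hyperparameters are taken from `config` and held fixed
#' across all N rounds (select them beforehand with [grid_search()]; note
#' that selecting on the full dataset and then jackknifing carries a mild
#' optimistic bias). The run is deterministic given the config.
#'
#' @param dataset A [labeled_dataset] with >= 2 classes, each with >= 2
#'   members.
#' @param config A [model_config()] naming the profile, word length and
#'   algorithm.
#' @param policy Non-canonical residue policy, see [reduce_sequence()].
#' @return List with `report` (a `metrics_report` over the N held-out
#'   predictions) and `predictions` (data.frame: id, truth, predicted).
#' @export
jackknife <- function(dataset, config = model_config(), policy = "mask") {
  fm <- prepare_eval(dataset, config, policy)
  n <- nrow(fm$x)
  predicted <- character(n)
  for (i in seq_len(n)) {
    model <- train_model(subset_feature_matrix(fm, -i), config)
    predicted[i] <- predict(model, subset_feature_matrix(fm, i))
  }
  finish_eval(fm, predicted, "jackknife", config)
}

#' Stratified k-fold cross-validation
#'
#' Folds are stratified by class and seeded. `k` equal to the dataset size
#' is the leave-one-out limit and is routed through [jackknife()];
#' otherwise `k` may not exceed the smallest class size.
#'
#' @inheritParams jackknife
#' @param k Number of folds.
#' @param seed Seed for the fold assignment.
#' @return As [jackknife()].
#' @export
kfold <- function(dataset, config = model_config(), k = 5L, seed = 1L,
                  policy = "mask") {
  stopifnot(inherits(dataset, "labeled_dataset"))
  n <- nrow(dataset$records)
  if (k == n) return(jackknife(dataset, config, policy = policy))
  fm <- prepare_eval(dataset, config, policy, min_class = 2L)
  sizes <- table(fm$labels)
  if (k < 2L) stop("k must be at least 2")
  if (k > min(sizes))
    stop("k = ", k, " exceeds the smallest class size (", min(sizes), ")")
  fold <- stratified_folds(fm$labels, k, seed)
  predicted <- character(nrow(fm$x))
  for (f in seq_len(k)) {
    test <- fold == f
    model <- train_model(subset_feature_matrix(fm, !test), config)
    predicted[test] <- predict(model, subset_feature_matrix(fm, test))
  }
  finish_eval(fm, predicted, sprintf("%d-fold", k), config)
}
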