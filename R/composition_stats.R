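# Composition analyses: per-residue one-way ANOVA across families with
# Fisher's LSD post hoc pairwise comparisons, and binomial tests for
# over-represented reduced n-peptides within a family.
#
# Neither analysis applies a multiple-testing correction: LSD is by
# definition uncorrected (pairwise tests are only run for residues whose
# ANOVA is already significant), and the enrichment confidence 1 - p is a
# per-word quantity. Treat the outputs as descriptive screens.

#' Per-sequence and per-class amino acid composition
#'
#' Frequencies of the 20 canonical residues per sequence (non-canonical
#' symbols are excluded from both numerator and denominator) and their
#' class means.
#'
#' @param dataset A [labeled_dataset].
#' @return An object of class `composition_table`: list with `freq`
#'   (numeric matrix, one row per sequence, 20 columns, rows sum to 1),
#'   `labels`, `class_means` (classes x 20), `class_sizes`.
#' @export
class_composition <- function(dataset) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  n <- nrow(dataset$records)
  freq <- matrix(0, nrow = n, ncol = length(CANONICAL_AA),
                 dimnames = list(dataset$records$id, CANONICAL_AA))
  keep <- rep.int(TRUE, n)
  for (i in seq_len(n)) {
    chars <- strsplit(toupper(dataset$records$sequence[i]), "",
                      fixed = TRUE)[[1]]
    chars <- chars[chars %in% CANONICAL_AA]
    if (length(chars) == 0L) {
      keep[i] <- FALSE
      next
    }
    counts <- table(factor(chars, levels = CANONICAL_AA))
    freq[i, ] <- as.numeric(counts) / length(chars)
  }
  if (any(!keep)) {
    warning("skipped ", sum(!keep), " sequence(s) with no canonical ",
            "residues: ",
            paste(dataset$records$id[!keep], collapse = ", "))
    freq <- freq[keep, , drop = FALSE]
  }
  labels <- dataset$records$label[keep]
  classes <- sort(unique(labels))
  means <- t(vapply(classes,
                    function(cl) colMeans(freq[labels == cl, , drop = FALSE]),
                    numeric(ncol(freq))))
  rownames(means) <- classes
  structure(list(freq = freq, labels = labels, class_means = means,
                 class_sizes = table(labels)),
            class = "composition_table")
}

#' Compare residue frequencies across classes (ANOVA + Fisher's LSD)
#'
#' For each of the 20 residues, a one-way ANOVA on the per-sequence
#' frequencies across classes; where the ANOVA p-value is below `alpha`,
#' all ordered class pairs are compared by Fisher's least significant
#' difference test (pairwise t statistics using the pooled within-group
#' mean square on its `N - k` degrees of freedom, uncorrected). A pairwise
#' verdict is `enriched_in_first` or `enriched_in_second` following the
#' sign of the mean difference, `not_significant` otherwise; verdicts are
#' only assigned for residues whose ANOVA passed.
#'
#' @param table A `composition_table` from [class_composition()].
#' @param alpha Significance level for both stages (default 0.05).
#' @return An object of class `enrichment_matrix`: list with `anova_p`
#'   (named vector, `NA` when the ANOVA is undefined, e.g. zero variance
#'   everywhere), `pairs` (data.frame `first`/`second`), `verdicts`
#'   (character matrix, residues x pairs), `pair_p` (matrix of LSD
#'   p-values), `class_means` and `alpha`.
#' @export
anova_lsd <- function(table, alpha = 0.05) {
  stopifnot(inherits(table, "composition_table"))
  labels <- factor(table$labels)
  classes <- levels(labels)
  if (length(classes) < 2L) stop("need at least 2 classes")
  sizes <- table(labels)
  if (min(sizes) < 2L)
    stop("class '", names(sizes)[which.min(sizes)],
         "' has fewer than 2 members")
  pairs <- t(utils::combn(classes, 2L))
  pair_names <- paste(pairs[, 1], pairs[, 2], sep = "-")
  residues <- colnames(table$freq)
  anova_p <- stats::setNames(rep(NA_real_, length(residues)), residues)
  verdicts <- matrix("not_significant", nrow = length(residues),
                     ncol = nrow(pairs),
                     dimnames = list(residues, pair_names))
  pair_p <- matrix(NA_real_, nrow = length(residues), ncol = nrow(pairs),
                   dimnames = list(residues, pair_names))
  N <- length(labels)
  df_within <- N - length(classes)
  for (r in residues) {
    y <- table$freq[, r]
    group_means <- tapply(y, labels, mean)
    sse <- sum((y - group_means[labels])^2)
    if (sse == 0 && stats::var(y) == 0) next   # flat residue: undefined
    fit <- stats::aov(y ~ labels)
    anova_p[r] <- summary(fit)[[1]][["Pr(>F)"]][1]
    if (is.na(anova_p[r]) || anova_p[r] >= alpha) next
    mse <- sse / df_within
    for (j in seq_len(nrow(pairs))) {
      a <- pairs[j, 1]; b <- pairs[j, 2]
      se <- sqrt(mse * (1 / sizes[[a]] + 1 / sizes[[b]]))
      diff <- group_means[[a]] - group_means[[b]]
      if (se == 0) {        # zero pooled variance: any difference is exact
        if (diff == 0) next
        tstat <- sign(diff) * Inf
        p <- 0
      } else {
        tstat <- diff / se
        p <- 2 * stats::pt(-abs(tstat), df_within)
      }
      pair_p[r, j] <- p
      if (p < alpha)
        verdicts[r, j] <- if (tstat > 0) "enriched_in_first"
                          else "enriched_in_second"
    }
  }
  structure(list(anova_p = anova_p,
                 pairs = data.frame(first = pairs[, 1], second = pairs[, 2],
                                    stringsAsFactors = FALSE),
                 verdicts = verdicts, pair_p = pair_p,
                 class_means = table$class_means, alpha = alpha),
            class = "enrichment_matrix")
}

#' Write an ANOVA/LSD verdict matrix to TSV
#'
#' Three-state table (residues x class pairs) mirroring the usual
#' composition-comparison heatmap, with the ANOVA p-value as a column.
#'
#' @param em An `enrichment_matrix`.
#' @param path Output path.
#' @export
write_composition_matrix <- function(em, path) {
  stopifnot(inherits(em, "enrichment_matrix"))
  df <- data.frame(residue = rownames(em$verdicts),
                   anova_p = unname(em$anova_p[rownames(em$verdicts)]),
                   em$verdicts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# raaclass composition\talpha=", em$alpha), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Upper-tail binomial probability
#'
#' `P(X >= m)` for `X ~ Binomial(size, prob)`, the p-value of the
#' over-representation test.
#'
#' @param m Observed count.
#' @param size Number of trials.
#' @param prob Success probability.
#' @return Numeric probability.
#' @export
binom_upper_p <- function(m, size, prob) {
  stats::pbinom(m - 1, size, prob, lower.tail = FALSE)
}

#' Over-represented reduced n-peptides per class
#'
#' For each class `c` and reduced word `t`, tests whether the count `m` of
#' `t` among the `M_c` windows of class `c` exceeds the binomial
#' expectation under a background probability `q_t`: the one-sided p-value
#' is `P(X >= m)` for `X ~ Binomial(M_c, q_t)`, and a word is reported when
#' its confidence `1 - p` exceeds `confidence_threshold`.
#'
#' The default background is the pooled frequency of `t` over the whole
#' dataset's windows; `background = "uniform"` uses `1 / D` instead. Use
#' profile `"CP20"` to test native (unreduced) n-peptides.
#'
#' @param dataset A [labeled_dataset].
#' @param profile A [cluster_profile] or built-in profile name.
#' @param n Word length, one of 1, 2, 3.
#' @param confidence_threshold Minimum confidence `1 - p` for a word to be
#'   reported (default 0.999).
#' @param background `"pooled"` (default) or `"uniform"`.
#' @param policy Non-canonical residue policy, see [reduce_sequence()].
#' @return data.frame of class `enrichment_results` with columns `class`,
#'   `word` (cluster-index tuple), `observed`, `class_windows`,
#'   `background_q`, `p_value`, `confidence`, sorted by confidence
#'   descending, then class, then word.
#' @export
binomial_enrichment <- function(dataset, profile, n,
                                confidence_threshold = 0.999,
                                background = c("pooled", "uniform"),
                                policy = "mask") {
  stopifnot(inherits(dataset, "labeled_dataset"))
  background <- match.arg(background)
  if (!is.numeric(confidence_threshold) || confidence_threshold <= 0 ||
      confidence_threshold >= 1)
    stop("confidence_threshold must be in (0, 1)")
  profile <- get_profile(profile)
  n <- check_word_length(n)
  D <- feature_dimension(profile, n)
  classes <- sort(unique(dataset$records$label))
  counts <- matrix(0, nrow = length(classes), ncol = D,
                   dimnames = list(classes, feature_names(profile, n)))
  windows <- stats::setNames(numeric(length(classes)), classes)
  for (i in seq_len(nrow(dataset$records))) {
    red <- reduce_sequence(dataset$records$sequence[i], profile,
                           policy = policy, id = dataset$records$id[i])
    nc <- npeptide_counts(red, profile$size, n)
    cl <- dataset$records$label[i]
    counts[cl, ] <- counts[cl, ] + nc$counts
    windows[cl] <- windows[cl] + nc$windows
  }
  total_windows <- sum(windows)
  if (total_windows == 0) stop("dataset yields no valid windows for n = ", n)
  q <- if (background == "uniform") rep(1 / D, D)
       else colSums(counts) / total_windows
  rows <- list()
  for (cl in classes) {
    m <- counts[cl, ]
    testable <- q > 0 & q < 1
    p <- rep(1, D)
    p[testable] <- binom_upper_p(m[testable], windows[[cl]], q[testable])
    hit <- (1 - p) > confidence_threshold
    if (any(hit)) {
      rows[[cl]] <- data.frame(class = cl,
                               word = colnames(counts)[hit],
                               observed = as.integer(m[hit]),
                               class_windows = as.integer(windows[[cl]]),
                               background_q = unname(q[hit]),
                               p_value = unname(p[hit]),
                               confidence = unname(1 - p[hit]),
                               stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(class = character(0), word = character(0),
                         observed = integer(0), class_windows = integer(0),
                         background_q = numeric(0), p_value = numeric(0),
                         confidence = numeric(0), stringsAsFactors = FALSE)
  out <- out[order(-out$confidence, out$class, out$word), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "profile_name") <- profile$name
  attr(out, "n") <- n
  attr(out, "background") <- background
  class(out) <- c("enrichment_results", "data.frame")
  out
}

#' Write enrichment results to TSV
#'
#' @param results An `enrichment_results` data.frame from
#'   [binomial_enrichment()].
#' @param path Output path.
#' @export
write_enrichment <- function(results, path) {
  stopifnot(inherits(results, "enrichment_results"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# raaclass enrichment\tprofile=",
                    attr(results, "profile_name"),
                    "\tn=", attr(results, "n"),
                    "\tbackground=", attr(results, "background")), con)
  utils::write.table(as.data.frame(results), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
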