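# n-peptide composition over a reduced alphabet.
#
# A sequence of length L yields L - n + 1 sliding windows; each window maps
# to one of k^n reduced words, and the feature vector is the vector of word
# frequencies f_i = N_i / W where W is the number of valid windows. For a
# clean (all-canonical) sequence W = L - n + 1; masked positions remove the
# windows that would span them, and W counts only the surviving windows so
# the frequencies remain a probability distribution.

#' Feature vector dimension
#'
#' Number of distinct n-peptides over the reduced alphabet of `profile`,
#' i.e. `k^n` for a profile with `k` clusters.
#'
#' @param profile A [cluster_profile] or built-in profile name.
#' @param n Word length, one of 1, 2, 3.
#' @return Integer `k^n`.
#' @examples
#' feature_dimension("CP8", 3)   # 512
#' feature_dimension("CP13", 2)  # 169
#' @export
feature_dimension <- function(profile, n) {
  profile <- get_profile(profile)
  n <- check_word_length(n)
  as.integer(profile$size^n)
}

check_word_length <- function(n) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n != as.integer(n) ||
      !(n %in% 1:3))
    stop("word length n must be 1, 2 or 3 (got ",
         paste(format(n), collapse = ","), ")")
  as.integer(n)
}

#' Names of the reduced words in feature order
#'
#' Feature order is lexicographic over 0-based cluster indices with the
#' first (leftmost) window position most significant; names spell the index
#' tuple with `.` separators, e.g. `"0.2.7"`.
#'
#' @inheritParams feature_dimension
#' @return Character vector of length `k^n`.
#' @export
feature_names <- function(profile, n) {
  profile <- get_profile(profile)
  n <- check_word_length(n)
  k <- profile$size
  grids <- rev(lapply(seq_len(n), function(i) 0:(k - 1)))
  g <- do.call(expand.grid, grids)        # last column varies slowest
  apply(as.matrix(g[, rev(seq_len(n)), drop = FALSE]), 1L, paste,
        collapse = ".")
}

# Window counts for a reduced sequence: integer vector of length k^n plus
# the number of valid windows. A window is valid when it does not span a
# recorded mask break.
npeptide_counts <- function(reduced, k, n) {
  idx <- reduced$indices
  L <- length(idx)
  D <- as.integer(k^n)
  counts <- integer(D)
  nwin <- L - n + 1L
  if (nwin < 1L) return(list(counts = counts, windows = 0L))
  # word code of the window starting at s, most significant position first
  code <- integer(nwin)
  for (j in seq_len(n)) {
    code <- code + idx[j:(j + nwin - 1L)] * k^(n - j)
  }
  valid <- rep.int(TRUE, nwin)
  for (b in reduced$breaks) {
    lo <- max(1L, b - n + 2L)
    hi <- min(nwin, b)
    if (lo <= hi) valid[lo:hi] <- FALSE
  }
  code <- code[valid]
  if (length(code)) {
    tab <- tabulate(code + 1L, nbins = D)
    counts <- as.integer(tab)
  }
  list(counts = counts, windows = length(code))
}

#' n-peptide composition of one sequence
#'
#' Computes the frequency vector of all `k^n` reduced words in a protein
#' sequence: `f_i = N_i / W`, `N_i` the count of windows equal to word `i`
#' and `W` the number of valid windows (`L - n + 1` for an all-canonical
#' sequence).
#'
#' @inheritParams reduce_sequence
#' @param n Word length, one of 1, 2, 3.
#' @return An object of class `feature_vector`: list with `profile_name`,
#'   `n`, `values` (named numeric, sums to 1), `counts`, `windows`,
#'   `dimension` and `source_length`.
#' @examples
#' fv <- npeptide_composition("GAG", "CP5", n = 2)
#' fv$values[fv$values > 0]
#' @export
npeptide_composition <- function(sequence, profile, n,
                                 policy = c("mask", "strict"), id = NULL) {
  profile <- get_profile(profile)
  n <- check_word_length(n)
  reduced <- if (inherits(sequence, "reduced_sequence")) sequence
             else reduce_sequence(sequence, profile, match.arg(policy), id = id)
  if (reduced$profile_name != profile$name)
    stop("reduced sequence was built with profile '", reduced$profile_name,
         "', not '", profile$name, "'")
  nc <- npeptide_counts(reduced, profile$size, n)
  if (nc$windows == 0L)
    stop("sequence '", if (is.null(id)) "<sequence>" else id,
         "' has no valid window of length n = ", n)
  values <- nc$counts / nc$windows
  names(values) <- feature_names(profile, n)
  structure(list(profile_name = profile$name, n = n, values = values,
                 counts = nc$counts, windows = nc$windows,
                 dimension = length(values),
                 source_length = reduced$length),
            class = "feature_vector")
}

#' Encode a labeled dataset as a feature matrix
#'
#' One row of n-peptide composition per sequence, rows in dataset order.
#'
#' @param dataset A [labeled_dataset].
#' @param profile A [cluster_profile] or built-in profile name.
#' @param n Word length, one of 1, 2, 3.
#' @param policy Non-canonical residue policy, see [reduce_sequence()].
#' @param on_error `"stop"` (default) re-raises any per-sequence failure
#'   with the sequence id attached; `"skip"` drops the failing sequence and
#'   records it in the `skipped` field with a warning.
#' @return An object of class `feature_matrix`: list with `x` (numeric
#'   matrix, one row per sequence, `k^n` columns named by reduced word),
#'   `ids`, `labels`, `profile_name`, `n`, and `skipped` (character vector
#'   of dropped ids, possibly empty).
#' @export
encode_dataset <- function(dataset, profile, n, policy = c("mask", "strict"),
                           on_error = c("stop", "skip")) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  profile <- get_profile(profile)
  n <- check_word_length(n)
  policy <- match.arg(policy)
  on_error <- match.arg(on_error)
  D <- feature_dimension(profile, n)
  rows <- vector("list", nrow(dataset$records))
  ok <- rep.int(TRUE, length(rows))
  for (i in seq_along(rows)) {
    id <- dataset$records$id[i]
    res <- tryCatch(
      npeptide_composition(dataset$records$sequence[i], profile, n,
                           policy = policy, id = id),
      error = function(e) e)
    if (inherits(res, "error")) {
      if (on_error == "stop") stop(conditionMessage(res), call. = FALSE)
      ok[i] <- FALSE
    } else rows[[i]] <- res$values
  }
  skipped <- dataset$records$id[!ok]
  if (length(skipped))
    warning("skipped ", length(skipped), " sequence(s): ",
            paste(skipped, collapse = ", "))
  x <- do.call(rbind, rows[ok])
  if (is.null(x)) x <- matrix(numeric(0), nrow = 0L, ncol = D,
                              dimnames = list(NULL, feature_names(profile, n)))
  rownames(x) <- dataset$records$id[ok]
  structure(list(x = x,
                 ids = dataset$records$id[ok],
                 labels = dataset$records$label[ok],
                 profile_name = profile$name, n = n,
                 skipped = skipped),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("Feature matrix: ", nrow(x$x), " sequence(s) x ", ncol(x$x),
      " reduced ", x$n, "-peptides (profile ", x$profile_name, ")\n",
      sep = "")
  if (length(x$skipped)) cat("  skipped:", length(x$skipped), "sequence(s)\n")
  invisible(x)
}

#' Write a feature matrix to TSV
#'
#' Columns: `id`, `label`, then one column per reduced word named by its
#' cluster-index tuple (e.g. `0.2.7`). A `#`-prefixed header line records
#' the profile and word length.
#'
#' @param fm A `feature_matrix`.
#' @param path Output path.
#' @export
write_features <- function(fm, path) {
  stopifnot(inherits(fm, "feature_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# raaclass features\tprofile=", fm$profile_name,
                    "\tn=", fm$n), con)
  df <- data.frame(id = fm$ids, label = fm$labels, check.names = FALSE)
  df <- cbind(df, as.data.frame(fm$x, check.names = FALSE))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a feature matrix written by [write_features()]
#'
#' @param path Path to the TSV file.
#' @return A `feature_matrix`.
#' @export
read_features <- function(path) {
  # leading comment lines may include a CLI stamp before the format header
  head <- readLines(path, n = 10L)
  header <- grep("^# raaclass features", head, value = TRUE)
  if (length(header) == 0L)
    stop("'", path, "' is not a raaclass feature TSV")
  kv <- strsplit(strsplit(header[1], "\t", fixed = TRUE)[[1]][-1], "=",
                 fixed = TRUE)
  meta <- stats::setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                          colClasses = "character")
  x <- as.matrix(df[, -(1:2), drop = FALSE])
  storage.mode(x) <- "double"
  rownames(x) <- df$id
  structure(list(x = x, ids = df$id, labels = df$label,
                 profile_name = unname(meta[["profile"]]),
                 n = as.integer(meta[["n"]]), skipped = character(0)),
            class = "feature_matrix")
}
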