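# Shared fixtures and independent oracles for the test suite.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Brute-force n-peptide counting oracle, independent of the package's
# counting path: walk the raw character sequence, split at non-canonical
# symbols, map each residue to its cluster by scanning the cluster strings,
# and tally window words in a named list.
oracle_counts <- function(sequence, profile, n) {
  cluster_strings <- vapply(profile$clusters, paste, "", collapse = "")
  map_residue <- function(ch) {
    for (i in seq_along(cluster_strings)) {
      if (grepl(ch, cluster_strings[i], fixed = TRUE)) return(i - 1L)
    }
    NA_integer_
  }
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  idx <- vapply(chars, map_residue, 1L)
  # segments between non-canonical symbols
  segs <- split(idx[!is.na(idx)], cumsum(is.na(idx))[!is.na(idx)])
  tallies <- new.env()
  total <- 0L
  for (seg in segs) {
    if (length(seg) < n) next
    for (s in seq_len(length(seg) - n + 1L)) {
      word <- paste(seg[s:(s + n - 1L)], collapse = ".")
      prev <- if (is.null(tallies[[word]])) 0L else tallies[[word]]
      tallies[[word]] <- prev + 1L
      total <- total + 1L
    }
  }
  list(counts = as.list(tallies), windows = total)
}

# Random protein-ish string, optionally with non-canonical symbols mixed in.
random_protein <- function(len, extra = character(0)) {
  paste(sample(c(AA20, extra), len, replace = TRUE), collapse = "")
}

# Four classes over disjoint residue alphabets: trivially separable by
# composition under any profile that keeps the groups apart (CP20 always).
separable_dataset <- function(per_class = 8L, len = 60L, seed = 42L) {
  pools <- list(I = c("A", "L"), II = c("I", "V"),
                III = c("N", "D"), IV = c("G", "P"))
  withr::with_seed(seed, {
    ids <- character(0); seqs <- character(0); labs <- character(0)
    for (cl in names(pools)) {
      for (i in seq_len(per_class)) {
        ids <- c(ids, sprintf("%s_%02d", cl, i))
        seqs <- c(seqs, paste(sample(pools[[cl]], len, replace = TRUE),
                              collapse = ""))
        labs <- c(labs, cl)
      }
    }
    labeled_dataset(ids, seqs, labs)
  })
}

# Tally -> expanded truth/prediction indicator vectors; Pearson correlation
# of the indicators is the textbook binary MCC.
mcc_by_correlation <- function(TP, TN, FP, FN) {
  truth <- c(rep(1, TP), rep(1, FN), rep(0, FP), rep(0, TN))
  pred  <- c(rep(1, TP), rep(0, FN), rep(1, FP), rep(0, TN))
  suppressWarnings(stats::cor(truth, pred))
}

expect_close <- function(x, y, tol = 1e-12) {
  expect_true(all(abs(x - y) <= tol),
              label = paste0("max |diff| = ", max(abs(x - y))))
}
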