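test_that("feature dimensions are k^n for every profile and word length", {
  dims <- data.frame(
    profile = rep(c("CP20", "CP13", "CP11", "CP9", "CP8", "CP5"), each = 3),
    n = rep(1:3, times = 6),
    D = c(20L, 400L, 8000L,
          13L, 169L, 2197L,
          11L, 121L, 1331L,
          9L, 81L, 729L,
          8L, 64L, 512L,
          5L, 25L, 125L))
  for (i in seq_len(nrow(dims))) {
    expect_identical(feature_dimension(dims$profile[i], dims$n[i]),
                     dims$D[i])
  }
  expect_error(feature_dimension("CP8", 4), "must be 1, 2 or 3")
  expect_error(feature_dimension("CP8", 0), "must be 1, 2 or 3")
})

test_that("feature order is lexicographic, leftmost position most significant", {
  nm <- feature_names("CP5", 2)
  expect_length(nm, 25L)
  expect_identical(nm[1:6], c("0.0", "0.1", "0.2", "0.3", "0.4", "1.0"))
  # "GF" under CP8: G -> 0, F -> 2, word 0.2 sits at position 0*8 + 2 + 1
  fv <- npeptide_composition("GF", "CP8", n = 2)
  expect_identical(unname(which(fv$values > 0)),
                   which(names(fv$values) == "0.2"))
  expect_identical(unname(which(fv$values > 0)), 3L)
})

test_that("homopolymer composition is a point mass with W = L - n + 1", {
  fv <- npeptide_composition("AAAAA", "CP8", n = 3)
  expect_identical(fv$windows, 3L)
  expect_identical(fv$dimension, 512L)
  expect_identical(unname(fv$values[["3.3.3"]]), 1)
  expect_identical(sum(fv$values > 0), 1L)
})

test_that("dipeptide windows of GAG under CP5 split evenly", {
  fv <- npeptide_composition("GAG", "CP5", n = 2)
  hits <- fv$values[fv$values > 0]
  expect_identical(sort(names(hits)), c("0.2", "2.0"))
  expect_equal(unname(hits[["0.2"]]), 0.5)
  expect_equal(unname(hits[["2.0"]]), 0.5)
})

test_that("composition is invariant to repeating the sequence (n = 1)", {
  a <- npeptide_composition("GFA", "CP8", n = 1)
  b <- npeptide_composition("GFAGFA", "CP8", n = 1)
  expect_equal(a$values, b$values)
})

test_that("counts match the brute-force window oracle on random sequences", {
  profs <- builtin_profiles()
  withr::with_seed(303, {
    for (rep in 1:25) {
      s <- random_protein(sample(5:50, 1),
                          extra = if (rep %% 3 == 0) c("X", "B") else
                            character(0))
      for (p in profs[c("CP20", "CP8", "CP5")]) {
        for (n in 1:3) {
          oracle <- oracle_counts(s, p, n)
          if (oracle$windows == 0) {
            expect_error(npeptide_composition(s, p, n), "no valid window")
            next
          }
          fv <- npeptide_composition(s, p, n)
          expect_identical(fv$windows, oracle$windows)
          for (w in names(oracle$counts)) {
            expect_identical(fv$counts[[which(names(fv$values) == w)]],
                             oracle$counts[[w]])
          }
          expect_identical(sum(fv$counts), oracle$windows)
        }
      }
    }
  })
})

test_that("frequencies are a probability distribution", {
  withr::with_seed(7, {
    for (rep in 1:15) {
      s <- random_protein(sample(3:60, 1))
      fv <- npeptide_composition(s, "CP9", sample(1:3, 1))
      expect_true(all(fv$values >= 0))
      expect_lt(abs(sum(fv$values) - 1), 1e-9)
    }
  })
})

test_that("masking removes windows that would span a masked position", {
  # AXA: two length-1 windows survive, no dipeptide window
  fv <- npeptide_composition("AXA", "CP8", n = 1)
  expect_identical(fv$windows, 2L)
  expect_error(npeptide_composition("AXA", "CP8", n = 2), "no valid window")
  # AAXAA: dipeptide windows only within each segment
  fv2 <- npeptide_composition("AAXAA", "CP8", n = 2)
  expect_identical(fv2$windows, 2L)
  expect_identical(unname(fv2$values[["3.3"]]), 1)
})

test_that("the concatenation of all reduced words touches every coordinate", {
  for (pname in c("CP5", "CP8")) {
    p <- get_profile(pname)
    reps <- vapply(p$clusters, `[`, "", 1L)   # one residue per cluster
    for (n in 1:2) {
      words <- expand.grid(rep(list(seq_len(p$size)), n))
      seq <- paste(apply(as.matrix(words[, rev(seq_len(n)), drop = FALSE]),
                         1L, function(w) paste(reps[w], collapse = "")),
                   collapse = "")
      fv <- npeptide_composition(seq, p, n)
      expect_true(all(fv$counts > 0))
      expect_identical(fv$dimension, feature_dimension(p, n))
    }
  }
})

test_that("encode_dataset keeps dataset order and labels", {
  ds <- separable_dataset(per_class = 3L, len = 30L)
  fm <- encode_dataset(ds, "CP5", 1)
  expect_identical(fm$ids, ds$records$id)
  expect_identical(fm$labels, ds$records$label)
  expect_identical(dim(fm$x), c(12L, 5L))
  expect_close(rowSums(fm$x), rep(1, 12), tol = 1e-9)
  # permuting the dataset permutes rows identically
  perm <- c(5L, 1L, 12L, 7L, 3L, 9L, 2L, 11L, 4L, 8L, 6L, 10L)
  ds2 <- labeled_dataset(ds$records$id[perm], ds$records$sequence[perm],
                         ds$records$label[perm])
  fm2 <- encode_dataset(ds2, "CP5", 1)
  expect_identical(fm2$x, fm$x[perm, ])
})

test_that("skip mode drops failing sequences and records them", {
  ds <- labeled_dataset(c("a", "b", "c", "d"),
                        c("ALMA", "XXXX", "EKEK", "NDND"),
                        c("I", "I", "II", "II"))
  expect_error(encode_dataset(ds, "CP8", 1), "'b'")
  expect_warning(fm <- encode_dataset(ds, "CP8", 1, on_error = "skip"),
                 "skipped 1")
  expect_identical(fm$ids, c("a", "c", "d"))
  expect_identical(fm$skipped, "b")
  expect_identical(nrow(fm$x), 3L)
})

test_that("feature matrices round-trip through TSV", {
  ds <- separable_dataset(per_class = 2L, len = 25L)
  fm <- encode_dataset(ds, "CP8", 2)
  path <- tempfile(fileext = ".tsv")
  write_features(fm, path)
  back <- read_features(path)
  expect_identical(back$ids, fm$ids)
  expect_identical(back$labels, fm$labels)
  expect_identical(back$profile_name, fm$profile_name)
  expect_identical(back$n, fm$n)
  expect_equal(back$x, fm$x, tolerance = 1e-12)
  expect_error(read_features(system.file("extdata", "cluster_profiles.tsv",
                                         package = "raaclass")),
               "not a raaclass feature")
})
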