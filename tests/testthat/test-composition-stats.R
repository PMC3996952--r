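test_that("per-sequence composition uses canonical-only denominators", {
  ds <- labeled_dataset(c("s1", "s2", "s3", "s4"),
                        c("AC", "ACXB", "GGGG", "GGGG"),
                        c("a", "a", "b", "b"))
  ct <- class_composition(ds)
  expect_equal(unname(ct$freq["s1", c("A", "C")]), c(0.5, 0.5))
  expect_equal(unname(ct$freq["s2", c("A", "C")]), c(0.5, 0.5))  # X,B dropped
  expect_close(rowSums(ct$freq), rep(1, 4), tol = 1e-12)
  # a class of identical sequences has the member row as its mean
  expect_equal(ct$class_means["b", ], ct$freq["s3", ])
})

test_that("sequences with no canonical residues are skipped with a warning", {
  ds <- labeled_dataset(c("ok1", "bad", "ok2", "ok3"),
                        c("ACAC", "XXXX", "GGGG", "ACGT"),
                        c("a", "a", "b", "b"))
  expect_warning(ct <- class_composition(ds), "bad")
  expect_identical(nrow(ct$freq), 3L)
})

test_that("identical groups yield no significant residues", {
  base <- withr::with_seed(5, replicate(6, random_protein(80)))
  ds <- labeled_dataset(paste0("s", 1:12), c(base, base),
                        rep(c("g1", "g2"), each = 6))
  em <- anova_lsd(class_composition(ds), alpha = 0.05)
  expect_true(all(em$verdicts == "not_significant"))
})

test_that("a planted composition shift is declared enriched in its class", {
  spec <- generator_spec(c(up = 25L, bg1 = 25L, bg2 = 25L),
                         length_range = c(150L, 250L),
                         bias = list(up = c(G = 0.05)), seed = 31L)
  ds <- generate_dataset(spec)
  em <- anova_lsd(class_composition(ds), alpha = 0.05)
  expect_lt(em$anova_p[["G"]], 0.05)
  g_pairs <- grepl("up", colnames(em$verdicts))
  verdicts <- em$verdicts["G", g_pairs]
  # "up" sorts after bg1/bg2, so it is the second member of each pair
  expect_true(all(verdicts == "enriched_in_second"))
  # verdict direction always follows the class-mean ordering
  for (j in seq_len(nrow(em$pairs))) {
    for (r in rownames(em$verdicts)) {
      v <- em$verdicts[r, j]
      if (v == "not_significant") next
      d <- em$class_means[em$pairs$first[j], r] -
           em$class_means[em$pairs$second[j], r]
      expect_identical(v, if (d > 0) "enriched_in_first"
                          else "enriched_in_second")
    }
  }
})

test_that("LSD verdicts appear only where the ANOVA passed", {
  spec <- generator_spec(c(a = 15L, b = 15L, c = 15L),
                         length_range = c(100L, 150L),
                         bias = list(a = c(W = 0.04)), seed = 77L)
  em <- anova_lsd(class_composition(generate_dataset(spec)), alpha = 0.05)
  for (r in rownames(em$verdicts)) {
    if (is.na(em$anova_p[[r]]) || em$anova_p[[r]] >= em$alpha)
      expect_true(all(em$verdicts[r, ] == "not_significant"),
                  label = paste("residue", r))
  }
})

test_that("flat residues flag the ANOVA as undefined rather than erroring", {
  ds <- labeled_dataset(paste0("s", 1:4),
                        rep("ALAL", 4), rep(c("x", "y"), each = 2))
  em <- anova_lsd(class_composition(ds))
  expect_true(all(is.na(em$anova_p)))
  expect_true(all(em$verdicts == "not_significant"))
})

test_that("upper-tail binomial p matches the brute-force point-mass sum", {
  brute <- function(m, M, q) {
    sum(vapply(m:M, function(j) choose(M, j) * q^j * (1 - q)^(M - j), 1))
  }
  withr::with_seed(9, {
    for (rep in 1:40) {
      M <- sample(1:20, 1)
      m <- sample(0:M, 1)
      q <- stats::runif(1, 0.01, 0.99)
      expect_lt(abs(binom_upper_p(m, M, q) - brute(m, M, q)), 1e-12)
    }
  })
  expect_identical(binom_upper_p(0, 10, 0.3), 1)   # P(X >= 0)
})

test_that("enrichment p-values are monotone in the observed count", {
  p <- binom_upper_p(0:50, 50, 0.2)
  expect_true(all(diff(p) <= 1e-15))
})

test_that("planted words surface as enriched; absent words never do", {
  spec <- generator_spec(c(hot = 30L, cold = 30L),
                         length_range = c(120L, 200L),
                         planted = data.frame(class = "hot", word = "GWG",
                                              prob = 0.02),
                         seed = 13L)
  ds <- generate_dataset(spec)
  res <- binomial_enrichment(ds, "CP8", 3, confidence_threshold = 0.999)
  # GWG reduces to G(0) W(2) G(0) under CP8 -> word "0.2.0"
  hot_hits <- res[res$class == "hot", ]
  expect_true("0.2.0" %in% hot_hits$word)
  expect_true(all(res$confidence > 0.999))
  expect_true(all(res$observed > 0))      # m = 0 gives p = 1, never reported
  expect_true(all(res$p_value >= 0 & res$p_value <= 1))
  # sorted by confidence, descending
  expect_true(all(diff(res$confidence) <= 0))
})

test_that("enrichment supports the uniform background and native words", {
  ds <- generate_dataset(generator_spec(c(a = 10L, b = 10L),
                                        length_range = c(60L, 90L),
                                        seed = 3L))
  res <- binomial_enrichment(ds, "CP20", 1, confidence_threshold = 0.9,
                             background = "uniform")
  expect_true(all(res$background_q == 1 / 20))
  expect_error(binomial_enrichment(ds, "CP8", 3, confidence_threshold = 1.2),
               "in \\(0, 1\\)")
})

test_that("composition and enrichment tables serialize with headers", {
  ds <- separable_dataset(per_class = 3L, len = 40L)
  em <- anova_lsd(class_composition(ds))
  path <- tempfile()
  write_composition_matrix(em, path)
  expect_match(readLines(path, n = 1), "raaclass composition")
  res <- binomial_enrichment(ds, "CP5", 1, confidence_threshold = 0.99)
  path2 <- tempfile()
  write_enrichment(res, path2)
  expect_match(readLines(path2, n = 1), "raaclass enrichment")
})
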