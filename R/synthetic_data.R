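# Seeded generator for labeled protein sequence sets with class-specific
# composition structure. Residues are drawn i.i.d. from a per-class
# distribution (background + additive per-class bias, renormalized);
# optional planted words are written over windows at a stated per-window
# probability, preserving sequence length. This is deliberately simpler
# than real protein evolution (no Markov structure, no domains): it
# exercises composition-based features, nothing more.

#' Specification for a synthetic labeled dataset
#'
#' @param classes Named integer vector: sequences per class label,
#'   e.g. `c(I = 60, II = 50, III = 100, IV = 20)`.
#' @param length_range Integer vector `c(min, max)`: sequence lengths are
#'   uniform on this range.
#' @param background Named numeric vector of probabilities over the 20
#'   canonical residues (default uniform, 0.05 each). Need not be
#'   normalized; it is rescaled to sum to 1.
#' @param bias Named list: per class label, a named numeric vector of
#'   additive frequency shifts (e.g. `list(I = c(G = 0.10))`). The shifted
#'   distribution must stay non-negative; it is renormalized.
#' @param planted Optional data.frame with columns `class`, `word`
#'   (canonical residue string), `prob` (per-window planting probability).
#' @param seed Integer seed; identical specs generate identical datasets.
#' @return A list of class `generator_spec`.
#' @export
generator_spec <- function(classes, length_range = c(100L, 300L),
                           background = NULL, bias = list(),
                           planted = NULL, seed = 1L) {
  if (is.null(names(classes)) || any(!nzchar(names(classes))))
    stop("'classes' must be a named vector of per-class counts")
  if (any(classes < 1L)) stop("every class count must be >= 1")
  if (length(length_range) != 2L || length_range[1] > length_range[2] ||
      length_range[1] < 1L)
    stop("length_range must be c(min, max) with 1 <= min <= max")
  if (is.null(background))
    background <- stats::setNames(rep(0.05, 20L), CANONICAL_AA)
  if (!setequal(names(background), CANONICAL_AA))
    stop("background must be named by the 20 canonical residues")
  background <- background[CANONICAL_AA]
  if (any(background < 0) || sum(background) <= 0)
    stop("background probabilities must be non-negative with positive sum")
  background <- background / sum(background)
  if (length(bias)) {
    if (is.null(names(bias)) || !all(names(bias) %in% names(classes)))
      stop("bias names must be class labels")
    for (cl in names(bias)) {
      shift <- bias[[cl]]
      if (!all(names(shift) %in% CANONICAL_AA))
        stop("bias for class '", cl, "' names unknown residues: ",
             paste(setdiff(names(shift), CANONICAL_AA), collapse = ","))
      p <- class_distribution(background, shift)
      if (any(p < 0))
        stop("bias for class '", cl, "' drives residue probability below ",
             "zero: ", paste(names(p)[p < 0], collapse = ","))
    }
  }
  if (!is.null(planted)) {
    stopifnot(is.data.frame(planted),
              all(c("class", "word", "prob") %in% names(planted)))
    if (!all(planted$class %in% names(classes)))
      stop("planted words reference unknown class(es)")
    bad <- !grepl(paste0("^[", paste(CANONICAL_AA, collapse = ""), "]+$"),
                  toupper(planted$word))
    if (any(bad))
      stop("planted word(s) contain non-canonical residues: ",
           paste(planted$word[bad], collapse = ", "))
    if (any(planted$prob <= 0 | planted$prob > 1))
      stop("planting probabilities must be in (0, 1]")
    if (any(nchar(planted$word) > length_range[1]))
      stop("planted word longer than the minimum sequence length")
  }
  structure(list(classes = classes, length_range = as.integer(length_range),
                 background = background, bias = bias, planted = planted,
                 seed = as.integer(seed)),
            class = "generator_spec")
}

# background + additive shift, clipped check left to caller, renormalized
class_distribution <- function(background, shift) {
  p <- background
  if (length(shift)) p[names(shift)] <- p[names(shift)] + shift
  if (all(p >= 0)) p / sum(p) else p
}

#' Per-class residue distributions implied by a generator spec
#'
#' @param spec A [generator_spec()].
#' @return Matrix (classes x 20 residues) of sampling probabilities.
#' @export
spec_distributions <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  out <- t(vapply(names(spec$classes), function(cl)
    class_distribution(spec$background, spec$bias[[cl]]),
    numeric(20L)))
  rownames(out) <- names(spec$classes)
  out
}

#' Generate a synthetic labeled dataset
#'
#' Draws every sequence i.i.d. residue-by-residue from its class
#' distribution, then plants any configured words by overwriting windows
#' left-to-right: at each eligible start position the word is written with
#' its per-window probability and scanning resumes after it. The spec
#' (including the seed) is stored in the dataset metadata as a manifest.
#'
#' @param spec A [generator_spec()].
#' @return A [labeled_dataset]; ids are `<label>_<index>`.
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  dists <- spec_distributions(spec)
  ids <- character(0); seqs <- character(0); labs <- character(0)
  withr::with_seed(spec$seed, {
    for (cl in names(spec$classes)) {
      k <- spec$classes[[cl]]
      planted <- if (!is.null(spec$planted))
        spec$planted[spec$planted$class == cl, , drop = FALSE] else NULL
      lens <- seq.int(spec$length_range[1], spec$length_range[2])
      for (i in seq_len(k)) {
        L <- lens[sample.int(length(lens), 1L)]
        chars <- sample(CANONICAL_AA, L, replace = TRUE, prob = dists[cl, ])
        if (!is.null(planted) && nrow(planted)) {
          for (j in seq_len(nrow(planted))) {
            w <- strsplit(toupper(planted$word[j]), "", fixed = TRUE)[[1]]
            wl <- length(w)
            pos <- 1L
            while (pos <= L - wl + 1L) {
              if (stats::runif(1) < planted$prob[j]) {
                chars[pos:(pos + wl - 1L)] <- w
                pos <- pos + wl
              } else pos <- pos + 1L
            }
          }
        }
        ids <- c(ids, sprintf("%s_%04d", cl, i))
        seqs <- c(seqs, paste(chars, collapse = ""))
        labs <- c(labs, cl)
      }
    }
  })
  labeled_dataset(ids, seqs, labs,
                  metadata = list(generator = list(
                    classes = as.list(spec$classes),
                    length_range = spec$length_range,
                    background = as.list(spec$background),
                    bias = spec$bias,
                    planted = spec$planted,
                    seed = spec$seed)))
}
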