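# Cluster profiles: ordered partitions of the 20 canonical residues used to
# rewrite protein sequences over a reduced alphabet before k-mer counting.

CANONICAL_AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Construct a cluster profile
#'
#' A cluster profile is an ordered partition of the 20 canonical amino acids
#' into `k` clusters. Sequences are rewritten over the cluster indices
#' (0-based, in the order the clusters are given) before n-peptide counting.
#'
#' @param name Short identifier, e.g. `"CP8"`.
#' @param clusters Character vector; each element is a string of one-letter
#'   residue codes forming one cluster, e.g. `c("G", "IV", "FYW", ...)`.
#' @return An object of class `cluster_profile` with fields `name`,
#'   `clusters` (list of character vectors) and `size`.
#' @examples
#' cp <- cluster_profile("toy2", c("ACDEFGHIK", "LMNPQRSTVWY"))
#' cp$size
#' @export
cluster_profile <- function(name, clusters) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (is.character(clusters)) clusters <- strsplit(clusters, "", fixed = TRUE)
  clusters <- lapply(clusters, function(x) toupper(as.character(x)))
  residues <- unlist(clusters, use.names = FALSE)
  if (anyDuplicated(residues)) {
    stop("profile '", name, "': clusters are not disjoint (duplicated: ",
         paste(unique(residues[duplicated(residues)]), collapse = ","), ")")
  }
  if (!setequal(residues, CANONICAL_AA)) {
    missing <- setdiff(CANONICAL_AA, residues)
    extra <- setdiff(residues, CANONICAL_AA)
    stop("profile '", name, "': clusters must partition the 20 canonical ",
         "residues", if (length(missing)) paste0("; missing: ",
         paste(missing, collapse = ",")),
         if (length(extra)) paste0("; unknown: ", paste(extra, collapse = ",")))
  }
  if (any(lengths(clusters) == 0L)) stop("profile '", name, "': empty cluster")
  structure(list(name = name, clusters = clusters, size = length(clusters)),
            class = "cluster_profile")
}

#' @export
print.cluster_profile <- function(x, ...) {
  cat("Cluster profile ", x$name, " (k = ", x$size, "): ",
      paste(vapply(x$clusters, paste, "", collapse = ""), collapse = "-"),
      "\n", sep = "")
  invisible(x)
}

#' Built-in cluster profiles
#'
#' The five protein-blocks cluster profiles CP(13), CP(11), CP(9), CP(8) and
#' CP(5), plus the identity 20-letter profile CP(20). Cluster order within
#' each profile is fixed and determines the 0-based index used by
#' [reduce_sequence()] and the feature ordering of [npeptide_composition()].
#'
#' The profiles are nested refinements: every CP(5) cluster is a union of
#' CP(8) clusters, every CP(8) cluster a union of CP(9) clusters, and so on
#' down to the singletons of CP(20).
#'
#' @return Named list of [cluster_profile] objects
#'   (`CP20`, `CP13`, `CP11`, `CP9`, `CP8`, `CP5`).
#' @examples
#' profs <- builtin_profiles()
#' profs$CP8
#' @export
builtin_profiles <- function() {
  list(
    CP20 = cluster_profile("CP20", CANONICAL_AA),
    CP13 = cluster_profile("CP13", c("G", "IV", "FYW", "A", "L", "M", "E",
                                     "QRK", "P", "ND", "HS", "T", "C")),
    CP11 = cluster_profile("CP11", c("G", "IV", "FYW", "A", "LM", "EQRK",
                                     "P", "ND", "HS", "T", "C")),
    CP9  = cluster_profile("CP9",  c("G", "IV", "FYW", "ALM", "EQRK", "P",
                                     "ND", "HS", "TC")),
    CP8  = cluster_profile("CP8",  c("G", "IV", "FYW", "ALM", "EQRK", "P",
                                     "ND", "HSTC")),
    CP5  = cluster_profile("CP5",  c("G", "IVFYW", "ALMEQRK", "P", "NDHSTC"))
  )
}

#' Look up a cluster profile by name
#'
#' @param profile A `cluster_profile`, or the name of a built-in one.
#' @return A `cluster_profile`.
#' @export
get_profile <- function(profile) {
  if (inherits(profile, "cluster_profile")) return(profile)
  if (is.character(profile) && length(profile) == 1L) {
    profs <- builtin_profiles()
    key <- toupper(gsub("[()]", "", profile))
    if (key %in% names(profs)) return(profs[[key]])
    stop("unknown profile '", profile, "'; built-ins are: ",
         paste(names(profs), collapse = ", "))
  }
  stop("'profile' must be a cluster_profile or the name of a built-in one")
}

#' Read cluster profiles from a definition file
#'
#' One profile per line, `NAME<TAB>cluster1-cluster2-...-clusterK`, clusters
#' written as residue strings (e.g. `CP8\tG-IV-FYW-ALM-EQRK-P-ND-HSTC`).
#' Blank lines and lines starting with `#` are skipped. Every profile is
#' validated against the partition invariants.
#'
#' @param path Path to the definition file.
#' @return Named list of [cluster_profile] objects, in file order.
#' @export
read_profiles <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (length(lines) == 0L) stop("no profile definitions in '", path, "'")
  profs <- lapply(lines, function(ln) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) != 2L)
      stop("malformed profile line (expected NAME<TAB>clusters): '", ln, "'")
    cluster_profile(trimws(parts[1]),
                    strsplit(trimws(parts[2]), "-", fixed = TRUE)[[1]])
  })
  names(profs) <- vapply(profs, `[[`, "", "name")
  if (anyDuplicated(names(profs)))
    stop("duplicate profile names in '", path, "'")
  profs
}

# residue -> 0-based cluster index lookup, named by residue
profile_index <- function(profile) {
  idx <- rep.int(NA_integer_, length(CANONICAL_AA))
  names(idx) <- CANONICAL_AA
  for (i in seq_along(profile$clusters)) {
    idx[profile$clusters[[i]]] <- i - 1L
  }
  idx
}

#' Rewrite a protein sequence over a reduced alphabet
#'
#' Each canonical residue is replaced by the 0-based index of its cluster in
#' `profile`. Non-canonical symbols (X, B, Z, U, O, gaps, ...) are handled
#' by `policy`:
#' \describe{
#'   \item{`"mask"`}{(default) the symbol is dropped and a window break is
#'     recorded at that point, so that no n-peptide window of a downstream
#'     counting step spans the masked position;}
#'   \item{`"strict"`}{any non-canonical symbol is an error, reported with
#'     its position.}
#' }
#' Input is uppercased before mapping.
#'
#' @param sequence Protein sequence (single string).
#' @param profile A [cluster_profile] or built-in profile name.
#' @param policy `"mask"` or `"strict"`.
#' @param id Optional sequence identifier used in error messages.
#' @return An object of class `reduced_sequence`: list with `profile_name`,
#'   `indices` (0-based integer vector), `breaks` (positions `i` such that a
#'   window may not span `indices[i]` and `indices[i + 1]`) and `length`.
#' @examples
#' reduce_sequence("GFA", "CP8")$indices  # 0 2 3
#' @export
reduce_sequence <- function(sequence, profile, policy = c("mask", "strict"),
                            id = NULL) {
  policy <- match.arg(policy)
  profile <- get_profile(profile)
  stopifnot(is.character(sequence), length(sequence) == 1L)
  label <- if (is.null(id)) "<sequence>" else id
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  lookup <- profile_index(profile)
  mapped <- unname(lookup[chars])   # NA for non-canonical
  bad <- is.na(mapped)
  if (any(bad)) {
    if (policy == "strict") {
      pos <- which(bad)[1]
      stop("sequence '", label, "': non-canonical residue '", chars[pos],
           "' at position ", pos, " under strict policy")
    }
    # mask: drop the symbols, record breaks so no window spans a mask
    keep <- !bad
    runs <- rle(keep)
    seg_len <- runs$lengths[runs$values]   # lengths of kept segments
    breaks <- if (length(seg_len) > 1L) cumsum(seg_len)[-length(seg_len)]
              else integer(0)
    mapped <- mapped[keep]
  } else {
    breaks <- integer(0)
  }
  if (length(mapped) == 0L)
    stop("sequence '", label, "' is empty after applying policy '", policy, "'")
  structure(list(profile_name = profile$name,
                 indices = as.integer(mapped),
                 breaks = as.integer(breaks),
                 length = length(mapped)),
            class = "reduced_sequence")
}

#' @export
print.reduced_sequence <- function(x, ...) {
  cat("Reduced sequence over ", x$profile_name, ": length ", x$length,
      if (length(x$breaks)) paste0(", ", length(x$breaks), " mask break(s)"),
      "\n", sep = "")
  invisible(x)
}
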