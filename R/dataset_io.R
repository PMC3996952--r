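# Reading and writing labeled sequence sets: FASTA for sequences, a
# two-column TSV for labels.

#' Construct a labeled dataset
#'
#' @param ids Character vector of unique sequence identifiers.
#' @param sequences Character vector of protein sequences (same length).
#' @param labels Character vector of family labels (same length).
#' @param metadata Optional named list (e.g. a declared redundancy-reduction
#'   identity threshold from external CD-HIT preprocessing; recorded, not
#'   verified).
#' @return An object of class `labeled_dataset`: list with `records` (a
#'   data.frame with columns `id`, `sequence`, `label`, in input order),
#'   `label_set` (distinct labels in order of first appearance) and
#'   `metadata`.
#' @export
labeled_dataset <- function(ids, sequences, labels, metadata = list()) {
  ids <- as.character(ids)
  sequences <- toupper(as.character(sequences))
  labels <- as.character(labels)
  if (length(ids) != length(sequences) || length(ids) != length(labels))
    stop("ids, sequences and labels must have equal length")
  if (length(ids) == 0L) stop("dataset has no records")
  if (anyDuplicated(ids))
    stop("duplicate sequence ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (any(!nzchar(sequences)))
    stop("zero-length sequence for id(s): ",
         paste(ids[!nzchar(sequences)], collapse = ", "))
  structure(list(records = data.frame(id = ids, sequence = sequences,
                                      label = labels,
                                      stringsAsFactors = FALSE),
                 label_set = unique(labels),
                 metadata = metadata),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat("Labeled dataset: ", nrow(x$records), " sequence(s), ",
      length(x$label_set), " label(s)\n", sep = "")
  print(table(label = x$records$label))
  invisible(x)
}

#' Number of sequences in a labeled dataset
#' @param x A `labeled_dataset`.
#' @return Integer count of records.
#' @export
dataset_size <- function(x) {
  stopifnot(inherits(x, "labeled_dataset"))
  nrow(x$records)
}

#' Read protein sequences from a FASTA file
#'
#' Record ids are the first whitespace-delimited token of each header line;
#' wrapped sequence lines are joined and uppercased.
#'
#' @param path Path to a FASTA file.
#' @return A data.frame with columns `id` and `sequence`, in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: '", path, "'")
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e)
                    stop("failed to parse '", path, "' as FASTA: ",
                         conditionMessage(e), call. = FALSE))
  if (length(set) == 0L) stop("'", path, "' contains no FASTA records")
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, "", 1L)
  seqs <- toupper(as.character(set))
  if (anyDuplicated(ids))
    stop("duplicate FASTA id(s) in '", path, "': ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  empty <- !nzchar(seqs)
  if (any(empty))
    stop("zero-length FASTA record(s) in '", path, "': ",
         paste(ids[empty], collapse = ", "))
  data.frame(id = ids, sequence = unname(seqs), stringsAsFactors = FALSE)
}

#' Read a two-column label table
#'
#' @param path TSV with columns id and label (no header, or a header line
#'   starting with `#`).
#' @return data.frame with columns `id`, `label`.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop("label file not found: '", path, "'")
  df <- utils::read.delim(path, header = FALSE, comment.char = "#",
                          colClasses = "character",
                          col.names = c("id", "label"))
  if (nrow(df) == 0L) stop("'", path, "' contains no label rows")
  if (anyDuplicated(df$id))
    stop("duplicate id(s) in label table '", path, "': ",
         paste(unique(df$id[duplicated(df$id)]), collapse = ", "))
  df
}

#' Load a labeled dataset from FASTA + label TSV
#'
#' Records keep FASTA order. Every FASTA id must appear in the label table;
#' label rows without a matching sequence are reported as a warning and
#' dropped.
#'
#' @param fasta_path Path to the FASTA file.
#' @param labels_path Path to the two-column (id, label) TSV.
#' @param metadata Optional named list stored on the dataset.
#' @return A [labeled_dataset].
#' @export
load_dataset <- function(fasta_path, labels_path, metadata = list()) {
  seqs <- read_fasta(fasta_path)
  labs <- read_labels(labels_path)
  missing <- setdiff(seqs$id, labs$id)
  if (length(missing))
    stop("FASTA id(s) missing from label table: ",
         paste(missing, collapse = ", "))
  extra <- setdiff(labs$id, seqs$id)
  if (length(extra))
    warning("label table has ", length(extra),
            " id(s) with no sequence (ignored): ",
            paste(utils::head(extra, 5L), collapse = ", "),
            if (length(extra) > 5L) ", ...")
  lab <- labs$label[match(seqs$id, labs$id)]
  labeled_dataset(seqs$id, seqs$sequence, lab, metadata = metadata)
}

#' Write a labeled dataset to FASTA + label TSV (+ optional JSON manifest)
#'
#' @param dataset A [labeled_dataset].
#' @param fasta_path Output FASTA path.
#' @param labels_path Output label TSV path.
#' @param manifest_path Optional path for a JSON manifest holding the
#'   dataset metadata and class breakdown.
#' @export
write_dataset <- function(dataset, fasta_path, labels_path,
                          manifest_path = NULL) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  set <- Biostrings::BStringSet(dataset$records$sequence)
  names(set) <- dataset$records$id
  Biostrings::writeXStringSet(set, fasta_path, width = 70L)
  utils::write.table(dataset$records[, c("id", "label")], labels_path,
                     sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  if (!is.null(manifest_path)) {
    manifest <- list(
      n_sequences = nrow(dataset$records),
      labels = as.list(table(dataset$records$label)),
      metadata = dataset$metadata)
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         pretty = TRUE)
  }
  invisible(dataset)
}
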