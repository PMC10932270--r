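#' Labeled sequence datasets
#'
#' A `seq_dataset` is the atomic data container of the package: a data frame
#' with one row per candidate window and columns `id` (unique character),
#' `sequence` (upper-case RNA or DNA window), `label` (1 = modified /
#' positive, 0 = unmodified / negative) and `site_index` (0-based position of
#' the candidate modified nucleotide; defaults to the window centre
#' `floor(L/2)`).
#'
#' @param id character vector of unique record ids.
#' @param sequence character vector of sequences over `{A,C,G,U}` or
#'   `{A,C,G,T}`; stored upper-cased.
#' @param label integer vector of 0/1 class labels.
#' @param site_index optional integer vector of 0-based candidate-site
#'   positions; `NA` entries default to the window centre.
#' @param name dataset name (e.g. `"m1AH"`-style modification + species tag).
#' @return A `seq_dataset` (a `data.frame` subclass).
#' @export
seq_dataset <- function(id, sequence, label, site_index = NA_integer_,
                        name = "dataset") {
  id <- as.character(id)
  sequence <- toupper(as.character(sequence))
  label <- as.integer(label)
  if (anyDuplicated(id)) {
    stop2("duplicate record id(s): ",
          paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  if (!all(label %in% c(0L, 1L))) stop2("labels must be 0 or 1")
  L <- nchar(sequence)
  site_index <- rep_len(as.integer(site_index), length(id))
  site_index[is.na(site_index)] <- (L %/% 2L)[is.na(site_index)]
  if (any(site_index < 0L | site_index >= L)) {
    stop2("site_index out of range for at least one record")
  }
  ds <- data.frame(id = id, sequence = sequence, label = label,
                   site_index = site_index, stringsAsFactors = FALSE)
  attr(ds, "name") <- name
  class(ds) <- c("seq_dataset", "data.frame")
  ds
}

#' @export
print.seq_dataset <- function(x, ...) {
  cat(sprintf("<seq_dataset '%s': %d records (%d positive / %d negative)>\n",
              dataset_name(x), nrow(x), n_positive(x), n_negative(x)))
  invisible(x)
}

#' Dataset accessors
#'
#' @param dataset a [seq_dataset()].
#' @return `n_positive()`/`n_negative()` return counts; `class_ratio()` the
#'   negative:positive ratio; `dataset_name()` the stored name.
#' @export
n_positive <- function(dataset) sum(dataset$label == 1L)

#' @rdname n_positive
#' @export
n_negative <- function(dataset) sum(dataset$label == 0L)

#' @rdname n_positive
#' @export
class_ratio <- function(dataset) n_negative(dataset) / n_positive(dataset)

#' @rdname n_positive
#' @export
dataset_name <- function(dataset) attr(dataset, "name") %||% "dataset"

subset_dataset <- function(dataset, keep) {
  out <- dataset[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "name") <- attr(dataset, "name")
  class(out) <- class(dataset)
  out
}

#' Read a FASTA file plus a label table into a dataset
#'
#' Sequences are read with `Biostrings`, upper-cased and stored verbatim
#' (mixed T/U alphabets are accepted; see [rna_to_dna_alphabet()] for
#' conversion).  The label table is a two-column delimited text file
#' (`id`, `label`), tab- or comma-separated (sniffed), header optional.
#' An optional third column `site_index` (0-based) is honoured.
#'
#' @param fasta_path path to a FASTA file.
#' @param label_table_path path to the id/label table.
#' @param name dataset name; defaults to the FASTA base name.
#' @return A [seq_dataset()] preserving the FASTA record order.
#' @export
read_fasta_dataset <- function(fasta_path, label_table_path,
                               name = NULL) {
  if (!file.exists(fasta_path)) stop2("FASTA file not found: ", fasta_path)
  seqs <- Biostrings::readBStringSet(fasta_path)
  if (length(seqs) == 0L) stop2("empty FASTA file: ", fasta_path)
  ids <- vapply(strsplit(names(seqs), "\\s+"), `[`, character(1), 1L)
  labels <- read_label_table(label_table_path)
  missing <- setdiff(ids, labels$id)
  if (length(missing)) {
    stop2("id(s) present in FASTA but absent from label table: ",
          paste(missing, collapse = ", "))
  }
  m <- match(ids, labels$id)
  site <- if ("site_index" %in% names(labels)) labels$site_index[m] else NA_integer_
  seq_dataset(id = ids,
              sequence = toupper(as.character(seqs)),
              label = labels$label[m],
              site_index = site,
              name = name %||% sub("\\.(fa|fasta|fna)$", "",
                                   basename(fasta_path)))
}

read_label_table <- function(path) {
  if (!file.exists(path)) stop2("label table not found: ", path)
  first <- readLines(path, n = 1L)
  if (!length(first)) stop2("empty label table: ", path)
  sep <- if (grepl("\t", first)) "\t" else ","
  fields <- strsplit(first, sep, fixed = TRUE)[[1]]
  header <- is.na(suppressWarnings(as.integer(trimws(fields[2]))))
  tab <- utils::read.table(path, sep = sep, header = header,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop2("label table needs at least 2 columns (id, label)")
  names(tab)[1:2] <- c("id", "label")
  if (ncol(tab) >= 3L) names(tab)[3] <- "site_index"
  tab$id <- as.character(tab$id)
  tab$label <- as.integer(tab$label)
  tab
}

#' Convert between RNA and DNA alphabets
#'
#' `rna_to_dna_alphabet()` replaces every `U` by `T` (the framing used to
#' tokenize RNA with a DNA-trained vocabulary); `dna_to_rna_alphabet()` is
#' the inverse.  Length and all other characters are preserved.
#'
#' @param sequence character vector over `{A,C,G,U,T}` (plus `N` when
#'   `permissive = TRUE`).
#' @param permissive allow IUPAC ambiguity characters (kept verbatim; they
#'   later tokenize to `[UNK]`).  Default rejects them.
#' @return Character vector of converted sequences.
#' @examples
#' rna_to_dna_alphabet("GAUUACAU")  # "GATTACAT"
#' @export
rna_to_dna_alphabet <- function(sequence, permissive = FALSE) {
  check_alphabet(sequence, permissive)
  chartr("U", "T", toupper(sequence))
}

#' @rdname rna_to_dna_alphabet
#' @export
dna_to_rna_alphabet <- function(sequence, permissive = FALSE) {
  check_alphabet(sequence, permissive)
  chartr("T", "U", toupper(sequence))
}

check_alphabet <- function(sequence, permissive = FALSE) {
  allowed <- if (permissive) "ACGUTNRYSWKMBDHV" else "ACGUT"
  bad <- grepl(sprintf("[^%s]", allowed), toupper(sequence))
  if (any(bad)) {
    stop2("sequence contains characters outside {A,C,G,U,T}",
          if (!permissive) " (set permissive = TRUE to accept IUPAC codes)")
  }
  invisible(TRUE)
}

#' Enforce the training-set class-ratio policy
#'
#' When the negative:positive ratio exceeds `trigger_ratio` (default 10,
#' i.e. worse than 1:10), negatives are randomly under-sampled without
#' replacement down to `target_ratio` times the number of positives.
#' Below the trigger the dataset is returned unchanged.  Positives are never
#' dropped.  Intended for training splits only: test sets keep their natural
#' imbalance.
#'
#' @param dataset a [seq_dataset()].
#' @param trigger_ratio under-sampling trigger on negatives/positives.
#' @param target_ratio negatives-per-positive after under-sampling.
#' @param seed integer seed for the subsample.
#' @return A [seq_dataset()] (order of surviving records preserved).
#' @export
apply_ratio_policy <- function(dataset, trigger_ratio = 10, target_ratio = 1,
                               seed = 1L) {
  npos <- n_positive(dataset)
  if (npos == 0L) stop2("dataset has no positive records")
  if (target_ratio < 1) stop2("target_ratio must be >= 1")
  nneg <- n_negative(dataset)
  if (nneg / npos <= trigger_ratio) return(dataset)
  n_keep <- min(nneg, as.integer(round(target_ratio * npos)))
  neg_idx <- which(dataset$label == 0L)
  keep_neg <- with_seed(seed, sort(sample(neg_idx, n_keep)))
  subset_dataset(dataset, sort(c(which(dataset$label == 1L), keep_neg)))
}

#' Stratified fold assignment for cross-validation
#'
#' Assigns every record to one of `n_folds` folds such that within each
#' label class fold sizes differ by at most one (label-stratified).
#'
#' @param dataset a [seq_dataset()].
#' @param n_folds number of folds (default 5).
#' @param seed integer seed for the shuffle.
#' @return A `fold_assignment`: list with `n_folds` and `assignment`, a named
#'   integer vector mapping record id to fold index in `0:(n_folds-1)`.
#' @export
make_stratified_folds <- function(dataset, n_folds = 5L, seed = 1L) {
  n_folds <- as.integer(n_folds)
  if (n_folds < 2L) stop2("n_folds must be >= 2")
  for (cls in c(0L, 1L)) {
    if (sum(dataset$label == cls) < n_folds) {
      stop2("class ", cls, " has fewer than n_folds = ", n_folds, " records")
    }
  }
  assignment <- integer(nrow(dataset))
  names(assignment) <- dataset$id
  with_seed(seed, {
    for (cls in c(0L, 1L)) {
      idx <- which(dataset$label == cls)
      idx <- sample(idx)
      assignment[idx] <- rep_len(0:(n_folds - 1L), length(idx))
    }
  })
  structure(list(n_folds = n_folds, assignment = assignment),
            class = "fold_assignment")
}

#' @export
print.fold_assignment <- function(x, ...) {
  cat(sprintf("<fold_assignment: %d folds over %d records>\n",
              x$n_folds, length(x$assignment)))
  invisible(x)
}

#' Write a dataset (and fold assignment) to disk
#'
#' Emits `\<stem\>.fasta` and `\<stem\>_labels.tsv`; `write_fold_assignment()`
#' emits a two-column `id`/`fold` TSV.
#'
#' @param dataset a [seq_dataset()].
#' @param stem output path stem.
#' @return Invisibly, the paths written.
#' @export
write_dataset <- function(dataset, stem) {
  fa <- paste0(stem, ".fasta")
  set <- Biostrings::BStringSet(dataset$sequence)
  names(set) <- dataset$id
  Biostrings::writeXStringSet(set, fa)
  lab <- paste0(stem, "_labels.tsv")
  utils::write.table(dataset[, c("id", "label", "site_index")], lab,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(fasta = fa, labels = lab))
}

#' @param folds a `fold_assignment` from [make_stratified_folds()].
#' @param path output TSV path.
#' @rdname write_dataset
#' @export
write_fold_assignment <- function(folds, path) {
  utils::write.table(
    data.frame(id = names(folds$assignment), fold = unname(folds$assignment)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
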