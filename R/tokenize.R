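#' Build the k-mer vocabulary
#'
#' The vocabulary for scale `k` holds all `4^k` DNA k-mers plus the five
#' special tokens `[PAD]`, `[UNK]`, `[CLS]`, `[SEP]`, `[MASK]`, for a total
#' of `4^k + 5` entries.  Special tokens occupy the reserved id block 0-4
#' (`[PAD]` = 0 so that padding and attention masks coincide); k-mer ids
#' follow in lexicographic order over `{A,C,G,T}`.
#'
#' @param k k-mer length, between 3 and 6.
#' @return A `kmer_vocab`: list with `k`, `tokens` (character vector ordered
#'   by id) and `ids` (named integer vector, 0-based).
#' @export
build_vocab <- function(k) {
  k <- as.integer(k)
  if (length(k) != 1L || is.na(k) || k < 3L || k > 6L) {
    stop2("k must be a single integer in [3, 6]")
  }
  bases <- c("A", "C", "G", "T")
  kmers <- bases
  if (k > 1L) {
    for (i in seq_len(k - 1L)) {
      kmers <- as.vector(t(outer(kmers, bases, paste0)))
    }
  }
  tokens <- c(SPECIAL_TOKENS, kmers)
  ids <- seq_along(tokens) - 1L
  names(ids) <- tokens
  structure(list(k = k, tokens = tokens, ids = ids), class = "kmer_vocab")
}

SPECIAL_TOKENS <- c("[PAD]", "[UNK]", "[CLS]", "[SEP]", "[MASK]")
PAD_ID <- 0L; UNK_ID <- 1L; CLS_ID <- 2L; SEP_ID <- 3L; MASK_ID <- 4L

#' @export
print.kmer_vocab <- function(x, ...) {
  cat(sprintf("<kmer_vocab k=%d: %d tokens (4^%d + 5)>\n",
              x$k, length(x$tokens), x$k))
  invisible(x)
}

#' @param vocab a `kmer_vocab`.
#' @param path two-column (token, id) text file.
#' @rdname build_vocab
#' @export
write_vocab <- function(vocab, path) {
  utils::write.table(data.frame(token = vocab$tokens,
                                id = unname(vocab$ids)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname build_vocab
#' @export
read_vocab <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  tab <- tab[order(tab$id), ]
  k <- as.integer(round(log(nrow(tab) - 5, 4)))
  v <- build_vocab(k)
  if (!identical(v$tokens, tab$token)) stop2("vocabulary file does not match the canonical k=", k, " vocabulary")
  v
}

#' Split a sequence into overlapping k-mers
#'
#' Stride-1 sliding window: a length-`L` sequence yields exactly
#' `L - k + 1` tokens, token `i` being `substr(sequence, i, i + k - 1)`.
#' The input alphabet is taken verbatim (RNA stays RNA).
#'
#' @param sequence a single sequence string.
#' @param k k-mer length.
#' @return Character vector of `L - k + 1` k-mers.
#' @examples
#' kmerize("GAUUACAU", 6)  # "GAUUAC" "AUUACA" "UUACAU"
#' @export
kmerize <- function(sequence, k) {
  stopifnot(length(sequence) == 1L)
  sequence <- toupper(sequence)
  L <- nchar(sequence)
  k <- as.integer(k)
  if (L < k) stop2("sequence length ", L, " is shorter than k = ", k)
  substring(sequence, 1:(L - k + 1L), k:L)
}

#' Encode a sequence as a padded token-id stream
#'
#' The tokenizer entry point: converts U to T, k-merizes, maps k-mers to
#' vocabulary ids, frames the stream as `[CLS] kmers... [SEP]` and pads with
#' `[PAD]` to `max_len`.  K-mers containing a character outside
#' `{A,C,G,T}` map to `[UNK]` (only reachable with `permissive = TRUE`).
#'
#' @param sequence a single RNA or DNA sequence.
#' @param vocab a [build_vocab()] vocabulary.
#' @param max_len total stream length after padding (default 64).
#' @param permissive accept IUPAC ambiguity characters (tokenized as
#'   `[UNK]`); default rejects them.
#' @param truncate `"error"` (default) refuses sequences whose framed stream
#'   exceeds `max_len`; `"center"` keeps the window of k-mers centred on
#'   `site_index`.
#' @param site_index 0-based candidate-site position used by centre
#'   truncation; defaults to the sequence centre.
#' @return A `tokenized_seq`: list with `ids` (0-based, length `max_len`),
#'   `k`, `source_length` and `attention_mask` (1 on content, 0 on padding).
#' @export
encode_tokens <- function(sequence, vocab, max_len = 64L, permissive = FALSE,
                          truncate = c("error", "center"), site_index = NULL) {
  truncate <- match.arg(truncate)
  check_alphabet(sequence, permissive)
  dna <- chartr("U", "T", toupper(sequence))
  k <- vocab$k
  L <- nchar(dna)
  kmers <- kmerize(dna, k)
  n_content <- length(kmers) + 2L
  if (n_content > max_len) {
    if (truncate == "error") {
      stop2("framed stream length ", n_content, " exceeds max_len = ",
            max_len, "; pass truncate = \"center\" to keep the window ",
            "around the candidate site")
    }
    site <- as.integer(site_index %||% (L %/% 2L))
    keep <- max_len - 2L
    first_tok <- min(max(site - k %/% 2L - (keep - 1L) %/% 2L, 0L),
                     length(kmers) - keep)
    kmers <- kmers[(first_tok + 1L):(first_tok + keep)]
  }
  ids <- unname(vocab$ids[kmers])
  ids[is.na(ids)] <- UNK_ID
  ids <- c(CLS_ID, ids, SEP_ID)
  mask <- c(rep(1L, length(ids)), rep(0L, max_len - length(ids)))
  ids <- c(ids, rep(PAD_ID, max_len - length(ids)))
  structure(list(ids = as.integer(ids), k = k, source_length = L,
                 attention_mask = as.integer(mask)),
            class = "tokenized_seq")
}

#' @export
print.tokenized_seq <- function(x, ...) {
  cat(sprintf("<tokenized_seq k=%d: %d content tokens, padded to %d>\n",
              x$k, sum(x$attention_mask), length(x$ids)))
  invisible(x)
}

#' Tokenize one sequence at two scales
#'
#' Produces the ordered pair of token streams consumed by the fusion gate;
#' the `(k1, k2)` order is preserved because the gate's two linear maps play
#' asymmetric roles.
#'
#' @inheritParams encode_tokens
#' @param k1,k2 two distinct k-mer scales in `[3, 6]`.
#' @param vocabs named list of vocabularies keyed by `as.character(k)`;
#'   built on the fly when omitted.
#' @return List of two `tokenized_seq` objects, in `(k1, k2)` order.
#' @export
multiscale_encode <- function(sequence, k1, k2, vocabs = NULL, max_len = 64L,
                              permissive = FALSE) {
  if (k1 == k2) stop2("k1 and k2 must differ for multi-scale encoding")
  vocabs <- vocabs %||% stats::setNames(
    lapply(c(k1, k2), build_vocab), as.character(c(k1, k2)))
  lapply(c(k1, k2), function(k) {
    encode_tokens(sequence, vocabs[[as.character(k)]], max_len = max_len,
                  permissive = permissive)
  })
}

# Tokenize a whole dataset at one scale into B x T id / mask matrices
# (0-based ids; +1 when indexing R embedding tables).
encode_dataset_matrix <- function(dataset, vocab, max_len = NULL,
                                  permissive = FALSE) {
  k <- vocab$k
  n_content <- max(nchar(dataset$sequence)) - k + 3L
  max_len <- max_len %||% n_content
  enc <- lapply(dataset$sequence, encode_tokens, vocab = vocab,
                max_len = max_len, permissive = permissive)
  list(ids = do.call(rbind, lapply(enc, `[[`, "ids")),
       mask = do.call(rbind, lapply(enc, `[[`, "attention_mask")),
       k = k, max_len = max_len)
}
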