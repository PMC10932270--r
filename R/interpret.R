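#' Per-token attention importance scores
#'
#' Extracts an importance score per content token from the encoder's
#' attention matrices.  The default policy reads the final layer's `[CLS]`
#' row averaged over heads: the softmax weight the sequence-summary anchor
#' assigns to each k-mer token.  Specific layers/heads, or the mean over
#' all layers, are selectable; special tokens (`[CLS]`, `[SEP]`, padding)
#' are excluded.
#'
#' @param output an [encode()] result.
#' @param layer `"last"`, `"mean"`, or a 1-based layer index.
#' @param head `"mean"` or a 1-based head index.
#' @return Numeric vector of nonnegative scores, one per content k-mer
#'   token (they sum to at most 1 under the default policy, being part of
#'   a softmax row).
#' @export
extract_token_attention <- function(output, layer = "last", head = "mean") {
  att <- output$attentions
  n_layers <- length(att)
  layers <- if (identical(layer, "last")) n_layers
            else if (identical(layer, "mean")) seq_len(n_layers)
            else as.integer(layer)
  if (any(layers < 1L | layers > n_layers)) {
    stop2("layer index out of range (model has ", n_layers, " layers)")
  }
  n_heads <- dim(att[[1]])[1]
  heads <- if (identical(head, "mean")) seq_len(n_heads) else as.integer(head)
  if (any(heads < 1L | heads > n_heads)) {
    stop2("head index out of range (model has ", n_heads, " heads)")
  }
  n_content <- sum(output$attention_mask)
  tok_cols <- 2L:(n_content - 1L)  # content k-mers between [CLS] and [SEP]
  rows <- vapply(layers, function(l) {
    colMeans(matrix(att[[l]][heads, 1L, tok_cols], nrow = length(heads),
                    byrow = FALSE))
  }, numeric(length(tok_cols)))
  rowMeans(matrix(rows, ncol = length(layers)))
}

#' Map token scores to per-nucleotide position scores
#'
#' Nucleotide position `i` (0-based) is covered by every k-mer token whose
#' window contains it; its raw score is the mean of those tokens' scores.
#' Raw scores are then min-max normalized to `[0, 1]`; a constant nonzero
#' profile maps to all ones, an all-zero profile stays zero.
#'
#' @param token_scores numeric vector of `L - k + 1` token scores.
#' @param k the k-mer scale the scores came from.
#' @param L the source sequence length.
#' @return Numeric vector of `L` normalized position scores.
#' @export
token_to_position_scores <- function(token_scores, k, L) {
  n_tok <- L - k + 1L
  if (length(token_scores) != n_tok) {
    stop2("expected ", n_tok, " token scores for L = ", L, ", k = ", k,
          "; got ", length(token_scores))
  }
  raw <- vapply(seq_len(L), function(i) {
    cover <- max(1L, i - k + 1L):min(i, n_tok)
    mean(token_scores[cover])
  }, numeric(1))
  normalize_minmax(raw)
}

normalize_minmax <- function(x) {
  rng <- max(x) - min(x)
  if (rng == 0) {
    if (max(x) > 0) rep(1, length(x)) else rep(0, length(x))
  } else {
    (x - min(x)) / rng
  }
}

#' Attention profile of one sequence
#'
#' End-to-end wrapper: tokenizes a sequence at the model's scale(s), runs
#' the encoder and maps token attention to normalized per-nucleotide
#' scores.  For a fusion-scale model the two per-scale position profiles
#' are averaged position-wise after normalization.
#'
#' @param model a trained `mod_transformer`.
#' @param sequence one RNA/DNA sequence.
#' @param layer,head aggregation policy, see [extract_token_attention()].
#' @return An `attention_profile`: list with `sequence`, `position_scores`
#'   (length `L`, in `[0, 1]`), per-scale `token_scores`, and the policy.
#' @export
attention_profile <- function(model, sequence, layer = "last", head = "mean") {
  L <- nchar(sequence)
  per_scale <- lapply(model$kmers, function(k) {
    key <- as.character(k)
    len <- model$stream_len[[key]] %||% (L - k + 3L)
    toks <- encode_tokens(sequence, model$vocabs[[key]], max_len = len)
    tok_scores <- extract_token_attention(encode(model, toks), layer, head)
    list(k = k, token_scores = tok_scores,
         position_scores = token_to_position_scores(tok_scores, k, L))
  })
  pos <- rowMeans(vapply(per_scale, `[[`, numeric(L), "position_scores"))
  structure(list(sequence = toupper(sequence),
                 position_scores = normalize_minmax(pos),
                 scales = per_scale,
                 policy = list(layer = layer, head = head)),
            class = "attention_profile")
}

#' Harvest high-attention windows into a position frequency matrix
#'
#' For each profiled sequence the length-`w` window with the largest summed
#' position score is extracted, provided its peak score exceeds the
#' `q`-quantile of that sequence's scores; the extracted windows are
#' stacked into 4 x `w` base counts over the RNA alphabet `A,C,G,U`.
#'
#' @param profiles list of [attention_profile()] objects.
#' @param w window width (odd).
#' @param q peak-quantile inclusion threshold in `[0, 1)`.
#' @return A `pfm`: list with `counts` (4 x w matrix), `w`, `n_windows`
#'   and the window `starts` (0-based, named by inclusion).
#' @export
harvest_motif <- function(profiles, w = 5L, q = 0.75) {
  w <- as.integer(w)
  if (w %% 2L == 0L) stop2("window width w must be odd")
  bases <- c("A", "C", "G", "U")
  counts <- matrix(0L, 4L, w, dimnames = list(bases, NULL))
  starts <- integer(0)
  n_win <- 0L
  for (pr in profiles) {
    s <- pr$position_scores
    L <- length(s)
    if (w > L) stop2("window width ", w, " exceeds sequence length ", L)
    sums <- vapply(1:(L - w + 1L), function(i) sum(s[i:(i + w - 1L)]),
                   numeric(1))
    best <- which.max(sums)
    if (max(s[best:(best + w - 1L)]) <= stats::quantile(s, q)) next
    win <- strsplit(chartr("T", "U", substr(pr$sequence, best, best + w - 1L)),
                    "")[[1]]
    for (j in seq_len(w)) {
      if (win[j] %in% bases) counts[win[j], j] <- counts[win[j], j] + 1L
    }
    n_win <- n_win + 1L
    starts <- c(starts, best - 1L)
  }
  structure(list(counts = counts, w = w, n_windows = n_win, starts = starts),
            class = "pfm")
}

#' @export
print.pfm <- function(x, ...) {
  cat(sprintf("<pfm: width %d from %d windows; consensus %s>\n",
              x$w, x$n_windows, pfm_consensus(x)))
  invisible(x)
}

#' @rdname harvest_motif
#' @param pfm a `pfm`.
#' @export
pfm_consensus <- function(pfm) {
  paste(rownames(pfm$counts)[apply(pfm$counts, 2L, which.max)], collapse = "")
}

#' Export a motif in MEME minimal format
#'
#' Writes the letter-probability matrix of a harvested motif in the MEME
#' minimal text format consumed by motif-comparison tools such as TOMTOM.
#'
#' @param pfm a [harvest_motif()] result with at least one window.
#' @param name motif name.
#' @param alphabet motif alphabet string (default RNA `"ACGU"`).
#' @param background background letter frequencies (length 4, sums to 1).
#' @param path optional output file; when `NULL` the text is returned.
#' @return The MEME minimal text, invisibly when written to `path`.
#' @export
export_meme_minimal <- function(pfm, name = "motif1", alphabet = "ACGU",
                                background = rep(0.25, 4), path = NULL) {
  if (pfm$n_windows == 0L) stop2("cannot export a motif with zero windows")
  letters <- strsplit(alphabet, "")[[1]]
  probs <- sweep(pfm$counts, 2L, colSums(pfm$counts), "/")
  lines <- c(
    "MEME version 4", "",
    paste0("ALPHABET= ", alphabet), "",
    "Background letter frequencies",
    paste(sprintf("%s %.6f", letters, background), collapse = " "), "",
    paste("MOTIF", name),
    sprintf("letter-probability matrix: alength= %d w= %d nsites= %d E= 0",
            length(letters), pfm$w, pfm$n_windows),
    apply(probs, 2L, function(col) paste(sprintf("%.6f", col), collapse = " ")))
  if (is.null(path)) return(paste(lines, collapse = "\n"))
  writeLines(lines, path)
  invisible(paste(lines, collapse = "\n"))
}

#' @rdname export_meme_minimal
#' @param text MEME minimal text (or a path to a file of it).
#' @return `parse_meme_minimal()` returns the 4 x w letter-probability
#'   matrix with the alphabet as row names.
#' @export
parse_meme_minimal <- function(text) {
  lines <- if (length(text) == 1L && file.exists(text)) readLines(text)
           else strsplit(paste(text, collapse = "\n"), "\n")[[1]]
  if (!any(grepl("^MEME version", lines))) stop2("not MEME minimal text")
  alpha <- sub("^ALPHABET=\\s*", "", grep("^ALPHABET=", lines, value = TRUE)[1])
  hdr <- grep("^letter-probability matrix:", lines)[1]
  w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[hdr]))
  rows <- lines[(hdr + 1L):(hdr + w)]
  mat <- t(vapply(strsplit(trimws(rows), "\\s+"),
                  function(x) as.numeric(x), numeric(nchar(alpha))))
  out <- t(mat)
  rownames(out) <- strsplit(alpha, "")[[1]]
  out
}

#' Scan for over-represented wildcard substrate patterns
#'
#' Enumerates every width-`width` pattern over `{A, C, G, U, .}` with at
#' most `max_wildcards` wildcard positions ('.' matches any base) and at
#' least one literal position, counts sequences matching the pattern within
#' an anchor region around the candidate site, and scores enrichment of the
#' positive set over the background by a one-sided binomial test (positive
#' match count against the background match rate), Bonferroni-corrected
#' over the enumerated patterns.  Patterns column-compatible with a
#' higher-ranked pattern (equal or wildcard at every position) are greedily
#' removed as duplicates.
#'
#' @param positives,background character vectors of site-centred RNA
#'   sequences (or [seq_dataset()]s, from which the positive / negative
#'   records are taken respectively).
#' @param width pattern width.
#' @param max_wildcards maximum number of '.' positions.
#' @param min_count minimum positive match count to report.
#' @param anchor_radius the pattern must lie within `site +/-
#'   anchor_radius`; defaults to `width`.
#' @param site_index 0-based candidate-site position; defaults to the
#'   sequence centre.
#' @return A `substrate_scan` data frame: `pattern`, `pos_count`,
#'   `bg_count`, `pos_rate`, `bg_rate`, `p_value`, `p_adj`, ranked by
#'   adjusted p-value.
#' @export
substrate_scan <- function(positives, background, width = 5L,
                           max_wildcards = 2L, min_count = 5L,
                           anchor_radius = NULL, site_index = NULL) {
  pos_seqs <- extract_seqs(positives, 1L)
  bg_seqs <- extract_seqs(background, 0L)
  if (!length(pos_seqs) || !length(bg_seqs)) {
    stop2("both positive and background sets must be nonempty")
  }
  width <- as.integer(width)
  L <- nchar(pos_seqs[1])
  if (width > L) stop2("pattern width exceeds sequence length")
  site <- as.integer(site_index %||% (L %/% 2L))
  anchor <- as.integer(anchor_radius %||% width)
  lo <- max(0L, site - anchor)               # 0-based region bounds
  hi <- min(L - 1L, site + anchor)
  region <- function(s) substr(chartr("T", "U", toupper(s)), lo + 1L, hi + 1L)
  pos_reg <- vapply(pos_seqs, region, character(1), USE.NAMES = FALSE)
  bg_reg <- vapply(bg_seqs, region, character(1), USE.NAMES = FALSE)
  patterns <- enumerate_patterns(width, max_wildcards)
  n_pos <- length(pos_reg); n_bg <- length(bg_reg)
  pos_count <- integer(length(patterns))
  bg_count <- integer(length(patterns))
  for (i in seq_along(patterns)) {
    pos_count[i] <- sum(grepl(patterns[i], pos_reg))
    bg_count[i] <- sum(grepl(patterns[i], bg_reg))
  }
  # add-one smoothed background rate keeps the null probability off 0/1
  bg_rate <- (bg_count + 1) / (n_bg + 2)
  p <- stats::pbinom(pos_count - 1L, n_pos, bg_rate, lower.tail = FALSE)
  p_adj <- pmin(1, p * length(patterns))
  keep <- pos_count >= min_count
  out <- data.frame(pattern = patterns[keep], pos_count = pos_count[keep],
                    bg_count = bg_count[keep],
                    pos_rate = pos_count[keep] / n_pos,
                    bg_rate = bg_count[keep] / n_bg,
                    p_value = p[keep], p_adj = p_adj[keep],
                    stringsAsFactors = FALSE)
  out <- out[order(out$p_adj, out$p_value, -out$pos_count), ]
  rownames(out) <- NULL
  # greedy de-duplication: drop patterns compatible with a kept one
  kept <- logical(nrow(out))
  for (i in seq_len(nrow(out))) {
    ki <- which(kept)
    kept[i] <- !any(vapply(ki, function(j) {
      patterns_compatible(out$pattern[i], out$pattern[j])
    }, logical(1)))
  }
  out <- out[kept, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("substrate_scan", "data.frame")
  out
}

extract_seqs <- function(x, label) {
  if (inherits(x, "seq_dataset")) x$sequence[x$label == label]
  else as.character(x)
}

enumerate_patterns <- function(width, max_wildcards) {
  alph <- c("A", "C", "G", "U", ".")
  grid <- do.call(expand.grid,
                  c(rep(list(alph), width),
                    list(stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)))
  pat <- do.call(paste0, grid)
  n_wild <- nchar(gsub("[^.]", "", pat))
  pat[n_wild <= max_wildcards & n_wild < width]
}

# two patterns are compatible when every column pair is equal or contains
# a wildcard -- i.e. one could match inside the other's match set
patterns_compatible <- function(a, b) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  all(ca == cb | ca == "." | cb == ".")
}

#' Export attention heatmap matrix and substrate table
#'
#' `write_attention_csv()` writes a sequences x positions matrix of
#' normalized attention scores; `write_substrate_tsv()` writes the ranked
#' substrate patterns.
#'
#' @param profiles list of [attention_profile()]s.
#' @param path output path.
#' @export
write_attention_csv <- function(profiles, path) {
  mat <- t(vapply(profiles, `[[`,
                  numeric(length(profiles[[1]]$position_scores)),
                  "position_scores"))
  colnames(mat) <- paste0("pos", seq_len(ncol(mat)) - 1L)
  utils::write.csv(mat, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_attention_csv
#' @param scan a [substrate_scan()] result.
#' @export
write_substrate_tsv <- function(scan, path) {
  utils::write.table(as.data.frame(scan), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
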