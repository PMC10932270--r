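# Shared fixtures: everything is generated in code at test time.

# A small hand-made dataset with known labels.
tiny_dataset <- function(n_pos = 6L, n_neg = 6L, L = 21L, seed = 11L) {
  spec <- synthetic_spec(n_pos = n_pos, n_neg = n_neg, length = L,
                         offset_jitter = 2L, seed = seed, name = "tiny")
  generate_dataset(spec)$dataset
}

# Write a FASTA + label table pair into tempdir, returning the paths.
write_fasta_fixture <- function(seqs, labels, dir = NULL,
                                sep = "\t", header = FALSE,
                                ids = sprintf("seq%02d", seq_along(seqs))) {
  if (is.null(dir)) dir <- withr::local_tempdir(.local_envir = parent.frame())
  fasta <- file.path(dir, "x.fasta")
  writeLines(as.vector(rbind(paste0(">", ids), seqs)), fasta)
  tab <- file.path(dir, "x_labels.tsv")
  lines <- paste(ids[seq_along(labels)], labels, sep = sep)
  if (header) lines <- c(paste("id", "label", sep = sep), lines)
  writeLines(lines, tab)
  list(fasta = fasta, labels = tab)
}

# Random sequence over a given alphabet (uses the caller's RNG stream).
random_seq <- function(L, alphabet = c("A", "C", "G", "U")) {
  paste(sample(alphabet, L, replace = TRUE), collapse = "")
}

# A tiny desk model plus a pre-tokenized batch, for forward/backward tests.
tiny_model_batch <- function(kmers = 3L, n = 8L, L = 15L, seed = 5L,
                             config = encoder_config("tiny")) {
  ds <- tiny_dataset(n_pos = n %/% 2L, n_neg = n - n %/% 2L, L = L,
                     seed = seed)
  model <- build_model(config, kmers, seed = seed)
  enc <- lapply(model$vocabs,
                function(v) modsite:::encode_dataset_matrix(ds, v))
  model$stream_len <- lapply(enc, `[[`, "max_len")
  batch <- lapply(enc, function(e) list(ids = e$ids, mask = e$mask))
  batch$y <- ds$label
  list(model = model, batch = batch, dataset = ds)
}
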