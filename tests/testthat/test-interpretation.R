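test_that("token attention extraction follows the [CLS]-row policy", {
  m <- build_model(encoder_config("tiny"), 3, seed = 8)
  tk <- encode_tokens("GAUUACAUGCAUGCA", m$vocabs[["3"]], max_len = 16)
  out <- encode(m, tk)
  sc <- extract_token_attention(out)
  n_tok <- sum(tk$attention_mask) - 2L
  expect_length(sc, n_tok)
  expect_true(all(sc >= 0))
  expect_lte(sum(sc), 1 + 1e-9)  # sub-row of a softmax row

  # default "last" equals explicit final layer index
  expect_identical(sc, extract_token_attention(out, layer = 2L))
  # head-mean equals the hand-average of per-head extractions
  per_head <- sapply(1:4, function(h) {
    extract_token_attention(out, head = h)
  })
  expect_equal(sc, rowMeans(per_head), tolerance = 1e-12)
  expect_error(extract_token_attention(out, layer = 3L), "out of range")
  expect_error(extract_token_attention(out, head = 5L), "out of range")
})

test_that("token-to-position mapping follows window coverage and min-max law", {
  # uniform token scores normalize to all ones
  expect_equal(token_to_position_scores(rep(0.2, 8), k = 3, L = 10),
               rep(1, 10))
  # all-zero input stays zero
  expect_equal(token_to_position_scores(rep(0, 8), k = 3, L = 10),
               rep(0, 10))
  # single token (L = k): every position shares it
  expect_equal(token_to_position_scores(0.7, k = 5, L = 5), rep(1, 5))
  expect_error(token_to_position_scores(rep(1, 5), k = 3, L = 10), "expected")

  # single nonzero token at index t covers exactly positions t .. t+k-1,
  # checked against a brute-force coverage oracle
  withr::with_seed(53, {
    for (rep in 1:10) {
      k <- sample(3:6, 1); L <- sample((k + 4):40, 1)
      n_tok <- L - k + 1
      t0 <- sample(n_tok, 1)
      sc <- numeric(n_tok); sc[t0] <- runif(1, 0.5, 2)
      pos <- token_to_position_scores(sc, k, L)
      expect_equal(which(pos > 0), t0:(t0 + k - 1))

      # full coverage-mean oracle on arbitrary scores
      sc2 <- round(runif(n_tok), 2)
      sc2[sample(n_tok, n_tok %/% 3)] <- 0
      pos2 <- token_to_position_scores(sc2, k, L)
      raw <- vapply(seq_len(L), function(i) {
        mean(sc2[max(1, i - k + 1):min(i, n_tok)])
      }, numeric(1))
      expect_equal(pos2, modsite:::normalize_minmax(raw), tolerance = 1e-12)
      # support conservation: zero normalized score iff no covering token
      if (min(raw) == 0) expect_equal(pos2 == 0, raw == 0)
    }
  })

  # normalization idempotence
  x <- c(0, 0.3, 1, 0.4)
  expect_identical(modsite:::normalize_minmax(modsite:::normalize_minmax(x)),
                   modsite:::normalize_minmax(x))
})

test_that("motif harvesting stacks peak windows into a consistent PFM", {
  # identical sequences with one sharp peak: single-base columns
  prof <- lapply(1:6, function(i) {
    structure(list(sequence = "AAAAUGACCAAAA",
                   position_scores = c(0, 0, 0, 0, 1, 1, 1, 1, 1, 0, 0, 0, 0)),
              class = "attention_profile")
  })
  pfm <- harvest_motif(prof, w = 5, q = 0.5)
  expect_equal(pfm$n_windows, 6L)
  expect_true(all(colSums(pfm$counts) == 6L))
  expect_true(all(apply(pfm$counts, 2, max) == 6L))
  expect_equal(pfm_consensus(pfm), "UGACC")
  expect_error(harvest_motif(prof, w = 4), "odd")
  expect_error(harvest_motif(prof, w = 15), "exceeds")
})

test_that("MEME minimal export is well-formed and round-trips", {
  counts <- matrix(c(10, 0, 0, 0,
                     2, 3, 4, 1,
                     0, 0, 0, 10), nrow = 4,
                   dimnames = list(c("A", "C", "G", "U"), NULL))
  pfm <- structure(list(counts = counts, w = 3L, n_windows = 10L),
                   class = "pfm")
  txt <- export_meme_minimal(pfm)
  expect_match(txt, "MEME version")
  expect_match(txt, "ALPHABET= ACGU")
  expect_match(txt, "1.000000 0.000000 0.000000 0.000000", fixed = TRUE)
  probs <- parse_meme_minimal(txt)
  expect_equal(unname(probs), unname(sweep(counts, 2, colSums(counts), "/")),
               tolerance = 1e-6)
  # and through a file on disk
  path <- withr::local_tempfile(fileext = ".meme")
  export_meme_minimal(pfm, path = path)
  expect_equal(parse_meme_minimal(path), probs, tolerance = 1e-6)
  empty <- structure(list(counts = counts * 0L, w = 3L, n_windows = 0L),
                     class = "pfm")
  expect_error(export_meme_minimal(empty), "zero windows")
})

test_that("substrate scan recovers a planted wildcard pattern", {
  withr::with_seed(61, {
    L <- 21L
    bg <- replicate(150, random_seq(L))
    pos <- replicate(150, {
      s <- strsplit(random_seq(L), "")[[1]]
      s[9:13] <- c("U", s[10], "A", "A", "U")  # plant U.AAU at the centre
      paste(s, collapse = "")
    })
    scan <- substrate_scan(pos, bg, width = 5, max_wildcards = 2,
                           min_count = 5)
    expect_s3_class(scan, "substrate_scan")
    expect_true(nrow(scan) >= 1)
    expect_true(modsite:::patterns_compatible(scan$pattern[1], "U.AAU"))
    expect_lt(scan$p_adj[1], 1e-10)
    expect_true(all(scan$pos_count >= 5))
  })
})

test_that("substrate match rate in uniform background follows the closed form", {
  # with a single anchored start, P(match U.AAU) = (1/4)^4 for the 4
  # literal positions under uniform composition
  withr::with_seed(67, {
    n <- 8000L
    bg <- replicate(n, random_seq(11))
    # anchor_radius 2 with width 5 allows exactly one start (the centre)
    hits <- sum(grepl("U.AAU", substr(bg, 4, 8)))
    expect_lt(abs(hits / n - 0.25^4), 3e-3)
  })
})

test_that("substrate scan stays quiet when positives equal background", {
  withr::with_seed(71, {
    for (rep in 1:2) {
      seqs <- replicate(120, random_seq(21))
      scan <- substrate_scan(seqs, seqs, width = 5, max_wildcards = 2,
                             min_count = 3)
      if (nrow(scan)) expect_gt(min(scan$p_adj), 0.05)
    }
  })
})

test_that("pattern compatibility and deduplication behave as documented", {
  expect_true(modsite:::patterns_compatible("U.AAU", "UCAAU"))
  expect_true(modsite:::patterns_compatible("U.AAU", "U.AA."))
  expect_false(modsite:::patterns_compatible("U.AAU", "C.AAU"))
})
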