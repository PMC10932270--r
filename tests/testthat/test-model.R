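test_that("encoder output obeys the shape and normalization contracts", {
  m <- build_model(encoder_config("tiny"), 3, seed = 4)
  tk <- encode_tokens("GAUUACAUGCAUGC", m$vocabs[["3"]], max_len = 16)
  out <- encode(m, tk)
  expect_equal(dim(out$hidden_states), c(16L, 64L))
  expect_length(out$pooled, 64L)
  expect_length(out$attentions, 2L)                  # tiny preset layers
  expect_equal(dim(out$attentions[[1]]), c(4L, 16L, 16L))  # heads x T x T
  # each attention row sums to 1 over unmasked positions
  n_content <- sum(tk$attention_mask)
  for (l in 1:2) for (h in 1:4) {
    rs <- rowSums(out$attentions[[l]][h, , seq_len(n_content)])
    expect_true(all(abs(rs - 1) < 1e-5))
    # no attention mass on padding
    expect_lt(max(out$attentions[[l]][h, , (n_content + 1):16]), 1e-6)
  }
  # bit-reproducible forward passes
  out2 <- encode(m, tk)
  expect_identical(out$hidden_states, out2$hidden_states)
  expect_error(encode(m, encode_tokens("GAUUAC", build_vocab(5),
                                       max_len = 8)),
               "no scale")
})

test_that("full preset instantiates exactly 12 layers and tiny exactly 2", {
  tiny <- build_model(encoder_config("tiny"), 3, seed = 0)
  expect_length(tiny$params$layers, 2L)
  full <- build_model(encoder_config("full"), 3, seed = 0)
  expect_length(full$params$layers, 12L)
  expect_equal(full$config$hidden_dim, 768L)
  expect_equal(ncol(full$params$emb[["3"]]), 768L)
})

test_that("fusion gate reproduces its closed forms and convexity bound", {
  d <- 16L
  zero <- list(W1 = matrix(0, d, d), W2 = matrix(0, d, d))
  withr::with_seed(23, {
    h1 <- rnorm(d); h2 <- rnorm(d)
    fg <- fusion_gate(h1, h2, zero)
    expect_equal(fg$gate, rep(0.5, d))            # sigmoid(0)
    expect_equal(fg$fused, (h1 + h2) / 2)

    params <- list(W1 = matrix(rnorm(d * d), d), W2 = matrix(rnorm(d * d), d))
    # equal inputs pass through unchanged whatever the gate
    h <- rnorm(d)
    expect_equal(fusion_gate(h, h, params)$fused, h)

    # scalar-loop oracle + elementwise convexity over seeded random triples
    for (rep in 1:200) {
      h1 <- rnorm(d); h2 <- rnorm(d)
      fg <- fusion_gate(h1, h2, params)
      oracle <- numeric(d)
      for (j in seq_len(d)) {
        z <- sum(h1 * params$W1[, j]) + sum(h2 * params$W2[, j])
        f <- 1 / (1 + exp(-z))
        oracle[j] <- f * h1[j] + (1 - f) * h2[j]
      }
      expect_lt(max(abs(fg$fused - oracle)), 1e-10)
      expect_true(all(fg$gate > 0 & fg$gate < 1))
      expect_true(all(fg$fused >= pmin(h1, h2) - 1e-12 &
                        fg$fused <= pmax(h1, h2) + 1e-12))
    }
  })
  expect_error(fusion_gate(rnorm(8), rnorm(8), zero), "width")
})

test_that("scalar gate broadcasts one component across the representation", {
  d <- 8L
  params <- list(W1 = matrix(1, d, 1), W2 = matrix(-1, d, 1))
  h1 <- rep(1, d); h2 <- rep(0, d)
  fg <- fusion_gate(h1, h2, params)
  f <- 1 / (1 + exp(-d))  # single gate value from the two inner products
  expect_equal(unique(round(fg$gate, 12)), round(f, 12))
  expect_equal(fg$fused, rep(f, d))
})

test_that("classification head is a calibrated logistic unit", {
  m <- build_model(encoder_config("tiny"), 3, seed = 1)
  m0 <- m
  m0$params$head$w[] <- 0
  m0$params$head$b <- 0
  expect_equal(classify(m0, rnorm(64)), 0.5)      # zero weights -> sigmoid(0)
  withr::with_seed(5, {
    for (i in 1:20) {
      p <- classify(m, rnorm(64, sd = 10))
      expect_true(p > 0 && p < 1)
    }
  })
  h <- rnorm(64)
  expect_identical(classify(m, h), classify(m, h))
})

test_that("masked-LM loss is nonnegative and equals log(V) under uniform logits", {
  m <- build_model(encoder_config("tiny"), 3, seed = 2)  # MLM head zero-init
  tk <- encode_tokens("GAUUACAUGCAUGCAAUGG", m$vocabs[["3"]], max_len = 24)
  loss <- masked_lm_step(m, tk, mask_prob = 0.15, seed = 3)
  expect_equal(loss, log(69), tolerance = 1e-10)
  # vanishing mask_prob still masks at least one token
  loss2 <- masked_lm_step(m, tk, mask_prob = 1e-9, seed = 3)
  expect_equal(loss2, log(69), tolerance = 1e-10)
  expect_gte(loss, 0)
  expect_error(masked_lm_step(m, tk, mask_prob = 1.5), "mask_prob")
})

test_that("masked-LM pretraining reduces the masked-token loss", {
  ds <- tiny_dataset(n_pos = 8L, n_neg = 8L, L = 21L, seed = 13L)
  m <- build_model(encoder_config("tiny"), 3, seed = 6)
  fit <- pretrain_mlm(m, ds, epochs = 3, learning_rate = 2e-3, seed = 9)
  expect_length(fit$history, 3L)
  expect_lt(fit$history[3], log(69))  # below the uniform-logit baseline
})

test_that("checkpoints round-trip through disk", {
  dir <- withr::local_tempdir()
  bm <- tiny_model_batch()
  path <- file.path(dir, "ck.rds")
  save_checkpoint(bm$model, path)
  expect_true(file.exists(paste0(path, ".yaml")))
  m2 <- load_checkpoint(path)
  expect_identical(predict_scores(m2, bm$dataset),
                   predict_scores(bm$model, bm$dataset))
})
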