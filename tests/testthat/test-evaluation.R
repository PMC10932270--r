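test_that("confusion counts tally with the >= threshold tie rule", {
  cc <- confusion(c(1, 0), c(0.9, 0.1))
  expect_equal(unlist(cc[c("TP", "TN", "FP", "FN")]),
               c(TP = 1L, TN = 1L, FP = 0L, FN = 0L))
  # ties at the threshold predict positive
  cc2 <- confusion(c(1, 0, 1), rep(0.5, 3))
  expect_equal(cc2$FP, 1L)
  expect_equal(cc2$FN, 0L)
  expect_error(confusion(c(1, 0), 0.5), "length")

  # brute-force tally oracle on seeded random cases
  withr::with_seed(7, {
    for (i in 1:25) {
      n <- sample(5:200, 1)
      y <- rbinom(n, 1, runif(1, 0.2, 0.8))
      s <- runif(n)
      th <- runif(1)
      cc <- confusion(y, s, th)
      tp <- tn <- fp <- fn <- 0L
      for (j in seq_len(n)) {
        pred <- s[j] >= th
        if (pred && y[j] == 1) tp <- tp + 1L
        else if (pred) fp <- fp + 1L
        else if (y[j] == 1) fn <- fn + 1L
        else tn <- tn + 1L
      }
      expect_equal(unlist(cc[c("TP", "TN", "FP", "FN")]),
                   c(TP = tp, TN = tn, FP = fp, FN = fn))
      expect_equal(cc$TP + cc$TN + cc$FP + cc$FN, n)
    }
  })
})

test_that("Sn/Sp/Acc/MCC match direct substitution and edge conventions", {
  m <- classification_metrics(list(TP = 50, FN = 50, TN = 100, FP = 0))
  expect_equal(m$Sn, 0.5)
  expect_equal(m$Sp, 1.0)
  expect_equal(m$Acc, 0.75)

  perfect <- classification_metrics(list(TP = 10, TN = 20, FP = 0, FN = 0))
  expect_equal(perfect$MCC, 1)

  m2 <- classification_metrics(list(TP = 90, FN = 10, TN = 80, FP = 20))
  expect_equal(m2$Sn, 0.9)
  expect_equal(m2$Sp, 0.8)
  expect_equal(m2$Acc, 0.85)
  expect_equal(m2$MCC, 7000 / sqrt(110 * 100 * 100 * 90), tolerance = 1e-12)

  # zero-denominator factor -> MCC 0; absent class -> NA rate, never 0
  allpos <- classification_metrics(list(TP = 5, FN = 5, TN = 0, FP = 0))
  expect_equal(allpos$MCC, 0)
  expect_true(is.na(allpos$Sp))
  expect_error(classification_metrics(list(TP = -1, TN = 1, FP = 0, FN = 0)),
               "negative")
})

test_that("metric identities hold against an independent implementation", {
  oracle <- function(tp, tn, fp, fn) {
    den <- (tp + fp) * (tn + fn) * (tp + fn) * (tn + fp)
    list(Sn = tp / (tp + fn), Sp = tn / (tn + fp),
         Acc = (tp + tn) / (tp + tn + fp + fn),
         MCC = if (den == 0) 0 else (tp * tn - fp * fn) / sqrt(den))
  }
  withr::with_seed(19, {
    tabs <- matrix(rpois(4 * 10000, lambda = 20), ncol = 4)
    tabs <- tabs[rowSums(tabs) > 0, ]
    worst <- 0
    for (i in seq_len(nrow(tabs))) {
      got <- classification_metrics(list(TP = tabs[i, 1], TN = tabs[i, 2],
                                         FP = tabs[i, 3], FN = tabs[i, 4]))
      want <- oracle(tabs[i, 1], tabs[i, 2], tabs[i, 3], tabs[i, 4])
      diffs <- abs(c(got$Sn - want$Sn, got$Sp - want$Sp,
                     got$Acc - want$Acc, got$MCC - want$MCC))
      worst <- max(worst, diffs[is.finite(diffs)])
      expect_true(got$MCC >= -1 - 1e-12 && got$MCC <= 1 + 1e-12)
    }
    expect_lt(worst, 1e-12)
  })
})

test_that("MCC is near zero for label-independent predictions", {
  withr::with_seed(29, {
    vals <- replicate(40, {
      y <- rbinom(500, 1, 0.5)
      s <- runif(500)
      classification_metrics(confusion(y, s))$MCC
    })
    expect_lt(mean(abs(vals)), 0.1)
  })
})

test_that("AUC equals pairwise concordance with half-weight ties", {
  expect_equal(roc_auc(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1)), 1.0)
  expect_equal(roc_auc(c(1, 1, 0, 0), c(0.8, 0.4, 0.6, 0.2)), 0.75)
  expect_equal(roc_auc(c(1, 0, 1, 0), rep(0.4, 4)), 0.5)
  expect_error(roc_auc(c(1, 1), c(0.2, 0.3)), "both classes")

  concordance <- function(y, s) {
    pos <- s[y == 1]; neg <- s[y == 0]
    tot <- 0
    for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
    tot / (length(pos) * length(neg))
  }
  withr::with_seed(37, {
    for (i in 1:20) {
      n <- sample(4:200, 1)
      y <- c(1, 0, rbinom(n - 2, 1, 0.5))
      s <- round(runif(n), sample(1:3, 1))  # rounding induces ties
      expect_equal(roc_auc(y, s), concordance(y, s), tolerance = 1e-12)
      # complement symmetry: flip labels and scores
      expect_equal(roc_auc(1 - y, 1 - s), roc_auc(y, s), tolerance = 1e-12)
    }
  })
})

test_that("AUC agrees with the pROC reference implementation", {
  withr::with_seed(43, {
    for (i in 1:5) {
      y <- c(1, 0, rbinom(80, 1, 0.4))
      s <- runif(82)
      ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                            direction = "<")))
      expect_equal(roc_auc(y, s), ref, tolerance = 1e-12)
    }
  })
})

test_that("cross-species evaluation produces a complete train x test matrix", {
  base <- synthetic_spec(n_pos = 10L, n_neg = 10L, length = 21L,
                         offset_jitter = 2L, seed = 3L)
  fam <- generate_species_family(base, c(a = "U.AAU", b = "C.GU."))
  M <- cross_species_evaluate(lapply(fam, `[[`, "dataset"),
                              encoder_config("tiny"),
                              adversarial_config(epochs = 1L, seed = 2L),
                              kmers = 3L, test_fraction = 0.25)
  expect_equal(dim(M), c(2L, 2L))
  expect_equal(colnames(M), c("a", "b"))
  expect_true(all(M >= 0 & M <= 1))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cross_species_matrix(M, path)
  expect_equal(dim(read.csv(path, row.names = 1)), c(2L, 2L))
})
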