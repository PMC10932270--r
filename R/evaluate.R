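#' Confusion counts at a score threshold
#'
#' Predicts positive when `score >= threshold` (ties count as positive) and
#' tallies TP, TN, FP, FN.
#'
#' @param labels binary 0/1 labels.
#' @param scores predicted probabilities in `[0, 1]`.
#' @param threshold decision threshold (default 0.5).
#' @return A `confusion_counts` list with `TP`, `TN`, `FP`, `FN`.
#' @export
confusion <- function(labels, scores, threshold = 0.5) {
  if (length(labels) != length(scores)) {
    stop2("labels and scores differ in length")
  }
  if (!length(labels)) stop2("empty input")
  if (!all(labels %in% c(0, 1))) stop2("labels must be 0/1")
  pred <- as.integer(scores >= threshold)
  structure(list(TP = sum(pred == 1L & labels == 1),
                 TN = sum(pred == 0L & labels == 0),
                 FP = sum(pred == 1L & labels == 0),
                 FN = sum(pred == 0L & labels == 1),
                 threshold = threshold),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts @%g: TP=%d TN=%d FP=%d FN=%d>\n",
              x$threshold, x$TP, x$TN, x$FP, x$FN))
  invisible(x)
}

#' Threshold classification metrics
#'
#' Sensitivity `Sn = TP/(TP+FN)`, specificity `Sp = TN/(TN+FP)`, accuracy
#' `Acc = (TP+TN)/total` and Matthews correlation coefficient
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TN+FN)(TP+FN)(TN+FP))`.
#' A zero factor in the MCC denominator yields `MCC = 0` (conventional);
#' `Sn`/`Sp` are `NA` when the corresponding class is absent, never a
#' silent 0.
#'
#' @param counts a [confusion()] result (or a list with TP/TN/FP/FN).
#' @return A `metrics_report` list with `Sn`, `Sp`, `Acc`, `MCC`,
#'   `threshold`.
#' @export
classification_metrics <- function(counts) {
  with(counts, {
    if (any(c(TP, TN, FP, FN) < 0)) stop2("negative confusion counts")
    total <- TP + TN + FP + FN
    if (total == 0) stop2("empty confusion table")
    Sn <- if (TP + FN > 0) TP / (TP + FN) else NA_real_
    Sp <- if (TN + FP > 0) TN / (TN + FP) else NA_real_
    denom <- sqrt(TP + FP) * sqrt(TN + FN) * sqrt(TP + FN) * sqrt(TN + FP)
    MCC <- if (denom == 0) 0 else (TP * TN - FP * FN) / denom
    structure(list(Sn = Sn, Sp = Sp, Acc = (TP + TN) / total, MCC = MCC,
                   threshold = counts$threshold %||% NA_real_),
              class = "metrics_report")
    })
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics: Sn=%.4f Sp=%.4f Acc=%.4f MCC=%.4f>\n",
              x$Sn, x$Sp, x$Acc, x$MCC))
  invisible(x)
}

#' Area under the ROC curve
#'
#' Rank-based Mann-Whitney formulation: the probability that a random
#' positive outscores a random negative, with ties counting one half --
#' exactly the trapezoidal area under the ROC curve.
#'
#' @param labels binary 0/1 labels (both classes must be present).
#' @param scores numeric scores.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(labels, scores) {
  if (length(labels) != length(scores)) stop2("labels and scores differ in length")
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop2("AUC undefined: both classes must be present")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Cross-species train/test AUC matrix
#'
#' Trains one model per dataset and evaluates it on every dataset's
#' held-out test split, probing whether the learned sequence determinants
#' transfer across (pseudo-)species.  Each dataset is split once,
#' stratified, into train and test; diagonal cells therefore always use
#' records the model never saw.  Single-class test splits are recorded as
#' `NA`, never 0.
#'
#' @param datasets named list of [seq_dataset()] objects.
#' @param config an [encoder_config()].
#' @param adv_config an [adversarial_config()].
#' @param kmers one k or a scale pair.
#' @param test_fraction fraction of each dataset held out for testing.
#' @param verbose print training progress.
#' @return A `cross_species_matrix`: AUC matrix with training datasets as
#'   columns and testing datasets as rows (heatmap layout: x = training,
#'   y = testing).
#' @export
cross_species_evaluate <- function(datasets, config = encoder_config("tiny"),
                                   adv_config = adversarial_config(),
                                   kmers = 3L, test_fraction = 0.25,
                                   verbose = FALSE) {
  if (is.null(names(datasets)) || anyDuplicated(names(datasets))) {
    stop2("datasets must be a uniquely named list")
  }
  nms <- names(datasets)
  splits <- lapply(seq_along(datasets), function(i) {
    ds <- datasets[[i]]
    n_folds <- max(2L, round(1 / test_fraction))
    fa <- make_stratified_folds(ds, n_folds,
                                seed = derive_seed(adv_config$seed, 3000L + i))
    test <- fa$assignment[ds$id] == 0L
    list(train = subset_dataset(ds, !test), test = subset_dataset(ds, test))
  })
  names(splits) <- nms
  M <- matrix(NA_real_, length(nms), length(nms),
              dimnames = list(testing = nms, training = nms))
  for (j in seq_along(nms)) {
    if (verbose) message("training on ", nms[j])
    adv_j <- adv_config
    adv_j$seed <- derive_seed(adv_config$seed, 4000L + j)
    model <- fit_model(splits[[j]]$train, config, adv_j, kmers,
                       verbose = verbose)
    for (i in seq_along(nms)) {
      test <- splits[[i]]$test
      if (n_positive(test) == 0L || n_negative(test) == 0L) next  # stays NA
      scores <- predict_scores(model, test)
      M[i, j] <- roc_auc(test$label, scores)
    }
  }
  structure(M, class = c("cross_species_matrix", "matrix"))
}

#' Write evaluation artifacts as CSV
#'
#' @param x a `cross_species_matrix` or `metrics_report`.
#' @param path output CSV path.
#' @export
write_cross_species_matrix <- function(x, path) {
  utils::write.csv(unclass(x), path, row.names = TRUE)
  invisible(path)
}
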