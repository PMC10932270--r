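#' Binary cross-entropy loss
#'
#' `L = -y * log(p) - (1 - y) * log(1 - p)`, elementwise over a vector of
#' predictions.  Probabilities outside `(0, 1)` are clamped to
#' `[1e-7, 1 - 1e-7]` with a warning, so the loss stays finite.
#'
#' @param p predicted probabilities of the positive class.
#' @param y binary labels (0/1), recycled against `p`.
#' @return Nonnegative per-sample losses (use `mean()` for the batch loss).
#' @export
binary_cross_entropy <- function(p, y) {
  eps <- 1e-7
  if (any(p <= 0 | p >= 1)) {
    warning("probabilities clamped to [1e-7, 1 - 1e-7] for numerical stability")
    p <- pmin(pmax(p, eps), 1 - eps)
  }
  -y * log(p) - (1 - y) * log(1 - p)
}

bce_mean <- function(p, y) {
  eps <- 1e-7
  p <- pmin(pmax(p, eps), 1 - eps)
  mean(-y * log(p) - (1 - y) * log(1 - p))
}

#' Fast-gradient-method perturbation
#'
#' Scales a loss gradient to an L2 magnitude of exactly `xi`:
#' `r_adv = sign * xi * g / ||g||2`.  The default sign is `+1`, the
#' loss-ascent (worst-case) direction; `paper_literal_sign = TRUE` gives the
#' descent-sign variant `-xi * g / ||g||2`.  A zero gradient has no
#' direction and returns a zero perturbation with a warning.
#'
#' @param g numeric gradient (vector, matrix or array).
#' @param xi perturbation magnitude (> 0).
#' @param paper_literal_sign use the descent sign.
#' @return Perturbation of the same shape as `g`, with `||r||2 == xi` for
#'   any nonzero `g`.
#' @export
fgm_perturbation <- function(g, xi, paper_literal_sign = FALSE) {
  if (any(!is.finite(g))) stop2("gradient contains non-finite values")
  if (xi <= 0) stop2("xi must be > 0")
  nrm <- sqrt(sum(g * g))
  if (nrm == 0) {
    warning("zero gradient: no perturbation direction, returning zeros")
    return(g)
  }
  s <- if (paper_literal_sign) -1 else 1
  s * xi * g / nrm
}

#' Mean adversarial loss over an epoch
#'
#' Averages per-batch adversarial cross-entropies, reported with the
#' standard nonnegative sign convention.
#'
#' @param per_batch_losses numeric vector of batch losses (length N >= 1).
#' @return Scalar mean loss.
#' @export
adversarial_epoch_loss <- function(per_batch_losses) {
  if (!length(per_batch_losses)) stop2("no batch losses supplied")
  mean(per_batch_losses)
}

#' One FGM training step
#'
#' The adversarial step runs (1) a clean forward/backward pass giving the
#' clean cross-entropy and the gradient `g` of the loss with respect to the
#' embedding output (the sequence representation); (2) an FGM perturbation
#' `r_adv` of L2 magnitude `xi` added to the embedding output (the
#' embedding tables themselves are never modified); (3) a perturbed
#' forward/backward pass giving the adversarial cross-entropy; (4) one Adam
#' update driven by the sum of both passes' gradients.  With
#' `adv_config$enabled = FALSE` the step reduces exactly to plain
#' cross-entropy training (single pass, `adv_loss == clean_loss`).
#'
#' @param model a `mod_transformer`.
#' @param batch list with `y` (labels) and, per scale key, `ids`/`mask`
#'   matrices (as built by the training loop).
#' @param adv_config an [adversarial_config()].
#' @param opt_state Adam state from a previous step, or `NULL` to start.
#' @return List with updated `model`, `opt_state`, `clean_loss`, `adv_loss`.
#' @export
adversarial_step <- function(model, batch, adv_config, opt_state = NULL) {
  fw <- model_forward(model, batch, want_cache = TRUE)
  clean_loss <- bce_mean(fw$p, batch$y)
  if (!is.finite(clean_loss)) stop2("non-finite clean loss; training aborted")
  bw <- model_backward(model, fw, batch$y)
  if (adv_config$enabled) {
    gnorm <- sqrt(sum(vapply(bw$dE, function(g) sum(g * g), numeric(1))))
    if (gnorm > 0) {
      s <- if (adv_config$paper_literal_sign) -1 else 1
      perturb <- lapply(bw$dE, function(g) s * adv_config$xi * g / gnorm)
    } else {
      perturb <- lapply(bw$dE, function(g) g * 0)
    }
    fw2 <- model_forward(model, batch, perturb = perturb, want_cache = TRUE)
    adv_loss <- bce_mean(fw2$p, batch$y)
    if (!is.finite(adv_loss)) stop2("non-finite adversarial loss; training aborted")
    bw2 <- model_backward(model, fw2, batch$y)
    grads <- tree_add(bw$grads, bw2$grads)
  } else {
    adv_loss <- clean_loss
    grads <- bw$grads
  }
  if (is.null(opt_state)) opt_state <- adam_init(grads)
  upd <- adam_step(model$params, grads, opt_state, adv_config$learning_rate)
  model$params <- upd$params
  list(model = model, opt_state = upd$state,
       clean_loss = clean_loss, adv_loss = adv_loss)
}

# Internal training loop over pre-tokenized matrices.  enc: per-scale list
# with ids/mask; y: labels.  Randomness (shuffles) comes from the caller's
# seeded RNG state.
train_loop <- function(model, enc, y, adv_config, verbose = FALSE) {
  n <- length(y)
  keys <- names(enc)
  opt_state <- NULL
  history <- data.frame()
  for (epoch in seq_len(adv_config$epochs)) {
    ord <- sample.int(n)
    starts <- seq(1L, n, by = adv_config$batch_size)
    clean <- adv <- numeric(length(starts))
    for (i in seq_along(starts)) {
      idx <- ord[starts[i]:min(starts[i] + adv_config$batch_size - 1L, n)]
      batch <- stats::setNames(lapply(keys, function(key) {
        list(ids = enc[[key]]$ids[idx, , drop = FALSE],
             mask = enc[[key]]$mask[idx, , drop = FALSE])
      }), keys)
      batch$y <- y[idx]
      step <- adversarial_step(model, batch, adv_config, opt_state)
      model <- step$model
      opt_state <- step$opt_state
      clean[i] <- step$clean_loss
      adv[i] <- step$adv_loss
    }
    history <- rbind(history, data.frame(
      epoch = epoch, clean_loss = mean(clean),
      adv_loss = adversarial_epoch_loss(adv), n_batches = length(starts)))
    if (verbose) {
      message(sprintf("  epoch %d: clean %.4f adv %.4f", epoch,
                      mean(clean), mean(adv)))
    }
  }
  list(model = model, history = history)
}

#' Train with stratified five-fold cross-validation
#'
#' For each fold the model is trained from fresh seeded weights on the
#' remaining folds and evaluated on the held-out fold (threshold metrics
#' plus ROC AUC); a final model is then refit on all records.  The input
#' dataset is expected to have passed [apply_ratio_policy()] already -- the
#' ratio policy belongs to training data only and is never applied here.
#'
#' @param dataset a [seq_dataset()].
#' @param config an [encoder_config()].
#' @param adv_config an [adversarial_config()]; its `seed` drives fold
#'   assignment, weight initialization and batch shuffling.
#' @param kmers one k or an ordered pair (fusion gate).
#' @param folds optional `fold_assignment`; built with
#'   [make_stratified_folds()] when omitted.
#' @param n_folds fold count when `folds` is omitted.
#' @param refit also fit a final model on all records (default `TRUE`).
#' @param verbose print per-epoch losses.
#' @return A `train_report`: list with `history` (per fold x epoch losses),
#'   `fold_metrics` (per-fold Sn/Sp/Acc/MCC/AUC), `mean_cv_auc`,
#'   `final_model` (or `NULL`), and the configurations used.
#' @export
train_model <- function(dataset, config = encoder_config("tiny"),
                        adv_config = adversarial_config(), kmers = 3L,
                        folds = NULL, n_folds = 5L, refit = TRUE,
                        verbose = FALSE) {
  kmers <- as.integer(kmers)
  folds <- folds %||% make_stratified_folds(dataset, n_folds,
                                            seed = derive_seed(adv_config$seed, 1L))
  proto <- build_model(config, kmers, seed = 0L)
  enc <- lapply(stats::setNames(as.character(kmers), as.character(kmers)),
                function(key) encode_dataset_matrix(dataset, proto$vocabs[[key]]))
  stream_len <- lapply(enc, `[[`, "max_len")
  y <- dataset$label
  fold_of <- folds$assignment[dataset$id]
  history <- data.frame()
  fold_metrics <- data.frame()
  for (f in 0:(folds$n_folds - 1L)) {
    tr <- which(fold_of != f)
    va <- which(fold_of == f)
    model <- build_model(config, kmers,
                         seed = derive_seed(adv_config$seed, 100L + f))
    model$stream_len <- stream_len
    enc_tr <- lapply(enc, function(e) {
      list(ids = e$ids[tr, , drop = FALSE], mask = e$mask[tr, , drop = FALSE])
    })
    fit <- with_seed(derive_seed(adv_config$seed, 200L + f),
                     train_loop(model, enc_tr, y[tr], adv_config, verbose))
    scores <- predict_scores(fit$model, subset_dataset(dataset, va))
    auc <- roc_auc(y[va], scores)
    mets <- classification_metrics(confusion(y[va], scores))
    history <- rbind(history, cbind(fold = f, fit$history))
    fold_metrics <- rbind(fold_metrics, data.frame(
      fold = f, n_val = length(va), auc = auc, acc = mets$Acc,
      sn = mets$Sn, sp = mets$Sp, mcc = mets$MCC))
  }
  final_model <- NULL
  if (refit) {
    final_model <- build_model(config, kmers,
                               seed = derive_seed(adv_config$seed, 999L))
    final_model$stream_len <- stream_len
    fit <- with_seed(derive_seed(adv_config$seed, 998L),
                     train_loop(final_model, enc, y, adv_config, verbose))
    final_model <- fit$model
    history <- rbind(history, cbind(fold = NA_integer_, fit$history))
  }
  structure(list(history = history, fold_metrics = fold_metrics,
                 mean_cv_auc = mean(fold_metrics$auc),
                 final_model = final_model, folds = folds,
                 encoder_config = config, adv_config = adv_config,
                 kmers = kmers),
            class = "train_report")
}

#' @export
print.train_report <- function(x, ...) {
  cat(sprintf("<train_report: %d folds, mean CV AUC %.3f%s>\n",
              x$folds$n_folds, x$mean_cv_auc,
              if (!is.null(x$final_model)) ", final model refit" else ""))
  print(x$fold_metrics, row.names = FALSE)
  invisible(x)
}

#' Fit one model without cross-validation
#'
#' Convenience wrapper used by the cross-species experiments: trains a
#' single model on the whole dataset.
#'
#' @inheritParams train_model
#' @return A trained `mod_transformer`.
#' @export
fit_model <- function(dataset, config = encoder_config("tiny"),
                      adv_config = adversarial_config(), kmers = 3L,
                      verbose = FALSE) {
  kmers <- as.integer(kmers)
  model <- build_model(config, kmers,
                       seed = derive_seed(adv_config$seed, 999L))
  enc <- lapply(model$vocabs, function(v) encode_dataset_matrix(dataset, v))
  model$stream_len <- lapply(enc, `[[`, "max_len")
  fit <- with_seed(derive_seed(adv_config$seed, 998L),
                   train_loop(model, enc, dataset$label, adv_config, verbose))
  fit$model
}

#' Export a training report as CSV
#'
#' @param report a `train_report`.
#' @param path output CSV path.
#' @export
write_train_report <- function(report, path) {
  utils::write.csv(merge(report$history, report$fold_metrics,
                         by = "fold", all.x = TRUE),
                   path, row.names = FALSE)
  invisible(path)
}
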