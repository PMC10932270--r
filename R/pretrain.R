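#' Small-scale masked-language-model pretraining
#'
#' Optional warm-up before classification fine-tuning: repeatedly masks
#' k-mer tokens (BERT 80/10/10 recipe, see [masked_lm_step()]) and updates
#' the encoder plus the MLM head by Adam on the masked-token
#' cross-entropy.  Intended for desk-scale experiments; genome-scale
#' pretraining is out of scope.
#'
#' @param model a `mod_transformer` built for a single scale.
#' @param dataset a [seq_dataset()] providing the unlabeled sequences.
#' @param epochs passes over the dataset.
#' @param mask_prob per-token masking probability.
#' @param learning_rate Adam learning rate.
#' @param batch_size sequences per update.
#' @param seed integer seed.
#' @param verbose print per-epoch loss.
#' @return List with the updated `model` and `history` (per-epoch mean
#'   masked-token loss).
#' @export
pretrain_mlm <- function(model, dataset, epochs = 2L, mask_prob = 0.15,
                         learning_rate = 2e-4, batch_size = 32L, seed = 1L,
                         verbose = FALSE) {
  key <- as.character(model$kmers[1])
  vocab <- model$vocabs[[key]]
  enc <- encode_dataset_matrix(dataset, vocab,
                               max_len = model$stream_len[[key]])
  model$stream_len <- stats::setNames(list(enc$max_len), key)
  V <- length(vocab$tokens)
  n <- nrow(enc$ids)
  opt_state <- NULL
  history <- numeric(epochs)
  with_seed(seed, {
    for (epoch in seq_len(epochs)) {
      ord <- sample.int(n)
      losses <- c()
      for (s in seq(1L, n, by = batch_size)) {
        idx <- ord[s:min(s + batch_size - 1L, n)]
        step <- mlm_train_step(model, enc$ids[idx, , drop = FALSE],
                               enc$mask[idx, , drop = FALSE], key, V,
                               mask_prob, opt_state, learning_rate)
        model <- step$model
        opt_state <- step$opt_state
        losses <- c(losses, step$loss)
      }
      history[epoch] <- mean(losses)
      if (verbose) message(sprintf("  mlm epoch %d: loss %.4f", epoch,
                                   history[epoch]))
    }
  })
  list(model = model, history = history)
}

# One masked-LM gradient step over a batch (uses the caller's RNG stream).
mlm_train_step <- function(model, ids, mask, key, V, mask_prob, opt_state,
                           learning_rate) {
  B <- nrow(ids); T_ <- ncol(ids)
  flat_ids <- as.vector(t(ids))
  flat_mask <- as.vector(t(mask))
  maskable <- which(flat_mask == 1L & flat_ids >= 5L)
  sel <- maskable[stats::runif(length(maskable)) < mask_prob]
  if (!length(sel)) sel <- sample(maskable, 1L)
  u <- stats::runif(length(sel))
  new_flat <- flat_ids
  new_flat[sel[u < 0.8]] <- MASK_ID
  rand <- sel[u >= 0.8 & u < 0.9]
  if (length(rand)) new_flat[rand] <- sample(5:(V - 1L), length(rand),
                                             replace = TRUE)
  new_ids <- matrix(new_flat, B, T_, byrow = TRUE)
  fw <- encoder_forward(model$params, model$config, new_ids, mask, key,
                        want_cache = TRUE, pooling = model$pooling)
  mlm <- model$params$mlm[[key]]
  H <- fw$X[sel, , drop = FALSE]
  logits <- H %*% mlm$W + row_bc(mlm$b, length(sel))
  logits <- logits - apply(logits, 1L, max)
  P <- exp(logits)
  P <- P / rowSums(P)
  tgt <- cbind(seq_along(sel), flat_ids[sel] + 1L)
  loss <- -mean(log(pmax(P[tgt], 1e-12)))
  dlogits <- P
  dlogits[tgt] <- dlogits[tgt] - 1
  dlogits <- dlogits / length(sel)
  dX <- matrix(0, B * T_, ncol(H))
  dX[sel, ] <- dlogits %*% t(mlm$W)
  bw <- encoder_backward(dX, NULL, fw, model$params, model$config,
                         pooling = model$pooling)
  grads <- list(emb = stats::setNames(list(bw$emb), key), pos = bw$pos,
                layers = bw$layers,
                mlm = stats::setNames(
                  list(list(W = crossprod(H, dlogits),
                            b = colSums(dlogits))), key))
  if (is.null(opt_state)) opt_state <- adam_init(grads)
  upd <- adam_step(model$params, grads, opt_state, learning_rate)
  model$params <- upd$params
  list(model = model, opt_state = upd$state, loss = loss)
}
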