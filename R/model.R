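#' Build a k-mer transformer classifier
#'
#' Assembles the full model: per-scale token-embedding tables, shared
#' position embeddings, a stack of post-layer-norm transformer encoder
#' layers (shared between the two scales when a scale pair is given), the
#' sigmoid fusion gate that blends the two pooled scale representations,
#' and a logistic classification head.  A masked-language-model head
#' (zero-initialized) is attached for optional small-scale pretraining.
#'
#' @param config an [encoder_config()].
#' @param kmers a single k in `[3, 6]`, or an ordered pair `c(k1, k2)` of
#'   distinct scales that engages the fusion gate.
#' @param seed integer seed for weight initialization.
#' @param pooling `"cls"` (default; the `[CLS]` position representation) or
#'   `"mean"` (mask-aware mean over content tokens).
#' @param gate `"vector"` (elementwise gate, default) or `"scalar"`
#'   (single shared gate component).
#' @return A `mod_transformer` model object.
#' @export
build_model <- function(config = encoder_config("tiny"), kmers = 3L,
                        seed = 0L, pooling = c("cls", "mean"),
                        gate = c("vector", "scalar")) {
  pooling <- match.arg(pooling)
  gate <- match.arg(gate)
  kmers <- as.integer(kmers)
  if (!length(kmers) %in% 1:2) stop2("kmers must be one k or a pair")
  if (length(kmers) == 2L && kmers[1] == kmers[2]) {
    stop2("the two fusion scales must differ")
  }
  vocabs <- stats::setNames(lapply(kmers, build_vocab), as.character(kmers))
  d <- config$hidden_dim
  params <- with_seed(seed, {
    p <- list(
      emb = lapply(vocabs, function(v) {
        matrix(stats::rnorm(length(v$tokens) * d, sd = 0.02),
               length(v$tokens), d)
      }),
      pos = matrix(stats::rnorm(config$max_tokens * d, sd = 0.02),
                   config$max_tokens, d),
      layers = lapply(seq_len(config$n_layers), function(i) {
        init_layer_params(d, config$intermediate_dim)
      }),
      head = list(w = matrix(stats::rnorm(d, sd = 0.02), d, 1),
                  b = 0))
    if (length(kmers) == 2L) {
      gd <- if (gate == "scalar") 1L else d
      p$gate <- list(W1 = matrix(0, d, gd), W2 = matrix(0, d, gd))
    }
    p$mlm <- lapply(vocabs, function(v) {
      list(W = matrix(0, d, length(v$tokens)), b = numeric(length(v$tokens)))
    })
    p
  })
  structure(list(config = config, kmers = kmers, vocabs = vocabs,
                 params = params, pooling = pooling, gate = gate,
                 seed = as.integer(seed), stream_len = NULL),
            class = "mod_transformer")
}

#' @export
print.mod_transformer <- function(x, ...) {
  cat(sprintf(
    "<mod_transformer: scales [%s]%s, %d layers, hidden %d, pooling '%s', %s parameters>\n",
    paste(x$kmers, collapse = ", "),
    if (length(x$kmers) == 2L) " with fusion gate" else "",
    x$config$n_layers, x$config$hidden_dim, x$pooling,
    format(n_model_params(x), big.mark = ",")))
  invisible(x)
}

#' @rdname build_model
#' @param model a `mod_transformer`.
#' @export
n_model_params <- function(model) {
  cnt <- function(x) if (is.list(x)) sum(vapply(x, cnt, numeric(1))) else length(x)
  cnt(model$params[setdiff(names(model$params), "mlm")])
}

#' Run the encoder over one tokenized sequence
#'
#' Exposes the raw encoder: final-layer hidden states, the pooled sequence
#' vector and every layer's per-head attention matrices (each attention row
#' sums to 1 over unmasked positions).
#'
#' @param model a [build_model()] model.
#' @param tokens a `tokenized_seq` from [encode_tokens()] at a scale the
#'   model was built for.
#' @return An `encoder_output`: list with `hidden_states` (T x d),
#'   `pooled` (length d), `attentions` (per layer, `n_heads x T x T`
#'   arrays) and `attention_mask`.
#' @export
encode <- function(model, tokens) {
  stopifnot(inherits(tokens, "tokenized_seq"))
  key <- as.character(tokens$k)
  if (!key %in% names(model$vocabs)) {
    stop2("model has no scale k = ", tokens$k)
  }
  fw <- encoder_forward(model$params, model$config,
                        matrix(tokens$ids, nrow = 1),
                        matrix(tokens$attention_mask, nrow = 1),
                        key, want_attn = TRUE, pooling = model$pooling)
  structure(list(hidden_states = fw$X,
                 pooled = drop(fw$pooled),
                 attentions = lapply(fw$attn, function(layer) {
                   aperm(simplify2array(layer[[1L]]), c(3L, 1L, 2L))
                 }),
                 attention_mask = tokens$attention_mask),
            class = "encoder_output")
}

#' Sigmoid fusion gate for two scale representations
#'
#' Combines the pooled representations of two k-mer scales.  The gate is
#' `F = sigmoid(h1 W1 + h2 W2)` and the fused representation the convex
#' blend `h_M = F * h1 + (1 - F) * h2` (elementwise), so each component of
#' `h_M` lies between the corresponding components of `h1` and `h2`.
#' With zero gate weights `F = 0.5` everywhere and `h_M` is the plain
#' average.
#'
#' @param h1,h2 numeric vectors (or row-matrices) of equal width `d`.
#' @param params list with `W1`, `W2`: `d x d` maps for a vector gate, or
#'   `d x 1` for a scalar gate (the single component is broadcast).
#' @return List with `gate` (values strictly in (0, 1)) and `fused`.
#' @export
fusion_gate <- function(h1, h2, params) {
  v1 <- is.vector(h1)
  if (v1) { h1 <- matrix(h1, nrow = 1); h2 <- matrix(h2, nrow = 1) }
  if (!identical(dim(h1), dim(h2))) stop2("h1 and h2 must have equal shape")
  if (nrow(params$W1) != ncol(h1)) {
    stop2("gate parameters expect width ", nrow(params$W1),
          ", got ", ncol(h1))
  }
  Fg <- sigmoid(h1 %*% params$W1 + h2 %*% params$W2)
  if (ncol(Fg) == 1L && ncol(h1) > 1L) {
    Fg <- matrix(Fg, nrow(h1), ncol(h1))  # scalar gate broadcast
  }
  fused <- Fg * h1 + (1 - Fg) * h2
  if (v1) list(gate = drop(Fg), fused = drop(fused))
  else list(gate = Fg, fused = fused)
}

#' Classification head
#'
#' Maps a pooled (or fused) representation to the predicted probability of
#' the positive (modified) class through a logistic unit.
#'
#' @param model a `mod_transformer`.
#' @param h numeric vector of width `hidden_dim`, or a row-matrix of them.
#' @return Probabilities in (0, 1).
#' @export
classify <- function(model, h) {
  if (is.vector(h)) h <- matrix(h, nrow = 1)
  drop(sigmoid(h %*% model$params$head$w + model$params$head$b))
}

# ---- joint forward / backward over one batch ---------------------------

# batch: list with, per scale key, list(ids = B x T, mask = B x T), plus y.
model_forward <- function(model, batch, perturb = NULL, want_cache = FALSE,
                          want_attn = FALSE) {
  keys <- as.character(model$kmers)
  encs <- lapply(keys, function(key) {
    encoder_forward(model$params, model$config,
                    batch[[key]]$ids, batch[[key]]$mask, key,
                    perturb = perturb[[key]],
                    want_cache = want_cache, want_attn = want_attn,
                    pooling = model$pooling)
  })
  names(encs) <- keys
  if (length(keys) == 2L) {
    fg <- fusion_gate(encs[[1]]$pooled, encs[[2]]$pooled, model$params$gate)
    h <- fg$fused
    gate <- fg$gate
  } else {
    h <- encs[[1]]$pooled
    gate <- NULL
  }
  logit <- h %*% model$params$head$w + model$params$head$b
  list(p = drop(sigmoid(logit)), h = h, gate = gate, encs = encs)
}

model_backward <- function(model, fw, y) {
  keys <- as.character(model$kmers)
  B <- length(y)
  dlogit <- matrix((fw$p - y) / B, ncol = 1)
  dh <- dlogit %*% t(model$params$head$w)
  grads <- list(head = list(w = crossprod(fw$h, dlogit), b = sum(dlogit)))
  if (length(keys) == 2L) {
    p1 <- fw$encs[[1]]$pooled; p2 <- fw$encs[[2]]$pooled
    Fg <- fw$gate
    scalar <- ncol(model$params$gate$W1) == 1L
    dFg <- dh * (p1 - p2)
    if (scalar) {
      dz <- matrix(rowSums(dFg * Fg * (1 - Fg)), ncol = 1)
      Fg1 <- Fg
    } else {
      dz <- dFg * Fg * (1 - Fg)
      Fg1 <- Fg
    }
    grads$gate <- list(W1 = crossprod(p1, dz), W2 = crossprod(p2, dz))
    dp1 <- dh * Fg1 + dz %*% t(model$params$gate$W1)
    dp2 <- dh * (1 - Fg1) + dz %*% t(model$params$gate$W2)
    dpooled <- list(dp1, dp2)
  } else {
    dpooled <- list(dh)
  }
  dE <- list()
  for (i in seq_along(keys)) {
    bw <- encoder_backward(NULL, dpooled[[i]], fw$encs[[i]],
                           model$params, model$config,
                           pooling = model$pooling)
    dE[[keys[i]]] <- bw$dE
    if (i == 1L) {
      grads$layers <- bw$layers
      grads$pos <- bw$pos
      grads$emb <- stats::setNames(list(bw$emb), keys[i])
    } else {
      grads$layers <- tree_add(grads$layers, bw$layers)
      grads$pos <- grads$pos + bw$pos
      grads$emb[[keys[i]]] <- bw$emb
    }
  }
  list(grads = grads, dE = dE)
}

#' Masked-language-model loss for one sequence
#'
#' Implements the BERT masking recipe for optional small-scale pretraining:
#' each content k-mer token is selected independently with probability
#' `mask_prob` (at least one is always selected); of the selected tokens
#' 80% are replaced by `[MASK]`, 10% by a random k-mer id and 10% left
#' unchanged.  Returns the mean cross-entropy of the model's vocabulary
#' predictions at the selected positions.
#'
#' @param model a `mod_transformer`.
#' @param tokens a `tokenized_seq` at one of the model's scales.
#' @param mask_prob masking probability in (0, 1).
#' @param seed integer seed for the token selection.
#' @return Scalar loss (nonnegative); with an untrained (zero) MLM head the
#'   per-token loss equals `log(vocab_size)`.
#' @export
masked_lm_step <- function(model, tokens, mask_prob = 0.15, seed = 1L) {
  if (mask_prob <= 0 || mask_prob >= 1) stop2("mask_prob must be in (0, 1)")
  key <- as.character(tokens$k)
  if (!key %in% names(model$vocabs)) stop2("model has no scale k = ", tokens$k)
  V <- length(model$vocabs[[key]]$tokens)
  ids <- tokens$ids
  maskable <- which(tokens$attention_mask == 1L & ids >= 5L)
  if (!length(maskable)) stop2("sequence has no maskable (non-special) tokens")
  with_seed(seed, {
    sel <- maskable[stats::runif(length(maskable)) < mask_prob]
    if (!length(sel)) sel <- sample(maskable, 1L)
    u <- stats::runif(length(sel))
    new_ids <- ids
    new_ids[sel[u < 0.8]] <- MASK_ID
    rand <- sel[u >= 0.8 & u < 0.9]
    if (length(rand)) {
      new_ids[rand] <- sample(5:(V - 1L), length(rand), replace = TRUE)
    }
    fw <- encoder_forward(model$params, model$config,
                          matrix(new_ids, nrow = 1),
                          matrix(tokens$attention_mask, nrow = 1),
                          key, pooling = model$pooling)
    logits <- fw$X[sel, , drop = FALSE] %*% model$params$mlm[[key]]$W +
      row_bc(model$params$mlm[[key]]$b, length(sel))
    logits <- logits - apply(logits, 1L, max)
    logp <- logits - log(rowSums(exp(logits)))
    -mean(logp[cbind(seq_along(sel), ids[sel] + 1L)])
  })
}

#' Predict modification probabilities for a dataset
#'
#' Tokenizes `dataset` at the model's scale(s) and returns the predicted
#' probability of the positive class for every record.  Evaluation is
#' batched to bound memory.
#'
#' @param model a trained `mod_transformer`.
#' @param dataset a [seq_dataset()].
#' @param batch_size evaluation batch size.
#' @return Named numeric vector of probabilities (names = record ids).
#' @export
predict_scores <- function(model, dataset, batch_size = 256L) {
  enc <- tokenize_for_model(model, dataset)
  n <- nrow(dataset)
  out <- numeric(n)
  starts <- seq(1L, n, by = batch_size)
  for (s in starts) {
    idx <- s:min(s + batch_size - 1L, n)
    batch <- lapply(enc, function(e) {
      list(ids = e$ids[idx, , drop = FALSE], mask = e$mask[idx, , drop = FALSE])
    })
    out[idx] <- model_forward(model, batch)$p
  }
  names(out) <- dataset$id
  out
}

# Tokenize a dataset at every model scale, honouring the stream length the
# model was trained with (so position embeddings line up).
tokenize_for_model <- function(model, dataset) {
  keys <- as.character(model$kmers)
  out <- lapply(keys, function(key) {
    len <- model$stream_len[[key]]
    encode_dataset_matrix(dataset, model$vocabs[[key]], max_len = len)
  })
  names(out) <- keys
  out
}

#' Save / load a model checkpoint
#'
#' The checkpoint is an RDS file holding the weights plus a plain-text YAML
#' sidecar (`<path>.yaml`) echoing the configuration, so runs remain
#' auditable without deserializing the weights.
#'
#' @param model a `mod_transformer`.
#' @param path checkpoint path.
#' @return `save_checkpoint()` the path, invisibly; `load_checkpoint()` the
#'   model.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(model, path)
  yaml::write_yaml(
    list(kmers = model$kmers, pooling = model$pooling, gate = model$gate,
         seed = model$seed,
         config = unclass(model$config)),
    paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "mod_transformer")) stop2("not a model checkpoint: ", path)
  model
}
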