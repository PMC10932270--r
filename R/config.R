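#' Encoder hyperparameter configuration
#'
#' Two presets are provided.  `"full"` mirrors the original BERT-base
#' geometry used by DNA language models: 12 layers, 12 heads, hidden width
#' 768, feed-forward width 3072, up to 512 tokens.  `"tiny"` is a desk-scale
#' model (2 layers, 4 heads, hidden 64) that trains in minutes on one CPU
#' and is used throughout the test-bench experiments.
#'
#' @param preset `"tiny"` or `"full"`.
#' @param n_layers,n_heads,hidden_dim,intermediate_dim,max_tokens,dropout
#'   optional overrides of the preset values; `hidden_dim` must be divisible
#'   by `n_heads`.
#' @return An `encoder_config` list.
#' @export
encoder_config <- function(preset = c("tiny", "full"), n_layers = NULL,
                           n_heads = NULL, hidden_dim = NULL,
                           intermediate_dim = NULL, max_tokens = NULL,
                           dropout = NULL) {
  preset <- match.arg(preset)
  base <- if (preset == "full") {
    list(n_layers = 12L, n_heads = 12L, hidden_dim = 768L,
         intermediate_dim = 3072L, max_tokens = 512L, dropout = 0.1)
  } else {
    list(n_layers = 2L, n_heads = 4L, hidden_dim = 64L,
         intermediate_dim = 128L, max_tokens = 64L, dropout = 0)
  }
  cfg <- list(preset = preset,
              n_layers = as.integer(n_layers %||% base$n_layers),
              n_heads = as.integer(n_heads %||% base$n_heads),
              hidden_dim = as.integer(hidden_dim %||% base$hidden_dim),
              intermediate_dim = as.integer(intermediate_dim %||% base$intermediate_dim),
              max_tokens = as.integer(max_tokens %||% base$max_tokens),
              dropout = dropout %||% base$dropout)
  if (cfg$hidden_dim %% cfg$n_heads != 0L) {
    stop2("hidden_dim must be divisible by n_heads")
  }
  if (cfg$dropout < 0 || cfg$dropout >= 1) stop2("dropout must be in [0, 1)")
  structure(cfg, class = "encoder_config")
}

#' @export
print.encoder_config <- function(x, ...) {
  cat(sprintf("<encoder_config '%s': %d layers, %d heads, hidden %d, ff %d, max %d tokens>\n",
              x$preset, x$n_layers, x$n_heads, x$hidden_dim,
              x$intermediate_dim, x$max_tokens))
  invisible(x)
}

#' Adversarial fine-tuning configuration
#'
#' Settings of the FGM training loop.  `xi` is the L2 magnitude of the
#' embedding-space perturbation (in embedding-norm units; 0.1, 0.5 and 1.0
#' are the conventional sweep, with 0.1 the default that keeps from-scratch
#' training stable).  The default
#' perturbation direction is the loss-ascent direction `+xi * g / ||g||2`,
#' the worst-case reading of the fast gradient method; set
#' `paper_literal_sign = TRUE` to use the descent sign `-xi * g / ||g||2`
#' instead.
#'
#' @param xi perturbation magnitude (> 0 when enabled).
#' @param enabled apply FGM perturbation during training.
#' @param epochs,batch_size,learning_rate Adam training-loop settings.
#' @param seed integer seed controlling every random choice of the run.
#' @param paper_literal_sign use the descent-sign perturbation.
#' @return An `adversarial_config` list.
#' @export
adversarial_config <- function(xi = 0.1, enabled = TRUE, epochs = 10L,
                               batch_size = 32L, learning_rate = 1e-3,
                               seed = 1L, paper_literal_sign = FALSE) {
  if (enabled && xi <= 0) stop2("xi must be > 0 when adversarial training is enabled")
  structure(list(xi = xi, enabled = isTRUE(enabled),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, seed = as.integer(seed),
                 paper_literal_sign = isTRUE(paper_literal_sign)),
            class = "adversarial_config")
}

#' @export
print.adversarial_config <- function(x, ...) {
  cat(sprintf("<adversarial_config: FGM %s (xi=%g), %d epochs, batch %d, lr %g, seed %d>\n",
              if (x$enabled) "on" else "off", x$xi, x$epochs, x$batch_size,
              x$learning_rate, x$seed))
  invisible(x)
}
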