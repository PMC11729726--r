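#' Model configuration
#'
#' Hyperparameters of the feed-forward-transformer squiggle generator. The
#' encoder and decoder each stack `n_enc_blocks`/`n_dec_blocks`
#' feed-forward-transformer blocks (multi-head self-attention plus a
#' position-wise feed-forward sublayer, residual connections and post-layer
#' normalization). `chunk_len` tokens (k-mers) are processed per window and
#' the length regulator may expand them to at most `max_expanded` signal
#' points at inference (`max_signal` caps training chunks).
#'
#' @param k k-mer size.
#' @param d_model hidden width (must be divisible by `n_heads`).
#' @param n_heads attention heads.
#' @param n_enc_blocks,n_dec_blocks encoder/decoder block counts (default 2+2).
#' @param d_ff feed-forward inner width.
#' @param d_head hidden width of the duration and noise sampler heads
#'   (default `2 * d_model`; the heads must resolve individual k-mers, so
#'   they benefit from extra width).
#' @param chunk_len tokens per window (default 16).
#' @param max_signal training signal-point cap per chunk (default 250).
#' @param max_expanded inference expansion cap per window.
#' @return An object of class `model_config`.
#' @export
model_config <- function(k, d_model = 256L, n_heads = 2L, n_enc_blocks = 2L,
                         n_dec_blocks = 2L, d_ff = 1024L,
                         d_head = 2L * d_model, chunk_len = 16L,
                         max_signal = 250L, max_expanded = 2000L) {
  stopifnot(d_model %% n_heads == 0, d_model > 0, n_heads > 0, d_ff > 0,
            d_head > 0, k >= 1, chunk_len >= 1, max_signal >= 1,
            max_expanded >= 1)
  structure(list(k = as.integer(k), d_model = as.integer(d_model),
                 n_heads = as.integer(n_heads),
                 n_enc_blocks = as.integer(n_enc_blocks),
                 n_dec_blocks = as.integer(n_dec_blocks),
                 d_ff = as.integer(d_ff), d_head = as.integer(d_head),
                 chunk_len = as.integer(chunk_len),
                 max_signal = as.integer(max_signal),
                 max_expanded = as.integer(max_expanded)),
            class = "model_config")
}

#' Initialise a squiggle model
#'
#' Builds a freshly initialised feed-forward-transformer with the given
#' configuration and pore profile. Weights are Glorot/He initialised from the
#' current RNG state (pass `seed` for reproducibility).
#'
#' @param config a [model_config()] (its `k` must match `profile$k`).
#' @param profile a [pore_profile()].
#' @param seed optional integer seed for weight initialisation.
#' @return An object of class `squiggle_model`: list with `config`,
#'   `profile`, `vocab` and the weight tree `params`.
#' @export
squiggle_model <- function(config, profile, seed = NULL) {
  stopifnot(inherits(config, "model_config"), inherits(profile, "pore_profile"))
  if (config$k != profile$k) {
    stop("config k (", config$k, ") does not match profile k (", profile$k, ")")
  }
  d <- config$d_model; d_in <- config$k * 5L; dh <- config$d_head
  # output biases of the sampler heads start at domain-typical values
  # (dwell ~9 samples => gamma(6, 0.67); amplitude sigma ~0.15 model units)
  # so training only has to learn per-k-mer deviations
  sp_inv <- function(y) log(expm1(y))
  params <- with_seed(seed, {
    list(
      We = init_linear(d_in, d, gain = sqrt(2)), be = rep(0, d),
      dur = list(W1 = init_linear(d, dh, gain = sqrt(2)), b1 = rep(0, dh),
                 W2 = init_linear(dh, 2L),
                 b2 = c(sp_inv(6), sp_inv(2 / 3))),
      sig = list(W1 = init_linear(d, dh, gain = sqrt(2)), b1 = rep(0, dh),
                 W2 = init_linear(dh, 1L), b2 = sp_inv(0.15)),
      enc = lapply(seq_len(config$n_enc_blocks),
                   function(i) init_block(d, config$d_ff)),
      dec = lapply(seq_len(config$n_dec_blocks),
                   function(i) init_block(d, config$d_ff)),
      proj_W = init_linear(d, 1L), proj_b = 0)
  })
  structure(list(config = config, profile = profile, vocab = vocabulary(),
                 params = params),
            class = "squiggle_model")
}

#' @export
print.squiggle_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<squiggle_model> k=%d d_model=%d heads=%d blocks=%d+%d d_ff=%d (%d parameters)\n",
    cfg$k, cfg$d_model, cfg$n_heads, cfg$n_enc_blocks, cfg$n_dec_blocks,
    cfg$d_ff, length(flatten_params(x$params))))
  invisible(x)
}

# positivity transform for alpha/beta: softplus plus a small epsilon
pos_eps <- 1e-6

#' Embed an encoded chunk
#'
#' Maps the flattened one-hot encoding of a chunk's tokens to hidden states
#' through a shared dense layer with ReLU activation (one hidden vector per
#' token position).
#'
#' @param model a [squiggle_model()].
#' @param encoded output of [encode_tokens()] (flat vector) or its matrix
#'   form (`chunk_len` x `k*5`).
#' @return Numeric matrix `chunk_len` x `d_model`, entries >= 0.
#' @export
embed <- function(model, encoded) {
  d_in <- model$config$k * 5L
  if (is.null(dim(encoded))) {
    if (length(encoded) %% d_in != 0) {
      stop("encoded length ", length(encoded), " is not a multiple of k*5 = ", d_in)
    }
    encoded <- matrix(encoded, ncol = d_in, byrow = TRUE)
  }
  if (ncol(encoded) != d_in) stop("encoded chunk has wrong width")
  relu_(add_bias(encoded %*% model$params$We, model$params$be))
}

#' Apply one feed-forward-transformer block
#'
#' Runs a single block (self-attention + position-wise feed-forward, each
#' with residual connection and layer normalization) from the encoder or
#' decoder stack over a hidden-state sequence.
#'
#' @param model a [squiggle_model()].
#' @param H hidden-state matrix (positions x `d_model`).
#' @param stage `"encoder"` or `"decoder"`.
#' @param block block index (1-based).
#' @return Matrix of the same shape as `H`.
#' @export
fft_block <- function(model, H, stage = c("encoder", "decoder"), block = 1L) {
  stage <- match.arg(stage)
  if (!nrow(H)) stop("empty hidden sequence")
  blk <- if (stage == "encoder") model$params$enc[[block]] else
    model$params$dec[[block]]
  fft_block_fwd(H, blk, list(seq_len(nrow(H))), model$config$n_heads)$out
}

#' Run the FFT encoder
#'
#' Adds sinusoidal positional encodings and applies the encoder blocks.
#'
#' @inheritParams fft_block
#' @return Matrix of the same shape as `H`.
#' @export
encode <- function(model, H) {
  H <- H + posenc(nrow(H), ncol(H))
  for (blk in model$params$enc) {
    H <- fft_block_fwd(H, blk, list(seq_len(nrow(H))), model$config$n_heads)$out
  }
  H
}

#' Length regulator
#'
#' Expands a hidden-state sequence to signal length by repeating position
#' `i`'s vector `durations[i]` times, preserving order.
#'
#' @param H hidden-state matrix (positions x d).
#' @param durations non-negative integer vector, one per row of `H`.
#' @return Matrix with `sum(durations)` rows.
#' @export
length_regulate <- function(H, durations) {
  stopifnot(nrow(H) == length(durations), all(durations >= 0))
  if (sum(durations) == 0) stop("all durations are zero; nothing to expand")
  H[rep(seq_len(nrow(H)), times = durations), , drop = FALSE]
}

#' Run the FFT decoder
#'
#' Adds positional encodings to the expanded hidden states, applies the
#' decoder blocks and projects each time step to one signal value.
#'
#' @param model a [squiggle_model()].
#' @param H_expanded expanded hidden states (T x `d_model`).
#' @param cap expansion cap; defaults to the config's `max_expanded`.
#' @return Numeric vector of length `nrow(H_expanded)` (the predicted signal).
#' @export
decode <- function(model, H_expanded, cap = model$config$max_expanded) {
  T_ <- nrow(H_expanded)
  if (T_ < 1) stop("empty expanded sequence")
  if (T_ > cap) {
    stop("expanded length ", T_, " exceeds the cap of ", cap,
         "; split the input into smaller chunks")
  }
  H <- H_expanded + posenc(T_, ncol(H_expanded))
  for (blk in model$params$dec) {
    H <- fft_block_fwd(H, blk, list(seq_len(T_)), model$config$n_heads)$out
  }
  as.vector(add_bias(H %*% model$params$proj_W, model$params$proj_b))
}

# shared two-layer head (dense-ReLU-dense) on the embedding
head_forward <- function(H, head) {
  h1 <- relu_(add_bias(H %*% head$W1, head$b1))
  add_bias(h1 %*% head$W2, head$b2)
}

#' Predict event-duration gamma parameters
#'
#' The duration sampler head: two dense layers with ReLU on the DNA
#' embedding, producing per-position shape \eqn{\alpha} and rate
#' \eqn{\beta} of the event-length gamma distribution (made strictly
#' positive by a softplus transform).
#'
#' @param model a [squiggle_model()].
#' @param H embedding output ([embed()]), positions x `d_model`.
#' @return List with numeric vectors `alpha` and `beta` (all > 0).
#' @export
predict_durations <- function(model, H) {
  raw <- head_forward(H, model$params$dur)
  list(alpha = softplus(raw[, 1]) + pos_eps,
       beta = softplus(raw[, 2]) + pos_eps)
}

#' Predict per-position amplitude-noise level
#'
#' The noise sampler head: two dense layers with ReLU on the DNA embedding,
#' predicting the standard deviation \eqn{\sigma} of the Gaussian amplitude
#' noise for each position.
#'
#' @inheritParams predict_durations
#' @return Numeric vector of non-negative `sigma_pred`, one per position.
#' @export
predict_sigma <- function(model, H) {
  as.vector(softplus(head_forward(H, model$params$sig)))
}

#' Sample integer event durations
#'
#' In `"stochastic"` mode draws each duration from Gamma(shape
#' \eqn{\alpha}, rate \eqn{\beta}), rounds to the nearest integer
#' (half-to-even) and clamps to >= 1. In `"ideal"` mode uses the
#' distribution mean \eqn{\alpha/\beta}, rounded and clamped the same way.
#' Padded positions (`pad`) get duration 0.
#'
#' @param params list with `alpha`, `beta` (from [predict_durations()]).
#' @param mode `"stochastic"` or `"ideal"`.
#' @param pad logical vector marking `"_"` positions (default none).
#' @param raw if `TRUE`, return the continuous pre-rounding draws
#'   (stochastic mode) or means (ideal mode) instead of integers.
#' @return Integer vector of durations (or numeric when `raw = TRUE`).
#' @export
sample_durations <- function(params, mode = c("stochastic", "ideal"),
                             pad = NULL, raw = FALSE) {
  mode <- match.arg(mode)
  a <- params$alpha; b <- params$beta
  stopifnot(length(a) == length(b), all(a > 0), all(b > 0))
  x <- if (mode == "stochastic") stats::rgamma(length(a), shape = a, rate = b)
       else a / b
  if (raw) return(x)
  d <- pmax(as.integer(round(x)), 1L)
  if (!is.null(pad)) d[pad] <- 0L
  d
}

#' Add per-event Gaussian amplitude noise
#'
#' Every signal sample belonging to event `i` receives an independent
#' Normal(0, `sigma[i]`) increment (mode `"on"`); mode `"off"` returns the
#' signal unchanged.
#'
#' @param s signal vector; `length(s)` must equal `sum(durations)`.
#' @param sigma per-event noise SD (>= 0), one per duration entry.
#' @param durations integer samples-per-event.
#' @param mode `"on"` or `"off"`.
#' @return Noised signal vector.
#' @export
add_noise <- function(s, sigma, durations, mode = c("on", "off")) {
  mode <- match.arg(mode)
  if (length(s) != sum(durations)) {
    stop("length(s) = ", length(s), " but sum(durations) = ", sum(durations))
  }
  if (mode == "off") return(s)
  stopifnot(length(sigma) == length(durations), all(sigma >= 0))
  s + stats::rnorm(length(s), mean = 0, sd = rep(sigma, times = durations))
}

#' Save / load a model checkpoint
#'
#' Checkpoints are single-file RDS containers with a versioned header
#' holding the weight tree, [model_config()], [pore_profile()] and the
#' vocabulary.
#'
#' @param model a [squiggle_model()].
#' @param path file path.
#' @return `load_checkpoint` returns the `squiggle_model`.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "squiggle_model"))
  saveRDS(list(.format = "squigglesim_checkpoint", .version = 1L,
               config = unclass(model$config),
               profile = unclass(model$profile),
               vocab = model$vocab, params = model$params), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  x <- readRDS(path)
  if (!identical(x$.format, "squigglesim_checkpoint")) {
    stop("not a squigglesim checkpoint: ", path)
  }
  structure(list(config = structure(x$config, class = "model_config"),
                 profile = structure(x$profile, class = "pore_profile"),
                 vocab = x$vocab, params = x$params),
            class = "squiggle_model")
}
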