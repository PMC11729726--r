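#' Training configuration
#'
#' @param tau duration-loss scale factor (default 0.0005).
#' @param batch_size chunks per optimisation step.
#' @param max_steps number of optimisation steps.
#' @param learning_rate peak Adam learning rate.
#' @param warmup_steps linear learning-rate warmup length.
#' @param seed RNG seed for batching and initial shuffling.
#' @param val_interval validate every this many steps (0 = never).
#' @param clip_norm global gradient-norm clip (default 1.0).
#' @return An object of class `train_config`.
#' @export
train_config <- function(tau = 5e-4, batch_size = 16L, max_steps = 1000L,
                         learning_rate = 1e-4, warmup_steps = 1000L,
                         seed = 1L, val_interval = 0L, clip_norm = 1.0) {
  stopifnot(tau > 0, batch_size >= 1, max_steps >= 1, learning_rate >= 0)
  structure(list(tau = tau, batch_size = as.integer(batch_size),
                 max_steps = as.integer(max_steps),
                 learning_rate = learning_rate,
                 warmup_steps = as.integer(warmup_steps),
                 seed = as.integer(seed),
                 val_interval = as.integer(val_interval),
                 clip_norm = clip_norm),
            class = "train_config")
}

# Pre-encode a chunk store for training: one-hot rows stacked chunk-major.
prepare_store <- function(store, k) {
  uniq <- unique(as.vector(store$tokens))
  enc_map <- encode_tokens_matrix(uniq, k)
  rownames(enc_map) <- uniq
  idx <- match(as.vector(t(store$tokens)), uniq)  # chunk-major order
  X <- enc_map[idx, , drop = FALSE]
  rownames(X) <- NULL
  list(X = X, durations = store$durations, sigma = store$sigma,
       signal = store$signal, mask = store$mask,
       P = store$chunk_len, N = nrow(store$tokens))
}

# Assemble the stacked batch tensors for a set of chunk indices.
make_batch <- function(prep, ids) {
  P <- prep$P
  rows <- as.vector(vapply(ids, function(b) (b - 1L) * P + seq_len(P),
                           integer(P)))
  dur <- prep$durations[ids, , drop = FALSE]
  sig <- prep$sigma[ids, , drop = FALSE]
  Tb <- rowSums(dur)
  sm <- t(prep$signal[ids, , drop = FALSE])
  mm <- t(prep$mask[ids, , drop = FALSE])
  list(X = prep$X[rows, , drop = FALSE],
       reps = as.vector(t(dur)),            # chunk-major durations
       sigma_ref = as.vector(t(sig)),
       target = as.vector(sm)[as.vector(mm)],  # concatenated real samples
       Tb = Tb, B = length(ids), P = P)
}

# Full forward (teacher-forced durations) and optional backward pass over a
# stacked batch. Returns the loss report and, when grads=TRUE, the gradient
# tree matching model$params.
forward_backward <- function(model, batch, tau, grads = TRUE) {
  p <- model$params; cfg <- model$config
  B <- batch$B; P <- batch$P
  nh <- cfg$n_heads
  reps <- batch$reps
  rp <- reps > 0                       # real (non-padded) positions

  ## embedding + heads
  H0pre <- add_bias(batch$X %*% p$We, p$be)
  H0 <- relu_(H0pre)
  d1pre_d <- add_bias(H0 %*% p$dur$W1, p$dur$b1); d1_d <- relu_(d1pre_d)
  raw_d <- add_bias(d1_d %*% p$dur$W2, p$dur$b2)
  alpha <- softplus(raw_d[, 1]) + pos_eps
  beta <- softplus(raw_d[, 2]) + pos_eps
  d1pre_s <- add_bias(H0 %*% p$sig$W1, p$sig$b1); d1_s <- relu_(d1pre_s)
  raw_s <- add_bias(d1_s %*% p$sig$W2, p$sig$b2)
  sigma_pred <- softplus(raw_s[, 1])

  ## encoder
  groups_enc <- lapply(seq_len(B), function(b) (b - 1L) * P + seq_len(P))
  Henc <- H0 + posenc(P, cfg$d_model)[rep(seq_len(P), B), , drop = FALSE]
  enc_caches <- vector("list", length(p$enc))
  for (i in seq_along(p$enc)) {
    fb <- fft_block_fwd(Henc, p$enc[[i]], groups_enc, nh)
    enc_caches[[i]] <- fb$cache; Henc <- fb$out
  }

  ## length regulator (teacher-forced durations)
  idx_exp <- rep(seq_len(B * P), times = reps)
  tpos <- sequence(batch$Tb)           # 1..T_b within each chunk
  E <- Henc[idx_exp, , drop = FALSE] + posenc(max(tpos), cfg$d_model)[tpos, ,
                                                                      drop = FALSE]
  off <- cumsum(c(0L, batch$Tb[-B]))
  groups_dec <- lapply(seq_len(B), function(b) off[b] + seq_len(batch$Tb[b]))
  groups_dec <- groups_dec[batch$Tb > 0L]

  ## decoder + projection
  Hd <- E
  dec_caches <- vector("list", length(p$dec))
  for (i in seq_along(p$dec)) {
    fb <- fft_block_fwd(Hd, p$dec[[i]], groups_dec, nh)
    dec_caches[[i]] <- fb$cache; Hd <- fb$out
  }
  s_pred <- as.vector(add_bias(Hd %*% p$proj_W, p$proj_b))

  ## losses
  Ntot <- length(s_pred)
  n_rp <- sum(rp)
  resid <- s_pred - batch$target
  mse_sig <- mean(resid^2)
  l <- reps[rp]; a <- alpha[rp]; b <- beta[rp]
  nll <- tau * mean(-(a * log(b) + (a - 1) * log(l) - b * l - lgamma(a)))
  sref <- batch$sigma_ref
  mse_noise <- mean((sref[rp] - sigma_pred[rp])^2)
  report <- total_loss(mse_sig, nll, mse_noise)
  if (!grads) return(list(report = report))

  g <- zero_like(p)

  ## signal loss -> decoder
  ds <- matrix(2 * resid / Ntot, ncol = 1)
  g$proj_W <- crossprod(Hd, ds); g$proj_b <- sum(ds)
  dHd <- tcrossprod(ds, p$proj_W)
  for (i in rev(seq_along(p$dec))) {
    bk <- fft_block_bwd(dHd, dec_caches[[i]], p$dec[[i]])
    g$dec[[i]] <- bk$grads; dHd <- bk$dH
  }
  ## scatter-add back through the length regulator
  dHenc <- matrix(0, B * P, cfg$d_model)
  contrib <- rowsum(dHd, group = idx_exp)
  dHenc[as.integer(rownames(contrib)), ] <- contrib
  for (i in rev(seq_along(p$enc))) {
    bk <- fft_block_bwd(dHenc, enc_caches[[i]], p$enc[[i]])
    g$enc[[i]] <- bk$grads; dHenc <- bk$dH
  }
  dH0 <- dHenc                          # positional encodings pass through

  ## duration NLL -> gamma params -> head
  dalpha <- rep(0, B * P); dbeta <- rep(0, B * P)
  dalpha[rp] <- tau / n_rp * (-log(b) - log(l) + digamma(a))
  dbeta[rp] <- tau / n_rp * (-a / b + l)
  draw_d <- cbind(dalpha * sigmoid_(raw_d[, 1]), dbeta * sigmoid_(raw_d[, 2]))
  g$dur$W2 <- crossprod(d1_d, draw_d); g$dur$b2 <- colSums(draw_d)
  dd1 <- tcrossprod(draw_d, p$dur$W2) * (d1pre_d > 0)
  g$dur$W1 <- crossprod(H0, dd1); g$dur$b1 <- colSums(dd1)
  dH0 <- dH0 + tcrossprod(dd1, p$dur$W1)

  ## noise MSE -> sigma head
  dsig <- rep(0, B * P)
  dsig[rp] <- 2 * (sigma_pred[rp] - sref[rp]) / n_rp
  draw_s <- matrix(dsig * sigmoid_(raw_s[, 1]), ncol = 1)
  g$sig$W2 <- crossprod(d1_s, draw_s); g$sig$b2 <- colSums(draw_s)
  ds1 <- tcrossprod(draw_s, p$sig$W2) * (d1pre_s > 0)
  g$sig$W1 <- crossprod(H0, ds1); g$sig$b1 <- colSums(ds1)
  dH0 <- dH0 + tcrossprod(ds1, p$sig$W1)

  ## embedding
  dH0pre <- dH0 * (H0pre > 0)
  g$We <- crossprod(batch$X, dH0pre); g$be <- colSums(dH0pre)

  list(report = report, grads = g)
}

#' Train the squiggle model
#'
#' Optimises the model on a chunk store with Adam (linear warmup, global
#' gradient-norm clipping). Durations are teacher-forced from the reference
#' segmentation; the duration and noise samplers are trained through their
#' own loss terms and only used at inference. When a validation store is
#' given, validation loss is computed every `cfg$val_interval` steps and the
#' returned model is the best-validation checkpoint.
#'
#' @param chunks training chunk store ([build_chunks()]).
#' @param model a [squiggle_model()] to train.
#' @param cfg a [train_config()].
#' @param val optional validation chunk store.
#' @param verbose print progress every 100 steps.
#' @return List with `model` (trained `squiggle_model`), `history`
#'   (data.frame of per-step losses) and `val_history`.
#' @export
train <- function(chunks, model, cfg, val = NULL, verbose = FALSE) {
  stopifnot(inherits(chunks, "chunk_store"), inherits(model, "squiggle_model"),
            inherits(cfg, "train_config"))
  if (!nrow(chunks$tokens)) stop("empty chunk store")
  set.seed(cfg$seed)
  k <- model$config$k
  prep <- prepare_store(chunks, k)
  prep_val <- if (!is.null(val)) prepare_store(val, k)

  skel <- model$params
  theta <- flatten_params(skel)
  m <- numeric(length(theta)); v <- numeric(length(theta))
  beta1 <- 0.9; beta2 <- 0.999; adam_eps <- 1e-8

  hist <- matrix(NA_real_, cfg$max_steps, 4,
                 dimnames = list(NULL, c("mse_signal", "nll_duration",
                                         "mse_noise", "total")))
  val_hist <- list()
  best_val <- Inf; best_theta <- theta

  for (step in seq_len(cfg$max_steps)) {
    ids <- sample.int(prep$N, min(cfg$batch_size, prep$N))
    batch <- make_batch(prep, ids)
    fb <- forward_backward(model, batch, cfg$tau, grads = TRUE)
    rep_ <- fb$report
    if (!is.finite(rep_$total)) {
      stop("non-finite loss at step ", step,
           " (signal=", rep_$mse_signal, ", duration=", rep_$nll_duration,
           ", noise=", rep_$mse_noise, "); aborting")
    }
    hist[step, ] <- c(rep_$mse_signal, rep_$nll_duration, rep_$mse_noise,
                      rep_$total)

    gvec <- flatten_params(fb$grads)
    gn <- sqrt(sum(gvec^2))
    if (is.finite(gn) && gn > cfg$clip_norm) gvec <- gvec * (cfg$clip_norm / gn)
    lr <- cfg$learning_rate *
      min(1, step / max(1L, cfg$warmup_steps))
    m <- beta1 * m + (1 - beta1) * gvec
    v <- beta2 * v + (1 - beta2) * gvec^2
    mhat <- m / (1 - beta1^step)
    vhat <- v / (1 - beta2^step)
    theta <- theta - lr * mhat / (sqrt(vhat) + adam_eps)
    model$params <- unflatten_params(theta, skel)

    if (!is.null(prep_val) && cfg$val_interval > 0 &&
        step %% cfg$val_interval == 0) {
      vl <- validate_loss(model, prep_val, cfg$tau)
      val_hist[[length(val_hist) + 1L]] <- c(step = step, total = vl)
      if (vl < best_val) { best_val <- vl; best_theta <- theta }
    }
    if (verbose && step %% 100 == 0) {
      message(sprintf("step %d  total %.4f  signal %.4f  dur %.6f  noise %.5f",
                      step, rep_$total, rep_$mse_signal, rep_$nll_duration,
                      rep_$mse_noise))
    }
  }
  if (!is.null(prep_val) && length(val_hist)) {
    model$params <- unflatten_params(best_theta, skel)
  }
  list(model = model,
       history = as.data.frame(hist),
       val_history = if (length(val_hist))
         as.data.frame(do.call(rbind, val_hist)) else NULL)
}

# Mean teacher-forced loss over a prepared validation store (in mini-batches
# to bound memory).
validate_loss <- function(model, prep, tau, batch_size = 32L) {
  tot <- 0; nb <- 0
  for (s in seq(1L, prep$N, by = batch_size)) {
    ids <- s:min(s + batch_size - 1L, prep$N)
    fb <- forward_backward(model, make_batch(prep, ids), tau, grads = FALSE)
    tot <- tot + fb$report$total; nb <- nb + 1
  }
  tot / nb
}
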