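# Internal dense-network primitives for the feed-forward-transformer.
# All forward functions return list(out, cache); backward functions take the
# upstream gradient plus the cache and return input gradients and per-weight
# gradients. Everything is plain double matrices so BLAS does the work.

softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))
sigmoid_ <- function(x) 1 / (1 + exp(-x))

add_bias <- function(X, b) X + rep(b, each = nrow(X))
scale_cols <- function(X, s) X * rep(s, each = nrow(X))

nn_linear_fwd <- function(X, W, b) list(out = add_bias(X %*% W, b), X = X)
nn_linear_bwd <- function(dY, X, W) {
  list(dX = tcrossprod(dY, W), dW = crossprod(X, dY), db = colSums(dY))
}

rmeans <- function(X) .rowMeans(X, nrow(X), ncol(X))

# Sinusoidal positional encoding, rows are positions 1..n (0-based inside);
# memoized since the same (n, d) recurs every training step.
pe_cache <- new.env(parent = emptyenv())
posenc <- function(n, d) {
  key <- paste0(n, "x", d)
  hit <- pe_cache[[key]]
  if (!is.null(hit)) return(hit)
  pos <- matrix(0:(n - 1), nrow = n, ncol = d)
  i <- matrix(rep(0:(d - 1) %/% 2, each = n), nrow = n)
  ang <- pos / (10000^(2 * i / d))
  even <- rep(seq_len(d) %% 2 == 1, each = n)  # columns 1,3,... use sin
  out <- matrix(0, n, d)
  out[even] <- sin(ang[even])
  out[!even] <- cos(ang[!even])
  if (n <= 4096) pe_cache[[key]] <- out
  out
}

ln_eps <- 1e-5

nn_ln_fwd <- function(X, g, b) {
  mu <- rmeans(X)
  xc <- X - mu
  v <- rmeans(xc * xc)
  inv <- 1 / sqrt(v + ln_eps)
  xhat <- xc * inv
  list(out = add_bias(scale_cols(xhat, g), b),
       cache = list(xhat = xhat, inv = inv, g = g))
}

nn_ln_bwd <- function(dY, cache) {
  xhat <- cache$xhat
  dxhat <- scale_cols(dY, cache$g)
  dX <- cache$inv * (dxhat - rmeans(dxhat) - xhat * rmeans(dxhat * xhat))
  list(dX = dX, dg = colSums(dY * xhat), db = colSums(dY))
}

relu_ <- function(x) { x[x < 0] <- 0; x }

softmax_rows <- function(S) {
  mx <- S[cbind(seq_len(nrow(S)), max.col(S, ties.method = "first"))]
  E <- exp(S - mx)
  E / .rowSums(E, nrow(E), ncol(E))
}

# Multi-head self-attention over independent row groups (one group per
# chunk); attention never crosses group boundaries.
nn_mha_fwd <- function(H, blk, groups, n_heads) {
  d <- ncol(H); dh <- d %/% n_heads; scale <- 1 / sqrt(dh)
  Q <- add_bias(H %*% blk$Wq, blk$bq)
  K <- add_bias(H %*% blk$Wk, blk$bk)
  V <- add_bias(H %*% blk$Wv, blk$bv)
  O <- matrix(0, nrow(H), d)
  A_all <- vector("list", length(groups))
  for (gi in seq_along(groups)) {
    idx <- groups[[gi]]
    A_heads <- vector("list", n_heads)
    for (h in seq_len(n_heads)) {
      cols <- (h - 1L) * dh + seq_len(dh)
      Qh <- Q[idx, cols, drop = FALSE]
      Kh <- K[idx, cols, drop = FALSE]
      A <- softmax_rows(tcrossprod(Qh, Kh) * scale)
      O[idx, cols] <- A %*% V[idx, cols, drop = FALSE]
      A_heads[[h]] <- A
    }
    A_all[[gi]] <- A_heads
  }
  out <- add_bias(O %*% blk$Wo, blk$bo)
  list(out = out,
       cache = list(H = H, Q = Q, K = K, V = V, O = O, A = A_all,
                    groups = groups, n_heads = n_heads, dh = dh,
                    scale = scale))
}

nn_mha_bwd <- function(dY, cache, blk) {
  ca <- cache
  dO <- tcrossprod(dY, blk$Wo)
  gWo <- crossprod(ca$O, dY); gbo <- colSums(dY)
  dQ <- matrix(0, nrow(dY), ncol(dY))
  dK <- dQ; dV <- dQ
  for (gi in seq_along(ca$groups)) {
    idx <- ca$groups[[gi]]
    for (h in seq_len(ca$n_heads)) {
      cols <- (h - 1L) * ca$dh + seq_len(ca$dh)
      A <- ca$A[[gi]][[h]]
      dOh <- dO[idx, cols, drop = FALSE]
      Vh <- ca$V[idx, cols, drop = FALSE]
      dA <- tcrossprod(dOh, Vh)
      dV[idx, cols] <- crossprod(A, dOh)
      dS <- A * (dA - rowSums(dA * A))
      dQ[idx, cols] <- dS %*% ca$K[idx, cols, drop = FALSE] * ca$scale
      dK[idx, cols] <- crossprod(dS, ca$Q[idx, cols, drop = FALSE]) * ca$scale
    }
  }
  dH <- tcrossprod(dQ, blk$Wq) + tcrossprod(dK, blk$Wk) +
    tcrossprod(dV, blk$Wv)
  list(dH = dH,
       grads = list(Wq = crossprod(ca$H, dQ), bq = colSums(dQ),
                    Wk = crossprod(ca$H, dK), bk = colSums(dK),
                    Wv = crossprod(ca$H, dV), bv = colSums(dV),
                    Wo = gWo, bo = gbo))
}

# One feed-forward-transformer block: self-attention and position-wise FFN,
# each wrapped in residual + post-layer-norm.
fft_block_fwd <- function(H, blk, groups, n_heads) {
  att <- nn_mha_fwd(H, blk, groups, n_heads)
  ln1 <- nn_ln_fwd(H + att$out, blk$ln1_g, blk$ln1_b)
  F1pre <- add_bias(ln1$out %*% blk$W1, blk$b1)
  F1 <- relu_(F1pre)
  F2 <- add_bias(F1 %*% blk$W2, blk$b2)
  ln2 <- nn_ln_fwd(ln1$out + F2, blk$ln2_g, blk$ln2_b)
  list(out = ln2$out,
       cache = list(att = att$cache, ln1 = ln1$cache, ln1_out = ln1$out,
                    F1pre = F1pre, F1 = F1, ln2 = ln2$cache))
}

fft_block_bwd <- function(dY, cache, blk) {
  b2 <- nn_ln_bwd(dY, cache$ln2)
  dR2 <- b2$dX
  dF1 <- tcrossprod(dR2, blk$W2)
  gW2 <- crossprod(cache$F1, dR2); gb2 <- colSums(dR2)
  dF1pre <- dF1 * (cache$F1pre > 0)
  dL1 <- dR2 + tcrossprod(dF1pre, blk$W1)
  gW1 <- crossprod(cache$ln1_out, dF1pre); gb1 <- colSums(dF1pre)
  b1 <- nn_ln_bwd(dL1, cache$ln1)
  dR1 <- b1$dX
  attb <- nn_mha_bwd(dR1, cache$att, blk)
  list(dH = dR1 + attb$dH,
       grads = c(attb$grads,
                 list(ln1_g = b1$dg, ln1_b = b1$db,
                      W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2,
                      ln2_g = b2$dg, ln2_b = b2$db)))
}

# Weight initialisation ------------------------------------------------------

init_linear <- function(fan_in, fan_out, gain = 1) {
  matrix(stats::rnorm(fan_in * fan_out, sd = gain * sqrt(2 / (fan_in + fan_out))),
         fan_in, fan_out)
}

init_block <- function(d, d_ff) {
  list(Wq = init_linear(d, d), bq = rep(0, d),
       Wk = init_linear(d, d), bk = rep(0, d),
       Wv = init_linear(d, d), bv = rep(0, d),
       Wo = init_linear(d, d), bo = rep(0, d),
       ln1_g = rep(1, d), ln1_b = rep(0, d),
       W1 = init_linear(d, d_ff, gain = sqrt(2)), b1 = rep(0, d_ff),
       W2 = init_linear(d_ff, d), b2 = rep(0, d),
       ln2_g = rep(1, d), ln2_b = rep(0, d))
}

# Flatten a nested parameter list to one numeric vector and back.
flatten_params <- function(p) unlist(p, use.names = FALSE)

unflatten_params <- function(v, skel) {
  pos <- 0L
  walk <- function(x) {
    if (is.list(x)) return(lapply(x, walk))
    n <- length(x)
    out <- v[pos + seq_len(n)]
    pos <<- pos + n
    attributes(out) <- attributes(x)
    out
  }
  out <- walk(skel)
  stopifnot(pos == length(v))
  out
}

zero_like <- function(p) {
  if (is.list(p)) return(lapply(p, zero_like))
  out <- p; out[] <- 0; out
}
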