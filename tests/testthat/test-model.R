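test_that("embedding is position-wise, deterministic and non-negative", {
  m <- tiny_model()
  enc_pad <- encode_tokens(rep("_", 16), k = 3)
  H <- embed(m, enc_pad)
  expect_equal(dim(H), c(16L, 16L))
  expect_true(all(H >= 0))
  # identical inputs give identical hidden states
  expect_true(all(apply(H, 2, function(col) all(col == col[1]))))

  set.seed(1)
  toks1 <- c(rep("ACG", 8), rep("TTT", 8))
  toks2 <- c(rep("ACG", 8), rep("GGA", 8))
  H1 <- embed(m, encode_tokens(toks1, 3))
  H2 <- embed(m, encode_tokens(toks2, 3))
  expect_equal(H1[1:8, ], H2[1:8, ])
  expect_error(embed(m, rep(0, 7)), "multiple of k")
})

test_that("fft blocks preserve sequence length down to length 1", {
  m <- tiny_model()
  for (n in c(1L, 3L, 50L, 250L)) {
    H <- matrix(rnorm(n * 16), n, 16)
    out <- fft_block(m, H, "encoder", 1L)
    expect_equal(dim(out), c(n, 16L))
    out_d <- fft_block(m, H, "decoder", 2L)
    expect_equal(dim(out_d), c(n, 16L))
  }
  expect_error(fft_block(m, matrix(0, 0, 16)), "empty")
})

test_that("zeroed block with residuals reduces to layer normalization", {
  m <- tiny_model()
  blk <- m$params$enc[[1]]
  for (nm in c("Wq", "bq", "Wk", "bk", "Wv", "bv", "Wo", "bo",
               "W1", "b1", "W2", "b2")) blk[[nm]][] <- 0
  m$params$enc[[1]] <- blk
  set.seed(2)
  H <- matrix(rnorm(5 * 16), 5, 16)
  got <- fft_block(m, H, "encoder", 1L)
  # hand-computed layer norm oracle
  ln <- t(apply(H, 1, function(r) (r - mean(r)) / sqrt(mean((r - mean(r))^2))))
  expect_equal(got, ln, tolerance = 1e-3)
})

test_that("encoder keeps shape for padded, single-token and full chunks", {
  m <- tiny_model()
  for (toks in list(rep("_", 16), c("ACG", rep("_", 15)),
                    rep(c("ACG", "CGT"), 8))) {
    H <- embed(m, encode_tokens(toks, 3))
    expect_equal(dim(encode(m, H)), c(16L, 16L))
  }
})

test_that("length regulator repeats rows in order", {
  H <- matrix(seq_len(4 * 3), 4, 3)
  out <- length_regulate(H, c(2L, 1L, 3L, 0L))
  expect_equal(nrow(out), 6L)
  expect_equal(out, H[c(1, 1, 2, 3, 3, 3), ])
  expect_equal(length_regulate(H, rep(1L, 4)), H)
  expect_error(length_regulate(H, rep(0L, 4)), "all durations are zero")
})

test_that("length regulator equals the naive repeat-concatenate oracle", {
  set.seed(3)
  for (i in 1:50) {
    n <- sample(1:16, 1)
    H <- matrix(rnorm(n * 8), n, 8)
    durations <- sample(0:5, n, replace = TRUE)
    if (sum(durations) == 0) durations[1] <- 1L
    expect_identical(unname(length_regulate(H, durations)),
                     unname(naive_length_regulate(H, durations)))
  }
})

test_that("decoder obeys the shape contract and the expansion cap", {
  m <- tiny_model()
  for (T_ in c(1L, 100L, 250L)) {
    H <- matrix(rnorm(T_ * 16), T_, 16)
    s <- decode(m, H)
    expect_length(s, T_)
  }
  expect_error(decode(m, matrix(0, 10, 16), cap = 5), "split")
})

test_that("duration and noise heads are positive and position-wise", {
  m <- tiny_model()
  H <- embed(m, encode_tokens(rep("_", 16), 3))
  dp <- predict_durations(m, H)
  expect_true(all(dp$alpha > 0) && all(dp$beta > 0))
  expect_equal(dp$alpha, rep(dp$alpha[1], 16))  # identical inputs
  sg <- predict_sigma(m, H)
  expect_true(all(sg >= 0))
  expect_equal(sg, rep(sg[1], 16))
})

test_that("analytic gradients match finite differences through all heads", {
  set.seed(4)
  ev <- events_for_read(sample(3:12, 20, replace = TRUE))
  st <- build_chunks(ev)
  m <- tiny_model()
  prep <- squigglesim:::prepare_store(st, 3)
  batch <- squigglesim:::make_batch(prep, seq_len(min(2, prep$N)))
  fb <- squigglesim:::forward_backward(m, batch, tau = 5e-4, grads = TRUE)
  theta <- squigglesim:::flatten_params(m$params)
  gvec <- squigglesim:::flatten_params(fb$grads)
  eps <- 1e-5
  loss_at <- function(th) {
    m$params <- squigglesim:::unflatten_params(th, m$params)
    squigglesim:::forward_backward(m, batch, 5e-4, grads = FALSE)$report$total
  }
  idx <- sample(which(abs(gvec) > 1e-8), 5)
  for (i in idx) {
    th <- theta; th[i] <- theta[i] + eps; up <- loss_at(th)
    th[i] <- theta[i] - eps; dn <- loss_at(th)
    fd <- (up - dn) / (2 * eps)
    expect_equal(gvec[i], fd, tolerance = 1e-3)
  }
})

test_that("duration sampling respects mode, clamping and padding", {
  p <- list(alpha = c(9, 4, 2), beta = c(1, 2, 4))
  expect_equal(sample_durations(p, "ideal"), c(9L, 2L, 1L))
  expect_equal(sample_durations(p, "ideal", pad = c(FALSE, TRUE, FALSE)),
               c(9L, 0L, 1L))
  set.seed(5)
  tiny <- list(alpha = rep(0.01, 200), beta = rep(5, 200))
  expect_true(all(sample_durations(tiny, "stochastic") >= 1L))
  draws <- sample_durations(list(alpha = rep(4, 2000), beta = rep(2, 2000)),
                            "stochastic", raw = TRUE)
  se <- sqrt(4 / 2^2 / 2000)
  expect_lt(abs(mean(draws) - 2), 3 * se)
})

test_that("amplitude noise is identity when off or sigma-zero", {
  s <- rnorm(30)
  dur <- c(10L, 15L, 5L)
  expect_identical(add_noise(s, c(1, 1, 1), dur, "off"), s)
  expect_equal(add_noise(s, c(0, 0, 0), dur, "on"), s)
  expect_error(add_noise(s, c(1, 1), c(10L, 15L), "on"), "sum")
})

test_that("forward pass is deterministic and obeys the shape law", {
  m <- tiny_model()
  set.seed(6)
  toks <- vapply(1:16, function(i)
    paste(sample(c("A", "C", "G", "T"), 3, replace = TRUE), collapse = ""), "")
  H <- embed(m, encode_tokens(toks, 3))
  durations <- sample(1:5, 16, replace = TRUE)
  s1 <- decode(m, length_regulate(encode(m, H), durations))
  s2 <- decode(m, length_regulate(encode(m, H), durations))
  expect_identical(s1, s2)
  expect_length(s1, sum(durations))
})

test_that("checkpoints round-trip weights, config and profile", {
  m <- tiny_model()
  p <- tempfile(fileext = ".ckpt")
  save_checkpoint(m, p)
  m2 <- load_checkpoint(p)
  expect_identical(m2$params, m$params)
  expect_equal(unclass(m2$config), unclass(m$config))
  expect_equal(unclass(m2$profile), unclass(m$profile))
  suppressWarnings(
    expect_error(load_checkpoint(tempfile()), "cannot open|not a squigglesim"))
})
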