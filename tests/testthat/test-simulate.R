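test_that("read lengths follow the requested family and clipping", {
  set.seed(1)
  d_fixed <- length_distribution("fixed", list(length = 100))
  expect_equal(sample_read_lengths(d_fixed, 5), rep(100L, 5))

  d_exp <- length_distribution("exponential", list(mean = 8000),
                               min_len = 1, max_len = 10000000)
  draws <- sample_read_lengths(d_exp, 1e5, raw = TRUE)
  se <- 8000 / sqrt(1e5)
  expect_lt(abs(mean(draws) - 8000), 3 * se)

  d_clip <- length_distribution("exponential", list(mean = 500),
                                min_len = 200, max_len = 900)
  x <- sample_read_lengths(d_clip, 2000)
  expect_true(all(x >= 200 & x <= 900))

  d_beta <- length_distribution("beta")
  expect_true(all(sample_read_lengths(d_beta, 100) <= 50000))
  d_mix <- length_distribution("mixed_gamma")
  expect_true(all(sample_read_lengths(d_mix, 100) >= 100))
  expect_error(length_distribution("exponential", list(mean = -1)), "invalid")
})

test_that("genome read sampling respects bounds, coverage and contig weights", {
  set.seed(2)
  g <- make_genome(1000, seed = 3)
  d100 <- length_distribution("fixed", list(length = 100), min_len = 10)
  reads <- sample_reads(g, n = 5, dist = d100)
  expect_equal(nrow(reads), 5L)
  expect_true(all(reads$start >= 0 & reads$start <= 900))
  expect_true(all(reads$end - reads$start == 100))
  expect_true(all(nchar(reads$sequence) == 100))

  cov_reads <- sample_reads(g, coverage = 10, dist = d100)
  expect_equal(nrow(cov_reads), 100L)  # 10 * 1000 / 100

  g2 <- c(c1 = paste(rep("A", 900), collapse = ""),
          c2 = paste(rep("C", 100), collapse = ""))
  d50 <- length_distribution("fixed", list(length = 50), min_len = 10)
  r2 <- sample_reads(g2, n = 10000, dist = d50)
  frac <- mean(r2$contig == "c1")
  p <- (900 - 49) / ((900 - 49) + (100 - 49)) # both contigs eligible; length-weighted
  expect_lt(abs(frac - 900 / 1000), 3 * sqrt(0.9 * 0.1 / 10000) + 0.02)

  # minus-strand reads are reverse-complemented
  set.seed(4)
  r3 <- sample_reads(g, n = 50, dist = d100)
  minus <- which(r3$strand == "-")[1]
  orig <- substr(g[[r3$contig[minus]]], r3$start[minus] + 1, r3$end[minus])
  expect_equal(r3$sequence[minus], squigglesim:::revcomp(orig))

  expect_error(sample_reads(g, n = 1,
                            dist = length_distribution("fixed",
                                                       list(length = 2000),
                                                       max_len = 5000)),
               "exceeds every contig")
})

test_that("k-mer decomposition slides with stride one", {
  expect_equal(sequence_to_kmers("ACGTA", 3), c("ACG", "CGT", "GTA"))
  expect_error(sequence_to_kmers("AC", 3), "shorter than k")
  set.seed(5)
  for (i in 1:10) {
    n <- sample(5:50, 1); k <- sample(2:5, 1)
    s <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
    expect_length(sequence_to_kmers(s, k), n - k + 1)
  }
})

test_that("noise-free simulation is deterministic with the expected length", {
  m <- tiny_model()
  seq1 <- "ACGTACGTAGCTAGCTAAACCGTATTTACG"
  off <- noise_config("off", "off")
  r1 <- simulate_signal(seq1, m, off, seed = 1)
  r2 <- simulate_signal(seq1, m, off, seed = 99)  # seed irrelevant when off
  expect_identical(r1$signal, r2$signal)
  expect_equal(length(r1$signal), sum(r1$durations))
  expect_true(all(diff(r1$event_bounds) > 0))
  expect_identical(r1$sequence, seq1)

  # static duration with zero spread forces 9 samples per k-mer
  st9 <- noise_config("off", "static", duration_mean = 9, duration_sd = 0)
  r3 <- simulate_signal(seq1, m, st9, seed = 2)
  expect_equal(length(r3$signal), 9 * (nchar(seq1) - 3 + 1))
})

test_that("noise modes share the deterministic duration skeleton", {
  m <- tiny_model()
  s <- "ACGTACGTAGCTAGCTAAACCGTATTTACG"
  base <- simulate_signal(s, m, noise_config("off", "off"), seed = 1)
  amp <- simulate_signal(s, m, noise_config("static", "off"), seed = 7)
  lrn <- simulate_signal(s, m, noise_config("learned", "off"), seed = 8)
  expect_identical(amp$durations, base$durations)
  expect_identical(lrn$durations, base$durations)
  expect_identical(amp$event_bounds, base$event_bounds)
  # amplitude noise perturbs but keeps length
  expect_length(amp$signal, length(base$signal))
  expect_false(identical(amp$signal, base$signal))
})

test_that("static amplitude noise has the configured spread", {
  m <- tiny_model()
  set.seed(6)
  s <- paste(sample(c("A", "C", "G", "T"), 120, replace = TRUE),
             collapse = "")
  st9 <- noise_config("off", "static", duration_mean = 9, duration_sd = 0)
  base <- simulate_signal(s, m, st9, seed = 3)
  noisy <- simulate_signal(s, m, noise_config("static", "static",
                                              amplitude_sd = 0.5,
                                              duration_mean = 9,
                                              duration_sd = 0), seed = 3)
  resid <- noisy$signal - base$signal
  expect_equal(sd(resid), 0.5, tolerance = 0.08)
})

test_that("simulate_run covers genome- and read-mode with reproducible output", {
  m <- tiny_model()
  g <- make_genome(600, seed = 10)
  out1 <- tempfile(fileext = ".slow5")
  d60 <- length_distribution("fixed", list(length = 60), min_len = 10)
  simulate_run(g, m, out1, n = 3, dist = d60,
               noise = noise_config("off", "off"), seed = 42)
  got <- read_slow5(out1)
  ids <- vapply(got$reads, `[[`, "", "read_id")
  expect_length(ids, 3L)
  expect_false(any(duplicated(ids)))
  truth <- data.table::fread(paste0(out1, ".truth.tsv"))
  expect_equal(names(truth),
               c("read_id", "contig", "start", "end", "strand", "n_samples"))
  expect_equal(truth$end - truth$start, rep(60L, 3))

  # same seed reproduces the payload byte-for-byte
  out2 <- tempfile(fileext = ".slow5")
  simulate_run(g, m, out2, n = 3, dist = d60,
               noise = noise_config("off", "off"), seed = 42)
  expect_identical(readLines(out1), readLines(out2))

  # read-mode: sequences taken verbatim, event counts are len - k + 1
  fq <- tempfile(fileext = ".fastq")
  writeLines(c("@readA", "ACGTACGTACGTACGTACGT", "+",
               paste(rep("I", 20), collapse = ""),
               "@readB", "TTTTGGGGCCCCAAAATTTTACG", "+",
               paste(rep("I", 23), collapse = "")), fq)
  out3 <- tempfile(fileext = ".slow5")
  reads <- simulate_run(fq, m, out3, read_input = TRUE,
                        noise = noise_config("off", "off"), seed = 1)
  expect_length(reads, 2L)
  expect_equal(reads[[1]]$sequence, "ACGTACGTACGTACGTACGT")
  expect_length(reads[[1]]$durations, 20 - 3 + 1)
  expect_length(reads[[2]]$durations, 23 - 3 + 1)
})
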