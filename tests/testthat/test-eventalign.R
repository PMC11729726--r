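test_that("parse_eventalign reads the default dialect and orders events", {
  set.seed(1)
  ev <- events_for_read(c(4L, 5L, 6L), k = 3L)
  tsv <- write_eventalign_tsv(ev, tempfile(fileext = ".tsv"))
  got <- parse_eventalign(tsv, pore_profile(k = 3))
  expect_equal(nrow(got), 3L)
  expect_equal(sum(lengths(got$samples)), 15L)
  expect_equal(got$position, 0:2)
  expect_equal(got$kmer, ev$kmer)
  # sample values survive the text round trip to printed precision
  expect_equal(unlist(got$samples), unlist(ev$samples), tolerance = 1e-7)
})

test_that("parse_eventalign handles empty input and rejects bad k-mers", {
  empty <- tempfile(fileext = ".tsv")
  file.create(empty)
  got <- parse_eventalign(empty, pore_profile(k = 3))
  expect_equal(nrow(got), 0L)

  set.seed(2)
  ev <- events_for_read(c(3L, 3L), k = 3L)
  ev$kmer[2] <- "ANT"
  tsv <- write_eventalign_tsv(ev, tempfile(fileext = ".tsv"))
  expect_error(parse_eventalign(tsv, pore_profile(k = 3)), "line 3.*ANT")

  ev2 <- events_for_read(c(3L, 3L), k = 4L)
  tsv2 <- write_eventalign_tsv(ev2, tempfile(fileext = ".tsv"))
  expect_error(parse_eventalign(tsv2, pore_profile(k = 3)), "length 4")
})

test_that("parse_eventalign falls back to mean+stdv+length columns", {
  dt <- data.table::data.table(
    read_name = "r1", contig = "c1", position = 0:1,
    model_kmer = c("ACG", "CGT"),
    event_level_mean = c(1.5, -0.5), event_stdv = c(0.1, 0.2),
    event_length = c(3L, 2L))
  tsv <- tempfile(fileext = ".tsv")
  data.table::fwrite(dt, tsv, sep = "\t")
  got <- parse_eventalign(tsv, pore_profile(k = 3))
  expect_equal(lengths(got$samples), c(3L, 2L))
  expect_equal(got$samples[[1]], rep(1.5, 3))
  expect_equal(got$event_stdv, c(0.1, 0.2))
})

test_that("build_chunks tiles windows, pads the tail and caps signal length", {
  set.seed(3)
  # 20 events x 10 samples: two chunks, the second padded
  st <- build_chunks(events_for_read(rep(10L, 20)))
  expect_equal(nrow(st$tokens), 2L)
  expect_equal(sum(st$tokens[1, ] != "_"), 16L)
  expect_equal(sum(st$mask[1, ]), 160L)
  expect_equal(sum(st$tokens[2, ] != "_"), 4L)
  expect_equal(st$tokens[2, 5:16], rep("_", 12))
  expect_equal(sum(st$mask[2, ]), 40L)
  expect_equal(st$durations[2, 5:16], rep(0L, 12))
  expect_equal(st$sigma[2, 5:16], rep(0, 12))

  # 16 events x 20 samples = 320 points: over the cap, dropped not truncated
  st2 <- build_chunks(events_for_read(rep(20L, 16)))
  expect_equal(nrow(st2$tokens), 0L)
  expect_equal(st2$n_dropped, 1L)

  # exactly at the cap with a single event
  st3 <- build_chunks(events_for_read(250L))
  expect_equal(st3$durations[1, ], c(250L, rep(0L, 15)))
  expect_true(all(st3$mask[1, ]))
})

test_that("chunk signal is the concatenation of event samples", {
  set.seed(4)
  ev <- events_for_read(c(3L, 2L, 4L))
  st <- build_chunks(ev)
  expect_equal(st$signal[1, 1:9], unlist(ev$samples))
  expect_equal(st$signal[1, 10:250], rep(0, 241))
})

test_that("position gaps split windows", {
  set.seed(5)
  ev <- events_for_read(rep(5L, 6))
  ev$position <- c(0:2, 10:12)  # gap after the third event
  st <- build_chunks(ev)
  expect_equal(nrow(st$tokens), 2L)
  expect_equal(rowSums(st$durations), c(15L, 15L))
})

test_that("chunking conserves samples and is deterministic", {
  set.seed(6)
  for (rep_i in 1:20) {
    lens <- sample(1:25, sample(1:40, 1), replace = TRUE)
    ev <- events_for_read(as.integer(lens))
    st <- build_chunks(ev)
    expect_equal(nrow(st$tokens), naive_chunk_count(lens))
    if (st$n_dropped == 0) {
      expect_equal(sum(st$mask), sum(lens))
      expect_equal(sum(st$durations), sum(lens))
    }
    st2 <- build_chunks(ev)
    expect_identical(st, st2)
  }
})

test_that("chunk store round-trips through its file container", {
  set.seed(7)
  st <- build_chunks(events_for_read(rep(8L, 20)))
  p <- tempfile(fileext = ".rds")
  write_chunks(st, p)
  expect_identical(read_chunks(p), st)
})

test_that("encode_tokens one-hot layout matches the vocabulary order", {
  expect_equal(encode_tokens("A", k = 1), c(1, 0, 0, 0, 0))
  expect_equal(encode_tokens("_", k = 3), rep(c(0, 0, 0, 0, 1), 3))
  set.seed(8)
  toks <- vapply(1:16, function(i)
    paste(sample(c("A", "C", "G", "T"), 9, replace = TRUE), collapse = ""), "")
  v <- encode_tokens(toks, k = 9)
  expect_length(v, 16 * 9 * 5)
  expect_equal(sum(v), 16 * 9)
  expect_identical(v, encode_tokens(toks, k = 9))
  expect_error(encode_tokens("AXG", k = 3), "unknown character")
  # spot-check: "ACGT..." block structure for the first token
  v2 <- encode_tokens(c("ACGT", rep("_", 15)), k = 4)
  expect_equal(v2[1:20],
               c(1, 0, 0, 0, 0,  0, 1, 0, 0, 0,  0, 0, 1, 0, 0,  0, 0, 0, 1, 0))
})
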