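# Independent oracles and tiny fixtures shared across the test files.
# Everything here is deliberately naive: the point is independence from the
# implementation paths being checked.

tiny_config <- function(k = 3L, d_model = 16L) {
  model_config(k = k, d_model = d_model, n_heads = 2L, d_ff = 2L * d_model)
}

tiny_model <- function(k = 3L, d_model = 16L, seed = 42L) {
  squiggle_model(tiny_config(k, d_model), pore_profile(k = k), seed = seed)
}

# naive repeat-and-concatenate expansion
naive_length_regulate <- function(H, durations) {
  out <- NULL
  for (i in seq_len(nrow(H))) {
    if (durations[i] > 0) {
      for (r in seq_len(durations[i])) out <- rbind(out, H[i, ])
    }
  }
  out
}

# exhaustive enumeration over all monotone warping paths (tiny inputs only)
naive_dtw <- function(x, y, cost = c("abs", "squared")) {
  cost <- match.arg(cost)
  cf <- if (cost == "abs") function(a, b) abs(a - b) else
    function(a, b) (a - b)^2
  rec <- function(i, j) {
    if (i == 1 && j == 1) return(cf(x[1], y[1]))
    best <- Inf
    if (i > 1) best <- min(best, rec(i - 1, j))
    if (j > 1) best <- min(best, rec(i, j - 1))
    if (i > 1 && j > 1) best <- min(best, rec(i - 1, j - 1))
    cf(x[i], y[j]) + best
  }
  rec(length(x), length(y))
}

# independent recount of how many windows of a gap-free read survive the
# signal-point cap under non-overlapping tiling
naive_chunk_count <- function(event_lengths, chunk_len = 16L,
                              max_signal = 250L) {
  n <- length(event_lengths)
  if (n == 0) return(0L)
  starts <- seq(1L, n, by = chunk_len)
  sum(vapply(starts, function(s) {
    sum(event_lengths[s:min(s + chunk_len - 1L, n)]) <= max_signal
  }, TRUE))
}

# event table for one read with given per-event sample counts
events_for_read <- function(lens, k = 3L, read_id = "r1", start = 0L,
                            level = 0) {
  kmers <- vapply(seq_along(lens), function(i) {
    paste(sample(c("A", "C", "G", "T"), k, replace = TRUE), collapse = "")
  }, "")
  data.table::data.table(
    read_id = read_id, contig = "c1",
    position = start + seq_along(lens) - 1L, kmer = kmers,
    samples = lapply(lens, function(n) rnorm(n, level)),
    event_stdv = rep(0.1, length(lens)))
}

# write a small eventalign TSV in the default dialect
write_eventalign_tsv <- function(events, path) {
  out <- data.table::data.table(
    read_name = events$read_id, contig = events$contig,
    position = events$position, model_kmer = events$kmer,
    samples = vapply(events$samples,
                     function(v) paste(sprintf("%.8g", v), collapse = ","),
                     ""),
    event_stdv = events$event_stdv)
  data.table::fwrite(out, path, sep = "\t")
  path
}
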