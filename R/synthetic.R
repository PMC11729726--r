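#' All k-mers over the DNA alphabet
#'
#' @param k k-mer size.
#' @return Character vector of the 4^k k-mers.
#' @export
all_kmers <- function(k) {
  do.call(paste0, rev(expand.grid(rep(list(c("A", "C", "G", "T")), k),
                                  stringsAsFactors = FALSE)))
}

#' Generate a synthetic ground-truth pore table
#'
#' Emulates a pore model with known stochastic structure: each k-mer gets an
#' i.i.d. standard-normal current level (model units), a gamma event-length
#' law with mean drawn uniformly in [5, 15] samples (shape uniform in
#' [2, 10], rate = shape/mean) and an amplitude-noise SD uniform in
#' [0.05, 0.3]. Duration and noise laws depend on the k-mer only, so a
#' correctly trained model can recover them with near-zero irreducible
#' error.
#'
#' @param k k-mer size.
#' @param seed RNG seed (deterministic table per seed).
#' @return An object of class `pore_table`: list with `k` and named vectors
#'   `level`, `alpha`, `beta`, `sigma` over all 4^k k-mers.
#' @export
make_pore_table <- function(k, seed = NULL) {
  kmers <- all_kmers(k)
  with_seed(seed, {
    level <- stats::rnorm(length(kmers))
    mean_dur <- stats::runif(length(kmers), 5, 15)
    alpha <- stats::runif(length(kmers), 2, 10)
    beta <- alpha / mean_dur
    sigma <- stats::runif(length(kmers), 0.05, 0.3)
    structure(list(k = as.integer(k),
                   level = stats::setNames(level, kmers),
                   alpha = stats::setNames(alpha, kmers),
                   beta = stats::setNames(beta, kmers),
                   sigma = stats::setNames(sigma, kmers)),
              class = "pore_table")
  })
}

#' @export
print.pore_table <- function(x, ...) {
  cat(sprintf("<pore_table> k=%d, %d k-mers; duration means %.1f-%.1f, sigma %.2f-%.2f\n",
              x$k, length(x$level), min(x$alpha / x$beta),
              max(x$alpha / x$beta), min(x$sigma), max(x$sigma)))
  invisible(x)
}

#' Generate a random genome
#'
#' Uniform i.i.d. bases over A/C/G/T.
#'
#' @param length total genome length (split evenly over `n_contigs`).
#' @param seed RNG seed.
#' @param n_contigs number of contigs.
#' @param path optional FASTA output path.
#' @return Named character vector of contig sequences (invisibly written to
#'   `path` as FASTA when given).
#' @export
make_genome <- function(length, seed = NULL, n_contigs = 1L, path = NULL) {
  stopifnot(length >= n_contigs)
  with_seed(seed, {
    per <- diff(round(seq(0, length, length.out = n_contigs + 1L)))
    g <- vapply(per, function(n) {
      paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
    }, "")
    names(g) <- paste0("contig", seq_len(n_contigs))
    if (!is.null(path)) {
      Biostrings::writeXStringSet(Biostrings::DNAStringSet(g), path)
    }
    g
  })
}

#' Generate a synthetic eventalign table
#'
#' Samples reads from the genome (as in genome-mode simulation), then per
#' k-mer draws a duration from the table's gamma law (rounded, clamped to
#' >= 1) and that many samples as `level + Normal(0, sigma)`. The result is
#' an eventalign-style table in the dialect [parse_eventalign()] expects
#' (`read_name`, `contig`, `position`, `model_kmer`, `samples`,
#' `event_stdv`; the stdv column is the per-event sample SD, 0 for
#' single-sample events), plus the ground truth needed for recovery tests.
#'
#' @param genome named character vector or `DNAStringSet`.
#' @param table a [make_pore_table()].
#' @param n_reads number of reads.
#' @param dist a [length_distribution()].
#' @param seed RNG seed.
#' @param path optional TSV output path.
#' @return List with `events` (a `data.table` in the [parse_eventalign()]
#'   schema: `read_id`, `contig`, `position`, `kmer`, `samples` list
#'   column, `event_stdv`), `reads` (coordinates from [sample_reads()]),
#'   `table` (the generating `pore_table`) and `path` (or `NULL`).
#' @export
make_eventalign <- function(genome, table, n_reads,
                            dist = length_distribution("fixed",
                                                       list(length = 300)),
                            seed = NULL, path = NULL) {
  stopifnot(inherits(table, "pore_table"))
  with_seed(seed, {
    reads <- sample_reads(genome, n = n_reads, dist = dist)
    ev <- vector("list", nrow(reads))
    for (i in seq_len(nrow(reads))) {
      kmers <- sequence_to_kmers(reads$sequence[i], table$k)
      a <- table$alpha[kmers]; b <- table$beta[kmers]
      mu <- table$level[kmers]; sg <- table$sigma[kmers]
      d <- pmax(as.integer(round(stats::rgamma(length(kmers), shape = a,
                                               rate = b))), 1L)
      noise <- stats::rnorm(sum(d), 0, rep(sg, d))
      samp <- split(rep(mu, d) + noise, rep(seq_along(kmers), d))
      stdv <- vapply(samp, function(v) if (length(v) > 1L) stats::sd(v) else 0,
                     0)
      ev[[i]] <- data.table::data.table(
        read_id = reads$read_id[i], contig = reads$contig[i],
        position = reads$start[i] + seq_along(kmers) - 1L,
        kmer = kmers, samples = unname(samp),
        event_stdv = unname(stdv))
    }
    events <- data.table::rbindlist(ev)
    if (!is.null(path)) {
      out <- data.table::data.table(
        read_name = events$read_id, contig = events$contig,
        position = events$position, model_kmer = events$kmer,
        samples = vapply(events$samples,
                         function(v) paste(sprintf("%.8g", v),
                                           collapse = ","), ""),
        event_stdv = events$event_stdv)
      data.table::fwrite(out, path, sep = "\t")
    }
    list(events = events, reads = reads, table = table, path = path)
  })
}

#' Linear de Bruijn sequence over ACGT
#'
#' Builds a sequence of length `4^k + k - 1` containing every k-mer exactly
#' once (greedy prefer-largest construction), useful for probing a model's
#' response to each k-mer in a realistic windowed context.
#'
#' @param k k-mer size.
#' @return A DNA string.
#' @export
debruijn_sequence <- function(k) {
  bases <- c("A", "C", "G", "T")
  n <- 4^k
  seen <- logical(n)
  code <- function(v) sum((v - 1L) * 4L^((k - 1L):0)) + 1L
  cur <- rep(1L, k)                 # start at AAAA...A
  out <- cur
  seen[code(cur)] <- TRUE
  for (i in seq_len(n - 1L)) {
    tail <- c(cur[-1L], NA)
    placed <- FALSE
    for (b in 4L:1L) {              # prefer largest unused extension
      tail[k] <- b
      if (!seen[code(tail)]) {
        seen[code(tail)] <- TRUE
        out <- c(out, b)
        cur <- tail
        placed <- TRUE
        break
      }
    }
    if (!placed) stop("de Bruijn construction stalled (internal error)")
  }
  paste(bases[out], collapse = "")
}
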