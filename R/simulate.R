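#' Read-length distribution
#'
#' Families available for genome-mode read sampling. Parameters are fully
#' configurable; the shipped defaults are practical values in the style of
#' earlier genome-mode simulators, not calibrated constants:
#' \itemize{
#' \item `exponential`: `params = list(mean = 8000)`
#' \item `beta`: `params = list(shape1 = 1.8, shape2 = 7.5, scale = 50000)`
#'   (a scaled Beta draw)
#' \item `mixed_gamma`: `params = list(weight = 0.7, shape1 = 2,
#'   scale1 = 1500, shape2 = 6, scale2 = 3000)` (two-component gamma
#'   mixture; `weight` is the probability of component 1)
#' \item `fixed`: `params = list(length = 1000)`
#' }
#' Draws are rounded and clipped to `[min_len, max_len]`.
#'
#' @param kind distribution family.
#' @param params named list of family parameters (defaults filled in).
#' @param min_len,max_len clipping bounds (integers).
#' @return An object of class `length_distribution`.
#' @export
length_distribution <- function(kind = c("exponential", "beta", "mixed_gamma",
                                         "fixed"),
                                params = list(), min_len = 100L,
                                max_len = 100000L) {
  kind <- match.arg(kind)
  defaults <- switch(kind,
    exponential = list(mean = 8000),
    beta = list(shape1 = 1.8, shape2 = 7.5, scale = 50000),
    mixed_gamma = list(weight = 0.7, shape1 = 2, scale1 = 1500,
                       shape2 = 6, scale2 = 3000),
    fixed = list(length = 1000))
  params <- utils::modifyList(defaults, params)
  bad <- vapply(params, function(x) !is.numeric(x) || !is.finite(x) || x <= 0,
                TRUE)
  if (any(bad)) stop("invalid length-distribution parameter(s): ",
                     paste(names(params)[bad], collapse = ", "))
  if (kind == "beta" && (params$shape1 <= 0 || params$shape2 <= 0)) {
    stop("beta shapes must be positive")
  }
  if (kind == "mixed_gamma" && (params$weight <= 0 || params$weight > 1)) {
    stop("mixture weight must be in (0, 1]")
  }
  stopifnot(min_len >= 1, max_len >= min_len)
  structure(list(kind = kind, params = params,
                 min_len = as.integer(min_len),
                 max_len = as.integer(max_len)),
            class = "length_distribution")
}

#' Sample read lengths
#'
#' Draws `n` independent read lengths from the configured family, rounds
#' them and clips to the distribution's `[min_len, max_len]`.
#'
#' @param dist a [length_distribution()].
#' @param n number of draws (>= 1).
#' @param raw if `TRUE`, return the continuous pre-rounding, pre-clipping
#'   draws.
#' @return Integer vector of length `n` (numeric when `raw = TRUE`).
#' @export
sample_read_lengths <- function(dist, n, raw = FALSE) {
  stopifnot(inherits(dist, "length_distribution"), n >= 1)
  p <- dist$params
  x <- switch(dist$kind,
    exponential = stats::rexp(n, rate = 1 / p$mean),
    beta = stats::rbeta(n, p$shape1, p$shape2) * p$scale,
    mixed_gamma = {
      comp1 <- stats::runif(n) < p$weight
      out <- numeric(n)
      out[comp1] <- stats::rgamma(sum(comp1), shape = p$shape1,
                                  scale = p$scale1)
      out[!comp1] <- stats::rgamma(sum(!comp1), shape = p$shape2,
                                   scale = p$scale2)
      out
    },
    fixed = rep(p$length, n))
  if (raw) return(x)
  pmin(pmax(as.integer(round(x)), dist$min_len), dist$max_len)
}

#' Sample reads from a genome
#'
#' Draws read coordinates: contig chosen with probability proportional to
#' its length (among contigs long enough for the drawn read length), start
#' uniform over valid positions, strand uniform; minus-strand sequences are
#' reverse-complemented so every returned sequence is 5'->3' as sequenced.
#' Coordinates are 0-based half-open.
#'
#' @param genome named character vector of contig sequences or a
#'   `Biostrings::DNAStringSet`.
#' @param n number of reads; alternatively give `coverage`.
#' @param coverage target coverage: sampling stops once the summed read
#'   lengths reach `coverage * sum(contig lengths)`.
#' @param dist a [length_distribution()].
#' @return `data.table` with columns `read_id`, `contig`, `start`, `end`,
#'   `strand`, `sequence`.
#' @export
sample_reads <- function(genome, n = NULL, coverage = NULL,
                         dist = length_distribution("fixed")) {
  if (inherits(genome, "DNAStringSet")) {
    genome <- stats::setNames(as.character(genome), names(genome))
  }
  stopifnot(is.character(genome), length(genome) >= 1)
  if (is.null(names(genome))) {
    names(genome) <- paste0("contig", seq_along(genome))
  }
  lens <- nchar(genome)
  if (any(lens <= dist$min_len)) {
    stop("all contigs must be longer than min_len = ", dist$min_len)
  }
  if (is.null(n) && is.null(coverage)) stop("give n or coverage")
  target <- if (!is.null(coverage)) coverage * sum(lens) else Inf
  n_target <- if (!is.null(n)) n else Inf

  out <- list(); total <- 0; i <- 0L
  while (i < n_target && total < target) {
    i <- i + 1L
    L <- sample_read_lengths(dist, 1L)
    ok <- lens >= L
    if (!any(ok)) {
      stop("requested read length ", L, " exceeds every contig length")
    }
    ci <- sample.int(length(genome), 1L, prob = lens * ok)
    start <- sample.int(lens[ci] - L + 1L, 1L) - 1L
    strand <- if (stats::runif(1) < 0.5) "+" else "-"
    s <- substr(genome[ci], start + 1L, start + L)
    if (strand == "-") s <- revcomp(s)
    out[[i]] <- list(read_id = sprintf("sim_%d", i),
                     contig = names(genome)[ci],
                     start = start, end = start + L, strand = strand,
                     sequence = s)
    total <- total + L
  }
  data.table::rbindlist(out)
}

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Decompose a sequence into overlapping k-mers
#'
#' Sliding window of width `k`, stride 1.
#'
#' @param sequence DNA string.
#' @param k k-mer size.
#' @return Character vector of `nchar(sequence) - k + 1` k-mers.
#' @export
sequence_to_kmers <- function(sequence, k) {
  n <- nchar(sequence)
  if (n < k) stop("sequence length ", n, " is shorter than k = ", k)
  substring(sequence, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L)
}

#' Noise configuration
#'
#' Controls the two stochastic components of simulation. Four qualitative
#' modes arise from combining them: no noise in either domain, amplitude
#' noise only, event-length noise only, or both.
#' \itemize{
#' \item `amplitude`: `"learned"` (Gaussian noise with the noise head's
#'   per-event \eqn{\sigma}), `"static"` (Gaussian with fixed
#'   `amplitude_mean`/`amplitude_sd`, default Normal(0, 1)), or `"off"`.
#' \item `duration`: `"learned"` (sample the duration head's gamma),
#'   `"off"` (ideal: the gamma mean \eqn{\alpha/\beta}, rounded), or
#'   `"static"` (Normal(`duration_mean`, `duration_sd`), default
#'   Normal(9, 4), rounded and clamped to >= 1).
#' }
#'
#' @param amplitude,duration mode selectors (see above).
#' @param amplitude_mean,amplitude_sd static amplitude-noise parameters.
#' @param duration_mean,duration_sd static duration parameters.
#' @return An object of class `noise_config`.
#' @export
noise_config <- function(amplitude = c("learned", "off", "static"),
                         duration = c("learned", "off", "static"),
                         amplitude_mean = 0, amplitude_sd = 1,
                         duration_mean = 9, duration_sd = 4) {
  amplitude <- match.arg(amplitude); duration <- match.arg(duration)
  stopifnot(amplitude_sd >= 0, duration_sd >= 0)
  structure(list(amplitude = amplitude, duration = duration,
                 amplitude_mean = amplitude_mean, amplitude_sd = amplitude_sd,
                 duration_mean = duration_mean, duration_sd = duration_sd),
            class = "noise_config")
}

# Batched inference over the windows of one read: returns per-k-mer alpha,
# beta, sigma, the chosen durations and the concatenated decoded signal.
infer_windows <- function(model, kmers, noise, cap = model$config$max_expanded) {
  cfg <- model$config; P <- cfg$chunk_len
  nK <- length(kmers)
  W <- ceiling(nK / P)
  tokens <- c(kmers, rep("_", W * P - nK))
  pad <- tokens == "_"
  X <- encode_tokens_matrix(tokens, cfg$k)
  p <- model$params

  H0 <- pmax(add_bias(X %*% p$We, p$be), 0)
  dp <- predict_durations(model, H0)
  sigma <- predict_sigma(model, H0)

  durations <- switch(noise$duration,
    learned = sample_durations(dp, "stochastic", pad = pad),
    off = sample_durations(dp, "ideal", pad = pad),
    static = {
      d <- pmax(as.integer(round(stats::rnorm(length(tokens),
                                              noise$duration_mean,
                                              noise$duration_sd))), 1L)
      d[pad] <- 0L
      d
    })

  groups <- lapply(seq_len(W), function(w) (w - 1L) * P + seq_len(P))
  Tw <- vapply(groups, function(g) sum(durations[g]), 0L)
  if (any(Tw > cap)) {
    stop("expanded window length ", max(Tw), " exceeds the cap of ", cap,
         "; split the input into smaller chunks")
  }
  H <- H0 + posenc(P, cfg$d_model)[rep(seq_len(P), W), , drop = FALSE]
  for (blk in p$enc) H <- fft_block_fwd(H, blk, groups, cfg$n_heads)$out

  idx_exp <- rep(seq_len(W * P), times = durations)
  tpos <- sequence(Tw)
  E <- H[idx_exp, , drop = FALSE] + posenc(max(tpos), cfg$d_model)[tpos, ,
                                                                   drop = FALSE]
  off <- cumsum(c(0L, Tw[-W]))
  dgroups <- lapply(which(Tw > 0L), function(w) off[w] + seq_len(Tw[w]))
  for (blk in p$dec) E <- fft_block_fwd(E, blk, dgroups, cfg$n_heads)$out
  s <- as.vector(add_bias(E %*% p$proj_W, p$proj_b))

  real <- !pad
  list(alpha = dp$alpha[real], beta = dp$beta[real], sigma = sigma[real],
       durations = durations[real], signal = s)
}

#' Simulate the signal for one sequence
#'
#' Runs the full inference path: k-mer decomposition, windowing into
#' 16-token chunks (last window padded with `"_"`), embedding, duration
#' selection per `noise$duration`, encoder, length regulation, decoder, and
#' amplitude noise per `noise$amplitude`. Window signals are concatenated in
#' order.
#'
#' @param sequence DNA string (length >= k).
#' @param model a [squiggle_model()] or checkpoint path.
#' @param noise a [noise_config()].
#' @param seed optional RNG seed for this read.
#' @return A `simulated_read`: list with `sequence`, `signal` (model
#'   units), `durations` (per k-mer), `event_bounds` (cumulative sample
#'   offsets, strictly increasing), `alpha`, `beta`, `sigma`.
#' @export
simulate_signal <- function(sequence, model, noise = noise_config(),
                            seed = NULL) {
  if (is.character(model)) model <- load_checkpoint(model)
  stopifnot(inherits(model, "squiggle_model"), inherits(noise, "noise_config"))
  with_seed(seed, {
    kmers <- sequence_to_kmers(sequence, model$config$k)
    iw <- infer_windows(model, kmers, noise)
    s <- iw$signal
    s <- switch(noise$amplitude,
      off = s,
      learned = add_noise(s, iw$sigma, iw$durations, "on"),
      static = s + stats::rnorm(length(s), noise$amplitude_mean,
                                noise$amplitude_sd))
    structure(list(sequence = sequence, signal = s,
                   durations = iw$durations,
                   event_bounds = cumsum(iw$durations),
                   alpha = iw$alpha, beta = iw$beta, sigma = iw$sigma),
              class = "simulated_read")
  })
}

#' Simulate a sequencing run
#'
#' Genome-mode: samples reads from the genome ([sample_reads()]) and
#' simulates each; read-mode (`read_input = TRUE`): simulates each input
#' record's sequence verbatim. Results are exported as ASCII SLOW5 and a
#' ground-truth TSV (`read_id`, `contig`, `start`, `end`, `strand`,
#' `n_samples`; 0-based half-open coordinates) is written alongside.
#'
#' @param input path to a FASTA genome (genome-mode) or FASTA/FASTQ reads
#'   (read-mode), or a named character vector / `DNAStringSet`.
#' @param model a [squiggle_model()] or checkpoint path.
#' @param out output SLOW5 path; the ground truth goes to
#'   `paste0(out, ".truth.tsv")` unless `truth_out` is given.
#' @param n,coverage genome-mode read count or coverage target.
#' @param dist a [length_distribution()] (genome-mode).
#' @param noise a [noise_config()].
#' @param read_input `TRUE` for read-mode.
#' @param seed RNG seed for the whole run.
#' @param truth_out optional ground-truth TSV path.
#' @return Invisibly, a list of `simulated_read` objects (with `read_id`,
#'   `contig`, `start`, `end`, `strand` fields filled in).
#' @export
simulate_run <- function(input, model, out, n = NULL, coverage = NULL,
                         dist = length_distribution("exponential"),
                         noise = noise_config(), read_input = FALSE,
                         seed = NULL, truth_out = NULL) {
  if (is.character(model)) model <- load_checkpoint(model)
  stopifnot(inherits(model, "squiggle_model"))
  if (model$config$k != model$profile$k) {
    stop("checkpoint k does not match its pore profile k")
  }
  seqs <- if (is.character(input) && length(input) == 1L && file.exists(input))
    read_sequences(input) else input
  if (inherits(seqs, "DNAStringSet")) {
    seqs <- stats::setNames(as.character(seqs), names(seqs))
  }
  with_seed(seed, {
    if (read_input) {
      tab <- data.table::data.table(
        read_id = if (!is.null(names(seqs))) names(seqs) else
          sprintf("sim_%d", seq_along(seqs)),
        contig = NA_character_, start = NA_integer_, end = NA_integer_,
        strand = NA_character_, sequence = unname(seqs))
    } else {
      tab <- sample_reads(seqs, n = n, coverage = coverage, dist = dist)
    }
    reads <- vector("list", nrow(tab))
    for (i in seq_len(nrow(tab))) {
      r <- simulate_signal(tab$sequence[i], model, noise)
      r$read_id <- tab$read_id[i]
      r$contig <- tab$contig[i]; r$start <- tab$start[i]
      r$end <- tab$end[i]; r$strand <- tab$strand[i]
      reads[[i]] <- r
    }
    write_slow5(reads, model$profile, out)
    gt <- data.table::data.table(
      read_id = tab$read_id, contig = tab$contig, start = tab$start,
      end = tab$end, strand = tab$strand,
      n_samples = vapply(reads, function(r) length(r$signal), 0))
    data.table::fwrite(gt, truth_out %||% paste0(out, ".truth.tsv"),
                       sep = "\t")
    invisible(reads)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
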