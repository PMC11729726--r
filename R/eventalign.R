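#' Default eventalign column map
#'
#' Column names used to interpret an eventalign-style TSV, in the dialect of
#' uncalled4/nanopolish `eventalign --samples` output. Override any entry, or
#' supply a YAML file with the same keys, to adapt to other layouts.
#'
#' `stdv_col` selects where the per-event amplitude-noise level
#' \eqn{\sigma_{ref}} comes from; the default is the per-event sample
#' standard deviation column.
#'
#' @return Named list of column names.
#' @export
eventalign_colmap <- function() {
  list(read_id = "read_name", contig = "contig", position = "position",
       kmer = "model_kmer", samples = "samples", stdv_col = "event_stdv",
       mean = "event_level_mean", length = "event_length")
}

#' Parse an eventalign-style TSV
#'
#' Reads a tab-separated segmentation table (one row per event, i.e. per
#' k-mer occupying the pore) and returns the events grouped by read in
#' ascending reference position order. Raw samples are taken from a
#' comma-separated `samples` column when present; otherwise each event is
#' reconstructed as `length` copies of its mean level with the reported
#' standard deviation kept as \eqn{\sigma_{ref}}.
#'
#' @param path TSV file path.
#' @param profile a [pore_profile()]; events must carry k-mers of length
#'   `profile$k`.
#' @param colmap column map as from [eventalign_colmap()], or a path to a
#'   YAML file with the same keys.
#' @return A `data.table` with columns `read_id`, `contig`, `position`
#'   (0-based k-mer start), `kmer`, `samples` (list column of numeric
#'   vectors), `event_stdv`; rows grouped by read, position-ascending.
#' @export
parse_eventalign <- function(path, profile, colmap = eventalign_colmap()) {
  stopifnot(file.exists(path))
  if (is.character(colmap) && length(colmap) == 1L) {
    colmap <- utils::modifyList(eventalign_colmap(), yaml::read_yaml(colmap))
  }
  if (file.size(path) == 0L) {
    return(data.table::data.table(read_id = character(), contig = character(),
                                  position = integer(), kmer = character(),
                                  samples = list(), event_stdv = numeric()))
  }
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = list(character = colmap$kmer))
  need <- c(colmap$read_id, colmap$contig, colmap$position, colmap$kmer)
  miss <- setdiff(need, names(dt))
  if (length(miss)) {
    stop("eventalign table is missing column(s): ", paste(miss, collapse = ", "))
  }
  out <- data.table::data.table(
    read_id  = as.character(dt[[colmap$read_id]]),
    contig   = as.character(dt[[colmap$contig]]),
    position = as.integer(dt[[colmap$position]]),
    kmer     = dt[[colmap$kmer]])

  bad_len <- which(nchar(out$kmer) != profile$k)
  if (length(bad_len)) {
    stop(sprintf("line %d: k-mer '%s' has length %d, expected k=%d",
                 bad_len[1] + 1L, out$kmer[bad_len[1]],
                 nchar(out$kmer[bad_len[1]]), profile$k))
  }
  bad_chr <- grep("[^ACGT]", out$kmer)
  if (length(bad_chr)) {
    stop(sprintf("line %d: k-mer '%s' contains characters outside {A,C,G,T}",
                 bad_chr[1] + 1L, out$kmer[bad_chr[1]]))
  }

  if (!is.null(colmap$samples) && colmap$samples %in% names(dt)) {
    raw <- as.character(dt[[colmap$samples]])
    samp <- lapply(seq_along(raw), function(i) {
      v <- suppressWarnings(as.numeric(strsplit(raw[i], ",", fixed = TRUE)[[1]]))
      if (length(v) == 0L || anyNA(v)) {
        stop(sprintf("line %d: malformed samples field", i + 1L))
      }
      v
    })
    if (colmap$stdv_col %in% names(dt)) {
      stdv <- as.numeric(dt[[colmap$stdv_col]])
    } else {
      stdv <- vapply(samp, function(v) if (length(v) > 1L) stats::sd(v) else 0, 0)
    }
  } else if (all(c(colmap$mean, colmap$stdv_col, colmap$length) %in% names(dt))) {
    n_samp <- as.integer(round(as.numeric(dt[[colmap$length]])))
    if (any(n_samp < 1L)) {
      stop(sprintf("line %d: event length < 1 sample", which(n_samp < 1L)[1] + 1L))
    }
    mu <- as.numeric(dt[[colmap$mean]])
    samp <- lapply(seq_along(mu), function(i) rep(mu[i], n_samp[i]))
    stdv <- as.numeric(dt[[colmap$stdv_col]])
  } else {
    stop("eventalign table needs either a '", colmap$samples,
         "' column or '", colmap$mean, "'+'", colmap$stdv_col, "'+'",
         colmap$length, "' columns")
  }
  if (any(stdv < 0)) {
    stop(sprintf("line %d: negative event stdv", which(stdv < 0)[1] + 1L))
  }
  out[, `:=`(samples = samp, event_stdv = stdv)]
  # group by read in order of first appearance, positions ascending within
  out[, .ord := seq_len(.N)]
  first <- out[, .(f = min(.ord)), by = read_id]
  out <- merge(out, first, by = "read_id", sort = FALSE)
  data.table::setorder(out, f, position)
  dup <- out[, any(duplicated(position)), by = read_id]
  if (any(dup$V1)) {
    stop("duplicated event position within read ", dup$read_id[dup$V1][1])
  }
  out[, c(".ord", "f") := NULL]
  out[]
}

#' Assemble training chunks from events
#'
#' Tiles each read's events into non-overlapping windows of `chunk_len`
#' consecutive k-mer positions (a gap in reference positions closes the
#' current window and starts a new one). The window's reference signal is the
#' concatenation of its events' raw samples, zero-padded to `max_signal`;
#' windows whose concatenated samples exceed `max_signal` are discarded
#' outright rather than truncated. A final partial window is padded with the
#' empty symbol `"_"` (duration 0, \eqn{\sigma_{ref}} 0).
#'
#' @param events event table from [parse_eventalign()] (or
#'   [make_eventalign()] with `as_table = TRUE`).
#' @param chunk_len tokens per chunk (default 16).
#' @param max_signal signal-point cap per chunk (default 250).
#' @return A chunk store: list with `tokens` (character matrix N x chunk_len,
#'   k-mers or `"_"`), `durations` (integer N x chunk_len), `sigma`
#'   (numeric N x chunk_len), `signal` (numeric N x max_signal, zero-padded),
#'   `mask` (logical N x max_signal), plus `k`, `chunk_len`, `max_signal`,
#'   `n_dropped` (windows over the cap).
#' @export
build_chunks <- function(events, chunk_len = 16L, max_signal = 250L) {
  chunk_len <- as.integer(chunk_len); max_signal <- as.integer(max_signal)
  tok_l <- list(); dur_l <- list(); sig_l <- list(); sd_l <- list()
  n_dropped <- 0L
  k <- if (nrow(events)) nchar(events$kmer[1]) else NA_integer_

  flush <- function(kmers, samp, stdv) {
    # one window (<= chunk_len events); returns NULL when over the cap
    total <- sum(lengths(samp))
    if (total > max_signal) return(NULL)
    n <- length(kmers)
    pad <- chunk_len - n
    list(tokens = c(kmers, rep("_", pad)),
         durations = c(lengths(samp), rep(0L, pad)),
         sigma = c(stdv, rep(0, pad)),
         signal = c(unlist(samp, use.names = FALSE),
                    rep(0, max_signal - total)),
         mask = c(rep(TRUE, total), rep(FALSE, max_signal - total)))
  }

  if (nrow(events)) {
    split_idx <- split(seq_len(nrow(events)),
                       factor(events$read_id, levels = unique(events$read_id)))
    for (idx in split_idx) {
      pos <- events$position[idx]
      # segments of consecutive positions (gap => new segment)
      seg_id <- cumsum(c(1L, as.integer(diff(pos) != 1L)))
      for (seg in split(idx, seg_id)) {
        n <- length(seg)
        starts <- seq.int(1L, n, by = chunk_len)
        for (s in starts) {
          e <- min(s + chunk_len - 1L, n)
          w <- seg[s:e]
          ch <- flush(events$kmer[w], events$samples[w], events$event_stdv[w])
          if (is.null(ch)) { n_dropped <- n_dropped + 1L; next }
          tok_l[[length(tok_l) + 1L]] <- ch$tokens
          dur_l[[length(dur_l) + 1L]] <- ch$durations
          sd_l[[length(sd_l) + 1L]] <- ch$sigma
          sig_l[[length(sig_l) + 1L]] <- c(ch$signal, ch$mask)
        }
      }
    }
  }

  n_chunks <- length(tok_l)
  sigmat <- matrix(0, n_chunks, max_signal)
  maskmat <- matrix(FALSE, n_chunks, max_signal)
  if (n_chunks) {
    m <- do.call(rbind, sig_l)
    sigmat <- m[, seq_len(max_signal), drop = FALSE]
    maskmat <- m[, max_signal + seq_len(max_signal), drop = FALSE] > 0
  }
  structure(list(
    tokens = matrix(if (n_chunks) unlist(tok_l) else character(),
                    nrow = n_chunks, ncol = chunk_len, byrow = TRUE),
    durations = matrix(if (n_chunks) as.integer(unlist(dur_l)) else integer(),
                       nrow = n_chunks, ncol = chunk_len, byrow = TRUE),
    sigma = matrix(if (n_chunks) unlist(sd_l) else numeric(),
                   nrow = n_chunks, ncol = chunk_len, byrow = TRUE),
    signal = sigmat, mask = maskmat,
    k = k, chunk_len = chunk_len, max_signal = max_signal,
    n_dropped = n_dropped), class = "chunk_store")
}

#' @export
print.chunk_store <- function(x, ...) {
  cat(sprintf("<chunk_store> %d chunks (%d x %d tokens, cap %d samples), %d dropped\n",
              nrow(x$tokens), nrow(x$tokens), x$chunk_len, x$max_signal,
              x$n_dropped))
  invisible(x)
}

#' Save / load a chunk store
#'
#' The store is a versioned RDS container holding the matrices described in
#' [build_chunks()] (`tokens` character, `durations` integer, `sigma` and
#' `signal` double, `mask` logical) plus the `k`/`chunk_len`/`max_signal`
#' metadata.
#'
#' @param store a `chunk_store`.
#' @param path file path.
#' @return `read_chunks` returns the `chunk_store`.
#' @export
write_chunks <- function(store, path) {
  stopifnot(inherits(store, "chunk_store"))
  saveRDS(c(list(.format = "squigglesim_chunks", .version = 1L),
            unclass(store)), path)
  invisible(path)
}

#' @rdname write_chunks
#' @export
read_chunks <- function(path) {
  x <- readRDS(path)
  if (!identical(x$.format, "squigglesim_chunks")) {
    stop("not a squigglesim chunk store: ", path)
  }
  x$.format <- NULL; x$.version <- NULL
  structure(x, class = "chunk_store")
}

#' One-hot encode a chunk's tokens
#'
#' Each of the `length(tokens)` positions holds a k-mer (or `"_"`); every
#' nucleotide is encoded as a length-5 indicator over the vocabulary
#' (A, C, G, T, _), and `"_"` as k copies of the `"_"` indicator. The
#' encoding is flattened position-major into a vector of length
#' `length(tokens) * k * 5`.
#'
#' @param tokens character vector of k-mers / `"_"` symbols.
#' @param k k-mer size.
#' @return Numeric 0/1 vector of length `length(tokens) * k * 5` containing
#'   exactly `length(tokens) * k` ones.
#' @export
encode_tokens <- function(tokens, k) {
  as.vector(t(encode_tokens_matrix(tokens, k)))
}

# Matrix form used internally: one row per position, k*5 columns.
encode_tokens_matrix <- function(tokens, k) {
  voc <- vocabulary()
  out <- matrix(0, nrow = length(tokens), ncol = k * 5L)
  # pad symbol: k repeats of the "_" indicator [0,0,0,0,1]
  pad_row <- rep(0, k * 5L); pad_row[seq_len(k) * 5L] <- 1
  for (i in seq_along(tokens)) {
    tk <- tokens[i]
    if (tk == "_") { out[i, ] <- pad_row; next }
    if (nchar(tk) != k) stop("token '", tk, "' does not have length k=", k)
    ch <- strsplit(tk, "", fixed = TRUE)[[1]]
    m <- match(ch, voc)
    if (anyNA(m)) stop("token '", tk, "' contains an unknown character")
    out[i, (seq_len(k) - 1L) * 5L + m] <- 1
  }
  out
}
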