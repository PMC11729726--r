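#' Digitize a model-space signal to ADC counts
#'
#' Applies the profile's linear maps: model units -> picoamperes
#' (`pA = x * norm_scale + norm_shift`) -> raw counts
#' (`raw = round(pA * digitisation / range - offset)`), clamped to the
#' signed 16-bit range. [undigitize()] is the documented inverse (exact up
#' to the rounding step).
#'
#' @param x numeric signal in model units (finite).
#' @param profile a [pore_profile()].
#' @return Integer vector of raw counts.
#' @export
digitize <- function(x, profile) {
  if (any(!is.finite(x))) stop("non-finite signal value cannot be digitized")
  pa <- x * profile$norm_scale + profile$norm_shift
  raw <- round(pa * profile$digitisation / profile$range - profile$offset)
  as.integer(pmin(pmax(raw, -32768), 32767))
}

#' @rdname digitize
#' @param raw integer raw counts.
#' @export
undigitize <- function(raw, profile) {
  pa <- (raw + profile$offset) * profile$range / profile$digitisation
  (pa - profile$norm_shift) / profile$norm_scale
}

# shortest decimal representation that round-trips the double exactly, so
# headers stay readable and the SLOW5 round trip is lossless
fmt_num <- function(x) {
  vapply(x, function(v) {
    if (v == round(v) && abs(v) < 1e15) return(sprintf("%.0f", v))
    for (d in 1:17) {
      s <- sprintf("%.*g", d, v)
      if (as.numeric(s) == v) return(s)
    }
    sprintf("%.17g", v)
  }, "")
}

#' Write reads to ASCII SLOW5
#'
#' Writes the v0.2 ASCII SLOW5 dialect: version/read-group header lines,
#' `@` attributes (digitisation, offset, range, sampling_rate), the two
#' column-description lines, and one tab-separated record per read with a
#' comma-separated raw-signal field. Signals held in model units are
#' digitized with the profile; integer signals (`$raw`) are written as-is.
#'
#' @param reads list of `simulated_read` objects (or lists with `read_id`
#'   and `signal` or `raw`).
#' @param profile a [pore_profile()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_slow5 <- function(reads, profile, path) {
  if (!length(reads)) stop("empty read list")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "#slow5_version\t0.2.0",
    "#num_read_groups\t1",
    paste0("@digitisation\t", fmt_num(profile$digitisation)),
    paste0("@offset\t", fmt_num(profile$offset)),
    paste0("@range\t", fmt_num(profile$range)),
    paste0("@sampling_rate\t", fmt_num(profile$sample_rate)),
    paste("#char*", "uint32_t", "double", "double", "double", "double",
          "uint64_t", "int16_t*", sep = "\t"),
    paste("#read_id", "read_group", "digitisation", "offset", "range",
          "sampling_rate", "len_raw_signal", "raw_signal", sep = "\t")),
    con)
  for (i in seq_along(reads)) {
    r <- reads[[i]]
    raw <- if (!is.null(r$raw)) as.integer(r$raw) else
      digitize(r$signal, profile)
    id <- r$read_id %||% sprintf("sim_%d", i)
    writeLines(paste(id, 0L, fmt_num(profile$digitisation),
                     fmt_num(profile$offset), fmt_num(profile$range),
                     fmt_num(profile$sample_rate), length(raw),
                     paste(raw, collapse = ","), sep = "\t"), con)
  }
  invisible(path)
}

#' Read an ASCII SLOW5 file
#'
#' Parses the dialect written by [write_slow5()]: raw counts are recovered
#' exactly as integers, header attributes as doubles.
#'
#' @param path SLOW5 path.
#' @return List with `reads` (list of `list(read_id, raw)` in file order)
#'   and `attrs` (named numeric: digitisation, offset, range,
#'   sampling_rate).
#' @export
read_slow5 <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || !startsWith(lines[1], "#slow5_version")) {
    stop("malformed SLOW5 header in ", path, ": missing #slow5_version")
  }
  attr_lines <- grep("^@", lines, value = TRUE)
  kv <- strsplit(attr_lines, "\t", fixed = TRUE)
  attrs <- stats::setNames(vapply(kv, function(x) as.numeric(x[2]), 0),
                           sub("^@", "", vapply(kv, `[`, "", 1)))
  need <- c("digitisation", "offset", "range", "sampling_rate")
  if (!all(need %in% names(attrs))) {
    stop("malformed SLOW5 header in ", path, ": missing attribute(s) ",
         paste(setdiff(need, names(attrs)), collapse = ", "))
  }
  rec <- lines[!startsWith(lines, "#") & !startsWith(lines, "@")]
  reads <- lapply(rec, function(ln) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 8) stop("malformed SLOW5 record: ", substr(ln, 1, 40))
    raw <- as.integer(strsplit(f[8], ",", fixed = TRUE)[[1]])
    if (length(raw) != as.integer(f[7])) {
      stop("len_raw_signal mismatch for read ", f[1])
    }
    list(read_id = f[1], raw = raw)
  })
  list(reads = reads, attrs = attrs)
}

#' Export reads to POD5
#'
#' POD5 is a binary vendor format; writing it is delegated to an external
#' POD5 writer hooked in via `options(squigglesim.pod5_writer = <function>)`.
#' Without such a hook this function stops with a pointer to SLOW5 export.
#'
#' @inheritParams write_slow5
#' @return Invisibly, `path`.
#' @export
export_pod5 <- function(reads, profile, path) {
  writer <- getOption("squigglesim.pod5_writer")
  if (is.null(writer)) {
    stop("POD5 export needs a POD5 library; none is hooked in ",
         "(options(squigglesim.pod5_writer=...)). ",
         "Use write_slow5() for the ASCII SLOW5 format instead.")
  }
  writer(reads, profile, path)
  invisible(path)
}

#' Read sequences from FASTA/FASTQ
#'
#' Format is inferred from the extension (`.fq`/`.fastq`, optionally
#' `.gz`-compressed, are FASTQ; everything else FASTA).
#'
#' @param path file path.
#' @return A `Biostrings::DNAStringSet`.
#' @export
read_sequences <- function(path) {
  fq <- grepl("\\.(fq|fastq)(\\.gz)?$", path, ignore.case = TRUE)
  Biostrings::readDNAStringSet(path, format = if (fq) "fastq" else "fasta")
}
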