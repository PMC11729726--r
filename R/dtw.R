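#' Z-normalize a signal
#'
#' Centers to mean 0 and scales to SD 1; a constant (zero-SD) input maps to
#' all zeros. Standard practice before DTW comparison of squiggles so that
#' per-read scaling/offset differences do not dominate the distance.
#'
#' @param x numeric vector.
#' @return Normalized vector.
#' @export
znorm <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

#' Dynamic time warping distance
#'
#' Exact quadratic dynamic program with steps \{(1,0), (0,1), (1,1)\} and
#' per-cell cost `|x_i - y_j|` (or its square). The reported `normalized`
#' value divides the warping cost by the length of `x`, the reference
#' signal, to account for read-length differences. Inputs should be
#' z-normalized by the caller (see [znorm()]).
#'
#' @param x reference signal (nonempty numeric).
#' @param y query signal (nonempty numeric).
#' @param cost `"abs"` or `"squared"` per-cell cost.
#' @return A `dtw_result`: list with `cost`, `path_len`, `normalized`.
#' @export
dtw <- function(x, y, cost = c("abs", "squared")) {
  cost <- match.arg(cost)
  if (!length(x) || !length(y)) stop("dtw: empty input signal")
  r <- dtw_cpp(as.numeric(x), as.numeric(y), cost == "squared")
  structure(list(cost = r$cost, path_len = r$path_len,
                 normalized = r$cost / length(x)),
            class = "dtw_result")
}

#' @export
print.dtw_result <- function(x, ...) {
  cat(sprintf("<dtw> cost=%.4f path_len=%d normalized=%.4f\n",
              x$cost, x$path_len, x$normalized))
  invisible(x)
}

#' Compare two signal runs by per-read DTW
#'
#' Pairs reads of two SLOW5 files by read id (read-mode comparison),
#' z-normalizes each raw signal, and computes the length-normalized DTW
#' distance per pair; at most `max_reads` pairs are scored to bound the
#' quadratic cost.
#'
#' @param real path to the reference (e.g. experimental) SLOW5 file; its
#'   signal lengths are the normalization denominators.
#' @param sim path to the simulated SLOW5 file.
#' @param max_reads cap on scored pairs (default 2000).
#' @param cost per-cell cost, as in [dtw()].
#' @return List with `table` (`data.table`: read_id, cost, path_len,
#'   normalized) and `median` (median normalized DTW).
#' @export
compare_runs <- function(real, sim, max_reads = 2000L,
                         cost = c("abs", "squared")) {
  cost <- match.arg(cost)
  a <- read_slow5(real); b <- read_slow5(sim)
  ids_a <- vapply(a$reads, `[[`, "", "read_id")
  ids_b <- vapply(b$reads, `[[`, "", "read_id")
  shared <- intersect(ids_a, ids_b)
  if (!length(shared)) stop("no shared read ids between the two files")
  shared <- shared[seq_len(min(length(shared), max_reads))]
  res <- lapply(shared, function(id) {
    xr <- a$reads[[match(id, ids_a)]]$raw
    yr <- b$reads[[match(id, ids_b)]]$raw
    d <- dtw(znorm(xr), znorm(yr), cost)
    data.table::data.table(read_id = id, cost = d$cost,
                           path_len = d$path_len, normalized = d$normalized)
  })
  tab <- data.table::rbindlist(res)
  list(table = tab, median = stats::median(tab$normalized))
}
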