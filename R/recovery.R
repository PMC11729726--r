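#' Evaluate parameter recovery against a ground-truth pore table
#'
#' Probes a trained model with a linear de Bruijn sequence (every k-mer
#' exactly once, embedded in fully populated 16-token windows) simulated in
#' noise-free ideal-duration mode, and compares three per-k-mer quantities
#' with the generating [make_pore_table()]:
#' \itemize{
#' \item the mean decoded signal over each k-mer's event vs the table level
#'   (Pearson correlation `level_r`);
#' \item the duration head's gamma mean \eqn{\alpha/\beta} vs the table's
#'   gamma mean (mean relative error `duration_mre`);
#' \item the noise head's \eqn{\sigma} vs the table's \eqn{\sigma}
#'   (mean relative error `sigma_mre`).
#' }
#'
#' @param model a trained [squiggle_model()].
#' @param table the generating `pore_table` (same k).
#' @return List with `level_r`, `duration_mre`, `sigma_mre`, `n_kmers` and
#'   a per-k-mer `data.table` (`kmer`, `level_true`, `level_pred`,
#'   `dur_mean_true`, `dur_mean_pred`, `sigma_true`, `sigma_pred`).
#' @export
evaluate_recovery <- function(model, table) {
  stopifnot(inherits(model, "squiggle_model"), inherits(table, "pore_table"),
            model$config$k == table$k)
  kmers <- sequence_to_kmers(debruijn_sequence(table$k), table$k)
  iw <- infer_windows(model, kmers, noise_config("off", "off"))
  cb <- cumsum(iw$durations)
  lev <- vapply(seq_along(kmers), function(i) {
    lo <- if (i == 1) 1L else cb[i - 1] + 1L
    mean(iw$signal[lo:cb[i]])
  }, 0)
  truth_mean <- unname((table$alpha / table$beta)[kmers])
  tab <- data.table::data.table(
    kmer = kmers,
    level_true = unname(table$level[kmers]), level_pred = lev,
    dur_mean_true = truth_mean, dur_mean_pred = iw$alpha / iw$beta,
    sigma_true = unname(table$sigma[kmers]), sigma_pred = iw$sigma)
  list(level_r = stats::cor(tab$level_true, tab$level_pred),
       duration_mre = mean(abs(tab$dur_mean_pred - tab$dur_mean_true) /
                             tab$dur_mean_true),
       sigma_mre = mean(abs(tab$sigma_pred - tab$sigma_true) /
                          tab$sigma_true),
       n_kmers = length(kmers), per_kmer = tab)
}
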