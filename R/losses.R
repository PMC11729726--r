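#' Masked signal loss (MSE)
#'
#' Mean squared error between reference and predicted signal over the real
#' (unpadded) samples only.
#'
#' @param s_ref,s_pred numeric vectors of equal length.
#' @param mask logical vector marking real samples; at least one `TRUE`.
#' @return Scalar MSE.
#' @export
signal_loss <- function(s_ref, s_pred, mask = rep(TRUE, length(s_ref))) {
  stopifnot(length(s_ref) == length(s_pred), length(mask) == length(s_ref))
  if (!any(mask)) stop("signal mask is empty: no real samples to score")
  mean((s_ref[mask] - s_pred[mask])^2)
}

#' Event-duration loss (gamma negative log-likelihood)
#'
#' \eqn{\tau}-scaled mean negative log-likelihood of the observed event
#' lengths under per-position Gamma(shape \eqn{\alpha}, rate \eqn{\beta})
#' distributions:
#' \deqn{\tau \cdot \frac{1}{n}\sum_i -\log f(l_i;\alpha_i,\beta_i), \quad
#'   f(l) = \frac{\beta^{\alpha} l^{\alpha-1} e^{-\beta l}}{\Gamma(\alpha)}}
#' Only real (non-padded) positions may be passed in.
#'
#' @param l_data positive event lengths (samples per event).
#' @param alpha,beta gamma shape and rate, > 0, same length as `l_data`.
#' @param tau loss scale factor (default 0.0005).
#' @return Scalar tau-scaled NLL.
#' @export
duration_loss <- function(l_data, alpha, beta, tau = 5e-4) {
  stopifnot(length(alpha) == length(l_data), length(beta) == length(l_data),
            all(alpha > 0), all(beta > 0), tau > 0)
  if (any(l_data <= 0)) stop("non-positive event length at a real position")
  nll <- -(alpha * log(beta) + (alpha - 1) * log(l_data) - beta * l_data -
             lgamma(alpha))
  tau * mean(nll)
}

#' Amplitude-noise loss (MSE)
#'
#' Mean squared error between the per-event reference noise SD
#' \eqn{\sigma_{ref}} and the predicted \eqn{\sigma_{pred}} over real
#' positions.
#'
#' @param sigma_ref,sigma_pred numeric vectors of equal length.
#' @return Scalar MSE.
#' @export
noise_loss <- function(sigma_ref, sigma_pred) {
  stopifnot(length(sigma_ref) == length(sigma_pred))
  mean((sigma_ref - sigma_pred)^2)
}

#' Combine the three losses
#'
#' Unweighted sum of the masked signal MSE, the tau-scaled duration NLL and
#' the noise MSE (the only weighting is the \eqn{\tau} factor already inside
#' the duration term).
#'
#' @param mse_signal,nll_duration,mse_noise the three component losses.
#' @return A `loss_report` list with the components and their `total`.
#' @export
total_loss <- function(mse_signal, nll_duration, mse_noise) {
  structure(list(mse_signal = mse_signal, nll_duration = nll_duration,
                 mse_noise = mse_noise,
                 total = mse_signal + nll_duration + mse_noise),
            class = "loss_report")
}

#' @export
print.loss_report <- function(x, ...) {
  cat(sprintf("loss total=%.6g (signal=%.6g, duration=%.6g, noise=%.6g)\n",
              x$total, x$mse_signal, x$nll_duration, x$mse_noise))
  invisible(x)
}
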