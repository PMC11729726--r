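#' Nanopore pore profile
#'
#' A pore profile bundles the constants needed to move between the three
#' signal spaces the package works in: model units (the normalized space the
#' segmentation tool emits and the network is trained in), picoamperes, and
#' digitized 16-bit ADC counts as stored in SLOW5/POD5 files.
#'
#' The linear maps are
#' \deqn{pA = x \cdot norm\_scale + norm\_shift}
#' \deqn{raw = round(pA \cdot digitisation / range - offset)}
#' and their inverses are used on import. `digitisation`, `range` and
#' `offset` for the shipped profiles are documented placeholders in the style
#' of the respective chemistries and can be overridden.
#'
#' @param k k-mer size occupying the pore (6 for R9-style, 9 for R10-style
#'   profiles; any positive integer is accepted for synthetic work).
#' @param sample_rate sampling rate in Hz (4000 or 5000 for shipped profiles).
#' @param digitisation ADC digitisation constant (> 0).
#' @param range pA span covered by the ADC (> 0).
#' @param offset ADC offset.
#' @param norm_scale,norm_shift linear map from model units to pA.
#' @param name profile label.
#' @return An object of class `pore_profile`.
#' @examples
#' p <- pore_profile(k = 5)
#' p$sample_rate
#' @export
pore_profile <- function(k = 6L, sample_rate = 4000, digitisation = 8192,
                         range = 1443.03, offset = 10, norm_scale = 20,
                         norm_shift = 90, name = "custom") {
  k <- as.integer(k)
  stopifnot(k >= 1L, digitisation > 0, range > 0, sample_rate > 0,
            is.finite(norm_scale), is.finite(norm_shift))
  structure(list(k = k, sample_rate = sample_rate,
                 digitisation = digitisation, range = range, offset = offset,
                 norm_scale = norm_scale, norm_shift = norm_shift,
                 name = name),
            class = "pore_profile")
}

#' Built-in pore profiles
#'
#' Returns one of the shipped profiles: `"r9-4khz"` (k = 6, 4 kHz),
#' `"r10-4khz"` (k = 9, 4 kHz) or `"r10-5khz"` (k = 9, 5 kHz).
#' Digitisation/range/offset values are representative defaults, not
#' vendor-calibrated constants; override them for exact pipelines.
#'
#' @param name profile name.
#' @return A `pore_profile`.
#' @export
default_profile <- function(name = c("r9-4khz", "r10-4khz", "r10-5khz")) {
  name <- match.arg(name)
  switch(name,
    "r9-4khz"  = pore_profile(k = 6L, sample_rate = 4000, digitisation = 8192,
                              range = 1443.03, offset = 10, norm_scale = 20,
                              norm_shift = 90, name = name),
    "r10-4khz" = pore_profile(k = 9L, sample_rate = 4000, digitisation = 2048,
                              range = 281.88, offset = 10, norm_scale = 15,
                              norm_shift = 80, name = name),
    "r10-5khz" = pore_profile(k = 9L, sample_rate = 5000, digitisation = 2048,
                              range = 281.88, offset = 10, norm_scale = 15,
                              norm_shift = 80, name = name))
}

#' @export
print.pore_profile <- function(x, ...) {
  cat(sprintf(
    "<pore_profile '%s'> k=%d, %g Hz, digitisation=%g, range=%g, offset=%g\n",
    x$name, x$k, x$sample_rate, x$digitisation, x$range, x$offset))
  invisible(x)
}

#' Model vocabulary
#'
#' The five symbols the model knows: the four DNA bases and the empty
#' (padding) symbol `"_"`, in this fixed order.
#'
#' @return Character vector `c("A","C","G","T","_")`.
#' @export
vocabulary <- function() c("A", "C", "G", "T", "_")

# Run code with a temporarily fixed RNG state; restores the caller's state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}
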