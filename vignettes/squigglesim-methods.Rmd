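---
title: "squigglesim: model, training and simulation methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{squigglesim: model, training and simulation methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

A nanopore sequencer reports an ionic-current time series (a "squiggle") as a
DNA molecule translocates the pore. At any instant the current level is
determined mostly by the k bases occupying the pore (k = 6 for R9-style
chemistry, k = 9 for R10-style), the dwell time of each k-mer is random, and
the measured amplitude is noisy. Simulating realistic squiggles from
nucleotide input is essential for benchmarking basecallers, variant-calling
pipelines and signal-level tools.

Classic simulators look up each k-mer's expected level in a fixed pore-model
table, draw an event duration from a fixed distribution and add Gaussian
noise with fixed parameters. squigglesim instead learns the whole mapping
end-to-end from segmented signal data: a feed-forward transformer (FFT)
predicts the signal directly from the sequence, and dedicated heads learn the
event-duration and amplitude-noise distributions per position.

## Model

The generator is non-autoregressive, in the style of feed-forward
text-to-speech models, where a short source sequence must be expanded to a
much longer target sequence:

1. **Tokens.** The input is processed in windows of 16 k-mers. The vocabulary
   has five symbols: A, C, G, T and the empty symbol `_` used to pad the last
   window. Every nucleotide of every k-mer is one-hot encoded over these five
   symbols and the window's encoding is flattened (16 x k x 5 values).
2. **Embedding.** A shared dense layer with ReLU maps each position's
   flattened one-hot vector (k x 5 values) to a `d_model`-dimensional hidden
   state.
3. **Encoder.** Sinusoidal positional encodings are added and two FFT blocks
   are applied. Each block is standard multi-head self-attention plus a
   position-wise feed-forward sublayer, each wrapped in a residual connection
   with post-layer-normalization.
4. **Length regulator.** Position i's hidden state is repeated `d_i` times,
   where `d_i` is the event duration in samples (teacher-forced from the
   segmentation during training, drawn from the duration head at inference).
5. **Decoder.** Positional encodings are added to the expanded sequence, two
   more FFT blocks run over it, and a position-wise linear projection yields
   one signal value per time step.
6. **Duration head.** Two dense layers with ReLU on the *embedding* output
   produce two scalars per position, transformed by softplus (+1e-6) into the
   shape `alpha` and rate `beta` of a gamma distribution over event length.
7. **Noise head.** The same architecture predicts `sigma`, the per-position
   SD of Gaussian amplitude noise, added to the decoded signal at inference.

Both samplers tap the embedding (pre-attention) rather than the encoder
output. The published architecture diagrams feed "the DNA embeddings" to
both heads; tapping pre-attention keeps the heads position-wise, so a
k-mer's duration and noise law depend only on the k-mer itself. This is
cheap, easy to reason about, and matches how segmentation statistics are
usually tabulated (per k-mer).

## Losses and training

Training uses chunks of 16 consecutive events, capped at 250 signal points
(longer windows are discarded, not truncated; the final partial window of a
read is padded with `_`, duration 0). With teacher-forced durations the
decoded signal aligns sample-by-sample with the reference, so three losses
apply:

* **Signal loss** — mean squared error between reference and predicted
  signal over real (unpadded) samples.
* **Duration loss** — negative log-likelihood of the reference event lengths
  under the predicted per-position Gamma(alpha, beta), scaled by
  tau = 0.0005 to bring it to the same order as the MSEs.
* **Noise loss** — mean squared error between the segmentation's per-event
  SD (`sigma_ref`) and the predicted `sigma`.

The total loss is their unweighted sum. All three exclude padded positions
and padded samples entirely (verified by test). Optimization is Adam with
linear warmup and global gradient-norm clipping at 1.0; the backward pass is
derived analytically and checked against finite differences in the test
suite. A non-finite loss aborts with a diagnostic rather than training on.

Because the duration and noise heads receive gradients only from their own
loss terms, Adam's per-parameter normalization makes their effective
learning rate independent of the tau scaling; tau matters for the shared
embedding, where it keeps the duration term from competing with the signal
term.

### Defaults and the scaled-down study size

The full-size configuration (`d_model = 256`, 2+2 blocks, `d_ff = 1024`,
2 heads) is the package default for real training data. The package's own
end-to-end validation uses a deliberately small study so that it runs on one
CPU: k = 5, a 50 kb uniform random genome, 500 reads of 300 nt
(~148,000 events), a tiny model (`d_model = 64`, 2+2 blocks, `d_ff = 128`,
`d_head = 128`), batch size 8 and 5000 Adam steps at peak learning rate
1e-3 with 300 warmup steps. These sizes were chosen as the smallest study
at which
per-k-mer recovery is sharply testable (1024 distinct k-mers, each seen
~145 times per epoch); they are stated here so the reported numbers can be
reproduced exactly with `scripts/acceptance.R`.

## Synthetic ground truth

The synthetic generator emulates the structure of eventalign-style training
data with fully known parameters:

* a **pore table** assigns each of the 4^k k-mers an i.i.d. standard-normal
  current level (model units), a gamma duration law with mean uniform in
  [5, 15] samples and shape uniform in [2, 10], and a noise SD uniform in
  [0.05, 0.3];
* a **genome** of uniform i.i.d. bases;
* **reads** sampled as in genome-mode simulation; per k-mer a duration is
  drawn from its gamma law (rounded, clamped to >= 1) and that many samples
  are drawn as `level + Normal(0, sigma)`; the per-event sample SD is
  recorded as `sigma_ref` (0 for single-sample events, which are kept — they
  are legitimate short events).

Duration and noise laws depend on the *center k-mer only*, with no
longer-range context, so a correct model can drive the recovery error to
nearly zero — making parameter recovery a sharp correctness test. This is
also what the generator deliberately does **not** emulate about real data:
sequence context beyond k, homopolymer-specific segmentation errors,
adapter/stall artifacts, and non-Gaussian amplitude noise. Passing the
recovery tests therefore demonstrates that the architecture and training
machinery work, not that the shipped defaults reproduce any particular
chemistry.

Recovery is probed with a linear de Bruijn sequence over ACGT (4^k + k - 1
bases, every k-mer exactly once), simulated in noise-free ideal-duration
mode; the per-event signal mean is compared with the table level, the
duration head's `alpha/beta` with the true gamma mean, and the noise head's
`sigma` with the true SD. The de Bruijn probe keeps every window fully
populated with real tokens, matching the training distribution.

## Simulation modes and noise

Genome-mode samples read coordinates (contig with probability proportional
to length, uniform start, uniform strand with reverse-complementing) with a
configurable read-length distribution: exponential, scaled beta,
two-component gamma mixture, or fixed. The shipped parameter defaults are
practical values, not calibrated constants — realistic length modelling is
configuration, not a claim of this package. Read-mode takes input sequences
verbatim (no strand flipping).

Inference tiles the k-mer list into windows of 16 with stride 16, the same
non-overlapping tiling used to build training chunks. The window stride is a
design choice: overlapping windows would generate each signal segment more
than once, and the train/inference correspondence is cleanest when both use
the same tiling. Junction artifacts at window boundaries are accepted and
visible only as slight discontinuities in noise-free signals.

Noise is controlled independently in two domains, yielding the four
qualitative modes (none / amplitude only / duration only / both):

* amplitude: `learned` (noise head sigma), `static` (default Normal(0, 1)),
  or `off`;
* duration: `learned` (sample the gamma), `off` (ideal: round(alpha/beta),
  the gamma mean), or `static` (Normal(9, 4), rounded, clamped >= 1).

The static parameters mirror the fixed distributions used by
pore-model-based simulators, enabling like-for-like comparisons between
learned and static sampling.

## Numerical choices

* Gamma draws are real-valued; signals need integer sample counts, so
  durations are rounded half-to-even and clamped to >= 1 (padded positions
  get 0).
* Positivity of alpha, beta is enforced by softplus plus 1e-6; sigma by
  softplus alone (it may legitimately be ~0).
* Layer normalization uses eps = 1e-5; blocks are post-norm (residual, then
  normalize), the standard feed-forward-transformer arrangement. Post-norm
  stacks are sensitive to aggressive learning rates: at peak 1e-3 with a few
  hundred warmup steps the signal path trains stably, while doubling the
  rate can collapse it to predicting the mean. The duration/noise heads are
  shallow and indifferent to this choice.
* Events with reference-position gaps close the current window and start a
  new one: signal across an alignment gap is not contiguous, so
  concatenating it would fabricate a junction that never existed.
* Chunks whose concatenated samples exceed 250 points are dropped, never
  truncated — truncation would mis-pair tokens with signal.
* The expansion cap at inference (`max_expanded`, default 2000) exists to
  bound decoder attention memory; exceeding it is an error instructing the
  caller to split the input.
* Ties and determinism: with noise off, simulation is a pure function of the
  weights and the sequence; all stochastic paths draw from R's RNG so a
  single seed reproduces an entire run.
* DTW uses the exact quadratic dynamic program with steps
  {(1,0), (0,1), (1,1)} (memory-efficient approximations are unnecessary at
  the signal lengths handled here, and the exact DP is the quantity those
  approximations target). Both signals are z-normalized first — amplitude
  scale is an acquisition property, not a similarity signal — and the cost
  is divided by the reference-signal length to compare reads of different
  lengths. Normalizing by the reference (rather than the path length or the
  mean of both lengths) makes the metric asymmetric but directly
  interpretable as cost per reference sample.

## File formats

* **eventalign input**: tab-separated, column names configurable (YAML or
  list); the default map matches uncalled4/nanopolish-style output with a
  comma-separated `samples` column. Without raw samples, events are
  reconstructed from mean/stdv/length columns. The `sigma_ref` source column
  is configurable (`stdv_col`); the default `event_stdv` is the per-event
  sample SD, which is the quantity the noise loss models.
* **SLOW5**: the ASCII v0.2 dialect is written natively (header attributes,
  two column-description lines, one record per read) with floats printed at
  full precision so the write/read round trip is lossless. Conversion to
  raw counts uses `pA = x * norm_scale + norm_shift` and
  `raw = round(pA * digitisation / range - offset)`, clamped to int16.
* **POD5** is a binary vendor format; export is delegated to an external
  writer hook and refuses to run without one, pointing users to SLOW5.
* Chunk stores and model checkpoints are versioned RDS containers (matrix
  layouts documented in `?build_chunks` and `?save_checkpoint`).

## Known limitations

* The shipped pore profiles carry representative (not vendor-calibrated)
  digitisation/range/offset values; override them for exact pipelines.
* No modelling of adapter signal, stalls, chimeric reads, or methylation;
  RNA signals would require retraining and are untested.
* The native R training loop is intended for the package's study sizes
  (up to ~10^4 chunks); training on full flow-cell datasets would need the
  same architecture on a GPU framework.
* Basecalling-based quality metrics (match rate, Q-scores) require an
  external basecaller and are out of scope; the package's evaluation module
  covers signal-space similarity only.
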