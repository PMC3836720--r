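# Held-out evaluation: cross-entropy, mutual-information lower bound with
# spike-history decomposition, and explained variance.

#' Held-out cross-entropy of a model
#'
#' Empirical average of \eqn{-\log_2 p(y_t \mid x_t, s_t)} over the bins of
#' a (held-out) design, reported per bin and per second. This estimates the
#' cross-entropy between the neuron's true conditional distribution and the
#' model's; it is minimized by maximum-likelihood fitting and is the
#' package's primary comparison measure (smaller is better).
#'
#' @param model Any object with a [firing_prob()] method: `spikemix_params`,
#'   a `spikemix_fit`, an [lnp_model()] or an `lnp_fit`.
#' @param data Design tibble ([as_design()] / [build_design()]).
#' @param dt Bin width in seconds; defaults to the design's `dt` attribute.
#' @return One-row tibble: `cross_entropy_bits_per_bin`,
#'   `cross_entropy_bits_per_s`, `n_test_bins`, `dt`.
#' @export
cross_entropy <- function(model, data, dt = NULL) {
  parts <- design_parts(data)
  dt <- dt %||% parts$dt
  if (is.null(dt)) stop("dt not given and design carries no dt attribute")
  p <- clip_prob(firing_prob(model, parts$X, parts$S))
  y <- parts$y
  bits <- -mean(y * log2(p) + (1 - y) * log2(1 - p))
  tibble::tibble(
    cross_entropy_bits_per_bin = bits,
    cross_entropy_bits_per_s = bits / dt,
    n_test_bins = length(y),
    dt = dt
  )
}

#' Mutual-information lower bound from a model pair
#'
#' The information a spike train carries about the stimulus, per unit time,
#' is lower-bounded by the drop in cross-entropy achieved by conditioning
#' on the stimulus: `(CE_history_only - CE_full) / dt` in bits per second,
#' where the history-only model is the full model with its
#' stimulus-dependent terms dropped and refitted ([fit_history_only()]).
#' Both reports must come from the same test set. The estimate can be
#' negative for models worse than the history-only baseline; it is a bound
#' on the truth only in expectation under the true response distribution.
#'
#' @param stim_model_report [cross_entropy()] report of the full
#'   (stimulus + history) model.
#' @param history_only_report [cross_entropy()] report of the history-only
#'   model on the same test set.
#' @return Scalar, bits per second.
#' @export
mi_lower_bound <- function(stim_model_report, history_only_report) {
  a <- stim_model_report; b <- history_only_report
  if (a$n_test_bins != b$n_test_bins || abs(a$dt - b$dt) > 1e-12) {
    stop("mismatched test sets: reports disagree on n_test_bins or dt")
  }
  (b$cross_entropy_bits_per_bin - a$cross_entropy_bits_per_bin) / a$dt
}

#' Explained variance between two smoothed rate vectors
#'
#' Squared Pearson correlation between a model PSTH and a reference PSTH
#' (both smoothed with the same kernel). Invariant to affine scaling of
#' either rate; sensitive to the kernel width used upstream.
#'
#' @param model_psth,reference_psth Equal-length numeric rate vectors.
#' @return \eqn{R^2} in \[0, 1\].
#' @export
explained_variance <- function(model_psth, reference_psth) {
  stopifnot(length(model_psth) == length(reference_psth))
  if (stats::sd(model_psth) == 0 || stats::sd(reference_psth) == 0) {
    stop("explained_variance() undefined for a zero-variance rate vector")
  }
  stats::cor(model_psth, reference_psth)^2
}

#' Paired model comparison across cells
#'
#' One-tailed Wilcoxon signed-rank test that model B's cross-entropy is
#' lower than model A's across cells (thin wrapper over
#' [stats::wilcox.test()]).
#'
#' @param ce_a,ce_b Per-cell cross-entropies (bits per bin) of the two
#'   models, aligned by cell.
#' @return The `htest` object.
#' @export
compare_models_signed_rank <- function(ce_a, ce_b) {
  stopifnot(length(ce_a) == length(ce_b))
  stats::wilcox.test(ce_a, ce_b, paired = TRUE, alternative = "greater")
}
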