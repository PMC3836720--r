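# Binned spike trains and interspike-interval histograms.
#
# The naive-Bayes spike-history term is the log-ratio of two interval
# distributions: g1, the distribution of time-since-last-spike at bins that
# contain a spike, and g0, the same at bins that do not. The log-ratio is
# exactly a linear filter applied to a one-hot most-recent-spike vector.

#' Binned spike train
#'
#' A binary response sequence with its bin width: `counts[t]` indicates the
#' presence or absence of a spike in bin `t` (half-open bins
#' `[(t-1) dt, t dt)`, 0-based time).
#'
#' @param counts Integer 0/1 vector, length >= 1.
#' @param dt Bin width in seconds (> 0).
#' @param trial_id Identifier for the trial.
#' @return An object of class `spike_train`.
#' @export
spike_train <- function(counts, dt, trial_id = 1L) {
  counts <- as.integer(counts)
  if (length(counts) < 1) stop("spike train must have at least one bin")
  if (!all(counts %in% c(0L, 1L))) stop("counts must be 0 or 1 in every bin")
  if (!is.numeric(dt) || length(dt) != 1 || dt <= 0) {
    stop("dt must be a positive scalar (seconds)")
  }
  structure(list(counts = counts, dt = dt, trial_id = trial_id),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat("<spike_train> trial ", x$trial_id, ": ", length(x$counts),
      " bins of ", x$dt * 1000, " ms, ", sum(x$counts), " spikes (",
      signif(mean(x$counts) / x$dt, 3), " Hz)\n", sep = "")
  invisible(x)
}

# time-since-last-spike in bins, for each bin t (spike in an earlier bin);
# NA when no spike has occurred yet.
bins_since_last_spike <- function(counts) {
  t_idx <- seq_along(counts)
  last <- cummax(ifelse(counts == 1L, t_idx, 0L))
  prev <- c(0L, last[-length(last)])  # most recent spike strictly before t
  delta <- t_idx - prev
  delta[prev == 0L] <- NA_integer_
  delta
}

#' Estimate interspike-interval histograms
#'
#' Histograms of the time since the most recent spike, conditioned on
#' whether the current bin contains a spike (`g1`) or not (`g0`), over a
#' fixed history window. Bins where no spike has yet occurred within the
#' window are excluded (they map to the all-zero history vector). A
#' pseudo-count of 0.5 is added to every histogram bin before normalization
#' so that log-ratios stay finite.
#'
#' @param spike_trains A `spike_train` or list of them (equal `dt`).
#' @param n_bins Number of interval histogram bins.
#' @param window History window length in seconds (> 0).
#' @return An object of class `isi_histograms` with fields `bin_edges`
#'   (seconds), `g1`, `g0` (each summing to 1), and `prior_logit`
#'   (log-odds of the overall spike frequency per bin).
#' @export
estimate_isi <- function(spike_trains, n_bins, window) {
  if (inherits(spike_trains, "spike_train")) spike_trains <- list(spike_trains)
  stopifnot(length(spike_trains) >= 1, n_bins >= 1, window > 0)
  dt <- spike_trains[[1]]$dt
  bw <- window / n_bins
  c1 <- numeric(n_bins)
  c0 <- numeric(n_bins)
  n_spikes <- 0
  n_total <- 0
  for (tr in spike_trains) {
    if (abs(tr$dt - dt) > 1e-12) stop("spike trains disagree on dt")
    y <- tr$counts
    n_spikes <- n_spikes + sum(y)
    n_total <- n_total + length(y)
    delta <- bins_since_last_spike(y) * dt
    j <- ceiling(delta / bw - 1e-9)           # interval bin, 1-based
    ok <- !is.na(j) & j >= 1 & j <= n_bins
    c1 <- c1 + tabulate(j[ok & y == 1L], n_bins)
    c0 <- c0 + tabulate(j[ok & y == 0L], n_bins)
  }
  if (n_spikes == 0) stop("no spikes in any train; cannot estimate ISIs")
  g1 <- (c1 + 0.5) / sum(c1 + 0.5)
  g0 <- (c0 + 0.5) / sum(c0 + 0.5)
  structure(
    list(bin_edges = seq(0, window, length.out = n_bins + 1),
         g1 = g1, g0 = g0,
         prior_logit = stats::qlogis(n_spikes / n_total),
         n_bins = n_bins, window = window),
    class = "isi_histograms"
  )
}

#' Interval histograms to spike-history filter
#'
#' Converts the naive-Bayes interval term into the equivalent linear filter
#' on the one-hot most-recent-spike vector:
#' \eqn{h_j = \log g_1(j) - \log g_0(j)}. [history_term()] with a one-hot
#' `s` then reproduces the log-ratio exactly.
#'
#' @param isi An [estimate_isi()] result.
#' @param H Required filter length; must equal the number of interval bins.
#' @return Numeric filter of length `H`.
#' @export
isi_to_history_filter <- function(isi, H) {
  stopifnot(inherits(isi, "isi_histograms"))
  if (H != isi$n_bins) {
    stop("bin-count mismatch: ISI histograms have ", isi$n_bins,
         " bins but a filter of length ", H, " was requested")
  }
  log(isi$g1) - log(isi$g0)
}
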