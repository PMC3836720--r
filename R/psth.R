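# The PSTH oracle: leave-one-trial-out kernel-smoothed predictions from
# repeated (frozen) trials. An optimistic history-free benchmark — it sees
# the neuron's actual responses to the very stimulus being predicted.

fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

# Discrete normalized Gaussian kernel over bins, truncated at +/- 4 sigma.
gaussian_kernel_bins <- function(fwhm, dt) {
  sigma <- fwhm_to_sigma(fwhm)
  half <- max(1L, ceiling(4 * sigma / dt))
  w <- stats::dnorm((-half:half) * dt, sd = sigma)
  w / sum(w)
}

# Zero-padded same-length convolution of x with kernel w (odd length).
smooth_same <- function(x, w) {
  half <- (length(w) - 1L) / 2L
  xp <- c(numeric(half), x, numeric(half))
  out <- stats::filter(xp, w, method = "convolution", sides = 2)
  as.numeric(out[(half + 1):(half + length(x))])
}

trials_to_matrix <- function(frozen_trials) {
  if (is.matrix(frozen_trials)) return(frozen_trials)
  if (inherits(frozen_trials, "spike_train")) {
    frozen_trials <- list(frozen_trials)
  }
  lens <- vapply(frozen_trials, function(tr) length(tr$counts), integer(1))
  if (length(unique(lens)) != 1) {
    stop("unequal trial lengths: ", paste(unique(lens), collapse = ", "))
  }
  do.call(rbind, lapply(frozen_trials, function(tr) tr$counts))
}

#' Leave-one-trial-out PSTH predictions
#'
#' For each frozen trial `r` and bin `t`, predicts the spike probability as
#' a small offset plus the Gaussian-kernel-smoothed average response of the
#' other `N - 1` trials at bin `t`, clipped just below 1. Deterministic
#' given the trials.
#'
#' @param frozen_trials List of `spike_train`s of equal length and `dt`
#'   (responses to the repeated frozen stimulus), or an `N` x `T` binary
#'   matrix plus `dt`.
#' @param kernel_fwhm Kernel full width at half maximum, seconds.
#' @param offset Probability floor added to the smoothed rate (> 0).
#' @param dt Bin width in seconds (taken from the trains if omitted).
#' @return A `psth_model`: `predictions` (`N` x `T`, prediction for each
#'   held-out trial), `psth` (all-trial smoothed rate per bin, spikes/bin),
#'   `kernel_fwhm`, `offset`, `dt`.
#' @export
psth_predict <- function(frozen_trials, kernel_fwhm, offset, dt = NULL) {
  stopifnot(kernel_fwhm > 0, offset > 0)
  if (is.null(dt)) {
    if (is.matrix(frozen_trials)) stop("dt required with a trial matrix")
    dt <- frozen_trials[[1]]$dt
  }
  Yr <- trials_to_matrix(frozen_trials)
  N <- nrow(Yr)
  if (N < 2) stop("PSTH prediction needs at least 2 trials")
  w <- gaussian_kernel_bins(kernel_fwhm, dt)
  # edge renormalization: divide by the kernel mass inside the trial so a
  # constant response stays constant at the boundaries
  norm <- smooth_same(rep(1, ncol(Yr)), w)
  smoothed <- t(apply(Yr, 1, function(r) smooth_same(r, w) / norm))
  tot <- colSums(smoothed)
  preds <- matrix(0, N, ncol(Yr))
  for (r in seq_len(N)) {
    loo <- (tot - smoothed[r, ]) / (N - 1)
    preds[r, ] <- pmin(offset + loo, 1 - 1e-9)
  }
  structure(
    list(predictions = preds, psth = colMeans(smoothed),
         kernel_fwhm = kernel_fwhm, offset = offset, dt = dt,
         n_trials = N),
    class = "psth_model"
  )
}

#' Leave-one-out cross-entropy of a PSTH model
#'
#' Average \eqn{-\log_2} Bernoulli likelihood of each trial under its
#' held-out PSTH prediction, in bits per bin.
#'
#' @param psth A [psth_predict()] result.
#' @param frozen_trials The same trials used to build it.
#' @return Scalar bits per bin.
#' @export
psth_cross_entropy <- function(psth, frozen_trials) {
  Yr <- trials_to_matrix(frozen_trials)
  stopifnot(all(dim(Yr) == dim(psth$predictions)))
  p <- clip_prob(psth$predictions)
  -mean(Yr * log2(p) + (1 - Yr) * log2(1 - p))
}

#' Select PSTH kernel width and offset by leave-one-out cross-entropy
#'
#' Exhaustive search over a prespecified grid, minimizing the mean
#' leave-one-trial-out cross-entropy; ties break toward the wider kernel,
#' then the larger offset. Default grids span 0.05-5 ms FWHM and
#' 1e-4-1e-1 offset, log-spaced.
#'
#' @inheritParams psth_predict
#' @param fwhm_grid Candidate kernel FWHMs, seconds.
#' @param offset_grid Candidate offsets.
#' @return List: `kernel_fwhm`, `offset`, `cross_entropy_bits_per_bin`, and
#'   the full search `grid` tibble.
#' @export
select_psth_params <- function(frozen_trials,
                               fwhm_grid = exp(seq(log(5e-5), log(5e-3),
                                                   length.out = 10)),
                               offset_grid = exp(seq(log(1e-4), log(1e-1),
                                                     length.out = 7)),
                               dt = NULL) {
  if (length(fwhm_grid) == 0 || length(offset_grid) == 0) {
    stop("empty parameter grid")
  }
  grid <- tidyr::expand_grid(kernel_fwhm = sort(fwhm_grid),
                             offset = sort(offset_grid))
  grid$ce <- purrr::map2_dbl(grid$kernel_fwhm, grid$offset, function(fw, of) {
    psth_cross_entropy(psth_predict(frozen_trials, fw, of, dt),
                       frozen_trials)
  })
  best_ce <- min(grid$ce)
  cand <- grid[grid$ce == best_ce, ]
  cand <- cand[order(-cand$kernel_fwhm, -cand$offset), ]
  list(kernel_fwhm = cand$kernel_fwhm[1], offset = cand$offset[1],
       cross_entropy_bits_per_bin = best_ce, grid = grid)
}
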