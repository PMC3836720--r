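# Simulator emulating the experimental pipeline: low-pass-filtered Gaussian
# noise stimulation, windowed + PCA-reduced stimulus features, one-hot
# most-recent-spike history encoding, frozen/unfrozen trials, and
# spike-train sampling with history feedback.
#
# Coordinate conventions (documented, used everywhere):
#  - bins are half-open [t*dt, (t+1)*dt), 0-based in time, 1-based as R
#    indices;
#  - the stimulus window for bin t covers the `window` seconds strictly
#    before the bin starts (causal: only stimulus preceding the spike
#    decision enters x_t);
#  - history index 1 = most recent history bin (a spike exactly one bin
#    before t lights entry 1); time since last spike increases with index.

#' Experiment design
#'
#' Bundles the stimulation and preprocessing geometry. Defaults follow the
#' reference protocol: 50 unfrozen + 50 frozen trials, 10 ms stimulus
#' windows reduced to 10 principal components, 25 ms of spike history in
#' 100 equal bins. The waveform sampling rate is 4 kHz with 0.25 ms spike
#' bins so that one history bin equals one spike bin (no bin can hold more
#' than one spike).
#'
#' @param n_unfrozen,n_frozen Trial counts.
#' @param trial_length Trial length, seconds.
#' @param dt Spike-train bin width, seconds.
#' @param fs Stimulus sampling rate, Hz (must be an integer multiple of
#'   `1/dt`).
#' @param cutoff Stimulus low-pass corner, Hz.
#' @param window Stimulus window length, seconds.
#' @param n_pc Retained principal components.
#' @param history_window Spike-history length, seconds.
#' @param history_bins Number of history bins (`history_window /
#'   history_bins` must equal `dt`).
#' @return An `experiment_design` list with derived fields `bins_per_trial`,
#'   `window_bins`, `samples_per_bin`.
#' @export
experiment_design <- function(n_unfrozen = 50L, n_frozen = 50L,
                              trial_length = 10, dt = 0.25e-3, fs = 4000,
                              cutoff = 100, window = 10e-3, n_pc = 10L,
                              history_window = 25e-3, history_bins = 100L) {
  stopifnot(trial_length > 0, dt > 0, window > 0, n_pc >= 1,
            history_window > 0, history_bins >= 1, fs > 2 * cutoff)
  spb <- fs * dt
  if (abs(spb - round(spb)) > 1e-9) {
    stop("fs * dt must be an integer number of samples per bin")
  }
  hist_bw <- history_window / history_bins
  if (abs(hist_bw - dt) > 1e-12) {
    stop("history_window / history_bins must equal dt so one history bin ",
         "is one spike bin (got ", hist_bw, " vs dt = ", dt, ")")
  }
  wb <- window / dt
  if (abs(wb - round(wb)) > 1e-9) stop("window must be a multiple of dt")
  structure(
    list(n_unfrozen = as.integer(n_unfrozen), n_frozen = as.integer(n_frozen),
         trial_length = trial_length, dt = dt, fs = fs, cutoff = cutoff,
         window = window, n_pc = as.integer(n_pc),
         history_window = history_window,
         history_bins = as.integer(history_bins),
         bins_per_trial = as.integer(round(trial_length / dt)),
         window_bins = as.integer(round(wb)),
         samples_per_bin = as.integer(round(spb))),
    class = "experiment_design"
  )
}

#' Generate a low-pass-filtered Gaussian noise stimulus
#'
#' Seeded Gaussian white noise, zero-phase low-pass filtered (4th-order
#' Butterworth applied forward and backward), then standardized to exactly
#' zero mean and unit variance. Frozen trials reuse one such waveform;
#' unfrozen trials each draw a fresh seed.
#'
#' @param duration Waveform length, seconds.
#' @param fs Sampling rate, Hz.
#' @param cutoff Low-pass corner, Hz (requires `fs > 2 * cutoff`).
#' @param seed Optional integer seed; the output is bit-identical for equal
#'   seeds.
#' @return A `stimulus_waveform`: `samples`, `fs`, `cutoff`.
#' @export
generate_stimulus <- function(duration, fs = 4000, cutoff = 100,
                              seed = NULL) {
  stopifnot(duration > 0)
  if (fs <= 2 * cutoff) {
    stop("fs must exceed twice the low-pass cutoff (fs = ", fs,
         ", cutoff = ", cutoff, ")")
  }
  n <- round(duration * fs)
  noise <- with_seed_local(seed, stats::rnorm(n))
  bf <- signal::butter(4, cutoff / (fs / 2), type = "low")
  x <- signal::filtfilt(bf, noise)
  x <- (x - mean(x)) / stats::sd(x)
  structure(list(samples = x, fs = fs, cutoff = cutoff),
            class = "stimulus_waveform")
}

# Window matrix: row t holds the `window_bins * samples_per_bin` stimulus
# samples strictly preceding bin t, oldest first. Rows exist only for bins
# with a full window (bins 1..window_bins are dropped).
stimulus_windows <- function(waveform, design, n_bins = NULL) {
  x <- waveform$samples
  spb <- design$samples_per_bin
  wb <- design$window_bins
  wlen <- wb * spb
  n_bins <- n_bins %||% min(design$bins_per_trial, floor(length(x) / spb))
  if (n_bins * spb > length(x)) {
    stop("waveform too short: ", length(x), " samples for ", n_bins,
         " bins at ", spb, " samples per bin")
  }
  valid <- (wb + 1):n_bins
  W <- matrix(0, length(valid), wlen)
  for (i in seq_along(valid)) {
    t <- valid[i]
    end <- (t - 1) * spb           # last sample strictly before bin t
    W[i, ] <- x[(end - wlen + 1):end]
  }
  attr(W, "bins") <- valid
  attr(W, "dropped") <- wb
  W
}

#' Fit a PCA basis for stimulus windows
#'
#' Principal components of the training windows (centered, not whitened:
#' features keep their natural variances). The basis must be fitted on
#' training data only and reused for test designs.
#'
#' @param waveform A training [generate_stimulus()] waveform.
#' @param design An [experiment_design()].
#' @return A `pca_basis`: `center`, `rotation` (window-dim x `n_pc`),
#'   `sdev` (all components).
#' @export
fit_pca_basis <- function(waveform, design) {
  W <- stimulus_windows(waveform, design)
  pc <- stats::prcomp(W, center = TRUE, scale. = FALSE)
  structure(list(center = pc$center,
                 rotation = pc$rotation[, seq_len(design$n_pc), drop = FALSE],
                 sdev = pc$sdev),
            class = "pca_basis")
}

# One-hot most-recent-spike matrix (T x H) from a 0/1 count vector.
history_matrix <- function(counts, H) {
  TT <- length(counts)
  S <- matrix(0, TT, H)
  if (H == 0L) return(S)
  delta <- bins_since_last_spike(counts)
  ok <- which(!is.na(delta) & delta <= H)
  S[cbind(ok, delta[ok])] <- 1
  S
}

#' Build a design tibble from a stimulus waveform and spikes
#'
#' Per bin `t`: `x` is the projection of the preceding stimulus window onto
#' the PCA basis; `s` is the one-hot position of the most recent spike
#' within the history window (all-zero if none); `y` is the bin's spike
#' indicator. Bins without a full stimulus window are dropped and counted
#' in attribute `dropped_bins`.
#'
#' @param waveform A [generate_stimulus()] waveform.
#' @param spikes A `spike_train` aligned with the waveform, or `NULL`
#'   (silent neuron: `y = 0`, all-zero history rows).
#' @param design An [experiment_design()].
#' @param basis A [fit_pca_basis()] result; fitted from `waveform` itself
#'   if omitted (training use only — pass the training basis for test
#'   designs).
#' @return A design tibble (see [as_design()]) with attributes `dt`,
#'   `dropped_bins`, `basis`, `design`.
#' @export
build_design <- function(waveform, spikes, design, basis = NULL) {
  basis <- basis %||% fit_pca_basis(waveform, design)
  n_bins <- if (is.null(spikes)) NULL else length(spikes$counts)
  W <- stimulus_windows(waveform, design, n_bins)
  bins <- attr(W, "bins")
  X <- sweep(W, 2, basis$center) %*% basis$rotation
  counts <- if (is.null(spikes)) integer(max(bins)) else spikes$counts
  S <- history_matrix(counts, design$history_bins)[bins, , drop = FALSE]
  out <- as_design(X, S, counts[bins], design$dt)
  out$t <- bins
  attr(out, "dropped_bins") <- attr(W, "dropped")
  attr(out, "basis") <- basis
  attr(out, "design") <- design
  out
}

#' Sample spike trains from a model with history feedback
#'
#' Sequential per-bin Bernoulli sampling: the stimulus contribution to the
#' predictor is precomputed for all bins, then bins are visited in order
#' and the history term is rebuilt from the spikes sampled so far (the
#' feedback loop that makes repeated trials differ even under a frozen
#' stimulus).
#'
#' @param params Model parameters of any family.
#' @param x `T` x `D` stimulus design matrix (e.g. the `x` column of
#'   [build_design()]).
#' @param dt Bin width, seconds.
#' @param n_trials Number of trains to sample.
#' @param seed Optional integer seed (reproducible).
#' @return List of `n_trials` [spike_train()]s of length `T`.
#' @export
simulate_spikes <- function(params, x, dt, n_trials = 1L, seed = NULL) {
  X <- as.matrix(x)
  f_stim <- predictor(params, X, NULL)
  h <- params$h
  H <- params$H
  TT <- nrow(X)
  with_seed_local(seed, {
    lapply(seq_len(n_trials), function(r) {
      y <- integer(TT)
      last <- -Inf
      u <- stats::runif(TT)
      for (t in seq_len(TT)) {
        j <- t - last
        f <- f_stim[t] + if (j <= H) h[j] else 0
        if (u[t] < sigmoid(f)) {
          y[t] <- 1L
          last <- t
        }
      }
      spike_train(y, dt, trial_id = r)
    })
  })
}

#' Ground-truth neuron
#'
#' @param params Model parameters of any family.
#' @param design An [experiment_design()].
#' @param basis The [fit_pca_basis()] the parameters live in.
#' @param seed Seed used to draw the neuron.
#' @return A `ground_truth_neuron`.
#' @export
ground_truth_neuron <- function(params, design, basis, seed = NULL) {
  stopifnot(inherits(params, "spikemix_params"),
            params$D == design$n_pc,
            params$H %in% c(0L, design$history_bins))
  structure(list(params = params, design = design, basis = basis,
                 seed = seed),
            class = "ground_truth_neuron")
}

#' Sample trials from a ground-truth neuron given a stimulus
#'
#' Builds the stimulus features with the neuron's own PCA basis and runs
#' [simulate_spikes()]. All trials share the waveform (frozen-trial
#' semantics); pass fresh waveforms per trial for unfrozen trials.
#'
#' @param neuron A [ground_truth_neuron()] (or [make_ground_truth()]).
#' @param waveform A [generate_stimulus()] waveform.
#' @param n_trials Number of trials.
#' @param seed Optional integer seed.
#' @return List of [spike_train()]s covering the bins with a full stimulus
#'   window; attribute `bins` maps them to waveform bins.
#' @export
sample_spike_train <- function(neuron, waveform, n_trials = 1L,
                               seed = NULL) {
  des <- neuron$design
  W <- stimulus_windows(waveform, des)
  X <- sweep(W, 2, neuron$basis$center) %*% neuron$basis$rotation
  trains <- simulate_spikes(neuron$params, X, des$dt, n_trials, seed)
  bins <- attr(W, "bins")
  # pad the dropped leading window so train index == waveform bin index
  trains <- lapply(trains, function(tr) {
    counts <- integer(max(bins))
    counts[bins] <- tr$counts
    spike_train(counts, tr$dt, tr$trial_id)
  })
  attr(trains, "bins") <- bins
  trains
}

# Draw raw (uncalibrated) parameters for a ground-truth family, scaled so
# the stimulus-driven predictor has a usable dynamic range on calib_X.
draw_ground_truth_params <- function(kind, D, H, K, calib_X,
                                     target_sd = 1.5) {
  scale_to <- function(v, sd_target) {
    s <- stats::sd(v)
    if (s < 1e-12) 1 else sd_target / s
  }
  h <- if (H > 0) {
    j <- seq_len(H)
    -6 * exp(-(j - 1) / 6)          # refractory-style suppression
  } else numeric(0)
  if (kind == "glm") {
    w <- stats::rnorm(D)
    w <- w * scale_to(drop(calib_X %*% w), target_sd)
    return(glm_params(w = w, h = h, b = 0))
  }
  if (kind == "quadratic") {
    w <- stats::rnorm(D)
    w <- w * scale_to(drop(calib_X %*% w), target_sd)
    v <- matrix(stats::rnorm(2 * D), D)
    A <- tcrossprod(v[, 1]) - tcrossprod(v[, 2])   # indefinite, rank 2
    q <- 0.5 * rowSums((calib_X %*% A) * calib_X)
    A <- A * scale_to(q, target_sd / 2)
    return(quad_params(A = A, w = w, h = h, b = 0))
  }
  if (kind == "stm") {
    A <- vector("list", K)
    Wm <- matrix(0, K, D)
    for (k in seq_len(K)) {
      w <- stats::rnorm(D)
      Wm[k, ] <- w * scale_to(drop(calib_X %*% w), target_sd)
      v <- stats::rnorm(D)
      Ak <- tcrossprod(v)
      q <- 0.5 * rowSums((calib_X %*% Ak) * calib_X)
      A[[k]] <- Ak * scale_to(q, target_sd / 3) *
        sample(c(-1, 1), 1)
    }
    return(stm_params(A = A, W = Wm, a = stats::rnorm(K, sd = 0.5), h = h))
  }
  stop("unknown ground-truth kind: ", kind)
}

# Shift all offsets of a parameter object by delta (bias search handle).
shift_offsets <- function(params, delta) {
  if (inherits(params, c("glm_params", "quad_params"))) {
    params$b <- params$b + delta
  } else {
    params$a <- params$a + delta
  }
  params
}

#' Draw a calibrated ground-truth neuron
#'
#' Seeded parameter draws for a GLM, quadratic or STM neuron on the PCA
#' feature space of a reference stimulus, with the offset calibrated by
#' bisection so that the simulated mean firing rate hits `target_rate_hz`
#' (physiological range 20-120 Hz) within `rate_tol` relative error. The
#' history filter is a refractory-style suppression of short interspike
#' intervals.
#'
#' @param kind `"glm"`, `"quadratic"` or `"stm"`.
#' @param design An [experiment_design()].
#' @param seed Integer seed; the same seed reproduces the neuron exactly.
#' @param target_rate_hz Desired mean rate (default 50 Hz).
#' @param K Components for `kind = "stm"` (default 3).
#' @param history Attach the refractory history filter? (default TRUE).
#' @param rate_tol Relative rate tolerance for calibration (default 0.03).
#' @param calib_duration Seconds of stimulus used for basis fitting and
#'   rate calibration (default 20).
#' @return A [ground_truth_neuron()].
#' @export
make_ground_truth <- function(kind = c("glm", "quadratic", "stm"), design,
                              seed = 1L, target_rate_hz = 50, K = 3L,
                              history = TRUE, rate_tol = 0.03,
                              calib_duration = 20) {
  kind <- match.arg(kind)
  stopifnot(target_rate_hz > 0)
  wave <- generate_stimulus(calib_duration, design$fs, design$cutoff,
                            seed = seed)
  basis <- fit_pca_basis(wave, design)
  W <- stimulus_windows(wave, design,
                        n_bins = floor(calib_duration / design$dt))
  X <- sweep(W, 2, basis$center) %*% basis$rotation
  H <- if (history) design$history_bins else 0L
  params <- with_seed_local(seed + 1L, {
    draw_ground_truth_params(kind, design$n_pc, H, K, X)
  })
  target_p <- target_rate_hz * design$dt
  # averaging several trials keeps Monte-Carlo noise well below rate_tol
  rate_at <- function(delta) {
    p <- shift_offsets(params, delta)
    trains <- simulate_spikes(p, X, design$dt, n_trials = 4, seed = seed + 2L)
    mean(vapply(trains, function(tr) mean(tr$counts), numeric(1)))
  }
  lo <- -30; hi <- 30
  if (rate_at(lo) > target_p || rate_at(hi) < target_p) {
    stop("rate calibration failed: target outside achievable range")
  }
  delta <- 0
  for (i in seq_len(100)) {
    delta <- (lo + hi) / 2
    r <- rate_at(delta)
    if (abs(r - target_p) / target_p <= rate_tol) break
    if (r < target_p) lo <- delta else hi <- delta
    if (i == 100) stop("rate calibration did not converge in 100 steps")
  }
  ground_truth_neuron(shift_offsets(params, delta), design, basis, seed)
}
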