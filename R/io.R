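# Plain-text file round-tripping: spike times, stimulus waveforms, model
# containers, run manifests.
#
# Bin convention everywhere: 0-based half-open bins [t*dt, (t+1)*dt), floor
# binning for spike times (with a 1e-9-bin guard against representation
# error so that written bin-start times re-bin exactly).

#' Load spike times from a text/CSV file
#'
#' Accepts either one time per line (seconds; a single trial) or
#' `trial,time` CSV rows (optionally with that header). Times must be
#' non-negative and sorted within each trial; two spikes falling in one bin
#' collapse to 1 with a warning.
#'
#' @param path File path.
#' @param dt Bin width, seconds.
#' @param trial_length Trial length in seconds (sets the bin count);
#'   defaults to covering the last spike.
#' @return List of [spike_train()]s (empty list for an empty file).
#' @export
load_spike_times <- function(path, dt, trial_length = NULL) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  lines <- lines[keep]
  lineno <- which(keep)
  if (length(lines) > 0 &&
      grepl("^\\s*trial\\s*,", lines[1], ignore.case = TRUE)) {
    lineno <- lineno[-1]
    lines <- lines[-1]
  }
  if (length(lines) == 0) return(list())
  has_trial <- grepl(",", lines[1])
  trial <- rep(1L, length(lines))
  times <- numeric(length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], ",")[[1]]
    if (has_trial) {
      if (length(fields) != 2) {
        stop("line ", lineno[i], ": expected 'trial,time'")
      }
      trial[i] <- as.integer(fields[1])
      times[i] <- as.numeric(fields[2])
    } else {
      times[i] <- as.numeric(fields[1])
    }
    if (is.na(times[i])) stop("line ", lineno[i], ": unparseable time")
    if (times[i] < 0) stop("line ", lineno[i], ": negative spike time")
    if (i > 1 && trial[i] == trial[i - 1] && times[i] < times[i - 1]) {
      stop("line ", lineno[i], ": spike times not sorted within trial")
    }
  }
  n_bins_for <- function(tt) {
    if (!is.null(trial_length)) return(as.integer(ceiling(trial_length / dt)))
    max(bin_of(tt, dt))
  }
  lapply(unique(trial), function(tr) {
    tt <- times[trial == tr]
    nb <- n_bins_for(tt)
    b <- bin_of(tt, dt)
    if (any(b > nb)) stop("spike time beyond trial_length in trial ", tr)
    counts <- integer(nb)
    dup <- sum(duplicated(b))
    if (dup > 0) {
      warning(dup, " spike(s) collapsed: multiple spikes in one bin")
    }
    counts[unique(b)] <- 1L
    spike_train(counts, dt, trial_id = tr)
  })
}

bin_of <- function(times, dt) as.integer(floor(times / dt + 1e-9)) + 1L

#' Save spike trains as trial,time CSV
#'
#' Writes each spike as its bin-start time in seconds; reloading with the
#' same `dt` reproduces the binning exactly.
#'
#' @param spike_trains List of [spike_train()]s (or one).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_spike_times <- function(spike_trains, path) {
  if (inherits(spike_trains, "spike_train")) spike_trains <- list(spike_trains)
  rows <- c("trial,time")
  for (tr in spike_trains) {
    bins <- which(tr$counts == 1L)
    if (length(bins) > 0) {
      rows <- c(rows, sprintf("%d,%.17g", tr$trial_id, (bins - 1) * tr$dt))
    }
  }
  writeLines(rows, path)
  invisible(path)
}

#' Save / load a stimulus waveform as single-column text
#'
#' @param waveform A [generate_stimulus()] result.
#' @param path File path.
#' @return `path` (save) or a `stimulus_waveform` (load).
#' @export
save_stimulus <- function(waveform, path) {
  writeLines(c(sprintf("# fs=%.17g", waveform$fs),
               sprintf("# cutoff=%.17g", waveform$cutoff),
               sprintf("%.17g", waveform$samples)), path)
  invisible(path)
}

#' @rdname save_stimulus
#' @export
load_stimulus <- function(path) {
  lines <- readLines(path)
  meta <- lines[grepl("^#", lines)]
  get <- function(key, default) {
    m <- meta[grepl(paste0("^# *", key, "="), meta)]
    if (length(m) == 0) return(default)
    as.numeric(sub(paste0("^# *", key, "="), "", m[1]))
  }
  samples <- as.numeric(lines[!grepl("^\\s*(#|$)", lines)])
  structure(list(samples = samples, fs = get("fs", NA_real_),
                 cutoff = get("cutoff", NA_real_)),
            class = "stimulus_waveform")
}

# ---- model container --------------------------------------------------------

MODEL_CONTAINER_VERSION <- 1L

num_out <- function(x) sprintf("%.17g", as.numeric(x))
num_in <- function(x) as.numeric(x)

#' Save / load model parameters
#'
#' Versioned JSON container holding the family tag, dimensions and all
#' parameter arrays. Numbers are stored as full-precision decimal strings,
#' so the round trip is bit-exact. Truncated or corrupt files and version
#' mismatches raise errors rather than returning partial models.
#'
#' @param params A `spikemix_params` object of any family (a
#'   `spikemix_fit`'s `params` work too).
#' @param path File path (`.json`).
#' @return `path` (save) or the reconstructed `spikemix_params` (load).
#' @export
save_model <- function(params, path) {
  if (inherits(params, "spikemix_fit")) params <- params$params
  stopifnot(inherits(params, "spikemix_params"))
  fam <- model_family(params)
  arrays <- switch(fam,
    glm = list(w = num_out(params$w), h = num_out(params$h),
               b = num_out(params$b)),
    quadratic = list(A = num_out(params$A), w = num_out(params$w),
                     h = num_out(params$h), b = num_out(params$b)),
    stm = list(A = num_out(unlist(params$A)),   # K blocks of D*D, column-major
               W = num_out(params$W), a = num_out(params$a),
               h = num_out(params$h)),
    fstm = list(U = num_out(params$U), B = num_out(params$B),
                W = num_out(params$W), a = num_out(params$a),
                h = num_out(params$h))
  )
  obj <- list(container = "spikemix-model",
              version = MODEL_CONTAINER_VERSION, family = fam,
              D = params$D, H = params$H, K = params$K %||% 1L,
              M = params$M %||% 0L, arrays = arrays)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) {
    stop("cannot parse model container (truncated or corrupt?): ",
         conditionMessage(e), call. = FALSE)
  })
  if (!identical(obj$container, "spikemix-model")) {
    stop("not a spikemix model container: ", path)
  }
  if (!identical(as.integer(obj$version), MODEL_CONTAINER_VERSION)) {
    stop("model container version ", obj$version,
         " not supported (expected ", MODEL_CONTAINER_VERSION, ")")
  }
  D <- obj$D; H <- obj$H; K <- obj$K; M <- obj$M
  ar <- obj$arrays
  mat <- function(v, nr, nc) matrix(num_in(v), nr, nc)
  out <- switch(obj$family,
    glm = glm_params(num_in(ar$w), num_in(ar$h), num_in(ar$b)),
    quadratic = quad_params(mat(ar$A, D, D), num_in(ar$w), num_in(ar$h),
                            num_in(ar$b)),
    stm = stm_params(lapply(seq_len(K), function(k) {
                       mat(ar$A[(k - 1) * D * D + seq_len(D * D)], D, D)
                     }),
                     mat(ar$W, K, D), num_in(ar$a), num_in(ar$h)),
    fstm = fstm_params(mat(ar$U, D, M), mat(ar$B, K, M), mat(ar$W, K, D),
                       num_in(ar$a), num_in(ar$h)),
    stop("unknown model family in container: ", obj$family)
  )
  if (n_parameters(out) != count_parameters(obj$family, D, H, K, M)) {
    stop("model container inconsistent with its declared dimensions")
  }
  out
}

#' Write a run manifest
#'
#' Records command, configuration hash, seeds, input/output paths, package
#' version and timestamp — enough to re-run a deterministic command
#' bit-identically.
#'
#' @param path Manifest path (`.json`).
#' @param command Command name.
#' @param config List of configuration values.
#' @param seeds Named seeds used.
#' @param inputs,outputs Character vectors of paths.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, command, config = list(), seeds = list(),
                           inputs = character(0), outputs = character(0)) {
  obj <- list(command = command, config = config,
              config_hash = rlang::hash(config), seeds = seeds,
              inputs = inputs, outputs = outputs,
              package_version = as.character(utils::packageVersion("spikemix")),
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
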