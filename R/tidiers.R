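# broom-style tidiers and ggplot2 autoplot methods for fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy model parameters into a long tibble
#'
#' One row per scalar parameter: `term` (`w`, `A`, `h`, `b`, `a`, `U`, `B`),
#' `component` (mixture component, `NA` for shared terms), `index` (position
#' within the term, column-major for matrices) and `value`.
#'
#' @param x A `spikemix_params` object.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy spikemix_params
#' @export
tidy.spikemix_params <- function(x, ...) {
  rows <- list()
  add <- function(term, value, component = NA_integer_) {
    if (length(value) == 0) return()
    rows[[length(rows) + 1]] <<- tibble::tibble(
      term = term, component = component,
      index = seq_along(value), value = as.numeric(value))
  }
  fam <- model_family(x)
  if (fam == "glm") {
    add("w", x$w); add("b", x$b)
  } else if (fam == "quadratic") {
    add("A", x$A); add("w", x$w); add("b", x$b)
  } else if (fam == "stm") {
    for (k in seq_len(x$K)) {
      add("A", x$A[[k]], k); add("w", x$W[k, ], k); add("a", x$a[k], k)
    }
  } else {
    add("U", x$U)
    for (k in seq_len(x$K)) {
      add("B", x$B[k, ], k); add("w", x$W[k, ], k); add("a", x$a[k], k)
    }
  }
  add("h", x$h)
  dplyr::bind_rows(rows)
}

#' @rdname tidy.spikemix_params
#' @method tidy spikemix_fit
#' @export
tidy.spikemix_fit <- function(x, ...) tidy(x$params, ...)

#' One-row summary of a fit
#'
#' @param x A `spikemix_fit`.
#' @param ... Unused.
#' @return Tibble with family, parameter count, final training objective in
#'   bits per bin, iteration count, and early-stopping information.
#' @method glance spikemix_fit
#' @export
glance.spikemix_fit <- function(x, ...) {
  tibble::tibble(
    family = x$family,
    n_parameters = n_parameters(x$params),
    objective_bits_per_bin = x$objective_bits,
    n_iter = x$n_iter,
    stopped_early = x$stopped_early,
    best_iter = x$best_iter
  )
}

#' @rdname glance.spikemix_fit
#' @method glance lnp_fit
#' @export
glance.lnp_fit <- function(x, ...) {
  tibble::tibble(
    family = x$family,
    accepted_stage = x$accepted_stage,
    heldout_bits_per_bin = unname(x$stage_val_bits[x$accepted_stage]),
    sigmoid_bits_per_bin = unname(x$stage_val_bits["sigmoid"])
  )
}

#' Training and validation curves of a fit
#'
#' Objective (bits per bin) per validation check; the dashed vertical line
#' marks the early-stopping optimum when present.
#'
#' @param object A `spikemix_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot spikemix_fit
#' @export
autoplot.spikemix_fit <- function(object, ...) {
  df <- tibble::tibble(
    check = seq_along(object$train_curve) - 1,
    train = object$train_curve,
    validation = if (length(object$val_curve) == length(object$train_curve))
      object$val_curve else NA_real_
  )
  df <- tidyr::pivot_longer(df, -"check", names_to = "set",
                            values_to = "bits")
  df <- df[!is.na(df$bits), ]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$check, y = .data$bits,
                                        colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "validation check", y = "cross-entropy (bits/bin)",
                  colour = NULL,
                  title = paste(object$family, "model training"))
  if (object$best_iter > 0 && length(object$val_curve) > 0) {
    cfg <- object$config
    p <- p + ggplot2::geom_vline(
      xintercept = object$best_iter / cfg$check_every, linetype = "dashed")
  }
  p
}

#' Plot a PSTH model
#'
#' Smoothed trial-averaged firing rate (spikes/s) over time.
#'
#' @param object A [psth_predict()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot psth_model
#' @export
autoplot.psth_model <- function(object, ...) {
  df <- tibble::tibble(
    time = (seq_along(object$psth) - 0.5) * object$dt,
    rate = object$psth / object$dt
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$rate)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "rate (spikes/s)",
                  title = sprintf("PSTH (%d trials, FWHM %.2g ms)",
                                  object$n_trials,
                                  object$kernel_fwhm * 1000))
}

#' Plot interspike-interval histograms
#'
#' Spike-conditional (`g1`) and no-spike-conditional (`g0`) distributions of
#' the time since the last spike; their log-ratio is the spike-history
#' filter.
#'
#' @param object An [estimate_isi()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot isi_histograms
#' @export
autoplot.isi_histograms <- function(object, ...) {
  mid <- (object$bin_edges[-1] + object$bin_edges[-length(object$bin_edges)]) / 2
  df <- tibble::tibble(
    interval = rep(mid, 2),
    mass = c(object$g1, object$g0),
    conditional = rep(c("spike (g1)", "no spike (g0)"), each = length(mid))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$interval * 1000,
                                   y = .data$mass,
                                   colour = .data$conditional)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "time since last spike (ms)", y = "probability mass",
                  colour = NULL)
}
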