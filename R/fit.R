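# Data-frame-first fitting front-ends for the four model families.

with_seed_local <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  old <- globalenv()$.Random.seed
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

safe_logit_rate <- function(y) stats::qlogis(min(max(mean(y), 1e-6), 1 - 1e-6))

#' Fit a sigmoid GLM (linear or quadratic) by maximum likelihood
#'
#' Concave Bernoulli likelihood with the logistic sigmoid: this is the
#' convex first stage of [fit_glm_pipeline()], exposed directly. The
#' quadratic family is the same GLM on a quadratically expanded feature
#' space (symmetric quadratic form), so it remains concave.
#'
#' @param data Design tibble ([as_design()] / [build_design()]).
#' @param family `"linear"` or `"quadratic"`.
#' @param config A [train_config()].
#' @param val_split Optional early-stopping fraction (see [finetune()]).
#' @return A `spikemix_fit`.
#' @export
fit_glm <- function(data, family = c("linear", "quadratic"),
                    config = train_config(), val_split = NULL) {
  family <- match.arg(family)
  parts <- design_parts(data)
  D <- ncol(parts$X); H <- ncol(parts$S)
  b0 <- safe_logit_rate(parts$y)
  init <- if (family == "linear") {
    glm_params(w = numeric(D), h = numeric(H), b = b0)
  } else {
    quad_params(A = matrix(0, D, D), w = numeric(D), h = numeric(H), b = b0)
  }
  finetune_mat(init, parts$X, parts$S, parts$y, config, val_split)
}

#' Fit a spike-triggered mixture model
#'
#' Generative initialization followed by discriminative fine-tuning: the
#' spike-triggered stimulus distribution is fitted with a `K`-component
#' Gaussian mixture by EM, the non-spike-triggered distribution with a
#' single Gaussian, and the pair is converted to STM parameters through
#' Bayes' rule ([bayes_to_stm()]). If the design carries a history term, the
#' history filter is initialized from interspike-interval histograms when
#' `isi` is supplied, otherwise at zero. The conditional likelihood is then
#' maximized by L-BFGS ([finetune()]).
#'
#' @inheritParams fit_glm
#' @param K Number of spike-triggered mixture components (default 3; the
#'   reference protocol used three to five).
#' @param init `"generative"` (default) or `"random"` (small seeded draws).
#' @param isi Optional [estimate_isi()] result used to initialize the
#'   history filter (its bin count must equal `H`).
#' @return A `spikemix_fit`.
#' @export
fit_stm <- function(data, K = 3, config = train_config(), val_split = NULL,
                    init = c("generative", "random"), isi = NULL) {
  init <- match.arg(init)
  parts <- design_parts(data)
  D <- ncol(parts$X); H <- ncol(parts$S)
  h0 <- if (!is.null(isi)) isi_to_history_filter(isi, H) else numeric(H)
  init_params <- if (init == "generative") {
    spk <- parts$X[parts$y == 1, , drop = FALSE]
    non <- parts$X[parts$y == 0, , drop = FALSE]
    if (nrow(spk) < 2 || nrow(non) < 2) {
      stop("need at least 2 spike and 2 non-spike bins for generative init")
    }
    mix1 <- fit_mog_em(spk, K, seed = config$seed)
    g0 <- fit_gaussian(non)
    bayes_to_stm(mix1, g0, safe_logit_rate(parts$y), h = h0)
  } else {
    with_seed_local(config$seed %||% 0L, {
      stm_params(
        A = lapply(seq_len(K), function(k) {
          Z <- matrix(stats::rnorm(D * D, sd = 0.1), D, D)
          (Z + t(Z)) / 2
        }),
        W = matrix(stats::rnorm(K * D, sd = 0.1), K, D),
        a = safe_logit_rate(parts$y) + stats::rnorm(K, sd = 0.1),
        h = h0
      )
    })
  }
  finetune_mat(init_params, parts$X, parts$S, parts$y, config, val_split)
}

#' Fit a factored STM
#'
#' The factored STM is trained discriminatively from small random
#' initializations (entries ~ N(0, 0.01) sd, offsets at the logit of the
#' empirical spike rate so initial predictions match the mean rate),
#' mirroring the reference protocol for this family.
#'
#' @inheritParams fit_stm
#' @param M Number of shared quadratic features (>= 0).
#' @return A `spikemix_fit`.
#' @export
fit_fstm <- function(data, K = 3, M = 5, config = train_config(),
                     val_split = NULL) {
  stopifnot(K >= 1, M >= 0)
  parts <- design_parts(data)
  D <- ncol(parts$X); H <- ncol(parts$S)
  init_params <- with_seed_local(config$seed %||% 0L, {
    fstm_params(
      U = matrix(stats::rnorm(D * M, sd = 0.1), D, M),
      B = matrix(stats::rnorm(K * M, sd = 0.1), K, M),
      W = matrix(stats::rnorm(K * D, sd = 0.1), K, D),
      a = safe_logit_rate(parts$y) + stats::rnorm(K, sd = 0.1),
      h = numeric(H)
    )
  })
  finetune_mat(init_params, parts$X, parts$S, parts$y, config, val_split)
}

#' Fit a history-only model
#'
#' GLM with the stimulus-dependent terms dropped: only the spike-history
#' filter and a bias are fitted. This is the conditioning model needed for
#' the spike-history decomposition of the mutual-information lower bound
#' ([mi_lower_bound()]).
#'
#' @inheritParams fit_glm
#' @return A `spikemix_fit` whose params have `D = 0`.
#' @export
fit_history_only <- function(data, config = train_config(),
                             val_split = NULL) {
  parts <- design_parts(data)
  H <- ncol(parts$S)
  init <- glm_params(w = numeric(0), h = numeric(H),
                     b = safe_logit_rate(parts$y))
  X0 <- matrix(0, length(parts$y), 0)
  finetune_mat(init, X0, parts$S, parts$y, config, val_split)
}
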