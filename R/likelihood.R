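# Bernoulli conditional likelihood and its analytic gradients.
#
# The optimizer works in nats (natural log); user-facing cross-entropies are
# reported in bits per bin. Probabilities are clipped to
# [1e-12, 1 - 1e-12] inside the likelihood to keep the objective finite at
# saturated predictions.

PROB_CLIP <- 1e-12

clip_prob <- function(p) pmin(pmax(p, PROB_CLIP), 1 - PROB_CLIP)

# Mean Bernoulli negative log-likelihood in nats given probabilities.
bernoulli_nll_nats <- function(p, y) {
  p <- clip_prob(p)
  -mean(y * log(p) + (1 - y) * log1p(-p))
}

#' Bernoulli negative log-likelihood (cross-entropy) in bits per bin
#'
#' \eqn{-\frac{1}{T} \sum_t [y_t \log_2 p_t + (1 - y_t) \log_2 (1 - p_t)]}
#' with \eqn{p_t} the model's firing probability at bin `t`. This is the
#' objective minimized during discriminative training and the evaluation
#' measure for model comparison.
#'
#' @param params A `spikemix_params` object (or any object with a
#'   [firing_prob()] method).
#' @param x `T` x `D` stimulus design matrix.
#' @param s `T` x `H` history design matrix, or `NULL`.
#' @param y Binary response vector of length `T` (0/1 spike indicator).
#' @return Nonnegative scalar, bits per bin.
#' @examples
#' p <- glm_params(w = numeric(0), h = numeric(0), b = 0)  # constant 0.5
#' bernoulli_nll(p, matrix(0, 4, 0), NULL, c(0, 1, 1, 0))  # exactly 1 bit
#' @export
bernoulli_nll <- function(params, x, s, y) {
  y <- check_response(y, nrow(rbind(x)))
  p <- firing_prob(params, x, s)
  bernoulli_nll_nats(p, y) / log(2)
}

check_response <- function(y, t_rows) {
  y <- as.numeric(y)
  if (length(y) != t_rows) {
    stop("misaligned inputs: design has ", t_rows, " rows but y has length ",
         length(y))
  }
  if (!all(y %in% c(0, 1))) stop("y must be a binary 0/1 vector")
  y
}

# ---- gradients --------------------------------------------------------------

# Accumulate sum_t g_t * d f_t / d theta in the flat layout, where f is the
# model predictor. This factorization serves both the plain sigmoid
# likelihood (g = (p - y)/T) and the flexible-nonlinearity stages of the GLM
# pipeline, where g carries the chain rule through the nonlinearity.
predictor_gradient_accum <- function(params, X, S, g) {
  UseMethod("predictor_gradient_accum")
}

#' @export
predictor_gradient_accum.glm_params <- function(params, X, S, g) {
  c(drop(crossprod(X, g)), drop(crossprod(S, g)), sum(g))
}

#' @export
predictor_gradient_accum.quad_params <- function(params, X, S, g) {
  G <- 0.5 * crossprod(X, X * g)
  c(ut_grad(G), drop(crossprod(X, g)), drop(crossprod(S, g)), sum(g))
}

#' @export
predictor_gradient_accum.stm_params <- function(params, X, S, g) {
  R <- row_softmax(stm_component_responses(params, X))
  comp <- unlist(lapply(seq_len(params$K), function(k) {
    gk <- g * R[, k]
    G <- 0.5 * crossprod(X, X * gk)
    c(ut_grad(G), drop(crossprod(X, gk)), sum(gk))
  }))
  c(comp, drop(crossprod(S, g)))
}

#' @export
predictor_gradient_accum.fstm_params <- function(params, X, S, g) {
  R <- row_softmax(fstm_component_responses(params, X))
  Rg <- R * g
  if (params$M > 0) {
    V <- X %*% params$U
    dB <- crossprod(Rg, V^2)                    # K x M
    dU <- crossprod(X, (2 * (Rg %*% params$B)) * V)  # D x M
  } else {
    dB <- matrix(0, params$K, 0)
    dU <- matrix(0, params$D, 0)
  }
  dW <- crossprod(Rg, X)                        # K x D
  da <- colSums(Rg)
  c(as.numeric(dU), as.numeric(dB), as.numeric(dW), da,
    drop(crossprod(S, g)))
}

#' Gradient of the Bernoulli negative log-likelihood
#'
#' Analytic gradient of the mean negative log-likelihood (in nats) with
#' respect to the flat parameter layout of [flatten_params()]. For the STM
#' families the stimulus-parameter gradients carry softmax component
#' responsibilities. Validated against central finite differences in the
#' test suite.
#'
#' @inheritParams bernoulli_nll
#' @return Numeric vector, same length and layout as
#'   `flatten_params(params)`.
#' @export
nll_gradient <- function(params, x, s, y) {
  io <- align_inputs(params, x, s)
  y <- check_response(y, nrow(io$X))
  p <- sigmoid(predictor(params, io$X, io$S))
  # exact sigmoid-Bernoulli gradient; bins whose probability is clipped in
  # the objective are flat there and contribute none
  g <- (p - y) / length(y)
  g[p < PROB_CLIP | p > 1 - PROB_CLIP] <- 0
  predictor_gradient_accum(params, io$X, io$S, g)
}
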