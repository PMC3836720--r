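# Elementary nonlinearities shared by every model family.

#' Logistic sigmoid
#'
#' Numerically stable logistic function \eqn{\sigma(z) = 1 / (1 + e^{-z})},
#' the output nonlinearity of all model families in this package: the
#' predictor (log-odds of a spike in a bin) is passed through `sigmoid()` to
#' obtain the firing probability.
#'
#' @param z Numeric vector of log-odds.
#' @return Numeric vector of probabilities, same length as `z`.
#' @examples
#' sigmoid(0)                 # 0.5
#' sigmoid(log(0.2 / 0.8))    # 0.2
#' @export
sigmoid <- function(z) {
  stopifnot(is.numeric(z))
  out <- numeric(length(z))
  pos <- !is.na(z) & z >= 0
  out[pos] <- 1 / (1 + exp(-z[pos]))
  ez <- exp(z[!pos])
  out[!pos] <- ez / (1 + ez)
  out[is.na(z)] <- NA_real_
  out
}

#' Log-sum-exp (soft maximum)
#'
#' Computes \eqn{\log \sum_i e^{q_i}} with max-subtraction for numerical
#' stability. This is the "soft maximum" combining the per-component
#' quadratic responses of a spike-triggered mixture model: the STM predictor
#' effectively takes the maximum of several quadratic models, smoothed.
#'
#' @param q Nonempty numeric vector.
#' @return Scalar, bounded by `max(q)` and `max(q) + log(length(q))`.
#' @examples
#' log_sum_exp(c(3.7))          # 3.7
#' log_sum_exp(rep(1, 4))       # 1 + log(4)
#' @export
log_sum_exp <- function(q) {
  if (length(q) == 0L) {
    stop("log_sum_exp() requires a nonempty vector")
  }
  m <- max(q)
  if (!is.finite(m)) {
    # all -Inf stays -Inf; any +Inf or NA propagates
    return(m + 0)
  }
  m + log(sum(exp(q - m)))
}

# Row-wise log-sum-exp for a T x K matrix of component responses.
row_log_sum_exp <- function(Q) {
  m <- do.call(pmax, as.data.frame(Q))
  m + log(rowSums(exp(Q - m)))
}

# Row-wise softmax responsibilities for a T x K matrix.
row_softmax <- function(Q) {
  m <- do.call(pmax, as.data.frame(Q))
  E <- exp(Q - m)
  E / rowSums(E)
}
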