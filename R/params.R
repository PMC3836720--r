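# Parameter containers and forward evaluation for the four model families.
#
# All families share the same structure: a scalar predictor f(x, s) feeding
# the logistic sigmoid, with an additive spike-history term h's shared across
# mixture components. Quadratic forms use the 1/2 * x'Ax convention with A
# stored symmetric; matrices are symmetrized (A + A')/2 on ingestion.

symmetrize <- function(A, tol = 1e-8) {
  A <- as.matrix(A)
  if (nrow(A) != ncol(A)) {
    stop("quadratic matrix must be square, got ", nrow(A), " x ", ncol(A))
  }
  asym <- max(abs(A - t(A)))
  if (asym > tol * max(1, max(abs(A)))) {
    warning("quadratic matrix asymmetric beyond tolerance (max |A - t(A)| = ",
            signif(asym, 3), "); symmetrizing")
  }
  (A + t(A)) / 2
}

check_finite <- function(x, what) {
  if (!all(is.finite(x))) stop(what, " must contain only finite values")
  x
}

#' Linear (GLM) model parameters
#'
#' Parameters of the linear-nonlinear-Bernoulli model: the predictor is
#' \eqn{f(x, s) = w'x + h's + b} and the firing probability is
#' \eqn{\sigma(f)}.
#'
#' @param w Stimulus filter, length `D`.
#' @param h Spike-history filter, length `H` (may be `numeric(0)` for a
#'   history-free model).
#' @param b Scalar bias.
#' @return An object of class `glm_params`.
#' @family model parameters
#' @export
glm_params <- function(w, h = numeric(0), b = 0) {
  w <- check_finite(as.numeric(w), "w")
  h <- check_finite(as.numeric(h), "h")
  b <- check_finite(as.numeric(b), "b")
  stopifnot(length(b) == 1L)
  structure(
    list(w = w, h = h, b = b, D = length(w), H = length(h)),
    class = c("glm_params", "spikemix_params")
  )
}

#' Quadratic model parameters
#'
#' Predictor \eqn{f(x, s) = \frac{1}{2} x'Ax + w'x + h's + b}. The quadratic
#' model is a GLM on a quadratically expanded feature space; its maximum
#' likelihood problem remains concave.
#'
#' @param A Symmetric `D` x `D` matrix (symmetrized on ingestion).
#' @inheritParams glm_params
#' @return An object of class `quad_params`.
#' @family model parameters
#' @export
quad_params <- function(A, w, h = numeric(0), b = 0) {
  w <- check_finite(as.numeric(w), "w")
  A <- symmetrize(check_finite(as.matrix(A), "A"))
  if (nrow(A) != length(w)) {
    stop("dimension mismatch: A is ", nrow(A), " x ", ncol(A),
         " but w has length ", length(w))
  }
  h <- check_finite(as.numeric(h), "h")
  b <- check_finite(as.numeric(b), "b")
  stopifnot(length(b) == 1L)
  structure(
    list(A = A, w = w, h = h, b = b, D = length(w), H = length(h)),
    class = c("quad_params", "spikemix_params")
  )
}

#' Spike-triggered mixture model (STM) parameters
#'
#' Predictor
#' \eqn{f(x, s) = \log \sum_k \exp(\frac{1}{2} x'A_k x + w_k'x + a_k) + h's}:
#' a soft maximum over `K` quadratic component responses plus a shared
#' spike-history term. The non-spike-triggered Gaussian's quadratic is
#' absorbed into each component's \eqn{(A_k, w_k, a_k)}, and the global bias
#' into the per-component offsets \eqn{a_k}.
#'
#' @param A List of `K` symmetric `D` x `D` matrices (or a `D` x `D` x `K`
#'   array), one per mixture component.
#' @param W `K` x `D` matrix of per-component linear filters (rows
#'   \eqn{w_k}).
#' @param a Length-`K` vector of per-component offsets.
#' @inheritParams glm_params
#' @return An object of class `stm_params`.
#' @family model parameters
#' @export
stm_params <- function(A, W, a, h = numeric(0)) {
  if (is.array(A) && length(dim(A)) == 3L) {
    A <- lapply(seq_len(dim(A)[3]), function(k) A[, , k])
  }
  if (!is.list(A)) A <- list(as.matrix(A))
  A <- lapply(A, function(Ak) symmetrize(check_finite(as.matrix(Ak), "A")))
  W <- check_finite(rbind(W), "W")
  a <- check_finite(as.numeric(a), "a")
  h <- check_finite(as.numeric(h), "h")
  K <- length(A)
  D <- nrow(A[[1]])
  if (K < 1L) stop("STM needs at least one component (K >= 1)")
  if (nrow(W) != K || length(a) != K) {
    stop("dimension mismatch: ", K, " components but W has ", nrow(W),
         " rows and a has length ", length(a))
  }
  if (ncol(W) != D) {
    stop("dimension mismatch: components are ", D, "-dimensional but W has ",
         ncol(W), " columns")
  }
  structure(
    list(A = A, W = W, a = a, h = h, D = D, H = length(h), K = K),
    class = c("stm_params", "spikemix_params")
  )
}

#' Factored STM parameters
#'
#' Low-rank STM variant sharing `M` quadratic features \eqn{u_m} across
#' components:
#' \eqn{f(x, s) = \log \sum_k \exp(\sum_m \beta_{km} (u_m'x)^2 + w_k'x + a_k)
#' + h's}. Parameter count grows linearly in the stimulus dimension `D`.
#' There is no global bias: it is absorbed into the per-component offsets
#' \eqn{a_k}.
#'
#' @param U `D` x `M` matrix of shared quadratic features (columns
#'   \eqn{u_m}); `M = 0` (zero columns) gives a mixture of linear models.
#' @param B `K` x `M` matrix of per-component feature coefficients
#'   \eqn{\beta_{km}}.
#' @param W `K` x `D` matrix of per-component linear filters.
#' @param a Length-`K` vector of per-component offsets.
#' @inheritParams glm_params
#' @return An object of class `fstm_params`.
#' @family model parameters
#' @export
fstm_params <- function(U, B, W, a, h = numeric(0)) {
  U <- check_finite(as.matrix(U), "U")
  B <- check_finite(as.matrix(B), "B")
  W <- check_finite(rbind(W), "W")
  a <- check_finite(as.numeric(a), "a")
  h <- check_finite(as.numeric(h), "h")
  D <- ncol(W)
  K <- nrow(W)
  M <- ncol(U)
  if (K < 1L) stop("factored STM needs at least one component (K >= 1)")
  if (length(a) != K || nrow(B) != K) {
    stop("dimension mismatch: ", K, " components but a has length ",
         length(a), " and B has ", nrow(B), " rows")
  }
  if (M > 0 && nrow(U) != D) {
    stop("dimension mismatch: W implies D = ", D, " but U has ", nrow(U),
         " rows")
  }
  if (ncol(B) != M) {
    stop("dimension mismatch: U has ", M, " features but B has ", ncol(B),
         " columns")
  }
  structure(
    list(U = U, B = B, W = W, a = a, h = h, D = D, H = length(h),
         K = K, M = M),
    class = c("fstm_params", "spikemix_params")
  )
}

#' @export
print.spikemix_params <- function(x, ...) {
  fam <- model_family(x)
  cat("<", fam, " model parameters>\n", sep = "")
  cat("  stimulus dimension D = ", x$D, ", history dimension H = ", x$H,
      sep = "")
  if (!is.null(x$K)) cat(", components K = ", x$K, sep = "")
  if (!is.null(x$M)) cat(", quadratic features M = ", x$M, sep = "")
  cat("\n  ", n_parameters(x), " parameters\n", sep = "")
  invisible(x)
}

#' Model family of a parameter object
#'
#' @param params A `spikemix_params` object.
#' @return One of `"glm"`, `"quadratic"`, `"stm"`, `"fstm"`.
#' @export
model_family <- function(params) {
  switch(class(params)[1],
    glm_params = "glm",
    quad_params = "quadratic",
    stm_params = "stm",
    fstm_params = "fstm",
    stop("not a spikemix parameter object")
  )
}

# ---- input coercion ---------------------------------------------------------

# Coerce x (vector or T x D matrix) and s (NULL, vector or T x H matrix) to
# aligned matrices; error messages name the offending dimension.
align_inputs <- function(params, x, s) {
  X <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  if (params$D == 0L && ncol(X) > 0L) {
    # a stimulus-free (history-only) model ignores stimulus features
    X <- X[, 0, drop = FALSE]
  }
  if (ncol(X) != params$D) {
    stop("stimulus dimension mismatch: model expects D = ", params$D,
         " but x has ", ncol(X), " columns")
  }
  if (is.null(s)) {
    S <- matrix(0, nrow(X), params$H)
  } else {
    S <- if (is.matrix(s)) s else matrix(s, nrow = 1)
    if (ncol(S) != params$H) {
      stop("history dimension mismatch: model expects H = ", params$H,
           " but s has ", ncol(S), " columns")
    }
    if (nrow(S) != nrow(X)) {
      stop("row mismatch: x has ", nrow(X), " rows but s has ", nrow(S))
    }
  }
  list(X = X, S = S)
}

#' Spike-history term
#'
#' Evaluates \eqn{h's} for a one-hot (or all-zero) most-recent-spike vector
#' `s`: 0 when no spike fell in the history window, `h[j]` when the most
#' recent spike sits in history bin `j`.
#'
#' @param s History vector (length `H`, at most one entry equal to 1) or a
#'   `T` x `H` matrix of such rows.
#' @param h History filter, length `H`.
#' @return Numeric vector of history contributions.
#' @export
history_term <- function(s, h) {
  S <- if (is.matrix(s)) s else matrix(s, nrow = 1)
  if (ncol(S) != length(h)) {
    stop("history dimension mismatch: filter has length ", length(h),
         " but s has ", ncol(S), " columns")
  }
  if (length(h) == 0L) return(numeric(nrow(S)))
  drop(S %*% h)
}

# ---- predictors -------------------------------------------------------------

#' Model predictor (log-odds of a spike)
#'
#' Evaluates the scalar predictor \eqn{f(x, s)} feeding the sigmoid, for any
#' model family. Accepts a single bin (vectors) or many bins (matrices with
#' one row per bin).
#'
#' @param params A `spikemix_params` object of any family.
#' @param x Stimulus feature vector (length `D`) or `T` x `D` matrix.
#' @param s Optional history vector (length `H`) or `T` x `H` matrix; `NULL`
#'   means no spike in the history window (all-zero rows).
#' @return Numeric vector of predictor values, one per bin.
#' @seealso [firing_prob()]
#' @export
predictor <- function(params, x, s = NULL) {
  UseMethod("predictor")
}

#' @export
predictor.glm_params <- function(params, x, s = NULL) {
  io <- align_inputs(params, x, s)
  drop(io$X %*% params$w) + history_term(io$S, params$h) + params$b
}

#' @export
predictor.quad_params <- function(params, x, s = NULL) {
  io <- align_inputs(params, x, s)
  quad <- 0.5 * rowSums((io$X %*% params$A) * io$X)
  quad + drop(io$X %*% params$w) + history_term(io$S, params$h) + params$b
}

# T x K matrix of per-component quadratic responses q_k(x).
stm_component_responses <- function(params, X) {
  K <- params$K
  Q <- matrix(0, nrow(X), K)
  for (k in seq_len(K)) {
    Q[, k] <- 0.5 * rowSums((X %*% params$A[[k]]) * X) +
      drop(X %*% params$W[k, ]) + params$a[k]
  }
  Q
}

#' @export
predictor.stm_params <- function(params, x, s = NULL) {
  io <- align_inputs(params, x, s)
  Q <- stm_component_responses(params, io$X)
  row_log_sum_exp(Q) + history_term(io$S, params$h)
}

# T x K matrix of factored component responses.
fstm_component_responses <- function(params, X) {
  V2 <- if (params$M > 0) (X %*% params$U)^2 else
    matrix(0, nrow(X), 0)
  lin <- X %*% t(params$W)
  Q <- lin + matrix(params$a, nrow(X), params$K, byrow = TRUE)
  if (params$M > 0) Q <- Q + V2 %*% t(params$B)
  Q
}

#' @export
predictor.fstm_params <- function(params, x, s = NULL) {
  io <- align_inputs(params, x, s)
  Q <- fstm_component_responses(params, io$X)
  row_log_sum_exp(Q) + history_term(io$S, params$h)
}

#' Firing probability
#'
#' \eqn{P(\mathrm{spike} \mid x, s) = \sigma(f(x, s))}: the per-bin Bernoulli
#' spike probability of any model.
#'
#' @inheritParams predictor
#' @param ... Passed to methods.
#' @return Numeric vector of probabilities in (0, 1).
#' @export
firing_prob <- function(params, x, s = NULL, ...) {
  UseMethod("firing_prob")
}

#' @export
firing_prob.spikemix_params <- function(params, x, s = NULL, ...) {
  sigmoid(predictor(params, x, s))
}

# ---- parameter counting -----------------------------------------------------

#' Number of free parameters of a model family
#'
#' Closed-form parameter counts: GLM `D + H + 1`; quadratic
#' `D(D+1)/2 + D + H + 1` (symmetric quadratic form); STM
#' `K (D(D+1)/2 + D + 1) + H`; factored STM `MD + KM + KD + K + H`. These
#' match the number of entries optimized during fitting.
#'
#' @param family `"glm"`, `"quadratic"`, `"stm"` or `"fstm"`.
#' @param D Stimulus dimension (>= 0).
#' @param H History dimension (>= 0).
#' @param K Number of mixture components (STM families; >= 1).
#' @param M Number of shared quadratic features (factored STM; >= 0).
#' @return Integer parameter count.
#' @examples
#' count_parameters("glm", D = 10, H = 100)               # 111
#' count_parameters("fstm", D = 10, H = 100, K = 6, M = 5) # 246
#' @export
count_parameters <- function(family, D, H, K = 1L, M = 0L) {
  stopifnot(D >= 0, H >= 0, M >= 0)
  family <- match.arg(family, c("glm", "quadratic", "stm", "fstm"))
  if (family %in% c("stm", "fstm") && K < 1) {
    stop("mixture families require K >= 1")
  }
  as.integer(switch(family,
    glm = D + H + 1,
    quadratic = D * (D + 1) / 2 + D + H + 1,
    stm = K * (D * (D + 1) / 2 + D + 1) + H,
    fstm = M * D + K * M + K * D + K + H
  ))
}

#' @rdname count_parameters
#' @param params A `spikemix_params` object.
#' @export
n_parameters <- function(params) {
  count_parameters(model_family(params), params$D, params$H,
                   params$K %||% 1L, params$M %||% 0L)
}
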