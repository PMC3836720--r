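# Flat parameter vectors for the quasi-Newton optimizer.
#
# Layouts (documented and stable; lengths equal count_parameters()):
#   glm:  [w (D), h (H), b]
#   quad: [upper triangle of A incl. diagonal, column-major (D(D+1)/2),
#          w (D), h (H), b]
#   stm:  for k = 1..K: [upper tri of A_k (D(D+1)/2), w_k (D), a_k], then
#          h (H)
#   fstm: [vec(U) column-major (D*M), vec(B) column-major (K*M),
#          vec(W) column-major (K*D), a (K), h (H)]
# Symmetric matrices are parametrized by their upper triangle so that the
# flat length matches the free parameter count.

ut_idx <- function(D) upper.tri(matrix(0, D, D), diag = TRUE)

sym_from_ut <- function(theta, D) {
  A <- matrix(0, D, D)
  A[ut_idx(D)] <- theta
  A <- A + t(A)
  diag(A) <- diag(A) / 2
  A
}

# Map a full symmetric gradient matrix G = dL/dA (with A treated entry-wise)
# to the gradient with respect to the upper-triangle parametrization.
ut_grad <- function(G) {
  D <- nrow(G)
  (2 * G - diag(diag(G), D, D))[ut_idx(D)]
}

#' Flatten model parameters to a numeric vector
#'
#' Deterministic, documented layout used by the optimizer and by the
#' finite-difference gradient checks; `unflatten_params()` inverts it.
#'
#' @param params A `spikemix_params` object.
#' @return Numeric vector of length `n_parameters(params)`.
#' @export
flatten_params <- function(params) {
  UseMethod("flatten_params")
}

#' @export
flatten_params.glm_params <- function(params) {
  c(params$w, params$h, params$b)
}

#' @export
flatten_params.quad_params <- function(params) {
  c(params$A[ut_idx(params$D)], params$w, params$h, params$b)
}

#' @export
flatten_params.stm_params <- function(params) {
  comp <- unlist(lapply(seq_len(params$K), function(k) {
    c(params$A[[k]][ut_idx(params$D)], params$W[k, ], params$a[k])
  }))
  c(comp, params$h)
}

#' @export
flatten_params.fstm_params <- function(params) {
  c(as.numeric(params$U), as.numeric(params$B), as.numeric(params$W),
    params$a, params$h)
}

#' @rdname flatten_params
#' @param theta Numeric vector in the layout produced by `flatten_params()`.
#' @param template A `spikemix_params` object supplying family and
#'   dimensions.
#' @export
unflatten_params <- function(theta, template) {
  UseMethod("unflatten_params", template)
}

take <- function(theta, pos, n) {
  if (n == 0L) return(list(x = numeric(0), pos = pos))
  list(x = theta[pos + seq_len(n)], pos = pos + n)
}

#' @export
unflatten_params.glm_params <- function(theta, template) {
  D <- template$D; H <- template$H
  stopifnot(length(theta) == D + H + 1)
  glm_params(w = theta[seq_len(D)],
             h = theta[D + seq_len(H)],
             b = theta[D + H + 1])
}

#' @export
unflatten_params.quad_params <- function(theta, template) {
  D <- template$D; H <- template$H
  nA <- D * (D + 1) / 2
  stopifnot(length(theta) == nA + D + H + 1)
  quad_params(A = sym_from_ut(theta[seq_len(nA)], D),
              w = theta[nA + seq_len(D)],
              h = theta[nA + D + seq_len(H)],
              b = theta[nA + D + H + 1])
}

#' @export
unflatten_params.stm_params <- function(theta, template) {
  D <- template$D; H <- template$H; K <- template$K
  nA <- D * (D + 1) / 2
  per <- nA + D + 1
  stopifnot(length(theta) == K * per + H)
  A <- vector("list", K)
  W <- matrix(0, K, D)
  a <- numeric(K)
  for (k in seq_len(K)) {
    blk <- theta[(k - 1) * per + seq_len(per)]
    A[[k]] <- sym_from_ut(blk[seq_len(nA)], D)
    W[k, ] <- blk[nA + seq_len(D)]
    a[k] <- blk[per]
  }
  stm_params(A = A, W = W, a = a, h = theta[K * per + seq_len(H)])
}

#' @export
unflatten_params.fstm_params <- function(theta, template) {
  D <- template$D; H <- template$H; K <- template$K; M <- template$M
  stopifnot(length(theta) == M * D + K * M + K * D + K + H)
  pos <- 0
  s <- take(theta, pos, D * M); U <- matrix(s$x, D, M); pos <- s$pos
  s <- take(theta, pos, K * M); B <- matrix(s$x, K, M); pos <- s$pos
  s <- take(theta, pos, K * D); W <- matrix(s$x, K, D); pos <- s$pos
  s <- take(theta, pos, K); a <- s$x; pos <- s$pos
  s <- take(theta, pos, H); h <- s$x
  fstm_params(U = U, B = B, W = W, a = a, h = h)
}
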