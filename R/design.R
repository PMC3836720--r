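# The design tibble: one row per spike-train bin, carrying the binary
# response `y`, the stimulus feature vector `x` (matrix-column, T x D) and
# the one-hot most-recent-spike history vector `s` (matrix-column, T x H).
# The bin width travels as attribute "dt" so evaluation can report rates
# per second. All fitting and evaluation functions take this tibble first,
# so calls chain with the pipe.

#' Assemble a design tibble
#'
#' @param x `T` x `D` matrix of per-bin stimulus features.
#' @param s `T` x `H` matrix of one-hot most-recent-spike history vectors
#'   (or `NULL` for a history-free design, `H = 0`).
#' @param y Binary 0/1 response vector of length `T`.
#' @param dt Bin width in seconds.
#' @return A tibble with columns `t`, `y`, `x`, `s` and attribute `dt`.
#' @export
as_design <- function(x, s, y, dt) {
  X <- as.matrix(x)
  TT <- nrow(X)
  S <- if (is.null(s)) matrix(0, TT, 0) else as.matrix(s)
  y <- check_response(y, TT)
  if (nrow(S) != TT) {
    stop("row mismatch: x has ", TT, " rows but s has ", nrow(S))
  }
  if (ncol(S) > 0) {
    bad <- which(rowSums(S != 0) > 1 | rowSums(S != 0 & S != 1) > 0)
    if (length(bad) > 0) {
      stop("history rows must be one-hot or all-zero; first offending row: ",
           bad[1])
    }
  }
  out <- tibble::tibble(t = seq_len(TT), y = y, x = X, s = S)
  attr(out, "dt") <- dt
  out
}

design_parts <- function(data) {
  stopifnot(is.data.frame(data), all(c("y", "x") %in% names(data)))
  X <- as.matrix(data$x)
  S <- if ("s" %in% names(data)) as.matrix(data$s) else matrix(0, nrow(X), 0)
  list(X = X, S = S, y = as.numeric(data$y), dt = attr(data, "dt"))
}

# Concatenate per-trial design tibbles (matrix columns) into one design.
combine_designs <- function(parts) {
  stopifnot(length(parts) >= 1)
  X <- do.call(rbind, lapply(parts, function(d) as.matrix(d$x)))
  S <- do.call(rbind, lapply(parts, function(d) as.matrix(d$s)))
  y <- unlist(lapply(parts, function(d) d$y))
  out <- as_design(X, S, y, attr(parts[[1]], "dt"))
  for (a in c("basis", "design")) attr(out, a) <- attr(parts[[1]], a)
  out
}

# Contiguous train/validation split: the trailing fraction is validation.
split_design_rows <- function(TT, val_split) {
  n_val <- floor(TT * val_split)
  if (n_val < 1 || n_val >= TT) {
    stop("val_split = ", val_split, " leaves no data in one of the splits")
  }
  list(train = seq_len(TT - n_val), val = (TT - n_val + 1):TT)
}
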