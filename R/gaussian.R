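# Generative estimation: Gaussian and mixture-of-Gaussians class
# conditionals for the spike-triggered / non-spike-triggered stimulus
# distributions, and their conversion through Bayes' rule into
# discriminative predictor parameters.

COV_JITTER <- 1e-6

#' Gaussian mixture component
#'
#' @param mean Length-`D` mean vector.
#' @param covariance Symmetric positive-definite `D` x `D` covariance.
#' @param weight Mixing weight in (0, 1].
#' @return An object of class `gaussian_component`.
#' @export
gaussian_component <- function(mean, covariance, weight = 1) {
  mean <- check_finite(as.numeric(mean), "mean")
  covariance <- symmetrize(check_finite(as.matrix(covariance), "covariance"))
  if (nrow(covariance) != length(mean)) {
    stop("dimension mismatch: mean has length ", length(mean),
         " but covariance is ", nrow(covariance), " x ", ncol(covariance))
  }
  stopifnot(weight > 0, weight <= 1)
  structure(list(mean = mean, covariance = covariance, weight = weight),
            class = "gaussian_component")
}

#' Gaussian mixture model
#'
#' @param components List of [gaussian_component()] objects whose weights
#'   sum to 1.
#' @return An object of class `mixture_model`.
#' @export
mixture_model <- function(components) {
  if (inherits(components, "gaussian_component")) {
    components <- list(components)
  }
  stopifnot(length(components) >= 1)
  w <- vapply(components, function(cp) cp$weight, numeric(1))
  if (abs(sum(w) - 1) > 1e-10) {
    stop("component weights must sum to 1 (got ", sum(w), ")")
  }
  D <- length(components[[1]]$mean)
  for (cp in components) {
    if (length(cp$mean) != D) stop("components disagree on dimension")
  }
  structure(list(components = components, D = D), class = "mixture_model")
}

# Add diagonal jitter until the Cholesky factorization succeeds.
ensure_pd <- function(sigma, jitter = COV_JITTER) {
  base <- jitter * mean(diag(sigma))
  if (base <= 0 || !is.finite(base)) base <- jitter
  for (i in 0:10) {
    boost <- if (i == 0) 0 else base * 10^(i - 1)
    ch <- tryCatch(chol(sigma + diag(boost, nrow(sigma))),
                   error = function(e) NULL)
    if (!is.null(ch)) return(sigma + diag(boost, nrow(sigma)))
  }
  stop("covariance could not be made positive definite by jitter")
}

#' Fit a single Gaussian to samples
#'
#' Maximum-likelihood mean and covariance (1/N normalization) with diagonal
#' jitter added if needed to reach positive definiteness (degenerate sample
#' clouds yield a jittered covariance, not a failure).
#'
#' @param samples `N` x `D` numeric matrix, `N >= 2`.
#' @param weight Mixing weight to record on the component.
#' @return A [gaussian_component()].
#' @export
fit_gaussian <- function(samples, weight = 1) {
  X <- as.matrix(samples)
  if (nrow(X) < 2) stop("fit_gaussian() needs at least 2 samples")
  if (!all(is.finite(X))) stop("samples must be finite")
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  sigma <- crossprod(Xc) / nrow(X)
  gaussian_component(mu, ensure_pd(symmetrize(sigma)), weight)
}

# Log-density of one Gaussian component at rows of X (no mixing weight).
gaussian_log_density <- function(component, X) {
  X <- rbind(X)
  D <- length(component$mean)
  ch <- chol(component$covariance)
  z <- forwardsolve(t(ch), t(sweep(X, 2, component$mean)))
  -0.5 * colSums(z^2) - sum(log(diag(ch))) - 0.5 * D * log(2 * pi)
}

#' Mixture log-density
#'
#' @param mix A [mixture_model()].
#' @param x Vector or `N` x `D` matrix of evaluation points.
#' @return Log-density at each point.
#' @export
mog_log_density <- function(mix, x) {
  X <- rbind(x)
  if (ncol(X) != mix$D) {
    stop("dimension mismatch: mixture is ", mix$D, "-dimensional but x has ",
         ncol(X), " columns")
  }
  L <- vapply(mix$components, function(cp) {
    log(cp$weight) + gaussian_log_density(cp, X)
  }, numeric(nrow(X)))
  L <- rbind(L)  # N x K even when N == 1
  if (nrow(X) == 1L) log_sum_exp(as.numeric(L)) else row_log_sum_exp(L)
}

#' Sample from a Gaussian mixture
#'
#' @param mix A [mixture_model()] or single [gaussian_component()].
#' @param n Number of draws.
#' @return `n` x `D` matrix.
#' @export
sample_mog <- function(mix, n) {
  if (inherits(mix, "gaussian_component")) mix <- mixture_model(list(mix))
  w <- vapply(mix$components, function(cp) cp$weight, numeric(1))
  ks <- sample.int(length(w), n, replace = TRUE, prob = w)
  X <- matrix(0, n, mix$D)
  for (k in unique(ks)) {
    cp <- mix$components[[k]]
    idx <- which(ks == k)
    Z <- matrix(stats::rnorm(length(idx) * mix$D), length(idx))
    X[idx, ] <- sweep(Z %*% chol(cp$covariance), 2, cp$mean, `+`)
  }
  X
}

# kmeans++-style seeding: spread K initial means over the data.
seed_means <- function(X, K) {
  N <- nrow(X)
  centers <- matrix(0, K, ncol(X))
  centers[1, ] <- X[sample.int(N, 1), ]
  if (K > 1) {
    d2 <- rowSums(sweep(X, 2, centers[1, ])^2)
    for (k in 2:K) {
      prob <- d2 / sum(d2)
      centers[k, ] <- X[sample.int(N, 1, prob = prob), ]
      d2 <- pmin(d2, rowSums(sweep(X, 2, centers[k, ])^2))
    }
  }
  centers
}

#' Fit a mixture of Gaussians by expectation maximization
#'
#' Standard EM for full-covariance Gaussian mixtures with kmeans++-style
#' seeding, diagonal covariance jitter, and multiple restarts (the best
#' local optimum by data log-likelihood is returned). Used to estimate the
#' spike-triggered distribution that initializes the STM. `K = 1` reduces
#' exactly to [fit_gaussian()].
#'
#' @param samples `N` x `D` matrix.
#' @param K Number of components (>= 1).
#' @param seed Optional integer seed for reproducible seeding/restarts.
#' @param n_restarts Number of EM restarts (default 5).
#' @param tol Stop when the log-likelihood improves by less than `tol`.
#' @param max_iter Iteration cap per restart.
#' @return A [mixture_model()] with attributes `loglik` (best final value)
#'   and `trace` (per-iteration log-likelihood of the winning restart,
#'   non-decreasing).
#' @export
fit_mog_em <- function(samples, K, seed = NULL, n_restarts = 5,
                       tol = 1e-6, max_iter = 200) {
  X <- as.matrix(samples)
  if (nrow(X) == 0) stop("empty samples")
  if (K < 1) stop("K must be >= 1")
  if (nrow(X) <= K * ncol(X)) {
    warning("few samples (N = ", nrow(X), ") for K = ", K, ", D = ",
            ncol(X), "; estimates may be unstable")
  }
  if (K == 1) {
    g <- fit_gaussian(X)
    mix <- mixture_model(list(g))
    ll <- sum(gaussian_log_density(g, X))
    attr(mix, "loglik") <- ll
    attr(mix, "trace") <- ll
    return(mix)
  }
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
        assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  best <- NULL
  for (r in seq_len(n_restarts)) {
    fit <- em_once(X, K, tol, max_iter)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  mix <- mixture_model(best$components)
  attr(mix, "loglik") <- best$loglik
  attr(mix, "trace") <- best$trace
  mix
}

em_once <- function(X, K, tol, max_iter) {
  N <- nrow(X); D <- ncol(X)
  mu <- seed_means(X, K)
  sigma0 <- ensure_pd(symmetrize(crossprod(sweep(X, 2, colMeans(X))) / N))
  comps <- lapply(seq_len(K), function(k) {
    gaussian_component(mu[k, ], sigma0, 1 / K)
  })
  trace <- numeric(0)
  ll_old <- -Inf
  for (iter in seq_len(max_iter)) {
    # E step in the log domain
    L <- vapply(comps, function(cp) {
      log(cp$weight) + gaussian_log_density(cp, X)
    }, numeric(N))
    norm <- row_log_sum_exp(L)
    R <- exp(L - norm)
    ll <- sum(norm)
    trace <- c(trace, ll)
    if (is.finite(ll_old) && ll - ll_old < tol) break
    ll_old <- ll
    # M step
    nk <- colSums(R)
    nk <- pmax(nk, 1e-8)
    for (k in seq_len(K)) {
      w <- R[, k] / nk[k]
      mu_k <- drop(crossprod(X, w))
      Xc <- sweep(X, 2, mu_k)
      sig_k <- ensure_pd(symmetrize(crossprod(Xc, Xc * w)))
      comps[[k]] <- gaussian_component(mu_k, sig_k, nk[k] / N)
    }
    # renormalize against the nk floor
    tot <- sum(vapply(comps, function(cp) cp$weight, numeric(1)))
    comps <- lapply(comps, function(cp) {
      cp$weight <- cp$weight / tot
      cp
    })
  }
  list(components = comps, loglik = trace[length(trace)], trace = trace)
}

#' Bayes-rule predictor from class-conditional mixtures
#'
#' Given the spike-triggered stimulus distribution `mix1`, the
#' non-spike-triggered distribution `mix0` and the prior log-odds of a
#' spike, returns the function
#' \eqn{f(x) = \log p(x \mid 1) - \log p(x \mid 0) + \mathrm{prior}}, so
#' that \eqn{\sigma(f(x))} is the exact posterior spike probability implied
#' by the generative model.
#'
#' @param mix1,mix0 [mixture_model()] objects of equal dimension.
#' @param prior_logit Scalar \eqn{\log(\pi / (1 - \pi))}.
#' @return A function mapping an `N` x `D` matrix (or length-`D` vector) to
#'   predictor values.
#' @export
bayes_predictor <- function(mix1, mix0, prior_logit) {
  if (mix1$D != mix0$D) {
    stop("dimension mismatch: mix1 is ", mix1$D, "-dimensional, mix0 is ",
         mix0$D)
  }
  force(prior_logit)
  function(x) {
    mog_log_density(mix1, x) - mog_log_density(mix0, x) + prior_logit
  }
}

#' Convert generative Gaussian parameters to STM parameters
#'
#' Closed-form Bayes-rule conversion assuming a Gaussian mixture for the
#' spike-triggered distribution and a single Gaussian for the
#' non-spike-triggered distribution:
#' \eqn{A_k = \Sigma_0^{-1} - \Sigma_k^{-1}},
#' \eqn{w_k = \Sigma_k^{-1}\mu_k - \Sigma_0^{-1}\mu_0}, and \eqn{a_k}
#' collecting log-weights, log-determinants, Mahalanobis constants and the
#' prior log-odds, so that `predictor(result, x)` equals the
#' [bayes_predictor()] value at every `x`. This is the generative
#' initialization of STM training.
#'
#' @param mix1 Spike-triggered [mixture_model()] (or single component).
#' @param gauss0 Non-spike-triggered [gaussian_component()].
#' @param prior_logit Scalar prior log-odds of a spike.
#' @param h Optional history filter to attach (default none).
#' @return An [stm_params()] object.
#' @export
bayes_to_stm <- function(mix1, gauss0, prior_logit, h = numeric(0)) {
  if (inherits(mix1, "gaussian_component")) mix1 <- mixture_model(list(mix1))
  if (mix1$D != length(gauss0$mean)) {
    stop("dimension mismatch: mix1 is ", mix1$D,
         "-dimensional but gauss0 has dimension ", length(gauss0$mean))
  }
  inv_chol <- function(sigma, who) {
    ch <- tryCatch(chol(sigma), error = function(e) {
      stop("singular ", who, " covariance; add diagonal jitter ",
           "(see fit_gaussian)", call. = FALSE)
    })
    list(inv = chol2inv(ch), logdet = 2 * sum(log(diag(ch))))
  }
  s0 <- inv_chol(gauss0$covariance, "non-spike-triggered")
  K <- length(mix1$components)
  D <- mix1$D
  A <- vector("list", K)
  W <- matrix(0, K, D)
  a <- numeric(K)
  mu0 <- gauss0$mean
  for (k in seq_len(K)) {
    cp <- mix1$components[[k]]
    sk <- inv_chol(cp$covariance, paste0("spike-triggered component ", k))
    A[[k]] <- symmetrize(s0$inv - sk$inv)
    W[k, ] <- drop(sk$inv %*% cp$mean - s0$inv %*% mu0)
    a[k] <- log(cp$weight) - 0.5 * sk$logdet + 0.5 * s0$logdet -
      0.5 * drop(crossprod(cp$mean, sk$inv %*% cp$mean)) +
      0.5 * drop(crossprod(mu0, s0$inv %*% mu0)) + prior_logit
  }
  stm_params(A = A, W = W, a = a, h = h)
}
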