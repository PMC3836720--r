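# Programmatic fixtures shared across the suite. All randomness is seeded
# at the call sites; parameters are drawn at moderate scale so predictors
# stay well inside the sigmoid's responsive range.

rand_sym <- function(D, sd = 0.3) {
  Z <- matrix(rnorm(D * D, sd = sd), D, D)
  (Z + t(Z)) / 2
}

rand_params <- function(family, D = 4, H = 6, K = 2, M = 3, sd = 0.3) {
  switch(family,
    glm = glm_params(rnorm(D, sd = sd), rnorm(H, sd = sd),
                     rnorm(1, sd = sd)),
    quadratic = quad_params(rand_sym(D, sd), rnorm(D, sd = sd),
                            rnorm(H, sd = sd), rnorm(1, sd = sd)),
    stm = stm_params(lapply(seq_len(K), function(k) rand_sym(D, sd)),
                     matrix(rnorm(K * D, sd = sd), K, D),
                     rnorm(K, sd = sd), rnorm(H, sd = sd)),
    fstm = fstm_params(matrix(rnorm(D * M, sd = sd), D, M),
                       matrix(rnorm(K * M, sd = sd), K, M),
                       matrix(rnorm(K * D, sd = sd), K, D),
                       rnorm(K, sd = sd), rnorm(H, sd = sd))
  )
}

# Random design with valid one-hot history rows (some all-zero).
rand_design_mats <- function(TT = 200, D = 4, H = 6, p_spike = 0.3) {
  X <- matrix(rnorm(TT * D), TT, D)
  S <- matrix(0, TT, H)
  if (H > 0) {
    S[cbind(seq_len(TT), sample.int(H, TT, replace = TRUE))] <- 1
    S[sample.int(TT, floor(TT / 4)), ] <- 0
  }
  y <- rbinom(TT, 1, p_spike)
  list(X = X, S = S, y = y)
}

# Central finite differences of the bits-per-bin objective in nats.
fd_gradient <- function(params, X, S, y, step = 1e-5) {
  th <- flatten_params(params)
  vapply(seq_along(th), function(i) {
    up <- th; up[i] <- th[i] + step
    dn <- th; dn[i] <- th[i] - step
    (bernoulli_nll(unflatten_params(up, params), X, S, y) -
       bernoulli_nll(unflatten_params(dn, params), X, S, y)) *
      log(2) / (2 * step)
  }, numeric(1))
}

# Well-separated 3-component spike-triggered mixture and broad
# non-spike-triggered Gaussian: the generative ground truth used by the
# recovery experiments.
ground_truth_mixture <- function(D = 5) {
  stopifnot(D >= 2)
  mu <- matrix(0, 3, D)
  mu[1, 1] <- 2.5
  mu[2, 1] <- -2.5; mu[2, 2] <- 1.5
  mu[3, 2] <- -2.5; mu[3, min(3, D)] <- mu[3, min(3, D)] + 1
  comps <- lapply(1:3, function(k) {
    sig <- diag(D) * (0.4 + 0.2 * k)
    sig[1, 2] <- sig[2, 1] <- 0.1
    gaussian_component(mu[k, ], sig, c(0.5, 0.3, 0.2)[k])
  })
  list(mix1 = mixture_model(comps),
       gauss0 = gaussian_component(rep(0, D), diag(D)))
}

# Refractory-style history filter over H bins.
refractory_filter <- function(H, strength = -5, tau = 4) {
  if (H == 0) return(numeric(0))
  strength * exp(-(seq_len(H) - 1) / tau)
}

# STM ground truth with history, plus designs sampled from it with spike
# feedback. Returns train/test design tibbles and the generating params.
stm_recovery_world <- function(n_train, n_test, D = 5, H = 20,
                               rate_logit = -3.2, seed = 1) {
  gt <- ground_truth_mixture(D)
  params <- bayes_to_stm(gt$mix1, gt$gauss0, rate_logit,
                         h = refractory_filter(H))
  TT <- n_train + n_test
  withr::with_seed(seed, {
    X <- matrix(rnorm(TT * D), TT, D)
    train <- simulate_spikes(params, X, dt = 1e-3, n_trials = 1,
                             seed = seed + 1)[[1]]
  })
  S <- spikemix:::history_matrix(train$counts, H)
  idx_tr <- seq_len(n_train)
  idx_te <- n_train + seq_len(n_test)
  list(
    params = params,
    train = as_design(X[idx_tr, , drop = FALSE], S[idx_tr, , drop = FALSE],
                      train$counts[idx_tr], 1e-3),
    test = as_design(X[idx_te, , drop = FALSE], S[idx_te, , drop = FALSE],
                     train$counts[idx_te], 1e-3)
  )
}

fast_config <- function(seed = 1, max_iter = 400) {
  train_config(max_iter = max_iter, tol = 1e-11, seed = seed)
}
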