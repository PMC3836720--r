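# Evaluation: cross-entropy reports, MI lower bound, PSTH oracle,
# explained variance.

test_that("cross_entropy report units and closed forms", {
  p05 <- glm_params(numeric(0), numeric(0), 0)
  dat <- as_design(matrix(0, 100, 0), NULL, rbinom(100, 1, 0.5), 0.001)
  rep1 <- cross_entropy(p05, dat)
  expect_equal(rep1$cross_entropy_bits_per_bin, 1)
  expect_equal(rep1$cross_entropy_bits_per_s, 1000)
  # halving dt doubles the rate at fixed bits/bin
  rep2 <- cross_entropy(p05, dat, dt = 0.0005)
  expect_equal(rep2$cross_entropy_bits_per_s,
               2 * rep1$cross_entropy_bits_per_s)
})

test_that("cross-entropy of the true model matches its entropy rate", {
  withr::with_seed(61, {
    truth <- rand_params("glm", D = 4, H = 0, sd = 0.8)
    X <- matrix(rnorm(2e5 * 4), ncol = 4)
    p <- firing_prob(truth, X, NULL)
    y <- rbinom(length(p), 1, p)
  })
  dat <- as_design(X, NULL, y, 1e-3)
  ce <- cross_entropy(truth, dat)$cross_entropy_bits_per_bin
  # plug-in conditional entropy of the simulated probabilities
  hcond <- mean(-p * log2(p) - (1 - p) * log2(1 - p))
  se <- sd(-(y * log2(p) + (1 - y) * log2(1 - p))) / sqrt(length(p))
  expect_lt(abs(ce - hcond), 3 * se)
})

test_that("mi_lower_bound decomposes and handles the null correctly", {
  p05 <- glm_params(numeric(0), numeric(0), 0)
  dat <- as_design(matrix(0, 50, 0), NULL, rbinom(50, 1, 0.5), 0.001)
  r <- cross_entropy(p05, dat)
  expect_equal(mi_lower_bound(r, r), 0)
  r2 <- r; r2$n_test_bins <- 49L
  expect_error(mi_lower_bound(r, r2), "mismatched")
})

test_that("stimulus-independent neurons carry no stimulus information", {
  # a pure history neuron: the full model's advantage over history-only is
  # zero in expectation
  ests <- vapply(1:10, function(s) {
    withr::with_seed(200 + s, {
      H <- 10
      truth <- glm_params(numeric(0), refractory_filter(H), qlogis(0.08))
      TT <- 6000
      Xd <- matrix(rnorm(TT * 3), TT)   # decoy stimulus, unused by the cell
      tr <- simulate_spikes(glm_params(numeric(0), truth$h, truth$b),
                            matrix(0, TT, 0), 1e-3, seed = s)[[1]]
      S <- spikemix:::history_matrix(tr$counts, H)
      half <- seq_len(TT / 2)
      train <- as_design(Xd[half, ], S[half, ], tr$counts[half], 1e-3)
      test <- as_design(Xd[-half, ], S[-half, ], tr$counts[-half], 1e-3)
      full <- fit_glm(train, "linear", fast_config(seed = s))
      hist_only <- fit_history_only(train, fast_config(seed = s))
      mi_lower_bound(cross_entropy(full$params, test),
                     cross_entropy(hist_only$params, test))
    })
  }, numeric(1))
  se <- sd(ests) / sqrt(length(ests))
  expect_lt(abs(mean(ests)), 2 * se + 1)   # bits/s at dt = 1 ms
})

test_that("strongly driven neurons yield a stable positive MI estimate", {
  world <- stm_recovery_world(30000, 30000, D = 5, H = 15, seed = 77)
  # generating model's own gap on a large test set
  hist_fit <- fit_history_only(world$train, fast_config(seed = 1))
  bound <- mi_lower_bound(cross_entropy(world$params, world$test),
                          cross_entropy(hist_fit$params, world$test))
  expect_gt(bound, 0)
  # a weaker competing model cannot beat the generating model's bound
  glm_fit <- fit_glm(world$train, "linear", fast_config(seed = 1))
  bound_glm <- mi_lower_bound(cross_entropy(glm_fit$params, world$test),
                              cross_entropy(hist_fit$params, world$test))
  expect_lt(bound_glm, bound * 1.05)
})

test_that("PSTH predictions: degenerate trials", {
  dt <- 1e-3
  zeros <- lapply(1:3, function(r) spike_train(rep(0L, 40), dt, r))
  m <- psth_predict(zeros, kernel_fwhm = 2e-3, offset = 0.01)
  expect_equal(unique(as.numeric(m$predictions)), 0.01)
  ones <- lapply(1:3, function(r) spike_train(rep(1L, 40), dt, r))
  m1 <- psth_predict(ones, kernel_fwhm = 2e-3, offset = 0.01)
  expect_true(all(m1$predictions >= 1 - 0.02))
  expect_true(all(m1$predictions <= 1 - 1e-10))
  expect_error(psth_predict(zeros[1], 2e-3, 0.01), "at least 2")
})

test_that("PSTH prediction matches the hand-expanded convolution", {
  dt <- 1e-3
  y1 <- rep(0L, 5); y1[2] <- 1L
  trials <- list(spike_train(y1, dt, 1),
                 spike_train(rep(0L, 5), dt, 2),
                 spike_train(rep(0L, 5), dt, 3))
  fwhm <- 0.4e-3   # near-delta: kernel mass concentrates in one bin
  offset <- 0.02
  m <- psth_predict(trials, fwhm, offset)
  w <- spikemix:::gaussian_kernel_bins(fwhm, dt)
  centre <- (length(w) + 1) / 2
  # held-out trials 2 and 3 see the average of the other two trials: only
  # trial 1 spikes, at bin 2
  for (r in 2:3) {
    expect_equal(m$predictions[r, 2], offset + 0.5 * w[centre],
                 tolerance = 1e-12)
    expect_equal(m$predictions[r, 3], offset + 0.5 * w[centre - 1],
                 tolerance = 1e-12)
  }
  # trial 1's own prediction sees only silence
  expect_equal(m$predictions[1, ], rep(offset, 5), tolerance = 1e-12)
})

test_that("select_psth_params minimizes the leave-one-out objective", {
  withr::with_seed(62, {
    dt <- 1e-3
    rate <- 0.15 * (1 + sin(seq(0, 6 * pi, length.out = 300))) / 2 + 0.02
    trials <- lapply(1:8, function(r) {
      spike_train(rbinom(300, 1, rate), dt, r)
    })
  })
  fwhm_grid <- c(1e-3, 4e-3, 16e-3)
  offset_grid <- c(0.005, 0.02)
  sel <- select_psth_params(trials, fwhm_grid, offset_grid)
  # exhaustive check of the definition
  for (fw in fwhm_grid) {
    for (of in offset_grid) {
      ce <- psth_cross_entropy(psth_predict(trials, fw, of), trials)
      expect_gte(ce, sel$cross_entropy_bits_per_bin - 1e-12)
    }
  }
  # singleton grids return the single point
  s1 <- select_psth_params(trials, 2e-3, 0.01)
  expect_equal(s1$kernel_fwhm, 2e-3)
  expect_equal(s1$offset, 0.01)
  expect_error(select_psth_params(trials, numeric(0), 0.01), "empty")
})

test_that("explained variance is a squared correlation with its invariances", {
  withr::with_seed(63, {
    a <- abs(rnorm(500)) + 0.1
  })
  expect_equal(explained_variance(a, a), 1)
  expect_equal(explained_variance(2.5 * a + 1, a), 1)
  withr::with_seed(64, {
    b <- rnorm(10000); cc <- rnorm(10000)
  })
  expect_lt(explained_variance(b, cc), 0.01)
  expect_error(explained_variance(rep(1, 5), 1:5), "zero-variance")
})

test_that("model ranking on STM data matches the expected ordering", {
  # GLM >= quadratic >= STM in held-out cross-entropy (median over seeds)
  ces <- sapply(1:5, function(s) {
    world <- stm_recovery_world(12000, 6000, D = 4, H = 10,
                                seed = 300 + s)
    cfg <- fast_config(seed = s, max_iter = 300)
    fits <- list(
      glm = fit_glm(world$train, "linear", cfg),
      quad = fit_glm(world$train, "quadratic", cfg),
      stm = fit_stm(world$train, K = 3, config = cfg)
    )
    vapply(fits, function(f) {
      cross_entropy(f$params, world$test)$cross_entropy_bits_per_bin
    }, numeric(1))
  })
  med <- apply(ces, 1, median)
  expect_gte(med["glm"], med["quad"] - 1e-6)
  expect_gte(med["quad"], med["stm"] - 1e-6)
})
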