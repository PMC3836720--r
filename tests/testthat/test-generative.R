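# Generative estimation: Gaussians, EM, Bayes-rule conversion, ISI
# histograms.

test_that("fit_gaussian recovers mean and covariance", {
  expect_equal(fit_gaussian(rbind(c(0, 0), c(2, 0)))$mean, c(1, 0))
  withr::with_seed(31, {
    X <- sample_mog(gaussian_component(c(1, -1), diag(2)), 50000)
    g <- fit_gaussian(X)
    # 3 standard errors of the mean at N = 50,000
    expect_lt(max(abs(g$mean - c(1, -1))), 3 / sqrt(50000) * 1.5)
    expect_lt(max(abs(g$covariance - diag(2))), 0.05)
  })
  expect_error(fit_gaussian(matrix(1, 1, 2)), "at least 2")
  # identical repeated points: jittered covariance, not a failure
  g <- fit_gaussian(matrix(1, 10, 3))
  expect_true(all(eigen(g$covariance)$values > 0))
})

test_that("EM with K = 1 equals fit_gaussian exactly", {
  withr::with_seed(32, {
    X <- matrix(rnorm(200 * 3), 200)
    m <- fit_mog_em(X, 1)
    g <- fit_gaussian(X)
    expect_equal(m$components[[1]]$mean, g$mean)
    expect_equal(m$components[[1]]$covariance, g$covariance)
  })
})

test_that("EM separates two well-spaced clusters and is monotone", {
  withr::with_seed(33, {
    X <- rbind(sweep(matrix(rnorm(1000 * 2), 1000), 2, c(-5, 0), `+`),
               sweep(matrix(rnorm(1000 * 2), 1000), 2, c(5, 0), `+`))
  })
  m <- fit_mog_em(X, 2, seed = 7)
  means <- t(vapply(m$components, function(cp) cp$mean, numeric(2)))
  o <- order(means[, 1])
  expect_lt(max(abs(means[o, ] - rbind(c(-5, 0), c(5, 0)))), 0.2)
  w <- vapply(m$components, function(cp) cp$weight, numeric(1))
  expect_lt(max(abs(w - 0.5)), 0.05)
  expect_true(all(diff(attr(m, "trace")) > -1e-8))
  expect_equal(sum(w), 1, tolerance = 1e-10)
})

test_that("EM agrees with an independent mixture fitter on loglik", {
  skip_if_not_installed("mclust")
  withr::local_package("mclust")
  withr::with_seed(34, {
    X <- rbind(sweep(matrix(rnorm(500 * 2, sd = 0.8), 500), 2, c(-3, 1), `+`),
               sweep(matrix(rnorm(700 * 2, sd = 1.2), 700), 2, c(3, -1), `+`))
  })
  ours <- fit_mog_em(X, 2, seed = 5, n_restarts = 5)
  ref <- mclust::Mclust(X, G = 2, modelNames = "VVV", verbose = FALSE)
  # same local optimum to within EM-vs-EM slack (mclust maximizes the same
  # likelihood with an N-1 covariance convention absorbed in convergence)
  expect_equal(attr(ours, "loglik"), ref$loglik, tolerance = 1e-3)
})

test_that("bayes_predictor reproduces the brute-force posterior", {
  withr::with_seed(35, {
    gt <- ground_truth_mixture(2)
    prior <- qlogis(0.2)
    f <- bayes_predictor(gt$mix1, mixture_model(list(gt$gauss0)), prior)
    # grid oracle: posterior from the mixture densities directly
    gx <- as.matrix(expand.grid(seq(-4, 4, length.out = 21),
                                seq(-4, 4, length.out = 21)))
    post_direct <- function(x) {
      l1 <- exp(mog_log_density(gt$mix1, x)) * 0.2
      l0 <- exp(mog_log_density(mixture_model(list(gt$gauss0)), x)) * 0.8
      l1 / (l1 + l0)
    }
    expect_lt(max(abs(sigmoid(f(gx)) - post_direct(gx))), 1e-12)
    # equal class conditionals: predictor is the prior logit everywhere
    g <- bayes_predictor(gt$mix1, gt$mix1, prior)
    expect_equal(g(gx), rep(prior, nrow(gx)), tolerance = 1e-9)
  })
})

test_that("equal covariances make the Bayes predictor affine", {
  sig <- matrix(c(1.5, 0.3, 0.3, 0.8), 2)
  m1 <- mixture_model(list(gaussian_component(c(1, 2), sig)))
  g0 <- gaussian_component(c(-1, 0), sig)
  p <- bayes_to_stm(m1, g0, 0.5)
  expect_lt(max(abs(p$A[[1]])), 1e-10)
  # regression of the predictor on a grid has no quadratic term
  x1 <- seq(-3, 3, length.out = 13)
  gx <- as.matrix(expand.grid(x1, x1))
  f <- predictor(p, gx)
  fit <- lm(f ~ gx[, 1] + gx[, 2] + I(gx[, 1]^2) + I(gx[, 2]^2) +
              I(gx[, 1] * gx[, 2]))
  expect_lt(max(abs(coef(fit)[4:6])), 1e-10)
})

test_that("bayes_to_stm matches bayes_predictor everywhere", {
  withr::with_seed(36, {
    gt <- ground_truth_mixture(5)
    prior <- qlogis(0.1)
    f <- bayes_predictor(gt$mix1, mixture_model(list(gt$gauss0)), prior)
    p <- bayes_to_stm(gt$mix1, gt$gauss0, prior)
    X <- matrix(rnorm(1000 * 5, sd = 2), 1000)
    expect_lt(max(abs(f(X) - predictor(p, X))), 1e-8)
  })
})

test_that("scaling both class densities by a common factor changes nothing", {
  # doubling every mixture weight is disallowed by the container, but the
  # same redundancy enters through the prior: adding c to the prior logit
  # and subtracting it from every a_k is a no-op
  withr::with_seed(37, {
    gt <- ground_truth_mixture(3)
    p1 <- bayes_to_stm(gt$mix1, gt$gauss0, 0.3)
    p2 <- bayes_to_stm(gt$mix1, gt$gauss0, 0.3 + 2)
    p2$a <- p2$a - 2
    X <- matrix(rnorm(200 * 3), 200)
    expect_equal(predictor(p2, X), predictor(p1, X), tolerance = 1e-12)
  })
})

test_that("ISI histograms: periodic train concentrates g1; normalization", {
  counts <- rep(c(rep(0L, 9), 1L), 20)
  tr <- spike_train(counts, dt = 0.001)
  isi <- estimate_isi(tr, n_bins = 20, window = 0.02)
  expect_equal(sum(isi$g1), 1, tolerance = 1e-10)
  expect_equal(sum(isi$g0), 1, tolerance = 1e-10)
  # every observed spike-conditional interval is exactly 10 bins; the
  # Laplace pseudo-count spreads the remaining mass evenly
  expect_equal(which.max(isi$g1), 10)
  expect_gt(isi$g1[10], 0.6)
  expect_lt(max(isi$g1[-10]), 0.05)
  expect_error(estimate_isi(spike_train(rep(0L, 50), 0.001), 10, 0.01),
               "no spikes")
})

test_that("independent Bernoulli firing gives matching conditionals", {
  withr::with_seed(38, {
    counts <- rbinom(1e5, 1, 0.05)
  })
  tr <- spike_train(counts, dt = 0.001)
  isi <- estimate_isi(tr, n_bins = 50, window = 0.05)
  tv <- 0.5 * sum(abs(isi$g1 - isi$g0))
  expect_lt(tv, 0.05)
  h <- isi_to_history_filter(isi, 50)
  expect_lt(max(abs(h)), 0.5)
  expect_equal(isi$prior_logit, qlogis(mean(counts)))
})

test_that("history filter equals the log-ratio bin by bin", {
  withr::with_seed(39, {
    counts <- rbinom(5000, 1, 0.1)
  })
  isi <- estimate_isi(spike_train(counts, 0.25e-3), n_bins = 25,
                      window = 25 * 0.25e-3)
  h <- isi_to_history_filter(isi, 25)
  for (j in seq_len(25)) {
    s <- numeric(25); s[j] <- 1
    expect_equal(history_term(s, h), log(isi$g1[j]) - log(isi$g0[j]))
  }
  expect_error(isi_to_history_filter(isi, 30), "mismatch")
  # equal histograms give the zero filter
  isi0 <- isi; isi0$g0 <- isi0$g1
  expect_equal(isi_to_history_filter(isi0, 25), rep(0, 25))
  expect_true(all(is.finite(h)))  # pseudo-count keeps empty bins finite
})

test_that("generative pipeline approaches the true model with more data", {
  gt <- ground_truth_mixture(3)
  prior <- qlogis(0.15)
  truth <- bayes_to_stm(gt$mix1, gt$gauss0, prior)
  gap_at <- function(N, seed) {
    withr::with_seed(seed, {
      X1 <- sample_mog(gt$mix1, round(N * 0.15))
      X0 <- sample_mog(mixture_model(list(gt$gauss0)), round(N * 0.85))
      Xte <- rbind(sample_mog(gt$mix1, 750),
                   sample_mog(mixture_model(list(gt$gauss0)), 4250))
    })
    yte <- c(rep(1, 750), rep(0, 4250))
    mix1 <- fit_mog_em(X1, 3, seed = seed)
    g0 <- fit_gaussian(X0)
    est <- bayes_to_stm(mix1, g0, prior)
    S <- matrix(0, nrow(Xte), 0)
    bernoulli_nll(est, Xte, S, yte) - bernoulli_nll(truth, Xte, S, yte)
  }
  gaps <- vapply(1:5, function(s) {
    c(gap_at(1000, s), gap_at(10000, s))
  }, numeric(2))
  expect_lte(median(gaps[2, ]), median(gaps[1, ]) + 1e-6)
  expect_lt(median(gaps[2, ]), 0.05)
})
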