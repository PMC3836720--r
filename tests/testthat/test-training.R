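# Discriminative training: likelihood, gradients, fine-tuning, the
# multi-step GLM pipeline, and factored STM fitting.

test_that("bernoulli_nll closed forms and hand-computed case", {
  # constant 0.5 predictor: exactly 1 bit/bin whatever the spikes
  p05 <- glm_params(numeric(0), numeric(0), 0)
  X0 <- matrix(0, 6, 0)
  expect_equal(bernoulli_nll(p05, X0, NULL, c(1, 0, 0, 1, 1, 0)), 1)
  # y = (1, 0), p = (0.8, 0.4): two-term arithmetic oracle
  pp <- glm_params(w = 1, h = numeric(0), b = 0)
  X <- matrix(c(qlogis(0.8), qlogis(0.4)), 2, 1)
  expect_equal(bernoulli_nll(pp, X, NULL, c(1, 0)),
               -(log2(0.8) + log2(0.6)) / 2, tolerance = 1e-12)
  # confident correct predictions drive the objective to ~0
  Xc <- matrix(c(20, -20), 2, 1)
  expect_lt(bernoulli_nll(pp, Xc, NULL, c(1, 0)), 1e-6)
  expect_error(bernoulli_nll(pp, X, NULL, c(1, 0, 1)), "misaligned")
})

test_that("analytic gradients match finite differences for all families", {
  withr::with_seed(41, {
    shapes <- list(
      list(fam = "glm", D = 4, H = 6, K = 1, M = 0),
      list(fam = "quadratic", D = 3, H = 4, K = 1, M = 0),
      list(fam = "stm", D = 4, H = 5, K = 2, M = 0),
      list(fam = "stm", D = 2, H = 0, K = 3, M = 0),
      list(fam = "fstm", D = 4, H = 6, K = 2, M = 3),
      list(fam = "fstm", D = 5, H = 3, K = 3, M = 0)
    )
    for (sh in shapes) {
      p <- rand_params(sh$fam, D = sh$D, H = sh$H, K = sh$K, M = sh$M)
      m <- rand_design_mats(200, D = sh$D, H = sh$H)
      g <- nll_gradient(p, m$X, m$S, m$y)
      fd <- fd_gradient(p, m$X, m$S, m$y)
      expect_lt(max(abs(g - fd) / pmax(abs(fd), 1e-6)), 1e-5,
                label = paste("finite-difference error,", sh$fam))
    }
  })
})

test_that("GLM gradient is the design-weighted residual", {
  withr::with_seed(42, {
    p <- rand_params("glm", D = 5, H = 4)
    m <- rand_design_mats(300, D = 5, H = 4)
    g <- nll_gradient(p, m$X, m$S, m$y)
    pr <- firing_prob(p, m$X, m$S)
    r <- (pr - m$y) / length(m$y)
    expect_equal(g, c(drop(crossprod(m$X, r)), drop(crossprod(m$S, r)),
                      sum(r)), tolerance = 1e-12)
  })
})

test_that("gradient vanishes when predictions equal the responses", {
  # large-magnitude bias drives p to y on a single-class response
  p <- glm_params(numeric(0), numeric(0), b = 30)
  X <- matrix(0, 50, 0)
  g <- nll_gradient(p, X, NULL, rep(1, 50))
  expect_lt(sqrt(sum(g^2)), 1e-10)
})

test_that("fine-tuned GLM reaches the optimum of an independent solver", {
  withr::with_seed(43, {
    m <- rand_design_mats(2000, D = 5, H = 8)
    truth <- rand_params("glm", D = 5, H = 8, sd = 0.5)
    y <- rbinom(2000, 1, firing_prob(truth, m$X, m$S))
  })
  dat <- as_design(m$X, m$S, y, 1e-3)
  ours <- fit_glm(dat, "linear", train_config(max_iter = 2000, tol = 1e-13))
  ref <- suppressWarnings(
    glm.fit(cbind(m$X, m$S, 1), y, family = binomial()))
  ce_ref <- -mean(y * log2(pmax(ref$fitted.values, 1e-12)) +
                    (1 - y) * log2(pmax(1 - ref$fitted.values, 1e-12)))
  expect_lt(abs(ours$objective_bits - ce_ref), 1e-6)
  # convexity: a different start reaches the same objective
  again <- finetune(rand_params("glm", D = 5, H = 8, sd = 0.2), dat,
                    train_config(max_iter = 2000, tol = 1e-13))
  expect_lt(abs(again$objective_bits - ours$objective_bits), 1e-6)
})

test_that("zero-iteration config returns the initialization unchanged", {
  withr::with_seed(44, {
    p <- rand_params("stm")
    m <- rand_design_mats(100)
  })
  dat <- as_design(m$X, m$S, m$y, 1e-3)
  fit <- finetune(p, dat, train_config(max_iter = 0))
  expect_equal(flatten_params(fit$params), flatten_params(p), tolerance = 0)
  expect_identical(fit$n_iter, 0L)
})

test_that("early stopping returns the best-validation parameters", {
  withr::with_seed(45, {
    # small training set and a flexible model: validation deteriorates
    m <- rand_design_mats(1500, D = 6, H = 0)
    truth <- rand_params("glm", D = 6, H = 0, sd = 0.6)
    y <- rbinom(1500, 1, firing_prob(truth, m$X, m$S))
  })
  dat <- as_design(m$X, m$S, y, 1e-3)
  cfg <- train_config(max_iter = 300, check_every = 5, patience = 8,
                      seed = 1)
  fit <- fit_stm(dat, K = 3, config = cfg, val_split = 0.5,
                 init = "random")
  expect_true(length(fit$val_curve) >= 2)
  checked <- fit$val_curve[-1]  # curve[1] is the initialization
  sp <- spikemix:::split_design_rows(1500, 0.5)
  va <- dat[sp$val, ]
  attr(va, "dt") <- 1e-3
  best_ce <- cross_entropy(fit$params, va)$cross_entropy_bits_per_bin
  expect_lt(best_ce, min(checked) + 1e-9)
})

test_that("training objective never exceeds the initialization's", {
  withr::with_seed(46, {
    for (fam in c("glm", "stm", "fstm")) {
      p <- rand_params(fam, D = 3, H = 4, K = 2, M = 2)
      m <- rand_design_mats(500, D = 3, H = 4)
      dat <- as_design(m$X, m$S, m$y, 1e-3)
      init_obj <- bernoulli_nll(p, m$X, m$S, m$y)
      fit <- finetune(p, dat, train_config(max_iter = 100))
      expect_lte(fit$objective_bits, init_obj + 1e-9)
    }
  })
})

test_that("pipeline stages never degrade held-out performance materially", {
  withr::with_seed(47, {
    m <- rand_design_mats(4000, D = 4, H = 0)
    truth <- rand_params("glm", D = 4, H = 0, sd = 0.8)
    y <- rbinom(4000, 1, firing_prob(truth, m$X, m$S))
  })
  dat <- as_design(m$X, m$S, y, 1e-3)
  fit <- fit_glm_pipeline(dat, "linear", fast_config(), n_rounds = 4)
  v <- fit$stage_val_bits
  accepted <- v[fit$accepted_stage]
  expect_lte(accepted, v["sigmoid"] + 1e-3)
  # well-specified sigmoid data: flexible stages buy essentially nothing
  expect_lt(v["sigmoid"] - min(v), 0.01)
})

test_that("histogram stage captures a sign-symmetric nonlinearity", {
  withr::with_seed(48, {
    TT <- 48000   # 150-bin histogram needs ~300 samples per bin
    X <- matrix(rnorm(TT * 3), TT)
    wtrue <- c(1.5, -1, 0.5)
    z <- drop(X %*% wtrue)
    p <- pmin(0.05 + 0.25 * abs(z) / 2, 0.9)   # V-shaped in w'x
    y <- rbinom(TT, 1, p)
  })
  dat <- as_design(X, NULL, y, 1e-3)
  fit <- fit_glm_pipeline(dat, "linear", fast_config(), n_rounds = 6)
  v <- fit$stage_val_bits
  expect_lt(v["histogram"], v["sigmoid"] - 0.005)
  # the recovered histogram nonlinearity is non-monotone (V-shaped)
  nlh <- fit$stage_models$histogram$nonlinearity
  d <- diff(nlh$prob)
  expect_true(any(d > 0.01) && any(d < -0.01))
})

test_that("histogram nonlinearity reproduces empirical bin frequencies", {
  withr::with_seed(49, {
    z <- rnorm(5000)
    y <- rbinom(5000, 1, plogis(z))
  })
  nl <- histogram_nonlinearity(z, y, n_bins = 150)
  pz <- spikemix:::eval_histogram(nl, z)
  idx <- pmin(pmax(findInterval(z, nl$breaks, rightmost.closed = TRUE), 1L),
              150L)
  for (b in unique(idx)) {
    expect_equal(unique(pz[idx == b]), mean(y[idx == b]))
  }
})

test_that("blob-stage gradients match finite differences", {
  withr::with_seed(50, {
    z <- rnorm(300)
    y <- rbinom(300, 1, 0.3)
    nl <- blob_nonlinearity(quantile(z, c(0.2, 0.5, 0.8), names = FALSE),
                            rep(log(0.5), 3), rep(log(0.4), 3))
  })
  obj <- spikemix:::blob_objective(z, y)
  th <- spikemix:::blob_flatten(nl)
  g <- obj$gr(th)
  fd <- vapply(seq_along(th), function(i) {
    up <- th; up[i] <- th[i] + 1e-6
    dn <- th; dn[i] <- th[i] - 1e-6
    (obj$fn(up) - obj$fn(dn)) / 2e-6
  }, numeric(1))
  expect_lt(max(abs(g - fd) / pmax(abs(fd), 1e-4)), 1e-4)
  # the blob nonlinearity stays a probability below 1
  p <- spikemix:::eval_blob(nl, seq(-5, 5, length.out = 101))
  expect_true(all(p >= 0 & p < 1))
})

test_that("factored STM with M = 0, K = 1 reduces to the GLM fit", {
  withr::with_seed(51, {
    m <- rand_design_mats(3000, D = 4, H = 5)
    truth <- rand_params("glm", D = 4, H = 5, sd = 0.5)
    y <- rbinom(3000, 1, firing_prob(truth, m$X, m$S))
  })
  dat <- as_design(m$X, m$S, y, 1e-3)
  f1 <- fit_fstm(dat, K = 1, M = 0, config = fast_config(seed = 2))
  f2 <- fit_glm(dat, "linear", fast_config(seed = 2))
  expect_lt(abs(f1$objective_bits - f2$objective_bits), 1e-4)
  expect_identical(length(flatten_params(f1$params)),
                   as.integer(count_parameters("fstm", 4, 5, 1, 0)))
})

test_that("factored STM fits are stable across initialization seeds", {
  world <- stm_recovery_world(6000, 3000, D = 4, H = 0, seed = 9)
  ces <- vapply(1:5, function(s) {
    fit <- fit_fstm(world$train, K = 3, M = 2,
                    config = fast_config(seed = s, max_iter = 300))
    cross_entropy(fit$params, world$test)$cross_entropy_bits_per_bin
  }, numeric(1))
  expect_lt(max(ces) - min(ces), 0.03)
})

test_that("held-out performance is non-increasing in training-set size", {
  sizes <- c(1000, 5000, 20000)
  gaps <- sapply(1:6, function(s) {
    world <- stm_recovery_world(20000, 4000, D = 4, H = 10, seed = 100 + s)
    vapply(sizes, function(n) {
      fit <- fit_fstm(world$train[seq_len(n), ], K = 2, M = 2,
                      config = fast_config(seed = s, max_iter = 250),
                      val_split = 0.5)
      cross_entropy(fit$params, world$test)$cross_entropy_bits_per_bin
    }, numeric(1))
  })
  med <- apply(gaps, 1, median)
  expect_true(all(diff(med) <= 1e-3))
})
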