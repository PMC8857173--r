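test_that("rhat approaches 1 for well-mixed chains and flags separation", {
  set.seed(501)
  good <- matrix(rnorm(4000), ncol = 4)
  expect_lt(rhat(good), 1.01)

  split_chains <- matrix(c(rnorm(500, 0), rnorm(500, 10)), ncol = 2)
  expect_gt(rhat(split_chains), 1.5)

  expect_true(is.na(rhat(matrix(1, 100, 4))))
  expect_error(rhat(matrix(rnorm(100), ncol = 1)), "2 chains")
  expect_error(rhat(matrix(rnorm(6), ncol = 2)), "4 draws")
})

test_that("rhat agrees with a direct split-statistic computation", {
  # direct implementation of the rank-normalized split statistic
  direct_rhat <- function(x) {
    half <- floor(nrow(x) / 2)
    xs <- cbind(x[1:half, ], x[(nrow(x) - half + 1):nrow(x), ])
    zb <- matrix(qnorm((rank(c(xs)) - 3 / 8) / (length(xs) + 1 / 4)),
                 nrow = half)
    zf <- matrix(qnorm((rank(abs(c(xs) - median(xs))) - 3 / 8) /
                         (length(xs) + 1 / 4)), nrow = half)
    basic <- function(z) {
      w <- mean(apply(z, 2, var))
      b <- half * var(colMeans(z))
      sqrt(((half - 1) / half * w + b / half) / w)
    }
    max(basic(zb), basic(zf))
  }
  set.seed(502)
  for (i in 1:5) {
    x <- matrix(rnorm(800, mean = rep(c(0, 0.3 * i), each = 200)), ncol = 4)
    expect_equal(rhat(x), direct_rhat(x), tolerance = 1e-12)
  }
})

test_that("ess is near nominal for independent draws and shrinks under AR(1)", {
  set.seed(503)
  iid <- matrix(rnorm(8000), ncol = 4)
  e <- ess_and_mcse(iid)
  expect_lt(abs(e$ess - 8000) / 8000, 0.1)

  rho <- 0.9
  ar <- replicate(4, as.numeric(arima.sim(list(ar = rho), 2000)))
  e_ar <- ess_and_mcse(ar)
  nominal <- 8000 * (1 - rho) / (1 + rho)
  expect_lt(abs(e_ar$ess - nominal) / nominal, 0.25)

  # mcse identity is definitional
  expect_equal(e_ar$mcse, sd(c(ar)) / sqrt(e_ar$ess), tolerance = 1e-12)
  expect_equal(e$mcse, sd(c(iid)) / sqrt(e$ess), tolerance = 1e-12)
})

test_that("brier score matches its formula and bounds", {
  expect_equal(brier_score(c(1, 0, 1), c(1, 0, 1)), 0)
  expect_equal(brier_score(rep(0.5, 7), rbinom(7, 1, 0.5)), 0.25)
  expect_equal(brier_score(c(0.8, 0.4, 0.1), c(1, 0, 0)), 0.07,
               tolerance = 1e-12)
  expect_error(brier_score(c(0.5, 1.2), c(0, 1)), "\\[0, 1\\]")
  expect_error(brier_score(c(0.5), c(0, 1)), "equal length")

  # independent two-line oracle on random inputs
  set.seed(504)
  for (i in 1:1000) {
    n <- sample(1:20, 1)
    p <- runif(n)
    a <- rbinom(n, 1, 0.5)
    expect_equal(brier_score(p, a), sum((p - a)^2) / n, tolerance = 1e-12)
  }
})

test_that("waic reduces to its closed form for constant log-likelihood", {
  ll <- matrix(log(0.5), nrow = 200, ncol = 2)
  w <- waic(ll)
  expect_equal(w$waic, -2 * 2 * log(0.5), tolerance = 1e-12)
  expect_equal(w$p_waic, 0, tolerance = 1e-12)

  # additivity: one more identical point adds exactly -2 log 0.5
  w3 <- waic(cbind(ll, log(0.5)))
  expect_equal(w3$waic - w$waic, -2 * log(0.5), tolerance = 1e-12)

  expect_error(waic(matrix(c(0, -Inf), 2, 1)), "finite")
})

test_that("psis-loo reduces to pointwise log-lik under degenerate weights", {
  ll <- matrix(rep(c(log(0.3), log(0.6)), each = 300), nrow = 300)
  res <- psis_loo(ll)
  expect_equal(res$elpd_loo, log(0.3) + log(0.6), tolerance = 1e-9)
})

test_that("psis-loo agrees with exact leave-one-out refits on a toy model", {
  # single free coefficient, 10 compounds: the exact LOO predictive is a
  # 1-D integral we evaluate by quadrature, refitting per left-out point
  set.seed(505)
  x <- matrix(rnorm(10), ncol = 1)
  y <- cbind(bdnf = rbinom(10, 1, plogis(x[, 1])),
             syn = rbinom(10, 1, plogis(x[, 1])),
             nnf = rbinom(10, 1, plogis(2 * x[, 1])),
             dnt = rbinom(10, 1, plogis(3 * x[, 1])))
  dm <- tiny_design(x, matrix(numeric(0), 10, 0), matrix(numeric(0), 10, 0), y)
  m <- dnt_model(dm, fix = c(mu = 0, sigma = 1))
  fit <- quiet_fit(m, chains = 4, iter = 1000, warmup = 500, seed = 506)
  res <- psis_loo(log_lik(fit))
  expect_true(all(is.finite(res$pointwise$pareto_k)))

  grid <- seq(-6, 6, length.out = 4001)
  point_ll <- function(beta, i) {
    th <- compute_theta_chain(x[i, 1] * beta, 0, 0)
    sum(unlist(y[i, ]) * unlist(th) - log1p(exp(unlist(th))))
  }
  prior <- dnorm(grid, 0, 1, log = TRUE)
  ll_grid <- vapply(seq_len(10),
                    function(i) vapply(grid, point_ll, numeric(1), i = i),
                    numeric(length(grid)))
  exact <- vapply(seq_len(10), function(i) {
    lp_rest <- prior + rowSums(ll_grid[, -i, drop = FALSE])
    w <- exp(lp_rest - max(lp_rest)); w <- w / sum(w)
    log(sum(w * exp(ll_grid[, i])))
  }, numeric(1))
  expect_lt(abs(res$elpd_loo - sum(exact)), 2 * res$se)
})

test_that("waic and psis-loo agree on a well-specified fit", {
  sim <- complete_sim(40, seed = 507)
  fit <- quiet_fit(dnt_model(build_design_matrices(sim$data)),
                   chains = 2, iter = 500, warmup = 400, seed = 508)
  ll <- log_lik(fit)
  w <- waic(ll)
  l <- psis_loo(ll)
  expect_lt(abs(-2 * l$elpd_loo - w$waic), 2 * sqrt(w$se^2 + (2 * l$se)^2))
})

test_that("full diagnostics bundle is shape-consistent", {
  sim <- complete_sim(20, seed = 509)
  fit <- quiet_fit(dnt_model(build_design_matrices(sim$data)),
                   chains = 2, iter = 250, warmup = 250, seed = 510)
  dg <- diagnose_fit(fit)
  expect_equal(nrow(dg$per_variable), ncol(fit$draws))
  expect_true(all(dg$per_variable$ess > 0, na.rm = TRUE))
  expect_equal(dg$per_variable$mcse,
               dg$per_variable$sd / sqrt(dg$per_variable$ess),
               tolerance = 1e-12)
  expect_equal(nrow(dg$brier), 4)
  expect_true(all(dg$brier$brier >= 0 & dg$brier$brier <= 1))
  expect_true(is.finite(dg$loo$elpd_loo))
})

test_that("sensitivity analysis tabulates settings and is stable to repeats", {
  sim <- complete_sim(30, seed = 511)
  dm <- build_design_matrices(sim$data)
  settings <- list(a = prior_spec(), b = prior_spec(),
                   c = prior_spec(hyper_sigma_scale = 2))
  sens <- sensitivity_analysis(dm, settings, chains = 2, iter = 250,
                               warmup = 250, seed = 512)
  expect_equal(nrow(sens$metrics), 3)
  expect_equal(dim(sens$max_delta), c(3, 3))
  # identical settings under the same seed reproduce identical predictions
  expect_equal(sens$max_delta["a", "b"], 0, tolerance = 1e-12)
  expect_true(all(c("elpd_loo", "waic", "brier_dnt") %in% names(sens$metrics)))
  expect_error(sensitivity_analysis(dm, settings["a"], seed = 1),
               "at least 2")
})
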