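test_that("theta chain telescopes block contributions down the pathway", {
  expect_equal(unlist(compute_theta_chain(0, 0, 0)), c(
    theta_bdnf = 0, theta_syn = 0, theta_nnf = 0, theta_dnt = 0))
  expect_equal(unlist(compute_theta_chain(1, 1, 1)), c(
    theta_bdnf = 1, theta_syn = 2, theta_nnf = 3, theta_dnt = 6))
  expect_equal(unlist(compute_theta_chain(0.5, -1, 0.25)), c(
    theta_bdnf = 0.5, theta_syn = -0.5, theta_nnf = -0.25, theta_dnt = -0.25))
  expect_equal(plogis(unlist(compute_theta_chain(0, 0, 0))),
               rep(0.5, 4), ignore_attr = TRUE)
  expect_error(compute_theta_chain(Inf, 0, 0), "finite")

  # algebraic identity theta_dnt = 3 c1 + 2 c2 + c3 on random inputs
  set.seed(301)
  for (i in 1:20) {
    cc <- rnorm(3, sd = 2)
    th <- compute_theta_chain(cc[1], cc[2], cc[3])
    expect_equal(th$theta_dnt, 3 * cc[1] + 2 * cc[2] + cc[3],
                 tolerance = 1e-12)
  }
})

test_that("raising a compound's first block contribution raises every probability", {
  set.seed(302)
  cc <- rnorm(3)
  for (delta in c(1e-3, 0.1, 1)) {
    a <- plogis(unlist(compute_theta_chain(cc[1], cc[2], cc[3])))
    b <- plogis(unlist(compute_theta_chain(cc[1] + delta, cc[2], cc[3])))
    expect_true(all(b > a))
  }
})

test_that("model census: nine named blocks always; scalars grow with missingness", {
  sim <- complete_sim(12, seed = 303)
  m <- dnt_model(build_design_matrices(sim$data))
  cen <- count_parameters(m)
  expect_equal(cen$hyperprior_blocks, 2L)
  expect_equal(cen$coefficient_blocks, 3L)
  expect_equal(cen$likelihood_blocks, 4L)
  expect_equal(cen$total_named, 9L)
  expect_equal(cen$imputation_blocks, 0L)
  expect_equal(cen$total_scalar_parameters, 2L + 7L + 3L + 4L)

  # one missing predictor cell adds a hyper pair plus one latent value
  d2 <- sim$data
  d2$logd[3] <- NA
  cen2 <- count_parameters(dnt_model(build_design_matrices(d2)))
  expect_equal(cen2$imputation_blocks, 1L)
  expect_equal(cen2$total_scalar_parameters,
               cen$total_scalar_parameters + 3L)
  expect_equal(cen2$total_named, 9L)

  # named blocks do not depend on n
  big <- dnt_model(build_design_matrices(complete_sim(40, seed = 304)$data))
  expect_equal(count_parameters(big)$total_named, 9L)
})

test_that("model construction enforces shape and label invariants", {
  sim <- complete_sim(6, seed = 305)
  dm <- build_design_matrices(sim$data)
  dm_bad <- dm
  dm_bad$miss$syn <- dm_bad$miss$syn[, -1, drop = FALSE]
  expect_error(dnt_model(dm_bad), "shape")
  dm_bad2 <- dm
  dm_bad2$y[2, "dnt"] <- NA
  expect_error(dnt_model(dm_bad2), "adverse-outcome label")
})

test_that("joint density matches the closed-form sum on a one-compound model", {
  y <- cbind(bdnf = 1, syn = 0, nnf = 1, dnt = 1)
  dm <- tiny_design(matrix(0.3), matrix(-0.2), matrix(0.7), y)
  m <- dnt_model(dm)
  lp <- log_joint_density(
    list(mu = 0, sigma = 1,
         beta = list(bdnf = 0, syn = 0, nnf = 0)), m)
  expected <- dnorm(0, 0, 0.1, log = TRUE) +
    (log(2) + dnorm(1, 0, 1, log = TRUE)) +
    3 * dnorm(0, 0, 1, log = TRUE) +
    4 * log(0.5)
  expect_equal(lp, expected, tolerance = 1e-12)
  expect_identical(log_joint_density(
    list(mu = 0, sigma = -1, beta = list(bdnf = 0, syn = 0, nnf = 0)), m),
    -Inf)
})

test_that("duplicating a compound adds exactly one copy of its likelihood", {
  y1 <- cbind(bdnf = 1, syn = 0, nnf = 1, dnt = 1)
  d1 <- tiny_design(matrix(0.4), matrix(1.1), matrix(-0.6), y1)
  d2 <- tiny_design(matrix(c(0.4, 0.4)), matrix(c(1.1, 1.1)),
                    matrix(c(-0.6, -0.6)), rbind(y1, y1))
  params <- list(mu = 0.05, sigma = 0.8,
                 beta = list(bdnf = 0.3, syn = -0.2, nnf = 0.5))
  m1 <- dnt_model(d1)
  m2 <- dnt_model(d2)
  lp1 <- log_joint_density(params, m1)
  lp2 <- log_joint_density(params, m2)
  th <- compute_theta_chain(0.4 * 0.3, 1.1 * -0.2, -0.6 * 0.5)
  lik <- sum(unlist(y1) * unlist(th) - log1p(exp(unlist(th))))
  expect_equal(lp2 - lp1, lik, tolerance = 1e-10)
})

test_that("compiled and plain-R densities agree up to the transform Jacobian", {
  sim <- simulate_dnt_data(n_compounds = 25, seed = 306)
  m <- dnt_model(build_design_matrices(sim$data))
  cdata <- qaopdnt:::model_cpp_data(m)
  K <- qaopdnt:::cpp_model_dim(cdata)
  set.seed(307)
  for (rep in 1:5) {
    q <- rnorm(K, sd = 0.5)
    nat <- qaopdnt:::constrain_draws(matrix(q, 1), m)[1, ]
    names(nat) <- m$param_names
    mu <- nat[["mu"]]; sigma <- nat[["sigma"]]
    params <- list(
      mu = mu, sigma = sigma,
      beta = lapply(setNames(c("bdnf", "syn", "nnf"), c("bdnf", "syn", "nnf")),
                    function(b) {
                      unname(nat[grep(paste0("^beta_", b, "\\["), names(nat))])
                    }),
      impute = lapply(setNames(c("bdnf", "syn", "nnf"), c("bdnf", "syn", "nnf")),
                      function(b) {
                        if (m$n_miss[[b]] == 0) return(NULL)
                        list(mu = nat[[paste0("mu_xmiss_", b)]],
                             sigma = nat[[paste0("sigma_xmiss_", b)]],
                             values = unname(nat[grep(paste0("^xmiss_", b, "\\["),
                                                      names(nat))]))
                      }))
    lp_r <- log_joint_density(params, m)
    lp_cpp <- qaopdnt:::cpp_log_joint(cdata, q)
    # compiled density is over (log sigma, raw beta, raw cells):
    # |J| contributes log sigma per sigma, and sigma^p per non-centered block
    jac <- log(sigma) + sum(m$p) * log(sigma)
    for (b in c("bdnf", "syn", "nnf")) {
      if (m$n_miss[[b]] > 0) {
        sg <- nat[[paste0("sigma_xmiss_", b)]]
        jac <- jac + log(sg) + m$n_miss[[b]] * log(sg)
      }
    }
    expect_equal(lp_cpp, lp_r + jac, tolerance = 1e-8)
  }
})

test_that("compiled gradient matches numerical differentiation", {
  sim <- simulate_dnt_data(n_compounds = 10, seed = 308)
  m <- dnt_model(build_design_matrices(sim$data))
  cdata <- qaopdnt:::model_cpp_data(m)
  K <- qaopdnt:::cpp_model_dim(cdata)
  set.seed(309)
  q <- rnorm(K, sd = 0.4)
  lg <- qaopdnt:::cpp_log_joint_grad(cdata, q)
  h <- 1e-6
  num <- vapply(seq_len(K), function(i) {
    qp <- q; qp[i] <- qp[i] + h
    qm <- q; qm[i] <- qm[i] - h
    (qaopdnt:::cpp_log_joint(cdata, qp) -
       qaopdnt:::cpp_log_joint(cdata, qm)) / (2 * h)
  }, numeric(1))
  expect_equal(as.numeric(lg$grad), num, tolerance = 1e-5)
})
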