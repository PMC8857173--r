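#' Fit the hierarchical qAOP model by NUTS
#'
#' Samples the posterior with the package's No-U-Turn sampler (dynamic
#' Hamiltonian Monte Carlo with multiplicative step-size adaptation and
#' diagonal metric estimation during warmup).  Coefficients and latent
#' imputed cells are sampled non-centered and reported on the natural
#' scale.  Divergent transitions after warmup are recorded per chain;
#' convergence is never silently assumed - run [tidy()] / [glance()] or
#' the diagnostics functions on the result.
#'
#' @param model A `dnt_model`.
#' @param chains Number of MCMC chains (run sequentially).
#' @param iter Post-warmup draws kept per chain.
#' @param warmup Warmup (adaptation) iterations per chain, discarded.
#' @param target_accept Target mean acceptance statistic for step-size
#'   adaptation.
#' @param max_treedepth Maximum NUTS tree depth.
#' @param seed Integer seed (mandatory); fixed seed implies reproducible
#'   draws.
#' @return An object of class `dnt_fit`: posterior draws for every free
#'   parameter on the natural scale (`draws`, iterations stacked over
#'   chains, one named column per scalar), `chain` ids, per-chain
#'   divergence counts and sampler metadata, and the model.
#' @export
#' @examples
#' sim <- simulate_dnt_data(n_compounds = 30, missingness = NULL, seed = 7)
#' dm <- build_design_matrices(sim$data)
#' fit <- fit_dnt(dnt_model(dm), chains = 2, iter = 200, warmup = 200, seed = 7)
#' glance(fit)
fit_dnt <- function(model, chains = 4, iter = 1000, warmup = 1000,
                    target_accept = 0.9, max_treedepth = 10, seed) {
  stopifnot(inherits(model, "dnt_model"))
  if (missing(seed)) abort("a seed is required for reproducible sampling")
  stopifnot(chains >= 1, iter >= 1, warmup >= 20)
  cdata <- model_cpp_data(model)
  dim_cpp <- cpp_model_dim(cdata)
  if (dim_cpp != length(model$param_names)) {
    abort("internal layout mismatch between model and sampler")
  }

  set.seed(seed)
  res <- vector("list", chains)
  for (ch in seq_len(chains)) {
    res[[ch]] <- cpp_nuts_chain(cdata, as.integer(warmup), as.integer(iter),
                                target_accept, as.integer(max_treedepth))
    if (!all(is.finite(res[[ch]]$draws))) {
      abort(paste0("sampler produced non-finite draws in chain ", ch))
    }
  }

  draws_un <- do.call(rbind, lapply(res, `[[`, "draws"))
  chain_id <- rep(seq_len(chains), each = iter)
  draws <- constrain_draws(draws_un, model)
  colnames(draws) <- model$param_names

  structure(
    list(
      model = model,
      draws = draws,
      chain = chain_id,
      iter = iter, warmup = warmup, chains = chains,
      target_accept = target_accept, max_treedepth = max_treedepth,
      seed = seed,
      divergences = vapply(res, `[[`, numeric(1), "divergences"),
      divergences_warmup = vapply(res, `[[`, numeric(1), "divergences_warmup"),
      treedepth = unlist(lapply(res, `[[`, "treedepth")),
      stepsize = vapply(res, `[[`, numeric(1), "stepsize"),
      mean_accept = vapply(res, `[[`, numeric(1), "mean_accept")
    ),
    class = "dnt_fit"
  )
}

# unconstrained sampler draws -> natural scale (mu, sigma, beta, imputation)
constrain_draws <- function(draws_un, model) {
  out <- draws_un
  pos <- 0L
  fix <- model$fix
  if (is.null(fix$mu)) {
    pos <- pos + 1L
    mu <- draws_un[, pos]
  } else {
    mu <- rep(fix$mu, nrow(draws_un))
  }
  if (is.null(fix$sigma)) {
    pos <- pos + 1L
    sigma <- exp(draws_un[, pos])
    out[, pos] <- sigma
  } else {
    sigma <- rep(fix$sigma, nrow(draws_un))
  }
  for (b in qaop_blocks) {
    pb <- model$p[[b]]
    if (pb > 0) {
      cols <- pos + seq_len(pb)
      out[, cols] <- mu + sigma * draws_un[, cols, drop = FALSE]
      pos <- pos + pb
    }
  }
  for (b in qaop_blocks) {
    mb <- model$n_miss[[b]]
    if (mb > 0) {
      mu_m <- draws_un[, pos + 1L]
      sg_m <- exp(draws_un[, pos + 2L])
      out[, pos + 2L] <- sg_m
      cells <- pos + 2L + seq_len(mb)
      out[, cells] <- mu_m + sg_m * draws_un[, cells, drop = FALSE]
      pos <- pos + 2L + mb
    }
  }
  out
}

#' @export
print.dnt_fit <- function(x, ...) {
  cat("<dnt_fit> ", x$chains, " chains x ", x$iter, " draws (warmup ",
      x$warmup, "), seed ", x$seed, "\n", sep = "")
  cat("  divergences:", sum(x$divergences),
      " | mean accept:", round(mean(x$mean_accept), 3),
      " | stepsize:", paste(signif(x$stepsize, 3), collapse = ", "), "\n")
  print(head(tidy(x), 8))
  invisible(x)
}

# draws of one variable as an iterations x chains matrix
draws_matrix <- function(fit, name) {
  matrix(fit$draws[, name], ncol = fit$chains)
}

#' Per-draw chained linear predictors and event probabilities
#'
#' Reconstructs, for every posterior draw, the per-compound linear
#' predictors along the pathway chain (with latent imputed predictor
#' cells substituted draw-wise) and maps them through the inverse-logit
#' link.
#'
#' @param fit A `dnt_fit`.
#' @return A list with `theta` and `prob`, each a draws x compounds x
#'   node array (nodes `bdnf`, `syn`, `nnf`, `dnt`).
#' @export
posterior_theta <- function(fit) {
  stopifnot(inherits(fit, "dnt_fit"))
  model <- fit$model
  d <- model$design
  D <- nrow(fit$draws)
  n <- d$n
  cc <- vector("list", 3)
  for (ki in seq_along(qaop_blocks)) {
    b <- qaop_blocks[ki]
    pb <- model$p[[b]]
    if (pb == 0 || n == 0) {
      cc[[ki]] <- matrix(0, D, n)
      next
    }
    bcols <- paste0("beta_", b, "[", colnames(d$x[[b]]), "]")
    B <- fit$draws[, bcols, drop = FALSE]
    Ck <- B %*% t(d$x[[b]])        # placeholders contribute 0
    mb <- model$n_miss[[b]]
    if (mb > 0) {
      idx <- model$miss_idx[[b]]
      cell_names <- sprintf("xmiss_%s[%d,%s]", b, idx[, 1] + 1,
                            colnames(d$x[[b]])[idx[, 2] + 1])
      for (c in seq_len(mb)) {
        i <- idx[c, 1] + 1L
        j <- idx[c, 2] + 1L
        Ck[, i] <- Ck[, i] + B[, j] * fit$draws[, cell_names[c]]
      }
    }
    cc[[ki]] <- Ck
  }
  theta <- array(0, dim = c(D, n, 4), dimnames = list(NULL, NULL, qaop_nodes))
  theta[, , 1] <- cc[[1]]
  theta[, , 2] <- cc[[2]] + theta[, , 1]
  theta[, , 3] <- cc[[3]] + theta[, , 2]
  theta[, , 4] <- theta[, , 1] + theta[, , 2] + theta[, , 3]
  list(theta = theta, prob = inv_link(theta))
}

#' Posterior-predictive draws of the binary labels
#'
#' Draws labels from Bernoulli(inverse-logit(theta)) per posterior draw.
#' For compounds whose label was observed this is the ordinary posterior
#' predictive; for missing labels it is the Bayesian imputation
#' distribution (missing outcomes are imputed from the posterior
#' predictive).
#'
#' @param fit A `dnt_fit`.
#' @param seed Integer seed for the Bernoulli draws.
#' @return A draws x compounds x node integer array.
#' @export
posterior_predict_labels <- function(fit, seed) {
  if (missing(seed)) abort("a seed is required")
  pp <- posterior_theta(fit)$prob
  set.seed(seed)
  y <- array(rbinom(length(pp), 1, pp), dim = dim(pp),
             dimnames = dimnames(pp))
  y
}

#' Pointwise log-likelihood matrix
#'
#' Per-compound log-likelihood of the observed labels at every posterior
#' draw (summed over the compound's observed nodes), the input to
#' [waic()] and [psis_loo()].
#'
#' @param fit A `dnt_fit`.
#' @param node One of `"all"` (sum over observed nodes per compound) or a
#'   single node name for a per-node matrix (unobserved labels give 0).
#' @return A draws x compounds matrix.
#' @export
log_lik <- function(fit, node = "all") {
  th <- posterior_theta(fit)$theta
  y <- fit$model$design$y
  D <- dim(th)[1]
  n <- dim(th)[2]
  ll <- matrix(0, D, n)
  nodes <- if (identical(node, "all")) qaop_nodes else match.arg(node, qaop_nodes)
  for (k in nodes) {
    obs <- which(!is.na(y[, k]))
    for (i in obs) {
      t_ik <- th[, i, k]
      ll[, i] <- ll[, i] + y[i, k] * t_ik -
        ifelse(t_ik > 35, t_ik, ifelse(t_ik < -35, exp(t_ik), log1p(exp(t_ik))))
    }
  }
  ll
}

#' @rdname fit_dnt
#' @param x,object A `dnt_fit`.
#' @param level Credible-interval level for `tidy()`.
#' @param ... Unused.
#' @export
tidy.dnt_fit <- function(x, level = 0.95, ...) {
  nm <- colnames(x$draws)
  purrr::map_dfr(nm, function(v) {
    dv <- x$draws[, v]
    ci <- credible_interval(dv, level = level)
    dm <- draws_matrix(x, v)
    tibble::tibble(
      term = v,
      estimate = mean(dv),
      std.error = sd(dv),
      conf.low = ci[["lo"]],
      conf.high = ci[["hi"]],
      rhat = rhat(dm),
      ess = ess_and_mcse(dm)$ess
    )
  })
}

#' @rdname fit_dnt
#' @export
glance.dnt_fit <- function(x, ...) {
  td <- tidy(x)
  tibble::tibble(
    n = x$model$design$n,
    parameters = ncol(x$draws),
    chains = x$chains,
    draws = nrow(x$draws),
    divergences = sum(x$divergences),
    max_rhat = max(td$rhat, na.rm = TRUE),
    min_ess = min(td$ess, na.rm = TRUE),
    mean_accept = mean(x$mean_accept)
  )
}
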