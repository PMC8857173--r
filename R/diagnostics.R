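split_chains <- function(x) {
  n <- nrow(x)
  half <- floor(n / 2)
  cbind(x[seq_len(half), , drop = FALSE],
        x[(n - half + 1):n, , drop = FALSE])
}

rank_normalize <- function(x) {
  r <- rank(c(x), ties.method = "average")
  z <- qnorm((r - 3 / 8) / (length(r) + 1 / 4))
  matrix(z, nrow = nrow(x))
}

# classic split-Rhat on an iterations x chains matrix (already transformed)
rhat_basic <- function(x) {
  m <- ncol(x)
  n <- nrow(x)
  means <- colMeans(x)
  vars <- apply(x, 2, var)
  w <- mean(vars)
  b <- n * var(means)
  if (!is.finite(w) || w <= 0) return(NA_real_)
  sqrt(((n - 1) / n * w + b / n) / w)
}

#' Rank-normalized split potential-scale-reduction statistic
#'
#' Measures how similar the chains are (within- versus between-chain
#' variance), approaching 1 as they mix.  Chains are split in half,
#' draws are rank-normalized, and the statistic is the larger of the
#' bulk value and the value computed on folded draws (absolute
#' deviations from the median), making it sensitive to both location and
#' scale disagreement.  Constant (zero-variance) input is undefined and
#' reported as `NA`, never as 1.
#'
#' @param x Numeric matrix of draws, iterations in rows, chains in
#'   columns (at least 2 chains of at least 4 draws).
#' @return A single number (>= ~1), or `NA` if undefined.
#' @export
rhat <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2) abort("rhat requires at least 2 chains")
  if (nrow(x) < 4) abort("rhat requires at least 4 draws per chain")
  if (sd(c(x)) == 0) return(NA_real_)
  xs <- split_chains(x)
  bulk <- rhat_basic(rank_normalize(xs))
  folded <- rhat_basic(rank_normalize(abs(xs - median(xs))))
  max(bulk, folded)
}

#' Effective sample size and Monte Carlo standard error
#'
#' Autocorrelation-based effective sample size of the chain mean (Geyer
#' initial-monotone-sequence estimator over split chains, combining
#' within-chain autocovariances with the between-chain variance), and
#' the Monte Carlo standard error of the posterior mean, defined as the
#' posterior standard deviation divided by the square root of the
#' effective sample size.
#'
#' @param x Numeric matrix of draws, iterations x chains (>= 2 chains,
#'   >= 4 draws each).
#' @return A list with elements `ess` and `mcse`.
#' @export
ess_and_mcse <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2) abort("ess requires at least 2 chains")
  if (nrow(x) < 4) abort("ess requires at least 4 draws per chain")
  if (sd(c(x)) == 0) return(list(ess = NA_real_, mcse = NA_real_))
  xs <- split_chains(x)
  n <- nrow(xs)
  m <- ncol(xs)

  chain_vars <- apply(xs, 2, var)
  w <- mean(chain_vars)
  var_plus <- (n - 1) / n * w + var(colMeans(xs))

  # mean autocovariance across chains (biased, 1/n normalization)
  max_lag <- n - 1
  acov <- matrix(0, max_lag + 1, m)
  for (j in seq_len(m)) {
    a <- acf(xs[, j], lag.max = max_lag, type = "covariance",
             plot = FALSE, demean = TRUE)$acf[, 1, 1]
    acov[, j] <- a
  }
  mean_acov <- rowMeans(acov)

  rho <- 1 - (w - mean_acov) / var_plus   # rho[1] is lag 0
  # Geyer: sum consecutive pairs while positive, enforce monotonicity
  tau <- 0
  prev_pair <- Inf
  t <- 1
  while (t + 1 <= length(rho)) {
    pair <- rho[t] + rho[t + 1]
    if (pair < 0) break
    pair <- min(pair, prev_pair)
    prev_pair <- pair
    tau <- tau + pair
    t <- t + 2
  }
  tau <- max(2 * tau - rho[1], 1 / log10(n * m + 1))   # tau >= ~0 guard
  ess <- n * m / tau
  mcse <- sd(c(x)) / sqrt(ess)
  list(ess = ess, mcse = mcse)
}

#' Brier score
#'
#' Mean squared difference between predicted probabilities and actual
#' binary outcomes; lies between zero (perfect) and one (maximally
#' wrong).
#'
#' @param predicted Numeric vector of probabilities in `[0, 1]`.
#' @param actual Binary vector (0/1) of the same length.
#' @return A single number in `[0, 1]`.
#' @export
#' @examples
#' brier_score(c(0.8, 0.4, 0.1), c(1, 0, 0))  # 0.07
brier_score <- function(predicted, actual) {
  if (length(predicted) != length(actual)) {
    abort("predicted and actual must have equal length")
  }
  if (any(predicted < 0 | predicted > 1)) {
    abort("predicted probabilities must lie in [0, 1]")
  }
  if (!all(actual %in% c(0, 1))) abort("actual outcomes must be 0 or 1")
  mean((predicted - actual)^2)
}

#' Widely applicable information criterion
#'
#' Computed pointwise from a log-likelihood matrix: the log pointwise
#' predictive density minus the effective-parameter penalty (the
#' per-point posterior variance of the log-likelihood), reported on the
#' deviance scale (-2 x elpd) with a standard error; the elpd scale is
#' also returned.
#'
#' @param pointwise_loglik Draws x points matrix of log-likelihood
#'   values (all finite).
#' @return A list with `waic`, `se`, `elpd_waic`, `p_waic`, and a
#'   `pointwise` tibble.
#' @export
waic <- function(pointwise_loglik) {
  ll <- as.matrix(pointwise_loglik)
  if (!all(is.finite(ll))) abort("log-likelihood draws must be finite")
  S <- nrow(ll)
  lppd_i <- apply(ll, 2, function(v) matrixStats_logSumExp(v) - log(S))
  p_i <- apply(ll, 2, var)
  elpd_i <- lppd_i - p_i
  waic_i <- -2 * elpd_i
  n <- ncol(ll)
  list(
    waic = sum(waic_i),
    se = sqrt(n * var(waic_i)),
    elpd_waic = sum(elpd_i),
    p_waic = sum(p_i),
    pointwise = tibble::tibble(lppd = lppd_i, p_waic = p_i, elpd = elpd_i,
                               waic = waic_i)
  )
}

matrixStats_logSumExp <- function(v) {
  m <- max(v)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(v - m)))
}

# Zhang & Stephens (2009) profile-likelihood fit of the generalized
# Pareto shape k to tail exceedances (location 0).
gpd_fit_k <- function(x) {
  x <- sort(x)
  n <- length(x)
  if (n < 5 || sd(x) == 0) return(NA_real_)
  prior_bs <- 3
  m <- 30 + floor(sqrt(n))
  bs <- 1 / x[n] + (1 - sqrt(m / (seq_len(m) - 0.5))) / prior_bs / x[ceiling(n / 4 + 0.5)]
  profile <- vapply(bs, function(b) {
    k <- -mean(log1p(-b * x))
    n * (log(b / k) + k - 1)
  }, numeric(1))
  w <- exp(profile - matrixStats_logSumExp(profile))
  b_hat <- sum(bs * w)
  -mean(log1p(-b_hat * x))
}

#' Pareto-smoothed importance-sampling leave-one-out cross-validation
#'
#' Estimates pointwise out-of-sample predictive density by importance
#' sampling, stabilizing each point's weights by fitting a generalized
#' Pareto distribution to the upper tail of the importance ratios and
#' replacing the tail by its smoothed order statistics (truncated at the
#' raw maximum).  Points with shape diagnostic k > 0.7 are flagged as
#' unreliable.
#'
#' @param pointwise_loglik Draws x points matrix of log-likelihood
#'   values (all finite; at least ~100 draws for tail fitting).
#' @return A list with `elpd_loo`, `se`, `looic` (-2 x elpd), and a
#'   `pointwise` tibble containing `elpd` and `pareto_k` (k is `NA` for
#'   a degenerate zero-variance tail, where smoothing is a no-op).
#' @export
psis_loo <- function(pointwise_loglik) {
  ll <- as.matrix(pointwise_loglik)
  if (!all(is.finite(ll))) abort("log-likelihood draws must be finite")
  S <- nrow(ll)
  n <- ncol(ll)
  elpd_i <- numeric(n)
  k_i <- numeric(n)
  M <- ceiling(min(0.2 * S, 3 * sqrt(S)))
  for (i in seq_len(n)) {
    lw <- -ll[, i]
    lw <- lw - max(lw)
    ord <- order(lw, decreasing = TRUE)
    tail_idx <- ord[seq_len(M)]
    cutoff <- exp(lw[ord[M + 1]])
    exceed <- exp(lw[tail_idx]) - cutoff
    k <- gpd_fit_k(exceed)
    if (is.finite(k)) {
      # smooth the tail with expected order statistics of the fitted GPD
      sigma_hat <- if (abs(k) < 1e-12) mean(exceed) else {
        # from k and mean relation of Zhang-Stephens parameterization
        k / gpd_b_hat(exceed)
      }
      p <- (seq_len(M) - 0.5) / M
      qs <- if (abs(k) < 1e-12) -sigma_hat * log(1 - p) else
        sigma_hat / k * ((1 - p)^(-k) - 1)
      smoothed <- log(cutoff + sort(qs))
      smoothed <- pmin(smoothed, 0)           # truncate at raw max (= 0)
      lw[tail_idx[order(lw[tail_idx])]] <- sort(smoothed)
    }
    k_i[i] <- k
    lw <- lw - matrixStats_logSumExp(lw)
    elpd_i[i] <- matrixStats_logSumExp(lw + ll[, i])
  }
  list(
    elpd_loo = sum(elpd_i),
    se = sqrt(n * var(elpd_i)),
    looic = -2 * sum(elpd_i),
    pointwise = tibble::tibble(elpd = elpd_i, pareto_k = k_i),
    n_bad_k = sum(is.finite(k_i) & k_i > 0.7)
  )
}

gpd_b_hat <- function(x) {
  x <- sort(x)
  n <- length(x)
  prior_bs <- 3
  m <- 30 + floor(sqrt(n))
  bs <- 1 / x[n] + (1 - sqrt(m / (seq_len(m) - 0.5))) / prior_bs / x[ceiling(n / 4 + 0.5)]
  profile <- vapply(bs, function(b) {
    k <- -mean(log1p(-b * x))
    n * (log(b / k) + k - 1)
  }, numeric(1))
  w <- exp(profile - matrixStats_logSumExp(profile))
  sum(bs * w)
}

#' Convergence and fit diagnostics of a posterior sample
#'
#' Per-variable rank-normalized split R-hat, effective sample size and
#' Monte Carlo standard error, total divergences, information criteria
#' (PSIS-LOO and WAIC over per-compound pointwise log-likelihoods) and
#' the Brier score of the posterior-mean probabilities against observed
#' labels per node.
#'
#' @param fit A `dnt_fit`.
#' @return An object of class `dnt_diagnostics`: list with tibbles
#'   `per_variable` and `brier`, scalars `divergences`, and the `loo` and
#'   `waic` lists.
#' @export
diagnose_fit <- function(fit) {
  stopifnot(inherits(fit, "dnt_fit"))
  per_var <- purrr::map_dfr(colnames(fit$draws), function(v) {
    dm <- draws_matrix(fit, v)
    em <- ess_and_mcse(dm)
    tibble::tibble(variable = v, rhat = rhat(dm), ess = em$ess,
                   mcse = em$mcse, sd = sd(c(dm)))
  })
  ll <- log_lik(fit)
  prob <- posterior_theta(fit)$prob
  pm <- apply(prob, c(2, 3), mean)
  y <- fit$model$design$y
  brier <- purrr::map_dfr(qaop_nodes, function(k) {
    obs <- !is.na(y[, k])
    tibble::tibble(
      node = k,
      n_evaluable = sum(obs),
      brier = if (any(obs)) brier_score(pm[obs, k], y[obs, k]) else NA_real_)
  })
  structure(
    list(per_variable = per_var,
         brier = brier,
         divergences = sum(fit$divergences),
         loo = psis_loo(ll),
         waic = waic(ll)),
    class = "dnt_diagnostics"
  )
}

#' @export
print.dnt_diagnostics <- function(x, ...) {
  cat("<dnt_diagnostics>\n")
  cat("  divergences:", x$divergences,
      " | max rhat:", signif(max(x$per_variable$rhat, na.rm = TRUE), 4),
      " | min ess:", signif(min(x$per_variable$ess, na.rm = TRUE), 4), "\n")
  cat("  elpd_loo:", signif(x$loo$elpd_loo, 5), "(se", signif(x$loo$se, 3),
      ") | waic:", signif(x$waic$waic, 5), "\n")
  cat("  Brier per node:\n")
  print(x$brier)
  invisible(x)
}

#' Hyperprior sensitivity analysis
#'
#' Refits the model under alternative weakly-informative hyperprior
#' settings and tabulates the three comparison metrics (PSIS-LOO, WAIC,
#' per-node Brier score) together with per-compound posterior-mean DNT
#' probabilities and their pairwise maximum absolute differences.  A
#' failed refit is recorded and does not abort the remaining settings.
#'
#' @param design A `dnt_design`.
#' @param settings Named list of [prior_spec()] objects (>= 2).
#' @param chains,iter,warmup,target_accept,seed Passed to [fit_dnt()]
#'   (the same seed is used for every setting).
#' @return An object of class `dnt_sensitivity`: list with `metrics`
#'   (tibble: setting, elpd_loo, waic, brier per node), `predictive`
#'   (tibble: setting, compound, mean DNT probability), `max_delta`
#'   (pairwise matrix of max absolute predictive-mean differences) and
#'   `errors`.
#' @export
sensitivity_analysis <- function(design, settings, chains = 2, iter = 500,
                                 warmup = 500, target_accept = 0.9, seed) {
  if (missing(seed)) abort("a seed is required")
  if (length(settings) < 2) abort("at least 2 hyperprior settings required")
  if (is.null(names(settings)) || any(names(settings) == "")) {
    names(settings) <- paste0("setting_", seq_along(settings))
  }
  metrics <- list()
  predictive <- list()
  errors <- list()
  means <- list()
  for (nm in names(settings)) {
    res <- tryCatch({
      fit <- fit_dnt(dnt_model(design, priors = settings[[nm]]),
                     chains = chains, iter = iter, warmup = warmup,
                     target_accept = target_accept, seed = seed)
      dg <- diagnose_fit(fit)
      pm <- apply(posterior_theta(fit)$prob, c(2, 3), mean)
      list(dg = dg, pm = pm)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors[[nm]] <- conditionMessage(res)
      next
    }
    bs <- setNames(res$dg$brier$brier, paste0("brier_", res$dg$brier$node))
    metrics[[nm]] <- tibble::tibble(
      setting = nm,
      elpd_loo = res$dg$loo$elpd_loo,
      waic = res$dg$waic$waic,
      !!!as.list(bs))
    means[[nm]] <- res$pm[, "dnt"]
    predictive[[nm]] <- tibble::tibble(
      setting = nm,
      compound = design$compound,
      mean_prob_dnt = res$pm[, "dnt"])
  }
  ok <- names(means)
  delta <- matrix(NA_real_, length(ok), length(ok), dimnames = list(ok, ok))
  for (a in ok) for (b in ok) {
    delta[a, b] <- max(abs(means[[a]] - means[[b]]))
  }
  structure(
    list(metrics = dplyr::bind_rows(metrics),
         predictive = dplyr::bind_rows(predictive),
         max_delta = delta,
         errors = errors),
    class = "dnt_sensitivity"
  )
}

#' @export
print.dnt_sensitivity <- function(x, ...) {
  cat("<dnt_sensitivity> ", nrow(x$metrics), " settings\n", sep = "")
  print(x$metrics)
  cat("  pairwise max |delta predictive mean| (DNT):\n")
  print(signif(x$max_delta, 3))
  if (length(x$errors) > 0) {
    cat("  failed settings:", paste(names(x$errors), collapse = ", "), "\n")
  }
  invisible(x)
}
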