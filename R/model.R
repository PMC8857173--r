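#' Chained linear predictors along the adverse outcome pathway
#'
#' Propagates per-compound block contributions `c_k = x_k' beta_k` along
#' the fixed causal chain BDNF -> synaptogenesis -> neural network
#' formation -> DNT: each key event's linear predictor adds its own block
#' contribution to the upstream predictor, and the adverse-outcome
#' predictor is the sum of the three key-event predictors (equivalently
#' `3*c1 + 2*c2 + c3`).  Pure and vectorized over compounds.
#'
#' @param c_bdnf,c_syn,c_nnf Numeric vectors (equal length) of per-
#'   compound block contributions.
#' @return A tibble with columns `theta_bdnf`, `theta_syn`, `theta_nnf`,
#'   `theta_dnt`.
#' @export
#' @examples
#' compute_theta_chain(1, 1, 1)   # 1, 2, 3, 6
compute_theta_chain <- function(c_bdnf, c_syn, c_nnf) {
  stopifnot(length(c_syn) == length(c_bdnf),
            length(c_nnf) == length(c_bdnf))
  if (!all(is.finite(c(c_bdnf, c_syn, c_nnf)))) {
    abort("block contributions must be finite")
  }
  theta_bdnf <- c_bdnf
  theta_syn <- c_syn + theta_bdnf
  theta_nnf <- c_nnf + theta_syn
  tibble::tibble(
    theta_bdnf = theta_bdnf,
    theta_syn = theta_syn,
    theta_nnf = theta_nnf,
    theta_dnt = theta_bdnf + theta_syn + theta_nnf
  )
}

#' Weakly-informative prior specification
#'
#' Hyperpriors of the partially pooled model: the common coefficient mean
#' is Normal(0, 0.1) and the common coefficient scale HalfNormal(1) (the
#' second Normal parameter is a standard deviation throughout).  The
#' imputation model for missing predictor cells uses an identical pair
#' per design block.  All four settings are overridable, e.g. for the
#' hyperprior sensitivity analysis.
#'
#' @param hyper_mu_loc,hyper_mu_scale Location and scale of the normal
#'   hyperprior on the common coefficient mean.
#' @param hyper_sigma_scale Scale of the half-normal hyperprior on the
#'   common coefficient standard deviation.
#' @param impute_mu_loc,impute_mu_scale,impute_sigma_scale The analogous
#'   settings of the per-block missing-predictor imputation model.
#' @return An object of class `prior_spec`.
#' @export
prior_spec <- function(hyper_mu_loc = 0, hyper_mu_scale = 0.1,
                       hyper_sigma_scale = 1,
                       impute_mu_loc = 0, impute_mu_scale = 0.1,
                       impute_sigma_scale = 1) {
  if (hyper_mu_scale <= 0 || hyper_sigma_scale <= 0 ||
      impute_mu_scale <= 0 || impute_sigma_scale <= 0) {
    abort("prior scales must be strictly positive")
  }
  if (hyper_mu_loc != 0 || impute_mu_loc != 0) {
    # kept for interface compatibility; the density uses location 0
    abort("non-zero prior locations are not supported")
  }
  structure(
    list(hyper_mu_scale = hyper_mu_scale,
         hyper_sigma_scale = hyper_sigma_scale,
         impute_mu_scale = impute_mu_scale,
         impute_sigma_scale = impute_sigma_scale),
    class = "prior_spec"
  )
}

#' @export
print.prior_spec <- function(x, ...) {
  cat("<prior_spec> mu ~ Normal(0, ", x$hyper_mu_scale, "), sigma ~ HalfNormal(",
      x$hyper_sigma_scale, ")\n  imputation: mu_xmiss ~ Normal(0, ",
      x$impute_mu_scale, "), sigma_xmiss ~ HalfNormal(", x$impute_sigma_scale,
      ")\n", sep = "")
  invisible(x)
}

# zero-based (row, col) index matrix of masked cells for one block
miss_index <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (length(idx) == 0) return(matrix(0L, nrow = 0, ncol = 2))
  storage.mode(idx) <- "integer"
  unname(idx - 1L)
}

#' Build the hierarchical qAOP model
#'
#' Assembles the single nested, partially pooled model over a set of
#' design matrices: two hyperpriors (common coefficient mean and scale),
#' one coefficient block per key event with every entry shrunk towards
#' the hyperpriors, one imputation block (hyperparameter pair plus one
#' latent value per masked cell) for each design block containing missing
#' predictors, and a Bernoulli likelihood with inverse-logit link on each
#' of the four outcome vectors.  Observed labels condition the fit;
#' missing labels are marginalized out and imputed from the posterior
#' predictive after sampling.
#'
#' @param design A `dnt_design` from [build_design_matrices()].
#' @param priors A [prior_spec()].
#' @param fix Optional named numeric vector fixing hyperparameters
#'   (`mu` and/or `sigma`) at constants instead of sampling them; used
#'   for conditional, reduced-parameter analyses.
#' @return An object of class `dnt_model` carrying the design, priors and
#'   parameter layout.
#' @export
dnt_model <- function(design, priors = prior_spec(), fix = NULL) {
  stopifnot(inherits(design, "dnt_design"))
  stopifnot(inherits(priors, "prior_spec"))
  for (b in qaop_blocks) {
    if (!identical(dim(design$x[[b]]), dim(design$miss[[b]]))) {
      abort(paste0("design and mask shapes differ in block '", b, "'"))
    }
  }
  if (nrow(design$y) != design$n) abort("outcome matrix shape mismatch")
  if (anyNA(design$y[, "dnt"])) {
    abort("the adverse-outcome label must be observed for every compound")
  }
  fix_mu <- !is.null(fix) && "mu" %in% names(fix)
  fix_sigma <- !is.null(fix) && "sigma" %in% names(fix)
  if (fix_sigma && fix[["sigma"]] <= 0) abort("fixed sigma must be positive")

  p <- vapply(design$x, ncol, integer(1))
  miss_idx <- lapply(design$miss, miss_index)
  m <- vapply(miss_idx, nrow, integer(1))

  # free-scalar layout on the unconstrained scale, mirroring the sampler
  nm <- character(0)
  if (!fix_mu) nm <- c(nm, "mu")
  if (!fix_sigma) nm <- c(nm, "sigma")
  for (b in qaop_blocks) {
    if (p[[b]] > 0) {
      nm <- c(nm, paste0("beta_", b, "[", colnames(design$x[[b]]), "]"))
    }
  }
  for (b in qaop_blocks) {
    if (m[[b]] > 0) {
      nm <- c(nm, paste0("mu_xmiss_", b), paste0("sigma_xmiss_", b),
              sprintf("xmiss_%s[%d,%s]", b, miss_idx[[b]][, 1] + 1,
                      colnames(design$x[[b]])[miss_idx[[b]][, 2] + 1]))
    }
  }

  structure(
    list(design = design, priors = priors,
         fix = list(mu = if (fix_mu) fix[["mu"]] else NULL,
                    sigma = if (fix_sigma) fix[["sigma"]] else NULL),
         p = p, miss_idx = miss_idx, n_miss = m,
         param_names = nm, link = .qaop_link),
    class = "dnt_model"
  )
}

# data list handed to the compiled log-density / sampler
model_cpp_data <- function(model) {
  d <- model$design
  y <- d$y
  yobs <- matrix(as.integer(!is.na(y)), nrow = nrow(y))
  y[is.na(y)] <- 0
  list(
    x = unname(lapply(d$x, function(x) `dimnames<-`(x, NULL))),
    miss = unname(model$miss_idx),
    y = unname(y),
    yobs = yobs,
    s_mu = model$priors$hyper_mu_scale,
    s_sig = model$priors$hyper_sigma_scale,
    s_mu_imp = model$priors$impute_mu_scale,
    s_sig_imp = model$priors$impute_sigma_scale,
    fix_mu = !is.null(model$fix$mu),
    fix_sigma = !is.null(model$fix$sigma),
    mu_value = if (is.null(model$fix$mu)) 0 else model$fix$mu,
    sigma_value = if (is.null(model$fix$sigma)) 1 else model$fix$sigma
  )
}

#' @export
print.dnt_model <- function(x, ...) {
  cen <- count_parameters(x)
  cat("<dnt_model> nested partial-pooling hierarchical model\n")
  cat("  ", x$design$n, " compounds; block dims (",
      paste(x$p, collapse = ", "), "); masked predictor cells (",
      paste(x$n_miss, collapse = ", "), ")\n", sep = "")
  cat("  named blocks: ", cen$total_named, " (", cen$hyperprior_blocks,
      " hyperpriors + ", cen$coefficient_blocks, " coefficient blocks + ",
      cen$likelihood_blocks, " likelihoods); imputation blocks: ",
      cen$imputation_blocks, "\n", sep = "")
  cat("  free scalar parameters:", cen$total_scalar_parameters, "\n")
  invisible(x)
}

#' Census of model blocks and scalar parameters
#'
#' Counts the model's building blocks by role: the two hyperpriors, the
#' three coefficient blocks (one per key event), and the four Bernoulli
#' likelihood blocks make nine named blocks for any complete-data
#' dataset, regardless of the number of compounds.  Imputation blocks
#' (one hyperparameter pair per design block with masked cells) are
#' counted separately, and the free-scalar total counts every sampled
#' scalar including latent imputed cells.
#'
#' @param model A `dnt_model`.
#' @return A one-row tibble with columns `hyperprior_blocks`,
#'   `coefficient_blocks`, `likelihood_blocks`, `imputation_blocks`,
#'   `total_named`, `total_scalar_parameters`.
#' @export
count_parameters <- function(model) {
  stopifnot(inherits(model, "dnt_model"))
  hyper <- 2L
  coefb <- 3L
  lik <- 4L
  impb <- sum(model$n_miss > 0)
  free_hyper <- sum(c(is.null(model$fix$mu), is.null(model$fix$sigma)))
  n_scalar <- free_hyper + sum(model$p) + sum(ifelse(model$n_miss > 0,
                                                    2L + model$n_miss, 0L))
  tibble::tibble(
    hyperprior_blocks = hyper,
    coefficient_blocks = coefb,
    likelihood_blocks = lik,
    imputation_blocks = as.integer(impb),
    total_named = hyper + coefb + lik,
    total_scalar_parameters = as.integer(n_scalar)
  )
}

#' Joint log-density of a full parameter assignment
#'
#' Evaluates, in plain R and on the natural scale, the sum of all prior
#' and observed-label likelihood terms of the hierarchical model: the
#' normal and half-normal hyperpriors, one normal prior per coefficient
#' shrunk to (mu, sigma), the per-block imputation hyperpriors and
#' latent-cell priors, and the Bernoulli(inverse-logit(theta))
#' likelihood of every observed label.  Returns `-Inf` for any
#' non-positive scale.  This is the reference density used by the
#' grid-integration oracles; the compiled sampler implements the same
#' density (up to the unconstraining transform) independently.
#'
#' @param params Named list: `mu`, `sigma`, `beta` (named list of
#'   vectors per block), and, per design block with masked cells,
#'   `impute` (named list with `mu`, `sigma`, `values`).
#' @param model A `dnt_model`.
#' @return A single finite number, or `-Inf` for out-of-support values.
#' @export
log_joint_density <- function(params, model) {
  stopifnot(inherits(model, "dnt_model"))
  pr <- model$priors
  mu <- if (is.null(model$fix$mu)) params$mu else model$fix$mu
  sigma <- if (is.null(model$fix$sigma)) params$sigma else model$fix$sigma
  if (is.null(mu) || is.null(sigma)) abort("params must assign mu and sigma")
  if (sigma <= 0) return(-Inf)

  lp <- 0
  if (is.null(model$fix$mu)) lp <- lp + dnorm(mu, 0, pr$hyper_mu_scale, log = TRUE)
  if (is.null(model$fix$sigma)) {
    lp <- lp + log(2) + dnorm(sigma, 0, pr$hyper_sigma_scale, log = TRUE)
  }

  x_filled <- model$design$x
  for (b in qaop_blocks) {
    beta_b <- params$beta[[b]]
    if (length(beta_b) != model$p[[b]]) {
      abort(paste0("beta block '", b, "' must have length ", model$p[[b]]))
    }
    lp <- lp + sum(dnorm(beta_b, mu, sigma, log = TRUE))
    if (model$n_miss[[b]] > 0) {
      imp <- params$impute[[b]]
      if (is.null(imp)) abort(paste0("params$impute$", b, " required"))
      if (imp$sigma <= 0) return(-Inf)
      lp <- lp + dnorm(imp$mu, 0, pr$impute_mu_scale, log = TRUE) +
        log(2) + dnorm(imp$sigma, 0, pr$impute_sigma_scale, log = TRUE) +
        sum(dnorm(imp$values, imp$mu, imp$sigma, log = TRUE))
      idx <- model$miss_idx[[b]]
      x_filled[[b]][idx + 1L] <- imp$values
    }
  }

  cc <- lapply(qaop_blocks,
               function(b) drop(x_filled[[b]] %*% params$beta[[b]]))
  if (model$design$n > 0) {
    th <- as.matrix(compute_theta_chain(cc[[1]], cc[[2]], cc[[3]]))
    y <- model$design$y
    for (k in seq_len(4)) {
      obs <- !is.na(y[, k])
      if (any(obs)) {
        thk <- th[obs, k]
        yk <- y[obs, k]
        log1pexp <- ifelse(thk > 35, thk,
                           ifelse(thk < -35, exp(thk), log1p(exp(thk))))
        lp <- lp + sum(yk * thk - log1pexp)
      }
    }
  }
  lp
}
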