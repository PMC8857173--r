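# Shared fixtures, all built in code.

# A hand-rolled minimal design: block dims (p1, p2, p3), complete data,
# labels supplied explicitly.  Used for oracle tests where the full CSV
# schema would only add noise.
tiny_design <- function(x_bdnf, x_syn, x_nnf, y, intercept = FALSE) {
  n <- nrow(y)
  as_block <- function(x) {
    x <- as.matrix(x)
    if (ncol(x) > 0 && is.null(colnames(x))) {
      colnames(x) <- paste0("v", seq_len(ncol(x)))
    }
    x
  }
  x <- list(bdnf = as_block(x_bdnf), syn = as_block(x_syn),
            nnf = as_block(x_nnf))
  structure(
    list(x = x,
         miss = lapply(x, function(m) {
           mm <- matrix(FALSE, nrow(m), ncol(m))
           colnames(mm) <- colnames(m)
           mm
         }),
         y = y,
         standardization = NULL,
         compound = paste0("cmp_", seq_len(n)),
         n = n,
         intercept = intercept),
    class = "dnt_design")
}

# labels for the 5-compound single-predictor toy used by grid oracles
toy_labels_5 <- function() {
  cbind(bdnf = c(1, 0, 1, 1, 0), syn = c(1, 1, 0, 1, 0),
        nnf = c(0, 1, 1, 1, 0), dnt = c(1, 0, 1, 1, 0))
}

# posterior mean of a single free coefficient by grid integration of the
# package's plain-R joint density (independent of the compiled sampler)
grid_posterior_mean <- function(model, lo = -5, hi = 5, points = 10001) {
  grid <- seq(lo, hi, length.out = points)
  lp <- vapply(grid, function(b) {
    log_joint_density(
      list(mu = 0, sigma = 1,
           beta = list(bdnf = b, syn = numeric(0), nnf = numeric(0))),
      model)
  }, numeric(1))
  w <- exp(lp - max(lp))
  w <- w / sum(w)
  sum(grid * w)
}

quiet_fit <- function(model, ...) {
  suppressMessages(fit_dnt(model, ...))
}

complete_sim <- function(n, seed, ...) {
  simulate_dnt_data(n_compounds = n, missingness = NULL, seed = seed, ...)
}
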