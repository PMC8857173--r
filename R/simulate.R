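#' Default MCAR missingness rates for the synthetic study
#'
#' Per-column missing-completely-at-random rates emulating the
#' composition of the kind of screening dataset the model targets:
#' literature evidence for BDNF reduction is absent for roughly half of
#' the compounds; in silico ADMET predictions are unavailable for a
#' small fraction (e.g. inorganics outside the models' applicability
#' domain); and each in vitro assay leaves about a quarter of compounds
#' without a usable label or effective concentration (assay-inactive
#' compounds are treated as missing upstream).  The in vivo DNT label is
#' never missing.
#'
#' @return Named numeric vector of rates in `[0, 1]`.
#' @export
default_missingness <- function() {
  c(logd = 0.05, bbb = 0.08, cbrain_cblood = 0.08,
    pgp_substrate = 0.08, pgp_inhibitor = 0.08, pgp_active = 0.08,
    bdnf_label = 0.5,
    syn_label = 0.25, syn_viability = 0.1, syn_ec30_um = 0.25,
    nnf_label = 0.25, nnf_viability = 0.1,
    nnf_ec50min_um = 0.25, nnf_ec50max_um = 0.25)
}

# Raw-scale locations/scales used to invert standardized draws back into
# plausible laboratory units, so a simulated CSV looks like real data.
raw_scales <- function() {
  tibble::tribble(
    ~column,          ~center, ~scale, ~log10,
    "logd",               2.0,    1.5,  FALSE,
    "cbrain_cblood",      1.0,    0.4,  FALSE,
    "syn_viability",     80.0,   15.0,  FALSE,
    "syn_ec30_um",        0.8,    0.9,   TRUE,
    "nnf_viability",     75.0,   18.0,  FALSE,
    "nnf_ec50min_um",     0.9,    0.8,   TRUE,
    "nnf_ec50max_um",     0.9,    0.8,   TRUE
  )
}

#' Simulate a compound-level dataset from the model's own generative process
#'
#' Draws predictors (continuous on the standardized scale from a standard
#' normal, binary from Bernoulli(0.5)), maps them back into raw
#' laboratory units (inverting the log10/z-score conventions, with the
#' two neural-network EC50 summaries sorted so min <= max), computes the
#' chained linear predictors for the three key events and the adverse
#' outcome exactly as the fitted model does, and draws all four binary
#' labels from Bernoulli(inverse-logit(theta)).  Optionally blanks cells
#' MCAR.  Identical seeds give identical output.
#'
#' True coefficients default to draws from Normal(`mu`, `sigma`) with
#' `(mu, sigma) = (0, 0.5)`, keeping simulated effects inside the
#' weakly-informative prior's plausible range.
#'
#' @param n_compounds Number of compounds to simulate.
#' @param mu,sigma True hyperparameters for coefficient generation.
#' @param beta Optional named list of true coefficient vectors
#'   (`bdnf`, `syn`, `nnf`), lengths matching the design blocks
#'   (including the intercept entry when `spec` has one).  If `NULL`,
#'   drawn from Normal(`mu`, `sigma`).
#' @param missingness Named per-column MCAR rates (see
#'   [default_missingness()]); use `NULL` or all-zero rates for complete
#'   data.  A positive rate for `dnt_label` is an error.
#' @param spec Predictor assignment (see [default_predictor_spec()]).
#' @param seed Integer seed (mandatory, for reproducibility).
#' @return A list with `data` (the compound tibble), and `truth`: a list
#'   with `mu`, `sigma`, `beta` (named list), `theta` (n-by-4 matrix of
#'   true linear predictors) and `prob` (n-by-4 true event
#'   probabilities), all defined on the standardized design scale
#'   actually seen by the model.
#' @export
#' @examples
#' sim <- simulate_dnt_data(n_compounds = 20, seed = 42)
#' sim$data
#' sim$truth$beta
simulate_dnt_data <- function(n_compounds = 88, mu = 0, sigma = 0.5,
                              beta = NULL, missingness = default_missingness(),
                              spec = default_predictor_spec(), seed) {
  if (missing(seed)) abort("a seed is required for reproducible simulation")
  stopifnot(n_compounds >= 1, sigma > 0)
  set.seed(seed)
  n <- n_compounds
  rs <- raw_scales()
  bin_cols <- setdiff(binary_columns(), outcome_columns())

  data <- tibble::tibble(
    compound_name = sprintf("compound_%03d", seq_len(n)),
    cas_rn = sprintf("SYN-%05d-%d", seq_len(n), (seq_len(n) * 7) %% 10),
    smiles = NA_character_,
    dtxsid = sprintf("DTXSYN%07d", seq_len(n))
  )
  # continuous raw predictors via inverse of the z-score/log10 conventions
  for (j in seq_len(nrow(rs))) {
    z <- rnorm(n)
    v <- rs$center[j] + rs$scale[j] * z
    data[[rs$column[j]]] <- if (rs$log10[j]) 10^v else v
  }
  # enforce EC50 min <= max per compound
  lo <- pmin(data$nnf_ec50min_um, data$nnf_ec50max_um)
  hi <- pmax(data$nnf_ec50min_um, data$nnf_ec50max_um)
  data$nnf_ec50min_um <- lo
  data$nnf_ec50max_um <- hi
  for (col in bin_cols) data[[col]] <- rbinom(n, 1, 0.5)

  # outcomes: placeholder so the design builder accepts the table
  for (col in outcome_columns()) data[[col]] <- 0L
  data <- data[, schema_columns()]

  # standardized design exactly as the fitter will see it
  design <- build_design_matrices(data, spec)
  if (is.null(beta)) {
    beta <- lapply(setNames(qaop_blocks, qaop_blocks),
                   function(b) rnorm(ncol(design$x[[b]]), mu, sigma))
  } else {
    for (b in qaop_blocks) {
      if (length(beta[[b]]) != ncol(design$x[[b]])) {
        abort(paste0("true beta block '", b, "' must have length ",
                     ncol(design$x[[b]])))
      }
    }
  }
  cc <- lapply(qaop_blocks, function(b) drop(design$x[[b]] %*% beta[[b]]))
  th <- compute_theta_chain(cc[[1]], cc[[2]], cc[[3]])
  theta <- as.matrix(th[, paste0("theta_", qaop_nodes)])
  colnames(theta) <- qaop_nodes
  prob <- inv_link(theta)

  oc <- outcome_columns()
  for (k in qaop_nodes) data[[oc[[k]]]] <- rbinom(n, 1, prob[, k])

  if (!is.null(missingness) && any(missingness > 0)) {
    data <- apply_missingness(data, missingness,
                              seed = sample.int(.Machine$integer.max, 1))
  }

  list(
    data = data,
    truth = list(mu = mu, sigma = sigma,
                 beta = setNames(beta, qaop_blocks),
                 theta = theta, prob = prob)
  )
}

#' Blank cells of a dataset completely at random
#'
#' Independently blanks each eligible cell with its column's rate
#' (missing completely at random).  The in vivo DNT label is never
#' eligible: every compound keeps its adverse-outcome classification.
#'
#' @param data A compound-level tibble.
#' @param rates Named numeric vector or list of per-column rates in
#'   `[0, 1]`.  A positive rate for `dnt_label` is a configuration error.
#' @param seed Integer seed.
#' @return The tibble with cells blanked to `NA`.
#' @export
apply_missingness <- function(data, rates, seed) {
  if (missing(seed)) abort("a seed is required for reproducible missingness")
  rates <- unlist(rates)
  if (any(rates < 0 | rates > 1)) abort("missingness rates must lie in [0, 1]")
  unknown <- setdiff(names(rates), schema_columns())
  if (length(unknown) > 0) {
    abort(paste0("missingness rate given for unknown column(s): ",
                 paste(unknown, collapse = ", ")))
  }
  if ("dnt_label" %in% names(rates) && rates[["dnt_label"]] > 0) {
    abort("dnt_label can never be blanked (the adverse-outcome label is always observed)")
  }
  set.seed(seed)
  for (col in names(rates)) {
    r <- rates[[col]]
    if (r <= 0) next
    blank <- runif(nrow(data)) < r
    data[[col]][blank] <- NA
  }
  data
}
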