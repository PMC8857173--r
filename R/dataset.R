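#' Column schema of the compound-level DNT dataset
#'
#' The canonical per-compound table mirrors how the evidence is collected
#' in practice: identifiers, an in vivo DNT classification, lipophilicity
#' and ADMET predictors feeding the molecular level, literature evidence
#' for BDNF reduction, and the two in vitro assays (synaptogenesis
#' imaging, microelectrode-array network formation) with their viability
#' and effective-concentration summaries.  Empty cells encode missing
#' information: no literature evidence for BDNF, in silico predictions
#' unavailable (e.g. inorganics), or an assay-inactive compound treated
#' as missing upstream of this package.
#'
#' @return A tibble with one row per column of the CSV schema: `column`,
#'   `type` (`"id"`, `"binary"`, `"continuous"`) and `role`.
#' @export
#' @examples
#' dnt_schema()
dnt_schema <- function() {
  tibble::tribble(
    ~column,           ~type,        ~role,
    "compound_name",   "id",         "identifier",
    "cas_rn",          "id",         "identifier",
    "smiles",          "id",         "identifier",
    "dtxsid",          "id",         "identifier",
    "dnt_label",       "binary",     "outcome",
    "logd",            "continuous", "predictor",
    "bbb",             "binary",     "predictor",
    "cbrain_cblood",   "continuous", "predictor",
    "pgp_substrate",   "binary",     "predictor",
    "pgp_inhibitor",   "binary",     "predictor",
    "pgp_active",      "binary",     "predictor",
    "bdnf_label",      "binary",     "outcome",
    "syn_label",       "binary",     "outcome",
    "syn_viability",   "continuous", "predictor",
    "syn_ec30_um",     "continuous", "predictor",
    "nnf_label",       "binary",     "outcome",
    "nnf_viability",   "continuous", "predictor",
    "nnf_ec50min_um",  "continuous", "predictor",
    "nnf_ec50max_um",  "continuous", "predictor"
  )
}

schema_columns <- function() dnt_schema()$column

binary_columns <- function() {
  sc <- dnt_schema()
  sc$column[sc$type == "binary"]
}

outcome_columns <- function() {
  c(bdnf = "bdnf_label", syn = "syn_label", nnf = "nnf_label",
    dnt = "dnt_label")
}

#' Read a compound-level DNT dataset from CSV
#'
#' Reads the canonical comma-separated, UTF-8 dialect (see [dnt_schema()]
#' for the exact header).  Empty cells are the sole encoding of missing
#' information and become `NA`.  Row order is preserved; the row index is
#' the stable compound index used throughout the pipeline.
#'
#' @param path Path to a CSV file with the exact schema header.
#' @return A tibble with one row per compound, columns typed per the
#'   schema, and a `provenance` attribute recording the source path.
#' @export
#' @seealso [validate_dnt_data()], [write_dnt_data()]
read_dnt_data <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("dataset file not found: ", path))
  }
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         na = character(), progress = FALSE)
  missing_cols <- setdiff(schema_columns(), names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("dataset is missing mandatory column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  raw <- raw[, schema_columns()]
  raw[raw == ""] <- NA

  parse_num <- function(col) {
    x <- raw[[col]]
    out <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & is.na(out))
    if (length(bad) > 0) {
      abort(paste0("non-numeric value in column '", col, "', row ", bad[1],
                   ": '", x[bad[1]], "'"))
    }
    out
  }
  out <- tibble::as_tibble(raw)
  for (col in schema_columns()) {
    sc <- dnt_schema()
    type <- sc$type[sc$column == col]
    if (type == "id") next
    vals <- parse_num(col)
    if (type == "binary") {
      bad <- which(!is.na(vals) & !(vals %in% c(0, 1)))
      if (length(bad) > 0) {
        abort(paste0("non-binary value in binary column '", col, "', row ",
                     bad[1], ": '", raw[[col]][bad[1]], "'"))
      }
      vals <- as.integer(vals)
    }
    out[[col]] <- vals
  }
  attr(out, "provenance") <- paste0("read from ", path)
  out
}

#' Write a compound-level DNT dataset to CSV
#'
#' Inverse of [read_dnt_data()]: writes the canonical dialect with empty
#' cells for missing values, so that a read/write round trip is the
#' identity on records and on the missingness pattern.
#'
#' @param data A compound-level tibble with the schema columns.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dnt_data <- function(data, path) {
  missing_cols <- setdiff(schema_columns(), names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("cannot write dataset; missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  readr::write_csv(data[, schema_columns()], path, na = "", progress = FALSE)
  invisible(path)
}

#' Validate a compound-level DNT dataset
#'
#' Checks every record-level invariant and returns the violations as
#' data, not as errors: a missing in vivo DNT label (every compound must
#' carry one), non-positive effective concentrations, an EC50 minimum
#' exceeding its maximum, duplicated CAS numbers, and out-of-range binary
#' codes.  An empty result means the dataset is model-ready.
#'
#' @param data A compound-level tibble (see [dnt_schema()]).
#' @return A tibble of violations with columns `row`, `column`, `problem`.
#' @export
#' @examples
#' d <- simulate_dnt_data(n_compounds = 5, seed = 1)$data
#' validate_dnt_data(d)   # 0 rows: clean
validate_dnt_data <- function(data) {
  v <- list()
  add <- function(rows, column, problem) {
    if (length(rows) > 0) {
      v[[length(v) + 1]] <<- tibble::tibble(row = as.integer(rows),
                                            column = column, problem = problem)
    }
  }
  add(which(is.na(data$dnt_label)), "dnt_label",
      "adverse-outcome label required for every compound")
  for (col in c("syn_ec30_um", "nnf_ec50min_um", "nnf_ec50max_um")) {
    add(which(!is.na(data[[col]]) & data[[col]] <= 0), col,
        "non-positive effective concentration")
  }
  both <- !is.na(data$nnf_ec50min_um) & !is.na(data$nnf_ec50max_um)
  add(which(both & data$nnf_ec50min_um > data$nnf_ec50max_um),
      "nnf_ec50min_um", "EC50 minimum exceeds EC50 maximum")
  dup <- duplicated(data$cas_rn) & !is.na(data$cas_rn)
  add(which(dup), "cas_rn", "duplicate CAS RN")
  for (col in binary_columns()) {
    add(which(!is.na(data[[col]]) & !(data[[col]] %in% c(0, 1))), col,
        "value outside {0, 1}")
  }
  if (length(v) == 0) {
    return(tibble::tibble(row = integer(), column = character(),
                          problem = character()))
  }
  dplyr::arrange(dplyr::bind_rows(v), .data$row)
}

#' Default predictor-to-key-event assignment
#'
#' Assigns raw columns to the three key-event design blocks: chemical and
#' ADMET properties feed the molecular event (BDNF reduction), and each
#' in vitro assay's viability and effective-concentration summaries feed
#' its own key event.  Effective concentrations span orders of magnitude
#' and are log10-transformed before standardization.  Each block carries
#' an intercept column (constant 1, never standardized) whose coefficient
#' is pooled like any other entry; set `intercept = FALSE` for a
#' literal-equation variant without intercepts.
#'
#' @param intercept Logical; include an intercept column per block.
#' @return A named list (one element per block `bdnf`, `syn`, `nnf`) of
#'   tibbles with columns `column` and `transform` (`"identity"` or
#'   `"log10"`), plus an `intercept` attribute.
#' @export
default_predictor_spec <- function(intercept = TRUE) {
  spec <- list(
    bdnf = tibble::tibble(
      column = c("logd", "bbb", "cbrain_cblood", "pgp_substrate",
                 "pgp_inhibitor", "pgp_active"),
      transform = "identity"),
    syn = tibble::tibble(
      column = c("syn_viability", "syn_ec30_um"),
      transform = c("identity", "log10")),
    nnf = tibble::tibble(
      column = c("nnf_viability", "nnf_ec50min_um", "nnf_ec50max_um"),
      transform = c("identity", "log10", "log10"))
  )
  attr(spec, "intercept") <- isTRUE(intercept)
  spec
}

#' Build standardized design matrices for the hierarchical model
#'
#' Maps raw predictor columns into one design block per key event.
#' Continuous columns are z-scored over their observed entries using the
#' sample (n-1) standard deviation; effective concentrations are
#' log10-transformed first; binary columns are kept as 0/1; the intercept
#' column is a constant 1.  No imputation happens here: every originally
#' missing cell is carried as a placeholder 0 together with a missingness
#' mask, and the model treats masked cells as latent quantities.
#'
#' @param data A validated compound-level tibble.
#' @param spec Predictor assignment, as from [default_predictor_spec()].
#' @return An object of class `dnt_design`: list with `x` (named list of
#'   n-by-p numeric matrices), `miss` (same-shape logical masks), `y`
#'   (n-by-4 outcome matrix with `NA` for missing labels),
#'   `standardization` (tibble of per-column location/scale/transform for
#'   round-tripping), `compound` (names), and `n`.
#' @export
build_design_matrices <- function(data, spec = default_predictor_spec()) {
  viol <- validate_dnt_data(data)
  if (nrow(viol) > 0) {
    abort(paste0("dataset has ", nrow(viol),
                 " invariant violation(s); run validate_dnt_data()"))
  }
  n <- nrow(data)
  intercept <- isTRUE(attr(spec, "intercept"))
  bin_cols <- binary_columns()

  std_rows <- list()
  one_block <- function(block) {
    bs <- spec[[block]]
    p <- nrow(bs) + intercept
    x <- matrix(0, nrow = n, ncol = p)
    m <- matrix(FALSE, nrow = n, ncol = p)
    cn <- character(p)
    j0 <- 0
    if (intercept) {
      x[, 1] <- 1
      cn[1] <- "intercept"
      j0 <- 1
    }
    for (j in seq_len(nrow(bs))) {
      col <- bs$column[j]
      tr <- bs$transform[j]
      raw <- data[[col]]
      obs <- !is.na(raw)
      if (n > 0 && !any(obs)) {
        abort(paste0("column '", col, "' is entirely missing; cannot standardize"))
      }
      vals <- raw
      if (tr == "log10") vals[obs] <- log10(raw[obs])
      if (col %in% bin_cols) {
        center <- 0; scale <- 1
        z <- vals
      } else {
        if (n >= 2 && sum(obs) >= 2) {
          center <- mean(vals[obs]); scale <- sd(vals[obs])
        } else {
          center <- if (any(obs)) vals[obs][1] else 0
          scale <- 1
        }
        if (!is.finite(scale) || scale == 0) {
          abort(paste0("column '", col, "' has zero variance over observed entries"))
        }
        z <- (vals - center) / scale
      }
      x[obs, j0 + j] <- z[obs]
      m[, j0 + j] <- !obs
      cn[j0 + j] <- col
      std_rows[[length(std_rows) + 1]] <<- tibble::tibble(
        block = block, column = col, transform = tr,
        center = if (col %in% bin_cols) 0 else center,
        scale = if (col %in% bin_cols) 1 else scale)
    }
    colnames(x) <- cn
    colnames(m) <- cn
    list(x = x, miss = m)
  }

  blocks <- lapply(qaop_blocks, one_block)
  names(blocks) <- qaop_blocks

  oc <- outcome_columns()
  y <- matrix(NA_real_, nrow = n, ncol = 4,
              dimnames = list(NULL, qaop_nodes))
  for (k in qaop_nodes) y[, k] <- as.numeric(data[[oc[[k]]]])

  structure(
    list(
      x = lapply(blocks, `[[`, "x"),
      miss = lapply(blocks, `[[`, "miss"),
      y = y,
      standardization = dplyr::bind_rows(std_rows),
      compound = data$compound_name,
      n = n,
      intercept = intercept
    ),
    class = "dnt_design"
  )
}

#' @export
print.dnt_design <- function(x, ...) {
  dims <- vapply(x$x, ncol, integer(1))
  nmiss <- vapply(x$miss, sum, numeric(1))
  cat("<dnt_design> ", x$n, " compounds; block dims (",
      paste(dims, collapse = ", "), "); masked predictor cells (",
      paste(nmiss, collapse = ", "), ")\n", sep = "")
  ymiss <- colSums(is.na(x$y))
  cat("  missing labels:", paste(names(ymiss), ymiss, sep = "=", collapse = " "),
      "\n")
  invisible(x)
}

#' Exploratory summary of a compound-level dataset
#'
#' Computes the descriptive battery used before modelling: variable
#' types, histograms of continuous columns, Pearson correlations over
#' pairwise-complete observations, per-column missing fractions, and the
#' class balance of each binary outcome among observed labels.  A
#' correlation with fewer than two complete pairs is reported as `NA`
#' (undefined), never as 0.
#'
#' @param data A compound-level tibble with at least two rows.
#' @param bins Number of histogram bins for continuous columns.
#' @return An object of class `dnt_eda`: list with tibbles
#'   `variable_types`, `missing_fraction`, `class_balance`, a named list
#'   `histograms` (tibbles of bin edges and counts), and the
#'   `correlations` matrix.
#' @export
explore_dnt_data <- function(data, bins = 10) {
  if (nrow(data) < 2) abort("need at least 2 records for exploration")
  sc <- dnt_schema()
  num_cols <- sc$column[sc$type != "id"]

  miss <- tibble::tibble(
    column = schema_columns(),
    missing_fraction = vapply(schema_columns(),
                              function(c) mean(is.na(data[[c]])), numeric(1),
                              USE.NAMES = FALSE))

  oc <- outcome_columns()
  balance <- tibble::tibble(
    outcome = names(oc),
    column = unname(oc),
    fraction_positive = vapply(unname(oc), function(c) {
      obs <- data[[c]][!is.na(data[[c]])]
      if (length(obs) == 0) NA_real_ else mean(obs == 1)
    }, numeric(1), USE.NAMES = FALSE))

  cont_cols <- sc$column[sc$type == "continuous"]
  histograms <- lapply(setNames(cont_cols, cont_cols), function(c) {
    v <- data[[c]][!is.na(data[[c]])]
    if (length(v) < 2) return(tibble::tibble(left = numeric(), right = numeric(),
                                             count = integer()))
    h <- graphics::hist(v, breaks = bins, plot = FALSE)
    tibble::tibble(left = h$breaks[-length(h$breaks)],
                   right = h$breaks[-1], count = h$counts)
  })

  x <- as.matrix(data[, num_cols])
  k <- length(num_cols)
  corr <- matrix(NA_real_, k, k, dimnames = list(num_cols, num_cols))
  for (i in seq_len(k)) {
    for (j in i:k) {
      ok <- !is.na(x[, i]) & !is.na(x[, j])
      if (sum(ok) >= 2 && sd(x[ok, i]) > 0 && sd(x[ok, j]) > 0) {
        corr[i, j] <- corr[j, i] <- cor(x[ok, i], x[ok, j])
      }
    }
    if (sum(!is.na(x[, i])) >= 1) corr[i, i] <- 1
  }

  structure(
    list(
      variable_types = sc[sc$type != "id", c("column", "type")],
      missing_fraction = miss,
      class_balance = balance,
      histograms = histograms,
      correlations = corr
    ),
    class = "dnt_eda"
  )
}

#' @export
print.dnt_eda <- function(x, ...) {
  cat("<dnt_eda>\n")
  cat("  class balance (fraction positive among observed):\n")
  print(x$class_balance, n = 4)
  top <- dplyr::arrange(x$missing_fraction, dplyr::desc(.data$missing_fraction))
  cat("  most-missing columns:\n")
  print(head(top, 4), n = 4)
  invisible(x)
}
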