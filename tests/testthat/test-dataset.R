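test_that("CSV round trip preserves records and missingness", {
  sim <- simulate_dnt_data(n_compounds = 50, seed = 101)
  path <- withr::local_tempfile(fileext = ".csv")
  write_dnt_data(sim$data, path)
  back <- read_dnt_data(path)
  expect_equal(as.data.frame(back), as.data.frame(sim$data),
               ignore_attr = TRUE)
  expect_identical(is.na(back), is.na(sim$data))
})

test_that("reader maps empty cells to missing and keeps row order", {
  path <- withr::local_tempfile(fileext = ".csv")
  d <- complete_sim(3, seed = 102)$data
  d$bdnf_label[2] <- NA
  write_dnt_data(d, path)
  back <- read_dnt_data(path)
  expect_equal(nrow(back), 3)
  expect_true(is.na(back$bdnf_label[2]))
  expect_false(anyNA(back$bdnf_label[-2]))
  expect_equal(back$compound_name, d$compound_name)
})

test_that("reader rejects malformed input with row/column context", {
  d <- complete_sim(3, seed = 103)$data
  path <- withr::local_tempfile(fileext = ".csv")

  bad <- d
  bad$dnt_label[2] <- 2
  write_dnt_data(bad, path)
  expect_error(read_dnt_data(path), "dnt_label.*row 2")

  txt <- readr::read_lines(path)
  txt[1] <- sub("cas_rn,", "", txt[1])
  txt[-1] <- sub("^([^,]*),[^,]*,", "\\1,", txt[-1])
  readr::write_lines(txt, path)
  expect_error(read_dnt_data(path), "cas_rn")

  expect_error(read_dnt_data(file.path(tempdir(), "nope.csv")), "not found")
})

test_that("the packaged complete-case fixture loads with no missing fields", {
  path <- system.file("extdata", "synthetic_complete_8.csv",
                      package = "qaopdnt")
  d <- read_dnt_data(path)
  expect_equal(nrow(d), 8)
  expect_equal(sum(is.na(d[, setdiff(names(d), "smiles")])), 0)
  expect_equal(nrow(validate_dnt_data(d)), 0)
  # fixture is exactly what the generator produces for its seed
  expect_equal(as.data.frame(d),
               as.data.frame(simulate_dnt_data(n_compounds = 8,
                                               missingness = NULL,
                                               seed = 8)$data),
               ignore_attr = TRUE)
})

test_that("a zero-missingness simulated dataset is complete and clean", {
  d <- complete_sim(8, seed = 104)$data
  expect_equal(nrow(d), 8)
  expect_equal(sum(is.na(d[, setdiff(names(d), c("smiles"))])), 0)
  expect_equal(nrow(validate_dnt_data(d)), 0)
})

test_that("validator reports each invariant violation with its record", {
  d <- complete_sim(5, seed = 105)$data
  d$syn_ec30_um[2] <- -1
  d$nnf_ec50min_um[3] <- d$nnf_ec50max_um[3] * 10
  d$dnt_label[4] <- NA
  d$cas_rn[5] <- d$cas_rn[1]
  v <- validate_dnt_data(d)
  expect_setequal(v$row, c(2L, 3L, 4L, 5L))
  expect_true(any(grepl("non-positive", v$problem)))
  expect_true(any(grepl("EC50 minimum exceeds", v$problem)))
  expect_true(any(grepl("label required", v$problem)))
  expect_true(any(grepl("duplicate CAS", v$problem)))
})

test_that("standardization follows the sample z-score with log10 for ECs", {
  d <- complete_sim(2, seed = 106)$data
  d$logd <- c(1, 3)
  d$syn_ec30_um <- c(10, 1000)
  dm <- build_design_matrices(d)
  expect_equal(unname(dm$x$bdnf[, "logd"]), c(-1, 1) / sqrt(2), tolerance = 1e-12)
  expect_equal(unname(dm$x$syn[, "syn_ec30_um"]), c(-1, 1) / sqrt(2),
               tolerance = 1e-12)
  # intercept constant and unstandardized
  expect_equal(unname(dm$x$bdnf[, "intercept"]), c(1, 1))
  # invertibility: location/scale recover raw values
  st <- dm$standardization
  row <- st[st$column == "syn_ec30_um", ]
  z <- dm$x$syn[, "syn_ec30_um"]
  expect_equal(10^(z * row$scale + row$center), d$syn_ec30_um, tolerance = 1e-9)
})

test_that("observed standardized columns have mean 0 and unit variance", {
  d <- simulate_dnt_data(n_compounds = 60, seed = 107)$data
  dm <- build_design_matrices(d)
  for (b in c("bdnf", "syn", "nnf")) {
    cols <- setdiff(colnames(dm$x[[b]]),
                    c("intercept", "bbb", "pgp_substrate", "pgp_inhibitor",
                      "pgp_active"))
    for (cn in cols) {
      obs <- !dm$miss[[b]][, cn]
      expect_equal(mean(dm$x[[b]][obs, cn]), 0, tolerance = 1e-9)
      expect_equal(var(dm$x[[b]][obs, cn]), 1, tolerance = 1e-9)
    }
  }
})

test_that("design building never imputes: masked cells equal missing raw fields", {
  d <- simulate_dnt_data(n_compounds = 80, seed = 108)$data
  dm <- build_design_matrices(d)
  spec <- default_predictor_spec()
  for (b in c("bdnf", "syn", "nnf")) {
    raw_missing <- sum(vapply(spec[[b]]$column,
                              function(cn) sum(is.na(d[[cn]])), numeric(1)))
    expect_equal(sum(dm$miss[[b]]), raw_missing)
    # placeholder cells carry 0, not a guess
    expect_true(all(dm$x[[b]][dm$miss[[b]]] == 0))
  }
})

test_that("design building rejects degenerate columns", {
  d <- complete_sim(5, seed = 109)$data
  d2 <- d
  d2$logd <- NA_real_
  expect_error(build_design_matrices(d2), "entirely missing")
  d3 <- d
  d3$logd <- 1.5
  expect_error(build_design_matrices(d3), "zero variance")
  d4 <- d
  d4$dnt_label[1] <- NA
  expect_error(build_design_matrices(d4), "violation")
})

test_that("exploratory report computes correlations, missingness, balance", {
  d <- complete_sim(10, seed = 110)$data
  d$cbrain_cblood <- 2 * d$logd          # exactly linear
  d$bdnf_label[1:4] <- NA
  eda <- explore_dnt_data(d)
  expect_equal(eda$correlations["logd", "cbrain_cblood"], 1, tolerance = 1e-12)
  expect_equal(eda$correlations["logd", "logd"], 1)
  expect_true(isSymmetric(eda$correlations))
  mf <- eda$missing_fraction
  expect_equal(mf$missing_fraction[mf$column == "bdnf_label"], 0.4)
  cb <- eda$class_balance
  expect_equal(cb$fraction_positive[cb$outcome == "bdnf"],
               mean(d$bdnf_label[5:10] == 1))
  expect_true(all(mf$missing_fraction >= 0 & mf$missing_fraction <= 1))
})

test_that("correlations with fewer than two complete pairs are undefined", {
  d <- complete_sim(4, seed = 111)$data
  d$logd[1:3] <- NA
  d$cbrain_cblood[4] <- NA   # no complete pair logd x cbrain_cblood
  eda <- explore_dnt_data(d)
  expect_true(is.na(eda$correlations["logd", "cbrain_cblood"]))
})
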