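#' Credible interval of a draw vector
#'
#' Equal-tailed intervals take the (1-level)/2 and (1+level)/2 quantiles
#' (the definition used for the reported 95% intervals: the 2.5th and
#' 97.5th percentiles as bounds); the highest-density alternative
#' returns the narrowest interval containing `level` posterior mass.
#'
#' @param draws Numeric vector of at least 20 draws.
#' @param level Interval mass in (0, 1).
#' @param method `"equal_tailed"` (default) or `"hdi"`.
#' @return Named numeric vector `c(lo, hi)` with `lo <= hi`.
#' @export
#' @examples
#' credible_interval(seq(0, 1, by = 0.001), 0.95)  # 0.025, 0.975
credible_interval <- function(draws, level = 0.95,
                              method = c("equal_tailed", "hdi")) {
  method <- match.arg(method)
  if (length(draws) < 20) abort("need at least 20 draws for an interval")
  if (level <= 0 || level >= 1) abort("level must lie in (0, 1)")
  if (method == "equal_tailed") {
    q <- quantile(draws, c((1 - level) / 2, (1 + level) / 2), names = FALSE)
    return(c(lo = q[1], hi = q[2]))
  }
  xs <- sort(draws)
  n <- length(xs)
  m <- ceiling(level * n)
  if (m >= n) return(c(lo = xs[1], hi = xs[n]))
  starts <- seq_len(n - m)
  widths <- xs[starts + m] - xs[starts]
  i <- which.min(widths)
  c(lo = xs[i], hi = xs[i + m])
}

#' Derive the two hazard-classification thresholds
#'
#' The default derives the low/high cut points from the predicted
#' posterior means themselves, as their empirical 1/3 and 2/3 quantiles
#' (tertiles); fixed user thresholds are passed through verbatim.
#'
#' @param dnt_means Numeric vector of per-compound posterior-mean DNT
#'   probabilities (>= 3 values for the tertile method).
#' @param thresholds Optional fixed `c(t_low, t_high)`; when supplied it
#'   is returned unchanged (after the `t_low < t_high` check).
#' @return Named numeric vector `c(t_low, t_high)`.
#' @export
derive_thresholds <- function(dnt_means, thresholds = NULL) {
  if (!is.null(thresholds)) {
    if (length(thresholds) != 2 || thresholds[1] >= thresholds[2]) {
      abort("fixed thresholds must satisfy t_low < t_high")
    }
    return(c(t_low = thresholds[1], t_high = thresholds[2]))
  }
  if (length(dnt_means) < 3) abort("need at least 3 compounds to derive thresholds")
  if (max(dnt_means) - min(dnt_means) < 1e-12) {
    abort("all predictive means are equal; supply fixed thresholds")
  }
  q <- quantile(dnt_means, c(1 / 3, 2 / 3), names = FALSE)
  if (q[1] >= q[2]) {
    abort("degenerate tertiles (heavily tied means); supply fixed thresholds")
  }
  c(t_low = q[1], t_high = q[2])
}

#' Classify probabilities into low/medium/high hazard levels
#'
#' Boundary convention: thresholds are inclusive on the upper class side
#' - a mean exactly at `t_low` is `medium`, exactly at `t_high` is
#' `high`.
#'
#' @param mean_prob Numeric vector of probabilities.
#' @param thresholds Named vector `c(t_low, t_high)` from
#'   [derive_thresholds()].
#' @return A factor with levels `low`, `medium`, `high`.
#' @export
classify_levels <- function(mean_prob, thresholds) {
  t_low <- thresholds[[1]]
  t_high <- thresholds[[2]]
  if (t_low >= t_high) abort("thresholds must satisfy t_low < t_high")
  out <- ifelse(mean_prob < t_low, "low",
                ifelse(mean_prob < t_high, "medium", "high"))
  factor(out, levels = c("low", "medium", "high"))
}

#' Per-compound prediction report
#'
#' Summarizes the posterior-predictive probability draws per compound
#' and node into means, credible intervals and two-threshold hazard
#' classes, ordered by increasing DNT probability.
#'
#' @param fit A `dnt_fit`.
#' @param level Credible-interval level.
#' @param method Interval method, `"equal_tailed"` or `"hdi"`.
#' @param thresholds Optional fixed `c(t_low, t_high)`; by default the
#'   tertiles of the per-compound mean DNT probabilities.
#' @return A tibble of class `dnt_predictions` (one row per compound x
#'   node): `compound`, `node`, `mean_prob`, `lo`, `hi`,
#'   `interval_method`, `hazard_class`, with the thresholds and level as
#'   attributes; rows ordered by increasing DNT probability within node.
#' @export
predict_report <- function(fit, level = 0.95,
                           method = c("equal_tailed", "hdi"),
                           thresholds = NULL) {
  stopifnot(inherits(fit, "dnt_fit"))
  method <- match.arg(method)
  prob <- posterior_theta(fit)$prob
  compounds <- fit$model$design$compound
  n <- dim(prob)[2]
  pm <- apply(prob, c(2, 3), mean)
  thr <- derive_thresholds(pm[, "dnt"], thresholds)

  rows <- purrr::map_dfr(qaop_nodes, function(k) {
    ci <- t(vapply(seq_len(n),
                   function(i) credible_interval(prob[, i, k], level, method),
                   numeric(2)))
    tibble::tibble(
      compound = compounds,
      node = k,
      mean_prob = pm[, k],
      lo = ci[, 1],
      hi = ci[, 2],
      interval_method = method,
      hazard_class = classify_levels(pm[, k], thr)
    )
  })
  ord <- order(pm[, "dnt"])
  rows <- dplyr::mutate(rows,
                        compound = factor(.data$compound,
                                          levels = compounds[ord]),
                        node = factor(.data$node, levels = qaop_nodes))
  rows <- dplyr::arrange(rows, .data$node, .data$compound)
  attr(rows, "thresholds") <- thr
  attr(rows, "level") <- level
  class(rows) <- c("dnt_predictions", class(rows))
  rows
}

#' Confusion-matrix performance metrics
#'
#' Binarizes posterior-mean probabilities at a decision cutoff
#' (predicted positive iff mean >= cutoff) and evaluates them against
#' observed binary labels: sensitivity TP/(TP+FN), specificity
#' TN/(TN+FP), accuracy (TP+TN)/(TP+FP+TN+FN), and balanced accuracy,
#' the average of sensitivity and specificity.  Compounds with missing
#' labels are excluded; with no observed positives (negatives) the
#' sensitivity (specificity) is undefined and reported `NA`, never 0.
#'
#' @param mean_prob Numeric vector of predicted probabilities.
#' @param labels Binary vector with `NA` for missing labels.
#' @param cutoff Decision cutoff (default 0.5).
#' @return A one-row tibble: `tp`, `fp`, `tn`, `fn`, `n_evaluable`,
#'   `sensitivity`, `specificity`, `accuracy`, `balanced_accuracy`.
#' @export
#' @examples
#' performance_metrics(c(0.9, 0.8, 0.2, 0.6), c(1, 0, 0, 1))
performance_metrics <- function(mean_prob, labels, cutoff = 0.5) {
  if (length(mean_prob) != length(labels)) {
    abort("probabilities and labels must have equal length")
  }
  obs <- !is.na(labels)
  if (!any(obs)) abort("need at least one observed label")
  p <- mean_prob[obs]
  y <- labels[obs]
  if (!all(y %in% c(0, 1))) abort("labels must be 0/1 (or NA)")
  pred <- as.integer(p >= cutoff)
  tp <- sum(pred == 1 & y == 1)
  fp <- sum(pred == 1 & y == 0)
  tn <- sum(pred == 0 & y == 0)
  fn <- sum(pred == 0 & y == 1)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  tibble::tibble(
    tp = tp, fp = fp, tn = tn, fn = fn,
    n_evaluable = sum(obs),
    sensitivity = sens,
    specificity = spec,
    accuracy = (tp + tn) / (tp + fp + tn + fn),
    balanced_accuracy = if (is.na(sens) || is.na(spec)) NA_real_
                        else (sens + spec) / 2
  )
}

#' Evaluate a fit against its observed labels per node
#'
#' Convenience wrapper applying [performance_metrics()] to every node of
#' a fitted model, using posterior-mean probabilities.
#'
#' @param fit A `dnt_fit`.
#' @param cutoff Decision cutoff.
#' @return A tibble with one row per node.
#' @export
evaluate_fit <- function(fit, cutoff = 0.5) {
  pm <- apply(posterior_theta(fit)$prob, c(2, 3), mean)
  y <- fit$model$design$y
  purrr::map_dfr(qaop_nodes, function(k) {
    if (all(is.na(y[, k]))) {
      return(tibble::tibble(node = k, tp = NA_integer_, fp = NA_integer_,
                            tn = NA_integer_, fn = NA_integer_,
                            n_evaluable = 0L, sensitivity = NA_real_,
                            specificity = NA_real_, accuracy = NA_real_,
                            balanced_accuracy = NA_real_))
    }
    dplyr::bind_cols(tibble::tibble(node = k),
                     performance_metrics(pm[, k], y[, k], cutoff))
  })
}
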