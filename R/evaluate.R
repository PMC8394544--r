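# Statistical characterization and diagnostic reporting: Se/Sp/Acc/AUC,
# Kruskal-Wallis group tests with Bonferroni correction, and partial
# Spearman correlations controlling for age.

#' Rank-statistic AUC
#'
#' Area under the ROC curve by the Mann-Whitney identity with midranks
#' for ties (a truth-independent constant score gives 0.5).
#'
#' @param y_true Binary truth (0/1, logical or two-level factor).
#' @param score Numeric scores; larger means more positive.
#' @return AUC in `[0, 1]`.
#' @export
auc_rank <- function(y_true, score) {
  y <- as_binary(y_true)
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("AUC requires both classes in the truth")
  r <- rank(score, ties.method = "average")
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Diagnostic metrics at a decision threshold
#'
#' Sensitivity, specificity and accuracy (percent) from the confusion
#' table at `score >= threshold`, plus the threshold-free rank AUC.
#'
#' @param y_true Binary truth.
#' @param score Posterior probabilities or scores.
#' @param threshold Decision threshold (default 0.5).
#' @return An object of class `diagnostic_report`: `se`, `sp`, `acc`
#'   (percent), `auc`, `confusion` (2x2 matrix), `threshold`.
#' @export
diagnostic_metrics <- function(y_true, score, threshold = 0.5) {
  y <- as_binary(y_true)
  pred <- as.integer(score >= threshold)
  tp <- sum(pred == 1 & y == 1)
  tn <- sum(pred == 0 & y == 0)
  fp <- sum(pred == 1 & y == 0)
  fn <- sum(pred == 0 & y == 1)
  confusion <- matrix(c(tn, fn, fp, tp), 2, 2,
                      dimnames = list(truth = c("0", "1"),
                                      predicted = c("0", "1")))
  auc <- if (length(unique(y)) == 2) auc_rank(y, score) else NA_real_
  structure(list(se = 100 * tp / (tp + fn), sp = 100 * tn / (tn + fp),
                 acc = 100 * (tp + tn) / length(y), auc = auc,
                 confusion = confusion, threshold = threshold),
            class = "diagnostic_report")
}

#' @export
print.diagnostic_report <- function(x, ...) {
  cat(sprintf("Se = %.1f%%  Sp = %.1f%%  Acc = %.1f%%  AUC = %.3f (threshold %.2f)\n",
              x$se, x$sp, x$acc, x$auc, x$threshold))
  invisible(x)
}

#' Kruskal-Wallis group-difference test with Bonferroni correction
#'
#' Tie-corrected Kruskal-Wallis test of a feature across severity
#' groups, with the p-value Bonferroni-adjusted for the number of
#' features tested in the same report; significance is declared at
#' adjusted `p < 0.01`. When every value is identical the statistic is
#' 0 and `p = 1` by convention.
#'
#' @param values Numeric feature values.
#' @param groups Group labels (factor); every group must be nonempty.
#' @param n_comparisons Bonferroni family size (default 1).
#' @param alpha Significance level on the adjusted p-value.
#' @return A list: `statistic` (H), `p`, `p_adjusted`, `significant`.
#' @export
group_difference_test <- function(values, groups, n_comparisons = 1,
                                  alpha = 0.01) {
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) < 2) stop("need at least two nonempty groups")
  if (any(tabulate(groups) == 0)) stop("empty group")
  if (length(unique(values)) == 1) {
    h <- 0; p <- 1
  } else {
    kt <- stats::kruskal.test(values, groups)
    h <- unname(kt$statistic)
    p <- kt$p.value
  }
  p_adj <- min(1, p * n_comparisons)
  list(statistic = h, p = p, p_adjusted = p_adj,
       significant = p_adj < alpha)
}

#' Partial Spearman correlation controlling for a covariate
#'
#' Rank-transforms `x`, `y` and `z` and computes the first-order
#' partial correlation of the ranks of `x` and `y` given the ranks of
#' `z` (typically age), with the p-value from the t approximation on
#' `n - 3` degrees of freedom.
#'
#' @param x,y Numeric vectors.
#' @param z Covariate to control for (e.g. age).
#' @return A list: `rho` (partial Spearman coefficient), `p`, `n`.
#' @export
partial_spearman <- function(x, y, z) {
  n <- length(x)
  stopifnot(length(y) == n, length(z) == n)
  if (n < 4) stop("need at least 4 observations")
  if (any(!is.finite(z))) stop("covariate must be finite")
  rx <- rank(x); ry <- rank(y); rz <- rank(z)
  if (stats::var(rx) == 0 || stats::var(ry) == 0 || stats::var(rz) == 0) {
    stop("zero variance in a ranked variable")
  }
  rxy <- stats::cor(rx, ry)
  rxz <- stats::cor(rx, rz)
  ryz <- stats::cor(ry, rz)
  den <- sqrt((1 - rxz^2) * (1 - ryz^2))
  if (den < .Machine$double.eps^0.5) {
    stop("degenerate partial correlation: covariate explains a variable exactly")
  }
  rho <- (rxy - rxz * ryz) / den
  rho <- max(-1, min(1, rho))
  df <- n - 3
  tstat <- rho * sqrt(df / max(1 - rho^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df)
  list(rho = rho, p = p, n = n)
}

#' Characterization report for selected features
#'
#' Per selected feature: group medians and quartiles by severity, the
#' tie-corrected Kruskal-Wallis p-value (Bonferroni-corrected across
#' the selected features), and the monotone-trend direction across
#' severity (sign of the Spearman correlation of the feature with the
#' ordered group index).
#'
#' @param table Feature table from [extract_feature_table()] (must
#'   contain a `severity` column).
#' @param selected Character vector of feature column names.
#' @param alpha Significance level on the adjusted p-value.
#' @return Data frame with one row per selected feature.
#' @export
characterization_report <- function(table, selected, alpha = 0.01) {
  sev <- factor(table$severity, levels = c("none", "mild", "moderate",
                                           "severe"))
  sev <- droplevels(sev)
  m <- length(selected)
  rows <- lapply(selected, function(f) {
    v <- table[[f]]
    kw <- group_difference_test(v, sev, n_comparisons = m, alpha = alpha)
    qs <- tapply(v, sev, stats::quantile, probs = c(0.25, 0.5, 0.75))
    trend <- if (length(unique(v)) == 1) 0 else
      sign(stats::cor(v, as.integer(sev), method = "spearman"))
    data.frame(feature = f, H = kw$statistic, p = kw$p,
               p_adjusted = kw$p_adjusted, significant = kw$significant,
               trend = trend,
               median_none = if ("none" %in% levels(sev)) qs[["none"]][2] else NA,
               median_severe = if ("severe" %in% levels(sev)) qs[["severe"]][2] else NA)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
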