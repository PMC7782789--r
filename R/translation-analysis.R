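# Downstream analyses of translated data: marker calling with Welch's t-test
# and Benjamini-Hochberg adjustment, and predicted-vs-observed group
# difference (log-fold-change) concordance.

#' Two-sided Welch's t-test
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of freedom.
#'
#' @param group_a,group_b numeric vectors with >= 2 values each.
#' @return list with `t` and two-sided `p`.
#' @export
welch_t <- function(group_a, group_b) {
  if (length(group_a) < 2 || length(group_b) < 2) {
    abort("each group needs at least 2 values")
  }
  if (stats::var(group_a) == 0 && stats::var(group_b) == 0) {
    if (mean(group_a) == mean(group_b)) return(list(t = 0, p = 1))
    abort("zero variance in both groups with unequal means")
  }
  ht <- stats::t.test(group_a, group_b, var.equal = FALSE)
  list(t = unname(ht$statistic), p = unname(ht$p.value))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param pvalues vector of p-values in \[0, 1\].
#' @return adjusted p-values in the input order (elementwise >= input,
#'   capped at 1).
#' @export
benjamini_hochberg <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE)) {
    abort("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Marker features between two groups
#'
#' Per-feature mean difference (group A minus group B), two-sided Welch's t,
#' BH-adjusted p, and marker flags: a feature is a marker when its adjusted
#' p-value is below `alpha` AND it ranks in the top `top_n` by absolute mean
#' difference within its direction. On log-normalized expression the mean
#' difference is the log-fold-change. Ties at the top-`top_n` cut are broken
#' by smaller adjusted p, then feature index.
#'
#' @param expression cells-by-features matrix.
#' @param labels two-group factor/vector over cells.
#' @param top_n marker set size per direction (default 50).
#' @param alpha adjusted-p threshold (default 0.05).
#' @return a `data.frame` (class `marker_table`) with columns `feature`,
#'   `mean_diff`, `t`, `p`, `p_adj`, `marker_group` (`"A"`, `"B"` or `""`).
#' @export
marker_genes <- function(expression, labels, top_n = 50, alpha = 0.05) {
  expression <- as.matrix(expression)
  groups <- unique(labels)
  if (length(groups) != 2) abort("labels must define exactly 2 groups")
  a <- labels == groups[1]
  b <- labels == groups[2]
  if (sum(a) < 2 || sum(b) < 2) abort("each group needs >= 2 cells")
  nf <- ncol(expression)
  mean_diff <- colMeans(expression[a, , drop = FALSE]) -
    colMeans(expression[b, , drop = FALSE])
  tt <- numeric(nf); pp <- numeric(nf)
  for (k in seq_len(nf)) {
    va <- stats::var(expression[a, k]); vb <- stats::var(expression[b, k])
    if (va == 0 && vb == 0) {
      tt[k] <- 0; pp[k] <- 1
    } else {
      w <- welch_t(expression[a, k], expression[b, k])
      tt[k] <- w$t; pp[k] <- w$p
    }
  }
  padj <- benjamini_hochberg(pp)
  feat <- colnames(expression) %||% paste0("f", seq_len(nf))
  marker_group <- rep("", nf)
  for (dir in c("A", "B")) {
    cand <- which(if (dir == "A") mean_diff > 0 else mean_diff < 0)
    cand <- cand[padj[cand] < alpha]
    if (length(cand) && top_n > 0) {
      ord <- cand[order(-abs(mean_diff[cand]), padj[cand], cand)]
      marker_group[utils::head(ord, top_n)] <- dir
    }
  }
  out <- data.frame(feature = feat, mean_diff = mean_diff, t = tt, p = pp,
                    p_adj = padj, marker_group = marker_group,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("marker_table", "data.frame")
  out
}

#' Concordance of predicted and observed per-feature group differences
#'
#' Computes the per-feature mean group difference in a translated expression
#' matrix and in an observed one (same feature set) and their Pearson
#' correlation — the translated-data analogue of comparing predicted and
#' observed fold changes between subpopulations.
#'
#' @param translated_expression,observed_expression cells-by-features
#'   matrices over the same features.
#' @param translated_labels,observed_labels two-group labels for each matrix.
#' @return list with `predicted_diff`, `observed_diff` (per feature) and
#'   `pearson_r`.
#' @export
fold_change_concordance <- function(translated_expression, translated_labels,
                                    observed_expression, observed_labels) {
  translated_expression <- as.matrix(translated_expression)
  observed_expression <- as.matrix(observed_expression)
  if (ncol(translated_expression) != ncol(observed_expression)) {
    abort("feature sets differ")
  }
  if (ncol(translated_expression) < 2) abort("need at least 2 features")
  gdiff <- function(X, lab) {
    g <- sort(unique(lab))
    if (length(g) != 2) abort("labels must define exactly 2 groups")
    colMeans(X[lab == g[1], , drop = FALSE]) -
      colMeans(X[lab == g[2], , drop = FALSE])
  }
  pd <- gdiff(translated_expression, translated_labels)
  od <- gdiff(observed_expression, observed_labels)
  list(predicted_diff = pd, observed_diff = od,
       pearson_r = stats::cor(pd, od))
}
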