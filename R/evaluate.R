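# Performance evaluation: sensitivity / specificity / accuracy on the
# GC vs non-GC split (cancer-adjacent tissue counts as cancer truth at
# evaluation time — it models inaccurately sampled biopsies), plus the
# nonparametric Hanley-McNeil AUC with its closed-form standard error and
# a normal-approximation 95% CI.

truth_is_gc <- function(truth, gc_adj_as = c("GC", "non-GC")) {
  gc_adj_as <- match.arg(gc_adj_as)
  gc_side <- if (gc_adj_as == "GC") c("GC", "GC_ADJ") else "GC"
  truth %in% gc_side
}

#' Format a fraction as a percentage with two decimals
#'
#' `format_pct(76/79)` gives `"96.20%"`.
#'
#' @param x Fraction in \[0, 1\].
#' @return Character vector.
#' @export
format_pct <- function(x) sprintf("%.2f%%", 100 * x)

#' Confusion-matrix metrics for vote results
#'
#' Sensitivity = correctly identified cancer samples / all cancer samples;
#' specificity = correctly identified non-cancer samples / all non-cancer
#' samples; accuracy = correct / all.  Abstained samples are excluded and
#' counted separately.
#'
#' @param results Data frame from [classify_matrix()].
#' @param truth Named class vector covering every (non-abstained) result.
#' @param gc_adj_as Which truth side `GC_ADJ` samples count toward;
#'   default `"GC"`.
#' @return Object of class `"reo_eval"` (metrics only; see
#'   [evaluate_predictions()] for metrics + AUC).
#' @export
confusion_metrics <- function(results, truth, gc_adj_as = "GC") {
  stopifnot(is.data.frame(results), all(c("sample_id", "label") %in%
                                          names(results)))
  n_abst <- sum(results$abstained)
  res <- results[!results$abstained, , drop = FALSE]
  missing <- setdiff(res$sample_id, names(truth))
  if (length(missing))
    stop("no truth label for sample(s): ", paste(missing, collapse = ", "))
  tr <- truth[res$sample_id]
  is_gc <- truth_is_gc(tr, gc_adj_as)
  pred_gc <- res$label == "GC"
  n_gc <- sum(is_gc); n_non <- sum(!is_gc)
  tp <- sum(pred_gc & is_gc); tn <- sum(!pred_gc & !is_gc)
  out <- list(n_gc = n_gc, n_non = n_non, tp = tp, tn = tn,
              sensitivity = if (n_gc > 0) tp / n_gc else NA_real_,
              specificity = if (n_non > 0) tn / n_non else NA_real_,
              accuracy = (tp + tn) / (n_gc + n_non),
              n_abstained = n_abst,
              auc = NA_real_, auc_se = NA_real_,
              ci95 = c(NA_real_, NA_real_))
  class(out) <- "reo_eval"
  out
}

#' Nonparametric Hanley-McNeil AUC with normal-approximation CI
#'
#' The AUC is the tie-corrected Mann-Whitney statistic: over all
#' (positive, negative) score pairs, a strictly larger positive score
#' counts 1 and an exact tie counts 1/2, divided by `n1 * n0`.  The
#' standard error is the Hanley-McNeil closed form
#' `se^2 = [A(1-A) + (n1-1)(Q1-A^2) + (n0-1)(Q2-A^2)] / (n1 n0)` with
#' `Q1 = A/(2-A)` and `Q2 = 2A^2/(1+A)`; the 95% CI is
#' `A +/- 1.96 se`, clipped to \[0, 1\].
#'
#' @param scores Numeric score per sample (larger = more cancer-like).
#' @param truth Logical vector (`TRUE` = cancer) or class labels, in which
#'   case `GC`/`GC_ADJ` form the positive side.
#' @return List with `auc`, `se`, `ci95` (length-2 vector).
#' @export
hanley_mcneil_auc <- function(scores, truth) {
  if (is.character(truth) || is.factor(truth))
    truth <- truth_is_gc(as.character(truth))
  truth <- as.logical(truth)
  stopifnot(length(scores) == length(truth), !anyNA(scores), !anyNA(truth))
  n1 <- sum(truth); n0 <- sum(!truth)
  if (n1 == 0 || n0 == 0)
    stop("both classes must be non-empty to compute an AUC")
  # midrank formulation of the tie-corrected Mann-Whitney statistic
  r <- rank(scores, ties.method = "average")
  A <- (sum(r[truth]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  q1 <- A / (2 - A)
  q2 <- 2 * A^2 / (1 + A)
  se <- sqrt((A * (1 - A) + (n1 - 1) * (q1 - A^2) + (n0 - 1) * (q2 - A^2)) /
               (n1 * n0))
  ci <- c(max(0, A - 1.96 * se), min(1, A + 1.96 * se))
  list(auc = A, se = se, ci95 = ci)
}

#' ROC curve of a score vector
#'
#' Sweeps thresholds over the distinct score values (plus a sentinel above
#' the maximum); a sample is called positive when its score is at or above
#' the threshold.  The trapezoidal area under the returned points equals
#' the tie-corrected Mann-Whitney AUC.
#'
#' @inheritParams hanley_mcneil_auc
#' @return Data frame of class `"reo_roc"` with columns `threshold`,
#'   `fpr`, `tpr`, and attribute `auc` (trapezoidal area).
#' @export
roc_curve <- function(scores, truth) {
  if (is.character(truth) || is.factor(truth))
    truth <- truth_is_gc(as.character(truth))
  truth <- as.logical(truth)
  n1 <- sum(truth); n0 <- sum(!truth)
  if (n1 == 0 || n0 == 0)
    stop("both classes must be non-empty to compute a ROC curve")
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) sum(scores[truth] >= t) / n1, numeric(1))
  fpr <- vapply(thr, function(t) sum(scores[!truth] >= t) / n0, numeric(1))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(data.frame(threshold = thr, fpr = fpr, tpr = tpr),
            class = c("reo_roc", "data.frame"), auc = auc)
}

#' @export
plot.reo_roc <- function(x, ...) {
  graphics::plot(x$fpr, x$tpr, type = "b", pch = 19,
                 xlab = "False positive rate", ylab = "True positive rate",
                 xlim = c(0, 1), ylim = c(0, 1), ...)
  graphics::abline(0, 1, lty = 3, col = "grey50")
  graphics::legend("bottomright", bty = "n",
                   legend = sprintf("AUC = %.3f", attr(x, "auc")))
  invisible(x)
}

#' Evaluate vote results against truth labels
#'
#' Combines [confusion_metrics()] with the Hanley-McNeil AUC of the
#' `votes/k` scores.
#'
#' @inheritParams confusion_metrics
#' @return Object of class `"reo_eval"` with sensitivity, specificity,
#'   accuracy, `auc`, `auc_se` and `ci95`.
#' @export
evaluate_predictions <- function(results, truth, gc_adj_as = "GC") {
  out <- confusion_metrics(results, truth, gc_adj_as)
  res <- results[!results$abstained, , drop = FALSE]
  is_gc <- truth_is_gc(truth[res$sample_id], gc_adj_as)
  a <- hanley_mcneil_auc(res$score, is_gc)
  out$auc <- a$auc
  out$auc_se <- a$se
  out$ci95 <- a$ci95
  out
}

#' @export
print.reo_eval <- function(x, ...) {
  cat("REO signature evaluation\n")
  cat(sprintf("  sensitivity: %s (%d/%d GC)\n",
              format_pct(x$sensitivity), x$tp, x$n_gc))
  cat(sprintf("  specificity: %s (%d/%d non-GC)\n",
              format_pct(x$specificity), x$tn, x$n_non))
  cat(sprintf("  accuracy:    %s (%d/%d)\n",
              format_pct(x$accuracy), x$tp + x$tn, x$n_gc + x$n_non))
  if (!is.na(x$auc))
    cat(sprintf("  AUC: %.2f (95%% CI %.2f-%.2f)\n",
                x$auc, x$ci95[1], x$ci95[2]))
  if (x$n_abstained > 0)
    cat(sprintf("  abstained: %d sample(s)\n", x$n_abstained))
  invisible(x)
}

#' Group-wise quantitative summaries of signature pairs
#'
#' The qualitative signature deliberately ignores effect sizes; this
#' helper reports them anyway, per pair and sample group: the median fold
#' change `gene_high / gene_low` (samples with a zero denominator are
#' skipped and counted) and the median difference `gene_high - gene_low`.
#'
#' @param m Expression matrix.
#' @param truth Named class vector.
#' @param s `reo_signature`.
#' @return Data frame with one row per (pair, group): `gene_high`,
#'   `gene_low`, `group`, `n`, `median_fc`, `n_fc_skipped`, `median_diff`.
#' @export
group_pair_summaries <- function(m, truth, s) {
  stopifnot(inherits(s, "reo_signature"))
  validate_expression_matrix(m)
  truth <- truth[intersect(names(truth), colnames(m))]
  groups <- list("GC" = names(truth)[truth == "GC"],
                 "non-GC" = names(truth)[truth %in% c("NORMAL", "GASTRITIS",
                                                      "IM")],
                 "GC_ADJ" = names(truth)[truth == "GC_ADJ"])
  groups <- groups[vapply(groups, length, integer(1)) > 0]
  if (length(groups) == 0) stop("no samples in any evaluable group")
  miss <- setdiff(unique(c(s$pairs$gene_high, s$pairs$gene_low)),
                  rownames(m))
  if (length(miss))
    stop("signature gene(s) absent from matrix: ",
         paste(miss, collapse = ", "))
  rows <- list()
  for (p in seq_len(s$k)) {
    hi <- s$pairs$gene_high[p]; lo <- s$pairs$gene_low[p]
    for (g in names(groups)) {
      ss <- groups[[g]]
      num <- m[hi, ss]; den <- m[lo, ss]
      ok <- den != 0
      if (any(!ok))
        message(sprintf("group_pair_summaries: %d sample(s) skipped for FC (%s/%s, %s): zero denominator",
                        sum(!ok), hi, lo, g))
      rows[[length(rows) + 1L]] <- data.frame(
        gene_high = hi, gene_low = lo, group = g, n = length(ss),
        median_fc = if (any(ok)) stats::median(num[ok] / den[ok]) else NA_real_,
        n_fc_skipped = sum(!ok),
        median_diff = stats::median(num - den),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
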