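# Confusion metrics, Hanley-McNeil AUC, ROC curves, group summaries.

mk_results <- function(pred_labels, ids = NULL) {
  ids <- ids %||% sprintf("s%03d", seq_along(pred_labels))
  data.frame(sample_id = ids,
             votes = ifelse(pred_labels == "GC", 2L, 0L), k = 2L,
             score = ifelse(pred_labels == "GC", 1, 0),
             label = pred_labels, abstained = FALSE,
             stringsAsFactors = FALSE)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("confusion metrics reproduce the printed rounding style", {
  # 153/158 GC correct, 76/79 non-GC correct
  truth <- stats::setNames(rep(c("GC", "NORMAL"), c(158, 79)),
                           sprintf("s%03d", 1:237))
  pred <- rep(c("GC", "non-GC", "non-GC", "GC"), c(153, 5, 76, 3))
  ev <- confusion_metrics(mk_results(pred), truth)
  expect_equal(ev$sensitivity, 153 / 158)
  expect_equal(ev$specificity, 76 / 79)
  expect_identical(format_pct(ev$sensitivity), "96.84%")
  expect_identical(format_pct(ev$specificity), "96.20%")
  expect_output(print(ev), "96.84%")

  all_right <- confusion_metrics(mk_results(rep(c("GC", "non-GC"),
                                                c(158, 79))), truth)
  expect_equal(all_right$sensitivity, 1)
  expect_equal(all_right$specificity, 1)
  expect_equal(all_right$accuracy, 1)
})

test_that("accuracy decomposes as the class-weighted mean of sens/spec", {
  set.seed(71)
  for (i in 1:20) {
    n_gc <- sample(5:50, 1); n_non <- sample(5:50, 1)
    truth <- stats::setNames(rep(c("GC", "NORMAL"), c(n_gc, n_non)),
                             sprintf("s%03d", seq_len(n_gc + n_non)))
    pred <- sample(c("GC", "non-GC"), n_gc + n_non, replace = TRUE)
    ev <- confusion_metrics(mk_results(pred), truth)
    expect_equal(ev$accuracy,
                 (ev$sensitivity * n_gc + ev$specificity * n_non) /
                   (n_gc + n_non))
  }
})

test_that("GC-adjacent truth counts toward the cancer side by default", {
  truth <- stats::setNames(c("GC", "GC_ADJ", "NORMAL", "IM"),
                           sprintf("s%03d", 1:4))
  pred <- c("GC", "GC", "non-GC", "non-GC")
  ev <- confusion_metrics(mk_results(pred), truth)
  expect_identical(ev$n_gc, 2L)
  expect_equal(ev$sensitivity, 1)
  ev2 <- confusion_metrics(mk_results(pred), truth, gc_adj_as = "non-GC")
  expect_identical(ev2$n_gc, 1L)
  expect_equal(ev2$specificity, 2 / 3)   # the GC-called adjacent now counts against
})

test_that("abstained samples are excluded and reported", {
  truth <- stats::setNames(rep("GC", 3), c("a", "b", "c"))
  res <- mk_results(c("GC", "GC", "GC"), ids = c("a", "b", "c"))
  res$abstained[2] <- TRUE
  ev <- confusion_metrics(res, truth)
  expect_identical(ev$n_gc, 2L)
  expect_identical(ev$n_abstained, 1L)
  expect_error(confusion_metrics(mk_results("GC", ids = "zz"), truth), "zz")
})

test_that("Hanley-McNeil AUC matches hand-countable cases", {
  # perfect separation: AUC 1, all SE terms vanish
  a <- hanley_mcneil_auc(c(0.9, 0.8, 0.2, 0.1), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(a$auc, 1)
  expect_equal(a$se, 0)
  expect_equal(a$ci95, c(1, 1))
  # identical scores: every comparison ties, AUC 1/2
  expect_equal(hanley_mcneil_auc(rep(0.5, 6), rep(c(TRUE, FALSE), 3))$auc,
               0.5)
  # 4-comparison count: win, win, loss, win = 3/4
  expect_equal(hanley_mcneil_auc(c(0.9, 0.3, 0.5, 0.1),
                                 c(TRUE, TRUE, FALSE, FALSE))$auc, 0.75)
  expect_error(hanley_mcneil_auc(1:3, c(TRUE, TRUE, TRUE)), "non-empty")
})

test_that("AUC equals the brute-force pairwise count and the CI is sane", {
  set.seed(83)
  for (i in 1:25) {
    n <- sample(8:40, 1)
    truth <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(truth) || all(truth)) next
    scores <- sample(seq(0, 1, by = 0.25), n, replace = TRUE)  # many ties
    a <- hanley_mcneil_auc(scores, truth)
    expect_equal(a$auc, brute_auc(scores, truth), tolerance = 1e-12)
    expect_true(a$ci95[1] >= 0 && a$ci95[2] <= 1)
    expect_true(a$ci95[1] <= a$auc && a$auc <= a$ci95[2])
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(97)
  truth <- sample(c(TRUE, FALSE), 60, replace = TRUE)
  scores <- stats::rnorm(60) + truth
  ours <- hanley_mcneil_auc(scores, truth)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(truth, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("ROC curves are monotone and their area matches the AUC", {
  r <- roc_curve(c(0.9, 0.8, 0.2, 0.1), c(TRUE, TRUE, FALSE, FALSE))
  expect_true(any(r$fpr == 0 & r$tpr == 1))   # perfect separation corner
  expect_equal(attr(r, "auc"), 1)

  r2 <- roc_curve(rep(0.3, 8), rep(c(TRUE, FALSE), 4))
  expect_identical(nrow(r2), 2L)              # (0,0) and (1,1) only
  expect_equal(attr(r2, "auc"), 0.5)

  set.seed(13)
  for (i in 1:20) {
    truth <- sample(c(TRUE, FALSE), 30, replace = TRUE)
    if (!any(truth) || all(truth)) next
    scores <- sample(seq(0, 1, 0.5), 30, replace = TRUE)
    r3 <- roc_curve(scores, truth)
    expect_true(all(diff(r3$fpr) >= 0) && all(diff(r3$tpr) >= 0))
    expect_equal(attr(r3, "auc"), brute_auc(scores, truth),
                 tolerance = 1e-12)
  }
})

test_that("evaluate_predictions combines metrics with the score AUC", {
  truth <- stats::setNames(rep(c("GC", "NORMAL"), each = 4),
                           sprintf("s%03d", 1:8))
  res <- mk_results(rep(c("GC", "non-GC"), each = 4))
  ev <- evaluate_predictions(res, truth)
  expect_equal(ev$auc, 1)
  expect_equal(ev$accuracy, 1)
})

test_that("group_pair_summaries reports median FC and differences", {
  s <- reo_signature(data.frame(gene_high = "CYR61", gene_low = "MMP28"))
  m <- matrix(c(10, 5, 20, 8, 4, 4), nrow = 2,
              dimnames = list(c("CYR61", "MMP28"), c("g1", "g2", "n1")))
  truth <- stats::setNames(c("GC", "GC", "NORMAL"), colnames(m))
  out <- group_pair_summaries(m, truth, s)
  gc_row <- out[out$group == "GC", ]
  expect_equal(gc_row$median_fc, median(c(2, 2.5)))      # 2.25
  expect_equal(gc_row$median_diff, median(c(5, 12)))     # 8.5
  non_row <- out[out$group == "non-GC", ]
  expect_equal(non_row$median_fc, 1)    # identical values: FC 1, diff 0
  expect_equal(non_row$median_diff, 0)
  expect_identical(non_row$n, 1L)       # median of a single sample

  # zero denominators are skipped with a count
  m2 <- m; m2["MMP28", "g2"] <- 0
  expect_message(out2 <- group_pair_summaries(m2, truth, s), "skipped")
  expect_identical(out2[out2$group == "GC", ]$n_fc_skipped, 1L)
  expect_equal(out2[out2$group == "GC", ]$median_fc, 2)
})
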