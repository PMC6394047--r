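# Reversal-degree scoring and top-k signature selection.
#
# For a reversal pair, the absolute rank difference R_ij = |R_i - R_j| is
# averaged separately over non-cancer and cancer samples, and the reversal
# degree is the geometric mean
#   avgR_ij = sqrt(mean[R_ij(non)] * mean[R_ij(gc)]).
# Pairs are sorted by descending degree; the signature is the shortest
# prefix maximizing training accuracy under the majority-vote rule.

#' Absolute within-sample rank difference of a gene pair
#'
#' @param ranks Rank matrix.
#' @param pair Character vector of the two gene ids (or a one-row data
#'   frame with `gene_high`, `gene_low`).
#' @param sample Sample id or column index.
#' @return `|rank(gene_high) - rank(gene_low)|` within the sample.
#' @export
rank_difference <- function(ranks, pair, sample) {
  if (is.data.frame(pair) || is.list(pair))
    pair <- c(pair$gene_high, pair$gene_low)
  pair <- as.character(pair)
  miss <- setdiff(pair, rownames(ranks))
  if (length(miss))
    stop("gene(s) absent from rank matrix: ", paste(miss, collapse = ", "))
  abs(ranks[pair[1], sample] - ranks[pair[2], sample])
}

#' Score reversal pairs by reversal degree
#'
#' Adds class-wise mean absolute rank differences and their geometric mean
#' (the reversal degree) to a table of reversal pairs.
#'
#' @param ranks Rank matrix.
#' @param labels Named class vector.
#' @param pairs Data frame with `gene_high`, `gene_low` (GC orientation),
#'   e.g. from [reversal_pairs()].
#' @param non_classes Classes forming the non-cancer side of the degree
#'   (training convention: normal + gastritis).
#' @param gc_classes Classes forming the cancer side.
#' @return `pairs` with columns `mean_rankdiff_non`, `mean_rankdiff_gc`
#'   and `degree` appended.
#' @export
reversal_degree <- function(ranks, labels, pairs,
                            non_classes = c("NORMAL", "GASTRITIS"),
                            gc_classes = "GC") {
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  non_s <- intersect(colnames(ranks), names(labels)[labels %in% non_classes])
  gc_s <- intersect(colnames(ranks), names(labels)[labels %in% gc_classes])
  if (length(non_s) == 0) stop("no samples in the non-cancer classes")
  if (length(gc_s) == 0) stop("no samples in the cancer classes")
  if (nrow(pairs) == 0) {
    pairs$mean_rankdiff_non <- numeric(0)
    pairs$mean_rankdiff_gc <- numeric(0)
    pairs$degree <- numeric(0)
    return(pairs)
  }
  ih <- match(pairs$gene_high, rownames(ranks))
  il <- match(pairs$gene_low, rownames(ranks))
  if (anyNA(ih) || anyNA(il)) {
    miss <- unique(c(pairs$gene_high[is.na(ih)], pairs$gene_low[is.na(il)]))
    stop("gene(s) absent from rank matrix: ", paste(miss, collapse = ", "))
  }
  D <- abs(ranks[ih, , drop = FALSE] - ranks[il, , drop = FALSE])
  pairs$mean_rankdiff_non <- rowMeans(D[, non_s, drop = FALSE])
  pairs$mean_rankdiff_gc <- rowMeans(D[, gc_s, drop = FALSE])
  pairs$degree <- sqrt(pairs$mean_rankdiff_non * pairs$mean_rankdiff_gc)
  pairs
}

#' Sort reversal pairs by descending reversal degree
#'
#' Ties are broken lexicographically by (`gene_high`, `gene_low`) so the
#' ordering is deterministic.
#'
#' @param pairs Data frame with a `degree` column (from
#'   [reversal_degree()]).
#' @return The same data frame, reordered.
#' @export
order_by_degree <- function(pairs) {
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  if (nrow(pairs) == 0) return(pairs)
  o <- order(-pairs$degree, pairs$gene_high, pairs$gene_low,
             method = "radix")
  out <- pairs[o, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Training accuracy of every top-k signature
#'
#' For each k in 1..`k_max`, classifies every training sample (the union
#' of the non-cancer and cancer classes) with the top-k pairs under the
#' vote rule, and records the fraction classified correctly.
#'
#' @param ordered Reversal pairs sorted by [order_by_degree()].
#' @param ranks Rank matrix.
#' @param labels Named class vector.
#' @param k_max Largest signature size to try (`<= nrow(ordered)`).
#' @param non_classes,gc_classes Training class split.
#' @param vote_rule `"at_least_half"` or `"all_pairs"`.
#' @return Numeric vector of accuracies, length `k_max`.
#' @export
sweep_topk <- function(ordered, ranks, labels, k_max = nrow(ordered),
                       non_classes = c("NORMAL", "GASTRITIS"),
                       gc_classes = "GC",
                       vote_rule = c("at_least_half", "all_pairs")) {
  vote_rule <- match.arg(vote_rule)
  if (k_max < 1) stop("k_max must be at least 1")
  if (k_max > nrow(ordered))
    stop(sprintf("k_max (%d) exceeds the number of pairs (%d)",
                 k_max, nrow(ordered)))
  samples <- intersect(colnames(ranks),
                       names(labels)[labels %in% c(non_classes, gc_classes)])
  if (length(samples) == 0) stop("no training samples found")
  truth_gc <- labels[samples] %in% gc_classes
  ih <- match(ordered$gene_high[seq_len(k_max)], rownames(ranks))
  il <- match(ordered$gene_low[seq_len(k_max)], rownames(ranks))
  V <- (ranks[ih, samples, drop = FALSE] >
          ranks[il, samples, drop = FALSE]) * 1L
  votes <- apply(V, 2L, cumsum)                 # k_max x n (or vector if k_max==1)
  if (k_max == 1L) votes <- matrix(votes, nrow = 1L)
  ks <- seq_len(k_max)
  vapply(ks, function(k) {
    pred_gc <- if (vote_rule == "at_least_half") 2L * votes[k, ] >= k
               else votes[k, ] == k
    mean(pred_gc == truth_gc)
  }, numeric(1))
}

#' Select the final signature from a top-k accuracy sweep
#'
#' The signature size is the smallest k attaining the maximum training
#' accuracy (parsimony tie-break).
#'
#' @param accuracies Accuracy vector from [sweep_topk()].
#' @param ordered The reversal pairs the sweep was run on.
#' @param vote_rule Vote rule recorded on the model.
#' @param ... Further fields stored on the returned object.
#' @return `reo_signature` with `training_accuracy` and `accuracy_by_k`.
#' @export
select_signature <- function(accuracies, ordered,
                             vote_rule = "at_least_half", ...) {
  if (length(accuracies) < 1) stop("empty accuracy vector")
  k_star <- which.max(accuracies)   # first max = smallest k
  reo_signature(ordered[seq_len(k_star), c("gene_high", "gene_low"),
                        drop = FALSE],
                vote_rule = vote_rule,
                training_accuracy = accuracies[k_star],
                accuracy_by_k = accuracies,
                reversals = ordered, ...)
}

#' Fit a REO gene-pair signature
#'
#' End-to-end signature discovery on a labeled training cohort:
#' rank-transform, mine stable pairs in each non-cancer class, intersect
#' them into the non-cancer consensus, mine the cancer-side stable pairs,
#' keep the pairs whose orientation reverses, score them by reversal
#' degree, and pick the top-k signature maximizing training accuracy under
#' the vote rule.
#'
#' `x` may be a single expression matrix or a list of matrices from
#' different platforms; lists are restricted to the common gene universe,
#' rank-transformed per dataset (REOs are within-sample, so pooling needs
#' no normalization) and pooled for the stability counts.
#'
#' @param x Expression matrix (genes x samples) or list of such matrices.
#' @param labels Named class vector covering the training samples.
#' @param threshold Stability fraction in (0.5, 1]; default 0.99.
#' @param k_max Largest signature size to sweep; defaults to the number
#'   of reversal pairs found.
#' @param non_gc_classes Non-cancer training classes (each mined
#'   separately, then intersected).
#' @param gc_class Cancer training class.
#' @param vote_rule `"at_least_half"` (default) or `"all_pairs"`.
#' @return Object of class `"reo_signature"`; see also
#'   [predict.reo_signature()].
#' @examples
#' co <- simulate_cohort(cohort_spec(n_normal = 30, n_gastritis = 30,
#'                                   n_gc = 30, n_genes = 60,
#'                                   purity = 1, noise_sd = 0, seed = 7))
#' fit <- reo_train(co$matrix, co$labels)
#' coef(fit)
#' @export
reo_train <- function(x, labels, threshold = 0.99, k_max = NULL,
                      non_gc_classes = c("NORMAL", "GASTRITIS"),
                      gc_class = "GC",
                      vote_rule = c("at_least_half", "all_pairs")) {
  vote_rule <- match.arg(vote_rule)
  if (is.list(x) && !is.matrix(x)) {
    mats <- intersect_genes(x)
    ranks <- do.call(cbind, lapply(mats, rank_transform))
  } else {
    ranks <- rank_transform(x)
  }
  validate_class_labels(labels)

  non_sets <- lapply(non_gc_classes, function(cl)
    stable_pairs(ranks, labels, cl, threshold))
  non_set <- if (length(non_sets) > 1) do.call(consensus_stable_pairs, non_sets)
             else non_sets[[1]]
  gc_set <- stable_pairs(ranks, labels, gc_class, threshold)
  rev <- reversal_pairs(non_set, gc_set)
  if (nrow(rev) == 0)
    stop("no reversal pairs found at threshold ", threshold,
         "; nothing to build a signature from")
  rev <- reversal_degree(ranks, labels, rev,
                         non_classes = non_gc_classes, gc_classes = gc_class)
  ordered <- order_by_degree(rev)
  if (is.null(k_max)) k_max <- nrow(ordered)
  acc <- sweep_topk(ordered, ranks, labels, k_max,
                    non_classes = non_gc_classes, gc_classes = gc_class,
                    vote_rule = vote_rule)
  select_signature(acc, ordered, vote_rule = vote_rule,
                   threshold = threshold,
                   n_stable_non = nrow(non_set),
                   n_stable_gc = nrow(gc_set),
                   non_gc_classes = non_gc_classes,
                   gc_class = gc_class,
                   n_train = length(intersect(
                     colnames(ranks),
                     names(labels)[labels %in% c(non_gc_classes, gc_class)])))
}
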