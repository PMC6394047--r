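# Majority-vote classification.  A pair votes for cancer when the
# measured abundance of its gene_high strictly exceeds its gene_low; an
# exact tie votes for neither side (fail-safe toward the strict-ordering
# definition).  A sample is called GC when 2 * votes >= k ("at least a
# half"), or when votes == k under the stricter all-pairs rule.  Samples
# missing a signature gene abstain rather than guess.

vote_label <- function(votes, k, vote_rule) {
  if (vote_rule == "at_least_half") ifelse(2L * votes >= k, "GC", "non-GC")
  else ifelse(votes == k, "GC", "non-GC")
}

#' Vote a single sample
#'
#' @param x Named numeric vector of abundances (or ranks; only the
#'   orderings matter).
#' @param s `reo_signature`.
#' @param vote_rule Override of the signature's vote rule.
#' @return One-row data frame: `sample_id`, `votes`, `k`, `score`
#'   (`votes/k`), `label`, `abstained`.
#' @export
vote <- function(x, s, vote_rule = s$vote_rule) {
  stopifnot(inherits(s, "reo_signature"))
  genes <- unique(c(s$pairs$gene_high, s$pairs$gene_low))
  if (!all(genes %in% names(x))) {
    miss <- setdiff(genes, names(x))
    message("vote: sample abstains, missing gene(s): ",
            paste(miss, collapse = ", "))
    return(data.frame(sample_id = NA_character_, votes = NA_integer_,
                      k = s$k, score = NA_real_, label = NA_character_,
                      abstained = TRUE, stringsAsFactors = FALSE))
  }
  v <- sum(x[s$pairs$gene_high] > x[s$pairs$gene_low])
  data.frame(sample_id = NA_character_, votes = as.integer(v), k = s$k,
             score = v / s$k,
             label = vote_label(v, s$k, vote_rule),
             abstained = FALSE, stringsAsFactors = FALSE)
}

#' Classify every sample of an expression matrix
#'
#' Applies the signature's vote rule to each sample.  If any signature
#' gene is absent from the matrix, every sample abstains (missing rows are
#' matrix-wide) and a message reports the genes.
#'
#' @param m Expression matrix (or rank matrix; orderings are identical).
#' @param s `reo_signature`.
#' @param vote_rule Override of the signature's vote rule.
#' @return Data frame with one row per sample: `sample_id`, `votes`, `k`,
#'   `score`, `label`, `abstained`.
#' @export
classify_matrix <- function(m, s, vote_rule = s$vote_rule) {
  stopifnot(inherits(s, "reo_signature"), is.matrix(m))
  genes <- unique(c(s$pairs$gene_high, s$pairs$gene_low))
  miss <- setdiff(genes, rownames(m))
  if (length(miss)) {
    message("classify_matrix: all samples abstain, missing gene(s): ",
            paste(miss, collapse = ", "))
    return(data.frame(sample_id = colnames(m), votes = NA_integer_,
                      k = s$k, score = NA_real_, label = NA_character_,
                      abstained = TRUE, stringsAsFactors = FALSE))
  }
  ih <- match(s$pairs$gene_high, rownames(m))
  il <- match(s$pairs$gene_low, rownames(m))
  V <- m[ih, , drop = FALSE] > m[il, , drop = FALSE]
  votes <- as.integer(colSums(V))
  data.frame(sample_id = colnames(m), votes = votes, k = s$k,
             score = votes / s$k,
             label = vote_label(votes, s$k, vote_rule),
             abstained = FALSE, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Predict method for REO signatures
#'
#' @param object `reo_signature`.
#' @param newdata Expression matrix (genes x samples).
#' @param type `"response"` for the GC / non-GC labels, `"score"` for the
#'   vote fractions, `"votes"` for raw vote counts, `"full"` for the whole
#'   per-sample table from [classify_matrix()].
#' @param ... Unused.
#' @return Named vector (or data frame for `type = "full"`).
#' @export
predict.reo_signature <- function(object, newdata,
                                  type = c("response", "score", "votes",
                                           "full"), ...) {
  type <- match.arg(type)
  res <- classify_matrix(newdata, object)
  switch(type,
         response = stats::setNames(res$label, res$sample_id),
         score = stats::setNames(res$score, res$sample_id),
         votes = stats::setNames(res$votes, res$sample_id),
         full = res)
}
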