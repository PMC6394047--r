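# Stable-pair mining.  A pair (i, j) is stable in a class when the strict
# ordering rank_i > rank_j (or the reverse) holds in at least `threshold`
# of the class's samples; ties count toward neither direction.  Since
# threshold > 0.5 at most one orientation can pass.

# proportion test: count/n >= threshold, robust to binary representation
# of thresholds like 0.99 (counts are integers, so the epsilon cannot
# change a true comparison)
meets_threshold <- function(count, n, threshold) {
  count >= threshold * n - 1e-9
}

#' Mine class-wise stable gene pairs
#'
#' Scans gene pairs (all unordered pairs, or a supplied candidate set) and
#' returns those whose within-sample ordering holds in at least
#' `threshold` of the samples of class `class`.
#'
#' @param ranks Rank matrix from [rank_transform()] (genes x samples).
#' @param labels Named class vector covering the samples of interest.
#' @param class Class whose samples are scanned (one of [tissue_classes]).
#' @param threshold Stability fraction in (0.5, 1]; default 0.99.
#' @param candidates Optional two-column data frame / matrix of gene pairs
#'   to restrict the scan to (unordered; orientation is determined from
#'   the data).
#' @return A `stable_pair_set`: data frame with columns `gene_high`,
#'   `gene_low`, `support` (fraction of samples with the strict ordering
#'   `gene_high > gene_low`), plus attributes `class_tag`, `threshold`,
#'   `n_samples` and `genes` (the sorted gene universe).
#' @export
stable_pairs <- function(ranks, labels, class, threshold = 0.99,
                         candidates = NULL) {
  if (!is.matrix(ranks) || !is.numeric(ranks))
    stop("ranks must be a numeric matrix from rank_transform()")
  if (length(threshold) != 1 || !is.finite(threshold) ||
      threshold <= 0.5 || threshold > 1)
    stop("threshold must lie in (0.5, 1]")
  samples <- intersect(colnames(ranks), names(labels)[labels == class])
  n <- length(samples)
  if (n < 2)
    stop(sprintf("need at least 2 samples of class '%s' (found %d)", class, n))
  R <- ranks[, samples, drop = FALSE]
  G <- nrow(R)
  genes <- rownames(R)
  # ties produce non-tied counts wins + losses < n; detect once whether any
  # sample has tied ranks so the common tie-free case costs one comparison
  has_ties <- any(vapply(seq_len(n),
                         function(s) anyDuplicated(R[, s]) > 0L, logical(1)))

  if (is.null(candidates)) {
    out_hi <- vector("list", G)
    out_lo <- vector("list", G)
    out_sup <- vector("list", G)
    for (i in seq_len(G - 1L)) {
      jdx <- (i + 1L):G
      M <- R[jdx, , drop = FALSE]
      ri_rep <- rep(R[i, ], each = length(jdx))
      wins <- rowSums(M < ri_rep)            # samples with rank_i > rank_j
      losses <- if (has_ties) rowSums(M > ri_rep) else n - wins
      w_ok <- meets_threshold(wins, n, threshold)
      l_ok <- meets_threshold(losses, n, threshold)
      if (any(w_ok) || any(l_ok)) {
        out_hi[[i]] <- c(rep(genes[i], sum(w_ok)), genes[jdx][l_ok])
        out_lo[[i]] <- c(genes[jdx][w_ok], rep(genes[i], sum(l_ok)))
        out_sup[[i]] <- c(wins[w_ok], losses[l_ok]) / n
      }
    }
    res <- data.frame(
      gene_high = as.character(unlist(out_hi, use.names = FALSE)),
      gene_low = as.character(unlist(out_lo, use.names = FALSE)),
      support = as.numeric(unlist(out_sup, use.names = FALSE)),
      stringsAsFactors = FALSE)
  } else {
    cand <- as.data.frame(candidates, stringsAsFactors = FALSE)
    ia <- match(as.character(cand[[1]]), genes)
    ib <- match(as.character(cand[[2]]), genes)
    if (anyNA(ia) || anyNA(ib)) {
      miss <- unique(c(as.character(cand[[1]])[is.na(ia)],
                       as.character(cand[[2]])[is.na(ib)]))
      stop("candidate gene(s) absent from rank matrix: ",
           paste(miss, collapse = ", "))
    }
    A <- R[ia, , drop = FALSE]
    B <- R[ib, , drop = FALSE]
    wins <- rowSums(A > B)
    losses <- if (has_ties) rowSums(A < B) else n - wins
    w_ok <- meets_threshold(wins, n, threshold)
    l_ok <- meets_threshold(losses, n, threshold) & !w_ok
    res <- data.frame(
      gene_high = c(genes[ia][w_ok], genes[ib][l_ok]),
      gene_low = c(genes[ib][w_ok], genes[ia][l_ok]),
      support = c(wins[w_ok], losses[l_ok]) / n,
      stringsAsFactors = FALSE)
  }
  res <- res[order(res$gene_high, res$gene_low, method = "radix"), ,
             drop = FALSE]
  rownames(res) <- NULL
  structure(res,
            class = c("stable_pair_set", "data.frame"),
            class_tag = class, threshold = threshold, n_samples = n,
            genes = sort(genes, method = "radix"))
}

#' Intersect stable-pair sets into a consensus set
#'
#' Pairs present in every input set with identical orientation; the
#' recorded support is the minimum across inputs.  Typical use: the
#' non-cancer consensus between the normal and gastritis stable sets.
#'
#' @param ... Two or more `stable_pair_set` objects over the same gene
#'   universe.
#' @return `stable_pair_set` tagged `"consensus"`.
#' @export
consensus_stable_pairs <- function(...) {
  sets <- list(...)
  if (length(sets) == 1 && is.list(sets[[1]]) &&
      !inherits(sets[[1]], "stable_pair_set"))
    sets <- sets[[1]]
  if (length(sets) < 2)
    stop("need at least 2 stable-pair sets to form a consensus")
  universes <- lapply(sets, attr, "genes")
  if (!all(vapply(universes[-1], identical, logical(1), universes[[1]])))
    stop("stable-pair sets cover different gene universes; ",
         "restrict matrices with intersect_genes() before mining")
  keys <- lapply(sets, function(s) paste(s$gene_high, s$gene_low, sep = "\r"))
  common <- Reduce(intersect, keys)
  first <- sets[[1]]
  idx <- match(common, keys[[1]])
  support <- first$support[idx]
  for (s in seq_along(sets)[-1])
    support <- pmin(support, sets[[s]]$support[match(common, keys[[s]])])
  res <- data.frame(gene_high = first$gene_high[idx],
                    gene_low = first$gene_low[idx],
                    support = support, stringsAsFactors = FALSE)
  res <- res[order(res$gene_high, res$gene_low, method = "radix"), ,
             drop = FALSE]
  rownames(res) <- NULL
  structure(res,
            class = c("stable_pair_set", "data.frame"),
            class_tag = "consensus",
            threshold = max(vapply(sets, attr, numeric(1), "threshold")),
            n_samples = sum(vapply(sets, attr, numeric(1), "n_samples")),
            genes = universes[[1]])
}

#' Find reversal pairs between a non-cancer and a cancer stable set
#'
#' A reversal pair is stable in both sets but with opposite orientations.
#' The returned orientation is the cancer (GC) one.
#'
#' @param non_gc,gc `stable_pair_set` objects over the same gene universe.
#' @return Data frame with columns `gene_high`, `gene_low` (GC
#'   orientation), `support_non`, `support_gc`, sorted by gene ids.
#' @export
reversal_pairs <- function(non_gc, gc) {
  stopifnot(inherits(non_gc, "stable_pair_set"),
            inherits(gc, "stable_pair_set"))
  if (!identical(attr(non_gc, "genes"), attr(gc, "genes")))
    stop("stable-pair sets cover different gene universes; ",
         "restrict matrices with intersect_genes() before mining")
  # non-GC pair (a > b) reversed in GC means GC holds (b > a)
  key_non_flipped <- paste(non_gc$gene_low, non_gc$gene_high, sep = "\r")
  key_gc <- paste(gc$gene_high, gc$gene_low, sep = "\r")
  idx <- match(key_gc, key_non_flipped)
  hit <- !is.na(idx)
  res <- data.frame(gene_high = gc$gene_high[hit],
                    gene_low = gc$gene_low[hit],
                    support_non = non_gc$support[idx[hit]],
                    support_gc = gc$support[hit],
                    stringsAsFactors = FALSE)
  res <- res[order(res$gene_high, res$gene_low, method = "radix"), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

#' @export
print.stable_pair_set <- function(x, ...) {
  cat(sprintf("Stable pair set [%s]: %d pair(s) at threshold %.4g over %d sample(s)\n",
              attr(x, "class_tag"), nrow(x), attr(x, "threshold"),
              attr(x, "n_samples")))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("...", nrow(x) - 10, "more\n")
  invisible(x)
}
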