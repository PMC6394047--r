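# S3 methods for fitted signature models.

#' @export
print.reo_signature <- function(x, ...) {
  cat(sprintf("REO gene-pair signature (k = %d, vote rule: %s)\n",
              x$k, x$vote_rule))
  for (i in seq_len(x$k))
    cat(sprintf("  pair %d: %s > %s in GC\n", i,
                x$pairs$gene_high[i], x$pairs$gene_low[i]))
  if (!is.null(x$training_accuracy))
    cat(sprintf("  training accuracy: %s\n",
                format_pct(x$training_accuracy)))
  invisible(x)
}

#' @export
summary.reo_signature <- function(object, ...) {
  structure(list(model = object), class = "summary.reo_signature")
}

#' @export
print.summary.reo_signature <- function(x, ...) {
  m <- x$model
  print(m)
  if (!is.null(m$threshold))
    cat(sprintf("  stability threshold: %.4g\n", m$threshold))
  if (!is.null(m$n_stable_non))
    cat(sprintf("  stable pairs: %d non-GC consensus, %d GC\n",
                m$n_stable_non, m$n_stable_gc))
  if (!is.null(m$reversals)) {
    cat(sprintf("  reversal pairs found: %d\n", nrow(m$reversals)))
    cat("  top reversals by degree:\n")
    print(utils::head(m$reversals[, c("gene_high", "gene_low",
                                      "mean_rankdiff_non",
                                      "mean_rankdiff_gc", "degree")], 6),
          digits = 4)
  }
  if (!is.null(m$accuracy_by_k)) {
    show <- utils::head(m$accuracy_by_k, 10)
    cat("  training accuracy by k: ",
        paste(sprintf("%d:%.4f", seq_along(show), show), collapse = "  "),
        if (length(m$accuracy_by_k) > 10) "..." else "", "\n")
  }
  invisible(x)
}

#' Signature pairs with their reversal degrees
#'
#' @param object `reo_signature`.
#' @param ... Unused.
#' @return Data frame of the selected pairs, with degree columns when the
#'   model was fitted by [reo_train()].
#' @export
coef.reo_signature <- function(object, ...) {
  if (!is.null(object$reversals)) {
    keys <- paste(object$pairs$gene_high, object$pairs$gene_low)
    idx <- match(keys, paste(object$reversals$gene_high,
                             object$reversals$gene_low))
    out <- object$reversals[idx, , drop = FALSE]
    rownames(out) <- NULL
    out
  } else object$pairs
}

#' Plot the top-k training-accuracy sweep
#'
#' @param x Fitted `reo_signature` (from [reo_train()]).
#' @param max_k Right edge of the plotted sweep; defaults to the smaller
#'   of 10 and the sweep length.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.reo_signature <- function(x, max_k = min(10L, length(x$accuracy_by_k)),
                               ...) {
  if (is.null(x$accuracy_by_k))
    stop("model carries no accuracy sweep; fit it with reo_train()")
  acc <- x$accuracy_by_k[seq_len(max_k)]
  graphics::plot(seq_along(acc), acc, type = "b", pch = 19,
                 xlab = "signature size k",
                 ylab = "training accuracy", ylim = c(min(acc) - 0.01, 1),
                 ...)
  graphics::abline(v = x$k, lty = 2, col = "grey40")
  graphics::mtext(sprintf("selected k = %d", x$k), side = 3, line = 0.2,
                  cex = 0.8)
  invisible(x)
}
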