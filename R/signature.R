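# The signature model: an ordered list of gene pairs, each oriented so that
# gene_high > gene_low is the cancer (GC) ordering, plus the vote rule.

#' Construct a REO signature model
#'
#' @param pairs Data frame with character columns `gene_high` and
#'   `gene_low`; row order is the signature order (strongest reversal
#'   first).  `gene_high > gene_low` is the GC-side ordering.
#' @param vote_rule `"at_least_half"` (a sample is called GC when at least
#'   half of the pairs show their GC ordering) or `"all_pairs"` (stricter
#'   sensitivity-analysis mode requiring every pair).
#' @param training_accuracy Optional training accuracy of the fitted model.
#' @param ... Further fields stored on the object (e.g. `accuracy_by_k`,
#'   `reversals`, `threshold`).
#' @return Object of class `"reo_signature"`.
#' @export
reo_signature <- function(pairs, vote_rule = c("at_least_half", "all_pairs"),
                          training_accuracy = NULL, ...) {
  vote_rule <- match.arg(vote_rule)
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  if (!all(c("gene_high", "gene_low") %in% names(pairs)))
    stop("pairs must have columns gene_high and gene_low")
  pairs$gene_high <- as.character(pairs$gene_high)
  pairs$gene_low <- as.character(pairs$gene_low)
  if (nrow(pairs) < 1) stop("a signature needs at least one gene pair")
  if (any(pairs$gene_high == pairs$gene_low))
    stop("a pair cannot compare a gene with itself")
  key <- unordered_key(pairs$gene_high, pairs$gene_low)
  if (anyDuplicated(key))
    stop("duplicate gene pair(s) in signature: ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  structure(
    list(pairs = pairs[, c("gene_high", "gene_low"), drop = FALSE],
         k = nrow(pairs),
         vote_rule = vote_rule,
         training_accuracy = training_accuracy,
         ...),
    class = "reo_signature")
}

# canonical key for an unordered pair
unordered_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "|")
}

#' Write a signature to a JSON file
#'
#' The on-disk format is versioned JSON:
#' `{"version": 1, "vote_rule": ..., "pairs": [{"gene_high": ...,
#' "gene_low": ...}, ...]}`.
#'
#' @param s `reo_signature` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_signature <- function(s, path) {
  stopifnot(inherits(s, "reo_signature"))
  payload <- list(version = 1L,
                  vote_rule = s$vote_rule,
                  pairs = s$pairs)
  if (!is.null(s$training_accuracy))
    payload$training_accuracy <- s$training_accuracy
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a signature from a JSON file
#'
#' @param path Path to a signature JSON written by [write_signature()] (or
#'   the shipped reference fixture, see
#'   `system.file("extdata", "gc_signature.json", package = "reosig")`).
#' @return `reo_signature` object.
#' @export
read_signature <- function(path) {
  if (!file.exists(path)) stop("signature file not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$version) || !obj$version %in% 1L)
    stop("unknown signature file version: ",
         if (is.null(obj$version)) "<missing>" else obj$version)
  pairs <- as.data.frame(obj$pairs, stringsAsFactors = FALSE)
  reo_signature(pairs,
                vote_rule = if (is.null(obj$vote_rule)) "at_least_half"
                            else obj$vote_rule,
                training_accuracy = obj$training_accuracy)
}

#' The shipped gastric-cancer signature
#'
#' Convenience loader for the two-pair, three-gene GC signature fixture:
#' pair 1 = CYR61 over MMP28, pair 2 = CYR61 over ACOX1 (CYR61 higher in
#' GC), with the at-least-half vote rule.
#'
#' @return `reo_signature` object.
#' @export
gc_signature <- function() {
  read_signature(system.file("extdata", "gc_signature.json",
                             package = "reosig", mustWork = TRUE))
}
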