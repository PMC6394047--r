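# Expression matrices are plain numeric matrices: rows = genes, columns =
# samples, both with unique names.  An optional per-sample batch/platform
# tag lives in attr(m, "batch") (named character vector).

#' Validate an expression matrix
#'
#' Checks the invariants every expression matrix in this package must
#' satisfy: a numeric matrix with unique, non-empty gene (row) and sample
#' (column) names, and all values finite and nonnegative.
#'
#' @param m Numeric matrix, genes in rows, samples in columns.
#' @return `m`, invisibly, if valid; otherwise an error.
#' @export
validate_expression_matrix <- function(m) {
  if (!is.matrix(m) || !is.numeric(m))
    stop("expression data must be a numeric matrix (genes x samples)")
  if (is.null(rownames(m)) || anyNA(rownames(m)) || any(rownames(m) == ""))
    stop("every gene (row) must be named")
  if (is.null(colnames(m)) || anyNA(colnames(m)) || any(colnames(m) == ""))
    stop("every sample (column) must be named")
  dup <- rownames(m)[duplicated(rownames(m))]
  if (length(dup))
    stop("duplicate gene identifier(s): ", paste(unique(dup), collapse = ", "),
         " (collapse probes explicitly with collapse_probes())")
  dup <- colnames(m)[duplicated(colnames(m))]
  if (length(dup))
    stop("duplicate sample identifier(s): ", paste(unique(dup), collapse = ", "))
  bad <- which(!is.finite(m) | m < 0)
  if (length(bad)) {
    i <- arrayInd(bad[1], dim(m))
    stop(sprintf("invalid value %s at gene '%s', sample '%s' (values must be finite and >= 0)",
                 format(m[bad[1]]), rownames(m)[i[1]], colnames(m)[i[2]]))
  }
  invisible(m)
}

#' Read a gene x sample expression matrix from TSV
#'
#' Expects a tab-separated file whose first column holds gene identifiers
#' and whose header row holds sample identifiers.  Duplicate gene rows are
#' an error: probe-level data must be collapsed explicitly with
#' [collapse_probes()].
#'
#' @param path Path to the TSV file.
#' @param batch_tag Optional batch/platform tag recorded for every sample
#'   in the file (stored in `attr(, "batch")`).
#' @return Validated numeric matrix (genes x samples).
#' @export
read_expression_matrix <- function(path, batch_tag = NULL) {
  if (!file.exists(path)) stop("expression matrix file not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE, colClasses = "character")
  if (ncol(tab) < 2)
    stop("malformed header in ", path,
         ": need a gene-id column plus at least one sample column")
  genes <- tab[[1]]
  samples <- colnames(tab)[-1]
  vals <- suppressWarnings(
    vapply(tab[-1], as.numeric, numeric(nrow(tab)))
  )
  vals <- matrix(vals, nrow = nrow(tab),
                 dimnames = list(genes, samples))
  bad <- which(is.na(vals))
  if (length(bad)) {
    i <- arrayInd(bad[1], dim(vals))
    stop(sprintf("non-numeric cell '%s' at gene '%s' (row %d), sample '%s'",
                 tab[i[1], i[2] + 1L], genes[i[1]], i[1], samples[i[2]]))
  }
  validate_expression_matrix(vals)
  if (!is.null(batch_tag)) {
    b <- rep(as.character(batch_tag), ncol(vals))
    names(b) <- colnames(vals)
    attr(vals, "batch") <- b
  }
  message(sprintf("read %d genes x %d samples from %s",
                  nrow(vals), ncol(vals), path))
  vals
}

#' Write an expression matrix to TSV
#'
#' @param m Expression matrix (genes x samples).
#' @param path Output path; first column is named `gene_id`.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(m, path) {
  validate_expression_matrix(m)
  out <- data.frame(gene_id = rownames(m), m, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Collapse probe-level rows to gene-level rows
#'
#' When several probes map to one gene, the gene's value per sample is the
#' arithmetic mean of its probes' values.  Probes absent from the map are
#' dropped (with a reported count); output genes are sorted by identifier.
#'
#' @param m Expression matrix keyed by probe identifiers.
#' @param probe_map Named character vector (`names` = probe ids, values =
#'   gene ids) or a two-column data frame `(probe, gene)`.  Each probe maps
#'   to exactly one gene.
#' @return Expression matrix keyed by gene identifiers.
#' @export
collapse_probes <- function(m, probe_map) {
  validate_expression_matrix(m)
  if (is.data.frame(probe_map)) {
    pm <- as.character(probe_map[[2]])
    names(pm) <- as.character(probe_map[[1]])
    probe_map <- pm
  }
  if (is.null(names(probe_map)) || anyDuplicated(names(probe_map)))
    stop("probe map must assign each probe to exactly one gene")
  keep <- rownames(m) %in% names(probe_map)
  if (!any(keep))
    stop("no probe in the matrix is present in the probe map")
  n_drop <- sum(!keep)
  if (n_drop > 0)
    message(sprintf("collapse_probes: dropping %d unmapped probe(s)", n_drop))
  mm <- m[keep, , drop = FALSE]
  gene <- unname(probe_map[rownames(mm)])
  sums <- rowsum(mm, group = gene)
  counts <- as.vector(table(gene)[rownames(sums)])
  out <- sums / counts
  out <- out[order(rownames(out), method = "radix"), , drop = FALSE]
  attr(out, "batch") <- attr(m, "batch")
  validate_expression_matrix(out)
  out
}

#' Within-sample rank transform
#'
#' Ranks every gene within each sample independently over the full gene set
#' of the matrix; ascending (rank 1 = lowest abundance) with average ranks
#' for ties, so the per-sample rank sum is always G(G+1)/2.  Ranks are all
#' any REO computation ever looks at, which is why the whole pipeline is
#' invariant to strictly increasing per-sample distortions.
#'
#' @param m Expression matrix (>= 2 genes).
#' @return Numeric matrix of ranks, same dimnames as `m`.
#' @export
rank_transform <- function(m) {
  validate_expression_matrix(m)
  if (nrow(m) < 2) stop("rank_transform needs at least 2 genes")
  r <- apply(m, 2L, rank, ties.method = "average")
  dimnames(r) <- dimnames(m)
  attr(r, "batch") <- attr(m, "batch")
  r
}

#' Restrict a list of expression matrices to their common gene universe
#'
#' Pooled stability counts are only meaningful on one gene universe, so
#' matrices from different platforms are intersected (and row-sorted)
#' before per-dataset rank transforms.
#'
#' @param mats List of expression matrices.
#' @return List of matrices, each restricted to the sorted common genes.
#' @export
intersect_genes <- function(mats) {
  stopifnot(is.list(mats), length(mats) >= 1)
  common <- Reduce(intersect, lapply(mats, rownames))
  if (length(common) < 2)
    stop("gene universes share fewer than 2 genes; nothing to intersect")
  common <- sort(common, method = "radix")
  lapply(mats, function(m) {
    out <- m[common, , drop = FALSE]
    b <- attr(m, "batch")
    if (!is.null(b)) attr(out, "batch") <- b
    out
  })
}

#' Read sample class labels from a two-column TSV
#'
#' @param path TSV with columns `sample_id` and `class`; classes must come
#'   from [tissue_classes].
#' @return Named character vector mapping sample id to class.
#' @export
read_class_labels <- function(path) {
  if (!file.exists(path)) stop("labels file not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("labels file needs columns sample_id, class: ", path)
  labels <- as.character(tab[[2]])
  names(labels) <- as.character(tab[[1]])
  validate_class_labels(labels)
  message(sprintf("read %d sample labels from %s", length(labels), path))
  labels
}

#' Write sample class labels
#' @param labels Named character vector (sample id -> class).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_class_labels <- function(labels, path) {
  validate_class_labels(labels)
  utils::write.table(
    data.frame(sample_id = names(labels), class = unname(labels)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Validate class labels
#'
#' @param labels Named character vector; values must be in [tissue_classes].
#' @param m Optional expression matrix every labeled sample must appear in.
#' @return `labels`, invisibly.
#' @export
validate_class_labels <- function(labels, m = NULL) {
  if (is.null(names(labels)) || any(names(labels) == ""))
    stop("labels must be a named vector (sample id -> class)")
  if (anyDuplicated(names(labels)))
    stop("duplicate sample id(s) in labels: ",
         paste(unique(names(labels)[duplicated(names(labels))]), collapse = ", "))
  bad <- setdiff(unique(labels), tissue_classes)
  if (length(bad))
    stop("unknown class label(s): ", paste(bad, collapse = ", "),
         " (expected one of ", paste(tissue_classes, collapse = ", "), ")")
  if (!is.null(m)) {
    missing <- setdiff(names(labels), colnames(m))
    if (length(missing))
      stop("labeled sample(s) absent from matrix: ",
           paste(missing, collapse = ", "))
  }
  invisible(labels)
}
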