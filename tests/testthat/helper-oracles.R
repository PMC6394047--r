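# Independent brute-force oracles and small fixture builders shared by the
# unit and acceptance tests.  The oracles deliberately use naive double
# loops so they share no code path with the package implementation.

# exhaustive stable-pair scan: loops over every unordered pair and sample
brute_stable_pairs <- function(ranks, labels, cls, threshold) {
  samples <- intersect(colnames(ranks), names(labels)[labels == cls])
  R <- ranks[, samples, drop = FALSE]
  n <- ncol(R)
  genes <- rownames(R)
  rows <- list()
  for (i in seq_len(nrow(R) - 1L)) {
    for (j in (i + 1L):nrow(R)) {
      wins <- 0L; losses <- 0L
      for (s in seq_len(n)) {
        if (R[i, s] > R[j, s]) wins <- wins + 1L
        else if (R[i, s] < R[j, s]) losses <- losses + 1L
      }
      if (wins / n >= threshold - 1e-12)
        rows[[length(rows) + 1L]] <- data.frame(
          gene_high = genes[i], gene_low = genes[j], support = wins / n,
          stringsAsFactors = FALSE)
      else if (losses / n >= threshold - 1e-12)
        rows[[length(rows) + 1L]] <- data.frame(
          gene_high = genes[j], gene_low = genes[i], support = losses / n,
          stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0)
    return(data.frame(gene_high = character(0), gene_low = character(0),
                      support = numeric(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out <- out[order(out$gene_high, out$gene_low, method = "radix"), ]
  rownames(out) <- NULL
  out
}

# all-pairs Mann-Whitney count: 1 per win, 0.5 per tie
brute_auc <- function(scores, truth) {
  pos <- scores[truth]
  neg <- scores[!truth]
  total <- 0
  for (p in pos) for (q in neg) {
    if (p > q) total <- total + 1
    else if (p == q) total <- total + 0.5
  }
  total / (length(pos) * length(neg))
}

# direct re-computation of the reversal degree from its definition
brute_degree <- function(ranks, labels, gene_high, gene_low,
                         non_classes = c("NORMAL", "GASTRITIS"),
                         gc_classes = "GC") {
  d_of <- function(cls_set) {
    ss <- names(labels)[labels %in% cls_set]
    mean(vapply(ss, function(s)
      abs(ranks[gene_high, s] - ranks[gene_low, s]), numeric(1)))
  }
  m_non <- d_of(non_classes)
  m_gc <- d_of(gc_classes)
  sqrt(m_non * m_gc)
}

# random expression matrix with gene-specific levels, so pair supports
# span the whole range from unstable to fully stable
structured_matrix <- function(n_genes, n_samples, noise_sd = 1.5,
                              prefix = "S") {
  mu <- stats::runif(n_genes, 0, 6)
  m <- exp(mu + matrix(stats::rnorm(n_genes * n_samples, 0, noise_sd),
                       nrow = n_genes))
  dimnames(m) <- list(sprintf("G%03d", seq_len(n_genes)),
                      sprintf("%s%03d", prefix, seq_len(n_samples)))
  m
}

# random expression matrix with unique-ish continuous values
random_matrix <- function(n_genes, n_samples, prefix = "S") {
  m <- matrix(stats::rexp(n_genes * n_samples, rate = 0.2),
              nrow = n_genes,
              dimnames = list(sprintf("G%03d", seq_len(n_genes)),
                              sprintf("%s%03d", prefix, seq_len(n_samples))))
  m
}

all_one_class <- function(m, cls = "GC") {
  stats::setNames(rep(cls, ncol(m)), colnames(m))
}

# strictly increasing random transform (random composition of power,
# affine and exponential-ish maps on the positive reals)
random_monotone_fun <- function() {
  a <- stats::runif(1, 0.3, 2.5)
  b <- stats::runif(1, 0.1, 3)
  c <- stats::runif(1, 0, 5)
  kind <- sample(3, 1)
  switch(kind,
         function(x) b * x^a + c,                 # power + affine
         function(x) log1p(b * x) * a + c,        # concave increasing
         function(x) expm1(a * x / (1 + max(x))) * b + c) # convex increasing
}

# tiny deterministic cohort used by several classification tests
toy_signature <- function() {
  reo_signature(data.frame(gene_high = c("CYR61", "CYR61"),
                           gene_low = c("MMP28", "ACOX1")))
}
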