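# Synthetic cohorts with the statistical structure the REO method assumes:
# planted reversal pairs with controlled latent separations, background
# genes whose templates never change between classes, batch-specific
# strictly increasing measurement distortions, and GC samples that are
# purity-weighted linear mixtures of tumor and normal profiles.

#' Default planted reversal pairs
#'
#' Two gene pairs planted on a background of class-invariant genes.  Latent
#' log-scale geometry (background templates filling `bg_log_range`):
#' pair 1 sits at baseline 4.5 with separations `delta_non = 3.5` (its
#' high gene *below* its partner in non-GC tissue) and `delta_gc = 7`
#' (above, in tumor); pair 2 at baseline 12.25 with `delta_non = 1.75`,
#' `delta_gc = 8.5`.  Under linear purity mixing a pair keeps its tumor
#' ordering down to
#' `p* = sinh(delta_non/2) / (sinh(delta_non/2) + sinh(delta_gc/2))`:
#' about 0.14 for pair 1 and 0.03 for pair 2, so a sufficiently impure
#' specimen defeats pair 1 while pair 2 still calls it cancer — the reason
#' a two-pair vote beats either single pair.  The baselines are 7.75
#' log-units apart (half the summed `delta_gc`s) so no cross-pair between
#' the two planted pairs forms a stable reversal of its own.
#'
#' @return Data frame with columns `gene_high`, `gene_low` (GC
#'   orientation), `delta_non`, `delta_gc`, `baseline`.
#' @export
default_planted_pairs <- function() {
  data.frame(
    gene_high = c("REV1A", "REV2A"),
    gene_low  = c("REV1B", "REV2B"),
    delta_non = c(3.5, 1.75),
    delta_gc  = c(7.0, 8.5),
    baseline  = c(4.5, 12.25),
    stringsAsFactors = FALSE)
}

#' Specify a synthetic cohort
#'
#' Defaults describe the package's reference benchmark: 500 genes, 100
#' samples per training class, 3 simulated platforms, latent Gaussian
#' noise of 0.15 log-units, and GC purities recycled from the upper range
#' of the measured tumor-purity series (values >= 0.73, emulating
#' resection specimens) plus one deliberately contaminated specimen at
#' 0.08 that only the weaker planted pair survives.
#'
#' @param n_normal,n_gastritis,n_gc Samples per training class.
#' @param n_im,n_gc_adj Optional intestinal-metaplasia and cancer-adjacent
#'   samples (validation-only classes).
#' @param n_genes Total gene count (planted pair genes included).
#' @param planted_pairs Data frame as in [default_planted_pairs()].
#' @param noise_sd Standard deviation of the gene-wise latent Gaussian
#'   noise (log scale).
#' @param purity Tumor epithelial proportions in (0, 1] applied to GC
#'   samples; recycled to `n_gc`.  Default: `0.08` followed by the
#'   `gc_tumor_purity` values at or above 0.73, recycled.
#' @param gc_adj_purity Range of purities for GC-adjacent samples, which
#'   are modelled as low-purity tumor mixtures.
#' @param n_batches Number of simulated platforms; each gets its own
#'   monotone distortion and samples are assigned round-robin.
#' @param bg_log_range Range of the uniform distribution background gene
#'   templates are drawn from (log scale).
#' @param seed Integer seed; the cohort is reproducible given the spec.
#' @return Object of class `"cohort_spec"`.
#' @export
cohort_spec <- function(n_normal = 100, n_gastritis = 100, n_gc = 100,
                        n_im = 0, n_gc_adj = 0,
                        n_genes = 500,
                        planted_pairs = default_planted_pairs(),
                        noise_sd = 0.15,
                        purity = NULL,
                        gc_adj_purity = c(0.1, 0.3),
                        n_batches = 3,
                        bg_log_range = c(0, 16),
                        seed = 1L) {
  planted_pairs <- as.data.frame(planted_pairs, stringsAsFactors = FALSE)
  need <- c("gene_high", "gene_low", "delta_non", "delta_gc")
  if (!all(need %in% names(planted_pairs)))
    stop("planted_pairs needs columns ", paste(need, collapse = ", "))
  if (is.null(planted_pairs$baseline))
    planted_pairs$baseline <- mean(bg_log_range)
  if (any(planted_pairs$delta_non <= 0) || any(planted_pairs$delta_gc <= 0))
    stop("planted pair separations delta_non and delta_gc must be > 0")
  npp <- nrow(planted_pairs)
  if (n_genes < 2 * npp)
    stop(sprintf("infeasible spec: %d genes cannot host %d planted pairs",
                 n_genes, npp))
  if (is.null(purity)) {
    pool <- gc_tumor_purity[gc_tumor_purity >= 0.73]
    purity <- if (n_gc >= 2) c(0.08, rep_len(sort(pool), n_gc - 1L)) else 1
  }
  if (any(purity <= 0 | purity > 1))
    stop("purity values must lie in (0, 1]")
  if (length(gc_adj_purity) != 2 || any(gc_adj_purity <= 0) ||
      any(gc_adj_purity > 1) || gc_adj_purity[1] > gc_adj_purity[2])
    stop("gc_adj_purity must be an increasing range within (0, 1]")
  stopifnot(n_normal >= 0, n_gastritis >= 0, n_gc >= 0, n_im >= 0,
            n_gc_adj >= 0, n_batches >= 1, noise_sd >= 0)
  structure(
    list(n_per_class = c(NORMAL = n_normal, GASTRITIS = n_gastritis,
                         IM = n_im, GC = n_gc, GC_ADJ = n_gc_adj),
         n_genes = n_genes,
         planted_pairs = planted_pairs,
         noise_sd = noise_sd,
         purity = rep_len(purity, max(n_gc, 1L)),
         gc_adj_purity = gc_adj_purity,
         n_batches = n_batches,
         bg_log_range = bg_log_range,
         seed = as.integer(seed)),
    class = "cohort_spec")
}

#' Mix tumor and normal abundance profiles at a given purity
#'
#' Bulk expression of a specimen containing a fraction `p` of tumor cells
#' is modelled as the convex combination `p * tumor + (1 - p) * normal`,
#' taken in linear abundance space (signal adds over cells).
#'
#' @param tumor,normal Nonnegative abundance vectors of equal length.
#' @param p Tumor epithelial proportion in (0, 1].
#' @return Mixed abundance vector.
#' @export
mix_purity <- function(tumor, normal, p) {
  if (length(p) != 1 || !is.finite(p) || p <= 0 || p > 1)
    stop("purity p must be a single value in (0, 1]")
  if (length(tumor) != length(normal))
    stop("tumor and normal profiles must have the same length")
  if (any(tumor < 0) || any(normal < 0))
    stop("abundance profiles must be nonnegative")
  p * tumor + (1 - p) * normal
}

#' Construct a strictly increasing measurement distortion
#'
#' A composition of a power map and an affine map,
#' `f(x) = scale * x^power + shift`, strictly increasing on the positive
#' reals whenever `power > 0`, `scale > 0` and `shift >= 0`.  Used to model
#' platform/batch effects that rescale measurements without touching
#' within-sample orderings.
#'
#' @param power,scale,shift Distortion parameters.
#' @return Object of class `"monotone_distortion"`.
#' @export
monotone_distortion <- function(power = 1, scale = 1, shift = 0) {
  if (!is.finite(power) || power <= 0)
    stop("non-monotone parameterization: power must be > 0")
  if (!is.finite(scale) || scale <= 0)
    stop("non-monotone parameterization: scale must be > 0")
  if (!is.finite(shift) || shift < 0)
    stop("shift must be >= 0 to keep abundances nonnegative")
  structure(list(power = power, scale = scale, shift = shift),
            class = "monotone_distortion")
}

#' Draw a random monotone distortion
#'
#' Power in [0.5, 2], log-uniform scale in [0.5, 2], shift in [0, 1];
#' consumes the R RNG stream.
#'
#' @return `monotone_distortion` object.
#' @export
random_distortion <- function() {
  monotone_distortion(power = stats::runif(1, 0.5, 2),
                      scale = exp(stats::runif(1, log(0.5), log(2))),
                      shift = stats::runif(1, 0, 1))
}

#' Apply a monotone distortion to abundances
#'
#' @param x Nonnegative abundance vector (or matrix, distorted
#'   elementwise).
#' @param d `monotone_distortion` object.
#' @return Distorted values; within-sample orderings are unchanged.
#' @export
monotone_distort <- function(x, d) {
  stopifnot(inherits(d, "monotone_distortion"))
  if (any(x < 0)) stop("monotone_distort expects nonnegative abundances")
  d$scale * x^d$power + d$shift
}

#' Simulate a synthetic expression cohort
#'
#' Generative model: each gene has a class template on the latent log
#' scale — background genes draw one template shared by all classes,
#' planted pairs put the GC-high gene `delta_non/2` below its partner in
#' non-GC classes and `delta_gc/2` above it in tumor.  Per sample, latent
#' log-abundance = template + Normal(0, `noise_sd`), exponentiated to
#' linear abundance.  GC (and GC-adjacent) samples are purity-`p` linear
#' mixtures of an independent tumor and normal draw.  Finally every sample
#' is passed through its batch's strictly increasing distortion.
#'
#' @param spec A [cohort_spec()].
#' @return Object of class `"synthetic_cohort"`: list with `matrix`
#'   (expression matrix with batch attribute), `labels` (named class
#'   vector), `truth` (planted pairs), `purity` (named vector for GC and
#'   GC_ADJ samples), `spec`.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)

  pp <- spec$planted_pairs
  npp <- nrow(pp)
  planted_genes <- c(rbind(pp$gene_high, pp$gene_low))
  n_bg <- spec$n_genes - 2L * npp
  bg_genes <- sprintf("BG%04d", seq_len(n_bg))
  genes <- c(planted_genes, bg_genes)

  # class templates on the log scale; background genes fill the abundance
  # range as a jittered grid (a low-discrepancy stand-in for the smooth
  # empirical abundance spectrum: every expression stratum is populated,
  # and planted-pair rank gaps do not fluctuate with placement luck)
  lo <- spec$bg_log_range[1]; hi <- spec$bg_log_range[2]
  spacing <- (hi - lo) / n_bg
  mu_bg <- lo + (seq_len(n_bg) - 0.5) * spacing +
    stats::runif(n_bg, -spacing / 2, spacing / 2)
  mu_non <- c(rbind(pp$baseline - pp$delta_non / 2,
                    pp$baseline + pp$delta_non / 2), mu_bg)
  mu_gc  <- c(rbind(pp$baseline + pp$delta_gc / 2,
                    pp$baseline - pp$delta_gc / 2), mu_bg)
  names(mu_non) <- names(mu_gc) <- genes

  npc <- spec$n_per_class
  cls <- rep(names(npc), npc)
  n_tot <- length(cls)
  if (n_tot == 0) stop("empty cohort: all class sizes are zero")
  ids <- unlist(lapply(names(npc), function(k) {
    if (npc[[k]] == 0) return(character(0))
    sprintf("%s_%03d", k, seq_len(npc[[k]]))
  }), use.names = FALSE)

  G <- spec$n_genes
  sd <- spec$noise_sd
  draw <- function(mu) exp(mu + stats::rnorm(G, 0, sd))

  purity_gc <- rep_len(spec$purity, max(npc[["GC"]], 1L))
  purity_out <- numeric(0)
  vals <- matrix(0, nrow = G, ncol = n_tot, dimnames = list(genes, ids))
  i_gc <- 0L
  for (s in seq_len(n_tot)) {
    if (cls[s] %in% c("NORMAL", "GASTRITIS", "IM")) {
      vals[, s] <- draw(mu_non)
    } else {
      p <- if (cls[s] == "GC") {
        i_gc <- i_gc + 1L
        purity_gc[i_gc]
      } else {
        stats::runif(1, spec$gc_adj_purity[1], spec$gc_adj_purity[2])
      }
      vals[, s] <- mix_purity(draw(mu_gc), draw(mu_non), p)
      purity_out <- c(purity_out, stats::setNames(p, ids[s]))
    }
  }

  # batch-specific monotone measurement distortions, applied after mixing
  batch_idx <- rep_len(seq_len(spec$n_batches), n_tot)
  batch <- stats::setNames(sprintf("batch%d", batch_idx), ids)
  distortions <- replicate(spec$n_batches, random_distortion(),
                           simplify = FALSE)
  for (s in seq_len(n_tot))
    vals[, s] <- monotone_distort(vals[, s], distortions[[batch_idx[s]]])
  attr(vals, "batch") <- batch

  labels <- stats::setNames(cls, ids)
  truth <- pp
  truth$orientation_gc <- paste(pp$gene_high, ">", pp$gene_low)
  truth$orientation_non <- paste(pp$gene_low, ">", pp$gene_high)
  validate_expression_matrix(vals)
  structure(
    list(matrix = vals, labels = labels, truth = truth,
         purity = purity_out, batch = batch,
         distortions = distortions, spec = spec),
    class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic REO cohort:", nrow(x$matrix), "genes x",
      ncol(x$matrix), "samples\n")
  print(table(factor(x$labels, levels = tissue_classes)))
  cat("planted pairs:", nrow(x$truth),
      "| batches:", x$spec$n_batches,
      "| noise sd:", x$spec$noise_sd,
      "| seed:", x$spec$seed, "\n")
  invisible(x)
}
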