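# Stable-pair mining, consensus intersection, reversal detection.

test_that("stable_pairs emits an orientation only at or above threshold", {
  # g1 > g2 in all 4 samples
  m <- matrix(c(5, 1, 6, 2, 7, 3, 8, 4), nrow = 2,
              dimnames = list(c("g1", "g2"), paste0("s", 1:4)))
  labels <- all_one_class(m, "NORMAL")
  r <- rank_transform(m)
  sp <- stable_pairs(r, labels, "NORMAL", threshold = 0.99)
  expect_identical(nrow(sp), 1L)
  expect_identical(sp$gene_high, "g1")
  expect_equal(sp$support, 1)

  # 3 of 4 samples (0.75) is below 0.99
  m2 <- m; m2[, 4] <- c(1, 5)
  sp2 <- stable_pairs(rank_transform(m2), labels, "NORMAL", 0.99)
  expect_identical(nrow(sp2), 0L)
  # ... but passes a 0.75 threshold
  sp3 <- stable_pairs(rank_transform(m2), labels, "NORMAL", 0.75)
  expect_equal(sp3$support, 0.75)
})

test_that("stable_pairs agrees with the exhaustive double-loop oracle", {
  set.seed(31)
  m <- structured_matrix(10, 20)
  labels <- all_one_class(m, "GC")
  r <- rank_transform(m)
  got <- stable_pairs(r, labels, "GC", threshold = 0.9)
  want <- brute_stable_pairs(r, labels, "GC", 0.9)
  expect_gt(nrow(got), 0)
  expect_equal(as.data.frame(got), want, ignore_attr = TRUE)
})

test_that("ties count toward neither orientation", {
  m <- matrix(c(2, 2, 5, 1, 6, 3), nrow = 2,
              dimnames = list(c("a", "b"), paste0("s", 1:3)))
  r <- rank_transform(m)    # sample 1 is tied
  labels <- all_one_class(m, "GC")
  sp <- stable_pairs(r, labels, "GC", threshold = 0.9)
  expect_identical(nrow(sp), 0L)   # 2/3 wins < 0.9, tie is not a win
  sp2 <- stable_pairs(r, labels, "GC", threshold = 2 / 3)
  expect_equal(sp2$support, 2 / 3)
})

test_that("the 99% cut behaves exactly at small-n boundaries", {
  # n = 23: 99% requires all 23; n = 100: exactly 99 suffices
  mk <- function(n, n_flip) {
    m <- matrix(rep(c(2, 1), n), nrow = 2,
                dimnames = list(c("hi", "lo"), paste0("s", seq_len(n))))
    if (n_flip > 0) m[, seq_len(n_flip)] <- c(1, 2)
    m
  }
  lab <- function(m) all_one_class(m, "GC")
  expect_identical(nrow(stable_pairs(rank_transform(mk(23, 1)),
                                     lab(mk(23, 1)), "GC", 0.99)), 0L)
  expect_identical(nrow(stable_pairs(rank_transform(mk(23, 0)),
                                     lab(mk(23, 0)), "GC", 0.99)), 1L)
  sp <- stable_pairs(rank_transform(mk(100, 1)), lab(mk(100, 1)), "GC", 0.99)
  expect_identical(nrow(sp), 1L)
  expect_equal(sp$support, 0.99)
  expect_identical(nrow(stable_pairs(rank_transform(mk(100, 2)),
                                     lab(mk(100, 2)), "GC", 0.99)), 0L)
})

test_that("raising the threshold never adds pairs", {
  set.seed(17)
  m <- random_matrix(15, 12)
  labels <- all_one_class(m, "NORMAL")
  r <- rank_transform(m)
  prev <- NULL
  for (t in c(0.6, 0.75, 0.9, 1.0)) {
    cur <- stable_pairs(r, labels, "NORMAL", t)
    key <- paste(cur$gene_high, cur$gene_low)
    if (!is.null(prev)) expect_true(all(key %in% prev))
    prev <- paste(cur$gene_high, cur$gene_low)
  }
})

test_that("mining is invariant to gene and sample permutations", {
  set.seed(23)
  m <- random_matrix(12, 10)
  labels <- all_one_class(m, "GC")
  r <- rank_transform(m)
  base <- stable_pairs(r, labels, "GC", 0.8)
  mp <- m[sample(nrow(m)), sample(ncol(m))]
  perm <- stable_pairs(rank_transform(mp), labels, "GC", 0.8)
  expect_equal(as.data.frame(base), as.data.frame(perm))
})

test_that("stable_pairs validates its inputs", {
  m <- random_matrix(4, 4)
  r <- rank_transform(m)
  labels <- all_one_class(m, "GC")
  expect_error(stable_pairs(r, labels, "NORMAL", 0.9), "at least 2 samples")
  expect_error(stable_pairs(r, labels, "GC", 0.5), "threshold")
  expect_error(stable_pairs(r, labels, "GC", 1.01), "threshold")
  expect_error(stable_pairs(r, labels, "GC", 0.9,
                            candidates = data.frame(a = "nope", b = "G001")),
               "nope")
})

test_that("consensus keeps identically oriented pairs with min support", {
  mk_set <- function(df, genes) {
    structure(df, class = c("stable_pair_set", "data.frame"),
              class_tag = "NORMAL", threshold = 0.9, n_samples = 10,
              genes = genes)
  }
  genes <- c("a", "b", "c", "d")
  s1 <- mk_set(data.frame(gene_high = c("a", "c"), gene_low = c("b", "d"),
                          support = c(1, 0.95)), genes)
  s2 <- mk_set(data.frame(gene_high = c("a", "d"), gene_low = c("b", "c"),
                          support = c(0.9, 1)), genes)
  out <- consensus_stable_pairs(s1, s2)
  expect_identical(nrow(out), 1L)
  expect_identical(out$gene_high, "a")
  expect_equal(out$support, 0.9)   # minimum across inputs

  expect_equal(as.data.frame(consensus_stable_pairs(s1, s1)),
               as.data.frame(s1), ignore_attr = TRUE)

  s3 <- mk_set(data.frame(gene_high = "b", gene_low = "a", support = 1),
               genes)
  expect_identical(nrow(consensus_stable_pairs(s1, s3)), 0L)

  s4 <- mk_set(s1, c("a", "b", "c", "e"))
  expect_error(consensus_stable_pairs(s1, s4), "intersect_genes")
  expect_error(consensus_stable_pairs(s1), "at least 2")
})

test_that("reversal_pairs wants opposite stable orientations in both sets", {
  mk_set <- function(df, tag) {
    structure(df, class = c("stable_pair_set", "data.frame"),
              class_tag = tag, threshold = 0.99, n_samples = 20,
              genes = c("a", "b", "c", "d"))
  }
  non <- mk_set(data.frame(gene_high = c("b", "c"), gene_low = c("a", "d"),
                           support = c(1, 1)), "consensus")
  gc <- mk_set(data.frame(gene_high = c("a", "c"), gene_low = c("b", "d"),
                          support = c(0.99, 1)), "GC")
  rev <- reversal_pairs(non, gc)
  expect_identical(nrow(rev), 1L)          # (c > d) has the same REO: no
  expect_identical(rev$gene_high, "a")     # GC orientation reported
  expect_equal(rev$support_non, 1)
  expect_equal(rev$support_gc, 0.99)

  # stable only in GC: excluded
  gc2 <- mk_set(data.frame(gene_high = "d", gene_low = "a", support = 1),
                "GC")
  expect_identical(nrow(reversal_pairs(non, gc2)), 0L)
})

test_that("zero-noise planted cohorts yield exactly the planted reversals", {
  spec <- cohort_spec(n_normal = 20, n_gastritis = 20, n_gc = 20,
                      n_genes = 80, noise_sd = 0, purity = 1, seed = 12)
  co <- simulate_cohort(spec)
  r <- rank_transform(co$matrix)
  non <- consensus_stable_pairs(
    stable_pairs(r, co$labels, "NORMAL", 0.99),
    stable_pairs(r, co$labels, "GASTRITIS", 0.99))
  gcs <- stable_pairs(r, co$labels, "GC", 0.99)
  rev <- reversal_pairs(non, gcs)
  # background templates are class-invariant and noise-free, so only pairs
  # involving a planted gene can reverse; restrict to planted-x-planted
  planted <- unlist(co$truth[, c("gene_high", "gene_low")])
  both_planted <- rev$gene_high %in% planted & rev$gene_low %in% planted
  expect_setequal(
    paste(rev$gene_high[both_planted], rev$gene_low[both_planted]),
    paste(co$truth$gene_high, co$truth$gene_low))
  neither_planted <- !(rev$gene_high %in% planted) &
    !(rev$gene_low %in% planted)
  expect_false(any(neither_planted))   # no background-only false positives
})
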