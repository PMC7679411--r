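# Dependent-enhancer calling from paired coverage tracks.

gm <- genome_model("chr1", 1e5)

step_track <- function(start, end, value, genome = gm, chrom = "chr1") {
  crest:::granges_from_0based(rep(chrom, length(start)), start, end, genome,
                              score = value)
}

test_that("normalize_track scales linearly to the target total", {
  tr <- step_track(c(0, 100), c(100, 200), c(10, 30))
  out <- normalize_track(tr, 1000)
  expect_equal(total_signal(out), 1000, tolerance = 1e-9)
  expect_equal(S4Vectors::mcols(out)$score,
               c(10, 30) * 1000 / 4000)
  same <- normalize_track(tr, total_signal(tr))
  expect_equal(S4Vectors::mcols(same)$score, c(10, 30))
  zero <- step_track(0, 10, 0)
  expect_error(normalize_track(zero, 1000), "zero total")
})

test_that("mean_merge_tracks averages per-base values", {
  t1 <- step_track(0, 100, 2)
  t2 <- step_track(c(0, 50), c(50, 100), c(4, 6))
  merged <- mean_merge_tracks(list(t1, t2))
  iv1 <- crest:::granges_from_0based("chr1", 0, 50, gm)
  iv2 <- crest:::granges_from_0based("chr1", 50, 100, gm)
  expect_equal(signal_in_interval(merged, iv1), 3 * 50)
  expect_equal(signal_in_interval(merged, iv2), 4 * 50)
})

test_that("dependency_log2_ratio follows the closed form", {
  expect_equal(dependency_log2_ratio(100, 50, 0.001),
               log2(50.001 / 100.001))
  expect_equal(dependency_log2_ratio(37, 37), 0)
  expect_equal(dependency_log2_ratio(0, 0), 0)
  expect_error(dependency_log2_ratio(-1, 5), "non-negative")
  # monotonicity
  expect_true(dependency_log2_ratio(100, 40) < dependency_log2_ratio(100, 60))
  expect_true(dependency_log2_ratio(80, 40) < dependency_log2_ratio(60, 40))
})

test_that("classify_dependency is strict at the threshold", {
  expect_true(classify_dependency(-1.0))
  expect_false(classify_dependency(0.0))
  expect_false(classify_dependency(-0.5))   # exactly at threshold: not called
  expect_true(classify_dependency(-0.5001))
})

test_that("dependency call monotone in knockdown signal", {
  # lowering kd signal can only turn not-dependent into dependent
  kd <- seq(100, 0, by = -10)
  calls <- classify_dependency(dependency_log2_ratio(100, kd))
  expect_true(all(diff(as.integer(calls)) >= 0))
})

test_that("call_enhancers quantifies peaks and reports the fraction", {
  # three TF-bound peaks; kd halves two of them
  peaks <- crest:::granges_from_0based(rep("chr1", 3),
                                       c(1000, 3000, 5000),
                                       c(2000, 4000, 6000), gm)
  tf <- crest:::granges_from_0based(rep("chr1", 3),
                                    c(1400, 3400, 5400),
                                    c(1600, 3600, 5600), gm)
  ctrl <- step_track(c(1000, 3000, 5000, 8000),
                     c(2000, 4000, 6000, 98000),
                     c(0.1, 0.1, 0.1, 1e-3))
  kd <- step_track(c(1000, 3000, 5000, 8000),
                   c(2000, 4000, 6000, 98000),
                   c(0.02, 0.02, 0.1, 1e-3))
  tot <- 1e4
  calls <- call_enhancers(peaks, tf, normalize_track(ctrl, tot),
                          normalize_track(kd, tot), pseudocount = 0.01)
  expect_equal(nrow(calls), 3)
  expect_equal(sum(calls$dependent), 2)
  expect_equal(attr(calls, "dependent_fraction"), 2 / 3)

  # identical tracks: nothing dependent
  same <- call_enhancers(peaks, tf, normalize_track(ctrl, tot),
                         normalize_track(ctrl, tot))
  expect_equal(sum(same$dependent), 0)

  # no overlap with TF peaks: empty result
  far_tf <- crest:::granges_from_0based("chr1", 90000, 90100, gm)
  none <- call_enhancers(peaks, far_tf, normalize_track(ctrl, tot),
                         normalize_track(kd, tot))
  expect_equal(nrow(none), 0)

  # unnormalized tracks rejected
  expect_error(call_enhancers(peaks, tf, ctrl, kd), "normalize")
})

test_that("call_enhancers invariant to joint rescaling with renormalization", {
  peaks <- crest:::granges_from_0based("chr1", 1000, 2000, gm)
  tf <- crest:::granges_from_0based("chr1", 1400, 1600, gm)
  ctrl <- step_track(c(1000, 5000), c(2000, 50000), c(0.2, 0.01))
  kd <- step_track(c(1000, 5000), c(2000, 50000), c(0.05, 0.01))
  scale_track <- function(tr, f) {
    S4Vectors::mcols(tr)$score <- S4Vectors::mcols(tr)$score * f
    tr
  }
  a <- call_enhancers(peaks, tf, normalize_track(ctrl, 1e4),
                      normalize_track(kd, 1e4))
  b <- call_enhancers(peaks, tf, normalize_track(scale_track(ctrl, 7), 1e4),
                      normalize_track(scale_track(kd, 7), 1e4))
  expect_equal(a$log2_ratio, b$log2_ratio, tolerance = 1e-9)
  expect_equal(a$dependent, b$dependent)
})

test_that("direct-target calling follows nearest-TSS and window rules", {
  gm1 <- genome_model("chr1", 1e6)
  # specific gene with a dependent enhancer 10 kb upstream + TF peak inside;
  # canonical gene whose only nearby peak is non-dependent
  genes <- gene_annotation(c("geneS", "geneC", "geneFar"),
                           rep("chr1", 3), c(50000, 200000, 800000),
                           rep("+", 3), gm1)
  classes <- classify_genes(common = c("geneS", "geneC", "geneFar"),
                            inducible = c("geneC", "geneFar"))
  calls <- data.frame(
    chrom = c("chr1", "chr1"),
    start = c(39000, 190000), end = c(40000, 191000),
    control_signal = c(100, 100), kd_signal = c(30, 95),
    log2_ratio = c(log2(31 / 101), log2(96 / 101)),
    dependent = c(TRUE, FALSE))
  class(calls) <- c("dependency_calls", "data.frame")
  tf <- crest:::granges_from_0based(c("chr1", "chr1"), c(39400, 190400),
                                    c(39600, 190600), gm1)
  out <- call_direct_targets(genes, classes, calls, tf, gm1, window = 1e5)
  expect_true(out$is_direct[out$gene_id == "geneS"])
  expect_false(out$is_direct[out$gene_id == "geneC"])   # peak not dependent
  expect_false(out$is_direct[out$gene_id == "geneFar"]) # nothing in window
  expect_equal(out$n_dependent_peaks[out$gene_id == "geneS"], 1L)

  missing <- classify_genes("ghost", character(0))
  expect_error(call_direct_targets(genes, missing, calls, tf, gm1), "ghost")
})

test_that("mann_whitney worked examples and branches", {
  r <- mann_whitney(c(1, 2), c(3, 4))
  expect_equal(r$U, 0)
  expect_equal(r$p_value, 1 / 3, tolerance = 1e-12)
  expect_true(r$exact)

  same <- mann_whitney(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$U, 9 / 2)
  expect_gte(same$p_value, 0.99)
  expect_false(same$exact)   # ties force the approximate branch

  far <- mann_whitney(1:8, 101:108)
  expect_lt(far$p_value, 0.001)
  expect_error(mann_whitney(numeric(0), 1:3), "non-empty")

  # large-sample branch engaged above 16 observations
  big <- mann_whitney(seq(1, 40, by = 2.1), seq(2, 30, by = 1.7))
  expect_false(big$exact)
  expect_true(big$p_value >= 0 && big$p_value <= 1)
})
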