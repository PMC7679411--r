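# Interval/coverage data model, standard-format I/O, and interval algebra.

gm2 <- genome_model(c("chr1", "chr2"), c(1e5, 5e4))

test_that("genome model validates names and lengths", {
  expect_error(genome_model(c("chr1", "chr1"), c(10, 20)), "unique")
  expect_error(genome_model("chr1", 0), "positive")
  expect_equal(unname(chrom_lengths(gm2)), c(1e5, 5e4))
})

test_that("BED reading maps fields and rejects malformed lines", {
  f <- withr::local_tempfile()
  writeLines("chr1\t0\t100\tpkA", f)
  gr <- read_bed(f, gm2)
  expect_equal(GenomicRanges::start(gr), 1L)
  expect_equal(GenomicRanges::end(gr), 100L)
  expect_equal(S4Vectors::mcols(gr)$name, "pkA")

  writeLines(character(0), f)
  expect_length(read_bed(f, gm2), 0)

  writeLines("chr1\t100\t100", f)
  expect_error(read_bed(f, gm2), "line 1")
  writeLines(c("chr1\t0\t50", "chr1\tten\t20"), f)
  expect_error(read_bed(f, gm2), "line 2")
  writeLines("chrX\t0\t50", f)
  expect_error(read_bed(f, gm2), "chrX")
})

test_that("BED round trip preserves coordinates, names and scores", {
  f <- withr::local_tempfile()
  gr <- crest:::granges_from_0based(
    c("chr1", "chr1", "chr2"), c(0, 500, 7), c(100, 900, 49), gm2,
    name = c("a", "b", "c"), score = c(1.5, 2, 0.25))
  write_bed(gr, f)
  back <- read_bed(f, gm2)
  expect_identical(GenomicRanges::start(back), GenomicRanges::start(gr))
  expect_identical(GenomicRanges::end(back), GenomicRanges::end(gr))
  expect_identical(S4Vectors::mcols(back)$name, S4Vectors::mcols(gr)$name)
  expect_identical(S4Vectors::mcols(back)$score, S4Vectors::mcols(gr)$score)

  # 3-column set stays 3 columns
  gr3 <- crest:::granges_from_0based("chr1", 10, 20, gm2)
  write_bed(gr3, f)
  expect_identical(readLines(f), "chr1\t10\t20")
})

test_that("bedGraph reader enforces step semantics", {
  f <- withr::local_tempfile()
  writeLines("chr1\t0\t10\t2.0", f)
  tr <- read_bedgraph(f, gm2)
  expect_equal(total_signal(tr), 20)

  writeLines(c("chr1\t0\t5\t1", "chr1\t5\t10\t3"), f)
  expect_equal(total_signal(read_bedgraph(f, gm2)), 20)

  writeLines(c("chr1\t0\t6\t1", "chr1\t5\t10\t3"), f)
  expect_error(read_bedgraph(f, gm2), "overlap")
  writeLines("chr1\t0\t10\t-1", f)
  expect_error(read_bedgraph(f, gm2), "negative")
})

test_that("bedGraph round trip is lossless", {
  f <- withr::local_tempfile()
  tr <- crest:::granges_from_0based(
    c("chr1", "chr1"), c(0, 10), c(10, 30), gm2, score = c(1.25, 3.5))
  write_bedgraph(tr, f)
  back <- read_bedgraph(f, gm2)
  expect_identical(GenomicRanges::start(back), GenomicRanges::start(tr))
  expect_identical(S4Vectors::mcols(back)$score, S4Vectors::mcols(tr)$score)
})

test_that("merge_intervals honours the gap threshold", {
  m <- crest:::granges_from_0based(c("chr1", "chr1"), c(0, 10), c(10, 20), gm2)
  expect_equal(GenomicRanges::width(merge_intervals(m, 0)), 20)
  m2 <- crest:::granges_from_0based(c("chr1", "chr1"), c(0, 15), c(10, 20), gm2)
  expect_length(merge_intervals(m2, 0), 2)
  expect_length(merge_intervals(m2, 4), 2)
  expect_length(merge_intervals(m2, 5), 1)
  expect_equal(covered_bases(merge_intervals(m2, 5)), 20)
})

test_that("half-open convention: [a,b) and [b,c) never intersect", {
  a <- crest:::granges_from_0based("chr1", 0, 10, gm2)
  b <- crest:::granges_from_0based("chr1", 10, 20, gm2)
  expect_equal(intersect_bases(a, b), 0)
  expect_length(overlapping_subset(a, b), 0)
})

test_that("intersect/union worked examples", {
  a <- crest:::granges_from_0based("chr1", 0, 100, gm2)
  b <- crest:::granges_from_0based("chr1", 50, 150, gm2)
  expect_equal(intersect_bases(a, b), 50)
  expect_equal(union_bases(a, b), 150)
  expect_equal(intersect_bases(a, a), 100)
  expect_equal(union_bases(b, b), 100)
})

test_that("overlapping_subset retains whole intervals, never clips", {
  a <- crest:::granges_from_0based("chr1", 0, 10, gm2)
  b <- crest:::granges_from_0based("chr1", 5, 6, gm2)
  out <- overlapping_subset(a, b)
  expect_equal(GenomicRanges::width(out), 10)
})

test_that("nearest_tss uses edge distance and deterministic tie-break", {
  genes <- gene_annotation(c("g1", "g2"), c("chr1", "chr1"), c(300, 1000),
                           c("+", "+"), gm2)
  iv <- crest:::granges_from_0based("chr1", 100, 200, gm2)
  hit <- nearest_tss(iv, genes, 500)
  expect_equal(hit$gene_id, "g1")
  expect_equal(hit$distance, 101)

  inside <- gene_annotation("g3", "chr1", 150, "+", gm2)
  expect_equal(nearest_tss(iv, inside, 500)$distance, 0)
  expect_null(nearest_tss(iv, genes, 100))

  tie <- gene_annotation(c("gB", "gA"), c("chr1", "chr1"), c(250, 50),
                         c("+", "+"), gm2)
  expect_equal(nearest_tss(iv, tie, 500)$gene_id, "gA")  # both distance 51
})

test_that("signal_in_interval is additive over partitions", {
  tr <- crest:::granges_from_0based(c("chr1", "chr1"), c(0, 10), c(10, 30),
                                    gm2, score = c(1, 3))
  iv <- crest:::granges_from_0based("chr1", 5, 15, gm2)
  expect_equal(signal_in_interval(tr, iv), 20)
  left <- crest:::granges_from_0based("chr1", 5, 9, gm2)
  right <- crest:::granges_from_0based("chr1", 9, 15, gm2)
  expect_equal(signal_in_interval(tr, left) + signal_in_interval(tr, right),
               20)
  outside <- crest:::granges_from_0based("chr2", 0, 100, gm2)
  expect_equal(signal_in_interval(tr, outside), 0)
})

test_that("subtract_intervals removes exactly the excluded bases", {
  a <- crest:::granges_from_0based("chr1", 0, 100, gm2)
  bl <- crest:::granges_from_0based("chr1", 40, 60, gm2)
  out <- subtract_intervals(a, bl)
  expect_equal(covered_bases(out), 80)
  expect_equal(intersect_bases(out, bl), 0)
})

test_that("interval algebra matches the per-base oracle on random cases", {
  tg <- toy_genome(c(chrA = 8000, chrB = 2000))
  set.seed(4242)
  for (rep in seq_len(100)) {
    da <- random_intervals(tg$lens)
    db <- random_intervals(tg$lens)
    ca <- pb_cover(da, tg$lens)
    cb <- pb_cover(db, tg$lens)
    ga <- df_to_granges(da, tg$model)
    gb <- df_to_granges(db, tg$model)
    expect_equal(intersect_bases(ga, gb), pb_intersect_bases(ca, cb))
    expect_equal(union_bases(ga, gb), pb_union_bases(ca, cb))
    gap <- sample(0:30, 1)
    expect_equal(covered_bases(merge_intervals(ga, gap)),
                     pb_bases(pb_merge(ca, gap)))
    keep <- pb_overlap_rows(da, cb)
    expect_equal(length(overlapping_subset(ga, gb)), sum(keep))
  }
})

test_that("intersect/union are symmetric and fragmentation-invariant", {
  tg <- toy_genome()
  set.seed(7)
  for (rep in seq_len(25)) {
    da <- random_intervals(tg$lens, 20)
    db <- random_intervals(tg$lens, 20)
    ga <- df_to_granges(da, tg$model)
    gb <- df_to_granges(db, tg$model)
    expect_equal(intersect_bases(ga, gb), intersect_bases(gb, ga))
    expect_equal(union_bases(ga, gb), union_bases(gb, ga))
    # split the first interval of a into two abutting halves
    if (da$end[1] - da$start[1] >= 2) {
      mid <- da$start[1] + 1
      dsplit <- rbind(
        data.frame(chrom = da$chrom[1], start = c(da$start[1], mid),
                   end = c(mid, da$end[1])),
        da[-1, ])
      gs <- df_to_granges(dsplit, tg$model)
      expect_equal(intersect_bases(gs, gb), intersect_bases(ga, gb))
      expect_equal(union_bases(gs, gb), union_bases(ga, gb))
    }
  }
})

test_that("signal quantification matches the per-base oracle", {
  tg <- toy_genome(c(chrA = 3000))
  set.seed(11)
  for (rep in seq_len(30)) {
    # random disjoint steps
    cuts <- sort(sample(0:3000, 20))
    cuts <- unique(cuts)
    steps <- data.frame(chrom = "chrA", start = head(cuts, -1),
                        end = cuts[-1],
                        value = round(runif(length(cuts) - 1) * 5, 2))
    steps <- steps[steps$end > steps$start, ]
    tr <- crest:::granges_from_0based(steps$chrom, steps$start, steps$end,
                                      tg$model, score = steps$value)
    sig <- pb_signal_vec(steps, tg$lens)
    s0 <- sample(0:2900, 1)
    e0 <- s0 + sample(1:100, 1)
    iv <- crest:::granges_from_0based("chrA", s0, e0, tg$model)
    expect_equal(signal_in_interval(tr, iv), pb_signal_in(sig, "chrA", s0, e0),
                 tolerance = 1e-12)
  }
})
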