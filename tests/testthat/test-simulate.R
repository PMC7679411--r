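# Seeded generators: planted structure, ground truth, determinism.

cfg_small <- sim_config(seed = 12, n_genes = 400, n_canonical = 20,
                        n_specific = 10, n_inducible_only = 30,
                        n_enhancers = 60, n_canonical_direct = 15,
                        n_specific_direct = 5, n_samples = 60)

test_that("sim_config validates its fields", {
  expect_error(sim_config(n_genes = 50, n_canonical = 40, n_specific = 20),
               "exceed")
  expect_error(sim_config(dependent_fraction = 1.5), "dependent_fraction")
  expect_error(sim_config(cofactors = c(A = 2)), "Jaccard")
  expect_error(sim_config(n_canonical_direct = 88), "exceed class sizes")
  expect_error(sim_config(n_samples = 5), "at least 10")
})

test_that("make_contrasts plants recoverable classes with exact truth", {
  con <- make_contrasts(cfg_small)
  expect_length(con$kd, 3)
  expect_length(con$ind, 2)
  cl <- classify_genes(common_downstream(con$kd), inducible_union(con$ind))
  truth <- con$truth
  expect_setequal(cl$canonical, truth$gene_id[truth$class == "canonical"])
  expect_setequal(cl$specific, truth$gene_id[truth$class == "specific"])
  expect_true("NOTCH3_like" %in% cl$specific)

  none <- make_contrasts(sim_config(seed = 3, n_genes = 100,
                                    n_canonical = 5, n_specific = 0,
                                    n_inducible_only = 10,
                                    n_specific_direct = 0,
                                    n_canonical_direct = 5))
  cl0 <- classify_genes(common_downstream(none$kd),
                        inducible_union(none$ind))
  expect_length(cl0$specific, 0)
})

test_that("make_contrasts is deterministic given the config", {
  a <- make_contrasts(cfg_small)
  b <- make_contrasts(cfg_small)
  expect_identical(a, b)
  c <- make_contrasts(sim_config(seed = 13, n_genes = 400, n_canonical = 20,
                                 n_specific = 10, n_inducible_only = 30,
                                 n_enhancers = 60, n_canonical_direct = 15,
                                 n_specific_direct = 5))
  expect_false(identical(a$kd[[1]]$p_adj, c$kd[[1]]$p_adj))
})

test_that("make_epigenome plants exact noise-free dependency structure", {
  cfg0 <- sim_config(seed = 5, noise = FALSE)
  epi <- make_epigenome(cfg0)
  ctrl <- normalize_track(epi$control_track, 1e6)
  kd <- normalize_track(epi$kd_track, 1e6)
  calls <- call_enhancers(epi$h3k27ac_peaks, epi$tf_peaks, ctrl, kd)
  truth <- epi$truth_enhancers
  key <- paste(calls$chrom, calls$start, calls$end)
  tkey <- paste(truth$chrom, truth$start, truth$end)
  expect_setequal(key, tkey)
  dep_true <- truth$dependent[match(key, tkey)]
  expect_identical(calls$dependent, dep_true)   # sens = spec = 1 exactly

  # NOTCH3-like geometry: dependent TF-bound peak ~10 kb upstream of TSS
  n3 <- truth[truth$gene_id == "NOTCH3_like", ]
  expect_true(n3$dependent)
  g3 <- epi$truth_genes[epi$truth_genes$gene_id == "NOTCH3_like", ]
  dist <- g3$tss - n3$end + 1
  expect_gt(dist, 9000)
  expect_lt(dist, 10100)
})

test_that("epigenome gene/class bookkeeping matches the config", {
  epi <- make_epigenome(cfg_small)
  tg <- epi$truth_genes
  expect_equal(sum(tg$class == "canonical" & tg$direct), 15)
  expect_equal(sum(tg$class == "specific" & tg$direct), 5)
  expect_equal(sum(tg$class == "canonical"), 20)
  expect_equal(sum(tg$class == "specific"), 10)
  expect_equal(nrow(epi$truth_enhancers), 60)
  expect_equal(sum(epi$truth_enhancers$dependent), 30)
  # every enhancer's nearest TSS is the planted gene
  gr <- crest:::granges_from_0based(epi$truth_enhancers$chrom,
                                    epi$truth_enhancers$start,
                                    epi$truth_enhancers$end, epi$genome)
  asg <- crest:::assign_nearest_tss(gr, epi$genes, 1e5)
  expect_identical(asg$gene_id, epi$truth_enhancers$gene_id)
})

test_that("cofactor catalog realizes its planted jaccards", {
  epi <- make_epigenome(cfg_small)
  ref <- reference_set(epi$tf_peaks, epi$h3k27ac_peaks)
  cof <- make_cofactor_catalog(cfg_small, ref, epi$genome)
  expect_setequal(names(cof$catalog), names(cfg_small$cofactors))
  for (i in seq_len(nrow(cof$truth))) {
    expect_lt(abs(cof$truth$realized_jaccard[i] -
                    cof$truth$target_jaccard[i]), 0.02)
  }
  # extremes
  ext <- sim_config(seed = 2, cofactors = c(SAME = 1, NONE = 0))
  ce <- make_cofactor_catalog(ext, ref, epi$genome)
  expect_equal(jaccard_index(ce$catalog$SAME, ref), 1)
  expect_equal(jaccard_index(ce$catalog$NONE, ref), 0)
})

test_that("cohort generator links genes to the latent activity", {
  coh <- make_cohort(cfg_small)
  expect_equal(dim(coh$matrix),
               c(6 + 1 + cfg_small$n_null_cohort, cfg_small$n_samples))
  # noise-free limit: score ranking equals activity ranking
  clean <- make_cohort(sim_config(seed = 9, n_samples = 50,
                                  noise_sd = 1e-6))
  sc <- activity_score(zscore_by_gene(clean$matrix))
  expect_identical(order(sc$score), order(clean$truth$activity))
})

test_that("written simulation bundles are byte-identical across runs", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_simulation(cfg_small, d1)
  write_simulation(cfg_small, d2)
  f1 <- sort(list.files(d1))
  expect_identical(f1, sort(list.files(d2)))
  for (f in f1) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), info = f)
  }
  # truth files are readable and consistent with the planted counts
  tg <- read.delim(file.path(d1, "truth_genes_contrasts.tsv"))
  expect_equal(sum(tg$class == "canonical"), 20)
  expect_equal(sum(tg$class == "specific"), 10)
})
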