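#' Simulation configuration
#'
#' One object collects every knob of the seeded generators. Defaults emulate
#' the study design the pipeline targets: three knockdown and two induction
#' expression contrasts sharing a planted common-downstream set of 123 genes
#' (87 canonical + 36 context-specific) among 10,000 genes; a 2 x 1 Mb
#' genome with 200 TF-bound H3K27ac peaks, half of them TF-dependent with a
#' true knockdown/control signal ratio of 0.4 under Poisson coverage noise;
#' a four-factor cofactor catalog with planted base-pair Jaccard values; and
#' a 503-sample tumor cohort whose six signature genes and one query gene
#' co-vary with a latent activity. A designated "NOTCH3-like"
#' context-specific gene receives a dependent TF-bound enhancer 10 kb
#' upstream of its TSS.
#'
#' @param seed Integer master seed; each generator derives its own stream
#'   from it, and identical configs give byte-identical outputs.
#' @param genome Named numeric vector of chromosome lengths.
#' @param n_genes,n_canonical,n_specific,n_inducible_only Gene universe for
#'   the contrast generator; planted counts must not exceed `n_genes`.
#' @param alpha Significance level used when planting p-values.
#' @param effect_log2fc Mean absolute log2 fold change of responsive genes.
#' @param flip_rate Fraction of per-table responsive calls flipped at
#'   random (0 disables).
#' @param n_enhancers Number of TF-bound H3K27ac peaks.
#' @param dependent_fraction Fraction of enhancers planted TF-dependent.
#' @param kd_ratio True knockdown/control signal ratio of dependent
#'   enhancers (0.4 corresponds to a true log2 ratio of about -1.32).
#' @param mean_control_signal Mean total control signal per peak (Poisson).
#' @param background_level Per-base background coverage outside peaks.
#' @param noise Poisson-sample the coverage? `FALSE` gives exact levels.
#' @param n_canonical_direct,n_specific_direct How many genes of each class
#'   receive a dependent TF-bound enhancer near their TSS.
#' @param cofactors Named numeric vector of target Jaccard indices.
#' @param n_samples,effect_signature,effect_query,noise_sd,n_null_cohort
#'   Cohort size, signature and query effect sizes, noise standard
#'   deviation, and number of pure-noise genes for the cohort generator.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(seed = 1,
                       genome = c(chr1 = 1e6, chr2 = 1e6),
                       n_genes = 10000,
                       n_canonical = 87,
                       n_specific = 36,
                       n_inducible_only = 500,
                       alpha = 0.05,
                       effect_log2fc = 2,
                       flip_rate = 0,
                       n_enhancers = 200,
                       dependent_fraction = 0.5,
                       kd_ratio = 0.4,
                       mean_control_signal = 100,
                       background_level = 1,
                       noise = TRUE,
                       n_canonical_direct = 77,
                       n_specific_direct = 21,
                       cofactors = c(GATA3 = 0.60, MAFK = 0.40,
                                     PBX3 = 0.20, CEBPB = 0.05),
                       n_samples = 503,
                       effect_signature = 1,
                       effect_query = 1,
                       noise_sd = 1,
                       n_null_cohort = 20) {
  cfg <- list(seed = as.integer(seed), genome = genome, n_genes = n_genes,
              n_canonical = n_canonical, n_specific = n_specific,
              n_inducible_only = n_inducible_only, alpha = alpha,
              effect_log2fc = effect_log2fc, flip_rate = flip_rate,
              n_enhancers = n_enhancers,
              dependent_fraction = dependent_fraction, kd_ratio = kd_ratio,
              mean_control_signal = mean_control_signal,
              background_level = background_level, noise = noise,
              n_canonical_direct = n_canonical_direct,
              n_specific_direct = n_specific_direct, cofactors = cofactors,
              n_samples = n_samples, effect_signature = effect_signature,
              effect_query = effect_query, noise_sd = noise_sd,
              n_null_cohort = n_null_cohort)
  counts <- c(cfg$n_genes, cfg$n_canonical, cfg$n_specific,
              cfg$n_inducible_only, cfg$n_enhancers, cfg$n_samples,
              cfg$n_null_cohort, cfg$n_canonical_direct,
              cfg$n_specific_direct)
  if (any(counts < 0)) stop("all counts must be non-negative")
  if (cfg$n_canonical + cfg$n_specific + cfg$n_inducible_only > cfg$n_genes) {
    stop("planted gene counts exceed the gene universe")
  }
  if (cfg$dependent_fraction < 0 || cfg$dependent_fraction > 1) {
    stop("dependent_fraction must lie in [0, 1]")
  }
  if (any(cfg$cofactors < 0 | cfg$cofactors > 1)) {
    stop("target Jaccard values must lie in [0, 1]")
  }
  if (cfg$n_canonical_direct > cfg$n_canonical ||
      cfg$n_specific_direct > cfg$n_specific) {
    stop("direct-target counts exceed class sizes")
  }
  n_direct <- cfg$n_canonical_direct + cfg$n_specific_direct
  if (n_direct > round(cfg$n_enhancers * cfg$dependent_fraction)) {
    stop("not enough dependent enhancers for the requested direct targets")
  }
  if (cfg$n_samples < 10) stop("cohort size must be at least 10")
  class(cfg) <- "sim_config"
  cfg
}

# Shared gene universe so contrasts, epigenome and cohort agree on ids.
# The designated NOTCH3-like gene is always the first specific gene.
sim_gene_ids <- function(config) {
  n_null <- config$n_genes - config$n_canonical - config$n_specific
  specific <- if (config$n_specific >= 1) {
    c("NOTCH3_like",
      if (config$n_specific > 1) sprintf("SPEC_%03d", 2:config$n_specific))
  } else character(0)
  list(
    canonical = if (config$n_canonical > 0)
      sprintf("CANON_%03d", seq_len(config$n_canonical)) else character(0),
    specific = specific,
    null = if (n_null > 0) sprintf("NULL_%05d", seq_len(n_null))
           else character(0)
  )
}

# Significant p-values drawn from Beta(0.1, 20) truncated below alpha via
# the inverse-CDF so no rejection loop is needed.
rtrunc_beta <- function(n, alpha) {
  stats::qbeta(stats::runif(n) * stats::pbeta(alpha, 0.1, 20), 0.1, 20)
}

#' Generate knockdown and induction contrast tables with planted classes
#'
#' Canonical genes are significantly down in every knockdown table and up
#' in at least one induction table; specific genes are down in every
#' knockdown table but never induction-responsive; a block of
#' inducible-only genes is up in induction tables without being knockdown
#' responsive; the remaining null genes carry uniform p-values floored
#' above alpha. Optionally a fraction of per-table calls is flipped to
#' emulate call noise.
#'
#' @param config A [sim_config()].
#' @return List with `kd` (3 knockdown `contrast_table`s), `ind` (2
#'   induction tables), and `truth` (data.frame `gene_id`, `class`).
#' @export
make_contrasts <- function(config) {
  ids <- sim_gene_ids(config)
  genes <- c(ids$canonical, ids$specific, ids$null)
  n <- length(genes)
  class_of <- rep(c("canonical", "specific", "null"),
                  c(length(ids$canonical), length(ids$specific),
                    length(ids$null)))
  inducible_only <- ids$null[seq_len(min(config$n_inducible_only,
                                         length(ids$null)))]
  kd_ctx <- c("A549", "H460", "H2023")
  ind_ctx <- c("ABC1", "HCC4006")
  local_seed(config$seed + 11L, {
    resp_kd <- matrix(class_of %in% c("canonical", "specific"),
                      nrow = n, ncol = 3)
    resp_ind <- matrix(FALSE, nrow = n, ncol = 2)
    up_pool <- class_of == "canonical" | genes %in% inducible_only
    for (j in 1:2) resp_ind[, j] <- up_pool & stats::runif(n) < 0.7
    none <- which(up_pool & !resp_ind[, 1] & !resp_ind[, 2])
    pick <- stats::runif(length(none)) < 0.5
    resp_ind[none[pick], 1] <- TRUE
    resp_ind[none[!pick], 2] <- TRUE
    if (config$flip_rate > 0) {
      for (j in 1:3) {
        fl <- stats::runif(n) < config$flip_rate
        resp_kd[fl, j] <- !resp_kd[fl, j]
      }
      for (j in 1:2) {
        fl <- stats::runif(n) < config$flip_rate
        resp_ind[fl, j] <- !resp_ind[fl, j]
      }
    }
    fill_table <- function(resp, direction, context, kind) {
      p <- numeric(n)
      lfc <- numeric(n)
      nr <- sum(resp)
      p[resp] <- rtrunc_beta(nr, config$alpha)
      p[!resp] <- config$alpha +
        (1 - config$alpha) * stats::runif(n - nr)
      lfc[resp] <- direction *
        pmax(0.5, config$effect_log2fc + stats::rnorm(nr, 0, 0.3))
      lfc[!resp] <- stats::rnorm(n - nr, 0, 0.5)
      contrast_table(genes, lfc, pmin(p, 1), context, kind)
    }
    kd <- lapply(1:3, function(j) fill_table(resp_kd[, j], -1,
                                             kd_ctx[j], "knockdown"))
    ind <- lapply(1:2, function(j) fill_table(resp_ind[, j], +1,
                                              ind_ctx[j], "induction"))
    list(kd = kd, ind = ind,
         truth = data.frame(gene_id = genes, class = class_of,
                            stringsAsFactors = FALSE))
  })
}

#' Generate a synthetic epigenome with planted dependent enhancers
#'
#' Places TF-bound H3K27ac peaks (500-2000 bp) in disjoint slots across the
#' genome, plants a configured fraction as TF-dependent (true knockdown
#' signal = `kd_ratio` x control), simulates Poisson coverage around the
#' true per-base levels, and lays out gene TSSs so that every peak's
#' nearest TSS is the gene it was planted for. Direct-target genes of both
#' classes sit next to dependent peaks; the remaining classified genes sit
#' next to independent peaks; leftover peaks belong to unclassified filler
#' genes. The NOTCH3-like gene gets its dependent peak 10 kb upstream of
#' its TSS, with empty flanking slots so the assignment is unambiguous.
#'
#' @param config A [sim_config()].
#' @return List with `genome`, `genes` (annotation data.frame), `tf_peaks`,
#'   `h3k27ac_peaks` (`GRanges`), `control_track`, `kd_track` (`GRanges`
#'   coverage), `truth_enhancers`, `truth_genes`.
#' @export
make_epigenome <- function(config) {
  genome <- genome_model(names(config$genome), config$genome)
  chroms <- names(config$genome)
  n_chr <- length(chroms)
  n_enh <- config$n_enhancers
  per_chr <- diff(round(seq(0, n_enh, length.out = n_chr + 1)))
  extra_slots <- c(2L, rep(0L, n_chr - 1))  # NOTCH3 flanks live on chrom 1
  slot_counts <- per_chr + extra_slots
  slot_width <- floor(config$genome / slot_counts)
  if (any(slot_width < 8800)) {
    stop("infeasible placement: genome too small for the requested enhancers")
  }

  local_seed(config$seed + 23L, {
    # choose the NOTCH3 slot on chromosome 1 with empty flanks
    k <- sample(2:(slot_counts[1] - 1), 1)
    slot_tab <- do.call(rbind, lapply(seq_len(n_chr), function(ci) {
      idx <- seq_len(slot_counts[ci])
      keep <- if (ci == 1) setdiff(idx, c(k - 1, k + 1)) else idx
      data.frame(chrom = chroms[ci],
                 slot_start = (keep - 1) * slot_width[ci],
                 is_notch3 = (ci == 1) & (keep == k),
                 stringsAsFactors = FALSE)
    }))
    stopifnot(nrow(slot_tab) == n_enh)

    jitter <- sample(-1000:1000, n_enh, replace = TRUE)
    widths <- sample(500:2000, n_enh, replace = TRUE)
    center <- slot_tab$slot_start + 3000 + jitter
    peak_start0 <- center - floor(widths / 2)
    peak_end <- peak_start0 + widths
    tss <- ifelse(slot_tab$is_notch3, center + 10000, center + 3000)

    # planted labels: dependent peaks host the direct-target genes
    n_dep <- round(n_enh * config$dependent_fraction)
    notch3_i <- which(slot_tab$is_notch3)
    if (n_dep < 1) stop("at least one dependent enhancer is required")
    others <- sample(setdiff(seq_len(n_enh), notch3_i))
    dep_idx <- c(notch3_i, others[seq_len(n_dep - 1)])
    indep_idx <- setdiff(others, dep_idx)
    dependent <- seq_len(n_enh) %in% dep_idx

    ids <- sim_gene_ids(config)
    spec_direct <- c("NOTCH3_like",
                     setdiff(ids$specific, "NOTCH3_like")[
                       seq_len(config$n_specific_direct - 1)])
    canon_direct <- ids$canonical[seq_len(config$n_canonical_direct)]
    spec_nondirect <- setdiff(ids$specific, spec_direct)
    canon_nondirect <- setdiff(ids$canonical, canon_direct)
    direct_ids <- c(spec_direct[-1], canon_direct)  # NOTCH3 pinned below
    dep_rest <- setdiff(dep_idx, notch3_i)
    if (length(direct_ids) > length(dep_rest)) {
      stop("not enough dependent enhancers for the requested direct targets")
    }
    gene_at <- rep(NA_character_, n_enh)
    gene_at[notch3_i] <- "NOTCH3_like"
    gene_at[dep_rest[seq_along(direct_ids)]] <- direct_ids
    nondirect_ids <- c(spec_nondirect, canon_nondirect)
    if (length(nondirect_ids) > length(indep_idx)) {
      stop("not enough independent enhancers for the non-direct genes")
    }
    gene_at[indep_idx[seq_along(nondirect_ids)]] <- nondirect_ids
    open <- which(is.na(gene_at))
    gene_at[open] <- sprintf("NULL_%05d", seq_along(open))

    genes <- gene_annotation(gene_at, slot_tab$chrom, tss,
                             rep("+", n_enh), genome)

    h3k27ac <- granges_from_0based(slot_tab$chrom, peak_start0, peak_end,
                                   genome, name = gene_at,
                                   what = "planted peaks")
    tf <- granges_from_0based(slot_tab$chrom, center - 100, center + 100,
                              genome, what = "planted TF peaks")

    tracks <- simulate_tracks(slot_tab$chrom, peak_start0, peak_end,
                              dependent, config, genome)

    cls <- ifelse(gene_at %in% ids$canonical, "canonical",
           ifelse(gene_at %in% ids$specific, "specific", "null"))
    truth_genes <- data.frame(
      gene_id = gene_at, class = cls,
      direct = gene_at %in% c(spec_direct, canon_direct),
      chrom = slot_tab$chrom, tss = tss, stringsAsFactors = FALSE)
    truth_enh <- data.frame(
      chrom = slot_tab$chrom, start = peak_start0, end = peak_end,
      dependent = dependent, gene_id = gene_at, stringsAsFactors = FALSE)

    list(genome = genome, genes = genes, tf_peaks = tf,
         h3k27ac_peaks = h3k27ac,
         control_track = tracks$control, kd_track = tracks$kd,
         truth_enhancers = truth_enh, truth_genes = truth_genes)
  })
}

# Poisson (or exact) coverage for control and knockdown conditions: peak
# regions carry the planted signal in fine bins, the rest of the genome a
# low background in coarse bins. Consumes RNG; caller fixes the seed.
simulate_tracks <- function(chrom, peak_start0, peak_end, dependent,
                            config, genome) {
  widths <- peak_end - peak_start0
  lam_ctrl <- config$mean_control_signal / widths  # per-base control level
  bin <- 50L
  bg_bin <- 1000L

  sample_steps <- function(level_per_base, s0, e1, binw) {
    # chop [s0, e1) into bins of binw and draw one value per bin
    starts <- seq(s0, e1 - 1L, by = binw)
    ends <- pmin(starts + binw, e1)
    w <- ends - starts
    v <- if (config$noise) {
      stats::rpois(length(w), level_per_base * w) / w
    } else {
      rep(level_per_base, length(w))
    }
    list(start = starts, end = ends, value = v)
  }

  build <- function(cond) {
    s_all <- integer(0); e_all <- integer(0); v_all <- numeric(0)
    ch_all <- character(0)
    for (i in seq_along(chrom)) {
      lv <- if (cond == "control" || !dependent[i]) lam_ctrl[i]
            else lam_ctrl[i] * config$kd_ratio
      st <- sample_steps(lv, peak_start0[i], peak_end[i], bin)
      ch_all <- c(ch_all, rep(chrom[i], length(st$start)))
      s_all <- c(s_all, st$start); e_all <- c(e_all, st$end)
      v_all <- c(v_all, st$value)
    }
    # background over the complement of the peaks
    lens <- GenomeInfoDb::seqlengths(genome)
    for (ch in names(lens)) {
      in_ch <- chrom == ch
      bounds <- sort(c(0, peak_start0[in_ch], peak_end[in_ch], lens[[ch]]))
      gap_s <- bounds[seq(1, length(bounds), by = 2)]
      gap_e <- bounds[seq(2, length(bounds), by = 2)]
      keep <- gap_e > gap_s
      for (g in which(keep)) {
        st <- sample_steps(config$background_level, gap_s[g], gap_e[g],
                           bg_bin)
        ch_all <- c(ch_all, rep(ch, length(st$start)))
        s_all <- c(s_all, st$start); e_all <- c(e_all, st$end)
        v_all <- c(v_all, st$value)
      }
    }
    granges_from_0based(ch_all, s_all, e_all, genome, score = v_all,
                        what = "simulated track")
  }

  list(control = build("control"), kd = build("kd"))
}

#' Generate cofactor peak sets with planted Jaccard indices
#'
#' For each factor with target Jaccard `j`, a fraction of reference bases
#' is copied (splitting the last interval to hit the base count exactly)
#' and disjoint filler intervals are added elsewhere in the genome so that
#' the realized base-pair Jaccard against the reference matches `j`
#' (recorded in the ground truth; within 0.02 of the target).
#'
#' @param config A [sim_config()] whose `cofactors` field names the factors
#'   and their target Jaccard indices.
#' @param reference `GRanges` reference set (non-empty).
#' @param genome Genome model.
#' @return List with `catalog` (named list of `GRanges`) and `truth`
#'   (data.frame `factor`, `target_jaccard`, `realized_jaccard`).
#' @export
make_cofactor_catalog <- function(config, reference, genome) {
  if (length(reference) == 0) stop("reference set is empty")
  ref <- merge_intervals(reference)
  r_bases <- covered_bases(ref)
  local_seed(config$seed + 37L, {
    catalog <- list()
    truth <- data.frame(factor = character(0), target_jaccard = numeric(0),
                        realized_jaccard = numeric(0),
                        stringsAsFactors = FALSE)
    for (nm in names(config$cofactors)) {
      j <- config$cofactors[[nm]]
      if (j >= 1) {
        gr <- ref
      } else {
        copy_frac <- if (j == 0) 0 else min(1, 2 * j)
        i_bases <- round(copy_frac * r_bases)
        filler <- if (j == 0) r_bases else round(i_bases / j) - r_bases
        copied <- copy_reference_bases(ref, i_bases)
        fill <- place_filler(filler, ref, genome)
        gr <- merge_intervals(c(copied, fill))
      }
      catalog[[nm]] <- gr
      truth <- rbind(truth, data.frame(
        factor = nm, target_jaccard = j,
        realized_jaccard = jaccard_index(gr, ref),
        stringsAsFactors = FALSE))
    }
    list(catalog = catalog, truth = truth)
  })
}

# First `n_bases` covered bases of the reference, in random interval order,
# with the last interval trimmed so the count is exact.
copy_reference_bases <- function(ref, n_bases) {
  if (n_bases <= 0) return(GenomicRanges::GRanges(seqinfo =
                                                    GenomeInfoDb::seqinfo(ref)))
  ord <- sample(length(ref))
  w <- GenomicRanges::width(ref)[ord]
  cum <- cumsum(w)
  take <- which(cum >= n_bases)[1]
  sel <- ref[ord[seq_len(take)]]
  excess <- cum[take] - n_bases
  if (excess > 0) {
    GenomicRanges::end(sel)[take] <- GenomicRanges::end(sel)[take] - excess
  }
  sel
}

# Disjoint filler intervals (~1 kb chunks) placed uniformly, avoiding the
# reference and already-placed filler; errors out if placement keeps
# colliding (genome too crowded).
place_filler <- function(n_bases, avoid, genome) {
  out <- GenomicRanges::GRanges(seqinfo = GenomeInfoDb::seqinfo(avoid))
  if (n_bases <= 0) return(out)
  lens <- GenomeInfoDb::seqlengths(genome)
  placed <- 0
  attempts <- 0
  while (placed < n_bases) {
    attempts <- attempts + 1
    if (attempts > 50000) stop("filler placement failed: genome too crowded")
    chunk <- min(1000, n_bases - placed)
    ch <- sample(names(lens), 1, prob = as.numeric(lens))
    s0 <- floor(stats::runif(1) * (lens[[ch]] - chunk))
    cand <- GenomicRanges::GRanges(ch, IRanges::IRanges(s0 + 1, width = chunk),
                                   seqinfo = genome)
    if (GenomicRanges::countOverlaps(cand, avoid) == 0 &&
        GenomicRanges::countOverlaps(cand, out) == 0) {
      out <- c(out, cand)
      placed <- placed + chunk
    }
  }
  GenomicRanges::sort(out)
}

#' Generate a tumor cohort driven by a latent activity variable
#'
#' Each sample draws a latent activity from a standard normal; signature
#' genes are `a * activity + noise`, the query gene `b * activity + noise`,
#' and null genes pure noise. Gene names follow the default six-gene
#' signature so the cohort can be scored without renaming.
#'
#' @param config A [sim_config()].
#' @return List with `matrix` (genes x samples) and `truth`
#'   (data.frame `sample_id`, `activity`).
#' @export
make_cohort <- function(config) {
  n <- config$n_samples
  local_seed(config$seed + 53L, {
    activity <- stats::rnorm(n)
    samples <- sprintf("TUMOR_%04d", seq_len(n))
    sig <- default_signature()
    rows <- lapply(sig, function(g) {
      config$effect_signature * activity + stats::rnorm(n, 0, config$noise_sd)
    })
    query <- config$effect_query * activity +
      stats::rnorm(n, 0, config$noise_sd)
    nulls <- lapply(seq_len(config$n_null_cohort), function(i) {
      stats::rnorm(n, 0, config$noise_sd)
    })
    m <- do.call(rbind, c(rows, list(query), nulls))
    rownames(m) <- c(sig, "NOTCH3_like",
                     if (config$n_null_cohort > 0)
                       sprintf("NULLC_%03d", seq_len(config$n_null_cohort)))
    colnames(m) <- samples
    list(matrix = m,
         truth = data.frame(sample_id = samples, activity = activity,
                            stringsAsFactors = FALSE))
  })
}

#' Write a complete simulated input bundle to disk
#'
#' Runs all four generators and writes every input the pipeline consumes
#' (contrast tables, genome table, gene annotation, peak BEDs, bedGraph
#' tracks, cofactor BEDs, cohort matrix) plus machine-readable ground-truth
#' tables. Identical config (including seed) reproduces identical bytes.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a manifest list of the written paths plus the
#'   in-memory objects.
#' @export
write_simulation <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(dir, ...)

  con <- make_contrasts(config)
  for (tb in c(con$kd, con$ind)) {
    kind <- attr(tb, "kind")
    write_contrast_table(tb, p(sprintf("%s_%s.tsv",
                                       ifelse(kind == "knockdown", "kd", "ind"),
                                       attr(tb, "context"))))
  }
  write_tsv(con$truth, p("truth_genes_contrasts.tsv"))

  epi <- make_epigenome(config)
  write_tsv(data.frame(chrom = GenomeInfoDb::seqnames(epi$genome),
                       length = GenomeInfoDb::seqlengths(epi$genome)),
            p("genome.tsv"))
  write_gene_annotation(epi$genes, p("genes.tsv"))
  write_bed(epi$tf_peaks, p("tf_peaks.bed"))
  write_bed(epi$h3k27ac_peaks, p("h3k27ac_peaks.bed"))
  write_bedgraph(epi$control_track, p("control.bdg"))
  write_bedgraph(epi$kd_track, p("kd.bdg"))
  write_tsv(epi$truth_enhancers, p("truth_enhancers.tsv"))
  write_tsv(epi$truth_genes, p("truth_genes_epigenome.tsv"))

  reference <- reference_set(epi$tf_peaks, epi$h3k27ac_peaks)
  cof <- make_cofactor_catalog(config, reference, epi$genome)
  for (nm in names(cof$catalog)) {
    write_bed(cof$catalog[[nm]], p(sprintf("cofactor_%s.bed", nm)))
  }
  write_tsv(cof$truth, p("truth_cofactors.tsv"))

  coh <- make_cohort(config)
  write_expression_matrix(coh$matrix, p("cohort.tsv"))
  write_tsv(coh$truth, p("truth_cohort.tsv"))

  manifest <- list(
    dir = dir,
    kd_tables = stats::setNames(
      p(sprintf("kd_%s.tsv", c("A549", "H460", "H2023"))),
      c("A549", "H460", "H2023")),
    ind_tables = stats::setNames(
      p(sprintf("ind_%s.tsv", c("ABC1", "HCC4006"))),
      c("ABC1", "HCC4006")),
    genome = p("genome.tsv"), genes = p("genes.tsv"),
    tf_peaks = p("tf_peaks.bed"), h3k27ac_peaks = p("h3k27ac_peaks.bed"),
    control_track = p("control.bdg"), kd_track = p("kd.bdg"),
    cofactors = stats::setNames(
      p(sprintf("cofactor_%s.bed", names(config$cofactors))),
      names(config$cofactors)),
    cohort = p("cohort.tsv"),
    contrasts = con, epigenome = epi, cofactor_truth = cof$truth,
    cohort_truth = coh$truth
  )
  invisible(manifest)
}
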