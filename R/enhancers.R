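#' Scale a coverage track to a target total signal
#'
#' Multiplies every step value by `target_total / total_signal(track)`, the
#' same linear depth normalization as scaling by total mapped reads. Control
#' and knockdown tracks must be brought to the same target before their
#' signals are compared.
#'
#' @param track `GRanges` coverage track with a `score` column.
#' @param target_total Desired total signal (> 0).
#' @return The rescaled track.
#' @export
normalize_track <- function(track, target_total = 1e6) {
  stopifnot(target_total > 0)
  tot <- total_signal(track)
  if (length(track) == 0 || tot <= 0) {
    stop("cannot normalize a track with zero total signal")
  }
  S4Vectors::mcols(track)$score <-
    S4Vectors::mcols(track)$score * (target_total / tot)
  track
}

#' Merge replicate tracks by mean value
#'
#' Computes the per-base mean of several coverage tracks, the conventional
#' way replicate ChIP-seq experiments are collapsed into a single profile
#' before comparison. Bases missing from a track contribute 0.
#'
#' @param tracks List of `GRanges` coverage tracks on the same genome.
#' @return A single merged coverage track.
#' @export
mean_merge_tracks <- function(tracks) {
  stopifnot(length(tracks) >= 1)
  if (length(tracks) == 1) return(tracks[[1]])
  covs <- lapply(tracks, function(tr) {
    GenomicRanges::coverage(tr, weight = S4Vectors::mcols(tr)$score)
  })
  mean_cov <- Reduce(`+`, covs) / length(tracks)
  gr <- GenomicRanges::bindAsGRanges(score = mean_cov)
  GenomeInfoDb::seqinfo(gr) <- GenomeInfoDb::seqinfo(tracks[[1]])
  gr <- gr[S4Vectors::mcols(gr)$score > 0]
  GenomicRanges::sort(gr)
}

#' Knockdown-versus-control log2 signal ratio
#'
#' `log2((kd + pseudocount) / (control + pseudocount))`. The pseudocount
#' keeps the ratio defined at zero coverage; with both signals zero the
#' ratio is exactly 0. Monotone increasing in the knockdown signal and
#' decreasing in the control signal.
#'
#' @param control_signal Non-negative control signal.
#' @param kd_signal Non-negative knockdown signal.
#' @param pseudocount Positive stabilizer, default 1 normalized signal unit.
#' @return The log2 ratio (vectorized).
#' @export
dependency_log2_ratio <- function(control_signal, kd_signal, pseudocount = 1) {
  stopifnot(pseudocount > 0)
  if (any(control_signal < 0) || any(kd_signal < 0)) {
    stop("signals must be non-negative")
  }
  log2((kd_signal + pseudocount) / (control_signal + pseudocount))
}

#' TF-dependence rule for an enhancer
#'
#' An H3K27ac deposition is called dependent when its knockdown/control
#' log2 ratio falls strictly below the threshold; a ratio exactly at the
#' threshold is not dependent.
#'
#' @param ratio Log2 ratio(s) from [dependency_log2_ratio()].
#' @param threshold Classification threshold, default -0.5.
#' @return Logical vector.
#' @export
classify_dependency <- function(ratio, threshold = -0.5) {
  ratio < threshold
}

#' Call TF-dependent enhancers from paired coverage tracks
#'
#' Restricts the H3K27ac peaks to those overlapping a TF binding peak,
#' quantifies control and knockdown signal over each whole retained peak,
#' and applies the log2-ratio rule. Both tracks must be normalized to the
#' same total signal.
#'
#' @param h3k27ac_peaks `GRanges` of H3K27ac peaks.
#' @param tf_peaks `GRanges` of TF binding peaks.
#' @param control_track,kd_track Normalized `GRanges` coverage tracks.
#' @param pseudocount Stabilizer for the ratio, default 1.
#' @param threshold Dependence threshold, default -0.5.
#' @return A `dependency_calls` data.frame with one row per retained peak
#'   (`chrom`, `start`, `end`, `control_signal`, `kd_signal`, `log2_ratio`,
#'   `dependent`) and the dependent fraction in `attr(, "dependent_fraction")`.
#' @export
call_enhancers <- function(h3k27ac_peaks, tf_peaks, control_track, kd_track,
                           pseudocount = 1, threshold = -0.5) {
  tot_c <- total_signal(control_track)
  tot_k <- total_signal(kd_track)
  if (abs(tot_c - tot_k) > 1e-6 * max(tot_c, tot_k)) {
    stop(sprintf(
      "tracks are not normalized to the same total (%g vs %g); run normalize_track first",
      tot_c, tot_k))
  }
  peaks <- overlapping_subset(h3k27ac_peaks, tf_peaks)
  ctrl <- signal_in_intervals(control_track, peaks)
  kd <- signal_in_intervals(kd_track, peaks)
  ratio <- dependency_log2_ratio(ctrl, kd, pseudocount)
  dep <- classify_dependency(ratio, threshold)
  out <- data.frame(
    chrom = as.character(GenomeInfoDb::seqnames(peaks)),
    start = GenomicRanges::start(peaks) - 1L,
    end = GenomicRanges::end(peaks),
    control_signal = ctrl,
    kd_signal = kd,
    log2_ratio = ratio,
    dependent = dep,
    stringsAsFactors = FALSE
  )
  class(out) <- c("dependency_calls", "data.frame")
  attr(out, "dependent_fraction") <-
    if (nrow(out) == 0) NA_real_ else mean(out$dependent)
  attr(out, "pseudocount") <- pseudocount
  attr(out, "threshold") <- threshold
  out
}

#' @export
print.dependency_calls <- function(x, ...) {
  cat(sprintf("dependency_calls: %d TF-bound peaks, %d dependent (fraction %.3f)\n",
              nrow(x), sum(x$dependent), attr(x, "dependent_fraction")))
  print.data.frame(utils::head(as.data.frame(x)), ...)
  invisible(x)
}

# Row order preserved (no sorting) so metadata columns of `calls` stay
# aligned with the returned ranges.
calls_to_granges <- function(calls, genome) {
  check_chromosomes(calls$chrom, calls$start, calls$end, genome,
                    what = "dependency calls")
  GenomicRanges::GRanges(
    seqnames = calls$chrom,
    ranges = IRanges::IRanges(start = calls$start + 1L, end = calls$end),
    seqinfo = genome)
}

#' Call direct TF target genes
#'
#' A classified gene is a direct target when (i) at least one dependent
#' H3K27ac peak is assigned to it and (ii) a TF binding peak lies within the
#' window around its TSS. Peak-to-gene assignment uses nearest-TSS
#' semantics: each enhancer supports only the gene whose TSS is closest to
#' it (within the window), so one enhancer never supports two genes.
#'
#' @param genes Gene annotation data.frame covering at least every
#'   classified gene.
#' @param gene_classes A `gene_classification` from [classify_genes()].
#' @param calls A `dependency_calls` table from [call_enhancers()].
#' @param tf_peaks `GRanges` of TF binding peaks.
#' @param genome Genome model.
#' @param window Assignment window around the TSS in bp; default 100000.
#' @return data.frame `gene_id`, `class`, `tf_bound`, `n_assigned_peaks`,
#'   `n_dependent_peaks`, `is_direct`.
#' @export
call_direct_targets <- function(genes, gene_classes, calls, tf_peaks, genome,
                                window = 1e5) {
  stopifnot(window > 0)
  classified <- data.frame(
    gene_id = c(gene_classes$canonical, gene_classes$specific),
    class = rep(c("canonical", "specific"),
                c(length(gene_classes$canonical),
                  length(gene_classes$specific))),
    stringsAsFactors = FALSE
  )
  missing <- setdiff(classified$gene_id, genes$gene_id)
  if (length(missing) > 0) {
    stop(sprintf("classified gene(s) absent from annotation: %s",
                 paste(utils::head(missing, 5), collapse = ", ")))
  }
  ann <- genes[match(classified$gene_id, genes$gene_id), , drop = FALSE]

  # assign every called peak to its nearest TSS among ALL annotated genes
  peak_gr <- calls_to_granges(calls, genome)
  assignment <- assign_nearest_tss(peak_gr, genes, max_distance = window)
  n_assigned <- table(assignment$gene_id[!is.na(assignment$gene_id)])
  dep_id <- assignment$gene_id[!is.na(assignment$gene_id) & calls$dependent]
  n_dependent <- table(dep_id)

  # TF binding anywhere within the window around the TSS; row order must
  # track `classified`, so build ranges directly without sorting
  lens <- GenomeInfoDb::seqlengths(genome)
  win_gr <- GenomicRanges::GRanges(
    seqnames = ann$chrom,
    ranges = IRanges::IRanges(
      start = pmax(1, ann$tss + 1 - window),
      end = pmin(as.numeric(lens[ann$chrom]), ann$tss + 1 + window)),
    seqinfo = genome)
  tf_bound <- GenomicRanges::countOverlaps(win_gr, tf_peaks) > 0

  out <- data.frame(
    gene_id = classified$gene_id,
    class = classified$class,
    tf_bound = tf_bound,
    n_assigned_peaks = as.integer(n_assigned[classified$gene_id]),
    n_dependent_peaks = as.integer(n_dependent[classified$gene_id]),
    stringsAsFactors = FALSE
  )
  out$n_assigned_peaks[is.na(out$n_assigned_peaks)] <- 0L
  out$n_dependent_peaks[is.na(out$n_dependent_peaks)] <- 0L
  out$is_direct <- out$tf_bound & out$n_dependent_peaks > 0
  rownames(out) <- NULL
  out
}

#' Mann-Whitney U comparison of two groups
#'
#' Rank-sum test with mid-ranks for ties. The two-sided p-value comes from
#' exact enumeration when the combined sample size is at most 16 and there
#' are no ties, otherwise from the normal approximation with tie and
#' continuity corrections (the classical large-sample branch of
#' [stats::wilcox.test()]).
#'
#' @param values_a,values_b Numeric observations of the two groups.
#' @param label_a,label_b Optional group labels for reporting.
#' @return List with `label_a`, `label_b`, `U`, `p_value`, `n_a`, `n_b`.
#' @export
mann_whitney <- function(values_a, values_b,
                         label_a = "A", label_b = "B") {
  if (length(values_a) < 1 || length(values_b) < 1) {
    stop("both groups must be non-empty")
  }
  n_a <- length(values_a)
  n_b <- length(values_b)
  has_ties <- anyDuplicated(c(values_a, values_b)) > 0
  use_exact <- (n_a + n_b) <= 16 && !has_ties
  wt <- suppressWarnings(stats::wilcox.test(
    values_a, values_b, alternative = "two.sided",
    exact = use_exact, correct = TRUE))
  list(label_a = label_a, label_b = label_b,
       U = unname(wt$statistic),
       p_value = min(1, unname(wt$p.value)),
       n_a = n_a, n_b = n_b, exact = use_exact)
}
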