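#' Reference set for colocalization: TF peaks carrying the enhancer mark
#'
#' TF binding peaks that overlap at least one H3K27ac peak, i.e. binding
#' events at active chromatin. This is the reference against which cofactor
#' peak sets are ranked.
#'
#' @param tf_peaks `GRanges` of TF peaks.
#' @param h3k27ac_peaks `GRanges` of H3K27ac peaks.
#' @return The overlapping subset of `tf_peaks`.
#' @export
reference_set <- function(tf_peaks, h3k27ac_peaks) {
  overlapping_subset(tf_peaks, h3k27ac_peaks)
}

#' Base-pair Jaccard index of two interval sets
#'
#' Overlapping bases divided by bases of the union, computed after merging
#' each set, so the result is independent of how intervals are fragmented.
#' Symmetric in its arguments.
#'
#' @param a,b `GRanges` interval sets; at least one must be non-empty.
#' @return Jaccard index in \[0, 1\].
#' @export
jaccard_index <- function(a, b) {
  iu <- pair_bases(a, b)
  if (iu[["union"]] == 0) {
    stop("Jaccard undefined: both interval sets are empty")
  }
  iu[["inter"]] / iu[["union"]]
}

#' Permutation null for an observed Jaccard index
#'
#' Each permutation repositions every query interval uniformly at random
#' within its own chromosome, preserving interval lengths and chromosome
#' assignment, and recomputes the Jaccard index against the fixed reference.
#' The p-value uses the add-one Monte-Carlo estimator
#' `p = (k + 1) / (n_perm + 1)` with `k` the number of permutations whose
#' Jaccard is at least the observed value, so it is never exactly zero.
#'
#' @param query `GRanges` query set.
#' @param reference `GRanges` reference set.
#' @param genome Genome model (supplies chromosome lengths).
#' @param n_perm Number of permutations (>= 19).
#' @param seed Integer seed; results are reproducible given the seed.
#' @return List with `observed` Jaccard, `p_value`, `n_perm`.
#' @export
permutation_null <- function(query, reference, genome, n_perm = 999,
                             seed = 1) {
  stopifnot(n_perm >= 19)
  observed <- jaccard_index(query, reference)
  qm <- merge_intervals(query)
  rm_ <- merge_intervals(reference)
  lens <- GenomeInfoDb::seqlengths(genome)
  chrom <- as.character(GenomeInfoDb::seqnames(qm))
  widths <- as.numeric(GenomicRanges::width(qm))
  max_start0 <- as.numeric(lens[chrom]) - widths  # valid 0-based starts
  if (any(max_start0 < 0)) {
    stop("query interval longer than its chromosome")
  }
  # flatten to one coordinate axis (chromosomes laid end to end) so each
  # permutation is plain vector arithmetic rather than GRanges construction
  offset <- stats::setNames(cumsum(c(0, as.numeric(lens)))[seq_along(lens)],
                            names(lens))
  ref_flat <- flatten_intervals(rm_, offset)
  q_off <- offset[chrom]
  k <- local_seed(seed, {
    kk <- 0L
    for (i in seq_len(n_perm)) {
      start0 <- floor(stats::runif(length(widths)) * (max_start0 + 1))
      s <- q_off + start0
      j <- sweep_jaccard(s, s + widths, ref_flat$start, ref_flat$end)
      if (j >= observed) kk <- kk + 1L
    }
    kk
  })
  list(observed = observed, p_value = (k + 1) / (n_perm + 1), n_perm = n_perm)
}

# 0-based flat coordinates of a GRanges on the concatenated genome axis.
flatten_intervals <- function(gr, offset) {
  off <- offset[as.character(GenomeInfoDb::seqnames(gr))]
  list(start = off + GenomicRanges::start(gr) - 1,
       end = off + GenomicRanges::end(gr))
}

# Intersection and union base counts of two interval lists on a common
# axis via an event sweep; inputs need not be merged (running coverage
# counts handle overlaps within a set).
sweep_inter_union <- function(a_start, a_end, b_start, b_end) {
  pos <- c(a_start, a_end, b_start, b_end)
  if (length(pos) == 0) return(c(inter = 0, union = 0))
  da <- c(rep(1, length(a_start)), rep(-1, length(a_end)),
          numeric(length(b_start) + length(b_end)))
  db <- c(numeric(length(a_start) + length(a_end)),
          rep(1, length(b_start)), rep(-1, length(b_end)))
  ord <- order(pos)
  pos <- pos[ord]
  ca <- cumsum(da[ord])
  cb <- cumsum(db[ord])
  seg <- diff(pos)
  n <- length(pos)
  in_a <- ca[-n] > 0
  in_b <- cb[-n] > 0
  c(inter = sum(seg[in_a & in_b]), union = sum(seg[in_a | in_b]))
}

# Base-pair Jaccard on flat coordinates.
sweep_jaccard <- function(a_start, a_end, b_start, b_end) {
  iu <- sweep_inter_union(a_start, a_end, b_start, b_end)
  if (iu[["union"]] == 0) {
    stop("Jaccard undefined: both interval sets are empty")
  }
  iu[["inter"]] / iu[["union"]]
}

#' Rank cofactor peak sets by colocalization with a reference
#'
#' Computes the base-pair Jaccard index of every catalog entry against the
#' reference, attaches a permutation p-value per factor, and ranks factors
#' by descending Jaccard. Ties are broken by factor name, and the result is
#' invariant to catalog insertion order.
#'
#' @param catalog Named list of `GRanges`, one per candidate factor.
#' @param reference `GRanges` reference set (non-empty).
#' @param genome Genome model.
#' @param n_perm Permutations per factor; default 999.
#' @param seed Integer seed.
#' @return data.frame `factor`, `jaccard`, `perm_p`, `rank` sorted by rank.
#' @export
rank_cofactors <- function(catalog, reference, genome, n_perm = 999,
                           seed = 1) {
  if (length(catalog) == 0) stop("catalog is empty")
  if (is.null(names(catalog)) || any(!nzchar(names(catalog)))) {
    stop("catalog must be a named list of interval sets")
  }
  if (length(reference) == 0) stop("reference set is empty")
  nm <- sort(names(catalog))
  res <- lapply(seq_along(nm), function(i) {
    pn <- permutation_null(catalog[[nm[i]]], reference, genome,
                           n_perm = n_perm, seed = seed + i)
    data.frame(factor = nm[i], jaccard = pn$observed, perm_p = pn$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out <- out[order(-out$jaccard, out$factor), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
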