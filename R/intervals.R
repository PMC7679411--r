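#' Read a BED file into a GRanges interval set
#'
#' Accepts 3+ column BED (tab separated, no header). Columns 4 and 5 are
#' captured as `name` and `score` metadata when present; further columns are
#' ignored. Coordinates on disk are 0-based half-open; the returned GRanges
#' uses the usual 1-based closed convention and carries the genome's
#' `Seqinfo`.
#'
#' @param path Path to a BED file.
#' @param genome Genome model from [genome_model()].
#' @return A sorted `GRanges`.
#' @export
read_bed <- function(path, genome) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(GenomicRanges::GRanges(seqinfo = genome))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- vapply(fields, length, integer(1))
  if (any(ncol < 3)) {
    stop(sprintf("BED parse error at line %d: fewer than 3 columns",
                 which(ncol < 3)[1]))
  }
  chrom <- vapply(fields, `[[`, character(1), 1)
  start0 <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 2)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 3)))
  bad <- is.na(start0) | is.na(end) |
    start0 != floor(start0) | end != floor(end)
  if (any(bad)) {
    stop(sprintf("BED parse error at line %d: non-integer coordinates",
                 which(bad)[1]))
  }
  degenerate <- start0 < 0 | start0 >= end
  if (any(degenerate)) {
    stop(sprintf("BED parse error at line %d: require 0 <= start < end",
                 which(degenerate)[1]))
  }
  name <- if (any(ncol >= 4)) {
    vapply(fields, function(f) if (length(f) >= 4) f[[4]] else NA_character_,
           character(1))
  } else NULL
  score <- if (any(ncol >= 5)) {
    suppressWarnings(as.numeric(
      vapply(fields, function(f) if (length(f) >= 5) f[[5]] else NA_character_,
             character(1))))
  } else NULL
  granges_from_0based(chrom, start0, end, genome,
                      name = name, score = score,
                      what = sprintf("BED file %s", basename(path)))
}

#' Write a GRanges interval set to BED
#'
#' Emits 3, 4 or 5 columns depending on whether `name`/`score` metadata are
#' present, using 0-based half-open coordinates. A round trip through
#' [read_bed()] reproduces coordinates, names and scores exactly.
#'
#' @param intervals A `GRanges`.
#' @param path Output path.
#' @export
write_bed <- function(intervals, path) {
  n <- length(intervals)
  mc <- S4Vectors::mcols(intervals)
  cols <- list(
    as.character(GenomeInfoDb::seqnames(intervals)),
    format(GenomicRanges::start(intervals) - 1L, scientific = FALSE, trim = TRUE),
    format(GenomicRanges::end(intervals), scientific = FALSE, trim = TRUE)
  )
  has_score <- "score" %in% names(mc) && !all(is.na(mc$score))
  has_name <- ("name" %in% names(mc) && !all(is.na(mc$name))) || has_score
  if (has_name) {
    nm <- if ("name" %in% names(mc)) mc$name else rep(NA_character_, n)
    nm[is.na(nm)] <- "."
    cols <- c(cols, list(nm))
  }
  if (has_score) {
    cols <- c(cols, list(format(mc$score, scientific = FALSE, trim = TRUE,
                                digits = 15)))
  }
  writeLines(if (n == 0) character(0) else do.call(paste, c(cols, sep = "\t")),
             path)
  invisible(path)
}

#' Read a bedGraph coverage track
#'
#' Strict reader for 4-column bedGraph: steps must be non-negative and must
#' not overlap within a chromosome (overlap is treated as an upstream error
#' rather than silently summed). Returns a sorted `GRanges` with a numeric
#' `score` column; total signal is `sum(score * width)`.
#'
#' @param path Path to a bedGraph file.
#' @param genome Genome model.
#' @return A sorted `GRanges` with a `score` metadata column.
#' @export
read_bedgraph <- function(path, genome) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    gr <- GenomicRanges::GRanges(seqinfo = genome)
    S4Vectors::mcols(gr)$score <- numeric(0)
    return(gr)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- vapply(fields, length, integer(1))
  if (any(ncol < 4)) {
    stop(sprintf("bedGraph parse error at line %d: fewer than 4 columns",
                 which(ncol < 4)[1]))
  }
  chrom <- vapply(fields, `[[`, character(1), 1)
  start0 <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 2)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 3)))
  value <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 4)))
  bad <- is.na(start0) | is.na(end) | is.na(value) |
    start0 != floor(start0) | end != floor(end) | start0 < 0 | start0 >= end
  if (any(bad)) {
    stop(sprintf("bedGraph parse error at line %d", which(bad)[1]))
  }
  if (any(value < 0)) {
    stop(sprintf("bedGraph parse error at line %d: negative value",
                 which(value < 0)[1]))
  }
  gr <- granges_from_0based(chrom, start0, end, genome, score = value,
                            what = sprintf("bedGraph file %s", basename(path)))
  if (!GenomicRanges::isDisjoint(gr)) {
    stop("bedGraph steps overlap; merged tracks must be step functions")
  }
  gr
}

#' Write a coverage track to bedGraph
#' @param track `GRanges` with a `score` column.
#' @param path Output path.
#' @export
write_bedgraph <- function(track, path) {
  n <- length(track)
  lines <- if (n == 0) character(0) else paste(
    as.character(GenomeInfoDb::seqnames(track)),
    format(GenomicRanges::start(track) - 1L, scientific = FALSE, trim = TRUE),
    format(GenomicRanges::end(track), scientific = FALSE, trim = TRUE),
    format(S4Vectors::mcols(track)$score, scientific = FALSE, trim = TRUE,
           digits = 15),
    sep = "\t"
  )
  writeLines(lines, path)
  invisible(path)
}

#' Merge intervals closer than a gap
#'
#' Intervals separated by at most `min_gap` bases are fused; `min_gap = 0`
#' merges only overlapping or abutting intervals, so the covered-base count
#' of an already-disjoint set is unchanged.
#'
#' @param a A `GRanges`.
#' @param min_gap Non-negative integer gap threshold.
#' @return A merged, sorted `GRanges` (metadata dropped).
#' @export
merge_intervals <- function(a, min_gap = 0L) {
  stopifnot(min_gap >= 0)
  GenomicRanges::reduce(a, min.gapwidth = min_gap + 1L)
}

#' Bases covered by both interval sets
#'
#' Fragmentation-independent: overlap within an input is handled by the
#' counting sweep, so splitting an interval into abutting pieces does not
#' change the result.
#'
#' @param a,b `GRanges` interval sets.
#' @return Number of bases covered by both `a` and `b`.
#' @export
intersect_bases <- function(a, b) {
  pair_bases(a, b)[["inter"]]
}

#' Bases covered by either interval set
#' @inheritParams intersect_bases
#' @return Number of bases covered by `a` or `b`.
#' @export
union_bases <- function(a, b) {
  pair_bases(a, b)[["union"]]
}

# Intersection and union base counts of two GRanges in one pass: both sets
# are flattened onto a single coordinate axis (chromosomes laid end to end)
# and swept with running coverage counts. Exactness is checked against a
# per-base oracle in the test suite.
pair_bases <- function(a, b) {
  chroms <- union(as.character(GenomeInfoDb::seqnames(a)),
                  as.character(GenomeInfoDb::seqnames(b)))
  if (length(chroms) == 0) return(c(inter = 0, union = 0))
  span <- max(c(GenomicRanges::end(a), GenomicRanges::end(b), 0)) + 1
  offset <- stats::setNames((seq_along(chroms) - 1) * span, chroms)
  fa <- offset[as.character(GenomeInfoDb::seqnames(a))]
  fb <- offset[as.character(GenomeInfoDb::seqnames(b))]
  sweep_inter_union(fa + GenomicRanges::start(a) - 1,
                    fa + GenomicRanges::end(a),
                    fb + GenomicRanges::start(b) - 1,
                    fb + GenomicRanges::end(b))
}

#' Bases covered by an interval set
#' @param a A `GRanges`.
#' @return Covered base count after merging.
#' @export
covered_bases <- function(a) {
  sum(as.numeric(GenomicRanges::width(merge_intervals(a))))
}

#' Intervals of one set that overlap another
#'
#' Returns the intervals of `a` sharing at least one base with some interval
#' of `b`. Whole intervals are retained, never clipped: downstream stages
#' classify whole H3K27ac depositions, not fragments. Half-open semantics on
#' disk mean `[a,b)` and `[b,c)` never overlap.
#'
#' @param a,b `GRanges` interval sets.
#' @return The overlapping subset of `a`.
#' @export
overlapping_subset <- function(a, b) {
  IRanges::subsetByOverlaps(a, b)
}

#' Subtract exclusion regions from an interval set
#'
#' Removes every base covered by `exclude` (e.g. an assay blacklist) from
#' `a`. Interval names and scores are dropped because intervals may be split.
#'
#' @param a A `GRanges`.
#' @param exclude Exclusion regions as `GRanges`.
#' @return The base-level difference as a merged `GRanges`.
#' @export
subtract_intervals <- function(a, exclude) {
  GenomicRanges::setdiff(merge_intervals(a), merge_intervals(exclude))
}

#' Nearest transcription start site of an interval
#'
#' Distance is 0 when a TSS falls inside the interval, otherwise the number
#' of bases from the nearest covered base to the TSS. Ties are broken by the
#' lexicographically smaller gene id so results are deterministic.
#'
#' @param interval A length-1 `GRanges`.
#' @param genes Gene annotation data.frame from [gene_annotation()].
#' @param max_distance Maximum distance in bp; farther genes are ignored.
#' @return List with `gene_id` and `distance`, or `NULL` if no gene is
#'   within `max_distance`.
#' @export
nearest_tss <- function(interval, genes, max_distance = 1e5) {
  stopifnot(length(interval) == 1)
  chrom <- as.character(GenomeInfoDb::seqnames(interval))
  g <- genes[genes$chrom == chrom, , drop = FALSE]
  if (nrow(g) == 0) return(NULL)
  start0 <- GenomicRanges::start(interval) - 1L
  last0 <- GenomicRanges::end(interval) - 1L  # last covered base, 0-based
  d <- ifelse(g$tss < start0, start0 - g$tss,
       ifelse(g$tss > last0, g$tss - last0, 0))
  ord <- order(d, g$gene_id)
  if (d[ord[1]] > max_distance) return(NULL)
  list(gene_id = g$gene_id[ord[1]], distance = unname(d[ord[1]]))
}

# Vectorized nearest-TSS assignment: one row per interval with gene_id NA
# when nothing lies within max_distance. Same tie-break as nearest_tss.
assign_nearest_tss <- function(intervals, genes, max_distance = 1e5) {
  n <- length(intervals)
  gene_id <- rep(NA_character_, n)
  distance <- rep(NA_real_, n)
  if (n == 0) {
    return(data.frame(gene_id = gene_id, distance = distance,
                      stringsAsFactors = FALSE))
  }
  chroms <- as.character(GenomeInfoDb::seqnames(intervals))
  starts0 <- GenomicRanges::start(intervals) - 1L
  lasts0 <- GenomicRanges::end(intervals) - 1L
  for (ch in unique(chroms)) {
    g <- genes[genes$chrom == ch, , drop = FALSE]
    idx <- which(chroms == ch)
    if (nrow(g) == 0) next
    g <- g[order(g$tss, g$gene_id), , drop = FALSE]
    for (i in idx) {
      d <- ifelse(g$tss < starts0[i], starts0[i] - g$tss,
           ifelse(g$tss > lasts0[i], g$tss - lasts0[i], 0))
      ord <- order(d, g$gene_id)
      if (d[ord[1]] <= max_distance) {
        gene_id[i] <- g$gene_id[ord[1]]
        distance[i] <- d[ord[1]]
      }
    }
  }
  data.frame(gene_id = gene_id, distance = distance, stringsAsFactors = FALSE)
}

#' Total signal of a coverage track
#' @param track `GRanges` with a `score` column.
#' @return `sum(score * width)`.
#' @export
total_signal <- function(track) {
  sum(as.numeric(S4Vectors::mcols(track)$score) *
        as.numeric(GenomicRanges::width(track)))
}

#' Signal of a track inside an interval
#'
#' Sums `value * overlap width` over all track steps intersecting the
#' interval; additive over any partition of the interval.
#'
#' @param track `GRanges` coverage track with a `score` column.
#' @param interval A length-1 `GRanges`.
#' @return Non-negative signal total.
#' @export
signal_in_interval <- function(track, interval) {
  stopifnot(length(interval) == 1)
  signal_in_intervals(track, interval)
}

# Vectorized per-interval quantification used by the enhancer caller.
signal_in_intervals <- function(track, intervals) {
  if (length(intervals) == 0) return(numeric(0))
  out <- numeric(length(intervals))
  hits <- GenomicRanges::findOverlaps(intervals, track)
  if (length(hits) > 0) {
    qi <- S4Vectors::queryHits(hits)
    si <- S4Vectors::subjectHits(hits)
    ov <- IRanges::pintersect(GenomicRanges::ranges(intervals)[qi],
                              GenomicRanges::ranges(track)[si])
    contrib <- as.numeric(IRanges::width(ov)) *
      as.numeric(S4Vectors::mcols(track)$score[si])
    agg <- tapply(contrib, qi, sum)
    out[as.integer(names(agg))] <- as.numeric(agg)
  }
  out
}
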