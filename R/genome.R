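#' Construct a genome model
#'
#' A genome model records the chromosome names and lengths that every
#' interval set, coverage track and gene annotation in a run must reference.
#' It is represented as a [GenomeInfoDb::Seqinfo] object so that all
#' GenomicRanges machinery can enforce bounds automatically.
#'
#' @param chrom_names Character vector of unique chromosome names.
#' @param chrom_lengths Integer vector of positive chromosome lengths
#'   (base pairs), one per chromosome.
#' @return A `Seqinfo` object.
#' @examples
#' gm <- genome_model(c("chr1", "chr2"), c(1e6, 1e6))
#' @export
genome_model <- function(chrom_names, chrom_lengths) {
  chrom_names <- as.character(chrom_names)
  if (anyDuplicated(chrom_names)) {
    stop("chromosome names must be unique")
  }
  chrom_lengths <- as.numeric(chrom_lengths)
  if (length(chrom_lengths) != length(chrom_names)) {
    stop("chrom_names and chrom_lengths must have equal length")
  }
  if (any(!is.finite(chrom_lengths)) || any(chrom_lengths <= 0) ||
      any(chrom_lengths != round(chrom_lengths))) {
    stop("chromosome lengths must be positive integers")
  }
  GenomeInfoDb::Seqinfo(seqnames = chrom_names,
                        seqlengths = as.integer(chrom_lengths))
}

#' @return Named integer vector of chromosome lengths.
#' @rdname genome_model
#' @param genome A `Seqinfo` genome model.
#' @export
chrom_lengths <- function(genome) {
  GenomeInfoDb::seqlengths(genome)
}

# Validate that chromosomes used by a table are declared in the genome,
# and that coordinates stay inside the chromosome. `what` names the input
# in error messages. start0/end are 0-based half-open.
check_chromosomes <- function(chrom, start0, end, genome, what = "input") {
  lens <- GenomeInfoDb::seqlengths(genome)
  unknown <- setdiff(unique(chrom), names(lens))
  if (length(unknown) > 0) {
    stop(sprintf("%s references unknown chromosome(s): %s",
                 what, paste(unknown, collapse = ", ")))
  }
  too_far <- end > lens[chrom]
  if (any(too_far)) {
    i <- which(too_far)[1]
    stop(sprintf("%s: interval %s:[%d,%d) exceeds chromosome length %d",
                 what, chrom[i], start0[i], end[i], lens[chrom[i]]))
  }
  invisible(TRUE)
}

# Build a GRanges from 0-based half-open coordinates, validated against a
# genome model. Used by all readers and generators.
granges_from_0based <- function(chrom, start0, end, genome,
                                name = NULL, score = NULL, what = "input") {
  stopifnot(length(start0) == length(end), length(chrom) == length(end))
  check_chromosomes(chrom, start0, end, genome, what)
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start0 + 1L, end = end),
    seqinfo = genome
  )
  if (!is.null(name)) S4Vectors::mcols(gr)$name <- name
  if (!is.null(score)) S4Vectors::mcols(gr)$score <- score
  GenomicRanges::sort(gr)
}

#' Read a gene annotation table
#'
#' Expects a 4-column tab-separated file with header
#' `gene_id`, `chrom`, `tss`, `strand`; `tss` is a 0-based position and
#' strand is `+` or `-`.
#'
#' @param path Path to the annotation file.
#' @param genome Genome model from [genome_model()].
#' @return A data.frame with columns `gene_id`, `chrom`, `tss`, `strand`.
#' @export
read_gene_annotation <- function(path, genome) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  required <- c("gene_id", "chrom", "tss", "strand")
  if (!all(required %in% names(df))) {
    stop("annotation must have columns gene_id, chrom, tss, strand")
  }
  gene_annotation(df$gene_id, df$chrom, df$tss, df$strand, genome)
}

#' Construct and validate a gene annotation
#'
#' @param gene_id Unique gene identifiers.
#' @param chrom Chromosome of each gene.
#' @param tss 0-based transcription start site position.
#' @param strand `+` or `-` per gene.
#' @param genome Genome model; TSS positions are checked against it.
#' @return A validated data.frame annotation.
#' @export
gene_annotation <- function(gene_id, chrom, tss, strand, genome) {
  gene_id <- as.character(gene_id)
  if (anyDuplicated(gene_id)) stop("gene ids must be unique")
  if (!all(strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  tss <- as.numeric(tss)
  lens <- GenomeInfoDb::seqlengths(genome)
  check_chromosomes(chrom, tss, tss + 1, genome, what = "gene annotation")
  if (any(tss < 0)) stop("tss must be >= 0")
  data.frame(gene_id = gene_id, chrom = as.character(chrom),
             tss = tss, strand = as.character(strand),
             stringsAsFactors = FALSE)
}

#' Write a gene annotation table
#' @param annotation Annotation data.frame from [gene_annotation()].
#' @param path Output path.
#' @export
write_gene_annotation <- function(annotation, path) {
  utils::write.table(annotation, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
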