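#' Construct a differential-expression contrast table
#'
#' One table holds the per-gene statistics of a single perturbation
#' (TF knockdown or electrophile induction) in one cellular context. The
#' perturbation kind decides which direction counts as "responsive"
#' downstream: knockdown contrasts look for downregulation, induction
#' contrasts for upregulation.
#'
#' @param gene_id Unique gene identifiers.
#' @param log2fc Log2 fold change, perturbation vs control.
#' @param p_adj Benjamini-Hochberg adjusted p-values in \[0, 1\].
#' @param context Context label, e.g. a cell-line name.
#' @param kind `"knockdown"` or `"induction"`.
#' @return A `contrast_table` data.frame with attributes `context`, `kind`.
#' @export
contrast_table <- function(gene_id, log2fc, p_adj, context, kind) {
  kind <- match.arg(kind, c("knockdown", "induction"))
  gene_id <- as.character(gene_id)
  if (anyDuplicated(gene_id)) stop("gene ids must be unique within a table")
  p_adj <- as.numeric(p_adj)
  if (any(is.na(p_adj)) || any(p_adj < 0 | p_adj > 1)) {
    stop("p_adj values must lie in [0, 1]")
  }
  out <- data.frame(gene_id = gene_id, log2fc = as.numeric(log2fc),
                    p_adj = p_adj, stringsAsFactors = FALSE)
  attr(out, "context") <- as.character(context)
  attr(out, "kind") <- kind
  class(out) <- c("contrast_table", "data.frame")
  out
}

#' @export
print.contrast_table <- function(x, ...) {
  cat(sprintf("contrast_table: %s (%s), %d genes\n",
              attr(x, "context"), attr(x, "kind"), nrow(x)))
  print.data.frame(utils::head(as.data.frame(x)), ...)
  if (nrow(x) > 6) cat(sprintf("... %d more rows\n", nrow(x) - 6L))
  invisible(x)
}

#' Read a contrast table from tab-separated text
#'
#' Expects a header with columns `gene_id`, `log2fc`, `p_adj`.
#'
#' @param path File path.
#' @inheritParams contrast_table
#' @return A `contrast_table`.
#' @export
read_contrast_table <- function(path, context, kind) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  required <- c("gene_id", "log2fc", "p_adj")
  if (!all(required %in% names(df))) {
    stop("contrast table must have columns gene_id, log2fc, p_adj")
  }
  contrast_table(df$gene_id, df$log2fc, df$p_adj, context, kind)
}

#' Write a contrast table
#' @param table A `contrast_table`.
#' @param path Output path.
#' @export
write_contrast_table <- function(table, path) {
  utils::write.table(as.data.frame(table)[, c("gene_id", "log2fc", "p_adj")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotone enforcement,
#' capped at 1; output order matches input order. Thin validated wrapper
#' around [stats::p.adjust()].
#'
#' @param p_values Raw p-values in \[0, 1\].
#' @return Adjusted p-values.
#' @export
bh_adjust <- function(p_values) {
  p_values <- as.numeric(p_values)
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Responsive genes of one contrast
#'
#' Significance alone is not enough: the direction of change must match the
#' perturbation. Knockdown contrasts select genes with `p_adj < alpha` and
#' `log2fc < 0` (downregulated when the TF is removed); induction contrasts
#' select `p_adj < alpha` and `log2fc > 0`. Both inequalities are strict.
#'
#' @param table A `contrast_table`.
#' @param alpha Significance level in (0, 1); default 0.05.
#' @return Character vector of responsive gene ids.
#' @export
responsive_genes <- function(table, alpha = 0.05) {
  stopifnot(is.numeric(alpha), alpha > 0, alpha < 1)
  kind <- attr(table, "kind")
  keep <- if (kind == "knockdown") {
    table$p_adj < alpha & table$log2fc < 0
  } else {
    table$p_adj < alpha & table$log2fc > 0
  }
  table$gene_id[keep]
}

check_kind <- function(tables, kind) {
  kinds <- vapply(tables, attr, character(1), "kind")
  if (!all(kinds == kind)) {
    stop(sprintf("all tables must be of kind '%s' (got: %s)",
                 kind, paste(unique(kinds), collapse = ", ")))
  }
  invisible(TRUE)
}

#' Genes responsive in every knockdown contrast
#'
#' Intersection of [responsive_genes()] across all knockdown tables: a gene
#' missing from one table counts as non-responsive there.
#'
#' @param kd_tables List of knockdown `contrast_table`s.
#' @param alpha Significance level.
#' @return Character vector of common downstream gene ids.
#' @export
common_downstream <- function(kd_tables, alpha = 0.05) {
  stopifnot(length(kd_tables) >= 1)
  check_kind(kd_tables, "knockdown")
  Reduce(intersect, lapply(kd_tables, responsive_genes, alpha = alpha))
}

#' Genes responsive in at least one induction contrast
#'
#' @param ind_tables List of induction `contrast_table`s.
#' @param alpha Significance level.
#' @return Character vector of inducible gene ids.
#' @export
inducible_union <- function(ind_tables, alpha = 0.05) {
  stopifnot(length(ind_tables) >= 1)
  check_kind(ind_tables, "induction")
  Reduce(union, lapply(ind_tables, responsive_genes, alpha = alpha))
}

#' Partition common downstream genes into canonical and context-specific
#'
#' Canonical targets respond both to persistent TF activation (knockdown
#' sensitive) and to transient activation by an inducer; context-specific
#' targets respond only to the persistent state. The two classes partition
#' the common downstream set:
#' `canonical = common n inducible`, `specific = common \\ inducible`.
#'
#' @param common Gene ids responsive in all knockdown contrasts.
#' @param inducible Gene ids responsive in at least one induction contrast.
#' @return A `gene_classification` list with elements `common_downstream`,
#'   `inducible`, `canonical`, `specific`.
#' @export
classify_genes <- function(common, inducible) {
  common <- unique(as.character(common))
  inducible <- unique(as.character(inducible))
  out <- list(
    common_downstream = common,
    inducible = inducible,
    canonical = sort(intersect(common, inducible)),
    specific = sort(setdiff(common, inducible))
  )
  class(out) <- "gene_classification"
  out
}

#' @export
print.gene_classification <- function(x, ...) {
  cat(sprintf(
    "gene_classification: %d common downstream = %d canonical + %d specific\n",
    length(x$common_downstream), length(x$canonical), length(x$specific)))
  invisible(x)
}

#' Filter candidate genes by correlation with TF activity
#'
#' Retains candidates whose cohort expression correlates with a per-sample
#' TF activity score at or above a threshold. Candidates absent from the
#' cohort, or with zero expression variance, are reported as skipped with a
#' warning rather than raising an error.
#'
#' @param candidates Candidate gene ids.
#' @param cohort Expression matrix (genes x samples).
#' @param scores Numeric activity score per sample, aligned to the cohort
#'   columns (or a data.frame with `sample_id` and `score` columns as
#'   returned by [activity_score()]).
#' @param method `"spearman"` (default) or `"pearson"`.
#' @param threshold Minimum correlation for retention; default 0.3.
#' @return data.frame `gene_id`, `correlation` sorted by descending
#'   correlation, with skipped genes in `attr(, "skipped")`.
#' @export
correlation_filter <- function(candidates, cohort, scores,
                               method = c("spearman", "pearson"),
                               threshold = 0.3) {
  method <- match.arg(method)
  if (is.data.frame(scores)) {
    stopifnot(all(c("sample_id", "score") %in% names(scores)))
    scores <- stats::setNames(scores$score, scores$sample_id)[colnames(cohort)]
  }
  if (ncol(cohort) < 3) stop("correlation needs at least 3 samples")
  if (length(scores) != ncol(cohort) || any(is.na(scores))) {
    stop("scores must align with cohort samples")
  }
  candidates <- unique(as.character(candidates))
  present <- candidates[candidates %in% rownames(cohort)]
  skipped <- setdiff(candidates, present)
  rho <- vapply(present, function(g) {
    x <- cohort[g, ]
    if (stats::sd(x) == 0) return(NA_real_)
    stats::cor(x, scores, method = method)
  }, numeric(1))
  degenerate <- present[is.na(rho)]
  if (length(degenerate) > 0) {
    warning(sprintf("skipping zero-variance gene(s): %s",
                    paste(degenerate, collapse = ", ")))
    skipped <- c(skipped, degenerate)
  }
  if (length(skipped) > 0 && length(setdiff(skipped, degenerate)) > 0) {
    warning(sprintf("candidate gene(s) absent from cohort: %s",
                    paste(setdiff(skipped, degenerate), collapse = ", ")))
  }
  keep <- !is.na(rho) & rho >= threshold
  out <- data.frame(gene_id = present[keep],
                    correlation = unname(rho[keep]),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$correlation, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}
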