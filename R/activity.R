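#' Read a gene-by-sample expression matrix
#'
#' Tab-separated text whose first column (`gene_id`) holds gene identifiers
#' and whose header names the samples.
#'
#' @param path File path.
#' @return Numeric matrix, genes in rows, samples in columns.
#' @export
read_expression_matrix <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1] != "gene_id") stop("first column must be gene_id")
  if (anyDuplicated(df$gene_id)) stop("duplicate gene ids")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene_id
  storage.mode(m) <- "double"
  if (any(!is.finite(m))) stop("expression values must be finite")
  m
}

#' Write an expression matrix
#' @param matrix Numeric genes-by-samples matrix.
#' @param path Output path.
#' @export
write_expression_matrix <- function(matrix, path) {
  df <- data.frame(gene_id = rownames(matrix), matrix,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' Default six-gene NRF2 activity signature
#'
#' Canonical NRF2 target genes whose mean z-scored expression defines the
#' per-sample NRF2 activity score of a cohort.
#'
#' @return Character vector of gene symbols.
#' @export
default_signature <- function() {
  c("NQO1", "SLC7A11", "GCLC", "GCLM", "TXNRD1", "NR0B1")
}

#' Z-score an expression matrix gene-wise
#'
#' Each gene row is transformed to `(x - mean) / sd` with the sample
#' (n - 1) standard deviation. Zero-variance rows become `NaN`; an error is
#' only raised downstream when such a gene is actually requested.
#'
#' @param matrix Numeric genes-by-samples matrix.
#' @return Matrix of the same shape with rows standardized.
#' @export
zscore_by_gene <- function(matrix) {
  mu <- rowMeans(matrix)
  sdv <- apply(matrix, 1, stats::sd)
  sweep(sweep(matrix, 1, mu, "-"), 1, sdv, "/")
}

#' Signature activity score per sample
#'
#' The per-sample score is the arithmetic mean of the signature genes'
#' z-scores; by construction the cohort mean score is 0.
#'
#' @param zmatrix Z-scored matrix from [zscore_by_gene()].
#' @param signature Character vector of signature gene ids; default the
#'   six-gene NRF2 signature.
#' @return data.frame `sample_id`, `score`.
#' @export
activity_score <- function(zmatrix, signature = default_signature()) {
  stopifnot(length(signature) >= 1)
  missing <- setdiff(signature, rownames(zmatrix))
  if (length(missing) > 0) {
    stop(sprintf("signature gene(s) missing from matrix: %s",
                 paste(missing, collapse = ", ")))
  }
  sub <- zmatrix[signature, , drop = FALSE]
  if (any(!is.finite(sub))) {
    bad <- signature[apply(!is.finite(sub), 1, any)]
    stop(sprintf("zero-variance signature gene(s): %s",
                 paste(bad, collapse = ", ")))
  }
  data.frame(sample_id = colnames(zmatrix), score = colMeans(sub),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Stratify samples into activity groups
#'
#' Quantile-style stratification: samples sorted by score (ties resolved by
#' stable sample-id order) are cut into `n_groups` ordinal strata whose
#' sizes differ by at most one; stratum 1 holds the lowest scores. Any
#' remainder samples are placed in the lower strata.
#'
#' @param scores data.frame `sample_id`, `score` from [activity_score()].
#' @param n_groups Number of strata (>= 2), default 3.
#' @return The input with an added integer `stratum` column.
#' @export
stratify <- function(scores, n_groups = 3) {
  stopifnot(n_groups >= 2)
  n <- nrow(scores)
  if (n_groups > n) stop("more groups than samples")
  ord <- order(scores$score, scores$sample_id)
  base <- n %/% n_groups
  extra <- n %% n_groups
  sizes <- rep(base, n_groups) + c(rep(1L, extra), rep(0L, n_groups - extra))
  stratum <- integer(n)
  stratum[ord] <- rep(seq_len(n_groups), sizes)
  scores$stratum <- stratum
  scores
}

#' One-way analysis of variance with Bonferroni pairwise tests
#'
#' Classical between/within decomposition (`F = MS_between / MS_within`)
#' with the p-value from the F distribution, plus all pairwise two-sample
#' pooled-variance t-tests Bonferroni-adjusted by the number of pairs.
#'
#' @param groups List of numeric vectors, each of length >= 2.
#' @return List with `F`, `p_value`, `df_between`, `df_within`, and a
#'   data.frame `pairwise` of adjusted pairwise p-values.
#' @export
anova_oneway <- function(groups) {
  stopifnot(length(groups) >= 2)
  if (any(vapply(groups, length, integer(1)) < 2)) {
    stop("each group needs at least 2 values")
  }
  if (is.null(names(groups))) names(groups) <- as.character(seq_along(groups))
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), vapply(groups, length, integer(1))),
              levels = names(groups))
  ss_within <- sum(vapply(groups, function(v) sum((v - mean(v))^2),
                          numeric(1)))
  if (ss_within == 0) {
    stop("zero within-group variance: F statistic undefined")
  }
  fit <- stats::anova(stats::lm(y ~ g))
  pairs <- utils::combn(names(groups), 2)
  n_pairs <- ncol(pairs)
  pw <- apply(pairs, 2, function(pr) {
    p <- stats::t.test(groups[[pr[1]]], groups[[pr[2]]],
                       var.equal = TRUE)$p.value
    min(1, p * n_pairs)
  })
  list(
    F = fit$`F value`[1],
    p_value = fit$`Pr(>F)`[1],
    df_between = fit$Df[1],
    df_within = fit$Df[2],
    pairwise = data.frame(group_a = pairs[1, ], group_b = pairs[2, ],
                          p_bonferroni = pw, stringsAsFactors = FALSE)
  )
}

#' Chi-square test of independence for a 2x2 table
#'
#' Shortcut formula
#' `N (|ad - bc| - c0)^2 / ((a+b)(c+d)(a+c)(b+d))` with continuity
#' correction `c0 = min(N/2, |ad - bc|)` when `yates = TRUE` and 0
#' otherwise; p-value from the chi-square distribution with 1 df.
#'
#' @param counts 2x2 matrix of non-negative integer counts with all
#'   marginals positive.
#' @param yates Apply the Yates continuity correction? Default `FALSE`.
#' @return List with `statistic`, `p_value`, `df`.
#' @export
chi_square_2x2 <- function(counts, yates = FALSE) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(2, 2))) stop("counts must be a 2x2 table")
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stop("all marginals must be positive")
  }
  a <- counts[1, 1]; b <- counts[1, 2]; c_ <- counts[2, 1]; d <- counts[2, 2]
  n <- sum(counts)
  cross <- abs(a * d - b * c_)
  corr <- if (yates) min(n / 2, cross) else 0
  stat <- n * (cross - corr)^2 /
    ((a + b) * (c_ + d) * (a + c_) * (b + d))
  list(statistic = stat, p_value = stats::pchisq(stat, df = 1,
                                                 lower.tail = FALSE),
       df = 1L)
}

#' Pearson correlation with two-tailed p-value
#'
#' Product-moment correlation; significance from the t transform with
#' `n - 2` degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length >= 3 with non-zero variance.
#' @return List with `r`, `p_value`, `n`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance: correlation undefined")
  }
  ct <- stats::cor.test(x, y, method = "pearson",
                        alternative = "two.sided")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}
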