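# Independent brute-force oracles used to check the package's interval
# algebra and statistics against first principles on small instances.

suppressPackageStartupMessages({
  library(GenomicRanges)
})

# --- per-base interval oracle -----------------------------------------------
# A set of intervals on a toy genome is represented as one logical vector of
# per-base membership per chromosome (0-based positions 0..len-1).

pb_cover <- function(df, genome_lens) {
  out <- lapply(genome_lens, function(len) logical(len))
  for (i in seq_len(nrow(df))) {
    ch <- df$chrom[i]
    out[[ch]][(df$start[i] + 1):df$end[i]] <- TRUE
  }
  out
}

pb_bases <- function(cov) sum(vapply(cov, sum, numeric(1)))

pb_intersect_bases <- function(ca, cb) {
  sum(mapply(function(a, b) sum(a & b), ca, cb))
}

pb_union_bases <- function(ca, cb) {
  sum(mapply(function(a, b) sum(a | b), ca, cb))
}

# merge oracle: close gaps of at most min_gap, return covered vector
pb_merge <- function(cov, min_gap) {
  lapply(cov, function(v) {
    r <- rle(v)
    if (min_gap > 0) {
      inner <- which(!r$values & r$lengths <= min_gap)
      inner <- inner[inner > 1 & inner < length(r$values)]
      r$values[inner] <- TRUE
    }
    inverse.rle(r)
  })
}

# overlapping-subset oracle: which rows of a share >= 1 base with b's cover
pb_overlap_rows <- function(df, cb) {
  vapply(seq_len(nrow(df)), function(i) {
    any(cb[[df$chrom[i]]][(df$start[i] + 1):df$end[i]])
  }, logical(1))
}

# per-base signal vector from bedGraph-style steps
pb_signal_vec <- function(steps, genome_lens) {
  out <- lapply(genome_lens, function(len) numeric(len))
  for (i in seq_len(nrow(steps))) {
    ch <- steps$chrom[i]
    out[[ch]][(steps$start[i] + 1):steps$end[i]] <- steps$value[i]
  }
  out
}

pb_signal_in <- function(sig, chrom, start, end) {
  sum(sig[[chrom]][(start + 1):end])
}

# random non-degenerate interval table on a toy genome
random_intervals <- function(genome_lens, max_n = 50) {
  n <- sample.int(max_n, 1)
  chrom <- sample(names(genome_lens), n, replace = TRUE)
  len <- genome_lens[chrom]
  start <- floor(runif(n) * (len - 1))
  width <- pmax(1, floor(runif(n) * pmin(200, len - start)))
  data.frame(chrom = chrom, start = start, end = start + width,
             stringsAsFactors = FALSE)
}

df_to_granges <- function(df, genome) {
  crest:::granges_from_0based(df$chrom, df$start, df$end, genome)
}

toy_genome <- function(lens = c(chrA = 5000, chrB = 3000)) {
  list(lens = lens, model = genome_model(names(lens), lens))
}

# --- statistics oracles ------------------------------------------------------

# Benjamini-Hochberg step-up: min over j >= i of p(j) * n / j, capped at 1
bh_oracle <- function(p) {
  n <- length(p)
  ord <- order(p)
  adj <- numeric(n)
  sorted <- p[ord]
  run <- rev(cummin(rev(sorted * n / seq_len(n))))
  adj[ord] <- pmin(1, run)
  adj
}

# Mann-Whitney exact two-sided p by full enumeration of group assignments
mw_enumeration <- function(a, b) {
  pooled <- c(a, b)
  n_a <- length(a)
  u_of <- function(x, y) sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  combos <- utils::combn(length(pooled), n_a)
  u_all <- apply(combos, 2, function(idx) {
    u_of(pooled[idx], pooled[-idx])
  })
  u_obs <- u_of(a, b)
  p <- 2 * min(mean(u_all <= u_obs + 1e-9), mean(u_all >= u_obs - 1e-9))
  list(U = u_obs, p = min(1, p))
}

# classical one-way ANOVA by the textbook sum-of-squares decomposition
anova_oracle <- function(groups) {
  y <- unlist(groups)
  k <- length(groups)
  n <- length(y)
  gbar <- mean(y)
  ss_b <- sum(vapply(groups, function(v) length(v) * (mean(v) - gbar)^2,
                     numeric(1)))
  ss_w <- sum(vapply(groups, function(v) sum((v - mean(v))^2), numeric(1)))
  f <- (ss_b / (k - 1)) / (ss_w / (n - k))
  list(F = f, p = stats::pf(f, k - 1, n - k, lower.tail = FALSE))
}

chi2_oracle <- function(m, yates = FALSE) {
  a <- m[1, 1]; b <- m[1, 2]; c_ <- m[2, 1]; d <- m[2, 2]
  n <- sum(m)
  cross <- abs(a * d - b * c_)
  corr <- if (yates) min(n / 2, cross) else 0
  stat <- n * (cross - corr)^2 / ((a + b) * (c_ + d) * (a + c_) * (b + d))
  list(stat = stat, p = stats::pchisq(stat, 1, lower.tail = FALSE))
}

pearson_oracle <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(t), n - 2))
}
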