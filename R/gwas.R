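# Intersection of candidate CNVs with a per-SNP association track: derived
# Bonferroni bound over the SNPs falling inside the candidate set, per-CNV
# minimum p, and a Monte-Carlo size-matched placement null for the number of
# significant-locus-containing CNVs.

#' Bonferroni-corrected significance threshold
#'
#' @param alpha familywise level in (0, 1).
#' @param n_tests number of tests (>= 1).
#' @return `alpha / n_tests`.
#' @export
bonferroni_threshold <- function(alpha = 0.05, n_tests) {
  alpha <- .check_fraction(alpha, "alpha", lo = 1e-300)
  n_tests <- .check_count(n_tests, "n_tests", min = 1)
  alpha / n_tests
}

#' Per-CNV SNP overlap summary
#'
#' The number of tests is the total count of SNPs falling inside the union
#' of the candidate CNVs (half-open containment: a SNP exactly at a CNV end
#' is outside). Each CNV reports its contained-SNP count and minimum p, and
#' is flagged significant when that minimum beats `alpha / n_tests`.
#'
#' @param cnvs call table of candidate CNVs.
#' @param snps SNP track (`chrom`, `pos`, `p`).
#' @param alpha familywise level.
#' @return list with `per_cnv` (data.frame `call_id`, `n_snps`, `min_p`,
#'   `significant`), `n_tests`, `bonferroni_alpha`.
#' @export
summarize_overlap <- function(cnvs, snps, alpha = 0.05) {
  n <- nrow(cnvs)
  n_snps <- integer(n); min_p <- rep(NA_real_, n)
  in_union <- rep(FALSE, nrow(snps))
  by_chrom <- split(seq_len(nrow(snps)), snps$chrom)
  for (i in seq_len(n)) {
    idx <- by_chrom[[cnvs$chrom[i]]]
    if (is.null(idx)) next
    inside <- idx[snps$pos[idx] >= cnvs$start[i] & snps$pos[idx] < cnvs$end[i]]
    n_snps[i] <- length(inside)
    if (length(inside)) min_p[i] <- min(snps$p[inside])
    in_union[inside] <- TRUE
  }
  n_tests <- sum(in_union)
  thr <- if (n_tests >= 1L) bonferroni_threshold(alpha, n_tests) else NA_real_
  per_cnv <- data.frame(call_id = cnvs$call_id, n_snps = n_snps, min_p = min_p,
                        significant = !is.na(min_p) & !is.na(thr) & min_p < thr,
                        stringsAsFactors = FALSE)
  list(per_cnv = per_cnv, n_tests = n_tests, bonferroni_alpha = thr)
}

#' Monte-Carlo enrichment of significant-locus-containing CNVs
#'
#' Null model: each draw places one random interval per candidate CNV,
#' size-matched, uniformly on the genome (chromosome chosen with probability
#' proportional to the room it offers), and counts how many placed intervals
#' contain at least one SNP below `threshold`. The p-value is
#' `(1 + #\{draws with count >= observed\}) / (1 + n_draws)`.
#'
#' @param n_significant observed number of significant-locus-containing CNVs.
#' @param cnvs candidate call table (sizes are reused for the placements).
#' @param snps SNP track.
#' @param chrom_lengths named numeric vector of chromosome lengths (bp).
#' @param threshold significance threshold for a SNP (e.g. the Bonferroni
#'   bound from [summarize_overlap()]).
#' @param n_draws Monte-Carlo draws.
#' @param seed integer seed.
#' @return list with `p_value`, `null_counts`.
#' @export
overlap_enrichment <- function(n_significant, cnvs, snps, chrom_lengths,
                               threshold, n_draws = 1000L, seed = 1L) {
  n_significant <- .check_count(n_significant, "n_significant")
  sizes <- cnvs$end - cnvs$start
  if (any(sizes > max(chrom_lengths)))
    .stopf("candidate interval larger than every chromosome")
  hits <- snps[snps$p < threshold, , drop = FALSE]
  hit_pos <- lapply(split(hits$pos, hits$chrom), sort)
  withr::local_seed(seed)
  chroms <- names(chrom_lengths)
  null_counts <- integer(n_draws)
  for (d in seq_len(n_draws)) {
    cnt <- 0L
    for (s in sizes) {
      room <- pmax(0, chrom_lengths - s)
      ci <- sample.int(length(chroms), 1L, prob = room)
      start <- floor(stats::runif(1) * room[ci])
      pos <- hit_pos[[chroms[ci]]]
      if (!is.null(pos)) {
        k <- findInterval(c(start - 1, start + s - 1), pos)
        if (k[2] > k[1]) cnt <- cnt + 1L
      }
    }
    null_counts[d] <- cnt
  }
  list(p_value = (1 + sum(null_counts >= n_significant)) / (1 + n_draws),
       null_counts = null_counts)
}
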