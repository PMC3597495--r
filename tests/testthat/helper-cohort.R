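# Small shared builders for unit tests.

small_config <- function(seed = 7L, ...) {
  defaults <- list(seed = seed, n_cases = 20L, n_controls = 60L, n_chromosomes = 4L,
                   chromosome_length_bp = 5e7, mean_calls_per_sample = 8,
                   polymorphic_pool_size = 5L, polymorphic_carrier_rate = 0.4,
                   n_snps = 500L, n_genes = 60L)
  args <- utils::modifyList(defaults, list(...))
  do.call(simulation_config, args)
}

# build a call table directly from coordinates
make_calls <- function(sample_id, chrom, start, end, copy_state = 1L, n_markers = 10L) {
  cnv_calls(data.frame(sample_id = sample_id, chrom = chrom, start = start,
                       end = end, copy_state = copy_state, n_markers = n_markers,
                       stringsAsFactors = FALSE))
}

# minimal single-gene annotation
make_gene <- function(gene_id = "g1", chrom = "chr1", start = 1000, end = 2000,
                      exon_starts = as.character(start),
                      exon_ends = as.character(end),
                      growth_gene = FALSE, mgi_growth = FALSE,
                      functional_candidate = FALSE, growth_tissue_expressed = FALSE,
                      decipher_overlap = FALSE, hi_percentile = 50) {
  gene_table(data.frame(gene_id = gene_id, chrom = chrom, start = start, end = end,
                        exon_starts = exon_starts, exon_ends = exon_ends,
                        growth_gene = growth_gene, mgi_growth = mgi_growth,
                        functional_candidate = functional_candidate,
                        growth_tissue_expressed = growth_tissue_expressed,
                        decipher_overlap = decipher_overlap,
                        hi_percentile = hi_percentile, stringsAsFactors = FALSE))
}

# independent Fisher oracle: enumerate all tables with the observed margins
# using binomial coefficients (no dhyper), two-sided mass rule
fisher_oracle <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0, k - n); hi <- min(k, m)
  av <- lo:hi
  probs <- choose(m, av) * choose(n, k - av) / choose(m + n, k)
  p_obs <- probs[a - lo + 1]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# independent Pearson chi2 (no correction) from a 2x2 table built explicitly
chi2_oracle <- function(status, is_case) {
  tab <- table(factor(status, levels = 0:1), factor(is_case, levels = c(FALSE, TRUE)))
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(e == 0)) return(0)
  sum((tab - e)^2 / e)
}
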