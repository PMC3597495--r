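test_that("configuration validation names the offending field", {
  expect_error(simulation_config(n_cases = -1), "n_cases")
  expect_error(simulation_config(size_log_sd = 0), "size_log_sd")
  expect_error(simulation_config(pathogenic_fraction = 1.2), "pathogenic_fraction")
  expect_error(simulation_config(polymorphic_carrier_rate = -0.1), "polymorphic_carrier_rate")
})

test_that("identical config and seed reproduce identical cohorts", {
  cfg <- small_config(seed = 11L)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  c <- generate_cohort(small_config(seed = 12L))
  expect_false(identical(a$case_calls, c$case_calls))
})

test_that("per-sample call counts are Poisson with the configured mean", {
  cfg <- simulation_config(seed = 1L, n_cases = 200L, n_controls = 0L,
                           mean_calls_per_sample = 32, pathogenic_fraction = 0,
                           polymorphic_pool_size = 0L, n_genes = 50L)
  co <- generate_cohort(cfg)
  total <- nrow(co$case_calls)
  expect_lt(abs(total - 200 * 32), 3 * sqrt(200 * 32))
  per_sample <- table(co$case_calls$sample_id)
  expect_equal(round(mean(per_sample)), 32)
})

test_that("ground truth indexes spikes and polymorphic pool correctly", {
  cfg <- small_config(seed = 5L, pathogenic_fraction = 0.5, de_novo_fraction = 0.5)
  co <- generate_cohort(cfg)
  expect_true(all(co$truth$spikes$call_id %in% co$case_calls$call_id))
  expect_false(any(co$truth$spikes$call_id %in% co$control_calls$call_id))
  expect_true(all(co$truth$spikes$inheritance %in% c("de_novo", "inherited_affected")))
  # inherited spikes present in the transmitting (affected) parent
  inh <- co$truth$spikes[co$truth$spikes$inheritance == "inherited_affected", ]
  for (i in seq_len(nrow(inh))) {
    pc <- co$parent_calls[co$parent_calls$sample_id == inh$transmitting_parent[i], ]
    key <- sub("^[^:]+:", "", inh$call_id[i])
    expect_true(any(sub("^[^:]+:", "", pc$call_id) == key))
    expect_true(co$samples$affected[co$samples$sample_id == inh$transmitting_parent[i]])
  }
  # de novo spikes absent from both parents
  dn <- co$truth$spikes[co$truth$spikes$inheritance == "de_novo", ]
  for (i in seq_len(nrow(dn))) {
    tr <- co$trios[co$trios$child_id == dn$sample_id[i], ]
    pc <- co$parent_calls[co$parent_calls$sample_id %in% c(tr$mother_id, tr$father_id), ]
    key <- sub("^[^:]+:", "", dn$call_id[i])
    expect_false(any(sub("^[^:]+:", "", pc$call_id) == key))
  }
  # no spikes, no pool -> empty truth sets
  co0 <- generate_cohort(small_config(pathogenic_fraction = 0, polymorphic_pool_size = 0L))
  expect_identical(nrow(co0$truth$spikes), 0L)
  expect_length(co0$truth$polymorphic_call_ids, 0)
})

test_that("polymorphic pool members recur in controls above the rarity cut", {
  cfg <- small_config(seed = 3L, n_controls = 100L, polymorphic_carrier_rate = 0.4)
  co <- generate_cohort(cfg)
  pool_calls <- co$control_calls[co$control_calls$call_id %in% co$truth$polymorphic_call_ids, ]
  carriers <- tapply(pool_calls$sample_id, paste(pool_calls$chrom, pool_calls$start), function(x) length(unique(x)))
  expect_true(all(carriers > 15))
})

test_that("gene annotation is non-overlapping with exons inside spans and calibrated flags", {
  cfg <- simulation_config(seed = 2L, n_genes = 100L, n_chromosomes = 1L,
                           chromosome_length_bp = 1e7)
  g <- generate_gene_annotation(cfg)
  expect_equal(nrow(g), 100L)
  ord <- g[order(g$start), ]
  expect_true(all(ord$start[-1] >= ord$end[-nrow(ord)]))
  ex <- gene_exons(g)
  span <- g[match(ex$gene_id, g$gene_id), ]
  expect_true(all(ex$start >= span$start & ex$end <= span$end))
  # flag rate within the binomial 99% interval
  cfg2 <- simulation_config(seed = 4L, n_genes = 1000L, n_chromosomes = 10L,
                            chromosome_length_bp = 1e8,
                            flag_rates = c(growth_gene = 0.1, mgi_growth = 0.05,
                                           functional_candidate = 0.05,
                                           growth_tissue_expressed = 0.3,
                                           decipher_overlap = 0.02))
  g2 <- generate_gene_annotation(cfg2)
  bounds <- qbinom(c(0.005, 0.995), 1000, 0.1)
  expect_gte(sum(g2$growth_gene), bounds[1])
  expect_lte(sum(g2$growth_gene), bounds[2])
  # degenerate cases
  expect_equal(nrow(generate_gene_annotation(small_config(n_genes = 0L))), 0L)
  expect_error(generate_gene_annotation(small_config(n_genes = 10000L, chromosome_length_bp = 1e5)),
               "too small")
})

test_that("expression generator recovers the configured dosage shift", {
  cfg <- small_config(seed = 9L)
  genes <- generate_gene_annotation(cfg)
  carriers <- data.frame(sample_id = "s1", gene_id = genes$gene_id[1], cnv_type = "gain")
  ids <- c("s1", sprintf("c%d", 1:5))
  m0 <- generate_expression(carriers, genes, ids, cfg, noise_sd = 1e-12)
  expect_equal(m0[genes$gene_id[1], "s1"] - mean(m0[genes$gene_id[1], -1]),
               log2(1.5), tolerance = 1e-6)
  # loss effect of -1 recovered within 3 SE at 50 carriers
  carr50 <- data.frame(sample_id = sprintf("s%d", 1:50), gene_id = genes$gene_id[2],
                       cnv_type = "loss")
  ids50 <- c(sprintf("s%d", 1:50), sprintf("c%d", 1:50))
  m1 <- generate_expression(carr50, genes, ids50, cfg, noise_sd = 0.3)
  shift <- mean(m1[genes$gene_id[2], 1:50]) - mean(m1[genes$gene_id[2], 51:100])
  se <- 0.3 * sqrt(2 / 50)
  expect_lt(abs(shift - (-1)), 3 * se)
  # unknown carrier reference rejected
  expect_error(generate_expression(data.frame(sample_id = "nope", gene_id = "nope2",
                                              cnv_type = "gain"), genes, ids, cfg),
               "unknown")
})

test_that("null expression p-values are uniform at the nominal rate", {
  cfg <- small_config(seed = 21L)
  genes <- generate_gene_annotation(small_config(seed = 21L, n_genes = 400L))
  ids <- c(sprintf("a%d", 1:10), sprintf("b%d", 1:10))
  m <- generate_expression(data.frame(sample_id = character(), gene_id = character(),
                                      cnv_type = character()), genes, ids, cfg)
  pv <- apply(m, 1, function(v) de_test(v, ids[1:10], ids[11:20])$p_value)
  expect_lt(abs(mean(pv < 0.05) - 0.05), 0.035)  # binomial noise at n=400
  expect_gt(suppressWarnings(ks.test(pv, "punif")$p.value), 0.01)
})

test_that("snp track has uniform background and guaranteed signal SNPs", {
  cfg <- small_config(seed = 13L, n_snps = 10000L)
  bg <- generate_snp_track(cfg)
  expect_equal(nrow(bg), 10000L)
  expect_gt(min(bg$p), 1 / 10000 / 100)  # min of n uniforms ~ 1/n order
  expect_lt(min(bg$p), 10 / 10000 * 10)
  loci <- data.frame(chrom = "chr1", start = 1e6, end = 2e6)
  tr <- generate_snp_track(cfg, loci, signal_level = 1e-14)
  inside <- tr$chrom == "chr1" & tr$pos >= 1e6 & tr$pos < 2e6
  expect_true(any(tr$p[inside] < 1e-14))
  empty <- generate_snp_track(small_config(n_snps = 0L))
  expect_equal(nrow(empty), 0L)
})

test_that("mlpa generator emits carrier ratios near the dosage expectation", {
  calls <- make_calls(c("p1", "p2"), "chr1", c(1000, 5000), c(3000, 8000),
                      copy_state = c(1L, 3L))
  ml <- generate_mlpa(calls, c("c1", "c2", "c3"), noise_sd = 0.02, seed = 3L)
  carrier <- ml[ml$sample_id %in% c("p1", "p2"), ]
  expect_equal(mlpa_classify(carrier$ratio[carrier$sample_id == "p1"]), "deletion")
  expect_equal(mlpa_classify(carrier$ratio[carrier$sample_id == "p2"]), "duplication")
  expect_true(all(mlpa_classify(ml$ratio[ml$sample_id %in% c("c1", "c2", "c3")]) == "normal"))
})
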