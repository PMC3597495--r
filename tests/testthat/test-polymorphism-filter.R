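test_that("size_overlap_fraction is asymmetric in its arguments", {
  a <- list(chrom = "chr1", start = 1000, end = 2000)
  expect_equal(size_overlap_fraction(a, a), 1.0)
  b <- list(chrom = "chr1", start = 5000, end = 6000)
  expect_equal(size_overlap_fraction(a, b), 0.0)
  c1 <- list(chrom = "chr1", start = 1500, end = 3000)
  expect_equal(size_overlap_fraction(a, c1), 0.5)       # 500 / 1000
  expect_equal(size_overlap_fraction(c1, a), 500 / 1500)
  other <- list(chrom = "chr2", start = 1000, end = 2000)
  expect_equal(size_overlap_fraction(a, other), 0.0)
})

test_that("control carrier counting matches a brute-force double loop", {
  cnv <- make_calls("q", "chr1", 10000, 20000, 1L)
  # 20 identical calls in distinct controls
  ctrl <- make_calls(sprintf("c%02d", 1:20), "chr1", 10000, 20000, 1L)
  expect_equal(control_carrier_count(cnv[1, ], ctrl), 20L)
  expect_equal(control_carrier_count(cnv[1, ], ctrl[0, ]), 0L)
  # gains do not match a loss query
  gains <- make_calls(sprintf("g%02d", 1:5), "chr1", 10000, 20000, 3L)
  expect_equal(control_carrier_count(cnv[1, ], rbind(ctrl, gains)), 20L)
  # random 50-control instance vs quadratic oracle
  withr::with_seed(42, {
    n <- 200
    ctrl <- make_calls(sample(sprintf("c%02d", 1:50), n, TRUE), "chr1",
                       s <- sample.int(50000, n), s + sample.int(15000, n) + 100,
                       copy_state = sample(c(1L, 3L), n, TRUE))
    queries <- make_calls("q", "chr1", qs <- sample.int(50000, 30),
                          qs + sample.int(15000, 30) + 100,
                          copy_state = sample(c(1L, 3L), 30, TRUE))
  })
  cfg <- filter_config()
  for (i in seq_len(nrow(queries))) {
    q <- queries[i, ]
    brute <- length(unique(unlist(lapply(seq_len(nrow(ctrl)), function(j) {
      b <- ctrl[j, ]
      ov <- max(0, min(q$end, b$end) - max(q$start, b$start))
      if (b$cnv_type == q$cnv_type && ov / (q$end - q$start) > 0.95) b$sample_id else NULL
    }))))
    expect_equal(control_carrier_count(q, ctrl, cfg), brute)
  }
})

test_that("gene-coverage exclusion requires every overlapped gene covered in enough controls", {
  g1 <- make_gene("g1", "chr1", 10000, 12000)
  cnv <- make_calls("q", "chr1", 9000, 13000, 1L)[1, ]
  covering <- make_calls(sprintf("c%02d", 1:15), "chr1", 9500, 12500, 1L)
  expect_true(gene_coverage_excluded(cnv, covering, g1))
  expect_false(gene_coverage_excluded(cnv, covering[1:14, ], g1))
  # a second, uncovered gene rescues the CNV
  g2 <- rbind(g1, make_gene("g2", "chr1", 12500, 12900))
  cnv2 <- make_calls("q", "chr1", 9000, 12950, 1L)[1, ]
  expect_false(gene_coverage_excluded(cnv2, covering, g2))
  # zero overlapped genes never triggers this rule
  far <- make_calls("q", "chr1", 1e6, 2e6, 1L)[1, ]
  expect_false(gene_coverage_excluded(far, covering, g1))
  # type-matched: loss query not covered by gains
  gains <- make_calls(sprintf("c%02d", 1:15), "chr1", 9500, 12500, 3L)
  expect_false(gene_coverage_excluded(cnv, gains, g1))
})

test_that("exonic filter keeps exon-intersecting calls only", {
  g <- make_gene("g1", "chr1", 10000, 20000, exon_starts = "10000,18000",
                 exon_ends = "11000,19000")
  expect_true(exonic_filter(make_calls("q", "chr1", 5000, 25000, 1L)[1, ], g))   # whole gene
  expect_false(exonic_filter(make_calls("q", "chr1", 12000, 15000, 1L)[1, ], g)) # intronic
  expect_false(exonic_filter(make_calls("q", "chr1", 1e6, 2e6, 1L)[1, ], g))     # intergenic
  expect_false(exonic_filter(make_calls("q", "chr2", 10500, 10900, 1L)[1, ], g)) # other chrom
})

test_that("cascade removes polymorphic pool calls and keeps pathogenic spikes", {
  cfg <- small_config(seed = 23L, n_controls = 100L, polymorphic_carrier_rate = 0.4,
                      pathogenic_fraction = 0.3)
  co <- generate_cohort(cfg)
  res <- run_cascade(co$case_calls, co$control_calls, co$genes)
  surv <- res$calls$call_id
  expect_false(any(co$truth$polymorphic_call_ids %in% surv))
  expect_true(all(co$truth$spikes$call_id %in% surv))
  # counts monotone non-increasing, one first-failing stage per exclusion
  expect_true(all(diff(res$report$n_out) <= 0 | res$report$n_in[-1] == res$report$n_out[-nrow(res$report)]))
  expect_true(all(res$report$n_out <= res$report$n_in))
  expect_false(any(duplicated(res$exclusions$call_id)))
  expect_equal(nrow(res$exclusions) + nrow(res$calls), nrow(co$case_calls))
})

test_that("cascade is idempotent and empty input yields an all-zero report", {
  cfg <- small_config(seed = 29L)
  co <- generate_cohort(cfg)
  res1 <- run_cascade(co$case_calls, co$control_calls, co$genes)
  res2 <- run_cascade(res1$calls, co$control_calls, co$genes)
  expect_equal(res2$calls$call_id, res1$calls$call_id)
  expect_equal(nrow(res2$exclusions), 0L)
  res0 <- run_cascade(co$case_calls[0, ], co$control_calls, co$genes)
  expect_equal(nrow(res0$calls), 0L)
  expect_true(all(res0$report$n_in == 0L & res0$report$n_out == 0L))
})

test_that("tightening the overlap fraction never excludes more at the polymorphism stage", {
  cfg <- small_config(seed = 31L, n_controls = 80L, polymorphic_carrier_rate = 0.35)
  co <- generate_cohort(cfg)
  excl_at <- function(frac) {
    fc <- filter_config(overlap_fraction = frac)
    res <- run_cascade(co$case_calls, co$control_calls, co$genes, fc)
    sum(res$exclusions$stage == "polymorphism")
  }
  counts <- vapply(c(0.5, 0.7, 0.9, 0.95, 0.99), excl_at, numeric(1))
  expect_true(all(diff(counts) <= 0))
})
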