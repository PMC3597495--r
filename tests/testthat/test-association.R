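test_that("pseudomarkers deduplicate endpoints and match a set oracle", {
  calls <- make_calls("s1", "chr1", 1000, 2000)
  m <- build_pseudomarkers(calls)
  expect_equal(m$position, c(1000, 2000))
  # two segments sharing a start -> 3 markers
  calls2 <- make_calls(c("s1", "s2"), "chr1", c(1000, 1000), c(2000, 3000))
  expect_equal(nrow(build_pseudomarkers(calls2)), 3L)
  # random instance vs brute-force endpoint union
  withr::with_seed(8, {
    n <- 100
    calls3 <- make_calls(sprintf("s%d", sample.int(20, n, TRUE)),
                         sprintf("chr%d", sample.int(3, n, TRUE)),
                         st <- sample.int(100000, n), st + sample.int(5000, n))
  })
  m3 <- build_pseudomarkers(calls3)
  brute <- unique(rbind(data.frame(chrom = calls3$chrom, position = calls3$start),
                        data.frame(chrom = calls3$chrom, position = calls3$end)))
  expect_equal(nrow(m3), nrow(brute))
  expect_setequal(paste(m3$chrom, m3$position), paste(brute$chrom, brute$position))
  expect_false(is.unsorted(m3$position[m3$chrom == "chr1"]))
})

test_that("carrier status respects half-open containment", {
  calls <- make_calls("s1", "chr1", 1000, 2000, 3L)
  markers <- data.frame(chrom = "chr1", position = c(1000, 1500, 2000), source = "start")
  sm <- status_matrix(calls, markers, c("s1", "s2"), "gain")
  expect_equal(sm["s1", ], c(1L, 1L, 0L))  # start in, end out
  expect_equal(sm["s2", ], c(0L, 0L, 0L))
  # losses invisible to a gain query
  expect_true(all(status_matrix(make_calls("s1", "chr1", 1000, 2000, 1L),
                                markers, "s1", "gain") == 0L))
  # random small instance vs double loop
  withr::with_seed(12, {
    calls2 <- make_calls(sprintf("s%d", sample.int(6, 40, TRUE)), "chr1",
                         st <- sample.int(5000, 40), st + sample.int(2000, 40),
                         copy_state = sample(c(1L, 3L), 40, TRUE))
  })
  mk <- build_pseudomarkers(calls2)
  ids <- sort(unique(calls2$sample_id))
  sm2 <- status_matrix(calls2, mk, ids, "loss")
  for (i in seq_along(ids)) for (j in seq_len(nrow(mk))) {
    sub <- calls2[calls2$sample_id == ids[i] & calls2$cnv_type == "loss", ]
    expect_equal(unname(sm2[i, j]),
                 as.integer(any(sub$start <= mk$position[j] & mk$position[j] < sub$end)))
  }
})

test_that("exhaustive permutation p equals independent enumeration on 8 samples", {
  withr::with_seed(3, {
    for (rep in 1:20) {
      status <- rbinom(8, 1, 0.5)
      if (sum(status) %in% c(0, 8)) next
      is_case <- c(rep(TRUE, 4), rep(FALSE, 4))
      r <- permutation_chi2(status, is_case, mode = "exhaustive")
      sets <- combn(8, 4)
      stats <- apply(sets, 2, function(ix) {
        lab <- rep(FALSE, 8); lab[ix] <- TRUE
        chi2_oracle(status, lab)
      })
      obs <- chi2_oracle(status, is_case)
      expect_equal(r$chi2, obs, tolerance = 1e-12)
      expect_equal(r$p_value, mean(stats >= obs - 1e-12), tolerance = 1e-12)
    }
  })
})

test_that("random-permutation p carries the +1 correction and flags degenerate markers", {
  status <- c(1, 1, 1, 1, 0, 0, 0, 0)
  is_case <- c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE)
  r <- permutation_chi2(status, is_case, n_perm = 200, seed = 5)
  expect_gte(r$p_value, 1 / 201)
  d <- permutation_chi2(rep(1, 8), is_case, n_perm = 100, seed = 1)
  expect_true(d$degenerate)
  expect_equal(d$p_value, 1)
  # equal carrier rates in both groups -> p near 1
  r2 <- permutation_chi2(c(1, 0, 1, 0, 1, 0, 1, 0), is_case, n_perm = 500, seed = 2)
  expect_gt(r2$p_value, 0.5)
  expect_error(permutation_chi2(c(1, 0), c(TRUE, FALSE)), "2 samples")
})

test_that("global label swap leaves permutation p-values unchanged", {
  # exact invariance at the single-marker level under exhaustive enumeration
  withr::with_seed(6, {
    for (k in 1:10) {
      status <- rbinom(10, 1, 0.5)
      if (sum(status) %in% c(0, 10)) next
      is_case <- sample(rep(c(TRUE, FALSE), 5))
      r1 <- permutation_chi2(status, is_case, mode = "exhaustive")
      r2 <- permutation_chi2(status, !is_case, mode = "exhaustive")
      expect_equal(r1$chi2, r2$chi2, tolerance = 1e-12)
      expect_equal(r1$p_value, r2$p_value, tolerance = 1e-12)
    }
  })
})

test_that("marker-wide association applies the Bonferroni correction within bounds", {
  cfg <- small_config(seed = 41L, n_cases = 8L, n_controls = 8L,
                      mean_calls_per_sample = 5, polymorphic_pool_size = 0L,
                      pathogenic_fraction = 0)
  co <- generate_cohort(cfg)
  a <- associate_markers(co$case_calls, co$control_calls, "both", n_perm = 300, seed = 9)
  expect_true(all(a$p_value >= 1 / 301))
  expect_true(all(a$bonferroni_p >= a$p_value - 1e-12))
  expect_true(all(a$bonferroni_p <= 1))
  expect_setequal(unique(a$cnv_type), c("gain", "loss"))
})
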