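test_that("two-group one-way ANOVA equals the squared pooled t", {
  withr::with_seed(5, {
    for (k in 1:10) {
      x <- rnorm(6); y <- rnorm(5, 1)
      v <- setNames(c(x, y), c(sprintf("a%d", 1:6), sprintf("b%d", 1:5)))
      r <- de_test(v, names(v)[1:6], names(v)[7:11])
      tt <- t.test(x, y, var.equal = TRUE)
      expect_equal(r$statistic, unname(tt$statistic)^2, tolerance = 1e-10)
      expect_equal(r$p_value, tt$p.value, tolerance = 1e-10)
    }
  })
  # strong separation with tiny jitter
  v <- setNames(c(0, 0, 0, 1, 1, 1) + c(1e-6, -1e-6, 0, 1e-6, -1e-6, 0),
                c("a1", "a2", "a3", "b1", "b2", "b3"))
  expect_lt(de_test(v, c("a1", "a2", "a3"), c("b1", "b2", "b3"))$p_value, 1e-3)
  # degenerate zero-variance cases
  z <- setNames(c(1, 1, 1, 1), c("a1", "a2", "b1", "b2"))
  expect_equal(de_test(z, c("a1", "a2"), c("b1", "b2"))$p_value, 1)
  z2 <- setNames(c(1, 1, 2, 2), c("a1", "a2", "b1", "b2"))
  expect_equal(de_test(z2, c("a1", "a2"), c("b1", "b2"))$p_value, 0)
  expect_error(de_test(z, "a1", c("b1", "b2")), "2 samples")
})

test_that("signed fold change uses the reciprocal convention", {
  expect_equal(signed_fold_change(9, 8), 2)
  expect_equal(signed_fold_change(8, 9), -2)
  expect_equal(signed_fold_change(8, 8), 1)
  expect_equal(signed_fold_change(8 + log2(1.5), 8), 1.5)
})

test_that("concordance calls require significance, direction and magnitude", {
  cfg <- expression_config()
  expect_true(concordance_call(0.01, 1.5, "gain", cfg))
  expect_false(concordance_call(0.001, -2.0, "gain", cfg))  # discordant direction
  expect_false(concordance_call(0.01, -1.30, "loss", cfg))  # magnitude below 1.33
  expect_true(concordance_call(0.01, -1.4, "loss", cfg))
  expect_false(concordance_call(0.2, 1.5, "gain", cfg))     # not significant
  expect_error(expression_config(fc_up_min = 0.9), "fc_up_min")
  expect_error(expression_config(fc_down_min = -0.5), "fc_down_min")
})

test_that("binomial concordance tail matches the closed-form oracle", {
  expect_equal(concordance_binomial(0, 188), 1.0)
  # oracle route: pbinom upper tail
  expect_equal(concordance_binomial(58, 188, 0.025),
               pbinom(57, 188, 0.025, lower.tail = FALSE), tolerance = 1e-10)
  expect_lt(concordance_binomial(58, 188, 0.025), 1e-3)
  expect_equal(concordance_binomial(5, 188, 0.025),
               pbinom(4, 188, 0.025, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(round(concordance_binomial(5, 188, 0.025), 4), 0.507)
  # monotone decreasing in k
  ks <- c(1, 3, 5, 10, 20, 58)
  ps <- vapply(ks, concordance_binomial, numeric(1), n_genes = 188)
  expect_true(all(diff(ps) < 0))
  expect_error(concordance_binomial(10, 5), "exceed")
})

test_that("single-carrier genes use the single-case comparison", {
  # one carrier of a strong loss vs 10 references: detectable and concordant
  cfg <- small_config(seed = 61L, n_genes = 10L)
  genes <- generate_gene_annotation(cfg)
  cm <- data.frame(sample_id = "p1", gene_id = genes$gene_id[1], cnv_type = "loss")
  ids <- c("p1", sprintf("r%02d", 1:10))
  m <- generate_expression(cm, genes, ids, cfg, noise_sd = 0.1)
  res <- analyze_expression(m, cm)
  expect_equal(nrow(res), 1L)
  expect_true(res$concordant)
  # Crawford-Howell p agrees with the closed form
  y <- m[genes$gene_id[1], -1]; x <- m[genes$gene_id[1], 1]
  tt <- (x - mean(y)) / (sd(y) * sqrt(1 + 1 / 10))
  expect_equal(res$p_value, 2 * pt(-abs(tt), 9), tolerance = 1e-12)
  # too few references: gene skipped rather than mis-tested
  res2 <- analyze_expression(m[, 1:3], cm)
  expect_equal(nrow(res2), 0L)
})

test_that("dosage-sensitive genes are recovered as concordant on synthetic data", {
  cfg <- small_config(seed = 53L, n_genes = 60L)
  genes <- generate_gene_annotation(cfg)
  # 20 dosage-sensitive genes, 10 carriers each, alternating gain/loss
  sens <- genes$gene_id[1:20]
  typ <- rep(c("gain", "loss"), 10)
  carriers <- do.call(rbind, lapply(1:20, function(i)
    data.frame(sample_id = sprintf("s%02d", 1:10), gene_id = sens[i],
               cnv_type = typ[i], stringsAsFactors = FALSE)))
  ids <- c(sprintf("s%02d", 1:10), sprintf("c%02d", 1:10))
  m <- generate_expression(carriers, genes, ids, cfg, noise_sd = 0.3)
  res <- analyze_expression(m, carriers)
  expect_gte(mean(res$concordant), 0.8)
  # a null (non-carrier) map on the same matrix calls almost nothing
  null_map <- data.frame(sample_id = rep(sprintf("c%02d", 1:10), 5),
                         gene_id = rep(genes$gene_id[41:45], each = 10),
                         cnv_type = "gain", stringsAsFactors = FALSE)
  res0 <- analyze_expression(m, null_map)
  expect_lte(mean(res0$concordant), 0.2)
})
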