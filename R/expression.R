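# Dosage-concordant differential expression: per-gene one-way ANOVA between
# carrier and non-carrier samples, a signed fold-change convention on
# anti-logged group means, direction-of-dosage concordance calls, and a
# binomial test of the concordant count against a per-gene null.

#' Build and validate an expression-analysis configuration
#'
#' @param alpha_per_gene per-gene significance level (raw, uncorrected; the
#'   global claim is carried by the binomial test, not per-gene adjustment).
#' @param fc_up_min minimum fold change for an up-regulation call (> 1).
#' @param fc_down_min maximum (signed) fold change for a down-regulation
#'   call (< -1; -1.33 means at least a 1.33-fold reduction).
#' @param null_concordance_p per-gene null probability of a concordant call:
#'   alpha 0.05 halved because direction must also match.
#' @return list of class `expression_config`.
#' @export
expression_config <- function(alpha_per_gene = 0.05, fc_up_min = 1.25,
                              fc_down_min = -1.33, null_concordance_p = 0.025) {
  if (fc_up_min <= 1) .stopf("'fc_up_min' must exceed 1")
  if (fc_down_min >= -1) .stopf("'fc_down_min' must be below -1")
  cfg <- list(alpha_per_gene = .check_fraction(alpha_per_gene, "alpha_per_gene", lo = 1e-12),
              fc_up_min = as.numeric(fc_up_min),
              fc_down_min = as.numeric(fc_down_min),
              null_concordance_p = .check_fraction(null_concordance_p, "null_concordance_p", lo = 1e-12))
  class(cfg) <- "expression_config"
  cfg
}

#' One-way ANOVA differential-expression test for one gene
#'
#' Equal-variance one-way ANOVA between carriers and non-carriers; with two
#' groups the F statistic equals the squared pooled-variance t statistic.
#' When both groups have zero within-group variance the test is undefined:
#' equal means return p = 1 by convention, unequal means p = 0.
#'
#' @param values named numeric vector of log2 expression for one gene.
#' @param carrier_ids,control_ids sample names of the two groups (>= 2 each).
#' @return list with `statistic` (F) and `p_value`.
#' @export
de_test <- function(values, carrier_ids, control_ids) {
  x <- values[carrier_ids]; y <- values[control_ids]
  if (length(x) < 2L || length(y) < 2L) .stopf("need at least 2 samples per group")
  if (any(!is.finite(c(x, y)))) .stopf("non-finite expression values")
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (mean(x) == mean(y)) return(list(statistic = 0, p_value = 1))
    return(list(statistic = Inf, p_value = 0))
  }
  g <- factor(rep(c("carrier", "control"), c(length(x), length(y))))
  ht <- stats::oneway.test(c(x, y) ~ g, var.equal = TRUE)
  list(statistic = unname(ht$statistic), p_value = ht$p.value)
}

#' Signed fold change from log2 group means
#'
#' Anti-logged ratio of carrier to control means, with the signed-reciprocal
#' convention: ratios >= 1 are reported as-is, ratios < 1 as the negative
#' reciprocal (so a halving is -2, not 0.5).
#'
#' @param carrier_mean,control_mean log2 group means.
#' @return signed fold change.
#' @export
signed_fold_change <- function(carrier_mean, control_mean) {
  r <- 2^(carrier_mean - control_mean)
  ifelse(r >= 1, r, -1 / r)
}

#' Direction-of-dosage concordance call
#'
#' A gene is concordant when its test is significant and its fold change
#' matches the CNV direction at the configured magnitude: gains need
#' fold >= `fc_up_min`, losses fold <= `fc_down_min`.
#'
#' @param p_value per-gene test p-value.
#' @param fold_change signed fold change.
#' @param cnv_type `"gain"` or `"loss"`.
#' @param config an [expression_config()].
#' @return logical.
#' @export
concordance_call <- function(p_value, fold_change, cnv_type, config = expression_config()) {
  sig <- p_value < config$alpha_per_gene
  dir_ok <- ifelse(cnv_type == "gain", fold_change >= config$fc_up_min,
                   fold_change <= config$fc_down_min)
  sig & dir_ok
}

# single-case comparison of one carrier against a reference group
# (Crawford-Howell): t = (x - mean(y)) / (sd(y) * sqrt(1 + 1/n)), df = n - 1
.single_case_test <- function(x, y) {
  n <- length(y)
  s <- stats::sd(y)
  if (s == 0) return(list(statistic = if (x == mean(y)) 0 else Inf,
                          p_value = as.numeric(x == mean(y))))
  tt <- (x - mean(y)) / (s * sqrt(1 + 1 / n))
  list(statistic = tt^2, p_value = 2 * stats::pt(-abs(tt), n - 1L))
}

#' Analyze carrier vs non-carrier expression for a set of genes
#'
#' Genes with two or more carriers are tested by the two-group one-way ANOVA
#' of [de_test()]; genes carried by a single sample (the common situation
#' when every candidate CNV has one proband) fall back to a single-case t
#' comparison against the reference group (Crawford-Howell), which needs at
#' least 3 reference samples.
#'
#' @param mat log2 expression matrix (genes x samples).
#' @param carrier_map data.frame with `gene_id`, `sample_id`, `cnv_type`
#'   marking which samples carry a CNV over each gene.
#' @param config an [expression_config()].
#' @return data.frame with `gene_id`, `cnv_type`, `carrier_mean`,
#'   `control_mean`, `fold_change`, `p_value`, `concordant`.
#' @export
analyze_expression <- function(mat, carrier_map, config = expression_config()) {
  genes <- unique(carrier_map$gene_id)
  rows <- lapply(genes, function(g) {
    cm <- carrier_map[carrier_map$gene_id == g, , drop = FALSE]
    carriers <- intersect(unique(cm$sample_id), colnames(mat))
    controls <- setdiff(colnames(mat), carriers)
    if (!(g %in% rownames(mat)) || length(carriers) < 1L)
      return(NULL)
    if (length(carriers) >= 2L && length(controls) >= 2L) {
      tst <- de_test(mat[g, ], carriers, controls)
    } else if (length(carriers) == 1L && length(controls) >= 3L) {
      tst <- .single_case_test(mat[g, carriers], mat[g, controls])
    } else return(NULL)
    fc <- signed_fold_change(mean(mat[g, carriers]), mean(mat[g, controls]))
    typ <- cm$cnv_type[1]
    data.frame(gene_id = g, cnv_type = typ,
               carrier_mean = mean(mat[g, carriers]),
               control_mean = mean(mat[g, controls]),
               fold_change = fc, p_value = tst$p_value,
               concordant = concordance_call(tst$p_value, fc, typ, config),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(gene_id = character(), cnv_type = character(),
                      carrier_mean = numeric(), control_mean = numeric(),
                      fold_change = numeric(), p_value = numeric(),
                      concordant = logical(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Upper-tail binomial probability of the concordant count
#'
#' `P(X >= k)` for `X ~ Binomial(n, p)`, computed by summation of the
#' binomial mass in log space (stable far into the tail).
#'
#' @param k_concordant observed concordant genes.
#' @param n_genes total genes tested.
#' @param null_p per-gene null concordance probability.
#' @return upper-tail probability.
#' @export
concordance_binomial <- function(k_concordant, n_genes, null_p = 0.025) {
  k <- .check_count(k_concordant, "k_concordant")
  n <- .check_count(n_genes, "n_genes")
  null_p <- .check_fraction(null_p, "null_p", lo = 1e-300, hi = 1 - 1e-12)
  if (k > n) .stopf("'k_concordant' cannot exceed 'n_genes'")
  if (k == 0L) return(1)
  lt <- stats::dbinom(k:n, n, null_p, log = TRUE)
  mx <- max(lt)
  min(exp(mx + log(sum(exp(lt - mx)))), 1)
}
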