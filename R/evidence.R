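# Lines-of-evidence aggregation: the candidate rule combining segregation
# with gene-level evidence, per-CNV evidence profiles, cohort summaries by
# inheritance group, and the carrier-vs-rest height comparison.

#' Candidate rule for a prioritized CNV
#'
#' A CNV is retained iff its inheritance is `de_novo` or
#' `inherited_affected` (co-segregation with the phenotype) AND at least one
#' gene-level evidence line is present: a known human growth gene, a mouse-
#' model growth-phenotype gene, a functional candidate gene, or an overlap
#' with a Decipher short-stature imbalance. Vectorized over its arguments.
#'
#' @param inheritance character: `de_novo`, `inherited_affected`,
#'   `inherited_unaffected` or `unresolved`.
#' @param has_growth_gene,has_mgi_growth,has_functional_candidate,has_decipher
#'   logical evidence flags.
#' @return logical.
#' @export
candidate_rule <- function(inheritance, has_growth_gene, has_mgi_growth,
                           has_functional_candidate, has_decipher) {
  seg_ok <- inheritance %in% c("de_novo", "inherited_affected")
  seg_ok & (has_growth_gene | has_mgi_growth | has_functional_candidate | has_decipher)
}

#' Genes disrupted by a CNV breakpoint
#'
#' Genes spanning exactly one boundary of the call (its start XOR its end);
#' genes fully inside, fully outside, or spanning the whole call are not
#' breakpoint-disrupted.
#'
#' @param cnv 1-row call table.
#' @param genes gene table.
#' @return character vector of gene ids.
#' @export
breakpoint_disrupted_genes <- function(cnv, genes) {
  g <- genes[genes$chrom == cnv$chrom, , drop = FALSE]
  spans_start <- g$start < cnv$start & g$end > cnv$start
  spans_end <- g$start < cnv$end & g$end > cnv$end
  g$gene_id[xor(spans_start, spans_end)]
}

#' Per-CNV evidence profile
#'
#' Aggregates the gene-level evidence lines for one candidate CNV: gene
#' count, per-flag gene counts, haploinsufficiency count (HI percentile
#' below `hi_cutoff`), breakpoint-disrupted genes, and optional GWAS minimum
#' p and differential-expression counts when those analyses are supplied.
#'
#' @param cnv 1-row call table.
#' @param genes gene table.
#' @param inheritance inheritance category for the CNV.
#' @param gwas_min_p optional minimum GWAS p inside the CNV.
#' @param n_diff_expressed,n_expr_assayed optional expression counts.
#' @param hi_cutoff haploinsufficiency percentile cut-off (default 10).
#' @return 1-row data.frame evidence profile.
#' @export
evidence_profile <- function(cnv, genes, inheritance, gwas_min_p = NA_real_,
                             n_diff_expressed = NA_integer_,
                             n_expr_assayed = NA_integer_, hi_cutoff = 10) {
  g <- genes[genes$chrom == cnv$chrom &
               .overlap_len(cnv$start, cnv$end, genes$start, genes$end) > 0, , drop = FALSE]
  data.frame(
    call_id = cnv$call_id, sample_id = cnv$sample_id, cnv_type = cnv$cnv_type,
    inheritance = inheritance, size_kb = cnv$size_kb,
    n_genes = nrow(g),
    growth_genes = paste(g$gene_id[g$growth_gene], collapse = ","),
    n_growth_function = sum(g$functional_candidate),
    n_gepis_tissue = sum(g$growth_tissue_expressed),
    n_decipher = sum(g$decipher_overlap),
    n_mgi_growth = sum(g$mgi_growth),
    n_hi_genes = sum(g$hi_percentile < hi_cutoff),
    n_diff_expressed = n_diff_expressed, n_expr_assayed = n_expr_assayed,
    gwas_min_p = gwas_min_p,
    breakpoint_genes = paste(breakpoint_disrupted_genes(cnv, genes), collapse = ","),
    candidate = candidate_rule(inheritance, any(g$growth_gene), any(g$mgi_growth),
                               any(g$functional_candidate), any(g$decipher_overlap)),
    stringsAsFactors = FALSE)
}

.inherit_group <- function(x) {
  ifelse(x %in% c("de novo", "de_novo"), "de_novo", "inherited")
}

#' Cohort summary by inheritance group
#'
#' Group means and counts over the final candidate set: total, de novo and
#' inherited. `cnvs` needs `inheritance` and `size_kb`; per-patient phenotype
#' columns (`sex`, `height_sds`, flags) are summarized when a `samples`
#' table is supplied (matched on `sample_id`/`patient`). Means are computed
#' at full precision; rounding is for display only.
#'
#' @param cnvs data.frame of candidate CNVs (one per patient).
#' @param samples optional sample table.
#' @return data.frame with one row per group (`total`, `de_novo`,
#'   `inherited`): `n`, `mean_size_kb`, and phenotype summaries when
#'   available.
#' @export
summarize_cohort <- function(cnvs, samples = NULL) {
  grp <- .inherit_group(cnvs$inheritance)
  groups <- list(total = rep(TRUE, nrow(cnvs)), de_novo = grp == "de_novo",
                 inherited = grp == "inherited")
  id_col <- intersect(c("sample_id", "patient"), names(cnvs))[1]
  rows <- lapply(names(groups), function(gn) {
    sel <- groups[[gn]]
    out <- data.frame(group = gn, n = sum(sel),
                      mean_size_kb = if (any(sel)) mean(cnvs$size_kb[sel]) else 0,
                      stringsAsFactors = FALSE)
    if (!is.null(samples) && !is.na(id_col)) {
      sm <- samples[match(cnvs[[id_col]][sel], samples$sample_id), , drop = FALSE]
      out$n_male <- sum(sm$sex == "M", na.rm = TRUE)
      out$n_female <- sum(sm$sex == "F", na.rm = TRUE)
      out$mean_height_sds <- if (nrow(sm)) mean(sm$height_sds, na.rm = TRUE) else NA_real_
      for (fl in intersect(c("proportionate", "syndromic", "prenatal_onset",
                             "learning_disability"), names(sm)))
        out[[paste0("n_", fl)]] <- sum(sm[[fl]], na.rm = TRUE)
    }
    out
  })
  do.call(rbind, rows)
}

#' Height-SDS comparison of candidate carriers vs the rest
#'
#' Two-sided Wilcoxon rank-sum test; exact enumeration when the combined
#' sample is small (<= 20) and tie-free, normal approximation with tie
#' correction otherwise.
#'
#' @param carrier_sds,rest_sds numeric vectors of height SD scores.
#' @return two-sided p-value.
#' @export
carrier_vs_rest_sds_test <- function(carrier_sds, rest_sds) {
  if (!length(carrier_sds) || !length(rest_sds)) .stopf("both groups must be non-empty")
  exact <- (length(carrier_sds) + length(rest_sds)) <= 20 &&
    !anyDuplicated(c(carrier_sds, rest_sds))
  suppressWarnings(stats::wilcox.test(carrier_sds, rest_sds, exact = exact,
                                      correct = !exact)$p.value)
}

#' Fisher test of candidate-carrier status against a phenotype flag
#'
#' @param is_carrier,flag logical vectors over the same samples.
#' @return list with `odds_ratio`, `p_value` (delegates to
#'   [fisher_exact_2x2()]).
#' @export
subgroup_fisher <- function(is_carrier, flag) {
  stopifnot(length(is_carrier) == length(flag))
  fisher_exact_2x2(sum(is_carrier & flag), sum(is_carrier & !flag),
                   sum(!is_carrier & flag), sum(!is_carrier & !flag))
}

#' Render the evidence report
#'
#' Deterministic column order matching the lines-of-evidence table layout;
#' written as TSV when a path is given.
#'
#' @param profiles data.frame of evidence profiles ([evidence_profile()] rows).
#' @param path optional output TSV path.
#' @return the ordered report data.frame, invisibly when written.
#' @export
render_report <- function(profiles, path = NULL) {
  cols <- c("call_id", "sample_id", "inheritance", "cnv_type", "size_kb",
            "n_genes", "growth_genes", "n_growth_function", "n_gepis_tissue",
            "n_decipher", "n_diff_expressed", "n_expr_assayed", "n_mgi_growth",
            "gwas_min_p", "breakpoint_genes", "n_hi_genes", "candidate")
  keep <- intersect(cols, names(profiles))
  out <- profiles[, keep, drop = FALSE]
  if (!is.null(path)) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste0("#", paste(keep, collapse = "\t")), con)
    if (nrow(out))
      utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE,
                         col.names = FALSE)
    return(invisible(out))
  }
  out
}
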