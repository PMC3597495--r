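# Trio segregation: inheritance classification of candidate CNVs, MLPA
# probe-ratio confirmation, and enrichment of de novo events against the
# population mutation-rate expectation.

#' Classify the inheritance of a child CNV from parental calls
#'
#' A parental match is a same-type parental call whose overlap fraction of
#' the child CNV is at least `match_fraction`. No match in either parent
#' gives `de_novo`; a match in an affected parent gives `inherited_affected`;
#' a match only in unaffected parents gives `inherited_unaffected` (such
#' calls are excluded downstream). Missing parental data (`NULL`) gives
#' `unresolved` rather than an error.
#'
#' The default `match_fraction` of 0.5 is deliberately looser than the
#' polymorphism filter's 0.95: parental confirmation often rests on a single
#' MLPA probe and breakpoint estimates jitter between platforms.
#'
#' @param child_cnv 1-row call table.
#' @param mother_calls,father_calls call tables for the parents, or `NULL`
#'   when no data is available.
#' @param mother_affected,father_affected parental affection status.
#' @param match_fraction minimum overlap fraction of the child CNV.
#' @return list with `category` (`de_novo`, `inherited_affected`,
#'   `inherited_unaffected`, `unresolved`) and `transmitting_parent`
#'   (`"mother"`, `"father"` or `NA`).
#' @export
classify_inheritance <- function(child_cnv, mother_calls, father_calls,
                                 mother_affected = FALSE, father_affected = FALSE,
                                 match_fraction = 0.5) {
  if (is.null(mother_calls) || is.null(father_calls))
    return(list(category = "unresolved", transmitting_parent = NA_character_))
  matches <- function(calls) {
    sub <- calls[calls$chrom == child_cnv$chrom & calls$cnv_type == child_cnv$cnv_type, , drop = FALSE]
    if (nrow(sub) == 0L) return(FALSE)
    any(.overlap_len(child_cnv$start, child_cnv$end, sub$start, sub$end) /
          (child_cnv$end - child_cnv$start) >= match_fraction)
  }
  mo <- matches(mother_calls); fa <- matches(father_calls)
  if (!mo && !fa) return(list(category = "de_novo", transmitting_parent = NA_character_))
  if (mo && mother_affected)
    return(list(category = "inherited_affected", transmitting_parent = "mother"))
  if (fa && father_affected)
    return(list(category = "inherited_affected", transmitting_parent = "father"))
  list(category = "inherited_unaffected",
       transmitting_parent = if (mo) "mother" else "father")
}

#' Classify every candidate call of every trio child
#'
#' Convenience wrapper applying [classify_inheritance()] across a cohort.
#'
#' @param candidate_calls call table of children's candidate CNVs.
#' @param trios trio table (`child_id`, `mother_id`, `father_id`,
#'   `mother_affected`, `father_affected`).
#' @param parent_calls call table holding all parental calls.
#' @param match_fraction see [classify_inheritance()].
#' @return `candidate_calls` with added `inheritance` and
#'   `transmitting_parent` columns.
#' @export
classify_cohort_inheritance <- function(candidate_calls, trios, parent_calls,
                                        match_fraction = 0.5) {
  by_sample <- split(seq_len(nrow(parent_calls)), parent_calls$sample_id)
  get_calls <- function(id) {
    idx <- by_sample[[id]]
    if (is.null(idx)) parent_calls[0L, , drop = FALSE] else parent_calls[idx, , drop = FALSE]
  }
  cat <- character(nrow(candidate_calls))
  par <- character(nrow(candidate_calls))
  for (i in seq_len(nrow(candidate_calls))) {
    tr <- trios[trios$child_id == candidate_calls$sample_id[i], , drop = FALSE]
    if (nrow(tr) == 0L) {
      cat[i] <- "unresolved"; par[i] <- NA_character_
      next
    }
    res <- classify_inheritance(candidate_calls[i, ],
                                get_calls(tr$mother_id[1]), get_calls(tr$father_id[1]),
                                tr$mother_affected[1], tr$father_affected[1],
                                match_fraction)
    cat[i] <- res$category
    par[i] <- if (is.na(res$transmitting_parent)) NA_character_ else
      switch(res$transmitting_parent, mother = tr$mother_id[1], father = tr$father_id[1])
  }
  candidate_calls$inheritance <- cat
  candidate_calls$transmitting_parent <- par
  candidate_calls
}

#' Classify MLPA probe ratios
#'
#' Relative quantity below 0.75 confirms a deletion, above 1.25 a
#' duplication; both cut-offs are strict, so the boundary values themselves
#' classify as normal.
#'
#' @param ratio positive numeric vector of probe ratios.
#' @return character vector: `"deletion"`, `"normal"` or `"duplication"`.
#' @export
mlpa_classify <- function(ratio) {
  if (any(!is.finite(ratio) | ratio <= 0)) .stopf("MLPA ratios must be positive")
  ifelse(ratio < 0.75, "deletion", ifelse(ratio > 1.25, "duplication", "normal"))
}

#' De novo CNV rate model
#'
#' @param rate_per_haploid_genome de novo CNV rate per haploid genome per
#'   generation (default 6e-3).
#' @param n_patients number of patients screened; the expected count is
#'   `2 * n_patients * rate` (two haploid genomes each).
#' @return list with `rate`, `n_patients`, `expected`.
#' @export
de_novo_rate_model <- function(rate_per_haploid_genome = 6e-3, n_patients = 200L) {
  rate <- .check_fraction(rate_per_haploid_genome, "rate_per_haploid_genome", lo = 1e-12)
  n <- .check_count(n_patients, "n_patients", min = 1)
  list(rate = rate, n_patients = n, expected = 2 * n * rate)
}

#' Upper-tail enrichment of observed de novo CNVs
#'
#' Probability of observing at least `observed` de novo CNVs under the
#' population expectation. `"poisson"` uses the tail of
#' Poisson(2 * n * rate), `"binomial"` the tail of Binomial(2n, rate), and
#' `"fisher_vs_expected"` a one-sided Fisher test of observed vs (rounded)
#' expected counts against the 2n parental genomes.
#'
#' @param observed observed de novo count.
#' @param model a [de_novo_rate_model()].
#' @param method one of `"poisson"`, `"binomial"`, `"fisher_vs_expected"`.
#' @return upper-tail p-value.
#' @export
de_novo_enrichment <- function(observed, model = de_novo_rate_model(),
                               method = c("poisson", "binomial", "fisher_vs_expected")) {
  observed <- .check_count(observed, "observed")
  method <- match.arg(method)
  genomes <- 2L * model$n_patients
  if (observed == 0L) return(1)
  switch(method,
    poisson = stats::ppois(observed - 1L, model$expected, lower.tail = FALSE),
    binomial = stats::pbinom(observed - 1L, genomes, model$rate, lower.tail = FALSE),
    fisher_vs_expected = {
      expected <- round(model$expected)
      tab <- matrix(c(observed, genomes - observed, expected, genomes - expected), 2L,
                    byrow = TRUE)
      stats::fisher.test(tab, alternative = "greater")$p.value
    })
}
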