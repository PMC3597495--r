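#' @keywords internal
"_PACKAGE"

# interval helpers -- all coordinates in the package are 0-based half-open;
# conversion from 1-based inclusive dialects happens only in the readers.
.overlap_len <- function(s1, e1, s2, e2) pmax(0L, pmin(e1, e2) - pmax(s1, s2))

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.call_id <- function(sample_id, chrom, start, end, copy_state)
  sprintf("%s:%s:%.0f-%.0f:%d", sample_id, chrom, start, end, as.integer(copy_state))

.check_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) .stopf("'%s' must be TRUE or FALSE", name)
  x
}

.check_count <- function(x, name, min = 0) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x))
    .stopf("'%s' must be an integer >= %s", name, min)
  as.integer(x)
}

.check_fraction <- function(x, name, lo = 0, hi = 1) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi)
    .stopf("'%s' must be a number in [%s, %s]", name, lo, hi)
  as.numeric(x)
}

.check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0)
    .stopf("'%s' must be a positive number", name)
  as.numeric(x)
}

#' Construct and validate a table of CNV segment calls
#'
#' The canonical in-memory representation of copy-number calls: one row per
#' segment per sample, 0-based half-open coordinates, copy state 1 (one-copy
#' loss) or 3 (one-copy gain). `cnv_type` is derived from the copy state
#' (state > 2 is a gain, state < 2 a loss; state 2 is diploid and not a call).
#'
#' @param df data.frame with columns `sample_id`, `chrom`, `start`, `end`,
#'   `copy_state`, `n_markers` and optionally `call_id`.
#' @return A validated data.frame with derived columns `cnv_type`, `size_kb`
#'   and a `call_id` (generated from sample and coordinates when absent).
#' @export
cnv_calls <- function(df) {
  req <- c("sample_id", "chrom", "start", "end", "copy_state", "n_markers")
  miss <- setdiff(req, names(df))
  if (length(miss)) .stopf("missing segment columns: %s", paste(miss, collapse = ", "))
  df$start <- as.numeric(df$start)
  df$end <- as.numeric(df$end)
  df$copy_state <- as.integer(df$copy_state)
  df$n_markers <- as.integer(df$n_markers)
  bad <- which(!(df$end > df$start))
  if (length(bad)) .stopf("end must exceed start (0-based half-open); offending rows: %s",
                          paste(utils::head(bad, 10L), collapse = ", "))
  bad <- which(df$copy_state == 2L | df$copy_state < 0L)
  if (length(bad)) .stopf("copy_state must be a non-negative integer != 2; offending rows: %s",
                          paste(utils::head(bad, 10L), collapse = ", "))
  df$cnv_type <- ifelse(df$copy_state > 2L, "gain", "loss")
  df$size_kb <- (df$end - df$start) / 1000
  if (is.null(df$call_id))
    df$call_id <- .call_id(df$sample_id, df$chrom, df$start, df$end, df$copy_state)
  rownames(df) <- NULL
  df
}

#' Construct and validate a gene annotation table
#'
#' Genes carry exon structure (comma-joined 0-based half-open coordinates in
#' `exon_starts`/`exon_ends`) plus the boolean evidence flags consumed by the
#' candidate rule, and a haploinsufficiency percentile in [0, 100] (low
#' percentile = predicted dosage sensitive).
#'
#' @param df data.frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `exon_starts`, `exon_ends`, `growth_gene`, `mgi_growth`,
#'   `functional_candidate`, `growth_tissue_expressed`, `decipher_overlap`,
#'   `hi_percentile`.
#' @return Validated data.frame.
#' @export
gene_table <- function(df) {
  req <- c("gene_id", "chrom", "start", "end", "exon_starts", "exon_ends",
           "growth_gene", "mgi_growth", "functional_candidate",
           "growth_tissue_expressed", "decipher_overlap", "hi_percentile")
  miss <- setdiff(req, names(df))
  if (length(miss)) .stopf("missing gene columns: %s", paste(miss, collapse = ", "))
  if (nrow(df) == 0L) return(df)
  if (anyDuplicated(df$gene_id)) {
    dup <- unique(df$gene_id[duplicated(df$gene_id)])
    .stopf("duplicated gene_id: %s", paste(utils::head(dup, 5L), collapse = ", "))
  }
  ex <- gene_exons(df)
  if (nrow(ex)) {
    span <- df[match(ex$gene_id, df$gene_id), ]
    bad <- ex$start < span$start | ex$end > span$end | ex$end <= ex$start
    if (any(bad)) .stopf("exons outside gene span or empty for gene(s): %s",
                         paste(unique(ex$gene_id[bad]), collapse = ", "))
  }
  df
}

#' Expand comma-joined exon coordinates to one row per exon
#'
#' @param genes gene table from [gene_table()].
#' @return data.frame with columns `gene_id`, `start`, `end`.
#' @export
gene_exons <- function(genes) {
  if (nrow(genes) == 0L)
    return(data.frame(gene_id = character(), start = numeric(), end = numeric()))
  starts <- strsplit(as.character(genes$exon_starts), ",", fixed = TRUE)
  ends <- strsplit(as.character(genes$exon_ends), ",", fixed = TRUE)
  n <- lengths(starts)
  if (any(n != lengths(ends))) .stopf("exon_starts/exon_ends length mismatch")
  data.frame(gene_id = rep(genes$gene_id, n),
             start = as.numeric(unlist(starts, use.names = FALSE)),
             end = as.numeric(unlist(ends, use.names = FALSE)))
}
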