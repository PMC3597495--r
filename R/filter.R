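# Filtering cascade that reduces raw segment calls to rare, gene-affecting
# candidates: calling prefilter (size/markers/chromosome), 50 kb candidate
# floor, polymorphism exclusion against the control cohort (>95% size overlap
# in >15 distinct controls), gene-coverage exclusion (every overlapped gene
# fully contained in calls of >=15 controls), exonic filter.

#' Build and validate a filter configuration
#'
#' @param min_size_kb candidate-stage size floor (kept when size >= this;
#'   the 109 kb minimum among reported candidates motivates an inclusive
#'   boundary).
#' @param calling_min_size_kb calling floor applied in the prefilter.
#' @param min_markers minimum supporting markers.
#' @param overlap_fraction polymorphism match: overlap fraction of the query
#'   that a control call must exceed (strict >).
#' @param max_control_carriers a query is excluded when carriers exceed this
#'   (strict >).
#' @param min_coverage_carriers gene-coverage rule: each overlapped gene must
#'   be contained in calls of at least this many controls (>=).
#' @param require_exonic drop candidates touching no exon.
#' @param exclude_chrom chromosomes dropped in the prefilter.
#' @param reciprocal if `TRUE` the polymorphism match also requires the
#'   overlap fraction of the control call to exceed `overlap_fraction`.
#' @param match_same_type restrict matches to the same CNV type (gain vs
#'   gain, loss vs loss).
#' @return list of class `filter_config`.
#' @export
filter_config <- function(min_size_kb = 50, calling_min_size_kb = 10,
                          min_markers = 5, overlap_fraction = 0.95,
                          max_control_carriers = 15, min_coverage_carriers = 15,
                          require_exonic = TRUE, exclude_chrom = "chrY",
                          reciprocal = FALSE, match_same_type = TRUE) {
  cfg <- list(
    min_size_kb = .check_positive(min_size_kb, "min_size_kb"),
    calling_min_size_kb = .check_positive(calling_min_size_kb, "calling_min_size_kb"),
    min_markers = .check_count(min_markers, "min_markers"),
    overlap_fraction = .check_fraction(overlap_fraction, "overlap_fraction", lo = 1e-9),
    max_control_carriers = .check_count(max_control_carriers, "max_control_carriers"),
    min_coverage_carriers = .check_count(min_coverage_carriers, "min_coverage_carriers"),
    require_exonic = .check_flag(require_exonic, "require_exonic"),
    exclude_chrom = as.character(exclude_chrom),
    reciprocal = .check_flag(reciprocal, "reciprocal"),
    match_same_type = .check_flag(match_same_type, "match_same_type"))
  class(cfg) <- "filter_config"
  cfg
}

#' Fraction of a query call covered by another call
#'
#' Asymmetric: returns overlap length divided by the size of `a` (the query);
#' 0 when the calls sit on different chromosomes.
#'
#' @param a query call (1-row data.frame or list with `chrom`, `start`, `end`).
#' @param b subject call, same shape (vectorized over rows of `b`).
#' @return numeric vector of fractions in [0, 1].
#' @export
size_overlap_fraction <- function(a, b) {
  ov <- .overlap_len(a$start, a$end, b$start, b$end)
  ifelse(b$chrom == a$chrom, ov / (a$end - a$start), 0)
}

#' Count distinct control samples carrying a matching call
#'
#' A control call matches when it is on the same chromosome, of the same CNV
#' type (when `match_same_type`), and covers strictly more than
#' `overlap_fraction` of the query (and, in reciprocal mode, vice versa).
#'
#' @param cnv query call (1-row data.frame).
#' @param control_calls call table of the control cohort.
#' @param config a [filter_config()].
#' @return integer count of distinct carrier samples.
#' @export
control_carrier_count <- function(cnv, control_calls, config = filter_config()) {
  sub <- control_calls[control_calls$chrom == cnv$chrom, , drop = FALSE]
  if (config$match_same_type) sub <- sub[sub$cnv_type == cnv$cnv_type, , drop = FALSE]
  if (nrow(sub) == 0L) return(0L)
  ov <- .overlap_len(cnv$start, cnv$end, sub$start, sub$end)
  hit <- ov / (cnv$end - cnv$start) > config$overlap_fraction
  if (config$reciprocal) hit <- hit & ov / (sub$end - sub$start) > config$overlap_fraction
  length(unique(sub$sample_id[hit]))
}

#' Gene-coverage exclusion rule
#'
#' `TRUE` (remove) iff the query overlaps at least one gene and every
#' overlapped gene is fully contained within same-type control calls of at
#' least `min_coverage_carriers` distinct control samples. A CNV overlapping
#' no genes returns `FALSE`: gene-free calls are the exonic filter's job, and
#' letting the vacuous case trigger removal would double-count exclusions.
#'
#' @param cnv query call (1-row data.frame).
#' @param control_calls control call table.
#' @param genes gene table.
#' @param config a [filter_config()].
#' @return logical.
#' @export
gene_coverage_excluded <- function(cnv, control_calls, genes, config = filter_config()) {
  g <- genes[genes$chrom == cnv$chrom &
               .overlap_len(cnv$start, cnv$end, genes$start, genes$end) > 0, , drop = FALSE]
  if (nrow(g) == 0L) return(FALSE)
  sub <- control_calls[control_calls$chrom == cnv$chrom, , drop = FALSE]
  if (config$match_same_type) sub <- sub[sub$cnv_type == cnv$cnv_type, , drop = FALSE]
  for (j in seq_len(nrow(g))) {
    contain <- sub$start <= g$start[j] & sub$end >= g$end[j]
    if (length(unique(sub$sample_id[contain])) < config$min_coverage_carriers)
      return(FALSE)
  }
  TRUE
}

#' Exonic filter
#'
#' Keep iff the call intersects at least one exon; calls confined to intronic
#' or intergenic sequence are dropped.
#'
#' @param cnv query call (1-row data.frame).
#' @param genes gene table (exons taken via [gene_exons()]).
#' @param exons optional precomputed exon table with a `chrom` column.
#' @return logical: `TRUE` to keep.
#' @export
exonic_filter <- function(cnv, genes, exons = NULL) {
  if (is.null(exons)) {
    exons <- gene_exons(genes)
    exons$chrom <- genes$chrom[match(exons$gene_id, genes$gene_id)]
  }
  e <- exons[exons$chrom == cnv$chrom, , drop = FALSE]
  any(.overlap_len(cnv$start, cnv$end, e$start, e$end) > 0)
}

# vectorized carrier counting: controls pre-split by (chrom [, type]) so each
# query only scans its own stratum; equals control_carrier_count row by row
.carrier_counts <- function(queries, control_calls, config) {
  key_q <- if (config$match_same_type) paste(queries$chrom, queries$cnv_type) else queries$chrom
  key_c <- if (config$match_same_type) paste(control_calls$chrom, control_calls$cnv_type) else control_calls$chrom
  groups <- split(seq_len(nrow(control_calls)), key_c)
  out <- integer(nrow(queries))
  for (i in seq_len(nrow(queries))) {
    idx <- groups[[key_q[i]]]
    if (is.null(idx)) next
    s <- control_calls$start[idx]; e <- control_calls$end[idx]
    ov <- pmax(0, pmin(queries$end[i], e) - pmax(queries$start[i], s))
    hit <- ov / (queries$end[i] - queries$start[i]) > config$overlap_fraction
    if (config$reciprocal) hit <- hit & ov / (e - s) > config$overlap_fraction
    out[i] <- length(unique(control_calls$sample_id[idx][hit]))
  }
  out
}

# gene-coverage exclusion for many queries: per-(gene, type) containment
# carrier counts are computed once, then each query checks its genes
.coverage_excluded <- function(queries, control_calls, genes, config) {
  if (nrow(genes) == 0L) return(rep(FALSE, nrow(queries)))
  types <- if (config$match_same_type) c("gain", "loss") else "any"
  counts <- matrix(0L, nrow = nrow(genes), ncol = length(types),
                   dimnames = list(genes$gene_id, types))
  by_chrom <- split(seq_len(nrow(control_calls)), control_calls$chrom)
  for (j in seq_len(nrow(genes))) {
    idx <- by_chrom[[genes$chrom[j]]]
    if (is.null(idx)) next
    contain <- control_calls$start[idx] <= genes$start[j] &
      control_calls$end[idx] >= genes$end[j]
    for (tt in types) {
      sel <- contain & (tt == "any" | control_calls$cnv_type[idx] == tt)
      counts[j, tt] <- length(unique(control_calls$sample_id[idx][sel]))
    }
  }
  out <- logical(nrow(queries))
  for (i in seq_len(nrow(queries))) {
    g <- which(genes$chrom == queries$chrom[i] &
                 pmin(queries$end[i], genes$end) > pmax(queries$start[i], genes$start))
    if (!length(g)) next
    tt <- if (config$match_same_type) queries$cnv_type[i] else "any"
    out[i] <- all(counts[g, tt] >= config$min_coverage_carriers)
  }
  out
}

#' Run the full polymorphism-filter cascade
#'
#' Stages, in order: calling prefilter (size >= `calling_min_size_kb`,
#' markers >= `min_markers`, excluded chromosomes dropped), candidate size
#' floor (>= `min_size_kb`), polymorphism exclusion (control carrier count
#' > `max_control_carriers`), gene-coverage exclusion, exonic filter. The
#' report records input/output counts per stage, and each excluded call its
#' first failing stage.
#'
#' @param case_calls case call table.
#' @param control_calls control call table.
#' @param genes gene table.
#' @param config a [filter_config()].
#' @return list with `calls` (survivors), `report` (data.frame `stage`,
#'   `n_in`, `n_out`) and `exclusions` (data.frame `call_id`, `stage`).
#' @export
run_cascade <- function(case_calls, control_calls, genes, config = filter_config()) {
  stages <- c("calling_prefilter", "candidate_size", "polymorphism",
              "gene_coverage", "exonic")
  report <- data.frame(stage = stages, n_in = NA_integer_, n_out = NA_integer_)
  excl <- list()
  cur <- case_calls

  keep_stage <- function(keep, stage) {
    report[report$stage == stage, c("n_in", "n_out")] <<- c(nrow(cur), sum(keep))
    if (any(!keep))
      excl[[stage]] <<- data.frame(call_id = cur$call_id[!keep], stage = stage,
                                   stringsAsFactors = FALSE)
    cur <<- cur[keep, , drop = FALSE]
  }

  keep_stage(cur$size_kb >= config$calling_min_size_kb &
               cur$n_markers >= config$min_markers &
               !(cur$chrom %in% config$exclude_chrom), "calling_prefilter")
  keep_stage(cur$size_kb >= config$min_size_kb, "candidate_size")

  if (nrow(cur)) {
    carriers <- .carrier_counts(cur, control_calls, config)
    keep_stage(carriers <= config$max_control_carriers, "polymorphism")
  } else keep_stage(logical(0), "polymorphism")

  if (nrow(cur)) {
    keep_stage(!.coverage_excluded(cur, control_calls, genes, config), "gene_coverage")
  } else keep_stage(logical(0), "gene_coverage")

  if (config$require_exonic) {
    if (nrow(cur)) {
      exons <- gene_exons(genes)
      exons$chrom <- genes$chrom[match(exons$gene_id, genes$gene_id)]
      keep <- vapply(seq_len(nrow(cur)), function(i)
        exonic_filter(cur[i, ], genes, exons), logical(1))
      keep_stage(keep, "exonic")
    } else keep_stage(logical(0), "exonic")
  } else keep_stage(rep(TRUE, nrow(cur)), "exonic")

  exclusions <- if (length(excl)) do.call(rbind, unname(excl)) else
    data.frame(call_id = character(), stage = character(), stringsAsFactors = FALSE)
  list(calls = cur, report = report, exclusions = exclusions)
}
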