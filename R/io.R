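# File dialects. The canonical segment file is a 6-column TSV with a
# '#'-prefixed header and 0-based half-open coordinates; the "array" dialect
# carries 1-based inclusive coordinates as emitted by array CNV-calling
# software and is converted on read.

.read_tsv_hash_header <- function(path) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  first <- readLines(path, n = 1L)
  if (!startsWith(first, "#")) .stopf("%s: expected a '#'-prefixed header line", path)
  header <- strsplit(sub("^#\\s*", "", first), "\t", fixed = TRUE)[[1]]
  df <- utils::read.delim(path, header = FALSE, skip = 1L, col.names = header,
                          stringsAsFactors = FALSE)
  df
}

#' Read a CNV segment file
#'
#' @param path path to a tab-separated segment file with a `#`-prefixed header
#'   and columns `sample_id`, `chrom`, `start`, `end`, `copy_state`,
#'   `n_markers`.
#' @param dialect `"canonical"` for 0-based half-open coordinates (the
#'   package-internal convention) or `"array"` for 1-based inclusive
#'   coordinates, which are converted on read (`start - 1`, `end` kept).
#' @return A validated call table (see [cnv_calls()]).
#' @export
read_segments <- function(path, dialect = c("canonical", "array")) {
  dialect <- match.arg(dialect)
  df <- .read_tsv_hash_header(path)
  req <- c("sample_id", "chrom", "start", "end", "copy_state", "n_markers")
  miss <- setdiff(req, names(df))
  if (length(miss)) .stopf("%s: missing columns: %s", path, paste(miss, collapse = ", "))
  num_bad <- which(is.na(suppressWarnings(as.numeric(df$start))) |
                   is.na(suppressWarnings(as.numeric(df$end))))
  if (length(num_bad))
    .stopf("%s: non-numeric coordinates on data line(s): %s", path,
           paste(utils::head(num_bad, 10L), collapse = ", "))
  df$start <- as.numeric(df$start)
  df$end <- as.numeric(df$end)
  if (dialect == "array") df$start <- df$start - 1
  ord_bad <- which(df$end <= df$start)
  if (length(ord_bad))
    .stopf("%s: end <= start on data line(s): %s", path,
           paste(utils::head(ord_bad, 10L), collapse = ", "))
  cnv_calls(df)
}

#' Write a CNV segment file in the canonical dialect
#'
#' @param calls a call table from [cnv_calls()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_segments <- function(calls, path) {
  cols <- c("sample_id", "chrom", "start", "end", "copy_state", "n_markers")
  out <- calls[, cols]
  out$start <- format(out$start, scientific = FALSE, trim = TRUE)
  out$end <- format(out$end, scientific = FALSE, trim = TRUE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", paste(cols, collapse = "\t")), con)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a pedigree/sample file and derive trios
#'
#' One row per individual; columns `sample_id`, `group` (case/control/parent),
#' `sex`, `height_sds`, `affected`, `mother_id`, `father_id` (0 = unknown) and
#' optional phenotype flags (`proportionate`, `syndromic`, `prenatal_onset`,
#' `learning_disability`). A trio is emitted for every individual with both
#' parents present; dangling parent references raise a linkage error.
#'
#' @param path path to the tab-separated pedigree file (`#`-prefixed header).
#' @return list with elements `samples` (data.frame) and `trios` (data.frame
#'   with `child_id`, `mother_id`, `father_id`, `mother_affected`,
#'   `father_affected`).
#' @export
read_ped <- function(path) {
  df <- .read_tsv_hash_header(path)
  req <- c("sample_id", "group", "sex", "height_sds", "affected", "mother_id", "father_id")
  miss <- setdiff(req, names(df))
  if (length(miss)) .stopf("%s: missing columns: %s", path, paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    .stopf("%s: duplicated sample_id: %s", path,
           paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  df$affected <- as.logical(df$affected)
  has_par <- df$mother_id != "0" & df$father_id != "0"
  ref <- unique(c(df$mother_id[has_par], df$father_id[has_par]))
  dangling <- setdiff(ref, df$sample_id)
  if (length(dangling))
    .stopf("%s: linkage error, parent id(s) not present as samples: %s", path,
           paste(dangling, collapse = ", "))
  kids <- df[has_par, , drop = FALSE]
  trios <- data.frame(
    child_id = kids$sample_id,
    mother_id = kids$mother_id,
    father_id = kids$father_id,
    mother_affected = df$affected[match(kids$mother_id, df$sample_id)],
    father_affected = df$affected[match(kids$father_id, df$sample_id)],
    stringsAsFactors = FALSE)
  bad <- trios$child_id == trios$mother_id | trios$child_id == trios$father_id |
    trios$mother_id == trios$father_id
  if (any(bad)) .stopf("%s: trio members must be distinct for child %s", path,
                       paste(trios$child_id[bad], collapse = ", "))
  list(samples = df, trios = trios)
}

#' Write a pedigree/sample file
#' @param samples sample data.frame as returned in [read_ped()]'s `samples`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ped <- function(samples, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", paste(names(samples), collapse = "\t")), con)
  utils::write.table(samples, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a gene annotation file
#'
#' BED-like TSV (`#`-prefixed header) with gene span, comma-joined exon
#' coordinates and the evidence attribute columns described in [gene_table()].
#'
#' @param path path to the gene file.
#' @return Validated gene table.
#' @export
read_genes <- function(path) {
  df <- .read_tsv_hash_header(path)
  for (fl in c("growth_gene", "mgi_growth", "functional_candidate",
               "growth_tissue_expressed", "decipher_overlap"))
    if (fl %in% names(df)) df[[fl]] <- as.logical(df[[fl]])
  gene_table(df)
}

#' Write a gene annotation file
#' @param genes gene table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genes <- function(genes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", paste(names(genes), collapse = "\t")), con)
  utils::write.table(genes, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a log2 expression matrix (genes x samples)
#'
#' @param path TSV whose first column is `gene_id` and remaining columns are
#'   sample ids; values are normalized log2 expression.
#' @return numeric matrix with gene rownames and sample colnames.
#' @export
read_expression <- function(path) {
  df <- .read_tsv_hash_header(path)
  if (names(df)[1] != "gene_id") .stopf("%s: first column must be gene_id", path)
  if (anyDuplicated(df$gene_id))
    .stopf("%s: duplicated gene_id: %s", path,
           paste(unique(df$gene_id[duplicated(df$gene_id)]), collapse = ", "))
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene_id
  storage.mode(m) <- "double"
  m
}

#' Write a log2 expression matrix
#' @param mat numeric matrix, genes in rows, samples in columns.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(mat, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#gene_id\t", paste(colnames(mat), collapse = "\t")), con)
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a per-SNP association p-value track
#'
#' @param path TSV with columns `chrom`, `pos`, `p`; p-values must lie in
#'   (0, 1]. Rows are returned sorted by chromosome and position.
#' @return data.frame sorted by (`chrom`, `pos`).
#' @export
read_snp_track <- function(path) {
  df <- .read_tsv_hash_header(path)
  miss <- setdiff(c("chrom", "pos", "p"), names(df))
  if (length(miss)) .stopf("%s: missing columns: %s", path, paste(miss, collapse = ", "))
  df$pos <- as.numeric(df$pos)
  df$p <- as.numeric(df$p)
  bad <- which(is.na(df$p) | df$p <= 0 | df$p > 1)
  if (length(bad)) .stopf("%s: p-values outside (0,1] on line(s): %s", path,
                          paste(utils::head(bad, 10L), collapse = ", "))
  df[order(df$chrom, df$pos), , drop = FALSE]
}

#' Write a per-SNP p-value track
#' @param snps data.frame with `chrom`, `pos`, `p`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_snp_track <- function(snps, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#chrom\tpos\tp", con)
  utils::write.table(snps[, c("chrom", "pos", "p")], con, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an MLPA probe-ratio table
#'
#' @param path TSV with columns `probe_id`, `locus`, `sample_id`, `ratio`
#'   (relative quantity vs the control-mean peak area; 1.0 = diploid).
#' @return data.frame.
#' @export
read_mlpa <- function(path) {
  df <- .read_tsv_hash_header(path)
  miss <- setdiff(c("probe_id", "locus", "sample_id", "ratio"), names(df))
  if (length(miss)) .stopf("%s: missing columns: %s", path, paste(miss, collapse = ", "))
  df$ratio <- as.numeric(df$ratio)
  if (any(is.na(df$ratio) | df$ratio <= 0)) .stopf("%s: ratios must be positive", path)
  df
}

#' Load the packaged 20-CNV lines-of-evidence fixture
#'
#' The packaged table of the 20 prioritized short-stature CNVs: inheritance,
#' gain/loss, cytogenetic locus, hg19 position (Mb, printed precision),
#' size (kb, as printed, not recomputed from the rounded positions), affected
#' gene count, and the per-CNV evidence columns (known short-stature genes,
#' microdeletion/duplication-syndrome overlap, growth-function and
#' growth-tissue gene counts, Decipher matches, differential-expression
#' counts, mouse-model growth genes, minimum GWAS p-value, breakpoint-
#' disrupted genes, haploinsufficiency-score count).
#'
#' @return data.frame with 20 rows, one per prioritized CNV.
#' @export
load_table2_fixture <- function() {
  path <- system.file("extdata", "table2_lines_of_evidence.tsv", package = "rarecnv")
  if (path == "") .stopf("packaged evidence fixture not found")
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (nrow(df) != 20L) .stopf("evidence fixture corrupted: expected 20 records, got %d", nrow(df))
  if (sum(df$cnv_type == "gain") != 10L || sum(df$cnv_type == "loss") != 10L)
    .stopf("evidence fixture corrupted: expected 10 gains and 10 losses")
  if (sum(df$inheritance == "de novo") != 7L)
    .stopf("evidence fixture corrupted: expected 7 de novo records")
  if (min(df$size_kb) != 109 || max(df$size_kb) != 14229)
    .stopf("evidence fixture corrupted: size range must span 109-14229 kb")
  df
}
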