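# Genome-wide copy-number association via pseudomarkers: carrier status is
# evaluated at every distinct segment endpoint and tested with a permutation
# chi-square, gains and losses as separate test families.

#' Build pseudomarkers at the endpoints of pooled segments
#'
#' One marker per distinct endpoint position per chromosome; positions are
#' deduplicated (a start takes precedence over a coincident end for the
#' `source` label) and sorted.
#'
#' @param calls pooled case + control call table.
#' @return data.frame with `chrom`, `position`, `source` (`start`/`end`).
#' @export
build_pseudomarkers <- function(calls) {
  if (nrow(calls) == 0L)
    return(data.frame(chrom = character(), position = numeric(), source = character()))
  df <- rbind(data.frame(chrom = calls$chrom, position = calls$start, source = "start",
                         stringsAsFactors = FALSE),
              data.frame(chrom = calls$chrom, position = calls$end, source = "end",
                         stringsAsFactors = FALSE))
  df <- df[order(df$chrom, df$position, df$source, method = "radix", decreasing = c(FALSE, FALSE, TRUE)), ]
  df <- df[!duplicated(df[c("chrom", "position")]), ]
  rownames(df) <- NULL
  df
}

#' Carrier-status matrix at pseudomarkers
#'
#' Sample s has status 1 at marker m iff it carries a call of the requested
#' type whose half-open interval contains m's position (so a marker at a
#' segment start is carried, one at its end is not).
#'
#' @param calls call table.
#' @param markers pseudomarker table from [build_pseudomarkers()].
#' @param sample_ids sample universe (matrix rows); defaults to the samples
#'   present in `calls`.
#' @param cnv_type `"gain"` or `"loss"`.
#' @return integer 0/1 matrix, samples x markers.
#' @export
status_matrix <- function(calls, markers, sample_ids = unique(calls$sample_id),
                          cnv_type = c("gain", "loss")) {
  cnv_type <- match.arg(cnv_type)
  m <- matrix(0L, nrow = length(sample_ids), ncol = nrow(markers),
              dimnames = list(sample_ids, NULL))
  sub <- calls[calls$cnv_type == cnv_type & calls$sample_id %in% sample_ids, , drop = FALSE]
  if (nrow(sub) == 0L || nrow(markers) == 0L) return(m)
  by_chrom <- split(seq_len(nrow(sub)), sub$chrom)
  for (j in seq_len(nrow(markers))) {
    idx <- by_chrom[[markers$chrom[j]]]
    if (is.null(idx)) next
    hit <- sub$start[idx] <= markers$position[j] & markers$position[j] < sub$end[idx]
    if (any(hit)) m[unique(sub$sample_id[idx][hit]), j] <- 1L
  }
  m
}

# Pearson chi-square on the 2x2 carrier-by-group table, no continuity
# correction; returns 0 for degenerate margins.
.chi2_stat <- function(a, m, n1, n) {
  # a carriers among cases, m carriers total, n1 cases, n samples
  b <- n1 - a; cc <- m - a; d <- n - n1 - m + a
  num <- n * (a * d - b * cc)^2
  den <- as.numeric(n1) * (n - n1) * m * (n - m)
  res <- num / den
  res[den == 0] <- 0
  res
}

#' Permutation chi-square association test at one marker
#'
#' Pearson chi-square (no continuity correction) on the carrier-by-group 2x2
#' table, with significance assessed by case/control label permutation:
#' `p = (1 + #\{chi2_perm >= chi2_obs\}) / (1 + n_perm)`. With
#' `mode = "exhaustive"` all label assignments are enumerated and the p-value
#' is the exact proportion of assignments at least as extreme. Degenerate
#' markers (all or no samples carriers) return p = 1 and are flagged.
#'
#' @param status 0/1 carrier vector over samples.
#' @param is_case logical vector, same length.
#' @param n_perm number of random permutations.
#' @param seed integer seed.
#' @param mode `"random"` or `"exhaustive"` (combined n small enough that
#'   `choose(n, n_cases)` <= 5e5).
#' @return list with `chi2`, `p_value`, `degenerate`.
#' @export
permutation_chi2 <- function(status, is_case, n_perm = 10000L, seed = 1L,
                             mode = c("random", "exhaustive")) {
  mode <- match.arg(mode)
  stopifnot(length(status) == length(is_case))
  n <- length(status); n1 <- sum(is_case); m <- sum(status)
  if (n1 < 2L || n - n1 < 2L) .stopf("need at least 2 samples per group")
  if (m == 0L || m == n)
    return(list(chi2 = 0, p_value = 1, degenerate = TRUE))
  obs <- .chi2_stat(sum(status[is_case]), m, n1, n)
  tol <- 1e-12
  if (mode == "exhaustive") {
    if (choose(n, n1) > 5e5) .stopf("exhaustive mode infeasible for choose(%d, %d) assignments", n, n1)
    sets <- utils::combn(n, n1)
    a_perm <- colSums(matrix(status[sets], nrow = n1))
    stats <- .chi2_stat(a_perm, m, n1, n)
    return(list(chi2 = obs, p_value = mean(stats >= obs - tol), degenerate = FALSE))
  }
  withr::local_seed(seed)
  a_perm <- vapply(seq_len(n_perm), function(i) sum(status[sample.int(n, n1)]), numeric(1))
  stats <- .chi2_stat(a_perm, m, n1, n)
  list(chi2 = obs,
       p_value = (1 + sum(stats >= obs - tol)) / (1 + n_perm),
       degenerate = FALSE)
}

#' Permutation association across all pseudomarkers
#'
#' Builds pseudomarkers from the pooled calls, evaluates carrier status for
#' the requested CNV type(s), and tests each marker with the permutation
#' chi-square. By default one set of label permutations is shared across
#' markers within a run (`share_permutations = FALSE` redraws per marker).
#' Bonferroni correction is applied over the union of markers tested across
#' the requested types.
#'
#' @param case_calls,control_calls call tables.
#' @param cnv_type `"gain"`, `"loss"` or `"both"`.
#' @param n_perm permutations per marker.
#' @param seed integer seed.
#' @param share_permutations reuse one permutation set across markers.
#' @return data.frame with `chrom`, `position`, `cnv_type`, `chi2`,
#'   `p_value`, `bonferroni_p`, `degenerate`.
#' @export
associate_markers <- function(case_calls, control_calls, cnv_type = c("both", "gain", "loss"),
                              n_perm = 10000L, seed = 1L, share_permutations = TRUE) {
  cnv_type <- match.arg(cnv_type)
  types <- if (cnv_type == "both") c("gain", "loss") else cnv_type
  pooled <- rbind(case_calls, control_calls)
  markers <- build_pseudomarkers(pooled)
  sample_ids <- unique(c(case_calls$sample_id, control_calls$sample_id))
  is_case <- sample_ids %in% case_calls$sample_id
  n <- length(sample_ids); n1 <- sum(is_case)
  withr::local_seed(seed)
  perms <- if (share_permutations)
    replicate(n_perm, sample.int(n, n1), simplify = FALSE) else NULL
  out <- list()
  for (tt in types) {
    sm <- status_matrix(pooled, markers, sample_ids, tt)
    res <- lapply(seq_len(ncol(sm)), function(j) {
      status <- sm[, j]
      m <- sum(status)
      if (m == 0L || m == n) return(c(0, 1, 1))
      obs <- .chi2_stat(sum(status[is_case]), m, n1, n)
      idxs <- if (share_permutations) perms else replicate(n_perm, sample.int(n, n1), simplify = FALSE)
      a_perm <- vapply(idxs, function(ix) sum(status[ix]), numeric(1))
      stats <- .chi2_stat(a_perm, m, n1, n)
      c(obs, (1 + sum(stats >= obs - 1e-12)) / (1 + n_perm), 0)
    })
    res <- do.call(rbind, res)
    out[[tt]] <- data.frame(chrom = markers$chrom, position = markers$position,
                            cnv_type = tt, chi2 = res[, 1], p_value = res[, 2],
                            degenerate = res[, 3] == 1, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out)
  n_tests <- sum(!out$degenerate)
  out$bonferroni_p <- pmin(1, out$p_value * n_tests)
  rownames(out) <- NULL
  out
}
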