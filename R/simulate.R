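# Synthetic cohorts with ground truth. The generator emulates the study
# conditions of the short-stature screen: ~32 array calls per individual with
# a heavy-tailed (log-normal) size distribution truncated at the 10 kb calling
# floor, a pool of polymorphic CNVs shared between cases and controls, and
# pathogenic CNVs spiked into ~10% of cases (de novo, or transmitted from an
# affected parent), plus matched expression, SNP and MLPA tracks.

#' Build and validate a simulation configuration
#'
#' Defaults reflect the emulated study: 200 cases vs 820 controls, a mean of
#' 32 calls per sample, 10% of cases carrying a pathogenic CNV of which 35%
#' are de novo, log2 dosage effects of +log2(1.5) for gains and -1 for losses.
#' Sizes are log-normal in kb (meanlog `size_log_mean`, sdlog `size_log_sd`)
#' truncated below at `min_size_kb`.
#'
#' @param seed integer seed; every generator draws only from this.
#' @param n_cases,n_controls cohort sizes.
#' @param n_chromosomes,chromosome_length_bp genome layout (equal-length
#'   autosomes).
#' @param mean_calls_per_sample Poisson mean of background calls per sample.
#' @param size_log_mean,size_log_sd log-normal size parameters (log kb).
#' @param min_size_kb calling floor below which no call is emitted.
#' @param polymorphic_pool_size number of distinct polymorphic CNV loci.
#' @param polymorphic_carrier_rate per-sample carrier probability for each
#'   pool locus.
#' @param case_size_shift multiplicative size inflation applied to case
#'   background calls larger than `case_size_shift_above_kb` (1 = null).
#' @param case_size_shift_above_kb size above which the shift applies.
#' @param case_excess_rate expected number of extra large calls injected per
#'   case (Poisson; 0 = null), emulating a case-specific excess of CNVs
#'   above `case_excess_min_kb`.
#' @param case_excess_min_kb size floor of the injected excess calls.
#' @param background_transmission_rate probability that a case background
#'   call is also present in one (unaffected) parent. The default leaves
#'   about `mean_calls_per_sample * (1 - rate)` truly de novo background
#'   calls per child, consistent with a de novo rate of a few per thousand
#'   per haploid genome per generation.
#' @param pathogenic_fraction fraction of cases receiving one spiked CNV.
#' @param de_novo_fraction fraction of spiked CNVs labelled de novo.
#' @param spike_size_log_mean,spike_size_log_sd log-normal size parameters of
#'   spiked CNVs (log kb); truncated below at `spike_min_size_kb`.
#' @param spike_min_size_kb minimum spiked-CNV size.
#' @param spike_evidence_fraction fraction of spikes centred on a gene
#'   carrying at least one evidence flag (growth gene, mouse growth
#'   knock-out, functional candidate, Decipher overlap) — pathogenic
#'   short-stature CNVs are expected to contain growth-relevant genes.
#' @param carrier_sds_shift additive height-SDS shift in spike carriers
#'   (carriers of pathogenic CNVs are shorter than the remaining cases).
#' @param dosage_log2_effect_gain,dosage_log2_effect_loss expression shift
#'   (log2) in carriers of a gain/loss over a dosage-sensitive gene.
#' @param expression_noise_sd per-measurement Gaussian noise SD (log2 units).
#' @param n_snps,n_genes track sizes.
#' @param flag_rates named numeric vector of per-gene annotation flag rates.
#' @return validated list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_cases = 200L,
                              n_controls = 820L,
                              n_chromosomes = 22L,
                              chromosome_length_bp = 1e8,
                              mean_calls_per_sample = 32,
                              size_log_mean = log(120),
                              size_log_sd = 0.8,
                              min_size_kb = 10,
                              polymorphic_pool_size = 30L,
                              polymorphic_carrier_rate = 0.05,
                              case_size_shift = 1.0,
                              case_size_shift_above_kb = 100,
                              case_excess_rate = 0,
                              case_excess_min_kb = 100,
                              background_transmission_rate = 0.9995,
                              pathogenic_fraction = 0.10,
                              de_novo_fraction = 0.35,
                              spike_size_log_mean = log(800),
                              spike_size_log_sd = 1.0,
                              spike_min_size_kb = 109,
                              spike_evidence_fraction = 0.8,
                              carrier_sds_shift = -0.6,
                              dosage_log2_effect_gain = log2(1.5),
                              dosage_log2_effect_loss = -1,
                              expression_noise_sd = 0.3,
                              n_snps = 10000L,
                              n_genes = 500L,
                              flag_rates = c(growth_gene = 0.02, mgi_growth = 0.05,
                                             functional_candidate = 0.05,
                                             growth_tissue_expressed = 0.30,
                                             decipher_overlap = 0.02)) {
  cfg <- list(
    seed = .check_count(seed, "seed"),
    n_cases = .check_count(n_cases, "n_cases"),
    n_controls = .check_count(n_controls, "n_controls"),
    n_chromosomes = .check_count(n_chromosomes, "n_chromosomes", min = 1),
    chromosome_length_bp = .check_positive(chromosome_length_bp, "chromosome_length_bp"),
    mean_calls_per_sample = .check_positive(mean_calls_per_sample, "mean_calls_per_sample"),
    size_log_mean = as.numeric(size_log_mean),
    size_log_sd = .check_positive(size_log_sd, "size_log_sd"),
    min_size_kb = .check_positive(min_size_kb, "min_size_kb"),
    polymorphic_pool_size = .check_count(polymorphic_pool_size, "polymorphic_pool_size"),
    polymorphic_carrier_rate = .check_fraction(polymorphic_carrier_rate, "polymorphic_carrier_rate"),
    case_size_shift = .check_positive(case_size_shift, "case_size_shift"),
    case_size_shift_above_kb = .check_positive(case_size_shift_above_kb, "case_size_shift_above_kb"),
    case_excess_rate = .check_fraction(case_excess_rate, "case_excess_rate", hi = Inf),
    case_excess_min_kb = .check_positive(case_excess_min_kb, "case_excess_min_kb"),
    background_transmission_rate = .check_fraction(background_transmission_rate,
                                                   "background_transmission_rate"),
    pathogenic_fraction = .check_fraction(pathogenic_fraction, "pathogenic_fraction"),
    de_novo_fraction = .check_fraction(de_novo_fraction, "de_novo_fraction"),
    spike_size_log_mean = as.numeric(spike_size_log_mean),
    spike_size_log_sd = .check_positive(spike_size_log_sd, "spike_size_log_sd"),
    spike_min_size_kb = .check_positive(spike_min_size_kb, "spike_min_size_kb"),
    spike_evidence_fraction = .check_fraction(spike_evidence_fraction, "spike_evidence_fraction"),
    carrier_sds_shift = as.numeric(carrier_sds_shift),
    dosage_log2_effect_gain = as.numeric(dosage_log2_effect_gain),
    dosage_log2_effect_loss = as.numeric(dosage_log2_effect_loss),
    expression_noise_sd = .check_positive(expression_noise_sd, "expression_noise_sd"),
    n_snps = .check_count(n_snps, "n_snps"),
    n_genes = .check_count(n_genes, "n_genes"),
    flag_rates = flag_rates)
  if (!is.numeric(flag_rates) || any(flag_rates < 0 | flag_rates > 1))
    .stopf("'flag_rates' must be probabilities in [0, 1]")
  class(cfg) <- "simulation_config"
  cfg
}

# truncated log-normal sizes in kb via inverse-CDF so no rejection loop
.rlnorm_trunc <- function(n, meanlog, sdlog, min_kb) {
  if (n == 0L) return(numeric())
  p0 <- stats::plnorm(min_kb, meanlog, sdlog)
  u <- p0 + stats::runif(n) * (1 - p0)
  stats::qlnorm(u, meanlog, sdlog)
}

.background_calls <- function(sample_ids, cfg) {
  n_calls <- stats::rpois(length(sample_ids), cfg$mean_calls_per_sample)
  tot <- sum(n_calls)
  if (tot == 0L)
    return(data.frame(sample_id = character(), chrom = character(),
                      start = numeric(), end = numeric(),
                      copy_state = integer(), n_markers = integer()))
  size_bp <- round(.rlnorm_trunc(tot, cfg$size_log_mean, cfg$size_log_sd,
                                 cfg$min_size_kb) * 1000)
  size_bp <- pmin(size_bp, cfg$chromosome_length_bp - 1)
  chrom <- sprintf("chr%d", sample.int(cfg$n_chromosomes, tot, replace = TRUE))
  start <- floor(stats::runif(tot) * (cfg$chromosome_length_bp - size_bp))
  state <- ifelse(stats::runif(tot) < 0.5, 1L, 3L)
  data.frame(sample_id = rep(sample_ids, n_calls), chrom = chrom,
             start = start, end = start + size_bp, copy_state = state,
             n_markers = 5L + stats::rpois(tot, size_bp / 20000),
             stringsAsFactors = FALSE)
}

#' Generate a synthetic case/control/trio cohort with ground truth
#'
#' Produces background calls for every case, control and parent (per-sample
#' counts Poisson with the configured mean), a shared polymorphic pool carried
#' by cases, controls and parents alike, and pathogenic spikes in a configured
#' fraction of cases. Spikes are placed over a randomly chosen annotated gene
#' (so they survive an exonic filter) and never appear in controls; de novo
#' spikes appear in neither parent, inherited spikes are copied into exactly
#' one parent who is then flagged affected.
#'
#' @param config a [simulation_config()].
#' @param genes optional gene table; generated from `config` when `NULL`.
#' @return list with elements `case_calls`, `control_calls`, `parent_calls`
#'   (validated call tables), `samples`, `trios`, `genes`, and `truth` (list
#'   with `spikes` data.frame — `call_id`, `sample_id`, `inheritance`,
#'   `gene_id` —, `polymorphic_call_ids`, `pool`, `dosage_sensitive_genes`).
#' @export
generate_cohort <- function(config, genes = NULL) {
  cfg <- config
  if (!inherits(cfg, "simulation_config")) .stopf("config must come from simulation_config()")
  if (is.null(genes)) genes <- generate_gene_annotation(cfg)
  withr::local_seed(cfg$seed)

  case_ids <- sprintf("case_%03d", seq_len(cfg$n_cases))
  ctrl_ids <- sprintf("ctrl_%03d", seq_len(cfg$n_controls))
  mo_ids <- sprintf("mother_%03d", seq_len(cfg$n_cases))
  fa_ids <- sprintf("father_%03d", seq_len(cfg$n_cases))

  case_bg <- .background_calls(case_ids, cfg)
  if (cfg$case_size_shift != 1 && nrow(case_bg)) {
    big <- (case_bg$end - case_bg$start) / 1000 > cfg$case_size_shift_above_kb
    grow <- round((case_bg$end[big] - case_bg$start[big]) * (cfg$case_size_shift - 1))
    case_bg$end[big] <- pmin(case_bg$end[big] + grow, cfg$chromosome_length_bp)
  }
  if (cfg$case_excess_rate > 0) {
    n_extra <- stats::rpois(cfg$n_cases, cfg$case_excess_rate)
    tot <- sum(n_extra)
    if (tot > 0L) {
      xsize <- round(.rlnorm_trunc(tot, cfg$size_log_mean, cfg$size_log_sd,
                                   cfg$case_excess_min_kb) * 1000)
      xsize <- pmin(xsize, cfg$chromosome_length_bp - 1)
      xstart <- floor(stats::runif(tot) * (cfg$chromosome_length_bp - xsize))
      case_bg <- rbind(case_bg, data.frame(
        sample_id = rep(case_ids, n_extra),
        chrom = sprintf("chr%d", sample.int(cfg$n_chromosomes, tot, TRUE)),
        start = xstart, end = xstart + xsize,
        copy_state = ifelse(stats::runif(tot) < 0.5, 1L, 3L),
        n_markers = 5L + stats::rpois(tot, xsize / 20000),
        stringsAsFactors = FALSE))
    }
  }
  ctrl_bg <- .background_calls(ctrl_ids, cfg)
  par_bg <- .background_calls(c(mo_ids, fa_ids), cfg)
  # nearly all background calls in a child are transmitted: mirror each into
  # one (unaffected) parent so trio classification sees them as inherited
  if (cfg$background_transmission_rate > 0 && nrow(case_bg)) {
    tr <- stats::runif(nrow(case_bg)) < cfg$background_transmission_rate
    if (any(tr)) {
      mirrored <- case_bg[tr, ]
      from_mother <- stats::runif(nrow(mirrored)) < 0.5
      ci <- match(mirrored$sample_id, case_ids)
      mirrored$sample_id <- ifelse(from_mother, mo_ids[ci], fa_ids[ci])
      par_bg <- rbind(par_bg, mirrored)
    }
  }

  # polymorphic pool: fixed loci, identical coordinates in every carrier
  pool <- data.frame(pool_id = character(), chrom = character(), start = numeric(),
                     end = numeric(), copy_state = integer(), stringsAsFactors = FALSE)
  if (cfg$polymorphic_pool_size > 0L) {
    np <- cfg$polymorphic_pool_size
    psize <- round(.rlnorm_trunc(np, cfg$size_log_mean, cfg$size_log_sd, 50) * 1000)
    psize <- pmin(psize, cfg$chromosome_length_bp - 1)
    # pool loci sit over genes (common CNVs are mostly gene-affecting), so
    # removing them is the polymorphism stage's job, not the exonic filter's
    if (nrow(genes)) {
      pg <- genes[sample.int(nrow(genes), np, replace = TRUE), ]
      pchrom <- pg$chrom
      pstart <- pmax(0, pmin((pg$start + pg$end) %/% 2 - psize %/% 2,
                             cfg$chromosome_length_bp - psize))
    } else {
      pchrom <- sprintf("chr%d", sample.int(cfg$n_chromosomes, np, TRUE))
      pstart <- floor(stats::runif(np) * (cfg$chromosome_length_bp - psize))
    }
    pool <- data.frame(
      pool_id = sprintf("pool_%03d", seq_len(np)),
      chrom = pchrom, start = pstart,
      copy_state = ifelse(stats::runif(np) < 0.5, 1L, 3L),
      stringsAsFactors = FALSE)
    pool$end <- pool$start + psize
  }
  empty_calls <- data.frame(sample_id = character(), chrom = character(),
                            start = numeric(), end = numeric(),
                            copy_state = integer(), n_markers = integer(),
                            stringsAsFactors = FALSE)
  .pool_calls <- function(sample_ids) {
    if (nrow(pool) == 0L || length(sample_ids) == 0L) return(empty_calls)
    carrier <- matrix(stats::runif(length(sample_ids) * nrow(pool)) < cfg$polymorphic_carrier_rate,
                      nrow = length(sample_ids))
    idx <- which(carrier, arr.ind = TRUE)
    if (nrow(idx) == 0L) return(empty_calls)
    data.frame(sample_id = sample_ids[idx[, 1]], chrom = pool$chrom[idx[, 2]],
               start = pool$start[idx[, 2]], end = pool$end[idx[, 2]],
               copy_state = pool$copy_state[idx[, 2]],
               n_markers = 5L + as.integer((pool$end - pool$start)[idx[, 2]] %/% 20000),
               stringsAsFactors = FALSE)
  }
  case_pool <- .pool_calls(case_ids)
  ctrl_pool <- .pool_calls(ctrl_ids)
  par_pool <- .pool_calls(c(mo_ids, fa_ids))

  # pathogenic spikes: one per selected case, centred on a random gene
  n_spike <- round(cfg$pathogenic_fraction * cfg$n_cases)
  spikes <- data.frame(sample_id = character(), chrom = character(), start = numeric(),
                       end = numeric(), copy_state = integer(), n_markers = integer(),
                       stringsAsFactors = FALSE)
  spike_truth <- data.frame(call_id = character(), sample_id = character(),
                            inheritance = character(), gene_id = character(),
                            stringsAsFactors = FALSE)
  parent_spikes <- spikes
  if (n_spike > 0L) {
    if (nrow(genes) == 0L) .stopf("cannot place pathogenic spikes without genes")
    carriers <- sample(case_ids, n_spike)
    flagged <- which(genes$growth_gene | genes$mgi_growth |
                       genes$functional_candidate | genes$decipher_overlap)
    pick <- sample.int(nrow(genes), n_spike, replace = TRUE)
    if (length(flagged)) {
      use_flag <- stats::runif(n_spike) < cfg$spike_evidence_fraction
      pick[use_flag] <- flagged[sample.int(length(flagged), sum(use_flag), replace = TRUE)]
    }
    g <- genes[pick, ]
    ssize <- round(.rlnorm_trunc(n_spike, cfg$spike_size_log_mean, cfg$spike_size_log_sd,
                                 cfg$spike_min_size_kb) * 1000)
    ssize <- pmin(ssize, cfg$chromosome_length_bp - 1)
    mid <- (g$start + g$end) %/% 2
    start <- pmax(0, pmin(mid - ssize %/% 2, cfg$chromosome_length_bp - ssize))
    state <- ifelse(stats::runif(n_spike) < 0.5, 1L, 3L)
    spikes <- data.frame(sample_id = carriers, chrom = g$chrom, start = start,
                         end = start + ssize, copy_state = state,
                         n_markers = 5L + as.integer(ssize %/% 20000),
                         stringsAsFactors = FALSE)
    n_dn <- round(cfg$de_novo_fraction * n_spike)
    inh <- rep("inherited_affected", n_spike)
    if (n_dn > 0L) inh[sample.int(n_spike, n_dn)] <- "de_novo"
    spike_truth <- data.frame(
      call_id = .call_id(spikes$sample_id, spikes$chrom, spikes$start,
                         spikes$end, spikes$copy_state),
      sample_id = carriers, inheritance = inh, gene_id = g$gene_id,
      stringsAsFactors = FALSE)
    # inherited spikes: copy into one parent (mother if coin says so)
    tr <- inh == "inherited_affected"
    if (any(tr)) {
      from_mother <- stats::runif(sum(tr)) < 0.5
      pid <- ifelse(from_mother,
                    mo_ids[match(carriers[tr], case_ids)],
                    fa_ids[match(carriers[tr], case_ids)])
      parent_spikes <- spikes[tr, ]
      parent_spikes$sample_id <- pid
      spike_truth$transmitting_parent <- NA_character_
      spike_truth$transmitting_parent[tr] <- pid
    } else spike_truth$transmitting_parent <- NA_character_
  }

  case_calls <- cnv_calls(rbind(case_bg, case_pool, spikes))
  control_calls <- cnv_calls(rbind(ctrl_bg, ctrl_pool))
  parent_calls <- cnv_calls(rbind(par_bg, par_pool, parent_spikes))

  affected_parents <- spike_truth$transmitting_parent[!is.na(spike_truth$transmitting_parent)]
  samples <- data.frame(
    sample_id = c(case_ids, ctrl_ids, mo_ids, fa_ids),
    group = c(rep("case", cfg$n_cases), rep("control", cfg$n_controls),
              rep("parent", 2L * cfg$n_cases)),
    sex = sample(c("M", "F"), cfg$n_cases + cfg$n_controls + 2L * cfg$n_cases, TRUE),
    height_sds = c(stats::rnorm(cfg$n_cases, -2.75, 0.6),
                   stats::rnorm(cfg$n_controls, 0, 1),
                   stats::rnorm(2L * cfg$n_cases, 0, 1)),
    affected = FALSE, mother_id = "0", father_id = "0",
    stringsAsFactors = FALSE)
  samples$affected[samples$group == "case"] <- TRUE
  samples$affected[samples$sample_id %in% affected_parents] <- TRUE
  carriers_of_spikes <- unique(spike_truth$sample_id)
  samples$height_sds[samples$sample_id %in% carriers_of_spikes] <-
    samples$height_sds[samples$sample_id %in% carriers_of_spikes] + cfg$carrier_sds_shift
  samples$mother_id[seq_len(cfg$n_cases)] <- mo_ids
  samples$father_id[seq_len(cfg$n_cases)] <- fa_ids
  trios <- data.frame(child_id = case_ids, mother_id = mo_ids, father_id = fa_ids,
                      mother_affected = mo_ids %in% affected_parents,
                      father_affected = fa_ids %in% affected_parents,
                      stringsAsFactors = FALSE)

  pool_ids <- function(calls) {
    key <- paste(calls$chrom, calls$start, calls$end, calls$copy_state)
    calls$call_id[key %in% paste(pool$chrom, pool$start, pool$end, pool$copy_state)]
  }

  truth <- list(
    spikes = spike_truth,
    polymorphic_call_ids = c(pool_ids(case_calls), pool_ids(control_calls)),
    pool = pool,
    dosage_sensitive_genes = unique(spike_truth$gene_id))

  list(case_calls = case_calls, control_calls = control_calls,
       parent_calls = parent_calls, samples = samples, trios = trios,
       genes = genes, truth = truth)
}

#' Generate a non-overlapping gene annotation with exons and evidence flags
#'
#' Genes are placed on an equal-slot grid per chromosome (guaranteeing
#' non-overlap), each with 2-8 exons inside its span; evidence flags are
#' Bernoulli at the configured rates and the haploinsufficiency percentile is
#' uniform on [0, 100].
#'
#' @param config a [simulation_config()].
#' @return validated gene table (see [gene_table()]).
#' @export
generate_gene_annotation <- function(config) {
  cfg <- config
  withr::local_seed(cfg$seed + 104729L)  # distinct stream from the cohort draw
  n <- cfg$n_genes
  empty <- gene_table(data.frame(
    gene_id = character(), chrom = character(), start = numeric(), end = numeric(),
    exon_starts = character(), exon_ends = character(), growth_gene = logical(),
    mgi_growth = logical(), functional_candidate = logical(),
    growth_tissue_expressed = logical(), decipher_overlap = logical(),
    hi_percentile = numeric(), stringsAsFactors = FALSE))
  if (n == 0L) return(empty)
  per_chrom <- diff(round(seq(0, n, length.out = cfg$n_chromosomes + 1L)))
  rows <- vector("list", cfg$n_chromosomes)
  gi <- 0L
  for (ci in seq_len(cfg$n_chromosomes)) {
    k <- per_chrom[ci]
    if (k == 0L) next
    slot <- cfg$chromosome_length_bp / k
    if (slot < 10000) .stopf("genome too small to place %d non-overlapping genes", n)
    glen <- round(stats::runif(k, 5000, pmin(100000, slot * 0.8)))
    gstart <- round((seq_len(k) - 1L) * slot + stats::runif(k) * (slot - glen))
    gend <- gstart + glen
    n_ex <- sample(2:8, k, replace = TRUE)
    exs <- character(k); exe <- character(k)
    for (j in seq_len(k)) {
      bounds <- round(seq(gstart[j], gend[j], length.out = n_ex[j] + 1L))
      w <- diff(bounds)
      es <- bounds[-length(bounds)] + floor(stats::runif(n_ex[j]) * (w * 0.5))
      ee <- pmin(es + pmax(50, round(w * 0.3)), bounds[-1])
      exs[j] <- paste(es, collapse = ",")
      exe[j] <- paste(ee, collapse = ",")
    }
    rows[[ci]] <- data.frame(
      gene_id = sprintf("gene_%05d", gi + seq_len(k)),
      chrom = sprintf("chr%d", ci), start = gstart, end = gend,
      exon_starts = exs, exon_ends = exe, stringsAsFactors = FALSE)
    gi <- gi + k
  }
  df <- do.call(rbind, rows)
  for (fl in names(config$flag_rates))
    df[[fl]] <- stats::runif(nrow(df)) < config$flag_rates[[fl]]
  df$hi_percentile <- stats::runif(nrow(df)) * 100
  gene_table(df)
}

#' Generate a log2 expression matrix with dosage effects in carriers
#'
#' Every gene has a Gaussian baseline (mean 8, SD 1 across genes) shared by
#' all samples plus per-measurement noise; for each (sample, gene) carrier
#' pair the configured dosage effect is added (`dosage_log2_effect_gain` for
#' gains, `dosage_log2_effect_loss` for losses).
#'
#' @param carriers data.frame with columns `sample_id`, `gene_id`, `cnv_type`
#'   listing which sample carries a CNV over which dosage-sensitive gene.
#' @param genes gene table providing the gene universe (rows of the matrix).
#' @param sample_ids character vector of samples (columns of the matrix).
#' @param config a [simulation_config()]; uses the dosage effects and
#'   `expression_noise_sd`.
#' @param noise_sd override for the noise SD (e.g. 0 for a noiseless check).
#' @return numeric matrix, genes x samples, log2 scale.
#' @export
generate_expression <- function(carriers, genes, sample_ids, config,
                                noise_sd = config$expression_noise_sd) {
  cfg <- config
  withr::local_seed(cfg$seed + 224737L)
  if (nrow(genes) == 0L || length(sample_ids) == 0L)
    return(matrix(numeric(), nrow = nrow(genes), ncol = length(sample_ids),
                  dimnames = list(genes$gene_id, sample_ids)))
  bad_s <- setdiff(carriers$sample_id, sample_ids)
  bad_g <- setdiff(carriers$gene_id, genes$gene_id)
  if (length(bad_s) || length(bad_g))
    .stopf("carriers reference unknown samples/genes: %s",
           paste(c(bad_s, bad_g), collapse = ", "))
  baseline <- stats::rnorm(nrow(genes), 8, 1)
  m <- matrix(baseline, nrow = nrow(genes), ncol = length(sample_ids)) +
    matrix(stats::rnorm(nrow(genes) * length(sample_ids), 0, noise_sd),
           nrow = nrow(genes))
  dimnames(m) <- list(genes$gene_id, sample_ids)
  if (nrow(carriers)) {
    eff <- ifelse(carriers$cnv_type == "gain",
                  cfg$dosage_log2_effect_gain, cfg$dosage_log2_effect_loss)
    idx <- cbind(match(carriers$gene_id, genes$gene_id),
                 match(carriers$sample_id, sample_ids))
    m[idx] <- m[idx] + eff
  }
  m
}

#' Generate a per-SNP p-value track with optional signal loci
#'
#' Background p-values are uniform on (0, 1); inside each signal locus at
#' least one SNP gets a p-value below `signal_level` (a SNP is added at the
#' locus midpoint if none falls inside).
#'
#' @param config a [simulation_config()].
#' @param signal_loci optional data.frame with `chrom`, `start`, `end`.
#' @param signal_level ceiling for the spiked p-value per signal locus.
#' @return data.frame (`chrom`, `pos`, `p`) sorted by chromosome, position.
#' @export
generate_snp_track <- function(config, signal_loci = NULL, signal_level = 1e-10) {
  cfg <- config
  withr::local_seed(cfg$seed + 350377L)
  n <- cfg$n_snps
  df <- data.frame(chrom = character(), pos = numeric(), p = numeric())
  if (n > 0L) {
    df <- data.frame(
      chrom = sprintf("chr%d", sample.int(cfg$n_chromosomes, n, TRUE)),
      pos = floor(stats::runif(n) * cfg$chromosome_length_bp),
      p = stats::runif(n), stringsAsFactors = FALSE)
  }
  if (!is.null(signal_loci) && nrow(signal_loci)) {
    if (any(signal_loci$end > cfg$chromosome_length_bp | signal_loci$start < 0))
      .stopf("signal loci outside the genome")
    for (i in seq_len(nrow(signal_loci))) {
      inside <- df$chrom == signal_loci$chrom[i] & df$pos >= signal_loci$start[i] &
        df$pos < signal_loci$end[i]
      if (!any(inside)) {
        df <- rbind(df, data.frame(
          chrom = signal_loci$chrom[i],
          pos = floor((signal_loci$start[i] + signal_loci$end[i]) / 2),
          p = signal_level * stats::runif(1), stringsAsFactors = FALSE))
      } else {
        j <- which(inside)[1L]
        df$p[j] <- signal_level * stats::runif(1)
      }
    }
  }
  df[order(df$chrom, df$pos), , drop = FALSE]
}

#' Generate MLPA probe ratios for a set of calls
#'
#' Expected relative quantity is 0.5 for a one-copy loss, 1.5 for a one-copy
#' gain, 1.0 for reference samples, plus Gaussian noise.
#'
#' @param calls call table whose loci get one probe each.
#' @param control_ids reference samples measured at every probe.
#' @param noise_sd Gaussian noise SD on the ratio scale.
#' @param seed integer seed.
#' @return data.frame (`probe_id`, `locus`, `sample_id`, `ratio`).
#' @export
generate_mlpa <- function(calls, control_ids, noise_sd = 0.05, seed = 1L) {
  withr::local_seed(seed)
  if (nrow(calls) == 0L)
    return(data.frame(probe_id = character(), locus = character(),
                      sample_id = character(), ratio = numeric()))
  probe <- sprintf("probe_%03d", seq_len(nrow(calls)))
  locus <- sprintf("%s:%d-%d", calls$chrom, calls$start, calls$end)
  expected <- ifelse(calls$cnv_type == "gain", 1.5, 0.5)
  carrier <- data.frame(probe_id = probe, locus = locus, sample_id = calls$sample_id,
                        ratio = pmax(0.01, expected + stats::rnorm(nrow(calls), 0, noise_sd)),
                        stringsAsFactors = FALSE)
  ctrl <- expand.grid(probe_id = probe, sample_id = control_ids,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  ctrl$locus <- locus[match(ctrl$probe_id, probe)]
  ctrl$ratio <- pmax(0.01, 1 + stats::rnorm(nrow(ctrl), 0, noise_sd))
  rbind(carrier, ctrl[, c("probe_id", "locus", "sample_id", "ratio")])
}
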