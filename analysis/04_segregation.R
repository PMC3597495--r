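#!/usr/bin/env Rscript
# Stage 4 — trio segregation, de novo enrichment and MLPA confirmation.
#
# Classifies each surviving candidate call against the parental calls
# (de novo / inherited from affected parent / inherited from unaffected
# parent), drops candidates transmitted by unaffected parents, tests the
# de novo count against the population expectation of 6e-3 de novo CNVs per
# haploid genome per generation, and confirms candidate dosage by MLPA
# probe-ratio classification.

suppressPackageStartupMessages({library(rarecnv); library(jsonlite)})

sim <- "results/sim"
cand <- read_segments("results/filtered_case_segments.tsv")
parents <- read_segments(file.path(sim, "parent_segments.tsv"))
ped <- read_ped(file.path(sim, "samples.ped.tsv"))

cls <- classify_cohort_inheritance(cand, ped$trios, parents)
keep <- cls$inheritance %in% c("de_novo", "inherited_affected")
cat(sprintf("candidates: %d; de novo %d, inherited (affected parent) %d, dropped %d\n",
            nrow(cls), sum(cls$inheritance == "de_novo"),
            sum(cls$inheritance == "inherited_affected"), sum(!keep)))

n_cases <- sum(ped$samples$group == "case")
model <- de_novo_rate_model(6e-3, n_cases)
p_dn <- de_novo_enrichment(sum(cls$inheritance == "de_novo"), model, "poisson")
cat(sprintf("de novo enrichment: observed %d vs expected %.1f, Poisson tail p = %.3g\n",
            sum(cls$inheritance == "de_novo"), model$expected, p_dn))

retained <- cls[keep, ]
ml <- generate_mlpa(retained, sprintf("ctrl_%03d", 1:5), noise_sd = 0.05, seed = 99L)
carrier_rows <- ml[ml$sample_id %in% retained$sample_id, ]
confirmed <- mlpa_classify(carrier_rows$ratio) ==
  ifelse(retained$cnv_type[match(carrier_rows$probe_id, sprintf("probe_%03d", seq_len(nrow(retained))))] == "gain",
         "duplication", "deletion")
cat(sprintf("MLPA confirmation rate: %.0f%%\n", 100 * mean(confirmed)))

con <- file("results/candidate_inheritance.tsv", "w")
writeLines(paste0("#", paste(names(retained), collapse = "\t")), con)
write.table(retained, con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
close(con)
write_json(list(n_candidates = nrow(retained),
                n_de_novo = sum(retained$inheritance == "de_novo"),
                expected_de_novo = model$expected, de_novo_p = p_dn,
                mlpa_confirmation = mean(confirmed)),
           "results/segregation_summary.json", auto_unbox = TRUE, digits = NA)
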