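#!/usr/bin/env Rscript
# Stage 1 — simulate the study cohort.
#
# Generates a synthetic short-stature cohort at the emulated study scale
# (200 cases with parents, 820 controls, ~32 calls per sample, 10% of cases
# carrying a pathogenic CNV of which 35% are de novo, plus a polymorphic CNV
# pool shared with controls) and writes every track in the package's file
# dialects, along with the ground-truth spike table used by later stages.

suppressPackageStartupMessages(library(rarecnv))

out <- "results/sim"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- simulation_config(seed = 20130314L)
co <- generate_cohort(cfg)

write_segments(co$case_calls, file.path(out, "case_segments.tsv"))
write_segments(co$control_calls, file.path(out, "control_segments.tsv"))
write_segments(co$parent_calls, file.path(out, "parent_segments.tsv"))
write_ped(co$samples, file.path(out, "samples.ped.tsv"))
write_genes(co$genes, file.path(out, "genes.tsv"))

con <- file(file.path(out, "truth_spikes.tsv"), "w")
writeLines(paste0("#", paste(names(co$truth$spikes), collapse = "\t")), con)
write.table(co$truth$spikes, con, sep = "\t", quote = FALSE,
            row.names = FALSE, col.names = FALSE)
close(con)
writeLines(co$truth$polymorphic_call_ids, file.path(out, "truth_polymorphic_ids.txt"))

cat(sprintf("cases: %d calls (%d samples), controls: %d calls (%d samples)\n",
            nrow(co$case_calls), cfg$n_cases, nrow(co$control_calls), cfg$n_controls))
cat(sprintf("mean calls per case: %.1f\n", nrow(co$case_calls) / cfg$n_cases))
cat(sprintf("spiked pathogenic CNVs: %d (%d de novo)\n", nrow(co$truth$spikes),
            sum(co$truth$spikes$inheritance == "de_novo")))
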