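#!/usr/bin/env Rscript

# Stage 2 — survey the panel for cluster homologs.
#
# Seed-and-chain candidate detection (word size 11) followed by the
# survey filters: completeness (all query genes present), synteny
# (template order, inversion allowed) and a 40% overall-identity floor.
# Writes hits.tsv, prevalence.tsv and hits.gff3 under results/survey/,
# and compares the accepted calls against the simulated truth.

suppressMessages(library(bgcsurvey))

inputs <- bgcsurvey:::load_panel_inputs("results/panel")
sv <- survey_panel(inputs$genomes, inputs$template, inputs$taxa,
                   survey_params(min_cluster_identity = 40),
                   out_dir = "results/survey")

truth <- jsonlite::read_json("results/panel/truth.json",
                             simplifyVector = TRUE)
acc <- unique(sv$hits$strain[sv$hits$accepted])
truthc <- truth$strain[truth$cluster_present]
tp <- length(intersect(acc, truthc))

message("accepted hits: ", length(acc), " of ", length(inputs$genomes),
        " genomes")
message(sprintf("precision %.3f, recall %.3f vs simulated truth",
                tp / length(acc), tp / length(truthc)))
message("prevalence by genus:")
print(sv$prevalence)
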