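#!/usr/bin/env Rscript

# Stage 5 — %GC anomaly screen.
#
# Computes each accepted cluster's %GC against its host replicon
# (cluster span excised from the baseline) and flags horizontal-transfer
# candidates at the 5-point anomaly threshold, with the direction of
# the deviation recorded.

suppressMessages(library(bgcsurvey))

inputs <- bgcsurvey:::load_panel_inputs("results/panel")
hits <- utils::read.table("results/survey/hits.tsv", header = TRUE,
                          sep = "\t", stringsAsFactors = FALSE)
acc <- hits[hits$accepted & !hits$cross_contig, ]

tbl <- gc_report(acc, inputs$genomes, flag_threshold = 5.0)
dir.create("results/gc", recursive = TRUE, showWarnings = FALSE)
utils::write.table(tbl, "results/gc/gc.tsv", sep = "\t", quote = FALSE,
                   row.names = FALSE)

message(sum(tbl$hgt_flag), " of ", nrow(tbl),
        " clusters flagged as compositional outliers")
message("mean cluster %GC ", round(mean(tbl$cluster_gc), 2),
        ", mean replicon baseline ", round(mean(tbl$replicon_gc), 2),
        ", mean delta ", round(mean(tbl$delta), 2), " points")
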