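#!/usr/bin/env Rscript

# Stage 1 — build the demonstration strain panel.
#
# Four enterobacterial-like genera (40 strains), 100-kb genomes at 54.6%
# GC, a 4-gene 4-kb antibiotic-like cluster implanted 14.6 points below
# the host baseline in half the lineages, one cross-genus horizontal
# transfer, occasional per-gene frameshifts, a clonal resequenced
# isolate, and transposase remnants next to some clusters. Everything
# downstream (survey, restriction, flanks, %GC, trees) reads this panel
# from results/panel/.

suppressMessages(library(bgcsurvey))

seed <- 20260101L
out_dir <- "results/panel"

st <- simulate_species_tree(c(10, 10, 10, 10),
                            within_bl = c(0.004, 0.012),
                            between_bl = 0.025, seed = seed)
tmpl <- make_cluster_template(n_genes = 4, gene_length = 900,
                              spacer = 80, gc = 40, seed = seed,
                              name = "synthetic_cluster")
carriers <- st$tree$tip.label[seq(1, 40, by = 2)]
cfg <- simulation_config(
  st$tree, st$genus_map,
  genome_length = 100000, host_gc = 54.6,
  cluster_template = tmpl,
  carrier_lineages = carriers,
  hgt_events = list(c(carriers[11], st$tree$tip.label[2])),
  frameshift_prob = 0.1,
  clonal_lineages = carriers[1], clonal_copies = 1L,
  flank_conservation = 0.7, mge_prob = 0.3,
  seed = seed)

panel <- simulate_panel(cfg, out_dir = out_dir)

message(sprintf("panel: %d genomes (%d carriers, %d via transfer), %s",
                length(panel$genomes),
                sum(panel$truth$cluster_present),
                sum(grepl("^hgt", panel$truth$acquisition)),
                out_dir))
message("cluster %GC: ",
        round(mean(panel$truth$cluster_gc, na.rm = TRUE), 2),
        " vs host ", cfg$host_gc)
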