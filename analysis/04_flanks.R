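#!/usr/bin/env Rscript

# Stage 4 — flanking-region conservation, mobile elements, frameshifts.
#
# Extracts the 5 kb on either side of every accepted cluster, predicts
# ORFs, groups them into homolog groups at 30% amino-acid identity,
# scores pairwise flank conservation (Jaccard over shared groups),
# flags transposase-like ORFs, and screens cluster genes for
# frameshift-interrupted copies.

suppressMessages(library(bgcsurvey))

inputs <- bgcsurvey:::load_panel_inputs("results/panel")
hits <- utils::read.table("results/survey/hits.tsv", header = TRUE,
                          sep = "\t", stringsAsFactors = FALSE)
acc <- hits[hits$accepted & !hits$cross_contig, ]
dir.create("results/flanks", recursive = TRUE, showWarnings = FALSE)

profiles <- lapply(seq_len(nrow(acc)), function(i) {
  h <- acc[i, ]
  flank_profile(inputs$genomes[[h$strain]], h$contig, h$start, h$end,
                h$strand)
})
cm <- conservation_matrix(profiles, min_identity = 30)
utils::write.table(cm$groups, "results/flanks/groups.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
utils::write.table(
  data.frame(strain = rownames(cm$jaccard), round(cm$jaccard, 4),
             check.names = FALSE),
  "results/flanks/conservation.tsv", sep = "\t", quote = FALSE,
  row.names = FALSE)
message(ncol(cm$presence), " flank homolog groups across ",
        nrow(acc), " carriers; mean off-diagonal Jaccard ",
        round(mean(cm$jaccard[upper.tri(cm$jaccard)]), 3))

mge_hits <- do.call(rbind, lapply(profiles, function(p) {
  if (nrow(p$orfs) == 0) return(NULL)
  fl <- flag_mobile_elements(p$orfs, reference = mge_reference_proteins())
  if (!any(fl)) return(NULL)
  data.frame(strain = p$strain, orf_id = p$orfs$orf_id[fl])
}))
message(if (is.null(mge_hits)) 0 else nrow(mge_hits),
        " transposase-like flank ORFs flagged")
if (!is.null(mge_hits)) {
  utils::write.table(mge_hits, "results/flanks/mge_flags.tsv",
                     sep = "\t", quote = FALSE, row.names = FALSE)
}

tmpl <- inputs$template
refs <- stats::setNames(vapply(tmpl$genes$gene, function(g) {
  sub("\\*$", "", translate_dna(cluster_gene_seq(tmpl, g)))
}, character(1)), tmpl$genes$gene)
interrupted <- do.call(rbind, lapply(seq_len(nrow(acc)), function(i) {
  h <- acc[i, ]
  cl <- substr(inputs$genomes[[h$strain]]$contigs[[h$contig]],
               h$start + 1, h$end)
  if (h$strand == "-") cl <- revcomp(cl)
  det <- detect_interrupted_genes(predict_orfs(cl, 60), refs, seq = cl)
  if (nrow(det) == 0) return(NULL)
  cbind(strain = h$strain, det)
}))
if (is.null(interrupted)) {
  message("no frameshift-interrupted cluster genes found")
} else {
  message(nrow(interrupted), " interrupted cluster gene calls:")
  print(interrupted)
  utils::write.table(interrupted, "results/flanks/interrupted_genes.tsv",
                     sep = "\t", quote = FALSE, row.names = FALSE)
}
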