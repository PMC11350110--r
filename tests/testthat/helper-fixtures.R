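# Shared small fixtures, built once per test run.

test_enzymes <- function() {
  list(restriction_enzyme("EcoRI", "GAATTC", 1L),
       restriction_enzyme("BamHI", "GGATCC", 1L),
       restriction_enzyme("HindIII", "AAGCTT", 1L))
}

# A small two-genus panel with 3 carriers out of 8 lineages.
small_panel <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      st <- simulate_species_tree(c(4, 4), seed = 7)
      tmpl <- make_cluster_template(n_genes = 4, gene_length = 600,
                                    spacer = 80, gc = 39.6, seed = 2)
      cfg <- simulation_config(
        st$tree, st$genus_map, genome_length = 50000,
        cluster_template = tmpl,
        carrier_lineages = c("genusA_s1", "genusA_s3", "genusB_s2"),
        seed = 11)
      cache <<- list(panel = simulate_panel(cfg), tree = st$tree,
                     genus_map = st$genus_map, template = tmpl)
    }
    cache
  }
})

panel_taxa <- function(panel) {
  stats::setNames(panel$truth$genus, panel$truth$strain)
}
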