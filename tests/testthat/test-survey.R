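test_that("align_pair matches the dynamic-programming oracle", {
  a <- align_pair("ACGT", "ACGT", mode = "global")
  expect_equal(a$identity, 100)
  expect_equal(a$coverage, 1.0)
  b <- align_pair("ACGT", "ACGA", mode = "global")
  expect_equal(b$identity, 75)
  # random nucleotide pairs against the full NW oracle; the optimal
  # score is unique, the identity is path-dependent only when length
  # differences admit co-optimal gap placements, so identity equality
  # is asserted on the substitution-only pairs
  for (k in 1:5) {
    x <- random_sequence(80 + 20 * k, 50, seed = 100 + k)
    y <- mutate_sequence(x, 0.15, seed = 200 + k)
    impl <- align_pair(x, y, mode = "global")
    orac <- nw_oracle(x, y)
    expect_equal(impl$score, orac$score, label = paste("score pair", k))
    expect_equal(impl$identity, orac$identity, tolerance = 1e-9,
                 label = paste("identity pair", k))
    y2 <- paste0(y, random_sequence(15, 50, seed = k))
    expect_equal(align_pair(x, y2, mode = "global")$score,
                 nw_oracle(x, y2)$score,
                 label = paste("score padded pair", k))
  }
})

test_that("local alignment finds an exact embedded query", {
  q <- random_sequence(300, 50, seed = 7)
  subj <- paste0(random_sequence(1400, 50, seed = 8), q,
                 random_sequence(1300, 50, seed = 9))
  al <- align_pair(q, subj, mode = "local")
  expect_equal(al$identity, 100)
  expect_equal(al$coverage, 1.0)
  expect_equal(al$subject_span, c(1400L, 1700L))
})

test_that("mixed alphabets are rejected", {
  expect_error(align_pair("ACGT", "MKLVWF"), "mixed")
})

test_that("candidate detection finds implants and ignores noise", {
  tmpl <- make_cluster_template(n_genes = 2, gene_length = 600,
                                spacer = 80, gc = 40, seed = 2)
  host <- random_sequence(40000, 54, seed = 3)
  g <- genome_record("s1", c(
    contig1 = paste0(substr(host, 1, 20000), tmpl$sequence,
                     substr(host, 20001, 40000))))
  cand <- find_candidate_loci(g, tmpl)
  expect_equal(nrow(cand), 1L)
  expect_lte(abs(cand$start - 20000), 25)
  expect_lte(abs(cand$end - (20000 + tmpl$length)), 25)
  # random genomes yield nothing above the chain floor
  for (sd in 1:3) {
    gr <- genome_record("r", c(c1 = random_sequence(100000, 54,
                                                    seed = 300 + sd)))
    expect_equal(nrow(find_candidate_loci(gr, tmpl)), 0L,
                 label = paste("noise seed", sd))
  }
})

test_that("clusters split across contigs yield per-contig candidates", {
  tmpl <- make_cluster_template(n_genes = 2, gene_length = 600,
                                spacer = 80, gc = 40, seed = 2)
  cut <- tmpl$genes$end[1] + 10  # split at a gene boundary
  g <- genome_record("draft", c(
    c1 = paste0(random_sequence(5000, 54, seed = 1),
                substr(tmpl$sequence, 1, cut)),
    c2 = paste0(substr(tmpl$sequence, cut + 1, tmpl$length),
                random_sequence(5000, 54, seed = 2))))
  cand <- find_candidate_loci(g, tmpl)
  expect_setequal(unique(cand$contig), c("c1", "c2"))
  hit <- survey_genome(g, tmpl)
  expect_true(hit$cross_contig)
  expect_true(hit$accepted)
})

test_that("synteny verdicts follow the inversion convention", {
  ok <- data.frame(template_index = 1:3, strand_agrees = TRUE)
  expect_true(check_synteny(ok))
  swapped <- data.frame(template_index = c(1, 3, 2),
                        strand_agrees = TRUE)
  expect_false(check_synteny(swapped))
  inverted <- data.frame(template_index = 3:1, strand_agrees = FALSE)
  expect_true(check_synteny(inverted))
  half <- data.frame(template_index = 3:1,
                     strand_agrees = c(FALSE, TRUE, FALSE))
  expect_false(check_synteny(half))
})

test_that("survey filters catch deletions and rearrangements", {
  tmpl <- make_cluster_template(n_genes = 3, gene_length = 600,
                                spacer = 80, gc = 40, seed = 4)
  host <- random_sequence(30000, 54, seed = 5)
  implant <- function(s) {
    genome_record("x", c(c1 = paste0(substr(host, 1, 15000), s,
                                     substr(host, 15001, 30000))))
  }
  # verbatim: accepted at 100%
  h0 <- survey_genome(implant(tmpl$sequence), tmpl)
  expect_true(h0$accepted)
  expect_equal(h0$overall_identity, 100, tolerance = 0.1)
  # one gene deleted: incomplete
  g2 <- tmpl$genes[2, ]
  del <- paste0(substr(tmpl$sequence, 1, g2$start),
                substr(tmpl$sequence, g2$end + 1, tmpl$length))
  h1 <- survey_genome(implant(del), tmpl)
  expect_false(h1$complete)
  expect_false(h1$accepted)
  # two internal genes swapped: non-syntenic
  g1 <- tmpl$genes[1, ]
  s1 <- substr(tmpl$sequence, g1$start + 1, g1$end)
  s2 <- substr(tmpl$sequence, g2$start + 1, g2$end)
  swapped <- paste0(substr(tmpl$sequence, 1, g1$start), s2,
                    substr(tmpl$sequence, g1$end + 1, g2$start), s1,
                    substr(tmpl$sequence, g2$end + 1, tmpl$length))
  h2 <- survey_genome(implant(swapped), tmpl)
  expect_false(h2$syntenic)
  expect_false(h2$accepted)
})

test_that("detection is invariant under contig reverse-complement", {
  fx <- small_panel()
  p <- fx$panel
  s <- "genusA_s1"
  g <- p$genomes[[s]]
  h0 <- survey_genome(g, p$template)
  grc <- genome_record(s, c(contig1 = revcomp(g$contigs[["contig1"]])))
  h1 <- survey_genome(grc, p$template)
  expect_true(h0$accepted && h1$accepted)
  expect_equal(h1$overall_identity, h0$overall_identity, tolerance = 0.5)
  clen <- nchar(g$contigs[["contig1"]])
  expect_equal(h1$start, clen - h0$end, tolerance = 30)
  expect_equal(h1$strand, "-")
})

test_that("detection is invariant under splitting outside the cluster", {
  fx <- small_panel()
  p <- fx$panel
  s <- "genusA_s1"
  g <- p$genomes[[s]]
  truth <- p$truth[p$truth$strain == s, ]
  contig <- g$contigs[["contig1"]]
  cut <- truth$end + 4000  # downstream of the cluster
  gs <- genome_record(s, c(cA = substr(contig, 1, cut),
                           cB = substr(contig, cut + 1, nchar(contig))))
  h <- survey_genome(gs, p$template)
  expect_true(h$accepted)
  expect_equal(h$contig, "cA")
})

test_that("acceptance is monotone in the identity threshold", {
  fx <- small_panel()
  p <- fx$panel
  taxa <- panel_taxa(p)
  loose <- survey_panel(p$genomes, p$template, taxa,
                        survey_params(min_cluster_identity = 40))
  strict <- survey_panel(p$genomes, p$template, taxa,
                         survey_params(min_cluster_identity = 90))
  acc_loose <- loose$hits$strain[loose$hits$accepted]
  acc_strict <- strict$hits$strain[strict$hits$accepted]
  expect_true(all(acc_strict %in% acc_loose))
})

test_that("candidate spans agree with a full-DP local alignment oracle", {
  tmpl <- make_cluster_template(n_genes = 2, gene_length = 600,
                                spacer = 80, gc = 40, seed = 6)
  host <- random_sequence(15000, 54, seed = 7)
  mut <- mutate_sequence(tmpl$sequence, 0.1, seed = 8)
  g <- genome_record("o", c(c1 = paste0(substr(host, 1, 7000), mut,
                                        substr(host, 7001, 15000))))
  cand <- find_candidate_loci(g, tmpl)
  expect_equal(nrow(cand), 1L)
  al <- align_pair(tmpl$sequence, g$contigs[["c1"]], mode = "local")
  expect_lte(abs(cand$start - al$subject_span[1]), 25)
  expect_lte(abs(cand$end - al$subject_span[2]), 25)
})

test_that("prevalence arithmetic uses half-away-from-zero 3-decimal rounding", {
  expect_equal(prevalence(178, 516), 34.496)
  expect_equal(prevalence(11, 354), 3.107)
  expect_equal(prevalence(0, 100), 0)
  expect_equal(prevalence(1, 1600), 0.063)  # 0.0625 rounds away from zero
  expect_error(prevalence(5, 0), "positive")
  expect_error(prevalence(7, 5), "count")
})

test_that("survey_panel tabulates per-genus prevalence and buckets unknowns", {
  fx <- small_panel()
  p <- fx$panel
  taxa <- panel_taxa(p)
  taxa <- taxa[names(taxa) != "genusB_s2"]
  expect_warning(
    sv <- survey_panel(p$genomes, p$template, taxa),
    "unknown")
  expect_true("unknown" %in% sv$prevalence$genus)
  rowA <- sv$prevalence[sv$prevalence$genus == "genusA", ]
  expect_equal(rowA$n_carriers, 2L)
  expect_equal(rowA$percent, prevalence(2, rowA$n_surveyed))
  out <- withr::local_tempdir()
  sv2 <- suppressWarnings(
    survey_panel(p$genomes, p$template, taxa, out_dir = out))
  expect_true(all(file.exists(file.path(
    out, c("hits.tsv", "prevalence.tsv", "hits.gff3")))))
})
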