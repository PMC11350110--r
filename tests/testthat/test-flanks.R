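test_that("translate_dna uses the bacterial code", {
  expect_equal(translate_dna("ATGAAATAA"), "MK*")
  expect_equal(translate_dna("TTG"), "L")
})

test_that("predict_orfs matches the six-frame brute-force oracle", {
  expect_equal(predict_orfs("ATGAAATAA", min_length = 9)$protein, "MK")
  for (sd in 1:3) {
    s <- random_sequence(10000, 50, seed = 900 + sd)
    impl <- predict_orfs(s, min_length = 150)
    orac <- sixframe_oracle(s, min_length = 150)
    expect_equal(nrow(impl), nrow(orac), label = paste("count seed", sd))
    expect_equal(impl$start, orac$start, label = paste("starts", sd))
    expect_equal(impl$end, orac$end, label = paste("ends", sd))
    expect_equal(impl$strand, orac$strand, label = paste("strands", sd))
  }
  expect_equal(nrow(predict_orfs(random_sequence(5000, 50, seed = 1),
                                 min_length = 1000000)), 0L)
})

test_that("predicted ORFs are frame-consistent and stop-terminated", {
  s <- random_sequence(6000, 54, seed = 77)
  orfs <- predict_orfs(s, min_length = 150)
  expect_true(all(orfs$length %% 3 == 0))
  for (i in seq_len(nrow(orfs))) {
    nt <- substr(s, orfs$start[i] + 1, orfs$end[i])
    if (orfs$strand[i] == "-") nt <- revcomp(nt)
    prot <- translate_dna(nt)
    if (!orfs$edge[i]) expect_match(prot, "\\*$")
    expect_false(grepl("\\*", substr(prot, 1, nchar(prot) - 1)))
  }
})

test_that("flank extraction truncates and orients correctly", {
  contig <- random_sequence(30000, 50, seed = 5)
  g <- genome_record("s", c(c1 = contig))
  centered <- extract_flanks(g, "c1", 12500, 17500)
  expect_equal(nchar(centered$upstream$seq), 5000L)
  expect_equal(nchar(centered$downstream$seq), 5000L)
  expect_false(centered$upstream$truncated)
  at_start <- extract_flanks(g, "c1", 0, 4000)
  expect_equal(nchar(at_start$upstream$seq), 0L)
  expect_true(at_start$upstream$truncated)
  # minus strand: flanks swap and reverse-complement
  minus <- extract_flanks(g, "c1", 12500, 17500, strand = "-")
  expect_equal(minus$upstream$seq, revcomp(centered$downstream$seq))
  expect_equal(minus$downstream$seq, revcomp(centered$upstream$seq))
})

test_that("homolog grouping is single-linkage at the identity cutoff", {
  p <- paste(rep("MKLVWFERTYHACDGS", 8), collapse = "")
  two_same <- c(a = p, b = p)
  g1 <- group_homologs(two_same)
  expect_equal(length(unique(g1$group)), 1L)
  # unrelated random proteins split (identity << 30%, checked by the
  # alignment itself)
  aa <- c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q","R",
          "S","T","V","W","Y")
  set.seed(9)
  r1 <- paste(sample(aa, 100, TRUE), collapse = "")
  r2 <- paste(sample(aa, 100, TRUE), collapse = "")
  expect_lt(align_pair(r1, r2, mode = "global",
                       alphabet = "protein")$identity, 30)
  g2 <- group_homologs(c(x = r1, y = r2))
  expect_equal(length(unique(g2$group)), 2L)
})

test_that("transitive chains collapse into one group", {
  # A~B and B~C above the cutoff, A~C below: single linkage joins all
  set.seed(11)
  aa <- c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q","R",
          "S","T","V","W","Y")
  A <- paste(sample(aa, 120, TRUE), collapse = "")
  mutate_prot <- function(p, k, seed) {
    set.seed(seed)
    x <- strsplit(p, "")[[1]]
    at <- sample(length(x), k)
    x[at] <- vapply(x[at], function(ch) sample(setdiff(aa, ch), 1), "")
    paste(x, collapse = "")
  }
  B <- mutate_prot(A, 70, 12)   # ~42% identity to A
  C <- mutate_prot(B, 70, 13)   # ~42% to B, ~17-25% to A
  idAB <- align_pair(A, B, "global", "protein")$identity
  idBC <- align_pair(B, C, "global", "protein")$identity
  idAC <- align_pair(A, C, "global", "protein")$identity
  expect_gt(idAB, 30); expect_gt(idBC, 30); expect_lt(idAC, 30)
  g <- group_homologs(c(A = A, B = B, C = C))
  expect_equal(length(unique(g$group)), 1L)
  # order invariance
  g_rev <- group_homologs(c(C = C, B = B, A = A))
  expect_identical(g[order(g$member), c("member", "group")],
                   g_rev[order(g_rev$member), c("member", "group")])
})

test_that("conservation scores are Jaccard indices over flank groups", {
  fake_profile <- function(strain, prots) {
    orfs <- data.frame(
      orf_id = paste(strain, "up", seq_along(prots), sep = "|"),
      contig = "c1", start = seq_along(prots) * 1000,
      end = seq_along(prots) * 1000 + 600, strand = "+",
      length = 600L, edge = FALSE, protein = prots, side = "upstream")
    structure(list(strain = strain, orfs = orfs,
                   truncated = c(upstream = FALSE, downstream = FALSE)),
              class = "flank_profile")
  }
  p <- vapply(1:4, function(i) {
    make_coding_seq(150, gc = 50, seed = 40 + i)
  }, character(1))
  prot <- vapply(p, function(s) sub("\\*$", "", translate_dna(s)), "")
  same <- conservation_matrix(list(fake_profile("s1", prot),
                                   fake_profile("s2", prot)))
  expect_equal(same$jaccard["s1", "s2"], 1.0)
  disjoint <- conservation_matrix(list(fake_profile("s1", prot[1:2]),
                                       fake_profile("s2", prot[3:4])))
  expect_equal(disjoint$jaccard["s1", "s2"], 0.0)
})

test_that("sister-pair flank conservation tracks the simulated fraction", {
  st <- simulate_species_tree(c(4, 4), seed = 7)
  cfg <- simulation_config(
    st$tree, st$genus_map, genome_length = 50000,
    cluster_template = make_cluster_template(n_genes = 2,
                                             gene_length = 600,
                                             spacer = 80, gc = 40,
                                             seed = 2),
    flank_conservation = 0.5, seed = 29)
  p <- simulate_panel(cfg)
  idx <- which(p$truth$cluster_present)
  profs <- lapply(idx, function(i) {
    h <- p$truth[i, ]
    flank_profile(p$genomes[[h$strain]], h$contig, h$start, h$end,
                  h$strand)
  })
  cm <- conservation_matrix(profs)
  sisters <- list(c("genusA_s1", "genusA_s3"),
                  c("genusA_s4", "genusA_s2"),
                  c("genusB_s1", "genusB_s4"))
  js <- vapply(sisters, function(s) cm$jaccard[s[1], s[2]], numeric(1))
  expect_lte(abs(mean(js) - 0.5), 0.15)
})

test_that("mobile-element flagging uses keywords and reference proteins", {
  orfs <- data.frame(orf_id = c("o1", "o2", "o3"), protein = c("M", "M", "M"))
  ann <- c("LysR-family transcriptional regulator",
           "IS3 family transposase",
           "hypothetical protein")
  expect_equal(flag_mobile_elements(orfs, annotations = ann),
               c(FALSE, TRUE, FALSE))
  expect_error(flag_mobile_elements(orfs), "annotations")
  # reference route: the simulator's transposase remnant
  mge_prot <- unname(mge_reference_proteins()[1])
  orfs2 <- data.frame(orf_id = "m", protein = mge_prot)
  expect_true(flag_mobile_elements(orfs2,
                                   reference = mge_reference_proteins()))
})

test_that("simulated transposase remnants are flagged in flanks", {
  st <- simulate_species_tree(c(2, 2), seed = 3)
  cfg <- simulation_config(
    st$tree, st$genus_map, genome_length = 30000,
    cluster_template = make_cluster_template(n_genes = 2,
                                             gene_length = 600,
                                             spacer = 80, gc = 40,
                                             seed = 2),
    mge_prob = 1, seed = 15)
  p <- simulate_panel(cfg)
  h <- p$truth[p$truth$mge_adjacent, ][1, ]
  fp <- flank_profile(p$genomes[[h$strain]], h$contig, h$start, h$end,
                      h$strand, min_orf_length = 250L)
  flags <- flag_mobile_elements(fp$orfs,
                                reference = mge_reference_proteins())
  expect_true(any(flags))
})

test_that("interrupted genes are detected from frameshift fragments", {
  tmpl <- make_cluster_template(n_genes = 3, gene_length = 900,
                                spacer = 80, gc = 40, seed = 4)
  refs <- stats::setNames(vapply(tmpl$genes$gene, function(g) {
    sub("\\*$", "", translate_dna(cluster_gene_seq(tmpl, g)))
  }, character(1)), tmpl$genes$gene)
  # intact cluster: nothing reported
  intact <- detect_interrupted_genes(predict_orfs(tmpl$sequence, 60),
                                     refs)
  expect_equal(nrow(intact), 0L)
  # frameshift mid-gene 2: exactly that gene reported
  g2 <- tmpl$genes[2, ]
  fs <- inject_frameshift(tmpl$sequence,
                          g2$start + round((g2$end - g2$start) / 2),
                          "deletion")
  det <- detect_interrupted_genes(predict_orfs(fs, 60), refs)
  expect_true("synthetic_cluster_g02" %in% det$gene)
  expect_false(any(setdiff(tmpl$genes$gene, "synthetic_cluster_g02")
                   %in% det$gene))
})

test_that("adjacent ORFs from different genes are not merged", {
  # two intact neighbouring genes: each matches its own reference fully,
  # so no interrupted-gene candidate may appear
  tmpl <- make_cluster_template(n_genes = 2, gene_length = 900,
                                spacer = 80, gc = 40, seed = 8)
  refs <- stats::setNames(vapply(tmpl$genes$gene, function(g) {
    sub("\\*$", "", translate_dna(cluster_gene_seq(tmpl, g)))
  }, character(1)), tmpl$genes$gene)
  det <- detect_interrupted_genes(predict_orfs(tmpl$sequence, 60), refs)
  expect_equal(nrow(det), 0L)
})

test_that("frameshift screening meets recall and false-positive targets", {
  st <- simulate_species_tree(c(4, 4), within_bl = c(0.01, 0.03),
                              between_bl = 0.03, seed = 7)
  tmpl <- make_cluster_template(n_genes = 4, gene_length = 900,
                                spacer = 80, gc = 39.6, seed = 5)
  refs <- stats::setNames(vapply(tmpl$genes$gene, function(g) {
    sub("\\*$", "", translate_dna(cluster_gene_seq(tmpl, g)))
  }, character(1)), tmpl$genes$gene)
  tp <- 0; fn <- 0; fp <- 0; tn <- 0
  for (sd in c(11, 23)) {
    cfg <- simulation_config(st$tree, st$genus_map,
                             genome_length = 50000,
                             cluster_template = tmpl,
                             frameshift_prob = 0.3, seed = sd)
    p <- simulate_panel(cfg)
    for (i in which(p$truth$cluster_present)) {
      h <- p$truth[i, ]
      cl <- substr(p$genomes[[h$strain]]$contigs[[h$contig]],
                   h$start + 1, h$end)
      det <- detect_interrupted_genes(predict_orfs(cl, 60), refs, seq = cl)
      truthg <- p$truth$frameshifts[[i]]$gene
      for (g in tmpl$genes$gene) {
        d <- g %in% det$gene
        tr <- g %in% truthg
        if (tr && d) tp <- tp + 1
        else if (tr && !d) fn <- fn + 1
        else if (!tr && d) fp <- fp + 1
        else tn <- tn + 1
      }
    }
  }
  expect_gte(tp / (tp + fn), 0.9)
  expect_lte(fp / (fp + tn), 0.05)
})
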