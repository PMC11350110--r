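test_that("build_msa aligns pairs exactly and sets zero gaps for twins", {
  twins <- c(a = "ACGTACGT", b = "ACGTACGT")
  m0 <- build_msa(twins)
  expect_identical(m0, twins)
  m1 <- build_msa(c(x = "ACGT", y = "ACT"))
  expect_equal(nchar(m1[["x"]]), 4L)
  expect_equal(sum(strsplit(m1[["y"]], "")[[1]] == "-"), 1L)
  # induced pairwise score equals the DP optimum
  sc <- 0
  xa <- strsplit(m1[["x"]], "")[[1]]
  ya <- strsplit(m1[["y"]], "")[[1]]
  for (i in seq_along(xa)) {
    sc <- sc + if (xa[i] == "-" || ya[i] == "-") -2
               else if (xa[i] == ya[i]) 1 else -1
  }
  expect_equal(sc, nw_oracle("ACGT", "ACT")$score)
  expect_error(build_msa(c(a = "ACGT")), ">= 2")
})

test_that("multiple alignment preserves residues and column bounds", {
  seqs <- c(s1 = random_sequence(400, 50, seed = 1),
            s2 = mutate_sequence(random_sequence(400, 50, seed = 1),
                                 0.1, seed = 2),
            s3 = paste0(mutate_sequence(random_sequence(400, 50, seed = 1),
                                        0.1, seed = 3), "ACGTAC"))
  m <- build_msa(seqs)
  expect_equal(length(unique(nchar(m))), 1L)
  expect_gte(nchar(m[[1]]), max(nchar(seqs)))
  for (nm in names(seqs)) {
    expect_identical(gsub("-", "", m[[nm]]), seqs[[nm]])
  }
})

test_that("pairwise distances follow their closed forms", {
  msa <- c(a = "ACGTACGT", b = "ACGTACGT")
  expect_equal(unname(pairwise_distance(msa, "p")["a", "b"]), 0)
  msa2 <- c(a = "ACGT", b = "ACGA")
  expect_equal(unname(pairwise_distance(msa2, "p")["a", "b"]), 0.25)
  # jc69 closed form at p = 0.3: -0.75 log(1 - 0.4)
  msa3 <- c(a = paste(rep("A", 10), collapse = ""),
            b = paste(c(rep("C", 3), rep("A", 7)), collapse = ""))
  expect_equal(unname(pairwise_distance(msa3, "jc69")["a", "b"]),
               -0.75 * log(1 - 0.4), tolerance = 1e-5)
  expect_equal(round(-0.75 * log(1 - 0.4), 5), 0.38312)
  # limit agreement: jc69 -> p as p -> 0
  msa4 <- c(a = paste(rep("A", 100), collapse = ""),
            b = paste(c("C", rep("A", 99)), collapse = ""))
  p <- unname(pairwise_distance(msa4, "p")["a", "b"])
  j <- unname(pairwise_distance(msa4, "jc69")["a", "b"])
  expect_equal(p, 0.01)
  expect_lt(abs(j - p) / p, 0.01)
  # saturation is capped and recorded
  msa5 <- c(a = "ACGTACGTAC", b = "CATGCATGCA")
  d5 <- pairwise_distance(msa5, "jc69")
  expect_equal(unname(d5["a", "b"]), 5)
  expect_true(attr(d5, "saturated")["a", "b"])
})

test_that("distances agree with ape::dist.dna", {
  set.seed(3)
  base <- random_sequence(600, 50, seed = 31)
  msa <- c(a = base,
           b = mutate_sequence(base, 0.05, seed = 32),
           c = mutate_sequence(base, 0.12, seed = 33))
  dn <- lapply(msa, function(s) strsplit(tolower(s), "")[[1]])
  bin <- ape::as.DNAbin(do.call(rbind, dn))
  for (mm in c("raw" = "p", "JC69" = "jc69", "K80" = "k2p")) {
    ours <- pairwise_distance(msa, mm)
    theirs <- as.matrix(ape::dist.dna(
      bin, model = names(which(c(raw = "p", JC69 = "jc69",
                                 K80 = "k2p") == mm))))
    expect_equal(unclass(ours)[rownames(theirs), colnames(theirs)],
                 theirs, tolerance = 1e-9, ignore_attr = TRUE,
                 label = mm)
  }
})

test_that("neighbor joining inverts additive matrices exactly", {
  trees <- c("((a:1,b:2):1,(c:3,d:4):1);",
             "(((a:0.5,b:0.7):0.3,c:1.1):0.4,(d:0.2,e:0.9):0.6);",
             "((a:2,(b:1,(c:4,d:1):2):3):1,(e:2,(f:3,g:1):1):2,h:4);")
  for (txt in trees) {
    tr <- ape::read.tree(text = txt)
    d <- ape::cophenetic.phylo(tr)
    nt <- nj_tree(d)
    # oracle: recompute path distances from the output tree
    back <- ape::cophenetic.phylo(nt)[rownames(d), colnames(d)]
    expect_equal(back, d, tolerance = 1e-8)
    expect_equal(rf_distance(nt, tr), 0L)
    # taxon order invariance
    perm <- sample(rownames(d))
    nt2 <- nj_tree(d[perm, perm])
    expect_equal(rf_distance(nt2, nt), 0L)
  }
  expect_error(nj_tree(matrix(0, 2, 2,
                              dimnames = list(c("a", "b"),
                                              c("a", "b")))), ">= 3")
})

test_that("bootstrap supports are deterministic and resolve clear splits", {
  base <- random_sequence(800, 50, seed = 51)
  left <- mutate_sequence(base, 0.2, seed = 52)
  msa <- build_msa(c(
    a1 = mutate_sequence(base, 0.01, seed = 53),
    a2 = mutate_sequence(base, 0.01, seed = 54),
    a3 = mutate_sequence(base, 0.01, seed = 55),
    a4 = mutate_sequence(base, 0.01, seed = 56),
    b1 = mutate_sequence(left, 0.01, seed = 57),
    b2 = mutate_sequence(left, 0.01, seed = 58),
    b3 = mutate_sequence(left, 0.01, seed = 59),
    b4 = mutate_sequence(left, 0.01, seed = 60)))
  t1 <- bootstrap_support(msa, n_reps = 200, seed = 9)
  t2 <- bootstrap_support(msa, n_reps = 200, seed = 9)
  expect_identical(t1$node.label, t2$node.label)
  expect_false(attr(t1, "degenerate"))
  # the a|b split must be near-unanimous
  core <- ape::getMRCA(ape::root(t1, "b1"), c("a1", "a2", "a3", "a4"))
  expect_gte(min(t1$node.label, na.rm = TRUE), 0)
  expect_gte(max(t1$node.label, na.rm = TRUE), 95)
  # degenerate alignment reported as such
  same <- c(x = "ACGTACGT", y = "ACGTACGT", z = "ACGTACGT")
  td <- bootstrap_support(same, n_reps = 10, seed = 1)
  expect_true(attr(td, "degenerate"))
})

test_that("RF distance agrees with bipartition enumeration", {
  t1 <- ape::read.tree(text = "((a,b),(c,d));")
  t2 <- ape::read.tree(text = "((a,c),(b,d));")
  expect_equal(rf_distance(t1, t1), 0L)
  expect_equal(rf_distance(t1, t2), 2L)
  # star versus resolved
  star <- ape::read.tree(text = "(a,b,c,d);")
  expect_equal(rf_distance(star, t1), 1L)
  expect_equal(rf_oracle(star, t1), 1L)
  # random trees up to 8 taxa
  for (sd in 1:6) {
    set.seed(700 + sd)
    n <- sample(4:8, 1)
    x <- ape::rtree(n, tip.label = letters[1:n])
    y <- ape::rtree(n, tip.label = letters[1:n])
    expect_equal(rf_distance(x, y), rf_oracle(x, y),
                 label = paste("seed", sd))
  }
  z <- ape::rtree(5, tip.label = letters[1:5])
  w <- ape::rtree(5, tip.label = letters[2:6])
  expect_error(rf_distance(z, w), "leaf")
  expect_silent(rf_distance(z, w, prune = TRUE))
})

test_that("congruent trees report no displacement", {
  tr <- ape::read.tree(text = "((a1:1,a2:1):2,(b1:1,b2:1):2);")
  gm <- c(a1 = "A", a2 = "A", b1 = "B", b2 = "B")
  rep_ <- congruence_report(tr, tr, gm)
  expect_equal(rep_$rf, 0L)
  expect_equal(rep_$normalized_rf, 0)
  expect_true(all(rep_$monophyly$cluster_tree))
  expect_length(rep_$displaced, 0)
  # one genus per leaf: trivially monophyletic everywhere
  gm2 <- stats::setNames(c("w", "x", "y", "z"), tr$tip.label)
  rep2 <- congruence_report(tr, tr, gm2)
  expect_true(all(rep2$monophyly$species_tree))
})

test_that("a cross-genus transfer shows up as the displaced leaf", {
  st <- simulate_species_tree(c(5, 5), seed = 3)
  cfg <- simulation_config(
    st$tree, st$genus_map, genome_length = 25000,
    cluster_template = make_cluster_template(n_genes = 2,
                                             gene_length = 600,
                                             spacer = 80, gc = 40,
                                             seed = 2),
    hgt_events = list(c("genusB_s2", "genusA_s4")), seed = 21)
  p <- simulate_panel(cfg)
  cl <- vapply(seq_len(nrow(p$truth)), function(i) {
    h <- p$truth[i, ]
    substr(p$genomes[[h$strain]]$contigs[[h$contig]], h$start + 1, h$end)
  }, character(1))
  names(cl) <- p$truth$strain
  ct <- nj_tree(pairwise_distance(build_msa(cl)))
  sp <- nj_tree(pairwise_distance(build_msa(p$markers)))
  rep_ <- congruence_report(ct, sp, st$genus_map)
  expect_true("genusA_s4" %in% rep_$displaced)
  expect_gt(rep_$rf, 0)
})

test_that("no-transfer panels give congruent cluster and species trees", {
  st <- simulate_species_tree(c(4, 4), within_bl = c(0.02, 0.06),
                              between_bl = 0.08, seed = 5)
  cfg <- simulation_config(
    st$tree, st$genus_map, genome_length = 25000,
    cluster_template = make_cluster_template(n_genes = 2,
                                             gene_length = 600,
                                             spacer = 80, gc = 40,
                                             seed = 2),
    seed = 33)
  p <- simulate_panel(cfg)
  cl <- vapply(seq_len(nrow(p$truth)), function(i) {
    h <- p$truth[i, ]
    substr(p$genomes[[h$strain]]$contigs[[h$contig]], h$start + 1, h$end)
  }, character(1))
  names(cl) <- p$truth$strain
  ct <- nj_tree(pairwise_distance(build_msa(cl)))
  sp <- nj_tree(pairwise_distance(build_msa(p$markers)))
  rep_ <- congruence_report(ct, sp, st$genus_map)
  expect_lte(rep_$normalized_rf, 0.1)
})
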