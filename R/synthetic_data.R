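# Synthetic strain-panel generator. Emits genomes evolved along a known
# species tree with biosynthetic gene clusters implanted under controlled
# conditions (GC offset, horizontal transfers, frameshifts, clonal
# duplicates, transposase remnants, tunable flank conservation) plus a
# complete ground-truth table, so every downstream survey stage can be
# validated without genome downloads.

BASES <- c("A", "C", "G", "T")
STOP_CODONS <- c("TAA", "TAG", "TGA")

# Run `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. seed = NULL runs in the ambient stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Random nucleotide sequence with an exact %GC
#'
#' The number of G+C bases is fixed at `round(length * gc / 100)` and
#' their positions drawn uniformly, so the emitted composition matches
#' the target exactly (up to the 1-base rounding), not merely in
#' expectation. This makes injected cluster/host GC offsets recoverable
#' to high precision.
#'
#' @param length Sequence length (bp).
#' @param gc Target %GC in [0, 100].
#' @param seed Optional integer seed (local RNG stream).
#' @return A nucleotide string.
#' @export
random_sequence <- function(length, gc = 50, seed = NULL) {
  stopifnot(length >= 1, gc >= 0, gc <= 100)
  with_seed(seed, {
    n_gc <- round(length * gc / 100)
    is_gc <- logical(length)
    if (n_gc > 0) is_gc[sample.int(length, n_gc)] <- TRUE
    out <- character(length)
    out[is_gc] <- sample(c("G", "C"), n_gc, replace = TRUE)
    out[!is_gc] <- sample(c("A", "T"), length - n_gc, replace = TRUE)
    paste(out, collapse = "")
  })
}

#' Mutate a sequence by independent per-site substitution
#'
#' Each site is substituted with probability `rate`; a substituted site
#' takes one of the three other bases uniformly (a Jukes-Cantor-like
#' process without multiple hits within a call). Length is preserved.
#'
#' @param seq Nucleotide string.
#' @param rate Per-site substitution probability in [0, 0.75].
#' @param seed Optional integer seed (local stream; same seed, same
#'   output).
#' @param on_invalid "error" rejects non-ACGT characters; "keep" passes
#'   them through unmutated.
#' @return Mutated sequence, same length.
#' @export
mutate_sequence <- function(seq, rate, seed = NULL,
                            on_invalid = c("error", "keep")) {
  on_invalid <- match.arg(on_invalid)
  stopifnot(rate >= 0, rate <= 0.75)
  chars <- strsplit(seq, "")[[1]]
  idx <- match(chars, BASES)
  if (anyNA(idx) && on_invalid == "error") {
    stop("non-ACGT characters in input; use on_invalid = \"keep\" to ",
         "pass them through")
  }
  if (rate == 0) return(seq)
  with_seed(seed, {
    hit <- which(stats::runif(length(chars)) < rate & !is.na(idx))
    if (length(hit) > 0) {
      shift <- sample.int(3L, length(hit), replace = TRUE)
      chars[hit] <- BASES[((idx[hit] - 1L + shift) %% 4L) + 1L]
    }
    paste(chars, collapse = "")
  })
}

#' Inject a single-base frameshift
#'
#' Inserts or deletes one base at `position` (0-based), shifting the
#' downstream reading frame, as seen in degraded cluster copies where
#' one gene is split into several consecutive ORFs.
#'
#' @param gene_seq Nucleotide string.
#' @param position 0-based offset, `0 <= position < nchar(gene_seq)`.
#'   Insertion places the new base before the base at `position`.
#' @param kind "insertion" or "deletion".
#' @param seed Seed for the inserted base (ignored for deletions).
#' @return Sequence with length changed by exactly +1 or -1.
#' @export
inject_frameshift <- function(gene_seq, position,
                              kind = c("insertion", "deletion"),
                              seed = NULL) {
  kind <- match.arg(kind)
  n <- nchar(gene_seq)
  if (position < 0 || position >= n) {
    stop("position out of range [0, ", n - 1, "]")
  }
  if (kind == "insertion") {
    base <- with_seed(seed, sample(BASES, 1L))
    paste0(substr(gene_seq, 1L, position), base,
           substr(gene_seq, position + 1L, n))
  } else {
    paste0(substr(gene_seq, 1L, position),
           substr(gene_seq, position + 2L, n))
  }
}

# Random protein-coding sequence: ATG + exact-composition interior with
# stops repaired GC-neutrally + TAA. Composition control matters: these
# sequences are implanted into genomes whose %GC baseline the pipeline
# measures.
make_coding_seq <- function(n_codons, gc = 50, seed = NULL) {
  stopifnot(n_codons >= 3)
  interior <- repair_internal_stops(
    random_sequence(3L * (n_codons - 2L), gc, seed = seed),
    keep_terminal = FALSE)
  paste0("ATG", interior, "TAA")
}

# Replace internal stop codons by GC-preserving non-stop codons
# (TAA->TTA, TAG->TAC, TGA->TCA), leaving the terminal stop alone.
# Keeps a random sequence readable as one open frame without touching
# its composition.
repair_internal_stops <- function(seq, keep_terminal = TRUE) {
  n <- nchar(seq) - nchar(seq) %% 3
  codons <- substring(seq, seq(1, n, 3), seq(3, n, 3))
  internal <- seq_len(max(length(codons) - keep_terminal, 0L))
  swap <- c(TAA = "TTA", TAG = "TAC", TGA = "TCA")
  hit <- internal[codons[internal] %in% names(swap)]
  codons[hit] <- swap[codons[hit]]
  paste(codons, collapse = "")
}

#' Generate a synthetic reference cluster template
#'
#' Genes are single open reading frames (ATG ... TAA, internal stops
#' removed GC-neutrally) tiling the cluster left to right with short
#' spacers; gene strands are mixed. The intergenic spacers are drawn
#' with a compensating base count so the total cluster %GC hits `gc`
#' exactly (to 1-base rounding) — composition is the signal the %GC
#' screen measures, so it is controlled tightly.
#'
#' @param n_genes Number of genes.
#' @param gene_length Gene length (bp, multiple of 3).
#' @param spacer Intergenic spacer (bp).
#' @param gc Cluster %GC.
#' @param seed Integer seed.
#' @param name Cluster name.
#' @return A [cluster_definition()].
#' @export
make_cluster_template <- function(n_genes = 4, gene_length = 900,
                                  spacer = 80, gc = 40, seed = 1,
                                  name = "synthetic_cluster") {
  stopifnot(gene_length %% 3 == 0, gene_length >= 90, spacer >= 10)
  total <- n_genes * gene_length + (n_genes + 1L) * spacer
  target_gc_count <- round(total * gc / 100)
  strands <- with_seed(derive_seed(seed, "strands"),
                       sample(c("+", "-"), n_genes, replace = TRUE))
  count_gc <- function(s) {
    sum(strsplit(s, "")[[1]] %in% c("G", "C"))
  }
  gene_seqs <- vapply(seq_len(n_genes), function(i) {
    interior <- repair_internal_stops(
      random_sequence(gene_length - 6L, gc,
                      seed = derive_seed(seed, paste0("gene", i))),
      keep_terminal = FALSE)
    paste0("ATG", interior, "TAA")
  }, character(1))
  genes_gc <- sum(vapply(gene_seqs, count_gc, numeric(1)))
  # spacers absorb the rounding left by gene construction
  spacer_total <- (n_genes + 1L) * spacer
  spacer_gc_needed <- min(max(target_gc_count - genes_gc, 0L),
                          spacer_total)
  spacer_seq <- random_sequence(spacer_total,
                                100 * spacer_gc_needed / spacer_total,
                                seed = derive_seed(seed, "spacers"))
  sp_parts <- substring(spacer_seq,
                        (seq_len(n_genes + 1L) - 1L) * spacer + 1L,
                        seq_len(n_genes + 1L) * spacer)
  parts <- character(0)
  starts <- integer(n_genes)
  pos <- 0L
  for (i in seq_len(n_genes)) {
    parts <- c(parts, sp_parts[i])
    pos <- pos + spacer
    starts[i] <- pos
    g <- gene_seqs[i]
    if (strands[i] == "-") g <- revcomp(g)
    parts <- c(parts, g)
    pos <- pos + gene_length
  }
  parts <- c(parts, sp_parts[n_genes + 1L])
  seqn <- paste(parts, collapse = "")
  genes <- data.frame(
    gene = sprintf("%s_g%02d", name, seq_len(n_genes)),
    start = starts, end = starts + gene_length,
    strand = strands, stringsAsFactors = FALSE
  )
  cluster_definition(name, seqn, genes,
                     source_strain = "synthetic", accession = "synthetic")
}

#' Simulate a genus-structured species tree
#'
#' Each genus is a random binary subtree with uniform branch lengths in
#' `within_bl`; genus subtrees are joined by a (balanced) backbone whose
#' edges have length `between_bl`, giving clearly separated genus clades
#' like those seen for cpn60 across related enterobacterial genera.
#'
#' @param n_per_genus Integer vector, leaves per genus.
#' @param genus_names Genus labels (defaults "genusA", "genusB", ...).
#' @param within_bl Range (min, max) of within-genus branch lengths,
#'   expected substitutions/site.
#' @param between_bl Backbone branch length.
#' @param seed Integer seed.
#' @return List with `tree` (ape phylo, rooted, binary) and `genus_map`
#'   (named character vector leaf -> genus).
#' @export
simulate_species_tree <- function(n_per_genus = c(4, 4),
                                  genus_names = NULL,
                                  within_bl = c(0.02, 0.08),
                                  between_bl = 0.15, seed = 1) {
  k <- length(n_per_genus)
  if (is.null(genus_names)) {
    genus_names <- paste0("genus", LETTERS[seq_len(k)])
  }
  stopifnot(length(genus_names) == k, all(n_per_genus >= 1))
  sub_newick <- function(genus, n, s) {
    tips <- sprintf("%s_s%d", genus, seq_len(n))
    if (n == 1L) {
      return(paste0(tips, ":", format(mean(within_bl), scientific = FALSE)))
    }
    tr <- with_seed(s, ape::rtree(n, tip.label = tips, br = stats::runif,
                                  min = within_bl[1], max = within_bl[2]))
    sub(";$", "", ape::write.tree(tr))
  }
  parts <- vapply(seq_len(k), function(i) {
    sub_newick(genus_names[i], n_per_genus[i],
               derive_seed(seed, paste0("genus", i)))
  }, character(1))
  # balanced pairwise join of genus subtrees
  while (length(parts) > 1L) {
    joined <- character(0)
    i <- 1L
    while (i + 1L <= length(parts)) {
      joined <- c(joined, paste0("(", parts[i], ":", between_bl, ",",
                                 parts[i + 1L], ":", between_bl, ")"))
      i <- i + 2L
    }
    if (i == length(parts)) joined <- c(joined, parts[i])
    parts <- joined
  }
  tree <- ape::read.tree(text = paste0(parts, ";"))
  genus_map <- rep(genus_names, n_per_genus)
  names(genus_map) <- unlist(lapply(seq_len(k), function(i) {
    sprintf("%s_s%d", genus_names[i], seq_len(n_per_genus[i]))
  }))
  list(tree = tree, genus_map = genus_map[tree$tip.label])
}

#' Build a simulation configuration
#'
#' Bundles and validates every knob of the panel generator. Defaults
#' describe an enterobacterial host panel: ~54.6% GC backbone with a
#' cluster implanted 15 points below it, the typical anomaly regime for
#' horizontally acquired antibiotic BGCs.
#'
#' @param species_tree Rooted binary ape phylo with branch lengths
#'   (expected substitutions/site).
#' @param genus_map Named character vector leaf -> genus.
#' @param genome_length Host genome length (bp); must be at least 10x
#'   the cluster length.
#' @param host_gc Host backbone %GC.
#' @param cluster_gc_offset Signed offset (percentage points) of the
#'   cluster %GC relative to `host_gc`; only used when the template is
#'   generated internally.
#' @param cluster_template Optional [cluster_definition()]; by default a
#'   template is generated at `host_gc + cluster_gc_offset`.
#' @param carrier_lineages Leaves whose genomes carry the cluster by
#'   vertical descent (default: all).
#' @param hgt_events List of `c(donor, recipient)` leaf-name pairs; the
#'   recipient's cluster is copied from the donor's evolved copy (so its
#'   divergence is donor-derived), then mutated by `hgt_divergence`.
#' @param hgt_divergence Extra substitutions/site applied to a
#'   transferred cluster after the transfer.
#' @param frameshift_prob Probability that each cluster gene of each
#'   carrier receives one single-base frameshift.
#' @param clonal_lineages Leaves duplicated as near-identical clones.
#' @param clonal_copies Clone count per selected lineage.
#' @param clonal_substitutions Max substitutions separating a clone from
#'   its parent (drawn uniformly from 0..this).
#' @param flank_conservation Fraction of flank ORF slots shared between
#'   sister (cherry) lineages.
#' @param n_flank_orfs Flank ORF slots per side of the cluster.
#' @param mge_prob Probability a carrier's cluster has a 300-bp
#'   transposase remnant within 1 kb of its upstream edge.
#' @param marker_length Length (bp) of the vertically inherited
#'   cpn60-like barcode sequence.
#' @param seed Master seed; all stage streams are derived from it.
#' @return A validated `simulation_config` object.
#' @export
simulation_config <- function(species_tree, genus_map = NULL,
                              genome_length = 100000L, host_gc = 54.6,
                              cluster_gc_offset = -15,
                              cluster_template = NULL,
                              carrier_lineages = NULL,
                              hgt_events = list(),
                              hgt_divergence = 0.01,
                              frameshift_prob = 0,
                              clonal_lineages = character(0),
                              clonal_copies = 1L,
                              clonal_substitutions = 2L,
                              flank_conservation = 1.0,
                              n_flank_orfs = 4L,
                              mge_prob = 0,
                              marker_length = 1650L,
                              seed = 1L) {
  stopifnot(inherits(species_tree, "phylo"),
            host_gc >= 0, host_gc <= 100,
            frameshift_prob >= 0, frameshift_prob <= 1,
            mge_prob >= 0, mge_prob <= 1,
            flank_conservation >= 0, flank_conservation <= 1,
            hgt_divergence >= 0, hgt_divergence <= 0.75)
  leaves <- species_tree$tip.label
  if (anyDuplicated(leaves)) stop("duplicate leaf names in species tree")
  if (is.null(species_tree$edge.length)) {
    stop("species tree must have branch lengths")
  }
  if (is.null(genus_map)) {
    genus_map <- stats::setNames(rep("genusA", length(leaves)), leaves)
  }
  if (!all(leaves %in% names(genus_map))) {
    stop("genus_map must label every leaf")
  }
  if (is.null(cluster_template)) {
    cluster_template <- make_cluster_template(
      gc = host_gc + cluster_gc_offset,
      seed = derive_seed(seed, "template"))
  }
  if (genome_length < 10L * cluster_template$length) {
    stop("genome_length must be at least 10x the cluster length (",
         10L * cluster_template$length, " bp)")
  }
  if (is.null(carrier_lineages)) carrier_lineages <- leaves
  if (!all(carrier_lineages %in% leaves)) stop("unknown carrier lineage")
  for (ev in hgt_events) {
    if (length(ev) != 2L || !all(ev %in% leaves)) {
      stop("hgt_events must be (donor, recipient) leaf-name pairs")
    }
  }
  if (!all(clonal_lineages %in% leaves)) stop("unknown clonal lineage")
  structure(
    list(species_tree = species_tree, genus_map = genus_map[leaves],
         n_lineages = length(leaves), genome_length = as.integer(genome_length),
         host_gc = host_gc, cluster_gc_offset = cluster_gc_offset,
         cluster_template = cluster_template,
         carrier_lineages = carrier_lineages, hgt_events = hgt_events,
         hgt_divergence = hgt_divergence,
         frameshift_prob = frameshift_prob,
         clonal_lineages = clonal_lineages,
         clonal_copies = as.integer(clonal_copies),
         clonal_substitutions = as.integer(clonal_substitutions),
         flank_conservation = flank_conservation,
         n_flank_orfs = as.integer(n_flank_orfs),
         mge_prob = mge_prob, marker_length = as.integer(marker_length),
         seed = as.integer(seed)),
    class = "simulation_config"
  )
}

# Evolve a root sequence along the tree; returns a named list of leaf
# sequences. Branch substitution rate = branch length (expected
# substitutions/site, single hit per site per branch).
evolve_along_tree <- function(tree, root_seq, seed, label) {
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  node_seq <- vector("list", max(tree$edge))
  node_seq[[root]] <- root_seq
  # traverse edges parent-before-child (ape edge matrix is not guaranteed
  # ordered, so iterate until all assigned)
  edges <- tree$edge
  remaining <- seq_len(nrow(edges))
  while (length(remaining) > 0) {
    progressed <- FALSE
    for (i in remaining) {
      p <- edges[i, 1]; ch <- edges[i, 2]
      if (!is.null(node_seq[[p]]) && is.null(node_seq[[ch]])) {
        node_seq[[ch]] <- mutate_sequence(
          node_seq[[p]], rate = tree$edge.length[i],
          seed = derive_seed(seed, paste0(label, "/edge", i)))
        remaining <- setdiff(remaining, i)
        progressed <- TRUE
      }
    }
    if (!progressed) stop("species tree is not a rooted connected tree")
  }
  out <- node_seq[seq_len(n_tip)]
  names(out) <- tree$tip.label
  out
}

# Restore the reading integrity of an evolved gene: internal stops
# repaired GC-neutrally, start and terminal stop codons restored.
# Models purifying selection on a functional gene; pseudogenization
# enters only through explicitly injected frameshifts.
repair_orf <- function(seq) {
  seq <- repair_internal_stops(seq, keep_terminal = TRUE)
  if (!substr(seq, 1L, 3L) %in% START_CODONS) {
    seq <- paste0("ATG", substr(seq, 4L, nchar(seq)))
  }
  last <- substr(seq, nchar(seq) - 2L, nchar(seq))
  if (!last %in% STOP_CODONS) {
    seq <- paste0(substr(seq, 1L, nchar(seq) - 3L), "TAA")
  }
  seq
}

repair_cluster_genes <- function(cl, genes) {
  for (gi in seq_len(nrow(genes))) {
    g <- genes[gi, ]
    sub <- substr(cl, g$start + 1L, g$end)
    if (g$strand == "-") sub <- revcomp(sub)
    sub <- repair_orf(sub)
    if (g$strand == "-") sub <- revcomp(sub)
    cl <- paste0(substr(cl, 1L, g$start), sub,
                 substr(cl, g$end + 1L, nchar(cl)))
  }
  cl
}

# The fixed synthetic transposase remnant: one 300-bp coding marker
# shared by every simulated panel, so flag_mobile_elements can carry a
# stable reference protein.
mge_marker_seq <- function() {
  make_coding_seq(100L, gc = 50, seed = 424243L)
}

#' Reference protein set for mobile-element flagging
#'
#' @return Named character vector of MGE reference proteins (currently
#'   the translated synthetic transposase remnant used by the panel
#'   generator).
#' @export
mge_reference_proteins <- function() {
  p <- translate_dna(mge_marker_seq())
  c(synthetic_transposase = sub("\\*$", "", p))
}

# Decide, per carrier leaf, which flank ORF slots carry the ancestral ORF.
# Cherries (sister leaf pairs, both carriers) share each slot with
# probability `conservation`; in a non-shared slot exactly one of the two
# carries the ORF, which makes the expected sister Jaccard index equal
# the conservation parameter. Other carriers keep each slot with the same
# marginal probability.
plan_flank_slots <- function(tree, carriers, n_slots, conservation, seed) {
  with_seed(seed, {
    plan <- stats::setNames(
      rep(list(rep(TRUE, n_slots)), length(carriers)), carriers)
    handled <- character(0)
    # find cherries
    n_tip <- length(tree$tip.label)
    tab <- table(tree$edge[, 1][tree$edge[, 2] <= n_tip])
    cherry_parents <- as.integer(names(tab)[tab == 2])
    for (p in cherry_parents) {
      kids <- tree$tip.label[tree$edge[tree$edge[, 1] == p, 2]]
      if (!all(kids %in% carriers)) next
      for (s in seq_len(n_slots)) {
        if (stats::runif(1) < conservation) {
          plan[[kids[1]]][s] <- TRUE; plan[[kids[2]]][s] <- TRUE
        } else {
          keep <- sample(kids, 1L)
          plan[[keep]][s] <- TRUE
          plan[[setdiff(kids, keep)]][s] <- FALSE
        }
      }
      handled <- c(handled, kids)
    }
    for (leaf in setdiff(carriers, handled)) {
      plan[[leaf]] <- stats::runif(n_slots) < conservation
    }
    plan
  })
}

#' Simulate a strain panel with ground truth
#'
#' Evolves a host genome, a cpn60-like marker, and (for carriers) the
#' cluster along the species tree; implants each carrier's cluster copy
#' with optional transposase remnant and flank ORF cassettes; applies
#' horizontal transfers (recipient receives the donor's evolved copy),
#' per-gene frameshifts, and clonal duplicates; and records a complete
#' per-strain truth table. All randomness derives from `config$seed`, so
#' a fixed config reproduces the panel byte for byte.
#'
#' @param config A [simulation_config()].
#' @param out_dir Optional directory; when given, genomes (FASTA),
#'   markers (FASTA), truth (GFF3 + JSON), taxa (TSV), the species tree
#'   (newick) and the cluster template (JSON) are written there.
#' @return A `bgc_panel`: list with `genomes` (named list of
#'   [genome_record()]), `markers` (named character vector),
#'   `truth` (data.frame, one row per strain), `tree`, `genus_map`,
#'   `template`, `config`.
#' @export
simulate_panel <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  seed <- config$seed
  tree <- config$species_tree
  leaves <- tree$tip.label
  tmpl <- config$cluster_template
  L <- config$genome_length

  root_genome <- random_sequence(L, config$host_gc,
                                 seed = derive_seed(seed, "root_genome"))
  root_marker <- random_sequence(config$marker_length, config$host_gc,
                                 seed = derive_seed(seed, "root_marker"))
  genomes_raw <- evolve_along_tree(tree, root_genome, seed, "genome")
  markers <- unlist(evolve_along_tree(tree, root_marker, seed, "marker"))
  clusters_raw <- evolve_along_tree(tree, tmpl$sequence, seed, "cluster")

  # horizontal transfers: recipient's copy derives from the donor's
  for (ev in config$hgt_events) {
    donor <- ev[1]; recip <- ev[2]
    clusters_raw[[recip]] <- mutate_sequence(
      clusters_raw[[donor]], rate = config$hgt_divergence,
      seed = derive_seed(seed, paste0("hgt/", donor, "/", recip)))
  }
  recipients <- vapply(config$hgt_events, `[`, character(1), 2L)
  donors <- stats::setNames(
    vapply(config$hgt_events, `[`, character(1), 1L), recipients)
  carriers <- union(config$carrier_lineages, recipients)

  # flank ORF machinery (ancestral ORFs evolve with root-to-tip distance)
  n_slots <- config$n_flank_orfs
  flank_len_per_slot <- 1050L  # 900-bp gene-sized ORF + 150-bp spacer
  slot_orfs <- lapply(seq_len(2L * n_slots), function(s) {
    evolve_along_tree(tree, make_coding_seq(
      300L, gc = config$host_gc,
      seed = derive_seed(seed, paste0("flank_orf", s))),
      seed, paste0("flank_orf", s))
  })
  # spacers carry a small compensating GC count: each coding ORF's fixed
  # ATG/TAA termini sit below the host composition, and the cassette as
  # a whole must not perturb the replicon baseline
  termini_deficit <- 6 * config$host_gc / 100 - 1
  spacer_gc <- 100 * (round(150 * config$host_gc / 100) +
                        round(termini_deficit)) / 150
  spacer_gc <- min(max(spacer_gc, 0), 100)
  slot_spacers <- lapply(seq_len(2L * n_slots), function(s) {
    evolve_along_tree(tree, random_sequence(
      150L, spacer_gc,
      seed = derive_seed(seed, paste0("flank_spacer", s))),
      seed, paste0("flank_spacer", s))
  })
  slot_plan_up <- plan_flank_slots(tree, carriers, n_slots,
                                   config$flank_conservation,
                                   derive_seed(seed, "slots_up"))
  slot_plan_dn <- plan_flank_slots(tree, carriers, n_slots,
                                   config$flank_conservation,
                                   derive_seed(seed, "slots_dn"))

  # vertical carriers share one insertion site; each HGT event opens a new
  # site in its recipient
  pos_vert <- max(6000L + n_slots * flank_len_per_slot,
                  min(L - 6000L - n_slots * flank_len_per_slot,
                      as.integer(round(L / 2))))
  mge_seq <- mge_marker_seq()

  genomes <- list()
  truth_rows <- list()
  gene_feats <- list()

  build_cassette <- function(leaf, plan, side) {
    # fixed total length so flank geometry is identical across strains
    parts <- character(0)
    for (s in seq_len(n_slots)) {
      slot_id <- if (side == "up") s else n_slots + s
      spacer <- slot_spacers[[slot_id]][[leaf]]
      if (plan[s]) {
        # stop/start codons degraded by simulation are repaired:
        # conserved flank genes stay open frames, emulating purifying
        # selection
        orf <- repair_orf(slot_orfs[[slot_id]][[leaf]])
      } else {
        orf <- random_sequence(900L, config$host_gc,
          seed = derive_seed(seed, paste0("norf/", leaf, "/", side, s)))
      }
      parts <- c(parts, spacer, orf)
    }
    paste(parts, collapse = "")
  }

  for (leaf in leaves) {
    g <- genomes_raw[[leaf]]
    present <- leaf %in% carriers
    row <- list(strain = leaf, genus = unname(config$genus_map[[leaf]]),
                cluster_present = present, contig = "contig1",
                start = NA_integer_, end = NA_integer_,
                strand = NA_character_, acquisition = NA_character_,
                frameshifts = I(list(data.frame())),
                cluster_gc = NA_real_, replicon_gc = NA_real_,
                mge_adjacent = FALSE, clonal_of = NA_character_)
    if (present) {
      is_hgt <- leaf %in% recipients
      cl <- repair_cluster_genes(clusters_raw[[leaf]], tmpl$genes)
      # per-gene frameshifts (coordinates shift as indels accumulate)
      fs <- data.frame(gene = character(0), position = integer(0),
                       kind = character(0))
      if (config$frameshift_prob > 0) {
        shift <- 0L
        for (gi in seq_len(nrow(tmpl$genes))) {
          grow <- tmpl$genes[gi, ]
          u <- with_seed(derive_seed(seed, paste0("fs?/", leaf, "/", gi)),
                         stats::runif(1))
          if (u < config$frameshift_prob) {
            sd2 <- derive_seed(seed, paste0("fs/", leaf, "/", gi))
            loc <- with_seed(sd2, sample.int(grow$end - grow$start, 1L) - 1L)
            kind <- with_seed(derive_seed(seed, paste0("fsk/", leaf, "/", gi)),
                              sample(c("insertion", "deletion"), 1L))
            pos_in_cl <- grow$start + loc + shift
            cl <- inject_frameshift(cl, pos_in_cl, kind,
                                    seed = derive_seed(seed,
                                      paste0("fsb/", leaf, "/", gi)))
            shift <- shift + if (kind == "insertion") 1L else -1L
            fs <- rbind(fs, data.frame(gene = grow$gene, position = loc,
                                       kind = kind))
          }
        }
      }
      pos <- if (is_hgt) {
        max(6000L + n_slots * flank_len_per_slot,
            as.integer(round(L * 0.3)))
      } else pos_vert
      mge <- with_seed(derive_seed(seed, paste0("mge?/", leaf)),
                       stats::runif(1)) < config$mge_prob
      up_cas <- build_cassette(leaf, slot_plan_up[[leaf]], "up")
      dn_cas <- build_cassette(leaf, slot_plan_dn[[leaf]], "dn")
      # cassettes are inserted, not overwritten: the host backbone keeps
      # its exact composition, so the %GC baseline stays clean
      pre <- substr(g, 1L, pos)
      post <- substr(g, pos + 1L, nchar(g))
      mid_mge <- if (mge) {
        gap <- with_seed(derive_seed(seed, paste0("mgegap/", leaf)),
                         sample(0:500, 1L))
        paste0(mge_seq, random_sequence(gap, config$host_gc,
          seed = derive_seed(seed, paste0("mgegapseq/", leaf))))
      } else ""
      contig <- paste0(pre, up_cas, mid_mge, cl, dn_cas, post)
      cl_start <- nchar(pre) + nchar(up_cas) + nchar(mid_mge)
      cl_end <- cl_start + nchar(cl)
      row$start <- cl_start; row$end <- cl_end; row$strand <- "+"
      row$acquisition <- if (is_hgt) paste0("hgt:", donors[[leaf]])
                         else "vertical"
      row$frameshifts <- I(list(fs))
      row$cluster_gc <- round(gc_content(cl), 4)
      row$replicon_gc <- round(gc_content(contig), 4)
      row$mge_adjacent <- mge
      genomes[[leaf]] <- genome_record(leaf, c(contig1 = contig))
      gene_feats[[leaf]] <- data.frame(
        seqid = "contig1", source = "bgcsurvey_sim",
        type = c("gene_cluster", rep("gene", nrow(tmpl$genes))),
        start = c(cl_start, cl_start + tmpl$genes$start),
        end = c(cl_end, cl_start + tmpl$genes$end),
        strand = c(row$strand, tmpl$genes$strand),
        attributes = c(
          paste0("ID=", tmpl$name, "_", leaf, ";product=", tmpl$name,
                 ";acquisition=", row$acquisition),
          paste0("ID=", tmpl$genes$gene, "_", leaf, ";Parent=",
                 tmpl$name, "_", leaf)),
        strain = leaf, stringsAsFactors = FALSE)
      if (mge) {
        mge_start <- nchar(pre) + nchar(up_cas)
        gene_feats[[leaf]] <- rbind(gene_feats[[leaf]], data.frame(
          seqid = "contig1", source = "bgcsurvey_sim",
          type = "mobile_element", start = mge_start,
          end = mge_start + nchar(mge_seq), strand = "+",
          attributes = paste0("ID=mge_", leaf,
                              ";product=transposase remnant"),
          strain = leaf, stringsAsFactors = FALSE))
      }
    } else {
      row$replicon_gc <- round(gc_content(g), 4)
      genomes[[leaf]] <- genome_record(leaf, c(contig1 = g))
    }
    truth_rows[[leaf]] <- row
  }

  # clonal duplicates
  for (leaf in config$clonal_lineages) {
    for (ci in seq_len(config$clonal_copies)) {
      id <- paste0(leaf, "_clone", ci)
      nsub <- with_seed(derive_seed(seed, paste0("clonal_n/", id)),
                        sample(0:config$clonal_substitutions, 1L))
      src <- genomes[[leaf]]$contigs[["contig1"]]
      contig <- if (nsub == 0) src else with_seed(
        derive_seed(seed, paste0("clonal/", id)), {
          chars <- strsplit(src, "")[[1]]
          at <- sample.int(length(chars), nsub)
          idx <- match(chars[at], BASES)
          ok <- !is.na(idx)
          chars[at[ok]] <- BASES[((idx[ok] - 1L +
            sample.int(3L, sum(ok), replace = TRUE)) %% 4L) + 1L]
          paste(chars, collapse = "")
        })
      genomes[[id]] <- genome_record(id, c(contig1 = contig))
      markers[[id]] <- markers[[leaf]]
      row <- truth_rows[[leaf]]
      row$strain <- id
      row$clonal_of <- leaf
      if (row$cluster_present) {
        row$cluster_gc <- round(gc_content(
          substr(contig, row$start + 1L, row$end)), 4)
        row$replicon_gc <- round(gc_content(contig), 4)
      }
      truth_rows[[id]] <- row
      if (!is.null(gene_feats[[leaf]])) {
        gf <- gene_feats[[leaf]]
        gf$strain <- id
        gf$attributes <- gsub(paste0("_", leaf), paste0("_", id),
                              gf$attributes, fixed = TRUE)
        gene_feats[[id]] <- gf
      }
    }
  }

  truth <- do.call(rbind, lapply(truth_rows, function(r) {
    data.frame(r[setdiff(names(r), "frameshifts")],
               stringsAsFactors = FALSE)
  }))
  truth$frameshifts <- I(lapply(truth_rows, `[[`, "frameshifts"))
  truth$frameshifts <- I(lapply(truth$frameshifts, `[[`, 1L))
  rownames(truth) <- NULL

  panel <- structure(
    list(genomes = genomes, markers = unlist(markers), truth = truth,
         tree = tree, genus_map = config$genus_map, template = tmpl,
         gene_feats = gene_feats, config = config),
    class = "bgc_panel")
  if (!is.null(out_dir)) write_panel(panel, out_dir)
  panel
}

#' @export
print.bgc_panel <- function(x, ...) {
  cat("<bgc_panel>", length(x$genomes), "genomes |",
      sum(x$truth$cluster_present), "carriers | cluster",
      x$template$name, paste0("(", x$template$length, " bp)\n"))
  invisible(x)
}

#' Write a simulated panel to disk
#'
#' @param panel A `bgc_panel` from [simulate_panel()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_panel <- function(panel, dir) {
  dir.create(file.path(dir, "genomes"), recursive = TRUE,
             showWarnings = FALSE)
  for (id in names(panel$genomes)) {
    g <- panel$genomes[[id]]
    write_fasta(stats::setNames(g$contigs,
                                paste0(id, "|", names(g$contigs))),
                file.path(dir, "genomes", paste0(id, ".fasta")))
  }
  write_fasta(panel$markers, file.path(dir, "markers.fasta"))
  write_newick(panel$tree, file.path(dir, "species_tree.nwk"))
  write_cluster_definition(panel$template,
                           file.path(dir, "cluster_template.json"))
  feats <- do.call(rbind, panel$gene_feats)
  if (is.null(feats)) {
    feats <- data.frame(seqid = character(0), source = character(0),
                        type = character(0), start = integer(0),
                        end = integer(0), strand = character(0),
                        attributes = character(0))
  } else {
    feats$seqid <- paste0(feats$strain, "|", feats$seqid)
    feats$strain <- NULL
  }
  write_gff3(feats, file.path(dir, "truth.gff3"))
  truth <- panel$truth
  tr <- truth
  tr$frameshifts <- vapply(truth$frameshifts, function(f) {
    jsonlite::toJSON(f, auto_unbox = FALSE)
  }, character(1))
  jsonlite::write_json(tr, file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  utils::write.table(
    data.frame(strain = names(panel$genomes),
               genus = vapply(names(panel$genomes), function(s) {
                 base <- sub("_clone[0-9]+$", "", s)
                 unname(panel$genus_map[[base]])
               }, character(1))),
    file.path(dir, "taxa.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  invisible(dir)
}
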