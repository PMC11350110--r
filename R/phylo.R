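# Tree building and congruence: cluster trees (whole-cluster nucleotide
# alignments) against cpn60-marker species trees. Distance methods
# (neighbor joining over p/JC69/K2P distances) are used throughout: they
# are deterministic, exactly invert additive distance matrices, and are
# sufficient for the congruence logic; likelihood methods with model
# selection are deliberately out of scope.

#' Multiple sequence alignment
#'
#' Progressive alignment via the MAFFT command-line tool (FFT-NS-2:
#' k-mer distance guide tree, two progressive passes; deterministic,
#' single thread). All input residues are preserved in the output
#' columns.
#'
#' @param seqs Named character vector of >= 2 homologous sequences
#'   (DNA or protein).
#' @return Named character vector of aligned rows, equal lengths.
#' @export
build_msa <- function(seqs) {
  if (length(seqs) < 2) stop("need >= 2 sequences to align")
  stopifnot(!is.null(names(seqs)), !anyDuplicated(names(seqs)))
  if (length(unique(nchar(seqs))) == 1 &&
      length(unique(seqs)) == 1) {
    return(seqs)  # identical sequences: alignment is the identity
  }
  if (length(seqs) == 2) {
    # two sequences: exact DP alignment, no progressive heuristic needed
    al <- align_pair(seqs[[1]], seqs[[2]], mode = "global")
    return(stats::setNames(al$aligned, names(seqs)))
  }
  mafft <- Sys.which("mafft")
  if (mafft == "") stop("mafft not found on PATH")
  tin <- tempfile(fileext = ".fasta")
  on.exit(unlink(tin))
  # guard ids against whitespace mangling
  ids <- names(seqs)
  write_fasta(stats::setNames(unname(seqs),
                              sprintf("s%06d", seq_along(seqs))), tin)
  out <- system2(mafft, c("--retree", "2", "--maxiterate", "0",
                          "--thread", "1", "--quiet", tin),
                 stdout = TRUE, stderr = FALSE)
  tout <- tempfile(fileext = ".fasta")
  on.exit(unlink(tout), add = TRUE)
  writeLines(out, tout)
  aln <- Biostrings::readBStringSet(tout)
  aln <- toupper(as.character(aln))
  ord <- as.integer(sub("^s", "", names(aln)))
  res <- stats::setNames(unname(aln[order(ord)]), ids)
  if (length(unique(nchar(res))) != 1) stop("alignment failed")
  res
}

#' Pairwise evolutionary distances from an alignment
#'
#' Gap and N columns are removed pairwise (pairwise deletion). Models:
#' `p` (raw proportion of differing compared columns), `jc69`
#' (-3/4 log(1 - 4p/3)), `k2p` (Kimura two-parameter from the
#' transition/transversion split). Saturated pairs (p >= 0.75 for
#' JC69, or an undefined K2P log) are capped at 5 substitutions/site
#' and recorded in the `saturated` attribute.
#'
#' @param msa Named character vector of aligned sequences.
#' @param model "p", "jc69" or "k2p".
#' @return Symmetric distance matrix with a logical `saturated`
#'   attribute matrix.
#' @export
pairwise_distance <- function(msa, model = c("jc69", "p", "k2p")) {
  model <- match.arg(model)
  stopifnot(length(msa) >= 2, length(unique(nchar(msa))) == 1)
  n <- length(msa)
  labs <- names(msa)
  rows <- lapply(msa, function(s) strsplit(s, "")[[1]])
  valid <- lapply(rows, function(r) r %in% BASES)
  d <- matrix(0, n, n, dimnames = list(labs, labs))
  sat <- matrix(FALSE, n, n, dimnames = list(labs, labs))
  transitions <- list(A = "G", G = "A", C = "T", T = "C")
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- valid[[i]] & valid[[j]]
      m <- sum(ok)
      if (m == 0) stop("no comparable columns between ", labs[i],
                       " and ", labs[j])
      a <- rows[[i]][ok]; b <- rows[[j]][ok]
      diffs <- a != b
      p <- sum(diffs) / m
      if (model == "p") {
        dist_ij <- p
      } else if (model == "jc69") {
        if (p >= 0.75) {
          dist_ij <- 5; sat[i, j] <- sat[j, i] <- TRUE
        } else {
          dist_ij <- -0.75 * log(1 - 4 * p / 3)
        }
      } else {
        is_ts <- diffs & unlist(transitions[a]) == b
        P <- sum(is_ts) / m
        Q <- p - P
        w1 <- 1 - 2 * P - Q
        w2 <- 1 - 2 * Q
        if (w1 <= 0 || w2 <= 0) {
          dist_ij <- 5; sat[i, j] <- sat[j, i] <- TRUE
        } else {
          dist_ij <- -0.5 * log(w1 * sqrt(w2))
        }
      }
      d[i, j] <- d[j, i] <- dist_ij
    }
  }
  attr(d, "saturated") <- sat
  d
}

#' Neighbor-joining tree
#'
#' Standard neighbor joining; on an additive matrix the result
#' reproduces the generating topology and branch lengths exactly.
#'
#' @param d Symmetric distance matrix (>= 3 taxa) with taxon labels.
#' @return Unrooted `phylo` tree (no supports).
#' @export
nj_tree <- function(d) {
  if (nrow(d) < 3) stop("neighbor joining needs >= 3 taxa")
  ape::nj(as.matrix(d))
}

#' Bootstrap support for an NJ tree
#'
#' Columns are resampled with replacement; each replicate alignment is
#' taken through the same distance + NJ route and support is the
#' percentage of replicates containing each original internal edge.
#' A single seed drives one RNG stream: replicate r consumes draw block
#' r, so supports are reproducible.
#'
#' @param msa Named character vector of aligned sequences.
#' @param n_reps Number of replicates.
#' @param seed Integer seed.
#' @param model Distance model for [pairwise_distance()].
#' @return The NJ tree with `node.label` set to supports (0-100; root
#'   node label NA) and attributes `support` and `degenerate`.
#' @export
bootstrap_support <- function(msa, n_reps = 1000L, seed = 1L,
                              model = "jc69") {
  stopifnot(n_reps >= 1)
  base_d <- pairwise_distance(msa, model)
  degenerate <- all(base_d == 0)
  tree <- nj_tree(base_d)
  mat <- do.call(rbind, strsplit(msa, ""))
  rownames(mat) <- names(msa)
  ncol_aln <- ncol(mat)
  boot_trees <- with_seed(seed, {
    lapply(seq_len(n_reps), function(r) {
      cols <- sample.int(ncol_aln, ncol_aln, replace = TRUE)
      sub <- apply(mat[, cols, drop = FALSE], 1, paste, collapse = "")
      nj_tree(pairwise_distance(sub, model))
    })
  })
  counts <- ape::prop.clades(tree, boot_trees, rooted = FALSE)
  support <- round(100 * counts / n_reps, 1)
  tree$node.label <- support
  attr(tree, "support") <- support
  attr(tree, "degenerate") <- degenerate
  tree
}

#' Robinson-Foulds distance
#'
#' Symmetric-difference count of non-trivial bipartitions between two
#' unrooted trees on the same leaf set; 0 iff the unrooted topologies
#' are identical.
#'
#' @param t1,t2 `phylo` trees.
#' @param prune If TRUE, prune both trees to their shared leaf set
#'   instead of rejecting unequal leaf sets.
#' @return Integer RF distance.
#' @export
rf_distance <- function(t1, t2, prune = FALSE) {
  l1 <- t1$tip.label; l2 <- t2$tip.label
  if (!setequal(l1, l2)) {
    if (!prune) stop("trees have different leaf sets ",
                     "(use prune = TRUE to restrict to shared leaves)")
    shared <- intersect(l1, l2)
    if (length(shared) < 3) stop("fewer than 3 shared leaves")
    t1 <- ape::keep.tip(t1, shared)
    t2 <- ape::keep.tip(t2, shared)
  }
  as.integer(phangorn::RF.dist(ape::unroot(t1), ape::unroot(t2),
                               check.labels = TRUE))
}

is_genus_monophyletic <- function(tree, tips) {
  if (length(tips) <= 1) return(TRUE)
  if (length(tips) == length(tree$tip.label)) return(TRUE)
  ape::is.monophyletic(tree, tips)
}

#' Congruence report between a cluster tree and a species tree
#'
#' Quantifies the visual tree-versus-tree comparison used to screen for
#' horizontal transfer: congruence (low RF, genus monophyly in both
#' trees) indicates vertical transmission; a leaf that must be removed
#' before the genus-level groupings agree is a transfer candidate.
#' Displaced leaves are found greedily: repeatedly drop the leaf whose
#' removal most reduces the number of non-monophyletic (genus, tree)
#' pairs, breaking ties by RF reduction then leaf name.
#'
#' @param cluster_tree,species_tree `phylo` trees; pruned to their
#'   shared leaf set.
#' @param genus_map Named character vector leaf -> genus.
#' @return A `congruence_report`: list with `rf`, `max_rf`,
#'   `normalized_rf`, `n_shared`, `monophyly` (data.frame: genus,
#'   cluster_tree, species_tree), `displaced` (character vector).
#' @export
congruence_report <- function(cluster_tree, species_tree, genus_map) {
  shared <- intersect(cluster_tree$tip.label, species_tree$tip.label)
  if (length(shared) < 4) stop("need >= 4 shared leaves")
  ct <- ape::unroot(ape::keep.tip(cluster_tree, shared))
  st <- ape::unroot(ape::keep.tip(species_tree, shared))
  stopifnot(all(shared %in% names(genus_map)))
  gm <- genus_map[shared]

  rf <- rf_distance(ct, st)
  n <- length(shared)
  max_rf <- 2L * (n - 3L)
  nrf <- if (max_rf > 0) rf / max_rf else 0

  mono_tbl <- function(t1, t2, leaves) {
    genera <- sort(unique(gm[leaves]))
    data.frame(
      genus = genera,
      cluster_tree = vapply(genera, function(g) {
        is_genus_monophyletic(t1, leaves[gm[leaves] == g])
      }, logical(1)),
      species_tree = vapply(genera, function(g) {
        is_genus_monophyletic(t2, leaves[gm[leaves] == g])
      }, logical(1)),
      row.names = NULL, stringsAsFactors = FALSE)
  }
  objective <- function(t1, t2, leaves) {
    m <- mono_tbl(t1, t2, leaves)
    sum(!m$cluster_tree) + sum(!m$species_tree)
  }

  monophyly <- mono_tbl(ct, st, shared)
  displaced <- character(0)
  cur_ct <- ct; cur_st <- st; cur_leaves <- shared
  while (objective(cur_ct, cur_st, cur_leaves) > 0 &&
         length(cur_leaves) > 4) {
    best <- NULL
    cur_obj <- objective(cur_ct, cur_st, cur_leaves)
    cur_rf <- rf_distance(cur_ct, cur_st)
    for (leaf in sort(cur_leaves)) {
      t1 <- ape::keep.tip(cur_ct, setdiff(cur_leaves, leaf))
      t2 <- ape::keep.tip(cur_st, setdiff(cur_leaves, leaf))
      obj <- objective(t1, t2, setdiff(cur_leaves, leaf))
      rfd <- rf_distance(t1, t2)
      cand <- list(leaf = leaf, obj = obj, rf = rfd, t1 = t1, t2 = t2)
      if (is.null(best) || obj < best$obj ||
          (obj == best$obj && rfd < best$rf)) {
        best <- cand
      }
    }
    if (best$obj >= cur_obj && best$rf >= cur_rf) break  # no progress
    displaced <- c(displaced, best$leaf)
    cur_leaves <- setdiff(cur_leaves, best$leaf)
    cur_ct <- best$t1; cur_st <- best$t2
  }

  structure(
    list(rf = rf, max_rf = max_rf, normalized_rf = nrf,
         n_shared = n, monophyly = monophyly, displaced = displaced),
    class = "congruence_report")
}

#' @export
print.congruence_report <- function(x, ...) {
  cat(sprintf(
    "<congruence_report> RF %d/%d (normalized %.3f), %d shared leaves\n",
    x$rf, x$max_rf, x$normalized_rf, x$n_shared))
  bad <- x$monophyly$genus[!(x$monophyly$cluster_tree &
                               x$monophyly$species_tree)]
  if (length(bad)) cat("  non-monophyletic:", paste(bad, collapse = ", "),
                       "\n")
  if (length(x$displaced)) cat("  displaced:",
                               paste(x$displaced, collapse = ", "), "\n")
  invisible(x)
}
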