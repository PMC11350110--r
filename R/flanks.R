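# Flanking-region profiling: the 5 kb on either side of a cluster carries
# the evidence for how it travels — conserved host ORFs indicate vertical
# descent, transposase remnants and non-homologous flanks indicate
# mobility, and runs of adjacent ORFs matching one reference protein
# betray frameshift-interrupted genes.

START_CODONS <- c("ATG", "GTG", "TTG")

#' Translate DNA with the bacterial genetic code (table 11)
#'
#' @param seq Nucleotide sequence; trailing partial codon is dropped.
#' @return Amino-acid string; stops as `*`, ambiguous codons as `X`.
#' @export
translate_dna <- function(seq) {
  n <- nchar(seq) - nchar(seq) %% 3
  if (n < 3) return("")
  as.character(Biostrings::translate(
    Biostrings::DNAString(substr(seq, 1, n)),
    genetic.code = Biostrings::getGeneticCode("11"),
    if.fuzzy.codon = "solve", no.init.codon = TRUE))
}

#' Predict ORFs on both strands
#'
#' Stop-to-stop scan in all six frames: within each inter-stop segment
#' the first ATG/GTG/TTG defines the ORF, which runs to the closing stop
#' (included in the span). Segments that run off the contig edge are
#' reported with `edge = TRUE`. This longest-ORF heuristic stands in for
#' trained gene finders; it affects ORF counts, not downstream logic.
#'
#' @param seq Nucleotide sequence.
#' @param min_length Minimum ORF length in nt, stop codon included
#'   (default 150).
#' @param contig Contig id recorded in the output.
#' @return data.frame: `orf_id`, `contig`, `start`, `end` (0-based
#'   half-open, forward-strand coordinates), `strand`, `length`,
#'   `edge`, `protein` (stop stripped), ordered by `start`.
#' @export
predict_orfs <- function(seq, min_length = 150L, contig = "contig1") {
  n <- nchar(seq)
  out <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") toupper(seq) else revcomp(seq)
    for (frame in 0:2) {
      n_cod <- (n - frame) %/% 3
      if (n_cod < 2) next
      starts_nt <- frame + 3L * (seq_len(n_cod) - 1L)
      codons <- substring(s, starts_nt + 1L, starts_nt + 3L)
      is_stop <- codons %in% STOP_CODONS
      prev <- 1L
      for (b in c(which(is_stop), n_cod + 1L)) {
        if (prev > b - 1L) {
          prev <- b + 1L
          next
        }
        seg <- prev:(b - 1L)
        prev <- b + 1L
        at_edge <- b > n_cod
        starts_in_seg <- seg[codons[seg] %in% START_CODONS]
        if (length(starts_in_seg) == 0) next
        first <- starts_in_seg[1]
        last_cod <- if (at_edge) n_cod else b
        len <- (last_cod - first + 1L) * 3L
        if (len < min_length) next
        nt_start <- starts_nt[first]
        nt_end <- nt_start + len
        if (strand == "-") {
          tmp <- n - nt_end
          nt_end <- n - nt_start
          nt_start <- tmp
        }
        orf_nt <- substring(s, starts_nt[first] + 1L,
                            starts_nt[first] + len)
        prot <- sub("\\*$", "", translate_dna(orf_nt))
        out[[length(out) + 1L]] <- data.frame(
          contig = contig, start = nt_start, end = nt_end,
          strand = strand, length = len, edge = at_edge, protein = prot,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(orf_id = character(0), contig = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), length = integer(0),
                      edge = logical(0), protein = character(0)))
  }
  orfs <- do.call(rbind, out)
  orfs <- orfs[order(orfs$start, orfs$end, orfs$strand), , drop = FALSE]
  orfs <- cbind(orf_id = sprintf("orf%03d", seq_len(nrow(orfs))), orfs,
                stringsAsFactors = FALSE)
  rownames(orfs) <- NULL
  orfs
}

#' Extract the flanking regions of a cluster
#'
#' Orientation is normalized to the cluster template: for a cluster on
#' the minus strand the flanks are swapped and reverse-complemented, so
#' "upstream" always precedes the cluster in template orientation.
#' Flanks truncated by a contig edge are returned shorter, with the
#' truncation recorded.
#'
#' @param genome A [genome_record()].
#' @param contig Contig carrying the cluster.
#' @param start,end Cluster span, 0-based half-open.
#' @param strand Cluster strand ("+"/"-").
#' @param length Flank length in bp (default 5000).
#' @return List of `upstream` and `downstream`, each with `seq`,
#'   `truncated`, `span` (forward-strand contig coordinates).
#' @export
extract_flanks <- function(genome, contig, start, end, strand = "+",
                           length = 5000L) {
  contig_seq <- genome$contigs[[contig]]
  if (is.null(contig_seq)) stop("unknown contig: ", contig)
  clen <- nchar(contig_seq)
  stopifnot(start >= 0, end <= clen, start < end)
  left_span <- c(max(0L, start - length), start)
  right_span <- c(end, min(clen, end + length))
  left <- list(seq = substr(contig_seq, left_span[1] + 1L, left_span[2]),
               truncated = (start - length) < 0, span = left_span)
  right <- list(seq = substr(contig_seq, right_span[1] + 1L,
                             right_span[2]),
                truncated = (end + length) > clen, span = right_span)
  if (strand == "+") {
    list(upstream = left, downstream = right)
  } else {
    list(upstream = list(seq = revcomp(right$seq),
                         truncated = right$truncated, span = right$span),
         downstream = list(seq = revcomp(left$seq),
                           truncated = left$truncated, span = left$span))
  }
}

#' Group proteins into homolog groups by single linkage
#'
#' All-versus-all global alignment; an edge links two proteins whose
#' percent identity (matches over aligned columns, end gaps excluded)
#' reaches `min_identity`. Connected components are the homolog groups.
#' Group ids are deterministic: each group is named after its
#' lexicographically smallest member.
#'
#' @param proteins Named character vector of amino-acid sequences.
#' @param min_identity Identity cutoff in percent (default 30, the
#'   conventional homology floor for cluster-comparison figures).
#' @return data.frame: `member`, `group`, `representative` (the group's
#'   representative protein sequence).
#' @export
group_homologs <- function(proteins, min_identity = 30) {
  stopifnot(length(proteins) >= 1, !is.null(names(proteins)),
            !anyDuplicated(names(proteins)))
  nm <- sort(names(proteins))
  proteins <- proteins[nm]
  n <- length(proteins)
  edges <- list()
  if (n > 1) {
    # batch the DP: align all earlier proteins against subject j at once
    for (j in 2:n) {
      idx <- 1:(j - 1)
      ident_pre <- vapply(idx, function(i) {
        identical(proteins[[i]], proteins[[j]])
      }, logical(1))
      todo <- idx[!ident_pre]
      ids <- numeric(length(idx))
      ids[ident_pre] <- 100
      if (length(todo) > 0) {
        pa <- Biostrings::pairwiseAlignment(
          Biostrings::AAStringSet(proteins[todo]),
          Biostrings::AAString(proteins[[j]]), type = "global",
          substitutionMatrix = "BLOSUM62", gapOpening = 10,
          gapExtension = 0.5)
        cols <- Biostrings::nchar(pa)
        ids[match(todo, idx)] <- ifelse(
          cols == 0, 0, 100 * Biostrings::nmatch(pa) / cols)
      }
      for (i in idx[ids >= min_identity]) {
        edges[[length(edges) + 1L]] <- c(nm[i], nm[j])
      }
    }
  }
  g <- igraph::graph_from_data_frame(
    if (length(edges) > 0) do.call(rbind, edges) else
      data.frame(from = character(0), to = character(0)),
    directed = FALSE, vertices = data.frame(name = nm))
  comp <- igraph::components(g)$membership
  groups <- vapply(split(names(comp), comp), function(members) {
    min(members)
  }, character(1))
  df <- data.frame(member = names(comp),
                   group = unname(groups[as.character(comp)]),
                   stringsAsFactors = FALSE)
  df$representative <- unname(proteins[df$group])
  df[order(df$group, df$member), ]
}

#' Flank profile of one cluster occurrence
#'
#' Extracts both flanks, predicts their ORFs and returns them with
#' flank-relative and contig coordinates.
#'
#' @inheritParams extract_flanks
#' @param strain Strain id recorded in the profile.
#' @param min_orf_length Passed to [predict_orfs()]. The default (600
#'   nt) is deliberately higher than the general-purpose ORF floor: the
#'   stop-to-stop caller has no coding model, and at ~55% GC a 5-kb
#'   flank yields dozens of spurious ORFs in the 150-300 nt range that
#'   would swamp conservation scores, while gene-sized (>= 600 nt)
#'   spurious ORFs are rare.
#' @return A `flank_profile`: list with `strain`, `orfs` (data.frame
#'   with `side` = upstream/downstream), `truncated` flags.
#' @export
flank_profile <- function(genome, contig, start, end, strand = "+",
                          length = 5000L, strain = genome$strain,
                          min_orf_length = 600L) {
  fl <- extract_flanks(genome, contig, start, end, strand, length)
  per_side <- lapply(c("upstream", "downstream"), function(side) {
    s <- fl[[side]]$seq
    if (nchar(s) < min_orf_length) {
      return(NULL)
    }
    orfs <- predict_orfs(s, min_length = min_orf_length, contig = contig)
    if (nrow(orfs) == 0) return(NULL)
    orfs$side <- side
    orfs$orf_id <- paste(strain, side, orfs$orf_id, sep = "|")
    orfs
  })
  orfs <- do.call(rbind, per_side)
  if (is.null(orfs)) {
    orfs <- data.frame(orf_id = character(0), contig = character(0),
                       start = integer(0), end = integer(0),
                       strand = character(0), length = integer(0),
                       edge = logical(0), protein = character(0),
                       side = character(0))
  }
  structure(list(strain = strain, orfs = orfs,
                 truncated = c(upstream = fl$upstream$truncated,
                               downstream = fl$downstream$truncated)),
            class = "flank_profile")
}

#' Flank conservation across strains
#'
#' Pools the flank ORFs of all profiles, groups them into homolog groups
#' at `min_identity`, and returns the presence/absence table plus the
#' pairwise Jaccard conservation score (shared groups over union).
#'
#' @param profiles List of [flank_profile()]s.
#' @param min_identity Homolog grouping cutoff (percent).
#' @return List: `presence` (strains x groups logical matrix),
#'   `jaccard` (strains x strains), `groups` (the [group_homologs()]
#'   table with a `strain` column).
#' @export
conservation_matrix <- function(profiles, min_identity = 30) {
  stopifnot(length(profiles) >= 2)
  strains <- vapply(profiles, `[[`, character(1), "strain")
  prot <- unlist(lapply(profiles, function(p) {
    stats::setNames(p$orfs$protein, p$orfs$orf_id)
  }))
  if (length(prot) == 0) stop("no flank ORFs to compare")
  groups <- group_homologs(prot, min_identity = min_identity)
  groups$strain <- vapply(strsplit(groups$member, "|", fixed = TRUE),
                          `[`, character(1), 1L)
  glev <- sort(unique(groups$group))
  presence <- matrix(FALSE, nrow = length(strains), ncol = length(glev),
                     dimnames = list(strains, glev))
  for (i in seq_len(nrow(groups))) {
    presence[groups$strain[i], groups$group[i]] <- TRUE
  }
  jac <- matrix(1, length(strains), length(strains),
                dimnames = list(strains, strains))
  for (i in seq_along(strains)) {
    for (j in seq_along(strains)) {
      a <- presence[i, ]; b <- presence[j, ]
      u <- sum(a | b)
      jac[i, j] <- if (u == 0) 1 else sum(a & b) / u
    }
  }
  list(presence = presence, jaccard = jac, groups = groups)
}

MGE_KEYWORDS <- c("transposase", "integrase", "insertion sequence",
                  "recombinase", "conjugal", "conjugation",
                  "mobile element")
# tra gene names (traI, traG, ...) matched case-sensitively so that
# "transcriptional" and the like do not fire
MGE_TRA_PATTERN <- "\\btra[A-Z]\\b"

#' Flag mobile-genetic-element ORFs
#'
#' An ORF is flagged when its annotation text matches an MGE keyword
#' (transposase, integrase, insertion sequence, recombinase,
#' conjugation/tra), or when its protein aligns to a supplied MGE
#' reference protein at >= `min_identity` over >= `min_coverage` of the
#' reference. At least one of `annotations` and `reference` must be
#' given.
#'
#' @param orfs data.frame with a `protein` column (e.g. from
#'   [predict_orfs()]).
#' @param annotations Optional character vector of annotation strings,
#'   parallel to `orfs` rows.
#' @param reference Optional named character vector of MGE reference
#'   proteins (see [mge_reference_proteins()]).
#' @param min_identity,min_coverage Reference-route thresholds.
#' @return Logical vector, one flag per ORF.
#' @export
flag_mobile_elements <- function(orfs, annotations = NULL,
                                 reference = NULL,
                                 min_identity = 30, min_coverage = 0.5) {
  if (is.null(annotations) && is.null(reference)) {
    stop("supply annotations and/or an MGE reference protein set")
  }
  n <- nrow(orfs)
  flags <- rep(FALSE, n)
  if (!is.null(annotations)) {
    stopifnot(length(annotations) == n)
    pat <- paste(MGE_KEYWORDS, collapse = "|")
    flags <- flags | grepl(pat, annotations, ignore.case = TRUE) |
      grepl(MGE_TRA_PATTERN, annotations)
  }
  if (!is.null(reference)) {
    for (i in seq_len(n)) {
      if (flags[i]) next
      for (ref in reference) {
        al <- align_pair(ref, orfs$protein[i], mode = "local",
                         alphabet = "protein")
        if (al$identity >= min_identity && al$coverage >= min_coverage) {
          flags[i] <- TRUE
          break
        }
      }
    }
  }
  flags
}

#' Detect frameshift-interrupted genes
#'
#' A reference gene is reported as interrupted when two or more adjacent
#' same-strand ORFs align to essentially non-overlapping segments of its
#' protein and jointly cover at least `min_joint_coverage` of it — the
#' signature of a single-base frameshift splitting one gene into
#' consecutive reading frames.
#'
#' @param orfs data.frame from [predict_orfs()] (needs `orf_id`,
#'   `start`, `end`, `strand`, `protein`). A lower `min_length` (e.g.
#'   60 nt) is recommended for this scan, since frameshift fragments can
#'   be short.
#' @param reference_proteins Named character vector of intact reference
#'   gene proteins.
#' @param seq Optional nucleotide sequence the ORFs were predicted
#'   from. When supplied, a secondary "disrupted terminus" rule also
#'   fires: a frameshift near a gene end leaves a protein remainder in
#'   a shifted reading frame that usually lacks its own start codon and
#'   therefore never becomes an ORF; it is found by translating the
#'   region adjacent to the anchored ORF in the other frames.
#' @param min_segment_identity Identity floor for an ORF-to-reference
#'   segment match (percent).
#' @param min_joint_coverage Minimum fraction of the reference protein
#'   jointly covered.
#' @param max_segment_overlap Maximum allowed overlap (aa) between the
#'   reference segments matched by adjacent ORFs. Local alignments of
#'   real fragments read through the frameshift point by a few tens of
#'   residues, so the allowance is generous; tandem duplicates (near
#'   full mutual overlap) remain excluded.
#' @param max_genomic_gap Maximum gap (bp) between consecutive ORFs of
#'   one candidate.
#' @param min_orf_coverage Minimum aligned fraction of an ORF for it to
#'   count as a segment (short fragments carry proportionally long
#'   read-through tails, so this floor is deliberately permissive; the
#'   joint-coverage requirement controls false positives).
#' @param min_ref_span Minimum fraction of the reference protein one
#'   segment must cover.
#' @param min_terminal_gap Minimum uncovered terminal stretch (aa) for
#'   the disrupted-terminus rule to engage.
#' @return data.frame of candidates: `gene`, `n_orfs`, `joint_coverage`,
#'   `orf_ids` (comma-separated), possibly empty.
#' @export
detect_interrupted_genes <- function(orfs, reference_proteins,
                                     seq = NULL,
                                     min_segment_identity = 40,
                                     min_joint_coverage = 0.7,
                                     max_segment_overlap = 45L,
                                     max_genomic_gap = 300L,
                                     min_orf_coverage = 0.2,
                                     min_ref_span = 0.05,
                                     min_terminal_gap = 10L) {
  stopifnot(!is.null(names(reference_proteins)))
  out <- list()
  if (nrow(orfs) == 0) return(empty_interrupted())
  orfs <- orfs[order(orfs$start), , drop = FALSE]
  ok_prot <- nzchar(orfs$protein)
  for (gname in names(reference_proteins)) {
    ref <- reference_proteins[[gname]]
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::AAStringSet(orfs$protein[ok_prot]),
      Biostrings::AAString(ref), type = "local",
      substitutionMatrix = "BLOSUM62", gapOpening = 10,
      gapExtension = 0.5)
    cols <- Biostrings::nchar(pa)
    idents <- ifelse(cols == 0, 0, 100 * Biostrings::nmatch(pa) / cols)
    q_start <- Biostrings::start(Biostrings::pattern(pa)) - 1L
    q_end <- Biostrings::end(Biostrings::pattern(pa))
    s_start <- Biostrings::start(Biostrings::subject(pa)) - 1L
    s_end <- Biostrings::end(Biostrings::subject(pa))
    segs <- list()
    for (kk in seq_along(idents)) {
      i <- which(ok_prot)[kk]
      ident <- idents[kk]
      coverage <- (q_end[kk] - q_start[kk]) / nchar(orfs$protein[i])
      if (ident >= min_segment_identity && coverage >= min_orf_coverage &&
          (s_end[kk] - s_start[kk]) >= min_ref_span * nchar(ref)) {
        segs[[length(segs) + 1L]] <- data.frame(
          orf_id = orfs$orf_id[i], strand = orfs$strand[i],
          start = orfs$start[i], end = orfs$end[i],
          frame = if (orfs$strand[i] == "+") orfs$start[i] %% 3 else
            orfs$end[i] %% 3,
          ref_start = s_start[kk], ref_end = s_end[kk])
      }
    }
    if (length(segs) == 0) next
    segs <- do.call(rbind, segs)
    reported <- FALSE
    for (strand in unique(segs$strand)) {
      ss <- segs[segs$strand == strand, , drop = FALSE]
      if (nrow(ss) < 2) next
      ss <- ss[order(ss$start), , drop = FALSE]
      run_id <- cumsum(c(1, (ss$start[-1] - ss$end[-nrow(ss)]) >
                           max_genomic_gap))
      for (r in split(seq_len(nrow(ss)), run_id)) {
        if (length(r) < 2) next
        sub <- ss[r, , drop = FALSE]
        # pick the best chain of segments with (near) non-overlapping
        # reference spans; spurious short matches inside the run must
        # not poison the real fragment pair
        sub <- sub[order(sub$ref_start, sub$ref_end), , drop = FALSE]
        m <- nrow(sub)
        cover <- sub$ref_end - sub$ref_start
        best <- cover
        prev <- rep(0L, m)
        for (b in seq_len(m)) {
          for (a in seq_len(b - 1L)) {
            ov <- sub$ref_end[a] - sub$ref_start[b]
            if (ov <= max_segment_overlap) {
              cand <- best[a] + cover[b] - max(ov, 0)
              if (cand > best[b]) {
                best[b] <- cand
                prev[b] <- a
              }
            }
          }
        }
        b <- which.max(best)
        chain <- b
        while (prev[b] > 0L) {
          b <- prev[b]
          chain <- c(b, chain)
        }
        sel <- sub[chain, , drop = FALSE]
        # a frameshift changes the reading frame; same-frame splits are
        # nonsense mutations, not frameshifts
        if (nrow(sel) < 2 || length(unique(sel$frame)) < 2) next
        joint <- best[which.max(best)] / nchar(ref)
        if (joint >= min_joint_coverage) {
          out[[length(out) + 1L]] <- data.frame(
            gene = gname, n_orfs = nrow(sel),
            joint_coverage = round(joint, 3),
            orf_ids = paste(sel$orf_id, collapse = ","),
            stringsAsFactors = FALSE)
          reported <- TRUE
        }
      }
    }
    if (!reported && !is.null(seq)) {
      cand <- terminal_disruption(segs, ref, seq, min_segment_identity,
                                  min_terminal_gap)
      if (!is.null(cand)) {
        cand$gene <- gname
        out[[length(out) + 1L]] <- cand[c("gene", "n_orfs",
                                          "joint_coverage", "orf_ids")]
      }
    }
  }
  if (length(out) == 0) return(empty_interrupted())
  do.call(rbind, out)
}

# Secondary frameshift signature: one well-anchored ORF covers most of
# the reference, and the uncovered terminal remainder is present in the
# adjacent sequence in a *different* reading frame (a same-frame
# remainder would be a nonsense split, not a frameshift).
terminal_disruption <- function(segs, ref, seq, min_identity,
                                min_terminal_gap) {
  bi <- which.max(segs$ref_end - segs$ref_start)
  b <- segs[bi, ]
  L <- nchar(ref)
  if ((b$ref_end - b$ref_start) < 0.5 * L) return(NULL)
  gene_forward <- b$strand == "+"
  clen <- nchar(seq)
  sides <- list()
  if (b$ref_start >= min_terminal_gap) {
    sides$left <- c(0L, b$ref_start)
  }
  if (L - b$ref_end >= min_terminal_gap) {
    sides$right <- c(b$ref_end, L)
  }
  for (side in names(sides)) {
    un <- sides[[side]][2] - sides[[side]][1]
    ref_seg <- substr(ref, sides[[side]][1] + 1L, sides[[side]][2])
    w <- 3L * un + 90L
    after <- (side == "right") == gene_forward
    if (after) {
      ws <- max(0L, b$end - 45L); we <- min(clen, b$end + w)
    } else {
      ws <- max(0L, b$start - w); we <- min(clen, b$start + 45L)
    }
    if (we - ws < 3L * min_terminal_gap) next
    piece <- substr(seq, ws + 1L, we)
    if (!gene_forward) piece <- revcomp(piece)
    for (f in 0:2) {
      prot <- translate_dna(substr(piece, f + 1L, nchar(piece)))
      if (nchar(prot) < min_terminal_gap) next
      al <- align_pair(prot, ref_seg, mode = "local",
                       alphabet = "protein")
      ref_cov <- (al$subject_span[2] - al$subject_span[1]) / un
      if (al$identity < min_identity || ref_cov < 0.6) next
      # matched nt offset within `piece` (gene orientation)
      off <- f + 3L * al$query_span[1]
      frame_match <- if (gene_forward) (ws + off) %% 3 else
        (we - off) %% 3
      frame_orf <- if (gene_forward) b$start %% 3 else b$end %% 3
      if (frame_match == frame_orf) next
      joint <- ((b$ref_end - b$ref_start) + ref_cov * un) / L
      return(data.frame(
        gene = NA_character_, n_orfs = 2L,
        joint_coverage = round(min(joint, 1), 3),
        orf_ids = paste0(b$orf_id, ",terminal_", side),
        stringsAsFactors = FALSE))
    }
  }
  NULL
}

empty_interrupted <- function() {
  data.frame(gene = character(0), n_orfs = integer(0),
             joint_coverage = numeric(0), orf_ids = character(0))
}
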