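# Internal coordinate convention: 0-based, half-open [start, end).
# GFF3 output converts to the standard 1-based inclusive convention.

VALID_DNA <- c("A", "C", "G", "T", "N")

#' Read a FASTA file of nucleotide sequences
#'
#' Sequences are normalized to uppercase. Only the unambiguous bases
#' A/C/G/T plus N are accepted after normalization; any other character
#' (including non-N IUPAC ambiguity codes) is rejected so downstream
#' identity and %GC arithmetic has a single, documented alphabet.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of uppercase sequences; names are the
#'   first whitespace-delimited token of each header.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("failed to parse FASTA '", path, "': ",
                             conditionMessage(e))
  )
  if (length(set) == 0L) {
    stop("empty FASTA file: ", path, call. = FALSE)
  }
  ids <- vapply(strsplit(names(set), "[ \t]"), `[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    stop("duplicate sequence ids in '", path, "': ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- toupper(as.character(set))
  names(seqs) <- ids
  bad <- vapply(seqs, function(s) {
    any(!strsplit(s, "")[[1]] %in% VALID_DNA)
  }, logical(1))
  if (any(bad)) {
    stop("non-ACGTN characters in sequence(s): ",
         paste(ids[bad], collapse = ", "))
  }
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width in bases.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(length(seqs) > 0L, !is.null(names(seqs)))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    n <- nchar(s)
    starts <- seq(1L, n, by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, n)), con)
  }
  invisible(path)
}

#' Construct a genome record
#'
#' A genome record holds one strain's assembly: an ordered set of contigs
#' plus optional replicon labels (chromosome/plasmid/unknown) used when
#' choosing the %GC baseline.
#'
#' @param strain Strain identifier.
#' @param contigs Named character vector of contig sequences (ACGTN).
#' @param replicon_labels Optional named character vector mapping contig id
#'   to one of "chromosome", "plasmid", "unknown".
#' @return A `genome_record` object.
#' @export
genome_record <- function(strain, contigs, replicon_labels = NULL) {
  stopifnot(is.character(strain), length(strain) == 1L)
  if (is.null(names(contigs)) || anyDuplicated(names(contigs))) {
    stop("contigs must have unique names")
  }
  contigs <- toupper(contigs)
  chars <- unique(unlist(strsplit(paste(contigs, collapse = ""), "")))
  if (any(!chars %in% VALID_DNA)) {
    stop("contig sequences contain non-ACGTN characters")
  }
  if (!is.null(replicon_labels)) {
    stopifnot(all(names(replicon_labels) %in% names(contigs)),
              all(replicon_labels %in% c("chromosome", "plasmid", "unknown")))
  }
  structure(
    list(strain = strain, contigs = contigs,
         replicon_labels = replicon_labels),
    class = "genome_record"
  )
}

#' @export
print.genome_record <- function(x, ...) {
  cat("<genome_record> strain:", x$strain, "|", length(x$contigs),
      "contig(s),", sum(nchar(x$contigs)), "bp\n")
  invisible(x)
}

#' Read a genome assembly from FASTA
#'
#' @param path FASTA path; each record becomes a contig.
#' @param strain Strain id; defaults to the file name without extension.
#' @return A [genome_record()].
#' @export
read_genome <- function(path, strain = NULL) {
  if (is.null(strain)) {
    strain <- sub("\\.(fa|fasta|fna)$", "", basename(path))
  }
  genome_record(strain, read_fasta(path))
}

#' Construct a reference cluster definition
#'
#' A cluster definition is the query unit of the survey: the full
#' nucleotide sequence of a reference biosynthetic gene cluster plus its
#' ordered gene table. Genes are stored sorted by start coordinate; the
#' original input order is kept in an `input_order` column. Coordinates
#' are 0-based half-open within the cluster sequence.
#'
#' @param name Cluster name (e.g. "pantocinA").
#' @param sequence Cluster nucleotide sequence.
#' @param genes data.frame with columns `gene`, `start`, `end`, `strand`
#'   (`"+"` or `"-"`).
#' @param source_strain,accession Free-text provenance fields.
#' @param overlap_slack Maximum tolerated overlap (bp) between adjacent
#'   genes; operonic BGC genes commonly overlap by a few bases.
#' @return A `cluster_definition` object with `length` and `orf_count`.
#' @export
cluster_definition <- function(name, sequence, genes,
                               source_strain = NA_character_,
                               accession = NA_character_,
                               overlap_slack = 30L) {
  sequence <- toupper(sequence)
  len <- nchar(sequence)
  stopifnot(is.data.frame(genes),
            all(c("gene", "start", "end", "strand") %in% names(genes)))
  if (anyDuplicated(genes$gene)) stop("duplicate gene names")
  if (any(genes$start < 0L) || any(genes$end > len) ||
      any(genes$start >= genes$end)) {
    stop("gene coordinates out of cluster bounds (0-based half-open, ",
         "0 <= start < end <= ", len, ")")
  }
  stopifnot(all(genes$strand %in% c("+", "-")))
  genes$input_order <- seq_len(nrow(genes))
  o <- order(genes$start)
  genes <- genes[o, , drop = FALSE]
  rownames(genes) <- NULL
  if (nrow(genes) > 1L) {
    overlap <- genes$end[-nrow(genes)] - genes$start[-1L]
    if (any(overlap > overlap_slack)) {
      stop("genes overlap by more than ", overlap_slack, " bp")
    }
  }
  structure(
    list(name = name, source_strain = source_strain, accession = accession,
         sequence = sequence, genes = genes, length = len,
         orf_count = nrow(genes)),
    class = "cluster_definition"
  )
}

#' @export
print.cluster_definition <- function(x, ...) {
  cat("<cluster_definition>", x$name, "|", x$length, "bp,",
      x$orf_count, "ORFs\n")
  invisible(x)
}

#' Extract a gene's sequence from a cluster definition
#'
#' @param cluster A [cluster_definition()].
#' @param gene Gene name.
#' @return Nucleotide sequence on the gene's own strand.
#' @export
cluster_gene_seq <- function(cluster, gene) {
  row <- cluster$genes[cluster$genes$gene == gene, ]
  if (nrow(row) != 1L) stop("unknown gene: ", gene)
  s <- substr(cluster$sequence, row$start + 1L, row$end)
  if (row$strand == "-") s <- revcomp(s)
  s
}

#' Read a cluster definition from JSON
#'
#' Expected keys: `name`, `sequence`, `genes` (array of objects with
#' `gene`, `start`, `end`, `strand`; 0-based half-open), optional
#' `source_strain`, `accession`.
#'
#' @param path JSON path.
#' @return A [cluster_definition()].
#' @export
read_cluster_definition <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(x$name) || is.null(x$sequence) || is.null(x$genes)) {
    stop("cluster definition must provide name, sequence and genes")
  }
  cluster_definition(
    name = x$name, sequence = x$sequence,
    genes = as.data.frame(x$genes),
    source_strain = x$source_strain %||% NA_character_,
    accession = x$accession %||% NA_character_
  )
}

#' Write a cluster definition to JSON
#' @param cluster A [cluster_definition()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cluster_definition <- function(cluster, path) {
  jsonlite::write_json(
    list(name = cluster$name, source_strain = cluster$source_strain,
         accession = cluster$accession, sequence = cluster$sequence,
         genes = cluster$genes[c("gene", "start", "end", "strand")]),
    path, auto_unbox = TRUE, pretty = TRUE
  )
  invisible(path)
}

#' Read / write Newick trees
#'
#' Thin wrappers over \pkg{ape} that validate the text and preserve
#' branch lengths to at least six decimals. Polytomies are preserved.
#'
#' @param path Newick file path (or, for `write_newick`, output path).
#' @param tree An \pkg{ape} `phylo` object.
#' @return `read_newick` returns a `phylo`; `write_newick` its path,
#'   invisibly.
#' @export
read_newick <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  n_open <- lengths(regmatches(txt, gregexpr("\\(", txt)))
  n_close <- lengths(regmatches(txt, gregexpr("\\)", txt)))
  if (n_open != n_close) stop("unbalanced parentheses in newick: ", path)
  tr <- ape::read.tree(text = txt)
  if (is.null(tr)) stop("failed to parse newick: ", path)
  tr
}

#' @rdname read_newick
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 10)
  invisible(path)
}

#' Write features to a GFF3 file
#'
#' Internal 0-based half-open spans are converted to the GFF3 1-based
#' inclusive convention.
#'
#' @param features data.frame with columns `seqid`, `source`, `type`,
#'   `start`, `end` (0-based half-open), `strand`, and optionally `score`
#'   and `attributes`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(features, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(features) > 0L) {
    score <- if ("score" %in% names(features)) features$score else "."
    attrs <- if ("attributes" %in% names(features)) features$attributes else "."
    lines <- paste(features$seqid, features$source, features$type,
                   features$start + 1L, features$end, score,
                   features$strand, ".", attrs, sep = "\t")
    writeLines(lines, con)
  }
  invisible(path)
}

#' Reverse complement of a nucleotide string
#' @param seq Nucleotide sequence (ACGTN).
#' @return Reverse complement string.
#' @export
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic child seed derived from a master seed and a stream label.
# Keeps every derived seed inside the 32-bit signed integer range.
derive_seed <- function(seed, label) {
  as.integer(string_hash(paste0(seed, "/", label)) %% 2147483586 + 1)
}

# Tiny stable polynomial string hash (mod 2^31 - 1); used only to derive
# independent child seeds from a master seed, never for data integrity.
string_hash <- function(x) {
  bytes <- utf8ToInt(x)
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  h
}

digest_hex <- function(x) {
  format(as.hexmode(string_hash(x)), width = 8)
}
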