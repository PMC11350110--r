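# %GC anomaly screening: clusters acquired horizontally tend to carry the
# compositional signature of their former host, so a cluster whose %GC sits
# well off its replicon's baseline is a horizontal-transfer candidate.

#' %GC content of a nucleotide sequence
#'
#' Computed as 100 * (G + C) / (A + C + G + T). N bases are excluded from
#' the denominator. Full precision is returned; round at report time.
#'
#' @param seq Nucleotide sequence (ACGTN), or a vector of sequences whose
#'   composition is pooled (length-weighted, i.e. %GC of the
#'   concatenation).
#' @return %GC in [0, 100].
#' @export
gc_content <- function(seq) {
  stopifnot(length(seq) >= 1L, all(nzchar(seq)))
  counts <- colSums(Biostrings::letterFrequency(
    Biostrings::DNAStringSet(seq), letters = c("A", "C", "G", "T")))
  denom <- sum(counts)
  if (denom == 0) stop("sequence contains no unambiguous bases (all N)")
  100 * (counts[["G"]] + counts[["C"]]) / denom
}

#' Cluster-versus-replicon %GC report
#'
#' Computes the %GC of a cluster and of its host replicon (chromosome or
#' plasmid), their difference, and a horizontal-transfer flag. The flag
#' fires when the absolute difference reaches `flag_threshold` percentage
#' points, the low end of the anomaly range typically observed for
#' horizontally acquired clusters; the sign records whether the cluster
#' sits below or above its host baseline (acquisitions from high-GC
#' donors show the latter).
#'
#' @param cluster_seq Cluster nucleotide sequence.
#' @param replicon_seq Host replicon sequence used as the baseline. When
#'   the cluster is plasmid-borne, pass the plasmid. To avoid the cluster
#'   contaminating its own baseline, callers may pass the replicon with
#'   the cluster span excised (see `exclude_span`).
#' @param cluster Cluster name for the report.
#' @param strain Strain id for the report.
#' @param flag_threshold Anomaly threshold in percentage points
#'   (default 5).
#' @param exclude_span Optional 0-based half-open `c(start, end)` span to
#'   excise from `replicon_seq` before computing the baseline (normally
#'   the cluster's own coordinates).
#' @return A one-row data.frame: `cluster`, `strain`, `cluster_gc`,
#'   `replicon_gc` (2 decimals), `delta` (replicon minus cluster,
#'   percentage points), `hgt_flag`, `direction`
#'   ("below_host"/"above_host"/"none").
#' @export
gc_delta <- function(cluster_seq, replicon_seq,
                     cluster = "cluster", strain = "strain",
                     flag_threshold = 5.0, exclude_span = NULL) {
  if (!is.null(exclude_span)) {
    stopifnot(length(exclude_span) == 2L,
              exclude_span[1] >= 0, exclude_span[2] <= nchar(replicon_seq))
    replicon_seq <- paste0(
      substr(replicon_seq, 1L, exclude_span[1]),
      substr(replicon_seq, exclude_span[2] + 1L, nchar(replicon_seq)))
  }
  cg <- gc_content(cluster_seq)
  rg <- gc_content(replicon_seq)
  delta <- rg - cg
  # compared at 0.1-point resolution: %GC anomalies are conventionally
  # quoted to ~0.1 point, and finite-sequence composition granularity
  # should not flip a flag sitting exactly on the threshold
  flagged <- round(abs(delta), 1) >= flag_threshold
  data.frame(
    cluster = cluster, strain = strain,
    cluster_gc = round(cg, 2), replicon_gc = round(rg, 2),
    delta = round(delta, 2), hgt_flag = flagged,
    direction = if (!flagged) "none"
                else if (delta > 0) "below_host" else "above_host",
    stringsAsFactors = FALSE
  )
}

#' %GC report for a panel of cluster hits
#'
#' @param hits data.frame with columns `cluster`, `strain`, `contig`,
#'   `start`, `end` (0-based half-open cluster span).
#' @param genomes Named list of [genome_record()]s keyed by strain.
#' @param flag_threshold Passed to [gc_delta()].
#' @param exclude_cluster If TRUE (default), the cluster span is excised
#'   from the replicon before computing the baseline.
#' @return data.frame, one [gc_delta()] row per hit.
#' @export
gc_report <- function(hits, genomes, flag_threshold = 5.0,
                      exclude_cluster = TRUE) {
  rows <- lapply(seq_len(nrow(hits)), function(i) {
    h <- hits[i, ]
    g <- genomes[[h$strain]]
    if (is.null(g)) stop("no genome for strain ", h$strain)
    contig_seq <- g$contigs[[h$contig]]
    cl_seq <- substr(contig_seq, h$start + 1L, h$end)
    gc_delta(cl_seq, contig_seq, cluster = h$cluster, strain = h$strain,
             flag_threshold = flag_threshold,
             exclude_span = if (exclude_cluster) c(h$start, h$end) else NULL)
  })
  do.call(rbind, rows)
}
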