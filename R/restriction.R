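# In-silico restriction digestion and map-based localization: a region
# carrying a known cluster can be pinned down in a genome by matching the
# ordered pattern of restriction sites published for it, without any
# sequence of the cluster itself.

IUPAC_CHARS <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                 "B", "D", "H", "V", "N")

#' Define a restriction enzyme
#'
#' @param name Enzyme name (e.g. "EcoRI").
#' @param site Recognition site as an IUPAC nucleotide pattern,
#'   length >= 4.
#' @param cut_offset Cut position in bp from the site start (within
#'   `[0, nchar(site)]`).
#' @return A `restriction_enzyme` object.
#' @export
restriction_enzyme <- function(name, site, cut_offset = 0L) {
  site <- toupper(site)
  if (nchar(site) < 4) stop("recognition site must be >= 4 bp")
  chars <- strsplit(site, "")[[1]]
  if (any(!chars %in% IUPAC_CHARS)) {
    stop("invalid IUPAC character(s) in site: ",
         paste(unique(chars[!chars %in% IUPAC_CHARS]), collapse = ","))
  }
  if (cut_offset < 0 || cut_offset > nchar(site)) {
    stop("cut_offset must lie within [0, site length]")
  }
  structure(list(name = name, site = site,
                 cut_offset = as.integer(cut_offset)),
            class = "restriction_enzyme")
}

is_palindromic_site <- function(site) {
  identical(site, as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(site))))
}

#' Find restriction sites in a sequence
#'
#' Scans both strands; a site is reported once per duplex at its
#' 0-based start on the forward strand. Palindromic sites match both
#' strands at the same duplex position and are counted once.
#'
#' @param seq Nucleotide sequence.
#' @param enzyme A [restriction_enzyme()].
#' @return Sorted integer vector of 0-based site starts.
#' @export
find_sites <- function(seq, enzyme) {
  stopifnot(inherits(enzyme, "restriction_enzyme"), nchar(seq) > 0)
  subj <- Biostrings::DNAString(toupper(seq))
  fwd <- Biostrings::start(Biostrings::matchPattern(
    enzyme$site, subj, fixed = "subject")) - 1L
  if (is_palindromic_site(enzyme$site)) return(sort(unique(fwd)))
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(enzyme$site)))
  rev_ <- Biostrings::start(Biostrings::matchPattern(
    rc, subj, fixed = "subject")) - 1L
  sort(unique(c(fwd, rev_)))
}

#' Digest a linear sequence with a set of enzymes
#'
#' Cut positions are site start + enzyme cut offset (forward-strand
#' sites) collapsed across enzymes; fragment lengths always sum to the
#' sequence length.
#'
#' @param seq Nucleotide sequence.
#' @param enzymes A [restriction_enzyme()] or list of them.
#' @return Integer vector of ordered fragment lengths (bp).
#' @export
digest <- function(seq, enzymes) {
  if (inherits(enzymes, "restriction_enzyme")) enzymes <- list(enzymes)
  stopifnot(length(enzymes) >= 1)
  n <- nchar(seq)
  cuts <- sort(unique(unlist(lapply(enzymes, function(e) {
    find_sites(seq, e) + e$cut_offset
  }))))
  cuts <- cuts[cuts > 0 & cuts < n]
  diff(c(0L, cuts, n))
}

#' Build a restriction map
#'
#' @param sites data.frame with columns `enzyme` and `position`
#'   (0-based bp within the mapped region), strictly increasing.
#' @param span Total span of the mapped region (bp).
#' @return A `restriction_map` object.
#' @export
restriction_map <- function(sites, span) {
  stopifnot(is.data.frame(sites),
            all(c("enzyme", "position") %in% names(sites)))
  sites <- sites[order(sites$position), , drop = FALSE]
  if (nrow(sites) >= 2 && any(diff(sites$position) <= 0)) {
    stop("site positions must be strictly increasing")
  }
  if (any(sites$position < 0) || any(sites$position > span)) {
    stop("site positions must lie within [0, span]")
  }
  structure(list(sites = sites, span = as.integer(span)),
            class = "restriction_map")
}

#' Restriction map of a region's own digest
#'
#' @param seq Region sequence.
#' @param enzymes List of [restriction_enzyme()]s.
#' @return A [restriction_map()] with every duplex site of every enzyme.
#' @export
map_from_region <- function(seq, enzymes) {
  if (inherits(enzymes, "restriction_enzyme")) enzymes <- list(enzymes)
  rows <- do.call(rbind, lapply(enzymes, function(e) {
    p <- find_sites(seq, e)
    if (length(p) == 0) return(NULL)
    data.frame(enzyme = e$name, position = p, stringsAsFactors = FALSE)
  }))
  if (is.null(rows)) stop("no sites found in region")
  restriction_map(rows, nchar(seq))
}

#' Write / read a restriction map as JSON
#' @param map A [restriction_map()].
#' @param path File path.
#' @return The map (read) or `path` invisibly (write).
#' @export
write_restriction_map <- function(map, path) {
  jsonlite::write_json(list(span = map$span, sites = map$sites), path,
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_restriction_map
#' @export
read_restriction_map <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  restriction_map(as.data.frame(x$sites), x$span)
}

# Score one candidate placement: order-preserving greedy matching of
# expected sites to observed sites of the same enzyme, positional error
# at most `slack`. Score = matched - missed - extra.
score_placement <- function(expected, observed_by_enzyme, offset, span,
                            slack) {
  matched <- 0L; missed <- 0L
  poserr <- 0
  used <- lapply(observed_by_enzyme, function(x) logical(length(x)))
  for (i in seq_len(nrow(expected))) {
    e <- expected$enzyme[i]
    target <- offset + expected$position[i]
    obs <- observed_by_enzyme[[e]]
    ok <- which(!used[[e]] & abs(obs - target) <= slack)
    if (length(ok) == 0) {
      missed <- missed + 1L
    } else {
      pick <- ok[which.min(abs(obs[ok] - target))]
      used[[e]][pick] <- TRUE
      matched <- matched + 1L
      poserr <- poserr + abs(obs[pick] - target)
    }
  }
  extra <- 0L
  for (e in names(observed_by_enzyme)) {
    obs <- observed_by_enzyme[[e]]
    inwin <- obs >= offset & obs <= offset + span
    extra <- extra + sum(inwin & !used[[e]])
  }
  c(matched = matched, missed = missed, extra = extra,
    score = matched - missed - extra, poserr = poserr)
}

#' Localize a region in a genome by its restriction map
#'
#' Slides the expected site pattern over each contig (both
#' orientations), anchoring candidate placements at every
#' observed-site/expected-site pairing, and scores each placement by
#' order-preserving site matching (+1 matched, -1 missed, -1 extra
#' observed site of a map enzyme inside the window; positional slack =
#' `tolerance * span`). Near-duplicate placements are collapsed to the
#' best-scoring one. Ranking is deterministic: score desc, then contig,
#' then position.
#'
#' @param genome A [genome_record()].
#' @param map A [restriction_map()] with at least 2 sites.
#' @param enzymes Named list of [restriction_enzyme()]s covering every
#'   enzyme named in the map.
#' @param tolerance Fractional positional tolerance (0 < t < 0.5).
#' @param max_candidates Number of ranked matches to return.
#' @return data.frame of ranked matches: `contig`, `start`, `end`,
#'   `orientation`, `matched`, `missed`, `extra`, `score`.
#' @export
locate_by_map <- function(genome, map, enzymes, tolerance = 0.05,
                          max_candidates = 10L) {
  stopifnot(inherits(map, "restriction_map"),
            tolerance > 0, tolerance < 0.5)
  if (nrow(map$sites) < 2) {
    stop("restriction map needs >= 2 sites (pattern under-determined)")
  }
  if (inherits(enzymes, "restriction_enzyme")) enzymes <- list(enzymes)
  enz_names <- vapply(enzymes, `[[`, character(1), "name")
  names(enzymes) <- enz_names
  need <- unique(map$sites$enzyme)
  if (!all(need %in% enz_names)) {
    stop("missing enzyme definition(s): ",
         paste(setdiff(need, enz_names), collapse = ", "))
  }
  span <- map$span
  slack <- tolerance * span
  site_len <- vapply(enzymes, function(e) nchar(e$site), integer(1))
  results <- list()
  for (contig in names(genome$contigs)) {
    seqn <- genome$contigs[[contig]]
    clen <- nchar(seqn)
    obs <- lapply(enzymes[need], function(e) find_sites(seqn, e))
    names(obs) <- need
    for (orientation in c("+", "-")) {
      expected <- map$sites
      if (orientation == "-") {
        expected$position <- span - expected$position -
          site_len[expected$enzyme]
        expected <- expected[order(expected$position), , drop = FALSE]
      }
      # anchor offsets at every (observed, expected) pairing
      offsets <- unlist(lapply(seq_len(nrow(expected)), function(i) {
        obs[[expected$enzyme[i]]] - expected$position[i]
      }))
      offsets <- unique(offsets[offsets > -slack &
                                  offsets < clen - span + slack])
      if (length(offsets) == 0) next
      sc <- t(vapply(offsets, function(o) {
        score_placement(expected, obs, o, span, slack)
      }, c(matched = 0, missed = 0, extra = 0, score = 0, poserr = 0)))
      df <- data.frame(contig = contig, start = as.integer(offsets),
                       end = as.integer(offsets) + span,
                       orientation = orientation, sc,
                       stringsAsFactors = FALSE)
      # collapse near-duplicate placements; among equal scores prefer
      # the placement with the smallest total positional error
      df <- df[order(-df$score, df$poserr, df$start), , drop = FALSE]
      keep <- rep(TRUE, nrow(df))
      for (i in seq_len(nrow(df))) {
        if (!keep[i]) next
        dup <- which(keep & seq_len(nrow(df)) > i &
                       abs(df$start - df$start[i]) < span / 2)
        keep[dup] <- FALSE
      }
      results[[length(results) + 1L]] <- df[keep, , drop = FALSE]
    }
  }
  if (length(results) == 0) {
    return(data.frame(contig = character(0), start = integer(0),
                      end = integer(0), orientation = character(0),
                      matched = numeric(0), missed = numeric(0),
                      extra = numeric(0), score = numeric(0),
                      poserr = numeric(0)))
  }
  out <- do.call(rbind, results)
  out <- out[order(-out$score, out$poserr, out$contig, out$start), ,
             drop = FALSE]
  rownames(out) <- NULL
  utils::head(out, max_candidates)
}
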