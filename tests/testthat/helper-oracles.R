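# Independent brute-force oracles. These deliberately share no code with
# the package implementation.

# Needleman-Wunsch, linear gap penalty, full traceback.
# Returns list(score, identity) with identity = matches / aligned
# columns excluding end-gap columns.
nw_oracle <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  S <- matrix(0, n + 1, m + 1)
  S[, 1] <- gap * (0:n)
  S[1, ] <- gap * (0:m)
  for (i in 1:n) {
    for (j in 1:m) {
      sub <- if (x[i] == y[j]) match else mismatch
      S[i + 1, j + 1] <- max(S[i, j] + sub, S[i, j + 1] + gap,
                             S[i + 1, j] + gap)
    }
  }
  # traceback (prefer diagonal, then up, then left)
  i <- n; j <- m
  ra <- character(0); rb <- character(0)
  while (i > 0 || j > 0) {
    sub <- if (i > 0 && j > 0 && x[i] == y[j]) match else mismatch
    if (i > 0 && j > 0 && S[i + 1, j + 1] == S[i, j] + sub) {
      ra <- c(x[i], ra); rb <- c(y[j], rb); i <- i - 1; j <- j - 1
    } else if (i > 0 && S[i + 1, j + 1] == S[i, j + 1] + gap) {
      ra <- c(x[i], ra); rb <- c("-", rb); i <- i - 1
    } else {
      ra <- c("-", ra); rb <- c(y[j], rb); j <- j - 1
    }
  }
  keep <- rep(TRUE, length(ra))
  for (row in list(ra, rb)) {
    non <- which(row != "-")
    keep[seq_along(row) < non[1]] <- FALSE
    keep[seq_along(row) > non[length(non)]] <- FALSE
  }
  cols <- sum(keep)
  list(score = S[n + 1, m + 1],
       identity = 100 * sum(ra[keep] == rb[keep] & ra[keep] != "-") / cols)
}

# Six-frame stop-to-stop ORF scan, written around Biostrings codons()
# rather than the package's substring bookkeeping.
sixframe_oracle <- function(seq, min_length) {
  res <- list()
  n <- nchar(seq)
  code <- Biostrings::getGeneticCode("11")
  for (strand in c("+", "-")) {
    s <- if (strand == "+") Biostrings::DNAString(seq) else
      Biostrings::reverseComplement(Biostrings::DNAString(seq))
    for (frame in 0:2) {
      sub <- Biostrings::subseq(s, start = frame + 1)
      nc <- floor(length(sub) / 3)
      if (nc < 2) next
      cods <- as.character(Biostrings::codons(
        Biostrings::subseq(sub, 1, nc * 3)))
      aa <- unname(code[cods])
      stops <- which(aa == "*")
      seg_bounds <- cbind(c(1, stops + 1), c(stops, nc + 1))
      for (k in seq_len(nrow(seg_bounds))) {
        lo <- seg_bounds[k, 1]; hi <- seg_bounds[k, 2]
        if (lo > nc) next
        at_edge <- hi > nc
        inner_hi <- min(hi - 1, nc)
        if (lo > inner_hi) next
        starts <- which(cods[lo:inner_hi] %in% c("ATG", "GTG", "TTG"))
        if (length(starts) == 0) next
        first <- lo + starts[1] - 1
        last <- if (at_edge) nc else hi
        len <- (last - first + 1) * 3
        if (len < min_length) next
        nt_start <- frame + (first - 1) * 3
        nt_end <- nt_start + len
        if (strand == "-") {
          tmp <- n - nt_end; nt_end <- n - nt_start; nt_start <- tmp
        }
        res[[length(res) + 1]] <- data.frame(
          start = nt_start, end = nt_end, strand = strand, length = len)
      }
    }
  }
  out <- do.call(rbind, res)
  if (is.null(out)) {
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0), length = integer(0)))
  }
  out[order(out$start, out$end, out$strand), ]
}

# Sliding-window IUPAC site scan on both strands, palindromes once.
iupac_regex <- c(A = "A", C = "C", G = "G", T = "T", R = "[AG]",
                 Y = "[CT]", S = "[GC]", W = "[AT]", K = "[GT]",
                 M = "[AC]", B = "[CGT]", D = "[AGT]", H = "[ACT]",
                 V = "[ACG]", N = "[ACGT]")

naive_site_scan <- function(seq, site) {
  pat_match <- function(p) {
    rx <- paste(iupac_regex[strsplit(p, "")[[1]]], collapse = "")
    w <- nchar(p)
    hits <- integer(0)
    for (i in seq_len(nchar(seq) - w + 1)) {
      if (grepl(paste0("^", rx, "$"), substr(seq, i, i + w - 1))) {
        hits <- c(hits, i - 1L)
      }
    }
    hits
  }
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(site)))
  if (rc == site) sort(unique(pat_match(site)))
  else sort(unique(c(pat_match(site), pat_match(rc))))
}

# All non-trivial bipartitions of an unrooted tree, as canonical strings.
bipartitions_oracle <- function(tree) {
  tree <- ape::unroot(tree)
  tips <- sort(tree$tip.label)
  n <- length(tips)
  out <- character(0)
  internal <- setdiff(unique(tree$edge[, 1]), seq_len(n))
  for (node in unique(tree$edge[, 2][tree$edge[, 2] > n])) {
    clade <- ape::extract.clade(tree, node)$tip.label
    side <- sort(clade)
    other <- sort(setdiff(tips, side))
    if (length(side) < 2 || length(other) < 2) next
    canon <- if (paste(side, collapse = ",") <
                 paste(other, collapse = ",")) side else other
    out <- c(out, paste(canon, collapse = ","))
  }
  unique(out)
}

rf_oracle <- function(t1, t2) {
  b1 <- bipartitions_oracle(t1)
  b2 <- bipartitions_oracle(t2)
  length(setdiff(b1, b2)) + length(setdiff(b2, b1))
}

# Brute-force restriction-map window scorer (independent of
# locate_by_map's anchoring): score a placement at offset o.
naive_map_score <- function(map, obs_by_enzyme, o, slack) {
  used <- lapply(obs_by_enzyme, function(x) rep(FALSE, length(x)))
  matched <- 0; missed <- 0
  for (i in seq_len(nrow(map$sites))) {
    e <- map$sites$enzyme[i]
    d <- abs(obs_by_enzyme[[e]] - (o + map$sites$position[i]))
    cand <- which(!used[[e]] & d <= slack)
    if (length(cand) == 0) missed <- missed + 1
    else {
      pick <- cand[which.min(d[cand])]
      used[[e]][pick] <- TRUE
      matched <- matched + 1
    }
  }
  extra <- 0
  for (e in names(obs_by_enzyme)) {
    inw <- obs_by_enzyme[[e]] >= o & obs_by_enzyme[[e]] <= o + map$span
    extra <- extra + sum(inw & !used[[e]])
  }
  matched - missed - extra
}
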