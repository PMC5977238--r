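# Junction extraction and the valid-read filter: recover phage-host junctions
# from virion reads, trim the phage portion, and quantify library chimeras via
# the truncated-genome control.

asReads <- function(x) {
  if (is(x, "ReadSet")) return(x@reads)
  if (is(x, "DNAStringSet")) return(x)
  if (is.character(x)) {
    out <- Biostrings::DNAStringSet(x)
    if (is.null(names(out))) names(out) <- sprintf("read_%06d", seq_along(out))
    return(out)
  }
  stop("expected a ReadSet, DNAStringSet or character vector of reads")
}

# first match start per read, NA where absent
firstMatchStart <- function(pattern, reads) {
  m <- Biostrings::vmatchPattern(pattern, reads)
  st <- Biostrings::startIndex(m)
  vapply(st, function(s) if (is.null(s) || !length(s)) NA_integer_ else s[[1L]],
         integer(1))
}

#' Extract left-end phage-host junctions from reads
#'
#' Finds reads that contain the phage left end preceded by host DNA: the
#' terminal 20-mer of the phage left end is located by exact match (in the
#' read or its reverse complement), the downstream overlap with the phage is
#' verified at >= 95% identity, and the upstream portion of at least
#' `minHost` bases is reported as the host fragment. Reads matching both
#' phage ends are assigned to the end with the longer phage overlap; ties are
#' discarded and counted.
#'
#' @param reads a [ReadSet-class], `DNAStringSet` or character vector.
#' @param phage the phage [Genome-class].
#' @param minHost minimum host bases before the junction (default 12).
#' @param minPhageOverlap minimum phage bases after the junction (default 20).
#' @param maxMismatchFrac tolerated mismatch fraction in the phage overlap
#'   beyond the exact seed (default 0.05 = 95% identity).
#' @return data.frame with columns `read_id`, `end`, `host_fragment`,
#'   `start_mark`, `phage_overlap`; attribute `tally` counts skipped reads by
#'   reason.
#' @export
extractLeftJunctions <- function(reads, phage, minHost = 12L,
                                 minPhageOverlap = 20L,
                                 maxMismatchFrac = 0.05) {
  reads <- asReads(reads)
  phageSeq <- genomeSeq(phage)
  Lp <- genomeLength(phage)
  k <- 20L
  leftSeed <- Biostrings::DNAString(substr(phageSeq, 1L, k))
  rightSeed <- Biostrings::DNAString(substr(phageSeq, Lp - k + 1L, Lp))
  tooShortN <- 0L; noJunction <- 0L; lowIdentity <- 0L; shortHost <- 0L
  tiedEnds <- 0L

  wid <- Biostrings::width(reads)
  tooShort <- wid < minHost + minPhageOverlap
  tooShortN <- sum(tooShort)
  cand <- reads[!tooShort]

  process <- function(rs) {
    # returns data.frame of junction hits among reads rs (already oriented)
    sL <- firstMatchStart(leftSeed, rs)
    sR <- firstMatchStart(rightSeed, rs)
    found <- !is.na(sL)
    rows <- list()
    widr <- Biostrings::width(rs)
    for (i in which(found)) {
      s <- sL[i]
      ovl <- widr[i] - s + 1L
      # both-ends disambiguation: right-end overlap would be s..(match of
      # right seed) -- compare lengths when the right seed is also present
      if (!is.na(sR[i])) {
        ovR <- sR[i] + k - 1L  # phage suffix overlap length if right-end read
        if (ovR == ovl) { tiedEnds <<- tiedEnds + 1L; next }
        if (ovR > ovl) next  # belongs to the right end
      }
      if (s - 1L < minHost) { shortHost <<- shortHost + 1L; next }
      if (ovl < minPhageOverlap) { lowIdentity <<- lowIdentity + 1L; next }
      rseq <- as.character(rs[[i]])
      overlapSeq <- substr(rseq, s, widr[i])
      phPrefix <- substr(phageSeq, 1L, ovl)
      if (hammingStr(overlapSeq, phPrefix) > floor(maxMismatchFrac * ovl)) {
        lowIdentity <<- lowIdentity + 1L; next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        read_id = names(rs)[i], end = "left",
        host_fragment = substr(rseq, 1L, s - 1L),
        start_mark = 1L, phage_overlap = ovl, stringsAsFactors = FALSE)
    }
    list(rows = rows, found = found)
  }

  fwd <- process(cand)
  rcCand <- Biostrings::reverseComplement(cand[!fwd$found])
  rev <- process(rcCand)
  noJunction <- sum(!rev$found)
  rows <- c(fwd$rows, rev$rows)
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(read_id = character(0), end = character(0),
               host_fragment = character(0), start_mark = integer(0),
               phage_overlap = integer(0), stringsAsFactors = FALSE)
  attr(out, "tally") <- c(too_short = tooShortN, no_junction = noJunction,
                          low_identity = lowIdentity, short_host = shortHost,
                          tied_ends = tiedEnds)
  out
}

#' Filter valid right-end junction reads
#'
#' A read is valid iff it (or its reverse complement) starts precisely with
#' the phage right-end fragment released by the enrichment digest -- exact
#' prefix match by default -- and at least `minHost` bases of flanking DNA
#' follow. Everything after the prefix is the host fragment. Rejected reads
#' are tallied by reason.
#'
#' @param reads a [ReadSet-class], `DNAStringSet` or character vector.
#' @param rightEndSeq the right-end phage fragment (181 bp in the modelled
#'   enrichment design).
#' @param minHost minimum flanking bases after the prefix (default 12).
#' @param maxMismatch substitutions tolerated inside the prefix (default 0,
#'   reading "starting precisely" strictly).
#' @return data.frame with columns `read_id`, `end`, `host_fragment`,
#'   `start_mark`, `phage_overlap`; attribute `tally` with rejection counts.
#' @export
filterValidRight <- function(reads, rightEndSeq, minHost = 12L,
                             maxMismatch = 0L) {
  reads <- asReads(reads)
  rightEndSeq <- toupper(as.character(rightEndSeq))
  w <- nchar(rightEndSeq)
  if (w < 20L) stop("rightEndSeq implausibly short")
  wid <- Biostrings::width(reads)

  prefixMatches <- function(px) {
    if (maxMismatch == 0L) px == rightEndSeq
    else vapply(px, function(p) hammingStr(p, rightEndSeq) <= maxMismatch,
                logical(1), USE.NAMES = FALSE)
  }

  longEnough <- wid >= w + minHost
  atLeastPrefix <- wid >= w
  ok <- logical(length(reads))
  hostFrag <- character(length(reads))
  # forward orientation
  idx <- which(atLeastPrefix)
  px <- substring(as.character(reads[idx]), 1L, w)
  hitF <- prefixMatches(px)
  # reverse complement for the rest
  idxR <- idx[!hitF]
  rc <- character(0)
  hitR <- logical(0)
  if (length(idxR)) {
    rc <- as.character(Biostrings::reverseComplement(reads[idxR]))
    hitR <- prefixMatches(substring(rc, 1L, w))
  }
  matched <- logical(length(reads))
  matched[idx[hitF]] <- TRUE
  matched[idxR[hitR]] <- TRUE
  seqOf <- character(length(reads))
  seqOf[idx[hitF]] <- as.character(reads[idx[hitF]])
  seqOf[idxR[hitR]] <- rc[hitR]

  valid <- matched & longEnough
  tally <- c(
    too_short = sum(!atLeastPrefix),
    prefix_mismatch = sum(atLeastPrefix & !matched),
    host_too_short = sum(matched & !longEnough)
  )
  nv <- sum(valid)
  out <- data.frame(
    read_id = names(reads)[valid], end = rep("right", nv),
    host_fragment = substring(seqOf[valid], w + 1L),
    start_mark = rep(w + 1L, nv),
    phage_overlap = rep(w, nv), stringsAsFactors = FALSE)
  attr(out, "tally") <- tally
  out
}

#' Trim junction reads to their host fragment
#'
#' Emits the host fragment of each junction read with the start annotation
#' reset to the fragment origin and read provenance retained, ready for
#' placement on a reference genome.
#'
#' @param junctions data.frame from [extractLeftJunctions()] or
#'   [filterValidRight()].
#' @return data.frame with columns `fragment`, `read_id`, `end`,
#'   `start_mark` (0 on the fragment scale).
#' @export
trimAndAnnotate <- function(junctions) {
  data.frame(fragment = junctions$host_fragment,
             read_id = junctions$read_id,
             end = junctions$end,
             start_mark = 0L,
             stringsAsFactors = FALSE)
}

#' Chimera control by mapping onto truncated phage genomes
#'
#' PCR chimeras formed during library preparation can mimic phage-host
#' junctions. Their rate is bounded by mapping the read set onto phage
#' genomes truncated at the left end: reads that appear to carry a junction
#' at an artificial end, with an overhang that places on the host genome, are
#' candidate chimeras. The bona fide left-end junction count provides the
#' comparison point.
#'
#' @param reads a [ReadSet-class] or `DNAStringSet`.
#' @param phage the phage [Genome-class].
#' @param truncations left-end truncations in bp
#'   (default 1000, 10000, 20000, 30000).
#' @param host the host [Genome-class] used to place candidate overhangs.
#' @param minHost,minPhageOverlap as in [extractLeftJunctions()].
#' @return list with `truncation_offsets`, `candidates_per_end` (named
#'   integer), `bona_fide_junctions`.
#' @export
chimeraControl <- function(reads, phage, truncations = c(1000L, 10000L,
                                                         20000L, 30000L),
                           host, minHost = 12L, minPhageOverlap = 20L) {
  truncations <- as.integer(truncations)
  if (any(truncations >= genomeLength(phage)))
    stop("truncations must be smaller than the phage genome")
  reads <- asReads(reads)
  bona <- nrow(extractLeftJunctions(reads, phage, minHost = minHost,
                                    minPhageOverlap = minPhageOverlap))
  idx <- buildIndex(host)
  phageSeq <- genomeSeq(phage)
  cand <- integer(length(truncations))
  names(cand) <- paste0("minus_", truncations, "bp")
  for (i in seq_along(truncations)) {
    t <- truncations[i]
    trunc <- Genome(paste0(genomeName(phage), "_trunc", t),
                    substr(phageSeq, t + 1L, genomeLength(phage)),
                    circular = FALSE)
    j <- extractLeftJunctions(reads, trunc, minHost = minHost,
                              minPhageOverlap = minPhageOverlap)
    if (!nrow(j)) next
    # overhang must place on the host genome to count as a pseudo-junction
    pl <- placeFragments(j$host_fragment, idx)
    cand[i] <- sum(pl$status == "unique")
  }
  list(truncation_offsets = truncations,
       candidates_per_end = cand,
       bona_fide_junctions = bona)
}
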