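# Degenerate consensus construction over hotspot flanks and IUPAC motif
# scanning with mismatch tolerance.

IUPAC_SETS <- local({
  map <- Biostrings::IUPAC_CODE_MAP
  lapply(map, function(x) strsplit(x, "")[[1]])
})

iupacCode <- function(bases) {
  bases <- sort(unique(bases))
  key <- paste(bases, collapse = "")
  hit <- names(Biostrings::IUPAC_CODE_MAP)[Biostrings::IUPAC_CODE_MAP == key]
  if (!length(hit)) stop("no IUPAC code for base set ", key)
  hit[1L]
}

# 4 x m logical matrix: does base (A,C,G,T) belong to motif column j's set
iupacMatrix <- function(motif) {
  cols <- strsplit(toupper(motif), "")[[1]]
  bad <- setdiff(cols, names(IUPAC_SETS))
  if (length(bad)) stop("invalid IUPAC character(s): ", paste(bad, collapse = ""))
  vapply(cols, function(cd) DNA_BASES %in% IUPAC_SETS[[cd]], logical(4))
}

#' Scan a genome for a degenerate (IUPAC) motif with mismatch tolerance
#'
#' A window matches iff the number of positions whose genome base is not a
#' member of the IUPAC set of the corresponding motif base is at most
#' `maxMismatches`. Both strands are scanned by default; overlapping hits on
#' opposite strands at the same locus are deduplicated to the
#' fewer-mismatches hit (ties keep the plus strand).
#'
#' @param genome a [Genome-class] (circular genomes are scanned across the
#'   origin).
#' @param motif a [ConsensusMotif-class] or IUPAC string.
#' @param maxMismatches tolerance (default 3).
#' @param bothStrands scan the minus strand too (default TRUE).
#' @param dedupe collapse overlapping opposite-strand hits (default TRUE).
#' @return data.frame with `position` (1-based plus-strand start), `strand`
#'   ("+"/"-") and `mismatches`; attribute `motifLength`.
#' @export
scanIUPAC <- function(genome, motif, maxMismatches = 3L, bothStrands = TRUE,
                      dedupe = TRUE) {
  iupac <- if (is(motif, "ConsensusMotif")) motifString(motif) else
    toupper(as.character(motif))
  m <- nchar(iupac)
  L <- genomeLength(genome)
  if (m > L) stop("motif longer than the genome")
  s <- genomeSeq(genome)
  if (isCircular(genome)) s <- paste0(s, substr(s, 1L, m - 1L))
  code <- match(strsplit(s, "")[[1]], DNA_BASES)
  n <- nchar(s) - m + 1L

  scanOne <- function(iu, strandLab) {
    mat <- iupacMatrix(iu)
    mism <- integer(n)
    for (j in seq_len(m)) {
      ok <- mat[, j][code[j:(n + j - 1L)]]
      mism <- mism + as.integer(!ok)
    }
    hit <- which(mism <= maxMismatches)
    hit <- hit[hit <= L]  # circular duplicates beyond the origin
    data.frame(position = hit, strand = rep(strandLab, length(hit)),
               mismatches = mism[hit], stringsAsFactors = FALSE)
  }

  hits <- scanOne(iupac, "+")
  if (bothStrands) {
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(iupac)))
    hits <- rbind(hits, scanOne(rc, "-"))
  }
  hits <- hits[order(hits$mismatches, hits$strand, hits$position), , drop = FALSE]
  if (dedupe && nrow(hits) > 1L) {
    keep <- logical(nrow(hits))
    kept <- data.frame(position = integer(0), strand = character(0))
    for (i in seq_len(nrow(hits))) {
      p <- hits$position[i]
      clash <- kept$strand != hits$strand[i] & abs(kept$position - p) < m / 2
      if (!any(clash)) {
        keep[i] <- TRUE
        kept <- rbind(kept, hits[i, c("position", "strand")])
      }
    }
    hits <- hits[keep, , drop = FALSE]
  }
  hits <- hits[order(hits$position), , drop = FALSE]
  rownames(hits) <- NULL
  attr(hits, "motifLength") <- m
  hits
}

#' Build a degenerate consensus from hotspot flanks
#'
#' Finds the best-conserved gapless block shared by the flanks: a seed k-mer
#' present in a majority of flanks anchors an ungapped column-wise alignment,
#' which is extended outwards while each column remains well conserved (at
#' most two bases at or above the `ambiguityRule` frequency, together
#' covering at least 75% of the flanks) and trimmed of
#' highly degenerate terminal columns. Each column's IUPAC code covers every
#' base whose frequency reaches `ambiguityRule`.
#'
#' @param flanks character vector of flank sequences (>= 2).
#' @param minBlock minimum block length to accept (default 20).
#' @param ambiguityRule column frequency threshold for inclusion in the code
#'   (default 0.25).
#' @param seedK seed k-mer length (default 12).
#' @return a [ConsensusMotif-class]; `offsets` give the 1-based block start
#'   within each flank (NA where the seed is absent), `flagged` is TRUE when
#'   no shared block of `minBlock` bp exists.
#' @export
buildConsensus <- function(flanks, minBlock = 20L, ambiguityRule = 0.25,
                           seedK = 12L) {
  stopifnot(length(flanks) >= 2L)
  flanks <- toupper(flanks)
  n <- length(flanks)
  noMotif <- new("ConsensusMotif", iupac = "",
                 offsets = rep(NA_integer_, n), flagged = TRUE)
  # seed: the k-mer present in the largest number of flanks (majority needed)
  kmersOf <- function(s) {
    l <- nchar(s)
    if (l < seedK) return(character(0))
    unique(substring(s, 1:(l - seedK + 1L), seedK:l))
  }
  tab <- table(unlist(lapply(flanks, kmersOf)))
  if (!length(tab)) return(noMotif)
  best <- max(tab)
  if (best < ceiling(n / 2)) return(noMotif)
  seed <- sort(names(tab)[tab == best])[1L]
  anchor <- vapply(flanks, function(s) {
    p <- regexpr(seed, s, fixed = TRUE)
    if (p < 0L) NA_integer_ else as.integer(p)
  }, integer(1), USE.NAMES = FALSE)
  used <- which(!is.na(anchor))
  # column base frequencies at offset d from the seed start
  colBases <- function(d) {
    p <- anchor[used] + d
    ok <- p >= 1L & p <= nchar(flanks[used])
    substring(flanks[used][ok], p[ok], p[ok])
  }
  colAgreement <- function(d) {
    # joint frequency of the two commonest bases (columns of a gapless
    # conserved block are mono- or dimorphic)
    b <- colBases(d)
    if (length(b) < length(used)) return(0)  # ran off a flank
    fr <- sort(table(b) / length(b), decreasing = TRUE)
    if (sum(fr >= ambiguityRule) > 2L) return(0)
    sum(fr[seq_len(min(2L, length(fr)))])
  }
  lo <- 0L
  while (colAgreement(lo - 1L) >= 0.75) lo <- lo - 1L
  hi <- seedK - 1L
  while (colAgreement(hi + 1L) >= 0.75) hi <- hi + 1L
  agree <- vapply(lo:hi, colAgreement, numeric(1))
  codes <- vapply(lo:hi, function(d) {
    b <- colBases(d)
    fr <- table(b) / length(b)
    iupacCode(names(fr)[fr >= ambiguityRule])
  }, character(1))
  # trim terminal columns less conserved than the seed's own worst column
  # (or highly degenerate), so the block does not creep into background
  trimThr <- min(agree[(1L - lo):(seedK - lo)])
  weak <- agree < trimThr |
    vapply(codes, function(cd) length(IUPAC_SETS[[cd]]) >= 3L, logical(1))
  first <- which(!weak)[1L]
  last <- length(codes) + 1L - which(rev(!weak))[1L]
  if (is.na(first) || last - first + 1L < minBlock) return(noMotif)
  codes <- codes[first:last]
  offsets <- anchor + (lo + first - 1L)
  new("ConsensusMotif", iupac = paste(codes, collapse = ""),
      offsets = as.integer(offsets), flagged = FALSE)
}
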