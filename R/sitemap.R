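# Placement of trimmed host fragments on a reference genome by exact-seed
# lookup and ungapped extension (with a gapped fallback), and construction of
# the per-position, per-orientation SiteTable.

#' SeedIndex: exact k-mer index of a reference genome
#'
#' @slot k seed length.
#' @slot refName,refLength,circular reference description.
#' @slot seqChar reference sequence (plus strand) as a character string.
#' @slot env hashed environment mapping each k-mer to its plus-strand start
#'   positions (wrap-around k-mers included for circular references).
#' @export
setClass("SeedIndex", representation(
  k = "integer",
  refName = "character",
  refLength = "integer",
  circular = "logical",
  seqChar = "character",
  env = "environment"
))

setMethod("show", "SeedIndex", function(object) {
  cat(sprintf("SeedIndex on '%s': %s bp, k = %d, %s\n", object@refName,
              format(object@refLength, big.mark = ","), object@k,
              if (object@circular) "circular" else "linear"))
})

#' Build a seed index for fragment placement
#'
#' Indexes every k-mer of the reference plus strand (honouring circularity);
#' minus-strand placements are found by querying the reverse complement of the
#' fragment.
#'
#' @param reference a [Genome-class].
#' @param k seed length (default 15); must not exceed the shortest fragment.
#' @return a [SeedIndex-class].
#' @export
buildIndex <- function(reference, k = 15L) {
  k <- as.integer(k)
  s <- genomeSeq(reference)
  L <- genomeLength(reference)
  if (k > L) stop("k larger than the reference")
  circ <- isCircular(reference)
  sExt <- if (circ) paste0(s, substr(s, 1L, k - 1L)) else s
  n <- if (circ) L else L - k + 1L
  kmers <- substring(sExt, seq_len(n), seq_len(n) + k - 1L)
  env <- list2env(split(seq_len(n), kmers), hash = TRUE)
  new("SeedIndex", k = k, refName = genomeName(reference),
      refLength = L, circular = circ, seqChar = s, env = env)
}

#' Look up a k-mer in a seed index
#'
#' @param index a [SeedIndex-class].
#' @param kmer character string of length `index@k`.
#' @return integer vector of plus-strand start positions (possibly empty).
#' @export
lookupKmer <- function(index, kmer) {
  hit <- index@env[[kmer]]
  if (is.null(hit)) integer(0) else hit
}

#' Place host fragments on a reference genome
#'
#' Seed-and-extend placement: exact k-mer seeds (three per query: start,
#' middle, end; both strands) propose candidate locations which are verified
#' by ungapped comparison. A candidate passes iff mismatches
#' <= floor(maxMismatchFrac x length), gaps <= floor(maxGapFrac x length) and
#' identity >= minIdentity (fractional limits floored per fragment, so 2% of
#' a 34 bp flank allows 0 mismatches). When no ungapped candidate passes and
#' the gap budget is positive, a gapped alignment against the candidate
#' window is attempted. A fragment is `unique` iff exactly one best-scoring
#' location passes, `ambiguous` for several, `unmapped` otherwise.
#'
#' @param fragments character vector (or DNAStringSet) of fragments.
#' @param index a [SeedIndex-class] from [buildIndex()].
#' @param maxMismatchFrac,maxGapFrac,minIdentity placement thresholds
#'   (defaults 0.02, 0.03, 0.95).
#' @return data.frame with one row per fragment: `fragment_id`, `status`
#'   ("unique"/"ambiguous"/"unmapped"), `strand` ("+"/"-"), `alignStart`,
#'   `alignEnd` (plus-strand coordinates of the placed span), `mismatches`,
#'   `gaps`.
#' @export
placeFragments <- function(fragments, index, maxMismatchFrac = 0.02,
                           maxGapFrac = 0.03, minIdentity = 0.95) {
  if (is(fragments, "DNAStringSet")) fragments <- as.character(fragments)
  n <- length(fragments)
  ids <- names(fragments)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  out <- data.frame(
    fragment_id = ids,
    status = rep("unmapped", n),
    strand = NA_character_,
    alignStart = NA_integer_,
    alignEnd = NA_integer_,
    mismatches = NA_integer_,
    gaps = NA_integer_,
    stringsAsFactors = FALSE
  )
  if (!n) return(out)
  if (any(!nzchar(fragments))) stop("empty fragment")
  L <- index@refLength
  circ <- index@circular
  # placement depends only on the sequence: compute once per distinct fragment
  uf <- unique(fragments)
  ufIdx <- match(fragments, uf)
  rcAll <- revcompChar(uf)
  nu <- length(uf)
  mlen <- nchar(uf)
  k <- index@k

  # bulk seed lookup: three offsets (start/middle/end) on both strands
  candU <- integer(0); candStrand <- character(0); candStart <- integer(0)
  for (strand in c("+", "-")) {
    qs <- if (strand == "+") uf else rcAll
    for (j in 1:3) {
      off <- switch(j, rep(1L, nu), (mlen - k) %/% 2L + 1L, mlen - k + 1L)
      valid <- which(mlen >= k & off >= 1L)
      if (!length(valid)) next
      keys <- substr(qs[valid], off[valid], off[valid] + k - 1L)
      hits <- mget(keys, envir = index@env, ifnotfound = list(NULL))
      nh <- lengths(hits)
      if (!sum(nh)) next
      candU <- c(candU, rep(valid, nh))
      candStrand <- c(candStrand, rep(strand, sum(nh)))
      candStart <- c(candStart, unlist(hits, use.names = FALSE) -
                       rep(off[valid], nh) + 1L)
    }
  }
  dup <- duplicated(paste(candU, candStrand, candStart))
  candU <- candU[!dup]; candStrand <- candStrand[!dup]; candStart <- candStart[!dup]
  candEnd <- candStart + mlen[candU] - 1L
  if (!circ) {
    inb <- candStart >= 1L & candEnd <= L
    candU <- candU[inb]; candStrand <- candStrand[inb]
    candStart <- candStart[inb]; candEnd <- candEnd[inb]
  }

  # verify candidates: vectorised exact comparison, Hamming only where needed
  mmBudget <- pmin(floor(maxMismatchFrac * mlen), floor((1 - minIdentity) * mlen))
  gapBudget <- floor(maxGapFrac * mlen)
  query <- ifelse(candStrand == "+", uf[candU], rcAll[candU])
  ref <- substrVec(index@seqChar, candStart, candEnd, L, circ)
  mm <- integer(length(candU))
  ne <- which(ref != query)
  mm[ne] <- vapply(ne, function(i) hammingStr(query[i], ref[i]), integer(1))

  # per-fragment best passing candidate (ungapped)
  resStatus <- rep("unmapped", nu)
  resStrand <- rep(NA_character_, nu); resStart <- rep(NA_integer_, nu)
  resEnd <- rep(NA_integer_, nu); resMM <- rep(NA_integer_, nu)
  resGaps <- rep(NA_integer_, nu)
  pass <- which(mm <= mmBudget[candU])
  if (length(pass)) {
    pu <- candU[pass]
    o <- pass[order(pu, mm[pass])]
    pu_s <- candU[o]
    firstIdx <- which(!duplicated(pu_s))
    bestRow <- o[firstIdx]
    uBest <- candU[bestRow]
    # ambiguous iff several candidates tie at the best score
    bestOfU <- mm[bestRow][match(pu_s, uBest)]
    nBest <- as.integer(table(factor(pu_s[mm[o] == bestOfU], levels = uBest)))
    resStatus[uBest] <- ifelse(nBest > 1L, "ambiguous", "unique")
    resStrand[uBest] <- candStrand[bestRow]
    resStart[uBest] <- candStart[bestRow]
    resEnd[uBest] <- candEnd[bestRow]
    resMM[uBest] <- mm[bestRow]
    resGaps[uBest] <- 0L
  }

  # gapped fallback for fragments whose seeds hit but no ungapped candidate
  # passed and whose gap budget allows indels
  need <- setdiff(unique(candU), which(resStatus != "unmapped"))
  need <- need[gapBudget[need] >= 1L]
  for (u in need) {
    rows <- which(candU == u)
    m <- mlen[u]
    passL <- list()
    for (ci in rows) {
      q <- if (candStrand[ci] == "+") uf[u] else rcAll[u]
      lo <- candStart[ci] - gapBudget[u]; hi <- candStart[ci] + m - 1L + gapBudget[u]
      if (!circ) { lo <- max(1L, lo); hi <- min(L, hi) }
      win <- substrCirc(index@seqChar, lo, hi, L, circ)
      al <- Biostrings::pairwiseAlignment(q, win, type = "global-local")
      mmi <- Biostrings::nmismatch(al)
      gp <- sum(Biostrings::nindel(al)@insertion[, "WidthSum"],
                Biostrings::nindel(al)@deletion[, "WidthSum"])
      ident <- Biostrings::pid(al) / 100
      if (mmi <= mmBudget[u] && gp <= gapBudget[u] && ident >= minIdentity) {
        passL[[length(passL) + 1L]] <- list(
          strand = candStrand[ci],
          start = lo + Biostrings::start(Biostrings::subject(al)) - 1L,
          end = lo + Biostrings::end(Biostrings::subject(al)) - 1L,
          mm = mmi, gaps = gp)
      }
    }
    if (length(passL)) {
      scores <- vapply(passL, function(c) c$mm + c$gaps, numeric(1))
      best <- passL[scores == min(scores)]
      b <- best[[1L]]
      resStatus[u] <- if (length(best) == 1L) "unique" else "ambiguous"
      resStrand[u] <- b$strand
      resStart[u] <- as.integer(b$start)
      resEnd[u] <- as.integer(b$end)
      resMM[u] <- as.integer(b$mm)
      resGaps[u] <- as.integer(b$gaps)
    }
  }

  out$status <- resStatus[ufIdx]
  out$strand <- resStrand[ufIdx]
  out$alignStart <- resStart[ufIdx]
  out$alignEnd <- resEnd[ufIdx]
  out$mismatches <- resMM[ufIdx]
  out$gaps <- resGaps[ufIdx]
  out
}

#' Build a SiteTable from fragment placements
#'
#' Only uniquely placed fragments contribute. The recorded junction position
#' is the first host base adjacent to the phage end: for right-end fragments
#' the low coordinate of a plus-strand placement and the high coordinate of a
#' minus-strand one; mirrored for left-end fragments. Plus-strand placements
#' are "forward" integrations, minus-strand ones "reverse".
#'
#' @param placements data.frame from [placeFragments()]; an optional `end`
#'   column ("left"/"right", e.g. merged from [trimAndAnnotate()] provenance)
#'   overrides the `end` argument per fragment.
#' @param reference the [Genome-class] the placements refer to.
#' @param end which phage end the fragments flank ("right" default).
#' @return a [SiteTable-class]; attribute `tally` counts
#'   unique/ambiguous/unmapped fragments.
#' @export
buildSiteTable <- function(placements, reference, end = c("right", "left")) {
  end <- match.arg(end)
  endVec <- if ("end" %in% names(placements)) placements$end else
    rep(end, nrow(placements))
  uq <- placements$status == "unique"
  pl <- placements[uq, , drop = FALSE]
  ev <- endVec[uq]
  plus <- pl$strand == "+"
  rightish <- ev == "right"
  junction <- ifelse(plus == rightish, pl$alignStart, pl$alignEnd)
  if (isCircular(reference) && length(junction))
    junction <- wrapPos(as.integer(junction), genomeLength(reference))
  orientation <- ifelse(plus, "forward", "reverse")
  tab <- SiteTable(junction, orientation, refName = genomeName(reference),
                   refLength = genomeLength(reference),
                   circular = isCircular(reference))
  attr(tab, "tally") <- c(unique = sum(uq),
                          ambiguous = sum(placements$status == "ambiguous"),
                          unmapped = sum(placements$status == "unmapped"))
  tab
}

#' Build a SiteTable directly from simulated events
#'
#' Convenience constructor for ground-truth comparisons and for analyses that
#' start from an event table rather than reads.
#'
#' @param events data.frame from [sampleInsertions()].
#' @param reference the target [Genome-class].
#' @param target which events to keep: "host" or "phage-copy".
#' @return a [SiteTable-class].
#' @export
siteTableFromEvents <- function(events, reference,
                                target = c("host", "phage-copy")) {
  target <- match.arg(target)
  ev <- events[events$target == target, , drop = FALSE]
  SiteTable(ev$position, ev$orientation, refName = genomeName(reference),
            refLength = genomeLength(reference),
            circular = isCircular(reference))
}
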