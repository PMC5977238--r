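# Self-insertion analysis on the phage genome: binned profile, domain
# segmentation at sharp boundary peaks, loop pairing, and the protected
# (transposition-free) central gap.

#' Bin a phage SiteTable into fixed-width bins
#'
#' @param table a [SiteTable-class] on the phage genome.
#' @param bin bin width in bp (default 50).
#' @return data.frame with columns `bin`, `start`, `end`, `forward`,
#'   `reverse`, `total`; attribute `bin` records the width.
#' @export
binProfile <- function(table, bin = 50L) {
  bin <- as.integer(bin)
  L <- refLength(table)
  nb <- ceiling(L / bin)
  fwd <- integer(nb); rev <- integer(nb)
  cc <- siteCounts(table)
  if (nrow(cc)) {
    b <- (cc$position - 1L) %/% bin + 1L
    isF <- cc$orientation == "forward"
    aggF <- tapply(cc$count[isF], b[isF], sum)
    aggR <- tapply(cc$count[!isF], b[!isF], sum)
    fwd[as.integer(names(aggF))] <- aggF
    rev[as.integer(names(aggR))] <- aggR
  }
  out <- data.frame(bin = seq_len(nb),
                    start = (seq_len(nb) - 1L) * bin + 1L,
                    end = pmin(seq_len(nb) * bin, L),
                    forward = fwd, reverse = rev, total = fwd + rev)
  attr(out, "bin") <- bin
  attr(out, "refLength") <- L
  out
}

# rolling median over bins, NA-tolerant, clamped at the ends
rollingMedian <- function(x, half = 10L) {
  n <- length(x)
  vapply(seq_len(n), function(i) {
    w <- x[max(1L, i - half):min(n, i + half)]
    stats::median(w, na.rm = TRUE)
  }, numeric(1))
}

#' Segment the phage genome into insertion-density domains
#'
#' Domain boundaries are sharp local maxima of the binned profile: bins whose
#' count exceeds `q` times the running median (floored at one event), kept at
#' a minimum mutual separation. Bins inside `exclusionZones` (e.g. the
#' artifact peaks flanking a restriction site used for enrichment) are masked
#' before peak calling. Domains are the inter-peak intervals plus the two
#' terminal intervals; domain event counts exclude boundary and masked bins,
#' which are reported separately.
#'
#' @param profile data.frame from [binProfile()].
#' @param q peak threshold as a multiple of the running median (default 5).
#' @param minSeparation minimum bins between boundary peaks (default 10).
#' @param medianHalfWidth half-width of the running-median window in bins
#'   (default 10).
#' @param exclusionZones list of `c(start, end)` bp spans to mask.
#' @param nBoundaries keep only the strongest n peaks (`NULL` = all).
#' @return data.frame with one row per domain: `label`, `start`, `end`,
#'   `count`, `density` (events/kb); attributes `boundaries` (bp),
#'   `boundaryEvents`, `maskedEvents`, and `flagged` (TRUE when no peak was
#'   found and a single domain is returned).
#' @export
segmentDomains <- function(profile, q = 5, minSeparation = 10L,
                           medianHalfWidth = 10L, exclusionZones = NULL,
                           nBoundaries = NULL) {
  stopifnot(nrow(profile) >= 2L)
  binw <- attr(profile, "bin")
  L <- attr(profile, "refLength")
  if (is.null(L)) L <- max(profile$end)
  x <- profile$total
  masked <- logical(length(x))
  if (!is.null(exclusionZones)) {
    for (z in exclusionZones)
      masked <- masked | (profile$end >= z[1L] & profile$start <= z[2L])
  }
  xm <- ifelse(masked, NA_real_, as.numeric(x))
  med <- rollingMedian(xm, half = as.integer(medianHalfWidth))
  thr <- q * pmax(med, 1)
  candIdx <- which(!masked & !is.na(xm) & xm > thr)
  # greedy separation: strongest peaks first
  candIdx <- candIdx[order(-x[candIdx], candIdx)]
  peaks <- integer(0)
  for (i in candIdx) {
    if (!length(peaks) || all(abs(peaks - i) >= minSeparation)) peaks <- c(peaks, i)
  }
  if (!is.null(nBoundaries) && length(peaks) > nBoundaries)
    peaks <- peaks[seq_len(nBoundaries)]
  peaks <- sort(peaks)
  flagged <- length(peaks) == 0L

  # domains tile the genome exactly; a boundary is the end of its peak bin,
  # the peak bin itself counting towards neither domain's events
  bStart <- profile$start[peaks]
  bEnd <- profile$end[peaks]
  domStart <- c(1L, bEnd + 1L)
  domEnd <- c(bEnd, L)
  k <- length(domStart)
  labels <- paste0("D", seq_len(k))
  binMid <- (profile$start + profile$end) / 2
  domOf <- findInterval(binMid, c(domStart, L + 1L))
  inPeak <- seq_along(x) %in% peaks
  counts <- vapply(seq_len(k), function(d) {
    sum(x[domOf == d & !masked & !inPeak])
  }, numeric(1))
  lens <- domEnd - domStart + 1L
  out <- data.frame(label = labels, start = domStart, end = domEnd,
                    count = as.integer(counts),
                    density = counts / (lens / 1000),
                    stringsAsFactors = FALSE)
  attr(out, "boundaries") <- as.integer(round((bStart + bEnd) / 2))
  attr(out, "boundaryEvents") <- sum(x[setdiff(peaks, which(masked))])
  attr(out, "maskedEvents") <- sum(x[masked])
  attr(out, "flagged") <- flagged
  out
}

#' Events per kilobase of a domain
#'
#' @param count event count.
#' @param lengthBp span length in bp.
#' @return density in events/kb.
#' @examples
#' domainDensity(9594, 7200)  # ~1332 events/kb
#' @export
domainDensity <- function(count, lengthBp) {
  stopifnot(lengthBp > 0)
  count / (lengthBp / 1000)
}

#' Pair phage domains into supercoiled loops
#'
#' Excluding the two terminal domains, the remaining (odd-count) interior
#' domains are paired outermost-inward: the second domain with the
#' second-to-last, and so on; the central domain forms the apex loop on its
#' own. Per-loop event shares are computed from the domain counts.
#'
#' @param domains data.frame from [segmentDomains()] (needs `label`, `count`).
#' @return a [LoopModel-class].
#' @export
pairLoops <- function(domains) {
  k <- nrow(domains)
  if (k < 3L) stop("need at least three domains (two terminal + interior)")
  interior <- domains[2:(k - 1L), , drop = FALSE]
  m <- nrow(interior)
  if (m %% 2L == 0L)
    stop("interior domain count must be odd to pair into loops around an apex")
  nPairs <- (m - 1L) %/% 2L
  rows <- lapply(seq_len(nPairs), function(j) {
    up <- interior[j, ]; dn <- interior[m + 1L - j, ]
    tot <- up$count + dn$count
    data.frame(loop = paste0("L", j), upstream = up$label,
               downstream = dn$label,
               upstreamCount = up$count, downstreamCount = dn$count,
               upstreamShare = up$count / tot, downstreamShare = dn$count / tot,
               stringsAsFactors = FALSE)
  })
  apex <- interior[nPairs + 1L, ]
  rows[[nPairs + 1L]] <- data.frame(
    loop = paste0("L", nPairs + 1L), upstream = apex$label,
    downstream = NA_character_, upstreamCount = apex$count,
    downstreamCount = NA_integer_, upstreamShare = 1, downstreamShare = NA_real_,
    stringsAsFactors = FALSE)
  new("LoopModel", loops = do.call(rbind, rows), apex = apex$label)
}

#' Locate the protected (transposition-free) gap near the phage middle
#'
#' Scans a window around the genome midpoint for maximal runs of positions
#' with zero events of length at least `minGap` bp -- the signature of a
#' protected core such as a strong gyrase site.
#'
#' @param table a [SiteTable-class] on the phage genome.
#' @param minGap minimum zero-event run length in bp (default 30).
#' @param searchCenter centre of the search window as a genome fraction
#'   (default 0.5).
#' @param searchRadius half-width of the search window in bp (default 1000).
#' @return data.frame with columns `start`, `end`, `length` and
#'   `offsetFromMiddle` (bp from the exact genome middle to the gap centre);
#'   attribute `uninformative` is TRUE when the whole window is event-free.
#' @export
protectedGap <- function(table, minGap = 30L, searchCenter = 0.5,
                         searchRadius = 1000L) {
  L <- refLength(table)
  mid <- round(searchCenter * L)
  lo <- max(1L, mid - as.integer(searchRadius))
  hi <- min(L, mid + as.integer(searchRadius))
  occ <- logical(hi - lo + 1L)
  cc <- siteCounts(table)
  inWin <- cc$position >= lo & cc$position <= hi
  occ[cc$position[inWin] - lo + 1L] <- TRUE
  if (!any(occ)) {
    out <- data.frame(start = lo, end = hi, length = hi - lo + 1L,
                      offsetFromMiddle = round((lo + hi) / 2 - L / 2))
    attr(out, "uninformative") <- TRUE
    return(out)
  }
  r <- rle(occ)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  zero <- which(!r$values & r$lengths >= minGap)
  out <- data.frame(
    start = lo + starts[zero] - 1L,
    end = lo + ends[zero] - 1L,
    length = r$lengths[zero],
    offsetFromMiddle = round((lo + starts[zero] - 1L + lo + ends[zero] - 1L) / 2 - L / 2)
  )
  rownames(out) <- NULL
  attr(out, "uninformative") <- FALSE
  out
}
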