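# Hotspot calling and flank extraction. Hotspots are single positions whose
# event count exceeds a threshold; nearby above-threshold positions (the
# paired forward/reverse peaks created by the target-site duplication) merge
# into one hotspot.

#' Call insertion hotspots
#'
#' Positions whose event count (orientations summed) reaches
#' `minEventsPerPosition` are hotspot peaks; peaks within `pairGap` bp of one
#' another merge into a single hotspot whose two strongest positions are
#' reported as the peak pair. When `referenceTotal` is supplied the threshold
#' auto-scales as `minEventsPerPosition x totalEvents(table)/referenceTotal`,
#' so scaled-down simulations remain comparable to a full-depth experiment.
#'
#' @param table a [SiteTable-class].
#' @param minEventsPerPosition per-position event threshold (default 3000, a
#'   full-depth 13-million-event experiment's value).
#' @param pairGap maximum bp between merged peaks (default 20).
#' @param referenceTotal event total at which `minEventsPerPosition` is
#'   calibrated (e.g. 13.4e6); `NULL` disables auto-scaling.
#' @return data.frame with one row per hotspot: `rank`, `peak1`, `peak2`
#'   (NA for single peaks), `start`, `end`, `eventCount`, `forwardRatio`;
#'   attribute `threshold` records the threshold used.
#' @export
callHotspots <- function(table, minEventsPerPosition = 3000, pairGap = 20L,
                         referenceTotal = NULL) {
  thr <- minEventsPerPosition
  if (!is.null(referenceTotal))
    thr <- minEventsPerPosition * totalEvents(table) / referenceTotal
  cc <- siteCounts(table)
  empty <- data.frame(rank = integer(0), peak1 = integer(0), peak2 = integer(0),
                      start = integer(0), end = integer(0),
                      eventCount = integer(0), forwardRatio = numeric(0))
  attr(empty, "threshold") <- thr
  if (!nrow(cc)) return(empty)
  tot <- tapply(cc$count, cc$position, sum)
  pos <- as.integer(names(tot))
  hot <- pos[tot >= thr]
  if (!length(hot)) return(empty)
  hot <- sort(hot)
  grp <- cumsum(c(1L, as.integer(diff(hot) > pairGap)))
  rows <- lapply(split(hot, grp), function(p) {
    span <- c(min(p), max(p))
    inSpan <- cc$position >= span[1L] & cc$position <= span[2L]
    cnt <- sum(cc$count[inSpan])
    fwd <- sum(cc$count[inSpan & cc$orientation == "forward"])
    pk <- p[order(-tot[as.character(p)], p)]
    data.frame(peak1 = pk[1L], peak2 = if (length(pk) > 1L) pk[2L] else NA_integer_,
               start = span[1L], end = span[2L], eventCount = cnt,
               forwardRatio = fwd / cnt)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$eventCount), , drop = FALSE]
  out <- cbind(rank = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  attr(out, "threshold") <- thr
  out
}

#' Extract the sequences flanking a hotspot
#'
#' Returns the `width` bp on each side of a hotspot span. Flanks wrap on
#' circular genomes; on linear genomes they are truncated at the ends and
#' flagged.
#'
#' @param hotspot one row of the [callHotspots()] result (or any list with
#'   `start` and `end`).
#' @param genome the reference [Genome-class].
#' @param width flank width in bp (default 280).
#' @return list with `left`, `right` (character), and logical `truncated`
#'   (named left/right).
#' @export
extractFlanks <- function(hotspot, genome, width = 280L) {
  width <- as.integer(width)
  L <- genomeLength(genome)
  if (width >= L) stop("flank width must be smaller than the genome")
  s <- as.integer(hotspot$start)
  e <- as.integer(hotspot$end)
  seqc <- genomeSeq(genome)
  truncated <- c(left = FALSE, right = FALSE)
  if (isCircular(genome)) {
    left <- substrCirc(seqc, s - width, s - 1L, L, TRUE)
    right <- substrCirc(seqc, e + 1L, e + width, L, TRUE)
  } else {
    lo <- max(1L, s - width)
    if (lo > s - 1L) { left <- "" } else left <- substr(seqc, lo, s - 1L)
    truncated["left"] <- (s - width) < 1L
    hi <- min(L, e + width)
    if (e + 1L > hi) { right <- "" } else right <- substr(seqc, e + 1L, hi)
    truncated["right"] <- (e + width) > L
  }
  list(left = left, right = right, truncated = truncated)
}

#' Quantify the motif-adjacent share of integration events
#'
#' Computes the fraction of all events falling within `window` bp of any
#' motif hit, and the fold bias of that share over the deduplicated footprint
#' of the motif windows (share / (covered bp / genome size)).
#'
#' @param table a [SiteTable-class].
#' @param hits data.frame from [scanIUPAC()] (needs `position`; motif length
#'   taken from the `motifLength` attribute or `motifLength` argument).
#' @param window bp added on each side of a hit (default 120).
#' @param motifLength motif length override.
#' @return list with `share`, `foldBias`, `coveredBp`.
#' @export
motifEventShare <- function(table, hits, window = 120L, motifLength = NULL) {
  if (is.null(motifLength)) motifLength <- attr(hits, "motifLength")
  if (is.null(motifLength)) stop("motifLength not available")
  N <- refLength(table)
  if (!nrow(hits)) return(list(share = 0, foldBias = 0, coveredBp = 0L))
  mask <- logical(N)
  lo <- pmax(1L, hits$position - as.integer(window))
  hi <- pmin(N, hits$position + as.integer(motifLength) - 1L + as.integer(window))
  for (i in seq_along(lo)) mask[lo[i]:hi[i]] <- TRUE
  cc <- siteCounts(table)
  share <- sum(cc$count[mask[cc$position]]) / totalEvents(table)
  covered <- sum(mask)
  list(share = share, foldBias = share / (covered / N),
       coveredBp = as.integer(covered))
}
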