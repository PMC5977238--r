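# Coincidence statistics: how many genome positions carry several independent
# integration events, compared with the closed-form random-placement model.

#' Expected coincidence spectrum under random placement
#'
#' For `nEvents` transposition events placed at random on a genome of
#' `genomeSize` positions, with R = nEvents/genomeSize, the expected number of
#' positions with two coincident events is E2 = nEvents x R / 2, and higher
#' orders follow the recurrence E(i+1) = ln(1/(1-R)) x Ei / (i+1). The
#' approximation is accurate for R below 0.1; larger ratios trigger a warning
#' but are still computed.
#'
#' @param nEvents total number of events (T).
#' @param genomeSize genome size in bp (N).
#' @param iMax highest multiplicity to report (default 5).
#' @return a [CoincidenceModel-class] with expectations E_2 .. E_iMax.
#' @examples
#' expectedCounts(expectedSpectrum(25000, 6.3e6))[c("2", "3")]
#' @export
expectedSpectrum <- function(nEvents, genomeSize, iMax = 5L) {
  stopifnot(nEvents > 0, genomeSize > 0, iMax >= 2L)
  R <- nEvents / genomeSize
  if (R >= 0.1)
    warning("R = T/N >= 0.1: the closed-form approximation is not valid there")
  E <- numeric(iMax - 1L)
  names(E) <- as.character(2:iMax)
  E[1L] <- nEvents * R / 2
  lf <- log(1 / (1 - R))
  if (iMax > 2L)
    for (i in 2:(iMax - 1L)) E[i] <- lf * E[i - 1L] / (i + 1L)
  new("CoincidenceModel", nEvents = nEvents, genomeSize = genomeSize,
      ratio = R, expected = E)
}

#' Observed coincidence spectrum of a SiteTable
#'
#' Counts, per genome position (orientations summed), how many positions
#' carry exactly i events and at least i events.
#'
#' @param table a [SiteTable-class].
#' @return a [CoincidenceSpectrum-class].
#' @export
observedSpectrum <- function(table) {
  cc <- siteCounts(table)
  if (!nrow(cc)) {
    return(new("CoincidenceSpectrum", observed = integer(0),
               atLeast = integer(0), total = 0L))
  }
  perPos <- tapply(cc$count, cc$position, sum)
  tab <- table(perPos)
  obs <- as.integer(tab)
  names(obs) <- names(tab)
  atLeast <- as.integer(rev(cumsum(rev(obs))))
  names(atLeast) <- names(obs)
  new("CoincidenceSpectrum", observed = obs, atLeast = atLeast,
      total = as.integer(sum(cc$count)))
}

#' Monte-Carlo coincidence check (balls in bins)
#'
#' Places `nEvents` events uniformly on `genomeSize` positions `reps` times
#' and reports the mean number of coincident pairs (which E2 = T R / 2
#' approximates) and the mean number of positions carrying at least two
#' events.
#'
#' @param nEvents,genomeSize events and genome size per replicate.
#' @param reps number of replicates.
#' @param seed RNG seed.
#' @return named numeric: `meanPairs`, `meanMulti` (positions with >= 2
#'   events), `sdPairs`.
#' @export
coincidenceMonteCarlo <- function(nEvents, genomeSize, reps = 10000L,
                                  seed = NULL) {
  withSeed(seed, {
    pairs <- numeric(reps)
    multi <- numeric(reps)
    for (r in seq_len(reps)) {
      tb <- tabulate(sample.int(genomeSize, nEvents, replace = TRUE),
                     nbins = genomeSize)
      occ <- tb[tb >= 2L]
      pairs[r] <- sum(choose(occ, 2))
      multi[r] <- length(occ)
    }
    c(meanPairs = mean(pairs), meanMulti = mean(multi), sdPairs = stats::sd(pairs))
  })
}

#' Event fraction and fold excess of a genome interval
#'
#' Reports which fraction of all events fall inside a 1-based inclusive
#' interval and the fold excess of that fraction over the interval's length
#' share of the genome (the uniform expectation).
#'
#' @param table a [SiteTable-class].
#' @param interval `c(start, end)`, 1-based inclusive, start <= end.
#' @param nEvents total event count (defaults to the table total).
#' @param genomeSize genome size (defaults to the table reference length).
#' @return list with `eventFraction`, `fold` and `eventsInInterval`.
#' @examples
#' # 22 events in a 34 bp window among 25,150 events is 0.09% of all events
#' @export
segmentFoldExcess <- function(table, interval, nEvents = NULL,
                              genomeSize = NULL) {
  stopifnot(length(interval) == 2L)
  s <- interval[1L]; e <- interval[2L]
  if (e < s) stop("empty interval")
  if (is.null(nEvents)) nEvents <- totalEvents(table)
  if (is.null(genomeSize)) genomeSize <- refLength(table)
  if (s < 1L || e > genomeSize) stop("interval outside the genome")
  cc <- siteCounts(table)
  inEv <- sum(cc$count[cc$position >= s & cc$position <= e])
  if (inEv == 0L) return(list(eventFraction = 0, fold = 0, eventsInInterval = 0L))
  frac <- inEv / nEvents
  fold <- frac / ((e - s + 1) / genomeSize)
  list(eventFraction = frac, fold = fold, eventsInInterval = as.integer(inEv))
}
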