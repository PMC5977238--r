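# Coldspot detection: sliding-window event density and GC content, and the
# low-density region caller.

#' Sliding-window event density and GC track
#'
#' Computes, for windows of `window` bp advanced by `step` bp, the event
#' density (events per kb, orientations summed) and the GC fraction. Windows
#' wrap on circular genomes; on linear genomes only fully contained windows
#' are emitted.
#'
#' @param table a [SiteTable-class].
#' @param genome the matching reference [Genome-class].
#' @param window window size in bp (default 1000).
#' @param step step between window starts in bp (default 200).
#' @return data.frame with columns `start`, `end`, `density`
#'   (events/kb) and `gc`; attributes `window`, `step`, `circular`.
#' @export
densityGCTrack <- function(table, genome, window = 1000L, step = 200L) {
  window <- as.integer(window); step <- as.integer(step)
  L <- genomeLength(genome)
  if (window > L) stop("window larger than the genome")
  circ <- isCircular(genome)
  chars <- strsplit(genomeSeq(genome), "")[[1]]
  gci <- as.integer(chars %in% c("G", "C"))
  evt <- numeric(L)
  cc <- siteCounts(table)
  if (nrow(cc)) {
    agg <- tapply(cc$count, cc$position, sum)
    evt[as.integer(names(agg))] <- agg
  }
  starts <- seq(1L, if (circ) L else L - window + 1L, by = step)
  if (circ) {
    gciX <- c(gci, gci[seq_len(window)])
    evtX <- c(evt, evt[seq_len(window)])
  } else {
    gciX <- gci; evtX <- evt
  }
  csG <- c(0, cumsum(gciX))
  csE <- c(0, cumsum(evtX))
  ends <- starts + window - 1L
  data.frame(
    start = starts,
    end = if (circ) wrapPos(ends, L) else ends,
    density = (csE[starts + window] - csE[starts]) / (window / 1000),
    gc = (csG[starts + window] - csG[starts]) / window
  ) -> out
  attr(out, "window") <- window
  attr(out, "step") <- step
  attr(out, "circular") <- circ
  out
}

#' Call transposition coldspots
#'
#' Maximal runs of consecutive windows whose event density stays below
#' `maxDensity` events/kb are collected; runs whose spans overlap or sit
#' closer than `mergeGap` bp (one window by default, absorbing isolated noisy
#' windows inside a large cold region) are merged. Regions of at least
#' `minLength` bp are reported with their aggregate density and GC (means
#' over the below-threshold member windows).
#'
#' @param track data.frame from [densityGCTrack()].
#' @param maxDensity density ceiling in events/kb (default 10).
#' @param minLength minimum region length in bp (default 1000).
#' @param mergeGap bp within which neighbouring runs merge (defaults to the
#'   track's window size).
#' @return data.frame with columns `start`, `end`, `length`, `density` and
#'   `gc`.
#' @export
callColdspots <- function(track, maxDensity = 10, minLength = 1000L,
                          mergeGap = NULL) {
  below <- track$density < maxDensity
  out <- data.frame(start = integer(0), end = integer(0), length = integer(0),
                    density = numeric(0), gc = numeric(0))
  if (!any(below)) return(out)
  window <- attr(track, "window")
  if (is.null(window)) window <- max(track$end - track$start + 1L)
  if (is.null(mergeGap)) mergeGap <- window
  r <- rle(below)
  endsIdx <- cumsum(r$lengths)
  startsIdx <- endsIdx - r$lengths + 1L
  runs <- lapply(which(r$values), function(i) {
    w <- startsIdx[i]:endsIdx[i]
    list(start = track$start[w[1L]],
         end = track$start[w[length(w)]] + window - 1L,
         windows = w)
  })
  # merge runs separated by less than mergeGap
  merged <- list(runs[[1L]])
  for (rn in runs[-1L]) {
    last <- merged[[length(merged)]]
    if (rn$start - last$end - 1L < mergeGap) {
      last$end <- max(last$end, rn$end)
      last$windows <- c(last$windows, rn$windows)
      merged[[length(merged)]] <- last
    } else merged[[length(merged) + 1L]] <- rn
  }
  rows <- list()
  for (rn in merged) {
    len <- rn$end - rn$start + 1L
    if (len < minLength) next
    rows[[length(rows) + 1L]] <- data.frame(
      start = rn$start, end = rn$end, length = len,
      density = mean(track$density[rn$windows]),
      gc = mean(track$gc[rn$windows]))
  }
  if (!length(rows)) return(out)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
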