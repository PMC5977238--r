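# Synthetic virion-read generator: host/phage genomes with planted features,
# a site-selection model, insertion-event sampling and read packaging.

#' Generate a host genome with planted low-GC islands and motifs
#'
#' Produces a random bacterial-style chromosome at a given background GC
#' fraction. Low-GC islands are written with their exact requested base
#' composition (randomly arranged), emulating horizontally acquired AT-rich
#' segments; motif instances are planted verbatim.
#'
#' @param length genome length in bp.
#' @param gc background GC fraction (default 0.65, a Pseudomonas-like value).
#' @param lowGCIslands data.frame with columns `start`, `length`, `gc`.
#' @param plantedMotifs data.frame with columns `position`, `motif`
#'   (concrete A/C/G/T strings planted verbatim, non-overlapping).
#' @param name,circular genome identity; circular by default.
#' @param seed RNG seed.
#' @return a [Genome-class].
#' @examples
#' g <- makeHostGenome(5000, gc = 0.65,
#'                     plantedMotifs = data.frame(position = 10, motif = "ACGT"),
#'                     seed = 1)
#' substr(genomeSeq(g), 10, 13)
#' @export
makeHostGenome <- function(length, gc = 0.65, lowGCIslands = NULL,
                           plantedMotifs = NULL, name = "host",
                           circular = TRUE, seed = NULL) {
  length <- as.integer(length)
  withSeed(seed, {
    chars <- strsplit(randomDNA(length, gc), "")[[1]]
    if (!is.null(lowGCIslands) && nrow(lowGCIslands)) {
      for (i in seq_len(nrow(lowGCIslands))) {
        s <- as.integer(lowGCIslands$start[i])
        l <- as.integer(lowGCIslands$length[i])
        if (s < 1L || s + l - 1L > length)
          stop("island outside genome bounds")
        chars[s:(s + l - 1L)] <- randomDNAExactGC(l, lowGCIslands$gc[i])
      }
    }
    if (!is.null(plantedMotifs) && nrow(plantedMotifs)) {
      pos <- as.integer(plantedMotifs$position)
      len <- nchar(plantedMotifs$motif)
      if (any(pos < 1L) || any(pos + len - 1L > length))
        stop("planted motif outside genome bounds")
      o <- order(pos)
      if (nrow(plantedMotifs) > 1L &&
          any(pos[o][-1L] <= (pos[o] + len[o] - 1L)[-nrow(plantedMotifs)]))
        stop("overlapping motif placements")
      for (i in seq_len(nrow(plantedMotifs))) {
        m <- strsplit(toupper(plantedMotifs$motif[i]), "")[[1]]
        if (!all(m %in% DNA_BASES)) stop("planted motifs must be concrete A/C/G/T")
        chars[pos[i]:(pos[i] + len[i] - 1L)] <- m
      }
    }
    Genome(name, paste(chars, collapse = ""), circular = circular)
  })
}

# NsiI-style palindromic recognition sequence; cutting after base
# recognitionStart + cutOffset leaves the site position as the last base of
# the upstream fragment.
ENZYME_RECOGNITION <- "ATGCAT"
ENZYME_CUT_OFFSET <- 4L

#' Generate a phage genome matching a PhageSpec
#'
#' The genome starts and ends with the conserved terminal trinucleotides and
#' carries the enzyme recognition sequence exactly at the positions implied by
#' `spec`'s cut sites (and nowhere else; spurious occurrences are mutated
#' away).
#'
#' @param spec a [PhageSpec-class].
#' @param gc background GC fraction (default 0.62).
#' @param name genome name.
#' @param seed RNG seed.
#' @return a linear [Genome-class].
#' @examples
#' ph <- makePhageGenome(PhageSpec(), seed = 1)
#' substr(genomeSeq(ph), 1, 3)                    # "TGT"
#' digestFragments(genomeLength(ph), enzymeCutSites(ph))
#' @export
makePhageGenome <- function(spec = PhageSpec(), gc = 0.62, name = "phage",
                            seed = NULL) {
  validObject(spec)
  L <- spec@length
  sites <- spec@enzymeSites
  recStarts <- sites - ENZYME_CUT_OFFSET
  recLen <- nchar(ENZYME_RECOGNITION)
  if (length(sites) &&
      (any(recStarts < 4L) || any(recStarts + recLen - 1L > L - 3L)))
    stop("enzyme sites too close to the genome ends to honour the terminal trinucleotides")
  withSeed(seed, {
    chars <- strsplit(randomDNA(L, gc), "")[[1]]
    chars[1:3] <- strsplit(spec@leftEnd, "")[[1]]
    chars[(L - 2L):L] <- strsplit(spec@rightEnd, "")[[1]]
    rec <- strsplit(ENZYME_RECOGNITION, "")[[1]]
    planted <- integer(0)
    for (p in recStarts) {
      chars[p:(p + recLen - 1L)] <- rec
      planted <- c(planted, p)
    }
    # remove spurious recognition sites (palindromic, so one strand suffices)
    for (iter in 1:100) {
      s <- paste(chars, collapse = "")
      occ <- Biostrings::start(Biostrings::matchPattern(ENZYME_RECOGNITION,
                                                        Biostrings::DNAString(s)))
      spurious <- setdiff(occ, planted)
      if (!length(spurious)) break
      for (sp in spurious) {
        # mutate a base of the spurious occurrence outside planted regions/ends
        cand <- sp:(sp + recLen - 1L)
        ok <- cand > 3L & cand < L - 2L &
          !vapply(cand, function(i) any(i >= planted & i <= planted + recLen - 1L),
                  logical(1))
        i <- cand[ok][1L]
        if (is.na(i)) stop("cannot purge a recognition site overlapping a planted one")
        chars[i] <- sample(setdiff(DNA_BASES, chars[i]), 1L)
      }
    }
    g <- Genome(name, paste(chars, collapse = ""), circular = FALSE)
    stopifnot(identical(enzymeCutSites(g), as.integer(sites)))
    g
  })
}

#' Locate enzyme cut positions on a genome
#'
#' Returns the 1-based positions after which the modelled restriction enzyme
#' cuts (the returned position is the last base of the upstream fragment).
#'
#' @param genome a [Genome-class].
#' @param recognition recognition sequence (palindromic; default "ATGCAT").
#' @param cutOffset bases between recognition start and the cut (default 4).
#' @return integer vector of cut positions.
#' @export
enzymeCutSites <- function(genome, recognition = ENZYME_RECOGNITION,
                           cutOffset = ENZYME_CUT_OFFSET) {
  occ <- Biostrings::start(Biostrings::matchPattern(recognition, genome@seq))
  sort(as.integer(occ + cutOffset))
}

#' Restriction digest fragment lengths
#'
#' Splits a genome of the given length at ordered cut positions and returns
#' the fragment lengths left to right. Fragments always sum to the genome
#' length and number one more than the cuts.
#'
#' @param genomeLength total length in bp.
#' @param sitePositions strictly increasing 1-based cut positions, each the
#'   last base of its upstream fragment.
#' @return integer vector of fragment lengths.
#' @examples
#' digestFragments(37205, c(6170, 37024))  # 6170, 30854, 181
#' @export
digestFragments <- function(genomeLength, sitePositions = integer(0)) {
  genomeLength <- as.integer(genomeLength)
  sitePositions <- as.integer(sitePositions)
  if (length(sitePositions)) {
    if (is.unsorted(sitePositions, strictly = TRUE))
      stop("cut positions must be strictly increasing")
    if (any(sitePositions <= 0L) || any(sitePositions >= genomeLength))
      stop("cut positions must lie strictly inside the genome")
  }
  diff(c(0L, sitePositions, genomeLength))
}

#' Per-position insertion weights for a host genome
#'
#' Implements the site-selection model: weight(p) = base x gcColdFactor (if
#' the windowed GC around p is below the threshold) x motifBoost (if p lies
#' within `motifWindow` bp of a planted motif edge, motif interior included).
#'
#' @param host a [Genome-class].
#' @param model a [SiteModel-class].
#' @return numeric weight vector of length `genomeLength(host)`.
#' @export
siteWeights <- function(host, model) {
  L <- genomeLength(host)
  if (model@gcWindow > L) stop("GC window larger than the genome")
  chars <- strsplit(genomeSeq(host), "")[[1]]
  w <- rep(model@baseWeight, L)
  gc <- rollingGC(chars, model@gcWindow, isCircular(host))
  w[gc < model@gcColdThreshold] <- w[gc < model@gcColdThreshold] * model@gcColdFactor
  if (nrow(model@motifRanges)) {
    for (i in seq_len(nrow(model@motifRanges))) {
      lo <- model@motifRanges[i, 1L] - model@motifWindow
      hi <- model@motifRanges[i, 2L] + model@motifWindow
      idx <- if (isCircular(host)) wrapPos(lo:hi, L) else max(1L, lo):min(L, hi)
      w[idx] <- w[idx] * model@motifBoost
    }
  }
  w
}

#' Sample insertion events
#'
#' Each event independently targets an already-inserted phage genome copy with
#' probability `model@immunityLeak` (position drawn from
#' `phageDomainProfile`), otherwise the host (position proportional to
#' [siteWeights()]). Orientation is uniform. For host-target events in reverse
#' orientation the recorded junction coordinate is shifted downstream by the
#' target-site duplication (`model@duplicationOffset`); phage self-insertions
#' are recorded at the sampled site itself.
#'
#' @param n number of events.
#' @param host,phage [Genome-class] objects.
#' @param model a [SiteModel-class].
#' @param phageDomainProfile per-bp relative densities over the phage genome
#'   (uniform when `NULL`); see [defaultDomainProfile()].
#' @param seed RNG seed.
#' @return data.frame with columns `target` ("host"/"phage-copy"),
#'   `position` (1-based on the target) and `orientation`.
#' @export
sampleInsertions <- function(n, host, phage, model,
                             phageDomainProfile = NULL, seed = NULL) {
  stopifnot(n > 0)
  n <- as.integer(n)
  Lh <- genomeLength(host)
  Lp <- genomeLength(phage)
  if (is.null(phageDomainProfile)) phageDomainProfile <- rep(1, Lp)
  if (length(phageDomainProfile) != Lp)
    stop("phageDomainProfile must have one weight per phage position")
  if (sum(phageDomainProfile) <= 0) stop("phageDomainProfile must have positive mass")
  withSeed(seed, {
    isPhage <- stats::runif(n) < model@immunityLeak
    np <- sum(isPhage)
    nh <- n - np
    target <- ifelse(isPhage, "phage-copy", "host")
    position <- integer(n)
    orientation <- sample(ORIENTATIONS, n, replace = TRUE)
    if (nh) {
      w <- siteWeights(host, model)
      hp <- sample.int(Lh, nh, replace = TRUE, prob = w)
      rev <- orientation[!isPhage] == "reverse"
      hp[rev] <- hp[rev] + model@duplicationOffset
      position[!isPhage] <- if (isCircular(host)) wrapPos(hp, Lh) else pmin(hp, Lh)
    }
    if (np)
      position[isPhage] <- sample.int(Lp, np, replace = TRUE,
                                      prob = phageDomainProfile)
    data.frame(target = target, position = position,
               orientation = orientation, stringsAsFactors = FALSE)
  })
}

#' Package insertion events into virion sequencing reads
#'
#' Emulates the virion chromosome: the packaged phage genome flanked by target
#' DNA on both sides (a short 31-36 bp left flank from the packaging start and
#' a longer, size-selected right flank). Two modes:
#'
#' * `"whole-virion"`: per event, one left-junction read (flank + phage left
#'   end), one right-junction read (phage right end + flank) and
#'   `internalReads` phage-internal reads, so molecule ends are
#'   overrepresented relative to mean coverage.
#' * `"enriched-right"`: per event, reads that start precisely at the enzyme
#'   cut preceding the phage right-end fragment and continue into the flank,
#'   mirroring a restriction enrichment of right-end junctions.
#'
#' For reverse-orientation events flanks are taken from the target minus
#' strand so that junction coordinates round-trip through mapping. Flanks that
#' would run off a linear target are truncated; events whose flank vanishes
#' are dropped and counted in the `log` slot.
#'
#' @param events data.frame from [sampleInsertions()].
#' @param host,phage [Genome-class] objects; self-insertion events take their
#'   flanks from the phage genome (the previously inserted copy).
#' @param mode `"whole-virion"` or `"enriched-right"`.
#' @param readLength read length in bp (>= 50).
#' @param leftFlankRange inclusive range of left-flank lengths (default 31-36).
#' @param rightFlankRange inclusive range of right-flank lengths before read
#'   truncation (default 170-2500, the size-selected fraction bounds).
#' @param internalReads phage-internal reads per event in whole-virion mode.
#' @param seed RNG seed.
#' @return a [ReadSet-class]; `truth` records the generating event for every
#'   junction-bearing read.
#' @export
packageReads <- function(events, host, phage,
                         mode = c("whole-virion", "enriched-right"),
                         readLength = 250L, leftFlankRange = c(31L, 36L),
                         rightFlankRange = c(170L, 2500L),
                         internalReads = 0L, seed = NULL) {
  mode <- match.arg(mode)
  readLength <- as.integer(readLength)
  if (readLength < 50L) stop("readLength must be >= 50")
  hostSeq <- genomeSeq(host)
  phageSeq <- genomeSeq(phage)
  Lh <- genomeLength(host)
  Lp <- genomeLength(phage)
  rightEnd <- substr(phageSeq, Lp - 180L, Lp)  # 181 bp right-end fragment

  withSeed(seed, {
    n <- nrow(events)
    tgt <- events$target
    q <- as.integer(events$position)
    orient <- events$orientation
    tl <- ifelse(tgt == "host", Lh, Lp)
    tcirc <- ifelse(tgt == "host", isCircular(host), isCircular(phage))

    # right flank visible in a read
    hl <- pmin(readLength - nchar(rightEnd),
               sample(rightFlankRange[1]:rightFlankRange[2], n, replace = TRUE))
    fwd <- orient == "forward"
    rs <- ifelse(fwd, q, q - hl + 1L)
    re <- ifelse(fwd, q + hl - 1L, q)
    # truncate at linear target bounds
    clampLo <- !tcirc & rs < 1L
    clampHi <- !tcirc & re > tl
    rs[clampLo] <- 1L
    re[clampHi] <- tl[clampHi]
    keep <- (re - rs + 1L) >= 1L & q >= 1L & q <= tl
    dropped <- sum(!keep)

    # vectorised per target group (flank source differs for self-insertions)
    rightFlank <- character(n)
    for (tg in c("host", "phage-copy")) {
      sel <- which(tgt == tg & keep)
      if (!length(sel)) next
      s <- if (tg == "host") hostSeq else phageSeq
      fl <- substrVec(s, rs[sel], re[sel], tl[sel][1L], tcirc[sel][1L])
      rv <- orient[sel] == "reverse"
      fl[rv] <- revcompChar(fl[rv])
      rightFlank[sel] <- fl
    }

    ids <- character(0); seqs <- character(0)
    truth <- NULL
    if (mode == "enriched-right") {
      sel <- which(keep)
      ids <- sprintf("er_%07d", sel)
      seqs <- paste0(rightEnd, rightFlank[sel])
      truth <- data.frame(read_id = ids, target = tgt[sel], position = q[sel],
                          orientation = orient[sel], end = "right",
                          host_len = nchar(rightFlank[sel]),
                          stringsAsFactors = FALSE)
    } else {
      # left-junction reads
      ll <- sample(leftFlankRange[1]:leftFlankRange[2], n, replace = TRUE)
      ls <- ifelse(fwd, q - ll + 1L, q)
      le <- ifelse(fwd, q, q + ll - 1L)
      okL <- keep & (tcirc | (ls >= 1L & le <= tl))
      leftFlank <- character(n)
      for (tg in c("host", "phage-copy")) {
        sel <- which(tgt == tg & okL)
        if (!length(sel)) next
        s <- if (tg == "host") hostSeq else phageSeq
        fl <- substrVec(s, ls[sel], le[sel], tl[sel][1L], tcirc[sel][1L])
        rv <- orient[sel] == "reverse"
        fl[rv] <- revcompChar(fl[rv])
        leftFlank[sel] <- fl
      }
      selL <- which(okL)
      idsL <- sprintf("lv_%07d", selL)
      seqsL <- paste0(leftFlank[selL],
                      substring(phageSeq, 1L, readLength - nchar(leftFlank[selL])))
      selR <- which(keep)
      idsR <- sprintf("rv_%07d", selR)
      phagePart <- readLength - nchar(rightFlank[selR])
      seqsR <- paste0(substring(phageSeq, Lp - phagePart + 1L, Lp), rightFlank[selR])
      ids <- c(idsL, idsR)
      seqs <- c(seqsL, seqsR)
      truth <- rbind(
        data.frame(read_id = idsL, target = tgt[selL], position = q[selL],
                   orientation = orient[selL], end = "left",
                   host_len = nchar(leftFlank[selL]), stringsAsFactors = FALSE),
        data.frame(read_id = idsR, target = tgt[selR], position = q[selR],
                   orientation = orient[selR], end = "right",
                   host_len = nchar(rightFlank[selR]), stringsAsFactors = FALSE))
      if (internalReads > 0L) {
        off <- sample.int(max(1L, Lp - readLength + 1L),
                          n * internalReads, replace = TRUE)
        idsI <- sprintf("in_%07d", seq_along(off))
        ids <- c(ids, idsI)
        seqs <- c(seqs, substring(phageSeq, off, off + readLength - 1L))
      }
      dropped <- dropped + sum(keep & !okL)
    }
    reads <- Biostrings::DNAStringSet(seqs)
    names(reads) <- ids
    new("ReadSet", reads = reads, truth = truth,
        log = c(dropped_events = dropped))
  })
}

#' Relative self-insertion density profile over a phage genome
#'
#' Builds a per-bp weight vector emulating the looped chromosomal-domain
#' organisation of a transposing phage: nine piecewise-constant density
#' domains (terminal domains low; the central domain densest), sharp
#' boundary spikes at the seven inter-domain crossing points, and an optional
#' protected zero-density gap near the genome middle (the strong-gyrase-site
#' candidate).
#'
#' Domain sizes and relative densities default to the 37.2 kb nine-domain
#' organisation (sizes 900, 2900, 6100, 5300, 7200, 4500, 3800, 5800, 700 bp;
#' relative densities 100, 330, 800, 800, 1332, 620, 709, 1049, 100 events/kb)
#' and are rescaled to `phageLength`.
#'
#' @param phageLength target genome length in bp.
#' @param domainSizes,domainDensities nine sizes (bp, rescaled) and relative
#'   densities.
#' @param boundaryFraction fraction of total mass concentrated at each
#'   boundary position (default 0.05).
#' @param gap optional `c(start, end)` zero-density protected span.
#' @return numeric weight vector of length `phageLength`; attributes
#'   `boundaries` (bp) and `domainStarts`.
#' @export
defaultDomainProfile <- function(phageLength,
                                 domainSizes = c(900, 2900, 6100, 5300, 7200,
                                                 4500, 3800, 5800, 700),
                                 domainDensities = c(100, 330, 800, 800, 1332,
                                                     620, 709, 1049, 100),
                                 boundaryFraction = 0.05,
                                 gap = NULL) {
  phageLength <- as.integer(phageLength)
  stopifnot(length(domainSizes) == length(domainDensities))
  sizes <- round(domainSizes / sum(domainSizes) * phageLength)
  sizes[length(sizes)] <- phageLength - sum(sizes[-length(sizes)])
  bounds <- cumsum(sizes)
  w <- rep(domainDensities, times = sizes)
  boundaries <- bounds[-length(bounds)]
  w[boundaries] <- w[boundaries] + boundaryFraction * sum(w)
  if (!is.null(gap)) {
    stopifnot(length(gap) == 2L, gap[1] >= 1L, gap[2] <= phageLength)
    w[gap[1]:gap[2]] <- 0
  }
  attr(w, "boundaries") <- as.integer(boundaries)
  attr(w, "domainStarts") <- as.integer(c(1L, boundaries + 1L))
  w
}
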