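#' @import methods
#' @importFrom stats runif median quantile setNames aggregate
NULL

#' Genome: a named nucleotide sequence with a circularity flag
#'
#' Container used for both host (bacterial, circular by default) and phage
#' (linear) genomes. The sequence is held as a [Biostrings::DNAString] and is
#' restricted to the unambiguous alphabet A/C/G/T.
#'
#' @slot name single identifier.
#' @slot seq a `DNAString` over A/C/G/T.
#' @slot circular logical flag; coordinate windows and flanks wrap when `TRUE`.
#' @export
setClass("Genome", representation(
  name = "character",
  seq = "DNAString",
  circular = "logical"
))

setValidity("Genome", function(object) {
  msg <- character(0)
  if (length(object@name) != 1L || is.na(object@name) || !nzchar(object@name))
    msg <- c(msg, "name must be a single non-empty string")
  if (length(object@seq) < 1L)
    msg <- c(msg, "seq must be non-empty")
  if (!all(strsplit(as.character(object@seq), "")[[1]] %in% DNA_BASES))
    msg <- c(msg, "seq must contain only A, C, G, T")
  if (length(object@circular) != 1L || is.na(object@circular))
    msg <- c(msg, "circular must be TRUE or FALSE")
  if (length(msg)) msg else TRUE
})

#' Construct a Genome
#'
#' @param name identifier.
#' @param seq character string or `DNAString` over A/C/G/T.
#' @param circular logical; defaults to `TRUE` (bacterial chromosome).
#' @return a [Genome-class] object.
#' @examples
#' g <- Genome("toy", "ACGTACGT", circular = FALSE)
#' genomeLength(g)
#' @export
Genome <- function(name, seq, circular = TRUE) {
  if (is.character(seq)) seq <- Biostrings::DNAString(seq)
  new("Genome", name = name, seq = seq, circular = circular)
}

setMethod("show", "Genome", function(object) {
  cat(sprintf("Genome '%s': %s bp, %s\n", object@name,
              format(length(object@seq), big.mark = ","),
              if (object@circular) "circular" else "linear"))
})

#' @describeIn Genome genome length in bp
#' @param x,object a `Genome`
#' @export
genomeLength <- function(x) length(x@seq)

#' @describeIn Genome sequence as a character string
#' @export
genomeSeq <- function(x) as.character(x@seq)

#' @describeIn Genome identifier
#' @export
genomeName <- function(x) x@name

#' @describeIn Genome circularity flag
#' @export
isCircular <- function(x) x@circular

#' PhageSpec: structural model of a transposable phage genome
#'
#' Describes the genome of a Mu-like (D3112-group) phage for simulation: total
#' length, the conserved terminal trinucleotides (these genomes start with TGT
#' and end with ACA), and the positions at which the rare-cutting restriction
#' enzyme used for right-end enrichment cuts. The default values describe a
#' 37,205 bp phage whose two recognition sites place cuts at 6170 and 37,024,
#' leaving a 181 bp right-end fragment.
#'
#' @slot length genome length in bp.
#' @slot leftEnd,rightEnd terminal trinucleotides.
#' @slot enzymeSites ordered 1-based cut positions (left fragment ends there).
#' @slot rightEndLen bp between the last cut and the right end; must equal
#'   `length - max(enzymeSites)`.
#' @export
setClass("PhageSpec", representation(
  length = "integer",
  leftEnd = "character",
  rightEnd = "character",
  enzymeSites = "integer",
  rightEndLen = "integer"
))

setValidity("PhageSpec", function(object) {
  msg <- character(0)
  L <- object@length
  if (L < 100L) msg <- c(msg, "length implausibly short")
  s <- object@enzymeSites
  if (length(s)) {
    if (any(s <= 0L) || any(s >= L)) msg <- c(msg, "enzyme sites must lie strictly inside the genome")
    if (is.unsorted(s, strictly = TRUE)) msg <- c(msg, "enzyme sites must be strictly increasing")
    if (object@rightEndLen != L - s[length(s)])
      msg <- c(msg, "rightEndLen must equal length - last enzyme site")
  }
  if (nchar(object@leftEnd) != 3L || nchar(object@rightEnd) != 3L)
    msg <- c(msg, "terminal trinucleotides must be 3 bp")
  if (length(msg)) msg else TRUE
})

#' Construct a PhageSpec
#'
#' @param length genome size in bp (default 37205).
#' @param leftEnd,rightEnd terminal trinucleotides (defaults "TGT"/"ACA").
#' @param enzymeSites ordered 1-based cut positions (defaults 6170, 37024).
#' @param rightEndLen right-end fragment length; computed from the last site
#'   when omitted.
#' @return a [PhageSpec-class].
#' @export
PhageSpec <- function(length = 37205L, leftEnd = "TGT", rightEnd = "ACA",
                      enzymeSites = c(6170L, 37024L), rightEndLen = NULL) {
  length <- as.integer(length)
  enzymeSites <- as.integer(enzymeSites)
  if (is.null(rightEndLen))
    rightEndLen <- if (base::length(enzymeSites)) length - enzymeSites[base::length(enzymeSites)] else 0L
  new("PhageSpec", length = length, leftEnd = leftEnd, rightEnd = rightEnd,
      enzymeSites = enzymeSites, rightEndLen = as.integer(rightEndLen))
}

setMethod("show", "PhageSpec", function(object) {
  cat(sprintf("PhageSpec: %s bp, ends %s...%s, cut sites [%s], right-end fragment %d bp\n",
              format(object@length, big.mark = ","), object@leftEnd, object@rightEnd,
              paste(object@enzymeSites, collapse = ", "), object@rightEndLen))
})

#' SiteModel: insertion site-selection model
#'
#' Parameterises where transposition events land. Each host position carries a
#' base weight, multiplied down by `gcColdFactor` where the windowed GC
#' fraction falls below `gcColdThreshold` (low-GC coldspots) and multiplied up
#' by `motifBoost` within `motifWindow` bp of a planted motif edge (hotspots).
#' A small fraction `immunityLeak` of events escapes target immunity and lands
#' in an already-inserted phage genome copy. Reverse-orientation events report
#' their junction shifted by `duplicationOffset` bp, reproducing the paired
#' forward/reverse peak geometry produced by the target-site duplication.
#'
#' @slot baseWeight positive per-position base weight.
#' @slot gcWindow bp window for the GC rule (default 500).
#' @slot gcColdThreshold GC fraction below which the cold factor applies (0.50).
#' @slot gcColdFactor multiplier < 1 for cold positions (default 0.005).
#' @slot motifRanges integer matrix with columns start,end (one motif per row).
#' @slot motifBoost multiplier for motif-adjacent positions (default 300).
#' @slot motifWindow bp around each motif edge that is boosted (default 120).
#' @slot immunityLeak probability a given event self-inserts (default 0.004).
#' @slot duplicationOffset target-site duplication length in bp (default 5).
#' @export
setClass("SiteModel", representation(
  baseWeight = "numeric",
  gcWindow = "integer",
  gcColdThreshold = "numeric",
  gcColdFactor = "numeric",
  motifRanges = "matrix",
  motifBoost = "numeric",
  motifWindow = "integer",
  immunityLeak = "numeric",
  duplicationOffset = "integer"
))

setValidity("SiteModel", function(object) {
  msg <- character(0)
  if (object@baseWeight <= 0) msg <- c(msg, "baseWeight must be > 0")
  if (object@gcColdFactor <= 0) msg <- c(msg, "gcColdFactor must be > 0")
  if (object@motifBoost <= 0) msg <- c(msg, "motifBoost must be > 0")
  if (object@immunityLeak < 0 || object@immunityLeak > 1)
    msg <- c(msg, "immunityLeak must lie in [0, 1]")
  if (ncol(object@motifRanges) != 2L) msg <- c(msg, "motifRanges must have 2 columns")
  if (nrow(object@motifRanges) &&
      any(object@motifRanges[, 2] < object@motifRanges[, 1]))
    msg <- c(msg, "motifRanges end < start")
  if (length(msg)) msg else TRUE
})

#' Construct a SiteModel
#'
#' @param baseWeight per-position base weight (default 1).
#' @param gcWindow,gcColdThreshold,gcColdFactor GC coldspot rule parameters.
#' @param motifPositions 1-based motif start positions on the host genome.
#' @param motifLength motif length in bp used to derive the motif end
#'   (default 35); ignored when `motifRanges` is given.
#' @param motifRanges two-column matrix (start, end); overrides
#'   `motifPositions`.
#' @param motifBoost,motifWindow hotspot boost parameters.
#' @param immunityLeak probability of self-insertion (default 0.004).
#' @param duplicationOffset target-site duplication in bp (default 5).
#' @return a [SiteModel-class].
#' @export
SiteModel <- function(baseWeight = 1, gcWindow = 500L, gcColdThreshold = 0.50,
                      gcColdFactor = 0.005, motifPositions = integer(0),
                      motifLength = 35L, motifRanges = NULL,
                      motifBoost = 300, motifWindow = 120L,
                      immunityLeak = 0.004, duplicationOffset = 5L) {
  if (is.null(motifRanges)) {
    motifPositions <- as.integer(motifPositions)
    motifRanges <- cbind(start = motifPositions,
                         end = motifPositions + as.integer(motifLength) - 1L)
  }
  storage.mode(motifRanges) <- "integer"
  colnames(motifRanges) <- c("start", "end")
  new("SiteModel", baseWeight = baseWeight, gcWindow = as.integer(gcWindow),
      gcColdThreshold = gcColdThreshold, gcColdFactor = gcColdFactor,
      motifRanges = motifRanges, motifBoost = motifBoost,
      motifWindow = as.integer(motifWindow), immunityLeak = immunityLeak,
      duplicationOffset = as.integer(duplicationOffset))
}

setMethod("show", "SiteModel", function(object) {
  cat(sprintf(paste0(
    "SiteModel: %d motif range(s) boosted x%g within %d bp;\n",
    "  GC < %.2f over %d bp windows weighted x%g; immunity leak %.4f; duplication %d bp\n"),
    nrow(object@motifRanges), object@motifBoost, object@motifWindow,
    object@gcColdThreshold, object@gcWindow, object@gcColdFactor,
    object@immunityLeak, object@duplicationOffset))
})

#' SiteTable: per-position, per-orientation integration-event counts
#'
#' The central tally of mapped integration events on one reference genome.
#' Rows are (position, orientation) pairs with a positive count; positions are
#' 1-based inclusive.
#'
#' @slot refName reference genome identifier.
#' @slot refLength reference length in bp.
#' @slot circular circularity of the reference.
#' @slot counts data.frame with columns `position`, `orientation`
#'   ("forward"/"reverse") and `count`.
#' @export
setClass("SiteTable", representation(
  refName = "character",
  refLength = "integer",
  circular = "logical",
  counts = "data.frame"
))

setValidity("SiteTable", function(object) {
  msg <- character(0)
  cc <- object@counts
  need <- c("position", "orientation", "count")
  if (!all(need %in% names(cc))) {
    msg <- c(msg, "counts must have columns position, orientation, count")
  } else if (nrow(cc)) {
    if (any(cc$position < 1L) || any(cc$position > object@refLength))
      msg <- c(msg, "positions must lie in [1, refLength]")
    if (!all(cc$orientation %in% ORIENTATIONS))
      msg <- c(msg, "orientation must be 'forward' or 'reverse'")
    if (any(cc$count < 1L)) msg <- c(msg, "counts must be positive")
    if (anyDuplicated(cc[c("position", "orientation")]))
      msg <- c(msg, "duplicate (position, orientation) rows")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a SiteTable from event coordinates
#'
#' Aggregates one row per observed (position, orientation) pair.
#'
#' @param positions integer vector of 1-based junction positions.
#' @param orientations character vector, "forward"/"reverse", recycled.
#' @param refName,refLength,circular reference description.
#' @return a [SiteTable-class].
#' @export
SiteTable <- function(positions, orientations, refName, refLength,
                      circular = TRUE) {
  positions <- as.integer(positions)
  orientations <- rep_len(as.character(orientations), length(positions))
  if (length(positions)) {
    key <- paste(positions, orientations)
    tab <- table(key)
    parts <- strsplit(names(tab), " ", fixed = TRUE)
    cc <- data.frame(
      position = as.integer(vapply(parts, `[`, "", 1L)),
      orientation = vapply(parts, `[`, "", 2L),
      count = as.integer(tab),
      stringsAsFactors = FALSE
    )
    cc <- cc[order(cc$position, cc$orientation), , drop = FALSE]
    rownames(cc) <- NULL
  } else {
    cc <- data.frame(position = integer(0), orientation = character(0),
                     count = integer(0), stringsAsFactors = FALSE)
  }
  new("SiteTable", refName = refName, refLength = as.integer(refLength),
      circular = circular, counts = cc)
}

setMethod("show", "SiteTable", function(object) {
  cat(sprintf("SiteTable on '%s' (%s bp): %s events at %d occupied positions\n",
              object@refName, format(object@refLength, big.mark = ","),
              format(totalEvents(object), big.mark = ","),
              length(unique(object@counts$position))))
})

#' @describeIn SiteTable the (position, orientation, count) data.frame
#' @param x,object a `SiteTable`
#' @export
siteCounts <- function(x) x@counts

#' @describeIn SiteTable total number of events (sum of counts)
#' @export
totalEvents <- function(x) sum(x@counts$count)

#' @describeIn SiteTable reference length in bp
#' @export
refLength <- function(x) x@refLength

#' @describeIn SiteTable reference name
#' @export
refName <- function(x) x@refName

#' CoincidenceModel: closed-form expectations for coincident events
#'
#' Expected numbers of genome positions carrying i coincident integration
#' events under random placement of `nEvents` events on `genomeSize`
#' positions, computed from the recurrence E2 = T*R/2,
#' E(i+1) = ln(1/(1-R)) * Ei / (i+1) with R = T/N.
#'
#' @slot nEvents,genomeSize,ratio model inputs and R = T/N.
#' @slot expected named numeric, names "2".."iMax".
#' @export
setClass("CoincidenceModel", representation(
  nEvents = "numeric",
  genomeSize = "numeric",
  ratio = "numeric",
  expected = "numeric"
))

setMethod("show", "CoincidenceModel", function(object) {
  cat(sprintf("CoincidenceModel: T = %s events, N = %s bp, R = %.3g\n",
              format(object@nEvents, big.mark = ","),
              format(object@genomeSize, big.mark = ","), object@ratio))
  print(signif(object@expected, 4))
})

#' @describeIn CoincidenceModel named vector of expectations E_i
#' @param x,object a `CoincidenceModel`
#' @export
expectedCounts <- function(x) x@expected

#' CoincidenceSpectrum: observed multiplicity spectrum of a SiteTable
#'
#' @slot observed named integer: multiplicity i -> number of positions with
#'   exactly i events (orientations summed).
#' @slot atLeast cumulative variant: positions with >= i events.
#' @slot total total number of events.
#' @export
setClass("CoincidenceSpectrum", representation(
  observed = "integer",
  atLeast = "integer",
  total = "integer"
))

setMethod("show", "CoincidenceSpectrum", function(object) {
  cat(sprintf("CoincidenceSpectrum: %s events\n",
              format(object@total, big.mark = ",")))
  if (length(object@observed))
    print(data.frame(multiplicity = as.integer(names(object@observed)),
                     exactly = as.integer(object@observed),
                     at_least = as.integer(object@atLeast)))
})

#' @describeIn CoincidenceSpectrum positions with exactly i events
#' @param x,object a `CoincidenceSpectrum`
#' @export
observedExactly <- function(x) x@observed

#' @describeIn CoincidenceSpectrum positions with at least i events
#' @export
observedAtLeast <- function(x) x@atLeast

#' ReadSet: simulated virion sequencing reads plus ground truth
#'
#' @slot reads named `DNAStringSet`.
#' @slot truth data.frame linking junction-bearing read ids to their
#'   generating insertion event (`read_id`, `target`, `position`,
#'   `orientation`, `end`, `host_len`).
#' @slot log named integer counters (e.g. dropped events on linear targets).
#' @export
setClass("ReadSet", representation(
  reads = "DNAStringSet",
  truth = "data.frame",
  log = "integer"
))

setValidity("ReadSet", function(object) {
  msg <- character(0)
  if (nrow(object@truth) && anyDuplicated(object@truth$read_id))
    msg <- c(msg, "read ids must appear at most once in truth")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ReadSet", function(object) {
  cat(sprintf("ReadSet: %s reads, %s truth-annotated junction reads\n",
              format(length(object@reads), big.mark = ","),
              format(nrow(object@truth), big.mark = ",")))
})

#' @describeIn ReadSet the reads as a DNAStringSet
#' @param x,object a `ReadSet`
#' @export
readSeqs <- function(x) x@reads

#' @describeIn ReadSet the ground-truth table
#' @export
readTruth <- function(x) x@truth

#' ConsensusMotif: degenerate consensus over hotspot flanks
#'
#' @slot iupac consensus string over the IUPAC nucleotide alphabet.
#' @slot offsets per-flank 1-based offset of the conserved block within the
#'   flank (NA where the seed was absent).
#' @slot flagged TRUE when no shared block could be found.
#' @export
setClass("ConsensusMotif", representation(
  iupac = "character",
  offsets = "integer",
  flagged = "logical"
))

setMethod("show", "ConsensusMotif", function(object) {
  if (object@flagged) cat("ConsensusMotif: <none found>\n")
  else cat(sprintf("ConsensusMotif: %s (%d bp, %d/%d flanks anchored)\n",
                   object@iupac, nchar(object@iupac),
                   sum(!is.na(object@offsets)), length(object@offsets)))
})

#' @describeIn ConsensusMotif the IUPAC consensus string
#' @param x,object a `ConsensusMotif`
#' @export
motifString <- function(x) x@iupac

#' @describeIn ConsensusMotif per-flank offsets of the conserved block
#' @export
motifOffsets <- function(x) x@offsets

#' LoopModel: pairing of phage chromosome domains into loops
#'
#' @slot loops data.frame with columns `loop`, `upstream`, `downstream`,
#'   `upstreamCount`, `downstreamCount`, `upstreamShare`, `downstreamShare`;
#'   the apex loop has `downstream = NA`.
#' @slot apex label of the central (apex) domain.
#' @export
setClass("LoopModel", representation(
  loops = "data.frame",
  apex = "character"
))

setMethod("show", "LoopModel", function(object) {
  cat(sprintf("LoopModel: %d loops, apex domain %s\n",
              nrow(object@loops), object@apex))
  print(object@loops)
})

#' @describeIn LoopModel the per-loop pairing table
#' @param x,object a `LoopModel`
#' @export
loopTable <- function(x) x@loops

#' @describeIn LoopModel label of the apex domain
#' @export
apexDomain <- function(x) x@apex
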