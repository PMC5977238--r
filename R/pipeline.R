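# End-to-end orchestration: simulate -> extract junctions -> map -> analyse,
# with stage-tagged logging, files for every artefact, and an md5 manifest so
# runs are verifiably deterministic.

#' Default pipeline configuration
#'
#' A toy-scale but fully featured run: a 100 kb circular host carrying
#' fourteen motif-boosted hotspot sites and two low-GC coldspot islands, a
#' 10 kb linear phage with an enrichment-compatible right end, and a
#' right-end-enriched read library.
#'
#' @param hostLength,phageLength genome sizes in bp.
#' @param nEvents number of transposition events to simulate.
#' @param nSelfEvents self-insertion events used for the phage-domain
#'   analysis.
#' @return named list of configuration values understood by [runPipeline()].
#' @export
defaultRunConfig <- function(hostLength = 1e5, phageLength = 1e4,
                             nEvents = 2e4, nSelfEvents = 2e4) {
  list(
    host_length = hostLength,
    host_gc = 0.65,
    phage_length = phageLength,
    n_events = nEvents,
    n_self_events = nSelfEvents,
    n_motifs = 14,
    motif_boost = 300,
    motif_window = 5,
    gc_cold_factor = 0.005,
    immunity_leak = 0.004,
    duplication_offset = 5,
    read_length = 250,
    min_host = 12,
    min_phage_overlap = 20,
    max_mismatch_frac = 0.02,
    max_gap_frac = 0.03,
    min_identity = 0.95,
    hotspot_min_events = 3000,
    hotspot_reference_total = 13383386,
    pair_gap = 20,
    flank_width = 280,
    motif_scan_mismatches = 3,
    coldspot_max_density = 10,
    coldspot_min_length = 1000,
    bin = 50,
    protected_min_gap = 30
  )
}

stageLog <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

# a concrete instantiation of the hotspot-adjacent palindromic consensus,
# used to plant motif sites in simulated hosts
plantMotifInstance <- function(consensus, seed = NULL) {
  withSeed(seed, {
    cols <- strsplit(consensus, "")[[1]]
    paste(vapply(cols, function(cd) sample(IUPAC_SETS[[cd]], 1L), character(1)),
          collapse = "")
  })
}

#' Reference degenerate consensus used by the simulator
#'
#' The 35 bp REP/BIME-like palindromic consensus adjacent to insertion
#' hotspots.
#' @return IUPAC string.
#' @export
hotspotConsensus <- function() "YGGCGGATAACCGCRAGCGGTTATTCGCCCTACGS"

#' Run the full analysis pipeline on a simulated data set
#'
#' Orchestrates all stages: genome and event simulation, read packaging,
#' valid-read filtering, fragment placement, site-table construction, and the
#' downstream analyses (coincidence spectrum, hotspots and consensus,
#' coldspots, phage-domain segmentation with loops and the protected gap).
#' All artefacts are written under `outDir` and listed with md5 checksums in
#' `manifest.tsv`; counts are logged per stage. Deterministic for a fixed
#' seed.
#'
#' @param config named list (see [defaultRunConfig()]); missing entries take
#'   defaults.
#' @param outDir output directory (created).
#' @param seed integer seed driving every stage.
#' @return invisibly, a list with the principal in-memory results.
#' @export
runPipeline <- function(config = defaultRunConfig(), outDir = tempfile("salto"),
                        seed = 1L) {
  cfg <- utils::modifyList(defaultRunConfig(), config)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(seed)

  ## --- simulate ---------------------------------------------------------
  consensus <- hotspotConsensus()
  mlen <- nchar(consensus)
  spacing <- floor(cfg$host_length / (cfg$n_motifs + 2))
  islands <- data.frame(
    start = c(round(cfg$host_length * 0.20) + spacing %/% 3L,
              round(cfg$host_length * 0.60) + spacing %/% 3L),
    length = c(1530L, min(13000L, round(cfg$host_length * 0.13))),
    gc = c(0.42, 0.46))
  # hotspot sites sit clear of the low-GC islands
  cand <- as.integer(seq(spacing, cfg$host_length - spacing,
                         by = max(100L, floor(spacing * 0.7))))
  inIsland <- vapply(cand, function(p)
    any(p + mlen + cfg$motif_window >= islands$start &
          p - cfg$motif_window <= islands$start + islands$length - 1L),
    logical(1))
  motifPos <- utils::head(cand[!inIsland], cfg$n_motifs)
  if (length(motifPos) < cfg$n_motifs)
    stop("host too small to place ", cfg$n_motifs, " motif sites")
  motifs <- data.frame(
    position = motifPos,
    motif = vapply(seq_along(motifPos),
                   function(i) plantMotifInstance(consensus, seed + i),
                   character(1)))
  host <- makeHostGenome(cfg$host_length, gc = cfg$host_gc,
                         lowGCIslands = islands, plantedMotifs = motifs,
                         seed = seed)
  spec <- PhageSpec(length = as.integer(cfg$phage_length),
                    enzymeSites = c(round(cfg$phage_length * 0.2),
                                    as.integer(cfg$phage_length - 181L)))
  phage <- makePhageGenome(spec, seed = seed + 1L)
  model <- SiteModel(motifPositions = motifPos, motifLength = mlen,
                     motifBoost = cfg$motif_boost,
                     motifWindow = cfg$motif_window,
                     gcColdFactor = cfg$gc_cold_factor,
                     immunityLeak = cfg$immunity_leak,
                     duplicationOffset = cfg$duplication_offset)
  gap <- c(round(cfg$phage_length / 2) + 22L, round(cfg$phage_length / 2) + 58L)
  profile <- defaultDomainProfile(genomeLength(phage), gap = gap)
  events <- sampleInsertions(cfg$n_events, host, phage, model,
                             phageDomainProfile = profile, seed = seed + 2L)
  reads <- packageReads(events, host, phage, mode = "enriched-right",
                        readLength = cfg$read_length, seed = seed + 3L)
  stageLog("simulate", "%d events, %d reads (%d events dropped)",
           nrow(events), length(readSeqs(reads)), reads@log[["dropped_events"]])
  writeGenomeFasta(host, file.path(outDir, "host.fasta"))
  writeGenomeFasta(phage, file.path(outDir, "phage.fasta"))
  writeReadsFastq(reads, file.path(outDir, "reads.fastq"))
  writeTruthTSV(reads, file.path(outDir, "truth.tsv"))

  ## --- junctions --------------------------------------------------------
  rightEnd <- substr(genomeSeq(phage), genomeLength(phage) - 180L,
                     genomeLength(phage))
  valid <- filterValidRight(reads, rightEnd, minHost = cfg$min_host)
  tally <- attr(valid, "tally")
  stageLog("junctions", "%d valid reads (rejected: %s)", nrow(valid),
           paste(names(tally), tally, sep = "=", collapse = ", "))
  frags <- trimAndAnnotate(valid)

  ## --- map --------------------------------------------------------------
  idx <- buildIndex(host)
  pl <- placeFragments(stats::setNames(frags$fragment, frags$read_id), idx,
                       maxMismatchFrac = cfg$max_mismatch_frac,
                       maxGapFrac = cfg$max_gap_frac,
                       minIdentity = cfg$min_identity)
  pl$end <- frags$end
  hostTable <- buildSiteTable(pl, host, end = "right")
  # fragments that fail on the host are candidate self-insertions: place the
  # unmapped ones on the phage genome itself
  un <- pl$status == "unmapped"
  idxP <- buildIndex(phage)
  plP <- placeFragments(stats::setNames(frags$fragment[un], frags$read_id[un]),
                        idxP, maxMismatchFrac = cfg$max_mismatch_frac,
                        maxGapFrac = cfg$max_gap_frac,
                        minIdentity = cfg$min_identity)
  phageTable <- buildSiteTable(plP, phage, end = "right")
  stageLog("map", "host: %s; phage self-insertions: %d unique",
           paste(names(attr(hostTable, "tally")), attr(hostTable, "tally"),
                 sep = "=", collapse = ", "),
           attr(phageTable, "tally")[["unique"]])
  writeSiteTableTSV(hostTable, file.path(outDir, "host_sites.tsv"))
  writeSiteTableBedGraph(hostTable, file.path(outDir, "host_sites.bedgraph"))
  writeSiteTableTSV(phageTable, file.path(outDir, "phage_sites.tsv"))

  ## --- coincidence ------------------------------------------------------
  spec2 <- observedSpectrum(hostTable)
  model2 <- withCallingHandlers(
    expectedSpectrum(max(totalEvents(hostTable), 1L), genomeLength(host)),
    warning = function(w) {
      stageLog("coincidence", "%s", conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  obs <- observedExactly(spec2)
  co <- data.frame(
    multiplicity = as.integer(names(obs)),
    observed_exact = as.integer(obs),
    observed_at_least = as.integer(observedAtLeast(spec2)))
  exp <- expectedCounts(model2)
  co$expected <- exp[as.character(co$multiplicity)]
  utils::write.table(co, file.path(outDir, "coincidence.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  ## --- hotspots ---------------------------------------------------------
  hs <- callHotspots(hostTable, minEventsPerPosition = cfg$hotspot_min_events,
                     pairGap = cfg$pair_gap,
                     referenceTotal = cfg$hotspot_reference_total)
  stageLog("hotspots", "%d hotspots above scaled threshold %.1f", nrow(hs),
           attr(hs, "threshold"))
  consensusOut <- NULL
  hits <- NULL
  if (nrow(hs) >= 2L) {
    # conserved-element discovery over each hotspot neighbourhood (the span
    # plus flank_width on both sides, since the shared element may sit inside
    # or beside the called span)
    flanks <- vapply(seq_len(nrow(hs)), function(i) {
      substrCirc(genomeSeq(host), hs$start[i] - cfg$flank_width,
                 hs$end[i] + cfg$flank_width, genomeLength(host),
                 isCircular(host))
    }, character(1))
    consensusOut <- buildConsensus(flanks)
    if (!consensusOut@flagged) {
      hits <- scanIUPAC(host, consensusOut,
                        maxMismatches = cfg$motif_scan_mismatches)
      share <- motifEventShare(hostTable, hits)
      stageLog("hotspots", "consensus %s; %d genome hits; event share %.3f",
               motifString(consensusOut), nrow(hits), share$share)
      utils::write.table(hits, file.path(outDir, "motif_hits.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
  }
  utils::write.table(hs, file.path(outDir, "hotspots.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  ## --- coldspots --------------------------------------------------------
  track <- densityGCTrack(hostTable, host)
  cold <- callColdspots(track, maxDensity = cfg$coldspot_max_density,
                        minLength = cfg$coldspot_min_length)
  stageLog("coldspots", "%d coldspot region(s)", nrow(cold))
  utils::write.table(cold, file.path(outDir, "coldspots.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  ## --- phagedomain ------------------------------------------------------
  selfModel <- model
  selfModel@immunityLeak <- 1
  selfEvents <- sampleInsertions(cfg$n_self_events, host, phage, selfModel,
                                 phageDomainProfile = profile, seed = seed + 4L)
  selfTable <- siteTableFromEvents(selfEvents, phage, target = "phage-copy")
  prof <- binProfile(selfTable, bin = cfg$bin)
  doms <- segmentDomains(prof)
  loops <- tryCatch(pairLoops(doms), error = function(e) NULL)
  gapHits <- protectedGap(selfTable, minGap = cfg$protected_min_gap)
  stageLog("phagedomain", "%d domains, %s loops, %d protected gap(s)",
           nrow(doms), if (is.null(loops)) "no" else nrow(loopTable(loops)),
           nrow(gapHits))
  utils::write.table(doms, file.path(outDir, "domains.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(loops))
    utils::write.table(loopTable(loops), file.path(outDir, "loops.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(gapHits, file.path(outDir, "protected_gap.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  ## --- summary + manifest ----------------------------------------------
  summary <- list(
    seed = seed,
    input_reads = length(readSeqs(reads)),
    valid_reads = nrow(valid),
    unique_placements = attr(hostTable, "tally")[["unique"]],
    host_events = totalEvents(hostTable),
    self_events = totalEvents(selfTable),
    hotspots = nrow(hs),
    coldspots = nrow(cold),
    domains = nrow(doms))
  writeKeyValue(summary, file.path(outDir, "summary.txt"))
  files <- sort(setdiff(list.files(outDir), "manifest.tsv"))
  manifest <- data.frame(file = files,
                         md5 = unname(tools::md5sum(file.path(outDir, files))))
  utils::write.table(manifest, file.path(outDir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(list(host = host, phage = phage, events = events,
                 reads = reads, valid = valid, placements = pl,
                 hostTable = hostTable, phageTable = phageTable,
                 selfTable = selfTable, coincidence = co, hotspots = hs,
                 consensus = consensusOut, motifHits = hits,
                 coldspots = cold, domains = doms, loops = loops,
                 protectedGap = gapHits, manifest = manifest,
                 outDir = outDir))
}
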