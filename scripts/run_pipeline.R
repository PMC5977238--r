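#!/usr/bin/env Rscript
# Thin command-line wrapper over the SaltoMap pipeline.
#
#   Rscript scripts/run_pipeline.R all --out <dir> [--seed N] [--config file]
#   Rscript scripts/run_pipeline.R simulate --out <dir> [--seed N] [--config file]
#   Rscript scripts/run_pipeline.R junctions --reads r.fastq --phage p.fasta --out <dir>
#   Rscript scripts/run_pipeline.R map --fragments f.tsv --host h.fasta --out <dir>
#   Rscript scripts/run_pipeline.R coincidence --sites s.tsv --host h.fasta --out <dir>
#   Rscript scripts/run_pipeline.R hotspots --sites s.tsv --host h.fasta --out <dir>
#   Rscript scripts/run_pipeline.R coldspots --sites s.tsv --host h.fasta --out <dir>
#   Rscript scripts/run_pipeline.R phagedomain --sites s.tsv --phage p.fasta --out <dir>
#
# A key = value --config file overrides any defaultRunConfig() entry.

suppressMessages(library(SaltoMap))
suppressMessages(library(optparse))

argv <- commandArgs(trailingOnly = TRUE)
if (!length(argv)) stop("missing subcommand; see header for usage")
sub <- argv[1]

parser <- OptionParser(option_list = list(
  make_option("--out", type = "character", default = "salto_out"),
  make_option("--seed", type = "integer", default = 1L),
  make_option("--config", type = "character", default = NULL),
  make_option("--reads", type = "character", default = NULL),
  make_option("--host", type = "character", default = NULL),
  make_option("--phage", type = "character", default = NULL),
  make_option("--fragments", type = "character", default = NULL),
  make_option("--sites", type = "character", default = NULL),
  make_option("--min-host", type = "integer", default = 12L,
              dest = "min_host")
))
opt <- parse_args(parser, args = argv[-1])

cfg <- defaultRunConfig()
if (!is.null(opt$config)) {
  if (!file.exists(opt$config)) stop("config file not found: ", opt$config)
  cfg <- utils::modifyList(cfg, readKeyValueConfig(opt$config))
}
dir.create(opt$out, showWarnings = FALSE, recursive = TRUE)

needFile <- function(path, what) {
  if (is.null(path)) stop("missing --", what)
  if (!file.exists(path)) stop(what, " file not found: ", path)
  path
}

loadSites <- function(path, genome) {
  tab <- utils::read.delim(needFile(path, "sites"))
  SiteTable(tab$end, tab$orientation, refName = genomeName(genome),
            refLength = genomeLength(genome), circular = isCircular(genome))
}

writeTSV <- function(x, name) {
  utils::write.table(x, file.path(opt$out, name), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  message("wrote ", file.path(opt$out, name))
}

if (sub == "all") {
  runPipeline(cfg, outDir = opt$out, seed = opt$seed)
} else if (sub == "simulate") {
  res <- runPipeline(cfg, outDir = opt$out, seed = opt$seed)
  message("genomes, reads and truth written under ", opt$out)
} else if (sub == "junctions") {
  reads <- readReadsFastq(needFile(opt$reads, "reads"))
  phage <- readGenomeFasta(needFile(opt$phage, "phage"), circular = FALSE)
  L <- genomeLength(phage)
  re <- substr(genomeSeq(phage), L - 180L, L)
  valid <- filterValidRight(reads, re, minHost = opt$min_host)
  writeTSV(trimAndAnnotate(valid), "fragments.tsv")
  writeTSV(data.frame(reason = names(attr(valid, "tally")),
                      reads = as.integer(attr(valid, "tally"))),
           "rejections.tsv")
} else if (sub == "map") {
  host <- readGenomeFasta(needFile(opt$host, "host"))
  fr <- utils::read.delim(needFile(opt$fragments, "fragments"))
  idx <- buildIndex(host)
  pl <- placeFragments(stats::setNames(fr$fragment, fr$read_id), idx)
  st <- buildSiteTable(pl, host, end = "right")
  writeSiteTableTSV(st, file.path(opt$out, "sites.tsv"))
  writeSiteTableBedGraph(st, file.path(opt$out, "sites.bedgraph"))
  message("wrote site table (", totalEvents(st), " events)")
} else if (sub == "coincidence") {
  host <- readGenomeFasta(needFile(opt$host, "host"))
  st <- loadSites(opt$sites, host)
  sp <- observedSpectrum(st)
  em <- suppressWarnings(expectedSpectrum(max(totalEvents(st), 1),
                                          genomeLength(host)))
  obs <- observedExactly(sp)
  co <- data.frame(multiplicity = as.integer(names(obs)),
                   observed_exact = as.integer(obs),
                   observed_at_least = as.integer(observedAtLeast(sp)))
  co$expected <- expectedCounts(em)[as.character(co$multiplicity)]
  writeTSV(co, "coincidence.tsv")
} else if (sub == "hotspots") {
  host <- readGenomeFasta(needFile(opt$host, "host"))
  st <- loadSites(opt$sites, host)
  hs <- callHotspots(st, minEventsPerPosition = cfg$hotspot_min_events,
                     pairGap = cfg$pair_gap,
                     referenceTotal = cfg$hotspot_reference_total)
  writeTSV(hs, "hotspots.tsv")
} else if (sub == "coldspots") {
  host <- readGenomeFasta(needFile(opt$host, "host"))
  st <- loadSites(opt$sites, host)
  cold <- callColdspots(densityGCTrack(st, host),
                        maxDensity = cfg$coldspot_max_density,
                        minLength = cfg$coldspot_min_length)
  writeTSV(cold, "coldspots.tsv")
} else if (sub == "phagedomain") {
  phage <- readGenomeFasta(needFile(opt$phage, "phage"), circular = FALSE)
  st <- loadSites(opt$sites, phage)
  dom <- segmentDomains(binProfile(st, bin = cfg$bin))
  writeTSV(dom, "domains.tsv")
  lp <- tryCatch(pairLoops(dom), error = function(e) NULL)
  if (!is.null(lp)) writeTSV(loopTable(lp), "loops.tsv")
  writeTSV(protectedGap(st, minGap = cfg$protected_min_gap),
           "protected_gap.tsv")
} else {
  stop("unknown subcommand: ", sub)
}
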