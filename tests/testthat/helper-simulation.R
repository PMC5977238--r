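# Shared simulation fixtures, built lazily once per test session. The main
# fixture mirrors the study conditions at reduced scale: 1e5 events on a
# 100 kb circular host carrying 14 motif-boosted hotspot sites and low-GC
# islands, with a 10 kb linear phage; self-insertion structure is probed with
# a dedicated 50,000-event sample from the nine-domain profile.

.fixtureEnv <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtureEnv[[name]])) assign(name, builder(), envir = .fixtureEnv)
  .fixtureEnv[[name]]
}

toyPhage <- function() fixture("toyPhage", function() {
  makePhageGenome(PhageSpec(length = 10000L, enzymeSites = c(2000L, 9819L)),
                  seed = 301)
})

rightEndOf <- function(phage) {
  L <- genomeLength(phage)
  substr(genomeSeq(phage), L - 180L, L)
}

# 14 hotspot sites clear of the islands and of each other
BIG_MOTIF_POS <- c(3000L, 9000L, 15000L, 26000L, 32000L, 38000L, 44000L,
                   51000L, 56000L, 76000L, 81000L, 86000L, 91000L, 96000L)
BIG_ISLANDS <- data.frame(
  start = c(20500L, 60500L, 47500L),
  length = c(1530L, 13000L, 1500L),
  gc = c(0.42, 0.46, 0.52))   # the 0.52 island must NOT become a coldspot

PLANTED_GAP <- c(5022L, 5058L)  # 37 bp, right of the 10 kb phage middle

bigSim <- function() fixture("bigSim", function() {
  consensus <- hotspotConsensus()
  motifs <- data.frame(
    position = BIG_MOTIF_POS,
    motif = vapply(seq_along(BIG_MOTIF_POS),
                   function(i) instantiateConsensus(consensus, i), character(1)))
  host <- makeHostGenome(1e5, gc = 0.65, lowGCIslands = BIG_ISLANDS,
                         plantedMotifs = motifs, seed = 101)
  phage <- toyPhage()
  model <- SiteModel(motifPositions = BIG_MOTIF_POS, motifWindow = 5L,
                     motifBoost = 300, immunityLeak = 0.004,
                     duplicationOffset = 5L)
  profile <- defaultDomainProfile(genomeLength(phage), gap = PLANTED_GAP)
  events <- sampleInsertions(1e5, host, phage, model,
                             phageDomainProfile = profile, seed = 102)
  reads <- packageReads(events, host, phage, mode = "enriched-right",
                        readLength = 250L, seed = 103)
  valid <- filterValidRight(reads, rightEndOf(phage))
  frags <- trimAndAnnotate(valid)
  index <- buildIndex(host)
  placements <- placeFragments(stats::setNames(frags$fragment, frags$read_id),
                               index)
  hostTable <- buildSiteTable(placements, host, end = "right")
  list(host = host, phage = phage, model = model, motifPos = BIG_MOTIF_POS,
       islands = BIG_ISLANDS, consensus = consensus, motifs = motifs,
       profile = profile, events = events, reads = reads, valid = valid,
       frags = frags, index = index, placements = placements,
       hostTable = hostTable)
})

# dedicated self-insertion sample at the scale the domain analysis needs
selfSim <- function() fixture("selfSim", function() {
  phage <- toyPhage()
  profile <- defaultDomainProfile(genomeLength(phage), gap = PLANTED_GAP)
  tinyHost <- makeHostGenome(5000L, seed = 201)
  selfModel <- SiteModel(immunityLeak = 1)
  events <- sampleInsertions(50000L, tinyHost, phage, selfModel,
                             phageDomainProfile = profile, seed = 202)
  table <- siteTableFromEvents(events, phage, target = "phage-copy")
  list(phage = phage, profile = profile, events = events, table = table)
})

# uniform-placement table for sampling-based checks
uniformTable <- function(nEvents = 20000L, genomeLength = 1e5, seed = 401) {
  set.seed(seed)
  pos <- sample.int(genomeLength, nEvents, replace = TRUE)
  ori <- sample(c("forward", "reverse"), nEvents, replace = TRUE)
  SiteTable(pos, ori, refName = "uniform", refLength = genomeLength)
}
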