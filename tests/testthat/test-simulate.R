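test_that("host genome honours length, planted motifs and island GC", {
  g <- makeHostGenome(50000, gc = 0.65,
                      lowGCIslands = data.frame(start = 20001, length = 1530,
                                                gc = 0.42),
                      plantedMotifs = data.frame(position = 10,
                                                 motif = "ACGT"),
                      seed = 1)
  expect_equal(genomeLength(g), 50000L)
  expect_equal(substr(genomeSeq(g), 10, 13), "ACGT")
  island <- strsplit(substr(genomeSeq(g), 20001, 21530), "")[[1]]
  expect_lt(abs(mean(island %in% c("G", "C")) - 0.42), 0.03)

  pureGC <- makeHostGenome(500, gc = 1.0, seed = 2)
  expect_true(all(strsplit(genomeSeq(pureGC), "")[[1]] %in% c("G", "C")))

  expect_error(makeHostGenome(1000, lowGCIslands = data.frame(
    start = 900, length = 200, gc = 0.4), seed = 1), "outside")
  expect_error(makeHostGenome(1000, plantedMotifs = data.frame(
    position = c(10, 12), motif = c("ACGTACGT", "ACGTACGT")), seed = 1),
    "overlapping")
})

test_that("phage genome carries the terminal trinucleotides and digest structure", {
  ph <- makePhageGenome(PhageSpec(), seed = 5)
  s <- genomeSeq(ph)
  expect_equal(substr(s, 1, 3), "TGT")
  expect_equal(substr(s, genomeLength(ph) - 2, genomeLength(ph)), "ACA")
  cuts <- enzymeCutSites(ph)
  expect_identical(cuts, c(6170L, 37024L))
  expect_identical(digestFragments(genomeLength(ph), cuts),
                   c(6170L, 30854L, 181L))
  # a spec without enzyme sites digests into a single fragment
  ph0 <- makePhageGenome(PhageSpec(length = 5000L, enzymeSites = integer(0)),
                         seed = 6)
  expect_identical(digestFragments(genomeLength(ph0), integer(0)), 5000L)
})

test_that("digest arithmetic matches the subtraction oracle and conserves length", {
  set.seed(11)
  for (i in 1:20) {
    L <- sample(1000:50000, 1)
    sites <- sort(sample(seq_len(L - 1L), 3))
    fr <- digestFragments(L, sites)
    # direct subtraction oracle
    expect_identical(fr, diff(c(0L, sites, L)))
    expect_equal(sum(fr), L)
    expect_length(fr, 4L)
  }
  expect_error(digestFragments(1000, c(500, 200)), "increasing")
  expect_error(digestFragments(1000, c(500, 1000)), "inside")
})

test_that("site weights apply the GC cold rule and the motif boost", {
  # uniform-GC genome without motifs: all weights equal
  g <- makeHostGenome(5000, gc = 0.65, seed = 21)
  w <- siteWeights(g, SiteModel())
  expect_true(all(w == w[1]))

  # inside a deep low-GC island the cold factor applies verbatim
  g2 <- makeHostGenome(10000, gc = 0.65,
                       lowGCIslands = data.frame(start = 4001, length = 1530,
                                                 gc = 0.42),
                       seed = 22)
  m <- SiteModel()
  w2 <- siteWeights(g2, m)
  expect_equal(w2[4800], m@baseWeight * m@gcColdFactor)
  expect_equal(w2[1000], m@baseWeight)

  # positions within the motif window are boosted
  m3 <- SiteModel(motifPositions = 2000L, motifWindow = 5L)
  w3 <- siteWeights(g, m3)
  expect_equal(w3[2000], m3@baseWeight * m3@motifBoost)
  expect_equal(w3[1995], m3@baseWeight * m3@motifBoost)   # start - window
  expect_equal(w3[2039], m3@baseWeight * m3@motifBoost)   # end + window
  expect_equal(w3[1994], m3@baseWeight)
  expect_equal(w3[2040], m3@baseWeight)
})

test_that("sampled insertions reproduce the weight model", {
  g <- makeHostGenome(10000, gc = 0.65, seed = 31)
  ph <- toyPhage()
  model <- SiteModel(motifPositions = 5000L, motifWindow = 5L,
                     immunityLeak = 0)
  n <- 1e5
  ev <- sampleInsertions(n, g, ph, model, seed = 32)
  expect_equal(sum(ev$target == "phage-copy"), 0L)

  # Monte-Carlo boost recovery: empirical insertion share of the boosted
  # footprint within 3 binomial standard errors of the exact weight share
  w <- siteWeights(g, model)
  boosted <- w > model@baseWeight
  # reverse events are recorded shifted; undo for comparison with weights
  site <- ifelse(ev$orientation == "reverse",
                 ev$position - model@duplicationOffset, ev$position)
  site <- ((site - 1L) %% genomeLength(g)) + 1L
  pExp <- sum(w[boosted]) / sum(w)
  pObs <- mean(boosted[site])
  se <- sqrt(pExp * (1 - pExp) / n)
  expect_lt(abs(pObs - pExp), 3 * se)
  # the implied fold enrichment is the configured boost
  nb <- sum(boosted)
  fold <- (pObs / nb) / ((1 - pObs) / (genomeLength(g) - nb))
  expect_lt(abs(fold - model@motifBoost) / model@motifBoost, 0.1)

  # chi-square goodness of fit on a 10-bin coarsening
  bins <- cut(site, breaks = seq(0, genomeLength(g), length.out = 11))
  pBins <- tapply(w, cut(seq_along(w), breaks = seq(0, genomeLength(g),
                                                    length.out = 11)), sum)
  gof <- suppressWarnings(stats::chisq.test(table(bins), p = pBins / sum(pBins)))
  expect_gt(gof$p.value, 0.01)
})

test_that("immunity leak is binomially consistent across seeds", {
  g <- makeHostGenome(20000, gc = 0.65, seed = 41)
  ph <- toyPhage()
  model <- SiteModel(immunityLeak = 0.004)
  n <- 1e5
  se <- sqrt(0.004 * 0.996 / n)
  for (seed in 42:44) {
    ev <- sampleInsertions(n, g, ph, model, seed = seed)
    frac <- mean(ev$target == "phage-copy")
    expect_lt(abs(frac - 0.004), 3 * se)
  }
})

test_that("packaged reads carry the junctions they claim", {
  g <- makeHostGenome(30000, gc = 0.65, seed = 51)
  ph <- toyPhage()
  ev <- data.frame(target = "host", position = 12345L,
                   orientation = "forward")
  rs <- packageReads(ev, g, ph, mode = "whole-virion", seed = 52)
  tr <- readTruth(rs)
  left <- tr[tr$end == "left", ]
  rd <- as.character(readSeqs(rs)[[left$read_id]])
  l <- left$host_len
  expect_true(l >= 31 && l <= 36)
  # host prefix ends exactly at the event position, then the phage "TGT..."
  expect_equal(substr(rd, 1, l),
               substr(genomeSeq(g), 12345 - l + 1, 12345))
  expect_equal(substr(rd, l + 1, l + 3), "TGT")

  # enriched-right mode: every junction read starts with the right-end fragment
  ev2 <- sampleInsertions(1000, g, ph, SiteModel(immunityLeak = 0), seed = 53)
  rs2 <- packageReads(ev2, g, ph, mode = "enriched-right", seed = 54)
  re <- rightEndOf(ph)
  starts <- substr(as.character(readSeqs(rs2)), 1, nchar(re))
  expect_true(all(starts == re))

  # junction count recovered downstream equals the truth reads with >=12 bp host
  v <- filterValidRight(rs2, re, minHost = 12L)
  expect_equal(nrow(v), sum(readTruth(rs2)$host_len >= 12))
})
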