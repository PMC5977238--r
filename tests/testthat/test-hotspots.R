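test_that("hotspot calling merges paired peaks and ranks by events", {
  empty <- SiteTable(integer(0), character(0), "g", 1000)
  expect_equal(nrow(callHotspots(empty, minEventsPerPosition = 5)), 0L)

  # two above-threshold peaks 5 bp apart merge into one paired hotspot
  pos <- c(rep(100L, 40), rep(105L, 35), rep(700L, 50))
  ori <- c(rep("forward", 40), rep("reverse", 35), rep("forward", 50))
  st <- SiteTable(pos, ori, "g", 1000)
  hs <- callHotspots(st, minEventsPerPosition = 30, pairGap = 20L)
  expect_equal(nrow(hs), 2L)
  paired <- hs[hs$start == 100, ]
  expect_equal(sort(c(paired$peak1, paired$peak2)), c(100L, 105L))
  expect_equal(paired$eventCount, 75L)
  expect_equal(paired$forwardRatio, 40 / 75)
  expect_equal(hs$rank[hs$start == 100], 1L)  # more events -> rank 1

  # permutation invariance of the input events
  st2 <- SiteTable(rev(pos), rev(ori), "g", 1000)
  expect_equal(callHotspots(st2, minEventsPerPosition = 30), hs)
})

test_that("all fourteen planted hotspots are recovered at the scaled threshold", {
  sim <- bigSim()
  hs <- callHotspots(sim$hostTable, referenceTotal = 13383386)
  expect_equal(nrow(hs), 14L)
  covered <- vapply(sim$motifPos, function(p)
    any(hs$start <= p + 45 & hs$end >= p - 10), logical(1))
  expect_true(all(covered))
  # forward/reverse usage is roughly balanced at every hotspot
  expect_true(all(abs(hs$forwardRatio - 0.5) < 0.1))
})

test_that("flank extraction honours width, circularity and truncation", {
  g <- makeHostGenome(5000, gc = 0.65, circular = TRUE, seed = 91)
  fl <- extractFlanks(list(start = 100, end = 110), g, width = 280)
  expect_equal(nchar(fl$left), 280L)   # wraps across the origin
  expect_equal(nchar(fl$right), 280L)
  expect_false(any(fl$truncated))
  expect_equal(fl$right, substr(genomeSeq(g), 111, 390))

  gl <- Genome("lin", genomeSeq(g), circular = FALSE)
  fl2 <- extractFlanks(list(start = 100, end = 110), gl, width = 280)
  expect_equal(nchar(fl2$left), 99L)
  expect_true(fl2$truncated[["left"]])
  expect_false(fl2$truncated[["right"]])
})

test_that("the consensus builder recovers a planted degenerate motif", {
  consensus <- hotspotConsensus()
  set.seed(92)
  offsets <- rep(54:60, length.out = 14)
  flanks <- vapply(1:14, function(i) {
    bg <- paste(sample(c("A", "C", "G", "T"), 280, replace = TRUE,
                       prob = c(.175, .325, .325, .175)), collapse = "")
    inst <- instantiateConsensus(consensus, i)
    paste0(substr(bg, 1, offsets[i] - 1), inst,
           substr(bg, offsets[i] + nchar(inst), 280))
  }, character(1))
  cm <- buildConsensus(flanks)
  expect_false(cm@flagged)
  expect_equal(motifString(cm), consensus)
  expect_equal(motifOffsets(cm), offsets)

  # a column with half C / half T becomes the code Y
  half <- vapply(1:14, function(i) {
    core <- paste0("GGATCGGATCGGATCGGATC", if (i <= 7) "C" else "T",
                   "AATTGGCCAATTGGCCAATT")
    paste0(strrep("A", 3), core, strrep("G", 3))
  }, character(1))
  cmY <- buildConsensus(half, minBlock = 20L)
  expect_true(grepl("Y", motifString(cmY)))
})

test_that("the IUPAC scanner agrees with the brute-force oracle", {
  consensus <- hotspotConsensus()
  # an exact instantiation is found once at zero mismatches
  g <- makeHostGenome(3000, gc = 0.65,
                      plantedMotifs = data.frame(
                        position = 1500,
                        motif = instantiateConsensus(consensus, 1)),
                      circular = FALSE, seed = 93)
  h0 <- scanIUPAC(g, consensus, maxMismatches = 0)
  expect_equal(nrow(h0), 1L)
  expect_equal(h0$position, 1500L)
  expect_equal(h0$mismatches, 0L)

  # a 2-substitution instantiation is found at tolerance 3
  inst <- instantiateConsensus(consensus, 2)
  substr(inst, 5, 5) <- "A"; substr(inst, 20, 20) <- "A"
  g2 <- makeHostGenome(3000, gc = 0.65,
                       plantedMotifs = data.frame(position = 800, motif = inst),
                       circular = FALSE, seed = 94)
  h2 <- scanIUPAC(g2, consensus, maxMismatches = 3)
  expect_true(800 %in% h2$position)

  # property: equality with the brute-force scan (no dedup) on random genomes
  for (seed in 95:97) {
    gr <- makeHostGenome(2000, gc = 0.65, circular = FALSE, seed = seed)
    mine <- scanIUPAC(gr, "YGGCGGATAACCGC", maxMismatches = 3, dedupe = FALSE)
    oracle <- bruteIUPACScan(genomeSeq(gr), "YGGCGGATAACCGC", 3)
    expect_equal(mine$position, oracle$position)
    expect_equal(mine$strand, oracle$strand)
    expect_equal(mine$mismatches, oracle$mismatches)
  }
  expect_error(scanIUPAC(g, "ACGTX"), "IUPAC")
})

test_that("scanning the reverse-complement genome mirrors hit coordinates", {
  motif <- "RGGCGGATAACCGY"  # non-palindromic query
  g <- makeHostGenome(4000, gc = 0.65,
                      plantedMotifs = data.frame(
                        position = c(1000, 2500),
                        motif = c(instantiateConsensus(motif, 1),
                                  instantiateConsensus(motif, 2))),
                      circular = FALSE, seed = 98)
  L <- genomeLength(g)
  gRC <- Genome("rc", as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(genomeSeq(g)))), circular = FALSE)
  h1 <- scanIUPAC(g, motif, maxMismatches = 1, dedupe = FALSE)
  h2 <- scanIUPAC(gRC, motif, maxMismatches = 1, dedupe = FALSE)
  m <- nchar(motif)
  mirrored <- sort(L - (h1$position + m - 1L) + 1L)
  expect_equal(sort(h2$position), mirrored)
})

test_that("the motif-adjacent event share matches the planted bias", {
  # no hits -> zero share
  ut <- uniformTable(1000, 50000, seed = 403)
  none <- data.frame(position = integer(0), strand = character(0),
                     mismatches = integer(0))
  expect_equal(motifEventShare(ut, none, motifLength = 35)$share, 0)

  # all events inside the windows -> share 1
  hits1 <- data.frame(position = 1L, strand = "+", mismatches = 0L)
  stAll <- SiteTable(rep(50L, 10), "forward", "g", 50000)
  expect_equal(motifEventShare(stAll, hits1, motifLength = 35)$share, 1)

  # planted-rate recovery on a simulated genome
  g <- makeHostGenome(50000, gc = 0.65,
                      plantedMotifs = data.frame(
                        position = 25000,
                        motif = instantiateConsensus(hotspotConsensus(), 3)),
                      seed = 99)
  model <- SiteModel(motifPositions = 25000L, motifWindow = 5L,
                     motifBoost = 58, immunityLeak = 0)
  n <- 2e4
  ev <- sampleInsertions(n, g, toyPhage(), model, seed = 100)
  st <- siteTableFromEvents(ev, g, target = "host")
  hits <- scanIUPAC(g, hotspotConsensus(), maxMismatches = 3)
  res <- motifEventShare(st, hits, window = 120)
  # expected share from the exact weights over the same footprint
  w <- siteWeights(g, model)
  mask <- logical(genomeLength(g))
  for (i in seq_len(nrow(hits)))
    mask[max(1, hits$position[i] - 120):min(genomeLength(g),
         hits$position[i] + 34 + 120)] <- TRUE
  pExp <- sum(w[mask]) / sum(w)
  se <- sqrt(pExp * (1 - pExp) / n)
  expect_lt(abs(res$share - pExp), 4 * se)
  foldExp <- pExp / (sum(mask) / genomeLength(g))
  expect_lt(abs(res$foldBias - foldExp) / foldExp, 0.1)
})
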