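test_that("the seed index resolves k-mers, including across a circular origin", {
  g <- makeHostGenome(100, gc = 0.5, circular = FALSE, seed = 81)
  idx <- buildIndex(g, k = 15L)
  # L - k + 1 plus-strand seeds on a linear genome
  expect_equal(sum(lengths(as.list(idx@env))), 86L)

  # a planted unique 15-mer is retrieved at exactly its position
  g2 <- makeHostGenome(2000, gc = 0.65,
                       plantedMotifs = data.frame(position = 500,
                                                  motif = "AAAAATTTTTAAAAA"),
                       seed = 82)
  idx2 <- buildIndex(g2, k = 15L)
  expect_identical(lookupKmer(idx2, "AAAAATTTTTAAAAA"), 500L)

  # wrap-around k-mers exist on circular genomes
  gc <- Genome("circ", paste(rep("ACGT", 25), collapse = ""), circular = TRUE)
  idxc <- buildIndex(gc, k = 15L)
  tailhead <- paste0(substr(genomeSeq(gc), 95, 100),
                     substr(genomeSeq(gc), 1, 9))
  expect_true(length(lookupKmer(idxc, tailhead)) >= 1)
})

test_that("placement enforces the floored mismatch budget", {
  g <- makeHostGenome(20000, gc = 0.65, circular = FALSE, seed = 83)
  idx <- buildIndex(g)
  f <- substr(genomeSeq(g), 5000, 5033)        # error-free 34 bp
  pl <- placeFragments(f, idx)
  expect_equal(pl$status, "unique")
  expect_equal(pl$alignStart, 5000L)
  expect_equal(pl$mismatches, 0L)
  # one substitution in 34 bp: floor(0.02 x 34) = 0 allowed -> unmapped
  f1 <- f
  substr(f1, 20, 20) <- if (substr(f, 20, 20) == "A") "C" else "A"
  expect_equal(placeFragments(f1, idx)$status, "unmapped")
  expect_error(placeFragments("", idx), "empty")
})

test_that("placement calls agree with the exhaustive alignment oracle", {
  g <- makeHostGenome(20000, gc = 0.65, circular = FALSE, seed = 84)
  idx <- buildIndex(g)
  set.seed(85)
  frags <- character(200)
  for (i in 1:200) {
    st <- sample.int(20000 - 59, 1)
    f <- substr(genomeSeq(g), st, st + 59)
    if (i %% 2 == 0) {  # up to one substitution
      p <- sample.int(60, 1)
      substr(f, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                        substr(f, p, p)), 1)
    }
    if (i %% 5 == 0)
      f <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(f)))
    frags[i] <- f
  }
  pl <- placeFragments(frags, idx)
  for (i in 1:200) {
    oracle <- brutePlaceStatus(frags[i], genomeSeq(g),
                               maxMismatch = floor(0.02 * 60))
    expect_equal(pl$status[i], oracle$status, label = paste("fragment", i))
    if (oracle$status == "unique") {
      expect_equal(pl$alignStart[i], oracle$start)
      expect_equal(pl$mismatches[i], oracle$mm)
    }
  }
})

test_that("mapping is strand-consistent under reference reverse-complement", {
  g <- makeHostGenome(10000, gc = 0.65, circular = FALSE, seed = 86)
  L <- genomeLength(g)
  gRC <- Genome("rc", as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(genomeSeq(g)))),
    circular = FALSE)
  idx <- buildIndex(g); idxRC <- buildIndex(gRC)
  set.seed(87)
  starts <- sample.int(L - 69, 20)
  frags <- substring(genomeSeq(g), starts, starts + 68)
  t1 <- buildSiteTable(placeFragments(frags, idx), g, end = "right")
  t2 <- buildSiteTable(placeFragments(frags, idxRC), gRC, end = "right")
  c1 <- siteCounts(t1); c2 <- siteCounts(t2)
  # forward events become reverse events at mirrored coordinates
  expect_equal(sum(c1$count[c1$orientation == "forward"]),
               sum(c2$count[c2$orientation == "reverse"]))
  expect_setequal(L - c1$position[c1$orientation == "forward"] + 1L,
                  c2$position[c2$orientation == "reverse"])
})

test_that("site tables aggregate unique placements only and tally the rest", {
  g <- makeHostGenome(5000, gc = 0.65, seed = 88)
  pl <- data.frame(
    fragment_id = c("a", "b", "c", "d", "e"),
    status = c("unique", "unique", "unique", "ambiguous", "unmapped"),
    strand = c("+", "+", "-", "+", NA),
    alignStart = c(100L, 100L, 150L, 7L, NA),
    alignEnd = c(140L, 140L, 190L, 47L, NA),
    mismatches = c(0L, 0L, 0L, 0L, NA), gaps = c(0L, 0L, 0L, 0L, NA))
  st <- buildSiteTable(pl, g, end = "right")
  cc <- siteCounts(st)
  expect_equal(totalEvents(st), 3L)
  expect_equal(cc$count[cc$position == 100 & cc$orientation == "forward"], 2L)
  expect_equal(cc$count[cc$position == 190 & cc$orientation == "reverse"], 1L)
  tl <- attr(st, "tally")
  expect_equal(sum(tl), nrow(pl))
  expect_equal(unname(tl), c(3L, 1L, 1L))

  # no unique placements -> empty table
  st0 <- buildSiteTable(pl[pl$status == "ambiguous", , drop = FALSE], g)
  expect_equal(totalEvents(st0), 0L)
})

test_that("simulated event tallies survive the full read/map round trip", {
  sim <- bigSim()
  truth <- readTruth(sim$reads)
  truthHost <- truth[truth$target == "host", ]
  pl <- sim$placements
  L <- genomeLength(sim$host)
  wrap <- function(p) ((p - 1L) %% L) + 1L
  rec <- data.frame(read_id = pl$fragment_id, status = pl$status,
                    pos = wrap(ifelse(pl$strand == "+", pl$alignStart,
                                      pl$alignEnd)),
                    ori = ifelse(pl$strand == "+", "forward", "reverse"))
  mm <- merge(rec, truthHost, by = "read_id")
  ok <- mm$status == "unique" & mm$pos == mm$position &
    mm$ori == mm$orientation
  expect_gte(mean(ok), 0.99)
  # and each unique placement is at its truth position
  expect_gte(mean(mm$pos[mm$status == "unique"] ==
                    mm$position[mm$status == "unique"]), 0.999)
})
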