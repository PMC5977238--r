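test_that("binning conserves counts and separates orientations", {
  st <- SiteTable(positions = c(3, 10, 48, 51, 200),
                  orientations = c("forward", "forward", "reverse", "forward",
                                   "reverse"),
                  refName = "phage", refLength = 300, circular = FALSE)
  bp <- binProfile(st, bin = 50)
  expect_equal(nrow(bp), 6L)
  expect_equal(bp$total[1], 3L)
  expect_equal(bp$forward[1], 2L)
  expect_equal(bp$reverse[1], 1L)
  expect_equal(sum(bp$total), totalEvents(st))

  empty <- binProfile(SiteTable(integer(0), character(0), "phage", 300,
                                circular = FALSE), bin = 50)
  expect_true(all(empty$total == 0L))
})

test_that("domain segmentation recovers the planted nine-domain organisation", {
  ss <- selfSim()
  bp <- binProfile(ss$table, bin = 50)
  dom <- segmentDomains(bp)
  expect_equal(nrow(dom), 9L)
  expect_equal(dom$label, paste0("D", 1:9))
  # boundaries within two bins (100 bp) of the planted ones
  planted <- attr(ss$profile, "boundaries")
  found <- attr(dom, "boundaries")
  expect_length(found, 8L)
  expect_true(all(abs(found - planted) <= 100))
  # interior relative densities within 10% of the planted profile
  plantedRel <- c(330, 800, 800, 1332, 620, 709, 1049)
  rel <- dom$density[2:8] / sum(dom$density[2:8]) * sum(plantedRel)
  expect_true(all(abs(rel - plantedRel) / plantedRel < 0.10))
  # domains tile the genome and all events are accounted for
  expect_equal(dom$start[1], 1L)
  expect_equal(dom$end[9], refLength(ss$table))
  expect_true(all(dom$start[-1] == dom$end[-9] + 1L))
  expect_equal(sum(dom$count) + attr(dom, "boundaryEvents") +
                 attr(dom, "maskedEvents"), sum(bp$total))
})

test_that("flat profiles yield a single flagged domain and masks suppress artifacts", {
  flat <- SiteTable(positions = rep(seq(10, 9990, by = 20), each = 2),
                    orientations = c("forward", "reverse"),
                    refName = "phage", refLength = 10000, circular = FALSE)
  bp <- binProfile(flat, bin = 50)
  dom <- segmentDomains(bp)
  expect_equal(nrow(dom), 1L)
  expect_true(attr(dom, "flagged"))

  # an artifact spike inside an exclusion zone must not become a boundary
  pos <- c(rep(seq(10, 9990, by = 20), each = 2), rep(2010L, 400))
  spiked <- SiteTable(pos, "forward", "phage", 10000, circular = FALSE)
  bp2 <- binProfile(spiked, bin = 50)
  withMask <- segmentDomains(bp2, exclusionZones = list(c(1900L, 2100L)))
  expect_equal(nrow(withMask), 1L)
  expect_gt(attr(withMask, "maskedEvents"), 400)
  noMask <- segmentDomains(bp2)
  expect_equal(nrow(noMask), 2L)
})

test_that("density arithmetic follows events per kilobase", {
  expect_equal(floor(domainDensity(9594, 7200)), 1332)
  expect_equal(floor(domainDensity(958, 2900)), 330)
  expect_equal(domainDensity(0, 1000), 0)
})

test_that("loop pairing mirrors the outermost-inward geometry", {
  mk <- function(counts) data.frame(label = paste0("D", seq_along(counts)),
                                    start = 1, end = 2, count = counts)
  # nine domains: D2..D8 interior, apex D5
  lp <- pairLoops(mk(c(10, 958, 100, 100, 500, 100, 100, 6084, 10)))
  tab <- loopTable(lp)
  expect_equal(nrow(tab), 4L)
  expect_equal(apexDomain(lp), "D5")
  expect_equal(tab$upstream, c("D2", "D3", "D4", "D5"))
  expect_equal(tab$downstream, c("D8", "D7", "D6", NA))
  # the denser side of loop L1 attracts 86% of its events
  expect_equal(round(100 * tab$downstreamShare[1]), 86)

  # symmetric counts halve evenly
  lp2 <- pairLoops(mk(c(1, 50, 50, 50, 9, 50, 50, 50, 1)))
  expect_true(all(loopTable(lp2)$upstreamShare[1:3] == 0.5))

  # an even interior cannot close around an apex
  expect_error(pairLoops(mk(c(1, 5, 5, 1))), "odd")
})

test_that("the protected gap near the genome middle is recovered exactly", {
  ss <- selfSim()
  pg <- protectedGap(ss$table, minGap = 30, searchRadius = 1000)
  expect_false(attr(pg, "uninformative"))
  expect_equal(nrow(pg), 1L)
  expect_lte(abs(pg$start - PLANTED_GAP[1]), 1)
  expect_lte(abs(pg$end - PLANTED_GAP[2]), 1)
  expect_equal(pg$offsetFromMiddle,
               round(mean(PLANTED_GAP) - refLength(ss$table) / 2))

  # a dense uniform profile leaves no gap of 30 bp or more
  for (seed in 601:603) {
    set.seed(seed)
    pos <- sample.int(10000, 13000, replace = TRUE)
    dense <- SiteTable(pos, "forward", "phage", 10000, circular = FALSE)
    expect_equal(nrow(protectedGap(dense, minGap = 30)), 0L)
  }

  # an empty table flags the whole window as uninformative
  pg0 <- protectedGap(SiteTable(integer(0), character(0), "phage", 10000,
                                circular = FALSE))
  expect_true(attr(pg0, "uninformative"))
  expect_equal(pg0$length, 2001L)
})
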