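test_that("left junctions are recovered from constructed reads", {
  ph <- toyPhage()
  host34 <- paste0(strrep("A", 17), strrep("C", 17))
  read <- paste0(host34, substr(genomeSeq(ph), 1, 60))
  j <- extractLeftJunctions(c(junc = read), ph)
  expect_equal(nrow(j), 1L)
  expect_equal(nchar(j$host_fragment), 34L)
  expect_equal(j$host_fragment, host34)
  expect_equal(j$phage_overlap, 60L)

  # a phage-internal read carries no junction
  internal <- substr(genomeSeq(ph), 3000, 3200)
  j2 <- extractLeftJunctions(c(int = internal), ph)
  expect_equal(nrow(j2), 0L)
  expect_equal(attr(j2, "tally")[["no_junction"]], 1L)

  # too-short reads are skipped and counted
  j3 <- extractLeftJunctions(c(short = substr(read, 1, 20)), ph)
  expect_equal(attr(j3, "tally")[["too_short"]], 1L)

  # the reverse-complemented read is found on the other orientation
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(read)))
  j4 <- extractLeftJunctions(c(rc = rc), ph)
  expect_equal(j4$host_fragment, host34)
})

test_that("simulated whole-virion reads give 31-36 bp left flanks at high recall", {
  host <- makeHostGenome(30000, gc = 0.65, seed = 61)
  ph <- toyPhage()
  ev <- sampleInsertions(2000, host, ph, SiteModel(immunityLeak = 0),
                         seed = 62)
  rs <- packageReads(ev, host, ph, mode = "whole-virion", seed = 63)
  j <- extractLeftJunctions(rs, ph)
  lens <- nchar(j$host_fragment)
  expect_true(all(lens >= 31 & lens <= 36))
  truthLeft <- readTruth(rs)[readTruth(rs)$end == "left", ]
  eligible <- truthLeft[truthLeft$host_len >= 12, ]
  expect_gte(nrow(j) / nrow(eligible), 0.99)
})

test_that("the valid-read filter enforces the exact prefix and the host minimum", {
  ph <- toyPhage()
  re <- rightEndOf(ph)
  ok12 <- paste0(re, strrep("A", 12))
  ok11 <- paste0(re, strrep("A", 11))
  mut <- re
  substr(mut, 90, 90) <- if (substr(re, 90, 90) == "A") "C" else "A"
  mismatched <- paste0(mut, strrep("A", 20))
  reads <- c(a = ok12, b = ok11, c = mismatched)
  v <- filterValidRight(reads, re)
  expect_equal(v$read_id, "a")
  expect_equal(nchar(v$host_fragment), 12L)
  tally <- attr(v, "tally")
  expect_equal(tally[["host_too_short"]], 1L)
  expect_equal(tally[["prefix_mismatch"]], 1L)
  expect_equal(nrow(v) + sum(tally), length(reads))

  # idempotent: filtering the accepted reads again keeps all of them
  again <- filterValidRight(paste0(re, v$host_fragment), re)
  expect_equal(nrow(again), nrow(v))

  # orientation-symmetric: reverse-complementing every read changes nothing
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(reads)))
  names(rc) <- names(reads)
  v2 <- filterValidRight(rc, re)
  expect_equal(nrow(v2), nrow(v))
  expect_equal(v2$host_fragment, v$host_fragment)
})

test_that("trimming removes the phage portion and keeps provenance", {
  ph <- toyPhage()
  re <- rightEndOf(ph)
  rd <- paste0(re, substr(strrep("ACGT", 18), 1, 69))  # 250 bp read, 69 bp host
  expect_equal(nchar(rd), 250L)
  v <- filterValidRight(c(r1 = rd), re)
  fr <- trimAndAnnotate(v)
  expect_equal(nchar(fr$fragment), 250L - 181L)
  expect_equal(fr$start_mark, 0L)
  expect_equal(fr$read_id, "r1")

  j <- data.frame(read_id = "x", end = "left", host_fragment = strrep("A", 34),
                  start_mark = 1L, phage_overlap = 40L)
  expect_equal(nchar(trimAndAnnotate(j)$fragment), 34L)
})

test_that("the truncated-genome control separates chimeras from real junctions", {
  host <- makeHostGenome(30000, gc = 0.65, seed = 71)
  ph <- toyPhage()
  ev <- sampleInsertions(800, host, ph, SiteModel(immunityLeak = 0), seed = 72)
  rs <- packageReads(ev, host, ph, mode = "whole-virion", seed = 73)
  truncs <- c(1000L, 3000L, 5000L)

  rep0 <- chimeraControl(rs, ph, truncations = truncs, host = host)
  expect_equal(rep0$truncation_offsets, truncs)
  expect_true(all(rep0$candidates_per_end <= 3))
  expect_gt(rep0$bona_fide_junctions, 500)

  # planted chimeric joins at one artificial end are detected in proportion
  set.seed(74)
  chim <- vapply(1:20, function(i) {
    hstart <- sample.int(29000, 1)
    paste0(substr(genomeSeq(host), hstart, hstart + 39),
           substr(genomeSeq(ph), 1001, 1160))
  }, character(1))
  names(chim) <- paste0("chim_", 1:20)
  rs2 <- Biostrings::DNAStringSet(c(as.character(readSeqs(rs)), chim))
  rep1 <- chimeraControl(rs2, ph, truncations = truncs, host = host)
  expect_gte(rep1$candidates_per_end[["minus_1000bp"]], 18)
  expect_equal(rep1$bona_fide_junctions, rep0$bona_fide_junctions)
})
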