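# Independent oracles used to cross-check the package implementations.
# Deliberately naive: straight loops, no shared code with the package paths
# they verify.

# sliding-window IUPAC motif scan by direct per-position comparison
bruteIUPACScan <- function(genomeStr, iupac, maxMismatches,
                           bothStrands = TRUE) {
  sets <- strsplit(Biostrings::IUPAC_CODE_MAP, "")
  g <- strsplit(genomeStr, "")[[1]]
  scan1 <- function(motif, strand) {
    mcols <- strsplit(motif, "")[[1]]
    m <- length(mcols)
    res <- list()
    for (p in seq_len(length(g) - m + 1L)) {
      mm <- 0L
      for (j in seq_len(m)) {
        if (!(g[p + j - 1L] %in% sets[[mcols[j]]])) mm <- mm + 1L
        if (mm > maxMismatches) break
      }
      if (mm <= maxMismatches)
        res[[length(res) + 1L]] <- data.frame(position = p, strand = strand,
                                              mismatches = mm)
    }
    if (length(res)) do.call(rbind, res) else
      data.frame(position = integer(0), strand = character(0),
                 mismatches = integer(0))
  }
  out <- scan1(iupac, "+")
  if (bothStrands) {
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(iupac)))
    out <- rbind(out, scan1(rc, "-"))
  }
  out[order(out$position, out$strand), , drop = FALSE]
}

# exhaustive fragment placement using Biostrings::matchPattern as the aligner
brutePlaceStatus <- function(fragment, genomeStr, maxMismatch) {
  subj <- Biostrings::DNAString(genomeStr)
  hits <- data.frame(strand = character(0), start = integer(0), mm = integer(0))
  for (strand in c("+", "-")) {
    pat <- if (strand == "+") fragment else
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(fragment)))
    m <- Biostrings::matchPattern(pat, subj, max.mismatch = maxMismatch)
    if (length(m)) {
      mm <- vapply(seq_along(m), function(i)
        sum(strsplit(as.character(m[[i]]), "")[[1]] !=
              strsplit(pat, "")[[1]]), integer(1))
      hits <- rbind(hits, data.frame(strand = strand,
                                     start = Biostrings::start(m), mm = mm))
    }
  }
  if (!nrow(hits)) return(list(status = "unmapped"))
  best <- hits[hits$mm == min(hits$mm), , drop = FALSE]
  list(status = if (nrow(best) == 1L) "unique" else "ambiguous",
       strand = best$strand[1L], start = best$start[1L], mm = best$mm[1L])
}

# deterministic instantiation of an IUPAC consensus: degenerate columns cycle
# through their allowed bases with flank index i
instantiateConsensus <- function(iupac, i) {
  sets <- strsplit(Biostrings::IUPAC_CODE_MAP, "")
  cols <- strsplit(iupac, "")[[1]]
  paste(vapply(seq_along(cols), function(j) {
    s <- sets[[cols[j]]]
    s[((i + j) %% length(s)) + 1L]
  }, character(1)), collapse = "")
}
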