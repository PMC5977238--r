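# Internal helpers shared across modules. No hidden RNG state: every public
# function that draws random numbers takes an explicit `seed` and restores the
# caller's .Random.seed on exit.

withSeed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer or NULL")
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) stats::runif(1L)
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

DNA_BASES <- c("A", "C", "G", "T")

# iid random sequence at a given GC fraction
randomDNA <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(DNA_BASES, n, replace = TRUE, prob = p), collapse = "")
}

# random arrangement with the exact base composition implied by `gc`
# (used for planted islands so their GC hits the requested value)
randomDNAExactGC <- function(n, gc) {
  ngc <- round(n * gc)
  x <- c(sample(c("G", "C"), ngc, replace = TRUE),
         sample(c("A", "T"), n - ngc, replace = TRUE))
  sample(x)
}

revcompChar <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# substring with circular wrap; span must be <= L
substrCirc <- function(s, start, end, L, circular = TRUE) {
  if (start >= 1L && end <= L) return(substr(s, start, end))
  if (!circular) stop("coordinates run off a linear sequence")
  start <- ((start - 1L) %% L) + 1L
  end <- ((end - 1L) %% L) + 1L
  if (start <= end) substr(s, start, end)
  else paste0(substr(s, start, L), substr(s, 1L, end))
}

# vectorised substring on one subject with optional circular wrap
substrVec <- function(s, starts, ends, L, circular = TRUE) {
  out <- character(length(starts))
  inb <- starts >= 1L & ends <= L
  out[inb] <- substring(s, starts[inb], ends[inb])
  if (any(!inb)) {
    if (!circular) stop("coordinates run off a linear sequence")
    idx <- which(!inb)
    out[idx] <- vapply(idx, function(i) substrCirc(s, starts[i], ends[i], L, TRUE),
                       character(1))
  }
  out
}

wrapPos <- function(pos, L) ((pos - 1L) %% L) + 1L

# Hamming distance between two equal-length strings (C-level via raw compare)
hammingStr <- function(a, b) sum(charToRaw(a) != charToRaw(b))

# sliding-window GC fraction, one value per position (window centred);
# windows wrap on circular sequences and shrink at the ends of linear ones
rollingGC <- function(chars, window, circular = TRUE) {
  L <- length(chars)
  if (window > L) stop("window larger than sequence")
  gci <- as.integer(chars %in% c("G", "C"))
  hw <- window %/% 2L
  if (circular) {
    pad <- c(gci[(L - hw + 1L):L], gci, gci[seq_len(window - hw - 1L)])
    cs <- c(0, cumsum(pad))
    (cs[(1:L) + window] - cs[1:L]) / window
  } else {
    cs <- c(0, cumsum(gci))
    lo <- pmax(1L, (1:L) - hw)
    hi <- pmin(L, (1:L) + (window - hw - 1L))
    (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  }
}

ORIENTATIONS <- c("forward", "reverse")
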