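# Readers/writers for the standard interchange formats: FASTA/FASTQ via
# Biostrings, tab-separated site tables, BED/bedGraph tracks, key=value
# configuration files.

#' Write a Genome as FASTA
#' @param genome a [Genome-class].
#' @param path output file.
#' @export
writeGenomeFasta <- function(genome, path) {
  x <- Biostrings::DNAStringSet(genomeSeq(genome))
  names(x) <- genomeName(genome)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a Genome from FASTA
#' @param path FASTA file (first record used).
#' @param circular circularity flag to attach.
#' @return a [Genome-class].
#' @export
readGenomeFasta <- function(path, circular = TRUE) {
  x <- Biostrings::readDNAStringSet(path)
  Genome(sub("\\s.*$", "", names(x)[1L]), as.character(x[[1L]]),
         circular = circular)
}

#' Write a ReadSet as FASTQ (constant placeholder qualities, phred+33)
#' @param readSet a [ReadSet-class].
#' @param path output file.
#' @export
writeReadsFastq <- function(readSet, path) {
  reads <- readSeqs(readSet)
  qual <- Biostrings::BStringSet(strrep("I", Biostrings::width(reads)))
  Biostrings::writeXStringSet(reads, path, format = "fastq", qualities = qual)
  invisible(path)
}

#' Read FASTQ into a ReadSet (no truth table)
#' @param path FASTQ file.
#' @return a [ReadSet-class] with an empty truth table.
#' @export
readReadsFastq <- function(path) {
  reads <- Biostrings::readDNAStringSet(path, format = "fastq")
  names(reads) <- sub("\\s.*$", "", names(reads))
  new("ReadSet", reads = reads,
      truth = data.frame(read_id = character(0), target = character(0),
                         position = integer(0), orientation = character(0),
                         end = character(0), host_len = integer(0),
                         stringsAsFactors = FALSE),
      log = c(dropped_events = 0L))
}

#' Write the truth table of a ReadSet as TSV
#' @param readSet a [ReadSet-class].
#' @param path output file.
#' @export
writeTruthTSV <- function(readSet, path) {
  utils::write.table(readTruth(readSet), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a SiteTable as a BED-like TSV (position, orientation, count)
#' @param table a [SiteTable-class].
#' @param path output file.
#' @export
writeSiteTableTSV <- function(table, path) {
  cc <- siteCounts(table)
  bed <- data.frame(chrom = refName(table), start = cc$position - 1L,
                    end = cc$position, orientation = cc$orientation,
                    count = cc$count)
  utils::write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a SiteTable as a dense bedGraph coverage track
#' @param table a [SiteTable-class].
#' @param path output file.
#' @export
writeSiteTableBedGraph <- function(table, path) {
  cc <- siteCounts(table)
  agg <- tapply(cc$count, cc$position, sum)
  pos <- as.integer(names(agg))
  df <- data.frame(chrom = refName(table), start = pos - 1L, end = pos,
                   value = as.integer(agg))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("track type=bedGraph name=%s", refName(table)), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a flat key = value configuration file
#'
#' Lines of the form `key = value`; blank lines and `#` comments ignored.
#' Values are coerced to numeric/logical where possible.
#'
#' @param path configuration file.
#' @return named list.
#' @export
readKeyValueConfig <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2L) stop("malformed config line: ", ln)
    key <- trimws(kv[1L])
    val <- trimws(paste(kv[-1L], collapse = "="))
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num
      else if (toupper(val) %in% c("TRUE", "FALSE")) as.logical(val)
      else val
  }
  out
}

#' Write a named list as key = value text
#' @param x named list/vector of scalars.
#' @param path output file.
#' @export
writeKeyValue <- function(x, path) {
  vals <- vapply(x, function(v) paste(format(v, scientific = FALSE),
                                      collapse = ","), character(1))
  writeLines(paste(names(x), "=", vals), path)
  invisible(path)
}
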