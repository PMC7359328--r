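#' Reading and writing screen tables and sequence files
#'
#' TSV count tables use one row per guide/cassette id and sample columns
#' named \code{<timepoint>_rep<label>} (e.g. \code{initial_rep1}). FASTQ and
#' FASTA go through Biostrings.
#'
#' @name io
NULL

#' @describeIn io write a [ScreenCounts-class] to TSV.
#' @param sc a [ScreenCounts-class].
#' @param path file path.
#' @export
writeCountTable <- function(sc, path) {
  a <- screenAssay(sc)
  df <- data.frame(id = rownames(a), a, check.names = FALSE)
  colnames(df)[-1] <- paste0(timepoints(sc), "_rep", replicates(sc))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @describeIn io read a TSV count table into a [ScreenCounts-class];
#'   sample labels are parsed from the column names.
#' @export
readCountTable <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  parts <- regmatches(colnames(m),
                      regexec("^(initial|final)_rep(.+)$", colnames(m)))
  if (any(lengths(parts) != 3))
    stop("sample columns must be named <timepoint>_rep<label>")
  screenCounts(m,
               timepoint = vapply(parts, `[`, character(1), 2),
               replicate = vapply(parts, `[`, character(1), 3))
}

#' @describeIn io write a guide or cassette annotation table to TSV.
#' @param annotation a DataFrame/data.frame.
#' @export
writeAnnotation <- function(annotation, path) {
  utils::write.table(as.data.frame(annotation), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @describeIn io read a guide annotation TSV.
#' @export
readAnnotation <- function(path) {
  DataFrame(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' @describeIn io write reads to FASTQ (constant quality; phred is ignored
#'   by the mapping rules).
#' @param reads a named DNAStringSet.
#' @export
writeFastq <- function(reads, path) {
  reads <- Biostrings::DNAStringSet(reads)
  if (is.null(names(reads)))
    names(reads) <- sprintf("read%06d", seq_along(reads))
  q <- Biostrings::BStringSet(vapply(Biostrings::width(reads), function(w)
    paste(rep("I", w), collapse = ""), character(1)))
  Biostrings::writeXStringSet(reads, path, format = "fastq", qualities = q)
  invisible(path)
}

#' @describeIn io read a FASTQ into a DNAStringSet (qualities dropped).
#' @export
readFastq <- function(path) {
  Biostrings::readDNAStringSet(path, format = "fastq")
}

#' @describeIn io write a [CassetteReference-class] to FASTA with headers
#'   \code{id|pos1|pos2|designed}.
#' @param reference a [CassetteReference-class].
#' @export
writeCassetteFasta <- function(reference, path) {
  p <- refPairs(reference)
  seqs <- refSequences(reference)
  names(seqs) <- paste(p$cassette_id, p$pos1, p$pos2,
                       ifelse(p$designed, "designed", "recombinant"),
                       sep = "|")
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' @describeIn io read a cassette reference FASTA written by
#'   [writeCassetteFasta()]. Spacer metadata is not recoverable from FASTA;
#'   the result supports mapping but not [expandRecombinants()].
#' @export
readCassetteFasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  parts <- strsplit(names(seqs), "|", fixed = TRUE)
  if (any(lengths(parts) < 4))
    stop("FASTA headers must be id|pos1|pos2|designed")
  # cassette ids may themselves contain '|'; take fields from the right
  field <- function(p, offset) p[length(p) - offset]
  pairs <- DataFrame(
    cassette_id = vapply(parts, function(p)
      paste(p[seq_len(length(p) - 3L)], collapse = "|"), character(1)),
    pos1 = vapply(parts, field, character(1), 2L),
    pos2 = vapply(parts, field, character(1), 1L),
    designed = vapply(parts, field, character(1), 0L) == "designed")
  names(seqs) <- pairs$cassette_id
  new("CassetteReference", pairs = pairs, sequences = seqs,
      spacers = character(0), dr = "")
}
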