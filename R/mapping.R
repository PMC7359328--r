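#' Read-to-cassette assignment and uncoupling estimation
#'
#' Implements the cassette quantification rules: length filtering,
#' minimum-edit-distance assignment with a unique-best requirement and a
#' mismatch budget covering substitutions, indels and unaligned tails, and
#' the uncoupling frequency (fraction of mapped reads hitting a
#' recombination product).
#'
#' @name cassette-mapping
NULL

#' Enumerate all recombination products of a designed cassette library
#'
#' Adds to the reference every ordered spacer pair absent from the designed
#' set, flagged \code{designed = FALSE}; reads mapping to these entries are
#' uncoupling events. Enumeration is eager; references above 500,000 total
#' entries are refused (trim the guide set instead).
#'
#' @param reference a [CassetteReference-class] of designed cassettes.
#' @return A [CassetteReference-class] with designed + recombinant entries.
#' @export
expandRecombinants <- function(reference) {
  p <- refPairs(reference)
  spacers <- refSpacers(reference)
  g <- names(spacers)
  if (length(g)^2 > 5e5)
    stop("refusing to enumerate ", length(g)^2, " cassette entries")
  grid <- expand.grid(pos2 = g, pos1 = g, stringsAsFactors = FALSE)
  grid <- grid[, c("pos1", "pos2")]
  designedKey <- paste(p$pos1, p$pos2)
  rec <- grid[!(paste(grid$pos1, grid$pos2) %in% designedKey), , drop = FALSE]
  all <- DataFrame(
    cassette_id = c(p$cassette_id, paste(rec$pos1, rec$pos2, sep = "|")),
    pos1 = c(p$pos1, rec$pos1),
    pos2 = c(p$pos2, rec$pos2),
    designed = c(p$designed, rep(FALSE, nrow(rec))))
  cassetteReference(all, spacers, dr = reference@dr)
}

# Edit distances from a set of reads to every reference entry.
.editDistances <- function(reads, refSeqs) {
  utils::adist(reads, refSeqs)
}

.assignReads <- function(reads, reference, policy) {
  refSeqs <- as.character(refSequences(reference))
  if (length(refSeqs) == 0) stop("empty cassette reference")
  ids <- refPairs(reference)$cassette_id
  reads <- toupper(as.character(reads))
  n <- length(reads)
  status <- rep("unmapped", n)
  hit <- rep(NA_character_, n)
  short <- nchar(reads) < policy@minReadLength
  status[short] <- "discarded"
  todo <- which(!short)
  if (length(todo)) {
    # fast path: exact copies of a reference entry
    exact <- match(reads[todo], refSeqs)
    ok <- !is.na(exact)
    hit[todo[ok]] <- ids[exact[ok]]
    status[todo[ok]] <- "mapped"
    rest <- todo[!ok]
    if (length(rest)) {
      d <- .editDistances(reads[rest], refSeqs)
      for (k in seq_along(rest)) {
        row <- d[k, ]
        m <- min(row)
        if (m <= policy@maxMismatch) {
          best <- which(row == m)
          if (length(best) == 1L || !policy@uniqueBest) {
            hit[rest[k]] <- ids[best[1L]]
            status[rest[k]] <- "mapped"
          }
        }
      }
    }
  }
  DataFrame(read = reads, status = status, cassette_id = hit)
}

#' Assign a single read to a cassette reference entry
#'
#' Reads shorter than the policy's minimum length are discarded. Otherwise
#' the entry at minimum edit distance (substitutions, indels and unaligned
#' tails all cost 1; N bases count as mismatches) is returned iff that
#' distance is within the mismatch budget and the minimum is strictly
#' unique; ties or over-budget distances are unmapped.
#'
#' @param read character or DNAString, alphabet {A,C,G,T,N}.
#' @param reference a [CassetteReference-class].
#' @param policy a [MappingPolicy-class].
#' @return The cassette id, or \code{"unmapped"} / \code{"discarded"}.
#' @export
mapRead <- function(read, reference, policy = mappingPolicy()) {
  a <- .assignReads(as.character(read), reference, policy)
  if (a$status[1] == "mapped") a$cassette_id[1] else a$status[1]
}

#' Count reads per cassette reference entry
#'
#' Applies [mapRead()] to every read and tallies per-entry counts;
#' discarded and unmapped reads are tallied separately in the run summary.
#'
#' @param reads character vector or DNAStringSet.
#' @param reference a [CassetteReference-class] (typically after
#'   [expandRecombinants()]).
#' @param policy a [MappingPolicy-class].
#' @return list with \code{counts} (named integer vector over reference
#'   entries) and \code{summary} (n_reads, n_mapped, n_unmapped,
#'   n_discarded).
#' @export
countCassettes <- function(reads, reference, policy = mappingPolicy()) {
  a <- .assignReads(reads, reference, policy)
  ids <- refPairs(reference)$cassette_id
  counts <- table(factor(a$cassette_id, levels = ids))
  counts <- stats::setNames(as.integer(counts), ids)
  list(counts = counts,
       summary = list(n_reads = nrow(a),
                      n_mapped = sum(a$status == "mapped"),
                      n_unmapped = sum(a$status == "unmapped"),
                      n_discarded = sum(a$status == "discarded")))
}

#' Uncoupling frequency from cassette counts
#'
#' The fraction of all reads mapped to a cassette recombination product over
#' total reads mapped to any reference entry.
#'
#' @param counts named integer vector of per-entry counts (as returned by
#'   [countCassettes()]).
#' @param reference the [CassetteReference-class] defining which entries are
#'   recombinant.
#' @return list with \code{fraction} (in [0,1]) and \code{percent}.
#' @export
uncouplingFrequency <- function(counts, reference) {
  p <- refPairs(reference)
  counts <- counts[p$cassette_id]
  total <- sum(counts)
  if (is.na(total) || total == 0)
    stop("no mapped reads: uncoupling frequency is undefined")
  frac <- sum(counts[!p$designed]) / total
  list(fraction = frac, percent = 100 * frac)
}

#' Count single-guide reads by exact spacer match
#'
#' A read increments a guide iff that guide's spacer occurs exactly in the
#' read (no mismatches permitted) and no other guide's spacer does;
#' everything else is tallied as unmatched.
#'
#' @param reads character vector or DNAStringSet.
#' @param spacers named character vector, guide id to spacer; must be
#'   unique.
#' @return list with \code{counts} (named integer per guide) and
#'   \code{n_unmatched}.
#' @export
countSingleGuides <- function(reads, spacers) {
  if (anyDuplicated(spacers))
    stop("duplicate spacers in reference: assignment would be ambiguous")
  reads <- Biostrings::DNAStringSet(reads)
  counts <- stats::setNames(integer(length(spacers)), names(spacers))
  if (length(reads) == 0)
    return(list(counts = counts, n_unmatched = 0L))
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(unname(spacers)))
  hits <- Biostrings::vwhichPDict(pd, reads)
  nHit <- lengths(hits)
  one <- nHit == 1L
  if (any(one)) {
    idx <- unlist(hits[one])
    tab <- table(factor(idx, levels = seq_along(spacers)))
    counts <- stats::setNames(as.integer(tab), names(spacers))
  }
  list(counts = counts, n_unmatched = sum(!one))
}

#' Trim a fixed-length 5' prefix from reads
#'
#' Convenience for simulator reads carrying a known vector prefix; real
#' adapter trimming is assumed done upstream.
#'
#' @param reads character vector or DNAStringSet.
#' @param prefixLength bases to remove from the 5' end.
#' @return DNAStringSet of trimmed reads.
#' @export
trimPrefix <- function(reads, prefixLength) {
  reads <- Biostrings::DNAStringSet(reads)
  Biostrings::subseq(reads, start = prefixLength + 1L)
}
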