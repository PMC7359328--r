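#' AsCas12a crRNA design utilities
#'
#' TTTV-PAM scanning on both strands, 23-nt spacer extraction, target-region
#' classification against domain and exon intervals, perfect-match
#' off-target filtering, per-domain guide selection and dual-library
#' enumeration.
#'
#' @name library-design
NULL

# Forward-strand TTTV sites of one sequence; returns 1-based PAM starts.
.pamStarts <- function(seq) {
  m <- Biostrings::matchPattern("TTTV", seq,
                                fixed = c(pattern = FALSE, subject = TRUE))
  BiocGenerics::start(m)
}

#' Scan a sequence set for TTTV PAM sites with full 23-nt spacers
#'
#' Every occurrence of TTTV (V = A, C or G) on either strand followed by a
#' complete 23-base protospacer is reported. Reverse-strand sites carry the
#' spacer as read on the minus strand, with PAM coordinates on the forward
#' sequence. An N anywhere in the PAM or spacer disqualifies the site. The
#' reported cut position is the midpoint proxy of the Cas12a staggered cut,
#' between protospacer positions 18 and 23 (PAM-distal).
#'
#' @param seqs a named DNAStringSet (or named character vector).
#' @return DataFrame with \code{seqnames}, \code{strand},
#'   \code{pam_start} (0-based, forward coordinates of the PAM's leftmost
#'   base), \code{pam}, \code{spacer}, \code{cut} (0-based forward
#'   coordinate of the cut-site proxy).
#' @export
scanPamSites <- function(seqs) {
  seqs <- Biostrings::DNAStringSet(seqs)
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  out <- lapply(seq_along(seqs), function(i) {
    s <- seqs[[i]]
    len <- length(s)
    nm <- names(seqs)[i]
    rows <- list()
    for (str in c("+", "-")) {
      subj <- if (str == "+") s else Biostrings::reverseComplement(s)
      starts <- .pamStarts(subj)
      starts <- starts[starts + 26 <= len]
      if (length(starts) == 0) next
      pam <- as.character(Biostrings::extractAt(
        subj, IRanges::IRanges(starts, width = 4)))
      spacer <- as.character(Biostrings::extractAt(
        subj, IRanges::IRanges(starts + 4, width = 23)))
      keep <- grepl("^[ACGT]+$", spacer) & grepl("^[ACGT]+$", pam)
      starts <- starts[keep]
      if (length(starts) == 0) next
      # cut proxy: midpoint of protospacer positions 18..23, on-strand
      # 0-based offset 24 from the PAM start
      cutOn <- (starts - 1L) + 24L
      if (str == "+") {
        pamFwd <- starts - 1L
        cutFwd <- cutOn
      } else {
        pamFwd <- len - (starts - 1L) - 4L
        cutFwd <- len - 1L - cutOn
      }
      rows[[str]] <- DataFrame(seqnames = nm, strand = str,
                               pam_start = pamFwd, pam = pam[keep],
                               spacer = spacer[keep], cut = cutFwd)
    }
    if (length(rows)) do.call(rbind, rows) else NULL
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0)
    return(DataFrame(seqnames = character(), strand = character(),
                     pam_start = integer(), pam = character(),
                     spacer = character(), cut = integer()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Classify PAM sites by targeted region
#'
#' The cut-site proxy decides the class: inside a domain interval ->
#' \code{domain} (precedence), else inside an exon -> \code{nondomain},
#' else \code{noncoding}. Intervals are 0-based half-open on the forward
#' strand (BED dialect), supplied as GRanges or data.frames with
#' \code{seqnames}/\code{chrom}, \code{start}, \code{end} and optionally
#' \code{name}.
#'
#' @param sites DataFrame from [scanPamSites()].
#' @param domains,exons interval sets.
#' @return The sites with \code{class} and \code{domain_name} columns added.
#' @export
classifyTargets <- function(sites, domains, exons) {
  asGR <- function(x) {
    if (methods::is(x, "GRanges")) return(x)
    x <- as.data.frame(x)
    chrom <- if ("seqnames" %in% names(x)) x$seqnames else x$chrom
    gr <- GenomicRanges::GRanges(chrom,
                                 IRanges::IRanges(x$start + 1L, x$end))
    if ("name" %in% names(x)) gr$name <- x$name
    gr
  }
  domGR <- asGR(domains)
  exGR <- asGR(exons)
  cutGR <- GenomicRanges::GRanges(sites$seqnames,
                                  IRanges::IRanges(sites$cut + 1L, width = 1))
  inDom <- GenomicRanges::findOverlaps(cutGR, domGR, select = "first")
  inEx <- !is.na(GenomicRanges::findOverlaps(cutGR, exGR, select = "first"))
  cls <- ifelse(!is.na(inDom), "domain",
                ifelse(inEx, "nondomain", "noncoding"))
  domName <- rep(NA_character_, length(cls))
  hasName <- !is.null(domGR$name)
  hit <- !is.na(inDom)
  domName[hit] <- if (hasName) domGR$name[inDom[hit]] else
    as.character(inDom[hit])
  sites$class <- cls
  sites$domain_name <- domName
  sites
}

#' Remove spacers with perfect-match off-target sites
#'
#' A site is removed iff its 23-mer spacer, or the spacer's reverse
#' complement, occurs in the background sequences anywhere other than its
#' own target locus (one occurrence is allowed when the site's own sequence
#' is part of the background).
#'
#' @param sites DataFrame from [scanPamSites()].
#' @param background named DNAStringSet of background (genome) sequences.
#' @return The retained sites.
#' @export
offtargetFilter <- function(sites, background) {
  background <- Biostrings::DNAStringSet(background)
  if (is.null(names(background)))
    names(background) <- paste0("seq", seq_along(background))
  keep <- vapply(seq_len(nrow(sites)), function(k) {
    sp <- Biostrings::DNAString(sites$spacer[k])
    hits <- sum(Biostrings::vcountPattern(sp, background)) +
      sum(Biostrings::vcountPattern(Biostrings::reverseComplement(sp),
                                    background))
    allowed <- if (sites$seqnames[k] %in% names(background)) 1L else 0L
    hits <= allowed
  }, logical(1))
  sites[keep, ]
}

#' Select up to k guides per domain, deterministically
#'
#' Domain-class sites are grouped by domain and the leftmost \code{k} cut
#' positions are taken; domains with fewer than \code{minK} candidates are
#' selected anyway but reported as under-covered.
#'
#' @param sites classified (and off-target filtered) DataFrame from
#'   [classifyTargets()].
#' @param k guides per domain (default 5).
#' @param minK coverage floor (default 3).
#' @return list with \code{selected} (sites) and \code{underCovered}
#'   (domain names with fewer than minK candidates).
#' @export
pickGuidesPerDomain <- function(sites, k = 5, minK = 3) {
  dom <- sites[sites$class == "domain" & !is.na(sites$domain_name), ]
  groups <- split(seq_len(nrow(dom)), dom$domain_name)
  sel <- lapply(groups, function(idx) {
    idx[order(dom$cut[idx])][seq_len(min(k, length(idx)))]
  })
  under <- names(groups)[lengths(groups) < minK]
  list(selected = dom[sort(unlist(sel, use.names = FALSE)), ],
       underCovered = under)
}

#' Enumerate a full pairwise dual-crRNA library
#'
#' All ordered pairs over the union of experimental and control guides
#' (self-pairs included), each with its assembled DR-spacer-DR-spacer
#' cassette sequence; n guides yield exactly n^2 cassettes in a
#' deterministic order.
#'
#' @param guides data.frame/DataFrame of experimental guides with
#'   \code{guide_id} and \code{spacer}.
#' @param controls same layout for control guides; ids must not overlap.
#' @param dr direct-repeat sequence (default the AsCas12a DR).
#' @return DataFrame with \code{cassette_id}, \code{pos1}, \code{pos2},
#'   \code{pos1_spacer}, \code{pos2_spacer}, \code{sequence}.
#' @export
enumerateDualLibrary <- function(guides, controls = NULL,
                                 dr = AS_CAS12A_DR) {
  all <- if (is.null(controls)) DataFrame(guides) else
    rbind(DataFrame(guides)[, c("guide_id", "spacer")],
          DataFrame(controls)[, c("guide_id", "spacer")])
  if (anyDuplicated(all$guide_id))
    stop("guide ids must be disjoint across sets")
  if (anyDuplicated(all$spacer))
    stop("duplicate spacer across guide ids")
  ids <- all$guide_id
  sp <- stats::setNames(all$spacer, ids)
  grid <- expand.grid(pos2 = ids, pos1 = ids, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)[, c("pos1", "pos2")]
  DataFrame(cassette_id = paste(grid$pos1, grid$pos2, sep = "|"),
            pos1 = grid$pos1, pos2 = grid$pos2,
            pos1_spacer = unname(sp[grid$pos1]),
            pos2_spacer = unname(sp[grid$pos2]),
            sequence = paste0(dr, sp[grid$pos1], dr, sp[grid$pos2]))
}

#' Load a dual-library guide design table
#'
#' Reads a TSV with columns \code{guide_id}, \code{spacer}, \code{gene},
#'   \code{domain}, \code{category}. The packaged synthetic design
#'   (\code{dual_library_design_synthetic.tsv}) mirrors the composition of
#'   a 21-domain epigenetic-regulator dual library: 69 experimental crRNAs
#'   plus 22 negative controls, 91 guides in total.
#'
#' @param path TSV path; default the packaged synthetic design.
#' @return DataFrame of guide annotation.
#' @export
readLibraryDesign <- function(path = system.file(
    "extdata", "dual_library_design_synthetic.tsv", package = "duoscreen")) {
  DataFrame(utils::read.delim(path, stringsAsFactors = FALSE))
}
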