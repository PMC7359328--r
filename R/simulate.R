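#' Synthetic pooled-screen generator
#'
#' Simulates single- and dual-crRNA dropout screens with known ground truth:
#' log-normal initial library skew, per-guide fitness effects with gene-level
#' structure, a configurable position-1 effect bias in dual cassettes,
#' planted synthetic-sick gene pairs, multinomial sequencing at fixed depth,
#' and cassette recombination for read-level simulation.
#'
#' @name simulate
NULL

# Run expr under a fixed seed without disturbing the caller's RNG stream.
.withFixedSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = .GlobalEnv)
  on.exit({
    if (had) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(seed)
  force(expr)
}

.randomSpacers <- function(n, width = 23L) {
  sp <- character(0)
  while (length(sp) < n) {
    need <- n - length(sp)
    new <- vapply(seq_len(need + 8L), function(i)
      paste(sample(c("A", "C", "G", "T"), width, replace = TRUE),
            collapse = ""), character(1))
    sp <- unique(c(sp, new))
  }
  sp[seq_len(n)]
}

#' Guide annotation implied by a simulator configuration
#'
#' Deterministic given the library composition: the same genes, guide ids and
#' spacers are produced for every seed, so only counts change across seeds.
#'
#' @param config a [SimConfig-class].
#' @return DataFrame with columns \code{guide_id}, \code{spacer}, \code{gene},
#'   \code{domain}, \code{category}.
#' @export
guideAnnotation <- function(config) {
  genes <- sprintf("gene%02d", seq_len(config@nGenes))
  expIds <- as.vector(t(outer(genes, seq_len(config@guidesPerGene),
                              function(g, k) sprintf("%s_g%d", g, k))))
  negIds <- sprintf("neg%02d", seq_len(config@nNegControls))
  ids <- c(expIds, negIds)
  spacers <- .withFixedSeed(8235711L, .randomSpacers(length(ids)))
  DataFrame(
    guide_id = ids,
    spacer = spacers,
    gene = c(rep(genes, each = config@guidesPerGene),
             rep("neg_ctrl", config@nNegControls)),
    domain = c(rep(paste0(genes, "_D1"), each = config@guidesPerGene),
               rep(NA_character_, config@nNegControls)),
    category = c(rep("domain", length(expIds)),
                 rep("negative_control", config@nNegControls)))
}

# Per-guide true log2 effects: gene effect + guide noise; negatives exactly 0.
# Draws from the current RNG stream.
.drawGuideEffects <- function(config, ann) {
  eff <- numeric(nrow(ann))
  names(eff) <- ann$guide_id
  isExp <- ann$category != "negative_control"
  geneEff <- config@geneEffects[match(ann$gene[isExp],
                                      sprintf("gene%02d",
                                              seq_len(config@nGenes)))]
  eff[isExp] <- geneEff + stats::rnorm(sum(isExp), 0, config@guideSd)
  eff
}

# Multinomial initial/final sampling shared by both screen simulators.
.sampleScreen <- function(config, ids, trueLfc) {
  n <- length(ids)
  p0 <- exp(stats::rnorm(n, 0, config@abundanceLogSd))
  p0 <- p0 / sum(p0)
  if (config@depth * stats::median(p0) < 1)
    stop("depth too small to represent the library: expected count of the ",
         "median element is below 1 read")
  pf <- p0 * 2^trueLfc
  pf <- pf / sum(pf)
  R <- config@replicates
  counts <- matrix(0L, nrow = n, ncol = 2L * R,
                   dimnames = list(ids, c(sprintf("initial_rep%d", seq_len(R)),
                                          sprintf("final_rep%d", seq_len(R)))))
  for (r in seq_len(R)) {
    counts[, r] <- stats::rmultinom(1, config@depth, p0)[, 1]
    counts[, R + r] <- stats::rmultinom(1, config@depth, pf)[, 1]
  }
  screenCounts(counts,
               timepoint = rep(c("initial", "final"), each = R),
               replicate = as.character(rep(seq_len(R), 2)))
}

#' Simulate a single-crRNA dropout screen
#'
#' Initial counts are drawn multinomially from log-normal abundance
#' proportions at the configured depth; each guide's true LFC is its gene
#' effect plus Normal(0, guideSd) noise (negative controls are exactly 0);
#' final expected proportions are initial proportions times 2^LFC,
#' renormalized and sampled multinomially, independently per replicate.
#'
#' @param config a [SimConfig-class].
#' @return list with \code{annotation} (guide table), \code{counts}
#'   ([ScreenCounts-class]) and \code{truth} (per-guide true LFC).
#' @examples
#' sim <- simulateSingleScreen(simConfig(seed = 1, depth = 1e4))
#' colSums(screenAssay(sim$counts))
#' @export
simulateSingleScreen <- function(config) {
  validObject(config)
  set.seed(config@seed)
  ann <- guideAnnotation(config)
  eff <- .drawGuideEffects(config, ann)
  sc <- .sampleScreen(config, ann$guide_id, eff)
  SummarizedExperiment::rowData(sc) <- ann
  list(annotation = ann,
       counts = sc,
       truth = DataFrame(guide_id = ann$guide_id, gene = ann$gene,
                         true_lfc = unname(eff)))
}

#' Simulate a dual-crRNA double-knockout screen
#'
#' The library is every ordered pair of guides (experimental and negative
#' controls, self-pairs included). A cassette's true LFC is
#' \code{positionBias * effect(pos1) + effect(pos2)}, plus the planted
#' \code{delta} when the two guides target a planted gene pair. Counts are
#' generated as in [simulateSingleScreen()].
#'
#' @param config a [SimConfig-class].
#' @return list with \code{annotation} (guide table), \code{cassettes}
#'   (cassette_id/pos1/pos2 table), \code{counts} ([ScreenCounts-class] with
#'   the cassette table as rowData) and \code{truth} (per-cassette true LFC).
#' @export
simulateDualScreen <- function(config) {
  validObject(config)
  set.seed(config@seed)
  ann <- guideAnnotation(config)
  pl <- config@plantedInteractions
  if (nrow(pl)) {
    known <- unique(ann$gene)
    bad <- setdiff(c(pl$geneA, pl$geneB), known)
    if (length(bad))
      stop("planted interaction names unknown gene(s): ",
           paste(bad, collapse = ", "))
  }
  eff <- .drawGuideEffects(config, ann)
  ids <- ann$guide_id
  grid <- expand.grid(pos2 = ids, pos1 = ids, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)[, c("pos1", "pos2")]
  cassettes <- DataFrame(
    cassette_id = paste(grid$pos1, grid$pos2, sep = "|"),
    pos1 = grid$pos1, pos2 = grid$pos2)
  geneOf <- stats::setNames(ann$gene, ann$guide_id)
  trueLfc <- config@positionBias * eff[cassettes$pos1] + eff[cassettes$pos2]
  if (nrow(pl)) {
    pairKey <- function(a, b) paste(pmin(a, b), pmax(a, b))
    planted <- stats::setNames(pl$delta, pairKey(pl$geneA, pl$geneB))
    key <- pairKey(geneOf[cassettes$pos1], geneOf[cassettes$pos2])
    hitIdx <- match(key, names(planted))
    extra <- ifelse(is.na(hitIdx), 0, pl$delta[hitIdx])
    # a planted interaction needs both genes actually knocked out
    extra[geneOf[cassettes$pos1] == geneOf[cassettes$pos2]] <- 0
    trueLfc <- trueLfc + extra
  }
  trueLfc <- unname(trueLfc)
  sc <- .sampleScreen(config, cassettes$cassette_id, trueLfc)
  SummarizedExperiment::rowData(sc) <- cassettes
  list(annotation = ann, cassettes = cassettes, counts = sc,
       truth = DataFrame(cassette_id = cassettes$cassette_id,
                         pos1 = cassettes$pos1, pos2 = cassettes$pos2,
                         true_lfc = trueLfc))
}

#' Simulate cassette sequencing reads with uncoupling
#'
#' Each read copies a designed cassette (log-normal abundance weights). With
#' probability \code{recombinationRate} the position-2 spacer is replaced by
#' a random other library spacer, modelling lentiviral/PCR recombination; a
#' read is labelled recombinant when the resulting guide pair is absent from
#' the designed set (a random re-pairing can collide with a designed
#' cassette). Substitution errors are applied at \code{errorRate} per base.
#'
#' @param config a [SimConfig-class]; \code{depth} is the number of reads.
#' @param reference a [CassetteReference-class]; only its designed entries
#'   are templates.
#' @return list with \code{reads} (named DNAStringSet) and \code{truth}
#'   (read_id, template cassette, realized pos1/pos2, recombinant flag).
#' @export
simulateCassetteReads <- function(config, reference) {
  validObject(config)
  validObject(reference)
  set.seed(config@seed)
  p <- refPairs(reference)
  des <- p[p$designed, , drop = FALSE]
  if (nrow(des) == 0) stop("reference has no designed entries")
  spacers <- refSpacers(reference)
  dr <- reference@dr
  if (any(nchar(dr) * 2 + nchar(spacers[des$pos1]) +
          nchar(spacers[des$pos2]) < 60))
    stop("reference cassette sequences must be at least 60 bases")
  nReads <- config@depth
  w <- exp(stats::rnorm(nrow(des), 0, config@abundanceLogSd))
  tmpl <- sample.int(nrow(des), nReads, replace = TRUE, prob = w)
  pos1 <- des$pos1[tmpl]
  pos2 <- des$pos2[tmpl]
  recombDraw <- stats::runif(nReads) < config@recombinationRate
  if (any(recombDraw)) {
    gids <- names(spacers)
    cur <- match(pos2[recombDraw], gids)
    # uniform over the other library spacers
    pick <- sample.int(length(gids) - 1L, sum(recombDraw), replace = TRUE)
    pick <- pick + (pick >= cur)
    pos2[recombDraw] <- gids[pick]
  }
  designedKey <- paste(des$pos1, des$pos2)
  recombinant <- !(paste(pos1, pos2) %in% designedKey)
  seqs <- paste0(dr, spacers[pos1], dr, spacers[pos2])
  if (config@errorRate > 0) {
    m <- matrix(unlist(strsplit(seqs, "", fixed = TRUE)),
                nrow = nReads, byrow = TRUE)
    hit <- which(stats::runif(length(m)) < config@errorRate)
    if (length(hit)) {
      bases <- c("A", "C", "G", "T")
      ci <- match(m[hit], bases)
      off <- sample.int(3L, length(hit), replace = TRUE)
      m[hit] <- bases[((ci - 1L + off) %% 4L) + 1L]
    }
    seqs <- apply(m, 1, paste, collapse = "")
  }
  reads <- Biostrings::DNAStringSet(seqs)
  names(reads) <- sprintf("read%06d", seq_len(nReads))
  list(reads = reads,
       truth = DataFrame(read_id = names(reads),
                         template = des$cassette_id[tmpl],
                         pos1 = pos1, pos2 = pos2,
                         recombinant = recombinant))
}
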