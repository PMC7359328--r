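#' @import methods
#' @importFrom S4Vectors DataFrame SimpleList
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' Configuration for the synthetic-screen generator
#'
#' Holds every parameter of the pooled-screen simulator: library composition,
#' per-gene fitness effects, guide-level noise, cassette position bias,
#' planted synthetic-sick interactions, sequencing depth and library skew,
#' cassette recombination (uncoupling) rate and per-base error rate.
#'
#' @slot nGenes number of experimental genes (one targeted domain per gene).
#' @slot guidesPerGene crRNAs designed per gene.
#' @slot nNegControls number of negative-control crRNAs.
#' @slot geneEffects numeric vector (length \code{nGenes}) of mean log2
#'   fitness effects per screen interval; negative = dropout.
#' @slot guideSd within-gene spread of guide effects (log2 units).
#' @slot positionBias multiplier applied to a guide's effect when it occupies
#'   cassette position 1 (dimensionless, >= 0; 1 = no bias).
#' @slot plantedInteractions data.frame with columns \code{geneA},
#'   \code{geneB}, \code{delta}: extra log2 effect of the double knockout.
#' @slot depth reads per sample (multinomial total).
#' @slot replicates number of biological replicates.
#' @slot abundanceLogSd natural-log sd of the initial library abundance skew.
#' @slot recombinationRate fraction of cassette reads whose position-2 spacer
#'   is re-paired at random (uncoupling).
#' @slot errorRate per-base substitution rate in simulated reads.
#' @slot seed integer RNG seed; fixing it fixes every output byte.
#' @export
setClass("SimConfig",
  representation(
    nGenes = "integer",
    guidesPerGene = "integer",
    nNegControls = "integer",
    geneEffects = "numeric",
    guideSd = "numeric",
    positionBias = "numeric",
    plantedInteractions = "data.frame",
    depth = "integer",
    replicates = "integer",
    abundanceLogSd = "numeric",
    recombinationRate = "numeric",
    errorRate = "numeric",
    seed = "integer"
  )
)

setValidity("SimConfig", function(object) {
  msg <- character()
  if (object@nGenes < 1L) msg <- c(msg, "nGenes must be >= 1")
  if (object@guidesPerGene < 1L) msg <- c(msg, "guidesPerGene must be >= 1")
  if (object@nNegControls < 1L) msg <- c(msg, "nNegControls must be >= 1")
  if (object@depth < 1L) msg <- c(msg, "depth must be >= 1")
  if (object@replicates < 1L) msg <- c(msg, "replicates must be >= 1")
  if (length(object@geneEffects) != object@nGenes)
    msg <- c(msg, "geneEffects must have length nGenes")
  if (object@guideSd < 0) msg <- c(msg, "guideSd must be >= 0")
  if (object@positionBias < 0) msg <- c(msg, "positionBias must be >= 0")
  if (object@recombinationRate < 0 || object@recombinationRate > 1)
    msg <- c(msg, "recombinationRate must be in [0, 1]")
  if (object@errorRate < 0 || object@errorRate >= 0.25)
    msg <- c(msg, "errorRate must be in [0, 0.25)")
  if (object@abundanceLogSd < 0) msg <- c(msg, "abundanceLogSd must be >= 0")
  pi <- object@plantedInteractions
  if (nrow(pi) > 0 &&
      !all(c("geneA", "geneB", "delta") %in% colnames(pi)))
    msg <- c(msg, "plantedInteractions needs columns geneA, geneB, delta")
  if (length(msg)) msg else TRUE
})

#' Construct a simulator configuration
#'
#' Defaults describe the dual-screen study design the package is calibrated
#' against: 15 experimental genes with 3 crRNAs each, 22 negative controls,
#' two replicates sequenced to one million reads, moderate library skew and
#' guide-level noise, no position bias and no planted interactions.
#'
#' @param nGenes,guidesPerGene,nNegControls library composition.
#' @param geneEffects per-gene mean log2 effects (default all 0, a null screen).
#' @param guideSd within-gene guide effect sd (log2 units).
#' @param positionBias effect multiplier in cassette position 1.
#' @param plantedInteractions data.frame(geneA, geneB, delta) of synthetic-sick
#'   pairs to plant (delta in log2 units, negative = sicker than expected).
#' @param depth reads per sample.
#' @param replicates number of replicates.
#' @param abundanceLogSd log-scale sd of initial abundance skew.
#' @param recombinationRate cassette uncoupling rate for read simulation.
#' @param errorRate per-base substitution rate for read simulation.
#' @param seed integer seed (mandatory).
#' @return A validated [SimConfig-class] object.
#' @examples
#' cfg <- simConfig(seed = 1, nGenes = 2, geneEffects = c(-4, 0))
#' @export
simConfig <- function(seed,
                      nGenes = 15, guidesPerGene = 3, nNegControls = 22,
                      geneEffects = rep(0, nGenes), guideSd = 0.5,
                      positionBias = 1,
                      plantedInteractions = data.frame(
                        geneA = character(), geneB = character(),
                        delta = numeric()),
                      depth = 1e6, replicates = 2,
                      abundanceLogSd = 0.5,
                      recombinationRate = 0.0033, errorRate = 0.001) {
  if (missing(seed)) stop("seed is mandatory")
  new("SimConfig",
      nGenes = as.integer(nGenes),
      guidesPerGene = as.integer(guidesPerGene),
      nNegControls = as.integer(nNegControls),
      geneEffects = as.numeric(geneEffects),
      guideSd = as.numeric(guideSd),
      positionBias = as.numeric(positionBias),
      plantedInteractions = as.data.frame(plantedInteractions),
      depth = as.integer(depth),
      replicates = as.integer(replicates),
      abundanceLogSd = as.numeric(abundanceLogSd),
      recombinationRate = as.numeric(recombinationRate),
      errorRate = as.numeric(errorRate),
      seed = as.integer(seed))
}

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@nGenes, "genes x", object@guidesPerGene,
      "guides +", object@nNegControls, "negative controls\n")
  cat("  depth", object@depth, "| replicates", object@replicates,
      "| seed", object@seed, "\n")
  cat("  guideSd", object@guideSd, "| positionBias", object@positionBias,
      "| planted pairs", nrow(object@plantedInteractions), "\n")
})

#' Screen count container
#'
#' A \linkS4class{SummarizedExperiment} holding a guide-or-cassette by sample
#' count matrix. \code{colData} carries a \code{timepoint} factor
#' (\code{initial}/\code{final}) and a \code{replicate} label; \code{rowData}
#' carries guide or cassette annotation (for dual screens, \code{pos1} and
#' \code{pos2} guide ids).
#'
#' @export
setClass("ScreenCounts", contains = "SummarizedExperiment")

setValidity("ScreenCounts", function(object) {
  msg <- character()
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("timepoint", "replicate") %in% colnames(cd)))
    msg <- c(msg, "colData must have 'timepoint' and 'replicate'")
  else if (!all(cd$timepoint %in% c("initial", "final")))
    msg <- c(msg, "timepoint must be 'initial' or 'final'")
  a <- SummarizedExperiment::assay(object, "counts")
  if (any(a < 0)) msg <- c(msg, "counts must be non-negative")
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "row ids must be unique")
  if (length(msg)) msg else TRUE
})

#' Build a ScreenCounts object
#'
#' @param counts numeric matrix, rows = guides or cassettes (rownames
#'   required), columns = samples.
#' @param timepoint character vector per column, \code{"initial"} or
#'   \code{"final"}.
#' @param replicate replicate label per column.
#' @param rowData optional per-row annotation (DataFrame or data.frame).
#' @return A [ScreenCounts-class] object.
#' @export
screenCounts <- function(counts, timepoint, replicate, rowData = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) stop("counts must have rownames")
  cd <- DataFrame(timepoint = as.character(timepoint),
                  replicate = as.character(replicate))
  if (is.null(colnames(counts)))
    colnames(counts) <- paste(cd$timepoint, cd$replicate, sep = "_rep")
  rownames(cd) <- colnames(counts)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = S4Vectors::SimpleList(counts = counts), colData = cd)
  if (!is.null(rowData))
    SummarizedExperiment::rowData(se) <- DataFrame(rowData)
  new("ScreenCounts", se)
}

#' Gaussian fit summary
#'
#' Mean, standard deviation (n-1 denominator) and sample size of a set of
#' LFC values; the building block of the position-sensitive interaction null.
#'
#' @slot mean fitted mean (log2 units).
#' @slot sd fitted sd (log2 units, >= 0).
#' @slot n number of values fitted.
#' @export
setClass("GaussianFit",
  representation(mean = "numeric", sd = "numeric", n = "integer"))

setValidity("GaussianFit", function(object) {
  msg <- character()
  if (!is.finite(object@mean)) msg <- c(msg, "mean must be finite")
  if (!is.finite(object@sd) || object@sd < 0)
    msg <- c(msg, "sd must be finite and >= 0")
  if (object@n < 1L) msg <- c(msg, "n must be >= 1")
  if (length(msg)) msg else TRUE
})

#' @param mean,sd,n see slots.
#' @rdname GaussianFit-class
#' @export
gaussianFit <- function(mean, sd, n) {
  new("GaussianFit", mean = as.numeric(mean), sd = as.numeric(sd),
      n = as.integer(n))
}

setMethod("show", "GaussianFit", function(object) {
  cat(sprintf("GaussianFit: N(%.4g, sd %.4g), n = %d\n",
              object@mean, object@sd, object@n))
})

#' Read-to-cassette mapping policy
#'
#' The mapping rules: reads shorter than \code{minReadLength} are discarded
#' (empty-vector products); a read is assigned to the reference entry of
#' minimum edit distance only if that distance is at most \code{maxMismatch}
#' (substitutions, indels and unaligned tails all count) and, when
#' \code{uniqueBest} is set, the minimum is strictly unique.
#'
#' @slot minReadLength minimum read length in bases (default 60).
#' @slot maxMismatch maximum edit distance (default 2).
#' @slot uniqueBest require a strictly unique best hit (default TRUE).
#' @export
setClass("MappingPolicy",
  representation(minReadLength = "integer", maxMismatch = "integer",
                 uniqueBest = "logical"))

setValidity("MappingPolicy", function(object) {
  msg <- character()
  if (object@minReadLength <= 0L) msg <- c(msg, "minReadLength must be > 0")
  if (object@maxMismatch < 0L) msg <- c(msg, "maxMismatch must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @param minReadLength,maxMismatch,uniqueBest see slots.
#' @rdname MappingPolicy-class
#' @export
mappingPolicy <- function(minReadLength = 60, maxMismatch = 2,
                          uniqueBest = TRUE) {
  new("MappingPolicy", minReadLength = as.integer(minReadLength),
      maxMismatch = as.integer(maxMismatch), uniqueBest = uniqueBest)
}

#' Dual-crRNA cassette reference
#'
#' The set of cassette sequences reads are assigned to: the designed library
#' plus (after [expandRecombinants()]) every possible recombination product.
#' Each entry records its position-1 and position-2 guide ids and whether it
#' is a designed cassette or a recombinant.
#'
#' @slot pairs DataFrame with columns \code{cassette_id}, \code{pos1},
#'   \code{pos2}, \code{designed} (logical).
#' @slot sequences \code{DNAStringSet} of full cassette sequences, parallel
#'   to \code{pairs}.
#' @slot spacers named character vector, guide id to 23-nt spacer.
#' @slot dr the direct-repeat sequence used to assemble cassettes.
#' @export
setClass("CassetteReference",
  representation(pairs = "DataFrame", sequences = "DNAStringSet",
                 spacers = "character", dr = "character"))

setValidity("CassetteReference", function(object) {
  msg <- character()
  p <- object@pairs
  if (!all(c("cassette_id", "pos1", "pos2", "designed") %in% colnames(p)))
    msg <- c(msg, "pairs needs cassette_id, pos1, pos2, designed")
  if (anyDuplicated(p$cassette_id)) msg <- c(msg, "cassette ids must be unique")
  if (length(object@sequences) != nrow(p))
    msg <- c(msg, "sequences must parallel pairs")
  if (length(object@sequences) &&
      !all(grepl("^[ACGT]+$", as.character(object@sequences))))
    msg <- c(msg, "sequences must be over {A,C,G,T}")
  key <- paste(p$pos1, p$pos2)
  if (any(key[!p$designed] %in% key[p$designed]))
    msg <- c(msg, "a recombinant entry duplicates a designed (pos1, pos2) pair")
  if (length(msg)) msg else TRUE
})

#' Build a cassette reference from a design table
#'
#' Cassette sequences are assembled as DR-spacer1-DR-spacer2 from the guide
#' spacer lookup unless explicit sequences are supplied.
#'
#' @param pairs data.frame/DataFrame with \code{cassette_id}, \code{pos1},
#'   \code{pos2} and optionally \code{designed} (default all TRUE).
#' @param spacers named character vector mapping guide ids to spacers.
#' @param dr direct-repeat sequence (default: the AsCas12a direct repeat).
#' @param sequences optional explicit cassette sequences (character or
#'   DNAStringSet), overriding assembly.
#' @return A [CassetteReference-class] object.
#' @export
cassetteReference <- function(pairs, spacers, dr = AS_CAS12A_DR,
                              sequences = NULL) {
  pairs <- DataFrame(pairs)
  if (is.null(pairs$designed)) pairs$designed <- rep(TRUE, nrow(pairs))
  if (is.null(pairs$cassette_id))
    pairs$cassette_id <- paste(pairs$pos1, pairs$pos2, sep = "|")
  if (is.null(sequences)) {
    miss <- setdiff(unique(c(pairs$pos1, pairs$pos2)), names(spacers))
    if (length(miss))
      stop("no spacer for guide(s): ", paste(miss, collapse = ", "))
    sequences <- if (nrow(pairs) == 0) character(0) else
      paste0(dr, spacers[pairs$pos1], dr, spacers[pairs$pos2])
  }
  seqs <- Biostrings::DNAStringSet(sequences)
  names(seqs) <- pairs$cassette_id
  new("CassetteReference", pairs = pairs, sequences = seqs,
      spacers = spacers, dr = dr)
}

setMethod("show", "CassetteReference", function(object) {
  p <- object@pairs
  cat("CassetteReference:", nrow(p), "entries (",
      sum(p$designed), "designed,", sum(!p$designed), "recombinant ),",
      length(object@spacers), "guides\n")
})

#' The AsCas12a direct-repeat sequence used to assemble crRNA cassettes
#' @export
AS_CAS12A_DR <- "AATTTCTACTCTTGTAGAT"
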