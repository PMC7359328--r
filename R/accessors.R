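#' Accessors for duoscreen classes
#'
#' @param object a duoscreen S4 object.
#' @name accessors
NULL

#' @describeIn accessors the raw or normalized count matrix of a
#'   [ScreenCounts-class].
#' @export
screenAssay <- function(object) {
  SummarizedExperiment::assay(object, "counts")
}

#' @describeIn accessors timepoint label per sample column.
#' @export
timepoints <- function(object) {
  SummarizedExperiment::colData(object)$timepoint
}

#' @describeIn accessors replicate label per sample column.
#' @export
replicates <- function(object) {
  SummarizedExperiment::colData(object)$replicate
}

#' @describeIn accessors fitted mean of a [GaussianFit-class].
#' @export
fitMean <- function(object) object@mean

#' @describeIn accessors fitted sd of a [GaussianFit-class].
#' @export
fitSd <- function(object) object@sd

#' @describeIn accessors number of values behind a [GaussianFit-class].
#' @export
fitN <- function(object) object@n

#' @describeIn accessors entry table of a [CassetteReference-class].
#' @export
refPairs <- function(object) object@pairs

#' @describeIn accessors cassette sequences of a [CassetteReference-class].
#' @export
refSequences <- function(object) object@sequences

#' @describeIn accessors guide-id to spacer lookup of a
#'   [CassetteReference-class].
#' @export
refSpacers <- function(object) object@spacers
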