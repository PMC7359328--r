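# Small shared fixtures, all built in code.

# A minimal cassette-level LFC table from explicit (pos1, pos2, lfc) triples.
makeLfc <- function(pos1, pos2, lfc) {
  S4Vectors::DataFrame(cassette_id = paste(pos1, pos2, sep = "|"),
                       pos1 = pos1, pos2 = pos2, lfc = lfc)
}

# Annotation for nExp experimental guides (one gene each unless genes given)
# and nNeg negative controls.
makeAnnotation <- function(nExp, nNeg, genes = NULL) {
  expIds <- sprintf("e%d", seq_len(nExp))
  negIds <- sprintf("n%d", seq_len(nNeg))
  if (is.null(genes)) genes <- sprintf("G%d", seq_len(nExp))
  S4Vectors::DataFrame(
    guide_id = c(expIds, negIds),
    spacer = NA_character_,
    gene = c(genes, rep("neg_ctrl", nNeg)),
    domain = c(paste0(genes, "_D"), rep(NA_character_, nNeg)),
    category = c(rep("domain", nExp), rep("negative_control", nNeg)))
}

# A tiny designed cassette reference over n guides with random spacers.
makeReference <- function(nGuides = 6, nDesigned = nGuides, seed = 99) {
  set.seed(seed)
  spacers <- character(0)
  while (length(spacers) < nGuides)
    spacers <- unique(c(spacers, randomSeq(23)))
  spacers <- stats::setNames(spacers[seq_len(nGuides)],
                             sprintf("g%d", seq_len(nGuides)))
  ids <- names(spacers)
  grid <- expand.grid(pos2 = ids, pos1 = ids,
                      stringsAsFactors = FALSE)[, c("pos1", "pos2")]
  des <- grid[seq_len(nDesigned), ]
  cassetteReference(S4Vectors::DataFrame(pos1 = des$pos1, pos2 = des$pos2),
                    spacers)
}

# Dual-screen study design used by the calibration/power checks: 15 genes x
# 3 guides (105 gene pairs), 22 negative controls, two replicates at one
# million reads.
studyConfig <- function(seed, ...) {
  simConfig(seed = seed, nGenes = 15, guidesPerGene = 3, nNegControls = 22,
            depth = 1e6, replicates = 2, ...)
}
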