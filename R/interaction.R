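#' Genetic-interaction calling for dual-crRNA screens
#'
#' Position-sensitive Gaussian null fits of each guide (and gene) paired
#' with negative controls, an expected no-interaction distribution for each
#' gene pair, a one-sample Kolmogorov-Smirnov test of the observed cassette
#' LFCs against it, Benjamini-Hochberg FDR control, and hit classification
#' by log2 differential and q-value.
#'
#' @name interaction
NULL

#' Condense replicate counts
#'
#' Raw counts are summed element-wise across replicates within each
#' timepoint before normalization and LFC computation.
#'
#' @param sc a [ScreenCounts-class] with one or more replicates, or a list
#'   of single-replicate [ScreenCounts-class] objects with identical rows.
#' @return A [ScreenCounts-class] with one condensed sample per timepoint.
#' @export
condenseReplicates <- function(sc) {
  if (is.list(sc)) {
    rn <- lapply(sc, rownames)
    if (!all(vapply(rn[-1], identical, logical(1), rn[[1]])))
      stop("replicate tables have mismatched row ids")
    merged <- do.call(cbind, lapply(sc, screenAssay))
    tp <- unlist(lapply(sc, timepoints))
    rd <- SummarizedExperiment::rowData(sc[[1]])
  } else {
    merged <- screenAssay(sc)
    tp <- timepoints(sc)
    rd <- SummarizedExperiment::rowData(sc)
  }
  out <- vapply(c("initial", "final"), function(t) {
    cols <- which(tp == t)
    if (length(cols) == 0) stop("no '", t, "' sample to condense")
    rowSums(merged[, cols, drop = FALSE])
  }, numeric(nrow(merged)))
  rownames(out) <- rownames(merged)
  screenCounts(out, timepoint = c("initial", "final"),
               replicate = c("condensed", "condensed"), rowData = rd)
}

#' Attach cassette position keys to an LFC table
#'
#' @param lfc DataFrame from [guideLfc()] computed on a cassette-level
#'   table (ids of the form \code{pos1|pos2}).
#' @param cassettes DataFrame with \code{cassette_id}, \code{pos1},
#'   \code{pos2}.
#' @return DataFrame with \code{cassette_id}, \code{pos1}, \code{pos2},
#'   \code{lfc}.
#' @export
cassetteLfc <- function(lfc, cassettes) {
  i <- match(lfc$guide_id, cassettes$cassette_id)
  if (anyNA(i)) stop("cassette ids in the LFC table missing from annotation")
  DataFrame(cassette_id = lfc$guide_id,
            pos1 = cassettes$pos1[i], pos2 = cassettes$pos2[i],
            lfc = lfc$lfc)
}

.negIds <- function(annotation)
  annotation$guide_id[annotation$category == "negative_control"]

.expIds <- function(annotation)
  annotation$guide_id[annotation$category != "negative_control"]

#' Eliminate guides with insufficient negative-control coverage
#'
#' For each experimental guide, the number of distinct negative controls
#' detected in the other cassette position is counted for both of its
#' positions; if either count is below \code{minNeg}, every cassette
#' containing that guide in either position is removed.
#'
#' @param lfc cassette-level LFC DataFrame (see [cassetteLfc()]).
#' @param annotation guide annotation marking \code{negative_control}s.
#' @param minNeg minimum distinct negative controls per position (default 4).
#' @return list with \code{lfc} (filtered) and \code{removedGuides}.
#' @export
filterNegCoverage <- function(lfc, annotation, minNeg = 4) {
  negs <- .negIds(annotation)
  # only guides detected at all can be eliminated; absent guides are absent
  exps <- intersect(.expIds(annotation), unique(c(lfc$pos1, lfc$pos2)))
  n1 <- lfc[lfc$pos1 %in% exps & lfc$pos2 %in% negs, ]
  n2 <- lfc[lfc$pos2 %in% exps & lfc$pos1 %in% negs, ]
  cov1 <- vapply(split(n1$pos2, factor(n1$pos1, levels = exps)),
                 function(v) length(unique(v)), integer(1))
  cov2 <- vapply(split(n2$pos1, factor(n2$pos2, levels = exps)),
                 function(v) length(unique(v)), integer(1))
  bad <- exps[cov1 < minNeg | cov2 < minNeg]
  keep <- !(lfc$pos1 %in% bad | lfc$pos2 %in% bad)
  list(lfc = lfc[keep, ], removedGuides = bad)
}

#' Retain gene pairs with enough detected cassettes
#'
#' A (unordered, distinct) gene pair is kept iff at least \code{minPairs}
#' experimental-by-experimental cassettes targeting it are detected, both
#' orientations counted.
#'
#' @param lfc filtered cassette-level LFC DataFrame.
#' @param annotation guide annotation.
#' @param minPairs minimum detected cassettes per gene pair (default 8).
#' @return DataFrame with \code{geneA}, \code{geneB}, \code{n_obs} for the
#'   retained pairs (geneA < geneB lexicographically).
#' @export
filterPairSupport <- function(lfc, annotation, minPairs = 8) {
  geneOf <- stats::setNames(annotation$gene, annotation$guide_id)
  exps <- .expIds(annotation)
  ee <- lfc[lfc$pos1 %in% exps & lfc$pos2 %in% exps, ]
  gA <- geneOf[ee$pos1]
  gB <- geneOf[ee$pos2]
  distinct <- gA != gB
  key <- paste(pmin(gA, gB), pmax(gA, gB), sep = "\r")[distinct]
  tab <- table(key)
  kept <- names(tab)[tab >= minPairs]
  parts <- strsplit(kept, "\r", fixed = TRUE)
  DataFrame(geneA = vapply(parts, `[`, character(1), 1),
            geneB = vapply(parts, `[`, character(1), 2),
            n_obs = as.integer(tab[kept]))
}

#' Restrict to genes with enough surviving guides
#'
#' @param lfc filtered cassette-level LFC DataFrame.
#' @param annotation guide annotation.
#' @param minValid minimum surviving experimental guides per gene
#'   (default 2).
#' @return character vector of valid gene ids.
#' @export
filterGeneGuides <- function(lfc, annotation, minValid = 2) {
  exps <- .expIds(annotation)
  surviving <- intersect(exps, unique(c(lfc$pos1, lfc$pos2)))
  genes <- annotation$gene[match(surviving, annotation$guide_id)]
  tab <- table(genes)
  names(tab)[tab >= minValid]
}

.fitValues <- function(values) {
  n <- length(values)
  if (n < 2L) stop("need at least 2 values for a Gaussian fit")
  gaussianFit(mean(values), stats::sd(values), n)
}

#' Position-sensitive Gaussian null fit of one guide
#'
#' Fits mean and sd (n-1 denominator) of the LFCs of cassettes carrying the
#' guide in the given position with any negative control in the other
#' position. Position 1 and position 2 fits are distinct objects.
#'
#' @param lfc cassette-level LFC DataFrame.
#' @param annotation guide annotation.
#' @param guide experimental guide id.
#' @param position 1 or 2.
#' @return A [GaussianFit-class]; sd 0 is permitted but flagged degenerate
#'   by downstream steps.
#' @export
fitGuideNull <- function(lfc, annotation, guide, position) {
  negs <- .negIds(annotation)
  vals <- if (position == 1)
    lfc$lfc[lfc$pos1 == guide & lfc$pos2 %in% negs]
  else
    lfc$lfc[lfc$pos2 == guide & lfc$pos1 %in% negs]
  .fitValues(vals)
}

#' Position-sensitive Gaussian null fit of one gene
#'
#' Pools the negative-control-paired LFCs of all surviving guides of the
#' gene in the given position and fits a single Gaussian.
#'
#' @param lfc cassette-level LFC DataFrame.
#' @param annotation guide annotation.
#' @param gene gene id.
#' @param position 1 or 2.
#' @param guides optional restriction to a surviving guide set.
#' @return A [GaussianFit-class].
#' @export
fitGeneNull <- function(lfc, annotation, gene, position, guides = NULL) {
  negs <- .negIds(annotation)
  g <- annotation$guide_id[annotation$gene == gene &
                           annotation$category != "negative_control"]
  if (!is.null(guides)) g <- intersect(g, guides)
  vals <- if (position == 1)
    lfc$lfc[lfc$pos1 %in% g & lfc$pos2 %in% negs]
  else
    lfc$lfc[lfc$pos2 %in% g & lfc$pos1 %in% negs]
  .fitValues(vals)
}

#' Expected no-interaction distribution of a guide or gene pair
#'
#' Default \code{additive} mode: the distribution of the sum of independent
#' draws from the two fits (mean the sum of means, variance the sum of
#' variances) — the expected double-knockout score when log2 effects
#' combine additively. The literal \code{density-product} mode
#' (precision-weighted mean, harmonic variance) is retained for comparison
#' only; its mean lies between the single-knockout means, which makes a
#' depletion differential test incoherent.
#'
#' @param fitA,fitB [GaussianFit-class] objects.
#' @param mode \code{"additive"} (default) or \code{"density-product"}.
#' @return A [GaussianFit-class].
#' @export
expectedPair <- function(fitA, fitB, mode = c("additive", "density-product")) {
  mode <- match.arg(mode)
  if (mode == "additive") {
    gaussianFit(fitA@mean + fitB@mean,
                sqrt(fitA@sd^2 + fitB@sd^2),
                fitA@n + fitB@n)
  } else {
    vA <- fitA@sd^2
    vB <- fitB@sd^2
    if (vA + vB == 0) return(gaussianFit(fitA@mean, 0, fitA@n + fitB@n))
    gaussianFit((fitA@mean * vB + fitB@mean * vA) / (vA + vB),
                sqrt(vA * vB / (vA + vB)),
                fitA@n + fitB@n)
  }
}

# Moment-matched equal-weight two-component Gaussian mixture.
.mixtureFit <- function(f1, f2) {
  m <- (f1@mean + f2@mean) / 2
  v <- (f1@sd^2 + f1@mean^2 + f2@sd^2 + f2@mean^2) / 2 - m^2
  gaussianFit(m, sqrt(max(v, 0)), f1@n + f2@n)
}

#' Observed LFC distribution of a gene pair
#'
#' All surviving experimental-by-experimental cassette LFCs targeting the
#' unordered pair, both orientations pooled, with their Gaussian fit.
#'
#' @param lfc cassette-level LFC DataFrame.
#' @param annotation guide annotation.
#' @param geneA,geneB the gene pair.
#' @return list with \code{fit} ([GaussianFit-class]) and \code{values}.
#' @export
observedPair <- function(lfc, annotation, geneA, geneB) {
  geneOf <- stats::setNames(annotation$gene, annotation$guide_id)
  exps <- .expIds(annotation)
  ee <- lfc$pos1 %in% exps & lfc$pos2 %in% exps
  gA <- geneOf[lfc$pos1]
  gB <- geneOf[lfc$pos2]
  sel <- ee & ((gA == geneA & gB == geneB) | (gA == geneB & gB == geneA))
  vals <- lfc$lfc[sel]
  if (length(vals) < 2L) {
    warning("gene pair ", geneA, "-", geneB, " has fewer than 2 observed ",
            "cassettes; dropped")
    return(NULL)
  }
  list(fit = .fitValues(vals), values = vals)
}

#' One-sample Kolmogorov-Smirnov test against an expected Gaussian
#'
#' D is the supremum distance between the empirical CDF of the observed LFC
#' values and the expected Gaussian CDF; the p-value is asymptotic
#' (Kolmogorov distribution).
#'
#' @param values observed LFC values.
#' @param expected a [GaussianFit-class] with sd > 0.
#' @return list with \code{D} and \code{p}.
#' @export
ksPair <- function(values, expected) {
  if (expected@sd <= 0)
    stop("expected distribution is degenerate (sd = 0); KS test undefined")
  kt <- suppressWarnings(
    stats::ks.test(values, "pnorm", mean = expected@mean, sd = expected@sd,
                   alternative = "two.sided", exact = FALSE))
  list(D = unname(kt$statistic), p = kt$p.value)
}

#' Classify synthetic-sick hits
#'
#' Benjamini-Hochberg q-values are computed across all retained gene pairs;
#' a pair is a hit iff \code{q < fdr} and the log2 differential
#' (expected mean minus observed mean; positive = observed more depleted
#' than expected) exceeds \code{minDifferential}. The z-score
#' (differential / expected sd) is reported alongside but not used for
#' gating.
#'
#' @param pairs DataFrame with at least \code{p} and \code{differential}.
#' @param fdr FDR cutoff (default 0.05).
#' @param minDifferential log2 differential cutoff (default 2.5).
#' @return The input with \code{q} and \code{hit} columns added.
#' @export
callHits <- function(pairs, fdr = 0.05, minDifferential = 2.5) {
  if (nrow(pairs) == 0) {
    warning("empty pair set; no hits to call")
    pairs$q <- numeric(0)
    pairs$hit <- logical(0)
    return(pairs)
  }
  pairs$q <- stats::p.adjust(pairs$p, method = "BH")
  pairs$hit <- !is.na(pairs$q) & pairs$q < fdr &
    pairs$differential > minDifferential
  pairs
}

#' Fraction of guides with a stronger effect in cassette position 1
#'
#' @param guideFits DataFrame with \code{guide}, \code{position},
#'   \code{mean} (as produced by [callInteractions()]).
#' @return Fraction of experimental guides whose position-1 null mean is
#'   strictly lower (stronger dropout) than their position-2 mean; guides
#'   lacking a fit in either position are excluded from the denominator.
#' @export
positionBias <- function(guideFits) {
  m1 <- guideFits$mean[guideFits$position == 1]
  names(m1) <- guideFits$guide[guideFits$position == 1]
  m2 <- guideFits$mean[guideFits$position == 2]
  names(m2) <- guideFits$guide[guideFits$position == 2]
  shared <- intersect(names(m1), names(m2))
  if (length(shared) == 0) stop("no guide has fits in both positions")
  mean(m1[shared] < m2[shared])
}

#' Full interaction-calling pipeline on a cassette LFC table
#'
#' Applies the coverage, pair-support and valid-guide filters, builds
#' position-sensitive guide and gene null fits, forms each retained pair's
#' expected distribution (the equal-weight mixture of the two orientation
#' convolutions pos1(A)+pos2(B) and pos1(B)+pos2(A)), tests the observed
#' cassette LFCs against it, and classifies hits.
#'
#' @param lfc cassette-level LFC DataFrame (see [cassetteLfc()]).
#' @param annotation guide annotation.
#' @param minNeg,minPairs,minValid filter thresholds (defaults 4, 8, 2).
#' @param fdr,minDifferential hit thresholds (defaults 0.05, 2.5).
#' @param expectedMode expected-pair mode, see [expectedPair()].
#' @return list with \code{pairs} (per-pair results: fits, KS D, p, q,
#'   differential, z, hit), \code{guideFits}, \code{geneFits},
#'   \code{removedGuides}, \code{validGenes}.
#' @export
callInteractions <- function(lfc, annotation, minNeg = 4, minPairs = 8,
                             minValid = 2, fdr = 0.05,
                             minDifferential = 2.5,
                             expectedMode = "additive") {
  cov <- filterNegCoverage(lfc, annotation, minNeg)
  # plain data.frames: the per-guide/per-pair loops below subset them heavily
  lfc2 <- as.data.frame(cov$lfc)
  annotation <- as.data.frame(annotation)
  support <- filterPairSupport(lfc2, annotation, minPairs)
  validGenes <- filterGeneGuides(lfc2, annotation, minValid)
  support <- support[support$geneA %in% validGenes &
                     support$geneB %in% validGenes, ]
  exps <- .expIds(annotation)
  surviving <- intersect(exps, unique(c(lfc2$pos1, lfc2$pos2)))
  guideFits <- do.call(rbind, lapply(surviving, function(g) {
    do.call(rbind, lapply(1:2, function(p) {
      f <- tryCatch(fitGuideNull(lfc2, annotation, g, p),
                    error = function(e) NULL)
      if (is.null(f)) return(NULL)
      data.frame(guide = g, position = p, mean = f@mean, sd = f@sd, n = f@n)
    }))
  }))
  geneFits <- do.call(rbind, lapply(validGenes, function(G) {
    do.call(rbind, lapply(1:2, function(p) {
      f <- tryCatch(fitGeneNull(lfc2, annotation, G, p, guides = surviving),
                    error = function(e) NULL)
      if (is.null(f)) return(NULL)
      data.frame(gene = G, position = p, mean = f@mean, sd = f@sd, n = f@n)
    }))
  }))
  geneFit <- function(G, p) {
    i <- which(geneFits$gene == G & geneFits$position == p)
    if (length(i) != 1L) return(NULL)
    gaussianFit(geneFits$mean[i], geneFits$sd[i], geneFits$n[i])
  }
  rows <- lapply(seq_len(nrow(support)), function(k) {
    A <- support$geneA[k]
    B <- support$geneB[k]
    fA1 <- geneFit(A, 1); fA2 <- geneFit(A, 2)
    fB1 <- geneFit(B, 1); fB2 <- geneFit(B, 2)
    if (is.null(fA1) || is.null(fA2) || is.null(fB1) || is.null(fB2))
      return(NULL)
    expFit <- .mixtureFit(expectedPair(fA1, fB2, expectedMode),
                          expectedPair(fB1, fA2, expectedMode))
    obs <- observedPair(lfc2, annotation, A, B)
    if (is.null(obs)) return(NULL)
    ks <- if (expFit@sd > 0) ksPair(obs$values, expFit)
          else list(D = NA_real_, p = NA_real_)
    diff <- expFit@mean - obs$fit@mean
    data.frame(geneA = A, geneB = B,
               expected_mean = expFit@mean, expected_sd = expFit@sd,
               observed_mean = obs$fit@mean, observed_sd = obs$fit@sd,
               n_obs = obs$fit@n, ks_D = ks$D, p = ks$p,
               differential = diff,
               z = if (expFit@sd > 0) diff / expFit@sd else NA_real_)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  pairs <- if (length(rows)) DataFrame(do.call(rbind, rows)) else
    DataFrame(geneA = character(), geneB = character(),
              expected_mean = numeric(), expected_sd = numeric(),
              observed_mean = numeric(), observed_sd = numeric(),
              n_obs = integer(), ks_D = numeric(), p = numeric(),
              differential = numeric(), z = numeric())
  pairs <- suppressWarnings(callHits(pairs, fdr, minDifferential))
  list(pairs = pairs,
       guideFits = if (is.null(guideFits)) NULL else DataFrame(guideFits),
       geneFits = if (is.null(geneFits)) NULL else DataFrame(geneFits),
       removedGuides = cov$removedGuides, validGenes = validGenes)
}

#' Analyze a dual-crRNA screen from raw counts
#'
#' Condenses replicates by raw-count summation, removes cassettes with low
#' initial counts, normalizes to \code{scale} reads, computes capped LFCs
#' and runs [callInteractions()].
#'
#' @param sc raw cassette-level [ScreenCounts-class] whose rowData carries
#'   \code{cassette_id}, \code{pos1}, \code{pos2}.
#' @param annotation guide annotation.
#' @param minInitial,scale,cap LFC-stage parameters (defaults 50, 1e6, 100).
#' @param ... passed to [callInteractions()].
#' @return list with \code{lfc} (cassette-level) and the
#'   [callInteractions()] results.
#' @export
analyzeDualScreen <- function(sc, annotation, minInitial = 50, scale = 1e6,
                              cap = 100, ...) {
  cond <- condenseReplicates(sc)
  flt <- filterLowInitial(cond, minInitial)
  norm <- normalizeDepth(flt$counts, scale)
  raw <- guideLfc(norm, cap)
  cassettes <- SummarizedExperiment::rowData(flt$counts)
  lfc <- cassetteLfc(raw, cassettes)
  res <- callInteractions(lfc, annotation, ...)
  c(list(lfc = lfc, removedCassettes = flt$removed), res)
}
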