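#' Single-screen scoring
#'
#' Depth normalization, low-initial-count filtering, capped log2 fold-change
#' (LFC), domain-level CRISPR Scores (CS), category comparisons and
#' replicate agreement.
#'
#' @name scoring
NULL

#' Rescale every sample to the same total read count
#'
#' Each column is multiplied by \code{scale / colSum}, so all samples sum to
#' \code{scale}; within-column order is preserved exactly.
#'
#' @param sc a [ScreenCounts-class].
#' @param scale target total per sample (default one million).
#' @return A [ScreenCounts-class] with normalized (real-valued) counts.
#' @export
normalizeDepth <- function(sc, scale = 1e6) {
  a <- screenAssay(sc)
  cs <- colSums(a)
  if (any(cs == 0)) stop("cannot normalize an all-zero sample column")
  a <- sweep(a, 2, cs / scale, "/")
  screenCounts(a, timepoints(sc), replicates(sc),
               rowData = SummarizedExperiment::rowData(sc))
}

#' Discard guides with low raw initial counts
#'
#' Rows whose raw count in any initial sample is below \code{minInitial}
#' are removed from all samples. Applied to raw (pre-normalization) counts.
#'
#' @param sc a [ScreenCounts-class] of raw counts.
#' @param minInitial minimum initial read count (default 50; a guide at
#'   exactly the threshold is kept).
#' @return list with \code{counts} (filtered [ScreenCounts-class]) and
#'   \code{removed} (character vector of dropped row ids).
#' @export
filterLowInitial <- function(sc, minInitial = 50) {
  ini <- screenAssay(sc)[, timepoints(sc) == "initial", drop = FALSE]
  if (ncol(ini) == 0) stop("table has no initial sample")
  low <- apply(ini, 1, min) < minInitial
  list(counts = sc[!low, ], removed = rownames(sc)[low])
}

#' Capped log2 fold-change per guide and replicate
#'
#' Fold-change is \code{(final + 1) / initial} on normalized abundances,
#' capped at \code{cap} (default 100) before taking log2; only the final
#' abundance receives the pseudocount. Depletion (the dropout direction) is
#' uncapped.
#'
#' @param sc a normalized [ScreenCounts-class] with matching
#'   initial/final replicate labels.
#' @param cap maximum fold-change (default 100).
#' @return DataFrame with \code{guide_id}, \code{replicate}, \code{lfc},
#'   \code{fc_capped}.
#' @export
guideLfc <- function(sc, cap = 100) {
  a <- screenAssay(sc)
  tp <- timepoints(sc)
  rep <- replicates(sc)
  reps <- unique(rep[tp == "initial"])
  out <- lapply(reps, function(r) {
    i <- which(tp == "initial" & rep == r)
    f <- which(tp == "final" & rep == r)
    if (length(i) != 1L || length(f) != 1L)
      stop("replicate '", r, "' needs exactly one initial and one final sample")
    ini <- a[, i]
    fin <- a[, f]
    if (any(ini <= 0))
      stop("initial abundance must be positive; apply filterLowInitial first")
    fc <- (fin + 1) / ini
    capped <- fc > cap
    fc[capped] <- cap
    DataFrame(guide_id = rownames(a), replicate = r,
              lfc = unname(log2(fc)), fc_capped = unname(capped))
  })
  do.call(rbind, out)
}

#' Domain-level CRISPR Scores
#'
#' The CS of a protein domain is the arithmetic mean LFC of all guides
#' targeting it; per-guide LFCs are first averaged across replicates.
#' Domains whose guides were all filtered out are absent from the result
#' (not reported as zero).
#'
#' @param lfc DataFrame from [guideLfc()].
#' @param annotation guide annotation with \code{guide_id}, \code{gene},
#'   \code{domain}.
#' @return DataFrame with \code{domain}, \code{gene}, \code{cs},
#'   \code{n_guides}.
#' @export
domainCS <- function(lfc, annotation) {
  perGuide <- vapply(split(lfc$lfc, lfc$guide_id), mean, numeric(1))
  ann <- annotation[match(names(perGuide), annotation$guide_id), ]
  if (anyNA(ann$guide_id)) stop("every guide must be annotated")
  keep <- !is.na(ann$domain)
  vals <- split(perGuide[keep], ann$domain[keep])
  doms <- names(vals)
  DataFrame(domain = doms,
            gene = annotation$gene[match(doms, annotation$domain)],
            cs = unname(vapply(vals, mean, numeric(1))),
            n_guides = unname(lengths(vals)))
}

#' Compare guide LFC distributions between target categories
#'
#' Reports the per-category median LFC and pairwise two-sided Mann-Whitney
#' U-test p-values (exact when both groups are small and untied, normal
#' approximation with tie correction otherwise).
#'
#' @param lfc DataFrame from [guideLfc()].
#' @param annotation guide annotation with \code{guide_id}, \code{category}.
#' @param exactLimit use the exact null distribution when the product of
#'   group sizes is at most this (default 1e4) and there are no ties.
#' @return list with \code{medians} (named numeric) and \code{tests}
#'   (DataFrame: groupA, groupB, U, p).
#' @export
categoryComparison <- function(lfc, annotation, exactLimit = 1e4) {
  perGuide <- vapply(split(lfc$lfc, lfc$guide_id), mean, numeric(1))
  cat <- annotation$category[match(names(perGuide), annotation$guide_id)]
  groups <- split(unname(perGuide), cat)
  groups <- groups[lengths(groups) >= 1L]
  if (length(groups) < 2L)
    stop("need at least two categories with at least one guide each")
  medians <- vapply(groups, stats::median, numeric(1))
  combos <- utils::combn(names(groups), 2)
  tests <- apply(combos, 2, function(gg) {
    x <- groups[[gg[1]]]
    y <- groups[[gg[2]]]
    ties <- anyDuplicated(c(x, y)) > 0
    exact <- !ties && length(x) * length(y) <= exactLimit
    wt <- suppressWarnings(
      stats::wilcox.test(x, y, alternative = "two.sided",
                         exact = exact, correct = TRUE))
    DataFrame(groupA = gg[1], groupB = gg[2],
              U = unname(wt$statistic), p = wt$p.value)
  })
  list(medians = medians, tests = do.call(rbind, tests))
}

#' Pearson correlation between replicate score vectors
#'
#' @param x,y named numeric vectors of per-domain (or per-guide) scores; the
#'   correlation is computed over shared names.
#' @return Pearson r.
#' @export
replicateCorrelation <- function(x, y) {
  shared <- intersect(names(x), names(y))
  if (length(shared) < 3L) stop("need at least 3 shared ids")
  x <- x[shared]
  y <- y[shared]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in a replicate vector: correlation undefined")
  stats::cor(x, y, method = "pearson")
}

#' Score a single-crRNA screen end to end
#'
#' Filters low-initial guides on raw counts, normalizes each sample, computes
#' per-replicate capped LFCs and domain CRISPR Scores.
#'
#' @param sc raw [ScreenCounts-class].
#' @param annotation guide annotation table.
#' @param minInitial,scale,cap see the individual steps.
#' @return list with \code{lfc}, \code{domainScores}, \code{removed}.
#' @export
scoreScreen <- function(sc, annotation, minInitial = 50, scale = 1e6,
                        cap = 100) {
  flt <- filterLowInitial(sc, minInitial)
  norm <- normalizeDepth(flt$counts, scale)
  lfc <- guideLfc(norm, cap)
  list(lfc = lfc,
       domainScores = domainCS(lfc, annotation),
       removed = flt$removed)
}
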