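test_that("replicate condensation sums raw counts per timepoint", {
  m <- cbind(initial_rep1 = c(10, 20), final_rep1 = c(7, 8),
             initial_rep2 = c(5, 5), final_rep2 = c(3, 2))
  rownames(m) <- c("x", "y")
  sc <- screenCounts(m, c("initial", "final", "initial", "final"),
                     c(1, 1, 2, 2))
  cond <- condenseReplicates(sc)
  expect_equal(unname(screenAssay(cond)[, "initial"]), c(15, 25))
  expect_equal(unname(screenAssay(cond)[, "final"]), c(10, 10))
  # single replicate: identity
  one <- screenCounts(m[, 1:2], c("initial", "final"), c(1, 1))
  expect_equal(unname(screenAssay(condenseReplicates(one))),
               unname(m[, 1:2]))
  # condense-then-normalize equals normalize-of-the-sum by definition
  expect_equal(screenAssay(normalizeDepth(cond, 100)),
               screenAssay(normalizeDepth(condenseReplicates(sc), 100)))
  bad <- list(one, screenCounts(m[2:1, 1:2], c("initial", "final"), c(1, 1)))
  expect_error(condenseReplicates(bad), "mismatched row ids")
})

test_that("negative-coverage filter implements the three-control elimination", {
  ann <- makeAnnotation(2, 5)
  # e1: only 3 distinct negatives in position 2, 4 in position 1
  # e2: 4 distinct negatives in both positions
  lfc <- makeLfc(
    pos1 = c("e1", "e1", "e1", "n1", "n2", "n3", "n4",
             "e2", "e2", "e2", "e2", "n1", "n2", "n3", "n4",
             "e1", "e2"),
    pos2 = c("n1", "n2", "n3", "e1", "e1", "e1", "e1",
             "n1", "n2", "n3", "n4", "e2", "e2", "e2", "e2",
             "e2", "e1"),
    lfc = 0)
  flt <- filterNegCoverage(lfc, ann)
  expect_identical(flt$removedGuides, "e1")
  # every cassette containing e1 in either position is gone
  expect_false(any(flt$lfc$pos1 == "e1" | flt$lfc$pos2 == "e1"))
  expect_true(all(flt$lfc$pos1 == "e2" | flt$lfc$pos2 == "e2"))
  # idempotent
  again <- filterNegCoverage(flt$lfc, ann)
  expect_length(again$removedGuides, 0)
  expect_equal(as.data.frame(again$lfc), as.data.frame(flt$lfc))
  # no negative controls at all: every experimental guide eliminated
  noNeg <- makeLfc(c("e1", "e2"), c("e2", "e1"), 0)
  expect_setequal(filterNegCoverage(noNeg, ann)$removedGuides, c("e1", "e2"))
})

test_that("gene pairs need at least 8 detected cassettes", {
  ann <- makeAnnotation(6, 4, genes = rep(c("GA", "GB", "GC"), each = 2))
  mk <- function(n, g1, g2) {
    a <- ann$guide_id[ann$gene == g1]
    b <- ann$guide_id[ann$gene == g2]
    grid <- expand.grid(pos1 = a, pos2 = b, stringsAsFactors = FALSE)
    grid[seq_len(n), ]
  }
  ab <- mk(4, "GA", "GB")      # + 4 reversed = 8 detected
  ac <- mk(4, "GA", "GC")      # + 3 reversed = 7 detected
  lfc <- makeLfc(
    pos1 = c(ab$pos1, ab$pos2, ac$pos1, ac$pos2[1:3]),
    pos2 = c(ab$pos2, ab$pos1, ac$pos2, ac$pos1[1:3]),
    lfc = 0)
  kept <- filterPairSupport(lfc, ann)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$geneA, "GA")
  expect_equal(kept$geneB, "GB")
  expect_equal(kept$n_obs, 8L)
  # 18 cassettes (3x3 guides, both orientations) are comfortably kept
  ann9 <- makeAnnotation(6, 2, genes = rep(c("GX", "GY"), each = 3))
  gx <- ann9$guide_id[ann9$gene == "GX"]
  gy <- ann9$guide_id[ann9$gene == "GY"]
  grid <- expand.grid(pos1 = gx, pos2 = gy, stringsAsFactors = FALSE)
  lfc18 <- makeLfc(c(grid$pos1, grid$pos2), c(grid$pos2, grid$pos1), 0)
  expect_equal(filterPairSupport(lfc18, ann9)$n_obs, 18L)
})

test_that("genes need at least two surviving guides", {
  ann <- makeAnnotation(3, 2, genes = c("GA", "GA", "GB"))
  lfc <- makeLfc(c("e1", "e2", "e3"), c("n1", "n1", "n1"), 0)
  expect_identical(filterGeneGuides(lfc, ann), "GA")
  lfc2 <- makeLfc(c("e1", "e2"), c("n1", "n1"), 0)
  expect_identical(filterGeneGuides(lfc2, ann), "GA")
  # all guides surviving keeps every gene with enough design
  expect_identical(filterGeneGuides(lfc, ann, minValid = 1), c("GA", "GB"))
})

test_that("guide and gene null fits are sample mean/sd over negative pairings", {
  ann <- makeAnnotation(2, 3, genes = c("GA", "GA"))
  lfc <- makeLfc(
    pos1 = c("e1", "e1", "e1", "e2", "e2", "n1", "n2"),
    pos2 = c("n1", "n2", "n3", "n1", "n2", "e1", "e1"),
    lfc = c(-1, -2, -3, -3.5, -2.5, -7, -8))
  f <- fitGuideNull(lfc, ann, "e1", 1)
  expect_equal(fitMean(f), -2)
  expect_equal(fitSd(f), 1)
  expect_equal(fitN(f), 3L)
  # position-sensitive: position 2 fit uses different cassettes
  f2 <- fitGuideNull(lfc, ann, "e1", 2)
  expect_equal(fitMean(f2), -7.5)
  # degenerate fit: sd 0 is representable
  lfcC <- makeLfc(rep("e1", 4), paste0("n", c(1, 2, 3, 1)), rep(-2, 4))
  expect_equal(fitSd(fitGuideNull(lfcC, ann, "e1", 1)), 0)
  expect_error(fitGuideNull(lfc, ann, "e2", 2), "at least 2")
  # gene fit pools member guides; single-guide pooling = guide fit
  g <- fitGeneNull(lfc, ann, "GA", 1)
  expect_equal(fitMean(g), mean(c(-1, -2, -3, -3.5, -2.5)))
  expect_equal(fitN(g), 5L)
  g1 <- fitGeneNull(lfc, ann, "GA", 1, guides = "e1")
  expect_equal(fitMean(g1), fitMean(f))
})

test_that("the additive expected-pair model is the exact convolution", {
  a <- gaussianFit(-1, 0.5, 10)
  b <- gaussianFit(-2, 0.5, 12)
  e <- expectedPair(a, b)
  expect_equal(fitMean(e), -3)
  expect_equal(fitSd(e), sqrt(0.5), tolerance = 1e-12)
  # commutative
  e2 <- expectedPair(b, a)
  expect_equal(fitMean(e), fitMean(e2))
  expect_equal(fitSd(e), fitSd(e2))
  # identity element
  z <- expectedPair(a, gaussianFit(0, 0, 2))
  expect_equal(fitMean(z), -1)
  expect_equal(fitSd(z), 0.5)
  # the literal density product lands between the two means
  dp <- expectedPair(a, b, mode = "density-product")
  expect_gt(fitMean(dp), -2)
  expect_lt(fitMean(dp), -1)
  expect_lt(fitSd(dp), 0.5)
})

test_that("observed pair pools both orientations of the gene pair", {
  ann <- makeAnnotation(4, 4, genes = rep(c("GA", "GB"), each = 2))
  lfc <- makeLfc(
    pos1 = c("e1", "e2", "e3", "e4", "e1", "n1"),
    pos2 = c("e3", "e4", "e1", "e2", "n1", "e3"),
    lfc = c(-6, -7, -8, -5, 0, 0))
  obs <- observedPair(lfc, ann, "GA", "GB")
  expect_equal(sort(obs$values), c(-8, -7, -6, -5))
  expect_equal(fitMean(obs$fit), -6.5)
  expect_warning(observedPair(makeLfc("e1", "e3", -1), ann, "GA", "GB"),
                 "fewer than 2")
})

test_that("the KS statistic equals the empirical-CDF supremum", {
  # closed-form construction: quantiles at (i - 0.5)/n give D = 0.5/n
  for (n in c(5, 20, 80)) {
    q <- qnorm((seq_len(n) - 0.5) / n, mean = -1, sd = 2)
    ks <- ksPair(q, gaussianFit(-1, 2, 10))
    expect_equal(ks$D, 0.5 / n, tolerance = 1e-12)
  }
  # frozen value computed from the brute-force oracle
  ks <- ksPair(c(-1, 0, 1), gaussianFit(0, 1, 10))
  expect_equal(ks$D, bruteKsD(c(-1, 0, 1), pnorm), tolerance = 1e-12)
  expect_equal(ks$D, 0.17468, tolerance = 1e-4)
  # far-shifted sample saturates D
  far <- ksPair(rnorm(50, -30, 0.1), gaussianFit(0, 1, 10))
  expect_gt(far$D, 0.999)
  expect_error(ksPair(c(-1, 0, 1), gaussianFit(0, 0, 5)), "degenerate")
})

test_that("hit calling applies BH and the differential gate", {
  pairs <- S4Vectors::DataFrame(
    geneA = letters[1:4], geneB = LETTERS[1:4],
    p = c(0.01, 0.02, 0.03, 0.04),
    differential = c(2.6, 2.4, 3.0, 3.0))
  out <- callHits(pairs)
  # BH by hand: every q = 0.04 here
  expect_equal(out$q, rep(0.04, 4))
  expect_true(out$hit[1])        # differential 2.6, q 0.04
  expect_false(out$hit[2])       # differential 2.4 fails the gate
  # FDR gate: q above the cutoff blocks any differential
  out2 <- callHits(S4Vectors::DataFrame(p = c(0.06, 0.5),
                                        differential = c(3.0, 3.0)))
  expect_false(any(out2$hit))
  expect_warning(callHits(S4Vectors::DataFrame(p = numeric(),
                                               differential = numeric())),
                 "empty")
})

test_that("position bias is the fraction of guides stronger in position 1", {
  gf <- S4Vectors::DataFrame(
    guide = rep(c("e1", "e2", "e3"), each = 2),
    position = rep(1:2, 3),
    mean = c(-3, -1, -2, -2.5, -4, -1))
  expect_equal(positionBias(gf), 2 / 3)
  allFirst <- S4Vectors::DataFrame(guide = rep("e1", 2), position = 1:2,
                                   mean = c(-2, -1))
  expect_equal(positionBias(allFirst), 1)
})

test_that("the interaction pipeline is invariant to input row order", {
  cfg <- simConfig(seed = 10, nGenes = 5, guidesPerGene = 3,
                   nNegControls = 8, depth = 2e5)
  d <- simulateDualScreen(cfg)
  res <- analyzeDualScreen(d$counts, d$annotation)
  perm <- sample(nrow(d$counts))
  res2 <- analyzeDualScreen(d$counts[perm, ], d$annotation)
  a <- as.data.frame(res$pairs)
  b <- as.data.frame(res2$pairs)
  key <- function(x) x[order(x$geneA, x$geneB), ]
  expect_equal(key(a), key(b), tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("position bias responds monotonically to the simulator's beta", {
  frac <- vapply(c(1, 1.5, 2.5), function(beta) {
    cfg <- simConfig(seed = 30, nGenes = 6, guidesPerGene = 3,
                     nNegControls = 8, depth = 1e6,
                     geneEffects = rep(-2, 6), guideSd = 0.2,
                     positionBias = beta)
    d <- simulateDualScreen(cfg)
    res <- analyzeDualScreen(d$counts, d$annotation)
    positionBias(res$guideFits)
  }, numeric(1))
  expect_true(all(diff(frac) >= 0))
  expect_gt(frac[3], 0.9)
  expect_lt(abs(frac[1] - 0.5), 0.35)
})
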