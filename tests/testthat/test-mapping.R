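test_that("mapRead applies the length, distance and uniqueness rules", {
  ref <- makeReference(nGuides = 4, nDesigned = 8)
  seqs <- as.character(refSequences(ref))
  ids <- refPairs(ref)$cassette_id
  # identity
  expect_identical(mapRead(seqs[3], ref), ids[3])
  # short reads are discarded regardless of content
  expect_identical(mapRead(substr(seqs[1], 1, 59), ref), "discarded")
  # 60-base tail of an 84-base cassette is 24 tail edits away: unmapped
  expect_identical(mapRead(substr(seqs[1], 1, 60), ref), "unmapped")
  # three substitutions exceed the two-mismatch budget
  r3 <- seqs[2]
  substr(r3, 1, 3) <- "CCC"  # reference starts with the DR (AAT...)
  expect_identical(mapRead(r3, ref), "unmapped")
  # two substitutions stay within budget
  r2 <- seqs[2]
  substr(r2, 1, 2) <- "CC"
  expect_identical(mapRead(r2, ref), ids[2])
  # N bases count as mismatches
  rN <- seqs[2]
  substr(rN, 1, 2) <- "NN"
  expect_identical(mapRead(rN, ref), ids[2])
  expect_error(mapRead(seqs[1], cassetteReference(
    S4Vectors::DataFrame(pos1 = character(), pos2 = character()),
    refSpacers(ref))), "empty")
})

test_that("ties between equally distant references are left unmapped", {
  spacers <- c(g1 = strrep("A", 23), g2 = strrep("C", 23),
               g3 = paste0(strrep("C", 21), "GG"))
  ref <- cassetteReference(
    S4Vectors::DataFrame(pos1 = c("g1", "g1"), pos2 = c("g2", "g3")),
    spacers)
  seqs <- as.character(refSequences(ref))
  # position-2 spacer C...CG sits at distance 1 from both C23 and C21GG
  read <- paste0(substr(seqs[1], 1, 61), strrep("C", 22), "G")
  d <- utils::adist(read, seqs)
  expect_equal(unname(d[1, 1]), unname(d[1, 2]))
  expect_identical(mapRead(read, ref), "unmapped")
})

test_that("read assignment agrees with a brute-force edit-distance oracle", {
  set.seed(101)
  ref <- makeReference(nGuides = 5, nDesigned = 12, seed = 101)
  seqs <- as.character(refSequences(ref))
  ids <- refPairs(ref)$cassette_id
  pol <- mappingPolicy()
  mutate <- function(s, k) {
    pos <- sample(nchar(s), k)
    ch <- strsplit(s, "")[[1]]
    ch[pos] <- sample(c("A", "C", "G", "T"), k, replace = TRUE)
    paste(ch, collapse = "")
  }
  reads <- c(
    sample(seqs, 10, replace = TRUE),
    vapply(sample(seqs, 15, replace = TRUE), mutate, "", k = 2),
    vapply(sample(seqs, 10, replace = TRUE), mutate, "", k = 5),
    vapply(1:5, function(i) randomSeq(84), ""),
    vapply(sample(seqs, 5), function(s) substr(s, 1, 58), ""))
  got <- vapply(reads, mapRead, "", reference = ref, policy = pol)
  want <- vapply(reads, bruteMapRead, "", refSeqs = seqs, ids = ids)
  expect_identical(unname(got), unname(want))
})

test_that("counting partitions reads exactly into mapped, unmapped, discarded", {
  ref <- makeReference(nGuides = 4, nDesigned = 8, seed = 7)
  seqs <- as.character(refSequences(ref))
  reads <- c(rep(seqs[1], 10), seqs[5], randomSeq(84), substr(seqs[2], 1, 40))
  cc <- countCassettes(reads, ref)
  expect_equal(unname(cc$counts[refPairs(ref)$cassette_id[1]]), 10)
  expect_equal(unname(cc$counts[refPairs(ref)$cassette_id[5]]), 1)
  expect_equal(cc$summary$n_discarded, 1)
  expect_equal(cc$summary$n_unmapped, 1)
  expect_equal(sum(cc$counts) + cc$summary$n_unmapped +
                 cc$summary$n_discarded, length(reads))
})

test_that("cassette counts match the simulator truth labels at zero error", {
  ref <- makeReference(nGuides = 6, nDesigned = 12, seed = 13)
  sim <- simulateCassetteReads(
    simConfig(seed = 13, depth = 800, recombinationRate = 0.2,
              errorRate = 0), ref)
  full <- expandRecombinants(ref)
  cc <- countCassettes(sim$reads, full)
  truthTally <- table(paste(sim$truth$pos1, sim$truth$pos2, sep = "|"))
  got <- cc$counts[cc$counts > 0]
  expect_identical(sort(names(got)), sort(names(truthTally)))
  expect_equal(as.integer(got[names(truthTally)]),
               as.integer(truthTally))
  uf <- uncouplingFrequency(cc$counts, full)
  expect_equal(uf$fraction, mean(sim$truth$recombinant))
})

test_that("uncoupling frequency is a simple mapped-read fraction", {
  ref <- makeReference(nGuides = 4, nDesigned = 8, seed = 21)
  full <- expandRecombinants(ref)
  p <- refPairs(full)
  counts <- stats::setNames(integer(nrow(p)), p$cassette_id)
  counts[p$cassette_id[p$designed][1]] <- 897L
  counts[p$cassette_id[!p$designed][1]] <- 3L
  uf <- uncouplingFrequency(counts, full)
  expect_equal(uf$fraction, 3 / 900)
  expect_equal(uf$percent, 100 * 3 / 900)
  # invariant under uniform duplication of all reads
  expect_equal(uncouplingFrequency(counts * 5L, full)$fraction, 3 / 900)
  # zero recombinant reads give zero
  counts[p$cassette_id[!p$designed][1]] <- 0L
  expect_equal(uncouplingFrequency(counts, full)$fraction, 0)
  expect_error(uncouplingFrequency(counts * 0L, full), "no mapped reads")
})

test_that("recombinant expansion adds exactly the non-designed ordered pairs", {
  ref <- makeReference(nGuides = 5, nDesigned = 9, seed = 3)
  full <- expandRecombinants(ref)
  p <- refPairs(full)
  expect_equal(nrow(p), 25)
  expect_equal(sum(p$designed), 9)
  expect_false(any(duplicated(paste(p$pos1, p$pos2))))
  expect_error(validObject(
    cassetteReference(S4Vectors::DataFrame(
      pos1 = c("g1", "g1"), pos2 = c("g2", "g2"),
      cassette_id = c("a", "b"), designed = c(TRUE, FALSE)),
      refSpacers(ref))), "duplicates a designed")
})

test_that("single-guide counting permits no mismatches", {
  set.seed(17)
  spacers <- c(gA = randomSeq(23), gB = randomSeq(23))
  oneMismatch <- spacers[["gA"]]
  substr(oneMismatch, 1, 1) <-
    setdiff(c("A", "C", "G", "T"), substr(oneMismatch, 1, 1))[1]
  reads <- c(paste0("ACGT", spacers["gA"], "ACGT"),
             paste0(spacers["gA"], "TT"),
             paste0("G", spacers["gB"]),
             paste0("AC", oneMismatch),
             randomSeq(30))
  got <- countSingleGuides(reads, spacers)
  expect_equal(unname(got$counts["gA"]), 2L)
  expect_equal(unname(got$counts["gB"]), 1L)
  expect_equal(got$n_unmatched, 2L)
  empty <- countSingleGuides(character(0), spacers)
  expect_true(all(empty$counts == 0L))
  expect_error(countSingleGuides(reads, c(a = "ACGT", b = "ACGT")),
               "duplicate spacers")
})
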