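smallDesign <- function(...) {
  simulationDesign(databases = c("A", "B", "C"), nGenera = 40L,
                   partitionCounts = c("3" = 10, "2" = 20, "1" = 30),
                   seed = 7L, ...)
}

recoverPartition <- function(sim, rank = "species") {
  files <- truthFiles(sim$truth)
  mans <- lapply(names(files), function(n) readManifestTsv(files[[n]], n))
  vennPartition(lapply(mans, projectToRank, tax = sim$taxonomy,
                       rank = rank))
}

test_that("generated taxonomy matches the designed hierarchy", {
  d <- smallDesign()
  out <- generateTaxonomy(d, withr::local_tempdir())
  nd <- taxonNodes(out$taxonomy)
  reg <- out$registry
  expect_equal(sum(nd$rank == "genus"), 40L)
  expect_equal(sum(nd$rank == "species"), nrow(reg$species))
  expect_equal(sum(nd$rank == "strain"), nrow(reg$strains))
  # every species hangs under a genus, every strain under a species
  expect_true(all(nd$parent[match(reg$species$taxid, nd$taxid)] %in%
                    nd$taxid[nd$rank == "genus"]))
  expect_true(all(nd$parent[match(reg$strains$taxid, nd$taxid)] %in%
                    reg$species$taxid))
})

test_that("taxdump emission is byte-identical given a seed", {
  d <- smallDesign()
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  s1 <- simulateStudy(d, d1)
  s2 <- simulateStudy(d, d2)
  for (f in names(s1$files))
    expect_identical(readLines(s1$files[[f]]), readLines(s2$files[[f]]),
                     info = f)
})

test_that("merged fraction zero leaves merged.dmp empty", {
  d <- simulationDesign(databases = c("A", "B"), nGenera = 10L,
                        partitionCounts = c("1" = 5), mergedFraction = 0,
                        seed = 3L)
  out <- generateTaxonomy(d, withr::local_tempdir())
  expect_length(readLines(out$files[["merged"]]), 0L)
  expect_length(mergedIds(out$taxonomy), 0L)
})

test_that("the concordance pipeline recovers the planted partition exactly", {
  # full-cell design
  d <- simulationDesign(databases = c("A", "B", "C"), nGenera = 50L,
                        partitionType = "cells",
                        partitionCounts = c("A;B;C" = 5, "A;B" = 7,
                                            "A;C" = 4, "B" = 14, "C" = 30),
                        seed = 13L)
  sim <- simulateStudy(d, withr::local_tempdir())
  p <- recoverPartition(sim)
  expect_true(samePartitionCells(partitionCells(p),
                                 partitionCells(plantedPartition(sim$truth))))
  expect_equal(unionSize(p), 60L)
  # exactly-k design
  sim2 <- simulateStudy(smallDesign(), withr::local_tempdir())
  p2 <- recoverPartition(sim2)
  expect_true(samePartitionCells(
    partitionCells(p2), partitionCells(plantedPartition(sim2$truth))))
  expect_equal(exactlyKCounts(p2), c("1" = 30L, "2" = 20L, "3" = 10L))
})

test_that("strain-level emission leaves the species partition unchanged", {
  base <- smallDesign(strainEmissionFraction = 0)
  strained <- smallDesign(strainEmissionFraction = 1)
  pA <- recoverPartition(simulateStudy(base, withr::local_tempdir()))
  pB <- recoverPartition(simulateStudy(strained, withr::local_tempdir()))
  expect_true(samePartitionCells(partitionCells(pA), partitionCells(pB)))
})

test_that("merged-id redirection is transparent to the pipeline", {
  pA <- recoverPartition(simulateStudy(smallDesign(mergedFraction = 0),
                                       withr::local_tempdir()))
  pB <- recoverPartition(simulateStudy(smallDesign(mergedFraction = 0.2),
                                       withr::local_tempdir()))
  expect_true(samePartitionCells(partitionCells(pA), partitionCells(pB)))
})

test_that("genus-attached isolates are excluded as rank-unprojectable", {
  d <- smallDesign(isolateFraction = 0.3)
  sim <- simulateStudy(d, withr::local_tempdir())
  files <- truthFiles(sim$truth)
  mans <- lapply(names(files), function(n) readManifestTsv(files[[n]], n))
  ex <- do.call(rbind, lapply(mans, function(m)
    exclusions(projectToRank(m, sim$taxonomy, "species"))))
  expect_gt(nrow(ex), 0L)
  expect_true(all(ex$reason == "no_ancestor_at_rank"))
  # the same isolates project fine at genus rank
  exg <- do.call(rbind, lapply(mans, function(m)
    exclusions(projectToRank(m, sim$taxonomy, "genus"))))
  expect_equal(nrow(exg), 0L)
})

test_that("planted composition fractions are recovered at simulation scale", {
  d <- simulationDesign(databases = c("A", "B"), nGenera = 700L,
                        speciesPerGenusLambda = 0.5,
                        partitionType = "cells",
                        partitionCounts = c("A;B" = 1000),
                        compositionFractions = rbind(
                          A = c(0.14, 0.81, 0.05),
                          B = c(0.11, 0.89, 0.00)),
                        seed = 29L)
  sim <- simulateStudy(d, withr::local_tempdir())
  z <- stats::qnorm(0.995)
  for (db in c("A", "B")) {
    m <- readManifestTsv(truthFiles(sim$truth)[[db]], db)
    prof <- compositionProfile(m)
    n <- sum(prof@counts)
    expect_equal(n, 1000L)
    for (cls in names(prof@counts)) {
      p <- plantedFractions(sim$truth)[db, cls]
      if (p == 0) expect_equal(unname(prof@counts[cls]), 0L)
      else expect_lt(abs(prof@counts[cls] - n * p),
                     z * sqrt(n * p * (1 - p)) + 1)
    }
  }
})

test_that("generated contig lengths match the lognormal mean", {
  d <- simulationDesign(databases = c("A", "B"), nGenera = 500L,
                        partitionType = "cells",
                        partitionCounts = c("A" = 400, "B" = 10),
                        compositionFractions = rbind(A = c(0, 1, 0),
                                                     B = c(0, 1, 0)),
                        lengthMeanBp = c(A = 5e5, B = 5e5),
                        contigsPerFragmented = 30, seed = 31L)
  sim <- simulateStudy(d, withr::local_tempdir())
  m <- readManifestTsv(truthFiles(sim$truth)[["A"]], "A")
  st <- contigLengthStats(m)
  expect_gt(st@n, 10000L)
  lens <- sequenceTable(m)$length
  se <- stats::sd(lens) / sqrt(st@n)
  expect_lt(abs(st@meanBp - 5e5), 3 * se)
})

test_that("a partition larger than the species pool is a usage error", {
  d <- simulationDesign(databases = c("A", "B"), nGenera = 2L,
                        partitionCounts = c("1" = 500), seed = 1L)
  out <- generateTaxonomy(d, withr::local_tempdir())
  expect_error(generateDatabases(d, out$registry, withr::local_tempdir()),
               "exceeds")
})
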