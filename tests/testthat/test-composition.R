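test_that("completeness classification follows the role trichotomy", {
  m <- makeManifest("db", c("A", "B", "C", "D", "E", "F"),
                    100:105,
                    list(c("chromosome", "chromosome"),
                         rep("contig", 5),
                         c("chromosome", "contig"),
                         NULL, NULL, c("scaffold", "scaffold")),
                    declared = c(NA, NA, NA, "Chromosome",
                                 "Complete Genome", NA))
  cl <- classifyReferences(m)
  expect_equal(cl$class[cl$accession == "A"], "COMPLETE")
  expect_equal(cl$class[cl$accession == "B"], "FRAGMENTED")
  expect_equal(cl$class[cl$accession == "C"], "MIXED")
  expect_equal(cl$class[cl$accession == "D"], "MIXED")      # declared level
  expect_equal(cl$class[cl$accession == "E"], "COMPLETE")   # declared level
  expect_equal(cl$class[cl$accession == "F"], "FRAGMENTED") # scaffolds=frag
})

test_that("per-sequence roles take precedence over a declared level", {
  m <- makeManifest("db", "A", 100L, list(rep("contig", 3)),
                    declared = "Complete Genome")
  expect_equal(classifyReferences(m)$class, "FRAGMENTED")
})

test_that("classification is exhaustive and exclusive over classifiable records", {
  d <- simulationDesign(databases = c("A", "B"), nGenera = 40L,
                        partitionCounts = c("1" = 30, "2" = 10), seed = 5L)
  sim <- simulateStudy(d, withr::local_tempdir())
  m <- readManifestTsv(truthFiles(sim$truth)[["A"]], "A")
  cl <- classifyReferences(m)
  expect_false(anyNA(cl$class))
  expect_true(all(cl$class %in% c("COMPLETE", "FRAGMENTED", "MIXED")))
  prof <- compositionProfile(m)
  expect_equal(sum(prof@counts), nrow(assemblies(m)))
})

test_that("composition profile computes percentages over classified records", {
  roles <- c(list(c("chromosome", "chromosome")),
             rep(list(rep("contig", 3)), 8),
             list(c("chromosome", "contig")))
  m <- makeManifest("db", sprintf("R%02d", 1:10), 100:109, roles)
  prof <- compositionProfile(m)
  expect_equal(unname(prof@counts), c(1L, 8L, 1L))
  expect_equal(unname(prof@percentages), c(10, 80, 10))
  expect_equal(sum(prof@percentages), 100)
  # boundary: all complete
  m2 <- makeManifest("db", c("R1", "R2"), c(100L, 101L),
                     rep(list("chromosome"), 2))
  expect_equal(unname(compositionProfile(m2)@percentages), c(100, 0, 0))
  # unclassifiable records are counted apart, all-unclassifiable errors
  m3 <- makeManifest("db", c("R1", "R2"), c(100L, 101L),
                     list("contig", NULL))
  p3 <- compositionProfile(m3)
  expect_equal(p3@nUnclassifiable, 1L)
  expect_equal(sum(p3@counts), 1L)
  m4 <- makeManifest("db", "R1", 100L, list(NULL))
  expect_error(compositionProfile(m4), "unclassifiable")
})

test_that("per-taxon aggregation marks a taxon complete if any reference is", {
  m <- makeManifest("db", c("R1", "R2", "R3"), c(100L, 100L, 101L),
                    list("chromosome", rep("contig", 2), "contig"))
  prof <- compositionProfile(m, by = "taxon")
  expect_equal(unname(prof@counts), c(1L, 1L, 0L))  # taxon 100 complete
  expect_equal(unname(prof@percentages), c(50, 50, 0))
})

test_that("contig length statistics cover contigs and scaffolds, not chromosomes", {
  m <- makeManifest("db", c("R1", "R2"), c(100L, 101L),
                    list(c("contig", "contig", "scaffold"),
                         c("chromosome", "contig")),
                    lengths = list(c(100L, 200L, 300L), c(999999L, 400L)))
  st <- contigLengthStats(m)
  expect_equal(st@n, 4L)  # the chromosome in the mixed record is excluded
  expect_equal(st@meanBp, mean(c(100, 200, 300, 400)))
  expect_equal(st@medianBp, 250)
  expect_equal(sum(st@histogram$count), st@n)
  # n + excluded chromosomes account for every sequence considered
  sq <- sequenceTable(m)
  expect_equal(st@n + sum(sq$role == "chromosome"), nrow(sq))
  # degenerate single-contig manifest
  m2 <- makeManifest("db", "R1", 100L, list("contig"),
                     lengths = list(5000L))
  st2 <- contigLengthStats(m2)
  expect_equal(st2@meanBp, 5000)
  expect_equal(st2@medianBp, 5000)
  expect_equal(st2@n, 1L)
  # no qualifying sequences is a usage error
  m3 <- makeManifest("db", "R1", 100L, list(c("chromosome")))
  expect_error(contigLengthStats(m3), "no contig")
})

test_that("explicit histogram breaks are honoured", {
  m <- makeManifest("db", "R1", 100L, list(rep("contig", 4)),
                    lengths = list(c(10L, 20L, 30L, 40L)))
  st <- contigLengthStats(m, breaks = c(0, 25, 50))
  expect_equal(st@histogram$count, c(2L, 2L))
})

test_that("complete-only projection keeps only complete references", {
  tax <- toyTaxonomy()
  nodes <- taxonNodes(tax)
  nodes <- rbind(nodes, data.frame(taxid = 101L, parent = 10L,
                                   rank = "species", name = "sp2"))
  tax2 <- Taxonomy(nodes)
  m <- makeManifest("db", c("R1", "R2", "R3", "R4"),
                    c(100L, 101L, 101L, 101L),
                    list(c("chromosome"), rep("contig", 2),
                         rep("contig", 3), rep("contig", 4)))
  pr <- completeOnlyProjection(m, tax2, "species")
  expect_equal(taxonSet(pr), 100L)
  # no complete records: empty taxon set
  m2 <- makeManifest("db", "R1", 100L, list(rep("contig", 2)))
  expect_length(taxonSet(completeOnlyProjection(m2, tax2, "species")), 0L)
})
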