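test_that("simulate writes a complete, reloadable dataset with truth", {
  d <- simulationDesign(databases = c("A", "B"), nGenera = 20L,
                        partitionCounts = c("2" = 5, "1" = 10), seed = 42L)
  out1 <- withr::local_tempdir()
  sim <- runSimulate(d, out1)
  expect_true(all(file.exists(file.path(out1,
    c("nodes.dmp", "names.dmp", "A.manifest.tsv", "B.manifest.tsv",
      "truth.json")))))
  tax <- loadTaxdump(file.path(out1, "nodes.dmp"),
                     file.path(out1, "names.dmp"))
  expect_s4_class(tax, "Taxonomy")
  expect_s4_class(readManifestTsv(file.path(out1, "A.manifest.tsv"), "A"),
                  "DatabaseManifest")
  truth <- jsonlite::read_json(file.path(out1, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$union_size, 15L)
  expect_equal(truth$metadata$seed, 42L)
  # same seed twice: identical truth JSON
  out2 <- withr::local_tempdir()
  runSimulate(d, out2)
  expect_identical(readLines(file.path(out1, "truth.json")),
                   readLines(file.path(out2, "truth.json")))
})

test_that("profile reports match the manifest composition", {
  roles <- c(list(c("chromosome", "chromosome")),
             rep(list(rep("contig", 3)), 8),
             list(c("chromosome", "contig")))
  m <- makeManifest("db", sprintf("R%02d", 1:10), 100:109, roles)
  f <- withr::local_tempfile(fileext = ".tsv")
  writeManifestTsv(m, f)
  out <- withr::local_tempdir()
  runProfile(f, "db", outDir = out)
  prof <- jsonlite::read_json(file.path(out, "profile.json"),
                              simplifyVector = TRUE)
  expect_equal(prof$percentages$COMPLETE, 10)
  expect_equal(prof$percentages$FRAGMENTED, 80)
  expect_equal(prof$percentages$MIXED, 10)
  expect_equal(sum(unlist(prof$percentages)), 100)
  profTsv <- read.delim(file.path(out, "profile.tsv"))
  expect_equal(profTsv$count, c(1L, 8L, 1L))
  hist <- read.delim(file.path(out, "length_histogram.tsv"))
  expect_equal(sum(hist$count), 25L)  # 24 contigs + 1 in the mixed record
})

test_that("assembly_summary and TSV inputs profile identically", {
  # same catalogue expressed in both dialects
  f1 <- withr::local_tempfile(fileext = ".tsv")
  writeManifestTsv(makeManifest("db", c("G1", "G2", "G3"), 100:102,
                                list(rep("chromosome", 2), rep("contig", 4),
                                     "scaffold")), f1)
  f2 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(paste(c("# assembly_accession", "taxid", "species_taxid",
                       "assembly_level"), collapse = "\t"),
               "G1\t100\t100\tComplete Genome",
               "G2\t101\t101\tContig",
               "G3\t102\t102\tScaffold"), f2)
  o1 <- withr::local_tempdir(); o2 <- withr::local_tempdir()
  runProfile(f1, "db", outDir = o1)
  runProfile(f2, "db", format = "assembly_summary", outDir = o2)
  p1 <- jsonlite::read_json(file.path(o1, "profile.json"))
  p2 <- jsonlite::read_json(file.path(o2, "profile.json"))
  expect_identical(p1$counts, p2$counts)
  expect_identical(p1$percentages, p2$percentages)
})

test_that("comparing a database with itself gives one all-both cell", {
  tax <- toyTaxonomy()
  dir <- withr::local_tempdir()
  writeTestTaxdump(dir, taxid = taxonNodes(tax)$taxid,
                   parent = taxonNodes(tax)$parent,
                   rank = taxonNodes(tax)$rank)
  f <- file.path(dir, "m.tsv")
  writeManifestTsv(makeManifest("x", c("R1", "R2"), c(100L, 1000L),
                                rep(list("contig"), 2)), f)
  out <- withr::local_tempdir()
  res <- runCompare(c(left = f, right = f), dir, rank = "species",
                    outDir = out)
  expect_equal(partitionCells(res$partition), list("left;right" = 100L))
  expect_equal(res$coverage$percent, c(100, 100))
  cov <- jsonlite::read_json(file.path(out, "coverage.json"),
                             simplifyVector = TRUE)
  expect_equal(cov$coverage$percent_rounded, c(100L, 100L))
  # a rank missing from the taxonomy is an error naming the rank
  expect_error(runCompare(c(left = f, right = f), dir, rank = "phylum",
                          outDir = out), "phylum")
})

test_that("complete-only comparison restricts the consensus to complete genomes", {
  dir <- withr::local_tempdir()
  writeTestTaxdump(dir, taxid = c(1L, 10L, 100L, 101L),
                   parent = c(1L, 1L, 10L, 10L),
                   rank = c("no rank", "genus", "species", "species"))
  # both dbs contain species 100 and 101; only db1 has 100 complete,
  # both have 101 complete
  f1 <- file.path(dir, "db1.tsv"); f2 <- file.path(dir, "db2.tsv")
  writeManifestTsv(makeManifest("db1", c("A1", "A2"), c(100L, 101L),
                                list("chromosome", "chromosome")), f1)
  writeManifestTsv(makeManifest("db2", c("B1", "B2"), c(100L, 101L),
                                list("contig", "chromosome")), f2)
  out <- withr::local_tempdir()
  res <- runCompare(c(db1 = f1, db2 = f2), dir, rank = "species",
                    outDir = out, completeOnly = TRUE)
  expect_equal(consensusSet(res$partition), 101L)
  cons <- read.delim(file.path(out, "consensus.tsv"))
  expect_equal(cons$taxid, 101L)
  # without the restriction both species are consensus
  res2 <- runCompare(c(db1 = f1, db2 = f2), dir, rank = "species",
                     outDir = withr::local_tempdir())
  expect_equal(consensusSet(res2$partition), c(100L, 101L))
})

test_that("simulate then compare round-trips the planted exactly-k vector", {
  d <- simulationDesign(databases = c("A", "B", "C"), nGenera = 60L,
                        partitionCounts = c("3" = 8, "2" = 12, "1" = 25),
                        seed = 97L)
  dir <- withr::local_tempdir()
  runSimulate(d, dir)
  out <- withr::local_tempdir()
  res <- runCompare(c(A = file.path(dir, "A.manifest.tsv"),
                      B = file.path(dir, "B.manifest.tsv"),
                      C = file.path(dir, "C.manifest.tsv")),
                    dir, rank = "species", outDir = out)
  ek <- jsonlite::read_json(file.path(out, "exactly_k.json"),
                            simplifyVector = TRUE)
  expect_equal(ek$exactly_k, list("1" = 25L, "2" = 12L, "3" = 8L))
  expect_equal(ek$union_size, 45L)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(ek$exactly_k[order(names(ek$exactly_k))],
               truth$exactly_k[order(names(truth$exactly_k))])
})

test_that("error paths reject unusable inputs with a clear message", {
  expect_error(runProfile("/nonexistent/file.tsv", "db",
                          outDir = withr::local_tempdir()),
               "not found")
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(paste(c("accession", "taxid", "seq_id", "seq_length",
                     "seq_role"), collapse = "\t"), f)
  expect_error(runProfile(f, "db", outDir = withr::local_tempdir()),
               "empty")
  expect_error(runCompare(c(only = f), withr::local_tempdir(),
                          outDir = withr::local_tempdir()),
               ">= 2")
})
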