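reportMetadata <- function(extra = list()) {
  c(list(tool = "dbconcord",
         version = as.character(utils::packageVersion("dbconcord"))),
    extra)
}

writeReportJson <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

readAnyManifest <- function(path, name, format = c("tsv",
                                                   "assembly_summary",
                                                   "fasta"),
                            taxidColumn = "taxid", fastaTaxid = NA) {
  format <- match.arg(format)
  switch(format,
         tsv = readManifestTsv(path, name),
         assembly_summary = readAssemblySummary(path, name, taxidColumn),
         fasta = scanFastaComposition(path, accession = name,
                                      taxid = fastaTaxid, name = name))
}

#' Profile the composition of one database
#'
#' Classifies every reference of one catalogue, writes the composition
#' profile (JSON and TSV), the contig/scaffold length statistics and
#' histogram (TSV), and the list of unclassifiable records. Length files
#' are only written when the catalogue carries per-sequence information.
#'
#' @param path manifest path.
#' @param name database label.
#' @param format one of `"tsv"`, `"assembly_summary"`, `"fasta"`.
#' @param outDir output directory, created if needed.
#' @param by aggregation unit for percentages; see [compositionProfile()].
#' @param nBins histogram bins; see [contigLengthStats()].
#' @param taxidColumn passed to [readAssemblySummary()].
#' @param fastaTaxid taxid for a FASTA input.
#' @return invisibly, a list with the profile, length stats (or NULL) and
#'   the written file paths.
#' @export
runProfile <- function(path, name, format = "tsv", outDir,
                       by = "reference", nBins = 50L,
                       taxidColumn = "taxid", fastaTaxid = NA) {
  m <- readAnyManifest(path, name, format, taxidColumn, fastaTaxid)
  if (!nrow(assemblies(m)))
    stop(sprintf("manifest %s is empty", path), call. = FALSE)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  prof <- compositionProfile(m, by = by)
  cl <- classifyReferences(m)

  profDf <- data.frame(class = COMPLETENESS_CLASSES,
                       count = unname(prof@counts),
                       percent = unname(prof@percentages),
                       stringsAsFactors = FALSE)
  data.table::fwrite(profDf, file.path(outDir, "profile.tsv"), sep = "\t")
  writeReportJson(list(
    metadata = reportMetadata(list(database = name, by = by)),
    counts = as.list(prof@counts),
    percentages = as.list(prof@percentages),
    n_unclassifiable = prof@nUnclassifiable),
    file.path(outDir, "profile.json"))

  un <- cl[is.na(cl$class), c("accession", "taxid"), drop = FALSE]
  data.table::fwrite(un, file.path(outDir, "unclassified.tsv"), sep = "\t")

  stats <- NULL
  hasFragSeq <- any(sequenceTable(m)$role %in% c("contig", "scaffold"))
  if (hasFragSeq) {
    stats <- contigLengthStats(m, nBins = nBins)
    data.table::fwrite(
      data.frame(n = stats@n, mean_bp = stats@meanBp,
                 median_bp = stats@medianBp, q25_bp = stats@q25,
                 q75_bp = stats@q75, min_bp = stats@minBp,
                 max_bp = stats@maxBp),
      file.path(outDir, "length_stats.tsv"), sep = "\t")
    data.table::fwrite(stats@histogram,
                       file.path(outDir, "length_histogram.tsv"),
                       sep = "\t")
  }
  invisible(list(profile = prof, lengthStats = stats,
                 files = list.files(outDir, full.names = TRUE)))
}

#' Compare databases at a taxonomic rank
#'
#' Harmonizes each catalogue to the requested rank against the taxonomy,
#' computes the overlap partition, and writes: the partition table
#' (`partition.tsv`), exactly-k counts (`exactly_k.json`), per-database
#' coverage (`coverage.json`), the consensus taxon list
#' (`consensus.tsv`, with scientific names) and the exclusion report
#' (`exclusions.tsv`). With `completeOnly = TRUE` only references
#' classified COMPLETE enter the comparison.
#'
#' @param manifests named character vector of manifest paths (names are
#'   the database labels; >= 2).
#' @param taxdumpDir directory holding nodes.dmp/names.dmp (and optionally
#'   merged.dmp/delnodes.dmp).
#' @param rank projection rank; must occur in the taxonomy.
#' @param outDir output directory.
#' @param completeOnly restrict to complete genomes.
#' @param formats per-manifest formats, recycled; see [runProfile()].
#' @return invisibly, a list with the partition, projections, coverage and
#'   written files.
#' @export
runCompare <- function(manifests, taxdumpDir, rank = "species", outDir,
                       completeOnly = FALSE, formats = "tsv") {
  if (length(manifests) < 2L || is.null(names(manifests)))
    stop("runCompare needs >= 2 named manifest paths", call. = FALSE)
  optional <- function(f) if (file.exists(f)) f else NULL
  tax <- loadTaxdump(file.path(taxdumpDir, "nodes.dmp"),
                     file.path(taxdumpDir, "names.dmp"),
                     optional(file.path(taxdumpDir, "merged.dmp")),
                     optional(file.path(taxdumpDir, "delnodes.dmp")))
  ranks <- tolower(trimws(taxonNodes(tax)$rank))
  if (!tolower(trimws(rank)) %in% ranks)
    stop(sprintf("rank '%s' does not occur in the taxonomy", rank),
         call. = FALSE)
  formats <- rep_len(formats, length(manifests))
  projections <- vector("list", length(manifests))
  for (i in seq_along(manifests)) {
    m <- readAnyManifest(manifests[[i]], names(manifests)[i], formats[[i]])
    projections[[i]] <- if (completeOnly)
      completeOnlyProjection(m, tax, rank) else projectToRank(m, tax, rank)
  }
  p <- vennPartition(projections)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)

  data.table::fwrite(partitionTable(p, members = TRUE),
                     file.path(outDir, "partition.tsv"), sep = "\t")
  meta <- reportMetadata(list(rank = rank,
                              databases = names(manifests),
                              complete_only = completeOnly))
  writeReportJson(list(metadata = meta,
                       union_size = p@unionSize,
                       exactly_k = as.list(exactlyKCounts(p))),
                  file.path(outDir, "exactly_k.json"))
  cov <- coveragePercent(p)
  writeReportJson(list(metadata = meta,
                       coverage = lapply(seq_len(nrow(cov)), function(i)
                         list(database = cov$database[i],
                              percent = cov$percent[i],
                              percent_rounded = cov$percent_rounded[i]))),
                  file.path(outDir, "coverage.json"))
  cons <- consensusSet(p)
  nd <- taxonNodes(tax)
  data.table::fwrite(
    data.frame(taxid = cons, name = nd$name[match(cons, nd$taxid)],
               stringsAsFactors = FALSE),
    file.path(outDir, "consensus.tsv"), sep = "\t")
  excl <- do.call(rbind, lapply(projections, function(pr) {
    ex <- exclusions(pr)
    if (nrow(ex)) cbind(database = pr@database, ex)
    else data.frame(database = character(0), accession = character(0),
                    taxid = integer(0), reason = character(0))
  }))
  data.table::fwrite(excl, file.path(outDir, "exclusions.tsv"), sep = "\t")

  invisible(list(partition = p, projections = projections, coverage = cov,
                 files = list.files(outDir, full.names = TRUE)))
}

#' Emit a synthetic study and its ground truth
#'
#' Runs [simulateStudy()] and serializes the planted truth as
#' `truth.json` (partition cells, exactly-k counts, composition fractions,
#' length means, seed) next to the taxdump and manifest files.
#'
#' @param design a [SimulationDesign-class].
#' @param outDir output directory.
#' @return invisibly, the [simulateStudy()] result.
#' @export
runSimulate <- function(design, outDir) {
  sim <- simulateStudy(design, outDir)
  truth <- sim$truth
  p <- plantedPartition(truth)
  writeReportJson(list(
    metadata = reportMetadata(list(seed = truth@seed,
                                   databases = p@databases)),
    union_size = p@unionSize,
    cells = lapply(p@cells, identity),
    exactly_k = as.list(exactlyKCounts(p)),
    composition_fractions = apply(plantedFractions(truth), 1L, as.list,
                                  simplify = FALSE),
    length_mean_bp = as.list(plantedLengthMeanBp(truth))),
    file.path(outDir, "truth.json"))
  invisible(sim)
}
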