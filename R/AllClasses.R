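#' @import methods
NULL

## Controlled vocabularies used across the package.
COMPLETENESS_CLASSES <- c("COMPLETE", "FRAGMENTED", "MIXED")
SEQ_ROLES <- c("chromosome", "contig", "scaffold")
ASSEMBLY_LEVELS <- c("Complete Genome", "Chromosome", "Scaffold", "Contig")
EXCLUSION_REASONS <- c("unknown_taxid", "deleted_taxid", "no_ancestor_at_rank")

#' Taxonomy: an NCBI-style taxonomic node graph
#'
#' Holds the node table parsed from a taxdump (`taxid`, `parent`, `rank`,
#' `name`), the transitively resolved merged-id map, and the deleted-id set.
#' The root node is the unique node whose parent is itself; every other
#' node's parent must exist and parent chains must be acyclic.
#'
#' @slot nodes data.frame with integer `taxid`, integer `parent`, character
#'   `rank` and character `name` columns; one row per node.
#' @slot merged named integer vector mapping old taxids (names, as decimal
#'   strings) to their canonical replacement taxids.
#' @slot deleted integer vector of withdrawn taxids.
#'
#' @seealso [loadTaxdump()], [resolveTaxid()], [ancestorAtRank()]
#' @exportClass Taxonomy
setClass("Taxonomy",
  representation(nodes = "data.frame", merged = "integer", deleted = "integer"))

setValidity("Taxonomy", function(object) {
  nd <- object@nodes
  req <- c("taxid", "parent", "rank", "name")
  if (!all(req %in% names(nd)))
    return(sprintf("nodes must have columns %s", paste(req, collapse = ", ")))
  if (nrow(nd) == 0L) return("taxonomy has no nodes")
  if (!is.integer(nd$taxid) || !is.integer(nd$parent))
    return("taxid and parent must be integer")
  if (any(nd$taxid <= 0L)) return("taxids must be positive")
  if (anyDuplicated(nd$taxid))
    return(sprintf("duplicated taxid %d", nd$taxid[duplicated(nd$taxid)][1L]))
  if (any(!nzchar(nd$rank))) return("rank labels must be non-empty")
  root <- nd$taxid[nd$taxid == nd$parent]
  if (length(root) != 1L)
    return("taxonomy must have exactly one root (parent == taxid)")
  dangling <- !(nd$parent %in% nd$taxid)
  if (any(dangling))
    return(sprintf("node %d has dangling parent %d",
                   nd$taxid[dangling][1L], nd$parent[dangling][1L]))
  ## Acyclicity: every node must be reachable from the root following
  ## child edges (parents all exist, so unreachable => cycle).
  kids <- split(nd$taxid, nd$parent)
  seen <- new.env(hash = TRUE, size = nrow(nd))
  queue <- root
  assign(as.character(root), TRUE, envir = seen)
  while (length(queue)) {
    ch <- unlist(kids[as.character(queue)], use.names = FALSE)
    ch <- setdiff(ch, root)
    ch <- ch[!vapply(as.character(ch), exists, logical(1), envir = seen,
                     inherits = FALSE)]
    for (x in as.character(ch)) assign(x, TRUE, envir = seen)
    queue <- ch
  }
  if (length(ls(seen)) != nrow(nd)) {
    off <- setdiff(nd$taxid, as.integer(ls(seen)))[1L]
    return(sprintf("cyclic parent chain involving taxid %d", off))
  }
  mkeys <- suppressWarnings(as.integer(names(object@merged)))
  if (length(object@merged)) {
    if (anyNA(mkeys)) return("merged map names must be integer taxids")
    if (any(mkeys %in% nd$taxid))
      return(sprintf("merged taxid %d also present in nodes",
                     mkeys[mkeys %in% nd$taxid][1L]))
    bad <- !(object@merged %in% nd$taxid)
    if (any(bad))
      return(sprintf("merged target %d not present in nodes",
                     object@merged[bad][1L]))
  }
  if (length(object@deleted)) {
    if (any(object@deleted %in% nd$taxid))
      return("deleted taxids overlap node taxids")
    if (any(object@deleted %in% mkeys))
      return("deleted taxids overlap merged taxids")
  }
  TRUE
})

#' Construct a Taxonomy from its components
#'
#' @param nodes data.frame with columns `taxid`, `parent`, `rank`, `name`.
#' @param merged named integer vector (old taxid as name, new taxid as value);
#'   chains are resolved transitively before storage.
#' @param deleted integer vector of withdrawn taxids.
#' @return A [Taxonomy-class] object.
#' @export
Taxonomy <- function(nodes, merged = integer(0), deleted = integer(0)) {
  nodes$taxid <- as.integer(nodes$taxid)
  nodes$parent <- as.integer(nodes$parent)
  nodes$rank <- as.character(nodes$rank)
  nodes$name <- as.character(nodes$name)
  rownames(nodes) <- NULL
  merged <- resolveMergedChains(as.integer(merged), names(merged))
  new("Taxonomy", nodes = nodes, merged = merged,
      deleted = as.integer(deleted))
}

## Follow merged chains (a -> b, b -> c becomes a -> c, b -> c).  A cycle in
## the map is a structural defect of the dump and is reported as such.
resolveMergedChains <- function(targets, keys) {
  if (!length(targets)) return(setNames(integer(0), character(0)))
  merged <- setNames(targets, keys)
  res <- merged
  for (i in seq_len(length(merged) + 1L)) {
    idx <- match(as.character(res), names(merged))
    hit <- !is.na(idx) & merged[idx] != res   # self-maps would spin forever
    if (!any(hit)) return(res)
    if (i > length(merged))
      stop("cycle detected in merged taxid map", call. = FALSE)
    res[hit] <- unname(merged[idx[hit]])
  }
  stop("cycle detected in merged taxid map", call. = FALSE)
}

#' DatabaseManifest: one database's reference catalogue
#'
#' A catalogue is stored as two tables: `assemblies` (one row per reference:
#' `accession`, `taxid`, optional `declared_level`) and `sequences` (one row
#' per sequence of a reference: `accession`, `seq_id`, `length`, `role`).
#' A reference may carry explicit sequences, a declared assembly level
#' (as in NCBI assembly_summary files), or both.
#'
#' @slot name database label.
#' @slot assemblies data.frame of references.
#' @slot sequences data.frame of per-sequence rows.
#' @exportClass DatabaseManifest
setClass("DatabaseManifest",
  representation(name = "character", assemblies = "data.frame",
                 sequences = "data.frame"))

setValidity("DatabaseManifest", function(object) {
  if (length(object@name) != 1L || !nzchar(object@name))
    return("manifest name must be a non-empty string")
  a <- object@assemblies
  s <- object@sequences
  if (!all(c("accession", "taxid", "declared_level") %in% names(a)))
    return("assemblies needs columns accession, taxid, declared_level")
  if (!all(c("accession", "seq_id", "length", "role") %in% names(s)))
    return("sequences needs columns accession, seq_id, length, role")
  if (nrow(a)) {
    if (any(!nzchar(a$accession))) return("empty accession")
    if (anyDuplicated(a$accession))
      return(sprintf("duplicate accession %s",
                     a$accession[duplicated(a$accession)][1L]))
    if (any(a$taxid <= 0L)) return("taxids must be positive")
    lev <- a$declared_level[!is.na(a$declared_level)]
    if (length(lev) && !all(lev %in% ASSEMBLY_LEVELS))
      return(sprintf("unknown declared_level '%s'",
                     setdiff(lev, ASSEMBLY_LEVELS)[1L]))
  }
  if (nrow(s)) {
    if (!all(s$accession %in% a$accession))
      return("sequence rows reference unknown accessions")
    if (!all(s$role %in% SEQ_ROLES))
      return(sprintf("unknown sequence role '%s'",
                     setdiff(s$role, SEQ_ROLES)[1L]))
    if (any(s$length < 0L)) return("sequence lengths must be >= 0")
    key <- paste(s$accession, s$seq_id, sep = "\r")
    if (anyDuplicated(key))
      return(sprintf("duplicate (accession, seq_id) pair: %s",
                     gsub("\r", "/", key[duplicated(key)][1L])))
  }
  TRUE
})

#' Construct a DatabaseManifest
#'
#' @param name database label.
#' @param assemblies data.frame with columns `accession`, `taxid` and
#'   optionally `declared_level` (NA where absent).
#' @param sequences data.frame with columns `accession`, `seq_id`, `length`,
#'   `role`; may be empty.
#' @return A [DatabaseManifest-class] object.
#' @export
DatabaseManifest <- function(name, assemblies,
                             sequences = emptySequenceTable()) {
  if (is.null(assemblies$declared_level))
    assemblies$declared_level <- NA_character_
  assemblies <- data.frame(
    accession = as.character(assemblies$accession),
    taxid = as.integer(assemblies$taxid),
    declared_level = as.character(assemblies$declared_level),
    stringsAsFactors = FALSE)
  sequences <- data.frame(
    accession = as.character(sequences$accession),
    seq_id = as.character(sequences$seq_id),
    length = as.integer(sequences$length),
    role = as.character(sequences$role),
    stringsAsFactors = FALSE)
  new("DatabaseManifest", name = name, assemblies = assemblies,
      sequences = sequences)
}

emptySequenceTable <- function() {
  data.frame(accession = character(0), seq_id = character(0),
             length = integer(0), role = character(0),
             stringsAsFactors = FALSE)
}

emptyAssemblyTable <- function() {
  data.frame(accession = character(0), taxid = integer(0),
             declared_level = character(0), stringsAsFactors = FALSE)
}

#' RankProjection: a database harmonized to one taxonomic rank
#'
#' The taxon set of a database after resolving each reference's taxid
#' (merged ids applied transitively) and projecting it to the requested
#' rank, together with the exclusion report for references that could not
#' be projected (unknown taxid, deleted taxid, or no ancestor at the rank —
#' the strain/isolate ambiguity case).
#'
#' @slot database database label.
#' @slot rank the projection rank (e.g. "species", "genus").
#' @slot taxa sorted integer vector of canonical taxids at the rank.
#' @slot exclusions data.frame with columns `accession`, `taxid`, `reason`.
#' @exportClass RankProjection
setClass("RankProjection",
  representation(database = "character", rank = "character",
                 taxa = "integer", exclusions = "data.frame"))

setValidity("RankProjection", function(object) {
  if (anyDuplicated(object@taxa)) return("taxon set contains duplicates")
  if (is.unsorted(object@taxa)) return("taxon set must be sorted")
  ex <- object@exclusions
  if (!all(c("accession", "taxid", "reason") %in% names(ex)))
    return("exclusions needs columns accession, taxid, reason")
  if (nrow(ex) && !all(ex$reason %in% EXCLUSION_REASONS))
    return(sprintf("unknown exclusion reason '%s'",
                   setdiff(ex$reason, EXCLUSION_REASONS)[1L]))
  TRUE
})

#' OverlapPartition: the N-set Venn partition of a taxon union
#'
#' Every taxid in the union of N database taxon sets is assigned to the
#' unique cell keyed by the exact subset of databases containing it. Cell
#' keys are semicolon-joined database labels in canonical (input) order.
#'
#' @slot databases ordered character vector of the N database labels.
#' @slot cells named list; each element an integer vector of taxids, named
#'   by the subset key.
#' @slot unionSize total number of distinct taxids across all cells.
#' @exportClass OverlapPartition
setClass("OverlapPartition",
  representation(databases = "character", cells = "list",
                 unionSize = "integer"))

setValidity("OverlapPartition", function(object) {
  if (length(object@databases) < 2L) return("need at least 2 databases")
  if (anyDuplicated(object@databases)) return("database labels must be unique")
  members <- unlist(object@cells, use.names = FALSE)
  if (anyDuplicated(members)) return("cells are not pairwise disjoint")
  if (length(members) != object@unionSize)
    return("cell sizes do not sum to unionSize")
  for (key in names(object@cells)) {
    labs <- strsplit(key, ";", fixed = TRUE)[[1L]]
    if (!length(labs) || !all(labs %in% object@databases))
      return(sprintf("cell key '%s' uses unknown labels", key))
    if (!identical(labs, object@databases[object@databases %in% labs]))
      return(sprintf("cell key '%s' not in canonical database order", key))
  }
  TRUE
})

#' CompositionProfile: completeness composition of one database
#'
#' Counts and percentages of references classified COMPLETE (all
#' chromosomes), FRAGMENTED (no chromosomes) or MIXED (both), percentages
#' taken over classified references only.
#'
#' @slot database database label.
#' @slot by aggregation unit: "reference" or "taxon".
#' @slot counts named integer vector over the three classes.
#' @slot percentages named numeric vector over the three classes.
#' @slot nUnclassifiable number of records with neither sequences nor a
#'   declared assembly level.
#' @exportClass CompositionProfile
setClass("CompositionProfile",
  representation(database = "character", by = "character",
                 counts = "integer", percentages = "numeric",
                 nUnclassifiable = "integer"))

setValidity("CompositionProfile", function(object) {
  if (!identical(names(object@counts), COMPLETENESS_CLASSES))
    return("counts must be named COMPLETE, FRAGMENTED, MIXED")
  if (!identical(names(object@percentages), COMPLETENESS_CLASSES))
    return("percentages must be named COMPLETE, FRAGMENTED, MIXED")
  if (any(object@counts < 0L)) return("negative count")
  if (sum(object@counts) > 0L &&
      abs(sum(object@percentages) - 100) > 1.5)
    return("percentages do not sum to 100 within rounding")
  TRUE
})

#' LengthStats: contig/scaffold length distribution summary
#'
#' @slot database database label.
#' @slot n number of contig and scaffold sequences summarized.
#' @slot meanBp arithmetic mean length in bp.
#' @slot medianBp median length in bp.
#' @slot q25 first quartile (bp).
#' @slot q75 third quartile (bp).
#' @slot minBp,maxBp observed range (bp).
#' @slot histogram data.frame with columns `bin_lo`, `bin_hi`, `count`.
#' @exportClass LengthStats
setClass("LengthStats",
  representation(database = "character", n = "integer", meanBp = "numeric",
                 medianBp = "numeric", q25 = "numeric", q75 = "numeric",
                 minBp = "numeric", maxBp = "numeric",
                 histogram = "data.frame"))

setValidity("LengthStats", function(object) {
  if (object@n != sum(object@histogram$count))
    return("histogram counts do not sum to n")
  if (object@meanBp < object@minBp || object@meanBp > object@maxBp)
    return("mean outside observed range")
  TRUE
})

#' SimulationDesign: parameters of the synthetic catalogue generator
#'
#' Defaults emulate the fungal study conditions: four databases, the
#' published exactly-k species partition, per-database completeness
#' fractions and lognormal contig length means. See the methods vignette
#' for the rationale behind the unpublished parameters.
#'
#' @exportClass SimulationDesign
setClass("SimulationDesign",
  representation(databases = "character", nGenera = "integer",
                 speciesPerGenusLambda = "numeric",
                 strainsPerSpeciesLambda = "numeric",
                 partitionType = "character", partitionCounts = "numeric",
                 compositionFractions = "matrix",
                 contigsPerFragmented = "numeric",
                 chromosomesPerComplete = "numeric",
                 lengthMeanBp = "numeric", lengthLogSd = "numeric",
                 scaffoldFraction = "numeric",
                 strainRank = "character",
                 strainEmissionFraction = "numeric",
                 mergedFraction = "numeric", isolateFraction = "numeric",
                 seed = "integer"))

setValidity("SimulationDesign", function(object) {
  nd <- length(object@databases)
  if (nd < 2L) return("need at least 2 databases")
  if (anyDuplicated(object@databases)) return("database labels must be unique")
  if (object@nGenera < 1L) return("nGenera must be >= 1")
  if (!object@partitionType %in% c("exactly_k", "cells"))
    return("partitionType must be 'exactly_k' or 'cells'")
  if (any(object@partitionCounts < 0)) return("partition counts must be >= 0")
  if (object@partitionType == "exactly_k") {
    ks <- suppressWarnings(as.integer(names(object@partitionCounts)))
    if (anyNA(ks) || any(ks < 1L | ks > nd))
      return("exactly_k counts must be named by k in 1..N")
  }
  cf <- object@compositionFractions
  if (!identical(rownames(cf), object@databases) ||
      !identical(colnames(cf), COMPLETENESS_CLASSES))
    return("compositionFractions must be databases x classes")
  if (any(cf < 0) || any(abs(rowSums(cf) - 1) > 1e-8))
    return("composition fractions must be >= 0 and sum to 1 per database")
  if (!identical(names(object@lengthMeanBp), object@databases))
    return("lengthMeanBp must be named by database")
  if (any(object@lengthMeanBp <= 0)) return("length means must be positive")
  fr <- c(object@strainEmissionFraction, object@mergedFraction,
          object@isolateFraction, object@scaffoldFraction)
  if (any(fr < 0 | fr > 1)) return("fractions must lie in [0, 1]")
  TRUE
})

#' SyntheticTruth: planted ground truth returned by the generator
#'
#' @slot plantedPartition the planted [OverlapPartition-class] over species
#'   taxids.
#' @slot plantedFractions databases x classes matrix of planted completeness
#'   fractions.
#' @slot plantedLengthMeanBp per-database expected contig length (bp).
#' @slot files named character vector of emitted file paths.
#' @slot seed the generator seed.
#' @exportClass SyntheticTruth
setClass("SyntheticTruth",
  representation(plantedPartition = "OverlapPartition",
                 plantedFractions = "matrix",
                 plantedLengthMeanBp = "numeric",
                 files = "character", seed = "integer"))

## ---- show methods -------------------------------------------------------

setMethod("show", "Taxonomy", function(object) {
  cat(sprintf("Taxonomy: %d nodes (%d ranks), %d merged ids, %d deleted ids\n",
              nrow(object@nodes), length(unique(object@nodes$rank)),
              length(object@merged), length(object@deleted)))
  tab <- sort(table(object@nodes$rank), decreasing = TRUE)
  cat("  ranks:", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "),
      "\n")
})

setMethod("show", "DatabaseManifest", function(object) {
  cat(sprintf("DatabaseManifest '%s': %d references, %d sequence rows\n",
              object@name, nrow(object@assemblies), nrow(object@sequences)))
})

setMethod("show", "RankProjection", function(object) {
  cat(sprintf("RankProjection '%s' at rank '%s': %d taxa, %d exclusions\n",
              object@database, object@rank, length(object@taxa),
              nrow(object@exclusions)))
})

setMethod("show", "OverlapPartition", function(object) {
  cat(sprintf("OverlapPartition over %d databases (%s): union %d taxa, %d occupied cells\n",
              length(object@databases),
              paste(object@databases, collapse = ", "),
              object@unionSize, sum(lengths(object@cells) > 0)))
})

setMethod("show", "CompositionProfile", function(object) {
  cat(sprintf("CompositionProfile '%s' (per %s): %s; %d unclassifiable\n",
              object@database, object@by,
              paste(sprintf("%s %.1f%%", names(object@percentages),
                            object@percentages), collapse = ", "),
              object@nUnclassifiable))
})

setMethod("show", "LengthStats", function(object) {
  cat(sprintf("LengthStats '%s': n = %d, mean = %.0f bp, median = %.0f bp [%.0f, %.0f]\n",
              object@database, object@n, object@meanBp, object@medianBp,
              object@minBp, object@maxBp))
})

setMethod("show", "SimulationDesign", function(object) {
  cat(sprintf("SimulationDesign: %d databases (%s), %d genera, seed %d\n",
              length(object@databases),
              paste(object@databases, collapse = ", "),
              object@nGenera, object@seed))
  cat(sprintf("  partition (%s): %s\n", object@partitionType,
              paste(sprintf("%s:%g", names(object@partitionCounts),
                            object@partitionCounts), collapse = " ")))
})

setMethod("show", "SyntheticTruth", function(object) {
  cat(sprintf("SyntheticTruth: planted union %d taxa across %d databases, seed %d\n",
              object@plantedPartition@unionSize,
              length(object@plantedPartition@databases), object@seed))
})
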