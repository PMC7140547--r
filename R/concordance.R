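#' Harmonize a catalogue to a taxonomic rank
#'
#' Resolves every reference taxid (applying merged ids transitively) and
#' projects it to the requested rank via [ancestorAtRank()]. References
#' whose taxid is deleted or unknown, or whose lineage contains no node at
#' the rank (the strain/isolate ambiguity), are excluded with a reason;
#' everything else contributes to the taxon set, duplicates collapsing
#' under set semantics. Strains thereby fold into their species: strain-
#' versus-species differences between catalogues disappear at this step.
#'
#' @param m a [DatabaseManifest-class].
#' @param tax a [Taxonomy-class].
#' @param rank rank label (e.g. "species", "genus").
#' @return A [RankProjection-class].
#' @export
projectToRank <- function(m, tax, rank) {
  stopifnot(is(m, "DatabaseManifest"), is(tax, "Taxonomy"),
            length(rank) == 1L, nzchar(rank))
  asm <- m@assemblies
  if (!nrow(asm)) {
    return(new("RankProjection", database = m@name, rank = rank,
               taxa = integer(0),
               exclusions = data.frame(accession = character(0),
                                       taxid = integer(0),
                                       reason = character(0),
                                       stringsAsFactors = FALSE)))
  }
  res <- resolveTaxid(tax, asm$taxid)
  reason <- rep(NA_character_, nrow(asm))
  reason[res$status == "deleted"] <- "deleted_taxid"
  reason[res$status == "unknown"] <- "unknown_taxid"
  ok <- is.na(reason)
  anc <- rep(NA_integer_, nrow(asm))
  if (any(ok)) anc[ok] <- ancestorAtRank(tax, res$canonical_taxid[ok], rank)
  reason[ok & is.na(anc)] <- "no_ancestor_at_rank"
  excluded <- !is.na(reason)
  new("RankProjection", database = m@name, rank = rank,
      taxa = sort(unique(anc[!excluded])),
      exclusions = data.frame(accession = asm$accession[excluded],
                              taxid = asm$taxid[excluded],
                              reason = reason[excluded],
                              stringsAsFactors = FALSE))
}

asNamedSets <- function(x) {
  if (is.list(x) && length(x) &&
      all(vapply(x, is, logical(1), "RankProjection"))) {
    sets <- lapply(x, taxonSet)
    names(sets) <- vapply(x, function(p) p@database, character(1))
    return(sets)
  }
  x
}

#' Partition a taxon union by database membership
#'
#' Assigns every taxid in the union of the input sets to the unique cell
#' keyed by the exact subset of databases containing it — the N-set Venn
#' (UpSet) partition. Cell keys are semicolon-joined labels in input order,
#' so output is deterministic.
#'
#' @param sets either a named list of integer taxid vectors (>= 2, unique
#'   labels) or a list of [RankProjection-class] objects (labels taken from
#'   their database slots).
#' @return An [OverlapPartition-class].
#' @examples
#' p <- vennPartition(list(A = c(1, 2, 3), B = c(2, 3, 4), C = c(3, 4, 5)))
#' exactlyKCounts(p)
#' consensusSet(p)
#' @export
vennPartition <- function(sets) {
  sets <- asNamedSets(sets)
  if (!is.list(sets) || length(sets) < 2L)
    stop("vennPartition needs at least 2 named sets", call. = FALSE)
  labels <- names(sets)
  if (is.null(labels) || any(!nzchar(labels)) || anyDuplicated(labels))
    stop("set labels must be present and unique", call. = FALSE)
  sets <- lapply(sets, function(s) unique(as.integer(s)))
  un <- sort(unique(unlist(sets, use.names = FALSE)))
  membership <- vapply(sets, function(s) un %in% s,
                       logical(length(un)))
  if (length(un) == 1L) membership <- matrix(membership, nrow = 1L)
  key <- apply(membership, 1L, function(row)
    paste(labels[row], collapse = ";"))
  cells <- split(un, key)
  new("OverlapPartition", databases = labels, cells = as.list(cells),
      unionSize = length(un))
}

#' Aggregate a partition into exactly-k counts
#'
#' `count[k]` is the number of taxa present in exactly k of the N
#' databases; the counts sum to the union size.
#'
#' @param p an [OverlapPartition-class].
#' @return named integer vector over k = 1..N.
#' @export
exactlyKCounts <- function(p) {
  stopifnot(is(p, "OverlapPartition"))
  n <- length(p@databases)
  k <- lengths(strsplit(names(p@cells), ";", fixed = TRUE))
  out <- setNames(integer(n), as.character(seq_len(n)))
  if (length(k)) {
    agg <- tapply(lengths(p@cells), k, sum)
    out[names(agg)] <- as.integer(agg)
  }
  out
}

#' Per-database coverage of the taxon union
#'
#' Coverage of a database is the share of the N-database union it
#' contains. Both the unrounded percentage and the nearest-integer percent
#' are reported.
#'
#' @param p an [OverlapPartition-class] with non-empty union.
#' @return data.frame with columns `database`, `percent`,
#'   `percent_rounded`.
#' @export
coveragePercent <- function(p) {
  stopifnot(is(p, "OverlapPartition"))
  if (p@unionSize == 0L)
    stop("coverage is undefined for an empty union", call. = FALSE)
  keyLabs <- strsplit(names(p@cells), ";", fixed = TRUE)
  sizes <- lengths(p@cells)
  pct <- vapply(p@databases, function(d)
    100 * sum(sizes[vapply(keyLabs, function(l) d %in% l, logical(1))]) /
      p@unionSize, numeric(1))
  data.frame(database = p@databases, percent = unname(pct),
             percent_rounded = as.integer(round(unname(pct))),
             stringsAsFactors = FALSE)
}

#' Taxa shared by all databases
#'
#' Returns the cell keyed by the full database set — the consensus taxa
#' present in every catalogue — or an empty vector when no taxon is shared
#' by all N.
#'
#' @param p an [OverlapPartition-class].
#' @return integer vector of taxids.
#' @export
consensusSet <- function(p) {
  stopifnot(is(p, "OverlapPartition"))
  cell <- p@cells[[paste(p@databases, collapse = ";")]]
  if (is.null(cell)) integer(0) else cell
}

#' Tabulate a partition as one row per cell
#'
#' @param p an [OverlapPartition-class].
#' @param members include a semicolon-joined member-taxid column.
#' @return data.frame with columns `subset`, `n_databases`, `count` and
#'   optionally `members`, ordered by decreasing subset size then key.
#' @export
partitionTable <- function(p, members = FALSE) {
  stopifnot(is(p, "OverlapPartition"))
  keys <- names(p@cells)
  k <- lengths(strsplit(keys, ";", fixed = TRUE))
  ord <- order(-k, keys)
  out <- data.frame(subset = keys[ord], n_databases = k[ord],
                    count = unname(lengths(p@cells)[ord]),
                    stringsAsFactors = FALSE)
  if (members)
    out$members <- vapply(p@cells[ord], paste, character(1), collapse = ";")
  out
}
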