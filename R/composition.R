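#' Classify references as complete, fragmented or mixed
#'
#' A reference with explicit sequences is COMPLETE when every sequence is a
#' chromosome, FRAGMENTED when none is, and MIXED when both chromosomes and
#' contigs/scaffolds are present (scaffolds count with contigs). Without
#' sequences the declared assembly level decides: "Complete Genome" ->
#' COMPLETE, "Chromosome" -> MIXED, "Scaffold"/"Contig" -> FRAGMENTED.
#' Per-sequence roles take precedence over a declared level.
#'
#' @param m a [DatabaseManifest-class].
#' @return data.frame with columns `accession`, `taxid`, `class`; `class`
#'   is NA for records with neither sequences nor a declared level
#'   (unclassifiable).
#' @export
classifyReferences <- function(m) {
  stopifnot(is(m, "DatabaseManifest"))
  asm <- m@assemblies
  sq <- m@sequences
  cls <- rep(NA_character_, nrow(asm))
  if (nrow(sq)) {
    anyChrom <- tapply(sq$role == "chromosome", sq$accession, any)
    anyFrag <- tapply(sq$role != "chromosome", sq$accession, any)
    i <- match(asm$accession, names(anyChrom))
    hasSeq <- !is.na(i)
    cls[hasSeq] <- ifelse(anyChrom[i[hasSeq]] & anyFrag[i[hasSeq]], "MIXED",
                          ifelse(anyChrom[i[hasSeq]], "COMPLETE",
                                 "FRAGMENTED"))
  }
  useLevel <- is.na(cls) & !is.na(asm$declared_level)
  levelMap <- c("Complete Genome" = "COMPLETE", "Chromosome" = "MIXED",
                "Scaffold" = "FRAGMENTED", "Contig" = "FRAGMENTED")
  cls[useLevel] <- unname(levelMap[asm$declared_level[useLevel]])
  data.frame(accession = asm$accession, taxid = asm$taxid, class = cls,
             stringsAsFactors = FALSE)
}

#' Completeness composition of a database
#'
#' Counts and percentages of COMPLETE / FRAGMENTED / MIXED references;
#' percentages are taken over classified references only, unclassifiable
#' records being counted separately. With `by = "taxon"` the unit is the
#' taxid instead of the reference: a taxon is COMPLETE when any of its
#' references is complete, otherwise MIXED when any reference is mixed,
#' otherwise FRAGMENTED.
#'
#' @param m a [DatabaseManifest-class] with at least one record.
#' @param by aggregation unit, `"reference"` (default) or `"taxon"`.
#' @return A [CompositionProfile-class].
#' @export
compositionProfile <- function(m, by = c("reference", "taxon")) {
  by <- match.arg(by)
  stopifnot(is(m, "DatabaseManifest"))
  if (!nrow(m@assemblies))
    stop(sprintf("manifest '%s' has no records", m@name), call. = FALSE)
  cl <- classifyReferences(m)
  nUn <- sum(is.na(cl$class))
  cl <- cl[!is.na(cl$class), , drop = FALSE]
  if (!nrow(cl))
    stop(sprintf("all records of '%s' are unclassifiable", m@name),
         call. = FALSE)
  if (by == "taxon") {
    rankCl <- function(classes) {
      if (any(classes == "COMPLETE")) "COMPLETE"
      else if (any(classes == "MIXED")) "MIXED"
      else "FRAGMENTED"
    }
    cls <- vapply(split(cl$class, cl$taxid), rankCl, character(1))
  } else {
    cls <- cl$class
  }
  counts <- setNames(integer(3), COMPLETENESS_CLASSES)
  tab <- table(factor(cls, levels = COMPLETENESS_CLASSES))
  counts[names(tab)] <- as.integer(tab)
  new("CompositionProfile", database = m@name, by = by, counts = counts,
      percentages = 100 * counts / sum(counts),
      nUnclassifiable = as.integer(nUn))
}

#' Length distribution of contig and scaffold sequences
#'
#' Summarizes the lengths of all contig and scaffold sequences belonging
#' to FRAGMENTED and MIXED references (chromosome sequences are excluded,
#' as are COMPLETE references, which have none by definition). Scaffolds
#' are pooled with contigs.
#'
#' @param m a [DatabaseManifest-class].
#' @param nBins number of equal-width histogram bins spanning 0 to the
#'   observed maximum (default 50).
#' @param breaks optional explicit break vector overriding `nBins`.
#' @return A [LengthStats-class].
#' @export
contigLengthStats <- function(m, nBins = 50L, breaks = NULL) {
  stopifnot(is(m, "DatabaseManifest"))
  cl <- classifyReferences(m)
  keep <- cl$accession[cl$class %in% c("FRAGMENTED", "MIXED")]
  sq <- m@sequences
  len <- sq$length[sq$accession %in% keep & sq$role %in% c("contig",
                                                           "scaffold")]
  if (!length(len))
    stop(sprintf("manifest '%s' has no contig or scaffold sequences in fragmented or mixed references",
                 m@name), call. = FALSE)
  if (is.null(breaks)) breaks <- seq(0, max(len), length.out = nBins + 1L)
  if (max(len) == 0) breaks <- c(0, 1)  # degenerate all-zero case
  bin <- cut(len, breaks, include.lowest = TRUE, right = TRUE)
  counts <- as.integer(table(bin))
  q <- stats::quantile(len, c(0.25, 0.5, 0.75), names = FALSE)
  new("LengthStats", database = m@name, n = length(len),
      meanBp = mean(len), medianBp = q[2L], q25 = q[1L], q75 = q[3L],
      minBp = min(len), maxBp = max(len),
      histogram = data.frame(bin_lo = breaks[-length(breaks)],
                             bin_hi = breaks[-1L], count = counts))
}

#' Rank projection restricted to complete genomes
#'
#' Identical to [projectToRank()] applied to the subset of references
#' classified COMPLETE — the basis of the complete-genome-only consensus
#' analysis.
#'
#' @inheritParams projectToRank
#' @return A [RankProjection-class].
#' @export
completeOnlyProjection <- function(m, tax, rank) {
  stopifnot(is(m, "DatabaseManifest"))
  cl <- classifyReferences(m)
  keep <- cl$accession[!is.na(cl$class) & cl$class == "COMPLETE"]
  sub <- DatabaseManifest(
    m@name,
    m@assemblies[m@assemblies$accession %in% keep, , drop = FALSE],
    m@sequences[m@sequences$accession %in% keep, , drop = FALSE])
  projectToRank(sub, tax, rank)
}
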