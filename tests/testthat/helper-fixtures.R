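## Independent writers/oracles used across tests. These deliberately do not
## call into the package's own emitters so that parser tests and oracle
## comparisons stay two-route.

tsvLine <- function(...) paste(..., sep = "\t")

## Write taxdump-dialect files from plain vectors.
writeTestTaxdump <- function(dir, taxid, parent, rank,
                             name = paste0("taxon", taxid),
                             merged = NULL, deleted = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(sprintf("%d\t|\t%d\t|\t%s\t|", taxid, parent, rank),
             file.path(dir, "nodes.dmp"))
  writeLines(sprintf("%d\t|\t%s\t|\t\t|\tscientific name\t|", taxid, name),
             file.path(dir, "names.dmp"))
  writeLines(if (length(merged))
    sprintf("%d\t|\t%d\t|", as.integer(names(merged)), unname(merged))
    else character(0), file.path(dir, "merged.dmp"))
  writeLines(if (length(deleted)) sprintf("%d\t|", deleted)
             else character(0), file.path(dir, "delnodes.dmp"))
  dir
}

loadTestTaxdump <- function(dir) {
  loadTaxdump(file.path(dir, "nodes.dmp"), file.path(dir, "names.dmp"),
              file.path(dir, "merged.dmp"), file.path(dir, "delnodes.dmp"))
}

## 4-node fixture: root 1, genus 10, species 100, strain 1000, plus merged
## alias 999 -> 100.
toyTaxonomy <- function(merged = c("999" = 100L), deleted = integer(0)) {
  Taxonomy(data.frame(taxid = c(1L, 10L, 100L, 1000L),
                      parent = c(1L, 1L, 10L, 100L),
                      rank = c("no rank", "genus", "species", "strain"),
                      name = c("root", "Toygenus", "Toygenus toyspecies",
                               "Toygenus toyspecies strain T1")),
           merged = merged, deleted = deleted)
}

## Quick manifest builder: one reference per accession; roles is a list of
## per-reference role vectors (NULL entry = no sequences).
makeManifest <- function(name, accession, taxid, roles,
                         declared = NA_character_, lengths = NULL) {
  asm <- data.frame(accession = accession, taxid = as.integer(taxid),
                    declared_level = rep_len(declared, length(accession)),
                    stringsAsFactors = FALSE)
  seqRows <- lapply(seq_along(accession), function(i) {
    r <- roles[[i]]
    if (is.null(r)) return(NULL)
    ln <- if (is.null(lengths)) rep(1000L, length(r)) else lengths[[i]]
    data.frame(accession = accession[i],
               seq_id = sprintf("%s_s%d", accession[i], seq_along(r)),
               length = as.integer(ln), role = r, stringsAsFactors = FALSE)
  })
  sq <- do.call(rbind, seqRows)
  if (is.null(sq)) sq <- data.frame(accession = character(0),
                                    seq_id = character(0),
                                    length = integer(0),
                                    role = character(0))
  DatabaseManifest(name, asm, sq)
}

## Per-element brute-force Venn oracle, independent of vennPartition.
bruteForcePartition <- function(sets) {
  un <- sort(unique(unlist(sets, use.names = FALSE)))
  key <- vapply(un, function(x)
    paste(names(sets)[vapply(sets, function(s) x %in% s, logical(1))],
          collapse = ";"), character(1))
  split(un, key)
}

samePartitionCells <- function(a, b) {
  setequal(names(a), names(b)) &&
    all(vapply(names(a), function(k)
      identical(sort(as.integer(a[[k]])), sort(as.integer(b[[k]]))),
      logical(1)))
}

## Build N named sets realizing given exactly-k counts (round-robin cell
## assignment; deterministic, package-independent).
plantExactlyKSets <- function(labels, counts) {
  sets <- setNames(rep(list(integer(0)), length(labels)), labels)
  nid <- 0L
  for (k in as.integer(names(counts))) {
    subs <- utils::combn(labels, k, simplify = FALSE)
    ck <- as.integer(counts[[as.character(k)]])
    if (!ck) next
    idx <- ((seq_len(ck) - 1L) %% length(subs)) + 1L
    for (j in seq_along(subs)) {
      ids <- nid + which(idx == j)
      for (d in subs[[j]]) sets[[d]] <- c(sets[[d]], ids)
    }
    nid <- nid + ck
  }
  sets
}

randomSets <- function(nSets, unionMax) {
  universe <- sample.int(10 * unionMax, unionMax)
  sets <- lapply(seq_len(nSets), function(i)
    sample(universe, sample.int(unionMax, 1L)))
  names(sets) <- paste0("db", seq_len(nSets))
  sets
}
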