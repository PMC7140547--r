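## NCBI taxdump dialect: fields separated by "\t|\t", lines terminated "\t|".

readDmpFields <- function(path, minFields, what) {
  if (!file.exists(path))
    stop(sprintf("%s file not found: %s", what, path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(lines)
  parts <- strsplit(sub("\t\\|$", "", lines[keep]), "\t|\t", fixed = TRUE)
  nf <- vapply(parts, length, integer(1))
  if (any(nf < minFields)) {
    bad <- which(keep)[which(nf < minFields)[1L]]
    stop(sprintf("malformed %s line %d in %s (expected >= %d fields)",
                 what, bad, path, minFields), call. = FALSE)
  }
  parts
}

dmpColumn <- function(parts, i) vapply(parts, `[[`, character(1), i)

#' Load an NCBI taxdump into a Taxonomy
#'
#' Parses `nodes.dmp` (taxid, parent, rank), the scientific names from
#' `names.dmp`, and optionally `merged.dmp` and `delnodes.dmp`, all in the
#' NCBI dump dialect (fields separated by `"\t|\t"`, lines terminated
#' `"\t|"`). Merged chains are resolved transitively at load time; a cycle
#' in the merged map, a dangling parent or a cyclic parent chain is a
#' structural error.
#'
#' @param nodesPath path to nodes.dmp.
#' @param namesPath path to names.dmp; nodes without a scientific name get
#'   an empty name.
#' @param mergedPath optional path to merged.dmp.
#' @param delnodesPath optional path to delnodes.dmp.
#' @return A [Taxonomy-class] object.
#' @examples
#' dir <- system.file("extdata", "toy_taxdump", package = "dbconcord")
#' tax <- loadTaxdump(file.path(dir, "nodes.dmp"), file.path(dir, "names.dmp"),
#'                    file.path(dir, "merged.dmp"))
#' tax
#' @export
loadTaxdump <- function(nodesPath, namesPath, mergedPath = NULL,
                        delnodesPath = NULL) {
  np <- readDmpFields(nodesPath, 3L, "nodes.dmp")
  taxid <- suppressWarnings(as.integer(dmpColumn(np, 1L)))
  parent <- suppressWarnings(as.integer(dmpColumn(np, 2L)))
  if (anyNA(taxid) || anyNA(parent))
    stop(sprintf("malformed nodes.dmp line %d in %s (non-integer taxid)",
                 which(is.na(taxid) | is.na(parent))[1L], nodesPath),
         call. = FALSE)
  nodes <- data.frame(taxid = taxid, parent = parent,
                      rank = dmpColumn(np, 3L), name = "",
                      stringsAsFactors = FALSE)

  nm <- readDmpFields(namesPath, 4L, "names.dmp")
  sci <- dmpColumn(nm, 4L) == "scientific name"
  idx <- match(suppressWarnings(as.integer(dmpColumn(nm, 1L)[sci])),
               nodes$taxid)
  nodes$name[idx[!is.na(idx)]] <- dmpColumn(nm, 2L)[sci][!is.na(idx)]

  merged <- integer(0)
  if (!is.null(mergedPath)) {
    mp <- readDmpFields(mergedPath, 2L, "merged.dmp")
    merged <- setNames(as.integer(dmpColumn(mp, 2L)), dmpColumn(mp, 1L))
  }
  deleted <- integer(0)
  if (!is.null(delnodesPath)) {
    dp <- readDmpFields(delnodesPath, 1L, "delnodes.dmp")
    deleted <- as.integer(dmpColumn(dp, 1L))
  }
  Taxonomy(nodes, merged, deleted)
}

#' Resolve taxids against a Taxonomy
#'
#' Applies the merged-id map transitively, then classifies each input as
#' `found` (current node), `merged` (redirected to a current node),
#' `deleted` (withdrawn) or `unknown`. Resolution is idempotent: resolving
#' a canonical taxid returns it with status `found`.
#'
#' @param tax a [Taxonomy-class].
#' @param taxids integer vector of taxids to resolve.
#' @return data.frame with columns `input_taxid`, `canonical_taxid` (NA for
#'   deleted/unknown) and `status`.
#' @export
resolveTaxid <- function(tax, taxids) {
  stopifnot(is(tax, "Taxonomy"))
  ti <- as.integer(taxids)
  nodes <- tax@nodes$taxid
  canonical <- rep(NA_integer_, length(ti))
  status <- rep("unknown", length(ti))

  found <- ti %in% nodes
  canonical[found] <- ti[found]
  status[found] <- "found"

  midx <- match(as.character(ti), names(tax@merged))
  hit <- !found & !is.na(midx)
  canonical[hit] <- unname(tax@merged[midx[hit]])
  status[hit] <- "merged"

  del <- !found & !hit & ti %in% tax@deleted
  status[del] <- "deleted"

  data.frame(input_taxid = ti, canonical_taxid = canonical,
             status = status, stringsAsFactors = FALSE)
}

#' Project taxids to an ancestor of a given rank
#'
#' Walks parent pointers from each node (inclusive) toward the root and
#' returns the first ancestor whose rank matches the requested label; rank
#' labels are compared case-insensitively after trimming. Returns NA when
#' the root is reached without a match (e.g. asking for "species" from a
#' genus-level node, or from an isolate attached above the species rank).
#'
#' @param tax a [Taxonomy-class].
#' @param taxids integer vector; merged ids are resolved first, but deleted
#'   or unknown ids are an error — filter them with [resolveTaxid()].
#' @param rank rank label to project to (e.g. "species", "genus").
#' @return integer vector of ancestor taxids, NA where no ancestor at the
#'   rank exists.
#' @export
ancestorAtRank <- function(tax, taxids, rank) {
  stopifnot(is(tax, "Taxonomy"), length(rank) == 1L, nzchar(rank))
  res <- resolveTaxid(tax, taxids)
  bad <- !(res$status %in% c("found", "merged"))
  if (any(bad))
    stop(sprintf("cannot resolve taxid %d (%s) to a taxonomy node",
                 res$input_taxid[bad][1L], res$status[bad][1L]),
         call. = FALSE)
  nd <- tax@nodes
  want <- tolower(trimws(rank))
  rk <- tolower(trimws(nd$rank))

  cur <- res$canonical_taxid
  out <- rep(NA_integer_, length(cur))
  active <- rep(TRUE, length(cur))
  for (step in seq_len(nrow(nd) + 1L)) {
    if (!any(active)) break
    i <- match(cur[active], nd$taxid)
    hit <- rk[i] == want
    ai <- which(active)
    out[ai[hit]] <- cur[ai[hit]]
    atRoot <- nd$parent[i] == nd$taxid[i]
    cur[ai] <- nd$parent[i]
    active[ai[hit | atRoot]] <- FALSE
  }
  out
}
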