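MANIFEST_TSV_COLS <- c("accession", "taxid", "seq_id", "seq_length",
                       "seq_role")

#' Read a catalogue from the canonical manifest TSV
#'
#' The canonical dialect is a UTF-8 TSV with header
#' `accession  taxid  seq_id  seq_length  seq_role`, one row per sequence.
#' Rows sharing an accession are grouped into one reference, preserving
#' row order; an accession must carry one taxid.
#'
#' @param path TSV file path.
#' @param name database label for the resulting manifest.
#' @return A [DatabaseManifest-class].
#' @seealso [writeManifestTsv()] for the inverse.
#' @export
readManifestTsv <- function(path, name) {
  if (!file.exists(path))
    stop(sprintf("manifest file not found: %s", path), call. = FALSE)
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = list(character = c("accession",
                                                          "seq_id",
                                                          "seq_role")),
                          data.table = FALSE)
  missing <- setdiff(MANIFEST_TSV_COLS, names(dt))
  if (length(missing))
    stop(sprintf("manifest %s lacks required column(s): %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  if (nrow(dt)) {
    badRole <- which(!(dt$seq_role %in% SEQ_ROLES))
    if (length(badRole))
      stop(sprintf("unknown seq_role '%s' at line %d of %s",
                   dt$seq_role[badRole[1L]], badRole[1L] + 1L, path),
           call. = FALSE)
    key <- paste(dt$accession, dt$seq_id, sep = "\r")
    if (anyDuplicated(key)) {
      d <- dt[duplicated(key), , drop = FALSE][1L, ]
      stop(sprintf("duplicate (accession, seq_id) pair %s/%s in %s",
                   d$accession, d$seq_id, path), call. = FALSE)
    }
    ntax <- tapply(dt$taxid, dt$accession, function(x) length(unique(x)))
    if (any(ntax > 1L))
      stop(sprintf("conflicting taxids for accession %s in %s",
                   names(ntax)[ntax > 1L][1L], path), call. = FALSE)
  }
  first <- !duplicated(dt$accession)
  asm <- data.frame(accession = dt$accession[first],
                    taxid = as.integer(dt$taxid[first]),
                    declared_level = rep(NA_character_, sum(first)),
                    stringsAsFactors = FALSE)
  seqs <- data.frame(accession = dt$accession, seq_id = dt$seq_id,
                     length = as.integer(dt$seq_length),
                     role = dt$seq_role, stringsAsFactors = FALSE)
  DatabaseManifest(name, asm, seqs)
}

#' Write a catalogue to the canonical manifest TSV
#'
#' Inverse of [readManifestTsv()]: one row per sequence, in stored order.
#' References without sequence rows cannot be expressed in this dialect
#' (it has no assembly-level column) and are an error.
#'
#' @param m a [DatabaseManifest-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeManifestTsv <- function(m, path) {
  stopifnot(is(m, "DatabaseManifest"))
  noSeq <- setdiff(m@assemblies$accession, m@sequences$accession)
  if (length(noSeq))
    stop(sprintf("reference %s has no sequence rows; the manifest TSV dialect cannot express it",
                 noSeq[1L]), call. = FALSE)
  s <- m@sequences
  out <- data.frame(accession = s$accession,
                    taxid = m@assemblies$taxid[match(s$accession,
                                                     m@assemblies$accession)],
                    seq_id = s$seq_id, seq_length = s$length,
                    seq_role = s$role, stringsAsFactors = FALSE)
  data.table::fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read an NCBI assembly_summary catalogue
#'
#' Parses the assembly_summary dialect: lines starting `#` are headers (the
#' last one carries the column names), data rows are tab-separated. Each
#' data row becomes one reference with no sequences and `declared_level`
#' taken from `assembly_level`; taxids come from the `taxid` or
#' `species_taxid` column as requested.
#'
#' @param path assembly_summary file path.
#' @param name database label.
#' @param taxidColumn which taxid column to use: `"taxid"` (default) or
#'   `"species_taxid"`.
#' @return A [DatabaseManifest-class].
#' @export
readAssemblySummary <- function(path, name,
                                taxidColumn = c("taxid", "species_taxid")) {
  taxidColumn <- match.arg(taxidColumn)
  if (!file.exists(path))
    stop(sprintf("assembly_summary file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  isHdr <- grepl("^#", lines)
  if (!any(isHdr))
    stop(sprintf("no header line (starting '#') in %s", path), call. = FALSE)
  cols <- strsplit(sub("^#\\s*", "", lines[max(which(isHdr))]), "\t",
                   fixed = TRUE)[[1L]]
  need <- c("assembly_accession", "taxid", "species_taxid", "assembly_level")
  if (!all(need %in% cols))
    stop(sprintf("%s lacks required column(s): %s", path,
                 paste(setdiff(need, cols), collapse = ", ")), call. = FALSE)
  dataIdx <- which(!isHdr & nzchar(lines))
  if (!length(dataIdx))
    return(DatabaseManifest(name, emptyAssemblyTable()))
  fields <- strsplit(lines[dataIdx], "\t", fixed = TRUE)
  getCol <- function(col) {
    j <- match(col, cols)
    vapply(fields, function(f) if (length(f) >= j) f[[j]] else NA_character_,
           character(1))
  }
  level <- getCol("assembly_level")
  bad <- which(!(level %in% ASSEMBLY_LEVELS))
  if (length(bad))
    stop(sprintf("unknown assembly_level '%s' at line %d of %s",
                 level[bad[1L]], dataIdx[bad[1L]], path), call. = FALSE)
  asm <- data.frame(accession = getCol("assembly_accession"),
                    taxid = as.integer(getCol(taxidColumn)),
                    declared_level = level, stringsAsFactors = FALSE)
  DatabaseManifest(name, asm)
}

#' Default FASTA header-to-role rules
#'
#' Ordered keyword rules applied case-insensitively to FASTA description
#' lines; the first matching keyword wins, anything else falls back to the
#' default role (contig — the conservative choice, since most reference
#' assemblies are fragmented).
#'
#' @return named character vector, keyword -> role.
#' @export
defaultHeaderRules <- function() {
  c("complete genome" = "chromosome",
    "chromosome" = "chromosome",
    "scaffold" = "scaffold")
}

#' Scan a FASTA file into a single-reference manifest
#'
#' Each FASTA entry becomes one sequence record: the length is the residue
#' count (whitespace ignored), the role comes from the first header rule
#' whose keyword occurs in the description line, else `defaultRole`.
#' Sequences containing characters outside the IUPAC nucleotide codes
#' (plus N and gap characters) are kept with a warning.
#'
#' @param path FASTA file path.
#' @param accession accession assigned to the reference.
#' @param taxid taxid assigned to the reference.
#' @param name database label; defaults to the accession.
#' @param headerRules ordered keyword -> role rules; see
#'   [defaultHeaderRules()].
#' @param defaultRole role when no rule matches.
#' @return A [DatabaseManifest-class] with one reference.
#' @export
scanFastaComposition <- function(path, accession, taxid, name = accession,
                                 headerRules = defaultHeaderRules(),
                                 defaultRole = "contig") {
  stopifnot(length(headerRules) >= 1L, defaultRole %in% SEQ_ROLES,
            all(headerRules %in% SEQ_ROLES))
  if (!file.exists(path))
    stop(sprintf("FASTA file not found: %s", path), call. = FALSE)
  ## BStringSet rather than DNAStringSet so that records with stray
  ## characters survive the scan (they are reported, not dropped).
  seqs <- Biostrings::readBStringSet(path)
  if (!length(seqs))
    stop(sprintf("empty FASTA: %s", path), call. = FALSE)
  headers <- names(seqs)
  seqId <- sub("\\s.*$", "", headers)
  hl <- tolower(headers)
  role <- rep(defaultRole, length(seqs))
  assigned <- rep(FALSE, length(seqs))
  for (kw in names(headerRules)) {
    hit <- !assigned & grepl(kw, hl, fixed = TRUE)
    role[hit] <- headerRules[[kw]]
    assigned <- assigned | hit
  }
  iupac <- "ACGTUMRWSYKVHDBNacgtumrwsykvhdbn.-"
  valid <- rowSums(Biostrings::letterFrequency(seqs, strsplit(iupac, "")[[1]]))
  offending <- which(valid < Biostrings::width(seqs))
  if (length(offending))
    warning(sprintf("%d sequence(s) in %s contain non-IUPAC characters (e.g. %s); records kept",
                    length(offending), path, seqId[offending[1L]]),
            call. = FALSE)
  asm <- data.frame(accession = accession, taxid = as.integer(taxid),
                    declared_level = NA_character_, stringsAsFactors = FALSE)
  sq <- data.frame(accession = accession, seq_id = seqId,
                   length = Biostrings::width(seqs), role = role,
                   stringsAsFactors = FALSE)
  DatabaseManifest(name, asm, sq)
}

#' Concatenate manifests into one database catalogue
#'
#' Binds the references of several manifests (e.g. per-genome FASTA scans)
#' into a single manifest under one database label. Accessions must be
#' unique across the inputs.
#'
#' @param manifests list of [DatabaseManifest-class] objects.
#' @param name database label for the combined manifest.
#' @return A [DatabaseManifest-class].
#' @export
bindManifests <- function(manifests, name) {
  stopifnot(length(manifests) >= 1L,
            all(vapply(manifests, is, logical(1), "DatabaseManifest")))
  asm <- do.call(rbind, lapply(manifests, assemblies))
  sq <- do.call(rbind, lapply(manifests, sequenceTable))
  DatabaseManifest(name, asm, sq)
}
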