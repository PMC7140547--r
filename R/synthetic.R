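#' Specify a synthetic catalogue simulation
#'
#' Builds a [SimulationDesign-class]. The defaults emulate the fungal
#' study conditions: four databases, the published exactly-k species
#' partition (48 in all four, 175 in exactly three, 189 in exactly two,
#' 993 unique to one), per-database complete/fragmented/mixed fractions,
#' and lognormal contig length means of 322/513/426/548 kbp. Parameters
#' the study does not pin down (log-sd, contigs per fragmented assembly,
#' chromosomes per complete genome, strain emission, merged-id fraction)
#' have field-realistic defaults discussed in the methods vignette.
#'
#' @param databases ordered database labels (>= 2).
#' @param nGenera number of genera in the synthetic taxonomy.
#' @param speciesPerGenusLambda species per genus are 1 + Poisson(lambda).
#' @param strainsPerSpeciesLambda strains per species are Poisson(lambda).
#' @param partitionType `"exactly_k"` (counts named by k, cells drawn
#'   uniformly among size-k subsets) or `"cells"` (counts named by
#'   semicolon-joined subset keys).
#' @param partitionCounts named non-negative counts; their sum is the
#'   number of planted species and may not exceed the species generated.
#' @param compositionFractions databases x (COMPLETE, FRAGMENTED, MIXED)
#'   matrix of per-reference class probabilities, rows summing to 1.
#' @param contigsPerFragmented mean contigs per fragmented reference
#'   (count is 1 + Poisson(mean - 1)).
#' @param chromosomesPerComplete mean chromosomes per complete reference.
#' @param lengthMeanBp per-database expected contig length in bp (the
#'   lognormal mean exp(mu + sigma^2/2)).
#' @param lengthLogSd lognormal log-scale standard deviation.
#' @param scaffoldFraction fraction of fragment sequences labelled
#'   scaffold rather than contig.
#' @param strainRank rank label given to strain nodes ("strain", or
#'   "no rank" to mimic dumps that leave strains unranked).
#' @param strainEmissionFraction probability that a record cites a strain
#'   child instead of its species (exercises rank projection).
#' @param mergedFraction fraction of species whose records cite an old
#'   taxid redirected through merged.dmp.
#' @param isolateFraction fraction of species emitted as genus-attached
#'   "no rank" isolates, which cannot be projected to species rank and
#'   reproduce the strain/isolate ambiguity.
#' @param seed integer seed; the whole emission is deterministic given it.
#' @return A [SimulationDesign-class].
#' @export
simulationDesign <- function(databases = c("Ensembl", "RefSeq", "JGI1K",
                                           "FungiDB"),
                             nGenera = 786L,
                             speciesPerGenusLambda = 1.0,
                             strainsPerSpeciesLambda = 1.0,
                             partitionType = "exactly_k",
                             partitionCounts = c("4" = 48, "3" = 175,
                                                 "2" = 189, "1" = 993),
                             compositionFractions = NULL,
                             contigsPerFragmented = 30,
                             chromosomesPerComplete = 8,
                             lengthMeanBp = NULL,
                             lengthLogSd = 1.2,
                             scaffoldFraction = 0.15,
                             strainRank = "strain",
                             strainEmissionFraction = 0.5,
                             mergedFraction = 0.05,
                             isolateFraction = 0,
                             seed = 1L) {
  if (is.null(compositionFractions)) {
    defaults <- rbind(Ensembl = c(0.16, 0.80, 0.04),
                      RefSeq = c(0.14, 0.81, 0.05),
                      JGI1K = c(0.02, 0.98, 0.00),
                      FungiDB = c(0.13, 0.81, 0.06))
    compositionFractions <-
      if (identical(sort(databases), sort(rownames(defaults))))
        defaults[databases, , drop = FALSE]
      else matrix(rep(c(0.12, 0.83, 0.05), each = length(databases)),
                  nrow = length(databases),
                  dimnames = list(databases, NULL))
  }
  colnames(compositionFractions) <- COMPLETENESS_CLASSES
  rownames(compositionFractions) <- databases
  if (is.null(lengthMeanBp)) {
    defaults <- c(Ensembl = 322e3, RefSeq = 513e3, JGI1K = 426e3,
                  FungiDB = 548e3)
    lengthMeanBp <-
      if (all(databases %in% names(defaults))) defaults[databases]
      else setNames(rep(500e3, length(databases)), databases)
  }
  names(lengthMeanBp) <- databases
  new("SimulationDesign", databases = databases,
      nGenera = as.integer(nGenera),
      speciesPerGenusLambda = speciesPerGenusLambda,
      strainsPerSpeciesLambda = strainsPerSpeciesLambda,
      partitionType = partitionType,
      partitionCounts = partitionCounts,
      compositionFractions = compositionFractions,
      contigsPerFragmented = contigsPerFragmented,
      chromosomesPerComplete = chromosomesPerComplete,
      lengthMeanBp = lengthMeanBp, lengthLogSd = lengthLogSd,
      scaffoldFraction = scaffoldFraction, strainRank = strainRank,
      strainEmissionFraction = strainEmissionFraction,
      mergedFraction = mergedFraction, isolateFraction = isolateFraction,
      seed = as.integer(seed))
}

withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

dmpLine <- function(...) paste(paste(..., sep = "\t|\t"), "\t|", sep = "")

#' Generate a synthetic taxonomy and emit it as a taxdump
#'
#' Builds a genus -> species -> strain hierarchy per the design and writes
#' `nodes.dmp`, `names.dmp`, `merged.dmp` and `delnodes.dmp` in the exact
#' NCBI taxdump dialect. A `mergedFraction` of species get an old-taxid
#' alias redirected through merged.dmp; an `isolateFraction` get an extra
#' "no rank" child attached directly to their genus (an isolate with no
#' species-rank ancestor). Deterministic given the design seed.
#'
#' @param design a [SimulationDesign-class].
#' @param dir output directory (created if needed).
#' @return list with elements `taxonomy` (the emitted files re-read via
#'   [loadTaxdump()]), `registry` (species/strain bookkeeping used by
#'   [generateDatabases()]) and `files`.
#' @export
generateTaxonomy <- function(design, dir) {
  stopifnot(is(design, "SimulationDesign"))
  validObject(design)
  if (design@nGenera < 1L) stop("design must have at least one genus",
                                call. = FALSE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  withSeed(design@seed, {
    G <- design@nGenera
    spPerGenus <- 1L + stats::rpois(G, design@speciesPerGenusLambda)
    S <- sum(spPerGenus)
    strPerSpecies <- stats::rpois(S, design@strainsPerSpeciesLambda)
    aliasDraw <- stats::runif(S)
    isoDraw <- stats::runif(S)

    genusIds <- seq.int(2L, 1L + G)
    speciesIds <- seq.int(2L + G, 1L + G + S)
    strainIds <- if (sum(strPerSpecies))
      seq.int(2L + G + S, 1L + G + S + sum(strPerSpecies)) else integer(0)
    nextId <- 2L + G + S + sum(strPerSpecies)

    genusOf <- rep(genusIds, spPerGenus)
    genusName <- sprintf("Synthgenus%04d", seq_len(G))
    spName <- sprintf("%s species%05d",
                      genusName[match(genusOf, genusIds)], seq_len(S))
    strSpecies <- rep(speciesIds, strPerSpecies)
    strName <- sprintf("%s strain%d", spName[match(strSpecies, speciesIds)],
                       sequence(strPerSpecies))

    hasAlias <- aliasDraw < design@mergedFraction
    aliasIds <- rep(NA_integer_, S)
    if (any(hasAlias)) {
      aliasIds[hasAlias] <- seq.int(nextId, nextId + sum(hasAlias) - 1L)
      nextId <- nextId + sum(hasAlias)
    }
    hasIso <- isoDraw < design@isolateFraction
    isoIds <- rep(NA_integer_, S)
    if (any(hasIso)) {
      isoIds[hasIso] <- seq.int(nextId, nextId + sum(hasIso) - 1L)
      nextId <- nextId + sum(hasIso)
    }

    nodes <- data.frame(
      taxid = c(1L, genusIds, speciesIds, strainIds, isoIds[hasIso]),
      parent = c(1L, rep(1L, G), genusOf, strSpecies, genusOf[hasIso]),
      rank = c("no rank", rep("genus", G), rep("species", S),
               rep(design@strainRank, length(strainIds)),
               rep("no rank", sum(hasIso))),
      name = c("root", genusName, spName, strName,
               sprintf("%s isolate", spName[hasIso])),
      stringsAsFactors = FALSE)

    files <- c(nodes = file.path(dir, "nodes.dmp"),
               names = file.path(dir, "names.dmp"),
               merged = file.path(dir, "merged.dmp"),
               delnodes = file.path(dir, "delnodes.dmp"))
    writeLines(dmpLine(nodes$taxid, nodes$parent, nodes$rank),
               files[["nodes"]])
    writeLines(dmpLine(nodes$taxid, nodes$name, "", "scientific name"),
               files[["names"]])
    mergedOld <- aliasIds[hasAlias]
    mergedNew <- speciesIds[hasAlias]
    writeLines(if (length(mergedOld)) dmpLine(mergedOld, mergedNew)
               else character(0), files[["merged"]])
    writeLines(character(0), files[["delnodes"]])

    firstStrain <- rep(NA_integer_, S)
    if (length(strainIds))
      firstStrain[match(unique(strSpecies), speciesIds)] <-
        strainIds[!duplicated(strSpecies)]
    registry <- list(
      species = data.frame(taxid = speciesIds, genus = genusOf,
                           name = spName, alias = aliasIds,
                           isolate = isoIds, firstStrain = firstStrain,
                           stringsAsFactors = FALSE),
      strains = data.frame(taxid = strainIds, species = strSpecies,
                           stringsAsFactors = FALSE))
    list(taxonomy = loadTaxdump(files[["nodes"]], files[["names"]],
                                files[["merged"]], files[["delnodes"]]),
         registry = registry, files = files)
  })
}

## Realize a partition design over concrete taxids: returns a named list of
## cells (canonical subset key -> taxid vector) consuming `sum(counts)` ids.
realizeCells <- function(databases, partitionType, partitionCounts, taxids) {
  n <- length(databases)
  if (partitionType == "exactly_k") {
    keys <- character(0)
    counts <- integer(0)
    for (k in sort(as.integer(names(partitionCounts)), decreasing = TRUE)) {
      ck <- partitionCounts[[as.character(k)]]
      subs <- utils::combn(databases, k, paste, collapse = ";")
      pick <- if (ck > 0) sample.int(length(subs), ck, replace = TRUE)
              else integer(0)
      keys <- c(keys, subs)
      counts <- c(counts, tabulate(pick, nbins = length(subs)))
    }
  } else {
    keys <- names(partitionCounts)
    canonical <- vapply(strsplit(keys, ";", fixed = TRUE), function(l) {
      if (!all(l %in% databases))
        stop(sprintf("cell key '%s' uses unknown database labels",
                     paste(l, collapse = ";")), call. = FALSE)
      paste(databases[databases %in% l], collapse = ";")
    }, character(1))
    keys <- canonical
    counts <- as.integer(partitionCounts)
  }
  stopifnot(sum(counts) == length(taxids))
  cells <- split(taxids, rep(seq_along(keys), counts))
  names(cells) <- keys[as.integer(names(cells))]
  cells
}

#' Generate database manifests with a planted overlap partition
#'
#' Assigns species to overlap cells per the partition design, then emits
#' one reference per member species per database: the cited taxid is the
#' species itself, a strain child (with probability
#' `strainEmissionFraction`), an old alias redirected through merged.dmp,
#' or a genus-attached isolate, so the projection machinery is exercised;
#' the reference's completeness class is drawn from the per-database
#' composition fractions and its contig lengths from the lognormal model.
#' Manifest TSVs are written in the canonical dialect.
#'
#' @param design a [SimulationDesign-class].
#' @param registry registry returned by [generateTaxonomy()].
#' @param dir output directory.
#' @return A [SyntheticTruth-class] carrying the planted partition,
#'   fractions, length means and emitted file paths.
#' @export
generateDatabases <- function(design, registry, dir) {
  stopifnot(is(design, "SimulationDesign"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sp <- registry$species
  total <- as.integer(sum(design@partitionCounts))
  if (total > nrow(sp))
    stop(sprintf("partition total (%d) exceeds generated species count (%d)",
                 total, nrow(sp)), call. = FALSE)
  withSeed(design@seed + 1L, {
    chosen <- sp[sample.int(nrow(sp))[seq_len(total)], , drop = FALSE]
    cells <- realizeCells(design@databases, design@partitionType,
                          design@partitionCounts, chosen$taxid)
    cells <- cells[lengths(cells) > 0L]
    planted <- new("OverlapPartition", databases = design@databases,
                   cells = lapply(cells, function(x) sort(unname(x))),
                   unionSize = total)

    keyLabs <- strsplit(names(cells), ";", fixed = TRUE)
    files <- character(0)
    sigma <- design@lengthLogSd
    for (d in design@databases) {
      members <- unlist(cells[vapply(keyLabs, function(l) d %in% l,
                                     logical(1))], use.names = FALSE)
      nm <- length(members)
      if (!nm) {
        path <- file.path(dir, paste0(d, ".manifest.tsv"))
        writeLines(paste(MANIFEST_TSV_COLS, collapse = "\t"), path)
        files[[d]] <- path
        next
      }
      row <- match(members, sp$taxid)
      strainDraw <- stats::runif(nm)
      emitted <- sp$taxid[row]
      useStrain <- strainDraw < design@strainEmissionFraction &
        !is.na(sp$firstStrain[row])
      emitted[useStrain] <- sp$firstStrain[row][useStrain]
      emitted[!is.na(sp$alias[row])] <- sp$alias[row][!is.na(sp$alias[row])]
      emitted[!is.na(sp$isolate[row])] <-
        sp$isolate[row][!is.na(sp$isolate[row])]

      cls <- sample(COMPLETENESS_CLASSES, nm, replace = TRUE,
                    prob = design@compositionFractions[d, ])
      nChromDraw <- stats::rpois(nm, max(design@chromosomesPerComplete - 1,
                                         0))
      nCtgDraw <- stats::rpois(nm, max(design@contigsPerFragmented - 1, 0))
      nChrom <- ifelse(cls == "COMPLETE", 1L + nChromDraw,
                       ifelse(cls == "MIXED", 1L, 0L))
      nCtg <- ifelse(cls == "COMPLETE", 0L, 1L + nCtgDraw)

      acc <- sprintf("SYN_%s_%07d", d, sp$taxid[row])
      mu <- log(design@lengthMeanBp[[d]]) - sigma^2 / 2
      chromLen <- pmax(1, round(stats::rlnorm(sum(nChrom),
                                              log(4e6) - 0.125, 0.5)))
      ctgLen <- pmax(1, round(stats::rlnorm(sum(nCtg), mu, sigma)))
      scafDraw <- stats::runif(sum(nCtg)) < design@scaffoldFraction

      seqs <- data.frame(
        accession = c(rep(acc, nChrom), rep(acc, nCtg)),
        seq_id = c(sprintf("%s_chr%d", rep(acc, nChrom), sequence(nChrom)),
                   sprintf("%s_ctg%d", rep(acc, nCtg), sequence(nCtg))),
        length = c(chromLen, ctgLen),
        role = c(rep("chromosome", sum(nChrom)),
                 ifelse(scafDraw, "scaffold", "contig")),
        stringsAsFactors = FALSE)
      ## interleave so each record's chromosomes precede its contigs
      seqs <- seqs[order(match(seqs$accession, acc)), , drop = FALSE]
      man <- DatabaseManifest(d,
        data.frame(accession = acc, taxid = emitted,
                   declared_level = NA_character_,
                   stringsAsFactors = FALSE), seqs)
      path <- file.path(dir, paste0(d, ".manifest.tsv"))
      writeManifestTsv(man, path)
      files[[d]] <- path
    }
    new("SyntheticTruth", plantedPartition = planted,
        plantedFractions = design@compositionFractions,
        plantedLengthMeanBp = design@lengthMeanBp,
        files = files, seed = design@seed)
  })
}

#' Run a full simulation: taxonomy plus database manifests
#'
#' Convenience wrapper calling [generateTaxonomy()] then
#' [generateDatabases()] into the same directory.
#'
#' @param design a [SimulationDesign-class].
#' @param dir output directory.
#' @return list with `taxonomy`, `registry`, `truth` and `files` (taxdump
#'   plus manifest paths).
#' @export
simulateStudy <- function(design, dir) {
  taxOut <- generateTaxonomy(design, dir)
  truth <- generateDatabases(design, taxOut$registry, dir)
  list(taxonomy = taxOut$taxonomy, registry = taxOut$registry,
       truth = truth, files = c(taxOut$files, truthFiles(truth)))
}
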