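#' Accessors for dbconcord classes
#'
#' Small accessor generics so downstream code never reaches into slots:
#' `taxonNodes`, `mergedIds` and `deletedIds` expose the parts of a
#' [Taxonomy-class]; `manifestName`, `assemblies` and `sequenceTable` the
#' parts of a [DatabaseManifest-class]; `taxonSet` and `exclusions` those of
#' a [RankProjection-class]; `databases`, `partitionCells` and `unionSize`
#' those of an [OverlapPartition-class].
#'
#' @param x the object.
#' @return The corresponding component (data.frame, vector or list).
#' @name accessors
#' @aliases taxonNodes mergedIds deletedIds manifestName assemblies
#'   sequenceTable taxonSet exclusions databases partitionCells unionSize
NULL

#' @rdname accessors
#' @export
setGeneric("taxonNodes", function(x) standardGeneric("taxonNodes"))
#' @rdname accessors
#' @export
setMethod("taxonNodes", "Taxonomy", function(x) x@nodes)

#' @rdname accessors
#' @export
setGeneric("mergedIds", function(x) standardGeneric("mergedIds"))
#' @rdname accessors
#' @export
setMethod("mergedIds", "Taxonomy", function(x) x@merged)

#' @rdname accessors
#' @export
setGeneric("deletedIds", function(x) standardGeneric("deletedIds"))
#' @rdname accessors
#' @export
setMethod("deletedIds", "Taxonomy", function(x) x@deleted)

#' @rdname accessors
#' @export
setGeneric("manifestName", function(x) standardGeneric("manifestName"))
#' @rdname accessors
#' @export
setMethod("manifestName", "DatabaseManifest", function(x) x@name)

#' @rdname accessors
#' @export
setGeneric("assemblies", function(x) standardGeneric("assemblies"))
#' @rdname accessors
#' @export
setMethod("assemblies", "DatabaseManifest", function(x) x@assemblies)

#' @rdname accessors
#' @export
setGeneric("sequenceTable", function(x) standardGeneric("sequenceTable"))
#' @rdname accessors
#' @export
setMethod("sequenceTable", "DatabaseManifest", function(x) x@sequences)

#' @rdname accessors
#' @export
setGeneric("taxonSet", function(x) standardGeneric("taxonSet"))
#' @rdname accessors
#' @export
setMethod("taxonSet", "RankProjection", function(x) x@taxa)

#' @rdname accessors
#' @export
setGeneric("exclusions", function(x) standardGeneric("exclusions"))
#' @rdname accessors
#' @export
setMethod("exclusions", "RankProjection", function(x) x@exclusions)

#' @rdname accessors
#' @export
setGeneric("databases", function(x) standardGeneric("databases"))
#' @rdname accessors
#' @export
setMethod("databases", "OverlapPartition", function(x) x@databases)

#' @rdname accessors
#' @export
setGeneric("partitionCells", function(x) standardGeneric("partitionCells"))
#' @rdname accessors
#' @export
setMethod("partitionCells", "OverlapPartition", function(x) x@cells)

#' @rdname accessors
#' @export
setGeneric("unionSize", function(x) standardGeneric("unionSize"))
#' @rdname accessors
#' @export
setMethod("unionSize", "OverlapPartition", function(x) x@unionSize)

#' @rdname accessors
#' @export
setGeneric("plantedPartition", function(x) standardGeneric("plantedPartition"))
#' @rdname accessors
#' @export
setMethod("plantedPartition", "SyntheticTruth", function(x) x@plantedPartition)

#' @rdname accessors
#' @export
setGeneric("plantedFractions", function(x) standardGeneric("plantedFractions"))
#' @rdname accessors
#' @export
setMethod("plantedFractions", "SyntheticTruth", function(x) x@plantedFractions)

#' @rdname accessors
#' @export
setGeneric("plantedLengthMeanBp",
           function(x) standardGeneric("plantedLengthMeanBp"))
#' @rdname accessors
#' @export
setMethod("plantedLengthMeanBp", "SyntheticTruth",
          function(x) x@plantedLengthMeanBp)

#' @rdname accessors
#' @export
setGeneric("truthFiles", function(x) standardGeneric("truthFiles"))
#' @rdname accessors
#' @export
setMethod("truthFiles", "SyntheticTruth", function(x) x@files)
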