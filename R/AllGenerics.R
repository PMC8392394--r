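#' Accessors for structure and model objects
#'
#' Small accessor generics so downstream code never touches slots directly.
#'
#' @param x an object of the documented class.
#' @return `dotbracket`: the dot-bracket string; `basePairs`: an integer
#'   matrix of 1-based `(i, j)` pairs; `mfe`: the free-energy scalar;
#'   `structureSource`: where the structure came from; `nStems`, `nLoops`,
#'   `nBulges`, `totBases`, `mcpn`: element counts; `regionRatios`: the 10
#'   per-subregion unpaired fractions; `featureManifestOf`: the manifest
#'   list stored in a model.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("dotbracket", function(x) standardGeneric("dotbracket"))
#' @rdname accessors
#' @export
setGeneric("basePairs", function(x) standardGeneric("basePairs"))
#' @rdname accessors
#' @export
setGeneric("mfe", function(x) standardGeneric("mfe"))
#' @rdname accessors
#' @export
setGeneric("structureSource", function(x) standardGeneric("structureSource"))
#' @rdname accessors
#' @export
setGeneric("nStems", function(x) standardGeneric("nStems"))
#' @rdname accessors
#' @export
setGeneric("nLoops", function(x) standardGeneric("nLoops"))
#' @rdname accessors
#' @export
setGeneric("nBulges", function(x) standardGeneric("nBulges"))
#' @rdname accessors
#' @export
setGeneric("totBases", function(x) standardGeneric("totBases"))
#' @rdname accessors
#' @export
setGeneric("mcpn", function(x) standardGeneric("mcpn"))
#' @rdname accessors
#' @export
setGeneric("regionRatios", function(x) standardGeneric("regionRatios"))
#' @rdname accessors
#' @export
setGeneric("featureManifestOf", function(x) standardGeneric("featureManifestOf"))

#' @rdname accessors
#' @export
setMethod("dotbracket", "SecondaryStructure", function(x) x@dotbracket)
#' @rdname accessors
#' @export
setMethod("basePairs", "SecondaryStructure", function(x) x@basePairs)
#' @rdname accessors
#' @export
setMethod("mfe", "SecondaryStructure", function(x) x@mfe)
#' @rdname accessors
#' @export
setMethod("structureSource", "SecondaryStructure", function(x) x@source)
#' @rdname accessors
#' @export
setMethod("nStems", "StructureElements", function(x) x@nStems)
#' @rdname accessors
#' @export
setMethod("nLoops", "StructureElements", function(x) x@nLoops)
#' @rdname accessors
#' @export
setMethod("nBulges", "StructureElements", function(x) x@nBulges)
#' @rdname accessors
#' @export
setMethod("totBases", "StructureElements", function(x) x@totBases)
#' @rdname accessors
#' @export
setMethod("mcpn", "StructureElements", function(x) x@mcpn)
#' @rdname accessors
#' @export
setMethod("regionRatios", "StructureElements", function(x) x@regionRatios)
#' @rdname accessors
#' @export
setMethod("featureManifestOf", "HairpinModel", function(x) x@manifest)
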