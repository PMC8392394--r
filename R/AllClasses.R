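#' @import methods
#' @importFrom stats predict sd var quantile plogis setNames
#' @importFrom utils head write.table read.table
#' @useDynLib hairpinSVM, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom e1071 svm
NULL

#' Secondary structure of an RNA hairpin candidate
#'
#' Holds a nested (pseudoknot-free) secondary structure in dot-bracket
#' notation together with its explicit base-pair list, a free-energy scalar
#' and the provenance of the structure. Coordinates are 1-based inclusive;
#' every pair `(i, j)` satisfies `i < j` and the minimal hairpin-loop
#' constraint `j - i > 3`.
#'
#' @slot dotbracket single string over `(`, `)`, `.`.
#' @slot basePairs integer matrix with columns `i`, `j`, one row per pair,
#'   sorted by `(i, j)`.
#' @slot mfe free energy in kcal/mol for thermodynamic engines, or the
#'   negated pair-weight score (pseudo-energy) for the fallback engine.
#' @slot source one of `"engine"`, `"fallback"`, `"provided"`.
#'
#' @seealso [foldHairpin()], [parseDotBracket()], [readVienna()]
#' @export
setClass("SecondaryStructure",
  representation(dotbracket = "character", basePairs = "matrix",
                 mfe = "numeric", source = "character"),
  prototype(dotbracket = "", basePairs = matrix(integer(0), 0, 2),
            mfe = 0, source = "provided"))

setValidity("SecondaryStructure", function(object) {
  db <- object@dotbracket
  if (length(db) != 1L) return("dotbracket must be a single string")
  chars <- strsplit(db, "")[[1]]
  if (!all(chars %in% c("(", ")", "."))) {
    return("dotbracket may contain only '(', ')' and '.'")
  }
  depth <- cumsum((chars == "(") - (chars == ")"))
  if (length(depth) && (any(depth < 0) || depth[length(depth)] != 0)) {
    return("unbalanced brackets")
  }
  bp <- object@basePairs
  if (ncol(bp) != 2L) return("basePairs must have two columns")
  if (nrow(bp) != sum(chars == "(")) {
    return("basePairs inconsistent with dot-bracket pair count")
  }
  if (nrow(bp)) {
    if (any(bp[, 2] - bp[, 1] <= 3L)) {
      return("hairpin loop shorter than 3 nt (j - i must exceed 3)")
    }
    if (anyDuplicated(as.vector(bp))) {
      return("a position participates in more than one pair")
    }
  }
  if (!object@source %in% c("engine", "fallback", "provided")) {
    return("source must be engine, fallback or provided")
  }
  TRUE
})

#' Structural element decomposition of a hairpin
#'
#' Counts of stems, loops and bulges plus pairing statistics extracted from
#' a [SecondaryStructure-class]. A stem is a run of at least three
#' consecutively stacked base pairs; a bulge is a maximal run of at least
#' three adjacent unpaired nucleotides; a loop is a maximal unpaired run
#' enclosed by at least one base pair.
#'
#' @slot L sequence length (nt).
#' @slot nStems,nLoops,nBulges element counts.
#' @slot totBases number of base pairs.
#' @slot pb,nb paired / unpaired nucleotide counts (`pb + nb == L`).
#' @slot biggestBulge size of the largest bulge (0 when none).
#' @slot mcpn maximum run of consecutive paired nucleotides.
#' @slot pairsByType named counts of A-U, G-C and G-U pairs.
#' @slot regionRatios per-subregion unpaired fraction over 10 contiguous
#'   sequence subregions.
#'
#' @seealso [decomposeStructure()]
#' @export
setClass("StructureElements",
  representation(L = "integer", nStems = "integer", nLoops = "integer",
                 nBulges = "integer", totBases = "integer", pb = "integer",
                 nb = "integer", biggestBulge = "integer", mcpn = "integer",
                 pairsByType = "numeric", regionRatios = "numeric"))

setValidity("StructureElements", function(object) {
  if (object@pb + object@nb != object@L) return("pb + nb must equal L")
  if (object@pb != 2L * object@totBases) return("pb must equal 2*tot_bases")
  if (abs(sum(object@pairsByType) - object@totBases) > 1e-9) {
    return("pair-type counts must sum to tot_bases")
  }
  if (length(object@regionRatios) &&
      (any(object@regionRatios < -1e-12) || any(object@regionRatios > 1 + 1e-12))) {
    return("region ratios must lie in [0, 1]")
  }
  if (object@mcpn > object@pb) return("mcpn cannot exceed pb")
  if (object@biggestBulge > object@nb) return("biggest bulge cannot exceed nb")
  TRUE
})

#' Knowledge-based k-mer pair potential table
#'
#' A pseudo-energy lookup trained by Boltzmann inversion: each entry is
#' `-ln((F+ + eps) / (F- + eps))` where `F+`/`F-` are relative frequencies
#' of a k-mer pair observation (in a position or distance bin) over the
#' positive and negative training sets. Negative entries mark observations
#' enriched in genuine pre-miRNA hairpins.
#'
#' @slot scheme `"position_specific"`, `"distance_specific"` or
#'   `"distance_dependent"`.
#' @slot k word length.
#' @slot nBins number of relative-position or relative-distance bins.
#' @slot entries numeric array of dimension `(4^k, 4^k, nBins)`, word index
#'   lexicographic over A < C < G < U.
#' @slot eps additive smoothing pseudocount.
#' @slot provenance short fingerprint of the training sets.
#'
#' @seealso [trainPotentials()]
#' @export
setClass("PotentialTable",
  representation(scheme = "character", k = "integer", nBins = "integer",
                 entries = "array", eps = "numeric", provenance = "character"))

setValidity("PotentialTable", function(object) {
  if (!object@scheme %in%
      c("position_specific", "distance_specific", "distance_dependent")) {
    return("unknown scheme")
  }
  w <- as.integer(4L^object@k)
  if (!identical(dim(object@entries), c(w, w, object@nBins))) {
    return("entries must be a (4^k, 4^k, nBins) array")
  }
  if (any(!is.finite(object@entries))) return("entries must be finite")
  if (object@eps <= 0) return("eps must be positive")
  TRUE
})

#' The full potential set used by the featurizer
#'
#' Bundles the trained tables that drive the three knowledge-based energy
#' feature blocks: one position-specific 2-mer pair table (34 bins),
#' distance-specific tables for k = 1..5 (one aggregate bin each) and
#' distance-dependent tables for k = 1..3 (20 relative-distance bins each).
#'
#' @slot positionTable a [PotentialTable-class], scheme
#'   `position_specific`.
#' @slot distanceTables list of five `distance_specific` tables (k = 1..5).
#' @slot distanceDependentTables list of three `distance_dependent` tables
#'   (k = 1..3).
#' @export
setClass("HairpinPotentials",
  representation(positionTable = "PotentialTable",
                 distanceTables = "list",
                 distanceDependentTables = "list"))

setValidity("HairpinPotentials", function(object) {
  if (object@positionTable@scheme != "position_specific") {
    return("positionTable must use the position_specific scheme")
  }
  if (length(object@distanceTables) != 5L ||
      !all(vapply(object@distanceTables, function(t) t@scheme,
                  character(1)) == "distance_specific") ||
      !identical(vapply(object@distanceTables, function(t) t@k,
                        integer(1)), 1:5)) {
    return("distanceTables must be distance_specific tables for k = 1..5")
  }
  if (length(object@distanceDependentTables) != 3L ||
      !all(vapply(object@distanceDependentTables, function(t) t@scheme,
                  character(1)) == "distance_dependent") ||
      !identical(vapply(object@distanceDependentTables, function(t) t@k,
                        integer(1)), 1:3)) {
    return("distanceDependentTables must be distance_dependent, k = 1..3")
  }
  TRUE
})

#' A trained hairpin classification model
#'
#' Bundle of everything prediction needs: the z-score scaler fitted on the
#' training features, the RBF-kernel support vector machine, the trained
#' potential tables, the frozen feature manifest, the grid-search record and
#' the training seed. Prediction refuses feature input whose manifest does
#' not match the model's, and never re-estimates scaler or potentials.
#'
#' @slot scaler list with per-feature `mu` and `sigma`.
#' @slot svm fitted `e1071::svm` object.
#' @slot cost,gamma selected penalty and kernel width.
#' @slot decisionSign +1/-1 orientation so positive decision values favour
#'   the positive class.
#' @slot potentials a [HairpinPotentials-class].
#' @slot manifest feature manifest (version string + ordered names).
#' @slot gridRecord data.frame of grid cells with per-fold CV AUCs.
#' @slot seed integer seed used for training.
#' @slot engine folding engine the model was trained with.
#' @export
setClass("HairpinModel",
  representation(scaler = "list", svm = "ANY", cost = "numeric",
                 gamma = "numeric", decisionSign = "numeric",
                 potentials = "HairpinPotentials", manifest = "list",
                 gridRecord = "data.frame", seed = "integer",
                 engine = "character"))

setValidity("HairpinModel", function(object) {
  if (object@cost <= 0) return("C must be positive")
  if (object@gamma <= 0) return("gamma must be positive")
  if (!all(c("version", "names") %in% names(object@manifest))) {
    return("manifest must carry version and names")
  }
  if (!identical(length(object@scaler$mu), length(object@scaler$sigma))) {
    return("scaler mu/sigma length mismatch")
  }
  TRUE
})

setMethod("show", "SecondaryStructure", function(object) {
  n <- nrow(object@basePairs)
  cat(sprintf("SecondaryStructure (%d nt, %d pairs, mfe %.2f, source %s)\n",
              nchar(object@dotbracket), n, object@mfe, object@source))
  cat(" ", object@dotbracket, "\n")
})

setMethod("show", "StructureElements", function(object) {
  cat(sprintf(
    "StructureElements: L=%d stems=%d loops=%d bulges=%d pairs=%d mcpn=%d\n",
    object@L, object@nStems, object@nLoops, object@nBulges,
    object@totBases, object@mcpn))
})

setMethod("show", "PotentialTable", function(object) {
  cat(sprintf("PotentialTable: %s, k=%d, %d bin(s), eps=%.3g [%s]\n",
              object@scheme, object@k, object@nBins, object@eps,
              object@provenance))
})

setMethod("show", "HairpinPotentials", function(object) {
  cat("HairpinPotentials: position-specific 2-mer (34 bins),",
      "distance-specific k=1..5, distance-dependent k=1..3 (20 bins)\n")
})

setMethod("show", "HairpinModel", function(object) {
  cat(sprintf(
    "HairpinModel: RBF-SVM (C=%.4g, gamma=%.4g), %d features [%s], seed %d\n",
    object@cost, object@gamma, length(object@manifest$names),
    object@manifest$version, object@seed))
})
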