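FEATURE_MANIFEST_VERSION <- "hairpinSVM-193-v1"

# block sizes in vector order; the total must be 193
FEATURE_BLOCK_SIZES <- c(position_potential = 34L, distance_potential = 5L,
                         region_ratios = 10L, structure_counts = 4L,
                         dinucleotide_pct = 16L, thermo1 = 5L,
                         pair_per_L = 3L, pair_pct_per_stem = 3L,
                         pairing_misc = 7L, kmer = 80L,
                         distance_dependent = 26L)

#' The frozen 193-feature manifest
#'
#' Feature order and names are fixed and versioned; a trained model stores
#' its manifest and refuses to score vectors built under a different one,
#' guarding against silent column drift between releases.
#'
#' @return List with `version` and the 193 ordered feature `names`.
#' @export
featureManifest <- function() {
  names <- c(
    sprintf("pspot_bin%02d", 1:34),
    sprintf("dspot_k%d", 1:5),
    sprintf("unpaired_ratio_r%02d", 1:10),
    c("biggest_bulge", "n_stems_per_L", "n_loops_per_L", "GC_pct"),
    paste0("pct_", kmerAlphabet(2)),
    c("dG", "MFE1", "MFE2", "dP", "MFE3"),
    c("AU_per_L", "GC_per_L", "GU_per_L"),
    c("pct_AU_per_stem", "pct_GC_per_stem", "pct_GU_per_stem"),
    c("avg_bp_stem1", "pb_nb_ratio", "MCPN", "n_bulges_per_L",
      "avg_bp_stem2", "MFE4", "MFE5"),
    paste0("freq2_", kmerAlphabet(2)),
    paste0("freq3_", kmerAlphabet(3)),
    sprintf("ddpot_bin%02d", 1:20),
    sprintf("ddpot_mean_k%d", 1:3),
    sprintf("ddpot_sd_k%d", 1:3))
  list(version = FEATURE_MANIFEST_VERSION, names = names)
}

#' Train the complete potential set
#'
#' Fits every knowledge-based potential table the featurizer needs from a
#' positive and a negative training set: the position-specific 2-mer pair
#' table (34 relative-position bins), distance-specific tables for
#' k = 1..5 and distance-dependent tables for k = 1..3 with 20
#' relative-distance bins.
#'
#' @param pos,neg training sequences.
#' @param posStructures,negStructures folded structures, parallel to the
#'   sequence sets.
#' @param eps smoothing pseudocount forwarded to [trainPotentials()]
#'   (default: per-table `1 / cells`).
#' @return A [HairpinPotentials-class].
#' @export
trainHairpinPotentials <- function(pos, neg, posStructures, negStructures,
                                   eps = NULL) {
  methods::new("HairpinPotentials",
    positionTable = trainPotentials(pos, neg, "position_specific", k = 2L,
                                    nBins = 34L,
                                    posStructures = posStructures,
                                    negStructures = negStructures,
                                    eps = eps),
    distanceTables = lapply(1:5, function(k) {
      trainPotentials(pos, neg, "distance_specific", k = k, eps = eps)
    }),
    distanceDependentTables = lapply(1:3, function(k) {
      trainPotentials(pos, neg, "distance_dependent", k = k, nBins = 20L,
                      eps = eps)
    }))
}

#' Neutral (all-zero) potentials, useful for featurizing without training
#' @return A [HairpinPotentials-class] whose every entry is 0.
#' @export
zeroHairpinPotentials <- function() {
  zt <- function(scheme, k, nBins) {
    W <- 4L^k
    methods::new("PotentialTable", scheme = scheme, k = as.integer(k),
                 nBins = as.integer(nBins),
                 entries = array(0, dim = c(W, W, nBins)),
                 eps = 1 / (as.numeric(W) * W * nBins), provenance = "zero")
  }
  methods::new("HairpinPotentials",
    positionTable = zt("position_specific", 2L, 34L),
    distanceTables = lapply(1:5, function(k) zt("distance_specific", k, 1L)),
    distanceDependentTables = lapply(1:3, function(k) {
      zt("distance_dependent", k, 20L)
    }))
}

#' Assemble the full 193-dimensional feature vector
#'
#' Concatenates, in fixed manifest order, the position-specific potential
#' scores (34), distance-specific potential scores (5), per-subregion
#' unpaired ratios (10), structure counts (biggest bulge, stems/L, loops/L,
#' GC%), dinucleotide percentages (16), thermodynamic ratios (5 + 3 + 3 +
#' 7), k-mer frequencies (16 + 64) and distance-dependent potential scores
#' (26). The result is a pure function of (residues, dot-bracket, mfe,
#' tables).
#'
#' @param seq the sequence (>= 10 nt).
#' @param ss its [SecondaryStructure-class] (folded or provided).
#' @param potentials a trained (or [zeroHairpinPotentials()])
#'   [HairpinPotentials-class].
#' @param pairPctStyle forwarded to [thermoPairingBlock()].
#' @return Named numeric vector of 193 finite values; degenerate-ratio
#'   flags in `attr(, "degenerate")`.
#' @export
featurizeHairpin <- function(seq, ss, potentials,
                             pairPctStyle = c("per_stems", "per_pairs")) {
  if (!methods::is(potentials, "HairpinPotentials")) {
    stop("potential tables missing: train or use zeroHairpinPotentials()")
  }
  s <- asRnaCharacter(seq)[[1]]
  L <- nchar(s)
  elems <- decomposeStructure(s, ss)
  comp <- compositionBlock(s)
  thermo <- thermoPairingBlock(s, ss, elems, pairPctStyle = pairPctStyle)
  pspot <- scorePositionSpecific(s, ss, potentials@positionTable)
  dspot <- vapply(potentials@distanceTables,
                  function(t) suppressWarnings(scoreDistanceSpecific(s, t)),
                  numeric(1))
  ddpot <- scoreDistanceDependent(s, potentials@distanceDependentTables)
  man <- featureManifest()
  vec <- c(
    stats::setNames(pspot, sprintf("pspot_bin%02d", seq_along(pspot))),
    stats::setNames(dspot, sprintf("dspot_k%d", 1:5)),
    stats::setNames(elems@regionRatios,
                    sprintf("unpaired_ratio_r%02d", 1:10)),
    biggest_bulge = as.numeric(elems@biggestBulge),
    n_stems_per_L = elems@nStems / L,
    n_loops_per_L = elems@nLoops / L,
    GC_pct = comp[["GC_pct"]],
    comp[paste0("pct_", kmerAlphabet(2))],
    thermo[c("dG", "MFE1", "MFE2", "dP", "MFE3")],
    thermo[c("AU_per_L", "GC_per_L", "GU_per_L")],
    thermo[c("pct_AU_per_stem", "pct_GC_per_stem", "pct_GU_per_stem")],
    thermo[c("avg_bp_stem1", "pb_nb_ratio", "MCPN", "n_bulges_per_L",
             "avg_bp_stem2", "MFE4", "MFE5")],
    comp[paste0("freq2_", kmerAlphabet(2))],
    comp[paste0("freq3_", kmerAlphabet(3))],
    ddpot)
  names(vec) <- man$names
  stopifnot(length(vec) == 193L, all(is.finite(vec)))
  attr(vec, "degenerate") <- attr(thermo, "degenerate")
  vec
}

#' Feature matrix for a sequence set
#'
#' @param seqs sequences ([Biostrings::RNAStringSet] or named character).
#' @param structures parallel list of [SecondaryStructure-class]; folded
#'   with `engine` when `NULL`.
#' @param potentials a [HairpinPotentials-class].
#' @param engine folding engine used when `structures` is `NULL`.
#' @inheritParams featurizeHairpin
#' @return Numeric matrix (sequences x 193) with manifest column names and
#'   `attr(, "manifestVersion")`.
#' @export
hairpinFeatureMatrix <- function(seqs, structures = NULL, potentials,
                                 engine = "auto",
                                 pairPctStyle = c("per_stems", "per_pairs")) {
  pairPctStyle <- match.arg(pairPctStyle)
  chars <- asRnaCharacter(seqs)
  if (is.null(structures)) structures <- foldHairpins(chars, engine)
  stopifnot(length(chars) == length(structures))
  man <- featureManifest()
  X <- matrix(NA_real_, nrow = length(chars), ncol = length(man$names),
              dimnames = list(names(chars), man$names))
  for (r in seq_along(chars)) {
    X[r, ] <- featurizeHairpin(chars[[r]], structures[[r]], potentials,
                               pairPctStyle = pairPctStyle)
  }
  attr(X, "manifestVersion") <- man$version
  X
}

#' Write / read a feature matrix as TSV
#'
#' TSV with the sequence id in column 1 and the 193 manifest-named feature
#' columns; the manifest version rides in a `#manifest:` comment line.
#'
#' @param X matrix from [hairpinFeatureMatrix()].
#' @param path file path.
#' @return `writeFeatureTSV`: invisibly, `path`; `readFeatureTSV`: the
#'   matrix with its manifest version attribute restored.
#' @export
writeFeatureTSV <- function(X, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#manifest: ", attr(X, "manifestVersion")), con)
  df <- data.frame(id = rownames(X), X, check.names = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeFeatureTSV
#' @export
readFeatureTSV <- function(path) {
  first <- readLines(path, n = 1L)
  ver <- sub("^#manifest:\\s*", "", first)
  df <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                          check.names = FALSE)
  X <- as.matrix(df[, -1, drop = FALSE])
  rownames(X) <- df[[1]]
  attr(X, "manifestVersion") <- ver
  X
}
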