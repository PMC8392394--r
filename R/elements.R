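#' Decompose a secondary structure into stems, loops and bulges
#'
#' Extracts the structural element counts used by the structure feature
#' block. Definitions: a *stem* is a maximal run of consecutively stacked
#' base pairs `(i, j), (i+1, j-1), ...` of at least 3 pairs; a *bulge* is a
#' maximal run of at least 3 adjacent unpaired nucleotides (by default
#' anywhere in the molecule, including the terminal loop — set
#' `excludeHairpinLoops = TRUE` for the classical definition that excludes
#' runs closed by a single pair); a *loop* is any maximal unpaired run
#' enclosed by at least one base pair (hairpin, interior and bulge loops
#' all count). `mcpn` is the longest run of consecutive paired sequence
#' positions, counted on bracket characters.
#'
#' @param seq the owning sequence (character/RNAString).
#' @param ss a [SecondaryStructure-class] for `seq`.
#' @param excludeHairpinLoops logical; see above.
#' @return A [StructureElements-class].
#' @examples
#' ss <- foldHairpin("GGGGAAAACCCC", engine = "fallback")
#' decomposeStructure("GGGGAAAACCCC", ss)
#' @export
decomposeStructure <- function(seq, ss, excludeHairpinLoops = FALSE) {
  s <- asRnaCharacter(seq)[[1]]
  L <- nchar(s)
  db <- dotbracket(ss)
  if (nchar(db) != L) stop("structure does not belong to this sequence")
  chars <- strsplit(db, "")[[1]]
  paired <- chars != "."
  bp <- basePairs(ss)
  totBases <- nrow(bp)

  # stems: maximal stacked runs of >= 3 pairs
  nStems <- 0L
  if (totBases) {
    ord <- bp[order(bp[, 1]), , drop = FALSE]
    run <- 1L
    for (r in seq_len(totBases)) {
      if (r > 1L && ord[r, 1] == ord[r - 1L, 1] + 1L &&
          ord[r, 2] == ord[r - 1L, 2] - 1L) {
        run <- run + 1L
      } else {
        if (r > 1L && run >= 3L) nStems <- nStems + 1L
        run <- 1L
      }
    }
    if (run >= 3L) nStems <- nStems + 1L
  }

  # maximal unpaired runs with start/end positions
  runs <- rle(paired)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  un <- which(!runs$values)
  runStart <- starts[un]; runEnd <- ends[un]; runLen <- runs$lengths[un]

  # loops: runs enclosed by at least one pair
  enclosed <- logical(length(un))
  if (length(un) && totBases) {
    for (r in seq_along(un)) {
      enclosed[r] <- any(bp[, 1] < runStart[r] & bp[, 2] > runEnd[r])
    }
  }
  nLoops <- sum(enclosed)

  # bulges: unpaired runs of >= 3 nt
  isBulge <- runLen >= 3L
  if (excludeHairpinLoops && any(isBulge) && totBases) {
    closing <- vapply(seq_along(un), function(r) {
      any(bp[, 1] == runStart[r] - 1L & bp[, 2] == runEnd[r] + 1L)
    }, logical(1))
    isBulge <- isBulge & !closing
  }
  nBulges <- sum(isBulge)
  biggestBulge <- if (nBulges) max(runLen[isBulge]) else 0L

  # mcpn on bracket characters
  pr <- rle(paired)
  mcpnVal <- if (any(pr$values)) max(pr$lengths[pr$values]) else 0L

  baseChars <- strsplit(s, "")[[1]]
  pbt <- c(AU = 0, GC = 0, GU = 0)
  if (totBases) {
    types <- vapply(seq_len(totBases), function(r) {
      t <- pairTypeOf(baseChars[bp[r, 1]], baseChars[bp[r, 2]])
      if (is.na(t)) "other" else t
    }, character(1))
    if (any(types == "other")) {
      stop("non-canonical base pair in structure (only A-U, G-C, G-U allowed)")
    }
    tab <- table(factor(types, levels = c("AU", "GC", "GU")))
    pbt <- c(AU = as.numeric(tab["AU"]), GC = as.numeric(tab["GC"]),
             GU = as.numeric(tab["GU"]))
  }

  ratios <- if (L >= 10L) unpairedRegionRatios(s, ss) else numeric(0)

  methods::new("StructureElements", L = L, nStems = as.integer(nStems),
               nLoops = as.integer(nLoops), nBulges = as.integer(nBulges),
               totBases = as.integer(totBases),
               pb = as.integer(sum(paired)), nb = as.integer(sum(!paired)),
               biggestBulge = as.integer(biggestBulge),
               mcpn = as.integer(mcpnVal), pairsByType = pbt,
               regionRatios = ratios)
}

#' Per-subregion unpaired-nucleotide ratios
#'
#' Cuts the sequence positions `1..L` into 10 contiguous subregions of size
#' `floor(L/10)` or `ceiling(L/10)` (the first `L mod 10` regions take the
#' extra position) and returns, for each region, the fraction of unpaired
#' positions. Conservation holds exactly: the region ratios weighted by
#' region sizes sum to the total unpaired count.
#'
#' @inheritParams decomposeStructure
#' @return Numeric vector of 10 ratios in `[0, 1]`.
#' @export
unpairedRegionRatios <- function(seq, ss) {
  s <- asRnaCharacter(seq)[[1]]
  L <- nchar(s)
  if (L < 10L) stop("sequence shorter than 10 nt cannot be cut into 10 regions")
  chars <- strsplit(dotbracket(ss), "")[[1]]
  if (length(chars) != L) stop("structure does not belong to this sequence")
  base <- L %/% 10L
  extra <- L %% 10L
  sizes <- rep(base, 10L) + c(rep(1L, extra), rep(0L, 10L - extra))
  region <- rep(seq_len(10L), times = sizes)
  unpaired <- chars == "."
  as.numeric(tapply(unpaired, region, mean))
}
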