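#' Pseudo-hairpin similarity filters learned from a positive set
#'
#' "Sufficient similarity" between pseudo and genuine pre-miRNAs is
#' operationalized with three checks applied to a folded candidate window:
#' it must contain at least one stem (>= 3 stacked pairs), its paired
#' fraction `dP = tot_bases/L` must fall inside the range observed in the
#' positive set, and its energy density `dG = mfe/L` must fall inside the
#' positive set's observed range. Ranges default to the positive min/max;
#' `trim` moves them to the (`trim`, `1 - trim`) quantiles.
#'
#' @param pos positive sequences.
#' @param posStructures their folded structures (same engine that will fold
#'   the candidate windows).
#' @param trim percentile trimming in `[0, 0.5)`.
#' @return List with `lengths` (empirical window-length pool), `dpRange`
#'   and `dgRange`.
#' @export
pseudoFilterFromPositives <- function(pos, posStructures, trim = 0) {
  chars <- asRnaCharacter(pos)
  stopifnot(length(chars) >= 1L, length(chars) == length(posStructures))
  dp <- vapply(seq_along(chars), function(r) {
    nrow(basePairs(posStructures[[r]])) / nchar(chars[[r]])
  }, numeric(1))
  dg <- vapply(seq_along(chars), function(r) {
    mfe(posStructures[[r]]) / nchar(chars[[r]])
  }, numeric(1))
  rng <- function(x) {
    if (trim > 0) as.numeric(stats::quantile(x, c(trim, 1 - trim)))
    else range(x)
  }
  list(lengths = nchar(chars), dpRange = rng(dp), dgRange = rng(dg))
}

passesPseudoFilter <- function(ss, L, filter) {
  bp <- basePairs(ss)
  if (!nrow(bp)) return(FALSE)
  ord <- bp[order(bp[, 1]), , drop = FALSE]
  run <- 1L; hasStem <- FALSE
  if (nrow(ord) >= 3L) {
    for (r in 2:nrow(ord)) {
      if (ord[r, 1] == ord[r - 1L, 1] + 1L && ord[r, 2] == ord[r - 1L, 2] - 1L) {
        run <- run + 1L
        if (run >= 3L) { hasStem <- TRUE; break }
      } else run <- 1L
    }
  }
  if (!hasStem) return(FALSE)
  dp <- nrow(bp) / L
  if (dp < filter$dpRange[1] || dp > filter$dpRange[2]) return(FALSE)
  dg <- mfe(ss) / L
  dg >= filter$dgRange[1] && dg <= filter$dgRange[2]
}

#' Construct pseudo pre-miRNA negatives from coding sequence
#'
#' Samples candidate windows from CDS records at lengths drawn from the
#' positive set's empirical length distribution, converts T to U, folds
#' each window and keeps those passing the similarity filters of
#' [pseudoFilterFromPositives()]. Accepted windows never overlap a
#' previously accepted window of the same source record, which avoids
#' near-duplicate negatives. Reproducible under `seed`.
#'
#' @param cds CDS records ([Biostrings::RNAStringSet] / named character;
#'   DNA-coded input is converted).
#' @param nWanted number of negatives requested.
#' @param filter output of [pseudoFilterFromPositives()].
#' @param seed integer seed.
#' @param engine folding engine (must match the one used for the filter).
#' @param maxAttempts sampling budget; when exhausted, fewer records are
#'   returned with a warning.
#' @return [Biostrings::RNAStringSet] with provenance headers
#'   `sourceId:start-end` (1-based inclusive).
#' @export
extractPseudoHairpins <- function(cds, nWanted, filter, seed = 1L,
                                  engine = "auto",
                                  maxAttempts = 200L * nWanted) {
  chars <- chartr("Tt", "Uu", toupper(asRnaCharacter(cds)))
  if (!length(chars)) stop("CDS set is empty")
  engine <- resolveEngine(engine)
  used <- lapply(chars, function(x) IRanges::IRanges())
  out <- character(0)
  ids <- character(0)
  withSeed(seed, {
    attempts <- 0L
    batch <- max(16L, min(256L, nWanted))
    while (length(out) < nWanted && attempts < maxAttempts) {
      n <- min(batch, maxAttempts - attempts)
      src <- sample(length(chars), n, replace = TRUE)
      wlen <- sample(filter$lengths, n, replace = TRUE)
      keepIdx <- which(nchar(chars)[src] >= wlen & wlen >= 10L)
      cand <- character(0); candId <- character(0)
      candRange <- list()
      for (q in keepIdx) {
        Lsrc <- nchar(chars[[src[q]]])
        start <- sample.int(Lsrc - wlen[q] + 1L, 1L)
        rng <- IRanges::IRanges(start, start + wlen[q] - 1L)
        if (length(IRanges::findOverlaps(rng, used[[src[q]]]))) next
        cand <- c(cand, substr(chars[[src[q]]], start, start + wlen[q] - 1L))
        candId <- c(candId, sprintf("%s:%d-%d", names(chars)[src[q]],
                                    start, start + wlen[q] - 1L))
        candRange[[length(cand)]] <- list(src = src[q], rng = rng)
      }
      attempts <- attempts + n
      if (!length(cand)) next
      sss <- foldHairpins(stats::setNames(cand, candId), engine)
      for (q in seq_along(cand)) {
        if (length(out) >= nWanted) break
        si <- candRange[[q]]$src
        # re-check: an earlier acceptance in this batch may now overlap
        if (length(IRanges::findOverlaps(candRange[[q]]$rng, used[[si]]))) {
          next
        }
        if (passesPseudoFilter(sss[[q]], nchar(cand[q]), filter)) {
          out <- c(out, cand[q])
          ids <- c(ids, candId[q])
          used[[si]] <- c(used[[si]], candRange[[q]]$rng)
        }
      }
    }
  })
  if (length(out) < nWanted) {
    warning("only ", length(out), " of ", nWanted,
            " pseudo hairpins found within the attempt budget")
  }
  res <- Biostrings::RNAStringSet(out)
  names(res) <- ids
  res
}
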