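positionBin <- function(i, L, nBins) {
  pmin(as.integer(floor(nBins * (i - 1) / L)) + 1L, nBins)
}

distanceBin <- function(d, L, nBins) {
  pmin(as.integer(floor(nBins * d / L)) + 1L, nBins)
}

# structure-contact observations: for each base pair (i, j), the k-mer
# starting at i paired with the k-mer ending at j, binned by relative
# position i/L
contactObservations <- function(codes, bp, k, nBins) {
  L <- length(codes)
  w <- kmerIndices(codes, k)
  if (!nrow(bp) || !length(w)) {
    return(cbind(u = integer(0), v = integer(0), b = integer(0)))
  }
  i <- bp[, 1]; j <- bp[, 2]
  keep <- (i + k - 1L <= L) & (j - k + 1L >= 1L)
  i <- i[keep]; j <- j[keep]
  if (!length(i)) return(cbind(u = integer(0), v = integer(0), b = integer(0)))
  cbind(u = w[i], v = w[j - k + 1L], b = positionBin(i, L, nBins))
}

countsPositionSpecific <- function(seqsChars, structures, k, nBins) {
  W <- 4L^k
  C <- array(0, dim = c(W, W, nBins))
  for (r in seq_along(seqsChars)) {
    obs <- contactObservations(seqToCodes(seqsChars[[r]]),
                               basePairs(structures[[r]]), k, nBins)
    if (nrow(obs)) {
      idx <- (obs[, "b"] - 1L) * W * W + (obs[, "v"] - 1L) * W + obs[, "u"]
      t <- tabulate(idx, nbins = W * W * nBins)
      C <- C + array(t, dim = c(W, W, nBins))
    }
  }
  C
}

countsDistanceSpecific <- function(seqsChars, k) {
  W <- 4L^k
  C <- matrix(0, W, W)
  for (s in seqsChars) {
    w <- kmerIndices(seqToCodes(s), k)
    n <- length(w)
    if (n < 2L) next
    cnt <- numeric(W)
    for (j in 2:n) {
      cnt[w[j - 1L]] <- cnt[w[j - 1L]] + 1
      C[, w[j]] <- C[, w[j]] + cnt
    }
  }
  array(C, dim = c(W, W, 1L))
}

countsDistanceDependent <- function(seqsChars, k, nBins) {
  W <- 4L^k
  C <- array(0, dim = c(W, W, nBins))
  for (s in seqsChars) {
    codes <- seqToCodes(s)
    L <- length(codes)
    w <- kmerIndices(codes, k)
    n <- length(w)
    if (n < 2L) next
    for (d in seq_len(n - 1L)) {
      b <- distanceBin(d, L, nBins)
      u <- w[seq_len(n - d)]
      v <- w[seq_len(n - d) + d]
      t <- tabulate((v - 1L) * W + u, nbins = W * W)
      C[, , b] <- C[, , b] + t
    }
  }
  C
}

#' Train a knowledge-based k-mer pair potential table
#'
#' Boltzmann inversion of word-pair observation frequencies: each entry is
#' `-ln((F+ + eps) / (F- + eps))`, where `F+` and `F-` are the relative
#' frequencies of the observation over the positive (genuine hairpin) and
#' negative (pseudo hairpin) training sets. Entries are negative where the
#' observation is enriched in positives, zero where the smoothed
#' frequencies agree, and swapping the two training sets negates the whole
#' table.
#'
#' Three observation schemes are supported:
#' \describe{
#'   \item{`position_specific`}{for every base pair `(i, j)` of a folded
#'     structure, the k-mer starting at `i` paired with the k-mer ending at
#'     `j`, binned by relative 5' position `i/L` into `nBins` bins
#'     (structures required).}
#'   \item{`distance_specific`}{every ordered pair of overlapping k-mer
#'     windows `i < j`, one aggregate bin (sequence only).}
#'   \item{`distance_dependent`}{the same window pairs binned by relative
#'     distance `floor(nBins * (j - i) / L)`, last bin closed.}
#' }
#'
#' @param pos,neg positive / negative training sequences
#'   ([Biostrings::RNAStringSet] or character vectors).
#' @param scheme observation scheme (above).
#' @param k word length (1-5).
#' @param nBins number of bins (ignored for `distance_specific`, which has
#'   one).
#' @param posStructures,negStructures lists of [SecondaryStructure-class],
#'   required for `position_specific`.
#' @param eps additive smoothing pseudocount; defaults to one over the
#'   number of table cells.
#' @return A [PotentialTable-class].
#' @examples
#' tab <- trainPotentials(c("ACGUACGUACGU"), c("AAAAUUUUAAAA"),
#'                        scheme = "distance_specific", k = 1)
#' @export
trainPotentials <- function(pos, neg,
                            scheme = c("position_specific",
                                       "distance_specific",
                                       "distance_dependent"),
                            k = 2L, nBins = 1L,
                            posStructures = NULL, negStructures = NULL,
                            eps = NULL) {
  scheme <- match.arg(scheme)
  posC <- asRnaCharacter(pos)
  negC <- asRnaCharacter(neg)
  if (!length(posC) || !length(negC)) {
    stop("both training classes must be non-empty")
  }
  if (any(nchar(c(posC, negC)) < k)) {
    stop("k exceeds the shortest training sequence")
  }
  k <- as.integer(k)
  nBins <- as.integer(if (scheme == "distance_specific") 1L else nBins)
  W <- 4L^k
  if (is.null(eps)) eps <- 1 / (as.numeric(W) * W * nBins)
  counts <- switch(scheme,
    position_specific = {
      if (is.null(posStructures) || is.null(negStructures)) {
        stop("position_specific training needs folded structures")
      }
      list(p = countsPositionSpecific(posC, posStructures, k, nBins),
           n = countsPositionSpecific(negC, negStructures, k, nBins))
    },
    distance_specific = list(p = countsDistanceSpecific(posC, k),
                             n = countsDistanceSpecific(negC, k)),
    distance_dependent = list(p = countsDistanceDependent(posC, k, nBins),
                              n = countsDistanceDependent(negC, k, nBins)))
  fp <- if (sum(counts$p) > 0) counts$p / sum(counts$p) else counts$p
  fn <- if (sum(counts$n) > 0) counts$n / sum(counts$n) else counts$n
  entries <- -log((fp + eps) / (fn + eps))
  methods::new("PotentialTable", scheme = scheme, k = k, nBins = nBins,
               entries = entries, eps = eps,
               provenance = sprintf("pos=%d neg=%d obs=%g/%g",
                                    length(posC), length(negC),
                                    sum(counts$p), sum(counts$n)))
}

#' Score a sequence with a distance-specific potential
#'
#' Mean potential over all ordered pairs of overlapping k-mer windows
#' `i < j` — the mean (not the sum) keeps the feature comparable across
#' sequence lengths. A sequence too short to form any window pair scores 0
#' with a warning.
#'
#' @param seq the sequence.
#' @param table a `distance_specific` [PotentialTable-class].
#' @return A single pseudo-energy score.
#' @export
scoreDistanceSpecific <- function(seq, table) {
  stopifnot(table@scheme == "distance_specific")
  w <- kmerIndices(seqToCodes(asRnaCharacter(seq)[[1]]), table@k)
  n <- length(w)
  if (n < 2L) {
    warning("sequence too short for any k-mer pair; score 0")
    return(0)
  }
  E <- table@entries[, , 1L]
  W <- 4L^table@k
  cnt <- numeric(W)
  s <- 0
  for (j in 2:n) {
    cnt[w[j - 1L]] <- cnt[w[j - 1L]] + 1
    s <- s + sum(cnt * E[, w[j]])
  }
  s / (n * (n - 1) / 2)
}

#' Score structure contacts with a position-specific potential
#'
#' For every base pair `(i, j)` of the structure the contact `(k-mer at i,
#' k-mer ending at j)` is looked up and assigned to the relative-position
#' bin of `i/L`; the return is the per-bin mean potential (0 for bins with
#' no contact), one feature per bin.
#'
#' @param seq the sequence.
#' @param ss its [SecondaryStructure-class].
#' @param table a `position_specific` [PotentialTable-class].
#' @return Numeric vector of length `table@nBins`.
#' @export
scorePositionSpecific <- function(seq, ss, table) {
  stopifnot(table@scheme == "position_specific")
  codes <- seqToCodes(asRnaCharacter(seq)[[1]])
  obs <- contactObservations(codes, basePairs(ss), table@k, table@nBins)
  out <- numeric(table@nBins)
  if (nrow(obs)) {
    vals <- table@entries[cbind(obs[, "u"], obs[, "v"], obs[, "b"])]
    m <- tapply(vals, factor(obs[, "b"], levels = seq_len(table@nBins)), mean)
    out[!is.na(m)] <- m[!is.na(m)]
  }
  out
}

#' Score a sequence with distance-dependent potentials (k = 1..3)
#'
#' Window pairs are binned by relative distance into `nBins` (20) bins per
#' table. The 26 features are: the 20 per-bin mean potentials pooled
#' (averaged) over k = 1..3, then the per-k mean and per-k standard
#' deviation of each k's 20 per-bin scores. Empty bins score 0.
#'
#' @param seq the sequence.
#' @param tables list of three `distance_dependent`
#'   [PotentialTable-class] objects for k = 1, 2, 3 with equal `nBins`.
#' @return Named numeric vector of `nBins + 6` values.
#' @export
scoreDistanceDependent <- function(seq, tables) {
  stopifnot(length(tables) == 3L)
  nBins <- tables[[1]]@nBins
  codes <- seqToCodes(asRnaCharacter(seq)[[1]])
  L <- length(codes)
  perK <- matrix(0, nrow = nBins, ncol = 3L)
  for (t in seq_along(tables)) {
    tab <- tables[[t]]
    stopifnot(tab@scheme == "distance_dependent", tab@nBins == nBins)
    w <- kmerIndices(codes, tab@k)
    n <- length(w)
    if (n < 2L) next
    sums <- numeric(nBins)
    cnts <- numeric(nBins)
    E <- tab@entries
    for (d in seq_len(n - 1L)) {
      b <- distanceBin(d, L, nBins)
      u <- w[seq_len(n - d)]
      v <- w[seq_len(n - d) + d]
      sums[b] <- sums[b] + sum(E[cbind(u, v, rep(b, length(u)))])
      cnts[b] <- cnts[b] + length(u)
    }
    perK[, t] <- ifelse(cnts > 0, sums / pmax(cnts, 1), 0)
  }
  pooled <- rowMeans(perK)
  stats::setNames(
    c(pooled, colMeans(perK), apply(perK, 2, stats::sd)),
    c(sprintf("ddpot_bin%02d", seq_len(nBins)),
      sprintf("ddpot_mean_k%d", 1:3), sprintf("ddpot_sd_k%d", 1:3)))
}
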