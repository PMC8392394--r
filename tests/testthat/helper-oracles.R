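# Independent brute-force oracles. These deliberately share no code with
# the package internals they check.

oraclePairWeight <- function(a, b) {
  key <- paste(sort(c(a, b)), collapse = "")
  if (key == "CG") 3 else if (key == "AU") 2 else if (key == "GU") 1 else 0
}

# every nested structure over positions i..j (min loop 3, canonical pairs),
# as a list of 2-column pair matrices (NULL = no pairs)
enumerateStructures <- function(chars, i, j) {
  if (j - i < 4) return(list(NULL))
  out <- enumerateStructures(chars, i + 1, j)  # i unpaired
  for (k in (i + 4):j) {
    if (oraclePairWeight(chars[i], chars[k]) == 0) next
    inner <- enumerateStructures(chars, i + 1, k - 1)
    right <- if (k + 1 <= j) enumerateStructures(chars, k + 1, j)
             else list(NULL)
    for (a in inner) for (b in right) {
      out <- c(out, list(rbind(c(i, k), a, b)))
    }
  }
  out
}

oracleScore <- function(chars, pairs) {
  if (is.null(pairs)) return(0)
  sum(apply(pairs, 1, function(p) oraclePairWeight(chars[p[1]], chars[p[2]])))
}

# lexicographic comparison of pair sets sorted by (i, j); TRUE if a < b
pairSetLess <- function(a, b) {
  av <- if (is.null(a)) numeric(0) else as.vector(t(a[order(a[, 1], a[, 2]), , drop = FALSE]))
  bv <- if (is.null(b)) numeric(0) else as.vector(t(b[order(b[, 1], b[, 2]), , drop = FALSE]))
  n <- min(length(av), length(bv))
  if (n > 0) {
    for (t in seq_len(n)) {
      if (av[t] < bv[t]) return(TRUE)
      if (av[t] > bv[t]) return(FALSE)
    }
  }
  length(av) < length(bv)
}

# exhaustive fold: max score, ties broken to the lexicographically
# smallest pair set
oracleFold <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  structs <- enumerateStructures(chars, 1, length(chars))
  scores <- vapply(structs, function(s) oracleScore(chars, s), numeric(1))
  best <- which(scores == max(scores))
  pick <- structs[[best[1]]]
  if (length(best) > 1) {
    for (bidx in best[-1]) {
      if (pairSetLess(structs[[bidx]], pick)) pick <- structs[[bidx]]
    }
  }
  sorted <- if (is.null(pick)) matrix(numeric(0), 0, 2)
            else pick[order(pick[, 1], pick[, 2]), , drop = FALSE]
  list(score = max(scores), pairs = sorted)
}

# O(n^2) pairwise AUC with ties counted half
oracleAuc <- function(scores, labels) {
  p <- scores[labels == 1]
  n <- scores[labels == 0]
  tot <- 0
  for (a in p) for (b in n) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(p) * length(n))
}

# naive overlapping k-mer counter
oracleKmerCount <- function(seq, kmer) {
  k <- nchar(kmer)
  L <- nchar(seq)
  if (L < k) return(0)
  sum(vapply(seq_len(L - k + 1), function(i) {
    substr(seq, i, i + k - 1) == kmer
  }, logical(1)))
}

randomRnaSeq <- function(L) {
  paste(sample(c("A", "C", "G", "U"), L, replace = TRUE), collapse = "")
}

kmersOf <- function(k) {
  B <- c("A", "C", "G", "U")
  sort(apply(do.call(expand.grid, rep(list(B), k)), 1, paste, collapse = ""))
}
kmers2 <- function() kmersOf(2)
kmers3 <- function() kmersOf(3)
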