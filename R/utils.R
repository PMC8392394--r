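RNA_BASES <- c("A", "C", "G", "U")

# Run a generator body under a fixed seed without clobbering the caller's
# RNG state; all synthetic-data functions are pure in (params, seed).
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  eval.parent(substitute(expr))
}

# 1-based integer codes A=1 C=2 G=3 U=4
seqToCodes <- function(x) {
  m <- match(strsplit(as.character(x), "")[[1]], RNA_BASES)
  if (anyNA(m)) stop("sequence contains non-AUCG characters")
  m
}

# index of the k-mer starting at each position (1 .. 4^k), NA-free by pre
kmerIndices <- function(codes, k) {
  L <- length(codes)
  if (L < k) return(integer(0))
  idx <- integer(L - k + 1L)
  for (t in seq_len(k)) {
    idx <- idx * 4L + (codes[t:(L - k + t)] - 1L)
  }
  idx + 1L
}

# all k-mers of the RNA alphabet in lexicographic order (A < C < G < U)
kmerAlphabet <- function(k) {
  g <- do.call(expand.grid, c(rep(list(RNA_BASES), k),
                              stringsAsFactors = FALSE))
  sort(apply(g, 1L, paste, collapse = ""))
}

reverseComplementRNA <- function(x) {
  chartr("AUCG", "UAGC", paste(rev(strsplit(x, "")[[1]]), collapse = ""))
}

pairTypeOf <- function(a, b) {
  key <- paste(sort(c(a, b)), collapse = "")
  switch(key, "AU" = "AU", "CG" = "GC", "GU" = "GU", NA_character_)
}

asRnaCharacter <- function(seqs) {
  if (methods::is(seqs, "XStringSet")) {
    out <- as.character(seqs)
    if (is.null(names(out))) names(out) <- paste0("seq", seq_along(out))
    out
  } else if (is.character(seqs)) {
    if (is.null(names(seqs)) && length(seqs)) {
      names(seqs) <- paste0("seq", seq_along(seqs))
    }
    seqs
  } else if (methods::is(seqs, "XString")) {
    stats::setNames(as.character(seqs), "seq1")
  } else {
    stop("sequences must be an RNAStringSet, RNAString or character vector")
  }
}
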