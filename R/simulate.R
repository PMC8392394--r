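# fixed codon pool for synthetic CDS: all sense codons, uniform weights
senseCodons <- function() setdiff(kmerAlphabet(3), c("UAA", "UAG", "UGA"))

#' Generate a synthetic pre-miRNA-like stem-loop
#'
#' Builds a hairpin the way curated plant pre-miRNA hairpins look to a
#' folding algorithm: a uniformly sampled 5' arm, a loop, and a 3' arm
#' that is the reverse complement of the 5' arm with independent
#' per-position mutations. Pure function of its parameters and `seed`.
#'
#' @param stemLen number of arm positions (>= 3).
#' @param loopLen loop length in nt (>= 3).
#' @param mutationRate per-position mutation probability on the 3' arm.
#' @param seed integer seed.
#' @return A single character string of length `2*stemLen + loopLen`.
#' @examples
#' makeHairpin(10, 5, 0, seed = 7)
#' @export
makeHairpin <- function(stemLen, loopLen = 6L, mutationRate = 0, seed = 1L) {
  stopifnot(stemLen >= 3L, loopLen >= 3L,
            mutationRate >= 0, mutationRate < 1)
  withSeed(seed, {
    arm5 <- sample(RNA_BASES, stemLen, replace = TRUE)
    loop <- sample(RNA_BASES, loopLen, replace = TRUE)
    arm3 <- strsplit(reverseComplementRNA(paste(arm5, collapse = "")),
                     "")[[1]]
    mut <- stats::runif(stemLen) < mutationRate
    if (any(mut)) {
      arm3[mut] <- vapply(arm3[mut], function(b) {
        sample(setdiff(RNA_BASES, b), 1L)
      }, character(1))
    }
    paste(c(arm5, loop, arm3), collapse = "")
  })
}

#' Generate a synthetic coding sequence
#'
#' RNA-coded CDS: starts with `AUG`, then `nCodons - 2` codons drawn
#' uniformly from the 61 sense codons (so no in-frame stop), and a
#' terminal stop codon.
#'
#' @param nCodons total codon count including start and stop (>= 10).
#' @param seed integer seed.
#' @return A character string of length `3 * nCodons`.
#' @export
makeCds <- function(nCodons, seed = 1L) {
  stopifnot(nCodons >= 10L)
  withSeed(seed, {
    body <- sample(senseCodons(), nCodons - 2L, replace = TRUE)
    stop <- sample(c("UAA", "UAG", "UGA"), 1L)
    paste(c("AUG", body, stop), collapse = "")
  })
}

sampleCdsWindow <- function(cdsPool, len) {
  repeat {
    src <- sample(length(cdsPool), 1L)
    if (nchar(cdsPool[src]) >= len) break
  }
  start <- sample.int(nchar(cdsPool[src]) - len + 1L, 1L)
  substr(cdsPool[src], start, start + len - 1L)
}

#' Generate a labelled hairpin-vs-CDS benchmark
#'
#' Positives are synthetic stem-loops (arm length 18-30 pairs, loop 4-10
#' nt); negatives are windows cut from synthetic CDS at the same length
#' distribution. `difficulty` in `[0, 1]` is the single separability knob:
#' the hairpin arms mutate at rate `0.4 * difficulty`, and above
#' `difficulty = 0.5` positives are additionally replaced, with probability
#' `2 * difficulty - 1`, by an independent draw from the same CDS-window
#' sampler the negatives use (the structure-destroying regime). At
#' `difficulty = 1` every positive is such a draw, the two classes are
#' exchangeable by construction, and any classifier's cross-validated AUC
#' sits at chance.
#'
#' @param nPos,nNeg class sizes.
#' @param difficulty separability knob in `[0, 1]`.
#' @param seed integer seed.
#' @return List with `pos` and `neg` ([Biostrings::RNAStringSet]) and
#'   `labels` (data.frame of `id`, `label`).
#' @examples
#' b <- makeBenchmark(20, 20, difficulty = 0.1, seed = 1)
#' @export
makeBenchmark <- function(nPos, nNeg, difficulty = 0.1, seed = 1L) {
  stopifnot(difficulty >= 0, difficulty <= 1)
  withSeed(seed, {
    nCds <- max(4L, ceiling((nPos + nNeg) / 10))
    cdsPool <- vapply(seq_len(nCds), function(i) {
      makeCds(120L, seed = sample.int(.Machine$integer.max, 1L))
    }, character(1))
    drawLen <- function() 2L * sample(18:30, 1L) + sample(4:10, 1L)
    replaceFrac <- max(0, 2 * difficulty - 1)
    pos <- vapply(seq_len(nPos), function(i) {
      if (stats::runif(1) < replaceFrac) {
        sampleCdsWindow(cdsPool, drawLen())
      } else {
        makeHairpin(sample(18:30, 1L), sample(4:10, 1L),
                    mutationRate = 0.4 * difficulty,
                    seed = sample.int(.Machine$integer.max, 1L))
      }
    }, character(1))
    neg <- vapply(seq_len(nNeg), function(i) {
      sampleCdsWindow(cdsPool, drawLen())
    }, character(1))
    posSet <- Biostrings::RNAStringSet(stats::setNames(
      pos, sprintf("pos_%04d", seq_len(nPos))))
    negSet <- Biostrings::RNAStringSet(stats::setNames(
      neg, sprintf("neg_%04d", seq_len(nNeg))))
    list(pos = posSet, neg = negSet,
         labels = data.frame(id = c(names(posSet), names(negSet)),
                             label = c(rep(1L, nPos), rep(0L, nNeg))))
  })
}
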