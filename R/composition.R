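#' Sequence-composition feature block
#'
#' GC percentage, overlapping dinucleotide percentages and overlapping
#' k-mer frequencies (k = 2 and 3) in fixed lexicographic order
#' (A < C < G < U). Dinucleotide percentages are counts over the `L - 1`
#' windows times 100; k-mer frequencies are counts over the `L - k + 1`
#' windows (so each k's frequencies sum to 1).
#'
#' @param seq character / RNAString of length at least 3 nt.
#' @return Named numeric vector: `GC_pct`, `pct_AA` .. `pct_UU` (16),
#'   `freq2_AA` .. (16), `freq3_AAA` .. (64).
#' @examples
#' compositionBlock("ACGU")
#' @export
compositionBlock <- function(seq) {
  s <- asRnaCharacter(seq)[[1]]
  L <- nchar(s)
  if (L < 3L) stop("sequence shorter than 3 nt")
  rna <- Biostrings::RNAString(s)
  mono <- Biostrings::oligonucleotideFrequency(rna, 1L)
  di <- Biostrings::oligonucleotideFrequency(rna, 2L)
  tri <- Biostrings::oligonucleotideFrequency(rna, 3L)
  gc <- (mono[["G"]] + mono[["C"]]) / L * 100
  pctXY <- di / (L - 1L) * 100
  f2 <- di / (L - 1L)
  f3 <- tri / (L - 2L)
  c(GC_pct = gc,
    stats::setNames(as.numeric(pctXY), paste0("pct_", names(di))),
    stats::setNames(as.numeric(f2), paste0("freq2_", names(di))),
    stats::setNames(as.numeric(f3), paste0("freq3_", names(tri))))
}

safeRatio <- function(num, den) if (den == 0) 0 else num / den

#' Thermodynamic and pairing ratio feature block
#'
#' The 18 structure/energy ratios: `dG = MFE/L`, `MFE1 = dG/GC%`,
#' `MFE2 = dG/n_stems`, `dP = tot_bases/L`, `MFE3 = dG/n_loops`, the three
#' per-length pair-type counts `|X-Y|/L`, the three `%(X-Y)/n_stems`
#' ratios, `Avg_bp_stem1 = tot_bases/n_stems`, `pb/nb`, `MCPN`,
#' `n_bulges/L`, `Avg_bp_stem2 = pb/n_stems`, `MFE4 = dG/tot_bases` and
#' `MFE5 = dG/n_bulges`. Any ratio with a zero denominator is emitted as 0
#' and the offending feature names are collected in `attr(, "degenerate")`,
#' so hairpin-less candidates remain scoreable.
#'
#' `%(X-Y)/n_stems` is computed literally as
#' `(|X-Y|/n_stems * 100) / n_stems`; set `pairPctStyle = "per_pairs"` for
#' the alternative reading `(|X-Y|/tot_bases * 100) / n_stems`.
#'
#' @param seq the sequence.
#' @param ss its [SecondaryStructure-class].
#' @param elems the matching [StructureElements-class] from
#'   [decomposeStructure()].
#' @param pairPctStyle `"per_stems"` (literal, default) or `"per_pairs"`.
#' @return Named numeric vector of 18 values.
#' @export
thermoPairingBlock <- function(seq, ss, elems,
                               pairPctStyle = c("per_stems", "per_pairs")) {
  pairPctStyle <- match.arg(pairPctStyle)
  s <- asRnaCharacter(seq)[[1]]
  L <- nchar(s)
  energy <- mfe(ss)
  if (is.na(energy)) stop("structure has no free energy; fold or provide one")
  dG <- energy / L
  gc <- (sum(strsplit(s, "")[[1]] %in% c("G", "C"))) / L * 100
  ns <- elems@nStems; nl <- elems@nLoops; nbl <- elems@nBulges
  tb <- elems@totBases; pb <- elems@pb; nb <- elems@nb
  pbt <- elems@pairsByType
  pctDen <- if (pairPctStyle == "per_stems") ns else tb
  pctXY <- vapply(pbt, function(x) safeRatio(x * 100, pctDen), numeric(1))
  out <- c(
    dG = dG,
    MFE1 = safeRatio(dG, gc),
    MFE2 = safeRatio(dG, ns),
    dP = tb / L,
    MFE3 = safeRatio(dG, nl),
    AU_per_L = pbt[["AU"]] / L,
    GC_per_L = pbt[["GC"]] / L,
    GU_per_L = pbt[["GU"]] / L,
    pct_AU_per_stem = safeRatio(pctXY[["AU"]], ns),
    pct_GC_per_stem = safeRatio(pctXY[["GC"]], ns),
    pct_GU_per_stem = safeRatio(pctXY[["GU"]], ns),
    avg_bp_stem1 = safeRatio(tb, ns),
    pb_nb_ratio = safeRatio(pb, nb),
    MCPN = as.numeric(elems@mcpn),
    n_bulges_per_L = nbl / L,
    avg_bp_stem2 = safeRatio(pb, ns),
    MFE4 = safeRatio(dG, tb),
    MFE5 = safeRatio(dG, nbl))
  degenerate <- character(0)
  if (gc == 0) degenerate <- c(degenerate, "MFE1")
  if (ns == 0) degenerate <- c(degenerate, "MFE2", "pct_AU_per_stem",
                               "pct_GC_per_stem", "pct_GU_per_stem",
                               "avg_bp_stem1", "avg_bp_stem2")
  if (nl == 0) degenerate <- c(degenerate, "MFE3")
  if (nb == 0) degenerate <- c(degenerate, "pb_nb_ratio")
  if (tb == 0) degenerate <- c(degenerate, "MFE4")
  if (nbl == 0) degenerate <- c(degenerate, "MFE5")
  attr(out, "degenerate") <- degenerate
  out
}
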