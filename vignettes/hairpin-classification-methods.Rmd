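---
title: "Classifying plant pre-miRNA hairpins with knowledge-based energy features"
author: "hairpinSVM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying plant pre-miRNA hairpins with knowledge-based energy features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hairpinSVM)
```

## The problem

Plant microRNAs are excised from precursor transcripts (pre-miRNAs) that
fold into characteristic stem–loop (hairpin) secondary structures. Many
genomic segments — in particular windows of protein-coding sequence —
also fold into hairpin-like shapes, so recognising genuine precursors
among hairpin-shaped candidates is a binary classification problem:
genuine pre-miRNA hairpins (positives, typically curated from miRBase)
against *pseudo hairpins* cut from CDS (negatives). Plant precursors are
longer and structurally more heterogeneous than animal ones, which is
why plant-specific classifiers exist as a lineage of their own.

`hairpinSVM` implements this classifier end to end: a 193-dimensional
feature representation whose core is a family of *knowledge-based k-mer
pair pseudo-energies*, a pseudo-hairpin negative-set constructor,
z-score normalization with scaler persistence, an RBF-kernel support
vector machine with grid search, and the standard evaluation stack
(accuracy, sensitivity, specificity, Matthews correlation, ROC/AUC,
stratified k-fold cross-validation, top-N ranking consistency).

## The feature space (193 columns, frozen)

Every candidate is folded once into a single secondary structure and
then featurized. The manifest order is fixed and versioned
(`featureManifest()`); a trained model refuses feature matrices built
under any other manifest, because silent column drift is the classic
failure mode of re-implemented featurizers. The blocks, in order:

| columns | block |
|---|---|
| 1–34 | position-specific 2-mer pair potentials (34 relative-position bins) |
| 35–39 | distance-specific k-mer pair potentials, k = 1..5 |
| 40–49 | unpaired-nucleotide ratio in 10 sequence subregions |
| 50–53 | biggest bulge, stems/L, loops/L, GC% |
| 54–69 | dinucleotide percentages (overlapping windows) |
| 70–87 | thermodynamic and pairing ratios (dG, MFE1..MFE5, dP, pair-type densities, stem averages, MCPN, bulge density) |
| 88–167 | overlapping k-mer frequencies, k = 2 and 3 |
| 168–193 | distance-dependent k-mer pair potentials (20 distance bins, pooled over k = 1..3, plus per-k mean and sd) |

### Knowledge-based potentials

The discriminative core is a Boltzmann inversion. For an observation
class $x$ (a pair of k-mers at some binned separation, or a 2-mer pair
in contact across a base pair) with smoothed relative frequencies
$F^+(x)$ in the positive and $F^-(x)$ in the negative training set, the
pseudo-energy is

$$E(x) = -\ln\frac{F^+(x) + \varepsilon}{F^-(x) + \varepsilon},$$

negative (favourable) when the observation is enriched in genuine
hairpins. The smoothing pseudocount defaults to one over the number of
table cells, which makes never-observed pairs exactly neutral and
guarantees finite entries. Swapping the training sets negates every
entry — a property the test suite checks directly.

Three observation schemes feed the three potential blocks:

* **Position-specific** (columns 1–34): for every base pair $(i, j)$ of
  the folded structure, the contact between the 2-mer starting at $i$
  and the 2-mer ending at $j$, binned by relative 5' position $i/L$
  into 34 bins. Features are per-bin mean potentials, 0 for empty bins.
* **Distance-specific** (columns 35–39): every ordered pair of
  overlapping k-mer windows, one aggregate bin, k = 1..5; the feature
  is the *mean* potential over all pairs so it is comparable across
  sequence lengths.
* **Distance-dependent** (columns 168–193): the same window pairs
  binned by relative separation $\lfloor 20\,(j-i)/L\rfloor$ (last bin
  closed), k = 1..3. The 26 features are the 20 per-bin scores pooled
  over k plus each k's mean and standard deviation of its 20 bin
  scores.

The 34-bin and 20-bin parameterizations preserve the published
dimensionalities of this feature family; the exact construction of the
original 34- and 26-column blocks lives in earlier tools of this
lineage, so ours is a documented reconstruction behind the same
interfaces, with overlapping windows chosen for statistical efficiency.
Distances and positions are *relative* ($d/L$), so potentials transfer
across the wide pre-miRNA length range. Potential tables are part of
the model bundle and are never re-estimated at prediction time.

### Structure features and their conventions

The structural vocabulary follows the printed definitions of this tool
family: a *stem* is a run of at least 3 consecutively stacked base
pairs (a single unpaired position terminates the run; two helices
separated by a 1-nt bulge are two candidate stems, each needing 3
pairs); a *bulge* is any maximal run of at least 3 adjacent unpaired
nucleotides — including, by the literal definition, the terminal loop
(`excludeHairpinLoops = TRUE` selects the classical reading); a *loop*
is any maximal unpaired run enclosed by at least one pair, so hairpin,
interior and bulge loops all count. `MCPN` counts consecutive paired
sequence positions (bracket characters), not stacked pairs. The
subregion ratios cut sequence positions $1..L$ into 10 contiguous
pieces (the first $L \bmod 10$ take the extra position), which is
reproducible and order-independent; the ratios weighted by region sizes
reconstruct the unpaired count exactly.

Two near-identical printed stem averages are disambiguated as
`avg_bp_stem1 = tot_bases/n_stems` (pairs per stem) and
`avg_bp_stem2 = pb/n_stems` (paired nucleotides per stem), making the
two columns deliberately non-redundant. The three pair-type percentage
columns follow the literal printed formula
$\%(X{-}Y)/n_{stems} = (|X{-}Y|/n_{stems}\times 100)/n_{stems}$;
`pairPctStyle = "per_pairs"` selects the per-base-pair alternative.

Any ratio with a zero denominator (no stems, no loops, no pairs, GC% of
zero…) is emitted as 0 and flagged, never as an error: prediction sets
legitimately contain hairpin-less windows and must stay scoreable.

## Folding

Every feature above needs one secondary structure per candidate. The
package treats folding as a pluggable engine: `"vienna"` shells out to
`RNAfold` (thermodynamic minimum free energy, kcal/mol), `"auto"`
prefers it and falls back with a warning, and `"fallback"` is a
self-contained Nussinov-style base-pair-maximization dynamic program
(pair weights GC = 3, AU = 2, GU = 1, minimum hairpin loop 3 nt,
canonical pairs only) whose negated score is reported as a
pseudo-energy. The fallback exists so that the entire pipeline — and
the entire test suite — runs with zero external dependencies; the
feature layer only requires *a* structure and an energy scalar, and
both classes of any one analysis must simply use the same engine.
Among co-optimal fallback structures the pair set that is
lexicographically smallest by $(i, j)$ is returned, which makes the
fallback bit-for-bit deterministic and lets the tests compare it
against an exhaustive enumeration oracle. Structures computed elsewhere
(e.g. `RNAfold` output read with `readVienna()`) bypass folding
entirely and are featurized bit-for-bit.

Sequences shorter than 10 nt cannot form the minimal hairpin and are
rejected. Input cleaning follows the curated-dataset rule: `T` is
silently mapped to `U` (genome-derived CDS is DNA-coded, miRBase is
RNA-coded), and records containing anything outside `A`, `U`, `C`, `G`
— including IUPAC ambiguity codes — are dropped with a logged count
(or rejected outright under `policy = "error"`). An optional
exact-duplicate filter exists but is off by default, since curated
collections legitimately carry identical hairpins from related species.

## Negative-set construction

`extractPseudoHairpins()` operationalizes "sufficiently similar to a
genuine precursor" with three filters applied to folded CDS windows,
mirroring the pseudo-hairpin constructions this tool lineage
established: (a) at least one stem of 3 stacked pairs, (b) paired
fraction `dP` inside the positive set's observed range, (c) energy
density `dG = mfe/L` inside the positive set's observed range. Window
lengths are drawn from the positive set's empirical length
distribution; ranges default to min/max with optional percentile
trimming. Accepted windows never overlap previously accepted windows of
the same source record, which avoids near-duplicate negatives, and the
whole procedure is reproducible under its seed.

## Normalization, kernel and training

Features are z-scored, $x^* = (x - \mu)/\sigma$, with $\mu, \sigma$
fitted on training rows only and persisted in the model bundle; a
constant column's $\sigma$ is replaced by 1 so it maps to 0. The SVM
uses the RBF kernel $K(X_i, X_j) = e^{-\gamma |X_i - X_j|^2}$ with the
default width $\gamma = 1/(n\,\sigma^2)$, where $n$ is the feature
count and $\sigma^2$ the generalized variance of the scaled training
matrix, read as the mean per-feature variance — the
determinant-of-covariance reading would collapse to essentially zero in
193 dimensions, while the mean-variance reading matches the widely used
`1/(n_features * X.var())` heuristic. Grid search selects $(C, \gamma)$
by mean stratified-CV AUC (default grid $C \in 2^{\{-5,-3,\dots,15\}}$,
$\gamma$ = the default plus $2^{\{-15,\dots,3\}}$), with ties broken
toward smaller $C$ then smaller $\gamma$, and the full grid record is
retained in the bundle.

Prediction maps the SVM decision value through a fixed logistic link to
a score in $[0, 1]$ (label 1 at score ≥ 0.5). A fitted Platt-style
calibration was considered and rejected: libsvm's internal calibration
cross-validates with its own random number stream, which breaks the
byte-identical determinism this package guarantees, whereas a fixed
strictly monotone link leaves every ranking-based quantity (AUC, top-N
overlap) identical to that of the raw decision values.

Cross-validation is stratified (per-class fold sizes differ by at most
one) and leak-free: potential tables *and* the scaler are refit inside
every training fold before the held-out fold is featurized and scored.
Structures are folded once up front, which leaks nothing because a
sequence's structure depends only on itself. MCC with a zero
denominator is reported as 0; AUC is the Mann–Whitney probability with
ties counted half. Top-N comparisons break ties at rank N by candidate
id so the cut is deterministic.

## Synthetic data: what it does and does not show

`makeHairpin()` emulates what a curated plant pre-miRNA looks like to a
folding algorithm — a sampled 5' arm, a loop, and a reverse-complement
3' arm with independent per-position mutations — and `makeCds()`
emulates the negative source: start codon, uniform sense codons, one
terminal stop. `makeBenchmark()` draws positives with arm lengths
18–30 pairs and loops of 4–10 nt (total lengths ≈ 40–70 nt) and
negatives as CDS windows at the same length distribution. A single
`difficulty` knob in $[0, 1]$ erodes separability: arms mutate at rate
$0.4 \times$ difficulty, and above 0.5 a positive is replaced with
probability $2\,\text{difficulty} - 1$ by an independent draw from the
same CDS-window sampler the negatives use. The two endpoint behaviours
are therefore exact by construction: at low difficulty positives are
near-perfect hairpins, and at difficulty 1 the classes are
exchangeable, so any classifier's cross-validated AUC sits at chance.
We deliberately did not implement the maximal-difficulty limit as
nucleotide shuffling: a shuffled CDS window remains learnably different
from an intact one through its k-mer spectrum, which would contaminate
the null.

Passing on this benchmark demonstrates that the pipeline recovers a
planted structural/compositional signal and respects a true null. It
does *not* demonstrate field performance on real data: synthetic
hairpins lack multibranch structures, conserved mature-arm sequence,
paralogous families and species-level composition biases, and synthetic
CDS lacks real codon-usage bias. Numbers obtained on it characterize
the implementation, not plant genomes.

## Problem sizes and numerical choices

The shipped tests and the acceptance script use deliberately desk-scale
problems: benchmarks of 200+200 (training on 150 per class, evaluating
on held-out 50 per class), 4-fold CV on 80+80, a 5-fold label-permuted
null (60+60 in the test suite, 100+100 in the acceptance script, the
larger size keeping the chance-level estimate tight), and
exhaustive-enumeration folding oracles on
sequences of length 10–14 — sizes chosen so a complete run takes
minutes on one core while every code path, including per-fold potential
refitting, is exercised. Curated-scale inputs (thousands of hairpins)
go through exactly the same functions.

Other fixed choices: coordinates are 1-based inclusive throughout the
structure layer; k-mer order is lexicographic over A < C < G < U and
versioned with the manifest; bin edges are half-open with the last bin
closed; fold tie-breaks are lexicographic as above; model bundles are
single serialized files carrying manifest, scaler, potentials, SVM
state, grid record and seed, and a reloaded bundle reproduces scores to
within 1e-10.

## Known limitations

* The fallback folder maximizes weighted pairs, not free energy; its
  "mfe" is a pseudo-energy on a different scale from kcal/mol. Models
  must be trained and applied with the same engine (the bundle records
  it).
* Pseudoknots, suboptimal ensembles and partition functions are out of
  scope.
* The 34/26-column potential parameterizations are reconstructions that
  preserve the published dimensionalities and bin counts; an
  implementation with access to the original definitions can substitute
  them behind `trainPotentials()` without touching the rest of the
  pipeline.
* Published headline numbers for this problem were obtained on curated
  miRBase positives and undisclosed CDS negatives; they are not
  reproducible from synthetic data and are not claimed here.

## A worked run

```{r example, eval = FALSE}
b <- makeBenchmark(200, 200, difficulty = 0.1, seed = 1)
model <- trainHairpinModel(b$pos[1:150], b$neg[1:150],
                           engine = "fallback",
                           grid = list(C = c(1, 8, 64)), folds = 4,
                           seed = 2)
pred <- predictHairpins(model,
                        c(as.character(b$pos[151:200]),
                          as.character(b$neg[151:200])),
                        engine = "fallback")
rocAuc(pred$score, rep(1:0, each = 50))$auc
```

The same computation, plus dataset bookkeeping, cross-validation and
the permuted-label null, is what `scripts/acceptance.R` re-runs from
scratch and writes to JSON.
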