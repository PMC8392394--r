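#' Binary classification metrics from a confusion table
#'
#' Accuracy `(TP+TN)/(TP+FP+TN+FN)`, sensitivity `TP/(TP+FN)`, specificity
#' `TN/(TN+FP)` and Matthews correlation coefficient
#' `(TP*TN - FN*FP) / sqrt((TP+FN)(TN+FP)(TP+FP)(TN+FN))`. When any factor
#' of the MCC denominator is zero the MCC is reported as 0 (standard
#' convention); a sensitivity or specificity with an empty class is
#' reported as `NaN`.
#'
#' @param tp,fp,tn,fn non-negative confusion counts (at least one
#'   positive).
#' @return List with `Ac`, `Se`, `Sp`, `MCC`.
#' @examples
#' confusionMetrics(tp = 50, fp = 0, tn = 50, fn = 0)
#' @export
confusionMetrics <- function(tp, fp, tn, fn) {
  counts <- c(tp, fp, tn, fn)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("confusion counts must be non-negative integers")
  }
  if (sum(counts) == 0) stop("all confusion counts are zero")
  denom <- (tp + fn) * (tn + fp) * (tp + fp) * (tn + fn)
  mcc <- if (denom == 0) 0 else (tp * tn - fn * fp) / sqrt(denom)
  list(Ac = (tp + tn) / sum(counts),
       Se = tp / (tp + fn),
       Sp = tn / (tn + fp),
       MCC = mcc)
}

#' ROC curve and AUC
#'
#' The AUC is the Mann-Whitney probability that a random positive outscores
#' a random negative, with ties counted half, computed from mid-ranks. The
#' ROC staircase enumerates all score thresholds (ties collapse into
#' diagonal segments).
#'
#' @param scores numeric scores, larger = more positive-like.
#' @param labels binary labels in `{0, 1}`; both classes must be present.
#' @return List with `auc` and `roc` (data.frame of `fpr`, `tpr`).
#' @export
rocAuc <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels))
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0 || n0 == 0) stop("both classes must be present for ROC/AUC")
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  ord <- order(-scores)
  tp <- cumsum(labels[ord] == 1L)
  fp <- cumsum(labels[ord] == 0L)
  keep <- c(diff(scores[ord]) != 0, TRUE)  # last point of each tie group
  roc <- data.frame(fpr = c(0, fp[keep] / n0), tpr = c(0, tp[keep] / n1))
  list(auc = auc, roc = roc)
}

#' Leak-free stratified k-fold cross-validation of the full pipeline
#'
#' Assigns sequences to stratified folds (per-class sizes differ by at most
#' one) and, for each fold, retrains the potential tables and the feature
#' scaler on the training part only before featurizing and scoring the
#' held-out part — the test fold never influences any trained quantity.
#' Structures are folded once up front (a sequence's structure depends on
#' nothing but itself).
#'
#' @param seqs sequences ([Biostrings::RNAStringSet] / named character).
#' @param labels binary labels in `{0, 1}`, parallel to `seqs`.
#' @param folds number of folds (must not exceed the minority class size).
#' @param seed integer seed driving the fold assignment.
#' @param structures optional pre-folded structures.
#' @param engine folding engine.
#' @param C SVM penalty for the per-fold fits.
#' @param gamma kernel width; `NULL` means the [defaultGamma()] heuristic
#'   computed on each fold's scaled training matrix.
#' @param grid optional grid list; when given, a nested [svmGridTrain()]
#'   runs inside every training fold instead of a fixed `(C, gamma)`.
#' @return List with `perFold` (fold, Ac, Se, Sp, MCC, AUC), `pooled`
#'   metrics from the summed confusion, `meanAUC`, `pooledAUC`, `scores`,
#'   `foldAssign`.
#' @export
kfoldCv <- function(seqs, labels, folds = 10L, seed = 1L,
                    structures = NULL, engine = "auto", C = 1,
                    gamma = NULL, grid = NULL) {
  chars <- asRnaCharacter(seqs)
  y <- as.integer(labels)
  stopifnot(length(chars) == length(y), all(y %in% c(0L, 1L)))
  if (folds < 2L) stop("need at least 2 folds")
  if (min(table(y)) < folds) stop("folds exceed the minority class size")
  engine <- resolveEngine(engine)
  if (is.null(structures)) structures <- foldHairpins(chars, engine)
  fold <- stratifiedFolds(y, folds, seed)
  scores <- numeric(length(y))
  perFold <- data.frame(fold = seq_len(folds), Ac = NA_real_, Se = NA_real_,
                        Sp = NA_real_, MCC = NA_real_, AUC = NA_real_)
  conf <- c(tp = 0, fp = 0, tn = 0, fn = 0)
  for (f in seq_len(folds)) {
    tr <- which(fold != f)
    te <- which(fold == f)
    pos <- tr[y[tr] == 1L]
    neg <- tr[y[tr] == 0L]
    potentials <- trainHairpinPotentials(chars[pos], chars[neg],
                                         structures[pos], structures[neg])
    Xtr <- hairpinFeatureMatrix(chars[tr], structures[tr], potentials)
    Xte <- hairpinFeatureMatrix(chars[te], structures[te], potentials)
    if (!is.null(grid)) {
      fit <- svmGridTrain(Xtr, y[tr], grid = grid, folds = min(5L, folds),
                          seed = seed + f)
      dv <- decisionValuesFor(fit$svm, applyScaler(fit$scaler, Xte),
                              fit$decisionSign)
    } else {
      scaler <- fitScaler(Xtr)
      Xs <- applyScaler(scaler, Xtr)
      g <- if (is.null(gamma)) defaultGamma(ncol(Xs), X = Xs) else gamma
      sfit <- svmFit(Xs, y[tr], C, g)
      dv <- decisionValuesFor(sfit, applyScaler(scaler, Xte),
                              decisionSignOf(sfit))
    }
    scores[te] <- dv
    tp <- sum(dv >= 0 & y[te] == 1L); fp <- sum(dv >= 0 & y[te] == 0L)
    tn <- sum(dv < 0 & y[te] == 0L); fn <- sum(dv < 0 & y[te] == 1L)
    conf <- conf + c(tp = tp, fp = fp, tn = tn, fn = fn)
    m <- confusionMetrics(tp, fp, tn, fn)
    perFold[f, c("Ac", "Se", "Sp", "MCC")] <- unlist(m)
    perFold$AUC[f] <- if (length(unique(y[te])) > 1L) {
      rocAuc(dv, y[te])$auc
    } else NA_real_
  }
  pooled <- confusionMetrics(conf["tp"], conf["fp"], conf["tn"], conf["fn"])
  list(perFold = perFold, pooled = pooled,
       meanAUC = mean(perFold$AUC, na.rm = TRUE),
       pooledAUC = rocAuc(scores, y)$auc,
       scores = scores, foldAssign = fold)
}

#' Top-N consistency between prediction rankings
#'
#' Compares the top-N candidate sets of two or three score rankings over
#' the same candidates, as used to check whether independently trained
#' predictors nominate the same best candidates. Ties at rank N are broken
#' by candidate id (alphabetical), which makes the cut deterministic.
#'
#' @param rankings named list of 2-3 data.frames with columns `id` and
#'   `score`; all must cover the identical id set.
#' @param n size of each top list.
#' @return List with `topSets` (the top-n ids per ranking), `pairwise`
#'   (matrix of pairwise overlap counts) and `regions` (exclusive Venn
#'   region cardinalities, names like `"A&B"`).
#' @export
topNOverlap <- function(rankings, n) {
  stopifnot(length(rankings) >= 2L, length(rankings) <= 3L)
  if (is.null(names(rankings))) {
    names(rankings) <- LETTERS[seq_along(rankings)]
  }
  idSets <- lapply(rankings, function(d) sort(as.character(d$id)))
  if (!all(vapply(idSets, identical, logical(1), y = idSets[[1]]))) {
    stop("rankings must cover identical candidate id sets")
  }
  tops <- lapply(rankings, function(d) {
    ord <- order(-d$score, as.character(d$id))
    as.character(d$id)[ord][seq_len(min(n, nrow(d)))]
  })
  k <- length(tops)
  pairwise <- matrix(NA_integer_, k, k,
                     dimnames = list(names(tops), names(tops)))
  for (a in seq_len(k)) for (b in seq_len(k)) {
    pairwise[a, b] <- length(intersect(tops[[a]], tops[[b]]))
  }
  allIds <- unique(unlist(tops))
  member <- vapply(tops, function(s) allIds %in% s, logical(length(allIds)))
  if (is.null(dim(member))) member <- matrix(member, nrow = 1)
  key <- apply(member, 1, function(row) {
    paste(names(tops)[row], collapse = "&")
  })
  regions <- table(key)
  list(topSets = tops, pairwise = pairwise,
       regions = stats::setNames(as.integer(regions), names(regions)))
}
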