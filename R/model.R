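#' Fit and apply the z-score feature scaler
#'
#' `fitScaler` learns per-column mean and standard deviation on training
#' data only; `applyScaler` standardizes any matrix with those training
#' parameters (`x* = (x - mu) / sigma`). The sigma of a constant column is
#' replaced by 1 so the column maps to 0. The fitted scaler is persisted
#' inside the model bundle and reused verbatim on test data.
#'
#' @param X numeric training matrix (>= 2 rows).
#' @param scaler a fitted scaler list.
#' @return `fitScaler`: list with `mu` and `sigma`; `applyScaler`: the
#'   standardized matrix.
#' @export
fitScaler <- function(X) {
  if (nrow(X) < 2L) stop("need at least 2 training rows to fit a scaler")
  mu <- colMeans(X)
  sigma <- apply(X, 2, stats::sd)
  sigma[sigma == 0] <- 1
  list(mu = mu, sigma = sigma)
}

#' @rdname fitScaler
#' @export
applyScaler <- function(scaler, X) {
  if (ncol(X) != length(scaler$mu)) {
    stop("matrix width does not match the fitted scaler")
  }
  sweep(sweep(X, 2, scaler$mu, "-"), 2, scaler$sigma, "/")
}

#' Default RBF kernel width
#'
#' `gamma = 1 / (n * sigma2)` with `n` the feature count and `sigma2` the
#' generalized variance of the (scaled) training matrix, read as the mean
#' per-feature variance — the determinant-of-covariance reading would
#' collapse to ~0 in 193 dimensions. Equivalent to the common
#' `1/(n_features * X.var())` heuristic.
#'
#' @param n feature count.
#' @param sigma2 generalized variance; computed from `X` when omitted.
#' @param X optional scaled training matrix.
#' @return Positive scalar gamma.
#' @examples
#' defaultGamma(193, 1)   # 1/193
#' @export
defaultGamma <- function(n, sigma2 = NULL, X = NULL) {
  if (is.null(sigma2)) {
    if (is.null(X)) stop("provide sigma2 or X")
    sigma2 <- mean(apply(X, 2, stats::var))
  }
  if (sigma2 <= 0) stop("degenerate data: generalized variance is zero")
  1 / (n * sigma2)
}

# libsvm orients decision values toward the first factor level it saw;
# normalize so positive decision values favour label 1
decisionValuesFor <- function(fit, X, sign) {
  dv <- attr(stats::predict(fit, X, decision.values = TRUE),
             "decision.values")
  as.numeric(dv) * sign
}

decisionSignOf <- function(fit) {
  cn <- colnames(attr(stats::predict(fit, fit$SV[1, , drop = FALSE],
                                     decision.values = TRUE),
                      "decision.values"))
  if (startsWith(cn, "1/")) 1 else -1
}

svmFit <- function(X, y, C, gamma) {
  e1071::svm(x = X, y = factor(y, levels = c(0, 1)), scale = FALSE,
             kernel = "radial", gamma = gamma, cost = C)
}

stratifiedFolds <- function(y, folds, seed) {
  assign <- integer(length(y))
  withSeed(seed, {
    for (cls in unique(y)) {
      idx <- which(y == cls)
      assign[idx] <- sample(rep(seq_len(folds), length.out = length(idx)))
    }
  })
  assign
}

#' Grid-search training of the RBF-SVM on a feature matrix
#'
#' Standardizes the matrix with a freshly fitted scaler, then selects
#' `(C, gamma)` by mean stratified-CV AUC over the candidate grid (ties
#' broken toward smaller `C`, then smaller `gamma`) and refits on all
#' training rows. The default gamma candidate is the generalized-variance
#' heuristic of [defaultGamma()]. Deterministic under `seed`.
#'
#' @param X feature matrix (rows = sequences, manifest columns).
#' @param y labels in `{0, 1}` (1 = genuine hairpin).
#' @param grid list with numeric `C` and `gamma` candidates; a `NULL`
#'   `gamma` entry means the [defaultGamma()] value only. Defaults:
#'   `C = 2^seq(-5, 15, 2)`, `gamma = defaultGamma` plus `2^seq(-15, 3, 2)`.
#' @param folds CV folds for grid selection.
#' @param seed integer seed (fold assignment).
#' @return List with `scaler`, `svm`, `C`, `gamma`, `decisionSign`,
#'   `gridRecord` (one row per grid cell with mean CV AUC).
#' @export
svmGridTrain <- function(X, y, grid = NULL, folds = 5L, seed = 1L) {
  y <- as.integer(y)
  if (length(unique(y)) < 2L) stop("training data contain a single class")
  if (anyNA(X)) {
    bad <- colnames(X)[colSums(is.na(X)) > 0]
    stop("NaN/NA feature values in column(s): ",
         paste(head(bad, 5), collapse = ", "))
  }
  scaler <- fitScaler(X)
  Xs <- applyScaler(scaler, X)
  g0 <- defaultGamma(ncol(Xs), X = Xs)
  if (is.null(grid)) grid <- list(C = 2^seq(-5, 15, 2), gamma = NULL)
  gammas <- sort(unique(c(g0, grid$gamma)))
  Cs <- sort(unique(grid$C))
  cells <- expand.grid(C = Cs, gamma = gammas)
  fold <- stratifiedFolds(y, folds, seed)
  auc <- numeric(nrow(cells))
  for (ci in seq_len(nrow(cells))) {
    scores <- numeric(length(y))
    for (f in seq_len(folds)) {
      tr <- fold != f
      fit <- svmFit(Xs[tr, , drop = FALSE], y[tr],
                    cells$C[ci], cells$gamma[ci])
      scores[!tr] <- decisionValuesFor(fit, Xs[!tr, , drop = FALSE],
                                       decisionSignOf(fit))
    }
    perFold <- vapply(seq_len(folds), function(f) {
      yf <- y[fold == f]
      if (length(unique(yf)) < 2L) return(NA_real_)
      rocAuc(scores[fold == f], yf)$auc
    }, numeric(1))
    auc[ci] <- mean(perFold, na.rm = TRUE)
  }
  cells$cvAUC <- auc
  best <- order(-round(auc, 12), cells$C, cells$gamma)[1]
  fit <- svmFit(Xs, y, cells$C[best], cells$gamma[best])
  list(scaler = scaler, svm = fit, C = cells$C[best],
       gamma = cells$gamma[best], decisionSign = decisionSignOf(fit),
       gridRecord = cells)
}

#' Train a hairpin classification model end to end
#'
#' Folds the training sequences (unless structures are supplied), trains
#' the knowledge-based potential tables on the full training set,
#' featurizes, and runs [svmGridTrain()]. The returned bundle carries
#' everything prediction needs — scaler, potentials, SVM, manifest — so no
#' training-time quantity is ever re-estimated at prediction time.
#'
#' @param pos,neg positive / negative training sequences.
#' @param posStructures,negStructures optional pre-folded structures.
#' @param engine folding engine.
#' @param grid,folds,seed forwarded to [svmGridTrain()].
#' @return A [HairpinModel-class].
#' @export
trainHairpinModel <- function(pos, neg, posStructures = NULL,
                              negStructures = NULL, engine = "auto",
                              grid = NULL, folds = 5L, seed = 1L) {
  engine <- resolveEngine(engine)
  posC <- asRnaCharacter(pos)
  negC <- asRnaCharacter(neg)
  if (is.null(posStructures)) posStructures <- foldHairpins(posC, engine)
  if (is.null(negStructures)) negStructures <- foldHairpins(negC, engine)
  potentials <- trainHairpinPotentials(posC, negC, posStructures,
                                       negStructures)
  X <- rbind(hairpinFeatureMatrix(posC, posStructures, potentials),
             hairpinFeatureMatrix(negC, negStructures, potentials))
  y <- c(rep(1L, length(posC)), rep(0L, length(negC)))
  fit <- svmGridTrain(X, y, grid = grid, folds = folds, seed = seed)
  methods::new("HairpinModel", scaler = fit$scaler, svm = fit$svm,
               cost = fit$C, gamma = fit$gamma,
               decisionSign = fit$decisionSign, potentials = potentials,
               manifest = featureManifest(), gridRecord = fit$gridRecord,
               seed = as.integer(seed),
               engine = if (is.function(engine)) "custom" else engine)
}

#' Score candidate sequences with a trained model
#'
#' Featurizes with the model's stored potential tables, standardizes with
#' the stored scaler, and maps the SVM decision value through a fixed
#' logistic link to a score in `[0, 1]` (label 1 when score >= 0.5). The
#' link is strictly monotone, so rankings (AUC, top-N) are those of the
#' raw decision values. Input may also be a pre-built feature matrix,
#' whose manifest version must match the model's.
#'
#' @param model a [HairpinModel-class].
#' @param seqs sequences, or a matrix from [hairpinFeatureMatrix()].
#' @param structures optional pre-folded structures.
#' @param engine folding engine (defaults to the model's).
#' @return data.frame with `id`, `decision`, `score`, `label`, in input
#'   order.
#' @export
predictHairpins <- function(model, seqs, structures = NULL, engine = NULL) {
  if (is.matrix(seqs)) {
    ver <- attr(seqs, "manifestVersion")
    if (is.null(ver) || !identical(ver, model@manifest$version) ||
        !identical(colnames(seqs), model@manifest$names)) {
      stop("feature manifest mismatch: refusing to score this matrix")
    }
    X <- seqs
  } else {
    if (is.null(engine)) engine <- model@engine
    X <- hairpinFeatureMatrix(seqs, structures, model@potentials,
                              engine = engine)
  }
  Xs <- applyScaler(model@scaler, X)
  dv <- decisionValuesFor(model@svm, Xs, model@decisionSign)
  data.frame(id = rownames(X), decision = dv, score = stats::plogis(dv),
             label = as.integer(dv >= 0), row.names = NULL)
}

#' Save / load a model bundle
#'
#' One portable file containing manifest, scaler, potential tables, SVM
#' state, grid-search record and seed. A loaded model reproduces
#' predictions to within 1e-10.
#'
#' @param model a [HairpinModel-class].
#' @param path bundle path.
#' @return `saveHairpinModel`: invisibly, `path`; `loadHairpinModel`: the
#'   model.
#' @export
saveHairpinModel <- function(model, path) {
  stopifnot(methods::is(model, "HairpinModel"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname saveHairpinModel
#' @export
loadHairpinModel <- function(path) {
  model <- readRDS(path)
  if (!methods::is(model, "HairpinModel")) stop("not a model bundle: ", path)
  methods::validObject(model)
  model
}
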