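test_that("the scaler standardizes training data and reuses train mu/sigma", {
  withr::with_seed(2, X <- cbind(a = rnorm(30, 5, 2), b = runif(30),
                                 c = rep(3, 30)))
  sc <- fitScaler(X)
  Xs <- applyScaler(sc, X)
  expect_equal(unname(colMeans(Xs)), c(0, 0, 0), tolerance = 1e-12)
  expect_equal(unname(apply(Xs[, 1:2], 2, sd)), c(1, 1), tolerance = 1e-12)
  expect_equal(unname(Xs[, 3]), rep(0, 30))            # constant column
  meanRow <- matrix(sc$mu, 1, dimnames = list(NULL, colnames(X)))
  expect_equal(unname(applyScaler(sc, meanRow)), matrix(0, 1, 3))
  expect_error(applyScaler(sc, X[, 1:2]), "width")
  expect_error(fitScaler(X[1, , drop = FALSE]), "at least 2")
})

test_that("the default kernel width follows the generalized-variance rule", {
  expect_equal(defaultGamma(193, 1), 1 / 193)
  expect_equal(defaultGamma(1, 2), 0.5)
  withr::with_seed(6, X <- matrix(rnorm(200, sd = 1.7), 20, 10))
  expect_equal(defaultGamma(10, X = X),
               1 / (10 * mean(apply(X, 2, var))), tolerance = 1e-12)
  expect_error(defaultGamma(5, 0), "degenerate")
})

test_that("grid search separates separable data and is seed-deterministic", {
  withr::with_seed(10, {
    X <- rbind(matrix(rnorm(100, 3), 50, 2), matrix(rnorm(100, -3), 50, 2))
    colnames(X) <- c("f1", "f2")
    y <- rep(c(1, 0), each = 50)
  })
  f1 <- svmGridTrain(X, y, grid = list(C = c(0.5, 2, 8)), folds = 5, seed = 3)
  expect_true(all(c("C", "gamma", "cvAUC") %in% names(f1$gridRecord)))
  dv <- hairpinSVM:::decisionValuesFor(f1$svm, applyScaler(f1$scaler, X),
                                       f1$decisionSign)
  expect_equal(as.integer(dv >= 0), as.integer(y))   # training accuracy 1
  f2 <- svmGridTrain(X, y, grid = list(C = c(0.5, 2, 8)), folds = 5, seed = 3)
  expect_identical(c(f1$C, f1$gamma), c(f2$C, f2$gamma))
  expect_equal(f1$gridRecord$cvAUC, f2$gridRecord$cvAUC)
  expect_error(svmGridTrain(X, rep(1, 100)), "single class")
  Xna <- X; Xna[3, 2] <- NA
  expect_error(svmGridTrain(Xna, y), "f2")
})

test_that("label-permuted features give chance-level CV AUC", {
  withr::with_seed(40, {
    X <- matrix(rnorm(120 * 8), 120, 8,
                dimnames = list(NULL, paste0("f", 1:8)))
    y <- sample(rep(c(0, 1), 60))
  })
  f <- svmGridTrain(X, y, grid = list(C = 1), folds = 5, seed = 9)
  auc <- max(f$gridRecord$cvAUC)
  expect_gte(auc, 0.35)
  expect_lte(auc, 0.65)
})

test_that("an end-to-end model predicts its own training classes", {
  b <- makeBenchmark(25, 25, difficulty = 0.05, seed = 13)
  m <- trainHairpinModel(b$pos, b$neg, engine = "fallback",
                         grid = list(C = c(1, 8)), folds = 3, seed = 2)
  expect_s4_class(m, "HairpinModel")
  expect_gt(m@gamma, 0)
  pr <- predictHairpins(m, c(as.character(b$pos), as.character(b$neg)),
                        engine = "fallback")
  expect_equal(nrow(pr), 50)
  expect_true(all(pr$score >= 0 & pr$score <= 1))
  expect_equal(pr$label, as.integer(pr$score >= 0.5))
  expect_gt(mean(pr$label[1:25]), 0.9)
  expect_lt(mean(pr$label[26:50]), 0.1)
  # scores are co-monotone with decision values
  expect_equal(order(pr$score), order(pr$decision))
  # duplicated input rows give identical scores
  X <- hairpinFeatureMatrix(c(a = as.character(b$pos[[1]]),
                              b = as.character(b$pos[[1]])),
                            potentials = m@potentials, engine = "fallback")
  pd <- predictHairpins(m, X)
  expect_equal(pd$score[1], pd$score[2])
})

test_that("training twice under one seed is byte-identical in predictions", {
  b <- makeBenchmark(15, 15, difficulty = 0.1, seed = 21)
  m1 <- trainHairpinModel(b$pos, b$neg, engine = "fallback",
                          grid = list(C = 1), folds = 3, seed = 5)
  m2 <- trainHairpinModel(b$pos, b$neg, engine = "fallback",
                          grid = list(C = 1), folds = 3, seed = 5)
  te <- makeBenchmark(10, 10, difficulty = 0.1, seed = 22)
  p1 <- predictHairpins(m1, te$pos, engine = "fallback")
  p2 <- predictHairpins(m2, te$pos, engine = "fallback")
  expect_identical(p1, p2)
})

test_that("model bundles round trip through disk within 1e-10", {
  b <- makeBenchmark(15, 15, difficulty = 0.1, seed = 31)
  m <- trainHairpinModel(b$pos, b$neg, engine = "fallback",
                         grid = list(C = 1), folds = 3, seed = 5)
  f <- withr::local_tempfile(fileext = ".rds")
  saveHairpinModel(m, f)
  m2 <- loadHairpinModel(f)
  te <- makeBenchmark(8, 8, difficulty = 0.1, seed = 32)
  p1 <- predictHairpins(m, te$pos, engine = "fallback")
  p2 <- predictHairpins(m2, te$pos, engine = "fallback")
  expect_equal(p1$score, p2$score, tolerance = 1e-10)
})

test_that("prediction refuses matrices from a different manifest", {
  b <- makeBenchmark(15, 15, difficulty = 0.1, seed = 41)
  m <- trainHairpinModel(b$pos, b$neg, engine = "fallback",
                         grid = list(C = 1), folds = 3, seed = 5)
  X <- hairpinFeatureMatrix(b$pos, potentials = m@potentials,
                            engine = "fallback")
  attr(X, "manifestVersion") <- "other-version"
  expect_error(predictHairpins(m, X), "manifest mismatch")
})
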