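test_that("confusion metrics follow their closed forms", {
  m <- confusionMetrics(tp = 50, fp = 0, tn = 50, fn = 0)
  expect_equal(unlist(m), c(Ac = 1, Se = 1, Sp = 1, MCC = 1))
  m2 <- confusionMetrics(tp = 40, fp = 0, tn = 0, fn = 10)
  expect_equal(m2$Se, 0.8)
  expect_equal(m2$MCC, 0)   # zero-denominator convention
  # longhand recomputation
  tp <- 30; fp <- 20; tn <- 35; fn <- 15
  m3 <- confusionMetrics(tp, fp, tn, fn)
  expect_equal(m3$Ac, (30 + 35) / 100)
  expect_equal(m3$Se, 30 / 45)
  expect_equal(m3$Sp, 35 / 55)
  expect_equal(m3$MCC,
               (30 * 35 - 15 * 20) / sqrt(45 * 55 * 50 * 50))
  expect_error(confusionMetrics(0, 0, 0, 0), "zero")
})

test_that("label swap exchanges Se/Sp and preserves |MCC|", {
  withr::with_seed(12, {
    for (rep in 1:20) {
      cnt <- sample(0:40, 4, replace = TRUE)
      if (sum(cnt) == 0) cnt[1] <- 1
      a <- confusionMetrics(cnt[1], cnt[2], cnt[3], cnt[4])
      b <- confusionMetrics(cnt[3], cnt[4], cnt[1], cnt[2])
      expect_equal(a$Se, b$Sp)
      expect_equal(a$Sp, b$Se)
      expect_equal(abs(a$MCC), abs(b$MCC))
    }
  })
})

test_that("AUC equals the exhaustive pairwise probability, ties half", {
  expect_equal(rocAuc(c(3, 4, 1, 2), c(1, 1, 0, 0))$auc, 1)
  expect_equal(rocAuc(rep(1, 10), rep(c(0, 1), 5))$auc, 0.5)
  withr::with_seed(23, {
    for (rep in 1:25) {
      n <- 20
      scores <- sample(1:8, n, replace = TRUE) + 0.1 * rbinom(n, 1, 0.5)
      labels <- rbinom(n, 1, 0.5)
      if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
      expect_equal(rocAuc(scores, labels)$auc, oracleAuc(scores, labels))
    }
  })
  expect_error(rocAuc(1:5, rep(1, 5)), "both classes")
})

test_that("AUC complements under score negation for tie-free scores", {
  withr::with_seed(29, {
    scores <- rnorm(40)
    labels <- rbinom(40, 1, 0.5); labels[1:2] <- c(0, 1)
  })
  expect_equal(rocAuc(scores, labels)$auc + rocAuc(-scores, labels)$auc, 1)
})

test_that("our AUC agrees with an independent ROC library", {
  withr::with_seed(31, {
    scores <- c(rnorm(30, 1), rnorm(30))
    labels <- rep(c(1, 0), each = 30)
  })
  ref <- suppressMessages(as.numeric(pROC::auc(labels, scores,
                                               direction = "<")))
  expect_equal(rocAuc(scores, labels)$auc, ref, tolerance = 1e-12)
})

test_that("stratified CV partitions cleanly and is seed-stable", {
  b <- makeBenchmark(18, 24, difficulty = 0.1, seed = 51)
  seqs <- c(as.character(b$pos), as.character(b$neg))
  y <- c(rep(1L, 18), rep(0L, 24))
  structures <- foldHairpins(seqs, "fallback")
  cv1 <- kfoldCv(seqs, y, folds = 6, seed = 4, structures = structures,
                 engine = "fallback")
  cv2 <- kfoldCv(seqs, y, folds = 6, seed = 4, structures = structures,
                 engine = "fallback")
  expect_identical(cv1$foldAssign, cv2$foldAssign)
  expect_identical(cv1$scores, cv2$scores)
  # every sample is tested exactly once
  expect_equal(sort(unique(cv1$foldAssign)), 1:6)
  expect_length(cv1$foldAssign, 42)
  # per-class fold sizes differ by at most one
  for (cls in 0:1) {
    sizes <- table(cv1$foldAssign[y == cls])
    expect_lte(max(sizes) - min(sizes), 1)
  }
  # easily separable: every fold AUC is high
  expect_true(all(cv1$perFold$AUC > 0.9))
  expect_error(kfoldCv(seqs, y, folds = 30, engine = "fallback"),
               "minority")
})

test_that("top-N overlap handles identical, reversed and random rankings", {
  ids <- sprintf("c%03d", 1:200)
  withr::with_seed(61, s <- runif(200))
  rankA <- data.frame(id = ids, score = s)
  same <- topNOverlap(list(A = rankA, B = rankA), 100)
  expect_equal(same$pairwise["A", "B"], 100L)
  rev2 <- data.frame(id = ids, score = -s)
  disj <- topNOverlap(list(A = rankA, B = rev2), 100)
  expect_equal(disj$pairwise["A", "B"], 0L)
  withr::with_seed(62, {
    r1 <- data.frame(id = ids, score = runif(200))
    r2 <- data.frame(id = ids, score = runif(200))
    r3 <- data.frame(id = ids, score = runif(200))
  })
  res <- topNOverlap(list(A = r1, B = r2, C = r3), 50)
  top <- function(d) d$id[order(-d$score, d$id)][1:50]
  tA <- top(r1); tB <- top(r2); tC <- top(r3)
  expect_equal(unname(res$pairwise["A", "B"]), length(intersect(tA, tB)))
  expect_equal(unname(res$pairwise["B", "C"]), length(intersect(tB, tC)))
  onlyABC <- length(intersect(intersect(tA, tB), tC))
  if (onlyABC > 0) {
    expect_equal(unname(res$regions[["A&B&C"]]), onlyABC)
  }
  expect_equal(sum(res$regions), length(union(union(tA, tB), tC)))
  bad <- data.frame(id = c(ids[-1], "zzz"), score = runif(200))
  expect_error(topNOverlap(list(A = rankA, B = bad), 10), "identical")
})

test_that("rank-N ties are broken by candidate id", {
  d1 <- data.frame(id = c("a", "b", "c", "d"), score = c(5, 1, 1, 1))
  d2 <- data.frame(id = c("a", "b", "c", "d"), score = c(5, 4, 3, 2))
  res <- topNOverlap(list(X = d1, Y = d2), 2)
  expect_equal(res$topSets$X, c("a", "b"))   # b beats c, d alphabetically
})
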