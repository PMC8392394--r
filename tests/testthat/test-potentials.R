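toyPair <- function() {
  pos <- c(p1 = "ACGUACGUACGU", p2 = "GGCAGGCAGGCA")
  neg <- c(n1 = "AAAAUUUUAAAA", n2 = "UUAAUUAAUUAA")
  list(pos = pos, neg = neg,
       posS = foldHairpins(pos, "fallback"),
       negS = foldHairpins(neg, "fallback"))
}

test_that("identical training classes give the all-zero table", {
  t <- toyPair()
  for (scheme in c("distance_specific", "distance_dependent")) {
    tab <- trainPotentials(t$pos, t$pos, scheme, k = 1,
                           nBins = if (scheme == "distance_dependent") 20 else 1)
    expect_true(all(tab@entries == 0))
  }
  tab <- trainPotentials(t$pos, t$pos, "position_specific", k = 2,
                         nBins = 34, posStructures = t$posS,
                         negStructures = t$posS)
  expect_true(all(tab@entries == 0))
})

test_that("swapping training classes negates every entry and every score", {
  t <- toyPair()
  a <- trainPotentials(t$pos, t$neg, "distance_specific", k = 2)
  b <- trainPotentials(t$neg, t$pos, "distance_specific", k = 2)
  expect_equal(a@entries, -b@entries)
  sq <- "ACGGUUACGGUA"
  expect_equal(scoreDistanceSpecific(sq, a), -scoreDistanceSpecific(sq, b))

  a3 <- lapply(1:3, function(k) {
    trainPotentials(t$pos, t$neg, "distance_dependent", k = k, nBins = 20)
  })
  b3 <- lapply(1:3, function(k) {
    trainPotentials(t$neg, t$pos, "distance_dependent", k = k, nBins = 20)
  })
  expect_equal(scoreDistanceDependent(sq, a3)[1:23],
               -scoreDistanceDependent(sq, b3)[1:23])
})

test_that("training equals a hand Boltzmann inversion on a tiny k=1 case", {
  pos <- c(p = "AACGUACGUAAC")
  neg <- c(n = "GGUCAUGGUCAU")
  tab <- trainPotentials(pos, neg, "distance_specific", k = 1)
  # brute-force double loop over all i < j position pairs
  countPairs <- function(s) {
    ch <- strsplit(s, "")[[1]]
    C <- matrix(0, 4, 4, dimnames = list(c("A","C","G","U"),
                                         c("A","C","G","U")))
    n <- length(ch)
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      C[ch[i], ch[j]] <- C[ch[i], ch[j]] + 1
    }
    C
  }
  fp <- countPairs(pos); fp <- fp / sum(fp)
  fn <- countPairs(neg); fn <- fn / sum(fn)
  eps <- 1 / 16
  want <- -log((fp + eps) / (fn + eps))
  expect_equal(tab@entries[, , 1], unname(want), tolerance = 1e-12)
  expect_equal(tab@eps, eps)
})

test_that("duplicating every training sequence changes nothing", {
  t <- toyPair()
  a <- trainPotentials(t$pos, t$neg, "distance_specific", k = 1)
  b <- trainPotentials(c(t$pos, t$pos), c(t$neg, t$neg),
                       "distance_specific", k = 1)
  expect_equal(a@entries, b@entries)
})

test_that("distance-specific scoring matches an exhaustive pair oracle", {
  t <- toyPair()
  tab <- trainPotentials(t$pos, t$neg, "distance_specific", k = 1)
  sq <- "GGCAUA"
  ch <- strsplit(sq, "")[[1]]
  idx <- match(ch, c("A", "C", "G", "U"))
  tot <- 0
  for (i in 1:5) for (j in (i + 1):6) {
    tot <- tot + tab@entries[idx[i], idx[j], 1]
  }
  expect_equal(scoreDistanceSpecific(sq, tab), tot / 15)

  # uniform table scores exactly its constant; zero table scores 0
  tab@entries[] <- 0.7
  expect_equal(scoreDistanceSpecific(sq, tab), 0.7)
  tab@entries[] <- 0
  expect_equal(scoreDistanceSpecific(sq, tab), 0)
})

test_that("position-specific scoring bins and averages contacts correctly", {
  sq <- "GGGGAAAACCCC"
  ss <- foldHairpin(sq, "fallback")   # pairs (1,12) (2,11) (3,10) (4,9)
  W <- 16
  tab <- methods::new("PotentialTable", scheme = "position_specific",
                      k = 2L, nBins = 34L,
                      entries = array(0, c(W, W, 34)),
                      eps = 1e-3, provenance = "toy")
  expect_equal(scorePositionSpecific(sq, ss, tab), rep(0, 34))

  # hand-built: value = i for the contact anchored at 5' position i
  codes <- match(strsplit(sq, "")[[1]], c("A", "C", "G", "U"))
  w2 <- function(i) (codes[i] - 1) * 4 + codes[i + 1] - 1 + 1
  ent <- array(0, c(W, W, 34))
  want <- rep(0, 34)
  for (p in 1:4) {
    i <- p; j <- 13 - p
    b <- min(floor(34 * (i - 1) / 12) + 1, 34)
    ent[w2(i), w2(j - 1), b] <- i
    want[b] <- i  # each bin receives exactly one contact here
  }
  tab@entries <- ent
  expect_equal(scorePositionSpecific(sq, ss, tab), want)

  # zero-pair structure scores all zeros even with a nonzero table
  open <- methods::new("SecondaryStructure", dotbracket = strrep(".", 12),
                       basePairs = matrix(integer(0), 0, 2), mfe = 0,
                       source = "provided")
  expect_equal(scorePositionSpecific(sq, open, tab), rep(0, 34))
})

test_that("distance-dependent scoring matches a brute-force pooled tally", {
  withr::with_seed(8, {
    tabs <- lapply(1:3, function(k) {
      W <- as.integer(4^k)
      methods::new("PotentialTable", scheme = "distance_dependent",
                   k = as.integer(k), nBins = 20L,
                   entries = array(rnorm(W * W * 20), c(W, W, 20)),
                   eps = 1e-3, provenance = "toy")
    })
    sq <- randomRnaSeq(30)
  })
  got <- scoreDistanceDependent(sq, tabs)
  ch <- strsplit(sq, "")[[1]]
  codes <- match(ch, c("A", "C", "G", "U"))
  perK <- matrix(0, 20, 3)
  for (k in 1:3) {
    n <- 30 - k + 1
    widx <- vapply(seq_len(n), function(i) {
      v <- 0
      for (t in 0:(k - 1)) v <- v * 4 + codes[i + t] - 1
      v + 1
    }, numeric(1))
    sums <- numeric(20); cnts <- numeric(20)
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      b <- min(floor(20 * (j - i) / 30) + 1, 20)
      sums[b] <- sums[b] + tabs[[k]]@entries[widx[i], widx[j], b]
      cnts[b] <- cnts[b] + 1
    }
    perK[, k] <- ifelse(cnts > 0, sums / pmax(cnts, 1), 0)
  }
  expect_equal(unname(got[1:20]), rowMeans(perK), tolerance = 1e-12)
  expect_equal(unname(got[21:23]), colMeans(perK), tolerance = 1e-12)
  expect_equal(unname(got[24:26]), apply(perK, 2, sd), tolerance = 1e-12)
})

test_that("constant distance-dependent tables give flat scores, sd 0", {
  tabs <- lapply(1:3, function(k) {
    W <- as.integer(4^k)
    methods::new("PotentialTable", scheme = "distance_dependent",
                 k = as.integer(k), nBins = 20L,
                 entries = array(0.4, c(W, W, 20)),
                 eps = 1e-3, provenance = "toy")
  })
  # long enough (64 nt) that every distance bin is populated for k <= 3
  got <- scoreDistanceDependent(strrep("ACGU", 16), tabs)
  expect_equal(unname(got[1:20]), rep(0.4, 20))
  expect_equal(unname(got[21:23]), rep(0.4, 3))
  expect_equal(unname(got[24:26]), rep(0, 3))
})

test_that("a planted motif pair separates the classes in the right direction", {
  withr::with_seed(19, {
    pos <- vapply(1:30, function(i) {
      paste0("GGGC", randomRnaSeq(12), "GCCC")
    }, character(1))
    neg <- vapply(1:30, function(i) randomRnaSeq(20), character(1))
    names(pos) <- paste0("p", 1:30); names(neg) <- paste0("n", 1:30)
  })
  tab <- trainPotentials(pos, neg, "distance_specific", k = 2)
  codes <- c(G = 3, C = 2)
  wGC <- (3 - 1) * 4 + 2 - 1 + 1   # "GC"
  # GC..GC long-range pairing is enriched in positives
  expect_lt(tab@entries[wGC, wGC, 1], 0)
  sp <- vapply(pos, function(s) scoreDistanceSpecific(s, tab), numeric(1))
  sn <- vapply(neg, function(s) scoreDistanceSpecific(s, tab), numeric(1))
  expect_lt(mean(sp), mean(sn))
})

test_that("degenerate training inputs are rejected", {
  t <- toyPair()
  expect_error(trainPotentials(character(0), t$neg, "distance_specific"),
               "non-empty")
  expect_error(trainPotentials(c(a = "ACG"), c(b = "AC"),
                               "distance_specific", k = 4), "shortest")
  expect_error(trainPotentials(t$pos, t$neg, "position_specific", k = 2,
                               nBins = 34), "structures")
})
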