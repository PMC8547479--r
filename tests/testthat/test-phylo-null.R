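test_that("cophenetic distances equal graph shortest paths", {
  for (seed in 1:3) {
    tr <- simulateTree(8, seed = seed)
    D <- as.matrix(copheneticDistances(tr))
    expect_equal(D, grPathDist(tr)[rownames(D), colnames(D)],
                 tolerance = 1e-10)
    expect_true(all(diag(D) == 0))
  }
  expect_equal(as.matrix(copheneticDistances(
    toyTree("(A:1,B:2);")))["A", "B"], 3)
})

test_that("MNTD weighted and unweighted forms are correct", {
  D <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  x <- c(A = 1, B = 1, C = 1)
  expect_equal(mntd(x, D), 8 / 3)
  expect_equal(mntd(x, D, weighted = FALSE), 8 / 3)
  # star tree: every nearest distance 4, any abundances
  Ds <- matrix(4, 3, 3, dimnames = dimnames(D))
  diag(Ds) <- 0
  expect_equal(mntd(c(A = 10, B = 1, C = 5), Ds), 4)
  expect_error(mntd(c(A = 3, B = 0, C = 0), D), "fewer than 2")
})

test_that("betaMNTD matches the brute-force oracle", {
  expect_equal(betaMNTD(c(a = 1), c(c = 1),
                        matrix(c(0, 4, 4, 0), 2, 2,
                               dimnames = list(c("a", "c"),
                                               c("a", "c")))), 4)
  for (seed in 1:5) {
    tr <- simulateTree(7, seed = seed + 10)
    D <- as.matrix(copheneticDistances(tr))
    ct <- randomCounts(tr, 3, seed = seed)
    m <- countMatrix(ct)
    for (w in c(TRUE, FALSE)) {
      got <- betaMNTD(m[1, ], m[2, ], D, weighted = w)
      expect_equal(got, bruteBetaMNTD(m[1, ], m[2, ], D, weighted = w),
                   tolerance = 1e-12)
      expect_equal(got, betaMNTD(m[2, ], m[1, ], D, weighted = w))
    }
    # scale invariance and self-identity
    expect_equal(betaMNTD(m[1, ] * 7, m[2, ], D),
                 betaMNTD(m[1, ], m[2, ], D))
    expect_equal(betaMNTD(m[1, ], m[1, ], D), 0)
  }
})

test_that("betaNTI is deterministic and never positive for identical pairs", {
  tr <- simulateTree(12, seed = 4)
  D <- copheneticDistances(tr)
  m <- countMatrix(randomCounts(tr, 3, seed = 9))
  m <- rbind(m, S4 = m[1, ])  # duplicate community
  ct <- CountTable(m)
  b1 <- suppressWarnings(betaNTIMatrix(ct, D, reps = 199, seed = 7))
  b2 <- suppressWarnings(betaNTIMatrix(ct, D, reps = 199, seed = 7))
  expect_identical(as.matrix(b1), as.matrix(b2))
  v <- pairValue(b1, "S1", "S4")
  expect_true(is.nan(v) || v <= 0)
  expect_true(is.na(as.matrix(b1)[1, 1]))
})

test_that("Monte-Carlo betaNTI null matches exhaustive tip permutations", {
  tr <- simulateTree(4, seed = 21)
  D <- as.matrix(copheneticDistances(tr))
  ct <- randomCounts(tr, 3, seed = 5, minRich = 2L)
  m <- countMatrix(ct)
  reps <- 1000L
  nm <- ecoassembly:::.betaMNTDNull(ct, D, reps = reps, seed = 11,
                                    weighted = TRUE)
  perms <- permAll(4L)
  taxa <- colnames(m)
  for (pair in list(c(1L, 2L), c(1L, 3L), c(2L, 3L))) {
    ex <- apply(perms, 1L, function(p) {
      Dp <- D[p, p]
      dimnames(Dp) <- list(taxa, taxa)
      bruteBetaMNTD(m[pair[1L], ], m[pair[2L], ], Dp)
    })
    exMean <- mean(ex)
    exSD <- stats::sd(ex) * sqrt((length(ex) - 1) / length(ex))
    se <- exSD / sqrt(reps)
    expect_lt(abs(nm$nullMean[pair[1L], pair[2L]] - exMean),
              3 * se + 1e-12)
    # sd of a sample sd is approximately sd/sqrt(2 reps)
    expect_lt(abs(nm$nullSD[pair[1L], pair[2L]] - exSD),
              3 * exSD / sqrt(2 * reps) + 1e-12)
    expect_equal(nm$obs[pair[1L], pair[2L]],
                 bruteBetaMNTD(m[pair[1L], ], m[pair[2L], ], D))
  }
})

test_that("NTI flags shuffle-invariant samples and detects clustering", {
  tr <- simulateTree(6, seed = 3)
  D <- copheneticDistances(tr)
  full <- matrix(c(3, 1, 4, 1, 5, 9), 1, 6,
                 dimnames = list("S1", tr$tip.label))
  res <- nti(CountTable(rbind(full, S2 = rep(1, 6))), D,
             reps = 99, seed = 2)
  # a sample holding every tip with equal weights is shuffle-invariant
  expect_true(isDegenerate(res$S2))
  expect_true(is.nan(nullScore(res$S2)))

  # two sister tips on a 6-tip caterpillar: clustered, NTI > 0,
  # and the null matches exhaustive enumeration of C(6,2) placements
  cat6 <- toyTree(
    "(((((A:1,B:1):1,C:2):1,D:3):1,E:4):1,F:5);")
  Dc <- as.matrix(copheneticDistances(cat6))
  x <- matrix(0, 2, 6, dimnames = list(c("P", "Q"), cat6$tip.label))
  x["P", c("A", "B")] <- 1
  x["Q", ] <- 1  # companion sample to satisfy class invariants
  resP <- nti(CountTable(x), Dc, reps = 999, seed = 13)$P
  expect_gt(nullScore(resP), 0)
  combos <- utils::combn(cat6$tip.label, 2)
  ex <- apply(combos, 2, function(tt) Dc[tt[1], tt[2]])
  exMean <- mean(ex)
  exSD <- stats::sd(ex) * sqrt((length(ex) - 1) / length(ex))
  expect_lt(abs(resP@nullMean - exMean), 3 * exSD / sqrt(999))
  expect_equal(resP@observed, Dc["A", "B"])
})

test_that("betaMNTD agrees with picante on a shared fixture", {
  skip_if_not_installed("picante")
  tr <- simulateTree(10, seed = 31)
  ct <- randomCounts(tr, 4, seed = 8)
  D <- as.matrix(copheneticDistances(tr))
  ours <- vapply(2:4, function(j)
    betaMNTD(countMatrix(ct)[1, ], countMatrix(ct)[j, ], D), numeric(1))
  ref <- as.matrix(picante::comdistnt(countMatrix(ct), D,
                                      abundance.weighted = TRUE))
  expect_equal(ours, unname(ref[1, 2:4]), tolerance = 1e-10)
})
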