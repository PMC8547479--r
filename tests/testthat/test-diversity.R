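test_that("Bray-Curtis matches the direct formula and its bounds", {
  m <- matrix(c(3, 1, 1, 3, 2, 2), 3, 2, byrow = TRUE,
              dimnames = list(c("S1", "S2", "S3"), c("a", "b")))
  ct <- CountTable(m)
  raw <- as.matrix(brayCurtisMatrix(ct, normalize = FALSE))
  expect_equal(raw["S1", "S2"], 0.5)  # (2+2)/(4+4)
  expect_equal(raw["S1", "S1"], 0)
  disj <- CountTable(matrix(c(4, 0, 0, 5), 2, 2,
                            dimnames = list(c("S1", "S2"),
                                            c("a", "b"))))
  expect_equal(pairValue(brayCurtisMatrix(disj), "S1", "S2"), 1)

  tr <- simulateTree(12, seed = 3)
  ct2 <- randomCounts(tr, 5, seed = 4)
  bc <- as.matrix(brayCurtisMatrix(ct2))
  m2 <- ecoassembly:::.relAbund(countMatrix(ct2))
  for (i in 1:4) for (j in (i + 1):5)
    expect_equal(bc[i, j], bruteBray(m2[i, ], m2[j, ], normalize = FALSE),
                 tolerance = 1e-12)
  expect_true(all(bc >= 0 & bc <= 1))
  # per-sample scaling is absorbed by normalization
  scaled <- countMatrix(ct2) * c(1, 10, 100, 3, 7)
  expect_equal(as.matrix(brayCurtisMatrix(CountTable(scaled))), bc)
})

test_that("richness and Pielou evenness follow their definitions", {
  m <- matrix(c(5, 5, 5, 5,
                75, 25, 0, 0,
                9, 0, 0, 0), 3, 4, byrow = TRUE,
              dimnames = list(c("even", "duo", "mono"),
                              paste0("t", 1:4)))
  ct <- CountTable(m)
  expect_identical(unname(richness(ct)), c(4L, 2L, 1L))
  J <- pielouEvenness(ct)
  expect_equal(unname(J["even"]), 1)
  H <- -(0.75 * log(0.75) + 0.25 * log(0.25))
  expect_equal(unname(J["duo"]), H / log(2), tolerance = 1e-12)
  expect_equal(round(H, 4), 0.5623)
  expect_equal(round(unname(J["duo"]), 4), 0.8113)
  expect_true(is.nan(J["mono"]))
})

test_that("environmental difference matrices respect missingness", {
  md <- data.frame(sample_id = c("S1", "S2", "S3"),
                   pH = c(11.5, 8.1, 9),
                   DIC = c(100, NA, 50),
                   flat = c(2, 2, 2))
  pm <- envDifferenceMatrix(md, "pH")
  expect_equal(pairValue(pm, "S1", "S2"), 3.4)
  expect_error(envDifferenceMatrix(md, "DIC"), "fewer than 3")
  expect_true(all(as.matrix(envDifferenceMatrix(md, "flat")) == 0))
  md$DIC2 <- c(NA, NA, NA)
  expect_error(envDifferenceMatrix(md, "DIC2"), "missing")
})

test_that("Mantel r and permutation p match brute-force expectations", {
  set.seed(11)
  n <- 6
  a <- matrix(0, n, n)
  a[lower.tri(a)] <- runif(choose(n, 2))
  a <- a + t(a)
  ids <- paste0("S", 1:n)
  dimnames(a) <- list(ids, ids)
  m1 <- PairwiseMatrix(a, "dissimilarity")
  expect_equal(mantelTest(m1, m1, permutations = 99, seed = 1)$r, 1)
  neg <- PairwiseMatrix(max(a) - a - diag(max(a), n), "dissimilarity")
  expect_equal(mantelTest(m1, neg, permutations = 99, seed = 1)$r, -1)

  # exhaustive permutation oracle at n = 4
  n <- 4
  ids <- paste0("S", 1:4)
  set.seed(5)
  A <- matrix(0, 4, 4); A[lower.tri(A)] <- runif(6); A <- A + t(A)
  B <- matrix(0, 4, 4); B[lower.tri(B)] <- runif(6); B <- B + t(B)
  dimnames(A) <- dimnames(B) <- list(ids, ids)
  rObs <- stats::cor(A[lower.tri(A)], B[lower.tri(B)])
  perms <- permAll(4L)
  rPerm <- apply(perms, 1, function(p) {
    Bp <- B[p, p]
    stats::cor(A[lower.tri(A)], Bp[lower.tri(Bp)])
  })
  pEx <- mean(abs(rPerm) >= abs(rObs) - 1e-12)
  got <- mantelTest(PairwiseMatrix(A, "dissimilarity"),
                    PairwiseMatrix(B, "dissimilarity"),
                    permutations = 999, seed = 3)
  expect_equal(got$r, rObs, tolerance = 1e-12)
  expect_lt(abs(got$p - pEx), 3 * sqrt(pEx * (1 - pEx) / 999) + 2e-3)
  expect_gte(got$p, 1 / 1000)
})

test_that("Mantel agrees with vegan on complete data", {
  tr <- simulateTree(10, seed = 7)
  ct <- randomCounts(tr, 7, seed = 8)
  bc <- brayCurtisMatrix(ct)
  md <- data.frame(sample_id = sampleIDs(ct), pH = runif(7, 7, 12))
  ed <- envDifferenceMatrix(md, "pH")
  ours <- mantelTest(bc, ed, permutations = 499, seed = 2)
  ref <- vegan::mantel(stats::as.dist(as.matrix(bc)),
                       stats::as.dist(as.matrix(ed)),
                       permutations = 499)
  expect_equal(ours$r, unname(ref$statistic), tolerance = 1e-10)
})

test_that("niche values are abundance-weighted environment means", {
  m <- matrix(c(5, 0, 2,
                0, 3, 2,
                0, 0, 0), 3, 3, byrow = TRUE,
              dimnames = list(c("S1", "S2", "S3"),
                              c("only1", "only2", "both")))
  m["S3", "only1"] <- 1  # keep sample total positive
  md <- data.frame(sample_id = c("S1", "S2", "S3"),
                   pH = c(11, 8, 10))
  nv <- nicheValues(CountTable(m), md, "pH")
  expect_equal(unname(nv["only2"]), 8)
  expect_equal(unname(nv["both"]), 9.5)  # equal counts at pH 11 and 8
  expect_true(all(nv >= 8 & nv <= 11))
})

test_that("the correlogram bins pairs exhaustively and guards degeneracy", {
  tr <- simulateTree(20, seed = 5)
  D <- copheneticDistances(tr)
  niche <- evolveTrait(tr, 1, 9, seed = 6)
  cg <- mantelCorrelogram(D, niche, nClasses = 4, permutations = 99,
                          seed = 1)
  expect_identical(nrow(cg), 4L)
  expect_equal(sum(cg$n_pairs), choose(20, 2))
  expect_equal(cg$class_lo[1], 0)
  expect_equal(cg$class_hi[4], max(as.matrix(D)))
  expect_equal(cg$class_hi[1], max(as.matrix(D)) / 4)
  expect_true(all(abs(cg$mantel_r) <= 1, na.rm = TRUE))

  flat <- stats::setNames(rep(1, 20), names(niche))
  cg0 <- mantelCorrelogram(D, flat, nClasses = 4, permutations = 99,
                           seed = 1)
  expect_false(any(cg0$significant))
})

test_that("PERMANOVA partitions the Gower-centered sum of squares", {
  # binary factor perfectly separating two pairs of identical samples
  m <- matrix(c(5, 0, 5, 0, 0, 7, 0, 7), 4, 2, byrow = TRUE,
              dimnames = list(paste0("S", 1:4), c("a", "b")))
  md <- data.frame(sample_id = paste0("S", 1:4),
                   grp = c("x", "x", "y", "y"))
  pt <- suppressWarnings(
    permanovaTable(brayCurtisMatrix(CountTable(m)), md, "grp",
                   permutations = 99, seed = 1))
  expect_equal(pt["grp", "R2"], 1)

  # six-sample toy against the matrix-algebra oracle
  tr <- simulateTree(15, seed = 9)
  ct <- randomCounts(tr, 6, seed = 10)
  md2 <- data.frame(sample_id = sampleIDs(ct),
                    f = rep(c("u", "v", "w"), 2),
                    z = c(1.2, 3.4, 2.2, 5.1, 0.3, 4.4))
  bc <- brayCurtisMatrix(ct)
  pt2 <- permanovaTable(bc, md2, c("f", "z"), permutations = 199,
                        seed = 2)
  D2 <- as.matrix(bc)^2
  n <- 6
  C <- diag(n) - matrix(1 / n, n, n)
  G <- -0.5 * C %*% D2 %*% C
  ssTotal <- sum(diag(G))
  X1 <- stats::model.matrix(~ f, data = md2)
  X2 <- stats::model.matrix(~ f + z, data = md2)
  hat <- function(X) X %*% solve(crossprod(X)) %*% t(X)
  ss1 <- sum(diag(hat(X1) %*% G))
  ss12 <- sum(diag(hat(X2) %*% G))
  expect_equal(pt2["f", "SumOfSqs"], ss1, tolerance = 1e-8)
  expect_equal(pt2["z", "SumOfSqs"], ss12 - ss1, tolerance = 1e-8)
  expect_equal(pt2["Total", "SumOfSqs"], ssTotal, tolerance = 1e-8)
  expect_equal(sum(pt2[c("f", "z", "Residual"), "SumOfSqs"]),
               ssTotal, tolerance = 1e-8)
  expect_equal(sum(pt2[c("f", "z", "Residual"), "R2"]), 1,
               tolerance = 1e-10)
})

test_that("samples missing term values are dropped listwise", {
  tr <- simulateTree(10, seed = 11)
  ct <- randomCounts(tr, 6, seed = 12)
  md <- data.frame(sample_id = sampleIDs(ct),
                   z = c(1, 2, NA, 4, 5, 6),
                   f = rep(c("p", "q"), 3))
  expect_warning(
    pt <- permanovaTable(brayCurtisMatrix(ct), md, c("f", "z"),
                         permutations = 49, seed = 1),
    "dropped")
  expect_equal(pt["Total", "Df"], 4)
})
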