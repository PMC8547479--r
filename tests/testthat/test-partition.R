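test_that("classifyPair reproduces the decision table with strict bounds", {
  expect_identical(classifyPair(2.5, NaN), "variable_selection")
  expect_identical(classifyPair(-2.5, NA), "homogeneous_selection")
  expect_identical(classifyPair(0.3, 0.97), "dispersal_limitation")
  expect_identical(classifyPair(0.3, -0.97), "homogenizing_dispersal")
  expect_identical(classifyPair(0.3, 0.5), "undominated")
  # boundary values are not significant
  expect_identical(classifyPair(2, 0.5), "undominated")
  expect_identical(classifyPair(-2, 0.5), "undominated")
  expect_identical(classifyPair(1, 0.95), "undominated")
  expect_identical(classifyPair(1, -0.95), "undominated")
  expect_error(classifyPair(0.3, NaN), "RCbray")
  expect_error(classifyPair(NaN, 0.5), "finite")
})

test_that("the five regions partition the score plane", {
  grid <- expand.grid(b = c(-3, -2.01, -2, -1, 0, 1, 2, 2.01, 3),
                      r = c(-1, -0.96, -0.95, -0.5, 0, 0.5, 0.95,
                            0.96, 1))
  for (k in seq_len(nrow(grid))) {
    got <- classifyPair(grid$b[k], grid$r[k])
    want <- if (grid$b[k] > 2) "variable_selection"
    else if (grid$b[k] < -2) "homogeneous_selection"
    else if (grid$r[k] > 0.95) "dispersal_limitation"
    else if (grid$r[k] < -0.95) "homogenizing_dispersal"
    else "undominated"
    expect_identical(got, want)
  }
})

md <- data.frame(
  sample_id = c("W1_1", "W1_2", "W1_3", "W1_4", "W2_1", "W2_2"),
  well_id = c("W1", "W1", "W1", "W1", "W2", "W2"),
  collection_day = c(1, 2, 3, 4, 1, 2),
  pH = c(8, 8.2, 8.1, 8, 11, 11.2))

test_that("groupings enumerate the expected pair sets", {
  w <- buildGroupings(md, "within_well")[[1]]
  expect_identical(nrow(groupingPairs(w)), 7L)  # C(4,2) + C(2,2)
  expect_identical(sum(groupingPairs(w)[, 1] %in%
                         md$sample_id[1:4] &
                       groupingPairs(w)[, 2] %in% md$sample_id[1:4]), 6L)
  b <- buildGroupings(md, "between_well")[[1]]
  expect_identical(nrow(groupingPairs(b)), 8L)  # 4 x 2
  a <- buildGroupings(md, "all")[[1]]
  expect_identical(nrow(groupingPairs(a)), 15L)
})

test_that("pH categories come from mean well pH or an explicit map", {
  g <- buildGroupings(md, "ph_category")
  names(g) <- vapply(g, function(x) x@name, character(1))
  expect_identical(nrow(groupingPairs(g$ph_neutral)), 6L)   # W1 pairs
  expect_identical(nrow(groupingPairs(g$ph_extreme)), 1L)   # W2 pair
  expect_identical(nrow(groupingPairs(g$ph_moderate)), 0L)
  gm <- buildGroupings(md, "ph_category",
                       phMap = c(W1 = "extreme", W2 = "extreme"))
  names(gm) <- vapply(gm, function(x) x@name, character(1))
  # pooled within- and between-well pairs inside the category
  expect_identical(nrow(groupingPairs(gm$ph_extreme)), 15L)
  expect_error(buildGroupings(md, "ph_category",
                              phMap = c(QV9 = "neutral")), "QV9")

  # the shipped well-to-category map drives explicit assignment
  mapFile <- system.file("extdata", "cromo_well_ph_categories.csv",
                         package = "ecoassembly")
  map <- utils::read.csv(mapFile, stringsAsFactors = FALSE)
  phMap <- stats::setNames(map$ph_category, map$well_id)
  expect_identical(unname(phMap["N08-A"]), "extreme")
  md2 <- data.frame(sample_id = paste0("s", seq_len(nrow(map))),
                    well_id = map$well_id)
  g2 <- buildGroupings(md2, "ph_category", phMap = phMap)
  sizes <- vapply(g2, function(x) nrow(groupingPairs(x)), integer(1))
  expect_equal(unname(sizes), rep(6L, 3L))
})

mkPM <- function(v, ids, kind) {
  dimnames(v) <- list(ids, ids)
  PairwiseMatrix(v, kind = kind)
}

test_that("process fractions count, percentage and exclude correctly", {
  ids <- paste0("S", 1:5)
  b <- matrix(0, 5, 5)
  r <- matrix(0, 5, 5)
  # craft pair values: S1S2 vs=2.5, S1S3 hs=-3, S1S4 dl rc=.99,
  # S1S5 hd rc=-.99, others undominated; S2S3 degenerate NaN
  b[1, 2] <- b[2, 1] <- 2.5
  b[1, 3] <- b[3, 1] <- -3
  b[2, 3] <- b[3, 2] <- NaN
  r[1, 4] <- r[4, 1] <- 0.99
  r[1, 5] <- r[5, 1] <- -0.99
  diag(b) <- NA; diag(r) <- NaN
  bm <- mkPM(b, ids, "bnti")
  rm_ <- mkPM(r, ids, "rcbray")
  g <- new("SampleGrouping", name = "all",
           pairs = t(utils::combn(ids, 2)), definition = "all")
  pf <- processFractions(bm, rm_, g)
  expect_identical(pf@nPairs, 10L)
  expect_identical(pf@nExcluded, 1L)
  cnt <- processCounts(pf)
  expect_identical(unname(cnt), c(1L, 1L, 1L, 1L, 5L))
  expect_equal(sum(processPercentages(pf)), 100)
  expect_equal(unname(processPercentages(pf)["undominated"]),
               100 * 5 / 9)
  # ten classified pairs at 50/20/20/10/0
  tab <- as.data.frame(pf)
  expect_identical(tab$n_pairs, 10L)
})

test_that("RCbray values are never consulted for significant betaNTI", {
  ids <- paste0("S", 1:4)
  b <- matrix(3, 4, 4); diag(b) <- NA
  rNA <- matrix(NaN, 4, 4)
  rAlt <- matrix(-0.99, 4, 4); diag(rAlt) <- NaN
  g <- new("SampleGrouping", name = "all",
           pairs = t(utils::combn(ids, 2)), definition = "all")
  f1 <- processFractions(mkPM(b, ids, "bnti"), mkPM(rNA, ids, "rcbray"), g)
  f2 <- processFractions(mkPM(b, ids, "bnti"), mkPM(rAlt, ids, "rcbray"), g)
  expect_identical(processCounts(f1), processCounts(f2))
  expect_equal(unname(processPercentages(f1)["variable_selection"]), 100)
})

test_that("degenerate groupings error clearly", {
  ids <- c("S1", "S2")
  b <- matrix(NaN, 2, 2)
  r <- matrix(NaN, 2, 2)
  g <- new("SampleGrouping", name = "all",
           pairs = matrix(ids, 1), definition = "all")
  expect_error(processFractions(mkPM(b, ids, "bnti"),
                                mkPM(r, ids, "rcbray"), g), "excluded")
  gUnknown <- new("SampleGrouping", name = "x",
                  pairs = matrix(c("S1", "S9"), 1), definition = "custom")
  expect_error(assemblyCalls(mkPM(b, ids, "bnti"),
                             mkPM(r, ids, "rcbray"), gUnknown), "S9")
})
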