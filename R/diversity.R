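#' Bray-Curtis dissimilarity matrix
#'
#' `BC(a, b) = sum|x_a - x_b| / sum(x_a + x_b)` over taxa, computed on
#' within-sample relative abundances by default so that per-sample
#' sequencing depth does not enter.
#'
#' @param counts a [CountTable-class].
#' @param normalize divide each sample by its total first (default TRUE).
#' @return A [PairwiseMatrix-class] of kind `"dissimilarity"` in \[0, 1\].
#' @export
brayCurtisMatrix <- function(counts, normalize = TRUE) {
  stopifnot(is(counts, "CountTable"))
  m <- countMatrix(counts)
  if (normalize) m <- .relAbund(m)
  d <- as.matrix(vegan::vegdist(m, method = "bray"))
  PairwiseMatrix(d, kind = "dissimilarity")
}

#' Per-sample richness
#'
#' Number of taxa with abundance greater than zero.
#'
#' @param counts a [CountTable-class].
#' @return named integer vector.
#' @export
richness <- function(counts) {
  stopifnot(is(counts, "CountTable"))
  s <- vegan::specnumber(countMatrix(counts))
  stats::setNames(as.integer(s), sampleIDs(counts))
}

#' Pielou evenness per sample
#'
#' `J = H / ln(S)` with Shannon `H = -sum p ln p` (natural log) and
#' richness `S`. Single-taxon samples have undefined evenness (NaN).
#'
#' @param counts a [CountTable-class].
#' @return named numeric vector in \[0, 1\] (NaN where S = 1).
#' @export
pielouEvenness <- function(counts) {
  stopifnot(is(counts, "CountTable"))
  m <- countMatrix(counts)
  H <- vegan::diversity(m, index = "shannon")
  S <- vegan::specnumber(m)
  J <- ifelse(S > 1, H / log(S), NaN)
  stats::setNames(as.numeric(J), sampleIDs(counts))
}

#' Environmental difference matrix
#'
#' Absolute pairwise difference of one metadata variable; pairs involving
#' a missing value are NA and are excluded from downstream statistics,
#' never imputed.
#'
#' @param metadata data.frame with `sample_id` and the variable.
#' @param variable column name.
#' @return A [PairwiseMatrix-class] of kind `"env_difference"`.
#' @export
envDifferenceMatrix <- function(metadata, variable) {
  if (!variable %in% colnames(metadata))
    stop("variable not in metadata: ", variable)
  v <- metadata[[variable]]
  ids <- as.character(metadata$sample_id)
  if (all(is.na(v))) stop("variable is entirely missing: ", variable)
  if (sum(!is.na(v)) < 3L)
    stop("variable present for fewer than 3 samples: ", variable)
  d <- abs(outer(v, v, "-"))
  diag(d) <- 0
  dimnames(d) <- list(ids, ids)
  PairwiseMatrix(d, kind = "env_difference")
}

# lower-triangle vector of a square matrix
.lowerTri <- function(m) m[lower.tri(m)]

#' Mantel test between two pairwise matrices
#'
#' Pearson correlation of the lower triangles, with a two-sided
#' permutation p-value obtained by jointly permuting the rows and columns
#' of the second matrix:
#' `p = (1 + #\{|r_perm| >= |r_obs|\}) / (1 + permutations)`.
#' Pairs missing in either matrix are excluded.
#'
#' @param m1,m2 [PairwiseMatrix-class] objects sharing sample IDs.
#' @param permutations number of permutations (default 999).
#' @param seed RNG seed.
#' @return list with `r`, `p`, `permutations`, `n` (samples used).
#' @export
mantelTest <- function(m1, m2, permutations = 999L, seed = 1L) {
  stopifnot(is(m1, "PairwiseMatrix"), is(m2, "PairwiseMatrix"))
  ids <- intersect(sampleIDs(m1), sampleIDs(m2))
  if (length(ids) < 4L) stop("fewer than 4 shared samples")
  a <- as.matrix(m1)[ids, ids]
  b <- as.matrix(m2)[ids, ids]
  t1 <- .lowerTri(a)
  mask1 <- is.finite(t1)
  if (!any(mask1)) stop("no usable pairs in first matrix")
  rOf <- function(bm) {
    t2 <- .lowerTri(bm)
    use <- mask1 & is.finite(t2)
    x <- t1[use]; y <- t2[use]
    if (length(x) < 3L || stats::sd(x) == 0 || stats::sd(y) == 0)
      stop("zero variance in a matrix triangle")
    stats::cor(x, y)
  }
  rObs <- rOf(b)
  set.seed(seed)
  n <- length(ids)
  exceed <- 0L
  for (k in seq_len(permutations)) {
    p <- sample.int(n)
    if (abs(rOf(b[p, p])) >= abs(rObs) - 1e-12) exceed <- exceed + 1L
  }
  list(r = rObs, p = (1 + exceed) / (1 + permutations),
       permutations = as.integer(permutations), n = n)
}

#' Abundance-weighted environmental niche values per taxon
#'
#' `niche_i = sum_s (n_is / n_i.) * v_s`: the mean of the environmental
#' variable over samples, weighted by where the taxon's reads occur. A
#' convex combination, so always within the observed range of the
#' variable. Taxa with zero total abundance are excluded with a report;
#' samples missing the variable are dropped first with a warning.
#'
#' @param counts a [CountTable-class].
#' @param metadata data.frame with `sample_id` and the variable.
#' @param variable column name (e.g. `"pH"`).
#' @return named numeric vector over taxa, in the variable's units.
#' @export
nicheValues <- function(counts, metadata, variable) {
  stopifnot(is(counts, "CountTable"))
  if (!variable %in% colnames(metadata))
    stop("variable not in metadata: ", variable)
  m <- countMatrix(counts)
  v <- metadata[[variable]][match(rownames(m), metadata$sample_id)]
  if (anyNA(v)) {
    drop <- rownames(m)[is.na(v)]
    warning("samples without ", variable, " dropped: ",
            paste(drop, collapse = ", "))
    m <- m[!is.na(v), , drop = FALSE]
    v <- v[!is.na(v)]
  }
  tot <- colSums(m)
  if (any(tot == 0))
    message(sum(tot == 0), " taxa with zero total abundance excluded")
  m <- m[, tot > 0, drop = FALSE]
  niche <- as.numeric(crossprod(m, v) / colSums(m))
  stats::setNames(niche, colnames(m))
}

#' Mantel correlogram of phylogenetic signal in niche values
#'
#' Splits tip-to-tip phylogenetic distances into equal-width classes
#' spanning (0, max\] and, per class, computes a Mantel statistic between
#' the class-membership indicator and the absolute niche difference
#' |niche_i - niche_j|. The reported statistic is sign-flipped
#' (`r = -cor(indicator, niche difference)`) so that positive values mean
#' taxa in that distance class have more similar niches than average —
#' positive short-distance classes indicate phylogenetic signal.
#' Two-sided permutation p-values (permuting taxa) are tested with a
#' progressive Bonferroni correction: class k is significant when
#' `p_k <= alpha / k`.
#'
#' @param tipDist tip distances ([PairwiseMatrix-class] of kind
#'   `"distance"` or matrix).
#' @param niche named numeric vector from [nicheValues()].
#' @param nClasses number of distance classes; default Sturges' rule on
#'   the number of tip pairs.
#' @param permutations permutations per class (default 999).
#' @param seed RNG seed.
#' @param alpha familywise significance level (default 0.05).
#' @return data.frame with columns class_lo, class_hi, n_pairs,
#'   mantel_r, p, significant.
#' @export
mantelCorrelogram <- function(tipDist, niche, nClasses = NULL,
                              permutations = 999L, seed = 1L,
                              alpha = 0.05) {
  D <- .distFor(tipDist, names(niche))
  nd <- abs(outer(niche, niche, "-"))
  n <- length(niche)
  td <- .lowerTri(D)
  ndt <- .lowerTri(nd)
  if (is.null(nClasses))
    nClasses <- max(2L, ceiling(log2(length(td)) + 1))
  edges <- seq(0, max(td), length.out = nClasses + 1L)
  cls <- cut(td, breaks = edges, include.lowest = TRUE)
  constNiche <- stats::sd(ndt) == 0
  set.seed(seed)
  perms <- if (constNiche) NULL else
    replicate(permutations, sample.int(n))
  out <- lapply(seq_len(nClasses), function(k) {
    ind <- as.integer(as.integer(cls) == k)
    npair <- sum(ind, na.rm = TRUE)
    if (npair == 0L || npair == length(ind) || constNiche)
      return(data.frame(class_lo = edges[k], class_hi = edges[k + 1L],
                        n_pairs = npair, mantel_r = NA_real_,
                        p = NA_real_, significant = FALSE))
    indM <- matrix(0L, n, n)
    indM[lower.tri(indM)] <- ind
    indM <- indM + t(indM)
    rObs <- -stats::cor(ind, ndt)
    exceed <- 0L
    for (j in seq_len(permutations)) {
      p <- perms[, j]
      rP <- -stats::cor(.lowerTri(indM[p, p]), ndt)
      if (abs(rP) >= abs(rObs) - 1e-12) exceed <- exceed + 1L
    }
    pval <- (1 + exceed) / (1 + permutations)
    data.frame(class_lo = edges[k], class_hi = edges[k + 1L],
               n_pairs = npair, mantel_r = rObs, p = pval,
               significant = pval <= alpha / k)
  })
  do.call(rbind, out)
}

#' PERMANOVA on a dissimilarity matrix
#'
#' Sequential (Type I) partitioning of the Gower-centered total sum of
#' squares in the given term order, with pseudo-F tests against the
#' residual by free permutation of sample identities (vegan's `adonis2`).
#' Samples missing any term are dropped listwise with a warning.
#'
#' @param dissim a [PairwiseMatrix-class] of kind `"dissimilarity"`.
#' @param metadata data.frame with `sample_id` and the term columns.
#' @param terms ordered character vector of metadata columns.
#' @param permutations number of permutations (default 999).
#' @param seed RNG seed.
#' @return data.frame with one row per term plus Residual and Total:
#'   Df, SumOfSqs, MeanSqs, F, R2, p.
#' @export
permanovaTable <- function(dissim, metadata, terms, permutations = 999L,
                           seed = 1L) {
  stopifnot(is(dissim, "PairwiseMatrix"))
  miss <- setdiff(terms, colnames(metadata))
  if (length(miss)) stop("terms not in metadata: ",
                         paste(miss, collapse = ", "))
  ids <- intersect(sampleIDs(dissim), as.character(metadata$sample_id))
  dat <- metadata[match(ids, metadata$sample_id), terms, drop = FALSE]
  keep <- stats::complete.cases(dat)
  if (!all(keep)) {
    warning(sum(!keep), " sample(s) dropped for missing term values")
    ids <- ids[keep]
    dat <- dat[keep, , drop = FALSE]
  }
  if (length(ids) < 3L) stop("too few complete samples for PERMANOVA")
  d <- stats::as.dist(as.matrix(dissim)[ids, ids])
  rownames(dat) <- ids
  set.seed(seed)
  fit <- vegan::adonis2(d ~ ., data = dat, by = "terms",
                        permutations = permutations)
  out <- data.frame(Df = fit$Df, SumOfSqs = fit$SumOfSqs,
                    MeanSqs = fit$SumOfSqs / fit$Df,
                    F = fit$F, R2 = fit$R2, p = fit$`Pr(>F)`)
  rownames(out) <- rownames(fit)
  out
}
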