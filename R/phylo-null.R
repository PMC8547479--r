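#' Patristic (cophenetic) tip distances
#'
#' Sum of branch lengths along the tree path between every pair of tips.
#'
#' @param tree an [ape::phylo] with branch lengths.
#' @return A [PairwiseMatrix-class] of kind `"distance"` over the tips.
#' @export
copheneticDistances <- function(tree) {
  validateTree(tree)
  PairwiseMatrix(ape::cophenetic.phylo(tree), kind = "distance")
}

# extract an aligned distance matrix for the given taxa
.distFor <- function(dist, taxa) {
  if (is(dist, "PairwiseMatrix")) dist <- as.matrix(dist)
  miss <- setdiff(taxa, rownames(dist))
  if (length(miss))
    stop("taxa absent from distance matrix: ", paste(miss, collapse = ", "))
  dist[taxa, taxa, drop = FALSE]
}

#' Mean nearest taxon distance of one sample
#'
#' Distance from each taxon present in the sample to its nearest
#' phylogenetic neighbour also present, averaged either with relative
#' abundance weights (default) or arithmetically.
#'
#' @param abundances named numeric vector of abundances for one sample.
#' @param dist tip distances ([PairwiseMatrix-class] of kind `"distance"`
#'   or a plain matrix).
#' @param weighted use relative-abundance weights (default TRUE).
#' @return MNTD as a single number.
#' @export
mntd <- function(abundances, dist, weighted = TRUE) {
  pres <- names(abundances)[abundances > 0]
  if (length(pres) < 2L)
    stop("MNTD undefined: fewer than 2 taxa present")
  D <- .distFor(dist, pres)
  diag(D) <- Inf
  nn <- apply(D, 1L, min)
  if (weighted) {
    p <- abundances[pres] / sum(abundances[pres])
    sum(p * nn)
  } else {
    mean(nn)
  }
}

#' Between-sample mean nearest taxon distance (betaMNTD)
#'
#' For each taxon in one sample, the distance to its nearest neighbour in
#' the other sample (zero for shared taxa), abundance-weighted within each
#' sample and averaged over the two directions. Symmetric in its two
#' samples and invariant to rescaling either sample's abundances.
#'
#' @param sampleA,sampleB named numeric abundance vectors.
#' @param dist tip distances covering all present taxa.
#' @param weighted use relative-abundance weights (default TRUE);
#'   otherwise each present taxon contributes equally.
#' @return betaMNTD as a single non-negative number.
#' @export
betaMNTD <- function(sampleA, sampleB, dist, weighted = TRUE) {
  presA <- names(sampleA)[sampleA > 0]
  presB <- names(sampleB)[sampleB > 0]
  if (!length(presA) || !length(presB)) stop("empty sample")
  D <- .distFor(dist, union(presA, presB))
  minToB <- apply(D[presA, presB, drop = FALSE], 1L, min)
  minToA <- apply(D[presB, presA, drop = FALSE], 1L, min)
  if (weighted) {
    pA <- sampleA[presA] / sum(sampleA[presA])
    pB <- sampleB[presB] / sum(sampleB[presB])
  } else {
    pA <- rep(1 / length(presA), length(presA))
    pB <- rep(1 / length(presB), length(presB))
  }
  0.5 * (sum(pA * minToB) + sum(pB * minToA))
}

# Vectorized betaMNTD over all sample pairs for one taxon relabeling.
# P: taxa x samples weight matrix (columns sum to 1), presence: list of
# integer taxon indices per sample, D: taxa x taxa distances, perm:
# integer permutation of taxa (identity for the observed statistic).
.betaMNTDAll <- function(P, presence, D, perm) {
  nsamp <- length(presence)
  ntaxa <- nrow(D)
  M <- matrix(0, ntaxa, nsamp)
  for (b in seq_len(nsamp)) {
    v <- .rowMinsCols(D, perm[presence[[b]]])
    M[, b] <- v[perm]
  }
  X <- crossprod(P, M)          # X[a, b] = sum_i P[i, a] * min dist to b
  0.5 * (X + t(X))
}

# shared machinery: observed betaMNTD matrix plus tip-shuffle null summary
.betaMNTDNull <- function(counts, dist, reps, seed, weighted,
                          keepNull = FALSE) {
  stopifnot(is(counts, "CountTable"), reps >= 1L)
  m <- countMatrix(counts)
  taxa <- colnames(m)
  D <- .distFor(dist, taxa)
  presence <- lapply(seq_len(nrow(m)), function(i) which(m[i, ] > 0))
  if (any(lengths(presence) < 1L)) stop("empty sample")
  W <- if (weighted) t(.relAbund(m)) else
    t(.relAbund((m > 0) * 1))
  idx <- seq_along(taxa)
  obs <- .betaMNTDAll(W, presence, D, idx)
  nsamp <- nrow(m)
  sumv <- matrix(0, nsamp, nsamp)
  sumsq <- matrix(0, nsamp, nsamp)
  draws <- if (keepNull) array(NA_real_, c(reps, nsamp, nsamp)) else NULL
  set.seed(seed)
  for (r in seq_len(reps)) {
    perm <- sample.int(length(idx))
    val <- .betaMNTDAll(W, presence, D, perm)
    sumv <- sumv + val
    sumsq <- sumsq + val * val
    if (keepNull) draws[r, , ] <- val
  }
  nullMean <- sumv / reps
  nullSD <- sqrt(pmax(sumsq / reps - nullMean^2, 0))  # population form
  dn <- list(rownames(m), rownames(m))
  dimnames(obs) <- dimnames(nullMean) <- dimnames(nullSD) <- dn
  list(obs = obs, nullMean = nullMean, nullSD = nullSD, draws = draws,
       ids = rownames(m))
}

#' betaNTI matrix by tip-shuffling null
#'
#' Standardizes observed betaMNTD for every sample pair against a null in
#' which taxon labels are shuffled across the full tip distance matrix.
#' One shared shuffle per replicate is applied to all pairs, and the null
#' standard deviation uses the population form (denominator `reps`), so
#' results are bit-reproducible for a given seed. Pairs whose null has
#' zero spread are flagged degenerate and reported as NaN with a warning.
#'
#' @param counts a [CountTable-class], taxa aligned to `dist`.
#' @param dist tip distances ([copheneticDistances()] output or matrix).
#' @param reps number of label shuffles (default 999).
#' @param seed RNG seed.
#' @param weighted abundance-weighted betaMNTD (default TRUE).
#' @return A [PairwiseMatrix-class] of kind `"bnti"` with an NA diagonal.
#'   betaNTI > 2 indicates variable selection, betaNTI < -2 homogeneous
#'   selection.
#' @export
betaNTIMatrix <- function(counts, dist, reps = 999L, seed = 1L,
                          weighted = TRUE) {
  nm <- .betaMNTDNull(counts, dist, reps, seed, weighted)
  z <- (nm$obs - nm$nullMean) / nm$nullSD
  degen <- nm$nullSD == 0
  diag(degen) <- FALSE
  if (any(degen)) {
    z[degen] <- NaN
    warning(sum(degen) / 2, " sample pair(s) with degenerate null (sd = 0)")
  }
  diag(z) <- NA_real_
  dimnames(z) <- list(nm$ids, nm$ids)
  PairwiseMatrix(z, kind = "bnti")
}

#' Nearest taxon index per sample
#'
#' Standardized deviation of each sample's observed MNTD from the same
#' tip-shuffling null used for betaNTI, with the sign flipped so that
#' positive values indicate phylogenetic clustering (observed relatives
#' closer than expected by chance).
#'
#' @inheritParams betaNTIMatrix
#' @param keepNull retain the per-sample null draws in the results.
#' @return Named list of [NullModelResult-class], one per sample; the
#'   score slot holds NTI.
#' @export
nti <- function(counts, dist, reps = 999L, seed = 1L, weighted = TRUE,
                keepNull = FALSE) {
  stopifnot(is(counts, "CountTable"), reps >= 1L)
  m <- countMatrix(counts)
  taxa <- colnames(m)
  D <- .distFor(dist, taxa)
  presence <- lapply(seq_len(nrow(m)), function(i) which(m[i, ] > 0))
  if (any(lengths(presence) < 2L))
    stop("NTI undefined for samples with fewer than 2 taxa: ",
         paste(rownames(m)[lengths(presence) < 2L], collapse = ", "))
  obs <- vapply(seq_len(nrow(m)), function(i)
    mntd(m[i, ], D, weighted = weighted), numeric(1))
  nulls <- matrix(NA_real_, reps, nrow(m))
  set.seed(seed)
  for (r in seq_len(reps)) {
    perm <- sample.int(length(taxa))
    for (i in seq_len(nrow(m))) {
      idx <- perm[presence[[i]]]
      Dsub <- D[idx, idx, drop = FALSE]
      diag(Dsub) <- Inf
      nn <- apply(Dsub, 1L, min)
      nulls[r, i] <- if (weighted) {
        p <- m[i, presence[[i]]] / sum(m[i, presence[[i]]])
        sum(p * nn)
      } else mean(nn)
    }
  }
  out <- lapply(seq_len(nrow(m)), function(i) {
    nv <- nulls[, i]
    mu <- mean(nv)
    sdv <- sqrt(mean((nv - mu)^2))
    score <- if (sdv == 0) NaN else -(obs[i] - mu) / sdv
    NullModelResult(observed = obs[i], nullValues = nv, score = score,
                    reps = reps, seed = seed, keepNull = keepNull)
  })
  names(out) <- rownames(m)
  out
}
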