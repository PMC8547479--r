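#' Build the metacommunity profile
#'
#' Per-taxon occurrence frequency (fraction of samples with abundance
#' > 0) and mean within-sample relative abundance across all samples.
#' These are the two sampling-weight vectors of the Raup-Crick null.
#' Taxa absent from every sample are excluded.
#'
#' @param counts a [CountTable-class].
#' @return A [MetacommunityProfile-class].
#' @export
buildMetacommunityProfile <- function(counts) {
  stopifnot(is(counts, "CountTable"))
  m <- countMatrix(counts)
  keep <- colSums(m) > 0
  m <- m[, keep, drop = FALSE]
  freq <- colMeans(m > 0)
  mra <- colMeans(.relAbund(m))
  mra <- mra / sum(mra)
  new("MetacommunityProfile", taxonIDs = colnames(m),
      occurrenceFreq = unname(freq), meanRelAbund = unname(mra),
      gamma = ncol(m))
}

# simulate one community: observed richness drawn by occurrence
# frequency, observed total filled by mean relative abundance, each
# drawn taxon seeded with one individual so the richness is realized
.simCommunity <- function(S, N, freq, mra) {
  gamma <- length(freq)
  sel <- sample.int(gamma, S, prob = freq)
  x <- numeric(gamma)
  x[sel] <- 1
  if (N > S) {
    p <- mra[sel]
    if (sum(p) <= 0) p <- rep(1, length(sel))
    x[sel] <- x[sel] + stats::rmultinom(1L, N - S, prob = p)[, 1L]
  }
  x
}

#' Abundance-weighted Raup-Crick (RCbray) for one sample pair
#'
#' Simulates both samples independently from the metacommunity profile —
#' richness drawn without replacement with probability proportional to
#' occurrence frequency, then the sample's total abundance distributed
#' with probability proportional to mean relative abundance over the
#' drawn taxa — and ranks the observed Bray-Curtis dissimilarity within
#' the null distribution:
#' `RC = 2 * (#\{null < obs\} + 0.5 * #\{null = obs\}) / reps - 1`.
#'
#' @param sampleA,sampleB named numeric count vectors.
#' @param profile a [MetacommunityProfile-class] covering their taxa.
#' @param reps null replicates (default 999).
#' @param seed RNG seed.
#' @param normalize compute Bray-Curtis on relative abundances (default
#'   TRUE) on both the observed and simulated side.
#' @param depthMode `"observed"` keeps each sample's own read total;
#'   `"rarefied"` uses the smaller of the two totals for both.
#' @param keepNull retain the null Bray-Curtis draws.
#' @return A [NullModelResult-class]; the score slot holds RCbray in
#'   \[-1, 1\]. RCbray > 0.95 indicates dispersal limitation,
#'   RCbray < -0.95 homogenizing dispersal.
#' @export
rcBrayPair <- function(sampleA, sampleB, profile, reps = 999L, seed = 1L,
                       normalize = TRUE,
                       depthMode = c("observed", "rarefied"),
                       keepNull = FALSE) {
  depthMode <- match.arg(depthMode)
  stopifnot(is(profile, "MetacommunityProfile"))
  if (reps < 1L) stop("reps must be >= 1")
  if (sum(sampleA) <= 0 || sum(sampleB) <= 0) stop("empty sample")
  taxa <- profile@taxonIDs
  a <- sampleA[taxa]
  b <- sampleB[taxa]
  a[is.na(a)] <- 0
  b[is.na(b)] <- 0
  extraA <- setdiff(names(sampleA)[sampleA > 0], taxa)
  extraB <- setdiff(names(sampleB)[sampleB > 0], taxa)
  if (length(extraA) || length(extraB))
    stop("taxa not covered by metacommunity profile: ",
         paste(union(extraA, extraB), collapse = ", "))
  SA <- sum(a > 0); SB <- sum(b > 0)
  if (SA > profile@gamma || SB > profile@gamma)
    stop("sample richness exceeds metacommunity gamma")
  NA_ <- round(sum(a)); NB <- round(sum(b))
  if (depthMode == "rarefied") NA_ <- NB <- min(NA_, NB)
  NA_ <- max(NA_, SA); NB <- max(NB, SB)
  obs <- .bray(a, b, normalize = normalize)
  freq <- profile@occurrenceFreq
  mra <- profile@meanRelAbund
  set.seed(seed)
  nulls <- vapply(seq_len(reps), function(r) {
    x <- .simCommunity(SA, NA_, freq, mra)
    y <- .simCommunity(SB, NB, freq, mra)
    .bray(x, y, normalize = normalize)
  }, numeric(1))
  tol <- 1e-10
  below <- sum(nulls < obs - tol)
  ties <- sum(abs(nulls - obs) <= tol)
  score <- 2 * (below + 0.5 * ties) / reps - 1
  NullModelResult(observed = obs, nullValues = nulls, score = score,
                  reps = reps, seed = seed, keepNull = keepNull)
}

#' RCbray matrix over all (or selected) sample pairs
#'
#' Each pair is evaluated with its own deterministic RNG substream
#' derived from the master seed and the sorted pair of sample IDs, so the
#' result does not depend on evaluation order and a matrix restricted to
#' a subset of pairs agrees exactly with the full matrix on those pairs.
#'
#' @param counts a [CountTable-class].
#' @param reps,seed,normalize,depthMode as in [rcBrayPair()].
#' @param pairs optional two-column character matrix of sample-ID pairs
#'   to evaluate; all other entries are left NA.
#' @return A [PairwiseMatrix-class] of kind `"rcbray"` with NaN diagonal.
#' @export
rcBrayMatrix <- function(counts, reps = 999L, seed = 1L, normalize = TRUE,
                         depthMode = c("observed", "rarefied"),
                         pairs = NULL) {
  depthMode <- match.arg(depthMode)
  stopifnot(is(counts, "CountTable"))
  m <- countMatrix(counts)
  ids <- rownames(m)
  profile <- buildMetacommunityProfile(counts)
  if (is.null(pairs)) pairs <- .allPairs(ids)
  bad <- setdiff(unique(c(pairs)), ids)
  if (length(bad))
    stop("unknown sample IDs in pairs: ", paste(bad, collapse = ", "))
  v <- matrix(NA_real_, length(ids), length(ids),
              dimnames = list(ids, ids))
  diag(v) <- NaN
  for (k in seq_len(nrow(pairs))) {
    # canonical evaluation order so results are pair-order invariant
    i <- pairs[k, 1L]; j <- pairs[k, 2L]
    if (match(i, ids) > match(j, ids)) { tmp <- i; i <- j; j <- tmp }
    res <- rcBrayPair(m[i, ], m[j, ], profile, reps = reps,
                      seed = .pairSeed(seed, i, j), normalize = normalize,
                      depthMode = depthMode)
    v[i, j] <- v[j, i] <- nullScore(res)
  }
  PairwiseMatrix(v, kind = "rcbray")
}
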