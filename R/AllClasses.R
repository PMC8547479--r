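#' @import methods
NULL

PROCESS_LEVELS <- c("variable_selection", "homogeneous_selection",
                    "dispersal_limitation", "homogenizing_dispersal",
                    "undominated")

PAIRWISE_KINDS <- c("bnti", "rcbray", "dissimilarity", "distance",
                    "env_difference")

#' Community count table
#'
#' Samples-by-taxa matrix of non-negative abundances. Row names are sample
#' IDs, column names are taxon IDs; both must be unique and every sample
#' must have a positive total.
#'
#' @slot counts numeric matrix, samples in rows, taxa in columns.
#' @exportClass CountTable
setClass("CountTable", slots = c(counts = "matrix"))

setValidity("CountTable", function(object) {
  m <- object@counts
  if (!is.numeric(m)) return("counts must be numeric")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    return("counts must have sample (row) and taxon (column) names")
  if (anyDuplicated(rownames(m))) return("duplicate sample IDs")
  if (anyDuplicated(colnames(m))) return("duplicate taxon IDs")
  if (anyNA(m)) return("counts contain missing values")
  if (any(m < 0)) return("counts contain negative values")
  tot <- rowSums(m)
  if (any(tot <= 0)) {
    bad <- rownames(m)[tot <= 0]
    return(paste0("samples with zero total abundance: ",
                  paste(bad, collapse = ", ")))
  }
  TRUE
})

#' Construct a CountTable
#'
#' @param counts numeric matrix (samples x taxa) with dimnames.
#' @return A [CountTable-class] object.
#' @examples
#' m <- matrix(c(5, 0, 1, 3), 2, 2,
#'             dimnames = list(c("S1", "S2"), c("otuA", "otuB")))
#' CountTable(m)
#' @export
CountTable <- function(counts) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  new("CountTable", counts = counts)
}

#' Square pairwise matrix
#'
#' Symmetric sample-by-sample (or taxon-by-taxon) matrix with a declared
#' kind. The diagonal is zero for dissimilarity/distance kinds and may be
#' NA for null-model scores (bnti, rcbray) whose self-comparison is
#' undefined.
#'
#' @slot ids character vector of row/column IDs.
#' @slot values square numeric matrix.
#' @slot kind one of `"bnti"`, `"rcbray"`, `"dissimilarity"`, `"distance"`,
#'   `"env_difference"`.
#' @exportClass PairwiseMatrix
setClass("PairwiseMatrix",
         slots = c(ids = "character", values = "matrix", kind = "character"))

setValidity("PairwiseMatrix", function(object) {
  v <- object@values
  ids <- object@ids
  if (length(object@kind) != 1L || !object@kind %in% PAIRWISE_KINDS)
    return(paste("kind must be one of:", paste(PAIRWISE_KINDS, collapse = ", ")))
  if (nrow(v) != ncol(v)) return("matrix is not square")
  if (length(ids) != nrow(v)) return("ids length does not match matrix")
  if (anyDuplicated(ids)) return("duplicate IDs")
  off <- v - t(v)
  off[is.na(off)] <- 0
  if (max(abs(off)) > 1e-8) return("matrix is not symmetric (tolerance 1e-8)")
  # NA must occur symmetrically
  if (any(is.na(v) != is.na(t(v)))) return("asymmetric missingness")
  d <- diag(v)
  if (object@kind %in% c("dissimilarity", "distance", "env_difference")) {
    if (any(is.na(d)) || max(abs(d)) > 1e-8)
      return("diagonal must be zero for this kind")
  }
  TRUE
})

#' Construct a PairwiseMatrix
#'
#' @param values square numeric matrix with matching dimnames.
#' @param kind matrix kind, see [PairwiseMatrix-class].
#' @param ids optional IDs; defaults to `rownames(values)`.
#' @return A [PairwiseMatrix-class] object.
#' @export
PairwiseMatrix <- function(values, kind, ids = rownames(values)) {
  values <- as.matrix(values)
  if (is.null(ids)) stop("pairwise matrix needs row/column IDs")
  dimnames(values) <- list(ids, ids)
  new("PairwiseMatrix", ids = as.character(ids), values = values, kind = kind)
}

#' Null model result
#'
#' Observed statistic, its null distribution summary and the standardized
#' score. For z-type statistics (betaNTI, NTI) the score is the signed
#' standardization of the observed value against the null; for
#' Raup-Crick it is the rank-based score rescaled to \[-1, 1\]. When the
#' null distribution has zero spread the result is flagged degenerate and
#' the score is NaN.
#'
#' @slot observed observed statistic.
#' @slot nullMean,nullSD summary of the null distribution (population SD).
#' @slot nullValues the retained null draws (may be empty).
#' @slot score standardized score.
#' @slot reps number of null draws.
#' @slot seed RNG seed used.
#' @slot degenerate TRUE when nullSD is zero.
#' @exportClass NullModelResult
setClass("NullModelResult",
         slots = c(observed = "numeric", nullMean = "numeric",
                   nullSD = "numeric", nullValues = "numeric",
                   score = "numeric", reps = "integer", seed = "integer",
                   degenerate = "logical"))

setValidity("NullModelResult", function(object) {
  if (object@reps < 1L) return("reps must be >= 1")
  if (length(object@nullValues) &&
      length(object@nullValues) != object@reps)
    return("nullValues length must equal reps when retained")
  TRUE
})

NullModelResult <- function(observed, nullValues, score, reps, seed,
                            keepNull = FALSE) {
  mu <- mean(nullValues)
  sdv <- sqrt(mean((nullValues - mu)^2))  # population form, reproducible
  new("NullModelResult",
      observed = observed, nullMean = mu, nullSD = sdv,
      nullValues = if (keepNull) nullValues else numeric(0),
      score = score, reps = as.integer(reps), seed = as.integer(seed),
      degenerate = sdv == 0)
}

#' Metacommunity profile
#'
#' Per-taxon occurrence frequency and mean relative abundance across the
#' regional pool of samples, used as the sampling weights of the
#' Raup-Crick null. Taxa with zero total abundance are excluded.
#'
#' @slot taxonIDs character taxa.
#' @slot occurrenceFreq fraction of samples where the taxon occurs, in (0, 1].
#' @slot meanRelAbund mean within-sample relative abundance; sums to 1.
#' @slot gamma number of taxa in the pool.
#' @exportClass MetacommunityProfile
setClass("MetacommunityProfile",
         slots = c(taxonIDs = "character", occurrenceFreq = "numeric",
                   meanRelAbund = "numeric", gamma = "integer"))

setValidity("MetacommunityProfile", function(object) {
  f <- object@occurrenceFreq
  a <- object@meanRelAbund
  if (length(f) != object@gamma || length(a) != object@gamma ||
      length(object@taxonIDs) != object@gamma)
    return("field lengths must equal gamma")
  if (any(f <= 0 | f > 1)) return("occurrenceFreq must lie in (0, 1]")
  if (abs(sum(a) - 1) > 1e-9) return("meanRelAbund must sum to 1")
  TRUE
})

#' Sample grouping
#'
#' A named set of unordered sample pairs over which assembly-process
#' fractions are tallied (e.g. all pairs, pairs within one well, pairs
#' among the wells of one pH category).
#'
#' @slot name grouping label.
#' @slot pairs two-column character matrix of sample IDs, one row per
#'   unordered pair.
#' @slot definition one of `"within_well"`, `"between_well"`, `"all"`,
#'   `"ph_category"`, `"custom"`.
#' @exportClass SampleGrouping
setClass("SampleGrouping",
         slots = c(name = "character", pairs = "matrix",
                   definition = "character"))

setValidity("SampleGrouping", function(object) {
  p <- object@pairs
  if (ncol(p) != 2L) return("pairs must have two columns")
  if (nrow(p)) {
    key <- apply(p, 1L, function(r) paste(sort(r), collapse = "\r"))
    if (anyDuplicated(key)) return("duplicate pairs")
    if (any(p[, 1L] == p[, 2L])) return("self-pairs are not allowed")
  }
  TRUE
})

#' Assembly-process fractions
#'
#' Counts and percentages of the five assembly processes over a sample
#' grouping. Pairs that could not be classified (degenerate null or
#' missing score) are tallied as excluded and do not enter the
#' percentages.
#'
#' @slot grouping grouping name.
#' @slot counts named integer vector over the five processes.
#' @slot percentages named numeric vector; sums to 100.
#' @slot nPairs total pairs in the grouping.
#' @slot nExcluded pairs excluded as unclassifiable.
#' @exportClass ProcessFractions
setClass("ProcessFractions",
         slots = c(grouping = "character", counts = "integer",
                   percentages = "numeric", nPairs = "integer",
                   nExcluded = "integer"))

setValidity("ProcessFractions", function(object) {
  if (!identical(names(object@counts), PROCESS_LEVELS))
    return("counts must be named by the five processes")
  if (sum(object@counts) != object@nPairs - object@nExcluded)
    return("counts must sum to nPairs - nExcluded")
  if (abs(sum(object@percentages) - 100) > 0.1)
    return("percentages must sum to 100 (tolerance 0.1)")
  TRUE
})

#' Simulation scenario configuration
#'
#' Parameters of the metacommunity simulator, including the ground-truth
#' assembly scenario.
#'
#' @slot scenario one of the five process scenarios or `"neutral"`.
#' @slot nTaxa,nSites,nTimepoints,communitySize problem sizes.
#' @slot traitSigma Brownian rate of niche-trait evolution (trait units
#'   per unit branch length, squared per unit time).
#' @slot selectionSigma width of the Gaussian environmental filter
#'   (trait units); `Inf` disables selection.
#' @slot migrationRate per-generation immigration probability m in \[0, 1\].
#' @slot driftGenerations number of Wright-Fisher resampling generations.
#' @slot envValues per-site environmental value (trait units, stored as
#'   pH in the emitted metadata).
#' @slot seed RNG seed.
#' @exportClass ScenarioConfig
setClass("ScenarioConfig",
         slots = c(scenario = "character", nTaxa = "integer",
                   nSites = "integer", nTimepoints = "integer",
                   communitySize = "integer", traitSigma = "numeric",
                   selectionSigma = "numeric", migrationRate = "numeric",
                   driftGenerations = "integer", envValues = "numeric",
                   seed = "integer"))

setValidity("ScenarioConfig", function(object) {
  ok <- c(PROCESS_LEVELS[1:4], "neutral")
  if (!object@scenario %in% ok)
    return(paste("scenario must be one of:", paste(ok, collapse = ", ")))
  if (object@nTaxa < 2L || object@nSites < 1L || object@nTimepoints < 1L ||
      object@communitySize < 1L || object@driftGenerations < 0L)
    return("sizes must be positive")
  if (object@migrationRate < 0 || object@migrationRate > 1)
    return("migrationRate must lie in [0, 1]")
  if (object@selectionSigma <= 0) return("selectionSigma must be > 0")
  if (length(object@envValues) != object@nSites)
    return("envValues must have one entry per site")
  TRUE
})

#' Synthetic metacommunity dataset
#'
#' Bundle of simulated counts, tree and metadata together with the
#' ground-truth scenario that generated them.
#'
#' @slot counts a [CountTable-class].
#' @slot tree an [ape::phylo] tree whose tips are the taxa.
#' @slot metadata data.frame with sample_id, well_id, collection_day, pH.
#' @slot truth the [ScenarioConfig-class] used.
#' @exportClass SyntheticDataset
setClass("SyntheticDataset",
         slots = c(counts = "CountTable", tree = "ANY",
                   metadata = "data.frame", truth = "ScenarioConfig"))

setValidity("SyntheticDataset", function(object) {
  if (!inherits(object@tree, "phylo")) return("tree must be a phylo object")
  ct <- object@counts@counts
  if (!setequal(colnames(ct), object@tree$tip.label))
    return("counts taxa and tree tips must match")
  if (!setequal(rownames(ct), object@metadata$sample_id))
    return("counts samples and metadata must match")
  TRUE
})
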