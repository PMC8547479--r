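#' Classify one pairwise comparison into an assembly process
#'
#' Five-way decision rule on the two null-model scores: betaNTI > 2 is
#' variable selection, betaNTI < -2 homogeneous selection; otherwise
#' RCbray > 0.95 is dispersal limitation, RCbray < -0.95 homogenizing
#' dispersal, and anything else is undominated. Thresholds are strict
#' inequalities, so boundary values fall to the less significant
#' category. RCbray may be missing only when |betaNTI| > 2 (it is never
#' consulted there).
#'
#' @param bnti finite betaNTI value.
#' @param rcbray RCbray value; may be NA/NaN when |bnti| > 2.
#' @return one of `"variable_selection"`, `"homogeneous_selection"`,
#'   `"dispersal_limitation"`, `"homogenizing_dispersal"`,
#'   `"undominated"`.
#' @export
classifyPair <- function(bnti, rcbray = NA_real_) {
  if (!is.finite(bnti)) stop("betaNTI must be finite")
  if (bnti > 2) return("variable_selection")
  if (bnti < -2) return("homogeneous_selection")
  if (!is.finite(rcbray))
    stop("|betaNTI| <= 2: an RCbray value is required to classify")
  if (rcbray > 0.95) return("dispersal_limitation")
  if (rcbray < -0.95) return("homogenizing_dispersal")
  "undominated"
}

#' Build sample groupings from metadata
#'
#' Constructs the pair sets over which process fractions are quantified:
#' all pairs, pairs of samples sharing a well, pairs spanning wells, or —
#' for pH categories — all pairs (within- and between-well) among the
#' wells of one category. Categories are assigned from each well's mean
#' pH against the breaks `c(7.5, phBreaks, 12)` (neutral / moderate /
#' extreme), or taken from an explicit well-to-category map when given.
#'
#' @param metadata data.frame with `sample_id`, `well_id` and, for pH
#'   categories, `pH`.
#' @param mode one of `"all"`, `"within_well"`, `"between_well"`,
#'   `"ph_category"`.
#' @param phBreaks the two interior pH breaks (default `c(9, 10.5)`).
#' @param phMap optional named character vector mapping well IDs to
#'   `"neutral"`, `"moderate"` or `"extreme"`; overrides mean-pH
#'   assignment. An entry for a well absent from the metadata is an
#'   error.
#' @return list of [SampleGrouping-class] objects (one per pH category in
#'   `"ph_category"` mode, a single grouping otherwise).
#' @export
buildGroupings <- function(metadata,
                           mode = c("all", "within_well", "between_well",
                                    "ph_category"),
                           phBreaks = c(9, 10.5), phMap = NULL) {
  mode <- match.arg(mode)
  if (!all(c("sample_id", "well_id") %in% colnames(metadata)))
    stop("metadata must contain sample_id and well_id")
  ids <- as.character(metadata$sample_id)
  well <- as.character(metadata$well_id)
  names(well) <- ids
  pairs <- .allPairs(ids)
  sameWell <- well[pairs[, 1L]] == well[pairs[, 2L]]
  mk <- function(name, p, def)
    new("SampleGrouping", name = name, pairs = p, definition = def)
  if (mode == "all")
    return(list(mk("all", pairs, "all")))
  if (mode == "within_well")
    return(list(mk("within_well", pairs[sameWell, , drop = FALSE],
                   "within_well")))
  if (mode == "between_well")
    return(list(mk("between_well", pairs[!sameWell, , drop = FALSE],
                   "between_well")))
  # ph_category
  cats <- c("neutral", "moderate", "extreme")
  if (!is.null(phMap)) {
    unknown <- setdiff(names(phMap), unique(well))
    if (length(unknown))
      stop("wells in phMap absent from metadata: ",
           paste(unknown, collapse = ", "))
    if (!all(phMap %in% cats))
      stop("phMap categories must be neutral/moderate/extreme")
    wellCat <- phMap
  } else {
    if (!"pH" %in% colnames(metadata))
      stop("pH column required for ph_category mode")
    meanPH <- tapply(metadata$pH, well, mean, na.rm = TRUE)
    wellCat <- as.character(cut(meanPH, breaks = c(7.5, phBreaks, 12),
                                labels = cats, include.lowest = TRUE))
    names(wellCat) <- names(meanPH)
    if (anyNA(wellCat)) {
      warning("wells with mean pH outside [7.5, 12] excluded: ",
              paste(names(wellCat)[is.na(wellCat)], collapse = ", "))
      wellCat <- wellCat[!is.na(wellCat)]
    }
  }
  lapply(cats, function(cg) {
    wells <- names(wellCat)[wellCat == cg]
    sub <- ids[well[ids] %in% wells]
    mk(paste0("ph_", cg), .allPairs(sub), "ph_category")
  })
}

#' Tabulate per-pair assembly calls
#'
#' Looks up betaNTI and RCbray for every pair of a grouping and applies
#' [classifyPair()]. Pairs with a missing/degenerate betaNTI, or with
#' |betaNTI| <= 2 but no RCbray value, are marked excluded.
#'
#' @param bnti a [PairwiseMatrix-class] of kind `"bnti"`.
#' @param rcbray a [PairwiseMatrix-class] of kind `"rcbray"`.
#' @param grouping a [SampleGrouping-class].
#' @return data.frame with columns sample_a, sample_b, bnti, rcbray,
#'   process (NA when excluded).
#' @export
assemblyCalls <- function(bnti, rcbray, grouping) {
  stopifnot(is(bnti, "PairwiseMatrix"), is(rcbray, "PairwiseMatrix"),
            is(grouping, "SampleGrouping"))
  pairs <- groupingPairs(grouping)
  missB <- setdiff(unique(c(pairs)), sampleIDs(bnti))
  missR <- setdiff(unique(c(pairs)), sampleIDs(rcbray))
  if (length(missB) || length(missR))
    stop("pairs reference samples absent from matrices: ",
         paste(union(missB, missR), collapse = ", "))
  b <- as.matrix(bnti)[pairs]
  r <- as.matrix(rcbray)[pairs]
  proc <- rep(NA_character_, nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    if (!is.finite(b[k])) next
    if (abs(b[k]) <= 2 && !is.finite(r[k])) next
    proc[k] <- classifyPair(b[k], r[k])
  }
  data.frame(sample_a = pairs[, 1L], sample_b = pairs[, 2L],
             bnti = b, rcbray = r, process = proc,
             stringsAsFactors = FALSE)
}

#' Quantify assembly-process fractions over a grouping
#'
#' Counts the classified pairs per process and divides by the number of
#' classifiable pairs; excluded pairs (degenerate or missing scores) are
#' tallied separately and do not enter the percentages.
#'
#' @inheritParams assemblyCalls
#' @return A [ProcessFractions-class].
#' @export
processFractions <- function(bnti, rcbray, grouping) {
  calls <- assemblyCalls(bnti, rcbray, grouping)
  if (!nrow(calls)) stop("empty grouping: no pairs to classify")
  excl <- sum(is.na(calls$process))
  kept <- calls$process[!is.na(calls$process)]
  if (!length(kept))
    stop("empty grouping: all pairs excluded")
  cnt <- table(factor(kept, levels = PROCESS_LEVELS))
  cnt <- stats::setNames(as.integer(cnt), PROCESS_LEVELS)
  pct <- 100 * cnt / sum(cnt)
  new("ProcessFractions", grouping = grouping@name, counts = cnt,
      percentages = pct, nPairs = nrow(calls),
      nExcluded = as.integer(excl))
}
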