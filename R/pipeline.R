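#' Run the full assembly analysis pipeline
#'
#' Ordered execution of the analysis: align inputs, betaNTI matrix,
#' RCbray matrix (computed only for pairs with non-significant betaNTI
#' unless `fullRC`, which never changes any classification because
#' significant betaNTI short-circuits the decision rule), per-grouping
#' classification and process fractions, and per-sample diversity. When
#' an output directory is given, every artifact is written along with a
#' manifest (inputs, seed, parameters, package version) sufficient to
#' reproduce each output bit.
#'
#' @param config named list or path to a YAML file with fields:
#'   `counts`, `tree`, `metadata` (paths) or `scenario` (simulate
#'   instead); `reps` (default 999); `seed` (default 1); `groupings`
#'   (subset of all / within_well / between_well / ph_category; default
#'   `"all"`); `phBreaks`; `normalize` (default TRUE); `fullRC`
#'   (default FALSE); `weighted` (default TRUE); `strict` (default
#'   TRUE); simulator size overrides (`nTaxa`, `nSites`, `nTimepoints`,
#'   `communitySize`).
#' @param outDir optional output directory for bnti.csv, rcbray.csv,
#'   calls.tsv, fractions.tsv, diversity.tsv and manifest.json.
#' @return list with elements `bnti`, `rcbray`, `calls`, `fractions`
#'   (data.frame over groupings), `diversity`, `manifest`.
#' @export
runPipeline <- function(config, outDir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  reps <- as.integer(config$reps %||% 999L)
  seed <- as.integer(config$seed %||% 1L)
  groupings <- config$groupings %||% "all"
  normalize <- config$normalize %||% TRUE
  fullRC <- isTRUE(config$fullRC)
  weighted <- config$weighted %||% TRUE
  if (!is.null(config$scenario)) {
    message("stage simulate: scenario ", config$scenario)
    ds <- generateDataset(config$scenario,
                          nTaxa = config$nTaxa %||% 200L,
                          nSites = config$nSites %||% 6L,
                          nTimepoints = config$nTimepoints %||% 2L,
                          communitySize = config$communitySize %||% 10000L,
                          seed = seed)
    counts <- countTable(ds)
    tree <- phyloTree(ds)
    metadata <- sampleData(ds)
  } else {
    for (f in c("counts", "tree", "metadata"))
      if (is.null(config[[f]]))
        stop("config needs either scenario or paths counts/tree/metadata")
    counts <- readCountTable(config$counts)
    tree <- readNewick(config$tree)
    metadata <- readMetadata(config$metadata)
  }
  message("stage align: ", length(sampleIDs(counts)), " samples, ",
          length(taxonIDs(counts)), " taxa")
  al <- alignInputs(counts, tree, metadata,
                    strict = config$strict %||% TRUE)
  counts <- al$counts
  metadata <- al$metadata
  D <- copheneticDistances(al$tree)
  message("stage bnti: reps = ", reps)
  bnti <- withCallingHandlers(
    betaNTIMatrix(counts, D, reps = reps, seed = seed,
                  weighted = weighted),
    warning = function(w) {
      message("WARN ", conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  bv <- as.matrix(bnti)
  allP <- .allPairs(sampleIDs(counts))
  need <- if (fullRC) allP else {
    sel <- abs(bv[allP]) <= 2 & is.finite(bv[allP])
    allP[sel, , drop = FALSE]
  }
  message("stage rcbray: ", nrow(need), " of ", nrow(allP), " pairs")
  rcb <- rcBrayMatrix(counts, reps = reps, seed = seed,
                      normalize = normalize, pairs = need)
  gl <- unlist(lapply(groupings, function(g)
    buildGroupings(metadata, mode = g,
                   phBreaks = config$phBreaks %||% c(9, 10.5))),
    recursive = FALSE)
  message("stage classify: ", length(gl), " grouping(s)")
  frac <- lapply(gl, function(g) processFractions(bnti, rcb, g))
  fracTab <- do.call(rbind, lapply(frac, as.data.frame))
  callsAll <- assemblyCalls(bnti, rcb,
                            buildGroupings(metadata, "all")[[1L]])
  div <- data.frame(sample_id = sampleIDs(counts),
                    richness = richness(counts),
                    pielou_evenness = pielouEvenness(counts))
  manifest <- list(
    package = "ecoassembly",
    version = as.character(utils::packageVersion("ecoassembly")),
    seed = seed, reps = reps, weighted = weighted,
    normalize = normalize, fullRC = fullRC,
    inputs = config[intersect(names(config),
                              c("counts", "tree", "metadata",
                                "scenario"))],
    n_samples = length(sampleIDs(counts)),
    n_taxa = length(taxonIDs(counts)),
    dropped = al$dropped,
    stages = c("align", "bnti", "rcbray", "classify", "diversity"))
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    writeSquareMatrix(bnti, file.path(outDir, "bnti.csv"))
    writeSquareMatrix(rcb, file.path(outDir, "rcbray.csv"))
    utils::write.table(callsAll, file.path(outDir, "calls.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(fracTab, file.path(outDir, "fractions.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(div, file.path(outDir, "diversity.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  list(bnti = bnti, rcbray = rcb, calls = callsAll, fractions = fracTab,
       fractionObjects = frac, diversity = div, manifest = manifest)
}
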