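#' Simulate a random phylogeny
#'
#' Birth-death tree with the requested number of tips and positive branch
#' lengths; tip labels are `t1 ... tn`. The high relative extinction
#' default yields the deep stem branches and shallow crown clades typical
#' of 16S phylogenies. Optionally one clade is turned into a recent rapid
#' radiation by compressing its internal branches to a fixed crown
#' height: a large set of very close relatives, the phylogenetic
#' structure of a habitat-specialized lineage.
#'
#' @param nTaxa number of tips (>= 2).
#' @param seed RNG seed.
#' @param birth,death birth-death rates (defaults 1 and 0.9).
#' @param radiationFrac if > 0, fraction of tips forming the radiation
#'   clade (the clade whose size is closest to `radiationFrac * nTaxa`).
#' @param radiationHeight crown height the radiation is compressed to.
#' @return an [ape::phylo]; when a radiation was made, its tip labels are
#'   stored in `attr(tree, "radiation")`.
#' @export
simulateTree <- function(nTaxa, seed = 1L, birth = 1, death = 0.9,
                         radiationFrac = 0, radiationHeight = 0.4) {
  if (nTaxa < 2L) stop("nTaxa must be >= 2")
  set.seed(seed)
  tr <- ape::rphylo(nTaxa, birth = birth, death = death)
  tr$tip.label <- paste0("t", seq_len(nTaxa))
  if (radiationFrac > 0) {
    nodes <- (nTaxa + 1L):(nTaxa + tr$Nnode)
    sz <- vapply(nodes, function(nd)
      length(ape::extract.clade(tr, nd)$tip.label), integer(1))
    target <- nodes[which.min(abs(sz - radiationFrac * nTaxa))]
    desc <- integer(0)
    stack <- target
    while (length(stack)) {
      nd <- stack[1L]
      stack <- stack[-1L]
      ch <- tr$edge[tr$edge[, 1L] == nd, 2L]
      desc <- c(desc, ch)
      stack <- c(stack, ch[ch > nTaxa])
    }
    eidx <- which(tr$edge[, 2L] %in% desc)
    tips <- ape::extract.clade(tr, target)$tip.label
    depth <- max(ape::cophenetic.phylo(
      ape::extract.clade(tr, target))) / 2
    if (depth > 0)
      tr$edge.length[eidx] <- tr$edge.length[eidx] *
        radiationHeight / depth
    attr(tr, "radiation") <- tips
  }
  validateTree(tr)
  tr
}

#' Evolve a niche trait along a tree by Brownian motion
#'
#' Each child node value is its parent's value plus a Normal(0,
#' traitSigma^2 * branch length) step, so the expected covariance of two
#' tips equals traitSigma^2 times their shared path length from the
#' root. This produces the phylogenetically conserved niche that the
#' betaNTI framework presupposes.
#'
#' @param tree an [ape::phylo].
#' @param traitSigma Brownian rate (trait units per sqrt branch length).
#' @param rootValue trait value at the root.
#' @param seed RNG seed.
#' @return named numeric vector of tip trait values.
#' @export
evolveTrait <- function(tree, traitSigma, rootValue = 0, seed = 1L) {
  validateTree(tree)
  set.seed(seed)
  tr <- ape::rTraitCont(tree, model = "BM", sigma = traitSigma,
                        root.value = rootValue)
  tr[tree$tip.label]
}

#' Assemble one local community under filtering, migration and drift
#'
#' Sampling weights combine the regional pool with a Gaussian
#' environmental filter. For a one-dimensional niche, `w_i` is
#' proportional to
#' `pool_i * exp(-(trait_i - env)^2 / (2 * selectionSigma^2))`;
#' with a multivariate niche (a trait matrix and an environment vector)
#' the squared distance is summed over niche dimensions
#' (`selectionSigma = Inf` disables filtering). The initial community is
#' a multinomial draw of `communitySize` individuals from `w`; each of
#' `driftGenerations` Wright-Fisher generations then resamples
#' `communitySize` individuals from
#' `(1 - m) * current relative abundances + m * w`.
#'
#' @param pool named numeric vector of regional relative abundances.
#' @param traits named numeric vector, or matrix with one row per pool
#'   taxon and one column per niche dimension.
#' @param envValue local environmental value(s), length matching the
#'   niche dimensions.
#' @param communitySize individuals per community (N).
#' @param selectionSigma Gaussian filter width (trait units).
#' @param migrationRate per-generation immigration fraction m.
#' @param driftGenerations number of resampling generations g.
#' @param initial optional starting counts (named, summing to
#'   `communitySize`); when given, the initial multinomial draw is
#'   skipped and drift continues from this state.
#' @return named integer vector of counts summing to `communitySize`.
#' @export
assembleLocal <- function(pool, traits, envValue, communitySize = 10000L,
                          selectionSigma = 0.5, migrationRate = 0.3,
                          driftGenerations = 100L, initial = NULL) {
  stopifnot(communitySize >= 1L, selectionSigma > 0,
            migrationRate >= 0, migrationRate <= 1)
  pool <- pool / sum(pool)
  taxa <- names(pool)
  if (is.infinite(selectionSigma)) {
    w <- pool
  } else {
    if (is.matrix(traits)) {
      stopifnot(length(envValue) == ncol(traits))
      d2 <- rowSums((traits[taxa, , drop = FALSE] -
                       matrix(envValue, length(taxa), ncol(traits),
                              byrow = TRUE))^2)
    } else {
      d2 <- (traits[taxa] - envValue[1L])^2
    }
    w <- pool * exp(-d2 / (2 * selectionSigma^2))
  }
  if (sum(w) <= 0)
    stop("all filter weights are zero: environment too far from all ",
         "traits; increase selectionSigma")
  w <- w / sum(w)
  x <- if (is.null(initial)) {
    stats::rmultinom(1L, communitySize, prob = w)[, 1L]
  } else {
    stopifnot(sum(initial) == communitySize)
    as.numeric(initial[taxa])
  }
  g <- driftGenerations
  m <- migrationRate
  while (g > 0L) {
    p <- (1 - m) * x / communitySize + m * w
    x <- stats::rmultinom(1L, communitySize, prob = p)[, 1L]
    g <- g - 1L
  }
  stats::setNames(as.integer(x), taxa)
}

# scenario presets: the generative conditions realizing each assembly
# process. poolSdlog controls regional-pool unevenness (hence occupancy
# patchiness), dispersalRange the number of sites each taxon can ever
# reach (founder limitation), nicheDims the dimensionality of the
# conserved niche, radiation whether the tree carries a compressed
# habitat-specialist clade targeted by the environment.
.scenarioPresets <- function() list(
  homogeneous_selection = list(
    selectionSigma = 0.75, migrationRate = 0, driftGenerations = 50L,
    poolSdlog = 0.5, dispersalRange = 1L, nicheDims = 3L,
    radiation = TRUE, envSpread = FALSE),
  variable_selection = list(
    selectionSigma = 0.5, migrationRate = 0.3, driftGenerations = 100L,
    poolSdlog = 2, dispersalRange = NA_integer_, nicheDims = 1L,
    radiation = FALSE, envSpread = TRUE),
  dispersal_limitation = list(
    selectionSigma = Inf, migrationRate = 0, driftGenerations = 100L,
    poolSdlog = 1.5, dispersalRange = 1L, nicheDims = 1L,
    radiation = FALSE, envSpread = FALSE),
  homogenizing_dispersal = list(
    selectionSigma = Inf, migrationRate = 0.95, driftGenerations = 2L,
    poolSdlog = 2, dispersalRange = NA_integer_, nicheDims = 1L,
    radiation = FALSE, envSpread = FALSE),
  neutral = list(
    selectionSigma = Inf, migrationRate = 0.05, driftGenerations = 30L,
    poolSdlog = 2, dispersalRange = NA_integer_, nicheDims = 1L,
    radiation = FALSE, envSpread = FALSE)
)

# map site environments (trait units) to a bounded pH-like column for
# the emitted metadata; constant environments sit at pH 9
.envToPH <- function(env) {
  if (max(env) - min(env) < 1e-12) return(rep(9, length(env)))
  7.5 + 4.5 * (env - min(env)) / (max(env) - min(env))
}

#' Generate a synthetic metacommunity dataset
#'
#' Simulates a tree, a Brownian niche (one or more dimensions), per-site
#' environments and local communities under one of five ground-truth
#' assembly scenarios, and emits aligned counts, tree and metadata (site
#' as `well_id`, timepoint as `collection_day`, a bounded monotone
#' transform of the site environment stored as `pH`). Within a site,
#' timepoints are serial: each continues drifting from the previous
#' community, so isolated sites diverge over time.
#'
#' Scenario presets:
#' * `homogeneous_selection` - identical environments targeting the
#'   conserved multivariate niche of a recent-radiation clade, narrow
#'   filter, founder-limited sites: turnover happens among the
#'   radiation's close relatives.
#' * `variable_selection` - environments spread across the niche range
#'   with a narrow filter, so different sites select different lineages.
#' * `dispersal_limitation` - no selection, no migration and
#'   founder-limited (disjoint) site pools followed by drift.
#' * `homogenizing_dispersal` - near-complete mixing with the regional
#'   pool every generation and few drift generations.
#' * `neutral` - no filtering, low migration, moderate drift.
#'
#' @param scenario one of `"homogeneous_selection"`,
#'   `"variable_selection"`, `"dispersal_limitation"`,
#'   `"homogenizing_dispersal"`, `"neutral"`.
#' @param nTaxa,nSites,nTimepoints,communitySize problem sizes
#'   (defaults 200 taxa, 6 sites, 2 timepoints, 10000 individuals).
#' @param traitSigma Brownian rate (default 1).
#' @param selectionSigma,migrationRate,driftGenerations,envValues,
#'   poolSdlog,dispersalRange override the scenario preset when
#'   non-NULL. `poolSdlog` is the log-sd of the lognormal regional
#'   abundance pool; `dispersalRange` is the number of sites each taxon
#'   can reach (NA = all sites).
#' @param rootValue trait/environment centre (default 9, a pH-like
#'   scale).
#' @param seed RNG seed; fixes every output bit.
#' @return A [SyntheticDataset-class].
#' @export
generateDataset <- function(scenario, nTaxa = 200L, nSites = 6L,
                            nTimepoints = 2L, communitySize = 10000L,
                            traitSigma = 1, selectionSigma = NULL,
                            migrationRate = NULL, driftGenerations = NULL,
                            envValues = NULL, poolSdlog = NULL,
                            dispersalRange = NULL, rootValue = 9,
                            seed = 1L) {
  presets <- .scenarioPresets()
  if (!scenario %in% names(presets))
    stop("unknown scenario: ", scenario)
  pr <- presets[[scenario]]
  selectionSigma <- selectionSigma %||% pr$selectionSigma
  migrationRate <- migrationRate %||% pr$migrationRate
  driftGenerations <- as.integer(driftGenerations %||%
                                   pr$driftGenerations)
  poolSdlog <- poolSdlog %||% pr$poolSdlog
  dispersalRange <- as.integer(dispersalRange %||%
                                 (if (is.na(pr$dispersalRange)) nSites
                                  else pr$dispersalRange))
  dispersalRange <- min(dispersalRange, nSites)
  tree <- simulateTree(nTaxa, seed = seed,
                       radiationFrac = if (pr$radiation) 0.5 else 0)
  niche <- vapply(seq_len(pr$nicheDims), function(k)
    evolveTrait(tree, traitSigma, rootValue = rootValue,
                seed = seed + k), numeric(nTaxa))
  rownames(niche) <- tree$tip.label
  set.seed(seed + 20L)
  pool <- stats::setNames(stats::rlnorm(nTaxa, 0, poolSdlog),
                          tree$tip.label)
  pool <- pool / sum(pool)
  if (is.null(envValues)) {
    envValues <- if (pr$envSpread) {
      stats::quantile(niche[, 1L],
                      probs = seq(0.1, 0.9, length.out = nSites),
                      names = FALSE)
    } else if (pr$radiation) {
      rep(mean(niche[attr(tree, "radiation"), 1L]), nSites)
    } else rep(rootValue, nSites)
  }
  stopifnot(length(envValues) == nSites)
  # site environments over all niche dimensions: dimension 1 varies
  # between sites, the remaining dimensions sit at the target lineage's
  # niche centre (or the root value)
  envMat <- matrix(rootValue, nSites, pr$nicheDims)
  envMat[, 1L] <- envValues
  if (pr$nicheDims > 1L && pr$radiation)
    envMat <- matrix(colMeans(niche[attr(tree, "radiation"), ,
                                    drop = FALSE]),
                     nSites, pr$nicheDims, byrow = TRUE)
  set.seed(seed + 21L)
  reach <- lapply(seq_len(nTaxa), function(i)
    sample.int(nSites, dispersalRange))
  counts <- matrix(0, nSites * nTimepoints, nTaxa,
                   dimnames = list(NULL, tree$tip.label))
  n <- nSites * nTimepoints
  meta <- data.frame(sample_id = character(n), well_id = character(n),
                     collection_day = numeric(n), pH = numeric(n),
                     stringsAsFactors = FALSE)
  phSite <- .envToPH(envValues)
  set.seed(seed + 22L)
  row <- 0L
  for (s in seq_len(nSites)) {
    founders <- vapply(reach, function(r) s %in% r, logical(1))
    if (!any(founders)) founders[sample.int(nTaxa, 1L)] <- TRUE
    fpool <- pool[founders] / sum(pool[founders])
    state <- NULL
    for (tp in seq_len(nTimepoints)) {
      state <- assembleLocal(fpool,
                             niche[founders, , drop = (pr$nicheDims == 1L)],
                             if (pr$nicheDims == 1L) envMat[s, 1L]
                             else envMat[s, ],
                             communitySize = communitySize,
                             selectionSigma = selectionSigma,
                             migrationRate = migrationRate,
                             driftGenerations = driftGenerations,
                             initial = state)
      row <- row + 1L
      counts[row, founders] <- state
      meta$sample_id[row] <- sprintf("W%d_T%d", s, tp)
      meta$well_id[row] <- sprintf("W%d", s)
      meta$collection_day[row] <- tp
      meta$pH[row] <- phSite[s]
    }
  }
  rownames(counts) <- meta$sample_id
  rownames(meta) <- meta$sample_id
  cfg <- new("ScenarioConfig", scenario = scenario,
             nTaxa = as.integer(nTaxa), nSites = as.integer(nSites),
             nTimepoints = as.integer(nTimepoints),
             communitySize = as.integer(communitySize),
             traitSigma = traitSigma, selectionSigma = selectionSigma,
             migrationRate = migrationRate,
             driftGenerations = driftGenerations,
             envValues = as.numeric(envValues), seed = as.integer(seed))
  new("SyntheticDataset", counts = CountTable(counts), tree = tree,
      metadata = meta, truth = cfg)
}

#' Write a synthetic dataset to disk
#'
#' Counts as TSV, tree as newick, metadata as CSV and the ground-truth
#' scenario as YAML, ready to re-enter the pipeline through the readers.
#'
#' @param x a [SyntheticDataset-class].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writeSyntheticDataset <- function(x, dir) {
  stopifnot(is(x, "SyntheticDataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeCountTable(countTable(x), file.path(dir, "counts.tsv"))
  ape::write.tree(phyloTree(x), file.path(dir, "tree.nwk"))
  writeMetadata(sampleData(x), file.path(dir, "metadata.csv"))
  tr <- scenarioTruth(x)
  yaml::write_yaml(list(scenario = tr@scenario, n_taxa = tr@nTaxa,
                        n_sites = tr@nSites,
                        n_timepoints = tr@nTimepoints,
                        community_size = tr@communitySize,
                        trait_sigma = tr@traitSigma,
                        selection_sigma = tr@selectionSigma,
                        migration_rate = tr@migrationRate,
                        drift_generations = tr@driftGenerations,
                        env_values = tr@envValues, seed = tr@seed),
                   file.path(dir, "truth.yaml"))
  invisible(dir)
}
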