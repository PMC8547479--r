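#' Read a community count table
#'
#' Reads a delimited (tab or comma) samples-by-taxa abundance table with
#' one ID axis in the header row and one in the first column. Orientation
#' is auto-detected by shape (community surveys have far more taxa than
#' samples, so the longer axis is taken to be taxa) or forced with
#' `orientationHint`.
#'
#' @param path path to a CSV/TSV file.
#' @param orientationHint `"auto"` (default), `"samples_by_taxa"`
#'   (rows are samples) or `"taxa_by_samples"` (rows are taxa; the table
#'   is transposed on read).
#' @return A validated [CountTable-class].
#' @export
readCountTable <- function(path,
                           orientationHint = c("auto", "samples_by_taxa",
                                               "taxa_by_samples")) {
  orientationHint <- match.arg(orientationHint)
  sep <- .detectSep(path)
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          quote = "\"", comment.char = "")
  if (!ncol(df) >= 2L) stop("count table format error: need ID column plus data")
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids))
    stop("count table format error: duplicate IDs in first column")
  if (anyDuplicated(colnames(df)[-1L]))
    stop("count table format error: duplicate IDs in header")
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop("count table format error: non-numeric entries")
  rownames(m) <- ids
  flip <- switch(orientationHint,
                 samples_by_taxa = FALSE,
                 taxa_by_samples = TRUE,
                 auto = nrow(m) > ncol(m))
  if (flip) m <- t(m)
  CountTable(m)
}

#' Write a community count table
#'
#' Samples as rows, taxa as header columns; tab-separated when the path
#' ends in `.tsv`/`.txt`, comma-separated otherwise.
#'
#' @param x a [CountTable-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeCountTable <- function(x, path) {
  stopifnot(is(x, "CountTable"))
  sep <- if (grepl("\\.(tsv|txt)$", path)) "\t" else ","
  m <- countMatrix(x)
  df <- data.frame(sample_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a phylogenetic tree from newick
#'
#' @param path newick file with branch lengths.
#' @return An [ape::phylo] tree, validated for unique tips, at least two
#'   tips and non-negative branch lengths.
#' @export
readNewick <- function(path) {
  tr <- tryCatch(ape::read.tree(path),
                 error = function(e) stop("newick parse error: ",
                                          conditionMessage(e)))
  if (is.null(tr)) stop("newick parse error: unreadable tree")
  validateTree(tr)
  tr
}

#' Validate a phylogenetic tree
#'
#' @param tree an [ape::phylo].
#' @return `tree`, invisibly; otherwise an error.
#' @export
validateTree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a phylo object")
  if (length(tree$tip.label) < 2L) stop("tree must have at least 2 tips")
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch lengths")
  invisible(tree)
}

#' Read per-sample metadata
#'
#' One row per sample. The columns `sample_id`, `well_id` and
#' `collection_day` are mandatory; environmental columns (pH,
#' temperature, conductance, DO, ORP, DIC, depth) are optional and empty
#' cells become `NA`, never zero.
#'
#' @param path CSV/TSV file.
#' @return data.frame keyed by `sample_id`.
#' @export
readMetadata <- function(path) {
  sep <- .detectSep(path)
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          quote = "\"", na.strings = c("", "NA"))
  if (!"sample_id" %in% colnames(df))
    stop("metadata format error: missing sample_id column")
  if (anyDuplicated(df$sample_id))
    stop("metadata format error: duplicate sample IDs")
  df$sample_id <- as.character(df$sample_id)
  num <- intersect(c("collection_day", "pH", "temperature", "conductance",
                     "DO", "ORP", "DIC", "depth"), colnames(df))
  for (v in num) df[[v]] <- as.numeric(df[[v]])
  if ("pH" %in% colnames(df)) {
    bad <- !is.na(df$pH) & (df$pH < 0 | df$pH > 14)
    if (any(bad))
      stop("metadata validation error: pH outside [0, 14] for ",
           paste(df$sample_id[bad], collapse = ", "))
  }
  rownames(df) <- df$sample_id
  df
}

#' Write per-sample metadata
#'
#' @param metadata data.frame as returned by [readMetadata()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeMetadata <- function(metadata, path) {
  utils::write.csv(metadata, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a square pairwise matrix
#'
#' CSV with an ID header row and an identical ID first column (the layout
#' of deposited betaNTI / RCbray matrices). Empty diagonal cells are
#' permitted for the `bnti` and `rcbray` kinds.
#'
#' @param path CSV file.
#' @param kind matrix kind, see [PairwiseMatrix-class].
#' @return A [PairwiseMatrix-class].
#' @export
readSquareMatrix <- function(path, kind) {
  sep <- .detectSep(path)
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          quote = "\"")
  ids <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (nrow(m) != ncol(m))
    stop("pairwise matrix format error: not square")
  if (!identical(ids, colnames(m)))
    stop("pairwise matrix format error: row IDs do not match column IDs")
  storage.mode(m) <- "double"
  rownames(m) <- ids
  off <- m - t(m)
  off[is.na(off)] <- 0
  if (max(abs(off)) > 1e-8)
    stop("pairwise matrix validation error: asymmetry beyond 1e-8")
  PairwiseMatrix(m, kind = kind)
}

#' Write a square pairwise matrix
#'
#' Inverse of [readSquareMatrix()]; values are written with 15 significant
#' digits so that a write-read round trip preserves them to at least 12.
#'
#' @param x a [PairwiseMatrix-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeSquareMatrix <- function(x, path) {
  stopifnot(is(x, "PairwiseMatrix"))
  v <- as.matrix(x)
  ids <- sampleIDs(x)
  rows <- vapply(seq_along(ids), function(i) {
    vals <- vapply(v[i, ], function(z) {
      if (is.na(z)) "" else format(z, digits = 15)
    }, character(1))
    paste(c(ids[i], vals), collapse = ",")
  }, character(1))
  writeLines(c(paste(c("", ids), collapse = ","), rows), path)
  invisible(path)
}

#' Align counts, tree and metadata
#'
#' Restricts the count table to taxa present as tree tips and to samples
#' present in the metadata, prunes the tree to the surviving taxa and
#' reports everything dropped. In strict mode (default) any count-table
#' taxon absent from the tree, or sample absent from the metadata, is an
#' error; permissive mode drops them with a report.
#'
#' @param counts a [CountTable-class].
#' @param tree an [ape::phylo].
#' @param metadata data.frame from [readMetadata()].
#' @param strict error on unmatched IDs (default) instead of pruning.
#' @return list with elements `counts`, `tree`, `metadata` and `dropped`
#'   (a list of dropped taxon and sample IDs).
#' @export
alignInputs <- function(counts, tree, metadata, strict = TRUE) {
  stopifnot(is(counts, "CountTable"))
  validateTree(tree)
  m <- countMatrix(counts)
  lostTaxa <- setdiff(colnames(m), tree$tip.label)
  lostSamples <- setdiff(rownames(m), metadata$sample_id)
  if (strict && length(lostTaxa))
    stop("taxa absent from tree: ", paste(lostTaxa, collapse = ", "))
  if (strict && length(lostSamples))
    stop("samples absent from metadata: ",
         paste(lostSamples, collapse = ", "))
  taxa <- intersect(colnames(m), tree$tip.label)
  samples <- intersect(rownames(m), metadata$sample_id)
  if (!length(taxa)) stop("no taxa shared between counts and tree")
  if (!length(samples)) stop("no samples shared between counts and metadata")
  m <- m[samples, taxa, drop = FALSE]
  zero <- rowSums(m) <= 0
  if (any(zero)) {
    if (strict)
      stop("samples with zero total after alignment: ",
           paste(rownames(m)[zero], collapse = ", "))
    lostSamples <- c(lostSamples, rownames(m)[zero])
    m <- m[!zero, , drop = FALSE]
    if (!nrow(m)) stop("no samples left after alignment")
  }
  prunedTree <- if (length(setdiff(tree$tip.label, taxa)))
    ape::keep.tip(tree, taxa) else tree
  list(counts = CountTable(m),
       tree = prunedTree,
       metadata = metadata[match(rownames(m), metadata$sample_id), ,
                           drop = FALSE],
       dropped = list(taxa = lostTaxa, samples = lostSamples))
}
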