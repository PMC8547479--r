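# internal helpers shared across modules

# relative abundance per row (sample); rows must have positive totals
.relAbund <- function(m) m / rowSums(m)

# row-wise minima of D restricted to the given columns
.rowMinsCols <- function(D, cols) {
  v <- D[, cols[1L]]
  for (j in cols[-1L]) v <- pmin.int(v, D[, j])
  v
}

# deterministic per-pair RNG seed, invariant to pair order; < 2^31
.pairSeed <- function(seed, a, b) {
  s <- paste(sort(c(as.character(a), as.character(b))), collapse = "\r")
  h <- 0
  for (k in utf8ToInt(s)) h <- (h * 31 + k) %% 2147483563
  as.integer((h + as.numeric(seed) * 7919) %% 2147483563) + 1L
}

# detect field separator of a delimited text file from its first line
.detectSep <- function(path) {
  line <- readLines(path, n = 1L)
  if (!length(line)) stop("empty file: ", path)
  if (lengths(regmatches(line, gregexpr("\t", line))) >=
      lengths(regmatches(line, gregexpr(",", line)))) "\t" else ","
}

# Bray-Curtis between two abundance vectors
.bray <- function(x, y, normalize = TRUE) {
  if (normalize) {
    x <- x / sum(x)
    y <- y / sum(y)
  }
  sum(abs(x - y)) / sum(x + y)
}

# all unordered pairs of a character vector, as a 2-column matrix
.allPairs <- function(ids) {
  if (length(ids) < 2L)
    return(matrix(character(0), 0L, 2L))
  t(utils::combn(ids, 2L))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
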