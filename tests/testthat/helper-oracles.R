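# brute-force oracles, deliberately independent of the package's
# vectorized implementations: plain loops and a graph shortest-path
# route for patristic distances

toyTree <- function(txt) ape::read.tree(text = txt)

# patristic distances via weighted shortest paths on the edge graph
grPathDist <- function(tree) {
  g <- igraph::graph_from_edgelist(apply(tree$edge, 2, as.character),
                                   directed = FALSE)
  igraph::E(g)$weight <- tree$edge.length
  d <- igraph::distances(g)
  tipv <- as.character(seq_along(tree$tip.label))
  out <- d[tipv, tipv]
  dimnames(out) <- list(tree$tip.label, tree$tip.label)
  out
}

bruteMNTD <- function(x, D, weighted = TRUE) {
  pres <- names(x)[x > 0]
  nn <- numeric(length(pres))
  for (i in seq_along(pres)) {
    best <- Inf
    for (j in seq_along(pres)) {
      if (i == j) next
      best <- min(best, D[pres[i], pres[j]])
    }
    nn[i] <- best
  }
  if (weighted) sum(x[pres] / sum(x[pres]) * nn) else mean(nn)
}

bruteBetaMNTD <- function(a, b, D, weighted = TRUE) {
  pa <- names(a)[a > 0]
  pb <- names(b)[b > 0]
  term <- function(from, to, w) {
    tot <- 0
    for (i in from) {
      best <- Inf
      for (j in to) best <- min(best, D[i, j])
      tot <- tot + w[i] * best
    }
    tot
  }
  wa <- if (weighted) a[pa] / sum(a[pa]) else
    stats::setNames(rep(1 / length(pa), length(pa)), pa)
  wb <- if (weighted) b[pb] / sum(b[pb]) else
    stats::setNames(rep(1 / length(pb), length(pb)), pb)
  unname(0.5 * (term(pa, pb, wa) + term(pb, pa, wb)))
}

# all permutations of 1..n (n small)
permAll <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permAll(n - 1L)
  out <- NULL
  for (k in seq_len(n)) {
    block <- cbind(k, sub + (sub >= k))
    out <- rbind(out, block)
  }
  out
}

# random small count table over the tips of a tree
randomCounts <- function(tree, nSamples, seed, minRich = 2L) {
  set.seed(seed)
  taxa <- tree$tip.label
  m <- matrix(0, nSamples, length(taxa),
              dimnames = list(paste0("S", seq_len(nSamples)), taxa))
  for (i in seq_len(nSamples)) {
    k <- sample(minRich:length(taxa), 1L)
    sel <- sample(taxa, k)
    m[i, sel] <- sample(1:20, k, replace = TRUE)
  }
  CountTable(m)
}

bruteBray <- function(x, y, normalize = TRUE) {
  if (normalize) {
    x <- x / sum(x)
    y <- y / sum(y)
  }
  num <- 0
  den <- 0
  for (k in seq_along(x)) {
    num <- num + abs(x[k] - y[k])
    den <- den + x[k] + y[k]
  }
  unname(num / den)
}
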