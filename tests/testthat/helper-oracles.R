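# Independent brute-force oracles. These deliberately avoid the package's
# own algorithms: exhaustive enumeration only.

# All simple paths between two nodes, as lists of node names.
allSimplePaths <- function(links, from, to) {
  adj <- split(c(links$geneB, links$geneA), c(links$geneA, links$geneB))
  out <- list()
  recurse <- function(path) {
    cur <- path[length(path)]
    if (cur == to) {
      out[[length(out) + 1L]] <<- path
      return(invisible())
    }
    for (nxt in adj[[cur]])
      if (!(nxt %in% path)) recurse(c(path, nxt))
  }
  recurse(from)
  out
}

# The unique optimal path under the package's documented tie rule:
# minimal total distance, then fewest hops, then lexicographically
# smallest node sequence. Returns NULL when unreachable.
oracleShortestPath <- function(links, from, to, tol = 1e-9) {
  key <- paste(pmin(links$geneA, links$geneB), pmax(links$geneA, links$geneB))
  w <- structure(links$distance, names = key)
  paths <- allSimplePaths(links, from, to)
  if (length(paths) == 0L) return(NULL)
  dist <- vapply(paths, function(p) {
    k <- paste(pmin(p[-length(p)], p[-1L]), pmax(p[-length(p)], p[-1L]))
    sum(w[k])
  }, 1)
  best <- which(dist <= min(dist) + tol)
  hops <- vapply(paths[best], length, 1L) - 1L
  best <- best[hops == min(hops)]
  seqs <- vapply(paths[best], paste, "", collapse = "\r")
  pick <- best[order(seqs)][1L]
  list(nodes = paths[[pick]], totalDistance = dist[pick],
       hops = length(paths[[pick]]) - 1L)
}

# Exact two-sided signed-rank p by enumerating all 2^n sign assignments
# over integer ranks (ties in |d| broken in input order).
oracleWilcoxExact <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d), ties.method = "first")
  w <- sum(r[d > 0])
  ws <- vapply(0:(2^n - 1L), function(mask) {
    sum(r[bitwAnd(mask, bitwShiftL(1L, 0:(n - 1L))) > 0L])
  }, 1)
  lo <- mean(ws <= w); hi <- mean(ws >= w)
  min(1, 2 * min(lo, hi))
}

# Brute-force hub triangles shared by two link tables.
oracleTriangleCount <- function(ltN, ltT, hubs) {
  keyN <- paste(ltN$geneA, ltN$geneB)
  keyT <- paste(ltT$geneA, ltT$geneB)
  common <- intersect(keyN, keyT)
  has <- function(a, b) paste(pmin(a, b), pmax(a, b)) %in% common
  nodes <- sort(unique(unlist(strsplit(common, " "))))
  cnt <- 0L
  for (h in hubs) for (i in seq_along(nodes)) for (j in seq_along(nodes)) {
    if (j <= i) next
    n1 <- nodes[i]; n2 <- nodes[j]
    if (n1 == h || n2 == h) next
    if (has(h, n1) && has(h, n2) && has(n1, n2)) cnt <- cnt + 1L
  }
  cnt
}

# Brute-force comparative motif count: all TFs, all receptor pairs with
# all four pathways present, pairwise link-set intersections.
oracleComparative <- function(pathsN, pathsT) {
  linksOf <- function(p) {
    n <- p[-length(p)]; m <- p[-1L]
    paste(pmin(n, m), pmax(n, m))
  }
  tabN <- pathwayTable(pathsN); tabT <- pathwayTable(pathsT)
  normal <- 0L; tumor <- 0L
  for (tf in intersect(tabN$tf, tabT$tf)) {
    recs <- sort(intersect(tabN$receptor[tabN$tf == tf],
                           tabT$receptor[tabT$tf == tf]))
    if (length(recs) < 2L) next
    for (i in seq_along(recs)) for (j in seq_along(recs)) {
      if (j <= i) next
      getp <- function(ps, r) {
        idx <- which(ps@receptor == r & ps@tf == tf)
        linksOf(ps@nodes[[idx]])
      }
      shN <- length(intersect(getp(pathsN, recs[i]),
                              getp(pathsN, recs[j]))) > 0L
      shT <- length(intersect(getp(pathsT, recs[i]),
                              getp(pathsT, recs[j]))) > 0L
      if (shN && !shT) normal <- normal + 1L
      if (shT && !shN) tumor <- tumor + 1L
    }
  }
  c(normal = normal, tumor = tumor)
}

# Inverse-CDF draws from the continuous power law with density
# proportional to f^-alpha on [fmin, Inf).
oraclePowerlawDraws <- function(n, alpha, fmin = 1) {
  fmin * (1 - runif(n))^(-1 / (alpha - 1))
}
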