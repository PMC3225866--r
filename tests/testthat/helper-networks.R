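# Fixture builders used across the suite. Everything is generated in code.

# A WeightedNetwork from an explicit link table. Specify either rho or
# distance per link (distance d is stored as rho = 1 - d).
toyNetwork <- function(geneA, geneB, rho = NULL, distance = NULL) {
  if (is.null(rho)) rho <- 1 - distance
  key <- paste(pmin(geneA, geneB), pmax(geneA, geneB))
  stopifnot(!anyDuplicated(key), all(geneA != geneB))
  g <- igraph::graph_from_data_frame(
    data.frame(from = pmin(geneA, geneB), to = pmax(geneA, geneB),
               rho = rho, distance = 1 - abs(rho)),
    directed = FALSE, vertices = sort(unique(c(geneA, geneB))))
  methods::new("WeightedNetwork", graph = g)
}

# A PathwaySet from a list of node sequences (first node = receptor,
# last = tf); distances default to hop counts.
toyPathwaySet <- function(nodeSeqs, totalDistance = NULL) {
  hops <- vapply(nodeSeqs, length, 1L) - 1L
  if (is.null(totalDistance)) totalDistance <- as.numeric(hops)
  methods::new("PathwaySet",
               receptor = vapply(nodeSeqs, `[`, "", 1L),
               tf = vapply(nodeSeqs, function(x) x[length(x)], ""),
               hops = hops, totalDistance = totalDistance,
               nodes = nodeSeqs)
}

# Random connected weighted graph on nMin..nMax nodes for property tests.
randomWeightedGraph <- function(nMax = 10L, pEdge = 0.45, nMin = 3L) {
  n <- if (nMin == nMax) nMin else sample(nMin:nMax, 1L)
  nodes <- sprintf("n%02d", seq_len(n))
  pairs <- t(combn(nodes, 2L))
  keep <- runif(nrow(pairs)) < pEdge
  # always keep a random spanning path so the graph is connected
  perm <- sample(nodes)
  spine <- cbind(pmin(perm[-n], perm[-1L]), pmax(perm[-n], perm[-1L]))
  el <- unique(rbind(pairs[keep, , drop = FALSE], spine))
  data.frame(geneA = el[, 1L], geneB = el[, 2L],
             rho = runif(nrow(el), -1, 1), stringsAsFactors = FALSE)
}

# Small expression fixture with known correlation structure.
toyExpression <- function(genes = c("g1", "g2", "g3", "g4"), n = 6L) {
  base <- seq_len(n)
  m <- rbind(base, base * 2, rev(base), rep(1, n))[seq_along(genes), ,
                                                   drop = FALSE]
  dimnames(m) <- list(genes, sprintf("s%d", seq_len(n)))
  makeExpressionMatrix(m)
}

writeTempTsv <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}
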