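# Synthetic data: scale-free interaction networks, role assignment, and
# paired cohorts with controlled edge-correlation structure.

#' Generate a scale-free interaction network
#'
#' Barabasi-Albert preferential attachment: each new node attaches `m` links
#' to existing nodes with probability proportional to their degree.  The
#' result is connected and has a heavy-tailed degree distribution, the
#' regime in which hub-centred signaling analyses are meaningful.
#'
#' @param n number of nodes (genes), `n > m`.
#' @param m links attached per new node, `m >= 1`.
#' @param seed integer seed; identical seeds give identical edge sets.
#' @return interaction data.frame (`geneA`, `geneB`) with gene symbols
#'   `g0001`, `g0002`, ...
#' @export
generateScaleFreeNetwork <- function(n, m, seed) {
  if (m < 1L || m >= n) stop("'m' must satisfy 1 <= m < n")
  g <- withSeed(seed, igraph::sample_pa(n, m = m, directed = FALSE))
  el <- igraph::as_edgelist(g, names = FALSE)
  width <- max(4L, nchar(as.character(n)))
  sym <- sprintf(paste0("g%0", width, "d"), seq_len(n))
  a <- sym[el[, 1L]]; b <- sym[el[, 2L]]
  keep <- a != b
  key <- sort(unique(linkKey(a[keep], b[keep])))
  linkKeyUnpack(key)
}

#' Assign receptor and transcription-factor roles
#'
#' Samples disjoint receptor and transcription-factor sets uniformly from
#' the network's nodes.
#'
#' @param interactions interaction data.frame (`geneA`, `geneB`).
#' @param nReceptors,nTfs set sizes; their sum must not exceed the number of
#'   nodes.
#' @param seed integer seed.
#' @return list with character vectors `receptors` and `tfs`.
#' @export
assignRoles <- function(interactions, nReceptors, nTfs, seed) {
  nodes <- sort(unique(c(interactions$geneA, interactions$geneB)))
  if (nReceptors < 1L || nTfs < 1L)
    stop("role set sizes must be positive")
  if (nReceptors + nTfs > length(nodes))
    stop("role sets exceed the number of nodes")
  picks <- withSeed(seed, sample(nodes, nReceptors + nTfs))
  list(receptors = sort(picks[seq_len(nReceptors)]),
       tfs = sort(picks[nReceptors + seq_len(nTfs)]))
}

#' Simulate one cohort with target edge correlations
#'
#' Gaussian propagation along a breadth-first spanning tree of the
#' interaction network: the root gene is standard normal per sample and each
#' child gene is `rho * parent + sqrt(1 - rho^2) * noise`, so the population
#' correlation of a tree edge equals its target.  Targets of non-tree edges
#' are not imposed; their empirical correlations emerge from the tree paths
#' (two genes at tree distance k correlate as the product of the k edge
#' targets).  An arbitrary edge-wise assignment on a cyclic graph need not
#' be positive definite, which is why only a spanning tree is controlled.
#'
#' @param interactions interaction data.frame (`geneA`, `geneB`); must be
#'   connected.
#' @param rhoTargets data.frame (`geneA`, `geneB`, `rho`) with target
#'   absolute correlations in `[0, 1]`; must cover at least the spanning
#'   tree (i.e. every interaction lacking a target is an error).
#' @param nSamples samples to draw (>= 3).
#' @param seed integer seed.
#' @return a `SummarizedExperiment` (genes x samples), see
#'   [makeExpressionMatrix()].
#' @export
simulateCohort <- function(interactions, rhoTargets, nSamples, seed) {
  if (nSamples < 3L) stop("at least 3 samples are required")
  if (any(rhoTargets$rho < 0 | rhoTargets$rho > 1))
    stop("target correlations must lie in [0, 1]")
  g <- igraph::graph_from_data_frame(
    interactions[, c("geneA", "geneB")], directed = FALSE,
    vertices = sort(unique(c(interactions$geneA, interactions$geneB))))
  if (igraph::components(g)$no != 1L)
    stop("interaction network must be connected")
  tkey <- linkKey(rhoTargets$geneA, rhoTargets$geneB)
  rho <- structure(rhoTargets$rho, names = tkey)

  root <- sort(igraph::V(g)$name)[1L]
  bfs <- igraph::bfs(g, root = root, father = TRUE)
  ord <- igraph::V(g)$name[as.integer(bfs$order)]
  father <- structure(
    igraph::V(g)$name[as.integer(bfs$father)], names = igraph::V(g)$name)

  n_genes <- igraph::vcount(g)
  mat <- withSeed(seed, {
    vals <- matrix(0, nrow = n_genes, ncol = nSamples,
                   dimnames = list(sort(igraph::V(g)$name),
                                   sprintf("s%03d", seq_len(nSamples))))
    for (v in ord) {
      p <- father[[v]]
      if (is.na(p)) {
        vals[v, ] <- stats::rnorm(nSamples)
      } else {
        k <- linkKey(p, v)
        r <- unname(rho[k])
        if (length(r) != 1L || is.na(r))
          stop("no correlation target for spanning-tree edge ", p, "-", v)
        vals[v, ] <- r * vals[p, ] +
          sqrt(1 - r^2) * stats::rnorm(nSamples)
      }
    }
    vals
  })
  makeExpressionMatrix(mat)
}

#' Generate a paired normal/tumor synthetic study
#'
#' Builds one scale-free interaction network, assigns receptor and
#' transcription-factor roles, draws target absolute correlations for every
#' link from `rhoLaw`, and simulates two cohorts: the normal cohort with the
#' drawn targets and the tumor cohort with the targets multiplied by the
#' attenuation `lambda` (multiplying rather than adding noise keeps targets
#' in `[0, 1]` by construction).  `lambda = 1` yields identically
#' distributed cohorts; `lambda < 1` reproduces the tumor regime of weaker
#' co-regulation, i.e. larger link distances.
#'
#' @param nNodes,m network size and attachment parameter; defaults 300 and 2.
#' @param nReceptors,nTfs role set sizes; defaults 20 and 15.
#' @param nSamples samples per cohort; default 200.
#' @param lambda attenuation of tumor correlations in `[0, 1]`; default 0.3.
#' @param rhoLaw function `k -> k` target absolute correlations in `[0, 1]`;
#'   default `rbeta(k, 4, 2)` (mean 2/3, matching the strong co-regulation
#'   of normal tissue).
#' @param seed integer seed driving network, roles, targets and both cohorts.
#' @return list with `normal`, `tumor` (`SummarizedExperiment`s),
#'   `interactions`, `receptors`, `tfs` and `rhoTargets` (the normal-cohort
#'   targets).
#' @export
generatePairedCohorts <- function(nNodes = 300, m = 2, nReceptors = 20,
                                  nTfs = 15, nSamples = 200, lambda = 0.3,
                                  rhoLaw = function(k) stats::rbeta(k, 4, 2),
                                  seed = 1) {
  if (lambda < 0 || lambda > 1) stop("'lambda' must lie in [0, 1]")
  if (nReceptors + nTfs > nNodes) stop("role sets exceed the node count")
  interactions <- generateScaleFreeNetwork(nNodes, m, seed)
  roles <- assignRoles(interactions, nReceptors, nTfs, seed + 1L)
  targets <- withSeed(seed + 2L, rhoLaw(nrow(interactions)))
  if (any(targets < 0 | targets > 1))
    stop("'rhoLaw' must return values in [0, 1]")
  rhoTargets <- data.frame(geneA = interactions$geneA,
                           geneB = interactions$geneB, rho = targets)
  tumorTargets <- rhoTargets
  tumorTargets$rho <- lambda * tumorTargets$rho
  list(normal = simulateCohort(interactions, rhoTargets, nSamples,
                               seed + 3L),
       tumor = simulateCohort(interactions, tumorTargets, nSamples,
                              seed + 4L),
       interactions = interactions, receptors = roles$receptors,
       tfs = roles$tfs, rhoTargets = rhoTargets)
}
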