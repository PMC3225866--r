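# Per-cohort topology and regulation features of the signaling network.

# Coerce the various network containers to the underlying igraph.
toGraph <- function(x) {
  if (methods::is(x, "SignalingNetwork")) return(x@network@graph)
  if (methods::is(x, "WeightedNetwork")) return(x@graph)
  if (methods::is(x, "igraph")) return(x)
  stop("expected a SignalingNetwork, WeightedNetwork or igraph object")
}

#' Link and node usage frequencies of a pathway set
#'
#' Counts, for every link and node, the number of pathways it lies on (the
#' endpoints of a pathway count as used).  This is a restricted betweenness:
#' only receptor-to-transcription-factor shortest paths are counted, not all
#' node pairs.
#'
#' @param paths a non-empty [PathwaySet-class].
#' @return list with `linkFreq` (data.frame `geneA`, `geneB`, `freq`),
#'   `nodeFreq` (named integer vector), `pathwayCount`,
#'   `avgLinkFreq` (total link usages divided by distinct used links) and
#'   `avgNodeFreq`.
#' @export
linkNodeFrequencies <- function(paths) {
  stopifnot(methods::is(paths, "PathwaySet"))
  if (pathwayCount(paths) == 0L) stop("empty pathway set")
  lf <- table(unlist(lapply(paths@nodes, pathLinkKeys)))
  linkFreq <- cbind(linkKeyUnpack(names(lf)),
                    freq = as.integer(lf))
  linkFreq <- linkFreq[order(linkFreq$geneA, linkFreq$geneB), , drop = FALSE]
  rownames(linkFreq) <- NULL
  nf <- table(unlist(paths@nodes))
  nodeFreq <- structure(as.integer(nf), names = names(nf))
  nodeFreq <- nodeFreq[sort(names(nodeFreq))]
  list(linkFreq = linkFreq, nodeFreq = nodeFreq,
       pathwayCount = pathwayCount(paths),
       avgLinkFreq = sum(linkFreq$freq) / nrow(linkFreq),
       avgNodeFreq = sum(nodeFreq) / length(nodeFreq))
}

#' Average pathway length in hops
#'
#' @param paths a non-empty [PathwaySet-class].
#' @return arithmetic mean of the hop counts over all pathways.
#' @export
averagePathLength <- function(paths) {
  stopifnot(methods::is(paths, "PathwaySet"))
  if (pathwayCount(paths) == 0L) stop("empty pathway set")
  mean(paths@hops)
}

#' Shannon entropy of pathway traffic over links
#'
#' Treats each link's usage count as proportional to the probability that a
#' signal passes through it, \eqn{p_i = f_i / \sum_j f_j}, and returns
#' \eqn{I = -\sum_i p_i \log_2 p_i} in bits.  The entropy is bounded by
#' `log2(n)` for `n` links, attained at uniform usage.
#'
#' @param freqs positive usage counts, either a numeric vector or the
#'   `linkFreq` data.frame of [linkNodeFrequencies()].
#' @return entropy in bits.
#' @export
shannonEntropy <- function(freqs) {
  if (is.data.frame(freqs)) freqs <- freqs$freq
  freqs <- as.numeric(freqs)
  if (length(freqs) == 0L || any(!is.finite(freqs)) || any(freqs <= 0))
    stop("'freqs' must be positive finite counts")
  p <- freqs / sum(freqs)
  -sum(p * log2(p))
}

#' Local clustering coefficient
#'
#' For a node with `k` neighbors and `L` links among those neighbors,
#' `C = 2L / (k (k - 1))`: 1 when the neighborhood is fully connected, 0 when
#' no two neighbors interact.  Nodes with fewer than two neighbors have
#' `C = 0` (the ratio is undefined there).
#'
#' @param net a [SignalingNetwork-class], [WeightedNetwork-class] or igraph.
#' @param nodes gene symbols to evaluate; default all nodes.
#' @return named numeric vector of coefficients in `[0, 1]`.
#' @export
clusteringCoefficient <- function(net, nodes = NULL) {
  g <- toGraph(net)
  all_nodes <- igraph::V(g)$name
  if (is.null(nodes)) nodes <- all_nodes
  if (!all(nodes %in% all_nodes))
    stop("unknown node(s): ",
         paste(setdiff(nodes, all_nodes), collapse = ", "))
  cc <- igraph::transitivity(g, type = "local", vids = nodes,
                             isolates = "zero")
  structure(ifelse(is.nan(cc), 0, cc), names = nodes)
}

#' Number of nodes with positive clustering coefficient
#'
#' @inheritParams clusteringCoefficient
#' @return integer count of nodes with `C > 0`.
#' @export
countClusteringPositive <- function(net) {
  sum(clusteringCoefficient(net) > 0)
}

#' Power-law exponent of a frequency distribution
#'
#' Continuous maximum-likelihood estimate of the exponent of
#' \eqn{P(f) \sim f^{-\alpha}} from the cumulative-distribution method,
#' \deqn{\hat\alpha = 1 + n \left[\sum_i \ln(f_i / f_{\min})\right]^{-1},}
#' which avoids the noisy tail of the binned distribution.  A discrete
#' half-step-corrected variant (`f_min - 0.5` in the denominator of the
#' ratios) is available.  With `fit = TRUE` the least-squares intercept of
#' the log-log regression line with fixed slope `-alpha` is also returned,
#' for plotting only.
#'
#' @param freqs at least 10 positive frequencies, not all equal.
#' @param fmin lower cut-off of the fit; defaults to the smallest observed
#'   frequency.
#' @param variant `"continuous"` (default) or `"discrete"`.
#' @param fit also return the plotting intercept.
#' @return the estimate `alpha`, or with `fit = TRUE` a list
#'   `list(alpha, intercept)`.
#' @export
estimatePowerlawExponent <- function(freqs, fmin = min(freqs),
                                     variant = c("continuous", "discrete"),
                                     fit = FALSE) {
  variant <- match.arg(variant)
  freqs <- as.numeric(freqs)
  if (length(freqs) < 10L) stop("at least 10 frequencies are required")
  if (any(!is.finite(freqs)) || any(freqs <= 0))
    stop("'freqs' must be positive and finite")
  if (min(freqs) < fmin) stop("'fmin' exceeds the smallest frequency")
  denom <- if (variant == "continuous") fmin else fmin - 0.5
  s <- sum(log(freqs / denom))
  if (s <= 0) stop("all frequencies equal: exponent undefined")
  alpha <- 1 + length(freqs) / s
  if (!fit) return(alpha)
  tab <- table(freqs)
  lx <- log10(as.numeric(names(tab)))
  ly <- log10(as.numeric(tab) / length(freqs))
  list(alpha = alpha, intercept = mean(ly + alpha * lx))
}

#' Average network diameter
#'
#' The mean hop distance over all unordered reachable node pairs; unreachable
#' pairs are excluded (the network may fragment after hub removal).
#'
#' @param net a [SignalingNetwork-class], [WeightedNetwork-class] or igraph.
#' @return mean shortest-path hop distance.
#' @export
networkDiameter <- function(net) {
  g <- toGraph(net)
  if (igraph::vcount(g) < 2L) stop("at least 2 nodes are required")
  d <- igraph::distances(g, weights = NA)
  vals <- d[upper.tri(d)]
  vals <- vals[is.finite(vals)]
  if (length(vals) == 0L) stop("no reachable node pair")
  mean(vals)
}

#' Diameter increase after directed hub removal
#'
#' Removes the `max(1, floor(fraction * n))` nodes of highest usage frequency
#' (ties broken by frequency, then lexicographically by name), recomputes the
#' average diameter on the largest remaining component and returns the ratio
#' diameter-after / diameter-before.  Scale-free networks are fragile against
#' exactly this kind of directed attack, so the ratio gauges how strongly the
#' network depends on its hubs.
#'
#' @param net a [SignalingNetwork-class], or any network accepted by
#'   [networkDiameter()] together with `nodeFreq`.
#' @param nodeFreq named numeric vector of node usage frequencies; taken from
#'   `net` when it is a [SignalingNetwork-class].
#' @param fraction fraction of nodes to remove, in (0, 1); default 0.10.
#' @return the diameter ratio (>= 0).
#' @export
hubRemovalRobustness <- function(net, nodeFreq = NULL, fraction = 0.10) {
  if (fraction <= 0 || fraction >= 1) stop("'fraction' must lie in (0, 1)")
  g <- toGraph(net)
  if (is.null(nodeFreq)) {
    if (!methods::is(net, "SignalingNetwork"))
      stop("'nodeFreq' is required unless 'net' is a SignalingNetwork")
    nodeFreq <- net@nodeFreq
  }
  names_all <- igraph::V(g)$name
  freq <- structure(rep(0, length(names_all)), names = names_all)
  common <- intersect(names(nodeFreq), names_all)
  freq[common] <- nodeFreq[common]
  k <- max(1L, floor(fraction * length(names_all)))
  ord <- order(-freq, names(freq))
  hubs <- names(freq)[ord[seq_len(k)]]
  before <- networkDiameter(g)
  rest <- igraph::delete_vertices(g, hubs)
  if (igraph::vcount(rest) < 2L) stop("hub removal emptied the network")
  comp <- igraph::components(rest)
  lcc <- igraph::induced_subgraph(
    rest, igraph::V(rest)$name[comp$membership == which.max(comp$csize)])
  if (igraph::vcount(lcc) < 2L) stop("no connected pair left after removal")
  networkDiameter(lcc) / before
}

#' Full per-cohort feature panel of a signaling network
#'
#' Computes the complete feature vector reported for each cohort: numbers of
#' links and nodes, average link/node usage frequency, average pathway length
#' (hops), Shannon entropy of link traffic (bits), mean clustering
#' coefficient, number of nodes with positive clustering, the power-law
#' exponent of the link-frequency distribution, average diameter, diameter
#' increase after removing the top `hubFraction` hubs, and the mean link
#' distance.  The exponent is `NA` when the link-frequency distribution is
#' degenerate (fewer than 10 links or all counts equal).
#'
#' @param snet a [SignalingNetwork-class].
#' @param hubFraction hub fraction for [hubRemovalRobustness()]; default 0.10.
#' @return one-row data.frame.
#' @export
networkFeatures <- function(snet, hubFraction = 0.10) {
  stopifnot(methods::is(snet, "SignalingNetwork"))
  g <- snet@network@graph
  lf <- snet@linkFreq$freq
  alpha <- tryCatch(estimatePowerlawExponent(lf), error = function(e) NA_real_)
  diam <- networkDiameter(g)
  ratio <- tryCatch(hubRemovalRobustness(snet, fraction = hubFraction),
                    error = function(e) NA_real_)
  data.frame(
    n_links = igraph::ecount(g),
    n_nodes = igraph::vcount(g),
    used_links_pct = 100 * igraph::ecount(g) / snet@originalLinks,
    used_nodes_pct = 100 * igraph::vcount(g) / snet@originalNodes,
    link_frequency = sum(lf) / length(lf),
    node_frequency = sum(snet@nodeFreq) / length(snet@nodeFreq),
    path_length = averagePathLength(snet@pathways),
    entropy = shannonEntropy(lf),
    clustering = mean(clusteringCoefficient(g)),
    clustering_positive = countClusteringPositive(g),
    alpha = alpha,
    diameter = diam,
    diameter_increase = ratio,
    link_distance = mean(igraph::E(g)$distance))
}
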