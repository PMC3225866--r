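# Pathway extraction: deterministic Dijkstra over link distances, one
# shortest path per (receptor, transcription factor) pair, and the
# pathway-pruned signaling network.

# Adjacency in index space. Vertices of a WeightedNetwork are created in
# lexicographic name order, so ascending neighbor indices equal ascending
# names -- the tie rule below relies on this.
adjacencyIndex <- function(net) {
  g <- net@graph
  n <- igraph::vcount(g)
  el <- igraph::as_edgelist(g, names = FALSE)
  w <- igraph::E(g)$distance
  from <- c(el[, 1L], el[, 2L])
  to <- c(el[, 2L], el[, 1L])
  wt <- c(w, w)
  ord <- order(from, to)
  from <- from[ord]; to <- to[ord]; wt <- wt[ord]
  idx <- split(seq_along(from), factor(from, levels = seq_len(n)))
  list(n = n, names = igraph::V(g)$name,
       nbr = lapply(idx, function(i) to[i]),
       wt = lapply(idx, function(i) wt[i]))
}

# Single-source Dijkstra returning, for every node, the minimal total
# distance and -- among distance-optimal paths -- the minimal hop count.
# Nodes are settled in (distance, hops) lexicographic order so both values
# are final when settled, also across zero-weight plateaus.
dijkstraTree <- function(adj, src, tol = 1e-12) {
  n <- adj$n
  dist <- rep(Inf, n); hops <- rep(Inf, n)
  dist[src] <- 0; hops[src] <- 0
  visited <- rep(FALSE, n)
  repeat {
    open <- which(!visited & is.finite(dist))
    if (length(open) == 0L) break
    d0 <- min(dist[open])
    cand <- open[dist[open] <= d0 + tol]
    u <- cand[which.min(hops[cand])]
    visited[u] <- TRUE
    nbr <- adj$nbr[[u]]; wt <- adj$wt[[u]]
    for (j in seq_along(nbr)) {
      v <- nbr[j]
      if (visited[v]) next
      nd <- dist[u] + wt[j]
      if (nd < dist[v] - tol) {
        dist[v] <- nd; hops[v] <- hops[u] + 1
      } else if (nd <= dist[v] + tol && hops[u] + 1 < hops[v]) {
        dist[v] <- min(dist[v], nd); hops[v] <- hops[u] + 1
      }
    }
  }
  list(dist = dist, hops = hops)
}

# Lexicographically smallest optimal path src -> dst, given the Dijkstra
# tree rooted at dst. At every step the smallest-named neighbor that still
# admits a (distance, hops)-optimal completion is taken.
walkOptimalPath <- function(adj, tree, src, dst, tol = 1e-9) {
  total <- tree$dist[src]; htot <- tree$hops[src]
  path <- integer(htot + 1L)
  path[1L] <- src
  acc <- 0; cur <- src
  for (k in seq_len(htot)) {
    nbr <- adj$nbr[[cur]]; wt <- adj$wt[[cur]]
    found <- FALSE
    for (j in seq_along(nbr)) {     # ascending name order
      v <- nbr[j]
      if (acc + wt[j] + tree$dist[v] <= total + tol &&
          k + tree$hops[v] == htot) {
        acc <- acc + wt[j]; cur <- v; path[k + 1L] <- v
        found <- TRUE
        break
      }
    }
    if (!found) stop("internal error: optimal path reconstruction failed")
  }
  if (cur != dst) stop("internal error: path did not reach the target")
  list(nodes = path, totalDistance = acc, hops = htot)
}

#' Deterministic Dijkstra shortest path between two genes
#'
#' Finds the minimum-total-distance path between `source` and `target` over
#' the link distances of the weighted network.  Among equal-distance optima
#' the path with the fewest hops is chosen, and among those the
#' lexicographically smallest node sequence -- a fixed tie rule, since link
#' and node usage counts (and hence the motif statistics) depend on which
#' optimum is reported.
#'
#' @param net a [WeightedNetwork-class].
#' @param source,target distinct gene symbols present in the network.
#' @return `NULL` when `target` is unreachable, otherwise a list with
#'   `nodes` (character sequence from `source` to `target`),
#'   `totalDistance` and `hops`.
#' @export
dijkstraShortestPath <- function(net, source, target) {
  stopifnot(methods::is(net, "WeightedNetwork"))
  if (source == target) stop("'source' and 'target' must differ")
  adj <- adjacencyIndex(net)
  si <- match(source, adj$names); ti <- match(target, adj$names)
  if (is.na(si)) stop("unknown node: ", source)
  if (is.na(ti)) stop("unknown node: ", target)
  tree <- dijkstraTree(adj, ti)
  if (!is.finite(tree$dist[si])) return(NULL)
  p <- walkOptimalPath(adj, tree, si, ti)
  list(nodes = adj$names[p$nodes], totalDistance = p$totalDistance,
       hops = p$hops)
}

#' Extract one pathway per (receptor, transcription factor) pair
#'
#' Computes the deterministic shortest path (see [dijkstraShortestPath()])
#' for every ordered pair of a receptor and a transcription factor that are
#' both present in the network, skipping pairs where the same gene holds both
#' roles; unreachable pairs are absent from the result.  One Dijkstra tree is
#' grown per transcription factor and shared across receptors.
#'
#' @param net a [WeightedNetwork-class].
#' @param receptors,tfs character vectors of gene symbols (role lists);
#'   symbols absent from the network are ignored.
#' @return a [PathwaySet-class].
#' @export
extractPathways <- function(net, receptors, tfs) {
  stopifnot(methods::is(net, "WeightedNetwork"))
  receptors <- unique(as.character(receptors))
  tfs <- unique(as.character(tfs))
  if (length(receptors) == 0L || length(tfs) == 0L)
    stop("receptor and transcription-factor lists must be non-empty")
  adj <- adjacencyIndex(net)
  ri <- match(receptors, adj$names); ri <- sort(ri[!is.na(ri)])
  ti <- match(tfs, adj$names); ti <- sort(ti[!is.na(ti)])
  if (length(ri) == 0L || length(ti) == 0L)
    stop("no receptor or no transcription factor present in the network")

  rec <- character(0); tfv <- character(0)
  hops <- integer(0); dist <- numeric(0); nodes <- list()
  for (t in ti) {
    tree <- dijkstraTree(adj, t)
    for (r in ri) {
      if (r == t || !is.finite(tree$dist[r])) next
      p <- walkOptimalPath(adj, tree, r, t)
      rec <- c(rec, adj$names[r]); tfv <- c(tfv, adj$names[t])
      hops <- c(hops, p$hops); dist <- c(dist, p$totalDistance)
      nodes <- c(nodes, list(adj$names[p$nodes]))
    }
  }
  if (length(rec) == 0L)
    stop("no receptor-transcription-factor pair is connected")
  ord <- order(rec, tfv)
  methods::new("PathwaySet", receptor = rec[ord], tf = tfv[ord],
               hops = as.integer(hops[ord]), totalDistance = dist[ord],
               nodes = nodes[ord])
}

#' Prune to the pathway-used largest connected component
#'
#' Restricts the weighted network to links used by at least one pathway, then
#' to the largest connected component of that restriction (ties broken toward
#' the component containing the lexicographically smallest node).  Pathways
#' whose nodes left the component are dropped, and link/node usage counts are
#' computed on the survivors.
#'
#' @param net the [WeightedNetwork-class] the pathways were extracted from.
#' @param paths a non-empty [PathwaySet-class].
#' @return a [SignalingNetwork-class].
#' @export
buildSignalingNetwork <- function(net, paths) {
  stopifnot(methods::is(net, "WeightedNetwork"),
            methods::is(paths, "PathwaySet"))
  if (pathwayCount(paths) == 0L) stop("empty pathway set")
  g <- net@graph
  used_keys <- unique(unlist(lapply(paths@nodes, pathLinkKeys)))
  all_el <- igraph::as_edgelist(g, names = TRUE)
  all_keys <- linkKey(all_el[, 1L], all_el[, 2L])
  sub <- igraph::subgraph_from_edges(g, which(all_keys %in% used_keys),
                                     delete.vertices = TRUE)
  comp <- igraph::components(sub)
  best <- which(comp$csize == max(comp$csize))
  if (length(best) > 1L) {
    firsts <- vapply(best, function(k)
      min(igraph::V(sub)$name[comp$membership == k]), "")
    best <- best[order(firsts)][1L]
  }
  lcc_nodes <- igraph::V(sub)$name[comp$membership == best]
  lcc <- igraph::induced_subgraph(sub, lcc_nodes)
  # reorder vertices lexicographically (induced_subgraph preserves order,
  # but be explicit: downstream tie rules assume sorted vertex names)
  lcc <- igraph::permute(lcc, match(igraph::V(lcc)$name,
                                    sort(igraph::V(lcc)$name)))

  keep <- vapply(paths@nodes, function(nd) all(nd %in% lcc_nodes), TRUE)
  if (!any(keep)) stop("no pathway survived the component restriction")
  surv <- methods::new("PathwaySet",
                       receptor = paths@receptor[keep], tf = paths@tf[keep],
                       hops = paths@hops[keep],
                       totalDistance = paths@totalDistance[keep],
                       nodes = paths@nodes[keep])

  lf <- table(unlist(lapply(surv@nodes, pathLinkKeys)))
  el <- igraph::as_edgelist(lcc, names = TRUE)
  ekey <- linkKey(el[, 1L], el[, 2L])
  linkFreq <- data.frame(geneA = pmin(el[, 1L], el[, 2L]),
                         geneB = pmax(el[, 1L], el[, 2L]),
                         freq = as.integer(lf[ekey]),
                         stringsAsFactors = FALSE)
  linkFreq <- linkFreq[order(linkFreq$geneA, linkFreq$geneB), , drop = FALSE]
  rownames(linkFreq) <- NULL
  nf <- table(unlist(surv@nodes))
  nodeFreq <- structure(as.integer(nf), names = names(nf))
  nodeFreq <- nodeFreq[sort(names(nodeFreq))]

  methods::new("SignalingNetwork",
               network = methods::new("WeightedNetwork", graph = lcc),
               pathways = surv, linkFreq = linkFreq, nodeFreq = nodeFreq,
               originalNodes = as.integer(igraph::vcount(g)),
               originalLinks = as.integer(igraph::ecount(g)))
}
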