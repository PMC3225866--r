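setOldClass("igraph")

#' WeightedNetwork: an undirected interaction network with correlation weights
#'
#' Wraps an undirected \pkg{igraph} graph whose edges carry the signed Pearson
#' correlation \code{rho} of the incident genes' expression and the link
#' distance \code{distance = 1 - |rho|}.  Links whose correlation is undefined
#' (a zero-variance gene) carry \code{rho = NA} and the maximal distance 1.
#'
#' @slot graph an undirected \pkg{igraph} object with vertex attribute
#'   \code{name} and edge attributes \code{rho} and \code{distance}.
#' @seealso [buildWeightedNetwork()], [linkTable()], [nodeNames()]
#' @export
setClass("WeightedNetwork", representation(graph = "igraph"))

setValidity("WeightedNetwork", function(object) {
  g <- object@graph
  if (igraph::is_directed(g)) return("graph must be undirected")
  if (igraph::ecount(g) == 0L) return("network has no links")
  if (any(igraph::which_loop(g))) return("self-links are not allowed")
  if (igraph::any_multiple(g)) return("duplicated links are not allowed")
  rho <- igraph::E(g)$rho
  d <- igraph::E(g)$distance
  if (is.null(rho) || is.null(d)) return("edges must carry 'rho' and 'distance'")
  expected <- ifelse(is.na(rho), 1, 1 - abs(rho))
  if (any(abs(d - expected) > 1e-12))
    return("edge distances must equal 1 - |rho|")
  if (any(d < -1e-12 | d > 1 + 1e-12)) return("distances must lie in [0, 1]")
  TRUE
})

#' PathwaySet: one shortest path per (receptor, transcription factor) pair
#'
#' @slot receptor,tf character vectors, one entry per pathway.
#' @slot hops integer hop counts (number of links on the path).
#' @slot totalDistance numeric summed link distances along the path.
#' @slot nodes list of character vectors, the ordered node sequences from
#'   receptor to transcription factor.
#' @seealso [extractPathways()], [pathwayTable()]
#' @export
setClass("PathwaySet", representation(
  receptor = "character", tf = "character", hops = "integer",
  totalDistance = "numeric", nodes = "list"))

setValidity("PathwaySet", function(object) {
  n <- length(object@receptor)
  if (length(object@tf) != n || length(object@hops) != n ||
      length(object@totalDistance) != n || length(object@nodes) != n)
    return("all slots must have equal length")
  if (n == 0L) return(TRUE)
  if (anyDuplicated(paste(object@receptor, object@tf)))
    return("at most one pathway per (receptor, tf) pair")
  first <- vapply(object@nodes, `[`, "", 1L)
  last <- vapply(object@nodes, function(x) x[length(x)], "")
  if (any(first != object@receptor) || any(last != object@tf))
    return("node sequences must start at the receptor and end at the tf")
  if (any(vapply(object@nodes, length, 1L) - 1L != object@hops))
    return("hops must equal length(nodes) - 1")
  TRUE
})

#' SignalingNetwork: the pathway-pruned largest connected component
#'
#' The correlation-weighted network restricted to links used by at least one
#' receptor-to-transcription-factor pathway, further restricted to its largest
#' connected component, together with the usage-count tables (a restricted
#' betweenness: the number of pathways each link or node lies on).
#'
#' @slot network the pruned [WeightedNetwork-class].
#' @slot pathways the surviving [PathwaySet-class] (pathways whose links left
#'   the largest connected component are dropped).
#' @slot linkFreq data.frame with columns \code{geneA}, \code{geneB},
#'   \code{freq}.
#' @slot nodeFreq named integer vector of node usage counts.
#' @slot originalNodes,originalLinks sizes of the unpruned weighted network,
#'   kept so coverage fractions can be reported.
#' @seealso [buildSignalingNetwork()], [linkFrequencies()], [nodeFrequencies()]
#' @export
setClass("SignalingNetwork", representation(
  network = "WeightedNetwork", pathways = "PathwaySet",
  linkFreq = "data.frame", nodeFreq = "numeric",
  originalNodes = "integer", originalLinks = "integer"))

setValidity("SignalingNetwork", function(object) {
  if (nrow(object@linkFreq) != igraph::ecount(object@network@graph))
    return("one frequency row per surviving link required")
  if (any(object@linkFreq$freq < 1) || any(object@nodeFreq < 1))
    return("every surviving link and node must be used by >= 1 pathway")
  TRUE
})
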