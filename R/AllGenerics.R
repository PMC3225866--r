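#' Accessors for network and pathway objects
#'
#' @param x a [WeightedNetwork-class], [SignalingNetwork-class] or
#'   [PathwaySet-class] object.
#' @return `linkTable` returns a data.frame with one row per link
#'   (`geneA`, `geneB`, `rho`, `distance`); `nodeNames` a character vector;
#'   `asIgraph` the underlying \pkg{igraph} graph; `pathwayTable` a data.frame
#'   with one row per pathway (node sequences joined by `"|"`);
#'   `linkFrequencies` a data.frame (`geneA`, `geneB`, `freq`);
#'   `nodeFrequencies` a named integer vector; `pathwayCount` the number of
#'   pathways.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("linkTable", function(x) standardGeneric("linkTable"))

#' @rdname accessors
#' @export
setGeneric("nodeNames", function(x) standardGeneric("nodeNames"))

#' @rdname accessors
#' @export
setGeneric("asIgraph", function(x) standardGeneric("asIgraph"))

#' @rdname accessors
#' @export
setGeneric("pathwayTable", function(x) standardGeneric("pathwayTable"))

#' @rdname accessors
#' @export
setGeneric("pathwayCount", function(x) standardGeneric("pathwayCount"))

#' @rdname accessors
#' @export
setGeneric("linkFrequencies", function(x) standardGeneric("linkFrequencies"))

#' @rdname accessors
#' @export
setGeneric("nodeFrequencies", function(x) standardGeneric("nodeFrequencies"))

#' @rdname accessors
#' @export
setMethod("linkTable", "WeightedNetwork", function(x) {
  g <- x@graph
  el <- igraph::as_edgelist(g, names = TRUE)
  df <- data.frame(geneA = pmin(el[, 1L], el[, 2L]),
                   geneB = pmax(el[, 1L], el[, 2L]),
                   rho = igraph::E(g)$rho,
                   distance = igraph::E(g)$distance,
                   stringsAsFactors = FALSE)
  df[order(df$geneA, df$geneB), , drop = FALSE]
})

#' @rdname accessors
#' @export
setMethod("linkTable", "SignalingNetwork", function(x) linkTable(x@network))

#' @rdname accessors
#' @export
setMethod("nodeNames", "WeightedNetwork",
          function(x) sort(igraph::V(x@graph)$name))

#' @rdname accessors
#' @export
setMethod("nodeNames", "SignalingNetwork", function(x) nodeNames(x@network))

#' @rdname accessors
#' @export
setMethod("asIgraph", "WeightedNetwork", function(x) x@graph)

#' @rdname accessors
#' @export
setMethod("asIgraph", "SignalingNetwork", function(x) x@network@graph)

#' @rdname accessors
#' @export
setMethod("pathwayTable", "PathwaySet", function(x) {
  data.frame(receptor = x@receptor, tf = x@tf, hops = x@hops,
             totalDistance = x@totalDistance,
             nodes = vapply(x@nodes, paste, "", collapse = "|"),
             stringsAsFactors = FALSE)
})

#' @rdname accessors
#' @export
setMethod("pathwayTable", "SignalingNetwork",
          function(x) pathwayTable(x@pathways))

#' @rdname accessors
#' @export
setMethod("pathwayCount", "PathwaySet", function(x) length(x@receptor))

#' @rdname accessors
#' @export
setMethod("pathwayCount", "SignalingNetwork",
          function(x) pathwayCount(x@pathways))

#' @rdname accessors
#' @export
setMethod("linkFrequencies", "SignalingNetwork", function(x) x@linkFreq)

#' @rdname accessors
#' @export
setMethod("nodeFrequencies", "SignalingNetwork", function(x) x@nodeFreq)

setMethod("show", "WeightedNetwork", function(object) {
  g <- object@graph
  cat(sprintf("WeightedNetwork: %d nodes, %d links\n",
              igraph::vcount(g), igraph::ecount(g)))
  cat(sprintf("  mean link distance: %.3f (%d undefined correlations)\n",
              mean(igraph::E(g)$distance), sum(is.na(igraph::E(g)$rho))))
})

setMethod("show", "PathwaySet", function(object) {
  n <- length(object@receptor)
  cat(sprintf("PathwaySet: %d pathways (%d receptors -> %d TFs)\n", n,
              length(unique(object@receptor)), length(unique(object@tf))))
  if (n > 0L)
    cat(sprintf("  hops: mean %.2f, range %d-%d\n", mean(object@hops),
                min(object@hops), max(object@hops)))
})

setMethod("show", "SignalingNetwork", function(object) {
  g <- object@network@graph
  cat(sprintf(
    "SignalingNetwork: %d/%d nodes, %d/%d links used by %d pathways\n",
    igraph::vcount(g), object@originalNodes,
    igraph::ecount(g), object@originalLinks, pathwayCount(object)))
})
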