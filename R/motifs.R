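# Motif analysis: cancer-mutated hub selection, shared-triangle
# enumeration, and the integration, maintenance and comparative motifs.

#' Select cancer-mutated hubs shared by both cohorts
#'
#' Intersects the cancer-mutated gene list with the nodes present in both
#' signaling networks, ranks that intersection by node usage frequency
#' separately per cohort (ties broken lexicographically), takes the top `k`
#' per cohort and returns the union; genes selected in both cohorts appear
#' once.
#'
#' @param freqNormal,freqTumor named numeric vectors of node usage
#'   frequencies (see [nodeFrequencies()]).
#' @param cancerGenes character vector of cancer-mutated gene symbols.
#' @param k hubs per cohort; default 50.
#' @return sorted character vector of hub symbols (possibly empty, with a
#'   warning).
#' @export
selectCancerHubs <- function(freqNormal, freqTumor, cancerGenes, k = 50) {
  stopifnot(k >= 1)
  pool <- intersect(intersect(names(freqNormal), names(freqTumor)),
                    unique(as.character(cancerGenes)))
  if (length(pool) == 0L) {
    warning("no cancer-mutated gene present in both networks")
    return(character(0))
  }
  top <- function(freq) {
    f <- freq[pool]
    pool[order(-f, pool)][seq_len(min(k, length(pool)))]
  }
  sort(union(top(freqNormal), top(freqTumor)))
}

#' Enumerate hub-centered triangles shared by both cohorts
#'
#' Finds every triple (hub, n1, n2) such that the three links hub-n1, hub-n2
#' and n1-n2 are present in both the normal and the tumor signaling network
#' (so counts are comparable between cohorts).  A triangle containing two
#' hubs yields one record per hub role.  Each record carries the correlation
#' and category of the three links in both cohorts.
#'
#' @param netN,netT the normal and tumor networks, either
#'   [SignalingNetwork-class] or [WeightedNetwork-class] objects (anything
#'   with a [linkTable()] method).
#' @param hubs character vector of hub symbols (see [selectCancerHubs()]).
#' @return data.frame with columns `hub`, `n1`, `n2` (with `n1 < n2`),
#'   `rho_*` and `cat_*` for the links `h1` (hub-n1), `h2` (hub-n2) and
#'   `n12` (n1-n2) in cohorts `N` and `T`; zero rows when no triangle exists.
#' @export
enumerateSharedTriangles <- function(netN, netT, hubs) {
  ltN <- linkTable(netN); ltT <- linkTable(netT)
  keyN <- linkKey(ltN$geneA, ltN$geneB)
  keyT <- linkKey(ltT$geneA, ltT$geneB)
  common <- intersect(keyN, keyT)
  empty <- data.frame(hub = character(0), n1 = character(0), n2 = character(0))
  if (length(common) == 0L || length(hubs) == 0L) return(empty)
  rhoN <- structure(ltN$rho[match(common, keyN)], names = common)
  rhoT <- structure(ltT$rho[match(common, keyT)], names = common)
  el <- linkKeyUnpack(common)
  g <- igraph::graph_from_data_frame(el, directed = FALSE)

  recs <- list()
  for (h in intersect(hubs, igraph::V(g)$name)) {
    nbr <- sort(igraph::V(g)$name[
      igraph::neighbors(g, h)])
    if (length(nbr) < 2L) next
    pairs <- utils::combn(nbr, 2L)
    closed <- linkKey(pairs[1L, ], pairs[2L, ]) %in% common
    if (!any(closed)) next
    recs[[h]] <- data.frame(hub = h, n1 = pairs[1L, closed],
                            n2 = pairs[2L, closed],
                            stringsAsFactors = FALSE)
  }
  if (length(recs) == 0L) return(empty)
  tri <- do.call(rbind, recs)
  rownames(tri) <- NULL
  k1 <- linkKey(tri$hub, tri$n1)
  k2 <- linkKey(tri$hub, tri$n2)
  k12 <- linkKey(tri$n1, tri$n2)
  tri$rho_h1_N <- unname(rhoN[k1]); tri$rho_h1_T <- unname(rhoT[k1])
  tri$rho_h2_N <- unname(rhoN[k2]); tri$rho_h2_T <- unname(rhoT[k2])
  tri$rho_n12_N <- unname(rhoN[k12]); tri$rho_n12_T <- unname(rhoT[k12])
  for (link in c("h1", "h2", "n12")) for (co in c("N", "T")) {
    tri[[paste0("cat_", link, "_", co)]] <-
      correlationCategory(tri[[paste0("rho_", link, "_", co)]])
  }
  tri[order(tri$hub, tri$n1, tri$n2), , drop = FALSE]
}

#' Count integration motifs
#'
#' A triangle shows the integration motif in a cohort when all three of its
#' links are highly correlated there (|rho| > 0.5): the hub is regulatorily
#' integrated with its neighborhood.
#'
#' @param triangles data.frame from [enumerateSharedTriangles()].
#' @return named integer vector `c(normal = ..., tumor = ...)`.
#' @export
countIntegrationMotifs <- function(triangles) {
  if (nrow(triangles) == 0L) return(c(normal = 0L, tumor = 0L))
  allHigh <- function(co) {
    triangles[[paste0("cat_h1_", co)]] == "high" &
      triangles[[paste0("cat_h2_", co)]] == "high" &
      triangles[[paste0("cat_n12_", co)]] == "high"
  }
  c(normal = sum(allHigh("N")), tumor = sum(allHigh("T")))
}

#' Count maintenance motifs
#'
#' A triangle shows the maintenance motif when both hub links (hub-n1,
#' hub-n2) are highly correlated in one cohort and uncorrelated in the other,
#' while the neighbor-neighbor link n1-n2 keeps its category across cohorts:
#' the hub is de-correlated but its vicinity maintains its regulation.  The
#' count is attributed to the cohort in which the hub is DE-correlated (so a
#' hub detached in the tumor increments the tumor count).
#'
#' @param triangles data.frame from [enumerateSharedTriangles()].
#' @return named integer vector `c(normal = ..., tumor = ...)`.
#' @export
countMaintenanceMotifs <- function(triangles) {
  if (nrow(triangles) == 0L) return(c(normal = 0L, tumor = 0L))
  stays <- triangles$cat_n12_N == triangles$cat_n12_T
  highN_noneT <- triangles$cat_h1_N == "high" & triangles$cat_h2_N == "high" &
    triangles$cat_h1_T == "none" & triangles$cat_h2_T == "none"
  highT_noneN <- triangles$cat_h1_T == "high" & triangles$cat_h2_T == "high" &
    triangles$cat_h1_N == "none" & triangles$cat_h2_N == "none"
  c(normal = sum(highT_noneN & stays), tumor = sum(highN_noneT & stays))
}

#' Count comparative network motifs
#'
#' For every transcription factor and every unordered pair of receptors whose
#' pathways to that factor exist in both cohorts, the normal count increments
#' when the two normal pathways share at least one link while the two tumor
#' pathways share none, and the tumor count in the mirror case.  Sharing is
#' judged on undirected links; shared nodes alone do not count.
#'
#' @param pathsN,pathsT [PathwaySet-class] objects for the two cohorts,
#'   extracted over the same role lists.
#' @return named integer vector `c(normal = ..., tumor = ...)`.
#' @export
countComparativeMotifs <- function(pathsN, pathsT) {
  stopifnot(methods::is(pathsN, "PathwaySet"),
            methods::is(pathsT, "PathwaySet"))
  keyN <- paste(pathsN@receptor, pathsN@tf, sep = "\r")
  keyT <- paste(pathsT@receptor, pathsT@tf, sep = "\r")
  normal <- 0L; tumor <- 0L
  for (tf in intersect(unique(pathsN@tf), unique(pathsT@tf))) {
    recs <- sort(intersect(pathsN@receptor[pathsN@tf == tf],
                           pathsT@receptor[pathsT@tf == tf]))
    if (length(recs) < 2L) next
    linksFor <- function(paths, key) {
      idx <- match(paste(recs, tf, sep = "\r"), key)
      lapply(idx, function(i) pathLinkKeys(paths@nodes[[i]]))
    }
    lkN <- linksFor(pathsN, keyN)
    lkT <- linksFor(pathsT, keyT)
    # receptor x link incidence, then pairwise overlap via crossproduct
    shareMatrix <- function(lk) {
      links <- unique(unlist(lk))
      inc <- vapply(lk, function(x) links %in% x,
                    logical(length(links)))
      if (length(links) == 1L) inc <- matrix(inc, nrow = 1L)
      crossprod(inc * 1) > 0
    }
    sN <- shareMatrix(lkN)
    sT <- shareMatrix(lkT)
    up <- upper.tri(sN)
    normal <- normal + sum(sN[up] & !sT[up])
    tumor <- tumor + sum(sT[up] & !sN[up])
  }
  c(normal = normal, tumor = tumor)
}
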