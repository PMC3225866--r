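test_that("dijkstraShortestPath finds the minimal-distance route", {
  net <- toyNetwork(c("A", "B", "A"), c("B", "C", "C"),
                    distance = c(0.1, 0.1, 0.3))
  p <- dijkstraShortestPath(net, "A", "C")
  expect_identical(p$nodes, c("A", "B", "C"))
  expect_equal(p$totalDistance, 0.2, tolerance = 1e-12)
  expect_identical(p$hops, 2)
})

test_that("equal-distance optima resolve by fewer hops then lexicographic order", {
  # direct link A-C ties the detour A-B-C at 0.3: fewer hops wins
  net <- toyNetwork(c("A", "B", "A"), c("B", "C", "C"),
                    distance = c(0.1, 0.2, 0.3))
  p <- dijkstraShortestPath(net, "A", "C")
  expect_identical(p$nodes, c("A", "C"))
  expect_identical(p$hops, 1)
  # two equal-cost, equal-hop routes: smallest node sequence wins
  net2 <- toyNetwork(c("A", "A", "B", "D"), c("B", "D", "C", "C"),
                     distance = c(0.2, 0.2, 0.2, 0.2))
  p2 <- dijkstraShortestPath(net2, "A", "C")
  expect_identical(p2$nodes, c("A", "B", "C"))
})

test_that("unreachable targets and invalid queries are handled", {
  net <- toyNetwork(c("A", "C"), c("B", "D"), distance = c(0.1, 0.1))
  expect_null(dijkstraShortestPath(net, "A", "C"))
  expect_error(dijkstraShortestPath(net, "A", "A"), "differ")
  expect_error(dijkstraShortestPath(net, "A", "Z"), "unknown")
})

test_that("dijkstra agrees with exhaustive simple-path enumeration", {
  withr::with_seed(42, {
    for (rep in 1:60) {
      links <- randomWeightedGraph(8)
      links$distance <- 1 - abs(links$rho)
      net <- toyNetwork(links$geneA, links$geneB, rho = links$rho)
      nodes <- nodeNames(net)
      pick <- sample(nodes, 2L)
      got <- dijkstraShortestPath(net, pick[1L], pick[2L])
      want <- oracleShortestPath(links, pick[1L], pick[2L])
      expect_equal(got$totalDistance, want$totalDistance, tolerance = 1e-9)
      expect_identical(got$nodes, want$nodes)
    }
  })
})

test_that("extractPathways yields one path per reachable role pair", {
  net <- toyNetwork(c("R1", "R2", "M", "M"), c("M", "M", "T1", "T2"),
                    distance = rep(0.2, 4))
  ps <- extractPathways(net, c("R1", "R2"), c("T1", "T2"))
  expect_identical(pathwayCount(ps), 4L)
  tab <- pathwayTable(ps)
  expect_identical(sort(paste(tab$receptor, tab$tf)),
                   c("R1 T1", "R1 T2", "R2 T1", "R2 T2"))
  # a gene holding both roles is skipped as a self-pair
  ps2 <- extractPathways(net, c("R1", "T1"), c("T1", "T2"))
  expect_false(any(ps2@receptor == ps2@tf))
  expect_identical(pathwayCount(ps2), 3L)
  # an isolated TF contributes no pathways
  net3 <- toyNetwork(c("R1", "M", "X"), c("M", "T1", "T2"),
                     distance = c(0.2, 0.2, 0.2))
  ps3 <- extractPathways(net3, "R1", c("T1", "T2"))
  expect_identical(unique(ps3@tf), "T1")
  # symbols absent from the network are ignored, not an error
  ps4 <- extractPathways(net, c("R1", "NOPE"), "T1")
  expect_identical(pathwayCount(ps4), 1L)
})

test_that("signaling network keeps only pathway-used links in the LCC", {
  # A-C lies on no shortest path (detour via B is cheaper)
  net <- toyNetwork(c("A", "B", "A"), c("B", "C", "C"),
                    distance = c(0.1, 0.1, 0.3))
  ps <- extractPathways(net, "A", "C")
  sn <- buildSignalingNetwork(net, ps)
  lt <- linkTable(sn)
  expect_identical(nrow(lt), 2L)
  expect_false(any(lt$geneA == "A" & lt$geneB == "C"))
  # every link used -> network unchanged
  net2 <- toyNetwork(c("A", "B"), c("B", "C"), distance = c(0.1, 0.1))
  sn2 <- buildSignalingNetwork(net2, extractPathways(net2, "A", "C"))
  expect_identical(nrow(linkTable(sn2)), 2L)
})

test_that("largest component survives pruning and frequencies follow", {
  # two disjoint clusters; pathways exist inside both; 3-node beats 2-node
  net <- toyNetwork(c("A", "B", "X"), c("B", "C", "Y"),
                    distance = c(0.2, 0.2, 0.2))
  ps <- extractPathways(net, c("A", "X"), c("C", "Y"))
  sn <- buildSignalingNetwork(net, ps)
  expect_identical(nodeNames(sn), c("A", "B", "C"))
  # pathways through the dropped component are gone
  expect_identical(pathwayCount(sn), 1L)
  # frequency bookkeeping: sum of link usages equals sum of surviving hops
  expect_identical(sum(linkFrequencies(sn)$freq), sum(sn@pathways@hops))
})

test_that("link frequency sums match pathway hops on random networks", {
  withr::with_seed(17, {
    for (rep in 1:10) {
      links <- randomWeightedGraph(9)
      net <- toyNetwork(links$geneA, links$geneB, rho = links$rho)
      nodes <- nodeNames(net)
      recs <- sample(nodes, 2L)
      tfs <- sample(setdiff(nodes, recs), 2L)
      ps <- extractPathways(net, recs, tfs)
      sn <- buildSignalingNetwork(net, ps)
      expect_identical(sum(linkFrequencies(sn)$freq), sum(sn@pathways@hops))
      expect_true(all(linkFrequencies(sn)$freq >= 1L))
      expect_true(all(nodeFrequencies(sn) >= 1L))
    }
  })
})

test_that("uniform link distances reduce pathways to unweighted BFS routes", {
  withr::with_seed(23, {
    links <- randomWeightedGraph(10)
    net <- toyNetwork(links$geneA, links$geneB,
                      distance = rep(0.5, nrow(links)))
    g <- igraph::graph_from_data_frame(links[, 1:2], directed = FALSE)
    nodes <- nodeNames(net)
    ps <- extractPathways(net, nodes[1:2], nodes[3:4])
    hopdist <- igraph::distances(g, weights = NA)
    for (i in seq_len(pathwayCount(ps))) {
      expect_identical(ps@hops[i],
                       as.integer(hopdist[ps@receptor[i], ps@tf[i]]))
    }
  })
})
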