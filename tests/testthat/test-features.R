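test_that("link and node frequencies count pathway membership", {
  ps <- toyPathwaySet(list(c("A", "B", "C"), c("D", "B", "C")))
  fr <- linkNodeFrequencies(ps)
  lf <- fr$linkFreq
  expect_identical(lf$freq[lf$geneA == "B" & lf$geneB == "C"], 2L)
  expect_identical(lf$freq[lf$geneA == "A" & lf$geneB == "B"], 1L)
  expect_identical(lf$freq[lf$geneA == "B" & lf$geneB == "D"], 1L)
  expect_equal(fr$avgLinkFreq, 4 / 3)
  # endpoints count as used
  expect_identical(unname(fr$nodeFreq["A"]), 1L)
  expect_identical(unname(fr$nodeFreq["B"]), 2L)
  # nodes on no pathway are absent
  expect_false("Z" %in% names(fr$nodeFreq))
})

test_that("average path length is the mean hop count", {
  expect_equal(averagePathLength(toyPathwaySet(
    list(c("A", "B", "C"), c("D", "E", "F", "G")))), 2.5)
  expect_equal(averagePathLength(toyPathwaySet(
    list(c("A", "B", "C", "D", "E")))), 4.0)
})

test_that("entropy matches closed forms and is maximal at uniformity", {
  expect_equal(shannonEntropy(rep(3, 8)), 3.0)
  expect_equal(shannonEntropy(c(2, 1, 1)), 1.5)
  expect_equal(shannonEntropy(5), 0.0)
  withr::with_seed(9, {
    f <- sample(1:50, 12, replace = TRUE)
    expect_lt(shannonEntropy(f), log2(12))
    expect_equal(shannonEntropy(rep(7, 12)), log2(12))
    # merging two links' counts never increases entropy
    merged <- c(f[1] + f[2], f[-(1:2)])
    expect_lte(shannonEntropy(merged), shannonEntropy(f))
  })
  expect_error(shannonEntropy(c(1, 0)), "positive")
})

test_that("clustering coefficient is the realized neighbor-link fraction", {
  # wheel: hub H plus 4 fully-connected neighbors -> C(H) = 1
  nb <- c("a", "b", "c", "d")
  pairs <- t(combn(nb, 2))
  wheel <- toyNetwork(c(rep("H", 4), pairs[, 1]), c(nb, pairs[, 2]),
                      distance = rep(0.5, 10))
  expect_equal(unname(clusteringCoefficient(wheel, "H")), 1.0)
  # star center: no neighbor links
  star <- toyNetwork(rep("H", 4), nb, distance = rep(0.5, 4))
  expect_equal(unname(clusteringCoefficient(star, "H")), 0.0)
  expect_identical(countClusteringPositive(star), 0L)
  # k = 3 with a single neighbor link -> 1/3
  g13 <- toyNetwork(c("H", "H", "H", "a"), c("a", "b", "c", "b"),
                    distance = rep(0.5, 4))
  expect_equal(unname(clusteringCoefficient(g13, "H")), 1 / 3)
  # triangle plus pendant: three positive nodes, pendant and leaf at zero
  tri <- toyNetwork(c("A", "B", "C", "C"), c("B", "C", "A", "P"),
                    distance = rep(0.5, 4))
  expect_identical(countClusteringPositive(tri), 3L)
  expect_error(clusteringCoefficient(tri, "Q"), "unknown")
})

test_that("power-law exponent MLE matches its closed form", {
  expect_equal(estimatePowerlawExponent(rep(exp(1), 50), fmin = 1), 2.0)
  expect_error(estimatePowerlawExponent(rep(4, 50)), "all frequencies equal")
  expect_error(estimatePowerlawExponent(1:5), "at least 10")
  # discrete half-step variant shifts the denominator
  f <- c(1, 1, 2, 3, 4, 5, 8, 13, 21, 34)
  a_cont <- estimatePowerlawExponent(f)
  a_disc <- estimatePowerlawExponent(f, variant = "discrete")
  expect_equal(a_cont, 1 + 10 / sum(log(f / 1)))
  expect_equal(a_disc, 1 + 10 / sum(log(f / 0.5)))
  fit <- estimatePowerlawExponent(f, fit = TRUE)
  expect_named(fit, c("alpha", "intercept"))
})

test_that("exponent estimates are consistent on seeded draws", {
  withr::with_seed(31, {
    draws <- oraclePowerlawDraws(20000, alpha = 1.6)
    expect_equal(estimatePowerlawExponent(draws), 1.6, tolerance = 0.05)
    # bias shrinks with n
    small <- abs(estimatePowerlawExponent(oraclePowerlawDraws(500, 2.2)) - 2.2)
    large <- abs(estimatePowerlawExponent(oraclePowerlawDraws(50000, 2.2)) - 2.2)
    expect_lt(large, small + 0.02)
  })
})

test_that("diameter is the mean hop distance over reachable pairs", {
  k5 <- t(combn(paste0("n", 1:5), 2))
  complete <- toyNetwork(k5[, 1], k5[, 2], distance = rep(0.5, 10))
  expect_equal(networkDiameter(complete), 1.0)
  path3 <- toyNetwork(c("A", "B"), c("B", "C"), distance = c(0.1, 0.9))
  expect_equal(networkDiameter(path3), 4 / 3)
  withr::with_seed(13, {
    for (rep in 1:10) {
      links <- randomWeightedGraph(10)
      net <- toyNetwork(links$geneA, links$geneB, rho = links$rho)
      g <- igraph::graph_from_data_frame(links[, 1:2], directed = FALSE)
      d <- igraph::distances(g, weights = NA)
      expect_equal(networkDiameter(net), mean(d[upper.tri(d)][
        is.finite(d[upper.tri(d)])]))
    }
  })
})

test_that("hub removal ratio recomputes the diameter without the top hubs", {
  k5 <- t(combn(paste0("n", 1:5), 2))
  complete <- toyNetwork(k5[, 1], k5[, 2], distance = rep(0.5, 10))
  freq <- structure(5:1, names = paste0("n", 1:5))
  expect_equal(hubRemovalRobustness(complete, freq, fraction = 0.3), 1.0)
  # fraction so small that floor() = 0 still removes exactly one node
  expect_equal(hubRemovalRobustness(complete, freq, fraction = 0.01), 1.0)

  # articulation hub: two triangles joined at H; oracle recomputation
  net <- toyNetwork(c("A", "B", "A", "C", "D", "C"),
                    c("B", "H", "H", "D", "H", "H"),
                    distance = rep(0.5, 6))
  freq2 <- structure(c(1, 1, 1, 1, 9), names = c("A", "B", "C", "D", "H"))
  before <- networkDiameter(net)
  g <- asIgraph(net)
  after <- networkDiameter(igraph::induced_subgraph(g, c("A", "B")))
  expect_equal(hubRemovalRobustness(net, freq2, fraction = 0.2),
               after / before)
  expect_error(hubRemovalRobustness(net, freq2, fraction = 1.2), "fraction")
})

test_that("networkFeatures assembles the full panel coherently", {
  withr::with_seed(77, {
    links <- randomWeightedGraph(10, nMin = 10)
    net <- toyNetwork(links$geneA, links$geneB, rho = links$rho)
    nodes <- nodeNames(net)
    ps <- extractPathways(net, nodes[1:3], nodes[8:10])
    sn <- buildSignalingNetwork(net, ps)
  })
  fv <- networkFeatures(sn)
  expect_identical(nrow(fv), 1L)
  expect_equal(fv$path_length, averagePathLength(sn@pathways))
  expect_equal(fv$entropy, shannonEntropy(linkFrequencies(sn)$freq))
  expect_true(fv$entropy <= log2(fv$n_links) + 1e-12)
  expect_true(fv$clustering >= 0 && fv$clustering <= 1)
  expect_equal(fv$link_frequency * fv$n_links, sum(sn@pathways@hops))
})
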