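test_that("cancer hubs are the per-cohort top-k of the shared intersection", {
  fN <- structure(c(10, 9, 8, 1, 2), names = c("a", "b", "c", "d", "e"))
  fT <- structure(c(1, 2, 10, 9, 8), names = c("a", "b", "c", "d", "e"))
  cancer <- c("a", "b", "c", "d", "e")
  # hand-ranked: normal top-2 = {a, b}; tumor top-2 = {c, d}
  expect_identical(selectCancerHubs(fN, fT, cancer, k = 2),
                   c("a", "b", "c", "d"))
  # identical rankings collapse to k genes
  expect_identical(selectCancerHubs(fN, fN, cancer, k = 2), c("a", "b"))
  # frequency ties break lexicographically
  fTie <- structure(c(5, 5, 5), names = c("z", "y", "x"))
  expect_identical(selectCancerHubs(fTie, fTie, c("x", "y", "z"), k = 2),
                   c("x", "y"))
  # genes absent from a network never qualify
  expect_identical(selectCancerHubs(fN[1:3], fT, cancer, k = 5),
                   c("a", "b", "c"))
  expect_warning(out <- selectCancerHubs(fN, fT, "none_such"), "no cancer")
  expect_length(out, 0L)
})

test_that("shared triangles require all three links in both cohorts", {
  # triangle H-A-B (same topology in both cohorts, different weights)
  gA <- c("A", "A", "B")
  gB <- c("H", "B", "H")
  sN <- toyNetwork(gA, gB, rho = c(0.8, 0.7, 0.6))
  sT <- toyNetwork(gA, gB, rho = c(0.8, 0.1, 0.6))
  tri <- enumerateSharedTriangles(sN, sT, "H")
  expect_identical(nrow(tri), 1L)
  expect_identical(tri$hub, "H")
  expect_identical(c(tri$n1, tri$n2), c("A", "B"))
  expect_equal(tri$rho_n12_N, 0.7)   # n1-n2 is A-B
  expect_equal(tri$rho_n12_T, 0.1)
  # link missing from one cohort's network excludes the triangle
  sT2 <- toyNetwork(c("A", "B"), c("H", "H"), rho = c(0.8, 0.6))
  expect_identical(nrow(enumerateSharedTriangles(sN, sT2, "H")), 0L)
  # a triangle with hubs at two corners yields one record per hub
  tri2 <- enumerateSharedTriangles(sN, sT, c("H", "A"))
  expect_identical(nrow(tri2), 2L)
  expect_identical(sort(tri2$hub), c("A", "H"))
})

triRow <- function(rhoN, rhoT) {
  tri <- data.frame(hub = "H", n1 = "A", n2 = "B",
                    rho_h1_N = rhoN[1], rho_h1_T = rhoT[1],
                    rho_h2_N = rhoN[2], rho_h2_T = rhoT[2],
                    rho_n12_N = rhoN[3], rho_n12_T = rhoT[3])
  for (link in c("h1", "h2", "n12")) for (co in c("N", "T")) {
    tri[[paste0("cat_", link, "_", co)]] <-
      correlationCategory(tri[[paste0("rho_", link, "_", co)]])
  }
  tri
}

test_that("integration motif needs all-high links in the counted cohort", {
  expect_identical(countIntegrationMotifs(
    triRow(c(0.8, 0.7, 0.6), c(0.8, 0.1, 0.6))), c(normal = 1L, tumor = 0L))
  expect_identical(countIntegrationMotifs(
    triRow(c(0.8, 0.8, 0.4), c(0.8, 0.8, 0.4))), c(normal = 0L, tumor = 0L))
  expect_identical(countIntegrationMotifs(
    triRow(c(0.8, 0.7, 0.6), c(0.9, 0.6, 0.55))), c(normal = 1L, tumor = 1L))
  empty <- data.frame(hub = character(0))
  expect_identical(countIntegrationMotifs(empty), c(normal = 0L, tumor = 0L))
})

test_that("maintenance motif tracks hub de-correlation with stable vicinity", {
  # hub high in normal, none in tumor, n1-n2 stays low -> tumor count
  expect_identical(countMaintenanceMotifs(
    triRow(c(0.8, 0.7, 0.4), c(0.1, 0.2, 0.35))), c(normal = 0L, tumor = 1L))
  # n1-n2 category changes -> no motif
  expect_identical(countMaintenanceMotifs(
    triRow(c(0.8, 0.7, 0.4), c(0.1, 0.2, 0.55))), c(normal = 0L, tumor = 0L))
  # hub links fall only to "low" -> no motif
  expect_identical(countMaintenanceMotifs(
    triRow(c(0.8, 0.7, 0.4), c(0.4, 0.2, 0.35))), c(normal = 0L, tumor = 0L))
  # mirror image attributes to normal
  expect_identical(countMaintenanceMotifs(
    triRow(c(0.1, 0.2, 0.35), c(0.8, 0.7, 0.4))), c(normal = 1L, tumor = 0L))
})

test_that("comparative motif compares shared links per receptor pair", {
  pN <- toyPathwaySet(list(c("R1", "X", "T"), c("R2", "X", "T")))
  pT <- toyPathwaySet(list(c("R1", "A", "T"), c("R2", "B", "T")))
  expect_identical(countComparativeMotifs(pN, pT),
                   c(normal = 1L, tumor = 0L))
  # identical pathway sets share in both cohorts -> neither counts
  expect_identical(countComparativeMotifs(pN, pN),
                   c(normal = 0L, tumor = 0L))
  # a pair missing one of the four pathways is skipped
  pT2 <- toyPathwaySet(list(c("R1", "A", "T")))
  expect_identical(countComparativeMotifs(pN, pT2),
                   c(normal = 0L, tumor = 0L))
  # swapping cohorts swaps the counts
  expect_identical(unname(countComparativeMotifs(pT, pN)),
                   unname(rev(countComparativeMotifs(pN, pT))))
})

test_that("triangle and comparative counters match brute-force enumeration", {
  withr::with_seed(57, {
    for (rep in 1:5) {
      mk <- function() {
        links <- randomWeightedGraph(12, pEdge = 0.35, nMin = 12)
        net <- toyNetwork(links$geneA, links$geneB, rho = links$rho)
        nodes <- nodeNames(net)
        ps <- extractPathways(net, nodes[1:4], nodes[7:10])
        buildSignalingNetwork(net, ps)
      }
      sN <- mk(); sT <- mk()
      hubs <- sample(union(nodeNames(sN), nodeNames(sT)), 3L)
      tri <- enumerateSharedTriangles(sN, sT, hubs)
      expect_identical(nrow(tri),
                       oracleTriangleCount(linkTable(sN), linkTable(sT),
                                           intersect(hubs, nodeNames(sN))))
      expect_identical(countComparativeMotifs(sN@pathways, sT@pathways),
                       oracleComparative(sN@pathways, sT@pathways))
      # cohort-swap symmetry across all three motifs
      expect_identical(unname(countIntegrationMotifs(tri)),
                       rev(unname(countIntegrationMotifs(
                         enumerateSharedTriangles(sT, sN, hubs)))))
      expect_identical(unname(countMaintenanceMotifs(tri)),
                       rev(unname(countMaintenanceMotifs(
                         enumerateSharedTriangles(sT, sN, hubs)))))
      expect_lte(sum(countIntegrationMotifs(tri)), 2L * nrow(tri))
    }
  })
})
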