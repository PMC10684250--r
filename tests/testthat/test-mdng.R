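test_that("buildMdng links regulators to shared significant pathways only", {
  ids <- c("P1", "P2")
  dis <- toyTable("disease", c(P1 = 0.001, P2 = 0.01), ids)
  m1 <- toyTable("m1", c(P1 = 0.02, P2 = 0.5), ids)
  d1 <- toyTable("d1", c(P1 = 0.03, P2 = 0.6), ids)
  net <- buildMdng(dis, list(m1 = m1), list(d1 = d1))
  expect_setequal(nodeIds(net), c("d1", "m1", "P1"))
  expect_identical(edgeCount(net), 2L)
  expect_identical(nodeCount(net, "pathway"), 1L)
  expect_true(validObject(net))
})

test_that("pathways lacking either regulator class are pruned", {
  ids <- c("P1", "P2")
  dis <- toyTable("disease", c(P1 = 0.001, P2 = 0.001), ids)
  m1 <- toyTable("m1", c(P1 = 0.02, P2 = 0.02), ids)   # both pathways
  d1 <- toyTable("d1", c(P1 = 0.03, P2 = 0.6), ids)    # P1 only
  net <- buildMdng(dis, list(m1 = m1), list(d1 = d1))
  expect_identical(nodeIds(net, "pathway"), "P1")      # P2 drug-less
  partial <- buildMdng(dis, list(m1 = m1), list(d1 = d1), keepPartial = TRUE)
  expect_setequal(nodeIds(partial, "pathway"), c("P1", "P2"))
})

test_that("no shared pathway yields an empty network with a warning", {
  ids <- c("P1", "P2")
  dis <- toyTable("disease", c(P1 = 0.001), ids)
  m1 <- toyTable("m1", c(P2 = 0.02), ids)
  expect_warning(net <- buildMdng(dis, list(m1 = m1), list()), "empty network")
  expect_identical(nodeCount(net), 0L)
})

test_that("node count is the sum of the class partition", {
  ids <- c("P1", "P2")
  dis <- toyTable("disease", c(P1 = 0.001, P2 = 0.01), ids)
  mir <- lapply(sprintf("m%d", 1:3), function(m)
    toyTable(m, c(P1 = 0.01, P2 = 0.02), ids))
  names(mir) <- sprintf("m%d", 1:3)
  drg <- lapply(sprintf("d%d", 1:4), function(d)
    toyTable(d, c(P1 = 0.01, P2 = 0.02), ids))
  names(drg) <- sprintf("d%d", 1:4)
  net <- buildMdng(dis, mir, drg)
  expect_identical(nodeCount(net),
                   nodeCount(net, "pathway") + nodeCount(net, "miRNA") +
                   nodeCount(net, "drug"))
  expect_identical(nodeCount(net), 2L + 3L + 4L)
})

test_that("degree distributions count nodes by degree", {
  star <- igraph::make_star(4, mode = "undirected")
  expect_identical(degreeDistribution(star), c(`1` = 3L, `3` = 1L))

  net <- Mdng(data.frame(regulator = c("m1", "d1"), class = c("miRNA", "drug"),
                         pathway = "P1"))
  expect_identical(degreeDistribution(net), c(`1` = 2L, `2` = 1L))
  expect_identical(degreeDistribution(net, nodeClass = "pathway"),
                   c(`2` = 1L))
  expect_error(degreeDistribution(Mdng(data.frame(regulator = character(),
                                                  class = character(),
                                                  pathway = character()))),
               "empty graph")

  set.seed(21)
  for (i in 1:100) {
    g <- igraph::sample_gnp(sample(3:30, 1), stats::runif(1, 0.1, 0.9))
    expect_identical(sum(degreeDistribution(g)),
                     as.integer(igraph::vcount(g)))
  }
})

test_that("power-law fits recover noiseless parameters and scale correctly", {
  dist <- stats::setNames(2 / (1:10), 1:10)
  fit <- fitPowerLaw(dist)
  expect_equal(fit@a, 2, tolerance = 1e-9)
  expect_equal(fit@b, -1, tolerance = 1e-9)
  expect_equal(fit@rSquared, 1, tolerance = 1e-9)
  expect_identical(fit@nPoints, 10L)

  scaled <- fitPowerLaw(dist * 7)
  expect_equal(scaled@a, 7 * fit@a, tolerance = 1e-9)
  expect_equal(scaled@b, fit@b, tolerance = 1e-9)

  expect_error(fitPowerLaw(c(`3` = 5)), "at least 2")
  flat <- fitPowerLaw(c(`1` = 4, `2` = 4, `3` = 4))
  expect_equal(flat@b, 0, tolerance = 1e-12)
})

test_that("topological coefficient matches hand-checked graphs", {
  k3 <- igraph::make_full_graph(3)
  expect_equal(unname(topologicalCoefficient(k3)), rep(1, 3))
  c4 <- igraph::make_ring(4)
  expect_equal(unname(topologicalCoefficient(c4)), rep(1, 4))
  path2 <- igraph::make_graph(~ a - b, simplify = TRUE)
  expect_true(all(is.na(topologicalCoefficient(path2))))  # degree-1 leaves
  expect_error(topologicalCoefficient(k3, node = "nope"), "unknown node")
})

test_that("topological coefficient matches the pairwise oracle", {
  set.seed(17)
  for (i in 1:100) {
    g <- igraph::sample_gnp(sample(3:8, 1), stats::runif(1, 0.2, 0.9))
    igraph::V(g)$name <- paste0("v", seq_len(igraph::vcount(g)))
    expect_equal(unname(topologicalCoefficient(g)), oracleTC(g),
                 tolerance = 1e-12)
  }
})

test_that("pathway dissection flags genes co-regulated by both classes", {
  gsc <- GeneSetCollection(list(PW = c("G1", "G2", "G3", "G4")))
  mir <- TargetMap(list(m1 = c("G1", "G2"), m2 = "G1"), "miRNA")
  drg <- TargetMap(list(d1 = c("G1", "G3")), "drug")
  dis <- dissectPathway("PW", gsc, c("G1", "G2", "G3", "G9"), mir, drg)
  expect_identical(nrow(dis), 3L)
  expect_identical(dis$co_regulated, c(TRUE, FALSE, FALSE))
  expect_identical(dis$mirnas[dis$gene == "G1"], "m1,m2")
  expect_identical(dis$n_drugs[dis$gene == "G2"], 0L)
  expect_error(dissectPathway("missing", gsc, "G1", mir, drg), "unknown set")
})

test_that("a planted co-regulation fixture yields exactly its planted rows", {
  genes <- sprintf("G%02d", 1:12)
  gsc <- GeneSetCollection(list(PW = genes))
  co <- genes[1:3]
  mir <- TargetMap(list(m1 = c(co, genes[4]), m2 = co[1]), "miRNA")
  drg <- TargetMap(list(d1 = c(co, genes[5])), "drug")
  dis <- dissectPathway("PW", gsc, genes[1:6], mir, drg)
  expect_identical(sum(dis$co_regulated), 3L)
  expect_setequal(dis$gene[dis$co_regulated], co)
})

test_that("networks built from random synthetic studies keep all invariants", {
  set.seed(33)
  for (i in 1:100) {
    study <- generateStudy(synthConfig(
      seed = 9000 + i,
      regulatorSignal = stats::runif(1, 0, 1),
      diseaseSignal = stats::runif(1, 0.3, 1)))
    disTab <- suppressWarnings(enrich(diseaseGenes(study),
      studyPathways(study), studyUniverse(study), entityName = "disease"))
    mirTabs <- suppressWarnings(enrichAll(
      suppressMessages(filterRegulators(mirnaTargets(study))),
      studyPathways(study), studyUniverse(study)))
    drugTabs <- suppressWarnings(enrichAll(
      suppressMessages(filterRegulators(drugTargets(study))),
      studyPathways(study), studyUniverse(study)))
    net <- suppressWarnings(buildMdng(disTab, mirTabs, drugTabs))
    expect_true(validObject(net))   # tripartite structure, no orphan nodes
    g <- mdngGraph(net)
    if (igraph::ecount(g)) {
      ends <- igraph::ends(g, igraph::E(g), names = FALSE)
      cls <- igraph::V(g)$class
      expect_true(all((cls[ends[, 1]] == "pathway") !=
                      (cls[ends[, 2]] == "pathway")))
      expect_false(igraph::any_multiple(g))
    }
  }
})
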