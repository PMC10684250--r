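test_that("association score uses the best shared significant pathway", {
  ids <- paste0("P", 1:3)
  dis <- toyTable("disease", c(P1 = 1e-3, P2 = 1e-4, P3 = 0.5), ids)
  drg <- toyTable("d", c(P1 = 1e-2, P2 = 1e-4, P3 = 0.01), ids)
  sc <- associationScore(dis, drg)
  expect_identical(sc$bestPathway, "P2")     # product 1e-8 beats 1e-5
  expect_equal(sc$S, 8, tolerance = 1e-12)

  solo <- associationScore(toyTable("disease", c(P1 = 1e-3), ids),
                           toyTable("d", c(P1 = 1e-2), ids))
  expect_equal(solo$S, 5, tolerance = 1e-12)

  none <- associationScore(toyTable("disease", c(P1 = 1e-3), ids),
                           toyTable("d", c(P2 = 1e-3), ids))
  expect_null(none)

  expect_error(associationScore(dis, drg, alpha = 2), "alpha")
  # product ties resolve to the lexicographically smallest pathway
  tie <- associationScore(toyTable("disease", c(P1 = 1e-3, P2 = 1e-3), ids),
                          toyTable("d", c(P1 = 1e-2, P2 = 1e-2), ids))
  expect_identical(tie$bestPathway, "P1")
})

test_that("profile permutation preserves the p-value multiset", {
  ids <- paste0("P", 1:6)
  dis <- toyTable("disease", c(P1 = 1e-4, P2 = 1e-3, P3 = 0.2), ids)
  same <- permuteDiseaseProfile(dis, perm = seq_along(ids))
  expect_identical(enrichResults(same), enrichResults(dis))

  set.seed(5)
  for (i in 1:20) {
    perm <- sample.int(length(ids))
    shuf <- permuteDiseaseProfile(dis, perm = perm)
    expect_setequal(enrichResults(shuf)$p_raw, enrichResults(dis)$p_raw)
    expect_true(all(enrichResults(shuf)$pathway %in% ids))
  }
})

test_that("permuted p-values land uniformly across labels", {
  ids <- paste0("P", sprintf("%02d", 1:10))
  p <- stats::setNames(c(1e-5, 10^-(4:1), 0.2, 0.3, 0.4, 0.5, 0.6), ids)
  dis <- toyTable("disease", p, ids)
  counts <- stats::setNames(rep(0L, 10), ids)
  set.seed(123)
  for (i in 1:10000) {
    shuf <- enrichResults(permuteDiseaseProfile(dis))
    lab <- shuf$pathway[shuf$p_raw == 1e-5]
    counts[lab] <- counts[lab] + 1L
  }
  expect_gt(stats::chisq.test(counts)$p.value, 0.001)
})

test_that("permutation null statistics follow hand arithmetic", {
  # two labels, drug significant on P1 only: identity permutation scores
  # -log10(0.01 * 0.1) = 3, the swap scores -log10(0.001 * 0.1) = 4
  ids <- c("P1", "P2")
  dis <- toyTable("disease", c(P1 = 1e-2, P2 = 1e-3), ids)
  drg <- toyTable("d", c(P1 = 1e-1), ids, alpha = 0.2)
  nul <- permutationNull(dis, drg, permMatrix = rbind(1:2, 2:1))
  expect_setequal(nul$sRandom, c(3, 4))
  expect_equal(nul$mean, 3.5)
  expect_equal(nul$sd, stats::sd(c(3, 4)))   # n-1 denominator
  expect_identical(nul$nUndefined, 0L)

  # generic mean/sd contract on the spec's toy numbers
  expect_equal(stats::sd(c(1, 3)), sqrt(2))
})

test_that("a fully symmetric profile collapses the null to sd = 0", {
  ids <- paste0("P", 1:4)
  dis <- toyTable("disease", stats::setNames(rep(1e-3, 4), ids), ids)
  drg <- toyTable("d", stats::setNames(rep(1e-2, 4), ids), ids)
  nul <- permutationNull(dis, drg, nPerm = 50, seed = 1)
  expect_equal(nul$sd, 0)
  expect_identical(nul$nUndefined, 0L)
  S <- associationScore(dis, drg)$S
  expect_true(is.na(zScore(S, nul)))         # degenerate null: Z undefined
})

test_that("permutation nulls are reproducible under a fixed seed", {
  ids <- paste0("P", 1:8)
  set.seed(2)
  dis <- toyTable("disease", stats::setNames(10^-stats::runif(8, 0, 5), ids), ids)
  drg <- toyTable("d", stats::setNames(10^-stats::runif(8, 0, 4), ids), ids)
  n1 <- permutationNull(dis, drg, nPerm = 200, seed = 77)
  n2 <- permutationNull(dis, drg, nPerm = 200, seed = 77)
  expect_identical(n1, n2)
})

test_that("undefined permutations are dropped and counted", {
  ids <- paste0("P", 1:5)
  dis <- toyTable("disease", c(P1 = 1e-4, P2 = 0.5, P3 = 0.5, P4 = 0.5,
                               P5 = 0.5), ids)
  drg <- toyTable("d", c(P1 = 1e-3), ids)
  perms <- t(vapply(1:100, function(i) sample.int(5), integer(5)))
  nul <- permutationNull(dis, drg, permMatrix = perms)
  hits <- sum(perms[, 1] == 1)   # significant disease row lands on P1
  expect_identical(length(nul$sRandom), hits)
  expect_identical(nul$nUndefined, 100L - hits)
})

test_that("z-scores standardise against the permutation null", {
  nul <- structure(list(drugId = "d", nPerm = 2L, sRandom = c(1, 3),
                        mean = 2, sd = sqrt(2), nUndefined = 0L,
                        seed = NA_integer_), class = "permutationNull")
  expect_equal(zScore(2, nul), 0)
  expect_equal(zScore(4, nul), sqrt(2), tolerance = 1e-12)
  expect_true(is.na(zScore(NA, nul)))
  nul$sd <- 0
  expect_true(is.na(zScore(4, nul)))
})

test_that("screening applies a strict cutoff and deterministic ranking", {
  scores <- data.frame(drug_id = c("b", "a", "c"), S = c(5, 4, 3),
                       Z = c(2.5, 1.96, 1.0), stringsAsFactors = FALSE)
  out <- screenDrugs(scores)
  expect_identical(sum(out$passed), 1L)      # 1.96 itself does not pass
  expect_identical(out$drug_id, c("b", "a", "c"))
  expect_identical(out$rank, 1:3)

  allNA <- screenDrugs(data.frame(drug_id = c("x", "y"), S = NA_real_,
                                  Z = NA_real_))
  expect_identical(sum(allNA$passed), 0L)
  expect_identical(allNA$drug_id, c("x", "y"))  # NA ties break by id

  ties <- screenDrugs(data.frame(drug_id = c("z", "a"), S = 1, Z = 2.2))
  expect_identical(ties$drug_id, c("a", "z"))
  expect_error(screenDrugs(scores, cutoff = -1), "cutoff")
})

test_that("S is exactly invariant under consistent pathway relabeling", {
  ids <- paste0("P", 1:6)
  set.seed(8)
  pd <- stats::setNames(10^-stats::runif(6, 0, 6), ids)
  pq <- stats::setNames(10^-stats::runif(6, 0, 4), ids)
  s0 <- associationScore(toyTable("disease", pd, ids), toyTable("d", pq, ids))
  relabel <- stats::setNames(paste0("Q", sample(6)), ids)
  ids2 <- sort(unname(relabel))
  pd2 <- stats::setNames(pd, relabel[names(pd)])
  pq2 <- stats::setNames(pq, relabel[names(pq)])
  s1 <- associationScore(toyTable("disease", pd2, ids2),
                         toyTable("d", pq2, ids2))
  expect_equal(s1$S, s0$S, tolerance = 1e-12)
  expect_identical(s1$bestPathway, unname(relabel[s0$bestPathway]))
})

test_that("the screen report is complete, consistent and seed-stable", {
  study <- generateStudy(synthConfig(seed = 7))
  f1 <- tempfile(); f2 <- tempfile()
  r1 <- suppressMessages(suppressWarnings(
    runScreen(study, nPerm = 200, seed = 7, out = f1)))
  r2 <- suppressMessages(suppressWarnings(
    runScreen(study, nPerm = 200, seed = 7, out = f2)))
  retained <- suppressMessages(filterRegulators(drugTargets(study)))
  expect_identical(nrow(r1), length(retained))
  expect_identical(readLines(f1), readLines(f2))    # byte-identical rerun
  expect_identical(r1$passed, !is.na(r1$Z) & r1$Z > 1.96)
  expect_identical(r1$rank, seq_len(nrow(r1)))
})

test_that("Z stabilises as the number of permutations grows", {
  study <- generateStudy(synthConfig(seed = 19))
  r1k <- suppressMessages(suppressWarnings(
    runScreen(study, nPerm = 1000, seed = 101)))
  r10k <- suppressMessages(suppressWarnings(
    runScreen(study, nPerm = 10000, seed = 202)))
  both <- merge(r1k[!is.na(r1k$Z), c("drug_id", "Z")],
                r10k[, c("drug_id", "Z")], by = "drug_id")
  expect_gt(nrow(both), 0)
  # Monte-Carlo standard error of a permutation Z at B = 1000
  se <- sqrt((1 + both$Z.x^2 / 2) / 1000)
  expect_true(all(abs(both$Z.x - both$Z.y) < 3 * se + 1e-8))
})

test_that("mean responsive-drug Z rises with the planted signal", {
  signals <- c(0, 0.3, 0.6, 0.9)
  meanZ <- vapply(signals, function(rs) {
    mean(vapply(1:20, function(s) {
      study <- generateStudy(synthConfig(seed = 700 + s,
                                         regulatorSignal = rs))
      rep <- suppressMessages(suppressWarnings(
        runScreen(study, nPerm = 500, seed = 700 + s)))
      z <- rep$Z[rep$drug_id %in% studyTruth(study)$responsiveDrugIds]
      mean(ifelse(is.na(z), 0, z))   # no shared pathway = no association
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(meanZ) > 0))
})
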