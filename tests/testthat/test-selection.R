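## Bayesian score algebra, PCA + clustering, candidate construction.

test_that("recall scaling hits its boundary and midpoint values", {
  expect_equal(scaleRecall(0.9, 0.5, 0.9), 1.0)
  expect_equal(scaleRecall(0.5, 0.5, 0.9), 0.0)
  expect_equal(scaleRecall(0.7, 0.5, 0.9), 0.5)
  expect_error(scaleRecall(0.4, 0.5, 0.9), "outside")
  expect_warning(v <- scaleRecall(c(0.6, 0.6), 0.6, 0.6), "uninformative")
  expect_equal(v, c(0.5, 0.5))
})

test_that("NOE posterior follows sqrt(P * pTM)", {
  expect_equal(pModelGivenNoe(1, 1), 1.0)
  expect_equal(pModelGivenNoe(0, 0.7), 0.0)
  expect_equal(pModelGivenNoe(0.5, 0.8), sqrt(0.40))
  expect_error(pModelGivenNoe(1.2, 0.5), "\\[0, 1\\]")
  expect_error(pModelGivenNoe(0.5, -0.1), "\\[0, 1\\]")
})

rciForScore <- function(rciVals) {
  n <- length(rciVals)
  p <- data.frame(chain = "A", resno = seq_len(n), resname = "ALA",
                  coverage = 6L, raw = rciVals, capped = rciVals,
                  rci = rciVals, rci06 = rciVals / 0.6)
  new("RciProfile", profile = p,
      coeffs = defaultRciCoeffs())
}

test_that("RCI posterior: anti-monotone profile, zero SCC, degenerate pLDDT", {
  rci <- rciForScore(seq(0.05, 0.5, length.out = 10))
  ## pLDDT strictly anti-monotone with RCI, mean 81 -> sqrt(1 x 0.81) = 0.9
  plddt <- stats::setNames(seq(94.5, 67.5, length.out = 10),
                           paste0("A:", 1:10))
  expect_equal(mean(plddt) / 100, 0.81)
  expect_equal(pModelGivenRci(plddt, rci), 0.9, tolerance = 1e-12)
  ## the two variant readings of the RCI posterior coincide at |SCC| = 1
  expect_equal(pModelGivenRci(plddt, rci, variant = "plddt-sqrt"), 0.9,
               tolerance = 1e-12)

  ## |SCC| = 0: symmetric pLDDT about the centre of a symmetric RCI profile
  rci0 <- rciForScore(c(0.1, 0.2, 0.3, 0.2, 0.1, 0.1, 0.2, 0.3, 0.2, 0.1))
  pl0 <- stats::setNames(c(60, 70, 80, 90, 100, 100, 90, 80, 70, 60),
                         paste0("A:", 1:10))
  expect_lt(abs(spearmanScc(pl0, rciProfile(rci0)$rci)), 1e-9)
  expect_equal(pModelGivenRci(pl0, rci0), 0.0, tolerance = 1e-9)

  ## constant pLDDT -> SCC undefined -> 0 with warning
  plC <- stats::setNames(rep(80, 10), paste0("A:", 1:10))
  expect_warning(v <- pModelGivenRci(plC, rci), "constant pLDDT")
  expect_equal(v, 0)

  ## fewer than 5 overlapping residues -> error
  plddt5 <- plddt[1:4]
  expect_error(pModelGivenRci(plddt5, rci), "at least 5")
})

test_that("combined posterior is the arithmetic mean and stays bounded", {
  expect_equal(pModelGivenNmr(1, 1), 1.0)
  expect_equal(pModelGivenNmr(0.6, 0.4), 0.5)
  expect_equal(pModelGivenNmr(0.3, 0.9), pModelGivenNmr(0.9, 0.3))
  set.seed(1)
  for (i in 1:50) {
    a <- runif(1); b <- runif(1)
    v <- pModelGivenNmr(a, b)
    expect_gte(v, min(a, b)); expect_lte(v, max(a, b))
  }
  expect_error(pModelGivenNmr(1.4, 0.2), "\\[0, 1\\]")
})

test_that("per-model scores stay in [0, 1] and respond monotonically to recall", {
  f <- makeTwoStateEnsemble(fixtureSpec(nResidues = 14, hingeRes = 8,
                                        modelsPerState = 3, seed = 12))
  nmr <- makeSyntheticNmr(f)
  rci <- computeRci(nmr$shifts)
  sc <- scoreModels(f$pooled, nmr$peaks, nmr$shifts, rci)
  for (col in c("pNoeGivenModel", "pModelGivenNoe", "sccAbs", "plddtMean",
                "pModelGivenRci", "pModelGivenNmr"))
    expect_true(all(sc[[col]] >= 0 & sc[[col]] <= 1))
  ## increasing a model's recall (others fixed) never lowers its final score
  i <- 2L
  p1 <- pModelGivenNmr(pModelGivenNoe(
    scaleRecall(sc$recall[i], attr(sc, "recallMin"), attr(sc, "recallMax")),
    sc$ptm[i]), sc$pModelGivenRci[i])
  r2 <- min(sc$recall[i] + 0.02, attr(sc, "recallMax"))
  p2 <- pModelGivenNmr(pModelGivenNoe(
    scaleRecall(r2, attr(sc, "recallMin"), attr(sc, "recallMax")),
    sc$ptm[i]), sc$pModelGivenRci[i])
  expect_gte(p2, p1)
})

test_that("PCA clustering: degenerate ensembles, planted partition, invariances", {
  set.seed(14)
  X <- matrix(rnorm(45, sd = 5), ncol = 3)
  ensSame <- caEnsemble(rep(list(X), 10))
  ca <- pcaCluster(ensSame, k = 1, seed = 1)
  expect_equal(length(unique(clusterLabels(ca))), 1L)
  expect_true(all(ca@varExplained == 0))
  expect_error(pcaCluster(ensSame, k = 2), "identical")
  expect_error(pcaCluster(ensSame, k = 20), "exceeds")

  ## hinged two-group fixture: partition matches construction exactly
  fx <- makeTwoStateEnsemble(fixtureSpec(nResidues = 20, hingeRes = 12,
                                         hingeAngle = 30, modelsPerState = 6,
                                         seed = 14))
  ca2 <- pcaCluster(fx$pooled, k = 2, seed = 1)
  lab <- clusterLabels(ca2)
  tab <- table(fx$trueLabels[names(lab)], lab)
  expect_true((tab[1, 2] == 0 && tab[2, 1] == 0) ||
              (tab[1, 1] == 0 && tab[2, 2] == 0))
  ## explained variance sorted non-increasing
  expect_true(all(diff(ca2@varExplained) <= 1e-12))
  expect_lte(sum(ca2@varExplained), 1)

  ## label partition invariant under model reordering
  perm <- sample(nModels(fx$pooled))
  ens2 <- fx$pooled[perm]
  ca3 <- pcaCluster(ens2, k = 2, seed = 1)
  lab3 <- clusterLabels(ca3)
  expect_true(all(vapply(split(names(lab3), lab3), function(ids)
    length(unique(lab[ids])) == 1L, TRUE)))
  ## fixed inputs -> bit-identical PC coordinates
  ca4 <- pcaCluster(fx$pooled, k = 2, seed = 1)
  expect_identical(ca2@coords, ca4@coords)
})

test_that("candidate ensembles: top-k selection, small clusters, ranking oracle", {
  fx <- makeTwoStateEnsemble(fixtureSpec(nResidues = 14, hingeRes = 8,
                                         modelsPerState = 4, seed = 15))
  nmr <- makeSyntheticNmr(fx)
  rci <- computeRci(nmr$shifts)
  sc <- scoreModels(fx$pooled, nmr$peaks, nmr$shifts, rci)
  ## assignment fixed to the construction labels so cluster sizes are known
  ids <- vapply(models(fx$pooled), function(m) m@modelId, 0L)
  lab <- stats::setNames(as.integer(fx$trueLabels[as.character(ids)]), ids)
  ca <- new("ClusterAssignment",
            coords = matrix(0, length(ids), 3), varExplained = rep(0, 3),
            labels = lab, populations = c(0.5, 0.5), linkage = "ward.D2",
            k = 2L, seed = 1L)
  warns <- capture_warnings(
    cands <- buildCandidateEnsembles(ca, sc, fx$pooled, kTop = 5))
  expect_length(warns, 2L)            # one per undersized cluster
  expect_match(warns, "only 4", all = TRUE)
  expect_length(cands, 2L)
  expect_equal(vapply(cands, function(c_) length(c_$modelIds), 0L), c(4L, 4L))
  ## ranking equals a brute-force sort of per-cluster mean scores
  bruteMeans <- sort(vapply(split(as.integer(names(lab)), lab), function(ids) {
    sub <- sc[sc$modelId %in% ids, ]
    mean(sort(sub$pModelGivenNmr, decreasing = TRUE)[1:min(5, nrow(sub))])
  }, 0), decreasing = TRUE)
  expect_equal(unname(vapply(cands, `[[`, 0, "meanScore")),
               unname(bruteMeans), tolerance = 1e-12)
  expect_equal(cands[[1]]$label, "alpha4")
  expect_equal(cands[[2]]$label, "beta4")

  ## single cluster -> single candidate with its top models
  ca1 <- pcaCluster(fx$pooled, k = 1, seed = 1)
  cands1 <- buildCandidateEnsembles(ca1, sc, fx$pooled, kTop = 5)
  expect_length(cands1, 1L)
  expect_setequal(cands1[[1]]$modelIds,
                  sc$modelId[order(-sc$pModelGivenNmr, -sc$ptm,
                                   sc$modelId)][1:5])
})
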