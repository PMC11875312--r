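## Peak matching, recall/precision, Double Recall, peak simulation.

smallFixture <- function(seed = 2, n = 14, m = 3) {
  fx <- makeTwoStateEnsemble(fixtureSpec(nResidues = n, hingeRes = 8,
                                         modelsPerState = m, seed = seed))
  nmr <- makeSyntheticNmr(fx)
  list(fx = fx, nmr = nmr)
}

test_that("matchPeak: exact coincidence, far peak, degenerate donors", {
  f <- smallFixture()
  s <- shifts(f$nmr$shifts)
  get <- function(rn, at) s$shift[s$resno == rn & s$atom == at]
  pk <- list(wHdonor = get(7, "H"), wX = get(7, "N"), wHacceptor = get(3, "HA"))
  cand <- matchPeak(pk, f$nmr$shifts, spectrumType = "N15-NOESY")
  expect_true(any(cand$donorResno == 7 & cand$donorGroup == "H" &
                  cand$acceptorResno == 3 & cand$acceptorGroup == "HA"))

  far <- list(wHdonor = get(7, "H") + 10, wX = get(7, "N"), wHacceptor = get(3, "HA"))
  expect_equal(nrow(matchPeak(far, f$nmr$shifts, spectrumType = "N15-NOESY")), 0L)

  ## two residues given identical HN/N shifts -> both donors returned
  s2 <- s
  s2$shift[s2$resno == 9 & s2$atom == "H"] <- get(7, "H")
  s2$shift[s2$resno == 9 & s2$atom == "N"] <- get(7, "N")
  st2 <- new("ShiftTable", shifts = s2)
  cand2 <- matchPeak(pk, st2, spectrumType = "N15-NOESY")
  expect_setequal(intersect(cand2$donorResno[cand2$donorGroup == "H"], c(7, 9)),
                  c(7, 9))
  ## exhaustive enumeration oracle for the donor set
  hs <- s2[s2$atom == "H", ]
  ns <- s2[s2$atom == "N", ]
  oracle <- hs$resno[abs(hs$shift - pk$wHdonor) <= 0.05 &
                     abs(ns$shift[match(hs$resno, ns$resno)] - pk$wX) <= 0.5]
  expect_setequal(unique(cand2$donorResno[cand2$donorGroup == "H"]), oracle)
})

test_that("ensemble pair distance: single model, midrange, merged minimum, methyls", {
  ## two CA-only pseudo-protons? use real fixture protons instead
  f <- smallFixture(seed = 3, m = 1)
  ens1 <- f$fx$states[[1]]
  m1 <- models(ens1)[[1]]
  a <- m1@atoms
  g <- function(rn, at) as.numeric(a[a$resno == rn & a$atom == at,
                                     c("x", "y", "z")])
  pair <- list(chain1 = "A", resno1 = 3, atom1 = "H", resname1 = "ALA",
               chain2 = "A", resno2 = 6, atom2 = "H", resname2 = "LEU")
  d <- ensemblePairDistance(ens1, pair)
  expect_equal(d, sqrt(sum((g(3, "H") - g(6, "H"))^2)), tolerance = 1e-12)

  ## methyl group: minimum over the three HB protons
  pairM <- list(chain1 = "A", resno1 = 3, atom1 = "QB", resname1 = "ALA",
                chain2 = "A", resno2 = 6, atom2 = "H", resname2 = "LEU")
  dM <- ensemblePairDistance(ens1, pairM)
  dsM <- vapply(1:3, function(k)
    sqrt(sum((g(3, paste0("HB", k)) - g(6, "H"))^2)), 0)
  expect_equal(dM, min(dsM), tolerance = 1e-12)
})

test_that("midrange and merged-minimum summaries follow their closed forms", {
  ## synthetic two-model ensemble with H-H distances 3 and 7 -> midrange 5
  mk <- function(d, id) {
    atoms <- data.frame(
      chain = "A", resno = c(1, 1, 2, 2), resname = "GLY",
      atom = c("CA", "HA", "CA", "HA"), element = c("C", "H", "C", "H"),
      x = c(0, 0, d, d), y = 0, z = 0, b = 50, stringsAsFactors = FALSE)
    new("ConformerModel", modelId = id, atoms = atoms,
        plddt = c(`A:1` = 50, `A:2` = 50), ptm = NA_real_)
  }
  ens <- new("ConformerEnsemble", label = "t", models = list(mk(3, 1L), mk(7, 2L)))
  pair <- list(chain1 = "A", resno1 = 1, atom1 = "HA", resname1 = "GLY",
               chain2 = "A", resno2 = 2, atom2 = "HA", resname2 = "GLY")
  expect_equal(ensemblePairDistance(ens, pair), 5.0, tolerance = 1e-12)

  ## two states with midranges 5.4 and 4.2 -> merged 4.2
  ensA <- new("ConformerEnsemble", label = "a", models = list(mk(5.4, 1L)))
  ensB <- new("ConformerEnsemble", label = "b", models = list(mk(4.2, 2L)))
  expect_equal(ensemblePairDistance(list(ensA, ensB), pair), 4.2,
               tolerance = 1e-12)
})

test_that("round-trip recall is exactly 1 and merging never hurts", {
  f <- smallFixture(seed = 4)
  repM <- scoreRecall(f$nmr$peaks, f$nmr$shifts, f$fx$states)
  expect_equal(recallScore(repM), 1.0)
  repA <- scoreRecall(f$nmr$peaks, f$nmr$shifts, f$fx$states[[1]])
  repB <- scoreRecall(f$nmr$peaks, f$nmr$shifts, f$fx$states[[2]])
  expect_gte(recallScore(repM), max(recallScore(repA), recallScore(repB)))
  ## merged explained set contains each single-state explained set
  expect_true(all(explainedPeaks(repA) %in% explainedPeaks(repM)))
  expect_true(all(explainedPeaks(repB) %in% explainedPeaks(repM)))
})

test_that("recall counts unmatched and long candidates correctly on a toy", {
  f <- smallFixture(seed = 5, m = 1)
  st <- f$nmr$shifts
  s <- shifts(st)
  get <- function(rn, at) s$shift[s$resno == rn & s$atom == at]
  ens <- f$fx$states[[1]]
  a <- models(ens)[[1]]@atoms
  g <- function(rn, at) as.numeric(a[a$resno == rn & a$atom == at,
                                     c("x", "y", "z")])
  dist <- function(r1, a1, r2, a2) sqrt(sum((g(r1, a1) - g(r2, a2))^2))
  ## three peaks at short pairs, one at a matched but long pair (sequential
  ## neighbours are short in a helix; residues 11 residues apart are long)
  expect_lt(dist(3, "H", 4, "H"), 5)
  expect_lt(dist(5, "H", 6, "H"), 5)
  expect_lt(dist(7, "H", 8, "H"), 5)
  expect_gt(dist(2, "H", 13, "H"), 5)
  mkPeak <- function(r1, r2) sprintf("%.4f\t%.4f\t%.4f", get(r1, "H"),
                                     get(r1, "N"), get(r2, "H"))
  fpk <- withr::local_tempfile(fileext = ".peaks")
  writeLines(c(mkPeak(3, 4), mkPeak(5, 6), mkPeak(7, 8), mkPeak(2, 13)), fpk)
  pl <- readPeakList(fpk, "N15-NOESY")
  rep_ <- scoreRecall(pl, st, ens)
  expect_equal(recallScore(rep_), 0.75)
  expect_equal(sum(peaks(rep_)$status == "unexplained"), 1L)
  ## exhaustive oracle agrees on the explained set
  expect_setequal(explainedPeaks(rep_),
                  bruteExplainedSet(pl, st, ens, matchTolerances()))
})

test_that("explained sets match the brute-force enumerator exactly", {
  for (seed in c(6, 7)) {
    f <- smallFixture(seed = seed, m = 2)
    tol <- matchTolerances()
    repM <- scoreRecall(f$nmr$peaks, f$nmr$shifts, f$fx$states, tol)
    brute <- bruteExplainedSet(f$nmr$peaks, f$nmr$shifts, f$fx$states, tol)
    expect_setequal(explainedPeaks(repM), brute)
    ## single-state reports too
    repA <- scoreRecall(f$nmr$peaks, f$nmr$shifts, f$fx$states[[1]], tol)
    bruteA <- bruteExplainedSet(f$nmr$peaks, f$nmr$shifts,
                                f$fx$states[[1]], tol)
    expect_setequal(explainedPeaks(repA), bruteA)
  }
})

test_that("widening tolerances never decreases recall", {
  f <- smallFixture(seed = 8, m = 2)
  ## jittered peaks so that tolerance actually matters
  fx <- makeTwoStateEnsemble(fixtureSpec(nResidues = 14, hingeRes = 8,
                                         modelsPerState = 2, seed = 8,
                                         peakJitter = 0.04))
  nmr <- makeSyntheticNmr(fx)
  r1 <- recallScore(scoreRecall(nmr$peaks, nmr$shifts, fx$states,
                                matchTolerances(hPpm = 0.02)))
  r2 <- recallScore(scoreRecall(nmr$peaks, nmr$shifts, fx$states,
                                matchTolerances(hPpm = 0.05)))
  r3 <- recallScore(scoreRecall(nmr$peaks, nmr$shifts, fx$states,
                                matchTolerances(hPpm = 0.12)))
  expect_lte(r1, r2); expect_lte(r2, r3)
  expect_true(all(c(r1, r2, r3) >= 0 & c(r1, r2, r3) <= 1))
})

test_that("Double Recall: identical ensembles, planted uniqueness, partition", {
  f <- smallFixture(seed = 9, m = 2)
  tol <- matchTolerances()
  repA <- scoreRecall(f$nmr$peaks, f$nmr$shifts, f$fx$states[[1]], tol)
  repB <- scoreRecall(f$nmr$peaks, f$nmr$shifts, f$fx$states[[2]], tol)

  same <- doubleRecall(repA, repA)
  expect_length(same@uniqueA, 0)
  expect_length(same@uniqueB, 0)

  dr <- doubleRecall(repA, repB, "state1", "state2")
  expect_length(intersect(dr@uniqueA, dr@uniqueB), 0)
  expect_length(intersect(dr@uniqueA, dr@shared), 0)
  expect_setequal(c(dr@uniqueA, dr@uniqueB, dr@shared),
                  union(explainedPeaks(repA), explainedPeaks(repB)))
  expect_setequal(c(dr@uniqueA, dr@shared), explainedPeaks(repA))

  ## long-range subsets respect the |i - j| >= 5 rule
  pkA <- peaks(repA)
  lr <- dr@longRange$uniqueA
  expect_true(all(abs(pkA$donorRes[match(lr, pkA$id)] -
                      pkA$acceptorRes[match(lr, pkA$id)]) >= 5))

  ## mismatched peak universes are rejected
  repC <- scoreRecall(f$nmr$peaks[[1]], f$nmr$shifts, f$fx$states[[1]], tol)
  expect_error(doubleRecall(repA, repC), "identical peak lists")
})

test_that("a peak short in A and long in B is unique to A", {
  mk <- function(d, id) {
    atoms <- data.frame(
      chain = "A", resno = c(1, 1, 1, 7, 7, 7),
      resname = "GLY",
      atom = rep(c("N", "CA", "H"), 2), element = rep(c("N", "C", "H"), 2),
      x = c(0, 1.4, -0.5, d, d + 1.4, d - 0.5), y = 0.2, z = 0, b = 60,
      stringsAsFactors = FALSE)
    new("ConformerModel", modelId = id, atoms = atoms,
        plddt = c(`A:1` = 60, `A:7` = 60), ptm = NA_real_)
  }
  ensA <- new("ConformerEnsemble", label = "A", models = list(mk(4, 1L)))
  ensB <- new("ConformerEnsemble", label = "B", models = list(mk(8, 2L)))
  s <- data.frame(chain = "A", resno = c(1, 1, 7, 7),
                  resname = "GLY", atom = c("H", "N", "H", "N"),
                  isotope = c("1H", "15N", "1H", "15N"),
                  shift = c(8.1, 120, 7.5, 115), stringsAsFactors = FALSE)
  st <- new("ShiftTable", shifts = s)
  fpk <- withr::local_tempfile(fileext = ".peaks")
  writeLines("8.100\t120.000\t7.500", fpk)
  pl <- readPeakList(fpk, "N15-NOESY")
  repA <- scoreRecall(pl, st, ensA)
  repB <- scoreRecall(pl, st, ensB)
  dr <- doubleRecall(repA, repB)
  expect_equal(dr@uniqueA, 1L)
  expect_length(dr@uniqueB, 0)
})

test_that("peak simulation: qualifying pairs, cutoff, round trip, determinism", {
  f <- smallFixture(seed = 10, m = 1)
  ens <- f$fx$states[[1]]
  st <- f$nmr$shifts
  tol <- matchTolerances()
  pl <- simulatePeaks(ens, st, tol, "N15-NOESY", jitter = 0, seed = 42)
  expect_gt(nrow(peaks(pl)), 0)
  ## every simulated peak is explained by the generating ensemble
  rep_ <- scoreRecall(pl, st, ens, tol)
  expect_equal(recallScore(rep_), 1.0)
  ## peaks sit exactly at assigned frequencies when jitter is 0
  s <- shifts(st)
  expect_true(all(round(peaks(pl)$wHdonor, 6) %in% round(s$shift, 6)))
  ## pairs beyond the cutoff yield no peak
  tolNarrow <- matchTolerances(distanceCutoff = 0.5)
  expect_equal(nrow(peaks(simulatePeaks(ens, st, tolNarrow, "N15-NOESY"))), 0L)
  ## determinism under a fixed seed
  p1 <- simulatePeaks(ens, st, tol, "C13-NOESY", jitter = 0.02, seed = 7)
  p2 <- simulatePeaks(ens, st, tol, "C13-NOESY", jitter = 0.02, seed = 7)
  expect_identical(peaks(p1), peaks(p2))
})
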