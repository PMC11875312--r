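## Seeded generator of two-state toy ensembles with matched synthetic
## chemical shifts and NOESY peak lists.
##
## The fixture is a helix-loop-helix peptide whose C-terminal helix is
## rotated about a hinge in state 2. Models carry backbone atoms plus a
## minimal proton set (amide H, HA, and a methyl on each alanine) -- enough
## to exercise peak matching including equivalent protons. The per-residue
## coordinate noise is amplified at the termini (flexible tails), so a single
## state already has a non-degenerate RMSF profile.

#' Fixture specification for the two-state generator
#'
#' @param nResidues peptide length (default 30).
#' @param hingeRes hinge residue (default 16, at the end of the loop).
#' @param hingeAngle hinge rotation of state 2, degrees (default 25).
#' @param modelsPerState models per state (default 20).
#' @param noiseSd base per-coordinate Gaussian noise, Angstrom (default 0.3);
#'   amplified at the termini by the flexible-tails factor
#'   `1 + exp(-(i-1)/2) + exp(-(n-i)/2)`.
#' @param ptm pTM assigned to states 1 and 2 (length-2, default 0.85, 0.80).
#' @param peakJitter Gaussian ppm noise for simulated peaks (default 0).
#' @param seed integer seed; fixed seed gives bit-identical output.
#' @return list of class `FixtureSpec`.
#' @export
fixtureSpec <- function(nResidues = 30L, hingeRes = 16L, hingeAngle = 25,
                        modelsPerState = 20L, noiseSd = 0.3,
                        ptm = c(0.85, 0.80), peakJitter = 0, seed = 1L) {
  stopifnot(nResidues > 0L, modelsPerState > 0L, noiseSd >= 0,
            hingeRes > 2L, hingeRes < nResidues - 1L)
  structure(list(nResidues = as.integer(nResidues),
                 hingeRes = as.integer(hingeRes), hingeAngle = hingeAngle,
                 modelsPerState = as.integer(modelsPerState),
                 noiseSd = noiseSd, ptm = ptm, peakJitter = peakJitter,
                 seed = as.integer(seed)),
            class = "FixtureSpec")
}

## ---------------------------------------------------------------------------
## internal geometry builder
## ---------------------------------------------------------------------------

## NeRF atom placement: d bonded to c, given chain a-b-c, bond length,
## bond angle at c (deg) and dihedral a-b-c-d (deg).
.placeAtom <- function(a, b, c_, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- -torsion * pi / 180    # so that dihedral(a, b, c, d) == torsion
  bc <- c_ - b; bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- .cross3(ab, bc); n <- n / sqrt(sum(n^2))
  m <- .cross3(n, bc)
  d2 <- bond * c(-cos(ang), sin(ang) * cos(tor), sin(ang) * sin(tor))
  c_ + d2[1L] * bc + d2[2L] * m + d2[3L] * n
}

## Build an L-peptide backbone (N, CA, C, O, CB, H, HA [+ Ala methyl]) from
## per-residue (phi, psi); omega fixed at 180.
.buildPeptide <- function(resnames, phi, psi) {
  n <- length(resnames)
  N <- CA <- C <- vector("list", n)
  N[[1L]] <- c(0, 0, 0)
  CA[[1L]] <- c(1.458, 0, 0)
  C[[1L]] <- CA[[1L]] + 1.525 * c(cos(pi - 111.2 * pi / 180),
                                  sin(pi - 111.2 * pi / 180), 0)
  for (i in 2:n) {
    N[[i]] <- .placeAtom(N[[i - 1L]], CA[[i - 1L]], C[[i - 1L]],
                         1.329, 116.2, psi[i - 1L])
    CA[[i]] <- .placeAtom(CA[[i - 1L]], C[[i - 1L]], N[[i]],
                          1.458, 121.7, 180)
    C[[i]] <- .placeAtom(C[[i - 1L]], N[[i]], CA[[i]], 1.525, 111.2, phi[i])
  }
  rows <- list()
  add <- function(resno, resname, atom, xyz) {
    rows[[length(rows) + 1L]] <<- data.frame(
      chain = "A", resno = resno, resname = resname, atom = atom,
      element = substring(atom, 1L, 1L), x = xyz[1L], y = xyz[2L],
      z = xyz[3L], b = 0, stringsAsFactors = FALSE)
  }
  for (i in seq_len(n)) {
    add(i, resnames[i], "N", N[[i]])
    add(i, resnames[i], "CA", CA[[i]])
    add(i, resnames[i], "C", C[[i]])
    oRef <- if (i < n) N[[i + 1L]] else
      .placeAtom(N[[i]], CA[[i]], C[[i]], 1.329, 116.2, psi[i])
    o <- .placeAtom(oRef, CA[[i]], C[[i]], 1.231, 120.5, 180)
    add(i, resnames[i], "O", o)
    ## CB: torsion about N-C-CA chosen to give the L configuration
    cb <- .placeAtom(N[[i]], C[[i]], CA[[i]], 1.521, 110.1, .cbTorsion)
    add(i, resnames[i], "CB", cb)
    ha <- .placeAtom(N[[i]], C[[i]], CA[[i]], 1.090, 108.0, -.cbTorsion)
    add(i, resnames[i], "HA", ha)
    hn <- .placeAtom(C[[i]], CA[[i]], N[[i]], 1.020, 118.0, 180)
    add(i, resnames[i], "H", hn)
    if (resnames[i] == "ALA") {
      for (k in 1:3)
        add(i, resnames[i], paste0("HB", k),
            .placeAtom(N[[i]], CA[[i]], cb, 1.090, 109.5, 60 + 120 * (k - 1)))
    }
  }
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  df
}

## dihedral sign (N, C, CA -> CB) giving L-amino-acid chirality; set so that
## the improper dihedral N-CA-C-CB is negative, matching real structures
.cbTorsion <- -122.6

## Rodrigues rotation of points about (origin, axis) by angle degrees.
.rotateAbout <- function(xyz, origin, axis, angleDeg) {
  th <- angleDeg * pi / 180
  k <- axis / sqrt(sum(axis^2))
  X <- sweep(as.matrix(xyz), 2L, origin)
  K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3L, 3L)
  R <- diag(3L) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  sweep(X %*% t(R), 2L, origin, `+`)
}

.flexFactor <- function(resno, n) {
  1 + 1 * exp(-(resno - 1) / 2) + 1 * exp(-(n - resno) / 2)
}

## Smooth per-residue random displacement field: neighbouring residues move
## together (collective motion), so covalent geometry survives, while the
## marginal per-axis variance is renormalised to exactly sd_i^2 (keeping the
## closed-form RMSF of the construction).
.smoothNoise <- function(n, sd_) {
  k <- -4:4
  w <- stats::dnorm(k, 0, 1.25)
  E <- matrix(stats::rnorm(3L * (n + 8L)), ncol = 3L)
  F_ <- matrix(0, n, 3L)
  for (i in seq_len(n))
    F_[i, ] <- colSums(w * E[i + 4L + k, , drop = FALSE])
  F_ <- F_ / sqrt(sum(w^2))
  F_ * sd_
}

## ---------------------------------------------------------------------------
## generators
## ---------------------------------------------------------------------------

#' Generate a seeded two-state toy ensemble
#'
#' State 1 is a helix-loop-helix peptide; state 2 is the same peptide with
#' everything C-terminal of the hinge rotated by the hinge angle. Each model
#' adds per-atom Gaussian jitter whose sigma is the base noise scaled by the
#' flexible-tails factor. Per-residue pLDDT is assigned by an anti-monotone
#' map from the true pooled RMSF onto \[50, 100\]; each state carries its
#' configured pTM. The true pooled RMSF at residue i is the closed form
#' `sqrt(d_i^2 / 4 + 3 sigma_i^2)` where `d_i` is the displacement between
#' the two state mean structures.
#'
#' @param spec a [fixtureSpec()].
#' @return list with `states` (two [ConformerEnsemble-class]s, model ids
#'   disjoint), `pooled` (all models, interleaved), `trueLabels` (named by
#'   model id), `trueRmsf` (named by residue), `meanAtoms` (list of the two
#'   noise-free atom tables) and `spec`.
#' @export
makeTwoStateEnsemble <- function(spec = fixtureSpec()) {
  n <- spec$nResidues
  if (spec$hingeAngle == 0)
    warning("hinge angle 0: the two states are identical")
  resnames <- rep(c("ALA", "LEU"), length.out = n)
  helix1 <- seq_len(spec$hingeRes - 3L)
  loop <- (spec$hingeRes - 2L):(spec$hingeRes + 1L)
  phi <- rep(-57, n); psi <- rep(-47, n)
  phi[loop] <- -75; psi[loop] <- 150
  base <- .buildPeptide(resnames, phi, psi)
  ca <- function(a, i) as.numeric(a[a$resno == i & a$atom == "CA",
                                    c("x", "y", "z")])
  h <- spec$hingeRes
  axis <- .cross3(ca(base, h) - ca(base, h - 1L),
                  ca(base, h + 1L) - ca(base, h))
  state2 <- base
  mv <- state2$resno > h
  state2[mv, c("x", "y", "z")] <- .rotateAbout(
    state2[mv, c("x", "y", "z")], ca(base, h), axis, spec$hingeAngle)
  ## closed-form true pooled RMSF
  d <- vapply(seq_len(n), function(i)
    sqrt(sum((ca(state2, i) - ca(base, i))^2)), 0)
  sigma <- spec$noiseSd * .flexFactor(seq_len(n), n)
  trueRmsf <- stats::setNames(sqrt(d^2 / 4 + 3 * sigma^2), seq_len(n))
  plddt <- 100 - 50 * (trueRmsf - min(trueRmsf)) /
    max(max(trueRmsf) - min(trueRmsf), 1e-9)
  set.seed(spec$seed)
  mkModels <- function(meanAtoms, ids, ptm) {
    lapply(ids, function(id) {
      a <- meanAtoms
      ## collective per-residue displacement: local covalent geometry (and
      ## hence chirality/omega) is preserved while the CA noise keeps the
      ## closed-form per-axis variance sigma_i^2
      sd_ <- spec$noiseSd * .flexFactor(seq_len(n), n)
      disp <- .smoothNoise(n, sd_)
      a[c("x", "y", "z")] <- a[c("x", "y", "z")] + disp[a$resno, ]
      a$b <- plddt[as.character(a$resno)]
      new("ConformerModel", modelId = as.integer(id), atoms = a,
          plddt = stats::setNames(plddt, paste0("A:", seq_len(n))),
          ptm = ptm)
    })
  }
  m <- spec$modelsPerState
  mods1 <- mkModels(base, seq_len(m), spec$ptm[1L])
  mods2 <- mkModels(state2, m + seq_len(m), spec$ptm[2L])
  ens1 <- new("ConformerEnsemble", label = "state1", models = mods1)
  ens2 <- new("ConformerEnsemble", label = "state2", models = mods2)
  ord <- as.vector(rbind(seq_len(m), m + seq_len(m)))   # interleave
  pooled <- new("ConformerEnsemble", label = "pooled",
                models = c(mods1, mods2)[ord])
  trueLabels <- stats::setNames(rep(1:2, each = m), c(seq_len(m), m + seq_len(m)))
  list(states = list(ens1, ens2), pooled = pooled, trueLabels = trueLabels,
       trueRmsf = trueRmsf, meanAtoms = list(base, state2), spec = spec)
}

#' Decoy ensemble with the hinge rotated the wrong way
#'
#' Same construction as state 2 of [makeTwoStateEnsemble()] but with the
#' hinge rotation reversed, so its specific contacts are absent from peak
#' lists simulated from the true states.
#'
#' @param fixture output of [makeTwoStateEnsemble()].
#' @return a [ConformerEnsemble-class] labelled `"decoy"` with model ids
#'   following the fixture's.
#' @export
makeDecoyEnsemble <- function(fixture) {
  spec <- fixture$spec
  n <- spec$nResidues
  base <- fixture$meanAtoms[[1L]]
  ca <- function(a, i) as.numeric(a[a$resno == i & a$atom == "CA",
                                    c("x", "y", "z")])
  h <- spec$hingeRes
  axis <- .cross3(ca(base, h) - ca(base, h - 1L),
                  ca(base, h + 1L) - ca(base, h))
  decoy <- base
  mv <- decoy$resno > h
  decoy[mv, c("x", "y", "z")] <- .rotateAbout(
    decoy[mv, c("x", "y", "z")], ca(base, h), axis, -spec$hingeAngle)
  dDecoy <- vapply(seq_len(n), function(i)
    sqrt(sum((ca(decoy, i) - ca(base, i))^2)), 0)
  sigma <- spec$noiseSd * .flexFactor(seq_len(n), n)
  rmsfD <- sqrt(dDecoy^2 / 4 + 3 * sigma^2)
  plddt <- 100 - 50 * (rmsfD - min(rmsfD)) /
    max(max(rmsfD) - min(rmsfD), 1e-9)
  set.seed(spec$seed + 104729L)
  m <- spec$modelsPerState
  mods <- lapply(2L * m + seq_len(m), function(id) {
    a <- decoy
    sd_ <- spec$noiseSd * .flexFactor(seq_len(n), n)
    disp <- .smoothNoise(n, sd_)
    a[c("x", "y", "z")] <- a[c("x", "y", "z")] + disp[a$resno, ]
    a$b <- plddt[a$resno]
    new("ConformerModel", modelId = as.integer(id), atoms = a,
        plddt = stats::setNames(plddt, paste0("A:", seq_len(n))),
        ptm = min(spec$ptm))
  })
  new("ConformerEnsemble", label = "decoy", models = mods)
}

#' Generate synthetic shifts and peak lists matched to a fixture
#'
#' Chemical shifts are placed at the random-coil value plus a signed
#' deviation whose magnitude is `1 / RCI_target` per resonance, where
#' `RCI_target = trueRMSF / 12.7` -- so [computeRci()] followed by
#' [rmsfFromRci()] approximates the true pooled fluctuations (three-point
#' smoothing blurs the correspondence slightly; the generator self-check is
#' a concordance bound, not equality). Alanine methyls get a seeded random
#' shift near 1.2 ppm. 15N- and 13C-resolved peak lists are back-calculated
#' from the merged true states under the minimum-distance rule.
#'
#' @param fixture output of [makeTwoStateEnsemble()].
#' @param tol a [MatchTolerances-class] used for the back-calculation.
#' @return list with `shifts` ([ShiftTable-class]), `peaks` (list of two
#'   [PeakList-class]: N15 and C13) and `rciTarget` (named numeric).
#' @export
makeSyntheticNmr <- function(fixture, tol = matchTolerances()) {
  spec <- fixture$spec
  trueRmsf <- fixture$trueRmsf
  rciTarget <- trueRmsf / 12.7
  if (any(rciTarget <= 0) || any(trueRmsf > 7.62))
    stop("true RMSF outside the RCI-representable range (0, 7.62] Angstrom")
  rc <- randomCoilTable()
  rcKey <- stats::setNames(rc$shift_ppm, paste(rc$residue_type, rc$atom_name))
  resnames <- rep(c("ALA", "LEU"), length.out = spec$nResidues)
  set.seed(spec$seed + 7919L)
  rows <- list()
  for (i in seq_len(spec$nResidues)) {
    rt <- resnames[i]
    dd <- 1 / rciTarget[i]
    for (at in c("CA", "C", "CB", "N", "H", "HA")) {
      rcv <- rcKey[paste(rt, at)]
      if (is.na(rcv)) next
      sgn <- sample(c(-1, 1), 1L)
      rows[[length(rows) + 1L]] <- data.frame(
        chain = "A", resno = i, resname = rt, atom = at,
        shift = as.numeric(rcv + sgn * dd), stringsAsFactors = FALSE)
    }
    if (rt == "ALA") {
      hb <- stats::runif(1L, 0.9, 1.5)
      for (k in 1:3)
        rows[[length(rows) + 1L]] <- data.frame(
          chain = "A", resno = i, resname = rt, atom = paste0("HB", k),
          shift = hb, stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  df$isotope <- vapply(df$atom, function(a)
    switch(substring(a, 1L, 1L), H = "1H", C = "13C", N = "15N"), "")
  st <- new("ShiftTable",
            shifts = df[c("chain", "resno", "resname", "atom", "isotope",
                          "shift")])
  pkN <- simulatePeaks(fixture$states, st, tol, "N15-NOESY",
                       jitter = spec$peakJitter, seed = spec$seed + 11L)
  pkC <- simulatePeaks(fixture$states, st, tol, "C13-NOESY",
                       jitter = spec$peakJitter, seed = spec$seed + 13L)
  list(shifts = st, peaks = list(pkN, pkC), rciTarget = rciTarget)
}
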