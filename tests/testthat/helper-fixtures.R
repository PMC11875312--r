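## Shared fixture builders and independent oracles.

## A CA-only ConformerModel from an n x 3 coordinate matrix.
caOnlyModel <- function(xyz, modelId = 1L, chain = "A", resname = "ALA",
                        plddt = NULL) {
  n <- nrow(xyz)
  atoms <- data.frame(chain = chain, resno = seq_len(n), resname = resname,
                      atom = "CA", element = "C",
                      x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L], b = 0,
                      stringsAsFactors = FALSE)
  if (is.null(plddt)) plddt <- rep(90, n)
  new("ConformerModel", modelId = as.integer(modelId), atoms = atoms,
      plddt = stats::setNames(plddt, paste0(chain, ":", seq_len(n))),
      ptm = NA_real_)
}

caEnsemble <- function(xyzList, label = "toy") {
  mods <- lapply(seq_along(xyzList), function(i)
    caOnlyModel(xyzList[[i]], modelId = i))
  new("ConformerEnsemble", label = label, models = mods)
}

## random rigid motion applied to an n x 3 matrix
rigidMove <- function(xyz, seed = 1L) {
  set.seed(seed)
  ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
  th <- stats::runif(1, 0.3, 2.5)
  K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  sweep(xyz %*% t(R), 2, stats::rnorm(3, 0, 10), `+`)
}

## ---------------------------------------------------------------------------
## independent oracles
## ---------------------------------------------------------------------------

## Horn quaternion superposition: optimal RMSD between matched coordinate
## sets, computed from the largest eigenvalue of the 4x4 key matrix --
## independent of the SVD route used by the package.
quaternionRmsd <- function(P, Q) {
  pc <- colMeans(P); qc <- colMeans(Q)
  P0 <- sweep(P, 2, pc); Q0 <- sweep(Q, 2, qc)
  S <- crossprod(P0, Q0)
  key <- matrix(0, 4, 4)
  key[1, 1] <- S[1, 1] + S[2, 2] + S[3, 3]
  key[1, 2] <- key[2, 1] <- S[2, 3] - S[3, 2]
  key[1, 3] <- key[3, 1] <- S[3, 1] - S[1, 3]
  key[1, 4] <- key[4, 1] <- S[1, 2] - S[2, 1]
  key[2, 2] <- S[1, 1] - S[2, 2] - S[3, 3]
  key[2, 3] <- key[3, 2] <- S[1, 2] + S[2, 1]
  key[2, 4] <- key[4, 2] <- S[1, 3] + S[3, 1]
  key[3, 3] <- -S[1, 1] + S[2, 2] - S[3, 3]
  key[3, 4] <- key[4, 3] <- S[2, 3] + S[3, 2]
  key[4, 4] <- -S[1, 1] - S[2, 2] + S[3, 3]
  lmax <- max(eigen(key, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(P0^2) + sum(Q0^2) - 2 * lmax) / nrow(P)
  sqrt(max(msd, 0))
}

## Brute-force NOESY explained-set enumerator: for every peak, every proton
## pair and every model, apply the matching tolerances and the distance rule
## directly on raw coordinates. Equivalent protons are collapsed with the
## minimum rule; distances are summarized by the midrange across models,
## minimised across states.
bruteExplainedSet <- function(peakLists, st, ensList, tol) {
  if (is(peakLists, "PeakList")) peakLists <- list(peakLists)
  if (is(ensList, "ConformerEnsemble")) ensList <- list(ensList)
  s <- shifts(st)
  hs <- s[s$isotope == "1H", ]
  ## proton group table (group-level shift, bonded heavy shift)
  grp <- mapply(ConformerSelect:::.protonGroup, hs$resname, hs$atom)
  key <- paste(hs$chain, hs$resno, grp, sep = ":")
  gtab <- hs[!duplicated(key), c("chain", "resno", "resname")]
  gtab$group <- grp[!duplicated(key)]
  gtab$key <- key[!duplicated(key)]
  gtab$shift <- as.numeric(tapply(hs$shift, key, mean)[gtab$key])
  gtab$heavy <- mapply(function(rn, g)
    ConformerSelect:::.bondedHeavy(rn,
      ConformerSelect:::.groupMembers(rn, g)[1L]), gtab$resname, gtab$group)
  hv <- paste(s$chain, s$resno, s$atom)
  gtab$heavyShift <- s$shift[match(paste(gtab$chain, gtab$resno, gtab$heavy), hv)]
  gtab$heavyIso <- substr(gtab$heavy, 1, 1)
  ## group distance in one model: min over member protons
  gDist <- function(model, i, j) {
    a <- model@atoms
    memIdx <- function(k) {
      mem <- ConformerSelect:::.groupMembers(gtab$resname[k], gtab$group[k])
      which(a$chain == gtab$chain[k] & a$resno == gtab$resno[k] &
            a$atom %in% mem)
    }
    ii <- memIdx(i); jj <- memIdx(j)
    if (!length(ii) || !length(jj)) return(NA_real_)
    dmin <- Inf
    for (p in ii) for (q in jj) {
      d <- sqrt(sum((as.numeric(a[p, c("x", "y", "z")]) -
                     as.numeric(a[q, c("x", "y", "z")]))^2))
      if (d < dmin) dmin <- d
    }
    dmin
  }
  pairDist <- function(i, j) {
    min(vapply(ensList, function(e) {
      ds <- vapply(models(e), gDist, 0, i = i, j = j)
      (min(ds) + max(ds)) / 2
    }, 0))
  }
  explained <- integer(0)
  id <- 0L
  for (pl in peakLists) {
    iso <- if (pl@spectrumType == "N15-NOESY") "N" else "C"
    tx <- if (iso == "N") tol@nPpm else tol@cPpm
    for (r in seq_len(nrow(peaks(pl)))) {
      id <- id + 1L
      pk <- peaks(pl)[r, ]
      hit <- FALSE
      for (i in seq_len(nrow(gtab))) {
        if (hit) break
        if (gtab$heavyIso[i] != iso || is.na(gtab$heavyShift[i])) next
        if (abs(gtab$shift[i] - pk$wHdonor) > tol@hPpm) next
        if (abs(gtab$heavyShift[i] - pk$wX) > tx) next
        for (j in seq_len(nrow(gtab))) {
          if (j == i) next
          if (abs(gtab$shift[j] - pk$wHacceptor) > tol@hPpm) next
          d <- pairDist(i, j)
          if (!is.na(d) && d <= tol@distanceCutoff) { hit <- TRUE; break }
        }
      }
      if (hit) explained <- c(explained, id)
    }
  }
  explained
}

## Exhaustive-seed TM-score oracle: every contiguous window of length >= 3 is
## a seed; superposition via the quaternion method; same extension rule as
## the definition (reselect residues below the search threshold, refit until
## stable); normalised by reference length.
bruteTmScore <- function(P, Q, d0) {
  L <- nrow(Q)
  fitOn <- function(sel) {
    pc <- colMeans(P[sel, , drop = FALSE]); qc <- colMeans(Q[sel, , drop = FALSE])
    P0 <- sweep(P[sel, , drop = FALSE], 2, pc)
    Q0 <- sweep(Q[sel, , drop = FALSE], 2, qc)
    S <- crossprod(P0, Q0)
    sv <- svd(S)
    d <- sign(det(sv$v %*% t(sv$u)))
    R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
    sweep(sweep(P, 2, pc) %*% t(R), 2, qc, `+`)
  }
  scoreSel <- function(sel) {
    best <- 0
    for (it in 1:20) {
      if (length(sel) < 3) break
      moved <- fitOn(sel)
      dd <- sqrt(rowSums((moved - Q)^2))
      sc <- sum(1 / (1 + (dd / d0)^2)) / L
      if (sc > best) best <- sc
      newSel <- which(dd < max(d0 + 1.5, 3.5))
      if (identical(newSel, sel)) break
      sel <- newSel
    }
    best
  }
  best <- scoreSel(seq_len(L))
  for (len in 3:L) for (s0 in 1:(L - len + 1)) {
    sc <- scoreSel(s0:(s0 + len - 1))
    if (sc > best) best <- sc
  }
  best
}
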