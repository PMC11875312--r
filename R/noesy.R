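## NOESY peak matching, recall/precision/F scoring, Double Recall and
## peak back-calculation.
##
## Protons are handled at the level of equivalence groups (methyl rotors,
## Phe/Tyr ring pairs collapse to one site); distances over a group use the
## minimum over member protons by default, or an r^-6-summed effective
## distance. Diagonal peaks (donor group == acceptor group) are excluded.

## ---------------------------------------------------------------------------
## proton site inventory
## ---------------------------------------------------------------------------

## One row per assigned proton equivalence group: the matching universe.
.protonInventory <- function(st) {
  s <- st@shifts
  h <- s[s$isotope == "1H", , drop = FALSE]
  if (!nrow(h)) stop("no assigned protons in shift table")
  grp <- mapply(.protonGroup, h$resname, h$atom)
  key <- paste(h$chain, h$resno, grp, sep = ":")
  first <- !duplicated(key)
  inv <- data.frame(
    key = key[first], chain = h$chain[first], resno = h$resno[first],
    resname = h$resname[first], group = grp[first],
    hShift = as.numeric(tapply(h$shift, key, mean)[key[first]]),
    stringsAsFactors = FALSE)
  inv$heavyAtom <- mapply(function(rn, g) {
    mem <- .groupMembers(rn, g)
    .bondedHeavy(rn, mem[1L])
  }, inv$resname, inv$group)
  inv$heavyIso <- vapply(inv$heavyAtom, .heavyIsotope, "")
  hv <- paste(s$chain, s$resno, s$atom)
  inv$heavyShift <- s$shift[match(paste(inv$chain, inv$resno, inv$heavyAtom), hv)]
  inv$members <- mapply(function(rn, g) list(.groupMembers(rn, g)),
                        inv$resname, inv$group)
  rownames(inv) <- NULL
  inv
}

## ---------------------------------------------------------------------------
## group-level distances within a model / across an ensemble
## ---------------------------------------------------------------------------

## site-by-site distance matrix for one model; corr holds the pseudo-atom
## correction (1 A) for sites represented by their bonded heavy atom.
.modelGroupDistances <- function(model, inv, method = "min") {
  a <- model@atoms
  akey <- paste(a$chain, a$resno, a$atom)
  n <- nrow(inv)
  rowsOf <- vector("list", n)
  coords <- list()
  corr <- numeric(n)
  usable <- logical(n)
  nFallback <- 0L
  rowOffset <- 0L
  for (i in seq_len(n)) {
    mem <- inv$members[[i]]
    hit <- match(paste(inv$chain[i], inv$resno[i], mem), akey)
    hit <- hit[!is.na(hit)]
    if (length(hit)) {
      usable[i] <- TRUE
    } else {
      hv <- match(paste(inv$chain[i], inv$resno[i], inv$heavyAtom[i]), akey)
      if (!is.na(hv)) {
        hit <- hv
        corr[i] <- 1.0
        usable[i] <- TRUE
        nFallback <- nFallback + 1L
      }
    }
    if (length(hit)) {
      rowsOf[[i]] <- rowOffset + seq_along(hit)
      rowOffset <- rowOffset + length(hit)
      coords <- c(coords, list(as.matrix(a[hit, c("x", "y", "z")])))
    }
  }
  if (nFallback)
    warning(nFallback, " proton site(s) missing from model ", model@modelId,
            ": using bonded heavy atom position with 1.0 A correction")
  X <- do.call(rbind, coords)
  D <- as.matrix(stats::dist(X))
  Dg <- matrix(NA_real_, n, n)
  if (method == "min") {
    R1 <- matrix(NA_real_, n, nrow(X))
    for (i in which(usable))
      R1[i, ] <- Reduce(pmin, asplit(D[rowsOf[[i]], , drop = FALSE], 1L))
    for (j in which(usable))
      Dg[, j] <- Reduce(pmin, asplit(R1[, rowsOf[[j]], drop = FALSE], 2L))
  } else {                                     # r6sum
    D6 <- D^(-6)
    R1 <- matrix(NA_real_, n, nrow(X))
    for (i in which(usable))
      R1[i, ] <- colSums(D6[rowsOf[[i]], , drop = FALSE])
    S <- matrix(NA_real_, n, n)
    for (j in which(usable))
      S[, j] <- rowSums(R1[, rowsOf[[j]], drop = FALSE])
    Dg <- S^(-1/6)
  }
  ## pseudo-atom correction, floored so distances stay positive
  if (any(corr > 0)) {
    Dg <- Dg - outer(corr, corr, `+`)
    Dg[Dg < 0.1] <- 0.1
  }
  diag(Dg) <- NA_real_
  Dg
}

## summarize a stack of per-model matrices into one ensemble matrix
.summarizeDistances <- function(stack, summarizer) {
  if (length(stack) == 1L) return(stack[[1L]])
  arr <- simplify2array(stack)
  switch(summarizer,
    min = apply(arr, c(1, 2), function(v)
      if (all(is.na(v))) NA_real_ else min(v, na.rm = TRUE)),
    midrange = apply(arr, c(1, 2), function(v) {
      if (all(is.na(v))) return(NA_real_)
      (min(v, na.rm = TRUE) + max(v, na.rm = TRUE)) / 2
    }),
    median = apply(arr, c(1, 2), function(v)
      if (all(is.na(v))) NA_real_ else stats::median(v, na.rm = TRUE)),
    per_model = stop("per_model summarizer has no single ensemble matrix"),
    stop("unknown summarizer: ", summarizer))
}

#' Summarized interproton distance for one pair
#'
#' Per model the pair distance is the minimum over equivalent-proton
#' expansions (or an r^-6 sum, per the tolerances object); across the models
#' of an ensemble distances are summarized by the configured summarizer
#' (midrange = (min + max) / 2 by default). For a set of states the minimum
#' of the per-state summaries is taken (merged-state rule). Protons missing
#' from a model fall back to the bonded heavy atom position with a 1.0 A
#' correction, with a warning.
#'
#' @param ens a [ConformerEnsemble-class] or a list of them (states).
#' @param pair list or data.frame row with `chain1`, `resno1`, `atom1`,
#'   `chain2`, `resno2`, `atom2` (atom may be a group key like `QB`).
#' @param st a [ShiftTable-class] providing residue types for the pair (or
#'   `NULL` if `pair` carries `resname1`/`resname2`).
#' @param tol a [MatchTolerances-class].
#' @return summarized distance in Angstrom.
#' @export
ensemblePairDistance <- function(ens, pair, st = NULL,
                                 tol = matchTolerances()) {
  ensList <- if (is(ens, "ConformerEnsemble")) list(ens) else ens
  getRes <- function(side) {
    nm <- pair[[paste0("resname", side)]]
    if (!is.null(nm)) return(nm)
    s <- st@shifts
    s$resname[s$chain == pair[[paste0("chain", side)]] &
              s$resno == pair[[paste0("resno", side)]]][1L]
  }
  inv <- data.frame(
    key = c("p1", "p2"),
    chain = c(pair$chain1, pair$chain2),
    resno = c(pair$resno1, pair$resno2),
    resname = c(getRes(1), getRes(2)),
    group = c(.protonGroup(getRes(1), pair$atom1),
              .protonGroup(getRes(2), pair$atom2)),
    hShift = NA_real_, heavyAtom = NA_character_, heavyIso = "",
    heavyShift = NA_real_, stringsAsFactors = FALSE)
  inv$heavyAtom <- mapply(function(rn, g)
    .bondedHeavy(rn, .groupMembers(rn, g)[1L]), inv$resname, inv$group)
  inv$members <- mapply(function(rn, g) list(.groupMembers(rn, g)),
                        inv$resname, inv$group)
  summ <- if (tol@summarizer == "per_model") "midrange" else tol@summarizer
  perState <- vapply(ensList, function(e) {
    stack <- lapply(e@models, .modelGroupDistances, inv = inv,
                    method = tol@equivalentMethod)
    .summarizeDistances(stack, summ)[1L, 2L]
  }, 0)
  min(perState)
}

## ---------------------------------------------------------------------------
## peak matching
## ---------------------------------------------------------------------------

.xTolerance <- function(tol, spectrumType) {
  if (spectrumType == "N15-NOESY") tol@nPpm else tol@cPpm
}

.spectrumIsotope <- function(spectrumType) {
  if (spectrumType == "N15-NOESY") "15N" else "13C"
}

## candidate (donor, acceptor) site-index pairs for one peak
.peakCandidates <- function(w1, w2, w3, inv, tol, spectrumType) {
  tx <- .xTolerance(tol, spectrumType)
  iso <- .spectrumIsotope(spectrumType)
  don <- which(inv$heavyIso == iso & !is.na(inv$heavyShift) &
               abs(inv$hShift - w1) <= tol@hPpm &
               abs(inv$heavyShift - w2) <= tx)
  acc <- which(abs(inv$hShift - w3) <= tol@hPpm)
  if (!length(don) || !length(acc))
    return(matrix(integer(0), ncol = 2L))
  cand <- expand.grid(donor = don, acceptor = acc)
  cand <- cand[cand$donor != cand$acceptor, , drop = FALSE]
  as.matrix(cand)
}

#' Match one NOESY peak to candidate proton pairs
#'
#' Returns every assigned proton pair (h1, h2) with the donor proton within
#' `hPpm` of w1, the donor's bonded heavy atom (of the spectrum's isotope)
#' within the X tolerance of w2, and the acceptor proton within `hPpm` of w3.
#' Pairs within the same equivalence group (diagonal peaks) are excluded. An
#' empty result means the peak is "unmatched".
#'
#' @param peak one-row data.frame (or list) with `wHdonor`, `wX`,
#'   `wHacceptor`.
#' @param st a [ShiftTable-class].
#' @param tol a [MatchTolerances-class].
#' @param spectrumType `"N15-NOESY"` or `"C13-NOESY"`.
#' @return data.frame of candidate pairs (donor and acceptor chain, residue,
#'   group).
#' @export
matchPeak <- function(peak, st, tol = matchTolerances(),
                      spectrumType = c("N15-NOESY", "C13-NOESY")) {
  spectrumType <- match.arg(spectrumType)
  inv <- .protonInventory(st)
  cand <- .peakCandidates(peak$wHdonor, peak$wX, peak$wHacceptor,
                          inv, tol, spectrumType)
  data.frame(
    donorChain = inv$chain[cand[, 1L]], donorResno = inv$resno[cand[, 1L]],
    donorGroup = inv$group[cand[, 1L]],
    acceptorChain = inv$chain[cand[, 2L]],
    acceptorResno = inv$resno[cand[, 2L]],
    acceptorGroup = inv$group[cand[, 2L]],
    stringsAsFactors = FALSE)
}

## ---------------------------------------------------------------------------
## recall / precision / F
## ---------------------------------------------------------------------------

## Internal engine shared by scoreRecall / scoreModels / simulatePeaks:
## computes site inventory, per-model group distance stacks per state and
## the merged (across states) summarized distance matrix.
.noesyEngine <- function(peakLists, st, ensList, tol) {
  inv <- .protonInventory(st)
  stacks <- lapply(ensList, function(e)
    lapply(e@models, .modelGroupDistances, inv = inv,
           method = tol@equivalentMethod))
  summ <- if (tol@summarizer == "per_model") "midrange" else tol@summarizer
  perState <- lapply(stacks, .summarizeDistances, summarizer = summ)
  merged <- Reduce(function(a, b) pmin(a, b, na.rm = TRUE), perState)
  peaksDf <- do.call(rbind, lapply(peakLists, function(pl) {
    p <- pl@peaks
    if (!nrow(p)) stop("empty peak list")
    data.frame(spectrum = pl@spectrumType, wHdonor = p$wHdonor, wX = p$wX,
               wHacceptor = p$wHacceptor, stringsAsFactors = FALSE)
  }))
  peaksDf$id <- seq_len(nrow(peaksDf))
  cands <- lapply(seq_len(nrow(peaksDf)), function(i)
    .peakCandidates(peaksDf$wHdonor[i], peaksDf$wX[i], peaksDf$wHacceptor[i],
                    inv, tol, peaksDf$spectrum[i]))
  sig <- paste(peaksDf$spectrum, sprintf("%.4f|%.4f|%.4f", peaksDf$wHdonor,
                                         peaksDf$wX, peaksDf$wHacceptor),
               collapse = ";")
  list(inv = inv, stacks = stacks, merged = merged, peaks = peaksDf,
       cands = cands, signature = sig)
}

## per-peak status given a distance matrix
.peakStatus <- function(eng, Dmat, cutoff) {
  inv <- eng$inv
  n <- nrow(eng$peaks)
  status <- character(n); bestPair <- rep(NA_character_, n)
  bestD <- rep(NA_real_, n)
  donorRes <- rep(NA_integer_, n); acceptorRes <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    cand <- eng$cands[[i]]
    if (!nrow(cand)) { status[i] <- "unmatched"; next }
    d <- Dmat[cand]
    if (all(is.na(d))) { status[i] <- "unmatched"; next }
    k <- which.min(d)
    bestD[i] <- d[k]
    bestPair[i] <- paste(inv$key[cand[k, 1L]], inv$key[cand[k, 2L]],
                         sep = " - ")
    donorRes[i] <- inv$resno[cand[k, 1L]]
    acceptorRes[i] <- inv$resno[cand[k, 2L]]
    status[i] <- if (bestD[i] <= cutoff) "explained" else "unexplained"
  }
  data.frame(id = eng$peaks$id, spectrum = eng$peaks$spectrum,
             status = status, bestPair = bestPair, bestDistance = bestD,
             donorRes = donorRes, acceptorRes = acceptorRes,
             stringsAsFactors = FALSE)
}

## eligible pairs for the precision denominator: assigned, observable
## (donor side can appear in one of the provided spectra), inter-residue.
.observablePairs <- function(eng, spectra) {
  inv <- eng$inv
  isos <- vapply(spectra, .spectrumIsotope, "")
  n <- nrow(inv)
  idx <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
  sep <- abs(inv$resno[idx[, 1L]] - inv$resno[idx[, 2L]])
  sameChain <- inv$chain[idx[, 1L]] == inv$chain[idx[, 2L]]
  keep <- !(sameChain & sep < 1L)
  canDonate <- function(i) inv$heavyIso[i] %in% isos & !is.na(inv$heavyShift[i])
  keep <- keep & (canDonate(idx[, 1L]) | canDonate(idx[, 2L]))
  idx[keep, , drop = FALSE]
}

#' Score an ensemble (or merged states) against NOESY peak lists
#'
#' A peak is *explained* when any candidate pair from [matchPeak()] has a
#' summarized interproton distance at or below the cutoff; *unexplained* when
#' candidates exist but all are long; *unmatched* when no assignment matches
#' its frequencies. Recall is the explained fraction of all peaks. Precision
#' is the fraction of the model's short (<= cutoff) interproton distances --
#' between assigned, observable protons at sequence separation >= 1 residue
#' -- supported by at least one matching peak. F is the harmonic mean
#' 2RP / (R + P). For a list of ensembles the merged minimum-distance rule is
#' applied across states.
#'
#' @param peakLists a [PeakList-class] or list of them.
#' @param st a [ShiftTable-class].
#' @param ens a [ConformerEnsemble-class] or list of them (states).
#' @param tol a [MatchTolerances-class].
#' @return a [RecallReport-class].
#' @export
scoreRecall <- function(peakLists, st, ens, tol = matchTolerances()) {
  if (is(peakLists, "PeakList")) peakLists <- list(peakLists)
  ensList <- if (is(ens, "ConformerEnsemble")) list(ens) else ens
  eng <- .noesyEngine(peakLists, st, ensList, tol)
  .reportFromEngine(eng, tol,
                    spectra = vapply(peakLists, function(p) p@spectrumType, ""))
}

.reportFromEngine <- function(eng, tol, spectra, Dmat = NULL) {
  if (is.null(Dmat)) Dmat <- eng$merged
  cutoff <- tol@distanceCutoff
  pk <- .peakStatus(eng, Dmat, cutoff)
  recall <- sum(pk$status == "explained") / nrow(pk)
  obs <- .observablePairs(eng, spectra)
  d <- Dmat[obs]
  short <- which(!is.na(d) & d <= cutoff)
  supported <- logical(length(short))
  if (length(short)) {
    ## a short pair is supported when it appears among some peak's candidates
    candKeys <- unique(unlist(lapply(eng$cands, function(cm) {
      if (!nrow(cm)) return(character(0))
      i <- pmin(cm[, 1L], cm[, 2L]); j <- pmax(cm[, 1L], cm[, 2L])
      paste(i, j)
    })))
    keys <- paste(pmin(obs[short, 1L], obs[short, 2L]),
                  pmax(obs[short, 1L], obs[short, 2L]))
    supported <- keys %in% candKeys
  }
  precision <- if (length(short)) mean(supported) else NA_real_
  f <- if (!is.na(precision) && (recall + precision) > 0)
    2 * recall * precision / (recall + precision) else 0
  new("RecallReport", peaks = pk, recall = recall, precision = precision,
      fMeasure = f, signature = eng$signature)
}

#' Per-model recall scores
#'
#' Scores every model of an ensemble individually (each model's own
#' distances) and returns per-model recall together with the set-wide
#' `recall_min` / `recall_max` needed for the scaled NOE likelihood.
#'
#' @inheritParams scoreRecall
#' @return data.frame with columns `modelId`, `recall`; attributes
#'   `recallMin`, `recallMax`.
#' @export
perModelRecall <- function(peakLists, st, ens, tol = matchTolerances()) {
  if (is(peakLists, "PeakList")) peakLists <- list(peakLists)
  eng <- .noesyEngine(peakLists, st, list(ens), tol)
  cutoff <- tol@distanceCutoff
  rec <- vapply(seq_along(ens@models), function(m) {
    Dm <- eng$stacks[[1L]][[m]]
    st_ <- .peakStatus(eng, Dm, cutoff)
    sum(st_$status == "explained") / nrow(st_)
  }, 0)
  out <- data.frame(modelId = vapply(ens@models, function(m) m@modelId, 0L),
                    recall = rec)
  attr(out, "recallMin") <- min(rec)
  attr(out, "recallMax") <- max(rec)
  out
}

## ---------------------------------------------------------------------------
## Double Recall
## ---------------------------------------------------------------------------

#' NOESY Double Recall: peaks uniquely explained by each of two ensembles
#'
#' Both reports must have been computed from identical peak lists and shift
#' assignments. `unique_to_A` is `explained(A) \\ explained(B)` and vice
#' versa. Multiple NOEs between the same residue pair collapse to a single
#' contact-map entry with a count; the per-residue histogram counts unique
#' peaks by donor residue; long-range subsets use sequence separation >= 5.
#'
#' @param reportA,reportB [RecallReport-class] objects for ensembles A and B.
#' @param labelA,labelB display labels.
#' @return a [DoubleRecallResult-class].
#' @export
doubleRecall <- function(reportA, reportB, labelA = "A", labelB = "B") {
  if (!identical(reportA@signature, reportB@signature))
    stop("reports were not built from identical peak lists")
  expA <- explainedPeaks(reportA)
  expB <- explainedPeaks(reportB)
  uniqueA <- setdiff(expA, expB)
  uniqueB <- setdiff(expB, expA)
  shared <- intersect(expA, expB)
  contactRows <- function(rep_, ids, set) {
    p <- rep_@peaks[rep_@peaks$id %in% ids, , drop = FALSE]
    if (!nrow(p)) return(NULL)
    key <- paste(p$donorRes, p$acceptorRes)
    agg <- as.data.frame(table(key), stringsAsFactors = FALSE)
    ij <- do.call(rbind, strsplit(agg$key, " "))
    data.frame(resI = as.integer(ij[, 1L]), resJ = as.integer(ij[, 2L]),
               set = set, count = agg$Freq, stringsAsFactors = FALSE)
  }
  contacts <- rbind(contactRows(reportA, uniqueA, "uniqueA"),
                    contactRows(reportB, uniqueB, "uniqueB"),
                    contactRows(reportA, shared, "shared"))
  if (is.null(contacts))
    contacts <- data.frame(resI = integer(0), resJ = integer(0),
                           set = character(0), count = integer(0))
  histRows <- function(rep_, ids, set) {
    p <- rep_@peaks[rep_@peaks$id %in% ids, , drop = FALSE]
    if (!nrow(p)) return(NULL)
    agg <- as.data.frame(table(p$donorRes), stringsAsFactors = FALSE)
    data.frame(resno = as.integer(agg$Var1), set = set, count = agg$Freq)
  }
  histogram <- rbind(histRows(reportA, uniqueA, "uniqueA"),
                     histRows(reportB, uniqueB, "uniqueB"))
  if (is.null(histogram))
    histogram <- data.frame(resno = integer(0), set = character(0),
                            count = integer(0))
  lr <- function(rep_, ids) {
    p <- rep_@peaks[rep_@peaks$id %in% ids, , drop = FALSE]
    p$id[abs(p$donorRes - p$acceptorRes) >= 5L]
  }
  new("DoubleRecallResult", labelA = labelA, labelB = labelB,
      uniqueA = as.integer(uniqueA), uniqueB = as.integer(uniqueB),
      shared = as.integer(shared), contacts = contacts,
      histogram = histogram,
      longRange = list(uniqueA = lr(reportA, uniqueA),
                       uniqueB = lr(reportB, uniqueB),
                       shared = lr(reportA, shared)))
}

#' Write the Double Recall contact map as TSV
#'
#' One row per (residue pair, set) suitable for plotting.
#'
#' @param dr a [DoubleRecallResult-class].
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeDoubleRecall <- function(dr, path) {
  utils::write.table(dr@contacts, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

## ---------------------------------------------------------------------------
## peak back-calculation
## ---------------------------------------------------------------------------

#' Back-calculate a synthetic NOESY peak list from an ensemble
#'
#' One peak per ordered (donor, acceptor) pair of assigned proton groups
#' whose summarized ensemble distance is at or below the cutoff, with the
#' donor's bonded heavy atom carrying the spectrum's isotope label.
#' Intra-residue pairs are excluded. Peaks are placed at the assigned
#' frequencies plus seeded Gaussian jitter. Qualifying short pairs involving
#' protons present in the models but absent from the shift table are counted
#' in the `skipped` attribute.
#'
#' @param ens a [ConformerEnsemble-class] or list of them (merged states).
#' @param st a [ShiftTable-class].
#' @param tol a [MatchTolerances-class].
#' @param spectrumType `"N15-NOESY"` or `"C13-NOESY"`.
#' @param jitter Gaussian frequency noise sigma (ppm) applied to all three
#'   dimensions.
#' @param seed integer seed for the jitter.
#' @return a [PeakList-class]; attribute `skipped` counts omitted pairs.
#' @export
simulatePeaks <- function(ens, st, tol = matchTolerances(),
                          spectrumType = c("N15-NOESY", "C13-NOESY"),
                          jitter = 0, seed = 1L) {
  spectrumType <- match.arg(spectrumType)
  ensList <- if (is(ens, "ConformerEnsemble")) list(ens) else ens
  inv <- .protonInventory(st)
  stacks <- lapply(ensList, function(e)
    lapply(e@models, .modelGroupDistances, inv = inv,
           method = tol@equivalentMethod))
  summ <- if (tol@summarizer == "per_model") "midrange" else tol@summarizer
  merged <- Reduce(function(a, b) pmin(a, b, na.rm = TRUE),
                   lapply(stacks, .summarizeDistances, summarizer = summ))
  iso <- .spectrumIsotope(spectrumType)
  canDonate <- inv$heavyIso == iso & !is.na(inv$heavyShift)
  n <- nrow(inv)
  rows <- list()
  for (i in which(canDonate)) for (j in seq_len(n)) {
    if (i == j) next
    if (inv$chain[i] == inv$chain[j] && inv$resno[i] == inv$resno[j]) next
    d <- merged[i, j]
    if (is.na(d) || d > tol@distanceCutoff) next
    rows[[length(rows) + 1L]] <- c(inv$hShift[i], inv$heavyShift[i],
                                   inv$hShift[j])
  }
  m <- if (length(rows)) do.call(rbind, rows) else
    matrix(numeric(0), ncol = 3L)
  if (jitter > 0 && nrow(m)) {
    set.seed(seed)
    m <- m + matrix(stats::rnorm(length(m), 0, jitter), nrow(m))
  }
  pl <- new("PeakList", spectrumType = spectrumType,
            peaks = data.frame(id = seq_len(nrow(m)),
                               wHdonor = m[, 1L], wX = m[, 2L],
                               wHacceptor = m[, 3L],
                               intensity = rep(NA_real_, nrow(m))))
  attr(pl, "skipped") <- .countUnassignedShortPairs(ensList[[1L]], inv, tol)
  pl
}

## pairs within the cutoff (first model) involving a proton without an
## assignment -- reported, not simulated
.countUnassignedShortPairs <- function(ens, inv, tol) {
  a <- ens@models[[1L]]@atoms
  h <- a[startsWith(a$atom, "H"), , drop = FALSE]
  grp <- mapply(.protonGroup, h$resname, h$atom)
  key <- paste(h$chain, h$resno, grp, sep = ":")
  un <- !(key %in% inv$key)
  if (!any(un)) return(0L)
  hu <- h[un, , drop = FALSE]
  X <- as.matrix(hu[c("x", "y", "z")])
  Yall <- as.matrix(h[c("x", "y", "z")])
  cnt <- 0L
  for (i in seq_len(nrow(X))) {
    d <- sqrt(rowSums(sweep(Yall, 2L, X[i, ])^2))
    other <- paste(h$chain, h$resno) != paste(hu$chain[i], hu$resno[i])
    cnt <- cnt + sum(d[other] <= tol@distanceCutoff)
  }
  as.integer(cnt)
}
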