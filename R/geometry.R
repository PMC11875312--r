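## Superposition, ensemble RMSF, distance features, TM-score,
## well-defined-range heuristic and physical-sanity filtering.

## Calpha coordinate matrix of a model, rows named by residue number.
.caMatrix <- function(model, residues = NULL) {
  a <- model@atoms
  ca <- a[a$atom == "CA", ]
  ca <- ca[order(ca$chain, ca$resno), ]
  m <- as.matrix(ca[c("x", "y", "z")])
  rownames(m) <- ca$resno
  if (!is.null(residues)) {
    want <- as.character(residues)
    miss <- setdiff(want, rownames(m))
    if (length(miss))
      stop("missing CA for residue(s): ", paste(miss, collapse = ", "))
    m <- m[want, , drop = FALSE]
  }
  m
}

## Residues that have a CA in every model of an ensemble.
.commonCaResidues <- function(ens) {
  sets <- lapply(ens@models, function(m) {
    a <- m@atoms
    a$resno[a$atom == "CA"]
  })
  Reduce(intersect, sets)
}

#' Least-squares (Kabsch) superposition
#'
#' Finds the proper rotation and translation minimising the RMSD between two
#' matched coordinate sets.
#'
#' @param mobile,reference n-by-3 coordinate matrices with matched rows.
#' @param mask optional logical or integer row selector over which the fit is
#'   computed (the transform still applies to all rows).
#' @return list with `rotation` (3x3, det +1), `translation` (length 3),
#'   `rmsd` (over masked rows) and `transformed` (mobile after the move).
#' @export
superposeKabsch <- function(mobile, reference, mask = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (is.null(mask)) mask <- seq_len(nrow(mobile))
  P <- mobile[mask, , drop = FALSE]
  Q <- reference[mask, , drop = FALSE]
  if (nrow(P) != nrow(Q)) stop("mobile and reference masks differ in size")
  if (nrow(P) < 3L) stop("need at least 3 matched pairs")
  pc <- colMeans(P); qc <- colMeans(Q)
  P0 <- sweep(P, 2L, pc); Q0 <- sweep(Q, 2L, qc)
  ## collinearity check: rank of the centred reference configuration
  if (min(svd(Q0)$d) < 1e-8 * max(svd(Q0)$d, 1))
    stop("degenerate (collinear) reference configuration")
  H <- crossprod(P0, Q0)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  moved <- sweep(sweep(mobile, 2L, pc) %*% t(R), 2L, qc, "+")
  rmsd <- sqrt(mean(rowSums((moved[mask, , drop = FALSE] - Q)^2)))
  list(rotation = R, translation = as.numeric(qc - pc %*% t(R)),
       rmsd = rmsd, transformed = moved)
}

#' Per-residue ensemble RMSF
#'
#' Each model is superposed (Kabsch, over `alignResidues`) onto the ensemble
#' mean structure, iterating the mean twice so the result does not depend on
#' model order. The per-residue RMSF is the root-mean-square Calpha deviation
#' about the mean coordinates, with equal weight per model. Residues lacking a
#' CA in any model are excluded.
#'
#' @param ens a [ConformerEnsemble-class].
#' @param alignResidues residue numbers used for the superposition (default:
#'   all residues common to every model).
#' @return an [RmsfProfile-class] with source `"ensemble"`.
#' @export
ensembleRmsf <- function(ens, alignResidues = NULL) {
  common <- .commonCaResidues(ens)
  if (is.null(alignResidues)) alignResidues <- common
  alignResidues <- intersect(alignResidues, common)
  if (length(alignResidues) < 3L)
    stop("need at least 3 common aligned residues")
  coords <- lapply(ens@models, .caMatrix, residues = common)
  if (length(coords) == 1L) {
    warning("single-model ensemble: RMSF is zero everywhere")
    return(new("RmsfProfile", residues = as.integer(common),
               rmsf = rep(0, length(common)), source = "ensemble"))
  }
  idx <- match(as.character(alignResidues), as.character(common))
  ## initial alignment onto the first model, then two passes onto the mean
  ref <- coords[[1L]]
  for (pass in 1:3) {
    coords <- lapply(coords, function(x)
      superposeKabsch(x, ref, mask = idx)$transformed)
    ref <- Reduce(`+`, coords) / length(coords)
  }
  dev2 <- Reduce(`+`, lapply(coords, function(x) rowSums((x - ref)^2)))
  new("RmsfProfile", residues = as.integer(common),
      rmsf = sqrt(dev2 / length(coords)), source = "ensemble")
}

#' Flattened Calpha-Calpha distance vector
#'
#' Upper-triangular (i < j) distances in row-major order; length L(L-1)/2.
#'
#' @param model a [ConformerModel-class].
#' @param residues residue numbers to use (default: all with a CA).
#' @return numeric feature vector.
#' @export
caDistanceVector <- function(model, residues = NULL) {
  m <- .caMatrix(model, residues)
  as.numeric(stats::dist(m))
}

#' TM-score between two structures
#'
#' Standard TM-score with `d0(L) = 1.24 (L - 15)^(1/3) - 1.8` (floored at
#' 0.5), where L is the number of aligned residues of the reference.
#' The score is maximised over contiguous seed fragments of decreasing length
#' with iterative extension: after superposing on a seed, residues closer
#' than a search threshold are reselected and the fit repeated until the
#' selection is stable.
#'
#' @param model,reference [ConformerModel-class] objects sharing numbering.
#' @param residues residue numbers compared (default: common CA residues).
#' @return TM-score in (0, 1], normalised by the reference length.
#' @export
tmScore <- function(model, reference, residues = NULL) {
  if (is.null(residues)) {
    residues <- intersect(rownames(.caMatrix(model)),
                          rownames(.caMatrix(reference)))
  }
  P <- .caMatrix(model, residues)
  Q <- .caMatrix(reference, residues)
  L <- nrow(Q)
  if (L < 16L) warning("fewer than 16 aligned residues: d0 floored at 0.5")
  d0 <- max(1.24 * (L - 15)^(1/3) - 1.8, 0.5)
  if (!is.finite(d0)) d0 <- 0.5
  seedLens <- unique(pmax(4L, c(L, L %/% 2L, L %/% 4L)))
  best <- 0
  for (len in seedLens) {
    starts <- seq(1L, L - len + 1L, by = max(1L, len %/% 2L))
    for (s0 in starts) {
      sel <- s0:(s0 + len - 1L)
      sc <- .tmExtend(P, Q, sel, d0)
      if (sc > best) best <- sc
    }
  }
  max(best, .tmEval(P, Q, seq_len(L), d0))
}

.tmEval <- function(P, Q, mask, d0) {
  fit <- superposeKabsch(P, Q, mask = mask)
  d <- sqrt(rowSums((fit$transformed - Q)^2))
  sum(1 / (1 + (d / d0)^2)) / nrow(Q)
}

.tmExtend <- function(P, Q, sel, d0, maxIter = 20L) {
  best <- 0
  for (it in seq_len(maxIter)) {
    if (length(sel) < 3L) break
    fit <- tryCatch(superposeKabsch(P, Q, mask = sel), error = function(e) NULL)
    if (is.null(fit)) break
    d <- sqrt(rowSums((fit$transformed - Q)^2))
    sc <- sum(1 / (1 + (d / d0)^2)) / nrow(Q)
    if (sc > best) best <- sc
    newSel <- which(d < max(d0 + 1.5, 3.5))
    if (identical(newSel, sel)) break
    sel <- newSel
  }
  best
}

#' Well-defined residue ranges
#'
#' A heuristic stand-in for convention-based range finders: residues whose
#' ensemble RMSF after global superposition is at or below `rmsfCutoff` are
#' kept, gaps of up to 2 residues are bridged, and ranges shorter than 4
#' residues are dropped. A user-supplied override string is returned verbatim
#' (parsed).
#'
#' @param ens a [ConformerEnsemble-class].
#' @param rmsfCutoff RMSF threshold in Angstrom (default 2.0).
#' @param override optional `"start-end[,start-end...]"` string.
#' @return integer vector of well-defined residue numbers (possibly empty,
#'   with a warning).
#' @export
wellDefinedRanges <- function(ens, rmsfCutoff = 2.0, override = NULL) {
  if (!is.null(override)) return(parseRanges(override))
  prof <- ensembleRmsf(ens)
  keep <- prof@residues[prof@rmsf <= rmsfCutoff]
  if (!length(keep)) {
    warning("no residue passes the RMSF cutoff")
    return(integer(0))
  }
  keep <- sort(keep)
  ## bridge gaps of <= 2 residues
  segs <- split(keep, cumsum(c(1L, diff(keep) > 3L)))
  bridged <- unlist(lapply(segs, function(s) seq(min(s), max(s))))
  segs <- split(bridged, cumsum(c(1L, diff(bridged) > 1L)))
  segs <- segs[vapply(segs, length, 0L) >= 4L]
  out <- as.integer(sort(unique(unlist(segs))))
  if (!length(out)) warning("no range of >= 4 residues remains")
  out
}

## signed dihedral angle (degrees) for points a-b-c-d
.dihedral <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- .cross3(b1, b2); n2 <- .cross3(b2, b3)
  m1 <- .cross3(n1, b2 / sqrt(sum(b2^2)))
  x <- sum(n1 * n2); y <- sum(m1 * n2)
  atan2(y, x) * 180 / pi
}

.cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

.atomXyz <- function(a, resno, atom) {
  i <- which(a$resno == resno & a$atom == atom)
  if (!length(i)) return(NULL)
  as.numeric(a[i[1L], c("x", "y", "z")])
}

#' Filter physically unreasonable models
#'
#' Three checks per model: amino-acid chirality via the improper dihedral at
#' Calpha (the N-CA-C-CB dihedral is ~ +122 degrees for L-residues; negative
#' values flag a D-configuration), cis peptide bonds (omega torsion
#' CA-C-N'-CA' with |omega| < 30 degrees) at non-proline residues, and
#' missing backbone atoms (N, CA, C). Flagged models are removed.
#'
#' @param ens a [ConformerEnsemble-class].
#' @return list with `ensemble` (clean models) and `report`
#'   ([SanityReport-class]). Errors if every model is flagged.
#' @export
sanityFilter <- function(ens) {
  rows <- lapply(ens@models, function(m) {
    a <- m@atoms
    res <- .residueTable(m)
    dList <- character(0); cisList <- character(0); missList <- character(0)
    for (r in seq_len(nrow(res))) {
      rn <- res$resno[r]; rt <- res$resname[r]
      if (!(rt %in% names(.aa1))) next
      bb <- c("N", "CA", "C")
      have <- vapply(bb, function(at) !is.null(.atomXyz(a, rn, at)), TRUE)
      if (!all(have)) { missList <- c(missList, rn); next }
      cb <- .atomXyz(a, rn, "CB")
      if (!is.null(cb) && rt != "GLY") {
        imp <- .dihedral(.atomXyz(a, rn, "N"), .atomXyz(a, rn, "CA"),
                         .atomXyz(a, rn, "C"), cb)
        if (imp < 0) dList <- c(dList, rn)
      }
      if (r < nrow(res)) {
        rn2 <- res$resno[r + 1L]
        if (rn2 == rn + 1L) {
          n2 <- .atomXyz(a, rn2, "N"); ca2 <- .atomXyz(a, rn2, "CA")
          if (!is.null(n2) && !is.null(ca2)) {
            om <- .dihedral(.atomXyz(a, rn, "CA"), .atomXyz(a, rn, "C"),
                            n2, ca2)
            if (abs(om) < 30 && res$resname[r + 1L] != "PRO")
              cisList <- c(cisList, rn2)
          }
        }
      }
    }
    data.frame(modelId = m@modelId,
               dChirality = paste(dList, collapse = ","),
               cisPeptide = paste(cisList, collapse = ","),
               missingBackbone = paste(missList, collapse = ","),
               pass = !length(dList) && !length(cisList) && !length(missList),
               stringsAsFactors = FALSE)
  })
  flags <- do.call(rbind, rows)
  verdict <- if (all(flags$pass)) "pass" else "fail"
  report <- new("SanityReport", flags = flags, verdict = verdict)
  if (!any(flags$pass))
    stop("all models flagged as physically unreasonable; nothing to score")
  list(ensemble = ens[flags$pass], report = report)
}

#' Medoid model of an ensemble
#'
#' The model with the minimum sum of pairwise Calpha RMSDs over the given
#' residues: a natural reference conformer.
#'
#' @param ens a [ConformerEnsemble-class].
#' @param residues residue numbers used for the pairwise fits (default: all
#'   common CA residues).
#' @return the index (position in `models(ens)`) of the medoid.
#' @export
medoidModel <- function(ens, residues = NULL) {
  if (is.null(residues)) residues <- .commonCaResidues(ens)
  coords <- lapply(ens@models, .caMatrix, residues = residues)
  n <- length(coords)
  if (n == 1L) return(1L)
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    D[i, j] <- D[j, i] <- superposeKabsch(coords[[i]], coords[[j]])$rmsd
  }
  which.min(rowSums(D))
}
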