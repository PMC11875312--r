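## Bayesian per-model scoring, PCA + hierarchical clustering, and
## candidate single-state ensemble construction.

#' Scale a recall value to a NOE likelihood
#'
#' `(recall - recall_min) / (recall_max - recall_min)` over the scored model
#' set. When all models have equal recall the likelihood is uninformative and
#' 0.5 is returned for every model, with a warning.
#'
#' @param recall recall value(s) of the model(s).
#' @param recallMin,recallMax extremes over the scored model set.
#' @return likelihood in \[0, 1\].
#' @export
scaleRecall <- function(recall, recallMin, recallMax) {
  if (any(recall < recallMin - 1e-12) || any(recall > recallMax + 1e-12))
    stop("recall outside [recall_min, recall_max]")
  if (recallMax == recallMin) {
    warning("recall_max == recall_min: uninformative likelihood, returning 0.5")
    return(rep(0.5, length(recall)))
  }
  pmin(pmax((recall - recallMin) / (recallMax - recallMin), 0), 1)
}

.check01 <- function(...) {
  v <- c(...)
  if (any(!is.finite(v)) || any(v < 0) || any(v > 1))
    stop("inputs must lie in [0, 1]")
}

#' Posterior score of a model given NOE data
#'
#' Geometric mean of the scaled NOE likelihood and the model's global
#' reliability pTM: `sqrt(P(NOE|model) * pTM)`.
#'
#' @param pNoeGivenModel scaled recall likelihood in \[0, 1\].
#' @param ptm pTM in \[0, 1\].
#' @return score in \[0, 1\].
#' @export
pModelGivenNoe <- function(pNoeGivenModel, ptm) {
  .check01(pNoeGivenModel, ptm)
  sqrt(pNoeGivenModel * ptm)
}

#' Posterior score of a model given RCI data
#'
#' The Spearman correlation between per-residue pLDDT and RCI is computed
#' over residues carrying both values (at least 5 required), together with
#' the mean pLDDT / 100 over the same residues. The default `"geometric"`
#' variant returns `sqrt(|SCC| * <pLDDT>)`; the `"plddt-sqrt"` variant
#' returns `|SCC| * <pLDDT>^(1/2)` (the two readings coincide when
#' |SCC| = 1). A constant pLDDT profile leaves the SCC undefined; the score
#' is 0 with a warning.
#'
#' @param plddt named per-residue pLDDT vector (names `chain:resno` or plain
#'   residue numbers).
#' @param rci an [RciProfile-class].
#' @param variant `"geometric"` or `"plddt-sqrt"`.
#' @return score in \[0, 1\].
#' @export
pModelGivenRci <- function(plddt, rci, variant = c("geometric", "plddt-sqrt")) {
  variant <- match.arg(variant)
  p <- rci@profile
  rciKeys <- paste(p$chain, p$resno, sep = ":")
  keys <- names(plddt)
  if (is.null(keys)) stop("plddt must be a named vector")
  if (!any(keys %in% rciKeys) && all(grepl("^[0-9]+$", keys)))
    keys <- paste(p$chain[1L], names(plddt), sep = ":")
  common <- intersect(keys, rciKeys)
  if (length(common) < 5L)
    stop("need at least 5 residues with both pLDDT and RCI")
  x <- plddt[match(common, keys)]
  y <- p$rci[match(common, rciKeys)]
  scc <- spearmanScc(x, y)
  if (is.na(scc)) {
    warning("constant pLDDT profile: SCC undefined, score 0")
    return(0)
  }
  meanPlddt <- mean(x) / 100
  switch(variant,
         geometric = sqrt(abs(scc) * meanPlddt),
         `plddt-sqrt` = abs(scc) * sqrt(meanPlddt))
}

#' Combined posterior score given both NOE and RCI data
#'
#' Arithmetic mean of the two component scores.
#'
#' @param pNoe score given NOE data, in \[0, 1\].
#' @param pRci score given RCI data, in \[0, 1\].
#' @return score in \[0, 1\].
#' @export
pModelGivenNmr <- function(pNoe, pRci) {
  .check01(pNoe, pRci)
  (pNoe + pRci) / 2
}

#' Score every model of an ensemble against NOESY and RCI data
#'
#' Computes, per model: its individual NOESY recall, the scaled NOE
#' likelihood (normalised by the recall extremes of this model set), the
#' pTM-weighted NOE posterior, the pLDDT-RCI concordance posterior, and the
#' combined selection score. Models without a pTM are given the neutral
#' prior 1.0 with a warning.
#'
#' @param ens a [ConformerEnsemble-class] (typically sanity-filtered).
#' @param peakLists a [PeakList-class] or list of them.
#' @param st a [ShiftTable-class].
#' @param rci an [RciProfile-class].
#' @param tol a [MatchTolerances-class].
#' @param variant passed to [pModelGivenRci()].
#' @return data.frame (one row per model) with columns `modelId`, `recall`,
#'   `pNoeGivenModel`, `ptm`, `pModelGivenNoe`, `sccAbs`, `plddtMean`,
#'   `pModelGivenRci`, `pModelGivenNmr`; attributes `recallMin`/`recallMax`.
#' @export
scoreModels <- function(ens, peakLists, st, rci, tol = matchTolerances(),
                        variant = "geometric") {
  pm <- perModelRecall(peakLists, st, ens, tol)
  rMin <- attr(pm, "recallMin"); rMax <- attr(pm, "recallMax")
  pNoeLik <- scaleRecall(pm$recall, rMin, rMax)
  ptm <- vapply(ens@models, function(m) m@ptm, 0)
  if (any(is.na(ptm))) {
    warning("model(s) without pTM: using neutral prior 1.0")
    ptm[is.na(ptm)] <- 1.0
  }
  pNoe <- mapply(pModelGivenNoe, pNoeLik, ptm)
  rciBits <- lapply(ens@models, function(m) {
    sc <- pModelGivenRci(m@plddt, rci, variant = variant)
    sc
  })
  pRci <- unlist(rciBits)
  sccAbs <- vapply(ens@models, function(m) {
    p <- rci@profile
    keys <- names(m@plddt)
    common <- intersect(keys, paste(p$chain, p$resno, sep = ":"))
    s <- spearmanScc(m@plddt[match(common, keys)],
                     p$rci[match(common, paste(p$chain, p$resno, sep = ":"))])
    if (is.na(s)) 0 else abs(s)
  }, 0)
  plddtMean <- vapply(ens@models, function(m) {
    p <- rci@profile
    keys <- names(m@plddt)
    common <- intersect(keys, paste(p$chain, p$resno, sep = ":"))
    mean(m@plddt[match(common, keys)]) / 100
  }, 0)
  out <- data.frame(
    modelId = pm$modelId, recall = pm$recall, pNoeGivenModel = pNoeLik,
    ptm = ptm, pModelGivenNoe = pNoe, sccAbs = sccAbs,
    plddtMean = plddtMean, pModelGivenRci = pRci,
    pModelGivenNmr = mapply(pModelGivenNmr, pNoe, pRci))
  attr(out, "recallMin") <- rMin
  attr(out, "recallMax") <- rMax
  out
}

#' PCA of Calpha-Calpha distance matrices with hierarchical clustering
#'
#' Flattened pairwise Calpha distance vectors are column-centred and
#' decomposed by SVD; agglomerative clustering (Ward linkage by default) is
#' performed on the first three principal component coordinates. The result
#' is deterministic given the inputs; the seed is recorded for provenance.
#'
#' @param ens a [ConformerEnsemble-class].
#' @param residues residue numbers used for the distance features (default:
#'   all common CA residues).
#' @param k number of clusters (default 4; `"auto"` picks 2..6 by average
#'   silhouette width).
#' @param linkage agglomeration method for [stats::hclust()].
#' @param seed integer recorded in the result.
#' @return a [ClusterAssignment-class].
#' @export
pcaCluster <- function(ens, residues = NULL, k = 4L, linkage = "ward.D2",
                       seed = 1L) {
  if (is.null(residues)) residues <- .commonCaResidues(ens)
  X <- do.call(rbind, lapply(ens@models, caDistanceVector,
                             residues = residues))
  n <- nrow(X)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  totVar <- sum(Xc^2)
  auto <- identical(k, "auto")
  if (!auto) {
    k <- as.integer(k)
    if (k > n) stop("k exceeds the number of models")
  }
  if (totVar < 1e-12) {
    if (auto || k > 1L) stop("all models identical: cannot form >1 cluster")
    coords <- matrix(0, n, 3L,
                     dimnames = list(NULL, paste0("PC", 1:3)))
    return(new("ClusterAssignment", coords = coords,
               varExplained = rep(0, 3L),
               labels = stats::setNames(rep(1L, n),
                 vapply(ens@models, function(m) m@modelId, 0L)),
               populations = 1, linkage = linkage, k = 1L,
               seed = as.integer(seed)))
  }
  s <- svd(Xc)
  ncomp <- min(3L, length(s$d))
  coords <- s$u[, seq_len(ncomp), drop = FALSE] %*%
    diag(s$d[seq_len(ncomp)], ncomp)
  ## fix component signs (largest-magnitude loading positive) so results do
  ## not depend on the LAPACK sign convention
  for (c_ in seq_len(ncomp)) {
    v <- s$v[, c_]
    if (v[which.max(abs(v))] < 0) coords[, c_] <- -coords[, c_]
  }
  colnames(coords) <- paste0("PC", seq_len(ncomp))
  varExplained <- (s$d^2 / totVar)[seq_len(ncomp)]
  hc <- stats::hclust(stats::dist(coords), method = linkage)
  if (auto) {
    ks <- 2:min(6L, n - 1L)
    sil <- vapply(ks, function(kk)
      .meanSilhouette(coords, stats::cutree(hc, k = kk)), 0)
    k <- ks[which.max(sil)]
  }
  labels <- stats::cutree(hc, k = k)
  names(labels) <- vapply(ens@models, function(m) m@modelId, 0L)
  pops <- as.numeric(table(labels)) / n
  new("ClusterAssignment", coords = coords, varExplained = varExplained,
      labels = labels, populations = pops, linkage = linkage,
      k = as.integer(k), seed = as.integer(seed))
}

.meanSilhouette <- function(coords, labels) {
  D <- as.matrix(stats::dist(coords))
  n <- nrow(D)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    a <- if (sum(own) > 1L) mean(D[i, own & seq_len(n) != i]) else 0
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(l)
      mean(D[i, labels == l]), 0))
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  mean(s)
}

.greekLabels <- c("alpha", "beta", "gamma", "delta", "epsilon", "zeta",
                  "eta", "theta")

#' Build ranked candidate single-state ensembles from clusters
#'
#' Per cluster the `kTop` models with the highest combined selection score
#' are taken (ties broken by higher pTM, then lower model id; clusters
#' smaller than `kTop` contribute all members with a warning). Candidates
#' are ranked by mean score and labelled alpha5, beta5, ... in descending
#' order; the top candidate is state 1.
#'
#' @param assignment a [ClusterAssignment-class].
#' @param scores the data.frame from [scoreModels()].
#' @param ens the scored [ConformerEnsemble-class].
#' @param kTop models per candidate ensemble (default 5).
#' @return list of candidates, each with elements `label`, `modelIds`,
#'   `meanScore` and `ensemble`.
#' @export
buildCandidateEnsembles <- function(assignment, scores, ens, kTop = 5L) {
  labels <- assignment@labels
  ids <- vapply(ens@models, function(m) m@modelId, 0L)
  cand <- list()
  for (cl in sort(unique(labels))) {
    memberIds <- as.integer(names(labels)[labels == cl])
    sub <- scores[scores$modelId %in% memberIds, , drop = FALSE]
    ord <- order(-sub$pModelGivenNmr, -sub$ptm, sub$modelId)
    take <- min(kTop, nrow(sub))
    if (take < kTop)
      warning("cluster ", cl, " has only ", nrow(sub), " model(s)")
    top <- sub[ord[seq_len(take)], , drop = FALSE]
    cand[[length(cand) + 1L]] <- list(
      cluster = cl, modelIds = top$modelId,
      meanScore = mean(top$pModelGivenNmr))
  }
  ord <- order(-vapply(cand, `[[`, 0, "meanScore"))
  cand <- cand[ord]
  for (i in seq_along(cand)) {
    c_ <- cand[[i]]
    c_$label <- paste0(.greekLabels[min(i, length(.greekLabels))],
                       length(c_$modelIds))
    c_$ensemble <- ens[match(c_$modelIds, ids)]
    c_$ensemble@label <- c_$label
    cand[[i]] <- c_
  }
  cand
}
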