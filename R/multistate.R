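## Correlation statistics, comparison SEM intervals, and the greedy
## multi-state combination.

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties. A constant vector leaves the
#' coefficient undefined; `NA` is returned (callers that need a score map it
#' to 0).
#'
#' @param x,y paired numeric vectors (at least 3 pairs).
#' @return coefficient in \[-1, 1\], or `NA` when undefined.
#' @export
spearmanScc <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 pairs")
  if (stats::var(x) == 0 || stats::var(y) == 0) return(NA_real_)
  stats::cor(x, y, method = "spearman")
}

#' Lin's concordance correlation coefficient
#'
#' `CCC = 2 cov(x, y) / (var(x) + var(y) + (mean(x) - mean(y))^2)` with
#' population (1/N) moments. Satisfies
#' `-1 <= -|PCC| <= CCC <= |PCC| <= 1`.
#'
#' @param x,y paired numeric vectors (at least 3 pairs; not both constant).
#' @return coefficient in \[-1, 1\].
#' @export
linCcc <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 pairs")
  mx <- mean(x); my <- mean(y)
  vx <- mean((x - mx)^2); vy <- mean((y - my)^2)
  if (vx == 0 && vy == 0) stop("both vectors constant: CCC undefined")
  cxy <- mean((x - mx) * (y - my))
  2 * cxy / (vx + vy + (mx - my)^2)
}

#' Comparison SEM interval of two per-residue profiles
#'
#' Combines two profiles per residue -- `"sum"` for flexibility-concordance
#' plots (RCI scaled to (0, 1\] plus pLDDT scaled by 1/100, so concordant
#' residues sum near 1) or `"difference"` (e.g. shift-derived minus
#' ensemble-derived RMSF) -- and computes the global mean, SD,
#' `SEM = SD / (N - 1)^(1/2)` and confidence band `CI_p = SEM * Z_p`, where
#' `Z_p` is the two-sided critical value of the t distribution with 1 degree
#' of freedom (12.706 at p = 0.95). Residues with pLDDT <= 50 (when a pLDDT
#' profile is supplied) or with either value missing are excluded from N.
#'
#' @param a,b named per-residue numeric vectors (names = residue numbers).
#'   For `"sum"` mode, `a` is rci06 and `b` is the average pLDDT (0-100,
#'   scaled by 1/100 internally).
#' @param mode `"sum"` or `"difference"`.
#' @param p confidence level (default 0.95).
#' @param plddt optional named per-residue pLDDT used for the <= 50 exclusion
#'   (in `"sum"` mode `b` itself is used when this is missing).
#' @return list with `residues`, `combined`, `mean`, `sd`, `sem`, `zP`,
#'   `ciP`, `n`, `flagged` (residues outside mean +/- CI) and `excluded`.
#' @export
comparisonInterval <- function(a, b, mode = c("sum", "difference"),
                               p = 0.95, plddt = NULL) {
  mode <- match.arg(mode)
  common <- intersect(names(a), names(b))
  excl <- character(0)
  if (mode == "sum" && is.null(plddt)) plddt <- b
  if (!is.null(plddt)) {
    low <- names(plddt)[!is.na(plddt) & plddt <= 50]
    excl <- intersect(common, low)
    common <- setdiff(common, low)
  }
  av <- a[common]; bv <- b[common]
  ok <- is.finite(av) & is.finite(bv)
  excl <- c(excl, common[!ok])
  common <- common[ok]; av <- av[ok]; bv <- bv[ok]
  n <- length(common)
  if (n < 2L) stop("need at least 2 usable residues")
  combined <- switch(mode, sum = av + bv / 100, difference = av - bv)
  m <- mean(combined); sdev <- stats::sd(combined)
  sem <- sdev / sqrt(n - 1)
  zP <- stats::qt(1 - (1 - p) / 2, df = 1)
  ciP <- sem * zP
  flagged <- common[combined < m - ciP | combined > m + ciP]
  list(residues = as.integer(common), combined = stats::setNames(combined, common),
       mean = m, sd = sdev, sem = sem, zP = zP, ciP = ciP, n = n,
       flagged = as.integer(flagged), excluded = as.integer(excl))
}

#' Pool candidate states into one ensemble (equal model weights)
#'
#' @param candidates list of candidates (elements with an `ensemble` slot)
#'   or of [ConformerEnsemble-class] objects.
#' @param label label for the pooled ensemble.
#' @return a [ConformerEnsemble-class].
#' @export
poolStates <- function(candidates, label = "pooled") {
  ensList <- lapply(candidates, function(x)
    if (is(x, "ConformerEnsemble")) x else x$ensemble)
  mods <- unlist(lapply(ensList, models), recursive = FALSE)
  new("ConformerEnsemble", label = label, models = mods)
}

#' Greedy multi-state combination against shift-derived RMSF
#'
#' State 1 is the top-ranked candidate. Its ensemble RMSF is compared with
#' the shift-derived RMSF by Lin's CCC; a non-positive entry concordance
#' aborts with a failure flag. Then, iteratively, each remaining candidate is
#' pooled (equal model weights) with the accepted states and the CCC
#' recomputed: candidates that do not improve the current CCC are permanently
#' eliminated, and the best strict improver is accepted. The process stops
#' when no candidate improves the fit. The result is adequate when the final
#' CCC is at least `adequacyThreshold`.
#'
#' @param candidates ranked candidate list from [buildCandidateEnsembles()].
#' @param rmsfRci an [RmsfProfile-class] with source `"rci"`.
#' @param alignResidues residues used for superposition in the ensemble RMSF
#'   (default: all residues common to the pooled models).
#' @param adequacyThreshold final-CCC threshold for the adequacy flag
#'   (default 0.4).
#' @return a [StateCombination-class].
#' @export
combineStates <- function(candidates, rmsfRci, alignResidues = NULL,
                          adequacyThreshold = 0.4) {
  if (!length(candidates)) stop("empty candidate list")
  rciVals <- stats::setNames(rmsfRci@rmsf, rmsfRci@residues)
  cccOf <- function(stateSet) {
    pooled <- poolStates(stateSet)
    prof <- ensembleRmsf(pooled, alignResidues = alignResidues)
    ensVals <- stats::setNames(prof@rmsf, prof@residues)
    common <- intersect(names(ensVals), names(rciVals))
    if (length(common) < 5L)
      stop("fewer than 5 residues with both ensemble and RCI RMSF")
    linCcc(ensVals[common], rciVals[common])
  }
  accepted <- list(candidates[[1L]])
  ccc1 <- cccOf(accepted)
  if (ccc1 <= 0) {
    return(new("StateCombination", states = list(),
               trajectory = numeric(0),
               rejected = data.frame(label = vapply(candidates, `[[`, "", "label"),
                                     reason = "entry test failed"),
               finalCcc = 0, adequate = FALSE, failed = TRUE))
  }
  trajectory <- ccc1
  remaining <- candidates[-1L]
  rejected <- data.frame(label = character(0), reason = character(0))
  current <- ccc1
  while (length(remaining)) {
    trial <- vapply(remaining, function(x)
      cccOf(c(accepted, list(x))), 0)
    improve <- trial > current + 1e-9   # strict improvement beyond round-off
    if (any(!improve)) {
      rejected <- rbind(rejected, data.frame(
        label = vapply(remaining[!improve], `[[`, "", "label"),
        reason = sprintf("no CCC improvement (%.4f <= %.4f)",
                         trial[!improve], current)))
    }
    if (!any(improve)) break
    ## best strict improver; ties broken by candidate rank (list order)
    k <- which(improve)[which.max(trial[improve])]
    accepted <- c(accepted, list(remaining[[k]]))
    current <- trial[k]
    trajectory <- c(trajectory, current)
    remaining <- remaining[improve & seq_along(remaining) != k]
  }
  new("StateCombination",
      states = lapply(accepted, function(x)
        list(label = x$label, modelIds = x$modelIds)),
      trajectory = trajectory, rejected = rejected, finalCcc = current,
      adequate = current >= adequacyThreshold, failed = FALSE)
}
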