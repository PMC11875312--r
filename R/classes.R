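#' @import methods
NULL

## ---------------------------------------------------------------------------
## Core data containers
## ---------------------------------------------------------------------------

#' ConformerModel: a single structural model
#'
#' Holds the atomic record of one conformer together with its per-residue
#' pLDDT confidence (0-100 scale, conventionally stored in the B-factor
#' column of AI-generated coordinate files) and an optional global pTM score.
#'
#' @slot modelId integer model identifier (MODEL record number).
#' @slot atoms data.frame with columns `chain`, `resno` (1-based author
#'   numbering), `resname` (3-letter code), `atom` (PDB v3 name), `element`,
#'   `x`, `y`, `z` (Angstrom) and `b` (B-factor column as read).
#' @slot plddt named numeric, per-residue pLDDT in \[0, 100\]; names are
#'   `chain:resno` keys.
#' @slot ptm numeric(1) global confidence in \[0, 1\] (`NA` if unknown).
#'
#' @export
setClass("ConformerModel",
  representation(
    modelId = "integer",
    atoms = "data.frame",
    plddt = "numeric",
    ptm = "numeric"
  ),
  prototype(modelId = 1L, ptm = NA_real_)
)

setValidity("ConformerModel", function(object) {
  a <- object@atoms
  need <- c("chain", "resno", "resname", "atom", "element", "x", "y", "z", "b")
  if (!all(need %in% names(a)))
    return(paste("atoms must have columns:", paste(need, collapse = ", ")))
  if (nrow(a) == 0L) return("model has no atoms")
  if (!all(is.finite(a$x)) || !all(is.finite(a$y)) || !all(is.finite(a$z)))
    return("non-finite coordinates")
  if (length(object@plddt) &&
      (any(!is.finite(object@plddt)) ||
       any(object@plddt < 0) || any(object@plddt > 100)))
    return("pLDDT values must be finite and within [0, 100]")
  key <- paste(a$chain, a$resno, a$atom)
  if (anyDuplicated(key))
    return(paste0("duplicate atom name within a residue: ",
                  key[duplicated(key)][1L]))
  std <- a$resname %in% names(.aa1)
  if (any(std)) {
    res <- unique(a[std, c("chain", "resno")])
    hasCa <- paste(a$chain[a$atom == "CA"], a$resno[a$atom == "CA"])
    miss <- !(paste(res$chain, res$resno) %in% hasCa)
    if (any(miss))
      return(paste0("standard residue without CA: residue ",
                    res$resno[miss][1L]))
  }
  TRUE
})

#' ConformerEnsemble: an ordered set of same-sequence models
#'
#' @slot label character label, e.g. `"alpha5"` or `"state1"`.
#' @slot models list of [ConformerModel-class] objects sharing an identical
#'   (chain, residue number, residue name) sequence.
#'
#' @export
setClass("ConformerEnsemble",
  representation(label = "character", models = "list"),
  prototype(label = "ensemble")
)

setValidity("ConformerEnsemble", function(object) {
  if (length(object@models) == 0L) return("ensemble is empty")
  if (!all(vapply(object@models, is, TRUE, "ConformerModel")))
    return("models must all be ConformerModel objects")
  ref <- .residueTable(object@models[[1L]])
  for (i in seq_along(object@models)[-1L]) {
    cur <- .residueTable(object@models[[i]])
    bad <- .firstSequenceMismatch(ref, cur)
    if (!is.null(bad))
      return(sprintf(
        "model %d sequence differs from model %d at residue %s",
        object@models[[i]]@modelId, object@models[[1L]]@modelId, bad))
  }
  TRUE
})

.residueTable <- function(model) {
  a <- model@atoms
  unique(a[order(a$chain, a$resno), c("chain", "resno", "resname")])
}

## returns a residue label for the first mismatch, or NULL if identical
.firstSequenceMismatch <- function(ref, cur) {
  kr <- paste(ref$chain, ref$resno, ref$resname)
  kc <- paste(cur$chain, cur$resno, cur$resname)
  if (identical(kr, kc)) return(NULL)
  n <- max(length(kr), length(kc))
  for (i in seq_len(n)) {
    if (i > length(kr)) return(paste0(cur$resno[i], " (extra)"))
    if (i > length(kc)) return(paste0(ref$resno[i], " (missing)"))
    if (kr[i] != kc[i]) return(as.character(ref$resno[i]))
  }
  NULL
}

#' ShiftTable: assigned chemical shifts
#'
#' @slot shifts data.frame with columns `chain`, `resno`, `resname`, `atom`,
#'   `isotope` and `shift` (ppm). At most one entry per (chain, resno, atom).
#'
#' @export
setClass("ShiftTable", representation(shifts = "data.frame"))

setValidity("ShiftTable", function(object) {
  s <- object@shifts
  need <- c("chain", "resno", "resname", "atom", "isotope", "shift")
  if (!all(need %in% names(s)))
    return(paste("shifts must have columns:", paste(need, collapse = ", ")))
  if (nrow(s) && !all(is.finite(s$shift))) return("non-finite shift value")
  key <- paste(s$chain, s$resno, s$atom)
  if (anyDuplicated(key))
    return(paste0("duplicate shift for ", key[duplicated(key)][1L]))
  TRUE
})

#' PeakList: a 3D NOESY peak list
#'
#' Dimension order is (H donor, heavy atom X bonded to the donor, H acceptor).
#'
#' @slot spectrumType `"N15-NOESY"` or `"C13-NOESY"`.
#' @slot peaks data.frame with columns `id`, `wHdonor`, `wX`, `wHacceptor`
#'   (ppm) and `intensity` (`NA` when the list carries none).
#'
#' @export
setClass("PeakList",
  representation(spectrumType = "character", peaks = "data.frame")
)

setValidity("PeakList", function(object) {
  if (!object@spectrumType %in% c("N15-NOESY", "C13-NOESY"))
    return("spectrumType must be 'N15-NOESY' or 'C13-NOESY'")
  p <- object@peaks
  need <- c("id", "wHdonor", "wX", "wHacceptor", "intensity")
  if (!all(need %in% names(p)))
    return(paste("peaks must have columns:", paste(need, collapse = ", ")))
  if (nrow(p)) {
    w <- c(p$wHdonor, p$wX, p$wHacceptor)
    if (!all(is.finite(w))) return("non-finite peak frequency")
  }
  TRUE
})

#' MatchTolerances: peak-matching tolerances and distance settings
#'
#' @slot hPpm proton matching tolerance (ppm, default 0.05).
#' @slot cPpm carbon matching tolerance (ppm, default 0.4).
#' @slot nPpm nitrogen matching tolerance (ppm, default 0.5).
#' @slot distanceCutoff NOE distance cutoff (Angstrom, default 5.0, max 6.5).
#' @slot summarizer how per-model distances are summarised across an ensemble:
#'   one of `"per_model"`, `"min"`, `"midrange"`, `"median"`.
#' @slot equivalentMethod distance over equivalent-proton groups: `"min"`
#'   (default) or `"r6sum"` (r^-6 summed effective distance).
#'
#' @export
setClass("MatchTolerances",
  representation(
    hPpm = "numeric", cPpm = "numeric", nPpm = "numeric",
    distanceCutoff = "numeric", summarizer = "character",
    equivalentMethod = "character"
  ),
  prototype(hPpm = 0.05, cPpm = 0.4, nPpm = 0.5, distanceCutoff = 5.0,
            summarizer = "midrange", equivalentMethod = "min")
)

setValidity("MatchTolerances", function(object) {
  if (object@hPpm <= 0 || object@cPpm <= 0 || object@nPpm <= 0)
    return("tolerances must be positive")
  if (object@distanceCutoff <= 0 || object@distanceCutoff > 6.5)
    return("distance cutoff must be in (0, 6.5] Angstrom")
  if (!object@summarizer %in% c("per_model", "min", "midrange", "median"))
    return("unknown summarizer")
  if (!object@equivalentMethod %in% c("min", "r6sum"))
    return("equivalentMethod must be 'min' or 'r6sum'")
  TRUE
})

#' Construct matching tolerances
#'
#' @param hPpm,cPpm,nPpm ppm matching tolerances for 1H, 13C, 15N.
#' @param distanceCutoff NOE distance cutoff in Angstrom.
#' @param summarizer ensemble distance summarizer.
#' @param equivalentMethod `"min"` or `"r6sum"` over equivalent protons.
#' @return a [MatchTolerances-class] object.
#' @export
matchTolerances <- function(hPpm = 0.05, cPpm = 0.4, nPpm = 0.5,
                            distanceCutoff = 5.0, summarizer = "midrange",
                            equivalentMethod = "min") {
  new("MatchTolerances", hPpm = hPpm, cPpm = cPpm, nPpm = nPpm,
      distanceCutoff = distanceCutoff, summarizer = summarizer,
      equivalentMethod = equivalentMethod)
}

## ---------------------------------------------------------------------------
## Result containers
## ---------------------------------------------------------------------------

#' RciProfile: per-residue random coil index
#'
#' @slot profile data.frame with columns `chain`, `resno`, `resname`,
#'   `coverage` (number of resonance types used), `raw` (uncapped inverse
#'   weighted shift deviation), `capped` (ceiling 0.6 applied), `rci`
#'   (three-point smoothed final value) and `rci06` (`rci / 0.6`).
#' @slot coeffs the six weighting coefficients used (CA, CO, CB, N, HN, HA).
#'
#' @export
setClass("RciProfile",
  representation(profile = "data.frame", coeffs = "numeric"))

setValidity("RciProfile", function(object) {
  p <- object@profile
  need <- c("chain", "resno", "resname", "coverage", "raw", "capped",
            "rci", "rci06")
  if (!all(need %in% names(p)))
    return(paste("profile must have columns:", paste(need, collapse = ", ")))
  if (nrow(p)) {
    if (any(p$rci <= 0 | p$rci > 0.6 + 1e-12))
      return("smoothed RCI must lie in (0, 0.6]")
    if (any(p$coverage < 1)) return("residues with no usable resonance must be absent")
  }
  TRUE
})

#' RmsfProfile: per-residue root-mean-square fluctuation
#'
#' @slot residues integer residue numbers covered.
#' @slot rmsf numeric RMSF in Angstrom (>= 0), parallel to `residues`.
#' @slot source `"ensemble"` (coordinate-derived) or `"rci"` (shift-derived).
#'
#' @export
setClass("RmsfProfile",
  representation(residues = "integer", rmsf = "numeric", source = "character"))

setValidity("RmsfProfile", function(object) {
  if (length(object@residues) != length(object@rmsf))
    return("residues and rmsf lengths differ")
  if (any(object@rmsf < 0)) return("RMSF must be >= 0")
  if (!object@source %in% c("ensemble", "rci"))
    return("source must be 'ensemble' or 'rci'")
  TRUE
})

#' SanityReport: physical-plausibility flags per model
#'
#' @slot flags data.frame with one row per model: `modelId`, `dChirality`,
#'   `cisPeptide`, `missingBackbone` (comma-separated residue lists, empty
#'   string when clean) and `pass`.
#' @slot verdict `"pass"` iff every model is clean.
#'
#' @export
setClass("SanityReport",
  representation(flags = "data.frame", verdict = "character"))

setValidity("SanityReport", function(object) {
  f <- object@flags
  dirty <- f$dChirality != "" | f$cisPeptide != "" | f$missingBackbone != ""
  if (any(dirty != !f$pass)) return("pass flags inconsistent with flag lists")
  v <- if (any(dirty)) "fail" else "pass"
  if (!identical(object@verdict, v)) return("verdict inconsistent with flags")
  TRUE
})

#' RecallReport: NOESY peak explanation summary
#'
#' @slot peaks data.frame with one row per peak: `id`, `spectrum`, `status`
#'   (`explained`/`unexplained`/`unmatched`), `bestPair`, `bestDistance`,
#'   `donorRes`, `acceptorRes`.
#' @slot recall,precision,fMeasure aggregate scores in \[0, 1\].
#' @slot recallMin,recallMax context values when a model set was scored
#'   (`NA` otherwise).
#' @slot signature internal digest of the peak universe, used to verify that
#'   two reports being compared were built from identical peaks.
#'
#' @export
setClass("RecallReport",
  representation(
    peaks = "data.frame",
    recall = "numeric", precision = "numeric", fMeasure = "numeric",
    recallMin = "numeric", recallMax = "numeric",
    signature = "character"
  ),
  prototype(recallMin = NA_real_, recallMax = NA_real_, signature = "")
)

setValidity("RecallReport", function(object) {
  p <- object@peaks
  if (!all(p$status %in% c("explained", "unexplained", "unmatched")))
    return("unknown peak status")
  r <- sum(p$status == "explained") / nrow(p)
  if (nrow(p) && abs(r - object@recall) > 1e-9)
    return("recall inconsistent with per-peak statuses")
  for (v in c(object@recall, object@precision, object@fMeasure))
    if (!is.na(v) && (v < 0 || v > 1)) return("scores must lie in [0, 1]")
  TRUE
})

#' DoubleRecallResult: peaks uniquely explained by each of two ensembles
#'
#' @slot labelA,labelB ensemble labels.
#' @slot uniqueA,uniqueB,shared disjoint peak-id sets.
#' @slot contacts data.frame (`resI`, `resJ`, `set`, `count`): residue-pair
#'   contact counts, one row per (pair, set).
#' @slot histogram data.frame (`resno`, `set`, `count`): unique-peak counts
#'   by donor residue.
#' @slot longRange list with elements `uniqueA`, `uniqueB`, `shared`: the
#'   subsets with donor/acceptor sequence separation >= 5.
#'
#' @export
setClass("DoubleRecallResult",
  representation(
    labelA = "character", labelB = "character",
    uniqueA = "integer", uniqueB = "integer", shared = "integer",
    contacts = "data.frame", histogram = "data.frame", longRange = "list"
  )
)

setValidity("DoubleRecallResult", function(object) {
  if (length(intersect(object@uniqueA, object@uniqueB)) ||
      length(intersect(object@uniqueA, object@shared)) ||
      length(intersect(object@uniqueB, object@shared)))
    return("uniqueA, uniqueB and shared must be pairwise disjoint")
  TRUE
})

#' ClusterAssignment: PCA + hierarchical clustering of conformers
#'
#' @slot coords model-by-component principal component coordinate matrix
#'   (at least 3 columns when available).
#' @slot varExplained fraction of variance per retained component.
#' @slot labels integer cluster label per model (named by model id).
#' @slot populations fraction of models per cluster.
#' @slot linkage agglomeration method used.
#' @slot k number of clusters requested.
#' @slot seed seed recorded for provenance.
#'
#' @export
setClass("ClusterAssignment",
  representation(
    coords = "matrix", varExplained = "numeric", labels = "integer",
    populations = "numeric", linkage = "character", k = "integer",
    seed = "integer"
  )
)

setValidity("ClusterAssignment", function(object) {
  if (length(object@labels) != nrow(object@coords))
    return("one label per model required")
  if (sum(object@varExplained) > 1 + 1e-8)
    return("explained-variance fractions must sum to <= 1")
  if (abs(sum(object@populations) - 1) > 1e-8)
    return("cluster populations must sum to 1")
  TRUE
})

#' StateCombination: greedy multi-state assembly trace
#'
#' @slot states list of accepted candidates; each element has `label` and
#'   `modelIds`.
#' @slot trajectory CCC value after each accepted addition (strictly
#'   increasing).
#' @slot rejected data.frame (`label`, `reason`).
#' @slot finalCcc final combined concordance.
#' @slot adequate logical: final CCC >= the adequacy threshold (0.4).
#' @slot failed logical: TRUE when the state-1 entry test (CCC <= 0) aborted
#'   the combination.
#'
#' @export
setClass("StateCombination",
  representation(
    states = "list", trajectory = "numeric", rejected = "data.frame",
    finalCcc = "numeric", adequate = "logical", failed = "logical"
  )
)

setValidity("StateCombination", function(object) {
  tr <- object@trajectory
  if (length(tr) > 1 && any(diff(tr) <= 0))
    return("CCC trajectory must be strictly increasing")
  if (!object@failed && length(tr) &&
      !identical(object@adequate, object@finalCcc >= 0.4))
    return("adequacy flag inconsistent with final CCC")
  TRUE
})

## ---------------------------------------------------------------------------
## show methods
## ---------------------------------------------------------------------------

setMethod("show", "ConformerModel", function(object) {
  cat(sprintf("ConformerModel #%d: %d atoms, %d residues, pTM %s\n",
              object@modelId, nrow(object@atoms),
              nrow(.residueTable(object)),
              ifelse(is.na(object@ptm), "NA", format(object@ptm))))
})

setMethod("show", "ConformerEnsemble", function(object) {
  cat(sprintf("ConformerEnsemble '%s': %d models, %d residues\n",
              object@label, length(object@models),
              nrow(.residueTable(object@models[[1L]]))))
})

setMethod("show", "ShiftTable", function(object) {
  cat(sprintf("ShiftTable: %d shifts, %d residues\n",
              nrow(object@shifts),
              length(unique(paste(object@shifts$chain, object@shifts$resno)))))
})

setMethod("show", "PeakList", function(object) {
  cat(sprintf("PeakList (%s): %d peaks\n",
              object@spectrumType, nrow(object@peaks)))
})

setMethod("show", "RciProfile", function(object) {
  p <- object@profile
  cat(sprintf("RciProfile: %d residues, RCI range [%.3f, %.3f]\n",
              nrow(p), min(p$rci), max(p$rci)))
})

setMethod("show", "RmsfProfile", function(object) {
  cat(sprintf("RmsfProfile (%s): %d residues, mean %.2f A\n",
              object@source, length(object@residues), mean(object@rmsf)))
})

setMethod("show", "RecallReport", function(object) {
  cat(sprintf(
    "RecallReport: %d peaks | recall %.3f precision %.3f F %.3f\n",
    nrow(object@peaks), object@recall, object@precision, object@fMeasure))
})

setMethod("show", "DoubleRecallResult", function(object) {
  cat(sprintf(
    "DoubleRecall %s vs %s: unique A %d, unique B %d, shared %d\n",
    object@labelA, object@labelB, length(object@uniqueA),
    length(object@uniqueB), length(object@shared)))
})

setMethod("show", "ClusterAssignment", function(object) {
  cat(sprintf("ClusterAssignment: %d models in %d clusters (%s linkage)\n",
              length(object@labels), object@k, object@linkage))
  cat("  populations:", paste(sprintf("%.2f", object@populations),
                              collapse = " "), "\n")
})

setMethod("show", "StateCombination", function(object) {
  if (object@failed) {
    cat("StateCombination: FAILED entry test (CCC(state 1) <= 0)\n")
  } else {
    cat(sprintf(
      "StateCombination: %d state(s), final CCC %.3f (%s)\n",
      length(object@states), object@finalCcc,
      if (object@adequate) "adequate" else "inadequate"))
  }
})

## ---------------------------------------------------------------------------
## accessors and small generics
## ---------------------------------------------------------------------------

#' @rdname accessors
#' @param x,object a ConformerSelect object.
#' @param i index.
#' @param ... unused.
#' @export
setGeneric("models", function(x) standardGeneric("models"))
#' @rdname accessors
#' @export
setMethod("models", "ConformerEnsemble", function(x) x@models)

#' @rdname accessors
#' @export
setGeneric("ensembleLabel", function(x) standardGeneric("ensembleLabel"))
#' @rdname accessors
#' @export
setMethod("ensembleLabel", "ConformerEnsemble", function(x) x@label)

#' @rdname accessors
#' @export
setGeneric("nModels", function(x) standardGeneric("nModels"))
#' @rdname accessors
#' @export
setMethod("nModels", "ConformerEnsemble", function(x) length(x@models))

#' Subset an ensemble by model position
#' @param x a [ConformerEnsemble-class].
#' @param i integer or logical index over models.
#' @param j,drop unused.
#' @param ... unused.
#' @export
setMethod("[", "ConformerEnsemble", function(x, i, j, ..., drop = FALSE) {
  new("ConformerEnsemble", label = x@label, models = x@models[i])
})

#' @rdname accessors
#' @export
setGeneric("shifts", function(x) standardGeneric("shifts"))
#' @rdname accessors
#' @export
setMethod("shifts", "ShiftTable", function(x) x@shifts)

#' @rdname accessors
#' @export
setGeneric("peaks", function(x) standardGeneric("peaks"))
#' @rdname accessors
#' @export
setMethod("peaks", "PeakList", function(x) x@peaks)
#' @rdname accessors
#' @export
setMethod("peaks", "RecallReport", function(x) x@peaks)

#' @rdname accessors
#' @export
setGeneric("rciProfile", function(x) standardGeneric("rciProfile"))
#' @rdname accessors
#' @export
setMethod("rciProfile", "RciProfile", function(x) x@profile)

#' @rdname accessors
#' @export
setGeneric("rmsf", function(x) standardGeneric("rmsf"))
#' @rdname accessors
#' @export
setMethod("rmsf", "RmsfProfile", function(x) {
  stats::setNames(x@rmsf, x@residues)
})

#' @rdname accessors
#' @export
setGeneric("recallScore", function(x) standardGeneric("recallScore"))
#' @rdname accessors
#' @export
setMethod("recallScore", "RecallReport", function(x) x@recall)

#' @rdname accessors
#' @export
setGeneric("precisionScore", function(x) standardGeneric("precisionScore"))
#' @rdname accessors
#' @export
setMethod("precisionScore", "RecallReport", function(x) x@precision)

#' @rdname accessors
#' @export
setGeneric("fMeasure", function(x) standardGeneric("fMeasure"))
#' @rdname accessors
#' @export
setMethod("fMeasure", "RecallReport", function(x) x@fMeasure)

#' @rdname accessors
#' @export
setGeneric("explainedPeaks", function(x) standardGeneric("explainedPeaks"))
#' @rdname accessors
#' @export
setMethod("explainedPeaks", "RecallReport", function(x) {
  x@peaks$id[x@peaks$status == "explained"]
})

#' @rdname accessors
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))
#' @rdname accessors
#' @export
setMethod("clusterLabels", "ClusterAssignment", function(x) x@labels)

#' @rdname accessors
#' @export
setGeneric("acceptedStates", function(x) standardGeneric("acceptedStates"))
#' @rdname accessors
#' @export
setMethod("acceptedStates", "StateCombination", function(x) x@states)

#' @rdname accessors
#' @export
setGeneric("cccTrajectory", function(x) standardGeneric("cccTrajectory"))
#' @rdname accessors
#' @export
setMethod("cccTrajectory", "StateCombination", function(x) x@trajectory)
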