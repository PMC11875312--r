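## Configuration-driven pipeline: sanity filter -> recall & RCI scoring ->
## PCA / clustering -> candidate ensembles -> state combination ->
## Double Recall of the final states.

.configKeys <- c("ensemble", "shifts", "peaks", "fixture", "tolerances",
                 "rci", "clustering", "kTop", "scoreVariant", "alignRanges",
                 "outDir", "seed", "adequacyThreshold")

#' Read and validate a YAML pipeline configuration
#'
#' Unknown top-level keys are rejected. Recognised keys: `fixture` (list of
#' [fixtureSpec()] arguments) or the input triple `ensemble`
#' (`path`/`fmt`/`ptm`), `shifts` (`path`/`dialect`) and `peaks` (list of
#' `path`/`spectrum` entries); `tolerances` ([matchTolerances()] arguments);
#' `rci` (`coeffs`, `randomCoil` path); `clustering` (`k`, `linkage`,
#' `seed`); `kTop`; `scoreVariant`; `alignRanges` (`"auto"` or a range
#' string); `outDir`; `seed`; `adequacyThreshold`.
#'
#' @param path YAML file.
#' @return validated config list.
#' @export
readPipelineConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  validatePipelineConfig(cfg)
}

#' @rdname readPipelineConfig
#' @param cfg a config list (as from YAML).
#' @export
validatePipelineConfig <- function(cfg) {
  unknown <- setdiff(names(cfg), .configKeys)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  if (is.null(cfg$fixture) && (is.null(cfg$ensemble) || is.null(cfg$shifts) ||
                               is.null(cfg$peaks)))
    stop("config needs either 'fixture' or all of 'ensemble', 'shifts', 'peaks'")
  cfg$kTop <- if (is.null(cfg$kTop)) 5L else as.integer(cfg$kTop)
  if (is.null(cfg$scoreVariant)) cfg$scoreVariant <- "geometric"
  if (is.null(cfg$alignRanges)) cfg$alignRanges <- "auto"
  if (is.null(cfg$seed)) cfg$seed <- 1L
  if (is.null(cfg$adequacyThreshold)) cfg$adequacyThreshold <- 0.4
  cfg
}

#' Run the full conformer-selection pipeline
#'
#' Stage order: load (or generate) inputs; physical-sanity filter; RCI and
#' shift-derived RMSF; per-model Bayesian scoring; PCA + clustering;
#' candidate single-state ensembles; greedy state combination; Double Recall
#' of the two top states. All intermediate tables and the thresholds actually
#' used are written under `outDir`. A stage failure aborts with the stage
#' name; partial outputs are retained.
#'
#' @param cfg config list (see [readPipelineConfig()]) or a YAML path.
#' @return summary list with `nStates`, `finalCcc`, `adequate`, `scores`,
#'   `clusters`, `combination`, `doubleRecall` (or `NULL`), `outDir`.
#' @export
runPipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- readPipelineConfig(cfg)
  cfg <- validatePipelineConfig(cfg)
  outDir <- cfg$outDir
  if (!is.null(outDir) && !dir.exists(outDir))
    dir.create(outDir, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  tol <- do.call(matchTolerances, as.list(cfg$tolerances))

  ## --- inputs -------------------------------------------------------------
  inputs <- stage("load", {
    if (!is.null(cfg$fixture)) {
      spec <- do.call(fixtureSpec, c(as.list(cfg$fixture),
                                     if (is.null(cfg$fixture$seed))
                                       list(seed = cfg$seed)))
      fx <- makeTwoStateEnsemble(spec)
      nmr <- makeSyntheticNmr(fx, tol)
      list(ens = fx$pooled, st = nmr$shifts, peaks = nmr$peaks, fixture = fx)
    } else {
      ens <- readEnsemble(cfg$ensemble$path,
                          fmt = if (is.null(cfg$ensemble$fmt)) "pdb"
                                else cfg$ensemble$fmt,
                          ptmFile = cfg$ensemble$ptm)
      st <- readShiftTable(cfg$shifts$path,
                           dialect = if (is.null(cfg$shifts$dialect)) "tsv"
                                     else cfg$shifts$dialect)
      pk <- lapply(cfg$peaks, function(p)
        readPeakList(p$path, spectrumType = p$spectrum))
      list(ens = ens, st = st, peaks = pk, fixture = NULL)
    }
  })

  ## --- sanity filter -------------------------------------------------------
  filt <- stage("sanity-filter", sanityFilter(inputs$ens))
  ens <- filt$ensemble

  ## --- RCI -----------------------------------------------------------------
  rci <- stage("rci", {
    coeffs <- if (!is.null(cfg$rci$coeffs)) unlist(cfg$rci$coeffs)
              else defaultRciCoeffs()
    rcTab <- randomCoilTable(cfg$rci$randomCoil)
    computeRci(inputs$st, coeffs = coeffs, randomCoil = rcTab)
  })
  rmsfRci <- rmsfFromRci(rci)

  ## --- per-model scoring ---------------------------------------------------
  scores <- stage("score", scoreModels(ens, inputs$peaks, inputs$st, rci,
                                       tol = tol, variant = cfg$scoreVariant))

  ## --- clustering ----------------------------------------------------------
  clusters <- stage("cluster", {
    k <- if (is.null(cfg$clustering$k)) 4L else cfg$clustering$k
    linkage <- if (is.null(cfg$clustering$linkage)) "ward.D2"
               else cfg$clustering$linkage
    pcaCluster(ens, k = k, linkage = linkage,
               seed = if (is.null(cfg$clustering$seed)) cfg$seed
                      else cfg$clustering$seed)
  })

  ## --- candidates and state combination ------------------------------------
  align <- stage("align-ranges", {
    if (identical(cfg$alignRanges, "auto")) {
      ## superpose on residues that are BOTH structurally well-defined and
      ## rigid according to the shift data (RMSF_RCI <= 2 A): with multiple
      ## underlying states a purely structural criterion under global
      ## superposition dilutes the apparent motion and fails to exclude the
      ## moving segment
      wdr <- wellDefinedRanges(ens)
      rigid <- rmsfRci@residues[rmsfRci@rmsf <= 2.0]
      sel <- intersect(wdr, rigid)
      if (length(sel) >= 5L) sel else wdr
    } else parseRanges(cfg$alignRanges)
  })
  candidates <- stage("candidates",
                      buildCandidateEnsembles(clusters, scores, ens,
                                              kTop = cfg$kTop))
  combo <- stage("combine-states",
                 combineStates(candidates, rmsfRci, alignResidues = align,
                               adequacyThreshold = cfg$adequacyThreshold))

  ## --- Double Recall of the two top states ---------------------------------
  dr <- NULL
  if (length(combo@states) >= 2L) {
    dr <- stage("double-recall", {
      byLabel <- stats::setNames(candidates,
                                 vapply(candidates, `[[`, "", "label"))
      sA <- byLabel[[combo@states[[1L]]$label]]$ensemble
      sB <- byLabel[[combo@states[[2L]]$label]]$ensemble
      repA <- scoreRecall(inputs$peaks, inputs$st, sA, tol)
      repB <- scoreRecall(inputs$peaks, inputs$st, sB, tol)
      doubleRecall(repA, repB, labelA = combo@states[[1L]]$label,
                   labelB = combo@states[[2L]]$label)
    })
  } else {
    message("single-state result: Double Recall skipped")
  }

  ## --- artifacts -----------------------------------------------------------
  if (!is.null(outDir)) {
    utils::write.table(scores, file.path(outDir, "scores.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    cl <- data.frame(modelId = as.integer(names(clusters@labels)),
                     cluster = clusters@labels,
                     clusters@coords, check.names = FALSE)
    utils::write.table(cl, file.path(outDir, "clusters.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    jsonlite::write_json(list(
      linkage = clusters@linkage, k = clusters@k, seed = clusters@seed,
      varExplained = clusters@varExplained,
      populations = clusters@populations),
      file.path(outDir, "clusters.json"), auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(list(
      states = combo@states, trajectory = combo@trajectory,
      finalCcc = combo@finalCcc, adequate = combo@adequate,
      failed = combo@failed,
      rejected = combo@rejected),
      file.path(outDir, "state_combination.json"), auto_unbox = TRUE,
      digits = NA)
    byLabel <- stats::setNames(candidates,
                               vapply(candidates, `[[`, "", "label"))
    for (s in combo@states)
      writeEnsemble(byLabel[[s$label]]$ensemble,
                    file.path(outDir, paste0(s$label, ".pdb")))
    if (length(combo@states))
      writeEnsemble(poolStates(lapply(combo@states, function(s)
        byLabel[[s$label]]$ensemble)), file.path(outDir, "pooled_states.pdb"))
    if (!is.null(dr))
      writeDoubleRecall(dr, file.path(outDir, "double_recall_contacts.tsv"))
    jsonlite::write_json(list(
      tolerances = list(hPpm = tol@hPpm, cPpm = tol@cPpm, nPpm = tol@nPpm,
                        distanceCutoff = tol@distanceCutoff,
                        summarizer = tol@summarizer,
                        equivalentMethod = tol@equivalentMethod),
      rciCoeffs = as.list(rci@coeffs), kTop = cfg$kTop,
      scoreVariant = cfg$scoreVariant, alignResidues = formatRanges(align),
      seed = cfg$seed, adequacyThreshold = cfg$adequacyThreshold,
      sanityVerdict = filt$report@verdict),
      file.path(outDir, "run_log.json"), auto_unbox = TRUE, digits = NA)
  }

  list(nStates = length(combo@states), finalCcc = combo@finalCcc,
       adequate = combo@adequate, failed = combo@failed, scores = scores,
       clusters = clusters, candidates = candidates, combination = combo,
       doubleRecall = dr, rci = rci, sanity = filt$report,
       alignResidues = align, outDir = outDir)
}

#' Write a recall report (per-peak TSV plus aggregate JSON)
#'
#' @param report a [RecallReport-class].
#' @param prefix output path prefix; writes `<prefix>.tsv` and
#'   `<prefix>.json`.
#' @return invisibly, the prefix.
#' @export
writeRecallReport <- function(report, prefix) {
  utils::write.table(report@peaks, paste0(prefix, ".tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(recall = report@recall,
                            precision = report@precision,
                            fMeasure = report@fMeasure,
                            recallMin = report@recallMin,
                            recallMax = report@recallMax),
                       paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(prefix)
}
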