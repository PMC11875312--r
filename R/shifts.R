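## Random coil index (RCI) and RCI-derived RMSF from chemical shifts.

#' Default RCI weighting coefficients
#'
#' Weights applied to the absolute secondary shifts of the six backbone
#' resonance types when forming the per-residue weighted mean. Carbon shifts
#' carry most of the weight, as in the original random-coil-index method.
#' These are package defaults and are fully configurable; exact parity with
#' any particular RCI server implementation is not promised.
#'
#' @return named numeric vector with elements `CA`, `CO`, `CB`, `N`, `HN`,
#'   `HA`.
#' @export
defaultRciCoeffs <- function() {
  c(CA = 0.74, CO = 0.72, CB = 0.13, N = 0.38, HN = 0.15, HA = 0.60)
}

#' Packaged random-coil reference shifts
#'
#' Literature-style random-coil chemical shifts for the 20 standard amino
#' acids (atoms CA, CB, C, N, H, HA). User-replaceable: any data.frame with
#' columns `residue_type`, `atom_name`, `shift_ppm` works.
#'
#' @param path optional path to an alternative TSV table.
#' @return data.frame with columns `residue_type`, `atom_name`, `shift_ppm`.
#' @export
randomCoilTable <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "random_coil_shifts.tsv",
                        package = "ConformerSelect", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

## map an observed atom name to one of the six RCI resonance types
.rciType <- function(atom) {
  switch(atom,
         CA = "CA", C = "CO", CB = "CB", N = "N",
         H = "HN", HN = "HN", HA = "HA", HA2 = "HA", HA3 = "HA",
         NA_character_)
}

#' Compute the per-residue random coil index
#'
#' For each residue the secondary shifts `delta_obs - delta_random_coil` of
#' the available backbone resonances (Calpha, CO, Cbeta, N, amide H, Halpha)
#' are combined as a weighted mean of absolute values, with the weights
#' renormalised over the resonances actually present (so a missing Cbeta does
#' not bias the result). The raw RCI is the reciprocal of that mean; values
#' above 0.6 are replaced by the ceiling 0.6 (a weighted mean of zero gives
#' raw RCI +Inf, capped to 0.6 rather than erroring). A sliding three-point
#' mean along the sequence (window shrunk at chain ends and gaps) yields the
#' final RCI, and `rci06 = RCI / 0.6` rescales it to (0, 1].
#'
#' @param st a [ShiftTable-class] of observed shifts.
#' @param coeffs six positive weights named `CA`, `CO`, `CB`, `N`, `HN`,
#'   `HA` (default [defaultRciCoeffs()]).
#' @param randomCoil random-coil reference data.frame
#'   (default [randomCoilTable()]).
#' @return an [RciProfile-class].
#' @export
computeRci <- function(st, coeffs = defaultRciCoeffs(),
                       randomCoil = randomCoilTable()) {
  if (any(coeffs <= 0)) stop("coefficients must be positive")
  need <- c("CA", "CO", "CB", "N", "HN", "HA")
  if (!all(need %in% names(coeffs)))
    stop("coeffs must be named ", paste(need, collapse = ", "))
  s <- st@shifts
  rcKey <- paste(randomCoil$residue_type, randomCoil$atom_name)
  rcVal <- stats::setNames(randomCoil$shift_ppm, rcKey)
  resKey <- paste(s$chain, s$resno, sep = ":")
  rows <- list()
  for (k in unique(resKey)) {
    sub <- s[resKey == k, ]
    rt <- sub$resname[1L]
    if (!rt %in% randomCoil$residue_type) {
      warning("residue type ", rt, " absent from random-coil table: skipped")
      next
    }
    types <- vapply(sub$atom, .rciType, "")
    dd <- numeric(0)
    for (ty in intersect(need, types[!is.na(types)])) {
      atomsOfType <- sub$atom[!is.na(types) & types == ty]
      ## random-coil name: HN is stored as H; others match directly
      rcAtom <- switch(ty, HN = "H", CO = "C", HA = "HA", ty)
      rc <- rcVal[paste(rt, rcAtom)]
      if (is.na(rc)) next
      obs <- mean(sub$shift[sub$atom %in% atomsOfType])
      dd[ty] <- abs(obs - rc)
    }
    if (!length(dd)) next
    w <- coeffs[names(dd)]
    wm <- sum(w * dd) / sum(w)
    raw <- if (wm == 0) Inf else 1 / wm
    rows[[length(rows) + 1L]] <- data.frame(
      chain = sub$chain[1L], resno = sub$resno[1L], resname = rt,
      coverage = length(dd), raw = raw, capped = min(raw, 0.6),
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("no residue with usable resonances")
  p <- do.call(rbind, rows)
  p <- p[order(p$chain, p$resno), ]
  rownames(p) <- NULL
  ## three-point smoothing, window shrunk at ends and across gaps
  p$rci <- vapply(seq_len(nrow(p)), function(i) {
    win <- which(p$chain == p$chain[i] & abs(p$resno - p$resno[i]) <= 1L)
    mean(p$capped[win])
  }, 0)
  p$rci06 <- p$rci / 0.6
  new("RciProfile", profile = p, coeffs = coeffs[need])
}

#' Shift-derived RMSF estimate
#'
#' Converts the final smoothed RCI into a per-residue fluctuation estimate,
#' `RMSF_RCI = RCI x 12.7` Angstrom. Residues absent from the RCI profile are
#' absent here too.
#'
#' @param profile an [RciProfile-class].
#' @return an [RmsfProfile-class] with source `"rci"`.
#' @export
rmsfFromRci <- function(profile) {
  p <- profile@profile
  new("RmsfProfile", residues = as.integer(p$resno),
      rmsf = p$rci * 12.7, source = "rci")
}
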