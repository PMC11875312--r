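## Amino-acid nomenclature helpers (PDB v3 atom names).

.aa1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V"
)

## Heavy atom covalently bonded to a given proton. Backbone amide H (named
## "H" or "HN") binds N; all other protons bind the carbon of the matching
## greek position (HA -> CA, HB* -> CB, HG1* -> CG1, ...). Side-chain amide
## and amine protons of Asn/Gln/Lys/Arg/Trp/His are mapped to their nitrogens.
.bondedHeavy <- function(resname, atom) {
  if (atom %in% c("H", "HN")) return("N")
  nitro <- list(
    ASN = c(HD21 = "ND2", HD22 = "ND2"),
    GLN = c(HE21 = "NE2", HE22 = "NE2"),
    LYS = c(HZ1 = "NZ", HZ2 = "NZ", HZ3 = "NZ"),
    ARG = c(HE = "NE", HH11 = "NH1", HH12 = "NH1", HH21 = "NH2", HH22 = "NH2"),
    TRP = c(HE1 = "NE1"),
    HIS = c(HD1 = "ND1", HE2 = "NE2")
  )
  if (!is.null(nitro[[resname]]) && atom %in% names(nitro[[resname]]))
    return(unname(nitro[[resname]][atom]))
  if (!startsWith(atom, "H")) stop("not a proton: ", atom)
  stem <- sub("[0-9]+$", "", substring(atom, 2L))
  if (stem == "") stem <- substring(atom, 2L)   # e.g. HA2 of Gly -> A
  paste0("C", stem)
}

## Isotope label of a heavy atom name.
.heavyIsotope <- function(atom) {
  switch(substring(atom, 1L, 1L), N = "15N", C = "13C", O = "O", S = "S",
         stop("unexpected heavy atom: ", atom))
}

## Equivalent-proton group key: protons that are degenerate in solution
## (methyl rotors, Phe/Tyr ring pairs) collapse to one group. The key is
## unique per (chain, residue, group).
.methylSets <- list(
  ALA = list(QB = c("HB1", "HB2", "HB3")),
  VAL = list(QG1 = c("HG11", "HG12", "HG13"), QG2 = c("HG21", "HG22", "HG23")),
  LEU = list(QD1 = c("HD11", "HD12", "HD13"), QD2 = c("HD21", "HD22", "HD23")),
  ILE = list(QG2 = c("HG21", "HG22", "HG23"), QD1 = c("HD11", "HD12", "HD13")),
  THR = list(QG2 = c("HG21", "HG22", "HG23")),
  MET = list(QE = c("HE1", "HE2", "HE3")),
  PHE = list(QD = c("HD1", "HD2"), QE = c("HE1", "HE2")),
  TYR = list(QD = c("HD1", "HD2"), QE = c("HE1", "HE2"))
)

.protonGroup <- function(resname, atom) {
  sets <- .methylSets[[resname]]
  if (!is.null(sets)) {
    for (g in names(sets)) if (atom %in% sets[[g]]) return(g)
  }
  atom
}

## Members of the group that a proton belongs to (itself when not grouped).
## Accepts either a member atom name or a group key (e.g. "QB").
.groupMembers <- function(resname, atom) {
  sets <- .methylSets[[resname]]
  if (!is.null(sets)) {
    if (atom %in% names(sets)) return(sets[[atom]])
    for (g in names(sets)) if (atom %in% sets[[g]]) return(sets[[g]])
  }
  atom
}

## Parse "start-end[,start-end...]" 1-based inclusive range strings.
#' Parse a residue-range string
#'
#' Ranges are written `"start-end[,start-end...]"`, 1-based inclusive,
#' e.g. `"7-19,34-81"`.
#'
#' @param txt range string.
#' @return integer vector of residue numbers.
#' @export
parseRanges <- function(txt) {
  parts <- strsplit(gsub(" ", "", txt), ",", fixed = TRUE)[[1L]]
  out <- integer(0)
  for (p in parts) {
    se <- as.integer(strsplit(p, "-", fixed = TRUE)[[1L]])
    if (length(se) == 1L) out <- c(out, se)
    else out <- c(out, seq.int(se[1L], se[2L]))
  }
  sort(unique(out))
}

#' Format residue numbers as a range string
#'
#' @param residues integer residue numbers.
#' @return `"start-end[,start-end...]"` string.
#' @export
formatRanges <- function(residues) {
  if (!length(residues)) return("")
  r <- sort(unique(as.integer(residues)))
  brk <- c(0L, which(diff(r) > 1L), length(r))
  paste(vapply(seq_len(length(brk) - 1L), function(i) {
    seg <- r[(brk[i] + 1L):brk[i + 1L]]
    if (length(seg) == 1L) as.character(seg)
    else paste0(seg[1L], "-", seg[length(seg)])
  }, ""), collapse = ",")
}
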