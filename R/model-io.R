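## Readers and writers for conformer ensembles, confidence metadata,
## chemical-shift tables and NOESY peak lists.

#' Read a conformer ensemble from a multi-model PDB or mmCIF file
#'
#' One [ConformerModel-class] is created per `MODEL` record (or per
#' `pdbx_PDB_model_num` block in mmCIF). Per-residue pLDDT is taken as the
#' mean of the atom B-factor values within the residue, following the
#' convention of AI structure predictors that store pLDDT in the B-factor
#' column. If every B-factor in the file is <= 1.01 the values are assumed to
#' be on a 0-1 scale and are rescaled by 100 with a warning. Insertion codes
#' are not supported; for alternate locations the first altloc wins with a
#' warning.
#'
#' @param path file path.
#' @param fmt `"pdb"` or `"mmcif"`.
#' @param label ensemble label.
#' @param ptmFile optional path to a JSON sidecar mapping model id to pTM
#'   (coordinate formats have no standard pTM slot). Models without an entry
#'   default to the neutral prior 1.0 with a warning.
#' @return a [ConformerEnsemble-class].
#' @export
readEnsemble <- function(path, fmt = c("pdb", "mmcif"), label = NULL,
                         ptmFile = NULL) {
  fmt <- match.arg(fmt)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(label)) label <- sub("\\.[^.]*$", "", basename(path))
  tabs <- switch(fmt, pdb = .parsePdb(path), mmcif = .parseMmcif(path))
  if (!length(tabs)) stop("no atomic coordinates found in ", path)
  allB <- unlist(lapply(tabs, `[[`, "b"))
  rescale <- all(allB <= 1.01)
  if (rescale)
    warning("all B-factors <= 1.01: assuming 0-1 pLDDT scale, rescaling by 100")
  mods <- lapply(tabs, function(a) {
    if (rescale) a$b <- a$b * 100
    key <- paste(a$chain, a$resno, sep = ":")
    plddt <- vapply(split(a$b, key), mean, 0)
    ## keep residue order
    plddt <- plddt[unique(key)]
    new("ConformerModel", modelId = a$model[1L],
        atoms = a[setdiff(names(a), "model")], plddt = plddt, ptm = NA_real_)
  })
  ens <- new("ConformerEnsemble", label = label, models = mods)
  if (!is.null(ptmFile)) ens <- applyPtmSidecar(ens, ptmFile)
  ens
}

.parsePdb <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- substring(lines, 1L, 6L)
  modelNo <- 1L
  inBlock <- FALSE
  out <- list()
  cur <- list()
  flush <- function() {
    if (length(cur)) {
      df <- do.call(rbind, cur)
      out[[length(out) + 1L]] <<- df
    }
    cur <<- list()
  }
  seenAlt <- FALSE
  for (i in seq_along(lines)) {
    r <- rec[i]
    if (startsWith(r, "MODEL")) {
      flush()
      modelNo <- suppressWarnings(as.integer(substring(lines[i], 11L, 14L)))
      if (is.na(modelNo)) modelNo <- length(out) + 1L
      inBlock <- TRUE
    } else if (startsWith(r, "ENDMDL")) {
      flush()
      inBlock <- FALSE
    } else if (r == "ATOM  " || r == "HETATM") {
      l <- lines[i]
      ins <- substring(l, 27L, 27L)
      if (ins != " ")
        stop("insertion codes are not supported (line ", i, ")")
      alt <- substring(l, 17L, 17L)
      if (!alt %in% c(" ", "A", "1")) { seenAlt <- TRUE; next }
      if (alt != " ") seenAlt <- TRUE
      xyz <- as.numeric(c(substring(l, 31L, 38L), substring(l, 39L, 46L),
                          substring(l, 47L, 54L)))
      b <- suppressWarnings(as.numeric(substring(l, 61L, 66L)))
      if (is.na(b)) b <- 0
      cur[[length(cur) + 1L]] <- data.frame(
        model = if (inBlock) modelNo else 1L,
        chain = substring(l, 22L, 22L),
        resno = as.integer(substring(l, 23L, 26L)),
        resname = trimws(substring(l, 18L, 20L)),
        atom = trimws(substring(l, 13L, 16L)),
        element = trimws(substring(l, 77L, 78L)),
        x = xyz[1L], y = xyz[2L], z = xyz[3L], b = b,
        stringsAsFactors = FALSE)
    }
  }
  flush()
  if (seenAlt) warning("alternate locations present: first altloc kept")
  out <- lapply(out, function(df) { rownames(df) <- NULL; df })
  out[vapply(out, nrow, 0L) > 0L]
}

## Minimal mmCIF _atom_site loop reader (multi-model via pdbx_PDB_model_num).
.parseMmcif <- function(path) {
  lines <- readLines(path, warn = FALSE)
  i <- 1L
  n <- length(lines)
  tags <- character(0)
  rows <- list()
  while (i <= n) {
    if (trimws(lines[i]) == "loop_") {
      j <- i + 1L
      ltags <- character(0)
      while (j <= n && startsWith(trimws(lines[j]), "_")) {
        ltags <- c(ltags, trimws(lines[j])); j <- j + 1L
      }
      if (any(startsWith(ltags, "_atom_site."))) {
        tags <- sub("^_atom_site\\.", "", ltags)
        while (j <= n) {
          t <- trimws(lines[j])
          if (t == "" || startsWith(t, "#") || startsWith(t, "_") ||
              t == "loop_" || startsWith(t, "data_")) break
          rows[[length(rows) + 1L]] <- scan(text = lines[j], what = "",
                                            quiet = TRUE)
          j <- j + 1L
        }
        break
      }
      i <- j
    } else i <- i + 1L
  }
  if (!length(rows)) return(list())
  m <- do.call(rbind, rows)
  colnames(m) <- tags
  pick <- function(auth, lab) {
    if (auth %in% tags) m[, auth] else if (lab %in% tags) m[, lab]
    else stop("mmCIF _atom_site missing column ", auth, "/", lab)
  }
  if ("pdbx_PDB_ins_code" %in% tags &&
      any(!m[, "pdbx_PDB_ins_code"] %in% c("?", ".")))
    stop("insertion codes are not supported")
  keep <- m[, "group_PDB"] %in% c("ATOM", "HETATM")
  m <- m[keep, , drop = FALSE]
  if ("label_alt_id" %in% tags) {
    alt <- m[, "label_alt_id"]
    sel <- alt %in% c(".", "?", "A", "1")
    if (!all(sel)) warning("alternate locations present: first altloc kept")
    m <- m[sel, , drop = FALSE]
  }
  df <- data.frame(
    model = if ("pdbx_PDB_model_num" %in% tags)
      as.integer(m[, "pdbx_PDB_model_num"]) else 1L,
    chain = pick("auth_asym_id", "label_asym_id"),
    resno = as.integer(pick("auth_seq_id", "label_seq_id")),
    resname = pick("auth_comp_id", "label_comp_id"),
    atom = gsub('"', "", pick("auth_atom_id", "label_atom_id")),
    element = if ("type_symbol" %in% tags) m[, "type_symbol"] else "",
    x = as.numeric(m[, "Cartn_x"]), y = as.numeric(m[, "Cartn_y"]),
    z = as.numeric(m[, "Cartn_z"]),
    b = if ("B_iso_or_equiv" %in% tags)
      as.numeric(m[, "B_iso_or_equiv"]) else 0,
    stringsAsFactors = FALSE)
  split(df, df$model)
}

#' Attach pTM scores from a JSON sidecar
#'
#' @param ens a [ConformerEnsemble-class].
#' @param path JSON file mapping model id (as a string) to pTM in \[0, 1\].
#' @return the ensemble with `ptm` slots filled.
#' @export
applyPtmSidecar <- function(ens, path) {
  ptm <- jsonlite::read_json(path, simplifyVector = TRUE)
  missing <- character(0)
  ens@models <- lapply(ens@models, function(m) {
    key <- as.character(m@modelId)
    if (!is.null(ptm[[key]]) && is.finite(as.numeric(ptm[[key]]))) {
      m@ptm <- as.numeric(ptm[[key]])
    } else {
      missing <<- c(missing, key)
      m@ptm <- 1.0
    }
    m
  })
  if (length(missing))
    warning("no pTM for model(s) ", paste(missing, collapse = ", "),
            ": using neutral prior 1.0")
  ens
}

#' Write an ensemble as a multi-model PDB file
#'
#' Coordinates are written at 3-decimal precision; the B-factor column
#' carries the per-residue pLDDT.
#'
#' @param ens a [ConformerEnsemble-class].
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeEnsemble <- function(ens, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (m in ens@models) {
    writeLines(sprintf("MODEL     %4d", m@modelId), con)
    a <- m@atoms
    key <- paste(a$chain, a$resno, sep = ":")
    b <- m@plddt[key]
    b[is.na(b)] <- a$b[is.na(b)]
    nm <- ifelse(nchar(a$atom) < 4L, paste0(" ", a$atom), a$atom)
    writeLines(sprintf(
      "ATOM  %5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      seq_len(nrow(a)), nm, " ", a$resname, a$chain, a$resno, " ",
      a$x, a$y, a$z, 1.0, b, a$element), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

## ---------------------------------------------------------------------------
## Chemical shifts
## ---------------------------------------------------------------------------

#' Read a chemical-shift table
#'
#' Two dialects are supported: a tab-separated table with header columns
#' `chain`, `residue_number`, `residue_type`, `atom_name`, `shift_ppm`; and
#' NMR-STAR 3.1, from which the `Atom_chem_shift` loop is read (columns
#' `Comp_index_ID`, `Comp_ID`, `Atom_ID`, `Val`, with
#' `Auth_asym_ID`/`Entity_assembly_ID` used as the chain when present).
#' The isotope is inferred from the atom name (H/C/N). Duplicate
#' (chain, residue, atom) rows are an error.
#'
#' @param path file path.
#' @param dialect `"tsv"` or `"nmrstar"`.
#' @return a [ShiftTable-class].
#' @export
readShiftTable <- function(path, dialect = c("tsv", "nmrstar")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- switch(dialect, tsv = .readShiftTsv(path), nmrstar = .readShiftStar(path))
  df$isotope <- vapply(df$atom, function(a)
    switch(substring(a, 1L, 1L), H = "1H", C = "13C", N = "15N",
           stop("cannot infer isotope for atom ", a)), "")
  key <- paste(df$chain, df$resno, df$atom)
  if (anyDuplicated(key))
    stop("duplicate shift entry for ", key[duplicated(key)][1L])
  df <- df[order(df$chain, df$resno, df$atom), ]
  rownames(df) <- NULL
  new("ShiftTable",
      shifts = df[c("chain", "resno", "resname", "atom", "isotope", "shift")])
}

.readShiftTsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          comment.char = "#", check.names = FALSE)
  need <- c("chain", "residue_number", "residue_type", "atom_name", "shift_ppm")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing required column(s): ",
                         paste(miss, collapse = ", "))
  shift <- suppressWarnings(as.numeric(df$shift_ppm))
  if (any(is.na(shift))) stop("non-numeric shift value in row ",
                              which(is.na(shift))[1L])
  data.frame(chain = as.character(df$chain), resno = as.integer(df$residue_number),
             resname = toupper(df$residue_type), atom = toupper(df$atom_name),
             shift = shift, stringsAsFactors = FALSE)
}

## Minimal NMR-STAR 3.1 reader targeting the Atom_chem_shift loop.
.readShiftStar <- function(path) {
  lines <- readLines(path, warn = FALSE)
  i <- 1L; n <- length(lines)
  tags <- character(0); rows <- list()
  while (i <= n) {
    if (trimws(lines[i]) == "loop_") {
      j <- i + 1L
      ltags <- character(0)
      while (j <= n && startsWith(trimws(lines[j]), "_")) {
        ltags <- c(ltags, trimws(lines[j])); j <- j + 1L
      }
      if (any(grepl("^_Atom_chem_shift\\.", ltags))) {
        tags <- sub("^_Atom_chem_shift\\.", "", ltags)
        while (j <= n) {
          t <- trimws(lines[j])
          if (t %in% c("", "stop_", "loop_") || startsWith(t, "_") ||
              startsWith(t, "save_")) break
          rows[[length(rows) + 1L]] <- scan(text = lines[j], what = "",
                                            quiet = TRUE)
          j <- j + 1L
        }
        break
      }
      i <- j
    } else i <- i + 1L
  }
  if (!length(rows)) stop("no Atom_chem_shift loop found in ", path)
  m <- do.call(rbind, rows)
  colnames(m) <- tags
  need <- c("Comp_index_ID", "Comp_ID", "Atom_ID", "Val")
  miss <- setdiff(need, tags)
  if (length(miss)) stop("missing required column(s): ",
                         paste(miss, collapse = ", "))
  chain <- if ("Auth_asym_ID" %in% tags && any(!m[, "Auth_asym_ID"] %in% c(".", "?")))
    m[, "Auth_asym_ID"]
  else if ("Entity_assembly_ID" %in% tags) m[, "Entity_assembly_ID"]
  else "A"
  chain[chain %in% c(".", "?")] <- "A"
  ## map numeric entity-assembly ids to letters for comparability with PDB
  if (all(grepl("^[0-9]+$", chain))) chain <- LETTERS[as.integer(chain)]
  shift <- suppressWarnings(as.numeric(m[, "Val"]))
  if (any(is.na(shift))) stop("non-numeric shift value in Atom_chem_shift loop")
  data.frame(chain = chain, resno = as.integer(m[, "Comp_index_ID"]),
             resname = toupper(m[, "Comp_ID"]), atom = toupper(m[, "Atom_ID"]),
             shift = shift, stringsAsFactors = FALSE)
}

#' Write a shift table in the TSV dialect
#'
#' @param st a [ShiftTable-class].
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeShiftTable <- function(st, path) {
  s <- st@shifts
  out <- data.frame(chain = s$chain, residue_number = s$resno,
                    residue_type = s$resname, atom_name = s$atom,
                    shift_ppm = sprintf("%.3f", s$shift))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## ---------------------------------------------------------------------------
## Peak lists
## ---------------------------------------------------------------------------

#' Read a 3D NOESY peak list
#'
#' The dialect is tab- (or whitespace-) separated columns
#' `w1 w2 w3 [intensity]` with dimension order (H donor, heavy atom X bonded
#' to the donor, H acceptor). Lines starting with `#` are comments. Peaks are
#' given sequential ids.
#'
#' @param path file path.
#' @param spectrumType `"N15-NOESY"` or `"C13-NOESY"`.
#' @return a [PeakList-class].
#' @export
readPeakList <- function(path, spectrumType = c("N15-NOESY", "C13-NOESY")) {
  spectrumType <- match.arg(spectrumType)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  rows <- vector("list", length(keep))
  for (k in seq_along(keep)) {
    i <- keep[k]
    f <- scan(text = lines[i], what = "", quiet = TRUE)
    if (!length(f) %in% c(3L, 4L))
      stop("line ", i, ": expected 3 or 4 columns, found ", length(f))
    v <- suppressWarnings(as.numeric(f))
    if (any(is.na(v[1:3])))
      stop("line ", i, ": non-numeric frequency")
    rows[[k]] <- c(v[1:3], if (length(v) == 4L) v[4L] else NA_real_)
  }
  m <- do.call(rbind, rows)
  if (is.null(m)) m <- matrix(numeric(0), ncol = 4L)
  new("PeakList", spectrumType = spectrumType,
      peaks = data.frame(id = seq_len(nrow(m)), wHdonor = m[, 1L],
                         wX = m[, 2L], wHacceptor = m[, 3L],
                         intensity = m[, 4L]))
}

#' Write a peak list in the TSV dialect
#'
#' @param pl a [PeakList-class].
#' @param path output path.
#' @return invisibly, the path.
#' @export
writePeakList <- function(pl, path) {
  p <- pl@peaks
  lines <- sprintf("%.3f\t%.3f\t%.3f%s", p$wHdonor, p$wX, p$wHacceptor,
                   ifelse(is.na(p$intensity), "",
                          sprintf("\t%.3f", p$intensity)))
  writeLines(c(sprintf("# %s  w1=Hdonor w2=X w3=Hacceptor [intensity]",
                       pl@spectrumType), lines), path)
  invisible(path)
}
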