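## Readers and writers: PDB / mmCIF ensembles, shift tables, peak lists.

writePdbFixture <- function(path, nModels = 2, b = 90.0, dropResidue = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  for (m in seq_len(nModels)) {
    writeLines(sprintf("MODEL     %4d", m), con)
    serial <- 0L
    for (r in 1:8) {
      if (!is.null(dropResidue) && m == 2 && r == dropResidue) next
      for (at in c("N", "CA", "C")) {
        serial <- serial + 1L
        nm <- sprintf(" %-3s", at)
        writeLines(sprintf(
          "ATOM  %5d %-4s ALA A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           %s",
          serial, nm, r, r * 3.8 + m * 0.01, 0.0, 0.0, 1.0, b,
          substring(at, 1, 1)), con)
      }
    }
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
}

test_that("multi-model PDB reading: model count, pLDDT from B, mismatch error", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writePdbFixture(f, nModels = 2, b = 90.0)
  ens <- readEnsemble(f, "pdb")
  expect_equal(nModels(ens), 2L)
  expect_true(all(abs(models(ens)[[1]]@plddt - 90.0) < 1e-9))

  f2 <- withr::local_tempfile(fileext = ".pdb")
  writePdbFixture(f2, nModels = 2, dropResidue = 7)
  expect_error(readEnsemble(f2, "pdb"), "residue 7")
})

test_that("B-factors on the 0-1 scale are rescaled with a warning", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writePdbFixture(f, nModels = 1, b = 0.87)
  expect_warning(ens <- readEnsemble(f, "pdb"), "0-1 pLDDT")
  expect_true(all(abs(models(ens)[[1]]@plddt - 87.0) < 1e-6))
})

test_that("mmCIF reading agrees with PDB for the same content", {
  fp <- withr::local_tempfile(fileext = ".pdb")
  writePdbFixture(fp, nModels = 2)
  ensP <- readEnsemble(fp, "pdb")
  fc <- withr::local_tempfile(fileext = ".cif")
  lines <- c("data_fixture", "loop_",
             paste0("_atom_site.",
                    c("group_PDB", "id", "auth_atom_id", "auth_comp_id",
                      "auth_asym_id", "auth_seq_id", "type_symbol",
                      "Cartn_x", "Cartn_y", "Cartn_z", "B_iso_or_equiv",
                      "pdbx_PDB_model_num")))
  id <- 0
  for (m in 1:2) {
    a <- models(ensP)[[m]]@atoms
    for (i in seq_len(nrow(a))) {
      id <- id + 1
      lines <- c(lines, sprintf("ATOM %d %s %s %s %d %s %.3f %.3f %.3f %.2f %d",
                                id, a$atom[i], a$resname[i], a$chain[i],
                                a$resno[i], a$element[i], a$x[i], a$y[i],
                                a$z[i], a$b[i], m))
    }
  }
  writeLines(c(lines, "#"), fc)
  ensC <- readEnsemble(fc, "mmcif")
  expect_equal(nModels(ensC), 2L)
  expect_equal(models(ensC)[[1]]@atoms$x, models(ensP)[[1]]@atoms$x,
               tolerance = 1e-9)
  expect_equal(models(ensC)[[2]]@plddt, models(ensP)[[2]]@plddt)
})

test_that("ensemble write/read round trip preserves coordinates to 3 decimals", {
  fx <- makeTwoStateEnsemble(fixtureSpec(nResidues = 8, hingeRes = 5,
                                         modelsPerState = 2, seed = 4))
  ens <- fx$states[[1]]
  f <- withr::local_tempfile(fileext = ".pdb")
  writeEnsemble(ens, f)
  back <- readEnsemble(f, "pdb")
  expect_equal(nModels(back), 2L)
  a0 <- models(ens)[[1]]@atoms
  a1 <- models(back)[[1]]@atoms
  expect_equal(a1$x, a0$x, tolerance = 5e-4)
  expect_equal(a1$y, a0$y, tolerance = 5e-4)
  expect_equal(a1$atom, a0$atom)
  ## B column carries per-residue pLDDT
  expect_equal(models(back)[[1]]@plddt, models(ens)[[1]]@plddt,
               tolerance = 5e-3)
})

test_that("pTM sidecar is applied; missing entries default to 1 with warning", {
  fx <- makeTwoStateEnsemble(fixtureSpec(nResidues = 8, hingeRes = 5,
                                         modelsPerState = 2, seed = 4))
  ens <- fx$states[[1]]
  f <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(`1` = 0.77), f, auto_unbox = TRUE)
  expect_warning(out <- applyPtmSidecar(ens, f), "neutral prior")
  expect_equal(models(out)[[1]]@ptm, 0.77)
  expect_equal(models(out)[[2]]@ptm, 1.0)
})

shiftTsvLines <- c(
  "chain\tresidue_number\tresidue_type\tatom_name\tshift_ppm",
  "A\t3\tALA\tHA\t4.100",
  "A\t5\tLEU\tH\t8.300",
  "A\t5\tLEU\tN\t121.200")

test_that("TSV shift table: row count, duplicates, missing columns, order", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(shiftTsvLines, f)
  st <- readShiftTable(f, "tsv")
  expect_equal(nrow(shifts(st)), 3L)
  expect_setequal(shifts(st)$isotope, c("1H", "15N"))

  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(shiftTsvLines, "A\t5\tLEU\tH\t8.400"), f2)
  expect_error(readShiftTable(f2, "tsv"), "duplicate")

  f3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chain\tresidue_number\tresidue_type\tatom_name",
               "A\t3\tALA\tHA"), f3)
  expect_error(readShiftTable(f3, "tsv"), "shift_ppm")

  ## set semantics: record order does not matter
  f4 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(shiftTsvLines[c(1, 4, 2, 3)], f4)
  expect_equal(shifts(readShiftTable(f4, "tsv")), shifts(st))
})

test_that("NMR-STAR reading yields the same table as the TSV dialect", {
  ft <- withr::local_tempfile(fileext = ".tsv")
  writeLines(shiftTsvLines, ft)
  stTsv <- readShiftTable(ft, "tsv")
  fs <- withr::local_tempfile(fileext = ".str")
  writeLines(c(
    "data_test", "save_assigned_chemical_shifts", "loop_",
    "_Atom_chem_shift.ID", "_Atom_chem_shift.Entity_assembly_ID",
    "_Atom_chem_shift.Comp_index_ID", "_Atom_chem_shift.Comp_ID",
    "_Atom_chem_shift.Atom_ID", "_Atom_chem_shift.Val",
    "1 1 3 ALA HA 4.100",
    "2 1 5 LEU H 8.300",
    "3 1 5 LEU N 121.200",
    "stop_", "save_"), fs)
  stStar <- readShiftTable(fs, "nmrstar")
  expect_equal(shifts(stStar), shifts(stTsv))
})

test_that("peak list reading: counts, errors with line number, optional intensity", {
  f <- withr::local_tempfile(fileext = ".peaks")
  writeLines(c("# comment", "8.10\t120.3\t4.22", "8.30\t119.1\t1.05",
               "7.95\t121.8\t8.31", "8.05\t118.2\t0.92"), f)
  pl <- readPeakList(f, "N15-NOESY")
  expect_equal(nrow(peaks(pl)), 4L)
  expect_true(all(is.na(peaks(pl)$intensity)))

  f2 <- withr::local_tempfile(fileext = ".peaks")
  writeLines(c("8.10\t120.3\t4.22", "8.30\t119.1"), f2)
  expect_error(readPeakList(f2, "N15-NOESY"), "line 2")

  f3 <- withr::local_tempfile(fileext = ".peaks")
  writeLines("8.10\tabc\t4.22", f3)
  expect_error(readPeakList(f3, "N15-NOESY"), "non-numeric")
})

test_that("peak list write/read round trip preserves ppm to 3 decimals", {
  p <- new("PeakList", spectrumType = "C13-NOESY",
           peaks = data.frame(id = 1:2, wHdonor = c(4.1234, 1.0456),
                              wX = c(55.678, 18.234),
                              wHacceptor = c(8.1111, 0.9222),
                              intensity = c(1.5, NA)))
  f <- withr::local_tempfile(fileext = ".peaks")
  writePeakList(p, f)
  back <- readPeakList(f, "C13-NOESY")
  expect_equal(peaks(back)$wHdonor, peaks(p)$wHdonor, tolerance = 5e-4)
  expect_equal(peaks(back)$wX, peaks(p)$wX, tolerance = 5e-4)
  expect_equal(peaks(back)$intensity[1], 1.5, tolerance = 5e-4)
  expect_true(is.na(peaks(back)$intensity[2]))
})

test_that("insertion codes are rejected", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "MODEL        1",
    "ATOM      1  CA  ALA A   3A     1.000   0.000   0.000  1.00 90.00           C",
    "ENDMDL"), f)
  expect_error(readEnsemble(f, "pdb"), "insertion")
})
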