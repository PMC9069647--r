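## PDB/mmCIF reading, sequence derivation, method classification, writing.

pdbFixture <- function(lines) {
  f <- tempfile(fileext = ".pdb")
  writeLines(lines, f)
  f
}

atomLine <- function(ser, resid, chain, resno, x, y, z, occ = 1, alt = " ",
                     type = "ATOM  ", name = " CA ") {
  sprintf("%-6s%5d %4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
          type, ser, name, alt, resid, chain, resno, x, y, z, occ, 0)
}

test_that("PDB parsing resolves altlocs by occupancy, keeps MSE, drops waters", {
  f <- pdbFixture(c(
    "EXPDTA    SOLID-STATE NMR",
    atomLine(1, "GLN", "A", 15, 11.0, 0, 0),
    atomLine(2, "LYS", "A", 16, 14.4, 0, 0),
    atomLine(3, "LEU", "A", 17, 17.8, 0, 0, occ = 0.4, alt = "A"),
    atomLine(4, "LEU", "A", 17, 17.9, 0.1, 0, occ = 0.6, alt = "B"),
    atomLine(5, "VAL", "A", 18, 21.2, 0, 0),
    atomLine(6, "MSE", "A", 19, 24.6, 0, 0, type = "HETATM"),
    atomLine(7, "HOH", "A", 101, 50, 50, 50, type = "HETATM", name = " O  "),
    "END"))
  s <- readStructure(f)
  expect_s4_class(s, "ProteinStructure")
  expect_equal(methodClass(s), "NMR")
  ch <- getChain(s, "A")
  expect_equal(nrow(ch), 5)                     # water excluded
  expect_equal(deriveSequence(ch), "QKLVM")     # MSE -> M
  expect_equal(ch$x[ch$resno == 17], 17.9)      # higher-occupancy altloc wins
  sX <- readStructure(f, mseToMet = FALSE)
  expect_equal(deriveSequence(getChain(sX, "A")), "QKLVX")
})

test_that("altloc occupancy ties break by altloc identifier order", {
  f <- pdbFixture(c(
    atomLine(1, "ALA", "A", 1, 0, 0, 0, occ = 0.5, alt = "B"),
    atomLine(2, "ALA", "A", 1, 1, 0, 0, occ = 0.5, alt = "A"),
    "END"))
  expect_equal(getChain(readStructure(f), "A")$x, 1)
})

test_that("multi-model files keep every model as a separate coordinate set", {
  f <- pdbFixture(c(
    "EXPDTA    SOLUTION NMR",
    "MODEL        1",
    atomLine(1, "GLY", "A", 1, 0, 0, 0),
    atomLine(2, "ALA", "A", 2, 3.4, 0, 0),
    "ENDMDL",
    "MODEL        2",
    atomLine(1, "GLY", "A", 1, 0, 0, 1),
    atomLine(2, "ALA", "A", 2, 3.4, 0, 1),
    "ENDMDL",
    "END"))
  s <- readStructure(f)
  expect_equal(nModels(s), 2)
  expect_equal(getChain(s, "A", model = 1)$z, c(0, 0))
  expect_equal(getChain(s, "A", model = 2)$z, c(1, 1))
})

test_that("a file with zero ATOM records yields an empty structure with a warning", {
  f <- pdbFixture(c("HEADER    EMPTY", "EXPDTA    X-RAY DIFFRACTION", "END"))
  expect_warning(s <- readStructure(f), "no parsable residues")
  expect_equal(nModels(s), 1)
  expect_length(chainIDs(s), 0)
})

test_that("mmCIF coordinate sections parse with author numbering and method", {
  f <- tempfile(fileext = ".cif")
  writeLines(c(
    "data_TST1",
    "_exptl.method 'X-RAY DIFFRACTION'",
    "loop_",
    "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
    "_atom_site.label_atom_id", "_atom_site.label_alt_id",
    "_atom_site.label_comp_id", "_atom_site.label_asym_id",
    "_atom_site.label_entity_id", "_atom_site.label_seq_id",
    "_atom_site.pdbx_PDB_ins_code", "_atom_site.Cartn_x", "_atom_site.Cartn_y",
    "_atom_site.Cartn_z", "_atom_site.occupancy", "_atom_site.B_iso_or_equiv",
    "_atom_site.pdbx_formal_charge", "_atom_site.auth_seq_id",
    "_atom_site.auth_comp_id", "_atom_site.auth_asym_id",
    "_atom_site.auth_atom_id", "_atom_site.pdbx_PDB_model_num",
    "ATOM 1 C CA . GLY A 1 1 ? 0.000 0.000 0.000 1.00 0.00 ? 10 GLY A CA 1",
    "ATOM 2 C CA . GLU A 1 2 ? 3.400 0.000 0.000 1.00 0.00 ? 11 GLU A CA 1",
    "ATOM 3 C CA . TYR A 1 3 ? 6.800 0.000 0.000 1.00 0.00 ? 12 TYR A CA 1"),
    f)
  s <- readStructure(f)
  expect_equal(entryID(s), "TST1")
  expect_equal(methodClass(s), "XRAY")
  ch <- getChain(s, "A")
  expect_equal(ch$resno, 10:12)
  expect_equal(deriveSequence(ch), "GEY")
})

test_that("method text maps onto NMR / XRAY / OTHER", {
  expect_equal(classifyMethod("SOLID-STATE NMR"), "NMR")
  expect_equal(classifyMethod("Solution NMR"), "NMR")
  expect_equal(classifyMethod("X-RAY DIFFRACTION"), "XRAY")
  expect_equal(classifyMethod("ELECTRON MICROSCOPY"), "OTHER")
  expect_equal(classifyMethod(""), "OTHER")
  expect_equal(classifyMethod(NA_character_), "OTHER")
})

test_that("sequences keep residues that lack a C-alpha", {
  ch <- makeChain(rbind(c(0, 0, 0), c(NA, NA, NA), c(6.8, 0, 0)),
                  aa = c("G", "E", "Y"))
  ch[2, c("x", "y", "z")] <- NA_real_
  expect_equal(deriveSequence(ch), "GEY")
  expect_equal(resolvedLength(ch), 2)
  expect_equal(deriveSequence(ch[0, ]), "")
})

test_that("written PDB files round-trip residues and coordinates", {
  for (sd in c(0, 0.25)) {
    spec <- sheetSpec("GAQKLVFFAEDGA", 4, 7, nChains = 2, noiseSD = sd,
                      seed = 11, nModels = 2, entryID = "SYN1")
    s <- generateParallelSheet(spec)
    f <- tempfile(fileext = ".pdb")
    writeStructurePDB(s, f)
    s2 <- readStructure(f)
    expect_equal(entryID(s2), "SYN1")
    expect_equal(methodClass(s2), methodClass(s))
    expect_equal(nModels(s2), 2)
    for (m in 1:2) for (cid in chainIDs(s)) {
      a <- getChain(s, cid, m); b <- getChain(s2, cid, m)
      expect_identical(b$resid, a$resid)
      expect_identical(b$resno, a$resno)
      expect_lt(max(abs(as.matrix(a[, c("x", "y", "z")]) -
                          as.matrix(b[, c("x", "y", "z")]))), 1e-3)
    }
  }
})

test_that("parsing identical bytes is deterministic", {
  spec <- sheetSpec("GAQKLVFFAEDGA", 4, 7, noiseSD = 0.3, seed = 3)
  f <- tempfile(fileext = ".pdb")
  writeStructurePDB(generateParallelSheet(spec), f)
  expect_identical(readStructure(f), readStructure(f))
})

test_that("wide chain identifiers are an error, not a silent truncation", {
  ch <- makeChain(cbind(3.4 * (0:3), 0, 0))
  s <- ProteinStructure("T", "NMR", models = list(list(AB = ch)))
  expect_error(writeStructurePDB(s, tempfile(fileext = ".pdb")),
               "chain-id column")
})

test_that("an empty structure writes header records only", {
  s <- ProteinStructure("EMT", "OTHER", models = list())
  f <- tempfile(fileext = ".pdb")
  writeStructurePDB(s, f)
  lines <- readLines(f)
  expect_false(any(grepl("^ATOM", lines)))
  expect_true(any(grepl("^EXPDTA", lines)))
})

test_that("FASTA export produces entry_chain headers", {
  s <- generateParallelSheet(sheetSpec("GAQKLVFFAEDGA", 4, 7, entryID = "SYN2"))
  f <- tempfile(fileext = ".fasta")
  writeStructureFasta(s, f)
  coll <- readSequenceCollection(f)
  expect_equal(coll$id, c("SYN2", "SYN2"))
  expect_equal(coll$chain, c("A", "B"))
  expect_equal(coll$sequence, rep("GAQKLVFFAEDGA", 2))
})
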