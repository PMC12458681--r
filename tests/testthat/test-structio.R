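test_that("multi-model files yield one StructureModel per MODEL record", {
  mods <- readStructure(fixturePath("nmr_two_model"))
  expect_length(mods, 2)
  expect_equal(vapply(mods, modelIndex, integer(1)), 1:2)
  expect_equal(nAtoms(mods[[1]]), nAtoms(mods[[2]]))
})

test_that("selectFirstModel picks the lowest model index and rejects empties", {
  mods <- readStructure(fixturePath("nmr_two_model"))
  expect_equal(modelIndex(selectFirstModel(mods)), 1L)
  expect_equal(modelIndex(selectFirstModel(rev(mods))), 1L)
  expect_equal(modelIndex(selectFirstModel(mods[1])), 1L)
  expect_error(selectFirstModel(list()), "empty")
})

test_that("the two-atom fixture parses with the expected atoms and spacing", {
  mods <- readStructure(fixturePath("two_atoms"))
  expect_length(mods, 1)
  m <- mods[[1]]
  expect_equal(nAtoms(m), 2L)
  expect_setequal(atoms(m)$element, c("N", "O"))
  d <- sqrt(sum((xyzOf(m)[1, ] - xyzOf(m)[2, ])^2))
  expect_equal(d, 4.0, tolerance = 1e-6)
})

test_that("mmCIF and PDB renderings of the same coordinates agree", {
  cif <- selectFirstModel(readStructure(fixturePath("assembly_cif")))
  helix <- InterfaceMap:::.idealHelix(12, "A")
  tmp <- tempfile(fileext = ".pdb")
  InterfaceMap:::.fixtureAtomsToPdb(helix, tmp)
  pdb <- selectFirstModel(readStructure(tmp))
  expect_equal(nAtoms(cif), nAtoms(pdb))
  expect_equal(atoms(cif)$name, atoms(pdb)$name)
  expect_lt(max(abs(xyzOf(cif) - xyzOf(pdb))), 1e-3)
})

test_that("write -> re-parse round trip preserves atoms and coordinates", {
  m <- fixtureModel("helix_pair")
  tmp <- tempfile(fileext = ".pdb")
  writeStructurePDB(m, tmp)
  m2 <- selectFirstModel(readStructure(tmp))
  expect_equal(nAtoms(m2), nAtoms(m))
  expect_equal(atoms(m2)$name, atoms(m)$name)
  expect_equal(atoms(m2)$chain, atoms(m)$chain)
  expect_lt(max(abs(xyzOf(m2) - xyzOf(m))), 1e-3)
})

test_that("assembly expansion applies the deposited operators", {
  m <- selectFirstModel(readStructure(fixturePath("assembly_cif")))
  expanded <- applyAssembly(m, "1")
  expect_setequal(unique(atoms(expanded)$chain), c("A", "A-2"))
  expect_equal(assemblyId(expanded), "1")
  # identity copy equals the asymmetric unit
  orig <- xyzOf(m)
  copyA <- as.matrix(atoms(expanded)[atoms(expanded)$chain == "A",
                                     c("x", "y", "z")])
  expect_equal(copyA, orig, ignore_attr = TRUE, tolerance = 1e-9)
  # rotated copy equals a hand-applied operator (2-fold about z + 12 A in x)
  R <- diag(c(-1, -1, 1))
  manual <- sweep(orig %*% t(R), 2, c(12, 0, 0), "+")
  copyB <- as.matrix(atoms(expanded)[atoms(expanded)$chain == "A-2",
                                     c("x", "y", "z")])
  rmsd <- sqrt(mean(rowSums((copyB - manual)^2)))
  expect_lt(rmsd, 1e-6)
})

test_that("unknown assemblies and PDB input without assembly data error", {
  m <- selectFirstModel(readStructure(fixturePath("assembly_cif")))
  err <- tryCatch(applyAssembly(m, "99"), error = conditionMessage)
  expect_match(err, "available: 1")
  pdb <- fixtureModel("helix_pair")
  expect_error(applyAssembly(pdb, "1"), "pre-expanded")
})

test_that("selection modes are resolved from chains, regions and content", {
  m <- fixtureModel("helix_pair")
  expect_equal(selectionMode(resolveSelection(m, regionSelection("A"),
                                              regionSelection("B"))),
               "interchain")
  intra <- resolveSelection(m, regionSelection("A", list(c(1, 5))),
                            regionSelection("A", list(c(8, 12))))
  expect_equal(selectionMode(intra), "intrachain")
  lig <- fixtureSelection("protein_ligand", "A", "L")
  expect_equal(selectionMode(lig), "ligand")
})

test_that("selection errors name the problem", {
  m <- fixtureModel("helix_pair")
  expect_error(resolveSelection(m, regionSelection("Z"), regionSelection("B")),
               "available chains")
  expect_error(resolveSelection(m, regionSelection("A", list(c(1, 6))),
                                regionSelection("A", list(c(5, 12)))),
               "overlap")
  expect_error(resolveSelection(m, regionSelection("A"), regionSelection("A")),
               "ranges")
  expect_error(regionSelection("A", list(c(9, 3))), "start <= end")
})

test_that("resolved atom sets are disjoint, heavy and water-free", {
  for (fx in list(c("helix_pair", "A", "B"), c("protein_ligand", "A", "L"),
                  c("nucleic_protein", "A", "B"))) {
    sel <- fixtureSelection(fx[1], fx[2], fx[3])
    idx <- atomIndices(sel)
    expect_length(intersect(idx$sel1, idx$sel2), 0)
    a <- atoms(sel@model)
    picked <- c(idx$sel1, idx$sel2)
    expect_false(any(a$element[picked] %in% c("H", "D")))
    expect_false(any(a$polymerClass[picked] == "water"))
  }
})

test_that("alternate locations collapse to the highest-occupancy conformer", {
  tmp <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N  AALA A   1       0.000   0.000   0.000  0.40  0.00           N",
    "ATOM      2  N  BALA A   1       1.000   0.000   0.000  0.60  0.00           N",
    "ATOM      3  CA  ALA A   1       2.000   0.000   0.000  1.00  0.00           C",
    "END"), tmp)
  m <- selectFirstModel(readStructure(tmp))
  a <- atoms(m)
  expect_equal(nrow(a), 2)
  expect_equal(a$x[a$name == "N"], 1.0)  # occupancy 0.60 wins
})

test_that("parsing failures and empty structures raise format errors", {
  bad <- tempfile(fileext = ".pdb")
  writeLines(c("REMARK nothing here", "END"), bad)
  expect_error(readStructure(bad), "empty structure|cannot parse")
  expect_error(readStructure(tempfile(fileext = ".pdb")), "not found")
})
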