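analysisBundle <- function(name, chain1 = "A", chain2 = "B") {
  sel <- fixtureSelection(name, chain1, chain2)
  contacts <- findContacts(sel)
  burials <- residueBurial(sel)
  ss <- assignSecondaryStructure(sel@model)
  list(sel = sel, contacts = contacts, burials = burials, ss = ss)
}

test_that("cell notation: polar trailing dot, nonpolar leading dot", {
  expect_equal(cellCode(3, 0), "3.")
  expect_equal(cellCode(0, 2), ".2")
  expect_equal(cellCode(3, 2), "3. .2")
  expect_equal(cellCode(12, 0), "12.")
  expect_error(cellCode(0, 0), "should not exist")
  expect_error(cellCode(-1, 2), "negative")
})

test_that("macromolecule runs write three class lists that conserve counts", {
  b <- analysisBundle("nucleic_protein")
  outdir <- file.path(tempdir(), "lists-macro")
  paths <- writeContactLists(b$contacts, selectionMode(b$sel), outdir)
  expect_length(paths, 3)
  expect_setequal(basename(paths), c("contacts_polar.txt",
                                     "contacts_nonpolar.txt",
                                     "contacts_other.txt"))
  nLines <- vapply(paths, function(p) length(readLines(p)) - 1L, integer(1))
  expect_equal(sum(nLines), nrow(b$contacts))
  expect_equal(unname(nLines[grepl("polar.txt", paths) &
                             !grepl("nonpolar", paths)]),
               sum(b$contacts$class == "polar"))
  # distances printed with two decimals
  body <- readLines(paths[1])[-1]
  expect_true(all(grepl("\\d+\\.\\d{2}$", body)))
})

test_that("ligand runs write a single untyped list", {
  b <- analysisBundle("protein_ligand", "A", "L")
  outdir <- file.path(tempdir(), "lists-ligand")
  p <- writeContactLists(b$contacts, selectionMode(b$sel), outdir)
  expect_length(p, 1)
  expect_equal(basename(p), "contacts_ligand.txt")
  expect_equal(length(readLines(p)) - 1L, nrow(b$contacts))
})

test_that("zero-contact runs still write headed empty files", {
  b <- analysisBundle("separated_chains")
  outdir <- file.path(tempdir(), "lists-empty")
  paths <- writeContactLists(b$contacts, selectionMode(b$sel), outdir)
  expect_length(paths, 3)
  for (p in paths) expect_equal(length(readLines(p)), 1L)
})

test_that("light maps cover exactly the contact-bearing residues", {
  b <- analysisBundle("helix_pair")
  light <- buildContactMap(b$sel, b$contacts, b$burials, b$ss, "light")
  full <- buildContactMap(b$sel, b$contacts, b$burials, b$ss, "full")
  sm <- summarizePairs(b$contacts)
  expect_equal(nrow(light@rowInfo), length(unique(sm$resno1)))
  expect_equal(nrow(light@colInfo), length(unique(sm$resno2)))
  expect_equal(nrow(full@rowInfo), 12)  # every residue of the selection
  expect_equal(nrow(full@colInfo), 12)
  # light is a sub-map of full, cell for cell
  keyL <- paste(light@rowInfo$resno[light@cells$row],
                light@colInfo$resno[light@cells$col], light@cells$text)
  keyF <- paste(full@rowInfo$resno[full@cells$row],
                full@colInfo$resno[full@cells$col], full@cells$text)
  expect_true(all(keyL %in% keyF))
  expect_equal(nrow(light@cells), nrow(full@cells))
  # conservation through map cells
  expect_equal(sum(full@cells$nPolar + full@cells$nNonpolar +
                   full@cells$nOther), nrow(b$contacts))
})

test_that("full maps of a residue range enumerate the whole range", {
  m <- fixtureModel("helix_pair")
  sel <- resolveSelection(m, regionSelection("A", list(c(2, 12))),
                          regionSelection("B"))
  b <- list(sel = sel, contacts = findContacts(sel),
            burials = residueBurial(sel),
            ss = assignSecondaryStructure(m))
  full <- buildContactMap(sel, b$contacts, b$burials, b$ss, "full")
  expect_equal(nrow(full@rowInfo), 11)
  expect_equal(full@rowInfo$resno, 2:12)
})

test_that("cell colors and shades follow the class counts", {
  b <- analysisBundle("nucleic_protein")
  map <- buildContactMap(b$sel, b$contacts, b$burials, b$ss, "light")
  cl <- map@cells
  expect_true(all(cl$color[cl$nPolar > 0 & cl$nNonpolar == 0] == "blue"))
  expect_true(all(cl$color[cl$nPolar == 0 & cl$nNonpolar > 0] == "yellow"))
  expect_true(all(cl$color[cl$nPolar > 0 & cl$nNonpolar > 0] == "green"))
  expect_true(all(InterfaceMap:::.shadeTier(7) >
                    InterfaceMap:::.shadeTier(1)))
  # margins carry SS for the protein side only and burial digits
  expect_true(all(map@colInfo$ss == ""))  # nucleic columns
  expect_true(any(map@rowInfo$ss == "H"))
  expect_true(all(map@rowInfo$bin %in% 0:9))
})

test_that("swapping the selections transposes the map", {
  m <- fixtureModel("helix_pair")
  mkMap <- function(c1, c2) {
    sel <- resolveSelection(m, regionSelection(c1), regionSelection(c2))
    buildContactMap(sel, findContacts(sel), residueBurial(sel),
                    assignSecondaryStructure(m), "light")
  }
  ab <- mkMap("A", "B"); ba <- mkMap("B", "A")
  expect_equal(ab@rowInfo, ba@colInfo)
  expect_equal(ab@colInfo, ba@rowInfo)
  keyAB <- sort(paste(ab@cells$row, ab@cells$col, ab@cells$text,
                      ab@cells$color, ab@cells$shade))
  keyBA <- sort(paste(ba@cells$col, ba@cells$row, ba@cells$text,
                      ba@cells$color, ba@cells$shade))
  expect_equal(keyAB, keyBA)
})

test_that("CSV round-trips every cell including the five margin lines", {
  b <- analysisBundle("helix_pair")
  map <- buildContactMap(b$sel, b$contacts, b$burials, b$ss, "light")
  p <- tempfile(fileext = ".csv")
  writeMapCSV(map, p)
  got <- as.matrix(utils::read.csv(p, header = FALSE,
                                   colClasses = "character"))
  want <- InterfaceMap:::.mapMatrices(map)$text
  expect_equal(unname(got), unname(want))
  expect_equal(unname(got[5, 5]), "burial")
  # one margin row holds the chain ids
  expect_true(all(got[1, 5 + seq_len(nrow(map@colInfo))] == "B"))
})

test_that("XLSX re-parses to the same text with class-colored fills", {
  b <- analysisBundle("nucleic_protein")
  map <- buildContactMap(b$sel, b$contacts, b$burials, b$ss, "light")
  p <- tempfile(fileext = ".xlsx")
  writeMapXLSX(map, p)
  code <- c(
    "import openpyxl, warnings",
    "warnings.filterwarnings('ignore')",
    sprintf("ws = openpyxl.load_workbook('%s').active", p),
    "for row in ws.iter_rows():",
    "    for c in row:",
    "        if c.value is not None and c.row > 5 and c.column > 5:",
    "            print(c.row, c.column, repr(str(c.value)), c.fill.fgColor.rgb)")
  out <- runPython(code)
  # cells rendered in the sheet: non-empty text or a colored fill
  visible <- map@cells[nzchar(map@cells$text) | map@cells$color != "none", ]
  expect_equal(length(out), nrow(visible))
  parsed <- read.table(text = out, stringsAsFactors = FALSE)
  fills <- InterfaceMap:::.XLSX_FILLS
  for (k in seq_len(nrow(visible))) {
    cl <- visible[k, ]
    row <- parsed[parsed$V1 == cl$row + 5 & parsed$V2 == cl$col + 5, ]
    expect_equal(nrow(row), 1)
    expect_equal(gsub("'", "", row$V3), cl$text)
    if (cl$color != "none")
      expect_equal(row$V4,
                   unname(fills[paste0(cl$color, cl$shade)]))
  }
})

test_that("ligand maps are atom-level with distances on a gray scale", {
  b <- analysisBundle("protein_ligand", "A", "L")
  map <- buildContactMap(b$sel, b$contacts, b$burials, b$ss, "light")
  expect_equal(map@mode, "ligand")
  expect_true(all(grepl("^\\d+\\.\\d{2}$", map@cells$text)))
  expect_true(all(map@cells$color == "gray"))
  expect_true(all(grepl("/", map@colInfo$label)))  # atom-level margins
  # closer contact -> darker or equal shade
  o <- order(as.numeric(map@cells$text))
  expect_true(all(diff(map@cells$shade[o]) <= 0))
})

test_that("the network conserves counts and round-trips through GraphML", {
  b <- analysisBundle("nucleic_protein")
  sm <- summarizePairs(b$contacts)
  g <- buildNetwork(sm)
  v <- igraph::as_data_frame(g, what = "vertices")
  e <- igraph::as_data_frame(g, what = "edges")
  expect_equal(nrow(e), nrow(sm))
  expect_equal(sum(e$nPolar + e$nNonpolar + e$nOther + e$nUntyped),
               nrow(b$contacts))
  for (k in seq_len(nrow(v))) {
    inc <- e$from == v$name[k] | e$to == v$name[k]
    expect_equal(v$contactCount[k],
                 sum(e$nPolar[inc] + e$nNonpolar[inc] + e$nOther[inc] +
                       e$nUntyped[inc]))
  }
  p <- tempfile(fileext = ".graphml")
  exportNetwork(g, "graphml", p)
  g2 <- igraph::read_graph(p, format = "graphml")
  expect_equal(igraph::vcount(g2), igraph::vcount(g))
  expect_equal(igraph::ecount(g2), igraph::ecount(g))
  expect_equal(sort(igraph::V(g2)$contactCount),
               sort(igraph::V(g)$contactCount))
  pj <- tempfile(fileext = ".json")
  exportNetwork(g, "json", pj)
  js <- jsonlite::read_json(pj, simplifyVector = TRUE)
  expect_equal(nrow(js$nodes), igraph::vcount(g))
})

test_that("visualization scripts select the interface and are deterministic", {
  b <- analysisBundle("helix_pair")
  pml <- genPymolScript(b$contacts, c("A", "B"))
  cxc <- genChimeraxScript(b$contacts, c("A", "B"))
  ifaceA <- sort(unique(c(b$contacts$resno1)))
  expect_true(any(grepl(paste0("chain A and resi ",
                               paste(ifaceA, collapse = "\\+")), pml)))
  expect_equal(sum(grepl("^color \\w+, chain ", pml)), 2)  # one per chain
  expect_true(any(grepl("^surface /A", cxc)))
  expect_identical(pml, genPymolScript(b$contacts, c("A", "B")))
  expect_identical(cxc, genChimeraxScript(b$contacts, c("A", "B")))
})
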