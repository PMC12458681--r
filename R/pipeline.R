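# End-to-end analysis: structure input -> selection -> contacts -> burial ->
# secondary structure -> reports -> hotspot windows, written as one output
# folder plus a machine-readable report.json. Fully deterministic: identical
# inputs give byte-identical outputs.

#' Run a complete interface analysis
#'
#' Executes the whole pipeline and writes the output file suite:
#' three per-class contact lists (one untyped list in ligand mode), light and
#' full contact maps as CSV (and XLSX unless disabled), the residue contact
#' network, PyMOL/ChimeraX scripts with a coordinate copy, a TSV of ranked
#' hotspot windows per chain, and `report.json` aggregating counts, the
#' burial table, secondary-structure labels and the window ranking.
#'
#' @param input path to a PDB or mmCIF file.
#' @param chain1,chain2 the two chain selections.
#' @param region1,region2 optional lists of `c(start, end)` residue ranges
#'   (required when `chain1 == chain2`).
#' @param format input format (`"auto"`, `"pdb"`, `"mmcif"`).
#' @param assembly optional mmCIF assembly id to expand before analysis.
#' @param threshold contact distance threshold in Angstrom (default 4.0).
#' @param sasaPoints Shrake-Rupley sample points per atom (default 960).
#' @param outdir output directory (created; default a fresh temp directory).
#' @param xlsx write XLSX maps as well as CSV (default TRUE).
#' @param networkFormat `"graphml"` or `"json"`.
#' @param dsspPath optional external mkdssp binary for secondary structure.
#' @param zipOutput also bundle the folder into `results.zip` (default FALSE).
#' @return Invisibly, a list with the parsed `report` and the `outdir`.
#' @examples
#' f <- makeFixture("helix_pair", tempdir())
#' res <- runAnalysis(f, chain1 = "A", chain2 = "B",
#'                    outdir = file.path(tempdir(), "helix_out"))
#' res$report$counts
#' @export
runAnalysis <- function(input, chain1, chain2, region1 = NULL, region2 = NULL,
                        format = "auto", assembly = NULL, threshold = 4.0,
                        sasaPoints = 960L, outdir = tempfile("ifmap"),
                        xlsx = TRUE, networkFormat = c("graphml", "json"),
                        dsspPath = NULL, zipOutput = FALSE) {
  networkFormat <- match.arg(networkFormat)
  stopifnot(threshold > 0)
  if (chain1 == chain2 && (is.null(region1) || is.null(region2)))
    stop("regions are required when both selections name the same chain")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  model <- selectFirstModel(readStructure(input, format = format))
  if (!is.null(assembly)) model <- applyAssembly(model, assembly)
  sel <- resolveSelection(model,
                          regionSelection(chain1, region1),
                          regionSelection(chain2, region2))
  contacts <- findContacts(sel, threshold = threshold)
  summaries <- summarizePairs(contacts)
  burials <- residueBurial(sel, nPoints = sasaPoints)
  ss <- assignSecondaryStructure(model, dsspPath = dsspPath)

  listFiles <- writeContactLists(contacts, sel@mode, outdir)
  mapLight <- buildContactMap(sel, contacts, burials, ss, "light", threshold)
  mapFull <- buildContactMap(sel, contacts, burials, ss, "full", threshold)
  writeMapCSV(mapLight, file.path(outdir, "map_light.csv"))
  writeMapCSV(mapFull, file.path(outdir, "map_full.csv"))
  if (xlsx) {
    writeMapXLSX(mapLight, file.path(outdir, "map_light.xlsx"))
    writeMapXLSX(mapFull, file.path(outdir, "map_full.xlsx"))
  }
  graph <- buildNetwork(summaries)
  exportNetwork(graph, networkFormat,
                file.path(outdir, paste0("network.", networkFormat)))
  writeStructurePDB(model, file.path(outdir, "coords.pdb"))
  chains <- unique(c(chain1, chain2))
  writeLines(genPymolScript(contacts, chains, "coords.pdb"),
             file.path(outdir, "view.pml"))
  writeLines(genChimeraxScript(contacts, chains, "coords.pdb"),
             file.path(outdir, "view.cxc"))

  windows <- lapply(chains, function(ch) {
    w <- rankWindows(summaries, burials, ch)
    utils::head(selectNonoverlapping(w, k = 5L), 5L)
  })
  names(windows) <- chains
  windowTable <- do.call(rbind, windows)
  rownames(windowTable) <- NULL
  if (!is.null(windowTable) && nrow(windowTable))
    utils::write.table(windowTable, file.path(outdir, "windows.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  else writeLines("chain\tstartRes\tendRes\tlength\tnContacts\tnBuried",
                  file.path(outdir, "windows.tsv"))

  report <- list(
    input = basename(input),
    mode = sel@mode,
    threshold = threshold,
    selections = list(list(chain = chain1, ranges = region1),
                      list(chain = chain2, ranges = region2)),
    counts = list(
      contacts = nrow(contacts),
      polar = sum(contacts$class == "polar"),
      nonpolar = sum(contacts$class == "nonpolar"),
      other = sum(contacts$class == "other"),
      untyped = sum(contacts$class == "untyped"),
      residuePairs = nrow(summaries)),
    burial = burials,
    secondaryStructure = ss,
    windows = windowTable)
  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = 6, pretty = TRUE,
                       dataframe = "rows")
  if (zipOutput) {
    fls <- list.files(outdir, recursive = TRUE)
    fls <- setdiff(fls, "results.zip")
    payload <- lapply(file.path(outdir, fls), function(p)
      readBin(p, "raw", file.info(p)$size))
    names(payload) <- fls
    .writeZip(payload, file.path(outdir, "results.zip"))
  }
  invisible(list(report = report, outdir = outdir,
                 files = list.files(outdir)))
}
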