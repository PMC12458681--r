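# Serialization of the analysis: per-class contact lists, light/full 2D
# contact maps (CSV + XLSX), ligand atom-level maps, the residue contact
# network and PyMOL/ChimeraX visualization scripts. File names are fixed:
# contacts_polar.txt / contacts_nonpolar.txt / contacts_other.txt (or
# contacts_ligand.txt), map_light.csv/.xlsx, map_full.csv/.xlsx,
# network.graphml/.json, view.pml, view.cxc, report.json.

.resTag <- function(chain, resname, resno, icode) {
  sprintf("%s/%s/%s%s", chain, resname, resno, icode)
}

#' Write the per-class contact list files
#'
#' Macromolecule mode writes exactly three files (polar, nonpolar, other);
#' ligand mode writes a single untyped file. Each line identifies both
#' residues (chain/residue-name/number), the two atom names and elements,
#' and the distance rendered to two decimals. Lines are ordered by the first
#' residue, then the second, then distance.
#'
#' @param contacts data.frame from [findContacts()].
#' @param mode analysis mode from [selectionMode()].
#' @param outdir output directory.
#' @return Character vector of the written file paths.
#' @export
writeContactLists <- function(contacts, mode, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  header <- paste("residue_1", "atom_1", "element_1",
                  "residue_2", "atom_2", "element_2", "distance_A",
                  sep = "\t")
  fmt <- function(df) {
    if (!nrow(df)) return(character(0))
    df <- df[order(df$chain1, df$resno1, df$icode1, df$name1,
                   df$chain2, df$resno2, df$icode2, df$name2,
                   df$distance), , drop = FALSE]
    sprintf("%s\t%s\t%s\t%s\t%s\t%s\t%.2f",
            .resTag(df$chain1, df$resname1, df$resno1, df$icode1),
            df$name1, df$element1,
            .resTag(df$chain2, df$resname2, df$resno2, df$icode2),
            df$name2, df$element2, .round2(df$distance))
  }
  if (mode == "ligand") {
    p <- file.path(outdir, "contacts_ligand.txt")
    writeLines(c(header, fmt(contacts)), p)
    return(p)
  }
  paths <- character(3)
  classes <- c(polar = "contacts_polar.txt", nonpolar = "contacts_nonpolar.txt",
               other = "contacts_other.txt")
  for (k in seq_along(classes)) {
    p <- file.path(outdir, classes[k])
    writeLines(c(header, fmt(contacts[contacts$class == names(classes)[k], ,
                                      drop = FALSE])), p)
    paths[k] <- p
  }
  paths
}

#' Render the in-cell contact-count notation
#'
#' Polar counts are followed by a dot, nonpolar counts preceded by one:
#' `(3,0)` renders `"3."`, `(0,2)` renders `".2"`, and a mixed cell renders
#' both tokens separated by a single space, `"3. .2"`.
#'
#' @param nPolar,nNonpolar non-negative contact counts (not both zero).
#' @return The cell text.
#' @export
cellCode <- function(nPolar, nNonpolar) {
  if (nPolar < 0 || nNonpolar < 0) stop("negative contact count")
  if (nPolar == 0 && nNonpolar == 0)
    stop("cell with zero polar and nonpolar contacts should not exist")
  if (nNonpolar == 0) sprintf("%d.", nPolar)
  else if (nPolar == 0) sprintf(".%d", nNonpolar)
  else sprintf("%d. .%d", nPolar, nNonpolar)
}

.shadeTier <- function(total) ifelse(total >= 6, 3L, ifelse(total >= 3, 2L, 1L))

.cellColor <- function(nPolar, nNonpolar) {
  ifelse(nPolar > 0 & nNonpolar == 0, "blue",
  ifelse(nNonpolar > 0 & nPolar == 0, "yellow",
  ifelse(nPolar > 0 & nNonpolar > 0, "green", "none")))
}

# margin info for every residue of a selection, in sequence order
.marginResidues <- function(model, idx, ss, burials, selNo) {
  a <- model@atoms
  key <- paste(a$chain[idx], a$resno[idx], a$icode[idx], sep = "\r")
  first <- idx[!duplicated(key)]
  info <- data.frame(chain = a$chain[first], resno = a$resno[first],
                     icode = a$icode[first], label = a$resname[first],
                     polymerClass = a$polymerClass[first],
                     stringsAsFactors = FALSE)
  mkey <- paste(info$chain, info$resno, info$icode)
  skey <- paste(ss$chain, ss$resno, ss$icode)
  info$ss <- ifelse(info$polymerClass == "protein",
                    ss$label[match(mkey, skey)], "")
  info$ss[is.na(info$ss)] <- ""
  b <- burials[burials$selection == selNo, , drop = FALSE]
  bkey <- paste(b$chain, b$resno, b$icode)
  info$bin <- b$bin[match(mkey, bkey)]
  info$bin[is.na(info$bin)] <- 0L
  info
}

#' Build a 2D contact map model
#'
#' Macromolecule mode: rows are selection-1 residues, columns selection-2
#' residues; cells carry the contact-count notation of [cellCode()], a color
#' (polar-only blue, nonpolar-only yellow, mixed green) and a shade tier that
#' darkens with the total count (1-2 contacts, 3-5, >= 6). Margins carry
#' chain, residue number, residue type, the H/S secondary-structure label
#' (proteins only) and the 0-9 burial code. Ligand mode: rows/columns are
#' atoms; cells show the interatomic distance (two decimals) on a gray scale
#' darkening as the distance decreases (linear from the threshold down to
#' 2.4 A). The `light` variant keeps only contact-bearing rows/columns; the
#' `full` variant enumerates every residue of the selections.
#'
#' @param sel an [InterfaceSelection-class].
#' @param contacts data.frame from [findContacts()].
#' @param burials data.frame from [residueBurial()].
#' @param ss data.frame from [assignSecondaryStructure()].
#' @param variant `"light"` or `"full"`.
#' @param threshold the contact threshold used (for the ligand gray scale).
#' @return A [ContactMap-class].
#' @export
buildContactMap <- function(sel, contacts, burials, ss,
                            variant = c("light", "full"), threshold = 4.0) {
  variant <- match.arg(variant)
  mode <- if (sel@mode == "ligand") "ligand" else "macromolecule"
  model <- sel@model
  a <- model@atoms
  if (mode == "ligand") {
    atomInfo <- function(idx) {
      data.frame(chain = a$chain[idx], resno = a$resno[idx],
                 icode = a$icode[idx],
                 label = paste0(a$resname[idx], "/", a$name[idx]),
                 ss = "", bin = 0L, key = paste(a$chain[idx], a$resno[idx],
                                                a$icode[idx], a$name[idx]),
                 stringsAsFactors = FALSE)
    }
    rowInfo <- atomInfo(sel@idx1)
    colInfo <- atomInfo(sel@idx2)
    ckey1 <- paste(contacts$chain1, contacts$resno1, contacts$icode1,
                   contacts$name1)
    ckey2 <- paste(contacts$chain2, contacts$resno2, contacts$icode2,
                   contacts$name2)
    if (variant == "light") {
      rowInfo <- rowInfo[rowInfo$key %in% ckey1, , drop = FALSE]
      colInfo <- colInfo[colInfo$key %in% ckey2, , drop = FALSE]
    }
    frac <- pmin(1, pmax(0, (threshold - contacts$distance) /
                              max(threshold - 2.4, 1e-9)))
    cells <- data.frame(
      row = match(ckey1, rowInfo$key), col = match(ckey2, colInfo$key),
      text = sprintf("%.2f", .round2(contacts$distance)),
      color = "gray", shade = 1L + (frac > 1 / 3) + (frac > 2 / 3),
      nPolar = 0L, nNonpolar = 0L, nOther = 0L, nUntyped = 1L,
      stringsAsFactors = FALSE)
    cells <- cells[!is.na(cells$row) & !is.na(cells$col), , drop = FALSE]
    rowInfo$key <- colInfo$key <- NULL
    rownames(rowInfo) <- rownames(colInfo) <- rownames(cells) <- NULL
    return(new("ContactMap", rowInfo = rowInfo, colInfo = colInfo,
               cells = cells, variant = variant, mode = mode))
  }
  summaries <- summarizePairs(contacts)
  rowInfo <- .marginResidues(model, sel@idx1, ss, burials, 1L)
  colInfo <- .marginResidues(model, sel@idx2, ss, burials, 2L)
  rowInfo$key <- paste(rowInfo$chain, rowInfo$resno, rowInfo$icode)
  colInfo$key <- paste(colInfo$chain, colInfo$resno, colInfo$icode)
  skey1 <- paste(summaries$chain1, summaries$resno1, summaries$icode1)
  skey2 <- paste(summaries$chain2, summaries$resno2, summaries$icode2)
  if (variant == "light") {
    rowInfo <- rowInfo[rowInfo$key %in% skey1, , drop = FALSE]
    colInfo <- colInfo[colInfo$key %in% skey2, , drop = FALSE]
  }
  if (nrow(summaries)) {
    total <- summaries$nPolar + summaries$nNonpolar + summaries$nOther
    text <- character(nrow(summaries))
    for (i in seq_len(nrow(summaries))) {
      text[i] <- if (summaries$nPolar[i] + summaries$nNonpolar[i] > 0)
        cellCode(summaries$nPolar[i], summaries$nNonpolar[i]) else ""
    }
    cells <- data.frame(
      row = match(skey1, rowInfo$key), col = match(skey2, colInfo$key),
      text = text,
      color = .cellColor(summaries$nPolar, summaries$nNonpolar),
      shade = .shadeTier(total),
      nPolar = summaries$nPolar, nNonpolar = summaries$nNonpolar,
      nOther = summaries$nOther, nUntyped = summaries$nUntyped,
      stringsAsFactors = FALSE)
    cells <- cells[!is.na(cells$row) & !is.na(cells$col), , drop = FALSE]
  } else {
    cells <- data.frame(row = integer(), col = integer(), text = character(),
                        color = character(), shade = integer(),
                        nPolar = integer(), nNonpolar = integer(),
                        nOther = integer(), nUntyped = integer(),
                        stringsAsFactors = FALSE)
  }
  rowInfo$key <- colInfo$key <- NULL
  rowInfo$polymerClass <- colInfo$polymerClass <- NULL
  rownames(rowInfo) <- rownames(colInfo) <- rownames(cells) <- NULL
  new("ContactMap", rowInfo = rowInfo, colInfo = colInfo, cells = cells,
      variant = variant, mode = mode)
}

# dense text + fill matrices with the 5 margin header rows/columns
# (chain, residue number, residue type, SS, burial), in that fixed order
.mapMatrices <- function(map) {
  ri <- map@rowInfo; ci <- map@colInfo
  nr <- nrow(ri); nc <- nrow(ci)
  marginNames <- c("chain", "number", "type", "SS", "burial")
  text <- matrix("", 5 + nr, 5 + nc)
  fill <- matrix("", 5 + nr, 5 + nc)
  for (k in 1:5) text[k, 5] <- text[5, k] <- marginNames[k]
  resnoTxt <- function(info) paste0(info$resno, info$icode)
  if (nc) {
    text[1, 5 + seq_len(nc)] <- ci$chain
    text[2, 5 + seq_len(nc)] <- resnoTxt(ci)
    text[3, 5 + seq_len(nc)] <- ci$label
    text[4, 5 + seq_len(nc)] <- ci$ss
    text[5, 5 + seq_len(nc)] <- as.character(ci$bin)
  }
  if (nr) {
    text[5 + seq_len(nr), 1] <- ri$chain
    text[5 + seq_len(nr), 2] <- resnoTxt(ri)
    text[5 + seq_len(nr), 3] <- ri$label
    text[5 + seq_len(nr), 4] <- ri$ss
    text[5 + seq_len(nr), 5] <- as.character(ri$bin)
  }
  cl <- map@cells
  for (i in seq_len(nrow(cl))) {
    text[5 + cl$row[i], 5 + cl$col[i]] <- cl$text[i]
    if (cl$color[i] != "none")
      fill[5 + cl$row[i], 5 + cl$col[i]] <- paste0(cl$color[i], cl$shade[i])
  }
  list(text = text, fill = fill)
}

#' Write a contact map as CSV
#'
#' RFC 4180 CSV (UTF-8) of the dense map matrix, including the five margin
#' header rows and columns. Re-reading the file recovers every cell text.
#'
#' @param map a [ContactMap-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeMapCSV <- function(map, path) {
  m <- .mapMatrices(map)$text
  utils::write.table(m, path, sep = ",", row.names = FALSE,
                     col.names = FALSE, qmethod = "double", quote = TRUE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Write a contact map as XLSX with colored cell backgrounds
#'
#' Same text layout as [writeMapCSV()], with each occupied cell filled in its
#' class color (blue/yellow/green, darker shades for more contacts; gray
#' scale in ligand mode).
#'
#' @param map a [ContactMap-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeMapXLSX <- function(map, path) {
  m <- .mapMatrices(map)
  .writeXlsxMatrix(m$text, m$fill, path)
  invisible(path)
}

#' Build the residue contact network
#'
#' Nodes are contact-bearing residues (attributes: `chain`, `resno`,
#' `resname`, `contactCount` = total incident atomic contacts); edges carry
#' the per-class counts. Node order is deterministic: selection 1 residues in
#' sequence order, then selection 2.
#'
#' @param summaries data.frame from [summarizePairs()].
#' @return An [igraph::igraph] graph.
#' @export
buildNetwork <- function(summaries) {
  if (!nrow(summaries)) {
    g <- igraph::make_empty_graph(0, directed = FALSE)
    for (at in c("chain", "resname", "id"))
      g <- igraph::set_vertex_attr(g, at, value = character(0))
    g <- igraph::set_vertex_attr(g, "resno", value = integer(0))
    g <- igraph::set_vertex_attr(g, "contactCount", value = numeric(0))
    for (at in c("nPolar", "nNonpolar", "nOther", "nUntyped"))
      g <- igraph::set_edge_attr(g, at, value = integer(0))
    return(g)
  }
  tag1 <- paste0(summaries$chain1, ":", summaries$resno1, summaries$icode1)
  tag2 <- paste0(summaries$chain2, ":", summaries$resno2, summaries$icode2)
  total <- summaries$nPolar + summaries$nNonpolar + summaries$nOther +
    summaries$nUntyped
  nodes1 <- unique(data.frame(id = tag1, chain = summaries$chain1,
                              resno = summaries$resno1,
                              resname = summaries$resname1,
                              stringsAsFactors = FALSE))
  nodes2 <- unique(data.frame(id = tag2, chain = summaries$chain2,
                              resno = summaries$resno2,
                              resname = summaries$resname2,
                              stringsAsFactors = FALSE))
  nodes <- rbind(nodes1, nodes2)
  nodes <- nodes[!duplicated(nodes$id), , drop = FALSE]
  nodes$contactCount <- vapply(nodes$id, function(id) {
    sum(total[tag1 == id]) + sum(total[tag2 == id])
  }, numeric(1))
  edges <- data.frame(from = tag1, to = tag2,
                      nPolar = summaries$nPolar,
                      nNonpolar = summaries$nNonpolar,
                      nOther = summaries$nOther,
                      nUntyped = summaries$nUntyped,
                      stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(edges, directed = FALSE, vertices = nodes)
}

#' Export the contact network to GraphML or JSON
#'
#' @param graph an igraph graph from [buildNetwork()].
#' @param format `"graphml"` or `"json"`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
exportNetwork <- function(graph, format = c("graphml", "json"), path) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(graph, path, format = "graphml")
  } else {
    v <- igraph::as_data_frame(graph, what = "vertices")
    e <- igraph::as_data_frame(graph, what = "edges")
    rownames(v) <- rownames(e) <- NULL
    jsonlite::write_json(list(nodes = v, edges = e), path,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

# chain color palettes (first chain lilac, second light orange, then cycle)
.PYMOL_COLORS <- c("violet", "lightorange", "palegreen", "lightblue",
                   "wheat", "salmon")
.CHIMERAX_COLORS <- c("#C8A2C8", "#FFD9B3", "#C8E6C9", "#B3D9FF",
                      "#F5DEB3", "#FA8072")

.interfaceResiduesByChain <- function(contacts) {
  both <- rbind(
    data.frame(chain = contacts$chain1, resno = contacts$resno1,
               stringsAsFactors = FALSE),
    data.frame(chain = contacts$chain2, resno = contacts$resno2,
               stringsAsFactors = FALSE))
  both <- unique(both)
  both <- both[order(both$chain, both$resno), , drop = FALSE]
  split(both$resno, both$chain)
}

#' Generate a PyMOL visualization script
#'
#' The script loads the coordinate file by relative path, draws each chain as
#' a cartoon in its own color, shows the interface residues as sticks colored
#' by element with carbons in the chain color, and displays the chains'
#' solvent-accessible surface. Output text is deterministic.
#'
#' @param contacts data.frame from [findContacts()].
#' @param chains the chain identifiers involved (selection order).
#' @param coordFile relative path of the coordinate file the script loads.
#' @return Character vector of script lines.
#' @export
genPymolScript <- function(contacts, chains, coordFile = "coords.pdb") {
  iface <- .interfaceResiduesByChain(contacts)
  out <- c(sprintf("load %s, complex", coordFile),
           "hide everything", "bg_color white",
           "set surface_quality, 1", "set transparency, 0.5")
  for (k in seq_along(chains)) {
    col <- .PYMOL_COLORS[(k - 1) %% length(.PYMOL_COLORS) + 1]
    out <- c(out,
      sprintf("show cartoon, chain %s", chains[k]),
      sprintf("color %s, chain %s", col, chains[k]),
      sprintf("show surface, chain %s", chains[k]))
    resnos <- iface[[chains[k]]]
    if (length(resnos)) {
      selName <- sprintf("iface_%s", chains[k])
      out <- c(out,
        sprintf("select %s, chain %s and resi %s", selName, chains[k],
                paste(resnos, collapse = "+")),
        sprintf("show sticks, %s", selName),
        sprintf("color atomic, %s and not elem C", selName))
    }
  }
  c(out, "deselect", "zoom")
}

#' Generate a ChimeraX visualization script
#'
#' ChimeraX counterpart of [genPymolScript()]: cartoons per chain in distinct
#' colors, interface residues as sticks (carbons in the chain color, other
#' elements by heteroatom coloring) and the chain surfaces.
#'
#' @inheritParams genPymolScript
#' @return Character vector of script lines.
#' @export
genChimeraxScript <- function(contacts, chains, coordFile = "coords.pdb") {
  iface <- .interfaceResiduesByChain(contacts)
  out <- c(sprintf("open %s", coordFile), "hide atoms", "show cartoons",
           "set bgColor white")
  for (k in seq_along(chains)) {
    col <- .CHIMERAX_COLORS[(k - 1) %% length(.CHIMERAX_COLORS) + 1]
    out <- c(out, sprintf("color /%s %s", chains[k], col))
    resnos <- iface[[chains[k]]]
    if (length(resnos)) {
      spec <- sprintf("/%s:%s", chains[k], paste(resnos, collapse = ","))
      out <- c(out, sprintf("show %s atoms", spec),
               sprintf("style %s stick", spec),
               sprintf("color %s byhetero", spec))
    }
    out <- c(out, sprintf("surface /%s", chains[k]),
             sprintf("transparency /%s 50", chains[k]))
  }
  out
}
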