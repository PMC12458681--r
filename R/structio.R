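# Structure input: PDB/mmCIF parsing (via bio3d), model and assembly
# handling, and resolution of the two interface selections into atom sets.

.PROTEIN_RES <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                  "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                  "THR", "TRP", "TYR", "VAL", "MSE", "SEC", "PYL", "HYP",
                  "SEP", "TPO", "PTR", "CSO", "MLY", "KCX")
.NUCLEIC_RES <- c("A", "C", "G", "U", "I", "N", "DA", "DC", "DG", "DT", "DU",
                  "DI", "PSU", "5MU", "1MA", "7MG", "OMC", "OMG", "H2U",
                  "M2G", "2MG", "5MC", "4SU")
.WATER_RES <- c("HOH", "WAT", "DOD", "H2O")

.TWO_LETTER_ELEMENTS <- c("HE", "LI", "BE", "NE", "NA", "MG", "AL", "SI",
  "CL", "AR", "CA", "SC", "TI", "CR", "MN", "FE", "CO", "NI", "CU", "ZN",
  "GA", "GE", "AS", "SE", "BR", "KR", "RB", "SR", "MO", "RU", "RH", "PD",
  "AG", "CD", "SN", "SB", "TE", "XE", "CS", "BA", "PT", "AU", "HG", "TL",
  "PB", "BI")

.polymerClassOf <- function(resname, hetero) {
  cls <- ifelse(resname %in% .WATER_RES, "water",
         ifelse(resname %in% .PROTEIN_RES, "protein",
         ifelse(resname %in% .NUCLEIC_RES, "nucleic", "ligand")))
  # HETATM records of standard residues (e.g. MSE) keep their polymer class
  cls
}

# Infer the element symbol from a PDB atom name when the element column is
# absent. Digits and primes are stripped; a leading two-letter symbol is used
# only when it is a real element and the name is not a typical remoteness
# code (CA = alpha carbon, not calcium, for polymer residues).
.elementFromName <- function(name, resname, hetero) {
  nm <- toupper(gsub("[0-9'\"*]", "", trimws(name)))
  out <- character(length(nm))
  for (k in seq_along(nm)) {
    s <- nm[k]
    if (!nzchar(s)) { out[k] <- "X"; next }
    two <- substr(s, 1, 2)
    isPolymer <- resname[k] %in% c(.PROTEIN_RES, .NUCLEIC_RES, .WATER_RES)
    if (nchar(s) >= 2 && two %in% .TWO_LETTER_ELEMENTS &&
        (!isPolymer || two %in% c("SE", "FE", "ZN", "MG", "MN", "CL", "BR"))) {
      # side-chain SE of MSE, metals and halogens in ligands
      if (isPolymer && two %in% c("CA", "CD", "CE", "NE", "ND", "OD", "OE"))
        out[k] <- substr(s, 1, 1)
      else out[k] <- two
    } else {
      out[k] <- substr(s, 1, 1)
    }
  }
  out
}

# bio3d atom data.frame (plus per-model xyz) -> StructureModel
.modelFromBio3d <- function(atomdf, xyz, modelIndex, assemblyData = list()) {
  n <- nrow(atomdf)
  coords <- matrix(xyz, ncol = 3, byrow = TRUE)
  el <- toupper(trimws(ifelse(is.na(atomdf$elesy) | atomdf$elesy == "",
                              NA, atomdf$elesy)))
  bad <- is.na(el) | el == "" | !grepl("^[A-Z]{1,2}$", el)
  if (any(bad))
    el[bad] <- .elementFromName(atomdf$elety[bad], atomdf$resid[bad],
                                atomdf$type[bad] == "HETATM")
  a <- data.frame(
    serial = as.integer(atomdf$eleno),
    name = trimws(atomdf$elety),
    alt = ifelse(is.na(atomdf$alt), "", atomdf$alt),
    resname = trimws(atomdf$resid),
    chain = ifelse(is.na(atomdf$chain), " ", atomdf$chain),
    resno = as.integer(atomdf$resno),
    icode = ifelse(is.na(atomdf$insert), "", atomdf$insert),
    x = coords[, 1], y = coords[, 2], z = coords[, 3],
    occupancy = ifelse(is.na(atomdf$o), 1, pmin(1, pmax(0, atomdf$o))),
    bfactor = ifelse(is.na(atomdf$b), 0, atomdf$b),
    element = el,
    hetero = atomdf$type == "HETATM",
    stringsAsFactors = FALSE)
  a$polymerClass <- .polymerClassOf(a$resname, a$hetero)
  a <- .collapseAltLocs(a)
  new("StructureModel", atoms = a, modelIndex = as.integer(modelIndex),
      assemblyId = "asymmetric", assemblyData = assemblyData)
}

# Alternate locations: keep the highest-occupancy altloc per atom name within
# a residue; first record wins ties. Surviving atoms get alt = "".
.collapseAltLocs <- function(a) {
  has <- a$alt != ""
  if (!any(has)) return(a)
  key <- paste(a$chain, a$resno, a$icode, a$resname, a$name, sep = "\r")
  keep <- rep(TRUE, nrow(a))
  for (k in unique(key[has])) {
    rows <- which(key == k)
    if (length(rows) < 2) next
    best <- rows[which.max(a$occupancy[rows])]  # which.max: first on ties
    keep[setdiff(rows, best)] <- FALSE
  }
  a <- a[keep, , drop = FALSE]
  a$alt <- ""
  rownames(a) <- NULL
  a
}

#' Read a structure file into one StructureModel per coordinate model
#'
#' Parses standard PDB or mmCIF coordinates (all ATOM and HETATM records,
#' including waters and hydrogens; filtering happens later, at selection
#' time). Alternate locations are collapsed to the highest-occupancy
#' conformer. Elements missing from the file are inferred from atom names.
#'
#' @param source path to a `.pdb`, `.ent`, `.cif` or `.mmcif` file.
#' @param format `"auto"` (by extension), `"pdb"` or `"mmcif"`.
#' @return A list of [StructureModel-class], one per MODEL record (a single
#'   model for files without MODEL records and for mmCIF input).
#' @examples
#' f <- makeFixture("two_atoms", tempdir())
#' mods <- readStructure(f)
#' nAtoms(mods[[1]])
#' @export
readStructure <- function(source, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (!file.exists(source)) stop("input file not found: ", source)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(source))
    format <- if (ext %in% c("cif", "mmcif")) "mmcif" else "pdb"
  }
  if (format == "pdb") {
    pdb <- tryCatch(
      suppressWarnings(bio3d::read.pdb(source, multi = TRUE, rm.alt = FALSE, verbose = FALSE)),
      error = function(e) stop("cannot parse PDB file '", source, "': ",
                               conditionMessage(e), call. = FALSE))
    if (is.null(pdb$atom) || !nrow(pdb$atom))
      stop("empty structure: no ATOM/HETATM records in ", source)
    nmod <- if (is.matrix(pdb$xyz)) nrow(pdb$xyz) else 1L
    lapply(seq_len(nmod), function(m) {
      xyz <- if (is.matrix(pdb$xyz)) pdb$xyz[m, ] else as.numeric(pdb$xyz)
      .modelFromBio3d(pdb$atom, xyz, m)
    })
  } else {
    cif <- tryCatch(
      suppressWarnings(bio3d::read.cif(source, rm.alt = FALSE, verbose = FALSE)),
      error = function(e) stop("cannot parse mmCIF file '", source, "': ",
                               conditionMessage(e), call. = FALSE))
    if (is.null(cif$atom) || !nrow(cif$atom))
      stop("empty structure: no atom_site records in ", source)
    asm <- .parseCifAssemblies(source)
    nmod <- if (is.matrix(cif$xyz)) nrow(cif$xyz) else 1L
    lapply(seq_len(nmod), function(m) {
      xyz <- if (is.matrix(cif$xyz)) cif$xyz[m, ] else as.numeric(cif$xyz)
      .modelFromBio3d(cif$atom, xyz, m, assemblyData = asm)
    })
  }
}

#' Select the first model of a multi-model (e.g. NMR) structure
#'
#' @param models list of [StructureModel-class] from [readStructure()].
#' @return The model with the lowest model index.
#' @export
selectFirstModel <- function(models) {
  if (!length(models)) stop("empty model list")
  idx <- vapply(models, modelIndex, integer(1))
  models[[which.min(idx)]]
}

# ---- mmCIF assembly support -------------------------------------------------

# Minimal reader for the two assembly categories of an mmCIF file. Values may
# be quoted; multi-line values are not supported (they do not occur in these
# categories).
.parseCifAssemblies <- function(path) {
  lines <- readLines(path, warn = FALSE)
  readLoop <- function(category) {
    starts <- grep("^loop_\\s*$", lines)
    for (s in starts) {
      i <- s + 1
      tags <- character()
      while (i <= length(lines) && grepl("^_", lines[i])) {
        tags <- c(tags, trimws(lines[i])); i <- i + 1
      }
      if (!length(tags) || !startsWith(tags[1], paste0("_", category, ".")))
        next
      vals <- list()
      while (i <= length(lines) && !grepl("^(loop_|#|_|data_)", lines[i]) &&
             nzchar(trimws(lines[i]))) {
        vals[[length(vals) + 1]] <- .cifTokens(lines[i]); i <- i + 1
      }
      if (!length(vals)) return(NULL)
      m <- do.call(rbind, vals)
      colnames(m) <- sub(paste0("^_", category, "\\."), "", tags)
      return(as.data.frame(m, stringsAsFactors = FALSE))
    }
    # non-loop (single row) form
    tagRows <- grep(paste0("^_", category, "\\."), lines)
    if (!length(tagRows)) return(NULL)
    out <- list()
    for (r in tagRows) {
      tok <- .cifTokens(lines[r])
      out[[sub(paste0("^_", category, "\\."), "", tok[1])]] <- tok[2]
    }
    as.data.frame(out, stringsAsFactors = FALSE)
  }
  gen <- readLoop("pdbx_struct_assembly_gen")
  oper <- readLoop("pdbx_struct_oper_list")
  if (is.null(gen) || is.null(oper)) return(list())
  list(gen = gen, oper = oper)
}

.cifTokens <- function(line) {
  # split on whitespace, honouring single/double quotes
  out <- character()
  rest <- trimws(line)
  while (nzchar(rest)) {
    ch <- substr(rest, 1, 1)
    if (ch %in% c("'", '"')) {
      m <- regexpr(paste0(ch, "([^", ch, "]*)", ch), rest)
      tok <- substr(rest, 2, attr(m, "match.length") - 1)
      rest <- trimws(substr(rest, attr(m, "match.length") + 1, nchar(rest)))
    } else {
      m <- regexpr("^\\S+", rest)
      tok <- substr(rest, 1, attr(m, "match.length"))
      rest <- trimws(substr(rest, attr(m, "match.length") + 1, nchar(rest)))
    }
    out <- c(out, tok)
  }
  out
}

# "1,2,4-6" -> c("1","2","4","5","6"); parenthesised cartesian expressions are
# not supported (rare; an explicit error is raised).
.expandOperExpression <- function(expr) {
  if (grepl("[()]", expr))
    stop("cartesian-product oper_expression not supported: ", expr)
  parts <- strsplit(expr, ",", fixed = TRUE)[[1]]
  out <- character()
  for (p in parts) {
    p <- trimws(p)
    if (grepl("^\\d+-\\d+$", p)) {
      ab <- as.integer(strsplit(p, "-", fixed = TRUE)[[1]])
      out <- c(out, as.character(seq(ab[1], ab[2])))
    } else out <- c(out, p)
  }
  out
}

.operMatrix <- function(oper, id) {
  row <- oper[oper$id == id, , drop = FALSE]
  if (!nrow(row)) stop("operator '", id, "' missing from pdbx_struct_oper_list")
  g <- function(nm) as.numeric(row[[nm]][1])
  R <- matrix(c(g("matrix[1][1]"), g("matrix[1][2]"), g("matrix[1][3]"),
                g("matrix[2][1]"), g("matrix[2][2]"), g("matrix[2][3]"),
                g("matrix[3][1]"), g("matrix[3][2]"), g("matrix[3][3]")),
              nrow = 3, byrow = TRUE)
  t <- c(g("vector[1]"), g("vector[2]"), g("vector[3]"))
  list(R = R, t = t)
}

#' Expand a biological assembly of an mmCIF structure
#'
#' Applies the rotation/translation operators listed in the file's
#' `pdbx_struct_assembly_gen` / `pdbx_struct_oper_list` categories to the
#' listed chains. Copies generated by non-identity operators are renamed
#' `"<chain>-<operator ordinal>"` (e.g. `"A-2"`), which is collision-free and
#' human-readable. PDB-format input carries no assembly instructions: use a
#' pre-expanded biological-unit file instead.
#'
#' @param model an asymmetric [StructureModel-class] read from mmCIF.
#' @param assemblyId assembly identifier as given in the file (e.g. `"1"`).
#' @return A new [StructureModel-class] with `assemblyId` set.
#' @export
applyAssembly <- function(model, assemblyId) {
  ad <- model@assemblyData
  if (!length(ad))
    stop("no assembly definitions available; PDB-format biological units ",
         "must be supplied as pre-expanded files")
  gen <- ad$gen[ad$gen$assembly_id == as.character(assemblyId), , drop = FALSE]
  if (!nrow(gen))
    stop("unknown assembly '", assemblyId, "'; available: ",
         paste(unique(ad$gen$assembly_id), collapse = ", "))
  a <- model@atoms
  pieces <- list()
  for (r in seq_len(nrow(gen))) {
    operIds <- .expandOperExpression(gen$oper_expression[r])
    chains <- trimws(strsplit(gen$asym_id_list[r], ",", fixed = TRUE)[[1]])
    sub <- a[a$chain %in% chains, , drop = FALSE]
    if (!nrow(sub))
      stop("assembly chains not present in model: ",
           paste(chains, collapse = ","))
    for (k in seq_along(operIds)) {
      op <- .operMatrix(ad$oper, operIds[k])
      isIdentity <- all(abs(op$R - diag(3)) < 1e-9) && all(abs(op$t) < 1e-9)
      copy <- sub
      if (!isIdentity) {
        xyz <- as.matrix(sub[, c("x", "y", "z")]) %*% t(op$R)
        copy$x <- xyz[, 1] + op$t[1]
        copy$y <- xyz[, 2] + op$t[2]
        copy$z <- xyz[, 3] + op$t[3]
        copy$chain <- paste0(sub$chain, "-", k)
      }
      pieces[[length(pieces) + 1]] <- copy
    }
  }
  out <- do.call(rbind, pieces)
  out <- out[!duplicated(paste(out$chain, out$serial)), , drop = FALSE]
  out$serial <- seq_len(nrow(out))
  rownames(out) <- NULL
  new("StructureModel", atoms = out, modelIndex = model@modelIndex,
      assemblyId = as.character(assemblyId), assemblyData = ad)
}

# ---- selections -------------------------------------------------------------

#' Describe one side of an interface selection
#'
#' @param chain chain identifier as it appears in the structure.
#' @param ranges optional list of inclusive `c(start, end)` author-numbered
#'   residue intervals; `NULL` selects the whole chain. Required (on both
#'   sides) when the two selections name the same chain.
#' @return A list usable as `sel1`/`sel2` in [resolveSelection()].
#' @export
regionSelection <- function(chain, ranges = NULL) {
  if (!is.null(ranges)) {
    if (!is.list(ranges)) ranges <- list(ranges)
    for (rg in ranges) {
      if (length(rg) != 2 || rg[1] > rg[2])
        stop("each range must be c(start, end) with start <= end")
    }
    rg <- do.call(rbind, ranges)
    o <- order(rg[, 1])
    rg <- rg[o, , drop = FALSE]
    if (nrow(rg) > 1 && any(rg[-1, 1] <= rg[-nrow(rg), 2]))
      stop("ranges within one selection overlap")
    ranges <- lapply(seq_len(nrow(rg)), function(i) rg[i, ])
  }
  list(chain = as.character(chain), ranges = ranges)
}

.selectionRows <- function(a, sel) {
  rows <- which(a$chain == sel$chain)
  if (!is.null(sel$ranges)) {
    inAny <- rep(FALSE, length(rows))
    for (rg in sel$ranges)
      inAny <- inAny | (a$resno[rows] >= rg[1] & a$resno[rows] <= rg[2])
    rows <- rows[inAny]
  }
  rows
}

#' Resolve two region selections into disjoint heavy-atom sets
#'
#' Hydrogen and deuterium atoms are always excluded; waters are excluded
#' unless a selection consists entirely of water (explicit water ligand).
#' The analysis mode is `"ligand"` when either selection resolves entirely to
#' small-molecule residues, `"intrachain"` when both selections are regions
#' of one chain, and `"interchain"` otherwise.
#'
#' @param model a [StructureModel-class].
#' @param sel1,sel2 selections from [regionSelection()].
#' @return An [InterfaceSelection-class].
#' @examples
#' f <- makeFixture("helix_pair", tempdir())
#' m <- selectFirstModel(readStructure(f))
#' sel <- resolveSelection(m, regionSelection("A"), regionSelection("B"))
#' selectionMode(sel)
#' @export
resolveSelection <- function(model, sel1, sel2) {
  a <- model@atoms
  for (s in list(sel1, sel2))
    if (!s$chain %in% a$chain)
      stop("unknown chain '", s$chain, "'; available chains: ",
           paste(unique(a$chain), collapse = ", "))
  sameChain <- sel1$chain == sel2$chain
  if (sameChain) {
    if (is.null(sel1$ranges) || is.null(sel2$ranges))
      stop("intrachain analysis requires residue ranges for both regions")
    for (r1 in sel1$ranges) for (r2 in sel2$ranges)
      if (r1[1] <= r2[2] && r2[1] <= r1[2])
        stop("intrachain regions overlap: ",
             paste(r1, collapse = "-"), " vs ", paste(r2, collapse = "-"))
  }
  resolveOne <- function(sel) {
    rows <- .selectionRows(a, sel)
    rows <- rows[!(a$element[rows] %in% c("H", "D"))]
    if (!length(rows))
      stop("selection resolves to zero heavy atoms (chain ", sel$chain, ")")
    allWater <- all(a$polymerClass[rows] == "water")
    if (!allWater) rows <- rows[a$polymerClass[rows] != "water"]
    list(rows = as.integer(rows), allWater = allWater,
         allLigand = all(a$polymerClass[rows] %in% c("ligand", "water")))
  }
  r1 <- resolveOne(sel1)
  r2 <- resolveOne(sel2)
  mode <- if (r1$allLigand || r2$allLigand) "ligand"
          else if (sameChain) "intrachain" else "interchain"
  new("InterfaceSelection", model = model, idx1 = r1$rows, idx2 = r2$rows,
      sel1 = sel1, sel2 = sel2, mode = mode)
}

# ---- PDB writing (round-trips and fixture support) -------------------------

#' Write a StructureModel as a PDB file
#'
#' Fixed-column wwPDB v3.3 ATOM/HETATM formatting; used for round-trip tests
#' and to place a coordinate copy next to generated visualization scripts.
#'
#' @param model a [StructureModel-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeStructurePDB <- function(model, path) {
  a <- model@atoms
  # PDB has a single-character chain field; assembly copies ("A-2") are
  # remapped deterministically onto unused one-character ids.
  uc <- unique(a$chain)
  if (any(nchar(uc) > 1)) {
    pool <- c(LETTERS, letters, as.character(0:9))
    map <- stats::setNames(uc, uc)
    long <- uc[nchar(uc) > 1]
    map[long] <- setdiff(pool, uc[nchar(uc) == 1])[seq_along(long)]
    a$chain <- unname(map[a$chain])
  }
  recs <- character(nrow(a))
  for (i in seq_len(nrow(a))) {
    nm <- a$name[i]
    # atom-name column alignment: element-first names of <4 chars indent 1
    nmF <- if (nchar(nm) >= 4) substr(nm, 1, 4)
           else sprintf(" %-3s", nm)
    recs[i] <- sprintf("%-6s%5d %s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      ifelse(a$hetero[i], "HETATM", "ATOM"), a$serial[i] %% 100000, nmF,
      substr(paste0(a$alt[i], " "), 1, 1), a$resname[i], a$chain[i],
      a$resno[i], substr(paste0(a$icode[i], " "), 1, 1),
      a$x[i], a$y[i], a$z[i], a$occupancy[i], a$bfactor[i], a$element[i])
  }
  writeLines(c(recs, "END"), path)
  invisible(path)
}
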