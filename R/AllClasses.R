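#' @import methods
NULL

# Columns every atom table must carry, in this order.
.ATOM_COLS <- c("serial", "name", "alt", "resname", "chain", "resno", "icode",
                "x", "y", "z", "occupancy", "bfactor", "element", "hetero",
                "polymerClass")

#' StructureModel: one coordinate model of a macromolecular structure
#'
#' A `StructureModel` holds a flat atom table (one row per atom) together with
#' the model index (1 for X-ray structures and for the first NMR model) and the
#' identifier of the biological assembly it represents (`"asymmetric"` unless
#' [applyAssembly()] was used). Atoms are stored in file order; every atom
#' belongs to exactly one residue identified by `(chain, resno, icode)` and
#' each residue carries a polymer class (`protein`, `nucleic`, `ligand`,
#' `water`) assigned once at parse time from standard residue-name tables.
#'
#' @slot atoms data.frame with columns `serial`, `name`, `alt`, `resname`,
#'   `chain`, `resno`, `icode`, `x`, `y`, `z`, `occupancy`, `bfactor`,
#'   `element`, `hetero`, `polymerClass`.
#' @slot modelIndex integer model number (>= 1).
#' @slot assemblyId character, `"asymmetric"` or the expanded assembly id.
#' @slot assemblyData list of parsed mmCIF assembly instructions (internal;
#'   empty for PDB input).
#'
#' @seealso [readStructure()], [atoms()], [resolveSelection()]
#' @export
setClass("StructureModel",
  representation(atoms = "data.frame", modelIndex = "integer",
                 assemblyId = "character", assemblyData = "list"),
  prototype(modelIndex = 1L, assemblyId = "asymmetric", assemblyData = list()))

setValidity("StructureModel", function(object) {
  a <- object@atoms
  if (!all(.ATOM_COLS %in% names(a)))
    return(paste("atom table lacks columns:",
                 paste(setdiff(.ATOM_COLS, names(a)), collapse = ", ")))
  if (nrow(a)) {
    if (!all(is.finite(a$x) & is.finite(a$y) & is.finite(a$z)))
      return("non-finite atom coordinates")
    if (any(a$occupancy < 0 | a$occupancy > 1, na.rm = TRUE))
      return("occupancy outside [0, 1]")
    if (!all(a$polymerClass %in% c("protein", "nucleic", "ligand", "water")))
      return("invalid polymerClass value")
  }
  if (length(object@modelIndex) != 1L || object@modelIndex < 1L)
    return("modelIndex must be a single integer >= 1")
  TRUE
})

#' InterfaceSelection: two resolved atom sets of an interface
#'
#' Produced by [resolveSelection()]. Holds the parent model, the row indices
#' (into `atoms(model)`) of the two heavy-atom sets, the original region
#' selections, and the analysis mode: `"interchain"` (two different chains),
#' `"intrachain"` (two regions of one chain) or `"ligand"` (one partner is a
#' small molecule).
#'
#' @slot model the parent [StructureModel-class].
#' @slot idx1,idx2 integer atom-row indices of selection 1 / 2.
#' @slot sel1,sel2 the region selections (lists with `chain`, `ranges`).
#' @slot mode character scalar: interchain, intrachain or ligand.
#' @export
setClass("InterfaceSelection",
  representation(model = "StructureModel", idx1 = "integer", idx2 = "integer",
                 sel1 = "list", sel2 = "list", mode = "character"))

setValidity("InterfaceSelection", function(object) {
  if (!object@mode %in% c("interchain", "intrachain", "ligand"))
    return("mode must be interchain, intrachain or ligand")
  if (length(intersect(object@idx1, object@idx2)))
    return("selections overlap")
  n <- nrow(object@model@atoms)
  if (length(object@idx1) && max(object@idx1) > n) return("idx1 out of range")
  if (length(object@idx2) && max(object@idx2) > n) return("idx2 out of range")
  TRUE
})

#' ContactMap: 2D residue-by-residue (or atom-level) interface map
#'
#' Rows are the residues (atoms in ligand mode) of selection 1, columns those
#' of selection 2. Cells are sparse: only pairs with at least one contact are
#' stored. The `light` variant restricts rows/columns to contact-bearing
#' residues; the `full` variant enumerates every residue of the selections.
#'
#' @slot rowInfo,colInfo data.frame margins: `chain`, `resno`, `icode`,
#'   `label` (residue type, or atom name in ligand mode), `ss` (H/S/blank)
#'   and `bin` (0-9 interface burial code).
#' @slot cells data.frame with `row`, `col` (1-based margin positions),
#'   `text`, `color` (blue/yellow/green/gray/none), `shade` (tier 1-3) and
#'   the class counts `nPolar`, `nNonpolar`, `nOther`, `nUntyped`.
#' @slot variant `"light"` or `"full"`.
#' @slot mode `"macromolecule"` or `"ligand"`.
#' @export
setClass("ContactMap",
  representation(rowInfo = "data.frame", colInfo = "data.frame",
                 cells = "data.frame", variant = "character",
                 mode = "character"))

setValidity("ContactMap", function(object) {
  if (!object@variant %in% c("light", "full")) return("bad variant")
  if (!object@mode %in% c("macromolecule", "ligand")) return("bad mode")
  cl <- object@cells
  if (nrow(cl)) {
    if (any(cl$row < 1 | cl$row > nrow(object@rowInfo))) return("cell row out of range")
    if (any(cl$col < 1 | cl$col > nrow(object@colInfo))) return("cell col out of range")
    if (!all(cl$color %in% c("blue", "yellow", "green", "gray", "none")))
      return("bad cell color")
    if (!all(cl$shade %in% 1:3)) return("bad shade tier")
  }
  TRUE
})
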