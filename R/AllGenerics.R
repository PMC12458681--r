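#' Accessors for StructureModel and InterfaceSelection
#'
#' `atoms()` returns the atom table, `nAtoms()` the number of atoms,
#' `chainIds()` the ordered unique chain identifiers, `modelIndex()` the model
#' number and `assemblyId()` the assembly provenance. For selections,
#' `atomIndices()` returns the two resolved index vectors and
#' `selectionMode()` the analysis mode.
#'
#' @param x a [StructureModel-class] or [InterfaceSelection-class].
#' @return See details; accessors return the corresponding slot contents.
#' @name accessors
#' @aliases atoms nAtoms chainIds modelIndex assemblyId atomIndices selectionMode
NULL

#' @rdname accessors
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))
#' @rdname accessors
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))
#' @rdname accessors
#' @export
setGeneric("chainIds", function(x) standardGeneric("chainIds"))
#' @rdname accessors
#' @export
setGeneric("modelIndex", function(x) standardGeneric("modelIndex"))
#' @rdname accessors
#' @export
setGeneric("assemblyId", function(x) standardGeneric("assemblyId"))
#' @rdname accessors
#' @export
setGeneric("atomIndices", function(x) standardGeneric("atomIndices"))
#' @rdname accessors
#' @export
setGeneric("selectionMode", function(x) standardGeneric("selectionMode"))

#' @rdname accessors
setMethod("atoms", "StructureModel", function(x) x@atoms)
#' @rdname accessors
setMethod("nAtoms", "StructureModel", function(x) nrow(x@atoms))
#' @rdname accessors
setMethod("chainIds", "StructureModel", function(x) unique(x@atoms$chain))
#' @rdname accessors
setMethod("modelIndex", "StructureModel", function(x) x@modelIndex)
#' @rdname accessors
setMethod("assemblyId", "StructureModel", function(x) x@assemblyId)

#' @rdname accessors
setMethod("atomIndices", "InterfaceSelection",
          function(x) list(sel1 = x@idx1, sel2 = x@idx2))
#' @rdname accessors
setMethod("selectionMode", "InterfaceSelection", function(x) x@mode)

setMethod("show", "StructureModel", function(object) {
  a <- object@atoms
  nres <- nrow(unique(a[, c("chain", "resno", "icode")]))
  cat(sprintf("StructureModel: %d atoms, %d residues, %d chain(s) [%s]\n",
              nrow(a), nres, length(unique(a$chain)),
              paste(unique(a$chain), collapse = ",")))
  cat(sprintf("  model %d, assembly %s\n", object@modelIndex, object@assemblyId))
  cls <- table(unique(a[, c("chain", "resno", "icode", "polymerClass")])$polymerClass)
  cat("  residue classes:", paste(names(cls), cls, sep = "=", collapse = " "), "\n")
})

setMethod("show", "InterfaceSelection", function(object) {
  cat(sprintf("InterfaceSelection (%s): %d vs %d heavy atoms\n", object@mode,
              length(object@idx1), length(object@idx2)))
})

setMethod("show", "ContactMap", function(object) {
  cat(sprintf("ContactMap [%s, %s]: %d x %d margins, %d occupied cells\n",
              object@variant, object@mode, nrow(object@rowInfo),
              nrow(object@colInfo), nrow(object@cells)))
})
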