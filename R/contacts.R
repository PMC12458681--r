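# Contact detection and chemical classification.
#
# A contact is a pair of heavy atoms, one per selection, whose euclidean
# separation is less than or equal to the threshold (default 4.0 A,
# inclusive). Classification is by element only, deliberately angle-free:
# both atoms in {N,O} -> polar, both in {C,S} -> nonpolar, one of each ->
# other. This lenient criterion is robust to low-resolution structures in
# which hydrogens are absent and Asn/Gln side-chain N/O may be swapped.

#' Polarity class of a heavy-atom element
#'
#' N and O are polar, C and S nonpolar. Phosphorus is treated as polar (it
#' anchors nucleic-acid phosphate contacts in the polar lists) and selenium
#' as nonpolar by analogy with sulfur (MSE). Any other heavy element (metals,
#' halogens) is `"other_element"`. Hydrogen/deuterium are an error: they are
#' excluded upstream from every analysis.
#'
#' @param element character vector of element symbols.
#' @return Character vector: `"polar"`, `"nonpolar"` or `"other_element"`.
#' @examples
#' atomPolarity(c("N", "O", "C", "S", "P", "SE", "FE"))
#' @export
atomPolarity <- function(element) {
  element <- toupper(element)
  if (any(element %in% c("H", "D")))
    stop("hydrogen/deuterium atoms must be filtered before classification")
  ifelse(element %in% c("N", "O", "P"), "polar",
  ifelse(element %in% c("C", "S", "SE"), "nonpolar", "other_element"))
}

#' Classify one contact from its two atom polarities
#'
#' In ligand mode every contact is `"untyped"`: atoms of small molecules are
#' not assigned polarities and all their contacts are listed together.
#'
#' @param polA,polB polarity classes from [atomPolarity()] (vectorized).
#' @param mode `"interchain"`, `"intrachain"` or `"ligand"`.
#' @return Character vector: `"polar"`, `"nonpolar"`, `"other"` or `"untyped"`.
#' @export
classifyContact <- function(polA, polB, mode = "interchain") {
  mode <- match.arg(mode, c("interchain", "intrachain", "ligand"))
  if (mode == "ligand") return(rep("untyped", max(length(polA), length(polB))))
  ifelse(polA == "polar" & polB == "polar", "polar",
  ifelse(polA == "nonpolar" & polB == "nonpolar", "nonpolar", "other"))
}

#' Detect all cross-selection contacts within a distance threshold
#'
#' Uses a uniform-grid spatial index; the result is identical to exhaustive
#' pairwise search. Distances are carried at full precision (rendering to two
#' decimals happens in the report writers). In intrachain mode, residue pairs
#' separated by fewer than two positions in sequence (covalently bonded
#' neighbours) are excluded and a message notes how many pairs were dropped.
#'
#' @param sel an [InterfaceSelection-class] from [resolveSelection()].
#' @param threshold contact distance threshold in Angstrom (inclusive);
#'   default 4.0.
#' @return data.frame with one row per contact: residue/atom identifiers of
#'   both endpoints (`chain1`, `resname1`, `resno1`, `icode1`, `name1`,
#'   `element1`, and the same for `2`), `distance` and `class`.
#' @examples
#' f <- makeFixture("two_atoms", tempdir())
#' m <- selectFirstModel(readStructure(f))
#' sel <- resolveSelection(m, regionSelection("A"), regionSelection("B"))
#' findContacts(sel)
#' @export
findContacts <- function(sel, threshold = 4.0) {
  stopifnot(is(sel, "InterfaceSelection"), threshold > 0)
  a <- sel@model@atoms
  xa <- as.matrix(a[sel@idx1, c("x", "y", "z")])
  xb <- as.matrix(a[sel@idx2, c("x", "y", "z")])
  pairs <- .crossPairsWithin(xa, xb, threshold)
  ia <- sel@idx1[pairs$i]
  ib <- sel@idx2[pairs$j]
  if (sel@mode == "intrachain" && nrow(pairs)) {
    near <- a$chain[ia] == a$chain[ib] & abs(a$resno[ia] - a$resno[ib]) < 2
    if (any(near))
      message("intrachain mode: excluded ", sum(near),
              " contact(s) between sequence-adjacent residues")
    ia <- ia[!near]; ib <- ib[!near]; pairs <- pairs[!near, , drop = FALSE]
  }
  cls <- if (!nrow(pairs)) character(0)
         else if (sel@mode == "ligand") rep("untyped", nrow(pairs))
         else classifyContact(atomPolarity(a$element[ia]),
                              atomPolarity(a$element[ib]), sel@mode)
  out <- data.frame(
    chain1 = a$chain[ia], resname1 = a$resname[ia], resno1 = a$resno[ia],
    icode1 = a$icode[ia], name1 = a$name[ia], element1 = a$element[ia],
    chain2 = a$chain[ib], resname2 = a$resname[ib], resno2 = a$resno[ib],
    icode2 = a$icode[ib], name2 = a$name[ib], element2 = a$element[ib],
    distance = pairs$d, class = cls, stringsAsFactors = FALSE)
  out <- out[order(out$chain1, out$resno1, out$icode1, out$name1,
                   out$chain2, out$resno2, out$icode2, out$name2,
                   out$distance), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Aggregate contacts into per-residue-pair summaries
#'
#' One summary row per distinct residue pair, carrying the number of polar,
#' nonpolar, other and untyped contacts and the minimum distance. Counts
#' conserve the contact multiset. Rows are ordered by the first residue's
#' sequence position, then the second's.
#'
#' @param contacts data.frame from [findContacts()].
#' @return data.frame with columns `chain1`, `resname1`, `resno1`, `icode1`,
#'   `chain2`, `resname2`, `resno2`, `icode2`, `nPolar`, `nNonpolar`,
#'   `nOther`, `nUntyped`, `minDistance`.
#' @export
summarizePairs <- function(contacts) {
  cols <- c("chain1", "resname1", "resno1", "icode1",
            "chain2", "resname2", "resno2", "icode2")
  if (!nrow(contacts)) {
    out <- contacts[, cols, drop = FALSE]
    out$nPolar <- out$nNonpolar <- out$nOther <- out$nUntyped <- integer(0)
    out$minDistance <- numeric(0)
    return(out)
  }
  key <- do.call(paste, c(contacts[cols], sep = "\r"))
  split <- split(seq_len(nrow(contacts)), key)
  rows <- lapply(split, function(ii) {
    first <- contacts[ii[1], cols, drop = FALSE]
    cl <- contacts$class[ii]
    cbind(first, data.frame(
      nPolar = sum(cl == "polar"), nNonpolar = sum(cl == "nonpolar"),
      nOther = sum(cl == "other"), nUntyped = sum(cl == "untyped"),
      minDistance = min(contacts$distance[ii])))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$chain1, out$resno1, out$icode1,
                   out$chain2, out$resno2, out$icode2), , drop = FALSE]
  rownames(out) <- NULL
  out
}
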