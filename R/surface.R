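# Solvent-accessible surface area (Shrake-Rupley) and interface burial.
#
# SASA is the area traced by the centre of a 1.4 A probe rolling over the van
# der Waals surface. The implementation samples each expanded sphere with a
# deterministic golden-spiral point set (no randomness anywhere), so repeated
# runs are bit-identical. Interface-buried SASA of a residue is its SASA in
# the free (partner-removed) state minus its SASA in the complex, clipped at
# zero, and is encoded as an integer 0-9 in uniform 10 A^2 steps
# (<= 9 A^2 -> 0, >= 90 A^2 -> 9).

#' Van der Waals radii set for SASA computation
#'
#' Element-keyed radii in the NACCESS tradition (C 1.70, N 1.65, O 1.40,
#' S 1.85, P 1.90; anything unknown falls back to `default`), plus the probe
#' radius (1.4 A, a water molecule). An optional plain-text two-column file
#' (element, radius) can override or extend the table.
#'
#' @param file optional path to a two-column whitespace-separated override
#'   file; lines starting with `#` are ignored.
#' @param probe probe radius in Angstrom.
#' @return A list with `radii` (named numeric vector), `default` and `probe`.
#' @export
defaultRadii <- function(file = NULL, probe = 1.4) {
  radii <- c(C = 1.70, N = 1.65, O = 1.40, S = 1.85, P = 1.90, SE = 1.90,
             F = 1.47, CL = 1.75, BR = 1.85, I = 1.98)
  if (!is.null(file)) {
    tab <- utils::read.table(file, header = FALSE, comment.char = "#",
                             col.names = c("element", "radius"),
                             stringsAsFactors = FALSE)
    radii[toupper(tab$element)] <- as.numeric(tab$radius)
  }
  stopifnot(all(radii > 0), probe > 0)
  list(radii = radii, default = 1.80, probe = probe)
}

.radiusOf <- function(elements, radii) {
  r <- unname(radii$radii[elements])
  unknown <- is.na(r)
  if (any(unknown)) {
    warning("no van der Waals radius for element(s) ",
            paste(unique(elements[unknown]), collapse = ", "),
            "; using default ", radii$default, " A", call. = FALSE)
    r[unknown] <- radii$default
  }
  r
}

# Deterministic near-uniform unit sphere sampling (golden spiral / Fibonacci).
.spherePoints <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  phi <- i * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Per-atom solvent-accessible surface area (Shrake-Rupley)
#'
#' For each atom, `nPoints` test points are placed on the sphere of radius
#' `r_atom + probe`; a point is exposed when it lies outside every
#' neighbour's expanded sphere. SASA = (exposed fraction) x 4 pi (r+probe)^2.
#'
#' @param xyz numeric n x 3 coordinate matrix (heavy atoms only).
#' @param elements character vector of element symbols, length n.
#' @param radii radii set from [defaultRadii()].
#' @param nPoints number of test points per atom (>= 60; default 960).
#' @return Numeric vector of per-atom SASA in Angstrom^2.
#' @examples
#' # an isolated carbon: the full expanded sphere, 4*pi*(1.7+1.4)^2
#' shrakeRupley(matrix(0, 1, 3), "C")
#' @export
shrakeRupley <- function(xyz, elements, radii = defaultRadii(),
                         nPoints = 960L) {
  xyz <- as.matrix(xyz)
  stopifnot(ncol(xyz) == 3, nPoints >= 60)
  n <- nrow(xyz)
  if (!n) return(numeric(0))
  if (any(toupper(elements) %in% c("H", "D")))
    stop("SASA expects hydrogen-free atom sets")
  r <- .radiusOf(toupper(elements), radii)
  rp <- r + radii$probe
  pts <- .spherePoints(as.integer(nPoints))
  # neighbour lists via the grid index; cutoff covers any touching pair
  cutoff <- 2 * max(rp)
  nb <- .crossPairsWithin(xyz, xyz, cutoff)
  nb <- nb[nb$i != nb$j, , drop = FALSE]
  nb <- nb[nb$d < rp[nb$i] + rp[nb$j], , drop = FALSE]
  nbList <- split(nb$j, factor(nb$i, levels = seq_len(n)))
  out <- numeric(n)
  for (i in seq_len(n)) {
    js <- nbList[[i]]
    area <- 4 * pi * rp[i]^2
    if (!length(js)) { out[i] <- area; next }
    p <- pts * rp[i]
    p <- sweep(p, 2, xyz[i, ], "+")
    buried <- rep(FALSE, nrow(p))
    for (j in js) {
      d2 <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 +
        (p[, 3] - xyz[j, 3])^2
      buried <- buried | d2 < rp[j]^2
      if (all(buried)) break
    }
    out[i] <- mean(!buried) * area
  }
  out
}

#' Encode interface-buried SASA as an integer 0-9 code
#'
#' Uniform 10 A^2 bins: `min(9, floor(delta / 10))`, the unique uniform
#' binning with the endpoints delta <= 9 A^2 -> 0 and delta >= 90 A^2 -> 9.
#'
#' @param delta non-negative buried-area value(s) in Angstrom^2.
#' @return Integer vector of codes in 0..9.
#' @examples
#' burialBin(c(0, 9, 55, 90, 120))
#' @export
burialBin <- function(delta) {
  if (any(delta < 0)) stop("negative buried area (clip upstream)")
  as.integer(pmin(9, floor(delta / 10)))
}

#' Per-residue interface burial for both selections
#'
#' The complex state contains both selections' atoms (for intrachain
#' analysis, the rest of the shared chain as well); each selection's free
#' state removes only the partner selection's atoms. The difference,
#' clipped at zero, is the interface-buried area of each residue.
#'
#' @param sel an [InterfaceSelection-class].
#' @param radii radii set from [defaultRadii()].
#' @param nPoints Shrake-Rupley sample points per atom.
#' @return data.frame with one row per residue of the two selections:
#'   `selection` (1 or 2), `chain`, `resname`, `resno`, `icode`,
#'   `polymerClass`, `sasaFree`, `sasaComplex`, `delta`, `bin`.
#' @export
residueBurial <- function(sel, radii = defaultRadii(), nPoints = 960L) {
  stopifnot(is(sel, "InterfaceSelection"))
  a <- sel@model@atoms
  if (sel@mode == "intrachain") {
    chainRows <- which(a$chain == sel@sel1$chain &
                       !(a$element %in% c("H", "D")) &
                       a$polymerClass != "water")
    ctx <- union(chainRows, union(sel@idx1, sel@idx2))
  } else {
    ctx <- c(sel@idx1, sel@idx2)
  }
  ctx <- sort(ctx)
  free1 <- sort(setdiff(ctx, sel@idx2))
  free2 <- sort(setdiff(ctx, sel@idx1))
  sasaOn <- function(rows) {
    s <- shrakeRupley(as.matrix(a[rows, c("x", "y", "z")]), a$element[rows],
                      radii, nPoints)
    stats::setNames(s, rows)
  }
  sComplex <- sasaOn(ctx)
  sFree1 <- sasaOn(free1)
  sFree2 <- sasaOn(free2)
  perResidue <- function(idx, sFree, selNo) {
    key <- paste(a$chain[idx], a$resno[idx], a$icode[idx], sep = "\r")
    split <- split(idx, factor(key, levels = unique(key)))
    rows <- lapply(split, function(ii) {
      f <- sum(sFree[as.character(ii)])
      cx <- sum(sComplex[as.character(ii)])
      data.frame(selection = selNo, chain = a$chain[ii[1]],
                 resname = a$resname[ii[1]], resno = a$resno[ii[1]],
                 icode = a$icode[ii[1]], polymerClass = a$polymerClass[ii[1]],
                 sasaFree = f, sasaComplex = cx,
                 delta = max(0, f - cx), stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }
  out <- rbind(perResidue(sel@idx1, sFree1, 1L), perResidue(sel@idx2, sFree2, 2L))
  out$bin <- burialBin(out$delta)
  rownames(out) <- NULL
  out
}
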