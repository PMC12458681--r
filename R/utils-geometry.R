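# Small 3D geometry helpers shared by the fixture builder, the secondary
# structure assignment and the assembly expansion. All vectors are length-3
# numeric, all units Angstrom / degrees.

.vnorm <- function(v) sqrt(sum(v * v))

.vunit <- function(v) {
  n <- .vnorm(v)
  if (n < 1e-10) return(NULL)  # degenerate; callers decide what to do
  v / n
}

.vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Place atom D given reference atoms a-b-c, the c-D bond length, the b-c-D
# angle and the a-b-c-D torsion (natural extension reference frame).
.placeAtom <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  bc <- .vunit(c - b)
  n <- .vunit(.vcross(b - a, bc))
  if (is.null(bc) || is.null(n)) stop("degenerate reference geometry")
  m <- .vcross(n, bc)
  d2 <- bond * c(-cos(ang), sin(ang) * cos(tor), sin(ang) * sin(tor))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

# Rotation matrix for an angle (degrees) about an arbitrary unit axis.
.rotationMatrix <- function(axis, angle) {
  u <- .vunit(axis)
  th <- angle * pi / 180
  ct <- cos(th); st <- sin(th)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  matrix(c(
    ct + ux^2 * (1 - ct), ux * uy * (1 - ct) - uz * st, ux * uz * (1 - ct) + uy * st,
    uy * ux * (1 - ct) + uz * st, ct + uy^2 * (1 - ct), uy * uz * (1 - ct) - ux * st,
    uz * ux * (1 - ct) - uy * st, uz * uy * (1 - ct) + ux * st, ct + uz^2 * (1 - ct)),
    nrow = 3, byrow = TRUE)
}

# Cross-set neighbour search with a uniform grid (cell width = cutoff).
# Returns a data.frame(i, j, d) of all pairs a[i,] x b[j,] with
# euclidean distance <= cutoff (inclusive).
.crossPairsWithin <- function(a, b, cutoff) {
  stopifnot(cutoff > 0)
  empty <- data.frame(i = integer(), j = integer(), d = numeric())
  if (!nrow(a) || !nrow(b)) return(empty)
  origin <- c(min(a[, 1], b[, 1]), min(a[, 2], b[, 2]), min(a[, 3], b[, 3]))
  cellOf <- function(m) {
    k <- floor(sweep(m, 2, origin) / cutoff)
    paste(k[, 1], k[, 2], k[, 3])
  }
  keyA <- cellOf(a)
  keyB <- cellOf(b)
  bCells <- split(seq_len(nrow(b)), keyB)
  aCells <- split(seq_len(nrow(a)), keyA)
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  out <- vector("list", length(aCells))
  n <- 0L
  for (k in names(aCells)) {
    cell <- as.numeric(strsplit(k, " ", fixed = TRUE)[[1]])
    neigh <- paste(cell[1] + off[, 1], cell[2] + off[, 2], cell[3] + off[, 3])
    bi <- unlist(bCells[neigh[neigh %in% names(bCells)]], use.names = FALSE)
    if (!length(bi)) next
    ai <- aCells[[k]]
    d2 <- outer(rowSums(a[ai, , drop = FALSE]^2), rowSums(b[bi, , drop = FALSE]^2), "+") -
      2 * (a[ai, , drop = FALSE] %*% t(b[bi, , drop = FALSE]))
    d2[d2 < 0] <- 0
    hit <- which(d2 <= cutoff^2 + 1e-12, arr.ind = TRUE)
    if (!nrow(hit)) next
    n <- n + 1L
    out[[n]] <- data.frame(i = ai[hit[, 1]], j = bi[hit[, 2]],
                           d = sqrt(d2[hit]))
  }
  if (!n) return(empty)
  res <- do.call(rbind, out[seq_len(n)])
  res <- res[res$d <= cutoff + 1e-12, , drop = FALSE]
  res[order(res$i, res$j), , drop = FALSE]
}

# Round half to even at k decimals (IEEE 754 default of round() in R).
.round2 <- function(x) round(x, 2)
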