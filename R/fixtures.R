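# Deterministic coordinate fixtures. Every test input is generated by code
# (byte-identical across runs): idealized polyalanine helices built from
# standard backbone geometry, a torsion-built beta-hairpin, a minimal
# nucleic-acid strand, a small-molecule ligand, a two-model "NMR" file and an
# mmCIF file with biological-assembly operators.

# Build an idealized peptide backbone (N, CA, C, O, CB except GLY) from
# per-residue (phi, psi) torsions. Standard bond lengths/angles; omega 180.
# Returns a data.frame of atoms in file order.
.buildPeptide <- function(phi, psi, chain = "A", startRes = 1L,
                          resname = "ALA") {
  n <- length(phi)
  stopifnot(length(psi) == n)
  atoms <- list()
  add <- function(name, el, resno, xyz) {
    atoms[[length(atoms) + 1]] <<- data.frame(
      name = name, element = el, resno = resno,
      x = xyz[1], y = xyz[2], z = xyz[3], stringsAsFactors = FALSE)
  }
  # seed residue frame
  N <- c(0, 0, 0)
  CA <- c(1.458, 0, 0)
  C <- .placeAtom(c(0, 1, 0), N, CA, 1.525, 111.0, -60)  # arbitrary frame
  prev <- list(N = N, CA = CA, C = C)
  for (i in seq_len(n)) {
    if (i > 1) {
      N <- .placeAtom(prev$N, prev$CA, prev$C, 1.329, 116.2, psi[i - 1])
      CA <- .placeAtom(prev$CA, prev$C, N, 1.458, 121.7, 180)
      C <- .placeAtom(prev$C, N, CA, 1.525, 111.0, phi[i])
    }
    O <- .placeAtom(N, CA, C, 1.231, 120.8, psi[i] + 180)
    resno <- startRes + i - 1L
    add("N", "N", resno, N)
    add("CA", "C", resno, CA)
    add("C", "C", resno, C)
    add("O", "O", resno, O)
    if (resname != "GLY")
      add("CB", "C", resno, .placeAtom(C, N, CA, 1.521, 110.5, 123.0))
    prev <- list(N = N, CA = CA, C = C)
  }
  df <- do.call(rbind, atoms)
  df$chain <- chain
  df$resname <- resname
  df$hetero <- FALSE
  df
}

.transformAtoms <- function(df, R = diag(3), t = c(0, 0, 0)) {
  xyz <- as.matrix(df[, c("x", "y", "z")]) %*% t(R)
  df$x <- xyz[, 1] + t[1]
  df$y <- xyz[, 2] + t[2]
  df$z <- xyz[, 3] + t[3]
  df
}

# Center coordinates at the origin and align the first principal axis to z.
.axisAlign <- function(df) {
  xyz <- as.matrix(df[, c("x", "y", "z")])
  xyz <- sweep(xyz, 2, colMeans(xyz))
  pc <- prcomp(xyz)
  rot <- pc$rotation
  if (det(rot) < 0) rot[, 3] <- -rot[, 3]
  xyz <- xyz %*% rot[, c(2, 3, 1)]  # main axis -> z
  df$x <- xyz[, 1]; df$y <- xyz[, 2]; df$z <- xyz[, 3]
  df
}

.fixtureAtomsToPdb <- function(df, path, models = list(df)) {
  lines <- character()
  multi <- length(models) > 1
  for (m in seq_along(models)) {
    a <- models[[m]]
    if (multi) lines <- c(lines, sprintf("MODEL     %4d", m))
    for (i in seq_len(nrow(a))) {
      nmF <- if (nchar(a$name[i]) >= 4) substr(a$name[i], 1, 4)
             else sprintf(" %-3s", a$name[i])
      lines <- c(lines, sprintf(
        "%-6s%5d %s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        ifelse(a$hetero[i], "HETATM", "ATOM"), i, nmF, a$resname[i],
        a$chain[i], a$resno[i], a$x[i], a$y[i], a$z[i], 1.0, 0.0,
        a$element[i]))
    }
    if (multi) lines <- c(lines, "ENDMDL")
  }
  writeLines(c(lines, "END"), path)
  path
}

.idealHelix <- function(nres = 12, chain = "A") {
  .axisAlign(.buildPeptide(rep(-57, nres), rep(-47, nres), chain = chain))
}

# Two packed antiparallel polyalanine helices, interface along x.
.helixPairAtoms <- function(separation = 9.4) {
  a <- .idealHelix(12, "A")
  b <- .idealHelix(12, "B")
  b <- .transformAtoms(b, R = .rotationMatrix(c(0, 1, 0), 180),
                       t = c(separation, 0, 0))
  rbind(a, b)
}

# Torsion-built two-strand antiparallel hairpin (chain A): 5-residue strands
# joined by a type I' like turn.
.betaHairpinAtoms <- function() {
  phi <- c(rep(-120, 5), 60, 90, rep(-120, 5))
  psi <- c(rep(135, 5), 30, 0, rep(135, 5))
  .buildPeptide(phi, psi, chain = "A")
}

.ligandAtoms <- function(center) {
  # six-atom ring-like ligand (resname LIG, chain L): alternating C/O plus P
  ring <- lapply(0:4, function(k) {
    ang <- 2 * pi * k / 5
    center + c(1.3 * cos(ang), 1.3 * sin(ang), 0)
  })
  el <- c("C", "O", "C", "O", "C")
  nm <- c("C1", "O1", "C2", "O2", "C3")
  df <- do.call(rbind, lapply(seq_along(ring), function(k) {
    data.frame(name = nm[k], element = el[k], resno = 501L,
               x = ring[[k]][1], y = ring[[k]][2], z = ring[[k]][3],
               stringsAsFactors = FALSE)
  }))
  df <- rbind(df, data.frame(name = "P1", element = "P", resno = 501L,
                             x = center[1], y = center[2], z = center[3] + 1.5,
                             stringsAsFactors = FALSE))
  df$chain <- "L"
  df$resname <- "LIG"
  df$hetero <- TRUE
  df
}

# Minimal 4-nucleotide single strand (resname U, chain B) with backbone P
# atoms; simplified but 3D-sane geometry stacked along z.
.nucleicAtoms <- function(origin = c(0, 0, 0)) {
  atoms <- list()
  for (i in 0:3) {
    base <- origin + c(0.8 * sin(i * 0.6), 0.8 * cos(i * 0.6), i * 3.4)
    local <- list(
      c("P", "P", c(0, 0, 0)), c("OP1", "O", c(1.25, 0.7, 0)),
      c("OP2", "O", c(-1.25, 0.7, 0)), c("O5'", "O", c(0, -0.9, 1.1)),
      c("C5'", "C", c(1.0, -1.5, 1.8)), c("C4'", "C", c(1.0, -0.9, 3.0)),
      c("C1'", "C", c(2.2, -0.2, 3.4)), c("N1", "N", c(3.3, -0.9, 3.6)),
      c("C2", "C", c(4.5, -0.3, 3.8)), c("O2", "O", c(4.6, 0.9, 3.8)))
    for (at in local) {
      xyz <- base + as.numeric(at[[3]])
      atoms[[length(atoms) + 1]] <- data.frame(
        name = at[[1]], element = at[[2]], resno = 1L + i,
        x = xyz[1], y = xyz[2], z = xyz[3], stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, atoms)
  df$chain <- "B"
  df$resname <- "U"
  df$hetero <- FALSE
  df
}

.fixtureAtomsToCif <- function(df, path, assembly = TRUE) {
  hdr <- c("data_fixture", "#", "loop_",
    "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
    "_atom_site.label_atom_id", "_atom_site.label_alt_id",
    "_atom_site.label_comp_id", "_atom_site.label_asym_id",
    "_atom_site.label_entity_id", "_atom_site.label_seq_id",
    "_atom_site.pdbx_PDB_ins_code", "_atom_site.Cartn_x",
    "_atom_site.Cartn_y", "_atom_site.Cartn_z", "_atom_site.occupancy",
    "_atom_site.B_iso_or_equiv", "_atom_site.auth_seq_id",
    "_atom_site.auth_comp_id", "_atom_site.auth_asym_id",
    "_atom_site.auth_atom_id", "_atom_site.pdbx_PDB_model_num")
  rows <- vapply(seq_len(nrow(df)), function(i) {
    sprintf("%s %d %s %s . %s %s 1 %d ? %.3f %.3f %.3f 1.00 0.00 %d %s %s %s 1",
            ifelse(df$hetero[i], "HETATM", "ATOM"), i, df$element[i],
            df$name[i], df$resname[i], df$chain[i], df$resno[i],
            df$x[i], df$y[i], df$z[i], df$resno[i], df$resname[i],
            df$chain[i], df$name[i])
  }, character(1))
  asm <- if (assembly) c("#", "loop_",
    "_pdbx_struct_assembly_gen.assembly_id",
    "_pdbx_struct_assembly_gen.oper_expression",
    "_pdbx_struct_assembly_gen.asym_id_list",
    "1 1,2 A", "#", "loop_",
    "_pdbx_struct_oper_list.id", "_pdbx_struct_oper_list.type",
    "_pdbx_struct_oper_list.matrix[1][1]", "_pdbx_struct_oper_list.matrix[1][2]",
    "_pdbx_struct_oper_list.matrix[1][3]", "_pdbx_struct_oper_list.vector[1]",
    "_pdbx_struct_oper_list.matrix[2][1]", "_pdbx_struct_oper_list.matrix[2][2]",
    "_pdbx_struct_oper_list.matrix[2][3]", "_pdbx_struct_oper_list.vector[2]",
    "_pdbx_struct_oper_list.matrix[3][1]", "_pdbx_struct_oper_list.matrix[3][2]",
    "_pdbx_struct_oper_list.matrix[3][3]", "_pdbx_struct_oper_list.vector[3]",
    "1 'identity operation' 1 0 0 0 0 1 0 0 0 0 1 0",
    "2 'point symmetry operation' -1 0 0 12 0 -1 0 0 0 0 1 0")
  else character(0)
  writeLines(c(hdr, rows, asm, "#"), path)
  path
}

#' Generate a named deterministic test fixture
#'
#' All fixtures are written by code with documented geometry and are
#' byte-identical across runs:
#' \describe{
#'   \item{two_atoms}{one alanine N (chain A) and one O (chain B) exactly
#'     `d` Angstrom apart along x.}
#'   \item{helix_pair}{two packed ideal 12-residue polyalanine alpha-helices
#'     (phi -57, psi -47), chains A and B, axes 8.8 A apart.}
#'   \item{separated_chains}{the same two helices 100 A apart.}
#'   \item{beta_hairpin}{a torsion-built two-strand antiparallel hairpin.}
#'   \item{protein_ligand}{one helix (chain A) plus a 6-atom HETATM ligand
#'     (resname LIG, chain L) packed against it.}
#'   \item{nmr_two_model}{a 2-MODEL file of one helix, second model shifted.}
#'   \item{assembly_cif}{mmCIF of one helix (chain A) with assembly "1":
#'     identity plus a 2-fold rotation about z translated by 12 A along x.}
#'   \item{nucleic_protein}{one helix (chain A) plus a 4-nt strand with P
#'     atoms (resname U, chain B) at its surface.}
#' }
#'
#' @param name fixture name (see above).
#' @param outdir output directory (created if missing).
#' @param d separation in Angstrom for `two_atoms` (default 4.0).
#' @return The path of the written file.
#' @export
makeFixture <- function(name, outdir = tempdir(), d = 4.0) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(outdir, paste0(name, if (name == "assembly_cif") ".cif"
                                         else ".pdb"))
  if (name == "two_atoms") {
    df <- data.frame(
      name = c("N", "O"), element = c("N", "O"), resno = c(1L, 1L),
      x = c(0, d), y = 0, z = 0, chain = c("A", "B"),
      resname = "ALA", hetero = FALSE, stringsAsFactors = FALSE)
    .fixtureAtomsToPdb(df, path)
  } else if (name == "helix_pair") {
    .fixtureAtomsToPdb(.helixPairAtoms(8.8), path)
  } else if (name == "separated_chains") {
    .fixtureAtomsToPdb(.helixPairAtoms(100), path)
  } else if (name == "beta_hairpin") {
    .fixtureAtomsToPdb(.betaHairpinAtoms(), path)
  } else if (name == "protein_ligand") {
    a <- .idealHelix(12, "A")
    lig <- .ligandAtoms(c(6.2, 0, 0))
    .fixtureAtomsToPdb(rbind(a, lig), path)
  } else if (name == "nmr_two_model") {
    a <- .idealHelix(12, "A")
    b <- .transformAtoms(a, t = c(0.5, 0, 0))
    .fixtureAtomsToPdb(a, path, models = list(a, b))
  } else if (name == "assembly_cif") {
    .fixtureAtomsToCif(.idealHelix(12, "A"), path)
  } else if (name == "nucleic_protein") {
    a <- .idealHelix(12, "A")
    nuc <- .nucleicAtoms(c(5.0, -2.0, -6.0))
    .fixtureAtomsToPdb(rbind(a, nuc), path)
  } else {
    stop("unknown fixture '", name, "'")
  }
  path
}
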