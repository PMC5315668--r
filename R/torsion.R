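# Side-chain chi dihedral definitions (atom name quadruples per residue type,
# standard rotamer-library conventions; ring chis use the CD1/OD1/ND1 branch).
.CHI_TABLE <- list(
  ARG = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD"),
             c("CB","CG","CD","NE"), c("CG","CD","NE","CZ")),
  ASN = list(c("N","CA","CB","CG"), c("CA","CB","CG","OD1")),
  ASP = list(c("N","CA","CB","CG"), c("CA","CB","CG","OD1")),
  CYS = list(c("N","CA","CB","SG")),
  GLN = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD"),
             c("CB","CG","CD","OE1")),
  GLU = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD"),
             c("CB","CG","CD","OE1")),
  HIS = list(c("N","CA","CB","CG"), c("CA","CB","CG","ND1")),
  ILE = list(c("N","CA","CB","CG1"), c("CA","CB","CG1","CD1")),
  LEU = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD1")),
  LYS = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD"),
             c("CB","CG","CD","CE"), c("CG","CD","CE","NZ")),
  MET = list(c("N","CA","CB","CG"), c("CA","CB","CG","SD"),
             c("CB","CG","SD","CE")),
  PHE = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD1")),
  PRO = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD")),
  SER = list(c("N","CA","CB","OG")),
  THR = list(c("N","CA","CB","OG1")),
  TRP = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD1")),
  TYR = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD1")),
  VAL = list(c("N","CA","CB","CG1")),
  GLY = list(), ALA = list()
)

#' Dihedral angle of four points
#'
#' @param p 4 x 3 matrix of coordinates (rows are the bonded atoms in order).
#' @return Angle in radians in (-pi, pi].
#' @export
dihedral_angle <- function(p) {
  b1 <- p[2, ] - p[1, ]
  b2 <- p[3, ] - p[2, ]
  b3 <- p[4, ] - p[3, ]
  n1 <- .cross(b1, b2)
  n2 <- .cross(b2, b3)
  m1 <- .cross(n1, b2 / sqrt(sum(b2^2)))
  -atan2(sum(m1 * n2), sum(n1 * n2))
}

.cross <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                           a[3] * b[1] - a[1] * b[3],
                           a[1] * b[2] - a[2] * b[1])

#' Analytic Cartesian gradient of a dihedral angle
#'
#' Gradient of the dihedral defined by four points with respect to all 12
#' Cartesian coordinates, using the standard normal-vector formulas. Returns
#' `NULL` for degenerate (collinear) geometries where the angle is undefined.
#'
#' @param p 4 x 3 coordinate matrix.
#' @return 4 x 3 matrix of partial derivatives, or `NULL` if degenerate.
#' @export
dihedral_gradient <- function(p) {
  b1 <- p[2, ] - p[1, ]
  b2 <- p[3, ] - p[2, ]
  b3 <- p[4, ] - p[3, ]
  n1 <- .cross(b1, b2)
  n2 <- .cross(b2, b3)
  n1sq <- sum(n1^2)
  n2sq <- sum(n2^2)
  b2n <- sqrt(sum(b2^2))
  scale2 <- max(sum(b1^2), sum(b2^2), sum(b3^2))
  if (n1sq < 1e-12 * scale2^2 || n2sq < 1e-12 * scale2^2) return(NULL)
  g1 <- -(b2n / n1sq) * n1
  g4 <- (b2n / n2sq) * n2
  c1 <- sum(b1 * b2) / sum(b2^2)
  c3 <- sum(b3 * b2) / sum(b2^2)
  g2 <- -(1 + c1) * g1 + c3 * g4
  g3 <- c1 * g1 - (1 + c3) * g4
  rbind(g1, g2, g3, g4)
}

#' Enumerate torsional degrees of freedom of a structure
#'
#' For all-atom structures: backbone phi (C-N-CA-C) and psi (N-CA-C-N) for
#' internal residues (those with both flanking residues present) plus
#' side-chain chi dihedrals from the standard per-residue tables. For
#' CA-only structures, pseudo-dihedrals over each window of four consecutive
#' CA atoms along a chain (the torsional-network convention for
#' coarse-grained models). Unknown residue names are skipped with a warning.
#'
#' @param s A [path_structure].
#' @param k_torsion Uniform per-dihedral stiffness (reduced units).
#' @return Object of class `torsion_topology`: list with `quadruples`
#'   (M x 4 integer matrix of atom indices), `labels`, `k_torsion`.
#' @export
enumerate_torsions <- function(s, k_torsion = 1) {
  stopifnot(k_torsion > 0)
  at <- s$atoms
  quads <- list()
  labels <- character()
  if (s$selection == "ca") {
    for (ch in unique(at$chain)) {
      idx <- which(at$chain == ch)
      idx <- idx[order(at$resno[idx])]
      if (length(idx) >= 4) {
        for (i in seq_len(length(idx) - 3)) {
          quads[[length(quads) + 1]] <- idx[i:(i + 3)]
          labels <- c(labels, sprintf("pseudo_%s%d", ch, at$resno[idx[i]]))
        }
      }
    }
  } else {
    n_unknown <- 0L
    key <- paste(at$chain, at$resno)
    for (ch in unique(at$chain)) {
      resnos <- sort(unique(at$resno[at$chain == ch]))
      find <- function(rn, nm) {
        i <- which(at$chain == ch & at$resno == rn & at$name == nm)
        if (length(i) == 1L) i else NA_integer_
      }
      for (pos in seq_along(resnos)) {
        rn <- resnos[pos]
        resname <- toupper(at$resname[at$chain == ch & at$resno == rn][1])
        internal <- pos > 1 && pos < length(resnos)
        if (internal) {
          prev <- resnos[pos - 1]; nxt <- resnos[pos + 1]
          phi <- c(find(prev, "C"), find(rn, "N"), find(rn, "CA"), find(rn, "C"))
          psi <- c(find(rn, "N"), find(rn, "CA"), find(rn, "C"), find(nxt, "N"))
          if (!anyNA(phi)) {
            quads[[length(quads) + 1]] <- phi
            labels <- c(labels, sprintf("phi_%s%d", ch, rn))
          }
          if (!anyNA(psi)) {
            quads[[length(quads) + 1]] <- psi
            labels <- c(labels, sprintf("psi_%s%d", ch, rn))
          }
        }
        if (!resname %in% names(.CHI_TABLE)) {
          n_unknown <- n_unknown + 1L
          next
        }
        chis <- .CHI_TABLE[[resname]]
        for (ci in seq_along(chis)) {
          q <- vapply(chis[[ci]], function(nm) find(rn, nm), integer(1))
          if (!anyNA(q)) {
            quads[[length(quads) + 1]] <- q
            labels <- c(labels, sprintf("chi%d_%s%d", ci, ch, rn))
          }
        }
      }
    }
    if (n_unknown > 0L)
      warning(n_unknown, " residue(s) with unknown name skipped in torsion ",
              "enumeration")
  }
  quads <- if (length(quads)) do.call(rbind, quads) else
    matrix(integer(), 0, 4)
  dup <- duplicated(quads)
  structure(list(quadruples = quads[!dup, , drop = FALSE],
                 labels = labels[!dup], k_torsion = k_torsion),
            class = "torsion_topology")
}

#' Build the torsional stiffness Hessian
#'
#' Each dihedral contributes a harmonic restraint half k (theta - theta0)^2
#' about its equilibrium value; at equilibrium its Hessian contribution is
#' k (grad theta)(grad theta)^T scattered into the 12 x 12 sub-block of the
#' four participating atoms. Degenerate (collinear) dihedrals are skipped
#' with a warning. The result is symmetric, positive semidefinite, and
#' annihilates rigid-body motions (the dihedral angle is invariant to them).
#'
#' @param s Equilibrium [path_structure].
#' @param topology A `torsion_topology` from [enumerate_torsions()]; built
#'   automatically when `NULL`.
#' @return A `path_hessian` with flavor `"torsion"`.
#' @export
build_torsional_hessian <- function(s, topology = NULL) {
  if (is.null(topology)) topology <- enumerate_torsions(s)
  n <- n_atoms(s)
  H <- matrix(0, 3 * n, 3 * n)
  q <- topology$quadruples
  n_degen <- 0L
  for (row in seq_len(nrow(q))) {
    idx <- q[row, ]
    if (length(unique(idx)) != 4L || any(idx < 1L | idx > n))
      stop("invalid dihedral quadruple at row ", row)
    g <- dihedral_gradient(s$coords[idx, , drop = FALSE])
    if (is.null(g)) {
      n_degen <- n_degen + 1L
      next
    }
    gv <- as.numeric(t(g))  # 12-vector in (x1,y1,z1,...,x4,...) order
    dofs <- as.vector(vapply(idx, function(i) (3 * (i - 1) + 1):(3 * i),
                             integer(3)))
    H[dofs, dofs] <- H[dofs, dofs] + topology$k_torsion * tcrossprod(gv)
  }
  if (n_degen > 0L)
    warning(n_degen, " degenerate (collinear) dihedral(s) skipped")
  new_path_hessian(H, "torsion", s)
}
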