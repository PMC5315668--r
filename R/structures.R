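# Atomic masses (amu) by element and mean residue masses for CA-only models.
.ELEMENT_MASS <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
                   P = 30.974, SE = 78.971, FE = 55.845, ZN = 65.38, MG = 24.305)

# Average residue masses within a chain (monomer minus water), amu.
.RESIDUE_MASS <- c(
  GLY = 57.05, ALA = 71.08, SER = 87.08, PRO = 97.12, VAL = 99.13,
  THR = 101.10, CYS = 103.14, LEU = 113.16, ILE = 113.16, ASN = 114.10,
  ASP = 115.09, GLN = 128.13, LYS = 128.17, GLU = 129.12, MET = 131.19,
  HIS = 137.14, PHE = 147.18, ARG = 156.19, TYR = 163.18, TRP = 186.21
)
.DEFAULT_RESIDUE_MASS <- 110  # mean amino-acid residue mass, used for UNK/synthetic

#' Construct a structure object
#'
#' An ordered atom set with Cartesian coordinates (Angstrom) and per-atom
#' masses (amu), the basic coordinate container for elastic-network models:
#' every Hessian in the package is built around one such equilibrium
#' structure, and trajectories are sequences of its coordinate states.
#'
#' @param atoms Data frame with columns `name`, `resname`, `resno`, `chain`,
#'   `element` (one row per atom, in file order).
#' @param coords Numeric N x 3 matrix of positions in Angstrom.
#' @param masses Numeric vector of per-atom masses in amu; if `NULL`, assigned
#'   from `element` (all-atom) or from the residue type (CA-only).
#' @param selection Either `"all-atom"` or `"ca"`.
#' @return An object of class `path_structure` with elements `atoms`
#'   (a tibble), `coords`, `masses` and `selection`.
#' @export
path_structure <- function(atoms, coords, masses = NULL,
                           selection = c("all-atom", "ca")) {
  selection <- match.arg(selection)
  atoms <- tibble::as_tibble(atoms)
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (nrow(coords) != nrow(atoms) || ncol(coords) != 3L)
    stop("coords must be an N x 3 matrix matching the atom table")
  if (nrow(coords) < 2L) stop("a structure needs at least 2 atoms")
  if (!all(is.finite(coords))) stop("non-finite coordinates")
  if (is.null(masses)) masses <- .assign_masses(atoms, selection)
  masses <- as.numeric(masses)
  if (length(masses) != nrow(atoms) || any(!is.finite(masses)) || any(masses <= 0))
    stop("masses must be positive and finite, one per atom")
  structure(
    list(atoms = atoms, coords = coords, masses = masses, selection = selection),
    class = "path_structure"
  )
}

.assign_masses <- function(atoms, selection) {
  if (selection == "ca") {
    m <- unname(.RESIDUE_MASS[toupper(atoms$resname)])
    m[is.na(m)] <- .DEFAULT_RESIDUE_MASS
  } else {
    m <- unname(.ELEMENT_MASS[toupper(atoms$element)])
    m[is.na(m)] <- .ELEMENT_MASS[["C"]]
  }
  m
}

#' @export
print.path_structure <- function(x, ...) {
  cat(sprintf("path_structure: %d atoms (%s), %d residues\n",
              nrow(x$coords), x$selection,
              length(unique(paste(x$atoms$chain, x$atoms$resno)))))
  invisible(x)
}

#' Number of atoms in a structure
#' @param s A `path_structure`.
#' @return Integer atom count.
#' @export
n_atoms <- function(s) nrow(s$coords)

#' Read a structure from a PDB file
#'
#' Reads the first model of a PDB file through bio3d and returns a
#' [path_structure]. Only `ATOM` records are kept unless `hetatm = TRUE`;
#' hydrogens are dropped unless `hydrogens = TRUE` (the elastic-network
#' convention); for alternate locations the highest-occupancy conformer is
#' kept (ties broken by file order). With `selection = "ca"` exactly one CA
#' atom per residue is retained and the residue mass is assigned to it.
#'
#' @param path Path to a PDB file.
#' @param selection `"all-atom"` or `"ca"`.
#' @param hetatm Keep HETATM records? Default `FALSE`.
#' @param hydrogens Keep hydrogen atoms? Default `FALSE`.
#' @return A [path_structure].
#' @export
read_structure <- function(path, selection = c("all-atom", "ca"),
                           hetatm = FALSE, hydrogens = FALSE) {
  selection <- match.arg(selection)
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  at <- pdb$atom
  if (!hetatm) at <- at[at$type == "ATOM", , drop = FALSE]
  # altloc: keep highest occupancy per (chain, resno, atom name); tie -> first
  if (any(nzchar(trimws(at$alt)) & !is.na(at$alt))) {
    key <- paste(at$chain, at$resno, at$insert, at$elety)
    occ <- ifelse(is.na(at$o), 1, at$o)
    keep <- unlist(lapply(split(seq_len(nrow(at)), key), function(idx) {
      idx[which.max(occ[idx])]
    }), use.names = FALSE)
    at <- at[sort(keep), , drop = FALSE]
  }
  elem <- trimws(at$elesy)
  miss <- is.na(elem) | !nzchar(elem)
  elem[miss] <- substr(gsub("[^A-Za-z].*", "", trimws(at$elety[miss])), 1, 1)
  if (!hydrogens) {
    keep_h <- toupper(elem) != "H"
    at <- at[keep_h, , drop = FALSE]
    elem <- elem[keep_h]
  }
  if (selection == "ca") {
    is_ca <- at$elety == "CA"
    at <- at[is_ca, , drop = FALSE]
    elem <- rep("C", nrow(at))
    key <- paste(at$chain, at$resno, at$insert)
    dup <- duplicated(key)
    if (any(dup))
      stop("duplicate CA in residue(s): ",
           paste(unique(key[dup]), collapse = ", "))
  }
  if (nrow(at) == 0L) stop("no atoms left after selection in ", path)
  atoms <- tibble::tibble(
    name = at$elety, resname = at$resid, resno = at$resno,
    chain = ifelse(is.na(at$chain) | !nzchar(at$chain), "A", at$chain),
    element = elem
  )
  coords <- cbind(at$x, at$y, at$z)
  path_structure(atoms, coords, selection = selection)
}

#' Write a structure (or trajectory frames) to a PDB file
#'
#' Writes fixed-column PDB `ATOM` records. When `coords_list` holds several
#' coordinate sets they are written as successive `MODEL`/`ENDMDL` blocks
#' (one frame per model), the standard container for trajectories.
#'
#' @param s A [path_structure] providing the atom table.
#' @param path Output file path.
#' @param coords_list Optional list of N x 3 coordinate matrices; defaults to
#'   the single set in `s`.
#' @return Invisibly, `path`.
#' @export
write_structure <- function(s, path, coords_list = NULL) {
  if (is.null(coords_list)) coords_list <- list(s$coords)
  multi <- length(coords_list) > 1L
  con <- file(path, "w")
  on.exit(close(con))
  at <- s$atoms
  for (m in seq_along(coords_list)) {
    xyz <- coords_list[[m]]
    if (multi) writeLines(sprintf("MODEL     %4d", m), con)
    nm <- ifelse(nchar(at$name) < 4, sprintf(" %-3s", at$name),
                 sprintf("%-4s", at$name))
    lines <- sprintf(
      "ATOM  %5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      seq_len(nrow(at)), nm, at$resname, at$chain, at$resno,
      xyz[, 1], xyz[, 2], xyz[, 3], 1, 0, toupper(at$element)
    )
    writeLines(lines, con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Pair two end-state structures of the same molecule
#'
#' Matches atoms by (chain, residue number, atom name), drops unmatched atoms
#' symmetrically, and returns both structures with identical atom counts and
#' ordering — the left/right equilibrium wells of a transition-path
#' calculation.
#'
#' @param left,right Two [path_structure] objects of the same molecule.
#' @return An object of class `end_state_pair`: list with `left`, `right`,
#'   `selection`.
#' @export
pair_end_states <- function(left, right) {
  kl <- paste(left$atoms$chain, left$atoms$resno, left$atoms$name)
  kr <- paste(right$atoms$chain, right$atoms$resno, right$atoms$name)
  if (anyDuplicated(kl) || anyDuplicated(kr))
    stop("ambiguous duplicate atom keys (chain, resno, name) in input")
  common <- intersect(kl, kr)
  if (length(common) < 2L) stop("fewer than 2 common atoms between end states")
  il <- sort(match(common, kl))
  ir <- match(kl[il], kr)
  sub <- function(s, idx) path_structure(s$atoms[idx, ], s$coords[idx, , drop = FALSE],
                                         s$masses[idx], s$selection)
  structure(list(left = sub(left, il), right = sub(right, ir),
                 selection = left$selection),
            class = "end_state_pair")
}

#' @export
print.end_state_pair <- function(x, ...) {
  cat(sprintf("end_state_pair: %d paired atoms (%s), rmsd %.3f A\n",
              n_atoms(x$left), x$selection,
              superpose_rmsd(x$right, x$left)$rmsd))
  invisible(x)
}
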