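#' Build a molecule from an atom table
#'
#' A molecule is the unit every other function operates on: an ordered atom
#' table (file order is significant and preserved through every
#' transformation) plus an optional bond list. Receptors and ligands use the
#' same container.
#'
#' @param atoms A data frame with one row per atom. Required columns:
#'   `name` (atom label), `element` (element symbol), `x`, `y`, `z`
#'   (Cartesian coordinates, Angstrom). Optional columns `serial`,
#'   `residue_name`, `chain_id`, `residue_number`, `is_hetero`, `b_factor`
#'   are filled with defaults when absent.
#' @param bonds A data frame with integer columns `i`, `j` (1-based atom
#'   indices), or `NULL` for no bond information.
#' @param name Molecule name (for library molecules, the pair root).
#' @param source_format One of `"pdb"`, `"mol2"`, `"pdbqt"`, or `NA`.
#'
#' @return An object of class `molecule`: a list with elements `name`,
#'   `atoms` (tibble), `bonds` (tibble) and `source_format`.
#' @export
#' @examples
#' m <- molecule(data.frame(name = c("C1", "O1"), element = c("C", "O"),
#'                          x = c(0, 1.2), y = 0, z = 0))
#' n_atoms(m)
molecule <- function(atoms, bonds = NULL, name = "molecule",
                     source_format = NA_character_) {
  atoms <- as_tibble(atoms)
  required <- c("name", "element", "x", "y", "z")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols) > 0) {
    abort(paste0("atom table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "crossdockr_format_error")
  }
  n <- nrow(atoms)
  if (!"serial" %in% names(atoms)) atoms$serial <- seq_len(n)
  if (!"residue_name" %in% names(atoms)) atoms$residue_name <- "LIG"
  if (!"chain_id" %in% names(atoms)) atoms$chain_id <- "A"
  if (!"residue_number" %in% names(atoms)) atoms$residue_number <- 1L
  if (!"is_hetero" %in% names(atoms)) atoms$is_hetero <- TRUE
  if (!"b_factor" %in% names(atoms)) atoms$b_factor <- 0
  atoms$element <- normalize_element(atoms$element)
  coords <- as.matrix(atoms[, c("x", "y", "z")])
  if (n > 0 && !all(is.finite(coords))) {
    abort("atom coordinates must be finite", class = "crossdockr_format_error")
  }
  atoms <- atoms[, c("serial", "name", "element", "residue_name", "chain_id",
                     "residue_number", "x", "y", "z", "is_hetero", "b_factor")]
  bonds <- validate_bonds(bonds, n)
  structure(
    list(name = name, atoms = atoms, bonds = bonds,
         source_format = source_format),
    class = "molecule"
  )
}

validate_bonds <- function(bonds, n_atoms) {
  if (is.null(bonds) || nrow(as.data.frame(bonds)) == 0) {
    return(tibble(i = integer(), j = integer()))
  }
  bonds <- as_tibble(bonds)[, c("i", "j")]
  bonds$i <- as.integer(bonds$i)
  bonds$j <- as.integer(bonds$j)
  if (any(bonds$i < 1 | bonds$i > n_atoms | bonds$j < 1 | bonds$j > n_atoms)) {
    abort("bond indices reference non-existent atoms",
          class = "crossdockr_format_error")
  }
  if (any(bonds$i == bonds$j)) {
    abort("self-bonds are not allowed", class = "crossdockr_format_error")
  }
  lo <- pmin(bonds$i, bonds$j)
  hi <- pmax(bonds$i, bonds$j)
  keep <- !duplicated(paste(lo, hi))
  tibble(i = lo[keep], j = hi[keep])
}

#' @export
print.molecule <- function(x, ...) {
  cat(sprintf("<molecule> %s: %d atoms (%d heavy), %d bonds [%s]\n",
              x$name, n_atoms(x), sum(x$atoms$element != "H"),
              nrow(x$bonds),
              ifelse(is.na(x$source_format), "in-memory", x$source_format)))
  invisible(x)
}

#' Number of atoms in a molecule
#' @param mol A `molecule`.
#' @return Integer atom count.
#' @export
n_atoms <- function(mol) nrow(mol$atoms)

#' Atom coordinates as a matrix
#' @param mol A `molecule`.
#' @param heavy_only Drop hydrogens first?
#' @return An n x 3 numeric matrix of Angstrom coordinates, in atom order.
#' @export
coords <- function(mol, heavy_only = FALSE) {
  atoms <- mol$atoms
  if (heavy_only) atoms <- atoms[atoms$element != "H", ]
  m <- as.matrix(atoms[, c("x", "y", "z")])
  dimnames(m) <- NULL
  m
}

#' Restrict a molecule to its heavy atoms
#'
#' Hydrogens are dropped and the bond list is re-indexed onto the surviving
#' atoms. Pose output from docking engines typically omits nonpolar
#' hydrogens, so all RMSD scoring works on this representation.
#'
#' @param mol A `molecule`.
#' @return A `molecule` containing only non-hydrogen atoms, original order
#'   preserved.
#' @export
heavy_atoms <- function(mol) {
  keep <- which(mol$atoms$element != "H")
  subset_atoms(mol, keep)
}

subset_atoms <- function(mol, keep) {
  idx_map <- match(seq_len(n_atoms(mol)), keep)
  bonds <- mol$bonds
  if (nrow(bonds) > 0) {
    bi <- idx_map[bonds$i]
    bj <- idx_map[bonds$j]
    ok <- !is.na(bi) & !is.na(bj)
    bonds <- tibble(i = bi[ok], j = bj[ok])
  }
  out <- mol
  out$atoms <- mol$atoms[keep, ]
  out$bonds <- bonds
  out
}

#' @export
as_tibble.molecule <- function(x, ...) x$atoms

# Covalent radii (Angstrom), single-bond values; used for distance-based
# bond perception.
COVALENT_RADII <- c(
  H = 0.31, B = 0.84, C = 0.76, N = 0.71, O = 0.66, F = 0.57,
  Na = 1.66, Mg = 1.41, Si = 1.11, P = 1.07, S = 1.05, Cl = 1.02,
  K = 2.03, Ca = 1.76, Mn = 1.39, Fe = 1.32, Co = 1.26, Ni = 1.24,
  Cu = 1.32, Zn = 1.22, Br = 1.20, I = 1.39, Se = 1.20
)

normalize_element <- function(el) {
  el <- as.character(el)
  el <- gsub("^\\s+|\\s+$", "", el)
  ifelse(nchar(el) > 1,
         paste0(toupper(substr(el, 1, 1)), tolower(substr(el, 2, 2))),
         toupper(el))
}

#' Guess an element symbol from an atom name
#'
#' Used when the input format has no element column (older PDB files) or
#' carries engine atom types instead (pdbqt). Two-letter elements common in
#' biomolecules are recognised; otherwise the first alphabetic character
#' wins, which is the PDB convention for names such as "CA" (an alpha
#' carbon, not calcium, when left-justified in the name field).
#'
#' @param name Character vector of atom names.
#' @return Character vector of element symbols.
#' @export
guess_element <- function(name) {
  nm <- toupper(gsub("[^A-Za-z]", "", as.character(name)))
  two <- c("CL", "BR", "ZN", "MG", "MN", "FE", "NA", "CA", "SE", "SI", "CU",
           "NI", "CO")
  vapply(nm, function(x) {
    if (nchar(x) == 0) return("C")
    first2 <- substr(x, 1, 2)
    # Two-letter match only when nothing follows (avoids CA=Ca for C-alpha)
    if (nchar(x) == 2 && first2 %in% two) {
      return(normalize_element(first2))
    }
    substr(x, 1, 1)
  }, character(1), USE.NAMES = FALSE)
}

#' Perceive covalent bonds from interatomic distances
#'
#' Adds a bond between every atom pair whose distance does not exceed 1.3
#' times the sum of the two covalent radii. Molecules that already carry a
#' bond list (mol2 input) are returned untouched, so file-specified
#' connectivity always wins over perception.
#'
#' @param mol A `molecule`.
#' @param tolerance Multiplier on the covalent-radius sum (default 1.3).
#' @return The molecule with `bonds` populated.
#' @export
#' @examples
#' m <- molecule(data.frame(name = c("C1", "C2"), element = "C",
#'                          x = c(0, 1.5), y = 0, z = 0))
#' nrow(perceive_bonds(m)$bonds)  # 1
perceive_bonds <- function(mol, tolerance = 1.3) {
  if (nrow(mol$bonds) > 0) return(mol)
  n <- n_atoms(mol)
  if (n < 2) return(mol)
  el <- mol$atoms$element
  unknown <- setdiff(unique(el), names(COVALENT_RADII))
  if (length(unknown) > 0) {
    abort(paste0("no covalent radius for element(s): ",
                 paste(unknown, collapse = ", ")),
          class = "crossdockr_element_error")
  }
  radii <- COVALENT_RADII[el]
  xyz <- coords(mol)
  d <- as.matrix(stats::dist(xyz))
  cutoff <- outer(radii, radii, "+") * tolerance
  hit <- which(d <= cutoff & upper.tri(d), arr.ind = TRUE)
  mol$bonds <- tibble(i = as.integer(hit[, 1]), j = as.integer(hit[, 2]))
  mol
}

#' Replace a molecule's coordinates
#' @param mol A `molecule`.
#' @param xyz An `n_atoms(mol)` x 3 matrix.
#' @return The molecule with new coordinates, everything else untouched.
#' @export
set_coords <- function(mol, xyz) {
  xyz <- as.matrix(xyz)
  if (nrow(xyz) != n_atoms(mol) || ncol(xyz) != 3) {
    abort("coordinate matrix does not match atom count",
          class = "crossdockr_format_error")
  }
  mol$atoms$x <- xyz[, 1]
  mol$atoms$y <- xyz[, 2]
  mol$atoms$z <- xyz[, 3]
  mol
}
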