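#' Read a structure file into a molecule
#'
#' Supported formats: PDB (fixed-column `ATOM`/`HETATM` records), Tripos
#' mol2 (`@<TRIPOS>ATOM` / `@<TRIPOS>BOND` sections) and pdbqt (PDB columns
#' plus partial charge and AutoDock atom type; `ROOT`/`BRANCH`/`TORSDOF`
#' torsion-tree lines are ignored). Atom order is the file order and is
#' preserved. mol2 input populates the bond list; PDB and pdbqt input leaves
#' it empty for later perception. Multi-model files yield the first model.
#'
#' @param path Path to the structure file.
#' @param format Format tag (`"pdb"`, `"mol2"`, `"pdbqt"`); inferred from
#'   the file extension when `NULL`.
#' @param name Molecule name; defaults to the file stem.
#' @return A [molecule].
#' @export
read_structure <- function(path, format = NULL, name = NULL) {
  if (!file.exists(path)) {
    abort(paste0("cannot read structure file: ", path),
          class = "crossdockr_io_error")
  }
  ext <- tolower(tools::file_ext(path))
  if (is.null(format)) {
    format <- switch(ext,
      pdb = "pdb", ent = "pdb", mol2 = "mol2", pdbqt = "pdbqt",
      abort(paste0("cannot infer format from extension '.", ext,
                   "'; pass `format`"),
            class = "crossdockr_format_error")
    )
  }
  format <- match.arg(format, c("pdb", "mol2", "pdbqt"))
  if (is.null(name)) name <- tools::file_path_sans_ext(basename(path))
  mol <- switch(format,
    pdb = read_pdb_file(path, name),
    mol2 = read_mol2_file(path, name),
    pdbqt = read_pdbqt_file(path, name)
  )
  if (n_atoms(mol) == 0) {
    abort(paste0("no atoms parsed from ", path),
          class = "crossdockr_empty_structure_error")
  }
  mol
}

first_model_lines <- function(lines) {
  end <- which(grepl("^ENDMDL", lines))
  if (length(end) > 0) lines <- lines[seq_len(end[1] - 1)]
  lines
}

read_pdb_file <- function(path, name) {
  lines <- first_model_lines(readLines(path, warn = FALSE))
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp))
  writeLines(lines, tmp)
  pdb <- quiet(bio3d::read.pdb(tmp, multi = FALSE, verbose = FALSE))
  a <- pdb$atom
  element <- as.character(a$elesy)
  blank <- is.na(element) | element == ""
  element[blank] <- guess_element(a$elety[blank])
  molecule(
    tibble(
      serial = as.integer(a$eleno),
      name = as.character(a$elety),
      element = element,
      residue_name = as.character(a$resid),
      chain_id = ifelse(is.na(a$chain) | a$chain == "", "A",
                        as.character(a$chain)),
      residue_number = as.integer(a$resno),
      x = a$x, y = a$y, z = a$z,
      is_hetero = a$type == "HETATM",
      b_factor = ifelse(is.na(a$b), 0, a$b)
    ),
    name = name, source_format = "pdb"
  )
}

read_mol2_file <- function(path, name) {
  m <- quiet(bio3d::read.mol2(path))
  a <- m$atom
  # SYBYL atom types carry the element before the dot (C.3, N.ar, O.co2)
  element <- sub("\\..*$", "", as.character(a$elety))
  bonds <- NULL
  if (!is.null(m$bond) && nrow(m$bond) > 0) {
    bonds <- tibble(i = as.integer(m$bond$origin),
                    j = as.integer(m$bond$target))
  }
  molecule(
    tibble(
      serial = as.integer(a$eleno),
      name = as.character(a$elena),
      element = element,
      residue_name = substr(as.character(a$resid), 1, 3),
      chain_id = "A",
      residue_number = as.integer(a$resno),
      x = a$x, y = a$y, z = a$z,
      is_hetero = TRUE,
      b_factor = 0
    ),
    bonds = bonds, name = name, source_format = "mol2"
  )
}

# AutoDock atom types -> element. Vina's types decorate the element with
# hybridisation/H-bond flags (A aromatic carbon, OA acceptor oxygen, HD
# polar hydrogen, ...).
ad_type_to_element <- function(type) {
  type <- toupper(gsub("^\\s+|\\s+$", "", type))
  map <- c(A = "C", C = "C", N = "N", NA. = "N", OA = "O", O = "O",
           SA = "S", S = "S", P = "P", F = "F", CL = "Cl", BR = "Br",
           I = "I", HD = "H", HS = "H", H = "H", MG = "Mg", MN = "Mn",
           ZN = "Zn", CA = "Ca", FE = "Fe")
  names(map)[names(map) == "NA."] <- "NA"
  out <- unname(map[type])
  missing <- is.na(out)
  out[missing] <- normalize_element(type[missing])
  out
}

read_pdbqt_file <- function(path, name) {
  lines <- first_model_lines(readLines(path, warn = FALSE))
  parse_pdbqt_atoms(lines, name)
}

parse_pdbqt_atoms <- function(lines, name) {
  rec <- lines[grepl("^(ATOM|HETATM)", lines)]
  if (length(rec) == 0) {
    return(molecule(tibble(name = character(), element = character(),
                           x = double(), y = double(), z = double()),
                    name = name, source_format = "pdbqt"))
  }
  field <- function(from, to) gsub("^\\s+|\\s+$", "", substr(rec, from, to))
  tail_part <- substr(rec, 67, nchar(rec))
  tail_tok <- strsplit(sub("^\\s+", "", tail_part), "\\s+")
  charge <- vapply(tail_tok, function(t) {
    v <- suppressWarnings(as.numeric(t[1]))
    if (is.na(v)) 0 else v
  }, double(1))
  ad_type <- vapply(tail_tok, function(t) {
    if (length(t) >= 2) t[2] else ""
  }, character(1))
  nm <- field(13, 16)
  element <- ifelse(ad_type == "", guess_element(nm),
                    ad_type_to_element(ad_type))
  mol <- molecule(
    tibble(
      serial = as.integer(field(7, 11)),
      name = nm,
      element = element,
      residue_name = field(18, 20),
      chain_id = ifelse(field(22, 22) == "", "A", field(22, 22)),
      residue_number = suppressWarnings(as.integer(field(23, 26))),
      x = as.numeric(field(31, 38)),
      y = as.numeric(field(39, 46)),
      z = as.numeric(field(47, 54)),
      is_hetero = grepl("^HETATM", rec),
      b_factor = suppressWarnings(as.numeric(field(61, 66)))
    ),
    name = name, source_format = "pdbqt"
  )
  mol$atoms$b_factor[is.na(mol$atoms$b_factor)] <- 0
  mol$atoms$residue_number[is.na(mol$atoms$residue_number)] <- 1L
  attr(mol, "partial_charge") <- charge
  mol
}

quiet <- function(expr) {
  out <- NULL
  utils::capture.output(out <- suppressMessages(expr))
  out
}

#' Write a molecule to a structure file
#'
#' Counterpart of [read_structure()]; supports the same three formats.
#' Coordinates are written to three decimals (the PDB column precision).
#'
#' @param mol A [molecule].
#' @param path Output path.
#' @param format Target format; inferred from the extension when `NULL`.
#' @return `path`, invisibly.
#' @export
write_structure <- function(mol, path, format = NULL) {
  ext <- tolower(tools::file_ext(path))
  if (is.null(format)) {
    format <- switch(ext, pdb = "pdb", mol2 = "mol2", pdbqt = "pdbqt",
                     abort(paste0("cannot infer format from extension '.",
                                  ext, "'"),
                           class = "crossdockr_format_error"))
  }
  format <- match.arg(format, c("pdb", "mol2", "pdbqt"))
  lines <- switch(format,
    pdb = format_pdb_lines(mol),
    pdbqt = format_pdbqt_lines(mol),
    mol2 = format_mol2_lines(mol)
  )
  writeLines(lines, path)
  invisible(path)
}

pdb_atom_name <- function(name, element) {
  # Standard PDB justification: names shorter than 4 characters start in
  # column 14 unless the element symbol has two letters.
  ifelse(nchar(name) >= 4 | nchar(element) > 1,
         sprintf("%-4s", substr(name, 1, 4)),
         sprintf(" %-3s", name))
}

pdb_record_66 <- function(a) {
  sprintf("%-6s%5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
          ifelse(a$is_hetero, "HETATM", "ATOM"),
          a$serial %% 100000L,
          pdb_atom_name(a$name, a$element),
          substr(a$residue_name, 1, 3), substr(a$chain_id, 1, 1),
          a$residue_number %% 10000L,
          a$x, a$y, a$z, 1.00, a$b_factor)
}

format_pdb_lines <- function(mol) {
  a <- mol$atoms
  body <- paste0(pdb_record_66(a), "          ",
                 sprintf("%2s", toupper(a$element)))
  c(body, "END")
}

format_pdbqt_lines <- function(mol) {
  a <- mol$atoms
  charge <- attr(mol, "partial_charge") %||% rep(0, nrow(a))
  body <- paste0(pdb_record_66(a),
                 sprintf("    %6.3f %-2s", charge, a$element))
  c(body, "TER")
}

format_mol2_lines <- function(mol) {
  a <- mol$atoms
  b <- mol$bonds
  header <- c("@<TRIPOS>MOLECULE", mol$name,
              sprintf("%5d%6d%6d", nrow(a), nrow(b), 1),
              "SMALL", "NO_CHARGES", "", "@<TRIPOS>ATOM")
  atom_lines <- sprintf("%7d %-8s %9.4f %9.4f %9.4f %-5s %5d %-8s %9.4f",
                        seq_len(nrow(a)), a$name, a$x, a$y, a$z, a$element,
                        a$residue_number, a$residue_name, 0)
  bond_lines <- if (nrow(b) > 0) {
    c("@<TRIPOS>BOND",
      sprintf("%6d%6d%6d%5s", seq_len(nrow(b)), b$i, b$j, "1"))
  } else {
    "@<TRIPOS>BOND"
  }
  c(header, atom_lines, bond_lines)
}

#' Remove crystallographic waters
#'
#' Drops every atom whose residue name is in the water set; all other
#' heteroatom records (cofactors, coenzymes, ions) are treated as part of
#' the receptor and retained. Relative atom order is preserved and the
#' operation is idempotent.
#'
#' @param mol A [molecule].
#' @param water_residues Residue names treated as water.
#' @return The molecule without water atoms.
#' @export
strip_waters <- function(mol, water_residues = c("HOH", "WAT", "H2O", "DOD")) {
  keep <- which(!(mol$atoms$residue_name %in% water_residues))
  subset_atoms(mol, keep)
}

#' Assemble a receptor/ligand structure library
#'
#' Pairs receptors and their co-crystallised ligands by the file-name
#' convention: a receptor file stem must end in `-p`, its ligand in `-l`,
#' with a shared root (e.g. `1hwj-p.pdb` / `1hwj-l.pdb`). Matching is
#' case-sensitive on the root and extension-agnostic, so mixed formats
#' pair freely. Waters are stripped from receptors at load time. All
#' structures are assumed to be pre-aligned in one coordinate frame; no
#' superposition is performed here or anywhere downstream.
#'
#' @param receptor_dir Directory of receptor files (`<root>-p.<ext>`).
#' @param ligand_dir Directory of ligand files (`<root>-l.<ext>`).
#' @param water_residues Residue names stripped from receptors.
#' @return A `structure_library`: a tibble with columns `root`,
#'   `receptor` (list of [molecule]), `ligand` (list of [molecule]),
#'   sorted by root.
#' @export
build_library <- function(receptor_dir, ligand_dir,
                          water_residues = c("HOH", "WAT", "H2O", "DOD")) {
  for (d in c(receptor_dir, ligand_dir)) {
    if (!dir.exists(d)) {
      abort(paste0("directory does not exist: ", d),
            class = "crossdockr_io_error")
    }
  }
  rec_files <- list_structure_files(receptor_dir)
  lig_files <- list_structure_files(ligand_dir)
  rec_roots <- roots_with_suffix(rec_files, "-p")
  lig_roots <- roots_with_suffix(lig_files, "-l")
  check_duplicates(rec_roots, "receptor")
  check_duplicates(lig_roots, "ligand")
  orphans_r <- setdiff(names(rec_roots), names(lig_roots))
  orphans_l <- setdiff(names(lig_roots), names(rec_roots))
  if (length(orphans_r) + length(orphans_l) > 0) {
    abort(paste0("unpaired structures; orphan roots: ",
                 paste(sort(c(orphans_r, orphans_l)), collapse = ", ")),
          class = "crossdockr_pairing_error")
  }
  roots <- sort(names(rec_roots), method = "radix")
  pairs <- purrr::map(roots, function(root) {
    rec <- read_structure(rec_roots[[root]], name = root)
    rec <- strip_waters(rec, water_residues)
    lig <- read_structure(lig_roots[[root]], name = root)
    list(receptor = rec, ligand = lig)
  })
  out <- tibble(
    root = roots,
    receptor = purrr::map(pairs, "receptor"),
    ligand = purrr::map(pairs, "ligand")
  )
  class(out) <- c("structure_library", class(out))
  out
}

list_structure_files <- function(dir) {
  list.files(dir, pattern = "\\.(pdb|ent|mol2|pdbqt)$", full.names = TRUE,
             ignore.case = TRUE)
}

roots_with_suffix <- function(files, suffix) {
  stems <- tools::file_path_sans_ext(basename(files))
  sel <- endsWith(stems, suffix)
  files <- files[sel]
  stems <- stems[sel]
  roots <- substr(stems, 1, nchar(stems) - nchar(suffix))
  setNames(as.list(files), roots)
}

check_duplicates <- function(roots, what) {
  dup <- unique(names(roots)[duplicated(names(roots))])
  if (length(dup) > 0) {
    abort(paste0("ambiguous ", what, " root(s) with multiple files: ",
                 paste(dup, collapse = ", ")),
          class = "crossdockr_pairing_error")
  }
}

#' @export
print.structure_library <- function(x, ...) {
  cat(sprintf("<structure_library> %d receptor/ligand pair(s): %s\n",
              nrow(x), paste(x$root, collapse = ", ")))
  invisible(x)
}
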