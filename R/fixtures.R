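#' Specification of a synthetic receptor/ligand family
#'
#' Describes a toy structure family for exercising the pipeline with known
#' ground truth: `n_pairs` receptor/ligand pairs written as PDB files in
#' one shared coordinate frame (pre-aligned by construction), each ligand
#' built on a chosen topology, and per-cell planted pose offsets and
#' energies for the mock engine. Fixture receptors are minimal atom cages
#' around the ligand site — the pipeline under test evaluates geometry and
#' bookkeeping, never physics.
#'
#' @param n_pairs Number of receptor/ligand pairs (1-20).
#' @param ligand_size Heavy atoms per ligand (3-12).
#' @param symmetry Ligand topology: `"none"` (an asymmetric hetero chain),
#'   `"swap-pair"` (a carboxylate-like pair of topologically equivalent
#'   oxygens), `"ring"` (a carbon ring with a rich automorphism group).
#' @param planted_pose_offsets Planted pose displacements (Angstrom):
#'   `NULL` for seeded defaults, a numeric vector applied to every cell,
#'   or a list of length `n_pairs^2` (row-major over sorted roots:
#'   ligand-major).
#' @param planted_energies Planted energies (kcal/mol), same shapes;
#'   default `-10 + offset` so better geometry scores better.
#' @param n_poses Poses per cell when generating default plants.
#' @param seed Integer seed controlling all generated values.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_pairs = 3L, ligand_size = 6L,
                         symmetry = c("none", "swap-pair", "ring"),
                         planted_pose_offsets = NULL,
                         planted_energies = NULL,
                         n_poses = 3L, seed = 1L) {
  symmetry <- match.arg(symmetry)
  if (n_pairs < 1 || n_pairs > 20) {
    abort("n_pairs must be in 1..20", class = "crossdockr_config_error")
  }
  if (ligand_size < 3 || ligand_size > 12) {
    abort("ligand_size must be in 3..12", class = "crossdockr_config_error")
  }
  structure(list(n_pairs = as.integer(n_pairs),
                 ligand_size = as.integer(ligand_size),
                 symmetry = symmetry,
                 planted_pose_offsets = planted_pose_offsets,
                 planted_energies = planted_energies,
                 n_poses = as.integer(n_poses),
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

fixture_ligand <- function(size, symmetry, center, name) {
  base <- switch(symmetry,
    "none" = {
      el <- rep(c("C", "N", "O", "S"), length.out = size)
      tibble(name = paste0(el, seq_len(size)), element = el,
             x = 1.5 * (seq_len(size) - 1), y = 0, z = 0)
    },
    "swap-pair" = {
      # O-C(-O)- head with an asymmetric carbon tail: the two oxygens are
      # topologically equivalent, nothing else is.
      head <- tibble(name = c("O1", "C1", "O2"), element = c("O", "C", "O"),
                     x = c(-1.2, 0, 1.2), y = 0, z = 0)
      tail_n <- size - 3
      if (tail_n > 0) {
        tail <- tibble(name = paste0("C", 1 + seq_len(tail_n)),
                       element = "C", x = 0, y = 1.5 * seq_len(tail_n),
                       z = 0)
        dplyr::bind_rows(head, tail)
      } else {
        head
      }
    },
    "ring" = {
      r <- 1.4 / (2 * sin(pi / size))
      ang <- 2 * pi * (seq_len(size) - 1) / size
      tibble(name = paste0("C", seq_len(size)), element = "C",
             x = r * cos(ang), y = r * sin(ang), z = 0)
    }
  )
  ctr <- c(mean(base$x), mean(base$y), mean(base$z))
  base$x <- base$x - ctr[1] + center[1]
  base$y <- base$y - ctr[2] + center[2]
  base$z <- base$z - ctr[3] + center[3]
  base$residue_name <- "LIG"
  base$is_hetero <- TRUE
  molecule(base, name = name)
}

# ~20-atom deterministic cage on a sphere around the site (Fibonacci
# lattice), plus one retained hetero cofactor atom and stripped-on-load
# crystallographic waters.
fixture_receptor <- function(center, name, n_cage = 20, radius = 8) {
  k <- seq_len(n_cage)
  golden <- pi * (3 - sqrt(5))
  zf <- 1 - 2 * (k - 0.5) / n_cage
  rf <- sqrt(pmax(0, 1 - zf^2))
  cage <- tibble(
    name = "CA", element = "C", residue_name = "ALA", chain_id = "A",
    residue_number = as.integer(k), is_hetero = FALSE,
    x = center[1] + radius * rf * cos(golden * k),
    y = center[2] + radius * rf * sin(golden * k),
    z = center[3] + radius * zf
  )
  cofactor <- tibble(
    name = "PA", element = "P", residue_name = "ADP", chain_id = "A",
    residue_number = n_cage + 1L, is_hetero = TRUE,
    x = center[1] + radius + 2, y = center[2], z = center[3]
  )
  waters <- tibble(
    name = "O", element = "O", residue_name = "HOH", chain_id = "A",
    residue_number = n_cage + 1L + seq_len(3), is_hetero = TRUE,
    x = center[1] + (radius + 4), y = center[2] + seq_len(3) * 2,
    z = center[3]
  )
  molecule(dplyr::bind_rows(cage, cofactor, waters), name = name)
}

#' Materialize a synthetic structure family with planted ground truth
#'
#' Writes `n_pairs` receptor and ligand PDB files under the `-p`/`-l`
#' naming convention into `receptors/` and `ligands/` subdirectories of
#' `dir`, builds the resulting [build_library()] library, and returns the
#' per-cell planted (offset, energy) lists that a [mock_engine()]
#' constructed from this family will reproduce. The same spec and seed
#' always produce byte-identical files.
#'
#' @param spec A [fixture_spec()].
#' @param dir Target directory (created; default a fresh temp directory).
#' @return A `fixture_family` list: `receptor_dir`, `ligand_dir`,
#'   `library`, `truth` (tibble `ligand_root`, `receptor_root`, `offsets`,
#'   `energies`), `spec`.
#' @export
generate_family <- function(spec = fixture_spec(), dir = NULL) {
  dir <- dir %||% tempfile("fixture_family_")
  rec_dir <- file.path(dir, "receptors")
  lig_dir <- file.path(dir, "ligands")
  dir.create(rec_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(lig_dir, recursive = TRUE, showWarnings = FALSE)
  roots <- sprintf("fx%02d", seq_len(spec$n_pairs))
  for (k in seq_len(spec$n_pairs)) {
    center <- c(15 * (k - 1), 0, 0)
    lig <- fixture_ligand(spec$ligand_size, spec$symmetry, center, roots[k])
    rec <- fixture_receptor(center, roots[k])
    write_structure(lig, file.path(lig_dir, paste0(roots[k], "-l.pdb")))
    write_structure(rec, file.path(rec_dir, paste0(roots[k], "-p.pdb")))
  }
  library <- build_library(rec_dir, lig_dir)
  truth <- fixture_truth(spec, roots)
  structure(list(receptor_dir = rec_dir, ligand_dir = lig_dir,
                 library = library, truth = truth, spec = spec),
            class = "fixture_family")
}

fixture_truth <- function(spec, roots) {
  grid <- tidyr::expand_grid(ligand_root = roots, receptor_root = roots)
  n_cells <- nrow(grid)
  offsets <- spec$planted_pose_offsets
  if (is.null(offsets)) {
    offsets <- purrr::map(seq_len(n_cells), function(k) {
      withr::with_seed(spec$seed + k, sort(stats::runif(spec$n_poses, 0, 4)))
    })
  } else if (is.numeric(offsets)) {
    offsets <- rep(list(offsets), n_cells)
  } else if (length(offsets) != n_cells) {
    abort("planted_pose_offsets list must have n_pairs^2 elements",
          class = "crossdockr_config_error")
  }
  energies <- spec$planted_energies
  if (is.null(energies)) {
    energies <- purrr::map(offsets, ~ -10 + .x)
  } else if (is.numeric(energies)) {
    energies <- rep(list(energies), n_cells)
  } else if (length(energies) != n_cells) {
    abort("planted_energies list must have n_pairs^2 elements",
          class = "crossdockr_config_error")
  }
  bad <- purrr::map2_lgl(offsets, energies,
                         ~ length(.x) != length(.y) || length(.x) == 0)
  if (any(bad)) {
    abort("offsets and energies must be non-empty and of equal length per cell",
          class = "crossdockr_config_error")
  }
  grid$offsets <- offsets
  grid$energies <- energies
  grid
}

#' Random small molecule for mapping stress tests
#'
#' A connected random graph (a spanning tree plus an optional extra edge)
#' over heavy atoms with random elements and Gaussian coordinates; bonds
#' are explicit, not perceived. Used to exercise symmetry-corrected RMSD
#' against brute-force mapping enumeration.
#'
#' @param n_heavy Heavy atom count.
#' @param seed Integer seed.
#' @param elements Element pool to sample from.
#' @param p_extra_edge Probability of adding one ring-closing edge.
#' @return A [molecule] with bonds populated.
#' @export
random_molecule <- function(n_heavy, seed,
                            elements = c("C", "N", "O"),
                            p_extra_edge = 0.4) {
  withr::with_seed(seed, {
    el <- sample(elements, n_heavy, replace = TRUE)
    bonds <- if (n_heavy > 1) {
      tibble(i = vapply(2:n_heavy, function(k) {
        sample.int(k - 1, 1)
      }, integer(1)), j = 2:n_heavy)
    } else {
      NULL
    }
    if (n_heavy >= 4 && stats::runif(1) < p_extra_edge) {
      pair <- sort(sample.int(n_heavy, 2))
      bonds <- dplyr::bind_rows(bonds, tibble(i = pair[1], j = pair[2]))
      bonds <- bonds[!duplicated(paste(bonds$i, bonds$j)), ]
    }
    molecule(
      tibble(name = paste0(el, seq_len(n_heavy)), element = el,
             x = stats::rnorm(n_heavy, sd = 2),
             y = stats::rnorm(n_heavy, sd = 2),
             z = stats::rnorm(n_heavy, sd = 2)),
      bonds = bonds, name = paste0("rnd", seed)
    )
  })
}
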