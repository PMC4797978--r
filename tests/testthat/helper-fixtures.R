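# Build a crossdock_result directly from per-cell pose tables, bypassing
# any engine, so aggregation and reporting can be tested on hand-picked
# numbers. `cells` is a tibble with ligand_root, receptor_root and a
# `poses` list-column of tibbles (mode_index, energy, rmsd); failures are
# rows with a zero-row pose table.
fake_result <- function(cells, seed = 0L) {
  records <- purrr::pmap(cells, function(ligand_root, receptor_root, poses) {
    failed <- nrow(poses) == 0
    if (!"symmetry_corrected" %in% names(poses)) {
      poses$symmetry_corrected <- rep(TRUE, nrow(poses))
    }
    base <- tibble::tibble(
      ligand_root = ligand_root, receptor_root = receptor_root,
      is_self_dock = ligand_root == receptor_root,
      failed = failed,
      fail_reason = if (failed) "planted failure" else NA_character_,
      poses = list(poses)
    )
    if (failed) {
      dplyr::bind_cols(base, tibble::tibble(
        best_rmsd = NA_real_, best_rmsd_energy = NA_real_,
        best_rmsd_mode = NA_integer_, best_energy = NA_real_,
        best_energy_rmsd = NA_real_, best_energy_mode = NA_integer_))
    } else {
      br <- crossdockr::select_best_rmsd(poses)
      be <- crossdockr::select_best_energy(poses)
      dplyr::bind_cols(base, tibble::tibble(
        best_rmsd = br$rmsd, best_rmsd_energy = br$energy,
        best_rmsd_mode = br$mode_index, best_energy = be$energy,
        best_energy_rmsd = be$rmsd, best_energy_mode = be$mode_index))
    }
  })
  roots <- sort(unique(c(cells$ligand_root, cells$receptor_root)),
                method = "radix")
  structure(list(records = dplyr::bind_rows(records),
                 params = crossdockr::docking_params(seed = seed),
                 roots = roots, box_size = c(20, 20, 20),
                 box_center = "native"),
            class = "crossdock_result")
}

# Full grid of single-pose cells from a best-RMSD matrix (ligand rows x
# receptor columns) and an optional matching energy matrix.
fake_grid_from_matrix <- function(rmsd_mat, energy_mat = NULL) {
  roots_l <- rownames(rmsd_mat)
  roots_r <- colnames(rmsd_mat)
  if (is.null(energy_mat)) energy_mat <- -10 + rmsd_mat
  cells <- tidyr::expand_grid(ligand_root = roots_l,
                              receptor_root = roots_r)
  cells$poses <- purrr::pmap(cells, function(ligand_root, receptor_root) {
    r <- rmsd_mat[ligand_root, receptor_root]
    e <- energy_mat[ligand_root, receptor_root]
    if (is.na(r)) {
      tibble::tibble(mode_index = integer(), energy = double(),
                     rmsd = double())
    } else {
      tibble::tibble(mode_index = 1L, energy = e, rmsd = r)
    }
  })
  fake_result(cells)
}

write_tiny_pdb <- function(path) {
  writeLines(c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   ALA A   1       2.000   1.400   0.000  1.00  0.00           C",
    "HETATM    4  O   HOH A   2       8.000   8.000   8.000  1.00  0.00           O",
    "END"), path)
  path
}

vina_pose_fixture_lines <- function() {
  c("MODEL 1",
    "REMARK VINA RESULT:    -7.5      0.000      0.000",
    "ROOT",
    "ATOM      1  C1  LIG A   1       1.000   2.000   3.000  1.00  0.00     0.010 C ",
    "ATOM      2  O1  LIG A   1       2.200   2.000   3.000  1.00  0.00    -0.350 OA",
    "ENDROOT",
    "TORSDOF 0",
    "ENDMDL",
    "MODEL 2",
    "REMARK VINA RESULT:    -6.1      1.800      2.400",
    "ROOT",
    "ATOM      1  C1  LIG A   1       1.500   2.500   3.500  1.00  0.00     0.010 C ",
    "ATOM      2  O1  LIG A   1       2.700   2.500   3.500  1.00  0.00    -0.350 OA",
    "ENDROOT",
    "TORSDOF 0",
    "ENDMDL")
}
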