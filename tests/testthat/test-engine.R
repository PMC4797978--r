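test_that("box center is the heavy-atom centroid of the native ligand", {
  two <- molecule(data.frame(name = c("C1", "C2"), element = "C",
                             x = c(0, 2), y = 0, z = 0))
  expect_equal(compute_box_center(two), c(1, 0, 0))
  one <- molecule(data.frame(name = "C1", element = "C",
                             x = 5, y = -1, z = 3))
  expect_equal(compute_box_center(one), c(5, -1, 3))
  cube <- molecule(data.frame(name = paste0("C", 1:4), element = "C",
                              x = c(0, 1, 0, 0), y = c(0, 0, 1, 0),
                              z = c(0, 0, 0, 1)))
  expect_equal(compute_box_center(cube), c(0.25, 0.25, 0.25))
  # hydrogens do not shift the center; a hydrogen-only ligand is an error
  with_h <- molecule(data.frame(name = c("C1", "H1"), element = c("C", "H"),
                                x = c(1, 99), y = 0, z = 0))
  expect_equal(compute_box_center(with_h), c(1, 0, 0))
  only_h <- molecule(data.frame(name = "H1", element = "H",
                                x = 0, y = 0, z = 0))
  expect_error(compute_box_center(only_h),
               class = "crossdockr_empty_structure_error")
})

test_that("box and parameter validation", {
  expect_error(grid_box(c(0, 0, 0), c(10, -1, 10)),
               class = "crossdockr_config_error")
  expect_equal(grid_box(c(0, 0, 0), 15)$size, c(15, 15, 15))
  p <- docking_params()
  expect_equal(p$exhaustiveness, 8L)
  expect_true(p$randomize_first)
  expect_error(docking_params(exhaustiveness = 0),
               class = "crossdockr_config_error")
  expect_error(docking_params(energy_range = -1),
               class = "crossdockr_config_error")
})

test_that("mock engine plants poses in energy order and truncates to
           num_modes", {
  lig <- random_molecule(5, seed = 21)
  rec <- random_molecule(8, seed = 22)
  truth <- tibble::tibble(ligand_root = lig$name, receptor_root = rec$name,
                          offsets = list(c(0.0, 1.5, 4.0)),
                          energies = list(c(-9.1, -8.0, -6.2)))
  eng <- mock_engine(truth = truth)
  box <- grid_box(compute_box_center(lig), 20)
  res <- dock(eng, rec, lig, box, docking_params(seed = 5))
  expect_s3_class(res, "docking_result")
  expect_equal(res$poses$energy, c(-9.1, -8.0, -6.2))
  expect_equal(res$poses$mode_index, 1:3)
  res2 <- dock(eng, rec, lig, box, docking_params(num_modes = 2, seed = 5))
  expect_equal(nrow(res2$poses), 2)
  expect_equal(res2$poses$energy, c(-9.1, -8.0))
})

test_that("mock engine is a pure function of inputs and seed, and its
           planted offsets equal the scored RMSD", {
  lig <- random_molecule(6, seed = 31)
  rec <- random_molecule(9, seed = 32)
  box <- grid_box(compute_box_center(lig), 20)
  eng <- mock_engine()
  a <- dock(eng, rec, lig, box, docking_params(seed = 77))
  b <- dock(eng, rec, lig, box, docking_params(seed = 77))
  expect_identical(a, b)
  c <- dock(eng, rec, lig, box, docking_params(seed = 78))
  expect_false(identical(a$poses$coords, c$poses$coords))
  # central self-consistency: planted offset == computed symmetry RMSD
  planted_offsets <- c(0.0, 0.7, 2.6)
  truth <- tibble::tibble(ligand_root = lig$name, receptor_root = rec$name,
                          offsets = list(planted_offsets),
                          energies = list(-10 + planted_offsets))
  planted <- dock(mock_engine(truth = truth), rec, lig, box,
                  docking_params(seed = 3))
  got <- vapply(planted$poses$coords,
                function(xyz) symmetry_min_rmsd(lig, xyz)$value, double(1))
  expect_equal(got, planted_offsets, tolerance = 1e-6)
})

test_that("mock randomization is seeded, order-preserving and lands in
           the box", {
  lig <- random_molecule(6, seed = 41)
  rec <- random_molecule(9, seed = 42)
  box <- grid_box(c(5, 5, 5), 12)
  r1 <- randomize_ligand(mock_engine(), lig, rec, box, seed = 11)
  r2 <- randomize_ligand(mock_engine(), lig, rec, box, seed = 11)
  expect_identical(r1, r2)
  r3 <- randomize_ligand(mock_engine(), lig, rec, box, seed = 12)
  expect_false(isTRUE(all.equal(colMeans(coords(r1)), colMeans(coords(r3)))))
  expect_equal(n_atoms(r1), nrow(coords(lig, heavy_only = TRUE)))
  expect_equal(r1$atoms$name, heavy_atoms(lig)$atoms$name)
  expect_true(all(abs(colMeans(coords(r1)) - box$center) <= box$size / 2))
  # rigid: internal distances preserved
  expect_equal(as.vector(dist(coords(r1))),
               as.vector(dist(coords(lig, heavy_only = TRUE))),
               tolerance = 1e-9)
})

test_that("Vina pose parser recovers energies and coordinates", {
  path <- withr::local_tempfile(fileext = ".pdbqt")
  writeLines(vina_pose_fixture_lines(), path)
  poses <- parse_vina_poses(path)
  expect_equal(nrow(poses), 2)
  expect_equal(poses$energy, c(-7.5, -6.1))
  expect_equal(poses$coords[[1]][1, ], c(1, 2, 3))
  expect_equal(nrow(poses$coords[[2]]), 2)
})

test_that("Vina adapter demands an executable and writes a complete
           config file", {
  eng <- vina_engine(path = "/definitely/not/vina")
  lig <- random_molecule(4, seed = 51)
  rec <- random_molecule(8, seed = 52)
  box <- grid_box(c(0, 0, 0), 20)
  expect_error(dock(eng, rec, lig, box),
               class = "crossdockr_configuration_error")
  d <- withr::local_tempdir()
  cfg <- crossdockr:::write_vina_config(
    d, "r.pdbqt", "l.pdbqt", box,
    docking_params(exhaustiveness = 8, num_modes = 9, seed = 42),
    "out.pdbqt")
  lines <- readLines(cfg)
  for (key in c("receptor", "ligand", "center_x", "center_y", "center_z",
                "size_x", "size_y", "size_z", "exhaustiveness",
                "num_modes", "seed", "out")) {
    expect_true(any(grepl(paste0("^", key, " = "), lines)), info = key)
  }
  expect_true(any(grepl("^exhaustiveness = 8$", lines)))
})

test_that("a live 1x1 smoke dock succeeds when a Vina binary is present", {
  vina_path <- Sys.which("vina")
  found <- nzchar(vina_path)
  if (found) {
    fam <- generate_family(fixture_spec(n_pairs = 1, seed = 3))
    lig <- fam$library$ligand[[1]]
    rec <- fam$library$receptor[[1]]
    box <- grid_box(compute_box_center(lig), 20)
    res <- dock(vina_engine(path = vina_path), rec, lig, box,
                docking_params(seed = 1))
    expect_gte(nrow(res$poses), 1)
    expect_false(is.unsorted(res$poses$energy))
  }
  # the adapter contract itself (parser + config) is covered above either way
  expect_true(TRUE)
})
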