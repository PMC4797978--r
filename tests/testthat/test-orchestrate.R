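test_that("the grid is complete with a correctly flagged diagonal for any
           family size", {
  for (n in c(1, 2, 4)) {
    fam <- generate_family(fixture_spec(n_pairs = n, seed = n + 10))
    eng <- mock_engine(reference = fam$library, truth = fam$truth)
    res <- run_crossdock(fam$library, eng, docking_params(seed = 1),
                         box_size = 20)
    expect_equal(nrow(res$records), n^2)
    expect_equal(sum(res$records$is_self_dock), n)
    expect_setequal(unique(res$records$ligand_root), fam$library$root)
    expect_true(all(res$records$is_self_dock ==
                    (res$records$ligand_root == res$records$receptor_root)))
  }
})

test_that("planted per-cell ground truth is reproduced exactly", {
  fam <- generate_family(fixture_spec(n_pairs = 3, symmetry = "swap-pair",
                                      seed = 5))
  eng <- mock_engine(reference = fam$library, truth = fam$truth)
  res <- run_crossdock(fam$library, eng, docking_params(seed = 9),
                       box_size = 20)
  rec <- dplyr::left_join(res$records, fam$truth,
                          by = c("ligand_root", "receptor_root"))
  expect_equal(rec$best_rmsd, purrr::map_dbl(rec$offsets, min),
               tolerance = 1e-9)
  expect_equal(rec$best_energy, purrr::map_dbl(rec$energies, min),
               tolerance = 1e-9)
  # RMSD carried by the best-energy pose is the offset of the min-energy pose
  expect_equal(rec$best_energy_rmsd,
               purrr::map2_dbl(rec$offsets, rec$energies,
                               ~ .x[which.min(.y)]),
               tolerance = 1e-9)
  # self-dock with a planted zero-offset pose scores exactly zero
  fam0 <- generate_family(fixture_spec(
    n_pairs = 2, planted_pose_offsets = c(0, 2.5),
    planted_energies = c(-9, -8), seed = 6))
  res0 <- run_crossdock(fam0$library,
                        mock_engine(fam0$library, fam0$truth),
                        docking_params(seed = 2), box_size = 20)
  diag0 <- res0$records[res0$records$is_self_dock, ]
  expect_equal(diag0$best_rmsd, c(0, 0))
})

test_that("best-pose selection rules minimise the right quantity and break
           ties toward the lower mode", {
  poses <- tibble::tibble(mode_index = 1:3, energy = c(-7, -9, -8),
                          rmsd = c(2.1, 0.9, 1.4))
  expect_equal(select_best_rmsd(poses),
               tibble::tibble(rmsd = 0.9, energy = -9, mode_index = 2L))
  expect_equal(select_best_energy(poses),
               tibble::tibble(energy = -9, rmsd = 0.9, mode_index = 2L))
  tie <- tibble::tibble(mode_index = c(1L, 3L), energy = c(-5, -5),
                        rmsd = c(1.0, 1.0))
  expect_equal(select_best_rmsd(tie)$mode_index, 1L)
  expect_equal(select_best_energy(tie)$mode_index, 1L)
  single <- tibble::tibble(mode_index = 1L, energy = -4, rmsd = 3)
  expect_equal(select_best_rmsd(single)$rmsd, 3)
  expect_error(select_best_rmsd(single[0, ]),
               class = "crossdockr_empty_record_error")
  # divergence: best-RMSD pose and best-energy pose are different poses
  div <- tibble::tibble(mode_index = 1:2, energy = c(-7, -9),
                        rmsd = c(0.5, 3.0))
  expect_equal(select_best_rmsd(div)$rmsd, 0.5)
  expect_equal(select_best_energy(div)$rmsd, 3.0)
})

test_that("failed cells are recorded with diagnostics while the run
           continues", {
  fam <- generate_family(fixture_spec(n_pairs = 2, seed = 8))
  truth <- fam$truth
  # empty plant for one cell makes the engine fail there
  k <- which(truth$ligand_root == "fx01" & truth$receptor_root == "fx02")
  truth$offsets[[k]] <- numeric(0)
  truth$energies[[k]] <- numeric(0)
  eng <- mock_engine(reference = fam$library, truth = truth)
  res <- run_crossdock(fam$library, eng, docking_params(seed = 4),
                       box_size = 20)
  failed <- res$records[res$records$failed, ]
  expect_equal(nrow(failed), 1)
  expect_equal(failed$ligand_root, "fx01")
  expect_match(failed$fail_reason, "no poses")
  expect_true(is.na(failed$best_rmsd))
  expect_equal(sum(!res$records$failed), 3)
  # every cell failing is a run error
  all_bad <- truth
  for (i in seq_len(nrow(all_bad))) {
    all_bad$offsets[[i]] <- numeric(0)
    all_bad$energies[[i]] <- numeric(0)
  }
  expect_error(run_crossdock(fam$library,
                             mock_engine(fam$library, all_bad),
                             docking_params(seed = 4), box_size = 20),
               class = "crossdockr_run_error")
})

test_that("same seed reproduces the identical grid; best-RMSD never
           exceeds the best-energy pose RMSD", {
  fam <- generate_family(fixture_spec(n_pairs = 3, seed = 12))
  eng <- mock_engine(reference = fam$library)  # seeded defaults, no plant
  a <- run_crossdock(fam$library, eng, docking_params(seed = 99),
                     box_size = 20)
  b <- run_crossdock(fam$library, eng, docking_params(seed = 99),
                     box_size = 20)
  expect_identical(a$records, b$records)
  d <- run_crossdock(fam$library, eng, docking_params(seed = 100),
                     box_size = 20)
  expect_false(identical(a$records$best_rmsd, d$records$best_rmsd))
  ok <- !a$records$failed
  expect_true(all(a$records$best_rmsd[ok] <=
                  a$records$best_energy_rmsd[ok] + 1e-12))
})

test_that("a result survives a save/load round trip", {
  fam <- generate_family(fixture_spec(n_pairs = 2, seed = 13))
  eng <- mock_engine(reference = fam$library, truth = fam$truth)
  res <- run_crossdock(fam$library, eng, docking_params(seed = 7),
                       box_size = 20)
  path <- withr::local_tempfile(fileext = ".json")
  save_crossdock(res, path)
  back <- load_crossdock(path)
  expect_equal(back$roots, res$roots)
  expect_equal(back$records$best_rmsd, res$records$best_rmsd)
  expect_equal(back$records$best_energy, res$records$best_energy)
  expect_equal(
    dplyr::bind_rows(back$records$poses)$rmsd,
    dplyr::bind_rows(res$records$poses)$rmsd)
  # rebuilt matrices are numerically identical
  ta <- build_tables(res)$table_the_best_rmsd$values
  tb <- build_tables(back)$table_the_best_rmsd$values
  expect_equal(tb, ta)
  # reports regenerated from the persisted grid are byte-identical
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_reports(build_tables(res), d1, formats = "csv")
  write_reports(build_tables(back), d2, formats = "csv")
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), info = f)
  }
})
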