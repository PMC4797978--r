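test_that("nearest-rank percentiles and band assignment", {
  v <- 1:10
  expect_equal(percentile_nearest_rank(v, 10), 1)
  expect_equal(percentile_nearest_rank(v, 50), 5)
  expect_equal(percentile_nearest_rank(v, 90), 9)
  b <- assign_bands(as.numeric(v))
  expect_equal(b[1], "green")
  expect_equal(b[5], "yellow")
  expect_equal(b[c(9, 10)], c("red", "red"))
  expect_equal(b[7], "none")
  # min is always green, max always red for >= 10 distinct values
  shuffled <- matrix(sample(seq(0.1, 5, length.out = 12)), 3, 4)
  bm <- assign_bands(shuffled)
  expect_equal(bm[which.min(shuffled)], "green")
  expect_equal(bm[which.max(shuffled)], "red")
  # degenerate all-equal matrix: thresholds collapse, best band wins
  expect_true(all(assign_bands(matrix(1.5, 3, 3)) == "green"))
  expect_true(is.na(assign_bands(c(1, NA, 3))[2]))
})

report_fixture <- function() {
  fam <- generate_family(fixture_spec(n_pairs = 3, seed = 17))
  eng <- mock_engine(reference = fam$library, truth = fam$truth)
  run_crossdock(fam$library, eng, docking_params(seed = 23), box_size = 20)
}

test_that("the six tables have the published shape, orientation and
           footers", {
  res <- report_fixture()
  tb <- build_tables(res)
  expect_named(tb, c("output", "output_best_rmsd", "table_the_best_rmsd",
                     "table_the_best_energy",
                     "table_rmsd_for_the_best_energy",
                     "table_energy_for_the_best_rmsd"))
  m <- tb$table_the_best_rmsd
  expect_equal(dim(m$values), c(3, 3))
  expect_equal(rownames(m$values), res$roots)   # ligands in rows
  expect_equal(colnames(m$values), res$roots)   # receptors in columns
  expect_equal(nrow(m$footer), 2)
  # footer average agrees with the aggregation module to 1e-9
  s <- summarize_receptors(res)
  expect_equal(unname(m$footer["average", ]), s$mean_best_rmsd,
               tolerance = 1e-9)
  expect_equal(unname(m$footer[2, ]), as.numeric(s$n_success))
  # bold mask marks exactly the self-docking diagonal
  expect_equal(m$bold_mask, diag(3) == 1)
  # energy matrices carry the average footer only
  expect_equal(nrow(tb$table_the_best_energy$footer), 1)
  # matrix (5) holds each record's RMSD-of-best-energy value
  rec <- res$records
  for (i in seq_len(nrow(rec))) {
    expect_equal(
      tb$table_rmsd_for_the_best_energy$values[rec$ligand_root[i],
                                               rec$receptor_root[i]],
      rec$best_energy_rmsd[i])
  }
  # long-form table row count is the total pose count
  expect_equal(nrow(tb$output), sum(purrr::map_int(rec$poses, nrow)))
  expect_error(build_tables(structure(
    list(records = rec[0, ], roots = character()),
    class = "crossdock_result")), class = "crossdockr_report_error")
})

test_that("failed cells appear as empty cells, not zeros", {
  m <- matrix(c(1, NA, 2, 3), 2, 2,
              dimnames = list(c("a", "b"), c("a", "b")))
  tb <- build_tables(fake_grid_from_matrix(m))
  expect_true(is.na(tb$table_the_best_rmsd$values["b", "a"]))
  expect_equal(unname(tb$table_the_best_rmsd$footer["average", "a"]), 1)
})

test_that("report files land on disk under the canonical names", {
  res <- report_fixture()
  tb <- build_tables(res)
  d <- withr::local_tempdir()
  write_reports(tb, d, formats = "csv")
  expected_csv <- c("Output.csv", "Output_the_best_RMSD.csv",
                    "Table_the_best_RMSD.csv", "Table_the_best_energy.csv",
                    "Table_RMSD_for_the_best_energy.csv",
                    "Table_energy_for_the_best_RMSD.csv",
                    "band_assignments.csv")
  expect_true(all(file.exists(file.path(d, expected_csv))))
  # csv matrix mirror: 3 body rows + 2 footer rows
  mat <- readr::read_csv(file.path(d, "Table_the_best_RMSD.csv"),
                         show_col_types = FALSE)
  expect_equal(nrow(mat), 5)
  expect_equal(names(mat), c("ligand", res$roots))
  bands <- readr::read_csv(file.path(d, "band_assignments.csv"),
                           show_col_types = FALSE)
  expect_equal(nrow(bands), 4 * 9)
  expect_true(all(bands$band %in% c("green", "yellow", "red", "none")))
  # spreadsheets appear when a python interpreter is available
  if (nzchar(Sys.which("python")) || nzchar(Sys.which("python3"))) {
    write_reports(tb, d, formats = "xlsx")
    expect_true(all(file.exists(
      file.path(d, sub("csv$", "xlsx", expected_csv[1:6])))))
  }
  # re-running into the same directory replaces files cleanly
  before <- readLines(file.path(d, "Table_the_best_RMSD.csv"))
  write_reports(tb, d, formats = "csv")
  expect_identical(readLines(file.path(d, "Table_the_best_RMSD.csv")),
                   before)
})

test_that("per-column banding is available as an alternative scope", {
  res <- report_fixture()
  tb_m <- build_tables(res, band_scope = "matrix")
  tb_c <- build_tables(res, band_scope = "column")
  bc <- tb_c$table_the_best_rmsd$bands
  # each column independently contains its own green minimum
  for (j in 1:3) {
    vals <- tb_c$table_the_best_rmsd$values[, j]
    expect_equal(bc[which.min(vals), j], "green")
  }
  expect_equal(dim(tb_m$table_the_best_rmsd$bands), c(3, 3))
})

test_that("tidy, glance and autoplot views agree with the records", {
  res <- report_fixture()
  long <- tidy(res)
  expect_equal(nrow(long), sum(purrr::map_int(res$records$poses, nrow)))
  expect_true(all(c("ligand_root", "receptor_root", "mode_index",
                    "energy", "rmsd") %in% names(long)))
  g <- glance(res)
  expect_equal(g$n_cells, 9L)
  expect_equal(g$n_failed, 0L)
  expect_equal(g$mean_best_rmsd, mean(res$records$best_rmsd))
  p <- autoplot(res)
  expect_s3_class(p, "ggplot")
})

test_that("manifests capture the run reproducibly", {
  res <- report_fixture()
  p1 <- withr::local_tempfile(fileext = ".json")
  p2 <- withr::local_tempfile(fileext = ".json")
  write_manifest(res, p1)
  write_manifest(res, p2)
  expect_identical(readLines(p1), readLines(p2))
  m <- jsonlite::read_json(p1)
  expect_equal(unlist(m$roots), res$roots)
  expect_equal(m$params$seed, 23)
  expect_equal(length(m$cell_seeds), 9)
})
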