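#' Nearest-rank percentile
#'
#' The p-th percentile by the nearest-rank definition: the value at sorted
#' position `ceiling(p/100 * n)`.
#'
#' @param values Numeric vector (non-finite values dropped).
#' @param p Percentile in (0, 100].
#' @return A single value from `values`.
#' @export
percentile_nearest_rank <- function(values, p) {
  v <- sort(values[is.finite(values)])
  if (length(v) == 0) {
    abort("no finite values", class = "crossdockr_report_error")
  }
  v[max(1L, ceiling(p / 100 * length(v)))]
}

#' Traffic-light band assignment for a result matrix
#'
#' Cells are banded against the 10th, 50th and 90th nearest-rank
#' percentiles of the pooled finite matrix values: at or below the 10th
#' percentile is green (best), at or below the median is yellow, at or
#' above the 90th percentile is red, everything in between is unbanded.
#' When thresholds collapse (ties, degenerate matrices) the best band
#' wins, so an all-equal matrix is entirely green.
#'
#' @param values Numeric matrix (or vector).
#' @return Character array of the same shape with entries `"green"`,
#'   `"yellow"`, `"red"`, `"none"` (`NA` for non-finite cells).
#' @export
assign_bands <- function(values) {
  t10 <- percentile_nearest_rank(values, 10)
  t50 <- percentile_nearest_rank(values, 50)
  t90 <- percentile_nearest_rank(values, 90)
  band <- ifelse(!is.finite(values), NA_character_,
          ifelse(values <= t10, "green",
          ifelse(values <= t50, "yellow",
          ifelse(values >= t90, "red", "none"))))
  if (is.matrix(values)) {
    band <- matrix(band, nrow(values), ncol(values),
                   dimnames = dimnames(values))
  }
  band
}

new_matrix_table <- function(values, kind, title, threshold, band_scope) {
  bands <- if (band_scope == "column") {
    apply(values, 2, assign_bands)
  } else {
    assign_bands(values)
  }
  dimnames(bands) <- dimnames(values)
  footer <- rbind(average = colMeans(values, na.rm = TRUE))
  if (kind == "rmsd") {
    footer <- rbind(footer,
      `n RMSD < threshold` = colSums(values < threshold, na.rm = TRUE))
  }
  bold_mask <- outer(rownames(values), colnames(values), "==")
  structure(list(values = values, footer = footer, bold_mask = bold_mask,
                 bands = bands, kind = kind, title = title,
                 threshold = threshold),
            class = "matrix_table")
}

#' @export
print.matrix_table <- function(x, digits = 2, ...) {
  cat(sprintf("<matrix_table> %s (%s)\n", x$title, x$kind))
  print(round(rbind(x$values, x$footer), digits))
  invisible(x)
}

result_matrix <- function(records, field, roots) {
  vals <- records[[field]]
  vals[records$failed] <- NA_real_
  m <- matrix(NA_real_, length(roots), length(roots),
              dimnames = list(ligand = roots, receptor = roots))
  m[cbind(match(records$ligand_root, roots),
          match(records$receptor_root, roots))] <- vals
  m
}

#' Build the report tables of a cross-docking run
#'
#' Produces the six result views: (1) the long-form table of every pose's
#' RMSD and energy; (2) the per-cell best-RMSD pose with its energy;
#' the four ligand-by-receptor matrices of (3) best RMSD, (4) best energy,
#' (5) RMSD of the best-energy pose, (6) energy of the best-RMSD pose.
#' Receptors are in columns, co-crystallised ligands in rows; the
#' self-docking diagonal carries a bold mask; RMSD matrices get footer
#' rows with the per-receptor average and the strict `< threshold`
#' success count; every matrix carries traffic-light percentile bands
#' (see [assign_bands()]).
#'
#' @param result A `crossdock_result`.
#' @param threshold Success cutoff (Angstrom, strict).
#' @param band_scope Pool band percentiles over the whole matrix
#'   (`"matrix"`, default) or per receptor column (`"column"`).
#' @return A `crossdock_tables` list: `output`, `output_best_rmsd`
#'   (tibbles) and four `matrix_table`s.
#' @export
build_tables <- function(result, threshold = 2.0,
                         band_scope = c("matrix", "column")) {
  band_scope <- match.arg(band_scope)
  rec <- result$records
  if (nrow(rec) == 0) {
    abort("empty cross-docking result", class = "crossdockr_report_error")
  }
  roots <- result$roots
  output <- rec |>
    dplyr::select("ligand_root", "receptor_root", "is_self_dock", "poses") |>
    tidyr::unnest("poses")
  ok <- !rec$failed
  output_best_rmsd <- tibble(
    ligand_root = rec$ligand_root[ok],
    receptor_root = rec$receptor_root[ok],
    best_rmsd = rec$best_rmsd[ok],
    energy = rec$best_rmsd_energy[ok],
    mode_index = rec$best_rmsd_mode[ok]
  )
  tables <- list(
    output = output,
    output_best_rmsd = output_best_rmsd,
    table_the_best_rmsd = new_matrix_table(
      result_matrix(rec, "best_rmsd", roots), "rmsd",
      "Best RMSD per dock (A)", threshold, band_scope),
    table_the_best_energy = new_matrix_table(
      result_matrix(rec, "best_energy", roots), "energy",
      "Best energy per dock (kcal/mol)", threshold, band_scope),
    table_rmsd_for_the_best_energy = new_matrix_table(
      result_matrix(rec, "best_energy_rmsd", roots), "rmsd",
      "RMSD of the best-energy pose (A)", threshold, band_scope),
    table_energy_for_the_best_rmsd = new_matrix_table(
      result_matrix(rec, "best_rmsd_energy", roots), "energy",
      "Energy of the best-RMSD pose (kcal/mol)", threshold, band_scope)
  )
  structure(tables, class = "crossdock_tables")
}

REPORT_FILES <- c(
  output = "Output",
  output_best_rmsd = "Output_the_best_RMSD",
  table_the_best_rmsd = "Table_the_best_RMSD",
  table_the_best_energy = "Table_the_best_energy",
  table_rmsd_for_the_best_energy = "Table_RMSD_for_the_best_energy",
  table_energy_for_the_best_rmsd = "Table_energy_for_the_best_RMSD"
)

matrix_table_frame <- function(mt) {
  df <- as.data.frame(mt$values)
  body <- cbind(ligand = rownames(mt$values), df)
  foot <- cbind(ligand = rownames(mt$footer), as.data.frame(mt$footer))
  out <- rbind(body, foot)
  rownames(out) <- NULL
  tibble::as_tibble(out)
}

atomic_write_csv <- function(df, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".csv")
  readr::write_csv(df, tmp, na = "")
  file.rename(tmp, path)
  invisible(path)
}

band_sidecar <- function(tables) {
  purrr::imap(tables, function(mt, nm) {
    if (!inherits(mt, "matrix_table")) return(NULL)
    b <- mt$bands
    tibble(
      table = REPORT_FILES[[nm]],
      ligand_root = rep(rownames(b), times = ncol(b)),
      receptor_root = rep(colnames(b), each = nrow(b)),
      band = as.vector(b)
    )
  }) |>
    dplyr::bind_rows()
}

#' Write the report files to disk
#'
#' Writes the six result files under their canonical names. CSV mirrors
#' (always written) carry full-precision values and are accompanied by a
#' `band_assignments.csv` sidecar with the traffic-light band of every
#' matrix cell. Spreadsheets (`.xlsx`) render values to two decimals with
#' green/yellow/red fills and a bold self-docking diagonal; they are
#' produced through a bundled openpyxl script and are skipped with a
#' warning when no `python` interpreter is on the PATH. Files are replaced
#' atomically (write-then-rename).
#'
#' @param tables A `crossdock_tables` from [build_tables()].
#' @param output_dir Output directory (created if needed).
#' @param formats Any of `"csv"`, `"xlsx"`.
#' @return Invisibly, a tibble of the files written.
#' @export
write_reports <- function(tables, output_dir, formats = c("xlsx", "csv")) {
  formats <- match.arg(formats, c("xlsx", "csv"), several.ok = TRUE)
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  if (file.access(output_dir, 2) != 0) {
    abort(paste0("output directory not writable: ", output_dir),
          class = "crossdockr_io_error")
  }
  written <- character()
  if ("csv" %in% formats) {
    for (nm in names(REPORT_FILES)) {
      path <- file.path(output_dir, paste0(REPORT_FILES[[nm]], ".csv"))
      obj <- tables[[nm]]
      df <- if (inherits(obj, "matrix_table")) matrix_table_frame(obj)
            else obj
      atomic_write_csv(df, path)
      written <- c(written, path)
    }
    side <- file.path(output_dir, "band_assignments.csv")
    atomic_write_csv(band_sidecar(tables), side)
    written <- c(written, side)
  }
  if ("xlsx" %in% formats) {
    written <- c(written, write_xlsx_reports(tables, output_dir))
  }
  invisible(tibble(file = written))
}

xlsx_payload <- function(tables, output_dir) {
  purrr::imap(tables, function(obj, nm) {
    file <- file.path(output_dir, paste0(REPORT_FILES[[nm]], ".xlsx"))
    if (inherits(obj, "matrix_table")) {
      df <- matrix_table_frame(obj)
      nr <- nrow(obj$values)
      bold <- which(obj$bold_mask, arr.ind = TRUE)
      fills <- which(!is.na(obj$bands) & obj$bands != "none",
                     arr.ind = TRUE)
      list(
        file = file,
        header = names(df),
        # rows as a list of lists; first cell label, rest numeric
        rows = purrr::pmap(df, function(...) list(...)),
        numeric_cols = seq(2, ncol(df)),
        bold = unname(apply(bold, 1, function(rc)
          c(rc[1] + 1, rc[2] + 1), simplify = FALSE)),
        fills = unname(apply(fills, 1, function(rc)
          list(row = rc[1] + 1, col = rc[2] + 1,
               band = obj$bands[rc[1], rc[2]]), simplify = FALSE)),
        n_body_rows = nr,
        number_format = "0.00"
      )
    } else {
      df <- obj
      list(file = file, header = names(df),
           rows = purrr::pmap(df, function(...) list(...)),
           numeric_cols = which(vapply(df, is.numeric, logical(1))),
           bold = list(), fills = list(), n_body_rows = nrow(df),
           number_format = "0.0000")
    }
  })
}

write_xlsx_reports <- function(tables, output_dir) {
  python <- Sys.which("python")
  if (!nzchar(python)) python <- Sys.which("python3")
  if (!nzchar(python)) {
    warn("no python interpreter found; spreadsheet output skipped (CSV mirrors still written)")
    return(character())
  }
  payload <- xlsx_payload(tables, output_dir)
  json_file <- tempfile(fileext = ".json")
  on.exit(unlink(json_file))
  jsonlite::write_json(unname(payload), json_file, auto_unbox = TRUE,
                       digits = NA, na = "null", null = "null")
  script <- system.file("python", "write_xlsx.py", package = "crossdockr")
  out <- suppressWarnings(system2(python, c(script, json_file),
                                  stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status") %||% 0L
  if (status != 0) {
    warn(paste0("spreadsheet writer failed (CSV mirrors unaffected):\n",
                paste(out, collapse = "\n")))
    return(character())
  }
  vapply(payload, function(p) p$file, character(1))
}

#' Write a reproducibility manifest
#'
#' Records everything needed to reproduce a run with the mock engine:
#' the docking parameters (including the global seed), the library roots,
#' box geometry and failure counts, plus the package version. The
#' manifest is deliberately timestamp-free so identical runs produce
#' byte-identical manifests.
#'
#' @param result A `crossdock_result`.
#' @param path Output JSON path.
#' @param config Optional configuration list echoed into the manifest.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(result, path, config = NULL) {
  manifest <- list(
    package = "crossdockr",
    version = as.character(utils::packageVersion("crossdockr")),
    roots = result$roots,
    n_cells = nrow(result$records),
    n_failed = sum(result$records$failed),
    box_size = result$box_size,
    box_center = result$box_center,
    params = unclass(result$params),
    cell_seeds = purrr::pmap_int(
      result$records[, c("ligand_root", "receptor_root")],
      function(ligand_root, receptor_root) {
        cell_seed(result$params$seed %||% 0L, ligand_root, receptor_root)
      }),
    config = config
  )
  tmp <- tempfile(tmpdir = dirname(path))
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  file.rename(tmp, path)
  invisible(path)
}
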