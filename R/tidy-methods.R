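#' Tidy a cross-docking result into a long pose table
#'
#' One row per scored pose: ligand, receptor, engine mode rank, predicted
#' energy (kcal/mol) and symmetry-corrected RMSD to the crystal pose
#' (Angstrom). This is the same long-form view the `Output` report file
#' carries.
#'
#' @param x A `crossdock_result`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.crossdock_result <- function(x, ...) {
  x$records |>
    dplyr::select("ligand_root", "receptor_root", "is_self_dock",
                  "failed", "poses") |>
    tidyr::unnest("poses")
}

#' One-row summary of a cross-docking run
#'
#' @param x A `crossdock_result`.
#' @param threshold Success cutoff (Angstrom, strict).
#' @param ... Unused.
#' @return A one-row tibble: grid dimensions, failed-cell count, mean
#'   self-docking RMSD, grid-wide mean best RMSD, and the total count of
#'   sub-threshold docks.
#' @export
glance.crossdock_result <- function(x, threshold = 2.0, ...) {
  rec <- x$records
  ok <- !rec$failed
  tibble(
    n_pairs = length(x$roots),
    n_cells = nrow(rec),
    n_failed = sum(rec$failed),
    mean_self_rmsd = mean(rec$best_rmsd[ok & rec$is_self_dock]),
    mean_best_rmsd = mean(rec$best_rmsd[ok]),
    n_success = sum(rec$best_rmsd[ok] < threshold),
    seed = x$params$seed %||% NA_integer_
  )
}

#' Heatmap of a cross-docking grid
#'
#' Receptors in columns, co-crystallised ligands in rows (the published
#' matrix orientation); self-docking cells are outlined. Low RMSD (or
#' energy) is the favourable end of the fill scale.
#'
#' @param object A `crossdock_result`.
#' @param value Which per-cell value to map: `"best_rmsd"`,
#'   `"best_energy_rmsd"` or `"best_energy"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.crossdock_result <- function(object,
                                      value = c("best_rmsd",
                                                "best_energy_rmsd",
                                                "best_energy"), ...) {
  value <- match.arg(value)
  rec <- object$records
  rec$ligand_root <- factor(rec$ligand_root, levels = rev(object$roots))
  rec$receptor_root <- factor(rec$receptor_root, levels = object$roots)
  lab <- c(best_rmsd = "best RMSD (Å)",
           best_energy_rmsd = "RMSD of best-energy pose (Å)",
           best_energy = "best energy (kcal/mol)")[[value]]
  ggplot2::ggplot(rec, ggplot2::aes(x = .data$receptor_root,
                                    y = .data$ligand_root,
                                    fill = .data[[value]])) +
    ggplot2::geom_tile(color = "grey30") +
    ggplot2::geom_tile(data = rec[rec$is_self_dock, ], fill = NA,
                       color = "black", linewidth = 1) +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f",
                                                    .data[[value]])),
                       size = 3, na.rm = TRUE) +
    ggplot2::scale_fill_gradient(low = "#2c7bb6", high = "#d7191c",
                                 na.value = "grey80", name = lab) +
    ggplot2::labs(x = "receptor", y = "co-crystallized ligand") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
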