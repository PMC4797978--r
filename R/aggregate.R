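#' Per-receptor summary statistics
#'
#' For each receptor column of the grid: the arithmetic mean of the
#' best-pose RMSDs, the count of docks with best RMSD strictly below the
#' success threshold (the conventional 2.0 Angstrom cutoff), and the same
#' two statistics for the best-energy pose selection. Means are taken over
#' the non-failed cells only, with the failed-cell count reported
#' alongside. Self-docking cells are included by default, as in the
#' published matrix layout where they are merely typographically bolded.
#'
#' @param result A `crossdock_result`.
#' @param threshold Success cutoff in Angstrom (strict `<`; default 2.0,
#'   so a dock at exactly 2.0 counts as a failure).
#' @param include_self Include the self-docking diagonal in means and
#'   counts (default `TRUE`).
#' @return A tibble with one row per receptor: `receptor_root`,
#'   `mean_best_rmsd`, `n_success`, `mean_bestenergy_rmsd`,
#'   `n_success_bestenergy`, `n_failed_cells`.
#' @export
summarize_receptors <- function(result, threshold = 2.0,
                                include_self = TRUE) {
  rec <- result$records
  if (!include_self) rec <- rec[!rec$is_self_dock, ]
  out <- rec |>
    dplyr::group_by(.data$receptor_root) |>
    dplyr::summarise(
      mean_best_rmsd = mean(.data$best_rmsd[!.data$failed]),
      n_success = sum(.data$best_rmsd[!.data$failed] < threshold),
      mean_bestenergy_rmsd = mean(.data$best_energy_rmsd[!.data$failed]),
      n_success_bestenergy =
        sum(.data$best_energy_rmsd[!.data$failed] < threshold),
      n_failed_cells = sum(.data$failed),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$receptor_root)
  bad <- is.nan(out$mean_best_rmsd)
  if (any(bad)) {
    abort(paste0("every cell failed for receptor(s): ",
                 paste(out$receptor_root[bad], collapse = ", "),
                 "; summary undefined"),
          class = "crossdockr_undefined_summary_error")
  }
  out
}

#' @rdname summarize_receptors
#' @param receptor_root A single receptor root present in the grid.
#' @export
summarize_receptor <- function(result, receptor_root, threshold = 2.0,
                               include_self = TRUE) {
  if (!receptor_root %in% result$roots) {
    abort(paste0("receptor not in grid: ", receptor_root),
          class = "crossdockr_run_error")
  }
  all_sum <- summarize_receptors(result, threshold, include_self)
  all_sum[all_sum$receptor_root == receptor_root, ]
}

#' Rank receptors for ensemble selection
#'
#' Orders the receptors by a selection criterion: structures with lower
#' average cross-docking RMSD and/or a higher count of sub-threshold docks
#' are the better candidates for pose prediction and virtual screening;
#' the best-energy-pose RMSD criterion reflects what a prospective screen
#' (which only sees the top-scored pose) would experience.
#'
#' @inheritParams summarize_receptors
#' @param criterion `"mean_best_rmsd"` (ascending), `"n_success"`
#'   (descending) or `"mean_bestenergy_rmsd"` (ascending).
#' @return The summary tibble ordered by the criterion, with the criterion
#'   recorded in attribute `"criterion"`. Ties break by the complementary
#'   statistic (success count for mean-based ranking, mean best RMSD for
#'   the count-based one), then lexicographically by root.
#' @export
rank_receptors <- function(result,
                           criterion = c("mean_best_rmsd", "n_success",
                                         "mean_bestenergy_rmsd"),
                           threshold = 2.0, include_self = TRUE) {
  criterion <- match.arg(criterion)
  s <- summarize_receptors(result, threshold, include_self)
  s <- switch(criterion,
    mean_best_rmsd = dplyr::arrange(s, .data$mean_best_rmsd,
                                    dplyr::desc(.data$n_success),
                                    .data$receptor_root),
    n_success = dplyr::arrange(s, dplyr::desc(.data$n_success),
                               .data$mean_best_rmsd, .data$receptor_root),
    mean_bestenergy_rmsd = dplyr::arrange(
      s, .data$mean_bestenergy_rmsd,
      dplyr::desc(.data$n_success_bestenergy), .data$receptor_root)
  )
  attr(s, "criterion") <- criterion
  s
}
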