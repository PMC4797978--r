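#' Run a full cross-docking grid
#'
#' For every ordered (ligand, receptor) pair of the library: the search box
#' is centered on the receptor's own co-crystallised ligand (or on the
#' incoming ligand with `box_center = "cross"`), the ligand conformation is
#' randomized with a per-cell seed, docked, and every returned pose is
#' scored by symmetry-corrected in-place RMSD against that ligand's crystal
#' pose. A failing cell is recorded with its diagnostic and the grid run
#' continues; only a grid where every cell failed is an error.
#'
#' Per-cell seeds are derived deterministically from the global seed and
#' the two root names, so grids are reproducible while cells stay
#' independent (and could be evaluated in any order with identical
#' results).
#'
#' @param library A `structure_library` from [build_library()].
#' @param engine A docking engine.
#' @param params [docking_params()]; `params$seed` is the global seed.
#' @param box_size Length-3 (or scalar) box edge lengths, Angstrom.
#' @param box_center `"native"` (receptor's own ligand defines the site)
#'   or `"cross"` (center on the incoming ligand).
#' @param max_mappings Automorphism cap passed to [symmetry_min_rmsd()].
#' @return A `crossdock_result`: list with `records` (one row per grid
#'   cell: roots, self-dock flag, scored pose table, best-RMSD and
#'   best-energy selections, failure info), `params`, `roots`, `box_size`.
#' @export
run_crossdock <- function(library, engine, params = docking_params(),
                          box_size = c(25, 25, 25),
                          box_center = c("native", "cross"),
                          max_mappings = 10000) {
  box_center <- match.arg(box_center)
  if (nrow(library) == 0) {
    abort("structure library is empty", class = "crossdockr_run_error")
  }
  if (length(box_size) == 1) box_size <- rep(box_size, 3)
  roots <- library$root
  ligands <- setNames(library$ligand, roots)
  receptors <- setNames(library$receptor, roots)
  grid <- tidyr::expand_grid(ligand_root = roots, receptor_root = roots)

  records <- purrr::pmap(grid, function(ligand_root, receptor_root) {
    seed <- cell_seed(params$seed %||% 0L, ligand_root, receptor_root)
    cell_params <- params
    cell_params$seed <- seed
    reference <- ligands[[ligand_root]]
    receptor <- receptors[[receptor_root]]
    center <- if (box_center == "native") {
      compute_box_center(ligands[[receptor_root]])
    } else {
      compute_box_center(reference)
    }
    box <- grid_box(center, box_size)
    tryCatch({
      start <- reference
      if (isTRUE(params$randomize_first)) {
        start <- randomize_ligand(engine, reference, receptor, box,
                                  seed = seed)
      }
      res <- dock(engine, receptor, start, box, cell_params)
      scored <- score_poses(res$poses, reference, max_mappings)
      c(list(failed = FALSE, fail_reason = NA_character_,
             poses = list(scored)),
        best_selections(scored))
    }, error = function(e) {
      list(failed = TRUE, fail_reason = conditionMessage(e),
           poses = list(empty_pose_table()),
           best_rmsd = NA_real_, best_rmsd_energy = NA_real_,
           best_rmsd_mode = NA_integer_,
           best_energy = NA_real_, best_energy_rmsd = NA_real_,
           best_energy_mode = NA_integer_)
    })
  })

  records <- dplyr::bind_cols(grid, dplyr::bind_rows(
    purrr::map(records, ~ tibble::as_tibble_row(.x))))
  records$is_self_dock <- records$ligand_root == records$receptor_root
  records <- records[, c("ligand_root", "receptor_root", "is_self_dock",
                         "failed", "fail_reason", "poses",
                         "best_rmsd", "best_rmsd_energy", "best_rmsd_mode",
                         "best_energy", "best_energy_rmsd",
                         "best_energy_mode")]
  if (all(records$failed)) {
    abort(paste0("every grid cell failed; first diagnostic: ",
                 records$fail_reason[1]),
          class = "crossdockr_run_error")
  }
  structure(list(records = records, params = params, roots = roots,
                 box_size = box_size, box_center = box_center),
            class = "crossdock_result")
}

empty_pose_table <- function() {
  tibble(mode_index = integer(), energy = double(), rmsd = double(),
         symmetry_corrected = logical())
}

score_poses <- function(poses, reference, max_mappings = 10000) {
  scored <- purrr::map(poses$coords, function(xyz) {
    symmetry_min_rmsd(reference, xyz, max_mappings = max_mappings)
  })
  tibble(mode_index = poses$mode_index,
         energy = poses$energy,
         rmsd = purrr::map_dbl(scored, "value"),
         symmetry_corrected = purrr::map_lgl(scored, "symmetry_corrected"))
}

best_selections <- function(scored) {
  br <- select_best_rmsd(scored)
  be <- select_best_energy(scored)
  list(best_rmsd = br$rmsd, best_rmsd_energy = br$energy,
       best_rmsd_mode = br$mode_index,
       best_energy = be$energy, best_energy_rmsd = be$rmsd,
       best_energy_mode = be$mode_index)
}

#' Best-RMSD pose of a dock
#'
#' The pose minimizing RMSD to the crystal reference; ties break toward
#' the lower (better-ranked) mode index.
#'
#' @param poses A scored pose table (`mode_index`, `energy`, `rmsd`).
#' @return One-row tibble with `rmsd`, `energy`, `mode_index`.
#' @export
select_best_rmsd <- function(poses) {
  if (nrow(poses) == 0) {
    abort("dock record contains no poses", class = "crossdockr_empty_record_error")
  }
  poses <- poses[order(poses$mode_index), ]
  k <- which.min(poses$rmsd)
  tibble(rmsd = poses$rmsd[k], energy = poses$energy[k],
         mode_index = poses$mode_index[k])
}

#' Best-energy pose of a dock
#'
#' The pose minimizing predicted binding energy, carrying its own RMSD —
#' this is the pose a prospective virtual screen would actually pick, and
#' it may differ from the best-RMSD pose. Ties break toward the lower mode
#' index.
#'
#' @inheritParams select_best_rmsd
#' @return One-row tibble with `energy`, `rmsd`, `mode_index`.
#' @export
select_best_energy <- function(poses) {
  if (nrow(poses) == 0) {
    abort("dock record contains no poses", class = "crossdockr_empty_record_error")
  }
  poses <- poses[order(poses$mode_index), ]
  k <- which.min(poses$energy)
  tibble(energy = poses$energy[k], rmsd = poses$rmsd[k],
         mode_index = poses$mode_index[k])
}

# Deterministic 31-bit per-cell seed from the global seed and both roots.
cell_seed <- function(global_seed, ligand_root, receptor_root) {
  s <- paste0(ligand_root, "|", receptor_root)
  h <- 0
  for (code in utf8ToInt(s)) h <- (h * 31 + code) %% 2147483647
  as.integer((h + as.numeric(global_seed)) %% 2147483647)
}

#' @export
print.crossdock_result <- function(x, ...) {
  n <- length(x$roots)
  cat(sprintf(
    "<crossdock_result> %d x %d grid (%d cells, %d failed), engine seed %s\n",
    n, n, nrow(x$records), sum(x$records$failed),
    x$params$seed %||% "unset"))
  invisible(x)
}

#' Save / load a cross-docking result
#'
#' Docking is the expensive step; the scored grid is persisted as JSON so
#' reports can be rebuilt without re-docking.
#'
#' @param result A `crossdock_result`.
#' @param path JSON file path.
#' @return `path` invisibly; `load_crossdock()` returns the restored
#'   `crossdock_result`.
#' @export
save_crossdock <- function(result, path) {
  payload <- list(
    roots = result$roots,
    box_size = result$box_size,
    box_center = result$box_center,
    params = unclass(result$params),
    records = purrr::pmap(result$records, function(...) {
      cell <- list(...)
      cell$poses <- as.data.frame(cell$poses)
      cell
    })
  )
  # I(17) significant digits: doubles survive the JSON round trip exactly
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       null = "null", na = "null")
  invisible(path)
}

#' @rdname save_crossdock
#' @export
load_crossdock <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  params <- payload$params
  params$randomize_first <- isTRUE(params$randomize_first)
  class(params) <- "docking_params"
  records <- dplyr::bind_rows(purrr::map(payload$records, function(cell) {
    poses <- purrr::map(cell$poses, ~ tibble::as_tibble_row(.x))
    poses <- if (length(poses) > 0) dplyr::bind_rows(poses) else
      empty_pose_table()
    tibble::as_tibble_row(c(
      lapply(cell[setdiff(names(cell), "poses")],
             function(v) if (is.null(v)) NA else v),
      list(poses = list(poses))
    ))
  }))
  records <- records[, c("ligand_root", "receptor_root", "is_self_dock",
                         "failed", "fail_reason", "poses",
                         "best_rmsd", "best_rmsd_energy", "best_rmsd_mode",
                         "best_energy", "best_energy_rmsd",
                         "best_energy_mode")]
  structure(list(records = records, params = params,
                 roots = unlist(payload$roots),
                 box_size = unlist(payload$box_size),
                 box_center = payload$box_center),
            class = "crossdock_result")
}
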