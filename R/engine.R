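#' Docking search box
#'
#' The rectangular search volume handed to the engine: a center and edge
#' lengths, all in Angstrom.
#'
#' @param center Numeric length-3 center (x, y, z).
#' @param size Numeric length-3 edge lengths; every component must be
#'   positive. A scalar is recycled.
#' @return A `grid_box`.
#' @export
grid_box <- function(center, size) {
  center <- as.numeric(center)
  size <- as.numeric(size)
  if (length(size) == 1) size <- rep(size, 3)
  if (length(center) != 3 || length(size) != 3 ||
      !all(is.finite(c(center, size)))) {
    abort("center and size must be finite length-3 vectors",
          class = "crossdockr_config_error")
  }
  if (any(size <= 0)) {
    abort("all grid box dimensions must be positive",
          class = "crossdockr_config_error")
  }
  structure(list(center = center, size = size), class = "grid_box")
}

#' Docking run parameters
#'
#' Defaults reproduce a stock AutoDock Vina run: exhaustiveness 8 (the
#' engine's search-effort knob), up to 9 binding modes.
#'
#' @param exhaustiveness Positive integer search effort (default 8).
#' @param num_modes Positive integer: maximum binding modes per dock.
#' @param energy_range Optional nonnegative kcal/mol window around the best
#'   pose that the engine may report.
#' @param seed Optional integer engine seed; forwarded for reproducibility.
#' @param randomize_first Randomize the ligand conformation before docking
#'   to avoid bias toward the crystal conformation (default `TRUE`).
#' @return A `docking_params` list.
#' @export
docking_params <- function(exhaustiveness = 8L, num_modes = 9L,
                           energy_range = NULL, seed = NULL,
                           randomize_first = TRUE) {
  if (exhaustiveness < 1 || num_modes < 1) {
    abort("exhaustiveness and num_modes must be positive integers",
          class = "crossdockr_config_error")
  }
  if (!is.null(energy_range) && energy_range < 0) {
    abort("energy_range must be nonnegative",
          class = "crossdockr_config_error")
  }
  structure(list(exhaustiveness = as.integer(exhaustiveness),
                 num_modes = as.integer(num_modes),
                 energy_range = energy_range,
                 seed = if (!is.null(seed)) as.integer(seed),
                 randomize_first = isTRUE(randomize_first)),
            class = "docking_params")
}

#' Grid-box center from a bound ligand
#'
#' The unweighted centroid of the ligand's heavy atoms. Cross-docking runs
#' center each receptor's search box on its own co-crystallised ligand;
#' since the family shares one aligned frame this pins the box on the
#' binding site for every incoming ligand.
#'
#' @param native_ligand A [molecule] with at least one heavy atom.
#' @return Numeric length-3 centroid (Angstrom).
#' @export
#' @examples
#' lig <- molecule(data.frame(name = c("C1", "C2"), element = "C",
#'                            x = c(0, 2), y = 0, z = 0))
#' compute_box_center(lig)  # c(1, 0, 0)
compute_box_center <- function(native_ligand) {
  xyz <- coords(native_ligand, heavy_only = TRUE)
  if (nrow(xyz) == 0) {
    abort("ligand has no heavy atoms; cannot place the grid box",
          class = "crossdockr_empty_structure_error")
  }
  unname(colMeans(xyz))
}

#' Dock a ligand into a receptor
#'
#' Engine-dispatched. Every adapter returns a `docking_result`: a pose
#' table sorted by energy ascending (at most `num_modes` rows), the engine
#' name, and the engine's text log.
#'
#' @param engine A docking engine ([mock_engine()] or [vina_engine()]).
#' @param receptor,ligand [molecule]s.
#' @param box A [grid_box()].
#' @param params A [docking_params()].
#' @return A `docking_result` with `poses` (tibble: `mode_index`, `energy`
#'   in kcal/mol, `coords` list-column of heavy-atom coordinate matrices),
#'   `engine_name`, `log`.
#' @export
dock <- function(engine, receptor, ligand, box, params = docking_params()) {
  UseMethod("dock")
}

#' Randomize a ligand conformation
#'
#' Produces a starting conformation with randomized position and
#' orientation inside the search box, removing bias toward the crystal
#' pose. Atom identity and order are preserved; the returned molecule is
#' the heavy-atom representation the engine will dock.
#'
#' @inheritParams dock
#' @param seed Integer seed; the same seed gives the same conformation.
#' @return A [molecule].
#' @export
randomize_ligand <- function(engine, ligand, receptor, box, seed = NULL) {
  UseMethod("randomize_ligand")
}

new_docking_result <- function(poses, engine_name, log = "") {
  if (nrow(poses) == 0) {
    abort("engine returned no poses", class = "crossdockr_engine_error")
  }
  if (is.unsorted(poses$energy)) {
    abort("pose energies must be nondecreasing with mode index",
          class = "crossdockr_engine_error")
  }
  structure(list(poses = poses, engine_name = engine_name, log = log),
            class = "docking_result")
}

#' @export
print.docking_result <- function(x, ...) {
  cat(sprintf("<docking_result> %s: %d pose(s), energies [%.2f, %.2f]\n",
              x$engine_name, nrow(x$poses), min(x$poses$energy),
              max(x$poses$energy)))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Mock engine

#' Deterministic mock docking engine
#'
#' A pure function of its inputs and the seed, for testing the whole
#' pipeline without a docking binary. Poses are planted at known RMSD from
#' the crystal reference: each pose is the reference ligand translated by a
#' seeded random direction times a specified offset, so its in-place RMSD
#' equals the offset exactly (a uniform translation leaves the identity
#' mapping optimal, so this survives symmetry correction too).
#'
#' @param reference Optional `structure_library` (or named list of
#'   [molecule]s) providing crystal reference ligands by root; when absent
#'   the incoming ligand itself anchors the planted poses.
#' @param truth Optional per-cell plant table: a tibble with columns
#'   `ligand_root`, `receptor_root`, `offsets` (list of Angstrom
#'   displacements) and `energies` (list of kcal/mol, same lengths).
#'   Cells absent from the table fall back to seeded defaults.
#' @param n_poses Poses per dock when generating defaults.
#' @param base_energy Default energy model intercept: a generated pose at
#'   offset d gets energy `base_energy + d` kcal/mol, so better geometry
#'   scores better.
#' @param max_offset Largest default offset (Angstrom).
#' @return A `mock_engine`.
#' @export
mock_engine <- function(reference = NULL, truth = NULL, n_poses = 3L,
                        base_energy = -10, max_offset = 4) {
  ref_list <- NULL
  if (!is.null(reference)) {
    if (inherits(reference, "structure_library")) {
      ref_list <- setNames(reference$ligand, reference$root)
    } else {
      ref_list <- reference
    }
  }
  structure(list(reference = ref_list, truth = truth,
                 n_poses = as.integer(n_poses), base_energy = base_energy,
                 max_offset = max_offset),
            class = c("mock_engine", "docking_engine"))
}

mock_cell_plant <- function(engine, ligand_root, receptor_root, seed) {
  if (!is.null(engine$truth)) {
    hit <- engine$truth$ligand_root == ligand_root &
      engine$truth$receptor_root == receptor_root
    if (any(hit)) {
      k <- which(hit)[1]
      return(list(offsets = as.numeric(engine$truth$offsets[[k]]),
                  energies = as.numeric(engine$truth$energies[[k]])))
    }
  }
  withr::with_seed(seed, {
    offsets <- sort(stats::runif(engine$n_poses, 0, engine$max_offset))
    list(offsets = offsets, energies = engine$base_energy + offsets)
  })
}

#' @rdname dock
#' @export
dock.mock_engine <- function(engine, receptor, ligand, box,
                             params = docking_params()) {
  ref_mol <- engine$reference[[ligand$name]] %||% ligand
  ref_xyz <- coords(ref_mol, heavy_only = TRUE)
  seed <- params$seed %||% 0L
  plant <- mock_cell_plant(engine, ligand$name, receptor$name, seed)
  stopifnot(length(plant$offsets) == length(plant$energies))
  dirs <- withr::with_seed(seed + 1L, {
    lapply(seq_along(plant$offsets), function(i) random_unit_vector())
  })
  poses <- tibble(
    energy = plant$energies,
    coords = purrr::map2(plant$offsets, dirs, function(d, u) {
      sweep(ref_xyz, 2, d * u, "+")
    })
  )
  poses <- poses[order(poses$energy), ]
  poses <- head(poses, params$num_modes)
  poses$mode_index <- seq_len(nrow(poses))
  poses <- poses[, c("mode_index", "energy", "coords")]
  new_docking_result(poses, "mock",
                     log = sprintf("mock dock %s into %s (seed %d)",
                                   ligand$name, receptor$name, seed))
}

random_unit_vector <- function() {
  repeat {
    v <- stats::rnorm(3)
    nv <- sqrt(sum(v^2))
    if (nv > 1e-12) return(v / nv)
  }
}

#' @rdname randomize_ligand
#' @export
randomize_ligand.mock_engine <- function(engine, ligand, receptor, box,
                                         seed = NULL) {
  lig_h <- heavy_atoms(ligand)
  xyz <- coords(lig_h)
  withr::with_seed(seed %||% 0L, {
    rot <- random_rotation_matrix()
    target <- box$center + stats::runif(3, -0.5, 0.5) * box$size
  })
  centroid <- colMeans(xyz)
  new_xyz <- sweep(sweep(xyz, 2, centroid) %*% rot, 2, target, "+")
  set_coords(lig_h, new_xyz)
}

random_rotation_matrix <- function() {
  qr_dec <- qr(matrix(stats::rnorm(9), 3))
  q <- qr.Q(qr_dec)
  q * sign(det(q))  # proper rotation
}

# ---------------------------------------------------------------------------
# AutoDock Vina adapter

#' AutoDock Vina adapter
#'
#' Shells out to a Vina executable: inputs are converted to pdbqt with Open
#' Babel when needed, a per-cell work directory with the engine's config
#' file is written, and the output pdbqt (MODEL blocks with
#' `REMARK VINA RESULT` energy lines) is parsed back into poses. The
#' conformational search and scoring are entirely Vina's.
#'
#' @param path Path to the Vina executable.
#' @param converter Path to the Open Babel executable used for pdbqt
#'   conversion.
#' @param work_dir Root directory for per-cell work directories; defaults
#'   to a session temp directory.
#' @return A `vina_engine`.
#' @export
vina_engine <- function(path = Sys.which("vina"),
                        converter = Sys.which("obabel"),
                        work_dir = NULL) {
  structure(list(path = path, converter = converter,
                 work_dir = work_dir %||% tempfile("vina_work_")),
            class = c("vina_engine", "docking_engine"))
}

check_vina_available <- function(engine) {
  if (is.null(engine$path) || !nzchar(engine$path) ||
      !file.exists(engine$path)) {
    abort("AutoDock Vina executable not found; set vina_engine(path = ...)",
          class = "crossdockr_configuration_error")
  }
}

ensure_pdbqt <- function(engine, mol, dir, tag, receptor = FALSE) {
  out <- file.path(dir, paste0(tag, ".pdbqt"))
  if (identical(mol$source_format, "pdbqt")) {
    write_structure(mol, out)
    return(out)
  }
  src_fmt <- if (is.na(mol$source_format)) "pdb" else mol$source_format
  src <- file.path(dir, paste0(tag, ".", src_fmt))
  write_structure(mol, src, format = src_fmt)
  if (!nzchar(engine$converter)) {
    abort("pdbqt conversion needs Open Babel; set vina_engine(converter=...)",
          class = "crossdockr_configuration_error")
  }
  args <- c(src, "-O", out, if (receptor) c("-xr"))
  status <- suppressWarnings(
    system2(engine$converter, args, stdout = TRUE, stderr = TRUE))
  if (!file.exists(out)) {
    abort(paste0("pdbqt conversion failed:\n",
                 paste(status, collapse = "\n")),
          class = "crossdockr_engine_error")
  }
  out
}

write_vina_config <- function(dir, receptor_file, ligand_file, box, params,
                              out_file, randomize_only = FALSE) {
  lines <- c(
    paste0("receptor = ", receptor_file),
    paste0("ligand = ", ligand_file),
    sprintf("center_x = %.3f", box$center[1]),
    sprintf("center_y = %.3f", box$center[2]),
    sprintf("center_z = %.3f", box$center[3]),
    sprintf("size_x = %.3f", box$size[1]),
    sprintf("size_y = %.3f", box$size[2]),
    sprintf("size_z = %.3f", box$size[3]),
    paste0("out = ", out_file)
  )
  if (!randomize_only) {
    lines <- c(lines,
               paste0("exhaustiveness = ", params$exhaustiveness),
               paste0("num_modes = ", params$num_modes),
               if (!is.null(params$energy_range))
                 paste0("energy_range = ", params$energy_range))
  }
  if (!is.null(params$seed)) lines <- c(lines, paste0("seed = ", params$seed))
  cfg <- file.path(dir, "config.txt")
  writeLines(lines, cfg)
  cfg
}

run_vina <- function(engine, cfg, extra = character()) {
  out <- suppressWarnings(
    system2(engine$path, c("--config", cfg, extra),
            stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status") %||% 0L
  if (status != 0) {
    abort(paste0("Vina exited with status ", status, ":\n",
                 paste(out, collapse = "\n")),
          class = "crossdockr_engine_error")
  }
  paste(out, collapse = "\n")
}

#' @rdname dock
#' @export
dock.vina_engine <- function(engine, receptor, ligand, box,
                             params = docking_params()) {
  check_vina_available(engine)
  dir <- file.path(engine$work_dir,
                   paste0(ligand$name, "_into_", receptor$name))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rec_file <- ensure_pdbqt(engine, receptor, dir, "receptor",
                           receptor = TRUE)
  lig_file <- ensure_pdbqt(engine, ligand, dir, "ligand")
  out_file <- file.path(dir, "out.pdbqt")
  cfg <- write_vina_config(dir, rec_file, lig_file, box, params, out_file)
  log <- run_vina(engine, cfg)
  poses <- parse_vina_poses(out_file)
  poses <- head(poses[order(poses$energy), ], params$num_modes)
  poses$mode_index <- seq_len(nrow(poses))
  new_docking_result(poses[, c("mode_index", "energy", "coords")],
                     "vina", log = log)
}

#' @rdname randomize_ligand
#' @export
randomize_ligand.vina_engine <- function(engine, ligand, receptor, box,
                                         seed = NULL) {
  check_vina_available(engine)
  dir <- file.path(engine$work_dir, paste0("randomize_", ligand$name))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rec_file <- ensure_pdbqt(engine, receptor, dir, "receptor",
                           receptor = TRUE)
  lig_file <- ensure_pdbqt(engine, ligand, dir, "ligand")
  out_file <- file.path(dir, "randomized.pdbqt")
  params <- docking_params(seed = seed)
  cfg <- write_vina_config(dir, rec_file, lig_file, box, params, out_file,
                           randomize_only = TRUE)
  run_vina(engine, cfg, extra = "--randomize_only")
  out <- read_structure(out_file, name = ligand$name)
  heavy_atoms(out)
}

#' Parse a Vina multi-model pose file
#'
#' Reads the pdbqt written by Vina's `--out`: one `MODEL` block per binding
#' mode, each carrying a `REMARK VINA RESULT: <energy> <rmsd_lb> <rmsd_ub>`
#' line. Only the predicted binding energy (first number) and the
#' heavy-atom coordinates are retained.
#'
#' @param path Path to the pose pdbqt (or a character vector of its lines).
#' @return Tibble with `mode_index`, `energy` (kcal/mol) and `coords`
#'   (list of heavy-atom coordinate matrices).
#' @export
parse_vina_poses <- function(path) {
  lines <- if (length(path) == 1 && file.exists(path)) {
    readLines(path, warn = FALSE)
  } else {
    as.character(path)
  }
  starts <- grep("^MODEL", lines)
  if (length(starts) == 0) {
    # Single-model output (e.g. randomize_only): treat the file as one block
    starts <- 1L
    ends <- length(lines)
  } else {
    ends <- c(starts[-1] - 1L, length(lines))
  }
  blocks <- purrr::map2(starts, ends, function(s, e) lines[s:e])
  poses <- purrr::imap(blocks, function(block, k) {
    remark <- grep("^REMARK VINA RESULT:", block, value = TRUE)
    energy <- if (length(remark) > 0) {
      as.numeric(strsplit(sub("^REMARK VINA RESULT:\\s*", "", remark[1]),
                          "\\s+")[[1]][1])
    } else {
      NA_real_
    }
    mol <- parse_pdbqt_atoms(block, paste0("pose_", k))
    if (n_atoms(mol) == 0) {
      abort("pose block contains no atoms", class = "crossdockr_parse_error")
    }
    list(energy = energy, coords = coords(mol, heavy_only = TRUE))
  })
  tibble(
    mode_index = seq_along(poses),
    energy = purrr::map_dbl(poses, "energy"),
    coords = purrr::map(poses, "coords")
  )
}
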