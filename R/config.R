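CONFIG_KEYS <- c(
  "receptor_dir", "ligand_dir", "output_dir",
  "size_x", "size_y", "size_z",
  "num_modes", "exhaustiveness", "energy_range", "seed",
  "engine", "engine_path",
  "success_threshold", "include_self_in_averages", "band_scope",
  "box_center", "water_residues"
)

#' Parse a run configuration file
#'
#' The configuration is a plain-text `key = value` file; `#` starts a
#' comment, blank lines are ignored, unknown keys are rejected with a
#' listing. `receptor_dir` and `ligand_dir` are mandatory; everything else
#' has a default reproducing a stock run: a 25 Angstrom cubic search box,
#' exhaustiveness 8, up to 9 binding modes, success threshold 2.0
#' Angstrom (strict), self-docks included in averages, matrix-pooled
#' percentile bands, box centered on each receptor's native ligand.
#'
#' @param path Path to the configuration file.
#' @return A `run_config` list.
#' @export
parse_config <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("config file not found: ", path),
          class = "crossdockr_config_error")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- lines[grepl("=", lines)]
  keys <- sub("^\\s*([^=]*?)\\s*=.*$", "\\1", lines)
  vals <- sub("^[^=]*=\\s*", "", lines)
  vals <- sub("\\s+$", "", vals)
  unknown <- setdiff(keys, CONFIG_KEYS)
  if (length(unknown) > 0) {
    abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", "),
                 "; known keys: ", paste(CONFIG_KEYS, collapse = ", ")),
          class = "crossdockr_config_error")
  }
  if (anyDuplicated(keys)) {
    abort(paste0("duplicate config key(s): ",
                 paste(unique(keys[duplicated(keys)]), collapse = ", ")),
          class = "crossdockr_config_error")
  }
  raw <- setNames(as.list(vals), keys)
  get_num <- function(key, default) {
    if (is.null(raw[[key]])) return(default)
    v <- suppressWarnings(as.numeric(raw[[key]]))
    if (is.na(v)) {
      abort(paste0("config key '", key, "' is not numeric: ", raw[[key]]),
            class = "crossdockr_config_error")
    }
    v
  }
  get_bool <- function(key, default) {
    if (is.null(raw[[key]])) return(default)
    tolower(raw[[key]]) %in% c("true", "yes", "1")
  }
  for (mandatory in c("receptor_dir", "ligand_dir")) {
    if (is.null(raw[[mandatory]])) {
      abort(paste0("mandatory config key missing: ", mandatory),
            class = "crossdockr_config_error")
    }
  }
  cfg <- list(
    receptor_dir = raw$receptor_dir,
    ligand_dir = raw$ligand_dir,
    output_dir = raw$output_dir %||% "crossdock_output",
    size_x = get_num("size_x", 25),
    size_y = get_num("size_y", 25),
    size_z = get_num("size_z", 25),
    num_modes = as.integer(get_num("num_modes", 9)),
    exhaustiveness = as.integer(get_num("exhaustiveness", 8)),
    energy_range = if (!is.null(raw$energy_range))
      get_num("energy_range", NULL),
    seed = if (!is.null(raw$seed)) as.integer(get_num("seed", NULL)),
    engine = match.arg(raw$engine %||% "vina", c("vina", "mock")),
    engine_path = raw$engine_path %||% "",
    success_threshold = get_num("success_threshold", 2.0),
    include_self_in_averages = get_bool("include_self_in_averages", TRUE),
    band_scope = match.arg(raw$band_scope %||% "matrix",
                           c("matrix", "column")),
    box_center = match.arg(raw$box_center %||% "native",
                           c("native", "cross")),
    water_residues = if (!is.null(raw$water_residues)) {
      strsplit(raw$water_residues, "\\s*,\\s*")[[1]]
    } else {
      c("HOH", "WAT", "H2O", "DOD")
    }
  )
  if (any(c(cfg$size_x, cfg$size_y, cfg$size_z) <= 0)) {
    abort("grid box sizes must be positive",
          class = "crossdockr_config_error")
  }
  if (cfg$success_threshold <= 0) {
    abort("success_threshold must be positive",
          class = "crossdockr_config_error")
  }
  if (cfg$num_modes < 1 || cfg$exhaustiveness < 1) {
    abort("num_modes and exhaustiveness must be positive integers",
          class = "crossdockr_config_error")
  }
  structure(cfg, class = "run_config")
}

#' Serialize a run configuration
#'
#' Writes a `key = value` file that [parse_config()] reads back to an
#' equal configuration.
#'
#' @param config A `run_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  fmt <- function(key) {
    v <- config[[key]]
    if (is.null(v)) return(NULL)
    if (is.logical(v)) v <- ifelse(v, "true", "false")
    if (key == "water_residues") v <- paste(v, collapse = ",")
    paste0(key, " = ", v)
  }
  lines <- unlist(lapply(CONFIG_KEYS, fmt))
  writeLines(lines, path)
  invisible(path)
}

#' Build the engine a configuration asks for
#'
#' @param config A `run_config`.
#' @param library Optional `structure_library`; the mock engine plants its
#'   poses relative to this library's crystal ligands.
#' @return A docking engine.
#' @export
engine_from_config <- function(config, library = NULL) {
  if (config$engine == "mock") {
    mock_engine(reference = library)
  } else {
    path <- if (nzchar(config$engine_path)) config$engine_path
            else Sys.which("vina")
    vina_engine(path = path)
  }
}
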