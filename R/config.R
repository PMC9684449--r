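## Study configuration: YAML-backed with all defaults materialized to the
## study conditions (2 mA, 10 mm motor ROI, standard conductivities).

#' Default study configuration
#'
#' @param ... Named overrides of the defaults.
#' @return Object of class `study_config` (named list): `n_subjects`, `seed`,
#'   `voxel_size_mm`, `current_mA`, `conductivities`, `montages`,
#'   `roi_label`, `roi_radius_mm`, `level_fraction`, `peak_percentile`,
#'   `p99_mask`, `solver_tol`, `variability`, `out_dir`.
#' @export
study_config <- function(...) {
  cfg <- list(
    n_subjects = 20L,
    seed = 1L,
    voxel_size_mm = 2,
    current_mA = 2,
    conductivities = as.list(default_conductivities()),
    montages = unique(montage_catalog()$name),
    roi_label = "C3",
    roi_radius_mm = 10,
    level_fraction = 0.5,
    peak_percentile = 99.9,
    p99_mask = c(4L, 5L),
    solver_tol = 1e-8,
    variability = list(),
    out_dir = "tdcsim-results"
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("config error: unknown field(s) ", paste(bad, collapse = ", "))
  cfg <- modifyList(cfg, over)
  validate_config(cfg)
}

validate_config <- function(cfg) {
  chk <- function(cond, field, msg) {
    if (!cond) stop("config error: field '", field, "' ", msg)
  }
  chk(is.numeric(cfg$voxel_size_mm) && cfg$voxel_size_mm > 0,
      "voxel_size_mm", "must be > 0")
  chk(is.numeric(cfg$current_mA) && cfg$current_mA > 0, "current_mA", "must be > 0")
  chk(cfg$n_subjects >= 0, "n_subjects", "must be >= 0")
  chk(cfg$roi_radius_mm > 0, "roi_radius_mm", "must be > 0")
  chk(cfg$level_fraction > 0 && cfg$level_fraction <= 1,
      "level_fraction", "must be in (0, 1]")
  chk(cfg$peak_percentile > 0 && cfg$peak_percentile <= 100,
      "peak_percentile", "must be in (0, 100]")
  chk(all(unlist(cfg$conductivities) > 0), "conductivities", "must be > 0")
  chk(all(c("skin", "skull", "csf", "gm", "wm") %in% names(cfg$conductivities)),
      "conductivities", "must name skin, skull, csf, gm, wm")
  chk(all(cfg$montages %in% montage_catalog()$name), "montages",
      "contains unknown montage names")
  chk(is.numeric(cfg$solver_tol) && cfg$solver_tol > 0, "solver_tol", "must be > 0")
  cfg$p99_mask <- as.integer(cfg$p99_mask)
  cfg$n_subjects <- as.integer(cfg$n_subjects)
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "study_config")
}

#' Load a study configuration from YAML
#'
#' Fields absent from the file take the standard study defaults (2 mA,
#' 10 mm ROI, standard conductivities). An empty file yields the full default
#' configuration.
#'
#' @param path YAML file path.
#' @return Validated `study_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config error: file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  do.call(study_config, raw)
}

#' Save a study configuration as YAML
#'
#' @param cfg A `study_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  out <- unclass(cfg)
  out$p99_mask <- as.integer(out$p99_mask)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Write a study table (plus provenance) to a results directory
#'
#' Writes `study_table.csv`, a units sidecar, and the exact configuration
#' used (`config.yaml`).
#'
#' @param table A study table.
#' @param cfg The `study_config` that produced it.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study_results <- function(table, cfg, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(table, file.path(dir, "study_table.csv"), row.names = FALSE)
  units <- data.frame(
    column = c("roi_mean", "p99_mean", "focality_mm3", "peak_offset_mm",
               "edge_distance_cm"),
    unit = c("V/m", "V/m", "mm^3", "mm", "cm"))
  write.csv(units, file.path(dir, "units.csv"), row.names = FALSE)
  save_config(cfg, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Read a study table written by [write_study_results()]
#' @param dir Results directory.
#' @return A `study_table`.
#' @export
read_study_results <- function(dir) {
  tab <- read.csv(file.path(dir, "study_table.csv"), stringsAsFactors = FALSE)
  class(tab) <- c("study_table", "data.frame")
  tab
}
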