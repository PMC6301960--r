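#' Read and validate a run configuration
#'
#' Run configurations are YAML key-value trees with four blocks:
#' `membrane` (either `preset: "#255"` or the [membrane_spec()] fields),
#' `lifecycle` ([lifecycle_params()] overrides), `force` ([force_params()]
#' overrides) and `run` (`T_total_h`, `snapshot_every_h`, `seed`,
#' `stem_spacing_um`, `out_dir`). Validation errors name the offending field
#' path before any computation starts.
#'
#' @param path path to a YAML file.
#' @return a validated config list of class `epiderm_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_config(cfg)
}

#' @rdname read_run_config
#' @param cfg a raw config list (as parsed from YAML).
#' @export
validate_config <- function(cfg) {
  if (!is.list(cfg)) stop("config must be a key-value tree")
  mem <- cfg$membrane
  if (is.null(mem)) stop("config$membrane is required")
  spec <- tryCatch({
    if (!is.null(mem$preset)) {
      membrane_preset(mem$preset,
                      domain_um = mem$domain_x_um %||% 300)
    } else {
      do.call(membrane_spec, mem)
    }
  }, error = function(e) stop("config$membrane: ", conditionMessage(e),
                              call. = FALSE))
  lp <- tryCatch(do.call(lifecycle_params, cfg$lifecycle %||% list()),
                 error = function(e) stop("config$lifecycle: ",
                                          conditionMessage(e), call. = FALSE))
  fp <- tryCatch(do.call(force_params, cfg$force %||% list()),
                 error = function(e) stop("config$force: ",
                                          conditionMessage(e), call. = FALSE))
  run <- cfg$run %||% list()
  run$T_total_h <- run$T_total_h %||% 500
  run$snapshot_every_h <- run$snapshot_every_h %||% 25
  run$seed <- as.integer(run$seed %||% 1L)
  run$stem_spacing_um <- run$stem_spacing_um %||% 10
  if (run$T_total_h < 0) stop("config$run$T_total_h must be >= 0")
  if (run$snapshot_every_h <= 0) stop("config$run$snapshot_every_h must be > 0")
  structure(list(spec = spec, lp = lp, fp = fp, run = run,
                 raw = cfg), class = "epiderm_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Provenance hash of a configuration
#'
#' MD5 digest of the canonical JSON serialisation of the run configuration,
#' recorded in run manifests so outputs can be traced to their inputs.
#'
#' @param cfg an `epiderm_config` (or any serialisable list).
#' @return a hex string.
#' @export
config_hash <- function(cfg) {
  if (inherits(cfg, "epiderm_config")) cfg <- cfg$raw
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

#' Run a simulation from a validated configuration
#'
#' @param cfg an `epiderm_config` from [read_run_config()], or a path to a
#'   YAML config file.
#' @param seed optional override of the config seed.
#' @return an `epiderm_trajectory` (with the config hash attached).
#' @export
run_simulation <- function(cfg, seed = NULL) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  stopifnot(inherits(cfg, "epiderm_config"))
  traj <- simulate_epidermis(cfg$spec, lp = cfg$lp, fp = cfg$fp,
                             T_total_h = cfg$run$T_total_h,
                             snapshot_every_h = cfg$run$snapshot_every_h,
                             seed = seed %||% cfg$run$seed,
                             stem_spacing_um = cfg$run$stem_spacing_um)
  traj$config_hash <- config_hash(cfg)
  traj
}

#' Write trajectory snapshots and a run manifest to disk
#'
#' One CSV per snapshot (columns id, x, y, z, a, c, state, age_in_state, ca;
#' comma-separated, header row, '.' decimal) plus `manifest.json` with the
#' configuration echo, its hash, and the per-snapshot counters.
#'
#' @param traj an `epiderm_trajectory`.
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
write_snapshots <- function(traj, dir) {
  stopifnot(inherits(traj, "epiderm_trajectory"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (i in seq_along(traj$snapshots)) {
    s <- traj$snapshots[[i]]
    path <- file.path(dir, sprintf("snapshot_%05.0fh.csv", s$t))
    cols <- c("id", "x", "y", "z", "a", "c", "state", "age_in_state", "ca")
    write.csv(s$cells[, cols], path, row.names = FALSE, quote = FALSE)
    paths <- c(paths, path)
  }
  manifest <- list(
    membrane = unclass(traj$spec), lifecycle = unclass(traj$lp),
    force = unclass(traj$fp), seed = traj$seed,
    stem_spacing_um = traj$stem_spacing_um,
    config_hash = traj$config_hash %||% config_hash(list(
      membrane = unclass(traj$spec), lifecycle = unclass(traj$lp),
      force = unclass(traj$fp), seed = traj$seed)),
    counters = traj$counters, snapshots = basename(paths))
  mpath <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(c(paths, mpath))
}

#' Read a snapshot CSV back into a `sim_state`
#'
#' The tabular snapshot format does not carry stem anchors; anchors are
#' reconstructed from the stem positions (stems rest at their anchor at
#' mechanical equilibrium). Counters unknown from a bare CSV are zero.
#'
#' @param path a snapshot CSV written by [write_snapshots()].
#' @return a `sim_state`.
#' @export
read_snapshot <- function(path) {
  cells <- read.csv(path, stringsAsFactors = FALSE)
  if (nrow(cells) > 0 && is.null(cells$anchor_x)) {
    stems <- cells$state == "STEM"
    cells$anchor_x <- ifelse(stems, cells$x, NA_real_)
    cells$anchor_y <- ifelse(stems, cells$y, NA_real_)
  }
  sim_state(cells)
}
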