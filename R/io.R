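#' Read a run configuration
#'
#' Loads and validates a YAML (or JSON, via yaml) configuration describing
#' a processing run.  The `geometry` block is mandatory with keys
#' `n_slow`, `n_fast`, `pixel_size_mm`, `distance_mm`, `beam_centre_px`
#' (length 2) and `wavelength_A`.  Optional blocks: `model`
#' (`min_images`, `median_window`, `diffusion_tol`, `n_az`, `valid_frac`),
#' `fit` (`c_tune`, `max_iter`, `tol`), `simulate` (passed to the
#' simulator), `paths` (`out_dir`, ...).  Defaults follow the algorithm's
#' stated defaults: `min_images` 10, `median_window` 10, Huber `c_tune` 3.
#' Validation errors name the offending key.
#'
#' @param path Path to a YAML file.
#' @return A list of class `run_config` with `geometry` already converted
#'   to a [detector_geometry()].
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_run_config(cfg)
}

#' @rdname read_run_config
#' @param cfg A raw configuration list (as parsed from YAML).
#' @export
validate_run_config <- function(cfg) {
  if (is.null(cfg$geometry))
    stop("config error: missing required block 'geometry'", call. = FALSE)
  g <- cfg$geometry
  for (key in c("n_slow", "n_fast", "pixel_size_mm", "distance_mm",
                "beam_centre_px", "wavelength_A")) {
    if (is.null(g[[key]]))
      stop("config error: missing geometry key '", key, "'", call. = FALSE)
  }
  if (length(g$beam_centre_px) != 2)
    stop("config error: geometry key 'beam_centre_px' must have 2 elements",
         call. = FALSE)
  geom <- detector_geometry(g$n_slow, g$n_fast, g$pixel_size_mm,
                            g$distance_mm, unlist(g$beam_centre_px),
                            g$wavelength_A)
  model <- utils::modifyList(
    list(min_images = 10L, median_window = 10L, diffusion_tol = 1e-6,
         n_az = 360L, valid_frac = 0.5),
    if (is.null(cfg$model)) list() else cfg$model)
  fit <- utils::modifyList(list(c_tune = 3, max_iter = 100L, tol = 1e-6),
                           if (is.null(cfg$fit)) list() else cfg$fit)
  structure(list(geometry = geom, model = model, fit = fit,
                 simulate = cfg$simulate, paths = cfg$paths),
            class = "run_config")
}

# geometry fingerprint: the parameter values themselves (no hashing
# dependency); cross-artefact checks compare them exactly
geometry_fingerprint <- function(geom) {
  unclass(geom)
}

check_geometry_match <- function(a, b, what = "artefact") {
  if (!isTRUE(all.equal(geometry_fingerprint(a), geometry_fingerprint(b))))
    stop("geometry mismatch: ", what,
         " was produced with a different detector geometry", call. = FALSE)
  invisible(TRUE)
}

#' Persist and restore a background model
#'
#' The model is stored as a single R data stream (RDS) holding the
#' background array, validity mask, pixel-statistics images (mean,
#' variance, dispersion), the build parameters and the detector geometry,
#' so a write/read round trip is lossless and any later operation can
#' verify the geometry it was built with.
#'
#' @param model A `background_model`.
#' @param path Output file path.
#' @return `write_background_model` returns `path` invisibly;
#'   `read_background_model` returns the `background_model`.
#' @export
write_background_model <- function(model, path) {
  stopifnot(inherits(model, "background_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname write_background_model
#' @export
read_background_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "background_model"))
    stop("data error: ", path, " does not contain a background model",
         call. = FALSE)
  model
}

#' Reflection-table I/O
#'
#' Reflection tables (one row per integrated reflection, as produced by
#' [integrate_shoeboxes()]) are written as plain CSV.
#'
#' @param table A data frame.
#' @param path CSV path.
#' @return `write_reflection_table` returns `path` invisibly;
#'   `read_reflection_table` the data frame.
#' @export
write_reflection_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_reflection_table
#' @export
read_reflection_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Pipeline commands
#'
#' Thin composition of the package stages used by the command-line front
#' end (and convenient from scripts): `cmd_simulate` generates a stack from
#' the config's `simulate` block, `cmd_model` builds and persists the
#' global background model (logging a count-conservation check),
#' `cmd_integrate` integrates the stack's shoeboxes with both the global
#' model and the flat baseline, and `cmd_diagnose` writes diagnostic
#' summaries.
#'
#' @param config A `run_config` (see [read_run_config()]).
#' @param sim A `sim_stack` from [cmd_simulate()] / [simulate_stack()].
#' @param out_dir Output directory (created if needed).
#' @param model_path Path of a persisted model (defaults inside `out_dir`).
#' @param quiet Suppress progress messages.
#' @return `cmd_simulate`: the `sim_stack`; `cmd_model`: the
#'   `background_model` (written to `model_path`); `cmd_integrate`: the
#'   reflection table (written to `reflections.csv`); `cmd_diagnose`: a
#'   list of diagnostic objects (series written as CSV).
#' @export
cmd_simulate <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  s <- config$simulate
  if (is.null(s)) stop("config error: missing block 'simulate'", call. = FALSE)
  preset <- if (!is.null(s$preset)) s$preset else "clean"
  cfg <- default_presets(preset,
                         n_images = if (is.null(s$n_images)) 40L else s$n_images,
                         seed = if (is.null(s$seed)) 1L else s$seed)
  if (!quiet) message("simulating preset '", preset, "' (",
                      cfg$n_images, " images)")
  simulate_stack(cfg)
}

#' @rdname cmd_simulate
#' @export
cmd_model <- function(config, sim, out_dir = ".", quiet = FALSE) {
  stopifnot(inherits(config, "run_config"), inherits(sim, "sim_stack"))
  check_geometry_match(config$geometry, sim$config$geometry, "stack")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  geom <- config$geometry
  mp <- config$model
  grid <- polar_grid(geom, n_az = mp$n_az)
  fractions <- pixel_overlap_fractions(geom, grid)
  # stage log: count conservation through the forward transform
  stats <- accumulate_mean(sim$stack, min_images = mp$min_images)
  mean_img <- stats$mean
  mean_img[is.na(mean_img)] <- 0
  usable <- stats$usable & !is.na(stats$mean)
  p <- polar_transform(mean_img, usable, fractions,
                       valid_frac = mp$valid_frac)
  on_grid <- logical(length(mean_img))
  on_grid[fractions$pixel] <- TRUE
  in_total <- sum(mean_img[usable & on_grid])
  out_total <- sum(p$values)
  ok <- abs(out_total - in_total) <= 1e-6 * max(in_total, 1)
  if (!quiet)
    message(sprintf("polar transform conservation: in %.6g, out %.6g [%s]",
                    in_total, out_total, if (ok) "PASS" else "FAIL"))
  model <- build_global_model(sim$stack, geom, min_images = mp$min_images,
                              median_window = mp$median_window,
                              diffusion_tol = mp$diffusion_tol,
                              fractions = fractions,
                              valid_frac = mp$valid_frac)
  model$provenance$conservation_pass <- ok
  path <- file.path(out_dir, "background_model.rds")
  write_background_model(model, path)
  if (!quiet) message("model written to ", path)
  model
}

#' @rdname cmd_simulate
#' @export
cmd_integrate <- function(config, sim, model_path = NULL, out_dir = ".",
                          quiet = FALSE) {
  stopifnot(inherits(config, "run_config"), inherits(sim, "sim_stack"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  model <- if (is.character(model_path)) read_background_model(model_path)
           else model_path
  stopifnot(inherits(model, "background_model"))
  check_geometry_match(config$geometry, model$geom, "model")
  check_geometry_match(config$geometry, sim$config$geometry, "stack")
  cfg <- robust_config(config$fit$c_tune, config$fit$max_iter,
                       config$fit$tol)
  tab <- integrate_shoeboxes(sim$shoeboxes, model, config$geometry,
                             cfg = cfg)
  path <- file.path(out_dir, "reflections.csv")
  write_reflection_table(tab, path)
  if (!quiet) message(nrow(tab), " reflections written to ", path)
  tab
}

#' @rdname cmd_simulate
#' @param table A reflection table from [cmd_integrate()].
#' @param model A `background_model` (for the dispersion report).
#' @export
cmd_diagnose <- function(config, table, model = NULL, out_dir = ".",
                         quiet = FALSE) {
  stopifnot(inherits(config, "run_config"), is.data.frame(table))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- list()
  out$ivr_global <- intensity_vs_resolution(table$d, table$I_global,
                                            table$var_I_global)
  out$ivr_flat <- intensity_vs_resolution(table$d, table$I_flat,
                                          table$var_I_flat)
  utils::write.csv(as.data.frame(out$ivr_global),
                   file.path(out_dir, "intensity_vs_resolution_global.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(out$ivr_flat),
                   file.path(out_dir, "intensity_vs_resolution_flat.csv"),
                   row.names = FALSE)
  if (!is.null(model) && !is.null(model$statistics)) {
    out$dispersion <- dispersion_report(model$statistics, config$geometry)
    utils::write.csv(out$dispersion$by_resolution,
                     file.path(out_dir, "dispersion_by_resolution.csv"),
                     row.names = FALSE)
  }
  if (!quiet) message("diagnostics written to ", out_dir)
  invisible(out)
}
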