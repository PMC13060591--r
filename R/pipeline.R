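## Configuration handling, the end-to-end simulation pipeline, and run
## provenance.

#' Default run configuration
#'
#' All parameters of the simulation with their default values: chip
#' geometry, 100 x 100 grid, 200 V / 10 ms / 10-pulse protocol with 65%
#' of nanochannels open, membrane constants (-70 / -55 / -200 mV, 1 ms
#' refractory, 120 m/s, 600 channels/um^2), material conductivities,
#' Gaussian smoothing sigma, transfection-efficiency distribution, and
#' stage seeds.
#'
#' @return Nested named list (class `run_config`).
#' @export
default_config <- function() {
  structure(list(
    chip = list(microchannel_width = 150, microchannel_depth = 185,
                nanochannel_width = 0.9, nanochannel_depth = 11,
                cone_base = 4, cone_height = 4.5,
                n_nanochannels = 20L, pitch = 8, wafer_thickness = 200),
    grid = list(n_rows = 100L, n_cols = 100L, extent_x = 160, extent_y = 160),
    protocol = list(voltage = 200, pulse_duration = 10, n_pulses = 10L,
                    inter_pulse_gap = 100),
    membrane = list(v_rest = -70, v_ap_threshold = -55,
                    v_poration_threshold = 200, refractory = 1,
                    conduction_velocity = 120, na_channel_density = 600,
                    coupling_radius = 5),
    materials = as.list(default_conductivities()),
    smoothing = list(sigma = 1),
    transfection = list(open_fraction = 0.65, mean_efficiency = 0.6,
                        sd_efficiency = 0.15),
    seeds = list(geometry = 1L, transfection = 2L)
  ), class = "run_config")
}

merge_config <- function(base, user, path = "") {
  for (nm in names(user)) {
    full <- if (path == "") nm else paste0(path, ".", nm)
    if (!nm %in% names(base)) {
      stop_input(sprintf("validation error: unknown configuration key '%s'",
                         full))
    }
    if (is.list(base[[nm]])) {
      if (!is.list(user[[nm]])) {
        stop_input(sprintf("validation error: '%s' must be a block", full))
      }
      base[[nm]] <- merge_config(base[[nm]], user[[nm]], full)
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

validate_config <- function(config) {
  chk <- function(value, field, lower = -Inf, upper = Inf) {
    if (!is.numeric(value) || length(value) != 1 || !is.finite(value) ||
        value < lower || value > upper) {
      stop_input(sprintf(
        "validation error: field '%s' = %s is out of range [%g, %g]",
        field, format(value), lower, upper))
    }
  }
  chk(config$protocol$voltage, "protocol.voltage", 0)
  chk(config$protocol$pulse_duration, "protocol.pulse_duration", 1e-9)
  chk(config$protocol$n_pulses, "protocol.n_pulses", 1)
  chk(config$grid$n_rows, "grid.n_rows", 2)
  chk(config$grid$n_cols, "grid.n_cols", 2)
  chk(config$grid$extent_x, "grid.extent_x", 1e-9)
  chk(config$grid$extent_y, "grid.extent_y", 1e-9)
  chk(config$transfection$open_fraction, "transfection.open_fraction", 0, 1)
  chk(config$transfection$mean_efficiency, "transfection.mean_efficiency", 0, 1)
  chk(config$transfection$sd_efficiency, "transfection.sd_efficiency", 0)
  chk(config$smoothing$sigma, "smoothing.sigma", 0)
  chk(config$membrane$refractory, "membrane.refractory", 1e-12)
  chk(config$membrane$coupling_radius, "membrane.coupling_radius", 1e-12)
  for (nm in names(config$materials)) {
    chk(config$materials[[nm]], paste0("materials.", nm), 0)
  }
  config
}

#' Load and validate a run configuration
#'
#' Reads a YAML (or JSON, which YAML subsumes) configuration file,
#' fills omitted fields with the defaults of [default_config()], rejects
#' unknown keys, and range-checks every field. An empty file yields the
#' all-defaults configuration.
#'
#' @param path Path to a YAML/JSON configuration file.
#' @return A validated `run_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop_input("configuration file not found: ", path)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  cfg <- merge_config(unclass(default_config()), user)
  validate_config(structure(cfg, class = "run_config"))
}

#' Save a run configuration as YAML
#'
#' @param config A `run_config`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(unclass(config), tmp)
  unname(tools::md5sum(tmp))
}

write_map_csv <- function(m, path) {
  utils::write.table(m, path, sep = ",", row.names = FALSE, col.names = FALSE)
}

#' Run the full simulation pipeline
#'
#' Executes geometry build, potential solve, field magnitude, Gaussian
#' smoothing, membrane-potential mapping, poration thresholding,
#' stochastic transfection and summary, in that order. When `out_dir` is
#' given, writes the potential, smoothed-field, membrane-potential,
#' poration and transfection maps as CSV plus a JSON summary and run
#' record with the configuration hash and seeds (sufficient to
#' regenerate every output bit-exactly).
#'
#' @param config A `run_config` (default: [default_config()]).
#' @param out_dir Optional output directory.
#' @return An object of class `tnt_run_record`: list with `config_hash`,
#'   `package_version`, `seeds`, `summary` (see
#'   [summarize_simulation()]), `stages` (per-stage scalars), `files`
#'   (written paths, if any) and `timestamp`.
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL) {
  config <- validate_config(structure(
    merge_config(unclass(default_config()), unclass(config)),
    class = "run_config"))

  chip <- do.call(chip_spec, config$chip)
  grid <- do.call(grid_spec, config$grid)
  protocol <- do.call(pulse_protocol, config$protocol)
  mem <- do.call(membrane_params, config$membrane)

  mg <- build_geometry(chip, grid,
                       open_fraction = config$transfection$open_fraction,
                       seed = config$seeds$geometry)
  cg <- conductivity_map(mg, props = config$materials)
  bc <- boundary_conditions(voltage = protocol$voltage,
                            anode_rows = grid$n_rows, cathode_rows = 1L)
  phi <- solve_potential(cg, bc)
  fld <- field_magnitude(phi)
  sm <- smooth_field(fld, sigma_smooth = config$smoothing$sigma)

  guard <- ceiling(4 * config$smoothing$sigma) + 1L
  tissue <- tissue_domain(mg, guard = guard)
  vm <- induced_vm(sm, mem, tissue)
  por <- poration_map(vm, mem, tissue)
  trans <- transfection_map(por,
                            mean_eff = config$transfection$mean_efficiency,
                            sd_eff = config$transfection$sd_efficiency,
                            seed = config$seeds$transfection)
  summ <- summarize_simulation(por, trans, tissue, field = sm, vm = vm)

  files <- character(0)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    maps <- list(potential = phi$phi, field_smoothed = sm$values,
                 vm = vm$vm, poration = por$porated * 1L,
                 transfection = trans$realized * 1L)
    for (nm in names(maps)) {
      p <- file.path(out_dir, paste0(nm, ".csv"))
      write_map_csv(maps[[nm]], p)
      files <- c(files, p)
    }
    p <- file.path(out_dir, "summary.json")
    jsonlite::write_json(unclass(summ), p, auto_unbox = TRUE, digits = NA)
    files <- c(files, p)
  }

  record <- structure(list(
    config_hash = config_hash(config),
    package_version = as.character(utils::packageVersion("tntsim")),
    seeds = config$seeds,
    summary = summ,
    stages = list(solver_residual = phi$residual,
                  n_open_channels = length(mg$open_channels),
                  poration_threshold_field_vpm = por$threshold_field),
    files = files,
    timestamp = format(Sys.time(), tz = "UTC")
  ), class = "tnt_run_record")

  if (!is.null(out_dir)) {
    rec_json <- record
    rec_json$summary <- unclass(rec_json$summary)
    jsonlite::write_json(unclass(rec_json),
                         file.path(out_dir, "run_record.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  record
}

#' Print a pipeline run record
#'
#' @param x A `tnt_run_record`.
#' @param ... Unused.
#' @return `x`, invisibly.
#' @exportS3Method base::print
print.tnt_run_record <- function(x, ...) {
  cat("TNT simulation run\n")
  cat("  config hash:     ", x$config_hash, "\n", sep = "")
  cat("  porated cells:   ", x$summary$n_porated,
      sprintf(" (%.1f%% of tissue)", 100 * x$summary$porated_fraction), "\n",
      sep = "")
  cat("  realized cells:  ", x$summary$n_realized,
      sprintf(" (%.1f%% of porated)", 100 * x$summary$realized_fraction),
      "\n", sep = "")
  cat("  max tissue field:", sprintf(" %.3g V/m", x$summary$max_field_vpm),
      "\n", sep = "")
  invisible(x)
}
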