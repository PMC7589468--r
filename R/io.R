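#' Load a device description from YAML
#'
#' Device configs are YAML with keys `name`, `arrangement` and a `beds`
#' list whose entries carry explicit unit suffixes:
#' `{length_mm, width_mm, depth_um, pillar_shape, pillar_size_um,
#' pillar_spacing_um, n_pillars}`. Two device fixtures ship with the
#' package (see [evcapture_fixture()]): a 3-bed serial chip with circular
#' 100 um pillars and a 7-bed parallel (z-configuration) chip with
#' diamond 10 um pillars.
#'
#' @param path Path to a YAML device file.
#' @return A `device_geometry`.
#' @export
load_device_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  for (key in c("name", "arrangement", "beds")) {
    if (is.null(raw[[key]])) {
      stop("device config is missing required key `", key, "`", call. = FALSE)
    }
  }
  bed_keys <- c("length_mm", "width_mm", "depth_um", "pillar_shape",
                "pillar_size_um", "pillar_spacing_um", "n_pillars")
  beds <- purrr::imap(raw$beds, function(b, i) {
    missing <- setdiff(bed_keys, names(b))
    if (length(missing)) {
      stop("bed ", i, " is missing required key `", missing[1], "`",
           call. = FALSE)
    }
    extra <- setdiff(names(b), bed_keys)
    if (length(extra)) {
      stop("bed ", i, " has unknown key `", extra[1],
           "` (units must use the documented suffixes)", call. = FALSE)
    }
    bed_geometry(b$length_mm, b$width_mm, b$depth_um, b$pillar_shape,
                 b$pillar_size_um, b$pillar_spacing_um, b$n_pillars)
  })
  device_geometry(beds, raw$arrangement, raw$name)
}

#' Load a kinetics parameterization from YAML
#'
#' Keys mirror [kinetics_params()]: `mode`,
#' `intrinsic_on_rate_cm2_per_pmol_s`, `encounter_radius_nm`,
#' `mab_density_pmol_cm2`, `antigens_per_ev`, `wall_density_multiplier`,
#' `p_encounter`, `provenance`.
#'
#' @param path Path to a YAML kinetics file.
#' @return A `kinetics_params`.
#' @export
load_kinetics_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw$mode)) {
    stop("kinetics config is missing required key `mode`", call. = FALSE)
  }
  kinetics_params(
    mode = raw$mode,
    intrinsic_on_rate = raw$intrinsic_on_rate_cm2_per_pmol_s,
    encounter_radius_nm = raw$encounter_radius_nm %||% 75,
    mab_density_pmol_cm2 = raw$mab_density_pmol_cm2 %||% 4.0,
    antigens_per_ev = raw$antigens_per_ev %||% 10,
    wall_density_multiplier = raw$wall_density_multiplier %||% 1.0,
    p_encounter = raw$p_encounter,
    provenance = raw$provenance
  )
}

#' Paths to packaged fixtures
#'
#' @param name One of `"evmap_3bed"`, `"evmap_7bed"`,
#'   `"chang_hammer_kinetics"`.
#' @return The installed path of the fixture file.
#' @examples
#' load_device_config(evcapture_fixture("evmap_7bed"))
#' @export
evcapture_fixture <- function(name = c("evmap_3bed", "evmap_7bed",
                                       "chang_hammer_kinetics")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".yaml"),
                      package = "evcapture", mustWork = TRUE)
  path
}

#' Small self-contained test configurations
#'
#' Toy device/transport/kinetics triples with analytically known
#' behaviour, used for fast checks:
#' * `"absorbing_channel"`: a single-gap channel with perfectly
#'   absorbing walls under plug flow; capture matches the closed-form
#'   eigenfunction series of [slab_survival()].
#' * `"no_binding"`: zero intrinsic rate; recovery is exactly 0.
#' * `"single_gap"`: one 10 um gap with moderate kinetics; a fast smoke
#'   configuration.
#'
#' @param name Fixture name.
#' @return A list with elements `device`, `ctx`, `kin` and `cfg`.
#' @export
make_toy_fixture <- function(name = c("absorbing_channel", "no_binding",
                                      "single_gap")) {
  name <- tryCatch(match.arg(name),
                   error = function(e) stop("unknown toy fixture name",
                                            call. = FALSE))
  # one pillar gap, 2 mm long, shallow bed; n_pillars = 1 keeps the
  # open-width fraction at spacing/(spacing + size)
  bed <- bed_geometry(2, 0.1, 50, "circular", 10, 10, 1)
  device <- device_geometry(bed, "serial", paste0("toy-", name))
  # absorbing_channel runs slow enough that D t_res / gap^2 ~ 0.9 and
  # essentially every particle reaches a wall before the outlet
  ctx <- transport_context(if (name == "absorbing_channel") 0.01 else 0.05)
  kin <- switch(name,
    absorbing_channel = kinetics_params("per_encounter", p_encounter = 1,
                                        encounter_radius_nm = 1),
    no_binding = kinetics_params("rate", intrinsic_on_rate = 0),
    single_gap = kinetics_params("rate", intrinsic_on_rate = 0.05)
  )
  cfg <- simulation_config(
    n_particles_per_batch = 1000, max_batches = 10, seed = 1,
    convergence_halfwidth = 0.02,
    launch = if (name == "absorbing_channel") "uniform" else "flux",
    profile = if (name == "absorbing_channel") "plug" else "poiseuille"
  )
  list(device = device, ctx = ctx, kin = kin, cfg = cfg)
}

sweep_csv_columns <- c("flow_ul_min", "recovery", "ci_low", "ci_high",
                       "n_bound", "n_lost", "batches", "converged")

#' Write simulation results with a run record
#'
#' Serializes a `recovery_result` or `sweep_result` to CSV (fixed column
#' order, see Details) or JSON, and writes a JSON run record next to the
#' data file (same path with extension `.run.json`) holding the
#' configuration snapshot, seed, package version and timestamps — enough
#' to re-execute the run bit-identically.
#'
#' CSV columns for sweeps: `flow_ul_min, recovery, ci_low, ci_high,
#' n_bound, n_lost, batches, converged`.
#'
#' @param x A `recovery_result` or `sweep_result`.
#' @param path Output file path.
#' @param format `"csv"` or `"json"`.
#' @return Invisibly, a manifest tibble naming the files written.
#' @export
write_results <- function(x, path, format = c("csv", "json")) {
  format <- match.arg(format)
  tbl <- generics::tidy(x)
  if (format == "csv") {
    ok <- tryCatch({
      utils::write.csv(as.data.frame(tbl), path, row.names = FALSE)
      TRUE
    }, error = function(e) {
      stop("failed to write `", path, "`: ", conditionMessage(e),
           call. = FALSE)
    })
  } else {
    jsonlite::write_json(tbl, path, auto_unbox = TRUE, digits = NA)
  }
  record_path <- paste0(sub("\\.(csv|json)$", "", path), ".run.json")
  cfg <- if (inherits(x, "sweep_result")) x$config else x$config
  record <- list(
    written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    package = "evcapture",
    version = as.character(utils::packageVersion("evcapture")),
    seed = cfg$seed,
    config = cfg[setdiff(names(cfg), "dt")],
    dt = cfg$dt,
    outputs = basename(path)
  )
  jsonlite::write_json(record, record_path, auto_unbox = TRUE, digits = NA,
                       null = "null", force = TRUE)
  invisible(tibble::tibble(file = c(path, record_path),
                           kind = c(format, "run_record")))
}

#' Read back a results table written by [write_results()]
#'
#' @param path Path to the CSV or JSON data file.
#' @return A tibble.
#' @export
read_results <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (grepl("\\.json$", path)) {
    tibble::as_tibble(jsonlite::fromJSON(path))
  } else {
    tibble::as_tibble(utils::read.csv(path))
  }
}
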