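# Reproducible end-to-end pipeline: configuration, file formats, manifest.
#
# Formats are all plain text: JSON-lines for scan records (arrays inline),
# CSV for the truth sidecar and every result table, YAML for the run
# configuration, JSON for the manifest.

#' Pipeline run configuration
#'
#' Collects every knob of the simulate -> invert -> QC pipeline with its
#' default, so a dumped configuration file fully documents a run.
#'
#' @param master_seed integer master seed for all randomness.
#' @param noise_rel relative detector noise amplitude.
#' @param beta gas-mixing carry-over fraction.
#' @param n_tracheal,n_dermal configurations per illumination arm.
#' @param replicates replicates per configuration and concentration.
#' @param concentrations nominal O2 fractions in administration order.
#' @param temperature,pressure,relative_humidity ambient gas conditions.
#' @param snr_threshold inversion validity threshold.
#' @param outlier_low,outlier_high pathlength outlier bounds, metres.
#' @param n_dark configurations forced below the detectability floor.
#' @param out_dir output directory for [run_pipeline()].
#' @return an object of class `gasmas_run_config` (a named list).
#' @export
run_config <- function(master_seed = 1L, noise_rel = 1e-5, beta = 0,
                       n_tracheal = 15L, n_dermal = 15L, replicates = 21L,
                       concentrations = c(0.21, 0.30, 0.50, 1.00),
                       temperature = 293, pressure = 101325,
                       relative_humidity = 1,
                       snr_threshold = 3, outlier_low = 0,
                       outlier_high = 0.23, n_dark = 2L,
                       out_dir = "gasmas_run") {
  cfg <- list(
    master_seed = as.integer(master_seed), noise_rel = noise_rel,
    beta = beta, n_tracheal = as.integer(n_tracheal),
    n_dermal = as.integer(n_dermal), replicates = as.integer(replicates),
    concentrations = concentrations,
    conditions = list(temperature = temperature, pressure = pressure,
                      relative_humidity = relative_humidity),
    snr_threshold = snr_threshold,
    outlier_low = outlier_low, outlier_high = outlier_high,
    n_dark = as.integer(n_dark), out_dir = out_dir
  )
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  stopifnot(is.list(cfg))
  required <- c("master_seed", "noise_rel", "beta", "n_tracheal", "n_dermal",
                "replicates", "concentrations", "conditions",
                "snr_threshold", "outlier_low", "outlier_high", "n_dark",
                "out_dir")
  missing <- setdiff(required, names(cfg))
  if (length(missing) > 0) {
    stop("run configuration misses field(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (cfg$noise_rel < 0) stop("noise_rel must be >= 0.", call. = FALSE)
  if (cfg$beta < 0 || cfg$beta >= 1) {
    stop("beta must lie in [0, 1).", call. = FALSE)
  }
  if (cfg$outlier_low >= cfg$outlier_high) {
    stop("outlier_low must be below outlier_high.", call. = FALSE)
  }
  # validates temperature/pressure/RH ranges
  do.call(ambient_conditions, cfg$conditions)
  structure(cfg, class = "gasmas_run_config")
}

#' @export
print.gasmas_run_config <- function(x, ...) {
  cat(sprintf(
    "<gasmas_run_config> seed %d, %d+%d configs x %d reps x %d conc, noise %g, beta %g\n",
    x$master_seed, x$n_tracheal, x$n_dermal, x$replicates,
    length(x$concentrations), x$noise_rel, x$beta))
  invisible(x)
}

#' Write / read a run configuration file
#'
#' YAML round trip of a [run_config()]; reading validates every field.
#'
#' @param config a `gasmas_run_config`.
#' @param path file path.
#' @return `write_run_config()` returns `path` invisibly; `read_run_config()`
#'   returns the validated configuration.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "gasmas_run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  cfg$concentrations <- as.numeric(unlist(cfg$concentrations))
  validate_run_config(cfg)
}

scan_record_fields <- c("config_id", "replicate", "channel", "o2_nominal",
                        "o2_effective", "detuning", "intensity",
                        "seed_used", "clipped")

#' Write / read a simulated dataset
#'
#' Scan records go to one JSON-lines file (`scans.jsonl`, one record per
#' line with the detuning and intensity arrays inline, 15+ significant
#' digits); the truth sidecar goes to `truth.csv`. A long-format CSV export
#' of the scans (`scans_long.csv`) is written as well.
#'
#' @param dataset a `gasmas_dataset` from [simulate_experiment()].
#' @param dir output directory (created if needed).
#' @param long_csv also write the long-format scan CSV.
#' @return invisibly, the paths written.
#' @export
write_dataset <- function(dataset, dir, long_csv = TRUE) {
  stopifnot(inherits(dataset, "gasmas_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  scans_path <- file.path(dir, "scans.jsonl")
  truth_path <- file.path(dir, "truth.csv")
  scans <- dataset$scans
  lines <- vapply(seq_len(nrow(scans)), function(i) {
    jsonlite::toJSON(
      list(config_id = scans$config_id[i],
           replicate = scans$replicate[i],
           channel = scans$channel[i],
           o2_nominal = scans$o2_nominal[i],
           o2_effective = scans$o2_effective[i],
           detuning = scans$detuning[[i]],
           intensity = scans$intensity[[i]],
           seed_used = scans$seed_used[i],
           clipped = scans$clipped[i]),
      auto_unbox = TRUE, digits = NA)
  }, character(1))
  writeLines(lines, scans_path)
  truth <- dataset$truth
  truth_out <- tibble::tibble(
    config_id = truth$config_id, geometry = truth$geometry,
    illumination = truth$illumination,
    detector_position = truth$detector_position, side = truth$side,
    phantom_props = truth$phantom_props,
    true_pathlength_m = truth$true_pathlength_m,
    o2_nominal = truth$o2_nominal, o2_effective = truth$o2_effective,
    tissue_transmission = truth$tissue_transmission, seed = truth$seed
  )
  readr::write_csv(truth_out, truth_path)
  paths <- c(scans = scans_path, truth = truth_path)
  if (long_csv) {
    long_path <- file.path(dir, "scans_long.csv")
    readr::write_csv(scans_long(scans), long_path)
    paths <- c(paths, scans_long = long_path)
  }
  invisible(paths)
}

#' @rdname write_dataset
#' @param check_fields verify that every record carries the documented
#'   fields.
#' @return `read_dataset()` returns a `gasmas_dataset` (without generator
#'   params).
#' @export
read_dataset <- function(dir, check_fields = TRUE) {
  scans_path <- file.path(dir, "scans.jsonl")
  truth_path <- file.path(dir, "truth.csv")
  if (!file.exists(scans_path)) {
    stop("no scans.jsonl under ", dir, call. = FALSE)
  }
  lines <- readLines(scans_path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  records <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    rec <- tryCatch(
      jsonlite::fromJSON(lines[i]),
      error = function(e) {
        stop("malformed scan record at line ", i, ": ", conditionMessage(e),
             call. = FALSE)
      }
    )
    if (check_fields) {
      missing <- setdiff(scan_record_fields, names(rec))
      if (length(missing) > 0) {
        stop("scan record at line ", i, " misses field(s): ",
             paste(missing, collapse = ", "), call. = FALSE)
      }
      if (length(rec$detuning) != length(rec$intensity)) {
        stop("scan record at line ", i,
             ": detuning and intensity lengths differ.", call. = FALSE)
      }
    }
    records[[i]] <- rec
  }
  scans <- tibble::tibble(
    config_id = vapply(records, `[[`, "", "config_id"),
    replicate = vapply(records, function(r) as.integer(r$replicate), 1L),
    channel = vapply(records, function(r) as.integer(r$channel), 1L),
    o2_nominal = vapply(records, function(r) as.numeric(r$o2_nominal), 1),
    o2_effective = vapply(records, function(r) as.numeric(r$o2_effective), 1),
    detuning = lapply(records, function(r) as.numeric(r$detuning)),
    intensity = lapply(records, function(r) as.numeric(r$intensity)),
    seed_used = vapply(records, function(r) as.integer(r$seed_used), 1L),
    clipped = vapply(records, function(r) isTRUE(r$clipped), TRUE)
  )
  truth <- if (file.exists(truth_path)) {
    readr::read_csv(truth_path, show_col_types = FALSE)
  } else {
    NULL
  }
  structure(list(scans = scans, truth = truth, params = NULL),
            class = "gasmas_dataset")
}

log_stage <- function(quiet, fmt, ...) {
  if (!quiet) {
    message(format(Sys.time(), "[%H:%M:%S] "), sprintf(fmt, ...))
  }
}

#' Run the full pipeline
#'
#' Executes simulate -> invert -> outlier screening -> replicate aggregation
#' -> KS comparability -> concentration boxes, writes every artifact under
#' `out_dir`, and returns a manifest. Rerunning with the same configuration
#' reproduces all non-timestamp content byte-identically.
#'
#' Artifacts: `run_config.yaml`, `scans.jsonl`, `truth.csv`,
#' `scans_long.csv`, `estimates.csv`, `config_summaries.csv`,
#' `ks_concentration.csv`, `box_stats.csv`, `manifest.json`.
#'
#' @param config a [run_config()].
#' @param out_dir output directory; defaults to the configuration's.
#' @param quiet suppress stage banners.
#' @param write_scans write the (large) scans.jsonl / scans_long.csv files.
#' @return the manifest, invisibly: a list with the config echo, row counts,
#'   file names with MD5 content hashes, and wall time.
#' @export
run_pipeline <- function(config = run_config(), out_dir = config$out_dir,
                         quiet = FALSE, write_scans = TRUE) {
  stopifnot(inherits(config, "gasmas_run_config"))
  t0 <- Sys.time()
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    log_stage(quiet, "stage %s", name)
    tryCatch(expr, error = function(e) {
      stop("stage ", name, " failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  conditions <- do.call(ambient_conditions, config$conditions)

  design <- stage("design", default_design(
    n_tracheal = config$n_tracheal, n_dermal = config$n_dermal,
    replicates = config$replicates, concentrations = config$concentrations))
  truth <- stage("truth", sample_truth(
    design, seed = config$master_seed, conditions = conditions,
    n_dark = config$n_dark))
  dataset <- stage("simulate", simulate_experiment(
    design, truth, noise_rel = config$noise_rel, beta = config$beta,
    master_seed = config$master_seed, conditions = conditions))
  estimates <- stage("invert", invert_scans(
    dataset, snr_threshold = config$snr_threshold))
  estimates <- stage("qc_outliers", flag_outliers(
    estimates, low = config$outlier_low, high = config$outlier_high))
  summaries <- stage("qc_aggregate", aggregate_replicates(estimates))
  ks_table <- stage("qc_ks", compare_configurations(
    dplyr::filter(estimates, !.data$outlier),
    group = o2_nominal, value = pathlength_m, within = config_id))
  boxes <- stage("qc_boxes", concentration_boxes(
    dplyr::filter(estimates, !.data$outlier)))

  files <- character(0)
  write_file <- function(name, writer) {
    path <- file.path(out_dir, name)
    writer(path)
    files <<- c(files, stats::setNames(path, name))
  }
  stage("write", {
    write_file("run_config.yaml", function(p) write_run_config(config, p))
    if (write_scans) {
      ds_paths <- write_dataset(dataset, out_dir)
      files <<- c(files, stats::setNames(ds_paths, basename(ds_paths)))
    } else {
      readr::write_csv(dataset$truth, file.path(out_dir, "truth.csv"))
      files <<- c(files, stats::setNames(file.path(out_dir, "truth.csv"),
                                         "truth.csv"))
    }
    write_file("estimates.csv",
               function(p) readr::write_csv(estimates, p))
    write_file("config_summaries.csv",
               function(p) readr::write_csv(summaries, p))
    write_file("ks_concentration.csv",
               function(p) readr::write_csv(ks_table, p))
    boxes_flat <- boxes
    boxes_flat$outlier_values <- vapply(
      boxes$outlier_values,
      function(v) paste(format(v, digits = 15), collapse = ";"), character(1))
    write_file("box_stats.csv",
               function(p) readr::write_csv(boxes_flat, p))
  })

  wall <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("gasmas")),
    config = unclass(config),
    row_counts = list(
      scans = nrow(dataset$scans),
      estimates = nrow(estimates),
      summaries = nrow(summaries),
      ks_comparisons = nrow(ks_table),
      box_groups = nrow(boxes)
    ),
    files = lapply(stats::setNames(nm = names(files)), function(nm) {
      list(path = unname(files[[nm]]),
           md5 = unname(tools::md5sum(files[[nm]])))
    }),
    wall_time_s = wall,
    timestamp = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    complete = TRUE
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_stage(quiet, "done in %.1f s", wall)
  invisible(c(manifest, list(
    results = list(estimates = estimates, summaries = summaries,
                   ks = ks_table, boxes = boxes, dataset = dataset))))
}
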