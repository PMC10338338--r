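trace_schema <- c("cell_id", "time_h", "cdk2", "apc", "ccna2", "divided",
                  "treatment", "treatment_time_h", "preset")

#' Write reporter traces to a long-format CSV
#'
#' @param traces A trace tibble (see [generate_population()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_traces <- function(traces, path) {
  missing_cols <- setdiff(trace_schema, names(traces))
  if (length(missing_cols)) {
    abort(paste0("Trace table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  readr::write_csv(traces[trace_schema], path, na = "")
  invisible(path)
}

#' Read reporter traces from a long-format CSV
#'
#' Validates the schema (column-level error messages), converts empty
#' cyclin A2 fields to missing values, and checks that time is strictly
#' increasing within every cell. A write/read round trip is lossless.
#'
#' @param path CSV path written by [write_traces()].
#' @return A trace tibble.
#' @export
read_traces <- function(path) {
  if (!file.exists(path)) abort(paste0("No such trace file: ", path))
  # a missing column triggers readr's parser-mismatch warning before our own
  # schema error below; the error message is the useful one
  out <- withCallingHandlers(readr::read_csv(
    path,
    col_types = readr::cols(
      cell_id = readr::col_character(),
      time_h = readr::col_double(),
      cdk2 = readr::col_double(),
      apc = readr::col_double(),
      ccna2 = readr::col_double(),
      divided = readr::col_integer(),
      treatment = readr::col_character(),
      treatment_time_h = readr::col_double(),
      preset = readr::col_character()
    )
  ), warning = function(w) {
    if (grepl("parsers don't match", conditionMessage(w))) {
      invokeRestart("muffleWarning")
    }
  })
  missing_cols <- setdiff(trace_schema, names(out))
  if (length(missing_cols)) {
    abort(paste0("Trace file is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  bad <- out |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::summarise(ok = !is.unsorted(.data$time_h, strictly = TRUE)) |>
    dplyr::filter(!.data$ok)
  if (nrow(bad)) {
    abort(paste0("Non-monotone `time_h` within cell(s): ",
                 paste(head(bad$cell_id, 5), collapse = ", ")))
  }
  out
}

# Stage seeds are derived from the master seed by hashing the stage name,
# so the RNG streams of the pipeline stages are decoupled but fully
# determined by one integer.
derive_seed <- function(master, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(master) * 7919 + h * 104729) %% 2147483647)
}

#' Run the full competing-clocks pipeline
#'
#' Executes generate -> analyse -> race -> kinetics -> ODE with a single
#' configuration, writes the trace and feature CSVs plus a machine-readable
#' summary JSON, and returns the summary. The summary is identical for
#' identical configurations (one master seed deterministically derives all
#' stage seeds).
#'
#' @param config A list with elements `seed` (integer), `out_dir` (path),
#'   and optionally `preset` (default `"MCF10A"`), `treatment` (default
#'   `"CDK46I"`), `n_cells` (default 500), `n_race` (default 1e5),
#'   `decay_n` (default 100), `decay_noise_cv` (default 0.04) — or the
#'   path of a JSON file holding such an object (schema shipped in
#'   `inst/schema/run_config.schema.json`).
#' @return The summary as a named list (also written to
#'   `summary.json` in `out_dir`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (is.null(config$seed) || is.null(config$out_dir)) {
    abort("`config` needs at least `seed` and `out_dir`.")
  }
  cfg <- utils::modifyList(
    list(preset = "MCF10A", treatment = "CDK46I", n_cells = 500,
         n_race = 1e5, decay_n = 100, decay_noise_cv = 0.04),
    config
  )
  if (cfg$n_cells < 1) abort("`n_cells` must be at least 1 (validation failed before any stage ran).")
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  preset <- make_preset(cfg$preset)

  # generate
  traces <- generate_population(preset, treatment_program(cfg$treatment),
                                n_cells = cfg$n_cells,
                                seed = derive_seed(cfg$seed, "generate"))
  write_traces(traces, file.path(cfg$out_dir, "traces.csv"))

  # analyse
  features <- classify_fates(traces)
  readr::write_csv(features, file.path(cfg$out_dir, "features.csv"))
  bins <- exit_fraction_by_offset(features)
  readr::write_csv(bins, file.path(cfg$out_dir, "exit_by_offset.csv"))
  logit <- fit_exit_logistic(features)

  # race
  exit_clock <- clock_distribution(
    "LOGNORMAL", median = predict_exit_time(preset),
    log_sd = preset$exit_clock_dispersion
  )
  race <- simulate_competition(exit_clock, preset$mitosis_clock,
                               n = cfg$n_race,
                               seed = derive_seed(cfg$seed, "race"))

  # kinetics
  assay <- generate_decay_assay(preset, n_cells = cfg$decay_n,
                                noise_cv = cfg$decay_noise_cv,
                                seed = derive_seed(cfg$seed, "kinetics"))
  hl <- estimate_half_lives(assay)
  presets4 <- c("MCF10A", "RPE1", "RPE1_CCNA2dd", "RPE1_CCNA2dd_DIA")
  cross <- fit_exit_vs_halflife(tibble::tibble(
    half_life = vapply(presets4, function(p) make_preset(p)$protein_half_life,
                       numeric(1)),
    exit_time = vapply(presets4, function(p) predict_exit_time(make_preset(p)),
                       numeric(1))
  ))

  # ODE architectures
  ff <- build_network("FEEDFORWARD")
  fb <- build_network("FEEDBACK")
  hw_ff <- hysteresis_width(ff, eval_time = Inf, dose_resolution = 0.02)
  hw_fb <- hysteresis_width(fb, eval_time = Inf, dose_resolution = 0.02)

  decided <- features$fate[features$post_r_at_treatment &
                             features$fate %in% c("EXIT", "MITOSIS")]
  summary <- list(
    seed = cfg$seed,
    preset = cfg$preset,
    treatment = cfg$treatment,
    n_cells = cfg$n_cells,
    exit_fraction_observed = mean(decided == "EXIT"),
    exit_fraction_simulated = race$exit_fraction,
    exit_fraction_analytic = analytic_exit_probability(exit_clock,
                                                       preset$mitosis_clock),
    exit_clock_median_h = exit_clock$median,
    mitosis_clock_median_h = preset$mitosis_clock$median,
    logistic_slope = logit$slope,
    logistic_p = logit$p_value,
    half_life_median_h = stats::median(hl$half_life),
    exit_vs_halflife_slope = cross$slope,
    exit_vs_halflife_intercept = cross$intercept,
    hysteresis_width_feedforward = hw_ff$width,
    hysteresis_width_feedback = hw_fb$width
  )
  jsonlite::write_json(summary, file.path(cfg$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  summary
}
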