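#' Read a run configuration file
#'
#' @param path YAML or JSON configuration with optional fields
#'   `compounds_file`, `temperature_K`, `models` (subset of
#'   `c("ideal", "unifac")`), `output_dir`, `floor_t_K`, `tolerance`,
#'   `x_grid_step`, `seed`.
#' @return A validated config list with defaults filled in.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("config file not found: ", path), class = "eutectr_format_error")
  }
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  run_config(
    compounds_file = cfg$compounds_file,
    temperature_K = cfg$temperature_K %||% 298,
    models = cfg$models %||% c("ideal", "unifac"),
    output_dir = cfg$output_dir %||% ".",
    floor_t_K = cfg$floor_t_K %||% 150,
    tolerance = cfg$tolerance %||% 1e-8,
    x_grid_step = cfg$x_grid_step %||% 0.02,
    seed = cfg$seed %||% 1
  )
}

#' Build a run configuration
#'
#' @param compounds_file Optional path to a compounds/systems YAML; the
#'   built-in terpene fixtures are used when absent.
#' @param temperature_K Report temperature (K).
#' @param models Activity models to run, subset of `c("ideal", "unifac")`;
#'   at least one required.
#' @param output_dir Directory for CSV/JSON outputs.
#' @param floor_t_K,tolerance Solver settings.
#' @param x_grid_step Phase-diagram composition grid step.
#' @param seed Seed recorded in the provenance block.
#' @return A config list of class `eutectr_config`.
#' @export
run_config <- function(compounds_file = NULL, temperature_K = 298,
                       models = c("ideal", "unifac"), output_dir = ".",
                       floor_t_K = 150, tolerance = 1e-8, x_grid_step = 0.02,
                       seed = 1) {
  if (!length(models)) {
    abort("at least one activity model must be requested",
          class = "eutectr_validation_error")
  }
  bad <- setdiff(models, c("ideal", "unifac"))
  if (length(bad)) {
    abort(paste0("unknown model(s): ", paste(bad, collapse = ", ")),
          class = "eutectr_validation_error")
  }
  if (tolerance <= 0 || floor_t_K <= 0 || x_grid_step <= 0) {
    abort("tolerances and grid steps must be > 0", class = "eutectr_validation_error")
  }
  if (!is.null(compounds_file) && !file.exists(compounds_file)) {
    abort(paste0("compounds file not found: ", compounds_file),
          class = "eutectr_format_error")
  }
  structure(list(
    compounds_file = compounds_file, temperature_K = temperature_K,
    models = models, output_dir = output_dir, floor_t_K = floor_t_K,
    tolerance = tolerance, x_grid_step = x_grid_step, seed = seed
  ), class = "eutectr_config")
}

model_list <- function(ids) {
  mods <- list(ideal = activity_ideal())
  if ("unifac" %in% ids) mods$unifac <- activity_unifac()
  mods[intersect(c("ideal", "unifac"), ids)]
}

#' Run the full characterization pipeline
#'
#' Orchestrates the property correlations, the solid-liquid-equilibrium
#' solves and the deep-eutectic classification for every configured binary
#' system, and writes the result tables (property report, eutectic summary,
#' per-system phase-diagram samples) plus a JSON provenance block to
#' `output_dir`. Outputs are deterministic for a fixed configuration.
#'
#' @param config An `eutectr_config`, see [run_config()].
#' @return Invisibly, a list with `properties`, `eutectics`, `diagrams`
#'   (tibbles) and `provenance`.
#' @export
#' @examples
#' \donttest{
#' out <- run_characterization(run_config(models = "ideal",
#'                                        output_dir = tempdir()))
#' out$eutectics
#' }
run_characterization <- function(config = run_config()) {
  stopifnot(inherits(config, "eutectr_config"))
  compounds <- if (is.null(config$compounds_file)) {
    terpene_compounds()
  } else {
    read_compounds(config$compounds_file)
  }
  systems <- if (is.null(config$compounds_file)) {
    terpene_systems()
  } else {
    cfg <- yaml::read_yaml(config$compounds_file)
    if (is.null(cfg$systems)) {
      abort("compounds file defines no systems", class = "eutectr_validation_error")
    }
    bind_rows(lapply(cfg$systems, as_tibble))
  }
  mods <- model_list(config$models)

  properties <- property_report(systems, compounds, t = config$temperature_K,
                                experimental = tryCatch(
                                  terpene_measured_properties(),
                                  error = function(e) NULL))
  # only attach experimental values for labels we actually have
  eutectics <- list()
  diagrams <- list()
  for (i in seq_len(nrow(systems))) {
    sys <- systems[i, ]
    pair <- system_pair(compounds, sys$comp_i, sys$comp_j)
    pd <- phase_diagram(pair, mods,
                        x_grid = seq(config$x_grid_step, 1 - config$x_grid_step,
                                     by = config$x_grid_step),
                        floor_t = config$floor_t_K)
    diagrams[[length(diagrams) + 1L]] <- mutate(pd$branches, label = sys$label)
    eu <- mutate(pd$eutectics, label = sys$label)
    if (all(c("ideal") %in% eu$model)) {
      t_ideal <- eu$t_e_K[eu$model == "ideal"]
      eu <- mutate(eu, classification = classify_deep(.data$t_e_K, t_ideal))
    }
    eutectics[[length(eutectics) + 1L]] <- eu
  }
  eutectics <- bind_rows(eutectics)
  diagrams <- bind_rows(diagrams)

  inputs <- c(config$compounds_file,
              extdata_path("unifac_subgroups.csv"),
              extdata_path("unifac_interactions.csv"),
              extdata_path("ljr_groups.csv"))
  provenance <- list(
    package_version = as.character(packageVersion("eutectr")),
    unifac_table = unifac_table_version(),
    models = config$models,
    temperature_K = config$temperature_K,
    floor_t_K = config$floor_t_K,
    tolerance = config$tolerance,
    seed = config$seed,
    input_md5 = as.list(tools::md5sum(inputs[file.exists(inputs)]))
  )

  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  stamp <- function(df) {
    mutate(df, package_version = provenance$package_version)
  }
  write.csv(stamp(properties),
            file.path(config$output_dir, "property_report.csv"), row.names = FALSE)
  write.csv(stamp(eutectics),
            file.path(config$output_dir, "eutectic_summary.csv"), row.names = FALSE)
  write.csv(stamp(diagrams),
            file.path(config$output_dir, "phase_diagrams.csv"), row.names = FALSE)
  jsonlite::write_json(provenance,
                       file.path(config$output_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(properties = properties, eutectics = eutectics,
                 diagrams = diagrams, provenance = provenance))
}
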