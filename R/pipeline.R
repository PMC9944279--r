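#' Assemble a pipeline run configuration
#'
#' Bundles every stage's parameters for a configuration-driven run:
#' per-treatment population (and optional census) parameters, the imaging
#' scene, detection settings, the size-class grid, settling-trial and
#' O2-assay settings, and physical constants. A single global seed is
#' fanned out to per-stage child seeds keyed by stage and treatment name,
#' so runs are deterministic and adding a stage never disturbs existing
#' streams. All cross-field constraints are checked up front via
#' [validate_config()], which reports every violation at once.
#'
#' The default configuration is a two-treatment demo mirroring the culture
#' experiment: a non-infected treatment (D3 2.37, ~201 m d^-1 at 2.4 mm,
#' rho_s 1.284 g cm^-3, k 0.16 d^-1) versus a fungal-infected treatment
#' (D3 2.64, ~144 m d^-1 at 2.4 mm, rho_s 1.258 g cm^-3, k 0.34 d^-1),
#' with an infection census attached to the infected treatment.
#'
#' @param seed global integer seed.
#' @param treatments named list; each element a list with `population` (a
#'   [population_params()]) and optional `census` (a [census_params()]).
#' @param scene a [scene_params()] for the shadowgraph rendering.
#' @param imaging an [imaging_config()] for detection (unit mm).
#' @param bins list with `lower_anchor`, `ratio`, `n_bins` for
#'   [build_bins()].
#' @param sample_volume_L imaged sample volume per treatment, litres.
#' @param settling list with `distance_cm`, `timing_noise_sd_s`.
#' @param assay list passed to [generate_o2_assays()] (vial volume,
#'   duration, drift, noise, controls).
#' @param constants a [physical_constants()].
#' @return validated configuration of class `agg_run_config`.
#' @export
run_config <- function(seed = 1L,
                       treatments = default_treatments(),
                       scene = scene_params(image_shape = c(360, 360),
                                            pixel_scale = 0.05, unit = "mm",
                                            noise_sd = 0.02),
                       imaging = imaging_config(pixel_scale = 0.05,
                                                unit = "mm", min_ecd = 0.4),
                       bins = list(lower_anchor = 0.35, ratio = 1.3,
                                   n_bins = 11),
                       sample_volume_L = 0.7,
                       settling = list(distance_cm = 15,
                                       timing_noise_sd_s = 0),
                       assay = list(vial_volume_mL = 20, duration_h = 24,
                                    o2_start_umol_L = 300,
                                    control_drift_frac = 0.02,
                                    noise_sd_umol_L = 0, n_controls = 3),
                       constants = physical_constants()) {
  validate_config(list(seed = seed, treatments = treatments, scene = scene,
                       imaging = imaging, bins = bins,
                       sample_volume_L = sample_volume_L,
                       settling = settling, assay = assay,
                       constants = constants))
}

#' Default two-treatment demo parameters
#'
#' Non-infected vs fungal-infected populations with the velocity prefactors
#' chosen so a 2.4 mm aggregate settles at ~201 and ~144 m d^-1
#' respectively; low velocity noise (sd 0.05) so treatment contrasts are
#' resolvable at n = 12.
#'
#' @param seed integer seed stored in the population parameter sets.
#' @return named list of treatment specifications.
#' @export
default_treatments <- function(seed = 1L) {
  list(
    non_infected = list(
      population = population_params(
        n_aggregates = 12, d_range = c(1.1, 4.9),
        size_dist = "log_uniform", d3_true = 2.37,
        velocity_scale_a = 60, velocity_noise_sd = 0.05,
        mass_density = 1.284, poc_per_solid_volume = 1480,
        resp_rate = 0.16, resp_rate_cv = 0.45, seed = seed),
      census = NULL),
    infected = list(
      population = population_params(
        n_aggregates = 12, d_range = c(1.3, 4.7),
        size_dist = "log_uniform", d3_true = 2.64,
        velocity_scale_a = 34, velocity_noise_sd = 0.05,
        mass_density = 1.258, poc_per_solid_volume = 2400,
        resp_rate = 0.34, resp_rate_cv = 0.25, seed = seed),
      census = census_params(n_cells = 500, seed = seed))
  )
}

#' Validate a pipeline configuration
#'
#' Checks a (possibly hand-built or YAML-loaded) configuration list,
#' filling defaults where constructors define them, and raises a single
#' aggregated error listing all problems found.
#'
#' @param config a list with the fields of [run_config()].
#' @return the validated `agg_run_config`.
#' @export
validate_config <- function(config) {
  problems <- character(0)
  note <- function(msg) problems <<- c(problems, msg)

  if (is.null(config$seed)) {
    note("`seed` is missing")
  } else if (!is.numeric(config$seed) || length(config$seed) != 1 ||
             config$seed != round(config$seed)) {
    note("`seed` must be a single integer")
  }

  coerce <- function(x, constructor, cls, label) {
    if (is.null(x)) return(do.call(constructor, list()))
    if (inherits(x, cls)) return(x)
    tryCatch(do.call(constructor, as.list(x)),
             error = function(e) {
               note(paste0(label, ": ", conditionMessage(e)))
               NULL
             })
  }

  if (is.null(config$treatments) || length(config$treatments) == 0 ||
      is.null(names(config$treatments)) ||
      any(!nzchar(names(config$treatments)))) {
    note("`treatments` must be a non-empty named list")
    treatments <- list()
  } else {
    treatments <- lapply(names(config$treatments), function(nm) {
      tr <- config$treatments[[nm]]
      pop <- coerce(tr$population, population_params,
                    "agg_population_params", paste0("treatment '", nm, "'"))
      cen <- if (is.null(tr$census)) NULL else
        coerce(tr$census, census_params, "agg_census_params",
               paste0("census '", nm, "'"))
      list(population = pop, census = cen)
    })
    names(treatments) <- names(config$treatments)
  }

  scene <- coerce(config$scene, scene_params, "agg_scene_params", "scene")
  imaging <- coerce(config$imaging, imaging_config, "agg_imaging_config",
                    "imaging")
  constants <- coerce(config$constants, physical_constants, "agg_constants",
                      "constants")

  bins <- config$bins %||% list(lower_anchor = 0.35, ratio = 1.3, n_bins = 11)
  bins_tbl <- tryCatch(do.call(build_bins, bins),
                       error = function(e) {
                         note(paste0("bins: ", conditionMessage(e)))
                         NULL
                       })

  if (!is.null(scene) && !is.null(imaging)) {
    if (!identical(scene$unit, imaging$unit)) {
      note("scene and imaging units differ")
    }
    if (!isTRUE(all.equal(scene$pixel_scale, imaging$pixel_scale))) {
      note("scene and imaging pixel scales differ")
    }
  }

  sample_volume_L <- config$sample_volume_L %||% 0.7
  if (!is.numeric(sample_volume_L) || sample_volume_L <= 0) {
    note("`sample_volume_L` must be > 0")
  }
  settling <- utils::modifyList(
    list(distance_cm = 15, timing_noise_sd_s = 0),
    config$settling %||% list())
  assay <- utils::modifyList(
    list(vial_volume_mL = 20, duration_h = 24, o2_start_umol_L = 300,
         control_drift_frac = 0.02, noise_sd_umol_L = 0, n_controls = 3),
    config$assay %||% list())

  if (length(problems) > 0) {
    abort_config("invalid configuration:\n",
                 paste0("- ", problems, collapse = "\n"))
  }
  structure(list(
    seed = as.integer(config$seed), treatments = treatments, scene = scene,
    imaging = imaging, bins = bins, bins_table = bins_tbl,
    sample_volume_L = sample_volume_L, settling = settling, assay = assay,
    constants = constants
  ), class = "agg_run_config")
}

#' Write / read a run configuration as YAML
#'
#' The YAML echo captures every parameter of a run; reading it back and
#' validating reproduces the identical configuration.
#'
#' @param config an `agg_run_config`.
#' @param path file path.
#' @return `write_run_config` invisibly returns `path`; `read_run_config`
#'   returns the validated `agg_run_config`.
#' @export
write_run_config <- function(config, path) {
  strip <- function(x) {
    if (is.list(x)) {
      x <- lapply(x, strip)
      attributes(x) <- list(names = names(x))
    } else if (is.atomic(x) && !is.null(names(x))) {
      x <- as.list(x) # yaml drops names on atomic vectors; maps keep them
    }
    x
  }
  raw <- list(
    seed = config$seed,
    treatments = lapply(config$treatments, function(tr) {
      list(population = strip(unclass(tr$population)),
           census = if (is.null(tr$census)) NULL else
             strip(unclass(tr$census)))
    }),
    scene = strip(unclass(config$scene)),
    imaging = strip(unclass(config$imaging)),
    bins = config$bins,
    sample_volume_L = config$sample_volume_L,
    settling = config$settling,
    assay = config$assay,
    constants = strip(unclass(config$constants))[c("nu", "g")]
  )
  yaml::write_yaml(raw, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  # yaml flattens named numeric vectors to lists; restore the ones we use
  fix_vec <- function(x) if (is.list(x)) unlist(x) else x
  raw$scene$image_shape <- fix_vec(raw$scene$image_shape)
  for (nm in names(raw$treatments)) {
    raw$treatments[[nm]]$population$d_range <-
      fix_vec(raw$treatments[[nm]]$population$d_range)
    if (!is.null(raw$treatments[[nm]]$census)) {
      raw$treatments[[nm]]$census$stage_mix <-
        fix_vec(raw$treatments[[nm]]$census$stage_mix)
      raw$treatments[[nm]]$census$bacteria_mean_per_stage <-
        fix_vec(raw$treatments[[nm]]$census$bacteria_mean_per_stage)
    }
  }
  validate_config(raw)
}

summarise_parameter <- function(x, parameter, unit, treatment) {
  tibble(treatment = treatment, parameter = parameter, unit = unit,
         mean = mean(x), sd = sd(x), min = min(x), max = max(x),
         n = length(x))
}

run_treatment <- function(name, tr, config) {
  pop_params <- tr$population
  pop_params$seed <- child_seed(config$seed, "population", name)
  population <- generate_aggregate_population(pop_params)

  sequence <- generate_image_sequence(
    population, config$scene, per_frame = 4,
    seed = child_seed(config$seed, "images", name))
  detections <- detect_particles(sequence$frames, config$imaging)
  matched <- match_detections(sequence$truth, detections)
  if (nrow(matched$matches) < 3) {
    rlang::abort(paste0("stage imaging (", name,
                        "): fewer than 3 aggregates recovered"))
  }
  d_meas <- detections$ecd[match(matched$matches$detection_id, detections$id)]
  ids <- matched$matches$truth_id

  trials <- generate_settling_trials(
    population, distance_cm = config$settling$distance_cm,
    timing_noise_sd_s = config$settling$timing_noise_sd_s,
    seed = child_seed(config$seed, "trials", name))
  u_meas <- settling_velocity(trials$time_s, trials$distance_cm[1],
                              config$constants)

  records <- tibble(id = ids, d_mm = d_meas,
                    u_m_d = u_meas[match(ids, trials$id)]) %>%
    aggregate_biophysics(pop_params$mass_density, config$constants) %>%
    mutate(treatment = name)

  d3 <- fractal_dimension(records)

  spectrum <- number_spectrum(
    dplyr::rename(detections, ecd_keep = "ecd") %>%
      mutate(ecd = .data$ecd_keep) %>% select(-"ecd_keep"),
    config$bins_table, config$sample_volume_L) %>%
    volume_spectrum() %>%
    log_transform_spectrum()

  assays <- do.call(generate_o2_assays, c(
    list(population = population,
         seed = child_seed(config$seed, "assays", name)),
    config$assay))
  rates <- o2_consumption(assays) %>%
    mutate(k_d = c_specific_rate(.data$o2_rate_umol_d, .data$poc_ug))

  census <- NULL
  if (!is.null(tr$census)) {
    cen_params <- tr$census
    cen_params$seed <- child_seed(config$seed, "census", name)
    census <- generate_cell_census(cen_params)
  }

  list(name = name, population = population, sequence = sequence,
       detections = detections, records = records, d3 = d3,
       spectrum = spectrum, assays = assays, rates = rates, census = census)
}

#' Run the full simulate-image-measure-compare pipeline
#'
#' For every treatment: generate a ground-truth population; render and
#' detect shadowgraph images; build the size spectrum; time settling
#' trials and derive the Stokes quantities per aggregate; estimate the
#' fractal dimension; run the O2 assays through the respiration chain; and
#' score the infection census where configured. Treatments are then
#' compared (size~velocity curve F-test, pairwise tests on the Stokes
#' quantities and respiration rates) and summarised in a Table-1-style
#' report. Deterministic for a given configuration seed.
#'
#' @param config an `agg_run_config` from [run_config()].
#' @return object of class `agg_report`; see [export_report()].
#' @export
run_pipeline <- function(config = run_config()) {
  if (!inherits(config, "agg_run_config")) {
    config <- validate_config(config)
  }
  results <- lapply(names(config$treatments), function(nm) {
    tryCatch(run_treatment(nm, config$treatments[[nm]], config),
             error = function(e) {
               rlang::abort(paste0("pipeline stage failed in treatment '",
                                   nm, "': ", conditionMessage(e)))
             })
  })
  names(results) <- names(config$treatments)

  summary <- bind_rows(lapply(results, function(r) {
    bind_rows(
      summarise_parameter(r$records$d_mm, "diameter", "mm", r$name),
      summarise_parameter(r$records$phi, "porosity", "-", r$name),
      summarise_parameter(r$records$drho_mg_cm3, "excess_density",
                          "mg cm-3", r$name),
      summarise_parameter(r$records$c_d, "drag_coefficient", "-", r$name),
      summarise_parameter(r$records$re, "reynolds_number", "-", r$name),
      summarise_parameter(r$records$u_m_d, "settling_velocity", "m d-1",
                          r$name),
      tibble(treatment = r$name, parameter = "fractal_dimension", unit = "-",
             mean = r$d3$d3, sd = r$d3$se, min = NA_real_, max = NA_real_,
             n = r$d3$n),
      summarise_parameter(r$rates$poc_ug, "poc", "ug C", r$name),
      summarise_parameter(r$rates$k_d, "c_specific_respiration", "d-1",
                          r$name)
    )
  }))

  comparisons <- NULL
  fit_comparison <- NULL
  if (length(results) >= 2) {
    r1 <- results[[1]]; r2 <- results[[2]]
    fit_comparison <- compare_fits(r1$records, r2$records) %>%
      mutate(group1 = r1$name, group2 = r2$name)
    cmp_one <- function(x, y, parameter) {
      pairwise_compare(x, y) %>%
        mutate(parameter = parameter, group1 = r1$name, group2 = r2$name)
    }
    comparisons <- bind_rows(
      cmp_one(r1$records$d_mm, r2$records$d_mm, "diameter"),
      cmp_one(r1$records$drho_mg_cm3, r2$records$drho_mg_cm3,
              "excess_density"),
      cmp_one(r1$records$phi, r2$records$phi, "porosity"),
      cmp_one(r1$rates$poc_ug, r2$rates$poc_ug, "poc"),
      cmp_one(r1$rates$k_d, r2$rates$k_d, "c_specific_respiration")
    )
  }

  census_summary <- bind_rows(lapply(results, function(r) {
    if (is.null(r$census)) return(NULL)
    prev_agg <- prevalence(r$census[r$census$compartment == "aggregate", ])
    prev_amb <- prevalence(r$census[r$census$compartment == "ambient", ])
    tibble(treatment = r$name,
           prevalence_aggregate_pct = prev_agg,
           prevalence_ambient_pct = prev_amb,
           enrichment_fold = enrichment(prev_agg, prev_amb),
           bacteria_per_aggregate = bacteria_per_aggregate(
             r$census[r$census$compartment == "aggregate", ]))
  }))

  structure(list(
    summary = summary,
    records = bind_rows(lapply(results, `[[`, "records")),
    spectra = bind_rows(lapply(results, function(r) {
      mutate(as_tibble(r$spectrum), treatment = r$name)
    })),
    rates = bind_rows(lapply(results, function(r) {
      mutate(r$rates, treatment = r$name)
    })),
    d3 = bind_rows(lapply(results, function(r) {
      mutate(r$d3, treatment = r$name)
    })),
    fit_comparison = fit_comparison,
    comparisons = comparisons,
    census_summary = census_summary,
    provenance = list(seed = config$seed,
                      package_version = as.character(
                        utils::packageVersion("aggsink")),
                      treatments = names(config$treatments))
  ), class = "agg_report")
}

#' @export
print.agg_report <- function(x, ...) {
  cat("Aggregate pipeline report (seed", x$provenance$seed, ")\n\n")
  print(tidyr::pivot_wider(
    x$summary %>%
      mutate(value = sprintf("%.3g +/- %.2g", .data$mean, .data$sd)) %>%
      select("treatment", "parameter", "value"),
    names_from = "treatment", values_from = "value"), n = Inf)
  if (!is.null(x$fit_comparison)) {
    cat(sprintf("\nsize~velocity curves: F(%d,%d) = %.3f, p = %.3g\n",
                x$fit_comparison$df1, x$fit_comparison$df2,
                x$fit_comparison$f, x$fit_comparison$p))
  }
  invisible(x)
}

#' Export a pipeline report to CSV and JSON
#'
#' Writes the summary, per-aggregate records, spectra and comparison tables
#' as CSV (numeric values unrounded; units carried in a dedicated column or
#' in `_unit` suffixes of the column names) plus a single JSON file with
#' the full report. Regeneration from the same report is bit-identical.
#'
#' @param report an `agg_report`.
#' @param dir output directory (created if needed).
#' @param formats subset of c("csv", "json").
#' @return invisibly, the files written.
#' @export
export_report <- function(report, dir, formats = c("csv", "json")) {
  if (!inherits(report, "agg_report")) {
    abort_config("`report` must be an agg_report")
  }
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE,
                                      showWarnings = FALSE)
  if (!ok || file.access(dir, 2) != 0) {
    abort_config("cannot write to directory: ", dir)
  }
  files <- character(0)
  if ("csv" %in% formats) {
    tabs <- list(summary = report$summary, records = report$records,
                 spectra = report$spectra, rates = report$rates,
                 comparisons = report$comparisons,
                 census_summary = report$census_summary)
    for (nm in names(tabs)) {
      if (is.null(tabs[[nm]]) || nrow(tabs[[nm]]) == 0) next
      path <- file.path(dir, paste0(nm, ".csv"))
      write.csv(tabs[[nm]], path, row.names = FALSE)
      files <- c(files, path)
    }
  }
  if ("json" %in% formats) {
    path <- file.path(dir, "report.json")
    jsonlite::write_json(
      lapply(unclass(report), function(x) {
        if (is.data.frame(x)) as.data.frame(x) else x
      }),
      path, auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE)
    files <- c(files, path)
  }
  invisible(files)
}
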