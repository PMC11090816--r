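#' Configuration of an end-to-end phytoclimate risk run
#'
#' Collects every tunable of the pipeline with defaults mirroring the
#' full-scale study design: presence cap 400, 20 environmental zones, 18
#' phytoclimatic zones, TSS acceptance cutoff 0.7, ambient CO2 338 ppm, and
#' 1000 Differential Evolution generations. Synthetic-study sizes (grid,
#' species number, DE generations) are scaled by the caller; every
#' stochastic stage derives its seed from the single `seed`.
#'
#' @param n_rows,n_cols,cell_size synthetic grid specification.
#' @param n_species number of virtual species.
#' @param n_occurrences occurrence count (scalar or range, 7..400).
#' @param prevalence_range suitable-fraction range for virtual species.
#' @param scenarios list of [scenario_spec()] objects; members sharing an
#'   `rcp_label` form a pseudo-GCM ensemble summarized by cellwise medians.
#' @param generations,pop Differential Evolution controls.
#' @param cap presence sample cap.
#' @param k_env environmental zones for sampling stratification.
#' @param k_zones phytoclimatic zones.
#' @param tss_cutoff model acceptance cutoff.
#' @param co2_ambient ambient CO2 (ppm).
#' @param seed master seed.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(n_rows = 30, n_cols = 30, cell_size = 25,
                            n_species = 28, n_occurrences = c(60, 200),
                            prevalence_range = c(0.15, 0.7),
                            scenarios = list(
                              scenario_spec("rcp26", delta_t = 1.5,
                                            precip_scale = 1.0, co2 = 438),
                              scenario_spec("rcp85", delta_t = 4,
                                            precip_scale = 0.85, co2 = 677)
                            ),
                            generations = 1000L, pop = 180L, cap = 400L,
                            k_env = 20L, k_zones = 18L, tss_cutoff = 0.7,
                            co2_ambient = 338, seed = 1L) {
  structure(
    list(n_rows = n_rows, n_cols = n_cols, cell_size = cell_size,
         n_species = n_species, n_occurrences = n_occurrences,
         prevalence_range = prevalence_range, scenarios = scenarios,
         generations = as.integer(generations), pop = as.integer(pop),
         cap = as.integer(cap), k_env = as.integer(k_env),
         k_zones = as.integer(k_zones), tss_cutoff = tss_cutoff,
         co2_ambient = co2_ambient, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

stage_seed <- function(config, offset) {
  as.integer((as.numeric(config$seed) * 131 + offset) %% .Machine$integer.max)
}

#' Run the full phytoclimate risk pipeline on synthetic data
#'
#' Executes simulate-data, soil-moisture, environmental zoning, species
#' generation and fitting, projection, the phytoclimatic transform, zone
#' clustering and the risk indices, and returns all stage artifacts plus a
#' machine-readable manifest. Scenario members sharing an `rcp_label` are
#' summarized by cellwise medians: index medians feed the risk maps,
#' suitability medians feed the future-zone assignment. If a growth form
#' ends up with no accepted species model it is dropped from the transform
#' with a warning (the suitability vectors then have fewer components).
#'
#' @param config a [pipeline_config()].
#' @param output_dir optional directory for the summary CSV and
#'   `manifest.json`.
#' @param constants growth-model constants.
#' @return list of class `pipeline_result` with elements `climatology`,
#'   `soil`, `env_zones`, `species`, `fits`, `accepted`, `phyto_ambient`,
#'   `zones`, `threshold`, `scenarios` (per-label list with surfaces,
#'   indices, zone assignment), `summary` (data.frame) and `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), output_dir = NULL,
                         constants = ttr_constants()) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- proc.time()[["elapsed"]]
  timings <- list()
  tick <- function(stage, start) {
    timings[[stage]] <<- round(proc.time()[["elapsed"]] - start, 2)
  }

  s <- proc.time()[["elapsed"]]
  clim <- generate_climatology(config$n_rows, config$n_cols, config$cell_size,
                               seed = stage_seed(config, 1),
                               co2 = config$co2_ambient)
  tick("simulate_data", s)

  s <- proc.time()[["elapsed"]]
  soil <- simulate_soil_moisture(clim)
  forcing <- ttr_forcing(clim, soil)
  tick("soil_moisture", s)

  s <- proc.time()[["elapsed"]]
  env_zones <- classify_env_zones(clim, k = config$k_env,
                                  seed = stage_seed(config, 2))
  tick("env_zones", s)

  s <- proc.time()[["elapsed"]]
  species <- generate_species(config$n_species, clim, soil,
                              seed = stage_seed(config, 3),
                              n_occurrences = config$n_occurrences,
                              prevalence_range = config$prevalence_range,
                              constants = constants, forcing = forcing)
  tick("generate_species", s)

  s <- proc.time()[["elapsed"]]
  cells <- forcing$cells
  bounds <- default_param_bounds(forcing)
  fits <- vector("list", length(species))
  for (i in seq_along(species)) {
    sp <- species[[i]]
    pres_cells <- cells[sp$occ_cells]
    pres <- sample_presences(pres_cells, env_zones, cap = config$cap,
                             seed = stage_seed(config, 100 + i))
    abs_cells <- sample_pseudo_absences(pres, env_zones,
                                        seed = stage_seed(config, 200 + i))
    fits[[i]] <- fit_species(pres, abs_cells, forcing, sp$pathway,
                             species_id = sp$species_id,
                             generations = config$generations,
                             pop = config$pop, bounds = bounds,
                             constants = constants,
                             tss_cutoff = config$tss_cutoff,
                             seed = stage_seed(config, 300 + i))
  }
  accepted <- vapply(fits, `[[`, TRUE, "accepted")
  if (!any(accepted)) stopf("fit-species stage failed: no model passed the TSS filter")
  tick("fit_species", s)

  s <- proc.time()[["elapsed"]]
  acc_fits <- fits[accepted]
  acc_forms <- vapply(species[accepted], `[[`, "", "growth_form")
  forms_used <- intersect(growth_forms(), unique(acc_forms))
  if (length(forms_used) < length(growth_forms())) {
    warning(sprintf("dropping %d growth form(s) with no accepted model",
                    length(growth_forms()) - length(forms_used)))
  }
  project_all <- function(fc) {
    vapply(acc_fits, function(m) project_species(m, fc, constants)$suitable,
           logical(length(fc$cells)))
  }
  project_all_scores <- function(fc) {
    lapply(acc_fits, function(m) project_species(m, fc, constants))
  }
  bin_ambient <- project_all(forcing)
  phyto_ambient <- growth_form_suitability(bin_ambient, acc_forms, forms_used)
  tick("project_ambient", s)

  s <- proc.time()[["elapsed"]]
  zones <- fit_zones(phyto_ambient, k = config$k_zones,
                     seed = stage_seed(config, 4))
  threshold <- significance_threshold(zones)
  tick("zones", s)

  s <- proc.time()[["elapsed"]]
  labels_by_rcp <- split(seq_along(config$scenarios),
                         vapply(config$scenarios, `[[`, "", "rcp_label"))
  scen_results <- list()
  for (lab in names(labels_by_rcp)) {
    members <- config$scenarios[labels_by_rcp[[lab]]]
    phyto_members <- list()
    chg <- nov <- dis <- list()
    for (j in seq_along(members)) {
      fut_clim <- generate_future(clim, members[[j]])
      fut_soil <- simulate_soil_moisture(fut_clim)
      fut_forcing <- ttr_forcing(fut_clim, fut_soil)
      bin_fut <- project_all(fut_forcing)
      ph <- growth_form_suitability(bin_fut, acc_forms, forms_used)
      phyto_members[[j]] <- ph
      chg[[j]] <- local_change(phyto_ambient, ph)
      nov[[j]] <- novelty(ph, phyto_ambient)
      dis[[j]] <- disappearance(phyto_ambient, ph)
    }
    phyto_med <- ensemble_median(phyto_members)
    change_med <- ensemble_median(chg)
    novelty_med <- ensemble_median(nov)
    disappearance_med <- ensemble_median(dis)
    fut_zones <- assign_future_zones(phyto_med, phyto_ambient, zones$labels,
                                     threshold)
    scen_results[[lab]] <- list(
      rcp_label = lab, phyto_future = phyto_med, change = change_med,
      novelty = novelty_med, disappearance = disappearance_med,
      future_zones = fut_zones,
      transitions = table(ambient = zones$labels, future = fut_zones)
    )
  }
  tick("risk", s)

  summary_df <- do.call(rbind, lapply(scen_results, function(r) {
    data.frame(
      scenario = r$rcp_label,
      pct_significant_change = 100 * area_fraction_significant(r$change, threshold),
      pct_novel = 100 * area_fraction_significant(r$novelty, threshold),
      pct_disappearing = 100 * area_fraction_significant(r$disappearance, threshold),
      n_novel_cells = sum(r$future_zones == 0L),
      threshold = threshold,
      row.names = NULL
    )
  }))

  manifest <- list(
    package = "phytoclim",
    version = as.character(utils::packageVersion("phytoclim")),
    seed = config$seed,
    stages = names(timings),
    timings_s = timings,
    n_land_cells = length(cells),
    n_species = length(species),
    n_accepted = sum(accepted),
    forms_used = forms_used,
    k_zones = zones$k,
    threshold = threshold,
    de = list(generations = config$generations, pop = config$pop),
    scenarios = lapply(config$scenarios, function(sc) {
      list(rcp_label = sc$rcp_label, delta_t = sc$delta_t, co2 = sc$co2,
           gcm_seed = sc$gcm_seed)
    })
  )
  if (config$generations < 1000L) {
    manifest$notes <- sprintf(
      "DE generations reduced from the full-scale default 1000 to %d",
      config$generations)
  }

  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(summary_df, file.path(output_dir, "summary.csv"),
                     row.names = FALSE)
    jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  structure(
    list(climatology = clim, soil = soil, env_zones = env_zones,
         species = species, fits = fits, accepted = accepted,
         forms_used = forms_used, forcing = forcing,
         phyto_ambient = phyto_ambient, zones = zones,
         threshold = threshold, scenarios = scen_results,
         summary = summary_df, manifest = manifest,
         elapsed_s = round(proc.time()[["elapsed"]] - t0, 2)),
    class = "pipeline_result"
  )
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d species (%d accepted), %d zones, threshold %.3f\n",
              length(x$fits), sum(x$accepted), x$zones$k, x$threshold))
  print(x$summary)
  invisible(x)
}
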