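# The fitted synthetic study shared by the parameter-recovery and
# end-to-end tests: a 30x30 world, 20 virtual species with 200 unbiased
# presences each, fitted by Differential Evolution at 200 generations.
# Built once per session (it is by far the most expensive fixture).
fitted_world <- function() {
  cache_get("fitted_world", function() {
    clim <- generate_climatology(30, 30, seed = 3)
    soil <- simulate_soil_moisture(clim)
    forcing <- ttr_forcing(clim, soil)
    species <- generate_species(20, clim, soil, seed = 7,
                                n_occurrences = 200,
                                prevalence_range = c(0.3, 0.55),
                                forcing = forcing)
    env_zones <- classify_env_zones(clim, k = 20, seed = 11)
    fits <- vector("list", length(species))
    truth_tss <- numeric(length(species))
    for (i in seq_along(species)) {
      sp <- species[[i]]
      pres <- sample_presences(forcing$cells[sp$occ_cells], env_zones,
                               seed = 500 + i)
      abs_s <- sample_pseudo_absences(pres, env_zones, seed = 600 + i)
      fit <- fit_species(pres, abs_s, forcing, sp$pathway,
                         species_id = sp$species_id,
                         generations = 200, pop = 24, seed = 700 + i)
      proj <- project_species(fit, forcing)
      truth <- sp$true_suitable
      tp <- sum(proj$suitable & truth); fp <- sum(proj$suitable & !truth)
      fn <- sum(!proj$suitable & truth); tn <- sum(!proj$suitable & !truth)
      truth_tss[i] <- tss(tp, fp, fn, tn)
      fits[[i]] <- fit
    }
    list(clim = clim, soil = soil, forcing = forcing, species = species,
         env_zones = env_zones, fits = fits, truth_tss = truth_tss)
  })
}

# ambient projection artifacts of the fitted world: binary maps, the
# phytoclimatic surface over the forms with accepted models, zones and the
# significance threshold
ambient_state <- function() {
  cache_get("ambient_state", function() {
    w <- fitted_world()
    accepted <- vapply(w$fits, `[[`, TRUE, "accepted")
    fits <- w$fits[accepted]
    forms <- vapply(w$species[accepted], `[[`, "", "growth_form")
    forms_used <- intersect(growth_forms(), unique(forms))
    bin <- vapply(fits, function(m) {
      project_species(m, w$forcing)$suitable
    }, logical(length(w$forcing$cells)))
    phyto <- growth_form_suitability(bin, forms, forms_used)
    zones <- fit_zones(phyto, k = 8, seed = 5)
    list(fits = fits, forms = forms, forms_used = forms_used,
         phyto = phyto, zones = zones,
         threshold = significance_threshold(zones))
  })
}

# project the accepted models of the fitted world onto a (future) forcing
project_world <- function(forcing) {
  st <- ambient_state()
  bin <- vapply(st$fits, function(m) {
    project_species(m, forcing)$suitable
  }, logical(length(forcing$cells)))
  growth_form_suitability(bin, st$forms, st$forms_used)
}
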