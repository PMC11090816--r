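#' The 14 plant growth forms
#'
#' Canonical growth-form categories used by the phytoclimatic transform:
#' evergreen, drought-deciduous and cold-deciduous broadleaf trees and
#' shrubs, needleleaf trees, therophytes, geophytes, forbs, C3 and C4
#' grasses, succulents and climbers.
#'
#' @return character vector of length 14.
#' @export
growth_forms <- function() {
  c("tree_evergreen", "tree_dry_deciduous", "tree_cold_deciduous",
    "tree_needleleaf", "shrub_evergreen", "shrub_dry_deciduous",
    "shrub_cold_deciduous", "therophyte", "geophyte", "forb",
    "grass_c3", "grass_c4", "succulent", "climber")
}

#' Generate a synthetic monthly climatology
#'
#' Builds a climatology with the statistical structure of a real gridded
#' product: mean temperature decreasing poleward (rows run north to south)
#' with seasonal amplitude increasing poleward, diurnal-range offsets giving
#' `tmin <= tmean <= tmax`, spatially autocorrelated precipitation with
#' seasonality, radiation a deterministic function of latitude band and
#' month, spatially autocorrelated soils with `wp <= fc`, and a smooth land
#' mask. All randomness is controlled by `seed`.
#'
#' @param n_rows,n_cols grid dimensions (>= 10 each).
#' @param cell_size cell edge (km).
#' @param seed integer seed.
#' @param land_fraction target fraction of land cells.
#' @param co2 atmospheric CO2 (ppm).
#' @return a [phy_climatology()].
#' @export
generate_climatology <- function(n_rows = 30, n_cols = 30, cell_size = 25,
                                 seed = 1, land_fraction = 0.85, co2 = 338) {
  if (n_rows < 10 || n_cols < 10) {
    stopf("argument error: synthetic grids must be at least 10 x 10")
  }
  with_seed(seed, {
    noise <- function(sd, radius = 3L) {
      smooth_field(matrix(stats::rnorm(n_rows * n_cols, 0, sd), n_rows, n_cols),
                   radius = radius, passes = 2L)
    }
    # latitude proxy: 65 deg at the top row, 0 at the bottom
    lat <- matrix(rep(seq(65, 0, length.out = n_rows), n_cols), n_rows, n_cols)
    t_ann <- 28 - 0.5 * lat + noise(4)
    amp <- 3 + 0.25 * lat + pmax(0, noise(2))
    d1 <- pmax(0.5, 4 + noise(2))
    d2 <- pmax(0.5, 5 + noise(2))

    colf <- matrix(rep((seq_len(n_cols) - 0.5) / n_cols, each = n_rows),
                   n_rows, n_cols)
    p_ann <- 1100 * exp(noise(2, radius = 4L) + 0.7 * (colf - 0.5))
    season <- pmin(0.85, pmax(0, 0.4 + noise(1.5)))

    tmean <- tmin <- tmax <- precip <- radiation <-
      array(NA_real_, c(n_rows, n_cols, 12L))
    for (m in 1:12) {
      cyc <- cos(2 * pi * (m - 7) / 12)
      tmean[, , m] <- t_ann + amp * cyc
      tmin[, , m] <- tmean[, , m] - d1
      tmax[, , m] <- tmean[, , m] + d2
      precip[, , m] <- pmax(0, p_ann / 12 * (1 + season * cyc))
      radiation[, , m] <- pmax(0.5, 24 - 0.18 * lat + (1.5 + 0.05 * lat) * cyc)
    }

    fc <- 60 + 180 * stats::plogis(noise(3, radius = 4L))
    wp <- fc * (0.15 + 0.35 * stats::plogis(noise(3, radius = 4L)))

    sea_score <- noise(3, radius = 4L)
    mask <- sea_score >= stats::quantile(sea_score, 1 - land_fraction)

    grid <- phy_grid(n_rows, n_cols, cell_size, origin = c(0, 0),
                     land_mask = mask)
    phy_climatology(grid, tmin = tmin, tmean = tmean, tmax = tmax,
                    precip = precip, radiation = radiation,
                    field_capacity = fc, wilting_point = wp, co2 = co2)
  })
}

#' Specification of a future climate scenario
#'
#' A pseudo-GCM projection: a uniform (or spatially varying) warming, a
#' multiplicative precipitation factor, a replacement CO2 concentration and
#' a seed generating the GCM-specific spatially smooth temperature noise.
#' Radiation is assumed unchanged in the future.
#'
#' @param rcp_label scenario name (e.g. `"rcp26"`, `"rcp85"`).
#' @param delta_t warming applied to all temperature layers (degC).
#' @param precip_scale multiplicative precipitation factor, scalar or matrix
#'   (> 0 everywhere).
#' @param co2 future CO2 (ppm, > 0).
#' @param gcm_seed integer; one pseudo-GCM per seed.
#' @param noise_sd standard deviation (degC) of the smooth GCM noise; 0
#'   disables it.
#' @return object of class `scenario_spec`.
#' @export
scenario_spec <- function(rcp_label, delta_t = 0, precip_scale = 1,
                          co2 = 338, gcm_seed = 1L, noise_sd = 0.3) {
  if (any(precip_scale <= 0)) stopf("argument error: precip_scale must be > 0")
  if (co2 <= 0) stopf("argument error: co2 must be > 0")
  structure(list(rcp_label = rcp_label, delta_t = delta_t,
                 precip_scale = precip_scale, co2 = co2,
                 gcm_seed = as.integer(gcm_seed), noise_sd = noise_sd),
            class = "scenario_spec")
}

#' Apply a future scenario to an ambient climatology
#'
#' Shifts all three temperature stacks by `delta_t` plus the scenario's
#' seeded, spatially smooth GCM noise; multiplies precipitation by
#' `precip_scale`; keeps radiation and soil properties unchanged; replaces
#' CO2.
#'
#' @param ambient a [phy_climatology()].
#' @param spec a [scenario_spec()].
#' @return a future [phy_climatology()].
#' @export
generate_future <- function(ambient, spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  g <- ambient$grid
  dt_field <- matrix(spec$delta_t, g$n_rows, g$n_cols)
  if (spec$noise_sd > 0) {
    dt_field <- dt_field + with_seed(spec$gcm_seed, {
      smooth_field(matrix(stats::rnorm(g$n_rows * g$n_cols, 0, 3 * spec$noise_sd),
                          g$n_rows, g$n_cols), radius = 3L, passes = 2L)
    })
  }
  scale <- spec$precip_scale
  if (is.matrix(scale) && !identical(dim(scale), c(g$n_rows, g$n_cols))) {
    stopf("argument error: precip_scale matrix must match the grid")
  }
  fut <- ambient
  for (m in 1:12) {
    fut$tmin[, , m] <- ambient$tmin[, , m] + dt_field
    fut$tmean[, , m] <- ambient$tmean[, , m] + dt_field
    fut$tmax[, , m] <- ambient$tmax[, , m] + dt_field
    fut$precip[, , m] <- ambient$precip[, , m] * scale
  }
  fut$co2 <- spec$co2
  validate_climatology(fut)
  fut
}

#' Generate virtual species with known physiology and occurrences
#'
#' Draws species with known (true) growth-model parameters organized around
#' growth-form-level climatic niches, computes each species' true
#' equilibrium-biomass surface, and samples occurrence records only from
#' cells where the species is truly suitable (so a perfect refit attains
#' TSS = 1 against truth). Species whose drawn parameters give a suitable
#' area outside `prevalence_range` (or too small for the requested
#' occurrence count) are redrawn up to `max_retry` times.
#'
#' @param n_species number of species (>= 14: at least one per growth form).
#' @param clim a [phy_climatology()].
#' @param soil matching `phy_soil_moisture`.
#' @param seed integer seed.
#' @param n_occurrences occurrence cells to sample per species (scalar or
#'   length-2 range, each in 7..400); capped at the suitable-cell count.
#' @param prevalence_range acceptable range of the suitable fraction of land.
#' @param bias if `TRUE`, thin occurrences outside a random "well-sampled"
#'   circular region (herbarium-style spatial bias), keeping outside records
#'   with probability `bias_keep`.
#' @param bias_keep keep probability outside the well-sampled region.
#' @param constants growth-model constants.
#' @param forcing optional precomputed [ttr_forcing()] (all land cells).
#' @param max_retry redraw limit per species.
#' @return list of class `virtual_species_set`: per-species records (id,
#'   growth form, pathway, `true_params`, realized prevalence, occurrence
#'   cell indices, true suitability vector over land cells), with the land
#'   cell index vector, occurrence and growth-form tables as attributes.
#' @export
generate_species <- function(n_species, clim, soil, seed = 1,
                             n_occurrences = 200,
                             prevalence_range = c(0.15, 0.7),
                             bias = FALSE, bias_keep = 0.3,
                             constants = ttr_constants(),
                             forcing = NULL, max_retry = 60L) {
  if (n_species < 14L) stopf("argument error: n_species must be >= 14")
  if (is.null(forcing)) forcing <- ttr_forcing(clim, soil)
  cells <- forcing$cells
  ncell <- length(cells)
  forms <- growth_forms()
  form_of <- rep(forms, length.out = n_species)

  tm_ann <- rowMeans(forcing$tmean)
  w_ann <- rowMeans(forcing$moisture)
  t_lo <- stats::quantile(tm_ann, 0.05); t_hi <- stats::quantile(tm_ann, 0.95)
  w_lo <- stats::quantile(w_ann, 0.05); w_hi <- stats::quantile(w_ann, 0.95)
  w_span <- max(w_hi - w_lo, 1)

  coords <- grid_coords(clim$grid)

  with_seed(seed, {
    # form-level niche centers: species of a form cluster in climate space
    t_centers <- stats::runif(length(forms), t_lo, t_hi)
    w_centers <- stats::runif(length(forms), w_lo + 0.2 * w_span,
                              w_hi - 0.1 * w_span)
    names(t_centers) <- names(w_centers) <- forms

    t_mid <- stats::median(tm_ann); w_mid <- stats::median(w_ann)

    # `widen` scales niche breadth; `pull` in [0,1] moves the niche toward
    # the climate median. The rejection loop adapts both so it terminates.
    draw_params <- function(form, widen = 1, pull = 0) {
      t_opt <- (1 - pull) * (t_centers[[form]] + stats::rnorm(1, 0, 2.5)) +
        pull * t_mid
      w_opt <- (1 - pull) *
        (w_centers[[form]] + stats::rnorm(1, 0, 0.08 * w_span)) +
        pull * w_mid
      tz <- function(center, plateau, skirt) {
        c(center - plateau - skirt, center - plateau,
          center + plateau, center + plateau + skirt)
      }
      g_temp <- tz(t_opt, widen * stats::runif(1, 5, 10),
                   widen * stats::runif(1, 4, 10))
      n_temp <- tz(t_opt + stats::rnorm(1, 0, 1.5),
                   widen * stats::runif(1, 6, 12), widen * stats::runif(1, 4, 10))
      wpl <- widen * stats::runif(1, 0.2, 0.45) * w_span
      wsk <- widen * stats::runif(1, 0.1, 0.3) * w_span
      c_moist <- tz(w_opt, wpl, wsk)
      n_moist <- tz(w_opt + stats::rnorm(1, 0, 0.05 * w_span),
                    wpl * stats::runif(1, 1, 1.4), wsk)
      c_moist[1] <- max(c_moist[1], 0); n_moist[1] <- max(n_moist[1], 0)
      c_moist <- cummax(c_moist); n_moist <- cummax(n_moist)
      ttr_params(n_temp = n_temp, n_moist = n_moist, c_moist = c_moist,
                 c_nitrogen = c(stats::runif(1, 0.005, 0.03),
                                stats::runif(1, 0.05, 0.3)),
                 g_temp = g_temp)
    }

    n_occ_range <- if (length(n_occurrences) == 1L) rep(n_occurrences, 2) else n_occurrences
    if (any(n_occ_range < 7) || any(n_occ_range > 400)) {
      stopf("argument error: n_occurrences must lie in 7..400")
    }

    species <- vector("list", n_species)
    failed <- character(0)
    for (s in seq_len(n_species)) {
      form <- form_of[s]
      pathway <- if (form == "grass_c4") "C4" else "C3"
      n_occ <- round(stats::runif(1, n_occ_range[1], n_occ_range[2]))
      ok <- FALSE
      widen <- 1; pull <- 0
      for (try in seq_len(max_retry)) {
        par <- draw_params(form, widen = widen, pull = pull)
        B <- equilibrium_biomass(par, forcing, pathway, constants)
        suit <- B > 0
        prev <- mean(suit)
        if (prev >= prevalence_range[1] && prev <= prevalence_range[2] &&
            sum(suit) >= max(n_occ, 7)) {
          ok <- TRUE
          break
        }
        if (prev < prevalence_range[1]) {
          widen <- widen * 1.25
          pull <- min(1, pull + 0.1)
        } else if (prev > prevalence_range[2]) {
          widen <- widen * 0.8
        }
      }
      if (!ok) {
        failed <- c(failed, sprintf("sp%03d (%s)", s, form))
        next
      }
      occ_pool <- which(suit)
      if (bias) {
        center <- occ_pool[sample.int(length(occ_pool), 1L)]
        cc <- coords[cells[center], ]
        d <- sqrt((coords$x[cells[occ_pool]] - cc$x)^2 +
                  (coords$y[cells[occ_pool]] - cc$y)^2)
        radius <- 0.35 * sqrt(clim$grid$n_rows^2 + clim$grid$n_cols^2) *
          clim$grid$cell_size
        keep <- d <= radius | stats::runif(length(occ_pool)) < bias_keep
        if (sum(keep) >= 7) occ_pool <- occ_pool[keep]
      }
      occ <- occ_pool[sample.int(length(occ_pool), min(n_occ, length(occ_pool)))]
      species[[s]] <- list(
        species_id = sprintf("sp%03d", s), growth_form = form,
        pathway = pathway, true_params = par, prevalence = prev,
        true_biomass = B, true_suitable = suit,
        occ_cells = sort(occ)
      )
    }
    if (length(failed)) {
      stopf("could not draw suitable parameters for: %s",
            paste(failed, collapse = ", "))
    }
    species <- Filter(Negate(is.null), species)

    occ_df <- do.call(rbind, lapply(species, function(sp) {
      idx <- cells[sp$occ_cells]
      data.frame(species_id = sp$species_id,
                 x = coords$x[idx], y = coords$y[idx])
    }))
    gf_df <- data.frame(
      species_id = vapply(species, `[[`, "", "species_id"),
      growth_form = vapply(species, `[[`, "", "growth_form")
    )
    structure(species, class = "virtual_species_set",
              cells = cells, occurrences = occ_df, growth_form_table = gf_df)
  })
}
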