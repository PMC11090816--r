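test_that("the same seed reproduces the climatology exactly", {
  a <- generate_climatology(12, 15, seed = 9)
  b <- generate_climatology(12, 15, seed = 9)
  expect_identical(a, b)
  c2 <- generate_climatology(12, 15, seed = 10)
  expect_false(identical(a$tmean, c2$tmean))
})

test_that("generated climatologies satisfy every type invariant", {
  for (seed in c(1, 7, 23)) {
    clim <- generate_climatology(14, 11, seed = seed)
    expect_true(all(clim$tmin <= clim$tmean))
    expect_true(all(clim$tmean <= clim$tmax))
    expect_true(all(clim$precip >= 0))
    expect_true(all(clim$radiation >= 0))
    expect_true(all(clim$wilting_point >= 0))
    expect_true(all(clim$wilting_point <= clim$field_capacity))
  }
})

test_that("annual mean temperature is spatially autocorrelated and zoned", {
  # Moran-style lag-1 statistic computed by the direct formula over rook
  # neighbours, for a sweep of seeds
  for (seed in 1:10) {
    clim <- generate_climatology(15, 15, seed = seed)
    tm <- apply(clim$tmean, c(1, 2), mean)
    z <- tm - mean(tm)
    num <- 0; wsum <- 0
    nr <- nrow(z); nc <- ncol(z)
    for (i in seq_len(nr)) for (j in seq_len(nc)) {
      if (i < nr) { num <- num + z[i, j] * z[i + 1, j]; wsum <- wsum + 1 }
      if (j < nc) { num <- num + z[i, j] * z[i, j + 1]; wsum <- wsum + 1 }
    }
    moran <- (length(z) / wsum) * num / sum(z^2)
    expect_gt(moran, 0)
  }
  # poleward cooling: top row colder than bottom row
  clim <- generate_climatology(15, 15, seed = 4)
  tm <- apply(clim$tmean, c(1, 2), mean)
  expect_lt(mean(tm[1, ]), mean(tm[15, ]))
  # seasonal amplitude increases poleward
  amp <- apply(clim$tmean, c(1, 2), function(x) diff(range(x)))
  expect_gt(mean(amp[1, ]), mean(amp[15, ]))
})

test_that("identity scenarios leave the climatology unchanged", {
  clim <- generate_climatology(12, 12, seed = 2)
  spec <- scenario_spec("null", delta_t = 0, precip_scale = 1, co2 = clim$co2,
                        noise_sd = 0)
  fut <- generate_future(clim, spec)
  expect_equal(fut, clim)
})

test_that("warming scenarios shift temperatures exactly when noise is off", {
  clim <- generate_climatology(12, 12, seed = 2)
  fut <- generate_future(clim, scenario_spec("w4", delta_t = 4, co2 = 677,
                                             noise_sd = 0))
  expect_equal(fut$tmean, clim$tmean + 4)
  expect_equal(fut$tmin, clim$tmin + 4)
  expect_equal(fut$tmax, clim$tmax + 4)
  expect_equal(fut$radiation, clim$radiation)  # held fixed in the future
  expect_equal(fut$field_capacity, clim$field_capacity)
  expect_equal(fut$co2, 677)
})

test_that("a pseudo-GCM ensemble scatters around the shared warming", {
  clim <- generate_climatology(12, 12, seed = 2)
  shifts <- sapply(1:5, function(g) {
    fut <- generate_future(clim, scenario_spec("w3", delta_t = 3,
                                               gcm_seed = g, noise_sd = 0.3))
    fut$tmean - clim$tmean
  })
  med <- apply(shifts, 1, median)
  expect_true(all(abs(med - 3) < 3 * 0.3))
  expect_gt(stats::sd(shifts), 0)  # members differ
})

test_that("scenario validation rejects impossible fields", {
  expect_error(scenario_spec("bad", precip_scale = 0), "precip_scale")
  expect_error(scenario_spec("bad", co2 = -1), "co2")
})

test_that("virtual species cover all growth forms with known truth", {
  w <- tiny_world()
  sps <- generate_species(28, w$clim, w$soil, seed = 21,
                          n_occurrences = 50,
                          prevalence_range = c(0.2, 0.7),
                          forcing = w$forcing)
  expect_length(sps, 28)
  expect_setequal(unique(vapply(sps, `[[`, "", "growth_form")),
                  growth_forms())
  for (sp in sps[c(1, 9, 20)]) {
    # exactly the requested number of distinct, truly suitable cells
    expect_length(sp$occ_cells, 50)
    expect_false(any(duplicated(sp$occ_cells)))
    expect_true(all(sp$true_suitable[sp$occ_cells]))
    # recomputation oracle: the stored truth equals a fresh simulation
    # from the stored parameters, cell for cell
    B <- equilibrium_biomass(sp$true_params, w$forcing, sp$pathway)
    expect_identical(B > 0, sp$true_suitable)
  }
  # C4 pathway goes with C4 grasses only
  pw <- vapply(sps, `[[`, "", "pathway")
  gf <- vapply(sps, `[[`, "", "growth_form")
  expect_true(all((pw == "C4") == (gf == "grass_c4")))
  # attached occurrence table parses back to the same cells
  occ <- attr(sps, "occurrences")
  thin <- thin_occurrences(occ, w$clim$grid)
  expect_equal(nrow(thin), nrow(occ))
})

test_that("species generation is deterministic given the seed", {
  w <- tiny_world()
  a <- generate_species(14, w$clim, w$soil, seed = 31, n_occurrences = 20,
                        forcing = w$forcing)
  b <- generate_species(14, w$clim, w$soil, seed = 31, n_occurrences = 20,
                        forcing = w$forcing)
  expect_identical(lapply(a, `[[`, "occ_cells"), lapply(b, `[[`, "occ_cells"))
  expect_identical(lapply(a, `[[`, "true_params"),
                   lapply(b, `[[`, "true_params"))
})

test_that("sampling bias thins records outside the well-sampled region", {
  w <- tiny_world()
  a <- generate_species(14, w$clim, w$soil, seed = 31, n_occurrences = 60,
                        prevalence_range = c(0.3, 0.8), forcing = w$forcing)
  b <- generate_species(14, w$clim, w$soil, seed = 31, n_occurrences = 60,
                        prevalence_range = c(0.3, 0.8), bias = TRUE,
                        forcing = w$forcing)
  # biased occurrences are still truly suitable and at most as widespread
  for (i in seq_along(b)) {
    expect_true(all(b[[i]]$true_suitable[b[[i]]$occ_cells]))
  }
})
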