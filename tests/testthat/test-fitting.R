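test_that("well-separated climate blobs are recovered as zones", {
  # two thermally distinct halves with a wide gap
  clim <- generate_climatology(16, 16, seed = 8, land_fraction = 1)
  shift <- matrix(0, 16, 16)
  shift[, 1:8] <- -30
  for (m in 1:12) {
    clim$tmin[, , m] <- clim$tmin[, , m] + shift
    clim$tmean[, , m] <- clim$tmean[, , m] + shift
    clim$tmax[, , m] <- clim$tmax[, , m] + shift
  }
  ez <- classify_env_zones(clim, k = 2, seed = 4)
  half <- rep(rep(c(1, 2), each = 8), times = 16)  # row-major column halves
  agree <- max(mean((ez$zone_of_cell == half)),
               mean((ez$zone_of_cell == 3 - half)))
  expect_equal(agree, 1)
})

test_that("environmental zoning is deterministic and covers all zones", {
  w <- tiny_world()
  a <- classify_env_zones(w$clim, k = 6, seed = 13)
  b <- classify_env_zones(w$clim, k = 6, seed = 13)
  expect_identical(a$zone_of_cell, b$zone_of_cell)
  expect_setequal(unique(a$zone_of_cell), 1:6)
  expect_error(classify_env_zones(w$clim, k = 10000), "land cells")
})

test_that("occurrence thinning keeps one record per species and cell", {
  g <- phy_grid(10, 10, cell_size = 10)
  rec <- data.frame(species_id = "a",
                    x = c(5, 6, 7, 25, 35), y = c(-5, -6, -4, -15, -25))
  out <- thin_occurrences(rec, g)
  expect_equal(nrow(out), 3)  # first three share cell (1,1)? no: 5,6,7 in col 1
  # records already unique stay unchanged
  rec2 <- data.frame(species_id = c("a", "a", "b"),
                     x = c(5, 15, 5), y = c(-5, -5, -5))
  expect_equal(nrow(thin_occurrences(rec2, g)), 3)
  # random records: output size equals distinct (species, cell) pairs
  set.seed(2)
  rec3 <- data.frame(species_id = sample(letters[1:5], 1000, TRUE),
                     x = runif(1000, 0, 100), y = runif(1000, -100, 0))
  thinned <- thin_occurrences(rec3, g)
  cells <- cell_index_of(g, rec3$x, rec3$y)
  expect_equal(nrow(thinned),
               nrow(unique(data.frame(rec3$species_id, cells))))
  # out-of-grid records are dropped with a message
  expect_message(thin_occurrences(
    data.frame(species_id = "a", x = c(5, 500), y = c(-5, -5)), g), "dropped")
})

test_that("presence sampling returns everything below the cap", {
  w <- tiny_world()
  ez <- classify_env_zones(w$clim, k = 5, seed = 2)
  pres <- ez$cells[1:120]
  expect_identical(sample_presences(pres, ez, cap = 400, seed = 1), pres)
  expect_error(sample_presences(ez$cells[1:5], ez), "7 presence")
})

test_that("stratified presence sampling matches largest-remainder counts", {
  w <- tiny_world()
  ez <- classify_env_zones(w$clim, k = 6, seed = 2)
  # synthetic presence multiset over the real zones
  z <- ez$zone_of_cell
  pres <- ez$cells[1:min(340, length(ez$cells))]
  out <- sample_presences(pres, ez, cap = 200, seed = 3)
  expect_length(out, 200)
  expect_true(all(out %in% pres))
  expect_false(any(duplicated(out)))
  # per-zone counts equal largest-remainder apportionment of the cap
  zp <- z[match(pres, ez$cells)]
  zo <- z[match(out, ez$cells)]
  zl <- sort(unique(zp))
  n <- as.numeric(table(factor(zp, levels = zl)))
  quota <- 200 * n / sum(n)
  base <- floor(quota)
  rem <- 200 - sum(base)
  if (rem > 0) {
    extra <- order(quota - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  got <- as.numeric(table(factor(zo, levels = zl)))
  expect_equal(got, base)
})

test_that("pseudo-absence sampling inverts the presence-zone weights", {
  w <- tiny_world()
  ez <- classify_env_zones(w$clim, k = 2, seed = 6)
  z <- ez$zone_of_cell
  zs <- sort(unique(z))
  cells1 <- ez$cells[z == zs[1]]
  cells2 <- ez$cells[z == zs[2]]
  n1 <- length(cells1); n2 <- length(cells2)
  # presences 80% zone 1 / 20% zone 2
  pres <- c(cells1[seq_len(min(80, n1 - 60))], cells2[seq_len(min(20, n2 - 60))])
  np <- length(pres)
  p1 <- mean(pres %in% cells1)
  w_inv <- (1 / c(p1, 1 - p1)); w_inv <- w_inv / sum(w_inv)
  draws <- sapply(1:50, function(s) {
    a <- sample_pseudo_absences(pres, ez, seed = s)
    expect_length(a, np)
    expect_length(intersect(a, pres), 0)
    mean(ez$zone_of_cell[match(a, ez$cells)] == zs[1])
  })
  # multinomial expectation within binomial error across 50 seeds
  se <- sqrt(w_inv[1] * (1 - w_inv[1]) / (50 * np))
  expect_lt(abs(mean(draws) - w_inv[1]), 4 * se + 0.02)
})

test_that("species with fewer presences than zones get 20 pseudo-absences", {
  w <- tiny_world()
  ez <- classify_env_zones(w$clim, k = 20, seed = 6)
  pres <- ez$cells[1:10]
  a <- sample_pseudo_absences(pres, ez, seed = 1)
  expect_length(a, 20)
  expect_length(intersect(a, pres), 0)
})

test_that("the suitability link is a floor-safe increasing cloglog", {
  # default eps keeps zero biomass essentially unsuitable
  expect_lt(suitability_score(0, c(0, 1)), 1e-5)
  # algebraic identity at b0 = 0, b1 = 1
  B <- c(0.3, 1, 4)
  expect_equal(suitability_score(B, c(0, 1)),
               1 - exp(-(B + 1e-6)))
  # monotonicity over a broad scan
  set.seed(8)
  b <- sort(runif(1e4, 0, 50))
  p <- suitability_score(b, c(-0.5, 0.8))
  expect_true(all(diff(p) >= 0))
  expect_error(suitability_score(-1, c(0, 1)), "B must be")
})

test_that("threshold choice maximizes TP+TN with the lowest tie-break", {
  # worked example: any cutoff in (0.2, 0.8] scores 4; the lowest candidate
  # above 0.2 is the midpoint 0.5
  expect_equal(choose_threshold(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 0.5)
  # separable case: TP + TN equals the sample size
  sc <- c(0.9, 0.85, 0.7, 0.3, 0.2)
  lab <- c(1, 1, 1, 0, 0)
  th <- choose_threshold(sc, lab)
  expect_equal(sum((sc >= th) == (lab == 1)), 5)
  # brute-force oracle on interleaved scores
  set.seed(4)
  for (rep in 1:20) {
    sc <- round(runif(40), 2)
    lab <- rbinom(40, 1, 0.5)
    if (length(unique(lab)) < 2) next
    th <- choose_threshold(sc, lab)
    v_at <- function(cc) sum(sc >= cc & lab == 1) + sum(sc < cc & lab == 0)
    best <- max(sapply(c(sc, sc - 1e-9, sc + 1e-9), v_at))
    expect_equal(v_at(th), best)
  }
  expect_error(choose_threshold(c(0.1, 0.2), c(1, 1)), "both classes")
})

test_that("the true skill statistic is sensitivity plus specificity minus one", {
  expect_equal(tss(10, 0, 0, 10), 1)
  expect_equal(tss(9, 2, 1, 8), 0.9 + 0.8 - 1)
  # predicting everything positive scores zero
  expect_equal(tss(10, 10, 0, 0), 0)
  expect_error(tss(0, 0, 0, 5), "presence")
})

test_that("differential evolution is reproducible and monotone", {
  sphere <- function(X) rowSums((X - 3)^2)
  a <- de_optimize(sphere, rep(-10, 4), rep(10, 4), pop = 20,
                   generations = 60, seed = 9, trace = TRUE)
  b <- de_optimize(sphere, rep(-10, 4), rep(10, 4), pop = 20,
                   generations = 60, seed = 9, trace = TRUE)
  expect_identical(a, b)
  # elitist selection: the best value never worsens with more generations
  expect_true(all(diff(a$trace) <= 0))
  expect_lt(a$value, 1e-6)
  expect_equal(a$par, rep(3, 4), tolerance = 1e-2)
})

test_that("decoded DE genes always give ordered trapezoids", {
  set.seed(12)
  G <- matrix(runif(18 * 50, 0, 10), 50, 18)
  P <- phytoclim:::decode_population(G)
  for (cols in list(1:4, 5:8, 9:12, 15:18)) {
    expect_true(all(P[, cols[1]] <= P[, cols[2]]))
    expect_true(all(P[, cols[2]] <= P[, cols[3]]))
    expect_true(all(P[, cols[3]] <= P[, cols[4]]))
  }
})

test_that("fitting rejects undersized or degenerate samples", {
  w <- tiny_world()
  cells <- w$forcing$cells
  expect_error(fit_species(cells[1:6], cells[10:20], w$forcing),
               "at least 7")
  expect_error(fit_species(cells[1:10], cells[5:15], w$forcing),
               "disjoint")
})

test_that("a separable sample is fitted to a perfect sample TSS", {
  w <- tiny_world()
  sps <- generate_species(14, w$clim, w$soil, seed = 77, n_occurrences = 60,
                          prevalence_range = c(0.25, 0.6),
                          forcing = w$forcing)
  sp <- sps[[3]]
  cells <- w$forcing$cells
  pres <- cells[sp$occ_cells]
  # absences drawn exactly where the species truly cannot grow
  unsuit <- cells[!sp$true_suitable]
  set.seed(5)
  abs_s <- sample(unsuit, 60)
  fit <- fit_species(pres, abs_s, w$forcing, sp$pathway,
                     generations = 150, pop = 30, seed = 31)
  expect_equal(fit$tss, 1)
  expect_true(fit$accepted)
  # the stored threshold reproduces the confusion matrix behind the TSS
  B <- equilibrium_biomass(fit$params, w$forcing, fit$pathway)
  idx <- match(c(pres, abs_s), cells)
  scores <- suitability_score(B[idx], fit$calib)
  y <- rep(c(1, 0), c(60, 60))
  pred <- scores >= fit$threshold
  again <- tss(sum(pred & y == 1), sum(pred & y == 0),
               sum(!pred & y == 1), sum(!pred & y == 0))
  expect_equal(again, fit$tss)
})

test_that("fit results round-trip through their CSV serialization", {
  f <- structure(
    list(species_id = "sp001", pathway = "C3",
         params = ttr_params(c(0, 5, 20, 30), c(10, 20, 100, 150),
                             c(10, 20, 100, 150), c(0.02, 0.1),
                             c(0, 8, 25, 33)),
         calib = c(b0 = -0.4, b1 = 1.2), threshold = 0.35, tss = 0.91,
         accepted = TRUE, loglik = -12.3, n_presence = 50, n_absence = 50,
         seed = 7L, eps = 1e-6),
    class = "fitted_species_model")
  path <- tempfile(fileext = ".csv")
  write_fit_results(list(f), path)
  got <- read_fit_results(path)[[1]]
  expect_identical(got$params, f$params)
  expect_equal(got$calib, f$calib)
  expect_equal(got$threshold, f$threshold)
  expect_equal(got$tss, f$tss)
  expect_true(got$accepted)
  unlink(path)
})
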