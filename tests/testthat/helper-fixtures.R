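# Shared fixtures, memoised across test files (helpers load once per session).
.fixture_cache <- new.env(parent = emptyenv())

cache_get <- function(key, make) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, make(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# small world used by unit tests
tiny_world <- function() {
  cache_get("tiny_world", function() {
    clim <- generate_climatology(20, 20, seed = 42)
    soil <- simulate_soil_moisture(clim)
    list(clim = clim, soil = soil, forcing = ttr_forcing(clim, soil))
  })
}

# a deliberately broad parameter set that grows over much of the tiny world
broad_params <- function(forcing) {
  w <- range(forcing$moisture)
  ws <- diff(w)
  ttr_params(
    n_temp = c(-5, 5, 26, 34),
    n_moist = c(w[1] - 1, w[1] + 0.15 * ws, w[2] - 0.05 * ws, w[2] + 1),
    c_moist = c(w[1] - 1, w[1] + 0.15 * ws, w[2] - 0.05 * ws, w[2] + 1),
    c_nitrogen = c(0.01, 0.1),
    g_temp = c(-2, 8, 24, 33)
  )
}

# independent R re-implementation of the monthly transport-resistance update,
# written directly from the documented equations; used as the step-through
# oracle against the compiled kernel
oracle_ttr_step <- function(state, tmean, moisture, amax, params, konst) {
  p <- ttr_params_vector(params)
  tz <- function(x, b) {
    if (x <= b[1] || x >= b[4]) return(0)
    if (x < b[2]) return((x - b[1]) / (b[2] - b[1]))
    if (x <= b[3]) return(1)
    (b[4] - x) / (b[4] - b[3])
  }
  Ms <- max(state[1], konst$mass_min); Mr <- max(state[2], konst$mass_min)
  B <- state[1] + state[2]
  dens <- 1 / (1 + B / konst$k_b)
  cs <- state[3] / Ms; cr <- state[4] / Mr
  ns <- state[5] / Ms; nr <- state[6] / Mr
  modC <- tz(moisture, p[9:12])
  modN <- tz(tmean, p[1:4]) * tz(moisture, p[5:8])
  modG <- tz(tmean, p[15:18])
  Uc <- amax * modC * (p[14] + (1 - p[14]) * ns / (ns + p[13])) * Ms * dens
  Un <- konst$sigma_n * modN * Mr * dens
  Tc <- (cs - cr) / konst$r_c * min(Ms, Mr)
  Tn <- (nr - ns) / konst$r_n * min(Ms, Mr)
  Tc <- min(Tc, state[3] + Uc); Tc <- max(Tc, -state[4])
  Tn <- min(Tn, state[6] + Un); Tn <- max(Tn, -state[5])
  csA <- state[3] + Uc - Tc; crA <- state[4] + Tc
  nsA <- state[5] + Tn; nrA <- state[6] + Un - Tn
  Gs <- konst$k_g * modG * cs * ns * Ms
  Gr <- konst$k_g * modG * cr * nr * Mr
  Gs <- max(0, min(Gs, csA / konst$f_c, nsA / konst$f_n))
  Gr <- max(0, min(Gr, crA / konst$f_c, nrA / konst$f_n))
  out <- c(
    shoot_mass = state[[1]] + Gs - konst$loss_shoot * state[[1]],
    root_mass = state[[2]] + Gr - konst$loss_root * state[[2]],
    shoot_c = csA - konst$f_c * Gs,
    root_c = crA - konst$f_c * Gr,
    shoot_n = nsA - konst$f_n * Gs,
    root_n = nrA - konst$f_n * Gr
  )
  pmax(out, 0)
}
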