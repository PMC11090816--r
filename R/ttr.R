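#' Trapezoidal environmental response function
#'
#' Piecewise-linear response used throughout the growth model: 0 outside
#' `(p1, p4)`, 1 on `[p2, p3]`, linear on the rising and falling limbs.
#' Breakpoints must be non-decreasing; equal breakpoints give step edges.
#'
#' @param x scalar or vector of forcing values.
#' @param p1,p2,p3,p4 breakpoints, `p1 <= p2 <= p3 <= p4`.
#' @return response in `[0, 1]`, same length as `x`.
#' @export
trapezoid <- function(x, p1, p2, p3, p4) {
  if (!(p1 <= p2 && p2 <= p3 && p3 <= p4)) {
    stopf("argument error: trapezoid breakpoints must satisfy p1 <= p2 <= p3 <= p4")
  }
  out <- numeric(length(x))
  rising <- x > p1 & x < p2
  if (p2 > p1) out[rising] <- (x[rising] - p1) / (p2 - p1)
  out[x >= p2 & x <= p3] <- 1
  falling <- x > p3 & x < p4
  if (p4 > p3) out[falling] <- (p4 - x[falling]) / (p4 - p3)
  out
}

#' Species parameter set of the growth model
#'
#' The 18 species-specific parameters: trapezoid breakpoints for nitrogen
#' uptake versus temperature (`n_temp`, degC) and soil moisture (`n_moist`,
#' mm), carbon uptake versus soil moisture (`c_moist`, mm), the
#' half-saturation and floor of the shoot-nitrogen dependence of carbon
#' uptake (`c_nitrogen`), and growth versus temperature (`g_temp`, degC).
#' Everything else in the model is universal (see [ttr_constants()]).
#'
#' @param n_temp,n_moist,c_moist,g_temp length-4 non-decreasing breakpoints.
#' @param c_nitrogen length-2: half-saturation (> 0) and floor in `[0, 1]`.
#' @return object of class `ttr_params`.
#' @export
ttr_params <- function(n_temp, n_moist, c_moist, c_nitrogen, g_temp) {
  chk <- function(p, nm) {
    if (length(p) != 4L || any(diff(p) < 0)) {
      stopf("argument error: %s must be 4 non-decreasing breakpoints", nm)
    }
  }
  chk(n_temp, "n_temp"); chk(n_moist, "n_moist")
  chk(c_moist, "c_moist"); chk(g_temp, "g_temp")
  if (length(c_nitrogen) != 2L || c_nitrogen[1] <= 0 ||
      c_nitrogen[2] < 0 || c_nitrogen[2] > 1) {
    stopf("argument error: c_nitrogen must be (half-saturation > 0, floor in [0,1])")
  }
  structure(list(n_temp = as.numeric(n_temp), n_moist = as.numeric(n_moist),
                 c_moist = as.numeric(c_moist),
                 c_nitrogen = as.numeric(c_nitrogen),
                 g_temp = as.numeric(g_temp)),
            class = "ttr_params")
}

#' @rdname ttr_params
#' @param params a `ttr_params` object.
#' @export
ttr_params_vector <- function(params) {
  stopifnot(inherits(params, "ttr_params"))
  c(params$n_temp, params$n_moist, params$c_moist, params$c_nitrogen,
    params$g_temp)
}

#' @rdname ttr_params
#' @param v numeric length-18 vector in the canonical order
#'   (n_temp, n_moist, c_moist, c_nitrogen, g_temp).
#' @export
ttr_params_from_vector <- function(v) {
  stopifnot(length(v) == 18L)
  ttr_params(v[1:4], v[5:8], v[9:12], v[13:14], v[15:18])
}

#' Universal constants of the growth model
#'
#' All species share these constants; species differ only in their 18
#' response parameters. Units are arbitrary mass units (amu) per plant and
#' months. `sigma_n` is the maximum specific nitrogen uptake rate (soil
#' nitrogen is assumed uniform across cells), `k_g` the growth coefficient,
#' `r_c`/`r_n` transport resistances, `f_c`/`f_n` the carbon/nitrogen
#' fractions of structural mass, `loss_*` first-order litter rates, `k_b`
#' the self-shading biomass scale of the uptake density dependence,
#' `init_*` the common initial state, and `b_floor` the biomass below which
#' a cell is considered unable to support the species.
#'
#' @param ... name-value overrides of individual constants.
#' @return named list of constants.
#' @export
ttr_constants <- function(...) {
  konst <- list(
    sigma_n = 0.05, k_g = 25, r_c = 1, r_n = 1,
    f_c = 0.45, f_n = 0.02, loss_shoot = 0.05, loss_root = 0.05,
    k_b = 10, init_mass = 0.5, init_substrate = 0.05,
    mass_min = 1e-6, b_floor = 0.05
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(konst))
  if (length(unknown)) stopf("unknown constant(s): %s", paste(unknown, collapse = ", "))
  konst[names(over)] <- over
  konst
}

#' Universal monthly carbon-uptake ceiling
#'
#' Farquhar-style colimitation of potential carbon assimilation by light,
#' temperature and CO2, with separate C3 and C4 parameterizations. The
#' ceiling is the minimum of a light-limited rate (saturating in radiation)
#' and a Rubisco/CO2-limited rate (saturating in CO2; the C4 pathway is
#' nearly CO2-saturated above ~400 ppm), scaled by a temperature response
#' peaking at an intermediate optimum (higher for C4). The ceiling is
#' universal: all species of a pathway share it, and species-specific
#' moisture and shoot-nitrogen dependencies can only reduce it.
#'
#' @param tmean temperature (degC), scalar or array.
#' @param radiation solar radiation (MJ m-2 day-1, >= 0).
#' @param co2 atmospheric CO2 (ppm, > 0).
#' @param pathway `"C3"` or `"C4"`.
#' @return maximum specific uptake rate (amu amu-1 month-1), same shape as
#'   the broadcast inputs.
#' @export
uptake_ceiling <- function(tmean, radiation, co2, pathway = c("C3", "C4")) {
  pathway <- match.arg(pathway)
  if (any(radiation < 0, na.rm = TRUE)) stopf("argument error: radiation must be >= 0")
  if (any(co2 <= 0)) stopf("argument error: co2 must be > 0")
  light <- 1 - exp(-radiation / 10)
  if (pathway == "C3") {
    ftemp <- exp(-((tmean - 22) / 14)^2)
    cco2 <- co2 / (co2 + 300)
  } else {
    ftemp <- exp(-((tmean - 30) / 13)^2)
    cco2 <- co2 / (co2 + 40)
  }
  0.6 * ftemp * pmin(light, cco2)
}

#' Assemble per-cell monthly forcing for growth simulations
#'
#' Extracts land-cell monthly mean temperature and plant-available soil
#' moisture and precomputes the universal C3 and C4 uptake ceilings, so that
#' repeated species simulations (and every Differential Evolution candidate)
#' reuse them.
#'
#' @param clim a [phy_climatology()].
#' @param soil a `phy_soil_moisture` from [simulate_soil_moisture()].
#' @param cells optional row-major cell indices (default: all land cells).
#' @return list with `tmean`, `moisture`, `amax_c3`, `amax_c4`
#'   (`ncell x 12` matrices), `cells`, `co2` and `grid`.
#' @export
ttr_forcing <- function(clim, soil, cells = NULL) {
  g <- clim$grid
  if (is.null(cells)) cells <- land_indices(g)
  pick <- function(stack) {
    out <- matrix(NA_real_, length(cells), 12L)
    for (m in 1:12) out[, m] <- layer_as_vector(stack[, , m])[cells]
    out
  }
  tm <- pick(clim$tmean)
  rad <- pick(clim$radiation)
  w <- pick(soil$moisture)
  list(
    tmean = tm, moisture = w,
    amax_c3 = uptake_ceiling(tm, rad, clim$co2, "C3"),
    amax_c4 = uptake_ceiling(tm, rad, clim$co2, "C4"),
    cells = cells, co2 = clim$co2, grid = g
  )
}

#' One monthly step of the transport-resistance dynamics
#'
#' Advances the six-pool state (shoot/root structural mass, carbon and
#' nitrogen substrate) by one month under the given forcing. Exposed mainly
#' for inspection and testing; simulations use [equilibrium_biomass()].
#'
#' @param state named numeric length-6: `shoot_mass`, `root_mass`,
#'   `shoot_c`, `root_c`, `shoot_n`, `root_n`.
#' @param tmean temperature (degC) of the month.
#' @param moisture plant-available soil moisture (mm) of the month.
#' @param amax universal uptake ceiling of the cell-month.
#' @param params a [ttr_params()].
#' @param constants a [ttr_constants()] list.
#' @return updated state vector with attributes `c_uptake` and `c_litter`
#'   (carbon flux bookkeeping of the step).
#' @export
ttr_step <- function(state, tmean, moisture, amax, params,
                     constants = ttr_constants()) {
  if (any(!is.finite(state))) stopf("numerical error: non-finite pool in state")
  ttr_step_cpp(as.numeric(state), tmean, moisture, amax,
               ttr_params_vector(params), constants)
}

#' Equilibrium biomass under an annual forcing cycle
#'
#' Repeats the 12-month forcing cycle from a fixed small initial state until
#' the annual-mean total biomass changes by less than `tol` (relative)
#' between consecutive cycles, or `max_cycles` is reached. Biomass below the
#' universal floor is returned as 0 (the cell cannot support the species).
#'
#' @param params a [ttr_params()] or length-18 numeric vector.
#' @param forcing a forcing list from [ttr_forcing()], or a list with
#'   `tmean` and `moisture` matrices.
#' @param pathway `"C3"` or `"C4"`: selects the uptake-ceiling surface.
#' @param constants a [ttr_constants()] list.
#' @param tol relative convergence tolerance on annual-mean biomass.
#' @param max_cycles maximum annual cycles.
#' @param warn if `TRUE`, warn when some cells hit `max_cycles` without
#'   settling (their last-cycle mean is still returned).
#' @return numeric vector of equilibrium biomass, one per forcing cell,
#'   with a logical `converged` attribute flagging cells that reached the
#'   tolerance. Cells near the niche edge relax arbitrarily slowly and may
#'   stay flagged at any finite cycle budget.
#' @export
equilibrium_biomass <- function(params, forcing, pathway = c("C3", "C4"),
                                constants = ttr_constants(),
                                tol = 1e-4, max_cycles = 80L, warn = FALSE) {
  pathway <- match.arg(pathway)
  par <- if (inherits(params, "ttr_params")) ttr_params_vector(params) else as.numeric(params)
  stopifnot(length(par) == 18L)
  amax <- if (pathway == "C3") forcing$amax_c3 else forcing$amax_c4
  B <- ttr_equilibrium_cpp(par, forcing$tmean, forcing$moisture, amax,
                           constants, tol, as.integer(max_cycles))
  if (any(!is.finite(B))) {
    stopf("numerical error: non-finite biomass in %d cells", sum(!is.finite(B)))
  }
  if (warn && !all(attr(B, "converged"))) {
    warning(sprintf("%d cells did not settle within %d cycles; returning last-cycle means",
                    sum(!attr(B, "converged")), max_cycles))
  }
  B
}
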