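#' Hargreaves potential evapotranspiration
#'
#' Monthly reference PET from monthly temperature statistics and solar
#' radiation, in the classical Hargreaves form
#' `PET = 0.0023 * 0.408 * Ra * (Tmean + 17.8) * sqrt(Tmax - Tmin)` (mm/day),
#' scaled by the number of days in the month and floored at zero. The 0.408
#' factor converts MJ m-2 day-1 to mm/day of evaporative equivalent.
#'
#' @param tmin,tmean,tmax monthly temperatures (degC); `tmax >= tmin`.
#' @param ra solar radiation (MJ m-2 day-1).
#' @param days days in the month.
#' @return PET in mm/month; vectorized over all arguments.
#' @export
hargreaves_pet <- function(tmin, tmean, tmax, ra, days = 30) {
  if (any(tmax < tmin, na.rm = TRUE)) {
    stopf("argument error: tmax < tmin in %d element(s)",
          sum(tmax < tmin, na.rm = TRUE))
  }
  pmax(0, 0.0023 * 0.408 * ra * (tmean + 17.8) * sqrt(tmax - tmin)) * days
}

#' Monthly plant-available soil moisture from a bucket model
#'
#' Runs a single-layer soil water bucket per cell: each month the store gains
#' precipitation, loses actual evapotranspiration
#' `AET = min(PET * f(W), W + P - wp)` with the soil-limited reduction
#' `f(W) = (W - wp) / (fc - wp)`, and is clamped into `[wp, fc]` (excess above
#' field capacity is lost to runoff/drainage). The annual cycle is iterated
#' until the January store changes by less than `tol` mm between consecutive
#' years (periodic steady state). Moisture is not influenced by vegetation.
#'
#' @param clim a [phy_climatology()].
#' @param tol convergence tolerance on the January store (mm).
#' @param max_cycles maximum annual cycles.
#' @param init `"fc"` or `"wp"`: start the store at field capacity or wilting
#'   point (the steady state is the same; exposed for uniqueness checks).
#' @return object of class `phy_soil_moisture`: list with `moisture` and
#'   `pet` stacks (`n_rows x n_cols x 12`), `aet` and `runoff` stacks for the
#'   converged cycle, and `converged` logical matrix.
#' @export
simulate_soil_moisture <- function(clim, tol = 0.01, max_cycles = 50L,
                                   init = c("fc", "wp")) {
  init <- match.arg(init)
  validate_climatology(clim)
  g <- clim$grid
  dm <- days_in_month()
  pet <- array(0, c(g$n_rows, g$n_cols, 12L))
  for (m in 1:12) {
    pet[, , m] <- hargreaves_pet(clim$tmin[, , m], clim$tmean[, , m],
                                 clim$tmax[, , m], clim$radiation[, , m],
                                 dm[m])
  }
  fc <- clim$field_capacity
  wp <- clim$wilting_point
  cap <- pmax(fc - wp, 1e-9)
  W <- if (init == "fc") fc else wp
  moisture <- array(NA_real_, c(g$n_rows, g$n_cols, 12L))
  aet <- array(NA_real_, c(g$n_rows, g$n_cols, 12L))
  runoff <- array(NA_real_, c(g$n_rows, g$n_cols, 12L))
  W_jan_prev <- W + Inf
  converged <- matrix(FALSE, g$n_rows, g$n_cols)
  for (cycle in seq_len(max_cycles)) {
    W_jan <- W
    for (m in 1:12) {
      moisture[, , m] <- W
      P <- clim$precip[, , m]
      f <- pmin(pmax((W - wp) / cap, 0), 1)
      AET <- pmin(pet[, , m] * f, pmax(W + P - wp, 0))
      Wn <- W + P - AET
      loss <- pmax(Wn - fc, 0)
      W <- pmin(pmax(Wn, wp), fc)
      aet[, , m] <- AET
      runoff[, , m] <- loss
    }
    converged <- abs(W - W_jan) < tol
    if (all(converged[g$land_mask])) break
    W_jan_prev <- W_jan
  }
  if (!all(converged[g$land_mask])) {
    n <- sum(!converged[g$land_mask])
    stopf("numerical error: soil moisture failed to converge in %d land cells after %d cycles",
          n, max_cycles)
  }
  structure(
    list(moisture = moisture, pet = pet, aet = aet, runoff = runoff,
         converged = converged, grid = g),
    class = "phy_soil_moisture"
  )
}
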