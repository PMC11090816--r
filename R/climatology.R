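#' Monthly climatology container
#'
#' Bundles the monthly forcing a growth simulation needs: minimum, mean and
#' maximum temperature (degC), precipitation (mm/month) and solar radiation
#' (MJ m-2 day-1) as 12-layer stacks, static soil field capacity and wilting
#' point (mm of plant-available storage), and the scalar atmospheric CO2
#' concentration (ppm). CO2 is scenario metadata, not a raster band: analyses
#' use single scalars per scenario.
#'
#' Monthly stacks are arrays `n_rows x n_cols x 12`; static layers are
#' matrices. Non-land cells may hold values; they are ignored downstream.
#'
#' @param grid a [phy_grid()].
#' @param tmin,tmean,tmax monthly temperature stacks (degC).
#' @param precip monthly precipitation stack (mm/month, >= 0).
#' @param radiation monthly solar radiation stack (MJ m-2 day-1, >= 0).
#' @param field_capacity,wilting_point static soil layers (mm),
#'   `0 <= wilting_point <= field_capacity`.
#' @param co2 scalar atmospheric CO2 (ppm, > 0).
#' @return an object of class `phy_climatology`.
#' @export
phy_climatology <- function(grid, tmin, tmean, tmax, precip, radiation,
                            field_capacity, wilting_point, co2 = 338) {
  obj <- structure(
    list(grid = grid, tmin = tmin, tmean = tmean, tmax = tmax,
         precip = precip, radiation = radiation,
         field_capacity = field_capacity, wilting_point = wilting_point,
         co2 = co2),
    class = "phy_climatology"
  )
  validate_climatology(obj)
  obj
}

#' Validate a climatology against its type invariants
#'
#' Checks layer shapes, `tmin <= tmean <= tmax` per cell and month (on land),
#' non-negative precipitation and radiation, `0 <= wp <= fc`, and `co2 > 0`.
#' Violations raise an error listing the offending variable and cell count.
#'
#' @param clim a [phy_climatology()].
#' @return `clim`, invisibly.
#' @export
validate_climatology <- function(clim) {
  g <- clim$grid
  stopifnot(inherits(g, "phy_grid"))
  d3 <- c(g$n_rows, g$n_cols, 12L)
  for (v in c("tmin", "tmean", "tmax", "precip", "radiation")) {
    if (!identical(dim(clim[[v]]), d3)) {
      stopf("format error: %s must be %d x %d x 12", v, g$n_rows, g$n_cols)
    }
  }
  for (v in c("field_capacity", "wilting_point")) {
    if (!identical(dim(clim[[v]]), d3[1:2])) {
      stopf("format error: %s must be %d x %d", v, g$n_rows, g$n_cols)
    }
  }
  land <- array(g$land_mask, dim = d3)
  bad <- function(cond, what) {
    n <- sum(cond & land, na.rm = TRUE)
    if (n > 0) stopf("validation error: %s violated in %d land cell-months", what, n)
  }
  bad(clim$tmin > clim$tmean + 1e-9, "tmin <= tmean")
  bad(clim$tmean > clim$tmax + 1e-9, "tmean <= tmax")
  bad(clim$precip < 0, "precip >= 0")
  bad(clim$radiation < 0, "radiation >= 0")
  land2 <- g$land_mask
  if (any((clim$wilting_point < 0)[land2], na.rm = TRUE) ||
      any((clim$wilting_point > clim$field_capacity + 1e-9)[land2], na.rm = TRUE)) {
    stopf("validation error: 0 <= wilting_point <= field_capacity violated")
  }
  if (!is.numeric(clim$co2) || length(clim$co2) != 1L || clim$co2 <= 0) {
    stopf("validation error: co2 must be a positive scalar (ppm)")
  }
  invisible(clim)
}

#' @export
print.phy_climatology <- function(x, ...) {
  cat(sprintf("<phy_climatology> %d x %d grid, CO2 %.0f ppm\n",
              x$grid$n_rows, x$grid$n_cols, x$co2))
  invisible(x)
}

clim_vars <- c("tmin", "tmean", "tmax", "precip", "radiation")

#' Write a climatology to a plain-text dataset directory
#'
#' Serializes grid metadata and CO2 to `meta.json` and all layers to a single
#' long-format `layers.csv` (columns `variable`, `month`, `row`, `col`,
#' `value`; static layers carry `month = 0`). The format is self-describing
#' and round-trips to full double precision.
#'
#' @param clim a [phy_climatology()].
#' @param path directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
write_climatology <- function(clim, path) {
  validate_climatology(clim)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  g <- clim$grid
  meta <- list(
    format = "phytoclim-grid-csv", version = 1L,
    n_rows = g$n_rows, n_cols = g$n_cols, cell_size = g$cell_size,
    origin = g$origin, co2 = clim$co2
  )
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  tabs <- list()
  for (v in clim_vars) {
    a <- clim[[v]]
    tabs[[v]] <- data.table::data.table(
      variable = v,
      month = rep(1:12, each = g$n_rows * g$n_cols),
      row = rep(rep(seq_len(g$n_rows), times = g$n_cols), times = 12),
      col = rep(rep(seq_len(g$n_cols), each = g$n_rows), times = 12),
      value = as.vector(a)
    )
  }
  for (v in c("field_capacity", "wilting_point")) {
    m <- clim[[v]]
    tabs[[v]] <- data.table::data.table(
      variable = v, month = 0L,
      row = rep(seq_len(g$n_rows), times = g$n_cols),
      col = rep(seq_len(g$n_cols), each = g$n_rows),
      value = as.vector(m)
    )
  }
  mask <- data.table::data.table(
    variable = "land_mask", month = 0L,
    row = rep(seq_len(g$n_rows), times = g$n_cols),
    col = rep(seq_len(g$n_cols), each = g$n_rows),
    value = as.numeric(as.vector(g$land_mask))
  )
  all <- data.table::rbindlist(c(tabs, list(mask)))
  data.table::fwrite(all, file.path(path, "layers.csv"))
  invisible(path)
}

#' Read a climatology from a plain-text dataset directory
#'
#' Inverse of [write_climatology()]. Missing variables or months raise a
#' format error naming the offender; invariant violations raise a validation
#' error. `co2` may be overridden (e.g. supplied via a sidecar config when a
#' dataset lacks it).
#'
#' @param path dataset directory.
#' @param co2 optional scalar overriding the stored CO2 (ppm).
#' @return a [phy_climatology()].
#' @export
read_climatology <- function(path, co2 = NULL) {
  metaf <- file.path(path, "meta.json")
  layf <- file.path(path, "layers.csv")
  if (!file.exists(metaf) || !file.exists(layf)) {
    stopf("format error: %s is not a phytoclim dataset directory", path)
  }
  meta <- jsonlite::read_json(metaf, simplifyVector = TRUE)
  dt <- data.table::fread(layf)
  nr <- meta$n_rows; nc <- meta$n_cols
  take_stack <- function(v) {
    a <- array(NA_real_, c(nr, nc, 12L))
    for (m in 1:12) {
      sub <- dt[dt$variable == v & dt$month == m, ]
      if (nrow(sub) != nr * nc) {
        stopf("format error: missing or incomplete band '%s month %d'", v, m)
      }
      a[cbind(sub$row, sub$col, m)] <- sub$value
    }
    a
  }
  take_static <- function(v) {
    sub <- dt[dt$variable == v & dt$month == 0L, ]
    if (nrow(sub) != nr * nc) stopf("format error: missing static layer '%s'", v)
    m <- matrix(NA_real_, nr, nc)
    m[cbind(sub$row, sub$col)] <- sub$value
    m
  }
  mask <- take_static("land_mask") > 0.5
  grid <- phy_grid(nr, nc, meta$cell_size, unlist(meta$origin), mask)
  phy_climatology(
    grid,
    tmin = take_stack("tmin"), tmean = take_stack("tmean"),
    tmax = take_stack("tmax"), precip = take_stack("precip"),
    radiation = take_stack("radiation"),
    field_capacity = take_static("field_capacity"),
    wilting_point = take_static("wilting_point"),
    co2 = if (is.null(co2)) meta$co2 else co2
  )
}

#' Read species occurrence records
#'
#' Expects a CSV with columns `species_id`, `x`, `y` (projected km).
#'
#' @param path CSV file.
#' @return data.frame of occurrences.
#' @export
read_occurrences <- function(path) {
  df <- as.data.frame(data.table::fread(path))
  need <- c("species_id", "x", "y")
  if (!all(need %in% names(df))) {
    stopf("format error: occurrences CSV must have columns %s",
          paste(need, collapse = ", "))
  }
  df[need]
}

#' Read the species-to-growth-form table
#'
#' Expects a CSV with columns `species_id`, `growth_form`.
#'
#' @param path CSV file.
#' @return data.frame mapping species to growth forms.
#' @export
read_growth_forms <- function(path) {
  df <- as.data.frame(data.table::fread(path))
  need <- c("species_id", "growth_form")
  if (!all(need %in% names(df))) {
    stopf("format error: growth-form CSV must have columns %s",
          paste(need, collapse = ", "))
  }
  df[need]
}
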