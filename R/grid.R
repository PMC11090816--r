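#' Equal-area analysis grid
#'
#' Defines the regular equal-area grid shared by all pipeline stages. Rows are
#' indexed top (north) to bottom, columns left to right (row-major); cell
#' coordinates refer to cell centers in projected km. Because cells are equal
#' area, land-cell counts are land-area fractions, which is what the area
#' summaries of the risk stage report.
#'
#' @param n_rows,n_cols grid dimensions (>= 1).
#' @param cell_size cell edge length in km (> 0).
#' @param origin numeric length-2, projected (x, y) of the upper-left corner
#'   of the upper-left cell.
#' @param land_mask logical matrix `n_rows x n_cols`; `TRUE` marks land cells.
#'   Defaults to all-land.
#' @return an object of class `phy_grid`.
#' @export
phy_grid <- function(n_rows, n_cols, cell_size = 25, origin = c(0, 0),
                     land_mask = NULL) {
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  if (n_rows < 1L || n_cols < 1L) stopf("grid dimensions must be >= 1")
  if (!is.numeric(cell_size) || cell_size <= 0) stopf("cell_size must be > 0")
  if (is.null(land_mask)) land_mask <- matrix(TRUE, n_rows, n_cols)
  if (!is.logical(land_mask) || !identical(dim(land_mask), c(n_rows, n_cols))) {
    stopf("land_mask must be a logical %d x %d matrix", n_rows, n_cols)
  }
  structure(
    list(n_rows = n_rows, n_cols = n_cols, cell_size = cell_size,
         origin = as.numeric(origin), land_mask = land_mask),
    class = "phy_grid"
  )
}

#' @export
print.phy_grid <- function(x, ...) {
  cat(sprintf("<phy_grid> %d x %d cells, %.1f km, %d land / %d total\n",
              x$n_rows, x$n_cols, x$cell_size,
              sum(x$land_mask), x$n_rows * x$n_cols))
  invisible(x)
}

#' Cell-center coordinates of a grid
#'
#' @param grid a [phy_grid()].
#' @return data.frame with columns `row`, `col`, `x`, `y` in row-major order.
#' @export
grid_coords <- function(grid) {
  stopifnot(inherits(grid, "phy_grid"))
  row <- rep(seq_len(grid$n_rows), each = grid$n_cols)
  col <- rep(seq_len(grid$n_cols), times = grid$n_rows)
  data.frame(
    row = row, col = col,
    x = grid$origin[1] + (col - 0.5) * grid$cell_size,
    y = grid$origin[2] - (row - 0.5) * grid$cell_size
  )
}

#' Map projected coordinates to row-major cell indices
#'
#' Points outside the grid extent get `NA`.
#'
#' @param grid a [phy_grid()].
#' @param x,y projected coordinates (km).
#' @return integer vector of row-major cell indices (1-based), `NA` outside.
#' @export
cell_index_of <- function(grid, x, y) {
  stopifnot(inherits(grid, "phy_grid"))
  col <- floor((x - grid$origin[1]) / grid$cell_size) + 1
  row <- floor((grid$origin[2] - y) / grid$cell_size) + 1
  ok <- col >= 1 & col <= grid$n_cols & row >= 1 & row <= grid$n_rows
  idx <- ifelse(ok, (row - 1) * grid$n_cols + col, NA_integer_)
  as.integer(idx)
}

# row-major linear indices of land cells
land_indices <- function(grid) {
  which(t(grid$land_mask))  # t() because R matrices are column-major
}

# extract a row-major vector from an n_rows x n_cols matrix layer
layer_as_vector <- function(layer) as.vector(t(layer))

vector_as_layer <- function(v, grid) {
  matrix(v, nrow = grid$n_rows, ncol = grid$n_cols, byrow = TRUE)
}

#' Mask a layer to land cells
#'
#' Sets all non-land cells to `NA`, excluding them from every downstream
#' statistic and distance pool.
#'
#' @param layer numeric matrix matching the mask dimensions.
#' @param mask logical matrix (or a [phy_grid()] whose `land_mask` is used).
#' @return the masked layer.
#' @export
apply_land_mask <- function(layer, mask) {
  if (inherits(mask, "phy_grid")) mask <- mask$land_mask
  if (!identical(dim(layer), dim(mask))) {
    stopf("layer is %s but mask is %s",
          paste(dim(layer), collapse = "x"), paste(dim(mask), collapse = "x"))
  }
  layer[!mask] <- NA_real_
  layer
}

#' Aggregate a fine-resolution layer to a coarser grid
#'
#' Each coarse cell is the mean of its `factor x factor` block of fine cells,
#' over land cells only; blocks with no land become `NA` (masked). Fine grids
#' whose dimensions are not divisible by `factor` are padded with masked cells
#' at the south/east edges, so aggregation is deterministic and mask-safe.
#'
#' @param layer numeric matrix on the fine grid.
#' @param factor integer aggregation factor (>= 1).
#' @param mask optional logical matrix of fine land cells (default: all
#'   finite cells of `layer`).
#' @return list with `values` (coarse matrix, `NA` where no land) and `mask`
#'   (coarse logical land mask).
#' @export
aggregate_grid <- function(layer, factor, mask = NULL) {
  if (!is.numeric(factor) || length(factor) != 1L || factor < 1 ||
      factor != round(factor)) {
    stopf("aggregation factor must be a positive integer")
  }
  factor <- as.integer(factor)
  if (is.null(mask)) mask <- is.finite(layer)
  if (!identical(dim(layer), dim(mask))) stopf("layer/mask shape mismatch")
  nr <- nrow(layer); nc <- ncol(layer)
  NR <- ceiling(nr / factor); NC <- ceiling(nc / factor)
  pl <- matrix(NA_real_, NR * factor, NC * factor)
  pm <- matrix(FALSE, NR * factor, NC * factor)
  pl[seq_len(nr), seq_len(nc)] <- layer
  pm[seq_len(nr), seq_len(nc)] <- mask
  pl[!pm] <- NA_real_
  vals <- matrix(NA_real_, NR, NC)
  cnt <- matrix(0L, NR, NC)
  for (i in seq_len(NR)) {
    ri <- ((i - 1L) * factor + 1L):(i * factor)
    for (j in seq_len(NC)) {
      cj <- ((j - 1L) * factor + 1L):(j * factor)
      block <- pl[ri, cj]
      n <- sum(is.finite(block))
      cnt[i, j] <- n
      if (n > 0L) vals[i, j] <- mean(block[is.finite(block)])
    }
  }
  list(values = vals, mask = cnt > 0L, land_count = cnt)
}
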