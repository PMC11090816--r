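#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's random state
#' afterwards, so package functions never leak changes into the global RNG.
#' All stochastic operations in the package route their randomness through
#' this helper with an explicit seed argument.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

#' Smooth a matrix with a separable box kernel, repeated
#'
#' Repeated box smoothing approximates a Gaussian blur; used to build
#' spatially autocorrelated synthetic fields. Edges are handled by
#' renormalizing over the in-bounds window, so no padding bias.
#'
#' @param m numeric matrix.
#' @param radius half-width of the box window in cells.
#' @param passes number of smoothing passes.
#' @return smoothed matrix of the same dimension.
#' @keywords internal
smooth_field <- function(m, radius = 2L, passes = 2L) {
  if (radius < 1L || passes < 1L) return(m)
  k <- 2L * radius + 1L
  ones <- matrix(1, nrow(m), ncol(m))
  for (p in seq_len(passes)) {
    num <- box_sum(m, radius)
    den <- box_sum(ones, radius)
    m <- num / den
  }
  m
}

# running-sum box filter along both dimensions
box_sum <- function(m, radius) {
  cs <- function(x, r) {
    n <- length(x)
    c0 <- cumsum(x)
    hi <- pmin(seq_len(n) + r, n)
    lo <- pmax(seq_len(n) - r, 1L)
    c0[hi] - c0[lo] + x[lo]
  }
  m <- apply(m, 2L, cs, r = radius)
  t(apply(m, 1L, cs, r = radius))
}

# month lengths used for PET totals (non-leap calendar)
days_in_month <- function() c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
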