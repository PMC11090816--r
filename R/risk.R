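#' Euclidean distance between two phytoclimates
#'
#' `ED(i, j) = sqrt(sum_k (b_k - a_k)^2)` over the growth-form suitability
#' components; the distance underlying all risk indices.
#'
#' @param a,b numeric suitability vectors of equal length (14 in the
#'   standard pipeline), components in `[0, 1]`.
#' @return the distance (>= 0; 0 iff identical).
#' @export
phyto_distance <- function(a, b) {
  if (length(a) != length(b)) {
    stopf("argument error: vectors of length %d vs %d", length(a), length(b))
  }
  sqrt(sum((b - a)^2))
}

# all pairwise distances between the rows of A (n x d) and B (m x d);
# fast quadratic form, accurate to ~1e-8 absolute (cancellation)
cross_distances <- function(A, B) {
  an <- rowSums(A^2); bn <- rowSums(B^2)
  d2 <- outer(an, bn, "+") - 2 * A %*% t(B)
  sqrt(pmax(d2, 0))
}

# exact minimum distance from each row of A to the rows of B: the fast form
# shortlists near-minimal candidates, whose distances are then recomputed
# by the direct sum of squared differences, so results equal a brute-force
# scan to machine precision
min_cross_distance <- function(A, B) {
  d <- cross_distances(A, B)
  n <- nrow(A)
  out <- numeric(n)
  nn <- integer(n)
  for (i in seq_len(n)) {
    di <- d[i, ]
    cand <- which(di <= min(di) + 1e-7)
    exact <- sqrt(colSums((t(B[cand, , drop = FALSE]) - A[i, ])^2))
    j <- which.min(exact)  # lowest index on ties
    out[i] <- exact[j]
    nn[i] <- cand[j]
  }
  list(dist = out, nearest = nn)
}

#' Local phytoclimatic change per cell
#'
#' Distance between the ambient and future phytoclimate of the same cell.
#'
#' @param ambient,future matrices `n_cells x n_forms` on the same grid and
#'   mask.
#' @return numeric vector of per-cell distances.
#' @export
local_change <- function(ambient, future) {
  if (!identical(dim(ambient), dim(future))) {
    stopf("error: ambient and future surfaces have different shapes")
  }
  sqrt(rowSums((future - ambient)^2))
}

#' Novelty of future phytoclimates
#'
#' For every future cell, the minimum distance to any cell of the global
#' ambient pool: the distance of a future phytoclimate to its closest
#' ambient analogue. High values mean the future phytoclimate has no
#' present-day analogue.
#'
#' @param future matrix `n_cells x n_forms`.
#' @param ambient_pool matrix of all ambient land-cell phytoclimates.
#' @param block number of future cells per distance block (memory control).
#' @return per-future-cell minimum distance.
#' @export
novelty <- function(future, ambient_pool, block = 2048L) {
  if (nrow(ambient_pool) == 0L) stopf("error: empty ambient pool")
  n <- nrow(future)
  out <- numeric(n)
  for (s in seq(1L, n, by = block)) {
    e <- min(s + block - 1L, n)
    out[s:e] <- min_cross_distance(future[s:e, , drop = FALSE],
                                   ambient_pool)$dist
  }
  out
}

#' Disappearance of ambient phytoclimates
#'
#' Mirror of [novelty()] with the roles of the surfaces swapped: for every
#' ambient cell, the minimum distance to any cell of the global future
#' pool. High values mean the ambient phytoclimate has no close future
#' analogue.
#'
#' @param ambient matrix `n_cells x n_forms`.
#' @param future_pool matrix of all future land-cell phytoclimates.
#' @param block block size.
#' @return per-ambient-cell minimum distance.
#' @export
disappearance <- function(ambient, future_pool, block = 2048L) {
  if (nrow(future_pool) == 0L) stopf("error: empty future pool")
  novelty(ambient, future_pool, block = block)
}

#' Assign future cells to phytoclimatic zones, designating novel cells
#'
#' Every future cell receives the zone label of its nearest ambient cell in
#' suitability space (ties broken by the lowest ambient cell index), unless
#' its novelty exceeds the significance threshold, in which case it is
#' designated novel (label 0).
#'
#' @param future matrix `n_cells x n_forms`.
#' @param ambient matrix of ambient land-cell phytoclimates.
#' @param ambient_labels integer zone labels of the ambient cells.
#' @param threshold significance distance (> 0) from
#'   [significance_threshold()].
#' @param block block size.
#' @return integer labels per future cell; 0 marks novel cells.
#' @export
assign_future_zones <- function(future, ambient, ambient_labels, threshold,
                                block = 2048L) {
  if (length(ambient_labels) != nrow(ambient)) {
    stopf("error: one label per ambient cell is required")
  }
  if (!is.numeric(threshold) || threshold <= 0) {
    stopf("argument error: threshold must be > 0")
  }
  n <- nrow(future)
  lab <- integer(n)
  for (s in seq(1L, n, by = block)) {
    e <- min(s + block - 1L, n)
    mc <- min_cross_distance(future[s:e, , drop = FALSE], ambient)
    l <- ambient_labels[mc$nearest]  # ties resolved to the lowest index
    l[mc$dist > threshold] <- 0L
    lab[s:e] <- l
  }
  lab
}

#' Cellwise median across an ensemble of surfaces
#'
#' Summarizes per-GCM projections by their cellwise median: per growth form
#' for suitability surfaces (feeding zone assignment) or per cell for risk
#' index surfaces (feeding risk maps). Both orders are supported because
#' the analysis uses both.
#'
#' @param members list of matrices (or vectors) on one grid.
#' @return the median surface, same shape as each member.
#' @export
ensemble_median <- function(members) {
  if (length(members) < 1L) stopf("error: at least one ensemble member")
  dims <- lapply(members, dim)
  if (length(unique(vapply(members, length, 1L))) != 1L ||
      length(unique(vapply(dims, paste, "", collapse = "x"))) != 1L) {
    stopf("error: ensemble members have mismatching shapes")
  }
  arr <- simplify2array(members)
  out <- apply(arr, seq_along(dim(arr))[-length(dim(arr))], stats::median)
  if (is.null(dim(members[[1]]))) as.numeric(out) else out
}

#' Fraction of land with an ecologically significant index value
#'
#' On an equal-area grid the cell-count fraction is the area fraction.
#'
#' @param index per-land-cell index values.
#' @param threshold significance threshold.
#' @return fraction of land cells with `index > threshold`.
#' @export
area_fraction_significant <- function(index, threshold) {
  index <- index[is.finite(index)]
  if (length(index) == 0L) stopf("error: empty land pool")
  mean(index > threshold)
}
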