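#' Growth-form suitability surface (the phytoclimatic transform)
#'
#' For every cell and growth form, the proportion of that form's modelled
#' species whose binary suitability map marks the cell suitable. The
#' resulting per-cell vector of proportions is the cell's phytoclimate.
#' Components are independent across forms (no sum constraint).
#'
#' @param binary_maps logical or 0/1 matrix, `n_cells x n_species`.
#' @param forms character vector of growth forms, one per species (column).
#' @param all_forms the form universe (default [growth_forms()]); every
#'   form must have at least one modelled species.
#' @return numeric matrix `n_cells x n_forms` with values in `[0, 1]`,
#'   columns named by form.
#' @export
growth_form_suitability <- function(binary_maps, forms,
                                    all_forms = growth_forms()) {
  binary_maps <- as.matrix(binary_maps) * 1
  if (ncol(binary_maps) != length(forms)) {
    stopf("argument error: one growth form per species column is required")
  }
  unknown <- setdiff(unique(forms), all_forms)
  if (length(unknown)) {
    stopf("validation error: unknown growth form(s): %s",
          paste(unknown, collapse = ", "))
  }
  missing <- setdiff(all_forms, unique(forms))
  if (length(missing)) {
    stopf("error: no modelled species for growth form(s): %s",
          paste(missing, collapse = ", "))
  }
  out <- matrix(NA_real_, nrow(binary_maps), length(all_forms),
                dimnames = list(NULL, all_forms))
  for (f in all_forms) {
    cols <- which(forms == f)
    out[, f] <- rowMeans(binary_maps[, cols, drop = FALSE])
  }
  out
}

#' Cluster phytoclimates into zones with a Gaussian mixture
#'
#' Finite Gaussian mixture model over the per-cell growth-form suitability
#' vectors, using the ellipsoidal equal-shape covariance family ("VEV":
#' varying volume, equal shape, varying orientation). A small seeded jitter
#' can be added to break the exact ties that degenerate synthetic surfaces
#' produce. Optionally scans a range of cluster counts and reports the BIC
#' per count.
#'
#' @param phyto numeric matrix `n_cells x n_forms` of suitability
#'   proportions.
#' @param k number of zones (default 18), or an integer vector to scan; the
#'   BIC-best count is kept.
#' @param seed integer seed (controls the jitter; mixture initialization is
#'   deterministic).
#' @param jitter_sd standard deviation of the tie-breaking jitter (0 to
#'   disable).
#' @return object of class `phyto_zone_model`: `k`, `centroids`
#'   (`k x n_forms`, on the unjittered data), `weights`, `labels` (per
#'   cell), `bic`, `bic_scan` (named vector when `k` was a vector), and the
#'   fitted `mclust` object.
#' @importFrom mclust Mclust mclustBIC
#' @export
fit_zones <- function(phyto, k = 18L, seed = 1, jitter_sd = 1e-4) {
  if (nrow(phyto) < max(k)) {
    stopf("argument error: fewer cells (%d) than clusters (%d)",
          nrow(phyto), max(k))
  }
  x <- phyto
  if (jitter_sd > 0) {
    x <- x + with_seed(seed, matrix(stats::rnorm(length(x), 0, jitter_sd),
                                    nrow(x), ncol(x)))
  }
  fit <- mclust::Mclust(x, G = k, modelNames = "VEV", verbose = FALSE)
  if (is.null(fit)) stopf("error: Gaussian mixture estimation failed for all k")
  labels <- as.integer(fit$classification)
  kk <- fit$G
  centroids <- matrix(NA_real_, kk, ncol(phyto),
                      dimnames = list(NULL, colnames(phyto)))
  for (g in seq_len(kk)) {
    centroids[g, ] <- colMeans(phyto[labels == g, , drop = FALSE])
  }
  bic_scan <- NULL
  if (length(k) > 1L) {
    bs <- fit$BIC[, "VEV"]
    bic_scan <- stats::setNames(as.numeric(bs), rownames(fit$BIC))
  }
  structure(
    list(k = kk, centroids = centroids,
         weights = fit$parameters$pro, labels = labels,
         bic = fit$bic, bic_scan = bic_scan, model = fit),
    class = "phyto_zone_model"
  )
}

#' @export
print.phyto_zone_model <- function(x, ...) {
  cat(sprintf("<phyto_zone_model> %d zones over %d cells, BIC %.1f\n",
              x$k, length(x$labels), x$bic))
  invisible(x)
}

#' Ecological significance threshold from intercentroid distances
#'
#' Computes all pairwise Euclidean distances between the zone centroids in
#' growth-form suitability space and returns their 5th percentile (linear
#' interpolation between order statistics). Index values above this
#' threshold are equivalent to a shift between some pair of phytoclimatic
#' zones and are treated as ecologically significant.
#'
#' @param zones a `phyto_zone_model` (or a centroid matrix) with at least
#'   two centroids.
#' @param probs percentile (default 0.05).
#' @return the threshold distance.
#' @export
significance_threshold <- function(zones, probs = 0.05) {
  centroids <- if (inherits(zones, "phyto_zone_model")) zones$centroids else zones
  if (nrow(centroids) < 2L) stopf("error: at least two centroids are required")
  d <- as.numeric(stats::dist(centroids))
  as.numeric(stats::quantile(d, probs, type = 7))
}

#' Serialize a zone model to JSON
#'
#' Writes centroids, mixture weights, per-cell labels, BIC and the
#' significance threshold to a self-describing JSON file.
#'
#' @param zones a `phyto_zone_model`.
#' @param path JSON file to write.
#' @param threshold optional significance distance to store (default:
#'   computed by [significance_threshold()]).
#' @return `path`, invisibly.
#' @export
write_zone_model <- function(zones, path,
                             threshold = significance_threshold(zones)) {
  obj <- list(
    k = zones$k,
    forms = colnames(zones$centroids),
    centroids = unname(apply(zones$centroids, 1, as.numeric, simplify = FALSE)),
    weights = as.numeric(zones$weights),
    labels = as.integer(zones$labels),
    bic = zones$bic,
    threshold = threshold
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
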