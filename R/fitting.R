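#' Classify land cells into environmental zones
#'
#' CLARA k-medoids clustering of standardized monthly forcing features
#' (tmin, tmean, tmax, precipitation, radiation: 60 features per cell),
#' followed by one reassignment pass of a discriminant analysis of principal
#' components (DAPC): linear discriminant axes are computed on the leading
#' principal components of the features and every cell is moved to the zone
#' with the highest discriminant posterior. The zones stratify presence and
#' pseudo-absence sampling for model fitting.
#'
#' @param clim a [phy_climatology()].
#' @param k number of zones (default 20).
#' @param samples number of CLARA subsamples.
#' @param sampsize subsample size (default `min(200 + 10 * k, n_land)`).
#' @param seed integer seed.
#' @param pca_var fraction of feature variance the retained principal
#'   components must explain.
#' @return object of class `env_zone_model`: `k`, `zone_of_cell` (integer
#'   per land cell), `cells` (land cell indices), `medoids`.
#' @export
classify_env_zones <- function(clim, k = 20L, samples = 10L, sampsize = NULL,
                               seed = 1, pca_var = 0.9) {
  g <- clim$grid
  cells <- land_indices(g)
  n <- length(cells)
  if (k > n) stopf("argument error: k = %d exceeds the %d land cells", k, n)
  feat <- matrix(NA_real_, n, 60L)
  j <- 0L
  for (v in c("tmin", "tmean", "tmax", "precip", "radiation")) {
    for (m in 1:12) {
      j <- j + 1L
      feat[, j] <- layer_as_vector(clim[[v]][, , m])[cells]
    }
  }
  feat <- scale(feat)
  feat[, !is.finite(colSums(feat))] <- 0  # constant features carry no signal
  if (is.null(sampsize)) sampsize <- min(200L + 10L * k, n)
  with_seed(seed, {
    cl <- cluster::clara(feat, k = k, samples = samples,
                         sampsize = sampsize, pamLike = TRUE, rngR = TRUE)
    labels <- cl$clustering
    # DAPC refinement: LDA on retained principal components, one pass
    pc <- stats::prcomp(feat)
    nv <- which(cumsum(pc$sdev^2) / sum(pc$sdev^2) >= pca_var)[1]
    nv <- max(2L, min(nv, ncol(pc$x)))
    scores <- pc$x[, seq_len(nv), drop = FALSE]
    keep <- table(factor(labels, levels = seq_len(k)))
    if (all(keep >= 2)) {
      ld <- MASS::lda(scores, grouping = factor(labels, levels = seq_len(k)))
      labels <- as.integer(stats::predict(ld, scores)$class)
    }
    structure(
      list(k = as.integer(k), zone_of_cell = labels, cells = cells,
           medoids = cl$medoids),
      class = "env_zone_model"
    )
  })
}

#' Thin occurrence records to one per species and grid cell
#'
#' Records outside the grid are dropped (count reported via a message).
#'
#' @param records data.frame with `species_id`, `x`, `y`.
#' @param grid a [phy_grid()].
#' @return data.frame with an added `cell` column, at most one row per
#'   (species, cell).
#' @export
thin_occurrences <- function(records, grid) {
  cell <- cell_index_of(grid, records$x, records$y)
  dropped <- sum(is.na(cell))
  if (dropped > 0) {
    message(sprintf("thin_occurrences: dropped %d out-of-grid records", dropped))
  }
  records <- records[!is.na(cell), , drop = FALSE]
  records$cell <- cell[!is.na(cell)]
  dup <- duplicated(records[c("species_id", "cell")])
  records[!dup, , drop = FALSE]
}

# largest-remainder apportionment of `total` among groups with counts n
apportion <- function(n, total) {
  quota <- total * n / sum(n)
  base <- floor(quota)
  rem <- total - sum(base)
  if (rem > 0) {
    frac <- quota - base
    take <- order(frac, decreasing = TRUE)[seq_len(rem)]
    base[take] <- base[take] + 1L
  }
  as.integer(base)
}

#' Stratified subsample of presence cells
#'
#' All presences are used when fewer than `cap` are available; otherwise a
#' seeded stratified sample of `cap` cells whose environmental-zone
#' proportions match the full presence set (largest-remainder
#' apportionment).
#'
#' @param presence_cells land-cell indices of the presences.
#' @param zones an `env_zone_model` from [classify_env_zones()].
#' @param cap sample cap (default 400).
#' @param seed integer seed.
#' @return subset of `presence_cells`.
#' @export
sample_presences <- function(presence_cells, zones, cap = 400L, seed = 1) {
  if (length(presence_cells) < 7L) {
    stopf("rejection error: at least 7 presence cells are required")
  }
  if (length(presence_cells) < cap) return(presence_cells)
  z <- zones$zone_of_cell[match(presence_cells, zones$cells)]
  if (any(is.na(z))) stopf("presence cells missing from the zone model")
  with_seed(seed, {
    zl <- sort(unique(z))
    counts <- vapply(zl, function(u) sum(z == u), 0L)
    take <- apportion(counts, cap)
    out <- integer(0)
    for (i in seq_along(zl)) {
      pool <- presence_cells[z == zl[i]]
      out <- c(out, pool[sample.int(length(pool), min(take[i], length(pool)))])
    }
    sort(out)
  })
}

#' Sample pseudo-absence cells stratified by environmental zone
#'
#' Draws background cells treated as absences. The probability of selecting
#' a cell in a zone is inversely proportional to the zone's proportion in
#' the presence sample, so zones where the species is common are rarely
#' sampled as absences. Zones with no presences receive the minimum observed
#' presence-zone proportion before inverse weighting. Species with at least
#' as many presences as zones get one pseudo-absence per presence; species
#' with fewer presences than zones get exactly 20 to better constrain the
#' fit.
#'
#' @param presence_cells presence sample (land-cell indices).
#' @param zones an `env_zone_model`.
#' @param seed integer seed.
#' @param n_min pseudo-absence count for small species (default 20).
#' @return integer vector of absence cell indices, disjoint from presences.
#' @export
sample_pseudo_absences <- function(presence_cells, zones, seed = 1,
                                   n_min = 20L) {
  z_pres <- zones$zone_of_cell[match(presence_cells, zones$cells)]
  if (any(is.na(z_pres))) stopf("presence cells missing from the zone model")
  k <- zones$k
  n_pres <- length(presence_cells)
  n_abs <- if (n_pres >= k) n_pres else as.integer(n_min)

  prop <- as.numeric(table(factor(z_pres, levels = seq_len(k)))) / n_pres
  minpos <- min(prop[prop > 0])
  prop[prop == 0] <- minpos
  w_zone <- (1 / prop) / sum(1 / prop)

  candidates <- setdiff(zones$cells, presence_cells)
  if (length(candidates) < n_abs) {
    stopf("error: only %d candidate cells for %d pseudo-absences",
          length(candidates), n_abs)
  }
  z_cand <- zones$zone_of_cell[match(candidates, zones$cells)]
  with_seed(seed, {
    # multinomial draw of per-zone counts, then uniform cells within each
    # zone; zones short of candidates spill over to a reweighted redraw
    counts <- as.integer(stats::rmultinom(1, n_abs, w_zone))
    out <- integer(0)
    short <- 0L
    for (zz in seq_len(k)) {
      pool <- candidates[z_cand == zz]
      take <- min(counts[zz], length(pool))
      short <- short + counts[zz] - take
      if (take > 0) out <- c(out, pool[sample.int(length(pool), take)])
    }
    while (short > 0L) {
      left <- setdiff(candidates, out)
      zl <- zones$zone_of_cell[match(left, zones$cells)]
      pick <- sample.int(length(left), min(short, length(left)),
                         prob = w_zone[zl])
      out <- c(out, left[pick])
      short <- short - length(pick)
    }
    sort(out)
  })
}

#' Suitability score from simulated biomass
#'
#' Complementary log-log link on the natural log of equilibrium biomass:
#' `p = 1 - exp(-exp(b0 + b1 * log(B + eps)))`. Strictly increasing in `B`
#' when `b1 > 0`; `eps` keeps the predictor finite at `B = 0`.
#'
#' @param B biomass (>= 0), vectorized.
#' @param calib numeric length-2 `(b0, b1)` calibration coefficients.
#' @param eps biomass offset (default 1e-6).
#' @return suitability probabilities in `(0, 1)`.
#' @export
suitability_score <- function(B, calib, eps = 1e-6) {
  if (any(B < 0, na.rm = TRUE)) stopf("argument error: B must be >= 0")
  lin <- calib[1] + calib[2] * log(B + eps)
  1 - exp(-exp(pmin(lin, 30)))
}

#' True skill statistic
#'
#' `TSS = sensitivity + specificity - 1`, in `[-1, 1]`.
#'
#' @param tp,fp,fn,tn confusion-matrix counts; both margins must be
#'   non-empty (`tp + fn > 0`, `tn + fp > 0`).
#' @return the TSS score.
#' @export
tss <- function(tp, fp, fn, tn) {
  if (tp + fn <= 0 || tn + fp <= 0) {
    stopf("error: TSS needs at least one observed presence and one absence")
  }
  tp / (tp + fn) + tn / (tn + fp) - 1
}

#' Binarization threshold maximizing true positives plus true negatives
#'
#' Scans candidate cutoffs (the observed score values plus midpoints between
#' consecutive distinct scores; prediction is positive when
#' `score >= cutoff`) and returns the cutoff with maximal TP + TN; ties are
#' broken by the lowest qualifying cutoff.
#'
#' @param scores suitability scores.
#' @param labels binary outcomes (1 presence, 0 absence); both classes
#'   required.
#' @return the selected cutoff.
#' @export
choose_threshold <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) {
    stopf("error: threshold selection needs both classes")
  }
  u <- sort(unique(scores))
  cand <- sort(unique(c(u, (u[-1] + u[-length(u)]) / 2)))
  np <- sum(labels == 1L); nn <- sum(labels == 0L)
  best_c <- cand[1]; best_v <- -Inf
  for (cc in cand) {
    pred <- scores >= cc
    v <- sum(pred & labels == 1L) + sum(!pred & labels == 0L)
    if (v > best_v) { best_v <- v; best_c <- cc }
  }
  best_c
}

#' Differential Evolution global optimizer
#'
#' Differential Evolution with binomial crossover and reflection at the box
#' bounds. Two mutation strategies are provided: `"ltobest1"`
#' (local-to-best, the default) moves each candidate toward the current
#' best while adding a random difference vector, and `"rand1"` is the
#' classic DE/rand/1. The objective is evaluated on the whole population at
#' once (a matrix of candidate rows), so expensive vectorized objectives
#' pay their overhead once per generation. Bit-reproducible for a fixed
#' seed; the best objective value is monotonically non-increasing over
#' generations.
#'
#' @param fn objective: function of a `pop x d` matrix returning a numeric
#'   vector of length `pop` (minimized).
#' @param lower,upper numeric bounds of length `d`.
#' @param pop population size (default `10 * d`).
#' @param generations number of generations.
#' @param F differential weight.
#' @param CR crossover probability.
#' @param strategy mutation strategy, `"ltobest1"` or `"rand1"`.
#' @param seed integer seed.
#' @param init optional `pop x d` matrix of initial candidates (clipped to
#'   the bounds); rows beyond `pop` are ignored, missing rows are drawn
#'   uniformly.
#' @param trace if `TRUE`, record the best value per generation.
#' @return list with `par` (best candidate), `value`, and optionally
#'   `trace`.
#' @export
de_optimize <- function(fn, lower, upper, pop = NULL, generations = 1000L,
                        F = 0.8, CR = 0.5,
                        strategy = c("ltobest1", "rand1"),
                        seed = 1, init = NULL, trace = FALSE) {
  strategy <- match.arg(strategy)
  d <- length(lower)
  stopifnot(length(upper) == d, all(upper >= lower))
  if (is.null(pop)) pop <- 10L * d
  pop <- max(4L, as.integer(pop))
  with_seed(seed, {
    X <- matrix(stats::runif(pop * d), pop, d)
    X <- sweep(sweep(X, 2, upper - lower, "*"), 2, lower, "+")
    if (!is.null(init)) {
      init <- as.matrix(init)
      stopifnot(ncol(init) == d)
      take <- min(nrow(init), pop)
      ini <- init[seq_len(take), , drop = FALSE]
      for (j in seq_len(d)) ini[, j] <- pmin(pmax(ini[, j], lower[j]), upper[j])
      X[seq_len(take), ] <- ini
    }
    fX <- fn(X)
    tr <- if (trace) numeric(generations) else NULL
    for (gen in seq_len(generations)) {
      idx <- vapply(seq_len(pop), function(i) {
        sample.int(pop - 1L, 3L)  # indices among the others
      }, integer(3))
      # map "among the others" to actual indices != i
      r <- t(idx)
      for (jj in 1:3) r[, jj] <- ifelse(r[, jj] >= seq_len(pop), r[, jj] + 1L, r[, jj])
      if (strategy == "ltobest1") {
        best <- X[rep(which.min(fX), pop), , drop = FALSE]
        V <- X + F * (best - X) +
          F * (X[r[, 1], , drop = FALSE] - X[r[, 2], , drop = FALSE])
      } else {
        V <- X[r[, 1], , drop = FALSE] +
          F * (X[r[, 2], , drop = FALSE] - X[r[, 3], , drop = FALSE])
      }
      # reflect into bounds
      for (j in seq_len(d)) {
        v <- V[, j]
        lo <- lower[j]; up <- upper[j]
        v <- ifelse(v < lo, pmin(up, 2 * lo - v), v)
        v <- ifelse(v > up, pmax(lo, 2 * up - v), v)
        V[, j] <- pmin(pmax(v, lo), up)
      }
      cross <- matrix(stats::runif(pop * d) < CR, pop, d)
      jrand <- sample.int(d, pop, replace = TRUE)
      cross[cbind(seq_len(pop), jrand)] <- TRUE
      U <- ifelse(cross, V, X)
      fU <- fn(U)
      better <- fU <= fX
      X[better, ] <- U[better, , drop = FALSE]
      fX[better] <- fU[better]
      if (trace) tr[gen] <- min(fX)
    }
    best <- which.min(fX)
    out <- list(par = X[best, ], value = fX[best])
    if (trace) out$trace <- tr
    out
  })
}

# Genes are (p1, plateau offset, rise, fall) deltas per trapezoid so every
# decoded candidate automatically satisfies p1 <= p2 <= p3 <= p4.
decode_genes <- function(g) {
  tr <- function(a) c(a[1], a[1] + a[2], a[1] + a[2] + a[3],
                      a[1] + a[2] + a[3] + a[4])
  c(tr(g[1:4]), tr(g[5:8]), tr(g[9:12]), g[13:14], tr(g[15:18]))
}

decode_population <- function(G) t(apply(G, 1L, decode_genes))

#' Default Differential Evolution search bounds from the climate envelope
#'
#' Gene encoding per trapezoid: lower breakpoint plus three non-negative
#' widths (rising limb, plateau, falling limb), which enforces breakpoint
#' ordering without constraint handling. Bounds derive from the forcing
#' data envelope plus a margin.
#'
#' @param forcing a [ttr_forcing()] list.
#' @param margin fractional envelope extension.
#' @return list with `lower` and `upper` gene bounds (length 18).
#' @export
default_param_bounds <- function(forcing, margin = 0.25) {
  t_rng <- range(forcing$tmean)
  w_rng <- range(forcing$moisture)
  t_span <- diff(t_rng); w_span <- max(diff(w_rng), 1)
  t_lo <- t_rng[1] - margin * t_span; t_hi <- t_rng[2] + margin * t_span
  w_lo <- max(0, w_rng[1] - margin * w_span); w_hi <- w_rng[2] + margin * w_span
  temp_gene <- function() list(lo = c(t_lo, 0, 0, 0),
                               hi = c(t_hi, t_span, 1.5 * t_span, t_span))
  moist_gene <- function() list(lo = c(w_lo, 0, 0, 0),
                                hi = c(w_hi, w_span, 1.5 * w_span, w_span))
  tg <- temp_gene(); wg <- moist_gene()
  list(
    lower = c(tg$lo, wg$lo, wg$lo, c(0.001, 0), tg$lo),
    upper = c(tg$hi, wg$hi, wg$hi, c(0.1, 0.8), tg$hi)
  )
}

#' Fit the growth model for one species by Differential Evolution
#'
#' Searches the 18 species parameters within `bounds`; each candidate is
#' scored by the Bernoulli log-likelihood of the cloglog suitability model
#' at the sample cells, with the calibration coefficients `(b0, b1)`
#' profiled by an inner cloglog regression per candidate. After the search,
#' the binarization threshold maximizing TP + TN is chosen on the fitting
#' sample and the TSS computed from the resulting confusion matrix. Models
#' with sample TSS <= `tss_cutoff` are flagged as not accepted.
#'
#' @param presence_cells,absence_cells disjoint land-cell index sets;
#'   at least 7 presences.
#' @param forcing a [ttr_forcing()] list covering all sample cells.
#' @param pathway `"C3"` or `"C4"`.
#' @param species_id identifier carried into the result.
#' @param generations DE generations (paper-scale default 1000; reduce for
#'   small studies).
#' @param pop DE population size (default `10 * 18`).
#' @param bounds gene bounds (default [default_param_bounds()]).
#' @param constants growth-model constants.
#' @param tss_cutoff acceptance cutoff on the sample TSS (default 0.7).
#' @param seed integer seed.
#' @param eps biomass offset of the cloglog predictor.
#' @param tol,max_cycles equilibrium solver controls.
#' @return object of class `fitted_species_model`: `species_id`, `params`
#'   ([ttr_params()]), `calib`, `threshold`, `tss`, `accepted`, `loglik`,
#'   sample sizes and the seed.
#' @export
fit_species <- function(presence_cells, absence_cells, forcing,
                        pathway = c("C3", "C4"), species_id = "species",
                        generations = 1000L, pop = 180L, bounds = NULL,
                        constants = ttr_constants(), tss_cutoff = 0.7,
                        seed = 1, eps = 1e-6, tol = 1e-4, max_cycles = 80L) {
  pathway <- match.arg(pathway)
  if (length(presence_cells) < 7L) {
    stopf("rejection error: at least 7 presence cells are required (got %d)",
          length(presence_cells))
  }
  if (length(intersect(presence_cells, absence_cells)) > 0L) {
    stopf("argument error: presence and absence cells must be disjoint")
  }
  sample_cells <- c(presence_cells, absence_cells)
  pos <- match(sample_cells, forcing$cells)
  if (any(is.na(pos))) stopf("argument error: forcing does not cover all sample cells")
  y <- c(rep(1L, length(presence_cells)), rep(0L, length(absence_cells)))
  if (length(unique(y)) < 2L) stopf("degenerate-sample error: one outcome class")

  tm <- forcing$tmean[pos, , drop = FALSE]
  wm <- forcing$moisture[pos, , drop = FALSE]
  am <- (if (pathway == "C3") forcing$amax_c3 else forcing$amax_c4)[pos, , drop = FALSE]
  if (is.null(bounds)) bounds <- default_param_bounds(forcing)

  # data-informed initial population: niches centered on the climates of
  # randomly chosen presence cells, so the search starts off the dead
  # plateau where no sample cell can grow
  npres <- length(presence_cells)
  t_ann <- rowMeans(tm[seq_len(npres), , drop = FALSE])
  w_ann <- rowMeans(wm[seq_len(npres), , drop = FALSE])
  t_span <- max(diff(range(forcing$tmean)), 1)
  w_span <- max(diff(range(forcing$moisture)), 1)
  init <- with_seed(seed + 1L, {
    t(vapply(seq_len(pop), function(i) {
      tc <- t_ann[sample.int(npres, 1L)] + stats::rnorm(1, 0, 0.05 * t_span)
      wc <- w_ann[sample.int(npres, 1L)] + stats::rnorm(1, 0, 0.05 * w_span)
      tg <- function(center) {
        pl <- stats::runif(1, 0.1, 0.4) * t_span
        sk <- stats::runif(1, 0.1, 0.4) * t_span
        c(center - pl / 2 - sk, sk, pl, sk)
      }
      wg <- function(center) {
        pl <- stats::runif(1, 0.1, 0.5) * w_span
        sk <- stats::runif(1, 0.1, 0.4) * w_span
        c(center - pl / 2 - sk, sk, pl, sk)
      }
      c(tg(tc), wg(wc), wg(wc), stats::runif(1, 0.005, 0.05),
        stats::runif(1, 0, 0.5), tg(tc))
    }, numeric(18)))
  })

  obj <- function(G) {
    P <- decode_population(G)
    ttr_objective_cpp(P, tm, wm, am, y, constants, tol,
                      as.integer(max_cycles), eps)
  }
  fit <- de_optimize(obj, bounds$lower, bounds$upper, pop = pop,
                     generations = generations, seed = seed, init = init)
  par18 <- decode_genes(fit$par)
  params <- ttr_params_from_vector(par18)

  B <- ttr_equilibrium_cpp(par18, tm, wm, am, constants, tol,
                           as.integer(max_cycles))
  cal <- cloglog_calibrate_cpp(log(B + eps), y)
  calib <- c(b0 = cal$b0, b1 = cal$b1)
  scores <- suitability_score(B, calib, eps)
  threshold <- choose_threshold(scores, y)
  pred <- scores >= threshold
  score <- tss(sum(pred & y == 1L), sum(pred & y == 0L),
               sum(!pred & y == 1L), sum(!pred & y == 0L))
  structure(
    list(species_id = species_id, pathway = pathway, params = params,
         calib = calib, threshold = threshold, tss = score,
         accepted = score > tss_cutoff, loglik = -fit$value,
         n_presence = length(presence_cells),
         n_absence = length(absence_cells), seed = seed, eps = eps),
    class = "fitted_species_model"
  )
}

#' @export
print.fitted_species_model <- function(x, ...) {
  cat(sprintf("<fitted_species_model> %s (%s): TSS %.3f, %s\n",
              x$species_id, x$pathway, x$tss,
              if (x$accepted) "accepted" else "rejected"))
  invisible(x)
}

#' Project a fitted species model onto a forcing grid
#'
#' Simulates equilibrium biomass in every forcing cell, converts it to the
#' cloglog suitability score with the model's calibration, and binarizes
#' with the model's threshold (chosen once, on the fitting sample).
#'
#' @param model a `fitted_species_model`.
#' @param forcing a [ttr_forcing()] list (e.g. all land cells of a
#'   scenario).
#' @param constants growth-model constants.
#' @param tol,max_cycles equilibrium solver controls.
#' @return list with `biomass`, `suitability` and logical `suitable`
#'   vectors over the forcing cells.
#' @export
project_species <- function(model, forcing, constants = ttr_constants(),
                            tol = 1e-4, max_cycles = 80L) {
  B <- equilibrium_biomass(model$params, forcing, model$pathway, constants,
                           tol, max_cycles)
  p <- suitability_score(B, model$calib, model$eps)
  list(biomass = B, suitability = p, suitable = p >= model$threshold)
}

#' Write and read per-species fit results
#'
#' Serializes fitted species models to a flat CSV, one record per species:
#' identifier, pathway, the 18 growth-model parameters, calibration
#' coefficients, binarization threshold, TSS, acceptance flag and seed.
#'
#' @param fits list of `fitted_species_model` objects.
#' @param path CSV file to write.
#' @return `path`, invisibly.
#' @export
write_fit_results <- function(fits, path) {
  rows <- lapply(fits, function(f) {
    p <- ttr_params_vector(f$params)
    names(p) <- paste0("par", seq_len(18))
    c(list(species_id = f$species_id, pathway = f$pathway),
      as.list(p),
      list(b0 = unname(f$calib[1]), b1 = unname(f$calib[2]),
           threshold = f$threshold, tss = f$tss, accepted = f$accepted,
           n_presence = f$n_presence, n_absence = f$n_absence,
           seed = f$seed))
  })
  df <- do.call(rbind, lapply(rows, function(r) as.data.frame(r)))
  data.table::fwrite(df, path)
  invisible(path)
}

#' @rdname write_fit_results
#' @param path CSV file to read.
#' @return for `read_fit_results`, a list of `fitted_species_model`
#'   objects.
#' @export
read_fit_results <- function(path) {
  df <- as.data.frame(data.table::fread(path))
  lapply(seq_len(nrow(df)), function(i) {
    r <- df[i, ]
    structure(
      list(species_id = r$species_id, pathway = r$pathway,
           params = ttr_params_from_vector(as.numeric(r[paste0("par", 1:18)])),
           calib = c(b0 = r$b0, b1 = r$b1), threshold = r$threshold,
           tss = r$tss, accepted = r$accepted, loglik = NA_real_,
           n_presence = r$n_presence, n_absence = r$n_absence,
           seed = r$seed, eps = 1e-6),
      class = "fitted_species_model"
    )
  })
}
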