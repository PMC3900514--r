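#' Stratified survey abundance index
#'
#' Swept-area style design-based total: `N = sum_i A_i * dbar_i` where
#' `dbar_i` is the mean standardised density (N/km^2) over the hauls of
#' depth stratum `i` and `A_i` its area (km^2).  Hauls where the target
#' species/class was absent count as zero-density stations.  Strata with no
#' haul are excluded with a warning (their contribution is undefined).
#'
#' @param hauls long-format haul table with columns `station_id`, `stratum`,
#'   `year`, `species`, `sex`, `length_mm`, `density` (N/km^2); one row per
#'   station x species x sex x length class actually observed, plus at least
#'   one row per sampled station (zero-density rows are fine)
#' @param strata data.frame as from [default_strata()], areas filled in
#' @param species,year target species code and year
#' @param length_mm optional length class (lower edge or midpoint as used in
#'   `hauls`); if NULL, densities are summed over all classes
#' @param sex optional sex filter ("M"/"F"); if NULL both sexes are summed
#' @return total abundance N (individuals)
#' @export
stratified_abundance <- function(hauls, strata, species, year,
                                 length_mm = NULL, sex = NULL) {
  hy <- hauls[hauls$year == year, , drop = FALSE]
  if (nrow(hy) == 0L) stop("no hauls for year ", year)
  if (!all(hy$stratum %in% strata$stratum)) {
    stop("haul references unknown stratum: ",
         paste(setdiff(unique(hy$stratum), strata$stratum), collapse = ", "))
  }
  sel <- hy$species == species
  if (!is.null(sex)) sel <- sel & hy$sex == sex
  if (!is.null(length_mm)) sel <- sel & hy$length_mm == length_mm
  total <- 0
  for (i in seq_len(nrow(strata))) {
    st <- strata$stratum[i]
    stations <- unique(hy$station_id[hy$stratum == st])
    if (length(stations) == 0L) {
      warning("stratum ", st, " has no hauls in year ", year, "; excluded")
      next
    }
    dens <- vapply(stations, function(sid) {
      sum(hy$density[sel & hy$station_id == sid])
    }, numeric(1))
    total <- total + strata$area_km2[i] * mean(dens)
  }
  total
}

#' Length-frequency distribution container
#'
#' @param breaks numeric vector of contiguous class edges (mm), increasing
#' @param counts non-negative counts (or standardised abundances) per class
#' @param species,sex,year labels
#' @return object of class `lfd`
#' @export
lfd <- function(breaks, counts, species = NA, sex = NA, year = NA) {
  stopifnot(length(breaks) == length(counts) + 1L, all(diff(breaks) > 0),
            all(counts >= 0))
  structure(list(breaks = breaks, counts = as.numeric(counts),
                 mids = (breaks[-1] + breaks[-length(breaks)]) / 2,
                 species = species, sex = sex, year = year),
            class = "lfd")
}

#' Build an LFD of stratified abundance indices from haul records
#'
#' @inheritParams stratified_abundance
#' @param breaks length-class edges (mm); haul length classes are matched to
#'   bins by their `length_mm` value
#' @return an `lfd` of stratified total abundances per class
#' @export
build_lfd <- function(hauls, strata, species, sex, year, breaks) {
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  hy <- hauls[hauls$year == year & hauls$species == species &
                hauls$sex == sex, , drop = FALSE]
  lens <- sort(unique(hy$length_mm))
  counts <- numeric(length(mids))
  for (l in lens) {
    bin <- findInterval(l, breaks, rightmost.closed = TRUE)
    if (bin < 1 || bin > length(mids)) next
    counts[bin] <- counts[bin] +
      suppressWarnings(stratified_abundance(hauls, strata, species, year,
                                            length_mm = l, sex = sex))
  }
  lfd(breaks, counts, species = species, sex = sex, year = year)
}

# truncated-normal first and second central moments on [a, b]; far-tail
# bins (vanishing mass) fall back to flat-bin moments for stability
.trunc_norm_moments <- function(a, b, mu, sigma) {
  al <- (a - mu) / sigma
  be <- (b - mu) / sigma
  z <- stats::pnorm(be) - stats::pnorm(al)
  pa <- stats::dnorm(al); pb <- stats::dnorm(be)
  ok <- z > 1e-12
  z[!ok] <- 1
  m <- mu + sigma * (pa - pb) / z
  v <- sigma^2 * (1 + (al * pa - be * pb) / z - ((pa - pb) / z)^2)
  m[!ok] <- ((a + b) / 2)[!ok]
  v[!ok] <- ((b - a)^2 / 12)[!ok]
  list(mean = m, var = pmax(v, 0))
}

# log-likelihood of binned data under a normal mixture (midpoint or exact);
# lo/hi are the bounds of the occupied bins
.mix_loglik <- function(x, w, lo, hi, prop, mu, sigma, method) {
  if (method == "cdf") {
    n_bin <- length(w)
    p <- matrix(0, n_bin, length(prop))
    for (h in seq_along(prop)) {
      p[, h] <- pmax(stats::pnorm(hi, mu[h], sigma[h]) -
                       stats::pnorm(lo, mu[h], sigma[h]), 1e-300)
    }
    dens <- as.vector(p %*% prop)
  } else {
    dens <- rowSums(vapply(seq_along(prop), function(h) {
      prop[h] * stats::dnorm(x, mu[h], sigma[h])
    }, numeric(length(x))))
    dens <- pmax(dens, 1e-300)
  }
  sum(w * log(dens))
}

#' Fit a normal mixture to a binned length-frequency distribution by EM
#'
#' Decomposes an LFD into `K` normal cohort components.  The default
#' (`method = "midpoint"`) runs weighted EM on the bin midpoints, treating
#' each class count as that many observations at the midpoint — the grouped
#' data approximation classically used for cohort splitting.  With
#' `method = "cdf"` the E-step uses exact bin probabilities (CDF
#' differences) and the M-step the corresponding truncated-normal moments.
#' Components are returned in ascending order of mean, which also resolves
#' EM label switching.  Several random restarts are run and the best
#' log-likelihood kept; restarts are seeded deterministically from `seed`.
#'
#' @param x an `lfd`
#' @param K number of components (3 for DPS/HKE, 2 for MUT)
#' @param restarts number of random initialisations (default 10)
#' @param init optional list(prop, mean, sd) used as one additional start
#' @param max_iter,tol EM stopping rule on the log-likelihood change
#' @param method "midpoint" (default) or "cdf"
#' @param seed integer seed for the random restarts
#' @return object of class `mixture_fit` with elements prop, mean, sd,
#'   loglik, converged, identifiable, K, iter
#' @export
fit_mixture <- function(x, K, restarts = 10, init = NULL,
                        max_iter = 500, tol = 1e-8,
                        method = c("midpoint", "cdf"), seed = 1L) {
  method <- match.arg(method)
  stopifnot(inherits(x, "lfd"), K >= 1, sum(x$counts) > 0)
  w <- x$counts
  mids <- x$mids
  keep <- w > 0
  xv <- mids[keep]; wv <- w[keep]
  lo_keep <- x$breaks[-length(x$breaks)][keep]
  hi_keep <- x$breaks[-1][keep]
  wtot <- sum(wv)
  mu0 <- sum(wv * xv) / wtot
  sd0 <- sqrt(sum(wv * (xv - mu0)^2) / wtot)
  bin_w <- min(diff(x$breaks))
  sigma_floor <- max(bin_w / 10, 1e-6)

  run_em <- function(prop, mu, sigma) {
    ll_old <- -Inf
    converged <- FALSE
    iter <- 0L
    n_bin <- length(xv)
    repeat {
      iter <- iter + 1L
      # E-step: responsibilities per (occupied) bin
      if (method == "cdf") {
        p <- matrix(0, n_bin, K)
        for (h in seq_len(K)) {
          p[, h] <- prop[h] *
            pmax(stats::pnorm(hi_keep, mu[h], sigma[h]) -
                   stats::pnorm(lo_keep, mu[h], sigma[h]), 1e-300)
        }
      } else {
        p <- vapply(seq_len(K), function(h) {
          prop[h] * stats::dnorm(xv, mu[h], sigma[h])
        }, numeric(n_bin))
        p <- matrix(p, n_bin, K)
      }
      rs <- rowSums(p)
      zero <- rs <= 0
      if (any(zero)) {
        p[zero, ] <- 1 / K
        rs[zero] <- 1
      }
      r <- p / rs
      # M-step
      nk <- colSums(wv * r)
      prop <- nk / wtot
      if (method == "cdf") {
        for (h in seq_len(K)) {
          tm <- .trunc_norm_moments(lo_keep, hi_keep, mu[h], sigma[h])
          mu[h] <- sum(wv * r[, h] * tm$mean) / nk[h]
          sigma[h] <- sqrt(sum(wv * r[, h] *
                                 (tm$var + (tm$mean - mu[h])^2)) / nk[h])
        }
      } else {
        for (h in seq_len(K)) {
          mu[h] <- sum(wv * r[, h] * xv) / nk[h]
          sigma[h] <- sqrt(sum(wv * r[, h] * (xv - mu[h])^2) / nk[h])
        }
      }
      sigma <- pmax(sigma, sigma_floor)
      prop <- pmax(prop, 1e-12); prop <- prop / sum(prop)
      ll <- .mix_loglik(xv, wv, lo_keep, hi_keep, prop, mu, sigma, method)
      if (ll < ll_old - 1e-6 * max(1, abs(ll_old))) {
        warning("EM log-likelihood decreased (", ll_old, " -> ", ll, ")")
      }
      if (abs(ll - ll_old) < tol * max(1, abs(ll))) {
        converged <- TRUE
        break
      }
      if (iter >= max_iter) break
      ll_old <- ll
    }
    list(prop = prop, mean = mu, sd = sigma, loglik = ll,
         converged = converged, iter = iter)
  }

  starts <- list()
  if (!is.null(init)) {
    starts[[length(starts) + 1L]] <- list(prop = init$prop, mu = init$mean,
                                          sigma = init$sd)
  }
  # quantile-spread deterministic start plus jittered random restarts;
  # with an explicit init and restarts = 1 the init is the only start
  qs <- .weighted_quantile(xv, wv, (seq_len(K) - 0.5) / K)
  if (is.null(init) || restarts > 1) {
    starts[[length(starts) + 1L]] <-
      list(prop = rep(1 / K, K), mu = qs,
           sigma = rep(max(sd0 / K, sigma_floor), K))
  }
  if (restarts > 1) {
    old_seed <- .save_rng()
    on.exit(.restore_rng(old_seed), add = TRUE)
    set.seed(seed)
    for (r in seq_len(restarts - 1)) {
      starts[[length(starts) + 1L]] <- list(
        prop = rep(1 / K, K),
        mu = sort(qs + stats::rnorm(K, 0, sd0 / 2)),
        sigma = rep(max(sd0 / K, sigma_floor), K) *
          stats::runif(K, 0.5, 2))
    }
  }

  best <- NULL
  for (s in starts) {
    fit <- tryCatch(run_em(s$prop, s$mu, s$sigma), error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  if (is.null(best)) stop("all EM starts failed")
  ord <- order(best$mean)
  identifiable <- !any(abs(diff(best$mean[ord])) < sigma_floor &
                         abs(diff(best$sd[ord])) < sigma_floor)
  structure(list(prop = best$prop[ord], mean = best$mean[ord],
                 sd = best$sd[ord], loglik = best$loglik,
                 converged = best$converged,
                 identifiable = identifiable, K = K, iter = best$iter,
                 species = x$species, sex = x$sex, year = x$year,
                 method = method),
            class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("mixture_fit %s/%s year %s: K=%d, logLik=%.2f%s%s\n",
              x$species, x$sex, x$year, x$K, x$loglik,
              if (x$converged) "" else " [not converged]",
              if (x$identifiable) "" else " [non-identifiable]"))
  print(data.frame(cohort = seq_len(x$K), prop = round(x$prop, 4),
                   mean_mm = round(x$mean, 2), sd_mm = round(x$sd, 2)))
  invisible(x)
}

.weighted_quantile <- function(x, w, probs) {
  ord <- order(x)
  x <- x[ord]; w <- w[ord]
  cw <- cumsum(w) / sum(w)
  vapply(probs, function(p) x[which.min(abs(cw - p))], numeric(1))
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.restore_rng <- function(seed) {
  if (is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", seed, envir = globalenv())
  }
}

#' Kolmogorov-Smirnov distance between an LFD and a fitted mixture
#'
#' Sup distance between the empirical CDF of the binned counts (a step
#' function jumping at bin upper edges) and the mixture CDF, evaluated
#' exhaustively at every bin edge (taking both one-sided limits of the step
#' function).  Used descriptively, as is customary for grouped-data cohort
#' fits; no correction for estimated parameters is applied.
#'
#' @param x an `lfd`
#' @param fit a `mixture_fit`
#' @param alpha significance level for the (asymptotic) two-sided decision
#' @return list(D, reject, D_crit, n)
#' @export
ks_distance <- function(x, fit, alpha = 0.05) {
  stopifnot(inherits(x, "lfd"), inherits(fit, "mixture_fit"))
  n <- sum(x$counts)
  if (n <= 0) stop("empty LFD")
  ecdf_right <- c(0, cumsum(x$counts) / n)     # value just after each edge
  mix_cdf <- rowSums(vapply(seq_len(fit$K), function(h) {
    fit$prop[h] * stats::pnorm(x$breaks, fit$mean[h], fit$sd[h])
  }, numeric(length(x$breaks))))
  D <- max(abs(mix_cdf - ecdf_right))
  c_alpha <- sqrt(-log(alpha / 2) / 2)
  D_crit <- c_alpha / sqrt(n)
  list(D = D, reject = D > D_crit, D_crit = D_crit, n = n)
}

#' Split length-class counts across cohorts by posterior responsibility
#'
#' Each class count is divided among the mixture components proportionally
#' to `prop_h * dnorm(midpoint, mean_h, sd_h)`.  Totals are conserved
#' exactly; classes where every component density underflows to zero are
#' split equally with a warning.
#'
#' @param counts numeric vector of per-class counts (or densities)
#' @param mids class midpoints (mm), same length as `counts`
#' @param fit a `mixture_fit`
#' @return list(matrix = classes x cohorts allocation, totals = per-cohort
#'   sums)
#' @export
allocate_cohorts <- function(counts, mids, fit) {
  stopifnot(length(counts) == length(mids))
  K <- fit$K
  dens <- vapply(seq_len(K), function(h) {
    fit$prop[h] * stats::dnorm(mids, fit$mean[h], fit$sd[h])
  }, numeric(length(mids)))
  dens <- matrix(dens, length(mids), K)
  rs <- rowSums(dens)
  zero <- rs <= 0 & counts > 0
  if (any(zero)) {
    warning(sum(zero), " class(es) with zero mixture density split equally")
    dens[rs <= 0, ] <- 1
    rs <- rowSums(dens)
  }
  rs[rs <= 0] <- 1
  alloc <- dens / rs * counts
  list(matrix = alloc, totals = colSums(alloc))
}

#' Per-station cohort abundances for one species, sexes summed
#'
#' Runs [allocate_cohorts()] on each station's per-sex length classes and
#' sums the per-cohort totals across sexes (the sex-specific fits must have
#' the same number of components).
#'
#' @inheritParams stratified_abundance
#' @param fits named list `list(F = , M = )` of `mixture_fit`s for the
#'   species/year
#' @return data.frame with station_id, lon, lat and one column per cohort
#' @export
station_cohorts <- function(hauls, species, year, fits) {
  stopifnot(fits$F$K == fits$M$K)
  K <- fits$F$K
  hy <- hauls[hauls$year == year & hauls$species == species, , drop = FALSE]
  stations <- unique(hauls$station_id[hauls$year == year])
  pos <- hauls[hauls$year == year, c("station_id", "lon", "lat")]
  pos <- pos[!duplicated(pos$station_id), ]
  out <- matrix(0, length(stations), K)
  for (i in seq_along(stations)) {
    for (sx in c("F", "M")) {
      rows <- hy[hy$station_id == stations[i] & hy$sex == sx, , drop = FALSE]
      if (nrow(rows) == 0L) next
      a <- allocate_cohorts(rows$density, rows$length_mm, fits[[sx]])
      out[i, ] <- out[i, ] + a$totals
    }
  }
  colnames(out) <- paste0("cohort", seq_len(K))
  cbind(pos[match(stations, pos$station_id), ], as.data.frame(out))
}

#' Interpolate station cohort abundances to per-cell matrices
#'
#' IDW-interpolates each cohort column of a [station_cohorts()] table onto
#' the grid; the returned matrix has one row per grid cell and one column
#' per cohort, with the grid mask restricted to cells covered for every
#' cohort.
#'
#' @param stations output of [station_cohorts()]
#' @param grid a `grid_spec`
#' @param radius_cells,power IDW parameters (see [idw_interpolate()])
#' @return list(matrix = cells x cohorts, grid = masked grid)
#' @export
cohort_matrix <- function(stations, grid, radius_cells = 3, power = 2) {
  coh_cols <- grep("^cohort", names(stations), value = TRUE)
  mats <- NULL
  g <- grid
  for (cc in coh_cols) {
    st <- data.frame(lon = stations$lon, lat = stations$lat,
                     value = stations[[cc]])
    lay <- idw_interpolate(st, grid, radius_cells = radius_cells,
                           power = power, variable = cc)
    g$active <- g$active & lay$grid$active
    mats <- cbind(mats, lay$values)
  }
  colnames(mats) <- coh_cols
  mats[!g$active, ] <- NA
  list(matrix = mats, grid = g)
}

#' Convert cohort abundances to a biomass layer
#'
#' Per-cell biomass (tons) = sum over cohorts of abundance times the weight
#' at the cohort mean length from the length-weight power law
#' `w = a * L^b` (grams), divided by 1e6 for grams -> tons.
#'
#' @param cohorts cells x cohorts abundance matrix (individuals)
#' @param grid a `grid_spec`
#' @param mean_lengths cohort mean lengths (mm), one per column
#' @param a,b length-weight coefficients (weight in grams, length in mm)
#' @param year year label
#' @return a `cell_layer` in tons
#' @export
biomass_layer <- function(cohorts, grid, mean_lengths, a, b,
                          year = NA_integer_) {
  if (any(mean_lengths < 0)) stop("negative mean length")
  stopifnot(ncol(cohorts) == length(mean_lengths))
  w_g <- a * mean_lengths^b
  vals <- as.vector(cohorts %*% w_g) / 1e6
  cell_layer(grid, vals, variable = "biomass_t", year = year)
}
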