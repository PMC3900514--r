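#' Map vessel pings to annual effort layers
#'
#' Runs the full effort chain on a ping table: per-trip track interpolation
#' at the 10-minute step, speed filtering with the trawling window, and
#' per-cell counting of fishing points.
#'
#' @param pings ping table with columns trip_id, time, lon, lat, year
#' @param grid a `grid_spec`
#' @param v_min,v_max trawling-speed window (knots)
#' @param step_min interpolation step (minutes)
#' @return named list (by year) of `effort_pattern`s
#' @export
map_effort <- function(pings, grid, v_min = 2.0, v_max = 4.5,
                       step_min = 10) {
  years <- sort(unique(pings$year))
  out <- list()
  for (y in years) {
    py <- pings[pings$year == y, , drop = FALSE]
    flagged <- lapply(split(py, py$trip_id), function(trip) {
      trip <- trip[order(trip$time), ]
      reg <- suppressWarnings(interpolate_track(trip, step_min = step_min))
      speed_filter(reg, v_min = v_min, v_max = v_max)
    })
    flagged <- do.call(rbind, flagged)
    out[[as.character(y)]] <- suppressMessages(
      effort_layer(flagged, grid, year = y))
  }
  out
}

#' Fit cohort mixtures to every species/sex/year LFD of a bundle
#'
#' Builds the stratified-abundance LFD for each species, sex and year and
#' decomposes it into the standard number of normal components (3 for DPS
#' and HKE, 2 for MUT).
#'
#' @param world a `synthetic_world` (or any list with `hauls`, `strata`)
#' @param restarts EM restarts per fit (default 4)
#' @param method EM flavour passed to [fit_mixture()]
#' @return nested list `fits[[species]][[year]]` with elements `F` and `M`
#'   (`mixture_fit`s) and `lfd_F`, `lfd_M`
#' @export
fit_survey <- function(world, restarts = 4, method = "midpoint") {
  n_coh <- c(DPS = 3, HKE = 3, MUT = 2)
  bin_mm <- world$truth$bin_mm
  if (is.null(bin_mm)) bin_mm <- c(DPS = 1, HKE = 10, MUT = 5)
  years <- sort(unique(world$hauls$year))
  fits <- list()
  for (sp in names(n_coh)) {
    fits[[sp]] <- list()
    hs <- world$hauls[world$hauls$species == sp, ]
    if (nrow(hs) == 0) next
    bw <- bin_mm[[sp]]
    lo <- floor(min(hs$length_mm) / bw) * bw - bw
    hi <- ceiling(max(hs$length_mm) / bw) * bw + bw
    breaks <- seq(lo, hi, by = bw)
    for (y in years) {
      entry <- list()
      for (sx in c("F", "M")) {
        lf <- build_lfd(world$hauls, world$strata, sp, sx, y, breaks)
        entry[[paste0("lfd_", sx)]] <- lf
        entry[[sx]] <- fit_mixture(lf, K = n_coh[[sp]], restarts = restarts,
                                   method = method, seed = 100 + y)
      }
      fits[[sp]][[as.character(y)]] <- entry
    }
  }
  fits
}

#' Interpolated per-cell cohort abundance matrices for every species/year
#'
#' Allocates station densities to cohorts (per sex) and IDW-interpolates
#' them onto the grid.  Returns both the sexes-summed matrices (used for
#' maps and the bio-economic index) and the sexes-separate matrices (the
#' Elman network keeps sexes as distinct inputs/outputs).
#'
#' Station densities (N/km^2) are interpolated and then multiplied by the
#' cell surface so the matrices hold absolute abundances in individuals.
#'
#' @param world a `synthetic_world`
#' @param fits output of [fit_survey()]
#' @param radius_cells,power IDW parameters
#' @return list with `sum[[sp]][[year]]` and `sex[[sp]][[year]]`
#'   (cells x cohorts matrices, NA outside interpolation coverage) and
#'   `grid[[sp]]` (mask common to all years of the species)
#' @export
build_cohort_layers <- function(world, fits, radius_cells = 3, power = 2) {
  years <- sort(unique(world$hauls$year))
  out <- list(sum = list(), sex = list(), grid = list())
  for (sp in names(fits)) {
    msum <- list(); msex <- list()
    g <- world$grid
    for (y in years) {
      fy <- fits[[sp]][[as.character(y)]]
      parts <- list()
      for (sx in c("F", "M")) {
        hy <- world$hauls[world$hauls$year == y &
                            world$hauls$species == sp &
                            world$hauls$sex == sx, , drop = FALSE]
        stations <- unique(world$hauls$station_id[world$hauls$year == y])
        pos <- world$hauls[world$hauls$year == y,
                           c("station_id", "lon", "lat")]
        pos <- pos[!duplicated(pos$station_id), ]
        K <- fy[[sx]]$K
        tot <- matrix(0, length(stations), K)
        for (i in seq_along(stations)) {
          rows <- hy[hy$station_id == stations[i], , drop = FALSE]
          if (nrow(rows) == 0L) next
          tot[i, ] <- allocate_cohorts(rows$density, rows$length_mm,
                                       fy[[sx]])$totals
        }
        colnames(tot) <- paste0("cohort", seq_len(K), "_", sx)
        st <- cbind(pos[match(stations, pos$station_id), ],
                    as.data.frame(tot))
        names(st)[4:(3 + K)] <- paste0("cohort", seq_len(K))
        cm <- cohort_matrix(st, world$grid, radius_cells = radius_cells,
                            power = power)
        cm$matrix <- cm$matrix * world$cell_area  # N/km^2 -> individuals
        colnames(cm$matrix) <- paste0("cohort", seq_len(K), "_", sx)
        parts[[sx]] <- cm
        g$active <- g$active & cm$grid$active
      }
      msex[[as.character(y)]] <- cbind(parts$F$matrix, parts$M$matrix)
      kf <- ncol(parts$F$matrix)
      msum[[as.character(y)]] <- parts$F$matrix +
        parts$M$matrix[, seq_len(kf), drop = FALSE]
    }
    out$sum[[sp]] <- msum
    out$sex[[sp]] <- msex
    out$grid[[sp]] <- g
  }
  out
}

#' Build the economics context from fitted pipeline pieces
#'
#' Expands the cohort abundances of `index_year` into length classes with
#' the fitted mixtures (each cohort spread over classes in proportion to
#' its normal density), estimates the fleet catchability per species from
#' the reference mortality, fits the fuel-cost model on the bundle's fuel
#' records, and assembles everything into an [econ_context()].
#'
#' @param world a `synthetic_world`
#' @param fits output of [fit_survey()]
#' @param cohorts output of [build_cohort_layers()]
#' @param effort output of [map_effort()]
#' @param index_year year whose abundance field prices the scenarios
#'   (default: last survey year)
#' @param fuel_price scenario fuel price (default: last fuel record)
#' @param params species parameter table
#' @return an `econ_context`
#' @export
build_econ <- function(world, fits, cohorts, effort,
                       index_year = NULL, fuel_price = NULL,
                       params = default_species_params()) {
  years <- sort(unique(world$hauls$year))
  if (is.null(index_year)) index_year <- max(years)
  if (is.null(fuel_price)) fuel_price <- utils::tail(world$fuel$E, 1)
  bin_mm <- world$truth$bin_mm
  if (is.null(bin_mm)) bin_mm <- c(DPS = 1, HKE = 10, MUT = 5)
  cost_model <- fit_cost_model(world$fuel)
  e_now <- effort[[as.character(index_year)]]$counts
  species_data <- list()
  for (sp in names(fits)) {
    fy <- fits[[sp]][[as.character(index_year)]]
    pr <- params[params$species == sp, ]
    bw <- bin_mm[[sp]]
    lo <- floor(min(fy$F$mean - 3 * fy$F$sd, fy$M$mean - 3 * fy$M$sd) / bw)
    hi <- ceiling(max(fy$F$mean + 3 * fy$F$sd, fy$M$mean + 3 * fy$M$sd) / bw)
    mids <- (seq(lo, hi) + 0.5) * bw
    coh_sex <- cohorts$sex[[sp]][[as.character(index_year)]]
    idx <- matrix(0, world$grid$n_cells, length(mids))
    col <- 0L
    for (sx in c("F", "M")) {
      fit <- fy[[sx]]
      for (h in seq_len(fit$K)) {
        col <- col + 1L
        dens <- stats::dnorm(mids, fit$mean[h], fit$sd[h])
        if (sum(dens) > 0) dens <- dens / sum(dens)
        idx <- idx + outer(coh_sex[, col], dens)
      }
    }
    # catchability from reference mortality on absolute standing numbers
    qM <- pr$qM[pr$sex == "F"]
    n_c <- qM * rowSums(idx)
    keep <- !is.na(n_c)
    q_hat <- estimate_q(pr$F_lca[1], n_c[keep], e_now[keep])
    # length-weight: sex-averaged coefficients for the aggregated index
    species_data[[sp]] <- list(
      index = idx, mids = mids, q = q_hat,
      L50 = pr$L50[1], L75 = pr$L75[1], qM = qM,
      a = mean(pr$a), b = mean(pr$b))
  }
  econ_context(world$grid, world$harbors, species_data, cost_model,
               fuel_price, world$prices)
}

# assemble a scaled feature array for prediction, reusing stored scalers
.predict_features <- function(dataset, cohorts, effort, d_mean, d_sd, sst,
                              grid, years) {
  cells <- dataset$cells
  n_coh <- (dim(dataset$X)[3] - 4) / 2
  nb <- lapply(as.character(years), function(y) {
    m <- cohorts[[y]]
    vapply(seq_len(n_coh), function(h) {
      lay <- cell_layer(grid, ifelse(grid$active, m[, h], NA_real_))
      suppressWarnings(neighbor_mean(lay, ray = 2))$values
    }, numeric(grid$n_cells))
  })
  d_in <- dim(dataset$X)[3]
  raw <- array(NA_real_, dim = c(length(cells), 4, d_in))
  for (t in 1:4) {
    y <- as.character(years[t])
    raw[, t, ] <- cbind(
      .log1p10(cohorts[[y]][cells, , drop = FALSE]),
      .log1p10(nb[[t]][cells, , drop = FALSE]),
      .log1p10(effort[[y]][cells]),
      d_mean[cells], d_sd[cells], sst[[y]][cells])
  }
  sc <- dataset$scalers
  X <- raw
  for (j in seq_len(d_in)) {
    rng <- sc$x_max[j] - sc$x_min[j]
    X[, , j] <- if (rng > 0) {
      pmin(pmax((raw[, , j] - sc$x_min[j]) / rng, 0), 1)
    } else 0
  }
  X
}

#' Train the Elman predictors for every species of a bundle
#'
#' @param world a `synthetic_world`
#' @param cohorts output of [build_cohort_layers()] (sexes-separate
#'   matrices feed the network)
#' @param effort output of [map_effort()]
#' @param config an [elman_config()]
#' @return list per species: `net` (`trained_elman`), `dataset`
#' @export
train_predictors <- function(world, cohorts, effort,
                             config = elman_config(restarts = 10)) {
  years <- sort(unique(world$hauls$year))
  stopifnot(length(years) >= 5)
  lag_years <- utils::tail(years, 5)[1:4]
  target <- utils::tail(years, 1)
  out <- list()
  for (sp in names(cohorts$sex)) {
    coh <- cohorts$sex[[sp]]
    eff <- lapply(effort, function(ep) ep$counts)
    ds <- build_dataset(coh, eff, world$d_mean, world$d_sd, world$sst,
                        world$grid, lag_years, target)
    net <- elman_train(ds, config)
    out[[sp]] <- list(net = net, dataset = ds)
  }
  out
}

#' Next-year biomass predictor for scenario simulation
#'
#' Returns a closure mapping a candidate effort pattern to the predicted
#' next-year total biomass (tons) per species: the pattern replaces the
#' last lag year's effort layer, the trained network predicts next-year
#' cohort abundances per cell, and abundances are converted to biomass at
#' the cohort mean lengths with the sex-specific length-weight laws.
#'
#' @param world a `synthetic_world`
#' @param fits output of [fit_survey()]
#' @param cohorts output of [build_cohort_layers()]
#' @param effort output of [map_effort()]
#' @param predictors output of [train_predictors()]
#' @param params species parameter table
#' @return `function(pattern)` returning a named numeric vector of tons
#' @export
make_biomass_predictor <- function(world, fits, cohorts, effort, predictors,
                                   params = default_species_params()) {
  years <- sort(unique(world$hauls$year))
  lag_years <- utils::tail(years, 5)[1:4]
  last_lag <- as.character(utils::tail(lag_years, 1))
  eff0 <- lapply(effort, function(ep) ep$counts)
  function(pattern) {
    eff <- eff0
    eff[[last_lag]] <- pattern$counts
    B <- c()
    for (sp in names(predictors)) {
      pd <- predictors[[sp]]
      X <- .predict_features(pd$dataset, cohorts$sex[[sp]], eff,
                             world$d_mean, world$d_sd, world$sst,
                             world$grid, lag_years)
      pred <- elman_forward(pd$net, X)
      ab <- unscale_targets(pd$dataset, pred)
      fy <- fits[[sp]][[as.character(utils::tail(years, 1))]]
      pr <- params[params$species == sp, ]
      w_g <- c(pr$a[pr$sex == "F"] * fy$F$mean^pr$b[pr$sex == "F"],
               pr$a[pr$sex == "M"] * fy$M$mean^pr$b[pr$sex == "M"])
      B[sp] <- sum(ab %*% w_g) / 1e6
    }
    B
  }
}

#' Run the full pipeline on a synthetic bundle
#'
#' Convenience wrapper chaining [map_effort()], [fit_survey()],
#' [build_cohort_layers()], [build_econ()] and (optionally)
#' [train_predictors()] / [make_biomass_predictor()].
#'
#' @param world a `synthetic_world`
#' @param train_nets train the Elman predictors (default TRUE; needs >= 5
#'   survey years)
#' @param elman an [elman_config()]
#' @param mixture_restarts EM restarts per LFD fit
#' @return list: effort, fits, cohorts, econ, predictors, predict_biomass
#' @export
run_pipeline <- function(world, train_nets = TRUE,
                         elman = elman_config(restarts = 10),
                         mixture_restarts = 4) {
  cfg <- world$config
  effort <- map_effort(world$pings, world$grid,
                       v_min = cfg$trawl_speed[1], v_max = cfg$trawl_speed[2])
  fits <- fit_survey(world, restarts = mixture_restarts)
  cohorts <- build_cohort_layers(world, fits)
  econ <- build_econ(world, fits, cohorts, effort)
  predictors <- NULL
  predict_biomass <- NULL
  if (train_nets) {
    predictors <- train_predictors(world, cohorts, effort, config = elman)
    predict_biomass <- make_biomass_predictor(world, fits, cohorts, effort,
                                              predictors)
  }
  list(effort = effort, fits = fits, cohorts = cohorts, econ = econ,
       predictors = predictors, predict_biomass = predict_biomass)
}
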