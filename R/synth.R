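#' Configuration of the synthetic world generator
#'
#' Describes a stylised Sicilian-channel-like shelf: a coast along the
#' northern edge of the bounding box, depth increasing southwards to the
#' 800 m contour, two wide shallow banks (< 100 m) in the western and
#' eastern sectors, harbours on the coast, a trawler fleet whose trips
#' concentrate near abundance hotspots, and an annual stratified-random
#' survey over the five depth strata of the standard Mediterranean design.
#'
#' @param lon_min,lon_max,lat_min,lat_max bounding box (degrees); defaults
#'   give 22 x 18 = 396 six-arc-minute cells
#' @param cell_arcmin grid cell side (arc-minutes, default 6)
#' @param years number of simulated survey years (default 5; at least 2,
#'   the predictor needs a lag)
#' @param n_hauls survey hauls per year (default 70), allocated to strata
#'   proportionally to area
#' @param n_vessels trawlers in the fleet (default 20)
#' @param trips_per_year fishing trips per vessel per year (default 8)
#' @param trawl_hours hours spent trawling per trip (default 5)
#' @param trawl_speed,steam_speed speed windows in knots: trawling pings
#'   are drawn uniformly in `trawl_speed` (default c(2.0, 4.5)), steaming
#'   in `steam_speed` (default c(8, 12)); these are also the thresholds the
#'   speed filter should use, so the filter is exactly testable
#' @param banks data.frame of shallow-bank bumps subtracted from the depth
#'   ramp: columns `u`, `v` (unit coordinates in the box, u west-east,
#'   v north-south), `amp` (m), `width` (unit lengths)
#' @param depth_pixel_sd sd (m) of the 1-arc-minute pixel noise around the
#'   deterministic depth field
#' @param density_scale peak survey density (N/km^2) per species and sex
#'   (named vector, defaults DPS 30000, HKE 2000, MUT 2000 — order-of-
#'   magnitude matches of survey indices for a heavily exploited
#'   Mediterranean shelf, chosen so fleet-scale revenues and fuel costs
#'   are commensurate)
#' @param swept_area_km2 area swept by one haul (km^2, default 0.05);
#'   haul counts are Poisson draws at `density * swept_area_km2` and are
#'   standardised back to N/km^2
#' @param mixture_props cohort mixture proportions used when drawing
#'   lengths; NULL (default) means equal proportions
#' @param spatial_noise_sd lognormal sd of the static per-cell abundance
#'   noise (default 0.3)
#' @param year_noise_sd lognormal sd of the independent per-cell/year
#'   abundance noise (default 0.1)
#' @param fuel_prices mean annual fuel price per simulated year plus one
#'   extra year (so the cost regression has years+1 >= 4 records); default
#'   an increasing sequence around 1.1 euro/l
#' @param fuel_noise_sd sd (euros) of the Gaussian noise added to the
#'   fuel-cost records (default 1e5; 0 puts records exactly on the plane)
#' @param cost_coefficients generative truth of the cost plane, default
#'   [default_cost_coefficients()]
#' @param seed integer seed; the same seed reproduces the bundle exactly
#' @return list of class `synth_config`
#' @export
synth_config <- function(lon_min = 12, lon_max = 14.2,
                         lat_min = 36, lat_max = 37.8,
                         cell_arcmin = 6, years = 5,
                         n_hauls = 70, n_vessels = 20, trips_per_year = 8,
                         trawl_hours = 5,
                         trawl_speed = c(2.0, 4.5), steam_speed = c(8, 12),
                         banks = data.frame(u = c(0.2, 0.8), v = c(0.25, 0.25),
                                            amp = c(330, 300),
                                            width = c(0.16, 0.14)),
                         depth_pixel_sd = 5,
                         density_scale = c(DPS = 30000, HKE = 2000,
                                           MUT = 2000),
                         swept_area_km2 = 0.05,
                         mixture_props = NULL,
                         spatial_noise_sd = 0.3, year_noise_sd = 0.1,
                         fuel_prices = NULL,
                         fuel_noise_sd = 1e5,
                         cost_coefficients = default_cost_coefficients(),
                         seed = 1L) {
  stopifnot(cell_arcmin > 0, years >= 2)
  if (is.null(fuel_prices)) {
    # at least 4 records so the 3-parameter cost regression is identified
    fuel_prices <- seq(0.95, 1.35, length.out = max(years + 1, 4))
  }
  stopifnot(length(fuel_prices) >= 4)
  structure(as.list(environment()), class = "synth_config")
}

# deterministic depth (m) at arbitrary positions for a config
.depth_field <- function(cfg, lon, lat) {
  u <- (lon - cfg$lon_min) / (cfg$lon_max - cfg$lon_min)
  v <- (cfg$lat_max - lat) / (cfg$lat_max - cfg$lat_min)  # 0 at coast
  d <- 20 + 780 * v^1.4
  for (i in seq_len(nrow(cfg$banks))) {
    b <- cfg$banks[i, ]
    d <- d - b$amp * exp(-((u - b$u)^2 + (v - b$v)^2) / (2 * b$width^2))
  }
  pmin(pmax(d, 12), 800)
}

# species depth preference (optimum, width in m)
.depth_pref <- function(species) {
  switch(species,
         DPS = c(opt = 260, width = 140),
         HKE = c(opt = 200, width = 150),
         MUT = c(opt = 80, width = 60),
         stop("unknown species ", species))
}

#' Generate a complete synthetic input bundle
#'
#' Produces every input the pipeline needs — bathymetry pixels, SST layers,
#' harbours, stratified-random survey hauls, vessel ping streams, a price
#' schedule and fuel-cost records — together with the ground truth used to
#' generate them (expected density surfaces, cohort mixture parameters,
#' speed windows, per-year true effort patterns, cost coefficients).  The
#' ground truth is for tests only; the pipeline never reads it.
#'
#' @param cfg a [synth_config()]
#' @return list of class `synthetic_world`; see Details
#' @details Elements: `config`, `grid`, `strata` (areas filled),
#'   `bathy_pixels` (cells x 36), `d_mean`, `d_sd`, `sst` (list by year),
#'   `harbors`, `hauls` (long CSV-style table), `pings`, `prices`, `fuel`
#'   (year, PS, E, TC), `truth`.
#' @export
generate_world <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "synth_config"))
  old_seed <- .save_rng()
  on.exit(.restore_rng(old_seed), add = TRUE)
  set.seed(cfg$seed)

  grid <- grid_spec(cfg$lon_min, cfg$lon_max, cfg$lat_min, cfg$lat_max,
                    cell_arcmin = cfg$cell_arcmin)
  cc <- cell_centers(grid)
  years <- seq_len(cfg$years)
  species <- c("DPS", "HKE", "MUT")

  ## bathymetry: 36 one-arc-minute pixels per 6-arc-minute cell
  px_per_side <- round(cfg$cell_arcmin)  # 1' pixels
  n_px <- px_per_side^2
  off <- (seq_len(px_per_side) - 0.5) / px_per_side - 0.5
  bathy <- matrix(NA_real_, grid$n_cells, n_px)
  for (i in seq_len(grid$n_cells)) {
    plon <- cc$lon[i] + rep(off, each = px_per_side) * grid$step
    plat <- cc$lat[i] + rep(off, times = px_per_side) * grid$step
    bathy[i, ] <- .depth_field(cfg, plon, plat) +
      stats::rnorm(n_px, 0, cfg$depth_pixel_sd)
  }
  di <- t(apply(bathy, 1, depth_indices, n_expected = n_px))
  d_mean <- di[, 1]; d_sd <- di[, 2]

  ## strata from mean depth; every stratum must be populated
  strata <- default_strata()
  brk <- c(0, 50, 100, 200, 500, Inf)
  cell_stratum <- findInterval(d_mean, brk)
  cell_stratum[cell_stratum < 1 | cell_stratum > 5] <- NA
  cell_area <- (1.852 * cfg$cell_arcmin)^2 * cos(cc$lat * pi / 180)
  empty <- setdiff(1:5, unique(stats::na.omit(cell_stratum)))
  if (length(empty) > 0) {
    stop("degenerate depth field: empty depth strata ",
         paste(apply(strata[empty, c("depth_min", "depth_max")], 1,
                     paste, collapse = "-"), collapse = ", "), " m")
  }
  strata$area_km2 <- vapply(1:5, function(s) {
    sum(cell_area[which(cell_stratum == s)])
  }, numeric(1))

  ## SST layers
  vlat <- (cfg$lat_max - cc$lat) / (cfg$lat_max - cfg$lat_min)
  sst <- stats::setNames(lapply(years, function(y) {
    19 + 1.2 * vlat + 0.4 * sin(2 * pi * y / cfg$years) +
      stats::rnorm(grid$n_cells, 0, 0.1)
  }), as.character(years))

  ## harbours on the northern coast
  harbors <- harbor_set(
    name = paste0("H", 1:4),
    lon = cfg$lon_min + c(0.15, 0.4, 0.6, 0.85) * (cfg$lon_max - cfg$lon_min),
    lat = rep(cfg$lat_max - 0.25 * grid$step, 4))

  ## ground-truth density surfaces (N/km^2), sexes and cohorts separate
  coh_tab <- default_cohort_params()
  n_coh <- c(DPS = 3, HKE = 3, MUT = 2)
  static_noise <- list()
  truth_density <- list()
  for (sp in species) {
    pref <- .depth_pref(sp)
    base <- exp(-((d_mean - pref["opt"]) / pref["width"])^2 / 2)
    for (sx in c("F", "M")) {
      sn <- exp(stats::rnorm(grid$n_cells, 0, cfg$spatial_noise_sd))
      static_noise[[paste(sp, sx)]] <- sn
      for (y in years) {
        yfac <- exp(0.15 * sin(2 * pi * y / cfg$years + match(sp, species)))
        props <- if (is.null(cfg$mixture_props)) {
          rep(1 / n_coh[[sp]], n_coh[[sp]])
        } else cfg$mixture_props[[sp]]
        yn <- exp(stats::rnorm(grid$n_cells, 0, cfg$year_noise_sd))
        dens <- outer(cfg$density_scale[[sp]] * base * sn * yn * yfac, props)
        colnames(dens) <- paste0("cohort", seq_len(n_coh[[sp]]))
        truth_density[[paste(sp, sx, y)]] <- dens
      }
    }
  }

  ## survey hauls: stratified random, counts proportional to area
  n_by_stratum <- .largest_remainder(strata$area_km2 /
                                       sum(strata$area_km2) * cfg$n_hauls)
  bin_mm <- c(DPS = 1, HKE = 10, MUT = 5)
  haul_rows <- list()
  station_id <- 0L
  for (y in years) {
    for (s in 1:5) {
      cells_s <- which(cell_stratum == s)
      picks <- sample(cells_s, n_by_stratum[s], replace = TRUE)
      for (cell in picks) {
        station_id <- station_id + 1L
        lon <- cc$lon[cell] + stats::runif(1, -0.5, 0.5) * grid$step
        lat <- cc$lat[cell] + stats::runif(1, -0.5, 0.5) * grid$step
        rows <- list(data.frame(
          station_id = station_id, lon = lon, lat = lat, stratum = s,
          year = y, species = "__station__", sex = "F",
          length_mm = 0, density = 0, stringsAsFactors = FALSE))
        for (sp in species) {
          for (sx in c("F", "M")) {
            lam <- truth_density[[paste(sp, sx, y)]][cell, ]
            cp <- coh_tab[coh_tab$species == sp & coh_tab$sex == sx &
                            coh_tab$year == y, ]
            lens <- numeric(0)
            for (h in seq_along(lam)) {
              n_ind <- stats::rpois(1, lam[h] * cfg$swept_area_km2)
              if (n_ind > 0) {
                lens <- c(lens, stats::rnorm(n_ind, cp$mean_mm[h],
                                             cp$sd_mm[h]))
              }
            }
            if (length(lens) == 0) next
            bw <- bin_mm[[sp]]
            mids <- (floor(lens / bw) + 0.5) * bw
            tab <- table(mids) / cfg$swept_area_km2
            rows[[length(rows) + 1L]] <- data.frame(
              station_id = station_id, lon = lon, lat = lat, stratum = s,
              year = y, species = sp, sex = sx,
              length_mm = as.numeric(names(tab)),
              density = as.numeric(tab), stringsAsFactors = FALSE)
          }
        }
        haul_rows[[length(haul_rows) + 1L]] <- do.call(rbind, rows)
      }
    }
  }
  hauls <- do.call(rbind, haul_rows)
  rownames(hauls) <- NULL

  ## vessel pings: harbour -> hotspot steam, trawl walk, steam home
  hotspot_w <- rowSums(truth_density[[paste("DPS", "F", 1)]]) +
    rowSums(truth_density[[paste("HKE", "F", 1)]]) +
    rowSums(truth_density[[paste("MUT", "F", 1)]])
  hotspot_p <- hotspot_w / sum(hotspot_w)
  step_h <- 10 / 60                      # 10-minute pings
  ping_rows <- list()
  trip_id <- 0L
  t0 <- as.numeric(as.POSIXct("2020-01-01", tz = "UTC"))
  for (y in years) {
    for (v in seq_len(cfg$n_vessels)) {
      t_cur <- t0 + (y - 1) * 365 * 86400 + v * 43200
      for (tr in seq_len(cfg$trips_per_year)) {
        trip_id <- trip_id + 1L
        hb <- harbors[sample.int(nrow(harbors), 1), ]
        target <- sample.int(grid$n_cells, 1, prob = hotspot_p)
        trip <- .simulate_trip(cfg, grid, hb, cc$lon[target], cc$lat[target],
                               t_cur, step_h)
        trip$vessel_id <- sprintf("V%02d", v)
        trip$trip_id <- trip_id
        trip$year <- y
        ping_rows[[length(ping_rows) + 1L]] <- trip
        t_cur <- max(trip$time) + stats::runif(1, 6, 36) * 3600
      }
    }
  }
  pings <- do.call(rbind, ping_rows)
  rownames(pings) <- NULL

  ## true effort patterns and fuel records
  true_effort <- stats::setNames(lapply(years, function(y) {
    fy <- pings[pings$year == y & pings$state == "fish", ]
    counts <- tabulate(cell_of(grid, fy$lon, fy$lat), nbins = grid$n_cells)
    effort_pattern(grid, counts, year = y)
  }), as.character(years))
  co <- cfg$cost_coefficients
  fuel_years <- seq_len(length(cfg$fuel_prices))
  ps_per_year <- vapply(fuel_years, function(y) {
    if (as.character(y) %in% names(true_effort)) {
      pattern_score(true_effort[[as.character(y)]], harbors)
    } else {
      # extra bookkeeping year beyond the simulated ones: reuse last pattern
      pattern_score(true_effort[[length(true_effort)]], harbors) *
        stats::runif(1, 0.95, 1.05)
    }
  }, numeric(1))
  fuel <- data.frame(
    year = fuel_years, PS = ps_per_year, E = cfg$fuel_prices,
    TC = co["b0"] + co["b_PS"] * ps_per_year + co["b_E"] * cfg$fuel_prices +
      stats::rnorm(length(fuel_years), 0, cfg$fuel_noise_sd))

  structure(list(
    config = cfg, grid = grid, strata = strata,
    bathy_pixels = bathy, d_mean = d_mean, d_sd = d_sd,
    cell_stratum = cell_stratum, cell_area = cell_area,
    sst = sst, harbors = harbors, hauls = hauls, pings = pings,
    prices = default_prices(), fuel = fuel,
    truth = list(density = truth_density, cohort_params = coh_tab,
                 mixture_props = cfg$mixture_props,
                 n_by_stratum = n_by_stratum,
                 trawl_speed = cfg$trawl_speed,
                 steam_speed = cfg$steam_speed,
                 effort = true_effort,
                 q = stats::setNames(
                   default_species_params()$q[c(1, 3, 5)],
                   c("DPS", "HKE", "MUT")),
                 cost_coefficients = co,
                 bin_mm = c(DPS = 1, HKE = 10, MUT = 5))
  ), class = "synthetic_world")
}

# integer allocation proportional to weights, totals preserved
.largest_remainder <- function(x) {
  fl <- floor(x)
  rem <- x - fl
  short <- round(sum(x)) - sum(fl)
  if (short > 0) {
    add <- order(rem, decreasing = TRUE)[seq_len(short)]
    fl[add] <- fl[add] + 1
  }
  as.integer(fl)
}

# One harbour-to-harbour trip.  Waypoints are laid down at the 10-minute
# step (steam out, trawl walk, steam home; the final harbour-arrival leg is
# shorter and gets a proportionally shorter timestamp gap).  Each ping then
# records the speed and state of the segment LEAVING it, recomputed from
# the actual positions — the same convention [interpolate_track()] uses to
# derive speeds — so the speed filter recovers the generating state
# exactly; trawl segments whose realised speed left the trawling window
# (boundary clamping) are demoted to "steam".
.simulate_trip <- function(cfg, grid, harbor, tlon, tlat, t_start, step_h) {
  km_per_deg_lat <- 111.195
  km_per_deg_lon <- 111.195 * cos(harbor$lat * pi / 180)
  advance <- function(lon, lat, brg, speed_kn) {
    d_km <- speed_kn * 1.852 * step_h
    c(lon + d_km * sin(brg) / km_per_deg_lon,
      lat + d_km * cos(brg) / km_per_deg_lat)
  }
  lons <- harbor$lon; lats <- harbor$lat; times <- t_start
  states <- character(0)   # state of segment i -> i+1
  lon <- harbor$lon; lat <- harbor$lat; t_cur <- t_start
  push <- function(p, state, dt_s) {
    lons <<- c(lons, p[1]); lats <<- c(lats, p[2])
    t_cur <<- t_cur + dt_s
    times <<- c(times, t_cur)
    states <<- c(states, state)
    lon <<- p[1]; lat <<- p[2]
  }
  # exact_arrival appends a shorter final leg landing on the destination;
  # only used for the homecoming so that all earlier pings stay on the
  # regular 10-minute lattice
  steam_to <- function(dlon, dlat, exact_arrival) {
    repeat {
      d_km <- haversine_km(lon, lat, dlon, dlat)
      sp <- stats::runif(1, cfg$steam_speed[1], cfg$steam_speed[2])
      step_km <- sp * 1.852 * step_h
      brg <- atan2((dlon - lon) * km_per_deg_lon,
                   (dlat - lat) * km_per_deg_lat)
      if (d_km <= step_km) {
        if (exact_arrival && d_km > 1e-9) {
          push(c(dlon, dlat), "steam", d_km / (sp * 1.852) * 3600)
        }
        break
      }
      push(advance(lon, lat, brg, sp), "steam", step_h * 3600)
    }
  }
  steam_to(tlon, tlat, exact_arrival = FALSE)
  n_fish <- max(3L, round(cfg$trawl_hours / step_h))
  brg <- stats::runif(1, 0, 2 * pi)
  for (i in seq_len(n_fish)) {
    sp <- stats::runif(1, cfg$trawl_speed[1], cfg$trawl_speed[2])
    brg <- brg + stats::rnorm(1, 0, 0.6)
    p <- advance(lon, lat, brg, sp)
    if (p[1] < grid$lon_min || p[1] > grid$lon_max ||
        p[2] < grid$lat_min || p[2] > grid$lat_max) {
      brg <- brg + pi
      p <- advance(lon, lat, brg, sp)
    }
    p[1] <- min(max(p[1], grid$lon_min + 1e-6), grid$lon_max - 1e-6)
    p[2] <- min(max(p[2], grid$lat_min + 1e-6), grid$lat_max - 1e-6)
    push(p, "fish", step_h * 3600)
  }
  steam_to(harbor$lon, harbor$lat, exact_arrival = TRUE)
  n <- length(lons)
  # realised lead-segment speeds (identical to what track interpolation
  # derives); last ping inherits the previous segment
  d_km <- haversine_km(lons[-n], lats[-n], lons[-1], lats[-1])
  dt_h <- diff(times) / 3600
  seg_kn <- (d_km / 1.852) / dt_h
  # demote trawl segments pushed out of the window by clamping
  in_window <- seg_kn >= cfg$trawl_speed[1] & seg_kn <= cfg$trawl_speed[2]
  states[states == "fish" & !in_window] <- "steam"
  data.frame(time = times, lon = lons, lat = lats,
             speed_kn = c(seg_kn, seg_kn[n - 1]),
             state = c(states, states[n - 1]))
}

#' Write a synthetic bundle to plain-text files
#'
#' One CSV per entity (hauls, pings, fuel records, prices, depth indices)
#' plus a JSON sidecar with the scalar ground truth (cohort parameters,
#' speed windows, cost coefficients, seed).
#'
#' @param world a `synthetic_world`
#' @param outdir output directory (created if needed)
#' @return `outdir`, invisibly
#' @export
write_world <- function(world, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(world$hauls, file.path(outdir, "hauls.csv"),
                   row.names = FALSE)
  utils::write.csv(world$pings, file.path(outdir, "pings.csv"),
                   row.names = FALSE)
  utils::write.csv(world$fuel, file.path(outdir, "fuel.csv"),
                   row.names = FALSE)
  utils::write.csv(world$prices, file.path(outdir, "prices.csv"),
                   row.names = FALSE)
  cc <- cell_centers(world$grid)
  utils::write.csv(
    data.frame(cell_id = cc$cell, lon = cc$lon, lat = cc$lat,
               d_mean = world$d_mean, d_sd = world$d_sd,
               stratum = world$cell_stratum),
    file.path(outdir, "cells.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(world$harbors),
                   file.path(outdir, "harbors.csv"), row.names = FALSE)
  gt <- list(seed = world$config$seed,
             trawl_speed = world$truth$trawl_speed,
             steam_speed = world$truth$steam_speed,
             cost_coefficients = as.list(world$truth$cost_coefficients),
             q = as.list(world$truth$q),
             n_by_stratum = world$truth$n_by_stratum,
             cohort_params = world$truth$cohort_params)
  jsonlite::write_json(gt, file.path(outdir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}
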