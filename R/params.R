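#' Default biological and fishery parameters for the three target species
#'
#' Returns the per-species, per-sex parameter set used throughout the
#' bio-economic engine for the three demersal target species of the Strait
#' of Sicily trawl fishery: deep-water rose shrimp (DPS,
#' *Parapenaeus longirostris*), European hake (HKE, *Merluccius merluccius*)
#' and red mullet (MUT, *Mullus barbatus*).
#'
#' Lengths are carapace length for DPS and total length for HKE/MUT, both in
#' mm.  `a`/`b` are the length-weight power-law coefficients giving weight in
#' grams from length in mm.  `L50`/`L75` are the retention lengths of the
#' 40 mm cod-end at 50% and 75%, `q` the catchability of the commercial
#' trawl (per fishing point), `qM` the survey-gear catchability (ratio of
#' absolute to swept-area standing stock), and `F_lca`/`F_lca_sd` the
#' reference total fishing mortality (mean and sd over the study years) from
#' external length-cohort analysis.
#'
#' @return A data.frame with one row per species/sex combination.
#' @export
default_species_params <- function() {
  data.frame(
    species = rep(c("DPS", "HKE", "MUT"), each = 2),
    sex     = rep(c("M", "F"), times = 3),
    Linf    = c(33.56, 42.71, 1000, 201.6, 236.1, 33.56),
    k       = c(0.73, 0.67, 0.116, 0.57, 0.45, 0.73),
    t0      = c(-0.13, -0.208, -0.5, -0.8, -0.8, -0.13),
    M       = c(1.2, 1.05, 0.43, 0.34, 1.0, 1.0),
    a       = c(0.0034, 0.0029, 3.598e-06, 3.598e-06, 2.648e-05, 1.532e-05),
    b       = c(2.4096, 2.4818, 3.125, 3.125, 2.823, 2.942),
    L50     = c(15, 15, 120, 120, 90, 90),
    L75     = c(18, 18, 140, 140, 110, 110),
    q       = c(0.0022, 0.0022, 0.0018, 0.0018, 0.0021, 0.0021),
    qM      = c(0.85, 0.85, 0.15, 0.15, 0.85, 0.85),
    F_lca   = c(1.33, 1.33, 1.15, 1.15, 1.47, 1.47),
    F_lca_sd = c(0.16, 0.16, 0.12, 0.12, 0.17, 0.17),
    stringsAsFactors = FALSE
  )
}

#' Look up the parameter row for one species/sex
#'
#' @param species one of "DPS", "HKE", "MUT"
#' @param sex "M" or "F"
#' @param params parameter table, defaults to [default_species_params()]
#' @return single-row data.frame
#' @export
species_params <- function(species, sex,
                           params = default_species_params()) {
  row <- params[params$species == species & params$sex == sex, ]
  if (nrow(row) != 1L) {
    stop("no unique parameter row for species '", species,
         "' sex '", sex, "'")
  }
  row
}

#' Default market price schedule by species and size band
#'
#' Per-kg first-sale prices by commercial size band (lengths in mm; bands are
#' closed on the left, open on the right).  The DPS bands and prices are the
#' recorded market values for the Sicilian-channel fleet; the HKE and MUT
#' schedules are synthetic stand-ins with the same banded structure, scaled
#' to plausible Mediterranean ex-vessel prices, and are labelled as such.
#'
#' @return data.frame with columns species, min_mm, max_mm, price_eur_kg.
#' @export
default_prices <- function() {
  data.frame(
    species = c(rep("DPS", 4), rep("HKE", 4), rep("MUT", 3)),
    min_mm  = c(0, 21, 25, 30,     0, 150, 250, 350,    0, 130, 180),
    max_mm  = c(21, 25, 30, Inf,   150, 250, 350, Inf,  130, 180, Inf),
    price_eur_kg = c(2.5, 5, 8, 16,   3, 6, 9, 12,   4, 8, 12),
    synthetic = c(rep(FALSE, 4), rep(TRUE, 4), rep(TRUE, 3)),
    stringsAsFactors = FALSE
  )
}

#' Default cohort structure of the length-frequency distributions
#'
#' Mean length and standard deviation (mm) of the normal cohort components
#' by species, sex and survey year.  Three cohorts for DPS and HKE (the
#' third grouping all age 3+ fish for HKE), two for MUT.  Component
#' proportions are not part of the published decomposition and default to
#' equal weights wherever the generator consumes this table.
#'
#' @param species optionally filter to one species
#' @param sex optionally filter to one sex
#' @param year optionally filter to one survey year (1..5, mirroring the
#'   five study years)
#' @return data.frame with columns species, sex, year, cohort, mean_mm, sd_mm
#' @export
default_cohort_params <- function(species = NULL, sex = NULL, year = NULL) {
  dps_f <- cbind(year = rep(1:5, each = 3), cohort = rep(1:3, 5),
                 mean = c(14.1, 23.4, 26.7,  15.6, 25.0, 31.5,
                          19.9, 24.4, 28.8,  19.3, 23.6, 27.9,
                          15.5, 22.8, 30.9),
                 sd   = c(2.1, 1.8, 3.5,  2.4, 2.2, 1.9,  2.1, 1.6, 2.5,
                          3.0, 1.6, 2.5,  3.3, 2.0, 2.1))
  dps_m <- cbind(year = rep(1:5, each = 3), cohort = rep(1:3, 5),
                 mean = c(15.7, 21.0, 25.5,  15.7, 21.0, 25.5,
                          16.7, 20.5, 25.0,  15.7, 21.0, 25.5,
                          15.7, 21.0, 25.5),
                 sd   = rep(c(1.8, 1.4, 1.6), 5))
  hke_f <- cbind(year = rep(1:5, each = 3), cohort = rep(1:3, 5),
                 mean = c(100, 200, 320,  105, 200, 320,  100, 200, 320,
                          100, 200, 320,  120, 220, 340),
                 sd   = c(16, 44.8, 110.5,  16, 44.8, 110.5,
                          16, 31.3, 110.5,  16, 31.3, 110.5,
                          16, 31.3, 110.5))
  hke_m <- cbind(year = rep(1:5, each = 3), cohort = rep(1:3, 5),
                 mean = c(100, 190, 280,  105, 190, 280,  100, 190, 280,
                          100, 190, 280,  120, 210, 300),
                 sd   = c(19, 44.2, 59.3,  19, 44.2, 59.3,
                          19, 30.9, 59.3,  19, 30.9, 59.3,
                          19, 30.9, 59.3))
  mut_f <- cbind(year = rep(1:5, each = 2), cohort = rep(1:2, 5),
                 mean = c(144, 169,  165, 176,  149, 175,  159.6, 187,
                          144, 169),
                 sd   = c(10, 21,  15, 20,  12, 20,  17, 19,  10, 21))
  mut_m <- cbind(year = rep(1:5, each = 2), cohort = rep(1:2, 5),
                 mean = c(130.9, 151,  123, 150,  134, 154,  122, 155,
                          134.2, 155),
                 sd   = c(7, 14,  7, 14,  9, 14,  8, 13,  8, 13))
  blocks <- list(DPS.F = dps_f, DPS.M = dps_m, HKE.F = hke_f,
                 HKE.M = hke_m, MUT.F = mut_f, MUT.M = mut_m)
  out <- do.call(rbind, lapply(names(blocks), function(nm) {
    sp <- sub("\\..*$", "", nm)
    sx <- sub("^.*\\.", "", nm)
    b <- as.data.frame(blocks[[nm]])
    data.frame(species = sp, sex = sx, year = b$year, cohort = b$cohort,
               mean_mm = b$mean, sd_mm = b$sd, stringsAsFactors = FALSE)
  }))
  if (!is.null(species)) out <- out[out$species %in% species, ]
  if (!is.null(sex)) out <- out[out$sex %in% sex, ]
  if (!is.null(year)) out <- out[out$year %in% year, ]
  rownames(out) <- NULL
  out
}

#' Reference fuel-cost regression coefficients
#'
#' Coefficients of the fleet-level fuel cost model
#' `TC = b0 + b_PS * PS + b_E * E` (total annual fuel cost in euros as a
#' linear function of the effort Pattern Score and the mean annual fuel
#' price).  Used by the synthetic generator as generative truth.
#'
#' @return named numeric vector with elements b0, b_PS, b_E.
#' @export
default_cost_coefficients <- function() {
  c(b0 = -1.607e7, b_PS = 2.200e2, b_E = 1.321e7)
}

#' Depth strata of the stratified-random survey design
#'
#' The five bathymetric strata of the annual bottom-trawl survey
#' (10-50, 51-100, 101-200, 200-500, 500-800 m).  Areas default to NA and
#' are filled in by the survey design or the synthetic generator.
#'
#' @param areas_km2 optional numeric vector of length 5 of stratum areas
#' @return data.frame with columns stratum, depth_min, depth_max, area_km2
#' @export
default_strata <- function(areas_km2 = rep(NA_real_, 5)) {
  stopifnot(length(areas_km2) == 5L)
  data.frame(
    stratum = 1:5,
    depth_min = c(10, 51, 101, 200, 500),
    depth_max = c(50, 100, 200, 500, 800),
    area_km2 = areas_km2,
    stringsAsFactors = FALSE
  )
}
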