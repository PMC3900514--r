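# stratified abundance, EM mixture decomposition, K-S distance, cohort
# allocation, biomass conversion

make_hauls <- function(density_by_station, stratum_by_station,
                       species = "DPS", sex = "F", year = 1,
                       length_mm = 20) {
  n <- length(density_by_station)
  data.frame(station_id = seq_len(n), lon = 0, lat = 0,
             stratum = stratum_by_station, year = year, species = species,
             sex = sex, length_mm = length_mm,
             density = density_by_station)
}

test_that("stratified_abundance sums area-weighted stratum means", {
  strata <- default_strata()
  # one stratum, A = 2, densities (5, 5) -> 10
  strata$area_km2 <- c(2, 0, 0, 0, 0)
  h <- make_hauls(c(5, 5), c(1, 1))
  expect_equal(suppressWarnings(
    stratified_abundance(h, strata[1, ], "DPS", 1)), 10)
  # areas (100, 300), mean densities (2, 1) -> 500
  strata2 <- default_strata(c(100, 300, 0, 0, 0))[1:2, ]
  h2 <- make_hauls(c(2, 2, 1, 1), c(1, 1, 2, 2))
  expect_equal(stratified_abundance(h2, strata2, "DPS", 1), 500)
  # permutation invariance
  h3 <- h2[sample(nrow(h2)), ]
  expect_equal(stratified_abundance(h3, strata2, "DPS", 1), 500)
  # empty stratum excluded with warning
  strata3 <- default_strata(c(100, 300, 50, 0, 0))[1:3, ]
  expect_warning(n3 <- stratified_abundance(h2, strata3, "DPS", 1),
                 "stratum 3")
  expect_equal(n3, 500)
  # unknown stratum errors
  h4 <- make_hauls(1, 9)
  expect_error(stratified_abundance(h4, strata2, "DPS", 1), "unknown stratum")
})

test_that("single-component EM lands on the weighted mean and sd", {
  x <- mixture_lfd(means = 50, sds = 5, n = 2000, bin = 1, seed = 3)
  fit <- fit_mixture(x, K = 1, restarts = 2)
  w <- x$counts; m <- x$mids
  mu_w <- sum(w * m) / sum(w)
  sd_w <- sqrt(sum(w * (m - mu_w)^2) / sum(w))
  expect_equal(fit$prop, 1)
  expect_equal(fit$mean, mu_w, tolerance = 1e-6)
  expect_equal(fit$sd, sd_w, tolerance = 1e-4)
  expect_true(fit$converged)
})

test_that("EM recovers a three-cohort shrimp LFD within 2 standard errors", {
  means <- c(14.1, 23.4, 26.7); sds <- c(2.1, 1.8, 3.5); n <- 1e4
  x <- mixture_lfd(means, sds, n, bin = 1, seed = 1)
  fit <- fit_mixture(x, K = 3, restarts = 8, seed = 1)
  se <- sds / sqrt(n * fit$prop)
  expect_true(all(abs(fit$mean - means) <= 2 * se + 0.05))
  expect_true(all(diff(fit$mean) > 0))
  expect_equal(sum(fit$prop), 1, tolerance = 1e-9)
})

test_that("identical starting components are flagged non-identifiable", {
  x <- mixture_lfd(means = c(30, 60), sds = c(4, 4), n = 2000, bin = 1,
                   seed = 9)
  init <- list(prop = c(0.5, 0.5), mean = c(45, 45), sd = c(10, 10))
  fit <- fit_mixture(x, K = 2, restarts = 1, init = init)
  expect_false(fit$identifiable)
})

test_that("exact-binned EM (cdf method) also recovers the components", {
  means <- c(100, 200); sds <- c(15, 30)
  x <- mixture_lfd(means, sds, n = 5000, bin = 10, seed = 4)
  fit <- fit_mixture(x, K = 2, restarts = 4, method = "cdf", seed = 4)
  expect_true(all(abs(fit$mean - means) < 4))
})

test_that("K-S distance: near-zero on a matching fit, near-one when shifted,
           equals the exhaustive edge scan", {
  means <- c(20, 40); sds <- c(3, 4)
  x <- mixture_lfd(means, sds, n = 5e4, bin = 0.5, seed = 6)
  fit <- fit_mixture(x, K = 2, restarts = 4, seed = 6)
  ks <- ks_distance(x, fit)
  expect_lt(ks$D, 0.02)
  # shifted mixture: disjoint support
  shifted <- fit
  shifted$mean <- fit$mean + 100
  expect_gt(ks_distance(x, shifted)$D, 0.99)
  # exhaustive oracle over both one-sided limits at every edge
  n <- sum(x$counts)
  e_right <- c(0, cumsum(x$counts) / n)
  mix_cdf <- rowSums(sapply(seq_len(fit$K), function(h)
    fit$prop[h] * pnorm(x$breaks, fit$mean[h], fit$sd[h])))
  D_brute <- max(abs(mix_cdf - e_right))
  expect_equal(ks$D, D_brute, tolerance = 1e-12)
  expect_error(ks_distance(lfd(0:1, 0), fit), "empty")
})

test_that("allocate_cohorts conserves totals and respects dominance", {
  fit <- structure(list(prop = c(0.5, 0.5), mean = c(10, 100),
                        sd = c(2, 2), K = 2), class = "mixture_fit")
  counts <- c(3, 7, 11)
  mids <- c(10, 55, 100)
  a <- allocate_cohorts(counts, mids, fit)
  expect_equal(sum(a$totals), sum(counts), tolerance = 1e-9)
  expect_equal(rowSums(a$matrix), counts, tolerance = 1e-9)
  # midpoint at a component mean, other >= 5 sd away: ~100% to it
  expect_gt(a$matrix[1, 1] / counts[1], 0.999999)
  expect_gt(a$matrix[3, 2] / counts[3], 0.999999)
  # all densities underflow (>> 38 sd from every component): equal split
  fit0 <- structure(list(prop = c(0.5, 0.5), mean = c(10, 300),
                         sd = c(1, 1), K = 2), class = "mixture_fit")
  expect_warning(a2 <- allocate_cohorts(4, 155, fit0),
                 "zero mixture density")
  expect_equal(unname(a2$matrix[1, ]), c(2, 2))
  # K = 1: everything to the single cohort
  fit1 <- structure(list(prop = 1, mean = 50, sd = 5, K = 1),
                    class = "mixture_fit")
  expect_equal(allocate_cohorts(counts, mids, fit1)$totals, sum(counts))
})

test_that("allocation conserves any random input to 1e-9", {
  set.seed(12)
  fit <- structure(list(prop = c(0.2, 0.3, 0.5), mean = c(15, 25, 30),
                        sd = c(2, 2, 3), K = 3), class = "mixture_fit")
  for (rep in 1:10) {
    counts <- runif(20, 0, 100)
    mids <- sort(runif(20, 5, 40))
    a <- allocate_cohorts(counts, mids, fit)
    expect_equal(sum(a$totals), sum(counts), tolerance = 1e-9)
  }
})

test_that("biomass conversion applies the length-weight power law", {
  g <- toy_grid(2)
  # one red-mullet female of 144 mm: w = a * 144^b grams
  coh <- matrix(0, 4, 1); coh[1, 1] <- 1
  pr <- species_params("MUT", "F")
  lay <- biomass_layer(coh, g, mean_lengths = 144, a = pr$a, b = pr$b)
  expect_equal(lay$values[1], pr$a * 144^pr$b / 1e6, tolerance = 1e-12)
  expect_equal(lay$values[2], 0)
  # linearity
  lay2 <- biomass_layer(2 * coh, g, 144, pr$a, pr$b)
  expect_equal(lay2$values, 2 * lay$values)
  expect_error(biomass_layer(coh, g, -5, pr$a, pr$b), "negative")
})

test_that("EM parameter recovery holds across seeded replicates", {
  means <- c(100, 200, 320); sds <- c(16, 44.8, 110.5); n <- 5000
  ok <- 0
  for (s in 1:8) {
    x <- mixture_lfd(means, sds, n, bin = 5, seed = 100 + s)
    fit <- fit_mixture(x, K = 3, restarts = 6, seed = s)
    se <- sds / sqrt(n * pmax(fit$prop, 1e-3))
    if (all(abs(fit$mean - means) <= 2 * se + 0.05 * means)) ok <- ok + 1
  }
  expect_gte(ok, 7)
})
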