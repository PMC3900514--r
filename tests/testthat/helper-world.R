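# Small seeded bundle shared across test files (built once per run).
# ~80 cells, 5 years: large enough to exercise every stage, small enough
# to keep the suite fast.

tiny_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_world(synth_config(
        lon_min = 12, lon_max = 13, lat_min = 36.6, lat_max = 37.4,
        n_hauls = 30, n_vessels = 6, trips_per_year = 4, seed = 11))
    }
    cache
  }
})

tiny_pipeline <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- run_pipeline(tiny_world(), train_nets = FALSE)
    }
    cache
  }
})

# 3x3 toy grid ~ small flat area; meridional offsets give exactly
# proportional haversine distances
toy_grid <- function(n = 3) {
  grid_spec(0, n * 0.1, 0, n * 0.1, cell_arcmin = 6)
}

# draw a binned sample from a normal mixture and wrap it as an lfd
mixture_lfd <- function(means, sds, n, bin, seed, props = NULL) {
  if (is.null(props)) props <- rep(1 / length(means), length(means))
  set.seed(seed)
  comp <- sample(seq_along(means), n, replace = TRUE, prob = props)
  lens <- stats::rnorm(n, means[comp], sds[comp])
  breaks <- seq(floor(min(lens) / bin) * bin - bin,
                ceiling(max(lens) / bin) * bin + bin, by = bin)
  counts <- hist(lens, breaks = breaks, plot = FALSE)$counts
  lfd(breaks, counts)
}
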