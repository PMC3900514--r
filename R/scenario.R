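#' Economics context: everything needed to price an effort pattern
#'
#' Bundles the per-species standing-stock indices by length class, the
#' species parameters, the price schedule, the fitted cost model and the
#' harbour set, so that any candidate effort pattern can be converted
#' deterministically into catches, revenue, cost and gains.
#'
#' @param grid a `grid_spec`
#' @param harbors a `harbor_set`
#' @param species_data named list (by species code); each element a list
#'   with `index` (cells x lengths relative abundance matrix), `mids`
#'   (class midpoints, mm), and scalars `q`, `L50`, `L75`, `qM`, `a`, `b`
#' @param cost_model a `cost_model` from [fit_cost_model()]
#' @param fuel_price scenario fuel price E (held constant)
#' @param prices price schedule, default [default_prices()]
#' @return list of class `econ_context`
#' @export
econ_context <- function(grid, harbors, species_data, cost_model,
                         fuel_price, prices = default_prices()) {
  for (sp in names(species_data)) {
    sd_ <- species_data[[sp]]
    stopifnot(nrow(sd_$index) == grid$n_cells,
              ncol(sd_$index) == length(sd_$mids))
  }
  structure(list(grid = grid, harbors = harbors,
                 species_data = species_data, cost_model = cost_model,
                 fuel_price = fuel_price, prices = prices),
            class = "econ_context")
}

#' Evaluate an effort pattern economically
#'
#' Computes, for a candidate effort pattern: catches per species, total
#' revenue, Pattern Score, predicted fuel cost, gains `G = R - TC`, and
#' the overall fishing mortality `F_s` per species.
#'
#' @param ctx an `econ_context`
#' @param pattern an `effort_pattern` on the context grid
#' @return list(G, R, TC, PS, F, catch_kg) with `F` and `catch_kg` named by
#'   species
#' @export
evaluate_pattern <- function(ctx, pattern) {
  stopifnot(inherits(ctx, "econ_context"))
  R <- 0
  Fs <- c(); ckg <- c()
  for (sp in names(ctx$species_data)) {
    sd_ <- ctx$species_data[[sp]]
    idx <- sd_$index
    idx[is.na(idx)] <- 0
    ct <- suppressWarnings(
      catches(idx, sd_$mids, pattern$counts, q = sd_$q,
              L50 = sd_$L50, L75 = sd_$L75, qM = sd_$qM,
              a = sd_$a, b = sd_$b))
    R <- R + revenue(ct$kg, sd_$mids, sp, ctx$prices)
    Fs[sp] <- total_F(ct$numbers, sd_$qM * idx)
    ckg[sp] <- sum(ct$kg, na.rm = TRUE)
  }
  PS <- pattern_score(pattern, ctx$harbors)
  TC <- predict_cost(ctx$cost_model, PS, ctx$fuel_price)
  list(G = gains(R, TC), R = R, TC = TC, PS = PS, F = Fs, catch_kg = ckg)
}

#' Per-cell fishing-point probabilities from an observed pattern
#'
#' @param observed an `effort_pattern` with `Tf > 0`
#' @return numeric vector `p_c = n_c / Tf`, summing to 1
#' @export
baseline_probabilities <- function(observed) {
  if (observed$Tf <= 0) stop("observed pattern has no fishing points")
  observed$counts / observed$Tf
}

#' Redistribute effort probability out of a closed box
#'
#' Sets the probability of the closed cells to zero and renormalises the
#' remaining cells proportionally (`p'_c = p_c / (1 - sum_box p)`), i.e.
#' the effort formerly inside the box is redistributed outside it in
#' proportion to current use.  Alternative redistribution kernels can be
#' plugged in via `kernel`.
#'
#' @param p cell probability vector summing to 1
#' @param box_cells integer ids of the closed cells
#' @param kernel optional function(p, box_cells) returning replacement
#'   probabilities; the default is proportional renormalisation
#' @return adjusted probability vector summing to 1
#' @export
closure_transform <- function(p, box_cells, kernel = NULL) {
  if (!is.null(kernel)) return(kernel(p, box_cells))
  if (length(box_cells) == 0L) return(p)
  mass <- sum(p[box_cells])
  if (mass >= 1) stop("closed box covers all fishing effort")
  p2 <- p
  p2[box_cells] <- 0
  p2 / (1 - mass)
}

#' Draw an effort pattern from cell probabilities
#'
#' The locations of the `Tf` fishing points are one multinomial draw over
#' the grid cells.
#'
#' @param p cell probabilities (summing to 1)
#' @param Tf total number of fishing points
#' @param grid a `grid_spec`
#' @param year year label
#' @return an `effort_pattern` with counts summing exactly to `Tf`
#' @export
sample_pattern <- function(p, Tf, grid, year = NA_integer_) {
  stopifnot(abs(sum(p) - 1) < 1e-9, Tf >= 0)
  counts <- if (Tf == 0) {
    integer(length(p))
  } else {
    as.integer(stats::rmultinom(1, Tf, p))
  }
  effort_pattern(grid, counts, year = year)
}

#' Gain-maximising stochastic hill climb over effort patterns
#'
#' Repeatedly proposes multinomial patterns from `p`; a proposal is
#' accepted iff its gains strictly exceed the incumbent's.  The run stops
#' when `stop_k` consecutive proposals fail to improve.  The accepted-G
#' sequence is therefore strictly increasing and the run always
#' terminates.
#'
#' @param start an `effort_pattern` used as incumbent
#' @param p proposal cell probabilities
#' @param Tf total fishing points of every proposal
#' @param ctx an `econ_context` (or any object the `eval_fn` understands)
#' @param stop_k consecutive non-improving proposals ending the run
#'   (default 100)
#' @param eval_fn function(ctx, pattern) returning at least `G`, `R`, `TC`,
#'   `PS`, `F`; defaults to [evaluate_pattern()] (swappable for testing and
#'   for alternative objective landscapes)
#' @return list of class `run_result`: `pattern`, `G`, `PS`, `F`,
#'   `accepted_G` (trajectory including the start), `iterations`
#' @export
hill_climb_run <- function(start, p, Tf, ctx, stop_k = 100,
                           eval_fn = evaluate_pattern) {
  inc <- start
  ev <- eval_fn(ctx, inc)
  accepted_G <- ev$G
  rejects <- 0L
  iter <- 0L
  while (rejects < stop_k) {
    iter <- iter + 1L
    prop <- sample_pattern(p, Tf, inc$grid, year = inc$year)
    ev_p <- eval_fn(ctx, prop)
    if (ev_p$G > ev$G) {
      inc <- prop
      ev <- ev_p
      accepted_G <- c(accepted_G, ev$G)
      rejects <- 0L
    } else {
      rejects <- rejects + 1L
    }
  }
  structure(list(pattern = inc, G = ev$G, R = ev$R, TC = ev$TC,
                 PS = ev$PS, F = ev$F, accepted_G = accepted_G,
                 iterations = iter),
            class = "run_result")
}

#' Scenario configuration
#'
#' @param type "effort_scaling" (total effort scaled, spatial probabilities
#'   unchanged) or "box_closure" (total effort unchanged, probabilities
#'   zeroed inside the closed boxes and renormalised outside)
#' @param level effort multiplier for scaling scenarios, one of
#'   0.7, 0.8, ..., 1.3 by convention (any positive value accepted)
#' @param boxes named list of integer cell-id vectors to close (closure
#'   scenarios); multiple boxes are closed simultaneously
#' @param runs independent optimisation runs (default 100)
#' @param stop_k stopping patience of each hill climb (default 100)
#' @param seed master seed; run `i` uses `seed + i`
#' @return list of class `scenario_config`
#' @export
scenario_config <- function(type = c("effort_scaling", "box_closure"),
                            level = 1.0, boxes = NULL, runs = 100,
                            stop_k = 100, seed = 1L) {
  type <- match.arg(type)
  if (type == "effort_scaling") stopifnot(level > 0)
  if (type == "box_closure" && (is.null(boxes) || length(boxes) == 0)) {
    stop("box_closure scenario needs at least one box")
  }
  structure(list(type = type, level = level, boxes = boxes,
                 runs = runs, stop_k = stop_k, seed = as.integer(seed)),
            class = "scenario_config")
}

#' Simulate a management scenario
#'
#' Runs `config$runs` independent gain-maximising hill climbs under the
#' scenario-adjusted proposal distribution, and summarises each optimised
#' pattern by its gains, Pattern Score, per-species fishing mortality and
#' (when a biomass predictor is supplied) next-year biomass per species.
#' The observed pattern's own evaluation is returned as the baseline.
#'
#' @param config a [scenario_config()]
#' @param observed the observed `effort_pattern` (reference year)
#' @param ctx an `econ_context`
#' @param predict_biomass optional `function(pattern)` returning a named
#'   vector of next-year biomasses (tons) per species, e.g. from
#'   [make_biomass_predictor()]
#' @return list of class `simulation_summary`: `runs` (tidy data.frame:
#'   run, G, PS, F_<sp>, B_<sp>), `baseline`, `config`
#' @export
run_scenario <- function(config, observed, ctx, predict_biomass = NULL) {
  p0 <- baseline_probabilities(observed)
  if (config$type == "effort_scaling") {
    p <- p0
    Tf <- as.integer(round(config$level * observed$Tf))
  } else {
    closed <- sort(unique(unlist(config$boxes)))
    p <- closure_transform(p0, closed)
    Tf <- observed$Tf
  }
  old_seed <- .save_rng()
  on.exit(.restore_rng(old_seed), add = TRUE)

  rows <- vector("list", config$runs)
  results <- vector("list", config$runs)
  for (i in seq_len(config$runs)) {
    set.seed(config$seed + i)
    start <- sample_pattern(p, Tf, observed$grid, year = observed$year)
    rr <- hill_climb_run(start, p, Tf, ctx, stop_k = config$stop_k)
    row <- data.frame(run = i, G = rr$G, PS = rr$PS, iterations = rr$iterations)
    for (sp in names(rr$F)) row[[paste0("F_", sp)]] <- rr$F[[sp]]
    if (!is.null(predict_biomass)) {
      B <- predict_biomass(rr$pattern)
      for (sp in names(B)) row[[paste0("B_", sp)]] <- B[[sp]]
    }
    rows[[i]] <- row
    results[[i]] <- rr
  }
  baseline <- evaluate_pattern(ctx, observed)
  if (!is.null(predict_biomass)) {
    baseline$B <- predict_biomass(observed)
  }
  structure(list(runs = do.call(rbind, rows), results = results,
                 baseline = baseline, config = config),
            class = "simulation_summary")
}

#' @export
print.simulation_summary <- function(x, ...) {
  cat(sprintf("simulation_summary: %s, %d run(s)\n", x$config$type,
              nrow(x$runs)))
  cat(sprintf("  G: median %.0f (baseline %.0f)\n",
              stats::median(x$runs$G), x$baseline$G))
  invisible(x)
}
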