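#' Per-cell fishing-effort pattern
#'
#' Integer counts of fishing points (vessel positions in a fishing state)
#' per grid cell, with their total `Tf`.
#'
#' @param grid a `grid_spec`
#' @param counts non-negative integer vector of length `grid$n_cells`
#' @param year integer year label
#' @return object of class `effort_pattern`
#' @export
effort_pattern <- function(grid, counts, year = NA_integer_) {
  stopifnot(length(counts) == grid$n_cells, all(counts >= 0),
            all(counts == round(counts)))
  structure(list(grid = grid, counts = as.integer(round(counts)),
                 Tf = as.integer(sum(counts)), year = year),
            class = "effort_pattern")
}

#' @export
print.effort_pattern <- function(x, ...) {
  cat(sprintf("effort_pattern (year %s): Tf = %d over %d occupied cells\n",
              x$year, x$Tf, sum(x$counts > 0)))
  invisible(x)
}

#' Interpolate a vessel track at a fixed time step
#'
#' Linearly interpolates ping positions in time at `step_min` minute
#' intervals (endpoints included) and derives the speed of each regularised
#' ping from the segment to the next one (the last ping inherits the
#' previous segment's speed).  Trips shorter than one step are returned
#' unchanged with a warning.
#'
#' @param pings data.frame for one trip with columns `time` (POSIXct or
#'   numeric seconds), `lon`, `lat`; must be sorted, strictly increasing
#' @param step_min interpolation step in minutes (default 10)
#' @return data.frame with columns time, lon, lat, speed_kn
#' @export
interpolate_track <- function(pings, step_min = 10) {
  stopifnot(nrow(pings) >= 2)
  tt <- as.numeric(pings$time)
  if (any(diff(tt) <= 0)) stop("ping timestamps must be strictly increasing")
  step_s <- step_min * 60
  if (tt[length(tt)] - tt[1] < step_s) {
    warning("trip spans less than one interpolation step; returned unchanged")
    out <- data.frame(time = pings$time, lon = pings$lon, lat = pings$lat)
  } else {
    grid_t <- seq(tt[1], tt[length(tt)], by = step_s)
    out <- data.frame(
      time = grid_t,
      lon = stats::approx(tt, pings$lon, xout = grid_t)$y,
      lat = stats::approx(tt, pings$lat, xout = grid_t)$y
    )
  }
  n <- nrow(out)
  if (n >= 2) {
    d_km <- haversine_km(out$lon[-n], out$lat[-n], out$lon[-1], out$lat[-1])
    dt_h <- diff(as.numeric(out$time)) / 3600
    seg_kn <- (d_km / 1.852) / dt_h
    out$speed_kn <- c(seg_kn, seg_kn[n - 1])
  } else {
    out$speed_kn <- 0
  }
  out
}

#' Flag fishing pings by speed
#'
#' A ping is in a fishing state iff its speed lies in the trawling window
#' `[v_min, v_max]` knots (inclusive).  Vessels in port (speed ~0) and
#' steaming vessels fall outside the window.
#'
#' @param pings data.frame with a `speed_kn` column
#' @param v_min,v_max trawling-speed window in knots (defaults 2.0 and 4.5)
#' @return `pings` with an added logical `fishing` column
#' @export
speed_filter <- function(pings, v_min = 2.0, v_max = 4.5) {
  stopifnot(v_min < v_max)
  pings$fishing <- pings$speed_kn >= v_min & pings$speed_kn <= v_max
  pings
}

#' Count fishing points per grid cell
#'
#' Builds the annual effort layer by counting fishing-flagged pings per
#' cell.  Pings outside the grid bounds are dropped; their number is
#' reported via a message.
#'
#' @param pings data.frame with columns lon, lat and logical `fishing`
#' @param grid a `grid_spec`
#' @param year year label
#' @return an `effort_pattern`
#' @export
effort_layer <- function(pings, grid, year = NA_integer_) {
  fp <- pings[pings$fishing, , drop = FALSE]
  cells <- cell_of(grid, fp$lon, fp$lat)
  dropped <- sum(is.na(cells))
  if (dropped > 0) {
    message(dropped, " fishing ping(s) outside grid bounds dropped")
  }
  counts <- tabulate(cells[!is.na(cells)], nbins = grid$n_cells)
  effort_pattern(grid, counts, year = year)
}
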