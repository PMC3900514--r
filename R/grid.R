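#' Build a regular lon/lat analysis grid
#'
#' Cells are squares of `cell_arcmin` arc-minutes, indexed row-major from
#' the north-west corner.  All coordinates are unprojected degrees; cell
#' "distance" computations use great-circle (haversine) kilometres.
#'
#' @param lon_min,lon_max,lat_min,lat_max bounding box in decimal degrees
#' @param cell_arcmin cell side in arc-minutes (default 6, i.e. one tenth of
#'   a degree, roughly 6 nautical miles meridionally)
#' @param active optional logical mask (length nrow*ncol); defaults to all
#'   cells active
#' @return an object of class `grid_spec`
#' @export
grid_spec <- function(lon_min, lon_max, lat_min, lat_max,
                      cell_arcmin = 6, active = NULL) {
  stopifnot(cell_arcmin > 0, lon_max > lon_min, lat_max > lat_min)
  step <- cell_arcmin / 60
  n_col <- max(1L, round((lon_max - lon_min) / step))
  n_row <- max(1L, round((lat_max - lat_min) / step))
  if (is.null(active)) active <- rep(TRUE, n_row * n_col)
  stopifnot(length(active) == n_row * n_col)
  structure(list(
    lon_min = lon_min, lat_min = lat_min,
    lon_max = lon_min + n_col * step, lat_max = lat_min + n_row * step,
    cell_arcmin = cell_arcmin, step = step,
    n_row = n_row, n_col = n_col, n_cells = n_row * n_col,
    active = active
  ), class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %d x %d cells (%g'), %d active, lon [%g, %g], lat [%g, %g]\n",
              x$n_row, x$n_col, x$cell_arcmin, sum(x$active),
              x$lon_min, x$lon_max, x$lat_min, x$lat_max))
  invisible(x)
}

#' Cell-centre coordinates
#'
#' @param grid a `grid_spec`
#' @return data.frame with cell, row, col, lon, lat (row 1 is northernmost)
#' @export
cell_centers <- function(grid) {
  idx <- seq_len(grid$n_cells)
  row <- (idx - 1L) %/% grid$n_col + 1L
  col <- (idx - 1L) %% grid$n_col + 1L
  data.frame(
    cell = idx, row = row, col = col,
    lon = grid$lon_min + (col - 0.5) * grid$step,
    lat = grid$lat_max - (row - 0.5) * grid$step
  )
}

#' Map points to cell indices
#'
#' @param grid a `grid_spec`
#' @param lon,lat coordinate vectors
#' @return integer cell index, NA for points outside the bounding box
#' @export
cell_of <- function(grid, lon, lat) {
  col <- floor((lon - grid$lon_min) / grid$step) + 1L
  row <- floor((grid$lat_max - lat) / grid$step) + 1L
  ok <- col >= 1L & col <= grid$n_col & row >= 1L & row <= grid$n_row
  out <- rep(NA_integer_, length(lon))
  out[ok] <- (row[ok] - 1L) * grid$n_col + col[ok]
  out
}

#' Great-circle distance in kilometres
#'
#' @param lon1,lat1,lon2,lat2 coordinates in degrees (vectorised)
#' @return distance in km
#' @export
haversine_km <- function(lon1, lat1, lon2, lat2) {
  r <- 6371.0088
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad
  dlon <- (lon2 - lon1) * to_rad
  a <- sin(dlat / 2)^2 +
    cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
  2 * r * asin(pmin(1, sqrt(a)))
}

#' One value per grid cell for one variable and year
#'
#' @param grid a `grid_spec`
#' @param values numeric vector of length `grid$n_cells`; NA allowed only on
#'   inactive cells (cells excluded by the interpolation-coverage rule)
#' @param variable variable name (e.g. "abundance", "effort", "depth", "sst")
#' @param year integer year label
#' @return object of class `cell_layer`
#' @export
cell_layer <- function(grid, values, variable = "value", year = NA_integer_) {
  stopifnot(length(values) == grid$n_cells)
  structure(list(grid = grid, values = as.numeric(values),
                 variable = variable, year = year),
            class = "cell_layer")
}

#' @export
print.cell_layer <- function(x, ...) {
  act <- x$values[x$grid$active]
  cat(sprintf("cell_layer '%s' (year %s): %d active cells, range [%g, %g]\n",
              x$variable, x$year, sum(x$grid$active),
              suppressWarnings(min(act, na.rm = TRUE)),
              suppressWarnings(max(act, na.rm = TRUE))))
  invisible(x)
}

#' Inverse-distance-weighted interpolation of station values onto a grid
#'
#' Each active cell receives `sum(w_i v_i)/sum(w_i)` with `w_i = d_i^-power`
#' over the stations whose distance from the cell centre is at most
#' `radius_cells` cell widths (distances in great-circle km, the radius
#' converted at 1 arc-minute = 1 nautical mile).  Cells with no station
#' within the radius are masked out of the returned layer's grid (made
#' inactive, value NA), mirroring the exclusion of uncovered cells from all
#' later analysis steps.  A station coinciding with a cell centre returns
#' that station's value (d -> 0 limit).
#'
#' @param stations data.frame with columns lon, lat, value
#' @param grid a `grid_spec`
#' @param radius_cells neighbourhood radius in cell widths (default 3)
#' @param power IDW distance exponent (default 2)
#' @param variable,year labels for the returned layer
#' @return a `cell_layer` whose grid mask excludes uncovered cells
#' @export
idw_interpolate <- function(stations, grid, radius_cells = 3, power = 2,
                            variable = "value", year = NA_integer_) {
  stopifnot(nrow(stations) >= 1, radius_cells >= 1)
  cc <- cell_centers(grid)
  radius_km <- radius_cells * grid$cell_arcmin * 1.852
  vals <- rep(NA_real_, grid$n_cells)
  covered <- rep(FALSE, grid$n_cells)
  for (i in which(grid$active)) {
    d <- haversine_km(stations$lon, stations$lat, cc$lon[i], cc$lat[i])
    inside <- d <= radius_km
    if (!any(inside)) next
    covered[i] <- TRUE
    d_in <- d[inside]
    v_in <- stations$value[inside]
    if (any(d_in < 1e-9)) {
      vals[i] <- mean(v_in[d_in < 1e-9])
    } else {
      w <- d_in^(-power)
      vals[i] <- sum(w * v_in) / sum(w)
    }
  }
  g2 <- grid
  g2$active <- grid$active & covered
  cell_layer(g2, vals, variable = variable, year = year)
}

#' Per-cell depth indices from bathymetry pixels
#'
#' Summarises the fine-resolution depth pixels falling in one grid cell into
#' the mean depth and its standard deviation (sample sd), the latter a proxy
#' for sea-bottom heterogeneity.  With 1-arc-minute pixels and 6-arc-minute
#' cells there are exactly 36 pixels per cell.
#'
#' @param pixels numeric vector of pixel depths (m) for one cell
#' @param n_expected required pixel count (default 36)
#' @param cell cell id used in error messages
#' @return named numeric vector c(d_mean, d_sd) in metres
#' @export
depth_indices <- function(pixels, n_expected = 36, cell = NA) {
  if (length(pixels) != n_expected) {
    stop("cell ", cell, ": expected ", n_expected, " depth pixels, got ",
         length(pixels))
  }
  c(d_mean = mean(pixels), d_sd = stats::sd(pixels))
}

#' Neighbourhood mean of a cell layer
#'
#' For every active cell, the mean of the active, non-NA values within
#' Chebyshev (king-move) distance `ray`, excluding the cell itself.  Cells
#' with no active neighbour get 0 and a warning is issued once.
#'
#' @param layer a `cell_layer`
#' @param ray neighbourhood radius in cells (default 2)
#' @return a `cell_layer` on the same grid
#' @export
neighbor_mean <- function(layer, ray = 2) {
  stopifnot(ray >= 1)
  g <- layer$grid
  cc <- cell_centers(g)
  vals <- rep(NA_real_, g$n_cells)
  lonely <- 0L
  for (i in which(g$active)) {
    nb <- which(g$active &
                  abs(cc$row - cc$row[i]) <= ray &
                  abs(cc$col - cc$col[i]) <= ray)
    nb <- setdiff(nb, i)
    nb <- nb[!is.na(layer$values[nb])]
    if (length(nb) == 0L) {
      vals[i] <- 0
      lonely <- lonely + 1L
    } else {
      vals[i] <- mean(layer$values[nb])
    }
  }
  if (lonely > 0L) {
    warning(lonely, " cell(s) had no active neighbours; set to 0")
  }
  cell_layer(g, vals, variable = paste0(layer$variable, "_nbmean"),
             year = layer$year)
}

#' Harbour set
#'
#' @param name character vector of harbour names
#' @param lon,lat coordinates in degrees
#' @return data.frame of class `harbor_set`
#' @export
harbor_set <- function(name, lon, lat) {
  stopifnot(length(name) == length(lon), length(lon) == length(lat))
  structure(data.frame(name = name, lon = lon, lat = lat,
                       stringsAsFactors = FALSE),
            class = c("harbor_set", "data.frame"))
}

#' Pattern Score of an effort pattern
#'
#' Fuel-consumption proxy of a spatial effort pattern: the sum over occupied
#' cells of log10(fishing points in the cell) times the mean great-circle
#' distance (km) from the cell centre to its three nearest harbours.  Cells
#' with zero points contribute nothing (the log is taken only on occupied
#' cells, so counts of 1 also contribute 0).
#'
#' @param effort an `effort_pattern` (see [effort_pattern()])
#' @param harbors a `harbor_set` with at least three harbours
#' @return scalar Pattern Score
#' @export
pattern_score <- function(effort, harbors) {
  if (nrow(harbors) < 3L) stop("pattern_score needs at least 3 harbors")
  g <- effort$grid
  counts <- effort$counts
  occ <- which(counts >= 1)
  if (length(occ) == 0L) return(0)
  cc <- cell_centers(g)
  ps <- 0
  for (i in occ) {
    d <- haversine_km(harbors$lon, harbors$lat, cc$lon[i], cc$lat[i])
    md3 <- mean(sort(d)[1:3])
    ps <- ps + log10(counts[i]) * md3
  }
  ps
}

#' Mean distance of each cell to its three nearest harbours
#'
#' @param grid a `grid_spec`
#' @param harbors a `harbor_set` with >= 3 harbours
#' @return numeric vector of length `grid$n_cells` (km)
#' @export
mean_dist3 <- function(grid, harbors) {
  if (nrow(harbors) < 3L) stop("mean_dist3 needs at least 3 harbors")
  cc <- cell_centers(grid)
  vapply(seq_len(grid$n_cells), function(i) {
    d <- haversine_km(harbors$lon, harbors$lat, cc$lon[i], cc$lat[i])
    mean(sort(d)[1:3])
  }, numeric(1))
}

#' Write / read a cell layer as CSV
#'
#' Round-trips the per-cell values with cell ids and centre coordinates.
#'
#' @param layer a `cell_layer`
#' @param path file path
#' @export
write_cell_layer <- function(layer, path) {
  cc <- cell_centers(layer$grid)
  utils::write.csv(
    data.frame(cell_id = cc$cell, lon_center = cc$lon, lat_center = cc$lat,
               value = layer$values),
    path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cell_layer
#' @param grid the `grid_spec` the file was written from
#' @param variable,year labels for the returned layer
#' @export
read_cell_layer <- function(path, grid, variable = "value",
                            year = NA_integer_) {
  df <- utils::read.csv(path)
  stopifnot(nrow(df) == grid$n_cells)
  cell_layer(grid, df$value[order(df$cell_id)], variable = variable,
             year = year)
}
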