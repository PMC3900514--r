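#' Logistic trawl selectivity
#'
#' Retention proportion of the cod-end at length `l`:
#' `S(l) = 1 / (1 + exp(-a (l - L50)))` with steepness
#' `a = log(3) / (L75 - L50)`, the unique logistic satisfying
#' `S(L50) = 0.5` and `S(L75) = 0.75`.
#'
#' @param l length (mm), vectorised
#' @param L50,L75 retention lengths at 50% and 75% (mm), `L75 > L50`
#' @return retention proportion in (0, 1)
#' @export
selectivity <- function(l, L50, L75) {
  stopifnot(L75 > L50)
  a <- log(3) / (L75 - L50)
  1 / (1 + exp(-a * (l - L50)))
}

#' Spatial fishing mortality (harvest rate) per cell and length
#'
#' `f_{c,l} = q * S(l) * e_c`: the product of the fleet catchability, the
#' gear selectivity at length `l` and the effort (fishing points) deployed
#' in the cell.  All vessels are assumed to have the same catching power.
#'
#' @param l length (mm), vectorised
#' @param effort_counts per-cell effort (fishing points), vectorised
#' @param q fleet catchability (per fishing point)
#' @param L50,L75 selectivity parameters (mm)
#' @return matrix cells x lengths of harvest rates (recycled if one of the
#'   two inputs is scalar)
#' @export
spatial_f <- function(l, effort_counts, q, L50, L75) {
  s <- selectivity(l, L50, L75)
  outer(effort_counts, s) * q
}

#' Estimate fleet catchability from a reference fishing mortality
#'
#' Finds the `q` minimising `sum_c (F_ref * n_c - q * e_c * n_c)^2`, the
#' squared difference between the reference theoretical catches (reference
#' mortality times standing numbers) and the effort-generated ones.  Solved
#' by 1-D numerical minimisation; the closed-form weighted-least-squares
#' solution `q* = F_ref * sum(n^2 e) / sum(n^2 e^2)` is the oracle it must
#' agree with to 1e-6 relative.
#'
#' @param F_ref reference total fishing mortality (from external assessment)
#' @param n per-cell standing numbers (individuals)
#' @param e per-cell effort counts
#' @param ref_catches optional per-cell reference catches replacing
#'   `F_ref * n` (e.g. catches generated under a known catchability)
#' @return estimated q
#' @export
estimate_q <- function(F_ref, n, e, ref_catches = NULL) {
  stopifnot(length(n) == length(e))
  if (is.null(ref_catches)) ref_catches <- F_ref * n
  stopifnot(length(ref_catches) == length(n))
  keep <- !is.na(n) & !is.na(e) & !is.na(ref_catches)
  n <- n[keep]; e <- e[keep]; r <- ref_catches[keep]
  if (!any(n > 0 & e > 0)) stop("q unidentifiable: no cell with n > 0 and e > 0")
  obj <- function(q) sum((r - q * e * n)^2)
  q_closed <- sum(r * e * n) / sum(e^2 * n^2)
  opt <- stats::optimize(obj, interval = c(0, max(2 * q_closed, 1e-12)))
  q <- opt$minimum
  if (abs(q - q_closed) > 1e-6 * max(abs(q_closed), 1e-12)) {
    # polish with the closed form if the bracket search lost precision
    q <- q_closed
  }
  q
}

#' Survey-gear catchability from paired stock estimates
#'
#' Ratio of the absolute standing stock in number (external assessment) to
#' the relative swept-area standing stock from the survey.  Values above 1
#' (herding) are allowed but reported.
#'
#' @param n_lca absolute standing stock in number
#' @param n_swept swept-area standing stock in number
#' @return catchability ratio qM
#' @export
medits_catchability <- function(n_lca, n_swept) {
  stopifnot(n_swept > 0)
  qm <- n_lca / n_swept
  if (qm > 1) message("survey catchability ratio > 1 (", round(qm, 3), ")")
  qm
}

#' Catches in number and biomass per cell and length class
#'
#' Converts relative survey indices into absolute standing numbers with the
#' survey catchability (`n = qM * index`), applies the per-cell harvest
#' rate (`c = n * f`, with `f` capped at 1 so that catch never exceeds
#' standing numbers; a warning names the affected cells) and converts
#' numbers to biomass with the length-weight power law evaluated at the
#' class midpoint (`h_kg = c * a * l^b / 1000`, weights in grams).
#'
#' @param index cells x lengths matrix of relative abundance indices
#' @param mids length-class midpoints (mm), one per column
#' @param effort_counts per-cell effort, length nrow(index)
#' @param q,L50,L75,qM,a,b species parameters
#' @return list(numbers, kg): two cells x lengths matrices
#' @export
catches <- function(index, mids, effort_counts, q, L50, L75, qM, a, b) {
  stopifnot(ncol(index) == length(mids),
            nrow(index) == length(effort_counts))
  n <- qM * index
  f <- spatial_f(mids, effort_counts, q, L50, L75)
  over <- which(rowSums(f > 1, na.rm = TRUE) > 0)
  if (length(over) > 0) {
    warning("harvest rate f > 1 capped in cell(s): ",
            paste(utils::head(over, 10), collapse = ", "))
    f <- pmin(f, 1)
  }
  cnum <- n * f
  w_kg <- (a * mids^b) / 1000
  kg <- sweep(cnum, 2, w_kg, `*`)
  list(numbers = cnum, kg = kg)
}

#' Revenue of a catch at banded size prices
#'
#' `R = sum_l P(l) * h_kg(l)` with `P(l)` the per-kg price of the size band
#' containing the class midpoint.  Every class with nonzero catch must fall
#' in a band.
#'
#' @param kg cells x lengths catch biomass matrix (kg), or a vector of
#'   per-class totals
#' @param mids class midpoints (mm)
#' @param species species code used against the schedule
#' @param prices price schedule as from [default_prices()]
#' @return revenue in euros
#' @export
revenue <- function(kg, mids, species, prices = default_prices()) {
  if (is.matrix(kg)) kg <- colSums(kg, na.rm = TRUE)
  stopifnot(length(kg) == length(mids))
  sched <- prices[prices$species == species, , drop = FALSE]
  if (nrow(sched) == 0L) stop("no price schedule for species ", species)
  p <- vapply(mids, function(l) {
    row <- which(l >= sched$min_mm & l < sched$max_mm)
    if (length(row) == 0L) NA_real_ else sched$price_eur_kg[row[1]]
  }, numeric(1))
  bad <- is.na(p) & kg > 0
  if (any(bad)) {
    stop("unpriced length class for ", species, ": ",
         paste(mids[bad], collapse = ", "), " mm")
  }
  p[is.na(p)] <- 0
  sum(p * kg)
}

#' Fit the fleet fuel-cost model by ordinary least squares
#'
#' Regresses the total annual fuel cost on the effort Pattern Score and the
#' mean annual fuel price: `TC = b0 + b_PS * PS + b_E * E`.
#'
#' @param records data.frame with columns `PS`, `E`, `TC` (one row per year)
#' @return object of class `cost_model` with coefficients and diagnostics
#' @export
fit_cost_model <- function(records) {
  stopifnot(all(c("PS", "E", "TC") %in% names(records)),
            nrow(records) >= 4)
  fit <- stats::lm(TC ~ PS + E, data = records)
  cf <- stats::coef(fit)
  singular <- anyNA(cf)
  sm <- if (singular) NULL else summary(fit)
  structure(list(
    b0 = unname(cf[1]), b_PS = unname(cf["PS"]), b_E = unname(cf["E"]),
    singular = singular,
    table = if (is.null(sm)) NULL else stats::coef(sm),
    sigma = if (is.null(sm)) NA_real_ else sm$sigma,
    n = nrow(records)
  ), class = "cost_model")
}

#' @export
print.cost_model <- function(x, ...) {
  cat("cost_model: TC = b0 + b_PS * PS + b_E * E\n")
  if (x$singular) {
    cat("  [singular fit: collinear or constant regressor]\n")
  } else {
    print(x$table)
  }
  invisible(x)
}

#' Predict the fleet fuel cost of an effort pattern
#'
#' @param model a `cost_model`
#' @param PS Pattern Score of the effort pattern
#' @param E mean annual fuel price
#' @return predicted total fuel cost (euros)
#' @export
predict_cost <- function(model, PS, E) {
  if (model$singular) stop("cannot predict from a singular cost model")
  model$b0 + model$b_PS * PS + model$b_E * E
}

#' Gains of an effort pattern
#'
#' @param R revenue (euros)
#' @param TC total cost (euros)
#' @return `G = R - TC`
#' @export
gains <- function(R, TC) R - TC

#' Overall fishing mortality as a number-weighted harvest ratio
#'
#' `F = sum(c) / sum(n)` over all cells and length classes: the fraction of
#' standing numbers harvested under the given effort pattern.
#'
#' @param catch_numbers cells x lengths catch matrix (numbers)
#' @param standing_numbers cells x lengths standing-stock matrix (numbers)
#' @return scalar F; NA with a warning when the stock is empty
#' @export
total_F <- function(catch_numbers, standing_numbers) {
  n_tot <- sum(standing_numbers, na.rm = TRUE)
  if (n_tot <= 0) {
    warning("zero total abundance: F undefined")
    return(NA_real_)
  }
  sum(catch_numbers, na.rm = TRUE) / n_tot
}

#' Length at age from the von Bertalanffy growth function
#'
#' Bookkeeping helper linking cohort age to expected length:
#' `L(t) = Linf * (1 - exp(-k (t - t0)))`.
#'
#' @param age age in years, vectorised
#' @param Linf,k,t0 growth parameters
#' @return expected length (same units as Linf)
#' @export
length_at_age <- function(age, Linf, k, t0) {
  Linf * (1 - exp(-k * (age - t0)))
}
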