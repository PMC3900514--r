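#' Configuration of the Elman recurrent predictor
#'
#' The network has one hidden layer whose activations are copied into an
#' equally sized bank of context units after every lag step; inputs for the
#' four lag years are fed sequentially and the output (next-year cohort
#' abundances, scaled to \[0,1\]) is read after the last step.  Logistic
#' activations throughout.  Training restarts differ only in their random
#' weight initialisation; the restart with the best held-out Pearson
#' correlation is kept.
#'
#' @param n_hidden hidden (= context) units, default 10
#' @param lr learning rate of full-batch gradient descent, default 0.1
#' @param max_epochs maximum training epochs per restart, default 500
#' @param tol stop when the loss change falls below this, default 1e-5
#' @param restarts random restarts, default 100
#' @param test_frac fraction of cells held out for evaluation, default 0.3
#' @param seed integer seed controlling the split and all initialisations
#' @return list of class `elman_config`
#' @export
elman_config <- function(n_hidden = 10, lr = 0.1, max_epochs = 500,
                         tol = 1e-5, restarts = 100, test_frac = 0.3,
                         seed = 1L) {
  stopifnot(restarts >= 1, n_hidden >= 1, test_frac > 0, test_frac < 1)
  structure(list(n_hidden = n_hidden, lr = lr, max_epochs = max_epochs,
                 tol = tol, restarts = restarts, test_frac = test_frac,
                 seed = as.integer(seed)),
            class = "elman_config")
}

# log10(x+1): admits zero abundances/effort
.log1p10 <- function(x) log10(x + 1)

#' Assemble the lagged training tensor for one species
#'
#' One sample per grid cell that is active (non-NA) in every input year.
#' Per lag year the feature vector is: cohort abundances (sexes kept as
#' separate columns), neighbour-mean cohort abundances (Chebyshev ray 2),
#' fishing effort, mean depth, depth sd, and that year's SST.  Abundances
#' and effort are `log10(x+1)` transformed; all features and targets are
#' then min-max scaled to \[0,1\] per variable (pooling lags); zero-range
#' variables map to 0.  Targets are the (transformed, scaled) cohort
#' abundances of the year following the last lag.
#'
#' @param cohorts named list (by year, as character) of cells x cohorts
#'   abundance matrices; must cover the 4 lag years and the target year
#' @param effort named list by year of per-cell effort counts
#' @param d_mean,d_sd per-cell depth indices (m)
#' @param sst named list by year of per-cell SST (deg C)
#' @param grid a `grid_spec` (its mask selects candidate cells)
#' @param years integer vector of the 4 lag years, oldest first
#' @param target_year year being predicted (usually `max(years) + 1`)
#' @return list of class `elman_dataset`: `X` (cells x 4 x d_in array),
#'   `Y` (cells x cohorts), `cells`, `scalers`, `groups` (feature-group
#'   labels for importance reporting)
#' @export
build_dataset <- function(cohorts, effort, d_mean, d_sd, sst, grid,
                          years, target_year) {
  stopifnot(length(years) == 4)
  need <- as.character(c(years, target_year))
  for (nm in need) {
    if (!(nm %in% names(cohorts))) stop("missing cohort layers for year ", nm)
  }
  for (nm in as.character(years)) {
    if (!(nm %in% names(effort))) stop("missing effort layer for year ", nm)
    if (!(nm %in% names(sst))) stop("missing SST layer for year ", nm)
  }
  n_coh <- ncol(cohorts[[need[1]]])
  n_cells <- grid$n_cells

  # neighbour means per lag year and cohort
  nb <- lapply(as.character(years), function(y) {
    m <- cohorts[[y]]
    vapply(seq_len(n_coh), function(h) {
      lay <- cell_layer(grid, ifelse(grid$active, m[, h], NA_real_))
      suppressWarnings(neighbor_mean(lay, ray = 2))$values
    }, numeric(n_cells))
  })

  keep <- grid$active
  for (y in need) keep <- keep & !apply(is.na(cohorts[[y]]), 1, any)
  keep <- keep & !is.na(d_mean) & !is.na(d_sd)
  cells <- which(keep)
  if (length(cells) == 0L) stop("no cell is complete across all years")

  d_in <- 2 * n_coh + 4
  groups <- c(rep("own_cohorts", n_coh), rep("neighbor_cohorts", n_coh),
              "effort", "d_mean", "d_sd", "sst")
  raw <- array(NA_real_, dim = c(length(cells), 4, d_in))
  for (t in 1:4) {
    y <- as.character(years[t])
    raw[, t, ] <- cbind(
      .log1p10(cohorts[[y]][cells, , drop = FALSE]),
      .log1p10(nb[[t]][cells, , drop = FALSE]),
      .log1p10(effort[[y]][cells]),
      d_mean[cells], d_sd[cells], sst[[y]][cells])
  }
  y_raw <- .log1p10(cohorts[[as.character(target_year)]][cells, ,
                                                         drop = FALSE])

  # min-max per feature column, pooled over lags
  x_min <- apply(raw, 3, min); x_max <- apply(raw, 3, max)
  X <- raw
  for (j in seq_len(d_in)) {
    rng <- x_max[j] - x_min[j]
    X[, , j] <- if (rng > 0) (raw[, , j] - x_min[j]) / rng else 0
  }
  y_min <- apply(y_raw, 2, min); y_max <- apply(y_raw, 2, max)
  Y <- y_raw
  for (j in seq_len(ncol(Y))) {
    rng <- y_max[j] - y_min[j]
    Y[, j] <- if (rng > 0) (y_raw[, j] - y_min[j]) / rng else 0
  }
  structure(list(X = X, Y = Y, cells = cells, groups = groups,
                 scalers = list(x_min = x_min, x_max = x_max,
                                y_min = y_min, y_max = y_max),
                 years = years, target_year = target_year),
            class = "elman_dataset")
}

#' Invert the dataset target scaling back to individuals
#'
#' @param dataset an `elman_dataset`
#' @param Ys matrix of scaled targets/predictions (cells x cohorts)
#' @return abundances in individuals
#' @export
unscale_targets <- function(dataset, Ys) {
  sc <- dataset$scalers
  out <- Ys
  for (j in seq_len(ncol(Ys))) {
    rng <- sc$y_max[j] - sc$y_min[j]
    out[, j] <- Ys[, j] * (if (rng > 0) rng else 0) + sc$y_min[j]
  }
  10^out - 1
}

#' Forward pass of the Elman network
#'
#' Context units start at zero for every sample sequence; at each lag step
#' `h = sigma(x W_in + c W_ctx + b_h)` and the context is overwritten with
#' `h`; after the last step the output is `sigma(h W_out + b_o)`.
#'
#' @param net a `trained_elman` (or bare weight list with elements W_in,
#'   W_ctx, W_out, b_h, b_o)
#' @param X samples x lags x inputs array (a single sample may be given as
#'   a lags x inputs matrix)
#' @return samples x outputs matrix, entries in (0, 1)
#' @export
elman_forward <- function(net, X) {
  if (length(dim(X)) == 2L) X <- array(X, dim = c(1, dim(X)))
  n <- dim(X)[1]; n_lag <- dim(X)[2]
  if (dim(X)[3] != nrow(net$W_in)) stop("input dimension mismatch")
  H <- matrix(0, n, ncol(net$W_in))
  for (t in seq_len(n_lag)) {
    A <- X[, t, , drop = FALSE]
    dim(A) <- c(n, dim(X)[3])
    H <- stats::plogis(A %*% net$W_in + H %*% net$W_ctx +
                         matrix(net$b_h, n, length(net$b_h), byrow = TRUE))
  }
  stats::plogis(H %*% net$W_out +
                  matrix(net$b_o, n, length(net$b_o), byrow = TRUE))
}

# one full training run from a given initialisation; returns NULL on NaN
.elman_fit_once <- function(X, Y, cfg, init) {
  n <- dim(X)[1]; n_lag <- dim(X)[2]; d <- dim(X)[3]
  nh <- cfg$n_hidden; no <- ncol(Y)
  net <- init
  loss_hist <- numeric(0)
  loss_old <- Inf
  for (epoch in seq_len(cfg$max_epochs)) {
    # forward, caching states
    Hs <- vector("list", n_lag)
    Cs <- vector("list", n_lag)  # context entering step t
    H <- matrix(0, n, nh)
    for (t in seq_len(n_lag)) {
      Cs[[t]] <- H
      A <- X[, t, , drop = FALSE]; dim(A) <- c(n, d)
      H <- stats::plogis(A %*% net$W_in + H %*% net$W_ctx +
                           matrix(net$b_h, n, nh, byrow = TRUE))
      Hs[[t]] <- H
    }
    out <- stats::plogis(H %*% net$W_out +
                           matrix(net$b_o, n, no, byrow = TRUE))
    err <- out - Y
    loss <- mean(err^2)
    if (!is.finite(loss)) return(NULL)
    loss_hist <- c(loss_hist, loss)
    if (abs(loss_old - loss) < cfg$tol) break
    loss_old <- loss
    # backward (truncated BPTT through the unrolled lags)
    d_out <- 2 * err * out * (1 - out) / n
    g_Wout <- t(H) %*% d_out
    g_bo <- colSums(d_out)
    dH <- d_out %*% t(net$W_out)
    g_Win <- matrix(0, d, nh); g_Wctx <- matrix(0, nh, nh)
    g_bh <- numeric(nh)
    for (t in rev(seq_len(n_lag))) {
      d_pre <- dH * Hs[[t]] * (1 - Hs[[t]])
      A <- X[, t, , drop = FALSE]; dim(A) <- c(n, d)
      g_Win <- g_Win + t(A) %*% d_pre
      g_Wctx <- g_Wctx + t(Cs[[t]]) %*% d_pre
      g_bh <- g_bh + colSums(d_pre)
      dH <- d_pre %*% t(net$W_ctx)
    }
    net$W_in <- net$W_in - cfg$lr * g_Win
    net$W_ctx <- net$W_ctx - cfg$lr * g_Wctx
    net$W_out <- net$W_out - cfg$lr * g_Wout
    net$b_h <- net$b_h - cfg$lr * g_bh
    net$b_o <- net$b_o - cfg$lr * g_bo
  }
  net$loss_hist <- loss_hist
  net
}

#' Train the Elman predictor with random restarts
#'
#' Splits the cells into train/test subsets under `config$seed`, then runs
#' `config$restarts` independent gradient-descent trainings from random
#' initialisations.  Each restart's held-out Pearson correlation (pooled
#' over cohort outputs) is recorded; the restart with the best test `r` is
#' returned (ties go to the earlier restart).  Restarts whose loss turns
#' non-finite are aborted and logged; if all abort, an error is raised.
#'
#' @param dataset an `elman_dataset` from [build_dataset()]
#' @param config an [elman_config()]
#' @return object of class `trained_elman`: weights, config, the train/test
#'   indices, `test_r`, per-restart `restart_r`, and the winning restart's
#'   loss history
#' @export
elman_train <- function(dataset, config = elman_config()) {
  X <- dataset$X; Y <- dataset$Y
  n <- dim(X)[1]; d <- dim(X)[3]; no <- ncol(Y); nh <- config$n_hidden
  old_seed <- .save_rng()
  on.exit(.restore_rng(old_seed), add = TRUE)
  set.seed(config$seed)
  n_test <- max(1L, round(config$test_frac * n))
  test_idx <- sort(sample.int(n, n_test))
  train_idx <- setdiff(seq_len(n), test_idx)
  if (length(train_idx) == 0L) stop("no training cells left after split")
  Xtr <- X[train_idx, , , drop = FALSE]; Ytr <- Y[train_idx, , drop = FALSE]
  Xte <- X[test_idx, , , drop = FALSE]; Yte <- Y[test_idx, , drop = FALSE]

  best <- NULL; best_r <- -Inf; restart_r <- rep(NA_real_, config$restarts)
  aborted <- 0L
  for (r in seq_len(config$restarts)) {
    scale <- 1 / sqrt(d)
    init <- list(
      W_in = matrix(stats::runif(d * nh, -scale, scale), d, nh),
      W_ctx = matrix(stats::runif(nh * nh, -scale, scale), nh, nh),
      W_out = matrix(stats::runif(nh * no, -scale, scale), nh, no),
      b_h = stats::runif(nh, -scale, scale),
      b_o = stats::runif(no, -scale, scale))
    net <- .elman_fit_once(Xtr, Ytr, config, init)
    if (is.null(net)) {
      aborted <- aborted + 1L
      next
    }
    ev <- elman_evaluate(net, Xte, Yte)
    restart_r[r] <- if (ev$flagged) NA_real_ else ev$r
    if (!ev$flagged && ev$r > best_r) {
      best_r <- ev$r
      best <- net
    }
  }
  if (aborted > 0L) message(aborted, " restart(s) aborted on non-finite loss")
  if (is.null(best)) stop("all training restarts failed")
  structure(list(W_in = best$W_in, W_ctx = best$W_ctx, W_out = best$W_out,
                 b_h = best$b_h, b_o = best$b_o,
                 loss_hist = best$loss_hist, test_r = best_r,
                 restart_r = restart_r, config = config,
                 train_idx = train_idx, test_idx = test_idx,
                 groups = dataset$groups),
            class = "trained_elman")
}

#' @export
print.trained_elman <- function(x, ...) {
  cat(sprintf("trained_elman: %d-%d-%d (+%d context), test r = %.3f over %d restart(s)\n",
              nrow(x$W_in), ncol(x$W_in), ncol(x$W_out), ncol(x$W_ctx),
              x$test_r, x$config$restarts))
  invisible(x)
}

#' Pooled Pearson correlation between observed and predicted abundances
#'
#' @param net a `trained_elman` or bare weight list
#' @param X samples x lags x inputs array
#' @param Y observed scaled targets (samples x outputs)
#' @return list(r, n, flagged); `flagged` is TRUE when either vector has
#'   zero variance (r undefined)
#' @export
elman_evaluate <- function(net, X, Y) {
  if (length(dim(X)) == 2L) X <- array(X, dim = c(1, dim(X)))
  if (dim(X)[1] < 3) stop("need at least 3 held-out samples")
  pred <- elman_forward(net, X)
  obs <- as.vector(Y); prd <- as.vector(pred)
  if (stats::sd(obs) == 0 || stats::sd(prd) == 0) {
    return(list(r = NA_real_, n = length(obs), flagged = TRUE))
  }
  list(r = stats::cor(obs, prd), n = length(obs), flagged = FALSE)
}

#' Garson relative importance of input groups
#'
#' For each input `i`, sums over hidden units the product of its share of
#' the absolute input weights into that unit and the unit's absolute
#' output weight (summed over outputs):
#' `c_i = sum_h (|w_ih| / sum_k |w_kh|) * sum_o |w_ho|`.
#' Contributions are aggregated by input group and normalised so the
#' relative importances sum to 100.  Context weights do not enter the
#' decomposition (they carry no input identity).
#'
#' @param net a `trained_elman` (or weight list with W_in, W_out)
#' @param groups character/factor vector, one group label per input row of
#'   `W_in`; defaults to `net$groups`
#' @return data.frame group, ri (percentages summing to 100)
#' @export
garson_ri <- function(net, groups = net$groups) {
  W_in <- abs(net$W_in); W_out <- abs(net$W_out)
  stopifnot(length(groups) == nrow(W_in))
  col_tot <- colSums(W_in)
  out_strength <- rowSums(W_out)
  d <- nrow(W_in)
  contrib <- numeric(d)
  for (h in seq_len(ncol(W_in))) {
    if (col_tot[h] > 0) {
      contrib <- contrib + W_in[, h] / col_tot[h] * out_strength[h]
    }
  }
  if (sum(contrib) == 0) {
    warning("all-zero weights: equal importance assigned")
    contrib <- rep(1, d)
  }
  agg <- tapply(contrib, groups, sum)
  ri <- 100 * agg / sum(agg)
  data.frame(group = names(ri), ri = as.numeric(ri), row.names = NULL)
}
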