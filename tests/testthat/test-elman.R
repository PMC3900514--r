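# Elman network: forward pass, training, evaluation, Garson importance

rand_net <- function(d, nh, no, seed = 1, scale = 1) {
  set.seed(seed)
  list(W_in = matrix(runif(d * nh, -scale, scale), d, nh),
       W_ctx = matrix(runif(nh * nh, -scale, scale), nh, nh),
       W_out = matrix(runif(nh * no, -scale, scale), nh, no),
       b_h = runif(nh, -scale, scale), b_o = runif(no, -scale, scale))
}

test_that("forward pass: sigma(0) limit, context-free equivalence,
           lag-order sensitivity, bounded outputs", {
  d <- 3; nh <- 4; no <- 2
  X <- array(runif(5 * 4 * d), dim = c(5, 4, d))
  # all-zero weights -> every output 0.5
  z <- list(W_in = matrix(0, d, nh), W_ctx = matrix(0, nh, nh),
            W_out = matrix(0, nh, no), b_h = rep(0, nh), b_o = rep(0, no))
  expect_equal(as.vector(elman_forward(z, X)), rep(0.5, 10))
  # W_ctx = 0: equals a plain MLP on the last lag only
  net <- rand_net(d, nh, no, seed = 2)
  net$W_ctx <- matrix(0, nh, nh)
  out <- elman_forward(net, X)
  x_last <- X[, 4, ]
  h <- plogis(x_last %*% net$W_in +
                matrix(net$b_h, 5, nh, byrow = TRUE))
  oracle <- plogis(h %*% net$W_out + matrix(net$b_o, 5, no, byrow = TRUE))
  expect_equal(out, oracle, tolerance = 1e-12)
  # with context, permuting the lag order changes the output
  net2 <- rand_net(d, nh, no, seed = 3)
  Xr <- X[, 4:1, , drop = FALSE]
  expect_false(isTRUE(all.equal(elman_forward(net2, X),
                                elman_forward(net2, Xr))))
  # outputs strictly inside (0, 1) and deterministic
  o1 <- elman_forward(net2, X)
  expect_true(all(o1 > 0 & o1 < 1))
  expect_identical(o1, elman_forward(net2, X))
  expect_error(elman_forward(net2, X[, , 1:2]), "dimension")
})

test_that("training learns a smooth target and restarts are reproducible", {
  set.seed(42)
  n <- 250; d <- 4
  X <- array(runif(n * 4 * d), dim = c(n, 4, d))
  # noiseless smooth function of the last-lag features
  y <- plogis(3 * X[, 4, 1] - 2 * X[, 4, 2] + X[, 3, 3] - 1)
  ds <- structure(list(X = X, Y = matrix(y, ncol = 1),
                       groups = paste0("x", 1:d)), class = "elman_dataset")
  cfg <- elman_config(n_hidden = 6, lr = 0.8, max_epochs = 800,
                      tol = 1e-9, restarts = 3, seed = 5)
  net <- elman_train(ds, cfg)
  expect_gte(net$test_r, 0.95)
  # loss trajectory of the winning restart is nonincreasing overall
  lh <- net$loss_hist
  expect_lt(lh[length(lh)], lh[1])
  # determinism with restarts = 1
  cfg1 <- elman_config(n_hidden = 4, lr = 0.5, max_epochs = 50,
                       restarts = 1, seed = 9)
  n1 <- elman_train(ds, cfg1)
  n2 <- elman_train(ds, cfg1)
  expect_identical(n1$W_in, n2$W_in)
  expect_identical(n1$test_r, n2$test_r)
})

test_that("a pure-noise target yields a test correlation near zero", {
  set.seed(43)
  n <- 200; d <- 3
  X <- array(runif(n * 4 * d), dim = c(n, 4, d))
  y <- runif(n)
  ds <- structure(list(X = X, Y = matrix(y, ncol = 1),
                       groups = paste0("x", 1:d)), class = "elman_dataset")
  cfg <- elman_config(n_hidden = 4, lr = 0.3, max_epochs = 150,
                      restarts = 2, seed = 6)
  net <- elman_train(ds, cfg)
  # |r| below the ~2/sqrt(n_test) noise scale (n_test = 60), with margin
  expect_lt(abs(net$test_r), 0.35)
})

test_that("evaluation is plain pooled Pearson correlation", {
  set.seed(8)
  obs <- matrix(runif(30), 10, 3)
  net <- rand_net(2, 3, 3, seed = 4)
  X <- array(runif(10 * 4 * 2), dim = c(10, 4, 2))
  pred <- elman_forward(net, X)
  ev <- elman_evaluate(net, X, obs)
  # textbook covariance formula oracle
  o <- as.vector(obs); p <- as.vector(pred)
  r_oracle <- sum((o - mean(o)) * (p - mean(p))) /
    sqrt(sum((o - mean(o))^2) * sum((p - mean(p))^2))
  expect_equal(ev$r, r_oracle, tolerance = 1e-12)
  # r = 1 and r = -1 limits via a direct correlation check
  expect_equal(cor(p, p), 1)
  expect_equal(cor(p, -p + 2), -1)
  # zero-variance observation vector is flagged
  ev0 <- elman_evaluate(net, X, matrix(0.5, 10, 3))
  expect_true(ev0$flagged)
  expect_error(elman_evaluate(net, X[1:2, , , drop = FALSE], obs[1:2, ]),
               "at least 3")
})

test_that("Garson importance: brute-force path oracle, symmetry, edge cases", {
  # 3-2-1 toy net, exhaustive path enumeration
  net <- rand_net(3, 2, 1, seed = 11)
  ri <- garson_ri(net, groups = c("a", "b", "c"))
  W <- abs(net$W_in); V <- abs(net$W_out)
  contrib <- sapply(1:3, function(i)
    sum(sapply(1:2, function(h) W[i, h] / sum(W[, h]) * V[h, 1])))
  oracle <- 100 * contrib / sum(contrib)
  expect_equal(ri$ri[match(c("a", "b", "c"), ri$group)], oracle,
               tolerance = 1e-12)
  expect_equal(sum(ri$ri), 100, tolerance = 1e-9)
  # a single input with nonzero weights takes all the importance
  net2 <- net
  net2$W_in[2:3, ] <- 0
  ri2 <- garson_ri(net2, groups = c("a", "b", "c"))
  expect_equal(ri2$ri[ri2$group == "a"], 100)
  # mirrored inputs share importance equally
  net3 <- net
  net3$W_in[2, ] <- net3$W_in[1, ]
  ri3 <- garson_ri(net3, groups = c("a", "b", "c"))
  expect_equal(ri3$ri[ri3$group == "a"], ri3$ri[ri3$group == "b"])
  # all-zero weights: equal split with warning
  net4 <- net
  net4$W_in[] <- 0; net4$W_out[] <- 0
  expect_warning(ri4 <- garson_ri(net4, groups = c("a", "b", "c")),
                 "all-zero")
  expect_equal(ri4$ri, rep(100 / 3, 3))
})

test_that("RI sums to 100 for random nets of assorted shapes", {
  for (s in 1:10) {
    d <- sample(3:12, 1); nh <- sample(2:8, 1); no <- sample(1:6, 1)
    net <- rand_net(d, nh, no, seed = s)
    groups <- sample(letters[1:3], d, replace = TRUE)
    expect_equal(sum(garson_ri(net, groups)$ri), 100, tolerance = 1e-9)
  }
})

test_that("best-of-restarts beats r = 0.8 when next-year abundance is a
           known smooth function of the inputs", {
  w <- tiny_world()
  g <- w$grid
  set.seed(20)
  n_coh <- 4
  eff <- setNames(lapply(1:4, function(y) rpois(g$n_cells, 20)), 1:4)
  base <- exp(-((w$d_mean - 150) / 120)^2 / 2)
  coh <- list()
  coh[["1"]] <- outer(1e4 * base * exp(rnorm(g$n_cells, 0, 0.3)),
                      rep(1, n_coh))
  for (y in 2:5) {
    prev <- coh[[as.character(y - 1)]]
    coh[[as.character(y)]] <- prev *
      exp(0.3 * base - 0.004 * eff[[as.character(min(y - 1, 4))]])
  }
  ds <- build_dataset(coh, eff, w$d_mean, w$d_sd, w$sst, g,
                      years = 1:4, target_year = 5)
  net <- elman_train(ds, elman_config(restarts = 10, max_epochs = 500,
                                      lr = 0.5, seed = 3))
  expect_gte(net$test_r, 0.8)
  # importance decomposition is dominated by the abundance groups
  ri <- garson_ri(net)
  coh_ri <- sum(ri$ri[ri$group %in% c("own_cohorts", "neighbor_cohorts")])
  expect_gt(coh_ri, ri$ri[ri$group == "sst"])
})

test_that("build_dataset scales to [0,1], masks incomplete cells,
           and target unscaling round-trips", {
  w <- tiny_world()
  pl <- tiny_pipeline()
  sp <- "MUT"
  coh <- pl$cohorts$sex[[sp]]
  eff <- lapply(pl$effort, function(e) e$counts)
  ds <- build_dataset(coh, eff, w$d_mean, w$d_sd, w$sst, w$grid,
                      years = 1:4, target_year = 5)
  expect_true(all(ds$X >= 0 & ds$X <= 1))
  expect_true(all(ds$Y >= 0 & ds$Y <= 1))
  # cells with NA in any year are excluded
  bad <- which(apply(is.na(coh[["1"]]), 1, any))
  expect_length(intersect(ds$cells, bad), 0)
  # unscaling returns the original abundances
  orig <- coh[["5"]][ds$cells, , drop = FALSE]
  expect_equal(unscale_targets(ds, ds$Y), orig, tolerance = 1e-8,
               ignore_attr = TRUE)
  # missing year errors by name
  expect_error(build_dataset(coh, eff, w$d_mean, w$d_sd, w$sst, w$grid,
                             years = 2:5, target_year = 6), "6")
})
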