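# selectivity, spatial F, catchability estimation, catches, revenue,
# cost model, gains, overall F

test_that("logistic selectivity hits its defining quantiles", {
  pars <- default_species_params()
  for (i in seq_len(nrow(pars))) {
    expect_equal(selectivity(pars$L50[i], pars$L50[i], pars$L75[i]), 0.5)
    expect_equal(selectivity(pars$L75[i], pars$L50[i], pars$L75[i]), 0.75)
    # logistic symmetry about L50: S(2*L50 - L75) = 0.25
    expect_equal(selectivity(2 * pars$L50[i] - pars$L75[i],
                             pars$L50[i], pars$L75[i]), 0.25)
  }
  # strictly increasing on the working range, saturating tails
  s <- selectivity(seq(0, 300, by = 5), 120, 140)
  expect_true(all(diff(s) > 0))
  expect_lt(selectivity(-500, 120, 140), 1e-9)
  expect_gt(selectivity(2000, 120, 140), 1 - 1e-9)
  expect_error(selectivity(10, 20, 20))
})

test_that("spatial_f multiplies catchability, selectivity and effort", {
  # q = 0.002, S = 1 (far above L75), e = 100 -> f = 0.2
  f <- spatial_f(1e5, 100, q = 0.002, L50 = 15, L75 = 18)
  expect_equal(f[1, 1], 0.2, tolerance = 1e-9)
  expect_equal(spatial_f(20, 0, 0.002, 15, 18)[1, 1], 0)
  # increasing in length at fixed q, e
  f2 <- spatial_f(c(10, 15, 20, 25), 50, 0.002, 15, 18)
  expect_true(all(diff(f2[1, ]) > 0))
})

test_that("estimate_q matches the closed-form WLS oracle on random cases", {
  set.seed(21)
  for (rep in 1:100) {
    n <- runif(30, 0.1, 100)
    e <- rpois(30, 20) + 1
    F_ref <- runif(1, 0.2, 2)
    q <- estimate_q(F_ref, n, e)
    q_star <- F_ref * sum(n^2 * e) / sum(n^2 * e^2)
    expect_equal(q, q_star, tolerance = 1e-6)
  }
  # uniform effort: q = F / e
  expect_equal(estimate_q(1.2, runif(10, 1, 5), rep(600, 10)), 0.002,
               tolerance = 1e-9)
  expect_error(estimate_q(1, c(0, 0), c(1, 1)), "unidentifiable")
})

test_that("q is recovered from catches generated under the true value", {
  set.seed(31)
  q_true <- species_params("DPS", "F")$q          # 0.0022
  n <- runif(100, 1, 1000)
  e <- rpois(100, 50) + 1
  ref <- q_true * e * n
  q_hat <- estimate_q(NULL, n, e, ref_catches = ref)
  expect_lt(abs(q_hat - q_true), 1e-4)
  expect_equal(q_hat, q_true, tolerance = 1e-6)
})

test_that("survey catchability is a plain ratio with logging above 1", {
  expect_equal(medits_catchability(85, 100), 0.85)
  expect_equal(medits_catchability(15, 100), 0.15)
  expect_equal(medits_catchability(42, 42), 1)
  expect_message(qm <- medits_catchability(120, 100), "> 1")
  expect_equal(qm, 1.2)
})

test_that("catches agree with a brute-force double loop and cap f at 1", {
  set.seed(7)
  n_cell <- 12; mids <- seq(10, 40, by = 2)
  idx <- matrix(runif(n_cell * length(mids), 0, 50), n_cell)
  e <- rpois(n_cell, 30)
  pr <- species_params("DPS", "F")
  ct <- catches(idx, mids, e, q = pr$q, L50 = pr$L50, L75 = pr$L75,
                qM = pr$qM, a = pr$a, b = pr$b)
  # loop oracle
  a_steep <- log(3) / (pr$L75 - pr$L50)
  tot <- 0; tot_kg <- 0
  for (c_ in seq_len(n_cell)) {
    for (j in seq_along(mids)) {
      s <- 1 / (1 + exp(-a_steep * (mids[j] - pr$L50)))
      f <- min(pr$q * s * e[c_], 1)
      cn <- pr$qM * idx[c_, j] * f
      tot <- tot + cn
      tot_kg <- tot_kg + cn * pr$a * mids[j]^pr$b / 1000
    }
  }
  expect_equal(sum(ct$numbers), tot, tolerance = 1e-9)
  expect_equal(sum(ct$kg), tot_kg, tolerance = 1e-9)
  # f = 0 everywhere -> zero catches; n = 100, f = 0.1 -> c = 10
  ct0 <- catches(idx, mids, rep(0, n_cell), pr$q, pr$L50, pr$L75,
                 pr$qM, pr$a, pr$b)
  expect_equal(sum(ct0$numbers), 0)
  ct1 <- catches(matrix(100), 1e5, 0.1 / 0.002, q = 0.002, L50 = 15,
                 L75 = 18, qM = 1, a = 1, b = 1)
  expect_equal(ct1$numbers[1, 1], 10, tolerance = 1e-6)
  # homogeneity of degree 1 in abundance
  ct2 <- catches(2 * idx, mids, e, pr$q, pr$L50, pr$L75, pr$qM, pr$a, pr$b)
  expect_equal(sum(ct2$numbers), 2 * sum(ct$numbers), tolerance = 1e-9)
  # cap warning
  expect_warning(
    catches(idx, mids, rep(1e6, n_cell), pr$q, pr$L50, pr$L75,
            pr$qM, pr$a, pr$b), "capped")
})

test_that("revenue prices catches by size band", {
  # 1 kg of large shrimp (>= 30 mm band) -> 16 euros
  expect_equal(revenue(1, mids = 32, species = "DPS"), 16)
  # 2 kg at 23 mm (21-25 band, 5 euros/kg) -> 10 euros
  expect_equal(revenue(2, mids = 23, species = "DPS"), 10)
  expect_equal(revenue(0, mids = 23, species = "DPS"), 0)
  expect_error(revenue(1, mids = 20, species = "XXX"), "no price schedule")
  # matrix input sums over cells
  kg <- matrix(c(1, 1), 2, 1)
  expect_equal(revenue(kg, 32, "DPS"), 32)
})

test_that("cost model: exact recovery, rank deficiency, orthogonality", {
  co <- default_cost_coefficients()
  set.seed(17)
  rec <- data.frame(PS = runif(6, 5000, 30000), E = runif(6, 0.9, 1.4))
  rec$TC <- co["b0"] + co["b_PS"] * rec$PS + co["b_E"] * rec$E
  m <- suppressWarnings(fit_cost_model(rec))
  expect_equal(m$b0, unname(co["b0"]), tolerance = 1e-9)
  expect_equal(m$b_PS, unname(co["b_PS"]), tolerance = 1e-9)
  expect_equal(m$b_E, unname(co["b_E"]), tolerance = 1e-9)
  # constant PS: singular, flagged
  rec2 <- rec; rec2$PS <- 1000
  expect_true(fit_cost_model(rec2)$singular)
  # residuals orthogonal to regressors under noise
  rec3 <- rec; rec3$TC <- rec3$TC + rnorm(6, 0, 1e5)
  m3 <- fit_cost_model(rec3)
  res <- rec3$TC - predict_cost(m3, rec3$PS, rec3$E)
  expect_equal(sum(res), 0, tolerance = 1e-6)
  expect_equal(sum(res * rec3$PS), 0, tolerance = 1e-3)
  expect_equal(sum(res * rec3$E), 0, tolerance = 1e-6)
})

test_that("predict_cost is the linear plane", {
  co <- default_cost_coefficients()
  m <- structure(list(b0 = unname(co["b0"]), b_PS = unname(co["b_PS"]),
                      b_E = unname(co["b_E"]), singular = FALSE),
                 class = "cost_model")
  expect_equal(predict_cost(m, 0, 0), unname(co["b0"]))
  expect_equal(predict_cost(m, 1e4, 1.25), 2642500)
  # linearity in PS
  expect_equal(predict_cost(m, 1e4 + 7, 1.25) - predict_cost(m, 1e4, 1.25),
               7 * unname(co["b_PS"]), tolerance = 1e-6)
})

test_that("gains is revenue minus cost", {
  expect_equal(gains(0, 0), 0)
  expect_equal(gains(100, 40), 60)
  r <- runif(5); tc <- runif(5)
  expect_equal(gains(r, tc) + tc, r)
})

test_that("total_F is the number-weighted harvest ratio", {
  set.seed(4)
  n <- matrix(runif(20, 10, 100), 4)
  expect_equal(total_F(0.1 * n, n), 0.1, tolerance = 1e-12)
  # cell relabelling leaves F unchanged
  perm <- sample(4)
  expect_equal(total_F(0.1 * n[perm, ], n[perm, ]), 0.1)
  expect_warning(f <- total_F(n * 0, n * 0), "undefined")
  expect_true(is.na(f))
  # small-f regime: doubling effort approximately doubles F
  mids <- seq(20, 40, 5)
  e <- rpois(4, 5)
  pr <- species_params("DPS", "F")
  ct1 <- catches(n[, 1:5], mids, e, q = 1e-5, L50 = pr$L50, L75 = pr$L75,
                 qM = 1, a = pr$a, b = pr$b)
  ct2 <- catches(n[, 1:5], mids, 2 * e, q = 1e-5, L50 = pr$L50,
                 L75 = pr$L75, qM = 1, a = pr$a, b = pr$b)
  f1 <- total_F(ct1$numbers, n[, 1:5])
  f2 <- total_F(ct2$numbers, n[, 1:5])
  expect_equal(f2 / f1, 2, tolerance = 1e-6)
})
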