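test_that("post-bounce distance d* follows the three-sigma Brownian step rule", {
  expect_equal(d_star(1.18e-10, 1e-7, 2.5e-6), 2.5252e-6, tolerance = 1e-4)
  # vanishing step collapses onto the receiver surface
  expect_equal(d_star(1.18e-10, 1e-30, 2.5e-6), 2.5e-6, tolerance = 1e-8)
  expect_lt(d_star(1e-10, 1e-7, 2.5e-6), d_star(2e-10, 1e-7, 2.5e-6))
  expect_lt(d_star(1e-10, 1e-7, 2.5e-6), d_star(1e-10, 2e-7, 2.5e-6))
  expect_error(d_star(-1, 1e-7, 2.5e-6), "> 0")
})

test_that("capture probability is a probability, grows with n, and vanishes with the pulse period", {
  pcs <- vapply(c(50, 100, 1000, 5000, 10000),
                function(nn) capture_probability(table1_config(n = nn)),
                numeric(1))
  expect_true(all(pcs >= 0 & pcs <= 1))
  expect_true(all(diff(pcs) > 0))
  expect_lte(pcs[1], 0.02)          # few tens of receptors: order 1-2%
  expect_lt(capture_probability(table1_config(delta_t = 1e-9, grid_dt = 1e-9)),
            1e-12)
})

test_that("recapture feedback raises the arrival rate as specified", {
  expect_identical(lambda_o_prime(0, 0.65, 0.25), 0)
  expect_equal(lambda_o_prime(0.04, 0, 0.25), 0.04)        # no feedback
  expect_equal(lambda_o_prime(0.0394, 0.65, 0.25),
               0.0394 * (1 + 0.65 * 0.0394 / 0.2894), tolerance = 1e-12)
  expect_true(lambda_o_prime(0.1, 0.5, 0.25) >= 0.1)
  expect_error(lambda_o_prime(0.1, 0.5, 0), "mu must be > 0")
  expect_error(lambda_o_prime(0.1, 1.5, 0.25), "Pc")
})

test_that("load, rejection and absorption rates satisfy the Erlang-B identities", {
  expect_equal(receptor_load(0.25, 0.25), 1)
  expect_identical(receptor_load(0, 0.25), 0)
  expect_equal(receptor_load(0.0429, 0.25), 0.1716)
  expect_error(receptor_load(0.1, -1), "mu must be > 0")
  expect_equal(rejection_rate(1, 0.25), 0.125)
  expect_equal(absorption_rate(1, 0.25), 0.125)
  expect_identical(rejection_rate(0, 0.25), 0)
  set.seed(7)
  Ao <- runif(50, 0, 20); mu <- runif(50, 1e-3, 10)
  lop <- Ao * mu
  # conservation and the single-server blocking fraction
  expect_equal(absorption_rate(Ao, mu) + rejection_rate(Ao, mu), lop,
               tolerance = 1e-14)
  expect_equal(rejection_rate(Ao, mu) / lop, Ao / (1 + Ao), tolerance = 1e-14)
})

test_that("rate series conserves molecules and integrates consistently", {
  cfg <- table1_config()
  ser <- build_rate_series(cfg)
  n <- cfg$n
  expect_equal(n * (ser$lambda_a + ser$lambda_r), ser$Lambda_o_prime,
               tolerance = 1e-13)
  expect_true(all(diff(ser$N_r) >= 0) && all(diff(ser$N_a) >= 0))
  expect_true(all(ser$E_busy >= 0 & ser$E_busy <= n))
  m <- nrow(ser)
  total_in <- pracma::trapz(ser$t, ser$Lambda_o_prime)
  expect_equal(ser$N_r[m] + ser$N_a[m], total_in, tolerance = 1e-3)
  # load bounded by its steady-state value
  Ao_bound <- lambda_o_prime(rabsorb_steady(cfg) / n, attr(ser, "Pc"), cfg$mu) / cfg$mu
  expect_true(all(ser$Ao <= Ao_bound * (1 + 1e-12)))
})

test_that("a silent transmitter produces an all-zero series", {
  ser0 <- build_rate_series(table1_config(Q = 0, t_end = 1))
  expect_true(all(as.matrix(ser0[, -1]) == 0))
})

test_that("cumulative counts are stable under grid refinement", {
  cfg <- table1_config()
  cfg_half <- table1_config(grid_dt = cfg$grid_dt / 2)
  a <- build_rate_series(cfg);  b <- build_rate_series(cfg_half)
  expect_equal(b$N_r[nrow(b)], a$N_r[nrow(a)], tolerance = 5e-3)
  expect_equal(b$N_a[nrow(b)], a$N_a[nrow(a)], tolerance = 5e-3)
})

test_that("saturable steady state recovers the absorbing receiver as trafficking accelerates", {
  cfg <- table1_config()
  target <- rabsorb_steady(cfg)
  expect_equal(steady_state_absorption(table1_config(mu = 1e6)), target,
               tolerance = 1e-4)
  expect_equal(steady_state_absorption(table1_config(mu = 1e9)), target,
               tolerance = 1e-6)
  las <- vapply(c(0.1, 0.25, 0.5, 2, 10, 100),
                function(m) steady_state_absorption(table1_config(mu = m)),
                numeric(1))
  expect_true(all(diff(las) > 0))
  expect_true(all(las < target))
  # reference operating point: n lambda_o' / (1 + Ao) ~ 366 molecules/s
  expect_equal(steady_state_absorption(cfg), 366, tolerance = 2e-3)
})
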