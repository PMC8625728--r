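test_that("Stokes-Einstein coefficient reproduces the reference D and scales inversely", {
  D <- stokes_einstein_D(310, 1.1e-3, 1.75e-9)
  expect_equal(D, 1.18e-10, tolerance = 0.03)
  expect_equal(stokes_einstein_D(310, 1.1e-3, 2 * 1.75e-9), D / 2)
  expect_error(stokes_einstein_D(310, -1e-3, 1.75e-9), "> 0")
  expect_error(stokes_einstein_D(0, 1.1e-3, 1.75e-9), "> 0")
})

test_that("hitting fraction is zero at t = 0 and approaches its analytic supremum", {
  cfg <- table1_config()
  expect_identical(fhit_cumulative(0, cfg), 0)
  expect_error(fhit_cumulative(-1, cfg), "t must be >= 0")
  sup <- fhit_sup(cfg)            # (Rr/d) * n rs / (n rs + pi Rr) ~ 0.0789
  expect_equal(sup, 0.0789, tolerance = 1e-3)
  tt <- 10^seq(-3, 9, length.out = 80)
  f <- fhit_cumulative(tt, cfg)
  expect_true(all(diff(f) >= 0))                 # nondecreasing
  expect_true(all(f <= sup + 1e-15))             # bounded by the supremum
  expect_equal(fhit_cumulative(1e9, cfg), sup, tolerance = 1e-4)
})

test_that("hitting fraction grows with receptor count and reaches the absorbing-sphere limit", {
  f_at_1s <- vapply(c(50, 100, 1000, 5000, 10000),
                    function(nn) fhit_cumulative(1, table1_config(n = nn)),
                    numeric(1))
  expect_true(all(diff(f_at_1s) > 0))
  # n rs / (pi Rr) ~ 5e5 >> 1e4: receptor factor indistinguishable from 1
  cfg_inf <- table1_config(n = 1e9)
  t_chk <- c(0.5, 1, 5)
  expect_equal(fhit_cumulative(t_chk, cfg_inf),
               sphere_cdf(t_chk, cfg_inf$D, cfg_inf$d, cfg_inf$Rr),
               tolerance = 1e-4)
})

test_that("window fractions telescope exactly", {
  cfg <- table1_config()
  expect_identical(fhit_window(0.3, 0.3, cfg), 0)
  expect_equal(fhit_window(0, 2, cfg), fhit_cumulative(2, cfg))
  set.seed(42)
  cuts <- c(0, sort(runif(9, 0, 4)), 4)
  parts <- fhit_window(cuts[-length(cuts)], cuts[-1], cfg)
  expect_equal(sum(parts), fhit_cumulative(4, cfg), tolerance = 1e-12)
  expect_error(fhit_window(2, 1, cfg), "t1 must not exceed t2")
})

test_that("pulsed-emission rate telescopes to the continuous-emission form on the pulse grid", {
  cfg <- table1_config()
  expect_identical(rabsorb_rate(0, cfg), 0)
  expect_error(rabsorb_rate(-0.1, cfg), "t must be >= 0")
  # on pulse-aligned times the sum over complete windows telescopes exactly
  t_al <- c(1, 2.5, 5, 10)
  expect_equal(rabsorb_rate(t_al, cfg),
               (cfg$Q / cfg$delta_t) * fhit_cumulative(t_al, cfg),
               tolerance = 1e-12)
  # off the grid the agreement is approximate but tight
  t_off <- c(1.2345, 7.34567)
  expect_equal(rabsorb_rate(t_off, cfg),
               (cfg$Q / cfg$delta_t) * fhit_cumulative(t_off, cfg),
               tolerance = 5e-3)
})

test_that("pulsed-emission rate is linear in Q and approaches the steady state monotonically", {
  cfg <- table1_config()
  cfg2 <- table1_config(Q = 100)
  tt <- c(0.5, 2, 10)
  expect_equal(rabsorb_rate(tt, cfg2), 2 * rabsorb_rate(tt, cfg), tolerance = 1e-12)
  expect_equal(rabsorb_steady(cfg), 394.3, tolerance = 1e-3)
  expect_equal(rabsorb_steady(cfg2) / rabsorb_steady(cfg), 2)
  # gap to the steady state shrinks as t grows (O(1/sqrt(t)) approach)
  cfg_long <- table1_config(t_end = 5000)
  gaps <- 1 - rabsorb_rate(c(100, 500, 5000), cfg_long) / rabsorb_steady(cfg_long)
  expect_true(all(gaps > 0) && all(diff(gaps) < 0))
  # n -> Inf: receptor factor -> 1
  expect_equal(rabsorb_steady(table1_config(n = 1e12)),
               (cfg$Q / cfg$delta_t) * cfg$Rr / cfg$d, tolerance = 1e-8)
})

test_that("per-receptor arrival rate is the aggregate split by n", {
  cfg <- table1_config()
  tt <- c(1, 5, 10)
  expect_equal(lambda_o(tt, cfg), rabsorb_rate(tt, cfg) / cfg$n)
  cfg1 <- table1_config(n = 1)
  expect_equal(lambda_o(tt, cfg1), rabsorb_rate(tt, cfg1))
})
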