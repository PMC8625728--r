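test_that("oracle refuses coarse steps and respects the diffusion lag", {
  expect_error(simulate_absorbing_sphere(100, 1.18e-10, 26.5e-6, 2.5e-6,
                                         dt = 5e-3, t_max = 1, seed = 1),
               "too coarse")
  expect_error(simulate_absorbing_sphere(100, 1.18e-10, 2.0e-6, 2.5e-6,
                                         dt = 1e-5, t_max = 1, seed = 1),
               "must exceed")
  # horizon far below the diffusion time (d-Rr)^2 / (100 D): nothing arrives
  lag <- simulate_absorbing_sphere(200, 1.18e-10, 26.5e-6, 2.5e-6,
                                   dt = 2e-5, t_max = 0.04, seed = 2)
  expect_true(all(lag$empirical_fhit == 0))
})

test_that("oracle runs are reproducible from the seed", {
  a <- simulate_absorbing_sphere(150, 1.18e-10, 6e-6, 2.5e-6,
                                 dt = 4e-4, t_max = 0.2, seed = 8)
  b <- simulate_absorbing_sphere(150, 1.18e-10, 6e-6, 2.5e-6,
                                 dt = 4e-4, t_max = 0.2, seed = 8)
  expect_identical(a, b)
})

test_that("per-axis step variance matches 2 D dt within chi-square bounds", {
  # absorption-free setting: release far from a small sphere, short horizon
  N <- 400; D <- 1e-10; dt <- 1e-4; steps <- 100
  orc <- simulate_absorbing_sphere(N, D, d = 1e-3, Rr = 1e-6, dt = dt,
                                   t_max = steps * dt, seed = 13)
  expect_true(all(is.na(orc$fp_times)))
  sig2 <- 2 * D * dt * steps              # per-axis variance after all steps
  for (ax in c("x", "y")) {
    v <- sum(orc$final_pos[, ax]^2) / N   # mean zero by construction
    expect_gt(v * N / sig2, qchisq(5e-4, N))
    expect_lt(v * N / sig2, qchisq(1 - 5e-4, N))
  }
})

test_that("empirical first-passage CDF matches the analytic absorbing sphere", {
  D <- 1.18e-10; d <- 6e-6; Rr <- 2.5e-6
  orc <- simulate_absorbing_sphere(4000, D, d, Rr, dt = 1e-4, t_max = 0.3,
                                   seed = 21)
  m <- length(orc$t_grid)
  ana <- sphere_cdf(orc$t_grid[m], D, d, Rr)
  # within 3 binomial SE plus a 10% one-sided discretization allowance
  dev <- orc$empirical_fhit[m] - ana
  if (dev < 0) dev <- min(dev + 0.1 * ana, 0)
  expect_lt(abs(dev), 3 * orc$se[m])
  cmp <- validate_fhit_limit(orc)
  expect_lt(attr(cmp, "max_abs_z"), 4)
  expect_true(all(diff(orc$empirical_fhit) >= 0))
})

test_that("end-of-step discretization bias is one-sided and shrinks with dt", {
  D <- 1.18e-10; d <- 6e-6; Rr <- 2.5e-6
  emp <- vapply(c(4e-4, 2e-4, 1e-4), function(dt) {
    o <- simulate_absorbing_sphere(20000, D, d, Rr, dt = dt, t_max = 0.3,
                                   seed = 11)
    o$empirical_fhit[length(o$t_grid)]
  }, numeric(1))
  ana <- sphere_cdf(0.3, D, d, Rr)
  expect_true(all(emp < ana))          # underestimate, no bridge correction
  expect_true(all(diff(emp) > 0))      # monotone approach as dt shrinks
})

test_that("oracle validation flags parameter mismatches and model bias", {
  orc <- simulate_absorbing_sphere(1000, 1.18e-10, 6e-6, 2.5e-6,
                                   dt = 2e-4, t_max = 0.2, seed = 17)
  wrong <- table1_config(d = 7e-6)
  expect_error(validate_fhit_limit(orc, config = wrong), "mismatch")
  expect_error(validate_fhit_limit(structure(list(t_grid = numeric(0), N = 0),
                                             class = "oracle_result")),
               "empty")
  # halving the model sphere radius must show up as systematic positive bias
  cmp_bias <- validate_fhit_limit(orc, Rr_model = 2.5e-6 / 2)
  expect_gt(max(cmp_bias$z), 6)
})
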