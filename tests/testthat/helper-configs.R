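# shared configurations for the test suite

# reference parameter set, optionally overriding fields
table1_config <- function(...) {
  cfg <- fixture_config("table1_q50_mu4")
  over <- list(...)
  for (f in names(over)) cfg[[f]] <- over[[f]]
  suppressWarnings(validate_config(cfg))  # huge-n limits trip the area warning
  cfg
}

# analytic supremum of the cumulative hitting fraction
fhit_sup <- function(cfg, d = cfg$d) {
  (cfg$Rr / d) * cfg$n * cfg$rs / (cfg$n * cfg$rs + pi * cfg$Rr)
}

# absorbing-sphere first-passage CDF (independent closed form)
sphere_cdf <- function(t, D, d, Rr) {
  ifelse(t > 0, (Rr / d) * 2 * pnorm((d - Rr) / sqrt(2 * D * t),
                                     lower.tail = FALSE), 0)
}

# hand-made constant-rate series for driving the queue bank directly
constant_rate_series <- function(cfg, rate_aggregate) {
  tg <- seq(0, cfg$t_end, by = cfg$grid_dt)
  structure(data.frame(t = tg,
                       Lambda_o_prime = rep(rate_aggregate, length(tg)),
                       N_r = NA_real_, N_a = NA_real_),
            class = c("rate_series", "data.frame"), config = cfg, Pc = 0)
}
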