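#' Post-bounce distance d*
#'
#' Distance of a ligand from the receiver centre just after bouncing off a
#' busy receptor: three standard deviations of a one-axis Brownian
#' displacement in one particle time step, scaled by `sqrt(3)` for the
#' three-dimensional motion, measured outward from the receiver surface:
#' `d* = sqrt(3) * 3 * sqrt(2 * D * dt_particle) + Rr`.
#'
#' @param D diffusion coefficient, m^2/s.
#' @param dt_particle particle-simulation time step, s.
#' @param Rr receiver radius, m.
#' @return Distance in metres, `> Rr`.
#' @examples
#' d_star(1.18e-10, 1e-7, 2.5e-6)  # 2.5252e-6 m
#' @export
d_star <- function(D, dt_particle, Rr) {
  if (any(D <= 0) || any(dt_particle <= 0) || any(Rr <= 0))
    stop("D, dt_particle and Rr must all be > 0")
  sqrt(3) * 3 * sqrt(2 * D * dt_particle) + Rr
}

#' Capture probability of a bounced ligand
#'
#' Probability that a molecule rejected by a busy receptor, now sitting at
#' the post-bounce distance [d_star()] from the receiver centre, reaches the
#' receiver's receptors again within one emission period `delta_t` (the
#' interval during which the pulse that carried it dominates). Evaluated as
#' the cumulative hitting fraction at `delta_t` with the centre distance
#' replaced by d*. It is a property of the configuration, constant in time,
#' and grows with the receptor count `n`.
#'
#' @param config a [model_config()].
#' @return Probability in `[0, 1]`.
#' @examples
#' cfg <- fixture_config("table1_q50_mu4")
#' capture_probability(cfg)            # about 0.65 at n = 10,000
#' @export
capture_probability <- function(config) {
  stopifnot(inherits(config, "model_config"))
  ds <- d_star(config$D, config$dt_particle, config$Rr)
  pc <- fhit_cumulative(config$delta_t, config, d_override = ds)
  min(max(pc, 0), 1)
}

#' Effective per-receptor arrival rate with recapture feedback
#'
#' Total Poisson arrival rate seen by one receptor: fresh arrivals at rate
#' `lambda_o` plus re-attempts by bounced molecules. A fraction
#' `lambda_o / (mu + lambda_o)` of arrivals find the receptor busy, and each
#' bounced molecule returns with probability `Pc`, giving
#' `lambda_o_prime = lambda_o * (1 + Pc * lambda_o / (mu + lambda_o))`.
#' The overflow stream is treated as Poisson (its true law has heavier
#' variance; the approximation is part of the model).
#'
#' @param lambda_o_t fresh per-receptor arrival rate(s), 1/s.
#' @param Pc capture probability in `[0, 1]`.
#' @param mu trafficking rate, 1/s.
#' @return Effective rate, `>= lambda_o_t`; equals it when `Pc = 0`.
#' @export
lambda_o_prime <- function(lambda_o_t, Pc, mu) {
  if (any(lambda_o_t < 0)) stop("lambda_o_t must be >= 0")
  if (any(Pc < 0 | Pc > 1)) stop("Pc must lie in [0, 1]")
  if (any(mu <= 0)) stop("mu must be > 0")
  lambda_o_t * (1 + Pc * lambda_o_t / (mu + lambda_o_t))
}

#' Per-receptor offered load
#'
#' `Ao = lambda_o_prime / mu`, the offered traffic of one receptor in
#' Erlangs. (Named `receptor_load` because `load` is a base R function.)
#'
#' @param lambda_o_prime_t effective arrival rate(s), 1/s.
#' @param mu trafficking rate, 1/s.
#' @return Dimensionless load, `>= 0`.
#' @export
receptor_load <- function(lambda_o_prime_t, mu) {
  if (any(mu <= 0)) stop("mu must be > 0")
  lambda_o_prime_t / mu
}

#' Per-receptor rejection rate
#'
#' Offered load times the single-server loss probability
#' `Ao / (1 + Ao)` (Erlang-B with one server), expressed as a rate:
#' `lambda_r = Ao^2 * mu / (1 + Ao)`.
#'
#' @param Ao offered load(s), dimensionless, `>= 0`.
#' @param mu trafficking rate, 1/s.
#' @return Rejection rate, 1/s.
#' @export
rejection_rate <- function(Ao, mu) {
  if (any(Ao < 0)) stop("Ao must be >= 0")
  Ao^2 * mu / (1 + Ao)
}

#' Per-receptor absorption rate
#'
#' The complement of [rejection_rate()] within the effective arrival stream:
#' `lambda_a = Ao * mu / (1 + Ao)`, so that
#' `lambda_a + lambda_r = lambda_o_prime` exactly.
#'
#' @inheritParams rejection_rate
#' @return Absorption rate, 1/s.
#' @export
absorption_rate <- function(Ao, mu) {
  if (any(Ao < 0)) stop("Ao must be >= 0")
  Ao * mu / (1 + Ao)
}

#' Build the full time-resolved rate series
#'
#' Evaluates the saturation chain on the configuration's time grid
#' `seq(0, t_end, by = grid_dt)`: fresh per-receptor rate `lambda_o(t)`
#' from the pulsed-emission diffusion model, the capture probability `Pc`
#' (constant in time), the effective rate `lambda_o_prime`, the load `Ao`,
#' rejection and absorption rates, their receiver-level aggregates
#' (`Lambda_* = n * lambda_*`), cumulative rejection and absorption counts
#' `N_r`, `N_a` by trapezoidal integration, and the expected number of busy
#' receptors `E_busy = n * Ao / (1 + Ao)`.
#'
#' @param config a [model_config()].
#' @return A `"rate_series"`: a data.frame with columns `t`, `lambda_o`,
#'   `lambda_o_prime`, `Ao`, `lambda_r`, `lambda_a`, `Lambda_o_prime`,
#'   `Lambda_r`, `Lambda_a`, `N_r`, `N_a`, `E_busy`, carrying the
#'   configuration and `Pc` as attributes.
#' @examples
#' cfg <- fixture_config("table1_q50_mu4")
#' ser <- build_rate_series(cfg)
#' tail(ser, 1)[, c("t", "N_r", "N_a")]   # cumulative counts at 10 s
#' @export
build_rate_series <- function(config) {
  stopifnot(inherits(config, "model_config"))
  tg <- seq(0, config$t_end, by = config$grid_dt)
  if (length(tg) < 2) stop("grid misconfiguration: fewer than 2 grid points")
  lo <- lambda_o(tg, config)
  Pc <- capture_probability(config)
  lop <- lambda_o_prime(lo, Pc, config$mu)
  Ao <- receptor_load(lop, config$mu)
  lr <- rejection_rate(Ao, config$mu)
  la <- absorption_rate(Ao, config$mu)
  n <- config$n
  ser <- data.frame(t = tg, lambda_o = lo, lambda_o_prime = lop, Ao = Ao,
                    lambda_r = lr, lambda_a = la,
                    Lambda_o_prime = n * lop, Lambda_r = n * lr,
                    Lambda_a = n * la,
                    N_r = as.numeric(pracma::cumtrapz(tg, n * lr)),
                    N_a = as.numeric(pracma::cumtrapz(tg, n * la)),
                    E_busy = n * Ao / (1 + Ao))
  structure(ser, class = c("rate_series", "data.frame"),
            config = config, Pc = Pc)
}

#' @export
print.rate_series <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("<rate_series> %d points, t in [%g, %g] s, Pc = %.4g\n",
              nrow(x), min(x$t), max(x$t), attr(x, "Pc")))
  last <- x[nrow(x), ]
  cat(sprintf("  at t = %g s: N_a = %.1f absorbed, N_r = %.1f rejected, E_busy = %.1f of %g\n",
              last$t, last$N_a, last$N_r, last$E_busy, cfg$n))
  NextMethod()
}

#' Steady-state receiver absorption rate with saturable receptors
#'
#' The `t -> Inf` aggregate absorption rate `Lambda_a = n * lambda_o' /
#' (1 + Ao)`, evaluated with the steady-state fresh rate
#' `lambda_o = rabsorb_steady / n`. As `mu -> Inf` (instantaneous
#' trafficking) the load vanishes and this tends to [rabsorb_steady()]:
#' the saturable receiver reduces to the absorbing one.
#'
#' @param config a [model_config()].
#' @return Rate in molecules/s.
#' @export
steady_state_absorption <- function(config) {
  stopifnot(inherits(config, "model_config"))
  lo <- rabsorb_steady(config) / config$n
  Pc <- capture_probability(config)
  lop <- lambda_o_prime(lo, Pc, config$mu)
  Ao <- receptor_load(lop, config$mu)
  config$n * lop / (1 + Ao)
}
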