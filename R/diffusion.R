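#' Stokes-Einstein diffusion coefficient
#'
#' `D = kB * T / (6 * pi * eta * rm)` for a spherical molecule of radius
#' `rm` in a medium of viscosity `eta` at absolute temperature `T`.
#'
#' @param temperature absolute temperature, K.
#' @param viscosity dynamic viscosity, Pa s.
#' @param rm molecule (hydrodynamic) radius, m.
#' @return Diffusion coefficient, m^2/s.
#' @examples
#' stokes_einstein_D(310, 1.1e-3, 1.75e-9)  # ~1.18e-10 m^2/s
#' @export
stokes_einstein_D <- function(temperature, viscosity, rm) {
  if (any(temperature <= 0) || any(viscosity <= 0) || any(rm <= 0))
    stop("temperature, viscosity and rm must all be > 0")
  D <- .kB * temperature / (6 * pi * viscosity * rm)
  if (any(!is.finite(D) | D <= 0)) stop("derived diffusion coefficient is not positive/finite")
  D
}

# core hitting-fraction kernel, vectorized in t (seconds), SI inputs.
# Fhit(t) = (Rr/d) * (n rs / (n rs + pi Rr)) *
#           [ erfc(u) - erfcx(B) * exp(-u^2) ],
# u = (d - Rr)/sqrt(4 D t),  B = u + alpha * sqrt(D t),
# alpha = (n rs + pi Rr)/(pi Rr^2).
# The erfcx form is the algebraically exact rewriting of
# exp(A) * erfc(B) with A - B^2 = -u^2; the naive exp(A) overflows.
.fhit <- function(t, Rr, rs, n, d, D) {
  pref <- (Rr / d) * (n * rs / (n * rs + pi * Rr))
  alpha <- (n * rs + pi * Rr) / (pi * Rr^2)
  out <- numeric(length(t))
  pos <- t > 0
  if (any(pos)) {
    tp <- t[pos]
    sq <- sqrt(4 * D * tp)
    u <- (d - Rr) / sq
    B <- u + alpha * sqrt(D * tp)
    out[pos] <- pref * (erfc(u) - erfcx(B) * exp(-u * u))
  }
  pmax(out, 0)
}

#' Cumulative hitting fraction of an n-receptor spherical receiver
#'
#' Expected fraction of a single pulse, released at time 0 from distance
#' `d`, that has been absorbed by the receiver's `n` receptors by time `t`.
#' The receptor coverage enters through the factor
#' `n rs / (n rs + pi Rr)`, which tends to 1 as `n` grows; in that limit the
#' curve reduces to the classic absorbing-sphere first-passage CDF
#' `(Rr/d) * erfc((d - Rr)/sqrt(4 D t))`. Evaluation uses the scaled
#' complementary error function ([erfcx()]) so the exponential terms never
#' overflow; `t = 0` returns 0 by continuity.
#'
#' @param t time since the pulse, s (vectorized, `t >= 0`).
#' @param config a [model_config()] supplying `Rr`, `rs`, `n`, `d`, `D`.
#' @param d_override optional replacement for the centre distance `d`, m
#'   (used for the capture probability, where the post-bounce distance d*
#'   takes the role of d).
#' @return Fraction in `[0, 1)`, nondecreasing in `t`, with supremum
#'   `(Rr/d) * n rs / (n rs + pi Rr)`.
#' @examples
#' cfg <- fixture_config("table1_q50_mu4")
#' fhit_cumulative(c(0.1, 1, 10), cfg)
#' @export
fhit_cumulative <- function(t, config, d_override = NULL) {
  stopifnot(inherits(config, "model_config"))
  if (any(t < 0)) stop("t must be >= 0")
  d <- if (is.null(d_override)) config$d else d_override
  if (any(d <= config$Rr)) stop("distance must exceed the receiver radius Rr")
  .fhit(t, config$Rr, config$rs, config$n, d, config$D)
}

#' Hitting fraction over a time window
#'
#' Fraction of a pulse absorbed between `t1` and `t2`:
#' `fhit_cumulative(t2) - fhit_cumulative(t1)`.
#'
#' @inheritParams fhit_cumulative
#' @param t1,t2 window bounds, s, `0 <= t1 <= t2` (vectorized in parallel).
#' @return Nonnegative fraction.
#' @export
fhit_window <- function(t1, t2, config, d_override = NULL) {
  if (any(t1 > t2)) stop("t1 must not exceed t2")
  pmax(fhit_cumulative(t2, config, d_override) -
         fhit_cumulative(t1, config, d_override), 0)
}

#' Absorption rate under pulsed emission (absorbing receptors)
#'
#' Instantaneous rate of molecule arrivals at the receptor-covered receiver
#' when the transmitter emits `Q` molecules every `delta_t` seconds. Each
#' past pulse `k` (released at `t_k = k * delta_t`) contributes its window
#' hitting fraction over the last `delta_t`, divided by
#' `min(t - t_k, delta_t)`:
#' `rabsorb(t) = Q * sum_k Fhit_k(t - delta_t, t) / min(t - t_k, delta_t)`.
#' Pulses with age `t - t_k` below half the evaluation-grid spacing are
#' dropped: their divisor approaches 0/0 while the diffusion lag makes the
#' true contribution negligible (first arrivals take of order
#' `(d - Rr)^2 / (4 D)` seconds, far longer than a pulse period at the
#' packaged geometry). The pulse train stops at the horizon `t_end`.
#'
#' @param t evaluation time(s), s, `t >= 0`.
#' @param config a [model_config()].
#' @return Rate in molecules/s (aggregate over all receptors).
#' @examples
#' cfg <- fixture_config("table1_q50_mu4")
#' rabsorb_rate(c(1, 5, 10), cfg)
#' rabsorb_steady(cfg)  # the t -> Inf limit
#' @export
rabsorb_rate <- function(t, config) {
  stopifnot(inherits(config, "model_config"))
  if (any(t < 0)) stop("t must be >= 0")
  dt <- config$delta_t
  eps <- config$grid_dt / 2
  vapply(t, function(ti) {
    if (ti <= 0 || config$Q == 0) return(0)
    NK <- min(floor(ti / dt), floor(config$t_end / dt))
    k <- 0:NK
    age <- ti - k * dt                      # t - t_k
    keep <- age >= eps
    if (!any(keep)) return(0)
    age <- age[keep]
    win <- fhit_window(pmax(0, age - dt), age, config)
    sum(config$Q * win / pmin(age, dt))
  }, numeric(1))
}

#' Per-receptor arrival rate
#'
#' The aggregate absorbing-receiver rate [rabsorb_rate()] split evenly over
#' the `n` receptors (all receptors are treated as co-located, so each sees
#' a 1/n share of the arrival stream).
#'
#' @inheritParams rabsorb_rate
#' @return Rate in molecules/s per receptor.
#' @export
lambda_o <- function(t, config) {
  rabsorb_rate(t, config) / config$n
}

#' Steady-state absorption rate of the absorbing-receptor receiver
#'
#' The `t -> Inf` limit of [rabsorb_rate()]:
#' `(Q / delta_t) * (Rr / d) * n rs / (n rs + pi Rr)`.
#'
#' @param config a [model_config()].
#' @return Rate in molecules/s.
#' @export
rabsorb_steady <- function(config) {
  stopifnot(inherits(config, "model_config"))
  with(config, (Q / delta_t) * (Rr / d) * (n * rs / (n * rs + pi * Rr)))
}

# absorbing-sphere first-passage CDF, the n -> Inf limit of .fhit
.fhit_sphere <- function(t, D, d, Rr) {
  out <- numeric(length(t))
  pos <- t > 0
  out[pos] <- (Rr / d) * erfc((d - Rr) / sqrt(4 * D * t[pos]))
  out
}
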