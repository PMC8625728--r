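#' Brownian Monte-Carlo of a fully absorbing sphere
#'
#' Independent oracle for the many-receptor limit of the hitting fraction:
#' `N` point particles are released at distance `d` from the centre of an
#' absorbing sphere of radius `Rr` and perform free Brownian motion with
#' per-axis step standard deviation `sqrt(2 * D * dt)`. A particle is
#' absorbed when its end-of-step radius is at most `Rr`; the empirical
#' first-passage CDF estimates `(Rr/d) * erfc((d - Rr)/sqrt(4 D t))`.
#' End-of-step testing (no Brownian-bridge correction) underestimates the
#' true CDF; the bias shrinks as `dt` decreases, and steps coarser than
#' `sqrt(2 D dt) > Rr / 5` are refused outright.
#'
#' @param N number of particles.
#' @param D diffusion coefficient, m^2/s.
#' @param d release distance from the sphere centre, m, `> Rr`.
#' @param Rr sphere radius, m.
#' @param dt time step, s.
#' @param t_max simulated horizon, s.
#' @param seed RNG seed.
#' @param t_grid evaluation grid for the empirical CDF; defaults to 201
#'   points spanning `[0, t_max]`.
#' @return An `"oracle_result"`: `t_grid`, `empirical_fhit`, binomial
#'   standard error `se`, first-passage times `fp_times` (NA if not
#'   absorbed), final positions, and the run parameters.
#' @examples
#' \donttest{
#' orc <- simulate_absorbing_sphere(N = 500, D = 1.18e-10, d = 6e-6,
#'                                  Rr = 2.5e-6, dt = 1e-4, t_max = 0.3,
#'                                  seed = 7)
#' orc
#' }
#' @export
simulate_absorbing_sphere <- function(N, D, d, Rr, dt, t_max, seed,
                                      t_grid = NULL) {
  if (d <= Rr) stop("release distance d must exceed the sphere radius Rr")
  if (N < 1 || D <= 0 || dt <= 0 || t_max <= 0) stop("invalid parameters")
  sigma <- sqrt(2 * D * dt)
  if (sigma > Rr / 5)
    stop(sprintf(paste("time step too coarse: per-axis step sd %.3g m exceeds",
                       "Rr/5 = %.3g m; reduce dt"), sigma, Rr / 5))
  n_steps <- ceiling(t_max / dt)
  set.seed(seed)
  raw <- brownian_absorbing_sphere(as.integer(N), sigma, d, Rr,
                                   as.integer(n_steps))
  fp <- raw$fp_step * dt
  if (is.null(t_grid)) t_grid <- seq(0, t_max, length.out = 201)
  hits <- findInterval(t_grid, sort(fp[!is.na(fp)]))
  p <- hits / N
  structure(list(t_grid = t_grid, empirical_fhit = p,
                 se = sqrt(p * (1 - p) / N),
                 fp_times = fp,
                 final_pos = cbind(x = raw$x, y = raw$y, z = raw$z),
                 N = N, D = D, d = d, Rr = Rr, dt = dt, t_max = t_max,
                 seed = seed),
            class = "oracle_result")
}

#' @export
print.oracle_result <- function(x, ...) {
  cat(sprintf("<oracle_result> %d particles, dt = %g s, horizon %g s, seed %d\n",
              x$N, x$dt, x$t_max, x$seed))
  m <- length(x$t_grid)
  cat(sprintf("  empirical hitting fraction at t = %g s: %.4g (se %.2g); analytic %.4g\n",
              x$t_grid[m], x$empirical_fhit[m], x$se[m],
              .fhit_sphere(x$t_max, x$D, x$d, x$Rr)))
  invisible(x)
}

#' Check the oracle against the many-receptor hitting-fraction limit
#'
#' Compares the empirical first-passage CDF from
#' [simulate_absorbing_sphere()] with [fhit_cumulative()] evaluated in the
#' absorbing-sphere regime (receptor coverage `n * rs / (pi * Rr) >= 1e4`,
#' where the receptor factor is within 1e-4 of 1). Because the end-of-step
#' test biases the empirical CDF low, a one-sided discretization allowance
#' (default 10% of the analytic value) is granted before computing z-scores:
#' deficits within the allowance are not penalized, surpluses are.
#'
#' @param oracle an `"oracle_result"`.
#' @param config optional [model_config()]; if supplied, its `D`, `d`, `Rr`
#'   must match the oracle's (parameter mismatch is an error) and its
#'   geometry is used after inflating `n` into the absorbing regime.
#' @param allowance one-sided discretization allowance as a fraction of the
#'   analytic value (default 0.1).
#' @param Rr_model sphere radius used on the model side (default: the
#'   oracle's). Perturbing it deliberately (e.g. halving) is a sensitivity
#'   check: the comparison should then flag a systematic bias.
#' @return A `"oracle_comparison"` data.frame with `t`, `empirical`,
#'   `analytic`, `se`, `z`; `max_abs_z` as an attribute.
#' @export
validate_fhit_limit <- function(oracle, config = NULL, allowance = 0.1,
                                Rr_model = NULL) {
  if (!inherits(oracle, "oracle_result")) stop("oracle must be an oracle_result")
  if (length(oracle$t_grid) == 0 || oracle$N < 1) stop("empty oracle result")
  if (!is.null(config)) {
    stopifnot(inherits(config, "model_config"))
    if (abs(config$D - oracle$D) > 1e-12 * oracle$D ||
        abs(config$d - oracle$d) > 1e-12 * oracle$d ||
        abs(config$Rr - oracle$Rr) > 1e-12 * oracle$Rr)
      stop("parameter mismatch: config D/d/Rr differ from the oracle's")
    geom <- config
  } else {
    geom <- model_config(Rr = oracle$Rr, rs = 4e-9, n = 10000,
                         d = oracle$d, D = oracle$D, Q = 1, delta_t = 1e-3,
                         t_end = max(oracle$t_max, 1e-3), mu = 1)
  }
  if (is.null(Rr_model)) Rr_model <- geom$Rr
  # inflate n so the receptor factor is within 1e-4 of the absorbing limit
  n_inf <- ceiling(1e4 * pi * Rr_model / geom$rs)
  geom <- suppressWarnings(
    model_config(Rr = Rr_model, rs = geom$rs, n = n_inf, d = oracle$d,
                 D = geom$D, Q = max(geom$Q, 1), delta_t = geom$delta_t,
                 t_end = geom$t_end, mu = geom$mu))
  analytic <- fhit_cumulative(oracle$t_grid, geom)
  emp <- oracle$empirical_fhit
  se <- pmax(oracle$se, sqrt(pmax(analytic * (1 - analytic), 1e-12) / oracle$N))
  diff <- emp - analytic
  neg <- diff < 0
  diff[neg] <- pmin(diff[neg] + allowance * analytic[neg], 0)
  z <- diff / se
  out <- data.frame(t = oracle$t_grid, empirical = emp, analytic = analytic,
                    se = se, z = z)
  structure(out, class = c("oracle_comparison", "data.frame"),
            max_abs_z = max(abs(z)))
}

#' @export
print.oracle_comparison <- function(x, ...) {
  cat(sprintf("<oracle_comparison> %d time points, max |z| = %.2f\n",
              nrow(x), attr(x, "max_abs_z")))
  invisible(x)
}
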