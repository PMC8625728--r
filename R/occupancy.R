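#' Per-receptor busy probability
#'
#' Probability that a given receptor is occupied, `pi_r = Ao / (1 + Ao)`.
#' For an M/M/1/1 queue this equals the blocking (rejection) probability,
#' so it is simultaneously the occupancy used in the binomial receptor
#' count and the fraction of the effective stream that is rejected.
#'
#' @param Ao offered load(s), `>= 0`.
#' @return Probability in `[0, 1)`.
#' @export
occupancy_probability <- function(Ao) {
  if (any(Ao < 0)) stop("Ao must be >= 0")
  Ao / (1 + Ao)
}

#' Distribution of the number of busy receptors
#'
#' With `n` receptors each independently busy with probability `pi_r`, the
#' busy count is Binomial(`n`, `pi_r`); for large `n` the normal
#' approximation `N(n pi_r, n pi_r (1 - pi_r))` is used instead (exact
#' binomial always available via `law = "binomial"`).
#'
#' @param n receptor count, `>= 1`.
#' @param pi_r per-receptor busy probability in `[0, 1]`.
#' @param law `"auto"` (binomial up to `threshold`, normal above),
#'   `"binomial"`, or `"normal"`.
#' @param threshold `n` above which `"auto"` switches to the normal
#'   approximation (default 1000).
#' @return An `"occupancy_distribution"` with fields `n`, `pi_r`, `law`,
#'   `mean`, `var` and query functions `pmf(k)`, `cdf(k)` and `tail(k)`
#'   (`tail(k)` is `P(busy >= k)`, the success probability of reaching at
#'   least `k` bound receptors).
#' @examples
#' od <- busy_distribution(2, 0.5)
#' od$tail(1)   # 0.75
#' @export
busy_distribution <- function(n, pi_r, law = c("auto", "binomial", "normal"),
                              threshold = 1000) {
  law <- match.arg(law)
  if (n < 1) stop("n must be >= 1")
  if (is.na(pi_r) || pi_r < 0 || pi_r > 1) stop("pi_r must lie in [0, 1]")
  if (law == "auto") law <- if (n > threshold) "normal" else "binomial"
  m <- n * pi_r
  v <- n * pi_r * (1 - pi_r)
  fns <- if (law == "binomial") {
    list(pmf = function(k) dbinom(k, n, pi_r),
         cdf = function(k) pbinom(k, n, pi_r),
         tail = function(k) ifelse(k <= 0, 1,
                                   pbinom(k - 1, n, pi_r, lower.tail = FALSE)))
  } else {
    s <- sqrt(v)
    # continuity-corrected normal approximation
    list(pmf = function(k) dnorm(k, m, s),
         cdf = function(k) pnorm(k + 0.5, m, s),
         tail = function(k) ifelse(k <= 0, 1,
                                   pnorm(k - 0.5, m, s, lower.tail = FALSE)))
  }
  structure(c(list(n = n, pi_r = pi_r, law = law, mean = m, var = v), fns),
            class = "occupancy_distribution")
}

#' @export
print.occupancy_distribution <- function(x, ...) {
  cat(sprintf("<occupancy_distribution> %s law, n = %g, pi_r = %.4g (mean %.4g, var %.4g)\n",
              x$law, x$n, x$pi_r, x$mean, x$var))
  invisible(x)
}

#' Success probability of a minimum receptor occupancy
#'
#' Probability that at least `nmin` of the `n` receptors are simultaneously
#' bound, `P(busy >= nmin)` under Binomial(`n`, `pi_r`). Computed through
#' the binomial survival function (`pbinom(..., lower.tail = FALSE)`), which
#' is numerically stable in the far tail where naive term summation loses
#' precision.
#'
#' @param nmin minimum required busy receptors, `0 <= nmin <= n`.
#' @param n receptor count.
#' @param pi_r per-receptor busy probability.
#' @return Probability in `[0, 1]`; 1 when `nmin = 0`.
#' @examples
#' p_success(1, 2, 0.5)   # 0.75
#' @export
p_success <- function(nmin, n, pi_r) {
  if (any(nmin < 0) || any(nmin > n)) stop("nmin must lie in [0, n]")
  if (any(pi_r < 0 | pi_r > 1)) stop("pi_r must lie in [0, 1]")
  ifelse(nmin <= 0, 1, pbinom(nmin - 1, n, pi_r, lower.tail = FALSE))
}

#' Invert the dose: release rate achieving a target occupancy
#'
#' Dose-planning inversion for targeted delivery: find the smallest release
#' rate `Q / delta_t` such that, in steady state, at least `nmin` of the
#' `n` receptors are simultaneously drug-bound with probability at least
#' `target`. The chain is inverted step by step, each step monotone:
#' \enumerate{
#'   \item minimal `pi_r` with `p_success(nmin, n, pi_r) >= target`, by
#'     bisection on `[0, 1]` (`p_success` is nondecreasing in `pi_r`);
#'   \item `Ao = pi_r / (1 - pi_r)`, then `lambda_o_prime = Ao * mu`;
#'   \item `lambda_o` from the recapture relation by bisection on
#'     `[0, lambda_o_prime]` (single code path whether or not `Pc = 0`);
#'   \item release rate from the steady-state hitting fraction:
#'     `Q/delta_t = lambda_o * n * (d / Rr) * (n rs + pi Rr) / (n rs)`.
#' }
#' The returned solution carries the forward-recomputed success probability,
#' which round-trips to at least `target` (up to bisection tolerance).
#'
#' @param nmin minimum busy receptors required, `0 <= nmin <= n`.
#' @param target required success probability, in `(0, 1)`.
#' @param config a [model_config()]; supplies `n`, `mu`, geometry and `Pc`.
#' @param tol_pi bisection tolerance on `pi_r` (default 1e-6).
#' @return A `"dosing_solution"` with `pi_r_required`, `Ao_required`,
#'   `lambda_o_required`, `release_rate` (molecules/s) and
#'   `achieved_p_success`.
#' @examples
#' cfg <- fixture_config("table1_q50_mu4")
#' invert_for_release_rate(nmin = 2000, target = 0.95, cfg)
#' @export
invert_for_release_rate <- function(nmin, target, config, tol_pi = 1e-6) {
  stopifnot(inherits(config, "model_config"))
  if (target <= 0 || target >= 1) stop("target must lie in (0, 1)")
  n <- config$n
  if (nmin < 0 || nmin > n) stop("nmin must lie in [0, n]")
  mu <- config$mu
  Pc <- capture_probability(config)

  if (nmin == 0) {
    warning("nmin = 0 is met by any dose; returning the smallest positive rate")
    return(structure(list(pi_r_required = 0, Ao_required = 0,
                          lambda_o_required = 0,
                          release_rate = .Machine$double.xmin,
                          achieved_p_success = 1, Pc = Pc, nmin = 0,
                          target = target),
                     class = "dosing_solution"))
  }
  if (p_success(nmin, n, 1 - 1e-12) < target)
    stop("target success probability unreachable with pi_r < 1")

  # step 1: minimal pi_r (monotone nondecreasing in pi_r)
  lo <- 0; hi <- 1
  while (hi - lo > tol_pi) {
    mid <- (lo + hi) / 2
    if (p_success(nmin, n, mid) >= target) hi <- mid else lo <- mid
  }
  pi_r <- hi
  if (pi_r >= 1) stop("target success probability unreachable with pi_r < 1")

  # steps 2-3: load, effective rate, then fresh rate by bisection
  Ao <- pi_r / (1 - pi_r)
  lop <- Ao * mu
  f <- function(l) lambda_o_prime(l, Pc, mu) - lop
  lam <- if (lop == 0) 0 else {
    lo2 <- 0; hi2 <- lop
    for (i in 1:200) {                    # ~1e-60 relative; cheap
      mid <- (lo2 + hi2) / 2
      if (f(mid) >= 0) hi2 <- mid else lo2 <- mid
      if ((hi2 - lo2) <= 1e-12 * max(hi2, 1e-300)) break
    }
    (lo2 + hi2) / 2
  }

  # step 4: steady-state inversion of the hitting fraction
  rate <- with(config, lam * n * (d / Rr) * (n * rs + pi * Rr) / (n * rs))

  # forward check
  lo_fwd <- rate * with(config, (Rr / d) * n * rs / (n * rs + pi * Rr)) / n
  Ao_fwd <- receptor_load(lambda_o_prime(lo_fwd, Pc, mu), mu)
  achieved <- p_success(nmin, n, occupancy_probability(Ao_fwd))

  structure(list(pi_r_required = pi_r, Ao_required = Ao,
                 lambda_o_required = lam, release_rate = rate,
                 achieved_p_success = achieved, Pc = Pc, nmin = nmin,
                 target = target),
            class = "dosing_solution")
}

#' @export
print.dosing_solution <- function(x, ...) {
  cat("<dosing_solution>\n")
  cat(sprintf("  occupancy target : >= %g busy receptors w.p. >= %.4g\n",
              x$nmin, x$target))
  cat(sprintf("  required pi_r    : %.6g  (load Ao = %.6g)\n",
              x$pi_r_required, x$Ao_required))
  cat(sprintf("  fresh rate       : %.6g /s per receptor\n", x$lambda_o_required))
  cat(sprintf("  release rate     : %.6g molecules/s\n", x$release_rate))
  cat(sprintf("  achieved P       : %.6g\n", x$achieved_p_success))
  invisible(x)
}
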