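#' Simulate the bank of M/M/1/1 receptor queues
#'
#' Stochastic counterpart of the closed-form rate series: aggregate ligand
#' arrivals are generated as a non-homogeneous Poisson process with rate
#' `Lambda_o_prime(t) = n * lambda_o_prime(t)` by thinning (Lewis-Shedler)
#' against a piecewise-constant majorant (1.05 x the per-cell maximum of the
#' precomputed rate, cell width = the evaluation grid spacing). Each arrival
#' is assigned to one of the `n` receptors uniformly at random (Poisson
#' splitting). An arrival at an idle receptor starts an exponential(`mu`)
#' service and counts as an absorption; an arrival at a busy receptor counts
#' as a rejection. The recapture feedback is already folded into the
#' precomputed `lambda_o_prime` (open loop): rejected molecules are not
#' re-injected dynamically.
#'
#' @param config a [model_config()].
#' @param seed master RNG seed (integer). Replicate `i` uses `seed + i - 1`,
#'   so runs are fully reproducible and replicates independent.
#' @param replicates number of independent replicates (`>= 1`).
#' @param series optional precomputed `"rate_series"` (from
#'   [build_rate_series()]); built from `config` when missing. Supplying a
#'   hand-made series allows driving the bank with an arbitrary rate curve.
#' @return A `"queue_sim_result"`: list with `seed`, `time_bins` (the grid),
#'   matrices `arrivals`, `absorptions`, `rejections` (cumulative counts,
#'   grid points x replicates), `n_busy` (busy receptors at each grid
#'   point), and `n`, `mu`.
#' @examples
#' cfg <- model_config(Rr = 2.5e-6, rs = 4e-9, n = 100, d = 26.5e-6,
#'                     D = 1.18e-10, Q = 50, delta_t = 0.01, t_end = 2,
#'                     mu = 0.25)
#' res <- simulate_bank(cfg, seed = 1, replicates = 3)
#' res
#' @export
simulate_bank <- function(config, seed, replicates = 1, series = NULL) {
  stopifnot(inherits(config, "model_config"))
  if (replicates < 1) stop("replicates must be >= 1")
  if (is.null(series)) series <- build_rate_series(config)
  if (!inherits(series, "rate_series")) stop("series must be a rate_series")
  tg <- series$t
  m <- length(tg)
  rate <- series$Lambda_o_prime
  if (any(rate < 0)) stop("negative arrival rate in series")
  n <- config$n
  mu <- config$mu
  # per-cell majorant: 1.05 x max of the rate at the cell endpoints
  maj <- 1.05 * pmax(rate[-m], rate[-1])

  arr_m <- abs_m <- rej_m <- busy_m <- matrix(0, m, replicates)
  for (r in seq_len(replicates)) {
    set.seed(seed + r - 1)
    # thinning, cell by cell
    times <- vector("list", m - 1)
    for (j in seq_len(m - 1)) {
      if (maj[j] <= 0) next
      width <- tg[j + 1] - tg[j]
      ncand <- rpois(1, maj[j] * width)
      if (ncand == 0) next
      tc <- sort(runif(ncand, tg[j], tg[j + 1]))
      # linear interpolation of the target rate inside the cell
      lam <- rate[j] + (rate[j + 1] - rate[j]) * (tc - tg[j]) / width
      if (any(lam > maj[j] * (1 + 1e-12)))
        stop("internal error: arrival rate exceeds its thinning majorant")
      keep <- runif(ncand) < lam / maj[j]
      if (any(keep)) times[[j]] <- tc[keep]
    }
    at <- unlist(times, use.names = FALSE)
    n_arr <- length(at)
    absorbed <- logical(n_arr)
    svc_start <- svc_end <- numeric(0)
    if (n_arr > 0) {
      rec <- sample.int(n, n_arr, replace = TRUE)
      busy_until <- numeric(n)       # receptors idle at t = 0
      svc_start <- svc_end <- numeric(n_arr)
      n_abs <- 0
      for (i in seq_len(n_arr)) {
        ri <- rec[i]
        if (busy_until[ri] <= at[i]) {
          busy_until[ri] <- at[i] + rexp(1, mu)
          absorbed[i] <- TRUE
          n_abs <- n_abs + 1
          svc_start[n_abs] <- at[i]
          svc_end[n_abs] <- busy_until[ri]
        }
      }
      svc_start <- svc_start[seq_len(n_abs)]
      svc_end <- svc_end[seq_len(n_abs)]
    }
    # cumulative counts on the grid
    arr_m[, r] <- findInterval(tg, sort(at))
    abs_m[, r] <- findInterval(tg, sort(at[absorbed]))
    rej_m[, r] <- findInterval(tg, sort(at[!absorbed]))
    # busy receptors at each grid point: +1 at service start, -1 at end
    if (length(svc_start)) {
      ev_t <- c(svc_start, svc_end)
      ev_d <- c(rep(1, length(svc_start)), rep(-1, length(svc_end)))
      o <- order(ev_t)
      busy_m[, r] <- c(0, cumsum(ev_d[o]))[findInterval(tg, ev_t[o]) + 1]
    }
  }
  structure(list(seed = seed, time_bins = tg, arrivals = arr_m,
                 absorptions = abs_m, rejections = rej_m, n_busy = busy_m,
                 n = n, mu = mu, replicates = replicates),
            class = "queue_sim_result")
}

#' @export
print.queue_sim_result <- function(x, ...) {
  m <- length(x$time_bins)
  cat(sprintf("<queue_sim_result> seed %d, %d replicate(s), t in [%g, %g] s\n",
              x$seed, x$replicates, x$time_bins[1], x$time_bins[m]))
  cat(sprintf("  final counts (mean over replicates): %.1f arrivals = %.1f absorbed + %.1f rejected\n",
              mean(x$arrivals[m, ]), mean(x$absorptions[m, ]),
              mean(x$rejections[m, ])))
  invisible(x)
}

#' Compare simulated counts with the closed-form model
#'
#' Per-bin z-scores of the replicate-mean cumulative absorption and
#' rejection counts against the model curves `N_a(t)`, `N_r(t)`. The
#' standard error of the mean uses the between-replicate spread, floored at
#' the Poisson-like value `sqrt((model + 1) / replicates)` so early bins
#' with zero spread do not produce spurious infinities.
#'
#' @param result a [simulate_bank()] result.
#' @param series the matching `"rate_series"`.
#' @return A `"queue_sim_comparison"`: data.frame with `t`, model and
#'   simulated means, and `z_absorptions`, `z_rejections`; `max_abs_z` as an
#'   attribute.
#' @export
compare_to_model <- function(result, series) {
  if (!inherits(result, "queue_sim_result")) stop("result must be a queue_sim_result")
  if (!inherits(series, "rate_series")) stop("series must be a rate_series")
  if (length(result$time_bins) != length(series$t) ||
      any(abs(result$time_bins - series$t) > 1e-9))
    stop("grid mismatch between simulation result and rate series")
  if (length(result$time_bins) == 0 || result$replicates < 1)
    stop("empty simulation result")
  R <- result$replicates
  zfun <- function(simmat, model) {
    mn <- rowMeans(simmat)
    se <- if (R > 1) apply(simmat, 1, sd) / sqrt(R) else rep(0, length(mn))
    se <- pmax(se, sqrt((model + 1) / R))
    (mn - model) / se
  }
  za <- zfun(result$absorptions, series$N_a)
  zr <- zfun(result$rejections, series$N_r)
  out <- data.frame(t = series$t,
                    N_a_model = series$N_a, N_a_sim = rowMeans(result$absorptions),
                    N_r_model = series$N_r, N_r_sim = rowMeans(result$rejections),
                    z_absorptions = za, z_rejections = zr)
  structure(out, class = c("queue_sim_comparison", "data.frame"),
            max_abs_z = max(abs(c(za, zr))))
}

#' @export
print.queue_sim_comparison <- function(x, ...) {
  cat(sprintf("<queue_sim_comparison> %d bins, max |z| = %.2f\n",
              nrow(x), attr(x, "max_abs_z")))
  last <- x[nrow(x), ]
  cat(sprintf("  at t = %g s: N_a sim %.1f vs model %.1f; N_r sim %.1f vs model %.1f\n",
              last$t, last$N_a_sim, last$N_a_model, last$N_r_sim, last$N_r_model))
  invisible(x)
}
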