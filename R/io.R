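#' Write and read rate series as CSV
#'
#' Fixed column order `t_s, lambda_o, lambda_o_prime, Ao, Lambda_r,
#' Lambda_a, N_r, N_a, E_busy`, floats at 17 significant digits so a
#' round-trip is exact to machine precision. An empty series writes a
#' header-only file. Writing is atomic: output lands in a temporary file
#' that is renamed into place, so a failure leaves nothing partial.
#'
#' @param series a `"rate_series"` from [build_rate_series()].
#' @param path destination CSV path.
#' @return `path`, invisibly.
#' @export
write_series <- function(series, path) {
  if (!inherits(series, "rate_series")) stop("series must be a rate_series")
  cols <- c(t_s = "t", lambda_o = "lambda_o", lambda_o_prime = "lambda_o_prime",
            Ao = "Ao", Lambda_r = "Lambda_r", Lambda_a = "Lambda_a",
            N_r = "N_r", N_a = "N_a", E_busy = "E_busy")
  out <- as.data.frame(lapply(unname(cols), function(cl)
    format(series[[cl]], digits = 17, scientific = TRUE, trim = TRUE)))
  if (nrow(series) == 0) out <- out[0, , drop = FALSE]
  names(out) <- names(cols)
  tmp <- paste0(path, ".tmp")
  on.exit(unlink(tmp), add = TRUE)
  write.csv(out, tmp, row.names = FALSE, quote = FALSE)
  if (!file.rename(tmp, path)) stop("cannot write to ", path)
  invisible(path)
}

#' @rdname write_series
#' @return `read_series()` returns the numeric data.frame (columns named as
#'   in the file).
#' @export
read_series <- function(path) {
  if (!file.exists(path)) stop("series file not found: ", path)
  read.csv(path, colClasses = "numeric")
}

#' Steady-state model summary
#'
#' Collects the scalar outputs of a configuration: capture probability,
#' steady-state absorbing-receiver rate, steady-state saturable absorption
#' rate, emission rate, load and busy-receptor expectation.
#'
#' @param config a [model_config()].
#' @return A named list (class `"model_summary"`).
#' @examples
#' model_summary(fixture_config("table1_q50_mu4"))
#' @export
model_summary <- function(config) {
  stopifnot(inherits(config, "model_config"))
  Pc <- capture_probability(config)
  rs_inf <- rabsorb_steady(config)
  lo <- rs_inf / config$n
  lop <- lambda_o_prime(lo, Pc, config$mu)
  Ao <- receptor_load(lop, config$mu)
  structure(list(
    label = config$label,
    emission_rate_per_s = config$Q / config$delta_t,
    Pc = Pc,
    rabsorb_steady_per_s = rs_inf,
    lambda_o_steady_per_s = lo,
    lambda_o_prime_steady_per_s = lop,
    Ao_steady = Ao,
    steady_state_absorption_per_s = steady_state_absorption(config),
    E_busy_steady = config$n * Ao / (1 + Ao)
  ), class = "model_summary")
}

#' @export
print.model_summary <- function(x, ...) {
  cat("<model_summary>", if (nzchar(x$label)) paste0(" ", x$label), "\n", sep = "")
  for (f in setdiff(names(x), "label"))
    cat(sprintf("  %-32s %.6g\n", f, x[[f]]))
  invisible(x)
}

#' Write a summary (or any named list) as JSON
#'
#' Keys keep their list order; numbers are written at full precision.
#' Writing is atomic (temp file + rename).
#'
#' @param summary a named list, e.g. from [model_summary()].
#' @param path destination `.json` path.
#' @return `path`, invisibly.
#' @export
write_summary <- function(summary, path) {
  if (is.null(names(summary)) || any(!nzchar(names(summary))))
    stop("summary must be a fully named list")
  tmp <- paste0(path, ".tmp")
  on.exit(unlink(tmp), add = TRUE)
  jsonlite::write_json(unclass(summary), tmp, auto_unbox = TRUE, digits = NA)
  if (!file.rename(tmp, path)) stop("cannot write to ", path)
  invisible(path)
}
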