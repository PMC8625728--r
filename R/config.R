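#' Model configuration
#'
#' Bundles every physical and numerical parameter of the receiver model in SI
#' units (metres, seconds). Geometry: receiver radius `Rr`, receptor radius
#' `rs`, receptor count `n`, transmitter-receiver centre distance `d`.
#' Medium: diffusion coefficient `D`, either given directly or derived by
#' Stokes-Einstein from temperature, viscosity and molecule radius. Emission:
#' `Q` molecules per pulse every `delta_t` seconds up to the horizon `t_end`.
#' Kinetics: trafficking (service) rate `mu`, the reciprocal of the mean time
#' a receptor spends internalizing a bound ligand. Numerics: `dt_particle`,
#' the particle-simulation time step that enters the post-bounce distance
#' d*, and `grid_dt`, the rate-evaluation grid spacing.
#'
#' @param Rr receiver radius, m.
#' @param rs receptor radius, m.
#' @param n number of surface receptors (positive integer).
#' @param d transmitter-receiver centre distance, m; must exceed `Rr`.
#' @param D diffusion coefficient, m^2/s. If `NULL`, derived from
#'   `temperature`, `viscosity` and `rm` via [stokes_einstein_D()].
#' @param temperature,viscosity,rm optional Stokes-Einstein ingredients
#'   (K, Pa s, m); used only when `D` is `NULL`. `rm` may also be recorded
#'   alongside a directly supplied `D`.
#' @param Q molecules per pulse. `Q = 0` is admitted and means no emission.
#' @param delta_t pulse period, s.
#' @param t_end evaluation horizon, s.
#' @param mu trafficking rate, 1/s.
#' @param dt_particle particle time step entering d*, s (default 100 ns).
#' @param grid_dt rate-evaluation grid spacing, s; defaults to `delta_t` and
#'   must not exceed it.
#' @param label free-text tag carried through outputs.
#' @return An object of class `"model_config"` (a validated named list).
#' @seealso [load_config()], [fixture_config()], [build_rate_series()]
#' @examples
#' cfg <- model_config(Rr = 2.5e-6, rs = 4e-9, n = 10000, d = 26.5e-6,
#'                     D = 1.18e-10, Q = 50, delta_t = 0.01, t_end = 10,
#'                     mu = 0.25)
#' cfg
#' @export
model_config <- function(Rr, rs, n, d, D = NULL,
                         temperature = NULL, viscosity = NULL, rm = NULL,
                         Q, delta_t, t_end = 10, mu,
                         dt_particle = 1e-7, grid_dt = delta_t,
                         label = "") {
  if (is.null(D)) {
    if (is.null(temperature) || is.null(viscosity) || is.null(rm))
      stop("supply D, or all of temperature, viscosity and rm to derive it")
    D <- stokes_einstein_D(temperature, viscosity, rm)
  }
  cfg <- structure(
    list(Rr = as.numeric(Rr), rs = as.numeric(rs), n = as.numeric(n),
         d = as.numeric(d), D = as.numeric(D),
         rm = if (is.null(rm)) NA_real_ else as.numeric(rm),
         Q = as.numeric(Q), delta_t = as.numeric(delta_t),
         t_end = as.numeric(t_end), mu = as.numeric(mu),
         dt_particle = as.numeric(dt_particle),
         grid_dt = as.numeric(grid_dt), label = as.character(label)),
    class = "model_config")
  validate_config(cfg)
}

#' Validate a model configuration
#'
#' Checks every field invariant and the cross-field constraints
#' (`d > Rr`, `grid_dt <= delta_t`, `t_end >= delta_t`). A receptor area
#' budget exceeding the receiver surface (`n * pi * rs^2 > 4 * pi * Rr^2`)
#' raises a warning, not an error.
#'
#' @param cfg a `"model_config"`.
#' @return `cfg`, invisibly unchanged, if valid; otherwise an error naming
#'   the offending field.
#' @export
validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "model_config"))
  chk <- function(ok, msg) if (!isTRUE(ok)) stop(msg, call. = FALSE)
  with(cfg, {
    chk(is.finite(Rr) && Rr > 0, "Rr: receiver radius must be > 0")
    chk(is.finite(rs) && rs > 0, "rs: receptor radius must be > 0")
    chk(!is.na(n) && n >= 1 && n == round(n),
        "n: receptor count must be a whole number >= 1")
    chk(is.finite(d) && d > Rr, "d: TX-RX distance must exceed Rr")
    chk(is.finite(D) && D > 0, "D: diffusion coefficient must be > 0")
    chk(is.finite(Q) && Q >= 0, "Q: molecules per pulse must be >= 0")
    chk(is.finite(delta_t) && delta_t > 0, "delta_t: pulse period must be > 0")
    chk(is.finite(t_end) && t_end >= delta_t, "t_end: horizon must be >= delta_t")
    chk(is.finite(mu) && mu > 0, "mu: trafficking rate must be > 0")
    chk(is.finite(dt_particle) && dt_particle > 0,
        "dt_particle: particle time step must be > 0")
    chk(is.finite(grid_dt) && grid_dt > 0, "grid_dt: grid spacing must be > 0")
    chk(grid_dt <= delta_t + 1e-15, "grid_dt: grid spacing must not exceed delta_t")
  })
  if (cfg$n * pi * cfg$rs^2 > 4 * pi * cfg$Rr^2)
    warning("receptor area n*pi*rs^2 exceeds the receiver surface 4*pi*Rr^2",
            call. = FALSE)
  invisible(cfg)
}

#' @export
print.model_config <- function(x, ...) {
  cat("<model_config>", if (nzchar(x$label)) paste0(" ", x$label), "\n", sep = "")
  cat(sprintf("  geometry : Rr = %.4g um, rs = %.4g nm, n = %g, d = %.4g um\n",
              x$Rr * 1e6, x$rs * 1e9, x$n, x$d * 1e6))
  cat(sprintf("  medium   : D = %.4g m^2/s\n", x$D))
  cat(sprintf("  emission : Q = %g every %.4g ms (rate %.4g /s), horizon %.4g s\n",
              x$Q, x$delta_t * 1e3, x$Q / x$delta_t, x$t_end))
  cat(sprintf("  kinetics : mu = %.4g /s (trafficking time %.4g s)\n",
              x$mu, 1 / x$mu))
  cat(sprintf("  numerics : dt_particle = %.4g s, grid_dt = %.4g s\n",
              x$dt_particle, x$grid_dt))
  invisible(x)
}

# unit-suffixed key -> (SI field, scale factor)
.unit_keys <- list(
  geometry = c(Rr_um = "Rr:1e-6", Rr_m = "Rr:1", rs_nm = "rs:1e-9",
               rs_m = "rs:1", n = "n:1", d_um = "d:1e-6", d_m = "d:1"),
  medium   = c(D_m2s = "D:1", T_K = "temperature:1", eta_Pas = "viscosity:1",
               rm_nm = "rm:1e-9", rm_m = "rm:1"),
  emission = c(Q = "Q:1", delta_t_ms = "delta_t:1e-3", delta_t_s = "delta_t:1",
               t_end_s = "t_end:1"),
  kinetics = c(mu_per_s = "mu:1", trafficking_time_s = "mu_inv:1"),
  numerics = c(dt_particle_ns = "dt_particle:1e-9", dt_particle_s = "dt_particle:1",
               grid_dt_ms = "grid_dt:1e-3", grid_dt_s = "grid_dt:1")
)

#' Load a model configuration from YAML or JSON
#'
#' Reads a config file whose keys carry explicit unit suffixes
#' (`Rr_um`, `rs_nm`, `d_um`, `delta_t_ms`, `dt_particle_ns`, ...) grouped
#' in sections `geometry`, `medium`, `emission`, `kinetics`, `numerics`,
#' plus an optional `label`. Values are converted to SI on load. Fields the
#' file leaves unspecified are filled from the packaged Table-1 default
#' fixture (`table1_q50_mu4`). Unknown keys are an error naming the key.
#' The medium section takes `D_m2s` directly or the Stokes-Einstein
#' ingredients `T_K`, `eta_Pas`, `rm_nm`; kinetics takes `mu_per_s` or its
#' reciprocal `trafficking_time_s`.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return A validated [model_config()].
#' @examples
#' cfg <- fixture_config("table1_q50_mu4")
#' tmp <- tempfile(fileext = ".yaml")
#' write_config(cfg, tmp)
#' identical_cfg <- load_config(tmp)
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
                yaml = , yml = yaml::read_yaml(path),
                json = jsonlite::read_json(path, simplifyVector = TRUE),
                stop("unsupported config format: .", ext, " (use YAML or JSON)"))
  config_from_list(raw)
}

# resolve a nested unit-suffixed list into a model_config, filling gaps
# from the packaged Table-1 defaults
config_from_list <- function(raw) {
  vals <- list()
  for (sec in names(.unit_keys)) {
    given <- raw[[sec]]
    if (is.null(given)) next
    if (!is.list(given)) stop("config section '", sec, "' must be a mapping")
    # YAML 1.1 reads the bare key `n` as a boolean; map it back
    names(given)[names(given) == "FALSE"] <- "n"
    for (key in names(given)) {
      spec <- unname(.unit_keys[[sec]][key])
      if (is.na(spec))
        stop("unknown config key '", sec, ".", key, "'")
      parts <- strsplit(spec, ":", fixed = TRUE)[[1]]
      v <- as.numeric(given[[key]]) * as.numeric(parts[2])
      if (parts[1] == "mu_inv") {
        if (v <= 0) stop("kinetics.", key, " must be > 0")
        vals[["mu"]] <- 1 / v
      } else vals[[parts[1]]] <- v
    }
  }
  extra <- setdiff(names(raw), c(names(.unit_keys), "label"))
  if (length(extra))
    stop("unknown config section(s): ", paste(extra, collapse = ", "))

  defaults <- .table1_defaults()
  fill <- function(field) if (!is.null(vals[[field]])) vals[[field]] else defaults[[field]]
  D <- vals[["D"]]
  if (is.null(D) && !is.null(vals$temperature) && !is.null(vals$viscosity) &&
      !is.null(vals$rm)) {
    D <- stokes_einstein_D(vals$temperature, vals$viscosity, vals$rm)
  }
  if (is.null(D)) D <- defaults$D
  delta_t <- fill("delta_t")
  grid_dt <- if (!is.null(vals$grid_dt)) vals$grid_dt else delta_t
  model_config(Rr = fill("Rr"), rs = fill("rs"), n = fill("n"), d = fill("d"),
               D = D, rm = fill("rm"),
               Q = fill("Q"), delta_t = delta_t, t_end = fill("t_end"),
               mu = fill("mu"), dt_particle = fill("dt_particle"),
               grid_dt = grid_dt,
               label = if (is.null(raw$label)) "" else as.character(raw$label))
}

# Table-1 parameter set in SI units (Q = 50, trafficking time 4 s)
.table1_defaults <- function() {
  list(Rr = 2.5e-6, rs = 4e-9, n = 10000, d = 26.5e-6, D = 1.18e-10,
       rm = 1.75e-9, Q = 50, delta_t = 0.01, t_end = 10, mu = 0.25,
       dt_particle = 1e-7)
}

#' Packaged parameter fixtures
#'
#' The package ships the reference simulation parameter set (receiver radius
#' 2.5 um, 10,000 receptors of radius 4 nm, D = 1.18e-10 m^2/s, TX-RX
#' distance 26.5 um, 10 ms pulse period, 100 ns particle step) in four
#' emission/kinetics variants: bursts of Q = 50 or 100 molecules with
#' trafficking times 2 or 4 s.
#'
#' @return `list_fixtures()` returns the fixture names; `fixture_config(name)`
#'   loads one as a [model_config()].
#' @examples
#' list_fixtures()
#' fixture_config("table1_q100_mu4")
#' @export
list_fixtures <- function() {
  files <- list.files(system.file("extdata", package = "rxqueue"),
                      pattern = "\\.yaml$")
  sort(sub("\\.yaml$", "", files))
}

#' @rdname list_fixtures
#' @param name fixture name, one of `list_fixtures()`.
#' @export
fixture_config <- function(name) {
  path <- system.file("extdata", paste0(name, ".yaml"), package = "rxqueue")
  if (!nzchar(path))
    stop("unknown fixture '", name, "'; see list_fixtures()")
  load_config(path)
}

#' Write a configuration back to YAML or JSON
#'
#' Serializes with the same unit-suffixed keys [load_config()] reads, so
#' `load_config(write_config(cfg, path))` round-trips.
#'
#' @param cfg a [model_config()].
#' @param path destination `.yaml` or `.json` path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "model_config"))
  out <- list(
    geometry = list(Rr_um = cfg$Rr * 1e6, rs_nm = cfg$rs * 1e9,
                    n = cfg$n, d_um = cfg$d * 1e6),
    medium = c(list(D_m2s = cfg$D),
               if (!is.na(cfg$rm)) list(rm_nm = cfg$rm * 1e9)),
    emission = list(Q = cfg$Q, delta_t_ms = cfg$delta_t * 1e3,
                    t_end_s = cfg$t_end),
    kinetics = list(mu_per_s = cfg$mu),
    numerics = list(dt_particle_ns = cfg$dt_particle * 1e9,
                    grid_dt_s = cfg$grid_dt),
    label = cfg$label)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(out, path, precision = 17)
  } else if (ext == "json") {
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  } else stop("unsupported config format: .", ext)
  invisible(path)
}
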