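#' Relative volume from relative silhouette area
#'
#' Converts a series of relative projected areas A/A0 to relative volumes
#' V/V0 under the spherical-oocyte assumption, V/V0 = (A/A0)^(3/2).
#'
#' @param rel_area Numeric vector of dimensionless area ratios, all > 0.
#' @return Numeric vector of relative volumes, same length.
#' @examples
#' relative_volume(c(1, 1.21, 4)) # 1, 1.1^3, 8
#' @export
relative_volume <- function(rel_area) {
  if (!is.numeric(rel_area) || length(rel_area) == 0) {
    stop("`rel_area` must be a non-empty numeric vector", call. = FALSE)
  }
  bad <- which(!is.finite(rel_area) | rel_area <= 0)
  if (length(bad) > 0) {
    stop("non-positive area ratio at index ", bad[1], call. = FALSE)
  }
  rel_area^(3 / 2)
}

#' Simulate a hypotonic oocyte swelling trace
#'
#' Integrates the osmotic influx model dV/dt = Pf * S * Vw * (c_in(t) - c_out)
#' with conserved internal solute, c_in(t) = c_in(0) * V0 / V(t), and constant
#' surface area. Concentrations are in mol/cm^3 (1 mmol/kg = 1e-6 mol/cm^3).
#' Integration uses fixed-step 4th-order Runge-Kutta with an internal step of
#' at most 1 s, resampled to the requested sampling grid. The silhouette area
#' read-out is rel_area = (V/V0)^(2/3), with multiplicative Gaussian noise of
#' standard deviation `noise_sd` applied to every point except t = 0 (traces
#' are normalized to their own first frame, which is therefore exactly 1).
#'
#' @param pf Osmotic water permeability coefficient, cm/s. Non-negative.
#' @param constants [assay_constants()] bundle.
#' @param dt Sampling interval, s (default 15 s as in a stereomicroscope
#'   time-lapse of the oocyte silhouette).
#' @param duration Total recording time, s (default 300 s, i.e. 5 min).
#' @param noise_sd Relative (multiplicative) standard deviation of the area
#'   noise; 0 for a noiseless trace.
#' @param seed Integer seed making the noise reproducible. The default is
#'   fixed (1) so that repeated calls with default arguments are identical.
#' @param oocyte_id,group,condition Labels copied into the output columns.
#'
#' @return A tibble of class `swelling_trace` with columns `oocyte_id`,
#'   `group`, `condition`, `time_s`, `rel_area`, `rel_volume`.
#' @examples
#' tr <- simulate_swelling(pf = 7.77e-3, noise_sd = 0)
#' head(tr)
#' @export
simulate_swelling <- function(pf, constants = assay_constants(), dt = 15,
                              duration = 300, noise_sd = 0, seed = 1L,
                              oocyte_id = "oo1", group = "expressing",
                              condition = "water") {
  .check_constants(constants)
  stopifnot(is.numeric(pf), length(pf) == 1, pf >= 0,
            dt > 0, duration >= dt)
  if (!is.numeric(noise_sd) || noise_sd < 0) {
    stop("`noise_sd` must be non-negative", call. = FALSE)
  }
  times <- seq(0, duration, by = dt)
  c_in0 <- .osm_to_mol_cm3(constants$osm_in)
  c_out <- .osm_to_mol_cm3(constants$osm_out)

  # internal RK4 grid: step <= 1 s, commensurate with the sampling grid
  n_sub <- max(1L, ceiling(dt / 1))
  grid <- seq(0, duration, by = dt / n_sub)
  rhs <- function(t, state, parms) {
    v <- state[["v"]]
    list(pf * constants$s * constants$vw * (c_in0 * constants$v0 / v - c_out))
  }
  sol <- deSolve::rk4(y = c(v = constants$v0), times = grid, func = rhs,
                      parms = NULL)
  v <- sol[, "v"]
  if (constants$osm_in > constants$osm_out && pf > 0 && any(diff(v) <= 0)) {
    stop("integration step too large: noiseless volume is not monotone",
         call. = FALSE)
  }
  rel_vol <- v[seq(1, length(v), by = n_sub)] / constants$v0
  rel_area <- rel_vol^(2 / 3)
  .finish_trace(times, rel_area, noise_sd, seed, oocyte_id, group, condition)
}

#' Simulate an isotonic solute-uptake trace
#'
#' Models the slow volume increase of an oocyte bathed in an isotonic
#' solution of a permeant solute (e.g. 140 mM glycerol, trehalose or urea):
#' water follows the solute in, and the relative volume grows linearly at
#' rate Psol * S / V0 per the apparent-permeability definition
#' Psol = d(V/V0)/dt * V0/S. Noise is applied as in [simulate_swelling()].
#'
#' @inheritParams simulate_swelling
#' @param psol Apparent solute permeability, cm/s. Non-negative.
#' @return A `swelling_trace` tibble (see [simulate_swelling()]).
#' @examples
#' simulate_solute_uptake(psol = 1e-5, noise_sd = 0)
#' @export
simulate_solute_uptake <- function(psol, constants = assay_constants(),
                                   dt = 15, duration = 300, noise_sd = 0,
                                   seed = 1L, oocyte_id = "oo1",
                                   group = "expressing",
                                   condition = "glycerol") {
  .check_constants(constants)
  stopifnot(is.numeric(psol), length(psol) == 1, psol >= 0,
            dt > 0, duration >= dt)
  if (!is.numeric(noise_sd) || noise_sd < 0) {
    stop("`noise_sd` must be non-negative", call. = FALSE)
  }
  times <- seq(0, duration, by = dt)
  rel_vol <- 1 + psol * constants$s / constants$v0 * times
  rel_area <- rel_vol^(2 / 3)
  .finish_trace(times, rel_area, noise_sd, seed, oocyte_id, group, condition)
}

.finish_trace <- function(times, rel_area, noise_sd, seed,
                          oocyte_id, group, condition) {
  if (noise_sd > 0) {
    noisy <- withr::with_seed(seed, {
      rel_area * (1 + stats::rnorm(length(rel_area), 0, noise_sd))
    })
    noisy[1] <- 1 # frame-0 normalisation pins the first point
    rel_area <- pmax(noisy, .Machine$double.eps)
  }
  new_swelling_trace(tibble::tibble(
    oocyte_id = oocyte_id, group = group, condition = condition,
    time_s = times, rel_area = rel_area,
    rel_volume = relative_volume(rel_area)
  ))
}

new_swelling_trace <- function(df) {
  class(df) <- unique(c("swelling_trace", class(df)))
  df
}

.validate_trace <- function(trace) {
  need <- c("oocyte_id", "time_s", "rel_area", "rel_volume")
  miss <- setdiff(need, names(trace))
  if (length(miss) > 0) {
    stop("trace is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  invisible(trace)
}
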