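#' Fit the initial rate of relative volume change
#'
#' Ordinary least-squares slope of V/V0 against time, restricted to the
#' initial window `[0, window_s]`. The permeability coefficients are defined
#' from this initial gradient, before osmotic back-pressure flattens the
#' swelling curve; the fit's R^2 is returned so poor linearity is visible.
#'
#' @param trace A single-oocyte trace: data frame with columns `time_s` and
#'   `rel_volume` (as produced by [simulate_swelling()] or
#'   [trace_from_frames()]).
#' @param window_s Length of the fitting window in seconds (default 60 s,
#'   i.e. the first five frames of a 15-s time-lapse).
#' @return A one-row tibble with columns `slope` (1/s), `fit_r2`,
#'   `n_points`, `window_s`. `fit_r2` is `NA` for an exactly constant
#'   series (zero total variance).
#' @examples
#' tr <- simulate_swelling(pf = 7.77e-3, noise_sd = 0)
#' fit_initial_slope(tr)
#' @export
fit_initial_slope <- function(trace, window_s = 60) {
  .validate_trace(trace)
  if (length(unique(trace$oocyte_id)) > 1) {
    stop("fit_initial_slope() expects a single oocyte; see estimate_permeability()",
         call. = FALSE)
  }
  keep <- trace$time_s >= 0 & trace$time_s <= window_s
  if (sum(keep) < 2) {
    stop("insufficient data: fewer than 2 points in [0, ", window_s, "] s",
         call. = FALSE)
  }
  t <- trace$time_s[keep]
  y <- trace$rel_volume[keep]
  fit <- stats::lm.fit(cbind(1, t), y)
  slope <- unname(fit$coefficients[2])
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss <= .Machine$double.eps) NA_real_ else 1 - sum(fit$residuals^2) / tss
  tibble::tibble(slope = slope, fit_r2 = r2, n_points = sum(keep),
                 window_s = window_s)
}

#' Osmotic water permeability from an initial slope
#'
#' Pf = V0 * d(V/V0)/dt / (S * Vw * (Osm_in - Osm_out)), with the osmolality
#' difference converted to mol/cm^3 (1 mmol/kg = 1e-6 mol/cm^3). With the
#' default assay constants a slope of 1.0e-3 1/s gives Pf = 7.77e-3 cm/s.
#'
#' @param slope Initial d(V/V0)/dt, 1/s.
#' @param constants [assay_constants()] bundle; requires `osm_in != osm_out`.
#' @return Pf in cm/s (same sign as `slope`).
#' @examples
#' pf_from_slope(1e-3)
#' @export
pf_from_slope <- function(slope, constants = assay_constants()) {
  .check_constants(constants)
  if (constants$osm_in == constants$osm_out) {
    stop("osmotic gradient is zero (osm_in == osm_out); Pf is undefined",
         call. = FALSE)
  }
  dc <- .osm_to_mol_cm3(constants$osm_in - constants$osm_out)
  constants$v0 * slope / (constants$s * constants$vw * dc)
}

#' Apparent solute permeability from an initial slope
#'
#' Psol = d(V/V0)/dt * V0/S. With the default constants V0/S = 0.02 cm.
#'
#' @inheritParams pf_from_slope
#' @return Psol in cm/s.
#' @examples
#' psol_from_slope(5e-4) # 1e-5 cm/s
#' @export
psol_from_slope <- function(slope, constants = assay_constants()) {
  .check_constants(constants)
  slope * constants$v0 / constants$s
}

#' Estimate permeabilities for every oocyte in a trace table
#'
#' Splits a tidy trace table by oocyte, fits the initial slope of V/V0 in
#' each, and converts it to Pf (hypotonic swelling) or Psol (isotonic solute
#' uptake). Only area ratios enter, so estimates are invariant to the
#' absolute magnification of the raw images.
#'
#' The fitting window trades bias against variance: the swelling curve
#' decelerates as the osmotic gradient dissipates, so long windows
#' underestimate the initial slope of fast swellers, while short windows
#' are noisy for near-control oocytes whose volume barely changes.
#' `window_s = "auto"` resolves this per oocyte with a two-pass rule: an
#' OLS fit over the whole trace gives a provisional slope s1, and the
#' final window is `delta_max / |s1|` (the time over which the relative
#' volume is expected to rise by `delta_max`, i.e. stays in the near-linear
#' regime), clamped to at least two sampling intervals and at most the
#' full trace.
#'
#' @param traces Data frame with columns `oocyte_id`, `group`, `condition`,
#'   `time_s`, `rel_area`, `rel_volume`; multiple oocytes allowed.
#' @param kind `"pf"` or `"psol"`.
#' @param constants [assay_constants()] bundle.
#' @param window_s Fitting window in seconds, or `"auto"` for the adaptive
#'   per-oocyte rule described above.
#' @param delta_max Targeted maximum relative-volume rise inside an
#'   `"auto"` window (default 0.05).
#' @return An object of class `permeability_estimates`: a tibble with one
#'   row per oocyte and columns `oocyte_id`, `group`, `condition`, `kind`,
#'   `slope`, `value` (cm/s), `fit_r2`, `n_points`, `window_s`.
#' @examples
#' tr <- simulate_swelling(pf = 7.77e-3, noise_sd = 0)
#' estimate_permeability(tr, kind = "pf")
#' @export
estimate_permeability <- function(traces, kind = c("pf", "psol"),
                                  constants = assay_constants(),
                                  window_s = 60, delta_max = 0.05) {
  kind <- match.arg(kind)
  .validate_trace(traces)
  .check_constants(constants)
  auto <- identical(window_s, "auto")
  if (!auto) stopifnot(is.numeric(window_s), window_s > 0)
  out <- traces |>
    dplyr::group_by(.data$oocyte_id) |>
    dplyr::group_modify(function(d, key) {
      tr1 <- tibble::tibble(oocyte_id = "x", time_s = d$time_s,
                            rel_area = d$rel_area, rel_volume = d$rel_volume)
      w <- if (auto) .auto_window(tr1, delta_max) else window_s
      fit <- fit_initial_slope(tr1, window_s = w)
      meta <- d[1, intersect(c("group", "condition"), names(d)), drop = FALSE]
      dplyr::bind_cols(meta, fit)
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      kind = .env$kind,
      value = if (.env$kind == "pf") pf_from_slope(.data$slope, constants)
              else psol_from_slope(.data$slope, constants)
    ) |>
    dplyr::select(dplyr::any_of(c("oocyte_id", "group", "condition", "kind",
                                  "slope", "value", "fit_r2", "n_points",
                                  "window_s")))
  class(out) <- unique(c("permeability_estimates", class(out)))
  out
}

# two-pass window rule: time for the provisional full-trace slope to raise
# V/V0 by delta_max, clamped to [2 sampling intervals, full trace]
.auto_window <- function(trace, delta_max) {
  full <- max(trace$time_s)
  s1 <- fit_initial_slope(trace, window_s = full)$slope
  if (!is.finite(s1) || s1 <= 0) return(full)
  dt <- min(diff(trace$time_s))
  min(full, max(2 * dt, delta_max / s1))
}

#' Compare permeability estimates between two groups
#'
#' Two-sided Student's t-test (pooled variance) between the `value` columns
#' of two estimate tables, with per-group mean, SEM, and the fold change
#' mean_a / mean_b. This mirrors the standard comparison of channel-
#' expressing oocytes against water-injected controls at alpha = 0.05.
#'
#' @param estimates_a,estimates_b `permeability_estimates` tables (or any
#'   data frame with a numeric `value` column and a single `kind`), each
#'   with at least two rows. Both must hold the same kind of coefficient.
#' @param alpha Significance level (default 0.05).
#' @return A one-row tibble: `mean_a`, `sem_a`, `n_a`, `mean_b`, `sem_b`,
#'   `n_b`, `fold`, `t_stat`, `p_value`, `significant`. When both groups
#'   have zero variance, `p_value` is 1 for equal means and 0 otherwise, by
#'   convention.
#' @examples
#' a <- data.frame(kind = "pf", value = c(7.5e-3, 7.9e-3, 7.7e-3))
#' b <- data.frame(kind = "pf", value = c(6.8e-4, 7.2e-4, 7.0e-4))
#' compare_groups(a, b)
#' @export
compare_groups <- function(estimates_a, estimates_b, alpha = 0.05) {
  for (e in list(estimates_a, estimates_b)) {
    if (!"value" %in% names(e) || nrow(e) < 2) {
      stop("each group needs a `value` column and >= 2 estimates",
           call. = FALSE)
    }
  }
  ka <- unique(estimates_a$kind)
  kb <- unique(estimates_b$kind)
  if (length(ka) == 1 && length(kb) == 1 && !identical(ka, kb)) {
    stop("cannot compare estimates of different kinds (", ka, " vs ", kb, ")",
         call. = FALSE)
  }
  a <- estimates_a$value
  b <- estimates_b$value
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    t_stat <- 0
    p <- if (mean(a) == mean(b)) 1 else 0
  } else {
    tt <- stats::t.test(a, b, var.equal = TRUE)
    t_stat <- unname(tt$statistic)
    p <- tt$p.value
  }
  tibble::tibble(
    mean_a = mean(a), sem_a = stats::sd(a) / sqrt(length(a)), n_a = length(a),
    mean_b = mean(b), sem_b = stats::sd(b) / sqrt(length(b)), n_b = length(b),
    fold = mean(a) / mean(b),
    t_stat = t_stat, p_value = p, significant = p < alpha
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.permeability_estimates <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @export
glance.permeability_estimates <- function(x, ...) {
  x |>
    tibble::as_tibble() |>
    dplyr::group_by(dplyr::across(dplyr::any_of(c("group", "condition", "kind")))) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data$value),
      sem = stats::sd(.data$value) / sqrt(dplyr::n()),
      median_r2 = stats::median(.data$fit_r2),
      .groups = "drop"
    )
}
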