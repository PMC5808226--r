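test_that("relative volume is the 3/2 power of relative area", {
  expect_equal(relative_volume(1), 1)
  expect_equal(relative_volume(4), 8)
  expect_equal(relative_volume(1.21), 1.331)
  expect_equal(relative_volume(c(1, 1.1))[1], 1)
  expect_error(relative_volume(c(1, -0.5, 2)), "index 2")
  expect_error(relative_volume(numeric(0)))
})

test_that("relative volume is monotone and bounded by relative area correctly", {
  x <- sort(stats::runif(50, 0.5, 3))
  v <- relative_volume(x)
  expect_true(all(diff(v) > 0))
  expect_true(all(v[x >= 1] >= x[x >= 1]))
  expect_true(all(v[x <= 1] <= x[x <= 1]))
})

test_that("initial slope fit recovers an exact line and flags degenerate input", {
  tr <- tibble::tibble(oocyte_id = "a", time_s = c(0, 15, 30, 45, 60),
                       rel_area = 1, # unused by the fit
                       rel_volume = 1 + 1e-3 * c(0, 15, 30, 45, 60))
  fit <- fit_initial_slope(tr, window_s = 60)
  expect_equal(fit$slope, 1e-3, tolerance = 1e-12)
  expect_equal(fit$fit_r2, 1)
  expect_equal(fit$n_points, 5L)

  const <- dplyr::mutate(tr, rel_volume = 2)
  fit0 <- fit_initial_slope(const)
  expect_equal(fit0$slope, 0)
  expect_true(is.na(fit0$fit_r2))

  expect_error(fit_initial_slope(tr, window_s = 10), "insufficient")
})

test_that("Pf conversion matches the arithmetic oracle and is linear", {
  expect_equal(pf_from_slope(0), 0)
  # 9e-4 * 1e-3 / (0.045 * 18 * 1.43e-4)
  expect_equal(pf_from_slope(1e-3), 9e-4 * 1e-3 / (0.045 * 18 * 143e-6))
  expect_equal(pf_from_slope(1e-3), 7.770e-3, tolerance = 1e-4)
  k <- assay_constants(v0 = 2e-3, s = 0.1, vw = 18, osm_in = 300,
                       osm_out = 100)
  expect_equal(pf_from_slope(2e-3, k), 2 * pf_from_slope(1e-3, k))
  expect_error(pf_from_slope(1e-3, assay_constants(osm_out = 202)),
               "gradient")
})

test_that("Psol conversion is slope times V0/S", {
  expect_equal(psol_from_slope(0), 0)
  expect_equal(psol_from_slope(5e-4), 1.0e-5)
  # the implied slope of a printed Psol of 5.031e-6 cm/s round-trips
  expect_equal(psol_from_slope(2.5155e-4), 5.031e-6, tolerance = 1e-6)
})

test_that("noiseless swelling simulation obeys the initial-slope identity", {
  tr <- simulate_swelling(pf = 7.770e-3, noise_sd = 0)
  expect_equal(tr$rel_volume[1], 1)
  # analytic initial slope Pf*S*Vw*dOsm/V0 = 1.0e-3 1/s; the two-point
  # slope averages the decaying derivative over [0,15] s (~1% low)
  two_point <- diff(tr$rel_volume[1:2]) / diff(tr$time_s[1:2])
  expect_lt(abs(two_point - 1.0e-3) / 1.0e-3, 0.02)
  # the window-30 OLS slope equals the mean derivative over [0,30]:
  # check it against the finite-difference oracle and the analytic value
  fit <- fit_initial_slope(tr, window_s = 30)
  fd <- (tr$rel_volume[3] - tr$rel_volume[1]) / 30
  expect_equal(fit$slope, fd, tolerance = 1e-9)
  expect_lt(abs(fit$slope - 1.0e-3) / 1.0e-3, 0.03)
})

test_that("zero water permeability gives a flat trace", {
  tr <- simulate_swelling(pf = 0, noise_sd = 0)
  expect_true(all(tr$rel_volume == 1))
})

test_that("long noiseless runs plateau at the osmolality ratio", {
  tr <- simulate_swelling(pf = 7.77e-3, dt = 60, duration = 12 * 3600,
                          noise_sd = 0)
  expect_equal(dplyr::last(tr$rel_volume), 202 / 59, tolerance = 0.005)
  expect_true(all(diff(tr$rel_volume) > 0)) # strictly increasing
  expect_true(all(tr$rel_volume < 202 / 59 + 1e-9))
})

test_that("fixed-step integration agrees with an adaptive reference solver", {
  constants <- assay_constants()
  c_in0 <- 202e-6; c_out <- 59e-6
  ref <- deSolve::ode(
    y = c(v = constants$v0), times = seq(0, 300, by = 15),
    func = function(t, y, p) {
      list(7.77e-3 * constants$s * constants$vw *
             (c_in0 * constants$v0 / y[["v"]] - c_out))
    }, parms = NULL, method = "lsoda", rtol = 1e-10, atol = 1e-12
  )
  tr <- simulate_swelling(pf = 7.77e-3, noise_sd = 0)
  expect_equal(tr$rel_volume, ref[, "v"] / constants$v0, tolerance = 1e-7,
               ignore_attr = TRUE)
})

test_that("simulation rejects invalid noise and non-positive steps", {
  expect_error(simulate_swelling(7.77e-3, noise_sd = -0.1), "non-negative")
  expect_error(simulate_swelling(7.77e-3, dt = 0))
})

test_that("noise is multiplicative, seeded, and pins the first frame", {
  a <- simulate_swelling(7.77e-3, noise_sd = 0.01, seed = 11)
  b <- simulate_swelling(7.77e-3, noise_sd = 0.01, seed = 11)
  c <- simulate_swelling(7.77e-3, noise_sd = 0.01, seed = 12)
  expect_identical(a, b)
  expect_false(identical(a$rel_area, c$rel_area))
  expect_equal(a$rel_area[1], 1)
})

test_that("solute uptake is linear with rate psol*S/V0 and inverts exactly", {
  flat <- simulate_solute_uptake(0, noise_sd = 0)
  expect_true(all(flat$rel_volume == 1))

  tr <- simulate_solute_uptake(1e-5, noise_sd = 0)
  slopes <- diff(tr$rel_volume) / diff(tr$time_s)
  expect_equal(unique(round(slopes, 12)), 5e-4)

  est <- psol_from_slope(fit_initial_slope(tr, window_s = 300)$slope)
  expect_equal(est, 1e-5, tolerance = 1e-10)
})

test_that("pf round-trips through simulate -> fit -> convert, noiselessly", {
  # two-point initial slope: curvature bias stays below 2% across the range
  for (pf in c(1e-3, 5e-3, 7.77e-3, 1e-2)) {
    tr <- simulate_swelling(pf, noise_sd = 0)
    est <- pf_from_slope(fit_initial_slope(tr, window_s = 15)$slope)
    expect_lt(abs(est - pf) / pf, 0.02)
  }
})

test_that("parameter recovery stays within 10% median error at assay-like noise", {
  set.seed(202)
  pfs <- stats::runif(200, 1e-3, 1e-2)
  errs <- vapply(seq_along(pfs), function(i) {
    tr <- simulate_swelling(pfs[i], noise_sd = 0.005, seed = i)
    est <- pf_from_slope(fit_initial_slope(tr, window_s = 120)$slope)
    abs(est - pfs[i]) / pfs[i]
  }, numeric(1))
  expect_lt(stats::median(errs), 0.10)
})

test_that("estimates depend only on area ratios, not raw magnification", {
  areas <- c(1000, 1030, 1061, 1092, 1124)
  make <- function(scale) {
    a <- areas * scale
    tibble::tibble(oocyte_id = "x", group = "expressing",
                   condition = "water", time_s = seq(0, 60, by = 15),
                   rel_area = a / a[1],
                   rel_volume = relative_volume(a / a[1]))
  }
  e1 <- estimate_permeability(make(1), kind = "pf")
  e2 <- estimate_permeability(make(137.5), kind = "pf")
  expect_equal(e1$value, e2$value)
})

test_that("estimate_permeability handles many oocytes and both kinds", {
  exp1 <- gen_swelling_experiment(n_expressing = 3, n_control = 2,
                                  noise_sd = 0, pf_cv = 0, seed = 9)
  est <- estimate_permeability(exp1$traces, kind = "pf", window_s = 30)
  expect_equal(nrow(est), 5)
  expect_setequal(unique(est$kind), "pf")
  expect_equal(est$value[est$group == "expressing"],
               rep(7.7e-3, 3), tolerance = 0.02)
  expect_equal(est$value[est$group == "control"],
               rep(7.0e-4, 2), tolerance = 0.02)
  g <- glance(est)
  expect_equal(nrow(g), 2)
})

test_that("group comparison reports fold, SEM, and a Student t p-value", {
  a <- tibble::tibble(kind = "pf", value = c(1, 2, 3))
  expect_equal(compare_groups(a, a)$fold, 1)
  expect_equal(compare_groups(a, a)$p_value, 1, tolerance = 1e-12)

  b <- tibble::tibble(kind = "pf", value = c(1, 2, 3) / 11)
  cmp <- compare_groups(a, b)
  expect_equal(cmp$fold, 11)
  expect_equal(cmp$sem_a, stats::sd(a$value) / sqrt(3))

  const <- tibble::tibble(kind = "pf", value = c(2, 2))
  expect_equal(compare_groups(const, const)$p_value, 1)

  psol <- tibble::tibble(kind = "psol", value = c(1, 2))
  expect_error(compare_groups(a, psol), "different kinds")
  expect_error(compare_groups(a[1, ], b), ">= 2")
})

test_that("an 11-fold permeability contrast is detected nearly always", {
  hits <- vapply(1:200, function(s) {
    exp1 <- gen_swelling_experiment(
      n_expressing = 10, n_control = 10, pf_expressing = 7.7e-3,
      pf_control = 7.0e-4, noise_sd = 0.01, seed = s
    )
    est <- estimate_permeability(exp1$traces, kind = "pf")
    cmp <- compare_groups(est[est$group == "expressing", ],
                          est[est$group == "control", ])
    cmp$significant
  }, logical(1))
  expect_gte(mean(hits), 0.99)
})

test_that("the adaptive window shortens for fast swellers and extends for controls", {
  fast <- simulate_swelling(7.7e-3, noise_sd = 0.01, seed = 3,
                            oocyte_id = "fast")
  slow <- simulate_swelling(7.0e-4, noise_sd = 0.01, seed = 4,
                            oocyte_id = "slow")
  est <- estimate_permeability(dplyr::bind_rows(fast, slow), kind = "pf",
                               window_s = "auto")
  w_fast <- est$window_s[est$oocyte_id == "fast"]
  w_slow <- est$window_s[est$oocyte_id == "slow"]
  expect_lt(w_fast, w_slow)
  expect_equal(w_slow, 300)
  # near-unbiased recovery for both regimes, averaged over seeds
  folds <- vapply(1:25, function(s) {
    ex <- gen_swelling_experiment(seed = s)
    est <- estimate_permeability(ex$traces, kind = "pf", window_s = "auto")
    mean(est$value[est$group == "expressing"]) /
      mean(est$value[est$group == "control"])
  }, numeric(1))
  expect_equal(mean(folds), 11, tolerance = 0.1)
})
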