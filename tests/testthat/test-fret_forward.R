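fp <- fret_params(R0 = 6.2, tauD = 4.0)

test_that("point-distance efficiency follows the sixth-power law", {
  expect_equal(fret_efficiency(fp$R0, fp), 0.5)
  expect_equal(fret_efficiency(2 * fp$R0, fp), 1 / 65)
  expect_equal(fret_efficiency(0, fp), 1)
  expect_true(all(diff(fret_efficiency(seq(0.1, 20, 0.1), fp)) < 0))
})

test_that("ensemble efficiency saturates in the short- and long-chain limits", {
  expect_gt(mean_efficiency(saw_params(0.57, R = 0.1 * fp$R0), fp), 0.99)
  expect_lt(mean_efficiency(saw_params(0.57, R = 10 * fp$R0), fp), 0.01)
})

test_that("quadrature observables match a Monte-Carlo average over the distance distribution", {
  p <- saw_params(0.57, R = 5.5)
  set.seed(7)
  E <- fret_efficiency(saw_sample(1e6, p), fp)
  se_m <- sd(E) / sqrt(length(E))
  expect_lt(abs(mean_efficiency(p, fp) - mean(E)), 3 * se_m)
  v_mc <- var(E)
  se_v <- sd((E - mean(E))^2) / sqrt(length(E))
  expect_lt(abs(efficiency_variance(p, fp) - v_mc), 3 * se_v)
})

test_that("efficiency variance is a bounded, non-negative [0,1]-variance", {
  for (nu in c(0.4, 0.57)) for (R in c(2, 6.2, 12)) {
    v <- efficiency_variance(saw_params(nu, R = R), fp)
    expect_gte(v, 0); expect_lte(v, 0.25)
  }
})

test_that("lifetime ratio reduces to the static line for a narrow distribution", {
  ## R << R0 with huge R0: E(r) is nearly constant over P(r), so var -> 0
  fp_wide <- fret_params(R0 = 100, tauD = 4.0)
  p <- saw_params(0.57, R = 0.5)
  expect_lt(efficiency_variance(p, fp_wide), 1e-6)
  expect_equal(lifetime_ratio(p, fp_wide),
               1 - mean_efficiency(p, fp_wide), tolerance = 1e-5)
})

test_that("dynamic line lies on or above the static line and spans the limits", {
  expect_equal(static_line(c(0, 0.5, 1)), c(1, 0.5, 0))
  expect_error(static_line(1.2), "\\[0, 1\\]")
  dl <- dynamic_line(3 / 5, fp, R_grid = seq(0.1, 5, by = 0.1) * fp$R0)
  expect_true(all(dl$tau_ratio >= static_line(dl$mean_E) - 1e-12))
  first <- dl[which.max(dl$mean_E), ]  # smallest R
  last <- dl[which.min(dl$mean_E), ]
  expect_gt(first$mean_E, 0.99); expect_lt(first$tau_ratio, 0.05)
  expect_lt(last$mean_E, 0.02); expect_gt(last$tau_ratio, 0.97)
})

test_that("offset above the static line equals var/(1-E) for all parameters", {
  for (nu in c(0.45, 0.6)) for (R in c(3, 6.2, 10)) {
    p <- saw_params(nu, R = R)
    mE <- mean_efficiency(p, fp)
    expect_equal(lifetime_ratio(p, fp) - (1 - mE),
                 efficiency_variance(p, fp) / (1 - mE), tolerance = 1e-9)
  }
})

test_that("both inversions are two-sided inverses of the forward maps", {
  for (R in c(3, 5, 6.2, 9, 12)) {
    p <- saw_params(0.57, R = R)
    expect_equal(invert_intensity(mean_efficiency(p, fp), 0.57, fp), R,
                 tolerance = 1e-3)
    expect_equal(invert_lifetime(lifetime_ratio(p, fp), 0.57, fp), R,
                 tolerance = 1e-3)
  }
  expect_error(invert_intensity(1.5, 0.57, fp), "inside \\(0, 1\\)")
  expect_error(invert_lifetime(0, 0.57, fp), "inside \\(0, 1\\)")
})

test_that("intensity inversion matches a high-precision bisection oracle", {
  target <- 0.5
  lo <- 0.05 * fp$R0; hi <- 10 * fp$R0
  for (k in 1:60) {  # bisection to ~1e-9 nm
    mid <- (lo + hi) / 2
    if (mean_efficiency(saw_params(0.57, R = mid), fp) > target) lo <- mid else hi <- mid
  }
  expect_equal(invert_intensity(0.5, 0.57, fp), (lo + hi) / 2, tolerance = 1e-5)
})

test_that("inverted distances are monotone in the observables", {
  Es <- c(0.2, 0.4, 0.6, 0.8)
  Ri <- vapply(Es, invert_intensity, numeric(1), nu = 0.57, fp = fp)
  expect_true(all(diff(Ri) < 0))  # higher E -> shorter distance
  taus <- c(0.2, 0.4, 0.6, 0.8)
  Rt <- vapply(taus, invert_lifetime, numeric(1), nu = 0.57, fp = fp)
  expect_true(all(diff(Rt) > 0))
})

test_that("fast quadrature curves agree with the adaptive-quadrature observables", {
  R_grid <- c(2, 4, 6.2, 9, 14)
  crv <- sawfret:::saw_forward_curves(0.57, fp, R_grid)
  for (k in seq_along(R_grid)) {
    p <- saw_params(0.57, R = R_grid[k])
    expect_equal(crv$mean_E[k], mean_efficiency(p, fp), tolerance = 1e-7)
    expect_equal(crv$tau_ratio[k], lifetime_ratio(p, fp), tolerance = 1e-6)
  }
})
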