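fp <- fret_params()
gt6 <- ground_truth(nu_true = 0.6, lp_true = 0.5)
truth6 <- make_construct_truth(gt6)
obs6 <- forward_centers(truth6, 0.6, fp)

test_that("the construct set matches the documented 14 label pairs", {
  cs <- alphasyn_constructs()
  expect_identical(nrow(cs), 14L)
  expect_identical(paste(cs$label_i, cs$label_j),
                   c("9 18", "9 27", "9 42", "9 69", "9 90", "9 140",
                     "18 90", "18 124", "42 85", "42 90", "56 69", "56 90",
                     "90 140", "130 140"))
  expect_identical(cs$dN, cs$label_j - cs$label_i)
})

test_that("noiseless centers invert to the generating distances under the true nu", {
  inf <- infer_distances(obs6, 0.6, fp)
  expect_equal(inf$R_int, truth6$R_true, tolerance = 1e-3)
  expect_equal(inf$R_tau, truth6$R_true, tolerance = 1e-3)
  expect_identical(inf$included, obs6$E_center < 0.9)
  ## a wrong exponent breaks the agreement between the two observables
  inf_bad <- infer_distances(obs6, 0.45, fp)
  use <- inf_bad$included
  expect_gt(mean(abs(inf_bad$R_int[use] - inf_bad$R_tau[use])), 0.05)
})

test_that("exponent scan recovers the generating exponent on noiseless data", {
  scan <- optimize_nu(obs6, fp)
  expect_equal(scan$nu_star, 0.6, tolerance = 0.01)
  expect_equal(scan$objective_curve$dR_norm[
    scan$objective_curve$nu == 3 / 5], 1, tolerance = 1e-12)
  ## smooth single-minimum objective: one sign change in the differences
  d <- diff(scan$objective_curve$dR_norm)
  expect_identical(sum(diff(sign(d)) != 0), 1L)
  expect_error(optimize_nu(obs6[1:2, ], fp), "at least 3")
})

test_that("persistence-length fit recovers the generating value and scales correctly", {
  inf <- infer_distances(obs6, 0.6, fp)
  lpf <- fit_persistence_length(inf, 0.6)
  expect_equal(lpf$lp, 0.5, tolerance = 1e-3 / 0.5)

  ## halving every distance quarters lp (R ~ sqrt(lp))
  inf_half <- inf
  inf_half$R_int <- inf$R_int / 2; inf_half$R_tau <- inf$R_tau / 2
  expect_equal(fit_persistence_length(inf_half, 0.6)$lp, 0.5 / 4,
               tolerance = 1e-2)
  expect_error(fit_persistence_length(inf[1, ], 0.6), "underdetermined")
})

test_that("deviation map is zero on-model and localizes a planted offset", {
  inf <- infer_distances(obs6, 0.6, fp)
  chain <- flory_chain(lp = 0.5, nu = 0.6)
  dm <- deviation_map(inf, chain)
  expect_lt(max(abs(dm$points$dR)), 2e-3)

  ## plant a -0.5 nm compaction on the 56-90 construct
  inf2 <- inf
  k <- which(inf2$label_i == 56 & inf2$label_j == 90)
  inf2$R_int[k] <- inf2$R_int[k] - 0.5; inf2$R_tau[k] <- inf2$R_tau[k] - 0.5
  dm2 <- deviation_map(inf2, chain)
  kk <- which(dm2$points$label_i == 56 & dm2$points$label_j == 90)
  expect_equal(dm2$points$dR[kk], -0.5, tolerance = 1e-2)
  expect_true(all(abs(dm2$points$dR[-kk]) < 2e-3))

  ## the interpolant passes through the data points
  z <- sawfret:::barycentric_interp(dm2$points$label_i, dm2$points$label_j,
                                    dm2$points$dR, dm2$points$label_i,
                                    dm2$points$label_j)
  expect_equal(z, dm2$points$dR, tolerance = 1e-9)
})

test_that("solvent differences carry the expansion sign convention", {
  expect_equal(solvent_delta(obs6, obs6)$dE, rep(0, 14))
  truth_exp <- truth6; truth_exp$R_true <- truth6$R_true * 1.2
  obs_exp <- forward_centers(truth_exp, 0.6, fp)
  expect_true(all(solvent_delta(obs6, obs_exp)$dE > 0))   # expansion: positive
  truth_cmp <- truth6; truth_cmp$R_true <- truth6$R_true * 0.8
  obs_cmp <- forward_centers(truth_cmp, 0.6, fp)
  expect_true(all(solvent_delta(obs6, obs_cmp)$dE < 0))   # compaction: negative
  expect_error(solvent_delta(obs6, obs6[1:5, ]), "do not match")
})

test_that("excluding high-efficiency constructs barely moves the optimum on-model", {
  scan_all <- optimize_nu(obs6, fp, E_max = 0.999)
  scan_cut <- optimize_nu(obs6, fp, E_max = 0.9)
  expect_lt(abs(scan_all$nu_star - scan_cut$nu_star), 0.01)
})
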