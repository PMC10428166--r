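test_that("construct truths follow the chain model and accept planted deviations", {
  gt <- ground_truth()
  truth <- make_construct_truth(gt)
  expect_identical(order(truth$R_true), order(truth$dN))
  chain <- flory_chain(lp = 0.49, nu = 0.57)
  expect_equal(truth$R_true, flory_distance(truth$dN, chain), tolerance = 1e-12)
  scale <- rep(1, 14); scale[truth$label_i == 56 & truth$label_j == 90] <- 0.9
  truth2 <- make_construct_truth(gt, scale = scale)
  expect_equal(truth2$R_true / truth$R_true, scale)
})

test_that("a planted compaction propagates to a negative deviation end-to-end", {
  gt <- ground_truth(nu_true = 0.6, lp_true = 0.5)
  scale <- rep(1, 14)
  k56 <- which(alphasyn_constructs()$label_i == 56 &
                 alphasyn_constructs()$label_j == 90)
  scale[k56] <- 0.9
  truth <- make_construct_truth(gt, scale = scale)
  fit <- flory_fit(forward_centers(truth, 0.6))
  dev <- fit$devmap$points
  kk <- which(dev$label_i == 56 & dev$label_j == 90)
  expect_lt(dev$dR[kk], -0.1)
})

test_that("photon streams embed their ground truth and regenerate identically", {
  gt <- ground_truth()
  ph1 <- simulate_bursts(gt, 5.5, 100, seed = 21)
  ph2 <- simulate_bursts(gt, 5.5, 100, seed = 21)
  expect_identical(ph1, ph2)
  tr <- attr(ph1, "ground_truth")
  expect_identical(tr$seed, 21)
  expect_identical(tr$R_true, 5.5)
  expect_s3_class(tr$gt, "ground_truth")
  ph3 <- simulate_bursts(gt, 5.5, 100, seed = 22)
  expect_false(identical(ph1$macro_time_s, ph3$macro_time_s))
})

test_that("the no-acceptor limit yields a donor-only stream with the right lifetime", {
  gt <- ground_truth(donor_only_frac = 0)
  ph <- simulate_bursts(gt, R_true = Inf, n_bursts = 400, seed = 23)
  res <- suppressWarnings(process_photons(ph, correction_factors_of(gt)))
  expect_gte(mean(res$bursts$kind == "donor_only"), 0.97)
  expect_equal(res$tauD, 4.0, tolerance = 0.1 / 4)
})

test_that("per-burst observables close the loop with the analytic forward model", {
  gt <- ground_truth(bg_donor = 0, bg_acceptor = 0, alpha_leak = 0,
                     donor_only_frac = 0)
  fp <- fret_params(gt$R0, gt$tauD)
  p <- saw_params(gt$nu_true, R = 5.5)
  ph <- simulate_bursts(gt, 5.5, 1500, seed = 24)
  res <- process_photons(ph, correction_factors_of(gt), tauD_fixed = gt$tauD)
  f <- res$bursts[res$bursts$kind == "fret" & is.finite(res$bursts$tau_burst), ]
  seE <- sd(f$E_burst) / sqrt(nrow(f))
  expect_lt(abs(mean(f$E_burst) - mean_efficiency(p, fp)), 3 * seE)
  ratio <- f$tau_burst / gt$tauD
  seT <- sd(ratio) / sqrt(length(ratio))
  expect_lt(abs(mean(ratio) - lifetime_ratio(p, fp)), 3 * seT)
})

test_that("aggregate and overbright events are planted with labels", {
  gt <- ground_truth(donor_only_frac = 0)
  ph <- simulate_trace_with_aggregates(gt, 6, n_bursts = 50, n_aggregates = 4,
                                       n_overbright = 2, seed = 25)
  tr <- attr(ph, "ground_truth")
  expect_length(tr$aggregate_bins, 4)
  expect_length(tr$overbright_bins, 2)
  expect_true(all(vapply(tr$aggregate_bins, length, 1L) >= 2))

  ph0 <- simulate_trace_with_aggregates(gt, 6, n_bursts = 50, seed = 25)
  b0 <- select_bursts(correct_trace(bin_photons(ph0),
                                    correction_factors_of(gt)))
  expect_identical(attr(b0, "n_accepted"), 50L)
})

test_that("solvent scenarios scale the three probe constructs as configured", {
  gt <- ground_truth()
  for (mode in c("low_salt", "urea", "methanol")) {
    sc <- solvent_scenario(gt, mode)
    expect_identical(paste(sc$label_i, sc$label_j), c("9 42", "56 90", "90 140"))
    expect_equal(sc$R_alt, sc$R_ref * sc$factor)
  }
  expect_true(all(solvent_scenario(gt, "urea")$factor > 1))
  ls <- solvent_scenario(gt, "low_salt")
  expect_identical(which(ls$factor != 1), 3L)
  expect_lt(solvent_scenario(gt, "methanol")$factor[1], 1)
  id <- solvent_scenario(gt, "urea", factors = rep(1, 3))
  expect_equal(id$R_alt, id$R_ref)
  expect_error(solvent_scenario(gt, "acetone"))
})
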