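test_that("binning conserves photons and places them in the right bins", {
  empty <- photon_records(character(), numeric(), numeric())
  expect_identical(nrow(bin_photons(empty)), 0L)

  ph <- photons_in_bins(3, 10)
  tr <- bin_photons(ph)
  expect_identical(tr$bin_index, 3)
  expect_identical(tr$donor + tr$acceptor, 10L)

  set.seed(1)
  n <- 5000
  ph <- photon_records(sample(c("donor", "acceptor"), n, TRUE),
                       sort(runif(n, 0, 0.5)), runif(n, 0, 50))
  tr <- bin_photons(ph)
  expect_identical(sum(tr$donor) + sum(tr$acceptor), as.integer(n))
  expect_error(photon_records("donor", numeric(2), numeric(2)), "lengths")
  expect_error(photon_records(c("donor", "donor"), c(2, 1), c(0, 0)),
               "non-decreasing")
})

test_that("zero correction factors leave the trace unchanged", {
  tr <- bin_photons(photons_in_bins(c(1, 5), c(80, 120)))
  cc <- correct_trace(tr, correction_factors())
  expect_equal(cc$I_D, cc$donor)
  expect_equal(cc$I_A, cc$acceptor)
})

test_that("leakage and background corrections recover the emitted signal", {
  gt <- ground_truth(bg_donor = 0, bg_acceptor = 0, alpha_leak = 0.05,
                     donor_only_frac = 0)
  ph <- simulate_bursts(gt, R_true = Inf, n_bursts = 200, seed = 3)
  cc <- correct_trace(bin_photons(ph), correction_factors_of(gt))
  ## donor-only emission: the leakage signal is removed (the residual
  ## comes from clipping corrected counts at zero, about sd/sqrt(2*pi))
  expect_gt(mean(cc$acceptor[cc$donor > 0]), 4)  # leakage really was present
  expect_lt(mean(cc$I_A[cc$donor > 0]),
            0.25 * mean(cc$acceptor[cc$donor > 0]))

  ## background-only stream corrects to ~0 in both channels
  set.seed(4)
  nb <- 400
  bg <- photon_records(sample(c("donor", "acceptor"), nb, TRUE),
                       sort(runif(nb, 0, 1)), runif(nb, 0, 50))
  cbg <- correct_trace(bin_photons(bg), correction_factors(bg_donor = 0.2,
                                                          bg_acceptor = 0.2))
  expect_lt(mean(cbg$I_D + cbg$I_A), 1.2)
})

test_that("burst selection applies both thresholds and the consecutive-bin rule", {
  tr <- bin_photons(photons_in_bins(c(2, 10, 20), c(49, 500, 1001)))
  b <- select_bursts(tr)
  expect_identical(attr(b, "n_accepted"), 1L)
  expect_identical(b$bin_index, 10)

  ## two adjacent qualifying bins are a slow diffuser: both rejected
  tr2 <- bin_photons(photons_in_bins(c(2, 5, 6, 30), c(300, 300, 300, 300)))
  b2 <- select_bursts(tr2)
  expect_identical(sort(b2$bin_index), c(2, 30))
  expect_identical(attr(b2, "n_rejected_slow"), 2L)
})

test_that("donor-only separation uses the leakage expectation on raw counts", {
  cf <- correction_factors(alpha_leak = 0.05)
  tr <- bin_photons(photons_in_bins(c(1, 8), c(200, 200)))  # donor-channel only
  b <- classify_bursts(select_bursts(correct_trace(tr, cf)), cf)
  expect_true(all(b$kind == "donor_only"))

  gt <- ground_truth(donor_only_frac = 0)
  ph <- simulate_bursts(gt, R_true = 6.2, n_bursts = 300, seed = 5)  # E ~ 0.5
  res <- process_photons(ph, correction_factors_of(gt), tauD_fixed = 4)
  expect_gt(mean(res$bursts$kind == "fret"), 0.98)
})

test_that("misclassification of a labeled donor-only + FRET mixture stays below 2%", {
  gt <- ground_truth(donor_only_frac = 1)  # one donor-only per FRET burst
  ph <- simulate_bursts(gt, R_true = 6.2, n_bursts = 800, seed = 6)
  truth <- attr(ph, "ground_truth")
  res <- process_photons(ph, correction_factors_of(gt), tauD_fixed = 4)
  b <- res$bursts
  lab <- ifelse(b$bin_index %in% truth$fret_bins, "fret", "donor_only")
  expect_lt(mean(b$kind != lab), 0.02)
})

test_that("per-burst observables reproduce intensity ratios and arrival times", {
  cf <- correction_factors()
  tr <- correct_trace(bin_photons(photons_in_bins(2, 100,
    channel = rep(c("donor", "acceptor"), 50))), cf)
  b <- burst_observables(select_bursts(tr), photons_in_bins(2, 100,
    channel = rep(c("donor", "acceptor"), 50)), cf)
  expect_equal(b$E_burst, 0.5)

  ## acceptor-only burst: E = 1
  ph_a <- photons_in_bins(2, 100, channel = "acceptor")
  b_a <- burst_observables(select_bursts(correct_trace(bin_photons(ph_a), cf)),
                           ph_a, cf)
  expect_equal(b_a$E_burst, 1)

  ## free-dye control: exponential arrivals of mean 4.1 ns + 2 ns offset
  set.seed(8)
  micro <- (2 + rexp(500, 1 / 4.1)) %% 50
  macro <- (3 + seq(0.05, 0.95, length.out = 500)) * 1e-3
  ph <- photon_records(rep("donor", 500), macro, micro)
  cf2 <- correction_factors(irf_offset = 2)
  b <- burst_observables(select_bursts(correct_trace(bin_photons(ph), cf2)),
                         ph, cf2)
  expect_equal(b$tau_burst, 4.1, tolerance = 0.2 / 4.1)
})

test_that("KDE cloud center finds the dominant density mode", {
  set.seed(9)
  x <- rnorm(2000, 0.5, 0.03); y <- rnorm(2000, 0.55, 0.03)
  ctr <- density_center(x, y)
  bw <- sd(x) * 2000^(-1 / 6)
  expect_lt(abs(ctr["x"] - 0.5), bw)
  expect_lt(abs(ctr["y"] - 0.55), bw)

  ## 70/30 mixture: the heavier mode wins
  x2 <- c(rnorm(1400, 0.3, 0.02), rnorm(600, 0.7, 0.02))
  y2 <- c(rnorm(1400, 0.7, 0.02), rnorm(600, 0.3, 0.02))
  ctr2 <- density_center(x2, y2)
  expect_lt(abs(ctr2["x"] - 0.3), 0.05)

  ## degenerate cloud: the common point itself
  expect_warning(ctr3 <- density_center(rep(0.4, 60), rep(0.6, 60)), NA)
  expect_equal(unname(ctr3), c(0.4, 0.6))

  expect_warning(density_center(1:10, 1:10), "medians")
})

test_that("donor lifetime comes from the burst mode and resists outliers", {
  gt <- ground_truth(donor_only_frac = 1)
  ph <- simulate_bursts(gt, R_true = Inf, n_bursts = 600, seed = 10)
  ## no real FRET population exists, so the (few-point) cloud center
  ## falls back to medians with a warning; only tauD matters here
  res <- suppressWarnings(process_photons(ph, correction_factors_of(gt)))
  expect_equal(res$tauD, 4.0, tolerance = 0.1 / 4)

  do_taus <- res$bursts$tau_burst[res$bursts$kind == "donor_only"]
  expect_equal(donor_only_lifetime(sample(do_taus)),
               donor_only_lifetime(do_taus))  # order invariance
  contaminated <- c(do_taus, rep(12, round(0.05 * length(do_taus))))
  expect_equal(donor_only_lifetime(contaminated), 4.0, tolerance = 0.15 / 4)
  expect_error(donor_only_lifetime(rnorm(10, 4)), "at least 50")
})
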