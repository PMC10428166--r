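test_that("sampling is reproducible and preserves bond lengths", {
  m <- chain_model(strrep("G", 25), k_bend = 0, attraction = 0,
                   termini_charged = FALSE)
  e1 <- sample_chain(m, n_frames = 50, seed = 11)
  e2 <- sample_chain(m, n_frames = 50, seed = 11)
  expect_identical(e1$frames, e2$frames)
  bonds <- apply(e1$frames, 3, function(xyz)
    sqrt(rowSums(diff(xyz)^2)))
  expect_true(all(abs(bonds - 0.38) < 1e-6))
})

test_that("hard-core ensembles contain no overlapping nonbonded beads", {
  m <- chain_model(strrep("G", 20), k_bend = 0, attraction = 0,
                   termini_charged = FALSE)
  e <- sample_chain(m, n_frames = 60, seed = 12)
  for (f in seq_len(10)) {
    d <- as.matrix(dist(e$frames[, , f]))
    nb <- abs(row(d) - col(d)) >= 2
    expect_gt(min(d[nb]), 0.38 - 1e-9)
  }
})

test_that("the non-interacting limit reproduces ideal-chain statistics", {
  N <- 40
  m <- chain_model(strrep("G", N), bead_diameter = 0, k_bend = 0,
                   attraction = 0, termini_charged = FALSE)
  e <- sample_chain(m, n_frames = 1500, seed = 13)
  r2 <- colSums((e$frames[1, , ] - e$frames[N, , ])^2)
  se <- sd(r2) / sqrt(length(r2))
  expect_lt(abs(mean(r2) - (N - 1) * 0.38^2), 3 * se)
})

test_that("label distances average frame-wise and add the dye correction", {
  m <- chain_model(strrep("G", 20), k_bend = 0, attraction = 0,
                   termini_charged = FALSE)
  e <- sample_chain(m, n_frames = 40, seed = 14)
  brute <- mean(vapply(seq_len(40), function(f)
    sqrt(sum((e$frames[3, , f] - e$frames[17, , f])^2)), numeric(1)))
  expect_equal(label_distance(e, 3, 17), brute, tolerance = 1e-12)
  expect_equal(label_distance(e, 3, 17, dye_mode = "bead_offset"),
               brute + 0.76 * 2^(3 / 5), tolerance = 1e-12)
  expect_error(label_distance(e, 5, 5), "differ")
})

test_that("contact maps are symmetric, band-excluded and match brute force", {
  ## a straight rod at bond spacing has no non-excluded pair within 0.7 nm
  rod <- array(0, c(12, 3, 2))
  rod[, 1, ] <- (0:11) * 0.38
  cm_rod <- contact_map(as_ensemble(rod))
  expect_true(all(cm_rod$fractions == 0))

  ## a pinned pair at 0.69 nm with |i-j| = 5 registers fraction 1
  pin <- rod
  pin[7, , ] <- pin[2, , ] + c(0.69, 0, 0)
  cm_pin <- contact_map(as_ensemble(pin))
  expect_equal(cm_pin$fractions[2, 7], 1)

  set.seed(15)
  for (k in 1:5) {
    N <- sample(8:30, 1); F <- sample(5:40, 1)
    fr <- array(runif(N * 3 * F, 0, 1.6), c(N, 3, F))
    cm <- contact_map(as_ensemble(fr))
    expect_identical(cm$fractions, t(cm$fractions))
    band <- abs(row(cm$fractions) - col(cm$fractions)) <= 3
    expect_true(all(cm$fractions[band] == 0))
    expect_equal(cm$fractions, contact_map_bruteforce(fr), tolerance = 1e-12)
    expect_equal(cm$n_contact, rowSums(cm$fractions))
  }
})

test_that("residue grouping partitions the 20 letters and normalizes by abundance", {
  g <- residue_groups()
  expect_identical(sort(names(g)), sort(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]))

  ## uniform contact fractions: every group cell equal after normalization
  N <- 140
  u <- matrix(0.2, N, N); diag(u) <- 0
  band <- abs(row(u) - col(u)) <= 3
  u[band] <- 0
  cm <- structure(list(fractions = u, exclusion = 3L,
                       sequence = alphasyn_sequence()), class = "contact_map")
  gm <- grouped_contact_map(cm)
  expect_true(all(abs(gm - 0.2) < 1e-12))

  ## single planted K-Y contact shows up only in the cationic x aromatic cell
  seqs <- alphasyn_sequence()
  res <- strsplit(seqs, "")[[1]]
  iK <- which(res == "K")[1]; iY <- which(res == "Y")[1]
  z <- matrix(0, N, N); z[iK, iY] <- z[iY, iK] <- 1
  cm2 <- structure(list(fractions = z, exclusion = 3L, sequence = seqs),
                   class = "contact_map")
  gm2 <- grouped_contact_map(cm2)
  expect_gt(gm2["cationic", "aromatic"], 0)
  gm2["cationic", "aromatic"] <- gm2["aromatic", "cationic"] <- 0
  expect_true(all(gm2 == 0))
  expect_error(grouped_contact_map(cm2, strrep("X", N)), "unknown residue")
})

test_that("shape metrics hit the rod and sphere limits", {
  rod <- array(0, c(30, 3, 1)); rod[, 1, 1] <- seq(0, 11, length.out = 30)
  sm_rod <- shape_metrics(as_ensemble(rod))
  expect_equal(unname(sm_rod$asphericity["mean"]), 1, tolerance = 1e-12)
  expect_equal(unname(sm_rod$shape["mean"]), 2, tolerance = 1e-12)

  two <- array(0, c(2, 3, 1)); two[2, 1, 1] <- 3
  expect_equal(unname(shape_metrics(as_ensemble(two))$Rg["mean"]), 1.5)

  set.seed(16)
  u <- matrix(rnorm(3000 * 3), ncol = 3)
  sphere <- array(u / sqrt(rowSums(u^2)), dim = c(3000, 3, 1))
  sm_sph <- shape_metrics(as_ensemble(sphere))
  expect_lt(unname(sm_sph$asphericity["mean"]), 0.01)
})

test_that("stiffer chains stretch label distances at fixed separation", {
  d <- vapply(c(0, 2, 6), function(k) {
    m <- chain_model(strrep("G", 30), k_bend = k, attraction = 0,
                     termini_charged = FALSE)
    label_distance(sample_chain(m, n_frames = 600, seed = 17), 1, 30)
  }, numeric(1))
  expect_true(all(diff(d) > 0))
})

test_that("low Monte Carlo acceptance triggers a warning", {
  ## a hard core just under the two-bond span forces near-straight bends,
  ## so almost every pivot is rejected
  m <- chain_model("GGGG", bead_diameter = 0.7599, k_bend = 0,
                   attraction = 0, termini_charged = FALSE)
  expect_warning(sample_chain(m, n_frames = 50, seed = 18, burnin = 500),
                 "acceptance")
})

test_that("hard-core chain end-to-end distances follow the SAW distance law", {
  ## links the sampler to the analytic distance distribution: the
  ## excluded-volume chain's end-to-end histogram should be consistent
  ## with the SAW density at a fitted exponent
  N <- 60
  m <- chain_model(strrep("G", N), k_bend = 0, attraction = 0,
                   termini_charged = FALSE)
  e <- sample_chain(m, n_frames = 4000, seed = 19, stride = N)
  r <- sqrt(colSums((e$frames[1, , ] - e$frames[N, , ])^2))
  R <- sqrt(mean(r^2))
  ks_at <- function(nu) {
    p <- saw_params(nu, R = R)
    suppressWarnings(ks.test(r, function(q) saw_cdf(q, p))$statistic)
  }
  nus <- seq(0.50, 0.70, by = 0.005)
  nu_fit <- nus[which.min(vapply(nus, ks_at, numeric(1)))]
  expect_gt(nu_fit, 0.5); expect_lt(nu_fit, 0.7)
  p_fit <- saw_params(nu_fit, R = R)
  ks <- suppressWarnings(ks.test(r, function(q) saw_cdf(q, p_fit)))
  expect_gt(ks$p.value, 0.01)
})
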