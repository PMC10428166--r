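#' Ground truth for synthetic smFRET experiments
#'
#' Bundles every parameter the photon-stream generator needs, so each
#' synthetic dataset carries its own ground truth. Chain defaults are the
#' reference values for alpha-synuclein under physiological salt
#' (`nu = 0.57`, `lp = 0.49` nm, bond 0.38 nm, +4 dye-padding residues);
#' instrument defaults describe a quiet pulsed confocal setup (donor
#' lifetime 4.0 ns, 50 ns pulse period, 2 ns IRF offset, 0.2 counts/ms
#' background per channel, 5% donor-to-acceptor leakage). Burst sizes are
#' log-normal (median 150 photons, log-sd 0.4) truncated to 60-950 so
#' accepted bursts populate the 50-1000 selection window; burst arrivals
#' are Poisson at `burst_rate_hz` with at least one empty bin between
#' bursts, so each molecule transit spans a single 1 ms bin.
#'
#' @param nu_true Flory exponent of the simulated chain.
#' @param lp_true persistence length (nm).
#' @param R0 Foerster radius (nm).
#' @param tauD,tauA donor / acceptor fluorescence lifetimes (ns).
#' @param burst_size_meanlog,burst_size_sdlog log-normal burst-size
#'   parameters (photons per burst).
#' @param burst_size_range truncation window for burst sizes.
#' @param burst_rate_hz mean burst arrival rate (1/s).
#' @param bg_donor,bg_acceptor background rates (counts/ms).
#' @param alpha_leak donor-to-acceptor leakage fraction.
#' @param gamma_det detection/quantum-yield factor.
#' @param irf_offset instrument-response offset (ns).
#' @param micro_period excitation period (ns).
#' @param donor_only_frac donor-only bursts generated per FRET burst
#'   (acceptor absent or bleached), as a fraction.
#' @param b_bond bond length (nm).
#' @param dye_padding_residues dye/linker contribution (+ residues).
#' @param seed default seed recorded with every output.
#' @return object of class `"ground_truth"`.
#' @export
ground_truth <- function(nu_true = 0.57, lp_true = 0.49, R0 = 6.2,
                         tauD = 4.0, tauA = 4.0,
                         burst_size_meanlog = log(150),
                         burst_size_sdlog = 0.4,
                         burst_size_range = c(60, 950),
                         burst_rate_hz = 50,
                         bg_donor = 0.2, bg_acceptor = 0.2,
                         alpha_leak = 0.05, gamma_det = 1,
                         irf_offset = 2.0, micro_period = 50,
                         donor_only_frac = 0.4,
                         b_bond = peptide_bond_length(),
                         dye_padding_residues = 4L, seed = 1L) {
  gt <- list(nu_true = nu_true, lp_true = lp_true, R0 = R0, tauD = tauD,
             tauA = tauA, burst_size_meanlog = burst_size_meanlog,
             burst_size_sdlog = burst_size_sdlog,
             burst_size_range = burst_size_range,
             burst_rate_hz = burst_rate_hz, bg_donor = bg_donor,
             bg_acceptor = bg_acceptor, alpha_leak = alpha_leak,
             gamma_det = gamma_det, irf_offset = irf_offset,
             micro_period = micro_period, donor_only_frac = donor_only_frac,
             b_bond = b_bond,
             dye_padding_residues = as.integer(dye_padding_residues),
             seed = as.integer(seed))
  stopifnot(all(vapply(gt[c("nu_true", "lp_true", "R0", "tauD", "tauA",
                            "burst_rate_hz", "micro_period")],
                       function(v) is.numeric(v) && v > 0, logical(1L))))
  structure(gt, class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("Ground truth: nu = %.3f, lp = %.3f nm, R0 = %.2f nm, tauD = %.2f ns (seed %d)\n",
              x$nu_true, x$lp_true, x$R0, x$tauD, x$seed))
  invisible(x)
}

#' @rdname ground_truth
#' @param gt a `ground_truth` object.
#' @export
correction_factors_of <- function(gt) {
  correction_factors(bg_donor = gt$bg_donor, bg_acceptor = gt$bg_acceptor,
                     alpha_leak = gt$alpha_leak, gamma_det = gt$gamma_det,
                     irf_offset = gt$irf_offset)
}

#' True distances for a construct set
#'
#' Root-mean-square distances per construct under the ground-truth Flory
#' chain, `R_true = sqrt(2 lp b) (dN + pad)^nu`, optionally scaled
#' per-construct to plant local deviations (values below 1 mimic
#' compacted regions, above 1 extended ones).
#'
#' @param gt a [ground_truth()].
#' @param constructs data.frame with `label_i`, `label_j` (default the 14
#'   alpha-synuclein constructs).
#' @param scale multiplicative deviation per construct (length 1 or
#'   `nrow(constructs)`).
#' @return the construct table with `dN` and `R_true` columns.
#' @export
make_construct_truth <- function(gt, constructs = alphasyn_constructs(),
                                 scale = 1) {
  chain <- flory_chain(lp = gt$lp_true, b_bond = gt$b_bond, nu = gt$nu_true,
                       dye_padding_residues = gt$dye_padding_residues)
  constructs$dN <- constructs$label_j - constructs$label_i
  constructs$R_true <- flory_distance(constructs$dN, chain) * scale
  constructs
}

## quantile lookup table for inverse-CDF sampling in the photon generator
saw_quantile_table <- function(nu, R, m = 4097L) {
  p <- seq(0, 1, length.out = m)
  p[1L] <- 1e-12; p[m] <- 1 - 1e-12
  saw_quantile(p, saw_params(nu, R = R))
}

## place n single-bin events with at least one empty bin between them
draw_burst_bins <- function(n, rate_hz, bin_ms) {
  p <- rate_hz * bin_ms * 1e-3            # bursts per bin
  gaps <- pmax(stats::rgeom(n, p) + 1L, 2L)
  cumsum(gaps)
}

## uniform macro times inside a bin (kept off the bin edges)
macro_in_bin <- function(bin_index, n_per, bin_ms) {
  (rep(bin_index, n_per) + stats::runif(sum(n_per), 0.02, 0.98)) * bin_ms * 1e-3
}

#' Simulate a photon stream for one construct
#'
#' Generates the photon records of `n_bursts` molecule transits at the
#' true distance `R_true`, plus a donor-only population and uniform
#' background. Within a burst every photon samples an independent
#' donor-acceptor distance from the SAW distribution (chain
#' reconfiguration, tens of ns, is fast against the 1 ms transit and slow
#' against the donor lifetime): the photon goes to the acceptor channel
#' with probability `E(r)`, otherwise to the donor channel with micro
#' time `Exp(tauD (1 - E(r)))` plus the IRF offset; donor photons leak to
#' the acceptor channel with probability `alpha_leak`. Donor-only bursts
#' contain donor emission only (plus leakage); background photons arrive
#' uniformly in time with uniform micro times.
#'
#' @param gt a [ground_truth()].
#' @param R_true root-mean-square donor-acceptor distance (nm); `Inf`
#'   gives a no-acceptor stream.
#' @param n_bursts number of FRET bursts.
#' @param seed integer seed.
#' @param n_donor_only donor-only bursts (default
#'   `round(gt$donor_only_frac * n_bursts)`).
#' @return a [photon_records()] table; attribute `ground_truth` records
#'   all parameters, the seed and the planted burst bins.
#' @export
simulate_bursts <- function(gt, R_true, n_bursts, seed = gt$seed,
                            n_donor_only = NULL) {
  stopifnot(inherits(gt, "ground_truth"), n_bursts >= 1)
  if (is.null(n_donor_only)) n_donor_only <- round(gt$donor_only_frac * n_bursts)
  set.seed(seed)
  n_tot <- n_bursts + n_donor_only
  sizes <- pmin(pmax(round(stats::rlnorm(n_tot, gt$burst_size_meanlog,
                                         gt$burst_size_sdlog)),
                     gt$burst_size_range[1L]), gt$burst_size_range[2L])
  is_fret <- sample(rep(c(TRUE, FALSE), c(n_bursts, n_donor_only)))
  bins <- draw_burst_bins(n_tot, gt$burst_rate_hz, 1)

  qtab <- if (is.finite(R_true)) saw_quantile_table(gt$nu_true, R_true)
          else rep(1e9, 8L)  # no acceptor: E(r) = 0 for every photon
  ph_f <- .sim_burst_photons(sizes[is_fret], qtab, gt$R0, gt$tauD, gt$tauA,
                             gt$alpha_leak, gt$irf_offset, gt$micro_period)
  ph_d <- .sim_burst_photons(sizes[!is_fret], rep(1e9, 8L), gt$R0, gt$tauD,
                             gt$tauA, gt$alpha_leak, gt$irf_offset,
                             gt$micro_period)
  bin_of <- c(bins[is_fret][ph_f$burst], bins[!is_fret][ph_d$burst])
  channel <- c(ph_f$channel, ph_d$channel)
  micro <- c(ph_f$micro_time_ns, ph_d$micro_time_ns)
  macro <- (bin_of + stats::runif(length(bin_of), 0.02, 0.98)) * 1e-3

  ## background over the whole trace
  T_ms <- max(bins) + 2
  n_bg <- stats::rpois(2L, c(gt$bg_donor, gt$bg_acceptor) * T_ms)
  macro <- c(macro, stats::runif(sum(n_bg), 0, T_ms * 1e-3))
  channel <- c(channel, rep(c(0L, 1L), n_bg))
  micro <- c(micro, stats::runif(sum(n_bg), 0, gt$micro_period))

  o <- order(macro)
  out <- photon_records(channel = c("donor", "acceptor")[channel[o] + 1L],
                        macro_time_s = macro[o], micro_time_ns = micro[o],
                        micro_period = gt$micro_period)
  attr(out, "ground_truth") <- list(
    gt = gt, R_true = R_true, n_bursts = n_bursts,
    n_donor_only = n_donor_only, seed = seed,
    fret_bins = bins[is_fret], donor_only_bins = bins[!is_fret])
  out
}

#' Simulate a trace with slow-diffusing aggregates and overbright events
#'
#' Adds to a normal single-molecule stream: `n_aggregates` slow-diffusing
#' events spanning 2-3 consecutive bins, each bin inside the photon
#' window (so only the consecutive-bin rule can reject them), and
#' `n_overbright` single bins above the maximum photon threshold. Labels
#' for every planted event are attached for use as ground truth.
#'
#' @inheritParams simulate_bursts
#' @param n_aggregates number of multi-bin aggregate events.
#' @param n_overbright number of single bins above 1000 photons.
#' @return a [photon_records()] table; attribute `ground_truth` gains
#'   `aggregate_bins` and `overbright_bins`.
#' @export
simulate_trace_with_aggregates <- function(gt, R_true, n_bursts,
                                           n_aggregates = 0L,
                                           n_overbright = 0L,
                                           seed = gt$seed) {
  base <- simulate_bursts(gt, R_true, n_bursts, seed = seed)
  truth <- attr(base, "ground_truth")
  last_bin <- max(truth$fret_bins, truth$donor_only_bins, 0) + 5
  extra_macro <- numeric(0); extra_channel <- integer(0); extra_micro <- numeric(0)
  agg_bins <- list(); over_bins <- integer(0)

  place <- function(width) {
    start <- last_bin + 2 + stats::rgeom(1L, 0.2)
    last_bin <<- start + width - 1
    seq(start, length.out = width)
  }
  for (k in seq_len(n_aggregates)) {
    bins_k <- place(sample(2:3, 1L))
    counts <- sample(200:800, length(bins_k), replace = TRUE)
    agg_bins[[k]] <- bins_k
    extra_macro <- c(extra_macro, macro_in_bin(bins_k, counts, 1))
    n_k <- sum(counts)
    extra_channel <- c(extra_channel, stats::rbinom(n_k, 1L, 0.5))
    extra_micro <- c(extra_micro, (gt$irf_offset + stats::rexp(n_k, 1 / gt$tauD)) %% gt$micro_period)
  }
  for (k in seq_len(n_overbright)) {
    bin_k <- place(1L)
    count <- sample(1500:2500, 1L)
    over_bins <- c(over_bins, bin_k)
    extra_macro <- c(extra_macro, macro_in_bin(bin_k, count, 1))
    extra_channel <- c(extra_channel, stats::rbinom(count, 1L, 0.5))
    extra_micro <- c(extra_micro, (gt$irf_offset + stats::rexp(count, 1 / gt$tauD)) %% gt$micro_period)
  }

  macro <- c(base$macro_time_s, extra_macro)
  channel <- c(base$channel, c("donor", "acceptor")[extra_channel + 1L])
  micro <- c(base$micro_time_ns, extra_micro)
  o <- order(macro)
  out <- photon_records(channel = channel[o], macro_time_s = macro[o],
                        micro_time_ns = micro[o],
                        micro_period = gt$micro_period)
  truth$aggregate_bins <- agg_bins
  truth$overbright_bins <- over_bins
  attr(out, "ground_truth") <- truth
  out
}

#' Simulate photon streams for a whole construct set
#'
#' One stream per construct (seeds derived from `seed` by construct
#' index), at the true distances of `truth`.
#'
#' @param gt a [ground_truth()].
#' @param truth a [make_construct_truth()] table.
#' @param n_bursts FRET bursts per construct.
#' @param seed base seed.
#' @return named list of [photon_records()] tables
#'   (`"<label_i>-<label_j>"`).
#' @export
simulate_construct_set <- function(gt, truth = make_construct_truth(gt),
                                   n_bursts = 2000L, seed = gt$seed) {
  streams <- lapply(seq_len(nrow(truth)), function(k)
    simulate_bursts(gt, truth$R_true[k], n_bursts,
                    seed = (seed * 1000L + k) %% .Machine$integer.max))
  names(streams) <- paste0(truth$label_i, "-", truth$label_j)
  streams
}

#' Solvent-perturbation scenarios
#'
#' Region-wise multiplicative distance factors for the three probe
#' constructs (9-42 for the N-terminal region, 56-90 for the central
#' hydrophobic region, 90-140 for the C-terminal region), giving the
#' qualitative response patterns of the three modified solvents: in
#' denaturant (`"urea"`) every region expands; in `"low_salt"` the
#' default scenario expands the C-terminal probe (the region dominated by
#' electrostatic repulsion); in `"methanol"` the N-terminal probe mildly
#' compacts. Factors are configurable.
#'
#' @param gt a [ground_truth()].
#' @param mode `"low_salt"`, `"urea"` or `"methanol"`.
#' @param factors optional length-3 numeric override of the distance
#'   factors for the three probe constructs.
#' @return data.frame `label_i`, `label_j`, `dN`, `R_ref` (physiological),
#'   `factor`, `R_alt` (modified solvent).
#' @export
solvent_scenario <- function(gt, mode = c("low_salt", "urea", "methanol"),
                             factors = NULL) {
  mode <- match.arg(mode)
  probes <- data.frame(label_i = c(9L, 56L, 90L), label_j = c(42L, 90L, 140L))
  defaults <- switch(mode,
                     low_salt = c(1.00, 1.00, 1.10),
                     urea     = c(1.12, 1.12, 1.12),
                     methanol = c(0.93, 1.00, 1.00))
  if (is.null(factors)) factors <- defaults
  if (length(factors) != 3L) stop("`factors` must have length 3", call. = FALSE)
  truth <- make_construct_truth(gt, probes)
  data.frame(label_i = probes$label_i, label_j = probes$label_j,
             dN = truth$dN, R_ref = truth$R_true, factor = factors,
             R_alt = truth$R_true * factors, mode = mode)
}
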