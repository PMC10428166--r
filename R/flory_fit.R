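#' Fit the global polymer scaling model to smFRET construct observables
#'
#' The package's central estimator. Given per-construct center observables
#' (FRET efficiency and relative donor lifetime), `flory_fit()`:
#'
#' 1. finds the Flory exponent `nu*` that makes the intensity-based and
#'    lifetime-based distances agree globally ([optimize_nu()]);
#' 2. converts the observables into distances at `nu*`
#'    ([infer_distances()]), excluding constructs with
#'    `E_center >= E_max`;
#' 3. fits the persistence length of the Flory chain model
#'    `R = sqrt(2 lp b) (dN + pad)^nu*` to the pooled distances
#'    ([fit_persistence_length()]);
#' 4. computes the per-construct deviation map from the global fit
#'    ([deviation_map()]).
#'
#' @param data a [construct_obs()] table, or a data.frame with columns
#'   `label_i`, `label_j`, `E_center`, `tau_center`.
#' @param fp a [fret_params()] object.
#' @param nu_range,step search range and grid step for the Flory exponent.
#' @param E_max efficiency inclusion threshold (default 0.9).
#' @param b_bond bond length (nm).
#' @param dye_padding_residues dye/linker contribution in residues.
#' @return object of class `"flory_fit"` with components `nu_star`, `lp`,
#'   `chain` (the fitted [flory_chain()]), `scan` (the objective curve),
#'   `lp_fit`, `observations` (with `R_int`, `R_tau`, `included`,
#'   `dR`), `devmap` and `fp`.
#' @examples
#' \donttest{
#' gt <- ground_truth(nu_true = 0.6, lp_true = 0.5)
#' truth <- make_construct_truth(gt)
#' obs <- construct_obs(truth$label_i, truth$label_j,
#'   E_center = vapply(truth$R_true, function(R)
#'     mean_efficiency(saw_params(gt$nu_true, R = R)), numeric(1)),
#'   tau_center = vapply(truth$R_true, function(R)
#'     lifetime_ratio(saw_params(gt$nu_true, R = R)), numeric(1)))
#' fit <- flory_fit(obs)
#' coef(fit)   # recovers nu = 0.6, lp = 0.5
#' }
#' @export
flory_fit <- function(data, fp = fret_params(), nu_range = c(0.3, 0.7),
                      step = 0.005, E_max = 0.9,
                      b_bond = peptide_bond_length(),
                      dye_padding_residues = 4L) {
  if (!inherits(data, "construct_obs"))
    data <- construct_obs(data$label_i, data$label_j, data$E_center,
                          data$tau_center)
  scan <- optimize_nu(data, fp, range = nu_range, step = step, E_max = E_max)
  obs <- infer_distances(data, scan$nu_star, fp, E_max = E_max)
  lpf <- fit_persistence_length(obs, scan$nu_star, b_bond = b_bond,
                                dye_padding_residues = dye_padding_residues)
  obs$dR <- (obs$R_int + obs$R_tau) / 2 - flory_distance(obs$dN, lpf$chain)
  devmap <- tryCatch(deviation_map(obs, lpf$chain),
                     error = function(e) NULL)  # < 3 usable points
  structure(list(nu_star = scan$nu_star, lp = lpf$lp, chain = lpf$chain,
                 scan = scan, lp_fit = lpf, observations = obs,
                 devmap = devmap, fp = fp, E_max = E_max,
                 call = match.call()),
            class = "flory_fit")
}

#' @export
print.flory_fit <- function(x, ...) {
  cat("Global polymer scaling fit (smFRET dual-observable)\n")
  cat(sprintf("  Flory exponent     nu = %.3f\n", x$nu_star))
  cat(sprintf("  persistence length lp = %.3f nm (se %.3f)\n",
              x$lp, x$lp_fit$lp_se))
  cat(sprintf("  constructs: %d used of %d (E < %.2f)\n",
              sum(x$observations$included), nrow(x$observations), x$E_max))
  invisible(x)
}

#' @export
summary.flory_fit <- function(object, ...) {
  obs <- object$observations
  structure(list(nu_star = object$nu_star, lp = object$lp,
                 lp_se = object$lp_fit$lp_se, dR_min = object$scan$dR_min,
                 table = obs, fp = object$fp, E_max = object$E_max),
            class = "summary.flory_fit")
}

#' @export
print.summary.flory_fit <- function(x, ...) {
  cat(sprintf("nu* = %.3f;  lp = %.3f nm (se %.3f);  min <|R_int - R_tau|> = %.3f nm\n",
              x$nu_star, x$lp, x$lp_se, x$dR_min))
  cat(sprintf("FRET pair: R0 = %.2f nm; inclusion: E_center < %.2f\n\n",
              x$fp$R0, x$E_max))
  tab <- x$table
  tab$E_center <- round(tab$E_center, 3); tab$tau_center <- round(tab$tau_center, 3)
  for (cl in c("R_int", "R_tau", "dR")) tab[[cl]] <- round(tab[[cl]], 2)
  print.data.frame(tab, row.names = FALSE)
  invisible(x)
}

#' @export
coef.flory_fit <- function(object, ...) {
  c(nu = object$nu_star, lp = object$lp)
}

#' Predicted root-mean-square distances from a scaling fit
#'
#' @param object a [flory_fit()].
#' @param newdata residue separations `dN` (numeric vector) or a
#'   data.frame with a `dN` column; defaults to the fitted constructs.
#' @param ... unused.
#' @return distances in nm.
#' @export
predict.flory_fit <- function(object, newdata = NULL, ...) {
  dN <- if (is.null(newdata)) object$observations$dN
        else if (is.data.frame(newdata)) newdata$dN else newdata
  flory_distance(dN, object$chain)
}

#' @export
residuals.flory_fit <- function(object, ...) {
  stats::setNames(object$observations$dR,
                  paste0(object$observations$label_i, "-",
                         object$observations$label_j))
}

#' Diagnostic plots for a scaling fit
#'
#' `which = 1`: normalized objective versus `nu` (the exponent scan);
#' `which = 2`: inferred distances versus sequence separation with the
#' fitted Flory curve; `which = 3`: the deviation-map surface.
#'
#' @param x a [flory_fit()].
#' @param which subset of `1:3`.
#' @param ... passed to the underlying plotting functions.
#' @export
plot.flory_fit <- function(x, which = 1:2, ...) {
  if (1L %in% which) {
    oc <- x$scan$objective_curve
    graphics::plot(oc$nu, oc$dR_norm, type = "l", xlab = "Flory exponent nu",
                   ylab = expression(Delta * R / Delta * R[nu == 3 / 5]), ...)
    graphics::abline(v = x$nu_star, lty = 2, col = "grey40")
  }
  if (2L %in% which) {
    obs <- x$observations[x$observations$included, ]
    rng <- range(obs$R_int, obs$R_tau)
    graphics::plot(obs$dN, obs$R_int, pch = 16, col = "firebrick",
                   ylim = rng, xlab = expression(Delta * N), ylab = "R (nm)", ...)
    graphics::points(obs$dN, obs$R_tau, pch = 17, col = "steelblue")
    dd <- seq(min(obs$dN), max(obs$dN), length.out = 200)
    graphics::lines(dd, flory_distance(dd, x$chain))
    graphics::legend("topleft", legend = c("R_int", "R_tau", "Flory fit"),
                     pch = c(16, 17, NA), lty = c(NA, NA, 1),
                     col = c("firebrick", "steelblue", "black"), bty = "n")
  }
  if (3L %in% which && !is.null(x$devmap)) {
    s <- x$devmap$surface
    graphics::image(s$i, s$j, s$z, xlab = "label i", ylab = "label j",
                    col = grDevices::hcl.colors(64, "Blue-Red 3"), ...)
    graphics::points(x$devmap$points$label_i, x$devmap$points$label_j, pch = 4)
  }
  invisible(x)
}

#' Simulate synthetic observation tables from a fitted model
#'
#' Runs the photon-stream generator and the burst pipeline at the fitted
#' `(nu, lp)` for the fitted constructs, returning one
#' [construct_obs()] table per replicate — a parametric-bootstrap
#' primitive.
#'
#' @param object a [flory_fit()].
#' @param nsim number of replicates.
#' @param seed integer seed.
#' @param n_bursts FRET bursts per construct and replicate.
#' @param ... unused.
#' @return list of `nsim` [construct_obs()] tables.
#' @export
simulate.flory_fit <- function(object, nsim = 1, seed = 1L,
                               n_bursts = 500L, ...) {
  gt <- ground_truth(nu_true = object$nu_star, lp_true = object$lp,
                     R0 = object$fp$R0, tauD = object$fp$tauD,
                     b_bond = object$chain$b_bond,
                     dye_padding_residues = object$chain$dye_padding_residues,
                     seed = as.integer(seed))
  constructs <- object$observations[, c("label_i", "label_j")]
  truth <- make_construct_truth(gt, constructs)
  lapply(seq_len(nsim), function(s) {
    streams <- simulate_construct_set(gt, truth, n_bursts = n_bursts,
                                      seed = seed + 7919L * (s - 1L))
    centers <- lapply(streams, process_photons, cf = correction_factors_of(gt))
    construct_obs(truth$label_i, truth$label_j,
                  E_center = vapply(centers, `[[`, numeric(1L), "E_center"),
                  tau_center = vapply(centers, `[[`, numeric(1L), "tau_ratio_center"))
  })
}
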