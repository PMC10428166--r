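#' Labeled construct definitions for alpha-synuclein
#'
#' The 14 double-labeled constructs used to probe intramolecular distances
#' across the 140-residue chain, identified by their two label positions
#' (1-based residue indices). `dN` is the sequence separation `j - i`.
#'
#' @return data.frame with columns `label_i`, `label_j`, `dN`.
#' @export
alphasyn_constructs <- function() {
  i <- c(9, 9, 9, 9, 9, 9, 18, 18, 42, 42, 56, 56, 90, 130)
  j <- c(18, 27, 42, 69, 90, 140, 90, 124, 85, 90, 69, 90, 140, 140)
  data.frame(label_i = i, label_j = j, dN = j - i)
}

#' Construct observation table
#'
#' Validates a per-construct table of center observables: label positions
#' on the chain, center FRET efficiency and center relative donor
#' lifetime. Distances `R_int`/`R_tau` are added by [infer_distances()].
#'
#' @param label_i,label_j 1-based label positions, `i < j`.
#' @param E_center center FRET efficiencies, in (0, 1).
#' @param tau_center center relative donor lifetimes `tau_DA/tau_D`, in
#'   (0, 1).
#' @param n_residues chain length (default 140).
#' @return data.frame of class `"construct_obs"`.
#' @export
construct_obs <- function(label_i, label_j, E_center, tau_center,
                          n_residues = 140L) {
  if (any(label_i < 1L) || any(label_j > n_residues) || any(label_i >= label_j))
    stop("label positions must satisfy 1 <= i < j <= ", n_residues, call. = FALSE)
  if (any(!is.finite(E_center)) || any(E_center <= 0 | E_center >= 1))
    stop("`E_center` must lie strictly inside (0, 1)", call. = FALSE)
  if (any(!is.finite(tau_center)))
    stop("`tau_center` must be finite", call. = FALSE)
  if (any(tau_center <= 0 | tau_center >= 1))
    warning("tau_center outside (0, 1) for ",
            sum(tau_center <= 0 | tau_center >= 1),
            " construct(s); they will be excluded from distance inference",
            call. = FALSE)
  out <- data.frame(label_i = as.integer(label_i), label_j = as.integer(label_j),
                    dN = as.integer(label_j - label_i),
                    E_center = E_center, tau_center = tau_center)
  class(out) <- c("construct_obs", "data.frame")
  out
}

## ---- fast forward curves -------------------------------------------------
## Fixed-node Gauss-Legendre quadrature of the SAW-averaged observables on a
## grid of R values; vectorized, used by the nu optimization where the
## adaptive-quadrature path would be needlessly slow. Accuracy is checked
## against the adaptive path in the tests.
saw_forward_curves <- function(nu, fp, R_grid, n_nodes = 256L) {
  ex <- reduced_exponents(nu)
  ab <- normalize_saw(nu)
  gl <- pracma::gaussLegendre(n_nodes, 0, 10)
  x <- gl$x; w <- gl$w
  px <- ab["a"] * x^(2 + ex$g) * exp(-ab["b_norm"] * x^ex$delta)
  wp <- w * px
  ## E(x R) for all (node, R) pairs
  Emat <- 1 / (1 + (outer(x, R_grid) / fp$R0)^6)
  mE <- as.numeric(crossprod(Emat, wp))
  mE2 <- as.numeric(crossprod(Emat^2, wp))
  vE <- pmax(mE2 - mE^2, 0)
  data.frame(R = R_grid, mean_E = mE, var_E = vE,
             tau_ratio = (1 - mE) + vE / (1 - mE))
}

## monotone-spline inversion of a forward curve; enforces a strictly
## increasing abscissa (saturated tails can produce numerical ties)
invert_on_curve <- function(curve, col, values) {
  o <- order(curve[[col]])
  x <- curve[[col]][o]; y <- curve$R[o]
  keep <- c(TRUE, diff(x) > 0)
  f <- stats::splinefun(x[keep], y[keep], method = "hyman")
  f(values)
}

#' Convert center observables into distances
#'
#' Applies both inversions per construct: `R_int` from the center
#' efficiency through the SAW-averaged intensity map and `R_tau` from the
#' center lifetime ratio through the lifetime map, both at the assumed
#' Flory exponent `nu`. Constructs with `E_center >= E_max` (default 0.9)
#' are flagged `included = FALSE`: at such high transfer the donor photon
#' count is inherently low and the center efficiency unreliable.
#'
#' @param obs a [construct_obs()] table.
#' @param nu assumed Flory exponent.
#' @param fp a [fret_params()] object.
#' @param E_max inclusion threshold on the center efficiency.
#' @return `obs` with columns `R_int`, `R_tau`, `included` added
#'   (constructs whose `tau_center` falls outside (0, 1) get `NA` for
#'   `R_tau` and are excluded).
#' @export
infer_distances <- function(obs, nu, fp = fret_params(), E_max = 0.9) {
  if (!inherits(obs, "construct_obs")) stop("`obs` must be a construct_obs table", call. = FALSE)
  tau_ok <- obs$tau_center > 0 & obs$tau_center < 1
  obs$R_int <- vapply(obs$E_center, invert_intensity, numeric(1L), nu = nu, fp = fp)
  obs$R_tau <- NA_real_
  obs$R_tau[tau_ok] <- vapply(obs$tau_center[tau_ok], invert_lifetime,
                              numeric(1L), nu = nu, fp = fp)
  obs$included <- obs$E_center < E_max & tau_ok
  obs
}

#' Global Flory-exponent optimization
#'
#' The intensity- and lifetime-based distances of a construct must agree
#' when the assumed Flory exponent matches the chain's true scaling
#' behaviour, because both observables report on the same underlying
#' distance distribution but depend on it differently. `optimize_nu()`
#' therefore scans `nu` over a grid (step 0.005), computes for each
#' construct with `E_center < E_max` the two distances, and minimizes the
#' mean absolute difference `<|R_int - R_tau|>`. The objective is
#' normalized by its value at the good-solvent exponent `nu = 3/5`; the
#' minimizing grid point is refined by a parabolic fit through its
#' neighbours.
#'
#' @inheritParams infer_distances
#' @param range search interval for `nu`.
#' @param step grid step.
#' @return list of class `"nu_scan"`: `nu_star`, `objective_curve`
#'   (data.frame of `nu` and normalized objective `dR_norm`), and the
#'   unnormalized minimum `dR_min` (nm).
#' @export
optimize_nu <- function(obs, fp = fret_params(), range = c(0.3, 0.7),
                        step = 0.005, E_max = 0.9) {
  if (!inherits(obs, "construct_obs")) stop("`obs` must be a construct_obs table", call. = FALSE)
  use <- obs$E_center < E_max & obs$tau_center > 0 & obs$tau_center < 1
  if (sum(use) < 3L)
    stop("need at least 3 constructs with E_center < ", E_max, call. = FALSE)
  E <- obs$E_center[use]; tr <- obs$tau_center[use]
  nus <- seq(range[1L], range[2L], by = step)
  R_grid <- exp(seq(log(0.05 * fp$R0), log(10 * fp$R0), length.out = 160L))
  objective <- vapply(nus, function(nu) {
    crv <- saw_forward_curves(nu, fp, R_grid)
    Rint <- invert_on_curve(crv, "mean_E", E)
    Rtau <- invert_on_curve(crv, "tau_ratio", tr)
    mean(abs(Rint - Rtau))
  }, numeric(1L))
  ref <- objective[which.min(abs(nus - 3 / 5))]
  if (abs(nus[which.min(abs(nus - 3 / 5))] - 3 / 5) > step / 2)
    ref <- stats::approx(nus, objective, xout = 3 / 5)$y
  if (diff(range(objective)) < 1e-10)
    warning("objective is flat over the nu range", call. = FALSE)
  k <- which.min(objective)
  nu_star <- nus[k]
  if (k > 1L && k < length(nus)) {  # parabolic refinement
    y1 <- objective[k - 1L]; y2 <- objective[k]; y3 <- objective[k + 1L]
    denom <- y1 - 2 * y2 + y3
    if (denom > 0) nu_star <- nus[k] + step * 0.5 * (y1 - y3) / denom
  }
  structure(list(nu_star = nu_star,
                 objective_curve = data.frame(nu = nus, dR_norm = objective / ref),
                 dR_min = objective[k], n_used = sum(use)),
            class = "nu_scan")
}

#' @export
print.nu_scan <- function(x, ...) {
  cat(sprintf("Flory exponent scan: nu* = %.4f (min <|R_int - R_tau|> = %.4f nm, %d constructs)\n",
              x$nu_star, x$dR_min, x$n_used))
  invisible(x)
}

#' Persistence length from the Flory chain model
#'
#' Nonlinear least-squares fit of the Flory model
#' `R = sqrt(2 lp b) (dN + pad)^nu` to the pooled intensity- and
#' lifetime-based distances of the included constructs, with `nu` fixed at
#' the globally optimal exponent and the bond length at 0.38 nm. The only
#' free parameter is the persistence length `lp`; fitting uses the
#' Levenberg-Marquardt algorithm.
#'
#' @param obs a [infer_distances()] table (distances and `included` set).
#' @param nu_star Flory exponent to fix in the model.
#' @param b_bond bond length (nm).
#' @param dye_padding_residues dye/linker contribution in effective
#'   residues (default +4).
#' @return list of class `"lp_fit"`: `lp` (nm), its standard error, the
#'   fitted [flory_chain()], residuals, and the pooled data.
#' @export
fit_persistence_length <- function(obs, nu_star, b_bond = peptide_bond_length(),
                                   dye_padding_residues = 4L) {
  if (is.null(obs$R_int) || is.null(obs$R_tau))
    stop("run infer_distances() first", call. = FALSE)
  use <- if (is.null(obs$included)) rep(TRUE, nrow(obs)) else obs$included
  pooled <- data.frame(dN = rep(obs$dN[use], 2L),
                       R = c(obs$R_int[use], obs$R_tau[use]),
                       source = rep(c("intensity", "lifetime"), each = sum(use)))
  if (nrow(pooled) < 2L || length(unique(pooled$dN)) < 2L)
    stop("persistence-length fit is underdetermined: need >= 2 distinct separations",
         call. = FALSE)
  Neff <- pooled$dN + dye_padding_residues
  fit <- minpack.lm::nlsLM(R ~ sqrt(2 * lp * b_bond) * Neff^nu_star,
                           data = data.frame(R = pooled$R, Neff = Neff),
                           start = list(lp = 0.5),
                           lower = 1e-4, upper = 100,
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  lp <- unname(stats::coef(fit)["lp"])
  chain <- flory_chain(lp = lp, b_bond = b_bond, nu = nu_star,
                       dye_padding_residues = dye_padding_residues)
  structure(list(lp = lp, lp_se = summary(fit)$coefficients["lp", "Std. Error"],
                 chain = chain, residuals = stats::residuals(fit),
                 pooled = pooled),
            class = "lp_fit")
}

#' @export
print.lp_fit <- function(x, ...) {
  cat(sprintf("Persistence length: lp = %.3f nm (se %.3f) at nu = %.3f\n",
              x$lp, x$lp_se, x$chain$nu))
  invisible(x)
}

#' Per-construct deviation from the global fit
#'
#' `dR = mean(R_int, R_tau) - R_model(dN)`: positive where a chain segment
#' is more extended than the global Flory fit predicts, negative where it
#' is more compact. The scattered per-construct values at their
#' `(label_i, label_j)` positions are interpolated onto a regular grid by
#' piecewise-linear (barycentric) interpolation on a Delaunay
#' triangulation; grid nodes outside the convex hull of the data are `NA`.
#' (Natural-neighbour interpolation is an equivalent display alternative;
#' the interpolant is a visual aid only and passes through the data
#' either way.)
#'
#' @param obs a [infer_distances()] table.
#' @param chain the globally fitted [flory_chain()].
#' @param grid_n interpolation grid resolution per axis.
#' @return list of class `"deviation_map"`: `points` (data.frame
#'   `label_i`, `label_j`, `dR`), `surface` (`i`, `j`, matrix `z`), and
#'   `method` metadata.
#' @export
deviation_map <- function(obs, chain, grid_n = 61L) {
  if (is.null(obs$R_int) || is.null(obs$R_tau))
    stop("run infer_distances() first", call. = FALSE)
  use <- if (is.null(obs$included)) rep(TRUE, nrow(obs)) else obs$included
  pts <- data.frame(label_i = obs$label_i[use], label_j = obs$label_j[use],
                    dR = (obs$R_int[use] + obs$R_tau[use]) / 2 -
                      flory_distance(obs$dN[use], chain))
  gi <- seq(min(pts$label_i), max(pts$label_i), length.out = grid_n)
  gj <- seq(min(pts$label_j), max(pts$label_j), length.out = grid_n)
  q <- expand.grid(i = gi, j = gj)
  z <- matrix(barycentric_interp(pts$label_i, pts$label_j, pts$dR, q$i, q$j),
              nrow = grid_n)
  structure(list(points = pts, surface = list(i = gi, j = gj, z = z),
                 method = "barycentric linear on Delaunay triangulation (natural-neighbour alternative noted)"),
            class = "deviation_map")
}

#' Solvent-perturbation efficiency differences
#'
#' Per-construct difference `dE = E_ref - E_alt` between the center
#' efficiencies measured in the reference (physiological salt) condition
#' and a modified solvent. Chain expansion lowers the transfer efficiency,
#' so positive values indicate expansion and negative values compaction.
#'
#' @param ref,alt [construct_obs()] tables for the two conditions; the
#'   constructs must match.
#' @return data.frame `label_i`, `label_j`, `dE`.
#' @export
solvent_delta <- function(ref, alt) {
  key_r <- paste(ref$label_i, ref$label_j)
  key_a <- paste(alt$label_i, alt$label_j)
  if (nrow(ref) != nrow(alt) || !setequal(key_r, key_a) || anyDuplicated(key_r))
    stop("constructs of the two conditions do not match", call. = FALSE)
  m <- match(key_r, key_a)
  data.frame(label_i = ref$label_i, label_j = ref$label_j,
             dE = ref$E_center - alt$E_center[m])
}
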