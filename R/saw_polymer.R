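#' Reduced exponents of the self-avoiding-walk distance distribution
#'
#' The end-to-end distance density of a self-avoiding chain is governed by
#' two exponents derived from the Flory scaling exponent `nu`:
#' `g = (gamma - 1) / nu` controls the small-distance power law and
#' `delta = 1 / (1 - nu)` the stretched-exponential decay. `gamma` is the
#' universal susceptibility exponent, 1.1615 for a three-dimensional
#' self-avoiding walk.
#'
#' @param nu Flory scaling exponent, strictly inside (0, 1).
#' @param gamma universal exponent (default 1.1615).
#' @return named list with elements `g` and `delta`.
#' @examples
#' reduced_exponents(0.5)   # g = 0.323, delta = 2
#' @export
reduced_exponents <- function(nu, gamma = saw_gamma()) {
  if (!is.numeric(nu) || length(nu) != 1L || !is.finite(nu) || nu <= 0 || nu >= 1)
    stop("`nu` must be a single number in (0, 1)", call. = FALSE)
  list(g = (gamma - 1) / nu, delta = 1 / (1 - nu))
}

#' @rdname saw_constants
#' @export
saw_gamma <- function() 1.1615

#' Constants of the chain models
#'
#' `saw_gamma()` returns the universal exponent gamma = 1.1615 used
#' throughout; `peptide_bond_length()` the 0.38 nm virtual bond between
#' consecutive residues; `dye_linker_offset()` the dye correction applied to
#' simulated label-pair distances: each dye center sits about two bond
#' lengths (0.76 nm) from the attachment C-alpha, and under good-solvent
#' statistics the two dye-peptide bonds add `0.76 * 2^(3/5) = 1.15` nm to
#' the inter-label distance.
#'
#' @param mode `"per_dye"` for the single-dye 0.76 nm span, `"combined"`
#'   for the 1.15 nm two-dye correction.
#' @return a single number (nm for the distances).
#' @name saw_constants
#' @export
peptide_bond_length <- function() 0.38

#' @rdname saw_constants
#' @export
dye_linker_offset <- function(mode = c("combined", "per_dye")) {
  mode <- match.arg(mode)
  per_dye <- 2 * peptide_bond_length()
  if (mode == "per_dye") per_dye else per_dye * 2^(3 / 5)
}

#' Normalization constants of the SAW distance distribution
#'
#' In reduced units `x = r / R` the self-avoiding-walk density reads
#' `P(x) = a * x^(2 + g) * exp(-b * x^delta)`. The constants `a` and `b`
#' are fixed by the two constraints `integral(P) = 1` and
#' `integral(x^2 P) = 1` (unit second moment, i.e. `R` is the
#' root-mean-square end-to-end distance). Working in reduced units makes
#' both constants independent of `R`.
#'
#' The closed form follows from moments of the generalized gamma
#' distribution: `b = [G((5+g)/delta) / G((3+g)/delta)]^(delta/2)` and
#' `a = delta * b^((3+g)/delta) / G((3+g)/delta)` with `G` the gamma
#' function. `method = "quadrature"` instead solves the two constraints
#' numerically and is retained as an independent cross-check.
#'
#' @inheritParams reduced_exponents
#' @param method `"gamma"` (closed form, default) or `"quadrature"`.
#' @return named numeric vector `c(a = , b_norm = )`.
#' @examples
#' normalize_saw(0.57)  # a close to 4.006, b close to 1.352
#' @export
normalize_saw <- function(nu, gamma = saw_gamma(),
                          method = c("gamma", "quadrature")) {
  method <- match.arg(method)
  ex <- reduced_exponents(nu, gamma)
  g <- ex$g; delta <- ex$delta
  if (method == "gamma") {
    b <- (gamma(((5 + g) / delta)) / gamma((3 + g) / delta))^(delta / 2)
    a <- delta * b^((3 + g) / delta) / gamma((3 + g) / delta)
    return(c(a = a, b_norm = b))
  }
  ## quadrature route: solve m0(b) * x2(b) constraint for b, then a from m0.
  ## m0(b) = int x^(2+g) exp(-b x^delta), m2(b) = int x^(4+g) exp(-b x^delta);
  ## unit second moment requires m2/m0 = 1.
  m <- function(b, p) {
    stats::integrate(function(x) x^p * exp(-b * x^delta), 0, Inf,
                     rel.tol = 1e-12, abs.tol = 1e-300)$value
  }
  f <- function(b) m(b, 4 + g) / m(b, 2 + g) - 1
  sol <- tryCatch(stats::uniroot(f, c(1e-3, 1e3), tol = 1e-12),
                  error = function(e)
                    stop("quadrature normalization failed to bracket b: ",
                         conditionMessage(e), call. = FALSE))
  b <- sol$root
  a <- 1 / m(b, 2 + g)
  c(a = a, b_norm = b)
}

#' Parameter set of the SAW distance distribution
#'
#' Bundles the Flory exponent, the derived exponents, the normalization
#' constants and the root-mean-square end-to-end distance `R` into a
#' validated parameter object used by `saw_pdf()` and the FRET forward
#' model.
#'
#' @inheritParams reduced_exponents
#' @param R root-mean-square end-to-end distance in nm.
#' @return object of class `"saw_params"`.
#' @examples
#' p <- saw_params(0.57, R = 5.5)
#' p$a; p$b_norm
#' @export
saw_params <- function(nu, R, gamma = saw_gamma()) {
  if (!is.numeric(R) || length(R) != 1L || !is.finite(R) || R <= 0)
    stop("`R` must be a single positive number (nm)", call. = FALSE)
  ex <- reduced_exponents(nu, gamma)
  ab <- normalize_saw(nu, gamma)
  structure(list(nu = nu, gamma = gamma, g = ex$g, delta = ex$delta,
                 a = unname(ab["a"]), b_norm = unname(ab["b_norm"]), R = R),
            class = "saw_params")
}

#' @export
print.saw_params <- function(x, ...) {
  cat("SAW end-to-end distance distribution\n")
  cat(sprintf("  nu = %.4f  (g = %.5f, delta = %.5f, gamma = %.4f)\n",
              x$nu, x$g, x$delta, x$gamma))
  cat(sprintf("  normalization a = %.4f, b = %.4f;  R = %.3f nm\n",
              x$a, x$b_norm, x$R))
  invisible(x)
}

is_saw_params <- function(x) inherits(x, "saw_params")

#' SAW end-to-end distance density
#'
#' Density of the donor-acceptor distance for a self-avoiding chain:
#' `P(r) = (a / R) * (r / R)^(2 + g) * exp(-b * (r / R)^delta)`.
#' Vanishes at zero distance and decays as a stretched exponential at large `r`;
#' normalized so that the distribution integrates to one and has second
#' moment `R^2`.
#'
#' @param r distance(s) in nm, non-negative.
#' @param params a [saw_params()] object.
#' @return density values (1/nm), same length as `r`.
#' @export
saw_pdf <- function(r, params) {
  if (!is_saw_params(params)) stop("`params` must be a saw_params object", call. = FALSE)
  if (any(r < 0)) stop("`r` must be non-negative", call. = FALSE)
  x <- r / params$R
  params$a / params$R * x^(2 + params$g) * exp(-params$b_norm * x^params$delta)
}

#' @rdname saw_pdf
#' @details `saw_cdf()` evaluates the cumulative distribution by the
#'   regularized incomplete gamma function (the distribution is a
#'   generalized gamma in `x = r/R`); `saw_quantile()` inverts it
#'   numerically and `saw_sample()` draws by inverse-CDF sampling.
#' @export
saw_cdf <- function(r, params) {
  if (!is_saw_params(params)) stop("`params` must be a saw_params object", call. = FALSE)
  x <- pmax(r / params$R, 0)
  shape <- (3 + params$g) / params$delta
  stats::pgamma(params$b_norm * x^params$delta, shape = shape)
}

#' @rdname saw_pdf
#' @param p probabilities in `[0, 1]`.
#' @export
saw_quantile <- function(p, params) {
  if (!is_saw_params(params)) stop("`params` must be a saw_params object", call. = FALSE)
  shape <- (3 + params$g) / params$delta
  y <- stats::qgamma(p, shape = shape)
  params$R * (y / params$b_norm)^(1 / params$delta)
}

#' @rdname saw_pdf
#' @param n number of draws.
#' @export
saw_sample <- function(n, params) {
  saw_quantile(stats::runif(n), params)
}

#' Tabulated normalization constants and interpolation across nu
#'
#' `saw_ab_grid()` evaluates `normalize_saw()` on the reference grid
#' `nu = 0.3, 0.4, 0.5, 0.6, 0.7`; `interpolate_ab()` recovers `(a, b)`
#' at intermediate `nu` using a cubic spline for `a` and linear
#' interpolation for `b`, mirroring the tabulate-then-interpolate
#' treatment used when the constants are solved in absolute units.
#'
#' @param nu_grid grid of Flory exponents to tabulate.
#' @return `saw_ab_grid()`: data.frame with columns `nu`, `a`, `b_norm`.
#' @export
saw_ab_grid <- function(nu_grid = c(0.3, 0.4, 0.5, 0.6, 0.7)) {
  ab <- vapply(nu_grid, normalize_saw, numeric(2))
  data.frame(nu = nu_grid, a = ab["a", ], b_norm = ab["b_norm", ])
}

#' @rdname saw_ab_grid
#' @inheritParams reduced_exponents
#' @param grid tabulated constants, as returned by [saw_ab_grid()].
#' @return `interpolate_ab()`: named numeric vector `c(a = , b_norm = )`.
#' @export
interpolate_ab <- function(nu, grid = saw_ab_grid()) {
  if (nu < min(grid$nu) || nu > max(grid$nu))
    stop(sprintf("`nu` = %g outside the tabulated range [%g, %g]; refusing to extrapolate",
                 nu, min(grid$nu), max(grid$nu)), call. = FALSE)
  a <- stats::spline(grid$nu, grid$a, xout = nu, method = "fmm")$y
  b <- stats::approx(grid$nu, grid$b_norm, xout = nu)$y
  c(a = a, b_norm = b)
}

#' Flory chain model
#'
#' `flory_chain()` holds the parameters of the Flory model for polymer
#' chain configurations, `R = sqrt(2 * lp * b) * N^nu`, which links the
#' root-mean-square end-to-end distance of a chain segment to the number
#' of residues `N` it spans. `lp` is the persistence length, `b` the
#' virtual bond length between consecutive residues (0.38 nm for a
#' polypeptide), and `dye_padding_residues` the effective extra residues
#' (+4 by default) that absorb the dye/linker contribution when `N` is
#' computed from label positions.
#'
#' @param lp persistence length in nm.
#' @param b_bond bond length in nm (default 0.38).
#' @param nu Flory scaling exponent.
#' @param dye_padding_residues non-negative integer added to the sequence
#'   separation before evaluating the model.
#' @return object of class `"flory_chain"`.
#' @examples
#' ch <- flory_chain(lp = 0.49, nu = 0.57)
#' flory_distance(131, ch)  # close to 10 nm end-to-end for the 9-140 pair
#' @export
flory_chain <- function(lp, b_bond = peptide_bond_length(), nu = 0.57,
                        dye_padding_residues = 4L) {
  if (!is.numeric(lp) || length(lp) != 1L || !is.finite(lp) || lp <= 0)
    stop("`lp` must be a single positive number (nm)", call. = FALSE)
  if (!is.numeric(b_bond) || b_bond <= 0)
    stop("`b_bond` must be positive (nm)", call. = FALSE)
  if (nu <= 0 || nu >= 1) stop("`nu` must be in (0, 1)", call. = FALSE)
  if (dye_padding_residues < 0) stop("`dye_padding_residues` must be >= 0", call. = FALSE)
  structure(list(lp = lp, b_bond = b_bond, nu = nu,
                 dye_padding_residues = as.integer(dye_padding_residues)),
            class = "flory_chain")
}

#' @export
print.flory_chain <- function(x, ...) {
  cat(sprintf("Flory chain: lp = %.3f nm, b = %.2f nm, nu = %.3f, dye padding = +%d residues\n",
              x$lp, x$b_bond, x$nu, x$dye_padding_residues))
  invisible(x)
}

#' Root-mean-square distance of a chain segment under the Flory model
#'
#' Evaluates `R = sqrt(2 * lp * b) * (dN + pad)^nu` where `dN` is the
#' number of residues between the two labeled positions and `pad` the
#' dye-padding residues of the chain model. Strictly increasing in `dN`.
#'
#' @param dN residue separation(s), at least 1.
#' @param chain a [flory_chain()] object.
#' @return distances in nm, same length as `dN`.
#' @export
flory_distance <- function(dN, chain) {
  if (!inherits(chain, "flory_chain")) stop("`chain` must be a flory_chain object", call. = FALSE)
  if (any(dN < 1)) stop("`dN` must be >= 1", call. = FALSE)
  sqrt(2 * chain$lp * chain$b_bond) * (dN + chain$dye_padding_residues)^chain$nu
}
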