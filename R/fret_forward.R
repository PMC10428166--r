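#' FRET dye-pair parameters
#'
#' `R0` is the Foerster radius of the donor/acceptor pair in nm (default
#' 6.2 nm, typical of the Alexa 488/568 class of pairs; configure to your
#' calibration) and `tauD` the donor-only fluorescence lifetime in ns.
#'
#' @param R0 Foerster radius (nm).
#' @param tauD donor-only lifetime (ns).
#' @return object of class `"fret_params"`.
#' @export
fret_params <- function(R0 = 6.2, tauD = 4.0) {
  if (!is.numeric(R0) || R0 <= 0) stop("`R0` must be positive (nm)", call. = FALSE)
  if (!is.numeric(tauD) || tauD <= 0) stop("`tauD` must be positive (ns)", call. = FALSE)
  structure(list(R0 = R0, tauD = tauD), class = "fret_params")
}

#' @export
print.fret_params <- function(x, ...) {
  cat(sprintf("FRET pair: R0 = %.2f nm, donor lifetime tauD = %.2f ns\n", x$R0, x$tauD))
  invisible(x)
}

#' Foerster transfer efficiency at a fixed distance
#'
#' The sixth-power distance law `E(r) = 1 / (1 + (r / R0)^6)`: unity at
#' contact, 1/2 at the Foerster radius, decreasing in `r`.
#'
#' @param r donor-acceptor distance(s) in nm.
#' @param fp a [fret_params()] object.
#' @return efficiencies in `[0, 1]`.
#' @export
fret_efficiency <- function(r, fp = fret_params()) {
  if (any(r < 0)) stop("`r` must be non-negative", call. = FALSE)
  1 / (1 + (r / fp$R0)^6)
}

## integrate h(x) against the reduced-unit SAW density a x^(2+g) exp(-b x^delta)
saw_expect <- function(h, params, fp) {
  f <- function(x) {
    h(x * params$R) * params$a * x^(2 + params$g) *
      exp(-params$b_norm * x^params$delta)
  }
  out <- tryCatch(
    stats::integrate(f, 0, 10, rel.tol = 1e-10, abs.tol = 1e-12,
                     subdivisions = 400L),
    error = function(e) stop("quadrature failure in FRET forward model: ",
                             conditionMessage(e), call. = FALSE))
  out$value
}

#' Ensemble FRET observables under the SAW distance distribution
#'
#' For a chain sampling the SAW distance distribution much faster than the
#' burst duration but slower than the donor lifetime, the ensemble
#' observables follow by averaging over `P(r)`:
#'
#' * `mean_efficiency()`: the intensity observable
#'   `<E> = integral E(r) P(r) dr`;
#' * `efficiency_variance()`: `sigma^2 = <E^2> - <E>^2`;
#' * `lifetime_ratio()`: the lifetime observable
#'   `tau_DA / tau_D = (1 - <E>) + sigma^2 / (1 - <E>)`.
#'
#' A donor photon is emitted with probability `1 - E(r)`, so donor arrival
#' times weight distances by `(1 - E) P(r)`; the resulting mean arrival
#' time is `tau_D <(1-E)^2> / <1-E>`, which rearranges to the expression
#' above. When the distribution collapses to a point (`sigma^2 = 0`) the
#' ratio reduces to `1 - <E>`, the static line.
#'
#' @param params a [saw_params()] object (defines `nu` and `R`).
#' @param fp a [fret_params()] object.
#' @return a single number.
#' @examples
#' p <- saw_params(0.57, R = 5.5)
#' mean_efficiency(p)                 # intensity observable
#' lifetime_ratio(p)                  # lies above 1 - mean_efficiency(p)
#' @export
mean_efficiency <- function(params, fp = fret_params()) {
  saw_expect(function(r) fret_efficiency(r, fp), params, fp)
}

#' @rdname mean_efficiency
#' @export
efficiency_variance <- function(params, fp = fret_params()) {
  m1 <- mean_efficiency(params, fp)
  m2 <- saw_expect(function(r) fret_efficiency(r, fp)^2, params, fp)
  v <- m2 - m1^2
  if (v < -1e-12) stop("negative FRET efficiency variance: quadrature inconsistency", call. = FALSE)
  max(v, 0)
}

#' @rdname mean_efficiency
#' @export
lifetime_ratio <- function(params, fp = fret_params()) {
  mE <- mean_efficiency(params, fp)
  if (1 - mE < 1e-12) return(0)  # fully quenched limit
  (1 - mE) + efficiency_variance(params, fp) / (1 - mE)
}

#' Static and dynamic lines in the efficiency-lifetime plane
#'
#' `static_line()` is the locus `tau_DA/tau_D = 1 - E` traced by rigid
#' molecules. `dynamic_line()` is the parametric curve
#' `(mean_E(R), tau_ratio(R))` traced over root-mean-square distances `R`
#' by chains sampling the SAW distance distribution at fixed `nu`; it lies
#' on or above the static line, the offset being
#' `sigma^2 / (1 - mean_E)`.
#'
#' @param E efficiencies in `[0, 1]`.
#' @return `static_line()`: `1 - E`.
#' @export
static_line <- function(E) {
  if (any(E < 0 | E > 1)) stop("`E` must lie in [0, 1]", call. = FALSE)
  1 - E
}

#' @rdname static_line
#' @param nu Flory exponent of the distance distribution (3/5 for the
#'   good-solvent display convention).
#' @param fp a [fret_params()] object.
#' @param R_grid root-mean-square distances (nm) to trace the curve over.
#' @return `dynamic_line()`: data.frame with columns `R`, `mean_E`,
#'   `tau_ratio`.
#' @export
dynamic_line <- function(nu = 3 / 5, fp = fret_params(),
                         R_grid = seq(0.2, 4, by = 0.05) * fp$R0) {
  rows <- lapply(R_grid, function(R) {
    p <- saw_params(nu, R = R)
    mE <- mean_efficiency(p, fp)
    data.frame(R = R, mean_E = mE, tau_ratio = lifetime_ratio(p, fp))
  })
  do.call(rbind, rows)
}

## monotone bracketed inversion shared by the two observables
invert_observable <- function(target, forward, lower, upper, tol = 1e-6) {
  f <- function(R) forward(R) - target
  fl <- f(lower); fu <- f(upper)
  if (fl * fu > 0)
    stop("observable outside the invertible range for this bracket", call. = FALSE)
  stats::uniroot(f, c(lower, upper), tol = tol)$root
}

#' Invert FRET observables to root-mean-square distances
#'
#' `invert_intensity()` finds the `R` whose SAW-averaged mean efficiency
#' equals the observed center efficiency (`R_int`); `invert_lifetime()`
#' finds the `R` whose predicted relative donor lifetime equals the
#' observed center ratio (`R_tau`). Both forward maps are strictly
#' monotone in `R`, so bracketed root-finding on
#' `[0.05 R0, 10 R0]` yields the unique solution.
#'
#' @param E_obs observed mean efficiency, strictly inside (0, 1).
#' @param nu Flory exponent assumed for the distance distribution.
#' @param fp a [fret_params()] object.
#' @param tol absolute tolerance on `R` (nm).
#' @return distance in nm.
#' @export
invert_intensity <- function(E_obs, nu, fp = fret_params(), tol = 1e-6) {
  if (!is.finite(E_obs) || E_obs <= 0 || E_obs >= 1)
    stop("`E_obs` must lie strictly inside (0, 1)", call. = FALSE)
  invert_observable(E_obs,
                    function(R) mean_efficiency(saw_params(nu, R = R), fp),
                    lower = 0.05 * fp$R0, upper = 10 * fp$R0, tol = tol)
}

#' @rdname invert_intensity
#' @param tau_obs observed relative donor lifetime, strictly inside (0, 1).
#' @export
invert_lifetime <- function(tau_obs, nu, fp = fret_params(), tol = 1e-6) {
  if (!is.finite(tau_obs) || tau_obs <= 0 || tau_obs >= 1)
    stop("`tau_obs` must lie strictly inside (0, 1)", call. = FALSE)
  invert_observable(tau_obs,
                    function(R) lifetime_ratio(saw_params(nu, R = R), fp),
                    lower = 0.05 * fp$R0, upper = 10 * fp$R0, tol = tol)
}
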