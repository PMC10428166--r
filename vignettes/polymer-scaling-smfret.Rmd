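---
title: "Inferring polymer scaling of disordered proteins from two smFRET observables"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring polymer scaling of disordered proteins from two smFRET observables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sawfret)
```

## The model

An intrinsically disordered protein such as alpha-synuclein behaves, to
first approximation, like a homopolymer in a solvent: the root-mean-square
(rms) distance between two residues separated by $\Delta N$ positions
scales as $R \sim \Delta N^{\nu}$, with the Flory exponent $\nu \approx
0.5$ at the theta point and $\nu \approx 0.588$ in a good solvent. The
package estimates the global $\nu$ and the persistence length $l_p$ of
such a chain from diffusion-based single-molecule FRET measurements on a
panel of double-labeled constructs, and maps local deviations from the
global behaviour.

Three model layers are involved.

**Distance distribution.** A rigid molecule has one donor-acceptor
distance; a disordered chain samples a distribution. We use the
self-avoiding-walk (des Cloizeaux) form in reduced units $x = r/R$:
$$P(x) = a\, x^{2+g}\, e^{-b x^{\delta}}, \qquad
g = \frac{\gamma - 1}{\nu},\quad \delta = \frac{1}{1-\nu},$$
with the universal exponent $\gamma = 1.1615$. The constants $a$ and $b$
are fixed by $\int P = 1$ and $\int x^2 P = 1$ (so that $R$ is the rms
distance), which have the closed form
$b = [\Gamma(\tfrac{5+g}{\delta})/\Gamma(\tfrac{3+g}{\delta})]^{\delta/2}$,
$a = \delta\, b^{(3+g)/\delta}/\Gamma(\tfrac{3+g}{\delta})$
(`normalize_saw()`). Working in reduced units makes both constants exactly
independent of $R$; the alternative convention of solving the constraints
in absolute units at a representative $R$ and interpolating over $\nu$
(spline for $a$, linear for $b$) is provided by `interpolate_ab()` and
agrees to better than 1%.

**FRET observables.** Energy transfer follows the Förster law
$E(r) = 1/(1 + (r/R_0)^6)$. Chain reconfiguration (tens of ns) is much
faster than the ~ms diffusion transit but slower than the donor lifetime
(~4 ns), so photons within a burst sample independent distances while each
individual excitation sees a quasi-static distance. Averaging over $P$
gives the intensity observable $\langle E \rangle = \int E(r) P(r)\,dr$
and, because a donor photon is emitted with probability $1 - E(r)$, the
lifetime observable
$$\frac{\tau_{DA}}{\tau_D} \;=\;
  \frac{\langle (1-E)^2 \rangle}{\langle 1-E \rangle}
  \;=\; (1 - \langle E\rangle) + \frac{\sigma^2}{1 - \langle E\rangle},
  \qquad \sigma^2 = \langle E^2\rangle - \langle E\rangle^2 .$$
Rigid molecules ($\sigma^2 = 0$) fall on the *static line*
$\tau_{DA}/\tau_D = 1 - E$; chains sampling $P(r)$ fall on the *dynamic
line* above it. The offset $\sigma^2/(1-\langle E\rangle)$ is what makes
the two observables carry independent information about $P(r)$.

**Chain model.** The rms distance of a segment follows the Flory form
$$R(\Delta N) = \sqrt{2\, l_p\, b}\; (\Delta N + 4)^{\nu},$$
with bond length $b = 0.38$ nm and the +4 effective residues absorbing
the dye/linker contribution. For the full-length 9–140 construct this
evaluates to just under 10 nm at the reference values $\nu = 0.57$,
$l_p = 0.49$ nm.

## The estimator

`flory_fit()` implements the dual-observable consistency argument. For an
assumed $\nu$, the center $E$ of each construct inverts (through the
$P(r)$-averaged Förster law) to a distance $R_{\rm int}$, and the center
$\tau_{DA}/\tau_D$ inverts to $R_\tau$. Both report on the same chain, so
they agree only if the assumed $\nu$ matches the chain's actual scaling.
The estimator scans $\nu \in [0.3, 0.7]$ in steps of 0.005, minimizes the
mean absolute difference $\langle |R_{\rm int} - R_\tau| \rangle$ over the
constructs with $E < 0.9$ (at higher transfer the donor photon count is
too low for reliable centers), refines the minimum parabolically, and
reports the objective normalized by its value at the good-solvent
exponent $\nu = 3/5$. With $\nu$ fixed at the optimum, $l_p$ is obtained
by Levenberg–Marquardt least squares of the Flory form on the pooled
$R_{\rm int} \cup R_\tau$ values, and the per-construct deviations
$\Delta R = \overline{R} - R(\Delta N)$ (negative = local compaction) are
interpolated over the label-position plane with barycentric-linear
interpolation on a Delaunay triangulation of the 14 scattered points
(natural-neighbour interpolation is an equivalent display choice; either
interpolant passes through the data).

```{r fit, eval = FALSE}
gt <- ground_truth(nu_true = 0.57, lp_true = 0.49)   # reference chain
obs <- forward <- local({
  truth <- make_construct_truth(gt)
  construct_obs(truth$label_i, truth$label_j,
    E_center  = sapply(truth$R_true, function(R)
      mean_efficiency(saw_params(0.57, R = R))),
    tau_center = sapply(truth$R_true, function(R)
      lifetime_ratio(saw_params(0.57, R = R))))
})
fit <- flory_fit(obs)
coef(fit)       # nu ~ 0.570, lp ~ 0.490
plot(fit, 1:2)  # exponent scan; R vs separation with the Flory curve
```

## The burst pipeline

Photon streams (channel, macro time, micro time) are reduced exactly as a
pulsed-excitation confocal experiment is analyzed: 1 ms binning of macro
times; intensity corrections for channel backgrounds, donor-to-acceptor
leakage and detection/quantum-yield asymmetry; burst selection keeping
single bins with 50–1000 corrected counts while rejecting runs of two or
more consecutive qualifying bins (slowly diffusing aggregates) and
overbright bins; donor-only separation by comparing raw acceptor counts
with the leakage + background expectation plus three Poisson standard
deviations; and per-burst observables $E = I_A/(I_A + I_D)$ and the mean
donor micro time minus the IRF offset. Two conventions deserve
explanation:

* *Leakage.* A leaked photon is detected in the acceptor channel
  **instead of** the donor channel. The correction therefore first
  restores the donor emission, $D_{\rm emit} = (D - bg_D)/(1-\alpha)$,
  and then removes $\alpha D_{\rm emit}$ from the acceptor channel.
  Subtracting $\alpha (D - bg_D)$ directly would undercorrect by
  $O(\alpha)$ and bias $E$ upward by ~0.01 at $\alpha = 0.05$.
* *Micro-time background.* Background photons arrive uniformly over the
  excitation period, so their expected contribution
  ($bg_D \cdot$ bin width counts at period/2) is subtracted from each
  burst's micro-time sum — the lifetime analogue of the intensity
  background subtraction. Without it, constructs with few donor photons
  per burst acquire an upward lifetime bias of several percent.

Per-construct centers are the *highest-density points* of the
$(E, \tau_{DA}/\tau_D)$ burst cloud: a separable Gaussian KDE with
Scott's-rule bandwidths per axis ($\sigma\, n^{-1/6}$), evaluated on a
201×201 grid over the data range, with ties resolved to the lowest-$E$
grid point; the donor-only lifetime is the 1-d KDE mode of the donor-only
bursts. Clouds with fewer than 50 points fall back to medians with a
warning.

### The mode of a skewed cloud

A per-burst mean arrival time is an average of $n_d$ roughly exponential
draws, i.e. gamma-distributed with relative skew $2/\sqrt{n_d}$; its mode
sits below its mean by about $\tau/n_d$. The ensemble relation above,
however, predicts the *mean*. The KDE-mode convention therefore
under-reads the lifetime ratio by roughly $1$–$3\%$ at the burst sizes of
a typical measurement (median ~150 photons), growing as $E \to 0.9$ where
$n_d$ is small. Because the exponent estimate responds strongly to
coherent lifetime distortions ($d\nu / d(\delta\tau/\tau) \approx 4$
under the study conditions used in the tests) and the persistence length
is in turn enslaved to the exponent
($d\ln l_p \approx -2\,\overline{\ln N}\, d\nu \approx -8\, d\nu$), this
small bias propagates into a systematic overestimate of $\nu$ of several
hundredths and an underestimate of $l_p$ of tens of percent. The test
suite characterizes this quantitatively; `process_photons(center =
"mean")` provides the unbiased (SE-limited) alternative, under which the
full photon-to-fit chain recovers generating parameters to within the
Monte-Carlo error of the centers. The mode convention remains the default
because it is the field's robust-center choice and what this pipeline
deliberately reproduces; users fitting scaling exponents quantitatively
should prefer the mean centers or burst sizes large enough that
$\tau/n_d$ is negligible.

## The synthetic-data generator

`simulate_bursts()` emulates a measurement with known ground truth. Study
conditions are fixed at the reference chain ($\nu = 0.57$, $l_p = 0.49$
nm) and a quiet pulsed setup: donor lifetime 4.0 ns (near the ~4.1 ns
free-dye control value), 50 ns excitation period, 2 ns IRF offset, 0.2 counts/ms background per
channel, 5% leakage, and a Förster radius of 6.2 nm (typical for the
Alexa 488/568-class pair; the analyses exposed here are insensitive to
its exact value because synthetic data and inversion share it). Burst
sizes are log-normal (median 150, log-sd 0.4, truncated to 60–950 so the
selection window is populated); burst arrivals are Poisson at 50/s with
at least one empty bin between events, so every molecule transit is a
single-bin burst by construction and selection counts can be checked
against planted truth exactly. Within a burst every photon samples an
independent distance from $P(r)$ — justified by the ~60 ns global
reconfiguration time against the ~ms transit — and donor photons carry
$\mathrm{Exp}(\tau_D (1-E(r)))$ micro times; no within-burst correlation,
triplet blinking or spectral crosstalk beyond the single leakage factor is
modelled. Passing tests on these streams therefore validate the
photon-statistics and inversion chain, not detector artefacts or dye
photophysics of real instruments.

Solvent scenarios scale the true distances of the three probe constructs
(9–42, 56–90, 90–140) by configurable region factors; the defaults
(denaturant expands all three by 12%; low salt expands the C-terminal
probe by 10%; methanol compacts the N-terminal probe by 7%) encode the
qualitative response patterns the package's sign conventions are tested
against, not measured magnitudes.

## The chain ensemble module

`sample_chain()` is a deliberately simple one-bead-per-residue sampler —
a stand-in for residue-resolved coarse-grained force fields whose
parameter sets are not reproduced here. It runs Metropolis Monte Carlo
(70% pivot, 30% crankshaft moves, both bond-preserving) on a fixed
0.38 nm bond chain with: hard-core excluded volume (0.38 nm), bending
stiffness $k(1-\cos\varphi)$ (0.5 kT, 3 kT at prolines), Debye–Hückel
electrostatics from formal charges at pH 7.4 (Bjerrum length 0.7 nm,
Debye length 0.78 nm at physiological ionic strength, cutoff $4\lambda_D$),
and a 0.7 nm square-well attraction between residue groups with modest
depths (0.3 kT aliphatic, 0.35 kT aromatic, 0.5 kT cation-$\pi$). These
well depths are qualitative defaults, not a calibrated force field; the
module's tested claims are physical limits (ideal-chain statistics when
interactions vanish, self-avoiding scaling with the hard core alone,
rod/sphere shape limits) and exact analytics (contact maps equal to a
brute-force oracle). Equilibrium averages are the target, so Monte Carlo
replaces Langevin dynamics; an equilibration prefix (default $200N$
moves) is discarded and frames are stored every $2N$ moves.

Contact maps count residue pairs within 0.7 nm, excluding $|i-j| \le 3$;
grouped maps aggregate into cationic/anionic/aromatic/aliphatic/
hydrophilic classes and divide by the number of available pairs per cell,
so group abundance does not masquerade as preference. Shape metrics
diagonalize the per-frame gyration tensor and report
$R_g = \sqrt{\lambda_1+\lambda_2+\lambda_3}$, the normalized asphericity
$\Delta = \tfrac{3}{2}\sum_i(\lambda_i - \bar\lambda)^2 / (\sum_i
\lambda_i)^2 \in [0, 1]$ and the shape parameter $S = 27 \prod_i
(\lambda_i - \bar\lambda)/(\sum_i \lambda_i)^3 \in [-1/4, 2]$ (rod: 1 and
2; sphere: 0 and 0). Other normalization conventions exist; comparisons
across programs must check the convention first.

## Numerical choices

* Quadratures over $P(r)$ use `stats::integrate` on $[0, 10R]$ (the
  density is below $10^{-12}$ beyond) at tolerance $10^{-10}$; the
  exponent scan replaces them with fixed 256-node Gauss–Legendre
  quadrature plus monotone (Hyman) spline inversion of the forward
  curves on a 160-point log-spaced distance grid, verified against the
  adaptive path to $10^{-6}$.
* Observable inversions bracket on $[0.05 R_0, 10 R_0]$ and solve to
  $10^{-6}$ nm; both forward maps are strictly monotone so the root is
  unique.
* The exponent grid step is 0.005 with parabolic refinement; the
  objective is the mean *absolute* difference (a mean signed difference
  can cancel).
* Sampling from $P(r)$ uses the exact inverse CDF via the regularized
  incomplete gamma function.
* KDE grids are 201×201; degenerate clouds (zero spread) return the
  common point; ties resolve to the lowest-$E$ grid point.
* The Monte Carlo sampler draws from R's RNG, so `set.seed()` makes
  trajectories and photon streams bit-reproducible.

## Problem sizes used by the test suite

The packaged tests run at desk scale: 14 constructs × 2000 bursts per
recovery replicate (20 replicates in the recovery study, 3 in the
flagship end-to-end check), 5000 bursts per condition in the
photon-physics consistency grid, 1500 frames per chain length in the
scaling-exponent fit over $N = 20$–$140$, and 4000 frames for the
sampler-versus-$P(r)$ consistency check. These sizes put Monte-Carlo
standard errors comfortably below the tolerances being asserted.

## Known limitations

* The KDE-mode center bias described above: the default pipeline
  reproduces the field's convention faithfully, including its small
  skew-induced lifetime bias; exponent estimates inherit that bias.
* The burst model has no diffusion kinetics: transits are single-bin
  events by construction, and multi-bin aggregates are planted rather
  than emergent.
* The chain sampler's nonbonded parameters are qualitative; simulated
  contact maps and shape statistics should be read as illustrating the
  analytics, not predicting alpha-synuclein's ensemble.
* Distances assume an isotropic orientation factor; no $\kappa^2$ or
  dye-photophysics corrections are applied.
* Lifetimes are mean arrival times, not deconvolved decays; the IRF
  enters only as a constant offset.
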