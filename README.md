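# sawfret

Polymer scaling analysis of intrinsically disordered proteins (IDPs) from
diffusion-based single-molecule FRET, built around the 140-residue protein
alpha-synuclein. The package is for people who measure two FRET observables
per labeled construct — the intensity-based transfer efficiency
`E = I_A/(I_A + I_D)` and the relative donor lifetime `tau_DA/tau_D` — on a
panel of label pairs spanning a chain, and want a *global* polymer
description of that chain plus a map of where it locally deviates.

## The method

A disordered chain samples a distance distribution rather than one
distance. `sawfret` models the end-to-end distance of the segment between
two labels with the self-avoiding-walk density (reduced units `x = r/R`)

    P(x) = a x^(2+g) exp(-b x^delta),   g = (gamma - 1)/nu,  delta = 1/(1 - nu)

with `gamma = 1.1615` and `(a, b)` fixed by unit normalization and unit
second moment. Averaging the Förster law `E(r) = 1/(1 + (r/R0)^6)` over
`P` gives the predicted efficiency; because donor photons are emitted with
probability `1 - E(r)`, the predicted lifetime ratio is

    tau_DA/tau_D = (1 - <E>) + sigma^2 / (1 - <E>),   sigma^2 = <E^2> - <E>^2.

Each observable inverts to a distance (`R_int` from intensity, `R_tau`
from lifetime) *given* a Flory exponent `nu` — and the two agree only at
the `nu` that actually describes the chain. `flory_fit()` scans `nu`,
minimizes the mean `|R_int - R_tau|` over constructs with `E < 0.9`, then
fits the persistence length `l_p` of the Flory chain model

    R(dN) = sqrt(2 l_p b) (dN + 4)^nu,    b = 0.38 nm,

and reports per-construct deviations `dR` from the global fit (negative =
local compaction). A photon-burst pipeline (1 ms binning, 50–1000 photon
thresholds, aggregate rejection, donor-only separation, KDE cloud
centers) produces the per-construct observables from raw photon records,
and a synthetic photon-stream generator plus a coarse-grained chain
sampler provide ground-truthed data for every stage.

## Worked example

Simulate a 14-construct experiment at known ground truth (`nu = 0.57`,
`l_p = 0.49` nm), reduce the photon streams, and fit:

```r
library(sawfret)

gt      <- ground_truth(nu_true = 0.57, lp_true = 0.49)
truth   <- make_construct_truth(gt)                    # R_true per construct
streams <- simulate_construct_set(gt, truth, n_bursts = 2000, seed = 1)
centers <- lapply(streams, process_photons,
                  cf = correction_factors_of(gt), center = "mean")
obs <- construct_obs(truth$label_i, truth$label_j,
                     sapply(centers, `[[`, "E_center"),
                     sapply(centers, `[[`, "tau_ratio_center"))
fit <- flory_fit(obs)
fit
#> Global polymer scaling fit (smFRET dual-observable)
#>   Flory exponent     nu = 0.575
#>   persistence length lp = 0.472 nm (se 0.001)
#>   constructs: 10 used of 14 (E < 0.90)
```

The fit recovers the generating exponent to 0.005 and the persistence
length to ~4%. `summary(fit)` prints the per-construct table — e.g. the
end-to-end 9–140 construct inverts to `R_int = 9.95` nm and
`R_tau = 9.96` nm, and short constructs with `E >= 0.9` are excluded from
the fit:

```
 label_i label_j  dN E_center tau_center R_int R_tau included    dR
       9      42  33    0.780      0.493  4.81  4.79     TRUE  0.03
       9     140 131    0.244      0.878  9.95  9.96     TRUE -0.08
      56      90  34    0.773      0.498  4.87  4.83     TRUE  0.00
      ...
```

`plot(fit, 1)` draws the exponent scan (the objective normalized to its
value at `nu = 3/5`), `plot(fit, 2)` the distances versus separation with
the fitted Flory curve, `plot(fit, 3)` the deviation map.
`center = "mean"` above selects unbiased burst-cloud centers; the default
(`"kde"`) reproduces the highest-density-point convention of the
burst-analysis protocol, whose small skew bias on the lifetime axis is
characterized in the methods vignette.

The chain-ensemble side mirrors the analysis on simulated conformations:

```r
ens <- sample_chain(chain_model(), n_frames = 2000, seed = 1)
label_distance(ens, 9, 140, dye_mode = "bead_offset")  # nm, incl. 1.15 nm dye term
cm  <- contact_map(ens)            # 0.7 nm cutoff, |i-j| <= 3 excluded
grouped_contact_map(cm)            # 5 residue classes, abundance-normalized
shape_metrics(ens)                 # Rg, asphericity, shape parameter
```

A thin command-line surface (`inst/cli/sawfret`) exposes the same
pipeline as subcommands `simulate`, `bursts`, `infer`, `ensemble`,
`contacts` and `report`.

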