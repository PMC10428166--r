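Package: sawfret
Title: Polymer Scaling Analysis of Disordered Proteins from Single-Molecule FRET
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to infer global polymer scaling behaviour of intrinsically
    disordered proteins from single-molecule FRET burst data. Implements the
    self-avoiding-walk end-to-end distance distribution and its normalization,
    forward and inverse mapping between chain distances and the two FRET
    observables (intensity-based efficiency and relative donor lifetime), a
    photon-burst analysis pipeline (1 ms binning, thresholding, donor-only
    separation, kernel-density cloud centers), global Flory-exponent and
    persistence-length estimation with a per-construct deviation map, a
    coarse-grained one-bead-per-residue chain sampler with contact-map and
    shape analytics, and a synthetic photon-stream generator with known ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    Rcpp,
    jsonlite,
    minpack.lm,
    pracma,
    seqinr,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
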