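# shared helpers for building tiny synthetic objects in tests

# analytic center observables for a construct-truth table
forward_centers <- function(truth, nu, fp = fret_params()) {
  E <- vapply(truth$R_true, function(R)
    mean_efficiency(saw_params(nu, R = R), fp), numeric(1))
  tr <- vapply(truth$R_true, function(R)
    lifetime_ratio(saw_params(nu, R = R), fp), numeric(1))
  construct_obs(truth$label_i, truth$label_j, E, tr)
}

# wrap a bare N x 3 x F coordinate array as a chain ensemble
as_ensemble <- function(frames, sequence = strrep("A", dim(frames)[1])) {
  structure(list(frames = frames, model = list(sequence = sequence),
                 seed = NA_integer_, acceptance = NA_real_),
            class = "chain_ensemble")
}

# O(N^2 * F) reference contact-map implementation
contact_map_bruteforce <- function(frames, cutoff = 0.7, exclusion = 3L) {
  N <- dim(frames)[1]; F <- dim(frames)[3]
  out <- matrix(0, N, N)
  for (f in seq_len(F)) {
    for (i in seq_len(N - 1)) {
      for (j in (i + 1):N) {
        if (j - i <= exclusion) next
        d <- sqrt(sum((frames[i, , f] - frames[j, , f])^2))
        if (d <= cutoff) out[i, j] <- out[i, j] + 1
      }
    }
  }
  out <- out / F
  out + t(out)
}

# photon table with all photons placed in given bins (helper for threshold tests)
photons_in_bins <- function(bins, counts, channel = "donor", micro = 5) {
  macro <- unlist(mapply(function(b, n) (b + seq(0.1, 0.9, length.out = n)) * 1e-3,
                         bins, counts, SIMPLIFY = FALSE))
  o <- order(macro)
  photon_records(rep(channel, length.out = length(macro))[o], macro[o],
                 rep(micro, length(macro)))
}
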