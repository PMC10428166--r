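#include <Rcpp.h>
using namespace Rcpp;

// Photon-level burst generator.
//
// Conformational dynamics is fast relative to the burst duration but slow
// relative to the donor lifetime, so each photon samples an independent
// donor-acceptor distance r from the chain's distance distribution. The
// distance is drawn by inverse-CDF lookup from a precomputed quantile table
// (qtab[k] = Q(k/(m-1))). A photon is emitted in the acceptor channel with
// probability E(r); donor photons carry a micro time Exp(tauD * (1 - E(r)))
// plus the IRF offset, reflecting the shortened donor lifetime at high
// transfer. Donor photons leak into the acceptor channel with probability
// alpha_leak (the leaked photon keeps its donor micro time). Acceptor micro
// times are modelled as Exp(tauA) + offset. Uses R's RNG: reproducible under
// set.seed().
//
// Returns a list with per-photon vectors: burst id, channel code
// (0 donor, 1 acceptor), micro time (ns), and the per-burst true E.
// [[Rcpp::export(name = ".sim_burst_photons")]]
List sim_burst_photons(IntegerVector burst_sizes, NumericVector qtab,
                       double R0, double tauD, double tauA,
                       double alpha_leak, double irf_offset,
                       double micro_period) {
  const int nb = burst_sizes.size();
  const int m = qtab.size();
  long total = 0;
  for (int i = 0; i < nb; ++i) total += burst_sizes[i];

  IntegerVector burst(total), channel(total);
  NumericVector micro(total), E_true(total);

  long k = 0;
  for (int i = 0; i < nb; ++i) {
    for (int p = 0; p < burst_sizes[i]; ++p, ++k) {
      double u = unif_rand() * (m - 1);
      int lo = (int)u;
      if (lo >= m - 1) lo = m - 2;
      double r = qtab[lo] + (u - lo) * (qtab[lo + 1] - qtab[lo]);
      double ratio = r / R0;
      double r6 = ratio * ratio * ratio;
      r6 *= r6;
      double E = 1.0 / (1.0 + r6);
      burst[k] = i + 1;
      E_true[k] = E;
      if (unif_rand() < E) {  // transfer: acceptor emission
        channel[k] = 1;
        double t = irf_offset + exp_rand() * tauA;
        micro[k] = t - micro_period * std::floor(t / micro_period);
      } else {               // donor emission, lifetime shortened by 1-E
        double t = irf_offset + exp_rand() * tauD * (1.0 - E);
        micro[k] = t - micro_period * std::floor(t / micro_period);
        channel[k] = (unif_rand() < alpha_leak) ? 1 : 0;
      }
    }
  }
  return List::create(_["burst"] = burst, _["channel"] = channel,
                      _["micro_time_ns"] = micro, _["E_true"] = E_true);
}
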