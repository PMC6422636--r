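#include <Rcpp.h>
using namespace Rcpp;

// Interval-jitter null for the paired-cell synchrony statistic.
//
// The time axis of every trial is partitioned into fixed, contiguous
// delta-bin windows anchored at bin 0; each event is re-placed uniformly at
// random among the bins of its own window, independently per event, per
// trial, per cell. This conserves per-window event counts exactly, so any
// structure at timescales coarser than delta survives while fine-timescale
// synchrony is destroyed. The synchrony statistic (number of occupied-bin
// pairs within +/- 1 bin, summed over trials, bins binarized) is recomputed
// for every resample.
//
// bins_*: 0-based bin of each event; trials_*: 0-based trial of each event.
// Uses the R RNG, so results are reproducible under set.seed().
// [[Rcpp::export(name = ".jitter_null_stats")]]
IntegerVector jitter_null_stats(IntegerVector bins_a, IntegerVector trials_a,
                                IntegerVector bins_b, IntegerVector trials_b,
                                int n_trials, int n_bins, int delta,
                                int n_resamples, bool jitter_a, bool jitter_b) {
  if (delta < 2) stop("jitter window must span at least 2 bins");
  if (n_bins < 1 || n_trials < 1) stop("degenerate train shape");
  const int na = bins_a.size(), nb = bins_b.size();
  IntegerVector out(n_resamples);
  std::vector<int> stamp_a((size_t)n_trials * n_bins, -1);
  std::vector<int> stamp_b((size_t)n_trials * n_bins, -1);
  std::vector<int> jit_a(na), jit_b(nb);

  for (int r = 0; r < n_resamples; ++r) {
    for (int i = 0; i < na; ++i) {
      int b = bins_a[i];
      if (jitter_a) {
        int w0 = (b / delta) * delta;
        int wlen = std::min(delta, n_bins - w0);
        b = w0 + (int)(unif_rand() * wlen);
        if (b >= w0 + wlen) b = w0 + wlen - 1;  // guard unif_rand() == 1
      }
      jit_a[i] = b;
    }
    for (int i = 0; i < nb; ++i) {
      int b = bins_b[i];
      if (jitter_b) {
        int w0 = (b / delta) * delta;
        int wlen = std::min(delta, n_bins - w0);
        b = w0 + (int)(unif_rand() * wlen);
        if (b >= w0 + wlen) b = w0 + wlen - 1;
      }
      jit_b[i] = b;
    }
    // binarized occupancy of cell A, stamped per resample to avoid clearing
    for (int i = 0; i < na; ++i)
      stamp_a[(size_t)trials_a[i] * n_bins + jit_a[i]] = r;
    int stat = 0;
    for (int i = 0; i < nb; ++i) {
      size_t idx = (size_t)trials_b[i] * n_bins + jit_b[i];
      if (stamp_b[idx] == r) continue;  // bin already counted (binarize B)
      stamp_b[idx] = r;
      int t0 = trials_b[i] * n_bins, j = jit_b[i];
      if (j > 0 && stamp_a[(size_t)t0 + j - 1] == r) ++stat;
      if (stamp_a[(size_t)t0 + j] == r) ++stat;
      if (j + 1 < n_bins && stamp_a[(size_t)t0 + j + 1] == r) ++stat;
    }
    out[r] = stat;
  }
  return out;
}
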