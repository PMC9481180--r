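#include <Rcpp.h>
using namespace Rcpp;

// Adaptive exponential integrate-and-fire integration for one square
// current step. Euler stepping at dt_ms (<= 0.025 ms); when V reaches the
// 0 mV cut-off a stereotyped cosine-shaped action-potential waveform of
// ap_len samples is written into the trace, the membrane is reset, and
// the adaptation current is incremented.
//
// Units: mV, ms, pA, nS, pF (pA/pF = mV/ms; nS*mV = pA).
// [[Rcpp::export(name = ".adex_integrate")]]
NumericVector adex_integrate(int n_samp, int nsub, double dt_ms,
                             double v_base, double i_hold, double amplitude,
                             int on_i, int off_i,
                             double g_l, double e_l, double delta_t,
                             double v_t, double c, double tau_w,
                             double b, double v_reset,
                             int ap_len, double peak_v) {
  NumericVector v(n_samp);
  double vi = v_base, wi = 0.0;
  int i = 0;  // 0-based sample index
  while (i < n_samp) {
    v[i] = vi;
    double i_ext = i_hold + ((i + 1 >= on_i && i + 1 < off_i) ? amplitude : 0.0);
    bool fired = false;
    for (int s = 0; s < nsub; s++) {
      double dv = (-g_l * (vi - e_l) +
                   g_l * delta_t * std::exp((vi - v_t) / delta_t) +
                   i_ext - wi) / c;
      double dw = (-wi) / tau_w;
      vi += dt_ms * dv;
      wi += dt_ms * dw;
      if (!std::isfinite(vi) || !std::isfinite(wi)) {
        stop("AdEx integration diverged (amplitude %f pA)", amplitude);
      }
      if (vi >= 0.0) { fired = true; break; }
    }
    if (fired) {
      // stereotyped waveform: cosine rise to peak over ~30% of ap_len,
      // cosine fall to reset over the remainder
      int n_up = std::max(2, (int) std::lround(ap_len * 0.3));
      int n_dn = ap_len - n_up;
      double v_start = v[i];
      for (int j = 0; j < n_up; j++) {
        int idx = i + 1 + j;
        if (idx >= n_samp) break;
        double ph = (double) j / (n_up - 1);
        v[idx] = v_start + (peak_v - v_start) * (1.0 - std::cos(M_PI * ph)) / 2.0;
      }
      for (int j = 1; j <= n_dn; j++) {
        int idx = i + n_up + j;
        if (idx >= n_samp) break;
        double ph = (double) j / n_dn;
        v[idx] = peak_v + (v_reset - peak_v) * (1.0 - std::cos(M_PI * ph)) / 2.0;
      }
      i += ap_len + 1;
      vi = v_reset;
      wi += b;
    } else {
      i += 1;
    }
  }
  return v;
}
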