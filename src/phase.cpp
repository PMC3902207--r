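#include <Rcpp.h>
using namespace Rcpp;

// Right-hand side of the activation-weighted Kuramoto network.
// phi, g: (nr, nc, K). Connection records give, per edge template,
// the column/row offset (dx, dy), afferent feature j, efferent feature k
// (both 1-based) and the sign w. An edge template connects the source
// neuron (r - dy, c - dx, j) to the target (r, c, k) at every grid
// position; sources falling outside the grid contribute nothing unless
// wrap (toroidal) is requested.
// [[Rcpp::export]]
NumericVector cpp_phase_deriv(NumericVector phi, NumericVector g,
                              IntegerVector dx, IntegerVector dy,
                              IntegerVector jf, IntegerVector kf,
                              NumericVector w, double tau, bool wrap) {
  IntegerVector d = phi.attr("dim");
  const int nr = d[0], nc = d[1];
  const int n = dx.size();
  NumericVector out(phi.size());
  out.attr("dim") = d;
  const double inv_tau = 1.0 / tau;
  for (int e = 0; e < n; ++e) {
    const int k = kf[e] - 1, j = jf[e] - 1;
    const int ddx = dx[e], ddy = dy[e];
    const double we = w[e];
    const double *phik = &phi[(size_t)k * nr * nc];
    const double *gk = &g[(size_t)k * nr * nc];
    const double *phij = &phi[(size_t)j * nr * nc];
    const double *gj = &g[(size_t)j * nr * nc];
    double *o = &out[(size_t)k * nr * nc];
    for (int c = 0; c < nc; ++c) {
      int sc = c - ddx;
      if (wrap) sc = ((sc % nc) + nc) % nc;
      else if (sc < 0 || sc >= nc) continue;
      const size_t tcol = (size_t)c * nr, scol = (size_t)sc * nr;
      for (int r = 0; r < nr; ++r) {
        int sr = r - ddy;
        if (wrap) sr = ((sr % nr) + nr) % nr;
        else if (sr < 0 || sr >= nr) continue;
        const double gt = gk[tcol + r];
        if (gt == 0.0) continue;
        const double gs = gj[scol + sr];
        if (gs == 0.0) continue;
        o[tcol + r] -= inv_tau * gt * we * gs *
          std::sin(phik[tcol + r] - phij[scol + sr]);
      }
    }
  }
  return out;
}
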