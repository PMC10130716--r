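// Laplace-domain Green's function series via stable Bessel-ratio recurrences.
//
// Every series here is built from the forward recurrence on ratios
//   t_m = K_{m+1}(z) / K_m(z),   t_m = 2m/z + 1/t_{m-1},
// which is stable for the increasing solution K and never overflows (the
// ratios grow only linearly in m).  Derivatives enter through
//   K_m'(z)/K_m(z) = -(1/t_{m-1} + t_m)/2,
// and two-argument ratios K_m(zR)/K_m(z) through the cumulative product of
// per-argument ratios.  Seeds K0, K1 are computed in R (besselk01) and
// passed in exponentially scaled form.

#include <Rcpp.h>
#include <complex>
using namespace Rcpp;
typedef std::complex<double> cplx;

// Sum of the regular-part series for the surface Green's function of the
// modified Helmholtz operator on the disc exterior:
//   for each dtheta: S = sum_{m=1}^{M} [ K_m(a)/(a K_m'(a)) + 1/m ] cos(m dtheta)
// Returns List(c0 = K_0(a)/(a K_0'(a)), sums, m_used).
// [[Rcpp::export]]
List rh_series_sum(std::complex<double> alpha,
                   std::complex<double> k0, std::complex<double> k1,
                   NumericVector dtheta, int mmax, double tol) {
  int K = dtheta.size();
  std::vector<cplx> acc(K, cplx(0.0, 0.0));
  cplx a = alpha;
  cplx c0 = -k0 / (a * k1);                 // K_0' = -K_1
  cplx tprev = k1 / k0;                     // K_1/K_0
  int small_run = 0, m = 0;
  for (m = 1; m <= mmax; ++m) {
    cplx tm = 2.0 * double(m) / a + 1.0 / tprev;
    cplx bracket = -2.0 / (a * (1.0 / tprev + tm)) + 1.0 / double(m);
    double mag = std::abs(bracket);
    for (int i = 0; i < K; ++i) acc[i] += bracket * std::cos(double(m) * dtheta[i]);
    tprev = tm;
    if (m >= 50) {
      if (mag < tol) { if (++small_run >= 2) break; } else small_run = 0;
    }
  }
  ComplexVector out(K);
  for (int i = 0; i < K; ++i) out[i] = Rcomplex{acc[i].real(), acc[i].imag()};
  return List::create(_["c0"] = cplx(c0.real(), c0.imag()),
                      _["sums"] = out, _["m_used"] = std::min(m, mmax));
}

// Bulk-to-surface series: for each dtheta,
//   S = sum_{m=1}^{M} [ K_m(aR)/(a K_m'(a)) ] cos(m dtheta)
// with T0 = K_0(aR)/(a K_0'(a)) returned separately.  p0 = K_0(aR)/K_0(a)
// must be supplied (computed in R with the exponential factor).
// [[Rcpp::export]]
List bulk_series_sum(std::complex<double> alpha, double R,
                     std::complex<double> k0a, std::complex<double> k1a,
                     std::complex<double> k0aR, std::complex<double> k1aR,
                     std::complex<double> p0,
                     NumericVector dtheta, int mmax, double tol) {
  int K = dtheta.size();
  std::vector<cplx> acc(K, cplx(0.0, 0.0));
  cplx a = alpha, aR = a * R;
  cplx T0 = -p0 * (k0a / (a * k1a));        // K0(aR)/(a K0'(a))
  cplx ta_prev = k1a / k0a;
  cplx tR_prev = k1aR / k0aR;
  cplx pm = p0;
  double ref = std::abs(T0) + 1e-300;
  int small_run = 0, m = 0;
  for (m = 1; m <= mmax; ++m) {
    cplx ta = 2.0 * double(m) / a + 1.0 / ta_prev;
    cplx tR = 2.0 * double(m) / aR + 1.0 / tR_prev;
    pm *= tR_prev / ta_prev;                // K_m(aR)/K_m(a)
    cplx ratio_d = -2.0 / (a * (1.0 / ta_prev + ta));   // K_m(a)/(a K_m'(a))
    cplx Tm = pm * ratio_d;
    double mag = std::abs(Tm);
    for (int i = 0; i < K; ++i) acc[i] += Tm * std::cos(double(m) * dtheta[i]);
    ta_prev = ta; tR_prev = tR;
    if (mag < tol * ref) { if (++small_run >= 2) break; } else small_run = 0;
    if (mag == 0.0) break;                  // underflow: geometric decay done
  }
  ComplexVector out(K);
  for (int i = 0; i < K; ++i) out[i] = Rcomplex{acc[i].real(), acc[i].imag()};
  return List::create(_["T0"] = cplx(T0.real(), T0.imag()),
                      _["sums"] = out, _["m_used"] = std::min(m, mmax));
}

// Robin-boundary flux modes chi_m(alpha) = K_m(aR) / (K_m(a) - Dk_inv a K_m'(a))
// for m = 0..mmodes, computed as
//   chi_m = [K_m(aR)/K_m(a)] / (1 - Dk_inv a K_m'(a)/K_m(a)).
// [[Rcpp::export]]
ComplexVector chi_mode_vector(std::complex<double> alpha, double R,
                              std::complex<double> k0a, std::complex<double> k1a,
                              std::complex<double> k0aR, std::complex<double> k1aR,
                              std::complex<double> p0, double Dk_inv, int mmodes) {
  cplx a = alpha, aR = a * R;
  ComplexVector out(mmodes + 1);
  cplx dlog0 = -k1a / k0a;                  // K_0'(a)/K_0(a)
  cplx chi0 = p0 / (1.0 - Dk_inv * a * dlog0);
  out[0] = Rcomplex{chi0.real(), chi0.imag()};
  cplx ta_prev = k1a / k0a, tR_prev = k1aR / k0aR, pm = p0;
  for (int m = 1; m <= mmodes; ++m) {
    cplx ta = 2.0 * double(m) / a + 1.0 / ta_prev;
    cplx tR = 2.0 * double(m) / aR + 1.0 / tR_prev;
    pm *= tR_prev / ta_prev;
    cplx dlog = -(1.0 / ta_prev + ta) / 2.0;   // K_m'(a)/K_m(a)
    cplx chim = pm / (1.0 - Dk_inv * a * dlog);
    out[m] = Rcomplex{chim.real(), chim.imag()};
    ta_prev = ta; tR_prev = tR;
  }
  return out;
}
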