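#include <Rcpp.h>
using namespace Rcpp;

// Fixed-step RK4 integrator for the two-pool vesicle system
//
//   dD/dt = -k1*D + km1*R          (depletable depot)
//   dR/dt =  k1*D - (km1 + k2(t))*R
//   dF/dt =  k2(t)*R
//
// In constant-supply mode the depot is frozen at D0 and the priming flux
// k1*D0 enters R as a constant. k2 is supplied as a series sampled at
// half-step resolution (length 2*n + 1 for n steps of size dt), so all four
// RK4 stages see the exact rate at t, t + dt/2 and t + dt.
//
// Because the three derivatives sum to zero term-by-term in depletable mode,
// every RK4 stage conserves D + R + F to round-off; the fixed-step scheme is
// therefore also the reference for mass-conservation checks.

struct Deriv {
  double dD, dR, dF;
};

static inline Deriv rhs(double D, double R, double k1, double km1, double k2,
                        double prime_const, bool depletable) {
  Deriv d;
  if (depletable) {
    d.dD = -k1 * D + km1 * R;
    d.dR = k1 * D - (km1 + k2) * R;
  } else {
    d.dD = 0.0;
    d.dR = prime_const - (km1 + k2) * R;
  }
  d.dF = k2 * R;
  return d;
}

// [[Rcpp::export]]
List pool_rk4_cpp(double k1, double km1, double D0, double R0,
                  NumericVector k2_half, double dt, bool depletable) {
  R_xlen_t m = k2_half.size();
  if (m < 3 || m % 2 == 0)
    stop("k2_half must have odd length >= 3 (half-step sampling)");
  if (dt <= 0) stop("dt must be positive");
  R_xlen_t n = (m - 1) / 2;
  NumericVector D(n + 1), R(n + 1), Fp(n + 1);
  D[0] = D0;
  R[0] = R0;
  Fp[0] = 0.0;
  const double prime_const = k1 * D0;
  for (R_xlen_t i = 0; i < n; ++i) {
    const double k2a = k2_half[2 * i];
    const double k2b = k2_half[2 * i + 1];
    const double k2c = k2_half[2 * i + 2];
    const double Di = D[i], Ri = R[i], Fi = Fp[i];

    Deriv d1 = rhs(Di, Ri, k1, km1, k2a, prime_const, depletable);
    Deriv d2 = rhs(Di + 0.5 * dt * d1.dD, Ri + 0.5 * dt * d1.dR,
                   k1, km1, k2b, prime_const, depletable);
    Deriv d3 = rhs(Di + 0.5 * dt * d2.dD, Ri + 0.5 * dt * d2.dR,
                   k1, km1, k2b, prime_const, depletable);
    Deriv d4 = rhs(Di + dt * d3.dD, Ri + dt * d3.dR,
                   k1, km1, k2c, prime_const, depletable);

    D[i + 1] = Di + dt / 6.0 * (d1.dD + 2.0 * d2.dD + 2.0 * d3.dD + d4.dD);
    R[i + 1] = Ri + dt / 6.0 * (d1.dR + 2.0 * d2.dR + 2.0 * d3.dR + d4.dR);
    Fp[i + 1] = Fi + dt / 6.0 * (d1.dF + 2.0 * d2.dF + 2.0 * d3.dF + d4.dF);
  }
  return List::create(_["D"] = D, _["R"] = R, _["F"] = Fp);
}
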