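// Stochastic simulation kernels and the basin-map integrator.
//
// All random draws go through R's RNG so set.seed() in R controls every
// simulation. The time-inhomogeneous SSA is implemented twice: by thinning
// against a per-interval upper bound and by closed-form inversion of the
// integrated hazard (possible because the time-varying birth rate is
// linear in t); the two samplers are cross-validated in the test suite.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// next waiting time for total hazard a_const + lam(t) with lam linear:
// solves  (a_const + lam(t)) tau + s tau^2 / 2 = E  (E ~ Exp(1)).
// Returns R_PosInf if the hazard to horizon is exhausted.
static double hazardInvert(double aConst, double lamNow, double slope,
                           double horizon, double E) {
  double b = aConst + lamNow;
  double Hmax = b * horizon + 0.5 * slope * horizon * horizon;
  if (E >= Hmax) return R_PosInf;
  if (std::fabs(slope) < 1e-300) return E / b;
  double disc = b * b + 2.0 * slope * E;
  if (disc < 0.0) return R_PosInf;           // cannot happen when E < Hmax
  return 2.0 * E / (b + std::sqrt(disc));
}

// [[Rcpp::export(name = ".ssaLinearBD")]]
IntegerMatrix ssaLinearBD(double lambda0, double slope, double delta,
                          int n0, NumericVector sampleTimes,
                          int nReps, int method) {
  const int nt = sampleTimes.size();
  IntegerMatrix out(nReps, nt);
  const double tEnd = sampleTimes[nt - 1];
  for (int r = 0; r < nReps; ++r) {
    double t = 0.0;
    int n = n0, si = 0;
    while (si < nt) {
      double lamNow = lambda0 + slope * t;
      double tNext;
      int doBirth = -1;  // -1 none, 1 birth, 0 death
      if (method == 0) {  // thinning against the interval maximum
        double lamMax = std::max(lamNow, lambda0 + slope * tEnd);
        double B = lamMax + delta * n;
        if (B <= 0.0) { tNext = R_PosInf; }
        else {
          tNext = t + R::exp_rand() / B;
          if (tNext <= tEnd) {
            double u = unif_rand() * B;
            double lamAt = lambda0 + slope * tNext;
            if (u < lamAt) doBirth = 1;
            else if (u < lamAt + delta * n) doBirth = 0;
            // else: thinned, no event
          }
        }
      } else {            // integrated-hazard inversion
        double tau = hazardInvert(delta * n, lamNow, slope, tEnd - t,
                                  R::exp_rand());
        tNext = t + tau;
        if (tNext <= tEnd) {
          double lamAt = lambda0 + slope * tNext;
          double u = unif_rand() * (lamAt + delta * n);
          doBirth = (u < lamAt) ? 1 : 0;
        }
      }
      while (si < nt && sampleTimes[si] < std::min(tNext, tEnd + 1e-300)) {
        out(r, si) = n; ++si;
      }
      if (si >= nt || !R_finite(tNext) || tNext > tEnd) {
        while (si < nt) { out(r, si) = n; ++si; }
        break;
      }
      t = tNext;
      if (doBirth == 1) ++n;
      else if (doBirth == 0) --n;
    }
  }
  return out;
}

// Dual-reporter lineage: two identically regulated genes (mRNA m1, m2 and
// proteins p1, p2) riding on a growing cell across several cell cycles.
// Per cycle k the shared mRNA birth rate is lam0[k] + slope[k] * t
// (t within the cycle), translation rate is lambdaP * tf[k] per mRNA, and
// at each division every species is split binomially (the lineage follows
// one daughter). Counts are returned at samplePhase of the last cycle.
// [[Rcpp::export(name = ".dualReporterLineage")]]
IntegerVector dualReporterLineage(NumericVector lam0, NumericVector slope,
                                  NumericVector cycleLen, NumericVector tf,
                                  double deltaM, double lambdaP,
                                  double deltaP, IntegerVector init,
                                  double samplePhase) {
  int nCyc = lam0.size();
  long long m1 = init[0], m2 = init[1], p1 = init[2], p2 = init[3];
  for (int k = 0; k < nCyc; ++k) {
    double L = cycleLen[k];
    double horizon = (k == nCyc - 1) ? samplePhase * L : L;
    double t = 0.0;
    double lpk = lambdaP * tf[k];
    while (true) {
      double aConst = deltaM * (m1 + m2) + lpk * (m1 + m2) +
                      deltaP * (p1 + p2);
      double lamNow = 2.0 * (lam0[k] + slope[k] * t);
      double tau = hazardInvert(aConst, lamNow, 2.0 * slope[k],
                                horizon - t, R::exp_rand());
      if (!R_finite(tau) || t + tau > horizon) break;
      t += tau;
      double lamAt = lam0[k] + slope[k] * t;
      double tot = aConst + 2.0 * lamAt;
      double u = unif_rand() * tot;
      if ((u -= lamAt) < 0) { ++m1; continue; }
      if ((u -= lamAt) < 0) { ++m2; continue; }
      if ((u -= deltaM * m1) < 0) { --m1; continue; }
      if ((u -= deltaM * m2) < 0) { --m2; continue; }
      if ((u -= lpk * m1) < 0) { ++p1; continue; }
      if ((u -= lpk * m2) < 0) { ++p2; continue; }
      if ((u -= deltaP * p1) < 0) { --p1; continue; }
      --p2;
    }
    if (k < nCyc - 1) {  // mitosis: binomial inheritance of every species
      m1 = (long long) R::rbinom((double) m1, 0.5);
      m2 = (long long) R::rbinom((double) m2, 0.5);
      p1 = (long long) R::rbinom((double) p1, 0.5);
      p2 = (long long) R::rbinom((double) p2, 0.5);
    }
  }
  return IntegerVector::create((int) m1, (int) m2, (int) p1, (int) p2);
}

// ---- fate-model ODEs -------------------------------------------------------

static inline double hillAct(double x, double thn, double n) {
  double xn = std::pow(x, n);
  return xn / (thn + xn);
}

// model 0: symmetric self-activation / cross-repression (Huang)
//   pars = a, b, k, theta, n
// model 1: Huang-type core + species X promoted by GATA1 and repressing
//   all PU.1 production; pars = a, b, k, theta, n, sG, sP, sX, aX, cX, kX
static void fateRhs(int model, double phi, const double* pars,
                    const double* y, double* dy) {
  double a = pars[0], b = pars[1], k = pars[2], th = pars[3], n = pars[4];
  double thn = std::pow(th, n);
  if (model == 0) {
    double x1 = std::max(y[0], 0.0), x2 = std::max(y[1], 0.0);
    dy[0] = phi * (a * hillAct(x1, thn, n) + b * thn / (thn + std::pow(x2, n)))
            - k * x1;
    dy[1] = phi * (a * hillAct(x2, thn, n) + b * thn / (thn + std::pow(x1, n)))
            - k * x2;
  } else {
    double sG = pars[5], sP = pars[6], sX = pars[7];
    double aX = pars[8], cX = pars[9], kX = pars[10];
    double G = std::max(y[0], 0.0), P = std::max(y[1], 0.0),
           X = std::max(y[2], 0.0);
    dy[0] = phi * (a * hillAct(G, thn, n) + b * thn / (thn + std::pow(P, n))
                   + sG) - k * G;
    dy[1] = phi * (a * hillAct(P, thn, n) + b * thn / (thn + std::pow(G, n))
                   + sP) / (1.0 + cX * X) - k * P;
    dy[2] = phi * aX * G * G / (1.0 + sX) - kX * X;
  }
}

// Cash-Karp embedded RK4(5) with step control; integration stops when the
// right-hand side's max norm falls below rhsTol (converged) or t exceeds
// tMax (unresolved).
// [[Rcpp::export(name = ".fateEndpoints")]]
List fateEndpoints(int model, double phi, NumericVector pars,
                   NumericMatrix inits, double tMax, double rhsTol,
                   double stepTol) {
  const int d = (model == 0) ? 2 : 3;
  const int np = inits.nrow();
  NumericMatrix ends(np, d);
  LogicalVector conv(np);
  static const double
    b21 = 1.0/5,
    b31 = 3.0/40, b32 = 9.0/40,
    b41 = 3.0/10, b42 = -9.0/10, b43 = 6.0/5,
    b51 = -11.0/54, b52 = 5.0/2, b53 = -70.0/27, b54 = 35.0/27,
    b61 = 1631.0/55296, b62 = 175.0/512, b63 = 575.0/13824,
    b64 = 44275.0/110592, b65 = 253.0/4096,
    c1 = 37.0/378, c3 = 250.0/621, c4 = 125.0/594, c6 = 512.0/1771,
    dc1 = c1 - 2825.0/27648, dc3 = c3 - 18575.0/48384,
    dc4 = c4 - 13525.0/55296, dc5 = -277.0/14336, dc6 = c6 - 1.0/4;
  std::vector<double> y(d), yt(d), k1(d), k2(d), k3(d), k4(d), k5(d), k6(d);
  const double* pp = pars.begin();
  for (int ip = 0; ip < np; ++ip) {
    for (int j = 0; j < d; ++j) y[j] = inits(ip, j);
    double t = 0.0, h = 0.01;
    bool ok = false;
    while (t < tMax) {
      fateRhs(model, phi, pp, y.data(), k1.data());
      double rmax = 0.0;
      for (int j = 0; j < d; ++j) rmax = std::max(rmax, std::fabs(k1[j]));
      if (rmax < rhsTol) { ok = true; break; }
      if (t + h > tMax) h = tMax - t;
      // Cash-Karp stages
      for (int j = 0; j < d; ++j) yt[j] = y[j] + h * b21 * k1[j];
      fateRhs(model, phi, pp, yt.data(), k2.data());
      for (int j = 0; j < d; ++j)
        yt[j] = y[j] + h * (b31 * k1[j] + b32 * k2[j]);
      fateRhs(model, phi, pp, yt.data(), k3.data());
      for (int j = 0; j < d; ++j)
        yt[j] = y[j] + h * (b41 * k1[j] + b42 * k2[j] + b43 * k3[j]);
      fateRhs(model, phi, pp, yt.data(), k4.data());
      for (int j = 0; j < d; ++j)
        yt[j] = y[j] + h * (b51 * k1[j] + b52 * k2[j] + b53 * k3[j] +
                            b54 * k4[j]);
      fateRhs(model, phi, pp, yt.data(), k5.data());
      for (int j = 0; j < d; ++j)
        yt[j] = y[j] + h * (b61 * k1[j] + b62 * k2[j] + b63 * k3[j] +
                            b64 * k4[j] + b65 * k5[j]);
      fateRhs(model, phi, pp, yt.data(), k6.data());
      double err = 0.0;
      for (int j = 0; j < d; ++j) {
        double e = h * (dc1 * k1[j] + dc3 * k3[j] + dc4 * k4[j] +
                        dc5 * k5[j] + dc6 * k6[j]);
        err = std::max(err, std::fabs(e));
      }
      if (err > stepTol && h > 1e-10) {
        h = std::max(1e-10, 0.9 * h * std::pow(stepTol / err, 0.25));
        continue;
      }
      for (int j = 0; j < d; ++j) {
        y[j] += h * (c1 * k1[j] + c3 * k3[j] + c4 * k4[j] + c6 * k6[j]);
        if (y[j] < 0.0) y[j] = 0.0;   // production is bounded, decay linear
      }
      t += h;
      double grow = (err > 0.0) ? 0.9 * std::pow(stepTol / err, 0.2) : 5.0;
      h *= std::min(5.0, std::max(0.2, grow));
    }
    for (int j = 0; j < d; ++j) ends(ip, j) = y[j];
    conv[ip] = ok;
  }
  return List::create(_["endpoints"] = ends, _["converged"] = conv);
}
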