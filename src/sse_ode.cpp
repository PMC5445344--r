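// State-dependent speciation-extinction pruning likelihoods.
//
// Per-branch integration of the coupled E/D ordinary differential
// equations with an adaptive Cash-Karp Runge-Kutta (4,5) scheme
// (absolute tolerance 1e-10, relative 1e-8 by default); partial
// likelihoods D are renormalized at every branch and node with an
// accumulated log scaler to prevent underflow on large trees.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

typedef void (*deriv_fn)(const double *y, double *dy, int k,
                         const double *pars);

// MuSSE with k states: y = (E_1..E_k, D_1..D_k).
// pars layout: lambda[k], mu[k], Q[k*k] row-major (Q[i*k+j] = rate i->j,
// diagonal ignored).
static void musse_deriv(const double *y, double *dy, int k,
                        const double *pars) {
  const double *lambda = pars, *mu = pars + k, *Q = pars + 2 * k;
  const double *E = y, *D = y + k;
  for (int i = 0; i < k; ++i) {
    double qi = 0.0, qE = 0.0, qD = 0.0;
    for (int j = 0; j < k; ++j) {
      if (j == i) continue;
      double q = Q[i * k + j];
      qi += q;
      qE += q * E[j];
      qD += q * D[j];
    }
    double tot = lambda[i] + mu[i] + qi;
    dy[i] = mu[i] - tot * E[i] + lambda[i] * E[i] * E[i] + qE;
    dy[k + i] = -tot * D[i] + 2.0 * lambda[i] * E[i] * D[i] + qD;
  }
}

// GeoSSE: states 0 = A, 1 = B, 2 = AB; y = (E_A,E_B,E_AB,D_A,D_B,D_AB).
// pars: sA, sB, sAB, xA, xB, dA, dB.
static void geosse_deriv(const double *y, double *dy, int k,
                         const double *pars) {
  (void)k;
  const double sA = pars[0], sB = pars[1], sAB = pars[2];
  const double xA = pars[3], xB = pars[4], dA = pars[5], dB = pars[6];
  const double EA = y[0], EB = y[1], EAB = y[2];
  const double DA = y[3], DB = y[4], DAB = y[5];
  dy[0] = xA - (sA + dA + xA) * EA + sA * EA * EA + dA * EAB;
  dy[1] = xB - (sB + dB + xB) * EB + sB * EB * EB + dB * EAB;
  dy[2] = -(sA + sB + sAB + xA + xB) * EAB + xA * EB + xB * EA
          + sA * EA * EAB + sB * EB * EAB + sAB * EA * EB;
  dy[3] = -(sA + dA + xA) * DA + 2.0 * sA * EA * DA + dA * DAB;
  dy[4] = -(sB + dB + xB) * DB + 2.0 * sB * EB * DB + dB * DAB;
  dy[5] = -(sA + sB + sAB + xA + xB) * DAB
          + xA * DB + xB * DA
          + sA * (EA * DAB + EAB * DA)
          + sB * (EB * DAB + EAB * DB)
          + sAB * (EA * DB + EB * DA);
}

// Cash-Karp tableau.
static const double CK_B[6][5] = {
    {0, 0, 0, 0, 0},
    {1.0 / 5, 0, 0, 0, 0},
    {3.0 / 40, 9.0 / 40, 0, 0, 0},
    {3.0 / 10, -9.0 / 10, 6.0 / 5, 0, 0},
    {-11.0 / 54, 5.0 / 2, -70.0 / 27, 35.0 / 27, 0},
    {1631.0 / 55296, 175.0 / 512, 575.0 / 13824, 44275.0 / 110592,
     253.0 / 4096}};
static const double CK_C[6] = {37.0 / 378, 0, 250.0 / 621, 125.0 / 594, 0,
                               512.0 / 1771};
static const double CK_DC[6] = {
    37.0 / 378 - 2825.0 / 27648, 0, 250.0 / 621 - 18575.0 / 48384,
    125.0 / 594 - 13525.0 / 55296, -277.0 / 14336, 512.0 / 1771 - 0.25};

// Integrate y over [0, len] with adaptive step control. Returns false if
// the step size underflows or the step budget is exhausted (treated by the
// caller as an impossible parameter region).
static bool integrate(deriv_fn f, std::vector<double> &y, int dim, int k,
                      const double *pars, double len, double atol,
                      double rtol) {
  if (len <= 0.0) return true;
  std::vector<double> ytmp(dim), yerr(dim), ks(6 * dim);
  double t = 0.0;
  double h = len / 10.0;
  if (h <= 0.0) h = len;
  int guard = 0;
  while (t < len && ++guard < 1000000) {
    if (t + h > len) h = len - t;
    // stages
    f(y.data(), &ks[0], k, pars);
    for (int s = 1; s < 6; ++s) {
      for (int i = 0; i < dim; ++i) {
        double acc = y[i];
        for (int q = 0; q < s; ++q) acc += h * CK_B[s][q] * ks[q * dim + i];
        ytmp[i] = acc;
      }
      f(ytmp.data(), &ks[s * dim], k, pars);
    }
    double errmax = 0.0;
    for (int i = 0; i < dim; ++i) {
      double dy5 = 0.0, err = 0.0;
      for (int s = 0; s < 6; ++s) {
        dy5 += CK_C[s] * ks[s * dim + i];
        err += CK_DC[s] * ks[s * dim + i];
      }
      ytmp[i] = y[i] + h * dy5;
      double sc = atol + rtol * std::fabs(ytmp[i]);
      double e = std::fabs(h * err) / sc;
      if (e > errmax) errmax = e;
    }
    if (errmax <= 1.0) {
      t += h;
      y = ytmp;
      double fac = (errmax > 1e-12) ? 0.9 * std::pow(errmax, -0.2) : 5.0;
      if (fac > 5.0) fac = 5.0;
      h *= fac;
    } else {
      double fac = 0.9 * std::pow(errmax, -0.25);
      if (fac < 0.2) fac = 0.2;
      h *= fac;
    }
    if (h < 1e-14 * len) return false;
  }
  return guard < 1000000;
}

// Shared pruning driver. family: 0 = musse, 1 = geosse.
// edge: (2N-2) x 2 (1-based ape node ids) in postorder; tip_d: ntip x k
// initial D rows; e0: length-k initial E.
static List prune(int family, const IntegerMatrix &edge,
                  const NumericVector &edge_length, int ntip,
                  const NumericMatrix &tip_d, const NumericVector &e0,
                  const NumericVector &pars, double atol, double rtol) {
  const int k = e0.size();
  const int dim = 2 * k;
  const int nnode = ntip + (int)edge.nrow() / 2 + 1;  // total node count
  deriv_fn f = (family == 0) ? musse_deriv : geosse_deriv;

  // per-node accumulators
  std::vector<std::vector<double>> partE(nnode + 1), partD(nnode + 1);
  std::vector<double> logsc(nnode + 1, 0.0);
  std::vector<int> seen(nnode + 1, 0);
  std::vector<double> lambda_node;  // node combination rates (musse)
  if (family == 0) {
    lambda_node.assign(pars.begin(), pars.begin() + k);
  }

  int root = edge(edge.nrow() - 1, 0);  // postorder: last edge's parent

  for (int ei = 0; ei < edge.nrow(); ++ei) {
    int parent = edge(ei, 0), child = edge(ei, 1);
    std::vector<double> y(dim);
    double base_log = 0.0;
    if (child <= ntip) {
      for (int i = 0; i < k; ++i) {
        y[i] = e0[i];
        y[k + i] = tip_d(child - 1, i);
      }
    } else {
      for (int i = 0; i < k; ++i) {
        y[i] = partE[child][i];
        y[k + i] = partD[child][i];
      }
      base_log = logsc[child];
    }
    bool finite =
        integrate(f, y, dim, k, pars.begin(), edge_length[ei], atol, rtol);
    // renormalize D; parameter regions where the integration overflows or
    // stalls are reported as impossible (-Inf) rather than as an error so
    // optimizers can back away from them
    for (int i = 0; i < dim; ++i)
      if (!R_finite(y[i])) finite = false;
    double s = 0.0;
    for (int i = 0; i < k; ++i) s += y[k + i];
    if (finite && s > 0.0) {
      for (int i = 0; i < k; ++i) y[k + i] /= s;
      base_log += std::log(s);
    } else {
      for (int i = 0; i < k; ++i) {
        y[i] = 0.5;                       // keep E sane for the ancestors
        y[k + i] = (i == 0) ? 1.0 : 0.0;
      }
      base_log = R_NegInf;
    }
    // deposit at parent
    if (!seen[parent]) {
      partE[parent].assign(y.begin(), y.begin() + k);
      partD[parent].assign(y.begin() + k, y.end());
      logsc[parent] = base_log;
      seen[parent] = 1;
    } else {
      // combine with stored sibling
      std::vector<double> El = partE[parent], Dl = partD[parent];
      std::vector<double> Er(y.begin(), y.begin() + k),
          Dr(y.begin() + k, y.end());
      std::vector<double> Dn(k), En(k);
      for (int i = 0; i < k; ++i) En[i] = 0.5 * (El[i] + Er[i]);
      if (family == 0) {
        for (int i = 0; i < k; ++i) Dn[i] = lambda_node[i] * Dl[i] * Dr[i];
      } else {
        const double sA = pars[0], sB = pars[1], sAB = pars[2];
        Dn[0] = sA * Dl[0] * Dr[0];
        Dn[1] = sB * Dl[1] * Dr[1];
        Dn[2] = 0.5 * (sA * (Dl[2] * Dr[0] + Dl[0] * Dr[2]) +
                       sB * (Dl[2] * Dr[1] + Dl[1] * Dr[2]) +
                       sAB * (Dl[0] * Dr[1] + Dl[1] * Dr[0]));
      }
      double s2 = 0.0;
      for (int i = 0; i < k; ++i) s2 += Dn[i];
      double lg = logsc[parent] + base_log;
      if (s2 > 0.0 && R_finite(s2)) {
        for (int i = 0; i < k; ++i) Dn[i] /= s2;
        lg += std::log(s2);
      } else {
        lg = R_NegInf;
      }
      partE[parent] = En;
      partD[parent] = Dn;
      logsc[parent] = lg;
    }
  }

  NumericVector Dr(k), Er(k);
  for (int i = 0; i < k; ++i) {
    Dr[i] = partD[root][i];
    Er[i] = partE[root][i];
  }
  return List::create(_["d_root"] = Dr, _["e_root"] = Er,
                      _["log_scale"] = logsc[root]);
}

// [[Rcpp::export]]
List musse_prune_cpp(IntegerMatrix edge, NumericVector edge_length, int ntip,
                     NumericMatrix tip_d, NumericVector e0,
                     NumericVector lambda, NumericVector mu, NumericMatrix Q,
                     double atol = 1e-10, double rtol = 1e-8) {
  int k = lambda.size();
  NumericVector pars(2 * k + k * k);
  for (int i = 0; i < k; ++i) {
    pars[i] = lambda[i];
    pars[k + i] = mu[i];
    for (int j = 0; j < k; ++j) pars[2 * k + i * k + j] = Q(i, j);
  }
  return prune(0, edge, edge_length, ntip, tip_d, e0, pars, atol, rtol);
}

// [[Rcpp::export]]
List geosse_prune_cpp(IntegerMatrix edge, NumericVector edge_length, int ntip,
                      NumericMatrix tip_d, NumericVector e0,
                      NumericVector pars, double atol = 1e-10,
                      double rtol = 1e-8) {
  return prune(1, edge, edge_length, ntip, tip_d, e0, pars, atol, rtol);
}
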