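// Mass-action ODE core: Dormand-Prince RK45 with forward sensitivities and
// the latent-trajectory observation log-likelihood with analytic gradients.
//
// State layout for the augmented system: y = [Z (N), dZ/dp_1 (N), ..., dZ/dp_Ns (N)]
// where each sensitivity parameter p is either a free reaction rate k_d or an
// initial-state coordinate (when the initial state is inferred).

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

struct ReactionTerm {
  int sp;   // species index
  int cnt;  // multiplicity (1 or 2)
};

struct CRNSystem {
  int N;  // species
  int D;  // reactions
  std::vector<std::vector<ReactionTerm>> reactants;  // per reaction, <=2 entries
  std::vector<double> stoich;  // D x N, row-major: net change
  double S(int d, int n) const { return stoich[(size_t)d * N + n]; }
};

CRNSystem make_system(const IntegerMatrix& stoich, const IntegerMatrix& rcount) {
  CRNSystem sys;
  sys.D = stoich.nrow();
  sys.N = stoich.ncol();
  sys.stoich.resize((size_t)sys.D * sys.N);
  sys.reactants.resize(sys.D);
  for (int d = 0; d < sys.D; ++d) {
    for (int n = 0; n < sys.N; ++n) {
      sys.stoich[(size_t)d * sys.N + n] = stoich(d, n);
      int c = rcount(d, n);
      if (c > 0) sys.reactants[d].push_back({n, c});
    }
  }
  return sys;
}

// mass-action rate basis f_d(Z) = prod over reactants of Z^cnt
inline void calc_f(const CRNSystem& sys, const double* Z, double* f) {
  for (int d = 0; d < sys.D; ++d) {
    double v = 1.0;
    for (const auto& rt : sys.reactants[d]) {
      v *= (rt.cnt == 2) ? Z[rt.sp] * Z[rt.sp] : Z[rt.sp];
    }
    f[d] = v;
  }
}

// J[n][m] = d(rhs_n)/dZ_m = sum_d S(d,n) k_d df_d/dZ_m
void calc_jac(const CRNSystem& sys, const double* Z, const double* k, double* J) {
  const int N = sys.N;
  std::fill(J, J + (size_t)N * N, 0.0);
  for (int d = 0; d < sys.D; ++d) {
    const auto& rs = sys.reactants[d];
    if (rs.empty()) continue;
    // df_d/dZ_m for each reactant m
    for (size_t i = 0; i < rs.size(); ++i) {
      double g;
      if (rs[i].cnt == 2) {
        g = 2.0 * Z[rs[i].sp];
      } else {
        g = 1.0;
        for (size_t j = 0; j < rs.size(); ++j)
          if (j != i) g *= (rs[j].cnt == 2) ? Z[rs[j].sp] * Z[rs[j].sp] : Z[rs[j].sp];
      }
      double kg = k[d] * g;
      int m = rs[i].sp;
      for (int n = 0; n < N; ++n) {
        double s = sys.S(d, n);
        if (s != 0.0) J[(size_t)n * N + m] += s * kg;
      }
    }
  }
}

struct AugmentedRHS {
  const CRNSystem* sys;
  const double* k;
  int Ns;                       // number of sensitivity parameters
  std::vector<int> sens_rxn;    // free reaction index per sens param, -1 for x0 sens
  mutable std::vector<double> f, J;

  void init(const CRNSystem& s, const double* kk, int ns) {
    sys = &s; k = kk; Ns = ns;
    f.resize(s.D);
    J.resize((size_t)s.N * s.N);
  }

  void operator()(const double* y, double* dy) const {
    const int N = sys->N, D = sys->D;
    calc_f(*sys, y, f.data());
    for (int n = 0; n < N; ++n) {
      double v = 0.0;
      for (int d = 0; d < D; ++d) {
        double s = sys->S(d, n);
        if (s != 0.0) v += s * k[d] * f[d];
      }
      dy[n] = v;
    }
    if (Ns == 0) return;
    calc_jac(*sys, y, k, J.data());
    for (int p = 0; p < Ns; ++p) {
      const double* u = y + (size_t)(p + 1) * N;
      double* du = dy + (size_t)(p + 1) * N;
      for (int n = 0; n < N; ++n) {
        double v = 0.0;
        const double* Jrow = J.data() + (size_t)n * N;
        for (int m = 0; m < N; ++m) v += Jrow[m] * u[m];
        du[n] = v;
      }
      int d = sens_rxn[p];
      if (d >= 0) {  // forcing term: d(rhs)/dk_d = S(d,.) * f_d
        double fd = f[d];
        for (int n = 0; n < N; ++n) {
          double s = sys->S(d, n);
          if (s != 0.0) du[n] += s * fd;
        }
      }
    }
  }
};

// Dormand-Prince 5(4) coefficients
const double c2 = 1.0 / 5, c3 = 3.0 / 10, c4 = 4.0 / 5, c5 = 8.0 / 9;
const double a21 = 1.0 / 5;
const double a31 = 3.0 / 40, a32 = 9.0 / 40;
const double a41 = 44.0 / 45, a42 = -56.0 / 15, a43 = 32.0 / 9;
const double a51 = 19372.0 / 6561, a52 = -25360.0 / 2187, a53 = 64448.0 / 6561,
             a54 = -212.0 / 729;
const double a61 = 9017.0 / 3168, a62 = -355.0 / 33, a63 = 46732.0 / 5247,
             a64 = 49.0 / 176, a65 = -5103.0 / 18656;
const double b1 = 35.0 / 384, b3 = 500.0 / 1113, b4 = 125.0 / 192,
             b5 = -2187.0 / 6784, b6 = 11.0 / 84;
const double e1 = 35.0 / 384 - 5179.0 / 57600, e3 = 500.0 / 1113 - 7571.0 / 16695,
             e4 = 125.0 / 192 - 393.0 / 640, e5 = -2187.0 / 6784 + 92097.0 / 339200,
             e6 = 11.0 / 84 - 187.0 / 2100, e7 = -1.0 / 40;

// Integrates the augmented system; calls `record(j, y)` at each requested
// output time (including times[0]). Steps are chosen adaptively by the error
// estimate alone; outputs inside a step come from the 5th-order dense-output
// interpolant, so dense observation grids do not force small steps.
// Returns false on failure.
template <typename Recorder>
bool rk45_integrate(const AugmentedRHS& rhs, std::vector<double>& y,
                    const NumericVector& times, double rtol, double atol,
                    int max_steps, Recorder record, int n_err = 0) {
  const size_t M = y.size();
  const size_t Merr = (n_err > 0 && (size_t)n_err < M) ? (size_t)n_err : M;
  const int T = times.size();
  // dense-output weights (Hairer's DOPRI5 contd5)
  const double d1 = -12715105075.0 / 11282082432.0,
               d3 = 87487479700.0 / 32700410799.0,
               d4 = -10690763975.0 / 1880347072.0,
               d5 = 701980252875.0 / 199316789632.0,
               d6 = -1453857185.0 / 822651844.0,
               d7 = 69997945.0 / 29380423.0;
  std::vector<double> k1(M), k2(M), k3(M), k4(M), k5(M), k6(M), k7(M),
      ytmp(M), ynew(M);
  double t = times[0];
  const double tfinal = times[T - 1];
  record(0, y.data());
  int j = 1;  // next output index
  if (T == 1) return true;
  rhs(y.data(), k1.data());
  // initial step heuristic
  double h;
  {
    double ny = 0.0, nf = 0.0;
    for (size_t i = 0; i < M; ++i) {
      ny = std::max(ny, std::abs(y[i]));
      nf = std::max(nf, std::abs(k1[i]));
    }
    h = (nf > 1e-12) ? 0.01 * std::max(ny, 1.0) / nf : 1e-3;
    h = std::min(h, tfinal - t);
  }
  int steps = 0;
  while (j < T) {
    if (++steps > max_steps) return false;
    double hstep = std::min(h, tfinal - t);
    // stages
    for (size_t i = 0; i < M; ++i) ytmp[i] = y[i] + hstep * a21 * k1[i];
    rhs(ytmp.data(), k2.data());
    for (size_t i = 0; i < M; ++i)
      ytmp[i] = y[i] + hstep * (a31 * k1[i] + a32 * k2[i]);
    rhs(ytmp.data(), k3.data());
    for (size_t i = 0; i < M; ++i)
      ytmp[i] = y[i] + hstep * (a41 * k1[i] + a42 * k2[i] + a43 * k3[i]);
    rhs(ytmp.data(), k4.data());
    for (size_t i = 0; i < M; ++i)
      ytmp[i] = y[i] + hstep * (a51 * k1[i] + a52 * k2[i] + a53 * k3[i] +
                                a54 * k4[i]);
    rhs(ytmp.data(), k5.data());
    for (size_t i = 0; i < M; ++i)
      ytmp[i] = y[i] + hstep * (a61 * k1[i] + a62 * k2[i] + a63 * k3[i] +
                                a64 * k4[i] + a65 * k5[i]);
    rhs(ytmp.data(), k6.data());
    for (size_t i = 0; i < M; ++i)
      ynew[i] = y[i] + hstep * (b1 * k1[i] + b3 * k3[i] + b4 * k4[i] +
                                b5 * k5[i] + b6 * k6[i]);
    rhs(ynew.data(), k7.data());
    // error estimate
    double errsq = 0.0;
    bool finite = true;
    for (size_t i = 0; i < Merr; ++i) {
      double err = hstep * (e1 * k1[i] + e3 * k3[i] + e4 * k4[i] +
                            e5 * k5[i] + e6 * k6[i] + e7 * k7[i]);
      double sc = atol + rtol * std::max(std::abs(y[i]), std::abs(ynew[i]));
      double r = err / sc;
      errsq += r * r;
    }
    for (size_t i = 0; i < M; ++i)
      if (!std::isfinite(ynew[i])) finite = false;
    double errnorm = std::sqrt(errsq / Merr);
    if (finite && errnorm <= 1.0) {
      double tnew = t + hstep;
      // emit outputs inside (t, tnew] via the dense-output interpolant
      const double eps_t = 1e-10 * std::max(1.0, std::abs(tnew));
      while (j < T && times[j] <= tnew + eps_t) {
        double theta = (times[j] - t) / hstep;
        if (theta >= 1.0) {
          record(j, ynew.data());
        } else {
          double th1 = 1.0 - theta;
          for (size_t i = 0; i < M; ++i) {
            double ydiff = ynew[i] - y[i];
            double bspl = hstep * k1[i] - ydiff;
            double r4 = ydiff - hstep * k7[i] - bspl;
            double r5 = hstep * (d1 * k1[i] + d3 * k3[i] + d4 * k4[i] +
                                 d5 * k5[i] + d6 * k6[i] + d7 * k7[i]);
            ytmp[i] = y[i] +
                theta * (ydiff + th1 * (bspl + theta * (r4 + th1 * r5)));
          }
          record(j, ytmp.data());
        }
        ++j;
      }
      t = tnew;
      std::swap(y, ynew);
      std::swap(k1, k7);  // FSAL
      for (int n = 0; n < rhs.sys->N; ++n)
        if (std::abs(y[n]) > 1e12) return false;
      double fac = 0.9 * std::pow(std::max(errnorm, 1e-10), -0.2);
      fac = std::min(5.0, std::max(0.2, fac));
      h = hstep * fac;
    } else {
      if (!finite) {
        h = hstep * 0.2;
      } else {
        double fac = 0.9 * std::pow(errnorm, -0.2);
        h = hstep * std::min(1.0, std::max(0.1, fac));
      }
      if (h < 1e-14 * std::max(1.0, std::abs(t))) return false;
    }
  }
  return true;
}

}  // namespace

// [[Rcpp::export]]
List crn_simulate_cpp(IntegerMatrix stoich, IntegerMatrix rcount,
                      NumericVector k, NumericVector x0, NumericVector times,
                      double rtol, double atol, int max_steps) {
  CRNSystem sys = make_system(stoich, rcount);
  if ((int)k.size() != sys.D) stop("rate vector length does not match library");
  if ((int)x0.size() != sys.N) stop("initial state length does not match library");
  AugmentedRHS rhs;
  rhs.init(sys, REAL(k), 0);
  std::vector<double> y(x0.begin(), x0.end());
  NumericMatrix states(times.size(), sys.N);
  bool ok = rk45_integrate(rhs, y, times, rtol, atol, max_steps,
                           [&](int j, const double* yy) {
                             for (int n = 0; n < sys.N; ++n) states(j, n) = yy[n];
                           });
  return List::create(_["states"] = states, _["ok"] = ok);
}

// Latent-ODE observation log-likelihood and gradient.
//
// obs_list:   list of L replicate observation matrices (T x Mobs)
// obsmap:     Mobs x N matrix A; observed mean is A %*% Z(t_j)
// free_idx:   0-based reaction indices whose rate sensitivities are required
// sens_x0:    also compute d(loglik)/d(x0)
// noise:      0 = log-normal (median Z), 1 = Poisson (mean Z)
// [[Rcpp::export]]
List crn_loglik_grad_cpp(IntegerMatrix stoich, IntegerMatrix rcount,
                         NumericVector k, IntegerVector free_idx,
                         NumericVector x0, bool sens_x0, NumericVector times,
                         List obs_list, NumericMatrix obsmap, double sigma,
                         int noise, double rtol, double atol, int max_steps,
                         bool err_z_only) {
  CRNSystem sys = make_system(stoich, rcount);
  const int N = sys.N;
  const int T = times.size();
  const int Mobs = obsmap.nrow();
  const int Df = free_idx.size();
  const int Ns = Df + (sens_x0 ? N : 0);
  const int L = obs_list.size();
  const double floor_eps = 1e-10;  // positivity floor inside the likelihood only

  AugmentedRHS rhs;
  rhs.init(sys, REAL(k), Ns);
  rhs.sens_rxn.resize(Ns);
  for (int p = 0; p < Df; ++p) rhs.sens_rxn[p] = free_idx[p];
  for (int p = Df; p < Ns; ++p) rhs.sens_rxn[p] = -1;

  std::vector<double> y((size_t)N * (1 + Ns), 0.0);
  for (int n = 0; n < N; ++n) y[n] = x0[n];
  if (sens_x0)
    for (int n = 0; n < N; ++n) y[(size_t)(Df + 1 + n) * N + n] = 1.0;

  std::vector<NumericMatrix> obs;
  for (int l = 0; l < L; ++l) obs.push_back(as<NumericMatrix>(obs_list[l]));

  double loglik = 0.0, grad_sigma = 0.0;
  std::vector<double> grad_p(Ns, 0.0);
  std::vector<double> dLdZ(N), mu(Mobs);
  const double log2pi = std::log(2.0 * M_PI);
  bool bad = false;

  bool ok = rk45_integrate(
      rhs, y, times, rtol, atol, max_steps, [&](int j, const double* yy) {
        if (bad) return;
        // observed means
        for (int m = 0; m < Mobs; ++m) {
          double v = 0.0;
          for (int n = 0; n < N; ++n) v += obsmap(m, n) * yy[n];
          mu[m] = v;
        }
        std::fill(dLdZ.begin(), dLdZ.end(), 0.0);
        for (int m = 0; m < Mobs; ++m) {
          double mum = std::max(mu[m], floor_eps);
          double dLdmu = 0.0;
          for (int l = 0; l < L; ++l) {
            double x = obs[l](j, m);
            if (noise == 0) {
              double r = std::log(x) - std::log(mum);
              loglik += -std::log(x) - std::log(sigma) - 0.5 * log2pi -
                        0.5 * r * r / (sigma * sigma);
              grad_sigma += -1.0 / sigma + r * r / (sigma * sigma * sigma);
              dLdmu += r / (sigma * sigma * mum);
            } else {
              loglik += x * std::log(mum) - mum - std::lgamma(x + 1.0);
              dLdmu += x / mum - 1.0;
            }
          }
          if (mu[m] > floor_eps) {
            for (int n = 0; n < N; ++n) dLdZ[n] += obsmap(m, n) * dLdmu;
          }
        }
        if (!std::isfinite(loglik)) bad = true;
        for (int p = 0; p < Ns; ++p) {
          const double* u = yy + (size_t)(p + 1) * N;
          double acc = 0.0;
          for (int n = 0; n < N; ++n) acc += u[n] * dLdZ[n];
          grad_p[p] += acc;
        }
      },
      err_z_only ? N : 0);

  ok = ok && !bad && std::isfinite(loglik);
  NumericVector gk(Df), gx0(sens_x0 ? N : 0);
  for (int p = 0; p < Df; ++p) gk[p] = grad_p[p];
  if (sens_x0)
    for (int n = 0; n < N; ++n) gx0[n] = grad_p[Df + n];
  return List::create(_["loglik"] = loglik, _["grad_k"] = gk,
                      _["grad_sigma"] = grad_sigma, _["grad_x0"] = gx0,
                      _["ok"] = ok);
}
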