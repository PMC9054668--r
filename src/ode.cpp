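#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Reaction-network right-hand side and an adaptive Dormand-Prince 5(4)
// integrator. The network is passed as flat arrays (see as_cnet() on the R
// side): law 0 = mass action (optional Hill gate on a modifier species),
// law 1 = saturable single-substrate (Hill; Michaelis-Menten when n = 1).
// Rate laws clip negative concentrations at 0 so solver noise below the
// abs-tol floor cannot generate spurious negative fluxes.

struct CNet {
  int ns, nr;
  std::vector<int> law, mod, rptr, ridx, rsto, pptr, pidx, psto;
  std::vector<double> kf, kr, km, hn, vol;
  std::vector<int> clamp;
};

static inline double posc(double x) { return x > 0.0 ? x : 0.0; }

static CNet unpack(const List& net) {
  CNet N;
  N.ns = as<int>(net["ns"]);
  N.nr = as<int>(net["nr"]);
  N.law = as<std::vector<int> >(net["law"]);
  N.mod = as<std::vector<int> >(net["mod"]);
  N.rptr = as<std::vector<int> >(net["rptr"]);
  N.ridx = as<std::vector<int> >(net["ridx"]);
  N.rsto = as<std::vector<int> >(net["rsto"]);
  N.pptr = as<std::vector<int> >(net["pptr"]);
  N.pidx = as<std::vector<int> >(net["pidx"]);
  N.psto = as<std::vector<int> >(net["psto"]);
  N.kf = as<std::vector<double> >(net["kf"]);
  N.kr = as<std::vector<double> >(net["kr"]);
  N.km = as<std::vector<double> >(net["km"]);
  N.hn = as<std::vector<double> >(net["hn"]);
  N.vol = as<std::vector<double> >(net["vol"]);
  N.clamp = as<std::vector<int> >(net["clamp"]);
  return N;
}

static void rhs(const CNet& N, const double* y, double* dy) {
  for (int i = 0; i < N.ns; ++i) dy[i] = 0.0;
  for (int j = 0; j < N.nr; ++j) {
    double v = 0.0;
    if (N.law[j] == 0) {
      double vf = N.kf[j];
      for (int p = N.rptr[j]; p < N.rptr[j + 1]; ++p) {
        double c = posc(y[N.ridx[p]]);
        for (int s = 0; s < N.rsto[p]; ++s) vf *= c;
      }
      v = vf;
      if (N.kr[j] >= 0.0) {
        double vr = N.kr[j];
        for (int p = N.pptr[j]; p < N.pptr[j + 1]; ++p) {
          double c = posc(y[N.pidx[p]]);
          for (int s = 0; s < N.psto[p]; ++s) vr *= c;
        }
        v -= vr;
      }
      if (N.mod[j] >= 0) {
        double m = std::pow(posc(y[N.mod[j]]), N.hn[j]);
        v *= m / (std::pow(N.km[j], N.hn[j]) + m);
      }
    } else {  // saturable single-substrate law; kf plays the role of Vmax
      double S = (N.rptr[j] < N.rptr[j + 1]) ? posc(y[N.ridx[N.rptr[j]]]) : 1.0;
      double sn = std::pow(S, N.hn[j]);
      v = N.kf[j] * sn / (std::pow(N.km[j], N.hn[j]) + sn);
    }
    for (int p = N.rptr[j]; p < N.rptr[j + 1]; ++p) dy[N.ridx[p]] -= N.rsto[p] * v;
    for (int p = N.pptr[j]; p < N.pptr[j + 1]; ++p) dy[N.pidx[p]] += N.psto[p] * v;
  }
  for (int i = 0; i < N.ns; ++i) {
    dy[i] /= N.vol[i];
    if (N.clamp[i]) dy[i] = 0.0;
  }
}

// [[Rcpp::export]]
NumericVector ode_rhs_cpp(List net, NumericVector y) {
  CNet N = unpack(net);
  if ((int)y.size() != N.ns) stop("state length does not match network");
  NumericVector dy(N.ns);
  rhs(N, y.begin(), dy.begin());
  return dy;
}

// Dormand-Prince 5(4) coefficients
static const double c2 = 1.0 / 5, c3 = 3.0 / 10, c4 = 4.0 / 5, c5 = 8.0 / 9;
static const double a21 = 1.0 / 5;
static const double a31 = 3.0 / 40, a32 = 9.0 / 40;
static const double a41 = 44.0 / 45, a42 = -56.0 / 15, a43 = 32.0 / 9;
static const double a51 = 19372.0 / 6561, a52 = -25360.0 / 2187,
                    a53 = 64448.0 / 6561, a54 = -212.0 / 729;
static const double a61 = 9017.0 / 3168, a62 = -355.0 / 33, a63 = 46732.0 / 5247,
                    a64 = 49.0 / 176, a65 = -5103.0 / 18656;
static const double b1 = 35.0 / 384, b3 = 500.0 / 1113, b4 = 125.0 / 192,
                    b5 = -2187.0 / 6784, b6 = 11.0 / 84;
static const double e1 = 71.0 / 57600, e3 = -71.0 / 16695, e4 = 71.0 / 1920,
                    e5 = -17253.0 / 339200, e6 = 22.0 / 525, e7 = -1.0 / 40;

// Integrate from out_times[0] to out_times[last]; returns states at
// out_times (rows). Output between accepted steps uses cubic Hermite
// interpolation, which preserves linear invariants of the flow exactly.
// [[Rcpp::export]]
NumericMatrix ode_integrate_cpp(List net, NumericVector y0, NumericVector out_times,
                                double rtol, double atol, double max_step,
                                int max_steps) {
  CNet N = unpack(net);
  const int ns = N.ns;
  const int nout = out_times.size();
  if ((int)y0.size() != ns) stop("state length does not match network");
  if (nout < 1) stop("need at least one output time");
  NumericMatrix out(nout, ns);

  std::vector<double> y(y0.begin(), y0.end());
  std::vector<double> f(ns), ynew(ns), fnew(ns), ytmp(ns);
  std::vector<double> k2(ns), k3(ns), k4(ns), k5(ns), k6(ns);

  double t = out_times[0], tend = out_times[nout - 1];
  for (int i = 0; i < ns; ++i) out(0, i) = y[i];
  if (nout == 1 || tend <= t) {
    for (int r = 1; r < nout; ++r)
      for (int i = 0; i < ns; ++i) out(r, i) = y[i];
    return out;
  }

  rhs(N, y.data(), f.data());
  for (int i = 0; i < ns; ++i)
    if (!std::isfinite(f[i])) stop("non-finite derivative at t = %f", t);

  double span = tend - t;
  if (max_step <= 0.0) max_step = span;
  double h = std::min(span / 100.0, max_step);
  if (h <= 0.0) h = span;
  int iout = 1;
  long nstep = 0;
  bool rejected = false;

  while (t < tend) {
    if (++nstep > max_steps) stop("integrator exceeded %d steps at t = %f", max_steps, t);
    if (h > max_step) h = max_step;
    if (t + h > tend) h = tend - t;
    if (h < 1e-14 * std::max(1.0, std::fabs(t)))
      stop("step size underflow at t = %f", t);

    for (int i = 0; i < ns; ++i) ytmp[i] = y[i] + h * a21 * f[i];
    rhs(N, ytmp.data(), k2.data());
    for (int i = 0; i < ns; ++i) ytmp[i] = y[i] + h * (a31 * f[i] + a32 * k2[i]);
    rhs(N, ytmp.data(), k3.data());
    for (int i = 0; i < ns; ++i)
      ytmp[i] = y[i] + h * (a41 * f[i] + a42 * k2[i] + a43 * k3[i]);
    rhs(N, ytmp.data(), k4.data());
    for (int i = 0; i < ns; ++i)
      ytmp[i] = y[i] + h * (a51 * f[i] + a52 * k2[i] + a53 * k3[i] + a54 * k4[i]);
    rhs(N, ytmp.data(), k5.data());
    for (int i = 0; i < ns; ++i)
      ytmp[i] = y[i] + h * (a61 * f[i] + a62 * k2[i] + a63 * k3[i] + a64 * k4[i] +
                            a65 * k5[i]);
    rhs(N, ytmp.data(), k6.data());
    for (int i = 0; i < ns; ++i)
      ynew[i] = y[i] + h * (b1 * f[i] + b3 * k3[i] + b4 * k4[i] + b5 * k5[i] +
                            b6 * k6[i]);
    rhs(N, ynew.data(), fnew.data());  // FSAL stage k7

    double err = 0.0;
    bool finite = true;
    for (int i = 0; i < ns; ++i) {
      if (!std::isfinite(ynew[i])) { finite = false; break; }
      double ei = h * (e1 * f[i] + e3 * k3[i] + e4 * k4[i] + e5 * k5[i] +
                       e6 * k6[i] + e7 * fnew[i]);
      double sc = atol + rtol * std::max(std::fabs(y[i]), std::fabs(ynew[i]));
      double r = ei / sc;
      err += r * r;
    }
    err = finite ? std::sqrt(err / ns) : 1e10;

    if (err <= 1.0) {
      double tnew = t + h;
      while (iout < nout && out_times[iout] <= tnew + 1e-12 * std::max(1.0, std::fabs(tnew))) {
        double th = (out_times[iout] - t) / h;
        double h00 = (1 + 2 * th) * (1 - th) * (1 - th);
        double h10 = th * (1 - th) * (1 - th);
        double h01 = th * th * (3 - 2 * th);
        double h11 = th * th * (th - 1);
        for (int i = 0; i < ns; ++i)
          out(iout, i) = h00 * y[i] + h10 * h * f[i] + h01 * ynew[i] + h11 * h * fnew[i];
        ++iout;
      }
      t = tnew;
      y.swap(ynew);
      f.swap(fnew);
      double fac = 0.9 * std::pow(err > 1e-30 ? err : 1e-30, -0.2);
      double facmax = rejected ? 1.0 : 5.0;
      h *= std::min(facmax, std::max(0.2, fac));
      rejected = false;
    } else {
      double fac = 0.9 * std::pow(err, -0.2);
      h *= std::max(0.1, std::min(1.0, fac));
      rejected = true;
    }
  }
  // exact endpoint state
  for (int i = 0; i < ns; ++i) out(nout - 1, i) = y[i];
  return out;
}
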