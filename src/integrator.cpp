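// Langevin (BAOAB) integrator for torsional coordinates with cosine-series
// reference potentials and BQ-TA-LER 3J-coupling restraints. Angles are
// handled in radians here; the R interface uses degrees.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double TWO_PI = 6.283185307179586476925286766559;

// wrap to (-pi, pi]
static inline double wrap_rad(double x) {
  double w = x - TWO_PI * std::floor((x + M_PI) / TWO_PI);
  if (w <= -M_PI) w = M_PI;  // guard the boundary against rounding
  return w;
}

struct CosineSeries {
  std::vector<double> k, n, delta;  // V = sum k (1 + cos(n th - delta))
  double force(double th) const {   // -dV/dth
    double f = 0.0;
    for (size_t j = 0; j < k.size(); ++j)
      f += k[j] * n[j] * std::sin(n[j] * th - delta[j]);
    return f;
  }
};

struct Restraint {
  int torsion;                      // 0-based torsion index
  double a, b, c;                   // Karplus coefficients, Hz
  double offset;                    // torsion -> Karplus dihedral, rad
  double J0, dJ_fb, K, tau;         // target, flat bottom, weight, memory
  int N_le;
  double width;                     // grid interval, rad
  std::vector<double> S;            // gated integral per bin, Hz^4 ps
  double t, avg_num, avg_den, J_avg;

  double coupling(double th) const {
    double ct = std::cos(th + offset);
    return a * ct * ct + b * ct + c;
  }
  int bin(double th) const {
    // half-open bins [th_i - w/2, th_i + w/2) around th_i = i*w, i=1..N
    long i = (long)std::floor(th / width + 0.5) % N_le;
    if (i <= 0) i += N_le;
    return (int)(i - 1);            // 0-based
  }
  void step_update(double th, double dt) {
    double J = coupling(th);
    double decay = std::exp(-dt / tau);
    avg_num = avg_num * decay + J * dt;
    avg_den = avg_den * decay + dt;
    J_avg = avg_num / avg_den;
    double hi = J0 + dJ_fb, lo = J0 - dJ_fb, f = 0.0;
    if (J >= hi && J_avg >= hi)
      f = (J - hi) * (J - hi) * (J_avg - hi) * (J_avg - hi);
    else if (J < lo && J_avg < lo)
      f = (J - lo) * (J - lo) * (J_avg - lo) * (J_avg - lo);
    S[bin(th)] += f * dt;
    t += dt;
  }
  // energy and generalized force with current weights (S/t)
  void energy_force(double th, double &V, double &F) const {
    V = 0.0; F = 0.0;
    if (t <= 0.0 || K == 0.0) return;
    double w2 = width * width;
    for (int i = 0; i < N_le; ++i) {
      if (S[i] == 0.0) continue;
      double omega = S[i] / t;
      double d = wrap_rad(th - width * (i + 1));
      double g = std::exp(-d * d / (2.0 * w2));
      V += K * omega * g;
      F += K * omega * g * d / w2;
    }
  }
};

// [[Rcpp::export(name = ".integrate_cpp")]]
List integrate_cpp(NumericVector theta0, List potentials, List restraints,
                   double dt, double temperature, double friction,
                   double inertia, int n_steps, int record_stride,
                   double force_bound) {
  const double kB = 0.008314462618;  // kJ mol^-1 K^-1
  int ntor = theta0.size();
  std::vector<CosineSeries> pots(ntor);
  for (int j = 0; j < ntor; ++j) {
    List p = potentials[j];
    NumericVector k = p["k"], n = p["n"], d = p["delta"];
    pots[j].k = as<std::vector<double> >(k);
    pots[j].n = as<std::vector<double> >(n);
    pots[j].delta = as<std::vector<double> >(d);
  }
  int nres = restraints.size();
  std::vector<Restraint> res(nres);
  for (int r = 0; r < nres; ++r) {
    List rr = restraints[r];
    Restraint &R = res[r];
    R.torsion = as<int>(rr["torsion"]) - 1;
    R.a = as<double>(rr["a"]); R.b = as<double>(rr["b"]);
    R.c = as<double>(rr["c"]); R.offset = as<double>(rr["offset"]);
    R.J0 = as<double>(rr["J0"]); R.dJ_fb = as<double>(rr["dJ_fb"]);
    R.K = as<double>(rr["K_Jr"]); R.tau = as<double>(rr["tau_J"]);
    R.N_le = as<int>(rr["N_le"]);
    R.width = TWO_PI / R.N_le;
    R.S.assign(R.N_le, 0.0);
    R.t = 0.0; R.avg_num = 0.0; R.avg_den = 0.0;
    R.J_avg = NA_REAL;
  }

  std::vector<double> th(ntor), v(ntor), F(ntor);
  for (int j = 0; j < ntor; ++j) {
    th[j] = theta0[j];
    v[j] = ::norm_rand() * std::sqrt(kB * temperature / inertia);
  }
  // initial force: reference + restraint (weights all zero initially)
  for (int j = 0; j < ntor; ++j) F[j] = pots[j].force(th[j]);

  double c1 = std::exp(-friction * dt);
  double c2 = std::sqrt(kB * temperature / inertia * (1.0 - c1 * c1));
  double half = 0.5 * dt;

  int nrec = n_steps / record_stride;
  NumericVector times(nrec);
  NumericMatrix th_rec(nrec, ntor);
  NumericMatrix Ji_rec(nrec, std::max(nres, 1));
  NumericMatrix Ja_rec(nrec, std::max(nres, 1));
  NumericVector V_rec(nrec);
  double kin_sum = 0.0;
  int irec = 0;

  for (int s = 1; s <= n_steps; ++s) {
    for (int j = 0; j < ntor; ++j) {
      v[j] += half * F[j] / inertia;            // B
      th[j] += half * v[j];                     // A
      v[j] = c1 * v[j] + c2 * ::norm_rand();    // O
      th[j] += half * v[j];                     // A
      th[j] = wrap_rad(th[j]);
    }
    // restraint bookkeeping at the new positions (average -> weights)
    for (int r = 0; r < nres; ++r)
      res[r].step_update(th[res[r].torsion], dt);
    // total force with the weights through this step
    double Vtot = 0.0;
    for (int j = 0; j < ntor; ++j) F[j] = pots[j].force(th[j]);
    for (int r = 0; r < nres; ++r) {
      double Vr, Fr;
      res[r].energy_force(th[res[r].torsion], Vr, Fr);
      Vtot += Vr;
      F[res[r].torsion] += Fr;
    }
    for (int j = 0; j < ntor; ++j) {
      if (!std::isfinite(F[j]) || std::fabs(F[j]) > force_bound)
        stop("integration diverged at step %d (|force| = %g)", s, F[j]);
      v[j] += half * F[j] / inertia;            // B
      kin_sum += 0.5 * inertia * v[j] * v[j];
    }
    if (s % record_stride == 0 && irec < nrec) {
      times[irec] = s * dt;
      for (int j = 0; j < ntor; ++j) th_rec(irec, j) = th[j];
      for (int r = 0; r < nres; ++r) {
        Ji_rec(irec, r) = res[r].coupling(th[res[r].torsion]);
        Ja_rec(irec, r) = res[r].J_avg;
      }
      V_rec[irec] = Vtot;
      ++irec;
    }
  }

  List states(nres);
  for (int r = 0; r < nres; ++r) {
    states[r] = List::create(_["S"] = wrap(res[r].S), _["t"] = res[r].t,
                             _["avg_num"] = res[r].avg_num,
                             _["avg_den"] = res[r].avg_den,
                             _["J_avg"] = res[r].J_avg);
  }
  return List::create(
    _["times"] = times, _["theta"] = th_rec,
    _["J_inst"] = Ji_rec, _["J_avg"] = Ja_rec,
    _["V_restraint"] = V_rec,
    _["mean_kinetic"] = kin_sum / ((double)n_steps * ntor),
    _["final_states"] = states);
}
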