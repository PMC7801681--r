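// Metropolis annealing for the maximal-repulsion configuration model in a
// spherical domain. The energy of a configuration is the negative mean
// nearest-neighbour distance; moves are uniform-in-ball displacements
// (optionally projected back onto each object's boundary-distance orbit),
// invalid proposals (overlap or containment failure) count as rejections,
// and the best-visited configuration is returned.
#include <Rcpp.h>
using namespace Rcpp;

static double config_energy(const NumericMatrix &P, int N) {
  double s = 0.0;
  for (int i = 0; i < N; ++i) {
    double best = R_PosInf;
    for (int j = 0; j < N; ++j) {
      if (j == i) continue;
      double dx = P(i, 0) - P(j, 0);
      double dy = P(i, 1) - P(j, 1);
      double dz = P(i, 2) - P(j, 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
    s += std::sqrt(best);
  }
  return -s / N;
}

// proposal: uniform point in the unit ball
static void runit_ball(double *u) {
  double n2;
  do {
    u[0] = 2.0 * unif_rand() - 1.0;
    u[1] = 2.0 * unif_rand() - 1.0;
    u[2] = 2.0 * unif_rand() - 1.0;
    n2 = u[0] * u[0] + u[1] * u[1] + u[2] * u[2];
  } while (n2 > 1.0);
}

// build a candidate move for object i; returns false if it must be rejected
static bool propose(const NumericMatrix &P, int i, int N,
                    const NumericVector &radii, const NumericVector &center,
                    double R, bool on_orbit, const NumericVector &orbits,
                    double delta, double *cand) {
  double u[3];
  runit_ball(u);
  for (int a = 0; a < 3; ++a) cand[a] = P(i, a) + delta * u[a];
  double q[3], nq = 0.0;
  for (int a = 0; a < 3; ++a) {
    q[a] = cand[a] - center[a];
    nq += q[a] * q[a];
  }
  nq = std::sqrt(nq);
  if (on_orbit) {
    double s = R - orbits[i];           // orbit shell radius
    if (nq < 1e-12 * R) return false;
    for (int a = 0; a < 3; ++a) cand[a] = center[a] + q[a] * (s / nq);
    nq = s;
  }
  if (nq > R - radii[i] + 1e-12 * R) return false;  // containment
  for (int j = 0; j < N; ++j) {
    if (j == i) continue;
    double dx = cand[0] - P(j, 0);
    double dy = cand[1] - P(j, 1);
    double dz = cand[2] - P(j, 2);
    double rr = radii[i] + radii[j];
    if (dx * dx + dy * dy + dz * dz < rr * rr) return false;  // hard core
  }
  return true;
}

static double move_energy(NumericMatrix &P, int i, int N,
                          const double *cand, double *saved) {
  for (int a = 0; a < 3; ++a) {
    saved[a] = P(i, a);
    P(i, a) = cand[a];
  }
  double e = config_energy(P, N);
  return e;
}

// [[Rcpp::export(name = ".mh_maxrep_sphere")]]
List mh_maxrep_sphere(NumericMatrix init, NumericVector radii,
                      NumericVector center, double R,
                      bool on_orbit, NumericVector orbits,
                      double beta0, double beta_growth, double delta0,
                      int window, double tol, int max_moves,
                      int probe_moves) {
  RNGScope scope;
  int N = init.nrow();
  NumericMatrix P = clone(init);
  NumericMatrix best = clone(init);
  double E = config_energy(P, N);
  double bestE = E;
  double delta = delta0;
  double cand[3], saved[3];

  // calibrate beta0 from probe moves so initial uphill acceptance ~ 0.5
  double beta = beta0;
  if (beta <= 0.0) {
    std::vector<double> up;
    for (int t = 0; t < probe_moves; ++t) {
      int i = (int)std::floor(unif_rand() * N);
      if (i >= N) i = N - 1;
      if (!propose(P, i, N, radii, center, R, on_orbit, orbits, delta, cand))
        continue;
      double e2 = move_energy(P, i, N, cand, saved);
      double dE = e2 - E;
      for (int a = 0; a < 3; ++a) P(i, a) = saved[a];  // undo
      if (dE > 0) up.push_back(dE);
    }
    if (up.size() > 0) {
      std::sort(up.begin(), up.end());
      double med = up[up.size() / 2];
      beta = (med > 0) ? std::log(2.0) / med : 1.0;
    } else {
      beta = 1.0;
    }
  }

  std::vector<double> tr_energy, tr_best, tr_accept;
  int moves = 0, win_acc = 0, win_cnt = 0;
  double win_sum = 0.0, prev_mean = R_PosInf;
  bool converged = false;

  while (moves < max_moves) {
    int i = (int)std::floor(unif_rand() * N);
    if (i >= N) i = N - 1;
    ++moves;
    ++win_cnt;
    bool accepted = false;
    if (propose(P, i, N, radii, center, R, on_orbit, orbits, delta, cand)) {
      double e2 = move_energy(P, i, N, cand, saved);
      double dE = e2 - E;
      double b = beta > 700.0 / std::max(std::abs(dE), 1e-300) ? R_PosInf
                                                               : beta;
      if (dE < 0 || (R_finite(b) && unif_rand() < std::exp(-b * dE))) {
        accepted = true;
        E = e2;
        if (E < bestE) {
          bestE = E;
          best = clone(P);
        }
      } else {
        for (int a = 0; a < 3; ++a) P(i, a) = saved[a];
      }
    }
    if (accepted) ++win_acc;
    win_sum += E;
    if (moves % N == 0) beta *= beta_growth;       // geometric per sweep
    if (beta > 1e12) beta = 1e12;
    if (win_cnt == window) {
      double mean = win_sum / window;
      double acc = (double)win_acc / window;
      tr_energy.push_back(mean);
      tr_best.push_back(bestE);
      tr_accept.push_back(acc);
      if (acc > 0.3) delta /= 0.9; else delta *= 0.9;
      if (delta > 2.0 * R) delta = 2.0 * R;
      if (delta < 1e-6 * R) delta = 1e-6 * R;
      if (R_finite(prev_mean) &&
          std::abs(mean - prev_mean) < tol * std::abs(mean)) {
        converged = true;
        break;
      }
      prev_mean = mean;
      win_cnt = 0;
      win_sum = 0.0;
      win_acc = 0;
    }
  }

  return List::create(_["centers"] = best, _["energy"] = bestE,
                      _["trace_energy"] = tr_energy,
                      _["trace_best"] = tr_best,
                      _["trace_accept"] = tr_accept,
                      _["converged"] = converged, _["moves"] = moves,
                      _["beta"] = beta, _["delta"] = delta);
}
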