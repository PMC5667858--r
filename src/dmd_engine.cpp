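// Event-driven discrete molecular dynamics for the hard-wall square-well
// (Go) model.  Particles move ballistically between pairwise wall events;
// tethered pairs bounce elastically off their inner/outer walls, non-tethered
// pairs off a hard core.  An Andersen-style thermostat resamples single-
// particle velocities from Maxwell-Boltzmann at rate nu per particle.
// All randomness goes through R's RNG so runs are reproducible via set.seed.

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

namespace {

const double INF = std::numeric_limits<double>::infinity();
const double NUDGE = 1e-9;

struct Event {
  double t;
  int i, j;        // j == -1: thermostat event
  int wall;        // 0 = outer, 1 = inner/core
  long ci, cj;     // per-particle collision counters at scheduling time
};

struct EventCmp {
  bool operator()(const Event& a, const Event& b) const {
    if (a.t != b.t) return a.t > b.t;            // min-heap on time
    if (a.i != b.i) return a.i > b.i;            // ties: smaller pair first
    return a.j > b.j;
  }
};

struct Engine {
  int N;
  std::vector<double> x, v, m;
  std::vector<long> cnt;
  std::vector<int> tetherOf;                     // pair index -> tether or -1
  std::vector<double> dmin2, dmax2;              // per tether, squared walls
  double dhc2;
  double tcur;
  std::priority_queue<Event, std::vector<Event>, EventCmp> q;

  int pairIdx(int i, int j) const {
    if (i > j) std::swap(i, j);
    return i * N - i * (i + 1) / 2 + (j - i - 1);
  }

  double ke() const {
    double k = 0;
    for (int i = 0; i < N; ++i) {
      double s = v[3*i]*v[3*i] + v[3*i+1]*v[3*i+1] + v[3*i+2]*v[3*i+2];
      k += 0.5 * m[i] * s;
    }
    return k;
  }

  void advanceAll(double t) {
    double dt = t - tcur;
    for (int i = 0; i < 3 * N; ++i) x[i] += v[i] * dt;
    tcur = t;
  }

  // smallest positive crossing times of the pair's walls, from current state
  void predict(int i, int j) {
    double dr[3], dv[3];
    for (int d = 0; d < 3; ++d) {
      dr[d] = x[3*i+d] - x[3*j+d];
      dv[d] = v[3*i+d] - v[3*j+d];
    }
    double a = dv[0]*dv[0] + dv[1]*dv[1] + dv[2]*dv[2];
    if (a <= 0) return;
    double b = dr[0]*dv[0] + dr[1]*dv[1] + dr[2]*dv[2];
    double r2 = dr[0]*dr[0] + dr[1]*dr[1] + dr[2]*dr[2];
    int k = tetherOf[pairIdx(i, j)];
    double tin = INF, tout = INF;
    double din2 = (k >= 0) ? dmin2[k] : dhc2;
    if (b < 0) {                                  // approaching: inner wall
      double disc = b*b - a*(r2 - din2);
      if (disc > 0) {
        double t1 = (-b - std::sqrt(disc)) / a;
        if (t1 > 0) tin = t1;
      }
    }
    if (k >= 0) {                                 // tethered: outer wall
      double disc = b*b - a*(r2 - dmax2[k]);
      if (disc >= 0) {
        double t2 = (-b + std::sqrt(disc)) / a;
        if (t2 > 0) tout = t2;
      }
    }
    if (tin < INF || tout < INF) {
      Event e;
      e.t = tcur + std::min(tin, tout);
      e.i = std::min(i, j); e.j = std::max(i, j);
      e.wall = (tin <= tout) ? 1 : 0;
      e.ci = cnt[e.i]; e.cj = cnt[e.j];
      q.push(e);
    }
  }

  void refreshParticle(int i, int skip = -1) {
    for (int k = 0; k < N; ++k)
      if (k != i && k != skip) predict(i, k);
  }

  // elastic hard-wall reflection; returns false on a grazing (stale) event
  bool reflect(int i, int j, int wall) {
    double dr[3];
    for (int d = 0; d < 3; ++d) dr[d] = x[3*i+d] - x[3*j+d];
    double r = std::sqrt(dr[0]*dr[0] + dr[1]*dr[1] + dr[2]*dr[2]);
    if (r <= 0) return false;
    double rh[3] = {dr[0]/r, dr[1]/r, dr[2]/r};
    double vr = 0;
    for (int d = 0; d < 3; ++d) vr += (v[3*i+d] - v[3*j+d]) * rh[d];
    if (wall == 0 && vr <= 0) return false;       // outer wall needs separation
    if (wall == 1 && vr >= 0) return false;       // inner wall needs approach
    double mu = m[i] * m[j] / (m[i] + m[j]);
    double J = 2.0 * mu * vr;
    for (int d = 0; d < 3; ++d) {
      v[3*i+d] -= (J / m[i]) * rh[d];
      v[3*j+d] += (J / m[j]) * rh[d];
    }
    // nudge separation just inside the wall to avoid re-detection
    int k = tetherOf[pairIdx(i, j)];
    double target = (wall == 0) ? std::sqrt(dmax2[k]) - NUDGE
                  : std::sqrt(k >= 0 ? dmin2[k] : dhc2) + NUDGE;
    double shift = (r - target) / 2.0;
    for (int d = 0; d < 3; ++d) {
      x[3*i+d] -= shift * rh[d];
      x[3*j+d] += shift * rh[d];
    }
    return true;
  }
};

} // namespace

// [[Rcpp::export(name = ".dmdRun")]]
List dmdRun(NumericMatrix pos0, NumericMatrix vel0,
            IntegerVector ti, IntegerVector tj,
            NumericVector tdmin, NumericVector tdmax,
            NumericVector mass, double dhc,
            int nEvents, double temperature, double nu, int snapEvery) {
  RNGScope rngScope;
  Engine E;
  E.N = pos0.nrow();
  const int N = E.N;
  E.x.resize(3 * N); E.v.resize(3 * N);
  for (int i = 0; i < N; ++i)
    for (int d = 0; d < 3; ++d) {
      E.x[3*i+d] = pos0(i, d);
      E.v[3*i+d] = vel0(i, d);
    }
  E.m.assign(mass.begin(), mass.end());
  E.cnt.assign(N, 0);
  E.tetherOf.assign(N * (N - 1) / 2, -1);
  int nt = ti.size();
  E.dmin2.resize(nt); E.dmax2.resize(nt);
  for (int k = 0; k < nt; ++k) {
    E.tetherOf[E.pairIdx(ti[k] - 1, tj[k] - 1)] = k;
    E.dmin2[k] = tdmin[k] * tdmin[k];
    E.dmax2[k] = tdmax[k] * tdmax[k];
  }
  E.dhc2 = dhc * dhc;
  E.tcur = 0.0;

  for (int i = 0; i < N - 1; ++i)
    for (int j = i + 1; j < N; ++j)
      E.predict(i, j);
  if (nu > 0) {
    Event th; th.t = R::rexp(1.0 / (nu * N)); th.i = -1; th.j = -1;
    th.wall = -1; th.ci = th.cj = 0;
    E.q.push(th);
  }

  int nsnapMax = nEvents / snapEvery + 2;
  std::vector<double> snaps; snaps.reserve((size_t)nsnapMax * 3 * N);
  std::vector<double> snapT; snapT.reserve(nsnapMax);
  auto takeSnap = [&]() {
    for (int i = 0; i < 3 * N; ++i) snaps.push_back(E.x[i]);
    snapT.push_back(E.tcur);
  };
  takeSnap();

  double keSegStart = E.ke();
  double maxDrift = 0.0;
  double keTimeInt = 0.0, keTimeIntH2 = 0.0, timeTot = 0.0, timeH2 = 0.0;
  long nDone = 0;

  while (nDone < nEvents) {
    if (E.q.empty()) break;
    Event ev = E.q.top(); E.q.pop();
    if (ev.i >= 0 && (E.cnt[ev.i] != ev.ci || E.cnt[ev.j] != ev.cj))
      continue;                                    // stale, lazily invalidated
    if (ev.t < E.tcur - 1e-9)
      stop("event-time regression: t=%g < current %g", ev.t, E.tcur);
    double dt = ev.t - E.tcur;
    double keNow = E.ke();
    keTimeInt += keNow * dt; timeTot += dt;
    if (nDone >= nEvents / 2) { keTimeIntH2 += keNow * dt; timeH2 += dt; }
    E.advanceAll(ev.t);

    if (ev.i < 0) {                                // thermostat
      double drift = std::fabs(E.ke() - keSegStart) /
                     std::max(keSegStart, 1e-300);
      if (drift > maxDrift) maxDrift = drift;
      int u = (int)std::floor(unif_rand() * N);
      if (u >= N) u = N - 1;
      double sd = std::sqrt(temperature / E.m[u]);
      for (int d = 0; d < 3; ++d) E.v[3*u+d] = norm_rand() * sd;
      E.cnt[u]++;
      E.refreshParticle(u);
      keSegStart = E.ke();
      Event th; th.t = E.tcur + R::rexp(1.0 / (nu * N));
      th.i = -1; th.j = -1; th.wall = -1; th.ci = th.cj = 0;
      E.q.push(th);
    } else {
      if (E.reflect(ev.i, ev.j, ev.wall)) {
        E.cnt[ev.i]++; E.cnt[ev.j]++;
        E.refreshParticle(ev.i);
        E.refreshParticle(ev.j, ev.i);
      } else {
        // grazing/stale wall contact: reschedule this pair only
        E.cnt[ev.i]++; E.cnt[ev.j]++;
        E.refreshParticle(ev.i);
        E.refreshParticle(ev.j, ev.i);
        continue;
      }
    }
    nDone++;
    if (nDone % snapEvery == 0) takeSnap();
  }
  double drift = std::fabs(E.ke() - keSegStart) / std::max(keSegStart, 1e-300);
  if (drift > maxDrift) maxDrift = drift;

  int nsnap = snapT.size();
  NumericVector frames(snaps.begin(), snaps.end());
  NumericVector times(snapT.begin(), snapT.end());
  return List::create(
    _["frames"] = frames, _["times"] = times, _["nsnap"] = nsnap,
    _["keMean"] = timeTot > 0 ? keTimeInt / timeTot : E.ke(),
    _["keMeanSecondHalf"] = timeH2 > 0 ? keTimeIntH2 / timeH2 : E.ke(),
    _["maxKeDrift"] = maxDrift,
    _["nEvents"] = (double)nDone);
}
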