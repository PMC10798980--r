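// Event-driven discrete molecular dynamics core.
//
// Particles move ballistically between instantaneous events: potential-step
// crossings (including bond walls), reflecting box walls, force-plane
// crossings of the steering potential, Anderson-thermostat velocity
// reassignments, and frame sampling.  Units: A, kcal/mol, Da; the derived
// time unit is ~48.89 fs.
//
// Pair potentials are piecewise constant: radii R[0..m-1] strictly
// increasing, levels E[0..m] with E[k] the energy for R[k-1] < r < R[k]
// (E[0] is the hard core, E[m] the region beyond the last radius; E[m] is
// +inf for bounded interactions, i.e. bond constraints).

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <cstdint>
#include <limits>

using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

struct PairPot {
  std::vector<double> R;
  std::vector<double> E; // size R.size() + 1
};

enum EvKind { EV_PAIR = 0, EV_WALL = 1, EV_PLANE = 2, EV_THERM = 3, EV_SAMPLE = 4 };

struct Event {
  double t;
  int kind;
  int i, j;       // pair beads; for WALL j = axis*2 + side; PLANE j = dir
  int ridx;       // radius index being crossed (PAIR)
  std::uint64_t ci, cj;
};

struct EventCmp {
  bool operator()(const Event& a, const Event& b) const {
    if (a.t != b.t) return a.t > b.t;
    if (a.kind != b.kind) return a.kind > b.kind;
    if (a.i != b.i) return a.i > b.i;
    return a.j > b.j;
  }
};

// deterministic RNG: splitmix64 + Box-Muller, identical on every platform
struct Rng {
  std::uint64_t s;
  explicit Rng(std::uint64_t seed) : s(seed + 0x9E3779B97f4A7C15ULL) {}
  std::uint64_t next() {
    std::uint64_t z = (s += 0x9E3779B97f4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  double unif() { // in (0, 1)
    return (next() >> 11) * (1.0 / 9007199254740992.0) + 5.6e-17;
  }
  double norm() {
    double u1 = unif(), u2 = unif();
    return std::sqrt(-2.0 * std::log(u1)) * std::cos(6.283185307179586 * u2);
  }
  double expo(double rate) { return -std::log(unif()) / rate; }
  int unif_int(int n) { return (int)(unif() * n) % n; }
};

class Engine {
public:
  int n;
  std::vector<double> x, v, mass, invm;
  std::vector<int> mobile;
  std::vector<PairPot> pots;
  std::vector<int> pairPot;   // n*n, -1 = none
  std::vector<int> band;      // n*n
  std::vector<std::uint64_t> cnt;
  double t, L, margin, t_end;
  double pe;                  // pair + steering potential ledger
  std::priority_queue<Event, std::vector<Event>, EventCmp> pq;
  // thermostat
  double kT, therm_rate_total;
  std::vector<int> mobile_idx;
  Rng rng;
  // steering
  bool steer;
  double sdir[3];
  double sdelta, sdu;         // per-bead per-plane energy, kcal/mol
  std::vector<int> pulled;    // flag per bead
  std::vector<long long> plane; // current plane index per pulled bead
  // stats
  long long n_events, n_pair, n_therm, n_wall, n_plane;

  Engine(std::uint64_t seed) : rng(seed) {
    t = 0; pe = 0; steer = false;
    n_events = n_pair = n_therm = n_wall = n_plane = 0;
    margin = 0.0;
  }

  inline int PP(int i, int j) const { return pairPot[i * n + j]; }
  inline int& BB(int i, int j) { return band[i * n + j]; }

  void advance_all(double te) {
    double dt = te - t;
    if (dt <= 0) { t = te; return; }
    for (int k = 0; k < n; ++k) {
      if (!mobile[k]) continue;
      x[3 * k] += v[3 * k] * dt;
      x[3 * k + 1] += v[3 * k + 1] * dt;
      x[3 * k + 2] += v[3 * k + 2] * dt;
    }
    t = te;
  }

  void schedule_pair(int i, int j) {
    int pid = PP(i, j);
    if (pid < 0) return;
    if (!mobile[i] && !mobile[j]) return;
    const PairPot& P = pots[pid];
    int b = BB(i, j);
    double r[3], w[3];
    for (int a = 0; a < 3; ++a) {
      r[a] = x[3 * j + a] - x[3 * i + a];
      w[a] = v[3 * j + a] - v[3 * i + a];
    }
    double v2 = w[0] * w[0] + w[1] * w[1] + w[2] * w[2];
    if (v2 <= 0) return;
    double bd = r[0] * w[0] + r[1] * w[1] + r[2] * w[2];
    double r2 = r[0] * r[0] + r[1] * r[1] + r[2] * r[2];
    int m = (int)P.R.size();
    double best = INF; int bidx = -1;
    if (b > 0 && bd < 0) { // inward crossing of R[b-1], approaching only
      double R = P.R[b - 1];
      double c = r2 - R * R;
      if (c <= 0) { // numerically already at/inside the radius
        best = 0; bidx = b - 1;
      } else {
        double disc = bd * bd - v2 * c;
        if (disc >= 0) {
          double tt = (-bd - std::sqrt(disc)) / v2;
          if (tt >= 0 && tt < best) { best = tt; bidx = b - 1; }
        }
      }
    }
    if (b < m) { // outward crossing of R[b]
      double R = P.R[b];
      double c = r2 - R * R;
      double disc = bd * bd - v2 * c;
      if (disc > 0) {
        double tt = (-bd + std::sqrt(disc)) / v2;
        if (tt >= 0 && tt < best) { best = tt; bidx = b; }
      }
    }
    if (bidx < 0 || !std::isfinite(best)) return;
    if (t + best > t_end) return; // beyond the run horizon
    Event e{t + best, EV_PAIR, i, j, bidx, cnt[i], cnt[j]};
    pq.push(e);
  }

  void schedule_wall(int i) {
    if (!mobile[i] || L <= 0) return;
    double best = INF; int code = -1;
    for (int a = 0; a < 3; ++a) {
      double vv = v[3 * i + a];
      if (vv > 0) {
        double tt = (L - x[3 * i + a]) / vv;
        if (tt >= 0 && tt < best) { best = tt; code = a * 2 + 1; }
      } else if (vv < 0) {
        double tt = (0.0 - x[3 * i + a]) / vv;
        if (tt >= 0 && tt < best) { best = tt; code = a * 2; }
      }
    }
    if (code < 0 || !std::isfinite(best) || t + best > t_end) return;
    Event e{t + best, EV_WALL, i, code, 0, cnt[i], 0};
    pq.push(e);
  }

  void schedule_plane(int i) {
    if (!steer || !pulled[i] || !mobile[i]) return;
    double vd = v[3 * i] * sdir[0] + v[3 * i + 1] * sdir[1] + v[3 * i + 2] * sdir[2];
    if (vd == 0) return;
    double s = x[3 * i] * sdir[0] + x[3 * i + 1] * sdir[1] + x[3 * i + 2] * sdir[2];
    double target = (vd > 0) ? (plane[i] + 1) * sdelta : plane[i] * sdelta;
    double tt = (target - s) / vd;
    if (tt < 0) tt = 0;
    if (t + tt > t_end) return;
    Event e{t + tt, EV_PLANE, i, vd > 0 ? 1 : -1, 0, cnt[i], 0};
    pq.push(e);
  }

  void reschedule_bead(int i) {
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      int a = std::min(i, j), b = std::max(i, j);
      schedule_pair(a, b);
    }
    schedule_wall(i);
    schedule_plane(i);
  }

  void do_pair(const Event& e) {
    int i = e.i, j = e.j;
    const PairPot& P = pots[PP(i, j)];
    int b = BB(i, j);
    int target = (e.ridx == b) ? b + 1 : b - 1;
    double r[3];
    for (int a = 0; a < 3; ++a) r[a] = x[3 * j + a] - x[3 * i + a];
    double rr = std::sqrt(r[0] * r[0] + r[1] * r[1] + r[2] * r[2]);
    if (rr <= 0) rr = 1e-12;
    double nh[3] = {r[0] / rr, r[1] / rr, r[2] / rr};
    double vr = (v[3 * j] - v[3 * i]) * nh[0] + (v[3 * j + 1] - v[3 * i + 1]) * nh[1] +
                (v[3 * j + 2] - v[3 * i + 2]) * nh[2];
    double mu = 1.0 / (invm[i] + invm[j]);
    double dU = P.E[target] - P.E[b];
    double vrp;
    bool crossed;
    if (std::isinf(dU) && dU > 0) {
      crossed = false;
      vrp = -vr;
    } else {
      double kin = 0.5 * mu * vr * vr;
      if (kin > dU) {
        crossed = true;
        double s = vr >= 0 ? 1.0 : -1.0;
        vrp = s * std::sqrt(vr * vr - 2.0 * dU / mu);
      } else {
        crossed = false;
        vrp = -vr;
      }
    }
    double dv = vrp - vr;
    for (int a = 0; a < 3; ++a) {
      v[3 * j + a] += mu * invm[j] * dv * nh[a];
      v[3 * i + a] -= mu * invm[i] * dv * nh[a];
    }
    if (crossed) {
      BB(i, j) = target;
      pe += dU;
    }
    cnt[i]++; cnt[j]++;
    reschedule_bead(i);
    reschedule_bead(j);
    n_pair++;
  }

  void do_wall(const Event& e) {
    int i = e.i, axis = e.j / 2;
    v[3 * i + axis] = -v[3 * i + axis];
    cnt[i]++;
    reschedule_bead(i);
    n_wall++;
  }

  void do_plane(const Event& e) {
    int i = e.i, dir = e.j;
    double vd = v[3 * i] * sdir[0] + v[3 * i + 1] * sdir[1] + v[3 * i + 2] * sdir[2];
    double m = mass[i];
    double vdp;
    if (dir > 0) { // moving along the force: always gains sdu
      vdp = std::sqrt(vd * vd + 2.0 * sdu / m);
      plane[i] += 1;
      pe -= sdu;
    } else { // against the force: climb or reflect
      if (0.5 * m * vd * vd > sdu) {
        vdp = -std::sqrt(vd * vd - 2.0 * sdu / m);
        plane[i] -= 1;
        pe += sdu;
      } else {
        vdp = -vd;
      }
    }
    double dv = vdp - vd;
    for (int a = 0; a < 3; ++a) v[3 * i + a] += dv * sdir[a];
    cnt[i]++;
    reschedule_bead(i);
    n_plane++;
  }

  void do_therm() {
    int k = mobile_idx[rng.unif_int((int)mobile_idx.size())];
    double sd = std::sqrt(kT / mass[k]);
    for (int a = 0; a < 3; ++a) v[3 * k + a] = sd * rng.norm();
    cnt[k]++;
    reschedule_bead(k);
    n_therm++;
  }

  double kinetic() const {
    double ke = 0;
    for (int k = 0; k < n; ++k) {
      if (!mobile[k]) continue;
      ke += 0.5 * mass[k] * (v[3 * k] * v[3 * k] + v[3 * k + 1] * v[3 * k + 1] +
                             v[3 * k + 2] * v[3 * k + 2]);
    }
    return ke;
  }
};

static int find_band(const PairPot& P, double r) {
  int b = 0;
  while (b < (int)P.R.size() && r > P.R[b] + 1e-12) ++b;
  return b;
}

// [[Rcpp::export(name = ".dmd_run_cpp")]]
List dmd_run_cpp(NumericMatrix pos0, NumericMatrix vel0, NumericVector mass,
                 IntegerVector mobile_in, List pot_list, IntegerMatrix pot_index,
                 double box_edge, double duration, double sampling_interval,
                 double temperature, double thermostat_rate, double rng_seed,
                 List steer_in) {
  int n = pos0.nrow();
  Engine eng((std::uint64_t)rng_seed);
  eng.n = n;
  eng.x.resize(3 * n); eng.v.resize(3 * n);
  eng.mass.assign(mass.begin(), mass.end());
  eng.invm.resize(n);
  eng.mobile.assign(mobile_in.begin(), mobile_in.end());
  for (int k = 0; k < n; ++k) {
    for (int a = 0; a < 3; ++a) {
      eng.x[3 * k + a] = pos0(k, a);
      eng.v[3 * k + a] = eng.mobile[k] ? vel0(k, a) : 0.0;
    }
    eng.invm[k] = eng.mobile[k] ? 1.0 / eng.mass[k] : 0.0;
    if (eng.mobile[k]) eng.mobile_idx.push_back(k);
  }
  eng.L = box_edge;
  eng.t_end = duration * (1 + 1e-12) + 1e-9;
  eng.kT = 0.0019872041 * temperature;

  int npot = pot_list.size();
  eng.pots.resize(npot);
  for (int p = 0; p < npot; ++p) {
    List pl = pot_list[p];
    NumericVector R = pl["radii"], E = pl["levels"];
    eng.pots[p].R.assign(R.begin(), R.end());
    eng.pots[p].E.assign(E.begin(), E.end());
    if ((int)eng.pots[p].E.size() != (int)eng.pots[p].R.size() + 1)
      stop("potential %d: levels must have length(radii) + 1", p + 1);
  }
  eng.pairPot.assign(n * n, -1);
  eng.band.assign(n * n, 0);
  eng.cnt.assign(n, 0);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      int pid = pot_index(i, j) - 1; // R is 1-based, 0 = none
      eng.pairPot[i * n + j] = pid;
      eng.pairPot[j * n + i] = pid;
      if (pid >= 0) {
        double dx = pos0(j, 0) - pos0(i, 0), dy = pos0(j, 1) - pos0(i, 1),
               dz = pos0(j, 2) - pos0(i, 2);
        double r = std::sqrt(dx * dx + dy * dy + dz * dz);
        int b = find_band(eng.pots[pid], r);
        if (std::isinf(eng.pots[pid].E[b]))
          stop("beads %d and %d start in a forbidden region (r = %.3f)",
               i + 1, j + 1, r);
        eng.band[i * n + j] = b;
        eng.pe += eng.pots[pid].E[b];
      }
    }
  }

  // steering protocol
  eng.pulled.assign(n, 0);
  eng.plane.assign(n, 0);
  if (steer_in.size() > 0) {
    NumericVector dir = steer_in["direction"];
    double du = as<double>(steer_in["energy_per_plane_per_bead"]);
    double delta = as<double>(steer_in["delta"]);
    IntegerVector pb = steer_in["pulled"];
    if (du > 0 && pb.size() > 0) {
      eng.steer = true;
      for (int a = 0; a < 3; ++a) eng.sdir[a] = dir[a];
      eng.sdelta = delta;
      eng.sdu = du;
      for (int k = 0; k < pb.size(); ++k) {
        int b = pb[k] - 1;
        eng.pulled[b] = 1;
        double s = eng.x[3 * b] * eng.sdir[0] + eng.x[3 * b + 1] * eng.sdir[1] +
                   eng.x[3 * b + 2] * eng.sdir[2];
        eng.plane[b] = (long long)std::floor(s / delta);
      }
    }
  }

  // initial schedule
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) eng.schedule_pair(i, j);
    eng.schedule_wall(i);
    eng.schedule_plane(i);
  }
  eng.therm_rate_total = thermostat_rate * eng.mobile_idx.size();
  double next_therm = (eng.therm_rate_total > 0 && !eng.mobile_idx.empty())
    ? eng.rng.expo(eng.therm_rate_total) : INF;

  int n_frames = (int)std::floor(duration / sampling_interval + 1e-9) + 1;
  NumericVector frame_times(n_frames), ke_out(n_frames), pe_out(n_frames);
  NumericVector frames(Dimension(n_frames, n, 3));
  int fi = 0;
  double next_sample = 0.0;

  long long tiny_streak = 0;
  double last_t = 0.0;
  while (true) {
    // next global event: sample, thermostat, or queue head
    double tq = eng.pq.empty() ? INF : eng.pq.top().t;
    double tnext = std::min(std::min(tq, next_therm), next_sample);
    if (tnext > duration + 1e-12) break;
    if (next_sample <= tq && next_sample <= next_therm) {
      eng.advance_all(next_sample);
      frame_times[fi] = eng.t;
      for (int k = 0; k < n; ++k)
        for (int a = 0; a < 3; ++a)
          frames[fi + n_frames * (k + n * a)] = eng.x[3 * k + a];
      ke_out[fi] = eng.kinetic();
      pe_out[fi] = eng.pe;
      fi++;
      if (fi >= n_frames) break;
      next_sample += sampling_interval;
      continue;
    }
    if (next_therm <= tq) {
      eng.advance_all(next_therm);
      eng.do_therm();
      next_therm = eng.t + eng.rng.expo(eng.therm_rate_total);
      eng.n_events++;
      continue;
    }
    Event e = eng.pq.top(); eng.pq.pop();
    bool valid = (e.ci == eng.cnt[e.i]) &&
                 (e.kind != EV_PAIR || e.cj == eng.cnt[e.j]);
    if (!valid) continue;
    if (e.t - last_t < 1e-12) {
      if (++tiny_streak > 1000000)
        stop("event-time underflow: beads %d and %d locked in zero-time events",
             e.i + 1, e.j + 1);
    } else tiny_streak = 0;
    last_t = e.t;
    eng.advance_all(e.t);
    switch (e.kind) {
      case EV_PAIR: eng.do_pair(e); break;
      case EV_WALL: eng.do_wall(e); break;
      case EV_PLANE: eng.do_plane(e); break;
    }
    eng.n_events++;
    if (eng.n_events % 262144 == 0) Rcpp::checkUserInterrupt();
  }
  // fill remaining frames (if duration not multiple of interval, none remain)
  int used = fi;

  NumericMatrix vout(n, 3);
  for (int k = 0; k < n; ++k)
    for (int a = 0; a < 3; ++a) vout(k, a) = eng.v[3 * k + a];

  return List::create(
    _["times"] = frame_times[Range(0, std::max(used - 1, 0))],
    _["frames"] = frames,
    _["n_frames"] = used,
    _["kinetic"] = ke_out[Range(0, std::max(used - 1, 0))],
    _["potential"] = pe_out[Range(0, std::max(used - 1, 0))],
    _["final_velocities"] = vout,
    _["n_events"] = (double)eng.n_events,
    _["n_pair_events"] = (double)eng.n_pair,
    _["n_thermostat_events"] = (double)eng.n_therm,
    _["n_wall_events"] = (double)eng.n_wall,
    _["n_plane_events"] = (double)eng.n_plane
  );
}
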