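// Bond fluctuation Monte Carlo engine with dynamic loop bonds.
//
// Monomers occupy 2x2x2 cubes on a periodic cubic lattice; the cube corner
// (smallest coordinates) is the monomer position. Positions are stored
// UNWRAPPED; only the occupancy lattice wraps, so observables never need
// minimum-image corrections as long as the chain extent stays below L/2.
//
// All randomness comes from a self-contained xoshiro256++ stream seeded from
// the caller, so trajectories are bitwise reproducible across machines.

#include <Rcpp.h>
#include <array>
#include <vector>
#include <unordered_map>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// RNG: splitmix64-seeded xoshiro256++, plus uniform/Poisson draws.

struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      x += 0x9E3779B97f4A7C15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
      z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t v, int k) {
    return (v << k) | (v >> (64 - k));
  }
  inline uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  inline double unif() { return (next() >> 11) * 0x1.0p-53; }
  inline int below(int n) { return (int)(next() % (uint64_t)n); }

  // Poisson: Knuth product method for small means, Hormann's PTRS
  // transformed rejection for large means.
  int poisson(double mu) {
    if (mu <= 0.0) return 0;
    if (mu < 30.0) {
      double lim = std::exp(-mu), p = 1.0;
      int k = 0;
      do { ++k; p *= unif(); } while (p > lim);
      return k - 1;
    }
    const double b = 0.931 + 2.53 * std::sqrt(mu);
    const double a = -0.059 + 0.02483 * b;
    const double inv_alpha = 1.1239 + 1.1328 / (b - 3.4);
    const double vr = 0.9277 - 3.6224 / (b - 2.0);
    for (;;) {
      double U = unif() - 0.5;
      double V = unif();
      double us = 0.5 - std::fabs(U);
      double k = std::floor((2.0 * a / us + b) * U + mu + 0.43);
      if (us >= 0.07 && V <= vr) return (int)k;
      if (k < 0.0 || (us < 0.013 && V > us)) continue;
      if (std::log(V) + std::log(inv_alpha) - std::log(a / (us * us) + b) <=
          k * std::log(mu) - mu - std::lgamma(k + 1.0)) return (int)k;
    }
  }
};

// ---------------------------------------------------------------------------
// Allowed bond vectors: all integer 3-vectors with squared length in
// {4, 5, 6, 9, 10} (the classic 3D set of 108 vectors; squared length 8 and
// anything > 10 are excluded, which prevents chain crossing).

static inline bool sq_allowed(int s2) {
  return s2 == 4 || s2 == 5 || s2 == 6 || s2 == 9 || s2 == 10;
}

static inline bool vec_allowed(long dx, long dy, long dz) {
  if (dx > 3 || dx < -3 || dy > 3 || dy < -3 || dz > 3 || dz < -3) return false;
  return sq_allowed((int)(dx * dx + dy * dy + dz * dz));
}

// The 108 vectors, enumerated once (used for SAW growth and proximity scan).
static std::vector<std::array<int, 3>> enumerate_allowed() {
  std::vector<std::array<int, 3>> v;
  for (int x = -3; x <= 3; ++x)
    for (int y = -3; y <= 3; ++y)
      for (int z = -3; z <= 3; ++z)
        if (vec_allowed(x, y, z)) v.push_back({x, y, z});
  return v;
}

// [[Rcpp::export]]
IntegerMatrix cpp_allowed_bond_vectors() {
  std::vector<std::array<int, 3>> v = enumerate_allowed();
  IntegerMatrix out(v.size(), 3);
  for (size_t i = 0; i < v.size(); ++i)
    for (int d = 0; d < 3; ++d) out(i, d) = v[i][d];
  return out;
}

// ---------------------------------------------------------------------------
// Occupancy lattice: site -> monomer id (-1 free). Dense array for small L,
// hash map for large L (full-scale L = 500 would need a 500 MB dense array).

struct Occupancy {
  long L;
  bool dense;
  std::vector<int32_t> grid;
  std::unordered_map<int64_t, int32_t> map;

  void init(long L_) {
    L = L_;
    dense = (L * L * L) <= 34000000L;
    if (dense) grid.assign((size_t)(L * L * L), -1);
    else map.clear();
  }
  inline long wrap(long a) const { long r = a % L; return r < 0 ? r + L : r; }
  inline int64_t key(long x, long y, long z) const {
    return (int64_t)((wrap(x) * L + wrap(y)) * L + wrap(z));
  }
  inline int32_t get(long x, long y, long z) const {
    int64_t k = key(x, y, z);
    if (dense) return grid[(size_t)k];
    std::unordered_map<int64_t, int32_t>::const_iterator it = map.find(k);
    return it == map.end() ? -1 : it->second;
  }
  inline void set(long x, long y, long z, int32_t id) {
    int64_t k = key(x, y, z);
    if (dense) grid[(size_t)k] = id;
    else map[k] = id;
  }
  inline void clear_site(long x, long y, long z) {
    int64_t k = key(x, y, z);
    if (dense) grid[(size_t)k] = -1;
    else map.erase(k);
  }
};

// ---------------------------------------------------------------------------
// Engine state.

struct LoopBond { int i, j; int64_t expires; };

struct Engine {
  int N;
  long L;
  std::vector<long> px, py, pz;        // unwrapped corner positions
  Occupancy occ;
  std::vector<std::vector<int>> partners;  // loop partners per monomer
  std::vector<LoopBond> bonds;
  int64_t clock_mcs;

  void place_cube(int id) {
    for (int a = 0; a < 2; ++a)
      for (int b = 0; b < 2; ++b)
        for (int c = 0; c < 2; ++c)
          occ.set(px[id] + a, py[id] + b, pz[id] + c, id);
  }

  // Build occupancy from positions; stop() on overlap.
  void build_occupancy() {
    occ.init(L);
    for (int i = 0; i < N; ++i) {
      for (int a = 0; a < 2; ++a)
        for (int b = 0; b < 2; ++b)
          for (int c = 0; c < 2; ++c) {
            if (occ.get(px[i] + a, py[i] + b, pz[i] + c) >= 0)
              stop("excluded-volume violation in input conformation (monomer %d)",
                   i + 1);
            occ.set(px[i] + a, py[i] + b, pz[i] + c, i);
          }
    }
  }

  bool cube_free(long x, long y, long z, int self) const {
    for (int a = 0; a < 2; ++a)
      for (int b = 0; b < 2; ++b)
        for (int c = 0; c < 2; ++c) {
          int32_t id = occ.get(x + a, y + b, z + c);
          if (id >= 0 && id != self) return false;
        }
    return true;
  }

  bool bonds_ok_at(int m, long nx, long ny, long nz) const {
    if (m > 0 &&
        !vec_allowed(nx - px[m - 1], ny - py[m - 1], nz - pz[m - 1]))
      return false;
    if (m < N - 1 &&
        !vec_allowed(nx - px[m + 1], ny - py[m + 1], nz - pz[m + 1]))
      return false;
    for (size_t k = 0; k < partners[m].size(); ++k) {
      int q = partners[m][k];
      if (!vec_allowed(nx - px[q], ny - py[q], nz - pz[q])) return false;
    }
    return true;
  }

  // One single-monomer move attempt; returns true iff accepted.
  bool attempt(int m, int dir) {
    static const int DX[6] = {1, -1, 0, 0, 0, 0};
    static const int DY[6] = {0, 0, 1, -1, 0, 0};
    static const int DZ[6] = {0, 0, 0, 0, 1, -1};
    long nx = px[m] + DX[dir], ny = py[m] + DY[dir], nz = pz[m] + DZ[dir];
    if (!bonds_ok_at(m, nx, ny, nz)) return false;
    // Entering face: the 4 sites of the new cube not covered by the old one.
    long ex = nx, ey = ny, ez = nz;
    int du = 0, dv = 1, dw = 2;  // axes spanning the face
    if (DX[dir] != 0) { ex = (DX[dir] > 0) ? px[m] + 2 : px[m] - 1; du = 1; dv = 2; }
    else if (DY[dir] != 0) { ey = (DY[dir] > 0) ? py[m] + 2 : py[m] - 1; du = 0; dv = 2; }
    else { ez = (DZ[dir] > 0) ? pz[m] + 2 : pz[m] - 1; du = 0; dv = 1; }
    (void)dw;
    for (int a = 0; a < 2; ++a)
      for (int b = 0; b < 2; ++b) {
        long sx = ex, sy = ey, sz = ez;
        long* c1 = (du == 0) ? &sx : (du == 1) ? &sy : &sz;
        long* c2 = (dv == 0) ? &sx : (dv == 1) ? &sy : &sz;
        *c1 += a; *c2 += b;
        int32_t id = occ.get(sx, sy, sz);
        if (id >= 0 && id != m) return false;
      }
    // Accept: clear leaving face, mark entering face, move.
    long lx = px[m], ly = py[m], lz = pz[m];
    if (DX[dir] != 0) lx = (DX[dir] > 0) ? px[m] : px[m] + 1;
    if (DY[dir] != 0) ly = (DY[dir] > 0) ? py[m] : py[m] + 1;
    if (DZ[dir] != 0) lz = (DZ[dir] > 0) ? pz[m] : pz[m] + 1;
    for (int a = 0; a < 2; ++a)
      for (int b = 0; b < 2; ++b) {
        long sx = lx, sy = ly, sz = lz;
        long* c1 = (du == 0) ? &sx : (du == 1) ? &sy : &sz;
        long* c2 = (dv == 0) ? &sx : (dv == 1) ? &sy : &sz;
        *c1 += a; *c2 += b;
        occ.clear_site(sx, sy, sz);
        long tx = ex, ty = ey, tz = ez;
        long* t1 = (du == 0) ? &tx : (du == 1) ? &ty : &tz;
        long* t2 = (dv == 0) ? &tx : (dv == 1) ? &ty : &tz;
        *t1 += a; *t2 += b;
        occ.set(tx, ty, tz, m);
      }
    px[m] = nx; py[m] = ny; pz[m] = nz;
    return true;
  }

  bool bonded(int i, int j) const {
    for (size_t k = 0; k < partners[i].size(); ++k)
      if (partners[i][k] == j) return true;
    return false;
  }

  void add_bond(int i, int j, int64_t expires) {
    bonds.push_back({i, j, expires});
    partners[i].push_back(j);
    partners[j].push_back(i);
  }

  void drop_partner(int i, int j) {
    std::vector<int>& v = partners[i];
    for (size_t k = 0; k < v.size(); ++k)
      if (v[k] == j) { v[k] = v.back(); v.pop_back(); return; }
  }

  double rg2() const {
    double cx = 0, cy = 0, cz = 0;
    for (int i = 0; i < N; ++i) { cx += px[i]; cy += py[i]; cz += pz[i]; }
    cx /= N; cy /= N; cz /= N;
    double s = 0;
    for (int i = 0; i < N; ++i) {
      double dx = px[i] - cx, dy = py[i] - cy, dz = pz[i] - cz;
      s += dx * dx + dy * dy + dz * dz;
    }
    return s / N;
  }
};

// Looping probability per pair; mode 0 = homogeneous, 1 = uniform_adapted,
// 2 = domain_adapted. domain_id: >= 1 inside a looped domain, 0 on a linker.
static inline double pair_prob(int i, int j, int mode, double p_short,
                               double p_long, double p_hom, int cutoff,
                               const std::vector<int>& domain_id,
                               bool linkers_inert) {
  if (mode == 0) return p_hom;
  if (mode == 1) return (std::abs(i - j) <= cutoff) ? p_short : p_long;
  int di = domain_id[i], dj = domain_id[j];
  if (di == 0 || dj == 0) return linkers_inert ? 0.0 : p_long;
  return (di == dj) ? p_short : p_long;
}

static Engine make_engine(const IntegerMatrix& pos, const IntegerMatrix& bonds,
                          long L, int64_t clock_mcs) {
  Engine e;
  e.N = pos.nrow();
  e.L = L;
  e.clock_mcs = clock_mcs;
  e.px.resize(e.N); e.py.resize(e.N); e.pz.resize(e.N);
  for (int i = 0; i < e.N; ++i) {
    e.px[i] = pos(i, 0); e.py[i] = pos(i, 1); e.pz[i] = pos(i, 2);
  }
  e.partners.assign(e.N, std::vector<int>());
  e.build_occupancy();
  for (int k = 0; k < bonds.nrow(); ++k) {
    int i = bonds(k, 0) - 1, j = bonds(k, 1) - 1;  // 1-based from R
    e.add_bond(i, j, bonds(k, 2));
  }
  return e;
}

static IntegerMatrix positions_out(const Engine& e) {
  IntegerMatrix out(e.N, 3);
  for (int i = 0; i < e.N; ++i) {
    out(i, 0) = (int)e.px[i]; out(i, 1) = (int)e.py[i]; out(i, 2) = (int)e.pz[i];
  }
  return out;
}

static IntegerMatrix bonds_out(const Engine& e) {
  IntegerMatrix out(e.bonds.size(), 3);
  for (size_t k = 0; k < e.bonds.size(); ++k) {
    out(k, 0) = e.bonds[k].i + 1;
    out(k, 1) = e.bonds[k].j + 1;
    out(k, 2) = (int)e.bonds[k].expires;
  }
  colnames(out) = CharacterVector::create("i", "j", "expires_at");
  return out;
}

// ---------------------------------------------------------------------------
// Main driver: run n_mcs Monte Carlo steps. Per MCS: moves_per_mcs move
// attempts, clock increment, bond dissociation (expires_at <= clock), then
// formation trials over currently proximal unbonded pairs in random order.

// [[Rcpp::export]]
List cpp_run(IntegerMatrix positions, IntegerMatrix loop_bonds, int L,
             double n_mcs, double clock_mcs, int moves_per_mcs, int mode,
             double p_short, double p_long, double p_hom, int cutoff,
             IntegerVector domain_id, bool linkers_inert, double t_bond,
             int max_bonds, double seed, double save_interval, int max_saves,
             double rg_interval, bool log_events) {
  Engine e = make_engine(positions, loop_bonds, L, (int64_t)clock_mcs);
  Xoshiro rng((uint64_t)seed);
  std::vector<int> dom(e.N, 0);
  if (domain_id.size() == e.N)
    for (int i = 0; i < e.N; ++i) dom[i] = domain_id[i];
  else if (mode == 2)
    stop("domain_adapted mode requires a domain layout of length N");

  bool any_p = (mode == 0 && p_hom > 0) ||
               (mode == 1 && (p_short > 0 || p_long > 0)) ||
               (mode == 2 && (p_short > 0 || (!linkers_inert || p_long > 0)));

  List snapshots;
  std::vector<double> snap_mcs;
  std::vector<double> rg_t, rg_v;
  std::vector<double> ev_mcs, ev_i, ev_j, ev_life;
  std::vector<int> ev_type;  // 1 form, 2 break
  double attempts = 0, accepts = 0;
  std::vector<std::pair<int, int>> cand;

  int64_t total = (int64_t)n_mcs;
  for (int64_t step = 0; step < total; ++step) {
    for (int t = 0; t < moves_per_mcs; ++t) {
      int m = rng.below(e.N);
      int dir = rng.below(6);
      ++attempts;
      if (e.attempt(m, dir)) ++accepts;
    }
    ++e.clock_mcs;

    // Dissociation.
    for (size_t k = 0; k < e.bonds.size();) {
      if (e.bonds[k].expires <= e.clock_mcs) {
        if (log_events) {
          ev_mcs.push_back((double)e.clock_mcs); ev_type.push_back(2);
          ev_i.push_back(e.bonds[k].i + 1); ev_j.push_back(e.bonds[k].j + 1);
          ev_life.push_back(NA_REAL);
        }
        e.drop_partner(e.bonds[k].i, e.bonds[k].j);
        e.drop_partner(e.bonds[k].j, e.bonds[k].i);
        e.bonds[k] = e.bonds.back();
        e.bonds.pop_back();
      } else ++k;
    }

    // Formation over proximal pairs (separation vector itself a legal bond
    // vector), visited in a freshly shuffled order.
    if (any_p) {
      static std::vector<std::array<int, 3>> offs = enumerate_allowed();
      cand.clear();
      for (int i = 0; i < e.N; ++i) {
        if ((int)e.partners[i].size() >= max_bonds) continue;
        for (size_t o = 0; o < offs.size(); ++o) {
          long tx = e.px[i] + offs[o][0], ty = e.py[i] + offs[o][1],
               tz = e.pz[i] + offs[o][2];
          int32_t j = e.occ.get(tx, ty, tz);
          if (j <= i + 1) continue;  // unordered pairs, |i-j| >= 2
          // corner must match exactly in unwrapped coordinates (no images)
          if (e.px[j] != tx || e.py[j] != ty || e.pz[j] != tz) continue;
          cand.push_back(std::make_pair(i, (int)j));
        }
      }
      // Fisher-Yates shuffle
      for (size_t k = cand.size(); k > 1; --k) {
        size_t r = (size_t)rng.below((int)k);
        std::swap(cand[k - 1], cand[r]);
      }
      for (size_t k = 0; k < cand.size(); ++k) {
        int i = cand[k].first, j = cand[k].second;
        if ((int)e.partners[i].size() >= max_bonds ||
            (int)e.partners[j].size() >= max_bonds) continue;
        if (e.bonded(i, j)) continue;
        double p = pair_prob(i, j, mode, p_short, p_long, p_hom, cutoff, dom,
                             linkers_inert);
        if (p <= 0.0) continue;
        if (rng.unif() < p) {
          int life = rng.poisson(t_bond);
          e.add_bond(i, j, e.clock_mcs + life);
          if (log_events) {
            ev_mcs.push_back((double)e.clock_mcs); ev_type.push_back(1);
            ev_i.push_back(i + 1); ev_j.push_back(j + 1);
            ev_life.push_back((double)life);
          }
        }
      }
    }

    if (rg_interval > 0 && ((step + 1) % (int64_t)rg_interval == 0)) {
      rg_t.push_back((double)e.clock_mcs);
      rg_v.push_back(e.rg2());
    }
    if (save_interval > 0 && ((step + 1) % (int64_t)save_interval == 0) &&
        snapshots.size() < max_saves) {
      snapshots.push_back(List::create(_["positions"] = positions_out(e),
                                       _["loop_bonds"] = bonds_out(e),
                                       _["mcs"] = (double)e.clock_mcs));
      snap_mcs.push_back((double)e.clock_mcs);
    }
    if ((step & 0x3FF) == 0) Rcpp::checkUserInterrupt();
  }

  List events = List::create(
      _["mcs"] = wrap(ev_mcs), _["event"] = wrap(ev_type),
      _["i"] = wrap(ev_i), _["j"] = wrap(ev_j), _["lifetime"] = wrap(ev_life));

  return List::create(
      _["positions"] = positions_out(e), _["loop_bonds"] = bonds_out(e),
      _["mcs_clock"] = (double)e.clock_mcs, _["snapshots"] = snapshots,
      _["snapshot_mcs"] = wrap(snap_mcs), _["rg2_mcs"] = wrap(rg_t),
      _["rg2"] = wrap(rg_v), _["events"] = events,
      _["attempts"] = attempts, _["accepts"] = accepts);
}

// ---------------------------------------------------------------------------
// Single deterministic move attempt (for tests and the attempt_move API).
// monomer 1-based; direction in 1..6 (+x,-x,+y,-y,+z,-z); if either is 0 the
// choice is drawn from the seeded stream.

// [[Rcpp::export]]
List cpp_attempt_move(IntegerMatrix positions, IntegerMatrix loop_bonds, int L,
                      int monomer, int direction, double seed) {
  Engine e = make_engine(positions, loop_bonds, L, 0);
  Xoshiro rng((uint64_t)seed);
  int m = (monomer > 0) ? monomer - 1 : rng.below(e.N);
  int dir = (direction > 0) ? direction - 1 : rng.below(6);
  bool ok = e.attempt(m, dir);
  return List::create(_["moved"] = ok, _["monomer"] = m + 1,
                      _["direction"] = dir + 1,
                      _["positions"] = positions_out(e));
}

// ---------------------------------------------------------------------------
// Proximal pairs through the occupancy lattice (spatial binning by cube
// sites); the R-level oracle is an all-pairs scan.

// [[Rcpp::export]]
IntegerMatrix cpp_proximal_pairs(IntegerMatrix positions, int L) {
  Engine e;
  e.N = positions.nrow();
  e.L = L;
  e.clock_mcs = 0;
  e.px.resize(e.N); e.py.resize(e.N); e.pz.resize(e.N);
  for (int i = 0; i < e.N; ++i) {
    e.px[i] = positions(i, 0); e.py[i] = positions(i, 1);
    e.pz[i] = positions(i, 2);
  }
  e.partners.assign(e.N, std::vector<int>());
  e.build_occupancy();
  std::vector<std::array<int, 3>> offs = enumerate_allowed();
  std::vector<int> ii, jj;
  for (int i = 0; i < e.N; ++i)
    for (size_t o = 0; o < offs.size(); ++o) {
      long tx = e.px[i] + offs[o][0], ty = e.py[i] + offs[o][1],
           tz = e.pz[i] + offs[o][2];
      int32_t j = e.occ.get(tx, ty, tz);
      if (j <= i + 1) continue;
      if (e.px[j] != tx || e.py[j] != ty || e.pz[j] != tz) continue;
      ii.push_back(i + 1); jj.push_back((int)j + 1);
    }
  IntegerMatrix out(ii.size(), 2);
  for (size_t k = 0; k < ii.size(); ++k) { out(k, 0) = ii[k]; out(k, 1) = jj[k]; }
  colnames(out) = CharacterVector::create("i", "j");
  return out;
}

// ---------------------------------------------------------------------------
// Random self-avoiding walk growth; restarts from scratch when trapped.

// [[Rcpp::export]]
IntegerMatrix cpp_init_saw(int N, int L, double seed, int max_restarts) {
  Xoshiro rng((uint64_t)seed);
  std::vector<std::array<int, 3>> offs = enumerate_allowed();
  const int nv = (int)offs.size();
  for (int attempt = 0; attempt <= max_restarts; ++attempt) {
    Occupancy occ;
    occ.init(L);
    std::vector<long> px(N), py(N), pz(N);
    px[0] = L / 2; py[0] = L / 2; pz[0] = L / 2;
    for (int a = 0; a < 2; ++a)
      for (int b = 0; b < 2; ++b)
        for (int c = 0; c < 2; ++c) occ.set(px[0] + a, py[0] + b, pz[0] + c, 0);
    bool ok = true;
    std::vector<int> order(nv);
    for (int k = 1; k < N && ok; ++k) {
      for (int v = 0; v < nv; ++v) order[v] = v;
      for (int v = nv; v > 1; --v) std::swap(order[v - 1], order[rng.below(v)]);
      bool placed = false;
      for (int v = 0; v < nv && !placed; ++v) {
        const std::array<int, 3>& d = offs[order[v]];
        long nx = px[k - 1] + d[0], ny = py[k - 1] + d[1], nz = pz[k - 1] + d[2];
        bool free_ = true;
        for (int a = 0; a < 2 && free_; ++a)
          for (int b = 0; b < 2 && free_; ++b)
            for (int c = 0; c < 2; ++c)
              if (occ.get(nx + a, ny + b, nz + c) >= 0) { free_ = false; break; }
        if (!free_) continue;
        px[k] = nx; py[k] = ny; pz[k] = nz;
        for (int a = 0; a < 2; ++a)
          for (int b = 0; b < 2; ++b)
            for (int c = 0; c < 2; ++c) occ.set(nx + a, ny + b, nz + c, k);
        placed = true;
      }
      if (!placed) ok = false;
    }
    if (ok) {
      IntegerMatrix out(N, 3);
      for (int i = 0; i < N; ++i) {
        out(i, 0) = (int)px[i]; out(i, 1) = (int)py[i]; out(i, 2) = (int)pz[i];
      }
      return out;
    }
  }
  stop("self-avoiding walk growth failed after %d restarts (lattice too dense?)",
       max_restarts + 1);
}

// [[Rcpp::export]]
IntegerVector cpp_poisson_draws(int n, double mean, double seed) {
  Xoshiro rng((uint64_t)seed);
  IntegerVector out(n);
  for (int k = 0; k < n; ++k) out[k] = rng.poisson(mean);
  return out;
}
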