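// Cubic-lattice Monte Carlo engine for polypeptide aggregation.
//
// Bead type codes: 0 = H, 1 = P, 2 = "+", 3 = "-", 4 = Ps (hydrophilic
// surface bead), 5 = Hs (hydrophobic surface bead).  Energies are in units
// of the hydrogen-bond energy; temperature in the same units (k_B = 1).
//
// Geometry: sites are 0-based integer triples inside an Lx x Ly x Lz box.
// Bulk systems are periodic on all axes.  With a surface attached the box
// is a slab: x and y periodic, z a wall axis with the surface plane at
// z = 0, balls at z = 1 (and 2), and chain beads restricted to
// 1 <= z <= Lz - 1.
//
// All randomness uses an explicitly seeded xoshiro-free mt19937_64 with
// modular integer draws and a 53-bit uniform double, so trajectories are
// bit-reproducible for a given seed independent of the C++ standard
// library's distribution implementations.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
#include <cstdlib>
#include <random>

using namespace Rcpp;

namespace {

const int DX[6] = {1, -1, 0, 0, 0, 0};
const int DY[6] = {0, 0, 1, -1, 0, 0};
const int DZ[6] = {0, 0, 0, 0, 1, -1};

struct Delta {
  double ei = 0.0, ee = 0.0, es = 0.0;
  long long ni = 0;
  double total() const { return ei + ee + es; }
};

// Move kinds: 0 tail rotation, 1 corner flip, 2 crankshaft,
//             3 rigid rotation, 4 rigid translation.
struct Prop {
  int kind = -1;
  int chain = -1;
  int nb = 0;
  std::vector<int> beads, ox, oy, oz, nx, ny, nz;
  bool valid = false;
  void ensure(int cap) {
    if ((int)beads.size() < cap) {
      beads.resize(cap); ox.resize(cap); oy.resize(cap); oz.resize(cap);
      nx.resize(cap); ny.resize(cap); nz.resize(cap);
    }
  }
  void reset() { nb = 0; valid = false; kind = -1; chain = -1; }
};

struct Sim {
  int Lx = 0, Ly = 0, Lz = 0;
  bool slab = false;
  int zmin = 0, zmax = 0;
  int N = 0, M = 0;
  std::vector<int> btype;          // per-bead chain types, length M
  std::vector<int> cx, cy, cz;     // N*M coordinates
  std::vector<int> occ;            // site -> occupant
  double emat[6][6];
  int surf_type = -1;              // 4 Ps, 5 Hs, -1 none
  double E_intra = 0, E_inter = 0, E_surf = 0;
  long long n_inter = 0;
  std::mt19937_64 rng;
  Prop prop;
  std::vector<int> scx, scy, scz;  // unwrap scratch
  long long att[5] = {0, 0, 0, 0, 0};
  long long rej[5] = {0, 0, 0, 0, 0};
  long long acc[5] = {0, 0, 0, 0, 0};

  static constexpr int EMPTY = -1;
  static constexpr int SURF = -2;

  inline long long ru(long long n) { return (long long)(rng() % (uint64_t)n); }
  inline double u01() { return (rng() >> 11) * (1.0 / 9007199254740992.0); }

  inline int idx(int x, int y, int z) const { return (z * Ly + y) * Lx + x; }
  inline int wx(int x) const { x %= Lx; return x < 0 ? x + Lx : x; }
  inline int wy(int y) const { y %= Ly; return y < 0 ? y + Ly : y; }
  inline int wz(int z) const {
    if (slab) return z;
    z %= Lz; return z < 0 ? z + Lz : z;
  }
  // neighbour site in direction d; false when the step crosses a wall
  inline bool nbr(int x, int y, int z, int d, int &ax, int &ay, int &az) const {
    ax = wx(x + DX[d]); ay = wy(y + DY[d]); az = z + DZ[d];
    if (slab) { if (az < 0 || az >= Lz) return false; }
    else az = wz(az);
    return true;
  }
  static inline int mimg(int d, int L, bool periodic) {
    if (!periodic) return d;
    if (d > L / 2) d -= L; else if (d < -L / 2) d += L;
    return d;
  }
  inline void sep(int x1, int y1, int z1, int x2, int y2, int z2,
                  int &dx, int &dy, int &dz) const {
    dx = mimg(x2 - x1, Lx, true);
    dy = mimg(y2 - y1, Ly, true);
    dz = mimg(z2 - z1, Lz, !slab);
  }
  inline bool dist1(int x1, int y1, int z1, int x2, int y2, int z2) const {
    int dx, dy, dz; sep(x1, y1, z1, x2, y2, z2, dx, dy, dz);
    return std::abs(dx) + std::abs(dy) + std::abs(dz) == 1;
  }
  inline double pe(int ta, int tb) const { return emat[ta][tb]; }

  void full_energy(double &ei, double &ee, double &es, long long &ni) const {
    ei = ee = es = 0.0; ni = 0;
    for (int c = 0; c < N; ++c) {
      for (int i = 0; i < M; ++i) {
        const int code = c * M + i;
        const int x = cx[code], y = cy[code], z = cz[code];
        const int ti = btype[i];
        for (int d = 0; d < 6; ++d) {
          int ax, ay, az;
          if (!nbr(x, y, z, d, ax, ay, az)) continue;
          const int o = occ[idx(ax, ay, az)];
          if (o == SURF) {
            es += pe(ti, surf_type);
          } else if (o >= 0 && (d == 0 || d == 2 || d == 4)) {
            // half shell (+x, +y, +z): each chain-chain pair counted once
            const int c2 = o / M, i2 = o % M;
            if (c2 == c) {
              if (std::abs(i2 - i) >= 2) ei += pe(ti, btype[i2]);
            } else {
              ee += pe(ti, btype[i2]);
              ++ni;
            }
          }
        }
      }
    }
  }

  // local contact terms of the moved-bead set against the rest of the
  // system (moved beads must already be absent from occ) plus pairs
  // inside the moved set
  Delta local_terms(const Prop &p, bool use_old) const {
    Delta t;
    for (int s = 0; s < p.nb; ++s) {
      const int i = p.beads[s];
      const int ti = btype[i];
      const int x = use_old ? p.ox[s] : p.nx[s];
      const int y = use_old ? p.oy[s] : p.ny[s];
      const int z = use_old ? p.oz[s] : p.nz[s];
      for (int d = 0; d < 6; ++d) {
        int ax, ay, az;
        if (!nbr(x, y, z, d, ax, ay, az)) continue;
        const int o = occ[idx(ax, ay, az)];
        if (o == SURF) {
          t.es += pe(ti, surf_type);
        } else if (o >= 0) {
          const int c2 = o / M, i2 = o % M;
          if (c2 == p.chain) {
            if (std::abs(i2 - i) >= 2) t.ei += pe(ti, btype[i2]);
          } else {
            t.ee += pe(ti, btype[i2]);
            ++t.ni;
          }
        }
      }
    }
    for (int s = 0; s < p.nb; ++s) {
      for (int s2 = s + 1; s2 < p.nb; ++s2) {
        if (std::abs(p.beads[s] - p.beads[s2]) < 2) continue;
        const int x1 = use_old ? p.ox[s] : p.nx[s];
        const int y1 = use_old ? p.oy[s] : p.ny[s];
        const int z1 = use_old ? p.oz[s] : p.nz[s];
        const int x2 = use_old ? p.ox[s2] : p.nx[s2];
        const int y2 = use_old ? p.oy[s2] : p.ny[s2];
        const int z2 = use_old ? p.oz[s2] : p.nz[s2];
        if (dist1(x1, y1, z1, x2, y2, z2))
          t.ei += pe(btype[p.beads[s]], btype[p.beads[s2]]);
      }
    }
    return t;
  }

  Delta delta_energy(const Prop &p) {
    for (int s = 0; s < p.nb; ++s)
      occ[idx(p.ox[s], p.oy[s], p.oz[s])] = EMPTY;
    const Delta before = local_terms(p, true);
    const Delta after = local_terms(p, false);
    for (int s = 0; s < p.nb; ++s)
      occ[idx(p.ox[s], p.oy[s], p.oz[s])] = p.chain * M + p.beads[s];
    Delta d;
    d.ei = after.ei - before.ei;
    d.ee = after.ee - before.ee;
    d.es = after.es - before.es;
    d.ni = after.ni - before.ni;
    return d;
  }

  void apply(const Prop &p, const Delta &d) {
    for (int s = 0; s < p.nb; ++s)
      occ[idx(p.ox[s], p.oy[s], p.oz[s])] = EMPTY;
    for (int s = 0; s < p.nb; ++s) {
      const int code = p.chain * M + p.beads[s];
      cx[code] = p.nx[s]; cy[code] = p.ny[s]; cz[code] = p.nz[s];
      occ[idx(p.nx[s], p.ny[s], p.nz[s])] = code;
    }
    E_intra += d.ei; E_inter += d.ee; E_surf += d.es; n_inter += d.ni;
  }

  void revert(const Prop &p, const Delta &d) {
    for (int s = 0; s < p.nb; ++s)
      occ[idx(p.nx[s], p.ny[s], p.nz[s])] = EMPTY;
    for (int s = 0; s < p.nb; ++s) {
      const int code = p.chain * M + p.beads[s];
      cx[code] = p.ox[s]; cy[code] = p.oy[s]; cz[code] = p.oz[s];
      occ[idx(p.ox[s], p.oy[s], p.oz[s])] = code;
    }
    E_intra -= d.ei; E_inter -= d.ee; E_surf -= d.es; n_inter -= d.ni;
  }

  inline bool z_ok(int z) const { return !slab || (z >= zmin && z <= zmax); }

  // Local move: uniform chain, uniform kind among {tail, corner, crank},
  // uniform applicable site for the kind; geometric failure leaves
  // prop.valid = false (a null attempt, preserving detailed balance).
  void gen_local(Prop &p) {
    p.reset();
    p.ensure(M);
    p.chain = (int)ru(N);
    const int base = p.chain * M;
    const int k = (int)ru(3);
    p.kind = k;
    if (k == 0) {                               // tail rotation
      const int i = ru(2) ? M - 1 : 0;
      const int a = (i == 0) ? 1 : M - 2;
      const int d = (int)ru(6);
      int tx, ty, tz;
      if (!nbr(cx[base + a], cy[base + a], cz[base + a], d, tx, ty, tz)) return;
      if (!z_ok(tz)) return;
      const int ci = base + i;
      const bool null_move =
        (tx == cx[ci] && ty == cy[ci] && tz == cz[ci]);
      if (!null_move && occ[idx(tx, ty, tz)] != EMPTY) return;
      p.nb = 1; p.beads[0] = i;
      p.ox[0] = cx[ci]; p.oy[0] = cy[ci]; p.oz[0] = cz[ci];
      p.nx[0] = tx; p.ny[0] = ty; p.nz[0] = tz;
      p.valid = true;
    } else if (k == 1) {                        // corner flip
      if (M < 3) return;
      const int i = 1 + (int)ru(M - 2);
      const int cm = base + i - 1, ci = base + i, cp = base + i + 1;
      int b1x, b1y, b1z, b2x, b2y, b2z;
      sep(cx[cm], cy[cm], cz[cm], cx[ci], cy[ci], cz[ci], b1x, b1y, b1z);
      sep(cx[ci], cy[ci], cz[ci], cx[cp], cy[cp], cz[cp], b2x, b2y, b2z);
      if (b1x == b2x && b1y == b2y && b1z == b2z) return;  // straight segment
      const int tx = wx(cx[cm] + b2x);
      const int ty = wy(cy[cm] + b2y);
      const int tz = slab ? cz[cm] + b2z : wz(cz[cm] + b2z);
      if (!z_ok(tz)) return;
      if (occ[idx(tx, ty, tz)] != EMPTY) return;
      p.nb = 1; p.beads[0] = i;
      p.ox[0] = cx[ci]; p.oy[0] = cy[ci]; p.oz[0] = cz[ci];
      p.nx[0] = tx; p.ny[0] = ty; p.nz[0] = tz;
      p.valid = true;
    } else {                                    // crankshaft
      if (M < 4) return;
      const int i = 1 + (int)ru(M - 3);         // U-segment (i, i+1)
      const int ca = base + i - 1, ci = base + i,
                cj = base + i + 1, cb = base + i + 2;
      int vx, vy, vz, ux, uy, uz, wxv, wyv, wzv;
      sep(cx[ca], cy[ca], cz[ca], cx[ci], cy[ci], cz[ci], vx, vy, vz);
      sep(cx[ci], cy[ci], cz[ci], cx[cj], cy[cj], cz[cj], ux, uy, uz);
      sep(cx[cj], cy[cj], cz[cj], cx[cb], cy[cb], cz[cb], wxv, wyv, wzv);
      if (wxv != -vx || wyv != -vy || wzv != -vz) return;  // not a U
      // candidate displacements: unit vectors perpendicular to the
      // anchor axis u, excluding the current v (3 of them; the 90, 180
      // and 270 degree rotations about the axis)
      int candd[4]; int ncand = 0;
      for (int d = 0; d < 6; ++d) {
        if (DX[d] * ux + DY[d] * uy + DZ[d] * uz != 0) continue;
        if (DX[d] == vx && DY[d] == vy && DZ[d] == vz) continue;
        candd[ncand++] = d;
      }
      const int d = candd[(int)ru(ncand)];
      const int n1x = wx(cx[ca] + DX[d]);
      const int n1y = wy(cy[ca] + DY[d]);
      const int n1z = slab ? cz[ca] + DZ[d] : wz(cz[ca] + DZ[d]);
      if (!z_ok(n1z)) return;
      const int n2x = wx(n1x + ux);
      const int n2y = wy(n1y + uy);
      const int n2z = slab ? n1z + uz : wz(n1z + uz);
      if (!z_ok(n2z)) return;
      const int o1 = occ[idx(n1x, n1y, n1z)];
      const int o2 = occ[idx(n2x, n2y, n2z)];
      // targets can never coincide with the old sites of beads i, i+1
      if (o1 != EMPTY || o2 != EMPTY) return;
      p.nb = 2;
      p.beads[0] = i; p.beads[1] = i + 1;
      p.ox[0] = cx[ci]; p.oy[0] = cy[ci]; p.oz[0] = cz[ci];
      p.ox[1] = cx[cj]; p.oy[1] = cy[cj]; p.oz[1] = cz[cj];
      p.nx[0] = n1x; p.ny[0] = n1y; p.nz[0] = n1z;
      p.nx[1] = n2x; p.ny[1] = n2y; p.nz[1] = n2z;
      p.valid = true;
    }
  }

  void unwrap_chain(int c) {
    const int base = c * M;
    scx[0] = cx[base]; scy[0] = cy[base]; scz[0] = cz[base];
    for (int i = 1; i < M; ++i) {
      int dx, dy, dz;
      sep(cx[base + i - 1], cy[base + i - 1], cz[base + i - 1],
          cx[base + i], cy[base + i], cz[base + i], dx, dy, dz);
      scx[i] = scx[i - 1] + dx;
      scy[i] = scy[i - 1] + dy;
      scz[i] = scz[i - 1] + dz;
    }
  }

  static inline void rot90(int axis, int s, int vx, int vy, int vz,
                           int &rx, int &ry, int &rz) {
    switch (axis) {
      case 0: rx = vx; ry = -s * vz; rz = s * vy; break;
      case 1: rx = s * vz; ry = vy; rz = -s * vx; break;
      default: rx = -s * vy; ry = s * vx; rz = vz; break;
    }
  }

  // Global move: half rigid translation by one lattice unit, half rigid
  // 90-degree rotation about a coordinate axis through a uniformly chosen
  // pivot bead.
  void gen_global(Prop &p) {
    p.reset();
    p.ensure(M);
    p.chain = (int)ru(N);
    const int base = p.chain * M;
    const bool translate = ru(2) == 0;
    p.kind = translate ? 4 : 3;
    if (translate) {
      const int d = (int)ru(6);
      for (int i = 0; i < M; ++i) {
        const int code = base + i;
        p.beads[i] = i;
        p.ox[i] = cx[code]; p.oy[i] = cy[code]; p.oz[i] = cz[code];
        p.nx[i] = wx(cx[code] + DX[d]);
        p.ny[i] = wy(cy[code] + DY[d]);
        const int tz = slab ? cz[code] + DZ[d] : wz(cz[code] + DZ[d]);
        if (!z_ok(tz)) return;
        p.nz[i] = tz;
      }
    } else {
      const int axis = (int)ru(3);
      const int sense = ru(2) ? 1 : -1;
      const int pv = (int)ru(M);
      unwrap_chain(p.chain);
      for (int i = 0; i < M; ++i) {
        const int code = base + i;
        p.beads[i] = i;
        p.ox[i] = cx[code]; p.oy[i] = cy[code]; p.oz[i] = cz[code];
        int rx, ry, rz;
        rot90(axis, sense, scx[i] - scx[pv], scy[i] - scy[pv],
              scz[i] - scz[pv], rx, ry, rz);
        const int tz = scz[pv] + rz;
        if (!z_ok(slab ? tz : wz(tz))) return;
        p.nx[i] = wx(scx[pv] + rx);
        p.ny[i] = wy(scy[pv] + ry);
        p.nz[i] = slab ? tz : wz(tz);
      }
    }
    p.nb = M;
    for (int i = 0; i < M; ++i) {
      const int o = occ[idx(p.nx[i], p.ny[i], p.nz[i])];
      if (o == EMPTY) continue;
      if (o >= 0 && o / M == p.chain) continue;  // own old site
      return;
    }
    // rigid images are distinct in unwrapped space; wrapping can fold a
    // chain onto itself only when an axis length is smaller than the
    // chain extent, so check explicitly
    for (int i = 0; i < M; ++i)
      for (int j = i + 1; j < M; ++j)
        if (p.nx[i] == p.nx[j] && p.ny[i] == p.ny[j] && p.nz[i] == p.nz[j])
          return;
    p.valid = true;
  }

  // one elementary attempt; returns true when the move was accepted
  bool attempt(double p_global, double temperature) {
    if (N == 0) return false;
    const bool global = u01() < p_global;
    if (global) gen_global(prop); else gen_local(prop);
    if (prop.kind >= 0) ++att[prop.kind];
    if (!prop.valid) {
      if (prop.kind >= 0) ++rej[prop.kind];
      return false;
    }
    const Delta d = delta_energy(prop);
    const double dE = d.total();
    if (dE <= 0.0 || u01() < std::exp(-dE / temperature)) {
      apply(prop, d);
      ++acc[prop.kind];
      return true;
    }
    return false;
  }
};

void check_emat(const NumericMatrix &emat) {
  if (emat.nrow() != 6 || emat.ncol() != 6)
    stop("energy matrix must be 6 x 6");
}

// Build a Sim from R-side state pieces, validating chain geometry and
// occupancy exclusivity (chains vs chains, chains vs surface sites).
Sim build_sim(const IntegerMatrix &coords, const IntegerVector &types,
              const IntegerVector &box, Nullable<IntegerMatrix> heights,
              int surf_chem, const NumericMatrix &emat, double seed) {
  Sim s;
  if (box.size() != 3) stop("box must have three dimensions");
  s.Lx = box[0]; s.Ly = box[1]; s.Lz = box[2];
  if (s.Lx < 4 || s.Ly < 4 || s.Lz < 4)
    stop("box dimensions must be at least 4");
  s.M = types.size();
  if (s.M < 1) stop("empty peptide sequence");
  s.btype.assign(types.begin(), types.end());
  for (int t : s.btype)
    if (t < 0 || t > 3) stop("chain bead types must be coded 0..3");
  if (coords.ncol() != 3) stop("coords must have three columns");
  if (coords.nrow() % s.M != 0)
    stop("coordinate rows are not a multiple of the sequence length");
  s.N = coords.nrow() / s.M;
  check_emat(emat);
  for (int a = 0; a < 6; ++a)
    for (int b = 0; b < 6; ++b) s.emat[a][b] = emat(a, b);
  s.occ.assign((size_t)s.Lx * s.Ly * s.Lz, Sim::EMPTY);
  s.slab = heights.isNotNull();
  s.zmin = 0; s.zmax = s.Lz - 1;
  s.surf_type = -1;
  if (s.slab) {
    IntegerMatrix h(heights);
    if (h.nrow() != s.Lx || h.ncol() != s.Ly)
      stop("height field must be Lx x Ly");
    if (surf_chem != 4 && surf_chem != 5)
      stop("surface chemistry must be Ps (4) or Hs (5)");
    s.surf_type = surf_chem;
    s.zmin = 1;
    for (int x = 0; x < s.Lx; ++x) {
      for (int y = 0; y < s.Ly; ++y) {
        const int hv = h(x, y);
        if (hv < 0 || hv > 2) stop("heights must be 0, 1 or 2");
        s.occ[s.idx(x, y, 0)] = Sim::SURF;
        if (hv >= 1) s.occ[s.idx(x, y, 1)] = Sim::SURF;
        if (hv == 2) s.occ[s.idx(x, y, 2)] = Sim::SURF;
      }
    }
  }
  s.cx.resize((size_t)s.N * s.M);
  s.cy.resize((size_t)s.N * s.M);
  s.cz.resize((size_t)s.N * s.M);
  for (int c = 0; c < s.N; ++c) {
    for (int i = 0; i < s.M; ++i) {
      const int code = c * s.M + i;
      const int x = coords(code, 0), y = coords(code, 1), z = coords(code, 2);
      if (x < 0 || x >= s.Lx || y < 0 || y >= s.Ly || z < 0 || z >= s.Lz)
        stop("bead (chain %d, bead %d) outside the box", c + 1, i + 1);
      if (s.slab && (z < s.zmin || z > s.zmax))
        stop("bead (chain %d, bead %d) inside the surface layer", c + 1, i + 1);
      const int at = s.idx(x, y, z);
      if (s.occ[at] == Sim::SURF)
        stop("bead (chain %d, bead %d) collides with a surface site",
             c + 1, i + 1);
      if (s.occ[at] != Sim::EMPTY)
        stop("site occupied twice: chain %d bead %d and chain %d bead %d",
             s.occ[at] / s.M + 1, s.occ[at] % s.M + 1, c + 1, i + 1);
      s.occ[at] = code;
      s.cx[code] = x; s.cy[code] = y; s.cz[code] = z;
      if (i > 0) {
        if (!s.dist1(s.cx[code - 1], s.cy[code - 1], s.cz[code - 1], x, y, z))
          stop("bond length != 1 between beads %d and %d of chain %d",
               i, i + 1, c + 1);
      }
    }
  }
  s.scx.resize(s.M); s.scy.resize(s.M); s.scz.resize(s.M);
  s.rng.seed((uint64_t)(int64_t)seed);
  s.rng.discard(8);
  s.full_energy(s.E_intra, s.E_inter, s.E_surf, s.n_inter);
  s.prop.ensure(s.M);
  return s;
}

IntegerMatrix coords_out(const Sim &s) {
  IntegerMatrix out(s.N * s.M, 3);
  for (int k = 0; k < s.N * s.M; ++k) {
    out(k, 0) = s.cx[k]; out(k, 1) = s.cy[k]; out(k, 2) = s.cz[k];
  }
  return out;
}

}  // namespace

// [[Rcpp::export]]
List cpp_total_energy(IntegerMatrix coords, IntegerVector types,
                      IntegerVector box, Nullable<IntegerMatrix> heights,
                      int surf_chem, NumericMatrix emat) {
  Sim s = build_sim(coords, types, box, heights, surf_chem, emat, 1.0);
  return List::create(_["e_intra"] = s.E_intra, _["e_inter"] = s.E_inter,
                      _["e_surf"] = s.E_surf,
                      _["e_total"] = s.E_intra + s.E_inter + s.E_surf,
                      _["n_inter"] = (double)s.n_inter);
}

// [[Rcpp::export]]
List cpp_run_trajectory(IntegerMatrix coords, IntegerVector types,
                        IntegerVector box, Nullable<IntegerMatrix> heights,
                        int surf_chem, NumericMatrix emat,
                        double temperature, double p_global,
                        double max_mcs, double measure_interval,
                        bool sweep_mode, double stop_contacts, double seed) {
  Sim s = build_sim(coords, types, box, heights, surf_chem, emat, seed);
  if (temperature <= 0) stop("temperature must be positive");
  const long long maxm = (long long)max_mcs;
  long long interval = (long long)measure_interval;
  if (interval < 1) interval = 1;
  const long long stop_n = stop_contacts > 0 ? (long long)stop_contacts : -1;
  const long long cap = maxm / interval + 3;
  NumericMatrix meas(cap, 6);
  long long nrow = 0;
  auto record = [&](long long mcs) {
    meas(nrow, 0) = (double)mcs;
    meas(nrow, 1) = s.E_intra;
    meas(nrow, 2) = s.E_inter;
    meas(nrow, 3) = s.E_surf;
    meas(nrow, 4) = s.E_intra + s.E_inter + s.E_surf;
    meas(nrow, 5) = (double)s.n_inter;
    ++nrow;
  };
  record(0);
  long long fp = -1;
  const int per_mcs = sweep_mode ? s.N * s.M : 1;
  if (s.N > 0 && !(stop_n > 0 && s.n_inter >= stop_n)) {
    for (long long mcs = 1; mcs <= maxm; ++mcs) {
      for (int a = 0; a < per_mcs; ++a) s.attempt(p_global, temperature);
      if (stop_n > 0 && s.n_inter >= stop_n) {
        fp = mcs;
        record(mcs);
        break;
      }
      if (mcs % interval == 0) record(mcs);
      if (mcs % 1048576 == 0) Rcpp::checkUserInterrupt();
    }
  } else if (stop_n > 0 && s.n_inter >= stop_n) {
    fp = 0;
  }
  NumericMatrix out(nrow, 6);
  for (long long r = 0; r < nrow; ++r)
    for (int c = 0; c < 6; ++c) out(r, c) = meas(r, c);
  colnames(out) = CharacterVector::create("mcs", "e_intra", "e_inter",
                                          "e_surf", "e_total", "n_inter");
  NumericMatrix counts(5, 3);
  for (int k = 0; k < 5; ++k) {
    counts(k, 0) = (double)s.att[k];
    counts(k, 1) = (double)s.rej[k];
    counts(k, 2) = (double)s.acc[k];
  }
  rownames(counts) = CharacterVector::create(
    "tail_rotation", "corner_flip", "crankshaft", "rigid_rotation",
    "rigid_translation");
  colnames(counts) = CharacterVector::create("attempted", "geometry_rejected",
                                             "accepted");
  return List::create(
    _["measurements"] = out, _["final_coords"] = coords_out(s),
    _["first_passage"] = fp < 0 ? NumericVector::create(NA_REAL)
                                : NumericVector::create((double)fp),
    _["move_counts"] = counts);
}

// [[Rcpp::export]]
NumericMatrix cpp_check_delta(IntegerMatrix coords, IntegerVector types,
                              IntegerVector box, Nullable<IntegerMatrix> heights,
                              int surf_chem, NumericMatrix emat,
                              double temperature, double p_global,
                              int n_proposals, double seed) {
  Sim s = build_sim(coords, types, box, heights, surf_chem, emat, seed);
  NumericMatrix out(n_proposals, 8);
  colnames(out) = CharacterVector::create(
    "inc_total", "full_total", "inc_intra", "full_intra",
    "inc_inter", "full_inter", "inc_surf", "full_surf");
  int got = 0;
  long long guard = 0;
  const long long guard_max = (long long)n_proposals * 10000 + 100000;
  double bi, be, bs; long long bn;
  s.full_energy(bi, be, bs, bn);
  while (got < n_proposals) {
    if (++guard > guard_max)
      stop("could not generate enough geometrically valid proposals");
    const bool global = s.u01() < p_global;
    if (global) s.gen_global(s.prop); else s.gen_local(s.prop);
    if (!s.prop.valid) continue;
    const Delta d = s.delta_energy(s.prop);
    s.apply(s.prop, d);
    double ai, ae, as; long long an;
    s.full_energy(ai, ae, as, an);
    out(got, 0) = d.total();
    out(got, 1) = (ai + ae + as) - (bi + be + bs);
    out(got, 2) = d.ei; out(got, 3) = ai - bi;
    out(got, 4) = d.ee; out(got, 5) = ae - be;
    out(got, 6) = d.es; out(got, 7) = as - bs;
    const double dE = d.total();
    if (dE <= 0.0 || s.u01() < std::exp(-dE / temperature)) {
      bi = ai; be = ae; bs = as; bn = an;     // keep the move
    } else {
      s.revert(s.prop, d);
    }
    ++got;
  }
  return out;
}

// [[Rcpp::export]]
List cpp_sample_proposals(IntegerMatrix coords, IntegerVector types,
                          IntegerVector box, Nullable<IntegerMatrix> heights,
                          int surf_chem, NumericMatrix emat,
                          double temperature, double p_global,
                          int n_proposals, double seed) {
  Sim s = build_sim(coords, types, box, heights, surf_chem, emat, seed);
  List out(n_proposals);
  const char *kinds[5] = {"tail_rotation", "corner_flip", "crankshaft",
                          "rigid_rotation", "rigid_translation"};
  for (int k = 0; k < n_proposals; ++k) {
    const bool global = s.u01() < p_global;
    if (global) s.gen_global(s.prop); else s.gen_local(s.prop);
    const Prop &p = s.prop;
    bool accepted = false;
    IntegerMatrix oldc(p.valid ? p.nb : 0, 3), newc(p.valid ? p.nb : 0, 3);
    IntegerVector beads(p.valid ? p.nb : 0);
    if (p.valid) {
      for (int i = 0; i < p.nb; ++i) {
        beads[i] = p.beads[i] + 1;
        oldc(i, 0) = p.ox[i]; oldc(i, 1) = p.oy[i]; oldc(i, 2) = p.oz[i];
        newc(i, 0) = p.nx[i]; newc(i, 1) = p.ny[i]; newc(i, 2) = p.nz[i];
      }
      const Delta d = s.delta_energy(p);
      const double dE = d.total();
      if (dE <= 0.0 || s.u01() < std::exp(-dE / temperature)) {
        s.apply(p, d);
        accepted = true;
      }
    }
    out[k] = List::create(
      _["kind"] = p.kind >= 0 ? String(kinds[p.kind]) : String(NA_STRING),
      _["chain"] = p.chain + 1, _["beads"] = beads,
      _["old_coords"] = oldc, _["new_coords"] = newc,
      _["valid"] = p.valid, _["accepted"] = accepted);
  }
  return out;
}

// [[Rcpp::export]]
List cpp_delta_energy(IntegerMatrix coords, IntegerVector types,
                      IntegerVector box, Nullable<IntegerMatrix> heights,
                      int surf_chem, NumericMatrix emat,
                      int chain, IntegerVector beads, IntegerMatrix new_coords) {
  Sim s = build_sim(coords, types, box, heights, surf_chem, emat, 1.0);
  if (chain < 1 || chain > s.N) stop("chain index out of range");
  if (beads.size() != new_coords.nrow())
    stop("beads and new_coords disagree in length");
  Prop p;
  p.ensure(s.M);
  p.kind = 0; p.chain = chain - 1; p.nb = beads.size();
  for (int i = 0; i < p.nb; ++i) {
    const int b = beads[i] - 1;
    if (b < 0 || b >= s.M) stop("bead index out of range");
    p.beads[i] = b;
    const int code = p.chain * s.M + b;
    p.ox[i] = s.cx[code]; p.oy[i] = s.cy[code]; p.oz[i] = s.cz[code];
    const int x = new_coords(i, 0), y = new_coords(i, 1), z = new_coords(i, 2);
    if (x < 0 || x >= s.Lx || y < 0 || y >= s.Ly || z < 0 || z >= s.Lz)
      stop("proposed coordinate outside the box");
    if (s.slab && (z < s.zmin || z > s.zmax))
      stop("proposed coordinate inside the surface layer");
    p.nx[i] = x; p.ny[i] = y; p.nz[i] = z;
  }
  p.valid = true;
  const Delta d = s.delta_energy(p);
  return List::create(_["e_intra"] = d.ei, _["e_inter"] = d.ee,
                      _["e_surf"] = d.es, _["e_total"] = d.total(),
                      _["n_inter"] = (double)d.ni);
}

// [[Rcpp::export]]
IntegerMatrix cpp_place_chains(int n_chains, IntegerVector types,
                               IntegerVector box,
                               Nullable<IntegerMatrix> heights, int surf_chem,
                               double seed, int max_retries) {
  IntegerMatrix empty(0, 3);
  NumericMatrix emat(6, 6);
  Sim s = build_sim(empty, types, box, heights, surf_chem, emat, seed);
  const int M = s.M;
  s.N = n_chains;
  s.cx.assign((size_t)n_chains * M, 0);
  s.cy.assign((size_t)n_chains * M, 0);
  s.cz.assign((size_t)n_chains * M, 0);
  std::vector<int> gx(M), gy(M), gz(M);
  for (int c = 0; c < n_chains; ++c) {
    int tries = 0;
    bool placed = false;
    while (!placed) {
      if (++tries > max_retries)
        stop("chain placement failed after %d retries; use a larger box",
             max_retries);
      gx[0] = (int)s.ru(s.Lx);
      gy[0] = (int)s.ru(s.Ly);
      gz[0] = s.zmin + (int)s.ru(s.zmax - s.zmin + 1);
      if (s.occ[s.idx(gx[0], gy[0], gz[0])] != Sim::EMPTY) continue;
      s.occ[s.idx(gx[0], gy[0], gz[0])] = 0;  // temporary marker
      int grown = 1;
      while (grown < M) {
        int cand[6]; int nc = 0;
        for (int d = 0; d < 6; ++d) {
          int ax, ay, az;
          if (!s.nbr(gx[grown - 1], gy[grown - 1], gz[grown - 1], d,
                     ax, ay, az)) continue;
          if (s.slab && (az < s.zmin || az > s.zmax)) continue;
          if (s.occ[s.idx(ax, ay, az)] != Sim::EMPTY) continue;
          cand[nc++] = d;
        }
        if (nc == 0) break;                    // dead end
        const int d = cand[(int)s.ru(nc)];
        int ax, ay, az;
        s.nbr(gx[grown - 1], gy[grown - 1], gz[grown - 1], d, ax, ay, az);
        gx[grown] = ax; gy[grown] = ay; gz[grown] = az;
        s.occ[s.idx(ax, ay, az)] = 0;
        ++grown;
      }
      if (grown == M) {
        for (int i = 0; i < M; ++i) {
          const int code = c * M + i;
          s.cx[code] = gx[i]; s.cy[code] = gy[i]; s.cz[code] = gz[i];
          s.occ[s.idx(gx[i], gy[i], gz[i])] = code;
        }
        placed = true;
      } else {
        for (int i = 0; i < grown; ++i)
          s.occ[s.idx(gx[i], gy[i], gz[i])] = Sim::EMPTY;
      }
    }
  }
  return coords_out(s);
}

// [[Rcpp::export]]
List cpp_anneal(IntegerMatrix coords, IntegerVector types,
                IntegerVector box, Nullable<IntegerMatrix> heights,
                int surf_chem, NumericMatrix emat,
                double t_hi, double t_lo, int n_stages,
                double mcs_per_stage, double p_global, bool sweep_mode,
                double seed) {
  Sim s = build_sim(coords, types, box, heights, surf_chem, emat, seed);
  if (t_hi <= 0 || t_lo <= 0 || t_lo > t_hi)
    stop("annealing schedule needs 0 < t_lo <= t_hi");
  double bestE = s.E_intra + s.E_inter + s.E_surf;
  std::vector<int> bx(s.cx), by(s.cy), bz(s.cz);
  const long long steps = (long long)mcs_per_stage;
  const int per_mcs = sweep_mode ? s.N * s.M : 1;
  for (int st = 0; st < n_stages; ++st) {
    const double f = n_stages == 1 ? 0.0 : (double)st / (n_stages - 1);
    const double T = t_hi * std::pow(t_lo / t_hi, f);
    for (long long m = 0; m < steps; ++m) {
      for (int a = 0; a < per_mcs; ++a) {
        if (s.attempt(p_global, T)) {
          const double E = s.E_intra + s.E_inter + s.E_surf;
          if (E < bestE - 1e-9) {
            bestE = E;
            bx = s.cx; by = s.cy; bz = s.cz;
          }
        }
      }
      if (m % 1048576 == 0) Rcpp::checkUserInterrupt();
    }
  }
  IntegerMatrix out(s.N * s.M, 3);
  for (int k = 0; k < s.N * s.M; ++k) {
    out(k, 0) = bx[k]; out(k, 1) = by[k]; out(k, 2) = bz[k];
  }
  // recompute the breakdown of the best state from scratch
  Sim sb = build_sim(out, types, box, heights, surf_chem, emat, 1.0);
  return List::create(
    _["coords"] = out, _["e_intra"] = sb.E_intra, _["e_inter"] = sb.E_inter,
    _["e_surf"] = sb.E_surf,
    _["e_total"] = sb.E_intra + sb.E_inter + sb.E_surf,
    _["n_inter"] = (double)sb.n_inter);
}

// Exhaustive enumeration of all self-avoiding conformations of one chain
// in open space (no periodic images), used as a ground-state oracle.  For
// a smooth surface the adsorbed energy of a conformation places its
// lowest layer at z = 1, where each bead contacts the plane bead below.
// [[Rcpp::export]]
List cpp_enumerate_ground(IntegerVector types, NumericMatrix emat,
                          int surf_chem) {
  const int M = types.size();
  if (M < 2 || M > 14) stop("enumeration supports 2 <= M <= 14");
  check_emat(emat);
  std::vector<int> tp(types.begin(), types.end());
  const int side = 2 * M + 1;
  std::vector<char> grid((size_t)side * side * side, 0);
  auto gidx = [&](int x, int y, int z) {
    return ((size_t)(z + M) * side + (y + M)) * side + (x + M);
  };
  std::vector<int> px(M), py(M), pz(M), dir(M, 0);
  px[0] = py[0] = pz[0] = 0;
  grid[gidx(0, 0, 0)] = 1;
  double best_bulk = R_PosInf, best_ads = R_PosInf;
  std::vector<int> bb(3 * M), ba(3 * M);
  long long count = 0;
  const bool surf = surf_chem >= 0;

  int depth = 1;
  dir[1] = 0;
  while (depth >= 1) {
    if (dir[depth] == 6) {
      // backtrack
      grid[gidx(px[depth - 1], py[depth - 1], pz[depth - 1])] = 1;
      --depth;
      if (depth >= 1) {
        grid[gidx(px[depth], py[depth], pz[depth])] = 0;
        ++dir[depth];
      }
      continue;
    }
    const int d = dir[depth];
    const int x = px[depth - 1] + DX[d];
    const int y = py[depth - 1] + DY[d];
    const int z = pz[depth - 1] + DZ[d];
    if (grid[gidx(x, y, z)]) { ++dir[depth]; continue; }
    px[depth] = x; py[depth] = y; pz[depth] = z;
    if (depth == M - 1) {
      ++count;
      double ei = 0.0;
      int minz = 0;
      for (int i = 0; i < M; ++i) {
        if (pz[i] < minz) minz = pz[i];
        for (int j = i + 2; j < M; ++j) {
          const int dd = std::abs(px[i] - px[j]) + std::abs(py[i] - py[j]) +
                         std::abs(pz[i] - pz[j]);
          if (dd == 1) ei += emat(tp[i], tp[j]);
        }
      }
      if (ei < best_bulk) {
        best_bulk = ei;
        for (int i = 0; i < M; ++i) {
          bb[3 * i] = px[i]; bb[3 * i + 1] = py[i]; bb[3 * i + 2] = pz[i];
        }
      }
      if (surf) {
        double ea = ei;
        for (int i = 0; i < M; ++i)
          if (pz[i] == minz) ea += emat(tp[i], surf_chem);
        if (ea < best_ads) {
          best_ads = ea;
          for (int i = 0; i < M; ++i) {
            ba[3 * i] = px[i]; ba[3 * i + 1] = py[i];
            ba[3 * i + 2] = pz[i] - minz + 1;  // lowest layer on z = 1
          }
        }
      }
      ++dir[depth];
    } else {
      grid[gidx(x, y, z)] = 1;
      ++depth;
      dir[depth] = 0;
    }
  }

  auto mat = [&](const std::vector<int> &v) {
    IntegerMatrix m(M, 3);
    int mnx = v[0], mny = v[1];
    for (int i = 0; i < M; ++i) {
      mnx = std::min(mnx, v[3 * i]); mny = std::min(mny, v[3 * i + 1]);
    }
    int mnz = v[2];
    for (int i = 0; i < M; ++i) mnz = std::min(mnz, v[3 * i + 2]);
    for (int i = 0; i < M; ++i) {
      m(i, 0) = v[3 * i] - mnx;
      m(i, 1) = v[3 * i + 1] - mny;
      m(i, 2) = surf ? v[3 * i + 2] : v[3 * i + 2] - mnz;
    }
    return m;
  };
  List out = List::create(
    _["e_min_bulk"] = best_bulk, _["coords_bulk"] = mat(bb),
    _["n_walks"] = (double)count,
    _["e_min_adsorbed"] = surf ? best_ads : NA_REAL,
    _["coords_adsorbed"] = surf ? (SEXP)mat(ba) : R_NilValue);
  return out;
}
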