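// Coarse-grained MD engine: shifted LJ/Coulomb pair terms, harmonic bonds,
// cosine-squared and harmonic angles, Fourier dihedrals; Verlet/cell neighbor
// search under orthorhombic PBC; BAOAB Langevin integration with an optional
// z-direction piston barostat; steepest-descent minimizer; RDF/MSD kernels.
//
// Units follow the "real" convention: length Angstrom, time fs, energy
// kcal/mol, mass amu, charge e, temperature K, pressure bar.
#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>
#include <algorithm>
using namespace Rcpp;

static const double KB      = 0.0019872041;   // kcal/mol/K
static const double FTM2V   = 4.184e-4;       // (kcal/mol/A)/amu -> A/fs^2
static const double MVV2E   = 1.0 / FTM2V;    // amu (A/fs)^2 -> kcal/mol
static const double NKTV2P  = 68568.415;      // kcal/mol/A^3 -> bar
static const double QQR2E   = 332.06371;      // e^2/A -> kcal/mol

// ---------------------------------------------------------------- RNG (pcg32)
struct Pcg32 {
  uint64_t state, inc;
  Pcg32(uint64_t seed, uint64_t seq = 54u) {
    state = 0u; inc = (seq << 1u) | 1u;
    next(); state += seed; next();
    zig_init();
  }
  uint32_t next() {
    uint64_t old = state;
    state = old * 6364136223846793005ULL + inc;
    uint32_t xorshifted = (uint32_t)(((old >> 18u) ^ old) >> 27u);
    uint32_t rot = (uint32_t)(old >> 59u);
    return (xorshifted >> rot) | (xorshifted << ((-rot) & 31));
  }
  double unif() { // (0,1)
    return (next() + 0.5) * (1.0 / 4294967296.0);
  }
  // Marsaglia-Tsang ziggurat for the normal distribution
  static uint32_t zkn[128];
  static double zwn[128], zfn[128];
  static bool ztab_ready;
  static void zig_init() {
    if (ztab_ready) return;
    const double m1 = 2147483648.0;
    double dn = 3.442619855899, tn = dn, vn = 9.91256303526217e-3;
    double q = vn / std::exp(-0.5 * dn * dn);
    zkn[0] = (uint32_t)((dn / q) * m1);
    zkn[1] = 0;
    zwn[0] = q / m1;
    zwn[127] = dn / m1;
    zfn[0] = 1.0;
    zfn[127] = std::exp(-0.5 * dn * dn);
    for (int i = 126; i >= 1; i--) {
      dn = std::sqrt(-2.0 * std::log(vn / dn + std::exp(-0.5 * dn * dn)));
      zkn[i + 1] = (uint32_t)((dn / tn) * m1);
      tn = dn;
      zfn[i] = std::exp(-0.5 * dn * dn);
      zwn[i] = dn / m1;
    }
    ztab_ready = true;
  }
  double gauss() {
    const double r = 3.442619855899;
    for (;;) {
      int32_t hz = (int32_t)next();
      uint32_t iz = hz & 127;
      if ((uint32_t)std::abs(hz) < zkn[iz]) return hz * zwn[iz];
      if (iz == 0) { // base strip: tail sampling
        double x, y;
        do {
          x = -std::log(unif()) / r;
          y = -std::log(unif());
        } while (y + y < x * x);
        return hz > 0 ? r + x : -r - x;
      }
      double x = hz * zwn[iz];
      if (zfn[iz] + unif() * (zfn[iz - 1] - zfn[iz]) <
          std::exp(-0.5 * x * x))
        return x;
    }
  }
};
uint32_t Pcg32::zkn[128];
double Pcg32::zwn[128], Pcg32::zfn[128];
bool Pcg32::ztab_ready = false;

// ------------------------------------------------------- shift function coefs
// GROMACS-style force-shift for an r^-p term between r1 and rc:
//   F(r) = p/r^(p+1) + A (r-r1)^2 + B (r-r1)^3   (r1 <= r <= rc)
// with F(rc) = F'(rc) = 0; the potential is the integral, offset so V(rc)=0.
struct ShiftP {
  double p, r1, rc, A, B, C;
  void init(double p_, double r1_, double rc_) {
    p = p_; r1 = r1_; rc = rc_;
    double d = rc - r1;
    A = -p * ((p + 4.0) * rc - (p + 1.0) * r1) / (std::pow(rc, p + 2.0) * d * d);
    B =  p * ((p + 3.0) * rc - (p + 1.0) * r1) / (std::pow(rc, p + 2.0) * d * d * d);
    C = std::pow(rc, -p) - A / 3.0 * d * d * d - B / 4.0 * d * d * d * d;
  }
  // value of the shifted r^-p "potential kernel" and its force kernel p/r^{p+1}+...
  inline void eval(double r, double &phi, double &f) const {
    double rp = std::pow(r, -p);
    if (r < r1) {
      phi = rp - C;
      f = p * rp / r;
    } else {
      double dr = r - r1;
      phi = rp - A / 3.0 * dr * dr * dr - B / 4.0 * dr * dr * dr * dr - C;
      f = p * rp / r + A * dr * dr + B * dr * dr * dr;
    }
  }
};

// --------------------------------------------------------------- force field
struct PairFF {
  int ntypes;
  std::vector<double> sigma, eps;   // ntypes*ntypes
  std::vector<double> c12, c6, sig6, eps4, wca_cut2, cutsq;
  std::vector<int> style;           // 0 = shifted LJ, 1 = WCA, 2 = none
  double cutoff, r1, eps_r, coul_cut;
  ShiftP s12, s6, s1;
  void init(NumericMatrix sig, NumericMatrix ep, IntegerMatrix sty,
            double cut, double ron, double epsr, double ccut) {
    ntypes = sig.nrow();
    sigma.assign(sig.begin(), sig.end());
    eps.assign(ep.begin(), ep.end());
    style.assign(sty.begin(), sty.end());
    cutoff = cut; r1 = ron; eps_r = epsr; coul_cut = ccut;
    s12.init(12.0, ron, cut);
    s6.init(6.0, ron, cut);
    s1.init(1.0, 0.0, ccut);
    size_t m = sigma.size();
    c12.resize(m); c6.resize(m); sig6.resize(m); eps4.resize(m);
    wca_cut2.resize(m); cutsq.resize(m);
    for (size_t k = 0; k < m; ++k) {
      double s6v = std::pow(sigma[k], 6.0);
      sig6[k] = s6v;
      c6[k] = 4.0 * eps[k] * s6v;
      c12[k] = 4.0 * eps[k] * s6v * s6v;
      eps4[k] = 4.0 * eps[k];
      wca_cut2[k] = sigma[k] * sigma[k] * std::pow(2.0, 1.0 / 3.0);
      cutsq[k] = (style[k] == 1) ? wca_cut2[k] : cutoff * cutoff;
    }
  }
  inline int idx(int ti, int tj) const { return ti * ntypes + tj; }
  // energy and force-over-distance (fmag/r, >0 repulsive) for one pair;
  // r2 = r*r (must be below cutoff^2). One division + one sqrt per call.
  inline void pair_ef(int ti, int tj, double qq, double r2, double &e_lj,
                      double &e_coul, double &f_over_r) const {
    e_lj = 0.0; e_coul = 0.0; f_over_r = 0.0;
    int k = idx(ti, tj);
    int st = style[k];
    double rinv2 = 1.0 / r2;
    double rinv = std::sqrt(rinv2);
    double r = r2 * rinv;
    double rinv6 = rinv2 * rinv2 * rinv2;
    double rinv12 = rinv6 * rinv6;
    if (st == 0) {
      if (r >= cutoff) { e_lj = 0; }
      else {
      double p12, f12, p6, f6;
      if (r < r1) {
        p12 = rinv12 - s12.C; f12 = 12.0 * rinv12 * rinv;
        p6 = rinv6 - s6.C;    f6 = 6.0 * rinv6 * rinv;
      } else {
        double dr = r - r1, dr2 = dr * dr, dr3 = dr2 * dr, dr4 = dr3 * dr;
        p12 = rinv12 - s12.A / 3.0 * dr3 - s12.B / 4.0 * dr4 - s12.C;
        f12 = 12.0 * rinv12 * rinv + s12.A * dr2 + s12.B * dr3;
        p6 = rinv6 - s6.A / 3.0 * dr3 - s6.B / 4.0 * dr4 - s6.C;
        f6 = 6.0 * rinv6 * rinv + s6.A * dr2 + s6.B * dr3;
      }
      e_lj = c12[k] * p12 - c6[k] * p6;
      f_over_r = (c12[k] * f12 - c6[k] * f6) * rinv;
      }
    } else if (st == 1) {
      if (r2 < wca_cut2[k]) {
        double sr6 = sig6[k] * rinv6, sr12 = sr6 * sr6;
        e_lj = eps4[k] * (sr12 - sr6) + eps[k];
        f_over_r = 6.0 * eps4[k] * (2.0 * sr12 - sr6) * rinv2;
      }
    }
    if (qq != 0.0 && r < coul_cut) {
      double p1 = rinv - s1.A / 3.0 * r2 * r - s1.B / 4.0 * r2 * r2 - s1.C;
      double f1 = rinv2 + s1.A * r2 + s1.B * r2 * r;
      double pref = QQR2E * qq / eps_r;
      e_coul = pref * p1;
      f_over_r += pref * f1 * rinv;
    }
  }

  // ---- tabulated fast path (dynamics): linear interpolation in r^2 ----
  // tables start at r2 = TAB_R2MIN; deeper overlaps fall back to the
  // analytic kernel (only reachable in unrelaxed configurations)
  static const int NTAB = 1024;
  static constexpr double TAB_R2MIN = 1.0;
  std::vector<std::vector<double>> tabs; // per unique pair: interleaved e,f
  std::vector<int> tab_of;               // k -> table index
  std::vector<double> tab_invd;          // k -> 1/dr2
  std::vector<double> ctab;              // coulomb per unit prefactor
  double ctab_invd = 0.0;
  bool use_tab = false;

  void build_tables() {
    tab_of.assign(ntypes * ntypes, -1);
    tab_invd.assign(ntypes * ntypes, 0.0);
    tabs.clear();
    for (int a = 0; a < ntypes; ++a)
      for (int b = a; b < ntypes; ++b) {
        int k = a * ntypes + b, k2 = b * ntypes + a;
        double hi = cutsq[k];
        double d = (hi - TAB_R2MIN) / (NTAB - 1);
        std::vector<double> t(2 * NTAB);
        for (int i = 0; i < NTAB; ++i) {
          double r2 = TAB_R2MIN + i * d;
          double e, ec, fr;
          pair_ef(a, b, 0.0, r2, e, ec, fr);
          t[2 * i] = e;
          t[2 * i + 1] = fr;
        }
        tabs.push_back(std::move(t));
        tab_of[k] = tab_of[k2] = (int)tabs.size() - 1;
        tab_invd[k] = tab_invd[k2] = 1.0 / d;
      }
    double hi = coul_cut * coul_cut;
    double d = (hi - TAB_R2MIN) / (NTAB - 1);
    ctab.assign(2 * NTAB, 0.0);
    for (int i = 0; i < NTAB; ++i) {
      double r2 = TAB_R2MIN + i * d;
      double rinv2 = 1.0 / r2, rinv = std::sqrt(rinv2), r = r2 * rinv;
      ctab[2 * i] = rinv - s1.A / 3.0 * r2 * r - s1.B / 4.0 * r2 * r2 - s1.C;
      ctab[2 * i + 1] = (rinv2 + s1.A * r2 + s1.B * r2 * r) * rinv;
    }
    ctab_invd = 1.0 / d;
  }

  inline void pair_ef_tab(int ti, int tj, double qq, double r2, double &e_lj,
                          double &e_coul, double &f_over_r) const {
    int k = ti * ntypes + tj;
    if (r2 < TAB_R2MIN) { pair_ef(ti, tj, qq, r2, e_lj, e_coul, f_over_r); return; }
    const double *t = tabs[tab_of[k]].data();
    double u = (r2 - TAB_R2MIN) * tab_invd[k];
    int i = (int)u;
    double w = u - i;
    e_lj = t[2 * i] + w * (t[2 * i + 2] - t[2 * i]);
    f_over_r = t[2 * i + 1] + w * (t[2 * i + 3] - t[2 * i + 1]);
    if (qq != 0.0) {
      double uc = (r2 - TAB_R2MIN) * ctab_invd;
      int ic = (int)uc;
      double wc = uc - ic;
      double pref = QQR2E * qq / eps_r;
      e_coul = pref * (ctab[2 * ic] + wc * (ctab[2 * ic + 2] - ctab[2 * ic]));
      f_over_r += pref * (ctab[2 * ic + 1] + wc * (ctab[2 * ic + 3] - ctab[2 * ic + 1]));
    } else e_coul = 0.0;
  }
};

struct Topology {
  int n;
  std::vector<int> type;        // 0-based
  std::vector<double> q, mass;
  std::vector<int> bond_i, bond_j;
  std::vector<double> bond_k, bond_r0;
  std::vector<int> ang_i, ang_j, ang_k, ang_t; // t: 0 cos-sq, 1 harmonic
  std::vector<double> ang_K, ang_th0;          // th0 radians
  std::vector<int> dih_i, dih_j, dih_k, dih_l;
  std::vector<double> dK, dn, dphi0;           // Fourier terms (shared table,
                                               // multiplicities ascending)
  std::vector<double> dcos0, dsin0;            // cos/sin of phi0
  // exclusions, CSR sorted
  std::vector<int> excl_start, excl_list;
  bool excluded(int i, int j) const {
    for (int k = excl_start[i]; k < excl_start[i + 1]; ++k)
      if (excl_list[k] == j) return true;
    return false;
  }
};

struct EnergyTerms {
  double lj = 0, coul = 0, bond = 0, angle = 0, dih = 0;
  double total() const { return lj + coul + bond + angle + dih; }
};

static inline double mimg(double d, double L) {
  if (d > 0.5 * L) d -= L * std::floor(d / L + 0.5);
  else if (d < -0.5 * L) d -= L * std::floor(d / L + 0.5);
  return d;
}

// ------------------------------------------------------------- neighbor list
// Verlet list built from a cell decomposition with per-type-pair list radii
// (WCA pairs carry short cutoffs). Lateral (x, y) coordinates are pre-wrapped
// at build time so the force loop needs only branch corrections; z uses the
// robust floor form because the barostat may rescale the box between builds.
struct NeighborList {
  // beads are spatially re-ordered (cell sort) at every build; the pair list,
  // scratch coordinates and forces live in the sorted index space
  std::vector<int> start, nbr;     // CSR half list, sorted indices
  std::vector<int> perm;           // sorted index -> original index
  std::vector<int> tsort;          // per-sorted-bead type
  std::vector<double> qsort;       // per-sorted-bead charge
  std::vector<double> x0;          // original-space positions at build
  std::vector<double> ssort;       // per-sorted-bead x/y wrap shifts (2 each)
  std::vector<double> xs, fs;      // sorted-space scratch coords / forces
  std::vector<int> pi_, pj_;       // scratch pair arrays
  std::vector<double> rl2;         // per-type-pair list radius^2
  int ntypes = 0;
  double skin = 2.0;
  double max_rlist = 0.0;
  bool built = false;

  void set_radii(const PairFF &ff) {
    ntypes = ff.ntypes;
    rl2.assign(ntypes * ntypes, 0.0);
    max_rlist = 0.0;
    for (int k = 0; k < ntypes * ntypes; ++k) {
      double cut = (ff.style[k] == 1) ? std::sqrt(ff.wca_cut2[k]) : ff.cutoff;
      double rl = cut + skin;
      rl2[k] = rl * rl;
      max_rlist = std::max(max_rlist, rl);
    }
  }

  void build_cell(const std::vector<double> &x, const double *box,
                  const Topology &top, const PairFF &ff) {
    if (ntypes == 0) set_radii(ff);
    int n = top.n;
    x0 = x;
    int ncx = std::max(1, (int)(box[0] / max_rlist));
    int ncy = std::max(1, (int)(box[1] / max_rlist));
    int ncz = std::max(1, (int)(box[2] / max_rlist));
    bool small = (ncx < 3 || ncy < 3 || ncz < 3);
    if (small) { ncx = ncy = ncz = 1; }
    int ncells = ncx * ncy * ncz;
    // cell of each bead (wrapped coordinates)
    std::vector<int> cellof(n), cnt(ncells + 1, 0);
    std::vector<double> wx(3 * n), shifts(2 * n);
    for (int i = 0; i < n; ++i) {
      double sx = box[0] * std::floor(x[3 * i] / box[0]);
      double sy = box[1] * std::floor(x[3 * i + 1] / box[1]);
      double sz = box[2] * std::floor(x[3 * i + 2] / box[2]);
      shifts[2 * i] = sx; shifts[2 * i + 1] = sy;
      wx[3 * i] = x[3 * i] - sx;
      wx[3 * i + 1] = x[3 * i + 1] - sy;
      wx[3 * i + 2] = x[3 * i + 2] - sz;
      int cx = std::min(ncx - 1, std::max(0, (int)(wx[3 * i] / box[0] * ncx)));
      int cy = std::min(ncy - 1, std::max(0, (int)(wx[3 * i + 1] / box[1] * ncy)));
      int cz = std::min(ncz - 1, std::max(0, (int)(wx[3 * i + 2] / box[2] * ncz)));
      cellof[i] = (cz * ncy + cy) * ncx + cx;
      ++cnt[cellof[i] + 1];
    }
    // counting sort by cell
    for (int c = 0; c < ncells; ++c) cnt[c + 1] += cnt[c];
    perm.resize(n); tsort.resize(n); qsort.resize(n);
    ssort.resize(2 * n); xs.resize(3 * n); fs.resize(3 * n);
    std::vector<int> cstart(cnt.begin(), cnt.end()); // cell -> first sorted idx
    {
      std::vector<int> fill(cnt.begin(), cnt.end() - 1);
      for (int i = 0; i < n; ++i) perm[fill[cellof[i]]++] = i;
    }
    std::vector<int> inv(n);
    for (int i = 0; i < n; ++i) {
      int o = perm[i];
      inv[o] = i;
      tsort[i] = top.type[o];
      qsort[i] = top.q[o];
      ssort[2 * i] = shifts[2 * o];
      ssort[2 * i + 1] = shifts[2 * o + 1];
      xs[3 * i] = wx[3 * o];
      xs[3 * i + 1] = wx[3 * o + 1];
      xs[3 * i + 2] = x[3 * o + 2]; // z stays raw (barostat-safe min image)
    }
    pi_.clear(); pj_.clear();
    if (small) {
      for (int i = 0; i < n; ++i)
        for (int j = i + 1; j < n; ++j) try_pair(i, j, box, top);
    } else {
      const int off[13][3] = {
          {1, 0, 0}, {0, 1, 0}, {0, 0, 1}, {1, 1, 0}, {1, -1, 0},
          {1, 0, 1}, {1, 0, -1}, {0, 1, 1}, {0, 1, -1}, {1, 1, 1},
          {1, 1, -1}, {1, -1, 1}, {1, -1, -1}};
      auto wrapc = [](int c, int nc) { return c < 0 ? c + nc : (c >= nc ? c - nc : c); };
      for (int cz = 0; cz < ncz; ++cz)
        for (int cy = 0; cy < ncy; ++cy)
          for (int cx = 0; cx < ncx; ++cx) {
            int c = (cz * ncy + cy) * ncx + cx;
            for (int i = cstart[c]; i < cstart[c + 1]; ++i) {
              for (int j = i + 1; j < cstart[c + 1]; ++j)
                try_pair(i, j, box, top);
              for (int s = 0; s < 13; ++s) {
                int oc = (wrapc(cz + off[s][2], ncz) * ncy +
                          wrapc(cy + off[s][1], ncy)) * ncx +
                         wrapc(cx + off[s][0], ncx);
                for (int j = cstart[oc]; j < cstart[oc + 1]; ++j)
                  try_pair(i, j, box, top);
              }
            }
          }
    }
    // CSR by sorted i
    int np = (int)pi_.size();
    start.assign(n + 1, 0);
    for (int p = 0; p < np; ++p) ++start[pi_[p] + 1];
    for (int i = 0; i < n; ++i) start[i + 1] += start[i];
    nbr.resize(np);
    std::vector<int> fill(start.begin(), start.end() - 1);
    for (int p = 0; p < np; ++p) nbr[fill[pi_[p]]++] = pj_[p];
    built = true;
  }

  inline void try_pair(int i, int j, const double *box, const Topology &top) {
    double dx = xs[3 * i] - xs[3 * j];
    if (dx > 0.5 * box[0]) dx -= box[0];
    else if (dx < -0.5 * box[0]) dx += box[0];
    double dy = xs[3 * i + 1] - xs[3 * j + 1];
    if (dy > 0.5 * box[1]) dy -= box[1];
    else if (dy < -0.5 * box[1]) dy += box[1];
    double dz = mimg(xs[3 * i + 2] - xs[3 * j + 2], box[2]);
    double r2 = dx * dx + dy * dy + dz * dz;
    if (r2 < rl2[tsort[i] * ntypes + tsort[j]] &&
        !top.excluded(perm[i], perm[j])) {
      pi_.push_back(i); pj_.push_back(j);
    }
  }

  bool needs_rebuild(const std::vector<double> &x) const {
    if (!built) return true;
    double lim = 0.25 * skin * skin;
    for (size_t i = 0; i < x.size(); i += 3) {
      double dx = x[i] - x0[i], dy = x[i + 1] - x0[i + 1], dz = x[i + 2] - x0[i + 2];
      if (dx * dx + dy * dy + dz * dz > lim) return true;
    }
    return false;
  }
};

// ------------------------------------------------------------- force routines
static void bonded_forces(const std::vector<double> &x, const double *box,
                          const Topology &top, std::vector<double> &f,
                          EnergyTerms &E, double &virial_zz) {
  int nb = (int)top.bond_i.size();
  for (int b = 0; b < nb; ++b) {
    int i = top.bond_i[b], j = top.bond_j[b];
    double dx = mimg(x[3 * i] - x[3 * j], box[0]);
    double dy = mimg(x[3 * i + 1] - x[3 * j + 1], box[1]);
    double dz = mimg(x[3 * i + 2] - x[3 * j + 2], box[2]);
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    double dr = r - top.bond_r0[b];
    E.bond += top.bond_k[b] * dr * dr;
    double fmag = -2.0 * top.bond_k[b] * dr; // >0 repulsive when compressed
    double fr = fmag / r;
    f[3 * i] += fr * dx; f[3 * i + 1] += fr * dy; f[3 * i + 2] += fr * dz;
    f[3 * j] -= fr * dx; f[3 * j + 1] -= fr * dy; f[3 * j + 2] -= fr * dz;
    virial_zz += fr * dz * dz;
  }
  int na = (int)top.ang_i.size();
  for (int a = 0; a < na; ++a) {
    int i = top.ang_i[a], j = top.ang_j[a], k = top.ang_k[a];
    double ax = mimg(x[3 * i] - x[3 * j], box[0]);
    double ay = mimg(x[3 * i + 1] - x[3 * j + 1], box[1]);
    double az = mimg(x[3 * i + 2] - x[3 * j + 2], box[2]);
    double bx = mimg(x[3 * k] - x[3 * j], box[0]);
    double by = mimg(x[3 * k + 1] - x[3 * j + 1], box[1]);
    double bz = mimg(x[3 * k + 2] - x[3 * j + 2], box[2]);
    double la = std::sqrt(ax * ax + ay * ay + az * az);
    double lb = std::sqrt(bx * bx + by * by + bz * bz);
    double cs = (ax * bx + ay * by + az * bz) / (la * lb);
    cs = std::max(-1.0, std::min(1.0, cs));
    double dVdcos;
    if (top.ang_t[a] == 0) { // cosine-squared
      double c0 = std::cos(top.ang_th0[a]);
      E.angle += top.ang_K[a] * (cs - c0) * (cs - c0);
      dVdcos = 2.0 * top.ang_K[a] * (cs - c0);
    } else {                 // harmonic in theta (radians)
      double th = std::acos(cs);
      double dth = th - top.ang_th0[a];
      E.angle += top.ang_K[a] * dth * dth;
      double sn = std::sqrt(std::max(1.0 - cs * cs, 1e-12));
      dVdcos = 2.0 * top.ang_K[a] * dth * (-1.0 / sn);
    }
    // grad of cos wrt r_i and r_k
    double gix = (bx / (la * lb)) - cs * ax / (la * la);
    double giy = (by / (la * lb)) - cs * ay / (la * la);
    double giz = (bz / (la * lb)) - cs * az / (la * la);
    double gkx = (ax / (la * lb)) - cs * bx / (lb * lb);
    double gky = (ay / (la * lb)) - cs * by / (lb * lb);
    double gkz = (az / (la * lb)) - cs * bz / (lb * lb);
    double fix = -dVdcos * gix, fiy = -dVdcos * giy, fiz = -dVdcos * giz;
    double fkx = -dVdcos * gkx, fky = -dVdcos * gky, fkz = -dVdcos * gkz;
    f[3 * i] += fix; f[3 * i + 1] += fiy; f[3 * i + 2] += fiz;
    f[3 * k] += fkx; f[3 * k + 1] += fky; f[3 * k + 2] += fkz;
    f[3 * j] -= fix + fkx; f[3 * j + 1] -= fiy + fky; f[3 * j + 2] -= fiz + fkz;
    virial_zz += fiz * az + fkz * bz;
  }
  int nd = (int)top.dih_i.size();
  int nterm = (int)top.dK.size();
  for (int d = 0; d < nd; ++d) {
    int i1 = top.dih_i[d], i2 = top.dih_j[d], i3 = top.dih_k[d], i4 = top.dih_l[d];
    double b1x = mimg(x[3 * i2] - x[3 * i1], box[0]);
    double b1y = mimg(x[3 * i2 + 1] - x[3 * i1 + 1], box[1]);
    double b1z = mimg(x[3 * i2 + 2] - x[3 * i1 + 2], box[2]);
    double b2x = mimg(x[3 * i3] - x[3 * i2], box[0]);
    double b2y = mimg(x[3 * i3 + 1] - x[3 * i2 + 1], box[1]);
    double b2z = mimg(x[3 * i3 + 2] - x[3 * i2 + 2], box[2]);
    double b3x = mimg(x[3 * i4] - x[3 * i3], box[0]);
    double b3y = mimg(x[3 * i4 + 1] - x[3 * i3 + 1], box[1]);
    double b3z = mimg(x[3 * i4 + 2] - x[3 * i3 + 2], box[2]);
    // normals
    double mx = b1y * b2z - b1z * b2y;
    double my = b1z * b2x - b1x * b2z;
    double mz = b1x * b2y - b1y * b2x;
    double nx = b2y * b3z - b2z * b3y;
    double ny = b2z * b3x - b2x * b3z;
    double nz = b2x * b3y - b2y * b3x;
    double m2 = mx * mx + my * my + mz * mz;
    double n2 = nx * nx + ny * ny + nz * nz;
    double lb2 = std::sqrt(b2x * b2x + b2y * b2y + b2z * b2z);
    if (m2 < 1e-12 || n2 < 1e-12) continue;
    double mdotn = mx * nx + my * ny + mz * nz;
    double cxx = my * nz - mz * ny, cyy = mz * nx - mx * nz, czz = mx * ny - my * nx;
    double sinphi_num = (cxx * b2x + cyy * b2y + czz * b2z) / lb2;
    // cos/sin of phi from the geometry; multiples by angle-addition
    // recursion (no trig calls): cos(n phi - phi0) expanded with the
    // precomputed cos/sin of phi0
    double inv_mn = 1.0 / std::sqrt(m2 * n2);
    double cphi = mdotn * inv_mn;
    double sphi = sinphi_num * inv_mn;
    double dV = 0.0;
    double cn = cphi, sn_ = sphi; // cos/sin of k*phi, k starting at 1
    int kmul = 1;
    for (int t = 0; t < nterm; ++t) {
      int nmul = (int)top.dn[t];
      while (kmul < nmul) {
        double c2 = cn * cphi - sn_ * sphi;
        sn_ = sn_ * cphi + cn * sphi;
        cn = c2;
        ++kmul;
      }
      double c0 = top.dcos0[t], s0 = top.dsin0[t];
      E.dih += top.dK[t] * (1.0 + cn * c0 + sn_ * s0);
      dV += -top.dK[t] * nmul * (sn_ * c0 - cn * s0);
    }
    // forces (Gromacs-style)
    double f1x = dV * lb2 / m2 * mx;
    double f1y = dV * lb2 / m2 * my;
    double f1z = dV * lb2 / m2 * mz;
    double f4x = -dV * lb2 / n2 * nx;
    double f4y = -dV * lb2 / n2 * ny;
    double f4z = -dV * lb2 / n2 * nz;
    double p = (b1x * b2x + b1y * b2y + b1z * b2z) / (lb2 * lb2);
    double q = (b3x * b2x + b3y * b2y + b3z * b2z) / (lb2 * lb2);
    double svx = -p * f1x + q * f4x;
    double svy = -p * f1y + q * f4y;
    double svz = -p * f1z + q * f4z;
    double f2x = -f1x + svx, f2y = -f1y + svy, f2z = -f1z + svz;
    double f3x = -f4x - svx, f3y = -f4y - svy, f3z = -f4z - svz;
    f[3 * i1] += f1x; f[3 * i1 + 1] += f1y; f[3 * i1 + 2] += f1z;
    f[3 * i2] += f2x; f[3 * i2 + 1] += f2y; f[3 * i2 + 2] += f2z;
    f[3 * i3] += f3x; f[3 * i3 + 1] += f3y; f[3 * i3 + 2] += f3z;
    f[3 * i4] += f4x; f[3 * i4 + 1] += f4y; f[3 * i4 + 2] += f4z;
    // virial: local coords relative to atom 2
    virial_zz += f1z * (-b1z) + f3z * b2z + f4z * (b2z + b3z);
  }
}

static void pair_forces_list(const std::vector<double> &x, const double *box,
                             const Topology &top, const PairFF &ff,
                             NeighborList &nl, std::vector<double> &f,
                             EnergyTerms &E, double &virial_zz) {
  int n = top.n;
  // refresh sorted-space coordinates from the build-time permutation/shifts
  for (int i = 0; i < n; ++i) {
    int o = nl.perm[i];
    nl.xs[3 * i] = x[3 * o] - nl.ssort[2 * i];
    nl.xs[3 * i + 1] = x[3 * o + 1] - nl.ssort[2 * i + 1];
    nl.xs[3 * i + 2] = x[3 * o + 2];
    nl.fs[3 * i] = 0.0; nl.fs[3 * i + 1] = 0.0; nl.fs[3 * i + 2] = 0.0;
  }
  const double *xs = nl.xs.data();
  double *fsrt = nl.fs.data();
  const int *tsort = nl.tsort.data();
  const double *qsort = nl.qsort.data();
  const double *cutsq = ff.cutsq.data();
  double hx = 0.5 * box[0], hy = 0.5 * box[1];
  for (int i = 0; i < n; ++i) {
    double xi = xs[3 * i], yi = xs[3 * i + 1], zi = xs[3 * i + 2];
    double qi = qsort[i];
    int ti = tsort[i];
    double fxi = 0, fyi = 0, fzi = 0;
    for (int k = nl.start[i]; k < nl.start[i + 1]; ++k) {
      int j = nl.nbr[k];
      double dx = xi - xs[3 * j];
      if (dx > hx) dx -= box[0]; else if (dx < -hx) dx += box[0];
      double dy = yi - xs[3 * j + 1];
      if (dy > hy) dy -= box[1]; else if (dy < -hy) dy += box[1];
      double dz = mimg(zi - xs[3 * j + 2], box[2]);
      double r2 = dx * dx + dy * dy + dz * dz;
      int tij = ti * ff.ntypes + tsort[j];
      if (r2 >= cutsq[tij]) continue;
      double elj, ec, fr;
      if (ff.use_tab)
        ff.pair_ef_tab(ti, tsort[j], qi * qsort[j], r2, elj, ec, fr);
      else
        ff.pair_ef(ti, tsort[j], qi * qsort[j], r2, elj, ec, fr);
      E.lj += elj; E.coul += ec;
      fxi += fr * dx; fyi += fr * dy; fzi += fr * dz;
      fsrt[3 * j] -= fr * dx; fsrt[3 * j + 1] -= fr * dy; fsrt[3 * j + 2] -= fr * dz;
      virial_zz += fr * dz * dz;
    }
    fsrt[3 * i] += fxi; fsrt[3 * i + 1] += fyi; fsrt[3 * i + 2] += fzi;
  }
  // scatter back to original order
  for (int i = 0; i < n; ++i) {
    int o = nl.perm[i];
    f[3 * o] += fsrt[3 * i];
    f[3 * o + 1] += fsrt[3 * i + 1];
    f[3 * o + 2] += fsrt[3 * i + 2];
  }
}

static void pair_forces_brute(const std::vector<double> &x, const double *box,
                              const Topology &top, const PairFF &ff,
                              std::vector<double> &f, EnergyTerms &E,
                              double &virial_zz) {
  int n = top.n;
  double cut2 = ff.cutoff * ff.cutoff;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      if (top.excluded(i, j)) continue;
      double dx = mimg(x[3 * i] - x[3 * j], box[0]);
      double dy = mimg(x[3 * i + 1] - x[3 * j + 1], box[1]);
      double dz = mimg(x[3 * i + 2] - x[3 * j + 2], box[2]);
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 >= cut2) continue;
      double elj, ec, fr;
      if (ff.use_tab)
        ff.pair_ef_tab(top.type[i], top.type[j], top.q[i] * top.q[j], r2, elj, ec, fr);
      else
        ff.pair_ef(top.type[i], top.type[j], top.q[i] * top.q[j], r2, elj, ec, fr);
      E.lj += elj; E.coul += ec;
      f[3 * i] += fr * dx; f[3 * i + 1] += fr * dy; f[3 * i + 2] += fr * dz;
      f[3 * j] -= fr * dx; f[3 * j + 1] -= fr * dy; f[3 * j + 2] -= fr * dz;
      virial_zz += fr * dz * dz;
    }
}

// ------------------------------------------------------------ R-side parsing
static Topology parse_topology(const List &state) {
  Topology top;
  NumericMatrix x = state["x"];
  top.n = x.nrow();
  IntegerVector tp = state["type"];
  NumericVector q = state["charge"], m = state["mass"];
  top.type.resize(top.n); top.q.resize(top.n); top.mass.resize(top.n);
  for (int i = 0; i < top.n; ++i) {
    top.type[i] = tp[i] - 1;
    top.q[i] = q[i];
    top.mass[i] = m[i];
  }
  if (state.containsElementNamed("bonds") && !Rf_isNull(state["bonds"])) {
    IntegerMatrix b = state["bonds"];
    NumericVector bk = state["bond_k"], br = state["bond_r0"];
    for (int i = 0; i < b.nrow(); ++i) {
      top.bond_i.push_back(b(i, 0) - 1);
      top.bond_j.push_back(b(i, 1) - 1);
      top.bond_k.push_back(bk[i]);
      top.bond_r0.push_back(br[i]);
    }
  }
  if (state.containsElementNamed("angles") && !Rf_isNull(state["angles"])) {
    IntegerMatrix a = state["angles"];
    IntegerVector at = state["angle_type"];
    NumericVector aK = state["angle_k"], a0 = state["angle_theta0"];
    for (int i = 0; i < a.nrow(); ++i) {
      top.ang_i.push_back(a(i, 0) - 1);
      top.ang_j.push_back(a(i, 1) - 1);
      top.ang_k.push_back(a(i, 2) - 1);
      top.ang_t.push_back(at[i]);
      top.ang_K.push_back(aK[i]);
      top.ang_th0.push_back(a0[i]);
    }
  }
  if (state.containsElementNamed("dihedrals") && !Rf_isNull(state["dihedrals"])) {
    IntegerMatrix dd = state["dihedrals"];
    NumericMatrix dt = state["dihedral_terms"]; // columns K, n, phi0(rad)
    for (int i = 0; i < dd.nrow(); ++i) {
      top.dih_i.push_back(dd(i, 0) - 1);
      top.dih_j.push_back(dd(i, 1) - 1);
      top.dih_k.push_back(dd(i, 2) - 1);
      top.dih_l.push_back(dd(i, 3) - 1);
    }
    for (int t = 0; t < dt.nrow(); ++t) {
      top.dK.push_back(dt(t, 0));
      top.dn.push_back(dt(t, 1));
      top.dphi0.push_back(dt(t, 2));
      top.dcos0.push_back(std::cos(dt(t, 2)));
      top.dsin0.push_back(std::sin(dt(t, 2)));
      if (t > 0 && dt(t, 1) < dt(t - 1, 1))
        stop("dihedral terms must be ordered by ascending multiplicity");
    }
  }
  // exclusions: CSR from an ne x 2 matrix (symmetric closure done here)
  std::vector<std::vector<int>> ex(top.n);
  if (state.containsElementNamed("exclusions") && !Rf_isNull(state["exclusions"])) {
    IntegerMatrix e = state["exclusions"];
    for (int i = 0; i < e.nrow(); ++i) {
      int a = e(i, 0) - 1, b = e(i, 1) - 1;
      ex[a].push_back(b);
      ex[b].push_back(a);
    }
  }
  top.excl_start.assign(top.n + 1, 0);
  for (int i = 0; i < top.n; ++i) {
    std::sort(ex[i].begin(), ex[i].end());
    ex[i].erase(std::unique(ex[i].begin(), ex[i].end()), ex[i].end());
    top.excl_start[i + 1] = top.excl_start[i] + (int)ex[i].size();
  }
  top.excl_list.resize(top.excl_start[top.n]);
  for (int i = 0; i < top.n; ++i)
    std::copy(ex[i].begin(), ex[i].end(), top.excl_list.begin() + top.excl_start[i]);
  return top;
}

static PairFF parse_ff(const List &ff) {
  PairFF p;
  p.init(as<NumericMatrix>(ff["sigma"]), as<NumericMatrix>(ff["epsilon"]),
         as<IntegerMatrix>(ff["style"]), as<double>(ff["cutoff"]),
         as<double>(ff["shift_onset"]), as<double>(ff["eps_r"]),
         as<double>(ff["coul_cutoff"]));
  p.build_tables();
  return p;
}

static void compute_all(const std::vector<double> &x, const double *box,
                        const Topology &top, const PairFF &ff,
                        NeighborList *nl, std::vector<double> &f,
                        EnergyTerms &E, double &virial_zz) {
  std::fill(f.begin(), f.end(), 0.0);
  E = EnergyTerms();
  virial_zz = 0.0;
  if (nl) {
    if (nl->needs_rebuild(x))
      nl->build_cell(x, box, top, ff);
    pair_forces_list(x, box, top, ff, *nl, f, E, virial_zz);
  } else {
    pair_forces_brute(x, box, top, ff, f, E, virial_zz);
  }
  bonded_forces(x, box, top, f, E, virial_zz);
}

// [[Rcpp::export]]
List cpp_compute(List state, List ffr, std::string method) {
  Topology top = parse_topology(state);
  PairFF ff = parse_ff(ffr);
  NumericMatrix xm = state["x"];
  NumericVector boxv = state["box"];
  double box[3] = {boxv[0], boxv[1], boxv[2]};
  for (int d = 0; d < 3; ++d)
    if (box[d] < 2.0 * ff.cutoff)
      stop("box edge %d (%.2f A) is smaller than twice the cutoff (%.1f A)",
           d + 1, box[d], ff.cutoff);
  std::vector<double> x(3 * top.n), f(3 * top.n);
  for (int i = 0; i < top.n; ++i)
    for (int d = 0; d < 3; ++d) x[3 * i + d] = xm(i, d);
  EnergyTerms E;
  double vzz = 0.0;
  if (method == "cell") {
    NeighborList nl;
    compute_all(x, box, top, ff, &nl, f, E, vzz);
  } else {
    compute_all(x, box, top, ff, nullptr, f, E, vzz);
  }
  NumericMatrix fm(top.n, 3);
  for (int i = 0; i < top.n; ++i)
    for (int d = 0; d < 3; ++d) fm(i, d) = f[3 * i + d];
  return List::create(
      _["energy"] = List::create(_["lj"] = E.lj, _["coul"] = E.coul,
                                 _["bond"] = E.bond, _["angle"] = E.angle,
                                 _["dihedral"] = E.dih, _["total"] = E.total()),
      _["forces"] = fm, _["virial_zz"] = vzz);
}

// [[Rcpp::export]]
List cpp_minimize(List state, List ffr, int max_iters, double ftol,
                  double max_step) {
  Topology top = parse_topology(state);
  PairFF ff = parse_ff(ffr);
  NumericMatrix xm = state["x"];
  NumericVector boxv = state["box"];
  double box[3] = {boxv[0], boxv[1], boxv[2]};
  int n = top.n;
  std::vector<double> x(3 * n), f(3 * n), xtrial(3 * n), ftrial(3 * n);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) x[3 * i + d] = xm(i, d);
  NeighborList nl;
  EnergyTerms E, Et;
  double vzz;
  compute_all(x, box, top, ff, &nl, f, E, vzz);
  double e = E.total();
  if (!std::isfinite(e)) stop("initial configuration has non-finite energy");
  double alpha = 1e-4;
  int it = 0;
  double fmax = 0.0;
  for (it = 0; it < max_iters; ++it) {
    fmax = 0.0;
    for (int i = 0; i < 3 * n; ++i) fmax = std::max(fmax, std::abs(f[i]));
    if (fmax < ftol) break;
    double a = alpha;
    if (a * fmax > max_step) a = max_step / fmax;
    for (int i = 0; i < 3 * n; ++i) xtrial[i] = x[i] + a * f[i];
    double vt;
    compute_all(xtrial, box, top, ff, &nl, ftrial, Et, vt);
    double et = Et.total();
    if (std::isfinite(et) && et <= e) {
      x = xtrial; f = ftrial; e = et;
      alpha *= 1.2;
    } else {
      alpha *= 0.5;
      if (alpha < 1e-12) break;
    }
  }
  NumericMatrix xo(n, 3);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) xo(i, d) = x[3 * i + d];
  return List::create(_["x"] = xo, _["energy"] = e, _["fmax"] = fmax,
                      _["iterations"] = it);
}

// [[Rcpp::export]]
List cpp_run(List state, List ffr, List settings) {
  Topology top = parse_topology(state);
  PairFF ff = parse_ff(ffr);
  NumericMatrix xm = state["x"];
  NumericVector boxv = state["box"];
  double box[3] = {boxv[0], boxv[1], boxv[2]};
  int n = top.n;

  double dt = as<double>(settings["dt"]);
  int nsteps = as<int>(settings["n_steps"]);
  double Ttarget = as<double>(settings["temperature"]);
  double gamma = as<double>(settings["friction"]);     // 1/fs; 0 => NVE
  int seed = as<int>(settings["seed"]);
  int frame_every = as<int>(settings["frame_every"]);
  int thermo_every = as<int>(settings["thermo_every"]);
  bool zero_mom = as<bool>(settings["zero_momentum"]);
  bool baro = as<bool>(settings["barostat"]);
  double Pext = baro ? as<double>(settings["pressure_z"]) : 0.0;
  double Wp = baro ? as<double>(settings["piston_mass"]) : 1.0;
  double gL = baro ? as<double>(settings["piston_friction"]) : 0.0;
  double t0 = settings.containsElementNamed("time0") ? as<double>(settings["time0"]) : 0.0;
  ff.use_tab = settings.containsElementNamed("tabulated") ?
      as<bool>(settings["tabulated"]) : true;
  bool use_cell = settings.containsElementNamed("use_cell") ?
      as<bool>(settings["use_cell"]) : true;

  std::vector<double> x(3 * n), v(3 * n, 0.0), f(3 * n);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) x[3 * i + d] = xm(i, d);
  Pcg32 rng((uint64_t)seed);
  if (state.containsElementNamed("v") && !Rf_isNull(state["v"])) {
    NumericMatrix vm = state["v"];
    for (int i = 0; i < n; ++i)
      for (int d = 0; d < 3; ++d) v[3 * i + d] = vm(i, d);
  } else if (Ttarget > 0.0) {
    // Maxwell-Boltzmann draw
    for (int i = 0; i < n; ++i) {
      double s = std::sqrt(KB * Ttarget * FTM2V / top.mass[i]);
      for (int d = 0; d < 3; ++d) v[3 * i + d] = s * rng.gauss();
    }
  }

  NeighborList nl;
  EnergyTerms E;
  double vzz = 0.0;
  compute_all(x, box, top, ff, use_cell ? &nl : nullptr, f, E, vzz);

  double c1 = std::exp(-gamma * dt);
  double c2 = std::sqrt(std::max(0.0, 1.0 - c1 * c1));

  int nframes = nsteps / frame_every;
  NumericMatrix frames(3 * n, std::max(nframes, 0));
  NumericVector frame_time(std::max(nframes, 0));
  NumericVector frame_lz(std::max(nframes, 0));
  int nth = nsteps / thermo_every;
  NumericMatrix thermo(std::max(nth, 0), 10);
  double vL = 0.0;
  int fidx = 0, tidx = 0;
  double area = box[0] * box[1];

  for (int step = 1; step <= nsteps; ++step) {
    // B
    for (int i = 0; i < n; ++i) {
      double a = dt * 0.5 * FTM2V / top.mass[i];
      v[3 * i] += a * f[3 * i];
      v[3 * i + 1] += a * f[3 * i + 1];
      v[3 * i + 2] += a * f[3 * i + 2];
    }
    // A
    double maxd2 = 0.0;
    for (int i = 0; i < 3 * n; ++i) x[i] += 0.5 * dt * v[i];
    // O
    if (gamma > 0.0) {
      double dpx = 0.0, dpy = 0.0, dpz = 0.0;
      for (int i = 0; i < n; ++i) {
        double s = c2 * std::sqrt(KB * Ttarget * FTM2V / top.mass[i]);
        double ovx = v[3 * i], ovy = v[3 * i + 1], ovz = v[3 * i + 2];
        v[3 * i] = c1 * v[3 * i] + s * rng.gauss();
        v[3 * i + 1] = c1 * v[3 * i + 1] + s * rng.gauss();
        v[3 * i + 2] = c1 * v[3 * i + 2] + s * rng.gauss();
        dpx += top.mass[i] * (v[3 * i] - ovx);
        dpy += top.mass[i] * (v[3 * i + 1] - ovy);
        dpz += top.mass[i] * (v[3 * i + 2] - ovz);
      }
      if (zero_mom) {
        double mtot = 0.0;
        for (int i = 0; i < n; ++i) mtot += top.mass[i];
        for (int i = 0; i < n; ++i) {
          v[3 * i] -= dpx / mtot;
          v[3 * i + 1] -= dpy / mtot;
          v[3 * i + 2] -= dpz / mtot;
        }
      }
    }
    // A
    for (int i = 0; i < 3 * n; ++i) x[i] += 0.5 * dt * v[i];
    // barostat: piston dynamics on Lz, instantaneous virial pressure
    if (baro) {
      double ke_z = 0.0;
      for (int i = 0; i < n; ++i) ke_z += top.mass[i] * v[3 * i + 2] * v[3 * i + 2];
      double vol = box[0] * box[1] * box[2];
      double pzz = (ke_z * MVV2E + vzz) / vol * NKTV2P; // bar
      double FL = (pzz - Pext) * area / NKTV2P;         // kcal/mol/A
      vL += dt * (FL / Wp * FTM2V);
      vL *= (1.0 - gL * dt);
      double newLz = box[2] + dt * vL;
      double mu = newLz / box[2];
      mu = std::max(0.9999, std::min(1.0001, mu));
      newLz = box[2] * mu;
      if (newLz < 2.0 * ff.cutoff) { newLz = 2.0 * ff.cutoff; vL = 0.0; }
      double zc = 0.5 * box[2];
      double zc_new = 0.5 * newLz;
      for (int i = 0; i < n; ++i)
        x[3 * i + 2] = zc_new + (x[3 * i + 2] - zc) * (newLz / box[2]);
      box[2] = newLz;
    }
    // forces
    compute_all(x, box, top, ff, use_cell ? &nl : nullptr, f, E, vzz);
    // B
    for (int i = 0; i < n; ++i) {
      double a = dt * 0.5 * FTM2V / top.mass[i];
      v[3 * i] += a * f[3 * i];
      v[3 * i + 1] += a * f[3 * i + 1];
      v[3 * i + 2] += a * f[3 * i + 2];
    }
    // blow-up guard
    for (int i = 0; i < n; ++i) {
      double spd2 = v[3 * i] * v[3 * i] + v[3 * i + 1] * v[3 * i + 1] +
                    v[3 * i + 2] * v[3 * i + 2];
      maxd2 = std::max(maxd2, spd2);
    }
    if (maxd2 * dt * dt > 4.0)
      stop("simulation blew up at step %d (per-step displacement > 2 A); "
           "check overlaps or reduce the timestep", step);
    if (!std::isfinite(E.total()))
      stop("non-finite energy at step %d", step);

    if (thermo_every > 0 && step % thermo_every == 0 && tidx < nth) {
      double ke = 0.0, ke_z = 0.0;
      for (int i = 0; i < n; ++i) {
        double v2 = v[3 * i] * v[3 * i] + v[3 * i + 1] * v[3 * i + 1] +
                    v[3 * i + 2] * v[3 * i + 2];
        ke += 0.5 * top.mass[i] * v2;
        ke_z += top.mass[i] * v[3 * i + 2] * v[3 * i + 2];
      }
      ke *= MVV2E;
      double Tinst = 2.0 * ke / (3.0 * n * KB);
      double vol = box[0] * box[1] * box[2];
      double pzz = (ke_z * MVV2E + vzz) / vol * NKTV2P;
      thermo(tidx, 0) = t0 + step * dt;
      thermo(tidx, 1) = E.lj;
      thermo(tidx, 2) = E.coul;
      thermo(tidx, 3) = E.bond;
      thermo(tidx, 4) = E.angle;
      thermo(tidx, 5) = E.dih;
      thermo(tidx, 6) = ke;
      thermo(tidx, 7) = Tinst;
      thermo(tidx, 8) = pzz;
      thermo(tidx, 9) = box[2];
      ++tidx;
    }
    if (frame_every > 0 && step % frame_every == 0 && fidx < nframes) {
      for (int i = 0; i < 3 * n; ++i) frames(i, fidx) = x[i];
      frame_time[fidx] = t0 + step * dt;
      frame_lz[fidx] = box[2];
      ++fidx;
    }
  }

  NumericMatrix xo(n, 3), vo(n, 3);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) {
      xo(i, d) = x[3 * i + d];
      vo(i, d) = v[3 * i + d];
    }
  return List::create(
      _["x"] = xo, _["v"] = vo, _["box"] = NumericVector::create(box[0], box[1], box[2]),
      _["frames"] = frames, _["frame_time"] = frame_time, _["frame_lz"] = frame_lz,
      _["thermo"] = thermo, _["piston_velocity"] = vL);
}

// ------------------------------------------------------------------ RDF kernel
// frames: (3N) x F matrix of unwrapped coordinates; idx: 1-based bead indices
// [[Rcpp::export]]
NumericVector cpp_rdf_hist(NumericMatrix frames, NumericVector box,
                           IntegerVector idx, double rmax, int nbins) {
  int F = frames.ncol();
  int m = idx.size();
  NumericVector hist(nbins);
  double dr = rmax / nbins;
  for (int fi = 0; fi < F; ++fi) {
    for (int a = 0; a < m; ++a) {
      int i = idx[a] - 1;
      for (int b = a + 1; b < m; ++b) {
        int j = idx[b] - 1;
        double dx = mimg(frames(3 * i, fi) - frames(3 * j, fi), box[0]);
        double dy = mimg(frames(3 * i + 1, fi) - frames(3 * j + 1, fi), box[1]);
        double dz = mimg(frames(3 * i + 2, fi) - frames(3 * j + 2, fi), box[2]);
        double r = std::sqrt(dx * dx + dy * dy + dz * dz);
        if (r < rmax) {
          int bin = (int)(r / dr);
          if (bin >= 0 && bin < nbins) hist[bin] += 2.0; // ordered pairs
        }
      }
    }
  }
  return hist;
}

// ---------------------------------------------------------------- MSD kernel
// Multi-origin MSD at the requested lags (in frames). rows: per-bead xyz.
// dims: integer vector of dimensions to include (1,2,3 for x,y,z).
// [[Rcpp::export]]
NumericVector cpp_msd(NumericMatrix frames, IntegerVector idx,
                      IntegerVector lags, IntegerVector dims,
                      int origin_stride) {
  int F = frames.ncol();
  int m = idx.size();
  int nl = lags.size();
  NumericVector out(nl);
  for (int li = 0; li < nl; ++li) {
    int lag = lags[li];
    double acc = 0.0;
    long cnt = 0;
    for (int t0 = 0; t0 + lag < F; t0 += origin_stride) {
      int t1 = t0 + lag;
      for (int a = 0; a < m; ++a) {
        int i = idx[a] - 1;
        double s = 0.0;
        for (int dd = 0; dd < dims.size(); ++dd) {
          int d = dims[dd] - 1;
          double diff = frames(3 * i + d, t1) - frames(3 * i + d, t0);
          s += diff * diff;
        }
        acc += s;
        ++cnt;
      }
    }
    out[li] = cnt > 0 ? acc / cnt : NA_REAL;
  }
  return out;
}

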