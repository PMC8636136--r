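// Coarse-grained energy/force kernel and Langevin propagator.
//
// Units: length Angstrom, energy kcal/mol, mass amu-like, time in the reduced
// unit implied by those choices. kB = 0.0019872041 kcal/mol/K.
//
// Energy terms (breakdown indices):
//   0 protein_local   harmonic bonds/angles + native-biased dihedrals (protein)
//   1 dna_bonded      harmonic bonds/angles + periodic dihedrals (DNA backbone)
//   2 dna_stack       nearest-neighbour intra-strand base stacking, 12-10 wells
//   3 dna_pair        Watson-Crick pairing, orientation-modulated 12-10 wells
//   4 go_protein      intra-protein native-contact 12-10 wells
//   5 go_protein_dna  protein-DNA native-contact 12-10 wells (the union set)
//   6 excluded_volume purely repulsive r^-12, truncated & shifted, capped at r->0
//   7 electrostatic   Debye-Hueckel, truncated & shifted at dh_cutoff

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>

using namespace Rcpp;

static const int N_TERMS = 8;
static const double KB = 0.0019872041;

// ---------------------------------------------------------------- RNG -------
// xoshiro256++ seeded via splitmix64; Box-Muller normals with a cached spare.
// Self-contained so trajectories are bit-reproducible for a given seed,
// independent of R's RNG state.
struct Xoshiro {
  uint64_t s[4];
  double spare;
  bool has_spare;
  explicit Xoshiro(uint64_t seed) : has_spare(false), spare(0.0) {
    uint64_t x = seed;
    for (int i = 0; i < 4; i++) {
      x += 0x9e3779b97f4a7c15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
      z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  inline double unif() {  // (0,1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  inline double norm() {
    if (has_spare) { has_spare = false; return spare; }
    double u1 = unif(), u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1));
    double th = 2.0 * M_PI * u2;
    spare = r * std::sin(th);
    has_spare = true;
    return r * std::cos(th);
  }
};

// ------------------------------------------------------------- system -------
struct BondT   { int i, j; double r0, k; int term; };
struct AngleT  { int i, j, k; double th0, kth; int term; };
struct DihT    { int i, j, k, l; double phi0, k1, k3; int term; };
struct PairT   { int i, j; double r0, eps; int term; };      // 12-10 wells
struct WCT     { int bi, bj, si, sj; double r0, eps, th10, th20, sig; };

struct System {
  int n;
  std::vector<BondT> bonds;
  std::vector<AngleT> angles;
  std::vector<DihT> dihs;
  std::vector<PairT> pairs;       // go_protein, go_protein_dna, dna_stack
  std::vector<WCT> wc;
  std::vector<double> charge, evR, mass;
  double ev_eps, dh_pref, dh_lambda, dh_cutoff;
  std::vector<std::vector<int>> excl;  // sorted exclusion lists (nonbonded skip)
  double cut_nb;                       // max nonbonded cutoff
};

static void add_excl(System& S, int i, int j) {
  S.excl[i].push_back(j);
  S.excl[j].push_back(i);
}
static bool is_excl(const System& S, int i, int j) {
  const std::vector<int>& e = S.excl[i];
  for (size_t k = 0; k < e.size(); k++) if (e[k] == j) return true;
  return false;
}

static System unpack_system(const List& sys) {
  System S;
  S.n = as<int>(sys["n"]);
  NumericMatrix bm = sys["bonds"];
  for (int r = 0; r < bm.nrow(); r++)
    S.bonds.push_back({(int)bm(r,0)-1, (int)bm(r,1)-1, bm(r,2), bm(r,3), (int)bm(r,4)});
  NumericMatrix am = sys["angles"];
  for (int r = 0; r < am.nrow(); r++)
    S.angles.push_back({(int)am(r,0)-1, (int)am(r,1)-1, (int)am(r,2)-1,
                        am(r,3), am(r,4), (int)am(r,5)});
  NumericMatrix dm = sys["dihedrals"];
  for (int r = 0; r < dm.nrow(); r++)
    S.dihs.push_back({(int)dm(r,0)-1, (int)dm(r,1)-1, (int)dm(r,2)-1, (int)dm(r,3)-1,
                      dm(r,4), dm(r,5), dm(r,6), (int)dm(r,7)});
  NumericMatrix pm = sys["pairs"];
  for (int r = 0; r < pm.nrow(); r++)
    S.pairs.push_back({(int)pm(r,0)-1, (int)pm(r,1)-1, pm(r,2), pm(r,3), (int)pm(r,4)});
  NumericMatrix wm = sys["wc"];
  for (int r = 0; r < wm.nrow(); r++)
    S.wc.push_back({(int)wm(r,0)-1, (int)wm(r,1)-1, (int)wm(r,2)-1, (int)wm(r,3)-1,
                    wm(r,4), wm(r,5), wm(r,6), wm(r,7), wm(r,8)});
  S.charge = as<std::vector<double>>(sys["charge"]);
  S.evR    = as<std::vector<double>>(sys["ev_radius"]);
  S.mass   = as<std::vector<double>>(sys["mass"]);
  S.ev_eps    = as<double>(sys["ev_eps"]);
  S.dh_pref   = as<double>(sys["dh_pref"]);    // 332.0637/eps_r
  S.dh_lambda = as<double>(sys["dh_lambda"]);
  S.dh_cutoff = as<double>(sys["dh_cutoff"]);

  S.excl.resize(S.n);
  for (size_t r = 0; r < S.bonds.size(); r++) add_excl(S, S.bonds[r].i, S.bonds[r].j);
  for (size_t r = 0; r < S.angles.size(); r++) add_excl(S, S.angles[r].i, S.angles[r].k);
  for (size_t r = 0; r < S.pairs.size(); r++) add_excl(S, S.pairs[r].i, S.pairs[r].j);
  // disabled pairs (eps <= 0, e.g. a mismatch window) keep their excluded
  // volume so melted strands cannot interpenetrate
  for (size_t r = 0; r < S.wc.size(); r++)
    if (S.wc[r].eps > 0.0) add_excl(S, S.wc[r].bi, S.wc[r].bj);

  double evmax = 0;
  for (int i = 0; i < S.n; i++) evmax = std::max(evmax, S.evR[i]);
  S.cut_nb = std::max(S.dh_cutoff, 2.0 * 2.0 * evmax);
  return S;
}

// ----------------------------------------------------- force helpers --------
static inline double dist(const double* x, int i, int j, double* d) {
  d[0] = x[3*i]   - x[3*j];
  d[1] = x[3*i+1] - x[3*j+1];
  d[2] = x[3*i+2] - x[3*j+2];
  return std::sqrt(d[0]*d[0] + d[1]*d[1] + d[2]*d[2]);
}

// 12-10 well: E = eps*(5 x^12 - 6 x^10), x = r0/r. Returns E, sets dE/dr.
// Capped: for r below rmin = 0.3*r0 the energy continues linearly (finite at 0).
static inline double e1210(double r, double r0, double eps, double* dEdr) {
  double rmin = 0.3 * r0;
  if (r < rmin) {
    double x = r0 / rmin;
    double x2 = x*x, x10 = x2*x2*x2*x2*x2, x12 = x10*x2;
    double E0 = eps * (5.0*x12 - 6.0*x10);
    double d0 = 60.0 * eps * x10 * (1.0 - x2) / rmin;  // dE/dr at rmin (<0)
    *dEdr = d0;
    return E0 + d0 * (r - rmin);
  }
  double x = r0 / r;
  double x2 = x*x, x10 = x2*x2*x2*x2*x2, x12 = x10*x2;
  *dEdr = 60.0 * eps * x10 * (1.0 - x2) / r;
  return eps * (5.0*x12 - 6.0*x10);
}

// Angle theta(i,j,k) and gradient w.r.t. the three beads.
// Returns theta; g is 9 doubles (gi, gj, gk). Degenerate geometries return
// theta with zero gradient.
static inline double angle_grad(const double* x, int i, int j, int k, double* g) {
  double u[3], v[3];
  double ru = dist(x, i, j, u);
  double rv = dist(x, k, j, v);
  for (int a = 0; a < 9; a++) g[a] = 0.0;
  if (ru < 1e-8 || rv < 1e-8) return 0.0;
  double c = (u[0]*v[0] + u[1]*v[1] + u[2]*v[2]) / (ru * rv);
  if (c > 1.0) c = 1.0;
  if (c < -1.0) c = -1.0;
  double th = std::acos(c);
  double s = std::sqrt(1.0 - c*c);
  // clamp near-collinear geometries: the exact gradient diverges as 1/sin,
  // which would kick the integrator; the capped force stays bounded
  if (s < 0.02) s = 0.02;
  for (int a = 0; a < 3; a++) {
    double dci = (v[a]/(ru*rv)) - c*u[a]/(ru*ru);
    double dck = (u[a]/(ru*rv)) - c*v[a]/(rv*rv);
    g[a]     = -dci / s;          // dtheta/dri
    g[6+a]   = -dck / s;          // dtheta/drk
    g[3+a]   = -(g[a] + g[6+a]);  // dtheta/drj
  }
  return th;
}

// Dihedral phi(i,j,k,l) and gradient (12 doubles). Standard formulation.
static inline double dih_grad(const double* x, int i, int j, int k, int l, double* g) {
  double b1[3], b2[3], b3[3];
  for (int a = 0; a < 3; a++) {
    b1[a] = x[3*j+a] - x[3*i+a];
    b2[a] = x[3*k+a] - x[3*j+a];
    b3[a] = x[3*l+a] - x[3*k+a];
  }
  double n1[3] = { b1[1]*b2[2]-b1[2]*b2[1], b1[2]*b2[0]-b1[0]*b2[2], b1[0]*b2[1]-b1[1]*b2[0] };
  double n2[3] = { b2[1]*b3[2]-b2[2]*b3[1], b2[2]*b3[0]-b2[0]*b3[2], b2[0]*b3[1]-b2[1]*b3[0] };
  double n1sq = n1[0]*n1[0]+n1[1]*n1[1]+n1[2]*n1[2];
  double n2sq = n2[0]*n2[0]+n2[1]*n2[1]+n2[2]*n2[2];
  double b2n  = std::sqrt(b2[0]*b2[0]+b2[1]*b2[1]+b2[2]*b2[2]);
  for (int a = 0; a < 12; a++) g[a] = 0.0;
  if (n1sq < 1e-12 || n2sq < 1e-12 || b2n < 1e-8) return 0.0;
  // clamp near-collinear backbones (|n| ~ |b||b'| sin): bounded gradient
  double nmin1 = 4e-4 * (b1[0]*b1[0]+b1[1]*b1[1]+b1[2]*b1[2]) * (b2n*b2n);
  double nmin2 = 4e-4 * (b3[0]*b3[0]+b3[1]*b3[1]+b3[2]*b3[2]) * (b2n*b2n);
  if (n1sq < nmin1) n1sq = nmin1;
  if (n2sq < nmin2) n2sq = nmin2;
  double m[3] = { n1[1]*n2[2]-n1[2]*n2[1], n1[2]*n2[0]-n1[0]*n2[2], n1[0]*n2[1]-n1[1]*n2[0] };
  double ycomp = (m[0]*b2[0]+m[1]*b2[1]+m[2]*b2[2]) / b2n;
  double xcomp = n1[0]*n2[0]+n1[1]*n2[1]+n1[2]*n2[2];
  double phi = std::atan2(ycomp, xcomp);
  double b1b2 = b1[0]*b2[0]+b1[1]*b2[1]+b1[2]*b2[2];
  double b3b2 = b3[0]*b2[0]+b3[1]*b2[1]+b3[2]*b2[2];
  for (int a = 0; a < 3; a++) {
    double dphi_di = -b2n / n1sq * n1[a];
    double dphi_dl =  b2n / n2sq * n2[a];
    g[a]   = dphi_di;
    g[9+a] = dphi_dl;
    g[3+a] = -(1.0 + b1b2 / (b2n*b2n)) * dphi_di + (b3b2 / (b2n*b2n)) * dphi_dl;
    g[6+a] = -(g[a] + g[3+a] + g[9+a]);
  }
  return phi;
}

// ----------------------------------------------------- neighbour list -------
struct NList {
  std::vector<int> pi, pj;
  std::vector<double> x_at_build;
  double skin;
  void build(const System& S, const double* x) {
    pi.clear(); pj.clear();
    double cut = S.cut_nb + skin;
    double cut2 = cut * cut;
    for (int i = 0; i < S.n; i++) {
      for (int j = i + 1; j < S.n; j++) {
        double dx = x[3*i]-x[3*j], dy = x[3*i+1]-x[3*j+1], dz = x[3*i+2]-x[3*j+2];
        if (dx*dx + dy*dy + dz*dz < cut2 && !is_excl(S, i, j)) {
          pi.push_back(i); pj.push_back(j);
        }
      }
    }
    x_at_build.assign(x, x + 3 * S.n);
  }
  bool stale(const System& S, const double* x) const {
    double lim = 0.25 * skin * skin;  // (skin/2)^2
    for (int i = 0; i < S.n; i++) {
      double dx = x[3*i]-x_at_build[3*i], dy = x[3*i+1]-x_at_build[3*i+1],
             dz = x[3*i+2]-x_at_build[3*i+2];
      if (dx*dx + dy*dy + dz*dz > lim) return true;
    }
    return false;
  }
};

// ------------------------------------------------------ energy/forces -------
static void eval_ef(const System& S, const double* x, const NList& nl,
                    double* terms, double* f) {
  for (int t = 0; t < N_TERMS; t++) terms[t] = 0.0;
  for (int a = 0; a < 3 * S.n; a++) f[a] = 0.0;
  double d[3];

  for (size_t r = 0; r < S.bonds.size(); r++) {
    const BondT& b = S.bonds[r];
    double rr = dist(x, b.i, b.j, d);
    double dr = rr - b.r0;
    terms[b.term] += b.k * dr * dr;
    double c = -2.0 * b.k * dr / std::max(rr, 1e-8);
    for (int a = 0; a < 3; a++) { f[3*b.i+a] += c*d[a]; f[3*b.j+a] -= c*d[a]; }
  }

  double g9[9];
  for (size_t r = 0; r < S.angles.size(); r++) {
    const AngleT& an = S.angles[r];
    double th = angle_grad(x, an.i, an.j, an.k, g9);
    double dth = th - an.th0;
    terms[an.term] += an.kth * dth * dth;
    double c = -2.0 * an.kth * dth;
    for (int a = 0; a < 3; a++) {
      f[3*an.i+a] += c * g9[a];
      f[3*an.j+a] += c * g9[3+a];
      f[3*an.k+a] += c * g9[6+a];
    }
  }

  double g12[12];
  for (size_t r = 0; r < S.dihs.size(); r++) {
    const DihT& dh = S.dihs[r];
    double phi = dih_grad(x, dh.i, dh.j, dh.k, dh.l, g12);
    double dphi = phi - dh.phi0;
    terms[dh.term] += dh.k1 * (1.0 - std::cos(dphi)) + dh.k3 * (1.0 - std::cos(3.0*dphi));
    double dE = dh.k1 * std::sin(dphi) + 3.0 * dh.k3 * std::sin(3.0*dphi);
    for (int a = 0; a < 3; a++) {
      f[3*dh.i+a] -= dE * g12[a];
      f[3*dh.j+a] -= dE * g12[3+a];
      f[3*dh.k+a] -= dE * g12[6+a];
      f[3*dh.l+a] -= dE * g12[9+a];
    }
  }

  // Native-contact wells (terms 4, 5) are truncated and shifted at 2*r0 so a
  // contact exerts no force once broken well beyond its native distance;
  // stacking (term 2) keeps the full tail (its partners are chain neighbours).
  for (size_t r = 0; r < S.pairs.size(); r++) {
    const PairT& p = S.pairs[r];
    double rr = dist(x, p.i, p.j, d);
    double dEdr;
    if (p.term != 2) {
      if (rr >= 2.0 * p.r0) continue;
      double dum;
      terms[p.term] += e1210(rr, p.r0, p.eps, &dEdr) -
                       e1210(2.0 * p.r0, p.r0, p.eps, &dum);
    } else {
      terms[p.term] += e1210(rr, p.r0, p.eps, &dEdr);
    }
    double c = -dEdr / std::max(rr, 1e-8);
    for (int a = 0; a < 3; a++) { f[3*p.i+a] += c*d[a]; f[3*p.j+a] -= c*d[a]; }
  }

  // Watson-Crick: E = eps * G(th1, th2) * U1210(r)
  // th1 = angle(si, bi, bj), th2 = angle(bi, bj, sj),
  // G = exp(-((th1-th10)^2 + (th2-th20)^2) / (2 sig^2))
  double gA[9], gB[9];
  for (size_t r = 0; r < S.wc.size(); r++) {
    const WCT& w = S.wc[r];
    if (w.eps <= 0.0) continue;
    double rr = dist(x, w.bi, w.bj, d);
    double dUdr;
    // flat-core pairing well: below ~0.89 r0 the energy plateaus at about
    // +eps, so re-enabling pairing on a distorted geometry (sequence revert)
    // gives a bounded push instead of a divergent core; the generic excluded
    // volume handles true overlap
    double rflat = w.r0 / 1.125;
    double U;
    if (rr < rflat) { U = e1210(rflat, w.r0, w.eps, &dUdr); dUdr = 0.0; }
    else U = e1210(rr, w.r0, w.eps, &dUdr);
    double th1 = angle_grad(x, w.si, w.bi, w.bj, gA);
    double th2 = angle_grad(x, w.bi, w.bj, w.sj, gB);
    double d1 = th1 - w.th10, d2 = th2 - w.th20;
    double G = std::exp(-(d1*d1 + d2*d2) / (2.0 * w.sig * w.sig));
    terms[3] += G * U;
    // radial part
    double c = -G * dUdr / std::max(rr, 1e-8);
    for (int a = 0; a < 3; a++) { f[3*w.bi+a] += c*d[a]; f[3*w.bj+a] -= c*d[a]; }
    // angular part: dE/dth = U * dG/dth
    double pre1 = -U * G * (-d1 / (w.sig * w.sig));  // -dE/dth1
    double pre2 = -U * G * (-d2 / (w.sig * w.sig));
    for (int a = 0; a < 3; a++) {
      f[3*w.si+a] += pre1 * gA[a];
      f[3*w.bi+a] += pre1 * gA[3+a];
      f[3*w.bj+a] += pre1 * gA[6+a];
      f[3*w.bi+a] += pre2 * gB[a];
      f[3*w.bj+a] += pre2 * gB[3+a];
      f[3*w.sj+a] += pre2 * gB[6+a];
    }
  }

  // Nonbonded: excluded volume + Debye-Hueckel, both truncated & shifted.
  double dhc2 = S.dh_cutoff * S.dh_cutoff;
  for (size_t p = 0; p < nl.pi.size(); p++) {
    int i = nl.pi[p], j = nl.pj[p];
    double rr = dist(x, i, j, d);
    double sig = S.evR[i] + S.evR[j];
    double evcut = 2.0 * sig;
    if (rr < evcut) {
      // E = eps*(sig/r)^12 - eps*(1/2)^12, capped below r = 0.55*sig by a
      // linear continuation so E(0) is finite.
      double rmin = 0.55 * sig, E, dEdr;
      double shift = S.ev_eps * std::pow(0.5, 12);
      if (rr < rmin) {
        double x12 = std::pow(sig / rmin, 12);
        E = S.ev_eps * x12 - shift;
        dEdr = -12.0 * S.ev_eps * x12 / rmin;
        E += dEdr * (rr - rmin);
      } else {
        double x12 = std::pow(sig / rr, 12);
        E = S.ev_eps * x12 - shift;
        dEdr = -12.0 * S.ev_eps * x12 / rr;
      }
      terms[6] += E;
      double c = -dEdr / std::max(rr, 1e-8);
      for (int a = 0; a < 3; a++) { f[3*i+a] += c*d[a]; f[3*j+a] -= c*d[a]; }
    }
    double qq = S.charge[i] * S.charge[j];
    if (qq != 0.0 && rr * rr < dhc2) {
      double pref = S.dh_pref * qq;
      double Ec = pref * std::exp(-S.dh_cutoff / S.dh_lambda) / S.dh_cutoff;
      double E = pref * std::exp(-rr / S.dh_lambda) / rr;
      terms[7] += E - Ec;
      double dEdr = -E * (1.0 / rr + 1.0 / S.dh_lambda);
      double c = -dEdr / rr;
      for (int a = 0; a < 3; a++) { f[3*i+a] += c*d[a]; f[3*j+a] -= c*d[a]; }
    }
  }
}

// [[Rcpp::export(name = ".cpp_energy_forces")]]
List cpp_energy_forces(NumericMatrix coords, List sys) {
  System S = unpack_system(sys);
  if (coords.nrow() != S.n) stop("coordinate/bead count mismatch");
  std::vector<double> x(3 * S.n), f(3 * S.n);
  for (int i = 0; i < S.n; i++)
    for (int a = 0; a < 3; a++) x[3*i+a] = coords(i, a);
  NList nl; nl.skin = 1e6;  // single-shot: include every pair once
  nl.build(S, x.data());
  double terms[N_TERMS];
  eval_ef(S, x.data(), nl, terms, f.data());
  NumericVector tv(N_TERMS);
  double tot = 0.0;
  for (int t = 0; t < N_TERMS; t++) { tv[t] = terms[t]; tot += terms[t]; }
  tv.attr("names") = CharacterVector::create(
    "protein_local", "dna_bonded", "dna_stack", "dna_pair",
    "go_protein", "go_protein_dna", "excluded_volume", "electrostatic");
  NumericMatrix fm(S.n, 3);
  for (int i = 0; i < S.n; i++)
    for (int a = 0; a < 3; a++) fm(i, a) = f[3*i+a];
  return List::create(_["terms"] = tv, _["total"] = tot, _["forces"] = fm);
}

// --------------------------------------------------------- integrator -------
// BAOAB Langevin splitting. temp_schedule: matrix (step, T), piecewise-linear
// in between, constant past the last knot.
static inline double sched_T(const NumericMatrix& ts, double step) {
  int m = ts.nrow();
  if (step <= ts(0, 0)) return ts(0, 1);
  for (int r = 1; r < m; r++) {
    if (step <= ts(r, 0)) {
      double w = (step - ts(r-1, 0)) / (ts(r, 0) - ts(r-1, 0));
      return ts(r-1, 1) + w * (ts(r, 1) - ts(r-1, 1));
    }
  }
  return ts(m - 1, 1);
}

// [[Rcpp::export(name = ".cpp_run_langevin")]]
List cpp_run_langevin(NumericMatrix coords, List sys, int n_steps, double dt,
                      double gamma, NumericMatrix temp_schedule, double seed,
                      int save_interval, Nullable<NumericMatrix> init_vel) {
  System S = unpack_system(sys);
  if (coords.nrow() != S.n) stop("coordinate/bead count mismatch");
  std::vector<double> x(3 * S.n), v(3 * S.n, 0.0), f(3 * S.n);
  for (int i = 0; i < S.n; i++)
    for (int a = 0; a < 3; a++) x[3*i+a] = coords(i, a);
  Xoshiro rng((uint64_t)seed);
  double T0 = sched_T(temp_schedule, 0.0);
  if (init_vel.isNotNull()) {
    NumericMatrix iv(init_vel);
    for (int i = 0; i < S.n; i++)
      for (int a = 0; a < 3; a++) v[3*i+a] = iv(i, a);
  } else if (T0 > 0.0) {
    for (int i = 0; i < S.n; i++) {
      double sd = std::sqrt(KB * T0 / S.mass[i]);
      for (int a = 0; a < 3; a++) v[3*i+a] = sd * rng.norm();
    }
  }

  NList nl; nl.skin = 4.0;
  nl.build(S, x.data());
  double terms[N_TERMS];
  eval_ef(S, x.data(), nl, terms, f.data());

  int n_save = n_steps / save_interval + 1;
  NumericVector frames(Dimension(n_save, S.n, 3));
  NumericMatrix elog(n_save, N_TERMS + 2);  // terms..., kinetic, total
  IntegerVector steps_out(n_save);
  int isave = 0;
  auto record = [&](int step) {
    double ke = 0.0, pe = 0.0;
    for (int i = 0; i < S.n; i++)
      for (int a = 0; a < 3; a++) ke += 0.5 * S.mass[i] * v[3*i+a]*v[3*i+a];
    for (int t = 0; t < N_TERMS; t++) { elog(isave, t) = terms[t]; pe += terms[t]; }
    elog(isave, N_TERMS) = ke;
    elog(isave, N_TERMS + 1) = ke + pe;
    for (int i = 0; i < S.n; i++)
      for (int a = 0; a < 3; a++) frames[isave + n_save*(i + S.n*a)] = x[3*i+a];
    steps_out[isave] = step;
    isave++;
  };
  record(0);

  for (int step = 1; step <= n_steps; step++) {
    double T = sched_T(temp_schedule, (double)step);
    double c1 = (gamma > 0.0) ? std::exp(-gamma * dt) : 1.0;
    double c2 = (gamma > 0.0) ? std::sqrt(std::max(0.0, 1.0 - c1*c1)) : 0.0;
    for (int i = 0; i < S.n; i++) {
      double im = 0.5 * dt / S.mass[i];
      for (int a = 0; a < 3; a++) v[3*i+a] += im * f[3*i+a];
    }
    for (int a = 0; a < 3 * S.n; a++) x[a] += 0.5 * dt * v[a];
    if (gamma > 0.0) {
      for (int i = 0; i < S.n; i++) {
        double sd = std::sqrt(KB * T / S.mass[i]);
        for (int a = 0; a < 3; a++)
          v[3*i+a] = c1 * v[3*i+a] + c2 * sd * rng.norm();
      }
    }
    for (int a = 0; a < 3 * S.n; a++) x[a] += 0.5 * dt * v[a];
    if (nl.stale(S, x.data())) nl.build(S, x.data());
    eval_ef(S, x.data(), nl, terms, f.data());
    for (int i = 0; i < S.n; i++) {
      double im = 0.5 * dt / S.mass[i];
      for (int a = 0; a < 3; a++) v[3*i+a] += im * f[3*i+a];
    }
    double tot = 0.0;
    for (int t = 0; t < N_TERMS; t++) tot += terms[t];
    if (!std::isfinite(tot) || std::fabs(tot) > 1e7)
      stop("energy divergence at step %d (total potential %g)", step, tot);
    if (step % save_interval == 0) record(step);
  }

  NumericMatrix vout(S.n, 3);
  for (int i = 0; i < S.n; i++)
    for (int a = 0; a < 3; a++) vout(i, a) = v[3*i+a];
  NumericMatrix xout(S.n, 3);
  for (int i = 0; i < S.n; i++)
    for (int a = 0; a < 3; a++) xout(i, a) = x[3*i+a];
  colnames(elog) = CharacterVector::create(
    "protein_local", "dna_bonded", "dna_stack", "dna_pair", "go_protein",
    "go_protein_dna", "excluded_volume", "electrostatic", "kinetic", "total");
  return List::create(_["frames"] = frames, _["energies"] = elog,
                      _["steps"] = steps_out, _["final_coords"] = xout,
                      _["final_velocities"] = vout);
}
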