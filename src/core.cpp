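// Compiled core: coarse-grained DNA + crowder energetics, Metropolis Monte
// Carlo with umbrella biasing, Brownian-dynamics propagation with interface
// predicates (for forward flux sampling), 1D toy propagators, hard-sphere
// packing and Widom insertion.
//
// Conventions: lengths in nm, time in ps, energies in units of kB*T0 with
// T0 = 300 K, temperatures in kelvin. beta(T) = (300/T) per kB*T0 unit.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <random>
using namespace Rcpp;

static const double T0 = 300.0;
static const double WCA_FACT = 1.122462048309373; // 2^(1/6)

// ---------------------------------------------------------------------------
// small vector helpers

struct V3 {
  double x, y, z;
  V3() : x(0), y(0), z(0) {}
  V3(double a, double b, double c) : x(a), y(b), z(c) {}
};
static inline V3 operator+(const V3& a, const V3& b) { return V3(a.x+b.x, a.y+b.y, a.z+b.z); }
static inline V3 operator-(const V3& a, const V3& b) { return V3(a.x-b.x, a.y-b.y, a.z-b.z); }
static inline V3 operator*(double s, const V3& a) { return V3(s*a.x, s*a.y, s*a.z); }
static inline double dot(const V3& a, const V3& b) { return a.x*b.x + a.y*b.y + a.z*b.z; }
static inline V3 cross(const V3& a, const V3& b) {
  return V3(a.y*b.z - a.z*b.y, a.z*b.x - a.x*b.z, a.x*b.y - a.y*b.x);
}
static inline double norm(const V3& a) { return std::sqrt(dot(a, a)); }
static inline V3 unit(const V3& a) { double n = norm(a); return V3(a.x/n, a.y/n, a.z/n); }

// minimum-image displacement in a cubic box of edge L
static inline V3 mindiff(const V3& a, const V3& b, double L) {
  V3 d = a - b;
  d.x -= L * std::nearbyint(d.x / L);
  d.y -= L * std::nearbyint(d.y / L);
  d.z -= L * std::nearbyint(d.z / L);
  return d;
}
static inline double mindist(const V3& a, const V3& b, double L) {
  return norm(mindiff(a, b, L));
}

// Rodrigues rotation of v about unit axis u by angle t
static inline V3 rotate_about(const V3& v, const V3& u, double t) {
  double c = std::cos(t), s = std::sin(t);
  V3 w = cross(u, v);
  double du = dot(u, v);
  return V3(v.x*c + w.x*s + u.x*du*(1-c),
            v.y*c + w.y*s + u.y*du*(1-c),
            v.z*c + w.z*s + u.z*du*(1-c));
}

// ---------------------------------------------------------------------------
// interaction parameters

struct Params {
  double d_back, d_base;
  double fene_k, fene_r0, fene_dr;
  double eps_st, a_st, d0_st, rc_st;
  double eps_hb, a_hb, d0_hb, rc_hb;
  double sig_bb, sig_bs, sig_ss, eps_exc;
  double r_site, eps_crowd;
  double bp_frac;
};

static Params read_params(const List& par) {
  Params p;
  p.d_back   = as<double>(par["d_back"]);
  p.d_base   = as<double>(par["d_base"]);
  p.fene_k   = as<double>(par["fene_k"]);
  p.fene_r0  = as<double>(par["fene_r0"]);
  p.fene_dr  = as<double>(par["fene_dr"]);
  p.eps_st   = as<double>(par["eps_st"]);
  p.a_st     = as<double>(par["a_st"]);
  p.d0_st    = as<double>(par["d0_st"]);
  p.rc_st    = as<double>(par["rc_st"]);
  p.eps_hb   = as<double>(par["eps_hb"]);
  p.a_hb     = as<double>(par["a_hb"]);
  p.d0_hb    = as<double>(par["d0_hb"]);
  p.rc_hb    = as<double>(par["rc_hb"]);
  p.sig_bb   = as<double>(par["sig_bb"]);
  p.sig_bs   = as<double>(par["sig_bs"]);
  p.sig_ss   = as<double>(par["sig_ss"]);
  p.eps_exc  = as<double>(par["eps_exc"]);
  p.r_site   = as<double>(par["r_site"]);
  p.eps_crowd= as<double>(par["eps_crowd"]);
  p.bp_frac  = as<double>(par["bp_frac"]);
  return p;
}

// WCA: purely repulsive truncated-and-shifted LJ; 0 beyond 2^(1/6) sigma.
static inline double wca(double d, double sig, double eps) {
  if (d >= sig * WCA_FACT) return 0.0;
  double s2 = (sig / d) * (sig / d);
  double s6 = s2 * s2 * s2;
  return 4.0 * eps * (s6 * s6 - s6) + eps;
}

// Morse well truncated at rc, shifted and renormalized so the minimum is
// exactly -eps at d0 and the potential is 0 at rc (continuous).
static inline double morse_well(double d, double eps, double a, double d0, double rc) {
  if (d >= rc) return 0.0;
  double m  = std::pow(1.0 - std::exp(-a * (d  - d0)), 2) - 1.0;
  double mc = std::pow(1.0 - std::exp(-a * (rc - d0)), 2) - 1.0;
  return eps * (m - mc) / (1.0 + mc);
}

// FENE; returns +Inf on overstretch
static inline double fene(double d, const Params& p) {
  double arg = (d - p.fene_r0) / p.fene_dr;
  if (std::fabs(arg) >= 1.0) return R_PosInf;
  return -0.5 * p.fene_k * p.fene_dr * p.fene_dr * std::log(1.0 - arg * arg);
}

// ---------------------------------------------------------------------------
// system state

struct Sys {
  int n;                    // nucleotides
  int nc;                   // crowders
  double L;                 // box edge
  double rc;                // crowder radius
  std::vector<V3> pos, e1, e3;
  std::vector<V3> cpos;
  std::vector<int> strand;  // 1-based strand id
  std::vector<int> prev5, next3; // 0-based intra-strand neighbours, -1 none
  std::vector<std::pair<int,int> > pairs; // native pairs (0-based)
  std::vector<std::vector<int> > pair_of; // pair rows touching nucleotide i
};

static std::vector<V3> mat_to_v3(const NumericMatrix& m) {
  std::vector<V3> v(m.nrow());
  for (int i = 0; i < m.nrow(); ++i) v[i] = V3(m(i,0), m(i,1), m(i,2));
  return v;
}
static NumericMatrix v3_to_mat(const std::vector<V3>& v) {
  NumericMatrix m(v.size(), 3);
  for (size_t i = 0; i < v.size(); ++i) { m(i,0)=v[i].x; m(i,1)=v[i].y; m(i,2)=v[i].z; }
  return m;
}

static Sys read_sys(const List& sys) {
  Sys s;
  NumericMatrix pos = sys["pos"];
  s.n = pos.nrow();
  s.pos = mat_to_v3(pos);
  s.e1  = mat_to_v3(as<NumericMatrix>(sys["e1"]));
  s.e3  = mat_to_v3(as<NumericMatrix>(sys["e3"]));
  NumericMatrix cp = sys["cpos"];
  s.nc = cp.nrow();
  s.cpos = mat_to_v3(cp);
  s.L  = as<double>(sys["L"]);
  s.rc = as<double>(sys["rc"]);
  IntegerVector st = sys["strand"], pr = sys["prev"], nx = sys["next"];
  s.strand.assign(st.begin(), st.end());
  s.prev5.assign(pr.begin(), pr.end());
  s.next3.assign(nx.begin(), nx.end());
  IntegerMatrix pm = sys["pairs"];
  s.pairs.resize(pm.nrow());
  s.pair_of.assign(s.n, std::vector<int>());
  for (int k = 0; k < pm.nrow(); ++k) {
    s.pairs[k] = std::make_pair(pm(k,0), pm(k,1));
    s.pair_of[pm(k,0)].push_back(k);
    s.pair_of[pm(k,1)].push_back(k);
  }
  return s;
}

static List write_sys(const Sys& s, const List& templ) {
  List out = clone(templ);
  out["pos"]  = v3_to_mat(s.pos);
  out["e1"]   = v3_to_mat(s.e1);
  out["e3"]   = v3_to_mat(s.e3);
  out["cpos"] = v3_to_mat(s.cpos);
  return out;
}

static inline V3 back_site(const Sys& s, const Params& p, int i) {
  return s.pos[i] - p.d_back * s.e1[i];
}
static inline V3 base_site(const Sys& s, const Params& p, int i) {
  return s.pos[i] + p.d_base * s.e1[i];
}

static inline bool is_native(const Sys& s, int i, int j) {
  for (size_t k = 0; k < s.pair_of[i].size(); ++k) {
    int r = s.pair_of[i][k];
    if (s.pairs[r].first == j || s.pairs[r].second == j) return true;
  }
  return false;
}

// hydrogen-bond energy of native pair row k: Morse well x squared-cosine
// angular modulation on the base normals (anti-aligned normals pair best)
static inline double hb_energy(const Sys& s, const Params& p, int k) {
  int i = s.pairs[k].first, j = s.pairs[k].second;
  double d = mindist(base_site(s, p, i), base_site(s, p, j), s.L);
  if (d >= p.rc_hb) return 0.0;
  double a3 = -dot(s.e3[i], s.e3[j]); if (a3 < 0) return 0.0;
  return morse_well(d, p.eps_hb, p.a_hb, p.d0_hb, p.rc_hb) * a3 * a3;
}

// stacking between consecutive nucleotides i and its 3' neighbour j
static inline double stack_energy(const Sys& s, const Params& p, int i, int j) {
  double d = mindist(base_site(s, p, i), base_site(s, p, j), s.L);
  if (d >= p.rc_st) return 0.0;
  double a3 = dot(s.e3[i], s.e3[j]);
  return morse_well(d, p.eps_st, p.a_st, p.d0_st, p.rc_st) * a3 * a3;
}

// site-site excluded volume between distinct nucleotides i<j.
// Exclusions: backbone-backbone for FENE-bonded neighbours (the FENE term
// handles that separation); base-base for native pairs (the HB Morse core
// handles it).
static inline double excl_energy(const Sys& s, const Params& p, int i, int j) {
  bool bonded = (s.next3[i] == j || s.prev5[i] == j);
  bool native = is_native(s, i, j);
  V3 bi = back_site(s, p, i), qi = base_site(s, p, i);
  V3 bj = back_site(s, p, j), qj = base_site(s, p, j);
  double e = 0.0;
  if (!bonded) e += wca(mindist(bi, bj, s.L), p.sig_bb, p.eps_exc);
  e += wca(mindist(bi, qj, s.L), p.sig_bs, p.eps_exc);
  e += wca(mindist(qi, bj, s.L), p.sig_bs, p.eps_exc);
  if (!native) e += wca(mindist(qi, qj, s.L), p.sig_ss, p.eps_exc);
  return e;
}

// crowder-nucleotide excluded volume (both sites)
static inline double crowder_site_energy(const Sys& s, const Params& p, int c, int i) {
  double sig = s.rc + p.r_site;
  double e = wca(mindist(s.cpos[c], back_site(s, p, i), s.L), sig, p.eps_crowd);
  e += wca(mindist(s.cpos[c], base_site(s, p, i), s.L), sig, p.eps_crowd);
  return e;
}

struct EnergyTerms {
  double fene, stack, hb, excl, crowd;
  bool overstretch;
  double total() const { return fene + stack + hb + excl + crowd; }
};

static EnergyTerms total_energy(const Sys& s, const Params& p) {
  EnergyTerms t; t.fene = t.stack = t.hb = t.excl = t.crowd = 0.0; t.overstretch = false;
  for (int i = 0; i < s.n; ++i) {
    int j = s.next3[i];
    if (j >= 0) {
      double df = mindist(back_site(s, p, i), back_site(s, p, j), s.L);
      double vf = fene(df, p);
      if (!R_FINITE(vf)) t.overstretch = true;
      t.fene += vf;
      t.stack += stack_energy(s, p, i, j);
    }
  }
  for (size_t k = 0; k < s.pairs.size(); ++k) t.hb += hb_energy(s, p, (int)k);
  for (int i = 0; i < s.n; ++i)
    for (int j = i + 1; j < s.n; ++j)
      t.excl += excl_energy(s, p, i, j);
  for (int c = 0; c < s.nc; ++c) {
    for (int i = 0; i < s.n; ++i) t.crowd += crowder_site_energy(s, p, c, i);
    for (int c2 = c + 1; c2 < s.nc; ++c2)
      t.crowd += wca(mindist(s.cpos[c], s.cpos[c2], s.L), 2.0 * s.rc, p.eps_crowd);
  }
  return t;
}

// [[Rcpp::export]]
List cpp_energy(List sys, List par) {
  Sys s = read_sys(sys);
  Params p = read_params(par);
  EnergyTerms t = total_energy(s, p);
  return List::create(_["total"] = t.total(), _["fene"] = t.fene,
                      _["stacking"] = t.stack, _["hbond"] = t.hb,
                      _["excluded"] = t.excl, _["crowder"] = t.crowd,
                      _["overstretch"] = t.overstretch);
}

// [[Rcpp::export]]
NumericVector cpp_hb_pair_energies(List sys, List par) {
  Sys s = read_sys(sys);
  Params p = read_params(par);
  NumericVector out(s.pairs.size());
  for (size_t k = 0; k < s.pairs.size(); ++k) out[k] = hb_energy(s, p, (int)k);
  return out;
}

static int count_bp(const Sys& s, const Params& p, const std::vector<int>& subset) {
  int n = 0;
  double thr = -p.bp_frac * p.eps_hb;
  for (size_t u = 0; u < subset.size(); ++u)
    if (hb_energy(s, p, subset[u]) < thr) ++n;
  return n;
}

static double min_dist_subset(const Sys& s, const Params& p, const std::vector<int>& subset) {
  double dm = R_PosInf;
  for (size_t u = 0; u < subset.size(); ++u) {
    int k = subset[u];
    double d = mindist(base_site(s, p, s.pairs[k].first),
                       base_site(s, p, s.pairs[k].second), s.L);
    if (d < dm) dm = d;
  }
  return dm;
}

static std::vector<int> all_rows(const Sys& s) {
  std::vector<int> v(s.pairs.size());
  for (size_t k = 0; k < v.size(); ++k) v[k] = (int)k;
  return v;
}

// [[Rcpp::export]]
int cpp_count_bp(List sys, List par) {
  Sys s = read_sys(sys);
  Params p = read_params(par);
  return count_bp(s, p, all_rows(s));
}

// [[Rcpp::export]]
double cpp_min_dist(List sys, List par, IntegerVector subset) {
  Sys s = read_sys(sys);
  Params p = read_params(par);
  std::vector<int> sub(subset.begin(), subset.end());
  return min_dist_subset(s, p, sub);
}

// ---------------------------------------------------------------------------
// local energies for Monte Carlo moves

// all interactions of nucleotide i with everything else (FENE+stack to
// neighbours, HB to native partners, excluded volume, crowders)
static double local_energy_nt(const Sys& s, const Params& p, int i, bool& over) {
  double e = 0.0;
  int jn = s.next3[i], jp = s.prev5[i];
  if (jn >= 0) {
    double vf = fene(mindist(back_site(s,p,i), back_site(s,p,jn), s.L), p);
    if (!R_FINITE(vf)) over = true;
    e += vf + stack_energy(s, p, i, jn);
  }
  if (jp >= 0) {
    double vf = fene(mindist(back_site(s,p,jp), back_site(s,p,i), s.L), p);
    if (!R_FINITE(vf)) over = true;
    e += vf + stack_energy(s, p, jp, i);
  }
  for (size_t u = 0; u < s.pair_of[i].size(); ++u) e += hb_energy(s, p, s.pair_of[i][u]);
  for (int j = 0; j < s.n; ++j) if (j != i) e += excl_energy(s, p, std::min(i,j), std::max(i,j));
  for (int c = 0; c < s.nc; ++c) e += crowder_site_energy(s, p, c, i);
  return e;
}

// interactions of a nucleotide set (membership flags) with the rest of the
// system, plus the set's internal non-bonded terms. Internal non-bonded
// terms must be included even for rigid moves: under periodic boundaries an
// extended chain can interact with its own image, and a rigid rotation
// changes those image distances. Bonded (FENE/stacking) terms between two
// set members are genuinely invariant (always within half a box) and are
// skipped.
static double local_energy_set(const Sys& s, const Params& p,
                               const std::vector<char>& in, bool& over) {
  double e = 0.0;
  for (int i = 0; i < s.n; ++i) {
    if (!in[i]) continue;
    int jn = s.next3[i], jp = s.prev5[i];
    if (jn >= 0 && !in[jn]) {
      double vf = fene(mindist(back_site(s,p,i), back_site(s,p,jn), s.L), p);
      if (!R_FINITE(vf)) over = true;
      e += vf + stack_energy(s, p, i, jn);
    }
    if (jp >= 0 && !in[jp]) {
      double vf = fene(mindist(back_site(s,p,jp), back_site(s,p,i), s.L), p);
      if (!R_FINITE(vf)) over = true;
      e += vf + stack_energy(s, p, jp, i);
    }
    for (size_t u = 0; u < s.pair_of[i].size(); ++u) {
      int k = s.pair_of[i][u];
      int j = (s.pairs[k].first == i) ? s.pairs[k].second : s.pairs[k].first;
      if (!in[j] || s.pairs[k].first == i) e += hb_energy(s, p, k);
    }
    for (int j = 0; j < s.n; ++j) {
      if (j == i) continue;
      if (!in[j] || j > i) e += excl_energy(s, p, std::min(i,j), std::max(i,j));
    }
    for (int c = 0; c < s.nc; ++c) e += crowder_site_energy(s, p, c, i);
  }
  return e;
}

static double local_energy_crowder(const Sys& s, const Params& p, int c) {
  double e = 0.0;
  for (int i = 0; i < s.n; ++i) e += crowder_site_energy(s, p, c, i);
  for (int c2 = 0; c2 < s.nc; ++c2)
    if (c2 != c) e += wca(mindist(s.cpos[c], s.cpos[c2], s.L), 2.0 * s.rc, p.eps_crowd);
  return e;
}

static inline V3 wrap(const V3& a, double L) {
  V3 r = a;
  r.x -= L * std::floor(r.x / L);
  r.y -= L * std::floor(r.y / L);
  r.z -= L * std::floor(r.z / L);
  return r;
}

static inline V3 rand_unit(std::mt19937_64& rng) {
  std::normal_distribution<double> g(0.0, 1.0);
  V3 v(g(rng), g(rng), g(rng));
  return unit(v);
}

// re-orthonormalize an orientation frame (guards against numerical drift)
static inline void fix_frame(V3& e1, V3& e3) {
  e1 = unit(e1);
  e3 = e3 - dot(e3, e1) * e1;
  e3 = unit(e3);
}

// ---------------------------------------------------------------------------
// Monte Carlo sampler with umbrella biasing on n_bp.
// Move set: single-nucleotide translation+rotation, crowder translation,
// rigid whole-strand translation+rotation (symmetric proposals).

// [[Rcpp::export]]
List cpp_run_mc(List sys, List par, double T, NumericVector weights,
                int n_sweeps, int sample_every, int seed,
                double dx_nt = 0.12, double dang_nt = 0.25,
                double dx_c = 0.25, double dx_s = 0.20, double dang_s = 0.15,
                int recompute_every = 500, int ree_strand = 0,
                double wl_f = 0.0, double dang_p = 0.60,
                int win_lo = -1, int win_hi = -1) {
  Sys s = read_sys(sys);
  Params p = read_params(par);
  double beta = T0 / T;
  std::mt19937_64 rng(seed);
  std::uniform_real_distribution<double> U(0.0, 1.0);

  int n_strands = 0;
  for (int i = 0; i < s.n; ++i) n_strands = std::max(n_strands, s.strand[i]);

  int npairs = (int)s.pairs.size();
  if (weights.size() != npairs + 1) stop("umbrella weights must have length n_pairs + 1");
  std::vector<double> lnw(npairs + 1);
  for (int k = 0; k <= npairs; ++k) {
    if (weights[k] <= 0) stop("umbrella weights must be positive");
    lnw[k] = std::log(weights[k]);
  }

  std::vector<int> rows = all_rows(s);
  double thr = -p.bp_frac * p.eps_hb;
  std::vector<double> hbE(npairs);
  int nbp = 0;
  for (int k = 0; k < npairs; ++k) {
    hbE[k] = hb_energy(s, p, k);
    if (hbE[k] < thr) ++nbp;
  }
  EnergyTerms t0 = total_energy(s, p);
  if (t0.overstretch) stop("initial configuration is overstretched");
  double E = t0.total();
  // optional hard window on n_bp (overlapping-window free-energy estimator)
  bool windowed = (win_lo >= 0);
  if (windowed && (nbp < win_lo || nbp > win_hi))
    stop("initial configuration outside the n_bp window");

  // move pool: single-nucleotide, crowder, rigid-strand, and pivot moves
  int n_mobile = 2 * s.n + s.nc + n_strands;
  std::vector<double> wl_hist(npairs + 1, 0.0);
  long acc = 0, att = 0;
  int n_samples = n_sweeps / sample_every;
  NumericMatrix samples(n_samples, 6); // sweep, nbp, dmin, E, weight, ree
  std::vector<double> hist(npairs + 1, 0.0);
  int si = 0;
  // terminal nucleotides of the strand whose end-to-end distance is recorded
  int ree_a = -1, ree_b = -1;
  if (ree_strand > 0) {
    for (int i = 0; i < s.n; ++i) if (s.strand[i] == ree_strand) {
      if (ree_a < 0) ree_a = i;
      ree_b = i;
    }
  }

  for (int sweep = 1; sweep <= n_sweeps; ++sweep) {
    for (int m = 0; m < n_mobile; ++m) {
      int pick = (int)(U(rng) * n_mobile);
      if (pick >= n_mobile) pick = n_mobile - 1;
      ++att;
      if (pick < s.n) {
        // single nucleotide translate + rotate
        int i = pick;
        bool over_old = false, over_new = false;
        double e_old = local_energy_nt(s, p, i, over_old);
        V3 old_pos = s.pos[i], old_e1 = s.e1[i], old_e3 = s.e3[i];
        s.pos[i] = wrap(s.pos[i] + V3((2*U(rng)-1)*dx_nt, (2*U(rng)-1)*dx_nt, (2*U(rng)-1)*dx_nt), s.L);
        V3 ax = rand_unit(rng);
        double ang = (2*U(rng)-1) * dang_nt;
        s.e1[i] = rotate_about(s.e1[i], ax, ang);
        s.e3[i] = rotate_about(s.e3[i], ax, ang);
        fix_frame(s.e1[i], s.e3[i]);
        double e_new = local_energy_nt(s, p, i, over_new);
        // n_bp change from this nucleotide's native pairs
        int dn = 0;
        std::vector<double> newhb(s.pair_of[i].size());
        for (size_t u = 0; u < s.pair_of[i].size(); ++u) {
          int k = s.pair_of[i][u];
          newhb[u] = hb_energy(s, p, k);
          dn += (newhb[u] < thr) - (hbE[k] < thr);
        }
        double dE = e_new - e_old;
        double lacc = -beta * dE + lnw[nbp + dn] - lnw[nbp];
        bool ok = !over_new && R_FINITE(dE) &&
          (!windowed || (nbp + dn >= win_lo && nbp + dn <= win_hi)) &&
          (lacc >= 0 || std::log(U(rng)) < lacc);
        if (ok) {
          for (size_t u = 0; u < s.pair_of[i].size(); ++u) hbE[s.pair_of[i][u]] = newhb[u];
          nbp += dn; E += dE; ++acc;
        } else {
          s.pos[i] = old_pos; s.e1[i] = old_e1; s.e3[i] = old_e3;
        }
      } else if (pick < s.n + s.nc) {
        // crowder translation (does not change n_bp)
        int c = pick - s.n;
        double e_old = local_energy_crowder(s, p, c);
        V3 old_pos = s.cpos[c];
        s.cpos[c] = wrap(s.cpos[c] + V3((2*U(rng)-1)*dx_c, (2*U(rng)-1)*dx_c, (2*U(rng)-1)*dx_c), s.L);
        double dE = local_energy_crowder(s, p, c) - e_old;
        if (dE <= 0 || U(rng) < std::exp(-beta * dE)) { E += dE; ++acc; }
        else s.cpos[c] = old_pos;
      } else if (pick < s.n + s.nc + n_strands) {
        // rigid whole-strand translation + rotation about its centroid
        int sid = pick - s.n - s.nc + 1;
        std::vector<char> in(s.n, 0);
        for (int i = 0; i < s.n; ++i) if (s.strand[i] == sid) in[i] = 1;
        bool over_old = false, over_new = false;
        double e_old = local_energy_set(s, p, in, over_old);
        std::vector<V3> old_pos = s.pos, old_e1 = s.e1, old_e3 = s.e3;
        // unwrap the strand along its backbone so the rigid move cannot be
        // corrupted by periodic images (strands may span more than L/2)
        int head = -1;
        for (int i = 0; i < s.n; ++i)
          if (s.strand[i] == sid && s.prev5[i] < 0) { head = i; break; }
        std::vector<int> chain;
        std::vector<V3> unw;
        for (int i = head; i >= 0; i = s.next3[i]) {
          if (chain.empty()) unw.push_back(s.pos[i]);
          else unw.push_back(unw.back() + mindiff(s.pos[i], s.pos[chain.back()], s.L));
          chain.push_back(i);
        }
        V3 cen(0,0,0);
        for (size_t u = 0; u < unw.size(); ++u) cen = cen + unw[u];
        cen = (1.0 / unw.size()) * cen;
        V3 tr((2*U(rng)-1)*dx_s, (2*U(rng)-1)*dx_s, (2*U(rng)-1)*dx_s);
        V3 ax = rand_unit(rng);
        double ang = (2*U(rng)-1) * dang_s;
        for (size_t u = 0; u < chain.size(); ++u) {
          int i = chain[u];
          s.pos[i] = wrap(cen + rotate_about(unw[u] - cen, ax, ang) + tr, s.L);
          s.e1[i] = rotate_about(s.e1[i], ax, ang);
          s.e3[i] = rotate_about(s.e3[i], ax, ang);
          fix_frame(s.e1[i], s.e3[i]);
        }
        double dE = local_energy_set(s, p, in, over_new) - e_old;
        int dn = 0;
        std::vector<double> newhb(npairs);
        for (int k = 0; k < npairs; ++k) {
          int a = s.pairs[k].first, b = s.pairs[k].second;
          if (in[a] || in[b]) {
            newhb[k] = hb_energy(s, p, k);
            dn += (newhb[k] < thr) - (hbE[k] < thr);
          } else newhb[k] = hbE[k];
        }
        double lacc = -beta * dE + lnw[nbp + dn] - lnw[nbp];
        if (!over_new && R_FINITE(dE) &&
            (!windowed || (nbp + dn >= win_lo && nbp + dn <= win_hi)) &&
            (lacc >= 0 || std::log(U(rng)) < lacc)) {
          hbE = newhb; nbp += dn; E += dE; ++acc;
        } else {
          s.pos = old_pos; s.e1 = old_e1; s.e3 = old_e3;
        }
      } else {
        // pivot move: rotate the chain segment on one side of a nucleotide
        // rigidly about that nucleotide's backbone site (symmetric proposal;
        // accelerates zipping, fraying and bubble closure)
        int i = pick - s.n - s.nc - n_strands;
        bool side3 = U(rng) < 0.5;
        std::vector<int> seg;
        for (int j = side3 ? s.next3[i] : s.prev5[i]; j >= 0;
             j = side3 ? s.next3[j] : s.prev5[j]) seg.push_back(j);
        if (seg.empty()) continue;
        std::vector<char> in(s.n, 0);
        for (size_t u = 0; u < seg.size(); ++u) in[seg[u]] = 1;
        bool over_old = false, over_new = false;
        double e_old = local_energy_set(s, p, in, over_old);
        std::vector<V3> old_pos = s.pos, old_e1 = s.e1, old_e3 = s.e3;
        // unwrap the segment along the chain starting from the pivot
        V3 piv = back_site(s, p, i);
        std::vector<V3> unw(seg.size());
        V3 prev_wrapped = s.pos[i], prev_unw = s.pos[i];
        for (size_t u = 0; u < seg.size(); ++u) {
          prev_unw = prev_unw + mindiff(s.pos[seg[u]], prev_wrapped, s.L);
          prev_wrapped = s.pos[seg[u]];
          unw[u] = prev_unw;
        }
        V3 ax = rand_unit(rng);
        double ang = (2*U(rng)-1) * dang_p;
        for (size_t u = 0; u < seg.size(); ++u) {
          int j = seg[u];
          s.pos[j] = wrap(piv + rotate_about(unw[u] - piv, ax, ang), s.L);
          s.e1[j] = rotate_about(s.e1[j], ax, ang);
          s.e3[j] = rotate_about(s.e3[j], ax, ang);
          fix_frame(s.e1[j], s.e3[j]);
        }
        double dE = local_energy_set(s, p, in, over_new) - e_old;
        int dn = 0;
        std::vector<double> newhb(npairs);
        for (int k = 0; k < npairs; ++k) {
          int a = s.pairs[k].first, b = s.pairs[k].second;
          if (in[a] || in[b]) {
            newhb[k] = hb_energy(s, p, k);
            dn += (newhb[k] < thr) - (hbE[k] < thr);
          } else newhb[k] = hbE[k];
        }
        double lacc = -beta * dE + lnw[nbp + dn] - lnw[nbp];
        if (!over_new && R_FINITE(dE) &&
            (!windowed || (nbp + dn >= win_lo && nbp + dn <= win_hi)) &&
            (lacc >= 0 || std::log(U(rng)) < lacc)) {
          hbE = newhb; nbp += dn; E += dE; ++acc;
        } else {
          s.pos = old_pos; s.e1 = old_e1; s.e3 = old_e3;
        }
      }
    }
    hist[nbp] += 1.0;
    // Wang-Landau refinement (adaptation only; production uses frozen
    // weights, wl_f = 0): penalise the visited state, and halve the
    // refinement amplitude whenever the stage histogram is roughly flat
    if (wl_f > 0) {
      lnw[nbp] -= wl_f;
      wl_hist[nbp] += 1.0;
      if (sweep % 500 == 0) {
        double mn = wl_hist[0], mean = 0;
        for (int k = 0; k <= npairs; ++k) { mn = std::min(mn, wl_hist[k]); mean += wl_hist[k]; }
        mean /= (npairs + 1);
        if (mn > 0.7 * mean) {
          wl_f *= 0.5;
          std::fill(wl_hist.begin(), wl_hist.end(), 0.0);
        }
      }
    }
    if (sweep % recompute_every == 0) {
      EnergyTerms tt = total_energy(s, p);
      E = tt.total();
    }
    if (sweep % sample_every == 0 && si < n_samples) {
      samples(si, 0) = sweep;
      samples(si, 1) = nbp;
      samples(si, 2) = s.pairs.empty() ? NA_REAL : min_dist_subset(s, p, rows);
      samples(si, 3) = E;
      samples(si, 4) = weights[nbp];
      samples(si, 5) = (ree_a >= 0) ?
        mindist(base_site(s, p, ree_a), base_site(s, p, ree_b), s.L) : NA_REAL;
      ++si;
    }
  }

  NumericVector wout(npairs + 1);
  double lmax = lnw[0];
  for (int k = 1; k <= npairs; ++k) lmax = std::max(lmax, lnw[k]);
  for (int k = 0; k <= npairs; ++k) wout[k] = std::exp(lnw[k] - lmax);
  return List::create(_["samples"] = samples,
                      _["final"] = write_sys(s, sys),
                      _["acceptance"] = (double)acc / (double)att,
                      _["hist"] = NumericVector(hist.begin(), hist.end()),
                      _["weights_out"] = wout);
}

// ---------------------------------------------------------------------------
// interface predicates (clause lists) for FFS / stopping conditions

struct Clause {
  int metric;  // 0 = d_min, 1 = n_bp
  int op;      // 0 = <=, 1 = >=, 2 = ==
  double value;
  std::vector<int> subset; // native-pair rows
};

static std::vector<Clause> read_clauses(const List& pred) {
  std::vector<Clause> cs;
  for (int k = 0; k < pred.size(); ++k) {
    List cl = pred[k];
    Clause c;
    c.metric = as<int>(cl["metric"]);
    c.op     = as<int>(cl["op"]);
    c.value  = as<double>(cl["value"]);
    IntegerVector sub = cl["subset"];
    c.subset.assign(sub.begin(), sub.end());
    cs.push_back(c);
  }
  return cs;
}

static bool eval_clauses(const Sys& s, const Params& p, const std::vector<Clause>& cs) {
  for (size_t k = 0; k < cs.size(); ++k) {
    const Clause& c = cs[k];
    double v = (c.metric == 0) ? min_dist_subset(s, p, c.subset)
                               : (double)count_bp(s, p, c.subset);
    bool ok = (c.op == 0) ? (v <= c.value) : (c.op == 1) ? (v >= c.value)
                          : (std::fabs(v - c.value) < 0.5);
    if (!ok) return false;
  }
  return true;
}

// ---------------------------------------------------------------------------
// Brownian-dynamics propagation: Gaussian free-diffusion trial displacements
// (variance 2 D dt per axis; rotations with variance 4 D_rot dt about a
// random axis) filtered by a Metropolis acceptance on the potential energy.
// Exactly Boltzmann-stationary; converges to overdamped Langevin as dt -> 0.

struct BDOpts {
  double T, dt, D_nt, D_c, D_rot;
  int seed;
};

// one BD step over all mobile entities; returns accepted-move count
static int bd_step(Sys& s, const Params& p, const BDOpts& o,
                   std::mt19937_64& rng, double beta,
                   std::vector<V3>& unwrapped_nt, std::vector<V3>& unwrapped_c) {
  std::normal_distribution<double> G(0.0, 1.0);
  std::uniform_real_distribution<double> U(0.0, 1.0);
  double sd_nt = std::sqrt(2.0 * o.D_nt * o.dt);
  double sd_c  = std::sqrt(2.0 * o.D_c  * o.dt);
  double sd_rot = std::sqrt(4.0 * o.D_rot * o.dt);
  int acc = 0;
  for (int i = 0; i < s.n; ++i) {
    bool ov_old = false, ov_new = false;
    double e_old = local_energy_nt(s, p, i, ov_old);
    V3 old_pos = s.pos[i], old_e1 = s.e1[i], old_e3 = s.e3[i];
    V3 step(sd_nt * G(rng), sd_nt * G(rng), sd_nt * G(rng));
    s.pos[i] = wrap(s.pos[i] + step, s.L);
    V3 ax = rand_unit(rng);
    double ang = sd_rot * G(rng);
    s.e1[i] = rotate_about(s.e1[i], ax, ang);
    s.e3[i] = rotate_about(s.e3[i], ax, ang);
    fix_frame(s.e1[i], s.e3[i]);
    double dE = local_energy_nt(s, p, i, ov_new) - e_old;
    if (!ov_new && R_FINITE(dE) && (dE <= 0 || U(rng) < std::exp(-beta * dE))) {
      unwrapped_nt[i] = unwrapped_nt[i] + step;
      ++acc;
    } else {
      s.pos[i] = old_pos; s.e1[i] = old_e1; s.e3[i] = old_e3;
    }
  }
  for (int c = 0; c < s.nc; ++c) {
    double e_old = local_energy_crowder(s, p, c);
    V3 old_pos = s.cpos[c];
    V3 step(sd_c * G(rng), sd_c * G(rng), sd_c * G(rng));
    s.cpos[c] = wrap(s.cpos[c] + step, s.L);
    double dE = local_energy_crowder(s, p, c) - e_old;
    if (dE <= 0 || U(rng) < std::exp(-beta * dE)) {
      unwrapped_c[c] = unwrapped_c[c] + step;
      ++acc;
    } else s.cpos[c] = old_pos;
  }
  return acc;
}

// General BD runner. Optional stop predicates stopA (success) / stopB (fail)
// are checked every check_every steps; status 0 = exhausted steps, 1 = A,
// 2 = B. Records order-parameter samples and unwrapped tracks for MSD.
// [[Rcpp::export]]
List cpp_run_bd(List sys, List par, double T, double D_nt, double D_c,
                double D_rot, double dt, int n_steps, int sample_every,
                int seed, Nullable<List> stopA = R_NilValue,
                Nullable<List> stopB = R_NilValue, int check_every = 10,
                int track_strand = 0, int track_crowder = 0) {
  Sys s = read_sys(sys);
  Params p = read_params(par);
  BDOpts o; o.T = T; o.dt = dt; o.D_nt = D_nt; o.D_c = D_c; o.D_rot = D_rot; o.seed = seed;
  double beta = T0 / T;
  std::mt19937_64 rng(seed);
  std::vector<Clause> A, B;
  bool haveA = false, haveB = false;
  if (stopA.isNotNull()) { A = read_clauses(stopA.get()); haveA = true; }
  if (stopB.isNotNull()) { B = read_clauses(stopB.get()); haveB = true; }

  std::vector<V3> unw_nt(s.n, V3()), unw_c(s.nc, V3());
  std::vector<int> rows = all_rows(s);

  int max_samp = (sample_every > 0) ? n_steps / sample_every + 1 : 0;
  NumericMatrix samples(max_samp, 4);
  // strand-COM and crowder displacement tracks (unwrapped)
  int track_n = max_samp;
  NumericMatrix com_track(track_strand > 0 ? track_n : 0, 3);
  NumericMatrix crw_track(track_crowder > 0 ? track_n : 0, 3);
  int si = 0;
  long acc = 0;
  int status = 0, steps_done = 0;

  for (int step = 1; step <= n_steps; ++step) {
    acc += bd_step(s, p, o, rng, beta, unw_nt, unw_c);
    steps_done = step;
    if (sample_every > 0 && step % sample_every == 0 && si < max_samp) {
      samples(si, 0) = step * dt;
      samples(si, 1) = s.pairs.empty() ? 0 : count_bp(s, p, rows);
      samples(si, 2) = s.pairs.empty() ? NA_REAL : min_dist_subset(s, p, rows);
      samples(si, 3) = total_energy(s, p).total();
      if (track_strand > 0) {
        V3 com(0,0,0); int cnt = 0;
        for (int i = 0; i < s.n; ++i) if (s.strand[i] == track_strand) { com = com + unw_nt[i]; ++cnt; }
        com_track(si,0) = com.x/cnt; com_track(si,1) = com.y/cnt; com_track(si,2) = com.z/cnt;
      }
      if (track_crowder > 0) {
        V3 u = unw_c[track_crowder - 1];
        crw_track(si,0) = u.x; crw_track(si,1) = u.y; crw_track(si,2) = u.z;
      }
      ++si;
    }
    if ((haveA || haveB) && step % check_every == 0) {
      if (haveA && eval_clauses(s, p, A)) { status = 1; break; }
      if (haveB && eval_clauses(s, p, B)) { status = 2; break; }
    }
  }

  return List::create(_["status"] = status, _["steps"] = steps_done,
                      _["time"] = steps_done * dt,
                      _["samples"] = samples(Range(0, std::max(si - 1, 0)), _),
                      _["n_samples"] = si,
                      _["com_track"] = com_track, _["crowder_track"] = crw_track,
                      _["acceptance"] = (double)acc / ((double)steps_done * (s.n + s.nc)),
                      _["final"] = write_sys(s, sys));
}

// Initial-flux runner: counts effective positive crossings of lambda0 from
// the basin side. A crossing is counted only if the trajectory visited the
// basin (lambda_fail region) since the previous crossing. Returns stored
// crossing configurations.
// [[Rcpp::export]]
List cpp_ffs_flux(List sys, List par, double T, double D_nt, double D_c,
                  double D_rot, double dt, int n_steps_max, int check_every,
                  int target_crossings, List lambda0, List basin, int seed) {
  Sys s = read_sys(sys);
  Params p = read_params(par);
  BDOpts o; o.T = T; o.dt = dt; o.D_nt = D_nt; o.D_c = D_c; o.D_rot = D_rot; o.seed = seed;
  double beta = T0 / T;
  std::mt19937_64 rng(seed);
  std::vector<Clause> L0 = read_clauses(lambda0);
  std::vector<Clause> BA = read_clauses(basin);
  std::vector<V3> unw_nt(s.n, V3()), unw_c(s.nc, V3());

  bool armed = eval_clauses(s, p, BA); // start should be in the basin
  long basin_steps = 0;
  int n_cross = 0;
  std::vector<double> cross_times;
  List configs;
  int steps_done = 0;

  for (int step = 1; step <= n_steps_max; ++step) {
    bd_step(s, p, o, rng, beta, unw_nt, unw_c);
    steps_done = step;
    bool at0 = false;
    if (step % check_every == 0) {
      at0 = eval_clauses(s, p, L0);
      if (!at0) {
        basin_steps += check_every;
        if (!armed && eval_clauses(s, p, BA)) armed = true;
      } else if (armed) {
        ++n_cross;
        cross_times.push_back(step * dt);
        configs.push_back(write_sys(s, sys));
        armed = false;
        if (target_crossings > 0 && n_cross >= target_crossings) break;
      }
    }
  }

  return List::create(_["n_crossings"] = n_cross,
                      _["basin_time"] = basin_steps * dt,
                      _["total_time"] = steps_done * dt,
                      _["cross_times"] = NumericVector(cross_times.begin(), cross_times.end()),
                      _["configs"] = configs);
}

// ---------------------------------------------------------------------------
// toy Markov chain on K discrete states (for sampler correctness oracles)

// [[Rcpp::export]]
List cpp_mc_toy(NumericVector energies, NumericVector weights, double beta,
                int n_sweeps, int seed, int n_keep = 0) {
  int K = energies.size();
  if (weights.size() != K) stop("weights length mismatch");
  std::mt19937_64 rng(seed);
  std::uniform_real_distribution<double> U(0.0, 1.0);
  std::vector<double> lnw(K);
  for (int k = 0; k < K; ++k) {
    if (weights[k] <= 0) stop("weights must be positive");
    lnw[k] = std::log(weights[k]);
  }
  int state = 0;
  NumericVector counts(K);
  NumericMatrix trans(K, K);
  IntegerVector head(std::max(n_keep, 0));
  for (int t = 0; t < n_sweeps; ++t) {
    int prop = state + (U(rng) < 0.5 ? -1 : 1);
    int nxt = state;
    if (prop >= 0 && prop < K) {
      double lacc = -beta * (energies[prop] - energies[state]) + lnw[prop] - lnw[state];
      if (lacc >= 0 || std::log(U(rng)) < lacc) nxt = prop;
    }
    trans(state, nxt) += 1.0;
    state = nxt;
    counts[state] += 1.0;
    if (t < n_keep) head[t] = state;
  }
  return List::create(_["counts"] = counts, _["trans"] = trans, _["head"] = head);
}

// ---------------------------------------------------------------------------
// 1D Brownian toys (free / harmonic / double well)

static inline double pot1d(int type, double a, double x) {
  switch (type) {
    case 0: return 0.0;              // free
    case 1: return 0.5 * a * x * x;  // harmonic, a = spring constant
    case 2: return a * (x*x - 1.0) * (x*x - 1.0); // double well, barrier a
  }
  return 0.0;
}

// [[Rcpp::export]]
NumericVector cpp_bd1d(int pot, double parm, double x0, double D, double dt,
                       double beta, int n_steps, int sample_every, int seed) {
  std::mt19937_64 rng(seed);
  std::normal_distribution<double> G(0.0, 1.0);
  std::uniform_real_distribution<double> U(0.0, 1.0);
  double sd = std::sqrt(2.0 * D * dt);
  double x = x0;
  int ns = n_steps / sample_every;
  NumericVector out(ns);
  int si = 0;
  for (int t = 1; t <= n_steps; ++t) {
    double xn = x + sd * G(rng);
    double dE = pot1d(pot, parm, xn) - pot1d(pot, parm, x);
    if (dE <= 0 || U(rng) < std::exp(-beta * dE)) x = xn;
    if (t % sample_every == 0 && si < ns) out[si++] = x;
  }
  return out;
}

// propagate until x >= hi (status 1) or x <= lo (status 2)
// [[Rcpp::export]]
List cpp_bd1d_until(int pot, double parm, double x0, double D, double dt,
                    double beta, double lo, double hi, int max_steps, int seed) {
  std::mt19937_64 rng(seed);
  std::normal_distribution<double> G(0.0, 1.0);
  std::uniform_real_distribution<double> U(0.0, 1.0);
  double sd = std::sqrt(2.0 * D * dt);
  double x = x0;
  int status = 0, steps = 0;
  for (int t = 1; t <= max_steps; ++t) {
    double xn = x + sd * G(rng);
    double dE = pot1d(pot, parm, xn) - pot1d(pot, parm, x);
    if (dE <= 0 || U(rng) < std::exp(-beta * dE)) x = xn;
    steps = t;
    if (x >= hi) { status = 1; break; }
    if (x <= lo) { status = 2; break; }
  }
  return List::create(_["status"] = status, _["steps"] = steps, _["x"] = x);
}

// effective positive flux through lambda0 (x >= l0) with basin x <= basin_x
// [[Rcpp::export]]
List cpp_bd1d_flux(int pot, double parm, double x0, double D, double dt,
                   double beta, double l0, double basin_x, int max_steps,
                   int target, int seed) {
  std::mt19937_64 rng(seed);
  std::normal_distribution<double> G(0.0, 1.0);
  std::uniform_real_distribution<double> U(0.0, 1.0);
  double sd = std::sqrt(2.0 * D * dt);
  double x = x0;
  bool armed = (x <= basin_x);
  long basin_steps = 0;
  int n_cross = 0, steps = 0;
  std::vector<double> xs;
  for (int t = 1; t <= max_steps; ++t) {
    double xn = x + sd * G(rng);
    double dE = pot1d(pot, parm, xn) - pot1d(pot, parm, x);
    if (dE <= 0 || U(rng) < std::exp(-beta * dE)) x = xn;
    steps = t;
    if (x < l0) {
      ++basin_steps;
      if (!armed && x <= basin_x) armed = true;
    } else if (armed) {
      ++n_cross;
      xs.push_back(x);
      armed = false;
      if (target > 0 && n_cross >= target) break;
    }
  }
  return List::create(_["n_crossings"] = n_cross,
                      _["basin_time"] = basin_steps * dt,
                      _["total_time"] = steps * dt,
                      _["states"] = NumericVector(xs.begin(), xs.end()));
}

// ---------------------------------------------------------------------------
// hard-sphere fluid: packing, relaxation, Widom insertion

static bool hs_overlap_any(const std::vector<V3>& pos, const V3& x, double dmin,
                           double L, int skip) {
  for (size_t j = 0; j < pos.size(); ++j) {
    if ((int)j == skip) continue;
    if (mindist(pos[j], x, L) < dmin) return true;
  }
  return false;
}

// random sequential addition with Monte Carlo relaxation fallback
// [[Rcpp::export]]
List cpp_hs_pack(int count, double rc, double L, int seed,
                 NumericMatrix existing, double clearance, double delta,
                 int max_tries = 2000, int relax_sweeps = 200) {
  std::mt19937_64 rng(seed);
  std::uniform_real_distribution<double> U(0.0, L);
  std::uniform_real_distribution<double> U1(0.0, 1.0);
  double dmin = 2.0 * rc * (1.0 - delta);
  std::vector<V3> ex = mat_to_v3(existing);
  std::vector<V3> pos;
  bool ok = true;
  for (int k = 0; k < count; ++k) {
    bool placed = false;
    for (int t = 0; t < max_tries; ++t) {
      V3 x(U(rng), U(rng), U(rng));
      if (hs_overlap_any(pos, x, dmin, L, -1)) continue;
      if (hs_overlap_any(ex, x, clearance, L, -1)) continue;
      pos.push_back(x); placed = true; break;
    }
    if (!placed) {
      // alternate Monte Carlo relaxation of the placed spheres with fresh
      // insertion attempts (random sequential addition jams well below
      // dense packings; relaxation opens new holes)
      for (int cycle = 0; cycle < 10 && !placed; ++cycle) {
        for (int sw = 0; sw < relax_sweeps; ++sw) {
          for (size_t i = 0; i < pos.size(); ++i) {
            V3 prop = wrap(pos[i] + V3((2*U1(rng)-1)*0.3*rc, (2*U1(rng)-1)*0.3*rc, (2*U1(rng)-1)*0.3*rc), L);
            if (!hs_overlap_any(pos, prop, dmin, L, (int)i) &&
                !hs_overlap_any(ex, prop, clearance, L, -1)) pos[i] = prop;
          }
        }
        for (int t = 0; t < max_tries && !placed; ++t) {
          V3 x(U(rng), U(rng), U(rng));
          if (!hs_overlap_any(pos, x, dmin, L, -1) &&
              !hs_overlap_any(ex, x, clearance, L, -1)) { pos.push_back(x); placed = true; }
        }
      }
      if (!placed) { ok = false; break; }
    }
  }
  if (!ok) {
    // lattice fallback: sequential addition jams below dense packings, so
    // start from a simple cubic lattice (feasible up to pi/6 packing) and
    // relax until every sphere also clears the existing DNA sites
    int nl = (int)std::ceil(std::cbrt((double)count));
    double sp = L / nl;
    // full lattice, keeping the `count` points farthest from the DNA sites
    std::vector<V3> lat;
    for (int i = 0; i < nl; ++i)
      for (int j = 0; j < nl; ++j)
        for (int k = 0; k < nl; ++k)
          lat.push_back(V3((i + 0.5) * sp, (j + 0.5) * sp, (k + 0.5) * sp));
    std::vector<double> dsite(lat.size(), R_PosInf);
    for (size_t q = 0; q < lat.size(); ++q)
      for (size_t e = 0; e < ex.size(); ++e)
        dsite[q] = std::min(dsite[q], mindist(lat[q], ex[e], L));
    std::vector<int> ord(lat.size());
    for (size_t q = 0; q < ord.size(); ++q) ord[q] = (int)q;
    std::sort(ord.begin(), ord.end(),
              [&](int a, int b) { return dsite[a] > dsite[b]; });
    pos.clear();
    for (int q = 0; q < count; ++q) pos.push_back(lat[ord[q]]);
    for (int cycle = 0; cycle < 200; ++cycle) {
      bool any_bad = false;
      for (int i = 0; i < count; ++i) {
        bool bad = hs_overlap_any(pos, pos[i], dmin, L, i) ||
                   hs_overlap_any(ex, pos[i], clearance, L, -1);
        any_bad = any_bad || bad;
        V3 prop = bad ? V3(U(rng), U(rng), U(rng))
                      : wrap(pos[i] + V3((2*U1(rng)-1)*0.3*rc, (2*U1(rng)-1)*0.3*rc, (2*U1(rng)-1)*0.3*rc), L);
        if (!hs_overlap_any(pos, prop, dmin, L, i) &&
            !hs_overlap_any(ex, prop, clearance, L, -1)) pos[i] = prop;
      }
      if (!any_bad && cycle > 0) { ok = true; break; }
    }
    if (!ok) {
      // final verification after the full relaxation budget
      ok = true;
      for (int i = 0; i < count && ok; ++i)
        if (hs_overlap_any(pos, pos[i], dmin, L, i) ||
            hs_overlap_any(ex, pos[i], clearance, L, -1)) ok = false;
    }
  }
  return List::create(_["ok"] = ok, _["pos"] = v3_to_mat(pos));
}

// hard-sphere Monte Carlo relaxation (equilibration for the Widom oracle)
// [[Rcpp::export]]
NumericMatrix cpp_hs_relax(NumericMatrix positions, double L, double rc,
                           int sweeps, double dx, int seed) {
  std::vector<V3> pos = mat_to_v3(positions);
  std::mt19937_64 rng(seed);
  std::uniform_real_distribution<double> U(0.0, 1.0);
  double dmin = 2.0 * rc;
  for (int sw = 0; sw < sweeps; ++sw) {
    for (size_t i = 0; i < pos.size(); ++i) {
      V3 prop = wrap(pos[i] + V3((2*U(rng)-1)*dx, (2*U(rng)-1)*dx, (2*U(rng)-1)*dx), L);
      if (!hs_overlap_any(pos, prop, dmin, L, (int)i)) pos[i] = prop;
    }
  }
  return v3_to_mat(pos);
}

// distance from point q to segment [a - h*u, a + h*u] under minimum image
// (valid when L exceeds the segment length plus interaction range)
static inline double point_segment_dist(const V3& q, const V3& a, const V3& u,
                                        double h, double L) {
  V3 d = mindiff(q, a, L);
  double t = dot(d, u);
  if (t > h) t = h;
  if (t < -h) t = -h;
  V3 c = d - t * u;
  return norm(c);
}

// Widom test-particle insertion of a hard sphere (probe_type 0, radius R) or
// hard spherocylinder (probe_type 1, radius R, cylinder length Lsc) into a
// hard-sphere fluid of radius rc. Returns the acceptance fraction.
// [[Rcpp::export]]
List cpp_widom(NumericMatrix positions, double L, double rc, int probe_type,
               double R, double Lsc, int n_insert, int seed) {
  std::vector<V3> pos = mat_to_v3(positions);
  std::mt19937_64 rng(seed);
  std::uniform_real_distribution<double> U(0.0, L);
  std::normal_distribution<double> G(0.0, 1.0);
  double dmin = R + rc;
  long n_ok = 0;
  double h = Lsc / 2.0;
  for (int t = 0; t < n_insert; ++t) {
    V3 x(U(rng), U(rng), U(rng));
    bool clash = false;
    if (probe_type == 0) {
      clash = hs_overlap_any(pos, x, dmin, L, -1);
    } else {
      V3 u = unit(V3(G(rng), G(rng), G(rng)));
      for (size_t j = 0; j < pos.size() && !clash; ++j)
        if (point_segment_dist(pos[j], x, u, h, L) < dmin) clash = true;
    }
    if (!clash) ++n_ok;
  }
  return List::create(_["frac"] = (double)n_ok / n_insert, _["n_ok"] = (double)n_ok,
                      _["n_insert"] = n_insert);
}
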