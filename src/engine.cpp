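// Monte Carlo engine for a discrete twist-storing DNA chain.
//
// State: n vertices (base-pair midpoints), n-1 segment material frames
// (unit tangent t = normalized bond vector, material normal u with u.t = 0),
// and a per-site binary pairing state. Twist lives on joints between
// consecutive segment frames and is measured after parallel-transport
// removal (minimal rotation taking one tangent to the next), so that for
// the virtually closed curve the discrete Calugareanu-White-Fuller
// decomposition Lk = Tw + Wr holds and is conserved by any move that does
// not let segments cross. Excluded volume is a hard core enforced at move
// time, which is what protects the linking number.
//
// All energies are in units of kBT.

#include <Rcpp.h>
#include <random>
#include <cmath>
#include <vector>
#include <map>
#include <functional>
#include <cstring>

using namespace Rcpp;

static const double TWO_PI = 6.283185307179586476925286766559;

struct V3 {
  double x, y, z;
};
static inline V3 v3(double x, double y, double z) { V3 r; r.x = x; r.y = y; r.z = z; return r; }
static inline V3 operator+(const V3 &a, const V3 &b) { return v3(a.x + b.x, a.y + b.y, a.z + b.z); }
static inline V3 operator-(const V3 &a, const V3 &b) { return v3(a.x - b.x, a.y - b.y, a.z - b.z); }
static inline V3 operator*(double s, const V3 &a) { return v3(s * a.x, s * a.y, s * a.z); }
static inline double dot(const V3 &a, const V3 &b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
static inline V3 cross(const V3 &a, const V3 &b) {
  return v3(a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x);
}
static inline double norm(const V3 &a) { return std::sqrt(dot(a, a)); }
static inline V3 unit(const V3 &a) { double n = norm(a); return v3(a.x / n, a.y / n, a.z / n); }

// Rodrigues rotation of v about unit axis k by angle ang.
static inline V3 rodrigues(const V3 &v, const V3 &k, double ang) {
  double c = std::cos(ang), s = std::sin(ang);
  V3 kxv = cross(k, v);
  double kv = dot(k, v);
  return v3(v.x * c + kxv.x * s + k.x * kv * (1.0 - c),
            v.y * c + kxv.y * s + k.y * kv * (1.0 - c),
            v.z * c + kxv.z * s + k.z * kv * (1.0 - c));
}

// Parallel transport of vector a from tangent t1 to tangent t2 (minimal
// rotation). Near-degenerate (antiparallel) tangents fall back to identity;
// such joints carry divergent bend energy and are rejected anyway.
static inline V3 transport(const V3 &a, const V3 &t1, const V3 &t2) {
  V3 ax = cross(t1, t2);
  double s = norm(ax), c = dot(t1, t2);
  if (s < 1e-14) return a;
  V3 k = v3(ax.x / s, ax.y / s, ax.z / s);
  return rodrigues(a, k, std::atan2(s, c));
}

// Twist angle between material frames (t1,u1) and (t2,u2), in radians.
static inline double twist_angle(const V3 &t1, const V3 &u1, const V3 &t2, const V3 &u2) {
  V3 a = transport(u1, t1, t2);
  double x = dot(a, u2);
  double y = dot(cross(a, u2), t2);
  return std::atan2(y, x);
}

// ---------------------------------------------------------------------------
// Writhe of a closed polygon by the exact per-segment-pair solid-angle
// formula (Klenin & Langowski, method 1a style).
// ---------------------------------------------------------------------------

static inline double asin_clamped(double x) {
  if (x > 1.0) x = 1.0;
  if (x < -1.0) x = -1.0;
  return std::asin(x);
}

static double writhe_pair(const V3 &p1, const V3 &p2, const V3 &q1, const V3 &q2) {
  V3 r13 = q1 - p1, r14 = q2 - p1, r23 = q1 - p2, r24 = q2 - p2;
  V3 n1 = cross(r13, r14), n2 = cross(r14, r24), n3 = cross(r24, r23), n4 = cross(r23, r13);
  double l1 = norm(n1), l2 = norm(n2), l3 = norm(n3), l4 = norm(n4);
  // degeneracy thresholds must be relative: coplanar / collinear segment
  // pairs (e.g. two pieces of the same straight run) have cross products
  // that vanish only up to rounding in the squared length scale
  double s13 = norm(r13), s14 = norm(r14), s23 = norm(r23), s24 = norm(r24);
  if (l1 < 1e-9 * s13 * s14 || l2 < 1e-9 * s14 * s24 ||
      l3 < 1e-9 * s24 * s23 || l4 < 1e-9 * s23 * s13)
    return 0.0;
  n1 = v3(n1.x / l1, n1.y / l1, n1.z / l1);
  n2 = v3(n2.x / l2, n2.y / l2, n2.z / l2);
  n3 = v3(n3.x / l3, n3.y / l3, n3.z / l3);
  n4 = v3(n4.x / l4, n4.y / l4, n4.z / l4);
  double omega = asin_clamped(dot(n1, n2)) + asin_clamped(dot(n2, n3)) +
                 asin_clamped(dot(n3, n4)) + asin_clamped(dot(n4, n1));
  double sgn = dot(cross(q2 - q1, p2 - p1), r13) >= 0.0 ? 1.0 : -1.0;
  return omega * sgn;
}

// points: m x 3, treated as a closed polygon (vertex m connects to vertex 1).
// [[Rcpp::export]]
double cpp_writhe_closed(NumericMatrix points) {
  int m = points.nrow();
  if (m < 3) stop("need at least 3 points");
  std::vector<V3> p(m);
  for (int i = 0; i < m; ++i) p[i] = v3(points(i, 0), points(i, 1), points(i, 2));
  double total = 0.0;
  for (int i = 0; i < m; ++i) {
    V3 a1 = p[i], a2 = p[(i + 1) % m];
    for (int j = i + 2; j < m; ++j) {
      if (i == 0 && j == m - 1) continue; // adjacent through closure
      V3 b1 = p[j], b2 = p[(j + 1) % m];
      total += writhe_pair(a1, a2, b1, b2);
    }
  }
  return total / TWO_PI;
}

// Per-joint twist angles (radians) for a conformation given as vertex
// positions and per-segment material normals. Returns length n-2: element k
// (0-based) is the twist between segment frames k and k+1.
// [[Rcpp::export]]
NumericVector cpp_joint_twists(NumericMatrix pos, NumericMatrix u) {
  int n = pos.nrow();
  if (u.nrow() != n - 1) stop("u must have n-1 rows");
  std::vector<V3> t(n - 1), un(n - 1);
  for (int i = 0; i < n - 1; ++i) {
    V3 d = v3(pos(i + 1, 0) - pos(i, 0), pos(i + 1, 1) - pos(i, 1), pos(i + 1, 2) - pos(i, 2));
    double dn = norm(d);
    if (dn < 1e-12) stop("degenerate (zero-length) segment at index %d", i + 1);
    t[i] = v3(d.x / dn, d.y / dn, d.z / dn);
    V3 uu = v3(u(i, 0), u(i, 1), u(i, 2));
    uu = uu - dot(uu, t[i]) * t[i];
    double unn = norm(uu);
    if (unn < 1e-12) stop("material normal parallel to tangent at segment %d", i + 1);
    un[i] = v3(uu.x / unn, uu.y / unn, uu.z / unn);
  }
  NumericVector out(n - 2);
  for (int k = 0; k < n - 2; ++k)
    out[k] = twist_angle(t[k], un[k], t[k + 1], un[k + 1]);
  return out;
}

// Contact pairs (i, j), 1-based, with j - i >= min_sep and distance <=
// cutoff. Returns a 3-column matrix (i, j, dist).
// [[Rcpp::export]]
NumericMatrix cpp_contact_pairs(NumericMatrix pos, int min_sep, double cutoff) {
  int n = pos.nrow();
  double c2 = cutoff * cutoff;
  std::vector<double> out;
  for (int i = 0; i < n; ++i) {
    for (int j = i + min_sep; j < n; ++j) {
      double dx = pos(i, 0) - pos(j, 0);
      double dy = pos(i, 1) - pos(j, 1);
      double dz = pos(i, 2) - pos(j, 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 <= c2) {
        out.push_back(i + 1);
        out.push_back(j + 1);
        out.push_back(std::sqrt(d2));
      }
    }
  }
  int m = (int)out.size() / 3;
  NumericMatrix res(m, 3);
  for (int k = 0; k < m; ++k) {
    res(k, 0) = out[3 * k];
    res(k, 1) = out[3 * k + 1];
    res(k, 2) = out[3 * k + 2];
  }
  colnames(res) = CharacterVector::create("i", "j", "dist");
  return res;
}

// Single-linkage clustering of contact pairs (i, j) under the Chebyshev
// metric max(|di|, |dj|) <= gap. Returns 1-based component ids.
// [[Rcpp::export]]
IntegerVector cpp_cluster_pairs(IntegerVector pi, IntegerVector pj, int gap) {
  int m = pi.size();
  std::vector<int> parent(m);
  for (int k = 0; k < m; ++k) parent[k] = k;
  std::function<int(int)> find = [&](int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  };
  for (int a = 0; a < m; ++a) {
    for (int b = a + 1; b < m; ++b) {
      int di = pi[a] - pi[b]; if (di < 0) di = -di;
      if (di > gap) continue;
      int dj = pj[a] - pj[b]; if (dj < 0) dj = -dj;
      if (dj > gap) continue;
      int ra = find(a), rb = find(b);
      if (ra != rb) parent[ra] = rb;
    }
  }
  std::map<int, int> relabel;
  IntegerVector out(m);
  for (int k = 0; k < m; ++k) {
    int r = find(k);
    auto it = relabel.find(r);
    if (it == relabel.end()) { int id = (int)relabel.size() + 1; relabel[r] = id; out[k] = id; }
    else out[k] = it->second;
  }
  return out;
}

// ---------------------------------------------------------------------------
// The chain engine
// ---------------------------------------------------------------------------

enum MoveType { M_CRANK = 0, M_TWIRL = 1, M_BLOCK = 2, M_ZSHIFT = 3, M_PAIR = 4, M_PIVOT = 5, M_LOCAL = 6, M_WAVE = 7, N_MOVES = 8 };

struct Engine {
  int n;              // vertices
  int hb;             // handle sites per end
  std::vector<V3> r;  // vertex positions (nm)
  std::vector<V3> t;  // segment tangents, n-1
  std::vector<V3> u;  // segment material normals, n-1
  std::vector<double> len; // segment lengths
  std::vector<int> open;   // per-site 1 = denatured
  std::vector<double> dG;  // per-site opening cost (kBT), weakening applied
  // Ribbon twist is a continuous variable: each joint carries a winding
  // number so that soft (denatured) joints can wind past +-pi without the
  // principal value slipping a full turn (which would leak linking number).
  std::vector<int> wrap;   // per-joint (vertex index) winding number

  // elastic parameters (kBT units)
  double h, kb_ds, kb_ss, kt_ds, kt_ss, tw0, ks, bcost;
  double dia_ds2, dia_ss2;
  int min_sep;

  // defect
  int mod_j0, n_mod;  // first modified joint (vertex index), count (0 = none)
  double phi, align_k;
  int def_site;       // 5'-most dimer site (absolute), -1 if none

  // protocol
  bool tweezer;       // traps + turn constraint (false = free chain)
  double force_red;   // F / kBT, nm^-1 (applied to last vertex z)
  double kplane;      // plane stiffness (kBT/nm^2), 0 = off
  double ktrap;       // xy trap stiffness on pulled handle (kBT/nm^2)
  double applied_turns;

  // MC
  std::mt19937_64 rng;
  double beta;
  double amp_crank, amp_twirl, amp_block, amp_zshift, amp_pivot, amp_local, amp_wave;
  int span_max, wave_span_max;
  double wmix[N_MOVES];
  double wcum[N_MOVES];
  long att[N_MOVES], acc[N_MOVES];
  bool minimize_mode;

  std::uniform_real_distribution<double> u01;

  Engine() : u01(0.0, 1.0) {}

  double runif() { return u01(rng); }
  int rint(int lo, int hi) { // uniform in [lo, hi]
    return lo + (int)(runif() * (hi - lo + 1 - 1e-12));
  }

  bool site_open(int i) const { return open[i] != 0; }
  bool joint_modified(int j) const { return n_mod > 0 && j >= mod_j0 && j < mod_j0 + n_mod; }

  // principal twist angle at joint j (between frames j-1 and j)
  double principal_twist(int j) const {
    return twist_angle(t[j - 1], u[j - 1], t[j], u[j]);
  }

  // continuous twist at joint j
  double cont_twist(int j) const {
    return principal_twist(j) + TWO_PI * wrap[j];
  }

  // bend + twist energy of joint j (between frames j-1 and j), j in 1..n-2.
  // The dimer's roll is a directional bend preference: the rotation vector
  // taking tangent j-1 to tangent j prefers phi times the material normal
  // (the roll axis) of the incoming segment.
  void joint_energy_split(int j, double &eb, double &et) const {
    V3 kv = cross(t[j - 1], t[j]);
    double s = norm(kv);
    double c = dot(t[j - 1], t[j]);
    if (c > 1.0) c = 1.0;
    if (c < -1.0) c = -1.0;
    double th = std::atan2(s, c);
    bool op = site_open(j);
    bool mod = joint_modified(j);
    double kb = op ? kb_ss : kb_ds;
    if (mod) {
      V3 om = s > 1e-14 ? (th / s) * kv : v3(0.0, 0.0, 0.0);
      V3 dx = om - phi * u[j - 1];
      double e_dir = 0.5 * dot(dx, dx);
      eb = op ? 0.5 * kb * th * th : kb * e_dir;
      if (op && align_k > 0.0) eb += align_k * e_dir;
    } else {
      eb = 0.5 * kb * th * th;
    }
    double tau = cont_twist(j);
    double kt = op ? kt_ss : kt_ds;
    double tp = op ? 0.0 : tw0;
    et = 0.5 * kt * (tau - tp) * (tau - tp);
    if (mod && op && align_k > 0.0)
      et += 0.5 * align_k * (tau - tw0) * (tau - tw0);
  }

  double joint_energy(int j) const {
    double eb, et;
    joint_energy_split(j, eb, et);
    return eb + et;
  }

  double stretch_energy(int s) const {
    double d = len[s] - h;
    return 0.5 * ks * d * d;
  }

  // plane repulsion for vertex i (core sites only)
  double plane_energy_vertex(int i, double zb, double zt) const {
    if (kplane <= 0.0) return 0.0;
    double e = 0.0;
    if (r[i].z < zb) { double d = r[i].z - zb; e += 0.5 * kplane * d * d; }
    if (r[i].z > zt) { double d = r[i].z - zt; e += 0.5 * kplane * d * d; }
    return e;
  }

  double plane_energy_total() const {
    if (!tweezer || kplane <= 0.0) return 0.0;
    double zb = r[hb - 1].z, zt = r[n - hb].z, e = 0.0;
    for (int i = hb; i < n - hb; ++i) e += plane_energy_vertex(i, zb, zt);
    return e;
  }

  double trap_energy_total() const {
    if (!tweezer || ktrap <= 0.0) return 0.0;
    double e = 0.0;
    for (int i = n - hb; i < n; ++i)
      e += 0.5 * ktrap * (r[i].x * r[i].x + r[i].y * r[i].y);
    return e;
  }

  double force_energy() const { return -force_red * (r[n - 1].z - r[0].z); }

  double pairing_energy_total() const {
    double e = 0.0;
    for (int i = 0; i < n; ++i) if (site_open(i)) e += dG[i];
    for (int i = 0; i + 1 < n; ++i) if (open[i] != open[i + 1]) e += bcost;
    return e;
  }

  // excluded-volume distance check between sites i and j
  bool ev_pair_ok(int i, int j) const {
    double dx = r[i].x - r[j].x, dy = r[i].y - r[j].y, dz = r[i].z - r[j].z;
    double d2 = dx * dx + dy * dy + dz * dz;
    double dia2 = (site_open(i) || site_open(j)) ? dia_ss2 : dia_ds2;
    return d2 >= dia2;
  }

  // check every pair with one side in [a, b] and the other outside
  bool ev_range_ok(int a, int b) const {
    if (dia_ds2 <= 0.0) return true;
    // bounding box of moved vertices, padded by the largest core
    double pad = std::sqrt(dia_ds2);
    double xlo = 1e300, xhi = -1e300, ylo = 1e300, yhi = -1e300, zlo = 1e300, zhi = -1e300;
    for (int i = a; i <= b; ++i) {
      if (r[i].x < xlo) xlo = r[i].x;
      if (r[i].x > xhi) xhi = r[i].x;
      if (r[i].y < ylo) ylo = r[i].y;
      if (r[i].y > yhi) yhi = r[i].y;
      if (r[i].z < zlo) zlo = r[i].z;
      if (r[i].z > zhi) zhi = r[i].z;
    }
    xlo -= pad; xhi += pad; ylo -= pad; yhi += pad; zlo -= pad; zhi += pad;
    for (int j = 0; j < n; ++j) {
      if (r[j].z < zlo || r[j].z > zhi || r[j].x < xlo || r[j].x > xhi ||
          r[j].y < ylo || r[j].y > yhi) continue;
      if (j >= a && j <= b) continue;
      for (int i = a; i <= b; ++i) {
        int sep = i > j ? i - j : j - i;
        if (sep < min_sep) continue;
        if (!ev_pair_ok(i, j)) return false;
      }
    }
    return true;
  }

  // excluded-volume check of trial positions (scratch_r) for moved range
  // [a, b] against the static rest of the chain
  std::vector<V3> scratch_r;
  bool ev_scratch_ok(int a, int b) const {
    if (dia_ds2 <= 0.0) return true;
    double pad = std::sqrt(dia_ds2);
    double xlo = 1e300, xhi = -1e300, ylo = 1e300, yhi = -1e300, zlo = 1e300, zhi = -1e300;
    for (int i = a; i <= b; ++i) {
      const V3 &p = scratch_r[i - a];
      if (p.x < xlo) xlo = p.x;
      if (p.x > xhi) xhi = p.x;
      if (p.y < ylo) ylo = p.y;
      if (p.y > yhi) yhi = p.y;
      if (p.z < zlo) zlo = p.z;
      if (p.z > zhi) zhi = p.z;
    }
    xlo -= pad; xhi += pad; ylo -= pad; yhi += pad; zlo -= pad; zhi += pad;
    for (int j = 0; j < n; ++j) {
      if (r[j].z < zlo || r[j].z > zhi || r[j].x < xlo || r[j].x > xhi ||
          r[j].y < ylo || r[j].y > yhi) continue;
      if (j >= a && j <= b) continue;
      for (int i = a; i <= b; ++i) {
        int sep = i > j ? i - j : j - i;
        if (sep < min_sep) continue;
        const V3 &p = scratch_r[i - a];
        double dx = p.x - r[j].x, dy = p.y - r[j].y, dz = p.z - r[j].z;
        double d2 = dx * dx + dy * dy + dz * dz;
        double dia2 = (site_open(i) || site_open(j)) ? dia_ss2 : dia_ds2;
        if (d2 < dia2) return false;
      }
    }
    return true;
  }

  // internal pairs of a non-rigidly deformed range (current positions)
  bool ev_internal_ok(int a, int b) const {
    if (dia_ds2 <= 0.0) return true;
    for (int i = a; i <= b; ++i)
      for (int j = i + min_sep; j <= b; ++j)
        if (!ev_pair_ok(i, j)) return false;
    return true;
  }

  bool ev_internal_scratch_ok(int a, int b) const {
    if (dia_ds2 <= 0.0) return true;
    for (int i = a; i <= b; ++i) {
      const V3 &p = scratch_r[i - a];
      for (int j = i + min_sep; j <= b; ++j) {
        const V3 &q = scratch_r[j - a];
        double dx = p.x - q.x, dy = p.y - q.y, dz = p.z - q.z;
        double d2 = dx * dx + dy * dy + dz * dz;
        double dia2 = (site_open(i) || site_open(j)) ? dia_ss2 : dia_ds2;
        if (d2 < dia2) return false;
      }
    }
    return true;
  }

  bool ev_all_ok() const {
    if (dia_ds2 <= 0.0) return true;
    for (int i = 0; i < n; ++i)
      for (int j = i + min_sep; j < n; ++j)
        if (!ev_pair_ok(i, j)) return false;
    return true;
  }

  double total_energy(double *out) const {
    double eb = 0.0, et = 0.0;
    for (int j = 1; j <= n - 2; ++j) {
      double ebj, etj;
      joint_energy_split(j, ebj, etj);
      eb += ebj;
      et += etj;
    }
    double es = 0.0;
    for (int s = 0; s < n - 1; ++s) es += stretch_energy(s);
    double ep = pairing_energy_total();
    double ef = tweezer || force_red != 0.0 ? force_energy() : 0.0;
    double epl = plane_energy_total();
    double etr = trap_energy_total();
    if (out) {
      out[0] = eb; out[1] = et; out[2] = es; out[3] = ep;
      out[4] = ef; out[5] = epl; out[6] = etr;
    }
    return eb + et + es + ep + ef + epl + etr;
  }

  // --- move bookkeeping helpers ---------------------------------------

  // recompute tangent + length of segment s from positions; transport the
  // material normal onto the new tangent
  void refresh_segment(int s) {
    V3 d = r[s + 1] - r[s];
    double dn = norm(d);
    V3 tn = v3(d.x / dn, d.y / dn, d.z / dn);
    u[s] = transport(u[s], t[s], tn);
    // keep u exactly orthonormal to t
    u[s] = u[s] - dot(u[s], tn) * tn;
    double un = norm(u[s]);
    u[s] = v3(u[s].x / un, u[s].y / un, u[s].z / un);
    t[s] = tn;
    len[s] = dn;
  }

  bool metropolis(double dE) {
    if (minimize_mode) return dE < 0.0;
    if (dE <= 0.0) return true;
    return runif() < std::exp(-beta * dE);
  }

  // --- affected-joint bookkeeping (wrap updates) -------------------------
  // Moves register the joints they touch before applying geometry; after
  // applying, joints_post() detects principal-value jumps across +-pi and
  // adjusts the winding numbers so the continuous twist changes smoothly.
  std::vector<int> mjl;
  std::vector<double> mjp;
  std::vector<int> mjd;

  void joints_clear() { mjl.clear(); mjp.clear(); mjd.clear(); }

  double joints_pre(int j0, int j1) {
    double e = 0.0;
    for (int j = std::max(1, j0); j <= std::min(n - 2, j1); ++j) {
      mjl.push_back(j);
      mjp.push_back(principal_twist(j));
      e += joint_energy(j);
    }
    return e;
  }

  double joints_post() {
    double e = 0.0;
    mjd.resize(mjl.size());
    for (size_t k = 0; k < mjl.size(); ++k) {
      int j = mjl[k];
      double d = principal_twist(j) - mjp[k];
      int dw = d > M_PI ? -1 : (d < -M_PI ? 1 : 0);
      mjd[k] = dw;
      wrap[j] += dw;
      e += joint_energy(j);
    }
    return e;
  }

  void joints_revert() {
    for (size_t k = 0; k < mjl.size(); ++k) wrap[mjl[k]] -= mjd[k];
  }

  // --- moves ------------------------------------------------------------

  void move_crankshaft() {
    att[M_CRANK]++;
    int alo = tweezer ? hb - 1 : 0;
    int bhi = tweezer ? n - hb : n - 1;
    if (bhi - alo < 2) return;
    int a = rint(alo, bhi - 2);
    int span = rint(2, span_max);
    int b = std::min(a + span, bhi);
    double ang = (2.0 * runif() - 1.0) * amp_crank;
    V3 ax = r[b] - r[a];
    double axn = norm(ax);
    if (axn < 1e-9) return;
    ax = v3(ax.x / axn, ax.y / axn, ax.z / axn);

    joints_clear();
    double e0 = joints_pre(a, a) + joints_pre(b, b);
    double pl0 = 0.0, pl1 = 0.0;
    double zb = 0.0, zt = 0.0;
    bool plane = tweezer && kplane > 0.0;
    if (plane) {
      zb = r[hb - 1].z; zt = r[n - hb].z;
      for (int i = a + 1; i <= b - 1; ++i) pl0 += plane_energy_vertex(i, zb, zt);
    }

    save_range(a, b);
    for (int i = a + 1; i <= b - 1; ++i) {
      V3 d = r[i] - r[a];
      r[i] = r[a] + rodrigues(d, ax, ang);
    }
    for (int s = a; s <= b - 1; ++s) {
      t[s] = rodrigues(t[s], ax, ang);
      u[s] = rodrigues(u[s], ax, ang);
    }
    double e1 = joints_post();
    if (plane) for (int i = a + 1; i <= b - 1; ++i) pl1 += plane_energy_vertex(i, zb, zt);
    // cheap energy test first; the hard-core scan only runs on acceptance
    if (!metropolis(e1 - e0 + pl1 - pl0) || !ev_range_ok(a + 1, b - 1) ||
        !ev_swept_rotation_ok(a, b, ax, ang)) {
      joints_revert();
      restore_range(a, b);
      return;
    }
    acc[M_CRANK]++;
  }

  // check intermediate configurations of a rigid rotation of vertices
  // a+1..b-1 about the axis through r[a] (old positions are in sr); a large
  // rotation could otherwise sweep an arm straight through another segment
  // between two valid endpoint states, silently changing the linking number
  bool ev_swept_rotation_ok(int a, int b, const V3 &ax, double ang) {
    double maxd2 = 0.0;
    for (int i = a + 1; i <= b - 1; ++i) {
      V3 d = r[i] - sr[i - a];
      double d2 = dot(d, d);
      if (d2 > maxd2) maxd2 = d2;
    }
    int nsub = (int)(std::sqrt(maxd2) / 0.7);
    if (nsub < 1) return true;
    int m = b - a - 1;
    if ((int)scratch_r.size() < m) scratch_r.resize(m);
    V3 origin = sr[0]; // r[a] (unmoved)
    for (int k = 1; k <= nsub; ++k) {
      double lam = ang * k / (nsub + 1);
      for (int i = a + 1; i <= b - 1; ++i) {
        V3 d = sr[i - a] - origin;
        scratch_r[i - a - 1] = origin + rodrigues(d, ax, lam);
      }
      if (!ev_scratch_ok(a + 1, b - 1)) return false;
    }
    return true;
  }

  // saved slices for revert
  std::vector<V3> sr, st, su;
  std::vector<double> slen_save;
  int save_a, save_b;
  void save_range(int a, int b) {
    save_a = a; save_b = b;
    int m = b - a + 1;
    sr.resize(m); st.resize(m); su.resize(m); slen_save.resize(m);
    for (int i = 0; i < m; ++i) {
      sr[i] = r[a + i];
      if (a + i < n - 1) { st[i] = t[a + i]; su[i] = u[a + i]; slen_save[i] = len[a + i]; }
    }
  }
  void restore_range(int a, int b) {
    int m = b - a + 1;
    for (int i = 0; i < m; ++i) {
      r[a + i] = sr[i];
      if (a + i < n - 1) { t[a + i] = st[i]; u[a + i] = su[i]; len[a + i] = slen_save[i]; }
    }
  }

  void move_twirl() {
    att[M_TWIRL]++;
    int slo = tweezer ? hb : 0;
    int shi = tweezer ? n - hb - 1 : n - 2;
    if (shi < slo) return;
    int s = rint(slo, shi);
    double ang = (2.0 * runif() - 1.0) * amp_twirl;
    joints_clear();
    double e0 = joints_pre(s, s + 1);
    V3 usave = u[s];
    u[s] = rodrigues(u[s], t[s], ang);
    double e1 = joints_post();
    if (metropolis(e1 - e0)) { acc[M_TWIRL]++; }
    else { joints_revert(); u[s] = usave; }
  }

  void move_block_twirl() {
    att[M_BLOCK]++;
    int slo = tweezer ? hb : 0;
    int shi = tweezer ? n - hb - 1 : n - 2;
    if (shi <= slo) return;
    int s0 = rint(slo, shi);
    int s1 = rint(s0, shi);
    double ang = (2.0 * runif() - 1.0) * amp_block;
    joints_clear();
    double e0 = joints_pre(s0, s0) + joints_pre(s1 + 1, s1 + 1);
    int m = s1 - s0 + 1;
    su.resize(m);
    for (int i = 0; i < m; ++i) su[i] = u[s0 + i];
    for (int s = s0; s <= s1; ++s) u[s] = rodrigues(u[s], t[s], ang);
    double e1 = joints_post();
    if (metropolis(e1 - e0)) { acc[M_BLOCK]++; }
    else {
      joints_revert();
      for (int i = 0; i < m; ++i) u[s0 + i] = su[i];
    }
  }

  // translate the chain above a split point along z, with the displacement
  // ramped over the preceding bonds so no single bond absorbs the whole
  // shift; this is the move that transports contour slack to and from the
  // pulled handle
  void move_zshift() {
    att[M_ZSHIFT]++;
    if (!tweezer) return;
    int a = rint(hb + 1, n - hb); // first fully shifted vertex
    int m = std::min(30, a - hb); // ramp length in bonds
    int r0 = a - m;               // last unmoved vertex
    double dz = (2.0 * runif() - 1.0) * amp_zshift;
    joints_clear();
    double e0 = joints_pre(r0, a) + plane_energy_total() + force_energy();
    for (int s = r0; s <= a - 1; ++s) e0 += stretch_energy(s);
    save_range(r0, std::min(a, n - 1));
    for (int i = r0 + 1; i < n; ++i) {
      double f = i >= a ? 1.0 : (double)(i - r0) / m;
      r[i].z += dz * f;
    }
    for (int s = r0; s <= a - 1; ++s) refresh_segment(s);
    double e1 = joints_post() + plane_energy_total() + force_energy();
    for (int s = r0; s <= a - 1; ++s) e1 += stretch_energy(s);
    if (!metropolis(e1 - e0) || !ev_range_ok(r0 + 1, n - 1)) {
      joints_revert();
      for (int i = r0 + 1; i < n; ++i) {
        double f = i >= a ? 1.0 : (double)(i - r0) / m;
        r[i].z -= dz * f;
      }
      restore_range(save_a, save_b);
      return;
    }
    acc[M_ZSHIFT]++;
  }

  // Pairing flip with twist re-partitioning. Opening a base pair drops the
  // joint's preferred twist from tw0 to 0; a bare flip against an
  // equilibrated duplex twist would carry the whole elastic mismatch as an
  // instantaneous barrier even when the open state is favourable at the
  // ambient torque. The move therefore co-rotates a ramp of m frames so the
  // flipped joint lands at its new preferred twist while the released twist
  // is spread as tw0/m over the neighbouring joints. The transformation is
  // an involution (closing applies the exact reverse), so plain Metropolis
  // acceptance is valid, and it conserves total twist exactly.
  void move_pairing() {
    att[M_PAIR]++;
    int i = rint(hb, n - hb - 1);
    bool opening = !site_open(i);
    double sgn = opening ? -1.0 : 1.0; // change of preferred twist at joint i
    int m = 40;
    int slo = hb, shi = n - hb - 1; // twirlable frames
    bool up = (i + m - 1 <= shi);
    bool down = (i - m >= slo);
    if (!up && !down) m = 0; // short chain: plain flip

    joints_clear();
    int j0 = m == 0 ? i : (up ? i : i - m);
    int j1 = m == 0 ? i : (up ? i + m : i);
    double e0 = dG_boundary_energy(i) + joints_pre(j0, j1);
    open[i] = 1 - open[i];
    if (!open[i]) {
      // closing can create hard-core overlaps (the ss core is thinner)
      bool ok = true;
      for (int j = 0; j < n && ok; ++j) {
        int sep = j > i ? j - i : i - j;
        if (sep < min_sep) continue;
        if (!ev_pair_ok(i, j)) ok = false;
      }
      if (!ok) { open[i] = 1; return; }
    }
    if (m > 0) {
      su.resize(m);
      if (up) {
        for (int k = 0; k < m; ++k) {
          su[k] = u[i + k];
          double a = sgn * tw0 * (1.0 - (double)k / m);
          u[i + k] = rodrigues(u[i + k], t[i + k], a);
        }
      } else {
        for (int k = 0; k < m; ++k) {
          int s = i - 1 - k;
          su[k] = u[s];
          double a = -sgn * tw0 * (1.0 - (double)k / m);
          u[s] = rodrigues(u[s], t[s], a);
        }
      }
    }
    double e1 = dG_boundary_energy(i) + joints_post();
    if (metropolis(e1 - e0)) { acc[M_PAIR]++; return; }
    joints_revert();
    open[i] = 1 - open[i];
    if (m > 0) {
      if (up) for (int k = 0; k < m; ++k) u[i + k] = su[k];
      else for (int k = 0; k < m; ++k) u[i - 1 - k] = su[k];
    }
  }

  double joint_energy_j(int j) const {
    if (j < 1 || j > n - 2) return 0.0;
    return joint_energy(j);
  }

  double dG_boundary_energy(int i) const {
    double e = site_open(i) ? dG[i] : 0.0;
    if (i > 0 && open[i] != open[i - 1]) e += bcost;
    if (i < n - 1 && open[i] != open[i + 1]) e += bcost;
    return e;
  }

  void move_pivot() {
    att[M_PIVOT]++;
    if (tweezer) return;
    int a = rint(0, n - 2);
    double ang = (2.0 * runif() - 1.0) * amp_pivot;
    // random unit axis
    double zz = 2.0 * runif() - 1.0;
    double ph = TWO_PI * runif();
    double rr = std::sqrt(std::max(0.0, 1.0 - zz * zz));
    V3 ax = v3(rr * std::cos(ph), rr * std::sin(ph), zz);
    joints_clear();
    double e0 = joints_pre(a, a) + force_energy();
    save_range(a, n - 1);
    for (int i = a + 1; i < n; ++i) {
      V3 d = r[i] - r[a];
      r[i] = r[a] + rodrigues(d, ax, ang);
    }
    for (int s = a; s <= n - 2; ++s) {
      t[s] = rodrigues(t[s], ax, ang);
      u[s] = rodrigues(u[s], ax, ang);
    }
    double e1 = joints_post() + force_energy();
    if (!metropolis(e1 - e0) || !ev_range_ok(a + 1, n - 1) ||
        !ev_swept_rotation_ok(a, n, ax, ang)) {
      joints_revert();
      restore_range(a, n - 1);
      return;
    }
    acc[M_PIVOT]++;
  }

  void move_local() {
    att[M_LOCAL]++;
    int lo = tweezer ? hb : 1;
    int hi = tweezer ? n - hb - 1 : n - 1;
    if (hi < lo) return;
    int i = rint(lo, hi);
    V3 dv = v3((2.0 * runif() - 1.0) * amp_local,
               (2.0 * runif() - 1.0) * amp_local,
               (2.0 * runif() - 1.0) * amp_local);
    int s0 = std::max(0, i - 1), s1 = std::min(n - 2, i);
    joints_clear();
    double e0 = joints_pre(i - 1, i + 1) + force_energy() + plane_energy_total();
    for (int s = s0; s <= s1; ++s) e0 += stretch_energy(s);
    save_range(std::max(0, i - 1), std::min(n - 1, i + 1));
    r[i] = r[i] + dv;
    for (int s = s0; s <= s1; ++s) refresh_segment(s);
    double e1 = joints_post() + force_energy() + plane_energy_total();
    for (int s = s0; s <= s1; ++s) e1 += stretch_energy(s);
    bool ok = metropolis(e1 - e0);
    if (ok) {
      for (int j = 0; j < n && ok; ++j) {
        int sep = j > i ? j - i : i - j;
        if (sep < min_sep) continue;
        if (!ev_pair_ok(i, j)) ok = false;
      }
    }
    if (!ok) { joints_revert(); restore_range(save_a, save_b); return; }
    acc[M_LOCAL]++;
  }

  // smooth transverse displacement of an arc: a sine bump vanishing at the
  // arc ends, which equilibrates long-wavelength bending modes that local
  // and crankshaft moves reach only slowly
  void move_wave() {
    att[M_WAVE]++;
    int alo = tweezer ? hb - 1 : 0;
    int bhi = tweezer ? n - hb : n - 1;
    if (bhi - alo < 6) return;
    // log-uniform spans so long-wavelength bending modes are reached too
    int smax = std::min(wave_span_max, bhi - alo);
    int span = (int)std::lround(std::exp(std::log(6.0) +
                 runif() * (std::log((double)smax) - std::log(6.0))));
    if (span < 6) span = 6;
    int a = rint(alo, bhi - 6);
    int b = std::min(a + span, bhi);
    double A = (2.0 * runif() - 1.0) * amp_wave * std::sqrt((b - a) / 50.0);
    double zz = 2.0 * runif() - 1.0;
    double ph = TWO_PI * runif();
    double rr = std::sqrt(std::max(0.0, 1.0 - zz * zz));
    V3 dir = v3(rr * std::cos(ph), rr * std::sin(ph), zz);
    joints_clear();
    double e0 = joints_pre(a, b);
    for (int s = a; s <= b - 1; ++s) e0 += stretch_energy(s);
    bool plane = tweezer && kplane > 0.0;
    double pl0 = 0.0, pl1 = 0.0, zb = 0.0, zt = 0.0;
    if (plane) {
      zb = r[hb - 1].z; zt = r[n - hb].z;
      for (int i = a + 1; i <= b - 1; ++i) pl0 += plane_energy_vertex(i, zb, zt);
    }
    save_range(a, b);
    double w = M_PI / (b - a);
    for (int i = a + 1; i <= b - 1; ++i) {
      double f = A * std::sin(w * (i - a));
      r[i] = r[i] + f * dir;
    }
    for (int s = a; s <= b - 1; ++s) refresh_segment(s);
    double e1 = joints_post();
    for (int s = a; s <= b - 1; ++s) e1 += stretch_energy(s);
    if (plane) for (int i = a + 1; i <= b - 1; ++i) pl1 += plane_energy_vertex(i, zb, zt);
    if (!metropolis(e1 - e0 + pl1 - pl0) || !ev_range_ok(a + 1, b - 1) ||
        !ev_internal_ok(a + 1, b - 1) || !ev_swept_wave_ok(a, b, dir, A, w)) {
      joints_revert();
      restore_range(a, b);
      return;
    }
    acc[M_WAVE]++;
  }

  // intermediate configurations of a sine-bump displacement
  bool ev_swept_wave_ok(int a, int b, const V3 &dir, double A, double w) {
    int nsub = (int)(std::fabs(A) / 0.7);
    if (nsub < 1) return true;
    int m = b - a - 1;
    if ((int)scratch_r.size() < m) scratch_r.resize(m);
    for (int k = 1; k <= nsub; ++k) {
      double lam = (double)k / (nsub + 1);
      for (int i = a + 1; i <= b - 1; ++i) {
        double f = lam * A * std::sin(w * (i - a));
        scratch_r[i - a - 1] = sr[i - a] + f * dir;
      }
      if (!ev_scratch_ok(a + 1, b - 1)) return false;
      if (!ev_internal_scratch_ok(a + 1, b - 1)) return false;
    }
    return true;
  }

  void one_attempt() {
    double x = runif() * wcum[N_MOVES - 1];
    int m = 0;
    while (m < N_MOVES - 1 && x > wcum[m]) ++m;
    switch (m) {
      case M_CRANK: move_crankshaft(); break;
      case M_TWIRL: move_twirl(); break;
      case M_BLOCK: move_block_twirl(); break;
      case M_ZSHIFT: move_zshift(); break;
      case M_PAIR: move_pairing(); break;
      case M_PIVOT: move_pivot(); break;
      case M_LOCAL: move_local(); break;
      case M_WAVE: move_wave(); break;
    }
  }

  void sweep() {
    for (int k = 0; k < n; ++k) one_attempt();
  }

  // impose d_turns additional turns by rotating the pulled-handle frames
  // about their (axial) tangents
  void wind_increment(double d_turns) {
    if (!tweezer || hb < 2) stop("winding requires tweezer mode with handle_bp >= 2");
    double ang = d_turns * TWO_PI;
    int j = n - hb; // injection joint (linker frame n-hb-1 | clamped frame n-hb)
    double p0 = principal_twist(j);
    for (int s = n - hb; s <= n - 2; ++s) u[s] = rodrigues(u[s], t[s], ang);
    double p1 = principal_twist(j);
    wrap[j] += (int)std::lround((ang - (p1 - p0)) / TWO_PI);
    applied_turns += d_turns;
  }

  double tw_sum(int k0, int k1) const {
    double s = 0.0;
    for (int k = k0; k <= k1; ++k)
      s += twist_angle(t[k], u[k], t[k + 1], u[k + 1]) + TWO_PI * wrap[k + 1];
    return s / TWO_PI;
  }

  // writhe of the chain closed through distant axial extensions
  double writhe_closed_chain() const {
    // virtual closure: straight down from vertex 0, straight up from the
    // last vertex, joined by a distant rectangle; far segments contribute
    // negligibly but are included exactly by the closed form
    double D = 4.0e3, W = 8.0e3;
    std::vector<V3> p;
    p.reserve(n + 4);
    for (int i = 0; i < n; ++i) p.push_back(r[i]);
    V3 top = r[n - 1], bot = r[0];
    p.push_back(v3(top.x, top.y, top.z + D));
    p.push_back(v3(top.x + W, top.y, top.z + D));
    p.push_back(v3(bot.x + W, bot.y, bot.z - D));
    p.push_back(v3(bot.x, bot.y, bot.z - D));
    int m = (int)p.size();
    double total = 0.0;
    for (int i = 0; i < m; ++i) {
      V3 a1 = p[i], a2 = p[(i + 1) % m];
      for (int j = i + 2; j < m; ++j) {
        if (i == 0 && j == m - 1) continue;
        V3 b1 = p[j], b2 = p[(j + 1) % m];
        total += writhe_pair(a1, a2, b1, b2);
      }
    }
    return total / TWO_PI;
  }
};

static void engine_from_r(Engine &E, NumericMatrix pos, NumericMatrix un,
                          IntegerVector open, NumericVector dG, List par,
                          List defect, List prot) {
  int n = pos.nrow();
  E.n = n;
  E.r.resize(n);
  for (int i = 0; i < n; ++i) E.r[i] = v3(pos(i, 0), pos(i, 1), pos(i, 2));
  E.t.resize(n - 1); E.u.resize(n - 1); E.len.resize(n - 1);
  for (int s = 0; s < n - 1; ++s) {
    V3 d = E.r[s + 1] - E.r[s];
    double dn = norm(d);
    if (dn < 1e-12) stop("zero-length segment in conformation");
    E.t[s] = v3(d.x / dn, d.y / dn, d.z / dn);
    E.len[s] = dn;
    V3 uu = v3(un(s, 0), un(s, 1), un(s, 2));
    uu = uu - dot(uu, E.t[s]) * E.t[s];
    double unn = norm(uu);
    if (unn < 1e-12) stop("material normal parallel to tangent at segment %d", s + 1);
    E.u[s] = v3(uu.x / unn, uu.y / unn, uu.z / unn);
  }
  E.open.assign(open.begin(), open.end());
  E.dG.assign(dG.begin(), dG.end());
  E.wrap.assign(n, 0);

  E.h = as<double>(par["rise_nm"]);
  double p_ds = as<double>(par["p_ds_nm"]), p_ss = as<double>(par["p_ss_nm"]);
  double C_ds = as<double>(par["C_ds_nm"]), C_ss = as<double>(par["C_ss_nm"]);
  E.kb_ds = p_ds / E.h; E.kb_ss = p_ss / E.h;
  E.kt_ds = C_ds / E.h; E.kt_ss = C_ss / E.h;
  E.tw0 = as<double>(par["intrinsic_twist_deg"]) * M_PI / 180.0;
  E.ks = as<double>(par["stretch_stiffness_kbt_nm2"]);
  E.bcost = as<double>(par["boundary_cost"]);
  double dds = as<double>(par["excluded_diameter_nm"]);
  double dss = as<double>(par["excluded_diameter_ss_nm"]);
  E.dia_ds2 = dds > 0 ? dds * dds : 0.0;
  E.dia_ss2 = dss > 0 ? dss * dss : 0.0;
  E.min_sep = as<int>(par["ev_min_separation"]);

  if (defect.size() > 0 && as<int>(defect["n_mod"]) > 0) {
    E.mod_j0 = as<int>(defect["mod_j0"]);
    E.n_mod = as<int>(defect["n_mod"]);
    E.phi = as<double>(defect["phi_deg"]) * M_PI / 180.0;
    E.align_k = as<double>(defect["align_k"]);
    E.def_site = as<int>(defect["def_site"]);
  } else {
    E.mod_j0 = -1; E.n_mod = 0; E.phi = 0.0; E.align_k = 0.0; E.def_site = -1;
  }

  E.hb = as<int>(prot["handle_bp"]);
  E.tweezer = as<bool>(prot["tweezer"]);
  E.force_red = as<double>(prot["force_red"]);
  E.kplane = as<double>(prot["kplane"]);
  E.ktrap = as<double>(prot["ktrap"]);
  E.applied_turns = as<double>(prot["applied_turns"]);
  if (E.hb < 1) stop("handle_bp must be >= 1");
  if (E.tweezer && n < 2 * E.hb + 10) stop("chain too short for tweezer handles");
}

static List engine_state_to_r(const Engine &E) {
  int n = E.n;
  NumericMatrix pos(n, 3), un(n - 1, 3);
  IntegerVector open(n);
  for (int i = 0; i < n; ++i) {
    pos(i, 0) = E.r[i].x; pos(i, 1) = E.r[i].y; pos(i, 2) = E.r[i].z;
    open[i] = E.open[i];
  }
  for (int s = 0; s < n - 1; ++s) {
    un(s, 0) = E.u[s].x; un(s, 1) = E.u[s].y; un(s, 2) = E.u[s].z;
  }
  return List::create(_["positions"] = pos, _["normals"] = un, _["open"] = open,
                      _["applied_turns"] = E.applied_turns);
}

static void set_schedule(Engine &E, List sched) {
  E.rng.seed((uint64_t)as<double>(sched["seed"]));
  E.beta = as<double>(sched["beta"]);
  List amp = sched["amplitudes"];
  E.amp_crank = as<double>(amp["crankshaft_max_deg"]) * M_PI / 180.0;
  E.amp_twirl = as<double>(amp["twirl_max_deg"]) * M_PI / 180.0;
  E.amp_block = as<double>(amp["block_twirl_max_deg"]) * M_PI / 180.0;
  E.amp_zshift = as<double>(amp["zshift_max_nm"]);
  E.amp_pivot = as<double>(amp["pivot_max_deg"]) * M_PI / 180.0;
  E.amp_local = as<double>(amp["local_max_nm"]);
  E.amp_wave = as<double>(amp["wave_max_nm"]);
  E.span_max = as<int>(amp["max_segment_span"]);
  E.wave_span_max = as<int>(amp["wave_max_span"]);
  List mix = sched["move_mix"];
  const char *nm[N_MOVES] = {"crankshaft", "twirl", "block_twirl", "zshift", "pairing", "pivot", "local", "wave"};
  double cum = 0.0;
  for (int m = 0; m < N_MOVES; ++m) {
    double w = mix.containsElementNamed(nm[m]) ? as<double>(mix[nm[m]]) : 0.0;
    E.wmix[m] = w;
    cum += w;
    E.wcum[m] = cum;
  }
  if (cum <= 0.0) stop("move_mix weights must sum to a positive value");
  for (int m = 0; m < N_MOVES; ++m) { E.att[m] = 0; E.acc[m] = 0; }
  E.minimize_mode = false;
}

// [[Rcpp::export]]
List cpp_run_mc(NumericMatrix pos, NumericMatrix un, IntegerVector open,
                NumericVector dG, List par, List defect, List prot, List sched) {
  Engine E;
  engine_from_r(E, pos, un, open, dG, par, defect, prot);
  set_schedule(E, sched);

  int wind_sweeps = as<int>(sched["wind_sweeps"]);
  int prod_sweeps = as<int>(sched["prod_sweeps"]);
  int sample_int = as<int>(sched["sample_interval"]);
  bool store_frames = as<bool>(sched["store_frames"]);
  bool wr_channel = as<bool>(sched["writhe_channel"]);
  double turns_target = as<double>(sched["turns_target"]);
  double lk_book0 = as<double>(sched["lk_book0"]);

  if (!E.ev_all_ok()) stop("initial conformation violates excluded volume");

  double dturn = wind_sweeps > 0 ? (turns_target - E.applied_turns) / wind_sweeps : 0.0;
  int total = wind_sweeps + prod_sweeps;
  int n_samples = sample_int > 0 ? total / sample_int : 0;

  int nch = 16;
  NumericMatrix channels(n_samples, nch);
  colnames(channels) = CharacterVector::create(
      "sweep", "applied_turns", "e_bend", "e_twist", "e_stretch", "e_pairing",
      "e_force", "e_plane", "e_trap", "extension_nm", "tw_all", "tw_core",
      "writhe", "lk_book", "n_open", "defect_open");
  List frames(store_frames ? n_samples : 0);

  int isamp = 0;
  for (int sw = 1; sw <= total; ++sw) {
    if (sw <= wind_sweeps) E.wind_increment(dturn);
    E.sweep();
    if (sample_int > 0 && sw % sample_int == 0 && isamp < n_samples) {
      double terms[7];
      E.total_energy(terms);
      double tw_all = E.tw_sum(0, E.n - 3);
      // core region of n_core bp spans exactly n_core twist steps:
      // frame pairs (k, k+1) for k in [hb-1, n-hb-2]
      double tw_core = E.tw_sum(E.hb - 1, E.n - E.hb - 2);
      double wr = wr_channel ? E.writhe_closed_chain() : NA_REAL;
      int nopen = 0;
      for (int i = 0; i < E.n; ++i) nopen += E.open[i];
      double dop = NA_REAL;
      if (E.def_site >= 0)
        dop = (E.open[E.def_site] && E.open[E.def_site + 1]) ? 1.0 : 0.0;
      channels(isamp, 0) = sw;
      channels(isamp, 1) = E.applied_turns;
      for (int k = 0; k < 7; ++k) channels(isamp, 2 + k) = terms[k];
      channels(isamp, 9) = E.r[E.n - 1].z - E.r[0].z;
      channels(isamp, 10) = tw_all;
      channels(isamp, 11) = tw_core;
      channels(isamp, 12) = wr;
      channels(isamp, 13) = lk_book0 + E.applied_turns;
      channels(isamp, 14) = nopen;
      channels(isamp, 15) = dop;
      if (store_frames) frames[isamp] = engine_state_to_r(E);
      ++isamp;
    }
  }

  NumericMatrix accm(N_MOVES, 2);
  rownames(accm) = CharacterVector::create("crankshaft", "twirl", "block_twirl",
                                           "zshift", "pairing", "pivot", "local",
                                           "wave");
  colnames(accm) = CharacterVector::create("attempts", "accepts");
  for (int m = 0; m < N_MOVES; ++m) { accm(m, 0) = (double)E.att[m]; accm(m, 1) = (double)E.acc[m]; }

  List st = engine_state_to_r(E);
  return List::create(_["state"] = st, _["channels"] = channels,
                      _["frames"] = frames, _["acceptance"] = accm);
}

// [[Rcpp::export]]
NumericVector cpp_total_energy(NumericMatrix pos, NumericMatrix un, IntegerVector open,
                               NumericVector dG, List par, List defect, List prot) {
  Engine E;
  engine_from_r(E, pos, un, open, dG, par, defect, prot);
  double terms[7];
  double tot = E.total_energy(terms);
  bool overlap = !E.ev_all_ok();
  NumericVector out = NumericVector::create(
      _["bend"] = terms[0], _["twist"] = terms[1], _["stretch"] = terms[2],
      _["pairing"] = terms[3], _["force"] = terms[4], _["plane"] = terms[5],
      _["trap"] = terms[6], _["overlap"] = overlap ? 1.0 : 0.0,
      _["total"] = overlap ? R_PosInf : tot);
  return out;
}

// Zero-temperature relaxation: downhill-only Metropolis with amplitude
// annealing. Converged when a full round of sweeps improves the energy by
// less than tol at the smallest amplitudes.
// [[Rcpp::export]]
List cpp_minimize(NumericMatrix pos, NumericMatrix un, IntegerVector open,
                  NumericVector dG, List par, List defect, List prot, List sched,
                  int max_rounds, double tol) {
  Engine E;
  engine_from_r(E, pos, un, open, dG, par, defect, prot);
  set_schedule(E, sched);
  E.minimize_mode = true;

  double e_prev = E.total_energy(nullptr);
  double scale = 1.0;
  int rounds = 0;
  bool converged = false;
  double a_crank = E.amp_crank, a_twirl = E.amp_twirl, a_block = E.amp_block,
         a_piv = E.amp_pivot, a_loc = E.amp_local, a_z = E.amp_zshift,
         a_wav = E.amp_wave;
  for (rounds = 1; rounds <= max_rounds; ++rounds) {
    E.amp_crank = a_crank * scale; E.amp_twirl = a_twirl * scale;
    E.amp_block = a_block * scale; E.amp_pivot = a_piv * scale;
    E.amp_local = a_loc * scale; E.amp_zshift = a_z * scale;
    E.amp_wave = a_wav * scale;
    for (int k = 0; k < 20; ++k) E.sweep();
    double e_now = E.total_energy(nullptr);
    double gain = e_prev - e_now;
    e_prev = e_now;
    // anneal once progress at the current amplitude stalls
    if (gain < 1e-6) scale *= 0.5;
    if (scale < 1e-6 && gain < tol) {
      converged = true;
      break;
    }
  }
  List st = engine_state_to_r(E);
  return List::create(_["state"] = st, _["converged"] = converged,
                      _["rounds"] = rounds, _["energy"] = e_prev);
}

// Writhe of an open polyline closed through distant axial extensions (the
// tweezer closure convention used by the engine).
// [[Rcpp::export]]
double cpp_writhe_axial_closure(NumericMatrix points) {
  int n = points.nrow();
  if (n < 4) stop("need at least 4 points");
  Engine E;
  E.n = n;
  E.r.resize(n);
  for (int i = 0; i < n; ++i) E.r[i] = v3(points(i, 0), points(i, 1), points(i, 2));
  return E.writhe_closed_chain();
}
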