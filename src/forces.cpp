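#include <Rcpp.h>
#include <cmath>
#include <unordered_map>
#include <vector>
using namespace Rcpp;

// Coarse-grained force field for an actomyosin network coupled to a
// triangulated membrane, plus a fused Brownian-dynamics inner loop. All
// positions in um, forces in pN, stiffnesses pN/um (springs), pN*um
// (angular), pN/um^2 (pressure-like). Indices arriving from R are 1-based
// and converted here.

static inline double clamp01(double x) {
  return x < 0.0 ? 0.0 : (x > 1.0 ? 1.0 : x);
}

struct V3 {
  double x, y, z;
  V3() : x(0), y(0), z(0) {}
  V3(double a, double b, double c) : x(a), y(b), z(c) {}
};
static inline V3 operator-(const V3 &a, const V3 &b) { return V3(a.x-b.x, a.y-b.y, a.z-b.z); }
static inline V3 operator+(const V3 &a, const V3 &b) { return V3(a.x+b.x, a.y+b.y, a.z+b.z); }
static inline V3 operator*(double s, const V3 &a) { return V3(s*a.x, s*a.y, s*a.z); }
static inline double dot(const V3 &a, const V3 &b) { return a.x*b.x + a.y*b.y + a.z*b.z; }
static inline V3 cross(const V3 &a, const V3 &b) {
  return V3(a.y*b.z - a.z*b.y, a.z*b.x - a.x*b.z, a.x*b.y - a.y*b.x);
}
static inline double norm(const V3 &a) { return std::sqrt(dot(a, a)); }

static inline V3 getp(const NumericMatrix &pos, int i) {
  return V3(pos(i, 0), pos(i, 1), pos(i, 2));
}
static inline void addf(NumericMatrix &F, int i, const V3 &f) {
  F(i, 0) += f.x; F(i, 1) += f.y; F(i, 2) += f.z;
}

// Closest points between segments p1-q1 and p2-q2 (Ericson, RTCD 5.1.9).
static void seg_seg_closest(const V3 &p1, const V3 &q1, const V3 &p2, const V3 &q2,
                            double &s, double &t) {
  V3 d1 = q1 - p1, d2 = q2 - p2, r = p1 - p2;
  double a = dot(d1, d1), e = dot(d2, d2), f = dot(d2, r);
  double c = dot(d1, r), b = dot(d1, d2);
  double denom = a * e - b * b;
  s = (denom > 1e-14) ? clamp01((b * f - c * e) / denom) : 0.0;
  t = (e > 1e-14) ? (b * s + f) / e : 0.0;
  if (t < 0.0) { t = 0.0; s = (a > 1e-14) ? clamp01(-c / a) : 0.0; }
  else if (t > 1.0) { t = 1.0; s = (a > 1e-14) ? clamp01((b - c) / a) : 0.0; }
}

// Candidate filament segment pairs within cutoff (midpoint prefilter with
// per-pair reach). Pairs sharing a node are excluded. Returns 1-based rows.
// [[Rcpp::export]]
IntegerMatrix seg_pairs_cpp(NumericMatrix pos, IntegerVector seg_a,
                            IntegerVector seg_b, double cutoff) {
  int ns = seg_a.size();
  std::vector<double> mx(ns), my(ns), mz(ns), half(ns);
  for (int i = 0; i < ns; ++i) {
    V3 a = getp(pos, seg_a[i] - 1), b = getp(pos, seg_b[i] - 1);
    mx[i] = 0.5 * (a.x + b.x); my[i] = 0.5 * (a.y + b.y); mz[i] = 0.5 * (a.z + b.z);
    half[i] = 0.5 * norm(b - a);
  }
  std::vector<int> pi, pj;
  for (int i = 0; i < ns; ++i) {
    for (int j = i + 1; j < ns; ++j) {
      if (seg_a[i] == seg_a[j] || seg_a[i] == seg_b[j] ||
          seg_b[i] == seg_a[j] || seg_b[i] == seg_b[j]) continue;
      double reach = half[i] + half[j] + cutoff;
      double dx = mx[i] - mx[j], dy = my[i] - my[j], dz = mz[i] - mz[j];
      if (dx * dx + dy * dy + dz * dz < reach * reach) { pi.push_back(i + 1); pj.push_back(j + 1); }
    }
  }
  IntegerMatrix out(pi.size(), 2);
  for (size_t k = 0; k < pi.size(); ++k) { out(k, 0) = pi[k]; out(k, 1) = pj[k]; }
  return out;
}

// Candidate (mesh vertex, filament segment) pairs within cutoff. 1-based.
// [[Rcpp::export]]
IntegerMatrix vert_seg_pairs_cpp(NumericMatrix pos, IntegerVector vidx,
                                 IntegerVector seg_a, IntegerVector seg_b,
                                 double cutoff) {
  int nv = vidx.size(), ns = seg_a.size();
  std::vector<int> pv, ps;
  for (int j = 0; j < ns; ++j) {
    V3 a = getp(pos, seg_a[j] - 1), b = getp(pos, seg_b[j] - 1);
    V3 m = 0.5 * (a + b);
    double reach = 0.5 * norm(b - a) + cutoff;
    double r2 = reach * reach;
    for (int i = 0; i < nv; ++i) {
      V3 p = getp(pos, vidx[i] - 1);
      V3 d = p - m;
      if (dot(d, d) < r2) { pv.push_back(vidx[i]); ps.push_back(j + 1); }
    }
  }
  IntegerMatrix out(pv.size(), 2);
  for (size_t k = 0; k < pv.size(); ++k) { out(k, 0) = pv[k]; out(k, 1) = ps[k]; }
  return out;
}

// Nearest point on any segment (within cutoff) for each query point.
// Columns: seg index (1-based, 0 if none), t in [0,1], distance.
// [[Rcpp::export]]
NumericMatrix point_seg_nearest_cpp(NumericMatrix pts, NumericMatrix pos,
                                    IntegerVector seg_a, IntegerVector seg_b,
                                    double cutoff,
                                    IntegerVector seg_fil = IntegerVector(0),
                                    IntegerVector excl_fil = IntegerVector(0)) {
  int np = pts.nrow(), ns = seg_a.size();
  bool excl = seg_fil.size() == ns && excl_fil.size() == np;
  NumericMatrix out(np, 3);
  if (np == 0 || ns == 0) {
    for (int i = 0; i < np; ++i) { out(i, 0) = 0; out(i, 2) = NA_REAL; }
    return out;
  }
  // uniform grid over segment midpoints; cell size covers half-length+cutoff
  double maxhalf = 0.0;
  std::vector<V3> mids(ns);
  double lo[3] = {1e300, 1e300, 1e300};
  for (int j = 0; j < ns; ++j) {
    V3 a = getp(pos, seg_a[j] - 1), b = getp(pos, seg_b[j] - 1);
    mids[j] = 0.5 * (a + b);
    double h = 0.5 * norm(b - a);
    if (h > maxhalf) maxhalf = h;
    if (mids[j].x < lo[0]) lo[0] = mids[j].x;
    if (mids[j].y < lo[1]) lo[1] = mids[j].y;
    if (mids[j].z < lo[2]) lo[2] = mids[j].z;
  }
  double cell = cutoff + maxhalf + 1e-9;
  auto cix = [&](double v, int k) {
    int c = (int)std::floor((v - lo[k]) / cell);
    return c < 0 ? 0 : c;
  };
  std::unordered_map<long long, std::vector<int>> grid;
  auto key = [](int ix, int iy, int iz) {
    return ((long long)ix << 42) ^ ((long long)iy << 21) ^ (long long)iz;
  };
  for (int j = 0; j < ns; ++j) {
    grid[key(cix(mids[j].x, 0), cix(mids[j].y, 1), cix(mids[j].z, 2))].push_back(j);
  }
  for (int i = 0; i < np; ++i) {
    V3 p(pts(i, 0), pts(i, 1), pts(i, 2));
    double best = cutoff; int bseg = 0; double bt = 0.0;
    int ix = cix(p.x, 0), iy = cix(p.y, 1), iz = cix(p.z, 2);
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dz = -1; dz <= 1; ++dz) {
          if (ix + dx < 0 || iy + dy < 0 || iz + dz < 0) continue;
          auto it = grid.find(key(ix + dx, iy + dy, iz + dz));
          if (it == grid.end()) continue;
          for (int j : it->second) {
            if (excl && seg_fil[j] == excl_fil[i]) continue;
            V3 a = getp(pos, seg_a[j] - 1), b = getp(pos, seg_b[j] - 1);
            V3 d = b - a;
            double dd = dot(d, d);
            double t = dd > 1e-14 ? clamp01(dot(p - a, d) / dd) : 0.0;
            V3 c = a + t * d;
            double dist = norm(p - c);
            if (dist < best) { best = dist; bseg = j + 1; bt = t; }
          }
        }
    out(i, 0) = bseg; out(i, 1) = bt; out(i, 2) = bseg ? best : NA_REAL;
  }
  return out;
}

// --- shared force evaluation -------------------------------------------------

struct SysRef {
  NumericMatrix pos;
  IntegerVector seg_a, seg_b;
  NumericVector seg_rest;
  double k_ext;
  IntegerMatrix bend_trip;
  double k_bend;
  IntegerMatrix rep_pairs;
  double r_rep, k_rep;
  IntegerMatrix spr_ia, spr_ib;
  NumericMatrix spr_wa, spr_wb;
  NumericVector spr_k, spr_rest;
  IntegerMatrix faces;
  NumericVector ref_area;
  double k_area;
  IntegerMatrix edge4;
  double k_bend_mem, ref_vol, k_vol;
  IntegerMatrix mrep_pairs;
  double r_mrep, k_mrep;
};

struct ForceOut {
  NumericMatrix F;
  NumericVector seg_t, spr_t, area;
  NumericMatrix spr_fB;
  double vol;
};

static void compute_forces(const SysRef &S, ForceOut &O) {
  const NumericMatrix &pos = S.pos;
  NumericMatrix &F = O.F;
  std::fill(F.begin(), F.end(), 0.0);
  int ns = S.seg_a.size();

  for (int i = 0; i < ns; ++i) {
    int ia = S.seg_a[i] - 1, ib = S.seg_b[i] - 1;
    V3 a = getp(pos, ia), b = getp(pos, ib);
    V3 d = b - a;
    double len = norm(d);
    if (len < 1e-12) stop("degenerate zero-length segment");
    double tension = S.k_ext * (len - S.seg_rest[i]);
    O.seg_t[i] = tension;
    V3 u = (1.0 / len) * d;
    addf(F, ia, tension * u);
    addf(F, ib, (-tension) * u);
  }

  // angular bending: E = 0.5 * kappa * theta^2, theta = 0 when straight
  for (int i = 0; i < S.bend_trip.nrow(); ++i) {
    int ii = S.bend_trip(i, 0) - 1, jj = S.bend_trip(i, 1) - 1, kk = S.bend_trip(i, 2) - 1;
    V3 a = getp(pos, ii) - getp(pos, jj), b = getp(pos, kk) - getp(pos, jj);
    double la = norm(a), lb = norm(b);
    if (la < 1e-12 || lb < 1e-12) continue;
    V3 ah = (1.0 / la) * a, bh = (1.0 / lb) * b;
    double cosA = dot(ah, bh);
    if (cosA > 1.0) cosA = 1.0;
    if (cosA < -1.0) cosA = -1.0;
    double sinA = std::sqrt(std::max(1.0 - cosA * cosA, 1e-24));
    double theta = M_PI - std::acos(cosA);
    double coef = -S.k_bend * theta / sinA; // force = -grad E
    V3 gi = (1.0 / la) * (bh - cosA * ah);
    V3 gk = (1.0 / lb) * (ah - cosA * bh);
    addf(F, ii, coef * gi);
    addf(F, kk, coef * gk);
    addf(F, jj, (-1.0) * (coef * gi) + (-1.0) * (coef * gk));
  }

  // segment-segment excluded volume
  for (int p = 0; p < S.rep_pairs.nrow(); ++p) {
    int i = S.rep_pairs(p, 0) - 1, j = S.rep_pairs(p, 1) - 1;
    int ia = S.seg_a[i] - 1, ib = S.seg_b[i] - 1, ja = S.seg_a[j] - 1, jb = S.seg_b[j] - 1;
    V3 p1 = getp(pos, ia), q1 = getp(pos, ib), p2 = getp(pos, ja), q2 = getp(pos, jb);
    double s, t;
    seg_seg_closest(p1, q1, p2, q2, s, t);
    V3 cA = p1 + s * (q1 - p1), cB = p2 + t * (q2 - p2);
    V3 d = cA - cB;
    double dist = norm(d);
    if (dist >= S.r_rep || dist < 1e-9) continue;
    double fmag = S.k_rep * (S.r_rep - dist);
    V3 u = (1.0 / dist) * d;
    addf(F, ia, (fmag * (1.0 - s)) * u);
    addf(F, ib, (fmag * s) * u);
    addf(F, ja, (-fmag * (1.0 - t)) * u);
    addf(F, jb, (-fmag * t) * u);
  }

  // generic springs with interpolated endpoints; B side of anchor springs is
  // the membrane anchor point
  int nspr = S.spr_k.size();
  for (int s = 0; s < nspr; ++s) {
    V3 pA, pB;
    for (int c = 0; c < 3; ++c) {
      if (S.spr_ia(s, c) > 0) pA = pA + S.spr_wa(s, c) * getp(pos, S.spr_ia(s, c) - 1);
      if (S.spr_ib(s, c) > 0) pB = pB + S.spr_wb(s, c) * getp(pos, S.spr_ib(s, c) - 1);
    }
    V3 d = pB - pA;
    double len = norm(d);
    double tension = (len > 1e-10) ? S.spr_k[s] * (len - S.spr_rest[s]) : 0.0;
    O.spr_t[s] = tension;
    if (len > 1e-10) {
      V3 u = (1.0 / len) * d;
      V3 fA = tension * u;
      V3 fB = (-tension) * u;
      O.spr_fB(s, 0) = fB.x; O.spr_fB(s, 1) = fB.y; O.spr_fB(s, 2) = fB.z;
      for (int c = 0; c < 3; ++c) {
        if (S.spr_ia(s, c) > 0) addf(F, S.spr_ia(s, c) - 1, S.spr_wa(s, c) * fA);
        if (S.spr_ib(s, c) > 0) addf(F, S.spr_ib(s, c) - 1, S.spr_wb(s, c) * fB);
      }
    } else {
      O.spr_fB(s, 0) = 0; O.spr_fB(s, 1) = 0; O.spr_fB(s, 2) = 0;
    }
  }

  // membrane: per-face area elasticity and global volume penalty
  int nf = S.faces.nrow();
  double vol = 0.0;
  for (int f = 0; f < nf; ++f) {
    V3 a = getp(pos, S.faces(f, 0) - 1), b = getp(pos, S.faces(f, 1) - 1), c = getp(pos, S.faces(f, 2) - 1);
    V3 N = cross(b - a, c - a);
    O.area[f] = 0.5 * norm(N);
    vol += dot(a, cross(b, c)) / 6.0;
  }
  O.vol = vol;
  if (nf > 0 && (S.k_area > 0.0 || S.k_vol > 0.0)) {
    for (int f = 0; f < nf; ++f) {
      int ia = S.faces(f, 0) - 1, ib = S.faces(f, 1) - 1, ic = S.faces(f, 2) - 1;
      V3 a = getp(pos, ia), b = getp(pos, ib), c = getp(pos, ic);
      V3 N = cross(b - a, c - a);
      double nn = norm(N);
      if (nn < 1e-14) stop("degenerate zero-area membrane triangle");
      V3 nh = (1.0 / nn) * N;
      if (S.k_area > 0.0 && S.ref_area[f] > 0.0) {
        double coefA = -S.k_area * (O.area[f] - S.ref_area[f]) / S.ref_area[f];
        addf(F, ia, coefA * (0.5 * cross(nh, c - b)));
        addf(F, ib, coefA * (0.5 * cross(nh, a - c)));
        addf(F, ic, coefA * (0.5 * cross(nh, b - a)));
      }
      if (S.k_vol > 0.0 && S.ref_vol > 0.0) {
        double coefV = -S.k_vol * (vol - S.ref_vol) / S.ref_vol;
        addf(F, ia, (coefV / 6.0) * cross(b, c));
        addf(F, ib, (coefV / 6.0) * cross(c, a));
        addf(F, ic, (coefV / 6.0) * cross(a, b));
      }
    }
  }

  // dihedral bending about flat reference: E = 0.5*k*theta^2
  if (S.k_bend_mem > 0.0) {
    for (int e = 0; e < S.edge4.nrow(); ++e) {
      int i1 = S.edge4(e, 0) - 1, i2 = S.edge4(e, 1) - 1, i3 = S.edge4(e, 2) - 1, i4 = S.edge4(e, 3) - 1;
      V3 x1 = getp(pos, i1), x2 = getp(pos, i2), x3 = getp(pos, i3), x4 = getp(pos, i4);
      V3 e0 = x2 - x1, e1 = x3 - x1, e2 = x4 - x1, e3 = x3 - x2, e4 = x4 - x2;
      V3 n1 = cross(e0, e1);   // face (1,2,3)
      V3 n2 = cross(e2, e0);   // face (1,4,2)
      double l0 = norm(e0), ln1 = dot(n1, n1), ln2 = dot(n2, n2);
      if (l0 < 1e-12 || ln1 < 1e-20 || ln2 < 1e-20) continue;
      double sin_t = dot(cross(n1, n2), e0) / (std::sqrt(ln1 * ln2) * l0);
      double cos_t = dot(n1, n2) / std::sqrt(ln1 * ln2);
      double theta = std::atan2(sin_t, cos_t);
      double coef = S.k_bend_mem * theta; // gradient formulas below are for -theta
      V3 g3 = (l0 / ln1) * n1;
      V3 g4 = (l0 / ln2) * n2;
      V3 g1 = (dot(e0, e3) / (l0 * ln1)) * n1 + (dot(e0, e4) / (l0 * ln2)) * n2;
      V3 g2 = (-dot(e0, e1) / (l0 * ln1)) * n1 + (-dot(e0, e2) / (l0 * ln2)) * n2;
      addf(F, i1, coef * g1);
      addf(F, i2, coef * g2);
      addf(F, i3, coef * g3);
      addf(F, i4, coef * g4);
    }
  }

  // mesh-vertex vs filament-segment repulsion (keeps the cortex inside)
  for (int p = 0; p < S.mrep_pairs.nrow(); ++p) {
    int iv = S.mrep_pairs(p, 0) - 1;
    int js = S.mrep_pairs(p, 1) - 1;
    int ja = S.seg_a[js] - 1, jb = S.seg_b[js] - 1;
    V3 v = getp(pos, iv), a = getp(pos, ja), b = getp(pos, jb);
    V3 d = b - a;
    double dd = dot(d, d);
    double t = dd > 1e-14 ? clamp01(dot(v - a, d) / dd) : 0.0;
    V3 c = a + t * d;
    V3 w = v - c;
    double dist = norm(w);
    if (dist >= S.r_mrep || dist < 1e-9) continue;
    double fmag = S.k_mrep * (S.r_mrep - dist);
    V3 u = (1.0 / dist) * w;
    addf(F, iv, fmag * u);
    addf(F, ja, (-fmag * (1.0 - t)) * u);
    addf(F, jb, (-fmag * t) * u);
  }
}

static SysRef make_sysref(NumericMatrix pos,
                          IntegerVector seg_a, IntegerVector seg_b,
                          NumericVector seg_rest, double k_ext,
                          IntegerMatrix bend_trip, double k_bend,
                          IntegerMatrix rep_pairs, double r_rep, double k_rep,
                          IntegerMatrix spr_ia, NumericMatrix spr_wa,
                          IntegerMatrix spr_ib, NumericMatrix spr_wb,
                          NumericVector spr_k, NumericVector spr_rest,
                          IntegerMatrix faces, NumericVector ref_area, double k_area,
                          IntegerMatrix edge4, double k_bend_mem,
                          double ref_vol, double k_vol,
                          IntegerMatrix mrep_pairs, double r_mrep, double k_mrep) {
  SysRef S{pos, seg_a, seg_b, seg_rest, k_ext, bend_trip, k_bend, rep_pairs,
           r_rep, k_rep, spr_ia, spr_ib, spr_wa, spr_wb, spr_k, spr_rest,
           faces, ref_area, k_area, edge4, k_bend_mem, ref_vol, k_vol,
           mrep_pairs, r_mrep, k_mrep};
  return S;
}

// Full force evaluation (single call).
// [[Rcpp::export]]
List net_forces_cpp(NumericMatrix pos,
                    IntegerVector seg_a, IntegerVector seg_b,
                    NumericVector seg_rest, double k_ext,
                    IntegerMatrix bend_trip, double k_bend,
                    IntegerMatrix rep_pairs, double r_rep, double k_rep,
                    IntegerMatrix spr_ia, NumericMatrix spr_wa,
                    IntegerMatrix spr_ib, NumericMatrix spr_wb,
                    NumericVector spr_k, NumericVector spr_rest,
                    IntegerMatrix faces, NumericVector ref_area, double k_area,
                    IntegerMatrix edge4, double k_bend_mem,
                    double ref_vol, double k_vol,
                    IntegerMatrix mrep_pairs, double r_mrep, double k_mrep) {
  SysRef S = make_sysref(pos, seg_a, seg_b, seg_rest, k_ext, bend_trip, k_bend,
                         rep_pairs, r_rep, k_rep, spr_ia, spr_wa, spr_ib,
                         spr_wb, spr_k, spr_rest, faces, ref_area, k_area,
                         edge4, k_bend_mem, ref_vol, k_vol, mrep_pairs,
                         r_mrep, k_mrep);
  ForceOut O{NumericMatrix(pos.nrow(), 3), NumericVector(seg_a.size()),
             NumericVector(spr_k.size()), NumericVector(faces.nrow()),
             NumericMatrix(spr_k.size(), 3), 0.0};
  compute_forces(S, O);
  return List::create(_["F"] = O.F, _["seg_tension"] = O.seg_t,
                      _["spr_tension"] = O.spr_t, _["spr_fB"] = O.spr_fB,
                      _["volume"] = O.vol, _["face_area"] = O.area);
}

// Fused overdamped Euler-Maruyama inner loop: n_steps of force evaluation,
// position update, optional radial clamping of filament nodes, and
// tangential sliding of membrane anchor points (fluid membrane). `noise` has
// n_steps * n rows of pre-drawn standard normals (R's RNG). Anchor springs
// are identified by `an_rows` (1-based rows of the spring table); their face
// ids and barycentric weights are updated in place.
// [[Rcpp::export]]
List run_chunk_cpp(NumericMatrix pos,
                   IntegerVector seg_a, IntegerVector seg_b,
                   NumericVector seg_rest, double k_ext,
                   IntegerMatrix bend_trip, double k_bend,
                   IntegerMatrix rep_pairs, double r_rep, double k_rep,
                   IntegerMatrix spr_ia, NumericMatrix spr_wa,
                   IntegerMatrix spr_ib, NumericMatrix spr_wb,
                   NumericVector spr_k, NumericVector spr_rest,
                   IntegerMatrix faces, NumericVector ref_area, double k_area,
                   IntegerMatrix edge4, double k_bend_mem,
                   double ref_vol, double k_vol,
                   IntegerMatrix mrep_pairs, double r_mrep, double k_mrep,
                   int n_steps, double dt, NumericVector zeta,
                   NumericMatrix noise, bool membrane_active,
                   int n_fil, int mesh_off,
                   NumericVector clamp_band,      // length 0 or 2
                   IntegerVector an_rows,         // anchor spring rows, 1-based
                   IntegerVector an_face,         // current face per anchor
                   IntegerMatrix meshF,           // mesh faces, 1-based vertex ids
                   IntegerMatrix face_adj,        // neighbor across edge opp. vertex k
                   double anchor_drag, double max_disp) {
  int n = pos.nrow();
  SysRef S = make_sysref(pos, seg_a, seg_b, seg_rest, k_ext, bend_trip, k_bend,
                         rep_pairs, r_rep, k_rep, spr_ia, spr_wa, spr_ib,
                         spr_wb, spr_k, spr_rest, faces, ref_area, k_area,
                         edge4, k_bend_mem, ref_vol, k_vol, mrep_pairs,
                         r_mrep, k_mrep);
  ForceOut O{NumericMatrix(n, 3), NumericVector(seg_a.size()),
             NumericVector(spr_k.size()), NumericVector(faces.nrow()),
             NumericMatrix(spr_k.size(), 3), 0.0};
  int n_an = an_rows.size();
  bool do_clamp = clamp_band.size() == 2;
  double worst = 0.0;
  bool unstable = false;

  for (int step = 0; step < n_steps && !unstable; ++step) {
    compute_forces(S, O);
    int off = step * n;
    for (int i = 0; i < n; ++i) {
      bool frozen = (!membrane_active) && i >= mesh_off;
      if (frozen) continue;
      double mob = dt / zeta[i];
      for (int c = 0; c < 3; ++c) {
        double d = O.F(i, c) * mob + noise(off + i, c);
        if (std::fabs(d) > worst) worst = std::fabs(d);
        pos(i, c) += d;
      }
    }
    if (worst > max_disp) { unstable = true; break; }
    if (do_clamp) {
      for (int i = 0; i < n_fil; ++i) {
        double r = std::sqrt(pos(i,0)*pos(i,0) + pos(i,1)*pos(i,1) + pos(i,2)*pos(i,2));
        if (r < 1e-12) continue;
        double rc = r < clamp_band[0] ? clamp_band[0] : (r > clamp_band[1] ? clamp_band[1] : r);
        if (rc != r) {
          double s = rc / r;
          pos(i,0) *= s; pos(i,1) *= s; pos(i,2) *= s;
        }
      }
    }
    if (membrane_active) {
      for (int q = 0; q < n_an; ++q) {
        int srow = an_rows[q] - 1;
        int face = an_face[q] - 1;
        int va = mesh_off + meshF(face, 0) - 1;
        int vb = mesh_off + meshF(face, 1) - 1;
        int vc = mesh_off + meshF(face, 2) - 1;
        V3 a = getp(pos, va), b = getp(pos, vb), c = getp(pos, vc);
        V3 pt = spr_wb(srow, 0) * a + spr_wb(srow, 1) * b + spr_wb(srow, 2) * c;
        V3 e1 = b - a, e2 = c - a;
        V3 nh = cross(e1, e2);
        double nn = norm(nh);
        if (nn < 1e-14) continue;
        nh = (1.0 / nn) * nh;
        V3 fB(O.spr_fB(srow, 0), O.spr_fB(srow, 1), O.spr_fB(srow, 2));
        V3 ft = fB - dot(fB, nh) * nh;
        V3 np = pt + (dt / anchor_drag) * ft;
        // barycentric on current face
        V3 d = np - a;
        double g11 = dot(e1, e1), g12 = dot(e1, e2), g22 = dot(e2, e2);
        double det = g11 * g22 - g12 * g12;
        if (det < 1e-300) continue;
        double u = (dot(d, e1) * g22 - dot(d, e2) * g12) / det;
        double v = (dot(d, e2) * g11 - dot(d, e1) * g12) / det;
        double w0 = 1.0 - u - v;
        if (w0 < -1e-9 || u < -1e-9 || v < -1e-9) {
          // hop across the edge opposite the most negative weight
          int k = 0; double wmin = w0;
          if (u < wmin) { wmin = u; k = 1; }
          if (v < wmin) { wmin = v; k = 2; }
          int nf = face_adj(face, k) - 1;
          int wa2 = mesh_off + meshF(nf, 0) - 1;
          int wb2 = mesh_off + meshF(nf, 1) - 1;
          int wc2 = mesh_off + meshF(nf, 2) - 1;
          V3 a2 = getp(pos, wa2), b2 = getp(pos, wb2), c2 = getp(pos, wc2);
          V3 E1 = b2 - a2, E2 = c2 - a2, D = np - a2;
          double h11 = dot(E1, E1), h12 = dot(E1, E2), h22 = dot(E2, E2);
          double det2 = h11 * h22 - h12 * h12;
          if (det2 > 1e-300) {
            u = (dot(D, E1) * h22 - dot(D, E2) * h12) / det2;
            v = (dot(D, E2) * h11 - dot(D, E1) * h12) / det2;
            w0 = 1.0 - u - v;
            face = nf;
            an_face[q] = nf + 1;
            spr_ib(srow, 0) = wa2 + 1; spr_ib(srow, 1) = wb2 + 1; spr_ib(srow, 2) = wc2 + 1;
          }
        }
        if (w0 < 0) w0 = 0;
        if (u < 0) u = 0;
        if (v < 0) v = 0;
        double s = w0 + u + v;
        if (s < 1e-12) { w0 = 1; u = 0; v = 0; s = 1; }
        spr_wb(srow, 0) = w0 / s; spr_wb(srow, 1) = u / s; spr_wb(srow, 2) = v / s;
      }
    }
  }
  return List::create(
    _["pos"] = pos, _["unstable"] = unstable, _["max_disp"] = worst,
    _["an_face"] = an_face, _["spr_ib"] = spr_ib, _["spr_wb"] = spr_wb,
    _["F"] = O.F, _["seg_tension"] = O.seg_t, _["spr_tension"] = O.spr_t,
    _["spr_fB"] = O.spr_fB, _["volume"] = O.vol, _["face_area"] = O.area);
}
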