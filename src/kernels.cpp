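#include <Rcpp.h>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Point / segment / polyline queries
// ---------------------------------------------------------------------------

static inline double sq(double x) { return x * x; }

// closest point on segment ab to p; returns squared distance, writes the
// parameter t in [0,1]
static double seg_query(const double* p, const double* a, const double* b,
                        double* t_out) {
  double ab[3] = { b[0] - a[0], b[1] - a[1], b[2] - a[2] };
  double ap[3] = { p[0] - a[0], p[1] - a[1], p[2] - a[2] };
  double denom = ab[0] * ab[0] + ab[1] * ab[1] + ab[2] * ab[2];
  double t = 0.0;
  if (denom > 0.0) {
    t = (ap[0] * ab[0] + ap[1] * ab[1] + ap[2] * ab[2]) / denom;
    if (t < 0.0) t = 0.0;
    if (t > 1.0) t = 1.0;
  }
  double d2 = sq(p[0] - (a[0] + t * ab[0])) + sq(p[1] - (a[1] + t * ab[1])) +
              sq(p[2] - (a[2] + t * ab[2]));
  *t_out = t;
  return d2;
}

struct PolyQuery {
  double dist, arclen;
  int seg;               // 0-based segment index
  double nearest[3];
};

// exact minimum over all segments; ties resolved toward the smaller segment
// index by strict-improvement updates in segment order
static PolyQuery polyline_query(const double* p, const NumericMatrix& line,
                                const std::vector<double>& cum) {
  int n = line.nrow();
  PolyQuery q;
  q.dist = R_PosInf; q.arclen = 0.0; q.seg = 0;
  q.nearest[0] = line(0, 0); q.nearest[1] = line(0, 1); q.nearest[2] = line(0, 2);
  for (int i = 0; i + 1 < n; ++i) {
    double a[3] = { line(i, 0), line(i, 1), line(i, 2) };
    double b[3] = { line(i + 1, 0), line(i + 1, 1), line(i + 1, 2) };
    double t, d2 = seg_query(p, a, b, &t);
    double d = std::sqrt(d2);
    if (d < q.dist - 1e-15) {
      q.dist = d;
      q.seg = i;
      q.arclen = cum[i] + t * (cum[i + 1] - cum[i]);
      for (int k = 0; k < 3; ++k) q.nearest[k] = a[k] + t * (b[k] - a[k]);
    }
  }
  return q;
}

static std::vector<double> cum_arclength(const NumericMatrix& line) {
  int n = line.nrow();
  std::vector<double> cum(n, 0.0);
  for (int i = 1; i < n; ++i) {
    cum[i] = cum[i - 1] + std::sqrt(sq(line(i, 0) - line(i - 1, 0)) +
                                    sq(line(i, 1) - line(i - 1, 1)) +
                                    sq(line(i, 2) - line(i - 1, 2)));
  }
  return cum;
}

// point on polyline at arc length s (clamped to [0, total])
static void point_at_arclength(const NumericMatrix& line,
                               const std::vector<double>& cum, double s,
                               double* out) {
  int n = line.nrow();
  if (s <= 0) { for (int k = 0; k < 3; ++k) out[k] = line(0, k); return; }
  if (s >= cum[n - 1]) { for (int k = 0; k < 3; ++k) out[k] = line(n - 1, k); return; }
  int i = 1;
  while (cum[i] < s) ++i;
  double t = (s - cum[i - 1]) / (cum[i] - cum[i - 1]);
  for (int k = 0; k < 3; ++k)
    out[k] = line(i - 1, k) + t * (line(i, k) - line(i - 1, k));
}

// [[Rcpp::export]]
NumericMatrix cpp_polyline_query(NumericMatrix pts, NumericMatrix line) {
  std::vector<double> cum = cum_arclength(line);
  int m = pts.nrow();
  NumericMatrix out(m, 6);  // dist, arclen, seg (1-based), nx, ny, nz
  for (int j = 0; j < m; ++j) {
    double p[3] = { pts(j, 0), pts(j, 1), pts(j, 2) };
    PolyQuery q = polyline_query(p, line, cum);
    out(j, 0) = q.dist; out(j, 1) = q.arclen; out(j, 2) = q.seg + 1;
    out(j, 3) = q.nearest[0]; out(j, 4) = q.nearest[1]; out(j, 5) = q.nearest[2];
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_point_at_arclength(NumericMatrix line, NumericVector s) {
  std::vector<double> cum = cum_arclength(line);
  int m = s.size();
  NumericMatrix out(m, 3);
  for (int j = 0; j < m; ++j) {
    double p[3];
    point_at_arclength(line, cum, s[j], p);
    out(j, 0) = p[0]; out(j, 1) = p[1]; out(j, 2) = p[2];
  }
  return out;
}

// ---------------------------------------------------------------------------
// Signed distance to analytic organ primitives
// organ row encoding (8 columns):
//   sphere : 1, cx, cy, cz,  -,  -,  -, r
//   capsule: 2, ax, ay, az, bx, by, bz, r
//   box    : 3, cx, cy, cz, hx, hy, hz, -   (axis-aligned half extents)
// ---------------------------------------------------------------------------

static double organ_sdf(const double* p, const double* row) {
  int code = (int)row[0];
  if (code == 1) {
    return std::sqrt(sq(p[0] - row[1]) + sq(p[1] - row[2]) + sq(p[2] - row[3])) -
           row[7];
  } else if (code == 2) {
    double a[3] = { row[1], row[2], row[3] }, b[3] = { row[4], row[5], row[6] };
    double t;
    return std::sqrt(seg_query(p, a, b, &t)) - row[7];
  } else if (code == 3) {
    double q[3];
    for (int k = 0; k < 3; ++k) q[k] = std::fabs(p[k] - row[1 + k]) - row[4 + k];
    double outside = std::sqrt(sq(std::max(q[0], 0.0)) + sq(std::max(q[1], 0.0)) +
                               sq(std::max(q[2], 0.0)));
    double inside = std::min(std::max(q[0], std::max(q[1], q[2])), 0.0);
    return outside + inside;
  }
  Rcpp::stop("unsupported organ shape code");
  return NA_REAL;
}

// [[Rcpp::export]]
NumericVector cpp_organ_sdf(NumericMatrix pts, NumericVector row) {
  int m = pts.nrow();
  NumericVector out(m);
  std::vector<double> r(row.begin(), row.end());
  for (int j = 0; j < m; ++j) {
    double p[3] = { pts(j, 0), pts(j, 1), pts(j, 2) };
    out[j] = organ_sdf(p, r.data());
  }
  return out;
}

// minimum signed distance over all organs + 1-based argmin
// [[Rcpp::export]]
NumericMatrix cpp_min_organ_sdf(NumericMatrix pts, NumericMatrix organs) {
  int m = pts.nrow(), no = organs.nrow();
  NumericMatrix out(m, 2);
  for (int j = 0; j < m; ++j) {
    double p[3] = { pts(j, 0), pts(j, 1), pts(j, 2) };
    double best = R_PosInf; int arg = 0;
    for (int i = 0; i < no; ++i) {
      double row[8];
      for (int k = 0; k < 8; ++k) row[k] = organs(i, k);
      double d = organ_sdf(p, row);
      if (d < best) { best = d; arg = i; }
    }
    out(j, 0) = best; out(j, 1) = arg + 1;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Deterministic RNG (PCG32 + polar Box-Muller), independent of R's RNG so
// cohort simulation is reproducible across platforms and R versions
// ---------------------------------------------------------------------------

struct Pcg32 {
  uint64_t state, inc;
  Pcg32(uint32_t seed) {
    state = 0u; inc = (0xda3e39cb94b95bdbULL << 1u) | 1u;
    next(); state += (0x853c49e6748fea9bULL ^ (uint64_t)seed); next();
  }
  uint32_t next() {
    uint64_t old = state;
    state = old * 6364136223846793005ULL + inc;
    uint32_t xorshifted = (uint32_t)(((old >> 18u) ^ old) >> 27u);
    uint32_t rot = (uint32_t)(old >> 59u);
    return (xorshifted >> rot) | (xorshifted << ((-rot) & 31));
  }
  double unif() { return (next() + 0.5) * (1.0 / 4294967296.0); }
  bool has_spare = false;
  double spare = 0.0;
  double normal() {
    if (has_spare) { has_spare = false; return spare; }
    double u, v, s;
    do {
      u = 2.0 * unif() - 1.0;
      v = 2.0 * unif() - 1.0;
      s = u * u + v * v;
    } while (s >= 1.0 || s == 0.0);
    double f = std::sqrt(-2.0 * std::log(s) / s);
    spare = v * f; has_spare = true;
    return u * f;
  }
};

// rotate unit vector d by angle theta about a random axis perpendicular to d
static void perturb_direction(double* d, double theta, double psi) {
  double ref[3] = { 0.0, 0.0, 0.0 };
  if (std::fabs(d[0]) < 0.9) ref[0] = 1.0; else ref[1] = 1.0;
  // e1 = normalize(d x ref), e2 = d x e1
  double e1[3] = { d[1] * ref[2] - d[2] * ref[1],
                   d[2] * ref[0] - d[0] * ref[2],
                   d[0] * ref[1] - d[1] * ref[0] };
  double n1 = std::sqrt(sq(e1[0]) + sq(e1[1]) + sq(e1[2]));
  for (int k = 0; k < 3; ++k) e1[k] /= n1;
  double e2[3] = { d[1] * e1[2] - d[2] * e1[1],
                   d[2] * e1[0] - d[0] * e1[2],
                   d[0] * e1[1] - d[1] * e1[0] };
  double ax[3];
  for (int k = 0; k < 3; ++k) ax[k] = std::cos(psi) * e1[k] + std::sin(psi) * e2[k];
  // Rodrigues with ax . d = 0
  double axd[3] = { ax[1] * d[2] - ax[2] * d[1],
                    ax[2] * d[0] - ax[0] * d[2],
                    ax[0] * d[1] - ax[1] * d[0] };
  double c = std::cos(theta), s = std::sin(theta);
  for (int k = 0; k < 3; ++k) d[k] = c * d[k] + s * axd[k];
}

// ---------------------------------------------------------------------------
// Fast agent session runner.  Mirrors the semantics of the R-level step():
// move -> containment -> event on inside->outside -> optional snap -> stop
// when within completion_eps of the destination or at max_time.
//
// mode: tube fixture if radius > 0 (organs ignored); free mode otherwise
// (collision against organs, path used for guidance/correction only).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_agent_session(NumericMatrix path, double radius, NumericMatrix organs,
                       double sigma, double lookahead, double dt,
                       double base_speed, double speed_mult,
                       double completion_eps, double max_time,
                       bool correction, double correction_threshold,
                       int seed, bool log_positions) {
  std::vector<double> cum = cum_arclength(path);
  double total_len = cum.back();
  int n_path = path.nrow();
  double dest[3] = { path(n_path - 1, 0), path(n_path - 1, 1), path(n_path - 1, 2) };
  double tip[3] = { path(0, 0), path(0, 1), path(0, 2) };
  bool fixture_mode = radius > 0.0;
  Pcg32 rng((uint32_t)seed);

  int max_steps = (int)std::llround(max_time / dt);
  double step_len = base_speed * speed_mult * dt;

  bool inside = true;
  int n_coll = 0, steps = 0;
  bool completed = false;
  double completion_time = max_time;

  std::vector<double> ev;   // t, x, y, z, penetration, segment, source, organ
  std::vector<double> logv; // x, y, z, snapped flag

  while (steps < max_steps) {
    PolyQuery qg = polyline_query(tip, path, cum);
    double target_s = qg.arclen + lookahead;
    if (target_s > total_len) target_s = total_len;
    double target[3];
    point_at_arclength(path, cum, target_s, target);
    double dir[3] = { target[0] - tip[0], target[1] - tip[1], target[2] - tip[2] };
    double nrm = std::sqrt(sq(dir[0]) + sq(dir[1]) + sq(dir[2]));
    if (nrm > 1e-12) {
      for (int k = 0; k < 3; ++k) dir[k] /= nrm;
      if (sigma > 0.0) {
        double theta = sigma * rng.normal();
        double psi = 2.0 * M_PI * rng.unif();
        perturb_direction(dir, theta, psi);
      }
      for (int k = 0; k < 3; ++k) tip[k] += dir[k] * step_len;
    }
    ++steps;
    double t_now = steps * dt;

    // containment + event
    double penetration = 0.0; int segment = 0, organ_idx = 0, source = 0;
    bool unsafe;
    if (fixture_mode) {
      PolyQuery q = polyline_query(tip, path, cum);
      penetration = q.dist - radius;
      segment = q.seg + 1;
      source = 1;
      unsafe = penetration > 0.0;
    } else {
      double best = R_PosInf;
      for (int i = 0; i < organs.nrow(); ++i) {
        double row[8];
        for (int k = 0; k < 8; ++k) row[k] = organs(i, k);
        double d = organ_sdf(tip, row);
        if (d < best) { best = d; organ_idx = i + 1; }
      }
      penetration = -best;
      source = 2;
      unsafe = penetration > 0.0;
    }
    if (inside && unsafe) {
      ++n_coll;
      ev.push_back(t_now); ev.push_back(tip[0]); ev.push_back(tip[1]);
      ev.push_back(tip[2]); ev.push_back(penetration);
      ev.push_back(fixture_mode ? segment : 0);
      ev.push_back(source); ev.push_back(fixture_mode ? 0 : organ_idx);
    }
    inside = !unsafe;

    // position correction against the guidance path
    bool snapped = false;
    if (correction) {
      PolyQuery qc = polyline_query(tip, path, cum);
      if (qc.dist > correction_threshold) {
        for (int k = 0; k < 3; ++k) tip[k] = qc.nearest[k];
        snapped = true;
        if (fixture_mode) {
          inside = true;  // snapped onto the centerline
        } else {
          double best = R_PosInf;
          for (int i = 0; i < organs.nrow(); ++i) {
            double row[8];
            for (int k = 0; k < 8; ++k) row[k] = organs(i, k);
            double d = organ_sdf(tip, row);
            if (d < best) best = d;
          }
          inside = !(best < 0.0);
        }
      }
    }
    if (log_positions) {
      logv.push_back(tip[0]); logv.push_back(tip[1]); logv.push_back(tip[2]);
      logv.push_back(snapped ? 1.0 : 0.0);
    }

    double dd = std::sqrt(sq(tip[0] - dest[0]) + sq(tip[1] - dest[1]) +
                          sq(tip[2] - dest[2]));
    if (dd <= completion_eps) {
      completed = true;
      completion_time = t_now;
      break;
    }
  }

  int n_ev = (int)(ev.size() / 8);
  NumericMatrix events(n_ev, 8);
  for (int i = 0; i < n_ev; ++i)
    for (int k = 0; k < 8; ++k) events(i, k) = ev[i * 8 + k];
  List out = List::create(
    _["n_collisions"] = n_coll, _["completion_time"] = completion_time,
    _["completed"] = completed, _["n_steps"] = steps, _["events"] = events);
  if (log_positions) {
    int nl = (int)(logv.size() / 4);
    NumericMatrix lg(nl, 4);
    for (int i = 0; i < nl; ++i)
      for (int k = 0; k < 4; ++k) lg(i, k) = logv[i * 4 + k];
    out["positions"] = lg;
  }
  return out;
}
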