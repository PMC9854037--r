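// Analog photon transport with collision-kerma track-length scoring.
//
// Geometry: optional nested-cylinder source (active core inside a capsule,
// drive-cable stub on the proximal end) at the center of either a water
// sphere or an air cube. Physics: Compton scattering on free stationary
// electrons (Klein-Nishina), photoelectric absorption, pair production with
// isotropic re-emission of the two 0.511 MeV annihilation photons at the
// interaction site. Photons are terminated below the energy cutoff or on
// leaving the world volume. Uses R's RNG stream, so runs are reproducible
// from set.seed().

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

static const double EMASS = 0.51099895;            // MeV
static const double BIG = 1e30;

// ---- Klein-Nishina ---------------------------------------------------------

static double kn_total_cpp(double E) {
  double a = E / EMASS;
  double re2 = 2.8179403262e-13 * 2.8179403262e-13;
  double l = std::log(1.0 + 2.0 * a);
  double t1 = (1.0 + a) / (a * a) *
              (2.0 * (1.0 + a) / (1.0 + 2.0 * a) - l / a);
  double t2 = l / (2.0 * a);
  double t3 = (1.0 + 3.0 * a) / ((1.0 + 2.0 * a) * (1.0 + 2.0 * a));
  return 2.0 * M_PI * re2 * (t1 + t2 - t3);
}

// composition-rejection sampling of the scattered-photon energy fraction
static void kn_sample(double E, double &Eout, double &cost) {
  double a = E / EMASS;
  double e0 = 1.0 / (1.0 + 2.0 * a);
  double a1 = -std::log(e0);
  double a2 = 0.5 * (1.0 - e0 * e0);
  double eps, greject;
  do {
    if (unif_rand() * (a1 + a2) < a1)
      eps = std::exp(-a1 * unif_rand());
    else
      eps = std::sqrt(e0 * e0 + (1.0 - e0 * e0) * unif_rand());
    double t = (1.0 - eps) / (a * eps);
    double sint2 = t * (2.0 - t);
    greject = 1.0 - eps * sint2 / (1.0 + eps * eps);
  } while (greject < unif_rand());
  Eout = eps * E;
  cost = 1.0 - (1.0 - eps) / (a * eps);
}

// [[Rcpp::export]]
NumericVector cpp_kn_total(NumericVector energy) {
  NumericVector out(energy.size());
  for (int i = 0; i < energy.size(); ++i) out[i] = kn_total_cpp(energy[i]);
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_kn_sample(double energy, int n) {
  NumericMatrix out(n, 2);
  for (int i = 0; i < n; ++i) {
    double E1, c1;
    kn_sample(energy, E1, c1);
    out(i, 0) = E1;
    out(i, 1) = c1;
  }
  return out;
}

// ---- interpolation ---------------------------------------------------------

struct LogTable {
  std::vector<double> logE;
  std::vector<std::vector<double> > logY;  // one column per material
  double interp(int mat, double logx) const {
    const std::vector<double> &y = logY[mat];
    int n = (int)logE.size();
    if (logx <= logE[0]) return std::exp(y[0]);
    if (logx >= logE[n - 1]) return std::exp(y[n - 1]);
    int lo = (int)(std::lower_bound(logE.begin(), logE.end(), logx) -
                   logE.begin()) - 1;
    double f = (logx - logE[lo]) / (logE[lo + 1] - logE[lo]);
    return std::exp(y[lo] + f * (y[lo + 1] - y[lo]));
  }
};

// ---- geometry --------------------------------------------------------------

struct Geom {
  bool has_source;
  double core_r, core_zlo, core_zhi;
  double cap_r, cap_zlo, cap_zhi;
  double cab_r, cab_zlo, cab_zhi;
  int world_type;       // 0 sphere, 1 cube
  double world_size;    // radius or half-side
};

// material index at a point: 0 core, 1 capsule, 2 cable, 3 surrounding,
// -1 outside world
static int classify(const Geom &g, double x, double y, double z) {
  if (g.has_source) {
    double r2 = x * x + y * y;
    if (r2 <= g.core_r * g.core_r && z >= g.core_zlo && z <= g.core_zhi)
      return 0;
    if (r2 <= g.cap_r * g.cap_r && z >= g.cap_zlo && z <= g.cap_zhi)
      return 1;
    if (r2 <= g.cab_r * g.cab_r && z >= g.cab_zlo && z <= g.cab_zhi)
      return 2;
  }
  if (g.world_type == 0) {
    if (x * x + y * y + z * z < g.world_size * g.world_size) return 3;
  } else {
    if (std::fabs(x) < g.world_size && std::fabs(y) < g.world_size &&
        std::fabs(z) < g.world_size)
      return 3;
  }
  return -1;
}

static double world_exit(const Geom &g, const double p[3], const double d[3]) {
  if (g.world_type == 0) {
    double b = p[0] * d[0] + p[1] * d[1] + p[2] * d[2];
    double c = p[0] * p[0] + p[1] * p[1] + p[2] * p[2] -
               g.world_size * g.world_size;
    double disc = b * b - c;
    if (disc <= 0) return 0.0;
    return -b + std::sqrt(disc);
  }
  double tmin = BIG;
  for (int i = 0; i < 3; ++i) {
    if (std::fabs(d[i]) > 1e-14) {
      double bound = d[i] > 0 ? g.world_size : -g.world_size;
      double t = (bound - p[i]) / d[i];
      if (t < tmin) tmin = t;
    }
  }
  return tmin;
}

static void push_cyl_ts(std::vector<double> &ts, const double p[3],
                        const double d[3], double R, double zlo, double zhi,
                        double tmax) {
  double a = d[0] * d[0] + d[1] * d[1];
  if (a > 1e-14) {
    double b = p[0] * d[0] + p[1] * d[1];
    double c = p[0] * p[0] + p[1] * p[1] - R * R;
    double disc = b * b - a * c;
    if (disc > 0) {
      double sq = std::sqrt(disc);
      double t1 = (-b - sq) / a, t2 = (-b + sq) / a;
      if (t1 > 0 && t1 < tmax) ts.push_back(t1);
      if (t2 > 0 && t2 < tmax) ts.push_back(t2);
    }
  }
  if (std::fabs(d[2]) > 1e-14) {
    double t1 = (zlo - p[2]) / d[2], t2 = (zhi - p[2]) / d[2];
    if (t1 > 0 && t1 < tmax) ts.push_back(t1);
    if (t2 > 0 && t2 < tmax) ts.push_back(t2);
  }
}

static void boundary_ts(const Geom &g, const double p[3], const double d[3],
                        double tmax, std::vector<double> &ts) {
  ts.clear();
  if (g.has_source) {
    push_cyl_ts(ts, p, d, g.core_r, g.core_zlo, g.core_zhi, tmax);
    push_cyl_ts(ts, p, d, g.cap_r, g.cap_zlo, g.cap_zhi, tmax);
    if (g.cab_r > 0 && g.cab_zhi > g.cab_zlo)
      push_cyl_ts(ts, p, d, g.cab_r, g.cab_zlo, g.cab_zhi, tmax);
  }
  ts.push_back(tmax);
  std::sort(ts.begin(), ts.end());
}

// ---- ray / annulus-slab intersection length -------------------------------

struct Cell {
  double rin2, rout2, zlo, zhi;
};

// length of {t in [ta,tb] : radial in [rin,rout], z in [zlo,zhi]}
static double cell_overlap(const Cell &c, const double p[3], const double d[3],
                           double ta, double tb) {
  // z slab
  double lo = ta, hi = tb;
  if (std::fabs(d[2]) > 1e-14) {
    double t1 = (c.zlo - p[2]) / d[2], t2 = (c.zhi - p[2]) / d[2];
    if (t1 > t2) std::swap(t1, t2);
    lo = std::max(lo, t1);
    hi = std::min(hi, t2);
  } else if (p[2] < c.zlo || p[2] > c.zhi) {
    return 0.0;
  }
  if (hi <= lo) return 0.0;
  double a = d[0] * d[0] + d[1] * d[1];
  double b = p[0] * d[0] + p[1] * d[1];
  double c0 = p[0] * p[0] + p[1] * p[1];
  double outer = 0.0, inner = 0.0;
  if (a > 1e-14) {
    double disc = b * b - a * (c0 - c.rout2);
    if (disc <= 0) return 0.0;
    double sq = std::sqrt(disc);
    double o1 = std::max(lo, (-b - sq) / a), o2 = std::min(hi, (-b + sq) / a);
    outer = std::max(0.0, o2 - o1);
    if (outer <= 0) return 0.0;
    double disci = b * b - a * (c0 - c.rin2);
    if (disci > 0) {
      double sqi = std::sqrt(disci);
      double i1 = std::max(lo, (-b - sqi) / a),
             i2 = std::min(hi, (-b + sqi) / a);
      inner = std::max(0.0, i2 - i1);
    }
    return outer - inner;
  }
  // ray parallel to axis: radial coordinate constant
  if (c0 >= c.rin2 && c0 <= c.rout2) return hi - lo;
  return 0.0;
}

// ---- main simulation -------------------------------------------------------

struct Photon {
  double p[3], d[3], E;
};

static void iso_dir(double d[3]) {
  double ct = 2.0 * unif_rand() - 1.0;
  double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
  double ph = 2.0 * M_PI * unif_rand();
  d[0] = st * std::cos(ph);
  d[1] = st * std::sin(ph);
  d[2] = ct;
}

static void rotate_dir(double d[3], double cost, double phi) {
  double sint = std::sqrt(std::max(0.0, 1.0 - cost * cost));
  double u = d[0], v = d[1], w = d[2];
  double sp = std::sin(phi), cp = std::cos(phi);
  double s = std::sqrt(std::max(1e-30, 1.0 - w * w));
  double nx, ny, nz;
  if (s > 1e-10) {
    nx = u * cost + sint * (u * w * cp - v * sp) / s;
    ny = v * cost + sint * (v * w * cp + u * sp) / s;
    nz = w * cost - sint * s * cp;
  } else {  // nearly parallel to z
    nx = sint * cp;
    ny = sint * sp;
    nz = (w > 0 ? 1.0 : -1.0) * cost;
  }
  double nn = std::sqrt(nx * nx + ny * ny + nz * nz);
  d[0] = nx / nn; d[1] = ny / nn; d[2] = nz / nn;
}

// args:
//  src        : c(has_source, core_r, core_zlo, core_zhi, cap_r, cap_zlo,
//               cap_zhi, cab_r, cab_zlo, cab_zhi)
//  world      : c(type, size)   type 0 sphere / 1 cube
//  cells      : matrix (rin, rout, zlo, zhi) per row
//  loge, logmu: energy grid (log MeV) and log linear attenuation (1/cm),
//               one column per material 0..3 (core, capsule, cable, medium)
//  logmuen    : log mass energy-absorption (cm^2/g) of the scoring medium
//  ne         : electrons per cm^3 per material (Compton split)
//  elines     : photon line energies per decay (MeV)
// [[Rcpp::export]]
List cpp_run_sim(NumericVector src, NumericVector world, NumericMatrix cells,
                 NumericVector loge, NumericMatrix logmu,
                 NumericVector logmuen, NumericVector ne,
                 NumericVector elines, double n_decays, int nbatch,
                 bool primary_only, double cutoff) {
  Geom g;
  g.has_source = src[0] > 0.5;
  g.core_r = src[1]; g.core_zlo = src[2]; g.core_zhi = src[3];
  g.cap_r = src[4]; g.cap_zlo = src[5]; g.cap_zhi = src[6];
  g.cab_r = src[7]; g.cab_zlo = src[8]; g.cab_zhi = src[9];
  g.world_type = (int)world[0];
  g.world_size = world[1];

  int ncell = cells.nrow();
  std::vector<Cell> cs(ncell);
  for (int i = 0; i < ncell; ++i) {
    cs[i].rin2 = cells(i, 0) * cells(i, 0);
    cs[i].rout2 = cells(i, 1) * cells(i, 1);
    cs[i].zlo = cells(i, 2);
    cs[i].zhi = cells(i, 3);
  }

  LogTable mu;
  mu.logE.assign(loge.begin(), loge.end());
  int nmat = logmu.ncol();
  mu.logY.resize(nmat);
  for (int m = 0; m < nmat; ++m)
    mu.logY[m].assign(logmu.column(m).begin(), logmu.column(m).end());
  LogTable men;
  men.logE = mu.logE;
  men.logY.resize(1);
  men.logY[0].assign(logmuen.begin(), logmuen.end());

  std::vector<double> batch(ncell, 0.0), tally(ncell, 0.0),
      bsum(ncell, 0.0), bsum2(ncell, 0.0);
  double emitted = 0.0, absorbed = 0.0, escaped = 0.0;
  long long n = (long long)n_decays;
  long long per_batch = (n + nbatch - 1) / nbatch;
  int nbatch_used = 0;

  std::vector<double> ts;
  ts.reserve(16);
  std::vector<Photon> stack;
  stack.reserve(8);

  for (long long h = 0; h < n; ++h) {
    // one decay: both line photons from one position uniform in the core
    double pos[3] = {0.0, 0.0, 0.0};
    if (g.has_source) {
      double rr = g.core_r * std::sqrt(unif_rand());
      double ph = 2.0 * M_PI * unif_rand();
      pos[0] = rr * std::cos(ph);
      pos[1] = rr * std::sin(ph);
      pos[2] = g.core_zlo + (g.core_zhi - g.core_zlo) * unif_rand();
    }
    stack.clear();
    for (int k = 0; k < elines.size(); ++k) {
      Photon ph0;
      ph0.p[0] = pos[0]; ph0.p[1] = pos[1]; ph0.p[2] = pos[2];
      iso_dir(ph0.d);
      ph0.E = elines[k];
      emitted += ph0.E;
      stack.push_back(ph0);
    }

    while (!stack.empty()) {
      Photon phn = stack.back();
      stack.pop_back();
      bool alive = true;
      while (alive) {
        double tmax = world_exit(g, phn.p, phn.d);
        if (tmax <= 0) { escaped += phn.E; break; }
        boundary_ts(g, phn.p, phn.d, tmax, ts);
        double logEc = std::log(phn.E);
        double muen_val = men.interp(0, logEc);
        double tau = -std::log(unif_rand());
        double tprev = 0.0;
        double tint = -1.0;
        for (size_t i = 0; i < ts.size(); ++i) {
          double tnext = ts[i];
          if (tnext <= tprev) continue;
          double tm = 0.5 * (tprev + tnext);
          int mat = classify(g, phn.p[0] + tm * phn.d[0],
                             phn.p[1] + tm * phn.d[1],
                             phn.p[2] + tm * phn.d[2]);
          if (mat < 0) { tprev = tnext; continue; }
          double muv = mu.interp(mat, logEc);
          double seg = tnext - tprev;
          double tstop = tnext;
          bool hit = false;
          if (muv * seg >= tau) {
            tstop = tprev + tau / muv;
            hit = true;
          } else {
            tau -= muv * seg;
          }
          if (mat == 3 && ncell > 0) {
            double w = phn.E * muen_val;
            for (int ic = 0; ic < ncell; ++ic) {
              double L = cell_overlap(cs[ic], phn.p, phn.d, tprev, tstop);
              if (L > 0) batch[ic] += L * w;
            }
          }
          if (hit) { tint = tstop; break; }
          tprev = tnext;
        }
        if (tint < 0) {  // escaped the world
          escaped += phn.E;
          break;
        }
        // move to the interaction site
        for (int i = 0; i < 3; ++i) phn.p[i] += tint * phn.d[i];
        if (primary_only) { absorbed += phn.E; break; }
        int mat = classify(g, phn.p[0], phn.p[1], phn.p[2]);
        if (mat < 0) { escaped += phn.E; break; }
        double muv = mu.interp(mat, logEc);
        double mu_c = kn_total_cpp(phn.E) * ne[mat];
        double fc = std::min(1.0, mu_c / muv);
        double xi = unif_rand();
        if (xi < fc) {  // Compton
          double Enew, cost;
          kn_sample(phn.E, Enew, cost);
          absorbed += phn.E - Enew;
          phn.E = Enew;
          rotate_dir(phn.d, cost, 2.0 * M_PI * unif_rand());
          if (phn.E < cutoff) { absorbed += phn.E; break; }
        } else if (phn.E >= 1.022) {  // pair production
          absorbed += phn.E - 2.0 * EMASS;
          Photon ann;
          ann.p[0] = phn.p[0]; ann.p[1] = phn.p[1]; ann.p[2] = phn.p[2];
          ann.E = EMASS;
          iso_dir(ann.d);
          stack.push_back(ann);
          phn.E = EMASS;
          iso_dir(phn.d);
          if (phn.E < cutoff) { absorbed += phn.E; break; }
        } else {  // photoelectric
          absorbed += phn.E;
          break;
        }
      }
    }

    if ((h + 1) % per_batch == 0 || h == n - 1) {
      for (int ic = 0; ic < ncell; ++ic) {
        tally[ic] += batch[ic];
        bsum[ic] += batch[ic];
        bsum2[ic] += batch[ic] * batch[ic];
        batch[ic] = 0.0;
      }
      nbatch_used++;
    }
    if ((h & 0xFFFFF) == 0) Rcpp::checkUserInterrupt();
  }

  NumericVector out_t(ncell), out_u(ncell);
  for (int ic = 0; ic < ncell; ++ic) {
    out_t[ic] = tally[ic];
    if (nbatch_used > 1 && tally[ic] > 0) {
      double m = bsum[ic] / nbatch_used;
      double var = (bsum2[ic] / nbatch_used - m * m) *
                   nbatch_used / (nbatch_used - 1.0);
      out_u[ic] = std::sqrt(std::max(0.0, var) * nbatch_used) / tally[ic];
    } else {
      out_u[ic] = NA_REAL;
    }
  }
  return List::create(_["track_mev_cm3_per_g"] = out_t,
                      _["rel_unc"] = out_u,
                      _["emitted"] = emitted,
                      _["absorbed"] = absorbed,
                      _["escaped"] = escaped,
                      _["nbatch"] = nbatch_used);
}

// ---- path lengths through the capsule assembly -----------------------------

// src: same layout as cpp_run_sim. Returns matrix (material, length) with
// material 1 = core, 2 = capsule, traced until the ray exits the capsule.
// [[Rcpp::export]]
NumericMatrix cpp_path_lengths(NumericVector src, NumericVector origin,
                               NumericVector dir) {
  Geom g;
  g.has_source = true;
  g.core_r = src[1]; g.core_zlo = src[2]; g.core_zhi = src[3];
  g.cap_r = src[4]; g.cap_zlo = src[5]; g.cap_zhi = src[6];
  g.cab_r = 0; g.cab_zlo = 0; g.cab_zhi = 0;
  g.world_type = 0;
  g.world_size = 1e6;
  double p[3] = {origin[0], origin[1], origin[2]};
  double d[3] = {dir[0], dir[1], dir[2]};

  // exit t from the capsule cylinder
  double a = d[0] * d[0] + d[1] * d[1];
  double texit = BIG;
  if (a > 1e-14) {
    double b = p[0] * d[0] + p[1] * d[1];
    double c = p[0] * p[0] + p[1] * p[1] - g.cap_r * g.cap_r;
    double disc = b * b - a * c;
    if (disc > 0) {
      double t2 = (-b + std::sqrt(disc)) / a;
      if (t2 > 0) texit = std::min(texit, t2);
      else texit = 0;
    } else {
      texit = 0;
    }
  }
  if (std::fabs(d[2]) > 1e-14) {
    double tz = d[2] > 0 ? (g.cap_zhi - p[2]) / d[2]
                         : (g.cap_zlo - p[2]) / d[2];
    texit = std::min(texit, std::max(0.0, tz));
  }
  std::vector<double> ts;
  boundary_ts(g, p, d, texit, ts);
  std::vector<int> mats;
  std::vector<double> lens;
  double tprev = 0.0;
  for (size_t i = 0; i < ts.size(); ++i) {
    double tnext = ts[i];
    if (tnext <= tprev + 1e-14) { tprev = std::max(tprev, tnext); continue; }
    double tm = 0.5 * (tprev + tnext);
    int mat = classify(g, p[0] + tm * d[0], p[1] + tm * d[1],
                       p[2] + tm * d[2]);
    if (mat == 0 || mat == 1) {
      if (!mats.empty() && mats.back() == mat + 1)
        lens.back() += tnext - tprev;
      else {
        mats.push_back(mat + 1);
        lens.push_back(tnext - tprev);
      }
    }
    tprev = tnext;
  }
  NumericMatrix out((int)mats.size(), 2);
  for (size_t i = 0; i < mats.size(); ++i) {
    out((int)i, 0) = mats[i];
    out((int)i, 1) = lens[i];
  }
  colnames(out) = CharacterVector::create("material", "length");
  return out;
}
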