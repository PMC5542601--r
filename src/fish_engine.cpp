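#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Agent-based collection-phase engine. At every fish time step the gear is
// linearly interpolated between kinematics frames (outer loop of the nested
// interpolation; the inner, along-rope interpolation is implicit in the
// piecewise-linear treatment of the logged node polylines). Fish react only
// to the seabed-contacting rope sections: a fish closer than l_min is herded
// a fixed distance l_move perpendicular to (and away from) the nearest rope
// segment with probability p_herd, or rises off the seabed with probability
// p_raise = 1 - p_herd and stays put until the rope has cleared l_min.

static inline uint64_t sm64(uint64_t& s) {
  s += 0x9E3779B97F4A7C15ULL;
  uint64_t z = s;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}
static inline double runif01(uint64_t& s) {
  return (sm64(s) >> 11) * (1.0 / 9007199254740992.0);
}

struct SegSet {
  std::vector<double> ax, ay, bx, by;
  int n() const { return (int)ax.size(); }
  void clear() { ax.clear(); ay.clear(); bx.clear(); by.clear(); }
  void add(double x1, double y1, double x2, double y2) {
    ax.push_back(x1); ay.push_back(y1); bx.push_back(x2); by.push_back(y2);
  }
};

struct Hash {
  double x0, y0, cell;
  int nx, ny;
  std::vector<std::vector<int>> bins;
  std::vector<int> used;
  void setup(double xmin, double ymin, double xmax, double ymax, double c) {
    cell = c; x0 = xmin; y0 = ymin;
    nx = std::max(1, (int)std::ceil((xmax - xmin) / c));
    ny = std::max(1, (int)std::ceil((ymax - ymin) / c));
    if ((size_t)nx * ny > bins.size()) bins.resize((size_t)nx * ny);
    for (int b : used) bins[b].clear();
    used.clear();
  }
  int cx(double x) const { int i = (int)std::floor((x - x0) / cell); return i < 0 ? 0 : (i >= nx ? nx - 1 : i); }
  int cy(double y) const { int j = (int)std::floor((y - y0) / cell); return j < 0 ? 0 : (j >= ny ? ny - 1 : j); }
  void insert(int idx, double xmin, double ymin, double xmax, double ymax) {
    int i0 = cx(xmin), i1 = cx(xmax), j0 = cy(ymin), j1 = cy(ymax);
    for (int j = j0; j <= j1; ++j)
      for (int i = i0; i <= i1; ++i) {
        int b = j * nx + i;
        if (bins[b].empty()) used.push_back(b);
        bins[b].push_back(idx);
      }
  }
  const std::vector<int>& at(double x, double y) const {
    return bins[cy(y) * nx + cx(x)];
  }
};

static inline double seg_dist(double px, double py, double ax, double ay,
                              double bx, double by, double& qx, double& qy) {
  double dx = bx - ax, dy = by - ay;
  double L2 = dx * dx + dy * dy;
  double t = 0.0;
  if (L2 > 0.0) {
    t = ((px - ax) * dx + (py - ay) * dy) / L2;
    if (t < 0.0) t = 0.0;
    if (t > 1.0) t = 1.0;
  }
  qx = ax + t * dx; qy = ay + t * dy;
  double ex = px - qx, ey = py - qy;
  return std::sqrt(ex * ex + ey * ey);
}

// parameter along p->r of the earliest proper intersection with segment a->b,
// or -1 when none
static inline double cross_param(double px, double py, double rx, double ry,
                                 double ax, double ay, double bx, double by) {
  double sx = bx - ax, sy = by - ay;
  double den = rx * sy - ry * sx;
  if (std::fabs(den) < 1e-15) return -1.0;
  double qx = ax - px, qy = ay - py;
  double t = (qx * sy - qy * sx) / den;
  double u = (qx * ry - qy * rx) / den;
  if (t >= 0.0 && t <= 1.0 && u >= 0.0 && u <= 1.0) return t;
  return -1.0;
}

// [[Rcpp::export(rng = false)]]
List run_collection_cpp(NumericVector times, NumericVector rope1, NumericVector rope2,
                        NumericVector net, NumericVector fish_x, NumericVector fish_y,
                        LogicalVector fish_raised, List params) {
  const double l_min = as<double>(params["l_min"]);
  const double l_move = as<double>(params["l_move"]);
  const double p_herd = as<double>(params["p_herd"]);
  const double dt_fish = as<double>(params["dt_fish"]);
  const double contact_tol = as<double>(params["contact_tol"]);
  const double rope_radius = as<double>(params["rope_radius"]);
  const double barrier = as<double>(params["barrier_margin"]);
  const double winch_start = as<double>(params["winch_start"]);
  const bool check_cross = as<bool>(params["check_crossings"]);
  const uint64_t seed = (uint64_t)as<double>(params["seed"]);

  IntegerVector d1 = rope1.attr("dim");
  const int N = d1[1], nf = d1[2];
  const double* R1 = REAL(rope1);
  const double* R2 = REAL(rope2);
  const double* NT = REAL(net);
  const double* TT = REAL(times);
  const int na = fish_x.size();

  std::vector<double> fx(na), fy(na), herded(na, 0.0);
  std::vector<char> raised(na);
  std::vector<uint64_t> rng(na);
  for (int i = 0; i < na; ++i) {
    fx[i] = fish_x[i]; fy[i] = fish_y[i];
    raised[i] = fish_raised[i] ? 1 : 0;
    rng[i] = seed * 0x9E3779B97F4A7C15ULL ^ (uint64_t)(i + 1) * 0xBF58476D1CE4E5B9ULL;
    sm64(rng[i]);
  }

  // interpolation buffers
  std::vector<double> x1(N), y1(N), z1(N), x2(N), y2(N), z2(N);
  SegSet segs;
  Hash hash;
  const double cell = 25.0, pad = 2.0;

  const double t0 = TT[0], tend = TT[nf - 1];
  const int nt = (int)std::floor((tend - t0) / dt_fish + 1e-9) + 1;
  NumericMatrix ind(nt, 4);
  long n_herd = 0, n_raise = 0, n_crossings = 0;
  int idx_winch = nt - 1;
  bool winch_seen = false;

  std::vector<double> ringx, ringy;
  std::vector<std::vector<int>> ybins;
  std::vector<int> cand;
  int k = 0;

  for (int it = 0; it < nt; ++it) {
    double t = t0 + it * dt_fish;
    if (t > tend) t = tend;
    while (k < nf - 2 && TT[k + 1] < t) ++k;
    double span = TT[k + 1] - TT[k];
    double al = span > 1e-12 ? (t - TT[k]) / span : 0.0;
    if (al < 0.0) al = 0.0;
    if (al > 1.0) al = 1.0;

    const double* A1 = R1 + (size_t)3 * N * k;
    const double* B1 = R1 + (size_t)3 * N * (k + 1);
    const double* A2 = R2 + (size_t)3 * N * k;
    const double* B2 = R2 + (size_t)3 * N * (k + 1);
    for (int j = 0; j < N; ++j) {
      x1[j] = A1[3 * j] + al * (B1[3 * j] - A1[3 * j]);
      y1[j] = A1[3 * j + 1] + al * (B1[3 * j + 1] - A1[3 * j + 1]);
      z1[j] = A1[3 * j + 2] + al * (B1[3 * j + 2] - A1[3 * j + 2]);
      x2[j] = A2[3 * j] + al * (B2[3 * j] - A2[3 * j]);
      y2[j] = A2[3 * j + 1] + al * (B2[3 * j + 1] - A2[3 * j + 1]);
      z2[j] = A2[3 * j + 2] + al * (B2[3 * j + 2] - A2[3 * j + 2]);
    }
    double nx_ = NT[3 * k] + al * (NT[3 * (k + 1)] - NT[3 * k]);
    double ny_ = NT[3 * k + 1] + al * (NT[3 * (k + 1) + 1] - NT[3 * k + 1]);

    // seabed-contact run per rope: contiguous contacting section nearest the net
    int a1 = -1, e1 = -1, a2 = -1, e2 = -1;
    for (int j = N - 1; j >= 0; --j)
      if (z1[j] - rope_radius <= contact_tol) { e1 = j; break; }
    if (e1 >= 0) { a1 = e1; while (a1 > 0 && z1[a1 - 1] - rope_radius <= contact_tol) --a1; }
    for (int j = N - 1; j >= 0; --j)
      if (z2[j] - rope_radius <= contact_tol) { e2 = j; break; }
    if (e2 >= 0) { a2 = e2; while (a2 > 0 && z2[a2 - 1] - rope_radius <= contact_tol) --a2; }

    // reaction sections: contact run, closed at the net vertex
    segs.clear();
    double sxmin = 1e300, symin = 1e300, sxmax = -1e300, symax = -1e300;
    if (e1 >= 0) {
      for (int j = a1; j < e1; ++j) segs.add(x1[j], y1[j], x1[j + 1], y1[j + 1]);
      segs.add(x1[e1], y1[e1], nx_, ny_);
    }
    if (e2 >= 0) {
      for (int j = a2; j < e2; ++j) segs.add(x2[j], y2[j], x2[j + 1], y2[j + 1]);
      segs.add(x2[e2], y2[e2], nx_, ny_);
    }
    int ns = segs.n();
    if (ns > 0) {
      for (int s = 0; s < ns; ++s) {
        sxmin = std::min(sxmin, std::min(segs.ax[s], segs.bx[s]));
        sxmax = std::max(sxmax, std::max(segs.ax[s], segs.bx[s]));
        symin = std::min(symin, std::min(segs.ay[s], segs.by[s]));
        symax = std::max(symax, std::max(segs.ay[s], segs.by[s]));
      }
      hash.setup(sxmin - pad - 1.0, symin - pad - 1.0, sxmax + pad + 1.0, symax + pad + 1.0, cell);
      for (int s = 0; s < ns; ++s) {
        hash.insert(s,
                    std::min(segs.ax[s], segs.bx[s]) - pad,
                    std::min(segs.ay[s], segs.by[s]) - pad,
                    std::max(segs.ax[s], segs.bx[s]) + pad,
                    std::max(segs.ay[s], segs.by[s]) + pad);
      }
    }

    // agents
    if (ns > 0) {
      for (int i = 0; i < na; ++i) {
        double px = fx[i], py = fy[i];
        if (px < sxmin - pad || px > sxmax + pad || py < symin - pad || py > symax + pad) {
          if (raised[i]) raised[i] = 0;  // rope is far away
          continue;
        }
        const std::vector<int>& bs = hash.at(px, py);
        double dmin = 1e300, qx = 0, qy = 0, qxb, qyb;
        int best = -1;
        for (int s : bs) {
          double d = seg_dist(px, py, segs.ax[s], segs.ay[s], segs.bx[s], segs.by[s], qxb, qyb);
          if (d < dmin) { dmin = d; qx = qxb; qy = qyb; best = s; }
        }
        if (raised[i]) {
          if (dmin > l_min) raised[i] = 0;
          continue;
        }
        if (best < 0 || dmin >= l_min) continue;
        // reaction: herd or raise
        bool herd = p_herd >= 1.0 || runif01(rng[i]) < p_herd;
        if (!herd) {
          raised[i] = 1;
          ++n_raise;
          continue;
        }
        double nxv, nyv;
        if (dmin > 1e-12) {
          nxv = (px - qx) / dmin; nyv = (py - qy) / dmin;
        } else {
          double sx = segs.bx[best] - segs.ax[best], sy = segs.by[best] - segs.ay[best];
          double sl = std::sqrt(sx * sx + sy * sy);
          if (sl < 1e-12) { sx = 1.0; sy = 0.0; sl = 1.0; }
          double side = runif01(rng[i]) < 0.5 ? 1.0 : -1.0;
          nxv = side * (-sy / sl); nyv = side * (sx / sl);
        }
        double rxv = l_move * nxv, ryv = l_move * nyv;
        // barrier with wall-following: a herding jump may not cross a seabed
        // rope section; it stops short of the obstructing segment and the
        // blocked remainder deflects along that segment (the direction of
        // the jump's tangential component), so fish squeezed in a narrow V
        // slide towards its opening instead of freezing in place
        cand.clear();
        const std::vector<int>& c1 = hash.at(px, py);
        const std::vector<int>& c2 = hash.at(px + rxv, py + ryv);
        cand.insert(cand.end(), c1.begin(), c1.end());
        if (&c2 != &c1) cand.insert(cand.end(), c2.begin(), c2.end());
        double tcross = 2.0;
        int blocker = -1;
        for (int s : cand) {
          if (s == best && dmin > 1e-12) {
            // moving directly away from the nearest segment cannot cross it
            continue;
          }
          double tc = cross_param(px, py, rxv, ryv, segs.ax[s], segs.ay[s], segs.bx[s], segs.by[s]);
          if (tc >= 0.0 && tc < tcross) { tcross = tc; blocker = s; }
        }
        double move = l_move, slide = 0.0;
        double newx, newy;
        if (tcross <= 1.0) {
          move = tcross * l_move - barrier;
          if (move < 0.0) move = 0.0;
          newx = px + move * nxv; newy = py + move * nyv;
          double rem = l_move - move;
          // deflect the remainder along the obstructing segment
          double dxs = segs.bx[blocker] - segs.ax[blocker];
          double dys = segs.by[blocker] - segs.ay[blocker];
          double dl = std::sqrt(dxs * dxs + dys * dys);
          double dot = nxv * dxs + nyv * dys;
          if (dl > 1e-12 && std::fabs(dot) > 1e-12 && rem > 0.0) {
            double sgn = dot > 0 ? 1.0 : -1.0;
            double sx2 = sgn * dxs / dl, sy2 = sgn * dys / dl;
            double t2 = 2.0;
            const std::vector<int>& c3 = hash.at(newx + rem * sx2, newy + rem * sy2);
            for (int s : cand) {
              if (s == blocker) continue;
              double tc = cross_param(newx, newy, rem * sx2, rem * sy2,
                                      segs.ax[s], segs.ay[s], segs.bx[s], segs.by[s]);
              if (tc >= 0.0 && tc < t2) t2 = tc;
            }
            for (int s : c3) {
              if (s == blocker) continue;
              double tc = cross_param(newx, newy, rem * sx2, rem * sy2,
                                      segs.ax[s], segs.ay[s], segs.bx[s], segs.by[s]);
              if (tc >= 0.0 && tc < t2) t2 = tc;
            }
            slide = rem;
            if (t2 <= 1.0) {
              slide = t2 * rem - barrier;
              if (slide < 0.0) slide = 0.0;
            }
            newx += slide * sx2; newy += slide * sy2;
          }
        } else {
          newx = px + move * nxv; newy = py + move * nyv;
        }
        if (check_cross && move + slide > 0.0) {
          // test both legs of the (possibly deflected) path
          double mx = px + move * nxv, my = py + move * nyv;
          for (int s : cand) {
            double tc = cross_param(px, py, mx - px, my - py,
                                    segs.ax[s], segs.ay[s], segs.bx[s], segs.by[s]);
            if (tc > 1e-9 && tc < 1.0 - 1e-9) { ++n_crossings; break; }
            double tc2 = cross_param(mx, my, newx - mx, newy - my,
                                     segs.ax[s], segs.ay[s], segs.bx[s], segs.by[s]);
            if (tc2 > 1e-9 && tc2 < 1.0 - 1e-9) { ++n_crossings; break; }
          }
        }
        fx[i] = newx; fy[i] = newy;
        herded[i] += move + slide;
        ++n_herd;
      }
    }

    // encirclement polygon: rope1 run, net vertex, rope2 run reversed
    double area = 0.0, width = 0.0;
    int count = 0;
    if (e1 >= 0 && e2 >= 0) {
      ringx.clear(); ringy.clear();
      for (int j = a1; j <= e1; ++j) { ringx.push_back(x1[j]); ringy.push_back(y1[j]); }
      ringx.push_back(nx_); ringy.push_back(ny_);
      for (int j = e2; j >= a2; --j) { ringx.push_back(x2[j]); ringy.push_back(y2[j]); }
      int m = (int)ringx.size();
      if (m >= 3) {
        double s2 = 0.0;
        double rxmin = 1e300, rxmax = -1e300, rymin = 1e300, rymax = -1e300;
        for (int j = 0; j < m; ++j) {
          int jn = (j + 1) % m;
          s2 += ringx[j] * ringy[jn] - ringx[jn] * ringy[j];
          rxmin = std::min(rxmin, ringx[j]); rxmax = std::max(rxmax, ringx[j]);
          rymin = std::min(rymin, ringy[j]); rymax = std::max(rymax, ringy[j]);
        }
        area = 0.5 * std::fabs(s2);
        double wx = x1[a1] - x2[a2], wy = y1[a1] - y2[a2];
        width = std::sqrt(wx * wx + wy * wy);
        // even-odd count of non-raised agents, edges bucketed by y
        int nb = 128;
        double dy = (rymax - rymin) / nb;
        if (dy <= 0.0) dy = 1.0;
        if ((int)ybins.size() < nb) ybins.resize(nb);
        for (int b = 0; b < nb; ++b) ybins[b].clear();
        for (int j = 0; j < m; ++j) {
          int jn = (j + 1) % m;
          double ylo = std::min(ringy[j], ringy[jn]), yhi = std::max(ringy[j], ringy[jn]);
          int b0 = (int)std::floor((ylo - rymin) / dy), b1 = (int)std::floor((yhi - rymin) / dy);
          if (b0 < 0) b0 = 0;
          if (b1 >= nb) b1 = nb - 1;
          for (int b = b0; b <= b1; ++b) ybins[b].push_back(j);
        }
        for (int i = 0; i < na; ++i) {
          if (raised[i]) continue;
          double px = fx[i], py = fy[i];
          if (px < rxmin || px > rxmax || py < rymin || py > rymax) continue;
          int b = (int)std::floor((py - rymin) / dy);
          if (b < 0) b = 0;
          if (b >= nb) b = nb - 1;
          bool inside = false;
          for (int j : ybins[b]) {
            int jn = (j + 1) % m;
            double yi = ringy[j], yj = ringy[jn];
            if ((yi > py) != (yj > py)) {
              double xint = (ringx[jn] - ringx[j]) * (py - yi) / (yj - yi) + ringx[j];
              if (px < xint) inside = !inside;
            }
          }
          if (inside) ++count;
        }
      }
    }

    ind(it, 0) = t;
    ind(it, 1) = area;
    ind(it, 2) = width;
    ind(it, 3) = count;
    if (!winch_seen && t >= winch_start - 1e-9) { idx_winch = it; winch_seen = true; }
    if (it % 200 == 0) Rcpp::checkUserInterrupt();
  }

  NumericVector ofx(na), ofy(na), oherd(na);
  LogicalVector oraised(na);
  for (int i = 0; i < na; ++i) {
    ofx[i] = fx[i]; ofy[i] = fy[i]; oherd[i] = herded[i]; oraised[i] = raised[i] == 1;
  }
  return List::create(_["indicators"] = ind,
                      _["x"] = ofx, _["y"] = ofy, _["raised"] = oraised,
                      _["herded_dist"] = oherd,
                      _["n_herd_events"] = (double)n_herd,
                      _["n_raise_events"] = (double)n_raise,
                      _["n_crossings"] = (double)n_crossings,
                      _["idx_winch"] = idx_winch + 1);
}
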