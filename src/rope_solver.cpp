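#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <string>
using namespace Rcpp;

// Lumped-mass seine-rope solver. Each rope is a chain of point masses joined
// by tension-only axial springs with viscous axial damping. Environmental
// forces per node: submerged weight, seabed penalty contact, Coulomb seabed
// friction, and Morison-type normal/tangential drag. The two ropes share a
// vessel attachment (prescribed motion) and a net body (point mass with its
// own contact/friction/drag).
//
// Integration is explicit (forward or symplectic Euler) for weight, tension
// and the contact normal; quadratic drag is applied as a semi-implicit
// velocity divisor and Coulomb friction as a stick-slip velocity projection
// (impulse clamped at the stopping impulse), both unconditionally stable.

struct Phys {
  double dt;
  bool semi;
  double lambda, diam, radius;
  double rho_w, rho_r;
  double EA, c_ax;
  double kc, cc, mu, mu_long;
  double cdn, cdt;
  double g, depth, max_speed;
  double net_mass, net_weight, net_mu, net_drag, net_k, net_c, net_radius;
};

static Phys read_phys(const List& p) {
  Phys ph;
  ph.dt = as<double>(p["dt"]);
  ph.semi = as<std::string>(p["integrator"]) == "semi_implicit";
  ph.lambda = as<double>(p["linear_mass"]);
  ph.diam = as<double>(p["diameter"]);
  ph.radius = 0.5 * ph.diam;
  ph.rho_w = as<double>(p["water_density"]);
  ph.rho_r = as<double>(p["rope_density"]);
  ph.EA = as<double>(p["EA"]);
  ph.c_ax = as<double>(p["axial_damping"]);
  ph.kc = as<double>(p["contact_stiffness"]);
  ph.cc = as<double>(p["contact_damping"]);
  ph.mu = as<double>(p["mu_seabed"]);
  ph.mu_long = as<double>(p["mu_longitudinal"]);
  ph.cdn = as<double>(p["cd_normal"]);
  ph.cdt = as<double>(p["cd_tangential"]);
  ph.g = as<double>(p["gravity"]);
  ph.depth = as<double>(p["depth"]);
  ph.max_speed = as<double>(p["max_speed"]);
  ph.net_mass = as<double>(p["net_mass"]);
  ph.net_weight = as<double>(p["net_weight"]);
  ph.net_mu = as<double>(p["net_mu"]);
  ph.net_drag = as<double>(p["net_drag"]);
  ph.net_k = as<double>(p["net_contact_stiffness"]);
  ph.net_c = as<double>(p["net_contact_damping"]);
  ph.net_radius = as<double>(p["net_radius"]);
  return ph;
}

struct Rope {
  int N, head;
  std::vector<double> px, py, pz, vx, vy, vz;
  std::vector<double> rest;   // N entries; rest[N-1] joins node N-1 to the net
  std::vector<double> fx, fy, fz;
  std::vector<double> tx, ty, tz;  // local tangents (drag decomposition)
  std::vector<double> cN;          // seabed normal force
  std::vector<double> ln;          // lumped rope length per node

  double remaining() const {
    double s = 0.0;
    for (int j = head; j < N; ++j) s += rest[j];
    return s;
  }
  void alloc(int n) {
    N = n; head = 0;
    px.resize(n); py.resize(n); pz.resize(n);
    vx.assign(n, 0.0); vy.assign(n, 0.0); vz.assign(n, 0.0);
    fx.resize(n); fy.resize(n); fz.resize(n);
    tx.resize(n); ty.resize(n); tz.resize(n);
    cN.resize(n); ln.resize(n);
    rest.assign(n, 0.0);
  }
};

static inline void add_tension(double ax, double ay, double az,
                               double bx, double by, double bz,
                               double vax, double vay, double vaz,
                               double vbx, double vby, double vbz,
                               double L, const Phys& ph,
                               double* fa, double* fb) {
  double dx = bx - ax, dy = by - ay, dz = bz - az;
  double len = std::sqrt(dx * dx + dy * dy + dz * dz);
  if (len < 1e-9 || L < 1e-9) return;
  double ux = dx / len, uy = dy / len, uz = dz / len;
  double rate = (vbx - vax) * ux + (vby - vay) * uy + (vbz - vaz) * uz;
  double T = ph.EA * (len - L) / L + ph.c_ax * rate;
  if (T < 0.0) T = 0.0;  // rope cannot push
  if (fa) { fa[0] += T * ux; fa[1] += T * uy; fa[2] += T * uz; }
  if (fb) { fb[0] -= T * ux; fb[1] -= T * uy; fb[2] -= T * uz; }
}

// weight + seabed normal (explicit part); stores the normal force for the
// friction projection
static inline double weight_contact(double pz_, double vz_, double l_node,
                                    const Phys& ph, double* f) {
  f[2] -= ph.lambda * l_node * ph.g * (1.0 - ph.rho_w / ph.rho_r);
  double clearance = pz_ - ph.radius;
  double Nf = 0.0;
  if (clearance < 0.0) {
    Nf = (ph.kc * (-clearance) + ph.cc * (-vz_)) * l_node;
    if (Nf < 0.0) Nf = 0.0;
    f[2] += Nf;
  }
  return Nf;
}

// semi-implicit quadratic drag + Coulomb stick-slip, applied to a velocity.
// Seabed friction is anisotropic, dominated by the transversal (plowing)
// component; sliding along the rope's own axis is only weakly resisted.
static inline void damp_velocity(double& vx_, double& vy_, double& vz_,
                                 double tx_, double ty_, double tz_,
                                 double qn, double qt, double m,
                                 double mu, double mu_long, double Nf, double dt) {
  double vt = vx_ * tx_ + vy_ * ty_ + vz_ * tz_;
  double wx = vx_ - vt * tx_, wy = vy_ - vt * ty_, wz = vz_ - vt * tz_;
  double wn = std::sqrt(wx * wx + wy * wy + wz * wz);
  double fn = 1.0 / (1.0 + qn * wn * dt / m);
  double ft = 1.0 / (1.0 + qt * std::fabs(vt) * dt / m);
  wx *= fn; wy *= fn; wz *= fn;
  vt *= ft;
  vx_ = wx + vt * tx_; vy_ = wy + vt * ty_; vz_ = wz + vt * tz_;
  if (Nf > 0.0 && (mu > 0.0 || mu_long > 0.0)) {
    // horizontal tangent direction (rope axis projected on the seabed)
    double hx = tx_, hy = ty_;
    double hl = std::sqrt(hx * hx + hy * hy);
    if (hl > 1e-9) { hx /= hl; hy /= hl; } else { hx = 1.0; hy = 0.0; }
    double vlong = vx_ * hx + vy_ * hy;
    double vtx = vx_ - vlong * hx, vty = vy_ - vlong * hy;
    // transversal stick-slip
    double spt = std::sqrt(vtx * vtx + vty * vty);
    double dvt = mu * Nf * dt / m;
    if (spt <= dvt) { vtx = 0.0; vty = 0.0; }
    else { double s = 1.0 - dvt / spt; vtx *= s; vty *= s; }
    // longitudinal stick-slip
    double dvl = mu_long * Nf * dt / m;
    if (std::fabs(vlong) <= dvl) vlong = 0.0;
    else vlong -= (vlong > 0 ? dvl : -dvl);
    vx_ = vtx + vlong * hx; vy_ = vty + vlong * hy;
  }
}

static void check_state(const Rope& r, int rope_id, double t, double vmax) {
  for (int i = r.head; i < r.N; ++i) {
    double s2 = r.vx[i] * r.vx[i] + r.vy[i] * r.vy[i] + r.vz[i] * r.vz[i];
    if (!std::isfinite(r.px[i]) || !std::isfinite(r.py[i]) || !std::isfinite(r.pz[i]) ||
        !std::isfinite(s2)) {
      stop("rope dynamics diverged: non-finite state at rope %d node %d, t = %.3f s",
           rope_id, i + 1, t);
    }
    if (s2 > vmax * vmax) {
      stop("rope dynamics diverged: node speed %.1f m/s at rope %d node %d, t = %.3f s",
           std::sqrt(s2), rope_id, i + 1, t);
    }
  }
}

// forces on all free nodes of one rope; tension on the net accumulated in fnet
static void rope_forces(Rope& r, const double* vessel, const double* vvel,
                        const double* net, const double* nvel,
                        const Phys& ph, double* fnet) {
  int N = r.N, h = r.head;
  for (int i = h; i < N; ++i) { r.fx[i] = 0.0; r.fy[i] = 0.0; r.fz[i] = 0.0; }
  r.px[h] = vessel[0]; r.py[h] = vessel[1]; r.pz[h] = vessel[2];
  r.vx[h] = vvel[0];   r.vy[h] = vvel[1];   r.vz[h] = vvel[2];
  for (int j = h; j < N - 1; ++j) {
    double fa[3] = {0, 0, 0}, fb[3] = {0, 0, 0};
    add_tension(r.px[j], r.py[j], r.pz[j], r.px[j + 1], r.py[j + 1], r.pz[j + 1],
                r.vx[j], r.vy[j], r.vz[j], r.vx[j + 1], r.vy[j + 1], r.vz[j + 1],
                r.rest[j], ph, fa, fb);
    r.fx[j] += fa[0]; r.fy[j] += fa[1]; r.fz[j] += fa[2];
    r.fx[j + 1] += fb[0]; r.fy[j + 1] += fb[1]; r.fz[j + 1] += fb[2];
  }
  {
    double fa[3] = {0, 0, 0}, fb[3] = {0, 0, 0};
    add_tension(r.px[N - 1], r.py[N - 1], r.pz[N - 1], net[0], net[1], net[2],
                r.vx[N - 1], r.vy[N - 1], r.vz[N - 1], nvel[0], nvel[1], nvel[2],
                r.rest[N - 1], ph, fa, fb);
    r.fx[N - 1] += fa[0]; r.fy[N - 1] += fa[1]; r.fz[N - 1] += fa[2];
    fnet[0] += fb[0]; fnet[1] += fb[1]; fnet[2] += fb[2];
  }
  for (int i = h + 1; i < N; ++i) {
    double l_node = 0.5 * (r.rest[i - 1] + r.rest[i]);
    r.ln[i] = l_node;
    double ax = r.px[i - 1], ay = r.py[i - 1], az = r.pz[i - 1];
    double bx = (i < N - 1) ? r.px[i + 1] : net[0];
    double by = (i < N - 1) ? r.py[i + 1] : net[1];
    double bz = (i < N - 1) ? r.pz[i + 1] : net[2];
    double tx = bx - ax, ty = by - ay, tz = bz - az;
    double tl = std::sqrt(tx * tx + ty * ty + tz * tz);
    if (tl > 1e-9) { tx /= tl; ty /= tl; tz /= tl; } else { tx = 1; ty = 0; tz = 0; }
    r.tx[i] = tx; r.ty[i] = ty; r.tz[i] = tz;
    double f[3] = {0, 0, 0};
    r.cN[i] = weight_contact(r.pz[i], r.vz[i], l_node, ph, f);
    r.fx[i] += f[0]; r.fy[i] += f[1]; r.fz[i] += f[2];
  }
}

static void integrate_rope(Rope& r, const Phys& ph) {
  int N = r.N, h = r.head;
  double dt = ph.dt;
  for (int i = h + 1; i < N; ++i) {
    double m = std::max(ph.lambda * r.ln[i], 1e-6);
    double qn = 0.5 * ph.rho_w * ph.cdn * ph.diam * r.ln[i];
    double qt = 0.5 * ph.rho_w * ph.cdt * M_PI * ph.diam * r.ln[i];
    if (!ph.semi) { r.px[i] += r.vx[i] * dt; r.py[i] += r.vy[i] * dt; r.pz[i] += r.vz[i] * dt; }
    r.vx[i] += r.fx[i] / m * dt;
    r.vy[i] += r.fy[i] / m * dt;
    r.vz[i] += r.fz[i] / m * dt;
    damp_velocity(r.vx[i], r.vy[i], r.vz[i], r.tx[i], r.ty[i], r.tz[i],
                  qn, qt, m, ph.mu, ph.mu_long, r.cN[i], dt);
    if (ph.semi) { r.px[i] += r.vx[i] * dt; r.py[i] += r.vy[i] * dt; r.pz[i] += r.vz[i] * dt; }
  }
}

// winch: shorten the head element; merge it into the next when short
static void winch_rope(Rope& r, double wspd, double dt, double elem_nominal,
                       const double* vessel) {
  if (r.head >= r.N - 2) return;  // keep at least one internal element
  r.rest[r.head] -= wspd * dt;
  if (r.rest[r.head] < 0.75 * elem_nominal) {
    r.rest[r.head + 1] += r.rest[r.head];
    r.rest[r.head] = 0.0;
    r.head += 1;
    r.px[r.head] = vessel[0]; r.py[r.head] = vessel[1]; r.pz[r.head] = vessel[2];
    r.vx[r.head] = 0.0; r.vy[r.head] = 0.0; r.vz[r.head] = 0.0;
  }
}

// resample the polyline vessel -> free nodes -> net at n_log equal arc steps
static void resample(const Rope& r, const double* vessel, const double* net,
                     int n_log, double* ox, double* oy, double* oz) {
  std::vector<double> qx, qy, qz;
  qx.reserve(r.N + 2); qy.reserve(r.N + 2); qz.reserve(r.N + 2);
  qx.push_back(vessel[0]); qy.push_back(vessel[1]); qz.push_back(vessel[2]);
  for (int i = r.head + 1; i < r.N; ++i) {
    qx.push_back(r.px[i]); qy.push_back(r.py[i]); qz.push_back(r.pz[i]);
  }
  qx.push_back(net[0]); qy.push_back(net[1]); qz.push_back(net[2]);
  int m = (int)qx.size();
  std::vector<double> cum(m, 0.0);
  for (int i = 1; i < m; ++i) {
    double dx = qx[i] - qx[i - 1], dy = qy[i] - qy[i - 1], dz = qz[i] - qz[i - 1];
    cum[i] = cum[i - 1] + std::sqrt(dx * dx + dy * dy + dz * dz);
  }
  double total = cum[m - 1];
  int k = 0;
  for (int j = 0; j < n_log; ++j) {
    double s = total * j / (n_log - 1.0);
    while (k < m - 2 && cum[k + 1] < s) ++k;
    double seg = cum[k + 1] - cum[k];
    double a = seg > 1e-12 ? (s - cum[k]) / seg : 0.0;
    ox[j] = qx[k] + a * (qx[k + 1] - qx[k]);
    oy[j] = qy[k] + a * (qy[k + 1] - qy[k]);
    oz[j] = qz[k] + a * (qz[k + 1] - qz[k]);
  }
}

// [[Rcpp::export(rng = false)]]
List simulate_haul_cpp(NumericMatrix rope1, NumericMatrix rope2,
                       NumericVector rest1, NumericVector rest2,
                       NumericVector net0, List params, List plan) {
  Phys ph = read_phys(params);
  double tow_speed = as<double>(plan["tow_speed"]);
  double tow_duration = as<double>(plan["tow_duration"]);
  double winch_tow_speed = as<double>(plan["winch_tow_speed"]);
  double winch_speed = as<double>(plan["winch_speed"]);
  double min_rope = as<double>(plan["min_rope"]);
  double max_time = as<double>(plan["max_time"]);
  double settle_time = as<double>(params["settle_time"]);
  double frame_interval = as<double>(params["frame_interval"]);
  double elem_nominal = as<double>(params["element_length"]);
  int n_log = as<int>(params["n_log"]);

  int N = rope1.nrow();
  Rope r1, r2;
  r1.alloc(N); r2.alloc(N);
  for (int i = 0; i < N; ++i) {
    r1.px[i] = rope1(i, 0); r1.py[i] = rope1(i, 1); r1.pz[i] = rope1(i, 2);
    r2.px[i] = rope2(i, 0); r2.py[i] = rope2(i, 1); r2.pz[i] = rope2(i, 2);
    r1.rest[i] = rest1[i]; r2.rest[i] = rest2[i];
  }
  double net[3] = {net0[0], net0[1], net0[2]};
  double nvel[3] = {0.0, 0.0, 0.0};
  double vessel[3] = {rope1(0, 0), rope1(0, 1), rope1(0, 2)};
  double vx0 = vessel[0], vy0 = vessel[1];
  double vvel[3] = {0.0, 0.0, 0.0};

  double dt = ph.dt;
  long n_settle = (long)std::ceil(settle_time / dt);
  double raise_time = std::max(1e-9, 0.6 * settle_time);
  long max_steps = n_settle + (long)std::ceil(max_time / dt) + 2;

  int max_frames = (int)std::ceil((max_time + settle_time) / frame_interval) + 3;
  std::vector<double> f_t; f_t.reserve(max_frames);
  std::vector<double> f_r1, f_r2, f_v, f_n, f_rem;
  f_r1.reserve((size_t)max_frames * n_log * 3);
  f_r2.reserve((size_t)max_frames * n_log * 3);
  std::vector<double> bx(n_log), by(n_log), bz(n_log);
  std::string end_reason = "max_time";

  double next_frame = -settle_time;  // first frame: gear exactly as laid out
  for (long step = 0; step <= max_steps; ++step) {
    double t = step * dt;            // global clock incl. settling
    double te = t - settle_time;     // haul clock (0 = start of towing)

    if (te < 0.0) {
      double s = std::min(1.0, t / raise_time);
      vessel[1] = vy0;
      vessel[2] = ph.depth * 0.5 * (1.0 - std::cos(M_PI * s));
      vvel[1] = 0.0;
      vvel[2] = (s < 1.0) ? ph.depth * 0.5 * M_PI / raise_time * std::sin(M_PI * s) : 0.0;
      // towed plans: after the raise, ramp up to towing speed and hold it,
      // so t = 0 is the start of the tow proper with developed tension
      double sp = 0.0;
      if (tow_duration > 0.0 && t > raise_time) {
        double ramp = std::min(30.0, 0.5 * (settle_time - raise_time));
        sp = tow_speed * std::min(1.0, (t - raise_time) / std::max(ramp, 1e-9));
      }
      vessel[0] += sp * dt;
      vvel[0] = sp;
    } else {
      double sp = te < tow_duration ? tow_speed : winch_tow_speed;
      vessel[0] += sp * dt; vessel[1] = vy0; vessel[2] = ph.depth;
      vvel[0] = sp; vvel[1] = 0.0; vvel[2] = 0.0;
    }
    bool winching = te >= tow_duration;

    if (te >= next_frame - 0.5 * dt) {
      f_t.push_back(te);
      resample(r1, vessel, net, n_log, bx.data(), by.data(), bz.data());
      for (int j = 0; j < n_log; ++j) { f_r1.push_back(bx[j]); f_r1.push_back(by[j]); f_r1.push_back(bz[j]); }
      resample(r2, vessel, net, n_log, bx.data(), by.data(), bz.data());
      for (int j = 0; j < n_log; ++j) { f_r2.push_back(bx[j]); f_r2.push_back(by[j]); f_r2.push_back(bz[j]); }
      f_v.push_back(vessel[0]); f_v.push_back(vessel[1]); f_v.push_back(vessel[2]);
      f_n.push_back(net[0]); f_n.push_back(net[1]); f_n.push_back(net[2]);
      f_rem.push_back(r1.remaining()); f_rem.push_back(r2.remaining());
      next_frame += frame_interval;
    }

    if (te >= max_time) { end_reason = "max_time"; break; }
    if (std::min(r1.remaining(), r2.remaining()) <= min_rope) {
      end_reason = "rope_exhausted";
      break;
    }

    double fnet[3] = {0.0, 0.0, 0.0};
    rope_forces(r1, vessel, vvel, net, nvel, ph, fnet);
    rope_forces(r2, vessel, vvel, net, nvel, ph, fnet);
    fnet[2] -= ph.net_weight;
    double netN = 0.0;
    double cl = net[2] - ph.net_radius;
    if (cl < 0.0) {
      netN = ph.net_k * (-cl) + ph.net_c * (-nvel[2]);
      if (netN < 0.0) netN = 0.0;
      fnet[2] += netN;
    }

    integrate_rope(r1, ph);
    integrate_rope(r2, ph);
    {
      double m = ph.net_mass;
      if (!ph.semi) { net[0] += nvel[0] * dt; net[1] += nvel[1] * dt; net[2] += nvel[2] * dt; }
      nvel[0] += fnet[0] / m * dt; nvel[1] += fnet[1] / m * dt; nvel[2] += fnet[2] / m * dt;
      // implicit quadratic drag, then Coulomb stick-slip
      double sp3 = std::sqrt(nvel[0] * nvel[0] + nvel[1] * nvel[1] + nvel[2] * nvel[2]);
      double fdiv = 1.0 / (1.0 + ph.net_drag * sp3 * dt / m);
      nvel[0] *= fdiv; nvel[1] *= fdiv; nvel[2] *= fdiv;
      if (netN > 0.0 && ph.net_mu > 0.0) {
        double sp = std::sqrt(nvel[0] * nvel[0] + nvel[1] * nvel[1]);
        double dv = ph.net_mu * netN * dt / m;
        if (sp <= dv) { nvel[0] = 0.0; nvel[1] = 0.0; }
        else { double s = 1.0 - dv / sp; nvel[0] *= s; nvel[1] *= s; }
      }
      if (ph.semi) { net[0] += nvel[0] * dt; net[1] += nvel[1] * dt; net[2] += nvel[2] * dt; }
    }

    if (winching) {
      winch_rope(r1, winch_speed, dt, elem_nominal, vessel);
      winch_rope(r2, winch_speed, dt, elem_nominal, vessel);
    }

    if (step % 25 == 0) {
      check_state(r1, 1, te, ph.max_speed);
      check_state(r2, 2, te, ph.max_speed);
    }
    if (step % 20000 == 0) Rcpp::checkUserInterrupt();
  }

  int nf = (int)f_t.size();
  NumericVector a1(f_r1.begin(), f_r1.end());  // [coord, node, frame]
  NumericVector a2(f_r2.begin(), f_r2.end());
  a1.attr("dim") = IntegerVector::create(3, n_log, nf);
  a2.attr("dim") = IntegerVector::create(3, n_log, nf);
  NumericVector vv(f_v.begin(), f_v.end());
  vv.attr("dim") = IntegerVector::create(3, nf);
  NumericVector nn(f_n.begin(), f_n.end());
  nn.attr("dim") = IntegerVector::create(3, nf);
  NumericVector rem(f_rem.begin(), f_rem.end());
  rem.attr("dim") = IntegerVector::create(2, nf);
  return List::create(_["times"] = NumericVector(f_t.begin(), f_t.end()),
                      _["rope1"] = a1, _["rope2"] = a2,
                      _["vessel"] = vv, _["net"] = nn,
                      _["remaining"] = rem,
                      _["end_reason"] = end_reason);
}

// Single-rope stepper used by step_dynamics(): optional pinned ends, no net
// body, optional winching at the head end.
// [[Rcpp::export(rng = false)]]
List rope_step_cpp(NumericMatrix pos, NumericMatrix vel, NumericVector rest,
                   List params, List boundary, int n_steps) {
  Phys ph = read_phys(params);
  double elem_nominal = as<double>(params["element_length"]);
  bool head_fixed = as<bool>(boundary["head_fixed"]);
  bool tail_fixed = as<bool>(boundary["tail_fixed"]);
  double winch_speed = as<double>(boundary["winch_speed"]);
  int N = pos.nrow();
  if (rest.size() != N - 1) stop("rest length vector must have n_nodes - 1 entries");

  Rope r;
  r.alloc(N);
  for (int i = 0; i < N; ++i) {
    r.px[i] = pos(i, 0); r.py[i] = pos(i, 1); r.pz[i] = pos(i, 2);
    r.vx[i] = vel(i, 0); r.vy[i] = vel(i, 1); r.vz[i] = vel(i, 2);
  }
  for (int j = 0; j < N - 1; ++j) r.rest[j] = rest[j];

  double headp[3] = {r.px[0], r.py[0], r.pz[0]};
  double tailp[3] = {r.px[N - 1], r.py[N - 1], r.pz[N - 1]};
  double dt = ph.dt;

  for (int step = 0; step < n_steps; ++step) {
    int h = r.head;
    for (int i = h; i < N; ++i) { r.fx[i] = 0.0; r.fy[i] = 0.0; r.fz[i] = 0.0; }
    if (head_fixed) {
      r.px[h] = headp[0]; r.py[h] = headp[1]; r.pz[h] = headp[2];
      r.vx[h] = 0.0; r.vy[h] = 0.0; r.vz[h] = 0.0;
    }
    if (tail_fixed) {
      r.px[N - 1] = tailp[0]; r.py[N - 1] = tailp[1]; r.pz[N - 1] = tailp[2];
      r.vx[N - 1] = 0.0; r.vy[N - 1] = 0.0; r.vz[N - 1] = 0.0;
    }
    for (int j = h; j < N - 1; ++j) {
      double fa[3] = {0, 0, 0}, fb[3] = {0, 0, 0};
      add_tension(r.px[j], r.py[j], r.pz[j], r.px[j + 1], r.py[j + 1], r.pz[j + 1],
                  r.vx[j], r.vy[j], r.vz[j], r.vx[j + 1], r.vy[j + 1], r.vz[j + 1],
                  r.rest[j], ph, fa, fb);
      r.fx[j] += fa[0]; r.fy[j] += fa[1]; r.fz[j] += fa[2];
      r.fx[j + 1] += fb[0]; r.fy[j + 1] += fb[1]; r.fz[j + 1] += fb[2];
    }
    int i_first = head_fixed ? h + 1 : h;
    int i_last = tail_fixed ? N - 2 : N - 1;
    for (int i = i_first; i <= i_last; ++i) {
      double l_prev = (i > h) ? r.rest[i - 1] : 0.0;
      double l_next = (i < N - 1) ? r.rest[i] : 0.0;
      double l_node = 0.5 * (l_prev + l_next);
      int ip = (i > h) ? i - 1 : i, in = (i < N - 1) ? i + 1 : i;
      double tx = r.px[in] - r.px[ip], ty = r.py[in] - r.py[ip], tz = r.pz[in] - r.pz[ip];
      double tl = std::sqrt(tx * tx + ty * ty + tz * tz);
      if (tl > 1e-9) { tx /= tl; ty /= tl; tz /= tl; } else { tx = 1; ty = 0; tz = 0; }
      double f[3] = {0, 0, 0};
      double Nf = weight_contact(r.pz[i], r.vz[i], l_node, ph, f);
      r.fx[i] += f[0]; r.fy[i] += f[1]; r.fz[i] += f[2];
      double m = std::max(ph.lambda * l_node, 1e-6);
      double qn = 0.5 * ph.rho_w * ph.cdn * ph.diam * l_node;
      double qt = 0.5 * ph.rho_w * ph.cdt * M_PI * ph.diam * l_node;
      if (!ph.semi) { r.px[i] += r.vx[i] * dt; r.py[i] += r.vy[i] * dt; r.pz[i] += r.vz[i] * dt; }
      r.vx[i] += r.fx[i] / m * dt;
      r.vy[i] += r.fy[i] / m * dt;
      r.vz[i] += r.fz[i] / m * dt;
      damp_velocity(r.vx[i], r.vy[i], r.vz[i], tx, ty, tz, qn, qt, m, ph.mu,
                    ph.mu_long, Nf, dt);
      if (ph.semi) { r.px[i] += r.vx[i] * dt; r.py[i] += r.vy[i] * dt; r.pz[i] += r.vz[i] * dt; }
    }
    if (winch_speed > 0.0 && head_fixed && r.head < N - 2) {
      r.rest[r.head] -= winch_speed * dt;
      if (r.rest[r.head] < 0.75 * elem_nominal) {
        r.rest[r.head + 1] += r.rest[r.head];
        r.rest[r.head] = 0.0;
        r.head += 1;
        r.px[r.head] = headp[0]; r.py[r.head] = headp[1]; r.pz[r.head] = headp[2];
        r.vx[r.head] = 0.0; r.vy[r.head] = 0.0; r.vz[r.head] = 0.0;
      }
    }
    if (step % 25 == 0) check_state(r, 1, step * dt, ph.max_speed);
  }

  int h = r.head;
  int n_out = N - h;
  NumericMatrix opos(n_out, 3), ovel(n_out, 3);
  NumericVector orest(std::max(n_out - 1, 0));
  for (int i = 0; i < n_out; ++i) {
    opos(i, 0) = r.px[h + i]; opos(i, 1) = r.py[h + i]; opos(i, 2) = r.pz[h + i];
    ovel(i, 0) = r.vx[h + i]; ovel(i, 1) = r.vy[h + i]; ovel(i, 2) = r.vz[h + i];
  }
  for (int j = 0; j < n_out - 1; ++j) orest[j] = r.rest[h + j];
  double ke = 0.0;
  for (int i = h; i < N; ++i) {
    double l_prev = (i > h) ? r.rest[i - 1] : 0.0;
    double l_next = (i < N - 1) ? r.rest[i] : 0.0;
    double m = ph.lambda * 0.5 * (l_prev + l_next);
    ke += 0.5 * m * (r.vx[i] * r.vx[i] + r.vy[i] * r.vy[i] + r.vz[i] * r.vz[i]);
  }
  return List::create(_["pos"] = opos, _["vel"] = ovel, _["rest"] = orest,
                      _["kinetic_energy"] = ke);
}
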