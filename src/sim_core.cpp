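// Fixed-step simulation core: rigid-body glenohumeral plant in Cardan-angle
// space plus the three-loop cascade/parallel PID muscle-force controller.
// Everything here is called through thin R wrappers; the R level owns all
// configuration, random numbers and file I/O.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double kDeg2Rad = M_PI / 180.0;
static const double kRad2Deg = 180.0 / M_PI;

// ---------------------------------------------------------------------------
// small 3-vector / 3x3 helpers (row-major 3x3)

static inline void rot_x(double a, double R[9]) {
  double c = std::cos(a), s = std::sin(a);
  R[0] = 1; R[1] = 0; R[2] = 0;
  R[3] = 0; R[4] = c; R[5] = -s;
  R[6] = 0; R[7] = s; R[8] = c;
}
static inline void rot_z(double f, double R[9]) {
  double c = std::cos(f), s = std::sin(f);
  R[0] = c; R[1] = -s; R[2] = 0;
  R[3] = s; R[4] = c;  R[5] = 0;
  R[6] = 0; R[7] = 0;  R[8] = 1;
}
static inline void rot_y(double r, double R[9]) {
  double c = std::cos(r), s = std::sin(r);
  R[0] = c;  R[1] = 0; R[2] = s;
  R[3] = 0;  R[4] = 1; R[5] = 0;
  R[6] = -s; R[7] = 0; R[8] = c;
}
static inline void mat_mul(const double A[9], const double B[9], double C[9]) {
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j)
      C[3 * i + j] = A[3 * i] * B[j] + A[3 * i + 1] * B[3 + j] +
                     A[3 * i + 2] * B[6 + j];
}
static inline void mat_vec(const double A[9], const double v[3], double w[3]) {
  for (int i = 0; i < 3; ++i)
    w[i] = A[3 * i] * v[0] + A[3 * i + 1] * v[1] + A[3 * i + 2] * v[2];
}
static inline void cross3(const double a[3], const double b[3], double c[3]) {
  c[0] = a[1] * b[2] - a[2] * b[1];
  c[1] = a[2] * b[0] - a[0] * b[2];
  c[2] = a[0] * b[1] - a[1] * b[0];
}
static inline double clampd(double x, double lo, double hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}

// R = Rx(abd) * Rz(flex) * Ry(rot), angles in radians
static void compose_xzy(const double th[3], double R[9]) {
  double A[9], B[9], C[9];
  rot_x(th[0], A);
  rot_z(th[1], B);
  mat_mul(A, B, C);
  rot_y(th[2], B);
  mat_mul(C, B, R);
}

// Jacobian mapping Cardan rates -> angular velocity in the scapular frame:
// omega = J * thdot; columns x-hat, Rx*z-hat, Rx*Rz*y-hat
static void jac_xzy(const double th[3], double J[9]) {
  double ca = std::cos(th[0]), sa = std::sin(th[0]);
  double cf = std::cos(th[1]), sf = std::sin(th[1]);
  J[0] = 1; J[1] = 0;   J[2] = -sf;
  J[3] = 0; J[4] = -sa; J[5] = ca * cf;
  J[6] = 0; J[7] = ca;  J[8] = sa * cf;
}

// ---------------------------------------------------------------------------
// specimen

#define N_MUSCLE 6
// muscle order everywhere: 0 MD, 1 AD, 2 PD, 3 ISP/TM, 4 SSC, 5 SSP

struct Spec {
  double ins[N_MUSCLE][3];   // insertion, humeral frame, m
  double gui[N_MUSCLE][3];   // effective origin / guide, scapular frame, m
  double mvc[N_MUSCLE];      // kinetic constraint, N
  double r_ad, r_pd, r_isp, r_ssc;  // prior loading ratios
  double ssp_abd[3], ssp_ratio[3];  // SSP ratio knots (deg, ratio)
  double pretension;         // N, initial centering tension
  double floor_n;            // N, never-slack force floor during runs
  double couple_cap_adpd;    // N, printed AD+PD couple cap
  int nmass;
  double mass[4];            // kg
  double mpos[4][3];         // humeral frame, m
  double inertia[3];         // generalized inertia per DOF, kg m^2
  double kpass[3];           // N m / rad
  double cpass[3];           // N m s / rad
  double rest[3];            // rad
  double ktrans[3];          // N / mm
  double head_off[3];        // head-centre offset from the pivot, m
  double R0[9];              // seated resting orientation (translation ref)
  double grav[3];            // m/s^2, scapular frame (inclination applied)
  double disloc_mm;
  double speed_lim;          // rad/s
};

static Spec parse_spec(const List& s) {
  Spec sp;
  NumericMatrix ins = s["insertion_mm"], gui = s["guide_mm"];
  NumericVector mvc = s["mvc_n"];
  for (int m = 0; m < N_MUSCLE; ++m) {
    for (int i = 0; i < 3; ++i) {
      sp.ins[m][i] = ins(i, m) / 1000.0;
      sp.gui[m][i] = gui(i, m) / 1000.0;
    }
    sp.mvc[m] = mvc[m];
  }
  NumericVector lr = s["loading_ratio"];  // MD, AD, PD, ISP, SSC (MD unused=1)
  sp.r_ad = lr[1]; sp.r_pd = lr[2]; sp.r_isp = lr[3]; sp.r_ssc = lr[4];
  NumericMatrix st = s["ssp_table"];
  for (int i = 0; i < 3; ++i) { sp.ssp_abd[i] = st(i, 0); sp.ssp_ratio[i] = st(i, 1); }
  sp.pretension = as<double>(s["pretension_n"]);
  sp.floor_n = as<double>(s["pretension_floor_n"]);
  sp.couple_cap_adpd = as<double>(s["couple_cap_adpd_n"]);
  NumericVector ms = s["mass_kg"];
  NumericMatrix mp = s["mass_pos_mm"];
  sp.nmass = ms.size();
  if (sp.nmass > 4) stop("at most 4 point masses supported");
  for (int j = 0; j < sp.nmass; ++j) {
    sp.mass[j] = ms[j];
    for (int i = 0; i < 3; ++i) sp.mpos[j][i] = mp(i, j) / 1000.0;
  }
  NumericVector in = s["inertia_kgm2"], kp = s["k_passive_nm_rad"],
                cp = s["c_passive_nms_rad"], rs = s["rest_deg"],
                kt = s["k_trans_n_mm"], gv = s["gravity_ms2"];
  for (int i = 0; i < 3; ++i) {
    sp.inertia[i] = in[i]; sp.kpass[i] = kp[i]; sp.cpass[i] = cp[i];
    sp.rest[i] = rs[i] * kDeg2Rad; sp.ktrans[i] = kt[i]; sp.grav[i] = gv[i];
  }
  NumericVector ho = s["head_center_offset_mm"], rp = s["translation_ref_pose_deg"];
  double th0[3];
  for (int i = 0; i < 3; ++i) {
    sp.head_off[i] = ho[i] / 1000.0;
    th0[i] = rp[i] * kDeg2Rad;
  }
  compose_xzy(th0, sp.R0);
  sp.disloc_mm = as<double>(s["dislocation_limit_mm"]);
  sp.speed_lim = as<double>(s["speed_limit_deg_s"]) * kDeg2Rad;
  return sp;
}

static double ssp_interp(const Spec& sp, double abd_deg) {
  if (abd_deg <= sp.ssp_abd[0]) return sp.ssp_ratio[0];
  if (abd_deg >= sp.ssp_abd[2]) return sp.ssp_ratio[2];
  int k = (abd_deg <= sp.ssp_abd[1]) ? 0 : 1;
  double w = (abd_deg - sp.ssp_abd[k]) / (sp.ssp_abd[k + 1] - sp.ssp_abd[k]);
  return sp.ssp_ratio[k] + w * (sp.ssp_ratio[k + 1] - sp.ssp_ratio[k]);
}

// total Cartesian muscle torque about the COR (N m, scapular frame);
// optionally per-muscle columns and the net muscle force vector (N)
static void muscle_torque(const Spec& sp, const double R[9], const double F[6],
                          double tau[3], double* per = 0, double* fnet = 0) {
  tau[0] = tau[1] = tau[2] = 0;
  if (fnet) fnet[0] = fnet[1] = fnet[2] = 0;
  for (int m = 0; m < N_MUSCLE; ++m) {
    double p[3], d[3], t[3];
    mat_vec(R, sp.ins[m], p);
    for (int i = 0; i < 3; ++i) d[i] = sp.gui[m][i] - p[i];
    double n = std::sqrt(d[0] * d[0] + d[1] * d[1] + d[2] * d[2]);
    if (n < 1e-9) stop("muscle insertion coincides with guide point");
    for (int i = 0; i < 3; ++i) d[i] = d[i] / n * F[m];
    cross3(p, d, t);
    for (int i = 0; i < 3; ++i) {
      tau[i] += t[i];
      if (fnet) fnet[i] += d[i];
    }
    if (per) for (int i = 0; i < 3; ++i) per[3 * m + i] = t[i];
  }
}

static void gravity_torque(const Spec& sp, const double R[9], double tau[3],
                           double* fnet = 0) {
  tau[0] = tau[1] = tau[2] = 0;
  for (int j = 0; j < sp.nmass; ++j) {
    double p[3], fg[3], t[3];
    mat_vec(R, sp.mpos[j], p);
    for (int i = 0; i < 3; ++i) fg[i] = sp.mass[j] * sp.grav[i];
    cross3(p, fg, t);
    for (int i = 0; i < 3; ++i) {
      tau[i] += t[i];
      if (fnet) fnet[i] += fg[i];
    }
  }
}

// y = [theta(3) rad, thetadot(3) rad/s]; muscle forces held over the step
static void plant_deriv(const Spec& sp, const double y[6], const double F[6],
                        double dy[6]) {
  double R[9], J[9], tau[3], taug[3], Q[3];
  compose_xzy(y, R);
  muscle_torque(sp, R, F, tau);
  gravity_torque(sp, R, taug);
  for (int i = 0; i < 3; ++i) tau[i] += taug[i];
  jac_xzy(y, J);
  for (int i = 0; i < 3; ++i)  // Q = J^T tau
    Q[i] = J[i] * tau[0] + J[3 + i] * tau[1] + J[6 + i] * tau[2];
  for (int i = 0; i < 3; ++i) {
    dy[i] = y[3 + i];
    dy[3 + i] = (Q[i] - sp.kpass[i] * (y[i] - sp.rest[i]) -
                 sp.cpass[i] * y[3 + i]) / sp.inertia[i];
  }
}

static void rk4_step(const Spec& sp, double y[6], const double F[6], double dt) {
  double k1[6], k2[6], k3[6], k4[6], yt[6];
  plant_deriv(sp, y, F, k1);
  for (int i = 0; i < 6; ++i) yt[i] = y[i] + 0.5 * dt * k1[i];
  plant_deriv(sp, yt, F, k2);
  for (int i = 0; i < 6; ++i) yt[i] = y[i] + 0.5 * dt * k2[i];
  plant_deriv(sp, yt, F, k3);
  for (int i = 0; i < 6; ++i) yt[i] = y[i] + dt * k3[i];
  plant_deriv(sp, yt, F, k4);
  for (int i = 0; i < 6; ++i)
    y[i] += dt / 6.0 * (k1[i] + 2 * k2[i] + 2 * k3[i] + k4[i]);
}

// Quasi-static translation of the humeral head (mm, scapular frame):
// an elastic shear deflection of the net joint force plus the kinematic
// excursion of the articular head centre, which sits a few mm away from the
// least-moving pivot and therefore rides with the rotation. Both terms are
// measured from the seated resting pose R0.
static void translation_mm(const Spec& sp, const double y[6], const double F[6],
                           double t[3]) {
  double R[9], tau[3], fm[3];
  compose_xzy(y, R);
  muscle_torque(sp, R, F, tau, 0, fm);
  double mtot = 0;
  for (int j = 0; j < sp.nmass; ++j) mtot += sp.mass[j];
  double o1[3], o0[3];
  mat_vec(R, sp.head_off, o1);
  mat_vec(sp.R0, sp.head_off, o0);
  for (int i = 0; i < 3; ++i)
    t[i] = (fm[i] + mtot * sp.grav[i]) / sp.ktrans[i] +
           (o1[i] - o0[i]) * 1000.0;
}

static double mech_energy(const Spec& sp, const double y[6]) {
  double R[9], e = 0;
  compose_xzy(y, R);
  for (int i = 0; i < 3; ++i) {
    e += 0.5 * sp.inertia[i] * y[3 + i] * y[3 + i];
    double d = y[i] - sp.rest[i];
    e += 0.5 * sp.kpass[i] * d * d;
  }
  for (int j = 0; j < sp.nmass; ++j) {  // V = - m g . (R p)
    double p[3];
    mat_vec(R, sp.mpos[j], p);
    e -= sp.mass[j] * (sp.grav[0] * p[0] + sp.grav[1] * p[1] + sp.grav[2] * p[2]);
  }
  return e;
}

// ---------------------------------------------------------------------------
// PID with conditional-integration anti-windup.
// u = Kc * (e + (1/Ti_s) * int e dt + Td_s * d(e)/dt), Ti/Td given in minutes.
// state: [integ (deg s), prev_e (deg), dfilt (deg/s), has_prev]

static double pid_apply(const double kc, const double ti_min, const double td_min,
                        double st[4], double sp, double pv, double dt,
                        double lo, double hi, int* sat) {
  double ti_s = ti_min * 60.0, td_s = td_min * 60.0;
  double e = sp - pv;
  double d_raw = st[3] > 0.5 ? (e - st[1]) / dt : 0.0;
  double tau_f = std::fmax(4.0 * dt, td_s / 8.0);
  st[2] += (dt / tau_f) * (d_raw - st[2]);
  double integ_try = st[0] + e * dt;
  double u = kc * (e + integ_try / ti_s + td_s * st[2]);
  *sat = 0;
  if (u > hi) {
    if (e > 0)  // freeze the accumulator while pushing further into the clamp
      u = kc * (e + st[0] / ti_s + td_s * st[2]);
    else
      st[0] = integ_try;
    if (u > hi) u = hi;
    *sat = 1;
  } else if (u < lo) {
    if (e < 0)
      u = kc * (e + st[0] / ti_s + td_s * st[2]);
    else
      st[0] = integ_try;
    if (u < lo) u = lo;
    *sat = 1;
  } else {
    st[0] = integ_try;
  }
  st[1] = e;
  st[3] = 1;
  return u;
}

// bumpless transfer: set the accumulator so the controller output equals
// u_target at the current error (derivative state cleared)
static void pid_retarget(const double kc, const double ti_min, double st[4],
                         double u_target, double e) {
  st[0] = ti_min * 60.0 * (u_target / kc - e);
  st[1] = e;
  st[2] = 0;
  st[3] = 1;
}

struct Gains {
  // rows: kc, ti_min, td_min
  double abd_p[3], abd_c[3];
  double fe_act[3], fe_dist_p[3], fe_dist_c[3];
  double ir_act[3], ir_dist_p[3], ir_dist_c[3];
  double s_abd;    // N of MD force per PID output unit (abduction activation)
  double s_cpl;    // N of couple total per PID unit (F/E and IR/ER activation)
  double s_dist;   // share fraction per PID unit (distribution controllers)
  bool ssp_slaved;
};

static void row3(const List& g, const char* nm, double out[3]) {
  NumericVector v = g[nm];
  out[0] = v[0]; out[1] = v[1]; out[2] = v[2];
}
static Gains parse_gains(const List& g) {
  Gains gn;
  row3(g, "abd_act_profile", gn.abd_p);
  row3(g, "abd_act_constant", gn.abd_c);
  row3(g, "fe_act", gn.fe_act);
  row3(g, "fe_dist_profile", gn.fe_dist_p);
  row3(g, "fe_dist_constant", gn.fe_dist_c);
  row3(g, "ir_act", gn.ir_act);
  row3(g, "ir_dist_profile", gn.ir_dist_p);
  row3(g, "ir_dist_constant", gn.ir_dist_c);
  gn.s_abd = as<double>(g["act_scale_abd"]);
  gn.s_cpl = as<double>(g["act_scale_couple"]);
  gn.s_dist = as<double>(g["dist_scale"]);
  gn.ssp_slaved = as<bool>(g["ssp_slaved"]);
  return gn;
}

// controller state matrix: 5 rows (abd_act, fe_act, fe_dist, ir_act, ir_dist)
// x 4 cols (integ, prev_e, dfilt, has_prev)

struct TickOut {
  double F[6];
  double share_fe, share_ir, tot_fe_raw, tot_ir_raw, u_abd;
  int sat;
};

// mode: 0 cascade, 1 parallel
static TickOut control_tick(const Spec& sp, const Gains& gn, double* cs,
                            const double spd[3], const double pv[3], double dt,
                            int mode, int abd_profile, int fe_profile,
                            int ir_profile, int fe_dir, int ir_dir) {
  TickOut o;
  o.sat = 0;
  int s;
  double pre = sp.floor_n;
  const double* ga = abd_profile ? gn.abd_p : gn.abd_c;
  double hi_abd = (sp.mvc[0] - pre) / gn.s_abd;
  o.u_abd = pid_apply(ga[0], ga[1], ga[2], cs, spd[0], pv[0], dt, 0.0, hi_abd, &s);
  if (s) o.sat |= 1;
  double MD = pre + gn.s_abd * o.u_abd;
  double SSP = clampd(MD * ssp_interp(sp, pv[0]), pre, sp.mvc[5]);
  if (SSP != MD * ssp_interp(sp, pv[0])) o.sat |= 64;

  // distribution shares first: the couple totals are capped so that the
  // agonist can honour its kinetic constraint without the overflow being
  // dumped onto the antagonist
  const double* gf = fe_profile ? gn.fe_dist_p : gn.fe_dist_c;
  double lim = 0.45 / gn.s_dist;
  double u = pid_apply(gf[0], gf[1], gf[2], cs + 8, spd[1], pv[1], dt,
                       -lim, lim, &s);
  if (s) o.sat |= 8;
  o.share_fe = 0.5 + gn.s_dist * u;  // in [0.05, 0.95]
  const double* gr = ir_profile ? gn.ir_dist_p : gn.ir_dist_c;
  u = pid_apply(gr[0], gr[1], gr[2], cs + 16, spd[2], pv[2], dt, -lim, lim, &s);
  if (s) o.sat |= 16;
  o.share_ir = 0.5 + gn.s_dist * u;

  double cap_fe = std::fmin(sp.couple_cap_adpd,
                  std::fmin(sp.mvc[1] / o.share_fe,
                            sp.mvc[2] / (1.0 - o.share_fe)));
  double cap_ir = std::fmin(sp.mvc[3] + sp.mvc[4],
                  std::fmin(sp.mvc[4] / o.share_ir,
                            sp.mvc[3] / (1.0 - o.share_ir)));
  if (mode == 0) {
    o.tot_fe_raw = (sp.r_ad + sp.r_pd) * MD;
    o.tot_ir_raw = (sp.r_ssc + sp.r_isp) * MD;
  } else {
    // The activation regulates the couple total (the co-contraction
    // envelope); the distribution controller decides the antagonist split.
    // In profile mode the activation error is signed by the commanded
    // motion direction; in constant (hold) mode it is the error magnitude,
    // so the total rises whichever way the hold is disturbed.
    double e_fe = fe_profile ? fe_dir * (spd[1] - pv[1])
                             : std::fabs(spd[1] - pv[1]);
    double e_ir = ir_profile ? ir_dir * (spd[2] - pv[2])
                             : std::fabs(spd[2] - pv[2]);
    double hi = (cap_fe - 2 * pre) / gn.s_cpl;
    u = pid_apply(gn.fe_act[0], gn.fe_act[1], gn.fe_act[2], cs + 4,
                  e_fe, 0.0, dt, 0.0, hi, &s);
    if (s) o.sat |= 2;
    o.tot_fe_raw = 2 * pre + gn.s_cpl * u;
    hi = (cap_ir - 2 * pre) / gn.s_cpl;
    u = pid_apply(gn.ir_act[0], gn.ir_act[1], gn.ir_act[2], cs + 12,
                  e_ir, 0.0, dt, 0.0, hi, &s);
    if (s) o.sat |= 4;
    o.tot_ir_raw = 2 * pre + gn.s_cpl * u;
  }
  double totF = clampd(o.tot_fe_raw, 2 * pre, cap_fe);
  double totR = clampd(o.tot_ir_raw, 2 * pre, cap_ir);
  if (totF != o.tot_fe_raw) o.sat |= 2;
  if (totR != o.tot_ir_raw) o.sat |= 4;

  double AD = clampd(o.share_fe * totF, std::fmax(pre, totF - sp.mvc[2]),
                     std::fmin(sp.mvc[1], totF - pre));
  if (AD != o.share_fe * totF) o.sat |= 32;
  double PD = totF - AD;
  double SSC = clampd(o.share_ir * totR, std::fmax(pre, totR - sp.mvc[3]),
                      std::fmin(sp.mvc[4], totR - pre));
  if (SSC != o.share_ir * totR) o.sat |= 32;
  double ISP = totR - SSC;

  o.F[0] = MD; o.F[1] = AD; o.F[2] = PD; o.F[3] = ISP; o.F[4] = SSC; o.F[5] = SSP;
  return o;
}

// ---------------------------------------------------------------------------
// exported single-step / small helpers

// [[Rcpp::export]]
NumericMatrix cpp_compose_xzy(NumericVector angles_deg) {
  double th[3] = {angles_deg[0] * kDeg2Rad, angles_deg[1] * kDeg2Rad,
                  angles_deg[2] * kDeg2Rad};
  double R[9];
  compose_xzy(th, R);
  NumericMatrix out(3, 3);
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) out(i, j) = R[3 * i + j];
  return out;
}

// [[Rcpp::export]]
List cpp_pid_step(double kc, double ti_min, double td_min, NumericVector state,
                  double sp, double pv, double dt, double lo, double hi) {
  double st[4] = {state[0], state[1], state[2], state[3]};
  int sat;
  double u = pid_apply(kc, ti_min, td_min, st, sp, pv, dt, lo, hi, &sat);
  return List::create(_["u"] = u,
                      _["state"] = NumericVector::create(st[0], st[1], st[2], st[3]),
                      _["saturated"] = sat == 1);
}

// [[Rcpp::export]]
List cpp_muscle_torques(List specimen, NumericVector angles_deg,
                        NumericVector forces_n) {
  Spec sp = parse_spec(specimen);
  double th[3] = {angles_deg[0] * kDeg2Rad, angles_deg[1] * kDeg2Rad,
                  angles_deg[2] * kDeg2Rad};
  double R[9], tau[3], per[18], fnet[3];
  compose_xzy(th, R);
  double F[6];
  for (int m = 0; m < 6; ++m) F[m] = forces_n[m];
  muscle_torque(sp, R, F, tau, per, fnet);
  NumericMatrix pm(3, 6);
  for (int m = 0; m < 6; ++m)
    for (int i = 0; i < 3; ++i) pm(i, m) = per[3 * m + i];
  return List::create(_["total_nm"] = NumericVector::create(tau[0], tau[1], tau[2]),
                      _["per_muscle_nm"] = pm,
                      _["net_force_n"] = NumericVector::create(fnet[0], fnet[1], fnet[2]));
}

// [[Rcpp::export]]
List cpp_plant_step(List specimen, NumericVector state, NumericVector forces_n,
                    double dt) {
  Spec sp = parse_spec(specimen);
  double y[6], F[6], t[3];
  for (int i = 0; i < 3; ++i) {
    y[i] = state[i] * kDeg2Rad;
    y[3 + i] = state[3 + i] * kDeg2Rad;
  }
  for (int m = 0; m < 6; ++m) F[m] = forces_n[m];
  rk4_step(sp, y, F, dt);
  translation_mm(sp, y, F, t);
  NumericVector out(6);
  for (int i = 0; i < 3; ++i) {
    out[i] = y[i] * kRad2Deg;
    out[3 + i] = y[3 + i] * kRad2Deg;
  }
  return List::create(_["state"] = out,
                      _["translation_mm"] = NumericVector::create(t[0], t[1], t[2]),
                      _["energy_j"] = mech_energy(sp, y));
}

// [[Rcpp::export]]
List cpp_passive_sim(List specimen, NumericVector forces_n, double duration_s,
                     double dt, bool record_energy) {
  Spec sp = parse_spec(specimen);
  int n = (int)std::ceil(duration_s / dt);
  double y[6] = {sp.rest[0], sp.rest[1], sp.rest[2], 0, 0, 0};
  double F[6];
  for (int m = 0; m < 6; ++m) F[m] = forces_n[m];
  NumericVector en(record_energy ? n + 1 : 0);
  if (record_energy) en[0] = mech_energy(sp, y);
  for (int i = 0; i < n; ++i) {
    rk4_step(sp, y, F, dt);
    if (record_energy) en[i + 1] = mech_energy(sp, y);
  }
  double t[3];
  translation_mm(sp, y, F, t);
  NumericVector st(6);
  for (int i = 0; i < 3; ++i) {
    st[i] = y[i] * kRad2Deg;
    st[3 + i] = y[3 + i] * kRad2Deg;
  }
  return List::create(_["state"] = st,
                      _["translation_mm"] = NumericVector::create(t[0], t[1], t[2]),
                      _["energy_j"] = en);
}

// [[Rcpp::export]]
List cpp_control_tick(List specimen, List gains, NumericMatrix ctrl_state,
                      NumericVector sp_deg, NumericVector pv_deg, double dt,
                      int mode, int abd_profile, int fe_profile, int ir_profile,
                      int fe_dir, int ir_dir) {
  Spec sp = parse_spec(specimen);
  Gains gn = parse_gains(gains);
  double cs[20];
  for (int r = 0; r < 5; ++r)
    for (int c = 0; c < 4; ++c) cs[4 * r + c] = ctrl_state(r, c);
  double spd[3] = {sp_deg[0], sp_deg[1], sp_deg[2]};
  double pvd[3] = {pv_deg[0], pv_deg[1], pv_deg[2]};
  TickOut o = control_tick(sp, gn, cs, spd, pvd, dt, mode, abd_profile,
                           fe_profile, ir_profile, fe_dir, ir_dir);
  NumericMatrix cso(5, 4);
  for (int r = 0; r < 5; ++r)
    for (int c = 0; c < 4; ++c) cso(r, c) = cs[4 * r + c];
  NumericVector F(6);
  for (int m = 0; m < 6; ++m) F[m] = o.F[m];
  return List::create(_["forces_n"] = F, _["state"] = cso,
                      _["share_fe"] = o.share_fe, _["share_ir"] = o.share_ir,
                      _["tot_fe_raw"] = o.tot_fe_raw, _["tot_ir_raw"] = o.tot_ir_raw,
                      _["sat_flags"] = o.sat);
}

// ---------------------------------------------------------------------------
// full trial: loading (cascade) -> settle -> scored segment, controller at
// every plant step, trace decimated for recording.
//
// profile: matrix with columns time_s, sp_abd, sp_fe, sp_rot, phase
//          (0 load, 1 settle, 2 scored, 3 tail)
// mode_parallel: 0 = cascade protocol (abduction), 1 = parallel
// fe_profile / ir_profile: distribution gain rows used after the load phase

// [[Rcpp::export]]
List cpp_run_trial(List specimen, List gains, NumericMatrix profile,
                   int mode_parallel, int fe_profile, int ir_profile,
                   int fe_dir, int ir_dir,
                   NumericVector init_state, double dt, int decim) {
  Spec sp = parse_spec(specimen);
  Gains gn = parse_gains(gains);
  int n = profile.nrow();
  double y[6];
  for (int i = 0; i < 3; ++i) {
    y[i] = init_state[i] * kDeg2Rad;
    y[3 + i] = init_state[3 + i] * kDeg2Rad;
  }
  double cs[20];
  for (int i = 0; i < 20; ++i) cs[i] = 0;  // controllers reset at trial start

  int nrec = (n + decim - 1) / decim;
  NumericMatrix tr(nrec, 22);
  int status = 0, irec = 0;
  int prev_phase = -1, prev_abd_row = -1, prev_mode = -1;
  double last_u_abd = 0, last_totF = 2 * sp.floor_n, last_totR = 2 * sp.floor_n;
  double last_share_fe = 0.5, last_share_ir = 0.5;
  int prev_fe_row = -1, prev_ir_row = -1;

  for (int i = 0; i < n; ++i) {
    double t = profile(i, 0);
    double spd[3] = {profile(i, 1), profile(i, 2), profile(i, 3)};
    int phase = (int)profile(i, 4);
    double pv[3] = {y[0] * kRad2Deg, y[1] * kRad2Deg, y[2] * kRad2Deg};

    // mode / gain-row schedule
    int mode = (phase == 0) ? 0 : mode_parallel;
    int abd_ramp = 0;
    if (i + 1 < n)
      abd_ramp = std::fabs(profile(i + 1, 1) - profile(i, 1)) > 1e-12 ? 1 : 0;
    int abd_row;   // 1 = profile gains, 0 = constant gains
    if (phase == 0) abd_row = 1;
    else if (mode == 0) abd_row = abd_ramp;
    else abd_row = 0;
    int fe_row = (phase == 0) ? 0 : (mode == 1 ? fe_profile : 0);
    int ir_row = (phase == 0) ? 0 : (mode == 1 ? ir_profile : 0);

    // bumpless transfers on row / mode changes
    if (prev_abd_row >= 0 && abd_row != prev_abd_row) {
      const double* g = abd_row ? gn.abd_p : gn.abd_c;
      pid_retarget(g[0], g[1], cs, last_u_abd, spd[0] - pv[0]);
    }
    if (prev_mode == 0 && mode == 1) {
      pid_retarget(gn.fe_act[0], gn.fe_act[1], cs + 4,
                   (last_totF - 2 * sp.floor_n) / gn.s_cpl,
                   fe_dir * (spd[1] - pv[1]));
      pid_retarget(gn.ir_act[0], gn.ir_act[1], cs + 12,
                   (last_totR - 2 * sp.floor_n) / gn.s_cpl,
                   ir_dir * (spd[2] - pv[2]));
    }
    if (prev_fe_row >= 0 && fe_row != prev_fe_row) {
      const double* g = fe_row ? gn.fe_dist_p : gn.fe_dist_c;
      pid_retarget(g[0], g[1], cs + 8, (last_share_fe - 0.5) / gn.s_dist,
                   spd[1] - pv[1]);
    }
    if (prev_ir_row >= 0 && ir_row != prev_ir_row) {
      const double* g = ir_row ? gn.ir_dist_p : gn.ir_dist_c;
      pid_retarget(g[0], g[1], cs + 16, (last_share_ir - 0.5) / gn.s_dist,
                   spd[2] - pv[2]);
    }
    prev_abd_row = abd_row; prev_mode = mode; prev_phase = phase;
    prev_fe_row = fe_row; prev_ir_row = ir_row;

    TickOut o = control_tick(sp, gn, cs, spd, pv, dt, mode, abd_row,
                             fe_row, ir_row, fe_dir, ir_dir);
    last_u_abd = o.u_abd;
    last_totF = clampd(o.tot_fe_raw, 2 * sp.floor_n, sp.couple_cap_adpd);
    last_totR = clampd(o.tot_ir_raw, 2 * sp.floor_n, sp.mvc[3] + sp.mvc[4]);
    last_share_fe = o.share_fe; last_share_ir = o.share_ir;

    double trans[3];
    translation_mm(sp, y, o.F, trans);

    if (i % decim == 0) {
      tr(irec, 0) = t; tr(irec, 1) = phase;
      for (int k = 0; k < 3; ++k) {
        tr(irec, 2 + k) = spd[k];
        tr(irec, 5 + k) = pv[k];
        tr(irec, 8 + k) = trans[k];
      }
      for (int m = 0; m < 6; ++m) tr(irec, 11 + m) = o.F[m];
      tr(irec, 17) = o.share_fe; tr(irec, 18) = o.share_ir;
      tr(irec, 19) = o.tot_fe_raw; tr(irec, 20) = o.tot_ir_raw;
      tr(irec, 21) = o.sat;
      ++irec;
    }

    rk4_step(sp, y, o.F, dt);

    double tmax = std::fmax(std::fabs(trans[0]),
                  std::fmax(std::fabs(trans[1]), std::fabs(trans[2])));
    if (tmax > sp.disloc_mm) { status = 1; break; }
    double wmax = std::fmax(std::fabs(y[3]),
                  std::fmax(std::fabs(y[4]), std::fabs(y[5])));
    if (wmax > sp.speed_lim || !std::isfinite(y[0] + y[1] + y[2])) {
      status = 2; break;
    }
  }

  NumericVector fin(6);
  for (int i = 0; i < 3; ++i) {
    fin[i] = y[i] * kRad2Deg;
    fin[3 + i] = y[3 + i] * kRad2Deg;
  }
  if (status != 0 && irec < nrec) {
    // truncate recording at the failure point
    NumericMatrix tt(irec, 22);
    for (int r = 0; r < irec; ++r)
      for (int c = 0; c < 22; ++c) tt(r, c) = tr(r, c);
    tr = tt;
  }
  return List::create(_["trace"] = tr, _["status"] = status,
                      _["final_state"] = fin);
}
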