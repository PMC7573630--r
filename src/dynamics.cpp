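// Implicit full-body dynamics core: forward kinematics over a chain of
// elementary (1-DOF) joints, recursive Newton-Euler inverse dynamics,
// Hill-type muscle residuals with the projected-CE-length state, and
// penetration ground contact. Everything is templated on the scalar type;
// a forward-mode dual-number type supplies machine-precision directional
// derivatives (algorithmic differentiation), assembled into the sparse
// collocation Jacobians with the backward-Euler chain rule.

#include <Rcpp.h>
#include <array>
#include <cmath>
#include <vector>

using Rcpp::List;
using Rcpp::NumericMatrix;
using Rcpp::NumericVector;

// ---------------- forward-mode dual number ----------------
struct Dual {
  double v, d;
  Dual() : v(0), d(0) {}
  Dual(double x) : v(x), d(0) {}
  Dual(double x, double dx) : v(x), d(dx) {}
};
static inline Dual operator+(Dual a, Dual b) { return {a.v + b.v, a.d + b.d}; }
static inline Dual operator-(Dual a, Dual b) { return {a.v - b.v, a.d - b.d}; }
static inline Dual operator-(Dual a) { return {-a.v, -a.d}; }
static inline Dual operator*(Dual a, Dual b) {
  return {a.v * b.v, a.d * b.v + a.v * b.d};
}
static inline Dual operator/(Dual a, Dual b) {
  double inv = 1.0 / b.v;
  return {a.v * inv, (a.d - a.v * b.d * inv) * inv};
}
static inline Dual& operator+=(Dual& a, Dual b) { a = a + b; return a; }
static inline Dual& operator-=(Dual& a, Dual b) { a = a - b; return a; }
static inline Dual sqrt(Dual a) {
  double s = std::sqrt(a.v);
  return {s, s > 0 ? a.d / (2 * s) : 0.0};
}
static inline Dual sin(Dual a) { return {std::sin(a.v), std::cos(a.v) * a.d}; }
static inline Dual cos(Dual a) { return {std::cos(a.v), -std::sin(a.v) * a.d}; }
static inline Dual exp(Dual a) {
  double e = std::exp(a.v);
  return {e, e * a.d};
}
static inline Dual asin(Dual a) {
  return {std::asin(a.v), a.d / std::sqrt(1.0 - a.v * a.v)};
}
static inline double re(double x) { return x; }
static inline double re(Dual x) { return x.v; }
static inline double der(double) { return 0.0; }
static inline double der(Dual x) { return x.d; }

template <class T> using V3 = std::array<T, 3>;
template <class T> using M3 = std::array<T, 9>; // row-major

template <class T> static inline V3<T> vadd(const V3<T>& a, const V3<T>& b) {
  return {a[0] + b[0], a[1] + b[1], a[2] + b[2]};
}
template <class T> static inline V3<T> vsub(const V3<T>& a, const V3<T>& b) {
  return {a[0] - b[0], a[1] - b[1], a[2] - b[2]};
}
template <class T> static inline V3<T> vscl(const V3<T>& a, T s) {
  return {a[0] * s, a[1] * s, a[2] * s};
}
template <class T> static inline V3<T> vcross(const V3<T>& a, const V3<T>& b) {
  return {a[1] * b[2] - a[2] * b[1], a[2] * b[0] - a[0] * b[2],
          a[0] * b[1] - a[1] * b[0]};
}
template <class T> static inline T vdot(const V3<T>& a, const V3<T>& b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}
template <class T> static inline V3<T> vzero() { return {T(0), T(0), T(0)}; }
template <class T> static inline V3<T> mv(const M3<T>& m, const V3<T>& v) {
  return {m[0] * v[0] + m[1] * v[1] + m[2] * v[2],
          m[3] * v[0] + m[4] * v[1] + m[5] * v[2],
          m[6] * v[0] + m[7] * v[1] + m[8] * v[2]};
}
template <class T> static inline M3<T> mm(const M3<T>& a, const M3<T>& b) {
  M3<T> c;
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j)
      c[3 * i + j] = a[3 * i] * b[j] + a[3 * i + 1] * b[3 + j] +
                     a[3 * i + 2] * b[6 + j];
  return c;
}
template <class T> static inline M3<T> meye() {
  return {T(1), T(0), T(0), T(0), T(1), T(0), T(0), T(0), T(1)};
}
template <class T> static inline M3<T> mtrans(const M3<T>& m) {
  return {m[0], m[3], m[6], m[1], m[4], m[7], m[2], m[5], m[8]};
}

// Rodrigues rotation about a fixed (real) unit axis
template <class T>
static inline M3<T> rot_axis(const double* a, const T& th) {
  T c = cos(th), s = sin(th);
  T omc = T(1) - c;
  M3<T> R;
  R[0] = c + a[0] * a[0] * omc;
  R[1] = a[0] * a[1] * omc - a[2] * s;
  R[2] = a[0] * a[2] * omc + a[1] * s;
  R[3] = a[1] * a[0] * omc + a[2] * s;
  R[4] = c + a[1] * a[1] * omc;
  R[5] = a[1] * a[2] * omc - a[0] * s;
  R[6] = a[2] * a[0] * omc - a[1] * s;
  R[7] = a[2] * a[1] * omc + a[0] * s;
  R[8] = c + a[2] * a[2] * omc;
  return R;
}

struct MuscleP {
  double fiso, lopt, lslack, W, vmax, ahill, fecc, h; // h = lopt*sin(phi_opt)
  double tact, tdeact, eps0, kpee, dce;
  int term_off, n_term;
};

struct ModelData {
  int nb = 0, nmus = 0, ntor = 0, ncp = 0;
  std::vector<int> parent, jtype; // jtype: 0 prismatic, 1 revolute
  std::vector<double> axis, offset;          // 3*nb each, parent frame
  std::vector<double> mass, com, inertia;    // nb, 3*nb, 9*nb
  std::vector<int> cp_body, cp_foot;         // ncp; foot: 0 right, 1 left
  std::vector<double> cp_local;              // 3*ncp
  std::vector<MuscleP> mus;
  std::vector<double> term_coef;
  std::vector<int> term_nd, term_doff, term_dof, term_pow;
  std::vector<int> tor_dof;
  std::vector<double> dof_damp;
  double tor_scale = 10.0;
  double grav[3] = {0, -9.81, 0};
  double mb_scale = 1.0, act_scale = 0.01;
  double k_n = 2.5e8, c_n = 1.0, mu = 1.0, v_c = 0.01, eps_p = 1e-3,
         f_eps = 1e-3;
  std::vector<unsigned char> anc; // nb*nb, anc[b*nb+j]: dof j moves body b
  int pel_tx = 0, pel_ty = 1, pel_tz = 2, pel_rot = 3;
};

static ModelData parse_model(const List& ml) {
  ModelData md;
  Rcpp::IntegerVector parent = ml["parent"], jtype = ml["jtype"];
  md.nb = parent.size();
  md.parent.assign(parent.begin(), parent.end());
  md.jtype.assign(jtype.begin(), jtype.end());
  NumericVector ax = ml["axis"], off = ml["offset"], mass = ml["mass"],
                com = ml["com"], inr = ml["inertia"];
  md.axis.assign(ax.begin(), ax.end());
  md.offset.assign(off.begin(), off.end());
  md.mass.assign(mass.begin(), mass.end());
  md.com.assign(com.begin(), com.end());
  md.inertia.assign(inr.begin(), inr.end());
  Rcpp::IntegerVector cb = ml["cp_body"], cf = ml["cp_foot"];
  md.ncp = cb.size();
  md.cp_body.assign(cb.begin(), cb.end());
  md.cp_foot.assign(cf.begin(), cf.end());
  NumericVector cl = ml["cp_local"];
  md.cp_local.assign(cl.begin(), cl.end());
  NumericMatrix mp = ml["mus_par"];
  md.nmus = mp.nrow();
  for (int i = 0; i < md.nmus; ++i) {
    MuscleP m;
    m.fiso = mp(i, 0); m.lopt = mp(i, 1); m.lslack = mp(i, 2);
    m.W = mp(i, 3); m.vmax = mp(i, 4); m.ahill = mp(i, 5);
    m.fecc = mp(i, 6); m.h = mp(i, 1) * std::sin(mp(i, 7));
    m.tact = mp(i, 8); m.tdeact = mp(i, 9); m.eps0 = mp(i, 10);
    m.kpee = mp(i, 11); m.dce = mp(i, 12);
    md.mus.push_back(m);
  }
  NumericVector tc = ml["term_coef"];
  Rcpp::IntegerVector tm = ml["term_mus"], tnd = ml["term_nd"],
                      tdof = ml["term_dof"], tpow = ml["term_pow"];
  md.term_coef.assign(tc.begin(), tc.end());
  md.term_nd.assign(tnd.begin(), tnd.end());
  md.term_dof.assign(tdof.begin(), tdof.end());
  md.term_pow.assign(tpow.begin(), tpow.end());
  {
    int nterm = tm.size(), pos = 0, dpos = 0;
    md.term_doff.resize(nterm);
    for (int t = 0; t < nterm; ++t) {
      md.term_doff[t] = dpos;
      dpos += tnd[t];
    }
    for (int i = 0; i < md.nmus; ++i) {
      md.mus[i].term_off = pos;
      int n = 0;
      while (pos + n < nterm && tm[pos + n] == i) ++n;
      md.mus[i].n_term = n;
      pos += n;
    }
  }
  Rcpp::IntegerVector td = ml["tor_dof"];
  md.tor_dof.assign(td.begin(), td.end());
  md.ntor = td.size();
  md.tor_scale = Rcpp::as<double>(ml["tor_scale"]);
  NumericVector dd = ml["dof_damp"];
  md.dof_damp.assign(dd.begin(), dd.end());
  NumericVector g = ml["gravity"];
  for (int k = 0; k < 3; ++k) md.grav[k] = g[k];
  md.mb_scale = Rcpp::as<double>(ml["mb_scale"]);
  md.act_scale = Rcpp::as<double>(ml["act_scale"]);
  NumericVector cp = ml["contact_par"];
  md.k_n = cp[0]; md.c_n = cp[1]; md.mu = cp[2];
  md.v_c = cp[3]; md.eps_p = cp[4]; md.f_eps = cp[5];
  md.anc.assign((size_t)md.nb * md.nb, 0);
  for (int b = 0; b < md.nb; ++b)
    for (int j = b; j >= 0; j = md.parent[j]) md.anc[(size_t)b * md.nb + j] = 1;
  Rcpp::IntegerVector pel = ml["pelvis_idx"];
  md.pel_tx = pel[0]; md.pel_ty = pel[1];
  md.pel_tz = pel[2]; md.pel_rot = pel[3];
  return md;
}

// ---------------- preallocated workspace ----------------
template <class T> struct Ws {
  std::vector<M3<T>> R;
  std::vector<V3<T>> O, sax, w, vO, dw;
  std::vector<V3<T>> wd, aO, ac, cw, fb, nb_;
  std::vector<T> tau_ext, tau, dldq, xk, xdot;
  void size_for(const ModelData& md, int nx) {
    int nb = md.nb;
    R.resize(nb); O.resize(nb); sax.resize(nb); w.resize(nb); vO.resize(nb);
    dw.resize(nb); wd.resize(nb); aO.resize(nb); ac.resize(nb);
    cw.resize(nb); fb.resize(nb); nb_.resize(nb);
    tau_ext.resize(nb); tau.resize(nb); dldq.resize(nb);
    xk.resize(nx); xdot.resize(nx);
  }
};

template <class T>
static void fk_pass(const ModelData& md, const T* q, const T* qd, Ws<T>& K) {
  int nb = md.nb;
  for (int i = 0; i < nb; ++i) {
    int p = md.parent[i];
    const M3<T>& Rp = (p < 0) ? meye<T>() : K.R[p];
    V3<T> Op = (p < 0) ? vzero<T>() : K.O[p];
    V3<T> wp = (p < 0) ? vzero<T>() : K.w[p];
    V3<T> vp = (p < 0) ? vzero<T>() : K.vO[p];
    const double* offd = &md.offset[3 * i];
    V3<T> off = {T(offd[0]), T(offd[1]), T(offd[2])};
    V3<T> dw = mv(Rp, off);
    K.dw[i] = dw;
    const double* axd = &md.axis[3 * i];
    V3<T> axT = {T(axd[0]), T(axd[1]), T(axd[2])};
    V3<T> s = mv(Rp, axT);
    K.sax[i] = s;
    if (md.jtype[i] == 1) { // revolute
      K.O[i] = vadd(Op, dw);
      K.R[i] = mm(Rp, rot_axis(axd, q[i]));
      K.w[i] = vadd(wp, vscl(s, qd[i]));
      K.vO[i] = vadd(vp, vcross(wp, dw));
    } else { // prismatic
      V3<T> u = vscl(s, q[i]);
      K.O[i] = vadd(vadd(Op, dw), u);
      K.R[i] = Rp;
      K.w[i] = wp;
      K.vO[i] = vadd(vadd(vp, vcross(wp, vadd(dw, u))), vscl(s, qd[i]));
    }
  }
}

template <class T>
static V3<T> point_pos(const Ws<T>& K, int b, const double* loc) {
  V3<T> l = {T(loc[0]), T(loc[1]), T(loc[2])};
  return vadd(K.O[b], mv(K.R[b], l));
}
template <class T>
static V3<T> point_vel(const Ws<T>& K, int b, const V3<T>& p) {
  return vadd(K.vO[b], vcross(K.w[b], vsub(p, K.O[b])));
}

template <class T>
static void add_point_force(const ModelData& md, const Ws<T>& K, int b,
                            const V3<T>& p, const V3<T>& F, T* tau) {
  const unsigned char* a = &md.anc[(size_t)b * md.nb];
  for (int j = 0; j <= b; ++j) {
    if (!a[j]) continue;
    if (md.jtype[j] == 1)
      tau[j] += vdot(vcross(K.sax[j], vsub(p, K.O[j])), F);
    else
      tau[j] += vdot(K.sax[j], F);
  }
}

// recursive Newton-Euler joint torques for (q, qd, qdd); gravity included
// via the base acceleration; no external forces (fk_pass must have run)
template <class T>
static void rne(const ModelData& md, Ws<T>& K, const T* qd, const T* qdd,
                T* tau) {
  int nb = md.nb;
  for (int i = 0; i < nb; ++i) {
    int p = md.parent[i];
    V3<T> wdp = (p < 0) ? vzero<T>() : K.wd[p];
    V3<T> aOp, wp;
    const V3<T>& s = K.sax[i];
    if (p < 0) {
      aOp = {T(-md.grav[0]), T(-md.grav[1]), T(-md.grav[2])};
      wp = vzero<T>();
    } else {
      aOp = K.aO[p];
      wp = K.w[p];
    }
    const V3<T>& dw = K.dw[i];
    if (md.jtype[i] == 1) {
      K.wd[i] = vadd(vadd(wdp, vscl(s, qdd[i])), vcross(wp, vscl(s, qd[i])));
      K.aO[i] = vadd(vadd(aOp, vcross(wdp, dw)), vcross(wp, vcross(wp, dw)));
    } else {
      K.wd[i] = wdp;
      V3<T> Op = (p < 0) ? vzero<T>() : K.O[p];
      V3<T> du = vadd(dw, vsub(vsub(K.O[i], Op), dw)); // dw + axis*q
      V3<T> base = vadd(vadd(aOp, vcross(wdp, du)),
                        vcross(wp, vcross(wp, du)));
      K.aO[i] = vadd(vadd(base, vscl(s, qdd[i])),
                     vscl(vcross(wp, s), T(2) * qd[i]));
    }
    const double* comd = &md.com[3 * i];
    V3<T> comT = {T(comd[0]), T(comd[1]), T(comd[2])};
    K.cw[i] = mv(K.R[i], comT);
    K.ac[i] = vadd(vadd(K.aO[i], vcross(K.wd[i], K.cw[i])),
                   vcross(K.w[i], vcross(K.w[i], K.cw[i])));
    K.fb[i] = vzero<T>();
    K.nb_[i] = vzero<T>();
  }
  for (int i = nb - 1; i >= 0; --i) {
    V3<T> Fi = vscl(K.ac[i], T(md.mass[i]));
    const double* Id = &md.inertia[9 * i];
    M3<T> IT;
    for (int k = 0; k < 9; ++k) IT[k] = T(Id[k]);
    M3<T> Iw = mm(mm(K.R[i], IT), mtrans(K.R[i]));
    V3<T> Ni = vadd(mv(Iw, K.wd[i]), vcross(K.w[i], mv(Iw, K.w[i])));
    K.fb[i] = vadd(K.fb[i], Fi);
    K.nb_[i] = vadd(K.nb_[i], vadd(Ni, vcross(K.cw[i], Fi)));
    int p = md.parent[i];
    if (p >= 0) {
      K.fb[p] = vadd(K.fb[p], K.fb[i]);
      K.nb_[p] = vadd(K.nb_[p],
                      vadd(K.nb_[i], vcross(vsub(K.O[i], K.O[p]), K.fb[i])));
    }
    tau[i] = (md.jtype[i] == 1) ? vdot(K.sax[i], K.nb_[i])
                                : vdot(K.sax[i], K.fb[i]);
  }
}

template <class T>
static V3<T> contact_force_pt(const ModelData& md, const V3<T>& p,
                              const V3<T>& v) {
  T y = p[1], yd = v[1];
  T pen = T(0.5) * (sqrt(y * y + T(md.eps_p * md.eps_p)) - y);
  T Fraw = T(md.k_n) * pen * pen * pen * (T(1) - T(md.c_n) * yd);
  T Fy = T(0.5) * (sqrt(Fraw * Fraw + T(md.f_eps * md.f_eps)) + Fraw);
  T vt2 = v[0] * v[0] + v[2] * v[2];
  T den = sqrt(vt2 + T(md.v_c * md.v_c));
  return {-T(md.mu) * Fy * v[0] / den, Fy, -T(md.mu) * Fy * v[2] / den};
}

template <class T>
static T mtu_length(const ModelData& md, int im, const T* q, T* dldq) {
  const MuscleP& m = md.mus[im];
  T l = T(0);
  for (int t = m.term_off; t < m.term_off + m.n_term; ++t) {
    T val = T(md.term_coef[t]);
    int nd = md.term_nd[t], off = md.term_doff[t];
    for (int k = 0; k < nd; ++k) {
      int d = md.term_dof[off + k], p = md.term_pow[off + k];
      for (int e = 0; e < p; ++e) val = val * q[d];
    }
    l += val;
    if (dldq) {
      for (int k = 0; k < nd; ++k) {
        int d = md.term_dof[off + k], p = md.term_pow[off + k];
        T dv = T(md.term_coef[t] * p);
        for (int e = 0; e < p - 1; ++e) dv = dv * q[d];
        for (int k2 = 0; k2 < nd; ++k2) {
          if (k2 == k) continue;
          int d2 = md.term_dof[off + k2], p2 = md.term_pow[off + k2];
          for (int e = 0; e < p2; ++e) dv = dv * q[d2];
        }
        dldq[d] += dv;
      }
    }
  }
  return l;
}

// Hill contraction residual in natural units (N)
template <class T>
static T hill_residual(const MuscleP& m, const T& a, const T& s, const T& sd,
                       const T& lmtu, T* fsee_out) {
  T lce = sqrt(s * s + T(m.h * m.h));
  T cosphi = s / lce;
  T vrel = sd * cosphi / T(m.lopt);
  T eps = (lmtu - s - T(m.lslack)) / T(m.lslack);
  T fsee = T(0);
  if (re(eps) > 0) {
    T r = eps / T(m.eps0);
    fsee = T(m.fiso) * r * r;
  }
  T str = lce / T(m.lopt) - T(1);
  T fpee = T(0);
  if (re(str) > 0) fpee = T(m.kpee) * T(m.fiso) * str * str;
  T z = str / T(m.W);
  T fl = exp(-(z * z));
  T fv;
  if (re(vrel) < 0) {
    fv = (T(m.vmax) + vrel) / (T(m.vmax) - vrel / T(m.ahill));
  } else {
    double s0 = (1.0 + 1.0 / m.ahill) / m.vmax;
    double c = (m.fecc - 1.0) / s0;
    fv = (T(m.fecc) * vrel + T(c)) / (vrel + T(c));
  }
  T fdamp = T(m.dce) * T(m.fiso) * vrel;
  T res = fsee - (a * T(m.fiso) * fl * fv + fpee + fdamp) * cosphi;
  if (fsee_out) *fsee_out = fsee;
  return res;
}

template <class T>
static T act_residual(const MuscleP& m, const T& a, const T& ad, const T& ne) {
  return ad - (ne - a) * (ne / T(m.tact) + (T(1) - ne) / T(m.tdeact));
}

// full node residual f(x, xdot, u); rows nondimensionalized
template <class T>
static void node_residual(const ModelData& md, const T* x, const T* xd,
                          const T* u, T* f, T* grf, Ws<T>& K) {
  int nd = md.nb, nm = md.nmus;
  const T* q = x;
  const T* qdot = x + nd;
  const T* s = x + 2 * nd;
  const T* a = x + 2 * nd + nm;
  const T* qdd = xd + nd;
  const T* sdot = xd + 2 * nd;
  const T* adot = xd + 2 * nd + nm;
  for (int i = 0; i < nd; ++i) f[i] = xd[i] - qdot[i];
  fk_pass(md, q, qdot, K);
  for (int i = 0; i < nd; ++i) K.tau_ext[i] = T(0);
  if (grf)
    for (int k = 0; k < 6; ++k) grf[k] = T(0);
  for (int c = 0; c < md.ncp; ++c) {
    int b = md.cp_body[c];
    V3<T> p = point_pos(K, b, &md.cp_local[3 * c]);
    V3<T> v = point_vel(K, b, p);
    V3<T> F = contact_force_pt(md, p, v);
    add_point_force(md, K, b, p, F, K.tau_ext.data());
    if (grf) {
      int off = md.cp_foot[c] == 0 ? 0 : 3;
      for (int k = 0; k < 3; ++k) grf[off + k] += F[k];
    }
  }
  for (int im = 0; im < nm; ++im) {
    for (int j = 0; j < nd; ++j) K.dldq[j] = T(0);
    T lmtu = mtu_length(md, im, q, K.dldq.data());
    T fsee;
    T res = hill_residual(md.mus[im], a[im], s[im], sdot[im], lmtu, &fsee);
    f[2 * nd + im] = res / T(md.mus[im].fiso);
    for (int j = 0; j < nd; ++j) K.tau_ext[j] += -(K.dldq[j] * fsee);
    f[2 * nd + nm + im] =
        act_residual(md.mus[im], a[im], adot[im], u[im]) * T(md.act_scale);
  }
  for (int t = 0; t < md.ntor; ++t)
    K.tau_ext[md.tor_dof[t]] += T(md.tor_scale) * u[nm + t];
  // passive viscous joint damping
  for (int i = 0; i < nd; ++i)
    if (md.dof_damp[i] != 0.0)
      K.tau_ext[i] += -T(md.dof_damp[i]) * qdot[i];
  rne(md, K, qdot, qdd, K.tau.data());
  for (int i = 0; i < nd; ++i)
    f[nd + i] = (K.tau[i] - K.tau_ext[i]) / T(md.mb_scale);
}

// periodicity map: virtual end state x(T) = P(x0, Tsim)
struct TaskData {
  int kind; // 0 standing, 1 straight, 2 curved
  double vx, vz, vnorm, radius;
};

template <class T>
static void periodic_image(const ModelData& md, const TaskData& td,
                           const T* x0, const T& Tsim, T* xN, int nx) {
  for (int i = 0; i < nx; ++i) xN[i] = x0[i];
  int nd = md.nb;
  if (td.kind == 1) {
    xN[md.pel_tx] += T(td.vx) * Tsim;
    xN[md.pel_tz] += T(td.vz) * Tsim;
  } else if (td.kind == 2) {
    T th = T(2) * asin(T(td.vnorm) * Tsim / T(2 * td.radius));
    T c = cos(th), s = sin(th);
    T tx = x0[md.pel_tx], tz = x0[md.pel_tz];
    xN[md.pel_tx] = c * tx + s * tz;
    xN[md.pel_tz] = T(0) - s * tx + c * tz;
    xN[md.pel_rot] = x0[md.pel_rot] + th;
    T vx0 = x0[nd + md.pel_tx], vz0 = x0[nd + md.pel_tz];
    xN[nd + md.pel_tx] = c * vx0 + s * vz0;
    xN[nd + md.pel_tz] = T(0) - s * vx0 + c * vz0;
  }
}

// defect block k: f(x_k, (x_k - x_{k-1})/h, u_k), h = Tsim/N; the wrap
// block routes x_k through the periodicity image of x_0
template <class T>
static void defect_block(const ModelData& md, const TaskData& td, int N,
                         bool wrap, const T* xk_or_x0, const T* xkm1,
                         const T* uk, const T& Tsim, T* f, int nx,
                         Ws<T>& K) {
  T* xk = K.xk.data();
  T* xdot = K.xdot.data();
  if (wrap)
    periodic_image(md, td, xk_or_x0, Tsim, xk, nx);
  else
    for (int i = 0; i < nx; ++i) xk[i] = xk_or_x0[i];
  T hinv = T((double)N) / Tsim;
  for (int i = 0; i < nx; ++i) xdot[i] = (xk[i] - xkm1[i]) * hinv;
  node_residual(md, xk, xdot, uk, f, (T*)nullptr, K);
}

// ---------------------------------------------------------------------
// dense Jacobian of one defect block over (x_k, x_{k-1}, u_k, Tsim):
// J is nx x (2 nx + nu + 1), column-major. Dual evaluations cover the
// x_k and Tsim columns and the qdd part of the xdot chain; the remaining
// x_{k-1}, u columns follow analytically from the block structure.
// ---------------------------------------------------------------------
struct BlockWork {
  std::vector<Dual> xk, xkm1, uk, fc;
  std::vector<double> fv;
  Ws<Dual> K;
  Ws<double> Kd;
};

static void block_jacobian(const ModelData& md, const TaskData& td, int N,
                           bool wrap, const double* xk0, const double* xkm1,
                           const double* uk, double Tsim, double* J, int nx,
                           int nu, BlockWork& W) {
  int nd = md.nb, nm = md.nmus;
  double h = Tsim / N, hinv = 1.0 / h;
  for (int i = 0; i < nx; ++i) {
    W.xk[i] = Dual(xk0[i]);
    W.xkm1[i] = Dual(xkm1[i]);
  }
  for (int i = 0; i < nu; ++i) W.uk[i] = Dual(uk[i]);
  Dual Tc(Tsim);
  int ncol = 2 * nx + nu + 1;
  std::fill(J, J + (size_t)nx * ncol, 0.0);
  // x_k (or x_0 through the wrap) columns
  for (int j = 0; j < nx; ++j) {
    W.xk[j].d = 1.0;
    defect_block(md, td, N, wrap, W.xk.data(), W.xkm1.data(), W.uk.data(),
                 Tc, W.fc.data(), nx, W.K);
    W.xk[j].d = 0.0;
    for (int i = 0; i < nx; ++i) J[(size_t)j * nx + i] = W.fc[i].d;
  }
  // Tsim column (also runs through the wrap map and the 1/h factor)
  {
    Tc.d = 1.0;
    defect_block(md, td, N, wrap, W.xk.data(), W.xkm1.data(), W.uk.data(),
                 Tc, W.fc.data(), nx, W.K);
    Tc.d = 0.0;
    for (int i = 0; i < nx; ++i)
      J[(size_t)(2 * nx + nu) * nx + i] = W.fc[i].d;
  }
  // x_{k-1} columns: -(1/h) * (df/dxdot); the qdd part needs dynamics
  // evaluations, the rest is structural
  {
    // evaluate the real block once to rebuild the (double) kinematics used
    // by the scalar muscle derivative below
    defect_block(md, td, N, wrap, xk0, xkm1, uk, Tsim, W.fv.data(), nx,
                 W.Kd);
    const double* xk = W.Kd.xk.data();
    const double* xdot = W.Kd.xdot.data();
    // kinematic identity rows: df_i/dxdot_q[i] = 1
    for (int j = 0; j < nd; ++j)
      J[(size_t)(nx + j) * nx + j] = -hinv;
    // qdd directions: dual through the multibody rows
    for (int j = 0; j < nd; ++j) {
      for (int i = 0; i < nx; ++i) {
        W.xk[i].d = 0.0;
      }
      std::vector<Dual>& xda = W.K.xdot; // reuse dual xdot storage
      for (int i = 0; i < nx; ++i) xda[i] = Dual(xdot[i]);
      xda[nd + j].d = 1.0;
      // x fixed at real values
      for (int i = 0; i < nx; ++i) W.K.xk[i] = Dual(xk[i]);
      node_residual(md, W.K.xk.data(), xda.data(), W.uk.data(),
                    W.fc.data(), (Dual*)nullptr, W.K);
      int col = nx + nd + j;
      for (int i = 0; i < nx; ++i)
        J[(size_t)col * nx + i] = -hinv * W.fc[i].d;
    }
    // sdot directions: single-muscle scalar derivative
    for (int im = 0; im < nm; ++im) {
      const MuscleP& m = md.mus[im];
      Dual a(xk[2 * nd + nm + im]), s(xk[2 * nd + im]);
      Dual sd(xdot[2 * nd + im], 1.0);
      double lm = mtu_length(md, im, xk, (double*)nullptr);
      Dual res = hill_residual(m, a, s, sd, Dual(lm), (Dual*)nullptr);
      J[(size_t)(nx + 2 * nd + im) * nx + (2 * nd + im)] =
          -hinv * res.d / m.fiso;
    }
    // adot directions: activation rows, coefficient 1
    for (int im = 0; im < nm; ++im)
      J[(size_t)(nx + 2 * nd + nm + im) * nx + (2 * nd + nm + im)] =
          -hinv * md.act_scale;
  }
  // u columns: excitation into activation rows, torques into multibody rows
  {
    const double* xk = W.Kd.xk.data();
    for (int im = 0; im < nm; ++im) {
      const MuscleP& m = md.mus[im];
      double a = xk[2 * nd + nm + im], ne = uk[im];
      double dres = -((ne / m.tact + (1 - ne) / m.tdeact) +
                      (ne - a) * (1 / m.tact - 1 / m.tdeact));
      J[(size_t)(2 * nx + im) * nx + (2 * nd + nm + im)] =
          dres * md.act_scale;
    }
    for (int t = 0; t < md.ntor; ++t)
      J[(size_t)(2 * nx + nm + t) * nx + (nd + md.tor_dof[t])] =
          -md.tor_scale / md.mb_scale;
  }
  // wrap: the x_k columns above are already d f / d x_0 via the chain
  // through P (dual seeded x0); nothing more to do
}

// ================= exported functions =================

// [[Rcpp::export]]
List cpp_fk(List model, NumericVector q, NumericVector qd) {
  ModelData md = parse_model(model);
  Ws<double> K;
  K.size_for(md, 2 * md.nb + 2 * md.nmus);
  fk_pass(md, q.begin(), qd.begin(), K);
  int nb = md.nb;
  NumericMatrix R(nb, 9), O(nb, 3), CW(nb, 3), CV(nb, 3);
  for (int i = 0; i < nb; ++i) {
    for (int k = 0; k < 9; ++k) R(i, k) = K.R[i][k];
    for (int k = 0; k < 3; ++k) O(i, k) = K.O[i][k];
    V3<double> com = {md.com[3 * i], md.com[3 * i + 1], md.com[3 * i + 2]};
    V3<double> cw = vadd(K.O[i], mv(K.R[i], com));
    V3<double> cv = point_vel(K, i, cw);
    for (int k = 0; k < 3; ++k) {
      CW(i, k) = cw[k];
      CV(i, k) = cv[k];
    }
  }
  NumericMatrix P(md.ncp, 3), V(md.ncp, 3);
  for (int c = 0; c < md.ncp; ++c) {
    V3<double> p = point_pos(K, md.cp_body[c], &md.cp_local[3 * c]);
    V3<double> v = point_vel(K, md.cp_body[c], p);
    for (int k = 0; k < 3; ++k) {
      P(c, k) = p[k];
      V(c, k) = v[k];
    }
  }
  return List::create(Rcpp::Named("rot") = R, Rcpp::Named("origin") = O,
                      Rcpp::Named("com") = CW, Rcpp::Named("com_vel") = CV,
                      Rcpp::Named("cp_pos") = P, Rcpp::Named("cp_vel") = V);
}

// [[Rcpp::export]]
NumericVector cpp_rne(List model, NumericVector q, NumericVector qd,
                      NumericVector qdd) {
  ModelData md = parse_model(model);
  Ws<double> K;
  K.size_for(md, 2 * md.nb + 2 * md.nmus);
  fk_pass(md, q.begin(), qd.begin(), K);
  NumericVector tau(md.nb);
  rne(md, K, qd.begin(), qdd.begin(), tau.begin());
  return tau;
}

// [[Rcpp::export]]
List cpp_contact_gen(List model, NumericVector q, NumericVector qd) {
  ModelData md = parse_model(model);
  Ws<double> K;
  K.size_for(md, 2 * md.nb + 2 * md.nmus);
  fk_pass(md, q.begin(), qd.begin(), K);
  NumericVector tau(md.nb);
  NumericMatrix Fpt(md.ncp, 3);
  NumericVector grf(6);
  for (int c = 0; c < md.ncp; ++c) {
    int b = md.cp_body[c];
    V3<double> p = point_pos(K, b, &md.cp_local[3 * c]);
    V3<double> v = point_vel(K, b, p);
    V3<double> F = contact_force_pt(md, p, v);
    add_point_force(md, K, b, p, F, tau.begin());
    int off = md.cp_foot[c] == 0 ? 0 : 3;
    for (int k = 0; k < 3; ++k) {
      Fpt(c, k) = F[k];
      grf[off + k] += F[k];
    }
  }
  return List::create(Rcpp::Named("tau") = tau, Rcpp::Named("grf") = grf,
                      Rcpp::Named("point_forces") = Fpt);
}

// [[Rcpp::export]]
List cpp_node_residual(List model, NumericVector x, NumericVector xd,
                       NumericVector u) {
  ModelData md = parse_model(model);
  int nx = x.size();
  Ws<double> K;
  K.size_for(md, nx);
  NumericVector f(nx), grf(6);
  node_residual(md, x.begin(), xd.begin(), u.begin(), f.begin(),
                grf.begin(), K);
  return List::create(Rcpp::Named("f") = f, Rcpp::Named("grf") = grf);
}

// [[Rcpp::export]]
List cpp_node_jacobians(List model, NumericVector x, NumericVector xd,
                        NumericVector u) {
  ModelData md = parse_model(model);
  int nx = x.size(), nu = u.size();
  NumericMatrix Jx(nx, nx), Jxd(nx, nx), Ju(nx, nu);
  Ws<Dual> K;
  K.size_for(md, nx);
  std::vector<Dual> xc(nx), xdc(nx), uc(nu), fc(nx);
  for (int i = 0; i < nx; ++i) {
    xc[i] = Dual(x[i]);
    xdc[i] = Dual(xd[i]);
  }
  for (int i = 0; i < nu; ++i) uc[i] = Dual(u[i]);
  for (int j = 0; j < nx; ++j) {
    xc[j].d = 1.0;
    node_residual(md, xc.data(), xdc.data(), uc.data(), fc.data(),
                  (Dual*)nullptr, K);
    xc[j].d = 0.0;
    for (int i = 0; i < nx; ++i) Jx(i, j) = fc[i].d;
  }
  for (int j = 0; j < nx; ++j) {
    xdc[j].d = 1.0;
    node_residual(md, xc.data(), xdc.data(), uc.data(), fc.data(),
                  (Dual*)nullptr, K);
    xdc[j].d = 0.0;
    for (int i = 0; i < nx; ++i) Jxd(i, j) = fc[i].d;
  }
  for (int j = 0; j < nu; ++j) {
    uc[j].d = 1.0;
    node_residual(md, xc.data(), xdc.data(), uc.data(), fc.data(),
                  (Dual*)nullptr, K);
    uc[j].d = 0.0;
    for (int i = 0; i < nx; ++i) Ju(i, j) = fc[i].d;
  }
  return List::create(Rcpp::Named("Jx") = Jx, Rcpp::Named("Jxd") = Jxd,
                      Rcpp::Named("Ju") = Ju);
}

// [[Rcpp::export]]
NumericVector cpp_mus_geometry(List model, NumericVector q) {
  ModelData md = parse_model(model);
  NumericVector out(md.nmus * (1 + md.nb));
  std::vector<double> dldq(md.nb);
  for (int im = 0; im < md.nmus; ++im) {
    std::fill(dldq.begin(), dldq.end(), 0.0);
    double l = mtu_length(md, im, q.begin(), dldq.data());
    out[im] = l;
    for (int j = 0; j < md.nb; ++j)
      out[md.nmus + im * md.nb + j] = -dldq[j];
  }
  return out;
}

static TaskData parse_task(NumericVector tv) {
  TaskData td;
  td.kind = (int)tv[0];
  td.vx = tv[1];
  td.vz = tv[2];
  td.vnorm = tv[3];
  td.radius = tv[4];
  return td;
}

// [[Rcpp::export]]
NumericVector cpp_traj_constraints(List model, NumericMatrix X,
                                   NumericMatrix U, double Tsim,
                                   NumericVector task) {
  ModelData md = parse_model(model);
  TaskData td = parse_task(task);
  int nx = X.nrow(), N = X.ncol();
  Ws<double> K;
  K.size_for(md, nx);
  if (td.kind == 0) {
    NumericVector c(nx);
    std::vector<double> xd(nx, 0.0);
    node_residual(md, &X(0, 0), xd.data(), &U(0, 0), c.begin(),
                  (double*)nullptr, K);
    return c;
  }
  NumericVector c(nx * N);
  std::vector<double> f(nx);
  for (int k = 1; k <= N; ++k) {
    bool wrap = (k == N);
    const double* xk = wrap ? &X(0, 0) : &X(0, k);
    const double* uk = wrap ? &U(0, 0) : &U(0, k);
    defect_block(md, td, N, wrap, xk, &X(0, k - 1), uk, Tsim, f.data(), nx,
                 K);
    for (int i = 0; i < nx; ++i) c[(k - 1) * nx + i] = f[i];
  }
  return c;
}

static BlockWork make_blockwork(const ModelData& md, int nx, int nu) {
  BlockWork W;
  W.xk.resize(nx);
  W.xkm1.resize(nx);
  W.uk.resize(nu);
  W.fc.resize(nx);
  W.fv.resize(nx);
  W.K.size_for(md, nx);
  W.Kd.size_for(md, nx);
  return W;
}

// gradient of w^T c(z) over z = (vec X, vec U, Tsim)
// [[Rcpp::export]]
NumericVector cpp_traj_gradmul(List model, NumericMatrix X, NumericMatrix U,
                               double Tsim, NumericVector task,
                               NumericVector w) {
  ModelData md = parse_model(model);
  TaskData td = parse_task(task);
  int nx = X.nrow(), N = X.ncol(), nu = U.nrow();
  NumericVector g(nx * N + nu * N + 1);
  BlockWork W = make_blockwork(md, nx, nu);
  if (td.kind == 0) {
    // standing: single block with xdot = 0; treat as x_k columns + u
    Ws<Dual>& K = W.K;
    std::vector<Dual> xdc(nx, Dual(0.0));
    for (int i = 0; i < nx; ++i) W.xk[i] = Dual(X(i, 0));
    for (int i = 0; i < nu; ++i) W.uk[i] = Dual(U(i, 0));
    for (int j = 0; j < nx; ++j) {
      W.xk[j].d = 1.0;
      node_residual(md, W.xk.data(), xdc.data(), W.uk.data(), W.fc.data(),
                    (Dual*)nullptr, K);
      W.xk[j].d = 0.0;
      double acc = 0;
      for (int i = 0; i < nx; ++i) acc += W.fc[i].d * w[i];
      g[j] = acc;
    }
    for (int j = 0; j < nu; ++j) {
      W.uk[j].d = 1.0;
      node_residual(md, W.xk.data(), xdc.data(), W.uk.data(), W.fc.data(),
                    (Dual*)nullptr, K);
      W.uk[j].d = 0.0;
      double acc = 0;
      for (int i = 0; i < nx; ++i) acc += W.fc[i].d * w[i];
      g[nx * N + j] = acc;
    }
    return g;
  }
  std::vector<double> J((size_t)nx * (2 * nx + nu + 1));
  for (int k = 1; k <= N; ++k) {
    bool wrap = (k == N);
    int kc = wrap ? 0 : k;
    const double* wblk = &w[(k - 1) * nx];
    block_jacobian(md, td, N, wrap, &X(0, kc), &X(0, k - 1), &U(0, kc), Tsim,
                   J.data(), nx, nu, W);
    auto addcol = [&](int col, int gidx) {
      double acc = 0;
      const double* cptr = &J[(size_t)col * nx];
      for (int i = 0; i < nx; ++i) acc += cptr[i] * wblk[i];
      g[gidx] += acc;
    };
    for (int j = 0; j < nx; ++j) addcol(j, kc * nx + j);
    for (int j = 0; j < nx; ++j) addcol(nx + j, (k - 1) * nx + j);
    for (int j = 0; j < nu; ++j) addcol(2 * nx + j, nx * N + kc * nu + j);
    addcol(2 * nx + nu, nx * N + nu * N);
  }
  return g;
}

// full sparse constraint Jacobian as triplets
// [[Rcpp::export]]
List cpp_traj_jacobian(List model, NumericMatrix X, NumericMatrix U,
                       double Tsim, NumericVector task) {
  ModelData md = parse_model(model);
  TaskData td = parse_task(task);
  int nx = X.nrow(), N = X.ncol(), nu = U.nrow();
  std::vector<int> ri, ci;
  std::vector<double> vv;
  BlockWork W = make_blockwork(md, nx, nu);
  auto push = [&](double v, int i, int j) {
    if (v != 0.0) {
      ri.push_back(i);
      ci.push_back(j);
      vv.push_back(v);
    }
  };
  if (td.kind == 0) {
    Ws<Dual>& K = W.K;
    std::vector<Dual> xdc(nx, Dual(0.0));
    for (int i = 0; i < nx; ++i) W.xk[i] = Dual(X(i, 0));
    for (int i = 0; i < nu; ++i) W.uk[i] = Dual(U(i, 0));
    for (int j = 0; j < nx; ++j) {
      W.xk[j].d = 1.0;
      node_residual(md, W.xk.data(), xdc.data(), W.uk.data(), W.fc.data(),
                    (Dual*)nullptr, K);
      W.xk[j].d = 0.0;
      for (int i = 0; i < nx; ++i) push(W.fc[i].d, i, j);
    }
    for (int j = 0; j < nu; ++j) {
      W.uk[j].d = 1.0;
      node_residual(md, W.xk.data(), xdc.data(), W.uk.data(), W.fc.data(),
                    (Dual*)nullptr, K);
      W.uk[j].d = 0.0;
      for (int i = 0; i < nx; ++i) push(W.fc[i].d, i, nx * N + j);
    }
    return List::create(Rcpp::Named("i") = ri, Rcpp::Named("j") = ci,
                        Rcpp::Named("v") = vv, Rcpp::Named("nrow") = nx,
                        Rcpp::Named("ncol") = nx * N + nu * N + 1);
  }
  std::vector<double> J((size_t)nx * (2 * nx + nu + 1));
  for (int k = 1; k <= N; ++k) {
    bool wrap = (k == N);
    int kc = wrap ? 0 : k;
    int row0 = (k - 1) * nx;
    block_jacobian(md, td, N, wrap, &X(0, kc), &X(0, k - 1), &U(0, kc), Tsim,
                   J.data(), nx, nu, W);
    auto pushcol = [&](int col, int gcol) {
      const double* cptr = &J[(size_t)col * nx];
      for (int i = 0; i < nx; ++i) push(cptr[i], row0 + i, gcol);
    };
    for (int j = 0; j < nx; ++j) pushcol(j, kc * nx + j);
    for (int j = 0; j < nx; ++j) pushcol(nx + j, (k - 1) * nx + j);
    for (int j = 0; j < nu; ++j) pushcol(2 * nx + j, nx * N + kc * nu + j);
    pushcol(2 * nx + nu, nx * N + nu * N);
  }
  return List::create(Rcpp::Named("i") = ri, Rcpp::Named("j") = ci,
                      Rcpp::Named("v") = vv, Rcpp::Named("nrow") = nx * N,
                      Rcpp::Named("ncol") = nx * N + nu * N + 1);
}

// simulated GRFs over a trajectory: values (6 x N) and, optionally, the
// Jacobian wrt (q, qdot) of each node (6 x 2*ndof x N)
// [[Rcpp::export]]
List cpp_traj_grf(List model, NumericMatrix X, bool want_jac) {
  ModelData md = parse_model(model);
  int N = X.ncol(), nd = md.nb;
  NumericMatrix G(6, N);
  Rcpp::NumericVector J(want_jac ? 6 * 2 * nd * N : 0);
  Ws<Dual> K;
  K.size_for(md, X.nrow());
  std::vector<Dual> q(nd), qd(nd), out(6);
  auto grf_of = [&]() {
    fk_pass(md, q.data(), qd.data(), K);
    for (int k = 0; k < 6; ++k) out[k] = Dual(0.0);
    for (int c = 0; c < md.ncp; ++c) {
      int b = md.cp_body[c];
      V3<Dual> p = point_pos(K, b, &md.cp_local[3 * c]);
      V3<Dual> v = point_vel(K, b, p);
      V3<Dual> F = contact_force_pt(md, p, v);
      int off = md.cp_foot[c] == 0 ? 0 : 3;
      for (int k = 0; k < 3; ++k) out[off + k] += F[k];
    }
  };
  for (int n = 0; n < N; ++n) {
    for (int i = 0; i < nd; ++i) {
      q[i] = Dual(X(i, n));
      qd[i] = Dual(X(nd + i, n));
    }
    grf_of();
    for (int k = 0; k < 6; ++k) G(k, n) = out[k].v;
    if (want_jac) {
      for (int j = 0; j < 2 * nd; ++j) {
        Dual& ref = (j < nd) ? q[j] : qd[j - nd];
        ref.d = 1.0;
        grf_of();
        ref.d = 0.0;
        for (int k = 0; k < 6; ++k)
          J[k + 6 * j + 6 * 2 * nd * n] = out[k].d;
      }
    }
  }
  if (want_jac) {
    J.attr("dim") = Rcpp::IntegerVector::create(6, 2 * nd, N);
    return List::create(Rcpp::Named("grf") = G, Rcpp::Named("jac") = J);
  }
  return List::create(Rcpp::Named("grf") = G);
}

// periodic image of x0 (used by the R-side periodicity residual)
// [[Rcpp::export]]
NumericVector cpp_periodic_image(List model, NumericVector x0, double Tsim,
                                 NumericVector task) {
  ModelData md = parse_model(model);
  TaskData td = parse_task(task);
  NumericVector xN(x0.size());
  periodic_image(md, td, x0.begin(), Tsim, xN.begin(), x0.size());
  return xN;
}
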