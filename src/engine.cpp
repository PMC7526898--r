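// Langevin dynamics engine with ratchet-and-pawl (rMD) and path-CV (SCPS)
// biasing, contact-map collective variables with analytic gradients, and
// frame-wise Kabsch RMSD.  Reduced units: k_B = 1, unit masses.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// ---------------------------------------------------------------------------
// smoothed contact function  C(r) = [1 - (r/r0)^6] / [1 - (r/r0)^10]
// removable singularity at r = r0 (limit 3/5) handled by a series branch;
// hard cutoff at rc (entries exactly 0 beyond).
static inline void contact_fun(double r, double r0, double rc,
                               double &c, double &dc) {
  if (r > rc) { c = 0.0; dc = 0.0; return; }
  double x = r / r0;
  double t = x - 1.0;
  if (std::fabs(t) < 1e-7) {
    // series about x = 1: C = 3/5 - (6/5) t + O(t^2)
    c  = 0.6 - 1.2 * t;
    dc = -1.2 / r0;
    return;
  }
  double x2 = x * x, x3 = x2 * x;
  double x5 = x3 * x2, x6 = x3 * x3, x9 = x6 * x3, x10 = x6 * x2 * x2;
  double f = 1.0 - x6, g = 1.0 - x10;
  c = f / g;
  double dcdx = (-6.0 * x5 * g + 10.0 * x9 * f) / (g * g);
  dc = dcdx / r0;
}

// [[Rcpp::export]]
NumericVector cpp_contact_values(const arma::mat &X,
                                 const arma::ivec &pi_, const arma::ivec &pj_,
                                 double r0, double rc) {
  int P = pi_.n_elem;
  NumericVector out(P);
  for (int p = 0; p < P; ++p) {
    arma::rowvec d = X.row(pi_[p]) - X.row(pj_[p]);
    double r = arma::norm(d);
    double c, dc;
    if (r == 0.0) { out[p] = 1.0; continue; }
    contact_fun(r, r0, rc, c, dc);
    out[p] = c;
  }
  return out;
}

// contact values + cached r and dC/dr (for chain-rule gradients)
static void contact_all(const arma::mat &X,
                        const arma::ivec &pi_, const arma::ivec &pj_,
                        double r0, double rc,
                        arma::vec &C, arma::vec &rv, arma::vec &dcv) {
  int P = pi_.n_elem;
  C.set_size(P); rv.set_size(P); dcv.set_size(P);
  for (int p = 0; p < P; ++p) {
    arma::rowvec d = X.row(pi_[p]) - X.row(pj_[p]);
    double r = arma::norm(d);
    rv[p] = r;
    if (r == 0.0) { C[p] = 1.0; dcv[p] = 0.0; continue; }
    double c, dc;
    contact_fun(r, r0, rc, c, dc);
    C[p] = c; dcv[p] = dc;
  }
}

// map a feature-space gradient alpha (dF/dC_p) to coordinate space
static void feature_grad_to_coords(const arma::mat &X,
                                   const arma::ivec &pi_, const arma::ivec &pj_,
                                   const arma::vec &alpha, const arma::vec &rv,
                                   const arma::vec &dcv, arma::mat &G) {
  int P = pi_.n_elem;
  for (int p = 0; p < P; ++p) {
    if (alpha[p] == 0.0 || dcv[p] == 0.0 || rv[p] == 0.0) continue;
    int i = pi_[p], j = pj_[p];
    arma::rowvec u = (X.row(i) - X.row(j)) / rv[p];
    arma::rowvec g = alpha[p] * dcv[p] * u;
    G.row(i) += g;
    G.row(j) -= g;
  }
}

// ---------------------------------------------------------------------------
// CV context: rMD (z vs reference map) or SCPS (s_lambda / w_lambda vs path)
struct CVContext {
  bool is_surface;          // features are the coordinates themselves
  arma::ivec pi_, pj_;
  double r0, rc;
  arma::vec cref;           // rMD reference feature vector
  arma::mat path;           // SCPS: NC x P mean-path feature maps
  double lambda;
  bool w_indexed;           // Eq-8 variant with index factor in the sum
};

static CVContext parse_cv(List cv) {
  CVContext ctx;
  ctx.is_surface = as<bool>(cv["is_surface"]);
  if (!ctx.is_surface) {
    ctx.pi_ = as<arma::ivec>(cv["pi"]);
    ctx.pj_ = as<arma::ivec>(cv["pj"]);
    ctx.r0 = as<double>(cv["r0"]);
    ctx.rc = as<double>(cv["rc"]);
  }
  if (cv.containsElementNamed("cref") && !Rf_isNull(cv["cref"]))
    ctx.cref = as<arma::vec>(cv["cref"]);
  if (cv.containsElementNamed("path") && !Rf_isNull(cv["path"])) {
    ctx.path = as<arma::mat>(cv["path"]);
    ctx.lambda = as<double>(cv["lambda"]);
    ctx.w_indexed = as<bool>(cv["w_indexed"]);
  }
  return ctx;
}

static void eval_features(const arma::mat &X, const CVContext &ctx,
                          arma::vec &C, arma::vec &rv, arma::vec &dcv) {
  if (ctx.is_surface) {
    C = arma::vectorise(X.t());
  } else {
    contact_all(X, ctx.pi_, ctx.pj_, ctx.r0, ctx.rc, C, rv, dcv);
  }
}

// z = sum_p (C_p - Cref_p)^2, with coordinate gradient
static double eval_z(const arma::mat &X, const CVContext &ctx, arma::mat &G) {
  arma::vec C, rv, dcv;
  eval_features(X, ctx, C, rv, dcv);
  arma::vec e = C - ctx.cref;
  double z = arma::dot(e, e);
  G.zeros(X.n_rows, X.n_cols);
  arma::vec alpha = 2.0 * e;
  if (ctx.is_surface) {
    G = arma::reshape(alpha, X.n_cols, X.n_rows).t();
  } else {
    feature_grad_to_coords(X, ctx.pi_, ctx.pj_, alpha, rv, dcv, G);
  }
  return z;
}

// s_lambda (progress, 1 -> 0) and d = -w_lambda (off-path distance), with
// coordinate gradients.  Log-sum-exp throughout.
static void eval_path_cvs(const arma::mat &X, const CVContext &ctx,
                          double &s, arma::mat &Gs,
                          double &d, arma::mat &Gd) {
  arma::vec C, rv, dcv;
  eval_features(X, ctx, C, rv, dcv);
  int NC = ctx.path.n_rows;
  arma::vec dist(NC);
  for (int k = 0; k < NC; ++k) {
    arma::vec e = C - ctx.path.row(k).t();
    dist[k] = arma::dot(e, e);
  }
  double dmin = dist.min();
  arma::vec q = arma::exp(-ctx.lambda * (dist - dmin));
  double S0 = arma::sum(q);
  double S1 = 0.0;
  for (int k = 0; k < NC; ++k) S1 += k * q[k];
  double m = S1 / S0;
  s = 1.0 - m / (NC - 1.0);

  // w_lambda = (1/lambda) ln sum_k exp(-lambda d_k)   [optionally k-weighted]
  double w;
  arma::vec pw(NC);           // dw/dd_k = -pw_k
  if (ctx.w_indexed) {
    double Sk = 0.0;
    for (int k = 0; k < NC; ++k) Sk += (k + 1.0) * q[k];
    w = std::log(Sk) / ctx.lambda - dmin;
    for (int k = 0; k < NC; ++k) pw[k] = (k + 1.0) * q[k] / Sk;
  } else {
    w = std::log(S0) / ctx.lambda - dmin;
    pw = q / S0;
  }
  d = -w;

  // ds/dd_k = lambda * q_k * (k - m) / (S0 * (NC - 1))
  arma::vec dsdd(NC), dddd(NC);
  for (int k = 0; k < NC; ++k) {
    dsdd[k] = ctx.lambda * q[k] * (k - m) / (S0 * (NC - 1.0));
    dddd[k] = pw[k];          // d = -w, dw/dd_k = -pw_k
  }

  int P = C.n_elem;
  arma::vec alpha_s(P, arma::fill::zeros), alpha_d(P, arma::fill::zeros);
  for (int k = 0; k < NC; ++k) {
    if (dsdd[k] == 0.0 && dddd[k] == 0.0) continue;
    arma::vec e = 2.0 * (C - ctx.path.row(k).t());
    alpha_s += dsdd[k] * e;
    alpha_d += dddd[k] * e;
  }
  Gs.zeros(X.n_rows, X.n_cols);
  Gd.zeros(X.n_rows, X.n_cols);
  if (ctx.is_surface) {
    Gs = arma::reshape(alpha_s, X.n_cols, X.n_rows).t();
    Gd = arma::reshape(alpha_d, X.n_cols, X.n_rows).t();
  } else {
    feature_grad_to_coords(X, ctx.pi_, ctx.pj_, alpha_s, rv, dcv, Gs);
    feature_grad_to_coords(X, ctx.pi_, ctx.pj_, alpha_d, rv, dcv, Gd);
  }
}

// [[Rcpp::export]]
List cpp_z_grad(const arma::mat &X, List cv) {
  CVContext ctx = parse_cv(cv);
  arma::mat G;
  double z = eval_z(X, ctx, G);
  return List::create(_["value"] = z, _["gradient"] = G);
}

// [[Rcpp::export]]
List cpp_path_cvs(const arma::mat &X, List cv) {
  CVContext ctx = parse_cv(cv);
  double s, d;
  arma::mat Gs, Gd;
  eval_path_cvs(X, ctx, s, Gs, d, Gd);
  return List::create(_["s"] = s, _["grad_s"] = Gs,
                      _["d"] = d, _["grad_d"] = Gd,
                      _["w"] = -d, _["grad_w"] = -Gd);
}

// ---------------------------------------------------------------------------
// Force fields

struct GoSys {
  int n;
  arma::imat bonds;   arma::vec bond_r0;  double kb;
  arma::imat angles;  arma::vec ang_th0;  double ka;
  arma::imat dihs;    arma::vec dih_phi0; double kd1, kd3;
  arma::imat con;     arma::vec con_sig;  arma::vec con_eps;
  arma::imat rep;     double eps_rep, sig_wca;
  bool has_container; arma::rowvec cc;    double cR, ck;
};

static GoSys parse_go(List sys) {
  GoSys g;
  g.n = as<int>(sys["n"]);
  g.bonds = as<arma::imat>(sys["bonds"]);   g.bond_r0 = as<arma::vec>(sys["bond_r0"]);
  g.kb = as<double>(sys["kb"]);
  g.angles = as<arma::imat>(sys["angles"]); g.ang_th0 = as<arma::vec>(sys["ang_th0"]);
  g.ka = as<double>(sys["ka"]);
  g.dihs = as<arma::imat>(sys["dihs"]);     g.dih_phi0 = as<arma::vec>(sys["dih_phi0"]);
  g.kd1 = as<double>(sys["kd1"]);           g.kd3 = as<double>(sys["kd3"]);
  g.con = as<arma::imat>(sys["contacts"]);  g.con_sig = as<arma::vec>(sys["con_sig"]);
  g.con_eps = as<arma::vec>(sys["con_eps"]);
  g.rep = as<arma::imat>(sys["repulsive"]);
  g.eps_rep = as<double>(sys["eps_rep"]);   g.sig_wca = as<double>(sys["sig_wca"]);
  g.has_container = as<bool>(sys["has_container"]);
  if (g.has_container) {
    g.cc = as<arma::rowvec>(sys["container_center"]);
    g.cR = as<double>(sys["container_radius"]);
    g.ck = as<double>(sys["container_k"]);
  }
  return g;
}

static double go_energy_forces(const GoSys &g, const arma::mat &X, arma::mat &F) {
  double E = 0.0;
  F.zeros(X.n_rows, 3);
  // bonds
  for (arma::uword b = 0; b < g.bonds.n_rows; ++b) {
    int i = g.bonds(b, 0), j = g.bonds(b, 1);
    arma::rowvec d = X.row(i) - X.row(j);
    double r = arma::norm(d), dr = r - g.bond_r0[b];
    E += g.kb * dr * dr;
    arma::rowvec f = -2.0 * g.kb * dr * d / r;
    F.row(i) += f; F.row(j) -= f;
  }
  // angles
  for (arma::uword a = 0; a < g.angles.n_rows; ++a) {
    int i = g.angles(a, 0), j = g.angles(a, 1), k = g.angles(a, 2);
    arma::rowvec u = X.row(i) - X.row(j), v = X.row(k) - X.row(j);
    double nu = arma::norm(u), nv = arma::norm(v);
    arma::rowvec uh = u / nu, vh = v / nv;
    double ct = arma::dot(uh, vh);
    ct = std::max(-1.0, std::min(1.0, ct));
    double th = std::acos(ct), st = std::sqrt(1.0 - ct * ct);
    if (st < 1e-8) st = 1e-8;
    double dth = th - g.ang_th0[a];
    E += g.ka * dth * dth;
    double dVdth = 2.0 * g.ka * dth;
    arma::rowvec dthdi = -(vh - ct * uh) / (nu * st);
    arma::rowvec dthdk = -(uh - ct * vh) / (nv * st);
    arma::rowvec dthdj = -(dthdi + dthdk);
    F.row(i) -= dVdth * dthdi;
    F.row(j) -= dVdth * dthdj;
    F.row(k) -= dVdth * dthdk;
  }
  // dihedrals:  V = kd1[1-cos(phi-phi0)] + kd3[1-cos(3(phi-phi0))]
  for (arma::uword t = 0; t < g.dihs.n_rows; ++t) {
    int i = g.dihs(t, 0), j = g.dihs(t, 1), k = g.dihs(t, 2), l = g.dihs(t, 3);
    arma::rowvec b1 = X.row(j) - X.row(i);
    arma::rowvec b2 = X.row(k) - X.row(j);
    arma::rowvec b3 = X.row(l) - X.row(k);
    arma::rowvec n1 = arma::cross(b1, b2), n2 = arma::cross(b2, b3);
    double nb2 = arma::norm(b2);
    double sn1 = arma::dot(n1, n1), sn2 = arma::dot(n2, n2);
    if (sn1 < 1e-12 || sn2 < 1e-12) continue;
    double x = arma::dot(n1, n2);
    double y = arma::dot(arma::cross(n1, n2), b2) / nb2;
    double phi = std::atan2(y, x);
    double dphi = phi - g.dih_phi0[t];
    E += g.kd1 * (1.0 - std::cos(dphi)) + g.kd3 * (1.0 - std::cos(3.0 * dphi));
    double dVdphi = g.kd1 * std::sin(dphi) + 3.0 * g.kd3 * std::sin(3.0 * dphi);
    arma::rowvec dpdi = -(nb2 / sn1) * n1;
    arma::rowvec dpdl =  (nb2 / sn2) * n2;
    double s12 = arma::dot(b1, b2) / (nb2 * nb2);
    double s32 = arma::dot(b3, b2) / (nb2 * nb2);
    arma::rowvec dpdj = -(1.0 + s12) * dpdi + s32 * dpdl;
    arma::rowvec dpdk = s12 * dpdi - (1.0 + s32) * dpdl;
    F.row(i) -= dVdphi * dpdi;
    F.row(j) -= dVdphi * dpdj;
    F.row(k) -= dVdphi * dpdk;
    F.row(l) -= dVdphi * dpdl;
  }
  // native contacts: 12-10 Lennard-Jones with minimum at the native distance
  for (arma::uword c = 0; c < g.con.n_rows; ++c) {
    int i = g.con(c, 0), j = g.con(c, 1);
    arma::rowvec d = X.row(i) - X.row(j);
    double r = arma::norm(d);
    double sr = g.con_sig[c] / r;
    double sr2 = sr * sr, sr4 = sr2 * sr2, sr10 = sr4 * sr4 * sr2, sr12 = sr10 * sr2;
    E += g.con_eps[c] * (5.0 * sr12 - 6.0 * sr10);
    double dVdr = (60.0 * g.con_eps[c] / r) * (sr10 - sr12);
    arma::rowvec f = -dVdr * d / r;
    F.row(i) += f; F.row(j) -= f;
  }
  // nonnative repulsion: WCA, zero (value and force) beyond 2^(1/6) sigma
  double rcut = std::pow(2.0, 1.0 / 6.0) * g.sig_wca;
  for (arma::uword c = 0; c < g.rep.n_rows; ++c) {
    int i = g.rep(c, 0), j = g.rep(c, 1);
    arma::rowvec d = X.row(i) - X.row(j);
    double r = arma::norm(d);
    if (r >= rcut) continue;
    double sr = g.sig_wca / r;
    double sr2 = sr * sr, sr6 = sr2 * sr2 * sr2, sr12 = sr6 * sr6;
    E += 4.0 * g.eps_rep * (sr12 - sr6) + g.eps_rep;
    double dVdr = (4.0 * g.eps_rep / r) * (-12.0 * sr12 + 6.0 * sr6);
    arma::rowvec f = -dVdr * d / r;
    F.row(i) += f; F.row(j) -= f;
  }
  // flat-bottom spherical container
  if (g.has_container) {
    for (arma::uword i = 0; i < X.n_rows; ++i) {
      arma::rowvec d = X.row(i) - g.cc;
      double r = arma::norm(d);
      if (r > g.cR) {
        double dr = r - g.cR;
        E += 0.5 * g.ck * dr * dr;
        F.row(i) += -g.ck * dr * d / r;
      }
    }
  }
  return E;
}

// 2-D analytic surfaces -----------------------------------------------------
struct Surf {
  int kind;          // 0 = gaussian sum (Mueller-Brown form), 1 = two-channel double well
  arma::mat G;       // gaussians: rows (A, a, b, c, x0, y0)
  arma::vec dw;      // double well: (ky, h, sx, sy, y0)
};

static Surf parse_surf(List sys) {
  Surf s;
  std::string kind = as<std::string>(sys["surface_kind"]);
  if (kind == "gaussians") { s.kind = 0; s.G = as<arma::mat>(sys["terms"]); }
  else { s.kind = 1; s.dw = as<arma::vec>(sys["dw_params"]); }
  return s;
}

static double surf_energy_forces(const Surf &s, const arma::mat &X, arma::mat &F) {
  double x = X(0, 0), y = X(0, 1), E = 0.0;
  double fx = 0.0, fy = 0.0;
  if (s.kind == 0) {
    for (arma::uword t = 0; t < s.G.n_rows; ++t) {
      double A = s.G(t, 0), a = s.G(t, 1), b = s.G(t, 2), c = s.G(t, 3);
      double dx = x - s.G(t, 4), dy = y - s.G(t, 5);
      double e = A * std::exp(a * dx * dx + b * dx * dy + c * dy * dy);
      E += e;
      fx -= e * (2.0 * a * dx + b * dy);
      fy -= e * (b * dx + 2.0 * c * dy);
    }
  } else {
    double ky = s.dw[0], h = s.dw[1], sx = s.dw[2], sy = s.dw[3], y0 = s.dw[4];
    double q = x * x - 1.0;
    double dy = y - y0;
    double bump = h * std::exp(-x * x / sx - dy * dy / sy);
    E = q * q + ky * y * y + bump;
    fx = -(4.0 * x * q) + bump * 2.0 * x / sx;
    fy = -(2.0 * ky * y) + bump * 2.0 * dy / sy;
  }
  F.set_size(1, 2);
  F(0, 0) = fx; F(0, 1) = fy;
  return E;
}

// [[Rcpp::export]]
List cpp_system_forces(List sys, const arma::mat &X) {
  std::string kind = as<std::string>(sys["kind"]);
  arma::mat F;
  double E;
  if (kind == "surface") {
    Surf s = parse_surf(sys);
    E = surf_energy_forces(s, X, F);
  } else {
    GoSys g = parse_go(sys);
    E = go_energy_forces(g, X, F);
  }
  return List::create(_["energy"] = E, _["forces"] = F);
}

// ---------------------------------------------------------------------------
// Trajectory runner

struct BiasAccum {
  double work_total = 0.0;   // bias force dot displacement, all steps
  double work_latent = 0.0;  // same, restricted to steps with latent bias
  int n_active = 0;
};

// evaluate total force; cv/bias evaluated with the memories passed in
// (memories updated by caller afterwards: evaluate-then-update order)
static void total_force(List sys, const std::string &syskind,
                        const GoSys *go, const Surf *sf,
                        const CVContext *ctx, int bias_mode,
                        double kR, double ks, double kw,
                        const arma::imat &ridx, const arma::mat &ranchor, double rk,
                        const arma::mat &X,
                        double mem1, double mem2,
                        arma::mat &F, arma::mat &Fbias,
                        double &cv1, double &cv2) {
  if (syskind == "surface") surf_energy_forces(*sf, X, F);
  else go_energy_forces(*go, X, F);
  // positional restraints
  for (arma::uword r = 0; r < ridx.n_rows; ++r) {
    int i = ridx(r, 0);
    arma::rowvec d = X.row(i) - ranchor.row(r);
    F.row(i) += -rk * d;
  }
  Fbias.zeros(X.n_rows, X.n_cols);
  cv1 = NA_REAL; cv2 = NA_REAL;
  if (bias_mode == 1) {            // rMD on z
    arma::mat Gz;
    double z = eval_z(X, *ctx, Gz);
    cv1 = z;
    if (R_finite(mem1) && z > mem1 && kR != 0.0)
      Fbias = -kR * (z - mem1) * Gz;
  } else if (bias_mode == 2) {     // SCPS on s_lambda and d = -w_lambda
    double s, d;
    arma::mat Gs, Gd;
    eval_path_cvs(X, *ctx, s, Gs, d, Gd);
    cv1 = s; cv2 = d;
    if (R_finite(mem1) && s > mem1 && ks != 0.0)
      Fbias += -ks * (s - mem1) * Gs;
    if (R_finite(mem2) && d > mem2 && kw != 0.0)
      Fbias += -kw * (d - mem2) * Gd;
  }
  F += Fbias;
}

// [[Rcpp::export]]
List cpp_run_trajectory(List sys, List cv, List engine,
                        const arma::mat &X0, Nullable<NumericMatrix> v0_) {
  std::string syskind = as<std::string>(sys["kind"]);
  GoSys go; Surf sf;
  if (syskind == "surface") sf = parse_surf(sys); else go = parse_go(sys);

  int bias_mode = as<int>(engine["bias_mode"]); // 0 none, 1 rmd, 2 scps
  CVContext ctx;
  if (cv.containsElementNamed("is_surface")) ctx = parse_cv(cv);

  double dt = as<double>(engine["dt"]);
  double gamma = as<double>(engine["friction"]);
  double T = as<double>(engine["temperature"]);
  int n_steps = as<int>(engine["n_steps"]);
  int stride = as<int>(engine["save_stride"]);
  bool overdamped = as<std::string>(engine["scheme"]) == "overdamped";
  double kR = as<double>(engine["k_r"]);
  double ks = as<double>(engine["k_s"]);
  double kw = as<double>(engine["k_w"]);
  double mem1 = as<double>(engine["mem1_init"]);  // NA -> first-frame value
  double mem2 = as<double>(engine["mem2_init"]);

  arma::imat ridx; arma::mat ranchor; double rk = 0.0;
  if (engine.containsElementNamed("restraint_idx") &&
      !Rf_isNull(engine["restraint_idx"])) {
    ridx = as<arma::imat>(engine["restraint_idx"]);
    ranchor = as<arma::mat>(engine["restraint_anchor"]);
    rk = as<double>(engine["restraint_k"]);
  }

  arma::mat X = X0;
  int n = X.n_rows, dim = X.n_cols, ndof = n * dim;
  arma::mat V(n, dim, arma::fill::zeros);
  if (v0_.isNotNull()) V = as<arma::mat>(v0_.get());
  else if (!overdamped && T > 0.0) {
    double sd = std::sqrt(T);
    for (int i = 0; i < n; ++i)
      for (int d2 = 0; d2 < dim; ++d2) V(i, d2) = sd * norm_rand();
  }

  int n_saved = n_steps / stride + 1;
  arma::mat frames(n_saved, ndof);
  arma::vec tr_cv1(n_saved), tr_cv2(n_saved), tr_m1(n_saved), tr_m2(n_saved);
  tr_cv1.fill(NA_REAL); tr_cv2.fill(NA_REAL);
  tr_m1.fill(NA_REAL);  tr_m2.fill(NA_REAL);

  arma::mat F, Fbias;
  double cv1, cv2;
  BiasAccum acc;

  total_force(sys, syskind, &go, &sf, &ctx, bias_mode, kR, ks, kw,
              ridx, ranchor, rk, X, mem1, mem2, F, Fbias, cv1, cv2);
  // initialize ratchet memories from the first frame
  if (bias_mode != 0) {
    if (!R_finite(mem1)) mem1 = cv1;
    else mem1 = std::min(mem1, cv1);
    if (bias_mode == 2) {
      if (!R_finite(mem2)) mem2 = cv2;
      else mem2 = std::min(mem2, cv2);
    }
  }
  frames.row(0) = arma::vectorise(X.t()).t();
  tr_cv1[0] = cv1; tr_cv2[0] = cv2; tr_m1[0] = mem1; tr_m2[0] = mem2;

  bool error = false;
  int saved = 1;
  double c1 = std::exp(-gamma * dt);
  double c2 = (T > 0.0) ? std::sqrt(T * (1.0 - c1 * c1)) : 0.0;
  double od_a = (gamma > 0.0) ? dt / gamma : dt;
  double od_b = (gamma > 0.0 && T > 0.0) ? std::sqrt(2.0 * T * dt / gamma) : 0.0;

  for (int step = 1; step <= n_steps; ++step) {
    arma::mat Xold = X;
    if (overdamped) {
      for (int i = 0; i < n; ++i)
        for (int d2 = 0; d2 < dim; ++d2)
          X(i, d2) += od_a * F(i, d2) + od_b * norm_rand();
    } else {
      V += 0.5 * dt * F;
      X += 0.5 * dt * V;
      for (int i = 0; i < n; ++i)
        for (int d2 = 0; d2 < dim; ++d2)
          V(i, d2) = c1 * V(i, d2) + c2 * norm_rand();
      X += 0.5 * dt * V;
    }
    if (!X.is_finite()) { error = true; break; }
    total_force(sys, syskind, &go, &sf, &ctx, bias_mode, kR, ks, kw,
                ridx, ranchor, rk, X, mem1, mem2, F, Fbias, cv1, cv2);
    if (!F.is_finite()) { error = true; break; }
    if (!overdamped) V += 0.5 * dt * F;

    // bias work bookkeeping (force at the memory used for this step)
    double wstep = arma::dot(arma::vectorise(Fbias), arma::vectorise(X - Xold));
    acc.work_total += wstep;
    bool active = arma::any(arma::vectorise(Fbias) != 0.0);
    if (active) acc.n_active++; else acc.work_latent += wstep;

    // evaluate-then-update: memories updated after the force evaluation
    if (bias_mode != 0) {
      mem1 = std::min(mem1, cv1);
      if (bias_mode == 2) mem2 = std::min(mem2, cv2);
    }
    if (step % stride == 0) {
      frames.row(saved) = arma::vectorise(X.t()).t();
      tr_cv1[saved] = cv1; tr_cv2[saved] = cv2;
      tr_m1[saved] = mem1; tr_m2[saved] = mem2;
      saved++;
    }
  }
  if (saved < n_saved) {
    frames = frames.rows(0, saved - 1);
    tr_cv1 = tr_cv1.subvec(0, saved - 1);
    tr_cv2 = tr_cv2.subvec(0, saved - 1);
    tr_m1 = tr_m1.subvec(0, saved - 1);
    tr_m2 = tr_m2.subvec(0, saved - 1);
  }
  return List::create(_["frames"] = frames,
                      _["cv1"] = tr_cv1, _["cv2"] = tr_cv2,
                      _["mem1"] = tr_m1, _["mem2"] = tr_m2,
                      _["velocities"] = V,
                      _["bias_work_total"] = acc.work_total,
                      _["bias_work_latent"] = acc.work_latent,
                      _["n_bias_active"] = acc.n_active,
                      _["error"] = error,
                      _["n_saved"] = saved);
}

// ---------------------------------------------------------------------------
// Kabsch superposition RMSD over trajectory frames.
// frames: n_frames x (n*3) row-major per bead (x1 y1 z1 x2 ...).
// align / calc are 0-based bead index vectors.
// [[Rcpp::export]]
NumericVector cpp_rmsd_frames(const arma::mat &frames, const arma::mat &ref,
                              const arma::uvec &align, const arma::uvec &calc) {
  int nf = frames.n_rows, n = ref.n_rows;
  NumericVector out(nf);
  arma::mat refA = ref.rows(align);
  arma::rowvec refAc = arma::mean(refA, 0);
  arma::mat refA0 = refA.each_row() - refAc;
  arma::mat refC = ref.rows(calc);
  for (int f = 0; f < nf; ++f) {
    arma::mat X(n, 3);
    for (int i = 0; i < n; ++i)
      for (int d = 0; d < 3; ++d) X(i, d) = frames(f, 3 * i + d);
    arma::mat XA = X.rows(align);
    arma::rowvec XAc = arma::mean(XA, 0);
    arma::mat XA0 = XA.each_row() - XAc;
    arma::mat H = XA0.t() * refA0;   // H = U diag(sv) V'
    arma::mat U, Vm; arma::vec sv;
    arma::svd(U, sv, Vm, H);
    double det = arma::det(Vm * U.t());
    arma::mat D = arma::eye(3, 3);
    if (det < 0) D(2, 2) = -1.0;
    arma::mat R = Vm * D * U.t();
    arma::mat Xc = X.each_row() - XAc;
    arma::mat Xfit = Xc * R.t();
    Xfit.each_row() += refAc;
    arma::mat diff = Xfit.rows(calc) - refC;
    out[f] = std::sqrt(arma::accu(diff % diff) / calc.n_elem);
  }
  return out;
}

// contact maps for every frame (rows of `frames` as in cpp_rmsd_frames)
// [[Rcpp::export]]
NumericMatrix cpp_contact_frames(const arma::mat &frames,
                                 const arma::ivec &pi_, const arma::ivec &pj_,
                                 double r0, double rc) {
  int nf = frames.n_rows, P = pi_.n_elem;
  NumericMatrix out(nf, P);
  for (int f = 0; f < nf; ++f) {
    for (int p = 0; p < P; ++p) {
      int i = pi_[p], j = pj_[p];
      double dx = frames(f, 3 * i) - frames(f, 3 * j);
      double dy = frames(f, 3 * i + 1) - frames(f, 3 * j + 1);
      double dz = frames(f, 3 * i + 2) - frames(f, 3 * j + 2);
      double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      double c, dc;
      if (r == 0.0) { out(f, p) = 1.0; continue; }
      contact_fun(r, r0, rc, c, dc);
      out(f, p) = c;
    }
  }
  return out;
}

// pairwise Ca distances for every frame, selected pairs
// [[Rcpp::export]]
NumericMatrix cpp_pair_distances(const arma::mat &frames,
                                 const arma::ivec &pi_, const arma::ivec &pj_) {
  int nf = frames.n_rows, P = pi_.n_elem;
  NumericMatrix out(nf, P);
  for (int f = 0; f < nf; ++f)
    for (int p = 0; p < P; ++p) {
      int i = pi_[p], j = pj_[p];
      double dx = frames(f, 3 * i) - frames(f, 3 * j);
      double dy = frames(f, 3 * i + 1) - frames(f, 3 * j + 1);
      double dz = frames(f, 3 * i + 2) - frames(f, 3 * j + 2);
      out(f, p) = std::sqrt(dx * dx + dy * dy + dz * dz);
    }
  return out;
}
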