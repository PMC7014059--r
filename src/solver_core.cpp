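// Finite-volume core: staggered (MAC) projection solver for incompressible
// variable-property two-phase flow with CSF surface tension + wall contact
// angle, FCT volume-of-fluid advection, and consistent fibrinogen transport.
//
// Layout: cell (i,j), i = 0..nx-1 horizontal (x), j = 0..ny-1 vertical (y),
// column-major index i + nx*j (matches R matrices).
// u lives on vertical faces: (nx+1) x ny ; v on horizontal faces: nx x (ny+1).
// SI units throughout (dx in metres). Depth is 1 m (2D convention).
//
// Boundaries: left = alveolar-bone inlet (u = u_in), bottom = blood inlet
// (v = v_in), top = pressure outlet (p = 0), right + thread solids = implant
// wall (no-slip, contact-angle wall adhesion).

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

static const double TINY = 1e-300;

struct Sim {
  int nx, ny;
  double dx;
  std::vector<int> solid;      // 1 = inside thread solid
  std::vector<int> interf;     // 1 = interfacial zone (fluid cells)
  // material constants
  double rho0, rho1, rho_rbc, mu_rbc, sigma, Dfib;
  // viscosity pieces: mu = (a*C^2 + b*C + c) * 1e-3 on [lo, hi)
  std::vector<double> va, vb, vc, vlo, vhi;
  // boundary conditions
  double u_in, v_in, alpha_in, s_in, theta; // theta radians
  bool left_inlet, bottom_inlet, top_outlet;
  // numerics
  int nsmooth, sor_maxit;
  double sor_tol;              // rms divergence residual target, 1/s
  double cfl_safety;
  double grad_eps;             // curvature active where |grad as| > grad_eps * max
  double alpha_eps;
  double c_compress;           // interface-compression coefficient (c_alpha)
  double s_cap;                // physical ceiling on q/alpha (kg fib / m^3 plasma)
  // fields
  std::vector<double> alpha, q, u, v, p;
  // scratch
  std::vector<double> rho, mu, as, nxc, nyc, kap, fx, fy, us, vs;
  std::vector<double> Fax, Fay;          // limited alpha volume-fluxes per face
  std::vector<double> sm_tmp, gmag_buf, FxL, FyL, Ax, Ay, atd, Rp, Rm, sbuf,
      Fqx, Fqy, dq, bE, bN, rhs, diag;
  std::vector<double> bTop;
  std::vector<double> cg_r, cg_z, cg_pk, cg_Ap, ic_d;
  // compact fluid-cell indexing for the pressure solve (static geometry)
  std::vector<int> fcell;               // compact k -> cell index c
  std::vector<int> fidx;                // cell index c -> compact k (-1 solid)
  std::vector<int> nbW, nbE, nbS, nbN;  // compact neighbor ids (-1 none)
  std::vector<int> iW, iE, iS, iN;      // padded ids (-1 -> nf ghost slot)
  std::vector<double> cW, cE, cS, cN, cD, crhs;
  long sor_iter_acc = 0;
  std::vector<int> wallAdj;              // implant-adjacent fluid cells
  std::vector<char> int9;                // interior cell with all 8 fluid nbrs
  std::vector<double> nwx, nwy;          // wall normal (into fluid)
  double time;
  // audits
  double fib_flux_acc;                   // kg through boundaries since last audit
  double max_fib_resid;
  int sor_fail;
  long n_substeps;

  int C(int i, int j) const { return i + nx * j; }
  int U(int i, int j) const { return i + (nx + 1) * j; }
  int V(int i, int j) const { return i + nx * j; }
  bool fluid(int i, int j) const {
    return i >= 0 && i < nx && j >= 0 && j < ny && !solid[C(i, j)];
  }
};

static double visc_piece(const Sim &S, double Cc) {
  if (Cc < 0) Cc = 0;
  for (size_t k = 0; k < S.va.size(); ++k)
    if (Cc >= S.vlo[k] && Cc < S.vhi[k])
      return (S.va[k] * Cc * Cc + S.vb[k] * Cc + S.vc[k]) * 1e-3;
  size_t k = S.va.size() - 1;
  return (S.va[k] * Cc * Cc + S.vb[k] * Cc + S.vc[k]) * 1e-3;
}

// q = alpha * s with s = rho_m(Y) * Y ; invert s -> Y (linear; mixing law is
// harmonic in mass fractions)
static inline double Y_from_s(const Sim &S, double s) {
  double denom = 1.0 + s * (1.0 / S.rho1 - 1.0 / S.rho0);
  double Y = (s / S.rho1) / denom;
  if (Y < 0) Y = 0;
  if (Y > 0.999) Y = 0.999;
  return Y;
}
static inline double rhom_from_Y(const Sim &S, double Y) {
  return 1.0 / (Y / S.rho0 + (1.0 - Y) / S.rho1);
}

static void cell_properties(Sim &S) {
  for (int j = 0; j < S.ny; ++j)
    for (int i = 0; i < S.nx; ++i) {
      int c = S.C(i, j);
      if (S.solid[c]) { S.rho[c] = S.rho_rbc; S.mu[c] = S.mu_rbc; continue; }
      double a = S.alpha[c];
      double s = (a > S.alpha_eps) ? S.q[c] / a : 0.0;
      double Y = Y_from_s(S, s);
      double rm = rhom_from_Y(S, Y);
      double Cc = 0.1 * Y * rm;            // g/100 mL
      double mum = visc_piece(S, Cc);
      S.rho[c] = a * rm + (1.0 - a) * S.rho_rbc;
      S.mu[c]  = a * mum + (1.0 - a) * S.mu_rbc;
    }
}

// --- smoothing (Neumann mirror at solids/boundaries) -----------------------
static void smooth_alpha(Sim &S) {
  S.as = S.alpha;
  std::vector<double> &tmp = S.sm_tmp;
  tmp.assign(S.as.size(), 0.0);
  const int nx = S.nx;
  for (int pass = 0; pass < S.nsmooth; ++pass) {
    const double *a = S.as.data();
    for (int j = 0; j < S.ny; ++j)
      for (int i = 0; i < S.nx; ++i) {
        int c = S.C(i, j);
        if (S.int9[c]) {
          tmp[c] = (a[c - nx - 1] + 2 * a[c - nx] + a[c - nx + 1] +
                    2 * a[c - 1] + 4 * a[c] + 2 * a[c + 1] +
                    a[c + nx - 1] + 2 * a[c + nx] + a[c + nx + 1]) * 0.0625;
          continue;
        }
        if (S.solid[c]) { tmp[c] = S.as[c]; continue; }
        double wsum = 0, vsum = 0;
        static const int di[9] = {-1,0,1,-1,0,1,-1,0,1};
        static const int dj[9] = {-1,-1,-1,0,0,0,1,1,1};
        static const double w[9] = {1,2,1,2,4,2,1,2,1};
        for (int k = 0; k < 9; ++k) {
          int ii = i + di[k], jj = j + dj[k];
          double val = S.fluid(ii, jj) ? S.as[S.C(ii, jj)] : S.as[c];
          wsum += w[k]; vsum += w[k] * val;
        }
        tmp[c] = vsum / wsum;
      }
    std::swap(S.as, tmp);
  }
}

// wall geometry for contact-angle enforcement (static; computed once)
static void build_fluid_index(Sim &S) {
  S.fidx.assign(S.nx * S.ny, -1);
  S.fcell.clear();
  for (int j = 0; j < S.ny; ++j)
    for (int i = 0; i < S.nx; ++i)
      if (!S.solid[S.C(i, j)]) {
        S.fidx[S.C(i, j)] = (int)S.fcell.size();
        S.fcell.push_back(S.C(i, j));
      }
  int nf = (int)S.fcell.size();
  S.nbW.assign(nf, -1); S.nbE.assign(nf, -1);
  S.nbS.assign(nf, -1); S.nbN.assign(nf, -1);
  for (int k = 0; k < nf; ++k) {
    int c = S.fcell[k];
    int i = c % S.nx, j = c / S.nx;
    if (i - 1 >= 0)   S.nbW[k] = S.fidx[S.C(i - 1, j)];
    if (i + 1 < S.nx) S.nbE[k] = S.fidx[S.C(i + 1, j)];
    if (j - 1 >= 0)   S.nbS[k] = S.fidx[S.C(i, j - 1)];
    if (j + 1 < S.ny) S.nbN[k] = S.fidx[S.C(i, j + 1)];
  }
  S.iW.assign(nf, nf); S.iE.assign(nf, nf); S.iS.assign(nf, nf); S.iN.assign(nf, nf);
  for (int k = 0; k < nf; ++k) {
    if (S.nbW[k] >= 0) S.iW[k] = S.nbW[k];
    if (S.nbE[k] >= 0) S.iE[k] = S.nbE[k];
    if (S.nbS[k] >= 0) S.iS[k] = S.nbS[k];
    if (S.nbN[k] >= 0) S.iN[k] = S.nbN[k];
  }
}

static void build_interior9(Sim &S) {
  S.int9.assign(S.nx * S.ny, 0);
  for (int j = 1; j < S.ny - 1; ++j)
    for (int i = 1; i < S.nx - 1; ++i) {
      bool ok = true;
      for (int dj = -1; dj <= 1 && ok; ++dj)
        for (int di = -1; di <= 1 && ok; ++di)
          if (S.solid[S.C(i + di, j + dj)]) ok = false;
      if (ok) S.int9[S.C(i, j)] = 1;
    }
}

static void build_wall_adjacency(Sim &S) {
  S.wallAdj.assign(S.nx * S.ny, 0);
  S.nwx.assign(S.nx * S.ny, 0.0);
  S.nwy.assign(S.nx * S.ny, 0.0);
  for (int j = 0; j < S.ny; ++j)
    for (int i = 0; i < S.nx; ++i) {
      int c = S.C(i, j);
      if (S.solid[c]) continue;
      double gx = 0, gy = 0;
      bool adj = false;
      // implant = right domain wall or thread solid
      if (i + 1 >= S.nx || S.solid[S.C(i + 1, j)]) { adj = true; gx -= 1.0; }
      if (i - 1 >= 0 && S.solid[S.C(i - 1, j)])    { adj = true; gx += 1.0; }
      if (j + 1 < S.ny && S.solid[S.C(i, j + 1)])  { adj = true; gy -= 1.0; }
      if (j - 1 >= 0 && S.solid[S.C(i, j - 1)])    { adj = true; gy += 1.0; }
      if (!adj) continue;
      double n = std::sqrt(gx * gx + gy * gy);
      if (n < 1e-12) continue;
      S.wallAdj[c] = 1;
      S.nwx[c] = gx / n;   // points from wall into fluid
      S.nwy[c] = gy / n;
    }
}

// interface normals (into plasma), wall adhesion, curvature, face forces
static void csf(Sim &S) {
  smooth_alpha(S);
  int n = S.nx * S.ny;
  S.nxc.assign(n, 0.0); S.nyc.assign(n, 0.0); S.kap.assign(n, 0.0);
  double gmax = 0;
  std::vector<double> &gmag = S.gmag_buf;
  gmag.assign(n, 0.0);
  for (int j = 0; j < S.ny; ++j)
    for (int i = 0; i < S.nx; ++i) {
      int c = S.C(i, j);
      if (S.solid[c]) continue;
      double aE = S.fluid(i + 1, j) ? S.as[S.C(i + 1, j)] : S.as[c];
      double aW = S.fluid(i - 1, j) ? S.as[S.C(i - 1, j)] : S.as[c];
      double aN = S.fluid(i, j + 1) ? S.as[S.C(i, j + 1)] : S.as[c];
      double aS_ = S.fluid(i, j - 1) ? S.as[S.C(i, j - 1)] : S.as[c];
      double gx = (aE - aW) / (2 * S.dx), gy = (aN - aS_) / (2 * S.dx);
      double g = std::sqrt(gx * gx + gy * gy);
      gmag[c] = g;
      if (g > gmax) gmax = g;
      if (g > 1e-12) { S.nxc[c] = gx / g; S.nyc[c] = gy / g; } // into plasma
    }
  if (gmax <= 0) { S.fx.assign((S.nx + 1) * S.ny, 0.0); S.fy.assign(S.nx * (S.ny + 1), 0.0); return; }
  double gcut = S.grad_eps * gmax;
  // wall adhesion on implant-adjacent cells
  double ct = std::cos(S.theta), st = std::sin(S.theta);
  for (int c = 0; c < n; ++c) {
    if (!S.wallAdj[c] || gmag[c] <= gcut) continue;
    double nwX = S.nwx[c], nwY = S.nwy[c];
    double gX = S.nxc[c], gY = S.nyc[c];
    double dot = gX * nwX + gY * nwY;
    double tX = gX - dot * nwX, tY = gY - dot * nwY;
    double tn = std::sqrt(tX * tX + tY * tY);
    if (tn > 1e-8) { tX /= tn; tY /= tn; }
    else {           // interface normal parallel to wall normal: pick a tangent
      tX = -nwY; tY = nwX;
    }
    S.nxc[c] = -ct * nwX + st * tX;     // normal into plasma
    S.nyc[c] = -ct * nwY + st * tY;
  }
  // curvature kappa = -div(nhat), face-averaged normals
  for (int j = 0; j < S.ny; ++j)
    for (int i = 0; i < S.nx; ++i) {
      int c = S.C(i, j);
      if (S.solid[c] || gmag[c] <= gcut) { S.kap[c] = 0; continue; }
      double nE = S.fluid(i + 1, j) ? 0.5 * (S.nxc[c] + S.nxc[S.C(i + 1, j)]) : S.nxc[c];
      double nW = S.fluid(i - 1, j) ? 0.5 * (S.nxc[c] + S.nxc[S.C(i - 1, j)]) : S.nxc[c];
      double nN = S.fluid(i, j + 1) ? 0.5 * (S.nyc[c] + S.nyc[S.C(i, j + 1)]) : S.nyc[c];
      double nS_ = S.fluid(i, j - 1) ? 0.5 * (S.nyc[c] + S.nyc[S.C(i, j - 1)]) : S.nyc[c];
      double k = -((nE - nW) + (nN - nS_)) / S.dx;
      // cap at the smallest resolvable radius (two cells): grid-scale
      // fragments otherwise drive unbounded parasitic currents
      double kmax = 0.25 / S.dx;
      if (k > kmax) k = kmax;
      if (k < -kmax) k = -kmax;
      S.kap[c] = k;
    }
  // face forces: sigma * kappa_face * d(alpha)/dn (raw alpha gradient)
  S.fx.assign((S.nx + 1) * S.ny, 0.0);
  S.fy.assign(S.nx * (S.ny + 1), 0.0);
  for (int j = 0; j < S.ny; ++j)
    for (int i = 1; i < S.nx; ++i) {
      if (!S.fluid(i - 1, j) || !S.fluid(i, j)) continue;
      int cL = S.C(i - 1, j), cR = S.C(i, j);
      double kf = 0.5 * (S.kap[cL] + S.kap[cR]);
      S.fx[S.U(i, j)] = S.sigma * kf * (S.alpha[cR] - S.alpha[cL]) / S.dx;
    }
  for (int j = 1; j < S.ny; ++j)
    for (int i = 0; i < S.nx; ++i) {
      if (!S.fluid(i, j - 1) || !S.fluid(i, j)) continue;
      int cS = S.C(i, j - 1), cN = S.C(i, j);
      double kf = 0.5 * (S.kap[cS] + S.kap[cN]);
      S.fy[S.V(i, j)] = S.sigma * kf * (S.alpha[cN] - S.alpha[cS]) / S.dx;
    }
}

// --- velocity boundary conditions ------------------------------------------
static void apply_velocity_bc(Sim &S, std::vector<double> &uu, std::vector<double> &vv) {
  // left / right u faces, solid-adjacent faces
  for (int j = 0; j < S.ny; ++j) {
    uu[S.U(0, j)]   = (S.left_inlet && S.fluid(0, j)) ? S.u_in : 0.0;
    uu[S.U(S.nx, j)] = 0.0;                                  // implant wall
    for (int i = 1; i < S.nx; ++i)
      if (!S.fluid(i - 1, j) || !S.fluid(i, j)) uu[S.U(i, j)] = 0.0;
  }
  for (int i = 0; i < S.nx; ++i) {
    vv[S.V(i, 0)] = (S.bottom_inlet && S.fluid(i, 0)) ? S.v_in : 0.0;
    if (!S.top_outlet || !S.fluid(i, S.ny - 1)) vv[S.V(i, S.ny)] = 0.0;
    for (int j = 1; j < S.ny; ++j)
      if (!S.fluid(i, j - 1) || !S.fluid(i, j)) vv[S.V(i, j)] = 0.0;
  }
}

// --- momentum predictor -----------------------------------------------------
static void momentum_predict(Sim &S, double dt) {
  S.us = S.u; S.vs = S.v;
  const double dx = S.dx;
  // u faces: interior i = 1..nx-1, both cells fluid
  for (int j = 0; j < S.ny; ++j)
    for (int i = 1; i < S.nx; ++i) {
      if (!S.fluid(i - 1, j) || !S.fluid(i, j)) continue;
      int f = S.U(i, j);
      int cL = S.C(i - 1, j), cR = S.C(i, j);
      double uc = S.u[f];
      double uE = S.u[S.U(i + 1, j)], uW = S.u[S.U(i - 1, j)];
      double uN = (j + 1 < S.ny) ? S.u[S.U(i, j + 1)] : uc;        // outlet: du/dy=0
      double uS_ = (j - 1 >= 0) ? S.u[S.U(i, j - 1)] : -uc;        // inlet wall: u_t=0
      double vb = 0.25 * (S.v[S.V(i - 1, j)] + S.v[S.V(i, j)] +
                          S.v[S.V(i - 1, j + 1)] + S.v[S.V(i, j + 1)]);
      // hybrid advection: central at low cell Peclet, upwind beyond
      double rfc = 0.5 * (S.rho[cL] + S.rho[cR]);
      double mfc = 0.5 * (S.mu[cL] + S.mu[cR]);
      double dudx, dudy;
      if (rfc * std::fabs(uc) * dx / mfc < 2.0)
        dudx = (uE - uW) / (2 * dx);
      else
        dudx = (uc >= 0) ? (uc - uW) / dx : (uE - uc) / dx;
      if (rfc * std::fabs(vb) * dx / mfc < 2.0)
        dudy = (uN - uS_) / (2 * dx);
      else
        dudy = (vb >= 0) ? (uc - uS_) / dx : (uN - uc) / dx;
      double conv = uc * dudx + vb * dudy;
      double muL = S.mu[cL], muR = S.mu[cR];
      double mun, mus;
      {
        double m1 = S.mu[cL], m2 = S.mu[cR];
        double m3 = S.fluid(i - 1, j + 1) ? S.mu[S.C(i - 1, j + 1)] : m1;
        double m4 = S.fluid(i, j + 1) ? S.mu[S.C(i, j + 1)] : m2;
        mun = 0.25 * (m1 + m2 + m3 + m4);
        double m5 = S.fluid(i - 1, j - 1) ? S.mu[S.C(i - 1, j - 1)] : m1;
        double m6 = S.fluid(i, j - 1) ? S.mu[S.C(i, j - 1)] : m2;
        mus = 0.25 * (m1 + m2 + m5 + m6);
      }
      double visc = (muR * (uE - uc) - muL * (uc - uW)) / (dx * dx)
                  + (mun * (uN - uc) - mus * (uc - uS_)) / (dx * dx);
      double rf = 0.5 * (S.rho[cL] + S.rho[cR]);
      S.us[f] = uc + dt * (-conv + (visc + S.fx[f]) / rf);
    }
  // v faces: interior j = 1..ny-1 plus outlet row j = ny (zero-gradient copy)
  for (int j = 1; j < S.ny; ++j)
    for (int i = 0; i < S.nx; ++i) {
      if (!S.fluid(i, j - 1) || !S.fluid(i, j)) continue;
      int f = S.V(i, j);
      int cS = S.C(i, j - 1), cN = S.C(i, j);
      double vc = S.v[f];
      double vN = S.v[S.V(i, j + 1)], vS_ = S.v[S.V(i, j - 1)];
      double vE, vW;
      if (i + 1 < S.nx && S.fluid(i + 1, j) && S.fluid(i + 1, j - 1))
        vE = S.v[S.V(i + 1, j)];
      else vE = -vc;                                        // no-slip wall/solid
      if (i - 1 >= 0 && S.fluid(i - 1, j) && S.fluid(i - 1, j - 1))
        vW = S.v[S.V(i - 1, j)];
      else vW = S.left_inlet && i == 0 ? -vc : -vc;         // v_t = 0 at inlet too
      double ub = 0.25 * (S.u[S.U(i, j - 1)] + S.u[S.U(i + 1, j - 1)] +
                          S.u[S.U(i, j)] + S.u[S.U(i + 1, j)]);
      double rfc = 0.5 * (S.rho[cS] + S.rho[cN]);
      double mfc = 0.5 * (S.mu[cS] + S.mu[cN]);
      double dvdx, dvdy;
      if (rfc * std::fabs(ub) * dx / mfc < 2.0)
        dvdx = (vE - vW) / (2 * dx);
      else
        dvdx = (ub >= 0) ? (vc - vW) / dx : (vE - vc) / dx;
      if (rfc * std::fabs(vc) * dx / mfc < 2.0)
        dvdy = (vN - vS_) / (2 * dx);
      else
        dvdy = (vc >= 0) ? (vc - vS_) / dx : (vN - vc) / dx;
      double conv = ub * dvdx + vc * dvdy;
      double mue, muw;
      {
        double m1 = S.mu[cS], m2 = S.mu[cN];
        double m3 = S.fluid(i + 1, j - 1) ? S.mu[S.C(i + 1, j - 1)] : m1;
        double m4 = S.fluid(i + 1, j) ? S.mu[S.C(i + 1, j)] : m2;
        mue = 0.25 * (m1 + m2 + m3 + m4);
        double m5 = S.fluid(i - 1, j - 1) ? S.mu[S.C(i - 1, j - 1)] : m1;
        double m6 = S.fluid(i - 1, j) ? S.mu[S.C(i - 1, j)] : m2;
        muw = 0.25 * (m1 + m2 + m5 + m6);
      }
      double visc = (mue * (vE - vc) - muw * (vc - vW)) / (dx * dx)
                  + (S.mu[cN] * (vN - vc) - S.mu[cS] * (vc - vS_)) / (dx * dx);
      double rf = 0.5 * (S.rho[cS] + S.rho[cN]);
      S.vs[f] = vc + dt * (-conv + (visc + S.fy[f]) / rf);
    }
  // outlet row: zero normal gradient (closed top: wall, handled by the BC)
  if (S.top_outlet)
    for (int i = 0; i < S.nx; ++i)
      if (S.fluid(i, S.ny - 1)) S.vs[S.V(i, S.ny)] = S.vs[S.V(i, S.ny - 1)];
  apply_velocity_bc(S, S.us, S.vs);
}


// --- pressure projection (variable-coefficient, red-black SOR) --------------
static void project(Sim &S, double dt) {
  const double dx = S.dx;
  int n = S.nx * S.ny;
  // face mobility beta = dt / rho_face on open faces; 0 on closed faces
  std::vector<double> &bE = S.bE, &bN = S.bN;
  std::vector<double> &bTop = S.bTop;
  bE.assign(n, 0.0); bN.assign(n, 0.0); bTop.assign(S.nx, 0.0);
  for (int j = 0; j < S.ny; ++j)
    for (int i = 0; i < S.nx; ++i) {
      int c = S.C(i, j);
      if (S.solid[c]) continue;
      if (i + 1 < S.nx && S.fluid(i + 1, j))
        bE[c] = dt / (0.5 * (S.rho[c] + S.rho[S.C(i + 1, j)]));
      if (j + 1 < S.ny && S.fluid(i, j + 1))
        bN[c] = dt / (0.5 * (S.rho[c] + S.rho[S.C(i, j + 1)]));
    }
  if (S.top_outlet)
    for (int i = 0; i < S.nx; ++i)
      if (S.fluid(i, S.ny - 1)) bTop[i] = dt / S.rho[S.C(i, S.ny - 1)];
  // rhs: divergence of predictor velocity
  std::vector<double> &rhs = S.rhs, &diag = S.diag;
  rhs.assign(n, 0.0); diag.assign(n, 0.0);
  for (int j = 0; j < S.ny; ++j)
    for (int i = 0; i < S.nx; ++i) {
      int c = S.C(i, j);
      if (S.solid[c]) continue;
      rhs[c] = (S.us[S.U(i + 1, j)] - S.us[S.U(i, j)] +
                S.vs[S.V(i, j + 1)] - S.vs[S.V(i, j)]) / dx;
      double d = bE[c] + bN[c];
      if (i - 1 >= 0 && S.fluid(i - 1, j)) d += bE[S.C(i - 1, j)];
      if (j - 1 >= 0 && S.fluid(i, j - 1)) d += bN[S.C(i, j - 1)];
      if (j == S.ny - 1) d += bTop[i];          // Dirichlet p=0 ghost at outlet
      diag[c] = d / (dx * dx);
    }
  // relaxed-modified-incomplete-Cholesky preconditioned conjugate gradients
  // on the compact fluid-cell numbering, warm-started from the previous
  // pressure. Convergence on the rms divergence residual (1/s):
  // ||r||_2 / sqrt(nf) < sor_tol.
  const double idx2 = 1.0 / (dx * dx);
  const int nf = (int)S.fcell.size();
  bool has_outlet = false;
  for (int i = 0; i < S.nx; ++i) if (bTop[i] > 0) has_outlet = true;
  std::vector<double> &r = S.cg_r, &z = S.cg_z, &pk = S.cg_pk, &Ap = S.cg_Ap,
      &d = S.ic_d;
  std::vector<double> &aW = S.cW, &aE2 = S.cE, &aS2 = S.cS, &aN2 = S.cN,
      &dg = S.cD, &b2 = S.crhs;
  r.assign(nf + 1, 0.0); z.assign(nf + 1, 0.0); pk.assign(nf + 1, 0.0);
  Ap.assign(nf + 1, 0.0); d.assign(nf, 0.0);
  aW.assign(nf, 0.0); aE2.assign(nf, 0.0); aS2.assign(nf, 0.0); aN2.assign(nf, 0.0);
  dg.assign(nf, 0.0); b2.assign(nf, 0.0);
  for (int k = 0; k < nf; ++k) {
    int c = S.fcell[k];
    dg[k] = diag[c];
    b2[k] = -rhs[c];
    if (S.nbE[k] >= 0 && bE[c] > 0) aE2[k] = -bE[c] * idx2;
    if (S.nbW[k] >= 0) { double b = bE[S.fcell[S.nbW[k]]]; if (b > 0) aW[k] = -b * idx2; }
    if (S.nbN[k] >= 0 && bN[c] > 0) aN2[k] = -bN[c] * idx2;
    if (S.nbS[k] >= 0) { double b = bN[S.fcell[S.nbS[k]]]; if (b > 0) aS2[k] = -b * idx2; }
  }
  if (!has_outlet) {            // singular operator: make rhs compatible
    double mean = 0;
    for (int k = 0; k < nf; ++k) mean += b2[k];
    mean /= nf;
    for (int k = 0; k < nf; ++k) b2[k] -= mean;
  }
  // relaxed modified IC(0) diagonal (5-point); the row-sum correction
  // sharply improves conditioning for Poisson-type operators
  const double mic_theta = 0.95;
  for (int k = 0; k < nf; ++k) {
    double dd = dg[k];
    if (S.nbW[k] >= 0 && aW[k] != 0 && d[S.nbW[k]] > 0) {
      int w = S.nbW[k];
      dd -= aW[k] * (aW[k] + mic_theta * aN2[w]) / d[w];
    }
    if (S.nbS[k] >= 0 && aS2[k] != 0 && d[S.nbS[k]] > 0) {
      int b = S.nbS[k];
      dd -= aS2[k] * (aS2[k] + mic_theta * aE2[b]) / d[b];
    }
    d[k] = (dd > 1e-300) ? dd : dg[k];
  }
  const int *iW = S.iW.data(), *iE = S.iE.data(), *iS = S.iS.data(),
            *iN = S.iN.data();
  auto applyA = [&](std::vector<double> &x, std::vector<double> &y) {
    x[nf] = 0.0;   // ghost slot
    const double *xp = x.data();
    for (int k = 0; k < nf; ++k)
      y[k] = dg[k] * xp[k] + aW[k] * xp[iW[k]] + aE2[k] * xp[iE[k]] +
             aS2[k] * xp[iS[k]] + aN2[k] * xp[iN[k]];
  };
  auto precond = [&](const std::vector<double> &rv, std::vector<double> &zv) {
    zv[nf] = 0.0;
    double *zp = zv.data();
    for (int k = 0; k < nf; ++k)
      zp[k] = (rv[k] - aW[k] * zp[iW[k]] - aS2[k] * zp[iS[k]]) / d[k];
    for (int k = nf - 1; k >= 0; --k)
      zp[k] = (zp[k] * d[k] - aE2[k] * zp[iE[k]] - aN2[k] * zp[iN[k]]) / d[k];
  };
  double tol2 = S.sor_tol * S.sor_tol * nf;
  std::vector<double> px(nf + 1, 0.0);
  for (int k = 0; k < nf; ++k) px[k] = S.p[S.fcell[k]];
  applyA(px, Ap);
  double rnorm2 = 0;
  for (int k = 0; k < nf; ++k) { r[k] = b2[k] - Ap[k]; rnorm2 += r[k] * r[k]; }
  int it = 0;
  if (rnorm2 >= tol2) {
    precond(r, z);
    for (int k = 0; k < nf; ++k) pk[k] = z[k];
    double rz = 0;
    for (int k = 0; k < nf; ++k) rz += r[k] * z[k];
    for (it = 1; it <= S.sor_maxit; ++it) {
      applyA(pk, Ap);
      double pAp = 0;
      for (int k = 0; k < nf; ++k) pAp += pk[k] * Ap[k];
      if (pAp <= 0) break;
      double alpha_k = rz / pAp;
      rnorm2 = 0;
      for (int k = 0; k < nf; ++k) {
        px[k] += alpha_k * pk[k];
        r[k] -= alpha_k * Ap[k];
        rnorm2 += r[k] * r[k];
      }
      if (rnorm2 < tol2) break;
      precond(r, z);
      double rznew = 0;
      for (int k = 0; k < nf; ++k) rznew += r[k] * z[k];
      double beta = rznew / rz;
      rz = rznew;
      for (int k = 0; k < nf; ++k) pk[k] = z[k] + beta * pk[k];
    }
  }
  if (it >= S.sor_maxit) S.sor_fail++;
  if (!has_outlet) {
    double mean = 0;
    for (int k = 0; k < nf; ++k) mean += px[k];
    mean /= nf;
    for (int k = 0; k < nf; ++k) px[k] -= mean;
  }
  for (int k = 0; k < nf; ++k) S.p[S.fcell[k]] = px[k];
  S.sor_iter_acc += it;
  // velocity correction
  S.u = S.us; S.v = S.vs;
  for (int j = 0; j < S.ny; ++j)
    for (int i = 1; i < S.nx; ++i) {
      int cL = S.C(i - 1, j);
      if (bE[cL] > 0)
        S.u[S.U(i, j)] -= bE[cL] * (S.p[S.C(i, j)] - S.p[cL]) / dx;
    }
  for (int j = 1; j < S.ny; ++j)
    for (int i = 0; i < S.nx; ++i) {
      int cS = S.C(i, j - 1);
      if (bN[cS] > 0)
        S.v[S.V(i, j)] -= bN[cS] * (S.p[S.C(i, j)] - S.p[cS]) / dx;
    }
  for (int i = 0; i < S.nx; ++i)
    if (S.fluid(i, S.ny - 1))
      S.v[S.V(i, S.ny)] = S.vs[S.V(i, S.ny)] - bTop[i] * (0.0 - S.p[S.C(i, S.ny - 1)]) / dx;
  apply_velocity_bc(S, S.u, S.v);
  // exact global balance: distribute residual imbalance over outlet faces
  double qin = 0.0, qout = 0.0; int nout = 0;
  if (S.left_inlet) for (int j = 0; j < S.ny; ++j) if (S.fluid(0, j)) qin += S.u_in * dx;
  if (S.bottom_inlet) for (int i = 0; i < S.nx; ++i) if (S.fluid(i, 0)) qin += S.v_in * dx;
  for (int i = 0; i < S.nx; ++i)
    if (S.fluid(i, S.ny - 1)) { qout += S.v[S.V(i, S.ny)] * dx; nout++; }
  if (nout > 0 && (S.left_inlet || S.bottom_inlet)) {
    double corr = (qin - qout) / (nout * dx);
    for (int i = 0; i < S.nx; ++i)
      if (S.fluid(i, S.ny - 1)) S.v[S.V(i, S.ny)] += corr;
  }
}

// --- FCT advection of alpha + consistent fibrinogen transport ----------------
static inline double superbee(double r) {
  double a = std::min(2.0 * r, 1.0), b = std::min(r, 2.0);
  return std::max(0.0, std::max(a, b));
}
static inline double minmod(double r) {
  return std::max(0.0, std::min(1.0, r));
}

// returns limited high-order face value for donor cell 'up'
static inline double muscl_face(double aupup, double aup, double adn, double cfl,
                                bool haveUU, bool sharp) {
  double d = adn - aup;
  if (std::fabs(d) < 1e-14 || !haveUU) return aup;
  double r = (aup - aupup) / d;
  double phi = sharp ? superbee(r) : minmod(r);
  return aup + 0.5 * phi * (1.0 - cfl) * d;
}

static void advect(Sim &S, double dt, bool update_alpha, bool update_q) {
  const double dx = S.dx;
  const double A = dx;              // face area per unit depth
  const double Vc = dx * dx;        // cell volume per unit depth
  int n = S.nx * S.ny;
  std::vector<double> &Fx = S.Fax, &Fy = S.Fay;    // total alpha volume-fluxes
  Fx.assign((S.nx + 1) * S.ny, 0.0);
  Fy.assign(S.nx * (S.ny + 1), 0.0);
  std::vector<double> &FxL = S.FxL, &FyL = S.FyL, &Ax = S.Ax, &Ay = S.Ay;
  FxL.assign((S.nx + 1) * S.ny, 0.0); FyL.assign(S.nx * (S.ny + 1), 0.0);
  Ax.assign((S.nx + 1) * S.ny, 0.0); Ay.assign(S.nx * (S.ny + 1), 0.0);
  std::vector<double> Axc((S.nx + 1) * S.ny, 0.0), Ayc(S.nx * (S.ny + 1), 0.0);

  // face fluxes of volume (G) and alpha (low order + antidiffusive)
  for (int j = 0; j < S.ny; ++j)
    for (int i = 0; i <= S.nx; ++i) {
      int f = S.U(i, j);
      double uf = S.u[f];
      double G = uf * dt * A;       // volume crossing face
      if (G == 0) continue;
      double aup, ahi;
      if (i == 0) {                 // left inlet
        aup = ahi = (G > 0) ? S.alpha_in : (S.fluid(0, j) ? S.alpha[S.C(0, j)] : 0.0);
      } else if (i == S.nx) {
        aup = ahi = S.fluid(S.nx - 1, j) ? S.alpha[S.C(S.nx - 1, j)] : 0.0;
      } else {
        if (!S.fluid(i - 1, j) || !S.fluid(i, j)) continue;
        double aL = S.alpha[S.C(i - 1, j)], aR = S.alpha[S.C(i, j)];
        double cfl = std::fabs(uf) * dt / dx;
        if (G > 0) {
          bool h = S.fluid(i - 2, j);
          double aUU = h ? S.alpha[S.C(i - 2, j)] : aL;
          aup = aL; ahi = muscl_face(aUU, aL, aR, cfl, h, true);
        } else {
          bool h = S.fluid(i + 1, j) && S.fluid(i + 1, j); // donor i, upup i+1
          bool h2 = S.fluid(i + 1, j);
          double aUU = h2 ? S.alpha[S.C(i + 1, j)] : aR;
          (void)h;
          aup = aR; ahi = muscl_face(aUU, aR, aL, cfl, h2, true);
        }
      }
      FxL[f] = G * aup;
      Ax[f] = G * ahi - FxL[f];
    }
  for (int j = 0; j <= S.ny; ++j)
    for (int i = 0; i < S.nx; ++i) {
      int f = S.V(i, j);
      double vf = S.v[f];
      double G = vf * dt * A;
      if (G == 0) continue;
      double aup, ahi;
      if (j == 0) {                 // bottom inlet
        aup = ahi = (G > 0) ? S.alpha_in : (S.fluid(i, 0) ? S.alpha[S.C(i, 0)] : 0.0);
      } else if (j == S.ny) {       // outlet: upwind out, ambient in
        aup = ahi = (G > 0) ? (S.fluid(i, S.ny - 1) ? S.alpha[S.C(i, S.ny - 1)] : 0.0)
                            : S.alpha_in;
      } else {
        if (!S.fluid(i, j - 1) || !S.fluid(i, j)) continue;
        double aS_ = S.alpha[S.C(i, j - 1)], aN = S.alpha[S.C(i, j)];
        double cfl = std::fabs(vf) * dt / dx;
        if (G > 0) {
          bool h = S.fluid(i, j - 2);
          double aUU = h ? S.alpha[S.C(i, j - 2)] : aS_;
          aup = aS_; ahi = muscl_face(aUU, aS_, aN, cfl, h, true);
        } else {
          bool h = S.fluid(i, j + 1);
          double aUU = h ? S.alpha[S.C(i, j + 1)] : aN;
          aup = aN; ahi = muscl_face(aUU, aN, aS_, cfl, h, true);
        }
      }
      FyL[f] = G * aup;
      Ay[f] = G * ahi - FyL[f];
    }

  // interface compression: an anti-diffusive face flux c_alpha |u_f| n_hat
  // alpha(1-alpha) along the interface normal (counter-gradient transport
  // that keeps the plasma front sharp). Folded into the antidiffusive flux
  // so the Zalesak limiter preserves [0,1] and exact conservation.
  if (S.c_compress > 0) {
    for (int j = 0; j < S.ny; ++j)
      for (int i = 1; i < S.nx; ++i) {
        if (!S.fluid(i - 1, j) || !S.fluid(i, j)) continue;
        int f = S.U(i, j);
        double uf = S.u[f];
        if (uf == 0) continue;
        int cL = S.C(i - 1, j), cR = S.C(i, j);
        double aL = S.alpha[cL], aR = S.alpha[cR];
        double gx = (aR - aL) / dx;
        double gyL = 0, gyR = 0;
        if (S.fluid(i - 1, j + 1) && S.fluid(i - 1, j - 1))
          gyL = (S.alpha[S.C(i - 1, j + 1)] - S.alpha[S.C(i - 1, j - 1)]) / (2 * dx);
        if (S.fluid(i, j + 1) && S.fluid(i, j - 1))
          gyR = (S.alpha[S.C(i, j + 1)] - S.alpha[S.C(i, j - 1)]) / (2 * dx);
        double gy = 0.5 * (gyL + gyR);
        double gn = std::sqrt(gx * gx + gy * gy);
        if (gn < 1e-12) continue;
        double af = 0.5 * (aL + aR);
        double G_c = S.c_compress * std::fabs(uf) * (gx / gn) *
                     af * (1.0 - af) * dt * A;
        Ax[f] += G_c;
        Axc[f] = G_c;
      }
    for (int j = 1; j < S.ny; ++j)
      for (int i = 0; i < S.nx; ++i) {
        if (!S.fluid(i, j - 1) || !S.fluid(i, j)) continue;
        int f = S.V(i, j);
        double vf = S.v[f];
        if (vf == 0) continue;
        int cS = S.C(i, j - 1), cN = S.C(i, j);
        double aS_ = S.alpha[cS], aN = S.alpha[cN];
        double gy = (aN - aS_) / dx;
        double gxS = 0, gxN = 0;
        if (S.fluid(i + 1, j - 1) && S.fluid(i - 1, j - 1))
          gxS = (S.alpha[S.C(i + 1, j - 1)] - S.alpha[S.C(i - 1, j - 1)]) / (2 * dx);
        if (S.fluid(i + 1, j) && S.fluid(i - 1, j))
          gxN = (S.alpha[S.C(i + 1, j)] - S.alpha[S.C(i - 1, j)]) / (2 * dx);
        double gx = 0.5 * (gxS + gxN);
        double gn = std::sqrt(gx * gx + gy * gy);
        if (gn < 1e-12) continue;
        double af = 0.5 * (aS_ + aN);
        double G_c = S.c_compress * std::fabs(vf) * (gy / gn) *
                     af * (1.0 - af) * dt * A;
        Ay[f] += G_c;
        Ayc[f] = G_c;
      }
  }

  // transported-diffused (low-order) solution
  std::vector<double> &atd = S.atd;
  atd.assign(n, 0.0);
  for (int j = 0; j < S.ny; ++j)
    for (int i = 0; i < S.nx; ++i) {
      int c = S.C(i, j);
      if (S.solid[c]) { atd[c] = 0; continue; }
      double din = FxL[S.U(i, j)] - FxL[S.U(i + 1, j)] + FyL[S.V(i, j)] - FyL[S.V(i, j + 1)];
      atd[c] = S.alpha[c] + din / Vc;
    }
  // Zalesak limiter with global bounds [0,1]
  std::vector<double> &Rp = S.Rp, &Rm = S.Rm;
  Rp.assign(n, 1.0); Rm.assign(n, 1.0);
  for (int j = 0; j < S.ny; ++j)
    for (int i = 0; i < S.nx; ++i) {
      int c = S.C(i, j);
      if (S.solid[c]) continue;
      double Pp = 0, Pm = 0;
      double aW = Ax[S.U(i, j)], aE = Ax[S.U(i + 1, j)];
      double aS_ = Ay[S.V(i, j)], aN = Ay[S.V(i, j + 1)];
      Pp += std::max(aW, 0.0) - std::min(aE, 0.0);
      Pp += std::max(aS_, 0.0) - std::min(aN, 0.0);
      Pm += std::max(aE, 0.0) - std::min(aW, 0.0);
      Pm += std::max(aN, 0.0) - std::min(aS_, 0.0);
      double Qp = std::max(0.0, (1.0 - atd[c])) * Vc;
      double Qm = std::max(0.0, atd[c]) * Vc;
      Rp[c] = (Pp > TINY) ? std::max(0.0, std::min(1.0, Qp / Pp)) : 1.0;
      Rm[c] = (Pm > TINY) ? std::max(0.0, std::min(1.0, Qm / Pm)) : 1.0;
    }
  auto limit_x = [&](int i, int j) -> double {
    int f = S.U(i, j);
    double a = Ax[f];
    if (a == 0) return 0.0;
    double cL = 1.0, cR = 1.0;
    bool hasL = i - 1 >= 0 && S.fluid(i - 1, j);
    bool hasR = i < S.nx && S.fluid(i, j);
    if (a > 0) {  // antidiffusive mass moves +x: leaves L, enters R
      cL = hasL ? Rm[S.C(i - 1, j)] : 1.0;
      cR = hasR ? Rp[S.C(i, j)] : 1.0;
    } else {
      cL = hasL ? Rp[S.C(i - 1, j)] : 1.0;
      cR = hasR ? Rm[S.C(i, j)] : 1.0;
    }
    return std::min(cL, cR) * a;
  };
  auto limit_y = [&](int i, int j) -> double {
    int f = S.V(i, j);
    double a = Ay[f];
    if (a == 0) return 0.0;
    double cS = 1.0, cN = 1.0;
    bool hasS = j - 1 >= 0 && S.fluid(i, j - 1);
    bool hasN = j < S.ny && S.fluid(i, j);
    if (a > 0) {
      cS = hasS ? Rm[S.C(i, j - 1)] : 1.0;
      cN = hasN ? Rp[S.C(i, j)] : 1.0;
    } else {
      cS = hasS ? Rp[S.C(i, j - 1)] : 1.0;
      cN = hasN ? Rm[S.C(i, j)] : 1.0;
    }
    return std::min(cS, cN) * a;
  };
  for (int j = 0; j < S.ny; ++j)
    for (int i = 0; i <= S.nx; ++i) Fx[S.U(i, j)] = FxL[S.U(i, j)] + limit_x(i, j);
  for (int j = 0; j <= S.ny; ++j)
    for (int i = 0; i < S.nx; ++i) Fy[S.V(i, j)] = FyL[S.V(i, j)] + limit_y(i, j);

  // consistent fibrinogen fluxes on the same alpha-fluxes
  if (update_q) {
    std::vector<double> &s = S.sbuf;
    s.assign(n, 0.0);
    for (int c = 0; c < n; ++c)
      if (!S.solid[c] && S.alpha[c] > S.alpha_eps) s[c] = S.q[c] / S.alpha[c];
    std::vector<double> &Fqx = S.Fqx, &Fqy = S.Fqy;
    Fqx.assign((S.nx + 1) * S.ny, 0.0); Fqy.assign(S.nx * (S.ny + 1), 0.0);
    for (int j = 0; j < S.ny; ++j)
      for (int i = 0; i <= S.nx; ++i) {
        int f = S.U(i, j);
        double G = Fx[f];
        if (G == 0) continue;
        double sf;
        double uf = S.u[f];
        if (i == 0) sf = (uf > 0) ? S.s_in : s[S.C(0, j)];
        else if (i == S.nx) sf = s[S.C(S.nx - 1, j)];
        else {
          double cfl = std::fabs(uf) * dt / dx;
          if (uf >= 0) {
            bool h = S.fluid(i - 2, j);
            sf = muscl_face(h ? s[S.C(i - 2, j)] : s[S.C(i - 1, j)],
                            s[S.C(i - 1, j)], s[S.C(i, j)], cfl, h, true);
          } else {
            bool h = S.fluid(i + 1, j);
            sf = muscl_face(h ? s[S.C(i + 1, j)] : s[S.C(i, j)],
                            s[S.C(i, j)], s[S.C(i - 1, j)], cfl, h, true);
          }
        }
        if (i > 0 && i < S.nx && Axc[f] != 0 && Ax[f] != 0) {
          // the limited compression share of the flux reconstructs the
          // interface; it carries the acceptor-side concentration so no
          // scalar is pumped across the reconstructed front
          double cf = (Fx[f] - FxL[f]) / Ax[f];       // Zalesak coefficient
          double Gc = cf * Axc[f];
          double Ga = G - Gc;
          double s_acc = (Gc > 0) ? s[S.C(i, j)] : s[S.C(i - 1, j)];
          Fqx[f] = Ga * sf + Gc * s_acc;
          continue;
        }
        Fqx[f] = G * sf;
      }
    for (int j = 0; j <= S.ny; ++j)
      for (int i = 0; i < S.nx; ++i) {
        int f = S.V(i, j);
        double G = Fy[f];
        if (G == 0) continue;
        double sf;
        double vf = S.v[f];
        if (j == 0) sf = (vf > 0) ? S.s_in : s[S.C(i, 0)];
        else if (j == S.ny) sf = (vf > 0) ? s[S.C(i, S.ny - 1)] : S.s_in;
        else {
          double cfl = std::fabs(vf) * dt / dx;
          if (vf >= 0) {
            bool h = S.fluid(i, j - 2);
            sf = muscl_face(h ? s[S.C(i, j - 2)] : s[S.C(i, j - 1)],
                            s[S.C(i, j - 1)], s[S.C(i, j)], cfl, h, true);
          } else {
            bool h = S.fluid(i, j + 1);
            sf = muscl_face(h ? s[S.C(i, j + 1)] : s[S.C(i, j)],
                            s[S.C(i, j)], s[S.C(i, j - 1)], cfl, h, true);
          }
        }
        if (j > 0 && j < S.ny && Ayc[f] != 0 && Ay[f] != 0) {
          double cf = (Fy[f] - FyL[f]) / Ay[f];
          double Gc = cf * Ayc[f];
          double Ga = G - Gc;
          double s_acc = (Gc > 0) ? s[S.C(i, j)] : s[S.C(i, j - 1)];
          Fqy[f] = Ga * sf + Gc * s_acc;
          continue;
        }
        Fqy[f] = G * sf;
      }
    // boundary fibrinogen mass audit (kg): influx positive
    for (int j = 0; j < S.ny; ++j) {
      if (S.fluid(0, j)) S.fib_flux_acc += Fqx[S.U(0, j)];
      if (S.fluid(S.nx - 1, j)) S.fib_flux_acc -= Fqx[S.U(S.nx, j)];
    }
    for (int i = 0; i < S.nx; ++i) {
      if (S.fluid(i, 0)) S.fib_flux_acc += Fqy[S.V(i, 0)];
      if (S.fluid(i, S.ny - 1)) S.fib_flux_acc -= Fqy[S.V(i, S.ny)];
    }
    for (int j = 0; j < S.ny; ++j)
      for (int i = 0; i < S.nx; ++i) {
        int c = S.C(i, j);
        if (S.solid[c]) continue;
        double din = Fqx[S.U(i, j)] - Fqx[S.U(i + 1, j)] + Fqy[S.V(i, j)] - Fqy[S.V(i, j + 1)];
        S.q[c] += din / Vc;
      }
    // interpolation slack between the limited alpha fluxes and the limited
    // concentration faces can strand concentration in nearly-empty cells;
    // clip to the physical ceiling; conservation is restored in proportion
    // to headroom (excess) or mass (deficit), so the total stays exact
    double netq = 0.0;
    for (int c = 0; c < S.nx * S.ny; ++c) {
      if (S.solid[c]) continue;
      double hi = S.alpha[c] * S.s_cap;
      if (S.q[c] < 0) { netq += S.q[c]; S.q[c] = 0; }
      else if (S.q[c] > hi) { netq += S.q[c] - hi; S.q[c] = hi; }
    }
    if (netq > 0.0) {
      // spread the excess over the remaining headroom in proportion
      double head = 0.0;
      for (int c = 0; c < S.nx * S.ny; ++c)
        if (!S.solid[c]) head += S.alpha[c] * S.s_cap - S.q[c];
      if (head > netq) {
        double f = netq / head;
        for (int c = 0; c < S.nx * S.ny; ++c)
          if (!S.solid[c]) S.q[c] += f * (S.alpha[c] * S.s_cap - S.q[c]);
      }
    } else if (netq < 0.0) {
      // draw the deficit back in proportion to the mass present
      double tot = 0.0;
      for (int c = 0; c < S.nx * S.ny; ++c)
        if (!S.solid[c]) tot += S.q[c];
      if (tot > -netq) {
        double f = netq / tot;
        for (int c = 0; c < S.nx * S.ny; ++c)
          if (!S.solid[c]) S.q[c] += f * S.q[c];
      }
    }
  }
  if (update_alpha) {
    // residual pressure-solve divergence can push alpha marginally out of
    // [0,1]; clip and redistribute the net so Sum(alpha V) is untouched
    double net = 0.0;
    for (int j = 0; j < S.ny; ++j)
      for (int i = 0; i < S.nx; ++i) {
        int c = S.C(i, j);
        if (S.solid[c]) continue;
        double din = Fx[S.U(i, j)] - Fx[S.U(i + 1, j)] + Fy[S.V(i, j)] - Fy[S.V(i, j + 1)];
        S.alpha[c] = atd[c] + (din - (FxL[S.U(i, j)] - FxL[S.U(i + 1, j)]
                                    + FyL[S.V(i, j)] - FyL[S.V(i, j + 1)])) / Vc;
        if (S.alpha[c] < 0) { net += S.alpha[c]; S.alpha[c] = 0; }
        else if (S.alpha[c] > 1) { net += S.alpha[c] - 1; S.alpha[c] = 1; }
      }
    if (net != 0.0) {
      int nmix = 0;
      for (int c = 0; c < S.nx * S.ny; ++c)
        if (!S.solid[c] && S.alpha[c] > 0.05 && S.alpha[c] < 0.95) nmix++;
      if (nmix > 0) {
        double add = net / nmix;
        for (int c = 0; c < S.nx * S.ny; ++c)
          if (!S.solid[c] && S.alpha[c] > 0.05 && S.alpha[c] < 0.95)
            S.alpha[c] += add;
      }
    }
  }
}

// --- explicit Fickian diffusion of fibrinogen (plasma-weighted) --------------
static void species_diffuse(Sim &S, double dt) {
  if (S.Dfib <= 0) return;
  const double dx = S.dx;
  int n = S.nx * S.ny;
  std::vector<double> &s = S.sbuf;
  s.assign(n, 0.0);
  for (int c = 0; c < n; ++c)
    if (!S.solid[c] && S.alpha[c] > S.alpha_eps) s[c] = S.q[c] / S.alpha[c];
  std::vector<double> &dq = S.dq;
  dq.assign(n, 0.0);
  for (int j = 0; j < S.ny; ++j)
    for (int i = 0; i < S.nx; ++i) {
      int c = S.C(i, j);
      if (S.solid[c]) continue;
      if (i + 1 < S.nx && S.fluid(i + 1, j)) {
        int cE = S.C(i + 1, j);
        double af = 0.5 * (S.alpha[c] + S.alpha[cE]);
        double Fd = S.Dfib * af * (s[cE] - s[c]) / dx * dx * dt;   // kg across face
        dq[c] += Fd; dq[cE] -= Fd;
      }
      if (j + 1 < S.ny && S.fluid(i, j + 1)) {
        int cN = S.C(i, j + 1);
        double af = 0.5 * (S.alpha[c] + S.alpha[cN]);
        double Fd = S.Dfib * af * (s[cN] - s[c]) / dx * dx * dt;
        dq[c] += Fd; dq[cN] -= Fd;
      }
    }
  const double Vc = dx * dx;
  for (int c = 0; c < n; ++c) S.q[c] += dq[c] / Vc;
}

// --- masses (kg, per 1 m depth) ---------------------------------------------
static void masses(const Sim &S, double out[4]) {
  // out: fib_interfacial, fib_total, plasma_interfacial, plasma_total
  double Vc = S.dx * S.dx;
  double fi = 0, ft = 0, pi = 0, pt = 0;
  for (int j = 0; j < S.ny; ++j)
    for (int i = 0; i < S.nx; ++i) {
      int c = S.C(i, j);
      if (S.solid[c]) continue;
      double a = S.alpha[c];
      double s = (a > S.alpha_eps) ? S.q[c] / a : 0.0;
      double Y = Y_from_s(S, s);
      double rm = rhom_from_Y(S, Y);
      double mf = a * s * Vc;               // alpha * rho_m * Y * V
      double mp = a * (rm - s) * Vc;        // alpha * rho_m * (1-Y) * V
      ft += mf; pt += mp;
      if (S.interf[c]) { fi += mf; pi += mp; }
    }
  out[0] = fi; out[1] = ft; out[2] = pi; out[3] = pt;
}

// --- stability limit ---------------------------------------------------------
static double stable_dt(const Sim &S, bool momentum) {
  double umax = 1e-12;
  for (double x : S.u) umax = std::max(umax, std::fabs(x));
  for (double x : S.v) umax = std::max(umax, std::fabs(x));
  double dt = S.dx / umax;                                   // advective
  if (momentum) {
    double numax = 1e-12;
    int n = S.nx * S.ny;
    for (int c = 0; c < n; ++c)
      if (!S.solid[c]) numax = std::max(numax, S.mu[c] / S.rho[c]);
    dt = std::min(dt, 0.25 * S.dx * S.dx / numax);           // viscous
    if (S.sigma > 0) {
      double rbar = 0.5 * (S.rho1 + S.rho_rbc);
      // capillary limit with the enforced curvature cap |kappa| <= 0.25/dx
      dt = std::min(dt, std::sqrt(rbar * S.dx * S.dx /
                                  (2.0 * M_PI * S.sigma * 0.25 / S.dx)));
      double fmax = 0.0;
      for (double f : S.fx) fmax = std::max(fmax, std::fabs(f));
      for (double f : S.fy) fmax = std::max(fmax, std::fabs(f));
      if (fmax > 0) {
        // a sub-step may not accelerate fluid past one cell of travel
        double amax = fmax / S.rho1;
        dt = std::min(dt, std::sqrt(2.0 * S.dx / amax));
      }
    }
  }
  if (S.Dfib > 0) dt = std::min(dt, 0.25 * S.dx * S.dx / S.Dfib);
  return S.cfl_safety * dt;
}

// --- builders ----------------------------------------------------------------
static Sim build_sim(IntegerMatrix solid, IntegerMatrix interfacial, double dx,
                     List props, List bc, List cfg,
                     NumericMatrix alpha0, NumericMatrix q0,
                     NumericMatrix u0, NumericMatrix v0, NumericMatrix p0,
                     double t0) {
  Sim S;
  S.nx = solid.nrow(); S.ny = solid.ncol(); S.dx = dx;
  S.solid.assign(solid.begin(), solid.end());
  S.interf.assign(interfacial.begin(), interfacial.end());
  S.rho0 = as<double>(props["rho_fibrinogen"]);
  S.rho1 = as<double>(props["rho_plasma"]);
  S.rho_rbc = as<double>(props["rho_rbc"]);
  S.mu_rbc = as<double>(props["mu_rbc"]);
  S.sigma = as<double>(props["sigma"]);
  S.Dfib = as<double>(props["D_fib"]);
  NumericMatrix vp = props["viscosity_pieces"];
  for (int k = 0; k < vp.nrow(); ++k) {
    S.va.push_back(vp(k, 0)); S.vb.push_back(vp(k, 1)); S.vc.push_back(vp(k, 2));
    S.vlo.push_back(vp(k, 3)); S.vhi.push_back(vp(k, 4));
  }
  S.u_in = as<double>(bc["u_in"]);
  S.v_in = as<double>(bc["v_in"]);
  S.alpha_in = as<double>(bc["alpha_in"]);
  double Yin = as<double>(bc["Y_in"]);
  S.s_in = rhom_from_Y(S, Yin) * Yin;
  S.theta = as<double>(bc["theta_rad"]);
  S.left_inlet = as<bool>(bc["left_inlet"]);
  S.bottom_inlet = as<bool>(bc["bottom_inlet"]);
  S.top_outlet = as<bool>(bc["top_outlet"]);
  S.nsmooth = as<int>(cfg["nsmooth"]);
  S.sor_tol = as<double>(cfg["p_tol"]);
  S.sor_maxit = as<int>(cfg["p_maxit"]);
  S.cfl_safety = as<double>(cfg["cfl_safety"]);
  S.grad_eps = as<double>(cfg["grad_eps"]);
  S.alpha_eps = as<double>(cfg["alpha_eps"]);
  S.c_compress = as<double>(cfg["c_compress"]);
  S.alpha.assign(alpha0.begin(), alpha0.end());
  S.q.assign(q0.begin(), q0.end());
  S.u.assign(u0.begin(), u0.end());
  S.v.assign(v0.begin(), v0.end());
  S.p.assign(p0.begin(), p0.end());
  S.time = t0;
  int n = S.nx * S.ny;
  S.rho.assign(n, S.rho1); S.mu.assign(n, S.mu_rbc);
  S.as.assign(n, 0.0); S.nxc.assign(n, 0.0); S.nyc.assign(n, 0.0); S.kap.assign(n, 0.0);
  S.fx.assign((S.nx + 1) * S.ny, 0.0);
  S.fy.assign(S.nx * (S.ny + 1), 0.0);
  S.fib_flux_acc = 0.0; S.max_fib_resid = 0.0; S.sor_fail = 0; S.n_substeps = 0;
  // fibrinogen concentration can never exceed the largest concentration
  // present initially or injected at the inlets (no concentrating mechanism)
  S.s_cap = S.s_in;
  for (int c = 0; c < n; ++c)
    if (!S.solid[c] && S.alpha[c] > S.alpha_eps)
      S.s_cap = std::max(S.s_cap, S.q[c] / S.alpha[c]);
  S.s_cap *= 1.01;   // 1% slack: a field sitting exactly at the ceiling
                     // must not be clipped by interpolation-level noise
  build_wall_adjacency(S);
  build_fluid_index(S);
  build_interior9(S);
  apply_velocity_bc(S, S.u, S.v);
  return S;
}

static void substep(Sim &S, double dt, bool do_mom, bool do_vof, bool do_sp,
                    bool do_st, bool props_fresh = false) {
  if (!props_fresh) cell_properties(S);
  if (do_mom) {
    if (do_st && S.sigma > 0) csf(S);
    else {
      S.fx.assign((S.nx + 1) * S.ny, 0.0);
      S.fy.assign(S.nx * (S.ny + 1), 0.0);
    }
    momentum_predict(S, dt);
    project(S, dt);
  }
  if (do_vof || do_sp) advect(S, dt, do_vof, do_sp);
  if (do_sp) species_diffuse(S, dt);
  S.time += dt;
  S.n_substeps++;
}

static List fields_out(const Sim &S) {
  NumericMatrix alpha(S.nx, S.ny), q(S.nx, S.ny), p(S.nx, S.ny);
  NumericMatrix u(S.nx + 1, S.ny), v(S.nx, S.ny + 1);
  std::copy(S.alpha.begin(), S.alpha.end(), alpha.begin());
  std::copy(S.q.begin(), S.q.end(), q.begin());
  std::copy(S.p.begin(), S.p.end(), p.begin());
  std::copy(S.u.begin(), S.u.end(), u.begin());
  std::copy(S.v.begin(), S.v.end(), v.begin());
  return List::create(_["alpha"] = alpha, _["q"] = q, _["u"] = u, _["v"] = v,
                      _["p"] = p, _["time"] = S.time);
}

// Advance from t0 to t_end in outer steps of cfg$dt, sub-stepped for
// stability; record mass series every sample_stride outer steps.
// [[Rcpp::export]]
List core_run(IntegerMatrix solid, IntegerMatrix interfacial, double dx,
              List props, List bc, List cfg,
              NumericMatrix alpha0, NumericMatrix q0,
              NumericMatrix u0, NumericMatrix v0, NumericMatrix p0,
              double t0, double t_end,
              bool do_momentum = true, bool do_vof = true, bool do_species = true,
              bool do_surface_tension = true) {
  Sim S = build_sim(solid, interfacial, dx, props, bc, cfg,
                    alpha0, q0, u0, v0, p0, t0);
  double dt = as<double>(cfg["dt"]);
  int stride = as<int>(cfg["sample_stride"]);
  double inner_tol = as<double>(cfg["inner_tolerance"]);
  long nsteps = (long)std::llround((t_end - t0) / dt);
  if (nsteps < 0) nsteps = 0;
  long nsamp = nsteps / stride + 1;
  NumericMatrix series(nsamp, 6);   // t, mfi, mft, mpi, mpt, fib_resid
  double m[4];
  masses(S, m);
  long row = 0;
  series(row, 0) = S.time;
  for (int k = 0; k < 4; ++k) series(row, k + 1) = m[k];
  series(row, 5) = 0.0;
  row++;
  double m_prev_tot = m[1];
  int inner_viol = 0;
  for (long step = 1; step <= nsteps; ++step) {
    S.fib_flux_acc = 0.0;
    // adaptive sub-stepping: re-evaluate the stability limit before every
    // sub-step so intra-step velocity growth cannot break the CFL bound
    double tau = 0.0;
    int guard = 0;
    while (tau < dt * (1.0 - 1e-12) && guard < 1000) {
      cell_properties(S);
      double dts = stable_dt(S, do_momentum);
      double remain = dt - tau;
      int nsplit = std::max(1, (int)std::ceil(remain / dts));
      double dsub = remain / nsplit;
      substep(S, dsub, do_momentum, do_vof, do_species, do_surface_tension,
              true);
      tau += dsub;
      guard++;
    }
    S.time = t0 + step * dt;   // tile exactly; no drift
    masses(S, m);
    double resid = std::fabs((m[1] - m_prev_tot) - S.fib_flux_acc);
    if (resid > S.max_fib_resid) S.max_fib_resid = resid;
    if (resid > inner_tol) inner_viol++;
    m_prev_tot = m[1];
    if (step % stride == 0 && row < nsamp) {
      series(row, 0) = t0 + step * dt;
      for (int k = 0; k < 4; ++k) series(row, k + 1) = m[k];
      series(row, 5) = resid;
      row++;
    }
    if (step % 2000 == 0) Rcpp::checkUserInterrupt();
  }
  List out = fields_out(S);
  out["series"] = series;
  out["n_substeps"] = (double)S.n_substeps;
  out["max_fib_residual"] = S.max_fib_resid;
  out["inner_violations"] = inner_viol;
  out["p_fail"] = S.sor_fail;
  out["p_iters"] = (double)S.sor_iter_acc;
  return out;
}

// Single-operator kernels (same code paths, selectable pieces), advancing
// exactly `dt` with `nsub` equal sub-steps. Velocities held fixed unless
// momentum is on.
// [[Rcpp::export]]
List core_advance(IntegerMatrix solid, IntegerMatrix interfacial, double dx,
                  List props, List bc, List cfg,
                  NumericMatrix alpha0, NumericMatrix q0,
                  NumericMatrix u0, NumericMatrix v0, NumericMatrix p0,
                  double t0, double dt, int nsub,
                  bool do_momentum, bool do_vof, bool do_species,
                  bool do_surface_tension) {
  Sim S = build_sim(solid, interfacial, dx, props, bc, cfg,
                    alpha0, q0, u0, v0, p0, t0);
  double dsub = dt / std::max(1, nsub);
  for (int k = 0; k < std::max(1, nsub); ++k)
    substep(S, dsub, do_momentum, do_vof, do_species, do_surface_tension);
  List out = fields_out(S);
  out["fib_boundary_flux"] = S.fib_flux_acc;
  out["p_fail"] = S.sor_fail;
  return out;
}

// Continuum-surface-force field for a given alpha field.
// [[Rcpp::export]]
List core_csf(IntegerMatrix solid, double dx, List props, List bc, List cfg,
              NumericMatrix alpha0) {
  IntegerMatrix interfacial(solid.nrow(), solid.ncol());
  NumericMatrix q0(solid.nrow(), solid.ncol());
  NumericMatrix u0(solid.nrow() + 1, solid.ncol());
  NumericMatrix v0(solid.nrow(), solid.ncol() + 1);
  NumericMatrix p0(solid.nrow(), solid.ncol());
  Sim S = build_sim(solid, interfacial, dx, props, bc, cfg,
                    alpha0, q0, u0, v0, p0, 0.0);
  csf(S);
  NumericMatrix fx(S.nx + 1, S.ny), fy(S.nx, S.ny + 1), kap(S.nx, S.ny);
  NumericMatrix fcx(S.nx, S.ny), fcy(S.nx, S.ny);
  std::copy(S.fx.begin(), S.fx.end(), fx.begin());
  std::copy(S.fy.begin(), S.fy.end(), fy.begin());
  std::copy(S.kap.begin(), S.kap.end(), kap.begin());
  for (int j = 0; j < S.ny; ++j)
    for (int i = 0; i < S.nx; ++i) {
      fcx(i, j) = 0.5 * (S.fx[S.U(i, j)] + S.fx[S.U(i + 1, j)]);
      fcy(i, j) = 0.5 * (S.fy[S.V(i, j)] + S.fy[S.V(i, j + 1)]);
    }
  return List::create(_["fx_face"] = fx, _["fy_face"] = fy, _["kappa"] = kap,
                      _["fx"] = fcx, _["fy"] = fcy);
}
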