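// Steady 2D incompressible laminar flow and passive scalar transport on a
// masked uniform staggered grid.
//
// Flow: artificial-compressibility pseudo-time marching (explicit).
//   u,v on faces, p in cell centers; first-order upwind momentum advection,
//   second-order central viscosity with reflected (no-slip) tangential
//   ghosts; plug inlet on the west boundary, zero-gradient outlet on the
//   east boundary rescaled each step for exact global mass balance.
// Scalar: explicit marching of advection-diffusion with a van-Leer TVD
//   limited second-order upwind face reconstruction (bounded scheme).
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline double vanleer(double r) {
  return (r + std::fabs(r)) / (1.0 + std::fabs(r));
}

// [[Rcpp::export]]
List cpp_solve_flow(IntegerMatrix mask, double h, double rho, double mu,
                    NumericVector uin, double c_factor, double cfl,
                    double tol_div, double tol_change, int max_steps,
                    int check_every,
                    Nullable<NumericMatrix> u_init = R_NilValue,
                    Nullable<NumericMatrix> v_init = R_NilValue,
                    Nullable<NumericMatrix> p_init = R_NilValue) {
  const int nx = mask.nrow(), ny = mask.ncol();
  const double nu = mu / rho;
  const int nu_faces = (nx + 1) * ny, nv_faces = nx * (ny + 1);
  std::vector<double> u(nu_faces, 0.0), v(nv_faces, 0.0), p(nx * ny, 0.0);
  std::vector<double> un(nu_faces, 0.0), vn(nv_faces, 0.0);
  std::vector<int> ut(nu_faces, 0), vt(nv_faces, 0);
  std::vector<int> cm(nx * ny, 0);
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) cm[i + j * nx] = mask(i, j);

  auto UI = [nx](int i, int j) { return i + j * (nx + 1); };
  auto VI = [nx](int i, int j) { return i + j * nx; };
  auto CI = [nx](int i, int j) { return i + j * nx; };

  // face classification: 0 wall, 1 interior, 2 inlet (west), 3 outlet (east)
  for (int j = 0; j < ny; ++j) {
    for (int i = 0; i <= nx; ++i) {
      int t = 0;
      if (i == 0) t = cm[CI(0, j)] ? 2 : 0;
      else if (i == nx) t = cm[CI(nx - 1, j)] ? 3 : 0;
      else t = (cm[CI(i - 1, j)] && cm[CI(i, j)]) ? 1 : 0;
      ut[UI(i, j)] = t;
    }
  }
  for (int j = 0; j <= ny; ++j)
    for (int i = 0; i < nx; ++i)
      vt[VI(i, j)] = (j > 0 && j < ny && cm[CI(i, j - 1)] && cm[CI(i, j)]) ? 1 : 0;

  double uref = 0.0, q_in = 0.0;
  int n_in = 0, n_out = 0;
  for (int j = 0; j < ny; ++j) {
    if (ut[UI(0, j)] == 2) {
      u[UI(0, j)] = uin[j];
      q_in += uin[j] * h;
      uref = std::max(uref, std::fabs(uin[j]));
      ++n_in;
    }
    if (ut[UI(nx, j)] == 3) ++n_out;
  }
  if (n_in == 0) stop("no inlet cells on the west boundary");
  if (n_out == 0) stop("no outlet cells on the east boundary");
  if (uref <= 0.0) {  // zero flow: trivial field
    return List::create(_["u"] = NumericMatrix(nx + 1, ny),
                        _["v"] = NumericMatrix(nx, ny + 1),
                        _["p"] = NumericMatrix(nx, ny),
                        _["steps"] = 0, _["converged"] = true,
                        _["resid"] = NumericMatrix(0, 3),
                        _["div_max"] = 0.0);
  }

  if (u_init.isNotNull()) {
    NumericMatrix ui(u_init);
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i <= nx; ++i)
        if (ut[UI(i, j)] == 1 || ut[UI(i, j)] == 3) u[UI(i, j)] = ui(i, j);
  }
  if (v_init.isNotNull()) {
    NumericMatrix vi(v_init);
    for (int j = 0; j <= ny; ++j)
      for (int i = 0; i < nx; ++i)
        if (vt[VI(i, j)] == 1) v[VI(i, j)] = vi(i, j);
  }
  if (p_init.isNotNull()) {
    NumericMatrix pi(p_init);
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i)
        if (cm[CI(i, j)]) p[CI(i, j)] = pi(i, j);
  }

  // pseudo-sound speed: at least c_factor * inlet speed, but never so slow
  // that the viscous step limit leaves pressure waves under-resolved
  const double csound = std::max(c_factor * uref, 4.0 * nu / h);
  const double c2rho = rho * csound * csound;
  double umax = 2.0 * uref;
  std::vector<double> rhist;
  std::vector<double> u_prev(u), v_prev(v);
  bool converged = false;
  int step = 0;
  double div_rel = NA_REAL, chg = NA_REAL;

  for (step = 1; step <= max_steps; ++step) {
    // combined acoustic + advective + viscous limit
    double dt = cfl / ((csound + umax) / h + 4.0 * nu / (h * h));

    // --- u momentum ---
    for (int j = 0; j < ny; ++j) {
      un[UI(0, j)] = u[UI(0, j)];
      un[UI(nx, j)] = u[UI(nx, j)];
      for (int i = 1; i < nx; ++i) {
        const int id = UI(i, j);
        if (ut[id] != 1) { un[id] = u[id]; continue; }
        const double uc = u[id];
        const double ue = u[UI(i + 1, j)], uw = u[UI(i - 1, j)];
        const double Fe = 0.5 * (uc + ue), Fw = 0.5 * (uw + uc);
        const double fx_e = Fe > 0 ? Fe * uc : Fe * ue;
        const double fx_w = Fw > 0 ? Fw * uw : Fw * uc;
        const double Vn = 0.5 * (v[VI(i - 1, j + 1)] + v[VI(i, j + 1)]);
        const double Vs = 0.5 * (v[VI(i - 1, j)] + v[VI(i, j)]);
        const double u_up = (j + 1 < ny) ? u[UI(i, j + 1)] : 0.0;
        const double u_dn = (j > 0) ? u[UI(i, j - 1)] : 0.0;
        const double fy_n = Vn > 0 ? Vn * uc : Vn * u_up;
        const double fy_s = Vs > 0 ? Vs * u_dn : Vs * uc;
        const double adv = (fx_e - fx_w + fy_n - fy_s) / h;
        const double uN = (j + 1 < ny && ut[UI(i, j + 1)] != 0) ? u[UI(i, j + 1)] : -uc;
        const double uS = (j > 0 && ut[UI(i, j - 1)] != 0) ? u[UI(i, j - 1)] : -uc;
        const double lap = (ue - 2.0 * uc + uw + uN - 2.0 * uc + uS) / (h * h);
        const double pg = (p[CI(i, j)] - p[CI(i - 1, j)]) / (rho * h);
        un[id] = uc + dt * (-adv - pg + nu * lap);
      }
    }
    // --- v momentum ---
    for (int i = 0; i < nx; ++i) {
      vn[VI(i, 0)] = v[VI(i, 0)];
      vn[VI(i, ny)] = v[VI(i, ny)];
    }
    for (int j = 1; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) {
        const int id = VI(i, j);
        if (vt[id] != 1) { vn[id] = v[id]; continue; }
        const double vc = v[id];
        const double vN = v[VI(i, j + 1)], vS = v[VI(i, j - 1)];
        const double Fn = 0.5 * (vc + vN), Fs = 0.5 * (vS + vc);
        const double fy_n = Fn > 0 ? Fn * vc : Fn * vN;
        const double fy_s = Fs > 0 ? Fs * vS : Fs * vc;
        const double Ue = 0.5 * (u[UI(i + 1, j - 1)] + u[UI(i + 1, j)]);
        const double Uw = 0.5 * (u[UI(i, j - 1)] + u[UI(i, j)]);
        const double v_e = (i + 1 < nx) ? v[VI(i + 1, j)] : 0.0;
        const double v_w = (i > 0) ? v[VI(i - 1, j)] : 0.0;
        const double fx_e = Ue > 0 ? Ue * vc : Ue * v_e;
        const double fx_w = Uw > 0 ? Uw * v_w : Uw * vc;
        const double adv = (fx_e - fx_w + fy_n - fy_s) / h;
        const double vE = (i + 1 < nx && vt[VI(i + 1, j)] != 0) ? v[VI(i + 1, j)] : -vc;
        const double vW = (i > 0 && vt[VI(i - 1, j)] != 0) ? v[VI(i - 1, j)] : -vc;
        const double lap = (vN - 2.0 * vc + vS + vE - 2.0 * vc + vW) / (h * h);
        const double pg = (p[CI(i, j)] - p[CI(i, j - 1)]) / (rho * h);
        vn[id] = vc + dt * (-adv - pg + nu * lap);
      }
    }
    u.swap(un);
    v.swap(vn);

    // outlet: zero-gradient then rescale for exact global mass balance
    double q_out = 0.0;
    for (int j = 0; j < ny; ++j)
      if (ut[UI(nx, j)] == 3) {
        u[UI(nx, j)] = u[UI(nx - 1, j)];
        q_out += u[UI(nx, j)] * h;
      }
    if (std::fabs(q_out) > 1e-30 * n_out) {
      const double f = q_in / q_out;
      if (f > 0 && std::isfinite(f))
        for (int j = 0; j < ny; ++j)
          if (ut[UI(nx, j)] == 3) u[UI(nx, j)] *= f;
    } else {
      for (int j = 0; j < ny; ++j)
        if (ut[UI(nx, j)] == 3) u[UI(nx, j)] = q_in / (n_out * h);
    }

    // pressure update from divergence (artificial compressibility)
    double dmax = 0.0;
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) {
        const int id = CI(i, j);
        if (!cm[id]) continue;
        const double div = (u[UI(i + 1, j)] - u[UI(i, j)] +
                            v[VI(i, j + 1)] - v[VI(i, j)]) / h;
        p[id] -= dt * c2rho * div;
        const double ad = std::fabs(div);
        if (ad > dmax) dmax = ad;
      }
    }
    // anchor pressure at the outlet column
    double p_ref = 0.0; int n_ref = 0;
    for (int j = 0; j < ny; ++j)
      if (cm[CI(nx - 1, j)]) { p_ref += p[CI(nx - 1, j)]; ++n_ref; }
    p_ref /= n_ref;
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i)
        if (cm[CI(i, j)]) p[CI(i, j)] -= p_ref;

    if (step % check_every == 0) {
      umax = uref;
      double du = 0.0;
      for (int k = 0; k < nu_faces; ++k) {
        umax = std::max(umax, std::fabs(u[k]));
        du = std::max(du, std::fabs(u[k] - u_prev[k]));
      }
      for (int k = 0; k < nv_faces; ++k) {
        umax = std::max(umax, std::fabs(v[k]));
        du = std::max(du, std::fabs(v[k] - v_prev[k]));
      }
      u_prev = u; v_prev = v;
      if (!std::isfinite(umax) || !std::isfinite(du))
        stop("flow march diverged (non-finite velocity); reduce cfl");
      div_rel = dmax * h / uref;
      chg = du / (uref * check_every);
      rhist.push_back((double)step);
      rhist.push_back(div_rel);
      rhist.push_back(chg);
      if (div_rel < tol_div && chg < tol_change) { converged = true; break; }
      Rcpp::checkUserInterrupt();
    }
  }

  NumericMatrix U(nx + 1, ny), V(nx, ny + 1), P(nx, ny);
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i <= nx; ++i) U(i, j) = u[UI(i, j)];
  for (int j = 0; j <= ny; ++j)
    for (int i = 0; i < nx; ++i) V(i, j) = v[VI(i, j)];
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) P(i, j) = p[CI(i, j)];
  const int nrow = rhist.size() / 3;
  NumericMatrix R(nrow, 3);
  for (int r = 0; r < nrow; ++r)
    for (int c = 0; c < 3; ++c) R(r, c) = rhist[3 * r + c];
  colnames(R) = CharacterVector::create("step", "div_rel", "change");
  return List::create(_["u"] = U, _["v"] = V, _["p"] = P,
                      _["steps"] = std::min(step, max_steps),
                      _["converged"] = converged, _["resid"] = R,
                      _["div_max"] = div_rel);
}

// [[Rcpp::export]]
List cpp_solve_species(IntegerMatrix mask, NumericMatrix U, NumericMatrix V,
                       double h, double D, NumericVector yin,
                       double cfl, double t_max, double tol_change,
                       int check_every, int max_steps) {
  const int nx = mask.nrow(), ny = mask.ncol();
  std::vector<int> cm(nx * ny, 0);
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) cm[i + j * nx] = mask(i, j);
  auto CI = [nx](int i, int j) { return i + j * nx; };

  std::vector<double> Y(nx * ny, 0.0), rate(nx * ny, 0.0);
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i)
      if (cm[CI(i, j)]) Y[CI(i, j)] = yin[j];  // streamwise fill initial guess

  double umax = 0.0;
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i <= nx; ++i) umax = std::max(umax, std::fabs(U(i, j)));
  for (int j = 0; j <= ny; ++j)
    for (int i = 0; i < nx; ++i) umax = std::max(umax, std::fabs(V(i, j)));
  // inlet Dirichlet faces double the local diffusive stiffness: use 6D/h^2
  double denom = 2.0 * umax / h + 6.0 * D / (h * h);
  if (denom <= 0) denom = 6.0 * std::max(D, 1e-12) / (h * h);
  const double dt = cfl / denom;

  std::vector<double> y_prev(Y);
  bool converged = false;
  double t = 0.0;
  int step = 0;
  double ymin_all = 1e300, ymax_all = -1e300;

  while (t < t_max && step < max_steps) {
    ++step;
    std::fill(rate.begin(), rate.end(), 0.0);
    // x faces (including inlet i=0 and outlet i=nx)
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i <= nx; ++i) {
        const bool mr = (i < nx) && cm[CI(i, j)];
        const bool ml = (i > 0) && cm[CI(i - 1, j)];
        const double uf = U(i, j);
        double flux;
        if (i == 0) {
          if (!mr) continue;
          flux = uf * yin[j] - 2.0 * D * (Y[CI(0, j)] - yin[j]) / h;
        } else if (i == nx) {
          if (!ml) continue;
          flux = uf * Y[CI(nx - 1, j)];
        } else {
          if (!(mr && ml)) continue;
          double up, dn, upup;
          if (uf >= 0) {
            up = Y[CI(i - 1, j)]; dn = Y[CI(i, j)];
            upup = (i >= 2 && cm[CI(i - 2, j)]) ? Y[CI(i - 2, j)] : up;
          } else {
            up = Y[CI(i, j)]; dn = Y[CI(i - 1, j)];
            upup = (i + 1 < nx && cm[CI(i + 1, j)]) ? Y[CI(i + 1, j)] : up;
          }
          const double dgrad = dn - up;
          double yf = up;
          if (std::fabs(dgrad) > 1e-300) {
            const double r = (up - upup) / dgrad;
            yf = up + 0.5 * vanleer(r) * dgrad;
          }
          flux = uf * yf - D * (Y[CI(i, j)] - Y[CI(i - 1, j)]) / h;
        }
        if (ml) rate[CI(i - 1, j)] -= flux / h;
        if (mr && i < nx) rate[CI(i, j)] += flux / h;
      }
    }
    // y faces (walls are zero-flux; no inlets/outlets north/south)
    for (int j = 1; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) {
        if (!(cm[CI(i, j - 1)] && cm[CI(i, j)])) continue;
        const double vf = V(i, j);
        double up, dn, upup;
        if (vf >= 0) {
          up = Y[CI(i, j - 1)]; dn = Y[CI(i, j)];
          upup = (j >= 2 && cm[CI(i, j - 2)]) ? Y[CI(i, j - 2)] : up;
        } else {
          up = Y[CI(i, j)]; dn = Y[CI(i, j - 1)];
          upup = (j + 1 < ny && cm[CI(i, j + 1)]) ? Y[CI(i, j + 1)] : up;
        }
        const double dgrad = dn - up;
        double yf = up;
        if (std::fabs(dgrad) > 1e-300) {
          const double r = (up - upup) / dgrad;
          yf = up + 0.5 * vanleer(r) * dgrad;
        }
        const double flux = vf * yf - D * (Y[CI(i, j)] - Y[CI(i, j - 1)]) / h;
        rate[CI(i, j - 1)] -= flux / h;
        rate[CI(i, j)] += flux / h;
      }
    }
    for (int k = 0; k < nx * ny; ++k)
      if (cm[k]) Y[k] += dt * rate[k];
    t += dt;

    if (step % check_every == 0) {
      double dy = 0.0;
      for (int k = 0; k < nx * ny; ++k) {
        const double d = std::fabs(Y[k] - y_prev[k]);
        if (!(d >= 0.0))
          stop("species march diverged (non-finite mass fraction)");
        if (d > dy) dy = d;
      }
      y_prev = Y;
      if (dy < tol_change) { converged = true; break; }
      Rcpp::checkUserInterrupt();
    }
  }
  for (int k = 0; k < nx * ny; ++k)
    if (cm[k]) {
      ymin_all = std::min(ymin_all, Y[k]);
      ymax_all = std::max(ymax_all, Y[k]);
    }

  NumericMatrix Ym(nx, ny);
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) Ym(i, j) = cm[CI(i, j)] ? Y[CI(i, j)] : NA_REAL;
  return List::create(_["Y"] = Ym, _["t"] = t, _["steps"] = step,
                      _["converged"] = converged,
                      _["ymin"] = ymin_all, _["ymax"] = ymax_all);
}
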