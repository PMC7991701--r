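// 1D pulse-wave solver core.
//
// Space discretisation: each (sub)segment carries a uniform grid; the
// interior is advanced with the two-step (Richtmyer) Lax-Wendroff
// scheme applied to the conservative form of the cross-sectionally
// averaged mass/momentum system
//   dA/dt + dQ/dx = 0
//   dQ/dt + d(alpha Q^2/A + beta A^{3/2} / (3 rho))/dx = -K_R Q/A
// closed by the elastic tube law P = beta (sqrt(A) - sqrt(A0)).
//
// Boundaries (inflow, junctions, RCR terminals, clamps, stenosis
// interfaces) are coupled each step through the outgoing Riemann
// invariants W = u +/- 4(c - c0), extrapolated along the outgoing
// characteristic, and a per-coupling Newton solve.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <cstring>

using namespace Rcpp;

namespace {

struct Segment {
  int off;      // global index of first node
  int n;        // number of nodes
  double dx;
  double A0, beta, alpha, KR;
  double k;     // c = k * A^{1/4}
  double c0;
};

struct Coupling {
  int type;                 // 0 junction, 1 terminal, 2 clamp, 3 stenosis
  std::vector<int> seg;     // segment indices
  std::vector<int> side;    // 0 proximal, 1 distal
  std::vector<double> par;  // terminal: R1,R2,C,Pv ; stenosis: a,b,e
  int state_idx;            // index into Pc (terminal) or Qprev (stenosis)
};

struct Model {
  std::vector<Segment> segs;
  std::vector<Coupling> cpl;
  int N;
  double rho, cfl;
  double q_mean, T, Ts, ramp_cycles;
  int inflow_seg;
};

inline double wavec(const Segment& s, double A) {
  return s.k * std::sqrt(std::sqrt(A));
}
inline double ptube(const Segment& s, double A) {
  return s.beta * (std::sqrt(A) - std::sqrt(s.A0));
}

// inflow: half-sine systole, zero diastole, mean = q_mean
inline double inflow_at(const Model& m, double t) {
  double tau = t - m.T * std::floor(t / m.T);
  double q = 0.0;
  if (tau < m.Ts) {
    double qpk = m.q_mean * m.T * M_PI / (2.0 * m.Ts);
    q = qpk * std::sin(M_PI * tau / m.Ts);
  }
  if (m.ramp_cycles > 0 && t < m.ramp_cycles * m.T)
    q *= t / (m.ramp_cycles * m.T);
  return q;
}

// outgoing invariant extrapolated to the foot of the characteristic
double extrap_W(const Model& m, const Segment& s,
                const double* A, const double* Q, int side, double dt) {
  if (side == 1) {                       // distal end: W_f = u + 4(c - c0)
    int i1 = s.off + s.n - 1, i0 = i1 - 1;
    double u1 = Q[i1] / A[i1], u0 = Q[i0] / A[i0];
    double w1 = u1 + 4.0 * (wavec(s, A[i1]) - s.c0);
    double w0 = u0 + 4.0 * (wavec(s, A[i0]) - s.c0);
    double lam = u1 + wavec(s, A[i1]);
    double foot = s.dx - lam * dt;       // position in [x_{n-2}, x_{n-1}]
    if (foot < 0) foot = 0; else if (foot > s.dx) foot = s.dx;
    return w0 + (w1 - w0) * foot / s.dx;
  } else {                               // proximal end: W_b = u - 4(c - c0)
    int i0 = s.off, i1 = i0 + 1;
    double u0 = Q[i0] / A[i0], u1 = Q[i1] / A[i1];
    double w0 = u0 - 4.0 * (wavec(s, A[i0]) - s.c0);
    double w1 = u1 - 4.0 * (wavec(s, A[i1]) - s.c0);
    double lam = u0 - wavec(s, A[i0]);   // negative
    double foot = -lam * dt;             // distance from node 0
    if (foot < 0) foot = 0; else if (foot > s.dx) foot = s.dx;
    return w0 + (w1 - w0) * foot / s.dx;
  }
}

// dense Gaussian elimination with partial pivoting (tiny systems)
bool solve_dense(int n, double* Jm, double* r) {
  for (int col = 0; col < n; ++col) {
    int piv = col;
    double best = std::fabs(Jm[col * n + col]);
    for (int row = col + 1; row < n; ++row) {
      double v = std::fabs(Jm[row * n + col]);
      if (v > best) { best = v; piv = row; }
    }
    if (best < 1e-300) return false;
    if (piv != col) {
      for (int k = 0; k < n; ++k) std::swap(Jm[col * n + k], Jm[piv * n + k]);
      std::swap(r[col], r[piv]);
    }
    for (int row = col + 1; row < n; ++row) {
      double f = Jm[row * n + col] / Jm[col * n + col];
      if (f == 0.0) continue;
      for (int k = col; k < n; ++k) Jm[row * n + k] -= f * Jm[col * n + k];
      r[row] -= f * r[col];
    }
  }
  for (int row = n - 1; row >= 0; --row) {
    double v = r[row];
    for (int k = row + 1; k < n; ++k) v -= Jm[row * n + k] * r[k];
    r[row] = v / Jm[row * n + row];
  }
  return true;
}

void solver_fail(const char* what, int seg, double t) {
  stop("1D solver failure (%s) at segment index %d, t = %.6f s",
       what, seg + 1, t);
}

// inflow boundary: prescribed Q, area from the backward invariant
void solve_inflow(const Model& m, const Segment& s, double Qin, double Wb,
                  double& Ab, double& Qb, double t) {
  double A = Ab;
  for (int it = 0; it < 60; ++it) {
    double f = Qin / A - 4.0 * (wavec(s, A) - s.c0) - Wb;
    double df = -Qin / (A * A) - wavec(s, A) / A;
    double step = f / df;
    if (A - step <= 0) step = A / 2;
    A -= step;
    if (std::fabs(step) < 1e-14 * s.A0 + 1e-16) break;
  }
  if (!std::isfinite(A) || A <= 0) solver_fail("inflow", m.inflow_seg, t);
  Ab = A; Qb = Qin;
}

// RCR terminal at a distal end; backward-Euler compliance update
void solve_terminal(const Model& m, const Segment& s, const Coupling& c,
                    double Wf, double dt, double& Ab, double& Qb,
                    double& Pc, double t) {
  double R1 = c.par[0], R2 = c.par[1], Cc = c.par[2], Pv = c.par[3];
  double den = 1.0 + dt / (R2 * Cc);
  double A = Ab, Q = Qb;
  for (int it = 0; it < 60; ++it) {
    double cA = wavec(s, A);
    double Pcn = (Pc + (dt / Cc) * (Q + Pv / R2)) / den;
    double g1 = Q / A + 4.0 * (cA - s.c0) - Wf;
    double g2 = ptube(s, A) - R1 * Q - Pcn;
    double a11 = -Q / (A * A) + cA / A;
    double a12 = 1.0 / A;
    double a21 = s.beta / (2.0 * std::sqrt(A));
    double a22 = -R1 - (dt / Cc) / den;
    double det = a11 * a22 - a12 * a21;
    double dA = (g1 * a22 - g2 * a12) / det;
    double dQ = (a11 * g2 - a21 * g1) / det;
    if (A - dA <= 0) dA = A / 2;
    A -= dA; Q -= dQ;
    if (std::fabs(dA) < 1e-13 * s.A0 && std::fabs(dQ) < 1e-11) break;
  }
  if (!std::isfinite(A) || A <= 0 || !std::isfinite(Q))
    solver_fail("terminal", c.seg[0], t);
  Ab = A; Qb = Q;
  Pc = (Pc + (dt / Cc) * (Q + Pv / R2)) / den;
}

// m-way junction: per-branch characteristic, mass conservation and
// continuity of total pressure P + rho u^2 / 2
double solve_junction(const Model& m, const Coupling& c,
                      const std::vector<double>& W,
                      double* Ab, double* Qb, double t) {
  int nb = (int)c.seg.size();
  int n = 2 * nb;
  double Jm[64], r[64], x[16];
  for (int j = 0; j < nb; ++j) { x[2 * j] = Ab[j]; x[2 * j + 1] = Qb[j]; }
  double rho = m.rho;
  for (int it = 0; it < 80; ++it) {
    std::memset(Jm, 0, sizeof(double) * n * n);
    // residuals: rows 0..nb-1 characteristics, nb mass, nb+1.. pressure
    for (int j = 0; j < nb; ++j) {
      const Segment& s = m.segs[c.seg[j]];
      double A = x[2 * j], Q = x[2 * j + 1];
      double sg = c.side[j] == 1 ? 1.0 : -1.0;
      double cA = wavec(s, A);
      r[j] = Q / A + 4.0 * sg * (cA - s.c0) - W[j];
      Jm[j * n + 2 * j] = -Q / (A * A) + sg * cA / A;
      Jm[j * n + 2 * j + 1] = 1.0 / A;
    }
    for (int j = 0; j < nb; ++j) {
      double sg = c.side[j] == 1 ? 1.0 : -1.0;
      Jm[nb * n + 2 * j + 1] = sg;
    }
    double mass = 0;
    for (int j = 0; j < nb; ++j)
      mass += (c.side[j] == 1 ? 1.0 : -1.0) * x[2 * j + 1];
    r[nb] = mass;
    const Segment& s0 = m.segs[c.seg[0]];
    double A0_ = x[0], Q0_ = x[1], u0 = Q0_ / A0_;
    double pt0 = ptube(s0, A0_) + 0.5 * rho * u0 * u0;
    double dpt0_dA = s0.beta / (2.0 * std::sqrt(A0_)) - rho * u0 * u0 / A0_;
    double dpt0_dQ = rho * u0 / A0_;
    for (int j = 1; j < nb; ++j) {
      const Segment& s = m.segs[c.seg[j]];
      int row = nb + j;
      double A = x[2 * j], Q = x[2 * j + 1], u = Q / A;
      r[row] = pt0 - (ptube(s, A) + 0.5 * rho * u * u);
      Jm[row * n + 0] = dpt0_dA;
      Jm[row * n + 1] = dpt0_dQ;
      Jm[row * n + 2 * j] = -(s.beta / (2.0 * std::sqrt(A)) - rho * u * u / A);
      Jm[row * n + 2 * j + 1] = -rho * u / A;
    }
    double res = 0;
    for (int j = 0; j < nb; ++j)
      res = std::max(res, std::fabs(r[j]) / m.segs[c.seg[j]].c0);
    res = std::max(res, std::fabs(r[nb]));
    for (int j = 1; j < nb; ++j)
      res = std::max(res, std::fabs(r[nb + j]) /
                            (m.segs[c.seg[0]].beta *
                             std::sqrt(m.segs[c.seg[0]].A0)));
    if (res < 1e-11 && it > 0) break;
    if (!solve_dense(n, Jm, r)) solver_fail("junction (singular)", c.seg[0], t);
    for (int j = 0; j < nb; ++j) {
      double dA = r[2 * j], dQ = r[2 * j + 1];
      if (x[2 * j] - dA <= 0) dA = x[2 * j] / 2;
      x[2 * j] -= dA;
      x[2 * j + 1] -= dQ;
    }
  }
  double defect = 0;
  for (int j = 0; j < nb; ++j) {
    if (!std::isfinite(x[2 * j]) || x[2 * j] <= 0)
      solver_fail("junction", c.seg[j], t);
    Ab[j] = x[2 * j]; Qb[j] = x[2 * j + 1];
    defect += (c.side[j] == 1 ? 1.0 : -1.0) * Qb[j];
  }
  return std::fabs(defect);
}

// lumped stenosis interface between the distal face of the left
// sub-segment and the proximal face of the right one; the pressure
// jump equals the three-term pressure-loss element at the interface
// flow, mass is conserved exactly
void solve_stenosis(const Model& m, const Coupling& c,
                    double WfL, double WbR, double dt,
                    double& AL, double& QL, double& AR, double& QR,
                    double& Qprev, double t) {
  const Segment& sL = m.segs[c.seg[0]];
  const Segment& sR = m.segs[c.seg[1]];
  double a = c.par[0], b = c.par[1], e = c.par[2];
  double rho = m.rho;
  double x[3] = { AL, AR, QL };   // common flow
  for (int it = 0; it < 80; ++it) {
    double A1 = x[0], A2 = x[1], Q = x[2];
    double u1 = Q / A1, u2 = Q / A2;
    double c1 = wavec(sL, A1), c2 = wavec(sR, A2);
    double dP = a * Q + b * Q * std::fabs(Q) + e * (Q - Qprev) / dt;
    double g0 = u1 + 4.0 * (c1 - sL.c0) - WfL;
    double g1 = u2 - 4.0 * (c2 - sR.c0) - WbR;
    double g2 = ptube(sL, A1) + 0.5 * rho * u1 * u1
              - ptube(sR, A2) - 0.5 * rho * u2 * u2 - dP;
    double res = std::max(std::fabs(g0) / sL.c0, std::fabs(g1) / sR.c0);
    res = std::max(res, std::fabs(g2) / (sL.beta * std::sqrt(sL.A0)));
    if (res < 1e-11 && it > 0) break;
    double Jm[9], r[3];
    Jm[0] = -Q / (A1 * A1) + c1 / A1; Jm[1] = 0.0;  Jm[2] = 1.0 / A1;
    Jm[3] = 0.0; Jm[4] = -Q / (A2 * A2) - c2 / A2;  Jm[5] = 1.0 / A2;
    Jm[6] = sL.beta / (2.0 * std::sqrt(A1)) - rho * u1 * u1 / A1;
    Jm[7] = -(sR.beta / (2.0 * std::sqrt(A2)) - rho * u2 * u2 / A2);
    Jm[8] = rho * u1 / A1 - rho * u2 / A2
            - (a + 2.0 * b * std::fabs(Q) + e / dt);
    r[0] = g0; r[1] = g1; r[2] = g2;
    if (!solve_dense(3, Jm, r)) solver_fail("stenosis (singular)", c.seg[0], t);
    if (x[0] - r[0] <= 0) r[0] = x[0] / 2;
    if (x[1] - r[1] <= 0) r[1] = x[1] / 2;
    x[0] -= r[0]; x[1] -= r[1]; x[2] -= r[2];
  }
  if (!std::isfinite(x[0]) || x[0] <= 0 || !std::isfinite(x[1]) || x[1] <= 0)
    solver_fail("stenosis", c.seg[0], t);
  AL = x[0]; AR = x[1]; QL = QR = x[2];
  Qprev = x[2];
}

Model build_model(List model) {
  Model m;
  IntegerVector off = model["offset"], nn = model["n_nodes"];
  NumericVector dx = model["dx"], A0 = model["A0"], beta = model["beta"],
                alpha = model["alpha"], KR = model["K_R"];
  m.rho = as<double>(model["rho"]);
  m.cfl = as<double>(model["cfl"]);
  m.q_mean = as<double>(model["q_mean"]);
  m.T = as<double>(model["period"]);
  m.Ts = as<double>(model["systole"]);
  m.ramp_cycles = as<double>(model["ramp_cycles"]);
  m.inflow_seg = as<int>(model["inflow_seg"]) - 1;
  int ns = off.size();
  m.segs.resize(ns);
  m.N = 0;
  for (int i = 0; i < ns; ++i) {
    Segment& s = m.segs[i];
    s.off = off[i] - 1; s.n = nn[i]; s.dx = dx[i];
    s.A0 = A0[i]; s.beta = beta[i]; s.alpha = alpha[i]; s.KR = KR[i];
    s.k = std::sqrt(s.beta / (2.0 * m.rho));
    s.c0 = wavec(s, s.A0);
    m.N = std::max(m.N, s.off + s.n);
  }
  List cpl = model["couplings"];
  for (int i = 0; i < cpl.size(); ++i) {
    List ci = cpl[i];
    Coupling c;
    c.type = as<int>(ci["type"]);
    IntegerVector sg = ci["seg"], sd = ci["side"];
    c.seg.assign(sg.begin(), sg.end());
    for (auto& v : c.seg) v -= 1;
    c.side.assign(sd.begin(), sd.end());
    NumericVector par = ci["par"];
    c.par.assign(par.begin(), par.end());
    c.state_idx = as<int>(ci["state_idx"]) - 1;
    m.cpl.push_back(c);
  }
  return m;
}

} // namespace

// [[Rcpp::export(name = ".cpp_run_cycles")]]
List cpp_run_cycles(List model, List state, int n_cycles) {
  Model m = build_model(model);
  NumericVector A_in = state["A"], Q_in = state["Q"],
                Pc_in = state["Pc"], Qp_in = state["Qprev"];
  double t = as<double>(state["t"]);
  int N = m.N;
  std::vector<double> A(A_in.begin(), A_in.end()),
      Q(Q_in.begin(), Q_in.end()),
      Pc(Pc_in.begin(), Pc_in.end()),
      Qprev(Qp_in.begin(), Qp_in.end());
  std::vector<double> F2(N), S(N), Ah(N), Qh(N), F2h(N), Sh(N),
      An(N), Qn(N), meanP(N), meanQ(N);
  double mass_defect_max = 0, dt_min = 1e30, dt_max = 0;
  long n_steps = 0;

  for (int cyc = 0; cyc < n_cycles; ++cyc) {
    std::fill(meanP.begin(), meanP.end(), 0.0);
    std::fill(meanQ.begin(), meanQ.end(), 0.0);
    double t_end = t + m.T, t_accum = 0;
    while (t < t_end - 1e-12) {
      // global CFL time step
      double dt = 1e30;
      for (const Segment& s : m.segs) {
        double lam = 0;
        for (int i = s.off; i < s.off + s.n; ++i) {
          double v = std::fabs(Q[i] / A[i]) + wavec(s, A[i]);
          if (v > lam) lam = v;
        }
        double cand = m.cfl * s.dx / lam;
        if (cand < dt) dt = cand;
      }
      if (t + dt > t_end) dt = t_end - t;
      if (!(dt > 0) || !std::isfinite(dt)) stop("CFL step collapsed");
      dt_min = std::min(dt_min, dt); dt_max = std::max(dt_max, dt);

      // fluxes and sources
      for (const Segment& s : m.segs) {
        double cb = s.beta / (3.0 * m.rho);
        for (int i = s.off; i < s.off + s.n; ++i) {
          F2[i] = s.alpha * Q[i] * Q[i] / A[i] + cb * A[i] * std::sqrt(A[i]);
          S[i] = -s.KR * Q[i] / A[i];
        }
      }
      // Richtmyer half step (values at i+1/2 stored at left index)
      for (const Segment& s : m.segs) {
        double lam = dt / (2.0 * s.dx);
        double cb = s.beta / (3.0 * m.rho);
        for (int i = s.off; i < s.off + s.n - 1; ++i) {
          Ah[i] = 0.5 * (A[i] + A[i + 1]) - lam * (Q[i + 1] - Q[i]);
          Qh[i] = 0.5 * (Q[i] + Q[i + 1]) - lam * (F2[i + 1] - F2[i])
                  + 0.25 * dt * (S[i] + S[i + 1]);
          if (Ah[i] <= 0) solver_fail("negative area",
                                      int(&s - &m.segs[0]), t);
          F2h[i] = s.alpha * Qh[i] * Qh[i] / Ah[i]
                   + cb * Ah[i] * std::sqrt(Ah[i]);
          Sh[i] = -s.KR * Qh[i] / Ah[i];
        }
      }
      // full step: interior nodes
      for (const Segment& s : m.segs) {
        double lam = dt / s.dx;
        for (int i = s.off + 1; i < s.off + s.n - 1; ++i) {
          An[i] = A[i] - lam * (Qh[i] - Qh[i - 1]);
          Qn[i] = Q[i] - lam * (F2h[i] - F2h[i - 1])
                  + 0.5 * dt * (Sh[i] + Sh[i - 1]);
          if (An[i] <= 0 || !std::isfinite(An[i]) || !std::isfinite(Qn[i]))
            solver_fail("negative area/NaN", int(&s - &m.segs[0]), t);
        }
      }
      // inflow boundary
      {
        const Segment& s = m.segs[m.inflow_seg];
        double Wb = extrap_W(m, s, A.data(), Q.data(), 0, dt);
        double Ab = A[s.off], Qb = Q[s.off];
        solve_inflow(m, s, inflow_at(m, t + dt), Wb, Ab, Qb, t);
        An[s.off] = Ab; Qn[s.off] = Qb;
      }
      // couplings
      for (Coupling& c : m.cpl) {
        int nb = (int)c.seg.size();
        std::vector<double> W(nb);
        double Ab[4], Qb[4];
        for (int j = 0; j < nb; ++j) {
          const Segment& s = m.segs[c.seg[j]];
          W[j] = extrap_W(m, s, A.data(), Q.data(), c.side[j], dt);
          int node = c.side[j] == 1 ? s.off + s.n - 1 : s.off;
          Ab[j] = A[node]; Qb[j] = Q[node];
        }
        if (c.type == 0) {
          double d = solve_junction(m, c, W, Ab, Qb, t);
          if (d > mass_defect_max) mass_defect_max = d;
        } else if (c.type == 1) {
          solve_terminal(m, m.segs[c.seg[0]], c, W[0], dt,
                         Ab[0], Qb[0], Pc[c.state_idx], t);
        } else if (c.type == 2) {
          // clamp: zero flow on both faces, area from the invariant
          for (int j = 0; j < nb; ++j) {
            const Segment& s = m.segs[c.seg[j]];
            double cA = c.side[j] == 1 ? s.c0 + W[j] / 4.0
                                       : s.c0 - W[j] / 4.0;
            if (cA <= 0) solver_fail("clamp", c.seg[j], t);
            double Aj = std::pow(cA / s.k, 4.0);
            Ab[j] = Aj; Qb[j] = 0.0;
          }
        } else {
          solve_stenosis(m, c, W[0], W[1], dt, Ab[0], Qb[0], Ab[1], Qb[1],
                         Qprev[c.state_idx], t);
        }
        for (int j = 0; j < nb; ++j) {
          const Segment& s = m.segs[c.seg[j]];
          int node = c.side[j] == 1 ? s.off + s.n - 1 : s.off;
          An[node] = Ab[j]; Qn[node] = Qb[j];
        }
      }
      A.swap(An); Q.swap(Qn);
      t += dt; t_accum += dt; ++n_steps;
      for (const Segment& s : m.segs) {
        for (int i = s.off; i < s.off + s.n; ++i) {
          meanP[i] += ptube(s, A[i]) * dt;
          meanQ[i] += Q[i] * dt;
        }
      }
    }
    for (int i = 0; i < N; ++i) { meanP[i] /= t_accum; meanQ[i] /= t_accum; }
  }

  return List::create(
    _["A"] = NumericVector(A.begin(), A.end()),
    _["Q"] = NumericVector(Q.begin(), Q.end()),
    _["Pc"] = NumericVector(Pc.begin(), Pc.end()),
    _["Qprev"] = NumericVector(Qprev.begin(), Qprev.end()),
    _["t"] = t,
    _["mean_P"] = NumericVector(meanP.begin(), meanP.end()),
    _["mean_Q"] = NumericVector(meanQ.begin(), meanQ.end()),
    _["mass_defect_max"] = mass_defect_max,
    _["dt_min"] = dt_min,
    _["dt_max"] = dt_max,
    _["n_steps"] = (double)n_steps);
}
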