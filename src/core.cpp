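// Coupled ventilation + transport core for the whole-lung washout model.
//
// The airway network is a binary tree of rigid pipes whose terminal pipes
// each feed one compliant trumpet lobule.  Both solvers below exploit the
// tree structure for O(N) direct solution:
//  * ventilation: backward-Euler step of the lumped-parameter DAE, damped
//    Newton iteration; the Newton linear system (diagonal lobule stiffness
//    plus the resistive-network coupling) is solved by a two-pass
//    admittance sweep over the tree.
//  * transport: operator-split finite volumes.  Advection is explicit
//    second-order MUSCL (minmod limiter), sub-stepped so every face
//    Courant number stays below ~0.45, with bifurcations acting as
//    zero-volume perfect mixers; diffusion is theta-implicit central
//    differences, whose per-airway tridiagonal blocks are Schur-eliminated
//    onto the junction unknowns and the reduced tree system solved
//    leaf-to-root.  A one-step implicit-upwind variant is retained for
//    comparison.
// The discrete scheme preserves spatially constant concentrations exactly
// (face flows are built from the same discrete volume changes that the
// ventilation step produced) and conserves tracer mass to round-off.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

struct LungModel {
  // ---- topology ----
  int np = 0, nlb = 0, ntc = 0;
  std::vector<int> parent, child1, child2, termLob; // per pipe (-1 = none)
  std::vector<int> lobPipe;                          // per lobule: terminal pipe
  // ---- pipe geometry / resistance ----
  std::vector<double> Rp, Sp, dpipe, lenp, hpipe;
  std::vector<int> ncell, cellOff;                   // transport cells per pipe
  int nPipeCells = 0, nCells = 0;
  std::vector<int> tOff;                             // trumpet cell offsets
  // ---- lobule parameters ----
  std::vector<double> V0, gam, pelCoef, Reff, St, Llb, p2c, Vmin;
  double n1 = 20, n2 = 2;
  // trumpet face tables, size nlb*(ntc+1)
  std::vector<double> tXf, tA1, tA2, tXn1, tXn2, tDloc, tSduct;
  bool ductTransport = true;
  // ---- gas / numerics ----
  double mu = 1.8e-5, rho = 1.2, Dmol = 2.2e-5;
  bool taylor = true;
  double theta = 0.5, newtonTol = 1e-10;
  int newtonMaxit = 50;
  double qScale = 1e-4, pScale = 1500.0;
  // ---- state ----
  double t = 0.0, ppl = 0.0;
  std::vector<double> V, dV, p1, p1prev, qPipe, conc, cJ;
  double cumMouthFlux = 0.0;          // integral of tracer flux at the mouth
  // ---- work arrays ----
  std::vector<double> wa, wb, wc, wr, wsP, wsD;      // tridiag work
  std::vector<double> solS, solP, solD;              // per-cell solution cols
  std::vector<double> AJ, BJ, GJ1, GJ2, RJ, cJnew;
  std::vector<double> faceQ, faceG, volNew, volOld;  // per-step geometry
  std::vector<double> lobA, lobB;                    // ventilation sweeps
  std::vector<double> psi, qsub;
  // cell geometry for slope reconstruction (center-face and center-center)
  std::vector<double> cdL, cdR, dcm, dcp;
  int advScheme = 0;            // 0 = explicit MUSCL split, 1 = implicit upwind
  double cflMax = 0.45;         // face-Courant bound per advection substep

  int tface(int k, int j) const { return k * (ntc + 1) + j; }

  double pel(int i, double Vi) const {
    return pelCoef[i] * expm1(gam[i] * (Vi - V0[i]));
  }
  double pelPrime(int i, double Vi) const {
    return pelCoef[i] * gam[i] * std::exp(gam[i] * (Vi - V0[i]));
  }
  double p1ofV(int k, double Vk) const {
    double l = Llb[k];
    return (Vk - p2c[k] * tA2[tface(k, ntc)] - St[k] * l) / tA1[tface(k, ntc)];
  }

  // ---- ventilation -------------------------------------------------------
  // residual of the backward-Euler step; fills qsub (pipe flows) and psi
  // (cumulative resistive pressure drop at each pipe's distal node)
  double residual(const std::vector<double>& Vn, const std::vector<double>& Vtry,
                  double pplTry, double Qin, double dt,
                  std::vector<double>& G, double& C) {
    for (int i = np - 1; i >= 0; --i) {
      double q = 0.0;
      if (termLob[i] >= 0) q += (Vtry[termLob[i]] - Vn[termLob[i]]) / dt;
      else { q += qsub[child1[i]] + qsub[child2[i]]; }
      qsub[i] = q;
    }
    for (int i = 0; i < np; ++i) {
      double up = (parent[i] >= 0) ? psi[parent[i]] : 0.0;
      psi[i] = up + Rp[i] * qsub[i];
    }
    double maxg = 0.0, sumQ = 0.0;
    for (int k = 0; k < nlb; ++k) {
      double Q = (Vtry[k] - Vn[k]) / dt;
      sumQ += Q;
      G[k] = pel(k, Vtry[k]) + Reff[k] * Q + psi[lobPipe[k]] + pplTry;
      double a = std::fabs(G[k]);
      if (a > maxg) maxg = a;
    }
    C = sumQ - Qin;
    double err = maxg / pScale;
    double ec = std::fabs(C) / qScale;
    return err > ec ? err : ec;
  }

  // solve (D + M/dt) x = b via two-pass tree sweep; D diagonal per lobule,
  // M the resistive path-overlap matrix of the pipe network
  void solveTree(const std::vector<double>& Dd, const std::vector<double>& b,
                 double dt, std::vector<double>& x) {
    // upward: subtree flow q = a + bcoef * psi_proximal
    for (int i = np - 1; i >= 0; --i) {
      double a, bc;
      if (termLob[i] >= 0) {
        int k = termLob[i];
        a = b[k] / Dd[k]; bc = -1.0 / Dd[k];
      } else {
        a = lobA[child1[i]] + lobA[child2[i]];
        bc = lobB[child1[i]] + lobB[child2[i]];
      }
      double den = 1.0 - bc * Rp[i] / dt;
      lobA[i] = a / den; lobB[i] = bc / den;
    }
    // downward: propagate psi, evaluate leaves
    for (int i = 0; i < np; ++i) {
      double up = (parent[i] >= 0) ? psi[parent[i]] : 0.0;
      double q = lobA[i] + lobB[i] * up;
      psi[i] = up + (Rp[i] / dt) * q;
      if (termLob[i] >= 0) {
        int k = termLob[i];
        x[k] = (b[k] - psi[i]) / Dd[k];
      }
    }
  }

  // one backward-Euler ventilation step; returns Newton iterations used,
  // or -1 on failure
  int ventStep(double Qin, double dt) {
    std::vector<double> Vn = V;
    std::vector<double> Vtry = V, G(nlb), Dd(nlb), y(nlb), w(nlb), ones(nlb, 1.0);
    // warm start: extrapolate the previous volume increments
    for (int k = 0; k < nlb; ++k) {
      double cand = V[k] + dV[k];
      if (cand > Vmin[k]) Vtry[k] = cand;
    }
    double pplTry = ppl;
    double C = 0.0;
    double err = residual(Vn, Vtry, pplTry, Qin, dt, G, C);
    int it = 0;
    bool dbg = std::getenv("MBWSIM_DEBUG") != nullptr;
    if (dbg) Rprintf("vent t=%g Qin=%g err0=%g C=%g\n", t, Qin, err, C);
    while (err > newtonTol && it < newtonMaxit) {
      ++it;
      for (int k = 0; k < nlb; ++k) {
        Dd[k] = pelPrime(k, Vtry[k]) + Reff[k] / dt;
        G[k] = -G[k];
      }
      solveTree(Dd, G, dt, y);
      solveTree(Dd, ones, dt, w);
      double sy = 0.0, sw = 0.0;
      for (int k = 0; k < nlb; ++k) { sy += y[k]; sw += w[k]; }
      double dp = (sy + dt * C) / sw;
      // damped update
      double lam = 1.0;
      for (int half = 0; half < 40; ++half) {
        bool ok = true;
        std::vector<double> Vc(nlb);
        for (int k = 0; k < nlb; ++k) {
          Vc[k] = Vtry[k] + lam * (y[k] - dp * w[k]);
          if (Vc[k] <= Vmin[k]) { ok = false; break; }
        }
        double pc = pplTry + lam * dp;
        double errNew = ok ? residual(Vn, Vc, pc, Qin, dt, G, C) : err + 1.0;
        if (dbg) Rprintf("  it=%d lam=%g errNew=%g dp=%g\n", it, lam,
                         ok ? errNew : -1.0, dp);
        if (ok && (errNew <= err || errNew < newtonTol)) {
          Vtry = Vc; pplTry = pc; err = errNew;
          break;
        }
        lam *= 0.5;
        if (half == 39) return -1;
      }
    }
    if (err > newtonTol) return -1;
    for (int k = 0; k < nlb; ++k) dV[k] = Vtry[k] - Vn[k];
    V = Vtry; ppl = pplTry;
    // final pipe flows for this step (residual() left qsub consistent)
    for (int i = 0; i < np; ++i) qPipe[i] = qsub[i];
    // trumpet shape update
    p1prev = p1;
    for (int k = 0; k < nlb; ++k) p1[k] = p1ofV(k, V[k]);
    return it;
  }

  // ---- transport ---------------------------------------------------------
  double dhat(double u, double d) const {
    if (!taylor) return Dmol;
    double Pe = std::fabs(u) * d / Dmol;
    return Dmol * (1.0 + Pe * Pe / 192.0);
  }

  // face flux, given left/right concentrations
  static inline double flux(double q, double g, double cL, double cR) {
    return q * (q >= 0 ? cL : cR) - g * (cR - cL);
  }

  // --- per-step geometry: face flows, conductances, cell volumes ---
  void computeStepGeometry(double dt) {
    // pipes: rigid, volumes constant
    for (int i = 0; i < np; ++i) {
      int m = ncell[i], off = cellOff[i];
      double vol = Sp[i] * hpipe[i];
      for (int k = 0; k < m; ++k) {
        volNew[off + k] = vol;
        volOld[off + k] = vol;
      }
    }
    // trumpets: cell volumes before/after the wall motion of this step
    for (int k = 0; k < nlb; ++k) {
      int off = tOff[k];
      for (int c = 0; c < ntc; ++c) {
        double dA1 = tA1[tface(k, c + 1)] - tA1[tface(k, c)];
        double dA2 = tA2[tface(k, c + 1)] - tA2[tface(k, c)];
        double dx = tXf[tface(k, c + 1)] - tXf[tface(k, c)];
        volOld[off + c] = p1prev[k] * dA1 + p2c[k] * dA2 + St[k] * dx;
        volNew[off + c] = p1[k] * dA1 + p2c[k] * dA2 + St[k] * dx;
      }
    }

    // face flows and diffusive conductances, all airways
    for (int a = 0; a < np + nlb; ++a) {
      bool isPipe = a < np;
      int m = isPipe ? ncell[a] : ntc;
      int off = isPipe ? cellOff[a] : tOff[a - np];
      for (int j = 0; j <= m; ++j) {
        double q, g;
        if (isPipe) {
          double h = hpipe[a];
          double u = qPipe[a] / Sp[a];
          double Dh = dhat(u, dpipe[a]);
          q = qPipe[a];
          double dx = (j == 0 || j == m) ? 0.5 * h : h;
          g = Sp[a] * Dh / dx;
        } else {
          int k = a - np;
          double Qt = dV[k] / dt;
          double dA1 = tA1[tface(k, j)];
          q = Qt - (p1[k] - p1prev[k]) * dA1 / dt;
          double p1m = 0.5 * (p1[k] + p1prev[k]);
          double Sf = p1m * tXn1[tface(k, j)] + p2c[k] * tXn2[tface(k, j)] + St[k];
          // axial transport cross-section: the airway-lumping (duct) law,
          // capped by the total lumen; the excess is alveolar volume that
          // holds tracer but does not carry axial flux
          double Sax = ductTransport ? std::min(tSduct[tface(k, j)], Sf) : Sf;
          double u = q / Sax;
          double Dh = dhat(u, tDloc[tface(k, j)]);
          double dx;
          if (j == 0) dx = 0.5 * (tXf[tface(k, 1)] - tXf[tface(k, 0)]);
          else if (j == m) dx = 0.5 * (tXf[tface(k, m)] - tXf[tface(k, m - 1)]);
          else dx = 0.5 * (tXf[tface(k, j + 1)] - tXf[tface(k, j - 1)]);
          g = Sax * Dh / dx;
        }
        faceQ[off + j + a] = q;   // faces stored with +a shift (m+1 per airway)
        faceG[off + j + a] = g;
      }
    }
  }

  double fq(int a, int off, int j) const { return faceQ[off + j + a]; }
  double fg(int a, int off, int j) const { return faceG[off + j + a]; }

  // theta-implicit network solve; with includeAdv = true this is the
  // one-step upwind/central theta scheme for the full equation, with
  // includeAdv = false it is the diffusion half of the operator split
  // (advection already applied explicitly, geometry already at end-of-step)
  void implicitPhase(double dt, double QinStep, bool includeAdv) {
    const double th = theta;
    const std::vector<double>& vOld = includeAdv ? volOld : volNew;
    double mouthFluxNew = 0.0, mouthFluxOld = 0.0;
    auto qv = [&](int a, int off, int j) {
      return includeAdv ? faceQ[off + j + a] : 0.0;
    };

    for (int a = 0; a < np + nlb; ++a) {
      bool isPipe = a < np;
      int m = isPipe ? ncell[a] : ntc;
      int off = isPipe ? cellOff[a] : tOff[a - np];
      // old junction concentrations at the two ends
      double cJp_old, cJd_old = 0.0;
      bool hasProxJ, hasDistJ;
      if (isPipe) {
        hasProxJ = parent[a] >= 0;
        cJp_old = hasProxJ ? cJ[parent[a]] : 0.0;
        hasDistJ = true;
        cJd_old = cJ[a];
      } else {
        hasProxJ = true;
        cJp_old = cJ[lobPipe[a - np]];
        hasDistJ = false;
      }
      double cpl = 0.0, cdl = 0.0;  // coupling coefficients to end junctions
      for (int k = 0; k < m; ++k) {
        double diag = volNew[off + k], lo = 0.0, up = 0.0;
        double rhs = vOld[off + k] * conc[off + k];
        // left face k
        double q = qv(a, off, k), g = fg(a, off, k);
        double FoldL;
        if (k > 0) {
          lo  -= dt * th * ((q >= 0 ? q : 0) + g);
          diag -= dt * th * ((q < 0 ? q : 0) - g);
          FoldL = flux(q, g, conc[off + k - 1], conc[off + k]);
        } else if (isPipe && parent[a] < 0) {
          // mouth boundary of the trachea
          if (QinStep > 0) {            // inspiration: pure O2 feed, c = 0
            diag += dt * th * g - dt * th * (q < 0 ? q : 0);
            FoldL = flux(q, g, 0.0, conc[off]);
          } else {                       // expiration: advective outflow only
            diag -= dt * th * q;
            FoldL = q * conc[off];
          }
        } else {
          // proximal junction
          cpl  -= dt * th * ((q >= 0 ? q : 0) + g);
          diag -= dt * th * ((q < 0 ? q : 0) - g);
          FoldL = flux(q, g, cJp_old, conc[off]);
        }
        // right face k+1
        q = qv(a, off, k + 1); g = fg(a, off, k + 1);
        double FoldR;
        if (k < m - 1) {
          diag += dt * th * ((q >= 0 ? q : 0) + g);
          up   += dt * th * ((q < 0 ? q : 0) - g);
          FoldR = flux(q, g, conc[off + k], conc[off + k + 1]);
        } else if (!isPipe) {
          FoldR = 0.0;                   // closed distal trumpet end
        } else {
          // distal junction
          diag += dt * th * ((q >= 0 ? q : 0) + g);
          cdl  += dt * th * ((q < 0 ? q : 0) - g);
          FoldR = flux(q, g, conc[off + m - 1], cJd_old);
        }
        rhs -= dt * (1.0 - th) * (FoldR - FoldL);
        wa[k] = lo; wb[k] = diag; wc[k] = up; wr[k] = rhs;
        wsP[k] = 0.0; wsD[k] = 0.0;
      }
      wsP[0] = -cpl;  // solve A x = rhs - cpl*e0*cJp - cdl*e_last*cJd
      wsD[m - 1] = -cdl;
      // Thomas elimination with 3 right-hand sides
      for (int k = 1; k < m; ++k) {
        double wfac = wa[k] / wb[k - 1];
        wb[k] -= wfac * wc[k - 1];
        wr[k] -= wfac * wr[k - 1];
        wsP[k] -= wfac * wsP[k - 1];
        wsD[k] -= wfac * wsD[k - 1];
      }
      solS[off + m - 1] = wr[m - 1] / wb[m - 1];
      solP[off + m - 1] = wsP[m - 1] / wb[m - 1];
      solD[off + m - 1] = wsD[m - 1] / wb[m - 1];
      for (int k = m - 2; k >= 0; --k) {
        solS[off + k] = (wr[k] - wc[k] * solS[off + k + 1]) / wb[k];
        solP[off + k] = (wsP[k] - wc[k] * solP[off + k + 1]) / wb[k];
        solD[off + k] = (wsD[k] - wc[k] * solD[off + k + 1]) / wb[k];
      }
      // cells(a) = solS + solP * cJprox + solD * cJdist
    }

    // --- junction equations, reduced onto the junction tree ---
    for (int i = 0; i < np; ++i) {
      int m = ncell[i], off = cellOff[i];
      double qp = qv(i, off, m), gp = fg(i, off, m);
      double aJJ = (qp < 0 ? qp : 0) - gp;
      double aLast = (qp >= 0 ? qp : 0) + gp;
      double RJold = flux(qp, gp, conc[off + m - 1], cJ[i]);
      double A = aJJ, B = 0.0, G1 = 0.0, G2 = 0.0, R = -RJold * (1.0 - th) / th;
      // parent pipe substitution: cLast = S + P cJprox + D cJ
      A += aLast * solD[off + m - 1];
      B += aLast * solP[off + m - 1];
      R -= aLast * solS[off + m - 1];
      // children
      int chA[2], nch = 0;
      if (termLob[i] >= 0) chA[nch++] = np + termLob[i];
      else { chA[nch++] = child1[i]; chA[nch++] = child2[i]; }
      for (int c = 0; c < nch; ++c) {
        int ac = chA[c];
        bool cPipe = ac < np;
        int offc = cPipe ? cellOff[ac] : tOff[ac - np];
        double qc = qv(ac, offc, 0), gc = fg(ac, offc, 0);
        double aJJc = -((qc >= 0 ? qc : 0) + gc);
        double aFirst = -((qc < 0 ? qc : 0) - gc);
        double cfOld = conc[offc];
        R += flux(qc, gc, cJ[i], cfOld) * (1.0 - th) / th;
        A += aJJc;
        // cFirst = S + P cJ(this) + D cJdist(child)
        A += aFirst * solP[offc];
        R -= aFirst * solS[offc];
        if (cPipe) {
          double gcoef = aFirst * solD[offc];
          if (c == 0) G1 = gcoef; else G2 = gcoef;
        }
      }
      AJ[i] = A; BJ[i] = B; GJ1[i] = G1; GJ2[i] = G2; RJ[i] = R;
    }
    // eliminate leaf-to-root (children have larger index)
    for (int i = np - 1; i >= 1; --i) {
      int p = parent[i];
      double g = (child1[p] == i) ? GJ1[p] : GJ2[p];
      AJ[p] -= g * BJ[i] / AJ[i];
      RJ[p] -= g * RJ[i] / AJ[i];
    }
    cJnew[0] = RJ[0] / AJ[0];
    for (int i = 1; i < np; ++i)
      cJnew[i] = (RJ[i] - BJ[i] * cJnew[parent[i]]) / AJ[i];

    // --- back-substitute cells ---
    for (int a = 0; a < np + nlb; ++a) {
      bool isPipe = a < np;
      int m = isPipe ? ncell[a] : ntc;
      int off = isPipe ? cellOff[a] : tOff[a - np];
      double cp = 0.0, cd = 0.0;
      if (isPipe) {
        cp = (parent[a] >= 0) ? cJnew[parent[a]] : 0.0;
        cd = cJnew[a];
      } else {
        cp = cJnew[lobPipe[a - np]];
      }
      for (int k = 0; k < m; ++k) {
        double cnewv = solS[off + k] + solP[off + k] * cp + solD[off + k] * cd;
        solS[off + k] = cnewv;   // reuse buffer for the new field
      }
    }
    // mouth flux (theta-weighted), before overwriting old concentrations
    {
      int off = cellOff[0];
      double q = qv(0, off, 0), g = fg(0, off, 0);
      if (QinStep > 0) {
        mouthFluxNew = flux(q, g, 0.0, solS[off]);
        mouthFluxOld = flux(q, g, 0.0, conc[off]);
      } else {
        mouthFluxNew = q * solS[off];
        mouthFluxOld = q * conc[off];
      }
    }
    cumMouthFlux += dt * (th * mouthFluxNew + (1.0 - th) * mouthFluxOld);
    for (int c = 0; c < nCells; ++c) conc[c] = solS[c];
    for (int i = 0; i < np; ++i) cJ[i] = cJnew[i];
  }

  // explicit flux-limited advection (minmod MUSCL), sub-stepped so that
  // every face Courant number stays below cflMax; junctions are treated
  // as zero-volume perfect mixers of their instantaneous inflows, which
  // is conservative and keeps concentrations within bounds
  void advectPhase(double dt, double QinStep) {
    (void)QinStep;
    double maxrate = 0.0;
    for (int a = 0; a < np + nlb; ++a) {
      bool isPipe = a < np;
      int m = isPipe ? ncell[a] : ntc;
      int off = isPipe ? cellOff[a] : tOff[a - np];
      for (int k = 0; k < m; ++k) {
        double ql = faceQ[off + k + a], qr = faceQ[off + k + 1 + a];
        double vmin = std::min(volOld[off + k], volNew[off + k]);
        double rate = (std::max(qr, 0.0) + std::max(-ql, 0.0)) / vmin;
        if (rate > maxrate) maxrate = rate;
      }
    }
    int nsub = std::max(1, (int)std::ceil(dt * maxrate / cflMax));
    double dta = dt / nsub;
    for (int s = 0; s < nsub; ++s) {
      // junction mixing values from the current field
      for (int i = 0; i < np; ++i) {
        int m = ncell[i], off = cellOff[i];
        double qp = faceQ[off + m + i];
        double fin = std::max(qp, 0.0) * conc[off + m - 1];
        double vin = std::max(qp, 0.0);
        if (termLob[i] >= 0) {
          int offc = tOff[termLob[i]];
          double qc = faceQ[offc + np + termLob[i]];
          fin += std::max(-qc, 0.0) * conc[offc];
          vin += std::max(-qc, 0.0);
        } else {
          int c1 = child1[i], c2 = child2[i];
          double q1 = faceQ[cellOff[c1] + c1], q2 = faceQ[cellOff[c2] + c2];
          fin += std::max(-q1, 0.0) * conc[cellOff[c1]] +
                 std::max(-q2, 0.0) * conc[cellOff[c2]];
          vin += std::max(-q1, 0.0) + std::max(-q2, 0.0);
        }
        if (vin > 1e-300) cJ[i] = fin / vin;
      }
      double fs = (double)s / nsub, fs1 = (double)(s + 1) / nsub;
      for (int a = 0; a < np + nlb; ++a) {
        bool isPipe = a < np;
        int m = isPipe ? ncell[a] : ntc;
        int off = isPipe ? cellOff[a] : tOff[a - np];
        const double* Q = &faceQ[off + a];
        const double* C = &conc[off];
        const double* vO = &volOld[off];
        const double* vN = &volNew[off];
        double* slope = &wsP[0];
        // limited slopes; first-order at airway end cells
        slope[0] = 0.0; slope[m - 1] = 0.0;
        for (int k = 1; k < m - 1; ++k) {
          double sl = (C[k] - C[k - 1]) / dcm[off + k];
          double sr = (C[k + 1] - C[k]) / dcp[off + k];
          slope[k] = (sl * sr <= 0) ? 0.0
                     : ((std::fabs(sl) < std::fabs(sr)) ? sl : sr);
        }
        // face fluxes
        double* F = &wr[0];
        {
          double q = Q[0], cf;
          if (isPipe && parent[a] < 0) {            // mouth
            cf = (q >= 0) ? 0.0 : C[0];
            cumMouthFlux += dta * q * cf;
          } else {
            int jn = isPipe ? parent[a] : lobPipe[a - np];
            cf = (q >= 0) ? cJ[jn] : C[0];
          }
          F[0] = q * cf;
        }
        for (int j = 1; j < m; ++j) {
          double q = Q[j];
          F[j] = q * ((q >= 0)
                      ? C[j - 1] + slope[j - 1] * cdR[off + j - 1]
                      : C[j] - slope[j] * cdL[off + j]);
        }
        if (!isPipe) F[m] = 0.0;                     // closed distal end
        else {
          double q = Q[m];
          F[m] = q * ((q >= 0) ? C[m - 1] : cJ[a]);
        }
        // conservative update on the linearly moving cell volumes
        double* Cw = &conc[off];
        for (int k = 0; k < m; ++k) {
          double dv = vN[k] - vO[k];
          double v0 = vO[k] + fs * dv;
          double v1 = vO[k] + fs1 * dv;
          wa[k] = (v0 * Cw[k] - dta * (F[k + 1] - F[k])) / v1;
        }
        for (int k = 0; k < m; ++k) Cw[k] = wa[k];
      }
    }
  }

  void transportStep(double dt, double QinStep) {
    computeStepGeometry(dt);
    if (advScheme == 0) {
      advectPhase(dt, QinStep);
      implicitPhase(dt, QinStep, false);
    } else {
      implicitPhase(dt, QinStep, true);
    }
  }

  double tracerMass() const {
    double Mtot = 0.0;
    for (int i = 0; i < np; ++i) {
      int m = ncell[i], off = cellOff[i];
      for (int k = 0; k < m; ++k) Mtot += Sp[i] * hpipe[i] * conc[off + k];
    }
    for (int k = 0; k < nlb; ++k) {
      int off = tOff[k];
      for (int c = 0; c < ntc; ++c) {
        double dA1 = tA1[tface(k, c + 1)] - tA1[tface(k, c)];
        double dA2 = tA2[tface(k, c + 1)] - tA2[tface(k, c)];
        double dx = tXf[tface(k, c + 1)] - tXf[tface(k, c)];
        Mtot += (p1[k] * dA1 + p2c[k] * dA2 + St[k] * dx) * conc[off + c];
      }
    }
    return Mtot;
  }
};

static LungModel* getModel(SEXP ptr) {
  Rcpp::XPtr<LungModel> xp(ptr);
  return xp.get();
}

// [[Rcpp::export]]
SEXP ml_create(List spec) {
  LungModel* M = new LungModel();
  IntegerVector parent = spec["parent"], termLob = spec["term_lobule"],
                ncell = spec["ncell"], lobPipe = spec["lob_pipe"];
  NumericVector Rp = spec["R_pipe"], Sp = spec["S_pipe"], dp = spec["d_pipe"],
                lenp = spec["len_pipe"];
  M->np = parent.size();
  M->parent.assign(parent.begin(), parent.end());
  M->termLob.assign(termLob.begin(), termLob.end());
  M->ncell.assign(ncell.begin(), ncell.end());
  M->Rp.assign(Rp.begin(), Rp.end());
  M->Sp.assign(Sp.begin(), Sp.end());
  M->dpipe.assign(dp.begin(), dp.end());
  M->lenp.assign(lenp.begin(), lenp.end());
  M->child1.assign(M->np, -1); M->child2.assign(M->np, -1);
  for (int i = 0; i < M->np; ++i) {
    int p = M->parent[i];
    if (p >= 0) {
      if (M->child1[p] < 0) M->child1[p] = i; else M->child2[p] = i;
    }
  }
  M->lobPipe.assign(lobPipe.begin(), lobPipe.end());
  M->nlb = lobPipe.size();
  NumericVector V0 = spec["V0"], gam = spec["gamma"], pelCoef = spec["pel_coef"],
                Reff = spec["R_eff"], St = spec["S_t"], Llb = spec["l_lb"],
                p2c = spec["p2"], p1init = spec["p1"];
  M->V0.assign(V0.begin(), V0.end());
  M->gam.assign(gam.begin(), gam.end());
  M->pelCoef.assign(pelCoef.begin(), pelCoef.end());
  M->Reff.assign(Reff.begin(), Reff.end());
  M->St.assign(St.begin(), St.end());
  M->Llb.assign(Llb.begin(), Llb.end());
  M->p2c.assign(p2c.begin(), p2c.end());
  M->n1 = as<double>(spec["n1"]);
  M->n2 = as<double>(spec["n2"]);
  NumericMatrix tf = spec["trumpet_faces"];  // (ntc+1) x nlb
  M->ntc = tf.nrow() - 1;
  NumericVector dloc = spec["trumpet_face_diam"]; // same layout, by column
  int nf = M->ntc + 1;
  M->tXf.resize((size_t)M->nlb * nf);
  M->tA1.resize((size_t)M->nlb * nf);
  M->tA2.resize((size_t)M->nlb * nf);
  M->tXn1.resize((size_t)M->nlb * nf);
  M->tXn2.resize((size_t)M->nlb * nf);
  M->tDloc.resize((size_t)M->nlb * nf);
  M->tSduct.resize((size_t)M->nlb * nf);
  NumericVector sduct = spec["trumpet_face_duct"];
  for (int k = 0; k < M->nlb; ++k)
    for (int j = 0; j < nf; ++j) {
      double x = tf(j, k);
      size_t id = (size_t)k * nf + j;
      M->tXf[id] = x;
      M->tXn1[id] = std::pow(x, M->n1);
      M->tXn2[id] = std::pow(x, M->n2);
      M->tA1[id] = std::pow(x, M->n1 + 1) / (M->n1 + 1);
      M->tA2[id] = std::pow(x, M->n2 + 1) / (M->n2 + 1);
      M->tDloc[id] = dloc[(size_t)k * nf + j];
      M->tSduct[id] = sduct[(size_t)k * nf + j];
    }
  M->ductTransport = as<bool>(spec["duct_transport"]);
  M->mu = as<double>(spec["mu"]);
  M->rho = as<double>(spec["rho"]);
  M->Dmol = as<double>(spec["D"]);
  M->taylor = as<bool>(spec["taylor"]);
  M->theta = as<double>(spec["theta"]);
  M->newtonTol = as<double>(spec["newton_tol"]);
  M->newtonMaxit = as<int>(spec["newton_maxit"]);
  M->qScale = as<double>(spec["q_scale"]);
  // cell offsets
  M->cellOff.resize(M->np);
  int off = 0;
  M->hpipe.resize(M->np);
  for (int i = 0; i < M->np; ++i) {
    M->cellOff[i] = off; off += M->ncell[i];
    M->hpipe[i] = M->lenp[i] / M->ncell[i];
  }
  M->nPipeCells = off;
  M->tOff.resize(M->nlb);
  for (int k = 0; k < M->nlb; ++k) { M->tOff[k] = off; off += M->ntc; }
  M->nCells = off;
  // state & buffers
  M->V = M->V0;
  M->dV.assign(M->nlb, 0.0);
  M->Vmin.resize(M->nlb);
  M->p1.resize(M->nlb);
  for (int k = 0; k < M->nlb; ++k) {
    M->Vmin[k] = M->St[k] * M->Llb[k] * 1.000001;
    M->p1[k] = M->p1ofV(k, M->V[k]);
  }
  M->p1prev = M->p1;
  M->qPipe.assign(M->np, 0.0);
  M->conc.assign(M->nCells, 1.0);
  M->cJ.assign(M->np, 1.0);
  int mMax = M->ntc;
  for (int i = 0; i < M->np; ++i) if (M->ncell[i] > mMax) mMax = M->ncell[i];
  M->wa.resize(mMax + 2); M->wb.resize(mMax + 2); M->wc.resize(mMax + 2);
  M->wr.resize(mMax + 2); M->wsP.resize(mMax + 2); M->wsD.resize(mMax + 2);
  // cell geometry for slope reconstruction
  M->cdL.resize(M->nCells); M->cdR.resize(M->nCells);
  M->dcm.assign(M->nCells, 1.0); M->dcp.assign(M->nCells, 1.0);
  for (int i = 0; i < M->np; ++i) {
    int m = M->ncell[i], off = M->cellOff[i];
    double h = M->hpipe[i];
    for (int k = 0; k < m; ++k) {
      M->cdL[off + k] = 0.5 * h; M->cdR[off + k] = 0.5 * h;
      M->dcm[off + k] = h; M->dcp[off + k] = h;
    }
  }
  for (int k = 0; k < M->nlb; ++k) {
    int m = M->ntc, off = M->tOff[k];
    std::vector<double> xc(m);
    for (int c = 0; c < m; ++c)
      xc[c] = 0.5 * (M->tXf[M->tface(k, c)] + M->tXf[M->tface(k, c + 1)]);
    for (int c = 0; c < m; ++c) {
      M->cdL[off + c] = xc[c] - M->tXf[M->tface(k, c)];
      M->cdR[off + c] = M->tXf[M->tface(k, c + 1)] - xc[c];
      if (c > 0) M->dcm[off + c] = xc[c] - xc[c - 1];
      if (c < m - 1) M->dcp[off + c] = xc[c + 1] - xc[c];
    }
  }
  M->advScheme = as<int>(spec["advection_scheme"]);
  M->solS.resize(M->nCells); M->solP.resize(M->nCells); M->solD.resize(M->nCells);
  M->AJ.resize(M->np); M->BJ.resize(M->np); M->GJ1.resize(M->np);
  M->GJ2.resize(M->np); M->RJ.resize(M->np); M->cJnew.resize(M->np);
  M->faceQ.resize((size_t)M->nCells + M->np + M->nlb);
  M->faceG.resize((size_t)M->nCells + M->np + M->nlb);
  M->volNew.resize(M->nCells); M->volOld.resize(M->nCells);
  M->lobA.resize(M->np); M->lobB.resize(M->np);
  M->psi.resize(M->np); M->qsub.resize(M->np);
  Rcpp::XPtr<LungModel> ptr(M, true);
  return ptr;
}

// [[Rcpp::export]]
NumericVector ml_solve_tree_test(SEXP ptr, NumericVector Dd, NumericVector b,
                                 double dt) {
  LungModel* M = getModel(ptr);
  std::vector<double> Ddv(Dd.begin(), Dd.end()), bv(b.begin(), b.end()),
      x(M->nlb);
  M->solveTree(Ddv, bv, dt, x);
  return NumericVector(x.begin(), x.end());
}

// [[Rcpp::export]]
int ml_vent_step(SEXP ptr, double Qin, double dt) {
  LungModel* M = getModel(ptr);
  int it = M->ventStep(Qin, dt);
  if (it >= 0) M->t += dt;
  return it;
}

// [[Rcpp::export]]
void ml_transport_step(SEXP ptr, double dt, double Qin) {
  getModel(ptr)->transportStep(dt, Qin);
}

// [[Rcpp::export]]
List ml_state(SEXP ptr) {
  LungModel* M = getModel(ptr);
  NumericVector lobC(M->nlb);
  for (int k = 0; k < M->nlb; ++k) {
    double num = 0.0, den = 0.0;
    int off = M->tOff[k];
    for (int c = 0; c < M->ntc; ++c) {
      double dA1 = M->tA1[M->tface(k, c + 1)] - M->tA1[M->tface(k, c)];
      double dA2 = M->tA2[M->tface(k, c + 1)] - M->tA2[M->tface(k, c)];
      double dx = M->tXf[M->tface(k, c + 1)] - M->tXf[M->tface(k, c)];
      double vol = M->p1[k] * dA1 + M->p2c[k] * dA2 + M->St[k] * dx;
      num += vol * M->conc[off + c]; den += vol;
    }
    lobC[k] = num / den;
  }
  return List::create(
    _["t"] = M->t, _["p_pl"] = M->ppl,
    _["V_lb"] = NumericVector(M->V.begin(), M->V.end()),
    _["dV_lb"] = NumericVector(M->dV.begin(), M->dV.end()),
    _["pipe_flows"] = NumericVector(M->qPipe.begin(), M->qPipe.end()),
    _["conc"] = NumericVector(M->conc.begin(), M->conc.end()),
    _["conc_junction"] = NumericVector(M->cJ.begin(), M->cJ.end()),
    _["c_mouth"] = M->conc[0],
    _["tracer_mass"] = M->tracerMass(),
    _["cum_mouth_flux"] = M->cumMouthFlux,
    _["p1"] = NumericVector(M->p1.begin(), M->p1.end()),
    _["lobule_mean_conc"] = lobC);
}

// [[Rcpp::export]]
void ml_set_concentration(SEXP ptr, NumericVector conc, NumericVector cJ) {
  LungModel* M = getModel(ptr);
  if ((int)conc.size() != M->nCells) stop("concentration length mismatch");
  if ((int)cJ.size() != M->np) stop("junction concentration length mismatch");
  std::copy(conc.begin(), conc.end(), M->conc.begin());
  std::copy(cJ.begin(), cJ.end(), M->cJ.begin());
}

// [[Rcpp::export]]
List ml_run(SEXP ptr, NumericVector Qin, double dt, IntegerVector breath_end) {
  LungModel* M = getModel(ptr);
  int ns = Qin.size();
  NumericVector tOut(ns), cM(ns), mass(ns), flux(ns), pplv(ns), itv(ns);
  int nb = breath_end.size();
  NumericMatrix lobC(nb, M->nlb), lobV(nb, M->nlb);
  int bi = 0;
  for (int s = 0; s < ns; ++s) {
    int it = M->ventStep(Qin[s], dt);
    if (it < 0)
      stop("ventilation step failed to converge at t = %f (step %d); "
           "try a smaller dt", M->t, s + 1);
    M->t += dt;
    M->transportStep(dt, Qin[s]);
    tOut[s] = M->t;
    cM[s] = M->conc[0];
    mass[s] = M->tracerMass();
    flux[s] = M->cumMouthFlux;
    pplv[s] = M->ppl;
    itv[s] = it;
    if (bi < nb && breath_end[bi] == s + 1) {
      List st = ml_state(ptr);
      NumericVector lc = st["lobule_mean_conc"];
      for (int k = 0; k < M->nlb; ++k) {
        lobC(bi, k) = lc[k];
        lobV(bi, k) = M->V[k];
      }
      ++bi;
    }
  }
  return List::create(_["t"] = tOut, _["c_mouth"] = cM, _["tracer_mass"] = mass,
                      _["cum_mouth_flux"] = flux, _["p_pl"] = pplv,
                      _["newton_iters"] = itv,
                      _["lobule_conc_breath"] = lobC,
                      _["lobule_vol_breath"] = lobV);
}

// Standalone single-airway stepper, sharing the discretizations of the
// network solver; used for oracle problems on a single pipe (pure
// advection front, free diffusion) and for refinement studies.
//
// scheme: 0 = explicit MUSCL advection substeps + theta-implicit
// diffusion (the network default), 1 = one-step theta-implicit
// upwind/central scheme.
// bcL / bcR: 0 = closed (zero flux), 1 = Dirichlet ghost value cbc
// (advective + diffusive exchange), 2 = advective outflow (no diffusion).
// [[Rcpp::export]]
NumericVector pipe_transport_run(NumericVector c0, NumericVector h,
                                 NumericVector vol, NumericVector qf,
                                 NumericVector gf, double dt, int nsteps,
                                 double theta, int bcL, double cbcL,
                                 int bcR, double cbcR, int scheme = 0) {
  int m = c0.size();
  if (h.size() != m || vol.size() != m || qf.size() != m + 1 ||
      gf.size() != m + 1)
    stop("inconsistent grid sizes");
  std::vector<double> c(c0.begin(), c0.end()), cn(m);
  std::vector<double> wa(m), wb(m), wc(m), wr(m);
  auto flx = [](double q, double g, double cL, double cR) {
    return q * (q >= 0 ? cL : cR) - g * (cR - cL);
  };
  // cell centers for slope reconstruction
  std::vector<double> xc(m), slp(m), fl(m + 1);
  {
    double x = 0.0;
    for (int k = 0; k < m; ++k) { xc[k] = x + 0.5 * h[k]; x += h[k]; }
  }
  auto advectSub = [&]() {
    double maxrate = 0.0;
    for (int k = 0; k < m; ++k) {
      double rate = (std::max(qf[k + 1], 0.0) + std::max(-qf[k], 0.0)) / vol[k];
      if (rate > maxrate) maxrate = rate;
    }
    int nsub = std::max(1, (int)std::ceil(dt * maxrate / 0.45));
    double dta = dt / nsub;
    for (int s = 0; s < nsub; ++s) {
      slp[0] = slp[m - 1] = 0.0;
      for (int k = 1; k < m - 1; ++k) {
        double sl = (c[k] - c[k - 1]) / (xc[k] - xc[k - 1]);
        double sr = (c[k + 1] - c[k]) / (xc[k + 1] - xc[k]);
        slp[k] = (sl * sr <= 0) ? 0.0
                 : ((std::fabs(sl) < std::fabs(sr)) ? sl : sr);
      }
      for (int j = 0; j <= m; ++j) {
        double q = qf[j], cf;
        if (j == 0) {
          if (bcL == 1) cf = (q >= 0) ? cbcL : c[0];
          else if (bcL == 2) cf = c[0];
          else { fl[j] = 0.0; continue; }
        } else if (j == m) {
          if (bcR == 1) cf = (q >= 0) ? c[m - 1] : cbcR;
          else if (bcR == 2) cf = c[m - 1];
          else { fl[j] = 0.0; continue; }
        } else {
          cf = (q >= 0) ? c[j - 1] + slp[j - 1] * 0.5 * h[j - 1]
                        : c[j] - slp[j] * 0.5 * h[j];
        }
        fl[j] = q * cf;
      }
      for (int k = 0; k < m; ++k)
        c[k] -= dta * (fl[k + 1] - fl[k]) / vol[k];
    }
  };
  if (scheme == 0) {
    // advective boundary handling happens in the substeps; the implicit
    // part below is diffusion-only
    for (int s = 0; s < nsteps; ++s) {
      advectSub();
      for (int k = 0; k < m; ++k) {
        double diag = vol[k], lo = 0.0, up = 0.0, rhs = vol[k] * c[k];
        double g = gf[k], FoldL = 0.0;
        if (k > 0) {
          lo -= dt * theta * g;
          diag += dt * theta * g;
          FoldL = -g * (c[k] - c[k - 1]);
        } else if (bcL == 1) {
          diag += dt * theta * g;
          rhs += dt * theta * g * cbcL;
          FoldL = -g * (c[0] - cbcL);
        }
        g = gf[k + 1];
        double FoldR = 0.0;
        if (k < m - 1) {
          diag += dt * theta * g;
          up -= dt * theta * g;
          FoldR = -g * (c[k + 1] - c[k]);
        } else if (bcR == 1) {
          diag += dt * theta * g;
          rhs += dt * theta * g * cbcR;
          FoldR = -g * (cbcR - c[m - 1]);
        }
        rhs -= dt * (1.0 - theta) * (FoldR - FoldL);
        wa[k] = lo; wb[k] = diag; wc[k] = up; wr[k] = rhs;
      }
      for (int k = 1; k < m; ++k) {
        double w = wa[k] / wb[k - 1];
        wb[k] -= w * wc[k - 1];
        wr[k] -= w * wr[k - 1];
      }
      cn[m - 1] = wr[m - 1] / wb[m - 1];
      for (int k = m - 2; k >= 0; --k)
        cn[k] = (wr[k] - wc[k] * cn[k + 1]) / wb[k];
      c = cn;
    }
    return NumericVector(c.begin(), c.end());
  }
  for (int s = 0; s < nsteps; ++s) {
    for (int k = 0; k < m; ++k) {
      double diag = vol[k], lo = 0.0, up = 0.0, rhs = vol[k] * c[k];
      double q = qf[k], g = gf[k], FoldL = 0.0;
      if (k > 0) {
        lo -= dt * theta * ((q >= 0 ? q : 0) + g);
        diag -= dt * theta * ((q < 0 ? q : 0) - g);
        FoldL = flx(q, g, c[k - 1], c[k]);
      } else if (bcL == 1) {
        diag -= dt * theta * ((q < 0 ? q : 0) - g);
        rhs += dt * theta * ((q >= 0 ? q : 0) + g) * cbcL;
        FoldL = flx(q, g, cbcL, c[0]);
      } else if (bcL == 2) {
        diag -= dt * theta * q;
        FoldL = q * c[0];
      }
      q = qf[k + 1]; g = gf[k + 1];
      double FoldR = 0.0;
      if (k < m - 1) {
        diag += dt * theta * ((q >= 0 ? q : 0) + g);
        up += dt * theta * ((q < 0 ? q : 0) - g);
        FoldR = flx(q, g, c[k], c[k + 1]);
      } else if (bcR == 1) {
        diag += dt * theta * ((q >= 0 ? q : 0) + g);
        rhs -= dt * theta * ((q < 0 ? q : 0) - g) * cbcR;
        FoldR = flx(q, g, c[m - 1], cbcR);
      } else if (bcR == 2) {
        diag += dt * theta * q;
        FoldR = q * c[m - 1];
      }
      rhs -= dt * (1.0 - theta) * (FoldR - FoldL);
      wa[k] = lo; wb[k] = diag; wc[k] = up; wr[k] = rhs;
    }
    for (int k = 1; k < m; ++k) {
      double w = wa[k] / wb[k - 1];
      wb[k] -= w * wc[k - 1];
      wr[k] -= w * wr[k - 1];
    }
    cn[m - 1] = wr[m - 1] / wb[m - 1];
    for (int k = m - 2; k >= 0; --k)
      cn[k] = (wr[k] - wc[k] * cn[k + 1]) / wb[k];
    c = cn;
  }
  return NumericVector(c.begin(), c.end());
}
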