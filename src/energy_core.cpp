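// Lattice-sum engines: direct-space Buckingham repulsion/dispersion and
// point-charge Ewald electrostatics for rigid molecules in a periodic
// cell, with analytic first derivatives with respect to the rigid-body
// variable vector Omega and (for the Buckingham part) the pair
// parameters A, B, C including the Omega-parameter cross derivatives.
//
// Geometry enters as per-site Cartesian/fractional coordinates plus the
// Jacobians dx/dOmega, df/dOmega and dL/dOmega computed by the R layer;
// the chain rule through symmetry, rigid-body rotations and cell
// constraints lives entirely on the R side. Inner loops use raw array
// indexing: these sums dominate the cost of the whole estimation.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double KE = 1389.35458; // kJ mol^-1 A e^-2 (Coulomb constant)

// Bounds for the image search: |n_i| <= reach/h_i with h_i the
// perpendicular width of the cell along axis i.
static ivec image_bounds(const mat &L, double reach) {
  vec a1 = L.col(0), a2 = L.col(1), a3 = L.col(2);
  double V = std::abs(dot(a1, cross(a2, a3)));
  vec h = {V / norm(cross(a2, a3)), V / norm(cross(a3, a1)),
           V / norm(cross(a1, a2))};
  ivec nmax(3);
  for (int i = 0; i < 3; ++i)
    nmax[i] = (int)std::ceil(reach / h[i]);
  return nmax;
}

static double site_span(const mat &X) {
  double s = 0.0;
  for (uword p = 0; p < X.n_rows; ++p)
    for (uword q = p + 1; q < X.n_rows; ++q) {
      double d0 = X(p, 0) - X(q, 0), d1 = X(p, 1) - X(q, 1),
             d2 = X(p, 2) - X(q, 2);
      s = std::max(s, d0 * d0 + d1 * d1 + d2 * d2);
    }
  return std::sqrt(s);
}

// [[Rcpp::export]]
Rcpp::List repdisp_core(const arma::mat &X, const arma::mat &L,
                        const arma::ivec &instance, const arma::ivec &typ,
                        const arma::mat &A, const arma::mat &B,
                        const arma::mat &C, double cutoff, double taper,
                        int Z, bool want_grad, bool want_dp,
                        const arma::cube &Jx, const arma::cube &dL) {
  const uword n = X.n_rows;
  const uword nom = want_grad ? Jx.n_slices : 0;
  const uword nt = A.n_rows;
  const uword npair = nt * (nt + 1) / 2;

  umat pidx(nt, nt);
  {
    uword k = 0;
    for (uword i = 0; i < nt; ++i)
      for (uword j = i; j < nt; ++j) { pidx(i, j) = k; pidx(j, i) = k; ++k; }
  }

  double U = 0.0;
  vec grad(nom, fill::zeros);
  vec dU_dp(want_dp ? 3 * npair : 0, fill::zeros);
  mat cross_dp(want_grad && want_dp ? nom : 0,
               want_dp ? 3 * npair : 0, fill::zeros);
  double minr2 = datum::inf;

  const double *Xp = X.memptr();           // n x 3 column-major
  const double *Jp = Jx.memptr();          // (n, 3, nom)
  double *gp = grad.memptr();
  const double cut2 = cutoff * cutoff;
  std::vector<double> gg(nom), dLn(3 * nom);

  ivec nmax = image_bounds(L, cutoff + site_span(X));
  for (int n1 = -nmax[0]; n1 <= nmax[0]; ++n1)
    for (int n2 = -nmax[1]; n2 <= nmax[1]; ++n2)
      for (int n3 = -nmax[2]; n3 <= nmax[2]; ++n3) {
        const double Ln0 = L(0,0)*n1 + L(0,1)*n2 + L(0,2)*n3;
        const double Ln1 = L(1,0)*n1 + L(1,1)*n2 + L(1,2)*n3;
        const double Ln2 = L(2,0)*n1 + L(2,1)*n2 + L(2,2)*n3;
        const bool home = (n1 == 0 && n2 == 0 && n3 == 0);
        if (want_grad)
          for (uword o = 0; o < nom; ++o) {
            const mat &D = dL.slice(o);
            dLn[3*o+0] = D(0,0)*n1 + D(0,1)*n2 + D(0,2)*n3;
            dLn[3*o+1] = D(1,0)*n1 + D(1,1)*n2 + D(1,2)*n3;
            dLn[3*o+2] = D(2,0)*n1 + D(2,1)*n2 + D(2,2)*n3;
          }
        for (uword p = 0; p < n; ++p) {
          const double xp0 = Xp[p], xp1 = Xp[p+n], xp2 = Xp[p+2*n];
          for (uword q = 0; q < n; ++q) {
            if (home && instance[p] == instance[q]) continue;
            const double d0 = Xp[q] + Ln0 - xp0;
            const double d1 = Xp[q+n] + Ln1 - xp1;
            const double d2 = Xp[q+2*n] + Ln2 - xp2;
            const double r2 = d0*d0 + d1*d1 + d2*d2;
            if (r2 > cut2) continue;
            if (r2 < minr2) minr2 = r2;
            if (r2 < 0.09)
              return Rcpp::List::create(Rcpp::Named("overlap") = true,
                                        Rcpp::Named("minr") = std::sqrt(minr2));
            const double r = std::sqrt(r2);
            const uword ti = typ[p], tj = typ[q];
            const double a = A(ti, tj), b = B(ti, tj), cc = C(ti, tj);
            const double ebr = std::exp(-b * r);
            const double r6 = r2 * r2 * r2;
            // C2-smooth quintic switching function on [cutoff-taper, cutoff]
            double sw = 1.0, dsw = 0.0;
            if (taper > 0.0 && r > cutoff - taper) {
              const double t = (r - (cutoff - taper)) / taper;
              sw = 1.0 + t * t * t * (-10.0 + t * (15.0 - 6.0 * t));
              dsw = t * t * (-30.0 + t * (60.0 - 30.0 * t)) / taper;
            }
            const double phi = a * ebr - cc / r6;
            U += 0.5 * phi * sw;
            const double dphidr =
                (-a * b * ebr + 6.0 * cc / (r6 * r)) * sw + phi * dsw;
            if (want_grad) {
              const double e0 = d0 / r, e1 = d1 / r, e2 = d2 / r;
              const double w = 0.5 * dphidr;
              for (uword o = 0; o < nom; ++o) {
                const double *J = Jp + o * 3 * n;
                const double gd =
                    e0 * (J[q] - J[p] + dLn[3*o]) +
                    e1 * (J[q+n] - J[p+n] + dLn[3*o+1]) +
                    e2 * (J[q+2*n] - J[p+2*n] + dLn[3*o+2]);
                gg[o] = gd;
                gp[o] += w * gd;
              }
            }
            if (want_dp) {
              const uword k = pidx(ti, tj);
              dU_dp[k] += 0.5 * ebr * sw;
              dU_dp[npair + k] += 0.5 * (-a * r * ebr) * sw;
              dU_dp[2 * npair + k] += 0.5 * (-1.0 / r6) * sw;
              if (want_grad) {
                const double d2A = 0.5 * (-b * ebr * sw + ebr * dsw);
                const double d2B = 0.5 * (a * ebr * (b * r - 1.0) * sw -
                                          a * r * ebr * dsw);
                const double d2C = 0.5 * (6.0 / (r6 * r) * sw -
                                          dsw / r6);
                double *cA = cross_dp.colptr(k);
                double *cB = cross_dp.colptr(npair + k);
                double *cC = cross_dp.colptr(2 * npair + k);
                for (uword o = 0; o < nom; ++o) {
                  cA[o] += d2A * gg[o];
                  cB[o] += d2B * gg[o];
                  cC[o] += d2C * gg[o];
                }
              }
            }
          }
        }
      }

  const double invZ = 1.0 / (double)Z;
  return Rcpp::List::create(
      Rcpp::Named("overlap") = false, Rcpp::Named("U") = U * invZ,
      Rcpp::Named("grad") = grad * invZ,
      Rcpp::Named("dU_dp") = dU_dp * invZ,
      Rcpp::Named("cross") = cross_dp * invZ,
      Rcpp::Named("minr") = std::sqrt(minr2));
}

// [[Rcpp::export]]
Rcpp::List ewald_core(const arma::mat &X, const arma::mat &F,
                      const arma::mat &L, const arma::vec &q,
                      const arma::ivec &instance, double alpha, double rcut,
                      double kcut, int Z, bool want_grad,
                      const arma::cube &Jx, const arma::cube &Jf,
                      const arma::cube &dL) {
  const uword n = X.n_rows;
  const uword nom = want_grad ? Jx.n_slices : 0;
  const double V = std::abs(det(L));
  const mat Linv = inv(L);

  double Ureal = 0.0, Urec = 0.0, Uself = 0.0, Ucorr = 0.0;
  vec grad(nom, fill::zeros);
  double *gp = grad.memptr();
  const double *Xp = X.memptr();
  const double *Jxp = Jx.memptr();
  const double *Jfp = Jf.memptr();

  // ---- real space -----------------------------------------------------
  {
    ivec nmax = image_bounds(L, rcut + site_span(X));
    const double cut2 = rcut * rcut;
    const double tsp = 2.0 * alpha / std::sqrt(datum::pi);
    std::vector<double> dLn(3 * nom);
    for (int n1 = -nmax[0]; n1 <= nmax[0]; ++n1)
      for (int n2 = -nmax[1]; n2 <= nmax[1]; ++n2)
        for (int n3 = -nmax[2]; n3 <= nmax[2]; ++n3) {
          const double Ln0 = L(0,0)*n1 + L(0,1)*n2 + L(0,2)*n3;
          const double Ln1 = L(1,0)*n1 + L(1,1)*n2 + L(1,2)*n3;
          const double Ln2 = L(2,0)*n1 + L(2,1)*n2 + L(2,2)*n3;
          const bool home = (n1 == 0 && n2 == 0 && n3 == 0);
          if (want_grad)
            for (uword o = 0; o < nom; ++o) {
              const mat &D = dL.slice(o);
              dLn[3*o+0] = D(0,0)*n1 + D(0,1)*n2 + D(0,2)*n3;
              dLn[3*o+1] = D(1,0)*n1 + D(1,1)*n2 + D(1,2)*n3;
              dLn[3*o+2] = D(2,0)*n1 + D(2,1)*n2 + D(2,2)*n3;
            }
          for (uword p = 0; p < n; ++p) {
            const double xp0 = Xp[p], xp1 = Xp[p+n], xp2 = Xp[p+2*n];
            for (uword qq = 0; qq < n; ++qq) {
              if (home && instance[p] == instance[qq]) continue;
              const double d0 = Xp[qq] + Ln0 - xp0;
              const double d1 = Xp[qq+n] + Ln1 - xp1;
              const double d2 = Xp[qq+2*n] + Ln2 - xp2;
              const double r2 = d0*d0 + d1*d1 + d2*d2;
              if (r2 > cut2) continue;
              const double r = std::sqrt(r2);
              const double qpq = KE * q[p] * q[qq];
              const double er = std::erfc(alpha * r);
              Ureal += 0.5 * qpq * er / r;
              if (want_grad) {
                const double dphidr =
                    qpq * (-er / r2 -
                           tsp * std::exp(-alpha * alpha * r2) / r);
                const double w = 0.5 * dphidr / r;
                for (uword o = 0; o < nom; ++o) {
                  const double *J = Jxp + o * 3 * n;
                  gp[o] += w * (d0 * (J[qq] - J[p] + dLn[3*o]) +
                                d1 * (J[qq+n] - J[p+n] + dLn[3*o+1]) +
                                d2 * (J[qq+2*n] - J[p+2*n] + dLn[3*o+2]));
                }
              }
            }
          }
        }
  }

  // ---- reciprocal space ----------------------------------------------
  {
    const double pref = KE * 2.0 * datum::pi / V;
    const double inv4a2 = 1.0 / (4.0 * alpha * alpha);
    ivec mmax(3);
    for (int i = 0; i < 3; ++i)
      mmax[i] = (int)std::ceil(kcut * norm(L.col(i)) / (2.0 * datum::pi));
    const double kcut2 = kcut * kcut;
    const mat G = 2.0 * datum::pi * Linv.t();    // k = G m
    std::vector<double> cphi(n), sphi(n);
    vec dVoverV(nom, fill::zeros);
    std::vector<mat> dLw(nom);                   // Linv-compatible cell part
    if (want_grad)
      for (uword o = 0; o < nom; ++o) {
        dVoverV[o] = trace(Linv * dL.slice(o));
        dLw[o] = dL.slice(o) * Linv;             // dk = -(dL Linv)^T' ...
      }
    const double twopi = 2.0 * datum::pi;
    for (int m1 = -mmax[0]; m1 <= mmax[0]; ++m1)
      for (int m2 = -mmax[1]; m2 <= mmax[1]; ++m2)
        for (int m3 = -mmax[2]; m3 <= mmax[2]; ++m3) {
          if (m1 == 0 && m2 == 0 && m3 == 0) continue;
          const double k0 = G(0,0)*m1 + G(0,1)*m2 + G(0,2)*m3;
          const double k1 = G(1,0)*m1 + G(1,1)*m2 + G(1,2)*m3;
          const double k2v = G(2,0)*m1 + G(2,1)*m2 + G(2,2)*m3;
          const double k2 = k0*k0 + k1*k1 + k2v*k2v;
          if (k2 > kcut2) continue;
          const double Fk = std::exp(-k2 * inv4a2) / k2;
          double Sr = 0.0, Si = 0.0;
          for (uword j = 0; j < n; ++j) {
            const double ph = twopi * (m1 * F(j,0) + m2 * F(j,1) + m3 * F(j,2));
            cphi[j] = std::cos(ph);
            sphi[j] = std::sin(ph);
            Sr += q[j] * cphi[j];
            Si += q[j] * sphi[j];
          }
          const double S2 = Sr * Sr + Si * Si;
          Urec += pref * Fk * S2;
          if (want_grad) {
            const double dFdk2 = Fk * (-inv4a2 - 1.0 / k2);
            for (uword o = 0; o < nom; ++o) {
              const double *J = Jfp + o * 3 * n;
              double term = 0.0;
              for (uword j = 0; j < n; ++j) {
                const double mj =
                    twopi * (m1 * J[j] + m2 * J[j+n] + m3 * J[j+2*n]);
                term += q[j] * mj * (Si * cphi[j] - Sr * sphi[j]);
              }
              double g = pref * Fk * 2.0 * term;
              // cell part: dk2_o = -2 k^T (dL Linv) k
              const mat &W = dLw[o];
              const double Wk0 = W(0,0)*k0 + W(0,1)*k1 + W(0,2)*k2v;
              const double Wk1 = W(1,0)*k0 + W(1,1)*k1 + W(1,2)*k2v;
              const double Wk2 = W(2,0)*k0 + W(2,1)*k1 + W(2,2)*k2v;
              const double dk2 = -2.0 * (k0*Wk0 + k1*Wk1 + k2v*Wk2);
              g += pref * dFdk2 * dk2 * S2;
              g -= pref * Fk * S2 * dVoverV[o];
              gp[o] += g;
            }
          }
        }
  }

  // ---- self and rigid intramolecular corrections ----------------------
  Uself = -KE * alpha / std::sqrt(datum::pi) * dot(q, q);
  for (uword p = 0; p < n; ++p)
    for (uword qq = p + 1; qq < n; ++qq) {
      if (instance[p] != instance[qq]) continue;
      const double d0 = Xp[p] - Xp[qq], d1 = Xp[p+n] - Xp[qq+n],
                   d2 = Xp[p+2*n] - Xp[qq+2*n];
      const double r = std::sqrt(d0*d0 + d1*d1 + d2*d2);
      Ucorr -= KE * q[p] * q[qq] * std::erf(alpha * r) / r;
    }

  const double invZ = 1.0 / (double)Z;
  return Rcpp::List::create(
      Rcpp::Named("U") = (Ureal + Urec + Uself + Ucorr) * invZ,
      Rcpp::Named("grad") = grad * invZ,
      Rcpp::Named("U_real") = Ureal * invZ, Rcpp::Named("U_rec") = Urec * invZ,
      Rcpp::Named("U_self") = Uself * invZ,
      Rcpp::Named("U_corr") = Ucorr * invZ);
}
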