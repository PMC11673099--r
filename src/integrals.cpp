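// McMurchie-Davidson (Hermite) Gaussian integral kernels.
//
// Shells arrive from R as a flat "shell environment" list (see shell_env()):
// angular momentum, center, primitive exponents and final contraction
// coefficients (primitive normalization and contracted renormalization are
// already folded in), plus the Cartesian -> real-spherical transformation
// matrix per angular momentum.  All angular classes share one recursion
// family; the two-electron kernel is templated on the floating type so the
// single-precision dispatch path runs genuinely in float and is accumulated
// into double by the caller.

#include <Rcpp.h>
#include <cmath>
#include <cstring>
#include <vector>
#include <set>
#include <array>
#include <algorithm>

using namespace Rcpp;

static const int LMAX = 4;  // shells above g are rejected at the R level

// ---------------------------------------------------------------- Boys F_m(T)
static void boys(double T, int mmax, double* F) {
  if (T < 1e-14) {
    for (int m = 0; m <= mmax; ++m) F[m] = 1.0 / (2.0 * m + 1.0);
    return;
  }
  if (T > 35.0) {
    // e^{-T} is negligible relative to F_0; upward recursion is stable here
    F[0] = 0.5 * std::sqrt(M_PI / T) * std::erf(std::sqrt(T));
    double eT = std::exp(-T);
    for (int m = 0; m < mmax; ++m)
      F[m + 1] = ((2.0 * m + 1.0) * F[m] - eT) / (2.0 * T);
    return;
  }
  double eT = std::exp(-T);
  double term = 1.0 / (2.0 * mmax + 1.0), sum = term;
  for (int i = 1; i < 400; ++i) {
    term *= 2.0 * T / (2.0 * mmax + 2.0 * i + 1.0);
    sum += term;
    if (term < 1e-17 * sum) break;
  }
  F[mmax] = eT * sum;
  for (int m = mmax; m > 0; --m)
    F[m - 1] = (2.0 * T * F[m] + eT) / (2.0 * m - 1.0);
}

// ------------------------------------------------- Hermite expansion E_t^{ij}
// E indexed [i][j][t], t = 0..i+j; flat layout with strides.
template <typename Real>
struct ETable {
  int imax, jmax, tdim;
  std::vector<Real> e;
  Real at(int i, int j, int t) const {
    if (t < 0 || t > i + j) return Real(0);
    return e[(i * (jmax + 1) + j) * tdim + t];
  }
  Real& ref(int i, int j, int t) { return e[(i * (jmax + 1) + j) * tdim + t]; }
};

template <typename Real>
static void hermiteE(int imax, int jmax, Real a, Real b, Real AB, ETable<Real>& E) {
  Real p = a + b, mu = a * b / p;
  Real PA = -b * AB / p;  // P - A with AB = A - B
  Real PB = a * AB / p;   // P - B
  Real oo2p = Real(0.5) / p;
  E.imax = imax; E.jmax = jmax; E.tdim = imax + jmax + 1;
  E.e.assign((imax + 1) * (jmax + 1) * E.tdim, Real(0));
  E.ref(0, 0, 0) = std::exp(-mu * AB * AB);
  for (int i = 0; i < imax; ++i) {
    for (int t = 0; t <= i + 1; ++t) {
      Real v = PA * E.at(i, 0, t) + Real(t + 1) * E.at(i, 0, t + 1);
      if (t > 0) v += oo2p * E.at(i, 0, t - 1);
      E.ref(i + 1, 0, t) = v;
    }
  }
  for (int i = 0; i <= imax; ++i) {
    for (int j = 0; j < jmax; ++j) {
      for (int t = 0; t <= i + j + 1; ++t) {
        Real v = PB * E.at(i, j, t) + Real(t + 1) * E.at(i, j, t + 1);
        if (t > 0) v += oo2p * E.at(i, j, t - 1);
        E.ref(i, j + 1, t) = v;
      }
    }
  }
}

// ------------------------------------------------------ Hermite R_{tuv} tensor
// R^0_{tuv} for t+u+v <= N, from Boys values; a = exponent of the Coulomb
// Gaussian, PQ = distance vector argument.
template <typename Real>
struct RTensor {
  int N, s;
  std::vector<Real> r;  // [n][t][u][v] flat, strides s = N+1
  Real at(int t, int u, int v) const { return r[((size_t)0 * s + t) * s * s + u * s + v]; }
};

template <typename Real>
static void hermiteR(int N, Real a, Real x, Real y, Real z, RTensor<Real>& R) {
  double T = (double)(a * (x * x + y * y + z * z));
  std::vector<double> F(N + 1);
  boys(T, N, F.data());
  int s = N + 1;
  R.N = N; R.s = s;
  std::vector<Real> cur((size_t)s * s * s, Real(0)), nxt((size_t)s * s * s, Real(0));
  // iterate n from N down to 0; cur holds level n+1, out holds level n
  std::vector<std::vector<Real>> lev(N + 1);
  double m2a = 1.0;
  for (int n = N; n >= 0; --n) {
    std::vector<Real>& out = lev[n];
    out.assign((size_t)s * s * s, Real(0));
    m2a = std::pow(-2.0 * (double)a, n);
    out[0] = Real(m2a * F[n]);
    if (n < N) {
      const std::vector<Real>& up = lev[n + 1];
      int cap = N - n;
      auto idx = [s](int t, int u, int v) { return ((size_t)t * s + u) * s + v; };
      for (int v = 0; v < cap; ++v)
        out[idx(0, 0, v + 1)] = Real(v) * (v > 0 ? up[idx(0, 0, v - 1)] : Real(0)) + z * up[idx(0, 0, v)];
      for (int u = 0; u < cap; ++u)
        for (int v = 0; v + u < cap; ++v)
          out[idx(0, u + 1, v)] = Real(u) * (u > 0 ? up[idx(0, u - 1, v)] : Real(0)) + y * up[idx(0, u, v)];
      for (int t = 0; t < cap; ++t)
        for (int u = 0; t + u < cap; ++u)
          for (int v = 0; t + u + v < cap; ++v)
            out[idx(t + 1, u, v)] = Real(t) * (t > 0 ? up[idx(t - 1, u, v)] : Real(0)) + x * up[idx(t, u, v)];
    }
  }
  R.r = lev[0];
}

// ------------------------------------------------------------- Cartesian lists
struct CartList { std::vector<int> lx, ly, lz; };
static CartList cart_list(int l) {
  CartList c;
  for (int ax = l; ax >= 0; --ax)
    for (int ay = l - ax; ay >= 0; --ay) {
      c.lx.push_back(ax); c.ly.push_back(ay); c.lz.push_back(l - ax - ay);
    }
  return c;
}
static int ncart(int l) { return (l + 1) * (l + 2) / 2; }
static int nsph(int l) { return 2 * l + 1; }

// --------------------------------------------------------------- shell struct
struct Shell {
  int l;
  double cx, cy, cz;
  std::vector<double> exps, coefs;
};

struct ShellEnv {
  std::vector<Shell> shells;
  std::vector<int> ao_off;
  int nao;
  std::vector<NumericMatrix> trans;  // per l: ncart x nsph
};

static ShellEnv read_env(List env) {
  ShellEnv se;
  IntegerVector l = env["l"];
  NumericVector cx = env["cx"], cy = env["cy"], cz = env["cz"];
  IntegerVector pstart = env["pstart"], pcount = env["pcount"];
  NumericVector exps = env["exps"], coefs = env["coefs"];
  IntegerVector off = env["ao_off"];
  int nshell = l.size();
  se.shells.resize(nshell);
  for (int s = 0; s < nshell; ++s) {
    Shell& sh = se.shells[s];
    sh.l = l[s]; sh.cx = cx[s]; sh.cy = cy[s]; sh.cz = cz[s];
    for (int p = 0; p < pcount[s]; ++p) {
      sh.exps.push_back(exps[pstart[s] + p]);
      sh.coefs.push_back(coefs[pstart[s] + p]);
    }
  }
  se.ao_off.assign(off.begin(), off.end());
  se.nao = as<int>(env["nao"]);
  List tr = env["trans"];
  for (int i = 0; i < tr.size(); ++i) se.trans.push_back(as<NumericMatrix>(tr[i]));
  return se;
}

// ------------------------------------------------- one-electron shell pair ops
// Cartesian 1D overlap from E table: S(i,j) = E^{ij}_0 * sqrt(pi/p)
static void one_electron_pair(const Shell& A, const Shell& B,
                              const std::vector<double>& Z,
                              const std::vector<double>& zx,
                              const std::vector<double>& zy,
                              const std::vector<double>& zz,
                              std::vector<double>& Scart,
                              std::vector<double>& Tcart,
                              std::vector<double>& Vcart) {
  CartList ca = cart_list(A.l), cb = cart_list(B.l);
  int na = ncart(A.l), nb = ncart(B.l);
  Scart.assign((size_t)na * nb, 0.0);
  Tcart.assign((size_t)na * nb, 0.0);
  Vcart.assign((size_t)na * nb, 0.0);
  double ABx = A.cx - B.cx, ABy = A.cy - B.cy, ABz = A.cz - B.cz;
  int Ltot = A.l + B.l;
  for (size_t ia = 0; ia < A.exps.size(); ++ia) {
    double a = A.exps[ia], caa = A.coefs[ia];
    for (size_t ib = 0; ib < B.exps.size(); ++ib) {
      double b = B.exps[ib], cbb = B.coefs[ib];
      double p = a + b, cc = caa * cbb;
      ETable<double> Ex, Ey, Ez;
      // kinetic needs j+2 on the ket side
      hermiteE<double>(A.l, B.l + 2, a, b, ABx, Ex);
      hermiteE<double>(A.l, B.l + 2, a, b, ABy, Ey);
      hermiteE<double>(A.l, B.l + 2, a, b, ABz, Ez);
      double sp = std::sqrt(M_PI / p);
      double Px = (a * A.cx + b * B.cx) / p;
      double Py = (a * A.cy + b * B.cy) / p;
      double Pz = (a * A.cz + b * B.cz) / p;
      // nuclear-attraction Hermite tensors per center
      std::vector<RTensor<double>> Rt(Z.size());
      for (size_t ic = 0; ic < Z.size(); ++ic)
        hermiteR<double>(Ltot, p, Px - zx[ic], Py - zy[ic], Pz - zz[ic], Rt[ic]);
      for (int pa = 0; pa < na; ++pa) {
        int ixa = ca.lx[pa], iya = ca.ly[pa], iza = ca.lz[pa];
        for (int pb = 0; pb < nb; ++pb) {
          int jxb = cb.lx[pb], jyb = cb.ly[pb], jzb = cb.lz[pb];
          double Sx = Ex.at(ixa, jxb, 0) * sp;
          double Sy = Ey.at(iya, jyb, 0) * sp;
          double Sz = Ez.at(iza, jzb, 0) * sp;
          auto kin1d = [&](const ETable<double>& E, int i, int j) {
            double t = -2.0 * b * (2.0 * j + 1.0) * E.at(i, j, 0);
            t += 4.0 * b * b * E.at(i, j + 2, 0);
            if (j >= 2) t += (double)j * (j - 1) * E.at(i, j - 2, 0);
            return -0.5 * t * sp;
          };
          double Kx = kin1d(Ex, ixa, jxb), Ky = kin1d(Ey, iya, jyb), Kz = kin1d(Ez, iza, jzb);
          Scart[(size_t)pa * nb + pb] += cc * Sx * Sy * Sz;
          Tcart[(size_t)pa * nb + pb] += cc * (Kx * Sy * Sz + Sx * Ky * Sz + Sx * Sy * Kz);
          // nuclear attraction
          double vsum = 0.0;
          for (size_t ic = 0; ic < Z.size(); ++ic) {
            double vv = 0.0;
            for (int t = 0; t <= ixa + jxb; ++t) {
              double ex = Ex.at(ixa, jxb, t);
              if (ex == 0.0) continue;
              for (int u = 0; u <= iya + jyb; ++u) {
                double ey = Ey.at(iya, jyb, u);
                if (ey == 0.0) continue;
                for (int v = 0; v <= iza + jzb; ++v) {
                  double ez = Ez.at(iza, jzb, v);
                  if (ez == 0.0) continue;
                  vv += ex * ey * ez * Rt[ic].at(t, u, v);
                }
              }
            }
            vsum += -Z[ic] * vv;
          }
          Vcart[(size_t)pa * nb + pb] += cc * (2.0 * M_PI / p) * vsum;
        }
      }
    }
  }
}

// Cart (na x nb) -> spherical via Ta^T * M * Tb
static void sph_transform2(const std::vector<double>& cart,
                           const NumericMatrix& Ta, const NumericMatrix& Tb,
                           std::vector<double>& sph) {
  int na = Ta.nrow(), ma = Ta.ncol(), nb = Tb.nrow(), mb = Tb.ncol();
  std::vector<double> tmp((size_t)ma * nb, 0.0);
  for (int i = 0; i < ma; ++i)
    for (int k = 0; k < na; ++k) {
      double t = Ta(k, i);
      if (t == 0.0) continue;
      for (int j = 0; j < nb; ++j) tmp[(size_t)i * nb + j] += t * cart[(size_t)k * nb + j];
    }
  sph.assign((size_t)ma * mb, 0.0);
  for (int i = 0; i < ma; ++i)
    for (int j = 0; j < mb; ++j) {
      double v = 0.0;
      for (int k = 0; k < nb; ++k) v += tmp[(size_t)i * nb + k] * Tb(k, j);
      sph[(size_t)i * mb + j] = v;
    }
}

// [[Rcpp::export]]
List cpp_one_electron(List env, NumericVector Z, NumericMatrix atom_xyz) {
  ShellEnv se = read_env(env);
  int n = se.nao, nshell = se.shells.size();
  NumericMatrix S(n, n), T(n, n), V(n, n);
  std::vector<double> zq(Z.begin(), Z.end()), zx, zy, zz;
  for (int i = 0; i < atom_xyz.nrow(); ++i) {
    zx.push_back(atom_xyz(i, 0)); zy.push_back(atom_xyz(i, 1)); zz.push_back(atom_xyz(i, 2));
  }
  std::vector<double> Sc, Tc, Vc, Ss, Ts, Vs;
  for (int a = 0; a < nshell; ++a) {
    for (int b = a; b < nshell; ++b) {
      const Shell &A = se.shells[a], &B = se.shells[b];
      one_electron_pair(A, B, zq, zx, zy, zz, Sc, Tc, Vc);
      const NumericMatrix &Ta = se.trans[A.l], &Tb = se.trans[B.l];
      sph_transform2(Sc, Ta, Tb, Ss);
      sph_transform2(Tc, Ta, Tb, Ts);
      sph_transform2(Vc, Ta, Tb, Vs);
      int ma = nsph(A.l), mb = nsph(B.l);
      for (int i = 0; i < ma; ++i)
        for (int j = 0; j < mb; ++j) {
          int I = se.ao_off[a] + i, J = se.ao_off[b] + j;
          double sv = Ss[(size_t)i * mb + j], tv = Ts[(size_t)i * mb + j], vv = Vs[(size_t)i * mb + j];
          S(I, J) = sv; S(J, I) = sv;
          T(I, J) = tv; T(J, I) = tv;
          V(I, J) = vv; V(J, I) = vv;
        }
    }
  }
  return List::create(_["S"] = S, _["T"] = T, _["V"] = V);
}

// ----------------------------------------------------------------- ERI kernel
// Packed Hermite index over t+u+v <= L
struct HermIndex {
  int L;
  std::vector<int> t, u, v;
  std::vector<int> pos;  // dense (L+1)^3 lookup -> packed index
  HermIndex(int L_) : L(L_) {
    pos.assign((L + 1) * (L + 1) * (L + 1), -1);
    for (int tt = 0; tt <= L; ++tt)
      for (int uu = 0; uu + tt <= L; ++uu)
        for (int vv = 0; vv + uu + tt <= L; ++vv) {
          pos[(tt * (L + 1) + uu) * (L + 1) + vv] = t.size();
          t.push_back(tt); u.push_back(uu); v.push_back(vv);
        }
  }
  int n() const { return t.size(); }
};

// Cartesian ERI block for one shell quartet, contracted over primitives.
// Output dims (na, nb, nc, nd) in row-major [a][b][c][d].
template <typename Real>
static void eri_cart_quartet(const Shell& A, const Shell& B, const Shell& C, const Shell& D,
                             std::vector<double>& out) {
  CartList ca = cart_list(A.l), cb = cart_list(B.l), cc = cart_list(C.l), cd = cart_list(D.l);
  int na = ncart(A.l), nb = ncart(B.l), nc = ncart(C.l), nd = ncart(D.l);
  int Lb = A.l + B.l, Lk = C.l + D.l, N = Lb + Lk;
  HermIndex hb(Lb), hk(Lk);
  size_t nout = (size_t)na * nb * nc * nd;
  std::vector<Real> acc(nout, Real(0));
  Real ABx = Real(A.cx - B.cx), ABy = Real(A.cy - B.cy), ABz = Real(A.cz - B.cz);
  Real CDx = Real(C.cx - D.cx), CDy = Real(C.cy - D.cy), CDz = Real(C.cz - D.cz);
  std::vector<Real> Eket((size_t)nc * nd * hk.n());
  std::vector<Real> g((size_t)hb.n() * nc * nd);
  for (size_t ia = 0; ia < A.exps.size(); ++ia)
    for (size_t ib = 0; ib < B.exps.size(); ++ib) {
      Real a = Real(A.exps[ia]), b = Real(B.exps[ib]);
      Real p = a + b;
      Real cab = Real(A.coefs[ia] * B.coefs[ib]);
      Real Px = (a * Real(A.cx) + b * Real(B.cx)) / p;
      Real Py = (a * Real(A.cy) + b * Real(B.cy)) / p;
      Real Pz = (a * Real(A.cz) + b * Real(B.cz)) / p;
      ETable<Real> Exb, Eyb, Ezb;
      hermiteE<Real>(A.l, B.l, a, b, ABx, Exb);
      hermiteE<Real>(A.l, B.l, a, b, ABy, Eyb);
      hermiteE<Real>(A.l, B.l, a, b, ABz, Ezb);
      for (size_t ic = 0; ic < C.exps.size(); ++ic)
        for (size_t id = 0; id < D.exps.size(); ++id) {
          Real c = Real(C.exps[ic]), d = Real(D.exps[id]);
          Real q = c + d;
          Real ccd = Real(C.coefs[ic] * D.coefs[id]);
          Real Qx = (c * Real(C.cx) + d * Real(D.cx)) / q;
          Real Qy = (c * Real(C.cy) + d * Real(D.cy)) / q;
          Real Qz = (c * Real(C.cz) + d * Real(D.cz)) / q;
          ETable<Real> Exk, Eyk, Ezk;
          hermiteE<Real>(C.l, D.l, c, d, CDx, Exk);
          hermiteE<Real>(C.l, D.l, c, d, CDy, Eyk);
          hermiteE<Real>(C.l, D.l, c, d, CDz, Ezk);
          Real alpha = p * q / (p + q);
          RTensor<Real> R;
          hermiteR<Real>(N, alpha, Px - Qx, Py - Qy, Pz - Qz, R);
          Real pref = cab * ccd * Real(2.0) * Real(std::pow(M_PI, 2.5)) /
                      (p * q * std::sqrt(p + q));
          // ket Hermite coefficients per (c,d) cart pair
          for (int pc = 0; pc < nc; ++pc)
            for (int pd = 0; pd < nd; ++pd) {
              int cx1 = cc.lx[pc], cy1 = cc.ly[pc], cz1 = cc.lz[pc];
              int dx1 = cd.lx[pd], dy1 = cd.ly[pd], dz1 = cd.lz[pd];
              Real* ek = &Eket[((size_t)pc * nd + pd) * hk.n()];
              for (int h = 0; h < hk.n(); ++h) {
                int tt = hk.t[h], uu = hk.u[h], vv = hk.v[h];
                if (tt > cx1 + dx1 || uu > cy1 + dy1 || vv > cz1 + dz1) { ek[h] = Real(0); continue; }
                Real e = Exk.at(cx1, dx1, tt) * Eyk.at(cy1, dy1, uu) * Ezk.at(cz1, dz1, vv);
                // (-1)^{t+u+v} from differentiating w.r.t. Q
                if ((tt + uu + vv) & 1) e = -e;
                ek[h] = e;
              }
            }
          // g[tuv][cd] = sum_ket Eket * R[t+tau, u+mu, v+phi]
          int s = R.s;
          std::fill(g.begin(), g.end(), Real(0));
          for (int h = 0; h < hb.n(); ++h) {
            int tt = hb.t[h], uu = hb.u[h], vv = hb.v[h];
            Real* gro = &g[(size_t)h * nc * nd];
            for (int pcd = 0; pcd < nc * nd; ++pcd) {
              const Real* ek = &Eket[(size_t)pcd * hk.n()];
              Real sum = Real(0);
              for (int h2 = 0; h2 < hk.n(); ++h2) {
                Real e = ek[h2];
                if (e == Real(0)) continue;
                int T2 = tt + hk.t[h2], U2 = uu + hk.u[h2], V2 = vv + hk.v[h2];
                sum += e * R.r[((size_t)T2 * s + U2) * s + V2];
              }
              gro[pcd] = sum;
            }
          }
          // bra contraction
          for (int pa = 0; pa < na; ++pa)
            for (int pb = 0; pb < nb; ++pb) {
              int ax1 = ca.lx[pa], ay1 = ca.ly[pa], az1 = ca.lz[pa];
              int bx1 = cb.lx[pb], by1 = cb.ly[pb], bz1 = cb.lz[pb];
              Real* accro = &acc[(((size_t)pa * nb + pb) * nc) * nd];
              for (int h = 0; h < hb.n(); ++h) {
                int tt = hb.t[h], uu = hb.u[h], vv = hb.v[h];
                if (tt > ax1 + bx1 || uu > ay1 + by1 || vv > az1 + bz1) continue;
                Real e = Exb.at(ax1, bx1, tt) * Eyb.at(ay1, by1, uu) * Ezb.at(az1, bz1, vv);
                if (e == Real(0)) continue;
                e *= pref;
                const Real* gro = &g[(size_t)h * nc * nd];
                for (int pcd = 0; pcd < nc * nd; ++pcd) accro[pcd] += e * gro[pcd];
              }
            }
        }
    }
  out.resize(nout);
  for (size_t i = 0; i < nout; ++i) out[i] = (double)acc[i];
}

// 4-index Cartesian -> spherical transform (done in double)
static void sph_transform4(std::vector<double>& blk, int na, int nb, int nc, int nd,
                           const NumericMatrix& Ta, const NumericMatrix& Tb,
                           const NumericMatrix& Tc, const NumericMatrix& Td) {
  auto apply = [](std::vector<double>& x, int npre, int nk, int npost, const NumericMatrix& T) {
    int m = T.ncol();
    std::vector<double> y((size_t)npre * m * npost, 0.0);
    for (int a = 0; a < npre; ++a)
      for (int k = 0; k < nk; ++k) {
        const double* xr = &x[((size_t)a * nk + k) * npost];
        for (int j = 0; j < m; ++j) {
          double t = T(k, j);
          if (t == 0.0) continue;
          double* yr = &y[((size_t)a * m + j) * npost];
          for (int b = 0; b < npost; ++b) yr[b] += t * xr[b];
        }
      }
    x.swap(y);
  };
  int ma = Ta.ncol(), mb = Tb.ncol(), mc = Tc.ncol();
  apply(blk, 1, na, nb * nc * nd, Ta);
  apply(blk, ma, nb, nc * nd, Tb);
  apply(blk, ma * mb, nc, nd, Tc);
  apply(blk, ma * mb * mc, nd, 1, Td);
}

static void eri_quartet_sph(const ShellEnv& se, int a, int b, int c, int d,
                            bool single, std::vector<double>& blk) {
  const Shell &A = se.shells[a], &B = se.shells[b], &C = se.shells[c], &D = se.shells[d];
  if (single) eri_cart_quartet<float>(A, B, C, D, blk);
  else eri_cart_quartet<double>(A, B, C, D, blk);
  sph_transform4(blk, ncart(A.l), ncart(B.l), ncart(C.l), ncart(D.l),
                 se.trans[A.l], se.trans[B.l], se.trans[C.l], se.trans[D.l]);
}

// [[Rcpp::export]]
NumericVector cpp_eri_quartet(List env, int a, int b, int c, int d, bool single) {
  ShellEnv se = read_env(env);
  std::vector<double> blk;
  eri_quartet_sph(se, a, b, c, d, single, blk);
  NumericVector out(blk.begin(), blk.end());
  out.attr("dim") = IntegerVector::create(
      nsph(se.shells[d].l), nsph(se.shells[c].l), nsph(se.shells[b].l), nsph(se.shells[a].l));
  // stored row-major [a][b][c][d]; R dim attribute above reverses -> give R
  // column-major dims (d,c,b,a); the R wrapper apermutes to (a,b,c,d).
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_schwarz(List env) {
  ShellEnv se = read_env(env);
  int nshell = se.shells.size();
  NumericMatrix Q(nshell, nshell);
  std::vector<double> blk;
  for (int a = 0; a < nshell; ++a)
    for (int b = a; b < nshell; ++b) {
      eri_quartet_sph(se, a, b, a, b, false, blk);
      int ma = nsph(se.shells[a].l), mb = nsph(se.shells[b].l);
      double mx = 0.0;
      for (int i = 0; i < ma; ++i)
        for (int j = 0; j < mb; ++j) {
          // diagonal element (ij|ij) of the quartet block
          double vv = blk[(((size_t)i * mb + j) * ma + i) * mb + j];
          if (vv > mx) mx = vv;
        }
      double q = std::sqrt(std::max(mx, 0.0));
      Q(a, b) = q; Q(b, a) = q;
    }
  return Q;
}

// canonical permutations of a quartet, as axis orders
static const int PERMS[8][4] = {
  {0, 1, 2, 3}, {1, 0, 2, 3}, {0, 1, 3, 2}, {1, 0, 3, 2},
  {2, 3, 0, 1}, {3, 2, 0, 1}, {2, 3, 1, 0}, {3, 2, 1, 0}};

// [[Rcpp::export]]
List cpp_build_jk(List env, NumericMatrix P, NumericMatrix Q,
                  double tol, double factor, bool mixed) {
  ShellEnv se = read_env(env);
  int nshell = se.shells.size(), n = se.nao;
  NumericMatrix J(n, n), K(n, n);
  int ncls = (LMAX + 1) * (LMAX + 1) * (LMAX + 1) * (LMAX + 1);
  IntegerMatrix cls(ncls, 3);  // columns: skip, single, double
  std::vector<double> blk;
  std::vector<int> dims(4), off(4);
  for (int a = 0; a < nshell; ++a)
    for (int b = 0; b <= a; ++b) {
      double qab = Q(a, b);
      for (int c = 0; c <= a; ++c) {
        int dmax = (c == a) ? b : c;
        for (int d = 0; d <= dmax; ++d) {
          double bound = qab * Q(c, d);
          int cid = ((se.shells[a].l * (LMAX + 1) + se.shells[b].l) * (LMAX + 1) +
                     se.shells[c].l) * (LMAX + 1) + se.shells[d].l;
          int cl;  // 0 skip, 1 single, 2 double
          if (bound < tol) cl = 0;
          else if (mixed && bound < tol * factor) cl = 1;
          else cl = 2;
          cls(cid, cl) += 1;
          if (cl == 0) continue;
          eri_quartet_sph(se, a, b, c, d, cl == 1, blk);
          int sh[4] = {a, b, c, d};
          int nA = nsph(se.shells[a].l), nB = nsph(se.shells[b].l);
          int nC = nsph(se.shells[c].l), nD = nsph(se.shells[d].l);
          int nd_[4] = {nA, nB, nC, nD};
          std::set<std::array<int, 4>> seen;
          for (int pi = 0; pi < 8; ++pi) {
            const int* ax = PERMS[pi];
            std::array<int, 4> tup = {sh[ax[0]], sh[ax[1]], sh[ax[2]], sh[ax[3]]};
            if (!seen.insert(tup).second) continue;
            int n0 = nd_[ax[0]], n1 = nd_[ax[1]], n2 = nd_[ax[2]], n3 = nd_[ax[3]];
            int o0 = se.ao_off[tup[0]], o1 = se.ao_off[tup[1]];
            int o2 = se.ao_off[tup[2]], o3 = se.ao_off[tup[3]];
            int q_[4];
            for (int p0 = 0; p0 < n0; ++p0)
              for (int p1 = 0; p1 < n1; ++p1)
                for (int p2 = 0; p2 < n2; ++p2)
                  for (int p3 = 0; p3 < n3; ++p3) {
                    q_[ax[0]] = p0; q_[ax[1]] = p1; q_[ax[2]] = p2; q_[ax[3]] = p3;
                    double I = blk[(((size_t)q_[0] * nB + q_[1]) * nC + q_[2]) * nD + q_[3]];
                    J(o0 + p0, o1 + p1) += P(o2 + p2, o3 + p3) * I;
                    K(o0 + p0, o2 + p2) += P(o1 + p1, o3 + p3) * I;
                  }
          }
        }
      }
    }
  return List::create(_["J"] = J, _["K"] = K, _["class_counts"] = cls);
}

// [[Rcpp::export]]
NumericVector cpp_eri_dense(List env) {
  ShellEnv se = read_env(env);
  int nshell = se.shells.size(), n = se.nao;
  NumericVector out((R_xlen_t)n * n * n * n);  // R array dims (n,n,n,n) col-major
  std::vector<double> blk;
  auto put = [&](int mu, int nu, int la, int si, double v) {
    out[((R_xlen_t)si * n * n * n) + ((R_xlen_t)la * n * n) + ((R_xlen_t)nu * n) + mu] = v;
  };
  for (int a = 0; a < nshell; ++a)
    for (int b = 0; b <= a; ++b)
      for (int c = 0; c <= a; ++c) {
        int dmax = (c == a) ? b : c;
        for (int d = 0; d <= dmax; ++d) {
          eri_quartet_sph(se, a, b, c, d, false, blk);
          int nA = nsph(se.shells[a].l), nB = nsph(se.shells[b].l);
          int nC = nsph(se.shells[c].l), nD = nsph(se.shells[d].l);
          int oA = se.ao_off[a], oB = se.ao_off[b], oC = se.ao_off[c], oD = se.ao_off[d];
          for (int i = 0; i < nA; ++i)
            for (int j = 0; j < nB; ++j)
              for (int k = 0; k < nC; ++k)
                for (int l = 0; l < nD; ++l) {
                  double v = blk[(((size_t)i * nB + j) * nC + k) * nD + l];
                  int mu = oA + i, nu = oB + j, lam = oC + k, sig = oD + l;
                  put(mu, nu, lam, sig, v); put(nu, mu, lam, sig, v);
                  put(mu, nu, sig, lam, v); put(nu, mu, sig, lam, v);
                  put(lam, sig, mu, nu, v); put(sig, lam, mu, nu, v);
                  put(lam, sig, nu, mu, v); put(sig, lam, nu, mu, v);
                }
        }
      }
  out.attr("dim") = IntegerVector::create(n, n, n, n);
  return out;
}

// ------------------------------------------------------------- AO on the grid
// [[Rcpp::export]]
List cpp_eval_ao(List env, NumericMatrix pts, bool deriv, NumericVector cutoff) {
  ShellEnv se = read_env(env);
  int np = pts.nrow(), n = se.nao, nshell = se.shells.size();
  NumericMatrix AO(np, n);
  NumericMatrix DX(deriv ? np : 1, deriv ? n : 1);
  NumericMatrix DY(deriv ? np : 1, deriv ? n : 1);
  NumericMatrix DZ(deriv ? np : 1, deriv ? n : 1);
  for (int s = 0; s < nshell; ++s) {
    const Shell& sh = se.shells[s];
    CartList cl = cart_list(sh.l);
    int nc = ncart(sh.l), ms = nsph(sh.l);
    const NumericMatrix& T = se.trans[sh.l];
    double rc = cutoff[s], rc2 = (R_finite(rc) ? rc * rc : R_PosInf);
    std::vector<double> cart(nc), cdx(nc), cdy(nc), cdz(nc);
    std::vector<double> powx(sh.l + 2), powy(sh.l + 2), powz(sh.l + 2);
    for (int g = 0; g < np; ++g) {
      double x = pts(g, 0) - sh.cx, y = pts(g, 1) - sh.cy, z = pts(g, 2) - sh.cz;
      double r2 = x * x + y * y + z * z;
      if (r2 > rc2) continue;
      double rad = 0.0, drad = 0.0;  // radial contraction and d/d(r2) part
      for (size_t p = 0; p < sh.exps.size(); ++p) {
        double e = sh.coefs[p] * std::exp(-sh.exps[p] * r2);
        rad += e;
        drad += -2.0 * sh.exps[p] * e;
      }
      powx[0] = powy[0] = powz[0] = 1.0;
      for (int i = 1; i <= sh.l + 1; ++i) {
        powx[i] = powx[i - 1] * x; powy[i] = powy[i - 1] * y; powz[i] = powz[i - 1] * z;
      }
      for (int k = 0; k < nc; ++k) {
        int ax = cl.lx[k], ay = cl.ly[k], az = cl.lz[k];
        double mono = powx[ax] * powy[ay] * powz[az];
        cart[k] = mono * rad;
        if (deriv) {
          double gx = (ax > 0 ? ax * powx[ax - 1] * powy[ay] * powz[az] : 0.0) * rad +
                      mono * drad * x;
          double gy = (ay > 0 ? ay * powy[ay - 1] * powx[ax] * powz[az] : 0.0) * rad +
                      mono * drad * y;
          double gz = (az > 0 ? az * powz[az - 1] * powx[ax] * powy[ay] : 0.0) * rad +
                      mono * drad * z;
          cdx[k] = gx; cdy[k] = gy; cdz[k] = gz;
        }
      }
      for (int m = 0; m < ms; ++m) {
        double v = 0.0, vx = 0.0, vy = 0.0, vz = 0.0;
        for (int k = 0; k < nc; ++k) {
          double t = T(k, m);
          if (t == 0.0) continue;
          v += t * cart[k];
          if (deriv) { vx += t * cdx[k]; vy += t * cdy[k]; vz += t * cdz[k]; }
        }
        int col = se.ao_off[s] + m;
        AO(g, col) = v;
        if (deriv) { DX(g, col) = vx; DY(g, col) = vy; DZ(g, col) = vz; }
      }
    }
  }
  if (deriv)
    return List::create(_["ao"] = AO, _["dx"] = DX, _["dy"] = DY, _["dz"] = DZ);
  return List::create(_["ao"] = AO);
}
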