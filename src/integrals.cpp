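// Obara-Saika integral engine over contracted Cartesian Gaussians (s, p, d).
//
// Shells arrive from R as flat vectors (l, atom, ptr, nprim) indexing into
// shared exponent/coefficient arrays.  Coefficients are expected to already
// contain primitive + contracted normalization for the (l,0,0) component;
// per-component double-factorial corrections are applied here.
//
// ERIs are stored packed over canonical compound indices
//   ij = i(i+1)/2 + j (i >= j),  idx = ij(ij+1)/2 + kl (ij >= kl)
// which realizes the 8-fold permutational symmetry exactly by storage.

#include <Rcpp.h>
#include <cmath>
#include <cstring>
#include <vector>
using namespace Rcpp;

static const int MAXL = 4;              // highest total angular momentum in HRR bra/ket
static const int NCOMP_CUM[6] = {0, 1, 4, 10, 20, 35}; // cumulative #components up to l-1

static inline int ncomp(int l) { return (l + 1) * (l + 2) / 2; }

// component index within its own l block, enumeration lx descending, then ly
static inline int comp_local(int lx, int ly, int lz) {
  int l = lx + ly + lz;
  int idx = 0;
  for (int x = l; x > lx; --x) idx += (l - x + 1);
  idx += (l - lx - ly);
  return idx;
}
// absolute component index across l = 0..4
static inline int cidx(int lx, int ly, int lz) {
  return NCOMP_CUM[lx + ly + lz] + comp_local(lx, ly, lz);
}

static inline double dfact(int n) {            // (n)!! with (-1)!! = 1
  double r = 1.0;
  for (int k = n; k > 1; k -= 2) r *= k;
  return r;
}

// per-component normalization correction relative to the (l,0,0) component
static inline double comp_factor(int lx, int ly, int lz) {
  int l = lx + ly + lz;
  return std::sqrt(dfact(2 * l - 1) /
                   (dfact(2 * lx - 1) * dfact(2 * ly - 1) * dfact(2 * lz - 1)));
}

// ---------------------------------------------------------------- Boys F_m(T)
// series + downward recursion for small T, asymptotic upward for large T
static void boys(double T, int mmax, double *F) {
  if (T < 1e-13) {
    for (int m = 0; m <= mmax; ++m) F[m] = 1.0 / (2.0 * m + 1.0) - T / (2.0 * m + 3.0);
    return;
  }
  if (T > 33.0) {
    double eT = (T < 700.0) ? std::exp(-T) : 0.0;
    F[0] = 0.5 * std::sqrt(M_PI / T);
    for (int m = 0; m < mmax; ++m) F[m + 1] = ((2.0 * m + 1.0) * F[m] - eT) / (2.0 * T);
    return;
  }
  double term = 1.0 / (2.0 * mmax + 1.0), s = term;
  for (int i = 1; i < 400; ++i) {
    term *= 2.0 * T / (2.0 * mmax + 2.0 * i + 1.0);
    s += term;
    if (term < 1e-16 * s) break;
  }
  double eT = std::exp(-T);
  F[mmax] = s * eT;
  for (int m = mmax; m > 0; --m) F[m - 1] = (2.0 * T * F[m] + eT) / (2.0 * m - 1.0);
}

// [[Rcpp::export(name = ".boys_cpp")]]
NumericVector boys_cpp(NumericVector T, int m) {
  NumericVector out(T.size());
  std::vector<double> F(m + 1);
  for (R_xlen_t i = 0; i < T.size(); ++i) {
    boys(T[i], m, F.data());
    out[i] = F[m];
  }
  return out;
}

// ------------------------------------------------------------- shell helpers
struct ShellSet {
  std::vector<int> l, atom, ptr, nprim, off; // off = first basis index
  std::vector<double> exps, coefs;
  NumericMatrix coords; // natom x 3 (bohr)
  int nbf;
  ShellSet(List sh, NumericMatrix xyz) : coords(xyz) {
    IntegerVector L = sh["l"], A = sh["atom"], P = sh["ptr"], NP = sh["nprim"];
    NumericVector E = sh["exps"], C = sh["coefs"];
    l.assign(L.begin(), L.end());
    atom.assign(A.begin(), A.end());
    ptr.assign(P.begin(), P.end());
    nprim.assign(NP.begin(), NP.end());
    exps.assign(E.begin(), E.end());
    coefs.assign(C.begin(), C.end());
    off.resize(l.size());
    nbf = 0;
    for (size_t s = 0; s < l.size(); ++s) { off[s] = nbf; nbf += ncomp(l[s]); }
  }
  int nshell() const { return (int)l.size(); }
  void center(int s, double *R) const {
    for (int k = 0; k < 3; ++k) R[k] = coords(atom[s], k);
  }
};

// enumerate components of shell with angular momentum l into lx[], ly[], lz[]
static void comps_of(int l, int *lx, int *ly, int *lz) {
  int n = 0;
  for (int x = l; x >= 0; --x)
    for (int y = l - x; y >= 0; --y) {
      lx[n] = x; ly[n] = y; lz[n] = l - x - y; ++n;
    }
}

// ------------------------------------------------ 1-D overlap recursion table
// fills S[i][j] for i<=imax, j<=jmax over one Cartesian direction
static void ovlp1d(double XPA, double XPB, double p, int imax, int jmax,
                   double S[7][7]) {
  double inv2p = 0.5 / p;
  S[0][0] = 1.0; // the sqrt(pi/p)*exp(-mu*AB^2) prefactor is applied once in 3D
  for (int i = 1; i <= imax; ++i)
    S[i][0] = XPA * S[i - 1][0] + (i - 1) * inv2p * (i >= 2 ? S[i - 2][0] : 0.0);
  for (int j = 1; j <= jmax; ++j)
    for (int i = 0; i <= imax; ++i) {
      double v = XPB * S[i][j - 1];
      if (i >= 1) v += i * inv2p * S[i - 1][j - 1];
      if (j >= 2) v += (j - 1) * inv2p * S[i][j - 2];
      S[i][j] = v;
    }
}

// ------------------------------------------------------- overlap and kinetic
// [[Rcpp::export(name = ".os_st_cpp")]]
List os_st_cpp(List sh, NumericMatrix xyz) {
  ShellSet S(sh, xyz);
  int n = S.nbf;
  NumericMatrix Smat(n, n), Tmat(n, n);
  int lx1[6], ly1[6], lz1[6], lx2[6], ly2[6], lz2[6];
  for (int s1 = 0; s1 < S.nshell(); ++s1)
    for (int s2 = 0; s2 <= s1; ++s2) {
      int l1 = S.l[s1], l2 = S.l[s2];
      int n1 = ncomp(l1), n2 = ncomp(l2);
      comps_of(l1, lx1, ly1, lz1);
      comps_of(l2, lx2, ly2, lz2);
      double A[3], B[3];
      S.center(s1, A); S.center(s2, B);
      double AB2 = 0;
      for (int k = 0; k < 3; ++k) AB2 += (A[k] - B[k]) * (A[k] - B[k]);
      std::vector<double> sacc(n1 * n2, 0.0), tacc(n1 * n2, 0.0);
      for (int p1 = 0; p1 < S.nprim[s1]; ++p1)
        for (int p2 = 0; p2 < S.nprim[s2]; ++p2) {
          double a = S.exps[S.ptr[s1] + p1], b = S.exps[S.ptr[s2] + p2];
          double cc = S.coefs[S.ptr[s1] + p1] * S.coefs[S.ptr[s2] + p2];
          double p = a + b, mu = a * b / p;
          double pref = std::pow(M_PI / p, 1.5) * std::exp(-mu * AB2) * cc;
          double P[3];
          for (int k = 0; k < 3; ++k) P[k] = (a * A[k] + b * B[k]) / p;
          double sx[7][7], sy[7][7], sz[7][7];
          ovlp1d(P[0] - A[0], P[0] - B[0], p, l1, l2 + 2, sx);
          ovlp1d(P[1] - A[1], P[1] - B[1], p, l1, l2 + 2, sy);
          ovlp1d(P[2] - A[2], P[2] - B[2], p, l1, l2 + 2, sz);
          for (int c1 = 0; c1 < n1; ++c1)
            for (int c2 = 0; c2 < n2; ++c2) {
              int i1 = lx1[c1], j1 = ly1[c1], k1 = lz1[c1];
              int i2 = lx2[c2], j2 = ly2[c2], k2 = lz2[c2];
              double Sx = sx[i1][i2], Sy = sy[j1][j2], Sz = sz[k1][k2];
              // 1-D kinetic via overlap ladder in the ket exponent b
              double Tx = -2.0 * b * b * sx[i1][i2 + 2] + b * (2 * i2 + 1) * Sx
                          - 0.5 * i2 * (i2 - 1) * (i2 >= 2 ? sx[i1][i2 - 2] : 0.0);
              double Ty = -2.0 * b * b * sy[j1][j2 + 2] + b * (2 * j2 + 1) * Sy
                          - 0.5 * j2 * (j2 - 1) * (j2 >= 2 ? sy[j1][j2 - 2] : 0.0);
              double Tz = -2.0 * b * b * sz[k1][k2 + 2] + b * (2 * k2 + 1) * Sz
                          - 0.5 * k2 * (k2 - 1) * (k2 >= 2 ? sz[k1][k2 - 2] : 0.0);
              sacc[c1 * n2 + c2] += pref * Sx * Sy * Sz;
              tacc[c1 * n2 + c2] += pref * (Tx * Sy * Sz + Sx * Ty * Sz + Sx * Sy * Tz);
            }
        }
      for (int c1 = 0; c1 < n1; ++c1)
        for (int c2 = 0; c2 < n2; ++c2) {
          double f = comp_factor(lx1[c1], ly1[c1], lz1[c1]) *
                     comp_factor(lx2[c2], ly2[c2], lz2[c2]);
          int i = S.off[s1] + c1, j = S.off[s2] + c2;
          Smat(i, j) = Smat(j, i) = f * sacc[c1 * n2 + c2];
          Tmat(i, j) = Tmat(j, i) = f * tacc[c1 * n2 + c2];
        }
    }
  return List::create(_["S"] = Smat, _["T"] = Tmat);
}

// ------------------------------------------------------------------- dipole
// position-operator integrals about `origin`; M(d) = M(0) - d (x) S identity
// [[Rcpp::export(name = ".os_dipole_cpp")]]
List os_dipole_cpp(List sh, NumericMatrix xyz, NumericVector origin) {
  ShellSet S(sh, xyz);
  int n = S.nbf;
  NumericMatrix Mx(n, n), My(n, n), Mz(n, n);
  int lx1[6], ly1[6], lz1[6], lx2[6], ly2[6], lz2[6];
  for (int s1 = 0; s1 < S.nshell(); ++s1)
    for (int s2 = 0; s2 <= s1; ++s2) {
      int l1 = S.l[s1], l2 = S.l[s2];
      int n1 = ncomp(l1), n2 = ncomp(l2);
      comps_of(l1, lx1, ly1, lz1);
      comps_of(l2, lx2, ly2, lz2);
      double A[3], B[3];
      S.center(s1, A); S.center(s2, B);
      double AB2 = 0;
      for (int k = 0; k < 3; ++k) AB2 += (A[k] - B[k]) * (A[k] - B[k]);
      std::vector<double> acc(3 * n1 * n2, 0.0);
      for (int p1 = 0; p1 < S.nprim[s1]; ++p1)
        for (int p2 = 0; p2 < S.nprim[s2]; ++p2) {
          double a = S.exps[S.ptr[s1] + p1], b = S.exps[S.ptr[s2] + p2];
          double cc = S.coefs[S.ptr[s1] + p1] * S.coefs[S.ptr[s2] + p2];
          double p = a + b, mu = a * b / p;
          double pref = std::pow(M_PI / p, 1.5) * std::exp(-mu * AB2) * cc;
          double P[3];
          for (int k = 0; k < 3; ++k) P[k] = (a * A[k] + b * B[k]) / p;
          double sx[7][7], sy[7][7], sz[7][7];
          ovlp1d(P[0] - A[0], P[0] - B[0], p, l1 + 1, l2, sx);
          ovlp1d(P[1] - A[1], P[1] - B[1], p, l1 + 1, l2, sy);
          ovlp1d(P[2] - A[2], P[2] - B[2], p, l1 + 1, l2, sz);
          for (int c1 = 0; c1 < n1; ++c1)
            for (int c2 = 0; c2 < n2; ++c2) {
              int i1 = lx1[c1], j1 = ly1[c1], k1 = lz1[c1];
              int i2 = lx2[c2], j2 = ly2[c2], k2 = lz2[c2];
              double Sx = sx[i1][i2], Sy = sy[j1][j2], Sz = sz[k1][k2];
              // <i|(x - Ox)|j> = S_{i+1,j} + (Ax - Ox) S_{ij}
              double Dx = sx[i1 + 1][i2] + (A[0] - origin[0]) * Sx;
              double Dy = sy[j1 + 1][j2] + (A[1] - origin[1]) * Sy;
              double Dz = sz[k1 + 1][k2] + (A[2] - origin[2]) * Sz;
              int o = (c1 * n2 + c2) * 3;
              acc[o]     += pref * Dx * Sy * Sz;
              acc[o + 1] += pref * Sx * Dy * Sz;
              acc[o + 2] += pref * Sx * Sy * Dz;
            }
        }
      for (int c1 = 0; c1 < n1; ++c1)
        for (int c2 = 0; c2 < n2; ++c2) {
          double f = comp_factor(lx1[c1], ly1[c1], lz1[c1]) *
                     comp_factor(lx2[c2], ly2[c2], lz2[c2]);
          int i = S.off[s1] + c1, j = S.off[s2] + c2, o = (c1 * n2 + c2) * 3;
          Mx(i, j) = Mx(j, i) = f * acc[o];
          My(i, j) = My(j, i) = f * acc[o + 1];
          Mz(i, j) = Mz(j, i) = f * acc[o + 2];
        }
    }
  return List::create(_["x"] = Mx, _["y"] = My, _["z"] = Mz);
}

// -------------------------------------------------- nuclear/charge attraction
struct NucCtx {
  double PA[3], PB[3], PC[3], p;
  double F[10];          // prefactor * Boys, indexed by m
  double memo[10][10][9];
  bool have[10][10][9];
};

static double nuc_rec(NucCtx &c, int ax, int ay, int az, int bx, int by, int bz, int m) {
  if (ax == 0 && ay == 0 && az == 0 && bx == 0 && by == 0 && bz == 0) return c.F[m];
  int ia = cidx(ax, ay, az), ib = cidx(bx, by, bz);
  if (c.have[ia][ib][m]) return c.memo[ia][ib][m];
  double inv2p = 0.5 / c.p, v;
  int a[3] = {ax, ay, az}, b[3] = {bx, by, bz};
  if (ax + ay + az > 0) {
    int i = (ax > 0) ? 0 : (ay > 0 ? 1 : 2);
    a[i] -= 1;
    v = c.PA[i] * nuc_rec(c, a[0], a[1], a[2], bx, by, bz, m)
      - c.PC[i] * nuc_rec(c, a[0], a[1], a[2], bx, by, bz, m + 1);
    if (a[i] > 0) {
      int aa[3] = {a[0], a[1], a[2]}; aa[i] -= 1;
      v += a[i] * inv2p * (nuc_rec(c, aa[0], aa[1], aa[2], bx, by, bz, m)
                         - nuc_rec(c, aa[0], aa[1], aa[2], bx, by, bz, m + 1));
    }
    if (b[i] > 0) {
      int bb[3] = {bx, by, bz}; bb[i] -= 1;
      v += b[i] * inv2p * (nuc_rec(c, a[0], a[1], a[2], bb[0], bb[1], bb[2], m)
                         - nuc_rec(c, a[0], a[1], a[2], bb[0], bb[1], bb[2], m + 1));
    }
  } else {
    int i = (bx > 0) ? 0 : (by > 0 ? 1 : 2);
    b[i] -= 1;
    v = c.PB[i] * nuc_rec(c, 0, 0, 0, b[0], b[1], b[2], m)
      - c.PC[i] * nuc_rec(c, 0, 0, 0, b[0], b[1], b[2], m + 1);
    if (b[i] > 0) {
      int bb[3] = {b[0], b[1], b[2]}; bb[i] -= 1;
      v += b[i] * inv2p * (nuc_rec(c, 0, 0, 0, bb[0], bb[1], bb[2], m)
                         - nuc_rec(c, 0, 0, 0, bb[0], bb[1], bb[2], m + 1));
    }
  }
  c.memo[ia][ib][m] = v;
  c.have[ia][ib][m] = true;
  return v;
}

// V_{mu,nu} = -sum_A q_A <mu| 1/|r-R_A| |nu>   (attractive for q_A > 0)
// [[Rcpp::export(name = ".os_nuclear_cpp")]]
NumericMatrix os_nuclear_cpp(List sh, NumericMatrix xyz,
                             NumericVector q, NumericMatrix qpos) {
  ShellSet S(sh, xyz);
  int n = S.nbf, nq = q.size();
  NumericMatrix V(n, n);
  int lx1[6], ly1[6], lz1[6], lx2[6], ly2[6], lz2[6];
  NucCtx ctx;
  for (int s1 = 0; s1 < S.nshell(); ++s1)
    for (int s2 = 0; s2 <= s1; ++s2) {
      int l1 = S.l[s1], l2 = S.l[s2];
      int n1 = ncomp(l1), n2 = ncomp(l2);
      comps_of(l1, lx1, ly1, lz1);
      comps_of(l2, lx2, ly2, lz2);
      double A[3], B[3];
      S.center(s1, A); S.center(s2, B);
      double AB2 = 0;
      for (int k = 0; k < 3; ++k) AB2 += (A[k] - B[k]) * (A[k] - B[k]);
      std::vector<double> acc(n1 * n2, 0.0);
      int mmax = l1 + l2;
      for (int p1 = 0; p1 < S.nprim[s1]; ++p1)
        for (int p2 = 0; p2 < S.nprim[s2]; ++p2) {
          double a = S.exps[S.ptr[s1] + p1], b = S.exps[S.ptr[s2] + p2];
          double cc = S.coefs[S.ptr[s1] + p1] * S.coefs[S.ptr[s2] + p2];
          double p = a + b, mu = a * b / p;
          double P[3];
          for (int k = 0; k < 3; ++k) P[k] = (a * A[k] + b * B[k]) / p;
          double Kab = std::exp(-mu * AB2);
          if (Kab * std::fabs(cc) < 1e-18) continue;
          double pref = 2.0 * M_PI / p * Kab * cc;
          ctx.p = p;
          for (int k = 0; k < 3; ++k) { ctx.PA[k] = P[k] - A[k]; ctx.PB[k] = P[k] - B[k]; }
          for (int iq = 0; iq < nq; ++iq) {
            double PC2 = 0;
            for (int k = 0; k < 3; ++k) {
              ctx.PC[k] = P[k] - qpos(iq, k);
              PC2 += ctx.PC[k] * ctx.PC[k];
            }
            double F[10];
            boys(p * PC2, mmax, F);
            for (int m = 0; m <= mmax; ++m) ctx.F[m] = pref * F[m];
            std::memset(ctx.have, 0, sizeof(ctx.have));
            for (int c1 = 0; c1 < n1; ++c1)
              for (int c2 = 0; c2 < n2; ++c2)
                acc[c1 * n2 + c2] -= q[iq] *
                  nuc_rec(ctx, lx1[c1], ly1[c1], lz1[c1], lx2[c2], ly2[c2], lz2[c2], 0);
          }
        }
      for (int c1 = 0; c1 < n1; ++c1)
        for (int c2 = 0; c2 < n2; ++c2) {
          double f = comp_factor(lx1[c1], ly1[c1], lz1[c1]) *
                     comp_factor(lx2[c2], ly2[c2], lz2[c2]);
          int i = S.off[s1] + c1, j = S.off[s2] + c2;
          V(i, j) = V(j, i) = f * acc[c1 * n2 + c2];
        }
    }
  return V;
}

// ----------------------------------------------------------------------- ERI
struct EriCtx {
  double PA[3], QC[3], WP[3], WQ[3];
  double zeta, eta, rho;
  double F[10];           // base (00|00)^m including all prefactors
  double memo[35][35][10];
  bool have[35][35][10];
};

// (e 0 | f 0)^m vertical recursion
static double vrr(EriCtx &c, int ex, int ey, int ez, int fx, int fy, int fz, int m) {
  if (ex == 0 && ey == 0 && ez == 0 && fx == 0 && fy == 0 && fz == 0) return c.F[m];
  int ie = cidx(ex, ey, ez), jf = cidx(fx, fy, fz);
  if (c.have[ie][jf][m]) return c.memo[ie][jf][m];
  double v;
  int e[3] = {ex, ey, ez}, f[3] = {fx, fy, fz};
  if (ex + ey + ez > 0) {
    int i = (ex > 0) ? 0 : (ey > 0 ? 1 : 2);
    e[i] -= 1;
    v = c.PA[i] * vrr(c, e[0], e[1], e[2], fx, fy, fz, m)
      + c.WP[i] * vrr(c, e[0], e[1], e[2], fx, fy, fz, m + 1);
    if (e[i] > 0) {
      int ee[3] = {e[0], e[1], e[2]}; ee[i] -= 1;
      v += e[i] / (2.0 * c.zeta) *
           (vrr(c, ee[0], ee[1], ee[2], fx, fy, fz, m)
            - c.rho / c.zeta * vrr(c, ee[0], ee[1], ee[2], fx, fy, fz, m + 1));
    }
    if (f[i] > 0) {
      int ff[3] = {fx, fy, fz}; ff[i] -= 1;
      v += f[i] / (2.0 * (c.zeta + c.eta)) *
           vrr(c, e[0], e[1], e[2], ff[0], ff[1], ff[2], m + 1);
    }
  } else {
    int i = (fx > 0) ? 0 : (fy > 0 ? 1 : 2);
    f[i] -= 1;
    v = c.QC[i] * vrr(c, 0, 0, 0, f[0], f[1], f[2], m)
      + c.WQ[i] * vrr(c, 0, 0, 0, f[0], f[1], f[2], m + 1);
    if (f[i] > 0) {
      int ff[3] = {f[0], f[1], f[2]}; ff[i] -= 1;
      v += f[i] / (2.0 * c.eta) *
           (vrr(c, 0, 0, 0, ff[0], ff[1], ff[2], m)
            - c.rho / c.eta * vrr(c, 0, 0, 0, ff[0], ff[1], ff[2], m + 1));
    }
  }
  c.memo[ie][jf][m] = v;
  c.have[ie][jf][m] = true;
  return v;
}

// contracted (e0|f0) accumulated over primitives for one shell quartet
struct QuartetE0F0 {
  double AB[3], CD[3];
  double v[35][35]; // indexed by absolute component index
};

static void quartet_e0f0(const ShellSet &S, int s1, int s2, int s3, int s4,
                         QuartetE0F0 &q) {
  double A[3], B[3], C[3], D[3];
  S.center(s1, A); S.center(s2, B); S.center(s3, C); S.center(s4, D);
  for (int k = 0; k < 3; ++k) { q.AB[k] = A[k] - B[k]; q.CD[k] = C[k] - D[k]; }
  int lab = S.l[s1] + S.l[s2], lcd = S.l[s3] + S.l[s4];
  int mmax = lab + lcd;
  double AB2 = q.AB[0]*q.AB[0] + q.AB[1]*q.AB[1] + q.AB[2]*q.AB[2];
  double CD2 = q.CD[0]*q.CD[0] + q.CD[1]*q.CD[1] + q.CD[2]*q.CD[2];
  std::memset(q.v, 0, sizeof(q.v));
  EriCtx c;
  int lxe[15], lye[15], lze[15], lxf[15], lyf[15], lzf[15];
  for (int p1 = 0; p1 < S.nprim[s1]; ++p1)
    for (int p2 = 0; p2 < S.nprim[s2]; ++p2) {
      double a1 = S.exps[S.ptr[s1] + p1], a2 = S.exps[S.ptr[s2] + p2];
      double zeta = a1 + a2;
      double Kab = std::exp(-a1 * a2 / zeta * AB2);
      double c12 = S.coefs[S.ptr[s1] + p1] * S.coefs[S.ptr[s2] + p2];
      if (std::fabs(c12) * Kab < 1e-18) continue;
      double P[3];
      for (int k = 0; k < 3; ++k) P[k] = (a1 * A[k] + a2 * B[k]) / zeta;
      for (int p3 = 0; p3 < S.nprim[s3]; ++p3)
        for (int p4 = 0; p4 < S.nprim[s4]; ++p4) {
          double a3 = S.exps[S.ptr[s3] + p3], a4 = S.exps[S.ptr[s4] + p4];
          double eta = a3 + a4;
          double Kcd = std::exp(-a3 * a4 / eta * CD2);
          double c34 = S.coefs[S.ptr[s3] + p3] * S.coefs[S.ptr[s4] + p4];
          double cc = c12 * c34;
          if (std::fabs(cc) * Kab * Kcd < 1e-18) continue;
          double Q[3], W[3], PQ2 = 0;
          for (int k = 0; k < 3; ++k) {
            Q[k] = (a3 * C[k] + a4 * D[k]) / eta;
            W[k] = (zeta * P[k] + eta * Q[k]) / (zeta + eta);
            PQ2 += (P[k] - Q[k]) * (P[k] - Q[k]);
          }
          c.zeta = zeta; c.eta = eta;
          c.rho = zeta * eta / (zeta + eta);
          for (int k = 0; k < 3; ++k) {
            c.PA[k] = P[k] - A[k]; c.QC[k] = Q[k] - C[k];
            c.WP[k] = W[k] - P[k]; c.WQ[k] = W[k] - Q[k];
          }
          double pref = 2.0 * std::pow(M_PI, 2.5) /
                        (zeta * eta * std::sqrt(zeta + eta)) * Kab * Kcd * cc;
          double F[10];
          boys(c.rho * PQ2, mmax, F);
          for (int m = 0; m <= mmax; ++m) c.F[m] = pref * F[m];
          std::memset(c.have, 0, sizeof(c.have));
          for (int le = S.l[s1]; le <= lab; ++le) {
            int ne = ncomp(le);
            comps_of(le, lxe, lye, lze);
            for (int lf = S.l[s3]; lf <= lcd; ++lf) {
              int nf = ncomp(lf);
              comps_of(lf, lxf, lyf, lzf);
              for (int ce = 0; ce < ne; ++ce)
                for (int cf = 0; cf < nf; ++cf)
                  q.v[cidx(lxe[ce], lye[ce], lze[ce])][cidx(lxf[cf], lyf[cf], lzf[cf])]
                    += vrr(c, lxe[ce], lye[ce], lze[ce], lxf[cf], lyf[cf], lzf[cf], 0);
            }
          }
        }
    }
}

// HRR: (a b | f 0) from contracted (e0|f0)
static double hrr_ab(const QuartetE0F0 &q, int ax, int ay, int az,
                     int bx, int by, int bz, int jf) {
  if (bx == 0 && by == 0 && bz == 0) return q.v[cidx(ax, ay, az)][jf];
  int i = (bx > 0) ? 0 : (by > 0 ? 1 : 2);
  int b[3] = {bx, by, bz}; b[i] -= 1;
  int a[3] = {ax, ay, az}; a[i] += 1;
  return hrr_ab(q, a[0], a[1], a[2], b[0], b[1], b[2], jf)
       + q.AB[i] * hrr_ab(q, ax, ay, az, b[0], b[1], b[2], jf);
}

// HRR: (a b | c d) from (a b | f 0)
static double hrr_cd(const QuartetE0F0 &q, int ax, int ay, int az,
                     int bx, int by, int bz, int cx, int cy, int cz,
                     int dx, int dy, int dz) {
  if (dx == 0 && dy == 0 && dz == 0)
    return hrr_ab(q, ax, ay, az, bx, by, bz, cidx(cx, cy, cz));
  int i = (dx > 0) ? 0 : (dy > 0 ? 1 : 2);
  int d[3] = {dx, dy, dz}; d[i] -= 1;
  int c[3] = {cx, cy, cz}; c[i] += 1;
  return hrr_cd(q, ax, ay, az, bx, by, bz, c[0], c[1], c[2], d[0], d[1], d[2])
       + q.CD[i] * hrr_cd(q, ax, ay, az, bx, by, bz, cx, cy, cz, d[0], d[1], d[2]);
}

static inline R_xlen_t pair_idx(R_xlen_t i, R_xlen_t j) { // i >= j
  return i * (i + 1) / 2 + j;
}
static inline R_xlen_t canon_idx(R_xlen_t i, R_xlen_t j, R_xlen_t k, R_xlen_t l) {
  R_xlen_t ij = (i >= j) ? pair_idx(i, j) : pair_idx(j, i);
  R_xlen_t kl = (k >= l) ? pair_idx(k, l) : pair_idx(l, k);
  return (ij >= kl) ? (ij * (ij + 1) / 2 + kl) : (kl * (kl + 1) / 2 + ij);
}

// [[Rcpp::export(name = ".os_eri_cpp")]]
List os_eri_cpp(List sh, NumericMatrix xyz, double thresh) {
  ShellSet S(sh, xyz);
  int ns = S.nshell(), n = S.nbf;
  R_xlen_t M = (R_xlen_t)n * (n + 1) / 2;
  NumericVector out(M * (M + 1) / 2);
  QuartetE0F0 q;
  int lx[4][6], ly[4][6], lz[4][6];

  // Cauchy-Schwarz bounds per shell pair: sqrt(max |(ab|ab)|)
  std::vector<double> bound(ns * ns, 0.0);
  for (int s1 = 0; s1 < ns; ++s1)
    for (int s2 = 0; s2 <= s1; ++s2) {
      quartet_e0f0(S, s1, s2, s1, s2, q);
      comps_of(S.l[s1], lx[0], ly[0], lz[0]);
      comps_of(S.l[s2], lx[1], ly[1], lz[1]);
      double mx = 0;
      for (int c1 = 0; c1 < ncomp(S.l[s1]); ++c1)
        for (int c2 = 0; c2 < ncomp(S.l[s2]); ++c2) {
          double v = hrr_cd(q, lx[0][c1], ly[0][c1], lz[0][c1],
                            lx[1][c2], ly[1][c2], lz[1][c2],
                            lx[0][c1], ly[0][c1], lz[0][c1],
                            lx[1][c2], ly[1][c2], lz[1][c2]);
          v *= std::pow(comp_factor(lx[0][c1], ly[0][c1], lz[0][c1]) *
                        comp_factor(lx[1][c2], ly[1][c2], lz[1][c2]), 2);
          if (std::fabs(v) > mx) mx = std::fabs(v);
        }
      bound[s1 * ns + s2] = bound[s2 * ns + s1] = std::sqrt(mx);
    }

  for (int s1 = 0; s1 < ns; ++s1)
    for (int s2 = 0; s2 <= s1; ++s2) {
      int sp12 = pair_idx(s1, s2);
      for (int s3 = 0; s3 <= s1; ++s3)
        for (int s4 = 0; s4 <= s3; ++s4) {
          if (pair_idx(s3, s4) > sp12) continue;
          if (bound[s1 * ns + s2] * bound[s3 * ns + s4] < thresh) continue;
          quartet_e0f0(S, s1, s2, s3, s4, q);
          int sl[4] = {s1, s2, s3, s4};
          int nc[4];
          for (int t = 0; t < 4; ++t) {
            nc[t] = ncomp(S.l[sl[t]]);
            comps_of(S.l[sl[t]], lx[t], ly[t], lz[t]);
          }
          for (int c1 = 0; c1 < nc[0]; ++c1) {
            double f1 = comp_factor(lx[0][c1], ly[0][c1], lz[0][c1]);
            for (int c2 = 0; c2 < nc[1]; ++c2) {
              double f2 = f1 * comp_factor(lx[1][c2], ly[1][c2], lz[1][c2]);
              for (int c3 = 0; c3 < nc[2]; ++c3) {
                double f3 = f2 * comp_factor(lx[2][c3], ly[2][c3], lz[2][c3]);
                for (int c4 = 0; c4 < nc[3]; ++c4) {
                  double f4 = f3 * comp_factor(lx[3][c4], ly[3][c4], lz[3][c4]);
                  double v = f4 * hrr_cd(q,
                      lx[0][c1], ly[0][c1], lz[0][c1],
                      lx[1][c2], ly[1][c2], lz[1][c2],
                      lx[2][c3], ly[2][c3], lz[2][c3],
                      lx[3][c4], ly[3][c4], lz[3][c4]);
                  out[canon_idx(S.off[s1] + c1, S.off[s2] + c2,
                                S.off[s3] + c3, S.off[s4] + c4)] = v;
                }
              }
            }
          }
        }
    }
  return List::create(_["values"] = out, _["nbf"] = n,
                      _["screening_threshold"] = thresh);
}

// vectorized packed lookup (0-based indices)
// [[Rcpp::export(name = ".eri_get_cpp")]]
NumericVector eri_get_cpp(NumericVector packed, IntegerVector i, IntegerVector j,
                          IntegerVector k, IntegerVector l) {
  R_xlen_t nn = i.size();
  NumericVector out(nn);
  for (R_xlen_t t = 0; t < nn; ++t)
    out[t] = packed[canon_idx(i[t], j[t], k[t], l[t])];
  return out;
}

// Coulomb matrix J_{ij} = sum_{kl} (ij|kl) P_{kl} from packed unique list
// [[Rcpp::export(name = ".eri_coulomb_cpp")]]
NumericMatrix eri_coulomb_cpp(NumericVector packed, NumericMatrix P) {
  int n = P.nrow();
  NumericMatrix J(n, n);
  R_xlen_t idx = 0;
  for (int i = 0; i < n; ++i)
    for (int j = 0; j <= i; ++j) {
      R_xlen_t ij = pair_idx(i, j);
      for (int k = 0; k <= i; ++k)
        for (int l = 0; l <= k; ++l) {
          if (pair_idx(k, l) > ij) break;
          double v = packed[idx++];
          if (v != 0.0) {
            double pkl = P(k, l) * ((k == l) ? 1.0 : 2.0);
            double pij = P(i, j) * ((i == j) ? 1.0 : 2.0);
            J(i, j) += v * pkl;
            if (ij != pair_idx(k, l)) J(k, l) += v * pij;
          }
        }
    }
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < i; ++j) J(j, i) = J(i, j);
  return J;
}
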