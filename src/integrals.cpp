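// Gaussian-basis one- and two-electron integrals (McMurchie-Davidson scheme)
// for the compact Hartree-Fock engine. All quantities in atomic units.
// Basis functions are individually normalized Cartesian contracted Gaussians,
// passed as flat arrays: per-bf angular momenta (i,j,k), center, and a slice
// [prim_start[b], prim_start[b+1]) into the primitive exponent/coefficient
// arrays (coefficients include all normalization constants).

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// ---------------------------------------------------------------- Boys F_m
// reference evaluation (series + downward recursion / asymptotic upward)
static void boys_ref(int m, double T, double* F) {
  if (T < 1e-13) {
    for (int i = 0; i <= m; ++i) F[i] = 1.0 / (2.0 * i + 1.0);
    return;
  }
  if (T > 35.0) {
    F[0] = 0.5 * std::sqrt(M_PI / T);
    double expT = (T < 700.0) ? std::exp(-T) : 0.0;
    for (int i = 0; i < m; ++i) F[i + 1] = ((2 * i + 1) * F[i] - expT) / (2.0 * T);
    return;
  }
  double expT = std::exp(-T);
  double sum = 1.0 / (2.0 * m + 1.0), term = sum;
  for (int k = 1; k < 10000; ++k) {
    term *= 2.0 * T / (2.0 * m + 2.0 * k + 1.0);
    sum += term;
    if (term < 1e-17 * sum) break;
  }
  F[m] = expT * sum;
  for (int i = m; i > 0; --i) F[i - 1] = (2.0 * T * F[i] + expT) / (2.0 * i - 1.0);
}

// tabulated evaluation: 6-term Taylor expansion of F_mmax on a 0.05 grid,
// then downward recursion. Table covers m <= BOYS_MMAX, T <= 35.
#define BOYS_MMAX 8
#define BOYS_MTAB (BOYS_MMAX + 7)
#define BOYS_NT 701
static double boys_tab[BOYS_NT][BOYS_MTAB + 1];
static bool boys_ready = false;
static void boys_init() {
  for (int it = 0; it < BOYS_NT; ++it)
    boys_ref(BOYS_MTAB, it * 0.05, boys_tab[it]);
  boys_ready = true;
}

static inline void boys(int m, double T, double* F) {
  if (T >= 35.0 || m > BOYS_MMAX) { boys_ref(m, T, F); return; }
  if (!boys_ready) boys_init();
  const int it = (int)(T * 20.0 + 0.5);
  const double d = T - it * 0.05;
  const double* tb = boys_tab[it];
  // F_m(T) = sum_k F_{m+k}(T0) (-d)^k / k!
  double fm = tb[m];
  double dk = -d;
  fm += tb[m + 1] * dk; dk *= -d * 0.5;
  fm += tb[m + 2] * dk; dk *= -d / 3.0;
  fm += tb[m + 3] * dk; dk *= -d * 0.25;
  fm += tb[m + 4] * dk; dk *= -d * 0.2;
  fm += tb[m + 5] * dk; dk *= -d / 6.0;
  fm += tb[m + 6] * dk;
  F[m] = fm;
  if (m > 0) {
    const double expT = std::exp(-T);
    for (int i = m; i > 0; --i) F[i - 1] = (2.0 * T * F[i] + expT) / (2.0 * i - 1.0);
  }
}

// ------------------------------------------------- 1D Hermite E coefficients
// E[(i*(jmax+1)+j)*tdim + t]; E(0,0,0) carries exp(-mu*AB^2) for this dim.
static void e_table(int imax, int jmax, double a, double b, double AB,
                    std::vector<double>& E) {
  const double p = a + b, mu = a * b / p, oo2p = 0.5 / p;
  const double PA = -b / p * AB, PB = a / p * AB;  // P - A, P - B with AB = A-B
  const int tdim = imax + jmax + 1, jd = jmax + 1;
  E.assign((imax + 1) * jd * tdim, 0.0);
  auto at = [&](int i, int j, int t) -> double& { return E[(i * jd + j) * tdim + t]; };
  at(0, 0, 0) = std::exp(-mu * AB * AB);
  for (int i = 1; i <= imax; ++i)
    for (int t = 0; t <= i; ++t) {
      double v = 0.0;
      if (t > 0) v += oo2p * at(i - 1, 0, t - 1);
      v += PA * at(i - 1, 0, t);
      if (t + 1 <= i - 1) v += (t + 1) * at(i - 1, 0, t + 1);
      at(i, 0, t) = v;
    }
  for (int j = 1; j <= jmax; ++j)
    for (int i = 0; i <= imax; ++i)
      for (int t = 0; t <= i + j; ++t) {
        double v = 0.0;
        if (t > 0) v += oo2p * at(i, j - 1, t - 1);
        v += PB * at(i, j - 1, t);
        if (t + 1 <= i + j - 1) v += (t + 1) * at(i, j - 1, t + 1);
        at(i, j, t) = v;
      }
}

// ------------------------------------------------------- Hermite R_{t,u,v}
// R0[(t*du + u)*dv + v]; caller provides a buffer of size
// (tmax+1)*(umax+1)*(vmax+1); internal scratch is stack-allocated
// (supports total order <= 12).
#define RT_MAXORD 12
static void r_tensor(int tmax, int umax, int vmax, double alpha,
                     double X, double Y, double Z, double* R0) {
  const int N = tmax + umax + vmax;
  double F[RT_MAXORD + 1];
  boys(N, alpha * (X * X + Y * Y + Z * Z), F);
  const int du = umax + 1, dv = vmax + 1;
  const int sz = (tmax + 1) * du * dv;
  double Rn[(RT_MAXORD + 1) * 13 * 13];  // generous upper bound reused below
  // layout: Rn[n*sz + (t*du+u)*dv + v]
  double m2a = 1.0;
  for (int n = 0; n <= N; ++n) { Rn[n * sz] = m2a * F[n]; m2a *= -2.0 * alpha; }
  for (int v = 0; v <= vmax; ++v)
    for (int u = 0; u <= umax; ++u)
      for (int t = 0; t <= tmax; ++t) {
        if (t + u + v == 0) continue;
        const int base = (t * du + u) * dv + v;
        for (int n = 0; n <= N - t - u - v; ++n) {
          double val;
          if (t > 0) {
            val = X * Rn[(n + 1) * sz + ((t - 1) * du + u) * dv + v];
            if (t > 1) val += (t - 1) * Rn[(n + 1) * sz + ((t - 2) * du + u) * dv + v];
          } else if (u > 0) {
            val = Y * Rn[(n + 1) * sz + (t * du + u - 1) * dv + v];
            if (u > 1) val += (u - 1) * Rn[(n + 1) * sz + (t * du + u - 2) * dv + v];
          } else {
            val = Z * Rn[(n + 1) * sz + (t * du + u) * dv + v - 1];
            if (v > 1) val += (v - 1) * Rn[(n + 1) * sz + (t * du + u) * dv + v - 2];
          }
          Rn[n * sz + base] = val;
        }
      }
  for (int q = 0; q < sz; ++q) R0[q] = Rn[q];
}

// --------------------------------------------------------- basis bookkeeping
struct Shells {
  IntegerMatrix ijk;       // nbf x 3
  NumericMatrix cen;       // nbf x 3
  IntegerVector pstart;    // nbf+1, 0-based
  NumericVector alpha, coef;
  int n;
};

static Shells unpack(IntegerMatrix ijk, NumericMatrix cen, IntegerVector pstart,
                     NumericVector alpha, NumericVector coef) {
  Shells s{ijk, cen, pstart, alpha, coef, (int)ijk.nrow()};
  return s;
}

// 1D overlap over t=0 Hermite coefficient
static double s1d(const std::vector<double>& E, int jd, int tdim,
                  int i, int j) {
  return E[(i * jd + j) * tdim + 0];
}

// [[Rcpp::export]]
List ints_one_electron(IntegerMatrix ijk, NumericMatrix cen, IntegerVector pstart,
                       NumericVector alpha, NumericVector coef,
                       NumericVector Zs, NumericMatrix nucpos) {
  Shells bs = unpack(ijk, cen, pstart, alpha, coef);
  const int n = bs.n, nnuc = Zs.size();
  NumericMatrix S(n, n), T(n, n), V(n, n);
  std::vector<double> Ex, Ey, Ez;
  for (int a = 0; a < n; ++a)
    for (int b = 0; b <= a; ++b) {
      const int la[3] = {ijk(a, 0), ijk(a, 1), ijk(a, 2)};
      const int lb[3] = {ijk(b, 0), ijk(b, 1), ijk(b, 2)};
      double AB[3] = {cen(a, 0) - cen(b, 0), cen(a, 1) - cen(b, 1),
                      cen(a, 2) - cen(b, 2)};
      double s_ab = 0.0, t_ab = 0.0, v_ab = 0.0;
      for (int pa = pstart[a]; pa < pstart[a + 1]; ++pa)
        for (int pb = pstart[b]; pb < pstart[b + 1]; ++pb) {
          const double ea = alpha[pa], eb = alpha[pb], p = ea + eb;
          const double cc = coef[pa] * coef[pb];
          // build E tables with jmax extended by 2 for kinetic energy
          e_table(la[0], lb[0] + 2, ea, eb, AB[0], Ex);
          e_table(la[1], lb[1] + 2, ea, eb, AB[1], Ey);
          e_table(la[2], lb[2] + 2, ea, eb, AB[2], Ez);
          const int jdx = lb[0] + 3, tdx = la[0] + lb[0] + 3;
          const int jdy = lb[1] + 3, tdy = la[1] + lb[1] + 3;
          const int jdz = lb[2] + 3, tdz = la[2] + lb[2] + 3;
          const double pref = std::pow(M_PI / p, 1.5);
          auto sx = [&](int dj) { return s1d(Ex, jdx, tdx, la[0], lb[0] + dj); };
          auto sy = [&](int dj) { return s1d(Ey, jdy, tdy, la[1], lb[1] + dj); };
          auto sz = [&](int dj) { return s1d(Ez, jdz, tdz, la[2], lb[2] + dj); };
          // overlap
          const double S0 = sx(0) * sy(0) * sz(0);
          s_ab += cc * pref * S0;
          // kinetic: T1d(j) = -2 b^2 s(j+2) + b(2j+1) s(j) - j(j-1)/2 s(j-2)
          auto t1d = [&](int dim) {
            const int j = lb[dim];
            const std::vector<double>& E = dim == 0 ? Ex : (dim == 1 ? Ey : Ez);
            const int jd = lb[dim] + 3, td = la[dim] + lb[dim] + 3, li = la[dim];
            auto sget = [&](int jj) {
              return (jj < 0) ? 0.0 : E[(li * jd + jj) * td + 0];
            };
            return -2.0 * eb * eb * sget(j + 2) + eb * (2.0 * j + 1.0) * sget(j)
                   - 0.5 * j * (j - 1.0) * sget(j - 2);
          };
          const double tx = t1d(0), ty = t1d(1), tz = t1d(2);
          t_ab += cc * pref * (tx * sy(0) * sz(0) + sx(0) * ty * sz(0) +
                               sx(0) * sy(0) * tz);
          // nuclear attraction
          const double Px = (ea * cen(a, 0) + eb * cen(b, 0)) / p;
          const double Py = (ea * cen(a, 1) + eb * cen(b, 1)) / p;
          const double Pz = (ea * cen(a, 2) + eb * cen(b, 2)) / p;
          const int tmax = la[0] + lb[0], umax = la[1] + lb[1],
                    vmax = la[2] + lb[2];
          double R0[81];  // (tmax+1)(umax+1)(vmax+1) <= 5*5*5 here
          const int du = umax + 1, dv = vmax + 1;
          for (int c = 0; c < nnuc; ++c) {
            r_tensor(tmax, umax, vmax, p, Px - nucpos(c, 0), Py - nucpos(c, 1),
                     Pz - nucpos(c, 2), R0);
            double acc = 0.0;
            for (int t = 0; t <= tmax; ++t) {
              double ext = Ex[(la[0] * jdx + lb[0]) * tdx + t];
              if (ext == 0.0) continue;
              for (int u = 0; u <= umax; ++u) {
                double eyu = Ey[(la[1] * jdy + lb[1]) * tdy + u];
                if (eyu == 0.0) continue;
                for (int v = 0; v <= vmax; ++v) {
                  double ezv = Ez[(la[2] * jdz + lb[2]) * tdz + v];
                  if (ezv == 0.0) continue;
                  acc += ext * eyu * ezv * R0[(t * du + u) * dv + v];
                }
              }
            }
            v_ab += -Zs[c] * cc * (2.0 * M_PI / p) * acc;
          }
        }
      S(a, b) = S(b, a) = s_ab;
      T(a, b) = T(b, a) = t_ab;
      V(a, b) = V(b, a) = v_ab;
    }
  return List::create(_["S"] = S, _["T"] = T, _["V"] = V);
}

// [[Rcpp::export]]
List ints_dipole(IntegerMatrix ijk, NumericMatrix cen, IntegerVector pstart,
                 NumericVector alpha, NumericVector coef) {
  Shells bs = unpack(ijk, cen, pstart, alpha, coef);
  const int n = bs.n;
  NumericMatrix X(n, n), Y(n, n), Z(n, n);
  std::vector<double> Ex, Ey, Ez;
  for (int a = 0; a < n; ++a)
    for (int b = 0; b <= a; ++b) {
      const int la[3] = {ijk(a, 0), ijk(a, 1), ijk(a, 2)};
      const int lb[3] = {ijk(b, 0), ijk(b, 1), ijk(b, 2)};
      double AB[3] = {cen(a, 0) - cen(b, 0), cen(a, 1) - cen(b, 1),
                      cen(a, 2) - cen(b, 2)};
      double d[3] = {0.0, 0.0, 0.0};
      for (int pa = pstart[a]; pa < pstart[a + 1]; ++pa)
        for (int pb = pstart[b]; pb < pstart[b + 1]; ++pb) {
          const double ea = alpha[pa], eb = alpha[pb], p = ea + eb;
          const double cc = coef[pa] * coef[pb];
          // raise bra angular momentum by 1: <i|x|j> = s(i+1,j) + Ax s(i,j)
          e_table(la[0] + 1, lb[0], ea, eb, AB[0], Ex);
          e_table(la[1] + 1, lb[1], ea, eb, AB[1], Ey);
          e_table(la[2] + 1, lb[2], ea, eb, AB[2], Ez);
          const int jdx = lb[0] + 1, tdx = la[0] + lb[0] + 2;
          const int jdy = lb[1] + 1, tdy = la[1] + lb[1] + 2;
          const int jdz = lb[2] + 1, tdz = la[2] + lb[2] + 2;
          const double pref = cc * std::pow(M_PI / p, 1.5);
          const double sx = s1d(Ex, jdx, tdx, la[0], lb[0]);
          const double sy = s1d(Ey, jdy, tdy, la[1], lb[1]);
          const double sz = s1d(Ez, jdz, tdz, la[2], lb[2]);
          const double mx = s1d(Ex, jdx, tdx, la[0] + 1, lb[0]) + cen(a, 0) * sx;
          const double my = s1d(Ey, jdy, tdy, la[1] + 1, lb[1]) + cen(a, 1) * sy;
          const double mz = s1d(Ez, jdz, tdz, la[2] + 1, lb[2]) + cen(a, 2) * sz;
          d[0] += pref * mx * sy * sz;
          d[1] += pref * sx * my * sz;
          d[2] += pref * sx * sy * mz;
        }
      X(a, b) = X(b, a) = d[0];
      Y(a, b) = Y(b, a) = d[1];
      Z(a, b) = Z(b, a) = d[2];
    }
  return List::create(_["X"] = X, _["Y"] = Y, _["Z"] = Z);
}

// ------------------------------------------------------------------- ERIs
struct PrimPairT {
  double p, Px, Py, Pz;
  int tmax, umax, vmax;
  std::vector<int> t, u, v;
  std::vector<double> c;  // coef_a * coef_b * Ex(t) Ey(u) Ez(v)
};
struct BFPair { int a, b; std::vector<PrimPairT> pp; };

static void build_pairs(const Shells& bs, std::vector<BFPair>& pairs) {
  const int n = bs.n;
  std::vector<double> Ex, Ey, Ez;
  pairs.clear();
  pairs.reserve((size_t)n * (n + 1) / 2);
  for (int a = 0; a < n; ++a)
    for (int b = 0; b <= a; ++b) {
      BFPair bp; bp.a = a; bp.b = b;
      const int la[3] = {bs.ijk(a, 0), bs.ijk(a, 1), bs.ijk(a, 2)};
      const int lb[3] = {bs.ijk(b, 0), bs.ijk(b, 1), bs.ijk(b, 2)};
      double AB[3] = {bs.cen(a, 0) - bs.cen(b, 0), bs.cen(a, 1) - bs.cen(b, 1),
                      bs.cen(a, 2) - bs.cen(b, 2)};
      for (int pa = bs.pstart[a]; pa < bs.pstart[a + 1]; ++pa)
        for (int pb = bs.pstart[b]; pb < bs.pstart[b + 1]; ++pb) {
          const double ea = bs.alpha[pa], eb = bs.alpha[pb], p = ea + eb;
          const double cc = bs.coef[pa] * bs.coef[pb];
          e_table(la[0], lb[0], ea, eb, AB[0], Ex);
          e_table(la[1], lb[1], ea, eb, AB[1], Ey);
          e_table(la[2], lb[2], ea, eb, AB[2], Ez);
          const int jdx = lb[0] + 1, tdx = la[0] + lb[0] + 1;
          const int jdy = lb[1] + 1, tdy = la[1] + lb[1] + 1;
          const int jdz = lb[2] + 1, tdz = la[2] + lb[2] + 1;
          PrimPairT pt;
          pt.p = p;
          pt.Px = (ea * bs.cen(a, 0) + eb * bs.cen(b, 0)) / p;
          pt.Py = (ea * bs.cen(a, 1) + eb * bs.cen(b, 1)) / p;
          pt.Pz = (ea * bs.cen(a, 2) + eb * bs.cen(b, 2)) / p;
          pt.tmax = la[0] + lb[0]; pt.umax = la[1] + lb[1]; pt.vmax = la[2] + lb[2];
          for (int t = 0; t <= pt.tmax; ++t) {
            double ext = Ex[(la[0] * jdx + lb[0]) * tdx + t];
            if (std::fabs(ext) < 1e-18) continue;
            for (int u = 0; u <= pt.umax; ++u) {
              double eyu = Ey[(la[1] * jdy + lb[1]) * tdy + u];
              if (std::fabs(eyu) < 1e-18) continue;
              for (int v = 0; v <= pt.vmax; ++v) {
                double ezv = Ez[(la[2] * jdz + lb[2]) * tdz + v];
                if (std::fabs(ezv) < 1e-18) continue;
                pt.t.push_back(t); pt.u.push_back(u); pt.v.push_back(v);
                pt.c.push_back(cc * ext * eyu * ezv);
              }
            }
          }
          if (!pt.c.empty()) bp.pp.push_back(std::move(pt));
        }
      pairs.push_back(std::move(bp));
    }
}

static double eri_quartet(const BFPair& bra, const BFPair& ket) {
  double val = 0.0;
  double R0[729];  // up to (8+1)^3 Hermite orders (d functions)
  for (const auto& pp1 : bra.pp)
    for (const auto& pp2 : ket.pp) {
      const double p = pp1.p, q = pp2.p;
      const double alpha = p * q / (p + q);
      const double pref = 2.0 * std::pow(M_PI, 2.5) /
        (p * q * std::sqrt(p + q));
      const double X = pp1.Px - pp2.Px, Y = pp1.Py - pp2.Py,
                   Z = pp1.Pz - pp2.Pz;
      if (pp1.tmax + pp1.umax + pp1.vmax + pp2.tmax + pp2.umax + pp2.vmax == 0) {
        // s-only fast path
        double F0;
        boys(0, alpha * (X * X + Y * Y + Z * Z), &F0);
        val += pref * pp1.c[0] * pp2.c[0] * F0;
        continue;
      }
      r_tensor(pp1.tmax + pp2.tmax, pp1.umax + pp2.umax, pp1.vmax + pp2.vmax,
               alpha, X, Y, Z, R0);
      const int du = pp1.umax + pp2.umax + 1, dv = pp1.vmax + pp2.vmax + 1;
      double acc = 0.0;
      const size_t n1 = pp1.c.size(), n2 = pp2.c.size();
      for (size_t m = 0; m < n1; ++m) {
        const int t1 = pp1.t[m], u1 = pp1.u[m], v1 = pp1.v[m];
        const double c1 = pp1.c[m];
        double inner = 0.0;
        for (size_t k = 0; k < n2; ++k) {
          const int tk = pp2.t[k], uk = pp2.u[k], vk = pp2.v[k];
          const double sgn = ((tk + uk + vk) & 1) ? -1.0 : 1.0;
          inner += sgn * pp2.c[k] *
            R0[((t1 + tk) * du + (u1 + uk)) * dv + (v1 + vk)];
        }
        acc += c1 * inner;
      }
      val += pref * acc;
    }
  return val;
}

// packed ERI vector over canonical quartets: pair index ij = a*(a+1)/2+b
// (a >= b), quartet index m = ij*(ij+1)/2 + kl (ij >= kl)
// [[Rcpp::export]]
NumericVector eri_packed(IntegerMatrix ijk, NumericMatrix cen, IntegerVector pstart,
                         NumericVector alpha, NumericVector coef,
                         double screen_tol = 1e-10) {
  Shells bs = unpack(ijk, cen, pstart, alpha, coef);
  std::vector<BFPair> pairs;
  build_pairs(bs, pairs);
  const size_t npair = pairs.size();
  // Schwarz bounds
  std::vector<double> Q(npair);
  for (size_t ij = 0; ij < npair; ++ij)
    Q[ij] = std::sqrt(std::fabs(eri_quartet(pairs[ij], pairs[ij])));
  NumericVector out((R_xlen_t)(npair * (npair + 1) / 2));
  size_t m = 0;
  for (size_t ij = 0; ij < npair; ++ij) {
    for (size_t kl = 0; kl <= ij; ++kl, ++m) {
      if (Q[ij] * Q[kl] < screen_tol) { out[m] = 0.0; continue; }
      out[m] = eri_quartet(pairs[ij], pairs[kl]);
    }
    Rcpp::checkUserInterrupt();
  }
  return out;
}

// Coulomb and exchange matrices from the packed ERI list and a (doubled,
// spin-summed) density matrix D: J_uv = sum D_ls (uv|ls),
// K_uv = sum D_ls (ul|vs)
// [[Rcpp::export]]
List fock_jk(NumericVector eri, NumericMatrix D) {
  const int n = D.nrow();
  const size_t npair = (size_t)n * (n + 1) / 2;
  NumericMatrix J(n, n), K(n, n);
  std::vector<int> pi(npair), pj(npair);
  {
    size_t ij = 0;
    for (int a = 0; a < n; ++a)
      for (int b = 0; b <= a; ++b, ++ij) { pi[ij] = a; pj[ij] = b; }
  }
  size_t m = 0;
  uint64_t seen[8];
  for (size_t ij = 0; ij < npair; ++ij) {
    const int i = pi[ij], j = pj[ij];
    for (size_t kl = 0; kl <= ij; ++kl, ++m) {
      const double v = eri[m];
      if (v == 0.0) continue;
      const int k = pi[kl], l = pj[kl];
      if (i != j && k != l && ij != kl) {
        // all eight index permutations are distinct tuples: unrolled scatter
        J(i, j) += D(k, l) * v; K(i, k) += D(j, l) * v;
        J(j, i) += D(k, l) * v; K(j, k) += D(i, l) * v;
        J(i, j) += D(l, k) * v; K(i, l) += D(j, k) * v;
        J(j, i) += D(l, k) * v; K(j, l) += D(i, k) * v;
        J(k, l) += D(i, j) * v; K(k, i) += D(l, j) * v;
        J(l, k) += D(i, j) * v; K(l, i) += D(k, j) * v;
        J(k, l) += D(j, i) * v; K(k, j) += D(l, i) * v;
        J(l, k) += D(j, i) * v; K(l, j) += D(k, i) * v;
        continue;
      }
      // coincident indices: deduplicate the permutations explicitly
      int quads[8][4] = {{i, j, k, l}, {j, i, k, l}, {i, j, l, k}, {j, i, l, k},
                         {k, l, i, j}, {l, k, i, j}, {k, l, j, i}, {l, k, j, i}};
      int nq = 0;
      for (int q = 0; q < 8; ++q) {
        uint64_t code = (((uint64_t)quads[q][0] * 1024 + quads[q][1]) * 1024 +
                         quads[q][2]) * 1024 + quads[q][3];
        bool dup = false;
        for (int s = 0; s < nq; ++s) if (seen[s] == code) { dup = true; break; }
        if (dup) continue;
        seen[nq++] = code;
        const int a = quads[q][0], b = quads[q][1], c = quads[q][2],
                  d = quads[q][3];
        J(a, b) += D(c, d) * v;
        K(a, c) += D(b, d) * v;
      }
    }
  }
  return List::create(_["J"] = J, _["K"] = K);
}

// basis function values at points: returns npoints x nbf matrix
// [[Rcpp::export]]
NumericMatrix eval_basis(IntegerMatrix ijk, NumericMatrix cen, IntegerVector pstart,
                         NumericVector alpha, NumericVector coef,
                         NumericMatrix points) {
  const int n = ijk.nrow(), np = points.nrow();
  NumericMatrix out(np, n);
  for (int b = 0; b < n; ++b) {
    const int li = ijk(b, 0), lj = ijk(b, 1), lk = ijk(b, 2);
    const double cx = cen(b, 0), cy = cen(b, 1), cz = cen(b, 2);
    for (int p = 0; p < np; ++p) {
      const double dx = points(p, 0) - cx, dy = points(p, 1) - cy,
                   dz = points(p, 2) - cz;
      const double r2 = dx * dx + dy * dy + dz * dz;
      double rad = 0.0;
      for (int pr = pstart[b]; pr < pstart[b + 1]; ++pr)
        rad += coef[pr] * std::exp(-alpha[pr] * r2);
      double ang = 1.0;
      for (int t = 0; t < li; ++t) ang *= dx;
      for (int t = 0; t < lj; ++t) ang *= dy;
      for (int t = 0; t < lk; ++t) ang *= dz;
      out(p, b) = ang * rad;
    }
  }
  return out;
}

// basis function values and Cartesian gradients at points:
// returns list(val, dx, dy, dz), each npoints x nbf
// [[Rcpp::export]]
List eval_basis_grad(IntegerMatrix ijk, NumericMatrix cen, IntegerVector pstart,
                     NumericVector alpha, NumericVector coef,
                     NumericMatrix points) {
  const int n = ijk.nrow(), np = points.nrow();
  NumericMatrix val(np, n), gx(np, n), gy(np, n), gz(np, n);
  for (int b = 0; b < n; ++b) {
    const int li = ijk(b, 0), lj = ijk(b, 1), lk = ijk(b, 2);
    const double cx = cen(b, 0), cy = cen(b, 1), cz = cen(b, 2);
    for (int p = 0; p < np; ++p) {
      const double dx = points(p, 0) - cx, dy = points(p, 1) - cy,
                   dz = points(p, 2) - cz;
      const double r2 = dx * dx + dy * dy + dz * dz;
      double rad = 0.0, drad = 0.0;  // radial part and d(rad)/d(r2)
      for (int pr = pstart[b]; pr < pstart[b + 1]; ++pr) {
        const double e = coef[pr] * std::exp(-alpha[pr] * r2);
        rad += e;
        drad += -alpha[pr] * e;
      }
      double px = 1.0, py = 1.0, pz = 1.0;
      for (int t = 0; t < li; ++t) px *= dx;
      for (int t = 0; t < lj; ++t) py *= dy;
      for (int t = 0; t < lk; ++t) pz *= dz;
      const double ang = px * py * pz;
      val(p, b) = ang * rad;
      // d/dx [x^li rad] = li x^(li-1) rad + x^li * 2x * drad
      double pxm = (li > 0) ? li * (li == 1 ? 1.0 : std::pow(dx, li - 1)) : 0.0;
      double pym = (lj > 0) ? lj * (lj == 1 ? 1.0 : std::pow(dy, lj - 1)) : 0.0;
      double pzm = (lk > 0) ? lk * (lk == 1 ? 1.0 : std::pow(dz, lk - 1)) : 0.0;
      gx(p, b) = (pxm * py * pz) * rad + ang * 2.0 * dx * drad;
      gy(p, b) = (px * pym * pz) * rad + ang * 2.0 * dy * drad;
      gz(p, b) = (px * py * pzm) * rad + ang * 2.0 * dz * drad;
    }
  }
  return List::create(_["val"] = val, _["dx"] = gx, _["dy"] = gy, _["dz"] = gz);
}
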