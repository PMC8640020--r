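#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Directional cumulative-profile matching kernel.
//
// For each discrete angle a line family covers the grid at unit intercept
// steps along the minor axis; each line is parameterized along its major
// axis (|tan| <= 1 -> x-major, otherwise y-major) to avoid the tangent
// singularity. Along each line the running cumulative flux of both images
// is formed (profiles normalized to a common total) and the displacement of
// plane-2 flux relative to plane-1 flux is read off by monotone inversion
// of the plane-2 profile at the plane-1 mid-sample levels (1-D transport).
//
// A displacement d measured along the major axis corresponds to an
// along-line transport of p = d / cos(alpha) (x-major) or p = e / sin(alpha)
// (y-major), an estimate of the projection of the local 2-D displacement
// field onto the line direction (cos a, sin a). Per pixel, the samples from
// all angles are combined by weighted least squares of the projection model
//   p(alpha) = dx cos(alpha) + dy sin(alpha)
// with precision weights cos^2 (x-major) / sin^2 (y-major) and bilinear
// splatting; the kernel returns the per-pixel normal-equation accumulators.
//
// Matrices are column-major; element (y, x) = M[x * nr + y]; 0-based pixel
// centres at integer coordinates.

static inline double sample_interp(const double* M, int nr, int nc,
                                   double pos, int fixed, bool xmajor) {
  int n = xmajor ? nr : nc;
  if (pos < 0.0 || pos > n - 1) return -1.0;  // outside grid
  int p0 = (int)std::floor(pos);
  if (p0 >= n - 1) p0 = n - 2;
  double w = pos - p0;
  double a, b;
  if (xmajor) { a = M[fixed * nr + p0]; b = M[fixed * nr + p0 + 1]; }
  else        { a = M[p0 * nr + fixed]; b = M[(p0 + 1) * nr + fixed]; }
  return a * (1.0 - w) + b * w;
}

// [[Rcpp::export(name = ".match_kernel")]]
List match_kernel(NumericMatrix I1, NumericMatrix I2, NumericVector angles,
                  double eps_rel, double min_flux) {
  const int nr = I1.nrow(), nc = I1.ncol();
  if (I2.nrow() != nr || I2.ncol() != nc)
    stop("intensity images must share dimensions");
  NumericMatrix Scc(nr, nc), Scs(nr, nc), Sss(nr, nc),
                Bc(nr, nc), Bs(nr, nc), Cov(nr, nc);
  const double* p1 = I1.begin();
  const double* p2 = I2.begin();

  const int nmax = std::max(nr, nc);
  std::vector<double> fs(nmax), gs(nmax), F(nmax), G(nmax);

  for (int ia = 0; ia < angles.size(); ++ia) {
    const double alpha = angles[ia];
    const double ca = std::cos(alpha), sa = std::sin(alpha);
    const double ta = std::tan(alpha);
    const bool xmajor = std::fabs(ta) <= 1.0 + 1e-12;
    const double slope = xmajor ? ta : 1.0 / ta;  // minor per unit major step
    const int nmaj = xmajor ? nc : nr;
    const int nmin = xmajor ? nr : nc;
    // per-sample least-squares contributions for a measured displacement d
    // (major-axis units): weight w0, regressors (see header comment)
    const double w0  = xmajor ? ca * ca : sa * sa;
    const double bcd = xmajor ? ca * ca : sa * ca;   // Bc += bcd * d
    const double bsd = xmajor ? ca * sa : sa * sa;   // Bs += bsd * d

    double off_end = slope * (nmaj - 1);
    int b_lo = (int)std::floor(0.0 - std::max(0.0, off_end));
    int b_hi = (int)std::ceil((nmin - 1) - std::min(0.0, off_end));

    for (int b = b_lo; b <= b_hi; ++b) {
      double Tf = 0.0, Tg = 0.0, fmax = 0.0, gmax = 0.0;
      for (int i = 0; i < nmaj; ++i) {
        double pos = b + slope * i;
        double v1 = sample_interp(p1, nr, nc, pos, i, xmajor);
        double v2 = sample_interp(p2, nr, nc, pos, i, xmajor);
        if (v1 < 0.0 || v2 < 0.0) { fs[i] = 0.0; gs[i] = 0.0; }
        else { fs[i] = v1; gs[i] = v2; }
        Tf += fs[i]; Tg += gs[i];
        if (fs[i] > fmax) fmax = fs[i];
        if (gs[i] > gmax) gmax = gs[i];
        F[i] = Tf; G[i] = Tg;
      }
      if (Tf <= min_flux || Tg <= min_flux) continue;
      // grazing lines that only clip a rim carry almost no transport
      // information but produce extreme endpoint readings; require a
      // minimal effective span (total flux in units of the peak sample)
      if (Tf < 6.0 * fmax || Tg < 6.0 * gmax) continue;
      const double scale = Tf / Tg;   // normalize plane-2 total to plane-1
      const double eps = eps_rel * Tf;

      int j = 0;
      for (int i = 0; i < nmaj; ++i) {
        if (fs[i] <= eps) continue;            // low local flux: skip sample
        const double L = F[i] - 0.5 * fs[i];   // mid-mass level of sample i
        while (j < nmaj - 1 && G[j] * scale < L) ++j;
        const double Gj = G[j] * scale;
        const double Gjm1 = (j > 0 ? G[j - 1] * scale : 0.0);
        double u;
        const double denom = Gj - Gjm1;
        if (denom > 0.0) {
          double frac = (L - Gjm1) / denom;
          if (frac < 0.0) frac = 0.0; else if (frac > 1.0) frac = 1.0;
          u = (j - 0.5) + frac;
        } else {
          u = (double)j;                        // flat interval: midpoint
        }
        const double d = u - i;                 // displacement, major-axis px

        // splat the LS contributions at the midpoint of the matched pair:
        // the displacement between the planes at -dz and +dz belongs to the
        // mid-plane (pupil) coordinate, halfway between the two matched
        // line positions; samples are additionally weighted by their local
        // flux (in units of the line's mean flux) -- low-flux samples carry
        // the least reliable transport
        const double imid = i + 0.5 * d;
        double pos = b + slope * imid;
        if (imid < 0.0 || imid > nmaj - 1) continue;
        if (pos < 0.0 || pos > nmin - 1) continue;
        int q0 = (int)std::floor(pos);
        if (q0 >= nmin - 1) q0 = nmin - 2;
        const double wq = pos - q0;
        int j0 = (int)std::floor(imid);
        if (j0 >= nmaj - 1) j0 = nmaj - 2;
        const double wj = imid - j0;
        const double wflux = fs[i] * nmaj / Tf;
        for (int cq = 0; cq < 2; ++cq) {
          for (int cj = 0; cj < 2; ++cj) {
            const double wspl = (cq ? wq : 1.0 - wq) *
                                (cj ? wj : 1.0 - wj) * wflux;
            if (wspl <= 0.0) continue;
            int y, x;
            if (xmajor) { y = q0 + cq; x = j0 + cj; }
            else        { y = j0 + cj; x = q0 + cq; }
            const int at = x * nr + y;
            Scc[at] += wspl * w0 * ca * ca;
            Scs[at] += wspl * w0 * ca * sa;
            Sss[at] += wspl * w0 * sa * sa;
            Bc[at]  += wspl * bcd * d;
            Bs[at]  += wspl * bsd * d;
            Cov[at] += wspl * w0;
          }
        }
      }
    }
  }
  return List::create(_["Scc"] = Scc, _["Scs"] = Scs, _["Sss"] = Sss,
                      _["Bc"] = Bc, _["Bs"] = Bs, _["Cov"] = Cov);
}
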