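#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Normalized cross-correlation spot tracking with a static frame-1 template
// and 3-point parabolic subpixel refinement, applied independently in x and
// y. Coordinates are 1-based: x indexes columns, y indexes rows.
//
// stack: h x w x n array; (x0, y0): initial marker position on frame 1;
// tr: template half-size; sr: search half-size around the previous position;
// floor_q: correlation floor below which the frame counts as lost and the
// previous position is held.
// [[Rcpp::export]]
List ncc_track_cpp(NumericVector stack, double x0, double y0,
                   int tr, int sr, double floor_q) {
  IntegerVector dims = stack.attr("dim");
  const int h = dims[0], w = dims[1], n = dims[2];
  const double *S = REAL(stack);
  const int tw = 2 * tr + 1;

  int cx = (int)std::lround(x0), cy = (int)std::lround(y0);
  if (cx - tr < 1 || cx + tr > w || cy - tr < 1 || cy + tr > h)
    stop("template window extends outside frame 1");

  // template (frame 1), mean-removed
  std::vector<double> T(tw * tw);
  double tmean = 0.0;
  for (int j = 0; j < tw; ++j)
    for (int i = 0; i < tw; ++i) {
      double v = S[(cy - tr - 1 + i) + (size_t)(cx - tr - 1 + j) * h];
      T[i + j * tw] = v;
      tmean += v;
    }
  tmean /= (tw * tw);
  double tnorm = 0.0;
  for (double &v : T) { v -= tmean; tnorm += v * v; }
  tnorm = std::sqrt(tnorm);

  NumericVector xs(n), ys(n), qs(n);
  LogicalVector lost(n);
  xs[0] = x0; ys[0] = y0; qs[0] = 1.0; lost[0] = false;
  double px = x0, py = y0; // previous position (continuous)

  std::vector<double> corr((2 * sr + 1) * (2 * sr + 1));

  for (int f = 1; f < n; ++f) {
    const double *F = S + (size_t)f * h * w;
    int pcx = (int)std::lround(px), pcy = (int)std::lround(py);
    // clamp candidate centers so the template stays inside the frame
    int xlo = std::max(pcx - sr, tr + 1), xhi = std::min(pcx + sr, w - tr);
    int ylo = std::max(pcy - sr, tr + 1), yhi = std::min(pcy + sr, h - tr);
    if (xlo > xhi || ylo > yhi)
      stop("search window left the frame at frame %d", f + 1);
    int nx = xhi - xlo + 1, ny = yhi - ylo + 1;
    double best = -2.0; int bi = 0, bj = 0;
    for (int j = 0; j < nx; ++j) {
      for (int i = 0; i < ny; ++i) {
        int ox = xlo + j, oy = ylo + i;
        // single pass: with a mean-removed template, centering the window
        // only affects the window variance term
        double s1 = 0.0, s2 = 0.0, num = 0.0;
        for (int jj = 0; jj < tw; ++jj) {
          const double *col = F + (oy - tr - 1) + (size_t)(ox - tr - 1 + jj) * h;
          const double *tc = &T[(size_t)jj * tw];
          for (int ii = 0; ii < tw; ++ii) {
            double wv = col[ii];
            s1 += wv;
            s2 += wv * wv;
            num += wv * tc[ii];
          }
        }
        double den = s2 - s1 * s1 / (tw * tw);
        double r = (den > 0 && tnorm > 0) ? num / (std::sqrt(den) * tnorm) : 0.0;
        corr[i + j * ny] = r;
        if (r > best) { best = r; bi = i; bj = j; }
      }
    }
    if (best < floor_q) {
      xs[f] = px; ys[f] = py; qs[f] = best; lost[f] = true;
      continue;
    }
    // parabolic refinement, x and y independently
    double dx = 0.0, dy = 0.0;
    if (bj > 0 && bj < nx - 1) {
      double rl = corr[bi + (bj - 1) * ny], r0 = best, rr = corr[bi + (bj + 1) * ny];
      double den2 = rl - 2 * r0 + rr;
      if (den2 < 0) dx = 0.5 * (rl - rr) / den2;
    }
    if (bi > 0 && bi < ny - 1) {
      double ru = corr[(bi - 1) + bj * ny], r0 = best, rd = corr[(bi + 1) + bj * ny];
      double den2 = ru - 2 * r0 + rd;
      if (den2 < 0) dy = 0.5 * (ru - rd) / den2;
    }
    if (std::fabs(dx) > 1.0) dx = 0.0;
    if (std::fabs(dy) > 1.0) dy = 0.0;
    px = (xlo + bj) + dx;
    py = (ylo + bi) + dy;
    xs[f] = px; ys[f] = py; qs[f] = best; lost[f] = false;
  }
  return List::create(_["x"] = xs, _["y"] = ys, _["quality"] = qs,
                      _["lost"] = lost);
}
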