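#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// 13 classical co-occurrence statistics of a normalised, symmetric GLCM p
// (levels x levels, row-major in `p`), with gray levels valued 1..L.
// Order: energy, contrast, correlation, variance, inverse difference moment,
// sum average, sum variance, sum entropy, entropy, difference variance,
// difference entropy, IMC1, IMC2.
static void haralick13(const std::vector<double> &p, int L, double *out) {
  std::vector<double> px(L, 0.0);
  std::vector<double> psum(2 * L - 1, 0.0);  // i+j = 2..2L  -> index i+j-2
  std::vector<double> pdiff(L, 0.0);         // |i-j| = 0..L-1
  double energy = 0, contrast = 0, idm = 0, entropy = 0, cross = 0;
  for (int i = 0; i < L; ++i) {
    for (int j = 0; j < L; ++j) {
      double v = p[i * L + j];
      if (v <= 0) continue;
      px[i] += v;
      psum[i + j] += v;
      pdiff[std::abs(i - j)] += v;
      energy += v * v;
      contrast += (double)(i - j) * (i - j) * v;
      idm += v / (1.0 + (double)(i - j) * (i - j));
      entropy -= v * std::log(v);
      cross += (double)(i + 1) * (j + 1) * v;
    }
  }
  double mux = 0, sx2 = 0;
  for (int i = 0; i < L; ++i) mux += (i + 1) * px[i];
  for (int i = 0; i < L; ++i) sx2 += (i + 1 - mux) * (i + 1 - mux) * px[i];
  double corr = (sx2 > 1e-12) ? (cross - mux * mux) / sx2 : 0.0;

  double sumavg = 0, sumvar = 0, sument = 0;
  for (int k = 0; k < 2 * L - 1; ++k) {
    double v = psum[k];
    if (v <= 0) continue;
    double kk = k + 2;  // actual i+j value
    sumavg += kk * v;
    sument -= v * std::log(v);
  }
  for (int k = 0; k < 2 * L - 1; ++k) {
    double v = psum[k];
    if (v <= 0) continue;
    double kk = k + 2;
    sumvar += (kk - sumavg) * (kk - sumavg) * v;
  }
  double dmean = 0, dvar = 0, dent = 0;
  for (int k = 0; k < L; ++k) {
    double v = pdiff[k];
    if (v <= 0) continue;
    dmean += k * v;
    dent -= v * std::log(v);
  }
  for (int k = 0; k < L; ++k) {
    double v = pdiff[k];
    if (v <= 0) continue;
    dvar += (k - dmean) * (k - dmean) * v;
  }
  // information measures of correlation (symmetric GLCM: py == px)
  double hx = 0, hxy1 = 0, hxy2 = 0;
  for (int i = 0; i < L; ++i) {
    if (px[i] > 0) hx -= px[i] * std::log(px[i]);
    for (int j = 0; j < L; ++j) {
      double pij = px[i] * px[j];
      if (pij <= 0) continue;
      double v = p[i * L + j];
      if (v > 0) hxy1 -= v * std::log(pij);
      hxy2 -= pij * std::log(pij);
    }
  }
  double imc1 = (hx > 1e-12) ? (entropy - hxy1) / hx : 0.0;
  double e2 = 1.0 - std::exp(-2.0 * (hxy2 - entropy));
  double imc2 = (e2 > 0) ? std::sqrt(e2) : 0.0;

  out[0] = energy;
  out[1] = contrast;
  out[2] = corr;
  out[3] = sx2;
  out[4] = idm;
  out[5] = sumavg;
  out[6] = sumvar;
  out[7] = sument;
  out[8] = entropy;
  out[9] = dvar;
  out[10] = dent;
  out[11] = imc1;
  out[12] = imc2;
}

// [[Rcpp::export(name = ".haralick_from_glcm")]]
NumericVector haralick_from_glcm(NumericMatrix glcm) {
  int L = glcm.nrow();
  if (glcm.ncol() != L) stop("GLCM must be square");
  double tot = 0;
  std::vector<double> p((size_t)L * L, 0.0);
  for (int i = 0; i < L; ++i)
    for (int j = 0; j < L; ++j) tot += glcm(i, j);
  if (tot <= 0) return NumericVector(13, 0.0);
  for (int i = 0; i < L; ++i)
    for (int j = 0; j < L; ++j) p[(size_t)i * L + j] = glcm(i, j) / tot;
  NumericVector out(13);
  haralick13(p, L, REAL(out));
  return out;
}

// Sliding-window, direction-averaged co-occurrence statistics.
// labels: flattened 3D integer array (column-major), 0 = unlabeled/invalid,
//         1..levels otherwise.
// compute: voxels at which the 13 statistics are wanted.
// radius: half-width of the cubic window (window = 2*radius+1 per axis,
//         clipped at the volume border).
// offsets: k x 3 integer displacement vectors; each pair is counted
//          symmetrically, and both ends must lie inside the window.
// Returns an (nvox x 13) matrix; rows where compute is FALSE are zero.
// [[Rcpp::export(name = ".glcm_window_stats")]]
NumericMatrix glcm_window_stats(IntegerVector labels, IntegerVector dims,
                                LogicalVector compute, int radius, int levels,
                                IntegerMatrix offsets) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (labels.size() != n || compute.size() != n)
    stop("labels/compute length does not match dims");
  if (2 * radius + 1 > std::max(nx, std::max(ny, nz)))
    stop("window larger than volume");
  const int L = levels, noff = offsets.nrow();
  NumericMatrix out(n, 13);
  std::vector<double> glcm((size_t)L * L);
  double stats[13];

  for (int cz = 0; cz < nz; ++cz) {
    for (int cy = 0; cy < ny; ++cy) {
      for (int cx = 0; cx < nx; ++cx) {
        R_xlen_t ci = (R_xlen_t)cz * nx * ny + (R_xlen_t)cy * nx + cx;
        if (!compute[ci]) continue;
        std::fill(glcm.begin(), glcm.end(), 0.0);
        const int x0 = std::max(0, cx - radius), x1 = std::min(nx - 1, cx + radius);
        const int y0 = std::max(0, cy - radius), y1 = std::min(ny - 1, cy + radius);
        const int z0 = std::max(0, cz - radius), z1 = std::min(nz - 1, cz + radius);
        double tot = 0;
        for (int pz = z0; pz <= z1; ++pz)
          for (int py = y0; py <= y1; ++py)
            for (int px = x0; px <= x1; ++px) {
              int l1 = labels[(R_xlen_t)pz * nx * ny + (R_xlen_t)py * nx + px];
              if (l1 <= 0) continue;
              for (int o = 0; o < noff; ++o) {
                int qx = px + offsets(o, 0);
                int qy = py + offsets(o, 1);
                int qz = pz + offsets(o, 2);
                if (qx < x0 || qx > x1 || qy < y0 || qy > y1 ||
                    qz < z0 || qz > z1)
                  continue;
                int l2 = labels[(R_xlen_t)qz * nx * ny + (R_xlen_t)qy * nx + qx];
                if (l2 <= 0) continue;
                glcm[(size_t)(l1 - 1) * L + (l2 - 1)] += 1.0;
                glcm[(size_t)(l2 - 1) * L + (l1 - 1)] += 1.0;
                tot += 2.0;
              }
            }
        if (tot > 0) {
          for (size_t k = 0; k < glcm.size(); ++k) glcm[k] /= tot;
          haralick13(glcm, L, stats);
          for (int s = 0; s < 13; ++s) out(ci, s) = stats[s];
        }
      }
    }
  }
  return out;
}
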