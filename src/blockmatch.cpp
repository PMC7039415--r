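#include <Rcpp.h>
using namespace Rcpp;

// Intensity variance of cubic blocks (half-size h) centred at 0-based voxel
// indices. Centres whose block leaves the volume get variance -1.
// [[Rcpp::export(name = ".cppBlockVariances")]]
NumericVector cppBlockVariances(NumericVector arr, IntegerVector dim,
                                IntegerMatrix centers, int h) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int m = centers.nrow();
  const double n = (2.0 * h + 1) * (2.0 * h + 1) * (2.0 * h + 1);
  NumericVector out(m);
  for (int b = 0; b < m; ++b) {
    const int cx = centers(b, 0), cy = centers(b, 1), cz = centers(b, 2);
    if (cx - h < 0 || cy - h < 0 || cz - h < 0 ||
        cx + h >= nx || cy + h >= ny || cz + h >= nz) {
      out[b] = -1.0;
      continue;
    }
    double s = 0.0, s2 = 0.0;
    for (int k = cz - h; k <= cz + h; ++k)
      for (int j = cy - h; j <= cy + h; ++j) {
        const double *p = &arr[cx - h + (size_t)nx * (j + (size_t)ny * k)];
        for (int i = 0; i <= 2 * h; ++i) {
          const double v = p[i];
          s += v;
          s2 += v * v;
        }
      }
    out[b] = s2 / n - (s / n) * (s / n);
  }
  return out;
}

// Squared correlation between a cached reference block and the moving block
// centred at (ox, oy, oz); -1 if the block leaves the volume or is flat.
static double blockScore(const std::vector<double> &rblock, double rs, double rvar,
                         const NumericVector &mov, int mnx, int mny, int mnz,
                         int ox, int oy, int oz, int h) {
  if (ox - h < 0 || oy - h < 0 || oz - h < 0 ||
      ox + h >= mnx || oy + h >= mny || oz + h >= mnz)
    return -1.0;
  const double n = (2.0 * h + 1) * (2.0 * h + 1) * (2.0 * h + 1);
  double ms = 0.0, ms2 = 0.0, rm = 0.0;
  int idx = 0;
  for (int k = oz - h; k <= oz + h; ++k)
    for (int j = oy - h; j <= oy + h; ++j) {
      const double *p = &mov[ox - h + (size_t)mnx * (j + (size_t)mny * k)];
      for (int i = 0; i <= 2 * h; ++i, ++idx) {
        const double v = p[i];
        ms += v;
        ms2 += v * v;
        rm += v * rblock[idx];
      }
    }
  const double mvar = n * ms2 - ms * ms;
  if (mvar <= 0.0) return -1.0;
  const double cov = n * rm - rs * ms;
  return (cov * cov) / (rvar * mvar);
}

// Exhaustive integer-offset block matching with parabolic refinement.
//
// For each reference block (centre `centers`, half-size h) the moving image
// is searched over all integer offsets within `radius` of the predicted
// centre `pred` (both 0-based voxel indices). The similarity score is the
// squared Pearson correlation of the block intensity vectors; the
// best-scoring offset wins, scanned in a fixed lexicographic order (first
// maximum kept) so matching is fully deterministic. The final offset is then
// refined to sub-voxel precision by fitting a 1D parabola through the scores
// at the best offset and its two axis neighbours (separately per axis,
// clamped to half a voxel); without this the integer quantization leaves a
// systematic deadband that aggregation cannot average away. Offsets whose
// moving block leaves the volume, or whose moving block has zero variance,
// are skipped; a block with no admissible offset (or a flat reference
// block) is returned as invalid.
// [[Rcpp::export(name = ".cppMatchBlocks")]]
List cppMatchBlocks(NumericVector ref, IntegerVector refDim,
                    NumericVector mov, IntegerVector movDim,
                    IntegerMatrix centers, IntegerMatrix pred,
                    int h, int radius) {
  const int rnx = refDim[0], rny = refDim[1];
  const int mnx = movDim[0], mny = movDim[1], mnz = movDim[2];
  const int m = centers.nrow();
  const int bs = 2 * h + 1;
  const int nvox = bs * bs * bs;
  const double n = (double)nvox;
  std::vector<double> rblock(nvox);

  NumericMatrix offsets(m, 3);
  NumericVector scores(m);
  LogicalVector valid(m);

  for (int b = 0; b < m; ++b) {
    const int cx = centers(b, 0), cy = centers(b, 1), cz = centers(b, 2);
    // reference block (extraction guarantees it is inside)
    double rs = 0.0, rs2 = 0.0;
    int idx = 0;
    for (int k = cz - h; k <= cz + h; ++k)
      for (int j = cy - h; j <= cy + h; ++j) {
        const double *p = &ref[cx - h + (size_t)rnx * (j + (size_t)rny * k)];
        for (int i = 0; i <= 2 * h; ++i, ++idx) {
          const double v = p[i];
          rblock[idx] = v;
          rs += v;
          rs2 += v * v;
        }
      }
    const double rvar = n * rs2 - rs * rs;
    if (rvar <= 0.0) { valid[b] = false; continue; }

    double best = -1.0;
    int bdx = 0, bdy = 0, bdz = 0;
    const int px = pred(b, 0), py = pred(b, 1), pz = pred(b, 2);
    for (int dx = -radius; dx <= radius; ++dx)
      for (int dy = -radius; dy <= radius; ++dy)
        for (int dz = -radius; dz <= radius; ++dz) {
          const double score = blockScore(rblock, rs, rvar, mov, mnx, mny, mnz,
                                          px + dx, py + dy, pz + dz, h);
          if (score > best) { best = score; bdx = dx; bdy = dy; bdz = dz; }
        }
    if (best < 0.0) { valid[b] = false; continue; }
    valid[b] = true;
    scores[b] = best > 1.0 ? 1.0 : best;  // guard fp overshoot
    double off[3] = {(double)bdx, (double)bdy, (double)bdz};
    // parabolic sub-voxel refinement per axis around the integer optimum;
    // an exact peak (score 1, e.g. self-matching) is already sub-voxel
    // perfect and must not be moved by asymmetric neighbour scores
    const int bo[3] = {px + bdx, py + bdy, pz + bdz};
    for (int ax = 0; best < 1.0 - 1e-12 && ax < 3; ++ax) {
      int lo[3] = {bo[0], bo[1], bo[2]};
      int hi2[3] = {bo[0], bo[1], bo[2]};
      lo[ax] -= 1;
      hi2[ax] += 1;
      const double sm = blockScore(rblock, rs, rvar, mov, mnx, mny, mnz,
                                   lo[0], lo[1], lo[2], h);
      const double sp = blockScore(rblock, rs, rvar, mov, mnx, mny, mnz,
                                   hi2[0], hi2[1], hi2[2], h);
      if (sm < 0.0 || sp < 0.0) continue;
      const double denom = sm - 2.0 * best + sp;
      if (denom >= -1e-12) continue;  // not a strict local maximum
      double d = 0.5 * (sm - sp) / denom;
      if (d > 0.5) d = 0.5;
      if (d < -0.5) d = -0.5;
      off[ax] += d;
    }
    offsets(b, 0) = off[0];
    offsets(b, 1) = off[1];
    offsets(b, 2) = off[2];
  }
  return List::create(_["offsets"] = offsets, _["scores"] = scores,
                      _["valid"] = valid);
}
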