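#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Pair counting for the masked GLCM. Counts every ordered pair
// (px[r, c], px[r + dr, c + dc]) whose two endpoints are BOTH masked;
// with symmetric = true each pair also contributes to the transposed
// cell. Counts are stored column-major: cell (i, j) at j * levels + i.
// [[Rcpp::export]]
List glcm_pair_counts(const IntegerMatrix& px, const LogicalMatrix& mask,
                      int dr, int dc, int levels, bool symmetric) {
  const int h = px.nrow(), w = px.ncol();
  IntegerVector counts(levels * levels);
  int* cnt = INTEGER(counts);
  long long n_pairs = 0;
  const int r_lo = std::max(0, -dr), r_hi = std::min(h, h - dr);
  const int c_lo = std::max(0, -dc), c_hi = std::min(w, w - dc);
  for (int c = c_lo; c < c_hi; ++c) {
    for (int r = r_lo; r < r_hi; ++r) {
      if (mask(r, c) && mask(r + dr, c + dc)) {
        const int i = px(r, c), j = px(r + dr, c + dc);
        ++cnt[j * levels + i];
        if (symmetric) ++cnt[i * levels + j];
        ++n_pairs;
      }
    }
  }
  return List::create(_["counts"] = counts,
                      _["n_pairs"] = (double)n_pairs);
}

// One pass over the probability matrix: the sums every Haralick feature
// is assembled from. Long-double accumulators match R's sum() precision.
// Entropy is returned in nats. p is column-major, cell (i, j) at
// j * levels + i with i the reference grey level.
// [[Rcpp::export]]
List glcm_feature_sums(const NumericVector& p, int levels) {
  const double* v = REAL(p);
  long double total = 0, asm_ = 0, contrast = 0, idm = 0, ent = 0, sij = 0;
  std::vector<long double> px_marg(levels, 0.0L), py_marg(levels, 0.0L);
  bool any_neg = false;
  for (int j = 0; j < levels; ++j) {
    const double* col = v + (size_t)j * levels;
    for (int i = 0; i < levels; ++i) {
      const double pij = col[i];
      if (pij == 0.0) continue;
      if (pij < 0.0) { any_neg = true; continue; }
      total += pij;
      asm_ += (long double)pij * pij;
      const double d = i - j;
      contrast += d * d * (long double)pij;
      idm += pij / (1.0 + d * d);
      ent -= pij * std::log(pij);
      sij += (long double)i * j * pij;
      px_marg[i] += pij;
      py_marg[j] += pij;
    }
  }
  long double mu_x = 0, mu_y = 0;
  for (int k = 0; k < levels; ++k) {
    mu_x += (long double)k * px_marg[k];
    mu_y += (long double)k * py_marg[k];
  }
  long double var_x = 0, var_y = 0;
  for (int k = 0; k < levels; ++k) {
    const long double dx = k - mu_x, dy = k - mu_y;
    var_x += dx * dx * px_marg[k];
    var_y += dy * dy * py_marg[k];
  }
  return List::create(
    _["total"] = (double)total, _["any_neg"] = any_neg,
    _["asm"] = (double)asm_, _["contrast"] = (double)contrast,
    _["idm"] = (double)idm, _["entropy_nats"] = (double)ent,
    _["sum_ij"] = (double)sij,
    _["mu_x"] = (double)mu_x, _["mu_y"] = (double)mu_y,
    _["var_x"] = (double)var_x, _["var_y"] = (double)var_y);
}

// round(gain * x + offset) clipped to [0, 255] in one pass; the frame
// quantiser and per-machine grey remapping share it.
// [[Rcpp::export]]
IntegerMatrix remap_u8(const NumericMatrix& x, double gain, double offset) {
  IntegerMatrix out(x.nrow(), x.ncol());
  const double* in = REAL(x);
  int* o = INTEGER(out);
  const R_xlen_t n = x.size();
  for (R_xlen_t k = 0; k < n; ++k) {
    double v = std::nearbyint(gain * in[k] + offset);
    if (v < 0) v = 0; else if (v > 255) v = 255;
    o[k] = (int)v;
  }
  return out;
}
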