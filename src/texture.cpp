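#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// The 13 unique 3D direction vectors at Chebyshev distance 1 (one of each
// antipodal pair). Pair-based structures (GLCM, runs) also use the reverse
// of each, giving the full 26-neighborhood.
static const int DIRS[13][3] = {
  {1,0,0},{0,1,0},{0,0,1},
  {1,1,0},{1,-1,0},{1,0,1},{1,0,-1},{0,1,1},{0,1,-1},
  {1,1,1},{1,1,-1},{1,-1,1},{1,-1,-1}
};

// VOI levels embedded in a grid padded by one background voxel on every
// side, so neighbor access is a plain offset read (padding absorbs all
// bounds checks; level 0 = outside the VOI).
struct VoiGrid {
  int px, py, pz;              // padded dims
  std::vector<int> lev;        // padded level grid
  std::vector<size_t> vid;     // padded linear index per VOI voxel
  int nvoi;
  int nbins;
  long dir_off[13];            // linear offsets of the 13 directions
  long nbr_off[26];            // linear offsets of the full 26-neighborhood

  void init_dims(const IntegerVector& dims) {
    px = dims[0] + 2; py = dims[1] + 2; pz = dims[2] + 2;
    lev.assign((size_t)px * py * pz, 0);
    for (int d = 0; d < 13; ++d) {
      dir_off[d] = DIRS[d][0] + (long)px * (DIRS[d][1] + (long)py * DIRS[d][2]);
      nbr_off[2 * d] = dir_off[d];
      nbr_off[2 * d + 1] = -dir_off[d];
    }
  }
  void set_voxels(const IntegerVector& idx0, const IntegerVector& dims) {
    const int nx = dims[0], ny = dims[1];
    nvoi = idx0.size();
    vid.resize(nvoi);
    for (int k = 0; k < nvoi; ++k) {
      size_t id = (size_t)idx0[k];
      if (id >= (size_t)dims[0] * dims[1] * dims[2]) stop("voxel index out of grid");
      const int x = (int)(id % nx);
      const int y = (int)((id / nx) % ny);
      const int z = (int)(id / ((size_t)nx * ny));
      vid[k] = (size_t)(x + 1) + (size_t)px * ((size_t)(y + 1) + (size_t)py * (z + 1));
    }
  }
  void set_levels(const IntegerVector& levels) {
    if ((int)levels.size() != nvoi) stop("levels and indices differ in length");
    for (int k = 0; k < nvoi; ++k) {
      const int l = levels[k];
      if (l < 1 || l > nbins) stop("level out of range 1..n_bins");
      if (lev[vid[k]] != 0) stop("duplicate voxel index in VOI");
      lev[vid[k]] = l;
    }
  }
  void clear_levels() {
    for (int k = 0; k < nvoi; ++k) lev[vid[k]] = 0;
  }
};

// ---- matrix builders -------------------------------------------------------

// One fused pass over the 26-neighborhood fills the symmetric GLCM (pair
// counts over 13 directions in both orientations = one ordered count per
// neighbor), the NGLDM dependence counts (equal-level neighbors, alpha = 0)
// and the NGTDM occurrence/difference accumulators.
static void pass_neighbors(const VoiGrid& g, std::vector<double>& glcm,
                           std::vector<double>& ngldm,
                           std::vector<double>& tn, std::vector<double>& ts) {
  glcm.assign((size_t)g.nbins * g.nbins, 0.0);
  ngldm.assign((size_t)g.nbins * 27, 0.0);
  tn.assign(g.nbins, 0.0);
  ts.assign(g.nbins, 0.0);
  for (int k = 0; k < g.nvoi; ++k) {
    const size_t id = g.vid[k];
    const int i = g.lev[id];
    int dep = 0, cnt = 0;
    double sum = 0.0;
    for (int d = 0; d < 26; ++d) {
      const int j = g.lev[id + g.nbr_off[d]];
      if (j == 0) continue;
      glcm[(size_t)(i - 1) + (size_t)g.nbins * (j - 1)] += 1.0;
      if (j == i) ++dep;
      sum += j; ++cnt;
    }
    ngldm[(size_t)(i - 1) + (size_t)g.nbins * dep] += 1.0;
    if (cnt > 0) {
      tn[i - 1] += 1.0;
      ts[i - 1] += std::fabs((double)i - sum / cnt);
    }
  }
}

// Maximal equal-level runs merged over the 13 directions, kept as sparse
// per-level rows: rows[i][l-1] = count of runs of level i+1 and length l.
static std::vector<std::vector<double>> build_glrlm(const VoiGrid& g, int& max_len) {
  std::vector<std::vector<double>> rows(g.nbins);
  max_len = 1;
  for (int d = 0; d < 13; ++d) {
    const long off = g.dir_off[d];
    for (int k = 0; k < g.nvoi; ++k) {
      const size_t id = g.vid[k];
      const int l = g.lev[id];
      if (g.lev[id - off] == l) continue;  // not a run start
      int len = 1;
      size_t cur = id + off;
      while (g.lev[cur] == l) { ++len; cur += off; }
      if (len > max_len) max_len = len;
      std::vector<double>& row = rows[l - 1];
      if ((int)row.size() < len) row.resize(len, 0.0);
      row[len - 1] += 1.0;
    }
  }
  return rows;
}

// 26-connected equal-level zones, same sparse row layout as build_glrlm.
static std::vector<std::vector<double>> build_glszm(const VoiGrid& g, int& max_size) {
  std::vector<std::vector<double>> rows(g.nbins);
  std::vector<char> seen(g.lev.size(), 0);
  std::vector<size_t> stack;
  max_size = 1;
  for (int k = 0; k < g.nvoi; ++k) {
    const size_t id = g.vid[k];
    if (seen[id]) continue;
    const int l = g.lev[id];
    int size = 0;
    seen[id] = 1;
    stack.clear();
    stack.push_back(id);
    while (!stack.empty()) {
      const size_t cur = stack.back(); stack.pop_back();
      ++size;
      for (int d = 0; d < 26; ++d) {
        const size_t nid = cur + g.nbr_off[d];
        if (seen[nid] || g.lev[nid] != l) continue;
        seen[nid] = 1;
        stack.push_back(nid);
      }
    }
    if (size > max_size) max_size = size;
    std::vector<double>& row = rows[l - 1];
    if ((int)row.size() < size) row.resize(size, 0.0);
    row[size - 1] += 1.0;
  }
  return rows;
}

// ---- feature computation ---------------------------------------------------

static inline double xlog2(double p) { return p > 0.0 ? p * std::log2(p) : 0.0; }

static void glcm_feats(const std::vector<double>& C, int N, double* out) {
  double S = 0.0;
  for (double v : C) S += v;
  for (int f = 0; f < 11; ++f) out[f] = 0.0;
  if (S <= 0.0) return;
  std::vector<double> px(N, 0.0), psum(2 * N + 1, 0.0), pdiff(N, 0.0);
  std::vector<double> inv_abs(N), inv_sq(N);
  for (int d = 0; d < N; ++d) {
    inv_abs[d] = 1.0 / (1.0 + d);
    inv_sq[d] = 1.0 / (1.0 + (double)d * d);
  }
  const double invS = 1.0 / S;
  double energy = 0, entropy = 0, contrast = 0, dissim = 0, invdiff = 0, idm = 0;
  double cross = 0;
  for (int j = 0; j < N; ++j) {
    for (int i = 0; i < N; ++i) {
      const double c = C[(size_t)i + (size_t)N * j];
      if (c == 0.0) continue;
      const double p = c * invS;
      const int ad = std::abs(i - j);
      energy += p * p;
      entropy -= xlog2(p);
      contrast += p * ad * ad;
      dissim += p * ad;
      invdiff += p * inv_abs[ad];
      idm += p * inv_sq[ad];
      cross += p * (i + 1.0) * (j + 1.0);
      px[i] += p;
      psum[i + j] += p;          // k = (i+1)+(j+1) stored at i+j
      pdiff[ad] += p;
    }
  }
  double mu = 0.0;
  for (int i = 0; i < N; ++i) mu += (i + 1.0) * px[i];
  double var = 0.0;
  for (int i = 0; i < N; ++i) var += (i + 1.0 - mu) * (i + 1.0 - mu) * px[i];
  double corr = (var > 1e-12) ? (cross - mu * mu) / var : 0.0;
  double sum_avg = 0.0, sum_ent = 0.0;
  for (int k = 0; k <= 2 * N - 2; ++k) {
    sum_avg += (k + 2.0) * psum[k];
    sum_ent -= xlog2(psum[k]);
  }
  double diff_ent = 0.0;
  for (int k = 0; k < N; ++k) diff_ent -= xlog2(pdiff[k]);
  out[0] = energy; out[1] = entropy; out[2] = contrast; out[3] = dissim;
  out[4] = invdiff; out[5] = idm; out[6] = corr; out[7] = var;
  out[8] = sum_avg; out[9] = sum_ent; out[10] = diff_ent;
}

// Shared skeleton for GLRLM/GLSZM features on sparse per-level rows, with a
// per-voxel denominator for the percentage feature.
static void rl_sz_feats(const std::vector<std::vector<double>>& rows, int N,
                        int Lmax, double pct_denom, double* out) {
  for (int f = 0; f < 13; ++f) out[f] = 0.0;
  double total = 0.0;
  for (const auto& row : rows) for (double v : row) total += v;
  if (total <= 0.0) return;
  std::vector<double> mi(N, 0.0), ml(Lmax, 0.0);
  double sre = 0, lre = 0, lgre = 0, hgre = 0, srlge = 0, srhge = 0, lrlge = 0, lrhge = 0;
  for (int i = 0; i < N; ++i) {
    const double I2 = (i + 1.0) * (i + 1.0);
    for (int l = 0; l < (int)rows[i].size(); ++l) {
      const double c = rows[i][l];
      if (c == 0.0) continue;
      const double p = c / total;
      const double L2 = (l + 1.0) * (l + 1.0);
      sre += p / L2; lre += p * L2;
      lgre += p / I2; hgre += p * I2;
      srlge += p / (I2 * L2); srhge += p * I2 / L2;
      lrlge += p * L2 / I2; lrhge += p * I2 * L2;
      mi[i] += c; ml[l] += c;
    }
  }
  double gln = 0.0, rln = 0.0, mu_i = 0.0, mu_l = 0.0;
  for (int i = 0; i < N; ++i) { gln += mi[i] * mi[i]; mu_i += (i + 1.0) * mi[i] / total; }
  for (int l = 0; l < Lmax; ++l) { rln += ml[l] * ml[l]; mu_l += (l + 1.0) * ml[l] / total; }
  gln /= total; rln /= total;
  double vi = 0.0, vl = 0.0;
  for (int i = 0; i < N; ++i) vi += (i + 1.0 - mu_i) * (i + 1.0 - mu_i) * mi[i] / total;
  for (int l = 0; l < Lmax; ++l) vl += (l + 1.0 - mu_l) * (l + 1.0 - mu_l) * ml[l] / total;
  out[0] = sre; out[1] = lre; out[2] = lgre; out[3] = hgre;
  out[4] = srlge; out[5] = srhge; out[6] = lrlge; out[7] = lrhge;
  out[8] = gln; out[9] = rln; out[10] = total / pct_denom;
  out[11] = vi; out[12] = vl;
}

static void ngldm_feats(const std::vector<double>& S, int N, double* out) {
  double total = 0.0;
  for (double v : S) total += v;
  for (int f = 0; f < 16; ++f) out[f] = 0.0;
  if (total <= 0.0) return;
  std::vector<double> si(N, 0.0), sj(27, 0.0);
  double lde = 0, hde = 0, lgce = 0, hgce = 0, ldlge = 0, ldhge = 0, hdlge = 0, hdhge = 0;
  double ent = 0, ene = 0;
  for (int j = 0; j < 27; ++j) {
    const double J2 = (j + 1.0) * (j + 1.0);
    for (int i = 0; i < N; ++i) {
      const double c = S[(size_t)i + (size_t)N * j];
      if (c == 0.0) continue;
      const double p = c / total;
      const double I2 = (i + 1.0) * (i + 1.0);
      lde += p / J2; hde += p * J2;
      lgce += p / I2; hgce += p * I2;
      ldlge += p / (I2 * J2); ldhge += p * I2 / J2;
      hdlge += p * J2 / I2; hdhge += p * I2 * J2;
      ent -= xlog2(p); ene += p * p;
      si[i] += c; sj[j] += c;
    }
  }
  double gln = 0.0, dcn = 0.0;
  for (int i = 0; i < N; ++i) gln += si[i] * si[i];
  for (int j = 0; j < 27; ++j) dcn += sj[j] * sj[j];
  double mu_i = 0.0, mu_j = 0.0;
  for (int i = 0; i < N; ++i) mu_i += (i + 1.0) * si[i] / total;
  for (int j = 0; j < 27; ++j) mu_j += (j + 1.0) * sj[j] / total;
  double vi = 0.0, vj = 0.0;
  for (int i = 0; i < N; ++i) vi += (i + 1.0 - mu_i) * (i + 1.0 - mu_i) * si[i] / total;
  for (int j = 0; j < 27; ++j) vj += (j + 1.0 - mu_j) * (j + 1.0 - mu_j) * sj[j] / total;
  out[0] = lde; out[1] = hde; out[2] = lgce; out[3] = hgce;
  out[4] = ldlge; out[5] = ldhge; out[6] = hdlge; out[7] = hdhge;
  out[8] = gln / total; out[9] = gln / (total * total);
  out[10] = dcn / total; out[11] = dcn / (total * total);
  out[12] = vi; out[13] = vj; out[14] = ent; out[15] = ene;
}

static void ngtdm_feats(const std::vector<double>& n, const std::vector<double>& s,
                        int N, double* out) {
  const double EPS = 1e-6;
  for (int f = 0; f < 5; ++f) out[f] = 0.0;
  double nvc = 0.0;
  for (double v : n) nvc += v;
  if (nvc <= 0.0) return;
  std::vector<double> p(N);
  int ngp = 0;
  double ps = 0.0, ssum = 0.0;
  for (int i = 0; i < N; ++i) {
    p[i] = n[i] / nvc;
    if (p[i] > 0.0) ++ngp;
    ps += p[i] * s[i];
    ssum += s[i];
  }
  out[0] = 1.0 / std::max(ps, EPS); // coarseness
  double cgrad = 0.0, busy_den = 0.0, cmplx = 0.0, strength_num = 0.0;
  for (int i = 0; i < N; ++i) {
    if (p[i] == 0.0) continue;
    for (int j = 0; j < N; ++j) {
      if (p[j] == 0.0) continue;
      const double dij = (double)(i - j);
      cgrad += p[i] * p[j] * dij * dij;
      busy_den += std::fabs((i + 1.0) * p[i] - (j + 1.0) * p[j]);
      cmplx += std::fabs(dij) * (p[i] * s[i] + p[j] * s[j]) / (p[i] + p[j]);
      strength_num += (p[i] + p[j]) * dij * dij;
    }
  }
  out[1] = (ngp > 1) ? (cgrad / (ngp * (ngp - 1.0))) * (ssum / nvc) : 0.0;
  out[2] = (busy_den > 0.0) ? ps / busy_den : 0.0;
  out[3] = cmplx / nvc;
  out[4] = (ssum > 0.0) ? strength_num / ssum : 0.0;
}

static void all_features(VoiGrid& g, double* out) {
  std::vector<double> glcm, ngldm, tn, ts;
  pass_neighbors(g, glcm, ngldm, tn, ts);
  glcm_feats(glcm, g.nbins, out);
  int max_run = 0, max_zone = 0;
  std::vector<std::vector<double>> R = build_glrlm(g, max_run);
  rl_sz_feats(R, g.nbins, max_run, 13.0 * g.nvoi, out + 11);
  std::vector<std::vector<double>> Z = build_glszm(g, max_zone);
  rl_sz_feats(Z, g.nbins, max_zone, (double)g.nvoi, out + 24);
  ngldm_feats(ngldm, g.nbins, out + 37);
  ngtdm_feats(tn, ts, g.nbins, out + 53);
}

// Fixed-bin-number quantization of the within-VOI values (same formula as
// the R-level quantize()).
static void quantize_into(const NumericVector& x, int nbins, std::vector<int>& lev) {
  const int n = x.size();
  lev.resize(n);
  double lo = x[0], hi = x[0];
  for (int i = 1; i < n; ++i) { lo = std::min(lo, x[i]); hi = std::max(hi, x[i]); }
  if (hi == lo) { std::fill(lev.begin(), lev.end(), 1); return; }
  for (int i = 0; i < n; ++i) {
    int l = (int)std::floor(nbins * (x[i] - lo) / (hi - lo)) + 1;
    lev[i] = l > nbins ? nbins : l;
  }
}

// ---- exported entry points -------------------------------------------------

// [[Rcpp::export]]
List cpp_texture_matrices(const IntegerVector& levels,
                          const IntegerVector& idx0,
                          const IntegerVector& dims,
                          int nbins) {
  VoiGrid g;
  g.nbins = nbins;
  g.init_dims(dims);
  g.set_voxels(idx0, dims);
  g.set_levels(levels);
  std::vector<double> C, S, nn, ss;
  pass_neighbors(g, C, S, nn, ss);
  int max_run = 0, max_zone = 0;
  std::vector<std::vector<double>> R = build_glrlm(g, max_run);
  std::vector<std::vector<double>> Z = build_glszm(g, max_zone);

  NumericMatrix glcm(nbins, nbins), glrlm(nbins, max_run),
                glszm(nbins, max_zone), ngldm(nbins, 27);
  std::copy(C.begin(), C.end(), glcm.begin());
  std::copy(S.begin(), S.end(), ngldm.begin());
  for (int i = 0; i < nbins; ++i) {
    for (int l = 0; l < (int)R[i].size(); ++l) glrlm(i, l) = R[i][l];
    for (int s = 0; s < (int)Z[i].size(); ++s) glszm(i, s) = Z[i][s];
  }
  return List::create(
    _["glcm_counts"] = glcm, _["glrlm"] = glrlm, _["glszm"] = glszm,
    _["ngldm"] = ngldm,
    _["ngtdm_n"] = NumericVector(nn.begin(), nn.end()),
    _["ngtdm_s"] = NumericVector(ss.begin(), ss.end()));
}

// All 58 texture features (11 GLCM, 13 GLRLM, 13 GLSZM, 16 NGLDM, 5 NGTDM)
// in registry order; names are attached on the R side.
// [[Rcpp::export]]
NumericVector cpp_texture_features(const IntegerVector& levels,
                                   const IntegerVector& idx0,
                                   const IntegerVector& dims,
                                   int nbins) {
  VoiGrid g;
  g.nbins = nbins;
  g.init_dims(dims);
  g.set_voxels(idx0, dims);
  g.set_levels(levels);
  NumericVector out(58);
  all_features(g, &out[0]);
  return out;
}

// Extraction fast path: quantize the within-VOI values at each bin setting
// and compute all 58 features per setting, re-using the padded grid.
// Returns a 58 x length(bins) matrix.
// [[Rcpp::export]]
NumericMatrix cpp_texture_features_multi(const NumericVector& voi_values,
                                         const IntegerVector& idx0,
                                         const IntegerVector& dims,
                                         const IntegerVector& bins) {
  VoiGrid g;
  g.init_dims(dims);
  g.set_voxels(idx0, dims);
  NumericMatrix out(58, bins.size());
  std::vector<int> lev;
  for (int b = 0; b < bins.size(); ++b) {
    g.nbins = bins[b];
    quantize_into(voi_values, g.nbins, lev);
    for (int k = 0; k < g.nvoi; ++k) g.lev[g.vid[k]] = lev[k];
    all_features(g, &out(0, b));
  }
  return out;
}
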