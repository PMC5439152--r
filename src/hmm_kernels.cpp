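// Li-Stephens haplotype-copying HMM kernels.
//
// Template haplotypes are passed as an |H| x M integer matrix of 0/1 alleles.
// The per-gamete transition matrix between adjacent markers is
//   T = (1 - theta_i) * I + (theta_i / |H|) * J,
// so a forward step costs O(|H|) (haploid) or O(|H|^2) (diploid, applying T
// to rows and columns) instead of the dense O(|H|^2) / O(|H|^4).
//
// Observation codes: haploid alleles 0/1, 9 missing; diploid genotypes
// 0/1/2, 9 missing, 3 = genotype in {0,1} (one gamete known to carry 0),
// 4 = genotype in {1,2}.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline double hap_emit(int obs, int tmpl, double eps) {
  if (obs == 9) return 1.0;
  return (obs == tmpl) ? 1.0 - eps : eps;
}

// genotype emission table for template alleles (a, b): each template allele is
// read with independent flip probability eps; the genotype is the sum of the
// two reads.
static inline void dip_emit_table(double eps, int obs, double out[2][2]) {
  for (int a = 0; a < 2; ++a) {
    for (int b = 0; b < 2; ++b) {
      double qa1 = (a == 1) ? 1.0 - eps : eps; // P(read 1 | a)
      double qb1 = (b == 1) ? 1.0 - eps : eps;
      double p0 = (1.0 - qa1) * (1.0 - qb1);
      double p1 = qa1 * (1.0 - qb1) + (1.0 - qa1) * qb1;
      double p2 = qa1 * qb1;
      double v;
      switch (obs) {
      case 0: v = p0; break;
      case 1: v = p1; break;
      case 2: v = p2; break;
      case 3: v = p0 + p1; break;
      case 4: v = p1 + p2; break;
      default: v = 1.0;
      }
      out[a][b] = v;
    }
  }
}

// [[Rcpp::export]]
List fb_haploid_full(IntegerVector obs, IntegerMatrix H, NumericVector theta,
                     NumericVector eps) {
  int nH = H.nrow(), M = H.ncol();
  NumericMatrix fwd(M, nH), post(M, nH);
  std::vector<double> bwd(nH, 1.0), tmp(nH);
  double loglik = 0.0;
  for (int i = 0; i < M; ++i) {
    double z = 0.0;
    for (int h = 0; h < nH; ++h) {
      double prev;
      if (i == 0) {
        prev = 1.0 / nH;
      } else {
        prev = 0.0; // filled below
      }
      fwd(i, h) = prev;
    }
    if (i > 0) {
      double s = 0.0;
      for (int h = 0; h < nH; ++h) s += fwd(i - 1, h);
      double c = theta[i - 1] / nH, d = 1.0 - theta[i - 1];
      for (int h = 0; h < nH; ++h) fwd(i, h) = c * s + d * fwd(i - 1, h);
    }
    for (int h = 0; h < nH; ++h) {
      fwd(i, h) *= hap_emit(obs[i], H(h, i), eps[i]);
      z += fwd(i, h);
    }
    if (z <= 0.0) stop("zero forward vector at marker %d", i + 1);
    for (int h = 0; h < nH; ++h) fwd(i, h) /= z;
    loglik += std::log(z);
  }
  for (int i = M - 1; i >= 0; --i) {
    double z = 0.0;
    for (int h = 0; h < nH; ++h) {
      post(i, h) = fwd(i, h) * bwd[h];
      z += post(i, h);
    }
    for (int h = 0; h < nH; ++h) post(i, h) /= z;
    if (i > 0) {
      double s = 0.0;
      for (int h = 0; h < nH; ++h) {
        tmp[h] = bwd[h] * hap_emit(obs[i], H(h, i), eps[i]);
        s += tmp[h];
      }
      double c = theta[i - 1] / nH, d = 1.0 - theta[i - 1];
      double zb = 0.0;
      for (int h = 0; h < nH; ++h) {
        bwd[h] = c * s + d * tmp[h];
        zb += bwd[h];
      }
      for (int h = 0; h < nH; ++h) bwd[h] /= zb;
    }
  }
  return List::create(_["posteriors"] = post, _["loglik"] = loglik);
}

// [[Rcpp::export]]
List fb_diploid_full(IntegerVector obs, IntegerMatrix H, NumericVector theta,
                     NumericVector eps) {
  int nH = H.nrow(), M = H.ncol(), S = nH * nH;
  NumericMatrix fwd(M, S), post(M, S);
  std::vector<double> bwd(S, 1.0), tmp(S), rowsum(nH), colsum(nH);
  double loglik = 0.0;
  double em[2][2];
  for (int i = 0; i < M; ++i) {
    if (i == 0) {
      for (int s = 0; s < S; ++s) fwd(0, s) = 1.0 / S;
    } else {
      double c = theta[i - 1] / nH, d = 1.0 - theta[i - 1];
      std::fill(rowsum.begin(), rowsum.end(), 0.0);
      std::fill(colsum.begin(), colsum.end(), 0.0);
      double tot = 0.0;
      for (int h = 0; h < nH; ++h)
        for (int k = 0; k < nH; ++k) {
          double v = fwd(i - 1, h * nH + k);
          rowsum[h] += v;
          colsum[k] += v;
          tot += v;
        }
      for (int h = 0; h < nH; ++h)
        for (int k = 0; k < nH; ++k) {
          double v = d * d * fwd(i - 1, h * nH + k) + d * c * rowsum[h] +
                     c * d * colsum[k] + c * c * tot;
          fwd(i, h * nH + k) = v;
        }
    }
    dip_emit_table(eps[i], obs[i], em);
    double z = 0.0;
    for (int h = 0; h < nH; ++h)
      for (int k = 0; k < nH; ++k) {
        double v = fwd(i, h * nH + k) * em[H(h, i)][H(k, i)];
        fwd(i, h * nH + k) = v;
        z += v;
      }
    if (z <= 0.0) stop("zero forward vector at marker %d", i + 1);
    for (int s = 0; s < S; ++s) fwd(i, s) /= z;
    loglik += std::log(z);
  }
  for (int i = M - 1; i >= 0; --i) {
    double z = 0.0;
    for (int s = 0; s < S; ++s) {
      post(i, s) = fwd(i, s) * bwd[s];
      z += post(i, s);
    }
    for (int s = 0; s < S; ++s) post(i, s) /= z;
    if (i > 0) {
      dip_emit_table(eps[i], obs[i], em);
      for (int h = 0; h < nH; ++h)
        for (int k = 0; k < nH; ++k)
          tmp[h * nH + k] = bwd[h * nH + k] * em[H(h, i)][H(k, i)];
      double c = theta[i - 1] / nH, d = 1.0 - theta[i - 1];
      std::fill(rowsum.begin(), rowsum.end(), 0.0);
      std::fill(colsum.begin(), colsum.end(), 0.0);
      double tot = 0.0;
      for (int h = 0; h < nH; ++h)
        for (int k = 0; k < nH; ++k) {
          rowsum[h] += tmp[h * nH + k];
          colsum[k] += tmp[h * nH + k];
          tot += tmp[h * nH + k];
        }
      double zb = 0.0;
      for (int h = 0; h < nH; ++h)
        for (int k = 0; k < nH; ++k) {
          double v = d * d * tmp[h * nH + k] + d * c * rowsum[h] +
                     c * d * colsum[k] + c * c * tot;
          bwd[h * nH + k] = v;
          zb += v;
        }
      for (int s = 0; s < S; ++s) bwd[s] /= zb;
    }
  }
  return List::create(_["posteriors"] = post, _["loglik"] = loglik);
}

static int sample_index(const double* w, int n, double total) {
  double u = unif_rand() * total, acc = 0.0;
  for (int j = 0; j < n; ++j) {
    acc += w[j];
    if (u <= acc) return j;
  }
  return n - 1;
}

static int sample_index_f(const float* w, int n, double total) {
  double u = unif_rand() * total, acc = 0.0;
  for (int j = 0; j < n; ++j) {
    acc += w[j];
    if (u <= acc) return j;
  }
  return n - 1;
}

// Haploid forward-backward with posterior allele probabilities and one
// stochastic traceback (path + per-interval jump indicators).
// [[Rcpp::export]]
List hmm_sample_haploid(IntegerVector obs, IntegerMatrix H, NumericVector theta,
                        NumericVector eps) {
  int nH = H.nrow(), M = H.ncol();
  static std::vector<double> fwd, bwd, tmp;
  fwd.resize((size_t)M * nH);
  bwd.assign(nH, 1.0);
  tmp.resize(nH);
  NumericVector p1(M);
  double loglik = 0.0;
  for (int i = 0; i < M; ++i) {
    double* fi = &fwd[(size_t)i * nH];
    if (i == 0) {
      for (int h = 0; h < nH; ++h) fi[h] = 1.0 / nH;
    } else {
      const double* fp = &fwd[(size_t)(i - 1) * nH];
      double s = 0.0;
      for (int h = 0; h < nH; ++h) s += fp[h];
      double c = theta[i - 1] / nH, d = 1.0 - theta[i - 1];
      for (int h = 0; h < nH; ++h) fi[h] = c * s + d * fp[h];
    }
    double z = 0.0;
    for (int h = 0; h < nH; ++h) {
      fi[h] *= hap_emit(obs[i], H(h, i), eps[i]);
      z += fi[h];
    }
    if (z <= 0.0) stop("zero forward vector at marker %d", i + 1);
    for (int h = 0; h < nH; ++h) fi[h] /= z;
    loglik += std::log(z);
  }
  // backward smoothing for allele-1 posterior probabilities
  for (int i = M - 1; i >= 0; --i) {
    const double* fi = &fwd[(size_t)i * nH];
    double z = 0.0, a1 = 0.0;
    for (int h = 0; h < nH; ++h) {
      double v = fi[h] * bwd[h];
      z += v;
      if (H(h, i) == 1) a1 += v;
    }
    p1[i] = a1 / z;
    if (i > 0) {
      double s = 0.0;
      for (int h = 0; h < nH; ++h) {
        tmp[h] = bwd[h] * hap_emit(obs[i], H(h, i), eps[i]);
        s += tmp[h];
      }
      double c = theta[i - 1] / nH, d = 1.0 - theta[i - 1];
      double zb = 0.0;
      for (int h = 0; h < nH; ++h) {
        bwd[h] = c * s + d * tmp[h];
        zb += bwd[h];
      }
      for (int h = 0; h < nH; ++h) bwd[h] /= zb;
    }
  }
  // stochastic traceback
  IntegerVector path(M), jumps(std::max(M - 1, 0)), alleles(M);
  {
    const double* fM = &fwd[(size_t)(M - 1) * nH];
    path[M - 1] = sample_index(fM, nH, 1.0);
  }
  for (int i = M - 2; i >= 0; --i) {
    const double* fi = &fwd[(size_t)i * nH];
    int hn = path[i + 1];
    double c = theta[i] / nH, d = 1.0 - theta[i];
    double w_jump = c * 1.0;          // uniform jump to hn (per state: c * f)
    double w_stay = d * fi[hn];
    // total over previous states: jump part c * sum(f) = c; stay part d*f[hn]
    double u = unif_rand() * (w_jump + w_stay);
    if (u <= w_stay) {
      path[i] = hn;
      jumps[i] = 0;
    } else {
      path[i] = sample_index(fi, nH, 1.0);
      jumps[i] = 1;
    }
  }
  for (int i = 0; i < M; ++i) alleles[i] = H(path[i], i);
  return List::create(_["p1"] = p1, _["loglik"] = loglik, _["path"] = path,
                      _["jumps"] = jumps, _["alleles"] = alleles);
}

// Diploid counterpart; obs are genotype codes (0/1/2/9/3/4).
//
// The diploid forward and backward matrices are symmetric in (h, k) — the
// two gamete labels are exchangeable under the uniform prior, the factorized
// transition and the genotype emission — so only the lower triangle is
// computed and mirrored, and the per-marker history is stored in single
// precision (the per-marker normalization keeps values well scaled).
// [[Rcpp::export]]
List hmm_sample_diploid(IntegerVector obs, IntegerMatrix H, NumericVector theta,
                        NumericVector eps) {
  int nH = H.nrow(), M = H.ncol(), S = nH * nH;
  // persistent buffers: repeated multi-megabyte allocations would otherwise
  // dominate runtime (R is single-threaded, so this is safe)
  static std::vector<float> fwd;
  static std::vector<double> cur, prev, bwd, tmp, rowsum;
  static std::vector<int> ai;
  fwd.resize((size_t)M * S);
  cur.resize(S);
  prev.resize(S);
  bwd.assign(S, 1.0);
  tmp.resize(S);
  rowsum.resize(nH);
  ai.resize((size_t)M * nH); // alleles by marker, contiguous
  for (int i = 0; i < M; ++i)
    for (int h = 0; h < nH; ++h) ai[(size_t)i * nH + h] = H(h, i);
  NumericVector p1(M), p2(M);
  double loglik = 0.0, em[2][2];
  for (int i = 0; i < M; ++i) {
    const int* a = &ai[(size_t)i * nH];
    dip_emit_table(eps[i], obs[i], em);
    double z = 0.0;
    if (i == 0) {
      double u = 1.0 / S;
      for (int h = 0; h < nH; ++h) {
        const double* eh = em[a[h]];
        for (int k = 0; k <= h; ++k) {
          double v = u * eh[a[k]];
          cur[(size_t)h * nH + k] = v;
          cur[(size_t)k * nH + h] = v;
          z += (k == h) ? v : 2.0 * v;
        }
      }
    } else {
      double c = theta[i - 1] / nH, d = 1.0 - theta[i - 1];
      double tot = 0.0;
      for (int h = 0; h < nH; ++h) {
        const double* ph = &prev[(size_t)h * nH];
        double rs = 0.0;
        for (int k = 0; k < nH; ++k) rs += ph[k];
        rowsum[h] = rs;
        tot += rs;
      }
      double dd = d * d, cd = c * d, cc = c * c;
      double base = cc * tot;
      for (int h = 0; h < nH; ++h) {
        const double* ph = &prev[(size_t)h * nH];
        const double* eh = em[a[h]];
        double add_h = cd * rowsum[h] + base;
        for (int k = 0; k <= h; ++k) {
          double v = (dd * ph[k] + add_h + cd * rowsum[k]) * eh[a[k]];
          cur[(size_t)h * nH + k] = v;
          cur[(size_t)k * nH + h] = v;
          z += (k == h) ? v : 2.0 * v;
        }
      }
    }
    if (z <= 0.0) stop("zero forward vector at marker %d", i + 1);
    double inv = 1.0 / z;
    float* fi = &fwd[(size_t)i * S];
    for (int s = 0; s < S; ++s) {
      cur[s] *= inv;
      fi[s] = (float)cur[s];
    }
    prev.swap(cur);
    loglik += std::log(z);
  }
  // backward smoothing: per-marker allele-1 posterior per gamete (equal by
  // symmetry)
  for (int i = M - 1; i >= 0; --i) {
    const float* fi = &fwd[(size_t)i * S];
    const int* a = &ai[(size_t)i * nH];
    double z = 0.0, a1 = 0.0;
    for (int h = 0; h < nH; ++h) {
      const float* fih = fi + (size_t)h * nH;
      const double* bh = &bwd[(size_t)h * nH];
      double zs = 0.0;
      for (int k = 0; k < nH; ++k) zs += (double)fih[k] * bh[k];
      z += zs;
      if (a[h] == 1) a1 += zs;
    }
    p1[i] = a1 / z;
    p2[i] = p1[i];
    if (i > 0) {
      dip_emit_table(eps[i], obs[i], em);
      double tot = 0.0;
      for (int h = 0; h < nH; ++h) {
        const double* bh = &bwd[(size_t)h * nH];
        double* th = &tmp[(size_t)h * nH];
        const double* eh = em[a[h]];
        double rs = 0.0;
        for (int k = 0; k < nH; ++k) {
          double v = bh[k] * eh[a[k]];
          th[k] = v;
          rs += v;
        }
        rowsum[h] = rs;
        tot += rs;
      }
      double c = theta[i - 1] / nH, d = 1.0 - theta[i - 1];
      double dd = d * d, cd = c * d, cc = c * c;
      double base = cc * tot;
      double zb = 0.0;
      for (int h = 0; h < nH; ++h) {
        double* bh = &bwd[(size_t)h * nH];
        const double* th = &tmp[(size_t)h * nH];
        double add_h = cd * rowsum[h] + base;
        double zs = 0.0;
        for (int k = 0; k <= h; ++k) {
          double v = dd * th[k] + add_h + cd * rowsum[k];
          bh[k] = v;
          bwd[(size_t)k * nH + h] = v;
          zs += (k == h) ? v : 2.0 * v;
        }
        zb += zs;
      }
      double inv = 1.0 / zb;
      for (int s = 0; s < S; ++s) bwd[s] *= inv;
    }
  }
  // stochastic traceback over pairs with per-gamete jump indicators
  IntegerVector path1(M), path2(M), jumps1(std::max(M - 1, 0)),
      jumps2(std::max(M - 1, 0)), al1(M), al2(M);
  {
    const float* fM = &fwd[(size_t)(M - 1) * S];
    int s = sample_index_f(fM, S, 1.0);
    path1[M - 1] = s / nH;
    path2[M - 1] = s % nH;
  }
  for (int i = M - 2; i >= 0; --i) {
    const float* fi = &fwd[(size_t)i * S];
    int hn = path1[i + 1], kn = path2[i + 1];
    double c = theta[i] / nH, d = 1.0 - theta[i];
    double R = 0.0, C = 0.0;
    for (int k = 0; k < nH; ++k) R += fi[(size_t)hn * nH + k];
    for (int h = 0; h < nH; ++h) C += fi[(size_t)h * nH + kn];
    double F0 = fi[(size_t)hn * nH + kn];
    double w_jj = c * c, w_sj = d * c * R, w_js = c * d * C, w_ss = d * d * F0;
    double u = unif_rand() * (w_jj + w_sj + w_js + w_ss);
    if (u <= w_ss) {
      path1[i] = hn;
      path2[i] = kn;
      jumps1[i] = 0;
      jumps2[i] = 0;
    } else if (u <= w_ss + w_sj) {
      path1[i] = hn;
      jumps1[i] = 0;
      path2[i] = sample_index_f(fi + (size_t)hn * nH, nH, R);
      jumps2[i] = 1;
    } else if (u <= w_ss + w_sj + w_js) {
      jumps1[i] = 1;
      jumps2[i] = 0;
      path2[i] = kn;
      double uu = unif_rand() * C, acc = 0.0;
      int hs = nH - 1;
      for (int h = 0; h < nH; ++h) {
        acc += fi[(size_t)h * nH + kn];
        if (uu <= acc) {
          hs = h;
          break;
        }
      }
      path1[i] = hs;
    } else {
      jumps1[i] = 1;
      jumps2[i] = 1;
      int s = sample_index_f(fi, S, 1.0);
      path1[i] = s / nH;
      path2[i] = s % nH;
    }
  }
  for (int i = 0; i < M; ++i) {
    al1[i] = H(path1[i], i);
    al2[i] = H(path2[i], i);
  }
  return List::create(_["p1"] = p1, _["p2"] = p2, _["loglik"] = loglik,
                      _["path1"] = path1, _["path2"] = path2,
                      _["jumps1"] = jumps1, _["jumps2"] = jumps2,
                      _["alleles1"] = al1, _["alleles2"] = al2);
}
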