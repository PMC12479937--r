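// Fast kernels for the split-half permutation loop.
//
// The costly step of every permutation is forming each half's node x node
// covariance and Fisher-z edge vector. Motion blocks are contiguous frame
// runs fixed per participant, and permutations reassign whole blocks, so
// each block's packed lower-triangle crossproduct is cached once and a
// half's crossproduct is assembled by summing the cached matrices of the
// half with fewer blocks (the other half follows by subtraction from the
// full-data total).

#define USE_FC_LEN_T
#include <RcppArmadillo.h>
#include <R_ext/BLAS.h>
#ifndef FCONE
#define FCONE
#endif
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// atanh via 0.5*log((1+r)/(1-r)) where that is accurate to ~1e-14 relative
// (|r| >= 0.02); std::atanh handles the small-|r| cancellation region.
static inline double fast_atanh(const double r) {
  return (r > 0.02 || r < -0.02)
    ? 0.5 * std::log((1.0 + r) / (1.0 - r))
    : std::atanh(r);
}

// S: column-major p x p with a valid lower triangle (and diagonal); s:
// column sums of the half; n: frames in the half. Writes atanh(clipped r)
// for the E = p(p-1)/2 edges in row-major upper-triangle order.
static void fisher_lower(const double* S, const double* s, const int p,
                         const double n, double* out) {
  std::vector<double> m(p), sd(p);
  for (int j = 0; j < p; ++j) {
    m[j] = s[j] / n;
    sd[j] = std::sqrt((S[j + (size_t)j * p] - n * m[j] * m[j]) / (n - 1.0));
  }
  const double cap = 1.0 - 1e-7;
  size_t k = 0;
  for (int j = 0; j < p; ++j) {
    for (int i = j + 1; i < p; ++i) {
      double cov = (S[i + (size_t)j * p] - n * m[i] * m[j]) / (n - 1.0);
      double r = cov / (sd[i] * sd[j]);
      if (r > cap) r = cap; else if (r < -cap) r = -cap;
      out[k++] = fast_atanh(r);
    }
  }
}

// fisher transform from a packed lower triangle (column-major, diagonal
// included)
static void fisher_packed(const double* S, const double* s, const int p,
                          const double n, double* out) {
  std::vector<double> m(p), sd(p);
  size_t q = 0;
  for (int j = 0; j < p; ++j) {
    m[j] = s[j] / n;
    sd[j] = std::sqrt((S[q] - n * m[j] * m[j]) / (n - 1.0));
    q += (size_t)(p - j);
  }
  const double cap = 1.0 - 1e-7;
  size_t k = 0;
  q = 0;
  for (int j = 0; j < p; ++j) {
    ++q;                                // skip diagonal
    for (int i = j + 1; i < p; ++i, ++q) {
      double cov = (S[q] - n * m[i] * m[j]) / (n - 1.0);
      double r = cov / (sd[i] * sd[j]);
      if (r > cap) r = cap; else if (r < -cap) r = -cap;
      out[k++] = fast_atanh(r);
    }
  }
}

// Per-participant interface used by consistency checks: Fisher-z edge
// vectors of the low half (given 1-based frame indices) and the high half.
// [[Rcpp::export(name = ".half_edges_cpp")]]
Rcpp::List half_edges_cpp(const arma::mat& X, const arma::mat& Stot,
                          const arma::vec& stot,
                          const arma::uvec& low_idx1) {
  const int p = X.n_rows;
  const uword n = X.n_cols;
  const uvec low = low_idx1 - 1;
  const uword nl = low.n_elem, nh = n - nl;
  if (nl < 3 || nh < 3) Rcpp::stop("each half needs at least 3 frames");
  mat Xa = X.cols(low);
  mat Sa = Xa * Xa.t();
  vec sa = sum(Xa, 1);
  mat Sb = Stot - Sa;
  vec sb = stot - sa;
  const size_t E = (size_t)p * (p - 1) / 2;
  Rcpp::NumericVector zlow(E), zhigh(E);
  fisher_lower(Sa.memptr(), sa.memptr(), p, (double)nl, zlow.begin());
  fisher_lower(Sb.memptr(), sb.memptr(), p, (double)nh, zhigh.begin());
  return Rcpp::List::create(Rcpp::Named("z_low") = zlow,
                            Rcpp::Named("z_high") = zhigh);
}

// Packed lower-triangle block statistics plus their totals. Block frames
// are contiguous columns of X, so each block crossproduct is one in-place
// rank-k update. Per-block matrices are cached in single precision (their
// totals in double); a permutation's half-covariance is later assembled by
// sgemm against a block-membership indicator, and the ~1e-7 relative
// rounding this admits is far below the sampling noise of the
// correlations themselves.
// [[Rcpp::export(name = ".block_stats_cpp")]]
Rcpp::List block_stats_cpp(const arma::mat& X, const arma::ivec& starts,
                           const arma::ivec& ends) {
  const int p = X.n_rows;
  const int B = starts.n_elem;
  const size_t L = (size_t)p * (p + 1) / 2;
  // float caches are bit-packed into R double vectors (two floats per
  // double) so no per-call conversion is needed on reuse
  Rcpp::NumericVector packSr((L * B + 1) / 2);
  Rcpp::NumericVector sblkr(((size_t)p * B + 1) / 2);
  float* packSf = reinterpret_cast<float*>(packSr.begin());
  float* sblkf = reinterpret_cast<float*>(sblkr.begin());
  arma::fmat packS(packSf, L, B, false, true);
  arma::fmat sblk(sblkf, p, B, false, true);
  arma::vec packTot(L, fill::zeros);
  arma::vec sTot(p, fill::zeros);
  std::vector<double> Sb((size_t)p * p);
  std::vector<double> sv(p);
  const double one = 1.0, zero = 0.0;
  for (int b = 0; b < B; ++b) {
    const int len = ends[b] - starts[b] + 1;
    const double* xb = X.colptr(starts[b] - 1);
    F77_CALL(dsyrk)("L", "N", &p, &len, &one, xb, &p, &zero,
                    Sb.data(), &p FCONE FCONE);
    std::fill(sv.begin(), sv.end(), 0.0);
    for (int k = 0; k < len; ++k) {
      const double* col = xb + (size_t)k * p;
      for (int r = 0; r < p; ++r) sv[r] += col[r];
    }
    float* out = packS.colptr(b);
    float* so = sblk.colptr(b);
    size_t q = 0;
    for (int j = 0; j < p; ++j) {
      const double* Scol = Sb.data() + (size_t)j * p;
      for (int i = j; i < p; ++i, ++q) {
        out[q] = (float)Scol[i];
        packTot[q] += Scol[i];
      }
    }
    for (int r = 0; r < p; ++r) {
      so[r] = (float)sv[r];
      sTot[r] += sv[r];
    }
  }
  return Rcpp::List::create(Rcpp::Named("packS") = packSr,
                            Rcpp::Named("sblk") = sblkr,
                            Rcpp::Named("packTot") = packTot,
                            Rcpp::Named("sTot") = sTot);
}

// float-input variant of the packed fisher transform (the half's packed
// crossproduct arrives in single precision; all derived arithmetic is
// double)
static void fisher_packed_f(const float* S, const float* s, const int p,
                            const double n, double* out) {
  std::vector<double> m(p), sd(p);
  size_t q = 0;
  for (int j = 0; j < p; ++j) {
    m[j] = (double)s[j] / n;
    sd[j] = std::sqrt(((double)S[q] - n * m[j] * m[j]) / (n - 1.0));
    q += (size_t)(p - j);
  }
  const double cap = 1.0 - 1e-7;
  size_t k = 0;
  q = 0;
  for (int j = 0; j < p; ++j) {
    ++q;
    for (int i = j + 1; i < p; ++i, ++q) {
      double cov = ((double)S[q] - n * m[i] * m[j]) / (n - 1.0);
      double r = cov / (sd[i] * sd[j]);
      if (r > cap) r = cap; else if (r < -cap) r = -cap;
      out[k++] = fast_atanh(r);
    }
  }
}

// Batched fill for K permutations at once. lowsBatch is a list of K
// permutations, each a list with one integer vector of 1-based low-half
// block ids per participant. For each participant the K low-half
// crossproducts are assembled in a single sgemm of the packed block cache
// against a block-membership indicator matrix (one cache read serves all K
// permutations); high halves follow by subtraction from the double totals.
// Outputs: per permutation k, columns of YlowList[[k]]/YhighList[[k]]
// (edge-major E x n) and column k of FdLow/FdHigh.
// [[Rcpp::export(name = ".fill_perm_edges_batch_cpp")]]
void fill_perm_edges_batch_cpp(Rcpp::List packSs, Rcpp::List sblks,
                               Rcpp::List packTots, Rcpp::List sTots,
                               Rcpp::List lens, Rcpp::List fdblks,
                               Rcpp::NumericVector fdTots,
                               Rcpp::List lowsBatch,
                               Rcpp::List YlowList, Rcpp::List YhighList,
                               Rcpp::NumericMatrix FdLow,
                               Rcpp::NumericMatrix FdHigh) {
  const int nsub = packSs.size();
  const int K = lowsBatch.size();
  std::vector<Rcpp::NumericMatrix> Yls, Yhs;
  for (int k = 0; k < K; ++k) {
    Yls.emplace_back(Rcpp::as<Rcpp::NumericMatrix>(YlowList[k]));
    Yhs.emplace_back(Rcpp::as<Rcpp::NumericMatrix>(YhighList[k]));
  }
  const size_t E = Yls[0].nrow();
  std::vector<double> Sh((size_t)E + 1024), sh;
  for (int i = 0; i < nsub; ++i) {
    Rcpp::NumericVector packTot = packTots[i];
    Rcpp::NumericVector sTot = sTots[i];
    Rcpp::IntegerVector len = lens[i];
    Rcpp::NumericVector fdb = fdblks[i];
    const size_t L = packTot.size();
    const int p = sTot.size();
    const int B = len.size();
    Rcpp::NumericVector packSr = packSs[i];
    Rcpp::NumericVector sblkr = sblks[i];
    const fmat packS(reinterpret_cast<float*>(packSr.begin()), L, B,
                     false, true);
    const fmat sblk(reinterpret_cast<float*>(sblkr.begin()), p, B,
                    false, true);
    int ntot = 0;
    for (int b = 0; b < B; ++b) ntot += len[b];

    fmat M(B, K, fill::zeros);
    std::vector<int> nl(K, 0);
    std::vector<double> fdl(K, 0.0);
    for (int k = 0; k < K; ++k) {
      Rcpp::List lows = lowsBatch[k];
      Rcpp::IntegerVector lw = lows[i];
      for (int q = 0; q < lw.size(); ++q) {
        const int b = lw[q] - 1;
        M(b, k) = 1.0f;
        nl[k] += len[b];
        fdl[k] += fdb[b];
      }
    }
    fmat Slow = packS * M;          // sgemm: L x K
    fmat slow = sblk * M;           // p x K
    Sh.resize(L); sh.resize(p);
    for (int k = 0; k < K; ++k) {
      const int nh = ntot - nl[k];
      if (nl[k] < 3 || nh < 3) {
        Rcpp::stop("each half needs at least 3 frames");
      }
      const float* Sl = Slow.colptr(k);
      const float* sl_ = slow.colptr(k);
      for (size_t q = 0; q < L; ++q) Sh[q] = packTot[q] - (double)Sl[q];
      for (int r = 0; r < p; ++r) sh[r] = sTot[r] - (double)sl_[r];
      fisher_packed_f(Sl, sl_, p, (double)nl[k], Yls[k].begin() + E * i);
      fisher_packed(Sh.data(), sh.data(), p, (double)nh,
                    Yhs[k].begin() + E * i);
      FdLow(i, k) = fdl[k] / nl[k];
      FdHigh(i, k) = (fdTots[i] - fdl[k]) / nh;
    }
  }
}

// Per-edge "count of ensemble statistics >= this one" for the NPC ranks:
// for each column e of s_null (P x E) and the observed s_obs[e], returns
// cnt_obs[e] = 1 + #{k: s_null[k,e] >= s_obs[e]} (the observed counts
// itself) and cnt_perm[j,e] = #{k: s_null[k,e] >= s_null[j,e]} +
// (s_obs[e] >= s_null[j,e]).
// [[Rcpp::export(name = ".npc_counts_cpp")]]
Rcpp::List npc_counts_cpp(const arma::mat& s_null,
                          const arma::vec& s_obs) {
  const uword P = s_null.n_rows, E = s_null.n_cols;
  Rcpp::IntegerVector cnt_obs(E);
  Rcpp::IntegerMatrix cnt_perm(P, E);
  std::vector<double> v(P);
  for (uword e = 0; e < E; ++e) {
    const double* col = s_null.colptr(e);
    std::copy(col, col + P, v.begin());
    std::sort(v.begin(), v.end());
    const double obs = s_obs[e];
    // #{v >= x} = P - #{v < x}
    cnt_obs[e] = 1 + (int)(P - (std::lower_bound(v.begin(), v.end(), obs)
                                - v.begin()));
    for (uword j = 0; j < P; ++j) {
      const double x = col[j];
      int c = (int)(P - (std::lower_bound(v.begin(), v.end(), x)
                         - v.begin()));
      if (obs >= x) ++c;
      cnt_perm(j, e) = c;
    }
  }
  return Rcpp::List::create(Rcpp::Named("cnt_obs") = cnt_obs,
                            Rcpp::Named("cnt_perm") = cnt_perm);
}

// Fisher-z edges of the full timeseries from its sufficient statistics.
// [[Rcpp::export(name = ".edges_from_stats_cpp")]]
Rcpp::NumericVector edges_from_stats_cpp(const arma::mat& Stot,
                                         const arma::vec& stot,
                                         const double n) {
  const int p = Stot.n_rows;
  const size_t E = (size_t)p * (p - 1) / 2;
  Rcpp::NumericVector z(E);
  fisher_lower(Stot.memptr(), stot.memptr(), p, n, z.begin());
  return z;
}

// Fused per-permutation statistics: residualize each half's edge matrix on
// (1, half mean FD) across participants, difference the residuals, and
// regress the difference on the design (intercept, trait, covariates),
// returning the trait t-value per edge. Inputs are edge-major (E x n);
// both passes stream participant columns sequentially while per-edge
// accumulators stay cache-resident. Mirrors the R reference path
// (.residual_difference_mat + .impact_t).
// [[Rcpp::export(name = ".impact_row_cpp")]]
Rcpp::NumericVector impact_row_cpp(const arma::mat& Ylow,
                                   const arma::mat& Yhigh,
                                   const arma::vec& fd_low,
                                   const arma::vec& fd_high,
                                   const arma::mat& Xd) {
  const uword n = Ylow.n_cols;
  const uword p = Xd.n_cols;
  const size_t E = Ylow.n_rows;
  if (n <= p) Rcpp::stop("too few participants for the design (n <= p)");
  vec xcl = fd_low - mean(fd_low);
  vec xch = fd_high - mean(fd_high);
  const double dl = dot(xcl, xcl), dh = dot(xch, xch);
  if (dl <= 0 || dh <= 0) {
    Rcpp::stop("design rank-deficient: motion covariate is constant across participants");
  }
  mat XtX = Xd.t() * Xd;
  mat XtXi;
  if (!inv_sympd(XtXi, XtX)) Rcpp::stop("rank-deficient design");
  const double df = (double)n - (double)p;

  // pass 1: per-edge means and FD slopes of each half
  std::vector<double> ml(E, 0.0), mh(E, 0.0), bl(E, 0.0), bh(E, 0.0);
  for (uword i = 0; i < n; ++i) {
    const double* yl = Ylow.colptr(i);
    const double* yh = Yhigh.colptr(i);
    const double cl = xcl[i], ch = xch[i];
    for (size_t e = 0; e < E; ++e) {
      ml[e] += yl[e]; bl[e] += cl * yl[e];
      mh[e] += yh[e]; bh[e] += ch * yh[e];
    }
  }
  for (size_t e = 0; e < E; ++e) {
    ml[e] /= n; bl[e] /= dl;
    mh[e] /= n; bh[e] /= dh;
  }

  // pass 2: residual difference on the fly; accumulate X'd and d'd
  mat xtd(p, E, fill::zeros);
  std::vector<double> dd(E, 0.0);
  std::vector<double> xdi(p);
  for (uword i = 0; i < n; ++i) {
    const double* yl = Ylow.colptr(i);
    const double* yh = Yhigh.colptr(i);
    const double cl = xcl[i], ch = xch[i];
    for (uword j = 0; j < p; ++j) xdi[j] = Xd(i, j);
    for (size_t e = 0; e < E; ++e) {
      const double d = (yh[e] - mh[e] - bh[e] * ch)
                     - (yl[e] - ml[e] - bl[e] * cl);
      dd[e] += d * d;
      double* xc = xtd.colptr(e);
      for (uword j = 0; j < p; ++j) xc[j] += xdi[j] * d;
    }
  }

  Rcpp::NumericVector t(E);
  vec bcoef(p);
  for (size_t e = 0; e < E; ++e) {
    const vec xtde(xtd.colptr(e), p);
    bcoef = XtXi * xtde;
    double rss = dd[e] - dot(bcoef, xtde);
    if (rss < 0) rss = 0;
    const double se = std::sqrt(rss / df * XtXi(1, 1));
    t[e] = se > 0 ? bcoef[1] / se : 0.0;
  }
  return t;
}
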