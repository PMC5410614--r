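#include <Rcpp.h>
using namespace Rcpp;

// EM for the admixture model on multiallelic copy-level data.
// Each allele copy m (line i_m, locus-allele level a_m) is drawn from the
// mixture sum_k q[i,k] * p[k,a]. Levels are per-locus allele classes laid
// out contiguously; p rows are normalized within each locus block.
// [[Rcpp::export]]
List em_admixture_cpp(IntegerVector line_idx, IntegerVector al_idx,
                      IntegerVector al_locus, int n_lines, int K,
                      int n_levels, int n_loci,
                      NumericMatrix q_init, NumericMatrix p_init,
                      int max_iter, double tol) {
  const int M = line_idx.size();
  // K-contiguous working copies: qT is K x n_lines, pT is K x n_levels
  std::vector<double> qT(K * n_lines), pT(K * n_levels);
  for (int i = 0; i < n_lines; ++i)
    for (int k = 0; k < K; ++k) qT[i * K + k] = q_init(i, k);
  for (int a = 0; a < n_levels; ++a)
    for (int k = 0; k < K; ++k) pT[a * K + k] = p_init(k, a);
  std::vector<double> copies_per_line(n_lines, 0.0);
  for (int m = 0; m < M; ++m) copies_per_line[line_idx[m]] += 1.0;
  const int* li = INTEGER(line_idx);
  const int* ai = INTEGER(al_idx);

  std::vector<double> loglik_trace;
  loglik_trace.reserve(max_iter);
  std::vector<double> qnew(n_lines * K), pnew(K * n_levels), r(8);
  double prev = R_NegInf;
  int iter = 0;
  for (iter = 0; iter < max_iter; ++iter) {
    std::fill(qnew.begin(), qnew.end(), 0.0);
    std::fill(pnew.begin(), pnew.end(), 0.0);
    double ll = 0.0;
    for (int m = 0; m < M; ++m) {
      const double* qi = &qT[li[m] * K];
      const double* pa = &pT[ai[m] * K];
      double* qn = &qnew[li[m] * K];
      double* pn = &pnew[ai[m] * K];
      double tot = 0.0;
      for (int k = 0; k < K; ++k) {
        r[k] = qi[k] * pa[k];
        tot += r[k];
      }
      if (tot <= 0.0) tot = 1e-300;
      ll += std::log(tot);
      const double inv = 1.0 / tot;
      for (int k = 0; k < K; ++k) {
        const double w = r[k] * inv;
        qn[k] += w;
        pn[k] += w;
      }
    }
    loglik_trace.push_back(ll);
    // M-step: ancestry rows
    for (int i = 0; i < n_lines; ++i)
      for (int k = 0; k < K; ++k)
        qT[i * K + k] = qnew[i * K + k] / copies_per_line[i];
    // M-step: frequencies, normalized within each locus block per component
    for (int k = 0; k < K; ++k) {
      int a = 0;
      while (a < n_levels) {
        const int l = al_locus[a];
        double s = 0.0;
        int b = a;
        while (b < n_levels && al_locus[b] == l) { s += pnew[b * K + k]; ++b; }
        double s2 = 0.0;
        for (int c = a; c < b; ++c) {
          double v = (s > 0.0) ? pnew[c * K + k] / s : 1.0 / (b - a);
          if (v < 1e-12) v = 1e-12;
          pT[c * K + k] = v;
          s2 += v;
        }
        for (int c = a; c < b; ++c) pT[c * K + k] /= s2;
        a = b;
      }
    }
    if (iter > 0 && std::abs(ll - prev) < tol) { ++iter; break; }
    prev = ll;
  }
  // final log-likelihood at current parameters
  double ll_final = 0.0;
  for (int m = 0; m < M; ++m) {
    const double* qi = &qT[li[m] * K];
    const double* pa = &pT[ai[m] * K];
    double tot = 0.0;
    for (int k = 0; k < K; ++k) tot += qi[k] * pa[k];
    ll_final += std::log(std::max(tot, 1e-300));
  }
  NumericMatrix q(n_lines, K), p(K, n_levels);
  for (int i = 0; i < n_lines; ++i)
    for (int k = 0; k < K; ++k) q(i, k) = qT[i * K + k];
  for (int a = 0; a < n_levels; ++a)
    for (int k = 0; k < K; ++k) p(k, a) = pT[a * K + k];
  return List::create(_["q"] = q, _["p"] = p,
                      _["loglik"] = ll_final,
                      _["loglik_trace"] = NumericVector(loglik_trace.begin(),
                                                        loglik_trace.end()),
                      _["n_iter"] = iter);
}

// Multiallelic composite r^2 between two loci from diploid calls.
// Joint counts pair each line's copies across loci with weight 1/2 over the
// four within-individual combinations (exact haplotype counts for
// homozygotes). r^2 is the frequency-weighted mean of per-allele-pair
// squared correlations: sum_ab p_a q_b D_ab^2 / (p_a(1-p_a) q_b(1-q_b)).
static double pair_r2(const int* x1, const int* x2,
                      const int* y1, const int* y2,
                      const int* ord, int n, int na, int nb,
                      bool* mono_out) {
  double C[64], pa[8], qb[8];
  std::fill(C, C + na * nb, 0.0);
  std::fill(pa, pa + na, 0.0);
  std::fill(qb, qb + nb, 0.0);
  double used = 0.0;
  for (int t = 0; t < n; ++t) {
    const int i = t, j = ord ? ord[t] : t;
    if (x1[i] == NA_INTEGER || y1[j] == NA_INTEGER) continue;
    const int a1 = x1[i] - 1, a2 = x2[i] - 1;
    const int b1 = y1[j] - 1, b2 = y2[j] - 1;
    pa[a1] += 1.0; pa[a2] += 1.0;
    qb[b1] += 1.0; qb[b2] += 1.0;
    C[a1 * nb + b1] += 0.5; C[a1 * nb + b2] += 0.5;
    C[a2 * nb + b1] += 0.5; C[a2 * nb + b2] += 0.5;
    used += 1.0;
  }
  if (used < 2.0) { *mono_out = true; return 0.0; }
  const double tot = 2.0 * used;
  bool mono_a = true, mono_b = true;
  for (int a = 0; a < na; ++a) { pa[a] /= tot; if (pa[a] > 0 && pa[a] < 1) mono_a = false; }
  for (int b = 0; b < nb; ++b) { qb[b] /= tot; if (qb[b] > 0 && qb[b] < 1) mono_b = false; }
  if (mono_a || mono_b) { *mono_out = true; return 0.0; }
  *mono_out = false;
  double r2 = 0.0;
  for (int a = 0; a < na; ++a) {
    if (pa[a] <= 0.0 || pa[a] >= 1.0) continue;
    for (int b = 0; b < nb; ++b) {
      if (qb[b] <= 0.0 || qb[b] >= 1.0) continue;
      const double D = C[a * nb + b] / tot - pa[a] * qb[b];
      r2 += pa[a] * qb[b] * (D * D) /
            (pa[a] * (1.0 - pa[a]) * qb[b] * (1.0 - qb[b]));
    }
  }
  if (r2 > 1.0) r2 = 1.0;
  return r2;
}

// All C(L,2) pairwise r^2 values with optional permutation p-values
// (permuting the line order of the second locus).
// i1, i2: n x L matrices of 1-based per-locus allele indices (NA = missing).
// perms: n_perm x n matrix of 1-based line permutations (may have 0 rows).
// [[Rcpp::export]]
DataFrame ld_matrix_cpp(IntegerMatrix i1, IntegerMatrix i2,
                        IntegerVector n_alleles, IntegerMatrix perms) {
  const int n = i1.nrow(), L = i1.ncol(), n_perm = perms.nrow();
  const int n_pairs = L * (L - 1) / 2;
  IntegerVector l1(n_pairs), l2(n_pairs);
  NumericVector r2v(n_pairs), pv(n_pairs);
  LogicalVector mono(n_pairs);
  std::vector<int> ord(n);
  int idx = 0;
  for (int a = 0; a < L - 1; ++a) {
    const int* x1 = &i1(0, a); const int* x2 = &i2(0, a);
    for (int b = a + 1; b < L; ++b) {
      const int* y1 = &i1(0, b); const int* y2 = &i2(0, b);
      bool is_mono = false;
      double obs = pair_r2(x1, x2, y1, y2, nullptr, n,
                           n_alleles[a], n_alleles[b], &is_mono);
      double p = NA_REAL;
      if (!is_mono && n_perm > 0) {
        int ge = 0;
        for (int s = 0; s < n_perm; ++s) {
          for (int t = 0; t < n; ++t) ord[t] = perms(s, t) - 1;
          bool m2 = false;
          double rp = pair_r2(x1, x2, y1, y2, ord.data(), n,
                              n_alleles[a], n_alleles[b], &m2);
          if (rp >= obs - 1e-12) ++ge;
        }
        p = (1.0 + ge) / (1.0 + n_perm);
      }
      l1[idx] = a + 1; l2[idx] = b + 1;
      r2v[idx] = obs; pv[idx] = p; mono[idx] = is_mono;
      ++idx;
    }
  }
  return DataFrame::create(_["locus1"] = l1, _["locus2"] = l2,
                           _["r2"] = r2v, _["p"] = pv,
                           _["monomorphic"] = mono);
}
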