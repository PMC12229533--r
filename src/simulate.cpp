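#include <Rcpp.h>
using namespace Rcpp;

// Liability-threshold cohort sampler.
//
// Haplotypes are generated per LD block by thresholding a latent AR(1)
// Gaussian chain (corr rho^|i-k|) at the per-variant frequency quantile;
// two haplotypes are summed to a dosage. Liability is the centered,
// weighted dosage sum plus N(0, resid_sd^2); a sample is a case when
// liability exceeds `threshold`. With `ascertain`, individuals are drawn
// from the population until the case/control quotas are met (rejection
// sampling); otherwise the first n_total draws are returned.
//
// qthr:      n_variants x K matrix of qnorm(freq) haplotype thresholds
// block_id:  0-based block index per variant (non-decreasing)
// beta:      per-allele liability effect per variant
// center:    per-variant centering term (2 * ancestral freq standardised)
// admix_alpha: Dirichlet concentration (length K) or empty for a fixed
//              single ancestry given by anc_fixed (0-based)
// [[Rcpp::export]]
List sample_cohort_cpp(NumericMatrix qthr, IntegerVector block_id, double rho,
                       NumericVector beta, NumericVector center,
                       double resid_sd, double threshold,
                       NumericVector admix_alpha, int anc_fixed,
                       bool ascertain, int n_cases, int n_controls,
                       int n_total, int max_attempts) {
  const int m = qthr.nrow();
  const int K = qthr.ncol();
  const bool admixed = admix_alpha.size() > 0;
  const double ar_sd = std::sqrt(1.0 - rho * rho);

  int n_out = ascertain ? (n_cases + n_controls) : n_total;
  IntegerMatrix dosage(n_out, m);
  NumericVector liability(n_out);
  IntegerVector is_case(n_out);
  NumericMatrix admix_rows(admixed ? n_out : 0, admixed ? K : 0);

  std::vector<int> g(m);
  std::vector<double> w(K);
  // ancestry per block per haplotype
  int n_blocks = m > 0 ? block_id[m - 1] + 1 : 0;
  std::vector<int> anc1(n_blocks), anc2(n_blocks);

  int kept = 0, kept_cases = 0, kept_controls = 0, attempts = 0;
  while (kept < n_out && attempts < max_attempts) {
    ++attempts;
    // per-individual admixture proportions
    if (admixed) {
      double s = 0.0;
      for (int k = 0; k < K; ++k) { w[k] = R::rgamma(admix_alpha[k], 1.0); s += w[k]; }
      for (int k = 0; k < K; ++k) w[k] /= s;
      for (int b = 0; b < n_blocks; ++b) {
        for (int hap = 0; hap < 2; ++hap) {
          double u = R::unif_rand(), acc = 0.0;
          int pick = K - 1;
          for (int k = 0; k < K; ++k) { acc += w[k]; if (u <= acc) { pick = k; break; } }
          if (hap == 0) anc1[b] = pick; else anc2[b] = pick;
        }
      }
    }
    // two haplotypes, latent AR(1) per block
    double liab = 0.0;
    for (int hap = 0; hap < 2; ++hap) {
      double z = 0.0;
      int prev_block = -1;
      for (int j = 0; j < m; ++j) {
        if (block_id[j] != prev_block) {
          z = R::norm_rand();
          prev_block = block_id[j];
        } else {
          z = rho * z + ar_sd * R::norm_rand();
        }
        int a = admixed ? (hap == 0 ? anc1[block_id[j]] : anc2[block_id[j]])
                        : anc_fixed;
        int allele = z < qthr(j, a) ? 1 : 0;
        if (hap == 0) g[j] = allele; else g[j] += allele;
      }
    }
    for (int j = 0; j < m; ++j)
      if (beta[j] != 0.0) liab += beta[j] * (g[j] - center[j]);
    liab += resid_sd * R::norm_rand();
    bool cs = liab > threshold;

    bool keep;
    if (ascertain) {
      keep = cs ? kept_cases < n_cases : kept_controls < n_controls;
    } else {
      keep = true;
    }
    if (keep) {
      for (int j = 0; j < m; ++j) dosage(kept, j) = g[j];
      liability[kept] = liab;
      is_case[kept] = cs ? 1 : 0;
      if (admixed) for (int k = 0; k < K; ++k) admix_rows(kept, k) = w[k];
      if (cs) ++kept_cases; else ++kept_controls;
      ++kept;
    }
  }

  return List::create(_["dosage"] = dosage, _["liability"] = liability,
                      _["is_case"] = is_case, _["admixture"] = admix_rows,
                      _["n_kept"] = kept, _["attempts"] = attempts);
}
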