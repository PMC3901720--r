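#include <Rcpp.h>
using namespace Rcpp;

// Monte-Carlo rejection counts for the regression trend test, means model
// (test_kind = 0) or variance-heterogeneity model (test_kind = 1).
//
// Genotypes are Binomial(2, p) via two uniforms; phenotypes are drawn from
// the model's conditional normal law with the measurement-error variance
// folded in. Per replicate the F statistic of the slope test is accumulated
// from one-pass sums, so no n-length vector is ever materialized. For the
// variance test the regressand is the squared standardized phenotype;
// because the F test is invariant to affine rescaling of the regressand,
// (y - ybar)^2 is regressed in place of ((y - ybar)/s)^2.
//
// Uses R's RNG (set.seed on the R side gives full reproducibility).
// [[Rcpp::export(name = ".sim_count_rejections")]]
int sim_count_rejections(int test_kind, int n, double p, double effect,
                         double sigma_e, double fcrit, int reps) {
  if (n < 3 || reps < 1)
    stop("n must be >= 3 and reps >= 1");
  const double se2 = sigma_e * sigma_e;
  const double nn = static_cast<double>(n);
  int rejections = 0;

  if (test_kind == 0) {
    const double resid = 1.0 - effect * effect * 2.0 * p * (1.0 - p);
    if (resid + se2 <= 0.0)
      stop("nonpositive residual variance in the means model");
    const double sd_tot = std::sqrt(resid + se2);
    for (int r = 0; r < reps; ++r) {
      double Sg = 0, Sgg = 0, Sy = 0, Syy = 0, Sgy = 0;
      for (int i = 0; i < n; ++i) {
        double g = (unif_rand() < p) + (unif_rand() < p);
        double y = effect * g + sd_tot * norm_rand();
        Sg += g; Sgg += g * g; Sy += y; Syy += y * y; Sgy += g * y;
      }
      double sxx = Sgg - Sg * Sg / nn;
      double syy = Syy - Sy * Sy / nn;
      double sxy = Sgy - Sg * Sy / nn;
      if (sxx <= 0.0 || syy <= 0.0) continue;  // degenerate: non-rejection
      double r2 = sxy * sxy / (sxx * syy);
      if (r2 >= 1.0) { ++rejections; continue; }
      double F = (nn - 2.0) * r2 / (1.0 - r2);
      if (F > fcrit) ++rejections;
    }
  } else {
    for (int r = 0; r < reps; ++r) {
      double Sg = 0, Sgg = 0, S1 = 0, S2 = 0, S3 = 0, S4 = 0,
             Sg1 = 0, Sg2 = 0;
      for (int i = 0; i < n; ++i) {
        double g = (unif_rand() < p) + (unif_rand() < p);
        double v = 1.0 + effect * g + se2;
        double y = std::sqrt(v) * norm_rand();
        double y2 = y * y;
        Sg += g; Sgg += g * g;
        S1 += y; S2 += y2; S3 += y2 * y; S4 += y2 * y2;
        Sg1 += g * y; Sg2 += g * y2;
      }
      double m = S1 / nn;
      // sums over u_i = (y_i - ybar)^2 from raw moments
      double Su  = S2 - nn * m * m;
      double Sgu = Sg2 - 2.0 * m * Sg1 + m * m * Sg;
      double Suu = S4 - 4.0 * m * S3 + 6.0 * m * m * S2
                   - 4.0 * m * m * m * S1 + nn * m * m * m * m;
      double sxx = Sgg - Sg * Sg / nn;
      double syy = Suu - Su * Su / nn;
      double sxy = Sgu - Sg * Su / nn;
      if (sxx <= 0.0 || syy <= 0.0) continue;
      double r2 = sxy * sxy / (sxx * syy);
      if (r2 >= 1.0) { ++rejections; continue; }
      double F = (nn - 2.0) * r2 / (1.0 - r2);
      if (F > fcrit) ++rejections;
    }
  }
  return rejections;
}
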