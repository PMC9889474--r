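#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Harrell's C. Comparable pairs: t_i < t_j with event_i = 1; ties in the
// risk score receive 0.5 credit; time-tied pairs are not comparable.
static double harrell(const std::vector<double>& risk,
                      const std::vector<double>& time,
                      const std::vector<int>& event) {
  const int n = (int)risk.size();
  double conc = 0, comp = 0;
  for (int i = 0; i < n; i++) {
    if (!event[i]) continue;
    for (int j = 0; j < n; j++) {
      if (time[i] < time[j]) {
        comp += 1;
        if (risk[i] > risk[j]) conc += 1;
        else if (risk[i] == risk[j]) conc += 0.5;
      }
    }
  }
  if (comp == 0) return NA_REAL;
  return conc / comp;
}

// [[Rcpp::export(name = ".harrell_c_cpp")]]
double harrell_c_cpp(NumericVector risk, NumericVector time,
                     IntegerVector event) {
  std::vector<double> r(risk.begin(), risk.end());
  std::vector<double> t(time.begin(), time.end());
  std::vector<int> e(event.begin(), event.end());
  return harrell(r, t, e);
}

// Percentile bootstrap of C over patient resamples (uses R's RNG).
// [[Rcpp::export(name = ".harrell_c_boot_cpp")]]
NumericVector harrell_c_boot_cpp(NumericVector risk, NumericVector time,
                                 IntegerVector event, int n_boot) {
  const int n = risk.size();
  NumericVector out(n_boot);
  std::vector<double> r(n), t(n);
  std::vector<int> e(n);
  GetRNGstate();
  for (int b = 0; b < n_boot; b++) {
    for (int i = 0; i < n; i++) {
      int idx = (int)std::floor(unif_rand() * n);
      if (idx == n) idx = n - 1;
      r[i] = risk[idx]; t[i] = time[idx]; e[i] = event[idx];
    }
    out[b] = harrell(r, t, e);
  }
  PutRNGstate();
  return out;
}

// Paired patient-level bootstrap of Delta-C = C(risk1) - C(risk2); the same
// resample is applied to both scores so the difference is paired.
// [[Rcpp::export(name = ".compare_c_boot_cpp")]]
NumericVector compare_c_boot_cpp(NumericVector risk1, NumericVector risk2,
                                 NumericVector time, IntegerVector event,
                                 int n_boot) {
  const int n = risk1.size();
  NumericVector out(n_boot);
  std::vector<double> r1(n), r2(n), t(n);
  std::vector<int> e(n);
  GetRNGstate();
  for (int b = 0; b < n_boot; b++) {
    for (int i = 0; i < n; i++) {
      int idx = (int)std::floor(unif_rand() * n);
      if (idx == n) idx = n - 1;
      r1[i] = risk1[idx]; r2[i] = risk2[idx];
      t[i] = time[idx]; e[i] = event[idx];
    }
    double c1 = harrell(r1, t, e), c2 = harrell(r2, t, e);
    out[b] = (ISNA(c1) || ISNA(c2)) ? NA_REAL : c1 - c2;
  }
  PutRNGstate();
  return out;
}

// Two-sample log-rank chi-square for every candidate cutoff of a score
// (group = score > cutoff). time must carry no NAs.
// [[Rcpp::export(name = ".logrank_profile_cpp")]]
NumericVector logrank_profile_cpp(NumericVector time, IntegerVector event,
                                  NumericVector score,
                                  NumericVector cutoffs) {
  const int n = time.size();
  // order patients by time ascending
  std::vector<int> ord(n);
  for (int i = 0; i < n; i++) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return time[a] < time[b]; });

  const int nc = cutoffs.size();
  NumericVector stat(nc);
  for (int c = 0; c < nc; c++) {
    double cut = cutoffs[c];
    // single pass over distinct event times
    double n1 = 0, n0 = 0;
    for (int i = 0; i < n; i++) {
      if (score[i] > cut) n1++; else n0++;
    }
    double U = 0, V = 0;
    int i = 0;
    while (i < n) {
      double tcur = time[ord[i]];
      int j = i;
      double d1 = 0, d = 0, r1rem = 0, rrem = 0;
      while (j < n && time[ord[j]] == tcur) {
        int idx = ord[j];
        bool g1 = score[idx] > cut;
        if (event[idx]) {
          d += 1;
          if (g1) d1 += 1;
        }
        rrem += 1;
        if (g1) r1rem += 1;
        j++;
      }
      double N = n1 + n0;
      if (d > 0 && N > 1) {
        double exp1 = d * n1 / N;
        U += d1 - exp1;
        V += d * (n1 / N) * (1 - n1 / N) * (N - d) / (N - 1);
      }
      n1 -= r1rem;
      n0 -= (rrem - r1rem);
      i = j;
    }
    stat[c] = (V > 0) ? U * U / V : 0.0;
  }
  return stat;
}
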