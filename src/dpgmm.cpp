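#include <Rcpp.h>
#include <vector>
#include <map>
#include <cmath>
using namespace Rcpp;

// Collapsed Gibbs sampler for a Dirichlet-process mixture of Gaussians
// with a conjugate Normal-Inverse-Gamma base measure (Neal's Algorithm 3).
// Data are standardized on entry, so the default base measure
// (mu0 = 0, kappa0 = 1, a0 = 2, b0 = 1) is uninformative on that scale.
//
// Per-cluster sufficient statistics (n, sum, sum of squares) give the
// Student-t posterior predictive used in the CRP updates. Uses R's RNG so
// results are reproducible under set.seed().

struct Cluster {
    int n = 0;
    double sum = 0.0, ssq = 0.0;
};

static inline double log_predictive(double x, const Cluster &c,
                                    double mu0, double kappa0,
                                    double a0, double b0) {
    double n = c.n;
    double kn = kappa0 + n;
    double mun = (kappa0 * mu0 + c.sum) / kn;
    double an = a0 + 0.5 * n;
    double bn = b0;
    if (c.n > 0) {
        double ybar = c.sum / n;
        bn += 0.5 * (c.ssq - n * ybar * ybar) +
              kappa0 * n * (ybar - mu0) * (ybar - mu0) / (2.0 * kn);
    }
    double nu = 2.0 * an;
    double s2 = bn * (kn + 1.0) / (an * kn);
    double d = x - mun;
    return R::lgammafn(0.5 * (nu + 1.0)) - R::lgammafn(0.5 * nu) -
           0.5 * std::log(nu * M_PI * s2) -
           0.5 * (nu + 1.0) * std::log1p(d * d / (nu * s2));
}

// [[Rcpp::export(name = ".dpgmmGibbs")]]
List dpgmm_gibbs(NumericVector z, double alpha, int n_iter, int n_burnin,
                 int min_occupancy, double mu0 = 0.0, double kappa0 = 1.0,
                 double a0 = 2.0, double b0 = 1.0) {
    const int N = z.size();
    std::vector<int> assign(N, 0);
    std::vector<Cluster> clusters(1);
    clusters[0].n = N;
    for (int i = 0; i < N; ++i) {
        clusters[0].sum += z[i];
        clusters[0].ssq += z[i] * z[i];
    }

    std::map<int, int> k_tally;                 // K -> sweeps at that K
    std::map<int, std::vector<int>> snapshots;  // K -> last assignment

    std::vector<double> logp;
    for (int iter = 0; iter < n_iter; ++iter) {
        for (int i = 0; i < N; ++i) {
            const double x = z[i];
            int ci = assign[i];
            clusters[ci].n -= 1;
            clusters[ci].sum -= x;
            clusters[ci].ssq -= x * x;
            if (clusters[ci].n == 0) {
                // swap-remove the emptied cluster
                int last = clusters.size() - 1;
                if (ci != last) {
                    clusters[ci] = clusters[last];
                    for (int j = 0; j < N; ++j)
                        if (assign[j] == last) assign[j] = ci;
                }
                clusters.pop_back();
            }
            const int K = clusters.size();
            logp.resize(K + 1);
            double mx = R_NegInf;
            for (int c = 0; c < K; ++c) {
                logp[c] = std::log((double)clusters[c].n) +
                          log_predictive(x, clusters[c], mu0, kappa0, a0, b0);
                if (logp[c] > mx) mx = logp[c];
            }
            Cluster empty;
            logp[K] = std::log(alpha) +
                      log_predictive(x, empty, mu0, kappa0, a0, b0);
            if (logp[K] > mx) mx = logp[K];
            double tot = 0.0;
            for (int c = 0; c <= K; ++c) {
                logp[c] = std::exp(logp[c] - mx);
                tot += logp[c];
            }
            double u = unif_rand() * tot;
            int pick = K;
            for (int c = 0; c <= K; ++c) {
                u -= logp[c];
                if (u <= 0.0) { pick = c; break; }
            }
            if (pick == K) clusters.push_back(Cluster());
            assign[i] = pick;
            clusters[pick].n += 1;
            clusters[pick].sum += x;
            clusters[pick].ssq += x * x;
        }
        if (iter >= n_burnin) {
            int K_occ = 0;
            for (const Cluster &c : clusters)
                if (c.n >= min_occupancy) ++K_occ;
            if (K_occ < 1) K_occ = 1;
            k_tally[K_occ] += 1;
            snapshots[K_occ] = assign;
        }
    }

    // posterior-mode cluster count; ties broken toward the smaller K
    int mode_k = 1, best = -1;
    for (auto &kv : k_tally)
        if (kv.second > best) { best = kv.second; mode_k = kv.first; }

    std::vector<int> &best_assign = snapshots[mode_k];
    IntegerVector out_assign(N);
    for (int i = 0; i < N; ++i) out_assign[i] = best_assign[i] + 1;

    IntegerVector ks(k_tally.size()), counts(k_tally.size());
    int idx = 0;
    for (auto &kv : k_tally) {
        ks[idx] = kv.first;
        counts[idx] = kv.second;
        ++idx;
    }
    counts.attr("names") = as<CharacterVector>(wrap(ks));
    return List::create(_["assignment"] = out_assign,
                        _["modeK"] = mode_k,
                        _["kCounts"] = counts);
}
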