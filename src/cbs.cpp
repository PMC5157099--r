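#include <Rcpp.h>
using namespace Rcpp;

// Weighted circular binary segmentation kernel.
//
// For a stretch of log-ratios x with positive weights w, the candidate change
// is the arc (i, j] (1-based, i < j) maximizing the weighted two-sample
// z-statistic between the arc and its complement, with the pooled variance
// taken as the weighted variance of the whole stretch. Arcs touching either
// end correspond to a single breakpoint; interior arcs to two.

static double arc_stat(const std::vector<double> &cw,
                       const std::vector<double> &cwx,
                       double W, double S, double sigma2,
                       int i, int j) {
    double W1 = cw[j] - cw[i];
    double S1 = cwx[j] - cwx[i];
    double W2 = W - W1;
    if (W1 <= 0.0 || W2 <= 0.0) return 0.0;
    double m1 = S1 / W1;
    double m2 = (S - S1) / W2;
    double se = std::sqrt(sigma2 * (1.0 / W1 + 1.0 / W2));
    if (se <= 0.0) se = 1e-12;
    return std::fabs(m1 - m2) / se;
}

static double max_arc(const NumericVector &x, const NumericVector &w,
                      int minw, int *bi, int *bj) {
    int n = x.size();
    std::vector<double> cw(n + 1, 0.0), cwx(n + 1, 0.0);
    double W = 0.0, S = 0.0, Sxx = 0.0;
    for (int k = 0; k < n; ++k) {
        cw[k + 1] = cw[k] + w[k];
        cwx[k + 1] = cwx[k] + w[k] * x[k];
    }
    W = cw[n];
    S = cwx[n];
    double mu = S / W;
    for (int k = 0; k < n; ++k) Sxx += w[k] * (x[k] - mu) * (x[k] - mu);
    double sigma2 = Sxx / W;
    if (sigma2 <= 0.0) sigma2 = 1e-12;

    double best = -1.0;
    *bi = -1; *bj = -1;
    for (int i = 0; i <= n - minw; ++i) {
        for (int j = i + minw; j <= n; ++j) {
            int arc_len = j - i;
            int comp_len = n - arc_len;
            if (comp_len < minw) continue;
            double st = arc_stat(cw, cwx, W, S, sigma2, i, j);
            if (st > best) { best = st; *bi = i; *bj = j; }
        }
    }
    return best;
}

// [[Rcpp::export(name = ".cbs_split")]]
List cbs_split(NumericVector x, NumericVector w, int min_width,
               int nperm, double alpha, int accept_n) {
    int n = x.size();
    int bi = -1, bj = -1;
    if (n < 2 * min_width) {
        return List::create(_["stat"] = NA_REAL, _["i"] = -1, _["j"] = -1,
                            _["p"] = 1.0, _["nperm"] = 0);
    }
    double obs = max_arc(x, w, min_width, &bi, &bj);
    if (obs < 0.0) {
        return List::create(_["stat"] = NA_REAL, _["i"] = -1, _["j"] = -1,
                            _["p"] = 1.0, _["nperm"] = 0);
    }

    // Permutation p-value with early stopping: stop rejecting once the
    // exceedance count guarantees p > alpha; stop accepting once a clean run
    // of accept_n permutations bounds p below the pruning threshold.
    RNGScope scope;
    std::vector<double> px(x.begin(), x.end());
    std::vector<double> pw(w.begin(), w.end());
    int reject_at = (int)std::floor(alpha * nperm) + 1;
    int count = 0, done = 0;
    NumericVector tx(n), tw(n);
    int ti, tj;
    for (int b = 0; b < nperm; ++b) {
        // Fisher-Yates on (x, w) pairs using R's RNG for reproducibility
        for (int k = n - 1; k > 0; --k) {
            int idx = (int)(unif_rand() * (k + 1));
            if (idx > k) idx = k;
            std::swap(px[k], px[idx]);
            std::swap(pw[k], pw[idx]);
        }
        for (int k = 0; k < n; ++k) { tx[k] = px[k]; tw[k] = pw[k]; }
        double st = max_arc(tx, tw, min_width, &ti, &tj);
        ++done;
        if (st >= obs) {
            ++count;
            if (count >= reject_at) break;
        }
        if (count == 0 && done >= accept_n) break;
    }
    double p = (count + 1.0) / (done + 1.0);
    return List::create(_["stat"] = obs, _["i"] = bi, _["j"] = bj,
                        _["p"] = p, _["nperm"] = done);
}
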