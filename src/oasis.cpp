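#include <Rcpp.h>
using namespace Rcpp;

// Sparse non-negative AR(1) deconvolution by an online active-set /
// pool-adjacent-violators sweep. Solves
//   min_c 0.5 * ||c - y||^2 + lambda * sum_t s_t
//   s.t.  s_t = c_t - gamma * c_{t-1} >= 0   (c_0 = 0)
// The l1 penalty on s is folded into the observations: sum_t s_t equals
// c_T + (1 - gamma) * sum_{t<T} c_t, so y_t is shifted by lambda*(1-gamma)
// (lambda for the final frame) before the unpenalized sweep.
//
// Pools carry (v, w, t, l): v = sum_k gamma^k y'_{t+k}, w = sum_k gamma^2k,
// so the optimal pool height is v / w. Adjacent pools merge while the next
// pool's height falls below the decayed continuation of the previous one
// (which would imply a negative spike at the boundary).
// [[Rcpp::export]]
List oasis_ar1(NumericVector y, double gamma, double lambda) {
    const int T = y.size();
    NumericVector c(T), s(T);
    if (T == 0)
        return List::create(_["c"] = c, _["s"] = s);

    std::vector<double> v(T), w(T);
    std::vector<int> t0(T), len(T);
    int np = 0;

    for (int t = 0; t < T; ++t) {
        double yt = y[t] - (t == T - 1 ? lambda : lambda * (1.0 - gamma));
        v[np] = yt; w[np] = 1.0; t0[np] = t; len[np] = 1;
        ++np;
        while (np > 1) {
            double g = std::pow(gamma, len[np - 2]);
            if (v[np - 1] / w[np - 1] >= g * v[np - 2] / w[np - 2])
                break;
            v[np - 2] += g * v[np - 1];
            w[np - 2] += g * g * w[np - 1];
            len[np - 2] += len[np - 1];
            --np;
        }
    }

    for (int i = 0; i < np; ++i) {
        double h = v[i] / w[i];
        if (h < 0.0) h = 0.0;
        double val = h;
        for (int k = 0; k < len[i]; ++k) {
            c[t0[i] + k] = val;
            val *= gamma;
        }
    }
    s[0] = c[0];
    for (int t = 1; t < T; ++t) {
        s[t] = c[t] - gamma * c[t - 1];
        if (s[t] < 0.0) s[t] = 0.0;  // guard against rounding
    }
    return List::create(_["c"] = c, _["s"] = s);
}
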