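// Logistic-regression likelihood-ratio machinery for the association
// stage. The permutation p-values need millions of maximum-likelihood
// fits (Freedman-Lane residual permutations), so the Newton solver and
// the permutation loop live here. The RNG is a private mt19937_64 with
// an explicit Fisher-Yates shuffle so permutations are identical across
// platforms and independent of R's RNG state.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline double stable_softplus(double x) {
    if (x > 35.0) return x;
    if (x < -35.0) return std::exp(x);
    return std::log1p(std::exp(x));
}

static double loglik(const vec& eta, const vec& y) {
    double ll = 0.0;
    for (uword i = 0; i < eta.n_elem; ++i)
        ll += y[i] * eta[i] - stable_softplus(eta[i]);
    return ll;
}

struct Fit {
    vec beta;
    double ll;
    bool converged;
    bool separated;
};

// Newton-Raphson with step halving; optional ridge penalty on the last
// coefficient (used to stabilise perfect separation). Convergence:
// relative log-likelihood change below tol, at most max_iter iterations.
static Fit fit_logistic(const mat& X, const vec& y, vec beta,
                        double ridge_last = 0.0, int max_iter = 100,
                        double tol = 1e-10) {
    const uword p = X.n_cols;
    vec eta = X * beta;
    double pen = ridge_last > 0.0
        ? 0.5 * ridge_last * beta[p - 1] * beta[p - 1] : 0.0;
    double ll = loglik(eta, y) - pen;
    bool converged = false;
    for (int it = 0; it < max_iter; ++it) {
        vec mu = 1.0 / (1.0 + exp(-eta));
        vec w = mu % (1.0 - mu);
        w.transform([](double v) { return v < 1e-12 ? 1e-12 : v; });
        vec grad = X.t() * (y - mu);
        mat H = X.t() * (X.each_col() % w);
        if (ridge_last > 0.0) {
            grad[p - 1] -= ridge_last * beta[p - 1];
            H(p - 1, p - 1) += ridge_last;
        }
        vec step;
        bool ok = solve(step, H, grad,
                        solve_opts::likely_sympd + solve_opts::no_approx);
        if (!ok) step = pinv(H) * grad;
        // step halving keeps the ascent monotone
        double ll_new = ll;
        vec beta_new = beta;
        for (int h = 0; h < 30; ++h) {
            beta_new = beta + step;
            vec eta_new = X * beta_new;
            double pen_new = ridge_last > 0.0
                ? 0.5 * ridge_last * beta_new[p - 1] * beta_new[p - 1]
                : 0.0;
            ll_new = loglik(eta_new, y) - pen_new;
            if (ll_new >= ll - 1e-12) { eta = eta_new; break; }
            step *= 0.5;
        }
        double delta = std::fabs(ll_new - ll);
        beta = beta_new;
        bool done = delta < tol * (std::fabs(ll_new) + 0.1);
        ll = ll_new;
        if (done) { converged = true; break; }
    }
    // perfect separation: every fitted probability has collapsed onto
    // its outcome (scale-invariant, unlike a coefficient-size check)
    vec mu_fin = 1.0 / (1.0 + exp(-eta));
    bool separated = abs(y - mu_fin).max() < 1e-3;
    return Fit{beta, ll, converged, separated};
}

// [[Rcpp::export(name = ".cpp_logistic_fit")]]
Rcpp::List cpp_logistic_fit(const arma::mat& X, const arma::vec& y,
                            double ridge_last = 0.0) {
    Fit f = fit_logistic(X, y, zeros<vec>(X.n_cols), ridge_last);
    return Rcpp::List::create(
        Rcpp::Named("coef") = f.beta, Rcpp::Named("loglik") = f.ll,
        Rcpp::Named("converged") = f.converged,
        Rcpp::Named("separated") = f.separated);
}

// LRT of logistic(y ~ Xnull + g) against logistic(y ~ Xnull). When the
// full fit is separated, both models are refit with a small ridge
// penalty on the gene coefficient and the result is flagged.
// [[Rcpp::export(name = ".cpp_logistic_lrt")]]
Rcpp::List cpp_logistic_lrt(const arma::mat& Xnull, const arma::vec& g,
                            const arma::vec& y, double ridge_sep = 1e-6) {
    Fit f0 = fit_logistic(Xnull, y, zeros<vec>(Xnull.n_cols));
    mat Xfull = join_rows(Xnull, g);
    vec warm = join_cols(f0.beta, zeros<vec>(1));
    Fit f1 = fit_logistic(Xfull, y, warm);
    bool flagged = false;
    if (f1.separated && ridge_sep > 0.0) {
        f1 = fit_logistic(Xfull, y, warm, ridge_sep);
        flagged = true;
    }
    if (!f0.converged || !f1.converged)
        Rcpp::stop("logistic LRT fit did not converge");
    double stat = 2.0 * (f1.ll - f0.ll);
    if (stat < 0.0) stat = 0.0;
    return Rcpp::List::create(
        Rcpp::Named("stat") = stat, Rcpp::Named("ll_null") = f0.ll,
        Rcpp::Named("ll_full") = f1.ll,
        Rcpp::Named("separated") = flagged);
}

// Freedman-Lane permutation loop: the gene variable is decomposed in R
// into covariate-fitted values plus residuals; here the residuals are
// shuffled, added back, and the full model refit (warm-started from the
// null coefficients). Returns the number of permuted statistics at
// least as large as obs_stat (with a tiny absolute tolerance) and,
// optionally, the permuted statistics themselves.
// [[Rcpp::export(name = ".cpp_perm_lrt")]]
Rcpp::List cpp_perm_lrt(const arma::mat& Xnull, const arma::vec& gfit,
                        const arma::vec& gres, const arma::vec& y,
                        double obs_stat, int B, double seed,
                        double ridge_sep = 1e-6,
                        bool return_stats = false) {
    const uword n = y.n_elem;
    Fit f0 = fit_logistic(Xnull, y, zeros<vec>(Xnull.n_cols));
    if (!f0.converged) Rcpp::stop("null model did not converge");
    mat Xfull = join_rows(Xnull, zeros<vec>(n));
    vec warm = join_cols(f0.beta, zeros<vec>(1));
    std::mt19937_64 rng(static_cast<uint64_t>(seed));
    std::vector<uword> idx(n);
    vec stats;
    if (return_stats) stats.set_size(B);
    long b_exceed = 0;
    const double eps = 1e-8;
    for (int b = 0; b < B; ++b) {
        for (uword i = 0; i < n; ++i) idx[i] = i;
        for (uword i = n - 1; i > 0; --i) {
            uword j = static_cast<uword>(rng() % (i + 1));
            std::swap(idx[i], idx[j]);
        }
        for (uword i = 0; i < n; ++i)
            Xfull(i, Xfull.n_cols - 1) = gfit[i] + gres[idx[i]];
        Fit f1 = fit_logistic(Xfull, y, warm);
        if (f1.separated && ridge_sep > 0.0)
            f1 = fit_logistic(Xfull, y, warm, ridge_sep);
        double stat = 2.0 * (f1.ll - f0.ll);
        if (stat < 0.0) stat = 0.0;
        if (stat >= obs_stat - eps) ++b_exceed;
        if (return_stats) stats[b] = stat;
        if ((b & 1023) == 0) Rcpp::checkUserInterrupt();
    }
    Rcpp::List out = Rcpp::List::create(
        Rcpp::Named("b_exceed") = static_cast<double>(b_exceed),
        Rcpp::Named("B") = B);
    if (return_stats) out["stats"] = stats;
    return out;
}
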