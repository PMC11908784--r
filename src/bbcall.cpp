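#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Beta-binomial log-pmf in the (mu, rho) parameterization:
//   a = mu * (1/rho - 1), b = (1 - mu) * (1/rho - 1)
// rho -> 0 recovers the binomial; rho below RHO_BINOM is treated as 0.
static const double RHO_BINOM = 1e-10;
static const double MU_FLOOR  = 1e-8;

static double bb_loglik1(double x, double n, double mu, double rho) {
    if (n <= 0.0) return 0.0;          // empty observation
    if (mu < MU_FLOOR) mu = MU_FLOOR;
    if (mu > 1.0 - MU_FLOOR) mu = 1.0 - MU_FLOOR;
    if (rho < RHO_BINOM)
        return R::dbinom(x, n, mu, 1);
    double s = 1.0 / rho - 1.0;
    double a = mu * s, b = (1.0 - mu) * s;
    return R::lchoose(n, x)
        + R::lbeta(x + a, n - x + b)
        - R::lbeta(a, b);
}

// [[Rcpp::export(name = ".bb_loglik_cpp")]]
NumericVector bb_loglik_cpp(NumericVector x, NumericVector n,
                            double mu, double rho) {
    R_xlen_t m = x.size();
    NumericVector out(m);
    for (R_xlen_t i = 0; i < m; ++i)
        out[i] = bb_loglik1(x[i], n[i], mu, rho);
    return out;
}

static double bb_loglik_sum(const double* x, const double* n, int m,
                            double mu, double rho) {
    double s = 0.0;
    for (int i = 0; i < m; ++i) s += bb_loglik1(x[i], n[i], mu, rho);
    return s;
}

// Golden-section maximization of the pooled background likelihood over
// log(rho), with mu held at the pooled-proportion plug-in estimate.
static double fit_rho_plugin(const double* x, const double* n, int m,
                             double mu) {
    const double lo = std::log(1e-8), hi = std::log(0.9);
    const double gr = 0.61803398874989484;
    double a = lo, b = hi;
    double c = b - gr * (b - a), d = a + gr * (b - a);
    double fc = bb_loglik_sum(x, n, m, mu, std::exp(c));
    double fd = bb_loglik_sum(x, n, m, mu, std::exp(d));
    for (int it = 0; it < 60 && (b - a) > 1e-4; ++it) {
        if (fc > fd) {
            b = d; d = c; fd = fc;
            c = b - gr * (b - a);
            fc = bb_loglik_sum(x, n, m, mu, std::exp(c));
        } else {
            a = c; c = d; fc = fd;
            d = a + gr * (b - a);
            fd = bb_loglik_sum(x, n, m, mu, std::exp(d));
        }
    }
    double rho = std::exp(0.5 * (a + b));
    // compare against the binomial boundary: rho at the floor wins ties
    double ll_in = bb_loglik_sum(x, n, m, mu, rho);
    double ll_floor = bb_loglik_sum(x, n, m, mu, 1e-8);
    return (ll_floor >= ll_in) ? 1e-8 : rho;
}

// Batch one-sided LRT calling for one cell-type batch.
// X, N: sites x samples matrices of alt counts and depths (combined
// strands). bg/test columns are 0-based. Per site: rho is fitted once on
// the background pool (ML over rho, pooled-proportion plug-in for mu) and
// shared by the null and alternative models, so the LRT has one free
// parameter (the test-sample rate) and a chi-square_1 reference.
// [[Rcpp::export(name = ".bb_call_batch_cpp")]]
List bb_call_batch_cpp(NumericMatrix X, NumericMatrix N,
                       IntegerVector bg_cols, IntegerVector test_cols) {
    int S = X.nrow();
    int nb = bg_cols.size(), nt = test_cols.size();
    NumericMatrix lambda(S, nt), pval(S, nt), mu_test(S, nt), mu_bg(S, nt);
    NumericVector rho_site(S);
    std::vector<double> xb(nb), db(nb);

    for (int s = 0; s < S; ++s) {
        double xs = 0.0, ns = 0.0;
        for (int j = 0; j < nb; ++j) {
            xb[j] = X(s, bg_cols[j]);
            db[j] = N(s, bg_cols[j]);
            xs += xb[j]; ns += db[j];
        }
        double mu_b = (ns > 0.0) ? xs / ns : MU_FLOOR;
        if (mu_b < MU_FLOOR) mu_b = MU_FLOOR;
        double rho = (xs > 0.0) ? fit_rho_plugin(xb.data(), db.data(), nb, mu_b)
                                : 1e-8;
        rho_site[s] = rho;
        double ll_bg_alt = bb_loglik_sum(xb.data(), db.data(), nb, mu_b, rho);

        for (int t = 0; t < nt; ++t) {
            double xt = X(s, test_cols[t]);
            double nt_dep = N(s, test_cols[t]);
            double mut = (nt_dep > 0.0) ? xt / nt_dep : 0.0;
            if (mut < MU_FLOOR) mut = MU_FLOOR;
            if (mut > 1.0 - MU_FLOOR) mut = 1.0 - MU_FLOOR;
            mu_test(s, t) = mut;
            mu_bg(s, t) = mu_b;
            if (nt_dep <= 0.0 || xt <= 0.0 || mut <= mu_b) {
                // no coverage or no excess: one-sided p = 1
                lambda(s, t) = 0.0;
                pval(s, t) = 1.0;
                continue;
            }
            double mu0 = (xs + xt) / (ns + nt_dep);
            if (mu0 < MU_FLOOR) mu0 = MU_FLOOR;
            double ll_null = bb_loglik_sum(xb.data(), db.data(), nb, mu0, rho)
                + bb_loglik1(xt, nt_dep, mu0, rho);
            double ll_alt = ll_bg_alt + bb_loglik1(xt, nt_dep, mut, rho);
            double lam = 2.0 * (ll_alt - ll_null);
            if (lam < 0.0) lam = 0.0;
            lambda(s, t) = lam;
            double p = 0.5 * R::pchisq(lam, 1.0, 0, 0);
            if (p < 1e-300) p = 1e-300;
            if (p > 1.0) p = 1.0;
            pval(s, t) = p;
        }
    }
    return List::create(_["lambda"] = lambda, _["p"] = pval,
                        _["mu_test"] = mu_test, _["mu_bg"] = mu_bg,
                        _["rho"] = rho_site);
}
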