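// Gaussian mixture EM inner loops. The soft-EM loop lives here entirely;
// the hard-EM (classification EM) and GHMRF fits reuse the exported
// log-density and M-step primitives so that their updates are numerically
// identical to the soft path's building blocks.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static arma::mat ridge_cov(const arma::mat& S, double ridge) {
    const int D = S.n_rows;
    double lambda = std::max(ridge * arma::trace(S) / D, 1e-12);
    return S + lambda * arma::eye(D, D);
}

static arma::mat log_densities(const arma::mat& X, const arma::mat& means,
                               const arma::cube& covs) {
    const int D = X.n_cols, C = means.n_rows;
    arma::mat out(X.n_rows, C);
    for (int c = 0; c < C; ++c) {
        arma::mat R;
        if (!arma::chol(R, covs.slice(c)))
            stop("covariance of class %d is not positive definite", c + 1);
        arma::mat Xc = X.each_row() - means.row(c);
        arma::mat Z = Xc * arma::inv(arma::trimatu(R));
        double logdet = 2.0 * arma::accu(arma::log(R.diag()));
        out.col(c) = -0.5 * (D * std::log(2.0 * M_PI) + logdet +
                             arma::sum(Z % Z, 1));
    }
    return out;
}

// [[Rcpp::export]]
arma::mat gauss_logdens_cpp(const arma::mat& X, const arma::mat& means,
                            const arma::cube& covs) {
    return log_densities(X, means, covs);
}

// ML Gaussian update from hard labels (1..C); emptied classes must be
// handled by the caller beforehand.
// [[Rcpp::export]]
List mstep_hard_cpp(const arma::mat& X, const arma::ivec& labels, int C,
                    double ridge) {
    const int D = X.n_cols;
    arma::mat means(C, D);
    arma::cube covs(D, D, C);
    for (int c = 0; c < C; ++c) {
        arma::uvec idx = arma::find(labels == c + 1);
        if (idx.n_elem == 0) stop("class %d is empty in mstep_hard", c + 1);
        arma::mat Xc = X.rows(idx);
        arma::rowvec mu = arma::mean(Xc, 0);
        means.row(c) = mu;
        Xc.each_row() -= mu;
        covs.slice(c) = ridge_cov(Xc.t() * Xc / Xc.n_rows, ridge);
    }
    return List::create(_["means"] = means, _["covariances"] = covs);
}

// Full soft-EM loop. Stops when the relative NLL change drops below tol
// (after the first iteration) or at max_iter. A component whose total
// responsibility falls below 1e-8 is re-seeded at the worst-fit point.
// [[Rcpp::export]]
List gmm_em_cpp(const arma::mat& X, arma::mat means, arma::cube covs,
                arma::vec priors, int max_iter, double tol, double ridge,
                bool update_priors) {
    const int N = X.n_rows, D = X.n_cols, C = means.n_rows;
    arma::mat gcov;
    {
        arma::mat Xc = X.each_row() - arma::mean(X, 0);
        gcov = ridge_cov(Xc.t() * Xc / N, 1e-6);
    }
    double nll_old = arma::datum::inf;
    bool have_old = false;
    int iter = 0;
    arma::mat resp;
    std::vector<double> nll_trace;
    while (iter < max_iter) {
        ++iter;
        arma::mat logj = log_densities(X, means, covs);
        logj.each_row() += arma::log(priors).t();
        arma::vec mx = arma::max(logj, 1);
        arma::vec lse = mx + arma::log(arma::sum(arma::exp(logj.each_col() - mx), 1));
        double nll = -arma::accu(lse);
        nll_trace.push_back(nll);
        resp = arma::exp(logj.each_col() - lse);
        arma::rowvec nc = arma::sum(resp, 0);
        arma::uvec dead = arma::find(nc < 1e-8);
        if (dead.n_elem > 0) {
            // starved component: re-seed at the worst-fit point
            arma::uvec hardest = arma::index_max(logj, 1);
            arma::mat logd = log_densities(X, means, covs);
            arma::vec fit(N);
            for (int n = 0; n < N; ++n) fit(n) = logd(n, hardest(n));
            for (arma::uword k = 0; k < dead.n_elem; ++k) {
                arma::uword worst = fit.index_min();
                means.row(dead(k)) = X.row(worst);
                covs.slice(dead(k)) = gcov;
                priors(dead(k)) = 1.0 / N;
                fit(worst) = arma::datum::inf;
            }
            priors /= arma::accu(priors);
            have_old = false;
            continue;
        }
        if (update_priors) priors = nc.t() / N;
        means = (resp.t() * X);
        means.each_col() /= nc.t();
        for (int c = 0; c < C; ++c) {
            arma::mat Xc = X.each_row() - means.row(c);
            arma::mat Xw = Xc.each_col() % resp.col(c);
            covs.slice(c) = ridge_cov(Xw.t() * Xc / nc(c), ridge);
        }
        if (have_old && std::abs(nll_old - nll) <= tol * std::abs(nll_old)) break;
        nll_old = nll;
        have_old = true;
    }
    // final evaluation under the updated parameters
    arma::mat logj = log_densities(X, means, covs);
    logj.each_row() += arma::log(priors).t();
    arma::vec mx = arma::max(logj, 1);
    arma::vec lse = mx + arma::log(arma::sum(arma::exp(logj.each_col() - mx), 1));
    resp = arma::exp(logj.each_col() - lse);
    arma::ivec labels(N);
    arma::uvec am = arma::index_max(logj, 1);
    for (int n = 0; n < N; ++n) labels(n) = am(n) + 1;
    return List::create(_["means"] = means, _["covariances"] = covs,
                        _["priors"] = priors, _["nll"] = -arma::accu(lse),
                        _["n_iter"] = iter, _["resp"] = resp,
                        _["labels"] = labels,
                        _["nll_trace"] = nll_trace);
}
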