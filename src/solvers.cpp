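// Pathwise coordinate-descent solvers for penalized logistic regression:
//  - lasso + graph-Laplacian quadratic penalty (sign-corrected) on gene
//    features, via IRLS with cyclic coordinate descent and active sets;
//  - logistic group lasso over CpG blocks, via blockwise MM (0.25 curvature
//    bound) with groupwise soft-thresholding;
//  - batched simple (1 predictor + intercept) logistic fits used by the
//    PLS and supervised-PC reductions.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;
using namespace arma;

static inline double soft(double x, double t) {
  if (x > t) return x - t;
  if (x < -t) return x + t;
  return 0.0;
}

static inline double clamp_eta(double e) {
  if (e > 30.0) return 30.0;
  if (e < -30.0) return -30.0;
  return e;
}

// negative log-likelihood/n + penalties
static double net_objective(const mat& Z, const vec& y, const sp_mat& M,
                            double b0, const vec& beta,
                            double lambda, double alpha) {
  const uword n = Z.n_rows;
  vec eta = b0 + Z * beta;
  double nll = 0.0;
  for (uword i = 0; i < n; ++i) {
    double e = clamp_eta(eta(i));
    nll += std::log1p(std::exp(e)) - y(i) * e;
  }
  nll /= (double)n;
  double l1 = accu(abs(beta));
  double quad = dot(beta, M * beta);
  return nll + lambda * alpha * l1 + lambda * (1.0 - alpha) * quad;
}

// [[Rcpp::export]]
List net_logit_path_cpp(const arma::mat& Z, const arma::vec& y,
                        const arma::sp_mat& M, double alpha,
                        int nlambda, double lambda_min_ratio,
                        Rcpp::Nullable<Rcpp::NumericVector> lambda_user,
                        int maxit_outer, int maxit_inner, double tol) {
  const uword n = Z.n_rows, p = Z.n_cols;
  const double alpha_eff = std::max(alpha, 0.01); // guard for lambda_max at alpha=0

  double ybar = mean(y);
  vec score0 = Z.t() * (y - ybar) / (double)n;
  double lmax = max(abs(score0)) / alpha_eff;
  if (!std::isfinite(lmax) || lmax <= 0) lmax = 1.0;

  vec lambdas;
  if (lambda_user.isNotNull()) {
    lambdas = as<vec>(lambda_user.get());
    nlambda = (int)lambdas.n_elem;
  } else {
    lambdas = exp(linspace<vec>(std::log(lmax * 1.000001),
                                std::log(lmax * lambda_min_ratio), nlambda));
  }

  mat betas(p, nlambda, fill::zeros);
  vec b0s(nlambda, fill::zeros);
  vec objs(nlambda, fill::zeros);
  ivec nnz(nlambda, fill::zeros);

  vec beta(p, fill::zeros);
  double b0 = std::log(ybar / (1.0 - ybar));
  vec Mbeta(p, fill::zeros); // M %*% beta, maintained incrementally

  for (int l = 0; l < nlambda; ++l) {
    double lambda = lambdas(l);
    double l1pen = lambda * alpha;
    double l2pen = 2.0 * lambda * (1.0 - alpha);

    double obj_prev = net_objective(Z, y, M, b0, beta, lambda, alpha);
    for (int outer = 0; outer < maxit_outer; ++outer) {
      // IRLS weights / working response at current iterate
      vec eta = b0 + Z * beta;
      vec pr(n), w(n), zw(n);
      for (uword i = 0; i < n; ++i) {
        double e = clamp_eta(eta(i));
        double pi = 1.0 / (1.0 + std::exp(-e));
        double wi = std::max(pi * (1.0 - pi), 1e-5);
        pr(i) = pi; w(i) = wi;
        zw(i) = eta(i) + (y(i) - pi) / wi;
      }
      double wsum = accu(w);
      vec res = zw - eta;                  // working residual
      vec a(p);                            // curvature (1/n) sum w z^2
      for (uword u = 0; u < p; ++u) a(u) = dot(w, square(Z.col(u))) / (double)n;

      // coordinate descent on the penalized weighted least squares problem
      std::vector<uword> active;
      bool check_all = true;
      for (int inner = 0; inner < maxit_inner; ++inner) {
        double maxdel = 0.0;
        if (check_all) active.clear();
        uword nloop = check_all ? p : active.size();
        for (uword k = 0; k < nloop; ++k) {
          uword u = check_all ? k : active[k];
          double bu = beta(u);
          double grad = dot(w % Z.col(u), res) / (double)n + a(u) * bu
                        - l2pen * (Mbeta(u) - M(u, u) * bu);
          double denom = a(u) + l2pen * M(u, u);
          double bnew = soft(grad, l1pen) / denom;
          double del = bnew - bu;
          if (del != 0.0) {
            beta(u) = bnew;
            res -= Z.col(u) * del;
            // incremental sparse update of M beta
            for (sp_mat::const_col_iterator it = M.begin_col(u); it != M.end_col(u); ++it)
              Mbeta(it.row()) += (*it) * del;
            maxdel = std::max(maxdel, a(u) * del * del);
          }
          if (check_all && beta(u) != 0.0) active.push_back(u);
        }
        // intercept (unpenalized)
        double db0 = dot(w, res) / wsum;
        if (db0 != 0.0) { b0 += db0; res -= db0; }
        maxdel = std::max(maxdel, 0.25 * db0 * db0);

        if (check_all) {
          if (maxdel < tol) break;
          check_all = false;
        } else if (maxdel < tol) {
          check_all = true; // verify on the full set before declaring done
        }
      }

      double obj = net_objective(Z, y, M, b0, beta, lambda, alpha);
      if (!std::isfinite(obj))
        stop("network-penalized fit diverged at lambda index %d", l + 1);
      if (std::abs(obj_prev - obj) < 1e-7 * (std::abs(obj_prev) + 1e-10)) { obj_prev = obj; break; }
      obj_prev = obj;
    }

    betas.col(l) = beta;
    b0s(l) = b0;
    objs(l) = obj_prev;
    nnz(l) = (int)accu(beta != 0.0);
  }

  return List::create(_["lambda"] = lambdas, _["beta"] = betas,
                      _["b0"] = b0s, _["objective"] = objs, _["nnz"] = nnz,
                      _["lambda_max"] = lmax);
}

// Logistic group lasso: -(1/n) loglik + lambda * sum_g sqrt(k_g) ||beta_g||_2.
// MM with the global 1/4 curvature bound; per-group Lipschitz constant
// gam_g = 0.25 * eigmax(X_g' X_g) / n precomputed once.
// group: 0-based group id per column, groups contiguous.
// [[Rcpp::export]]
List group_lasso_path_cpp(const arma::mat& X, const arma::vec& y,
                          const arma::ivec& group, int nlambda,
                          double lambda_min_ratio, int maxit, double tol) {
  const uword n = X.n_rows, P = X.n_cols;
  const int G = group.max() + 1;

  // group column ranges
  std::vector<uword> gstart(G, P), gend(G, 0);
  for (uword j = 0; j < P; ++j) {
    int g = group(j);
    gstart[g] = std::min(gstart[g], j);
    gend[g] = std::max(gend[g], j);
  }
  vec gk(G), gam(G), pw(G);
  for (int g = 0; g < G; ++g) {
    uword k = gend[g] - gstart[g] + 1;
    gk(g) = (double)k;
    pw(g) = std::sqrt((double)k);
    mat gram = X.cols(gstart[g], gend[g]).t() * X.cols(gstart[g], gend[g]);
    vec ev = eig_sym(gram);
    gam(g) = 0.25 * ev.max() / (double)n;
    if (gam(g) <= 0) gam(g) = 1e-8;
  }

  double ybar = mean(y);
  double lmax = 0.0;
  {
    vec s = X.t() * (y - ybar) / (double)n;
    for (int g = 0; g < G; ++g)
      lmax = std::max(lmax, norm(s.subvec(gstart[g], gend[g])) / pw(g));
  }
  vec lambdas = exp(linspace<vec>(std::log(lmax * 1.000001),
                                  std::log(lmax * lambda_min_ratio), nlambda));

  vec beta(P, fill::zeros);
  double b0 = std::log(ybar / (1.0 - ybar));
  vec eta(n); eta.fill(b0);
  mat betas(P, nlambda, fill::zeros);
  vec b0s(nlambda);
  imat sel(G, nlambda, fill::zeros);

  for (int l = 0; l < nlambda; ++l) {
    double lambda = lambdas(l);
    std::vector<int> active;
    bool check_all = true;
    for (int it = 0; it < maxit; ++it) {
      double maxdel = 0.0;
      if (check_all) active.clear();
      size_t nloop = check_all ? (size_t)G : active.size();
      vec pr(n);
      for (uword i = 0; i < n; ++i) pr(i) = 1.0 / (1.0 + std::exp(-clamp_eta(eta(i))));
      for (size_t k = 0; k < nloop; ++k) {
        int g = check_all ? (int)k : active[k];
        uword a = gstart[g], b = gend[g];
        vec bg = beta.subvec(a, b);
        // gradient of -loglik/n restricted to the group, at current eta
        vec grad = X.cols(a, b).t() * (pr - y) / (double)n;
        vec u = gam(g) * bg - grad;
        double un = norm(u);
        double thr = lambda * pw(g);
        vec bnew(bg.n_elem, fill::zeros);
        if (un > thr) bnew = u * ((un - thr) / (gam(g) * un));
        vec del = bnew - bg;
        double dn = norm(del);
        if (dn > 0) {
          beta.subvec(a, b) = bnew;
          eta += X.cols(a, b) * del;
          for (uword i = 0; i < n; ++i) pr(i) = 1.0 / (1.0 + std::exp(-clamp_eta(eta(i))));
          maxdel = std::max(maxdel, dn);
        }
        if (check_all && norm(beta.subvec(a, b)) > 0) active.push_back(g);
      }
      // intercept MM step (curvature bound 1/4)
      double db0 = 4.0 * mean(y - pr);
      b0 += db0; eta += db0;
      maxdel = std::max(maxdel, std::abs(db0));

      if (check_all) {
        if (maxdel < tol) break;
        check_all = false;
      } else if (maxdel < tol) {
        check_all = true;
      }
    }
    betas.col(l) = beta;
    b0s(l) = b0;
    for (int g = 0; g < G; ++g)
      sel(g, l) = norm(beta.subvec(gstart[g], gend[g])) > 0 ? 1 : 0;
  }

  return List::create(_["lambda"] = lambdas, _["beta"] = betas,
                      _["b0"] = b0s, _["selected"] = sel,
                      _["lambda_max"] = lmax);
}

// Simple logistic regression y ~ 1 + x per column of X (Newton, few steps).
// Returns the slope per column, capped at +/- cap (perfect separation guard).
// [[Rcpp::export]]
arma::vec logit1d_batch(const arma::mat& X, const arma::vec& y,
                        int maxit, double cap) {
  const uword n = X.n_rows, k = X.n_cols;
  vec out(k);
  for (uword j = 0; j < k; ++j) {
    vec x = X.col(j);
    double b0 = 0.0, b1 = 0.0;
    for (int it = 0; it < maxit; ++it) {
      double g0 = 0, g1 = 0, h00 = 0, h01 = 0, h11 = 0;
      for (uword i = 0; i < n; ++i) {
        double e = clamp_eta(b0 + b1 * x(i));
        double pi = 1.0 / (1.0 + std::exp(-e));
        double wi = std::max(pi * (1.0 - pi), 1e-8);
        double r = y(i) - pi;
        g0 += r; g1 += r * x(i);
        h00 += wi; h01 += wi * x(i); h11 += wi * x(i) * x(i);
      }
      double det = h00 * h11 - h01 * h01;
      if (std::abs(det) < 1e-12) break;
      double d0 = (h11 * g0 - h01 * g1) / det;
      double d1 = (h00 * g1 - h01 * g0) / det;
      b0 += d0; b1 += d1;
      if (std::abs(b1) > cap) { b1 = b1 > 0 ? cap : -cap; break; }
      if (std::abs(d0) < 1e-10 && std::abs(d1) < 1e-10) break;
    }
    if (std::abs(b1) > cap) b1 = b1 > 0 ? cap : -cap;
    out(j) = b1;
  }
  return out;
}

// K-fold cross-validated deviance of the 1-predictor logistic model y ~ 1 + z.
// fold: 0-based fold id per sample.
// [[Rcpp::export]]
double cv_dev_1d(const arma::vec& z, const arma::vec& y,
                 const arma::ivec& fold, int maxit) {
  int K = fold.max() + 1;
  const uword n = z.n_elem;
  double dev = 0.0;
  for (int f = 0; f < K; ++f) {
    uvec tr = find(fold != f), te = find(fold == f);
    vec xt = z(tr), yt = y(tr);
    // fit on training fold
    double b0 = 0.0, b1 = 0.0;
    for (int it = 0; it < maxit; ++it) {
      double g0 = 0, g1 = 0, h00 = 0, h01 = 0, h11 = 0;
      for (uword i = 0; i < xt.n_elem; ++i) {
        double e = clamp_eta(b0 + b1 * xt(i));
        double pi = 1.0 / (1.0 + std::exp(-e));
        double wi = std::max(pi * (1.0 - pi), 1e-8);
        double r = yt(i) - pi;
        g0 += r; g1 += r * xt(i);
        h00 += wi; h01 += wi * xt(i); h11 += wi * xt(i) * xt(i);
      }
      double det = h00 * h11 - h01 * h01;
      if (std::abs(det) < 1e-12) break;
      double d0 = (h11 * g0 - h01 * g1) / det;
      double d1 = (h00 * g1 - h01 * g0) / det;
      b0 += d0; b1 += d1;
      if (std::abs(b1) > 15.0) { b1 = b1 > 0 ? 15.0 : -15.0; break; }
      if (std::abs(d0) < 1e-10 && std::abs(d1) < 1e-10) break;
    }
    for (uword i = 0; i < te.n_elem; ++i) {
      double e = clamp_eta(b0 + b1 * z(te(i)));
      dev += 2.0 * (std::log1p(std::exp(e)) - y(te(i)) * e);
    }
  }
  (void)n;
  return dev;
}
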