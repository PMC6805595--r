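#' Normalized graph Laplacian over genes
#'
#' \eqn{l_{uu} = 1} when gene u has at least one link (0 for isolated genes)
#' and \eqn{l_{uv} = -(d_u d_v)^{-1/2}} when u and v are linked. The
#' resulting matrix is symmetric positive semidefinite; its quadratic form
#' penalizes differences between degree-scaled coefficients of linked genes.
#'
#' @param graph a \code{module_graph}, or a list with \code{n_nodes} and an
#'   integer 2-column \code{edges} matrix.
#' @return Sparse symmetric p x p \code{Matrix}.
#' @export
build_laplacian <- function(graph) {
  p <- graph$n_nodes
  e <- graph$edges
  if (nrow(e) > 0 && max(e) > p) stop("unknown gene id in edge list")
  d <- graph_degrees(p, e)
  diagv <- as.numeric(d > 0)
  if (nrow(e) > 0) {
    off <- -1 / sqrt(d[e[, 1]] * d[e[, 2]])
    L <- Matrix::sparseMatrix(i = c(e[, 1], e[, 2], seq_len(p)),
                              j = c(e[, 2], e[, 1], seq_len(p)),
                              x = c(off, off, diagv), dims = c(p, p))
  } else {
    L <- Matrix::Diagonal(p, diagv)
  }
  L
}

#' Estimate coefficient signs for the sign-corrected Laplacian penalty
#'
#' Preliminary per-gene coefficient signs from a logistic fit of the
#' phenotype on all gene features jointly: ordinary logistic regression when
#' p < n, ridge-penalized logistic regression when p >= n. A zero coefficient
#' maps to +1. When the ordinary fit does not converge (quasi-separation,
#' common for p close to n), the ridge estimator is used as fallback; only
#' the signs are consumed downstream.
#'
#' @param features \code{gene_feature_matrix} or plain n x p matrix.
#' @param y binary phenotype.
#' @param ridge_lambda l2 penalty used when p >= n (default 1.0).
#' @return Integer p-vector of signs in \{-1, +1\}.
#' @export
estimate_signs <- function(features, y, ridge_lambda = 1.0) {
  z <- if (inherits(features, "gene_feature_matrix")) features$z else as.matrix(features)
  y <- as.numeric(y)
  if (length(unique(y)) < 2) stop("phenotype is constant")
  p <- ncol(z); n <- nrow(z)
  if (p < n) {
    fit <- suppressWarnings(stats::glm.fit(cbind(1, z), y,
                                           family = stats::binomial(),
                                           control = stats::glm.control(maxit = 100)))
    co <- fit$coefficients[-1]
    if (!fit$converged || anyNA(co)) {
      # quasi-separation: fall back to a lightly ridged logistic fit, whose
      # coefficient signs are what this step is after
      fit2 <- glmnet::glmnet(z, y, family = "binomial", alpha = 0,
                             lambda = ridge_lambda / n, standardize = FALSE)
      co <- as.numeric(fit2$beta[, 1])
      if (!all(is.finite(co))) stop("sign-estimation glm did not converge")
    }
  } else {
    fit <- glmnet::glmnet(z, y, family = "binomial", alpha = 0,
                          lambda = ridge_lambda / n, standardize = FALSE)
    co <- as.numeric(fit$beta[, 1])
  }
  s <- sign(co)
  s[s == 0 | is.na(s)] <- 1
  as.integer(s)
}

#' Pathwise network-penalized logistic regression
#'
#' Minimizes
#' \deqn{-\frac{1}{n}\sum_i [y_i \log p(z_i) + (1-y_i)\log(1-p(z_i))]
#'   + \lambda\alpha\|\beta\|_1 + \lambda(1-\alpha)\,\beta^T S^T L S \beta}
#' over a descending log-spaced \eqn{\lambda} grid starting at the smallest
#' \eqn{\lambda} with an all-zero solution, by IRLS with cyclic coordinate
#' descent and warm starts. The intercept is unpenalized. \eqn{S} is the
#' diagonal sign matrix from [estimate_signs()]; \eqn{L} the Laplacian from
#' [build_laplacian()].
#'
#' @param features \code{gene_feature_matrix} or n x p matrix.
#' @param y binary phenotype.
#' @param L p x p Laplacian (sparse ok).
#' @param signs p-vector in \{-1, +1\}; defaults to all +1.
#' @param alpha lasso/Laplacian mixing proportion in [0, 1].
#' @param n_lambda,lambda_min_ratio grid size and ratio
#'   \eqn{\lambda_{min}/\lambda_{max}} (defaults 50 and 0.01).
#' @param lambda optional user grid (overrides the automatic one).
#' @param standardize scale feature columns to unit standard deviation
#'   before fitting (skip for nPC features, which are already norm-1).
#'   Coefficients are reported on the fitting scale; only their support
#'   feeds selection probabilities.
#' @param maxit_outer,maxit_inner,tol solver controls.
#' @return A \code{penalized_path}: list with \code{lambda}, \code{beta}
#'   (p x n_lambda), \code{b0}, \code{objective}, \code{nnz}, \code{alpha}.
#' @export
fit_path <- function(features, y, L, signs = NULL, alpha = 0.5,
                     n_lambda = 50L, lambda_min_ratio = 0.01, lambda = NULL,
                     standardize = TRUE, maxit_outer = 25L,
                     maxit_inner = 1000L, tol = 1e-9) {
  z <- if (inherits(features, "gene_feature_matrix")) features$z else as.matrix(features)
  y <- as.numeric(y)
  p <- ncol(z)
  if (!all(is.finite(z))) stop("non-finite feature values")
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]")
  if (is.null(signs)) signs <- rep(1L, p)
  if (standardize) {
    sdv <- apply(z, 2, stats::sd)
    sdv[sdv < 1e-12] <- 1
    z <- sweep(z, 2, sdv, "/")
  }
  # S^T L S has entries s_u s_v l_uv
  M <- Matrix::Diagonal(p, signs) %*% L %*% Matrix::Diagonal(p, signs)
  M <- methods::as(methods::as(M, "generalMatrix"), "CsparseMatrix")
  res <- net_logit_path_cpp(z, y, M, alpha, as.integer(n_lambda),
                            lambda_min_ratio, lambda,
                            as.integer(maxit_outer), as.integer(maxit_inner),
                            tol)
  structure(list(lambda = drop(res$lambda), beta = res$beta, b0 = drop(res$b0),
                 objective = drop(res$objective), nnz = drop(res$nnz),
                 lambda_max = res$lambda_max, alpha = alpha,
                 gene_ids = colnames(z) %||% seq_len(p)),
            class = "penalized_path")
}

#' Logistic group lasso over raw CpG columns
#'
#' Comparator that selects whole genes (groups of CpG columns) jointly,
#' without network information: penalty
#' \eqn{\lambda \sum_m \sqrt{k_m}\,\|\beta_{(m)}\|_2} on the logistic
#' likelihood, solved by blockwise MM descent. A gene is selected when its
#' group norm is nonzero.
#'
#' @param x n x (sum k_m) CpG matrix (or \code{methylation_dataset}).
#' @param y binary phenotype.
#' @param annotation column-to-gene map (taken from the dataset if omitted).
#' @param n_lambda,lambda_min_ratio path grid controls.
#' @param standardize scale CpG columns to unit sd before fitting.
#' @param maxit,tol solver controls.
#' @return A \code{penalized_path} with an extra \code{selected} indicator
#'   matrix (genes x lambdas) and \code{gene_ids}.
#' @export
group_lasso_path <- function(x, y = NULL, annotation = NULL, n_lambda = 50L,
                             lambda_min_ratio = 0.01, standardize = TRUE,
                             maxit = 500L, tol = 1e-5) {
  if (inherits(x, "methylation_dataset")) {
    annotation <- x$annotation
    if (is.null(y)) y <- x$y
    x <- x$x
  }
  y <- as.numeric(y)
  if (nrow(annotation) != ncol(x)) stop("empty group or unannotated column: annotation rows must match CpG columns")
  gene_ids <- unique(annotation$gene_id)
  gidx <- match(annotation$gene_id, gene_ids)
  ord <- order(gidx)
  x <- x[, ord, drop = FALSE]
  gidx <- gidx[ord]
  if (any(tabulate(gidx, length(gene_ids)) == 0)) stop("empty group")
  x <- sweep(x, 2, colMeans(x))
  if (standardize) {
    sdv <- apply(x, 2, stats::sd)
    sdv[sdv < 1e-12] <- 1
    x <- sweep(x, 2, sdv, "/")
  }
  res <- group_lasso_path_cpp(x, y, as.integer(gidx - 1L),
                              as.integer(n_lambda), lambda_min_ratio,
                              as.integer(maxit), tol)
  structure(list(lambda = drop(res$lambda), beta = res$beta, b0 = drop(res$b0),
                 selected = res$selected, lambda_max = res$lambda_max,
                 gene_ids = gene_ids, alpha = NA_real_),
            class = "penalized_path")
}

#' Objective of the network-penalized logistic regression
#'
#' Exposed for testing: evaluates the penalized negative log-likelihood at an
#' arbitrary (b0, beta).
#'
#' @param z n x p feature matrix; \code{b0}, \code{beta} candidate solution.
#' @param y phenotype; \code{M} the (sign-corrected) penalty matrix
#'   \eqn{S^T L S}; \code{lambda}, \code{alpha} tuning values.
#' @return Scalar objective value.
#' @keywords internal
#' @export
net_objective_r <- function(z, y, M, b0, beta, lambda, alpha) {
  eta <- pmin(pmax(b0 + drop(z %*% beta), -30), 30)
  nll <- mean(log1p(exp(eta)) - y * eta)
  nll + lambda * alpha * sum(abs(beta)) +
    lambda * (1 - alpha) * drop(crossprod(beta, as.matrix(M) %*% beta))
}
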