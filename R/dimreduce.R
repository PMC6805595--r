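#' First principal component of a gene's CpG block
#'
#' Computes the leading eigenvector \eqn{\theta} (\eqn{\|\theta\|_2 = 1}) of
#' the unscaled Gram matrix \eqn{X^T X} of the mean-centered block and returns
#' the projected feature \eqn{z = X\theta}. The eigenvalue convention is the
#' unscaled one, so that the normalized PC ([normalized_pc()]) has unit
#' l2-norm exactly. The eigenvector sign is fixed so that the loading entry
#' of largest magnitude is positive.
#'
#' @param block n x k matrix of one gene's methylation values; columns are
#'   mean-centered internally.
#' @return List with \code{feature} (n-vector), \code{theta} (k loadings) and
#'   \code{e} (leading eigenvalue of \eqn{X^T X}).
#' @export
first_pc <- function(block) {
  block <- as.matrix(block)
  if (nrow(block) < 2) stop("need at least 2 samples")
  X <- sweep(block, 2, colMeans(block))
  G <- crossprod(X)
  if (all(abs(G) < 1e-30)) {
    warning("all-zero gene block; returning zero feature")
    return(list(feature = numeric(nrow(X)), theta = c(1, numeric(ncol(X) - 1)),
                e = 0))
  }
  es <- eigen(G, symmetric = TRUE)
  theta <- es$vectors[, 1]
  if (theta[which.max(abs(theta))] < 0) theta <- -theta
  list(feature = drop(X %*% theta), theta = theta, e = es$values[1])
}

#' Normalized first principal component
#'
#' The first PC scaled by \eqn{1/\sqrt{e}}, which gives the feature unit
#' l2-norm (whitening of the leading direction).
#'
#' @inheritParams first_pc
#' @param tol eigenvalue tolerance below which the gene is degenerate.
#' @return n-vector with \eqn{\|z\|_2 = 1}.
#' @export
normalized_pc <- function(block, tol = 1e-12) {
  pc <- first_pc(block)
  if (pc$e <= tol) stop("degenerate gene block: leading eigenvalue ~ 0")
  pc$feature / sqrt(pc$e)
}

#' Supervised first principal component
#'
#' Screens CpG sites by the magnitude of their two-sample (Welch) t statistic
#' against the phenotype, keeps the sites above a threshold (at least the
#' single best site), and returns the first PC of the retained sub-block.
#' The threshold is chosen from \code{threshold_grid} by 5-fold
#' cross-validated deviance of a univariate logistic regression of the
#' phenotype on the resulting feature.
#'
#' @inheritParams first_pc
#' @param y binary phenotype (0/1).
#' @param threshold_grid absolute-t thresholds to consider.
#' @param nfolds folds for the threshold CV.
#' @param seed RNG seed for the CV fold split.
#' @return List with \code{feature}, \code{selected_sites} (column indices of
#'   the retained sites), \code{threshold}, \code{theta} and \code{e}.
#' @export
supervised_pc <- function(block, y, threshold_grid = c(0, 0.5, 1, 1.5, 2, 2.5),
                          nfolds = 5L, seed = 1L) {
  block <- as.matrix(block)
  y <- as.numeric(y)
  if (length(unique(y)) < 2) stop("phenotype is constant")
  tt <- abs(welch_t(block, y))
  sets <- lapply(threshold_grid, function(th) {
    s <- which(tt > th)
    if (length(s) == 0) s <- which.max(tt)
    sort(s)
  })
  keys <- vapply(sets, paste, "", collapse = ",")
  uidx <- which(!duplicated(keys))
  if (length(uidx) == 1) {
    best <- 1L
  } else {
    old <- local_seed(seed)
    on.exit(restore_seed(old), add = TRUE)
    fold <- sample(rep_len(seq_len(nfolds), length(y))) - 1L
    udev <- vapply(uidx, function(i) {
      f <- first_pc(block[, sets[[i]], drop = FALSE])$feature
      cv_dev_1d(f, y, fold, 25L)
    }, 0)
    best <- which.min(udev[match(keys, keys[uidx])])
  }
  sel <- sets[[best]]
  pc <- first_pc(block[, sel, drop = FALSE])
  list(feature = pc$feature, selected_sites = sel,
       threshold = threshold_grid[best], theta = pc$theta, e = pc$e)
}

# vectorized Welch two-sample t statistics per column (class 1 minus class 0)
welch_t <- function(block, y) {
  a <- block[y == 1, , drop = FALSE]
  b <- block[y == 0, , drop = FALSE]
  n1 <- nrow(a); n0 <- nrow(b)
  m1 <- colMeans(a); m0 <- colMeans(b)
  v1 <- colSums(sweep(a, 2, m1)^2) / (n1 - 1)
  v0 <- colSums(sweep(b, 2, m0)^2) / (n0 - 1)
  se <- sqrt(v1 / n1 + v0 / n0)
  (m1 - m0) / pmax(se, 1e-300)
}

#' First partial-least-squares component
#'
#' Each site's weight is the slope \eqn{\hat\gamma_j} of a simple logistic
#' regression of the phenotype on that site; the weight vector is normalized,
#' \eqn{\theta = \hat\gamma/\|\hat\gamma\|_2}, so \eqn{\theta^T\theta = 1}
#' and the feature is \eqn{X\theta}. Slopes are capped at \eqn{\pm 10} to
#' guard against perfect separation.
#'
#' @inheritParams supervised_pc
#' @param cap absolute bound on the per-site logistic slopes.
#' @return List with \code{feature}, \code{theta} and \code{gamma_hat}.
#' @export
pls_component <- function(block, y, cap = 10) {
  block <- as.matrix(block)
  y <- as.numeric(y)
  if (length(unique(y)) < 2) stop("phenotype is constant")
  X <- sweep(block, 2, colMeans(block))
  gam <- drop(logit1d_batch(X, y, 25L, cap))
  nrm <- sqrt(sum(gam^2))
  theta <- if (nrm > 1e-12) gam / nrm else c(1, numeric(length(gam) - 1))
  list(feature = drop(X %*% theta), theta = theta, gamma_hat = gam)
}

#' Reduce every gene's CpG block to one feature
#'
#' Applies one of the four reduction techniques gene by gene and assembles
#' the n x p gene-feature matrix, with columns ordered by gene id.
#'
#' @param x n x (sum k_m) methylation matrix, or a
#'   \code{methylation_dataset}.
#' @param annotation data frame (\code{cpg_id}, \code{gene_id}) mapping each
#'   column of \code{x} to a gene; taken from the dataset when \code{x} is a
#'   \code{methylation_dataset}.
#' @param y phenotype (needed for \code{"sPC"} and \code{"PLS"}).
#' @param method one of \code{"PC"}, \code{"nPC"}, \code{"sPC"},
#'   \code{"PLS"}.
#' @param seed seed for the sPC threshold cross-validation.
#' @return A \code{gene_feature_matrix}: list with \code{z} (n x p),
#'   \code{method}, \code{gene_ids}, and per-gene metadata (\code{loadings},
#'   \code{eigenvalue}, \code{selected_sites} or \code{gamma_hat} as
#'   applicable).
#' @export
reduce_all <- function(x, annotation = NULL, y = NULL,
                       method = c("nPC", "PC", "sPC", "PLS"), seed = 1L) {
  method <- match.arg(method)
  if (inherits(x, "methylation_dataset")) {
    annotation <- x$annotation
    if (is.null(y)) y <- x$y
    x <- x$x
  }
  if (is.null(annotation)) stop("annotation required")
  if (nrow(annotation) != ncol(x)) stop("annotation does not cover all columns")
  gene_ids <- unique(annotation$gene_id)
  cols <- split(seq_len(ncol(x)), factor(annotation$gene_id, levels = gene_ids))
  if (any(lengths(cols) == 0)) {
    stop("gene(s) with zero CpG columns: ",
         paste(gene_ids[lengths(cols) == 0], collapse = ", "))
  }
  n <- nrow(x); p <- length(gene_ids)
  z <- matrix(0, n, p)
  loadings <- vector("list", p)
  eigenvalue <- rep(NA_real_, p)
  selected <- vector("list", p)
  gamma_hat <- vector("list", p)
  for (m in seq_len(p)) {
    blk <- x[, cols[[m]], drop = FALSE]
    f <- switch(method,
      PC = first_pc(blk),
      nPC = { pc <- first_pc(blk); pc$feature <- normalized_pc(blk); pc },
      sPC = supervised_pc(blk, y, seed = derive_seed(seed, "misc", m)),
      PLS = pls_component(blk, y))
    z[, m] <- f$feature
    loadings[[m]] <- f$theta
    eigenvalue[m] <- f$e %||% NA_real_
    selected[[m]] <- f$selected_sites
    gamma_hat[[m]] <- f$gamma_hat
  }
  colnames(z) <- as.character(gene_ids)
  structure(list(z = z, method = method, gene_ids = gene_ids,
                 loadings = loadings, eigenvalue = eigenvalue,
                 selected_sites = selected, gamma_hat = gamma_hat),
            class = "gene_feature_matrix")
}
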