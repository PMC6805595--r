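#' First canonical correlation between two CpG blocks
#'
#' Largest canonical correlation between the columns of two gene blocks,
#' computed from the SVD of
#' \eqn{\Sigma_{aa}^{-1/2}\Sigma_{ab}\Sigma_{bb}^{-1/2}}. Within-block
#' covariances are ridge-regularized by \code{ridge * trace/k} whenever a
#' block has at least as many sites as samples (rank deficiency), and always
#' by a tiny jitter for numerical safety.
#'
#' @param block_a,block_b n x k_a and n x k_b matrices.
#' @param ridge relative ridge for rank-deficient blocks (default 1e-3).
#' @return First canonical correlation in [0, 1].
#' @export
canonical_correlation <- function(block_a, block_b, ridge = 1e-3) {
  A <- scale(as.matrix(block_a), center = TRUE, scale = FALSE)
  B <- scale(as.matrix(block_b), center = TRUE, scale = FALSE)
  n <- nrow(A)
  if (n < 3) stop("need at least 3 samples")
  if (all(abs(A) < 1e-300) || all(abs(B) < 1e-300)) stop("zero-variance block")
  Saa <- crossprod(A) / (n - 1)
  Sbb <- crossprod(B) / (n - 1)
  Sab <- crossprod(A, B) / (n - 1)
  reg <- function(S, k, needs_ridge) {
    tr <- sum(diag(S))
    r <- if (needs_ridge) ridge * tr / k else 1e-10 * max(tr / k, 1e-300)
    S + diag(r, k)
  }
  Saa <- reg(Saa, ncol(A), ncol(A) >= n)
  Sbb <- reg(Sbb, ncol(B), ncol(B) >= n)
  ia <- inv_sqrt(Saa)
  ib <- inv_sqrt(Sbb)
  d <- svd(ia %*% Sab %*% ib, nu = 0, nv = 0)$d
  min(max(d[1], 0), 1)
}

inv_sqrt <- function(S) {
  es <- eigen(S, symmetric = TRUE)
  v <- pmax(es$values, max(es$values) * 1e-12)
  es$vectors %*% (t(es$vectors) / sqrt(v))
}

#' Mean canonical correlation over gene pairs
#'
#' @param pairs 2-column matrix (or data frame) of gene ids.
#' @param x CpG matrix or \code{methylation_dataset}.
#' @param annotation column-to-gene map (from the dataset if omitted).
#' @param ridge passed to [canonical_correlation()].
#' @return Arithmetic mean of the pairs' first canonical correlations.
#' @export
mean_ccc <- function(pairs, x, annotation = NULL, ridge = 1e-3) {
  if (inherits(x, "methylation_dataset")) {
    annotation <- x$annotation
    x <- x$x
  }
  pairs <- as.matrix(pairs)
  gene_ids <- unique(annotation$gene_id)
  if (!all(pairs %in% gene_ids)) {
    stop("missing gene(s): ",
         paste(utils::head(setdiff(unique(as.vector(pairs)), gene_ids)),
               collapse = ", "))
  }
  cols <- split(seq_len(ncol(x)), factor(annotation$gene_id, levels = gene_ids))
  names(cols) <- as.character(gene_ids)
  ccs <- vapply(seq_len(nrow(pairs)), function(i) {
    canonical_correlation(x[, cols[[as.character(pairs[i, 1])]], drop = FALSE],
                          x[, cols[[as.character(pairs[i, 2])]], drop = FALSE],
                          ridge = ridge)
  }, 0)
  mean(ccs)
}

#' Permutation test: are linked genes more co-methylated than random pairs?
#'
#' Compares the mean first canonical correlation \eqn{c^*} of the network's
#' gene pairs against K draws of the same number of uniformly random
#' unordered gene pairs (no self-pairs, no duplicates within a draw):
#' \deqn{p = (\sum_k I(c_k > c^*) + 1)/(K + 1).}
#'
#' @param x CpG matrix or \code{methylation_dataset}.
#' @param annotation column-to-gene map.
#' @param edges 2-column matrix of linked gene-id pairs.
#' @param K permutation count.
#' @param seed RNG seed.
#' @param ridge passed to [canonical_correlation()].
#' @return List of class \code{cca_permutation} with \code{c_star},
#'   \code{c_k} (K-vector), \code{K} and \code{pvalue}.
#' @export
permutation_test <- function(x, annotation = NULL, edges, K = 1000L, seed = 1L,
                             ridge = 1e-3) {
  if (inherits(x, "methylation_dataset")) {
    annotation <- x$annotation
    x <- x$x
  }
  gene_ids <- unique(annotation$gene_id)
  p <- length(gene_ids)
  edges <- as.matrix(edges)
  n_pairs <- nrow(edges)
  total <- p * (p - 1) / 2
  if (n_pairs > total) stop("more edges than possible unordered pairs")
  c_star <- mean_ccc(edges, x, annotation, ridge = ridge)
  old <- local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  c_k <- vapply(seq_len(K), function(k) {
    # sample unordered pairs uniformly without replacement within the draw
    code <- sample(total, n_pairs)
    m <- ceiling((sqrt(8 * code + 1) - 1) / 2) # code in (m(m-1)/2, m(m+1)/2]
    u <- m + 1
    v <- code - m * (m - 1) / 2
    mean_ccc(cbind(gene_ids[u], gene_ids[v]), x, annotation, ridge = ridge)
  }, 0)
  structure(list(c_star = c_star, c_k = c_k, K = K,
                 pvalue = (sum(c_k > c_star) + 1) / (K + 1)),
            class = "cca_permutation")
}
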