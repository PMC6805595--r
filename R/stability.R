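#' Balanced half-sample resampling scheme
#'
#' @param n_resamples number of resamples S (reference defaults: 100 for
#'   simulations, 500 for data analysis).
#' @param balanced draw \eqn{\lfloor n_1/2 \rfloor} cases and
#'   \eqn{\lfloor n_2/2 \rfloor} controls (recommended); otherwise
#'   \eqn{\lfloor n/2 \rfloor} samples ignoring class.
#' @param seed base seed; resample s uses seed + s.
#' @return A \code{subsample_scheme} list.
#' @export
subsample_scheme <- function(n_resamples = 100L, balanced = TRUE, seed = 1L) {
  stopifnot(n_resamples >= 2)
  structure(list(n_resamples = as.integer(n_resamples), balanced = balanced,
                 seed = as.integer(seed)),
            class = "subsample_scheme")
}

draw_subsample <- function(y, scheme, s) {
  old <- local_seed((scheme$seed + s) %% 2147483629)
  on.exit(restore_seed(old), add = TRUE)
  repeat {
    idx <- if (scheme$balanced) {
      cases <- which(y == 1); ctrls <- which(y == 0)
      c(sample(cases, floor(length(cases) / 2)),
        sample(ctrls, floor(length(ctrls) / 2)))
    } else {
      sample(seq_along(y), floor(length(y) / 2))
    }
    if (length(unique(y[idx])) == 2) return(sort(idx))
    message("resample ", s, " had a single class; redrawn")
  }
}

#' Per-gene selection probabilities from half-sample resampling
#'
#' For each resample and each \eqn{\alpha} on the grid, the full
#' \eqn{\lambda} path of the network-penalized logistic regression is fit on
#' the subsample (the \eqn{\lambda} grid is recomputed from that subsample's
#' own \eqn{\lambda_{max}}). The selection probability of gene j is the
#' maximum over all \eqn{(\alpha, \lambda)} of the fraction of resamples in
#' which \eqn{\hat\beta_j \neq 0}.
#'
#' @param features \code{gene_feature_matrix} or n x p matrix.
#' @param y binary phenotype.
#' @param L Laplacian matrix; \code{signs} sign vector (estimated once on the
#'   full data if \code{NULL}).
#' @param alpha_grid mixing proportions (default \code{c(0.1, 0.5, 0.9)}).
#' @param n_lambda,lambda_min_ratio path grid controls.
#' @param scheme a [subsample_scheme()].
#' @param standardize passed to [fit_path()].
#' @return A \code{selection_profile}: list with \code{sp} (p-vector),
#'   \code{ranking} (gene indices by the rule in [rank_genes()]),
#'   \code{per_grid_counts} (p x (alpha x lambda) selection counts),
#'   \code{mean_abs_beta} and \code{gene_ids}.
#' @export
selection_probability <- function(features, y, L, signs = NULL,
                                  alpha_grid = c(0.1, 0.5, 0.9),
                                  n_lambda = 50L, lambda_min_ratio = 0.01,
                                  scheme = subsample_scheme(),
                                  standardize = TRUE) {
  z <- if (inherits(features, "gene_feature_matrix")) features$z else as.matrix(features)
  y <- as.numeric(y)
  p <- ncol(z)
  if (is.null(signs)) signs <- estimate_signs(z, y)
  S <- scheme$n_resamples
  counts <- matrix(0L, p, length(alpha_grid) * n_lambda)
  absbeta <- numeric(p)
  for (s in seq_len(S)) {
    idx <- draw_subsample(y, scheme, s)
    for (a in seq_along(alpha_grid)) {
      fit <- fit_path(z[idx, , drop = FALSE], y[idx], L, signs,
                      alpha = alpha_grid[a], n_lambda = n_lambda,
                      lambda_min_ratio = lambda_min_ratio,
                      standardize = standardize)
      cols <- (a - 1L) * n_lambda + seq_len(n_lambda)
      counts[, cols] <- counts[, cols] + (fit$beta != 0)
      absbeta <- absbeta + rowSums(abs(fit$beta))
    }
  }
  sp <- apply(counts, 1, max) / S
  mean_abs <- absbeta / (S * length(alpha_grid) * n_lambda)
  prof <- structure(list(sp = sp, per_grid_counts = counts,
                         mean_abs_beta = mean_abs,
                         n_resamples = S, alpha_grid = alpha_grid,
                         gene_ids = colnames(z) %||% seq_len(p)),
                    class = "selection_profile")
  prof$ranking <- rank_genes(prof)
  prof
}

#' Rank genes by selection probability
#'
#' Descending SP; ties broken by descending mean absolute coefficient over
#' the whole tuning grid, then by gene index (deterministic).
#'
#' @param profile a \code{selection_profile}.
#' @return Integer permutation of gene indices (best first).
#' @export
rank_genes <- function(profile) {
  order(-profile$sp, -profile$mean_abs_beta, seq_along(profile$sp))
}

#' True positive rate of a ranking at several cut-offs
#'
#' \eqn{TPR(k) = |top\mbox{-}k \cap truth| / |truth|}.
#'
#' @param ranking integer gene indices, best first (e.g.
#'   \code{profile$ranking}), or a \code{selection_profile}.
#' @param truth integer indices of the outcome-related genes.
#' @param top_k cut-offs (default 10, 20, ..., 100).
#' @return Named numeric vector of TPR values.
#' @export
rank_and_tpr <- function(ranking, truth, top_k = seq(10, 100, by = 10)) {
  if (inherits(ranking, "selection_profile")) ranking <- ranking$ranking
  if (length(truth) == 0) stop("truth set is empty")
  if (any(top_k > length(ranking))) stop("top_k exceeds number of genes")
  out <- vapply(top_k, function(k) {
    sum(ranking[seq_len(k)] %in% truth) / length(truth)
  }, 0)
  names(out) <- paste0("k", top_k)
  out
}

#' Write a selection profile as TSV
#' @param profile a \code{selection_profile}; \code{file} output path.
#' @return \code{file}, invisibly.
#' @export
write_sp_tsv <- function(profile, file) {
  rk <- integer(length(profile$sp))
  rk[profile$ranking] <- seq_along(profile$sp)
  utils::write.table(data.frame(gene_id = profile$gene_ids, sp = profile$sp,
                                rank = rk),
                     file, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Selection probabilities for the group-lasso comparator
#'
#' Same resampling scheme as [selection_probability()], but the per-resample
#' fit is the logistic group lasso on raw CpG columns and a gene counts as
#' selected when its group norm is nonzero (no alpha grid).
#'
#' @inheritParams selection_probability
#' @param x CpG matrix or \code{methylation_dataset}; \code{annotation}
#'   column-to-gene map.
#' @return A \code{selection_profile}.
#' @export
selection_probability_grouplasso <- function(x, y = NULL, annotation = NULL,
                                             n_lambda = 50L,
                                             lambda_min_ratio = 0.01,
                                             scheme = subsample_scheme()) {
  if (inherits(x, "methylation_dataset")) {
    annotation <- x$annotation
    if (is.null(y)) y <- x$y
    x <- x$x
  }
  y <- as.numeric(y)
  gene_ids <- unique(annotation$gene_id)
  p <- length(gene_ids)
  S <- scheme$n_resamples
  counts <- matrix(0L, p, n_lambda)
  normsum <- numeric(p)
  for (s in seq_len(S)) {
    idx <- draw_subsample(y, scheme, s)
    fit <- group_lasso_path(x[idx, , drop = FALSE], y[idx], annotation,
                            n_lambda = n_lambda,
                            lambda_min_ratio = lambda_min_ratio)
    counts <- counts + fit$selected
    gn <- rowsum(rowSums(abs(fit$beta)), annotation$gene_id, reorder = FALSE)
    normsum <- normsum + gn[match(gene_ids, rownames(gn)), 1]
  }
  sp <- apply(counts, 1, max) / S
  prof <- structure(list(sp = sp, per_grid_counts = counts,
                         mean_abs_beta = normsum / (S * n_lambda),
                         n_resamples = S, alpha_grid = NA_real_,
                         gene_ids = gene_ids),
                    class = "selection_profile")
  prof$ranking <- rank_genes(prof)
  prof
}
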