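#' Simulation configuration
#'
#' Bundles the parameters of the three-step case-control methylation
#' simulator: a gene network is turned into a Gaussian-graphical-model
#' covariance, latent gene values are drawn per subject with a case-specific
#' mean shift, and CpG-level methylation values are emitted around each
#' gene's latent value.
#'
#' @param n_cases,n_controls group sizes (defaults 100/100).
#' @param n_modules number of disjoint network modules (default 10).
#' @param genes_per_module genes per module (default 100).
#' @param delta signal strength \eqn{\delta} of the case mean shift
#'   (default 1.5, giving latent shifts between 0.5 and 1.5 in magnitude).
#' @param omega number of causal CpG sites per gene (default 8). Ignored for
#'   scenario 3, where \code{causal_fraction} applies.
#' @param causal_fraction fraction of a causal gene's sites that are causal
#'   (scenario 3 only; default 0.40).
#' @param sigma emission noise standard deviation (default 2.0).
#' @param sites_per_gene fixed CpG count per gene (default 10), or the string
#'   \code{"gamma"} to draw per-gene counts from a Gamma distribution
#'   (scenario 3).
#' @param gamma_shape,gamma_scale,min_sites Gamma-size parameters for
#'   scenario 3 (defaults 2, 5, 1).
#' @param scenario \code{"scenario1"}, \code{"scenario2"} or
#'   \code{"scenario3"}.
#' @param edge_weight GGM edge weight passed to [graph_to_covariance()].
#' @param seed master RNG seed.
#' @return A \code{sim_config} list.
#' @export
sim_config <- function(n_cases = 100L, n_controls = 100L, n_modules = 10L,
                       genes_per_module = 100L, delta = 1.5, omega = 8L,
                       causal_fraction = 0.40, sigma = 2.0,
                       sites_per_gene = 10L, gamma_shape = 2, gamma_scale = 5,
                       min_sites = 1L,
                       scenario = c("scenario1", "scenario2", "scenario3"),
                       edge_weight = 0.5, seed = 1L) {
  scenario <- match.arg(scenario)
  stopifnot(n_cases > 0, n_controls > 0, delta > 0, sigma > 0,
            genes_per_module > 0)
  if (scenario == "scenario3") {
    if (!(causal_fraction > 0 && causal_fraction <= 1)) {
      stop("invalid config: causal_fraction must be in (0, 1]")
    }
    sites_per_gene <- "gamma"
  } else if (!(omega > 0 && omega <= sites_per_gene)) {
    stop("invalid config: need 0 < omega <= sites_per_gene")
  }
  structure(list(n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
                 n_modules = as.integer(n_modules),
                 genes_per_module = as.integer(genes_per_module),
                 delta = delta, omega = as.integer(omega),
                 causal_fraction = causal_fraction, sigma = sigma,
                 sites_per_gene = sites_per_gene, gamma_shape = gamma_shape,
                 gamma_scale = gamma_scale, min_sites = as.integer(min_sites),
                 scenario = scenario, edge_weight = edge_weight,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Gaussian graphical model covariance from a gene graph
#'
#' Builds a sparse precision matrix whose off-diagonal support equals the
#' graph's edge set, inverts it, and standardizes the result to a correlation
#' matrix. The precision is \eqn{\Omega = (1+r) I - w D^{-1/2} A D^{-1/2}}
#' where \eqn{A} is the adjacency and \eqn{D} the degree matrix; the
#' normalized adjacency has spectral radius at most 1, so \eqn{\Omega} is
#' positive definite for any \eqn{|w| < 1 + r}. Linked genes end up more
#' correlated than unlinked genes of the same module.
#'
#' @param graph a \code{module_graph} (typically [assemble_modules()] output).
#' @param edge_weight \eqn{w}, default 0.5.
#' @param ridge diagonal inflation \eqn{r}, default 0.05.
#' @return A list of class \code{covariance_model} with sparse
#'   \code{precision} and dense correlation \code{sigma_mat}.
#' @export
graph_to_covariance <- function(graph, edge_weight = 0.5, ridge = 0.05) {
  p <- graph$n_nodes
  d <- pmax(graph$degrees, 1L)
  e <- graph$edges
  if (nrow(e) > 0) {
    val <- -edge_weight / sqrt(d[e[, 1]] * d[e[, 2]])
    prec <- Matrix::sparseMatrix(i = c(e[, 1], e[, 2], seq_len(p)),
                                 j = c(e[, 2], e[, 1], seq_len(p)),
                                 x = c(val, val, rep(1 + ridge, p)),
                                 dims = c(p, p), symmetric = FALSE)
  } else {
    prec <- Matrix::Diagonal(p, 1 + ridge)
  }
  ev_min <- 1 + ridge - abs(edge_weight) # lower bound via normalized adjacency
  if (ev_min <= 0) {
    stop("precision matrix not positive definite; shrink edge_weight below ",
         1 + ridge)
  }
  sigma <- as.matrix(Matrix::solve(prec))
  sigma <- stats::cov2cor((sigma + t(sigma)) / 2)
  structure(list(precision = prec, sigma_mat = sigma),
            class = "covariance_model")
}

#' Case-group latent mean vector
#'
#' Outcome-related genes receive a degree-dependent mean shift: the centered
#' gene gets \eqn{\delta} (\eqn{-\delta} for the hub of a negatively
#' associated module); genes in groups g1/g3 get
#' \eqn{+(\delta/3)\sqrt{d_j}}; genes in g2/g4 get
#' \eqn{-(\delta/3)\sqrt{d_j}}; neutral genes get 0.
#'
#' @param graph a labelled \code{module_graph}.
#' @param delta signal strength \eqn{\delta}.
#' @return Numeric p-vector \eqn{\mu}.
#' @export
make_mean_vector <- function(graph, delta) {
  mu <- numeric(graph$n_nodes)
  lab <- graph$labels
  d <- graph$degrees
  mu[lab == "centered"] <- delta
  mu[lab == "centered_neg"] <- -delta
  pos <- lab %in% c("g1", "g3")
  neg <- lab %in% c("g2", "g4")
  mu[pos] <- (delta / 3) * sqrt(d[pos])
  mu[neg] <- -(delta / 3) * sqrt(d[neg])
  mu
}

#' Draw latent gene values for cases and controls
#'
#' Controls are N(0, Sigma); cases are N(mu, Sigma). Rows are cases first,
#' then controls.
#'
#' @param mu mean p-vector for cases.
#' @param cov a \code{covariance_model}.
#' @param n_cases,n_controls group sizes.
#' @param seed RNG seed.
#' @param chol_sigma optional pre-computed upper Cholesky factor of
#'   \code{cov$sigma_mat} (saves repeated factorizations across replicates).
#' @return List with \code{z} (n x p latent matrix) and \code{y} (phenotype
#'   0/1 vector, 1 = case).
#' @export
sample_latent <- function(mu, cov, n_cases, n_controls, seed = 1L,
                          chol_sigma = NULL) {
  p <- length(mu)
  if (!is.null(cov) && ncol(cov$sigma_mat) != p) stop("dimension mismatch between mu and covariance")
  R <- chol_sigma %||% chol(cov$sigma_mat)
  n <- n_cases + n_controls
  old <- local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  z <- matrix(stats::rnorm(n * p), n, p) %*% R
  z[seq_len(n_cases), ] <- sweep(z[seq_len(n_cases), , drop = FALSE], 2, mu, "+")
  list(z = z, y = c(rep(1L, n_cases), rep(0L, n_controls)))
}

#' Emit CpG-level methylation values around latent gene values
#'
#' Within each gene, the first \eqn{\omega_m} sites are the gene's latent
#' value plus N(0, sigma^2) noise; the remaining sites are pure noise centered
#' at the gene's pooled latent mean (computed once over all n subjects).
#'
#' @param latent output of [sample_latent()].
#' @param omega causal site count; scalar or per-gene vector.
#' @param sigma emission noise standard deviation.
#' @param sites_per_gene CpG count per gene; scalar or per-gene vector.
#' @param seed RNG seed.
#' @param truth_genes integer ids of outcome-related genes (stored as truth).
#' @return A \code{methylation_dataset}: list with matrix \code{x}
#'   (columns named \code{gene<g>_cpg<j>}), \code{annotation} data frame
#'   (\code{cpg_id}, \code{gene_id}), \code{y}, \code{truth},
#'   \code{sites_per_gene} and \code{omega}.
#' @export
emit_methylation <- function(latent, omega, sigma, sites_per_gene, seed = 1L,
                             truth_genes = integer(0)) {
  z <- latent$z
  n <- nrow(z); p <- ncol(z)
  k <- rep_len(as.integer(sites_per_gene), p)
  w <- rep_len(as.integer(omega), p)
  if (any(w > k)) stop("omega exceeds sites_per_gene for gene(s) ",
                       paste(utils::head(which(w > k)), collapse = ", "))
  total <- sum(k)
  old <- local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  x <- matrix(stats::rnorm(n * total, sd = sigma), n, total)
  col_gene <- rep.int(seq_len(p), k)
  site_idx <- sequence(k)
  causal_col <- site_idx <= w[col_gene]
  zbar <- colMeans(z)
  # causal sites: add the subject's latent value; noise sites: add the
  # gene's pooled latent mean (a constant per gene)
  x[, causal_col] <- x[, causal_col] + z[, col_gene[causal_col], drop = FALSE]
  if (any(!causal_col)) {
    x[, !causal_col] <- sweep(x[, !causal_col, drop = FALSE], 2,
                              zbar[col_gene[!causal_col]], "+")
  }
  cpg_id <- paste0("gene", col_gene, "_cpg", site_idx)
  colnames(x) <- cpg_id
  structure(list(x = x,
                 annotation = data.frame(cpg_id = cpg_id,
                                         gene_id = col_gene),
                 y = latent$y, truth = as.integer(truth_genes),
                 sites_per_gene = k, omega = w),
            class = "methylation_dataset")
}

#' Per-gene CpG counts from a Gamma distribution
#'
#' Rounded Gamma draws floored at \code{min_sites}, emulating the long-tailed
#' distribution of CpG sites per gene on methylation arrays.
#'
#' @param p number of genes.
#' @param shape,scale Gamma parameters.
#' @param min_sites lower floor for the counts.
#' @param seed RNG seed.
#' @return Integer p-vector of site counts.
#' @export
gamma_gene_sizes <- function(p, shape = 2, scale = 5, min_sites = 1L, seed = 1L) {
  stopifnot(shape > 0, scale > 0)
  old <- local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  pmax(as.integer(round(stats::rgamma(p, shape = shape, scale = scale))),
       as.integer(min_sites))
}

#' Run the full three-step simulator
#'
#' Convenience wrapper: builds the module graphs for the configured scenario,
#' assembles the GGM covariance, draws latent values and emits CpG data.
#'
#' @param config a [sim_config()].
#' @param cache optional environment; when supplied, the assembled graph,
#'   covariance and Cholesky factor are memoized there so repeated replicates
#'   skip the expensive covariance inversion.
#' @return A \code{methylation_dataset} with an extra \code{graph} element.
#' @export
simulate_methylation <- function(config, cache = NULL) {
  key <- paste0(config$scenario, "_", config$n_modules, "_",
                config$genes_per_module, "_", config$edge_weight)
  built <- if (!is.null(cache) && !is.null(cache[[key]])) cache[[key]] else {
    graph_seed <- derive_seed(config$seed, "graph")
    mods <- switch(config$scenario,
      scenario1 = ,
      scenario3 = {
        c(list(build_module_graph(config$genes_per_module, "scenario1",
                                  seed = graph_seed)),
          lapply(seq_len(config$n_modules - 1), function(k)
            build_module_graph(config$genes_per_module, "neutral",
                               seed = derive_seed(config$seed, "graph", k))))
      },
      scenario2 = {
        # four causal modules (two positive, two negative), rest neutral
        lapply(seq_len(config$n_modules), function(k) {
          if (k <= 4) {
            build_module_graph(config$genes_per_module, "scenario2_module",
                               seed = derive_seed(config$seed, "graph", k),
                               negate = k > 2)
          } else {
            build_module_graph(config$genes_per_module, "neutral",
                               seed = derive_seed(config$seed, "graph", k))
          }
        })
      })
    graph <- assemble_modules(mods)
    cov <- graph_to_covariance(graph, edge_weight = config$edge_weight)
    list(graph = graph, cov = cov, chol = chol(cov$sigma_mat))
  }
  if (!is.null(cache)) cache[[key]] <- built
  graph <- built$graph

  mu <- make_mean_vector(graph, config$delta)
  latent <- sample_latent(mu, built$cov, config$n_cases, config$n_controls,
                          seed = derive_seed(config$seed, "latent"),
                          chol_sigma = built$chol)
  p <- graph$n_nodes
  truth <- which(graph$labels != "neutral")
  if (config$scenario == "scenario3") {
    k <- gamma_gene_sizes(p, config$gamma_shape, config$gamma_scale,
                          config$min_sites,
                          seed = derive_seed(config$seed, "sizes"))
    w <- rep(0L, p)
    w[truth] <- as.integer(ceiling(config$causal_fraction * k[truth]))
    w[-truth] <- pmin(k[-truth], as.integer(ceiling(config$causal_fraction * k[-truth])))
  } else {
    k <- rep(as.integer(config$sites_per_gene), p)
    w <- rep(as.integer(config$omega), p)
  }
  ds <- emit_methylation(latent, w, config$sigma, k,
                         seed = derive_seed(config$seed, "emission"),
                         truth_genes = truth)
  ds$graph <- graph
  ds
}

#' Write / read a simulated dataset as plain-text tables
#'
#' The methylation matrix goes to a TSV with CpG-id header, the phenotype to
#' a two-column TSV (\code{sample_id}, \code{y}) and the causal-gene truth to
#' a one-column file.
#'
#' @param ds a \code{methylation_dataset}.
#' @param dir output directory (created if missing).
#' @return The directory path, invisibly.
#' @export
write_dataset_tsv <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(cbind(sample_id = seq_len(nrow(ds$x)), as.data.frame(ds$x)),
                     file.path(dir, "methylation.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(data.frame(sample_id = seq_len(nrow(ds$x)), y = ds$y),
                     file.path(dir, "phenotype.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(ds$annotation, file.path(dir, "annotation.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  writeLines(as.character(ds$truth), file.path(dir, "truth.txt"))
  invisible(dir)
}

#' @rdname write_dataset_tsv
#' @export
read_dataset_tsv <- function(dir) {
  xm <- utils::read.delim(file.path(dir, "methylation.tsv"), check.names = FALSE)
  x <- as.matrix(xm[, -1, drop = FALSE])
  ph <- utils::read.delim(file.path(dir, "phenotype.tsv"))
  ann <- utils::read.delim(file.path(dir, "annotation.tsv"))
  truth <- as.integer(readLines(file.path(dir, "truth.txt")))
  structure(list(x = x, annotation = ann, y = ph$y, truth = truth,
                 sites_per_gene = as.integer(table(factor(ann$gene_id,
                   levels = unique(ann$gene_id))))),
            class = "methylation_dataset")
}
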