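test_that("scenario-1 module graph has the stated causal structure", {
  g <- build_module_graph(100, "scenario1", seed = 5)
  expect_equal(sum(g$labels != "neutral"), 45)
  expect_equal(sum(g$labels == "centered"), 1)
  expect_equal(as.integer(table(g$labels)[paste0("g", 1:4)]), rep(11L, 4))
  expect_equal(sum(g$labels == "neutral"), 55)
  expect_lte(max(g$degrees), 9)
  # every causal gene has at least one link, so |mu_j| >= delta/3
  expect_true(all(g$degrees[g$labels != "neutral"] >= 1))
  # causal component is connected through the centered gene
  cs <- which(g$labels != "neutral")
  reach <- 1L # centered gene id
  repeat {
    nb <- unique(c(g$edges[g$edges[, 1] %in% reach, 2],
                   g$edges[g$edges[, 2] %in% reach, 1]))
    nb <- intersect(nb, cs)
    new <- union(reach, nb)
    if (length(new) == length(reach)) break
    reach <- new
  }
  expect_setequal(reach, cs)
  # neutral genes never link to causal genes
  causal_edge <- (g$edges[, 1] %in% cs) != (g$edges[, 2] %in% cs)
  expect_false(any(causal_edge))
})

test_that("scenario-2 module and error paths behave", {
  g <- build_module_graph(100, "scenario2_module", seed = 2)
  expect_equal(sum(g$labels != "neutral"), 12)
  expect_equal(sum(g$labels == "centered"), 1)
  g12 <- build_module_graph(12, "scenario2_module", seed = 2)
  expect_equal(sum(g12$labels != "neutral"), 12)
  expect_error(build_module_graph(40, "scenario1"), "invalid config")
  expect_error(build_module_graph(11, "scenario2_module"), "invalid config")
})

test_that("GGM covariance matches hand-derived 2x2 inverse and block structure", {
  # two nodes, one edge: precision [[1+r, -w], [-w, 1+r]] after degree scaling
  g2 <- list(n_nodes = 2L, edges = matrix(c(1L, 2L), 1))
  g2$degrees <- c(1L, 1L)
  w <- 0.6; r <- 0.05
  cm <- graph_to_covariance(g2, edge_weight = w, ridge = r)
  # oracle: invert the 2x2 by hand, corr = w / (1+r)
  expect_equal(cm$sigma_mat[1, 2], w / (1 + r), tolerance = 1e-10)

  # empty graph: identity after standardization
  g0 <- edgeless_graph(4); g0$degrees <- integer(4)
  cm0 <- graph_to_covariance(g0)
  expect_equal(cm0$sigma_mat, diag(4))

  # assembled modules: cross-module covariance exactly zero
  mods <- lapply(1:3, function(k) build_module_graph(20, "neutral", seed = k))
  gg <- assemble_modules(mods)
  cm3 <- graph_to_covariance(gg)
  expect_true(all(abs(cm3$sigma_mat[1:20, 21:60]) < 1e-12))

  # PD guard
  expect_error(graph_to_covariance(g2, edge_weight = 1.2), "shrink edge_weight")
})

test_that("precision sparsity pattern equals adjacency plus diagonal", {
  g <- build_module_graph(100, "scenario1", seed = 7)
  cm <- graph_to_covariance(g)
  prec <- as.matrix(cm$precision)
  adj <- matrix(FALSE, 100, 100)
  adj[g$edges] <- TRUE; adj <- adj | t(adj)
  off <- abs(prec) > 1e-8; diag(off) <- FALSE
  expect_identical(off, adj)
  ev <- eigen(prec, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), 0)
  expect_true(isSymmetric(as.matrix(cm$sigma_mat), tol = 1e-12))
})

test_that("mean vector follows the piecewise degree formula", {
  g <- build_module_graph(100, "scenario1", seed = 1)
  mu <- make_mean_vector(g, delta = 1.5)
  expect_equal(mu[g$labels == "centered"], 1.5)
  expect_equal(mu[g$labels == "neutral"], rep(0, 55))
  for (lab in paste0("g", 1:4)) {
    i <- which(g$labels == lab)
    sgn <- if (lab %in% c("g1", "g3")) 1 else -1
    expect_equal(mu[i], sgn * (1.5 / 3) * sqrt(g$degrees[i]))
  }
  causal <- g$labels != "neutral"
  expect_true(all(abs(mu[causal]) >= 0.5 - 1e-12))
  expect_true(all(abs(mu[causal]) <= 1.5 + 1e-12))
  # direct arithmetic spot check: a g2 gene with d_j = 4 would get -1.0
  g_fake <- g; g_fake$labels[3] <- "g2"; g_fake$degrees[3] <- 4L
  expect_equal(make_mean_vector(g_fake, 1.5)[3], -1.0)
})

test_that("latent sampling is reproducible and matches its mean structure", {
  g <- build_module_graph(100, "scenario1", seed = 3)
  cm <- graph_to_covariance(g)
  mu <- make_mean_vector(g, 1.5)
  l1 <- sample_latent(mu, cm, 50, 50, seed = 9)
  l2 <- sample_latent(mu, cm, 50, 50, seed = 9)
  expect_identical(l1$z, l2$z)
  expect_equal(l1$y, c(rep(1L, 50), rep(0L, 50)))
  expect_error(sample_latent(mu[1:10], cm, 5, 5), "dimension mismatch")

  # CLT check at large n: case column means within 4 * sqrt(Sigma_jj / n)
  n <- 5000
  lc <- sample_latent(mu, cm, n, 1, seed = 21)
  cm_means <- colMeans(lc$z[1:n, ])
  tol <- 4 * sqrt(diag(cm$sigma_mat) / n)
  expect_true(all(abs(cm_means - mu) < tol))

  # mu = 0: cases and controls exchangeable (same marginal moments)
  l0 <- sample_latent(numeric(100), cm, 2500, 2500, seed = 4)
  d <- colMeans(l0$z[l0$y == 1, ]) - colMeans(l0$z[l0$y == 0, ])
  expect_true(all(abs(d) < 4 * sqrt(2 * diag(cm$sigma_mat) / 2500)))
})

test_that("linked latent pairs are more correlated than unlinked pairs", {
  g <- build_module_graph(100, "scenario1", seed = 3)
  cm <- graph_to_covariance(g)
  l <- sample_latent(numeric(100), cm, 5000, 1, seed = 2)
  cc <- cor(l$z[1:5000, ])
  linked <- mean(abs(cc[g$edges]))
  set.seed(11)
  adj <- matrix(FALSE, 100, 100); adj[g$edges] <- TRUE; adj <- adj | t(adj)
  un <- which(!adj & upper.tri(adj), arr.ind = TRUE)
  un <- un[sample(nrow(un), 500), ]
  expect_gt(linked, mean(abs(cc[un])))
})

test_that("CpG emission matches the latent/noise site split", {
  g <- build_module_graph(50, "neutral", seed = 1)
  cm <- graph_to_covariance(g)
  lat <- sample_latent(rnorm(50), cm, 20, 20, seed = 5)

  # noiseless limit: every causal column equals its gene's latent column
  ds0 <- emit_methylation(lat, omega = 3, sigma = 1e-12, sites_per_gene = 3,
                          seed = 1)
  expect_equal(dim(ds0$x), c(40, 150))
  expect_equal(unname(ds0$x[, 1:3]), cbind(lat$z[, 1], lat$z[, 1], lat$z[, 1]),
               tolerance = 1e-9)

  # noise columns are centered at the gene's pooled latent mean
  ds <- emit_methylation(lat, omega = 2, sigma = 1e-12, sites_per_gene = 4,
                         seed = 1)
  gene1_noise <- ds$x[, 3]
  expect_equal(unname(gene1_noise), rep(mean(lat$z[, 1]), 40), tolerance = 1e-9)

  expect_error(emit_methylation(lat, omega = 5, sigma = 1, sites_per_gene = 4),
               "omega exceeds")

  # causal site vs noise site of the same gene are uncorrelated at large n
  lat_big <- sample_latent(numeric(50), cm, 4000, 1, seed = 6)
  dsb <- emit_methylation(lat_big, omega = 2, sigma = 1, sites_per_gene = 3,
                          seed = 2)
  expect_lt(abs(cor(dsb$x[, 1], dsb$x[, 3])), 0.06)
})

test_that("scenario-1 defaults give the stated dataset dimensions", {
  ds <- simulate_methylation(sim_config(seed = 2))
  expect_equal(dim(ds$x), c(200, 10000))
  expect_equal(length(ds$truth), 45)
  expect_equal(length(unique(ds$annotation$gene_id)), 1000)
  expect_equal(sum(ds$y), 100)
  # determinism of the full pipeline
  ds2 <- simulate_methylation(sim_config(seed = 2))
  expect_identical(ds$x, ds2$x)
})

test_that("neutral CpG columns carry no case/control signal", {
  # scaled-down version of the n = 10,000 z-test invariant: one causal +
  # one neutral module, n = 2000, Bonferroni across neutral columns
  cfg <- sim_config(n_cases = 1000, n_controls = 1000, n_modules = 2,
                    omega = 8, sigma = 2, seed = 31)
  ds <- simulate_methylation(cfg)
  neutral_genes <- setdiff(seq_len(200), ds$truth)
  ncols <- which(ds$annotation$gene_id %in% neutral_genes)
  x1 <- ds$x[ds$y == 1, ncols]; x0 <- ds$x[ds$y == 0, ncols]
  z <- (colMeans(x1) - colMeans(x0)) /
    sqrt(apply(x1, 2, var) / nrow(x1) + apply(x0, 2, var) / nrow(x0))
  pv <- 2 * pnorm(-abs(z))
  expect_gte(mean(pv > 0.05 / length(ncols)), 0.95)
})

test_that("gamma gene sizes respect floor, fraction arithmetic, determinism", {
  k <- gamma_gene_sizes(500, shape = 2, scale = 5, min_sites = 1, seed = 3)
  expect_true(all(k >= 1))
  expect_identical(k, gamma_gene_sizes(500, 2, 5, 1, seed = 3))
  expect_equal(ceiling(0.40 * 10), 4)

  cfg <- sim_config(n_cases = 15, n_controls = 15, n_modules = 2,
                    scenario = "scenario3", seed = 4)
  ds <- simulate_methylation(cfg)
  expect_equal(ncol(ds$x), sum(ds$sites_per_gene))
  expect_equal(unname(ds$omega[ds$truth]),
               as.integer(ceiling(0.40 * ds$sites_per_gene[ds$truth])))
})

test_that("dataset TSV round-trip preserves the data", {
  ds <- simulate_methylation(sim_config(n_cases = 10, n_controls = 10,
                                        n_modules = 1, genes_per_module = 45,
                                        omega = 2, sites_per_gene = 3,
                                        seed = 8))
  dir <- withr::local_tempdir()
  write_dataset_tsv(ds, dir)
  back <- read_dataset_tsv(dir)
  expect_equal(unname(back$x), unname(ds$x), tolerance = 1e-10)
  expect_equal(back$y, ds$y)
  expect_equal(back$truth, ds$truth)

  write_graph_tsv(ds$graph, file.path(dir, "e.tsv"), file.path(dir, "n.tsv"))
  g2 <- read_graph_tsv(file.path(dir, "e.tsv"), file.path(dir, "n.tsv"))
  expect_equal(g2$edges, ds$graph$edges)
  expect_equal(g2$labels, ds$graph$labels)
})
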