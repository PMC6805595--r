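test_that("Laplacian matches the exact formula on hand-computable graphs", {
  # two nodes, one edge
  L2 <- as.matrix(build_laplacian(chain_graph(2)))
  expect_equal(L2, matrix(c(1, -1, -1, 1), 2), ignore_attr = TRUE)
  # path a-b-c: l_ab = -(1*2)^(-1/2)
  L3 <- as.matrix(build_laplacian(chain_graph(3)))
  expect_equal(L3[1, 2], -1 / sqrt(2))
  expect_equal(L3[2, 3], -1 / sqrt(2))
  expect_equal(diag(L3), rep(1, 3), ignore_attr = TRUE)
  # isolated node gets a zero diagonal
  g <- list(n_nodes = 3L, edges = matrix(c(1L, 2L), 1))
  Li <- as.matrix(build_laplacian(g))
  expect_equal(diag(Li), c(1, 1, 0), ignore_attr = TRUE)
  expect_error(build_laplacian(list(n_nodes = 2L,
                                    edges = matrix(c(1L, 5L), 1))),
               "unknown gene id")
})

test_that("Laplacian quadratic form equals the degree-scaled edge sum", {
  set.seed(3)
  for (rep in 1:5) {
    p <- 12
    ne <- sample(5:20, 1)
    e <- unique(t(apply(matrix(sample(p, 2 * ne, replace = TRUE), ncol = 2),
                        1, sort)))
    e <- e[e[, 1] != e[, 2], , drop = FALSE]
    storage.mode(e) <- "integer"
    g <- list(n_nodes = p, edges = e)
    L <- as.matrix(build_laplacian(g))
    d <- tabulate(e, p)
    beta <- rnorm(p)
    oracle <- sum((beta[e[, 1]] / sqrt(d[e[, 1]]) -
                   beta[e[, 2]] / sqrt(d[e[, 2]]))^2)
    expect_equal(drop(beta %*% L %*% beta), oracle, tolerance = 1e-8)
    ev <- eigen(L, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), -1e-10)
  }
})

test_that("sign estimation is directionally correct and equivariant", {
  tf <- toy_features(n = 120, p = 3, seed = 5, beta = c(2, 0, 0))
  s <- estimate_signs(tf$z, tf$y)
  expect_equal(s[1], 1L)
  zneg <- tf$z; zneg[, 2] <- -zneg[, 2]
  s2 <- estimate_signs(zneg, tf$y)
  expect_equal(s2[1], s[1])
  expect_equal(s2[2], -s[2])
  expect_equal(s2[3], s[3])
  # ridge branch when p >= n
  set.seed(8)
  zp <- matrix(rnorm(20 * 30), 20, 30)
  yp <- rbinom(20, 1, 0.5); yp[1:3] <- 1; yp[4:6] <- 0
  expect_length(estimate_signs(zp, yp), 30)
  expect_true(all(estimate_signs(zp, yp) %in% c(-1L, 1L)))
})

test_that("alpha = 1 path matches an independent lasso solver", {
  tf <- toy_features(n = 80, p = 5, seed = 11)
  L <- build_laplacian(chain_graph(5))
  fit <- fit_path(tf$z, tf$y, L, alpha = 1, n_lambda = 20,
                  lambda_min_ratio = 0.05, standardize = FALSE)
  gn <- glmnet::glmnet(tf$z, tf$y, family = "binomial", alpha = 1,
                       lambda = fit$lambda, standardize = FALSE,
                       thresh = 1e-12)
  expect_equal(as.matrix(gn$beta), fit$beta, tolerance = 1e-4,
               ignore_attr = TRUE)
  expect_equal(as.numeric(gn$a0), fit$b0, tolerance = 1e-4,
               ignore_attr = TRUE)
})

test_that("the null end of the path is the intercept-only model", {
  tf <- toy_features(n = 60, p = 4, seed = 2)
  L <- build_laplacian(chain_graph(4))
  fit <- fit_path(tf$z, tf$y, L, alpha = 0.5, n_lambda = 10)
  expect_equal(unname(fit$beta[, 1]), rep(0, 4))
  expect_equal(fit$b0[1], log(mean(tf$y) / (1 - mean(tf$y))),
               tolerance = 1e-6)
  # nonzero count weakly increases as lambda decreases (solver jitter <= 2)
  expect_true(all(diff(fit$nnz) >= -2))
})

test_that("returned solutions are local minima with small KKT residuals", {
  tf <- toy_features(n = 50, p = 3, seed = 13, beta = c(1.5, -1, 0.5))
  L <- build_laplacian(chain_graph(3))
  signs <- estimate_signs(tf$z, tf$y)
  alpha <- 0.5
  fit <- fit_path(tf$z, tf$y, L, signs, alpha = alpha, n_lambda = 8,
                  lambda_min_ratio = 0.05, standardize = FALSE)
  S <- diag(as.numeric(signs))
  M <- S %*% as.matrix(L) %*% S
  z <- tf$z
  for (l in c(3, 6, 8)) {
    lam <- fit$lambda[l]; b0 <- fit$b0[l]; beta <- fit$beta[, l]
    obj0 <- net_objective_r(z, tf$y, M, b0, beta, lam, alpha)
    # brute-force local optimality: random perturbations never improve
    set.seed(100 + l)
    for (i in 1:1000) {
      u <- rnorm(3); u <- u / sqrt(sum(u^2))
      expect_gte(net_objective_r(z, tf$y, M, b0, beta + 0.01 * u, lam, alpha),
                 obj0 - 1e-10)
    }
    # KKT subgradient residual
    pr <- 1 / (1 + exp(-(b0 + drop(z %*% beta))))
    grad <- -drop(crossprod(z, tf$y - pr)) / nrow(z) +
      2 * lam * (1 - alpha) * drop(M %*% beta)
    for (u in 1:3) {
      if (beta[u] != 0) {
        expect_lt(abs(grad[u] + lam * alpha * sign(beta[u])), 1e-4)
      } else {
        expect_lte(abs(grad[u]), lam * alpha + 1e-4)
      }
    }
    expect_lt(abs(mean(tf$y - pr)), 1e-4) # intercept score
  }
})

test_that("identity penalty matrix reproduces an elastic net fit", {
  tf <- toy_features(n = 70, p = 4, seed = 17)
  Lid <- Matrix::Diagonal(4, 1)
  alpha <- 0.4; lam <- 0.05
  fit <- fit_path(tf$z, tf$y, Lid, alpha = alpha, lambda = c(0.3, lam),
                  standardize = FALSE)
  # map to glmnet parameterization: lam_g*ag = lam*alpha,
  # lam_g*(1-ag)/2 = lam*(1-alpha)
  lam_g <- lam * alpha + 2 * lam * (1 - alpha)
  a_g <- lam * alpha / lam_g
  gn <- glmnet::glmnet(tf$z, tf$y, family = "binomial", alpha = a_g,
                       lambda = c(lam_g * 4, lam_g), standardize = FALSE,
                       thresh = 1e-12)
  expect_equal(fit$beta[, 2], as.numeric(gn$beta[, 2]), tolerance = 1e-4,
               ignore_attr = TRUE)
})

test_that("flipping a feature sign and its s_u leaves the objective value unchanged", {
  tf <- toy_features(n = 60, p = 4, seed = 19)
  L <- build_laplacian(chain_graph(4))
  signs <- c(1L, 1L, 1L, 1L)
  f1 <- fit_path(tf$z, tf$y, L, signs, alpha = 0.3, n_lambda = 12,
                 standardize = FALSE)
  z2 <- tf$z; z2[, 2] <- -z2[, 2]
  signs2 <- c(1L, -1L, 1L, 1L)
  f2 <- fit_path(z2, tf$y, L, signs2, alpha = 0.3, n_lambda = 12,
                 standardize = FALSE)
  expect_equal(f1$objective, f2$objective, tolerance = 1e-6)
  expect_equal(f1$beta[2, ], -f2$beta[2, ], tolerance = 1e-5)
})

test_that("group lasso selects whole genes jointly", {
  set.seed(23)
  n <- 60
  ann <- data.frame(cpg_id = paste0("c", 1:12),
                    gene_id = rep(1:3, each = 4))
  x <- matrix(rnorm(n * 12), n, 12)
  eta <- rowSums(x[, 1:4]) * 0.8
  y <- rbinom(n, 1, plogis(eta))
  fit <- group_lasso_path(x, y, ann, n_lambda = 15, lambda_min_ratio = 0.05)
  # at lambda_max nothing is selected
  expect_equal(sum(fit$selected[, 1]), 0)
  # coefficients enter and leave jointly within a group
  for (l in seq_along(fit$lambda)) {
    for (g in 1:3) {
      cols <- (g - 1) * 4 + 1:4
      nz <- fit$beta[cols, l] != 0
      expect_true(all(nz) || all(!nz))
    }
  }
  # the signal group is selected before the noise groups along the path
  first_sel <- apply(fit$selected, 1, function(s) {
    w <- which(s > 0); if (length(w)) min(w) else Inf
  })
  expect_equal(which.min(first_sel), 1L)
  expect_error(group_lasso_path(x, y, ann[1:8, ]), "empty group")
})
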