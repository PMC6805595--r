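# Small fixtures shared across test files. Everything is generated in code;
# sizes are kept desk-scale (the full simulation design is exercised, scaled
# down only in Monte-Carlo effort).

# a tiny two-module world: one scenario-1 module (p = 200) + neutral module
tiny_config <- function(seed = 1L, omega = 8L, sigma = 2.0,
                        n_cases = 30L, n_controls = 30L, n_modules = 2L) {
  sim_config(n_cases = n_cases, n_controls = n_controls,
             n_modules = n_modules, genes_per_module = 100L,
             omega = omega, sigma = sigma, seed = seed)
}

tiny_dataset <- function(...) simulate_methylation(tiny_config(...))

# deterministic toy gene block: n x k with a case/control mean shift
toy_block <- function(n = 40, k = 5, shift = 0, seed = 1) {
  set.seed(seed)
  y <- rep(c(1, 0), each = n / 2)
  x <- matrix(rnorm(n * k), n, k)
  x[y == 1, ] <- x[y == 1, ] + shift
  list(x = x, y = y)
}

# tiny feature problem for solver tests
toy_features <- function(n = 50, p = 5, seed = 3, beta = NULL) {
  set.seed(seed)
  z <- matrix(rnorm(n * p), n, p)
  if (is.null(beta)) beta <- c(1.5, -1, numeric(p - 2))
  eta <- drop(z %*% beta)
  y <- rbinom(n, 1, 1 / (1 + exp(-eta)))
  list(z = z, y = y, beta = beta)
}

chain_graph <- function(p) {
  e <- cbind(seq_len(p - 1), 2:p)
  storage.mode(e) <- "integer"
  list(n_nodes = p, edges = e)
}

edgeless_graph <- function(p) list(n_nodes = p, edges = matrix(integer(0), ncol = 2))
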