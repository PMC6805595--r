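#' Experiment configuration
#'
#' Bundles simulator, reduction, solver, resampling and replication settings
#' for [run_experiment()] / [run_methods_battery()]. Serializable to JSON via
#' [write_experiment_config()].
#'
#' @param simulation a [sim_config()].
#' @param reduction_method one of \code{"PC"}, \code{"nPC"}, \code{"sPC"},
#'   \code{"PLS"}.
#' @param alpha_grid,n_lambda,lambda_min_ratio solver grid settings.
#' @param n_resamples resamples per replicate for selection probabilities.
#' @param replicates number of simulation replicates (reference design: 100).
#' @param top_k TPR cut-offs.
#' @param test_B permutation count for the comparator tests.
#' @param output_dir optional directory for result tables.
#' @return An \code{experiment_config} list.
#' @export
experiment_config <- function(simulation = sim_config(),
                              reduction_method = "nPC",
                              alpha_grid = c(0.1, 0.5, 0.9),
                              n_lambda = 50L, lambda_min_ratio = 0.01,
                              n_resamples = 100L, replicates = 100L,
                              top_k = seq(10, 100, by = 10),
                              test_B = 1000L, output_dir = NULL) {
  stopifnot(replicates >= 1)
  structure(list(simulation = simulation,
                 reduction_method = reduction_method,
                 alpha_grid = alpha_grid, n_lambda = as.integer(n_lambda),
                 lambda_min_ratio = lambda_min_ratio,
                 n_resamples = as.integer(n_resamples),
                 replicates = as.integer(replicates), top_k = top_k,
                 test_B = as.integer(test_B), output_dir = output_dir),
            class = "experiment_config")
}

#' Read / write an experiment configuration as JSON
#' @param config an \code{experiment_config}; \code{file} a path.
#' @return \code{read_experiment_config} returns an \code{experiment_config}.
#' @export
write_experiment_config <- function(config, file) {
  jsonlite::write_json(unclass_deep(config), file, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(file)
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}

#' @rdname write_experiment_config
#' @export
read_experiment_config <- function(file) {
  j <- jsonlite::read_json(file, simplifyVector = TRUE)
  simargs <- j$simulation[intersect(names(j$simulation),
                                    names(formals(sim_config)))]
  eargs <- j[intersect(names(j), names(formals(experiment_config)))]
  eargs$simulation <- do.call(sim_config, simargs)
  do.call(experiment_config, eargs)
}

net_method_sp <- function(ds, method, config, rep_seed) {
  feats <- reduce_all(ds, method = method, seed = derive_seed(rep_seed, "misc"))
  L <- build_laplacian(ds$graph)
  signs <- estimate_signs(feats$z, ds$y)
  selection_probability(feats, ds$y, L, signs,
                        alpha_grid = config$alpha_grid,
                        n_lambda = config$n_lambda,
                        lambda_min_ratio = config$lambda_min_ratio,
                        scheme = subsample_scheme(config$n_resamples,
                          seed = derive_seed(rep_seed, "resample")),
                        standardize = (method != "nPC"))
}

evaluate_method <- function(ds, method, config, rep_seed, battery_cache) {
  if (method %in% c("Net+PC", "Net+nPC", "Net+sPC", "Net+PLS")) {
    prof <- net_method_sp(ds, sub("^Net\\+", "", method), config, rep_seed)
    prof$ranking
  } else if (method == "group-lasso") {
    prof <- selection_probability_grouplasso(ds,
      n_lambda = config$n_lambda, lambda_min_ratio = config$lambda_min_ratio,
      scheme = subsample_scheme(config$n_resamples,
        seed = derive_seed(rep_seed, "resample")))
    prof$ranking
  } else {
    key <- c(`t-test` = "ttest", `global-test` = "gt", `sam-gs` = "samgs",
             hotelling = "ht")[[method]]
    if (is.null(battery_cache$res)) {
      battery_cache$res <- gene_test_battery(ds, B = config$test_B,
        seed = derive_seed(rep_seed, "permutation"))
    }
    battery_cache$res$ranking[[key]]
  }
}

#' Run one full simulate-reduce-regularize-rank experiment
#'
#' For each replicate: generate a dataset, reduce CpG blocks to gene
#' features, compute selection probabilities by half-sample resampling, rank
#' genes and record TPR at the configured cut-offs. Deterministic under the
#' master seed of \code{config$simulation}.
#'
#' @param config an [experiment_config()].
#' @param quiet suppress progress messages.
#' @return List with \code{per_replicate} (replicates x k matrix) and
#'   \code{tpr} (mean TPR per cut-off). Tables are written to
#'   \code{config$output_dir} when set.
#' @export
run_experiment <- function(config, quiet = TRUE) {
  res <- run_methods_battery(config,
                             methods = paste0("Net+", config$reduction_method),
                             quiet = quiet)
  out <- list(per_replicate = res$per_replicate[[1]], tpr = res$tpr[, 2])
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(res$tpr, file.path(config$output_dir, "tpr.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(cbind(replicate = seq_len(nrow(out$per_replicate)),
                             out$per_replicate),
                       file.path(config$output_dir, "tpr_replicates.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  out
}

#' Evaluate several methods on the same simulated replicates
#'
#' All methods see the identical datasets (shared replicate seeds), so the
#' resulting TPR curves are paired.
#'
#' @param config an [experiment_config()].
#' @param methods subset of \code{c("Net+PC", "Net+nPC", "Net+sPC",
#'   "Net+PLS", "group-lasso", "t-test", "global-test", "sam-gs",
#'   "hotelling")}.
#' @param quiet suppress per-replicate progress messages.
#' @return List with \code{tpr} (data frame: k column plus one mean-TPR
#'   column per method) and \code{per_replicate} (named list of replicate x k
#'   matrices).
#' @export
run_methods_battery <- function(config, methods = c("Net+nPC", "group-lasso"),
                                quiet = TRUE) {
  known <- c("Net+PC", "Net+nPC", "Net+sPC", "Net+PLS", "group-lasso",
             "t-test", "global-test", "sam-gs", "hotelling")
  bad <- setdiff(methods, known)
  if (length(bad)) stop("unknown method name(s): ", paste(bad, collapse = ", "))
  ks <- config$top_k
  per <- lapply(methods, function(m) matrix(NA_real_, config$replicates,
                                            length(ks),
                                            dimnames = list(NULL, paste0("k", ks))))
  names(per) <- methods
  cache <- new.env(parent = emptyenv())
  for (r in seq_len(config$replicates)) {
    rep_seed <- derive_seed(config$simulation$seed, "replicate", r)
    sim <- config$simulation
    sim$seed <- rep_seed
    t0 <- Sys.time()
    ds <- simulate_methylation(sim, cache = cache)
    battery_cache <- new.env(parent = emptyenv())
    for (m in methods) {
      ranking <- evaluate_method(ds, m, config, rep_seed, battery_cache)
      per[[m]][r, ] <- rank_and_tpr(ranking, ds$truth, ks)
    }
    if (!quiet) {
      message(sprintf("replicate %d/%d done in %.1fs", r, config$replicates,
                      as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    }
  }
  tpr <- data.frame(k = ks)
  for (m in methods) tpr[[m]] <- colMeans(per[[m]])
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(tpr, file.path(config$output_dir, "tpr_battery.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  list(tpr = tpr, per_replicate = per)
}
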