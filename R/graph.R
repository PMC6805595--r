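#' Build one simulation network module
#'
#' Constructs the undirected gene graph used by the simulator. Under
#' \code{scenario = "scenario1"} the module contains \code{genes_per_module}
#' genes of which 45 are outcome-related: one centered hub gene plus four
#' groups (\code{g1}..\code{g4}) of 11 genes each. The centered gene links to
#' one "head" gene per group; each group of 11 is a small hub (six children)
#' followed by a four-gene chain, so that node degrees stay between 1 and 9.
#' The remaining genes are neutral and form sparse random links (degrees 1-3)
#' among themselves only. Under \code{scenario = "scenario2_module"} the
#' module carries 12 outcome-related genes: one centered gene plus a single
#' linked group of 11.
#'
#' @param genes_per_module number of genes in the module (>= 45 for
#'   scenario 1, >= 12 for a scenario-2 causal module).
#' @param scenario one of \code{"scenario1"}, \code{"scenario2_module"},
#'   \code{"neutral"} (no outcome-related genes; used for the modules of
#'   scenario 2 that carry no signal).
#' @param seed integer seed controlling the random neutral-gene links.
#' @param negate logical; if \code{TRUE} the single causal group of a
#'   scenario-2 module is labelled \code{g2} (negative effect) instead of
#'   \code{g1}.
#' @return An object of class \code{module_graph}: a list with
#'   \code{n_nodes}, integer 2-column matrix \code{edges} (1-based node
#'   pairs, u < v), \code{labels} (\code{centered}, \code{centered_neg},
#'   \code{g1}..\code{g4}, \code{neutral}) and \code{degrees}.
#' @export
build_module_graph <- function(genes_per_module, scenario = c("scenario1", "scenario2_module", "neutral"),
                               seed = 1L, negate = FALSE) {
  scenario <- match.arg(scenario)
  min_needed <- switch(scenario, scenario1 = 45L, scenario2_module = 12L, neutral = 1L)
  if (genes_per_module < min_needed) {
    stop("invalid config: genes_per_module = ", genes_per_module,
         " is too small for ", scenario, " (needs >= ", min_needed, ")")
  }
  n <- as.integer(genes_per_module)
  labels <- rep("neutral", n)
  edges <- matrix(integer(0), ncol = 2)

  # One group of 11: node layout c(head, children x6, chain x4).
  # head--child (x6), child6--chain1--chain2--chain3--chain4.
  group_edges <- function(ids) {
    head <- ids[1]; ch <- ids[2:7]; tail <- ids[8:11]
    rbind(cbind(head, ch),
          cbind(c(ch[6], tail[1], tail[2], tail[3]), tail))
  }

  if (scenario == "scenario1") {
    centered <- 1L
    labels[centered] <- "centered"
    groups <- split(2:45, rep(1:4, each = 11))
    for (g in 1:4) {
      ids <- groups[[g]]
      labels[ids] <- paste0("g", g)
      edges <- rbind(edges, cbind(centered, ids[1]), group_edges(ids))
    }
    neutral_ids <- if (n > 45) 46:n else integer(0)
  } else if (scenario == "scenario2_module") {
    centered <- 1L
    labels[centered] <- if (negate) "centered_neg" else "centered"
    ids <- 2:12
    labels[ids] <- if (negate) "g2" else "g1"
    edges <- rbind(edges, cbind(centered, ids[1]), group_edges(ids))
    neutral_ids <- if (n > 12) 13:n else integer(0)
  } else {
    neutral_ids <- seq_len(n)
  }

  # sparse random links among neutral genes, degrees kept in 1..3
  if (length(neutral_ids) >= 2) {
    old <- local_seed(seed)
    on.exit(restore_seed(old), add = TRUE)
    deg <- integer(n)
    ord <- sample(neutral_ids)
    for (i in seq_along(ord)[-1]) {
      cand <- ord[seq_len(i - 1)]
      cand <- cand[deg[cand] < 3L]
      if (length(cand) == 0) next
      v <- if (length(cand) == 1) cand else sample(cand, 1)
      edges <- rbind(edges, cbind(min(ord[i], v), max(ord[i], v)))
      deg[ord[i]] <- deg[ord[i]] + 1L
      deg[v] <- deg[v] + 1L
    }
  }

  edges <- unique(edges[order(edges[, 1], edges[, 2]), , drop = FALSE])
  dimnames(edges) <- NULL
  storage.mode(edges) <- "integer"
  g <- structure(list(n_nodes = n, edges = edges, labels = labels,
                      degrees = graph_degrees(n, edges)),
                 class = "module_graph")
  validate_module_graph(g)
  g
}

graph_degrees <- function(n, edges) {
  tabulate(c(edges[, 1], edges[, 2]), nbins = n)
}

validate_module_graph <- function(g) {
  if (any(g$edges[, 1] == g$edges[, 2])) stop("self-loop in module graph")
  if (anyDuplicated(g$edges)) stop("duplicate edge in module graph")
  if (max(g$degrees) > 9L) stop("module graph degree exceeds 9")
  invisible(g)
}

#' Assemble disjoint network modules into one gene graph
#'
#' Stacks modules block-wise (no inter-module edges), offsetting node ids.
#'
#' @param modules list of \code{module_graph} objects.
#' @return A \code{module_graph} over the union of nodes, with an extra
#'   \code{module} integer vector recording each gene's module.
#' @export
assemble_modules <- function(modules) {
  offset <- 0L
  edges <- list(); labels <- character(0); module <- integer(0)
  for (k in seq_along(modules)) {
    m <- modules[[k]]
    edges[[k]] <- m$edges + offset
    labels <- c(labels, m$labels)
    module <- c(module, rep(k, m$n_nodes))
    offset <- offset + m$n_nodes
  }
  edges <- do.call(rbind, edges)
  storage.mode(edges) <- "integer"
  structure(list(n_nodes = offset, edges = edges, labels = labels,
                 module = module, degrees = graph_degrees(offset, edges)),
            class = "module_graph")
}

#' Read / write a graph as a two-column edge-list TSV
#'
#' @param g a \code{module_graph}.
#' @param edge_file path of the edge list TSV (columns \code{gene_u},
#'   \code{gene_v}).
#' @param node_file optional path of a node attribute TSV (columns
#'   \code{gene}, \code{label}, \code{module}).
#' @return \code{write_graph_tsv} returns \code{edge_file} invisibly;
#'   \code{read_graph_tsv} returns a \code{module_graph}.
#' @export
write_graph_tsv <- function(g, edge_file, node_file = NULL) {
  utils::write.table(data.frame(gene_u = g$edges[, 1], gene_v = g$edges[, 2]),
                     edge_file, sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(node_file)) {
    utils::write.table(data.frame(gene = seq_len(g$n_nodes), label = g$labels,
                                  module = if (is.null(g$module)) 1L else g$module),
                       node_file, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(edge_file)
}

#' @rdname write_graph_tsv
#' @param n_nodes node count when reading without a node file.
#' @export
read_graph_tsv <- function(edge_file, node_file = NULL, n_nodes = NULL) {
  e <- utils::read.delim(edge_file)
  edges <- as.matrix(e[, 1:2]); dimnames(edges) <- NULL
  storage.mode(edges) <- "integer"
  if (!is.null(node_file)) {
    nd <- utils::read.delim(node_file)
    n <- nrow(nd); labels <- as.character(nd$label); module <- nd$module
  } else {
    n <- if (is.null(n_nodes)) max(edges) else as.integer(n_nodes)
    labels <- rep("neutral", n); module <- rep(1L, n)
  }
  structure(list(n_nodes = n, edges = edges, labels = labels, module = module,
                 degrees = graph_degrees(n, edges)),
            class = "module_graph")
}
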