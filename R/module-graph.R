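#' Connectivity score between two modules
#'
#' Module-to-module edge weight in `[0, 1]`. Default: absolute Pearson
#' correlation of the two module eigengenes. Alternative
#' (`method = "adjacency"`): mean gene-level adjacency between the two gene
#' sets. Symmetric in its arguments. Self-loops are excluded at the graph
#' level: [build_module_graph()] never pairs a module with itself, and the
#' adjacency method rejects identical gene sets.
#'
#' @param q1,q2 Either eigengene vectors (default method) or gene-ID vectors
#'   (`method = "adjacency"`).
#' @param method `"eigengene"` or `"adjacency"`.
#' @param adjacency Gene-level adjacency matrix (adjacency method only).
#' @return Connectivity score in `[0, 1]`.
#' @export
connectivity_score <- function(q1, q2, method = c("eigengene", "adjacency"),
                               adjacency = NULL) {
  method <- match.arg(method)
  if (method == "eigengene") {
    abs(cor(q1, q2))
  } else {
    if (is.null(adjacency)) {
      mf_abort("adjacency matrix required for method = 'adjacency'",
               "modflex_config_error")
    }
    if (setequal(q1, q2)) {
      mf_abort("identical modules: self-loops are not allowed",
               "modflex_config_error")
    }
    mean(adjacency[q1, q2, drop = FALSE])
  }
}

#' Connectivity-score matrix over modules
#'
#' @param eigengenes Tibble from [module_eigengenes()] (`sample_id` plus one
#'   column per module) or a numeric matrix with module columns.
#' @param method,adjacency,partition See [connectivity_score()];
#'   `partition` supplies gene sets for the adjacency method.
#' @return Symmetric matrix of scores with `NA` diagonal.
#' @export
cs_matrix <- function(eigengenes, method = c("eigengene", "adjacency"),
                      adjacency = NULL, partition = NULL) {
  method <- match.arg(method)
  if (method == "eigengene") {
    me <- if (is.data.frame(eigengenes)) {
      as.matrix(eigengenes[, setdiff(names(eigengenes), "sample_id"),
                           drop = FALSE])
    } else {
      eigengenes
    }
    cs <- abs(cor(me))
  } else {
    assignment <- if (inherits(partition, "module_partition")) {
      partition$assignment
    } else {
      partition
    }
    labels <- setdiff(unique(assignment$module), "unassigned")
    labels <- labels[order(as.integer(sub("^M", "", labels)))]
    sets <- lapply(labels, function(m) {
      assignment$gene_id[assignment$module == m]
    })
    n <- length(labels)
    cs <- matrix(NA_real_, n, n, dimnames = list(labels, labels))
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i != j) cs[i, j] <- mean(adjacency[sets[[i]], sets[[j]]])
      }
    }
  }
  diag(cs) <- NA_real_
  cs
}

#' Build the module-level network
#'
#' Nodes are modules (typically the DEMs), edges are module pairs whose
#' connectivity score reaches the threshold. Node sizes carry the gene
#' counts.
#'
#' @param modules Character vector of module labels to include as nodes.
#' @param cs Connectivity-score matrix covering those labels.
#' @param threshold Minimum score for an edge (default 0.3).
#' @param sizes Optional named vector or tibble (`module`, `n_genes`) of
#'   module gene counts.
#' @return A `module_graph`: `graph` (igraph), `nodes`, `edges` tibbles,
#'   `threshold`.
#' @export
build_module_graph <- function(modules, cs, threshold = 0.3, sizes = NULL) {
  if (length(modules) == 0) {
    mf_abort("empty module list", "modflex_config_error")
  }
  if (threshold < 0 || threshold > 1) {
    mf_abort("threshold must lie in [0, 1]", "modflex_config_error")
  }
  cs <- cs[modules, modules, drop = FALSE]
  pairs <- which(upper.tri(cs), arr.ind = TRUE)
  edges <- tibble(
    module_1 = modules[pairs[, 1]],
    module_2 = modules[pairs[, 2]],
    cs = cs[pairs]
  ) |>
    dplyr::filter(!is.na(.data$cs), .data$cs >= threshold)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = modules))
  node_sizes <- if (is.data.frame(sizes)) {
    setNames(sizes$n_genes, sizes$module)[modules]
  } else if (!is.null(sizes)) {
    sizes[modules]
  } else {
    rep(NA_integer_, length(modules))
  }
  structure(
    list(
      graph = g,
      nodes = tibble(module = modules, n_genes = unname(node_sizes)),
      edges = edges,
      threshold = threshold
    ),
    class = "module_graph"
  )
}

#' @export
print.module_graph <- function(x, ...) {
  cat(sprintf("<module_graph> %d nodes, %d edges (cs >= %g)\n",
              nrow(x$nodes), nrow(x$edges), x$threshold))
  invisible(x)
}

#' Global topology of a simple undirected graph
#'
#' Density, characteristic path length (mean shortest-path length over
#' reachable unordered pairs; unreachable pairs are excluded with a
#' message), mean local clustering coefficient (nodes with degree < 2
#' contribute 0), and the small-world coefficient
#' `sigma = (C / C_rand) / (L / L_rand)` against `n_random` seeded
#' Erdos-Renyi graphs with matched node and edge counts.
#'
#' @param g A `module_graph`, an igraph, or a symmetric binary adjacency
#'   matrix.
#' @param n_random Random graphs for the small-world baseline (>= 20 used by
#'   default).
#' @param seed Seed for the random baseline.
#' @return One-row tibble: `n_nodes`, `n_edges`, `density`,
#'   `characteristic_path_length`, `clustering_coefficient`,
#'   `small_world_sigma`.
#' @export
topology_features <- function(g, n_random = 20, seed = 1) {
  g <- as_simple_graph(g)
  n <- igraph::vcount(g)
  if (n < 2) {
    mf_abort("topology features need at least 2 nodes",
             "modflex_degenerate_error")
  }
  m <- igraph::ecount(g)
  dens <- m / (n * (n - 1) / 2)
  comp <- igraph::components(g)
  if (comp$no > 1) {
    sz <- comp$csize
    unreachable <- (sum(sz)^2 - sum(sz^2)) / 2
    inform(sprintf("graph is disconnected: %g unreachable pair(s) excluded from the path length",
                   unreachable))
  }
  cpl <- if (m == 0) NA_real_ else igraph::mean_distance(g, directed = FALSE,
                                                         unconnected = TRUE)
  local_c <- igraph::transitivity(g, type = "localundirected",
                                  isolates = "zero")
  local_c[igraph::degree(g) < 2] <- 0
  cc <- mean(local_c)

  sigma <- NA_real_
  if (m > 0 && !is.na(cpl)) {
    rand <- withr::with_seed(seed, {
      purrr::map(seq_len(n_random), function(i) {
        rg <- igraph::sample_gnm(n, m)
        rc <- igraph::transitivity(rg, type = "localundirected",
                                   isolates = "zero")
        rc[igraph::degree(rg) < 2] <- 0
        c(C = mean(rc),
          L = igraph::mean_distance(rg, directed = FALSE, unconnected = TRUE))
      })
    })
    c_rand <- mean(purrr::map_dbl(rand, "C"))
    l_rand <- mean(purrr::map_dbl(rand, "L"))
    if (c_rand > 0 && l_rand > 0) {
      sigma <- (cc / c_rand) / (cpl / l_rand)
    }
  }

  tibble(
    n_nodes = n,
    n_edges = m,
    density = dens,
    characteristic_path_length = cpl,
    clustering_coefficient = cc,
    small_world_sigma = sigma
  )
}

# coerce module_graph / adjacency / igraph to a simple undirected igraph
as_simple_graph <- function(g) {
  if (inherits(g, "module_graph")) return(g$graph)
  if (igraph::is_igraph(g)) {
    return(igraph::simplify(igraph::as_undirected(g)))
  }
  if (is.matrix(g)) {
    return(igraph::graph_from_adjacency_matrix(g != 0, mode = "undirected",
                                               diag = FALSE))
  }
  mf_abort("cannot interpret input as a graph", "modflex_config_error")
}

#' Export a module graph to GraphML
#'
#' @param x A `module_graph`.
#' @param path Output `.graphml` path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(x, path) {
  g <- as_simple_graph(x)
  if (inherits(x, "module_graph") && any(!is.na(x$nodes$n_genes))) {
    igraph::V(g)$n_genes <- x$nodes$n_genes
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Plot a module graph
#'
#' Nodes scaled by gene count, edges by connectivity score.
#'
#' @param object A `module_graph`.
#' @param seed Layout seed.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.module_graph <- function(object, seed = 1, ...) {
  g <- object$graph
  coords <- withr::with_seed(seed, igraph::layout_with_fr(g))
  nodes <- object$nodes
  nodes$x <- coords[, 1]
  nodes$y <- coords[, 2]
  edges <- object$edges |>
    dplyr::left_join(nodes[, c("module", "x", "y")],
                     by = c(module_1 = "module")) |>
    dplyr::left_join(nodes[, c("module", "x", "y")],
                     by = c(module_2 = "module"), suffix = c("", "_end"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$x_end,
                   yend = .data$y_end, linewidth = .data$cs),
      colour = "grey60", alpha = 0.7
    ) +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, size = .data$n_genes),
      colour = "#2c3e50"
    ) +
    ggplot2::geom_text(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, label = .data$module),
      vjust = -1, size = 3
    ) +
    ggplot2::scale_linewidth(range = c(0.2, 1.5), name = "CS") +
    ggplot2::scale_size(range = c(2, 8), name = "genes") +
    ggplot2::theme_void()
}
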