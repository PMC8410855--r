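#' Weighted co-expression adjacency
#'
#' Soft-thresholded correlation adjacency: unsigned `a_ij = |cor(x_i,
#' x_j)|^power`, signed `a_ij = ((1 + cor) / 2)^power`. The diagonal is set
#' to 1 by convention.
#'
#' @param x Expression matrix (genes x samples).
#' @param power Soft threshold `beta >= 1`.
#' @param signed Use the signed transform.
#' @return Symmetric adjacency matrix with entries in `[0, 1]`.
#' @export
build_adjacency <- function(x, power = 6, signed = FALSE) {
  if (power < 1) mf_abort("power must be >= 1", "modflex_config_error")
  gene_sd <- apply(x, 1, sd)
  if (any(gene_sd == 0)) {
    mf_abort(sprintf("zero-variance gene(s): %s (filter before network construction)",
                     paste(head(rownames(x)[gene_sd == 0], 5), collapse = ", ")),
             "modflex_config_error")
  }
  r <- cor(t(x))
  a <- if (signed) ((1 + r) / 2)^power else abs(r)^power
  a <- pmin(pmax(a, 0), 1)
  diag(a) <- 1
  a
}

#' Topological overlap matrix
#'
#' Unsigned TOM: `tom_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `l_ij = sum_u a_iu a_uj` over `u != i, j` and `k_i` the connectivity
#' `sum_{u != i} a_iu`. The diagonal is 1; `1 - tom` is the clustering
#' dissimilarity.
#'
#' @param adjacency Symmetric adjacency matrix (diagonal 1).
#' @return TOM matrix, symmetric with entries in `[0, 1]`.
#' @export
compute_tom <- function(adjacency) {
  stopifnot(is.matrix(adjacency), nrow(adjacency) == ncol(adjacency))
  a0 <- adjacency
  diag(a0) <- 0
  l <- crossprod(a0)                 # u = i, j terms vanish with zero diagonal
  k <- rowSums(a0)
  kmin <- outer(k, k, pmin)
  tom <- (l + a0) / (kmin + 1 - a0)
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adjacency)
  tom
}

# scale-free topology fit: regress log10 p(k) on log10 k over >= 10 bins;
# R^2 counts only when the slope is negative
scale_free_fit <- function(k, n_bins = 10) {
  k <- k[k > 0]
  if (length(unique(k)) < 3) return(c(rsq = NA_real_, slope = NA_real_))
  bins <- cut(k, breaks = n_bins)
  p_k <- tapply(k, bins, length) / length(k)
  k_mean <- tapply(k, bins, mean)
  keep <- !is.na(p_k) & p_k > 0
  if (sum(keep) < 3) return(c(rsq = NA_real_, slope = NA_real_))
  fit <- lm(log10(p_k[keep]) ~ log10(k_mean[keep]))
  c(rsq = summary(fit)$r.squared, slope = unname(coef(fit)[2]))
}

#' Choose the soft-threshold power by scale-free fit
#'
#' For each candidate power the adjacency is built, the connectivity
#' distribution is binned, and `log10 p(k)` is regressed on `log10 k`; the
#' smallest power whose fit reaches `rsq_target` with a negative slope is
#' chosen. When no candidate reaches the target the power with the best
#' negative-slope fit is returned with a warning.
#'
#' @param x Expression matrix (genes x samples).
#' @param candidate_powers Powers to scan.
#' @param signed Signed adjacency transform.
#' @param rsq_target Scale-free fit target (default 0.85).
#' @param n_bins Connectivity histogram bins.
#' @return List: `power` (chosen), `reached_target` (logical), `fits`
#'   (tibble of `power`, `rsq`, `slope`, `mean_k`).
#' @export
pick_soft_threshold <- function(x, candidate_powers = c(1:10, seq(12, 20, 2)),
                                signed = FALSE, rsq_target = 0.85,
                                n_bins = 10) {
  if (ncol(x) < 8) {
    warn("fewer than 8 samples: correlation estimates are unstable")
  }
  gene_sd <- apply(x, 1, sd)
  if (all(gene_sd == 0)) {
    mf_abort("all genes are constant: no valid correlations",
             "modflex_config_error")
  }
  r <- cor(t(x[gene_sd > 0, , drop = FALSE]))
  base <- if (signed) (1 + r) / 2 else abs(r)
  fits <- purrr::map_dfr(candidate_powers, function(p) {
    a <- base^p
    diag(a) <- 0
    k <- rowSums(a)
    sf <- scale_free_fit(k, n_bins)
    tibble(power = p, rsq = sf["rsq"], slope = sf["slope"],
           mean_k = mean(k))
  })
  ok <- !is.na(fits$rsq) & !is.na(fits$slope) & fits$slope < 0
  hit <- ok & fits$rsq >= rsq_target
  if (any(hit)) {
    chosen <- fits$power[which(hit)[1]]
    reached <- TRUE
  } else {
    reached <- FALSE
    pool <- if (any(ok)) which(ok) else seq_len(nrow(fits))
    chosen <- fits$power[pool[which.max(fits$rsq[pool])]]
    warn(sprintf(
      "no candidate power reaches scale-free fit R^2 >= %.2f; using power %g (best R^2 = %.3f)",
      rsq_target, chosen, max(fits$rsq[pool], na.rm = TRUE)
    ))
  }
  list(power = chosen, reached_target = reached, fits = fits)
}

#' Module eigengene
#'
#' First principal component of the per-gene z-scored module submatrix,
#' scaled to unit variance and sign-oriented so that it correlates
#' non-negatively with the module's mean standardized expression.
#'
#' @param x Expression matrix (genes x samples).
#' @param genes Gene IDs of the module.
#' @return Named numeric vector (one value per sample), `sd = 1`.
#' @export
module_eigengene <- function(x, genes) {
  genes <- intersect(genes, rownames(x))
  if (length(genes) < 1) {
    mf_abort("no module genes present in the expression matrix",
             "modflex_config_error")
  }
  sub <- x[genes, , drop = FALSE]
  gene_sd <- apply(sub, 1, sd)
  if (any(gene_sd == 0)) {
    warn(sprintf("excluding %d zero-variance gene(s) from the eigengene",
                 sum(gene_sd == 0)))
    sub <- sub[gene_sd > 0, , drop = FALSE]
    if (nrow(sub) == 0) {
      mf_abort("all module genes have zero variance", "modflex_config_error")
    }
  }
  z <- t(scale(t(sub)))
  e <- svd(t(z), nu = 1, nv = 0)$u[, 1]
  e <- e / sd(e)
  avg <- colMeans(z)
  s <- suppressWarnings(cor(e, avg))
  if (!is.na(s) && s < 0) e <- -e
  setNames(e, colnames(x))
}

#' Eigengenes for every module of a partition
#'
#' @param x Expression matrix (genes x samples).
#' @param partition A `module_partition` or an assignment tibble with
#'   `gene_id` and `module` columns.
#' @return Tibble: `sample_id` plus one column per module (unassigned genes
#'   are skipped).
#' @export
module_eigengenes <- function(x, partition) {
  assignment <- if (inherits(partition, "module_partition")) {
    partition$assignment
  } else {
    partition
  }
  labels <- setdiff(unique(assignment$module), "unassigned")
  labels <- labels[order(as.integer(sub("^M", "", labels)))]
  me <- purrr::map(labels, function(m) {
    module_eigengene(x, assignment$gene_id[assignment$module == m])
  })
  dplyr::bind_cols(tibble(sample_id = colnames(x)),
                   as_tibble(setNames(me, labels)))
}

#' Detect co-expression modules from the TOM
#'
#' Average-linkage hierarchical clustering of the dissimilarity `1 - TOM`,
#' cut statically at `cut_height`; clusters smaller than `min_module_size`
#' become `"unassigned"`; modules whose eigengenes correlate at
#' `>= 1 - merge_height` are merged iteratively (closest pair first).
#' Surviving modules are labelled `M1, M2, ...` by decreasing size.
#'
#' @param x Expression matrix (genes x samples) used for eigengenes.
#' @param tom TOM from [compute_tom()] on the same genes.
#' @param min_module_size Minimum module size (>= 3).
#' @param cut_height Static tree-cut height on `1 - TOM` (default 0.99).
#' @param merge_height Eigengene-dissimilarity threshold below which modules
#'   merge (default 0.25, i.e. eigengene correlation 0.75).
#' @return A `module_partition`: `assignment` tibble (`gene_id`, `module`),
#'   `eigengenes` tibble, `dendrogram` (hclust), `params`.
#' @export
detect_modules <- function(x, tom, min_module_size = 30, cut_height = 0.99,
                           merge_height = 0.25) {
  if (min_module_size < 3) {
    mf_abort("min_module_size must be >= 3", "modflex_config_error")
  }
  stopifnot(identical(rownames(x), rownames(tom)))
  hc <- hclust(as.dist(1 - tom), method = "average")
  cl <- cutree(hc, h = cut_height)
  sizes <- table(cl)
  keep <- as.integer(names(sizes)[sizes >= min_module_size])
  groups <- lapply(keep, function(g) rownames(x)[cl == g])

  if (length(groups) > 1) {
    me <- lapply(groups, function(g) module_eigengene(x, g))
    repeat {
      cm <- suppressWarnings(cor(do.call(cbind, me)))
      diag(cm) <- -Inf
      top <- max(cm)
      if (is.na(top) || top < 1 - merge_height) break
      ij <- which(cm == top, arr.ind = TRUE)[1, ]
      i <- min(ij); j <- max(ij)
      groups[[i]] <- c(groups[[i]], groups[[j]])
      me[[i]] <- module_eigengene(x, groups[[i]])
      groups[[j]] <- NULL
      me[[j]] <- NULL
      if (length(groups) < 2) break
    }
  }

  groups <- groups[order(-lengths(groups))]
  assignment <- tibble(gene_id = rownames(x), module = "unassigned")
  for (q in seq_along(groups)) {
    assignment$module[assignment$gene_id %in% groups[[q]]] <- paste0("M", q)
  }
  eg <- if (length(groups)) {
    module_eigengenes(x, assignment)
  } else {
    tibble(sample_id = colnames(x))
  }
  structure(
    list(
      assignment = assignment,
      eigengenes = eg,
      dendrogram = hc,
      params = list(min_module_size = min_module_size,
                    cut_height = cut_height, merge_height = merge_height)
    ),
    class = "module_partition"
  )
}

#' @export
print.module_partition <- function(x, ...) {
  sizes <- module_sizes(x)
  cat(sprintf("<module_partition> %d module(s), %d/%d genes assigned\n",
              nrow(sizes), sum(sizes$n_genes),
              nrow(x$assignment)))
  if (nrow(sizes)) print(sizes, n = 10)
  invisible(x)
}

#' Module sizes of a partition
#'
#' @param partition A `module_partition`.
#' @return Tibble `module`, `n_genes`, sorted by decreasing size
#'   (`"unassigned"` excluded).
#' @export
module_sizes <- function(partition) {
  partition$assignment |>
    dplyr::filter(.data$module != "unassigned") |>
    dplyr::count(.data$module, name = "n_genes") |>
    dplyr::arrange(dplyr::desc(.data$n_genes), .data$module)
}

#' @export
tidy.module_partition <- function(x, ...) x$assignment

#' @export
glance.module_partition <- function(x, ...) {
  tibble(
    n_modules = nrow(module_sizes(x)),
    n_assigned = sum(x$assignment$module != "unassigned"),
    n_genes = nrow(x$assignment),
    min_module_size = x$params$min_module_size,
    cut_height = x$params$cut_height,
    merge_height = x$params$merge_height
  )
}

#' Build a full co-expression network
#'
#' Convenience wrapper: optional automatic power selection, adjacency, and
#' TOM in one object.
#'
#' @param x Expression matrix (genes x samples).
#' @param power Numeric soft threshold or `"auto"` for
#'   [pick_soft_threshold()].
#' @param signed Signed adjacency transform.
#' @param ... Passed to [pick_soft_threshold()] when `power = "auto"`.
#' @return A `coexpression_network`: `adjacency`, `tom`, `power`, `signed`,
#'   `gene_ids`.
#' @export
build_network <- function(x, power = 6, signed = FALSE, ...) {
  if (identical(power, "auto")) {
    power <- pick_soft_threshold(x, signed = signed, ...)$power
  }
  adj <- build_adjacency(x, power = power, signed = signed)
  structure(
    list(adjacency = adj, tom = compute_tom(adj), power = power,
         signed = signed, gene_ids = rownames(x)),
    class = "coexpression_network"
  )
}

#' @export
print.coexpression_network <- function(x, ...) {
  cat(sprintf("<coexpression_network> %d genes, %s power %g\n",
              length(x$gene_ids), if (x$signed) "signed" else "unsigned",
              x$power))
  invisible(x)
}
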