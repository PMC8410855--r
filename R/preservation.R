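#' Permutation Z statistics of module preservation
#'
#' Quantifies how well each reference module is preserved in a test network,
#' with a composite permutation Z statistic. For a module with gene set `S`
#' (size `m`) three observed statistics are computed: `mean_adjacency`, the
#' mean off-diagonal test adjacency inside `S` (density branch); `cor_kim`,
#' the correlation over genes in `S` between intramodular connectivity in
#' the reference and in the test network; and `cor_adj`, the correlation of
#' the within-`S` off-diagonal adjacency entries between the two networks
#' (connectivity branch). The null is built from `n_permutations` random
#' gene sets of size `m` drawn from the shared gene universe (sets may
#' overlap the module); each statistic is standardised as
#' `Z = (observed - mean_null) / sd_null`. Then `z_density = Z(mean_adjacency)`,
#' `z_connectivity = median(Z(cor_kim), Z(cor_adj))`, `z_summary` their
#' mean, and a module with `z_summary < 0` is a differentially expressed
#' module (DEM) — the drug-targeted-module call.
#'
#' @param ref_net,test_net `coexpression_network` objects or adjacency
#'   matrices over the same gene universe.
#' @param partition A `module_partition` or assignment tibble (`gene_id`,
#'   `module`); modules with fewer than 4 genes are skipped with a warning.
#' @param n_permutations Random sets per module (>= 50).
#' @param seed RNG seed for the permutation draws.
#' @return A tibble of class `module_preservation`: `module`, `module_size`,
#'   `mean_adjacency`, `cor_kim`, `cor_adj`, `z_density`, `z_connectivity`,
#'   `z_summary`, `is_dem`, `n_permutations`.
#' @export
module_preservation <- function(ref_net, test_net, partition,
                                n_permutations = 100, seed = 1) {
  ref <- if (inherits(ref_net, "coexpression_network")) ref_net$adjacency else ref_net
  test <- if (inherits(test_net, "coexpression_network")) test_net$adjacency else test_net
  if (!identical(rownames(ref), rownames(test))) {
    mf_abort("reference and test networks must share the same gene universe",
             "modflex_config_error")
  }
  if (n_permutations < 50) {
    mf_abort("n_permutations must be >= 50", "modflex_config_error")
  }
  assignment <- if (inherits(partition, "module_partition")) {
    partition$assignment
  } else {
    partition
  }
  labels <- setdiff(unique(assignment$module), "unassigned")
  labels <- labels[order(as.integer(sub("^M", "", labels)))]
  universe <- rownames(ref)
  n_univ <- length(universe)

  stats_for <- function(idx) {
    sub_r <- ref[idx, idx]
    sub_t <- test[idx, idx]
    off <- upper.tri(sub_t)
    k_r <- rowSums(sub_r) - diag(sub_r)
    k_t <- rowSums(sub_t) - diag(sub_t)
    c(
      mean_adj = mean(sub_t[off]),
      cor_kim = suppressWarnings(cor(k_r, k_t)),
      cor_adj = suppressWarnings(cor(sub_r[off], sub_t[off]))
    )
  }

  rows <- withr::with_seed(seed, {
    purrr::map(labels, function(lab) {
      genes <- assignment$gene_id[assignment$module == lab]
      m <- length(genes)
      if (m < 4) {
        warn(sprintf("module %s has %d genes (< 4): skipped", lab, m))
        return(NULL)
      }
      idx <- match(genes, universe)
      if (anyNA(idx)) {
        mf_abort(sprintf("module %s has genes outside the network universe", lab),
                 "modflex_config_error")
      }
      obs <- stats_for(idx)
      null <- vapply(seq_len(n_permutations), function(b) {
        stats_for(sample.int(n_univ, m))
      }, numeric(3))
      mu <- rowMeans(null, na.rm = TRUE)
      sdev <- apply(null, 1, sd, na.rm = TRUE)
      if (any(sdev == 0 | is.na(sdev)) || anyNA(obs)) {
        mf_abort(sprintf(
          "degenerate null for module %s (sd = 0 or undefined statistic); increase n_permutations or check the networks",
          lab), "modflex_degenerate_error")
      }
      z <- (obs - mu) / sdev
      z_density <- unname(z["mean_adj"])
      z_connectivity <- median(c(z["cor_kim"], z["cor_adj"]))
      z_summary <- mean(c(z_density, z_connectivity))
      tibble(
        module = lab, module_size = m,
        mean_adjacency = unname(obs["mean_adj"]),
        cor_kim = unname(obs["cor_kim"]),
        cor_adj = unname(obs["cor_adj"]),
        z_density = z_density,
        z_connectivity = z_connectivity,
        z_summary = z_summary,
        is_dem = z_summary < 0,
        n_permutations = n_permutations
      )
    })
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("module_preservation", class(out))
  out
}

#' Plot module preservation Z statistics
#'
#' Z_summary against module size; modules below the zero line are DEMs.
#'
#' @param object A `module_preservation` tibble.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.module_preservation <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$module_size,
                                       y = .data$z_summary)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$is_dem), size = 2.5) +
    ggplot2::geom_text(ggplot2::aes(label = .data$module),
                       vjust = -0.8, size = 3) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#c0392b",
                                            `FALSE` = "#2980b9"),
                                 name = "DEM (Z_summary < 0)") +
    ggplot2::labs(x = "module size (genes)", y = expression(Z[summary])) +
    ggplot2::theme_minimal()
}
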