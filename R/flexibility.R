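#' Instantiate a module's gene set in a stratum network
#'
#' Binary graph on the module's genes with an edge wherever the stratum
#' network's adjacency reaches `tau_g`. With `tau_g` anchored at the
#' reference stratum's minimum within-module adjacency (see
#' [flexibility_profiles()]) the reference instantiation is a complete
#' graph.
#'
#' @param genes Module gene IDs (>= 2 present in the network).
#' @param adjacency Stratum-level gene adjacency matrix.
#' @param tau_g Adjacency threshold in `[0, 1]`.
#' @return An igraph on `genes`.
#' @export
instantiate_module <- function(genes, adjacency, tau_g) {
  genes <- intersect(genes, rownames(adjacency))
  if (length(genes) < 2) {
    mf_abort("fewer than 2 module genes present in the stratum network",
             "modflex_config_error")
  }
  sub <- adjacency[genes, genes]
  bin <- sub >= tau_g
  diag(bin) <- FALSE
  igraph::graph_from_adjacency_matrix(bin, mode = "undirected", diag = FALSE)
}

#' Euclidean topological distance between two graphs
#'
#' Distance `D` between bounded topology feature vectors: density, mean
#' local clustering, characteristic path length scaled as `min(CPL / 2, 1)`
#' (1 when the graph has no path), and normalized mean degree
#' (`mean degree / (n - 1)`). `D = 0` for identical graphs; symmetric.
#'
#' @param features_a,features_b One-row tibbles from [topology_features()].
#' @return Non-negative distance.
#' @export
d_value <- function(features_a, features_b) {
  sum((feature_vector(features_a) - feature_vector(features_b))^2)^0.5
}

feature_vector <- function(f) {
  stopifnot(all(c("n_nodes", "n_edges", "density",
                  "characteristic_path_length",
                  "clustering_coefficient") %in% names(f)))
  cpl <- f$characteristic_path_length
  cpl_scaled <- if (is.na(cpl)) 1 else min(cpl / 2, 1)
  mean_deg <- 2 * f$n_edges / f$n_nodes
  c(
    density = f$density,
    clustering = f$clustering_coefficient,
    cpl = cpl_scaled,
    mean_degree = mean_deg / (f$n_nodes - 1)
  )
}

#' Modular flexibility of a gene set across response strata
#'
#' Bins treated subjects at the follow-up timepoint into `n_bins`
#' equal-width `delta_af` bins (bins with fewer than `min_bin_size`
#' subjects are dropped with a message), rebuilds the module's network
#' inside each bin, and measures each instantiation's topology and its
#' Euclidean distance `D` to the reference instantiation (the bin with the
#' highest mean `delta_af`). The default edge rule keeps gene pairs with
#' `adjacency >= 0.3^power`, i.e. `|r| >= 0.3`, the correlation threshold
#' the method uses elsewhere; `tau_g = "anchor"` instead sets the threshold
#' to the minimum within-module adjacency of the reference bin, which makes
#' the reference instantiation complete (density 1) but degenerates to
#' all-complete instantiations when bins hold few samples (the sampled
#' minimum adjacency approaches 0).
#'
#' @param x Expression matrix (genes x samples).
#' @param meta Sample metadata tibble.
#' @param genes Module (METM) gene IDs.
#' @param n_bins Number of equal-width response bins (default 6).
#' @param min_bin_size Minimum subjects per bin (default 4).
#' @param power,signed Adjacency parameters for the per-bin networks.
#' @param tau_g Adjacency threshold: a number, `NULL` for `0.3^power`, or
#'   `"anchor"` for the reference-bin minimum.
#' @param arm,timepoint Samples used for the per-bin networks.
#' @return Tibble of class `flexibility_profiles`: `stratum`,
#'   `mean_delta_af`, `n_subjects`, `n_nodes`, `n_edges`, `density`, `cpl`,
#'   `clustering`, `d_value`; `tau_g` as an attribute.
#' @export
flexibility_profiles <- function(x, meta, genes, n_bins = 6,
                                 min_bin_size = 4, power = 6, signed = FALSE,
                                 tau_g = NULL, arm = "DHI",
                                 timepoint = "Day30") {
  treated <- meta |>
    dplyr::filter(.data$arm == !!arm, .data$timepoint == !!timepoint)
  if (nrow(treated) < n_bins) {
    mf_abort("fewer treated subjects than response bins",
             "modflex_config_error")
  }
  treated$bin <- cut(treated$delta_af, breaks = n_bins)
  bins <- treated |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(mean_delta_af = mean(.data$delta_af),
                     n_subjects = dplyr::n(),
                     samples = list(.data$sample_id)) |>
    dplyr::filter(.data$n_subjects >= min_bin_size) |>
    dplyr::arrange(.data$mean_delta_af)
  if (nrow(bins) < nrow(dplyr::count(treated, .data$bin))) {
    inform(sprintf("dropping %d response bin(s) with fewer than %d subjects",
                   nrow(dplyr::count(treated, .data$bin)) - nrow(bins),
                   min_bin_size))
  }
  if (nrow(bins) < 3) {
    mf_abort("fewer than 3 usable response bins", "modflex_config_error")
  }

  adj <- purrr::map(bins$samples, function(s) {
    build_adjacency(x[genes, s, drop = FALSE], power = power, signed = signed)
  })
  ref_idx <- which.max(bins$mean_delta_af)
  if (is.null(tau_g)) {
    tau_g <- 0.3^power
  } else if (identical(tau_g, "anchor")) {
    ref_a <- adj[[ref_idx]]
    tau_g <- min(ref_a[upper.tri(ref_a)])
  }

  feats <- purrr::map(adj, function(a) {
    topology_features(instantiate_module(genes, a, tau_g))
  })
  ref_feat <- feats[[ref_idx]]
  out <- dplyr::bind_cols(
    bins[, c("mean_delta_af", "n_subjects")],
    dplyr::bind_rows(feats) |>
      dplyr::select(n_nodes = "n_nodes", n_edges = "n_edges",
                    density = "density",
                    cpl = "characteristic_path_length",
                    clustering = "clustering_coefficient")
  )
  out <- dplyr::bind_cols(tibble(stratum = as.character(bins$bin)), out)
  out$d_value <- purrr::map_dbl(feats, d_value, features_b = ref_feat)
  attr(out, "tau_g") <- tau_g
  class(out) <- c("flexibility_profiles", class(out))
  out
}

#' Regress flexibility on response
#'
#' Ordinary least squares of the topological distance `D` on the stratum
#' mean `delta_af`, and separately of the instantiated edge count on mean
#' `delta_af`. A negative `D` slope with a positive edge slope says the
#' module's wiring approaches the reference topology as the clinical effect
#' grows.
#'
#' @param profiles A `flexibility_profiles` tibble (>= 3 rows).
#' @return A `flexibility_fit`: list of `lm` fits (`d_value`, `n_edges`)
#'   plus the profiles; see [tidy()] and [glance()] methods.
#' @export
flexibility_regression <- function(profiles) {
  if (nrow(profiles) < 3) {
    mf_abort("at least 3 strata required", "modflex_config_error")
  }
  if (sd(profiles$mean_delta_af) == 0) {
    mf_abort("constant predictor: strata share one mean delta_af",
             "modflex_config_error")
  }
  fits <- list(
    d_value = lm(d_value ~ mean_delta_af, data = profiles),
    n_edges = lm(n_edges ~ mean_delta_af, data = profiles)
  )
  structure(list(fits = fits, profiles = profiles),
            class = "flexibility_fit")
}

#' @export
print.flexibility_fit <- function(x, ...) {
  g <- glance(x)
  cat("<flexibility_fit>\n")
  print(g)
  invisible(x)
}

#' @export
tidy.flexibility_fit <- function(x, ...) {
  purrr::imap_dfr(x$fits, function(fit, nm) {
    s <- summary(fit)$coefficients
    tibble(
      response = nm,
      term = rownames(s),
      estimate = s[, "Estimate"],
      std_error = s[, "Std. Error"],
      p_value = s[, "Pr(>|t|)"]
    )
  })
}

#' @export
glance.flexibility_fit <- function(x, ...) {
  purrr::imap_dfr(x$fits, function(fit, nm) {
    s <- summary(fit)
    tibble(
      response = nm,
      slope = unname(coef(fit)[2]),
      intercept = unname(coef(fit)[1]),
      r_squared = s$r.squared,
      p_value = s$coefficients[2, "Pr(>|t|)"],
      n_points = length(fit$residuals)
    )
  })
}

#' Plot flexibility profiles against response
#'
#' Topological distance `D` and edge count against stratum mean `delta_af`,
#' with least-squares lines.
#'
#' @param object A `flexibility_profiles` tibble.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.flexibility_profiles <- function(object, ...) {
  long <- object |>
    dplyr::select("mean_delta_af", "d_value", "n_edges") |>
    tidyr::pivot_longer(c("d_value", "n_edges"),
                        names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$mean_delta_af,
                                     y = .data$value)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "#c0392b", linewidth = 0.6) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = expression(Delta * "AF (stratum mean)"), y = NULL) +
    ggplot2::theme_minimal()
}
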