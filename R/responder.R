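#' Default response strata
#'
#' Best effect `delta_af >= 40`, mild effect `40 > delta_af >= 20`, no
#' effect `delta_af < 20`. Intervals are lower-inclusive, upper-exclusive.
#'
#' @return Tibble: `stratum`, `min`, `max`.
#' @export
default_strata <- function() {
  tibble(
    stratum = c("best", "mild", "none"),
    min = c(40, 20, -Inf),
    max = c(Inf, 40, 20)
  )
}

#' Stratify treated subjects by clinical response
#'
#' Assigns every treated subject to one response stratum by its `delta_af`
#' (change in the angina-frequency score from baseline). Strata are
#' half-open intervals `[min, max)`; custom rules must not overlap. Subjects
#' covered by no interval get `NA` with a warning.
#'
#' @param meta Sample metadata tibble (one `delta_af` per subject).
#' @param rules Stratum table as in [default_strata()].
#' @param arm Treated-arm label.
#' @return Tibble: `subject_id`, `delta_af`, `stratum`.
#' @export
stratify <- function(meta, rules = default_strata(), arm = "DHI") {
  stopifnot(all(c("stratum", "min", "max") %in% names(rules)))
  if (any(rules$min >= rules$max)) {
    mf_abort("each stratum needs min < max", "modflex_config_error")
  }
  ord <- order(rules$min)
  if (any(rules$max[ord][-nrow(rules)] > rules$min[ord][-1])) {
    mf_abort("stratum intervals overlap", "modflex_config_error")
  }
  subjects <- meta |>
    dplyr::filter(.data$arm == !!arm) |>
    dplyr::distinct(.data$subject_id, .data$delta_af)
  if (anyNA(subjects$delta_af)) {
    mf_abort("delta_af missing for one or more treated subjects",
             "modflex_config_error")
  }
  hit <- function(d) {
    w <- which(d >= rules$min & d < rules$max)
    if (length(w) == 1) rules$stratum[w] else NA_character_
  }
  subjects$stratum <- vapply(subjects$delta_af, hit, character(1))
  if (anyNA(subjects$stratum)) {
    warn(sprintf("%d subject(s) fall outside all strata",
                 sum(is.na(subjects$stratum))))
  }
  subjects
}

#' Correlate module eigengenes with the response
#'
#' Pearson correlation of each module eigengene (or eigengene change) with
#' `delta_af`, with a two-sided t-based p value. A module is significant
#' when `|r| >= r_threshold` and `p < p_threshold`.
#'
#' @param eigengenes Tibble (`sample_id`/`subject_id` first column, one
#'   column per module) or numeric matrix with module columns; rows aligned
#'   to `delta_af`.
#' @param delta_af Response per row of `eigengenes`.
#' @param r_threshold,p_threshold Significance rule (defaults 0.3 and 0.05).
#' @return Tibble of class `trait_correlation`: `module`, `r`, `p_value`,
#'   `is_significant`.
#' @export
module_trait_correlation <- function(eigengenes, delta_af,
                                     r_threshold = 0.3, p_threshold = 0.05) {
  me <- if (is.data.frame(eigengenes)) {
    as.matrix(eigengenes[, !vapply(eigengenes, is.character, logical(1)),
                         drop = FALSE])
  } else {
    as.matrix(eigengenes)
  }
  n <- nrow(me)
  if (length(delta_af) != n) {
    mf_abort("delta_af must align with the eigengene rows",
             "modflex_config_error")
  }
  if (n < 3) mf_abort("at least 3 subjects required", "modflex_config_error")
  const <- apply(me, 2, sd) == 0
  if (any(const)) {
    warn(sprintf("excluding constant eigengene(s): %s",
                 paste(colnames(me)[const], collapse = ", ")))
    me <- me[, !const, drop = FALSE]
  }
  r <- as.vector(cor(me, delta_af))
  out <- tibble(
    module = colnames(me),
    r = r,
    p_value = cor_p_value(r, n),
    is_significant = abs(r) >= r_threshold & cor_p_value(r, n) < p_threshold
  )
  class(out) <- c("trait_correlation", class(out))
  out
}

#' Select the most effective therapeutic module (METM)
#'
#' Among significant modules, returns the label with the largest `|r|`;
#' ties break by smaller p value, then by module label. Returns `NA` with a
#' warning when nothing is significant.
#'
#' @param correlations Tibble from [module_trait_correlation()].
#' @return Module label, or `NA_character_`.
#' @export
select_metm <- function(correlations) {
  if (is.null(correlations) || nrow(correlations) == 0) {
    warn("no module correlations supplied: no METM")
    return(NA_character_)
  }
  sig <- correlations |>
    dplyr::filter(.data$is_significant) |>
    dplyr::arrange(dplyr::desc(abs(.data$r)), .data$p_value, .data$module)
  if (nrow(sig) == 0) {
    warn("no significant module: no METM")
    return(NA_character_)
  }
  sig$module[1]
}

#' Gene significance and module membership
#'
#' For each gene: gene significance `GS = |cor(expression, delta_af)|` and
#' module membership `MM = cor(expression, eigengene)`. Zero-variance genes
#' are excluded with a warning.
#'
#' @param x Expression matrix (genes x samples) for one module (or any gene
#'   set).
#' @param eigengene Module eigengene aligned to `colnames(x)`.
#' @param delta_af Response aligned to `colnames(x)`.
#' @return Tibble: `gene_id`, `gene_significance`, `module_membership`.
#' @export
gene_stats <- function(x, eigengene, delta_af) {
  n <- ncol(x)
  stopifnot(length(eigengene) == n, length(delta_af) == n)
  gene_sd <- apply(x, 1, sd)
  if (any(gene_sd == 0)) {
    warn(sprintf("excluding %d zero-variance gene(s)", sum(gene_sd == 0)))
    x <- x[gene_sd > 0, , drop = FALSE]
  }
  tibble(
    gene_id = rownames(x),
    gene_significance = abs(as.vector(cor(t(x), delta_af))),
    module_membership = as.vector(cor(t(x), eigengene))
  )
}

#' Hub genes of a module
#'
#' Ranks module genes by intramodular connectivity (row sums of the
#' within-module adjacency) and returns the top `k`.
#'
#' @param adjacency Gene-level adjacency matrix.
#' @param genes Module gene IDs.
#' @param k Number of hub genes.
#' @return Tibble: `gene_id`, `k_im`, sorted by decreasing connectivity.
#' @export
hub_genes <- function(adjacency, genes, k = 5) {
  sub <- adjacency[genes, genes, drop = FALSE]
  kim <- rowSums(sub) - diag(sub)
  tibble(gene_id = genes, k_im = unname(kim)) |>
    dplyr::arrange(dplyr::desc(.data$k_im), .data$gene_id) |>
    head(k)
}

#' Plot module-response correlations
#'
#' @param object A `trait_correlation` tibble.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.trait_correlation <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = stats::reorder(.data$module, abs(.data$r)),
                               y = .data$r, fill = .data$is_significant)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = c(-0.3, 0.3), linetype = "dotted") +
    ggplot2::coord_flip() +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#27ae60",
                                          `FALSE` = "grey70"),
                               name = "|r| >= 0.3 & p < 0.05") +
    ggplot2::labs(x = NULL, y = "eigengene-response correlation (r)") +
    ggplot2::theme_minimal()
}
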