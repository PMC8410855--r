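#' Read a gene-by-sample expression matrix from TSV
#'
#' Expects a tab-separated file whose first column holds gene identifiers and
#' whose header names the samples. Values are log-scale expression. Genes
#' containing any missing value are dropped with a message; duplicated gene
#' or sample identifiers and non-numeric cells are errors naming the
#' offender.
#'
#' @param path Path to the TSV file.
#' @return Numeric matrix (genes x samples) with gene IDs as rownames.
#' @export
read_expression_matrix <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (nrow(raw) == 0 || ncol(raw) < 2) {
    mf_abort(sprintf("'%s' holds no expression values", path),
             "modflex_format_error")
  }
  gene_ids <- raw[[1]]
  if (anyDuplicated(gene_ids)) {
    dup <- unique(gene_ids[duplicated(gene_ids)])
    mf_abort(sprintf("duplicated gene ID(s): %s",
                     paste(head(dup, 5), collapse = ", ")),
             "modflex_format_error")
  }
  sample_ids <- names(raw)[-1]
  if (anyDuplicated(sample_ids)) {
    dup <- unique(sample_ids[duplicated(sample_ids)])
    mf_abort(sprintf("duplicated sample ID(s): %s",
                     paste(head(dup, 5), collapse = ", ")),
             "modflex_format_error")
  }
  vals <- as.matrix(raw[, -1])
  missing_before <- is.na(vals)
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals),
                                 dimnames = list(gene_ids, sample_ids)))
  bad <- is.na(num) & !missing_before
  if (any(bad)) {
    w <- which(bad, arr.ind = TRUE)[1, ]
    mf_abort(sprintf("non-numeric value '%s' at gene %s, sample %s",
                     vals[w[1], w[2]], gene_ids[w[1]], sample_ids[w[2]]),
             "modflex_format_error")
  }
  drop <- rowSums(is.na(num)) > 0
  if (any(drop)) {
    inform(sprintf("dropping %d gene(s) with missing values", sum(drop)))
    num <- num[!drop, , drop = FALSE]
  }
  if (nrow(num) == 0) {
    mf_abort("no genes left after dropping missing values",
             "modflex_format_error")
  }
  num
}

#' Write an expression matrix as TSV
#'
#' Inverse of [read_expression_matrix()]: gene IDs in the first column
#' (`gene_id`), samples in the header.
#'
#' @param x Numeric genes x samples matrix with dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path) {
  stopifnot(is.matrix(x), !is.null(rownames(x)), !is.null(colnames(x)))
  df <- dplyr::bind_cols(tibble(gene_id = rownames(x)), as_tibble(x))
  readr::write_tsv(df, path)
  invisible(path)
}

#' Read sample metadata from TSV
#'
#' Requires columns `sample_id`, `subject_id`, `arm`, `timepoint`,
#' `delta_af`. When an expression matrix is supplied, checks that every
#' sample has exactly one metadata row.
#'
#' @param path Path to the metadata TSV.
#' @param expression Optional expression matrix to validate against.
#' @return Tibble of sample metadata.
#' @export
read_sample_metadata <- function(path, expression = NULL) {
  meta <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("sample_id", "subject_id", "arm", "timepoint", "delta_af")
  missing <- setdiff(required, names(meta))
  if (length(missing)) {
    mf_abort(sprintf("metadata lacks column(s): %s",
                     paste(missing, collapse = ", ")),
             "modflex_format_error")
  }
  if (anyDuplicated(meta$sample_id)) {
    mf_abort("duplicated sample_id in metadata", "modflex_format_error")
  }
  if (!is.null(expression)) {
    absent <- setdiff(colnames(expression), meta$sample_id)
    if (length(absent)) {
      mf_abort(sprintf("expression sample(s) missing from metadata: %s",
                       paste(head(absent, 5), collapse = ", ")),
               "modflex_format_error")
    }
  }
  meta
}

#' Keep the most variable genes
#'
#' Retains the `top_n` genes by variance across samples; ties are broken by
#' gene ID (ascending), and the returned genes are ordered by decreasing
#' variance then gene ID.
#'
#' @param x Expression matrix (genes x samples).
#' @param top_n Number of genes to keep.
#' @return The filtered expression matrix.
#' @export
filter_variance <- function(x, top_n) {
  if (top_n <= 0) mf_abort("top_n must be positive", "modflex_config_error")
  if (top_n > nrow(x)) {
    mf_abort("top_n exceeds the number of genes", "modflex_config_error")
  }
  v <- apply(x, 1, var)
  ord <- order(-v, rownames(x))
  x[ord[seq_len(top_n)], , drop = FALSE]
}

#' Call differentially expressed genes
#'
#' Per-gene two-sided t-test on log2 values with a fold-change filter: a
#' gene is differentially expressed when `p < p_threshold` and its fold
#' change is at least `fc_threshold` (boundary inclusive; the fold change is
#' `2^|mean log2 difference|`, applied symmetrically to up- and
#' down-regulation). P values are unadjusted by default; set
#' `adjust_method = "BH"` for Benjamini-Hochberg.
#'
#' Two contrasts are supported: `"between_arms"` compares treated vs control
#' at one `timepoint` (Welch unequal-variance t-test); `"within_arm"`
#' compares the two timepoints inside one arm, paired by subject when both
#' timepoints exist for a subject.
#'
#' @param x Expression matrix (genes x samples), log2 scale.
#' @param meta Sample metadata tibble (see [read_sample_metadata()]).
#' @param contrast `"between_arms"` or `"within_arm"`.
#' @param timepoint Timepoint for the between-arm contrast.
#' @param arm Treated-arm label (between: numerator group; within: the arm
#'   analysed).
#' @param timepoints Baseline and follow-up labels for the within-arm
#'   contrast (difference is follow-up minus baseline).
#' @param p_threshold,fc_threshold Significance and fold-change cutoffs.
#' @param adjust_method Passed to [stats::p.adjust()]; `"none"` by default.
#' @return Tibble: `gene_id`, `log2_fold_change` (signed), `fold_change`
#'   (`>= 1`), `p_value`, `direction` (`up`/`down`), `is_deg`.
#' @export
call_degs <- function(x, meta,
                      contrast = c("between_arms", "within_arm"),
                      timepoint = "Day30",
                      arm = "DHI",
                      timepoints = c("Day0", "Day30"),
                      p_threshold = 0.05,
                      fc_threshold = 1.5,
                      adjust_method = "none") {
  contrast <- match.arg(contrast)
  meta <- meta[meta$sample_id %in% colnames(x), , drop = FALSE]

  if (contrast == "between_arms") {
    g1 <- meta$sample_id[meta$arm == arm & meta$timepoint == timepoint]
    g2 <- meta$sample_id[meta$arm != arm & meta$timepoint == timepoint]
    if (length(g1) < 2 || length(g2) < 2) {
      mf_abort("each side of the contrast needs at least 2 samples",
               "modflex_contrast_error")
    }
    m1 <- x[, g1, drop = FALSE]
    m2 <- x[, g2, drop = FALSE]
    res <- vapply(seq_len(nrow(x)), function(i) {
      ht <- tryCatch(t.test(m1[i, ], m2[i, ]), error = function(e) NULL)
      if (is.null(ht)) c(mean(m1[i, ]) - mean(m2[i, ]), NA_real_)
      else c(unname(diff(rev(ht$estimate))), ht$p.value)
    }, numeric(2))
  } else {
    sub <- meta[meta$arm == arm & meta$timepoint %in% timepoints, ,
                drop = FALSE]
    wide <- tidyr::pivot_wider(sub[, c("subject_id", "timepoint", "sample_id")],
                               names_from = "timepoint",
                               values_from = "sample_id")
    wide <- wide[stats::complete.cases(wide), , drop = FALSE]
    if (nrow(wide) < 2) {
      mf_abort("fewer than 2 subjects with both timepoints",
               "modflex_contrast_error")
    }
    d <- x[, wide[[timepoints[2]]], drop = FALSE] -
      x[, wide[[timepoints[1]]], drop = FALSE]
    if (all(apply(d, 1, sd) == 0)) {
      mf_abort(paste("degenerate paired contrast: all within-subject",
                     "differences are constant"),
               "modflex_contrast_error")
    }
    res <- vapply(seq_len(nrow(d)), function(i) {
      ht <- tryCatch(t.test(d[i, ]), error = function(e) NULL)
      if (is.null(ht)) c(mean(d[i, ]), NA_real_)
      else c(unname(ht$estimate), ht$p.value)
    }, numeric(2))
  }

  lfc <- res[1, ]
  p <- p.adjust(res[2, ], method = adjust_method)
  fc <- 2^abs(lfc)
  tibble(
    gene_id = rownames(x),
    log2_fold_change = lfc,
    fold_change = fc,
    p_value = p,
    direction = ifelse(lfc >= 0, "up", "down"),
    is_deg = !is.na(p) & p < p_threshold & fc >= fc_threshold
  )
}

#' Correlate each gene with a continuous trait
#'
#' Pearson correlation of every gene's expression with a trait (for example
#' `delta_af`), with a two-sided p value from the t transform on `n - 2`
#' degrees of freedom. Zero-variance genes (or a constant trait) yield `NA`
#' with a warning.
#'
#' @param x Expression matrix (genes x samples).
#' @param trait Numeric vector aligned to `colnames(x)`.
#' @return Tibble: `gene_id`, `r`, `p_value`.
#' @export
gene_trait_correlation <- function(x, trait) {
  n <- ncol(x)
  if (length(trait) != n) {
    mf_abort("trait length must match the number of samples",
             "modflex_config_error")
  }
  if (n < 3) mf_abort("at least 3 samples required", "modflex_config_error")
  if (sd(trait) == 0) {
    warn("trait has zero variance; all correlations are NA")
    return(tibble(gene_id = rownames(x), r = NA_real_, p_value = NA_real_))
  }
  gene_sd <- apply(x, 1, sd)
  if (any(gene_sd == 0)) {
    warn(sprintf("%d zero-variance gene(s): correlation reported as NA",
                 sum(gene_sd == 0)))
  }
  r <- suppressWarnings(as.vector(cor(t(x), trait)))
  r[gene_sd == 0] <- NA_real_
  tibble(gene_id = rownames(x), r = r, p_value = cor_p_value(r, n))
}

# two-sided p for a Pearson r on n - 2 df
cor_p_value <- function(r, n) {
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  2 * pt(abs(tstat), df = n - 2, lower.tail = FALSE)
}
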