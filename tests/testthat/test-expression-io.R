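make_tsv <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("a well-formed TSV reads to the expected matrix", {
  path <- make_tsv(c(
    "gene_id\ts1\ts2\ts3\ts4",
    "g1\t1\t2\t3\t4",
    "g2\t0.5\t0.5\t0.5\t0.5",
    "g3\t-1\t0\t1\t2"
  ))
  x <- read_expression_matrix(path)
  expect_equal(dim(x), c(3L, 4L))
  expect_identical(rownames(x), c("g1", "g2", "g3"))
  expect_equal(x["g3", "s4"], 2)
})

test_that("format errors name the offending row or column", {
  dup <- make_tsv(c("gene_id\ts1\ts2", "g1\t1\t2", "g1\t3\t4"))
  expect_error(read_expression_matrix(dup), "g1",
               class = "modflex_format_error")
  bad <- make_tsv(c("gene_id\ts1\ts2", "g1\t1\tx", "g2\t3\t4"))
  expect_error(read_expression_matrix(bad), "g1.*s2",
               class = "modflex_format_error")
  empty <- make_tsv("gene_id\ts1")
  expect_error(read_expression_matrix(empty),
               class = "modflex_format_error")
})

test_that("genes with missing values are dropped with a message", {
  path <- make_tsv(c("gene_id\ts1\ts2", "g1\t1\tNA", "g2\t3\t4"))
  expect_message(x <- read_expression_matrix(path), "1 gene")
  expect_identical(rownames(x), "g2")
})

test_that("write then read is the identity", {
  x <- matrix(rnorm(12), 3, 4,
              dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_expression_matrix(x, path)
  expect_equal(read_expression_matrix(path), x, tolerance = 1e-12)
})

test_that("variance filtering keeps the right genes with a stable tie rule", {
  x <- rbind(
    flat = rep(1, 5),
    b_tied = c(0, 1, 0, 1, 0),
    a_tied = c(1, 0, 1, 0, 1),
    wild = c(-5, 5, -5, 5, 0)
  )
  colnames(x) <- paste0("s", 1:5)
  expect_identical(rownames(filter_variance(x, 1)), "wild")
  # identical variance: lexicographically smaller gene id wins
  expect_identical(rownames(filter_variance(x, 2)), c("wild", "a_tied"))
  expect_identical(sort(rownames(filter_variance(x, 4))), sort(rownames(x)))
  expect_error(filter_variance(x, 0), class = "modflex_config_error")
})

deg_fixture <- function(lfc_per_gene, n_per_arm = 10, sd = 0.2, seed = 1) {
  # treated follow-up is the control follow-up block shifted by lfc, so the
  # between-arm mean difference equals lfc exactly
  withr::with_seed(seed, {
    n_genes <- length(lfc_per_gene)
    subj <- c(sprintf("T%02d", 1:n_per_arm), sprintf("C%02d", 1:n_per_arm))
    meta <- tidyr::expand_grid(
      tibble::tibble(subject_id = subj,
                     arm = rep(c("DHI", "control"), each = n_per_arm)),
      timepoint = c("Day0", "Day30")
    )
    meta$sample_id <- paste(meta$subject_id, meta$timepoint, sep = ".")
    meta$delta_af <- 0
    x <- matrix(rnorm(n_genes * nrow(meta), sd = sd), n_genes,
                dimnames = list(sprintf("g%02d", 1:n_genes), meta$sample_id))
    shift <- meta$arm == "DHI" & meta$timepoint == "Day30"
    ctrl <- meta$arm == "control" & meta$timepoint == "Day30"
    x[, shift] <- x[, ctrl] + lfc_per_gene
    list(x = x, meta = meta)
  })
}

test_that("the DEG rule is p < 0.05 with fold change at least 1.5, boundary inclusive", {
  fx <- deg_fixture(c(g_at = 0.585, g_below = log2(1.49), g_null = 0),
                    sd = 0.05)
  res <- call_degs(fx$x, fx$meta, "between_arms", timepoint = "Day30")
  at <- res[res$gene_id == "g01", ]   # 0.585 log2 ~ FC 1.50
  expect_gte(at$fold_change, 1.5)
  expect_lt(at$p_value, 0.05)
  expect_true(at$is_deg)
  expect_identical(at$direction, "up")
  below <- res[res$gene_id == "g02", ]  # FC 1.49, p tiny: still not a DEG
  expect_lt(below$p_value, 0.05)
  expect_false(below$is_deg)
  expect_false(res$is_deg[res$gene_id == "g03"])
})

test_that("identical groups give p near 1, fold change 1, no DEG call", {
  x <- matrix(rep(c(1, 2, 3, 4), each = 2), nrow = 2,
              dimnames = list(c("g1", "g2"), paste0("s", 1:4)))
  x[2, ] <- c(5, 1, 5, 1)
  meta <- tibble::tibble(
    sample_id = paste0("s", 1:4),
    subject_id = paste0("p", 1:4),
    arm = c("DHI", "DHI", "control", "control"),
    timepoint = "Day30", delta_af = 0
  )
  # arrange identical values across arms
  x[1, ] <- c(1, 2, 1, 2)
  res <- call_degs(x, meta, "between_arms", timepoint = "Day30")
  expect_equal(res$p_value[1], 1)
  expect_equal(res$fold_change[1], 1)
  expect_false(res$is_deg[1])
})

test_that("the paired within-arm contrast detects a per-subject shift", {
  fx <- deg_fixture(c(g1 = 0.8, g2 = 0), sd = 0.1)
  res <- call_degs(fx$x, fx$meta, "within_arm", arm = "DHI",
                   timepoints = c("Day0", "Day30"))
  expect_true(res$is_deg[res$gene_id == "g01"])
  expect_false(res$is_deg[res$gene_id == "g02"])
})

test_that("degenerate contrasts error", {
  fx <- deg_fixture(c(g1 = 0, g2 = 0))
  meta_one_arm <- fx$meta[fx$meta$arm == "DHI", ]
  expect_error(
    call_degs(fx$x[, meta_one_arm$sample_id, drop = FALSE], meta_one_arm,
              "between_arms"),
    class = "modflex_contrast_error"
  )
  # duplicated samples across timepoints: all paired differences constant
  meta <- fx$meta[fx$meta$arm == "DHI", ]
  x <- fx$x[, meta$sample_id, drop = FALSE]
  x[, meta$timepoint == "Day30"] <- x[, meta$timepoint == "Day0"]
  expect_error(call_degs(x, meta, "within_arm"),
               class = "modflex_contrast_error")
})

test_that("BH adjustment is available behind a flag", {
  fx <- deg_fixture(rep(0, 50), sd = 1, seed = 7)
  raw <- call_degs(fx$x, fx$meta, "between_arms")
  adj <- call_degs(fx$x, fx$meta, "between_arms", adjust_method = "BH")
  expect_identical(adj$p_value, p.adjust(raw$p_value, "BH"))
  expect_lte(sum(adj$is_deg), sum(raw$is_deg))
})

test_that("gene-trait correlation matches cor.test and handles edge cases", {
  trait <- c(2.1, -0.5, 3.3, 0.7, 1.9)
  x <- rbind(
    same = trait,
    anti = -trait,
    toy = c(1.0, 0.4, -2.2, 0.8, 1.5),
    flat = rep(1, 5)
  )
  colnames(x) <- paste0("s", 1:5)
  expect_warning(res <- gene_trait_correlation(x, trait), "zero-variance")
  expect_equal(res$r[res$gene_id == "same"], 1)
  expect_equal(res$r[res$gene_id == "anti"], -1)
  ct <- cor.test(x["toy", ], trait)
  expect_equal(res$r[res$gene_id == "toy"], unname(ct$estimate),
               tolerance = 1e-12)
  expect_equal(res$p_value[res$gene_id == "toy"], ct$p.value,
               tolerance = 1e-12)
  expect_true(is.na(res$r[res$gene_id == "flat"]))
  expect_warning(flat <- gene_trait_correlation(x, rep(1, 5)), "trait")
  expect_true(all(is.na(flat$r)))
})
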