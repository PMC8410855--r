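test_that("adjacency matches the closed-form soft threshold", {
  # cor(x1, x2) = 0.5 exactly by construction
  x <- rbind(g1 = c(1, 2, 3), g2 = c(2, 1, 3))
  colnames(x) <- paste0("s", 1:3)
  expect_equal(cor(x["g1", ], x["g2", ]), 0.5)
  a_uns <- build_adjacency(x, power = 6, signed = FALSE)
  expect_equal(a_uns["g1", "g2"], 0.5^6)            # 0.015625
  a_sgn <- build_adjacency(x, power = 6, signed = TRUE)
  expect_equal(a_sgn["g1", "g2"], 0.75^6)           # 0.177978515625
  # perfectly correlated pair: adjacency 1 at any power
  y <- rbind(g1 = c(1, 2, 3), g2 = c(2, 4, 6))
  colnames(y) <- paste0("s", 1:3)
  expect_equal(build_adjacency(y, power = 9)["g1", "g2"], 1)
})

test_that("adjacency is bounded, symmetric, unit-diagonal, and monotone in power", {
  x <- withr::with_seed(1, matrix(rnorm(200), 10, 20,
                                  dimnames = list(paste0("g", 1:10),
                                                  paste0("s", 1:20))))
  a2 <- build_adjacency(x, power = 2)
  a5 <- build_adjacency(x, power = 5)
  for (a in list(a2, a5)) {
    expect_true(isSymmetric(a))
    expect_true(all(a >= 0 & a <= 1))
    expect_equal(unname(diag(a)), rep(1, 10))
  }
  off <- upper.tri(a2)
  expect_true(all(a5[off] <= a2[off]))
  x[1, ] <- 7  # constant gene
  expect_error(build_adjacency(x, power = 6), "g1",
               class = "modflex_config_error")
})

test_that("TOM reproduces hand-evaluated values and bounds", {
  a <- matrix(c(1, .5, .2,
                .5, 1, .4,
                .2, .4, 1), 3, 3, byrow = TRUE,
              dimnames = list(paste0("g", 1:3), paste0("g", 1:3)))
  tom <- compute_tom(a)
  # l_12 = 0.2 * 0.4, k = (0.7, 0.9, 0.6): (0.08 + 0.5) / (0.7 + 1 - 0.5)
  expect_equal(tom["g1", "g2"], 0.58 / 1.2, tolerance = 1e-10)
  expect_true(isSymmetric(tom))
  expect_equal(unname(diag(tom)), rep(1, 3))
  expect_true(all(tom >= 0 & tom <= 1))

  # binary adjacency, genes 1-2 connected with identical neighbour profiles
  b <- matrix(0, 4, 4)
  b[1, 2] <- b[2, 1] <- 1
  b[1, 3] <- b[3, 1] <- 1
  b[2, 3] <- b[3, 2] <- 1
  diag(b) <- 1
  expect_equal(compute_tom(b)[1, 2], 1)

  # empty off-diagonal stays empty
  e <- diag(3)
  tome <- compute_tom(e)
  expect_true(all(tome[upper.tri(tome)] == 0))

  # random input: bounds and symmetry hold
  ra <- withr::with_seed(2, {
    m <- matrix(runif(64), 8, 8)
    m <- (m + t(m)) / 2
    diag(m) <- 1
    m
  })
  rt <- compute_tom(ra)
  expect_true(all(rt >= 0 & rt <= 1 + 1e-12))
  expect_true(isSymmetric(rt))
})

test_that("eigengene matches an explicit SVD and its conventions", {
  x <- withr::with_seed(3, matrix(rnorm(40), 2, 20,
                                  dimnames = list(c("g1", "g2"),
                                                  paste0("s", 1:20))))
  e <- module_eigengene(x, c("g1", "g2"))
  # independent oracle: right singular vector of the row-standardized matrix
  z <- t(scale(t(x)))
  v <- svd(z)$v[, 1]
  v <- v / sd(v)
  if (cor(v, colMeans(z)) < 0) v <- -v
  expect_equal(unname(e), v, tolerance = 1e-10)
  expect_equal(sd(e), 1, tolerance = 1e-12)
  expect_gte(cor(e, colMeans(z)), 0)

  # module of identical genes: eigengene is the shared z-scored profile
  y <- rbind(g1 = x[1, ], g2 = x[1, ], g3 = x[1, ])
  ey <- module_eigengene(y, rownames(y))
  expect_equal(unname(ey), unname(as.vector(scale(x[1, ]))),
               tolerance = 1e-10)

  # single-gene module: the z-scored gene itself
  e1 <- module_eigengene(x, "g1")
  expect_equal(unname(e1), unname(as.vector(scale(x[1, ]))),
               tolerance = 1e-12)

  # permuting gene order leaves the eigengene unchanged exactly
  big <- withr::with_seed(4, matrix(rnorm(200), 10, 20,
                                    dimnames = list(paste0("g", 1:10),
                                                    paste0("s", 1:20))))
  perm <- withr::with_seed(5, sample(rownames(big)))
  expect_equal(module_eigengene(big, rownames(big)),
               module_eigengene(big, perm), tolerance = 1e-12)

  # zero-variance gene excluded with a warning
  big[1, ] <- 0
  expect_warning(module_eigengene(big, rownames(big)), "zero-variance")
})

test_that("soft-threshold selection behaves at its boundaries", {
  # single candidate is returned as-is
  st <- simulate_study(small_config())
  base <- st$metadata$sample_id[st$metadata$timepoint == "Day0"]
  x <- st$expression[1:80, base]
  one <- suppressWarnings(pick_soft_threshold(x, candidate_powers = 7))
  expect_equal(one$power, 7)

  # near-deterministic pure one-factor structure: a small power suffices
  # (saturated correlations are not scale-free, so this exercises the
  # best-fit fallback rather than the R^2 >= 0.85 branch)
  coh <- simulate_study(small_config(
    n_genes = 300, module_sizes = c(100, 100, 100),
    within_module_cor = 0.95, dissolved_modules = integer(),
    causal_module = 1, deg_genes = 0
  ))
  res <- suppressWarnings(pick_soft_threshold(coh$expression[, base]))
  expect_lte(res$power, 6)

  # pure noise cannot reach the scale-free target: fallback with warning
  noise <- withr::with_seed(6, matrix(rnorm(100 * 20), 100, 20,
                                      dimnames = list(paste0("g", 1:100),
                                                      paste0("s", 1:20))))
  expect_warning(fb <- pick_soft_threshold(noise, candidate_powers = 1:4),
                 "fallback|no candidate")
  expect_false(fb$reached_target)

  # all-constant expression is rejected
  flat <- matrix(1, 5, 10, dimnames = list(paste0("g", 1:5),
                                           paste0("s", 1:10)))
  expect_error(pick_soft_threshold(flat), class = "modflex_config_error")
})

test_that("module detection recovers planted structure and handles corner cases", {
  st <- simulate_study(small_config(within_module_cor = 0.8))
  base <- st$metadata$sample_id[st$metadata$timepoint == "Day0"]
  x <- st$expression[, base]
  net <- build_network(x, power = 6)
  part <- detect_modules(x, net$tom, min_module_size = 15)
  # at this scale the static cut recovers every planted module intact
  # (perfect recall) while attaching some hub-correlated noise genes, so
  # assert per-module recall plus a global agreement floor
  joint <- dplyr::inner_join(st$truth$assignment, part$assignment,
                             by = "gene_id",
                             suffix = c("_truth", "_found"))
  for (m in names(st$truth$module_genes)) {
    found <- joint$module_found[joint$module_truth == m]
    expect_equal(length(unique(found)), 1)
    expect_false(unique(found) == "unassigned")
  }
  expect_gte(mclust::adjustedRandIndex(joint$module_truth,
                                       joint$module_found), 0.6)
  # labels ordered by size, eigengenes unit variance
  sizes <- module_sizes(part)
  expect_identical(sizes$module, paste0("M", seq_len(nrow(sizes))))
  expect_true(all(diff(sizes$n_genes) <= 0))
  me <- part$eigengenes
  expect_equal(unname(vapply(me[-1], sd, numeric(1))),
               rep(1, ncol(me) - 1), tolerance = 1e-10)

  # a single planted module covering all genes collapses to one module
  one <- simulate_study(simulation_config(
    n_genes = 60, module_sizes = 60, n_treated = 15, n_control = 10,
    dissolved_modules = integer(), causal_module = 1, deg_genes = 0, seed = 2
  ))
  xb <- one$expression[, one$metadata$sample_id[
    one$metadata$timepoint == "Day0"]]
  p1 <- detect_modules(xb, build_network(xb, power = 6)$tom,
                       min_module_size = 10)
  expect_equal(nrow(module_sizes(p1)), 1)

  # all-noise input yields no module
  noise <- withr::with_seed(8, matrix(rnorm(150 * 30), 150, 30,
                                      dimnames = list(paste0("g", 1:150),
                                                      paste0("s", 1:30))))
  p0 <- detect_modules(noise, build_network(noise, power = 6)$tom,
                       min_module_size = 20)
  expect_lte(nrow(module_sizes(p0)), 1)

  expect_error(detect_modules(x, net$tom, min_module_size = 2),
               class = "modflex_config_error")
})

test_that("tidy and glance summarise a partition", {
  st <- simulate_study(small_config())
  base <- st$metadata$sample_id[st$metadata$timepoint == "Day0"]
  x <- st$expression[, base]
  part <- detect_modules(x, build_network(x, power = 6)$tom,
                         min_module_size = 15)
  expect_identical(tidy(part), part$assignment)
  g <- glance(part)
  expect_equal(g$n_genes, nrow(x))
  expect_equal(g$n_modules, nrow(module_sizes(part)))
})
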