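# Independent brute-force graph oracles (no igraph): Floyd-Warshall path
# lengths, triangle-counting local clustering, density by the pair formula.

brute_topology <- function(adj) {
  stopifnot(is.matrix(adj), isSymmetric(unname(adj)))
  a <- (adj != 0) * 1
  diag(a) <- 0
  n <- nrow(a)
  m <- sum(a) / 2
  d <- ifelse(a == 1, 1, Inf)
  diag(d) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  ut <- d[upper.tri(d)]
  cpl <- if (any(is.finite(ut))) mean(ut[is.finite(ut)]) else NA_real_
  local_c <- vapply(seq_len(n), function(i) {
    nb <- which(a[i, ] == 1)
    if (length(nb) < 2) return(0)
    sub <- a[nb, nb, drop = FALSE]
    sum(sub) / (length(nb) * (length(nb) - 1))
  }, numeric(1))
  list(
    n_nodes = n, n_edges = m,
    density = m / (n * (n - 1) / 2),
    cpl = cpl,
    clustering = mean(local_c)
  )
}

# seeded Erdos-Renyi binary adjacency
random_binary_adjacency <- function(n, p, seed) {
  withr::with_seed(seed, {
    a <- matrix(0, n, n)
    a[upper.tri(a)] <- as.numeric(runif(n * (n - 1) / 2) < p)
    a + t(a)
  })
}

# tiny study used across tests; overrides replace the desk-scale defaults
small_config <- function(...) {
  args <- utils::modifyList(
    list(n_genes = 400, module_sizes = c(50, 40, 30),
         within_module_cor = 0.7, n_treated = 20, n_control = 12,
         dissolved_modules = c(1, 3), causal_module = 2, deg_genes = 30,
         seed = 42),
    list(...)
  )
  do.call(simulation_config, args)
}

# K25 minus 32 edges chosen so every non-adjacent pair still shares a
# common neighbour (degrees stay >= 20 of 24)
paper_dem_graph <- function() {
  a <- matrix(1, 25, 25)
  diag(a) <- 0
  drop <- rbind(
    cbind(1:24, 2:25),          # consecutive pairs: 24 edges
    cbind(1:8, 3:10)            # skip-one pairs:     8 edges
  )
  for (r in seq_len(nrow(drop))) {
    a[drop[r, 1], drop[r, 2]] <- 0
    a[drop[r, 2], drop[r, 1]] <- 0
  }
  a
}
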