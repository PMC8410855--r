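#' Configure a synthetic two-arm, two-timepoint expression study
#'
#' Builds and validates the parameter set for [simulate_study()]. The
#' generator plants co-expression modules with a one-factor Gaussian model,
#' dissolves a subset of them in the treated arm at the follow-up timepoint,
#' and couples a continuous clinical response (`delta_af`, change in the
#' Seattle Angina Questionnaire angina-frequency score) to the eigengene
#' change of one designated causal module.
#'
#' Gene `i` of module `k` in sample `s` is
#' `sqrt(rho_k) * f_k[s] + sqrt(1 - rho_k) * e_i[s]` with `f_k` and `e_i`
#' independent standard normal, so the expected pairwise correlation inside
#' module `k` equals `rho_k`. Background genes are independent standard
#' normal. Values are on a log2-like scale: a mean shift of `d` corresponds
#' to a `2^d` fold change.
#'
#' @param n_genes Total number of genes (module genes plus background).
#' @param module_sizes Integer vector of planted module sizes.
#' @param within_module_cor Within-module correlation `rho` per module, in
#'   (0, 1); recycled across modules.
#' @param n_treated,n_control Subjects per arm.
#' @param timepoints Two timepoint labels, baseline first.
#' @param dissolved_modules Indices of modules whose `rho` is multiplied by
#'   `dissolution_factor` in the treated arm at the follow-up timepoint.
#' @param dissolution_factor Multiplier in `[0, 1]` applied to `rho` of
#'   dissolved modules (0 = complete dissolution, 1 = no effect).
#' @param causal_module Index of the module whose eigengene change drives the
#'   phenotype.
#' @param phenotype_beta Effect size linking the causal factor change to
#'   `delta_af` (`delta_af` gains `40 * phenotype_beta` points per unit of
#'   factor change).
#' @param phenotype_noise_sd SD of the additive phenotype noise, in
#'   `delta_af` points.
#' @param deg_genes Number of background genes given a mean shift of
#'   `deg_log2fc` in the treated arm at follow-up (true differential
#'   expression).
#' @param deg_log2fc Size of that shift on the log2 scale.
#' @param graded_dissolution If `TRUE`, the causal module's coherence at
#'   follow-up in the treated arm scales with a per-subject latent response
#'   `u` in (0, 1) (`rho_s = rho * (dissolution_factor + (1 -
#'   dissolution_factor) * u)`), and `delta_af` derives from `u`. This
#'   emulates response-graded module reorganisation for flexibility
#'   analysis; the default arm-level model applies one `rho` to the whole
#'   arm.
#' @param treated_daf_shift,control_daf_shift Additive centres of `delta_af`
#'   in each arm (the control shift is the placebo response).
#' @param daf_range Numeric length-2; `delta_af` is clipped to this range
#'   after noise.
#' @param seed RNG seed; identical seed and configuration give byte-identical
#'   output.
#'
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_genes = 2000,
                              module_sizes = c(100, 80, 60, 50, 40),
                              within_module_cor = 0.7,
                              n_treated = 41,
                              n_control = 21,
                              timepoints = c("Day0", "Day30"),
                              dissolved_modules = c(1, 5),
                              dissolution_factor = 0.1,
                              causal_module = 1,
                              phenotype_beta = 0.5,
                              phenotype_noise_sd = 10,
                              deg_genes = 90,
                              deg_log2fc = 0.75,
                              graded_dissolution = FALSE,
                              treated_daf_shift = 18,
                              control_daf_shift = 10,
                              daf_range = c(-25, 100),
                              seed = 1) {
  k <- length(module_sizes)
  rho <- rep_len(within_module_cor, k)
  if (sum(module_sizes) > n_genes) {
    mf_abort(
      sprintf("sum(module_sizes) = %d exceeds n_genes = %d",
              sum(module_sizes), n_genes),
      "modflex_config_error"
    )
  }
  if (any(rho <= 0 | rho >= 1)) {
    mf_abort("within_module_cor must lie strictly in (0, 1)",
             "modflex_config_error")
  }
  if (dissolution_factor < 0 || dissolution_factor > 1) {
    mf_abort("dissolution_factor must lie in [0, 1]", "modflex_config_error")
  }
  if (length(timepoints) != 2L) {
    mf_abort("exactly two timepoints are supported", "modflex_config_error")
  }
  if (length(dissolved_modules) && any(!dissolved_modules %in% seq_len(k))) {
    mf_abort("dissolved_modules must index module_sizes",
             "modflex_config_error")
  }
  if (!causal_module %in% seq_len(k)) {
    mf_abort("causal_module must index module_sizes", "modflex_config_error")
  }
  if (deg_genes > n_genes - sum(module_sizes)) {
    mf_abort("deg_genes exceeds the number of background genes",
             "modflex_config_error")
  }
  structure(
    list(
      n_genes = as.integer(n_genes),
      module_sizes = as.integer(module_sizes),
      within_module_cor = rho,
      n_treated = as.integer(n_treated),
      n_control = as.integer(n_control),
      timepoints = as.character(timepoints),
      dissolved_modules = as.integer(dissolved_modules),
      dissolution_factor = dissolution_factor,
      causal_module = as.integer(causal_module),
      phenotype_beta = phenotype_beta,
      phenotype_noise_sd = phenotype_noise_sd,
      deg_genes = as.integer(deg_genes),
      deg_log2fc = deg_log2fc,
      graded_dissolution = isTRUE(graded_dissolution),
      treated_daf_shift = treated_daf_shift,
      control_daf_shift = control_daf_shift,
      daf_range = daf_range,
      seed = as.integer(seed)
    ),
    class = "simulation_config"
  )
}

#' Simulate a two-arm, two-timepoint expression study with planted modules
#'
#' Generates log-scale expression for every subject at both timepoints,
#' sample metadata with the `delta_af` phenotype, and the planted ground
#' truth (module assignment, dissolved and causal module indices, true
#' differentially expressed genes). See [simulation_config()] for the model.
#'
#' @param config A [simulation_config()].
#' @return A `simulated_study` list with elements `expression` (genes x
#'   samples numeric matrix, log2-like scale), `metadata` (tibble:
#'   `sample_id`, `subject_id`, `arm`, `timepoint`, `delta_af`), `truth`
#'   (list: `assignment` tibble, `module_genes`, `dissolved_modules`,
#'   `causal_module`, `deg_genes`, per-subject latent response `u` when
#'   graded), and `config`.
#' @export
#' @examples
#' study <- simulate_study(simulation_config(
#'   n_genes = 200, module_sizes = c(40, 30), n_treated = 10, n_control = 6,
#'   dissolved_modules = 1, causal_module = 1, deg_genes = 10, seed = 7
#' ))
#' dim(study$expression)
simulate_study <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  cfg <- config
  k <- length(cfg$module_sizes)
  tp0 <- cfg$timepoints[1]
  tp1 <- cfg$timepoints[2]

  subjects <- c(sprintf("DHI_%02d", seq_len(cfg$n_treated)),
                sprintf("CTL_%02d", seq_len(cfg$n_control)))
  arms <- rep(c("DHI", "control"), c(cfg$n_treated, cfg$n_control))
  meta <- tidyr::expand_grid(
    tibble(subject_id = subjects, arm = arms),
    timepoint = cfg$timepoints
  )
  meta$sample_id <- paste(meta$subject_id, meta$timepoint, sep = ".")
  n_samples <- nrow(meta)

  gene_ids <- sprintf("G%04d", seq_len(cfg$n_genes))
  module_of <- rep("unassigned", cfg$n_genes)
  pos <- 0L
  module_rows <- vector("list", k)
  for (q in seq_len(k)) {
    idx <- pos + seq_len(cfg$module_sizes[q])
    module_rows[[q]] <- idx
    module_of[idx] <- paste0("M", q)
    pos <- pos + cfg$module_sizes[q]
  }
  background <- which(module_of == "unassigned")

  out <- withr::with_seed(cfg$seed, {
    f <- matrix(rnorm(k * n_samples), nrow = k)        # module factors
    eps <- matrix(rnorm(cfg$n_genes * n_samples), nrow = cfg$n_genes)
    u <- runif(cfg$n_treated)                          # latent response
    deg <- sort(sample(background, cfg$deg_genes))
    noise_t <- rnorm(cfg$n_treated, sd = cfg$phenotype_noise_sd)
    noise_c <- rnorm(cfg$n_control, sd = cfg$phenotype_noise_sd)
    list(f = f, eps = eps, u = u, deg = deg,
         noise_t = noise_t, noise_c = noise_c)
  })

  is_post_treated <- meta$arm == "DHI" & meta$timepoint == tp1
  subj_index <- match(meta$subject_id, subjects)       # per sample

  expr <- out$eps
  for (q in seq_len(k)) {
    rho_s <- rep(cfg$within_module_cor[q], n_samples)
    if (q %in% cfg$dissolved_modules) {
      rho_s[is_post_treated] <- rho_s[is_post_treated] * cfg$dissolution_factor
    }
    if (cfg$graded_dissolution && q == cfg$causal_module) {
      us <- out$u[subj_index[is_post_treated]]
      rho_s[is_post_treated] <- cfg$within_module_cor[q] *
        (cfg$dissolution_factor + (1 - cfg$dissolution_factor) * us)
    }
    rows <- module_rows[[q]]
    sig <- matrix(sqrt(rho_s), nrow = length(rows), ncol = n_samples,
                  byrow = TRUE)
    expr[rows, ] <- sig * matrix(out$f[q, ], nrow = length(rows),
                                 ncol = n_samples, byrow = TRUE) +
      sqrt(1 - sig^2) * out$eps[rows, ]
  }
  if (cfg$deg_genes > 0) {
    expr[out$deg, is_post_treated] <- expr[out$deg, is_post_treated] +
      cfg$deg_log2fc
  }
  dimnames(expr) <- list(gene_ids, meta$sample_id)

  # phenotype: treated response couples to the causal eigengene change
  # (or to the latent u under graded dissolution); control is placebo noise
  s0 <- meta$sample_id[meta$arm == "DHI" & meta$timepoint == tp0]
  s1 <- meta$sample_id[meta$arm == "DHI" & meta$timepoint == tp1]
  f_causal <- out$f[cfg$causal_module, ]
  names(f_causal) <- meta$sample_id
  if (cfg$graded_dissolution) {
    raw_t <- cfg$treated_daf_shift +
      60 * cfg$phenotype_beta * (out$u - 0.5) + out$noise_t
  } else {
    raw_t <- cfg$treated_daf_shift +
      40 * cfg$phenotype_beta * (f_causal[s1] - f_causal[s0]) + out$noise_t
  }
  raw_c <- cfg$control_daf_shift + out$noise_c
  daf <- pmin(pmax(c(raw_t, raw_c), cfg$daf_range[1]), cfg$daf_range[2])
  names(daf) <- subjects
  meta$delta_af <- unname(daf[meta$subject_id])
  meta <- meta[, c("sample_id", "subject_id", "arm", "timepoint", "delta_af")]

  truth <- list(
    assignment = tibble(gene_id = gene_ids, module = module_of),
    module_genes = setNames(
      lapply(module_rows, function(i) gene_ids[i]),
      paste0("M", seq_len(k))
    ),
    dissolved_modules = paste0("M", cfg$dissolved_modules),
    causal_module = paste0("M", cfg$causal_module),
    deg_genes = gene_ids[out$deg],
    causal_factor_change = setNames(f_causal[s1] - f_causal[s0],
                                    subjects[seq_len(cfg$n_treated)]),
    u = if (cfg$graded_dissolution) {
      setNames(out$u, subjects[seq_len(cfg$n_treated)])
    }
  )

  structure(
    list(expression = expr, metadata = meta, truth = truth, config = cfg),
    class = "simulated_study"
  )
}

#' @export
print.simulated_study <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<simulated_study> %d genes x %d samples (%d treated + %d control, %s/%s)\n",
    nrow(x$expression), ncol(x$expression), cfg$n_treated, cfg$n_control,
    cfg$timepoints[1], cfg$timepoints[2]
  ))
  cat(sprintf("  planted modules: %s; dissolved: %s; causal: %s\n",
              paste(cfg$module_sizes, collapse = "/"),
              paste(x$truth$dissolved_modules, collapse = ","),
              x$truth$causal_module))
  invisible(x)
}

#' Write a simulated study to disk
#'
#' Writes `expression.tsv` (gene-ID first column, sample header),
#' `metadata.tsv`, and `truth.json` into `dir`.
#'
#' @param study A `simulated_study`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "simulated_study"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_expression_matrix(study$expression, file.path(dir, "expression.tsv"))
  readr::write_tsv(study$metadata, file.path(dir, "metadata.tsv"))
  truth <- study$truth
  truth$assignment <- NULL  # recoverable from module_genes
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
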