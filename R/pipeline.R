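#' Default pipeline configuration
#'
#' Flat key-value configuration driving [run_pipeline()]. Unknown keys
#' passed to [pipeline_config()] are errors. Simulation keys are forwarded
#' to [simulation_config()]; set `expression_path`/`metadata_path` to run on
#' real data instead.
#'
#' @return Named list of defaults.
#' @export
default_config <- function() {
  list(
    # input: either simulate (default) or read from disk
    expression_path = NULL,
    metadata_path = NULL,
    # simulation (see simulation_config())
    n_genes = 2000L,
    module_sizes = c(100L, 80L, 60L, 50L, 40L),
    within_module_cor = 0.7,
    n_treated = 41L,
    n_control = 21L,
    timepoints = c("Day0", "Day30"),
    dissolved_modules = c(1L, 5L),
    dissolution_factor = 0.1,
    causal_module = 1L,
    phenotype_beta = 0.5,
    phenotype_noise_sd = 10,
    deg_genes = 90L,
    deg_log2fc = 0.75,
    graded_dissolution = FALSE,
    # preprocessing
    top_n_genes = NULL,          # NULL = keep all genes
    # network
    power = 6,                   # or "auto"
    signed = FALSE,
    min_module_size = 30L,
    cut_height = 0.99,
    merge_height = 0.25,
    # preservation / DEM call
    n_permutations = 100L,
    # module graph
    cs_threshold = 0.3,
    module_graph_nodes = "dems", # "dems" or "all"
    # responder analysis
    r_threshold = 0.3,
    p_threshold = 0.05,
    metm_scope = "dems",         # "dems" or "all"
    # flexibility
    n_response_bins = 6L,
    min_bin_size = 4L,
    tau_g = NULL,                # NULL = anchor to the reference bin
    seed = 1L
  )
}

#' Build and validate a pipeline configuration
#'
#' @param ... Overrides of [default_config()] keys; an unknown key is an
#'   error naming it.
#' @return Named configuration list.
#' @export
pipeline_config <- function(...) {
  overrides <- list(...)
  defaults <- default_config()
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown)) {
    mf_abort(sprintf("unknown configuration key(s): %s",
                     paste(unknown, collapse = ", ")),
             "modflex_config_error")
  }
  utils::modifyList(defaults, overrides, keep.null = TRUE)
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file of configuration keys.
#' @return Validated configuration list.
#' @export
read_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Run the full modular-pharmacology pipeline
#'
#' Stages, in order: (1) simulate or load the study; (2) call
#' differentially expressed genes (treated vs control at follow-up);
#' (3) build the baseline co-expression network (all subjects at the first
#' timepoint) and detect modules; (4) call differentially expressed modules
#' (DEMs) by permutation Z_summary of the baseline modules against the
#' treated follow-up network, plus per-stratum DEM counts; (5) build the
#' module-level connectivity-score network and its topology; (6) stratify
#' treated subjects by response, correlate per-subject eigengene change
#' with `delta_af` in the best stratum, and select the most effective
#' therapeutic module (METM); (7) profile the METM's flexibility across
#' response bins and regress `D` and edge count on response.
#'
#' @param config From [pipeline_config()] / [read_config()].
#' @param out_dir Optional directory for TSV/JSON stage outputs.
#' @return A `modflex_report` list; its `summary` element is written as
#'   `run_summary.json` when `out_dir` is given.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  defaults <- default_config()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) {
    mf_abort(sprintf("unknown configuration key(s): %s",
                     paste(unknown, collapse = ", ")),
             "modflex_config_error")
  }
  config <- utils::modifyList(defaults, config, keep.null = TRUE)
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  t_start <- Sys.time()
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e) {
      mf_abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
               "modflex_stage_error")
    })
    inform(sprintf("[%s] done in %.1fs", name,
                   as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    res
  }

  # -- input ---------------------------------------------------------------
  study <- stage("input", {
    if (!is.null(config$expression_path)) {
      expr <- read_expression_matrix(config$expression_path)
      meta <- read_sample_metadata(config$metadata_path, expr)
      list(expression = expr, metadata = meta, truth = NULL)
    } else {
      sim_keys <- intersect(names(config), names(formals(simulation_config)))
      simulate_study(do.call(simulation_config, config[sim_keys]))
    }
  })
  expr <- study$expression
  meta <- study$metadata
  tp0 <- config$timepoints[1]
  tp1 <- config$timepoints[2]
  if (!is.null(config$top_n_genes)) {
    expr <- filter_variance(expr, config$top_n_genes)
  }

  # -- DEGs ----------------------------------------------------------------
  degs <- stage("deg", {
    call_degs(expr, meta, contrast = "between_arms", timepoint = tp1,
              p_threshold = config$p_threshold)
  })

  # -- baseline network and modules ---------------------------------------
  base_samples <- meta$sample_id[meta$timepoint == tp0]
  treated_post <- meta$sample_id[meta$arm == "DHI" & meta$timepoint == tp1]
  net_base <- stage("network", {
    build_network(expr[, base_samples], power = config$power,
                  signed = config$signed)
  })
  partition <- stage("modules", {
    detect_modules(expr[, base_samples], net_base$tom,
                   min_module_size = config$min_module_size,
                   cut_height = config$cut_height,
                   merge_height = config$merge_height)
  })
  sizes <- module_sizes(partition)

  # -- DEM call ------------------------------------------------------------
  preservation <- stage("preservation", {
    net_post <- build_adjacency(expr[, treated_post], power = net_base$power,
                                signed = config$signed)
    module_preservation(net_base$adjacency, net_post, partition,
                        n_permutations = config$n_permutations,
                        seed = config$seed)
  })
  dems <- preservation$module[preservation$is_dem]

  # -- responder strata and per-stratum DEM counts -------------------------
  strata <- stage("strata", stratify(meta))
  stratum_dems <- stage("stratum_dems", {
    purrr::map_dfr(unique(strata$stratum[!is.na(strata$stratum)]),
                   function(st) {
      subj <- strata$subject_id[strata$stratum == st]
      samp <- meta$sample_id[meta$subject_id %in% subj &
                               meta$timepoint == tp1]
      if (length(samp) < 4) {
        return(tibble(stratum = st, n_subjects = length(samp),
                      n_dems = NA_integer_))
      }
      pres <- module_preservation(
        net_base$adjacency,
        build_adjacency(expr[, samp], power = net_base$power,
                        signed = config$signed),
        partition, n_permutations = config$n_permutations,
        seed = config$seed
      )
      tibble(stratum = st, n_subjects = length(samp),
             n_dems = sum(pres$is_dem))
    })
  })

  # -- module-level network -------------------------------------------------
  me_post <- module_eigengenes(expr[, treated_post], partition)
  graph_nodes <- if (identical(config$module_graph_nodes, "dems") &&
                       length(dems) >= 3) {
    dems
  } else {
    if (identical(config$module_graph_nodes, "dems") && length(dems) < 3) {
      inform("fewer than 3 DEMs: module graph built on all modules")
    }
    sizes$module
  }
  mod_graph <- stage("module_graph", {
    build_module_graph(graph_nodes, cs_matrix(me_post),
                       threshold = config$cs_threshold, sizes = sizes)
  })
  topo <- stage("topology", topology_features(mod_graph, seed = config$seed))

  # -- METM ----------------------------------------------------------------
  me_change <- eigengene_change(expr, meta, partition, tp0, tp1)
  best <- strata[!is.na(strata$stratum) & strata$stratum == "best", ]
  metm_result <- stage("metm", {
    if (nrow(best) < 3) {
      warn("best-effect stratum has fewer than 3 subjects: no METM")
      list(correlations = NULL, metm = NA_character_)
    } else {
      mc <- me_change[match(best$subject_id, me_change$subject_id), ]
      pool <- if (identical(config$metm_scope, "dems")) {
        intersect(names(mc), dems)
      } else {
        setdiff(names(mc), "subject_id")
      }
      if (length(pool) == 0) {
        warn("no modules in METM scope")
        list(correlations = NULL, metm = NA_character_)
      } else {
        corr <- module_trait_correlation(mc[, pool, drop = FALSE],
                                         best$delta_af,
                                         r_threshold = config$r_threshold,
                                         p_threshold = config$p_threshold)
        list(correlations = corr, metm = suppressWarnings(select_metm(corr)))
      }
    }
  })
  metm <- metm_result$metm

  # -- flexibility ----------------------------------------------------------
  flexibility <- stage("flexibility", {
    if (is.na(metm)) {
      inform("no METM: flexibility stage skipped")
      NULL
    } else {
      genes <- partition$assignment$gene_id[
        partition$assignment$module == metm
      ]
      profiles <- flexibility_profiles(
        expr, meta, genes, n_bins = config$n_response_bins,
        min_bin_size = config$min_bin_size, power = net_base$power,
        signed = config$signed, tau_g = config$tau_g,
        timepoint = tp1
      )
      list(profiles = profiles, fit = flexibility_regression(profiles))
    }
  })

  # -- report ---------------------------------------------------------------
  flex_glance <- if (!is.null(flexibility)) glance(flexibility$fit)
  metm_row <- if (!is.null(metm_result$correlations) && !is.na(metm)) {
    metm_result$correlations[metm_result$correlations$module == metm, ]
  }
  summary <- list(
    n_genes = nrow(expr),
    n_samples = ncol(expr),
    power = net_base$power,
    n_modules = nrow(sizes),
    module_sizes = setNames(sizes$n_genes, sizes$module),
    n_dems = length(dems),
    dems = dems,
    dem_counts_by_stratum = stratum_dems,
    n_degs = sum(degs$is_deg),
    module_graph = as.list(topo),
    metm = metm,
    metm_r = if (!is.null(metm_row)) metm_row$r,
    metm_p_value = if (!is.null(metm_row)) metm_row$p_value,
    best_stratum_n = nrow(best),
    flexibility = flex_glance,
    elapsed_s = as.numeric(difftime(Sys.time(), t_start, units = "secs")),
    config = config
  )

  if (!is.null(out_dir)) {
    readr::write_tsv(degs, file.path(out_dir, "degs.tsv"))
    readr::write_tsv(partition$assignment,
                     file.path(out_dir, "module_assignment.tsv"))
    readr::write_tsv(partition$eigengenes,
                     file.path(out_dir, "eigengenes_baseline.tsv"))
    readr::write_tsv(preservation, file.path(out_dir, "preservation.tsv"))
    readr::write_tsv(mod_graph$edges, file.path(out_dir, "module_edges.tsv"))
    readr::write_tsv(strata, file.path(out_dir, "strata.tsv"))
    if (!is.null(metm_result$correlations)) {
      readr::write_tsv(metm_result$correlations,
                       file.path(out_dir, "metm_correlations.tsv"))
    }
    if (!is.null(flexibility)) {
      readr::write_tsv(flexibility$profiles,
                       file.path(out_dir, "flexibility_profiles.tsv"))
    }
    jsonlite::write_json(summary, file.path(out_dir, "run_summary.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         dataframe = "rows", force = TRUE)
  }

  structure(
    list(
      study = study, degs = degs, network = net_base, partition = partition,
      preservation = preservation, module_graph = mod_graph,
      topology = topo, strata = strata,
      metm_correlations = metm_result$correlations, metm = metm,
      flexibility = flexibility, summary = summary
    ),
    class = "modflex_report"
  )
}

# per-subject eigengene change (follow-up minus baseline) for treated
# subjects, using the baseline module definitions
eigengene_change <- function(expr, meta, partition, tp0, tp1, arm = "DHI") {
  treated <- meta[meta$arm == arm, , drop = FALSE]
  wide <- tidyr::pivot_wider(treated[, c("subject_id", "timepoint", "sample_id")],
                             names_from = "timepoint",
                             values_from = "sample_id")
  wide <- wide[stats::complete.cases(wide), , drop = FALSE]
  me0 <- module_eigengenes(expr[, wide[[tp0]], drop = FALSE], partition)
  me1 <- module_eigengenes(expr[, wide[[tp1]], drop = FALSE], partition)
  mods <- setdiff(names(me0), "sample_id")
  change <- as_tibble(as.matrix(me1[, mods]) - as.matrix(me0[, mods]))
  dplyr::bind_cols(tibble(subject_id = wide$subject_id), change)
}

#' @export
print.modflex_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<modflex_report> %d genes, %d samples\n", s$n_genes,
              s$n_samples))
  cat(sprintf("  modules: %d  |  DEMs: %d  |  DEGs: %d\n",
              s$n_modules, s$n_dems, s$n_degs))
  cat(sprintf("  module graph: %d nodes, %d edges, density %.3f\n",
              s$module_graph$n_nodes, s$module_graph$n_edges,
              s$module_graph$density))
  cat(sprintf("  METM: %s (r = %s, best-stratum n = %d)\n",
              s$metm,
              if (is.null(s$metm_r)) "NA" else sprintf("%.3f", s$metm_r),
              s$best_stratum_n))
  if (!is.null(s$flexibility)) {
    d <- s$flexibility[s$flexibility$response == "d_value", ]
    e <- s$flexibility[s$flexibility$response == "n_edges", ]
    cat(sprintf("  flexibility: slope(D) = %.4f (r2 = %.3f), slope(edges) = %.2f (r2 = %.3f)\n",
                d$slope, d$r_squared, e$slope, e$r_squared))
  }
  invisible(x)
}
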