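#' Validate and normalise a pipeline run configuration
#'
#' Fills defaults (depth 13595, n_perm 9999, n_null 999, thresholds 2 /
#' 0.95), checks minima, and rejects unknown keys with a suggestion.
#'
#' @param config Named list. Recognised keys: `otu_table`, `tree`,
#'   `metadata` (input paths) or `generate` (a [scenario_config()]);
#'   `depth`, `n_perm`, `n_null`, `seed`, `bnti_threshold`, `rc_threshold`,
#'   `group_var`, `geo_mode`, `mantel_method`, `weighted`, `scope`,
#'   `out_dir`, `log_base`, `include_root`, `samples_in_rows`.
#' @return Normalised configuration list of class `run_config`.
#' @export
validate_run_config <- function(config = list()) {
  defaults <- list(
    otu_table = NULL, tree = NULL, metadata = NULL, generate = NULL,
    depth = 13595L, n_perm = 9999L, n_null = 999L, seed = 1L,
    bnti_threshold = 2, rc_threshold = 0.95, group_var = "habitat",
    geo_mode = "cartesian", mantel_method = "spearman", weighted = TRUE,
    scope = "within_group", out_dir = NULL, log_base = exp(1),
    include_root = TRUE, samples_in_rows = FALSE
  )
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0L) {
    hint <- vapply(unknown, function(k) {
      cand <- agrep(k, names(defaults), max.distance = 0.3, value = TRUE)
      if (length(cand) > 0L) paste0(" (did you mean '", cand[1L], "'?)") else ""
    }, "")
    stop("unknown config key(s): ",
         paste0(unknown, hint, collapse = ", "),
         "; accepted keys: ", paste(names(defaults), collapse = ", "))
  }
  cfg <- utils::modifyList(defaults, config)
  if (cfg$depth < 1) stop("depth must be >= 1")
  if (cfg$n_perm < 99) stop("n_perm must be >= 99")
  if (cfg$n_null < 99) stop("n_null must be >= 99")
  if (is.null(cfg$generate) &&
      (is.null(cfg$otu_table) || is.null(cfg$tree) || is.null(cfg$metadata))) {
    stop("provide input paths (otu_table, tree, metadata) or a 'generate' scenario")
  }
  structure(cfg, class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Executes, in order: input loading (or synthetic generation), alignment,
#' rarefaction, alpha diversity with group tests and environmental
#' correlations, Bray-Curtis beta diversity with NMDS / ANOSIM / Mantel /
#' distance-decay, environmental PCA and group t-tests, and the two-step
#' null-model assembly analysis. All result tables are written to
#' `out_dir` as TSV plus a JSON run summary recording seeds, effective
#' sample sizes and configuration. Identical configurations produce
#' byte-identical outputs.
#'
#' Stage seeds derive deterministically from `seed` so stages can be
#' re-run independently.
#'
#' @param config A list accepted by [validate_run_config()].
#' @return Invisibly, a list with every stage's result objects and the run
#'   summary.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- validate_run_config(config)
  stage_seed <- function(k) (cfg$seed * 97L + k * 1009L) %% .Machine$integer.max

  stage <- "load_inputs"
  res <- tryCatch({
    if (!is.null(cfg$generate)) {
      bundle <- generate_bundle(cfg$generate)
      counts <- bundle$counts; tree <- bundle$tree; meta <- bundle$meta
    } else {
      counts <- read_otu_table(cfg$otu_table,
                               samples_in_rows = cfg$samples_in_rows)
      tree <- read_phylogeny(cfg$tree)
      meta <- read_sample_metadata(cfg$metadata)
    }
    al <- align_inputs(counts, tree, meta)

    stage <- "rarefy"
    rare <- rarefy_counts(al$counts, depth = cfg$depth, seed = stage_seed(1L))
    al <- align_inputs(rare, al$tree, al$meta)
    rare <- al$counts; tree <- al$tree; meta <- al$meta

    stage <- "alpha"
    alpha <- alpha_table(rare, tree, base = cfg$log_base,
                         include_root = cfg$include_root)
    groups <- meta[[cfg$group_var]]
    alpha_tests <- alpha_group_test(alpha, groups)
    alpha_env <- alpha_env_correlations(alpha, meta)

    stage <- "beta"
    comm <- bray_curtis(transform_community(rare))
    nmds <- run_nmds(comm, k = 2, seed = stage_seed(2L))
    anosim_res <- anosim_test(comm, groups, n_perm = cfg$n_perm,
                              seed = stage_seed(3L))
    geo <- geo_distance_matrix(meta, mode = cfg$geo_mode)
    mantel_geo <- mantel_test(comm, geo, n_perm = cfg$n_perm,
                              method = cfg$mantel_method,
                              seed = stage_seed(4L))
    decay <- distance_decay(comm, geo, n_perm = cfg$n_perm,
                            seed = stage_seed(5L))

    stage <- "environment"
    env_num <- meta[vapply(meta, is.numeric, TRUE)]
    env_num$latitude <- NULL; env_num$longitude <- NULL
    env_num$shore_km <- NULL
    env_t <- transform_env(env_num)
    env_pca <- tryCatch(pca_env(env_t), error = function(e) NULL)
    env_tests <- if (length(unique(groups)) == 2L) {
      env_group_test(env_t, groups)
    } else NULL

    stage <- "assembly"
    assembly <- run_assembly(rare, tree, meta, group_var = cfg$group_var,
                             n_null = cfg$n_null, weighted = cfg$weighted,
                             bnti_threshold = cfg$bnti_threshold,
                             rc_threshold = cfg$rc_threshold,
                             scope = cfg$scope, seed = stage_seed(6L))

    list(counts = rare, tree = tree, meta = meta, alpha = alpha,
         alpha_tests = alpha_tests, alpha_env = alpha_env,
         bray_curtis = comm, nmds = nmds, anosim = anosim_res,
         mantel_geo = mantel_geo, distance_decay = decay,
         env_pca = env_pca, env_tests = env_tests, assembly = assembly)
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })

  summary <- list(
    package_version = as.character(utils::packageVersion("intertidr")),
    seed = cfg$seed, depth = cfg$depth, n_perm = cfg$n_perm,
    n_null = cfg$n_null, bnti_threshold = cfg$bnti_threshold,
    rc_threshold = cfg$rc_threshold, group_var = cfg$group_var,
    n_samples = nrow(res$counts), n_otus = ncol(res$counts),
    effective_n = list(
      anosim = res$anosim$n, mantel_geo = res$mantel_geo$n,
      distance_decay = res$distance_decay$n,
      assembly_pairs = sum(!is.na(res$assembly$pairs$process))
    ),
    stress = res$nmds$stress
  )
  res$run_summary <- summary

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    wt <- function(x, f) utils::write.table(
      x, file.path(cfg$out_dir, f), sep = "\t", quote = FALSE,
      row.names = FALSE, fileEncoding = "UTF-8")
    write_otu_table(res$counts, file.path(cfg$out_dir, "rarefied_otu_table.tsv"))
    wt(res$alpha, "alpha.tsv")
    wt(res$alpha_tests, "alpha_tests.tsv")
    wt(res$alpha_env, "alpha_env_corr.tsv")
    write_distance_matrix(res$bray_curtis, file.path(cfg$out_dir, "bray_curtis.tsv"))
    wt(res$nmds$points, "nmds.tsv")
    wt(dplyr::bind_rows(tidy(res$anosim), tidy(res$mantel_geo),
                        tidy(res$distance_decay)), "matrix_tests.tsv")
    if (!is.null(res$env_tests)) wt(res$env_tests, "env_tests.tsv")
    wt(res$assembly$pairs, "processes.tsv")
    wt(res$assembly$summary, "process_summary.tsv")
    jsonlite::write_json(summary, file.path(cfg$out_dir, "run_summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(res)
}
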