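#' Configuration for the end-to-end synthetic analysis
#'
#' Assembles and validates every parameter of [run_pipeline()]: the
#' enrichment-test settings (whose defaults follow the study conventions
#' of 20-kb windows, 10,000 rotations and FDR 0.05), the two synthetic
#' generators, and the output directory. The configuration can also be
#' read from a YAML file with [read_pipeline_config()]; keys mirror the
#' argument names, with `gwas_sim` and `sc_sim` as nested maps.
#'
#' @param outdir Output directory for all written artifacts.
#' @param seed Root seed; every stage's randomness derives from it via
#'   named substreams, so one seed fixes the whole run.
#' @param n_traits Number of simulated traits for the enrichment grid.
#' @param enriched_set_ids Set ids given inflated effects in trait 1 when
#'   `gwas_sim$enrichment_lambda > 1`.
#' @param window_bp Flank around gene bodies for marker mapping.
#' @param n_perm Rotations per enrichment test.
#' @param alpha_fdr FDR threshold used in summaries and plots.
#' @param p_floor Whether empirical p-values are floored at `1/n_perm`
#'   (the package always reports the raw exceedance count alongside).
#' @param proliferation_threshold `"cluster_mean"` or `"grand_mean"`.
#' @param pseudocell_size,n_pseudocells Pseudocell sampling parameters.
#' @param trajectory_tolerance Return-to-baseline tolerance for
#'   [classify_trajectory()].
#' @param gwas_sim A [gwas_sim_config()] (seed is overridden by `seed`).
#' @param sc_sim An [sc_sim_config()] (seed is overridden by `seed`).
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(outdir = tempfile("cellgwas_run_"),
                            seed = 1,
                            n_traits = 3,
                            enriched_set_ids = character(),
                            window_bp = 20000,
                            n_perm = 10000,
                            alpha_fdr = 0.05,
                            p_floor = TRUE,
                            proliferation_threshold = "cluster_mean",
                            pseudocell_size = 100,
                            n_pseudocells = 100,
                            trajectory_tolerance = 0.25,
                            gwas_sim = gwas_sim_config(),
                            sc_sim = sc_sim_config()) {
  stopifnot(inherits(gwas_sim, "gwas_sim_config"),
            inherits(sc_sim, "sc_sim_config"))
  cfg <- list(
    outdir = outdir,
    seed = check_count(seed, "seed", min = 0L),
    n_traits = check_count(n_traits, "n_traits"),
    enriched_set_ids = as.character(enriched_set_ids),
    window_bp = check_number(window_bp, "window_bp", min = 0),
    n_perm = check_count(n_perm, "n_perm"),
    alpha_fdr = check_number(alpha_fdr, "alpha_fdr", min = 0, max = 1,
                             strict_min = TRUE),
    p_floor = isTRUE(p_floor),
    proliferation_threshold = match.arg(proliferation_threshold,
                                        c("cluster_mean", "grand_mean")),
    pseudocell_size = check_count(pseudocell_size, "pseudocell_size"),
    n_pseudocells = check_count(n_pseudocells, "n_pseudocells"),
    trajectory_tolerance = check_number(trajectory_tolerance,
                                        "trajectory_tolerance", min = 0),
    gwas_sim = gwas_sim,
    sc_sim = sc_sim
  )
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file mirroring the `pipeline_config()` arguments.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- setdiff(names(formals(pipeline_config)), c("gwas_sim", "sc_sim"))
  bad <- setdiff(names(raw), c(known, "gwas_sim", "sc_sim"))
  if (length(bad) > 0L) {
    rlang::abort(sprintf("unknown config field(s): %s.",
                         paste(bad, collapse = ", ")))
  }
  args <- raw[intersect(names(raw), known)]
  if (!is.null(raw$gwas_sim)) {
    args$gwas_sim <- do.call(gwas_sim_config, raw$gwas_sim)
  }
  if (!is.null(raw$sc_sim)) {
    sc <- raw$sc_sim
    if (!is.null(sc$cycling_fraction)) {
      sc$cycling_fraction <- unlist(sc$cycling_fraction)
    }
    if (!is.null(sc$module_trajectories)) {
      sc$module_trajectories <- lapply(sc$module_trajectories, unlist)
    }
    args$sc_sim <- do.call(sc_sim_config, sc)
  }
  do.call(pipeline_config, args)
}

#' Run the full synthetic analysis end to end
#'
#' Executes simulate -> map -> enrich -> cell-cycle scoring -> module
#' scoring -> pseudocell aggregation on synthetic inputs, writing every
#' intermediate and result table under `config$outdir` together with a
#' JSON manifest of parameter values, seeds, package version and output
#' checksums. Re-running with an identical config reproduces every output
#' byte-identically.
#'
#' Files written (all plain text): `inputs/` (GWAS TSVs, genes BED, gene
#' sets, panels, single-cell bundle), `results/marker_counts.tsv`,
#' `results/enrichment_grid.tsv`, `results/cycle_flags.tsv`,
#' `results/cycle_index.tsv`, `results/module_scores.tsv`,
#' `results/module_patterns.tsv`, `results/pseudocells.tsv`, and
#' `manifest.json`.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the in-memory results (`gwas_sim`,
#'   `sc_sim`, `marker_counts`, `grid`, `flags`, `cycle_index`,
#'   `module_scores`, `module_patterns`, `pseudocells`, `manifest`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  outdir <- config$outdir
  for (d in c(outdir, file.path(outdir, "inputs"),
              file.path(outdir, "results"))) {
    if (!dir.exists(d)) dir.create(d, recursive = TRUE)
  }

  # -- simulate ------------------------------------------------------------
  gcfg <- config$gwas_sim
  sims <- vector("list", config$n_traits)
  base <- NULL
  for (i in seq_len(config$n_traits)) {
    cfg_i <- gcfg
    cfg_i$seed <- as.integer(derive_seed(config$seed, i))
    # trait 1 carries the injected enrichment; the rest are null traits
    sims[[i]] <- simulate_gwas(
      cfg_i,
      genes = base$genes, sets = base$sets,
      enriched_set_ids = if (i == 1L) config$enriched_set_ids
                         else character(),
      trait_id = sprintf("trait_%02d", i))
    if (is.null(base)) base <- sims[[1]]
  }
  gwas <- dplyr::bind_rows(lapply(sims, `[[`, "markers"))
  scfg <- config$sc_sim
  scfg$seed <- as.integer(derive_seed(config$seed, 1000))
  sc <- simulate_sc(scfg)

  for (i in seq_len(config$n_traits)) {
    write_gwas_tsv(sims[[i]]$markers,
                   file.path(outdir, "inputs",
                             sprintf("gwas_trait_%02d.tsv", i)))
  }
  write_genes_bed(base$genes, file.path(outdir, "inputs", "genes.bed"))
  write_gene_sets(base$sets, file.path(outdir, "inputs", "gene_sets.tsv"))
  write_panels(sc$panels, file.path(outdir, "inputs", "panels.tsv"))
  write_sc_bundle(sc$counts, sc$cell_meta, file.path(outdir, "inputs", "sc"))

  # -- map + enrich --------------------------------------------------------
  marker_counts <- marker_set_counts(sims[[1]]$markers, base$sets,
                                     base$genes, config$window_bp)
  grid <- run_grid(gwas, base$sets, base$genes,
                   window_bp = config$window_bp, n_perm = config$n_perm,
                   seed = as.integer(derive_seed(config$seed, 2000)))
  readr::write_tsv(marker_counts,
                   file.path(outdir, "results", "marker_counts.tsv"))
  readr::write_tsv(tibble::as_tibble(grid),
                   file.path(outdir, "results", "enrichment_grid.tsv"))

  # -- cell-state scoring --------------------------------------------------
  norm <- normalize_cells(sc$counts)
  scores <- cycle_score(norm, sc$panels)
  flags <- classify_proliferating(scores, sc$cell_meta,
                                  threshold = config$proliferation_threshold)
  ci <- cycle_index(flags, sc$cell_meta,
                    group_by = c("cluster", "timepoint"))
  modules <- sc$panels[!sc$panels$panel_id %in% c("G1S", "G2M"), ]
  mono <- sc$cell_meta$cell_id[sc$cell_meta$cluster ==
                                 sc$cell_meta$cluster[1]]
  ms <- module_score(norm[, colnames(norm) %in% mono, drop = FALSE],
                     sc$cell_meta, modules, group_by = "timepoint")
  patterns <- classify_module_trajectories(ms, config$trajectory_tolerance)
  pc <- pseudocell_aggregate(norm, sc$cell_meta,
                             size = config$pseudocell_size,
                             n_pseudocells = config$n_pseudocells,
                             seed = as.integer(derive_seed(config$seed, 3000)))
  readr::write_tsv(flags, file.path(outdir, "results", "cycle_flags.tsv"))
  readr::write_tsv(ci, file.path(outdir, "results", "cycle_index.tsv"))
  readr::write_tsv(tibble::as_tibble(ms),
                   file.path(outdir, "results", "module_scores.tsv"))
  readr::write_tsv(patterns,
                   file.path(outdir, "results", "module_patterns.tsv"))
  pc_out <- dplyr::bind_cols(tibble::tibble(gene_id = rownames(pc$matrix)),
                             tibble::as_tibble(pc$matrix))
  readr::write_tsv(pc_out, file.path(outdir, "results", "pseudocells.tsv"))

  # -- manifest ------------------------------------------------------------
  files <- sort(setdiff(list.files(outdir, recursive = TRUE),
                        "manifest.json"))
  manifest <- list(
    package = "cellgwas",
    version = as.character(utils::packageVersion("cellgwas")),
    seed = config$seed,
    parameters = config_as_list(config),
    outputs = as.list(setNames(
      unname(tools::md5sum(file.path(outdir, files))), files))
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(gwas_sim = sims, sc_sim = sc,
                 marker_counts = marker_counts, grid = grid, flags = flags,
                 cycle_index = ci, module_scores = ms,
                 module_patterns = patterns, pseudocells = pc,
                 manifest = manifest))
}

# Flatten a pipeline_config into plain lists for the JSON manifest.
config_as_list <- function(config) {
  out <- unclass(config)
  out$gwas_sim <- unclass(out$gwas_sim)
  out$sc_sim <- unclass(out$sc_sim)
  out$sc_sim$cycling_fraction <- as.list(out$sc_sim$cycling_fraction)
  out$outdir <- NULL  # path is machine-specific, not a parameter
  out
}
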