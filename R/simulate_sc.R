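#' Configuration for the synthetic single-cell count generator
#'
#' Bundles and validates the parameters of [simulate_sc()]. The generator
#' emulates the features of an LPS-stimulation time-course experiment that
#' the cell-state scoring stages consume: clusters (cell types) observed at
#' ordered time points, a cycling subpopulation per cluster with elevated
#' expression of the cell-cycle gene panel, and gene modules whose
#' per-time-point mean expression follows configured trajectories.
#'
#' Counts follow a negative binomial with mean `mu` and variance
#' `mu + nb_dispersion * mu^2` (the standard scRNA-seq noise model).
#' The default time points mirror an LPS challenge sampled before
#' stimulation and at 2, 4 and 8 hours, and the default module
#' trajectories encode the canonical contrast between transient programs
#' (core antiviral and peaked inflammatory: rise to a 4-hour maximum, back
#' to baseline by 8 hours) and the sustained inflammatory program (rise
#' and hold through 4 hours with only a slight decline at 8 hours).
#'
#' @param n_genes Number of genes in the simulated matrix.
#' @param n_cells_per_group Cells per (cluster x time point) group.
#' @param cluster_labels Character vector of cluster (cell-type) labels.
#' @param timepoint_labels Ordered character vector of time-point labels.
#' @param cycling_fraction Named numeric vector, one value in `[0, 1]` per
#'   cluster: the fraction of that cluster's cells that truly cycle.
#' @param cycle_effect Mean multiplier (> 1) applied to cell-cycle panel
#'   genes in cycling cells.
#' @param module_trajectories Named list, one numeric vector per module
#'   panel giving the mean multiplier at each time point (all > 0, length
#'   equal to `length(timepoint_labels)`).
#' @param nb_dispersion Negative-binomial dispersion (> 0).
#' @param baseline_mean Baseline mean count per gene per cell (> 0).
#' @param seed Integer seed.
#' @return A validated list of class `sc_sim_config`.
#' @seealso [simulate_sc()], [example_panels()]
#' @export
sc_sim_config <- function(n_genes = 1000,
                          n_cells_per_group = 200,
                          cluster_labels = c("monocyte", "CD4T", "B"),
                          timepoint_labels = c("Control", "LPS_2h",
                                               "LPS_4h", "LPS_8h"),
                          cycling_fraction = c(monocyte = 0.2, CD4T = 0.4,
                                               B = 0.5),
                          cycle_effect = 5,
                          module_trajectories = list(
                            core_antiviral = c(1, 2.2, 3.0, 1.1),
                            peaked_inflammatory = c(1, 2.8, 3.5, 1.2),
                            sustained_inflammatory = c(1, 2.2, 3.0, 2.6)),
                          nb_dispersion = 0.4,
                          baseline_mean = 2,
                          seed = 1) {
  cluster_labels <- as.character(cluster_labels)
  timepoint_labels <- as.character(timepoint_labels)
  if (length(cluster_labels) < 1L || anyDuplicated(cluster_labels)) {
    rlang::abort("`cluster_labels` must be a non-empty set of unique labels.")
  }
  if (length(timepoint_labels) < 1L || anyDuplicated(timepoint_labels)) {
    rlang::abort("`timepoint_labels` must be non-empty, unique, and ordered.")
  }
  if (!all(cluster_labels %in% names(cycling_fraction))) {
    rlang::abort("`cycling_fraction` must be named with every cluster label.")
  }
  cycling_fraction <- cycling_fraction[cluster_labels]
  if (any(cycling_fraction < 0 | cycling_fraction > 1)) {
    rlang::abort("`cycling_fraction` values must lie in [0, 1].")
  }
  for (mod in names(module_trajectories)) {
    tr <- module_trajectories[[mod]]
    if (length(tr) != length(timepoint_labels) || any(!is.finite(tr)) ||
        any(tr <= 0)) {
      rlang::abort(sprintf(
        "`module_trajectories[['%s']]` must be %d positive multipliers.",
        mod, length(timepoint_labels)))
    }
  }
  structure(list(
    n_genes = check_count(n_genes, "n_genes"),
    n_cells_per_group = check_count(n_cells_per_group, "n_cells_per_group"),
    cluster_labels = cluster_labels,
    timepoint_labels = timepoint_labels,
    cycling_fraction = cycling_fraction,
    cycle_effect = check_number(cycle_effect, "cycle_effect", min = 1,
                                strict_min = TRUE),
    module_trajectories = module_trajectories,
    nb_dispersion = check_number(nb_dispersion, "nb_dispersion", min = 0,
                                 strict_min = TRUE),
    baseline_mean = check_number(baseline_mean, "baseline_mean", min = 0,
                                 strict_min = TRUE),
    seed = check_count(seed, "seed", min = 0L)
  ), class = "sc_sim_config")
}

#' Example gene panels for a simulated genome
#'
#' Carves disjoint gene panels out of the first genes of a simulated
#' matrix: a cell-cycle panel of 43 G1/S plus 55 G2/M genes (the panel
#' sizes used in bovine PBMC cell-cycle scoring) and three LPS-response
#' modules (core antiviral, peaked inflammatory, sustained inflammatory).
#' Gene ids follow the `g%04d` naming of [simulate_sc()]. Panel content is
#' interchangeable for exercising the scoring code: any disjoint lists of
#' these sizes behave identically.
#'
#' @param n_genes Total genes in the simulated matrix; must be at least
#'   `98 + 3 * module_size`.
#' @param module_size Genes per LPS-response module.
#' @return A tibble with columns `panel_id` (one of `G1S`, `G2M`,
#'   `core_antiviral`, `peaked_inflammatory`, `sustained_inflammatory`)
#'   and `gene_id`.
#' @export
example_panels <- function(n_genes = 1000, module_size = 50) {
  n_genes <- check_count(n_genes, "n_genes")
  module_size <- check_count(module_size, "module_size")
  sizes <- c(G1S = 43L, G2M = 55L, core_antiviral = module_size,
             peaked_inflammatory = module_size,
             sustained_inflammatory = module_size)
  if (sum(sizes) > n_genes) {
    rlang::abort(sprintf("need n_genes >= %d to carve disjoint panels.",
                         sum(sizes)))
  }
  tibble::tibble(
    panel_id = rep(names(sizes), times = sizes),
    gene_id = sprintf("g%04d", seq_len(sum(sizes)))
  )
}

#' Simulate a single-cell count matrix with known cell-state ground truth
#'
#' Draws a genes x cells negative-binomial count matrix over a
#' cluster-by-time-point design. A configured fraction of each cluster's
#' cells is flagged as truly cycling and has its cell-cycle panel
#' (`G1S` + `G2M`) means multiplied by `cycle_effect`; module panel genes
#' have their means scaled per time point by the configured trajectories.
#' The true cycling flag is returned in the cell metadata so recovery
#' tests need no side channel.
#'
#' The number of cycling cells per (cluster x time point) group is
#' `round(fraction * n_cells_per_group)`, so the realised per-cluster
#' cycling fraction equals the configured one up to rounding.
#'
#' @param config An [sc_sim_config()].
#' @param panels Panel tibble (`panel_id`, `gene_id`) as from
#'   [example_panels()]; must contain `G1S` and `G2M`, plus one panel per
#'   name in `config$module_trajectories`. Panels must be disjoint and
#'   reference genes within the simulated matrix.
#' @return A list of class `sc_sim` with `counts` (sparse dgCMatrix,
#'   genes x cells, dimnames set), `cell_meta` (tibble `cell_id, cluster,
#'   timepoint, true_cycling`), `genes` (tibble `gene_id`), and `panels`.
#' @examples
#' sim <- simulate_sc(sc_sim_config(n_cells_per_group = 50))
#' dim(sim$counts)
#' @export
simulate_sc <- function(config, panels = example_panels(config$n_genes)) {
  stopifnot(inherits(config, "sc_sim_config"))
  panels <- tibble::as_tibble(panels)
  check_columns(panels, c("panel_id", "gene_id"), "panels")
  gene_ids <- sprintf("g%04d", seq_len(config$n_genes))
  if (!all(panels$gene_id %in% gene_ids)) {
    rlang::abort("panel genes must reference genes within `n_genes`.")
  }
  if (anyDuplicated(panels$gene_id)) {
    rlang::abort("panels must be disjoint: a gene appears in two panels.")
  }
  needed <- c("G1S", "G2M", names(config$module_trajectories))
  missing <- setdiff(needed, unique(panels$panel_id))
  if (length(missing) > 0L) {
    rlang::abort(sprintf("panels missing: %s.",
                         paste(missing, collapse = ", ")))
  }

  cycle_idx <- match(panels$gene_id[panels$panel_id %in% c("G1S", "G2M")],
                     gene_ids)
  module_idx <- lapply(names(config$module_trajectories), function(mod) {
    match(panels$gene_id[panels$panel_id == mod], gene_ids)
  })
  names(module_idx) <- names(config$module_trajectories)

  n_grp <- config$n_cells_per_group
  design <- expand.grid(timepoint = config$timepoint_labels,
                        cluster = config$cluster_labels,
                        stringsAsFactors = FALSE)[, c("cluster", "timepoint")]
  n_cells <- nrow(design) * n_grp

  counts <- matrix(0L, nrow = config$n_genes, ncol = n_cells)
  meta <- vector("list", nrow(design))
  with_seed(config$seed, {
    for (g in seq_len(nrow(design))) {
      cl <- design$cluster[g]
      tp <- design$timepoint[g]
      tp_i <- match(tp, config$timepoint_labels)
      mu_gene <- rep(config$baseline_mean, config$n_genes)
      for (mod in names(module_idx)) {
        mu_gene[module_idx[[mod]]] <- mu_gene[module_idx[[mod]]] *
          config$module_trajectories[[mod]][tp_i]
      }
      mu <- matrix(mu_gene, nrow = config$n_genes, ncol = n_grp)
      n_cyc <- round(config$cycling_fraction[[cl]] * n_grp)
      cyc <- rep(FALSE, n_grp)
      if (n_cyc > 0) {
        cyc[sample.int(n_grp, n_cyc)] <- TRUE
        mu[cycle_idx, cyc] <- mu[cycle_idx, cyc] * config$cycle_effect
      }
      draw <- rnbinom(length(mu), mu = mu, size = 1 / config$nb_dispersion)
      cols <- (g - 1L) * n_grp + seq_len(n_grp)
      counts[, cols] <- draw
      meta[[g]] <- tibble::tibble(
        cell_id = sprintf("cell%05d", cols),
        cluster = cl, timepoint = tp, true_cycling = cyc)
    }
  })
  cell_meta <- dplyr::bind_rows(meta)
  cell_meta$timepoint <- factor(cell_meta$timepoint,
                                levels = config$timepoint_labels)
  dimnames(counts) <- list(gene_ids, cell_meta$cell_id)
  structure(list(
    counts = as_sparse(counts),
    cell_meta = cell_meta,
    genes = tibble::tibble(gene_id = gene_ids),
    panels = panels
  ), class = "sc_sim")
}
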