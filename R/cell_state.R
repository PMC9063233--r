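#' Depth-normalize and log-transform a count matrix
#'
#' Scales each cell's counts to the median total count across cells and
#' applies `log(1 + x)`. Cells with zero total count cannot be scaled and
#' are dropped with a message. This is the expression scale on which all
#' cell-state scoring in the package operates.
#'
#' @param counts Genes x cells matrix (dense or sparse `Matrix`), with
#'   dimnames; counts must be non-negative.
#' @return A sparse genes x cells matrix of normalized values, with
#'   attributes `size_factors` (named, per retained cell: total / median
#'   total) and `dropped_cells` (character vector of removed cell ids).
#' @export
normalize_cells <- function(counts) {
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    rlang::abort("`counts` must have gene rownames and cell colnames.")
  }
  counts <- as_sparse(counts)
  if (any(counts@x < 0)) rlang::abort("`counts` must be non-negative.")
  depth <- Matrix::colSums(counts)
  drop <- depth == 0
  if (any(drop)) {
    rlang::inform(sprintf("normalize_cells: dropped %d cell(s) with zero counts.",
                          sum(drop)))
    counts <- counts[, !drop, drop = FALSE]
    depth <- depth[!drop]
  }
  sf <- depth / median(depth)
  norm <- counts %*% Matrix::Diagonal(x = 1 / sf)
  dimnames(norm) <- dimnames(counts)
  norm@x <- log1p(norm@x)
  attr(norm, "size_factors") <- setNames(sf, colnames(counts))
  attr(norm, "dropped_cells") <- names(drop)[drop]
  norm
}

#' Per-cell cell-cycle score
#'
#' The mean normalized expression of the cell-cycle panel (the union of
#' the G1/S and G2/M gene lists) in every single cell. Panel genes absent
#' from the matrix are dropped from the denominator with a message; if no
#' panel gene is present the call errors, naming the panel.
#'
#' @param norm Normalized genes x cells matrix from [normalize_cells()].
#' @param panel_genes Character vector of panel gene ids, or a panel
#'   tibble (`panel_id`, `gene_id`) from which the `G1S` and `G2M` rows
#'   are taken.
#' @param panel_name Label used in messages; default "cell-cycle".
#' @return A tibble `cell_id, score`.
#' @export
cycle_score <- function(norm, panel_genes, panel_name = "cell-cycle") {
  if (is.data.frame(panel_genes)) {
    check_columns(panel_genes, c("panel_id", "gene_id"), "panel_genes")
    panel_genes <- panel_genes$gene_id[panel_genes$panel_id %in%
                                         c("G1S", "G2M")]
  }
  panel_genes <- unique(as.character(panel_genes))
  present <- intersect(panel_genes, rownames(norm))
  if (length(present) == 0L) {
    rlang::abort(sprintf("no gene of the %s panel is present in the matrix.",
                         panel_name))
  }
  if (length(present) < length(panel_genes)) {
    rlang::inform(sprintf("cycle_score: %d %s panel gene(s) absent, dropped.",
                          length(panel_genes) - length(present), panel_name))
  }
  tibble::tibble(
    cell_id = colnames(norm),
    score = unname(Matrix::colMeans(norm[present, , drop = FALSE]))
  )
}

#' Classify actively proliferating cells
#'
#' A cell is flagged as actively proliferating when its cell-cycle score
#' is strictly greater than the reference threshold: by default the
#' unweighted mean over clusters of the within-cluster mean score (so
#' small clusters weigh as much as large ones), with the grand mean over
#' all cells available as the alternative reading of "the average values
#' of all clusters".
#'
#' @param scores Tibble `cell_id, score` from [cycle_score()].
#' @param meta Cell metadata with `cell_id` and `cluster` columns.
#' @param threshold `"cluster_mean"` (default) or `"grand_mean"`.
#' @return A tibble `cell_id, cluster, score, proliferating`, one row per
#'   scored cell, with the threshold in attribute `threshold`.
#' @export
classify_proliferating <- function(scores, meta,
                                   threshold = c("cluster_mean",
                                                 "grand_mean")) {
  threshold <- match.arg(threshold)
  check_columns(scores, c("cell_id", "score"), "scores")
  check_columns(meta, c("cell_id", "cluster"), "meta")
  df <- dplyr::inner_join(scores,
                          dplyr::select(meta, "cell_id", "cluster"),
                          by = "cell_id")
  if (nrow(df) < nrow(scores)) {
    rlang::abort("every scored cell must have a cluster label in `meta`.")
  }
  tau <- if (threshold == "cluster_mean") {
    cl_means <- dplyr::summarise(dplyr::group_by(df, .data$cluster),
                                 m = mean(.data$score))
    mean(cl_means$m)
  } else {
    mean(df$score)
  }
  out <- dplyr::mutate(df, proliferating = .data$score > tau)
  out <- dplyr::select(out, "cell_id", "cluster", "score", "proliferating")
  attr(out, "threshold") <- tau
  out
}

#' Cell-cycle index per group
#'
#' The ratio of actively proliferating cells within each group — per
#' cluster, per sample/time point, or per their cross — the quantity
#' reported as the cell-cycle index of each cell type or treatment time
#' point. Groups with zero cells are omitted.
#'
#' @param flags Tibble from [classify_proliferating()] (needs `cell_id`
#'   and `proliferating`).
#' @param meta Cell metadata carrying the grouping columns.
#' @param group_by Character vector of metadata column names to group by,
#'   e.g. `"cluster"`, `"timepoint"`, or `c("cluster", "timepoint")`.
#' @return A tibble of the grouping columns plus `n_cells,
#'   n_proliferating, cycle_index` with `cycle_index` in `[0, 1]`.
#' @export
cycle_index <- function(flags, meta, group_by = "cluster") {
  check_columns(flags, c("cell_id", "proliferating"), "flags")
  missing <- setdiff(group_by, names(meta))
  if (length(missing) > 0L) {
    rlang::abort(sprintf("unknown grouping column(s): %s.",
                         paste(missing, collapse = ", ")))
  }
  df <- dplyr::inner_join(
    dplyr::select(flags, "cell_id", "proliferating"),
    dplyr::select(meta, dplyr::all_of(c("cell_id", group_by))),
    by = "cell_id")
  dplyr::summarise(
    dplyr::group_by(df, dplyr::across(dplyr::all_of(group_by))),
    n_cells = dplyr::n(),
    n_proliferating = sum(.data$proliferating),
    cycle_index = mean(.data$proliferating),
    .groups = "drop")
}

#' Scaled module scores over groups
#'
#' For each gene of each module panel: the mean normalized expression per
#' group (typically per time point, within one cell type the caller has
#' subset to), z-scaled across groups using the population SD (divide by
#' n groups). The module score per group is the mean of its genes' scaled
#' values; genes with zero variance across groups contribute 0. This is
#' the computation behind scaled-expression heatmaps of gene modules over
#' a treatment time course.
#'
#' @param norm Normalized genes x cells matrix from [normalize_cells()].
#' @param meta Cell metadata with `cell_id` and the `group_by` column;
#'   if that column is a factor its level order defines the group order,
#'   otherwise order of first appearance.
#' @param panels Panel tibble (`panel_id`, `gene_id`); every distinct
#'   `panel_id` is scored as one module.
#' @param group_by Name of the grouping column; default `"timepoint"`.
#' @return A tibble of class `module_scores` with columns `module, group,
#'   score` (`group` a factor in group order); per-gene scaled values in
#'   attribute `gene_scores`.
#' @export
module_score <- function(norm, meta, panels, group_by = "timepoint") {
  check_columns(meta, c("cell_id", group_by), "meta")
  check_columns(panels, c("panel_id", "gene_id"), "panels")
  cells <- intersect(colnames(norm), meta$cell_id)
  if (length(cells) == 0L) rlang::abort("no cell of `norm` appears in `meta`.")
  grp_all <- meta[[group_by]][match(cells, meta$cell_id)]
  levels <- if (is.factor(grp_all)) levels(grp_all) else unique(as.character(grp_all))
  grp <- factor(as.character(grp_all), levels = levels)

  modules <- unique(panels$panel_id)
  gene_rows <- list()
  scores <- list()
  for (mod in modules) {
    genes <- intersect(panels$gene_id[panels$panel_id == mod],
                       rownames(norm))
    if (length(genes) == 0L) {
      rlang::abort(sprintf("module '%s' has no gene present in the matrix.",
                           mod))
    }
    sub <- norm[genes, cells, drop = FALSE]
    # per-gene mean per group, then population-SD z-score across groups
    gm <- vapply(levels, function(lv) {
      Matrix::rowMeans(sub[, grp == lv, drop = FALSE])
    }, numeric(length(genes)))
    gm <- matrix(gm, nrow = length(genes),
                 dimnames = list(genes, levels))
    mu <- rowMeans(gm)
    sdp <- sqrt(rowMeans((gm - mu)^2))
    z <- (gm - mu) / ifelse(sdp > 0, sdp, 1)
    z[sdp == 0, ] <- 0
    gene_rows[[mod]] <- tibble::tibble(
      module = mod,
      gene_id = rep(genes, times = length(levels)),
      group = rep(levels, each = length(genes)),
      scaled = as.vector(z))
    scores[[mod]] <- tibble::tibble(module = mod, group = levels,
                                    score = unname(colMeans(z)))
  }
  out <- dplyr::bind_rows(scores)
  out$group <- factor(out$group, levels = levels)
  attr(out, "gene_scores") <- dplyr::bind_rows(gene_rows)
  class(out) <- c("module_scores", class(out))
  out
}

#' Classify the temporal pattern of a module trajectory
#'
#' Labels an ordered vector of per-time-point module scores as `"peaked"`
#' (maximum at an interior time point with the final score back within
#' `tolerance` of the first), `"sustained"` (maximum at an interior or
#' final time point with the final score remaining above the first by
#' more than `tolerance`), or `"flat"` otherwise. This encodes the
#' qualitative contrast between transient LPS-response programs that rise
#' and fall back to baseline and sustained programs that hold their
#' elevation through the last time point.
#'
#' @param scores Numeric vector of scores at >= 3 ordered time points.
#' @param tolerance Return-to-baseline tolerance in the same (scaled)
#'   units as the scores; default 0.25.
#' @return One of `"peaked"`, `"sustained"`, `"flat"`.
#' @examples
#' classify_trajectory(c(-1.0, 0.8, 1.0, -0.9))   # "peaked"
#' classify_trajectory(c(-1.2, 0.3, 0.9, 0.7))    # "sustained"
#' @export
classify_trajectory <- function(scores, tolerance = 0.25) {
  if (length(scores) < 3L || any(!is.finite(scores))) {
    rlang::abort("`scores` must be >= 3 finite ordered values.")
  }
  tolerance <- check_number(tolerance, "tolerance", min = 0)
  n <- length(scores)
  imax <- which.max(scores)
  interior <- imax > 1L && imax < n
  returns <- abs(scores[n] - scores[1]) <= tolerance
  holds <- scores[n] > scores[1] + tolerance
  if (interior && returns) return("peaked")
  if ((interior || imax == n) && holds) return("sustained")
  "flat"
}

#' Classify every module of a `module_scores` table
#'
#' @param ms A [module_score()] result.
#' @inheritParams classify_trajectory
#' @return A tibble `module, pattern`.
#' @export
classify_module_trajectories <- function(ms, tolerance = 0.25) {
  stopifnot(inherits(ms, "module_scores"))
  dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(ms), .data$module),
    pattern = classify_trajectory(.data$score[order(.data$group)],
                                  tolerance),
    .groups = "drop")
}
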