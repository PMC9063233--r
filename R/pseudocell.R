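#' Pseudocell aggregation within clusters
#'
#' Stabilizes expression profiles for co-expression analysis by averaging
#' fixed-size random samples of cells within each cluster: each
#' pseudocell is the per-gene mean of `size` cells sampled without
#' replacement in one draw; draws are independent (so a cell can recur
#' across pseudocells). Clusters with fewer than `size` cells are skipped
#' with a warning, mirroring the practice of excluding small cell types
#' from network construction.
#'
#' @param mat Genes x cells matrix (counts or normalized), with dimnames.
#' @param meta Cell metadata with `cell_id` and `cluster`.
#' @param size Cells averaged per pseudocell; default 100.
#' @param n_pseudocells Pseudocells per retained cluster; default 100.
#' @param seed Integer seed; the same seed reproduces the pseudocells
#'   exactly.
#' @return A list of class `pseudocell_set` with `matrix` (dense genes x
#'   pseudocells), `meta` (tibble `pseudocell_id, cluster`), and
#'   `skipped_clusters` (character).
#' @export
pseudocell_aggregate <- function(mat, meta, size = 100, n_pseudocells = 100,
                                 seed = 1) {
  size <- check_count(size, "size")
  n_pseudocells <- check_count(n_pseudocells, "n_pseudocells")
  check_columns(meta, c("cell_id", "cluster"), "meta")
  if (is.null(colnames(mat))) rlang::abort("`mat` must have cell colnames.")
  meta <- meta[meta$cell_id %in% colnames(mat), , drop = FALSE]
  clusters <- unique(meta$cluster)
  sizes <- table(meta$cluster)
  keep <- clusters[sizes[clusters] >= size]
  skipped <- setdiff(clusters, keep)
  if (length(skipped) > 0L) {
    rlang::warn(sprintf(
      "pseudocell_aggregate: skipped cluster(s) with < %d cells: %s.",
      size, paste(skipped, collapse = ", ")))
  }
  if (length(keep) == 0L) {
    rlang::abort(sprintf("no cluster has at least %d cells.", size))
  }
  blocks <- with_seed(seed, lapply(keep, function(cl) {
    cells <- meta$cell_id[meta$cluster == cl]
    sub <- mat[, cells, drop = FALSE]
    out <- vapply(seq_len(n_pseudocells), function(i) {
      pick <- sample.int(length(cells), size)
      Matrix::rowMeans(sub[, pick, drop = FALSE])
    }, numeric(nrow(mat)))
    matrix(out, nrow = nrow(mat))
  }))
  pm <- do.call(cbind, blocks)
  pmeta <- tibble::tibble(
    pseudocell_id = sprintf("pc_%s_%03d",
                            rep(keep, each = n_pseudocells),
                            rep(seq_len(n_pseudocells), length(keep))),
    cluster = rep(keep, each = n_pseudocells))
  dimnames(pm) <- list(rownames(mat), pmeta$pseudocell_id)
  structure(list(matrix = pm, meta = pmeta,
                 skipped_clusters = as.character(skipped)),
            class = "pseudocell_set")
}
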