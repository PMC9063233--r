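#' Resolve gene sets to genomic test windows
#'
#' Extends each gene interval of each set by `window_bp` on both sides
#' (clipped at position 0) to capture potential cis-regulatory variants,
#' the convention used when testing GWAS signal enrichment in gene lists.
#' Genes in a set that are absent from the annotation are dropped and
#' counted; sets in which no gene resolves are excluded from the output
#' and recorded so downstream reporting can flag them instead of crashing.
#'
#' All coordinates are 0-based half-open, the package's single internal
#' convention: a marker at 1-based position `p` lies in a window
#' `[start, end)` iff `start <= p - 1 < end`.
#'
#' @param sets Gene-set tibble with columns `set_id`, `gene_id`.
#' @param annotation Gene annotation tibble with columns
#'   `gene_id, chrom, start, end` (0-based half-open); `gene_id` unique.
#'   Strand, if present, is ignored: windows extend symmetrically.
#' @param window_bp Non-negative flank added to each side of the gene body;
#'   default 20000 (20-kb windows).
#' @return A tibble `set_id, gene_id, chrom, start, end` of windows, with
#'   attributes `n_unresolved` (named integer: dropped genes per set) and
#'   `excluded_sets` (character: sets with zero resolvable genes).
#' @examples
#' ann <- tibble::tibble(gene_id = "gA", chrom = "1",
#'                       start = 100000, end = 105000)
#' sets <- tibble::tibble(set_id = "s1", gene_id = "gA")
#' resolve_windows(sets, ann)  # window [80000, 125000)
#' @export
resolve_windows <- function(sets, annotation, window_bp = 20000) {
  sets <- tibble::as_tibble(sets)
  annotation <- tibble::as_tibble(annotation)
  check_columns(sets, c("set_id", "gene_id"), "sets")
  check_columns(annotation, c("gene_id", "chrom", "start", "end"),
                "annotation")
  if (anyDuplicated(annotation$gene_id)) {
    rlang::abort("`annotation` gene_ids must be unique.")
  }
  if (any(annotation$start < 0) || any(annotation$start >= annotation$end)) {
    rlang::abort("annotation intervals must satisfy 0 <= start < end.")
  }
  window_bp <- check_number(window_bp, "window_bp", min = 0)

  hit <- match(sets$gene_id, annotation$gene_id)
  unresolved <- tapply(is.na(hit), sets$set_id, sum)
  n_unresolved <- setNames(as.integer(unresolved), names(unresolved))
  if (sum(n_unresolved) > 0) {
    rlang::inform(sprintf(
      "resolve_windows: dropped %d gene(s) absent from the annotation.",
      sum(n_unresolved)))
  }

  keep <- !is.na(hit)
  windows <- tibble::tibble(
    set_id = sets$set_id[keep],
    gene_id = sets$gene_id[keep],
    chrom = annotation$chrom[hit[keep]],
    start = pmax(annotation$start[hit[keep]] - window_bp, 0),
    end = annotation$end[hit[keep]] + window_bp
  )
  excluded <- setdiff(unique(sets$set_id), unique(windows$set_id))
  if (length(excluded) > 0) {
    rlang::inform(sprintf(
      "resolve_windows: excluded set(s) with no resolvable genes: %s.",
      paste(excluded, collapse = ", ")))
  }
  attr(windows, "n_unresolved") <- n_unresolved
  attr(windows, "excluded_sets") <- excluded
  windows
}

#' Map genome-ordered markers into gene-set windows
#'
#' For each set, finds the de-duplicated set of marker indices (positions
#' into the genome-ordered marker vector) whose position falls inside any
#' of the set's windows. The cardinality of each index set is the m_f of
#' the sum-based enrichment statistic. A marker overlapped by the windows
#' of two genes of the same set counts once. Markers on chromosomes absent
#' from the annotation can never be in-set but keep their place in the
#' genome vector, where they participate in the rotation null.
#'
#' @param markers Marker tibble `marker_id, chrom, pos, b` (1-based `pos`),
#'   sorted by (chromosome, position) under the natural chromosome order —
#'   see [order_markers()].
#' @param windows Window tibble from [resolve_windows()].
#' @param chrom_order Optional explicit chromosome order for the sortedness
#'   check; defaults to [chrom_natural_order()] of the marker chromosomes.
#' @return Named list (one element per set id present in `windows`, in
#'   order of first appearance) of sorted unique integer indices into
#'   `markers`; an empty window table gives an empty list.
#' @export
markers_in_set <- function(markers, windows, chrom_order = NULL) {
  markers <- tibble::as_tibble(markers)
  check_columns(markers, c("marker_id", "chrom", "pos", "b"), "markers")
  check_columns(windows, c("set_id", "chrom", "start", "end"), "windows")
  assert_markers_sorted(markers, chrom_order)
  set_ids <- unique(windows$set_id)
  if (nrow(windows) == 0L) {
    return(stats::setNames(list(), character(0)))
  }
  # 0-based half-open [start, end) == 1-based closed [start + 1, end].
  gr_m <- GenomicRanges::GRanges(markers$chrom,
                                 IRanges::IRanges(markers$pos, width = 1L))
  gr_w <- GenomicRanges::GRanges(windows$chrom,
                                 IRanges::IRanges(windows$start + 1,
                                                  windows$end))
  ov <- GenomicRanges::findOverlaps(gr_m, gr_w)
  hit_set <- windows$set_id[S4Vectors::subjectHits(ov)]
  idx_by_set <- split(S4Vectors::queryHits(ov), hit_set)
  out <- lapply(set_ids, function(s) {
    sort(unique(idx_by_set[[s]])) %||% integer(0)
  })
  stats::setNames(out, set_ids)
}

#' Per-set marker-count table
#'
#' Convenience summary combining [resolve_windows()] and
#' [markers_in_set()]: one row per set with the number of genes that
#' resolved against the annotation and the number of markers m_f falling
#' inside the set's windows. Sets excluded for having no resolvable genes
#' appear with `n_genes = 0` and `m_f = 0`.
#'
#' @inheritParams markers_in_set
#' @inheritParams resolve_windows
#' @return A tibble `set_id, n_genes, m_f`.
#' @export
marker_set_counts <- function(markers, sets, annotation, window_bp = 20000) {
  windows <- resolve_windows(sets, annotation, window_bp)
  idx <- markers_in_set(markers, windows)
  n_genes <- table(windows$set_id)
  all_sets <- unique(sets$set_id)
  ng <- as.integer(n_genes[all_sets])
  tibble::tibble(
    set_id = all_sets,
    n_genes = ifelse(is.na(ng), 0L, ng),
    m_f = vapply(all_sets, function(s) length(idx[[s]]), integer(1),
                 USE.NAMES = FALSE)
  )
}
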