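# Readers and writers for the plain-text formats the package exchanges:
# GWAS summary TSV, BED/GFF3 gene annotation, gene-set and panel TSVs,
# and MatrixMarket single-cell bundles. Every writer's output round-trips
# through the matching reader.

#' Read / write GWAS summary statistics
#'
#' Tab-separated with a required header and columns `marker_id, chrom,
#' pos, b` (1-based positions, signed effects) plus optional `trait_id`.
#' On read, markers are sorted into the natural chromosome order so the
#' genome-ordered invariant holds from the start.
#'
#' @param path File path.
#' @param markers Marker tibble to write.
#' @param trait_id Optional trait label to attach when the file has no
#'   `trait_id` column.
#' @return `read_gwas_tsv()`: a genome-ordered marker tibble.
#'   `write_gwas_tsv()`: `path`, invisibly.
#' @export
read_gwas_tsv <- function(path, trait_id = NULL) {
  df <- readr::read_tsv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          chrom = readr::col_character()))
  check_columns(df, c("marker_id", "chrom", "pos", "b"), basename(path))
  if (!is.null(trait_id)) df$trait_id <- trait_id
  if (any(!is.finite(df$b))) rlang::abort("column `b` must be finite.")
  order_markers(df)
}

#' @rdname read_gwas_tsv
#' @export
write_gwas_tsv <- function(markers, path) {
  check_columns(markers, c("marker_id", "chrom", "pos", "b"), "markers")
  readr::write_tsv(markers, path)
  invisible(path)
}

#' Read / write gene annotation
#'
#' BED is 0-based half-open on disk and is kept so internally (columns 1-4
#' used: chrom, start, end, name; strand from column 6 when present).
#' GFF3 `gene` features are 1-based inclusive on disk and are converted to
#' the internal convention as `[start - 1, end)`; the gene id is taken
#' from the `ID`, `gene_id` or `Name` attribute, in that order. Import
#' goes through `rtracklayer`, the standard parser for both formats.
#'
#' @param path File path.
#' @param genes Annotation tibble (`gene_id, chrom, start, end`, 0-based
#'   half-open, optional `strand`) to write.
#' @return Readers: an annotation tibble `gene_id, chrom, start, end,
#'   strand` (0-based half-open). `write_genes_bed()`: `path`, invisibly.
#' @export
read_genes_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  tibble::tibble(
    gene_id = if (!is.null(gr$name)) as.character(gr$name)
              else sprintf("gene%05d", seq_along(gr)),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,  # back to BED 0-based
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr))
  )
}

#' @rdname read_genes_bed
#' @export
read_genes_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "GFF3")
  gr <- gr[gr$type == "gene"]
  if (length(gr) == 0L) rlang::abort("no `gene` features in GFF3 file.")
  meta <- S4Vectors::mcols(gr)
  id <- NULL
  for (field in c("ID", "gene_id", "Name")) {
    if (field %in% names(meta) && !all(is.na(meta[[field]]))) {
      id <- as.character(meta[[field]])
      break
    }
  }
  if (is.null(id)) rlang::abort("GFF3 gene features carry no usable id.")
  tibble::tibble(
    gene_id = id,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,  # 1-based inclusive -> 0-based
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr))
  )
}

#' @rdname read_genes_bed
#' @export
write_genes_bed <- function(genes, path) {
  check_columns(genes, c("gene_id", "chrom", "start", "end"), "genes")
  strand <- if ("strand" %in% names(genes)) {
    ifelse(genes$strand %in% c("+", "-"), genes$strand, "*")
  } else "*"
  gr <- GenomicRanges::GRanges(
    genes$chrom,
    IRanges::IRanges(genes$start + 1, genes$end),  # GRanges is 1-based
    strand = strand, name = genes$gene_id, score = 0L)
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read / write gene-set and panel tables
#'
#' Two-column TSVs with headers: gene sets carry `set_id, gene_id`,
#' panels carry `panel_id, gene_id`.
#'
#' @param path File path.
#' @param sets,panels Tibble to write.
#' @return Readers return the tibble; writers return `path`, invisibly.
#' @export
read_gene_sets <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  check_columns(df, c("set_id", "gene_id"), basename(path))
  df
}

#' @rdname read_gene_sets
#' @export
write_gene_sets <- function(sets, path) {
  check_columns(sets, c("set_id", "gene_id"), "sets")
  readr::write_tsv(sets[, c("set_id", "gene_id")], path)
  invisible(path)
}

#' @rdname read_gene_sets
#' @export
read_panels <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  check_columns(df, c("panel_id", "gene_id"), basename(path))
  df
}

#' @rdname read_gene_sets
#' @export
write_panels <- function(panels, path) {
  check_columns(panels, c("panel_id", "gene_id"), "panels")
  readr::write_tsv(panels[, c("panel_id", "gene_id")], path)
  invisible(path)
}

#' Read / write a single-cell expression bundle
#'
#' The on-disk layout is the conventional MatrixMarket trio plus
#' metadata: `matrix.mtx` (genes x cells sparse counts), `genes.tsv`
#' (one `gene_id` per row), `barcodes.tsv` (one `cell_id` per row) and
#' `cell_meta.tsv` (tab-separated, `cell_id` plus label columns such as
#' `cluster` and `timepoint`).
#'
#' @param dir Directory holding (or to hold) the bundle.
#' @param counts Genes x cells matrix with dimnames.
#' @param cell_meta Cell metadata tibble with a `cell_id` column matching
#'   the matrix columns.
#' @return `read_sc_bundle()`: a list with `counts` (dgCMatrix) and
#'   `cell_meta`. `write_sc_bundle()`: `dir`, invisibly.
#' @export
read_sc_bundle <- function(dir) {
  counts <- as_sparse(Matrix::readMM(file.path(dir, "matrix.mtx")))
  genes <- readr::read_tsv(file.path(dir, "genes.tsv"),
                           col_names = "gene_id", show_col_types = FALSE)
  cells <- readr::read_tsv(file.path(dir, "barcodes.tsv"),
                           col_names = "cell_id", show_col_types = FALSE)
  meta <- readr::read_tsv(file.path(dir, "cell_meta.tsv"),
                          show_col_types = FALSE)
  check_columns(meta, "cell_id", "cell_meta.tsv")
  if (nrow(genes) != nrow(counts) || nrow(cells) != ncol(counts)) {
    rlang::abort("matrix dimensions disagree with genes.tsv/barcodes.tsv.")
  }
  dimnames(counts) <- list(genes$gene_id, cells$cell_id)
  list(counts = counts, cell_meta = meta)
}

#' @rdname read_sc_bundle
#' @export
write_sc_bundle <- function(counts, cell_meta, dir) {
  check_columns(cell_meta, "cell_id", "cell_meta")
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    rlang::abort("`counts` must carry gene and cell dimnames.")
  }
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  Matrix::writeMM(as_sparse(counts), file.path(dir, "matrix.mtx"))
  readr::write_tsv(tibble::tibble(x = rownames(counts)),
                   file.path(dir, "genes.tsv"), col_names = FALSE)
  readr::write_tsv(tibble::tibble(x = colnames(counts)),
                   file.path(dir, "barcodes.tsv"), col_names = FALSE)
  readr::write_tsv(cell_meta, file.path(dir, "cell_meta.tsv"))
  invisible(dir)
}
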