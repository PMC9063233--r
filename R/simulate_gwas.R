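#' Configuration for the synthetic GWAS generator
#'
#' Bundles and validates the parameters of [simulate_gwas()]. The generator
#' emulates the substrate of the sum-based marker-set enrichment test:
#' a genome-ordered vector of signed single-marker effects with block-wise
#' correlation standing in for linkage disequilibrium (LD), and optional
#' variance inflation inside designated gene windows as the ground-truth
#' enrichment signal.
#'
#' Within each block of `ld_block_size` consecutive markers the effects are
#' generated from an equicorrelated factor model,
#' `b = effect_sd * (sqrt(ld_rho) * z_block + sqrt(1 - ld_rho) * z_marker)`,
#' which gives exact pairwise correlation `ld_rho` inside the block and
#' independence across blocks. Blocks never span chromosome boundaries.
#'
#' @param n_chromosomes Number of simulated chromosomes.
#' @param markers_per_chromosome Markers per chromosome.
#' @param marker_spacing_bp Distance in bp between consecutive markers;
#'   marker `i` on a chromosome sits at 1-based position
#'   `i * marker_spacing_bp`.
#' @param effect_sd Standard deviation of the baseline marker effect `b`.
#' @param ld_block_size Markers per correlated block (1 = independent).
#' @param ld_rho Pairwise correlation of effects within a block, in `[0, 1)`.
#' @param enrichment_lambda Multiplicative inflation of the effect SD for
#'   markers inside the gene bodies of enriched sets; must be >= 1, with 1
#'   meaning no enrichment.
#' @param seed Integer seed; identical config + seed gives byte-identical
#'   output.
#' @return A validated list of class `gwas_sim_config`.
#' @seealso [simulate_gwas()]
#' @export
gwas_sim_config <- function(n_chromosomes = 5,
                            markers_per_chromosome = 200,
                            marker_spacing_bp = 10000,
                            effect_sd = 0.1,
                            ld_block_size = 10,
                            ld_rho = 0.3,
                            enrichment_lambda = 1,
                            seed = 1) {
  cfg <- list(
    n_chromosomes = check_count(n_chromosomes, "n_chromosomes"),
    markers_per_chromosome = check_count(markers_per_chromosome,
                                         "markers_per_chromosome"),
    marker_spacing_bp = check_count(marker_spacing_bp, "marker_spacing_bp"),
    effect_sd = check_number(effect_sd, "effect_sd", min = 0,
                             strict_min = TRUE),
    ld_block_size = check_count(ld_block_size, "ld_block_size"),
    ld_rho = check_number(ld_rho, "ld_rho", min = 0, max = 1,
                          strict_max = TRUE),
    enrichment_lambda = check_number(enrichment_lambda, "enrichment_lambda",
                                     min = 1),
    seed = check_count(seed, "seed", min = 0L)
  )
  structure(cfg, class = "gwas_sim_config")
}

#' Simulate GWAS summary statistics with known enrichment ground truth
#'
#' Generates one trait's genome-ordered signed marker effects on a simulated
#' genome, together with a gene annotation and a gene-set catalog, so that
#' the marker-set enrichment test can be exercised offline with known truth.
#' When `genes`/`sets` are not supplied the generator fabricates contiguous
#' marker-aligned gene intervals and random gene sets on the simulated
#' genome. Markers falling inside the gene bodies of sets named in
#' `enriched_set_ids` have their effect SD multiplied by
#' `config$enrichment_lambda`.
#'
#' @param config A [gwas_sim_config()].
#' @param genes Optional gene annotation tibble with columns
#'   `gene_id, chrom, start, end, strand` (0-based half-open coordinates).
#' @param sets Optional gene-set tibble with columns `set_id, gene_id`.
#' @param enriched_set_ids Character vector of set ids whose gene-body
#'   markers receive inflated effects; must be a subset of the catalog.
#' @param trait_id Label stored in the `trait_id` column of the output.
#' @param n_sets,genes_per_set,gene_span_markers Shape of the fabricated
#'   catalog when `genes`/`sets` are `NULL`: number of sets, genes per set,
#'   and markers covered by each gene body.
#' @return A list of class `gwas_sim` with elements `markers` (tibble
#'   `marker_id, chrom, pos, b, trait_id`, genome-ordered), `genes`,
#'   `sets`, and `enriched_set_ids`.
#' @examples
#' sim <- simulate_gwas(gwas_sim_config(seed = 42))
#' head(sim$markers)
#' @export
simulate_gwas <- function(config,
                          genes = NULL,
                          sets = NULL,
                          enriched_set_ids = character(),
                          trait_id = "trait_1",
                          n_sets = 8,
                          genes_per_set = 6,
                          gene_span_markers = 5) {
  stopifnot(inherits(config, "gwas_sim_config"))
  if (xor(is.null(genes), is.null(sets))) {
    rlang::abort("supply both `genes` and `sets`, or neither.")
  }
  n_sets <- check_count(n_sets, "n_sets")
  genes_per_set <- check_count(genes_per_set, "genes_per_set")
  gene_span_markers <- check_count(gene_span_markers, "gene_span_markers")

  chroms <- as.character(seq_len(config$n_chromosomes))
  mpc <- config$markers_per_chromosome
  spacing <- config$marker_spacing_bp
  m <- config$n_chromosomes * mpc
  chrom_len_bp <- (mpc + 1) * spacing  # markers sit strictly inside

  markers <- tibble::tibble(
    marker_id = sprintf("m%06d", seq_len(m)),
    chrom = rep(chroms, each = mpc),
    pos = rep(seq_len(mpc) * spacing, times = config$n_chromosomes)
  )

  with_seed(config$seed, {
    if (is.null(genes)) {
      fab <- fabricate_catalog(chroms, mpc, spacing, n_sets, genes_per_set,
                               gene_span_markers)
      genes <- fab$genes
      sets <- fab$sets
    } else {
      genes <- tibble::as_tibble(genes)
      sets <- tibble::as_tibble(sets)
      check_columns(genes, c("gene_id", "chrom", "start", "end"), "genes")
      check_columns(sets, c("set_id", "gene_id"), "sets")
      if (!"strand" %in% names(genes)) genes$strand <- "."
      bad <- !(genes$chrom %in% chroms) | genes$start < 0 |
        genes$end > chrom_len_bp | genes$start >= genes$end
      if (any(bad)) {
        rlang::abort(sprintf(
          "gene(s) outside the simulated genome or malformed: %s",
          paste(head(genes$gene_id[bad], 5L), collapse = ", ")))
      }
    }
    if (length(enriched_set_ids) > 0 &&
        !all(enriched_set_ids %in% sets$set_id)) {
      rlang::abort("`enriched_set_ids` must name sets present in the catalog.")
    }

    # Equicorrelated block factor model for the LD proxy.
    rho <- config$ld_rho
    block_within <- (seq_len(mpc) - 1L) %/% config$ld_block_size
    block <- rep(block_within, times = config$n_chromosomes) +
      rep((seq_len(config$n_chromosomes) - 1L) * (max(block_within) + 1L),
          each = mpc)
    z_block <- rnorm(length(unique(block)))[match(block, unique(block))]
    z_marker <- rnorm(m)
    b <- config$effect_sd * (sqrt(rho) * z_block + sqrt(1 - rho) * z_marker)

    if (length(enriched_set_ids) > 0 && config$enrichment_lambda > 1) {
      enriched_sets <- sets[sets$set_id %in% enriched_set_ids, , drop = FALSE]
      win <- resolve_windows(enriched_sets, genes, window_bp = 0)
      idx <- unique(unlist(markers_in_set(
        dplyr::mutate(markers, b = 0), win), use.names = FALSE))
      b[idx] <- b[idx] * config$enrichment_lambda
    }
    markers$b <- b
  })

  markers$trait_id <- trait_id
  structure(list(markers = markers, genes = genes, sets = sets,
                 enriched_set_ids = enriched_set_ids),
            class = "gwas_sim")
}

# Fabricate non-overlapping marker-aligned gene intervals and random sets.
# Genes occupy disjoint slots of `span` consecutive markers; the interval is
# 0-based half-open and covers exactly those markers' positions.
fabricate_catalog <- function(chroms, mpc, spacing, n_sets, genes_per_set,
                              span) {
  n_genes <- n_sets * genes_per_set
  slots_per_chrom <- mpc %/% span
  total_slots <- slots_per_chrom * length(chroms)
  if (n_genes > total_slots) {
    rlang::abort(sprintf(
      "cannot place %d genes of %d markers each: only %d slots available.",
      n_genes, span, total_slots))
  }
  slot <- sort(sample.int(total_slots, n_genes))
  slot_chrom <- chroms[(slot - 1L) %/% slots_per_chrom + 1L]
  slot_within <- (slot - 1L) %% slots_per_chrom  # 0-based slot on chrom
  first_marker <- slot_within * span + 1L
  last_marker <- first_marker + span - 1L
  genes <- tibble::tibble(
    gene_id = sprintf("gene%04d", seq_len(n_genes)),
    chrom = slot_chrom,
    start = first_marker * spacing - 1L,  # 0-based: includes first marker pos
    end = last_marker * spacing,          # half-open: includes last marker pos
    strand = "."
  )
  sets <- tibble::tibble(
    set_id = rep(sprintf("set%02d", seq_len(n_sets)), each = genes_per_set),
    gene_id = sample(genes$gene_id)
  )
  list(genes = genes, sets = dplyr::arrange(sets, .data$set_id))
}
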