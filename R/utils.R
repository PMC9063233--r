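# Internal helpers: argument checks, chromosome ordering, seed derivation.

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    rlang::abort(sprintf("`%s` must be a single integer >= %d.", name, min))
  }
  as.integer(x)
}

check_number <- function(x, name, min = -Inf, max = Inf,
                         strict_min = FALSE, strict_max = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (strict_min) x > min else x >= min) &&
    (if (strict_max) x < max else x <= max)
  if (!ok) {
    rlang::abort(sprintf("`%s` must be a single finite number in %s%s, %s%s.",
                         name,
                         if (strict_min) "(" else "[", format(min),
                         format(max), if (strict_max) ")" else "]"))
  }
  as.numeric(x)
}

check_columns <- function(df, cols, name) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    rlang::abort(sprintf("`%s` is missing required column(s): %s.",
                         name, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

#' Natural chromosome order
#'
#' Orders chromosome labels so that numeric chromosomes come first in
#' numeric order (1, 2, ..., 10, ...) followed by non-numeric labels
#' (X, Y, MT, ...) alphabetically. One fixed genome ordering is required
#' by the cyclical-permutation null, which rotates a single genome-wide
#' vector of squared effects.
#'
#' @param chroms Character vector of chromosome labels (duplicates allowed).
#' @return Character vector of the unique labels in natural order.
#' @examples
#' chrom_natural_order(c("10", "2", "X", "1"))
#' @export
chrom_natural_order <- function(chroms) {
  u <- unique(as.character(chroms))
  num <- suppressWarnings(as.numeric(u))
  c(u[!is.na(num)][order(num[!is.na(num)])], sort(u[is.na(num)]))
}

# Deterministic child seed for the rank-th unit of work under a root seed.
# Kept below 2^31 - 1 so it is always a valid R integer seed.
derive_seed <- function(root_seed, rank) {
  ((as.double(root_seed) %% 65011) * 2654435 + 7919 * as.double(rank)) %%
    2147483647
}

# Run `expr` under a fixed seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Sort a marker table by (chrom in natural order, pos); used by readers and
# generators so that downstream code can rely on one genome ordering.
order_markers <- function(markers, chrom_order = NULL) {
  check_columns(markers, c("marker_id", "chrom", "pos", "b"), "markers")
  chrom_order <- chrom_order %||% chrom_natural_order(markers$chrom)
  extra <- setdiff(unique(markers$chrom), chrom_order)
  if (length(extra) > 0L) {
    rlang::abort(sprintf("markers contain chromosome(s) not in `chrom_order`: %s",
                         paste(extra, collapse = ", ")))
  }
  ord <- order(match(markers$chrom, chrom_order), markers$pos)
  tibble::as_tibble(markers[ord, , drop = FALSE])
}

# Coerce dense or sparse input to dgCMatrix, keeping dimnames.
as_sparse <- function(x) {
  if (!methods::is(x, "Matrix")) x <- Matrix::Matrix(x, sparse = TRUE)
  methods::as(x, "CsparseMatrix")
}

assert_markers_sorted <- function(markers, chrom_order = NULL) {
  chrom_order <- chrom_order %||% chrom_natural_order(markers$chrom)
  key <- match(markers$chrom, chrom_order) * 2^40 + markers$pos
  if (is.unsorted(key)) {
    rlang::abort(paste0("markers must be sorted by (chromosome, position) under ",
                        "the declared chromosome order; see `order_markers()`."))
  }
  invisible(markers)
}
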