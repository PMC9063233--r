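#' Sum-based marker-set statistic
#'
#' The observed statistic of the marker-set enrichment test: the sum of
#' squared single-marker GWAS effects over the markers of a gene set,
#' `T_sum = sum(b^2)` over the `m_f` in-set markers.
#'
#' @param b Numeric vector of signed marker effects, genome-ordered.
#' @param idx Integer vector of 1-based in-set marker indices (as from
#'   [markers_in_set()]); may be empty, giving 0.
#' @return The statistic, a single non-negative number.
#' @examples
#' t_sum(c(1, -2, 3, 4), c(1, 2))  # 1 + 4 = 5
#' @export
t_sum <- function(b, idx) {
  stopifnot(is.numeric(b), all(is.finite(b)))
  if (length(idx) == 0L) return(0)
  idx <- as.integer(idx)
  if (any(idx < 1L) || any(idx > length(b)) || anyNA(idx)) {
    rlang::abort("`idx` must index into `b` (1-based).")
  }
  sum(b[idx]^2)
}

#' Rotate the genome-ordered squared-effect vector
#'
#' One step of the cyclical (genotype) permutation: marker `k` (0-based
#' offset) is designated the new first marker and the remaining squared
#' effects follow in their original order, wrapping around the genome.
#' Gene-set index positions stay fixed at their original chromosome
#' locations; only the effect vector moves. Rotation preserves the
#' multiset of values, and hence the total sum, which is what makes the
#' null LD-preserving.
#'
#' @param b2 Numeric vector (genome-ordered squared effects).
#' @param k Integer offset in `0:(length(b2) - 1)`; 0 is the identity.
#' @return The rotated vector `c(b2[(k+1):m], b2[1:k])`.
#' @examples
#' rotate_effects(c(1, 2, 3), 1)  # 2 3 1
#' @export
rotate_effects <- function(b2, k) {
  m <- length(b2)
  k <- check_count(k, "k", min = 0L)
  if (k >= m) rlang::abort("`k` must lie in 0:(length(b2) - 1).")
  if (k == 0L) return(b2)
  c(b2[(k + 1L):m], b2[seq_len(k)])
}

# T_sum of every rotation offset in `ks`, without materialising rotations:
# T(k) = sum over i in idx of b2[((i - 1 + k) mod m) + 1]. Chunked to bound
# memory at ~ m_f x 2000 doubles.
rotation_stats <- function(b2, idx, ks) {
  m <- length(b2)
  i0 <- as.integer(idx) - 1L
  out <- numeric(length(ks))
  chunk <- 2000L
  for (s in seq(1L, length(ks), by = chunk)) {
    e <- min(s + chunk - 1L, length(ks))
    pos <- outer(i0, ks[s:e], "+") %% m + 1L
    out[s:e] <- colSums(matrix(b2[pos], nrow = length(i0)))
  }
  out
}

#' Cyclical-permutation null distribution of the marker-set statistic
#'
#' Builds the null for one (trait, gene set) test by rotating the
#' genome-ordered squared-effect vector while holding the set's marker
#' positions fixed. When the number of distinct non-identity rotations
#' `m - 1` does not exceed `n_perm`, the null is enumerated exactly over
#' every rotation (`exact = TRUE`); otherwise `n_perm` offsets are sampled
#' uniformly with replacement from `1:(m - 1)` (the identity is never
#' drawn), matching the Monte-Carlo procedure of drawing 10,000 random
#' rotations.
#'
#' @param b Numeric vector of signed effects, genome-ordered (squared
#'   internally).
#' @param idx Non-empty integer vector of in-set marker indices.
#' @param n_perm Number of sampled rotations when not enumerating;
#'   default 10000.
#' @param seed Optional integer seed for the sampled case; the caller's
#'   RNG state is left untouched when supplied.
#' @param enumerate_all `TRUE`/`FALSE` to force, or `NULL` (default) for
#'   the automatic rule `m - 1 <= n_perm`.
#' @return A list with `t_null` (numeric vector of null statistics) and
#'   `exact` (logical).
#' @export
null_distribution <- function(b, idx, n_perm = 10000, seed = NULL,
                              enumerate_all = NULL) {
  m <- length(b)
  if (m < 2L) rlang::abort("need at least 2 markers to rotate.")
  if (length(idx) == 0L) {
    rlang::abort("`idx` is empty: the set test is undefined without markers.")
  }
  n_perm <- check_count(n_perm, "n_perm")
  b2 <- b^2
  exact <- enumerate_all %||% (m - 1L <= n_perm)
  if (exact) {
    ks <- seq_len(m - 1L)
  } else {
    draw <- function() sample.int(m - 1L, n_perm, replace = TRUE)
    ks <- if (is.null(seed)) draw() else with_seed(seed, draw())
  }
  list(t_null = rotation_stats(b2, idx, ks), exact = exact)
}

#' One-tailed empirical p-value against a permutation null
#'
#' The proportion of null statistics strictly greater than the observed
#' one, floored at `1/n` so that a p-value of exactly zero is never
#' reported to downstream FDR control. The unfloored exceedance count is
#' returned alongside so the alternative (unfloored, or >=) convention is
#' recoverable.
#'
#' @param t_obs Observed statistic.
#' @param t_null Non-empty numeric vector of null statistics.
#' @return A list with `p_emp` (in `(0, 1]`) and `n_exceed`
#'   (`sum(t_null > t_obs)`, strict).
#' @examples
#' empirical_p(3, c(5, 7, 5))  # p = 1, n_exceed = 3
#' @export
empirical_p <- function(t_obs, t_null) {
  stopifnot(length(t_null) > 0L, is.numeric(t_null))
  n_exceed <- sum(t_null > t_obs)
  list(p_emp = max(n_exceed, 1L) / length(t_null), n_exceed = n_exceed)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment across one family of tests
#' (all (trait, set) cells of a grid run). Thin, named wrapper over
#' `stats::p.adjust(method = "BH")` so the procedure used by the grid is
#' explicit and testable in one place.
#'
#' @param p Numeric vector of p-values in `(0, 1]`.
#' @return q-values of the same length; empty input gives empty output.
#' @export
fdr_adjust <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (any(!is.finite(p) | p <= 0 | p > 1)) {
    rlang::abort("all p-values must lie in (0, 1].")
  }
  p.adjust(p, method = "BH")
}

#' Run the full trait-by-gene-set enrichment grid
#'
#' For every (trait, set) pair: resolves the set's 20-kb gene windows,
#' maps markers, computes the observed `T_sum`, builds the
#' cyclical-permutation null, and reports the one-tailed empirical
#' p-value; q-values are Benjamini-Hochberg across every test of the run.
#' Sets with no in-set markers are reported with `NA` p and q and a
#' reason code rather than dropped silently. Per-(trait, set) seeds are
#' derived from `seed` by a fixed scheme over the sorted pair labels, so
#' results do not depend on iteration order.
#'
#' @param gwas Either one marker tibble with a `trait_id` column (several
#'   traits stacked) or a named list of marker tibbles, one per trait.
#' @param sets Gene-set tibble (`set_id`, `gene_id`).
#' @param annotation Gene annotation tibble (0-based half-open).
#' @param window_bp Flank around gene bodies; default 20000.
#' @param n_perm Rotations per test; default 10000. Tests where the
#'   marker count allows exact enumeration use it instead (flagged).
#' @param seed Root seed for sampled nulls.
#' @return A tibble of class `enrich_grid` with columns `trait_id,
#'   set_id, n_genes, m_f, t_obs, n_perm, n_exceed, p_emp, q_fdr, exact,
#'   note`, one row per (trait, set).
#' @seealso [tidy.enrich_grid()], [autoplot.enrich_grid()]
#' @export
run_grid <- function(gwas, sets, annotation, window_bp = 20000,
                     n_perm = 10000, seed = 1) {
  if (is.data.frame(gwas)) {
    check_columns(gwas, c("marker_id", "chrom", "pos", "b", "trait_id"),
                  "gwas")
    gwas <- split(tibble::as_tibble(gwas), gwas$trait_id)
  }
  if (length(gwas) == 0L || nrow(sets) == 0L) {
    rlang::abort("need at least one trait and one gene set.")
  }
  if (is.null(names(gwas)) || any(names(gwas) == "")) {
    names(gwas) <- vapply(gwas, function(g) g$trait_id[1], character(1))
  }
  windows <- resolve_windows(sets, annotation, window_bp)
  n_genes_by_set <- table(windows$set_id)
  all_sets <- unique(sets$set_id)
  idx_by_trait <- lapply(gwas, function(mk) markers_in_set(mk, windows))

  pairs <- tidyr::expand_grid(trait_id = names(gwas), set_id = all_sets)
  pairs <- dplyr::arrange(pairs, .data$trait_id, .data$set_id)
  pairs$rank <- seq_len(nrow(pairs))

  rows <- purrr::pmap(pairs, function(trait_id, set_id, rank) {
    markers <- gwas[[trait_id]]
    idx <- idx_by_trait[[trait_id]][[set_id]] %||% integer(0)
    ng <- n_genes_by_set[set_id]
    n_genes <- if (is.na(ng)) 0L else as.integer(ng)
    base <- tibble::tibble(trait_id = trait_id, set_id = set_id,
                           n_genes = n_genes, m_f = length(idx))
    if (length(idx) == 0L) {
      return(dplyr::mutate(base, t_obs = NA_real_, n_perm = 0L,
                           n_exceed = NA_integer_, p_emp = NA_real_,
                           exact = NA, note = "no_markers"))
    }
    nd <- null_distribution(markers$b, idx, n_perm = n_perm,
                            seed = derive_seed(seed, rank))
    ep <- empirical_p(t_sum(markers$b, idx), nd$t_null)
    dplyr::mutate(base, t_obs = t_sum(markers$b, idx),
                  n_perm = length(nd$t_null),
                  n_exceed = as.integer(ep$n_exceed), p_emp = ep$p_emp,
                  exact = nd$exact, note = "")
  })
  grid <- dplyr::bind_rows(rows)
  if (all(is.na(grid$p_emp))) {
    rlang::abort("no (trait, set) pair overlaps any marker; nothing to test.")
  }
  grid$q_fdr <- NA_real_
  ok <- !is.na(grid$p_emp)
  grid$q_fdr[ok] <- fdr_adjust(grid$p_emp[ok])
  grid <- grid[, c("trait_id", "set_id", "n_genes", "m_f", "t_obs",
                   "n_perm", "n_exceed", "p_emp", "q_fdr", "exact", "note")]
  class(grid) <- c("enrich_grid", class(grid))
  grid
}
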