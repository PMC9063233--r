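# Shared fixtures and independent oracles. Oracles are deliberately naive
# (linear scans, hand rules) and never call the code paths they check.

# Brute-force marker-to-window mapping: every marker against every window.
brute_markers_in_set <- function(markers, windows) {
  sets <- unique(windows$set_id)
  out <- lapply(sets, function(s) {
    w <- windows[windows$set_id == s, , drop = FALSE]
    hits <- vapply(seq_len(nrow(markers)), function(i) {
      pos0 <- markers$pos[i] - 1
      any(w$chrom == markers$chrom[i] & w$start <= pos0 & pos0 < w$end)
    }, logical(1))
    which(hits)
  })
  stats::setNames(out, sets)
}

# Benjamini-Hochberg step-up by the textbook formula:
# q_(i) = min_{j >= i} p_(j) * m / j, mapped back to input order.
bh_by_hand <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- pmin(rev(cummin(rev(p[ord] * m / seq_len(m)))), 1)
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

# Exact rotation null by materialising every rotated vector (slow path).
brute_rotation_null <- function(b2, idx) {
  m <- length(b2)
  vapply(seq_len(m - 1L), function(k) {
    rot <- c(b2[(k + 1):m], b2[seq_len(k)])
    sum(rot[idx])
  }, numeric(1))
}

# Small deterministic marker table on two chromosomes.
tiny_markers <- function() {
  tibble::tibble(
    marker_id = sprintf("m%02d", 1:8),
    chrom = rep(c("1", "2"), each = 4),
    pos = rep(c(10000L, 20000L, 30000L, 40000L), 2),
    b = c(0.1, -0.2, 0.3, 0.4, -0.5, 0.6, -0.7, 0.8)
  )
}

# Balanced accuracy of a binary classification.
balanced_accuracy <- function(truth, call) {
  sens <- mean(call[truth])
  spec <- mean(!call[!truth])
  (sens + spec) / 2
}

# Small single-cluster, single-timepoint simulation config used by several
# cell-state tests.
small_sc_config <- function(..., seed = 1) {
  sc_sim_config(
    n_genes = 300, n_cells_per_group = 80,
    cluster_labels = "A", timepoint_labels = "Control",
    cycling_fraction = c(A = 0.3),
    module_trajectories = list(core_antiviral = 1,
                               peaked_inflammatory = 1,
                               sustained_inflammatory = 1),
    ..., seed = seed)
}
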