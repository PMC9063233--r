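test_that("window arithmetic extends, clips at zero, and honours
           window_bp = 0", {
  ann <- tibble::tibble(
    gene_id = c("gA", "gB"), chrom = "1",
    start = c(100000, 5000), end = c(105000, 9000), strand = "+")
  sets <- tibble::tibble(set_id = c("s1", "s1"), gene_id = c("gA", "gB"))
  w <- resolve_windows(sets, ann, window_bp = 20000)
  expect_equal(w$start[w$gene_id == "gA"], 80000)
  expect_equal(w$end[w$gene_id == "gA"], 125000)
  expect_equal(w$start[w$gene_id == "gB"], 0)  # clipped
  expect_equal(w$end[w$gene_id == "gB"], 29000)
  w0 <- resolve_windows(sets, ann, window_bp = 0)
  expect_equal(w0$start, ann$start[match(w0$gene_id, ann$gene_id)])
  expect_equal(w0$end, ann$end[match(w0$gene_id, ann$gene_id)])
})

test_that("unresolvable genes are dropped with a count and empty sets are
           excluded, not fatal", {
  ann <- tibble::tibble(gene_id = "gA", chrom = "1",
                        start = 1000, end = 2000)
  sets <- tibble::tibble(set_id = c("s1", "s1", "s2"),
                         gene_id = c("gA", "missing1", "missing2"))
  expect_message(w <- resolve_windows(sets, ann), "dropped 2")
  expect_equal(attr(w, "n_unresolved")[["s1"]], 1L)
  expect_equal(attr(w, "excluded_sets"), "s2")
  expect_equal(unique(w$set_id), "s1")
})

test_that("membership uses the half-open convention and de-duplicates
           markers shared by genes of one set", {
  markers <- tibble::tibble(
    marker_id = sprintf("m%d", 1:3), chrom = "1",
    pos = c(79999L, 80001L, 125001L), b = c(1, 1, 1))
  win <- tibble::tibble(set_id = "s1", gene_id = "gA", chrom = "1",
                        start = 80000, end = 125000)
  idx <- markers_in_set(markers, win)
  expect_equal(idx$s1, 2L)  # 79999 (pos0 = 79998) and 125001 excluded

  # boundary marker exactly at window start is included (pos0 == start)
  m2 <- tibble::tibble(marker_id = "mX", chrom = "1", pos = 80001L, b = 1)
  expect_equal(markers_in_set(m2, win)$s1, 1L)

  # two overlapping genes of one set count the shared marker once:
  # all three markers fall in the union, and the marker covered by both
  # genes appears a single time
  win2 <- tibble::tibble(set_id = "s1", gene_id = c("gA", "gB"),
                         chrom = "1", start = c(0, 50000),
                         end = c(100000, 150000))
  idx2 <- markers_in_set(markers, win2)
  expect_equal(idx2$s1, c(1L, 2L, 3L))

  # empty window table gives an empty list
  expect_equal(length(markers_in_set(markers, win[0, ])), 0)
})

test_that("unsorted markers are rejected", {
  m <- tiny_markers()[c(2, 1, 3:8), ]
  win <- tibble::tibble(set_id = "s", gene_id = "g", chrom = "1",
                        start = 0, end = 1e6)
  expect_error(markers_in_set(m, win), "sorted")
})

test_that("mapping agrees with a brute-force linear-scan oracle on random
           instances, and window growth is monotone", {
  set.seed(7)
  for (r in 1:20) {
    n_mark <- sample(100:1000, 1)
    markers <- order_markers(tibble::tibble(
      marker_id = sprintf("m%04d", seq_len(n_mark)),
      chrom = sample(c("1", "2", "10", "X"), n_mark, replace = TRUE),
      pos = sample.int(2e5, n_mark, replace = TRUE),
      b = rnorm(n_mark)))
    n_gene <- sample(3:12, 1)
    ann <- tibble::tibble(
      gene_id = sprintf("g%02d", seq_len(n_gene)),
      chrom = sample(c("1", "2", "10"), n_gene, replace = TRUE),
      start = sample.int(15e4, n_gene))
    ann$end <- ann$start + sample.int(3e4, n_gene)
    sets <- tibble::tibble(
      set_id = sample(c("sA", "sB"), n_gene, replace = TRUE),
      gene_id = ann$gene_id)
    win <- resolve_windows(sets, ann, window_bp = 5000)
    expect_identical(markers_in_set(markers, win),
                     brute_markers_in_set(markers, win))

    # monotonicity: enlarging the window never decreases m_f
    tab_small <- marker_set_counts(markers, sets, ann, window_bp = 1000)
    tab_large <- marker_set_counts(markers, sets, ann, window_bp = 10000)
    expect_true(all(tab_large$m_f >= tab_small$m_f))
  }
})

test_that("disjoint sets have disjoint marker index sets", {
  markers <- tiny_markers()
  ann <- tibble::tibble(
    gene_id = c("g1", "g2"), chrom = c("1", "2"),
    start = c(5000, 5000), end = c(25000, 25000))
  sets <- tibble::tibble(set_id = c("sA", "sB"), gene_id = c("g1", "g2"))
  idx <- markers_in_set(markers, resolve_windows(sets, ann, 0))
  expect_length(intersect(idx$sA, idx$sB), 0)
})

test_that("markers on chromosomes absent from the annotation stay in the
           genome vector but are never in-set", {
  markers <- tiny_markers()  # chroms 1 and 2
  ann <- tibble::tibble(gene_id = "g1", chrom = "1",
                        start = 0, end = 50000)
  sets <- tibble::tibble(set_id = "s", gene_id = "g1")
  idx <- markers_in_set(markers, resolve_windows(sets, ann, 0))
  expect_true(all(markers$chrom[idx$s] == "1"))
  expect_equal(nrow(markers), 8)  # chrom-2 markers still present
})
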