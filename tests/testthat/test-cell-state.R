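make_norm <- function(mat) {
  # small dense matrix -> normalized, keeping the test arithmetic visible
  normalize_cells(mat)
}

test_that("normalization scales to the median depth and drops empty cells", {
  m <- matrix(c(1, 2, 3,
                2, 4, 6,
                0, 0, 0), nrow = 3, byrow = FALSE,
              dimnames = list(c("gA", "gB", "gC"),
                              c("c1", "c2", "c3")))
  expect_message(norm <- normalize_cells(m), "dropped 1")
  expect_equal(attr(norm, "dropped_cells"), "c3")
  # c2 has double c1's counts: after depth scaling they are identical
  expect_equal(norm[, "c1"], norm[, "c2"])
  # median depth cell keeps its raw values (size factor 1)
  depths <- c(6, 12)
  sf <- depths / median(depths)
  expect_equal(attr(norm, "size_factors"), c(c1 = sf[1], c2 = sf[2]))
  expect_equal(unname(norm[, "c1"]), log1p(c(1, 2, 3) / sf[1]))

  # equal depths: size factor exactly 1 everywhere
  m2 <- matrix(c(1, 3, 2, 2), 2,
               dimnames = list(c("g1", "g2"), c("c1", "c2")))
  n2 <- normalize_cells(m2)
  expect_equal(unname(attr(n2, "size_factors")), c(1, 1))
  expect_equal(as.matrix(n2), log1p(m2), ignore_attr = TRUE)
})

test_that("cycle_score is the per-cell mean over present panel genes", {
  # equal depths (108) keep all size factors at 1, so normalized values
  # are exactly log1p(counts)
  m <- matrix(c(3, 5, 100,
                0, 0, 108), nrow = 3,
              dimnames = list(c("p1", "p2", "other"), c("c1", "c2")))
  norm <- normalize_cells(m)
  sc <- cycle_score(norm, c("p1", "p2"))
  expect_equal(sc$score[1], mean(log1p(c(3, 5))))
  # a cell with zero panel expression scores 0
  expect_equal(sc$score[2], 0)
  # absent panel genes are excluded from the denominator
  expect_message(sc2 <- cycle_score(norm, c("p1", "p2", "ghost")),
                 "1 cell-cycle panel gene")
  expect_equal(sc2$score, sc$score)
  expect_error(cycle_score(norm, c("ghostA", "ghostB")), "no gene")
})

test_that("proliferation threshold is the mean of cluster means, strict", {
  scores <- tibble::tibble(cell_id = sprintf("c%d", 1:6),
                           score = c(2, 2, 6, 6, 5, 4))
  meta <- tibble::tibble(cell_id = sprintf("c%d", 1:6),
                         cluster = c("A", "A", "B", "B", "B", "B"))
  # cluster means: A = 2, B = 5.25 -> tau = 3.625
  fl <- classify_proliferating(scores, meta)
  expect_equal(attr(fl, "threshold"), (2 + 5.25) / 2)
  expect_equal(fl$proliferating, c(2, 2, 6, 6, 5, 4) > 3.625)

  # textbook two-cluster case: means 2 and 6, tau = 4; 5 -> TRUE, 4 -> FALSE
  s2 <- tibble::tibble(cell_id = c("x1", "x2", "x3", "x4"),
                       score = c(2, 6, 5, 4))
  m2 <- tibble::tibble(cell_id = c("x1", "x2", "x3", "x4"),
                       cluster = c("A", "B", "A", "A"))
  # cluster means: A = (2+5+4)/3, B = 6
  tau2 <- (mean(c(2, 5, 4)) + 6) / 2
  fl2 <- classify_proliferating(s2, m2)
  expect_equal(attr(fl2, "threshold"), tau2)

  # identical scores: tau equals the score, strict > flags nothing
  s3 <- tibble::tibble(cell_id = c("y1", "y2"), score = c(3, 3))
  m3 <- tibble::tibble(cell_id = c("y1", "y2"), cluster = c("A", "B"))
  expect_false(any(classify_proliferating(s3, m3)$proliferating))

  # grand-mean alternative
  fl4 <- classify_proliferating(scores, meta, threshold = "grand_mean")
  expect_equal(attr(fl4, "threshold"), mean(scores$score))
})

test_that("classification is invariant to cell order", {
  set.seed(10)
  scores <- tibble::tibble(cell_id = sprintf("c%02d", 1:30),
                           score = rnorm(30))
  meta <- tibble::tibble(cell_id = scores$cell_id,
                         cluster = rep(c("A", "B", "C"), 10))
  a <- classify_proliferating(scores, meta)
  b <- classify_proliferating(scores[sample(30), ], meta[sample(30), ])
  a_ord <- a[order(a$cell_id), ]
  b_ord <- b[order(b$cell_id), ]
  expect_equal(a_ord$proliferating, b_ord$proliferating)
  expect_equal(attr(a, "threshold"), attr(b, "threshold"))
})

test_that("cycle_index is the flagged fraction per group and sums coherently", {
  flags <- tibble::tibble(
    cell_id = sprintf("c%02d", 1:10),
    proliferating = c(rep(TRUE, 3), rep(FALSE, 7)))
  meta <- tibble::tibble(cell_id = flags$cell_id,
                         cluster = rep("A", 10),
                         timepoint = rep(c("t0", "t1"), each = 5))
  ci <- cycle_index(flags, meta, "cluster")
  expect_equal(ci$cycle_index, 0.3)
  ci2 <- cycle_index(flags, meta, c("cluster", "timepoint"))
  expect_equal(sum(ci2$n_proliferating), sum(flags$proliferating))
  expect_true(all(ci2$cycle_index >= 0 & ci2$cycle_index <= 1))
  expect_error(cycle_index(flags, meta, "nope"), "unknown grouping")

  flags$proliferating <- FALSE
  expect_true(all(cycle_index(flags, meta, "cluster")$cycle_index == 0))
})

test_that("module scores are two-point z-scores on a one-gene toy and
           constant genes contribute zero", {
  # two groups, one module gene with means 2 and 4 -> scaled -1, +1;
  # a padding gene keeps every cell at depth 9 so size factors are 1
  counts <- matrix(c(2, 2, 4, 4,
                     5, 5, 5, 5,
                     2, 2, 0, 0), nrow = 3, byrow = TRUE,
                   dimnames = list(c("gMod", "gConst", "gPad"),
                                   sprintf("c%d", 1:4)))
  meta <- tibble::tibble(cell_id = sprintf("c%d", 1:4),
                         timepoint = factor(rep(c("t0", "t1"), each = 2),
                                            levels = c("t0", "t1")))
  norm <- normalize_cells(counts)

  ms <- module_score(norm, meta,
                     tibble::tibble(panel_id = "mod",
                                    gene_id = c("gMod", "gConst")))
  expect_s3_class(ms, "module_scores")
  gene_scores <- attr(ms, "gene_scores")
  zmod <- gene_scores$scaled[gene_scores$gene_id == "gMod"]
  expect_equal(zmod, c(-1, 1))
  zconst <- gene_scores$scaled[gene_scores$gene_id == "gConst"]
  expect_equal(zconst, c(0, 0))
  # module score = mean over genes: (-1 + 0)/2 and (1 + 0)/2
  expect_equal(ms$score, c(-0.5, 0.5))

  # rows have mean 0 and population SD <= 1 across groups
  expect_equal(mean(ms$score), 0, tolerance = 1e-12)
  expect_error(module_score(norm, meta,
                            tibble::tibble(panel_id = "m",
                                           gene_id = "ghost")),
               "no gene present")
})

test_that("module score rows are centred with population SD at most 1", {
  sim <- simulate_sc(sc_sim_config(n_cells_per_group = 40, seed = 13))
  norm <- normalize_cells(sim$counts)
  mono <- sim$cell_meta$cell_id[sim$cell_meta$cluster == "monocyte"]
  ms <- module_score(norm[, mono], sim$cell_meta,
                     sim$panels[!sim$panels$panel_id %in% c("G1S", "G2M"), ])
  gs <- attr(ms, "gene_scores")
  by_gene <- split(gs$scaled, gs$gene_id)
  mu <- vapply(by_gene, mean, numeric(1))
  sdp <- vapply(by_gene, function(z) sqrt(mean((z - mean(z))^2)), numeric(1))
  expect_true(all(abs(mu) < 1e-10))
  expect_true(all(sdp <= 1 + 1e-10))
})

test_that("trajectory classification follows the stated rules", {
  expect_equal(classify_trajectory(c(-1.0, 0.8, 1.0, -0.9)), "peaked")
  expect_equal(classify_trajectory(c(-1.2, 0.3, 0.9, 0.7)), "sustained")
  expect_equal(classify_trajectory(c(0.01, -0.02, 0.0, 0.01)), "flat")
  # max at the final point with a held elevation is sustained
  expect_equal(classify_trajectory(c(-1, 0, 0.5, 1)), "sustained")
  # monotone decrease is flat (never peaked/sustained)
  expect_equal(classify_trajectory(c(1, 0.5, 0, -1)), "flat")
  expect_error(classify_trajectory(c(1, 2)), ">= 3")
})
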