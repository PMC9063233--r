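test_that("t_sum sums squared effects over the index set", {
  b <- c(1, -2, 3, 4)
  expect_equal(t_sum(b, c(1, 2)), 5)
  expect_equal(t_sum(b, integer(0)), 0)
  expect_equal(t_sum(b, 1:4), sum(b^2))
  expect_error(t_sum(b, 5), "index")
})

test_that("rotation follows the definition and conserves the multiset", {
  expect_equal(rotate_effects(c(1, 2, 3), 1), c(2, 3, 1))
  expect_equal(rotate_effects(c(1, 2, 3), 0), c(1, 2, 3))
  expect_error(rotate_effects(c(1, 2, 3), 3), "0:")
  set.seed(1)
  b2 <- rnorm(50)^2
  for (k in c(1, 7, 49)) {
    r <- rotate_effects(b2, k)
    expect_equal(sort(r), sort(b2))
    expect_equal(sum(r), sum(b2), tolerance = 1e-9)
  }
})

test_that("the worked exact null is {5, 7, 5} with t_obs = 3 and p = 1", {
  b <- c(1, sqrt(2), sqrt(3), 2)  # b^2 = 1, 2, 3, 4
  idx <- c(1, 2)
  nd <- null_distribution(b, idx, enumerate_all = TRUE)
  expect_true(nd$exact)
  expect_equal(nd$t_null, c(5, 7, 5))
  expect_equal(nd$t_null, brute_rotation_null(b^2, idx))
  t_obs <- t_sum(b, idx)
  expect_equal(t_obs, 3)
  ep <- empirical_p(t_obs, nd$t_null)
  expect_equal(ep$n_exceed, 3)
  expect_equal(ep$p_emp, 1)
})

test_that("the full marker set is rotation-invariant: all null values tie
           with the observed statistic", {
  set.seed(2)
  b <- rnorm(40)
  nd <- null_distribution(b, 1:40, enumerate_all = TRUE)
  expect_true(all(abs(nd$t_null - sum(b^2)) < 1e-9 * sum(b^2)))
  # ties never count as exceedances under strict >, so the floored
  # p-value is 1/n_null (the documented tie convention)
  ep <- empirical_p(t_sum(b, 1:40), nd$t_null)
  expect_equal(ep$n_exceed, 0L)
  expect_equal(ep$p_emp, 1 / 39)
})

test_that("exact enumeration matches the brute-force rotation oracle on
           random instances", {
  set.seed(3)
  for (r in 1:10) {
    m <- sample(10:80, 1)
    b <- rnorm(m)
    idx <- sort(sample.int(m, sample(1:5, 1)))
    nd <- null_distribution(b, idx, enumerate_all = TRUE)
    expect_equal(nd$t_null, brute_rotation_null(b^2, idx))
  }
})

test_that("empirical p uses strict exceedance with a 1/n floor", {
  expect_equal(empirical_p(10, c(1, 2, 3)),
               list(p_emp = 1 / 3, n_exceed = 0L))
  # ties do not exceed under strict >
  expect_equal(empirical_p(2, c(2, 2, 2))$n_exceed, 0L)
  expect_equal(empirical_p(2, c(2, 2, 2))$p_emp, 1 / 3)
})

test_that("the sampled null converges to the exact null (KS distance on
           m = 500)", {
  set.seed(4)
  m <- 500
  b <- rnorm(m)
  idx <- sort(sample.int(m, 25))
  exact <- null_distribution(b, idx, enumerate_all = TRUE)
  sampled <- null_distribution(b, idx, n_perm = 10000, seed = 8,
                               enumerate_all = FALSE)
  expect_false(sampled$exact)
  ks <- suppressWarnings(
    stats::ks.test(sampled$t_null, exact$t_null))$statistic
  expect_lt(unname(ks), 0.03)
})

test_that("relabelling the first marker before rotation leaves the exact
           null multiset unchanged", {
  set.seed(5)
  m <- 60
  b <- rnorm(m)
  idx <- sort(sample.int(m, 6))
  base <- sort(c(t_sum(b, idx),
                 null_distribution(b, idx, enumerate_all = TRUE)$t_null))
  for (shift in c(1, 13, 59)) {
    b_s <- rotate_effects(b, shift)
    idx_s <- sort((idx - 1 - shift) %% m + 1)
    shifted <- sort(c(t_sum(b_s, idx_s),
                      null_distribution(b_s, idx_s,
                                        enumerate_all = TRUE)$t_null))
    expect_equal(shifted, base)
  }
})

test_that("fdr_adjust matches hand-computed Benjamini-Hochberg values", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_adjust(0.5), 0.5)
  expect_equal(fdr_adjust(numeric(0)), numeric(0))
  set.seed(6)
  for (r in 1:20) {
    p <- runif(sample(1:10, 1))
    q <- fdr_adjust(p)
    expect_equal(q, bh_by_hand(p))
    # q is non-decreasing along sorted p (ties allowed)
    expect_true(all(diff(q[order(p)]) >= -1e-12))
  }
  expect_error(fdr_adjust(c(0.5, 0)), "\\(0, 1\\]")
})

test_that("a 1 x 1 grid reduces to the manual composition of the pieces", {
  sim <- simulate_gwas(gwas_sim_config(seed = 31), trait_id = "t1")
  one_set <- sim$sets[sim$sets$set_id == "set03", ]
  grid <- run_grid(sim$markers, one_set, sim$genes, window_bp = 20000,
                   n_perm = 500, seed = 17)
  expect_equal(nrow(grid), 1)

  win <- resolve_windows(one_set, sim$genes, 20000)
  idx <- markers_in_set(sim$markers, win)[["set03"]]
  expect_equal(grid$m_f, length(idx))
  expect_equal(grid$t_obs, t_sum(sim$markers$b, idx))
  # same derived seed scheme as the grid: single pair has rank 1
  nd <- null_distribution(sim$markers$b, idx, n_perm = 500,
                          seed = cellgwas:::derive_seed(17, 1))
  ep <- empirical_p(grid$t_obs, nd$t_null)
  expect_equal(grid$p_emp, ep$p_emp)
  expect_equal(grid$q_fdr, ep$p_emp)  # BH of a single test is identity
})

test_that("grid output is deterministic, order-invariant, and reports
           untestable sets with a reason code", {
  sim1 <- simulate_gwas(gwas_sim_config(seed = 41), trait_id = "tA")
  sim2 <- simulate_gwas(gwas_sim_config(seed = 42), genes = sim1$genes,
                        sets = sim1$sets, trait_id = "tB")
  gwas <- dplyr::bind_rows(sim1$markers, sim2$markers)
  sets <- rbind(sim1$sets,
                tibble::tibble(set_id = "ghost", gene_id = "absent_gene"))
  suppressMessages({
    g1 <- run_grid(gwas, sets, sim1$genes, n_perm = 300, seed = 5)
    g2 <- run_grid(list(tB = sim2$markers, tA = sim1$markers), sets,
                   sim1$genes, n_perm = 300, seed = 5)
  })
  expect_equal(tibble::as_tibble(g1), tibble::as_tibble(g2))
  ghost <- g1[g1$set_id == "ghost", ]
  expect_true(all(ghost$note == "no_markers"))
  expect_true(all(is.na(ghost$p_emp)))
  expect_equal(nrow(g1), 2 * 9)
  tested <- !is.na(g1$p_emp)
  expect_equal(g1$q_fdr[tested], fdr_adjust(g1$p_emp[tested]))
})
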