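test_that("midranks behave like competition-averaged ranks", {
  expect_equal(rank_average_ties(c(10, 20, 30)), c(1, 2, 3))
  expect_equal(rank_average_ties(c(5, 5)), c(1.5, 1.5))
  expect_equal(rank_average_ties(c(3, 1, 3, 2)), c(3.5, 1, 3.5, 2))
  set.seed(5)
  for (i in 1:25) {
    v <- sample(1:6, 12, replace = TRUE)
    r <- rank_average_ties(v)
    expect_equal(r, rank(v, ties.method = "average"))
    expect_equal(sum(r), length(v) * (length(v) + 1) / 2)
  }
})

test_that("Mann-Whitney U matches hand-derived and enumerated values", {
  t1 <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3))
  expect_equal(t1$statistic, 4.5)
  expect_gt(t1$p_value, 0.9)
  t2 <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(t2$statistic, 0)
  expect_equal(t2$method, "exact")
  expect_equal(t2$p_value, 0.100)
  expect_error(mann_whitney_u(numeric(0), 1:3), "nonempty")
})

test_that("exact U p-value equals the full-permutation oracle (tie-free n = 6 + 6)", {
  set.seed(17)
  for (i in 1:10) {
    x <- rnorm(6); y <- rnorm(6, 0.5)
    got <- mann_whitney_u(x, y)
    expect_equal(got$method, "exact")
    expect_equal(got$p_value, permutation_mw_p(x, y), tolerance = 1e-12)
  }
})

test_that("U_x + U_y = n1 n2 and p-values live in [0, 1]", {
  set.seed(23)
  for (i in 1:30) {
    n1 <- sample(2:12, 1); n2 <- sample(2:12, 1)
    x <- sample(1:8, n1, replace = TRUE); y <- sample(1:8, n2, replace = TRUE)
    r <- rank_average_ties(c(x, y))
    ux <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
    res <- mann_whitney_u(x, y)
    expect_equal(res$statistic, min(ux, n1 * n2 - ux))
    expect_gte(res$p_value, 0); expect_lte(res$p_value, 1)
    expect_lte(res$statistic, n1 * n2)
  }
})

test_that("normal approximation tracks base wilcox.test with ties and continuity", {
  set.seed(31)
  for (i in 1:15) {
    x <- sample(seq(0, 5, 0.5), 20, replace = TRUE)
    y <- sample(seq(1, 6, 0.5), 25, replace = TRUE)
    ours <- mann_whitney_u(x, y)
    ref <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = TRUE))
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)
  }
})

test_that("exact and normal-approximation p agree closely at n1 = n2 = 8", {
  set.seed(41)
  for (i in 1:10) {
    x <- rnorm(8); y <- rnorm(8, 0.7)
    pe <- mann_whitney_u(x, y, exact = TRUE)$p_value
    pa <- mann_whitney_u(x, y, exact = FALSE)$p_value
    expect_lt(abs(pe - pa), 0.02)
  }
})

test_that("Kruskal-Wallis matches the closed form and base R", {
  kw <- kruskal_wallis(list(c(1, 2), c(3, 4), c(5, 6)))
  expect_equal(kw$statistic, 4.571, tolerance = 1e-3)
  expect_equal(kw$df, 2)
  same <- kruskal_wallis(list(rep(2, 3), rep(2, 4), rep(2, 5)))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_error(kruskal_wallis(list(1:3)), "two groups")
  set.seed(7)
  for (i in 1:10) {
    g <- lapply(sample(3:9, 3), function(n) sample(1:6, n, replace = TRUE))
    ours <- kruskal_wallis(g)
    ref <- kruskal.test(g)
    expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("two-group Kruskal-Wallis equals the squared U z-statistic", {
  set.seed(13)
  for (i in 1:10) {
    x <- rnorm(9); y <- rnorm(11, 0.4)
    h <- kruskal_wallis(list(x, y))$statistic
    p <- mann_whitney_u(x, y, continuity = FALSE, exact = FALSE)$p_value
    z2 <- qnorm(p / 2)^2
    expect_equal(h, z2, tolerance = 1e-9)
  }
})

test_that("Dunn post-hoc separates, caps at 1.000, and dominates raw p", {
  set.seed(19)
  g <- list(a = rnorm(10), b = rnorm(10), c = rnorm(10) + 10, d = rnorm(10))
  res <- dunn_posthoc(g)
  expect_equal(nrow(res), 6)
  expect_lt(res$adjusted_p[res$group_a == "b" & res$group_b == "c"], 0.05)
  expect_true(all(res$adjusted_p >= res$p_raw - 1e-15))
  expect_true(all(res$adjusted_p <= 1))
  # identical groups among four: the capped p = 1.000 exactly
  g$d <- g$a
  res2 <- dunn_posthoc(g)
  expect_equal(res2$adjusted_p[res2$group_a == "a" & res2$group_b == "d"], 1.000)
})

test_that("Spearman equals the rank-then-Pearson oracle, ties included", {
  expect_equal(spearman(1:4, c(10, 20, 30, 40))$statistic, 1.0)
  expect_equal(spearman(1:4, c(8, 6, 4, 2))$statistic, -1.0)
  expect_equal(spearman(1:4, c(8, 6, 4, 2))$p_value, 0)
  expect_error(spearman(1:2, 1:2), "3 complete pairs")
  set.seed(29)
  for (i in 1:20) {
    x <- sample(1:5, 15, replace = TRUE)
    y <- x + sample(1:4, 15, replace = TRUE)
    got <- spearman(x, y)
    expect_equal(got$statistic, rank_pearson_rho(x, y), tolerance = 1e-12)
    ref <- suppressWarnings(cor.test(x, y, method = "spearman"))
    expect_equal(got$statistic, unname(ref$estimate), tolerance = 1e-12)
  }
})

test_that("correlation matrix is symmetric, unit-diagonal, pairwise-complete", {
  coh <- compute_panel(generate_cohort(cohort_config(seed = 2)))
  cm <- correlation_matrix(coh, c("age", "q_alb", "q_igg", "csf_kflc",
                                  "kflc_index", "kigg_index"))
  expect_identical(cm$rho, t(cm$rho))
  expect_equal(unname(diag(cm$rho)), rep(1, 6))
  expect_identical(cm$p, t(cm$p))
  expect_true(all(cm$p >= 0 & cm$p <= 1, na.rm = TRUE))
  # effective n reflects pairwise deletion of the missing FLC fields
  expect_lte(cm$n["csf_kflc", "kflc_index"], cm$n["age", "q_alb"])
  # CSF kappa-FLC and its index are strongly coupled by construction
  expect_gt(cm$rho["csf_kflc", "kflc_index"], 0.6)
})

test_that("independent columns rarely show |rho| above 0.3 at n = 76", {
  set.seed(37)
  hits <- replicate(100, {
    abs(spearman(rnorm(76), rnorm(76))$statistic) < 0.3
  })
  expect_gte(mean(hits), 0.95)
})
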