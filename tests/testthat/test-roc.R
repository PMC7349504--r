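test_that("ROC handles perfect, null and crossing score configurations", {
  lab <- function(np, nn) c(rep("MS", np), rep("CONTROL", nn))
  expect_equal(roc_curve(c(2, 3, 0, 1), lab(2, 2))$auc, 1.0)
  expect_equal(roc_curve(c(1, 2, 1, 2), lab(2, 2))$auc, 0.5)
  crossing <- roc_curve(c(1, 3, 2, 4), lab(2, 2))
  expect_equal(crossing$auc, 0.25)
  expect_true(crossing$uninformative)
  expect_error(roc_curve(1:4, rep("MS", 4)), "both classes")
})

test_that("curve endpoints are (0,0) and (1,1) with monotone fpr/tpr", {
  set.seed(3)
  for (i in 1:20) {
    sc <- sample(1:10, 30, replace = TRUE)
    lb <- sample(c("MS", "CONTROL"), 30, replace = TRUE, prob = c(0.4, 0.6))
    if (length(unique(lb)) < 2) next
    cv <- roc_curve(sc, lb)
    pts <- cv$points
    expect_equal(pts$fpr[1], 0); expect_equal(pts$tpr[1], 0)
    expect_equal(pts$fpr[nrow(pts)], 1); expect_equal(pts$tpr[nrow(pts)], 1)
    expect_true(all(diff(pts$fpr) >= 0))
    expect_true(all(diff(pts$tpr) >= 0))
    expect_gte(cv$auc, 0); expect_lte(cv$auc, 1)
  }
})

test_that("trapezoidal AUC equals pairwise-U AUC on every input", {
  expect_equal(auc_u_equivalence(c(1, 3, 2, 4), c("MS", "MS", "CONTROL", "CONTROL")),
               0.25)
  expect_equal(auc_u_equivalence(rep(1, 6), c(rep("MS", 3), rep("CONTROL", 3))),
               0.5)
  set.seed(101)
  for (i in 1:100) {
    n <- sample(6:25, 1)
    sc <- sample(1:8, n, replace = TRUE) + sample(c(0, 0.5), n, replace = TRUE)
    lb <- c("MS", "CONTROL", sample(c("MS", "CONTROL"), n - 2, replace = TRUE))
    expect_equal(roc_curve(sc, lb)$auc, auc_u_equivalence(sc, lb),
                 tolerance = 1e-12)
  }
})

test_that("AUC is invariant under strictly increasing score transforms", {
  set.seed(7)
  sc <- rlnorm(40); lb <- sample(c("MS", "CONTROL"), 40, replace = TRUE,
                                 prob = c(0.45, 0.55))
  base <- roc_curve(sc, lb)$auc
  for (f in list(log, sqrt, function(x) 3 * x + 2, function(x) x^3))
    expect_equal(roc_curve(f(sc), lb)$auc, base, tolerance = 1e-12)
})

test_that("AUC agrees with pROC on a simulated index", {
  coh <- compute_panel(generate_cohort(cohort_config(seed = 5)))
  ok <- !is.na(coh$kigg_index)
  ours <- roc_curve(coh$kigg_index, coh$group)$auc
  ref <- suppressMessages(pROC::auc(pROC::roc(
    response = coh$group[ok], predictor = coh$kigg_index[ok],
    levels = c("CONTROL", "MS"), direction = "<")))
  expect_equal(ours, as.numeric(ref), tolerance = 1e-12)
})

test_that("Youden cut-off maximizes J with the documented tie-breaks", {
  cv <- roc_curve(c(10, 20, 30, 1, 2, 3),
                  c(rep("MS", 3), rep("CONTROL", 3)))
  cut <- youden_cutoff(cv)
  expect_equal(cut$cutoff, 10)     # lowest observed value achieving J = 1
  expect_equal(cut$j, 1)
  flat <- youden_cutoff(roc_curve(c(1, 2, 1, 2), c("MS", "MS", "CONTROL", "CONTROL")))
  expect_true(flat$uninformative)
  expect_equal(flat$cutoff, 1)     # ties -> higher sensitivity -> lower threshold
  # J is reproducible from the confusion matrix at the chosen cut-off
  set.seed(9)
  sc <- c(rlnorm(30, 1), rlnorm(40)); lb <- c(rep("MS", 30), rep("CONTROL", 40))
  cut2 <- youden_cutoff(roc_curve(sc, lb))
  perf <- performance_at_cutoff(sc, lb, cut2$cutoff)
  expect_equal(cut2$j, perf$sensitivity / 100 + perf$specificity / 100 - 1,
               tolerance = 1e-12)
})

test_that("performance metrics match the published-style arithmetic", {
  sc <- c(rep(2, 28), rep(0, 3), rep(0, 33), rep(2, 8))
  lb <- c(rep("MS", 31), rep("CONTROL", 41))
  perf <- performance_at_cutoff(sc, lb, 1)
  expect_equal(unname(perf$confusion), c(28, 3, 33, 8))
  expect_equal(unname(perf$display),
               c(90.32, 80.49, 77.78, 91.67, 84.72))
  expect_equal(perf$accuracy, 100 * 61 / 72)
})

test_that("degenerate cut-offs flag undefined metrics instead of NaN", {
  sc <- c(5, 6, 7, 8); lb <- c("MS", "MS", "CONTROL", "CONTROL")
  all_pos <- performance_at_cutoff(sc, lb, 0)
  expect_equal(all_pos$specificity, 0)
  expect_true(is.na(all_pos$npv))
  expect_identical(all_pos$undefined, "npv")
  expect_equal(all_pos$sensitivity, 100)
  all_neg <- performance_at_cutoff(sc, lb, 100)
  expect_equal(c(all_neg$sensitivity, all_neg$specificity), c(0, 100))
})
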