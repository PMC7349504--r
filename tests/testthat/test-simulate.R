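test_that("log-normal calibration pins the median and reads range as 4 sigma", {
  expect_equal(unname(calibrate_lognormal(1, exp(-2), exp(2))), c(0, 1))
  got <- calibrate_lognormal(3.050, 0.30, 50.0)
  expect_equal(unname(got), c(log(3.050), (log(50) - log(0.30)) / 4),
               tolerance = 1e-12)
  expect_equal(unname(got), c(1.11514, 1.27900), tolerance = 1e-5)
  expect_error(calibrate_lognormal(5, 1, 4), "within")
  expect_error(calibrate_lognormal(-1, 1, 4), "positive")
})

test_that("published range defects are repaired with explicit warnings", {
  ref <- reference_analytes()
  w <- capture_warnings(analyte_models(ref))
  expect_true(any(grepl("decimal misprint", w)))      # serum Ig maxima
  expect_true(any(grepl("widened to the median", w))) # MS CSF IgG median > max
  m <- analyte_models(ref, quiet = TRUE)
  expect_true(all(is.finite(m$sigma)) && all(m$sigma > 0))
  # medians are authoritative: exp(mu) reproduces each configured median
  expect_equal(exp(m$mu), ref$median)
  # serum IgG sigma is plausible after decimal rescue
  expect_lt(m$sigma[m$analyte == "serum_igg" & m$group == "MS"], 0.5)
})

test_that("generation is a pure function of (config, seed)", {
  c1 <- generate_cohort(cohort_config(seed = 42))
  c2 <- generate_cohort(cohort_config(seed = 42))
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_cohort(c1, f1); write_cohort(c2, f2)
  expect_identical(readLines(f1), readLines(f2))
  c3 <- generate_cohort(cohort_config(seed = 43))
  expect_false(identical(c1$csf_kflc, c3$csf_kflc))
})

test_that("default cohorts have the configured composition", {
  coh <- generate_cohort(cohort_config(seed = 8))
  expect_equal(sum(coh$group == "MS"), 34)
  expect_equal(sum(coh$group == "CONTROL"), 42)
  tb <- table(coh$ocb_pattern[coh$group == "MS"])
  expect_equal(as.integer(tb[c("2", "3")]), c(31, 3))
  tb2 <- table(coh$ocb_pattern[coh$group == "CONTROL"])
  expect_equal(as.integer(tb2[c("1", "3", "4", "5")]), c(21, 4, 16, 1))
  expect_true(all(coh$ocb_pattern[coh$group == "MS"] %in% c(2, 3)))
})

test_that("censoring is correct: no CSF FLC below its limit, flags exact", {
  for (seed in 1:5) {
    coh <- generate_cohort(cohort_config(seed = seed))
    expect_true(all(coh$csf_kflc >= 0.30, na.rm = TRUE))
    expect_true(all(coh$csf_lflc >= 0.65, na.rm = TRUE))
    expect_true(all(coh$csf_kflc[coh$csf_kflc_below_lod] == 0.30, na.rm = TRUE))
    expect_true(all(coh$csf_lflc[coh$csf_lflc_below_lod] == 0.65, na.rm = TRUE))
    expect_false(any(is.na(coh$csf_kflc) & coh$csf_kflc_below_lod))
  }
})

test_that("zero-noise cohorts collapse to the group-median arithmetic", {
  cfg <- cohort_config(sigma_scale = 0, pattern_shifts = FALSE,
                       missingness = numeric(0), seed = 1)
  coh <- compute_panel(generate_cohort(cfg))
  ms <- coh[coh$group == "MS", ]; ct <- coh[coh$group == "CONTROL", ]
  expect_equal(unique(ms$csf_kflc), 3.050)
  expect_equal(unique(ct$csf_kflc), 0.310)
  expect_equal(unique(ms$kflc_index),
               compute_flc_index(3.050, 13.480, 187.95, 43.90))
  expect_equal(unique(ms$kigg_index),
               compute_igg_index(3.050, 13.480, 43.19, 10.72))
  expect_equal(unique(ms$lflc_index),
               compute_flc_index(2.050, 11.715, 187.95, 43.90))
  expect_equal(unique(ms$ligg_index),
               compute_igg_index(2.050, 11.715, 43.19, 10.72))
  # and the round trip recovers the configured medians exactly
  rp <- recover_parameters(coh)
  expect_equal(rp$median[rp$variable == "csf_lflc" & rp$group == "CONTROL"], 0.720)
})

test_that("control CSF kappa-FLC sits near its LOD with a censored mass", {
  coh <- generate_cohort(cohort_config(seed = 12))
  ctrl <- coh[coh$group == "CONTROL", ]
  expect_gt(sum(ctrl$csf_kflc_below_lod, na.rm = TRUE), 5)
  expect_lt(median(ctrl$csf_kflc, na.rm = TRUE), 2 * 0.30)
})

test_that("non-default group sizes rescale the pattern frequencies", {
  cfg <- cohort_config(n_ms = 17, n_control = 21, seed = 4)
  coh <- generate_cohort(cfg)
  expect_equal(sum(coh$group == "MS"), 17)
  expect_equal(sum(coh$group == "CONTROL"), 21)
  expect_true(all(coh$ocb_pattern[coh$group == "MS"] %in% c(2, 3)))
})

test_that("latent correlation targets are PSD-repaired, not rejected", {
  m <- matrix(c(1, 0.9, -0.9, 0.9, 1, 0.9, -0.9, 0.9, 1), 3, 3)
  r <- nearest_psd(m)
  expect_true(all(eigen(r, symmetric = TRUE)$values >= 0))
  expect_equal(unname(diag(r)), rep(1, 3))
  expect_equal(spearman_to_pearson(0), 0)
  expect_equal(spearman_to_pearson(1), 1)
})
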