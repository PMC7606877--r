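test_that("chi-squared follows its defining identities", {
  expect_equal(chi_squared(c(1, 2, 3), c(1, 2, 3), c(1, 1, 1)), 0)
  expect_equal(chi_squared(5, 4, 1), 1)           # one point, one SD off
  expect_equal(chi_squared(c(1, 2), c(0, 0), c(1, 1)), 5)
  expect_equal(chi_squared(c(1, 2), c(0, 0)), 5)  # unweighted RSS
  # invariant under common rescaling of (obs, pred, sd)
  o <- c(1.2, 3.4, 0.8); p <- c(1, 3, 1); s <- c(0.2, 0.4, 0.3)
  expect_equal(chi_squared(10 * o, 10 * p, 10 * s), chi_squared(o, p, s))
  expect_error(chi_squared(1, 0, 0), "positive")
  expect_error(chi_squared(1, c(0, 1)), "equal length")
})

test_that("cell-count fit recovers a noiseless amplitude exactly", {
  p <- pscd_params(N_bar0 = 535, Phi_bar0 = 1, d0 = 0.1)
  d <- generate_assay_dataset(p, cv_count = 0, cv_alp = 0, seed = 1)
  f <- fit_cell_counts(d, weighted = FALSE)
  expect_equal(f$estimates[["N_bar0"]], 535, tolerance = 1e-9)
  expect_equal(f$rss_unweighted, 0, tolerance = 1e-6)
  expect_equal(f$dof, 3L)
})

test_that("closed-form amplitude equals an iterative optimizer's estimate", {
  p <- pscd_params(N_bar0 = 535, Phi_bar0 = 1, d0 = 0.1)
  d <- generate_assay_dataset(p, cv_count = 0.1, cv_alp = 0.05, seed = 42)
  for (weighted in c(TRUE, FALSE)) {
    f <- fit_cell_counts(d, weighted = weighted)
    w <- if (weighted) 1 / d$cell_count_sd^2 else rep(1, 4)
    opt <- optimize(function(a) sum(w * (d$cell_count_mean - a * d$day^2)^2),
                    interval = c(0, 2000), tol = 1e-12)
    expect_equal(f$estimates[["N_bar0"]], opt$minimum, tolerance = 1e-9)
  }
})

test_that("pooled and per-condition count fits are both reported", {
  pair <- generate_paperlike_pair(seed = 3)
  f <- fit_cell_counts(list(pair$control, pair$stimulated))
  expect_named(f, c("pooled", "per_condition"))
  expect_named(f$per_condition, c("control", "stimulated"))
  expect_s3_class(f$pooled, "fit_result")
  # pooled estimate lies between the per-condition estimates
  ests <- sort(vapply(f$per_condition, function(x) x$estimates[["N_bar0"]], 1))
  expect_gte(f$pooled$estimates[["N_bar0"]], ests[1] - 1e-9)
  expect_lte(f$pooled$estimates[["N_bar0"]], ests[2] + 1e-9)
})

test_that("ALP fit recovers noiseless parameters to optimizer tolerance", {
  truth <- ref_params_control()
  d <- generate_assay_dataset(truth, cv_count = 0, cv_alp = 0, seed = 1)
  f <- fit_alp_activity(d, weighted = FALSE, t0 = 7)
  expect_true(f$converged)
  expect_equal(f$estimates[["d0"]], 1 / 5.84, tolerance = 1e-8)
  expect_equal(f$estimates[["Phi_bar0"]], truth$Phi_bar0, tolerance = 1e-8)
  expect_equal(f$estimates[["inv_d0"]], 5.84, tolerance = 1e-7)
  expect_equal(f$estimates[["Phi0"]], 0.8007, tolerance = 1e-7)
  expect_equal(f$rss_unweighted, 0, tolerance = 1e-12)
})

test_that("weighted ALP fits refuse data without SDs, with a clear message", {
  truth <- ref_params_control()
  d <- generate_assay_dataset(truth, seed = 1)
  d$alp_sd <- NA_real_
  expect_error(fit_alp_activity(d, weighted = TRUE), "weighted = FALSE")
  expect_s3_class(fit_alp_activity(d, weighted = FALSE), "fit_result")
})

test_that("estimator bias of the degradation time vanishes as noise shrinks", {
  truth <- ref_params_control()
  bias_at <- function(cv) {
    est <- vapply(1:40, function(s) {
      d <- generate_assay_dataset(truth, cv_count = 0.1, cv_alp = cv,
                                  seed = 500 + s)
      fit_alp_activity(d, weighted = FALSE)$estimates[["inv_d0"]]
    }, numeric(1))
    abs(mean(est) / 5.84 - 1)
  }
  b_hi <- bias_at(0.10); b_lo <- bias_at(0.01)
  expect_lt(b_lo, 0.01)
  expect_lt(b_lo, b_hi + 0.005)
})

test_that("condition comparison reports the degradation-rate contrast", {
  truth_c <- ref_params_control(); truth_s <- ref_params_stim()
  dc <- generate_assay_dataset(truth_c, cv_alp = 0.02, seed = 10,
                               condition = "control")
  ds <- generate_assay_dataset(truth_s, cv_alp = 0.02, seed = 11,
                               condition = "stimulated")
  fc <- fit_alp_activity(dc); fs <- fit_alp_activity(ds)
  cmp <- compare_conditions(fc, fs)
  expect_lt(cmp$ratio_d0, 1)
  expect_match(cmp$verdict, "slower ALP degradation")
  # identical fits: ratio exactly 1, no difference
  cmp0 <- compare_conditions(fc, fc)
  expect_equal(cmp0$ratio_d0, 1)
  expect_match(cmp0$verdict, "no difference")
  # swapping inputs inverts the ratio
  cmp_rev <- compare_conditions(fs, fc)
  expect_equal(cmp_rev$ratio_d0, 1 / cmp$ratio_d0, tolerance = 1e-12)
  # the generating contrast: 5.84 vs 6.2 gives a ratio near 0.942
  expect_equal((1 / 6.2) / (1 / 5.84), 0.9419, tolerance = 1e-3)
})

test_that("model selection prefers the rise-and-fall curve on peaked data", {
  truth <- ref_params_control()
  d <- generate_assay_dataset(truth, cv_alp = 0.05, seed = 21)
  sel <- model_selection(d)
  expect_equal(sel$preferred, "pscd")
  expect_true(sel$iscd_flagged)
  expect_lt(sel$chi2_pscd, sel$chi2_iscd)
  # monotone (quadratic-growth) data does not flag the monotone model
  d2 <- generate_assay_dataset(iscd_params(N_bar0 = 535, Phi_bar0 = 0.05),
                               cv_alp = 0.05, seed = 22)
  sel2 <- model_selection(d2)
  expect_false(sel2$iscd_flagged)
})
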