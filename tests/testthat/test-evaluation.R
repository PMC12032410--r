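test_that("RMSE per lead matches closed forms and brute force", {
  set.seed(10)
  mk <- function() random_12lead(300)
  real <- list(a = mk(), b = mk())
  # identical reconstruction: zero error everywhere
  expect_true(all(rmse_per_lead(real, real)$rmse_uv == 0))
  # constant 50 uV offset: RMSE exactly 50
  shift <- lapply(real, function(s) ecg_signal(s$samples + 50, 500))
  expect_equal(rmse_per_lead(real, shift)$rmse_uv, rep(50, 8), ignore_attr = TRUE)
  # random pair: brute-force recomputation per lead
  recon <- lapply(real, function(s) ecg_signal(s$samples + rnorm(length(s$samples), sd = 30), 500))
  out <- rmse_per_lead(real, recon)
  for (ld in c("I", "V3", "V6")) {
    expect_equal(out$rmse_uv[out$lead == ld],
                 brute_rmse(c(real$a$samples[ld, ], real$b$samples[ld, ]),
                            c(recon$a$samples[ld, ], recon$b$samples[ld, ])))
  }
  expect_error(rmse_per_lead(real, recon[1]), "differ")
})

test_that("error percentiles follow the interpolated order-statistic convention", {
  m_real <- markers_from_matrix(matrix(0, 100, 1, dimnames = list(NULL, "V3")))
  m_recon <- markers_from_matrix(matrix(1:100, 100, 1, dimnames = list(NULL, "V3")))
  out <- error_percentiles(m_real, m_recon)
  expect_equal(out$p5, brute_quantile7(1:100, 0.05))
  expect_equal(out$p95, brute_quantile7(1:100, 0.95))
  expect_false(out$unstable)
  # constant errors: every percentile equals the constant
  cst <- error_percentiles(m_real, markers_from_matrix(matrix(7, 100, 1,
                             dimnames = list(NULL, "V3"))))
  expect_true(all(c(cst$p5, cst$p10, cst$p90, cst$p95) == 7))
  # negating the errors swaps and negates the percentile pairs
  neg <- error_percentiles(m_real, markers_from_matrix(matrix(-(1:100), 100, 1,
                             dimnames = list(NULL, "V3"))))
  expect_equal(neg$p5, -out$p95)
  expect_equal(neg$p90, -out$p10)
  # small cells are flagged unstable
  small <- error_percentiles(m_real[1:10, ], m_recon[1:10, ])
  expect_true(small$unstable)
})

test_that("t- and F-tests agree with hand-coded formulas on random instances", {
  set.seed(20)
  for (i in 1:25) {
    n <- sample(10:400, 1)
    x <- rnorm(n, 100, 20)
    y <- x + rnorm(n, sample(c(0, 5), 1), sample(c(10, 30), 1))
    mr <- markers_from_matrix(matrix(x, dimnames = list(NULL, "V3")))
    mc <- markers_from_matrix(matrix(y, dimnames = list(NULL, "V3")))
    cmp <- compare_means_variances(mr, mc)
    expect_equal(cmp$p_means, brute_t_paired(x, y), tolerance = 1e-10)
    expect_equal(cmp$p_variance, brute_f(x, y), tolerance = 1e-10)
    expect_equal(cmp$var_ratio, var(y) / var(x), tolerance = 1e-12)
    r2 <- marker_r2(mr, mc)
    expect_equal(r2$r2, brute_pearson(x, y)^2, tolerance = 1e-10)
  }
  # identical groups are degenerate: no p-values emitted
  xx <- rnorm(50)
  m1 <- markers_from_matrix(matrix(xx, dimnames = list(NULL, "V3")))
  cmp0 <- compare_means_variances(m1, m1)
  expect_true(cmp0$degenerate)
  expect_true(is.na(cmp0$p_means))
})

test_that("the F-test flags strongly shrunken variance", {
  set.seed(21)
  x <- rnorm(500, 0, 20)
  y <- rnorm(500, 0, 10)  # variance / 4
  mr <- markers_from_matrix(matrix(x, dimnames = list(NULL, "V3")))
  mc <- markers_from_matrix(matrix(y, dimnames = list(NULL, "V3")))
  cmp <- compare_means_variances(mr, mc)
  expect_lt(cmp$p_variance, 1e-10)
  expect_lt(cmp$var_ratio, 1)
})

test_that("Bland-Altman analysis has the documented closed-form extremes", {
  set.seed(30)
  x <- rnorm(200, 500, 100)
  # perfect reconstruction: all differences zero, degenerate
  ba0 <- bland_altman(x, x)
  expect_true(ba0$degenerate)
  expect_equal(c(ba0$mean_diff, ba0$loa_low, ba0$loa_high), c(0, 0, 0))
  # constant (mean) prediction: slope exactly -1, r2 exactly 1
  ba1 <- bland_altman(x, rep(mean(x), 200))
  expect_equal(ba1$slope, -1, tolerance = 1e-12)
  expect_equal(ba1$r2_diff_vs_real, 1, tolerance = 1e-12)
  # limits of agreement at +/- 1.96 SD of the differences
  y <- x + rnorm(200, 10, 20)
  ba2 <- bland_altman(x, y)
  d <- y - x
  expect_equal(ba2$loa_high, mean(d) + 1.96 * sd(d))
  expect_equal(ba2$slope, cov(d, x) / var(x), tolerance = 1e-12)
  expect_equal(ba2$r2_diff_vs_real, brute_pearson(d, x)^2, tolerance = 1e-10)
  # independent additive noise: slope and r2 shrink toward 0 with n
  xx <- rnorm(4000, 0, 100)
  ba3 <- bland_altman(xx, xx + rnorm(4000, 0, 50))
  expect_lt(abs(ba3$slope), 0.05)
  expect_lt(ba3$r2_diff_vs_real, 0.01)
  # constant real marker: correlation undefined, reported as degenerate 0
  ba4 <- bland_altman(rep(5, 50), rnorm(50))
  expect_true(ba4$degenerate)
  expect_equal(ba4$r2_diff_vs_real, 0)
})

test_that("inter-lead correlations compare real and reconstructed coupling", {
  set.seed(40)
  n <- 400
  ref <- rnorm(n, 800, 150)
  mk <- function(v3) dplyr::bind_rows(
    markers_from_matrix(matrix(ref, dimnames = list(NULL, "I"))),
    markers_from_matrix(matrix(v3, dimnames = list(NULL, "V3"))))
  # exact affine dependence: R2 = 1, and affine rescaling leaves R2 unchanged
  il <- interlead_correlation(mk(2 * ref), mk(2 * ref), "R", leads = "V3")
  expect_equal(il$r2_real, 1, tolerance = 1e-12)
  il_aff <- interlead_correlation(mk(2 * ref), mk(-0.3 * (2 * ref) + 40), "R", "V3")
  expect_equal(il_aff$r2_recon, 1, tolerance = 1e-12)
  # independent markers: R2 near zero
  il0 <- interlead_correlation(mk(rnorm(n)), mk(rnorm(n)), "R", leads = "V3")
  expect_lt(il0$r2_real, 0.02)
  # zero-variance reconstruction flagged as the degenerate constant case
  ilc <- interlead_correlation(mk(rnorm(n)), mk(rep(3, n)), "R", leads = "V3")
  expect_true(ilc$recon_constant)
})

test_that("the regression-to-the-mean verdict flags exactly the right regimes", {
  set.seed(50)
  n <- 300
  leads <- c("V1", "V2", "V3", "V6")
  base <- matrix(rnorm(n * 5, 600, 150), n, 5,
                 dimnames = list(NULL, c("I", leads)))
  m_real <- markers_from_matrix(base)
  # perfect reconstruction: nothing flagged
  v0 <- regression_to_mean_report(m_real, m_real, features = "R", leads = leads)
  expect_false(any(v0$rtm))
  # population-mean reconstruction: every cell flagged
  const <- base
  for (ld in leads) const[, ld] <- mean(base[, ld])
  v1 <- regression_to_mean_report(m_real, markers_from_matrix(const),
                                  features = "R", leads = leads)
  expect_true(all(v1$rtm))
  # small independent noise: variance increases, so no variance flag
  noisy <- base + rnorm(length(base), 0, 30)
  v2 <- regression_to_mean_report(m_real, markers_from_matrix(noisy),
                                  features = "R", leads = leads)
  expect_false(any(v2$variance_shrunk))
  expect_false(any(v2$rtm))
})

test_that("evaluate_reconstruction produces a coherent report on a small cohort", {
  co <- fix_cohort_tiny(12, 2)
  mp <- baseline_mean_predictor(co[1:8], "one_lead")
  rec <- reconstruct_cohort(mp, co[9:12])
  rep <- evaluate_reconstruction(co[9:12], rec)
  expect_s3_class(rep, "ecg_evaluation")
  expect_true(all(rep$rmse$rmse_uv[rep$rmse$lead == "I"] == 0))
  expect_true(all(rep$percentiles$p5 <= rep$percentiles$p95))
  ok <- !rep$bland_altman$degenerate
  expect_true(all(rep$bland_altman$loa_low[ok] <= rep$bland_altman$mean_diff[ok]))
  expect_true(all(rep$verdict$rtm %in% c(TRUE, FALSE)))
  d <- withr::local_tempdir()
  write_evaluation_report(rep, d)
  expect_true(all(file.exists(file.path(d, c("rmse.tsv", "percentiles.tsv",
                                             "comparison.tsv", "verdict.tsv",
                                             "marker-pairs.csv")))))
  expect_s3_class(plot_bland_altman(rep, "R", "V3"), "ggplot")
  expect_s3_class(plot_interlead(rep, "R", "V3"), "ggplot")
  expect_s3_class(glance(rep), "tbl_df")
})
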