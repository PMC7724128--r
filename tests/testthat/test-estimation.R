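# Difference-in-means estimators against closed-form cell-mean oracles,
# brute-force normal equations, and Monte-Carlo recovery.

test_that("single-list OLS equals the difference of arm means exactly", {
  set.seed(101)
  long <- long_fixture(sample(0:3, 40, TRUE), sample(0:4, 35, TRUE))
  est <- estimate_single_list(long, "A")
  y0 <- long$Y[long$T == 0]; y1 <- long$Y[long$T == 1]
  expect_equal(est$beta, mean(y1) - mean(y0), tolerance = 1e-12)
  expect_equal(est$lambda, mean(y0), tolerance = 1e-12)
  expect_equal(est$ci95, est$beta + c(-1.96, 1.96) * est$se)
  # hand-computed example: control (1,2), treated (2,3)
  est2 <- estimate_single_list(long_fixture(c(1, 2), c(2, 3)), "A")
  expect_equal(est2$beta, 1.0)
  expect_equal(est2$lambda, 1.5)
  # identical arms
  est3 <- estimate_single_list(long_fixture(c(1, 2, 3), c(1, 2, 3)), "A")
  expect_equal(est3$beta, 0)
  expect_error(estimate_single_list(long_fixture(c(1, 2), integer(0)), "A"),
               "degenerate")
})

test_that("arm means 2.43 and 1.63 give a prevalence of exactly 0.800", {
  long <- long_fixture(vec_with_mean(100, 1.63), vec_with_mean(100, 2.43))
  est <- estimate_single_list(long, "A")
  expect_equal(est$beta, 0.800, tolerance = 1e-12)
})

test_that("pooled OLS matches an explicit normal-equations solve", {
  d <- validate_survey(data.frame(
    respondent_id = 1:6, group = rep(c(1L, 2L), 3),
    y_listA = c(3L, 1L, 2L, 0L, 4L, 2L), y_listB = c(2L, 3L, 1L, 2L, 0L, 4L),
    direct_report = c(1L, 0L, 1L, 1L, 0L, 0L)))
  long <- to_long(d)
  est <- estimate_pooled(long)
  X <- cbind(1, long$T, long$list_A_flag)
  beta_oracle <- ols_normal_eq(X, long$Y)
  expect_equal(est$lambda, beta_oracle[1], tolerance = 1e-10)
  expect_equal(est$beta, beta_oracle[2], tolerance = 1e-10)
  # cluster-robust covariance equals the hand-rolled CR1 sandwich
  V <- doublelist:::vcov_for(est$fit, "cluster", cluster = long$respondent_id)
  expect_equal(unname(V), unname(cr1_vcov(est$fit, long$respondent_id)),
               tolerance = 1e-10)
  expect_equal(V, t(V))
  expect_true(all(eigen(V, symmetric = TRUE)$values > -1e-12))
})

test_that("balanced design: pooled estimate is the mean of the list estimates", {
  wide <- validate_survey(wide_fixture(1000, 1.700, 1.485, 1.700, 1.439))
  long <- to_long(wide)
  ea <- estimate_single_list(long, "A")
  eb <- estimate_single_list(long, "B")
  ep <- estimate_pooled(long)
  expect_equal(ea$beta, 0.215, tolerance = 1e-12)
  expect_equal(eb$beta, 0.261, tolerance = 1e-12)
  expect_equal(ep$beta, 0.238, tolerance = 1e-12)
  expect_equal(ep$beta, (ea$beta + eb$beta) / 2, tolerance = 1e-12)
})

test_that("identical data on both lists: pooled equals single, no list shift", {
  # both lists carry the same arm samples (respondents swap roles)
  la <- long_fixture(c(0, 1, 2, 2), c(1, 2, 3, 2), list = "A")
  lb <- long_fixture(c(0, 1, 2, 2), c(1, 2, 3, 2), list = "B")
  lb$list_A_flag <- 0L
  lb$respondent_id <- c(5:8, 1:4)
  long <- structure(rbind(la, lb), class = c("long_dataset", "data.frame"))
  ea <- estimate_single_list(long, "A")
  ep <- estimate_pooled(long)
  expect_equal(coef(ep$fit)[["list_A_flag"]], 0, tolerance = 1e-12)
  expect_equal(ep$beta, ea$beta, tolerance = 1e-12)
  expect_equal(ep$beta, estimate_single_list(long, "B")$beta, tolerance = 1e-12)
})

test_that("subgroup interaction model reproduces the cell means", {
  # S0: control mean 1.0, treated 1.5; S1: control 1.0, treated 2.0
  long <- long_fixture(c(1, 1, 1, 1), c(1, 2, 2, 2))
  long$S <- c(0, 0, 1, 1, 0, 0, 1, 1)
  est <- estimate_subgroup(long, "S", list = "A")
  expect_equal(est$beta, 0.5, tolerance = 1e-12)
  expect_equal(est$alpha, 0.5, tolerance = 1e-12)
  expect_equal(est$prevalence_S1 - est$beta, est$alpha, tolerance = 1e-12)
  # empty S x T cell is a degenerate design
  long2 <- long_fixture(c(1, 2), c(2, 3))
  long2$S <- c(0, 0, 0, 0)
  expect_error(estimate_subgroup(long2, "S", list = "A"), "degenerate")
})

test_that("no-moderation simulation: interaction is within Monte-Carlo error of 0", {
  cfg <- simulation_config(n = 4000, behavior = behavior_model(0.3),
                           covariates = list(list(name = "S", type = "binary", p = 0.5)),
                           seed = 31)
  est <- estimate_subgroup(to_long(simulate_survey(cfg)), "S")
  se_alpha <- sqrt(sum(diag(doublelist:::vcov_for(
    est$fit, "cluster", cluster = est$cluster)[c("T", "T:S"), c("T", "T:S")])))
  expect_lt(abs(est$alpha), 3 * se_alpha)
})

test_that("subgroup prevalences 0.18/0.26 are recovered over replicates", {
  R <- 500
  rec <- vapply(seq_len(R), function(r) {
    cfg <- simulation_config(
      n = 1706,
      behavior = behavior_model(0.18, subgroup_effects = c(S = 0.08)),
      misreport = misreport_model("under_report", 0.7),
      covariates = list(list(name = "S", type = "binary", p = 0.5)),
      seed = 5000 + r)
    est <- estimate_subgroup(to_long(simulate_survey(cfg)), "S")
    c(est$beta, est$prevalence_S1)
  }, numeric(2))
  mc_se <- apply(rec, 1L, sd) / sqrt(R)
  expect_lt(abs(mean(rec[1, ]) - 0.18), 2 * mc_se[1])
  expect_lt(abs(mean(rec[2, ]) - 0.26), 2 * mc_se[2])
})

test_that("internal-consistency Wald test from printed estimates gives -0.007", {
  w <- wald_equal_lists(
    est_a = prevalence_estimate(0.800, 0.062, 495, scope = "list A"),
    est_b = prevalence_estimate(0.793, 0.058, 495, scope = "list B"))
  expect_equal(w$difference, -0.007, tolerance = 1e-12)
  expect_equal(w$statistic, w$difference / w$se_diff)
  expect_true(w$p_value >= 0 && w$p_value <= 1)
})

test_that("identical lists give a zero difference with p = 1", {
  # exact symmetry: both lists carry the same arm samples
  yl <- long_fixture(c(0, 1, 2, 3), c(1, 2, 3, 4), list = "A")
  yB <- long_fixture(c(0, 1, 2, 3), c(1, 2, 3, 4), list = "B")
  yB$list_A_flag <- 0L
  yB$respondent_id <- c(5:8, 1:4)   # every respondent treated exactly once
  stacked <- structure(rbind(yl, yB), class = c("long_dataset", "data.frame"))
  w <- wald_equal_lists(stacked)
  expect_equal(w$difference, 0, tolerance = 1e-12)
  expect_equal(w$p_value, 1)
})

test_that("stacked equal-lists test has nominal size under the null", {
  R <- 1000
  rej <- vapply(seq_len(R), function(r) {
    cfg <- simulation_config(n = 400, behavior = behavior_model(0.3),
                             misreport = misreport_model("under_report", 0.5),
                             seed = 20000 + r)
    wald_equal_lists(to_long(simulate_survey(cfg)))$p_value < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.03)
  expect_lte(mean(rej), 0.07)
})

test_that("misreporting Wald test reproduces printed p-values", {
  est_a <- prevalence_estimate(0.800, 0.062, 495, scope = "list A")
  w <- wald_vs_direct(est_a, direct_mean = 0.968, n = 495)
  expect_equal(round(w$p_value, 3), 0.007)
  expect_equal(w$misreporting, 0.168, tolerance = 1e-12)
  est_b <- prevalence_estimate(0.793, 0.058, 495, scope = "list B")
  wb <- wald_vs_direct(est_b, direct_mean = 0.968, n = 495)
  expect_equal(round(wb$p_value, 3), 0.003)
  # direct equal to the list estimate: no evidence of misreporting
  w0 <- wald_vs_direct(prevalence_estimate(0.5, 0.05, 100),
                       direct_mean = 0.5, n = 100)
  expect_equal(w0$statistic, 0)
  expect_equal(w0$p_value, 1)
})

test_that("stacked misreporting test accounts for shared respondents", {
  d <- simulate_survey(study_preset("burkina", seed = 77))
  long <- to_long(d)
  est <- estimate_single_list(long, "A")
  w_ind <- wald_vs_direct(est, data = d)
  w_stk <- wald_vs_direct(est, data = d, method = "stacked")
  expect_equal(w_stk$difference, w_ind$difference)
  expect_gt(w_stk$se_diff, 0)
  # both flag the large injected under-reporting
  expect_lt(w_ind$p_value, 0.01)
  expect_lt(w_stk$p_value, 0.01)
})
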