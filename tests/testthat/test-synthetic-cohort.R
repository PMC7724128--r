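# The simulator is first-class code: these tests pin its closed-form
# moments against enumeration oracles and Monte-Carlo bands.

test_that("group assignment alternates by arrival parity", {
  expect_identical(assign_groups(4), c(1L, 2L, 1L, 2L))
  expect_identical(assign_groups(1), 1L)
  expect_identical(as.integer(table(assign_groups(1706))), c(853L, 853L))
  expect_error(assign_groups(0), "positive integer")
  expect_error(assign_groups(-3), "positive integer")
})

test_that("degenerate probabilities give deterministic counts", {
  cfg <- simulation_config(
    n = 50,
    designs = list(list_design("A", c(0, 0, 0)), list_design("B", c(0, 0, 0))),
    behavior = behavior_model(1), misreport = misreport_model("under_report", 0),
    respondent_sd = 0, seed = 3)
  d <- simulate_survey(cfg)
  treated_y <- ifelse(d$treated_list == "A", d$y_listA, d$y_listB)
  control_y <- ifelse(d$treated_list == "A", d$y_listB, d$y_listA)
  expect_true(all(treated_y == 1L))
  expect_true(all(control_y == 0L))
  expect_true(all(d$direct_report == 1L))
})

test_that("a fixed seed reproduces the dataset exactly", {
  cfg <- study_preset("senegal", seed = 99)
  d1 <- simulate_survey(cfg)
  d2 <- simulate_survey(cfg)
  expect_identical(d1, d2)
  d3 <- simulate_survey(study_preset("senegal", seed = 100))
  expect_false(identical(d1, d3))
})

test_that("control-list counts follow the Poisson-binomial of the item probs", {
  probs <- c(0.9, 0.5, 0.1)
  cfg <- simulation_config(n = 1e5, behavior = behavior_model(0.3),
                           respondent_sd = 0, seed = 17)
  d <- simulate_survey(cfg)
  y0 <- ifelse(d$treated_list == "A", d$y_listB, d$y_listA)  # control counts
  expected <- pb_pmf(probs)
  for (k in 0:3) {
    p_hat <- mean(y0 == k)
    p_true <- expected[[as.character(k)]]
    tol <- 3 * sqrt(p_true * (1 - p_true) / length(y0))
    expect_lt(abs(p_hat - p_true), tol)
  }
})

test_that("misreporting closed forms hold for both directions", {
  # under-reporting, Burkina-style: E(direct) = pi (1 - q) = 0.054
  cfg <- study_preset("burkina", seed = 7)
  d <- simulate_survey(cfg)
  band <- 3 * sqrt(0.054 * 0.946 / cfg$n)
  expect_lt(abs(mean(d$direct_report) - 0.054), band)
  # treated-minus-control difference estimates pi = 0.24
  est <- estimate_pooled(to_long(d))
  expect_lt(abs(est$beta - 0.24), 3 * est$se)
  # over-reporting: E(direct) = pi + q (1 - pi)
  cfg2 <- simulation_config(n = 5e4, behavior = behavior_model(0.3),
                            misreport = misreport_model("over_report", 0.5),
                            seed = 8)
  d2 <- simulate_survey(cfg2)
  e_direct <- 0.3 + 0.5 * 0.7
  expect_lt(abs(mean(d2$direct_report) - e_direct),
            3 * sqrt(e_direct * (1 - e_direct) / cfg2$n))
})

test_that("ceiling deflation pulls the treated mean below control + pi", {
  probs <- c(0.9, 0.9, 0.9)
  pi <- 0.3
  mu_enum <- enum_liar_treated_mean(pi, probs)   # exhaustive over 2^4 patterns
  expect_lt(mu_enum, sum(probs) + pi)            # strictly deflated
  cfg <- simulation_config(
    n = 1e5,
    designs = list(list_design("A", probs), list_design("B", probs)),
    behavior = behavior_model(pi),
    violations = violation_config(liar_mode = "deflate_at_ceiling"),
    respondent_sd = 0, seed = 21)
  d <- simulate_survey(cfg)
  y1 <- ifelse(d$treated_list == "A", d$y_listA, d$y_listB)
  y0 <- ifelse(d$treated_list == "A", d$y_listB, d$y_listA)
  expect_lt(abs(mean(y1) - mu_enum), 3 * sd(y1) / sqrt(length(y1)))
  expect_lt(mean(y1), mean(y0) + pi)
})

test_that("probability shifts outside [0,1] are clamped with a warning", {
  cfg <- simulation_config(n = 100, behavior = behavior_model(0.2),
                           violations = violation_config(design_effect_shift = 0.5),
                           respondent_sd = 0, seed = 5)
  w <- capture_warnings(simulate_survey(cfg))   # one warning per list
  expect_length(w, 2)
  expect_true(all(grepl("clamped", w)))
})

test_that("invalid configurations are rejected", {
  expect_error(simulation_config(n = 2), "n")
  expect_error(behavior_model(1.2), "probability")
  expect_error(misreport_model("under_report", -0.1), "probability")
  expect_error(list_design("A", c(0.5)), "J >= 2")
  expect_error(list_design("A", c(0.5, 1.4)), "\\[0, 1\\]")
})

test_that("guideline compliance requires a high- and a low-agreement item", {
  expect_true(list_design("A", c(0.9, 0.5, 0.1))$guideline_compliant)
  expect_false(list_design("A", c(0.6, 0.5, 0.4))$guideline_compliant)
})

test_that("subgroup effects shift the latent prevalence", {
  cfg <- simulation_config(
    n = 4e4,
    behavior = behavior_model(0.18, subgroup_effects = c(S = 0.08)),
    covariates = list(list(name = "S", type = "binary", p = 0.5)),
    misreport = misreport_model("under_report", 0), seed = 13)
  d <- simulate_survey(cfg)
  p1 <- mean(d$direct_report[d$S == 1])   # truthful direct report = Z
  p0 <- mean(d$direct_report[d$S == 0])
  expect_lt(abs(p0 - 0.18), 3 * sqrt(0.18 * 0.82 / sum(d$S == 0)))
  expect_lt(abs(p1 - 0.26), 3 * sqrt(0.26 * 0.74 / sum(d$S == 1)))
})

test_that("a simulation config round-trips through a YAML file", {
  path <- tempfile(fileext = ".yaml")
  on.exit(unlink(path))
  writeLines(c(
    "n: 120", "pi: 0.3", "seed: 9",
    "misreport:", "  direction: over_report", "  q: 0.4",
    "respondent_sd: 0",
    "covariates:", "- name: urban", "  type: binary", "  p: 0.5"), path)
  cfg <- read_simulation_config(path)
  expect_s3_class(cfg, "simulation_config")
  expect_identical(cfg$n, 120L)
  expect_identical(cfg$misreport$direction, "over_report")
  d <- simulate_survey(cfg)
  expect_identical(nrow(d), 120L)
  expect_true("urban" %in% names(d))
})
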