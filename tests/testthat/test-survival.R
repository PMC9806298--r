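# Survival statistics: Kaplan-Meier, log-rank, fixed-horizon ROC,
# Wilcoxon, chi-square, and stratified comparisons.

test_that("Kaplan-Meier reproduces hand product-limit values", {
  all_cens <- km_estimate(c(3, 7, 11), c(0, 0, 0))
  expect_true(all(all_cens$surv == 1))

  two <- km_estimate(c(2, 4), c(1, 1))
  expect_equal(two$surv[two$time == 2], 0.5)
  expect_equal(two$surv[two$time == 4], 0)

  mixed <- km_estimate(c(1, 2, 3), c(1, 0, 1))
  expect_equal(mixed$surv[mixed$time == 1], 2 / 3)
  expect_equal(mixed$surv[mixed$time == 3], 0)  # risk set shrank at 2
  expect_error(km_estimate(numeric(0), numeric(0)), "empty")
})

test_that("log-rank is exactly null on duplicated groups", {
  set.seed(32)
  t1 <- rexp(30, 0.1) + 0.01
  e1 <- rbinom(30, 1, 0.7)
  lr <- logrank_test(rep(c("a", "b"), each = 30), c(t1, t1), c(e1, e1))
  expect_equal(lr$chisq, 0, tolerance = 1e-12)
  expect_equal(lr$p, 1)
  expect_equal(lr$df, 1L)
  expect_error(logrank_test(rep("a", 10), rexp(10) + 0.1, rep(1, 10)),
               "2 non-empty")
})

test_that("fixed-horizon AUC equals the concordant-pair fraction", {
  # separable and hand-enumerated cases, all events observed
  r1 <- roc_horizon(c(0.9, 0.8, 0.2, 0.1), c(10, 20, 90, 95),
                    c(1, 1, 1, 1), horizon_months = 60)
  expect_equal(r1$auc, 1)
  r2 <- roc_horizon(c(0.9, 0.8, 0.2, 0.1), c(10, 90, 20, 95),
                    c(1, 1, 1, 1), horizon_months = 60)
  expect_equal(r2$auc, 0.75)
  # oracle equivalence on random instances with ties
  set.seed(33)
  for (rep in 1:20) {
    n <- 30
    sc <- sample(seq(0, 1, 0.1), n, replace = TRUE)
    tm <- rexp(n, 0.02) + 0.01
    ev <- rbinom(n, 1, 0.8)
    keep <- !(tm < 60 & ev == 0)
    pos <- (tm <= 60 & ev == 1)[keep]
    if (sum(pos) == 0 || sum(!pos) == 0) next
    r <- roc_horizon(sc, tm, ev, 60)
    expect_equal(r$auc, oracle_auc(sc[keep], pos), tolerance = 1e-12)
    expect_equal(r$n_used + r$n_excluded, n)
  }
  expect_error(roc_horizon(c(1, 2), c(100, 120), c(0, 0), 60), "class")
})

test_that("rank-sum statistics match exact enumeration", {
  w <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6), alternative = "less")
  expect_equal(w$statistic, 0)
  expect_equal(w$p, 1 / 20)  # all C(6,3)=20 arrangements, one as extreme
  same <- wilcoxon_rank_sum(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_gt(same$p, 0.9)
  set.seed(34)
  for (rep in 1:20) {
    x <- sample(1:100, sample(3:7, 1))
    y <- sample(1:100, sample(3:7, 1)) + 0.5  # half-integers: never tied
    got <- wilcoxon_rank_sum(x, y)$p
    expect_equal(got, oracle_wilcoxon_p(x, y), tolerance = 1e-9)
  }
})

test_that("2x2 chi-square matches the closed form and is symmetric", {
  even <- chi_square_2x2(matrix(c(10, 10, 10, 10), 2))
  expect_equal(even$chisq, 0)
  expect_equal(even$p, 1)
  tab <- matrix(c(20, 10, 10, 20), 2)
  res <- chi_square_2x2(tab)
  expect_equal(res$chisq, 60 * (20 * 20 - 10 * 10)^2 / (30 * 30 * 30 * 30),
               tolerance = 1e-12)  # = 6.667
  expect_equal(chi_square_2x2(t(tab))$chisq, res$chisq)
  expect_error(chi_square_2x2(matrix(c(0, 0, 5, 5), 2)), "margin")
})

test_that("stratified survival detects a planted therapy interaction", {
  p <- simulation_params(n_samples = 300, hormone_benefit = -1.5,
                         covariate_missing_rate = 0, seed = 41)
  sim <- simulate_infiltration(p)
  clin <- simulate_survival(sim$truth, p)
  # high immune score corresponds to the low-infiltration group B
  is_group <- factor(ifelse(sim$truth$group == "B", "high", "low"),
                     levels = c("high", "low"))
  names(is_group) <- names(sim$truth$group)
  sc <- stratified_survival(clin, is_group, covariate = "hormone_therapy")
  expect_equal(sc$df, 3L)
  expect_lt(sc$p, 0.05)
  # the treated low-IS stratum has the best survival at 36 months
  surv_at <- vapply(sc$curves, function(km) {
    i <- findInterval(36, km$time)
    if (i == 0) 1 else km$surv[i]
  }, numeric(1L))
  expect_identical(names(which.max(surv_at)), "IS-low/treated")
})

test_that("stratified survival enforces its filters and contracts", {
  p <- simulation_params(n_samples = 200, covariate_missing_rate = 0.1,
                         seed = 42)
  sim <- simulate_infiltration(p)
  clin <- simulate_survival(sim$truth, p)
  is_group <- factor(ifelse(sim$truth$group == "B", "high", "low"))
  names(is_group) <- names(sim$truth$group)
  sc <- stratified_survival(clin, is_group, covariate = "gleason_binary",
                            stage_filter = c("T3", "T4"))
  expect_equal(sum(sc$n), length(sc$groups))
  expect_gt(sc$n_excluded_missing, 0)
  expect_error(stratified_survival(clin, is_group,
                                   covariate = "n_status",
                                   stage_filter = "T9"),
               "excluded all")
})
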