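# Synthetic-cohort generator: planted shifts, correlation structure,
# survival ordering, determinism, round trips.

test_that("latent infiltration shift matches the generating mean", {
  diffs <- vapply(1:8, function(s) {
    sim <- simulate_infiltration(simulation_params(
      n_samples = 200, infiltration_shift = 3, infiltration_sd = 0.5,
      seed = s))
    grp <- sim$truth$group
    mean(sim$f[, grp == "A"]) - mean(sim$f[, grp == "B"])
  }, numeric(1L))
  expect_true(abs(mean(diffs) - 3) < 0.2)
})

test_that("zero shift leaves only sampling noise between groups", {
  sim <- simulate_infiltration(simulation_params(
    n_samples = 200, infiltration_shift = 0, seed = 11))
  grp <- sim$truth$group
  p <- t.test(colMeans(sim$f)[grp == "A"], colMeans(sim$f)[grp == "B"])$p.value
  expect_gt(p, 0.001)
})

test_that("generators are pure functions of (params, seed)", {
  a <- generate_cohort(simulation_params(n_samples = 40, seed = 3))
  b <- generate_cohort(simulation_params(n_samples = 40, seed = 3))
  expect_identical(a$expr, b$expr)
  expect_identical(a$clinical, b$clinical)
  expect_identical(a$truth$group, b$truth$group)
  c2 <- generate_cohort(simulation_params(n_samples = 40, seed = 4))
  expect_identical(dim(c2$expr), dim(a$expr))
  expect_false(identical(c2$expr, a$expr))
})

test_that("signature structure appears in the expression matrix", {
  co <- unit_cohort()
  gm <- co$truth$gene_module
  sig1 <- names(gm)[gm == rownames(co$truth$f)[1L]]
  sig2 <- names(gm)[gm == rownames(co$truth$f)[2L]]
  within <- abs(cor(t(co$expr[sig1, ])))
  between <- abs(cor(t(co$expr[sig1, ]), t(co$expr[sig2, ])))
  expect_gt(mean(within[upper.tri(within)]), mean(between))
  # checkpoint genes track mean infiltration positively
  mean_f <- colMeans(co$truth$f)
  expect_gt(cor(co$expr["CTLA4", ], mean_f), 0)
  expect_gt(cor(co$expr["CD274", ], mean_f), 0)
})

test_that("zero signature effect leaves signature genes like background", {
  p <- simulation_params(n_samples = 100, signature_effect = 0,
                         n_background_genes = 500, seed = 5)
  sim <- simulate_infiltration(p)
  ex <- simulate_expression(sim$truth, sim$f, p)
  gm <- ex$gene_module
  sig <- ex$expr[gm != "background" & gm != "checkpoint", ]
  bg <- ex$expr[gm == "background", ]
  # centred values should share one marginal distribution
  ks <- ks.test(as.numeric(sig - rowMeans(sig)),
                as.numeric(bg - rowMeans(bg)))
  expect_gt(ks$p.value, 0.01)
})

test_that("group B progresses earlier; tiny censoring window censors all", {
  p <- simulation_params(n_samples = 400, log_hr_B = 1,
                         baseline_hazard = 0.02, censoring_window = 120,
                         covariate_missing_rate = 0, seed = 9)
  sim <- simulate_infiltration(p)
  clin <- simulate_survival(sim$truth, p)
  grp <- sim$truth$group[clin$sample_id]
  km_a <- km_estimate(clin$pfs_time[grp == "A"], clin$pfs_event[grp == "A"])
  km_b <- km_estimate(clin$pfs_time[grp == "B"], clin$pfs_event[grp == "B"])
  grid <- seq(6, 96, by = 6)
  step_at <- function(km, t) {
    i <- findInterval(t, km$time)
    if (i == 0L) 1 else km$surv[i]
  }
  sa <- vapply(grid, step_at, 0, km = km_a)
  sb <- vapply(grid, step_at, 0, km = km_b)
  expect_true(all(sb <= sa))
  # gleason > 7 and N+ enriched in group B
  expect_gt(mean(clin$gleason[grp == "B"] > 7, na.rm = TRUE),
            mean(clin$gleason[grp == "A"] > 7, na.rm = TRUE))
  expect_gt(mean(clin$n_status[grp == "B"] == "N+", na.rm = TRUE),
            mean(clin$n_status[grp == "A"] == "N+", na.rm = TRUE))

  p0 <- simulation_params(n_samples = 50, censoring_window = 1e-4, seed = 9)
  clin0 <- simulate_survival(simulate_infiltration(p0)$truth, p0)
  expect_equal(sum(clin0$pfs_event), 0L)
})

test_that("written cohorts parse back through the readers without loss", {
  co <- generate_cohort(simulation_params(n_samples = 30, seed = 21))
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  expr2 <- read_expression_matrix(file.path(dir, "expression.tsv"))
  expect_equal(expr2, co$expr, tolerance = 0)
  sets2 <- read_gmt(file.path(dir, "signatures.gmt"))
  expect_identical(sets2[[1L]], co$gene_sets[[1L]])
  clin2 <- read_clinical(file.path(dir, "clinical.tsv"))
  expect_equal(clin2$pfs_time, co$clinical$pfs_time)
  expect_identical(clin2$pfs_event, co$clinical$pfs_event)
})

test_that("a minimal 20-sample cohort runs through the whole pipeline", {
  co <- generate_cohort(simulation_params(
    n_samples = 20, n_background_genes = 400,
    covariate_missing_rate = 0, seed = 13))
  cfg <- run_config(k_range = 2:3, n_restarts = 5, n_top = 500, seed = 13)
  res <- suppressWarnings(run_pipeline(co$expr, co$gene_sets, co$clinical,
                                       cfg))
  expect_s3_class(res, "immunoscore_result")
  expect_true(all(is.finite(res$is_table$IS)))
})
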