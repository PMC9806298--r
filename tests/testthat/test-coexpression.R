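# Co-expression network: variance filter, soft threshold, adjacency, TOM
# (with triple-loop oracle), module detection, eigengenes, MM/GS.

test_that("variance filter keeps the most variable genes, MAD-sorted", {
  set.seed(10)
  expr <- matrix(rnorm(1000 * 10), 1000, 10,
                 dimnames = list(paste0("G", 1:1000), paste0("S", 1:10)))
  expr["G1", ] <- 7  # constant gene
  expect_identical(filter_genes(expr, 0L), expr)
  top <- filter_genes(expr, 100L)
  expect_equal(nrow(top), 100L)
  mads <- apply(expr, 1, mad)
  expect_identical(rownames(top), names(sort(mads, decreasing = TRUE))[1:100])
  expect_false("G1" %in% rownames(top))
})

test_that("soft-threshold picker returns the grid element with its fit", {
  set.seed(12)
  expr <- matrix(rnorm(60 * 40), 60, 40,
                 dimnames = list(paste0("G", 1:60), paste0("S", 1:40)))
  res <- suppressWarnings(pick_soft_threshold(expr, beta_grid = 6))
  expect_equal(res$beta, 6)
  expect_equal(nrow(res$fit_table), 1L)
  # pure noise: no power reaches the target, the warning path fires
  expect_warning(pick_soft_threshold(expr, beta_grid = c(2, 4, 6)),
                 "falling back|no power")
  expect_error(pick_soft_threshold(expr[1:10, ]), "few genes")
})

test_that("adjacency follows |cor|^beta", {
  set.seed(13)
  x <- rnorm(50)
  expr <- rbind(a = x, b = -3 * x + 1, c = rnorm(50), d = rnorm(50))
  colnames(expr) <- paste0("S", 1:50)
  adj1 <- adjacency_matrix(expr, 1)
  expect_equal(unname(adj1["a", "b"]), 1)
  expect_equal(adj1[3:4, 3:4], abs(cor(t(expr[3:4, ]))), tolerance = 1e-12)
  adj6 <- adjacency_matrix(expr, 6)
  expect_equal(unname(adj6["a", "b"]), 1)
  expect_lt(adj6["c", "d"], 0.05)
  expr2 <- rbind(expr, e = rep(1, 50))
  expect_error(adjacency_matrix(expr2, 6), "e")
})

test_that("topological overlap matches the triple-loop oracle", {
  set.seed(14)
  for (rep in 1:5) {
    p <- 20L
    r <- matrix(runif(p * p), p)
    adj <- (r + t(r)) / 2
    diag(adj) <- 1
    dimnames(adj) <- list(paste0("G", 1:p), paste0("G", 1:p))
    tom <- tom_similarity(adj)
    expect_equal(unname(tom), oracle_tom(adj), tolerance = 1e-12)
    expect_true(isSymmetric(tom))
    expect_true(all(tom >= 0 & tom <= 1 + 1e-12))
  }
  # full-overlap pair and empty network limits
  a3 <- matrix(1, 3, 3, dimnames = list(paste0("G", 1:3), paste0("G", 1:3)))
  expect_equal(unname(tom_similarity(a3)[1, 2]), 1)
  a0 <- diag(3); dimnames(a0) <- dimnames(a3)
  t0 <- tom_similarity(a0)
  expect_equal(unname(t0[upper.tri(t0)]), rep(0, 3))
})

test_that("module detection recovers planted signatures and is order-stable", {
  co <- unit_cohort()
  expr <- filter_genes(co$expr, 1000L)
  adj <- adjacency_matrix(expr, 6)
  labels <- detect_modules(1 - tom_similarity(adj))
  gm <- co$truth$gene_module
  sig <- intersect(signature_genes(co), names(labels))
  expect_gte(adjusted_rand(labels[sig], gm[sig]), 0.8)
  # permuting gene order yields the identical partition
  perm <- sample(nrow(expr))
  labels2 <- detect_modules(1 - tom_similarity(adj[perm, perm]))
  expect_gte(adjusted_rand(labels2[names(labels)], labels), 0.999)
  # degenerate min_size sends everything to grey
  expect_warning(
    all_grey <- detect_modules(1 - tom_similarity(adj), min_size = 5000L),
    "grey")
  expect_true(all(all_grey == "grey"))
})

test_that("eigengenes are unit-variance, sign-oriented, rank-1-faithful", {
  set.seed(15)
  profile <- rnorm(30)
  expr <- t(sapply(1:5, function(i) 2 * profile + 4))
  rownames(expr) <- paste0("G", 1:5)
  colnames(expr) <- paste0("S", 1:30)
  labels <- stats::setNames(rep("turquoise", 5), rownames(expr))
  eg <- module_eigengenes(expr, labels)
  z <- (profile - mean(profile)) / sd(profile)
  expect_equal(unname(eg["turquoise", ]), z, tolerance = 1e-8)
  expect_equal(sd(eg["turquoise", ]), 1)
  # global negation leaves the eigengene unchanged (orientation rule)
  eg2 <- module_eigengenes(-expr, labels)
  expect_equal(unname(eg2["turquoise", ]), -z, tolerance = 1e-8)
})

test_that("module-trait correlation is exact for self and antisymmetric", {
  set.seed(16)
  trait <- rep(c(0, 1), each = 20)
  names(trait) <- paste0("S", 1:40)
  expr <- rbind(g1 = trait + rnorm(40, sd = 1e-6),
                g2 = trait + rnorm(40, sd = 1e-6),
                g3 = rnorm(40), g4 = rnorm(40))
  colnames(expr) <- names(trait)
  labels <- stats::setNames(c("blue", "blue", "red", "red"), rownames(expr))
  eg <- module_eigengenes(expr, labels)
  mt <- module_trait_correlation(eg, trait)
  expect_equal(mt$r[mt$module == "blue"], 1, tolerance = 1e-6)
  mt_flip <- module_trait_correlation(eg, 1 - trait)
  expect_equal(mt_flip$r, -mt$r, tolerance = 1e-12)
  expect_error(module_trait_correlation(eg, rep(1, 40)), "constant")
})

test_that("eigengene-based merging joins only near-duplicate modules", {
  set.seed(18)
  shared <- rnorm(40)
  other <- rnorm(40)
  expr <- rbind(a1 = shared + rnorm(40, sd = 0.05),
                a2 = shared + rnorm(40, sd = 0.05),
                b1 = shared + rnorm(40, sd = 0.05),
                b2 = shared + rnorm(40, sd = 0.05),
                c1 = other + rnorm(40, sd = 0.05),
                c2 = other + rnorm(40, sd = 0.05))
  colnames(expr) <- paste0("S", 1:40)
  labels <- stats::setNames(c("blue", "blue", "red", "red",
                              "green", "green"), rownames(expr))
  merged <- merge_close_modules(expr, labels, merge_cor = 0.75)
  expect_length(unique(merged[c("a1", "b1")]), 1L)  # duplicates joined
  expect_false(merged[["c1"]] %in% merged[c("a1", "b1")])
})

test_that("MM and GS behave at their extremes", {
  set.seed(17)
  trait <- rep(c(0, 1), each = 25)
  names(trait) <- paste0("S", 1:50)
  expr <- rbind(t1 = trait + rnorm(50, sd = 0.01),
                t2 = trait + rnorm(50, sd = 0.01),
                n1 = rnorm(50), n2 = rnorm(50), n3 = rnorm(50))
  colnames(expr) <- names(trait)
  labels <- stats::setNames(c("blue", "blue", "grey", "grey", "grey"),
                            rownames(expr))
  eg <- module_eigengenes(expr, labels)
  mg <- compute_mm_gs(expr, eg, labels, trait)
  expect_gt(mg$MM[mg$gene == "t1"], 0.99)
  expect_gt(mg$GS[mg$gene == "t1"], 0.99)
  expect_true(all(is.na(mg$MM[mg$module == "grey"])))
  expect_lt(max(mg$GS[mg$gene %in% c("n1", "n2", "n3")]), 0.5)
  expect_true(all(mg$GS >= 0 & mg$GS <= 1))
})
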