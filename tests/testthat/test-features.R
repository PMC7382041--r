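test_that("centroid projection is invariant to positive affine profile maps", {
  set.seed(1)
  cen <- mk_expr(matrix(rnorm(40), 10, 4), genes = sprintf("g%03d", 1:10),
                 samples = paste0("c", 1:4))
  x <- mk_expr(matrix(rnorm(30), 10, 3), genes = sprintf("g%03d", 1:10))
  sf <- subc_project(x, cen)
  x2 <- 3.7 * x + 11
  sf2 <- subc_project(x2, cen)
  expect_equal(sf2$zeta, sf$zeta, tolerance = 1e-12)
})

test_that("zeta is the clipped Fisher transform: atanh(0) = 0 and |r| = 1 clips", {
  cen <- mk_expr(matrix(c(1, 2, 3, 4), 4, 1), genes = paste0("g", 1:4),
                 samples = "c1")
  # profile equal to the centroid up to positive affine map: r = 1, clipped
  x <- mk_expr(cbind(2 * c(1, 2, 3, 4) + 5, c(1, -1, 1, -1.5)),
               genes = paste0("g", 1:4))
  sf <- subc_project(x, cen)
  expect_equal(unname(sf$zeta[1, 1]), atanh(1 - 1e-6))
  # exactly uncorrelated profile -> zeta = 0
  y <- mk_expr(cbind(c(1, -1, -1, 1), rnorm(4)), genes = paste0("g", 1:4))
  expect_lt(abs(subc_project(y, cen)$zeta[1, 1]), 1e-12)
  # Fisher transform is monotone: zeta order matches r order
  set.seed(2)
  z <- mk_expr(matrix(rnorm(40), 4, 10), genes = paste0("g", 1:4))
  sfz <- subc_project(z, cen)
  r <- cor(z, cen)
  expect_identical(order(sfz$zeta[, 1]), order(r[, 1]))
})

test_that("centroid projection guards degenerate inputs", {
  cen <- mk_expr(matrix(rnorm(8), 4, 2), genes = paste0("g", 1:4))
  tiny <- mk_expr(matrix(rnorm(4), 2, 2), genes = c("g1", "g2"))
  expect_error(subc_project(tiny, cen), ">= 3")
  flat <- mk_expr(cbind(c(1, 1, 1, 1), rnorm(4)), genes = paste0("g", 1:4),
                  samples = c("sFlat", "sOK"))
  expect_error(subc_project(flat, cen), "sFlat")
})

test_that("interaction ranking finds the one truly interacting gene", {
  hits <- 0L
  for (rep in 1:10) {
    cf <- synthetic_config(n = 400, p = 12, gamma = 1.5, beta = 0,
                           n_informative = 1, loading = 1, noise_sd = 0.3,
                           seed = 100 + rep)
    tr <- generate_trial(cf)
    ranked <- rank_genes_by_interaction(standardize(tr$expr)$expr, tr$clin)
    if (ranked$gene_id[1] == "g00001") hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})

test_that("duplicate gene profiles get adjacent ranks in deterministic id order", {
  set.seed(3)
  tr <- small_trial(n = 80, p = 10)
  x <- tr$expr
  x <- rbind(x, `g_dupA` = x[1, ], `g_dupB` = x[1, ])
  x <- x[rownames(x) != rownames(tr$expr)[1], ]
  ranked <- rank_genes_by_interaction(x, tr$clin)
  ia <- which(ranked$gene_id == "g_dupA")
  ib <- which(ranked$gene_id == "g_dupB")
  expect_equal(ib, ia + 1L)
})

test_that("select_top honors bounds", {
  ranked <- data.frame(gene_id = letters[1:5], p_value = 1:5 / 10)
  expect_identical(select_top(ranked, 3), c("a", "b", "c"))
  expect_identical(select_top(ranked, 5), letters[1:5])
  expect_error(select_top(ranked, 0), "mtop")
  expect_error(select_top(ranked, 6), "mtop")
})

test_that("PC basis is orthonormal with the symmetric two-gene solution", {
  set.seed(4)
  s <- rnorm(30)
  x <- mk_expr(rbind(s, s) + 0, genes = c("gA", "gB"))
  b <- fit_pc_basis(x, c("gA", "gB"), K = 1)
  expect_equal(abs(unname(b$components[, 1])), rep(1 / sqrt(2), 2),
               tolerance = 1e-10)
  expect_gt(max(b$components[, 1]), 0)

  y <- mk_expr(matrix(rnorm(200), 10, 20))
  b2 <- fit_pc_basis(y, rownames(y), K = 3)
  gram <- crossprod(b2$components)
  expect_equal(gram, diag(3), tolerance = 1e-8, ignore_attr = TRUE)
  expect_error(fit_pc_basis(x, c("gA", "gB"), K = 2), "rank")
})

test_that("PC1 recovers a known dominant factor", {
  set.seed(5)
  n <- 500; g <- 30
  w <- rnorm(n)
  load <- runif(g, 0.5, 1.5)
  x <- mk_expr(outer(load, w) + matrix(rnorm(g * n, sd = 0.1), g, n))
  b <- fit_pc_basis(x, rownames(x), K = 1)
  expect_gt(abs(cor(b$components[, 1], load)), 0.99)
  proj <- project_features(
    structure(list(spec = feature_spec("spc", mtop = g, K = 1), basis = b),
              class = "feature_fit"), x)
  expect_gt(abs(cor(proj[, 1], w)), 0.99)
})

test_that("projection reuses training centering and never refits on test data", {
  tr <- small_trial(n = 120)
  expr <- standardize(tr$expr)$expr
  cen <- generate_random_centroids(rownames(expr), 4, 20, seed = 9)
  spec <- feature_spec("subc", centroids = cen)
  train <- 1:80; test <- 81:120
  ffit <- fit_features(expr[, train], tr$clin[train, ], spec)
  cov_train <- project_features(ffit, expr[, train])
  expect_true(all(abs(colMeans(cov_train)) < 1e-12))

  # perturbing test samples never changes the fitted basis / selection
  spec2 <- feature_spec("spc", mtop = 8, K = 1)
  f1 <- fit_features(expr[, train], tr$clin[train, ], spec2)
  expr2 <- expr
  expr2[, test] <- expr2[, test] + 100
  f2 <- fit_features(expr2[, train], tr$clin[train, ], spec2)
  expect_identical(f1$genes, f2$genes)
  expect_equal(f1$basis$components, f2$basis$components)

  one <- project_features(ffit, expr[, test[1], drop = FALSE])
  expect_identical(dim(one), c(1L, 4L))
})

test_that("MOA restriction and direct-genes mode shape the covariates", {
  tr <- small_trial(n = 100, p = 40)
  expr <- standardize(tr$expr)$expr
  gs <- rownames(expr)[1:15]
  spec <- feature_spec("moa", geneset = gs, mtop = 5, K = 1)
  f <- fit_features(expr, tr$clin, spec)
  expect_true(all(f$genes %in% gs))
  cov <- project_features(f, expr)
  expect_identical(ncol(cov), 1L)

  spec_g <- feature_spec("moa", geneset = gs, mtop = 5,
                         moa_covariates = "genes")
  covg <- project_features(fit_features(expr, tr$clin, spec_g), expr)
  expect_identical(ncol(covg), 5L)
})

test_that("feature_spec validates requirements", {
  expect_error(feature_spec("subc"), "centroid")
  expect_error(feature_spec("moa", geneset = NULL, mtop = 5), "gene list")
  expect_error(feature_spec("spc"), "mtop")
})
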