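# Helper: hand-built hROC object with constant, fully defined curves.
mk_hroc <- function(q, hR_S, hR_R, hR_all = 0.6) {
  pts <- data.frame(threshold = q, q = q, n_S = round(q * 100),
                    hR_S = hR_S, p_S = 0.05, def_S = TRUE,
                    hR_R = hR_R, p_R = 0.05, def_R = TRUE)
  allc <- structure(list(hazard_ratio = hR_all, ci_low = hR_all / 2,
                         ci_high = hR_all * 2, p_value = 0.01, n = 100,
                         n_events = 70, defined = TRUE),
                    class = "group_comparison")
  structure(list(points = pts, hR_all = allc, n = 100), class = "hroc")
}

test_that("threshold split is closed on the sensitive side", {
  sc <- data.frame(sample_id = letters[1:5], dlhr = c(-2, -1, 0, 1, 2))
  sp <- split_at_threshold(sc, 0)
  expect_identical(unname(sp$labels), c("S", "S", "S", "R", "R"))
  expect_equal(sp$q, 3 / 5)
  expect_equal(split_at_threshold(sc, -3)$q, 0)
  expect_equal(split_at_threshold(sc, 2)$q, 1)    # closed inequality at max
  expect_equal(sp$n_S + sp$n_R, 5)
})

test_that("compare_arms is symmetric and flags undefined groups", {
  # identical survival data in both arms -> hR = 1
  tm <- c(1, 2, 3, 4, 5, 6); ev <- c(1, 1, 0, 1, 1, 0)
  clin <- mk_clin(c(tm, tm), c(ev, ev), c(rep(0, 6), rep(1, 6)))
  cmp <- compare_arms(clin)
  expect_equal(cmp$hazard_ratio, 1, tolerance = 1e-6)
  # one arm absent -> undefined
  sub <- clin$sample_id[clin$arm == 0]
  cmp0 <- compare_arms(clin, sub)
  expect_false(cmp0$defined)
  expect_error(compare_arms(clin, character(0)), "empty subset")
})

test_that("compare_arms p-value equals the log-rank test", {
  tr <- small_trial(n = 120)
  cmp <- compare_arms(tr$clin)
  sd <- survival::survdiff(
    survival::Surv(pfs_months, event) ~ arm, data = tr$clin)
  expect_equal(cmp$p_value, pchisq(sd$chisq, 1, lower.tail = FALSE),
               tolerance = 1e-6)
})

test_that("survival scatter export is one row per scored sample", {
  tr <- small_trial(n = 40)
  sc <- data.frame(sample_id = tr$clin$sample_id, dlhr = rnorm(40))
  tab <- survival_scatter(sc, tr$clin)
  expect_identical(nrow(tab), 40L)
  expect_named(tab, c("sample_id", "dlhr", "pfs_months", "event", "arm"))
  expect_identical(tab$pfs_months, tr$clin$pfs_months)
})

test_that("sweeping tie-free scores yields n + 1 partitions with q increasing", {
  tr <- small_trial(n = 60)
  set.seed(10)
  sc <- data.frame(sample_id = tr$clin$sample_id, dlhr = rnorm(60))
  h <- hroc_sweep(sc, tr$clin)
  expect_identical(nrow(h$points), 61L)
  expect_true(all(diff(h$points$q) > 0))
  expect_equal(h$points$q[1], 0)
  expect_equal(h$points$q[61], 1)
  # degenerate endpoints marked undefined
  expect_false(h$points$def_S[1])
  expect_false(h$points$def_R[61])
})

test_that("ties collapse partitions: constant scores give exactly 2", {
  tr <- small_trial(n = 30)
  sc <- data.frame(sample_id = tr$clin$sample_id, dlhr = rep(0.5, 30))
  h <- hroc_sweep(sc, tr$clin)
  expect_identical(nrow(h$points), 2L)
  expect_equal(h$points$q, c(0, 1))
})

test_that("hR(S) equals hR(all) exactly at q = 1", {
  tr <- small_trial(n = 80)
  set.seed(11)
  sc <- data.frame(sample_id = tr$clin$sample_id, dlhr = rnorm(80))
  h <- hroc_sweep(sc, tr$clin)
  last <- h$points[nrow(h$points), ]
  expect_true(last$def_S)
  expect_identical(last$hR_S, h$hR_all$hazard_ratio)
})

test_that("sweep points agree with standalone compare_arms on the same subsets", {
  tr <- small_trial(n = 50)
  set.seed(12)
  sc <- data.frame(sample_id = tr$clin$sample_id, dlhr = rnorm(50))
  h <- hroc_sweep(sc, tr$clin)
  mid <- h$points[c(15, 30, 42), ]
  for (i in seq_len(nrow(mid))) {
    sp <- split_at_threshold(sc, mid$threshold[i])
    cS <- compare_arms(tr$clin, names(sp$labels)[sp$labels == "S"],
                       min_n = 5)
    if (cS$defined) expect_equal(mid$hR_S[i], cS$hazard_ratio)
    cR <- compare_arms(tr$clin, names(sp$labels)[sp$labels == "R"],
                       min_n = 5)
    if (cR$defined) expect_equal(mid$hR_R[i], cR$hazard_ratio)
  }
})

test_that("sigma transform properties and Abc closed forms", {
  h <- c(0.1, 0.5, 1, 2, 10)
  expect_equal(sigma_hr(1), 0)
  expect_equal(sigma_hr(1 / h), -sigma_hr(h))
  expect_true(all(diff(sigma_hr(h)) > 0))
  expect_true(all(abs(sigma_hr(h)) < 1))

  # identical curves integrate to zero
  q <- seq(0.1, 0.9, by = 0.1)
  expect_equal(area_between_curves(mk_hroc(q, 0.7, 0.7))$abc, 0)

  # constant curves hR_R = 3, hR_S = 1/3 over q in [0, 1]:
  # Abc = sigma(3) - sigma(1/3) = 0.5 - (-0.5) = 1 (benefit concentrated in S)
  q01 <- seq(0, 1, by = 0.1)
  res <- area_between_curves(mk_hroc(q01, 1 / 3, 3))
  expect_equal(res$abc, 1)
  expect_equal(res$A_hR, 0.5)
  expect_equal(res$A_hS, -0.5)
  expect_lte(abs(res$abc), 1.5)

  expect_error(area_between_curves(mk_hroc(0.5, 1, 1)), "fewer than 2")
})

test_that("Abc is positive for real benefit in S and antisymmetric under negation", {
  tr <- small_trial(n = 150, gamma = 1.5)
  folds <- make_folds(tr$clin, 5, 21)
  sc <- prevalidate(standardize(tr$expr)$expr, tr$clin,
                    feature_spec("spc", mtop = 15, K = 1), folds)
  abc_pos <- area_between_curves(hroc_sweep(sc, tr$clin))$abc
  expect_gt(abc_pos, 0)
  sc_neg <- sc
  sc_neg$dlhr <- -sc$dlhr
  abc_neg <- area_between_curves(hroc_sweep(sc_neg, tr$clin))$abc
  expect_lt(abc_neg, 0)
})

test_that("selectivity index is the ratio of group hazard ratios", {
  gc <- function(h, defined = TRUE) structure(
    list(hazard_ratio = h, ci_low = h / 2, ci_high = h * 2, p_value = 0.05,
         n = 50, n_events = 30, defined = defined), class = "group_comparison")
  expect_equal(selectivity_index(gc(0.303), gc(0.722)), 0.303 / 0.722)
  expect_equal(selectivity_index(gc(0.5), gc(0.5)), 1)
  expect_identical(selectivity_index(gc(0.5), gc(0)), Inf)
  expect_true(is.na(selectivity_index(gc(0.5), gc(NA, defined = FALSE))))
})
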