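test_that("minimum imputation variants fill as documented", {
  expect_equal(min_impute(c(NA, 2, 3), "min"), c(2, 2, 3))
  expect_equal(min_impute(c(NA, 2, 3), "half_min"), c(1, 2, 3))
  imp <- min_impute(c(NA, 2, 3), "below_min")
  expect_true(imp[1] < 2)
  expect_equal(min_impute(c(1, 2, 3)), c(1, 2, 3))
  expect_error(min_impute(c(NA_real_, NA_real_)), "all values missing")
})

test_that("c-index agrees with the established implementation to 1e-12", {
  set.seed(20)
  for (r in 1:100) {
    n <- sample(10:80, 1)
    if (r %% 3 == 0) {      # discrete: x and y ties exercised
      x <- sample(1:5, n, replace = TRUE)
      y <- sample(1:6, n, replace = TRUE)
    } else {
      x <- rnorm(n); y <- x + runif(1, 0.2, 3) * rnorm(n)
    }
    if (length(unique(y)) < 2 || length(unique(x)) < 2) next
    expect_equal(cindex(y, x),
                 unname(survival::concordance(y ~ x)$concordance),
                 tolerance = 1e-12)
  }
  expect_equal(cindex(1:5, 1:5), 1)
  expect_equal(cindex(1:5, 5:1), 0)
  expect_error(cindex(c(NA, 1, 2), 1:3), "complete")
})

test_that("c-index matches the double-loop oracle on tied data", {
  set.seed(21)
  for (r in 1:30) {
    n <- sample(5:12, 1)
    x <- sample(1:4, n, replace = TRUE)
    y <- sample(1:4, n, replace = TRUE)
    if (length(unique(y)) < 2) next
    expect_equal(cindex(y, x), bf_cindex(y, x))
  }
})

test_that("high-confidence hits combine Wilcoxon and Fisher by union", {
  set.seed(22)
  n <- 120
  g <- rep(c("A", "B"), each = n / 2)
  mat <- matrix(rnorm(n * 6), n,
                dimnames = list(NULL, paste0("f", 1:6)))
  # f1: mean shift, fully observed -> Wilcoxon hit
  mat[g == "B", 1] <- mat[g == "B", 1] + 3
  # f2: observed in A, missing in B -> Fisher hit
  mat[g == "B", 2] <- NA
  # f3: both signals
  mat[g == "B", 3] <- mat[g == "B", 3] + 3
  mat[sample(which(g == "B"), 40), 3] <- NA
  # f4: null with equal moderate missingness in both groups
  mat[c(sample(which(g == "A"), 10), sample(which(g == "B"), 10)), 4] <- NA
  # f5: too few observed values in group A for a rank test, but the
  # missingness separation itself is an extreme Fisher signal
  mat[g == "A", 5] <- NA
  mat[sample(which(g == "A"), 1), 5] <- 0
  res <- hc_hits(mat, g, alpha = 0.05)
  expect_equal(res$feature, paste0("f", 1:6))
  expect_true(res$is_hc_hit[1])
  expect_true(res$is_hc_hit[2])    # fully missing in B: Fisher-only hit
  expect_true(res$is_hc_hit[3])
  expect_false(res$is_hc_hit[4])
  expect_true(res$is_hc_hit[5])
  expect_true(is.na(res$wilcoxon_p[5]))
  expect_match(res$wilcoxon_skipped_reason[5], "fewer than 2")
  expect_false(res$is_hc_hit[6])
  # union rule holds set-algebraically (NA = test unavailable)
  expect_equal(res$is_hc_hit,
               (!is.na(res$wilcoxon_p_adj) & res$wilcoxon_p_adj < 0.05) |
                 (!is.na(res$fisher_p_adj) & res$fisher_p_adj < 0.05))
  # adjusted p-values use the requested correction
  expect_equal(res$wilcoxon_p_adj,
               p.adjust(res$wilcoxon_p, "bonferroni"))
  expect_error(hc_hits(mat, rep("A", n)), "two levels")
})

test_that("complete-case concordance test ranks features like CCA Wilcoxon", {
  # binary outcome: both are rank tests on the observed values, so their
  # p-value orderings should agree closely over a feature panel
  set.seed(23)
  n <- 120; nf <- 40
  g <- rep(0:1, each = n / 2)
  pw <- pl <- numeric(nf)
  for (f in 1:nf) {
    v <- rnorm(n) + runif(1, 0, 1.2) * g
    v[sample.int(n, 30)] <- NA
    pl[f] <- lodc_test(v, g, mode = "cca")$p.value
    pw[f] <- suppressWarnings(wilcox.test(v ~ g)$p.value)
  }
  expect_gt(cor(rank(pl), rank(pw)), 0.95)
})

test_that("planted group shifts: the censored-data test recovers at least the
           complete-case + imputation hits", {
  set.seed(24)
  n <- 100; nf <- 30
  g <- rep(0:1, each = n / 2)
  p_lodc <- p_minimp <- numeric(nf)
  shifted <- rep(c(TRUE, FALSE), length.out = nf)
  for (f in 1:nf) {
    v <- rnorm(n) + ifelse(shifted[f], 1.5, 0) * g
    v[order(v, seq_along(v))[1:40]] <- NA    # strict LOD 40%
    p_lodc[f] <- lodc_test(v, g)$p.value
    p_minimp[f] <- suppressWarnings(
      wilcox.test(min_impute(v, "min") ~ g)$p.value)
  }
  cut <- 0.05 / nf
  hits_lodc <- sum(p_lodc[shifted] < cut)
  hits_minimp <- sum(p_minimp[shifted] < cut)
  expect_gte(hits_lodc, hits_minimp)
  # false positives controlled on the unshifted features
  expect_equal(sum(p_lodc[!shifted] < cut), 0)
})
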