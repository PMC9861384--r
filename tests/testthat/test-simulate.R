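test_that("lambda tuning reaches the target concordance", {
  expect_equal(tune_lambda(1, n = 500, seed = 1)$lambda, 0)
  expect_equal(tune_lambda(1, n = 500, seed = 1)$realized_d, 1)
  tl <- tune_lambda(0.85, n = 10000, seed = 2)
  expect_lt(abs(tl$realized_d - 0.85), 0.01)
  # unreachable target errors and names the achievable range
  expect_error(tune_lambda(0.505, n = 400, seed = 3, lambda_max = 0.5),
               "achievable range")
})

test_that("concordance decreases with the noise scale", {
  set.seed(4)
  n <- 4000
  x <- rnorm(n); eps <- rnorm(n)
  d <- vapply(c(0.1, 0.4, 0.8, 1.6, 3.2),
              function(l) cindex(x + l * eps, x), numeric(1))
  expect_true(all(diff(d) < 0))
})

test_that("strict censoring masks exactly the lowest values", {
  expect_equal(apply_strict_lod(1:10, 0), 1:10)
  y <- apply_strict_lod(1:10, 0.5)
  expect_equal(which(is.na(y)), 1:5)
  set.seed(5)
  yy <- rnorm(103)
  cz <- apply_strict_lod(yy, 0.3)
  expect_equal(sum(is.na(cz)), floor(103 * 0.3))
  expect_true(max(yy[is.na(cz)]) <= min(yy[!is.na(cz)]))
  expect_error(apply_strict_lod(1:5, 1), "missing_frac")
})

test_that("probabilistic censoring spans MAR to strict LOD", {
  set.seed(6)
  y <- rnorm(2000)
  # plod = 1: effectively a hard threshold, same set as strict censoring
  z1 <- apply_prob_lod(y, 0.5, 1, seed = 7)
  zs <- apply_strict_lod(y, 0.5)
  expect_lt(abs(sum(is.na(z1)) - sum(is.na(zs))), 2)
  expect_true(max(y[is.na(z1)]) <= min(y[!is.na(z1)]))

  # plod = 0: missingness ignores the value (MAR)
  diffs <- replicate(60, {
    z0 <- apply_prob_lod(y, 0.4, 0)
    mean(y[is.na(z0)]) - mean(y[!is.na(z0)])
  })
  expect_lt(abs(mean(diffs)), 3 * sd(diffs) / sqrt(length(diffs)))

  # calibration: realized fraction within 3 binomial errors at any plod
  for (pl in c(0, 0.25, 0.5, 0.75, 1)) {
    z <- apply_prob_lod(y, 0.3, pl, seed = 8)
    se <- sqrt(0.3 * 0.7 / 2000)
    expect_lt(abs(mean(is.na(z)) - 0.3), 3 * se + 1e-3)
  }
  # intermediate strictness: missing values concentrate low but not sharply
  zm <- apply_prob_lod(y, 0.5, 0.5, seed = 9)
  expect_lt(mean(y[is.na(zm)]), mean(y[!is.na(zm)]))
  expect_gt(max(y[is.na(zm)]), min(y[!is.na(zm)]))  # blurred threshold
})

test_that("multivariable generator has the stated moments and is reproducible", {
  d <- simulate_multivariable(200000, seed = 10)
  expect_lt(abs(cor(d$x, d$z) - 1 / sqrt(2)), 0.01)
  expect_lt(abs(var(d$y) - 14) / 14, 0.03)
  expect_lt(abs(mean(d$y)), 0.05)
  d2 <- simulate_multivariable(200000, seed = 10)
  expect_identical(d, d2)
  expect_error(simulate_multivariable(5), "at least 10")
})

test_that("seeded generators do not disturb the caller's RNG stream", {
  set.seed(11); a <- rnorm(2)
  set.seed(11)
  invisible(simulate_multivariable(50, seed = 99))
  invisible(tune_lambda(0.9, n = 300, seed = 98))
  b <- rnorm(2)
  expect_identical(a, b)
})

test_that("benchmark table is deterministic and coherent", {
  grid <- data.frame(n = 150, target_d = 0.85,
                     missing_frac = c(0, 0.4))
  b1 <- run_benchmark(grid, methods = c("auto", "strict", "cca", "min_imp"),
                      reps = 3, seed = 12, n_tune = 3000)
  b2 <- run_benchmark(grid, methods = c("auto", "strict", "cca", "min_imp"),
                      reps = 3, seed = 12, n_tune = 3000)
  expect_identical(b1, b2)
  expect_equal(nrow(b1), 2 * 4 * 3)
  expect_true(all(b1$estimate >= 0 & b1$estimate <= 1))
  expect_equal(b1$error, b1$estimate - b1$target_d)
  # without missing values all methods coincide
  complete <- b1[b1$missing_frac == 0, ]
  for (r in unique(complete$rep))
    expect_equal(var(complete$estimate[complete$rep == r]), 0)
})

test_that("subsampling protocol agrees with the large-sample estimate", {
  # repeated small draws from one large population, strict LOD; the mean
  # of the self-adjusting estimates matches the big-sample estimate
  set.seed(13)
  N <- 50000
  x <- rnorm(N); y <- x + 0.75 * rnorm(N)
  idx_big <- sample.int(N, 4000)
  big <- lodc(apply_strict_lod(y[idx_big], 0.3), x[idx_big])$estimate
  small <- replicate(300, {
    idx <- sample.int(N, 100)
    yy <- apply_strict_lod(y[idx], 0.3)
    lodc(yy, x[idx])$estimate
  })
  expect_lt(abs(mean(small) - big), 0.02)
})
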