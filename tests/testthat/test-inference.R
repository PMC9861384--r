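test_that("null variance reduces to the Kendall-score variance on complete data", {
  set.seed(1)
  for (n in c(10, 25, 60)) {
    y <- rnorm(n); x <- rnorm(n)
    expect_equal(cvar_null(y, x, 1), (2 * n + 5) / (18 * n * (n - 1)),
                 tolerance = 1e-12)
  }
})

test_that("null variance tracks the Monte-Carlo variance under independence", {
  set.seed(2)
  reps <- 600; n <- 150
  est <- cv <- numeric(reps)
  for (r in 1:reps) {
    x <- rnorm(n); y <- rnorm(n)
    y[rank(y) <= 45] <- NA               # 30% strict LOD
    p <- 0.7
    part <- pair_partition(y, x)
    est[r] <- weighted_concordance(part, p)
    cv[r] <- cvar_null(y, x, p)
  }
  expect_lt(abs(mean(cv) / var(est) - 1), 0.15)
})

test_that("infinitesimal jackknife matches survival's influence variance", {
  # complete data: identical construction to the established concordance
  # implementation
  set.seed(3)
  for (r in 1:10) {
    n <- sample(20:80, 1)
    x <- rnorm(n); y <- x + runif(1, 0.3, 2) * rnorm(n)
    cf <- survival::concordance(y ~ x)
    expect_equal(ivar_jackknife(y, x, 1), unname(cf$var), tolerance = 1e-10)
  }
})

test_that("infinitesimal jackknife approximates the leave-one-out jackknife", {
  set.seed(4)
  checked <- 0
  for (r in 1:100) {
    n <- sample(15:40, 1)
    x <- rnorm(n); y <- x + 0.8 * rnorm(n)
    y[order(y, seq_along(y))[seq_len(floor(0.3 * n))]] <- NA
    p <- sum(!is.na(y)) / n
    iv <- ivar_jackknife(y, x, p)
    th <- vapply(seq_len(n), function(i)
      weighted_concordance(pair_partition(y[-i], x[-i]), p), numeric(1))
    jk <- (n - 1) / n * sum((th - mean(th))^2)
    expect_lt(abs(iv / jk - 1), 0.25)
    checked <- checked + 1
  }
  expect_gte(checked, 90)
})

test_that("infinitesimal jackknife is unbiased away from the null", {
  set.seed(5)
  reps <- 1500; n <- 200
  est <- iv <- numeric(reps)
  for (r in 1:reps) {
    x <- rnorm(n); y <- x + 0.75 * rnorm(n)   # concordance ~0.8
    y[rank(y) <= 60] <- NA
    p <- 0.7
    part <- pair_partition(y, x)
    est[r] <- weighted_concordance(part, p)
    iv[r] <- ivar_jackknife(y, x, p)
  }
  expect_lt(abs(mean(iv) / var(est) - 1), 0.15)
})

test_that("z is zero and p is one at an estimate of exactly one half", {
  tt <- lodc_test(c(1, 2, 3, 4), c(1, 2, 2, 1))
  expect_equal(unname(tt$statistic), 0)
  expect_equal(tt$p.value, 1)
  expect_equal(unname(tt$estimate), 0.5)
})

test_that("p-values are invariant to monotone transforms and mirror on -x", {
  set.seed(6)
  for (r in 1:20) {
    inst <- rand_censored(sample(20:60, 1))
    if (sum(!is.na(inst$y)) < 3) next
    t0 <- lodc_test(inst$y, inst$x)
    t1 <- lodc_test(exp(inst$y), rank(inst$x))
    expect_equal(t0$p.value, t1$p.value, tolerance = 1e-10)
    # two-sided symmetry: flipping the direction flips z, keeps p
    t2 <- lodc_test(inst$y, -inst$x)
    expect_equal(unname(t2$statistic), -unname(t0$statistic),
                 tolerance = 1e-10)
    expect_equal(t2$p.value, t0$p.value, tolerance = 1e-10)
  }
})

test_that("type-I error stays near nominal across missingness fractions", {
  set.seed(7)
  n <- 200; reps <- 500
  for (frac in c(0, 0.3, 0.6)) {
    rej <- 0
    for (r in 1:reps) {
      x <- rnorm(n); y <- rnorm(n)
      if (frac > 0) y[rank(y) <= n * frac] <- NA
      rej <- rej + (lodc_test(y, x)$p.value < 0.05)
    }
    expect_gt(rej / reps, 0.02)
    expect_lt(rej / reps, 0.085)
  }
})

test_that("one-sided alternatives split the two-sided p-value", {
  set.seed(8)
  x <- rnorm(60); y <- x + rnorm(60); y[rank(y) <= 18] <- NA
  tg <- lodc_test(y, x, alternative = "greater")
  tl <- lodc_test(y, x, alternative = "less")
  expect_equal(tg$p.value + tl$p.value, 1)
  expect_lt(tg$p.value, 0.5)   # positive association
})

test_that("rejection rate grows with the true concordance", {
  set.seed(9)
  n <- 80; reps <- 120
  lam <- c(6.3, 2.0, 1.2)      # concordance ~0.55, 0.65, 0.75
  rate <- numeric(3)
  for (k in 1:3) {
    rej <- 0
    for (r in 1:reps) {
      x <- rnorm(n); y <- x + lam[k] * rnorm(n)
      y[rank(y) <= 24] <- NA
      rej <- rej + (lodc_test(y, x)$p.value < 0.05)
    }
    rate[k] <- rej / reps
  }
  expect_true(all(diff(rate) > 0))
  expect_gt(rate[3], 0.5)
})
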