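# Independent brute-force oracles and random-instance generators used
# across the suite. These deliberately share no code with the package's
# vectorised pair machinery.

# O(n^2) double-loop pair classification under the LOD assumption
bf_partition <- function(y, x) {
  n <- length(y)
  count1 <- countb <- ytie <- noncomp <- 0L
  conc1 <- concb <- 0
  for (i in seq_len(n - 1)) {
    for (j in seq.int(i + 1, n)) {
      mi <- is.na(y[i]); mj <- is.na(y[j])
      if (mi && mj) { noncomp <- noncomp + 1L; next }
      if (!mi && !mj && y[i] == y[j]) { ytie <- ytie + 1L; next }
      o <- if (mi) -1 else if (mj) 1 else sign(y[i] - y[j])
      s <- sign(x[i] - x[j]) * o
      cc <- (1 + s) / 2
      if (mi || mj) { countb <- countb + 1L; concb <- concb + cc }
      else { count1 <- count1 + 1L; conc1 <- conc1 + cc }
    }
  }
  list(count1 = count1, countb = countb, conc1 = conc1, concb = concb,
       dropped_y_ties = ytie, noncomparable = noncomp)
}

# classical tie-aware c-index by double loop (complete data)
bf_cindex <- function(y, x) {
  p <- bf_partition(y, x)
  p$conc1 / p$count1
}

# random censored instance; ties = TRUE draws from a coarse grid so x and
# y ties occur
rand_censored <- function(n, miss_frac = runif(1, 0, 0.5), ties = FALSE) {
  if (ties) {
    x <- sample(1:4, n, replace = TRUE)
    y <- sample(1:5, n, replace = TRUE) + 0
  } else {
    x <- rnorm(n)
    y <- x + runif(1, 0.2, 2) * rnorm(n)
  }
  k <- floor(n * miss_frac)
  if (k > 0) y[order(y, seq_along(y))[seq_len(k)]] <- NA
  list(y = y, x = x)
}
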