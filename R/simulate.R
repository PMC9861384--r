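# Simulation framework: concordance-targeted data generation by noise
# tuning, strict and probabilistic (sigmoid) LOD censoring, the
# multivariable generative model, and the benchmark runner.

# restore the caller's RNG state on exit; seed only if requested
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv())
    on.exit(if (has_old) assign(".Random.seed", old, envir = globalenv())
            else rm(".Random.seed", envir = globalenv()))
    set.seed(seed)
  }
  expr
}

# classical concordance of complete continuous data; survival's O(n log n)
# implementation (identical tie conventions, see cindex())
complete_concordance <- function(y, x) {
  survival::concordance(y ~ x)$concordance
}

#' Tune the noise scale to reach a target concordance
#'
#' Generates X and a noise term from standard normals, sets
#' Y = X + lambda * noise, and scans lambda upward on a grid (step 0.01)
#' until the empirical complete-data concordance of a fixed tuning sample
#' first drops to the target. Larger lambda means weaker association;
#' lambda = 0 gives concordance 1 exactly.
#'
#' @param target_d target concordance in (0.5, 1].
#' @param n tuning sample size.
#' @param seed optional integer seed for the tuning sample.
#' @param lambda_max upper end of the search grid.
#' @param step grid step.
#' @return list with \code{lambda} and \code{realized_d} (the tuning-sample
#'   concordance at that lambda).
#' @examples
#' tune_lambda(0.85, n = 2000, seed = 1)
#' @export
tune_lambda <- function(target_d, n = 10000, seed = NULL, lambda_max = 8,
                        step = 0.01) {
  if (!is.numeric(target_d) || target_d <= 0.5 || target_d > 1)
    stop("'target_d' must be in (0.5, 1]")
  with_seed(seed, {
    x <- stats::rnorm(n)
    eps <- stats::rnorm(n)
    grid <- seq(0, lambda_max, by = step)
    d <- NA_real_
    for (lam in grid) {
      d <- if (lam == 0) 1 else complete_concordance(x + lam * eps, x)
      if (d <= target_d)
        return(list(lambda = lam, realized_d = d))
    }
    stop("target concordance ", target_d, " not reachable on the grid: ",
         "achievable range is [", format(d, digits = 4), ", 1] for lambda",
         " in [0, ", lambda_max, "]")
  })
}

#' Strict limit-of-detection censoring
#'
#' Masks the \code{floor(n * missing_frac)} smallest values (ties broken by
#' position) as missing, emulating a hard detection threshold.
#'
#' @param y numeric vector (complete).
#' @param missing_frac fraction to censor, in \code{[0, 1)}.
#' @return \code{y} with the censored entries set to \code{NA}.
#' @examples
#' apply_strict_lod(1:10, 0.5)
#' @export
apply_strict_lod <- function(y, missing_frac) {
  if (missing_frac < 0 || missing_frac >= 1)
    stop("'missing_frac' must be in [0, 1)")
  k <- floor(length(y) * missing_frac)
  if (k > 0) y[order(y, seq_along(y))[seq_len(k)]] <- NA
  y
}

#' Probabilistic limit-of-detection censoring
#'
#' Masks each value independently with a probability that decreases with
#' the value along a logistic curve. The steepness is controlled by
#' \code{plod}: 0 gives a constant probability (missing at random), 1 an
#' effectively hard threshold (strict LOD), intermediate values a blurred
#' detection limit. The curve's steepness is tan(plod * pi / 2) * 2 / sd(y)
#' and its location is calibrated by root finding so that the expected
#' missing fraction equals \code{missing_frac}.
#'
#' @param y numeric vector (complete).
#' @param missing_frac expected fraction of missing values, in \code{[0, 1)}.
#' @param plod censoring strictness in \code{[0, 1]}.
#' @param seed optional integer seed for the Bernoulli draws.
#' @return \code{y} with censored entries set to \code{NA}.
#' @export
apply_prob_lod <- function(y, missing_frac, plod, seed = NULL) {
  if (plod < 0 || plod > 1) stop("'plod' must be in [0, 1]")
  if (missing_frac < 0 || missing_frac >= 1)
    stop("'missing_frac' must be in [0, 1)")
  if (missing_frac == 0) return(y)
  n <- length(y)
  if (plod == 0) {
    prob <- rep(missing_frac, n)
  } else {
    s <- tan(plod * pi / 2) * 2 / stats::sd(y)
    f <- function(v0) mean(stats::plogis(-s * (y - v0))) - missing_frac
    rng <- range(y)
    span <- diff(rng) + 1
    root <- tryCatch(
      stats::uniroot(f, lower = rng[1] - span, upper = rng[2] + span,
                     extendInt = "upX", tol = 1e-10)$root,
      error = function(e) stop("calibration of the censoring curve failed: ",
                               conditionMessage(e)))
    prob <- stats::plogis(-s * (y - root))
  }
  with_seed(seed, {
    y[stats::runif(n) < prob] <- NA
    y
  })
}

#' Simulate a censored response and covariate with target concordance
#'
#' Draws a fresh evaluation sample X ~ N(0,1), Y = X + lambda * noise,
#' applies strict (\code{plod = 1}) or probabilistic censoring, and records
#' the realized complete-data concordance.
#'
#' @param n sample size.
#' @param lambda noise scale (e.g. from \code{\link{tune_lambda}}).
#' @param missing_frac fraction of Y to censor.
#' @param plod censoring strictness in \code{[0, 1]}; 1 = strict LOD.
#' @param seed optional integer seed.
#' @return list with \code{x}, \code{y_complete}, \code{y} (censored),
#'   \code{lambda}, \code{realized_d} (complete-data concordance of the
#'   draw) and \code{realized_missing_frac}.
#' @export
simulate_censored_pair <- function(n, lambda, missing_frac = 0, plod = 1,
                                   seed = NULL) {
  with_seed(seed, {
    x <- stats::rnorm(n)
    y_complete <- x + lambda * stats::rnorm(n)
    y <- if (plod >= 1) apply_strict_lod(y_complete, missing_frac)
         else apply_prob_lod(y_complete, missing_frac, plod)
    list(x = x, y_complete = y_complete, y = y, lambda = lambda,
         realized_d = complete_concordance(y_complete, x),
         realized_missing_frac = mean(is.na(y)))
  })
}

#' Simulate the multivariable generative model
#'
#' X ~ N(0,1); Z = X + eps_z; Y = X + Z + 3 * eps_y, with independent
#' standard-normal error terms. Both X and Z carry signal for Y
#' (Var(Y) = 14, cor(X, Z) = 1/sqrt(2)).
#'
#' @param n sample size (at least 10).
#' @param seed optional integer seed.
#' @return data frame with columns \code{x}, \code{z}, \code{y}.
#' @export
simulate_multivariable <- function(n, seed = NULL) {
  if (n < 10) stop("'n' must be at least 10")
  with_seed(seed, {
    x <- stats::rnorm(n)
    z <- x + stats::rnorm(n)
    y <- x + z + 3 * stats::rnorm(n)
    data.frame(x = x, z = z, y = y)
  })
}

#' Run the estimator benchmark over a scenario grid
#'
#' For every scenario (rows of \code{scenarios}: columns \code{n},
#' \code{target_d}, \code{missing_frac}, and optionally \code{plod},
#' default 1 = strict LOD) the noise scale is tuned once on an independent
#' tuning sample, then \code{reps} evaluation datasets are drawn, censored,
#' and analysed with each requested method:
#' \itemize{
#'   \item \code{auto}: the self-adjusting weighted estimator,
#'   \item \code{strict}: the weighted estimator with p = n1/n always,
#'   \item \code{cca}: complete-case concordance,
#'   \item \code{min_imp}: minimum imputation followed by the classical
#'     concordance index.
#' }
#'
#' @param scenarios data frame of scenario settings.
#' @param methods character subset of
#'   \code{c("auto", "strict", "cca", "min_imp")}.
#' @param reps replicates per scenario.
#' @param seed integer seed (one stream for the whole run).
#' @param n_tune tuning sample size.
#' @return long-format data frame: scenario columns + \code{method},
#'   \code{rep}, \code{estimate}, \code{error} (estimate - target),
#'   \code{p_weight} (NA for non-adaptive methods) and \code{lambda}.
#' @export
run_benchmark <- function(scenarios,
                          methods = c("auto", "cca", "min_imp"),
                          reps = 10, seed = 1, n_tune = 10000) {
  methods <- match.arg(methods, c("auto", "strict", "cca", "min_imp"),
                       several.ok = TRUE)
  stopifnot(is.data.frame(scenarios),
            all(c("n", "target_d", "missing_frac") %in% names(scenarios)))
  if (is.null(scenarios$plod)) scenarios$plod <- 1
  with_seed(seed, {
    out <- vector("list", nrow(scenarios))
    for (sc in seq_len(nrow(scenarios))) {
      s <- scenarios[sc, ]
      tuned <- tune_lambda(s$target_d, n = n_tune)
      rows <- vector("list", reps)
      for (r in seq_len(reps)) {
        sim <- simulate_censored_pair(s$n, tuned$lambda, s$missing_frac,
                                      s$plod)
        est <- pw <- stats::setNames(rep(NA_real_, length(methods)),
                                     methods)
        part <- pair_partition(sim$y, sim$x)
        chk <- lod_consistency(part)
        pdef <- concordance_weight(part$n1, part$n)
        for (m in methods) {
          est[m] <- switch(m,
            auto = weighted_concordance(
              part, if (part$countb > 0 && chk$consistent) pdef else 0),
            strict = weighted_concordance(part, pdef),
            cca = weighted_concordance(part, 0),
            min_imp = cindex(min_impute(sim$y, "min"), sim$x))
          pw[m] <- if (m == "auto")
            (if (part$countb > 0 && chk$consistent) pdef else 0)
          else NA_real_
        }
        rows[[r]] <- data.frame(
          n = s$n, target_d = s$target_d, missing_frac = s$missing_frac,
          plod = s$plod, method = methods, rep = r,
          estimate = unname(est), error = unname(est) - s$target_d,
          p_weight = unname(pw), lambda = tuned$lambda,
          row.names = NULL)
      }
      out[[sc]] <- do.call(rbind, rows)
    }
    do.call(rbind, out)
  })
}
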