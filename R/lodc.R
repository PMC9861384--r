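#' Concordance between a left-censored response and a covariate
#'
#' Estimates the probability of concordance between a response \code{y}
#' subject to limit-of-detection (LOD) missingness and a fully observed
#' covariate \code{x}, without imputation. Missing responses are treated as
#' "low": a missing and an observed value can still be ranked, so pairs with
#' exactly one missing member (bridge pairs) contribute to the estimate.
#' Bridge pairs are down-weighted by p = n1/n to remove the upward bias
#' caused by discarding the uninformative missing-missing pairs.
#'
#' In \code{mode = "auto"} (the self-adjusting estimator) the bridge weight
#' is applied only when the missingness pattern looks LOD-like
#' (\code{\link{lod_consistency}}); otherwise the estimator falls back to
#' complete-case concordance (p = 0). \code{mode = "strict"} always uses
#' p = n1/n; \code{mode = "cca"} always uses p = 0. With no missing values
#' all modes coincide with the classical tie-aware concordance index.
#'
#' @param y numeric response; \code{NA} marks values below the LOD.
#' @param x numeric covariate, same length, no missing values. Continuous,
#'   ordinal-coded or 0/1 binary.
#' @param mode \code{"auto"}, \code{"strict"} or \code{"cca"}.
#' @param p optional explicit bridge weight in \code{[0, 1]}, overriding
#'   \code{mode}.
#' @return Object of class \code{"lodc"}: a list with \code{estimate},
#'   \code{p_weight} (the weight actually applied), \code{d1}, \code{db},
#'   \code{lod_consistent}, \code{direction}, \code{partition} (stratum
#'   counts), \code{n}, \code{n1}, \code{n0}, \code{mode} and
#'   \code{x_constant}.
#' @examples
#' set.seed(1)
#' x <- rnorm(100)
#' y <- x + 0.3 * rnorm(100)
#' y[y < quantile(y, 0.3)] <- NA     # strict LOD, 30% missing
#' lodc(y, x)
#' @seealso \code{\link{lodc_test}} for inference, \code{\link{conreg}} for
#'   the multivariable model.
#' @export
lodc <- function(y, x, mode = c("auto", "strict", "cca"), p = NULL) {
  mode <- match.arg(mode)
  part <- pair_partition(y, x)
  if (part$n1 < 2L)
    stop("insufficient observed values (need at least 2 non-missing y)")
  if (part$count1 == 0L)
    stop("no complete pairs: all observed y values are tied")

  chk <- lod_consistency(part)
  if (!is.null(p)) {
    p_weight <- p
  } else {
    p_weight <- switch(mode,
      auto   = if (part$countb > 0L && chk$consistent)
                 concordance_weight(part$n1, part$n) else 0,
      strict = concordance_weight(part$n1, part$n),
      cca    = 0)
    if (part$countb == 0L) p_weight <- 0  # no bridge pairs: weight is moot
  }
  est <- weighted_concordance(part, p_weight)

  x_constant <- length(unique(x)) == 1L
  if (x_constant)
    warning("'x' is constant: all pairs are x-tied, estimate is 0.5")

  structure(list(
    estimate = est,
    p_weight = p_weight,
    d1 = chk$d1, db = chk$db,
    lod_consistent = chk$consistent,
    direction = chk$direction,
    partition = part,
    n = part$n, n1 = part$n1, n0 = part$n0,
    mode = mode,
    x_constant = x_constant
  ), class = "lodc")
}

#' @export
print.lodc <- function(x, digits = 4, ...) {
  cat("Concordance with LOD-censored response (mode = ", x$mode, ")\n",
      sep = "")
  cat("  estimate :", format(x$estimate, digits = digits), "\n")
  cat("  n =", x$n, " observed =", x$n1, " missing =", x$n0, "\n")
  cat("  bridge weight p =", format(x$p_weight, digits = digits), "\n")
  if (x$partition$countb > 0L) {
    cat(sprintf("  d1 = %s, db = %s -> %s (%s direction)\n",
                format(x$d1, digits = digits),
                format(x$db, digits = digits),
                if (isTRUE(x$lod_consistent)) "LOD-consistent"
                else "not LOD-consistent (complete-case fallback)",
                x$direction))
  } else {
    cat("  no missing values: classical concordance index\n")
  }
  invisible(x)
}
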