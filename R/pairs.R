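#' Enumerate and classify observation pairs under the LOD assumption
#'
#' Classifies every unordered pair of observations of a left-censored
#' response \code{y} (missing = below the limit of detection, LOD) against a
#' fully observed covariate \code{x}. Under the LOD assumption a missing
#' value is lower than every observed value, so a pair with exactly one
#' missing response is still comparable (a \emph{bridge} pair); a pair with
#' both responses missing carries no ordering information.
#'
#' Pairs are partitioned into four strata:
#' \itemize{
#'   \item \code{pi1}: both responses observed and distinct,
#'   \item \code{pib}: exactly one response missing (bridge pairs),
#'   \item pairs dropped because both responses are observed and tied,
#'   \item noncomparable pairs (both responses missing).
#' }
#' A pair contributes 1 to its stratum's concordance tally when the signs of
#' the x- and y-differences agree, 0.5 when the x-values are tied (neither
#' concordant nor discordant), and 0 otherwise.
#'
#' @param y numeric response; \code{NA}/\code{NaN} entries are the censored
#'   (missing) values.
#' @param x numeric covariate of the same length, no missing values.
#' @param detail logical; if \code{TRUE} the per-pair index and orientation
#'   vectors are kept (needed by the pairwise likelihood and the variance
#'   estimators), otherwise only stratum counts and tallies are returned.
#' @return An object of class \code{"pair_partition"}: a list with
#'   \code{count1}, \code{countb}, \code{conc1}, \code{concb},
#'   \code{dropped_y_ties}, \code{noncomparable}, \code{n}, \code{n1},
#'   \code{n0}, and, when \code{detail = TRUE}, vectors \code{i}, \code{j},
#'   \code{stratum} (\code{"1"} or \code{"b"}), \code{o} (orientation
#'   sgn(y_i - y_j), with the missing member ranked lowest), \code{s}
#'   (sgn(x_i - x_j) * o) and \code{conc} ((1 + s)/2) over the comparable
#'   pairs.
#' @examples
#' pair_partition(c(NA, 2, 3), c(1, 2, 3))
#' @export
pair_partition <- function(y, x, detail = FALSE) {
  if (length(x) != length(y))
    stop("'x' and 'y' must have the same length (", length(x), " vs ",
         length(y), ")")
  if (anyNA(x))
    stop("'x' must not contain missing values")
  if (!is.numeric(y) || !is.numeric(x))
    stop("'x' and 'y' must be numeric")
  n <- length(y)
  if (n < 2L) stop("need at least two observations")
  obs <- !is.na(y)
  n1 <- sum(obs)
  if (n1 == 0L) stop("no observed values")

  m <- n - 1L
  I <- rep.int(seq_len(m), rev(seq_len(m)))
  J <- sequence(rev(seq_len(m)), from = seq.int(2L, n))
  oI <- obs[I]
  oJ <- obs[J]
  both_obs <- oI & oJ
  bridge <- oI != oJ
  noncomp <- !oI & !oJ

  o <- sign(y[I] - y[J])
  o[bridge & oI] <- 1                     # missing member ranks lowest
  o[bridge & !oI] <- -1
  o[noncomp] <- 0
  ytie <- both_obs & o == 0
  p1 <- both_obs & o != 0

  sx <- sign(x[I] - x[J])
  s <- sx * o
  conc <- (1 + s) / 2

  out <- list(
    count1 = sum(p1),
    countb = sum(bridge),
    conc1 = sum(conc[p1]),
    concb = sum(conc[bridge]),
    dropped_y_ties = sum(ytie),
    noncomparable = sum(noncomp),
    n = n, n1 = n1, n0 = n - n1
  )
  if (detail) {
    keep <- p1 | bridge
    out$i <- I[keep]
    out$j <- J[keep]
    stratum <- rep("1", sum(keep))
    stratum[bridge[keep]] <- "b"
    out$stratum <- stratum
    out$o <- o[keep]
    out$s <- s[keep]
    out$conc <- conc[keep]
  }
  class(out) <- "pair_partition"
  out
}

#' @export
print.pair_partition <- function(x, ...) {
  cat("Pair partition over", x$n, "observations (", x$n1, "observed,",
      x$n0, "missing )\n")
  cat(sprintf("  pi1    : %d pairs, concordance tally %.1f\n",
              x$count1, x$conc1))
  cat(sprintf("  pib    : %d bridge pairs, concordance tally %.1f\n",
              x$countb, x$concb))
  cat(sprintf("  dropped: %d y-ties, %d noncomparable (both missing)\n",
              x$dropped_y_ties, x$noncomparable))
  invisible(x)
}

#' Weighted concordance from a pair partition
#'
#' Computes (conc1 + p * concb) / (count1 + p * countb): the concordance over
#' comparable pairs with the bridge stratum down-weighted by \code{p}.
#' \code{p = 1} is the strict-LOD estimator (all comparable pairs count
#' equally); \code{p = 0} is complete-case concordance.
#'
#' @param part a \code{\link{pair_partition}}.
#' @param p bridge-pair weight in \code{[0, 1]}.
#' @return concordance estimate in \code{[0, 1]}.
#' @examples
#' part <- pair_partition(c(NA, 2, 3, 4), c(4, 1, 2, 3))
#' weighted_concordance(part, 1)    # strict-LOD estimate
#' weighted_concordance(part, 0)    # complete-case estimate
#' @export
weighted_concordance <- function(part, p = 1) {
  stopifnot(inherits(part, "pair_partition"))
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1)
    stop("'p' must be a single number in [0, 1]")
  denom <- part$count1 + p * part$countb
  if (denom <= 0)
    stop("no comparable pairs at weight p = ", p)
  (part$conc1 + p * part$concb) / denom
}

#' Debiasing weight for bridge pairs
#'
#' The default bridge-pair weight p = n1/n (observed count over total count).
#' Excluding the noncomparable missing-missing pairs inflates positive
#' concordance; down-weighting the bridge stratum by the observed fraction
#' removes that bias.
#'
#' @param n1 number of observed (non-missing) response values.
#' @param n total number of observations.
#' @return n1/n, in (0, 1].
#' @examples
#' concordance_weight(7, 10)
#' @export
concordance_weight <- function(n1, n) {
  if (n1 <= 0) stop("'n1' must be positive (no observed values)")
  if (n < n1) stop("'n' must be at least 'n1'")
  n1 / n
}

#' Check whether the missingness pattern is consistent with an LOD mechanism
#'
#' Compares the complete-pair concordance d1 = conc1/count1 with the
#' bridge-pair concordance db = concb/countb. Under a strict LOD (left
#' truncation), positive association (d1 >= 0.5) implies d1 < db, and
#' negative association implies db < d1. When the relevant inequality fails,
#' the missingness is not LOD-like and bridge pairs should be ignored
#' (complete-case analysis).
#'
#' With no bridge pairs (no missing values) the check is not applicable and
#' \code{consistent} is \code{FALSE} with \code{db = NA}; the weighting is
#' irrelevant in that case.
#'
#' @param part a \code{\link{pair_partition}}.
#' @return list with \code{consistent} (logical), \code{direction}
#'   (\code{"positive"}, \code{"negative"} or \code{"undetermined"}),
#'   \code{d1} and \code{db}.
#' @export
lod_consistency <- function(part) {
  stopifnot(inherits(part, "pair_partition"))
  if (part$count1 <= 0)
    stop("d1 undefined: no complete pairs")
  d1 <- part$conc1 / part$count1
  if (part$countb <= 0) {
    return(list(consistent = FALSE, direction = "undetermined",
                d1 = d1, db = NA_real_))
  }
  db <- part$concb / part$countb
  # d1 exactly 0.5 is treated as the positive branch; equality d1 == db
  # fails the strict inequality and is treated as inconsistent.
  if (d1 >= 0.5) {
    list(consistent = d1 < db, direction = "positive", d1 = d1, db = db)
  } else {
    list(consistent = db < d1, direction = "negative", d1 = d1, db = db)
  }
}
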