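# Comparator methods and ground-truth utilities: minimum imputation, the
# classical concordance index, and the high-confidence hit construction
# (complete-case Wilcoxon + Fisher's exact test on missingness).

#' Minimum imputation of censored values
#'
#' Replaces missing entries with the observed minimum (\code{"min"}), half
#' of it (\code{"half_min"}), or a constant strictly below the minimum
#' (\code{"below_min"}, observed minimum minus 1). The \code{"below_min"}
#' variant makes every imputed value rank strictly below every observed
#' one, so the classical concordance index on the imputed data equals the
#' strict-LOD weighted estimator with p = 1.
#'
#' @param y numeric vector with \code{NA} for censored values.
#' @param variant \code{"min"}, \code{"half_min"} or \code{"below_min"}.
#' @return imputed numeric vector (no \code{NA}).
#' @examples
#' min_impute(c(NA, 2, 3), "min")
#' min_impute(c(NA, 2, 3), "half_min")
#' @export
min_impute <- function(y, variant = c("min", "half_min", "below_min")) {
  variant <- match.arg(variant)
  if (all(is.na(y))) stop("all values missing: nothing to impute from")
  m <- min(y, na.rm = TRUE)
  fill <- switch(variant, min = m, half_min = m / 2, below_min = m - 1)
  y[is.na(y)] <- fill
  y
}

#' Classical tie-aware concordance index
#'
#' Fraction of concordant pairs among comparable pairs for two complete
#' numeric vectors: pairs tied in \code{y} are dropped, pairs tied in
#' \code{x} count 0.5 (neither concordant nor discordant). 0.5 means random
#' ordering, 1 perfect concordance, 0 perfect discordance.
#'
#' @param y numeric response, no missing values.
#' @param x numeric covariate, no missing values.
#' @return concordance in \code{[0, 1]}.
#' @examples
#' cindex(1:5, c(2, 1, 4, 3, 5))
#' @export
cindex <- function(y, x) {
  if (anyNA(y)) stop("'y' must be complete; use lodc() for censored data")
  part <- pair_partition(y, x)
  if (part$count1 < 1L) stop("fewer than one usable (untied) pair")
  weighted_concordance(part, 1)
}

#' High-confidence hits from two complementary tests
#'
#' Builds a high-confidence set of feature-outcome associations for a
#' two-group comparison by combining two tests with low false-positive
#' rates under antithetical missingness mechanisms: (1) the Wilcoxon
#' rank-sum test on observed values only (complete-case analysis) and
#' (2) Fisher's exact test on the 2x2 table of missingness status versus
#' group. P-values are adjusted across features within each test, and a
#' feature is a high-confidence hit when either adjusted p-value falls
#' below \code{alpha} (union rule). The Wilcoxon test is skipped (with a
#' recorded reason) for features with fewer than two observed values in
#' either group; Fisher's exact test on the missingness table is always
#' computable, so such features can still be hits through extreme
#' missingness separation.
#'
#' @param data numeric matrix, samples in rows and features in columns
#'   (column names are the feature ids); \code{NA} marks missing values.
#' @param group binary grouping: a factor, or anything coercible to a
#'   factor with exactly two levels, one entry per sample.
#' @param alpha significance cutoff applied to the adjusted p-values.
#' @param correction multiple-testing correction passed to
#'   \code{\link[stats]{p.adjust}} (default Bonferroni).
#' @return data frame with one row per feature: \code{feature},
#'   \code{n_obs}, \code{wilcoxon_p}, \code{fisher_p}, their adjusted
#'   versions, \code{is_hc_hit}, and \code{wilcoxon_skipped_reason}
#'   (\code{NA} where the Wilcoxon test ran).
#' @export
hc_hits <- function(data, group, alpha = 0.05, correction = "bonferroni") {
  data <- as.matrix(data)
  group <- factor(group)
  if (nlevels(group) != 2L)
    stop("'group' must have exactly two levels")
  if (length(group) != nrow(data))
    stop("'group' length must match the number of samples (rows)")
  if (any(table(group) == 0)) stop("both groups must be non-empty")
  feats <- colnames(data)
  if (is.null(feats)) feats <- paste0("feature", seq_len(ncol(data)))

  nfeat <- ncol(data)
  wp <- fp <- rep(NA_real_, nfeat)
  nobs <- integer(nfeat)
  reason <- rep(NA_character_, nfeat)
  for (f in seq_len(nfeat)) {
    v <- data[, f]
    obs <- !is.na(v)
    nobs[f] <- sum(obs)
    cnt <- table(factor(group[obs], levels = levels(group)))
    if (min(cnt) < 2) {
      reason[f] <- "fewer than 2 observed values in a group"
    } else {
      wp[f] <- suppressWarnings(
        stats::wilcox.test(v[obs] ~ group[obs])$p.value)
    }
    tab <- table(factor(is.na(v), levels = c(FALSE, TRUE)), group)
    fp[f] <- stats::fisher.test(tab)$p.value
  }
  wpa <- stats::p.adjust(wp, method = correction)
  fpa <- stats::p.adjust(fp, method = correction)
  hit <- (!is.na(wpa) & wpa < alpha) | (!is.na(fpa) & fpa < alpha)
  data.frame(feature = feats, n_obs = nobs,
             wilcoxon_p = wp, fisher_p = fp,
             wilcoxon_p_adj = wpa, fisher_p_adj = fpa,
             is_hc_hit = hit, wilcoxon_skipped_reason = reason,
             row.names = NULL)
}
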