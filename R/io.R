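# Delimited-text feature-table input and the standard metabolomics
# preprocessing step (probabilistic quotient normalisation + log2).

#' Read a delimited feature table
#'
#' Reads a rectangular TSV/CSV feature table (first column = row ids,
#' header = column ids) into a numeric matrix with samples in rows and
#' features in columns. Declared NA tokens become missing values; any other
#' non-numeric cell is an error naming its location. Duplicate sample or
#' feature ids are rejected.
#'
#' @param path file path; \code{.csv} is comma-separated, anything else
#'   tab-separated (override with \code{sep}).
#' @param na_tokens character vector of cell values to treat as missing.
#' @param orientation \code{"samples_rows"} (default) if rows are samples,
#'   \code{"features_rows"} if the file is transposed.
#' @param sep field separator; inferred from the extension when \code{NULL}.
#' @return list with \code{values} (numeric matrix, samples x features),
#'   \code{sample_ids} and \code{feature_ids}.
#' @export
read_feature_matrix <- function(path,
                                na_tokens = c("NA", "NaN", ""),
                                orientation = c("samples_rows",
                                                "features_rows"),
                                sep = NULL) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           quote = "\"", comment.char = "",
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 2L) stop("table must have an id column and data columns")
  ids <- raw[[1L]]
  if (anyDuplicated(ids))
    stop("duplicate row ids: ", paste(unique(ids[duplicated(ids)]),
                                      collapse = ", "))
  cn <- colnames(raw)[-1L]
  if (anyDuplicated(cn))
    stop("duplicate column ids: ", paste(unique(cn[duplicated(cn)]),
                                         collapse = ", "))
  vals <- as.matrix(raw[, -1L, drop = FALSE])
  vals[vals %in% na_tokens] <- NA
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop("non-numeric cell at row '", ids[bad[1, 1]], "', column '",
         cn[bad[1, 2]], "': \"", vals[bad[1, , drop = FALSE]], "\"")
  dimnames(num) <- list(ids, cn)
  if (orientation == "features_rows") num <- t(num)
  list(values = num,
       sample_ids = rownames(num),
       feature_ids = colnames(num))
}

#' Probabilistic quotient normalisation followed by log2
#'
#' Corrects sample-wise dilution effects: a reference profile is built as
#' the per-feature median over samples, using only features with a missing
#' fraction below \code{max_missing_for_reference}; each sample's quotient
#' is the median ratio of its values to the reference over those features,
#' and the sample is divided by its quotient. All observed values are then
#' log2 transformed. The missingness pattern is unchanged.
#'
#' @param mat numeric matrix, samples in rows, features in columns;
#'   intensities must be positive where observed.
#' @param max_missing_for_reference maximum per-feature missing fraction
#'   for a feature to enter the reference profile (default 0.20).
#' @return normalised, log2-transformed matrix of the same shape.
#' @export
pqn_log2 <- function(mat, max_missing_for_reference = 0.20) {
  mat <- as.matrix(mat)
  if (any(mat <= 0, na.rm = TRUE))
    stop("intensities must be positive for log2 transformation")
  miss_frac <- colMeans(is.na(mat))
  ref_feats <- which(miss_frac < max_missing_for_reference)
  if (length(ref_feats) == 0L)
    stop("no feature has missing fraction below ",
         max_missing_for_reference, ": cannot build a reference sample")
  reference <- apply(mat[, ref_feats, drop = FALSE], 2, stats::median,
                     na.rm = TRUE)
  ratios <- sweep(mat[, ref_feats, drop = FALSE], 2, reference, "/")
  quotient <- apply(ratios, 1, stats::median, na.rm = TRUE)
  if (any(!is.finite(quotient)))
    stop("sample(s) with no observed reference features: ",
         paste(rownames(mat)[!is.finite(quotient)], collapse = ", "))
  log2(sweep(mat, 1, quotient, "/"))
}
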