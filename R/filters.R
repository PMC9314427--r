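# Three-stage feature pruning: degenerate columns, pairwise correlation,
# iterative variance-inflation-factor removal.  All three operate on the
# numeric columns of a data frame; non-numeric columns (identifiers) pass
# through untouched.  Filters only ever remove columns, never modify values.
# The intended pipeline order is drop_degenerate() |> correlation_filter()
# |> vif_filter().

.numeric_cols <- function(data) names(data)[vapply(data, is.numeric, logical(1))]

#' Remove degenerate descriptor columns
#'
#' Drops every numeric column that is constant over all rows (a single
#' value carries no information) or that contains any missing value
#' (descriptor failures are molecule-specific, so the column - not the row -
#' is removed).
#'
#' @param data A data frame; numeric columns are treated as features.
#' @return The data frame without the degenerate columns.
#' @export
drop_degenerate <- function(data) {
  stopifnot(is.data.frame(data))
  drop <- vapply(data, function(col) {
    if (!is.numeric(col)) return(FALSE)
    anyNA(col) || length(unique(col)) <= 1
  }, logical(1))
  data[, !drop, drop = FALSE]
}

#' Prune highly correlated descriptor pairs
#'
#' Scans ordered column pairs (i before j in table order); whenever both are
#' still present and |Pearson r(i, j)| exceeds the threshold, the later
#' column j is dropped.  The comparison is strict (a pair at exactly the
#' threshold is retained); a 1e-10 guard absorbs last-bit rounding in the
#' computed correlation.  After the scan no surviving pair exceeds the
#' threshold.
#'
#' @param data A data frame with no missing values in its numeric columns.
#' @param threshold Absolute-correlation cutoff, default 0.7.
#' @return The data frame with correlated later columns removed.
#' @export
correlation_filter <- function(data, threshold = 0.7) {
  stopifnot(is.data.frame(data), threshold > 0)
  feats <- .numeric_cols(data)
  if (length(feats) < 2) return(data)
  if (anyNA(data[feats])) abort("correlation_filter requires no missing values")
  r <- abs(suppressWarnings(cor(as.matrix(data[feats]))))
  keep <- rep(TRUE, length(feats))
  for (j in 2:length(feats)) {
    if (any(keep[1:(j - 1)] & r[1:(j - 1), j] > threshold + 1e-10, na.rm = TRUE)) {
      keep[j] <- FALSE
    }
  }
  data[, setdiff(names(data), feats[!keep]), drop = FALSE]
}

# VIFs for all columns of a numeric matrix at once via the inverse of the
# correlation matrix; returns +Inf for exactly collinear columns.
.vif_scores <- function(x) {
  p <- ncol(x)
  r <- suppressWarnings(cor(x))
  v <- tryCatch(diag(solve(r)), error = function(e) NULL)
  if (!is.null(v) && all(is.finite(v))) return(pmax(v, 1))
  # singular correlation matrix: identify linearly dependent columns by
  # pivoted QR on the centered/scaled design
  z <- scale(x)
  qrz <- qr(z)
  v <- rep(1, p)
  if (qrz$rank < p) {
    dependent <- qrz$pivot[(qrz$rank + 1):p]
    v[dependent] <- Inf
  }
  v
}

#' Iterative variance-inflation-factor filter
#'
#' Repeatedly removes the numeric column with the largest variance inflation
#' factor, VIF_k = 1 / (1 - R^2_k) with R^2_k from regressing column k on all
#' other surviving columns, until every surviving VIF is below the
#' threshold.  Perfect collinearity gives VIF = +Inf and that column is
#' removed first; ties go to the later column in table order.
#'
#' @param data A data frame with no missing values in its numeric columns.
#' @param threshold VIF cutoff, default 4 (removal continues while any
#'   VIF >= threshold).
#' @return The data frame with multicollinear columns removed.
#' @export
vif_filter <- function(data, threshold = 4) {
  stopifnot(is.data.frame(data), threshold > 1)
  feats <- .numeric_cols(data)
  if (anyNA(data[feats])) abort("vif_filter requires no missing values")
  x <- as.matrix(data[feats])
  keep <- feats
  while (length(keep) >= 2) {
    v <- .vif_scores(x[, keep, drop = FALSE])
    if (all(v < threshold)) break
    worst <- utils::tail(which(v == max(v)), 1)
    keep <- keep[-worst]
  }
  data[, setdiff(names(data), setdiff(feats, keep)), drop = FALSE]
}
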