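# Empirical selection comparisons and least-squares index->yield models.

#' Overlap between yield-based and index-based top-fraction selection
#'
#' Ranks entries by yield and by the criterion, takes the top fraction `q`
#' of each (including all entries tied with the threshold value, so the
#' realized set can exceed ceiling(q * n)), and reports the percentage of
#' the top-q yield set recovered by the criterion. `direction = "auto"`
#' selects low criterion values when the criterion correlates negatively
#' with yield (as the water index NWI-1 does) and high values otherwise.
#'
#' @param yield_values named per-entry yield values.
#' @param criterion_values named per-entry criterion values (shared entries
#'   used).
#' @param q selected fraction in (0, 1).
#' @param direction `"high"`, `"low"` or `"auto"`.
#' @return list with `percent` (of top-q yield lines correctly selected),
#'   `selected` (criterion top set), `top_yield`, `n_target`, `direction`.
#' @export
selectionOverlap <- function(yield_values, criterion_values, q = 0.25,
                             direction = c("auto", "high", "low")) {
  direction <- match.arg(direction)
  shared <- intersect(names(yield_values), names(criterion_values))
  if (!length(shared)) stop("no shared entries between yield and criterion")
  yv <- yield_values[shared]
  cv <- criterion_values[shared]
  stopifnot(q > 0, q < 1)
  n <- length(shared)
  if (q * n < 1) stop("q * n < 1: nothing to select")
  n_target <- ceiling(q * n)
  if (direction == "auto")
    direction <- if (stats::cor(yv, cv) < 0) "low" else "high"
  top_set <- function(v, decreasing) {
    s <- sort(v, decreasing = decreasing)
    thr <- s[n_target]
    if (decreasing) names(v)[v >= thr] else names(v)[v <= thr]
  }
  top_y <- top_set(yv, TRUE)
  sel <- top_set(cv, direction == "high")
  list(percent = 100 * length(intersect(sel, top_y)) / length(top_y),
       selected = sel, top_yield = top_y, n_target = n_target,
       direction = direction)
}

#' Least-squares yield model from spectral indices across stages
#'
#' Ordinary least squares of per-entry yield on per-entry index values
#' (one column per index x stage). Reports RMSE = sqrt(SSE/n) (predictive
#' convention; set `df_adjust = TRUE` for sqrt(SSE/(n-p))), the Gaussian
#' BIC = n*log(SSE/n) + p*log(n) with p the fitted parameters including the
#' intercept (a fixed-offset convention: only BIC differences are
#' meaningful), and the correlation between fitted and observed yield.
#' Rows with missing covariates are dropped with a message; collinear
#' terms are dropped by the QR with a warning.
#'
#' @param sri_table data.frame of per-entry index values; any non-numeric
#'   columns other than `entry_id` are ignored.
#' @param yield named per-entry yield values.
#' @param df_adjust divide SSE by n - p instead of n for RMSE.
#' @return list with `fit` (lm), `coefficients`, `rmse`, `bic`,
#'   `correlation`, `n`, `p`.
#' @export
fitLSYieldModel <- function(sri_table, yield, df_adjust = FALSE) {
  stopifnot("entry_id" %in% names(sri_table))
  idx <- match(sri_table$entry_id, names(yield))
  keep <- !is.na(idx)
  df <- sri_table[keep, setdiff(names(sri_table), "entry_id"), drop = FALSE]
  df <- df[, vapply(df, is.numeric, logical(1)), drop = FALSE]
  df$.yield <- yield[idx[keep]]
  cc <- stats::complete.cases(df)
  if (any(!cc)) message(sum(!cc), " row(s) with missing values dropped")
  df <- df[cc, , drop = FALSE]
  p_terms <- ncol(df)  # predictors + intercept
  if (nrow(df) <= p_terms) stop("need n > number of fitted parameters")
  fit <- stats::lm(.yield ~ ., data = df)
  if (anyNA(stats::coef(fit)))
    warning("collinear term(s) dropped: ",
            paste(names(stats::coef(fit))[is.na(stats::coef(fit))], collapse = ", "))
  n <- nrow(df)
  p <- sum(!is.na(stats::coef(fit)))
  sse <- sum(stats::residuals(fit)^2)
  rmse <- sqrt(sse / if (df_adjust) (n - p) else n)
  bic <- n * log(sse / n) + p * log(n)
  corr <- if (stats::var(stats::fitted(fit)) > 0)
    stats::cor(stats::fitted(fit), df$.yield) else NA_real_
  list(fit = fit, coefficients = stats::coef(fit), rmse = rmse, bic = bic,
       correlation = corr, n = n, p = p)
}
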