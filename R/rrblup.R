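# Ridge-regression BLUP: y = X beta + M u + eps with u ~ N(0, sigma2_u I)
# over centered marker dosages M (the infinitesimal model with equal marker
# variance). The variance ratio lambda = sigma2_eps / sigma2_u is estimated
# by REML through the spectral decomposition of the marker kernel M M'
# (profiled restricted likelihood in the single ratio), after which marker
# effects have the closed form u = M'(MM' + lambda I)^-1 (y - X beta_hat),
# identical to (M'M + lambda I)^-1 M'(y - X beta_hat).

.profileREML <- function(y, X, K) {
  n <- length(y)
  p <- ncol(X)
  XtXi <- solve(crossprod(X))
  S <- diag(n) - X %*% XtXi %*% t(X)
  eg <- eigen(S %*% K %*% S, symmetric = TRUE)
  xi <- pmax(eg$values[seq_len(n - p)], 0)
  U <- eg$vectors[, seq_len(n - p), drop = FALSE]
  eta <- drop(crossprod(U, y))
  ll <- function(logd) {
    d <- exp(logd)
    ss <- sum(eta^2 / (xi + d))
    0.5 * ((n - p) * (log((n - p) / (2 * pi)) - 1 - log(ss)) - sum(log(xi + d)))
  }
  grid <- seq(log(1e-6), log(1e6), length.out = 61)
  vals <- vapply(grid, ll, numeric(1))
  i <- which.max(vals)
  lo <- grid[max(1, i - 1)]
  hi <- grid[min(length(grid), i + 1)]
  opt <- stats::optimize(ll, c(lo, hi), maximum = TRUE, tol = 1e-10)
  delta <- exp(opt$maximum)
  sigma2_u <- sum(eta^2 / (xi + delta)) / (n - p)
  list(delta = delta, sigma2_u = sigma2_u, sigma2_eps = delta * sigma2_u)
}

.asCovariateMatrix <- function(fixed, ids) {
  if (is.null(fixed)) return(NULL)
  f <- as.data.frame(fixed)
  if (!is.null(rownames(f)) && all(ids %in% rownames(f)))
    f <- f[ids, , drop = FALSE]
  else if (nrow(f) != length(ids))
    stop("covariate table must cover every training/test line")
  fm <- as.matrix(f)
  storage.mode(fm) <- "double"
  if (anyNA(fm)) stop("covariates contain missing values")
  fm
}

#' Fit a ridge-regression BLUP genomic prediction model
#'
#' Fits `y = X beta + M u + eps` with centered marker dosages `M`, an
#' intercept plus optional secondary-trait covariates in `X`, and i.i.d.
#' marker effects shrunk by `lambda = sigma2_eps / sigma2_u`. The variance
#' components are REML estimates from the spectral decomposition of the
#' marker kernel; pass `lambda` to fix the ridge parameter instead.
#'
#' @param y named numeric vector of adjusted phenotypes (names = line ids
#'   present in `g`), or unnamed with one value per line of `g`.
#' @param g a [GenotypeMatrix-class] without missing calls (impute first).
#' @param fixed optional per-line covariate table (data.frame or matrix;
#'   rownames matched to line ids when present).
#' @param lambda optional fixed ridge parameter (skips REML).
#' @return a [GSModel-class].
#' @export
fitRRBLUP <- function(y, g, fixed = NULL, lambda = NULL) {
  d <- dosage(g)
  if (is.null(names(y))) {
    if (length(y) != nrow(d)) stop("unnamed y must have one value per line of g")
    names(y) <- rownames(d)
  }
  miss_l <- setdiff(names(y), rownames(d))
  if (length(miss_l)) stop(length(miss_l), " line(s) of y absent from g")
  M <- d[names(y), , drop = FALSE]
  if (anyNA(M)) stop("missing genotype calls present; run imputeMissing() first")
  if (length(y) < 2) stop("need >= 2 training lines")
  if (stats::var(y) == 0) stop("constant response; nothing to fit")
  centers <- colMeans(M)
  Mc <- sweep(M, 2, centers)
  Fm <- .asCovariateMatrix(fixed, names(y))
  X <- cbind(`(Intercept)` = rep(1, length(y)), Fm)
  if (qr(X)$rank < ncol(X))
    stop("collinear fixed-effect covariates: ",
         paste(colnames(X)[-1], collapse = ", "))
  K <- tcrossprod(Mc)
  if (is.null(lambda)) {
    vc <- .profileREML(y, X, K)
    lambda <- vc$delta
    s2u <- vc$sigma2_u
    s2e <- vc$sigma2_eps
  } else {
    stopifnot(is.finite(lambda), lambda > 0)
    s2u <- NA_real_
    s2e <- NA_real_
  }
  H <- K + lambda * diag(length(y))
  Hiy <- solve(H, cbind(y, X))
  XtHiX <- crossprod(X, Hiy[, -1, drop = FALSE])
  beta <- drop(solve(XtHiX, crossprod(X, Hiy[, 1])))
  names(beta) <- colnames(X)
  resid <- y - drop(X %*% beta)
  u <- drop(crossprod(Mc, solve(H, resid)))
  names(u) <- colnames(M)
  new("GSModel", beta = beta, u = u, lambda = lambda,
      sigma2_u = s2u, sigma2_eps = s2e,
      centers = stats::setNames(centers, colnames(M)),
      covariates = colnames(X)[-1] %||% character(),
      covariate_means = if (is.null(Fm)) numeric() else colMeans(Fm))
}

#' Genomic estimated breeding values for new lines
#'
#' GEBV = X_test beta_hat + M_test u, with the test dosages centered by the
#' training-set constants. Test markers are matched by marker id and must
#' cover every fitted marker. Models carrying secondary-trait fixed effects
#' require covariate values for the test lines; `covariate_policy =
#' "train_mean"` instead substitutes the training means (an extrapolation:
#' the covariate then shifts all predictions equally).
#'
#' @param model a [GSModel-class].
#' @param g_test [GenotypeMatrix-class] for the candidate lines.
#' @param fixed_test optional covariate table for the test lines.
#' @param covariate_policy `"require"` (default) or `"train_mean"`.
#' @return named numeric vector of GEBVs, one per test line.
#' @export
predictGEBV <- function(model, g_test, fixed_test = NULL,
                        covariate_policy = c("require", "train_mean")) {
  covariate_policy <- match.arg(covariate_policy)
  d <- dosage(g_test)
  miss <- setdiff(names(model@u), colnames(d))
  if (length(miss))
    stop(length(miss), " fitted marker(s) absent from the test panel")
  M <- d[, names(model@u), drop = FALSE]
  if (anyNA(M)) stop("missing genotype calls in test panel; impute first")
  Mc <- sweep(M, 2, model@centers)
  if (length(model@covariates)) {
    if (is.null(fixed_test)) {
      if (covariate_policy == "require")
        stop("model carries fixed-effect covariate(s) ",
             paste(model@covariates, collapse = ", "),
             "; supply fixed_test or set covariate_policy = 'train_mean'")
      Fm <- matrix(rep(model@covariate_means, each = nrow(M)), nrow = nrow(M),
                   dimnames = list(rownames(M), model@covariates))
    } else {
      Fm <- .asCovariateMatrix(fixed_test, rownames(M))
      if (!all(model@covariates %in% colnames(Fm)))
        stop("fixed_test lacks covariate(s): ",
             paste(setdiff(model@covariates, colnames(Fm)), collapse = ", "))
      Fm <- Fm[, model@covariates, drop = FALSE]
    }
    X <- cbind(1, Fm)
  } else {
    X <- matrix(1, nrow(M), 1)
  }
  drop(X %*% model@beta + Mc %*% model@u)
}

#' Pearson prediction accuracy
#'
#' Correlation between observed adjusted means (BLUEs/BLUPs) and GEBVs.
#' @param observed,gebv paired per-line values (>= 3 pairs, non-constant).
#' @return Pearson r in \[-1, 1\].
#' @export
predictionAccuracy <- function(observed, gebv) {
  ok <- !is.na(observed) & !is.na(gebv)
  observed <- observed[ok]
  gebv <- gebv[ok]
  if (length(observed) < 3) stop("need >= 3 paired values")
  if (stats::var(observed) == 0 || stats::var(gebv) == 0)
    stop("undefined correlation: constant input")
  stats::cor(observed, gebv)
}
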