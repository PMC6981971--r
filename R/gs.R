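# Marker QC, imputation, and the two validation schemes used for genomic
# prediction of yield: k-fold cross-validation within a panel, and
# independent validation of separate test panels.

#' Filter markers on minor-allele frequency
#'
#' Retains markers with MAF strictly greater than `threshold` (so a marker
#' sitting exactly at the threshold is removed). Marker order is preserved;
#' the numbers of markers before/after are recorded in the `"filter_log"`
#' attribute.
#'
#' @param g a [GenotypeMatrix-class].
#' @param threshold frequency in \[0, 0.5).
#' @return the filtered [GenotypeMatrix-class].
#' @export
filterMAF <- function(g, threshold = 0.05) {
  stopifnot(threshold >= 0, threshold < 0.5)
  f <- maf(g)
  keep <- which(!is.na(f) & f > threshold)
  if (!length(keep)) stop("MAF filter removed every marker")
  out <- g[, keep]
  attr(out, "filter_log") <- c(before = ncol(g), after = length(keep),
                               removed = ncol(g) - length(keep))
  out
}

#' Impute missing genotype calls
#'
#' `method = "mean"` replaces each missing call by the marker mean of the
#' non-missing calls (fractional dosages allowed). `method = "ld_knn"` is
#' LD-informed k-nearest-neighbour imputation: for each marker with missing
#' calls, the `l` other markers most correlated with it (r^2 over pairwise
#' complete calls) are selected; each missing cell is then filled with the
#' inverse-distance-weighted mean call of the `k` lines nearest to the
#' target line by matching distance (proportion of differing calls) on
#' those markers. Both methods are deterministic given the data.
#'
#' @param g a [GenotypeMatrix-class].
#' @param method `"mean"` or `"ld_knn"`.
#' @param k neighbour count for `ld_knn`.
#' @param l candidate-marker count for `ld_knn`.
#' @return a [GenotypeMatrix-class] without missing calls; the number of
#'   imputed cells is in the `"impute_log"` attribute.
#' @export
imputeMissing <- function(g, method = c("mean", "ld_knn"), k = 10, l = 30) {
  method <- match.arg(method)
  d <- dosage(g)
  all_miss <- colSums(!is.na(d)) == 0
  if (any(all_miss))
    stop("marker(s) 100% missing: ",
         paste(colnames(d)[all_miss][seq_len(min(5, sum(all_miss)))], collapse = ", "))
  n_imp <- sum(is.na(d))
  if (n_imp == 0) {
    attr(g, "impute_log") <- c(imputed = 0)
    return(g)
  }
  if (method == "mean") {
    cm <- colMeans(d, na.rm = TRUE)
    for (j in which(colSums(is.na(d)) > 0)) d[is.na(d[, j]), j] <- cm[j]
  } else {
    d <- .ldknnImpute(d, k, l)
  }
  out <- GenotypeMatrix(d, chrom = g@chrom, pos = g@pos)
  attr(out, "impute_log") <- c(imputed = n_imp)
  out
}

.ldknnImpute <- function(d, k, l) {
  targets <- which(colSums(is.na(d)) > 0)
  filled <- d
  for (j in targets) {
    r <- suppressWarnings(stats::cor(d[, j], d, use = "pairwise.complete.obs"))
    r2 <- drop(r)^2
    r2[j] <- NA
    r2[is.na(r2)] <- -Inf
    cand <- order(r2, decreasing = TRUE)[seq_len(min(l, ncol(d) - 1))]
    cand <- cand[is.finite(r2[cand])]
    donors_all <- which(!is.na(d[, j]))
    for (i in which(is.na(d[, j]))) {
      if (!length(cand)) {  # no informative markers: fall back to marker mean
        filled[i, j] <- mean(d[donors_all, j])
        next
      }
      prof <- d[i, cand]
      dist <- vapply(donors_all, function(h) {
        ok <- !is.na(prof) & !is.na(d[h, cand])
        if (!any(ok)) return(1)
        mean(prof[ok] != d[h, cand][ok])
      }, numeric(1))
      ord <- order(dist, donors_all)
      nb <- donors_all[ord[seq_len(min(k, length(donors_all)))]]
      w <- 1 / (dist[ord[seq_len(length(nb))]] + 1e-6)
      filled[i, j] <- sum(w * d[nb, j]) / sum(w)
    }
  }
  filled
}

.newPredictionResult <- function(gebv, assignment, accuracy, per_fold = NULL,
                                 scenario = list()) {
  out <- list(gebv = gebv, assignment = assignment, accuracy = accuracy,
              per_fold = per_fold, scenario = scenario)
  class(out) <- "PredictionResult"
  out
}

#' @exportS3Method base::print
print.PredictionResult <- function(x, ...) {
  cat("PredictionResult:", length(x$gebv), "line(s)\n")
  if (!is.null(x$per_fold))
    cat("  per-fold accuracy:", paste(sprintf("%.3f", x$per_fold), collapse = " "), "\n")
  cat(sprintf("  accuracy (Pearson) = %.4f\n", x$accuracy))
  if (length(x$scenario))
    cat("  scenario:", paste(names(x$scenario), unlist(x$scenario),
                             sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' k-fold cross-validation of RRBLUP prediction accuracy
#'
#' Lines are partitioned into `k` near-equal random folds (sizes differing
#' by at most one, seeded); each fold is predicted by a model fitted on the
#' remaining lines. Accuracy is the Pearson correlation of observed values
#' and GEBVs within each fold, averaged over folds. The ridge parameter is
#' estimated once on the full data and reused per fold unless
#' `per_fold_lambda = TRUE`.
#'
#' @param y named numeric vector of adjusted phenotypes.
#' @param g [GenotypeMatrix-class] covering the lines of `y`.
#' @param fixed optional covariate table (see [fitRRBLUP()]).
#' @param k number of folds (>= 2).
#' @param seed RNG seed for the fold assignment.
#' @param per_fold_lambda re-estimate the variance ratio inside every fold.
#' @return a `PredictionResult` with per-line GEBVs, fold assignment,
#'   per-fold accuracies and their mean.
#' @export
kfoldCV <- function(y, g, fixed = NULL, k = 5, seed = 1, per_fold_lambda = FALSE) {
  stopifnot(k >= 2, length(y) >= k)
  if (is.null(names(y))) names(y) <- lineIds(g)[seq_along(y)]
  n <- length(y)
  set.seed(seed)
  fold <- sample(rep(seq_len(k), length.out = n))
  names(fold) <- names(y)
  lam <- if (per_fold_lambda) NULL else fitRRBLUP(y, g, fixed)@lambda
  gebv <- stats::setNames(rep(NA_real_, n), names(y))
  per_fold <- rep(NA_real_, k)
  Fm <- if (is.null(fixed)) NULL else .asCovariateMatrix(fixed, names(y))
  for (f in seq_len(k)) {
    tr <- names(y)[fold != f]
    te <- names(y)[fold == f]
    mod <- fitRRBLUP(y[tr], g[tr, ],
                     fixed = if (is.null(Fm)) NULL else Fm[tr, , drop = FALSE],
                     lambda = lam)
    gebv[te] <- predictGEBV(mod, g[te, ],
                            fixed_test = if (is.null(Fm)) NULL else Fm[te, , drop = FALSE])
    if (stats::var(y[te]) == 0) {
      warning("fold ", f, " has constant observed values; accuracy undefined, excluded")
    } else {
      per_fold[f] <- stats::cor(y[te], gebv[te])
    }
  }
  .newPredictionResult(gebv, fold, mean(per_fold, na.rm = TRUE), per_fold,
                       scenario = list(k = k, seed = seed,
                                       fixed = paste(colnames(Fm), collapse = "+")))
}

#' Independent train/test validation
#'
#' Fits RRBLUP on the full training panel and predicts a separate test
#' panel over the markers shared by both panels (matched by marker id).
#' Accuracy is the Pearson correlation between the test panel's observed
#' adjusted means and the GEBVs.
#'
#' @param y_train,g_train training phenotypes and genotypes.
#' @param y_test,g_test test-panel phenotypes and genotypes.
#' @param fixed_train,fixed_test optional covariate tables.
#' @param covariate_policy forwarded to [predictGEBV()].
#' @param scenario_name label stored in the result metadata.
#' @return a `PredictionResult`.
#' @export
independentValidation <- function(y_train, g_train, y_test, g_test,
                                  fixed_train = NULL, fixed_test = NULL,
                                  covariate_policy = "require",
                                  scenario_name = "independent") {
  shared <- intersect(markerIds(g_train), markerIds(g_test))
  if (!length(shared)) stop("no markers shared between training and test panels")
  mod <- fitRRBLUP(y_train, g_train[, shared], fixed = fixed_train)
  gebv <- predictGEBV(mod, g_test[, shared], fixed_test = fixed_test,
                      covariate_policy = covariate_policy)
  if (is.null(names(y_test))) names(y_test) <- lineIds(g_test)[seq_along(y_test)]
  gebv <- gebv[names(y_test)]
  acc <- predictionAccuracy(y_test, gebv)
  .newPredictionResult(gebv,
                       stats::setNames(rep("test", length(y_test)), names(y_test)),
                       acc,
                       scenario = list(name = scenario_name,
                                       n_train = length(y_train),
                                       n_test = length(y_test),
                                       m_shared = length(shared)))
}
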