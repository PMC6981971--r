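# Augmented-design adjustment. Per-environment BLUEs treat block, genotype
# and check terms as fixed; across-environment BLUPs treat genotype, check
# identity, environment and their interactions (and blocks nested in
# environments) as random, with a 1-df fixed indicator separating replicated
# checks from un-replicated test entries. REML fitting is delegated to lme4.

# tight optimizer tolerances: REML estimates are quoted against closed-form
# oracles to 1e-6, which the default stopping rules do not guarantee
.lmerCtrl <- function() {
  lme4::lmerControl(optimizer = "bobyqa",
                    check.nobs.vs.nlev = "ignore",
                    check.nobs.vs.nRE = "ignore",
                    optCtrl = list(rhoend = 1e-13))
}

.genoFactor <- function(tt) {
  ifelse(tt$is_check, tt$check_id, tt$entry_id)
}

.prepTrial <- function(tt) {
  tt <- tt[!is.na(tt$response), , drop = FALSE]
  if (!nrow(tt)) stop("no non-missing responses in trial table")
  tt$gen <- .genoFactor(tt)
  tt$entry_f <- ifelse(tt$is_check, ".check.", tt$entry_id)
  tt$check_f <- ifelse(tt$is_check, tt$check_id, ".entry.")
  tt$blk <- paste(tt$environment_id, tt$block_id, sep = ":")
  tt
}

#' Augmented-design adjusted genotype means
#'
#' `mode = "BLUE_single_env"` fits the single-environment fixed-effects
#' model (response = mean + block + genotype, with checks providing the
#' block information) by ordinary least squares and reports, per genotype,
#' the adjusted mean under a sum-to-zero block convention. All non-check
#' entries (and the checks) get one value each.
#'
#' `mode = "BLUP_combined"` fits the across-environment model with random
#' genotype, check identity, environment, their interactions and blocks
#' nested in environments (REML via lme4), and reports mean + genotype BLUP,
#' i.e. values shrunk toward the grand mean.
#'
#' @param trial trial-table data.frame (see [readTrialTable()]).
#' @param mode `"BLUE_single_env"` or `"BLUP_combined"`.
#' @return data.frame with columns `entry_id`, `is_check`, `value`;
#'   attributes `mode`, `response`, `sigma2_eps`, `converged`.
#' @export
fitAdjustedMeans <- function(trial, mode = c("BLUE_single_env", "BLUP_combined")) {
  mode <- match.arg(mode)
  resp <- attr(trial, "response") %||% "yield"
  tt <- .prepTrial(trial)
  if (mode == "BLUE_single_env") {
    if (length(unique(tt$environment_id)) != 1)
      stop("BLUE_single_env requires a single environment; subset first")
    out <- .fitBlueSingleEnv(tt)
  } else {
    if (length(unique(tt$environment_id)) < 2)
      stop("BLUP_combined requires >= 2 environments")
    out <- .fitBlupCombined(tt)
  }
  attr(out, "mode") <- mode
  attr(out, "response") <- resp
  out
}

.fitBlueSingleEnv <- function(tt) {
  blocks <- unique(tt$block_id)
  if (length(unique(tt$gen)) == 1) {
    # degenerate single-genotype case: nothing to contrast, report the mean
    out <- data.frame(entry_id = tt$gen[1], is_check = tt$is_check[1],
                      value = mean(tt$response), stringsAsFactors = FALSE)
    attr(out, "sigma2_eps") <- if (nrow(tt) > 1) stats::var(tt$response) else NA_real_
    attr(out, "converged") <- TRUE
    return(out)
  }
  if (length(blocks) > 1) {
    has_check <- vapply(blocks, function(b) any(tt$is_check[tt$block_id == b]),
                        logical(1))
    if (!all(has_check))
      stop("block(s) without checks are inestimable: ",
           paste(blocks[!has_check], collapse = ", "))
    tt$block_f <- factor(tt$block_id)
    X <- stats::model.matrix(~ 0 + gen + block_f, data = tt,
                             contrasts.arg = list(block_f = "contr.sum"))
  } else {
    X <- stats::model.matrix(~ 0 + gen, data = tt)
  }
  fit <- stats::lm.fit(X, tt$response)
  if (any(is.na(fit$coefficients)))
    stop("rank-deficient design; confounded term(s): ",
         paste(names(fit$coefficients)[is.na(fit$coefficients)], collapse = ", "))
  co <- fit$coefficients
  gens <- unique(tt[, c("gen", "is_check")])
  val <- co[paste0("gen", gens$gen)]
  rdf <- nrow(tt) - fit$rank
  s2 <- if (rdf > 0) sum(fit$residuals^2) / rdf else NA_real_
  out <- data.frame(entry_id = gens$gen, is_check = gens$is_check,
                    value = unname(val), stringsAsFactors = FALSE)
  attr(out, "sigma2_eps") <- s2
  attr(out, "converged") <- TRUE
  out
}

.augmentedFormula <- function(tt, include_blocks = TRUE) {
  has_checks <- any(tt$is_check %in% c(TRUE, "TRUE"))
  multi_env <- length(unique(tt$environment_id)) > 1
  terms <- c("(1 | entry_f)")
  if (has_checks) terms <- c(terms, "(1 | check_f)")
  if (multi_env) {
    terms <- c(terms, "(1 | environment_id)", "(1 | entry_f:environment_id)")
    if (has_checks) terms <- c(terms, "(1 | check_f:environment_id)")
  }
  if (include_blocks && length(unique(tt$blk)) > length(unique(tt$environment_id)))
    terms <- c(terms, "(1 | blk)")
  fixed <- if (has_checks) "response ~ 1 + is_check" else "response ~ 1"
  stats::as.formula(paste(fixed, "+", paste(terms, collapse = " + ")))
}

.fitBlupCombined <- function(tt) {
  tt$is_check <- factor(tt$is_check, levels = c(FALSE, TRUE))
  fm <- .augmentedFormula(tt, include_blocks = any(tt$is_check == "TRUE"))
  fit <- lme4::lmer(fm, data = tt, REML = TRUE, control = .lmerCtrl())
  mu <- unname(lme4::fixef(fit)[1])
  re <- lme4::ranef(fit)$entry_f
  entries <- setdiff(unique(tt$entry_f), ".check.")
  blup <- stats::setNames(rep(0, length(entries)), entries)
  hit <- intersect(entries, rownames(re))
  blup[hit] <- re[hit, 1]
  out <- data.frame(entry_id = entries, is_check = FALSE,
                    value = mu + unname(blup), stringsAsFactors = FALSE)
  attr(out, "sigma2_eps") <- stats::sigma(fit)^2
  attr(out, "converged") <- length(fit@optinfo$conv$lme4$messages) == 0
  out
}

#' REML variance components for heritability
#'
#' Fits the across-environment random model (genotype, genotype x
#' environment, environment, check terms when checks are present, blocks
#' nested in environments for augmented layouts) and returns the components
#' entering broad-sense heritability. Estimates are REML with the
#' non-negativity constraint inherent to the parameterisation, and are
#' deterministic given the data.
#'
#' `blocks = "auto"` includes the nested-block term only when checks are
#' present (augmented layout, blocks estimable through checks); in plainly
#' replicated balanced trials the block label is a bare replicate index and
#' is excluded, which makes the estimator coincide with the classical
#' ANOVA expected-mean-squares solution on balanced data.
#'
#' @param trial trial-table data.frame.
#' @param blocks `"auto"`, `"include"` or `"exclude"`.
#' @return an object of class `VarianceComponents`: list with `sigma2_G`,
#'   `sigma2_GEI` (`NA` when only one environment), `sigma2_eps`, `n_env`,
#'   `n_rep`, `converged`.
#' @export
estimateVarianceComponents <- function(trial, blocks = c("auto", "include", "exclude")) {
  blocks <- match.arg(blocks)
  tt <- .prepTrial(trial)
  if (stats::var(tt$response) == 0) stop("response is constant; variance components undefined")
  n_env <- length(unique(tt$environment_id))
  inc_blocks <- switch(blocks, auto = any(tt$is_check),
                       include = TRUE, exclude = FALSE)
  tt$is_check <- factor(tt$is_check, levels = c(FALSE, TRUE))
  fm <- .augmentedFormula(tt, include_blocks = inc_blocks)
  fit <- lme4::lmer(fm, data = tt, REML = TRUE, control = .lmerCtrl())
  vc <- as.data.frame(lme4::VarCorr(fit))
  getv <- function(g) {
    v <- vc$vcov[vc$grp == g]
    if (length(v)) v else NA_real_
  }
  # replications per environment among test entries (1 in augmented layouts)
  ent <- tt[tt$is_check == "FALSE", , drop = FALSE]
  if (!nrow(ent)) ent <- tt
  n_rep <- mean(table(ent$entry_f, ent$environment_id)[
    table(ent$entry_f, ent$environment_id) > 0])
  out <- list(
    sigma2_G = getv("entry_f"),
    sigma2_GEI = if (n_env >= 2) getv("entry_f:environment_id") else NA_real_,
    sigma2_eps = stats::sigma(fit)^2,
    n_env = n_env,
    n_rep = n_rep,
    converged = length(fit@optinfo$conv$lme4$messages) == 0
  )
  class(out) <- "VarianceComponents"
  out
}

#' @exportS3Method base::print
print.VarianceComponents <- function(x, ...) {
  cat("Variance components (REML):\n")
  cat(sprintf("  sigma2_G   = %.6g\n", x$sigma2_G))
  cat(sprintf("  sigma2_GEI = %.6g\n", x$sigma2_GEI))
  cat(sprintf("  sigma2_eps = %.6g\n", x$sigma2_eps))
  cat(sprintf("  n_env = %d, n_rep = %.2f\n", x$n_env, x$n_rep))
  invisible(x)
}

# per-environment BLUEs stacked across environments (pooled scale for
# phenotypic correlations)
.pooledBlues <- function(trial) {
  envs <- unique(trial$environment_id)
  resp <- attr(trial, "response") %||% "yield"
  out <- lapply(envs, function(e) {
    sub <- trial[trial$environment_id == e, , drop = FALSE]
    attr(sub, "response") <- resp
    am <- fitAdjustedMeans(sub, "BLUE_single_env")
    data.frame(entry_id = am$entry_id, is_check = am$is_check,
               environment_id = e, value = am$value, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
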