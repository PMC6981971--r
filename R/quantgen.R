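# Falconer indirect-selection statistics. Selecting on a secondary trait x
# (a spectral index) instead of the target y (yield) pays off when the
# correlated response CR = sqrt(H2_x) * r_G * sigma_gy exceeds the direct
# response R_y = sqrt(H2_y) * sigma_gy, i.e. when RE = CR/R_y > 1.

#' Broad-sense heritability on an entry-mean basis
#'
#' H2 = sigma2_G / (sigma2_G + sigma2_GEI/n + sigma2_eps/(n*r)), with n the
#' number of environments and r the replications per environment.
#'
#' @param vc a `VarianceComponents` object (see
#'   [estimateVarianceComponents()]) or a list with the same fields.
#' @return heritability in \[0, 1\].
#' @examples
#' broadSenseHeritability(list(sigma2_G = 1, sigma2_GEI = 2, sigma2_eps = 2,
#'                             n_env = 2, n_rep = 1))  # 1/3
#' @export
broadSenseHeritability <- function(vc) {
  g <- vc$sigma2_G
  gei <- vc$sigma2_GEI
  if (is.na(gei)) gei <- 0
  e <- vc$sigma2_eps
  n <- vc$n_env
  r <- vc$n_rep
  stopifnot(g >= 0, gei >= 0, e >= 0, n >= 1, r >= 1)
  denom <- g + gei / n + e / (n * r)
  if (denom == 0) stop("all variance components are zero; heritability undefined")
  g / denom
}

#' Genetic covariance between two traits via the pairwise-sums identity
#'
#' Cov_g(x, y) = (sigma2_G(x + y) - sigma2_G(x) - sigma2_G(y)) / 2, with
#' each genotypic variance estimated by REML on the corresponding response
#' ([estimateVarianceComponents()]). The two trials must share their plot
#' structure (entry, environment, block, check status).
#'
#' @param trial_x,trial_y trial tables for the two traits measured on the
#'   same plots.
#' @return list with `cov_g`, `var_gx`, `var_gy`, and the three underlying
#'   `VarianceComponents` fits.
#' @export
geneticCovariance <- function(trial_x, trial_y) {
  keyx <- paste(trial_x$entry_id, trial_x$environment_id, trial_x$block_id, sep = "\r")
  keyy <- paste(trial_y$entry_id, trial_y$environment_id, trial_y$block_id, sep = "\r")
  idx <- match(keyx, keyy)
  if (anyNA(idx)) stop("trial_x and trial_y do not share plot structure (",
                       sum(is.na(idx)), " unmatched plot(s))")
  if (length(unique(trial_x$environment_id)) < 2)
    stop("genetic covariance needs >= 2 shared environments")
  sum_t <- trial_x
  sum_t$response <- trial_x$response + trial_y$response[idx]
  attr(sum_t, "response") <- "sum"
  vx <- estimateVarianceComponents(trial_x)
  vy_t <- trial_y[idx, , drop = FALSE]
  attr(vy_t, "response") <- attr(trial_y, "response") %||% "yield"
  vy <- estimateVarianceComponents(vy_t)
  vs <- estimateVarianceComponents(sum_t)
  list(cov_g = (vs$sigma2_G - vx$sigma2_G - vy$sigma2_G) / 2,
       var_gx = vx$sigma2_G, var_gy = vy$sigma2_G,
       vc_x = vx, vc_y = vy, vc_sum = vs)
}

#' Genetic correlation from genetic (co)variances
#'
#' r_G = Cov_g / sqrt(var_gx * var_gy). When sampling error pushes |r_G|
#' beyond 1 the value is clipped to +/-1 and flagged via the `"clipped"`
#' attribute.
#'
#' @param cov_g genetic covariance.
#' @param var_gx,var_gy genotypic variances (must be positive).
#' @return r_G in \[-1, 1\].
#' @export
geneticCorrelation <- function(cov_g, var_gx, var_gy) {
  if (var_gx <= 0 || var_gy <= 0)
    stop("undefined genetic correlation: nonpositive genotypic variance")
  r <- cov_g / sqrt(var_gx * var_gy)
  clipped <- abs(r) > 1
  if (clipped) {
    warning(sprintf("genetic correlation %.3f outside [-1, 1]; clipped", r))
    r <- sign(r)
  }
  attr(r, "clipped") <- clipped
  r
}

#' Response to selection R = sqrt(H2_x) * sigma_gx
#' @param H2_x broad-sense heritability of the selected trait.
#' @param sigma_gx genotypic standard deviation of the selected trait.
#' @return response to selection (same units as the trait).
#' @export
responseToSelection <- function(H2_x, sigma_gx) {
  stopifnot(H2_x >= 0, H2_x <= 1, sigma_gx >= 0)
  sqrt(H2_x) * sigma_gx
}

#' Correlated response CR = sqrt(H2_x) * r_G * sigma_gy
#'
#' Expected change in the target trait y when selection acts on the
#' secondary trait x; the sign follows the genetic correlation.
#' @param H2_x heritability of the secondary trait.
#' @param r_G genetic correlation between x and y.
#' @param sigma_gy genotypic standard deviation of the target trait.
#' @return correlated response in y units.
#' @export
correlatedResponse <- function(H2_x, r_G, sigma_gy) {
  stopifnot(H2_x >= 0, H2_x <= 1, abs(r_G) <= 1, sigma_gy >= 0)
  sqrt(H2_x) * r_G * sigma_gy
}

#' Relative efficiency of indirect selection RE = CR_x / R_y
#'
#' RE > 1 flags a secondary trait whose indirect response in yield beats
#' selecting on yield itself.
#' @param CR_x correlated response of yield to selection on the secondary
#'   trait.
#' @param R_y direct response to selection for yield.
#' @return relative selection efficiency.
#' @examples
#' relativeEfficiency(-0.022, 0.033)  # about -0.67
#' @export
relativeEfficiency <- function(CR_x, R_y) {
  if (R_y == 0) stop("undefined relative efficiency: R_y is zero")
  CR_x / R_y
}

#' Indirect-selection summary table across traits and stages
#'
#' For each secondary-trait trial (one per index x growth stage) against
#' the shared yield trial, computes heritabilities, the trait mean,
#' phenotypic correlation (Pearson, on per-environment BLUEs pooled across
#' environments), genetic correlation, response to selection, correlated
#' response and relative selection efficiency. Rows whose components fail
#' (e.g. zero genotypic variance) are flagged in `note` rather than
#' aborting the report.
#'
#' @param trials named list of trial tables for the secondary traits
#'   (names like `"NDVI_Gf1"`).
#' @param yield_trial yield trial table on the same plots.
#' @return data.frame with one row per secondary trait: trait, H2_x, H2_y,
#'   mean_x, r_P, r_G, sigma_gx, sigma_gy, R_x, R_y, CR_x, RE, note.
#' @export
indirectSelectionReport <- function(trials, yield_trial) {
  stopifnot(length(trials) >= 1, !is.null(names(trials)))
  vy <- estimateVarianceComponents(yield_trial)
  H2_y <- broadSenseHeritability(vy)
  sigma_gy <- sqrt(vy$sigma2_G)
  R_y <- responseToSelection(H2_y, sigma_gy)
  blue_y <- .pooledBlues(yield_trial)
  rows <- lapply(names(trials), function(nm) {
    tx <- trials[[nm]]
    shared <- intersect(tx$entry_id, yield_trial$entry_id)
    if (!length(shared))
      return(data.frame(trait = nm, H2_x = NA, H2_y = H2_y, mean_x = NA,
                        r_P = NA, r_G = NA, sigma_gx = NA, sigma_gy = sigma_gy,
                        R_x = NA, R_y = R_y, CR_x = NA, RE = NA,
                        note = "no shared entries"))
    out <- try({
      gc <- geneticCovariance(tx, yield_trial)
      H2_x <- broadSenseHeritability(gc$vc_x)
      r_G <- as.numeric(geneticCorrelation(gc$cov_g, gc$var_gx, gc$var_gy))
      blue_x <- .pooledBlues(tx)
      key <- paste(blue_x$entry_id, blue_x$environment_id)
      idx <- match(key, paste(blue_y$entry_id, blue_y$environment_id))
      r_P <- stats::cor(blue_x$value[!is.na(idx)],
                        blue_y$value[idx[!is.na(idx)]])
      sigma_gx <- sqrt(gc$var_gx)
      CR_x <- correlatedResponse(H2_x, r_G, sigma_gy)
      data.frame(trait = nm, H2_x = H2_x, H2_y = H2_y,
                 mean_x = mean(tx$response, na.rm = TRUE),
                 r_P = r_P, r_G = r_G,
                 sigma_gx = sigma_gx, sigma_gy = sigma_gy,
                 R_x = responseToSelection(H2_x, sigma_gx), R_y = R_y,
                 CR_x = CR_x, RE = relativeEfficiency(CR_x, R_y),
                 note = "", stringsAsFactors = FALSE)
    }, silent = TRUE)
    if (inherits(out, "try-error"))
      out <- data.frame(trait = nm, H2_x = NA, H2_y = H2_y, mean_x = NA,
                        r_P = NA, r_G = NA, sigma_gx = NA, sigma_gy = sigma_gy,
                        R_x = NA, R_y = R_y, CR_x = NA, RE = NA,
                        note = conditionMessage(attr(out, "condition")))
    out
  })
  do.call(rbind, rows)
}
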