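#' GenotypeMatrix: lines x biallelic markers as minor-allele dosage
#'
#' Container for a biallelic SNP genotype panel coded as counts of the minor
#' allele (0/1/2), with missing calls stored as `NA`. Marker metadata
#' (chromosome, 1-based position) may be unknown (`NA`) for unmapped markers,
#' as is common for GBS-derived SNPs. The per-marker minor-allele frequency
#' is kept alongside the dosages and is always recomputable from them.
#'
#' Freshly read or simulated matrices hold integer dosages in \{0, 1, 2\};
#' after imputation (see [imputeMissing()]) cells may hold fractional values
#' in \[0, 2\], which is what ridge-regression BLUP expects.
#'
#' @slot dosage numeric matrix, lines x markers, values in \[0, 2\] or `NA`
#'   (missing call). Row names are line ids, column names marker ids.
#' @slot chrom character vector, per-marker chromosome label (`NA` allowed).
#' @slot pos integer vector, per-marker 1-based coordinate (`NA` allowed).
#' @slot maf numeric vector, per-marker minor-allele frequency in \[0, 0.5\],
#'   computed over non-missing calls.
#'
#' @seealso [GenotypeMatrix()], [readGenotypeMatrix()], [filterMAF()]
#' @export
setClass("GenotypeMatrix",
  representation(
    dosage = "matrix",
    chrom = "character",
    pos = "integer",
    maf = "numeric"
  )
)

setValidity("GenotypeMatrix", function(object) {
  d <- object@dosage
  msg <- character()
  if (is.null(rownames(d)) || is.null(colnames(d)))
    msg <- c(msg, "dosage must carry line ids (rownames) and marker ids (colnames)")
  else {
    if (anyDuplicated(rownames(d))) msg <- c(msg, "line ids must be unique")
    if (anyDuplicated(colnames(d))) msg <- c(msg, "marker ids must be unique")
  }
  v <- d[!is.na(d)]
  if (length(v) && (min(v) < 0 || max(v) > 2))
    msg <- c(msg, "dosage values must lie in [0, 2] (NA = missing)")
  if (length(object@chrom) != ncol(d)) msg <- c(msg, "chrom length != marker count")
  if (length(object@pos) != ncol(d)) msg <- c(msg, "pos length != marker count")
  if (length(object@maf) != ncol(d)) msg <- c(msg, "maf length != marker count")
  f <- .mafFromDosage(d)
  ok <- is.na(f) == is.na(object@maf)
  if (!all(ok) || max(abs(f - object@maf), na.rm = TRUE) > 1e-12)
    msg <- c(msg, "stored maf does not match maf recomputed from dosages")
  if (length(msg)) msg else TRUE
})

#' GSModel: fitted ridge-regression BLUP state
#'
#' Holds everything needed to reproduce predictions from a fitted RRBLUP
#' model bit-exactly: fixed-effect coefficients, per-marker effects, the
#' ridge parameter lambda = sigma2_eps / sigma2_u, both variance components,
#' and the training-set marker centering constants.
#'
#' @slot beta numeric, fixed-effect coefficients (named; first is intercept).
#' @slot u numeric, per-marker effects (named by marker id).
#' @slot lambda numeric(1), ridge shrinkage sigma2_eps / sigma2_u.
#' @slot sigma2_u numeric(1), marker-effect variance component.
#' @slot sigma2_eps numeric(1), residual variance component.
#' @slot centers numeric, training-set column means of the dosage matrix
#'   (named by marker id), applied before prediction.
#' @slot covariates character, names of secondary-trait fixed-effect
#'   covariates (empty for the intercept-only model).
#' @slot covariate_means numeric, training means of the covariates (used by
#'   the `"train_mean"` prediction policy for lines lacking measurements).
#'
#' @seealso [fitRRBLUP()], [predictGEBV()]
#' @export
setClass("GSModel",
  representation(
    beta = "numeric",
    u = "numeric",
    lambda = "numeric",
    sigma2_u = "numeric",
    sigma2_eps = "numeric",
    centers = "numeric",
    covariates = "character",
    covariate_means = "numeric"
  )
)

setValidity("GSModel", function(object) {
  msg <- character()
  if (length(object@u) != length(object@centers))
    msg <- c(msg, "u and centers must have one entry per fitted marker")
  if (!identical(names(object@u), names(object@centers)))
    msg <- c(msg, "u and centers must be named by the same marker ids")
  if (length(object@lambda) != 1 || !is.finite(object@lambda) || object@lambda <= 0)
    msg <- c(msg, "lambda must be a single positive finite value")
  if (length(object@beta) < 1) msg <- c(msg, "beta must contain at least an intercept")
  if (length(msg)) msg else TRUE
})
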