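# minor-allele frequency of the counted allele, folded to [0, 0.5]
.mafFromDosage <- function(d) {
  f <- colMeans(d, na.rm = TRUE) / 2
  f[is.nan(f)] <- NA_real_
  pmin(f, 1 - f)
}

#' Construct a GenotypeMatrix
#'
#' @param dosage lines x markers matrix of minor-allele dosages in \[0, 2\]
#'   (`NA` = missing call); must carry rownames (line ids) and colnames
#'   (marker ids), or supply `line_ids` / `marker_ids`.
#' @param chrom optional per-marker chromosome labels (default unknown).
#' @param pos optional per-marker 1-based positions (default unknown).
#' @param line_ids,marker_ids optional identifiers overriding dimnames.
#'
#' @return A [GenotypeMatrix-class] object with `maf` computed from the
#'   non-missing dosages.
#' @examples
#' d <- matrix(c(0, 1, 2, 2, 1, 0), nrow = 3,
#'             dimnames = list(paste0("L", 1:3), c("m1", "m2")))
#' g <- GenotypeMatrix(d)
#' maf(g)
#' @export
GenotypeMatrix <- function(dosage, chrom = NULL, pos = NULL,
                           line_ids = NULL, marker_ids = NULL) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "double"
  if (!is.null(line_ids)) rownames(dosage) <- line_ids
  if (!is.null(marker_ids)) colnames(dosage) <- marker_ids
  if (is.null(rownames(dosage)))
    rownames(dosage) <- paste0("line", seq_len(nrow(dosage)))
  if (is.null(colnames(dosage)))
    colnames(dosage) <- paste0("mk", seq_len(ncol(dosage)))
  m <- ncol(dosage)
  if (is.null(chrom)) chrom <- rep(NA_character_, m)
  if (is.null(pos)) pos <- rep(NA_integer_, m)
  new("GenotypeMatrix",
      dosage = dosage,
      chrom = as.character(chrom),
      pos = as.integer(pos),
      maf = .mafFromDosage(dosage))
}

#' @describeIn GenotypeMatrix line identifiers, in matrix order.
#' @param x a `GenotypeMatrix`.
#' @export
setMethod("lineIds", "GenotypeMatrix", function(x) rownames(x@dosage))

#' @describeIn GenotypeMatrix marker identifiers, in matrix order.
#' @export
setMethod("markerIds", "GenotypeMatrix", function(x) colnames(x@dosage))

#' @describeIn GenotypeMatrix the dosage matrix (`NA` = missing call).
#' @export
setMethod("dosage", "GenotypeMatrix", function(x) x@dosage)

#' @describeIn GenotypeMatrix per-marker minor-allele frequency.
#' @export
setMethod("maf", "GenotypeMatrix", function(x) {
  stats::setNames(x@maf, colnames(x@dosage))
})

#' @describeIn GenotypeMatrix marker metadata as a data.frame
#'   (marker_id, chrom, pos, maf).
#' @export
setMethod("markerInfo", "GenotypeMatrix", function(x) {
  data.frame(marker_id = colnames(x@dosage), chrom = x@chrom, pos = x@pos,
             maf = x@maf, row.names = NULL, stringsAsFactors = FALSE)
})

#' @export
setMethod("dim", "GenotypeMatrix", function(x) dim(x@dosage))

#' Subset a GenotypeMatrix by lines (i) and/or markers (j)
#'
#' `maf` is recomputed on the subset, so the counted allele of the full panel
#' may be the major allele within a subset; readers orient at import time.
#' @param x a `GenotypeMatrix`; `i` selects lines, `j` markers.
#' @param i,j,...,drop as for matrix subsetting (`drop` ignored).
#' @export
setMethod("[", "GenotypeMatrix", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nrow(x@dosage))
  if (missing(j)) j <- seq_len(ncol(x@dosage))
  if (is.character(i)) i <- match(i, rownames(x@dosage))
  if (is.character(j)) j <- match(j, colnames(x@dosage))
  d <- x@dosage[i, j, drop = FALSE]
  new("GenotypeMatrix", dosage = d, chrom = x@chrom[j], pos = x@pos[j],
      maf = .mafFromDosage(d))
})

#' @export
setMethod("show", "GenotypeMatrix", function(object) {
  d <- object@dosage
  nmiss <- sum(is.na(d))
  cat("GenotypeMatrix:", nrow(d), "lines x", ncol(d), "markers\n")
  cat(sprintf("  missing calls: %d (%.2f%%)\n", nmiss, 100 * nmiss / length(d)))
  mf <- object@maf[!is.na(object@maf)]
  if (length(mf))
    cat(sprintf("  MAF range: [%.3f, %.3f]\n", min(mf), max(mf)))
  cat("  mapped markers:", sum(!is.na(object@chrom)), "of", ncol(d), "\n")
})

#' @export
setMethod("show", "GSModel", function(object) {
  cat("GSModel (ridge-regression BLUP)\n")
  cat("  markers:", length(object@u), "\n")
  cat(sprintf("  lambda = %.4g (sigma2_u = %.4g, sigma2_eps = %.4g)\n",
              object@lambda, object@sigma2_u, object@sigma2_eps))
  if (length(object@covariates))
    cat("  fixed-effect covariates:", paste(object@covariates, collapse = ", "), "\n")
  else cat("  fixed effects: intercept only\n")
})

#' @describeIn GSModel per-marker effect estimates.
#' @param object a `GSModel`.
#' @export
setMethod("markerEffects", "GSModel", function(object) object@u)

#' @describeIn GSModel fixed-effect coefficients (intercept first).
#' @export
setMethod("fixedEffects", "GSModel", function(object) object@beta)
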