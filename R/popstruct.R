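# Relatedness diagnostics between panels: Roger's genetic distance on
# allele frequencies and PCA of the marker matrix.

#' Roger's genetic distance between two panels
#'
#' Per shared locus j with counted-allele frequencies p (panel A) and q
#' (panel B), the locus distance is sqrt(0.5 * sum over alleles of
#' (p_a - q_a)^2), which for a biallelic locus reduces to |p - q|; the
#' panel distance is the mean over loci. Loci without any non-missing call
#' in either panel are skipped and listed in the `"skipped"` attribute. A
#' line-to-line distance is the same quantity with single-line panels.
#' Both panels must code the same allele per marker (same import pipeline).
#'
#' @param pop_a,pop_b [GenotypeMatrix-class] panels sharing marker ids.
#' @param per_locus also return the per-locus contributions.
#' @return distance in \[0, 1\] (numeric); per-locus values in the
#'   `"per_locus"` attribute when requested.
#' @export
rogersDistance <- function(pop_a, pop_b, per_locus = FALSE) {
  shared <- intersect(markerIds(pop_a), markerIds(pop_b))
  if (!length(shared)) stop("no shared markers between the panels")
  da <- dosage(pop_a)[, shared, drop = FALSE]
  db <- dosage(pop_b)[, shared, drop = FALSE]
  p <- colMeans(da, na.rm = TRUE) / 2
  q <- colMeans(db, na.rm = TRUE) / 2
  ok <- !is.na(p) & !is.na(q)
  if (!any(ok)) stop("every shared locus lacks calls in one of the panels")
  dj <- sqrt(0.5 * ((p[ok] - q[ok])^2 + ((1 - p[ok]) - (1 - q[ok]))^2))
  out <- mean(dj)
  if (any(!ok)) attr(out, "skipped") <- shared[!ok]
  if (per_locus) attr(out, "per_locus") <- dj
  out
}

#' Principal components of the marker matrix
#'
#' PCA of the marker-mean-centered dosage matrix (optionally unit-variance
#' scaled per marker). Missing calls must be imputed first.
#'
#' @param g [GenotypeMatrix-class] without missing calls.
#' @param n_components number of components (<= min(lines, markers)).
#' @param scale. unit-variance scaling per marker (default off).
#' @return list with `scores` (lines x components), `explained` (variance
#'   fractions, non-increasing, summing to <= 1) and `rotation`.
#' @export
markerPCA <- function(g, n_components = 2, scale. = FALSE) {
  d <- dosage(g)
  if (anyNA(d)) stop("missing calls present; run imputeMissing() first")
  stopifnot(n_components >= 1, n_components <= min(dim(d)))
  if (scale.) {
    sds <- apply(d, 2, stats::sd)
    d <- d[, sds > 0, drop = FALSE]
  }
  pc <- stats::prcomp(d, center = TRUE, scale. = scale.)
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x[, seq_len(n_components), drop = FALSE],
       explained = expl[seq_len(n_components)],
       rotation = pc$rotation[, seq_len(n_components), drop = FALSE])
}
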