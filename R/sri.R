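# Spectral reflectance indices from discrete CROPSCAN-style band
# reflectances. Band matching is by exact nm key (680, 700, 750, 800, 900,
# 970); no nearest-band interpolation, so a mislabelled band surfaces as an
# error rather than a silently shifted index.

.sriDefs <- list(
  NDRE1 = list(type = "nd", num = 800, den = 700),
  NDRE2 = list(type = "nd", num = 800, den = 750),
  NDVI  = list(type = "nd", num = 800, den = 680),
  NWI1  = list(type = "nd", num = 970, den = 900),
  SR    = list(type = "ratio", num = 900, den = 680)
)

#' Names of the supported spectral reflectance indices
#' @return character vector: NDRE1, NDRE2, NDVI, NWI1, SR.
#' @export
sriNames <- function() names(.sriDefs)

#' Bands (nm) required by an index
#' @param index index name, see [sriNames()].
#' @return integer vector of wavelengths in nm.
#' @export
sriBands <- function(index) {
  def <- .sriDefs[[match.arg(index, names(.sriDefs))]]
  c(def$num, def$den)
}

#' Compute one spectral reflectance index from band reflectances
#'
#' Normalized-difference indices are (Ra - Rb)/(Ra + Rb):
#' NDRE-1 uses (800, 700) nm, NDRE-2 (800, 750), NDVI (800, 680) and
#' NWI-1 (970, 900); SR is the simple ratio R900/R680. Reflectances are
#' fractions in \[0, 1\].
#'
#' @param bands named numeric vector of reflectances, names `R<nm>` (or bare
#'   nm values).
#' @param index one of [sriNames()].
#' @return the index value.
#' @examples
#' computeIndex(c(R800 = 0.5, R680 = 0.1), "NDVI")   # (0.5-0.1)/(0.5+0.1)
#' computeIndex(c(R900 = 0.9, R680 = 0.05), "SR")    # 18
#' @export
computeIndex <- function(bands, index = sriNames()) {
  index <- match.arg(index)
  def <- .sriDefs[[index]]
  nm <- names(bands)
  if (is.null(nm)) stop("band reflectances must be named by wavelength")
  names(bands) <- paste0("R", sub("^[Rr]", "", nm))
  get_band <- function(w) {
    key <- paste0("R", w)
    if (!key %in% names(bands) || is.na(bands[[key]]))
      stop(sprintf("index %s requires band %d nm, which is missing", index, w))
    bands[[key]]
  }
  a <- get_band(def$num)
  b <- get_band(def$den)
  if (def$type == "nd") {
    if (a + b == 0) stop(sprintf("undefined %s: zero denominator R%d + R%d",
                                 index, def$num, def$den))
    (a - b) / (a + b)
  } else {
    if (b == 0) stop(sprintf("undefined %s: zero denominator R%d", index, def$den))
    a / b
  }
}

#' Compute all five indices for every row of a reflectance table
#'
#' @param refl data.frame from [readReflectanceTable()] (or any table with
#'   plot-key columns plus `R<nm>` band columns).
#' @param indices which indices to compute (default all five).
#' @return the plot-key columns (entry_id, environment_id, block_id, stage)
#'   with one column per computed index.
#' @export
computeIndices <- function(refl, indices = sriNames()) {
  indices <- match.arg(indices, several.ok = TRUE)
  keys <- intersect(c("entry_id", "environment_id", "block_id", "stage"),
                    names(refl))
  bandcols <- grep("^R[0-9]+$", names(refl), value = TRUE)
  out <- refl[, keys, drop = FALSE]
  for (idx in indices) {
    out[[idx]] <- vapply(seq_len(nrow(refl)), function(i) {
      b <- unlist(refl[i, bandcols])
      computeIndex(b, idx)
    }, numeric(1))
  }
  out
}

#' Percent change between two stage means
#'
#' Returns 100 * (mean_to - mean_from) / |mean_from|; negative values are
#' decreases. The absolute value in the denominator keeps the sign
#' convention meaningful for negative-valued indices such as NWI-1, whose
#' mean rising from -0.08 to -0.06 is a +25% increase.
#'
#' @param mean_from,mean_to stage means (e.g. heading vs late grain fill).
#' @return percent change.
#' @examples
#' stageChange(0.83, 0.63)    # about -24.1
#' stageChange(-0.08, -0.06)  # +25
#' @export
stageChange <- function(mean_from, mean_to) {
  if (mean_from == 0) stop("undefined percent change: starting mean is zero")
  100 * (mean_to - mean_from) / abs(mean_from)
}

#' Per-stage arithmetic means of index values
#'
#' Means are taken over non-missing plots per stage across environments
#' (set `by_environment = TRUE` to average per-environment means instead).
#'
#' @param sri table from [computeIndices()].
#' @param index index column to summarise.
#' @param by_environment average per-environment means rather than pooling
#'   plots.
#' @return named numeric vector of stage means (Hd, Gf1, Gf2 as present).
#' @export
stageMeans <- function(sri, index, by_environment = FALSE) {
  stopifnot(index %in% names(sri))
  if (by_environment) {
    pm <- tapply(sri[[index]], list(sri$stage, sri$environment_id),
                 mean, na.rm = TRUE)
    out <- rowMeans(pm, na.rm = TRUE)
  } else {
    out <- tapply(sri[[index]], sri$stage, mean, na.rm = TRUE)
  }
  out[intersect(c("Hd", "Gf1", "Gf2"), names(out))]
}
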