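# Readers/writers for the formats the pipeline touches: VCF 4.x (GT only),
# HapMap-like TSV, plain dosage TSV, and the trial / reflectance CSV tables.
# Downstream modules consume only GenotypeMatrix and the data.frame tables
# returned here.

.orientToMinor <- function(dosage) {
  # flip per-marker coding so the counted allele is the minor one
  f <- colMeans(dosage, na.rm = TRUE) / 2
  flip <- which(!is.na(f) & f > 0.5)
  if (length(flip)) dosage[, flip] <- 2 - dosage[, flip]
  dosage
}

#' Read a genotype panel into a GenotypeMatrix
#'
#' Supports three dialects: `vcf` (VCF 4.x, GT field only), `hapmap_tsv`
#' (rs, alleles, chrom, pos, then one column of diploid base calls per
#' sample, `NN`/`N` = missing) and `dosage_tsv` (lines x markers table of
#' 0/1/2 counts, first column the line id). Only biallelic sites are kept;
#' multi-allelic sites are dropped when `drop_multiallelic = TRUE` and
#' rejected otherwise. Dosages are re-oriented per site so that the counted
#' allele is the minor allele (mean dosage / 2 <= 0.5 over non-missing
#' calls); missing calls are preserved as `NA`; marker order follows file
#' order.
#'
#' @param path file path.
#' @param format one of `"vcf"`, `"hapmap_tsv"`, `"dosage_tsv"`.
#' @param drop_multiallelic drop non-biallelic sites instead of erroring.
#' @param missing_warn_rate warn when the overall missing-call rate exceeds
#'   this fraction (no hard cap is imposed).
#' @param orient re-orient each site so the counted allele is the minor one
#'   within this file. Disable when several panels must keep a shared,
#'   pipeline-defined orientation (e.g. a dosage file written from a panel
#'   oriented by a larger reference set).
#' @return a [GenotypeMatrix-class].
#' @export
readGenotypeMatrix <- function(path,
                               format = c("vcf", "hapmap_tsv", "dosage_tsv"),
                               drop_multiallelic = TRUE,
                               missing_warn_rate = 0.5,
                               orient = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("genotype file not found: ", path)
  g <- switch(format,
    vcf = .readVcfGeno(path, drop_multiallelic),
    hapmap_tsv = .readHapmapGeno(path, drop_multiallelic),
    dosage_tsv = .readDosageGeno(path)
  )
  if (orient) {
    d <- .orientToMinor(dosage(g))
    g <- GenotypeMatrix(d, chrom = g@chrom, pos = g@pos)
  }
  miss <- mean(is.na(dosage(g)))
  if (miss > missing_warn_rate)
    warning(sprintf("missing-genotype rate %.1f%% exceeds %.1f%%",
                    100 * miss, 100 * missing_warn_rate))
  g
}

.readVcfGeno <- function(path, drop_multiallelic) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  alt <- fix[, "ALT"]
  ref <- fix[, "REF"]
  biall <- !is.na(alt) & !grepl(",", alt) & nchar(ref) == 1 & nchar(alt) == 1
  if (!all(biall)) {
    if (!drop_multiallelic)
      stop(sum(!biall), " non-biallelic site(s) present; ",
           "set drop_multiallelic = TRUE to drop them")
    v <- v[biall, ]
    fix <- fix[biall, , drop = FALSE]
  }
  if (nrow(fix) == 0) stop("no biallelic sites left in ", path)
  gt <- vcfR::extract.gt(v, element = "GT")
  # count ALT alleles per call; any missing allele ('.') -> NA
  cnt <- function(x) {
    out <- rep(NA_real_, length(x))
    ok <- !is.na(x) & !grepl("\\.", x)
    a <- strsplit(gsub("\\|", "/", x[ok]), "/")
    out[ok] <- vapply(a, function(al) sum(al != "0"), numeric(1))
    out
  }
  d <- t(apply(gt, 1, cnt))
  if (ncol(gt) == 1) d <- matrix(d, ncol = 1)
  colnames(d) <- colnames(gt)
  d <- t(d)  # lines x markers
  ids <- fix[, "ID"]
  noid <- is.na(ids) | ids == "."
  ids[noid] <- paste0(fix[noid, "CHROM"], ":", fix[noid, "POS"])
  colnames(d) <- ids
  GenotypeMatrix(d, chrom = fix[, "CHROM"],
                 pos = suppressWarnings(as.integer(fix[, "POS"])))
}

.readHapmapGeno <- function(path, drop_multiallelic) {
  h <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                         comment.char = "")
  need <- c("rs", "alleles", "chrom", "pos")
  if (!all(need %in% names(h)))
    stop("malformed HapMap header: need columns ", paste(need, collapse = ", "),
         " (line 1)")
  samp_cols <- setdiff(names(h), need)
  allele_list <- strsplit(h$alleles, "/", fixed = TRUE)
  biall <- lengths(allele_list) == 2
  if (!all(biall)) {
    if (!drop_multiallelic) stop(sum(!biall), " non-biallelic site(s) present")
    h <- h[biall, , drop = FALSE]
    allele_list <- allele_list[biall]
  }
  d <- matrix(NA_real_, nrow = length(samp_cols), ncol = nrow(h),
              dimnames = list(samp_cols, h$rs))
  for (j in seq_len(nrow(h))) {
    a1 <- allele_list[[j]][1]
    calls <- toupper(as.character(h[j, samp_cols]))
    calls[calls %in% c("NN", "N", "--", "")] <- NA
    one <- substr(calls, 1, 1)
    two <- substr(calls, 2, 2)
    two[two == ""] <- one[two == ""]  # haploid-style single-letter call
    d[, j] <- (one == a1) + (two == a1)
  }
  GenotypeMatrix(d, chrom = as.character(h$chrom), pos = as.integer(h$pos))
}

.readDosageGeno <- function(path) {
  x <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(x) < 2) stop("malformed dosage table: need line-id column plus markers (line 1)")
  ids <- as.character(x[[1]])
  d <- as.matrix(x[, -1, drop = FALSE])
  storage.mode(d) <- "double"
  bad <- d[!is.na(d)]
  if (length(bad) && !all(bad %in% c(0, 1, 2)))
    stop("dosage values must be 0, 1, 2 or missing")
  rownames(d) <- ids
  GenotypeMatrix(d)
}

#' Write a GenotypeMatrix as a plain dosage TSV
#'
#' Inverse of `readGenotypeMatrix(format = "dosage_tsv")`; a write-then-read
#' round trip reproduces the dosages exactly.
#' @param g a [GenotypeMatrix-class] with integer-valued dosages.
#' @param path output path.
#' @export
writeGenotypeMatrix <- function(g, path) {
  d <- dosage(g)
  out <- data.frame(line_id = rownames(d), d, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a plot-level trial table
#'
#' Expects a CSV with columns `entry_id`, `environment_id`, `block_id`,
#' `is_check`, `check_id`, and one response column (default `yield`, units
#' t/ha unless the column is named otherwise). Blank responses are kept as
#' missing, not dropped. `check_id` must be present exactly on rows flagged
#' `is_check`.
#'
#' @param path CSV file path.
#' @param response name of the response column (default `"yield"`).
#' @return a data.frame ("trial table") with columns entry_id,
#'   environment_id, block_id, is_check, check_id, response; the response
#'   name is kept in `attr(, "response")`.
#' @export
readTrialTable <- function(path, response = "yield") {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("entry_id", "environment_id", "block_id", "is_check", "check_id", response)
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("trial table missing column(s): ", paste(miss, collapse = ", "))
  tt <- data.frame(
    entry_id = as.character(x$entry_id),
    environment_id = as.character(x$environment_id),
    block_id = as.character(x$block_id),
    is_check = as.logical(x$is_check),
    check_id = as.character(x$check_id),
    response = as.numeric(x[[response]]),
    stringsAsFactors = FALSE
  )
  tt$check_id[tt$check_id == ""] <- NA_character_
  validateTrialTable(tt, response)
}

#' Validate a trial table against the augmented-design contract
#'
#' @param tt trial-table data.frame (see [readTrialTable()]).
#' @param response response name recorded on the table.
#' @return the validated table (invisibly the same object).
#' @export
validateTrialTable <- function(tt, response = attr(tt, "response") %||% "yield") {
  bad <- which(!tt$is_check & !is.na(tt$check_id))
  if (length(bad))
    stop("check_id set on non-check row(s): ", paste(head(bad, 5), collapse = ", "))
  bad <- which(tt$is_check & is.na(tt$check_id))
  if (length(bad))
    stop("is_check row(s) lacking check_id: ", paste(head(bad, 5), collapse = ", "))
  key <- paste(tt$entry_id, tt$environment_id, tt$block_id, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (entry, environment, block) record(s), e.g. ",
         gsub("\r", "/", key[duplicated(key)][1]))
  attr(tt, "response") <- response
  tt
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a trial table as CSV (round-trip inverse of [readTrialTable()])
#' @param tt trial-table data.frame.
#' @param path output path.
#' @export
writeTrialTable <- function(tt, path) {
  out <- tt
  names(out)[names(out) == "response"] <- attr(tt, "response") %||% "yield"
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

.stageAliases <- c(
  hd = "Hd", heading = "Hd",
  gf1 = "Gf1", grainfill1 = "Gf1", milk = "Gf1", earlygrainfill = "Gf1",
  gf2 = "Gf2", grainfill2 = "Gf2", softdough = "Gf2", lategrainfill = "Gf2"
)

.normalizeStage <- function(stage) {
  key <- gsub("[^a-z0-9]", "", tolower(stage))
  out <- .stageAliases[key]
  if (anyNA(out))
    stop("unknown growth-stage label(s): ",
         paste(unique(stage[is.na(out)]), collapse = ", "),
         "; accepted: Hd (heading), Gf1 (early grain fill), Gf2 (late grain fill)")
  unname(out)
}

#' Read a plot-level spectral reflectance table
#'
#' Expects columns `entry_id`, `environment_id`, `block_id`, `stage`, plus
#' one numeric column per wavelength band named by its nm value (optionally
#' prefixed `R`, e.g. `R800`). Stage labels are normalized to
#' `Hd`/`Gf1`/`Gf2`. Reflectance is stored as a fraction in \[0, 1\];
#' percent-scale files (0-100) are rescaled when `percent = TRUE`.
#'
#' @param path CSV file path.
#' @param percent input values are percentages; divide by 100.
#' @return a data.frame of spectral records, one row per plot x stage, with
#'   band columns named `R<nm>`; band wavelengths in `attr(, "bands")`.
#' @export
readReflectanceTable <- function(path, percent = FALSE) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("entry_id", "environment_id", "block_id", "stage")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("reflectance table missing column(s): ",
                         paste(miss, collapse = ", "))
  bandcols <- setdiff(names(x), need)
  nm <- suppressWarnings(as.integer(sub("^[Rr]", "", bandcols)))
  if (anyNA(nm)) stop("non-wavelength column(s): ",
                      paste(bandcols[is.na(nm)], collapse = ", "))
  rec <- data.frame(
    entry_id = as.character(x$entry_id),
    environment_id = as.character(x$environment_id),
    block_id = as.character(x$block_id),
    stage = .normalizeStage(x$stage),
    stringsAsFactors = FALSE
  )
  for (i in seq_along(bandcols)) {
    v <- as.numeric(x[[bandcols[i]]])
    if (percent) v <- v / 100
    rec[[paste0("R", nm[i])]] <- v
  }
  vals <- unlist(rec[paste0("R", nm)], use.names = FALSE)
  vals <- vals[!is.na(vals)]
  if (length(vals) && (min(vals) < 0 || max(vals) > 1))
    stop("reflectance outside [0, 1] after rescaling; ",
         "use percent = TRUE for percent-scale files")
  attr(rec, "bands") <- sort(nm)
  rec
}
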