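# Fixtures are built in code: tiny genotype panels, trial tables and text
# files in the external formats.

makeGeno <- function(d, ...) {
  if (is.null(rownames(d))) rownames(d) <- paste0("L", seq_len(nrow(d)))
  if (is.null(colnames(d))) colnames(d) <- paste0("m", seq_len(ncol(d)))
  GenotypeMatrix(d, ...)
}

randomGeno <- function(n, m, seed = 1, p = NULL) {
  set.seed(seed)
  if (is.null(p)) p <- runif(m, 0.1, 0.5)
  makeGeno(matrix(rbinom(n * m, 2, rep(p, each = n)), n, m))
}

# minimal augmented trial: checks in every block, entries un-replicated
makeTrial <- function(entry_values, env = "E1", blocks = 2,
                      check_values = NULL, response = "yield") {
  entries <- names(entry_values)
  blk <- rep(seq_len(blocks), length.out = length(entries))
  rows <- data.frame(entry_id = entries, environment_id = env,
                     block_id = paste0("B", blk), is_check = FALSE,
                     check_id = NA_character_, response = unname(entry_values),
                     stringsAsFactors = FALSE)
  if (!is.null(check_values)) {
    for (b in seq_len(blocks)) {
      rows <- rbind(rows, data.frame(
        entry_id = names(check_values), environment_id = env,
        block_id = paste0("B", b), is_check = TRUE,
        check_id = names(check_values), response = unname(check_values),
        stringsAsFactors = FALSE))
    }
  }
  validateTrialTable(rows, response)
}

# balanced genotype x environment x replicate trial (no checks); environment
# main effects are drawn with SD s_env so the env variance component sits
# away from its zero boundary
makeBalancedTrial <- function(n_geno, n_env, n_rep, s_g, s_ge, s_e, seed = 1,
                              mu = 10, s_env = 1) {
  set.seed(seed)
  g <- rnorm(n_geno, 0, s_g)
  env <- rnorm(n_env, 0, s_env)
  rows <- expand.grid(entry_id = paste0("G", seq_len(n_geno)),
                      environment_id = paste0("E", seq_len(n_env)),
                      block_id = paste0("B", seq_len(n_rep)),
                      stringsAsFactors = FALSE)
  ge <- rnorm(n_geno * n_env, 0, s_ge)
  names(ge) <- as.vector(outer(paste0("G", seq_len(n_geno)),
                               paste0("E", seq_len(n_env)), paste))
  rows$is_check <- FALSE
  rows$check_id <- NA_character_
  rows$response <- mu + g[match(rows$entry_id, paste0("G", seq_len(n_geno)))] +
    env[match(rows$environment_id, paste0("E", seq_len(n_env)))] +
    ge[paste(rows$entry_id, rows$environment_id)] +
    rnorm(nrow(rows), 0, s_e)
  validateTrialTable(rows, "yield")
}

writeTempVcf <- function(lines) {
  f <- tempfile(fileext = ".vcf")
  writeLines(lines, f)
  f
}

vcfHeader <- function(samples) {
  c("##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
}
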