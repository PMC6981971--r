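# Seeded synthetic-data generator emulating the structure the analysis
# assumes: a diversity training panel plus smaller test panels of inbred
# (DH-style) lines, ~11k independent biallelic markers with MAF above the
# QC threshold, an infinitesimal genetic architecture with chosen genetic
# correlations between yield and each spectral index, and multi-environment
# augmented block trials (replicated checks, un-replicated entries) with
# genotype-by-environment interaction. One global seed governs every draw
# through a fixed splitting scheme so each sub-stage is reproducible.

.scSeed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 1009 + 97 * stage) %% 2147483629) + 1L
}

.defaultTraits <- function() {
  # per-index Gf1-style architecture: heritability, genetic correlation with
  # yield, trait mean and genotypic SD on the trait's own scale
  list(
    yield = list(h2 = 0.19, r_G = 1.00, mean = 6.00, sigma_g = 0.50),
    NDRE1 = list(h2 = 0.63, r_G = 0.65, mean = 0.71, sigma_g = 0.050),
    NDRE2 = list(h2 = 0.53, r_G = 0.65, mean = 0.13, sigma_g = 0.040),
    NDVI  = list(h2 = 0.52, r_G = 0.66, mean = 0.80, sigma_g = 0.050),
    NWI1  = list(h2 = 0.16, r_G = -0.42, mean = -0.07, sigma_g = 0.015),
    SR    = list(h2 = 0.55, r_G = 0.57, mean = 15.8, sigma_g = 2.00)
  )
}

#' Define a simulation scenario
#'
#' Defaults mirror the emulated wheat study: a 456-line training panel,
#' 11,089 biallelic markers with MAF above 0.05, fully homozygous (DH-style)
#' lines, yield heritability 0.19 with moderate genotype-by-environment
#' interaction, four environments of augmented blocks with two replicated
#' checks per block, and five spectral indices whose heritabilities and
#' genetic correlations with yield span the low-to-moderate range observed
#' for such traits (including a negatively correlated water index).
#'
#' @param seed global seed; all draws derive from it.
#' @param n_train,n_test line counts (test panel optional, 0 disables).
#' @param m marker count.
#' @param maf_range founder allele-frequency range.
#' @param n_env,blocks_per_env,checks_per_block trial layout.
#' @param gei_frac sigma2_GEI as a fraction of sigma2_G.
#' @param block_frac block variance as a fraction of sigma2_G.
#' @param r_E within-plot residual correlation between each index and yield
#'   (indices and yield are measured on the same physical plot, so their
#'   residuals share micro-environment; this drives the phenotypic
#'   correlation beyond the genetic component).
#' @param relatedness fraction of the founder frequency pool shared between
#'   training and test panels (1 = same pool).
#' @param dh fully homozygous lines (no heterozygous calls).
#' @param traits named list of per-trait parameters (`h2`, `r_G`, `mean`,
#'   `sigma_g`); must include `yield`. See the package defaults.
#' @param post_qc guarantee realized MAF > 0.05 for every simulated marker.
#' @param band_noise_sd Gaussian noise SD added to synthesised reflectance
#'   bands.
#' @return a `SimScenario` (list) consumed by the `simulate*` functions.
#' @export
simScenario <- function(seed = 1, n_train = 456, n_test = 0, m = 11089,
                        maf_range = c(0.1, 0.5), n_env = 4,
                        blocks_per_env = 8, checks_per_block = 2,
                        gei_frac = 0.5, block_frac = 0.25, r_E = 0.6,
                        relatedness = 1,
                        dh = TRUE, traits = .defaultTraits(),
                        post_qc = TRUE, band_noise_sd = 0.01) {
  stopifnot(maf_range[1] > 0, maf_range[2] <= 0.5, maf_range[1] <= maf_range[2],
            "yield" %in% names(traits), abs(r_E) <= 1)
  for (tr in traits) {
    stopifnot(tr$h2 > 0, tr$h2 < 1, abs(tr$r_G) <= 1, tr$sigma_g > 0)
    feas <- 1 / tr$h2 - 1 - gei_frac / n_env
    if (feas <= 0)
      stop("infeasible heritability target given gei_frac and n_env")
  }
  sc <- list(seed = seed, n_train = n_train, n_test = n_test, m = m,
             maf_range = maf_range, n_env = n_env,
             blocks_per_env = blocks_per_env,
             checks_per_block = checks_per_block,
             gei_frac = gei_frac, block_frac = block_frac, r_E = r_E,
             relatedness = relatedness, dh = dh, traits = traits,
             post_qc = post_qc, band_noise_sd = band_noise_sd)
  class(sc) <- "SimScenario"
  sc
}

.drawPanel <- function(p, n, dh, prefix) {
  m <- length(p)
  d <- if (dh) 2 * matrix(stats::rbinom(n * m, 1, rep(p, each = n)), n, m)
       else matrix(stats::rbinom(n * m, 2, rep(p, each = n)), n, m)
  rownames(d) <- sprintf("%s%03d", prefix, seq_len(n))
  colnames(d) <- sprintf("mk%05d", seq_len(m))
  d
}

#' Simulate training and test genotype panels
#'
#' Founder allele frequencies are drawn from `maf_range`; the test panel's
#' frequencies are a `relatedness`-weighted mixture of the shared founder
#' pool and an independent pool, so lower relatedness yields a larger
#' Roger's distance to the training panel. With `post_qc = TRUE` markers
#' whose realized training-panel MAF falls at or below 0.05 are redrawn, so
#' the panel is already past the QC filter.
#'
#' @param scenario a [simScenario()].
#' @param seed_offset stage offset into the scenario's seed stream.
#' @return list with `train` and (when `n_test > 0`) `test`
#'   [GenotypeMatrix-class] panels sharing marker ids and orientation.
#' @export
simulateGenotypes <- function(scenario, seed_offset = 1) {
  sc <- scenario
  set.seed(.scSeed(sc$seed, seed_offset))
  p <- stats::runif(sc$m, sc$maf_range[1], sc$maf_range[2])
  d_train <- .drawPanel(p, sc$n_train, sc$dh, "DP")
  if (sc$post_qc) {
    for (it in 1:50) {
      f <- .mafFromDosage(d_train)
      bad <- which(f <= 0.05)
      if (!length(bad)) break
      p[bad] <- stats::runif(length(bad), max(0.2, sc$maf_range[1]),
                             sc$maf_range[2])
      d_train[, bad] <- .drawPanel(p[bad], sc$n_train, sc$dh, "DP")
    }
  }
  chrom <- sample(paste0(rep(1:7, each = 3), c("A", "B", "D")), sc$m,
                  replace = TRUE)
  pos <- sample.int(8e8, sc$m, replace = TRUE)
  # shared pipeline orientation: flip by the TRAINING panel's realized
  # frequency and apply the same flips to any test panel
  flip <- which(colMeans(d_train, na.rm = TRUE) / 2 > 0.5)
  if (length(flip)) d_train[, flip] <- 2 - d_train[, flip]
  out <- list(train = GenotypeMatrix(d_train, chrom = chrom, pos = pos))
  if (sc$n_test > 0) {
    p_ind <- stats::runif(sc$m, sc$maf_range[1], sc$maf_range[2])
    p_test <- sc$relatedness * p + (1 - sc$relatedness) * p_ind
    d_test <- .drawPanel(p_test, sc$n_test, sc$dh, "TL")
    if (length(flip)) d_test[, flip] <- 2 - d_test[, flip]
    out$test <- GenotypeMatrix(d_test, chrom = chrom, pos = pos)
  }
  out
}

#' Simulate correlated trait architectures on a genotype panel
#'
#' Yield marker effects are i.i.d. normal (infinitesimal model, equal
#' marker variance); each index's effects are `r_G * u_yield +
#' sqrt(1 - r_G^2) * u_indep`, giving the target genetic correlation in
#' expectation. Breeding values (centered dosage x effects) are
#' standardised to unit genotypic variance per trait; trial simulation
#' rescales to each trait's `sigma_g`.
#'
#' @param g [GenotypeMatrix-class] (training panel; test panels reuse the
#'   same effects).
#' @param scenario a [simScenario()].
#' @param seed_offset stage offset into the seed stream.
#' @return list with `bv` (lines x traits matrix of standardised breeding
#'   values) and `effects` (markers x traits, on the standardised scale).
#' @export
simulateTraits <- function(g, scenario, seed_offset = 2) {
  sc <- scenario
  set.seed(.scSeed(sc$seed, seed_offset))
  d <- dosage(g)
  Mc <- sweep(d, 2, colMeans(d))
  m <- ncol(Mc)
  u_y <- stats::rnorm(m, 0, sqrt(1 / m))
  traits <- names(sc$traits)
  eff <- matrix(0, m, length(traits), dimnames = list(colnames(d), traits))
  for (tr in traits) {
    r <- sc$traits[[tr]]$r_G
    eff[, tr] <- if (tr == "yield") u_y
                 else r * u_y + sqrt(1 - r^2) * stats::rnorm(m, 0, sqrt(1 / m))
  }
  bv <- Mc %*% eff
  scl <- apply(bv, 2, stats::sd)
  if (any(scl == 0)) stop("degenerate panel: a trait has zero genetic variance")
  bv <- sweep(bv, 2, scl, "/")
  eff <- sweep(eff, 2, scl, "/")
  list(bv = bv, effects = eff)
}

.traitNoise <- function(tp, sc) {
  s2g <- tp$sigma_g^2
  list(sd_gei = sqrt(sc$gei_frac * s2g),
       sd_blk = sqrt(sc$block_frac * s2g),
       sd_eps = sqrt(sc$n_env * 1 * s2g * (1 / tp$h2 - 1 - sc$gei_frac / sc$n_env)))
}

#' Simulate an augmented multi-environment trial for one trait
#'
#' Plot value = trait mean + genetic value + genotype-by-environment
#' deviation + block effect + residual. Checks are replicated once per
#' block; entries are un-replicated and re-randomised over blocks within
#' each environment. Residual and interaction variances are solved from the
#' trait's target heritability on the entry-mean basis.
#'
#' @param bv named vector of standardised breeding values (entries).
#' @param scenario a [simScenario()].
#' @param trait trait name in `scenario$traits`.
#' @param seed_offset stage offset into the seed stream.
#' @return a trial-table data.frame (see [readTrialTable()]) with the true
#'   genetic values of the entries in `attr(, "true_g")`.
#' @export
simulateTrial <- function(bv, scenario, trait = "yield", seed_offset = 3) {
  sc <- scenario
  tp <- sc$traits[[trait]]
  if (is.null(tp)) stop("unknown trait: ", trait)
  entries <- names(bv)
  # field layout (entry-to-block assignment per environment) depends only on
  # the scenario seed, so all traits measured on the panel share their plots
  layout <- lapply(seq_len(sc$n_env), function(e) {
    set.seed(.scSeed(sc$seed, 900 + e))
    sample(rep(seq_len(sc$blocks_per_env), length.out = length(entries)))
  })
  # standard-normal plot noise shared by every trait measured on the panel;
  # yield uses it directly, indices mix it with their own draw at r_E, so
  # residuals of traits on the same plot correlate as they do in the field
  z_shared <- lapply(seq_len(sc$n_env), function(e) {
    set.seed(.scSeed(sc$seed, 950 + e))
    list(ent = stats::rnorm(length(entries)),
         chk = matrix(stats::rnorm(sc$blocks_per_env * sc$checks_per_block),
                      sc$blocks_per_env, sc$checks_per_block))
  })
  set.seed(.scSeed(sc$seed, seed_offset))
  nz <- .traitNoise(tp, sc)
  # residual correlation with yield carries the trait's sign: an index that
  # tracks yield negatively (the water index) does so within plots as well
  re <- tp$r_E %||% (sign(tp$r_G) * sc$r_E)
  mix <- function(zs, n_own) {
    if (trait == "yield") return(zs)
    re * zs + sqrt(1 - re^2) * stats::rnorm(n_own)
  }
  g_ent <- tp$mean + tp$sigma_g * bv
  checks <- sprintf("CHK%d", seq_len(sc$checks_per_block))
  g_chk <- stats::setNames(tp$mean + stats::rnorm(length(checks), 0, tp$sigma_g),
                           checks)
  g_all <- c(g_ent, g_chk)
  rows <- vector("list", sc$n_env)
  for (e in seq_len(sc$n_env)) {
    env <- sprintf("ENV%d", e)
    ge <- stats::setNames(stats::rnorm(length(g_all), 0, nz$sd_gei), names(g_all))
    blk_eff <- stats::rnorm(sc$blocks_per_env, 0, nz$sd_blk)
    blk_of <- layout[[e]]
    z_ent <- mix(z_shared[[e]]$ent, length(entries))
    z_chk <- mix(z_shared[[e]]$chk, length(z_shared[[e]]$chk))
    ent_rows <- data.frame(
      entry_id = entries, environment_id = env,
      block_id = sprintf("B%d", blk_of),
      is_check = FALSE, check_id = NA_character_,
      response = g_ent + ge[entries] + blk_eff[blk_of] + nz$sd_eps * z_ent,
      stringsAsFactors = FALSE)
    chk_rows <- do.call(rbind, lapply(seq_len(sc$blocks_per_env), function(b) {
      data.frame(entry_id = checks, environment_id = env,
                 block_id = sprintf("B%d", b),
                 is_check = TRUE, check_id = checks,
                 response = g_chk + ge[checks] + blk_eff[b] +
                   nz$sd_eps * z_chk[b, ],
                 stringsAsFactors = FALSE)
    }))
    rows[[e]] <- rbind(ent_rows, chk_rows)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "response") <- trait
  attr(out, "true_g") <- g_ent
  validateTrialTable(out, trait)
}

#' Synthesise band reflectances consistent with simulated index values
#'
#' Inverts the normalized-difference formulas: given per-plot NDRE-1,
#' NDRE-2, NDVI and NWI-1 values, fixes R800 (and R900) near typical canopy
#' levels and solves each remaining band, then adds Gaussian band noise and
#' clamps to \[0, 1\]. SR is implied by the resulting R900/R680 rather than
#' targeted. This exercises the index module end to end; it makes no claim
#' to radiometric realism.
#'
#' @param index_table data.frame with plot-key columns and columns NDRE1,
#'   NDRE2, NDVI, NWI1 (values in (-1, 1)).
#' @param scenario a [simScenario()] (for `band_noise_sd` and seed).
#' @param seed_offset stage offset into the seed stream.
#' @return a reflectance data.frame matching [readReflectanceTable()] output.
#' @export
simulateReflectance <- function(index_table, scenario, seed_offset = 4) {
  sc <- scenario
  set.seed(.scSeed(sc$seed, seed_offset))
  n <- nrow(index_table)
  # clamp simulated index values away from +/-1 so inverted bands stay
  # strictly inside (0, 1); plot noise can otherwise push an index past 1
  cl <- function(v) pmax(pmin(v, 0.95), -0.95)
  inv_nd <- function(Ra, v) Ra * (1 - v) / (1 + v)  # solve (Ra-Rb)/(Ra+Rb)=v for Rb
  R800 <- rep(0.50, n)
  R900 <- rep(0.45, n)
  out <- index_table[, intersect(c("entry_id", "environment_id", "block_id",
                                   "stage"), names(index_table)), drop = FALSE]
  out$R680 <- inv_nd(R800, cl(index_table$NDVI))
  out$R700 <- inv_nd(R800, cl(index_table$NDRE1))
  out$R750 <- inv_nd(R800, cl(index_table$NDRE2))
  out$R800 <- R800
  out$R900 <- R900
  out$R970 <- R900 * (1 + cl(index_table$NWI1)) / (1 - cl(index_table$NWI1))
  for (b in c("R680", "R700", "R750", "R800", "R900", "R970"))
    out[[b]] <- pmin(1, pmax(0.005, out[[b]] + stats::rnorm(n, 0, sc$band_noise_sd)))
  attr(out, "bands") <- c(680L, 700L, 750L, 800L, 900L, 970L)
  out
}

#' Generate a complete named scenario bundle
#'
#' Presets (all seeded and reproducible; identical `(preset, seed)` calls
#' give byte-identical fixture directories when `dir` is set):
#' * `table1_like` — one panel, four environments, all five indices with
#'   heritabilities/genetic correlations in the observed low-to-moderate
#'   range; for heritability and genetic-correlation recovery.
#' * `cv_like` — one panel with yield plus NDVI/NWI-1/SR for
#'   cross-validated genomic prediction with secondary-trait fixed effects.
#' * `independent_like` — a diversity-panel-like training set plus two test
#'   panels at different relatedness levels (a closer DH-like and a more
#'   distant F5-like panel).
#'
#' @param preset one of `"table1_like"`, `"cv_like"`, `"independent_like"`.
#' @param seed global seed.
#' @param dir optional directory: writes the bundle in the external formats
#'   (dosage TSV, trial CSVs, reflectance CSV).
#' @param ... overrides forwarded to [simScenario()] (e.g. smaller `m` for
#'   quick runs).
#' @return list with `scenario`, `geno` (train/test panels), `traits`
#'   (breeding values and effects), `trials` (named trial tables),
#'   `reflectance`, and for test panels `y_test` line means.
#' @export
generateScenario <- function(preset = c("table1_like", "cv_like", "independent_like"),
                             seed = 1, dir = NULL, ...) {
  preset <- match.arg(preset)
  base <- switch(preset,
    table1_like = list(n_train = 500, n_test = 0, m = 1000, n_env = 4),
    cv_like = list(
      n_train = 456, n_test = 0, m = 2000, n_env = 4,
      traits = .defaultTraits()[c("yield", "NDVI", "NWI1", "SR")]),
    independent_like = list(
      n_train = 456, n_test = 449, m = 2000, n_env = 4, relatedness = 0.9,
      traits = .defaultTraits()[c("yield", "NDVI", "NWI1", "SR")])
  )
  args <- utils::modifyList(c(list(seed = seed), base), list(...))
  sc <- do.call(simScenario, args)
  geno <- simulateGenotypes(sc)
  if (preset == "independent_like") {
    # second, more distant test panel (F5-like) from the same founder pool;
    # identical seed stream up to the test draw, so the training panel and
    # marker set are shared between the two calls
    sc_f5 <- sc
    sc_f5$relatedness <- max(0, sc$relatedness - 0.3)
    sc_f5$n_test <- 501
    geno_f5 <- simulateGenotypes(sc_f5)
    geno <- list(train = geno$train, test = geno$test, test_f5 = geno_f5$test)
  }
  tr <- simulateTraits(geno$train, sc)
  trait_names <- names(sc$traits)
  trials <- stats::setNames(lapply(seq_along(trait_names), function(i) {
    simulateTrial(tr$bv[, trait_names[i]], sc, trait_names[i],
                  seed_offset = 10 + i)
  }), trait_names)
  refl <- NULL
  nd_traits <- intersect(c("NDRE1", "NDRE2", "NDVI", "NWI1"), trait_names)
  if (length(nd_traits) >= 1) {
    first <- trials[[nd_traits[1]]]
    it <- first[, c("entry_id", "environment_id", "block_id")]
    it$stage <- "Gf1"
    for (nm in c("NDRE1", "NDRE2", "NDVI", "NWI1"))
      it[[nm]] <- if (nm %in% trait_names) trials[[nm]]$response
                  else sc$traits[[nd_traits[1]]]$mean + numeric(nrow(it))
    refl <- simulateReflectance(it, sc, seed_offset = 30)
  }
  out <- list(scenario = sc, geno = geno, traits = tr, trials = trials,
              reflectance = refl)
  # observed line means (phenotype at the stated line-mean heritability) and
  # secondary-trait covariate tables for each test panel; the DH-like panel
  # is both closer to the training panel and more heritable than the
  # F5-like panel, as is typical for such material
  panel_h2 <- c(test = 0.55, test_f5 = 0.14)
  for (pn in intersect(names(panel_h2), names(geno))) {
    pd <- .testPanelData(geno[[pn]], geno$train, tr$effects, sc,
                         h2_yield = panel_h2[[pn]],
                         seed_offset = 40 + match(pn, names(panel_h2)))
    out$y_test[[pn]] <- pd$y
    out$fixed_test[[pn]] <- pd$covariates
    out$g_test_true[[pn]] <- pd$g_true
  }
  if (!is.null(dir)) .writeBundle(out, dir)
  out
}

.testPanelData <- function(g_test, g_train, effects, sc, h2_yield, seed_offset) {
  set.seed(.scSeed(sc$seed, seed_offset))
  Mc <- sweep(dosage(g_test), 2, colMeans(dosage(g_train)))
  bv <- Mc %*% effects  # standardized training scale
  tp <- sc$traits$yield
  g_true <- tp$mean + tp$sigma_g * bv[, "yield"]
  y <- g_true + stats::rnorm(nrow(bv), 0, tp$sigma_g * sqrt(1 / h2_yield - 1))
  covs <- setdiff(colnames(bv), "yield")
  cv <- NULL
  if (length(covs)) {
    cv <- vapply(covs, function(tr) {
      tx <- sc$traits[[tr]]
      tx$mean + tx$sigma_g * bv[, tr] +
        stats::rnorm(nrow(bv), 0, tx$sigma_g * sqrt(1 / tx$h2 - 1))
    }, numeric(nrow(bv)))
    rownames(cv) <- rownames(Mc)
  }
  list(y = stats::setNames(y, rownames(Mc)), covariates = cv, g_true = g_true)
}

.writeBundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeGenotypeMatrix(bundle$geno$train, file.path(dir, "geno_train.tsv"))
  if (!is.null(bundle$geno$test))
    writeGenotypeMatrix(bundle$geno$test, file.path(dir, "geno_test.tsv"))
  for (nm in names(bundle$trials))
    writeTrialTable(bundle$trials[[nm]], file.path(dir, paste0("trial_", nm, ".csv")))
  if (!is.null(bundle$reflectance))
    utils::write.csv(bundle$reflectance, file.path(dir, "reflectance.csv"),
                     row.names = FALSE)
  invisible(dir)
}
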