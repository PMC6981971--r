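test_that("MAF filter is strict at the threshold and keeps marker order", {
  # marker j carries j heterozygous lines out of 50: maf = j/100
  d <- matrix(0, 50, 10, dimnames = list(paste0("L", 1:50), paste0("m", 1:10)))
  for (j in 1:10) d[seq_len(j), j] <- 1
  g <- makeGeno(d)
  expect_equal(unname(maf(g)), (1:10) / 100)
  kept <- filterMAF(g, 0.05)
  expect_equal(markerIds(kept), paste0("m", 6:10))  # 0.05 itself removed
  expect_equal(unname(attr(kept, "filter_log")),
               c(10, 5, 5))
  mono <- makeGeno(cbind(d, mono = 0))
  expect_equal(ncol(filterMAF(mono, 0)), 10)  # monomorphic gone at any threshold
  expect_error(filterMAF(makeGeno(matrix(0, 4, 2)), 0.05), "every marker")
})

test_that("mean imputation fills missing cells with marker means", {
  d <- matrix(c(2, 2, 2, NA, 0, 1, 2, 1), 4, 2,
              dimnames = list(paste0("L", 1:4), c("m1", "m2")))
  g <- makeGeno(d)
  gi <- imputeMissing(g, "mean")
  expect_equal(dosage(gi)["L4", "m1"], 2)
  expect_false(anyNA(dosage(gi)))
  expect_equal(unname(attr(gi, "impute_log")["imputed"]), 1)
  # untouched when nothing is missing
  gfull <- makeGeno(matrix(c(0, 1, 2, 1), 2, 2))
  expect_identical(dosage(imputeMissing(gfull, "mean")), dosage(gfull))
  # fully missing marker is an error
  dbad <- d; dbad[, 2] <- NA
  expect_error(imputeMissing(makeGeno(dbad)), "100% missing")
})

test_that("LD-kNN imputation uses correlated markers to pick donor lines", {
  # m1 and m2 in perfect LD; line L3's missing m2 call must follow its m1 call
  d <- cbind(m1 = c(2, 2, 2, 0, 0, 0),
             m2 = c(2, 2, NA, 0, 0, 0),
             m3 = c(1, 0, 1, 0, 1, 0))  # noise marker
  rownames(d) <- paste0("L", 1:6)
  gi <- imputeMissing(makeGeno(d), "ld_knn", k = 2, l = 1)
  expect_equal(dosage(gi)["L3", "m2"], 2)
  # a lone missing cell where all other lines carry dosage 2
  d2 <- cbind(m1 = c(2, 2, 2, NA), m2 = c(1, 1, 0, 0))
  rownames(d2) <- paste0("L", 1:4)
  expect_equal(dosage(imputeMissing(makeGeno(d2), "ld_knn", k = 3, l = 1))["L4", "m1"], 2)
  expect_equal(dosage(imputeMissing(makeGeno(d2), "mean"))["L4", "m1"], 2)
})

test_that("RRBLUP at fixed lambda equals the closed-form ridge oracle", {
  g2 <- makeGeno(matrix(c(2, 0), 2, 1, dimnames = list(c("a", "b"), "m1")))
  m2 <- fitRRBLUP(setNames(c(1, -1), c("a", "b")), g2, lambda = 1)
  expect_equal(unname(markerEffects(m2)), 2 / 3)  # (M'M + 1)^-1 M'y with M = (1,-1)'
  expect_equal(unname(predictGEBV(m2, g2)), c(2 / 3, -2 / 3))

  set.seed(10)
  for (rep in 1:5) {
    n <- sample(6:20, 1); m <- sample(10:100, 1); lam <- runif(1, 0.5, 20)
    g <- randomGeno(n, m, seed = rep + 100)
    y <- setNames(rnorm(n), lineIds(g))
    mod <- fitRRBLUP(y, g, lambda = lam)
    Mc <- scale(dosage(g), center = TRUE, scale = FALSE)
    X <- matrix(1, n, 1)
    H <- Mc %*% t(Mc) + lam * diag(n)
    beta <- solve(t(X) %*% solve(H, X), t(X) %*% solve(H, y))
    u <- solve(t(Mc) %*% Mc + lam * diag(m), t(Mc) %*% (y - X %*% beta))
    expect_equal(unname(fixedEffects(mod)), as.vector(beta), tolerance = 1e-8)
    expect_equal(unname(markerEffects(mod)), as.vector(u), tolerance = 1e-8)
  }
})

test_that("marker-model GEBVs equal GBLUP with the MM' kernel", {
  set.seed(11)
  g <- randomGeno(15, 80, seed = 12)
  y <- setNames(rnorm(15), lineIds(g))
  mod <- fitRRBLUP(y, g)  # REML lambda
  lam <- mod@lambda
  Mc <- scale(dosage(g), center = TRUE, scale = FALSE)
  K <- Mc %*% t(Mc)
  X <- matrix(1, 15, 1)
  H <- K + lam * diag(15)
  beta <- solve(t(X) %*% solve(H, X), t(X) %*% solve(H, y))
  gblup <- K %*% solve(H, y - X %*% beta)  # genetic values under the kernel model
  marker_part <- Mc %*% markerEffects(mod)
  expect_equal(as.vector(marker_part), as.vector(gblup), tolerance = 1e-8)
})

test_that("dosage coding {0,1,2} vs {-1,0,1} gives identical GEBVs", {
  g <- randomGeno(12, 40, seed = 13)
  y <- setNames(rnorm(12), lineIds(g))
  m1 <- fitRRBLUP(y, g, lambda = 4)
  d2 <- dosage(g) - 1
  g2 <- GenotypeMatrix(d2 + 1)  # same values; shift handled by centering
  stopifnot(identical(dosage(g2), dosage(g)))
  # recenter manually on the shifted coding and compare predictions
  Mc1 <- scale(dosage(g), center = TRUE, scale = FALSE)
  Mc2 <- scale(d2, center = TRUE, scale = FALSE)
  expect_equal(Mc1, Mc2, ignore_attr = TRUE, tolerance = 1e-10)
  expect_equal(unname(predictGEBV(m1, g)),
               unname(predictGEBV(m1, g2)), tolerance = 1e-10)
})

test_that("huge shrinkage collapses marker effects and GEBVs to the mean", {
  g <- randomGeno(10, 30, seed = 14)
  y <- setNames(rnorm(10, 5), lineIds(g))
  mod <- fitRRBLUP(y, g, lambda = 1e12)
  expect_lt(max(abs(markerEffects(mod))), 1e-6)
  expect_equal(unname(predictGEBV(mod, g)), rep(mean(y), 10), tolerance = 1e-4)
})

test_that("prediction respects training centering, ordering and errors", {
  g <- randomGeno(10, 25, seed = 15)
  y <- setNames(rnorm(10), lineIds(g))
  mod <- fitRRBLUP(y, g, lambda = 2)
  fitted_vals <- predictGEBV(mod, g)
  # a test line identical to a training line gets that line's fitted value
  expect_equal(unname(predictGEBV(mod, g[3, ])), unname(fitted_vals[3]))
  # permuting test lines permutes GEBVs identically
  perm <- c(4, 1, 3, 2, 5, 8, 6, 10, 9, 7)
  expect_equal(predictGEBV(mod, g[perm, ]), fitted_vals[perm])
  # marker mismatch errors with a count
  expect_error(predictGEBV(mod, g[, 1:10]), "15 fitted marker")
})

test_that("covariate models require test covariates unless told otherwise", {
  g <- randomGeno(12, 30, seed = 16)
  y <- setNames(rnorm(12), lineIds(g))
  fx <- data.frame(NDVI = rnorm(12), row.names = lineIds(g))
  mod <- fitRRBLUP(y, g, fixed = fx)
  expect_error(predictGEBV(mod, g), "train_mean")
  p1 <- predictGEBV(mod, g, fixed_test = fx)
  p2 <- predictGEBV(mod, g, covariate_policy = "train_mean")
  expect_equal(length(p1), 12)
  # train-mean policy shifts all lines equally: same centered pattern
  expect_equal(p2 - mean(p2),
               (predictGEBV(mod, g, fixed_test = fx * 0) -
                  mean(predictGEBV(mod, g, fixed_test = fx * 0))))
  expect_error(fitRRBLUP(y, g, fixed = cbind(fx, NDVI2 = fx$NDVI * 2)),
               "collinear")
})

test_that("cross-validation folds are near-equal, seeded and reproducible", {
  g <- randomGeno(60, 50, seed = 17)
  set.seed(99)
  y <- setNames(dosage(g) %*% rnorm(50, 0, 0.2) + rnorm(60), lineIds(g))
  y <- setNames(as.vector(y), lineIds(g))
  r1 <- kfoldCV(y, g, k = 5, seed = 7)
  r2 <- kfoldCV(y, g, k = 5, seed = 7)
  expect_identical(r1$assignment, r2$assignment)
  expect_equal(r1$accuracy, r2$accuracy)
  expect_true(all(abs(table(r1$assignment) - 12) <= 1))
  # the documented 456-line, 5-fold split: sizes 92, 91, 91, 91, 91
  set.seed(1)
  f <- sample(rep(1:5, length.out = 456))
  expect_equal(sort(as.vector(table(f)), decreasing = TRUE),
               c(92, 91, 91, 91, 91))
})

test_that("pearson accuracy matches hand computation and affine invariance", {
  expect_equal(predictionAccuracy(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(predictionAccuracy(c(1, 2, 3), c(-1, -2, -3)), -1)
  expect_equal(predictionAccuracy(c(1, 2, 3), c(1, 2, 4)),
               cor(c(1, 2, 3), c(1, 2, 4)))
  expect_equal(round(predictionAccuracy(c(1, 2, 3), c(1, 2, 4)), 3), 0.982)
  obs <- rnorm(10); geb <- rnorm(10)
  expect_equal(predictionAccuracy(obs, geb),
               predictionAccuracy(obs, 3 + 2 * geb))
  expect_error(predictionAccuracy(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(predictionAccuracy(c(1, 2), c(1, 2)), ">= 3")
})

test_that("independent validation works over the shared marker set", {
  b <- generateScenario("independent_like", seed = 8, m = 300, n_train = 150)
  am <- suppressMessages(fitAdjustedMeans(b$trials$yield, "BLUP_combined"))
  y <- setNames(am$value, am$entry_id)
  r <- independentValidation(y, b$geno$train, b$y_test$test, b$geno$test)
  expect_true(abs(r$accuracy) <= 1)
  expect_equal(r$scenario$m_shared, 300)
  # test = train reduces to the in-sample fit correlation
  mod <- fitRRBLUP(y, b$geno$train)
  rr <- independentValidation(y, b$geno$train, y, b$geno$train)
  expect_equal(rr$accuracy, cor(y, predictGEBV(mod, b$geno$train)[names(y)]),
               tolerance = 1e-8)
  g_none <- b$geno$test
  g_none@dosage <- g_none@dosage[, 1:5]
  colnames(g_none@dosage) <- paste0("zz", 1:5)
  g_none@chrom <- g_none@chrom[1:5]; g_none@pos <- g_none@pos[1:5]
  g_none@maf <- g_none@maf[1:5]
  expect_error(independentValidation(y, b$geno$train, b$y_test$test[1:5], g_none),
               "no markers shared")
})
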