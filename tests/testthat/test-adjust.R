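test_that("single-environment BLUEs match the least-squares oracle", {
  tt <- makeTrial(c(X = 10), blocks = 1, check_values = NULL)
  tt$block_id <- "B1"
  am <- fitAdjustedMeans(tt, "BLUE_single_env")
  expect_equal(am$value[am$entry_id == "X"], 10)  # single block: no adjustment

  # two blocks connected by one check; entries X (block 1) and Y (block 2)
  tt <- data.frame(entry_id = c("CHK", "CHK", "X", "Y"),
                   environment_id = "E1", block_id = c("B1", "B2", "B1", "B2"),
                   is_check = c(TRUE, TRUE, FALSE, FALSE),
                   check_id = c("CHK", "CHK", NA, NA),
                   response = c(5, 7, 10, 10))
  tt <- validateTrialTable(tt)
  am <- fitAdjustedMeans(tt, "BLUE_single_env")
  # OLS oracle on the same design, sum-to-zero blocks
  of <- lm(response ~ 0 + gen + C(factor(block_id), "contr.sum"),
           data = transform(tt, gen = ifelse(is_check, check_id, entry_id)))
  oracle <- coef(of)[paste0("gen", am$entry_id)]
  expect_equal(am$value, unname(oracle), tolerance = 1e-8)
  # block 2 ran +2 hot, so Y is adjusted 2 below X whatever the intercept
  expect_equal(am$value[am$entry_id == "X"] - am$value[am$entry_id == "Y"], 2)
})

test_that("entry contrasts are invariant to a constant added to one block", {
  set.seed(3)
  tt <- makeTrial(setNames(rnorm(8, 10), paste0("G", 1:8)), blocks = 2,
                  check_values = c(CHK1 = 9.5, CHK2 = 10.5))
  am1 <- fitAdjustedMeans(tt, "BLUE_single_env")
  tt2 <- tt
  tt2$response[tt2$block_id == "B2"] <- tt2$response[tt2$block_id == "B2"] + 5
  am2 <- fitAdjustedMeans(tt2, "BLUE_single_env")
  d1 <- am1$value - am1$value[1]
  d2 <- am2$value - am2$value[1]
  expect_equal(d1, d2, tolerance = 1e-8)
})

test_that("a block without checks is flagged inestimable", {
  tt <- makeTrial(c(X = 10, Y = 11), blocks = 2, check_values = c(CHK = 9))
  tt <- tt[!(tt$is_check & tt$block_id == "B2"), ]
  expect_error(fitAdjustedMeans(validateTrialTable(tt), "BLUE_single_env"),
               "without checks")
})

test_that("combined-analysis BLUPs shrink entry values toward the mean", {
  b <- generateScenario("table1_like", seed = 11, m = 100, n_train = 120,
                        n_env = 3)
  tt <- b$trials$yield
  am <- suppressMessages(fitAdjustedMeans(tt, "BLUP_combined"))
  raw <- tapply(tt$response[!tt$is_check], tt$entry_id[!tt$is_check], mean)
  expect_lte(var(am$value), var(raw[am$entry_id]))
  # BLUPs should still rank lines usefully: positive association with truth
  expect_gt(cor(am$value, attr(tt, "true_g")[am$entry_id]), 0.3)
})

test_that("without genetic signal BLUPs collapse toward the grand mean", {
  set.seed(5)
  tt <- makeBalancedTrial(40, 3, 1, s_g = 0, s_ge = 0, s_e = 1)
  am <- suppressMessages(fitAdjustedMeans(tt, "BLUP_combined"))
  raw <- tapply(tt$response, tt$entry_id, mean)
  expect_lt(var(am$value), 0.05 * var(raw[am$entry_id]))
})

test_that("REML matches the ANOVA expected-mean-squares oracle on balanced data", {
  tt <- makeBalancedTrial(30, 4, 2, s_g = 1, s_ge = 0.7, s_e = 1, seed = 2)
  vc <- estimateVarianceComponents(tt)
  a <- anova(lm(response ~ entry_id * environment_id, data = tt))
  ms <- a[["Mean Sq"]]
  r <- 2; e <- 4
  s2_eps <- ms[4]
  s2_ge <- (ms[3] - s2_eps) / r
  s2_g <- (ms[1] - ms[3]) / (r * e)
  expect_gt(s2_ge, 0)  # interior solution, where REML and EMS coincide
  expect_gt(s2_g, 0)
  expect_equal(vc$sigma2_eps, s2_eps, tolerance = 1e-6)
  expect_equal(vc$sigma2_GEI, s2_ge, tolerance = 1e-6)
  expect_equal(vc$sigma2_G, s2_g, tolerance = 1e-6)
})

test_that("variance-component estimates recover simulated truth within 15%", {
  # averaged over a few replicates so the check measures the estimator, not
  # the luck of a single Monte-Carlo draw
  est <- sapply(7:9, function(s) {
    tt <- makeBalancedTrial(500, 4, 2, s_g = 1, s_ge = sqrt(0.5),
                            s_e = sqrt(2), seed = s)
    vc <- estimateVarianceComponents(tt)
    c(vc$sigma2_G, vc$sigma2_GEI, vc$sigma2_eps)
  })
  expect_equal(mean(est[1, ]), 1, tolerance = 0.15)
  expect_equal(mean(est[2, ]), 0.5, tolerance = 0.15)
  expect_equal(mean(est[3, ]), 2, tolerance = 0.15)
  tt <- makeBalancedTrial(20, 4, 2, s_g = 1, s_ge = 0.5, s_e = 1, seed = 1)
  vc <- estimateVarianceComponents(tt)
  expect_equal(vc$n_env, 4)
  expect_equal(vc$n_rep, 2)
})

test_that("estimates are invariant to record order", {
  tt <- makeBalancedTrial(25, 3, 2, s_g = 1, s_ge = 0.5, s_e = 1, seed = 4)
  vc1 <- estimateVarianceComponents(tt)
  set.seed(1)
  tt2 <- tt[sample(nrow(tt)), ]
  vc2 <- estimateVarianceComponents(validateTrialTable(tt2, "yield"))
  expect_equal(vc1$sigma2_G, vc2$sigma2_G, tolerance = 1e-6)
  expect_equal(vc1$sigma2_eps, vc2$sigma2_eps, tolerance = 1e-6)
})

test_that("degenerate inputs are rejected with clear messages", {
  tt <- makeTrial(c(X = 5, Y = 5), check_values = c(CHK = 5))
  expect_error(estimateVarianceComponents(tt), "constant")
  tt2 <- makeTrial(c(X = 5, Y = 6), check_values = c(CHK = 5))
  expect_error(fitAdjustedMeans(tt2, "BLUP_combined"), ">= 2 environments")
})
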