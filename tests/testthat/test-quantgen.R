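test_that("heritability formula handles its boundary and interior cases", {
  expect_equal(broadSenseHeritability(list(sigma2_G = 1, sigma2_GEI = 0,
                                           sigma2_eps = 0, n_env = 1, n_rep = 1)), 1)
  expect_equal(broadSenseHeritability(list(sigma2_G = 1, sigma2_GEI = 2,
                                           sigma2_eps = 2, n_env = 2, n_rep = 1)),
               1 / 3)
  expect_equal(broadSenseHeritability(list(sigma2_G = 0, sigma2_GEI = 1,
                                           sigma2_eps = 1, n_env = 3, n_rep = 2)), 0)
  expect_error(broadSenseHeritability(list(sigma2_G = 0, sigma2_GEI = 0,
                                           sigma2_eps = 0, n_env = 1, n_rep = 1)),
               "undefined")
  # a single environment cannot separate GEI; it is treated as absent
  expect_equal(broadSenseHeritability(list(sigma2_G = 1, sigma2_GEI = NA,
                                           sigma2_eps = 1, n_env = 1, n_rep = 1)),
               0.5)
})

test_that("genetic correlation from covariances behaves and clips", {
  expect_equal(as.numeric(geneticCorrelation(0, 1, 1)), 0)
  expect_equal(as.numeric(geneticCorrelation(2, 4, 1)), 1)
  expect_equal(as.numeric(geneticCorrelation(1, 4, 1)), 0.5)
  expect_warning(r <- geneticCorrelation(3, 4, 1), "clipped")
  expect_equal(as.numeric(r), 1)
  expect_error(geneticCorrelation(1, 0, 1), "nonpositive")
})

test_that("response, correlated response and relative efficiency are exact", {
  expect_equal(responseToSelection(1, 1), 1)
  expect_equal(responseToSelection(0.25, 2), 1)
  expect_equal(responseToSelection(0, 5), 0)
  expect_equal(correlatedResponse(1, 1, 1), 1)
  expect_equal(correlatedResponse(0.25, 0.5, 2), 0.5)
  expect_equal(correlatedResponse(0.25, -0.5, 2), -0.5)
  expect_equal(relativeEfficiency(0, 0.033), 0)
  expect_error(relativeEfficiency(1, 0), "zero")
})

test_that("genetic covariance is symmetric and exact for identical traits", {
  b <- generateScenario("table1_like", seed = 21, m = 120, n_train = 150,
                        n_env = 3)
  tx <- b$trials$NDVI
  ty <- b$trials$yield
  gxy <- suppressMessages(geneticCovariance(tx, ty))
  gyx <- suppressMessages(geneticCovariance(ty, tx))
  expect_equal(gxy$cov_g, gyx$cov_g, tolerance = 1e-6)
  # x against itself: covariance equals the genotypic variance
  gxx <- suppressMessages(geneticCovariance(tx, tx))
  expect_equal(gxx$cov_g, gxx$var_gx, tolerance = 1e-6)
  expect_equal(as.numeric(geneticCorrelation(gxx$cov_g, gxx$var_gx, gxx$var_gy)),
               1, tolerance = 1e-6)
})

test_that("a simulated uncorrelated trait shows near-zero genetic covariance", {
  sc_traits <- list(
    yield = list(h2 = 0.4, r_G = 1, mean = 6, sigma_g = 0.5),
    FLAT = list(h2 = 0.4, r_G = 0, mean = 1, sigma_g = 0.3))
  b <- generateScenario("table1_like", seed = 31, m = 300, n_train = 400,
                        n_env = 3, traits = sc_traits)
  gc <- suppressMessages(geneticCovariance(b$trials$FLAT, b$trials$yield))
  r <- as.numeric(suppressWarnings(
    geneticCorrelation(gc$cov_g, gc$var_gx, gc$var_gy)))
  expect_lt(abs(r), 0.2)
})

test_that("indirect-selection report satisfies the Falconer identity exactly", {
  b <- generateScenario("table1_like", seed = 41, m = 150, n_train = 150,
                        n_env = 3)
  rep_tab <- suppressMessages(suppressWarnings(
    indirectSelectionReport(b$trials[c("NDVI", "NWI1")], b$trials$yield)))
  expect_equal(nrow(rep_tab), 2)
  ok <- !is.na(rep_tab$RE)
  expect_true(any(ok))
  # RE = r_G * sqrt(H2_x / H2_y) is an algebraic consequence of R and CR
  expect_equal(rep_tab$RE[ok],
               rep_tab$r_G[ok] * sqrt(rep_tab$H2_x[ok] / rep_tab$H2_y[ok]),
               tolerance = 1e-12)
  # the water-index row must carry the negative sign through CR and RE
  nwi <- rep_tab[rep_tab$trait == "NWI1", ]
  if (!is.na(nwi$r_G) && nwi$r_G < 0) {
    expect_lt(nwi$CR_x, 0)
    expect_lt(nwi$RE, 0)
  }
})

test_that("identity trait gives unit correlations and RE driven by heritability", {
  b <- generateScenario("table1_like", seed = 51, m = 100, n_train = 120,
                        n_env = 3)
  ty <- b$trials$yield
  tx <- ty
  attr(tx, "response") <- "copy"
  rep_tab <- suppressMessages(indirectSelectionReport(list(copy = tx), ty))
  # r_G assembled from three separate REML fits, equal up to optimizer noise
  expect_equal(rep_tab$r_G, 1, tolerance = 1e-5)
  expect_equal(rep_tab$r_P, 1, tolerance = 1e-10)
  expect_equal(rep_tab$RE, 1, tolerance = 1e-5)  # same trait: H2_x = H2_y
})

test_that("report errors cleanly when entry sets do not intersect", {
  b <- generateScenario("table1_like", seed = 61, m = 60, n_train = 40,
                        n_env = 2)
  ty <- b$trials$yield
  tx <- b$trials$NDVI
  tx$entry_id <- paste0("other_", tx$entry_id)
  tx$check_id[tx$is_check] <- paste0("other_", tx$check_id[tx$is_check])
  rep_tab <- suppressMessages(
    indirectSelectionReport(list(NDVI = validateTrialTable(tx, "NDVI")), ty))
  expect_true(is.na(rep_tab$RE))
  expect_match(rep_tab$note, "shared")
})
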