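# Climate amplitudes, logistic screening, FDR adjustment, additive models.

test_that("climate amplitudes are summer minus winter means", {
  mk <- function(vals, years) {
    do.call(rbind, lapply(seq_along(years), function(i) {
      data.frame(year = years[i], month = 1:12, value = vals[[i]])
    }))
  }
  const <- mk(list(rep(2, 12), rep(2, 12)), 1990:1991)
  expect_equal(unname(climate_amplitude(const, years = 1991)), 0)
  v <- rep(0, 12); v[c(6, 7, 8)] <- 1.5; v[c(12, 1, 2)] <- -0.5
  two <- mk(list(v, v), 1990:1991)
  expect_equal(unname(climate_amplitude(two, years = 1991)), 2.0)
  # generator round-trip at a configured amplitude
  ci <- gen_climate_indices(1989:1991, list(NPGO = setNames(c(0, 1.3, 0.4),
                                                            1989:1991)),
                            noise_sd = 0, seed = 1)
  expect_equal(unname(climate_amplitude(ci, years = 1990)["1990"]), 1.3)
})

test_that("lagged amplitude covariates shift by the per-index lag", {
  amps <- setNames(seq(0.1, 2, length.out = 20), 1981:2000)
  ci <- gen_climate_indices(1981:2000, list(PDO = amps, MEI = amps),
                            noise_sd = 0, seed = 2)
  tab <- climate_amplitude_table(ci, 1991:1995, lags = c(PDO = 5, MEI = 0))
  expect_equal(tab$PDO, unname(amps[as.character(1986:1990)]), tolerance = 1e-12)
  expect_equal(tab$MEI, unname(amps[as.character(1991:1995)]), tolerance = 1e-12)
})

test_that("degenerate selection series are flagged untestable", {
  x <- rnorm(29)
  r_all <- logistic_lrt(rep(1, 29), x)
  expect_identical(r_all$flag, "constant")
  expect_true(is.na(r_all$p))
  r_few <- logistic_lrt(c(0, 1, 0), rnorm(3))
  expect_identical(r_few$flag, "too_few")
  # complete separation
  xs <- sort(rnorm(30))
  ys <- rep(c(0, 1), each = 15)
  r_sep <- logistic_lrt(ys, xs)
  expect_identical(r_sep$flag, "separation")
  expect_true(is.na(r_sep$p))
})

test_that("the LRT statistic is invariant to affine rescaling of the amplitude", {
  set.seed(12)
  x <- rnorm(29)
  y <- rbinom(29, 1, plogis(0.3 + 0.8 * x))
  a <- logistic_lrt(y, x)
  b <- logistic_lrt(y, 100 * x - 7)
  expect_equal(a$statistic, b$statistic, tolerance = 1e-8)
})

test_that("a strong generating slope is detected with high power", {
  hits <- 0L
  for (r in 1:100) {
    set.seed(300 + r)
    x <- rnorm(200)
    y <- rbinom(200, 1, plogis(2 * x))
    res <- logistic_lrt(y, x)
    if (!is.na(res$p) && res$p < 0.05) hits <- hits + 1L
  }
  expect_gte(hits, 90)
})

test_that("the step-up adjustment matches the hand formula and the reference", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(0.04, 5)), rep(0.04, 5))
  # independent implementation on random vectors, NAs passed through
  for (seed in 1:20) {
    set.seed(seed)
    p <- runif(sample(3:40, 1))^sample(1:3, 1)
    if (seed %% 3 == 0) p[sample(length(p), 2)] <- NA
    got <- bh_adjust(p)
    ref <- p.adjust(p, method = "BH")
    expect_equal(got, unname(ref), tolerance = 1e-12)
  }
})

test_that("the step-up adjustment is monotone in the input ranks", {
  set.seed(77)
  p <- runif(25)
  a1 <- bh_adjust(p)
  expect_true(all(a1 >= p))
  expect_true(all(a1 >= 0 & a1 <= 1))
  # order of adjusted values respects the order of raw values
  expect_true(all(diff(a1[order(p)]) >= -1e-12))
})

test_that("deviance explained follows its defining identity", {
  y <- c(0, 1, 2)
  expect_equal(deviance_explained(y, c(0, 1, 1)), 0.5)
  expect_equal(deviance_explained(y, rep(mean(y), 3)), 0)
  expect_equal(deviance_explained(y, y), 1)
  expect_true(is.na(deviance_explained(rep(2, 5), rnorm(5))))
})

test_that("a noiseless linear signal yields edf near 1 and the least-squares fit", {
  set.seed(21)
  n <- 29
  a <- data.frame(PDO = rnorm(n), MEI = rnorm(n), NPGO = rnorm(n))
  y <- 1 + 2 * a$PDO + rnorm(n, sd = 1e-8)
  g <- fit_additive_model(y, a)
  expect_lt(abs(g$edf[["PDO"]] - 1), 0.2)
  ols <- fitted(lm(y ~ PDO + MEI + NPGO, data = a))
  expect_equal(unname(g$fitted), unname(ols), tolerance = 1e-4)
  expect_equal(g$deviance_explained, 1, tolerance = 1e-6)
})

test_that("a saturated additive fit reports deviance explained of one", {
  set.seed(22)
  y <- rnorm(20)
  expect_equal(deviance_explained(y, y), 1)
})

test_that("the additive model rejects too few complete cases", {
  a <- data.frame(PDO = rnorm(10), MEI = rnorm(10), NPGO = rnorm(10))
  expect_error(fit_additive_model(rnorm(10), a), "complete cases")
})

test_that("association screening respects the year window and the FDR family", {
  set.seed(30)
  years <- 1980:2013
  all_years <- c(1966:1979, years, 2014)
  amps <- setNames(rnorm(length(all_years)), all_years)
  amps2 <- setNames(rnorm(length(all_years)), all_years)
  ci <- gen_climate_indices(1966:2014,
                            list(PDO = amps, MEI = amps * 0.5, NPGO = amps2),
                            noise_sd = 0, seed = 3)
  m <- matrix(rbinom(3 * length(years), 1, 0.5), 3,
              dimnames = list(c("v1", "v2", "v3"), as.character(years)))
  m <- cbind(m, allyrs = c(1L, 0L, 1L))
  sm <- structure(m, species = "sablefish", response = "CPUE",
                  class = c("selection_matrix", "matrix"))
  res <- associate_selection(sm, ci, lag = 5, years_window = 1985:2013)
  expect_equal(nrow(res), 9)            # 3 variables x 3 indices
  expect_true(all(res$n <= 29))         # only 1985..2013 enter
  expect_true(all(res$p_adj >= res$p - 1e-12, na.rm = TRUE))
  # pooled family: the adjustment is computed over all nine tests at once
  expect_equal(res$p_adj, bh_adjust(res$p), tolerance = 1e-12)
  res_pi <- associate_selection(sm, ci, lag = 5, years_window = 1985:2013,
                                family_mode = "per_index")
  for (k in unique(res_pi$index)) {
    sel <- res_pi$index == k
    expect_equal(res_pi$p_adj[sel], bh_adjust(res_pi$p[sel]), tolerance = 1e-12)
  }
})
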