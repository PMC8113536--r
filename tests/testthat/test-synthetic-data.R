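# Generators: known ground truth, seeded determinism, round-trips.

test_that("noiseless SIVCM data equal the reconstructed signal exactly", {
  tr <- sivcm_truth(p = 5, nonzero = 1:2, noise_sd = 0, snr = NULL,
                    n = 200, seed = 11)
  d <- gen_sivcm_data(tr)
  expect_identical(d$y, d$signal)
  # reconstruct sum_j g_j(theta' Z) x_j from stored pieces
  G <- vapply(tr$g_funcs, function(g) g(d$u), numeric(length(d$u)))
  recon <- G[, 1] + rowSums(G[, -1, drop = FALSE] * d$X[, -1])
  expect_equal(d$y, recon, tolerance = 1e-12)
})

test_that("generators are bitwise-reproducible under a fixed seed", {
  tr <- sivcm_truth(n = 100, seed = 5)
  expect_identical(gen_sivcm_data(tr), gen_sivcm_data(tr))
  spec <- list(locations = data.frame(lon = -150, lat = 55), years = 1990:1992,
               variables = list(T = list(class = "physical", amplitude = 3)),
               noise_sd = 0.3)
  expect_identical(gen_monthly_env(spec, seed = 9), gen_monthly_env(spec, seed = 9))
  ci <- gen_climate_indices(1990:1995, list(PDO = 1), noise_sd = 0.2, seed = 3)
  expect_identical(ci, gen_climate_indices(1990:1995, list(PDO = 1),
                                           noise_sd = 0.2, seed = 3))
})

test_that("realized noise variance matches the configured noise_sd", {
  tr <- sivcm_truth(p = 4, nonzero = 1:2, noise_sd = 2, snr = NULL,
                    n = 10000, seed = 21)
  d <- gen_sivcm_data(tr)
  expect_equal(var(d$y - d$signal), 4, tolerance = 0.05 * 4)
})

test_that("truth construction rejects invalid specifications", {
  expect_error(sivcm_truth(theta_true = c(2, 0, 0)), "unit")
  expect_error(sivcm_truth(theta_true = c(-1, 0, 0)), "positive")
  expect_error(sivcm_truth(n = 0), "n >= 1")
  expect_error(gen_monthly_env(list(locations = data.frame(lon = numeric(0),
                                                           lat = numeric(0)),
                                    years = 1990,
                                    variables = list())))
})

test_that("configured seasonal structure round-trips through seasonal_amplitude", {
  loc <- data.frame(lon = -150, lat = 55)
  mm_phys <- rep(0, 12); mm_phys[c(6, 7, 8)] <- 10; mm_phys[c(12, 1, 2)] <- 2
  mm_const <- rep(4, 12)
  mm_chem <- rep(6, 12); mm_chem[c(8, 9, 10)] <- 5; mm_chem[c(3, 4, 5)] <- 7
  spec <- list(locations = loc, years = 1990:1993, noise_sd = 0,
               variables = list(
                 phys = list(class = "physical", month_means = mm_phys),
                 flat = list(class = "physical", month_means = mm_const),
                 chem = list(class = "chembio", month_means = mm_chem)))
  env <- gen_monthly_env(spec, seed = 1)
  amp_of <- function(vn, cls) {
    sub <- env[env$variable == vn, c("year", "month", "value")]
    seasonal_amplitude(sub, cls)
  }
  a_phys <- amp_of("phys", "physical")
  # December of the first winter lives in the year before the range
  expect_equal(a_phys$amplitude[a_phys$year %in% 1991:1993], rep(8, 3))
  a_flat <- amp_of("flat", "physical")
  expect_equal(a_flat$amplitude[a_flat$year %in% 1991:1993], rep(0, 3))
  a_chem <- amp_of("chem", "chembio")
  expect_equal(a_chem$amplitude, rep(-2, 4))
})

test_that("amplitude-driven generation round-trips for every configured year", {
  spec <- list(locations = data.frame(lon = c(-150, -140), lat = c(55, 57)),
               years = 1990:1999, noise_sd = 0,
               variables = list(
                 wtmp = list(class = "physical",
                             amplitude = setNames(seq(0.5, 5, length.out = 10),
                                                  1990:1999)),
                 chl = list(class = "chembio", amplitude = -1.5)))
  env <- gen_monthly_env(spec, seed = 2)
  truth <- attr(env, "truth")
  for (vn in names(truth)) {
    cls <- attr(env, "classes")[vn]
    sub <- env[env$variable == vn & env$lon == -150, c("year", "month", "value")]
    got <- seasonal_amplitude(sub, cls)
    yrs <- if (cls == "physical") 1991:1999 else 1990:1999
    expect_equal(setNames(got$amplitude[got$year %in% yrs], yrs),
                 truth[[vn]][as.character(yrs)], tolerance = 1e-12)
  }
})

test_that("climate-index generator hits its configured amplitudes", {
  ci <- gen_climate_indices(1988:1992,
                            list(PDO = setNames(c(0.5, 2, 1.3, -1, 0), 1988:1992)),
                            noise_sd = 0, seed = 1)
  amp <- climate_amplitude(ci[ci$index == "PDO", ], years = 1989:1992)
  expect_equal(unname(amp["1990"]), 1.3)
  expect_equal(unname(amp["1991"]), -1)
  ci0 <- gen_climate_indices(1990:1994, list(MEI = 0), noise_sd = 0, seed = 1)
  amp0 <- climate_amplitude(ci0[ci0$index == "MEI", ], years = 1991:1994)
  expect_equal(unname(amp0), rep(0, 4))
})

test_that("selection-series generator matches its Bernoulli model", {
  yrs <- seq_len(5000)
  amps <- setNames(rnorm(5000), yrs)
  s <- gen_selection_series(list(beta0 = 0, beta_k = 0, years = yrs),
                            amps, seed = 4)
  # symmetric null: long-run frequency near 0.5 within binomial error
  expect_lt(abs(mean(s$selected) - 0.5), 3 * 0.5 / sqrt(5000))
  s0 <- gen_selection_series(list(beta0 = -50, beta_k = 0, years = yrs),
                             amps, seed = 4)
  expect_true(all(s0$selected == 0))
  expect_error(gen_selection_series(list(beta0 = 0, beta_k = 1,
                                         years = 1:10),
                                    amps[1:5], seed = 1), "missing")
})

test_that("logistic fits recover the generating slope at nominal coverage", {
  # slope recovery: the 95% Wald CI covers beta_k in >= 90% of replicates
  yrs <- seq_len(500)
  hits <- 0L
  n_rep <- 100
  for (r in seq_len(n_rep)) {
    set.seed(1000 + r)
    amps <- setNames(rnorm(500), yrs)
    s <- gen_selection_series(list(beta0 = 0, beta_k = 1.5, years = yrs),
                              amps, seed = 2000 + r)
    fit <- glm(selected ~ amplitude, family = binomial(), data = s)
    ci <- suppressMessages(confint.default(fit))["amplitude", ]
    if (ci[1] <= 1.5 && 1.5 <= ci[2]) hits <- hits + 1L
  }
  expect_gte(hits, 90)
})
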