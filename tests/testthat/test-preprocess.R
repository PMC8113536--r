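# Collinearity pruning, interpolation, amplitudes, lag alignment.

test_that("VIF is 1 for orthogonal centered columns and Inf for duplicates", {
  x1 <- rep(c(1, -1), 8)
  x2 <- rep(c(1, 1, -1, -1), 4)
  expect_equal(as.numeric(compute_vif(cbind(x1, x2))), c(1, 1))
  set.seed(1)
  X <- cbind(a = rnorm(30), b = rnorm(30))
  X <- cbind(X, dup = X[, "a"])
  v <- compute_vif(X)
  expect_true(is.infinite(v["a"]) && is.infinite(v["dup"]))
})

test_that("a column built to have R^2 = 0.8 reports VIF 5", {
  set.seed(7)
  n <- 60
  z1 <- rnorm(n); z2 <- rnorm(n)
  e <- residuals(lm(rnorm(n) ~ z1 + z2))
  f <- z1 + 0.5 * z2
  fc <- f - mean(f)
  # scale the orthogonal residual so RSS/TSS is exactly 0.2
  cfac <- sqrt(0.25 * sum(fc^2) / sum(e^2))
  x3 <- f + cfac * e
  # verify R^2 = 0.8 by direct residual computation on this instance
  fit <- lm(x3 ~ z1 + z2)
  r2 <- 1 - sum(residuals(fit)^2) / sum((x3 - mean(x3))^2)
  expect_equal(r2, 0.8, tolerance = 1e-10)
  v <- compute_vif(cbind(z1 = z1, z2 = z2, x3 = x3))
  expect_equal(unname(v["x3"]), 5, tolerance = 1e-6)
})

test_that("constant columns are flagged rather than scored", {
  set.seed(2)
  X <- cbind(a = rnorm(20), b = rnorm(20), k = rep(3, 20))
  v <- compute_vif(X)
  expect_true(is.na(v["k"]))
  expect_true(attr(v, "constant")["k"])
})

test_that("backward elimination removes nothing when columns are independent", {
  set.seed(3)
  X <- matrix(rnorm(200 * 5), 200, 5, dimnames = list(NULL, letters[1:5]))
  rep <- vif_backward_eliminate(X)
  expect_identical(rep$retained, letters[1:5])
  expect_length(rep$removed, 0)
})

test_that("elimination drops exactly one of a duplicated pair (the later one)", {
  set.seed(4)
  X <- matrix(rnorm(100 * 3), 100, 3, dimnames = list(NULL, c("a", "b", "c")))
  X <- cbind(X, a2 = X[, "a"])
  rep <- vif_backward_eliminate(X)
  expect_identical(rep$removed, "a2")
  expect_identical(rep$retained, c("a", "b", "c"))
})

test_that("elimination matches the brute-force oracle on planted dependencies", {
  set.seed(5)
  n <- 150
  Z <- matrix(rnorm(n * 4), n, 4)
  # planted 3-variable near-dependency among 5 columns
  X <- cbind(v1 = Z[, 1], v2 = Z[, 2],
             v3 = Z[, 1] + Z[, 2] + 0.1 * rnorm(n),
             v4 = Z[, 3], v5 = Z[, 4])
  got <- vif_backward_eliminate(X)
  oracle <- oracle_vif_eliminate(X)
  expect_identical(got$removed, oracle$removed)
  expect_identical(got$retained, oracle$retained)
})

test_that("elimination equals the oracle across random instances (<= 8 columns)", {
  for (seed in 1:12) {
    set.seed(seed)
    n <- 80
    p <- sample(3:8, 1)
    X <- matrix(rnorm(n * p), n, p)
    # plant a near-collinear block about half the time
    if (seed %% 2 == 0 && p >= 3) {
      X[, p] <- X[, 1] - X[, 2] + rnorm(n, sd = runif(1, 0.05, 0.5))
    }
    colnames(X) <- paste0("v", seq_len(p))
    got <- vif_backward_eliminate(X)
    oracle <- oracle_vif_eliminate(X)
    expect_identical(got$removed, oracle$removed, label = paste("seed", seed))
    expect_identical(got$retained, oracle$retained)
  }
})

test_that("IDW honors the zero-distance rule and the weight formula", {
  st <- data.frame(lon = c(-150, -149), lat = c(55, 56), value = c(3.7, 9))
  expect_equal(idw_interpolate(st, -150, 55), 3.7)
  # two stations at equal distances straddling the target on a meridian
  st2 <- data.frame(lon = c(-150, -150), lat = c(55 - 0.3, 55 + 0.3),
                    value = c(2, 4))
  expect_equal(idw_interpolate(st2, -150, 55), 3, tolerance = 1e-9)
  # meridian arc distances scale exactly with the latitude offset:
  # distances in ratio 1:2 with values (0, 6), power 2 -> 6*0.25/1.25 = 1.2
  st3 <- data.frame(lon = c(-150, -150), lat = c(55.01, 55.02), value = c(0, 6))
  expect_equal(idw_interpolate(st3, -150, 55), 1.2, tolerance = 1e-6)
  # direct weight-formula oracle with haversine distances
  set.seed(8)
  st4 <- data.frame(lon = -150 + rnorm(5, sd = 0.5),
                    lat = 55 + rnorm(5, sd = 0.5), value = rnorm(5))
  d <- geosphere::distHaversine(cbind(st4$lon, st4$lat), c(-150, 55)) / 1000
  w <- d^-2
  expect_equal(idw_interpolate(st4, -150, 55), sum(w * st4$value) / sum(w))
  # interpolation is a convex combination: bounded by station values
  expect_gte(idw_interpolate(st4, -150, 55), min(st4$value))
  expect_lte(idw_interpolate(st4, -150, 55), max(st4$value))
  expect_true(is.na(idw_interpolate(st4[0, ], -150, 55)))
})

test_that("seasonal amplitudes follow the class-specific month windows", {
  mk <- function(vals_by_month, years) {
    do.call(rbind, lapply(years, function(yr) {
      data.frame(year = yr, month = 1:12, value = vals_by_month)
    }))
  }
  const <- mk(rep(5, 12), 1990:1992)
  expect_equal(seasonal_amplitude(const, "physical")$amplitude[-1], rep(0, 2))
  phys <- rep(2, 12); phys[c(6, 7, 8)] <- 10
  a <- seasonal_amplitude(mk(phys, 1990:1992), "physical")
  expect_equal(a$amplitude[a$year >= 1991], rep(8, 2))
  chem <- rep(0, 12); chem[c(8, 9, 10)] <- 5; chem[c(3, 4, 5)] <- 7
  expect_equal(seasonal_amplitude(mk(chem, 1990), "chembio")$amplitude, -2)
  # missing required month -> NA flag
  gap <- mk(phys, 1990:1991)
  gap <- gap[!(gap$year == 1991 & gap$month == 7), ]
  a2 <- seasonal_amplitude(gap, "physical")
  expect_true(is.na(a2$amplitude[a2$year == 1991]))
})

test_that("seasonal amplitude is linear and shift-invariant in the series", {
  set.seed(9)
  series <- data.frame(year = rep(1989:1991, each = 12),
                       month = rep(1:12, 3), value = rnorm(36))
  base <- seasonal_amplitude(series, "physical")$amplitude
  scaled <- series; scaled$value <- 2.5 * series$value + 7
  got <- seasonal_amplitude(scaled, "physical")$amplitude
  expect_equal(got, 2.5 * base, tolerance = 1e-12)
})

test_that("winter-window convention switches the December year", {
  s <- data.frame(year = rep(1989:1990, each = 12), month = rep(1:12, 2),
                  value = 0)
  s$value[s$year == 1989 & s$month == 12] <- 30   # Dec 1989
  s$value[s$year == 1990 & s$month == 12] <- 60   # Dec 1990
  prev <- seasonal_amplitude(s, "physical", years = 1990,
                             djf_year_convention = "previous")
  same <- seasonal_amplitude(s, "physical", years = 1990,
                             djf_year_convention = "same")
  expect_equal(prev$amplitude, -10)   # JJA 0 - mean(30, 0, 0)
  expect_equal(same$amplitude, -20)   # JJA 0 - mean(60, 0, 0)
})

test_that("lag alignment pairs responses with amplitudes lag years earlier", {
  amp <- expand.grid(variable = c("wtmp", "chl"), year = 1980:1995)
  amp$lon <- -150; amp$lat <- 55
  amp$amplitude <- as.numeric(amp$year) + ifelse(amp$variable == "chl", 100, 0)
  resp <- data.frame(species = "sablefish", response = "CPUE",
                     lon = -150, lat = 55, year = c(1990, 1995),
                     value = c(1.5, 2.5))
  d5 <- lag_align(amp, resp, 5)
  expect_equal(unname(d5$X[1, "wtmp"]), 1985)   # 1990 response, 1985 amplitude
  expect_equal(unname(d5$X[2, "chl"]), 100 + 1990)
  expect_equal(d5$X[, 1], c(1, 1))              # leading ones column
  d10 <- lag_align(amp, resp, 10)
  expect_equal(unname(d10$X[d10$Z[, "year"] == 1995, "wtmp"]), 1985)
  d0 <- lag_align(amp, resp, 0)
  expect_equal(unname(d0$X[, "wtmp"]), c(1990, 1995))
  # unmatched rows are dropped and counted
  resp2 <- rbind(resp, data.frame(species = "sablefish", response = "CPUE",
                                  lon = -150, lat = 55, year = 1970,
                                  value = 9))
  d <- lag_align(amp, resp2, 5)
  expect_equal(d$n_dropped, 1)
  expect_equal(length(d$y), 2)
  # empty intersection -> empty design with warning
  expect_warning(de <- lag_align(amp, transform(resp, year = 2050), 5),
                 "no response rows")
  expect_length(de$y, 0)
})

test_that("bulk amplitude construction agrees with the scalar operations", {
  spec <- list(locations = data.frame(lon = c(-152, -148, -150),
                                      lat = c(54, 56, 57)),
               years = 1989:1992, noise_sd = 0.1,
               variables = list(
                 wtmp = list(class = "physical", amplitude = 4, base = 8),
                 chl = list(class = "chembio", amplitude = -2, base = 1)))
  env <- gen_monthly_env(spec, seed = 10)
  pts <- data.frame(lon = c(-151, -149.5), lat = c(55, 55.5))
  tab <- build_amplitude_table(env, pts, c(wtmp = "physical", chl = "chembio"))
  # oracle: scalar IDW per slice then seasonal_amplitude
  for (vn in c("wtmp", "chl")) {
    sub <- env[env$variable == vn, ]
    for (pi in 1:2) {
      slices <- split(sub, paste(sub$year, sub$month))
      series <- do.call(rbind, lapply(slices, function(sl) data.frame(
        year = sl$year[1], month = sl$month[1],
        value = idw_interpolate(sl, pts$lon[pi], pts$lat[pi]))))
      amp <- seasonal_amplitude(series, ifelse(vn == "wtmp", "physical",
                                               "chembio"))
      amp <- amp[!is.na(amp$amplitude), ]
      got <- tab[tab$variable == vn & tab$lon == pts$lon[pi], ]
      got <- got[order(got$year), ]
      expect_equal(got$amplitude, amp$amplitude[match(got$year, amp$year)],
                   tolerance = 1e-10)
    }
  }
})
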