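# Association of selection patterns and responses with climate-index
# amplitudes: logistic likelihood-ratio screening with Benjamini-Hochberg
# FDR control, and a three-smooth Gaussian additive model per response.

#' Summer-minus-winter amplitude of a climate index
#'
#' Mean of June, July, August minus the mean of December, January,
#' February; under the default convention the December is that of the
#' preceding calendar year (the winter preceding the summer).
#'
#' @param monthly_index_series data frame `year, month, value` for one
#'   index.
#' @param years years to compute amplitudes for.
#' @param djf_convention `"previous"` (default) or `"same"`.
#' @return numeric vector of amplitudes named by year (`NA` where a month
#'   is missing).
#' @export
climate_amplitude <- function(monthly_index_series, years = NULL,
                              djf_convention = c("previous", "same")) {
  djf_convention <- match.arg(djf_convention)
  a <- seasonal_amplitude(monthly_index_series, "physical", years = years,
                          djf_year_convention = djf_convention)
  setNames(a$amplitude, a$year)
}

#' Lagged climate-amplitude covariates for a set of years
#'
#' Builds the per-year amplitude of each index, lagged per index: the value
#' attached to year t is the amplitude of year t - lag.
#'
#' @param climate_table long table `index, year, month, value`.
#' @param years target years (e.g. `1985:2013`).
#' @param lags named numeric vector of per-index lags in years (recycled
#'   scalar allowed).
#' @param djf_convention winter-window convention.
#' @return data frame with column `year` and one column per index.
#' @export
climate_amplitude_table <- function(climate_table, years,
                                    lags = 5, djf_convention = "previous") {
  idx <- sort(unique(climate_table$index))
  if (length(lags) == 1 && is.null(names(lags))) {
    lags <- setNames(rep(lags, length(idx)), idx)
  }
  out <- data.frame(year = as.integer(years))
  for (k in idx) {
    sub <- climate_table[climate_table$index == k, , drop = FALSE]
    lag_k <- unname(lags[k]); if (is.na(lag_k)) lag_k <- 0
    src <- as.integer(years) - lag_k
    amp <- climate_amplitude(sub, years = src,
                             djf_convention = djf_convention)
    out[[k]] <- as.numeric(amp[as.character(src)])
  }
  out
}

#' Likelihood-ratio screen of a binary selection series on an amplitude
#'
#' Fits a logistic regression (logit link, intercept plus one slope) of the
#' per-year selection indicator on the climate amplitude and compares it to
#' the intercept-only model: the statistic is the deviance difference on 1
#' degree of freedom with an upper-tail chi-square p-value. Constant series
#' and completely separated fits are flagged untestable (`p = NA`).
#'
#' @param selection_series binary 0/1 vector (one value per year).
#' @param amplitudes numeric vector of the same length.
#' @param min_pairs minimum usable complete pairs (default 5).
#' @return list with `statistic`, `df`, `p`, `n`, `flag`
#'   (`"ok"`, `"constant"`, `"separation"`, `"too_few"`).
#' @export
logistic_lrt <- function(selection_series, amplitudes, min_pairs = 5) {
  ok <- complete.cases(selection_series, amplitudes)
  yv <- as.numeric(selection_series[ok])
  xv <- as.numeric(amplitudes[ok])
  n <- length(yv)
  if (n < min_pairs) {
    return(list(statistic = NA_real_, df = 1L, p = NA_real_, n = n,
                flag = "too_few"))
  }
  if (length(unique(yv)) < 2) {
    return(list(statistic = NA_real_, df = 1L, p = NA_real_, n = n,
                flag = "constant"))
  }
  fit <- suppressWarnings(glm(yv ~ xv, family = binomial()))
  mu <- fitted(fit)
  separated <- !fit$converged ||
    (max(mu[yv == 1]) > 1 - 1e-8 && min(mu[yv == 0]) < 1e-8 &&
       min(mu[yv == 1]) > max(mu[yv == 0]))
  if (separated) {
    return(list(statistic = NA_real_, df = 1L, p = NA_real_, n = n,
                flag = "separation"))
  }
  stat <- fit$null.deviance - fit$deviance
  list(statistic = stat, df = 1L,
       p = pchisq(stat, df = 1, lower.tail = FALSE), n = n, flag = "ok")
}

#' Benjamini-Hochberg step-up adjustment
#'
#' `adj p_(i) = min over j >= i of min(1, m p_(j) / j)` in sort order,
#' mapped back to the original order; missing entries pass through and do
#' not count toward the family size m.
#'
#' @param p numeric vector of p-values in `[0, 1]` (NAs allowed).
#' @return adjusted p-values in the original order.
#' @export
bh_adjust <- function(p) {
  out <- rep(NA_real_, length(p))
  idx <- which(!is.na(p))
  m <- length(idx)
  if (m == 0) return(out)
  pv <- p[idx]
  stopifnot(all(pv >= 0 & pv <= 1))
  o <- order(pv)
  adj <- pmin(1, m * pv[o] / seq_len(m))
  adj <- rev(cummin(rev(adj)))
  out[idx[o]] <- adj
  out
}

#' Screen every (variable, index) pair of a selection matrix
#'
#' For each candidate variable's per-year selection series (years restricted
#' to `years_window`, the `"allyrs"` column excluded) and each climate
#' index, runs the logistic likelihood-ratio screen against the index's
#' lagged seasonal amplitude, then adjusts p-values by Benjamini-Hochberg
#' within the species-response family (by default pooling all indices; set
#' `family_mode = "per_index"` to adjust within each index separately).
#'
#' @param sel a `selection_matrix`.
#' @param climate_table long climate table `index, year, month, value`.
#' @param lag lag in years applied to every index amplitude (5, or 10 for
#'   Pacific halibut responses).
#' @param years_window years entering the screen (default 1985:2013).
#' @param djf_convention winter-window convention.
#' @param family_mode `"pooled"` (default) or `"per_index"`.
#' @return data frame of class `association_result`: one row per (variable,
#'   index) with `statistic`, `p`, `p_adj`, `flag`.
#' @export
associate_selection <- function(sel, climate_table, lag = 5,
                                years_window = 1985:2013,
                                djf_convention = "previous",
                                family_mode = c("pooled", "per_index")) {
  family_mode <- match.arg(family_mode)
  stopifnot(inherits(sel, "selection_matrix"))
  yr_cols <- setdiff(colnames(sel), "allyrs")
  yrs <- intersect(as.integer(yr_cols), years_window)
  amp <- climate_amplitude_table(climate_table, yrs, lags = lag,
                                 djf_convention = djf_convention)
  indices <- setdiff(names(amp), "year")
  rows <- list()
  for (v in rownames(sel)) {
    series <- unclass(sel)[v, as.character(yrs)]
    for (k in indices) {
      r <- logistic_lrt(series, amp[[k]])
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, index = k, statistic = r$statistic, df = r$df,
        p = r$p, n = r$n, flag = r$flag)
    }
  }
  out <- do.call(rbind, rows)
  if (family_mode == "pooled") {
    out$p_adj <- bh_adjust(out$p)
  } else {
    out$p_adj <- NA_real_
    for (k in indices) {
      sel_k <- out$index == k
      out$p_adj[sel_k] <- bh_adjust(out$p[sel_k])
    }
  }
  attr(out, "species") <- attr(sel, "species")
  attr(out, "response") <- attr(sel, "response")
  class(out) <- c("association_result", "data.frame")
  out
}

#' Gaussian additive model of a response on three climate amplitudes
#'
#' Fits `E(y) = f0 + f1(a1) + f2(a2) + f3(a3)` with penalized cubic
#' B-spline smooths (second-order difference penalty); smoothing parameters
#' are chosen by restricted maximum likelihood by default (generalized
#' cross-validation is available via `method`), and per-smooth p-values are
#' Wald-type statistics on each smooth's coefficients at its effective
#' degrees of freedom. When the data admit an (essentially) exact fit the
#' smoothing criterion is flat, so ties are broken toward the smoothest
#' model that achieves the same fit: if forcing heavy smoothing reproduces
#' the fitted values, the heavily smoothed (lower effective-df) fit is
#' returned.
#'
#' @param y numeric response (one value per year).
#' @param amplitudes data frame with exactly three numeric covariate
#'   columns (any `year` column is ignored).
#' @param k basis dimension per smooth (default 10).
#' @param min_years minimum complete cases (default 15).
#' @param method smoothing-parameter criterion passed to [mgcv::gam()]
#'   (default `"REML"`).
#' @param gamma effective-degrees-of-freedom charge passed to
#'   [mgcv::gam()]; the default `log(n)/2` applies a BIC-type penalty on
#'   model complexity, matching the BIC-type tuning used elsewhere in the
#'   package and keeping the per-smooth tests close to nominal size at the
#'   short (decades-long) series this model is fit to.
#' @return object of class `gam_summary`: list with `edf`, `p` (per
#'   smooth), `deviance_explained`, `fitted`, `n`, and the underlying
#'   `mgcv` fit.
#' @export
fit_additive_model <- function(y, amplitudes, k = 10, min_years = 15,
                               method = "REML", gamma = NULL) {
  amplitudes <- amplitudes[, setdiff(names(amplitudes), "year"), drop = FALSE]
  stopifnot(ncol(amplitudes) == 3)
  dat <- data.frame(y = as.numeric(y), amplitudes)
  names(dat) <- c("y", "a1", "a2", "a3")
  cc <- complete.cases(dat)
  if (sum(cc) < min_years) {
    stop(sprintf("additive model rejected: %d complete cases, need %d",
                 sum(cc), min_years))
  }
  dat <- dat[cc, , drop = FALSE]
  kk <- min(k, max(4, sum(cc) - 5))  # keep the basis below the sample size
  if (is.null(gamma)) gamma <- log(nrow(dat)) / 2
  form <- y ~ s(a1, bs = "ps", k = kk) + s(a2, bs = "ps", k = kk) +
    s(a3, bs = "ps", k = kk)
  heavy_fit <- function() mgcv::gam(form, data = dat, sp = rep(1e8, 3),
                                    family = gaussian())
  fit <- withCallingHandlers(
    tryCatch(
      mgcv::gam(form, data = dat, method = method, gamma = gamma,
                family = gaussian()),
      # an exactly representable response makes the smoothing criterion
      # degenerate; fall back to the maximally smoothed fit
      error = function(e) heavy_fit()
    ),
    warning = function(w) {
      # criterion-flat step failures are resolved by the tie-break below
      if (grepl("step failure", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  # parsimony tie-break for degenerate (near-interpolating) fits: when the
  # criterion is flat, prefer the smoothest model achieving the same fit
  rss <- sum((dat$y - fitted(fit))^2)
  tss <- sum((dat$y - mean(dat$y))^2)
  if (tss > 0 && rss / tss < 1e-10) {
    smooth_fit <- heavy_fit()
    rss_s <- sum((dat$y - fitted(smooth_fit))^2)
    if (rss_s / tss < 1e-10) fit <- smooth_fit
  }
  sm <- summary(fit)
  dev <- deviance_explained(dat$y, fitted(fit))
  structure(
    list(edf = setNames(sm$edf, names(amplitudes)),
         p = setNames(sm$s.table[, "p-value"], names(amplitudes)),
         deviance_explained = dev,
         fitted = fitted(fit), n = nrow(dat),
         rank_deficient = any(!is.finite(coef(fit))),
         fit = fit),
    class = "gam_summary"
  )
}

#' Fraction of variance explained (Gaussian deviance explained)
#'
#' `1 - sum((y - fitted)^2) / sum((y - mean(y))^2)`; for a Gaussian model
#' this equals one minus residual over null deviance.
#'
#' @param y observed response.
#' @param fitted fitted values of the same length.
#' @return scalar fraction, or `NA` when the total sum of squares is zero.
#' @export
deviance_explained <- function(y, fitted) {
  stopifnot(length(y) == length(fitted), length(y) >= 2)
  tss <- sum((y - mean(y))^2)
  if (tss == 0) return(NA_real_)
  1 - sum((y - fitted)^2) / tss
}
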