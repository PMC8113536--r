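# Preprocessing of station series and survey locations into the lagged
# seasonal-amplitude design matrix: variance-inflation-factor pruning,
# inverse-distance-weighted interpolation, seasonal amplitudes, lag
# alignment.

#' Variance inflation factors
#'
#' `VIF_i = 1/(1 - R_i^2)` where `R_i^2` is the coefficient of
#' determination of column i regressed (with intercept) on all other
#' columns. Exactly collinear columns report `Inf`; constant columns are
#' flagged `NA` (no meaningful regression).
#'
#' @param covariate_matrix numeric matrix or data frame with at least two
#'   columns and more rows than columns.
#' @return named numeric vector of VIFs with attribute `constant` marking
#'   flagged constant columns.
#' @export
compute_vif <- function(covariate_matrix) {
  X <- as.matrix(covariate_matrix)
  stopifnot(ncol(X) >= 2, nrow(X) > ncol(X))
  if (is.null(colnames(X))) colnames(X) <- paste0("v", seq_len(ncol(X)))
  sds <- apply(X, 2, sd)
  constant <- !is.finite(sds) | sds == 0
  out <- rep(NA_real_, ncol(X))
  names(out) <- colnames(X)
  for (i in seq_len(ncol(X))) {
    if (constant[i]) next
    others <- X[, -i, drop = FALSE]
    fit <- lm.fit(cbind(1, others), X[, i])
    rss <- sum(fit$residuals^2)
    tss <- sum((X[, i] - mean(X[, i]))^2)
    r2 <- 1 - rss / tss
    out[i] <- if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }
  attr(out, "constant") <- constant
  out
}

#' Backward elimination of collinear variables by VIF
#'
#' Iteratively removes the single variable with the largest VIF exceeding
#' `threshold`, recomputing all VIFs after each removal, until every
#' retained variable has VIF at or below the threshold. Ties on the maximal
#' VIF (e.g. an exactly duplicated pair) are broken by removing the variable
#' later in column order, which keeps the procedure deterministic and
#' auditable.
#'
#' @inheritParams compute_vif
#' @param threshold VIF threshold (default 5).
#' @return object of class `vif_report`: list with `retained` (column
#'   names), `removed` (in removal order), and `rounds` (per-round VIF
#'   vectors and the variable removed).
#' @export
vif_backward_eliminate <- function(covariate_matrix, threshold = 5) {
  X <- as.matrix(covariate_matrix)
  if (is.null(colnames(X))) colnames(X) <- paste0("v", seq_len(ncol(X)))
  removed <- character(0)
  rounds <- list()
  repeat {
    if (ncol(X) < 2) break
    v <- compute_vif(X)
    vv <- ifelse(is.na(v), -Inf, v)
    mx <- max(vv)
    if (!(mx > threshold)) {
      rounds[[length(rounds) + 1L]] <- list(vif = v, removed = NA_character_)
      break
    }
    # ties: remove the later column
    drop_i <- max(which(vv == mx))
    rounds[[length(rounds) + 1L]] <- list(vif = v,
                                          removed = colnames(X)[drop_i])
    removed <- c(removed, colnames(X)[drop_i])
    X <- X[, -drop_i, drop = FALSE]
  }
  structure(list(retained = colnames(X), removed = removed, rounds = rounds,
                 threshold = threshold),
            class = "vif_report")
}

#' @export
print.vif_report <- function(x, ...) {
  cat(sprintf("VIF backward elimination (threshold %.3g)\n", x$threshold))
  cat(sprintf("  removed (%d): %s\n", length(x$removed),
              if (length(x$removed)) paste(x$removed, collapse = ", ") else "none"))
  cat(sprintf("  retained (%d): %s\n", length(x$retained),
              paste(x$retained, collapse = ", ")))
  invisible(x)
}

#' Inverse-distance-weighted interpolation at a target location
#'
#' `value = sum_s w_s v_s / sum_s w_s` with `w_s = d_s^(-power)` and `d_s`
#' the great-circle (haversine) distance in kilometres from the target to
#' station s. A station coincident with the target returns that station's
#' value exactly. With no stations the missing-value flag `NA` is returned.
#'
#' @param station_samples data frame with columns `lon`, `lat`, `value`
#'   (one slice: a single variable, year and month).
#' @param target_lon,target_lat target coordinates in decimal degrees.
#' @param power inverse-distance power (default 2).
#' @return interpolated value, or `NA` when no stations are available.
#' @export
idw_interpolate <- function(station_samples, target_lon, target_lat,
                            power = 2) {
  s <- station_samples[is.finite(station_samples$value), , drop = FALSE]
  if (nrow(s) == 0) return(NA_real_)
  d_km <- geosphere::distHaversine(cbind(s$lon, s$lat),
                                   c(target_lon, target_lat)) / 1000
  hit <- which(d_km < 1e-9)
  if (length(hit)) return(s$value[hit[1]])
  w <- d_km^(-power)
  sum(w * s$value) / sum(w)
}

# month windows per variable class; DJF straddles the year boundary
amplitude_windows <- function(variable_class) {
  switch(variable_class,
         physical = list(high = c(6, 7, 8), low = c(12, 1, 2),
                         low_crosses_year = TRUE),
         chembio = list(high = c(8, 9, 10), low = c(3, 4, 5),
                        low_crosses_year = FALSE),
         stop("variable_class must be 'physical' or 'chembio'"))
}

#' Seasonal amplitude of a monthly series
#'
#' For physical variables: mean of June, July, August minus the mean of
#' December, January, February (the winter preceding the summer under the
#' default convention, i.e. December of year t-1 with January/February of
#' year t). For chemical/biological variables: mean of August, September,
#' October minus the mean of March, April, May. A year with any required
#' month absent gets the missing flag `NA`.
#'
#' @param monthly_series data frame with columns `year`, `month`, `value`
#'   for one variable at one location.
#' @param variable_class `"physical"` or `"chembio"`.
#' @param years years to compute amplitudes for (default: all years
#'   present).
#' @param djf_year_convention `"previous"` (default; December of year t-1)
#'   or `"same"` (December of year t) for the winter window.
#' @return data frame `year, amplitude` (`NA` where months are missing).
#' @export
seasonal_amplitude <- function(monthly_series, variable_class,
                               years = NULL,
                               djf_year_convention = c("previous", "same")) {
  djf_year_convention <- match.arg(djf_year_convention)
  win <- amplitude_windows(variable_class)
  ms <- monthly_series
  stopifnot(all(c("year", "month", "value") %in% names(ms)))
  if (is.null(years)) years <- sort(unique(ms$year))
  lookup <- function(yr, mo) {
    v <- ms$value[ms$year == yr & ms$month == mo]
    if (length(v) == 0) NA_real_ else v[length(v)]    # last wins
  }
  amp <- vapply(years, function(yr) {
    hi <- vapply(win$high, function(mo) lookup(yr, mo), numeric(1))
    lo <- vapply(win$low, function(mo) {
      yr_use <- yr
      if (win$low_crosses_year && mo == 12 &&
          djf_year_convention == "previous") {
        yr_use <- yr - 1
      }
      lookup(yr_use, mo)
    }, numeric(1))
    if (anyNA(hi) || anyNA(lo)) NA_real_ else mean(hi) - mean(lo)
  }, numeric(1))
  data.frame(year = as.integer(years), amplitude = amp)
}

#' Interpolate station series to target points and compute amplitudes
#'
#' For every (variable, target point, year, month) slice, interpolates the
#' station values to the target by inverse distance weighting, then reduces
#' the monthly series to one seasonal amplitude per (variable, point,
#' year).
#'
#' @param env_table long environmental table (`variable, lon, lat, year,
#'   month, value`).
#' @param points data frame of target locations (`lon`, `lat`).
#' @param classes named character vector mapping variable names to
#'   `"physical"`/`"chembio"`.
#' @param power inverse-distance power.
#' @param djf_year_convention winter-window convention, see
#'   [seasonal_amplitude()].
#' @return amplitude table: data frame `variable, lon, lat, year,
#'   amplitude`.
#' @export
build_amplitude_table <- function(env_table, points, classes, power = 2,
                                  djf_year_convention = "previous") {
  out <- list()
  for (vn in unique(env_table$variable)) {
    sub <- env_table[env_table$variable == vn, , drop = FALSE]
    cls <- unname(classes[vn])
    if (is.na(cls)) stop("no variable class for ", vn)
    # stations are fixed across time slices, so the distance matrix from
    # every target point to every station is computed once per variable
    st <- unique(sub[, c("lon", "lat")])
    skey <- loc_key(st$lon, st$lat)
    sub$sidx <- match(loc_key(sub$lon, sub$lat), skey)
    Dm <- vapply(seq_len(nrow(st)), function(s) {
      geosphere::distHaversine(cbind(points$lon, points$lat),
                               c(st$lon[s], st$lat[s])) / 1000
    }, numeric(nrow(points)))
    Dm <- matrix(Dm, nrow = nrow(points))
    W <- Dm^(-power)
    slice_id <- paste(sub$year, sub$month)
    slices <- split(sub, slice_id)
    # interpolated value matrix: points x slices
    interp <- vapply(slices, function(sl) {
      v <- rep(NA_real_, nrow(st))
      v[sl$sidx] <- sl$value
      ok <- is.finite(v)
      if (!any(ok)) return(rep(NA_real_, nrow(points)))
      Wk <- W[, ok, drop = FALSE]
      res <- drop(Wk %*% v[ok]) / rowSums(Wk)
      # zero-distance rule: a target coincident with a station takes that
      # station's value exactly
      hit <- which(Dm[, ok, drop = FALSE] < 1e-9, arr.ind = TRUE)
      if (nrow(hit)) res[hit[, 1]] <- v[ok][hit[, 2]]
      res
    }, numeric(nrow(points)))
    interp <- matrix(interp, nrow = nrow(points))
    sl_year <- vapply(slices, function(sl) sl$year[1], numeric(1))
    sl_month <- vapply(slices, function(sl) sl$month[1], numeric(1))
    # amplitude per year, vectorized over target points (same month
    # windows and winter convention as seasonal_amplitude)
    win <- amplitude_windows(cls)
    for (yr in sort(unique(sl_year))) {
      hi_cols <- vapply(win$high, function(mo) {
        k <- which(sl_year == yr & sl_month == mo)
        if (length(k)) k[1] else NA_integer_
      }, integer(1))
      lo_cols <- vapply(win$low, function(mo) {
        yr_use <- yr
        if (win$low_crosses_year && mo == 12 &&
            djf_year_convention == "previous") yr_use <- yr - 1
        k <- which(sl_year == yr_use & sl_month == mo)
        if (length(k)) k[1] else NA_integer_
      }, integer(1))
      if (anyNA(hi_cols) || anyNA(lo_cols)) next
      amp <- rowMeans(interp[, hi_cols, drop = FALSE]) -
        rowMeans(interp[, lo_cols, drop = FALSE])
      ok <- is.finite(amp)
      if (any(ok)) {
        out[[length(out) + 1L]] <- data.frame(
          variable = vn, lon = points$lon[ok], lat = points$lat[ok],
          year = yr, amplitude = amp[ok])
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

loc_key <- function(lon, lat) paste(round(lon, 6), round(lat, 6))

#' Pair responses with lagged amplitudes into a design matrix
#'
#' A response observed at (location, year t) is paired with the seasonal
#' amplitudes at the same location in year t - `lag_years`. Rows with any
#' missing lagged amplitude are dropped listwise and counted. The design
#' gains a leading all-ones column; the index covariates are (longitude,
#' latitude, year).
#'
#' @param amplitude_table data frame `variable, lon, lat, year, amplitude`.
#' @param response_table data frame `species, response, lon, lat, year,
#'   value`.
#' @param lag_years nonnegative lag in years.
#' @return object of class `sivcm_design`: list with `y`, `X` (leading
#'   ones column), `Z` (lon, lat, year), `meta` (species, response, per-row
#'   year), `n_dropped`, `lag_years`.
#' @export
lag_align <- function(amplitude_table, response_table, lag_years) {
  stopifnot(lag_years >= 0)
  at <- amplitude_table
  rt <- response_table
  vars <- sort(unique(at$variable))
  # wide amplitude lookup: (location, year) -> named amplitude vector
  at$key <- paste(loc_key(at$lon, at$lat), at$year)
  amp_map <- split(at, at$key)
  rt <- rt[is.finite(rt$value), , drop = FALSE]
  keys <- paste(loc_key(rt$lon, rt$lat), rt$year - lag_years)
  rows <- vector("list", nrow(rt))
  keep <- logical(nrow(rt))
  for (i in seq_len(nrow(rt))) {
    m <- amp_map[[keys[i]]]
    if (is.null(m)) next
    x <- setNames(rep(NA_real_, length(vars)), vars)
    x[m$variable] <- m$amplitude
    if (anyNA(x)) next
    keep[i] <- TRUE
    rows[[i]] <- x
  }
  n_dropped <- sum(!keep)
  if (!any(keep)) {
    warning("no response rows could be paired with lagged amplitudes")
    return(structure(list(y = numeric(0),
                          X = matrix(numeric(0), 0, length(vars) + 1,
                                     dimnames = list(NULL, c("(Intercept)", vars))),
                          Z = matrix(numeric(0), 0, 3,
                                     dimnames = list(NULL, c("lon", "lat", "year"))),
                          meta = rt[0, ], n_dropped = n_dropped,
                          lag_years = lag_years),
                     class = "sivcm_design"))
  }
  Xv <- do.call(rbind, rows[keep])
  rtk <- rt[keep, , drop = FALSE]
  structure(
    list(y = rtk$value,
         X = cbind(`(Intercept)` = 1, Xv),
         Z = cbind(lon = rtk$lon, lat = rtk$lat, year = rtk$year),
         meta = rtk[, c("species", "response", "year")],
         n_dropped = n_dropped, lag_years = lag_years),
    class = "sivcm_design"
  )
}
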